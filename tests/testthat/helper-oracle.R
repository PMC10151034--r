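# Independent numeric oracles. These deliberately avoid the code paths (and
# the stats:: functions) used by the implementation: the normal CDF comes
# from pracma's complementary error function and the quantile from bisection
# on that CDF, and path enumeration is an unpruned scan of the full edge
# table.

oracle_norm_cdf <- function(x) {
  0.5 * pracma::erfc(-x / sqrt(2))
}

# vectorised bisection on oracle_norm_cdf; 90 halvings of [-40, 40]
oracle_norm_quantile <- function(p) {
  lo <- rep(-40, length(p))
  hi <- rep(40, length(p))
  for (i in 1:90) {
    mid <- (lo + hi) / 2
    below <- oracle_norm_cdf(mid) < p
    lo[below] <- mid[below]
    hi[!below] <- mid[!below]
  }
  (lo + hi) / 2
}

oracle_combine_z <- function(p, eps = 1e-6) {
  p <- pmin(pmax(p, eps), 1 - eps)
  oracle_norm_cdf(sum(oracle_norm_quantile(p)))
}

# All simple paths from `seed` with <= max_steps edges, by brute-force
# extension against the raw edge table; joint probabilities by product, then
# post-hoc threshold and endpoint-type filtering.
oracle_paths <- function(graph, seed, direction, max_steps,
                         min_joint, endpoint_type = NULL) {
  e <- kg_edges(graph)
  ents <- kg_entities(graph)
  res <- list()
  grow <- function(nodes, joint) {
    tip <- nodes[length(nodes)]
    for (i in seq_len(nrow(e))) {
      s <- e$subject_id[i]
      o <- e$object_id[i]
      if (s == o) next
      nxt <- NULL
      if (e$directed[i]) {
        if (direction %in% c("incoming", "both") && o == tip) nxt <- c(nxt, s)
        if (direction %in% c("outgoing", "both") && s == tip) nxt <- c(nxt, o)
      } else {
        if (s == tip) nxt <- o
        if (o == tip) nxt <- s
      }
      for (v in nxt) {
        if (v %in% nodes) next
        j <- joint * e$combined_probability[i]
        res[[length(res) + 1]] <<- list(nodes = c(nodes, v), joint = j)
        if (length(nodes) < max_steps) grow(c(nodes, v), j)
      }
    }
  }
  grow(seed, 1.0)
  keep <- vapply(res, function(p) p$joint >= min_joint, logical(1))
  res <- res[keep]
  if (!is.null(endpoint_type)) {
    term <- vapply(res, function(p) p$nodes[length(p$nodes)], character(1))
    ttype <- ents$entity_type[match(term, ents$id)]
    res <- res[ttype %in% endpoint_type]
  }
  res
}

# canonical sortable signature of a path set, for set comparison
path_signatures <- function(nodes_list) {
  sort(vapply(nodes_list, paste, character(1), collapse = "|"))
}
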