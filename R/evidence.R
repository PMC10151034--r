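# Evidence-based probability assignment and per-triple combination.
#
# Each assertion gets a probability from its evidence: manually curated
# sources are trusted at a fixed high probability, experimental records get
# the probability of their detection method's expert-rated confidence level.
# Redundant records for one triple are then merged into a single edge
# probability. The default merger is unweighted Stouffer (composite Z-score)
# voting: convert each probability to a standard-normal quantile, sum, and
# map the sum back through the normal CDF. Concordant reports above 0.5
# therefore reinforce each other, unlike a (geometric) mean.

#' Specify how redundant record probabilities are combined
#'
#' @param method `"composite_z"` (default) for Stouffer composite Z-score
#'   voting, or `"geometric_mean"`. The mean is kept for comparison only: it
#'   cannot express reinforcement, since n identical reports of p combine to
#'   p exactly.
#' @param clamp_epsilon Probabilities are clamped into
#'   `[clamp_epsilon, 1 - clamp_epsilon]` before the quantile transform, which
#'   is unbounded at 0 and 1. Must lie in (0, 0.01].
#' @param deduplicate Drop records identical on (triple, source database,
#'   method, publication reference) before combining. Mirrored copies of one
#'   experiment across databases are not independent evidence and would
#'   otherwise inflate the combined probability; set `FALSE` to reproduce the
#'   uncorrected behaviour.
#' @return A `combiner_spec` object.
#' @export
combiner_spec <- function(method = c("composite_z", "geometric_mean"),
                          clamp_epsilon = 1e-6, deduplicate = TRUE) {
  method <- arg_match(method)
  if (!is.numeric(clamp_epsilon) || length(clamp_epsilon) != 1 ||
    clamp_epsilon <= 0 || clamp_epsilon > 0.01) {
    abort_validation("clamp_epsilon must lie in (0, 0.01]")
  }
  structure(
    list(
      method = method, clamp_epsilon = as.numeric(clamp_epsilon),
      deduplicate = isTRUE(deduplicate)
    ),
    class = "combiner_spec"
  )
}

#' Assign evidence-based probabilities to assertion records
#'
#' Curated records receive `config$curated_probability`; experimental records
#' receive the probability of their detection method's confidence level.
#' Method codes absent from the configuration are handled per
#' `config$unknown_method_policy`: `"error"` aborts naming the code,
#' `"default_level_1"` falls back to the level-1 probability.
#'
#' @param records A record tibble (see [kg_add_assertions()]); the
#'   `probability` column may be absent or NA.
#' @param config An [evidence_config()].
#' @return The records with `probability` filled in.
#' @export
assign_probabilities <- function(records, config) {
  check_evidence_config(config)
  records <- as_tibble(records)
  if (nrow(records) == 0) {
    records$probability <- double()
    return(records)
  }
  levels <- method_level_for(records$method_code, config)
  records$probability <- ifelse(
    records$evidence_type == "curated",
    config$curated_probability,
    unname(config$level_probabilities[as.character(levels)])
  )
  records
}

# Confidence level for each method code, applying the unknown-method policy.
# Curated rows (method NA alongside evidence_type == "curated") map to NA.
method_level_for <- function(method_code, config) {
  level <- config$method_levels[method_code]
  unknown <- is.na(level) & !is.na(method_code)
  if (any(unknown)) {
    if (config$unknown_method_policy == "error") {
      abort_validation(paste0(
        "unknown detection-method code(s): ",
        paste(unique(method_code[unknown]), collapse = ", ")
      ))
    }
    level[unknown] <- 1L
  }
  unname(level)
}

#' Combine probabilities by composite Z-score (Stouffer) voting
#'
#' Computes `CDF(sum_i Q(p_i))` with `Q` the standard-normal quantile function
#' and `CDF` the standard-normal cumulative distribution. A single value is a
#' fixed point (`CDF(Q(p)) = p`); several concordant values above 0.5 combine
#' to something larger than any of them, modelling that independent
#' experiments reporting the same interaction reinforce each other.
#'
#' @param probabilities Non-empty numeric vector of probabilities in (0, 1).
#' @param spec A [combiner_spec()]; only `clamp_epsilon` is used here.
#' @return A single probability strictly inside (0, 1).
#' @examples
#' combine_composite_z(c(0.8, 0.8)) # ~0.954: two weak reports reinforce
#' @export
combine_composite_z <- function(probabilities, spec = combiner_spec()) {
  check_combine_input(probabilities)
  eps <- spec$clamp_epsilon
  p <- pmin(pmax(probabilities, eps), 1 - eps)
  z <- sum(qnorm(p))
  res <- pnorm(z)
  # the CDF underflows to 0/1 for |z| beyond ~38; keep the contract (0,1)
  pmin(pmax(res, .Machine$double.xmin), 1 - .Machine$double.eps)
}

#' Combine probabilities by geometric mean
#'
#' `(prod_i p_i)^(1/n)`, always between the smallest and largest input. Kept
#' as the non-reinforcing alternative to [combine_composite_z()].
#'
#' @inheritParams combine_composite_z
#' @return A single probability in (0, 1).
#' @export
combine_geometric_mean <- function(probabilities, spec = combiner_spec()) {
  check_combine_input(probabilities)
  exp(mean(log(probabilities)))
}

check_combine_input <- function(probabilities) {
  if (length(probabilities) == 0) {
    abort_validation("cannot combine an empty probability list")
  }
  if (anyNA(probabilities) || any(probabilities <= 0) ||
    any(probabilities >= 1)) {
    abort_validation("probabilities must lie strictly inside (0, 1)")
  }
  invisible(probabilities)
}

#' Recompute every edge's combined probability
#'
#' Applies the graph's combiner (or `spec`, if given) to the record
#' probabilities behind each edge, clearing all stale markers. With
#' `spec$deduplicate` set, records identical on (triple, source database,
#' method code, publication reference) count once; the number dropped is
#' reported via a message.
#'
#' @param graph A `knowledge_graph` whose records all carry probabilities.
#' @param spec Optional [combiner_spec()] overriding the graph's own.
#' @return The graph with `combined_probability` filled on every edge.
#' @export
recombine_edges <- function(graph, spec = NULL) {
  check_graph(graph)
  spec <- spec %||% graph$combiner
  stopifnot(inherits(spec, "combiner_spec"))
  recs <- graph$records
  if (anyNA(recs$probability)) {
    abort_validation("all records need assigned probabilities; see assign_probabilities()")
  }
  combine <- switch(spec$method,
    composite_z = combine_composite_z,
    geometric_mean = combine_geometric_mean
  )
  keys <- edge_key(recs$subject_id, recs$interaction_type, recs$object_id)
  dropped <- 0L
  if (spec$deduplicate && nrow(recs) > 0) {
    dup <- duplicated(paste(
      keys, recs$source_db, recs$method_code, recs$primary_ref,
      sep = EDGE_SEP
    ))
    dropped <- sum(dup)
    recs <- recs[!dup, ]
    keys <- keys[!dup]
  }
  if (dropped > 0) {
    inform(sprintf(
      "recombine_edges: %d duplicate record(s) ignored during combination",
      dropped
    ))
  }
  by_edge <- split(recs$probability, keys)
  combined <- map_dbl(by_edge, combine, spec = spec)
  graph$edges$combined_probability <-
    unname(combined[graph$edges$edge_key])
  graph$combiner <- spec
  graph
}
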