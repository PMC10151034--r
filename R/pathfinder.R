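# Joint-probability path expansion.
#
# The probability that a chain of interactions is simultaneously true is the
# product of the per-edge combined probabilities. Because every edge
# probability is <= 1, extending a path can never raise its joint
# probability, so the depth-first expansion prunes any partial path that has
# already fallen below the threshold without losing a single valid path.

#' Joint probability of a set of interactions
#'
#' The probability that every interaction in the set is true: the product of
#' the individual probabilities. The empty set is the empty conjunction, 1.
#'
#' @param edge_probabilities Numeric vector of probabilities in (0, 1].
#' @return A single number in (0, 1].
#' @examples
#' joint_probability(c(0.99, 0.99)) # 0.9801
#' @export
joint_probability <- function(edge_probabilities) {
  if (length(edge_probabilities) == 0) {
    return(1.0)
  }
  if (anyNA(edge_probabilities) || any(edge_probabilities <= 0) ||
    any(edge_probabilities > 1)) {
    abort_validation("edge probabilities must lie in (0, 1]")
  }
  prod(edge_probabilities)
}

#' Describe a path-expansion query
#'
#' Defaults are the operating point used throughout: paths of at most three
#' interaction steps with joint probability at least 0.93, expanding incoming
#' links and keeping only paths that end at a drug.
#'
#' @param direction Traversal direction from the seed: `"incoming"` follows
#'   edges into the current node (toward upstream participants), `"outgoing"`
#'   follows edges out of it, `"both"` ignores orientation. Undirected edges
#'   are traversable under every direction.
#' @param max_steps Maximum number of edges per path (>= 1).
#' @param min_joint_probability Joint-probability threshold in (0, 1].
#' @param endpoint_type Optional entity type the path must end at
#'   (intermediate nodes are unrestricted); `NULL` keeps every endpoint.
#' @return An `expansion_query` object.
#' @export
expansion_query <- function(direction = c("incoming", "outgoing", "both"),
                            max_steps = 3L,
                            min_joint_probability = 0.93,
                            endpoint_type = "drug") {
  direction <- arg_match(direction)
  if (!is.numeric(max_steps) || length(max_steps) != 1 || max_steps < 1) {
    abort_validation("max_steps must be an integer >= 1")
  }
  if (!is.numeric(min_joint_probability) ||
    min_joint_probability <= 0 || min_joint_probability > 1) {
    abort_validation("min_joint_probability must lie in (0, 1]")
  }
  if (!is.null(endpoint_type) && !endpoint_type %in% ENTITY_TYPES) {
    abort_validation(paste0("unknown endpoint_type: ", endpoint_type))
  }
  structure(
    list(
      direction = direction, max_steps = as.integer(max_steps),
      min_joint_probability = as.numeric(min_joint_probability),
      endpoint_type = endpoint_type
    ),
    class = "expansion_query"
  )
}

# Edge-row candidates leaving `node` under the query direction, with the far
# endpoint for each. Directed edges are traversed only along the direction;
# undirected edges go both ways. Self-loops never advance a path.
traversable_steps <- function(graph, node, direction) {
  e <- graph$edges
  rows <- switch(direction,
    incoming = graph$index$incoming[[node]],
    outgoing = graph$index$outgoing[[node]],
    both = union(
      graph$index$incoming[[node]], graph$index$outgoing[[node]]
    )
  )
  if (length(rows) == 0) {
    return(list(rows = integer(), nxt = character()))
  }
  nxt <- ifelse(e$subject_id[rows] == node, e$object_id[rows], e$subject_id[rows])
  keep <- nxt != node
  list(rows = rows[keep], nxt = nxt[keep])
}

#' Expand paths from a seed entity
#'
#' Depth-first enumeration of every simple path (no node revisited) from the
#' seed that satisfies the query's step and joint-probability limits. A
#' partial path is pruned as soon as its joint probability drops below the
#' threshold; anti-monotonicity of the product guarantees this loses nothing.
#'
#' @param graph A `knowledge_graph` with combined edge probabilities (run
#'   [recombine_edges()] first).
#' @param seed A registered entity id.
#' @param query An [expansion_query()].
#' @return A `kg_paths` tibble with one row per path: `terminal_id`, `steps`,
#'   `joint_probability`, and list columns `node_ids` (seed first),
#'   `edge_keys`, `edge_types`, `edge_probabilities`.
#' @export
kg_expand <- function(graph, seed, query = expansion_query()) {
  check_graph(graph)
  stopifnot(inherits(query, "expansion_query"))
  if (!seed %in% graph$entities$id) {
    abort_missing_entity(seed)
  }
  if (anyNA(graph$edges$combined_probability)) {
    abort_validation("graph has stale edges; run recombine_edges() first")
  }
  probs <- graph$edges$combined_probability
  acc <- list()
  walk <- function(node, visited, edge_rows, joint) {
    if (length(edge_rows) >= query$max_steps) {
      return()
    }
    step <- traversable_steps(graph, node, query$direction)
    for (k in seq_along(step$rows)) {
      row <- step$rows[k]
      nxt <- step$nxt[k]
      if (nxt %in% visited) next
      j <- joint * probs[row]
      if (j < query$min_joint_probability) next
      path_rows <- c(edge_rows, row)
      acc[[length(acc) + 1]] <<- list(
        nodes = c(visited, nxt), rows = path_rows, joint = j
      )
      walk(nxt, c(visited, nxt), path_rows, j)
    }
  }
  walk(seed, seed, integer(), 1.0)

  if (!is.null(query$endpoint_type)) {
    terminal <- map_chr(acc, function(p) p$nodes[length(p$nodes)])
    acc <- acc[entity_type_of(graph, terminal) %in% query$endpoint_type]
  }
  e <- graph$edges
  paths <- tibble(
    terminal_id = map_chr(acc, function(p) p$nodes[length(p$nodes)]),
    steps = map_int(acc, function(p) length(p$rows)),
    joint_probability = map_dbl(acc, "joint"),
    node_ids = map(acc, "nodes"),
    edge_keys = map(acc, function(p) e$edge_key[p$rows]),
    edge_types = map(acc, function(p) e$interaction_type[p$rows]),
    edge_probabilities = map(acc, function(p) probs[p$rows])
  )
  class(paths) <- c("kg_paths", class(paths))
  paths
}

#' Find drug-repositioning candidates for a disease
#'
#' Expands incoming links from the disease, keeps paths ending at a drug,
#' groups them by terminal drug, and reports each drug's best path: highest
#' joint probability, ties broken by fewer steps, then by the lexicographic
#' node-id sequence. Rows are sorted by joint probability (descending), steps
#' (ascending), then drug label.
#'
#' @param graph A `knowledge_graph` with combined edge probabilities.
#' @param disease_id Id of a disease-type entity.
#' @param min_joint_probability,max_steps Filter thresholds; defaults 0.93
#'   and 3.
#' @return A `candidate_table` tibble with columns `drug_id`, `drug_label`,
#'   `disease_id`, `steps`, `joint_probability`, `path_node_ids` and
#'   `path_edge_types` (pipe-separated, ordered drug to disease).
#' @export
find_candidates <- function(graph, disease_id,
                            min_joint_probability = 0.93, max_steps = 3L) {
  check_graph(graph)
  if (!disease_id %in% graph$entities$id) {
    abort_missing_entity(disease_id)
  }
  if (!identical(entity_type_of(graph, disease_id), "disease")) {
    abort_validation(paste0(disease_id, " is not a disease-type entity"))
  }
  paths <- kg_expand(graph, disease_id, expansion_query(
    direction = "incoming", max_steps = max_steps,
    min_joint_probability = min_joint_probability, endpoint_type = "drug"
  ))
  if (nrow(paths) == 0) {
    return(empty_candidate_table())
  }
  # paths run disease -> ... -> drug; report them drug -> ... -> disease
  paths <- mutate(paths,
    path_node_ids = map_chr(.data$node_ids, function(n) {
      paste(rev(n), collapse = "|")
    }),
    path_edge_types = map_chr(.data$edge_types, function(t) {
      paste(rev(t), collapse = "|")
    })
  )
  best <- paths |>
    mutate(drug_id = .data$terminal_id) |>
    arrange(
      desc(.data$joint_probability), .data$steps, .data$path_node_ids
    ) |>
    group_by(.data$drug_id) |>
    slice(1) |>
    ungroup()
  labels <- kg_entities(graph)
  out <- best |>
    mutate(
      drug_label = labels$label[match(.data$drug_id, labels$id)],
      disease_id = disease_id
    ) |>
    select(
      "drug_id", "drug_label", "disease_id", "steps",
      "joint_probability", "path_node_ids", "path_edge_types"
    ) |>
    arrange(
      desc(.data$joint_probability), .data$steps, .data$drug_label
    )
  class(out) <- c("candidate_table", class(out))
  out
}

empty_candidate_table <- function() {
  out <- tibble(
    drug_id = character(), drug_label = character(),
    disease_id = character(), steps = integer(),
    joint_probability = double(), path_node_ids = character(),
    path_edge_types = character()
  )
  class(out) <- c("candidate_table", class(out))
  out
}

#' Write a candidate table as the summary CSV
#'
#' Joint probabilities are printed with six decimal places.
#'
#' @param candidates A `candidate_table` from [find_candidates()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_candidates_csv <- function(candidates, path) {
  out <- as_tibble(candidates)
  out$joint_probability <- sprintf("%.6f", out$joint_probability)
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a candidate summary CSV
#'
#' @param path A CSV written by [write_candidates_csv()].
#' @return A `candidate_table` tibble.
#' @export
read_candidates_csv <- function(path) {
  if (!file.exists(path)) {
    abort_io(paste0("cannot read candidate CSV: ", path))
  }
  out <- readr::read_csv(
    path,
    col_types = readr::cols(
      drug_id = readr::col_character(),
      drug_label = readr::col_character(),
      disease_id = readr::col_character(),
      steps = readr::col_integer(),
      joint_probability = readr::col_double(),
      path_node_ids = readr::col_character(),
      path_edge_types = readr::col_character()
    ),
    progress = FALSE
  )
  class(out) <- c("candidate_table", class(out))
  out
}

#' Plot a candidate table
#'
#' Lollipop chart of each candidate drug's best-path joint probability,
#' coloured by step count, with the default 0.93 operating threshold marked.
#'
#' @param object A `candidate_table`.
#' @param threshold Joint-probability threshold to mark; default 0.93.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.candidate_table <- function(object, threshold = 0.93, ...) {
  dat <- as_tibble(object)
  dat$drug_label <- stats::reorder(dat$drug_label, dat$joint_probability)
  ggplot2::ggplot(
    dat,
    ggplot2::aes(
      x = .data$joint_probability, y = .data$drug_label,
      colour = factor(.data$steps)
    )
  ) +
    ggplot2::geom_segment(
      ggplot2::aes(x = 0, xend = .data$joint_probability, yend = .data$drug_label),
      linewidth = 0.3, colour = "grey70"
    ) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_vline(xintercept = threshold, linetype = "dashed") +
    ggplot2::labs(
      x = "joint probability of best path", y = NULL, colour = "steps",
      title = "Drug-repositioning candidates"
    ) +
    ggplot2::theme_minimal()
}

#' Substring lookup of entities by label or synonym
#'
#' Case-insensitive; intended as the command-line analogue of a typeahead
#' search box.
#'
#' @param graph A `knowledge_graph`.
#' @param text Query substring.
#' @param entity_type Optional entity-type restriction.
#' @return A tibble of matching entities.
#' @export
kg_lookup <- function(graph, text, entity_type = NULL) {
  check_graph(graph)
  ent <- graph$entities
  if (!is.null(entity_type)) {
    ent <- ent[ent$entity_type %in% entity_type, ]
  }
  hay <- tolower(paste(
    ent$id, ent$label, map_chr(ent$synonyms, paste, collapse = " ")
  ))
  ent[grepl(tolower(text), hay, fixed = TRUE), ]
}
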