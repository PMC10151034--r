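# Hit-based information-retrieval evaluation of candidate tables.
#
# Ground truth is a table of (drug, disease) pairs labelled with their
# position in the drug-discovery pipeline. A "hit" is any pairing with a
# published positive in vivo / in vitro experiment or a clinical-trial
# record -- every status except "novel". Precision is hits among returned
# candidates; recall is returned hits among all known hits. Sweeping the
# joint-probability and step thresholds over these metrics is how the 0.93 /
# 3-step operating point is selected.

#' Read drug-disease hit labels
#'
#' @param path Tab-separated file with header columns `drug_id`, `disease_id`,
#'   `status`; statuses from `approved`, `phase_iii`, `phase_ii`, `phase_i`,
#'   `case_study`, `in_vitro`, `in_vivo`, `novel`.
#' @return A `hit_labels` tibble.
#' @export
read_hit_labels <- function(path) {
  if (!file.exists(path)) {
    abort_io(paste0("cannot read label table: ", path))
  }
  labels <- readr::read_tsv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  hit_labels(labels)
}

#' Validate a hit-label table
#'
#' @param labels Data frame with columns `drug_id`, `disease_id`, `status`.
#' @return A `hit_labels` tibble.
#' @export
hit_labels <- function(labels) {
  labels <- as_tibble(labels)
  missing <- setdiff(c("drug_id", "disease_id", "status"), names(labels))
  if (length(missing) > 0) {
    abort_validation(paste0(
      "label table is missing column(s): ", paste(missing, collapse = ", ")
    ))
  }
  bad <- setdiff(unique(labels$status), HIT_STATUSES)
  if (length(bad) > 0) {
    abort_validation(paste0(
      "unknown status value(s): ", paste(bad, collapse = ", "),
      " (expected ", paste(HIT_STATUSES, collapse = ", "), ")"
    ))
  }
  labels <- distinct(labels, .data$drug_id, .data$disease_id, .keep_all = TRUE)
  class(labels) <- c("hit_labels", class(labels))
  labels
}

#' Precision, recall and f-measure of a candidate table
#'
#' @param candidates A `candidate_table` (see [find_candidates()]).
#' @param labels A `hit_labels` table; every known hit for the disease should
#'   be present, since its hit rows are the recall denominator.
#' @param strict Error on candidate pairs absent from `labels`; when `FALSE`
#'   (default) unlabeled pairs count as non-hits and their number is reported
#'   via a message.
#' @param f_mean `"harmonic"` (the conventional F1, default) or `"geometric"`
#'   (`sqrt(P * R)`).
#' @return A one-row tibble: `precision`, `recall`, `f_measure`,
#'   `n_candidates`, `n_hits_returned`, `n_known_hits`, `n_unlabeled`. All
#'   three metrics are 0 (with a warning) when their denominators vanish.
#' @export
precision_recall_f <- function(candidates, labels, strict = FALSE,
                               f_mean = c("harmonic", "geometric")) {
  f_mean <- arg_match(f_mean)
  if (!inherits(labels, "hit_labels")) {
    labels <- hit_labels(labels)
  }
  if (nrow(labels) == 0) {
    abort_validation("label table is empty")
  }
  cand <- as_tibble(candidates)
  key <- function(d, z) paste(d, z, sep = EDGE_SEP)
  lab_key <- key(labels$drug_id, labels$disease_id)
  cand_key <- key(cand$drug_id, cand$disease_id)
  unlabeled <- !cand_key %in% lab_key
  if (any(unlabeled)) {
    if (strict) {
      abort_validation(paste0(
        "candidate pair(s) without labels: ",
        paste(head(cand_key[unlabeled], 5), collapse = "; ")
      ))
    }
    inform(sprintf(
      "precision_recall_f: %d unlabeled candidate pair(s) counted as non-hits",
      sum(unlabeled)
    ))
  }
  hit_keys <- lab_key[labels$status %in% hit_statuses()]
  n_candidates <- nrow(cand)
  n_hits_returned <- sum(cand_key %in% hit_keys)
  n_known_hits <- length(hit_keys)

  precision <- if (n_candidates == 0) {
    warn("precision_recall_f: no candidates returned; metrics set to 0")
    0
  } else {
    n_hits_returned / n_candidates
  }
  recall <- if (n_known_hits == 0) 0 else n_hits_returned / n_known_hits
  f_measure <- if (precision + recall == 0) {
    0
  } else if (f_mean == "harmonic") {
    2 * precision * recall / (precision + recall)
  } else {
    sqrt(precision * recall)
  }
  tibble(
    precision = precision, recall = recall, f_measure = f_measure,
    n_candidates = n_candidates, n_hits_returned = n_hits_returned,
    n_known_hits = n_known_hits, n_unlabeled = sum(unlabeled)
  )
}

#' Sweep a candidate-filter threshold and evaluate each point
#'
#' Re-runs [find_candidates()] at every grid value of one threshold, holding
#' the other at its default (steps <= 3 while sweeping the probability axis;
#' p >= 0.93 while sweeping steps), and evaluates each candidate set against
#' the labels. The f-measure-optimal threshold is reported with ties broken
#' toward the stricter value (higher probability / fewer steps).
#'
#' @param graph A `knowledge_graph` with combined edge probabilities.
#' @param disease_id Disease entity id.
#' @param labels A `hit_labels` table.
#' @param axis `"joint_probability"` or `"steps"`.
#' @param grid Threshold grid; defaults to 0.50..0.99 by 0.01 for the
#'   probability axis and 1..6 steps for the step axis.
#' @param f_mean Passed to [precision_recall_f()].
#' @return A `sweep_result` with a `points` tibble (one row per grid value)
#'   and the optimum; see [tidy.sweep_result()] and [glance.sweep_result()].
#' @export
threshold_sweep <- function(graph, disease_id, labels,
                            axis = c("joint_probability", "steps"),
                            grid = NULL,
                            f_mean = c("harmonic", "geometric")) {
  axis <- arg_match(axis)
  f_mean <- arg_match(f_mean)
  if (is.null(grid)) {
    grid <- if (axis == "joint_probability") seq(0.50, 0.99, by = 0.01) else 1:6
  }
  if (length(grid) == 0 || is.unsorted(grid)) {
    abort_validation("grid must be non-empty and sorted ascending")
  }
  points <- map(grid, function(g) {
    cand <- if (axis == "joint_probability") {
      find_candidates(graph, disease_id, min_joint_probability = g)
    } else {
      find_candidates(graph, disease_id, max_steps = g)
    }
    metrics <- withCallingHandlers(
      precision_recall_f(cand, labels, strict = FALSE, f_mean = f_mean),
      warning = function(w) invokeRestart("muffleWarning"),
      message = function(m) invokeRestart("muffleMessage")
    )
    mutate(metrics, threshold = g, .before = 1)
  }) |>
    bind_rows() |>
    select(
      "threshold", "precision", "recall", "f_measure", "n_candidates"
    )
  best_f <- max(points$f_measure)
  at_best <- points$threshold[points$f_measure == best_f]
  optimum <- if (axis == "joint_probability") max(at_best) else min(at_best)
  structure(
    list(
      axis = axis, points = points, optimum = optimum,
      optimum_f = best_f, f_mean = f_mean, disease_id = disease_id
    ),
    class = "sweep_result"
  )
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf(
    "<sweep_result> axis: %s, %d points, f-optimal threshold: %s (f = %.4f)\n",
    x$axis, nrow(x$points), format(x$optimum), x$optimum_f
  ))
  print(x$points)
  invisible(x)
}

#' Tidy a threshold sweep
#'
#' @param x A `sweep_result`.
#' @param ... Unused.
#' @return The per-threshold metrics tibble.
#' @export
tidy.sweep_result <- function(x, ...) {
  x$points
}

#' One-row summary of a threshold sweep
#'
#' @param x A `sweep_result`.
#' @param ... Unused.
#' @return A tibble with the axis, the f-optimal threshold and its metrics.
#' @export
glance.sweep_result <- function(x, ...) {
  at <- x$points[x$points$threshold == x$optimum, ]
  tibble(
    axis = x$axis, optimal_threshold = x$optimum,
    precision = at$precision, recall = at$recall, f_measure = at$f_measure,
    n_candidates = at$n_candidates, f_mean = x$f_mean
  )
}

#' Plot a threshold sweep
#'
#' Precision, recall and f-measure against the swept threshold, with the
#' f-optimal threshold marked.
#'
#' @param object A `sweep_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sweep_result <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object$points, c("precision", "recall", "f_measure"),
    names_to = "metric", values_to = "value"
  )
  ggplot2::ggplot(
    long,
    ggplot2::aes(.data$threshold, .data$value, colour = .data$metric)
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_vline(xintercept = object$optimum, linetype = "dashed") +
    ggplot2::labs(
      x = if (object$axis == "joint_probability") {
        "minimum joint probability"
      } else {
        "maximum interaction steps"
      },
      y = NULL,
      title = sprintf("Threshold sweep (%s axis)", object$axis)
    ) +
    ggplot2::theme_minimal()
}

#' Write sweep points as CSV
#'
#' @param sweep A `sweep_result`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_sweep_csv <- function(sweep, path) {
  readr::write_csv(sweep$points, path, progress = FALSE)
  invisible(path)
}

#' Scott's Pi inter-annotator agreement
#'
#' Chance-corrected agreement between two annotators over a shared category
#' set. Observed agreement `Ao` is the fraction of items both annotators
#' labelled identically; expected agreement `Ae` is the sum of squared pooled
#' marginal category proportions (both annotators' labels pooled, which is
#' what distinguishes Pi from Cohen's kappa); `pi = (Ao - Ae) / (1 - Ae)`.
#'
#' @param annotations_a,annotations_b Equal-length non-empty vectors of
#'   category labels.
#' @return A one-row tibble: `observed_agreement`, `expected_agreement`,
#'   `pi`, `n_items`.
#' @examples
#' scotts_pi(c(1, 1, 2, 2), c(1, 2, 1, 2)) # Ao = 0.5, Ae = 0.5, pi = 0
#' @export
scotts_pi <- function(annotations_a, annotations_b) {
  if (length(annotations_a) != length(annotations_b)) {
    abort_validation("annotation vectors must have equal length")
  }
  if (length(annotations_a) == 0) {
    abort_validation("annotation vectors must be non-empty")
  }
  a <- as.character(annotations_a)
  b <- as.character(annotations_b)
  ao <- mean(a == b)
  pooled <- table(c(a, b)) / (2 * length(a))
  ae <- sum(pooled^2)
  if (ae >= 1) {
    abort(
      "Scott's Pi is undefined when both annotators use a single category",
      class = "drugrepo_undefined_pi"
    )
  }
  tibble(
    observed_agreement = ao, expected_agreement = as.numeric(ae),
    pi = (ao - ae) / (1 - ae), n_items = length(a)
  )
}
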