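# Readers for the tabular source formats and the evidence-confidence
# configuration.
#
# Three desk-scale dialects are supported, all tab-separated with a header:
#
#   * PSI-MITAB-like protein-protein interactions (minimal 6-column dialect:
#     interactor_a, interactor_b, detection_method, interaction_type,
#     source_db, publication_ref; extra columns are ignored by name)
#   * drug-target tables (drug_id, drug_name, target_id, optional action)
#   * gene-disease association tables (gene_id, disease_id, disease_label)
#
# Every row becomes one assertion record carrying its provenance; evidence
# probabilities are taken from an EvidenceConfig, the flat-file stand-in for
# an evidence-code ontology: curated sources get one fixed probability,
# experimental detection methods are rated into confidence levels 1-3.

PPI_INTERACTION_TYPE <- "psi-mi:MI:0915" # physical association
DRUG_TARGET_TYPE <- "sio:targets"
GENE_DISEASE_TYPE <- "sio:is-associated-with"

#' Build an evidence-confidence configuration
#'
#' @param curated_sources Character vector of source database names whose
#'   assertions are trusted at `curated_probability`.
#' @param method_levels Named integer vector mapping detection-method codes
#'   (e.g. PSI-MI `"MI:0018"`) to confidence levels 1, 2 or 3: 1 = weak
#'   evidence needing independent verification, 2 = generally reliable,
#'   3 = high quality with few false positives.
#' @param level_probabilities Named numeric vector with names `"1"`, `"2"`,
#'   `"3"`; defaults 0.8, 0.95, 0.99.
#' @param curated_probability Probability for curated assertions; default
#'   0.999, and always greater than every level probability.
#' @param unknown_method_policy `"error"` or `"default_level_1"`.
#' @param id_aliases Optional named character vector mapping source-specific
#'   identifiers to their canonical namespace, applied by every reader before
#'   graph insertion.
#' @return An `evidence_config` object.
#' @export
evidence_config <- function(curated_sources = character(),
                            method_levels = integer(),
                            level_probabilities = c(
                              "1" = 0.8, "2" = 0.95, "3" = 0.99
                            ),
                            curated_probability = 0.999,
                            unknown_method_policy = c(
                              "error", "default_level_1"
                            ),
                            id_aliases = character()) {
  unknown_method_policy <- arg_match(unknown_method_policy)
  lp <- level_probabilities
  if (!setequal(names(lp), c("1", "2", "3"))) {
    abort_validation("level_probabilities must have exactly the names 1, 2, 3")
  }
  lp <- lp[c("1", "2", "3")]
  if (any(lp <= 0 | lp >= 1) || curated_probability <= 0 ||
    curated_probability >= 1) {
    abort_validation("all probabilities must lie strictly inside (0, 1)")
  }
  if (any(curated_probability <= lp)) {
    abort_validation(
      "curated_probability must exceed every level probability"
    )
  }
  ml <- as.integer(method_levels)
  names(ml) <- names(method_levels)
  if (length(ml) > 0 && !all(ml %in% 1:3)) {
    abort_validation("method levels must be drawn from {1, 2, 3}")
  }
  structure(
    list(
      curated_sources = as.character(curated_sources),
      method_levels = ml,
      level_probabilities = lp,
      curated_probability = as.numeric(curated_probability),
      unknown_method_policy = unknown_method_policy,
      id_aliases = id_aliases
    ),
    class = "evidence_config"
  )
}

check_evidence_config <- function(config) {
  if (!inherits(config, "evidence_config")) {
    abort_validation("expected an evidence_config object")
  }
  invisible(config)
}

#' Load an evidence configuration from YAML
#'
#' Recognised keys: `curated_sources` (list), `method_levels` (map of method
#' code to level 1-3), `level_probabilities` (map with keys 1, 2, 3),
#' `curated_probability`, `unknown_method_policy`, `id_aliases`. Omitted
#' probability keys fall back to the defaults 0.8 / 0.95 / 0.99 and 0.999.
#'
#' @param path Path to a YAML file.
#' @return An [evidence_config()].
#' @export
load_evidence_config <- function(path) {
  if (!file.exists(path)) {
    abort_io(paste0("cannot read evidence config: ", path))
  }
  raw <- yaml::read_yaml(path)
  lp <- c("1" = 0.8, "2" = 0.95, "3" = 0.99)
  if (!is.null(raw$level_probabilities)) {
    given <- unlist(raw$level_probabilities)
    bad <- setdiff(names(given), c("1", "2", "3"))
    if (length(bad) > 0) {
      abort_validation(paste0(
        "level_probabilities has level(s) outside {1,2,3}: ",
        paste(bad, collapse = ", ")
      ))
    }
    lp[names(given)] <- as.numeric(given)
  }
  ml <- integer()
  if (!is.null(raw$method_levels)) {
    ml <- unlist(raw$method_levels)
  }
  evidence_config(
    curated_sources = as.character(unlist(raw$curated_sources)),
    method_levels = ml,
    level_probabilities = lp,
    curated_probability = raw$curated_probability %||% 0.999,
    unknown_method_policy = raw$unknown_method_policy %||% "error",
    id_aliases = unlist(raw$id_aliases) %||% character()
  )
}

#' Default illustrative evidence configuration
#'
#' A small user-replaceable method-code table covering common PSI-MI
#' detection methods; the full expert rating of every method is data, not
#' algorithm, and can be supplied via [load_evidence_config()].
#'
#' @return An [evidence_config()].
#' @export
default_evidence_config <- function() {
  evidence_config(
    curated_sources = c("drugbank", "omim", "cosmic"),
    method_levels = c(
      "MI:0018" = 1L, # two hybrid
      "MI:0045" = 1L, # experimental interaction detection (generic)
      "MI:0096" = 2L, # pull down
      "MI:0006" = 2L, # anti bait coimmunoprecipitation
      "MI:0019" = 2L, # coimmunoprecipitation
      "MI:0114" = 3L, # x-ray crystallography
      "MI:0077" = 3L # nuclear magnetic resonance
    ),
    unknown_method_policy = "default_level_1"
  )
}

#' Serialise an evidence configuration to YAML
#'
#' Inverse of [load_evidence_config()].
#'
#' @param config An [evidence_config()].
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_evidence_config <- function(config, path) {
  check_evidence_config(config)
  out <- list(
    curated_sources = as.list(config$curated_sources),
    curated_probability = config$curated_probability,
    level_probabilities = as.list(config$level_probabilities),
    method_levels = as.list(config$method_levels),
    unknown_method_policy = config$unknown_method_policy
  )
  if (length(config$id_aliases) > 0) {
    out$id_aliases <- as.list(config$id_aliases)
  }
  yaml::write_yaml(out, path)
  invisible(path)
}

apply_aliases <- function(ids, config) {
  hit <- match(ids, names(config$id_aliases))
  ifelse(is.na(hit), ids, unname(config$id_aliases[hit]))
}

read_table_checked <- function(path, required, reader_name) {
  if (!file.exists(path)) {
    abort_io(paste0(reader_name, ": cannot read ", path))
  }
  tab <- readr::read_tsv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0) {
    abort_io(paste0(
      reader_name, ": ", path, " is missing column(s): ",
      paste(missing, collapse = ", ")
    ))
  }
  tab
}

blankish <- function(x) is.na(x) | !nzchar(trimws(x))

#' Read a PSI-MITAB-like protein-protein interaction table
#'
#' Emits one undirected experimental assertion per binary row. Rows with a
#' missing interactor id and n-ary/complex rows (a `complex:`-prefixed
#' interactor or an `expansion` column value other than `none`) are skipped,
#' with the skip count reported via a message.
#'
#' @param path Tab-separated file with header columns `interactor_a`,
#'   `interactor_b`, `detection_method`, `interaction_type`, `source_db`,
#'   `publication_ref` (extra columns ignored).
#' @param config An [evidence_config()]; supplies the method-level
#'   probabilities and the unknown-method policy.
#' @return A record tibble with probabilities assigned and endpoint
#'   type/label columns for auto-registration (entity type `protein`).
#' @export
read_mitab <- function(path, config) {
  check_evidence_config(config)
  required <- c(
    "interactor_a", "interactor_b", "detection_method",
    "interaction_type", "source_db", "publication_ref"
  )
  tab <- read_table_checked(path, required, "read_mitab")
  n_total <- nrow(tab)
  is_complex <- grepl("^complex:", tab$interactor_a) |
    grepl("^complex:", tab$interactor_b)
  if ("expansion" %in% names(tab)) {
    is_complex <- is_complex |
      (!blankish(tab$expansion) & tab$expansion != "none")
  }
  keep <- !blankish(tab$interactor_a) & !blankish(tab$interactor_b) &
    !is_complex
  if (any(!keep)) {
    inform(sprintf(
      "read_mitab: skipped %d of %d rows (missing ids or n-ary complexes)",
      sum(!keep), n_total
    ))
  }
  tab <- tab[keep, ]
  records <- tibble(
    subject_id = apply_aliases(tab$interactor_a, config),
    interaction_type = ifelse(
      blankish(tab$interaction_type), PPI_INTERACTION_TYPE, tab$interaction_type
    ),
    object_id = apply_aliases(tab$interactor_b, config),
    directed = FALSE,
    source_db = tab$source_db,
    evidence_type = "experimental",
    method_code = tab$detection_method,
    primary_ref = ifelse(blankish(tab$publication_ref), "", tab$publication_ref),
    subject_type = "protein",
    subject_label = sub("^[^:]*:", "", apply_aliases(tab$interactor_a, config)),
    object_type = "protein",
    object_label = sub("^[^:]*:", "", apply_aliases(tab$interactor_b, config))
  )
  assign_probabilities(records, config)
}

#' Read a drug-target table
#'
#' Emits directed curated drug-to-protein assertions (source `drugbank`,
#' probability `config$curated_probability`).
#'
#' @param path Tab-separated file with header columns `drug_id`, `drug_name`,
#'   `target_id`; optional `action`.
#' @inheritParams read_mitab
#' @return A record tibble with probabilities assigned.
#' @export
read_drug_targets <- function(path, config) {
  check_evidence_config(config)
  tab <- read_table_checked(
    path, c("drug_id", "drug_name", "target_id"), "read_drug_targets"
  )
  keep <- !blankish(tab$drug_id) & !blankish(tab$target_id)
  if (nrow(tab) == 0) {
    warn("read_drug_targets: empty table")
  } else if (any(!keep)) {
    inform(sprintf(
      "read_drug_targets: skipped %d of %d rows (missing ids)",
      sum(!keep), nrow(tab)
    ))
  }
  tab <- tab[keep, ]
  records <- tibble(
    subject_id = tab$drug_id,
    interaction_type = DRUG_TARGET_TYPE,
    object_id = apply_aliases(tab$target_id, config),
    directed = TRUE,
    source_db = "drugbank",
    evidence_type = "curated",
    method_code = NA_character_,
    primary_ref = "",
    subject_type = "drug",
    subject_label = tab$drug_name,
    object_type = "protein",
    object_label = sub("^[^:]*:", "", apply_aliases(tab$target_id, config))
  )
  assign_probabilities(records, config)
}

#' Read a gene-disease association table
#'
#' Emits directed curated gene-to-disease assertions.
#'
#' @param path Tab-separated file with header columns `gene_id`, `disease_id`,
#'   `disease_label`.
#' @param source_db `"omim"` or `"cosmic"`.
#' @inheritParams read_mitab
#' @return A record tibble with probabilities assigned.
#' @export
read_gene_disease <- function(path, source_db = c("omim", "cosmic"), config) {
  source_db <- arg_match(source_db)
  check_evidence_config(config)
  tab <- read_table_checked(
    path, c("gene_id", "disease_id", "disease_label"), "read_gene_disease"
  )
  keep <- !blankish(tab$gene_id) & !blankish(tab$disease_id)
  if (any(!keep)) {
    inform(sprintf(
      "read_gene_disease: skipped %d of %d rows (missing ids)",
      sum(!keep), nrow(tab)
    ))
  }
  tab <- tab[keep, ]
  records <- tibble(
    subject_id = apply_aliases(tab$gene_id, config),
    interaction_type = GENE_DISEASE_TYPE,
    object_id = tab$disease_id,
    directed = TRUE,
    source_db = source_db,
    evidence_type = "curated",
    method_code = NA_character_,
    primary_ref = "",
    subject_type = "gene",
    subject_label = sub("^[^:]*:", "", apply_aliases(tab$gene_id, config)),
    object_type = "disease",
    object_label = ifelse(
      blankish(tab$disease_label), tab$disease_id, tab$disease_label
    )
  )
  assign_probabilities(records, config)
}
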