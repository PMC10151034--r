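# Deterministic synthetic source-data generators.
#
# Two generators back the test and evaluation harness:
#
#   * generate_random_kg() emulates desk-scale extracts of the real sources
#     (a MITAB-like PPI table, a drug-target table, gene-disease tables) for
#     property tests, together with a manifest of every planted record's
#     probability so downstream edge probabilities can be recomputed
#     independently.
#
#   * generate_table1_replica() rebuilds the published melanoma neighbourhood:
#     25 candidate drugs reaching melanoma in 2 or 3 interaction steps whose
#     joint probabilities round to the printed values (0.93/0.95/0.97/0.98),
#     plus decoy drugs that fail the 0.93 / 3-step filter and make that
#     operating point the f-measure optimum. The original knowledge base's
#     per-edge probabilities are not recoverable; the replica's evidence
#     configuration (curated 0.99, levels 0.73/0.95/0.97) is chosen so the
#     planted paths reproduce the printed roundings, and is explicitly NOT
#     claimed to equal the original values.

MELANOMA_ID <- "efo:EFO_0000756"

#' The published 25-drug melanoma candidate table
#'
#' The reference worked example shipped with the package: per drug its
#' discovery status (`approved` through `novel`), acting pathway, interaction
#' steps to melanoma, and the joint probability rounded to two decimals.
#'
#' @return A tibble with columns `status`, `drug`, `pathway`, `steps`,
#'   `joint_p`.
#' @export
melanoma_reference_table <- function() {
  path <- system.file(
    "extdata", "melanoma_reference_candidates.tsv",
    package = "drugrepo", mustWork = TRUE
  )
  readr::read_tsv(
    path,
    col_types = readr::cols(
      status = readr::col_character(), drug = readr::col_character(),
      pathway = readr::col_character(), steps = readr::col_integer(),
      joint_p = readr::col_double()
    ),
    progress = FALSE
  )
}

replica_drug_id <- function(label) {
  paste0("drugbank:DB_", gsub("[^A-Za-z0-9]+", "_", toupper(label)))
}

# Route plan for the replica: for 2-step drugs the drug targets the disease
# gene itself; 3-step drugs go drug -> target protein -- pathway gene ->
# melanoma, with the middle PPI edge's record levels chosen so the joint
# probability reproduces the printed rounding (see module header).
replica_routes <- function() {
  tribble_routes <- list(
    # drug                    target             via             mid levels
    c("Vemurafenib",          "hgnc:BRAF",       NA,             NA),
    c("Dabrafenib",           "hgnc:BRAF",       NA,             NA),
    c("Sorafenib",            "hgnc:BRAF",       NA,             NA),
    c("Vinblastine",          "uniprot:TUBB",    "hgnc:MAP2K1",  "2"),
    c("Zidovudine",           "hgnc:TERT",       NA,             NA),
    c("Trametinib",           "hgnc:MAP2K1",     NA,             NA),
    c("Regorafenib",          "hgnc:BRAF",       NA,             NA),
    c("Nadroparin",           "uniprot:SDC1",    "hgnc:MYC",     "3+1"),
    c("Vinorelbine",          "uniprot:TUBB",    "hgnc:MAP2K1",  "2"),
    c("Irinotecan",           "uniprot:TOP1",    "hgnc:CDKN2A",  "2"),
    c("Topotecan",            "uniprot:TOP1",    "hgnc:CDKN2A",  "2"),
    c("Sodium stibogluconate", "uniprot:PTPN6",  "hgnc:CDKN2A",  "2"),
    c("Ingenol mebutate",     "uniprot:PRKCA",   "hgnc:BRAF",    "3"),
    c("Bosutinib",            "hgnc:MAP2K1",     NA,             NA),
    c("Purvalanol",           "uniprot:CDK1",    "hgnc:TP53",    "3+1"),
    c("Ellagic acid",         "uniprot:PRKCA",   "hgnc:BRAF",    "3"),
    c("Albendazole",          "uniprot:TUBA1A",  "hgnc:CDKN2A",  "2"),
    c("Colchicine",           "uniprot:TUBB",    "hgnc:MAP2K1",  "2"),
    c("Plerixafor",           "uniprot:CXCL12",  "hgnc:CXCR4",   "3+1"),
    c("Vincristine",          "uniprot:TUBB",    "hgnc:MAP2K1",  "2"),
    c("L-Methionine",         "uniprot:MAT2A",   "hgnc:CDKN2A",  "2"),
    c("Mebendazole",          "uniprot:TUBA1A",  "hgnc:CDKN2A",  "2"),
    c("Framycetin",           "uniprot:NRP1",    "hgnc:CXCR4",   "3+1"),
    c("Lucanthone",           "uniprot:TOP2A",   "hgnc:CDKN2A",  "2"),
    c("Podofilox",            "uniprot:TUBB",    "hgnc:MAP2K1",  "2")
  )
  tibble(
    drug = map_chr(tribble_routes, 1),
    target_id = map_chr(tribble_routes, 2),
    via_id = map_chr(tribble_routes, 3),
    mid_levels = map_chr(tribble_routes, 4)
  )
}

replica_config <- function() {
  evidence_config(
    curated_sources = c("drugbank", "omim", "cosmic"),
    method_levels = c("MI:0018" = 1L, "MI:0096" = 2L, "MI:0114" = 3L),
    level_probabilities = c("1" = 0.73, "2" = 0.95, "3" = 0.97),
    curated_probability = 0.99,
    unknown_method_policy = "error"
  )
}

level_method <- c("1" = "MI:0018", "2" = "MI:0096", "3" = "MI:0114")

#' Generate the melanoma replica fixture
#'
#' Writes the four source tables, the evidence configuration, and the
#' status-label TSV reproducing the published 25-drug melanoma neighbourhood
#' (see [melanoma_reference_table()]), plus decoys: five 3-step drugs whose
#' joint probability (~0.72) fails the 0.93 threshold but keeps them in a
#' low-threshold sweep, and one 4-step drug (joint ~0.97) excluded by the
#' 3-step limit. Running [build_graph()] then [find_candidates()] at the
#' default thresholds on these tables returns exactly the 25 reference drugs.
#'
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with `paths` (named file paths), `disease_id`,
#'   `expected_candidates` (the candidate table the pipeline must produce,
#'   with exact joint probabilities), and `labels` (the status table).
#' @export
generate_table1_replica <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  config <- replica_config()
  ref <- melanoma_reference_table()
  routes <- left_join(ref, replica_routes(), by = "drug")
  stopifnot(!anyNA(routes$target_id))
  cur <- config$curated_probability
  lp <- config$level_probabilities

  mid_prob <- function(levels_spec) {
    lv <- strsplit(levels_spec, "+", fixed = TRUE)[[1]]
    combine_composite_z(unname(lp[lv]))
  }

  # --- drug-target table (one row per drug, plus decoys)
  decoy3 <- sprintf("DECOY%d", 1:5)
  dt <- tibble(
    drug_id = c(
      replica_drug_id(routes$drug),
      replica_drug_id(decoy3), replica_drug_id("FARSIDE")
    ),
    drug_name = c(routes$drug, decoy3, "FARSIDE"),
    target_id = c(
      routes$target_id, sprintf("uniprot:DECOYP%d", 1:5), "uniprot:FSP1"
    ),
    action = "inhibitor"
  )

  # --- PPI table: one block per distinct (target, via) middle edge
  mids <- routes |>
    filter(!is.na(.data$via_id)) |>
    distinct(.data$target_id, .data$via_id, .data$mid_levels)
  ppi_rows <- function(a, b, levels_spec, ref_base) {
    lv <- strsplit(levels_spec, "+", fixed = TRUE)[[1]]
    tibble(
      interactor_a = a, interactor_b = b,
      detection_method = unname(level_method[lv]),
      interaction_type = PPI_INTERACTION_TYPE,
      source_db = "irefindex",
      publication_ref = sprintf("pubmed:%d", ref_base + seq_along(lv) - 1)
    )
  }
  mitab <- bind_rows(
    pmap(
      list(mids$target_id, mids$via_id, mids$mid_levels, 9100000 + 10 * seq_len(nrow(mids))),
      ppi_rows
    ),
    # low-probability decoy arms (level 1, joint ~0.72)
    pmap(
      list(
        sprintf("uniprot:DECOYP%d", 1:5), sprintf("hgnc:DECOYG%d", 1:5),
        "1", 9200000 + 10 * (1:5)
      ),
      ppi_rows
    ),
    # 4-step decoy chain: two strong PPI hops
    ppi_rows("uniprot:FSP1", "uniprot:FSP2", "3+1", 9300000),
    ppi_rows("uniprot:FSP2", "hgnc:FSG", "3+1", 9300010)
  )

  # --- gene-disease tables
  cosmic_genes <- c("hgnc:BRAF", "hgnc:CDKN2A", "hgnc:MYC", "hgnc:TP53")
  omim_genes <- c(
    "hgnc:TERT", "hgnc:MAP2K1", "hgnc:CXCR4",
    sprintf("hgnc:DECOYG%d", 1:5), "hgnc:FSG"
  )
  gd <- function(genes) {
    tibble(
      gene_id = genes, disease_id = MELANOMA_ID, disease_label = "melanoma"
    )
  }

  labels <- tibble(
    drug_id = replica_drug_id(ref$drug),
    disease_id = MELANOMA_ID,
    status = ref$status
  )

  paths <- list(
    config = file.path(dir, "evidence_config.yaml"),
    mitab = file.path(dir, "ppi_mitab.tsv"),
    drug_targets = file.path(dir, "drug_targets.tsv"),
    omim = file.path(dir, "gene_disease_omim.tsv"),
    cosmic = file.path(dir, "gene_disease_cosmic.tsv"),
    labels = file.path(dir, "hit_labels.tsv")
  )
  write_evidence_config(config, paths$config)
  readr::write_tsv(mitab, paths$mitab, progress = FALSE)
  readr::write_tsv(dt, paths$drug_targets, progress = FALSE)
  readr::write_tsv(gd(omim_genes), paths$omim, progress = FALSE)
  readr::write_tsv(gd(cosmic_genes), paths$cosmic, progress = FALSE)
  readr::write_tsv(labels, paths$labels, progress = FALSE)

  # --- the candidate table the pipeline must reproduce, with exact joints
  expected <- routes |>
    mutate(
      drug_id = replica_drug_id(.data$drug),
      drug_label = .data$drug,
      disease_id = MELANOMA_ID,
      joint_probability = map_dbl(.data$mid_levels, function(lv) {
        if (is.na(lv)) cur^2 else cur^2 * mid_prob(lv)
      }),
      path_node_ids = ifelse(
        is.na(.data$via_id),
        paste(.data$drug_id, .data$target_id, MELANOMA_ID, sep = "|"),
        paste(
          .data$drug_id, .data$target_id, .data$via_id, MELANOMA_ID,
          sep = "|"
        )
      ),
      path_edge_types = ifelse(
        is.na(.data$via_id),
        paste(DRUG_TARGET_TYPE, GENE_DISEASE_TYPE, sep = "|"),
        paste(
          DRUG_TARGET_TYPE, PPI_INTERACTION_TYPE, GENE_DISEASE_TYPE,
          sep = "|"
        )
      )
    ) |>
    select(
      "drug_id", "drug_label", "disease_id", "steps",
      "joint_probability", "path_node_ids", "path_edge_types"
    ) |>
    arrange(desc(.data$joint_probability), .data$steps, .data$drug_label)
  class(expected) <- c("candidate_table", class(expected))

  invisible(list(
    paths = paths, disease_id = MELANOMA_ID,
    expected_candidates = expected, labels = hit_labels(labels),
    config = config
  ))
}

# ---- random fixture ---------------------------------------------------------

#' Specify a random knowledge-graph fixture
#'
#' @param seed Integer seed; identical seeds produce byte-identical output.
#' @param n_drugs,n_proteins,n_diseases Entity counts (each >= 1).
#' @param ppi_density Probability that any unordered protein pair interacts.
#' @param mean_records_per_edge Mean record multiplicity per PPI edge
#'   (>= 1; the excess over 1 is Poisson).
#' @param evidence_mix Proportions (summing to 1) of curated and level-1/2/3
#'   records: the level part sets the experimental method mix, the curated
#'   part is realised by the drug-target and gene-disease table sizes.
#' @return A `fixture_spec` object.
#' @export
fixture_spec <- function(seed = 1L, n_drugs = 12L, n_proteins = 25L,
                         n_diseases = 2L, ppi_density = 0.08,
                         mean_records_per_edge = 1.5,
                         evidence_mix = c(
                           curated = 0.4, level1 = 0.2,
                           level2 = 0.2, level3 = 0.2
                         )) {
  counts <- c(n_drugs = n_drugs, n_proteins = n_proteins, n_diseases = n_diseases)
  if (any(counts < 1)) {
    abort_validation("entity counts must all be >= 1")
  }
  if (ppi_density <= 0 || ppi_density >= 1) {
    abort_validation("ppi_density must lie in (0, 1)")
  }
  if (mean_records_per_edge < 1) {
    abort_validation("mean_records_per_edge must be >= 1")
  }
  if (!setequal(names(evidence_mix), c("curated", "level1", "level2", "level3")) ||
    abs(sum(evidence_mix) - 1) > 1e-8) {
    abort_validation(
      "evidence_mix needs proportions curated/level1/level2/level3 summing to 1"
    )
  }
  structure(
    list(
      seed = as.integer(seed), n_drugs = as.integer(n_drugs),
      n_proteins = as.integer(n_proteins), n_diseases = as.integer(n_diseases),
      ppi_density = ppi_density,
      mean_records_per_edge = mean_records_per_edge,
      evidence_mix = evidence_mix[c("curated", "level1", "level2", "level3")]
    ),
    class = "fixture_spec"
  )
}

# Run fn with a locally seeded RNG, leaving global random state untouched.
with_local_seed <- function(seed, fn) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  fn()
}

#' Generate random source tables emulating the real extracts
#'
#' Writes a MITAB-like PPI table, a drug-target table, two gene-disease
#' tables, the default evidence configuration, and a manifest recording every
#' planted record's probability (so that edge probabilities obtained by
#' ingesting the tables are independently recomputable).
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with `paths` (named file paths) and `manifest`
#'   (a tibble of planted records with their probabilities).
#' @export
generate_random_kg <- function(spec, dir) {
  stopifnot(inherits(spec, "fixture_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  config <- default_evidence_config()
  with_local_seed(spec$seed, function() {
    proteins <- sprintf("uniprot:RP%03d", seq_len(spec$n_proteins))
    drugs <- sprintf("drugbank:RD%03d", seq_len(spec$n_drugs))
    diseases <- sprintf("efo:RDIS%02d", seq_len(spec$n_diseases))

    # experimental level mix and the method codes that realise each level;
    # an all-curated mix suppresses the experimental PPI table entirely
    mix <- spec$evidence_mix[c("level1", "level2", "level3")]
    if (sum(mix) > 0) mix <- mix / sum(mix)
    codes_by_level <- split(
      names(config$method_levels), config$method_levels
    )

    pairs <- utils::combn(proteins, 2)
    linked <- runif(ncol(pairs)) < spec$ppi_density
    if (sum(mix) == 0) linked[] <- FALSE
    ppi <- map(which(linked), function(j) {
      n_rec <- 1L + stats::rpois(1, spec$mean_records_per_edge - 1)
      lv <- sample(c("1", "2", "3"), n_rec, replace = TRUE, prob = mix)
      tibble(
        interactor_a = pairs[1, j], interactor_b = pairs[2, j],
        detection_method = map_chr(lv, function(l) {
          sample(codes_by_level[[l]], 1)
        }),
        interaction_type = PPI_INTERACTION_TYPE,
        source_db = sample(c("irefindex", "intact", "biogrid"), n_rec,
          replace = TRUE
        ),
        publication_ref = sprintf(
          "pubmed:%07d", sample.int(9999999, n_rec)
        )
      )
    }) |>
      bind_rows()
    if (nrow(ppi) == 0) {
      ppi <- tibble(
        interactor_a = character(), interactor_b = character(),
        detection_method = character(), interaction_type = character(),
        source_db = character(), publication_ref = character()
      )
    }

    dt <- map(drugs, function(d) {
      tibble(
        drug_id = d,
        drug_name = sub("^drugbank:", "", d),
        target_id = sample(proteins, sample(1:3, 1)),
        action = "inhibitor"
      )
    }) |>
      bind_rows()

    gd <- map(diseases, function(z) {
      tibble(
        gene_id = sample(proteins, sample(2:5, 1)),
        disease_id = z,
        disease_label = sub("^efo:", "", z)
      )
    }) |>
      bind_rows()
    half <- seq_len(nrow(gd)) <= ceiling(nrow(gd) / 2)

    paths <- list(
      config = file.path(dir, "evidence_config.yaml"),
      mitab = file.path(dir, "ppi_mitab.tsv"),
      drug_targets = file.path(dir, "drug_targets.tsv"),
      omim = file.path(dir, "gene_disease_omim.tsv"),
      cosmic = file.path(dir, "gene_disease_cosmic.tsv"),
      manifest = file.path(dir, "manifest.tsv")
    )
    write_evidence_config(config, paths$config)
    readr::write_tsv(ppi, paths$mitab, progress = FALSE)
    readr::write_tsv(dt, paths$drug_targets, progress = FALSE)
    readr::write_tsv(gd[half, ], paths$omim, progress = FALSE)
    readr::write_tsv(gd[!half, ], paths$cosmic, progress = FALSE)

    manifest <- bind_rows(
      tibble(
        subject_id = ppi$interactor_a, object_id = ppi$interactor_b,
        interaction_type = ppi$interaction_type,
        source_db = ppi$source_db, evidence_type = "experimental",
        method_code = ppi$detection_method,
        primary_ref = ppi$publication_ref,
        probability = unname(config$level_probabilities[as.character(
          config$method_levels[ppi$detection_method]
        )])
      ),
      tibble(
        subject_id = dt$drug_id, object_id = dt$target_id,
        interaction_type = DRUG_TARGET_TYPE,
        source_db = "drugbank", evidence_type = "curated",
        method_code = NA_character_, primary_ref = "",
        probability = config$curated_probability
      ),
      tibble(
        subject_id = gd$gene_id, object_id = gd$disease_id,
        interaction_type = GENE_DISEASE_TYPE,
        source_db = ifelse(half, "omim", "cosmic"),
        evidence_type = "curated",
        method_code = NA_character_, primary_ref = "",
        probability = config$curated_probability
      )
    )
    readr::write_tsv(manifest, paths$manifest, progress = FALSE)
    invisible(list(paths = paths, manifest = manifest, config = config))
  })
}
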