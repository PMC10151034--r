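write_tsv_fixture <- function(df) {
  f <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  readr::write_tsv(df, f, progress = FALSE)
  f
}

test_that("evidence config applies defaults, overrides, and validation", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "curated_sources: [drugbank, omim]",
    "method_levels:",
    "  'MI:0018': 1",
    "  'MI:0114': 3"
  ), f)
  cfg <- load_evidence_config(f)
  expect_equal(unname(cfg$level_probabilities), c(0.8, 0.95, 0.99))
  expect_equal(cfg$curated_probability, 0.999)
  expect_equal(unname(cfg$method_levels[c("MI:0018", "MI:0114")]), c(1L, 3L))

  writeLines(c(
    "level_probabilities:",
    "  '2': 0.9"
  ), f)
  expect_equal(load_evidence_config(f)$level_probabilities[["2"]], 0.9)

  writeLines(c(
    "method_levels:",
    "  'MI:0018': 4"
  ), f)
  expect_error(load_evidence_config(f), class = "drugrepo_validation")

  writeLines(c(
    "level_probabilities:",
    "  '4': 0.5"
  ), f)
  expect_error(load_evidence_config(f), class = "drugrepo_validation")

  expect_error(
    evidence_config(curated_probability = 0.9),
    class = "drugrepo_validation"
  )

  # round trip through the writer
  f2 <- withr::local_tempfile(fileext = ".yaml")
  write_evidence_config(default_evidence_config(), f2)
  expect_equal(load_evidence_config(f2), default_evidence_config())
})

test_that("read_mitab emits one experimental record per binary row", {
  cfg <- default_evidence_config()
  f <- write_tsv_fixture(tibble::tibble(
    interactor_a = c("uniprot:P1", "uniprot:P2", "uniprot:P3"),
    interactor_b = c("uniprot:P2", "uniprot:P3", "uniprot:P1"),
    detection_method = c("MI:0018", "MI:0096", "MI:0114"),
    interaction_type = "psi-mi:MI:0915",
    source_db = "irefindex",
    publication_ref = c("pubmed:1", "pubmed:2", "pubmed:3")
  ))
  recs <- read_mitab(f, cfg)
  expect_equal(nrow(recs), 3)
  expect_equal(recs$evidence_type, rep("experimental", 3))
  expect_equal(recs$probability, c(0.8, 0.95, 0.99))
  expect_false(any(recs$directed))
})

test_that("read_mitab skips incomplete and n-ary rows and applies the unknown-method policy", {
  cfg <- default_evidence_config() # policy: default_level_1
  f <- write_tsv_fixture(tibble::tibble(
    interactor_a = c("uniprot:P1", "", "complex:C1", "uniprot:P4"),
    interactor_b = c("uniprot:P2", "uniprot:P3", "uniprot:P2", "uniprot:P5"),
    detection_method = c("MI:0018", "MI:0018", "MI:0018", "MI:9999"),
    interaction_type = "psi-mi:MI:0915",
    source_db = "irefindex",
    publication_ref = "pubmed:1"
  ))
  expect_message(recs <- read_mitab(f, cfg), "skipped 2 of 4")
  expect_equal(nrow(recs), 2)
  # unknown code fell back to level 1
  expect_equal(recs$probability[recs$method_code == "MI:9999"], 0.8)

  strict <- evidence_config(
    method_levels = c("MI:0018" = 1L), unknown_method_policy = "error"
  )
  expect_error(read_mitab(f, strict), "MI:9999")
})

test_that("read_drug_targets emits directed curated records at 0.999", {
  cfg <- default_evidence_config()
  f <- write_tsv_fixture(tibble::tibble(
    drug_id = "drugbank:DB1", drug_name = "drug one",
    target_id = "uniprot:P1", action = "inhibitor"
  ))
  recs <- read_drug_targets(f, cfg)
  expect_equal(nrow(recs), 1)
  expect_true(recs$directed)
  expect_equal(recs$evidence_type, "curated")
  expect_equal(recs$probability, 0.999)

  # duplicated rows stay two records but merge into one edge
  f2 <- write_tsv_fixture(tibble::tibble(
    drug_id = rep("drugbank:DB1", 2), drug_name = "drug one",
    target_id = "uniprot:P1", action = "inhibitor"
  ))
  recs2 <- read_drug_targets(f2, cfg)
  expect_equal(nrow(recs2), 2)
  g <- kg_add_assertions(knowledge_graph(), recs2, auto_register = TRUE)
  expect_equal(nrow(kg_edges(g)), 1)

  f3 <- write_tsv_fixture(tibble::tibble(
    drug_id = character(), drug_name = character(), target_id = character()
  ))
  expect_warning(recs3 <- read_drug_targets(f3, cfg), "empty")
  expect_equal(nrow(recs3), 0)
})

test_that("read_gene_disease emits curated gene->disease records and skips malformed rows", {
  cfg <- default_evidence_config()
  f <- write_tsv_fixture(tibble::tibble(
    gene_id = c("hgnc:BRAF", "hgnc:CDKN2A", "hgnc:MYC"),
    disease_id = c("efo:1", "efo:1", ""),
    disease_label = c("melanoma", "melanoma", "melanoma")
  ))
  expect_message(recs <- read_gene_disease(f, "cosmic", cfg), "skipped 1 of 3")
  expect_equal(nrow(recs), 2)
  expect_equal(recs$source_db, rep("cosmic", 2))
  expect_equal(recs$probability, rep(0.999, 2))
  expect_equal(recs$object_id, rep("efo:1", 2))
  expect_true(all(recs$directed))
})

test_that("curated and experimental records carry exactly the configured probabilities", {
  res <- generate_random_kg(
    fixture_spec(seed = 33), withr::local_tempdir()
  )
  cfg <- load_evidence_config(res$paths$config)
  g <- suppressMessages(build_graph(
    cfg, res$paths$mitab, res$paths$drug_targets,
    list(omim = res$paths$omim, cosmic = res$paths$cosmic)
  ))
  recs <- kg_records(g)
  expect_true(all(
    recs$probability[recs$evidence_type == "curated"] == 0.999
  ))
  expect_true(all(
    recs$probability[recs$evidence_type == "experimental"] %in%
      c(0.8, 0.95, 0.99)
  ))
  # emitted records account for every table row
  expect_equal(nrow(recs), nrow(res$manifest))
})

test_that("identifier aliases normalise ids before graph insertion", {
  cfg <- evidence_config(
    method_levels = c("MI:0018" = 1L),
    unknown_method_policy = "error",
    id_aliases = c("refseq:NP_1" = "uniprot:P1")
  )
  f <- write_tsv_fixture(tibble::tibble(
    interactor_a = "refseq:NP_1", interactor_b = "uniprot:P2",
    detection_method = "MI:0018", interaction_type = "psi-mi:MI:0915",
    source_db = "irefindex", publication_ref = "pubmed:1"
  ))
  recs <- read_mitab(f, cfg)
  expect_equal(recs$subject_id, "uniprot:P1")
})
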