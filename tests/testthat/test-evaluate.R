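toy_candidates <- function(drugs) {
  tibble::tibble(
    drug_id = drugs, drug_label = drugs, disease_id = "dis:Z",
    steps = 2L, joint_probability = 0.95,
    path_node_ids = "", path_edge_types = ""
  )
}

toy_labels <- function(drugs, statuses) {
  hit_labels(tibble::tibble(
    drug_id = drugs, disease_id = "dis:Z", status = statuses
  ))
}

test_that("precision, recall and f-measure match hand-counted cases", {
  labels <- toy_labels(
    sprintf("d%d", 1:6),
    c(rep("in_vitro", 5), "novel")
  ) # 5 known hits
  # return 4, of which 3 are hits
  m <- precision_recall_f(toy_candidates(c("d1", "d2", "d3", "d6")), labels)
  expect_equal(m$precision, 0.75)
  expect_equal(m$recall, 0.6)
  expect_equal(m$f_measure, 2 * 0.75 * 0.6 / 1.35)

  # perfect retrieval
  p <- precision_recall_f(toy_candidates(sprintf("d%d", 1:5)), labels)
  expect_equal(c(p$precision, p$recall, p$f_measure), c(1, 1, 1))

  # nothing returned
  expect_warning(
    z <- precision_recall_f(toy_candidates(character()), labels),
    "no candidates"
  )
  expect_equal(c(z$precision, z$recall, z$f_measure), c(0, 0, 0))

  # geometric f-measure variant
  gm <- precision_recall_f(
    toy_candidates(c("d1", "d2", "d3", "d6")), labels,
    f_mean = "geometric"
  )
  expect_equal(gm$f_measure, sqrt(0.75 * 0.6))
})

test_that("unlabeled candidates are non-hits unless strict", {
  labels <- toy_labels("d1", "in_vivo")
  expect_message(
    m <- precision_recall_f(toy_candidates(c("d1", "dX")), labels),
    "unlabeled"
  )
  expect_equal(m$precision, 0.5)
  expect_equal(m$n_unlabeled, 1)
  expect_error(
    precision_recall_f(toy_candidates(c("d1", "dX")), labels, strict = TRUE),
    class = "drugrepo_validation"
  )
  expect_error(
    precision_recall_f(
      toy_candidates("d1"),
      tibble::tibble(
        drug_id = character(), disease_id = character(), status = character()
      )
    ),
    class = "drugrepo_validation"
  )
})

test_that("harmonic <= geometric <= arithmetic mean of precision and recall", {
  withr::with_seed(3, {
    for (i in 1:30) {
      n_hits_known <- sample(2:8, 1)
      labels <- toy_labels(
        sprintf("d%d", 1:10),
        sample(
          c(rep("in_vitro", n_hits_known), rep("novel", 10 - n_hits_known))
        )
      )
      returned <- sample(sprintf("d%d", 1:10), sample(1:10, 1))
      h <- precision_recall_f(toy_candidates(returned), labels)
      g <- precision_recall_f(
        toy_candidates(returned), labels,
        f_mean = "geometric"
      )
      expect_lte(h$f_measure, g$f_measure + 1e-12)
      expect_lte(g$f_measure, (h$precision + h$recall) / 2 + 1e-12)
      expect_true(all(
        c(h$precision, h$recall, h$f_measure) >= 0 &
          c(h$precision, h$recall, h$f_measure) <= 1
      ))
    }
  })
})

test_that("threshold sweeps are monotone and report the stricter optimum on ties", {
  rep <- generate_table1_replica(withr::local_tempdir())
  g <- build_graph(
    config = load_evidence_config(rep$paths$config),
    mitab = rep$paths$mitab, drug_targets = rep$paths$drug_targets,
    gene_disease = list(omim = rep$paths$omim, cosmic = rep$paths$cosmic)
  )
  swp <- threshold_sweep(
    g, rep$disease_id, rep$labels,
    axis = "joint_probability"
  )
  pts <- tidy(swp)
  expect_true(all(diff(pts$recall) <= 1e-12))
  expect_true(all(diff(pts$n_candidates) <= 0))
  expect_equal(swp$optimum, 0.93)

  sws <- threshold_sweep(g, rep$disease_id, rep$labels, axis = "steps")
  expect_true(all(diff(tidy(sws)$recall) >= -1e-12))
  expect_equal(sws$optimum, 3)

  # single grid value reduces to direct evaluation
  one <- threshold_sweep(
    g, rep$disease_id, rep$labels,
    axis = "joint_probability", grid = 0.93
  )
  direct <- suppressMessages(precision_recall_f(
    find_candidates(g, rep$disease_id), rep$labels
  ))
  expect_equal(tidy(one)$precision, direct$precision)
  expect_equal(tidy(one)$f_measure, direct$f_measure)
  expect_equal(nrow(tidy(one)), 1)

  expect_s3_class(autoplot(swp), "ggplot")
  f <- withr::local_tempfile(fileext = ".csv")
  write_sweep_csv(swp, f)
  expect_equal(nrow(readr::read_csv(f, show_col_types = FALSE)), nrow(pts))
})

test_that("Scott's Pi matches hand-worked values", {
  # identical annotations over two used categories
  expect_equal(scotts_pi(c(1, 2, 1, 2), c(1, 2, 1, 2))$pi, 1)

  # hand computation: Ao = 0.5, pooled marginals (1/2, 1/2), Ae = 0.5, pi = 0
  r <- scotts_pi(c(1, 1, 2, 2), c(1, 2, 1, 2))
  expect_equal(r$observed_agreement, 0.5)
  expect_equal(r$expected_agreement, 0.5)
  expect_equal(r$pi, 0)

  # invariance under relabeling and annotator swap
  a <- c(1, 1, 2, 3, 2, 1)
  b <- c(1, 2, 2, 3, 1, 1)
  expect_equal(scotts_pi(a, b)$pi, scotts_pi(b, a)$pi)
  relab <- c("x", "y", "z")
  expect_equal(scotts_pi(a, b)$pi, scotts_pi(relab[a], relab[b])$pi)

  expect_error(scotts_pi(1:3, 1:4), class = "drugrepo_validation")
  expect_error(
    scotts_pi(c(1, 1), c(1, 1)),
    class = "drugrepo_undefined_pi"
  )
})

test_that("Scott's Pi on a 104-method annotation table matches the frozen hand computation", {
  # two raters over 104 methods, 3 confidence levels; agreement on the first
  # 58 items, cyclic disagreement on the rest
  a <- rep(c(1, 2, 3), c(40, 34, 30))
  b <- a
  b[59:104] <- a[59:104] %% 3 + 1
  r <- scotts_pi(a, b)
  # by hand: Ao = 58/104; pooled counts 110/52/46 of 208 -> Ae = 16920/43264
  expect_equal(r$observed_agreement, 58 / 104)
  expect_equal(r$expected_agreement, 16920 / 43264)
  expect_equal(r$pi, (58 / 104 - 16920 / 43264) / (1 - 16920 / 43264))
  expect_equal(r$pi, 0.2736107, tolerance = 1e-6)
})

test_that("label tables are validated", {
  expect_error(
    hit_labels(tibble::tibble(
      drug_id = "d", disease_id = "z", status = "phase_iv"
    )),
    class = "drugrepo_validation"
  )
  f <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(
    tibble::tibble(drug_id = "d", disease_id = "z", status = "approved"), f
  )
  expect_s3_class(read_hit_labels(f), "hit_labels")
})
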