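test_that("joint probability is the product, with the empty conjunction at 1", {
  expect_equal(joint_probability(numeric()), 1.0)
  expect_equal(joint_probability(0.93), 0.93)
  expect_equal(joint_probability(c(0.99, 0.99)), 0.9801)
  expect_error(joint_probability(c(0.5, 0)), class = "drugrepo_validation")
  expect_error(joint_probability(c(0.5, 1.2)), class = "drugrepo_validation")
})

test_that("a linear drug->protein->disease chain is found from the disease side", {
  g <- linear_graph(0.999, 0.999)
  paths <- kg_expand(g, "dis:Z1", expansion_query(
    direction = "incoming", max_steps = 3, min_joint_probability = 0.93,
    endpoint_type = "drug"
  ))
  expect_equal(nrow(paths), 1)
  expect_equal(paths$steps, 2L)
  expect_equal(paths$joint_probability, 0.999^2, tolerance = 1e-9)
  expect_equal(paths$node_ids[[1]], c("dis:Z1", "prot:P1", "drug:D1"))

  # threshold above the joint probability excludes everything
  none <- kg_expand(g, "dis:Z1", expansion_query(
    direction = "incoming", min_joint_probability = 0.999
  ))
  expect_equal(nrow(none), 0)
  expect_error(
    kg_expand(g, "dis:NOPE", expansion_query()),
    class = "drugrepo_missing_entity"
  )
})

test_that("directed edges are only walked along the query direction", {
  g <- linear_graph()
  # outgoing from the disease: nothing to walk
  out <- kg_expand(g, "dis:Z1", expansion_query(
    direction = "outgoing", endpoint_type = NULL,
    min_joint_probability = 0.5
  ))
  expect_equal(nrow(out), 0)
  # outgoing from the drug reaches the disease
  fwd <- kg_expand(g, "drug:D1", expansion_query(
    direction = "outgoing", endpoint_type = "disease",
    min_joint_probability = 0.5
  ))
  expect_equal(nrow(fwd), 1)
  expect_equal(fwd$terminal_id, "dis:Z1")
})

test_that("self-interactions never advance a path", {
  g <- toy_graph(tibble::tibble(
    subject_id = c("prot:A", "prot:A"),
    object_id = c("prot:A", "dis:Z"),
    probability = c(0.99, 0.99),
    directed = TRUE
  ))
  paths <- kg_expand(g, "dis:Z", expansion_query(
    direction = "incoming", endpoint_type = NULL,
    min_joint_probability = 0.5
  ))
  expect_equal(nrow(paths), 1) # only dis:Z <- prot:A, no loop step
})

test_that("expansion equals the brute-force enumeration oracle on random graphs", {
  withr::with_seed(99, {
    for (i in 1:40) {
      rg <- random_toy_graph(
        n_nodes = sample(6:30, 1), n_edges = sample(10:45, 1)
      )
      seed_node <- sample(rg$ids, 1)
      dir <- sample(c("incoming", "outgoing", "both"), 1)
      steps <- sample(2:4, 1)
      thr <- runif(1, 0.3, 0.9)
      filt <- if (runif(1) < 0.5) NULL else "drug"

      got <- kg_expand(rg$graph, seed_node, expansion_query(
        direction = dir, max_steps = steps,
        min_joint_probability = thr, endpoint_type = filt
      ))
      want <- oracle_paths(rg$graph, seed_node, dir, steps, thr, filt)

      expect_identical(
        path_signatures(got$node_ids),
        path_signatures(lapply(want, `[[`, "nodes"))
      )
      # joint probabilities agree path-by-path; parallel edge types can give
      # several paths over one node sequence, so order by (signature, joint)
      got_sig <- vapply(got$node_ids, paste, character(1), collapse = "|")
      want_sig <- vapply(want, function(p) {
        paste(p$nodes, collapse = "|")
      }, character(1))
      got_j <- got$joint_probability[order(got_sig, got$joint_probability)]
      want_raw <- vapply(want, `[[`, numeric(1), "joint")
      want_j <- want_raw[order(want_sig, want_raw)]
      expect_equal(got_j, want_j, tolerance = 1e-12)
    }
  })
})

test_that("appending an edge never raises a path's joint probability", {
  withr::with_seed(7, {
    rg <- random_toy_graph(n_nodes = 12, n_edges = 30)
  })
  paths <- kg_expand(rg$graph, rg$ids[1], expansion_query(
    direction = "both", max_steps = 4, min_joint_probability = 0.2,
    endpoint_type = NULL
  ))
  if (nrow(paths) > 0) {
    expect_true(all(
      paths$joint_probability <=
        purrr::map_dbl(paths$edge_probabilities, min) + 1e-15
    ))
  }
})

test_that("candidate grouping picks the best path with deterministic tie-breaks", {
  # one drug reachable by a strong 2-step and a weak 3-step route
  g <- toy_graph(tibble::tibble(
    subject_id = c("drug:D", "prot:A", "drug:D", "prot:B", "prot:C"),
    object_id = c("prot:A", "dis:Z", "prot:B", "prot:C", "dis:Z"),
    probability = c(0.99, 0.99, 0.99, 0.97, 0.97),
    directed = c(TRUE, TRUE, TRUE, FALSE, TRUE)
  ))
  cand <- find_candidates(g, "dis:Z", min_joint_probability = 0.9)
  expect_equal(nrow(cand), 1)
  expect_equal(cand$steps, 2L)
  expect_equal(cand$joint_probability, 0.9801, tolerance = 1e-12)
  expect_equal(cand$path_node_ids, "drug:D|prot:A|dis:Z")

  # exact probability tie: fewer steps wins
  tie <- toy_graph(tibble::tibble(
    subject_id = c("drug:D", "drug:D", "prot:B"),
    object_id = c("dis:Z", "prot:B", "dis:Z"),
    probability = c(0.9801, 0.99, 0.99),
    directed = TRUE
  ))
  cand2 <- find_candidates(tie, "dis:Z", min_joint_probability = 0.9)
  expect_equal(cand2$steps, 1L)

  # isolated disease yields an empty table
  iso <- toy_graph(tibble::tibble(
    subject_id = "drug:D", object_id = "prot:A", probability = 0.99
  ))
  iso <- kg_add_entities(iso, tibble::tibble(
    id = "dis:LONE", label = "lone", entity_type = "disease"
  ))
  expect_equal(nrow(find_candidates(iso, "dis:LONE")), 0)
  expect_error(
    find_candidates(g, "prot:A"),
    class = "drugrepo_validation"
  )
})

test_that("tightening either threshold never adds a candidate", {
  rep <- generate_table1_replica(withr::local_tempdir())
  g <- build_graph(
    config = load_evidence_config(rep$paths$config),
    mitab = rep$paths$mitab, drug_targets = rep$paths$drug_targets,
    gene_disease = list(omim = rep$paths$omim, cosmic = rep$paths$cosmic)
  )
  thresholds <- c(0.5, 0.7, 0.93, 0.96, 0.99)
  sets_p <- lapply(thresholds, function(t) {
    find_candidates(g, rep$disease_id, min_joint_probability = t)$drug_id
  })
  for (i in seq_along(sets_p)[-1]) {
    expect_true(all(sets_p[[i]] %in% sets_p[[i - 1]]))
  }
  sets_s <- lapply(1:5, function(s) {
    find_candidates(g, rep$disease_id, max_steps = s)$drug_id
  })
  for (i in seq_along(sets_s)[-1]) {
    expect_true(all(sets_s[[i - 1]] %in% sets_s[[i]]))
  }
})

test_that("candidate CSV round-trips with six-decimal probabilities", {
  g <- linear_graph()
  cand <- find_candidates(g, "dis:Z1")
  f <- withr::local_tempfile(fileext = ".csv")
  write_candidates_csv(cand, f)
  line <- readLines(f)[2]
  expect_match(line, "0\\.998001")
  back <- read_candidates_csv(f)
  expect_equal(back$drug_id, cand$drug_id)
  expect_equal(back$joint_probability, round(cand$joint_probability, 6))
})
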