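# Programmatic graph fixtures. Entity types are inferred from the id prefix
# so toy graphs can be written as compact edge lists.

prefix_type <- function(ids) {
  c(
    drug = "drug", prot = "protein", gene = "gene",
    dis = "disease", proc = "process"
  )[sub(":.*", "", ids)]
}

# Build a combined-probability graph straight from an edge list:
# tibble(subject_id, object_id, probability, directed, interaction_type).
toy_graph <- function(edges, combiner = combiner_spec()) {
  edges <- tibble::as_tibble(edges)
  if (!"directed" %in% names(edges)) edges$directed <- TRUE
  if (!"interaction_type" %in% names(edges)) edges$interaction_type <- "t"
  ids <- unique(c(edges$subject_id, edges$object_id))
  g <- knowledge_graph(combiner = combiner)
  g <- kg_add_entities(g, tibble::tibble(
    id = ids, label = sub(".*:", "", ids), entity_type = unname(prefix_type(ids))
  ))
  g <- kg_add_assertions(g, tibble::tibble(
    subject_id = edges$subject_id,
    interaction_type = edges$interaction_type,
    object_id = edges$object_id,
    directed = edges$directed,
    source_db = "toy",
    evidence_type = "experimental",
    method_code = "MI:0018",
    primary_ref = sprintf("ref:%d", seq_len(nrow(edges))),
    probability = edges$probability
  ))
  recombine_edges(g)
}

# Random mixed-direction typed graph for oracle-equivalence tests.
# One record per edge so combined probability == planted probability.
random_toy_graph <- function(n_nodes = 20, n_edges = 35) {
  types <- sample(c("drug", "prot", "gene", "dis"), n_nodes,
    replace = TRUE, prob = c(0.3, 0.4, 0.15, 0.15)
  )
  ids <- sprintf("%s:N%02d", types, seq_len(n_nodes))
  from <- sample(ids, n_edges, replace = TRUE)
  to <- sample(ids, n_edges, replace = TRUE)
  keep <- from != to
  edges <- tibble::tibble(
    subject_id = from[keep],
    object_id = to[keep],
    probability = round(runif(sum(keep), 0.3, 0.99), 3),
    directed = runif(sum(keep)) < 0.5,
    interaction_type = sample(c("t1", "t2"), sum(keep), replace = TRUE)
  )
  # one record per triple: drop duplicates (incl. undirected reversals)
  a <- pmin(edges$subject_id, edges$object_id)
  b <- pmax(edges$subject_id, edges$object_id)
  und_key <- paste(a, edges$interaction_type, b)
  key <- ifelse(
    edges$directed,
    paste(edges$subject_id, edges$interaction_type, edges$object_id),
    und_key
  )
  edges <- edges[!duplicated(und_key) & !duplicated(key), ]
  g <- toy_graph(edges)
  # register isolated nodes too, so any id can seed an expansion
  g <- kg_add_entities(g, tibble::tibble(
    id = ids, label = sub(".*:", "", ids), entity_type = unname(prefix_type(ids))
  ))
  list(graph = g, ids = ids, edges = edges)
}

# Tiny linear pipeline fixture: drug -> protein -> disease.
linear_graph <- function(p1 = 0.999, p2 = 0.999) {
  toy_graph(tibble::tibble(
    subject_id = c("drug:D1", "prot:P1"),
    object_id = c("prot:P1", "dis:Z1"),
    probability = c(p1, p2),
    directed = TRUE
  ))
}
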