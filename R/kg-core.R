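# In-memory heterogeneous knowledge graph.
#
# Entities are typed (drug / protein / gene / disease / process) and edges are
# keyed by the (subject, interaction type, object) triple. Every edge carries
# the full list of assertion records that back it -- one record per source
# nanopublication -- plus a single combined probability computed by the
# evidence module.

EDGE_SEP <- "" # unit separator; never occurs in CURIE-style ids

edge_key <- function(subject_id, interaction_type, object_id) {
  paste(subject_id, interaction_type, object_id, sep = EDGE_SEP)
}

#' Create an empty knowledge graph
#'
#' A knowledge graph holds typed entities, assertion records (one per source
#' interaction report, with provenance), and edges -- the per-triple aggregate
#' of all records sharing one (subject, interaction type, object) key. Edge
#' probabilities are combined from record probabilities by
#' [recombine_edges()]; until then newly touched edges are marked stale
#' (`combined_probability = NA`).
#'
#' @param combiner A [combiner_spec()] describing how redundant records are
#'   merged into one edge probability. Defaults to composite Z-score voting.
#' @return An object of class `knowledge_graph`.
#' @examples
#' g <- knowledge_graph()
#' glance(g)
#' @export
knowledge_graph <- function(combiner = combiner_spec()) {
  stopifnot(inherits(combiner, "combiner_spec"))
  g <- structure(
    list(
      entities = tibble(
        id = character(), label = character(),
        entity_type = character(), synonyms = list()
      ),
      records = empty_records(),
      edges = tibble(
        edge_key = character(), subject_id = character(),
        interaction_type = character(), object_id = character(),
        directed = logical(), combined_probability = double(),
        n_records = integer()
      ),
      index = list(outgoing = list(), incoming = list()),
      combiner = combiner
    ),
    class = "knowledge_graph"
  )
  g
}

empty_records <- function() {
  tibble(
    subject_id = character(), interaction_type = character(),
    object_id = character(), directed = logical(),
    source_db = character(), evidence_type = character(),
    method_code = character(), primary_ref = character(),
    probability = double()
  )
}

RECORD_COLS <- c(
  "subject_id", "interaction_type", "object_id", "directed", "source_db",
  "evidence_type", "method_code", "primary_ref", "probability"
)

#' Register entities in a knowledge graph
#'
#' Already-registered ids are left untouched (first registration wins, so the
#' caller's ingestion order resolves cross-source type disagreements
#' deterministically).
#'
#' @param graph A `knowledge_graph`.
#' @param entities Data frame with columns `id`, `label`, `entity_type`, and
#'   optionally `synonyms` (a list column of character vectors).
#' @return The updated graph.
#' @export
kg_add_entities <- function(graph, entities) {
  check_graph(graph)
  entities <- as_tibble(entities)
  required <- c("id", "label", "entity_type")
  missing <- setdiff(required, names(entities))
  if (length(missing) > 0) {
    abort_validation(paste0(
      "entity table is missing column(s): ", paste(missing, collapse = ", ")
    ))
  }
  if (!"synonyms" %in% names(entities)) {
    entities$synonyms <- replicate(nrow(entities), character(), simplify = FALSE)
  }
  entities <- entities[, c("id", "label", "entity_type", "synonyms")]
  if (any(!nzchar(entities$id)) || anyNA(entities$id)) {
    abort_validation("entity ids must be non-empty")
  }
  if (any(!nzchar(entities$label)) || anyNA(entities$label)) {
    abort_validation("entity labels must be non-empty")
  }
  bad <- setdiff(unique(entities$entity_type), ENTITY_TYPES)
  if (length(bad) > 0) {
    abort_validation(paste0(
      "unknown entity_type(s): ", paste(bad, collapse = ", "),
      " (expected one of ", paste(ENTITY_TYPES, collapse = ", "), ")"
    ))
  }
  entities <- distinct(entities, .data$id, .keep_all = TRUE)
  new <- entities[!entities$id %in% graph$entities$id, ]
  graph$entities <- bind_rows(graph$entities, new)
  graph
}

#' Add assertion records to a knowledge graph
#'
#' Each row is one nanopublication-equivalent: a subject-type-object assertion
#' with its provenance (source database, evidence, publication reference) and
#' an already-assigned probability (see [assign_probabilities()]). Records
#' sharing a triple accumulate on the same edge; undirected records are
#' canonicalised so the lexicographically smaller endpoint is the subject,
#' making (A,t,B) and (B,t,A) the same undirected edge.
#'
#' @param graph A `knowledge_graph`.
#' @param records Data frame with columns `subject_id`, `interaction_type`,
#'   `object_id`, `directed`, `source_db`, `evidence_type` (`"curated"` or
#'   `"experimental"`), `method_code` (NA for curated records), `primary_ref`,
#'   `probability`. Extra columns `subject_type`/`subject_label`/
#'   `object_type`/`object_label` drive auto-registration and are dropped from
#'   storage.
#' @param auto_register Register unseen endpoint entities from the
#'   `*_type`/`*_label` columns. When `FALSE`, an unknown endpoint is an error.
#' @param allow_self Accept self-interactions (subject == object). They are
#'   stored but never traversed during path expansion.
#' @return The updated graph, with touched edges marked stale.
#' @seealso [recombine_edges()], [kg_neighbors()]
#' @export
kg_add_assertions <- function(graph, records, auto_register = FALSE,
                              allow_self = TRUE) {
  check_graph(graph)
  records <- as_tibble(records)
  missing <- setdiff(RECORD_COLS, names(records))
  if (length(missing) > 0) {
    abort_validation(paste0(
      "assertion table is missing column(s): ", paste(missing, collapse = ", ")
    ))
  }
  if (nrow(records) == 0) {
    return(graph)
  }
  p <- records$probability
  if (anyNA(p) || any(p <= 0) || any(p >= 1)) {
    abort_validation("record probabilities must lie strictly inside (0, 1)")
  }
  bad_ev <- setdiff(unique(records$evidence_type), c("curated", "experimental"))
  if (length(bad_ev) > 0) {
    abort_validation(paste0(
      "evidence_type must be 'curated' or 'experimental', got: ",
      paste(bad_ev, collapse = ", ")
    ))
  }
  if (!allow_self && any(records$subject_id == records$object_id)) {
    abort_validation("self-interactions are not allowed here")
  }

  if (auto_register) {
    graph <- kg_add_entities(graph, record_endpoints(records))
  }
  unknown <- setdiff(
    unique(c(records$subject_id, records$object_id)), graph$entities$id
  )
  if (length(unknown) > 0) {
    abort_missing_entity(unknown)
  }

  # canonical orientation for undirected records
  swap <- !records$directed & records$object_id < records$subject_id
  if (any(swap)) {
    tmp <- records$subject_id[swap]
    records$subject_id[swap] <- records$object_id[swap]
    records$object_id[swap] <- tmp
  }

  graph$records <- bind_rows(graph$records, records[, RECORD_COLS])
  graph <- rebuild_edges(graph, stale_keys = edge_key(
    records$subject_id, records$interaction_type, records$object_id
  ))
  graph$index <- build_adjacency(graph)
  graph
}

# Pull endpoint entity descriptions out of a record table (for auto_register).
record_endpoints <- function(records) {
  need <- c("subject_type", "object_type")
  if (!all(need %in% names(records))) {
    abort_validation(
      "auto_register requires subject_type/object_type columns on the records"
    )
  }
  col_or <- function(nm, fallback) {
    if (nm %in% names(records)) records[[nm]] else fallback
  }
  subj_label <- col_or("subject_label", records$subject_id)
  obj_label <- col_or("object_label", records$object_id)
  ends <- tibble(
    id = c(records$subject_id, records$object_id),
    label = c(subj_label, obj_label),
    entity_type = c(records$subject_type, records$object_type)
  )
  ends$label <- ifelse(is.na(ends$label) | !nzchar(ends$label), ends$id, ends$label)
  distinct(ends, .data$id, .keep_all = TRUE)
}

# Recompute the edge table from the record table. Stale keys get
# combined_probability = NA; others keep their previous combined value.
rebuild_edges <- function(graph, stale_keys = character()) {
  recs <- graph$records
  keys <- edge_key(recs$subject_id, recs$interaction_type, recs$object_id)
  grp <- split(seq_len(nrow(recs)), keys)
  ord <- match(unique(keys), names(grp)) # keep first-seen order
  grp <- grp[names(grp)[ord]]
  first <- map_int(grp, 1L)
  directed <- map_lgl_strict(grp, function(i) {
    d <- unique(recs$directed[i])
    if (length(d) > 1) {
      abort_validation(paste0(
        "records for triple (", recs$subject_id[i[1]], ", ",
        recs$interaction_type[i[1]], ", ", recs$object_id[i[1]],
        ") disagree on directedness"
      ))
    }
    d
  })
  old <- graph$edges
  combined <- old$combined_probability[match(names(grp), old$edge_key)]
  combined[names(grp) %in% stale_keys] <- NA_real_
  graph$edges <- tibble(
    edge_key = names(grp),
    subject_id = recs$subject_id[first],
    interaction_type = recs$interaction_type[first],
    object_id = recs$object_id[first],
    directed = directed,
    combined_probability = combined,
    n_records = unname(lengths(grp))
  )
  graph
}

map_lgl_strict <- function(x, f) vapply(x, f, logical(1))

# Adjacency indexes: for every entity, the edge-row indices reachable leaving
# it (outgoing) or arriving at it (incoming). Undirected edges appear in both.
build_adjacency <- function(graph) {
  e <- graph$edges
  out <- list()
  inc <- list()
  add <- function(idx, id, i) {
    idx[[id]] <- c(idx[[id]], i)
    idx
  }
  for (i in seq_len(nrow(e))) {
    s <- e$subject_id[i]
    o <- e$object_id[i]
    out <- add(out, s, i)
    inc <- add(inc, o, i)
    if (!e$directed[i] && s != o) {
      out <- add(out, o, i)
      inc <- add(inc, s, i)
    }
  }
  list(outgoing = out, incoming = inc)
}

#' Edges incident to an entity
#'
#' `direction = "incoming"` returns edges the entity is a target of (directed
#' edges pointing at it plus undirected edges touching it); `"outgoing"` is
#' symmetric; `"both"` is their duplicate-free union.
#'
#' @param graph A `knowledge_graph`.
#' @param entity_id A registered entity id.
#' @param direction One of `"both"`, `"incoming"`, `"outgoing"`.
#' @param entity_type Optional filter on the far endpoint's entity type
#'   (e.g. `"drug"`).
#' @return A tibble of edges with an extra `neighbor_id` column naming the far
#'   endpoint.
#' @export
kg_neighbors <- function(graph, entity_id,
                         direction = c("both", "incoming", "outgoing"),
                         entity_type = NULL) {
  check_graph(graph)
  direction <- arg_match(direction)
  if (!entity_id %in% graph$entities$id) {
    abort_missing_entity(entity_id)
  }
  rows <- switch(direction,
    incoming = graph$index$incoming[[entity_id]],
    outgoing = graph$index$outgoing[[entity_id]],
    both = union(
      graph$index$incoming[[entity_id]], graph$index$outgoing[[entity_id]]
    )
  )
  res <- graph$edges[sort(unique(rows)), ]
  res$neighbor_id <- ifelse(
    res$subject_id == entity_id, res$object_id, res$subject_id
  )
  if (!is.null(entity_type)) {
    types <- entity_type_of(graph, res$neighbor_id)
    res <- res[types %in% entity_type, ]
  }
  res
}

entity_type_of <- function(graph, ids) {
  graph$entities$entity_type[match(ids, graph$entities$id)]
}

#' Component tables of a knowledge graph
#'
#' @param graph A `knowledge_graph`.
#' @return A tibble of entities, edges, or assertion records respectively.
#' @export
kg_entities <- function(graph) {
  check_graph(graph)
  graph$entities
}

#' @rdname kg_entities
#' @export
kg_edges <- function(graph) {
  check_graph(graph)
  graph$edges
}

#' @rdname kg_entities
#' @export
kg_records <- function(graph) {
  check_graph(graph)
  graph$records
}

check_graph <- function(graph) {
  if (!inherits(graph, "knowledge_graph")) {
    abort_validation("expected a knowledge_graph object")
  }
  invisible(graph)
}

#' @export
print.knowledge_graph <- function(x, ...) {
  cat(sprintf(
    "<knowledge_graph> %d entities, %d edges, %d records (combiner: %s)\n",
    nrow(x$entities), nrow(x$edges), nrow(x$records), x$combiner$method
  ))
  tab <- table(x$entities$entity_type)
  if (length(tab) > 0) {
    cat("  entities:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
  if (anyNA(x$edges$combined_probability)) {
    cat("  note: stale edges present; run recombine_edges()\n")
  }
  invisible(x)
}

#' @export
tidy.knowledge_graph <- function(x, ...) {
  select(x$edges, -"edge_key")
}

#' @export
glance.knowledge_graph <- function(x, ...) {
  tibble(
    n_entities = nrow(x$entities),
    n_edges = nrow(x$edges),
    n_records = nrow(x$records),
    n_stale_edges = sum(is.na(x$edges$combined_probability)),
    combiner = x$combiner$method
  )
}

# ---- JSON-lines dump / load --------------------------------------------------

#' Dump a knowledge graph as JSON lines
#'
#' Line 1 is a header object carrying the combiner configuration and the full
#' entity table; every following line is one assertion record. The format
#' round-trips losslessly: `kg_write_jsonl()` then [kg_read_jsonl()] then
#' `kg_write_jsonl()` is byte-identical.
#'
#' @param graph A `knowledge_graph`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
kg_write_jsonl <- function(graph, path) {
  check_graph(graph)
  ent <- graph$entities
  header <- list(
    type = "header",
    combiner = list(
      method = graph$combiner$method,
      clamp_epsilon = graph$combiner$clamp_epsilon
    ),
    entities = pmap(ent, function(id, label, entity_type, synonyms) {
      list(
        id = id, label = label, entity_type = entity_type,
        synonyms = as.list(synonyms)
      )
    })
  )
  to_line <- function(x) {
    jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null", na = "null")
  }
  lines <- c(
    to_line(header),
    map_chr(seq_len(nrow(graph$records)), function(i) {
      r <- as.list(graph$records[i, ])
      r$method_code <- if (is.na(r$method_code)) NULL else r$method_code
      to_line(c(list(type = "record"), r))
    })
  )
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Load a knowledge graph from a JSON-lines dump
#'
#' @param path A file written by [kg_write_jsonl()].
#' @return A `knowledge_graph`; edge probabilities are left stale until
#'   [recombine_edges()] is run with the dumped combiner.
#' @export
kg_read_jsonl <- function(path) {
  if (!file.exists(path)) {
    abort_io(paste0("cannot read graph dump: ", path))
  }
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0) {
    abort_io(paste0("empty graph dump: ", path))
  }
  header <- jsonlite::fromJSON(lines[1], simplifyVector = FALSE)
  if (!identical(header$type, "header")) {
    abort_io("graph dump does not start with a header line")
  }
  spec <- combiner_spec(
    method = header$combiner$method,
    clamp_epsilon = header$combiner$clamp_epsilon
  )
  g <- knowledge_graph(combiner = spec)
  if (length(header$entities) > 0) {
    ents <- tibble(
      id = map_chr(header$entities, "id"),
      label = map_chr(header$entities, "label"),
      entity_type = map_chr(header$entities, "entity_type"),
      synonyms = map(header$entities, function(e) {
        as.character(unlist(e$synonyms))
      })
    )
    g <- kg_add_entities(g, ents)
  }
  if (length(lines) > 1) {
    recs <- map(lines[-1], jsonlite::fromJSON, simplifyVector = FALSE)
    records <- tibble(
      subject_id = map_chr(recs, "subject_id"),
      interaction_type = map_chr(recs, "interaction_type"),
      object_id = map_chr(recs, "object_id"),
      directed = map_lgl_strict(recs, function(r) isTRUE(r$directed)),
      source_db = map_chr(recs, "source_db"),
      evidence_type = map_chr(recs, "evidence_type"),
      method_code = map_chr(recs, function(r) r$method_code %||% NA_character_),
      primary_ref = map_chr(recs, "primary_ref"),
      probability = map_dbl(recs, "probability")
    )
    g <- kg_add_assertions(g, records)
  }
  g
}

# ---- TriG nanopublication export --------------------------------------------

#' Export assertions as TriG nanopublications
#'
#' Writes one nanopublication per assertion record, with the conventional
#' assertion / provenance / publication-info named graphs. Write-only
#' interoperability surface; the package never reads TriG back.
#'
#' @param graph A `knowledge_graph`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
kg_write_trig <- function(graph, path) {
  check_graph(graph)
  recs <- graph$records
  out <- c(
    "@prefix np: <http://www.nanopub.org/nschema#> .",
    "@prefix prov: <http://www.w3.org/ns/prov#> .",
    "@prefix sio: <http://semanticscience.org/resource/> .",
    "@prefix : <http://example.org/nanopub/> .",
    ""
  )
  ent <- function(id) paste0("<urn:entity:", id, ">")
  for (i in seq_len(nrow(recs))) {
    np <- paste0(":np", i)
    prob <- format(recs$probability[i], digits = 15)
    out <- c(
      out,
      paste0(np, "_head {"),
      paste0("  ", np, " a np:Nanopublication ;"),
      paste0("    np:hasAssertion ", np, "_assertion ;"),
      paste0("    np:hasProvenance ", np, "_provenance ;"),
      paste0("    np:hasPublicationInfo ", np, "_pubinfo ."),
      "}",
      paste0(np, "_assertion {"),
      paste0(
        "  ", ent(recs$subject_id[i]), " <urn:interaction:",
        recs$interaction_type[i], "> ", ent(recs$object_id[i]),
        " . # p=", prob
      ),
      "}",
      paste0(np, "_provenance {"),
      paste0(
        "  ", np, "_assertion prov:wasDerivedFrom \"",
        recs$source_db[i], "\" ."
      ),
      if (!is.na(recs$method_code[i])) {
        paste0(
          "  ", np, "_assertion prov:wasGeneratedBy <urn:method:",
          recs$method_code[i], "> ."
        )
      },
      "}",
      paste0(np, "_pubinfo {"),
      paste0(
        "  ", np, " prov:hadPrimarySource \"", recs$primary_ref[i], "\" ."
      ),
      "}",
      ""
    )
  }
  writeLines(out, path, useBytes = TRUE)
  invisible(path)
}

# ---- error helpers ----------------------------------------------------------

abort_validation <- function(msg) {
  abort(msg, class = "drugrepo_validation")
}

abort_missing_entity <- function(ids) {
  abort(
    paste0("unknown entity id(s): ", paste(ids, collapse = ", ")),
    class = "drugrepo_missing_entity"
  )
}

abort_io <- function(msg) {
  abort(msg, class = "drugrepo_io")
}
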