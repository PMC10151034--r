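# End-to-end graph construction from source tables.

#' Build an evidence-weighted knowledge graph from source tables
#'
#' Ingests the three table formats in a fixed order (protein-protein
#' interactions, drug targets, gene-disease associations -- first
#' registration wins for entities shared across sources), assigns evidence
#' probabilities, and combines redundant records per triple.
#'
#' @param config An [evidence_config()].
#' @param mitab Optional path to a PSI-MITAB-like table (see [read_mitab()]).
#' @param drug_targets Optional path to a drug-target table.
#' @param gene_disease Optional named list of gene-disease table paths; names
#'   must be `omim` or `cosmic`.
#' @param combiner A [combiner_spec()].
#' @return A `knowledge_graph` with combined edge probabilities.
#' @examples
#' rep <- generate_table1_replica(tempfile("replica"))
#' g <- build_graph(
#'   config = load_evidence_config(rep$paths$config),
#'   mitab = rep$paths$mitab,
#'   drug_targets = rep$paths$drug_targets,
#'   gene_disease = list(omim = rep$paths$omim, cosmic = rep$paths$cosmic)
#' )
#' glance(g)
#' @export
build_graph <- function(config, mitab = NULL, drug_targets = NULL,
                        gene_disease = list(), combiner = combiner_spec()) {
  check_evidence_config(config)
  graph <- knowledge_graph(combiner = combiner)
  add <- function(graph, records) {
    kg_add_assertions(graph, records, auto_register = TRUE)
  }
  if (!is.null(mitab)) {
    graph <- add(graph, read_mitab(mitab, config))
  }
  if (!is.null(drug_targets)) {
    graph <- add(graph, read_drug_targets(drug_targets, config))
  }
  if (length(gene_disease) > 0) {
    bad <- setdiff(names(gene_disease), c("omim", "cosmic"))
    if (length(bad) > 0 || is.null(names(gene_disease))) {
      abort_validation(
        "gene_disease must be a named list with names 'omim' and/or 'cosmic'"
      )
    }
    for (src in names(gene_disease)) {
      graph <- add(graph, read_gene_disease(gene_disease[[src]], src, config))
    }
  }
  recombine_edges(graph)
}
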