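# drugrepo

Evidence-weighted knowledge graphs for drug repositioning.

Finding new disease indications for existing drugs is cheaper and faster
than de-novo discovery, but the evidence connecting a drug to a disease is
scattered across heterogeneous sources: curated drug–target databases,
experimental protein–protein interaction (PPI) repositories, and
gene–disease association catalogues. These sources disagree in reliability —
a manually curated drug–target entry is far more trustworthy than a single
yeast two-hybrid screen — and they frequently report the same interaction
more than once.

`drugrepo` integrates such tabular assertion records into one typed
drug–protein–gene–disease knowledge graph, attaches a probability to every
assertion based on its evidence, merges redundant reports, and proposes
repositioning candidates as the drugs reachable from a disease through
high-confidence interaction chains. Each assertion keeps its provenance
(source database, detection method, publication), in the spirit of the
nanopublication model; a TriG export is available for interoperability.

## The model

**Assertion probabilities.** Manually curated assertions (drug–target,
gene–disease) receive *p* = 0.999. Experimental assertions receive a
probability from an expert rating of their detection method on a 1–3
confidence scale:

| level | meaning | *p* |
|---|---|---|
| 1 | weak evidence, needs independent verification | 0.8 |
| 2 | generally reliable | 0.95 |
| 3 | high quality, few false positives | 0.99 |

The method→level map and the probabilities are configuration
(`evidence_config()` / YAML), not code.

**Per-triple combination.** The graph stores one edge per
(subject, interaction type, object) triple. When several records back one
triple, their probabilities are combined by unweighted Stouffer voting
("composite Z-scores"):

    P(x₁…xₙ) = Φ( Σᵢ Φ⁻¹(P(xᵢ)) )

where Φ is the standard-normal CDF and Φ⁻¹ its quantile function. Concordant
reports above 0.5 reinforce each other — two independent level-1 reports
(0.8 each) combine to ≈ 0.954 — which a (geometric) mean cannot express; the
geometric mean remains selectable for comparison. Records identical on
(triple, source, method, publication) are de-duplicated before combination,
since mirrored copies of one experiment are not independent evidence.

**Candidate search.** The joint probability of an interaction chain is the
product of its edge probabilities, P(x₁∧…∧xₙ) = Πᵢ P(xᵢ). Starting from a
disease, `drugrepo` enumerates every simple path over incoming links that
satisfies a step limit and a joint-probability threshold (default: ≤ 3 steps,
*p* ≥ 0.93), keeps paths ending at a drug, and reports each drug's best
path. Because extending a path can only lower its probability, the search
prunes below-threshold partial paths without losing any valid path.

**Evaluation.** Candidates are scored against drug–disease labels from the
discovery pipeline (approved … in vitro … novel); every status except
`novel` counts as a validated "hit". `threshold_sweep()` traces precision,
recall and f-measure across either threshold to locate the operating point.
Scott's Pi (`scotts_pi()`) quantifies agreement between the two experts who
rated the detection methods.

## Worked example

The package ships a deterministic replica of a published melanoma
neighbourhood (25 candidate drugs; `melanoma_reference_table()` holds the
reference rows). Everything below is real output.

```r
library(drugrepo)

rep <- generate_table1_replica(tempfile("replica"))
graph <- build_graph(
  config = load_evidence_config(rep$paths$config),
  mitab = rep$paths$mitab,
  drug_targets = rep$paths$drug_targets,
  gene_disease = list(omim = rep$paths$omim, cosmic = rep$paths$cosmic)
)
graph
#> <knowledge_graph> 63 entities, 62 edges, 68 records (combiner: composite_z)
#>   entities: disease=1, drug=31, protein=31

candidates <- find_candidates(graph, "efo:EFO_0000756")  # melanoma
head(tibble::as_tibble(candidates)[, 2:6], 4)
#> # A tibble: 4 × 4
#>   drug_label  steps joint_probability path_node_ids
#>   <chr>       <int>             <dbl> <chr>
#> 1 Bosutinib       2             0.980 drugbank:DB_BOSUTINIB|hgnc:MAP2K1|efo:EFO…
#> 2 Dabrafenib      2             0.980 drugbank:DB_DABRAFENIB|hgnc:BRAF|efo:EFO_…
#> 3 Regorafenib     2             0.980 drugbank:DB_REGORAFENIB|hgnc:BRAF|efo:EFO…
#> 4 Sorafenib       2             0.980 drugbank:DB_SORAFENIB|hgnc:BRAF|efo:EFO_0…
```

25 drugs pass the default filter; each row shows the most probable chain
from drug to disease (e.g. Bosutinib → MAP2K1 → melanoma, joint probability
0.99 × 0.99 = 0.98). Scoring them against the shipped status labels:

```r
precision_recall_f(candidates, rep$labels)
#> # A tibble: 1 × 7
#>   precision recall f_measure n_candidates n_hits_returned n_known_hits
#> 1      0.88      1     0.936           25              22           22

glance(threshold_sweep(graph, "efo:EFO_0000756", rep$labels,
                       axis = "joint_probability"))
#> # A tibble: 1 × 7
#>   axis              optimal_threshold precision recall f_measure n_candidates
#> 1 joint_probability              0.93      0.88      1     0.936           25
```

22 of the 25 candidates are validated hits (precision 0.88) and all 22 known
hits are recovered (recall 1); the sweep confirms 0.93 as the
f-measure-optimal probability cutoff. `autoplot()` on the sweep or the
candidate table draws the corresponding ggplot figures.

A command-line surface wraps the same pipeline:

```sh
Rscript exec/drugrepo build --config cfg.yaml --mitab ppi.tsv \
    --drug-targets dt.tsv --omim omim.tsv --cosmic cosmic.tsv --out graph.jsonl
Rscript exec/drugrepo candidates --graph graph.jsonl --disease melanoma --out cand.csv
Rscript exec/drugrepo evaluate --candidates cand.csv --labels labels.tsv --out metrics.csv
```

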