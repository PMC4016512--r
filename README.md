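# clemine

Discovery of **CLE** and **CLE-LIKE (CLEL)** peptide-ligand genes in
plant EST and genomic sequence collections, implemented as a tested,
reusable R pipeline.

CLE genes encode ~80-100 aa secreted precursors — a signal peptide, a
degenerate non-conserved region (NCS1), and a 14-aa motif whose final
12 residues form the mature peptide hormone (for the CLE41/44 group this
is TDIF, `HEVPSGPNPISN`, the tracheary-element differentiation
inhibitor). CLEL precursors are similar but their 13-16 aa peptides
begin Asp/Glu-Tyr, and some CLEL genes are alternatively spliced via two
3'-terminal acceptor exons, each encoding a distinct peptide, downstream
of an `AG^GTA` donor context. These genes are short, largely intronless
(CLE) and deeply diverged outside the motif, so they are found by
translated motif searching rather than by generic gene prediction.

`clemine` provides each stage as an exported function and as one
orchestrated pipeline:

| Stage | Functions |
|---|---|
| Synthetic data with ground truth | `synth_config()`, `generate_dataset()`, `write_dataset()` |
| Translated six-frame motif scan (Smith-Waterman, BLOSUM62) | `translate_six_frames()`, `scan_motifs()`, `iterate_search()` |
| Species-aware greedy contig assembly + variant calls | `assemble()`, `detect_variants()`, `validate_contig()` |
| Signal-peptide prediction and full-length gates | `predict_signal_peptide()`, `full_length_gate()`, `call_genomic_candidate()` |
| Gene models: spliced alignment, intronless calls, alt terminal exons | `spliced_align()`, `call_intronless_genes()`, `find_alt_terminal_exons()` |
| Mature-peptide catalog and expression tallies | `extract_mature_peptide()`, `dedup_and_group()`, `compare_to_reference()`, `expression_tally()` |
| Phylogenetics (Poisson + pairwise deletion, NJ, bootstrap) | `progressive_align()`, `poisson_distances()`, `neighbor_joining()`, `bootstrap_consensus()` |
| End-to-end run with recovery scoring | `run_pipeline()` |

The key methodological definitions — the Poisson-corrected distance
d = −ln(1 − p) with pairwise deletion, the von Heijne (−3,−1)
signal-peptide rule, the 5'-most-Met full-length gate, and the
AG^GTA / polypyrimidine-AG alternative-splice rules — are described in
the methods vignette (`vignettes/clemine-methods.Rmd`).

## A worked example

```r
library(clemine)

cfg <- synth_config(seed = 42, n_species = 3, n_cle_genes = 3,
                    n_clel_genes = 2, est_error_rate = 0,
                    est_indel_rate = 0, est_full_length = TRUE)
res <- run_pipeline(config = cfg, reference = load_reference_peptides())
res$funnel
#>   n_ests n_scaffolds n_est_hits_round1 n_contigs n_validated_contigs
#> 1     54           9                54        18                  18
#>   n_full_length n_est_hits_round2 n_genomic_models n_est_models
#> 1            18                54                9           18
#>   n_alt_variants n_unique_peptides
#> 1              3                 6
res$report
#>           category recall precision
#> 1   gene_discovery      1         1
#> 2 full_length_gate      1         1
#> 3   exon_junctions      1         1
#> 4  splice_variants      1         1
#> 5  unique_peptides      1         1
```

Three species are planted with 3 CLE and 2 CLEL genes each (one CLEL
gene per species carries an alternative terminal exon, hence 18
transcripts and contigs). The funnel mirrors the analysis narrative: 54
ESTs are all motif-positive, assemble into 18 species-pure contigs, all
pass validation and the full-length gate; the genomic route recovers the
9 intronless CLE genes and spliced alignment models all 18 transcripts,
with the 3 planted alternative 3'-terminal-exon variants detected. The
report scores predictions against the generator's manifest: at zero EST
error, every category is recovered with precision and recall 1.0. The
catalog collapses the 15 genes to 6 unique peptides because orthologous
peptides are perfectly conserved across the planted species; exactly one
of them (TDIF) matches the bundled reference peptide set
(`attr(res$compare, "n_perfect")` is 1).

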