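---
title: "Mining CLE and CLEL peptide-ligand genes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining CLE and CLEL peptide-ligand genes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

CLE and CLE-LIKE (CLEL) genes encode small precursor proteins that are
secreted and proteolytically processed into short peptide hormones: a
12-aa dodecapeptide for CLE (the last 12 residues of a 14-aa conserved
motif) and a 13-16 aa peptide beginning Asp/Glu-Tyr for CLEL. Their
precursors share a common architecture: an N-terminal signal peptide
(15-30 aa), a highly degenerate non-conserved region (NCS1), the peptide
motif near the C-terminus, and sometimes a short C-terminal tail (NCS2).
The genes are short (CLE coding regions are ~240-300 nt and usually
intronless; CLEL genes carry introns, occasionally with two alternative
3'-terminal acceptor exons encoding distinct peptides), which makes them
hard for generic gene finders and well suited to translated motif
searching.

`clemine` implements the complete discovery workflow as a reusable,
testable pipeline: translated six-frame motif scanning of EST
collections, species-aware contig assembly with variant classification, a
signal-peptide gate for full-length validation, gene-model construction
by spliced alignment to genomic scaffolds with alternative
terminal-exon detection, a mature-peptide catalog with cross-species
deduplication and comparison to a reference peptide set, and
Poisson-corrected Neighbour-Joining phylogenetics with bootstrap support.
Because the original inputs (public EST databases, multi-gigabase conifer
genome assemblies) are not practical to ship or re-query, every stage is
exercised against a synthetic-data generator that plants genes with a
known ground-truth manifest.

# The synthetic-data generator

`synth_config()` / `generate_dataset()` plant CLE and CLEL loci on random
scaffolds for a configurable number of species and derive transcripts and
error-bearing ESTs from them. The generator is the package's definition
of the study conditions, and its defaults encode the architecture ranges
above:

* **CLE genes** are intronless; precursor length is drawn in 80-100 aa
  (240-300 nt coding) with NCS1 at least 40 aa and an optional short
  NCS2. One designated gene per species carries the TDIF dodecapeptide
  `HEVPSGPNPISN` exactly, in every species, emulating the one peptide
  perfectly conserved across gymnosperms and angiosperms.
* **CLEL genes** carry one intron inside NCS1. A configurable fraction
  (default one half) additionally carry an alternative 3'-terminal
  acceptor exon ~1 kb downstream (`alt_exon_spacing`) of an `AG^GTA`
  donor context planted in the middle of the primary terminal exon; the
  alternative exon encodes a distinct Asp/Glu-Tyr peptide in the same
  reading frame.
* **Orthologues** across species are derived from a per-gene ancestral
  precursor by per-site substitution outside the signal peptide and the
  peptide motif (`mutate_orthologue`). The default per-site divergence
  (0.25) is calibrated so whole-precursor identity between orthologues is
  ~84-85%, the level reported between congeneric conifer CLE precursors,
  while the mature peptide itself is perfectly conserved. Species 2
  copies species 1's TDIF-gene precursor unchanged, emulating the 100%
  conserved congeneric pair.
* **ESTs** are substrings of mature transcripts (optionally full-length)
  with configurable per-base substitution and 1-nt indel rates; they
  carry `species=` and `library=` tags drawn from the tissue vocabulary
  {bark/phloem, xylem, root, shoot/foliage, mixed, embryo, strobilus}.
  Each gene has a home tissue; one designated gene's ESTs are split
  between xylem and bark/phloem to exercise the cross-tissue overlap
  report.
* **Queries.** The pipeline's first-round query set emulates the known
  reference-flora motifs: each archetype motif diverged at
  `query_divergence` (default 0.12), on the premise that every planted
  gene family has a detectable homologue among the queries.

Two generator guarantees keep ground truth unambiguous. First, 5'-UTRs
are stripped of `ATG` trinucleotides so the 5'-most in-frame Met of every
transcript is the true initiator (the full-length gate is defined in
terms of that Met). Second, the neighbourhood of each planted alternative
splice structure is scrubbed of decoy signals: no `AGGTA` donor context
survives in exonic sequence except the planted one, and no spurious
acceptor within the search window satisfies the acceptor rules (an AG
preceded by a polypyrimidine tract, followed by an in-frame exon ending
in a stop with a 13-16 aa Asp/Glu-Tyr peptide immediately before it).
Scrubbing edits only bases that change no planted protein (UTRs, intron
interiors, or synonymous codon swaps). Without this guarantee a random
1-5 kb window contains, in expectation, a handful of AG dinucleotides
that satisfy the rules by chance, and planted-variant precision would not
be a meaningful recovery statistic.

What the generator does **not** emulate: realistic conifer repeat
content, multi-gigabase scaffold scale, chimeric or vector-contaminated
ESTs, quality values, and antisense ESTs (all reads are sense-strand).
Passing recovery tests therefore demonstrates the correctness of the
pipeline's logic under the planted-gene model, not its robustness to
every artefact of real EST archives.

# Motif scanning

`scan_motifs()` is a desk-scale stand-in for TBLASTN: every query is
Smith-Waterman aligned (BLOSUM62, affine gaps, gap open 11 / extend 1 —
the BLAST protein defaults) against all six translated frames of each
subject, and hits are mapped back to forward-strand nucleotide
coordinates. Defaults `min_identity = 0.5` and `min_score = 40` over a
span of at least 12 aa are chosen to reproduce TBLASTN-like sensitivity
for short degenerate motifs; the original search's E-value cutoff is not
recoverable, so these thresholds are a documented substitute and are
exposed as parameters. Multiple hits per frame are obtained by masking
each accepted hit and re-aligning. Alignment itself is delegated to
`Biostrings::pairwiseAlignment`; the test suite checks the reported
scores against an independent quadratic dynamic-programming oracle.
`iterate_search()` re-queries with motifs discovered in validated
contigs, which with identical thresholds can only grow the hit set.

# Assembly and contig validation

`assemble()` is a greedy overlap-layout-consensus assembler: exact
14-mer seeds propose placements, overlaps of at least 40 nt at 95%
identity or better are merged best-first, and reads carrying different
species labels are never merged (the high cross-species conservation of
these genes makes species-blind assembly collapse orthologues).
Containment is preferred over extension at equal overlap quality, and an
ends-free alignment fallback tolerates occasional indels, which are
recorded per member rather than absorbed into the consensus. The
consensus is a per-column majority with ties broken toward the
lexicographically earliest read id, making the result independent of
input order. `detect_variants()` classifies member-versus-consensus
differences by region (5'-UTR / coding / 3'-UTR) and effect (silent vs
amino-acid-changing by codon comparison), flagging insertions that
duplicate the adjacent equal-length segment as direct repeats.

Manual curation is operationalized in `validate_contig()` as a
three-part rule; a contig is discarded only when weak motif conservation
(identity below 0.6), a truncated open reading frame in the motif frame,
and a longer antisense ORF over the hit all co-occur. Any single symptom
is insufficient — matching the one worked rejection the screen's
curation logic is known from.

# Signal-peptide gate

The published screen delegated signal-peptide calls to SignalP; that
model cannot be reproduced from the text, so `predict_signal_peptide()`
is an explicit, self-contained substitute whose contract (boolean call,
score, cleavage position) matches what the pipeline consumes, and whose
grammar is shared with the generator: the score combines (i) the best
mean Kyte-Doolittle hydropathy over 7-15 residue windows within residues
2-30 (h-region), (ii) the von Heijne (-3,-1) small-residue weight at
candidate cleavage sites shortly downstream of the h-region within
residues 15-45, and (iii) a penalty for Asp/Glu among the first 30
residues. The default decision threshold (0.58) separates
grammar-generated signal peptides from random decoys at better than 95%
sensitivity and specificity in the bundled recovery test.

Two gates use it. The EST gate (`full_length_gate`) evaluates **only**
the 5'-most in-frame Met: if that Met yields a signal peptide the contig
is full-length, otherwise partial — deliberately with no fallback to
downstream Mets, a strict reading of the screen's stated rule. The
genomic gate (`call_genomic_candidate`) accepts any Met whose predicted
signal peptide lies between the Met and the motif; a motif hit with no
such Met is treated as spurious. The two rules differ on purpose: they
are implemented as stated, one per input class.

# Gene models and alternative terminal exons

`spliced_align()` aligns a transcript/contig to a scaffold with exact
16-mer anchors grouped into diagonals, colinear chaining (scaffold gaps
of 40-10,000 nt become introns), and junction refinement that shifts
each junction by a few nt to satisfy GT..AG when sequence ambiguity
permits, preferring canonical junctions, then fewer introns, then the
5'-most donor on ties. Both strands are tried and the higher
coverage-times-identity chain wins; chains covering less than 80% of the
transcript are rejected with a reason. Substitution errors are tolerated
by the junction refinement; transcript indels are not modelled (the
assembler's majority consensus removes almost all of them at realistic
rates).

`find_alt_terminal_exons()` scans the interior of a model's terminal
coding exon for `AG^GTA` donor contexts and, for each, searches as far
as 5 kb downstream for acceptors: an `AG` preceded by a polypyrimidine
tract (at least 6 pyrimidines in the preceding 8 nt), followed by an
exon that continues the reading frame and reaches a stop codon with a
13-16 aa Asp/Glu-Tyr peptide immediately before it. Candidates encoding
the primary transcript's own peptide, or a peptide already emitted, are
discarded (5'-most acceptor wins), so every reported variant carries a
distinct peptide — which is also the biological definition of the
phenomenon being sought. The polypyrimidine-tract requirement is the
canonical 3'-splice-site context; without it, random AG dinucleotides
satisfy the frame-and-peptide rules often enough to swamp true variants.

`call_intronless_genes()` covers the genomic route for CLE: each motif
hit is extended to its stop-to-stop ORF in the hit frame and screened
with the genomic gate; accepted ORFs become single-exon models. Tandem
duplicates yield two distinct models.

# Catalog and expression tallies

`extract_mature_peptide()` applies the family rules (final 12 aa of the
14-aa CLE motif; Asp/Glu-Tyr to the C-terminus capped at 16 aa for
CLEL). Where CLEL peptides end when a C-terminal tail exists is not
defined by the architecture; the default (through the C-terminus, cap
16) matches the stated 13-16 aa range and is configurable.
`dedup_and_group()` groups peptides by exact string across genes and
species; `compare_to_reference()` reports the closest reference peptide
by ungapped distance (Hamming at equal length; best sliding offset with
one penalty per overhang residue otherwise) with per-position mismatch
annotation. The bundled 32-entry reference
(`inst/extdata/athaliana_cle_reference_synthetic.fasta`) contains the
three real published dodecapeptides printed in the primary literature
(CLV3, CLE13, CLE41/44-TDIF) plus synthetic CLE-like stand-ins for the
rest — the full published set is not redistributed — which suffices for
conservation screening because the generator excludes the reference
strings from its sampled peptides. `expression_tally()` aggregates EST
tissue labels per gene and reports genes seen in two or more tissue
classes, with the xylem/bark-phloem intersection called out explicitly.

# Phylogenetics

`progressive_align()` builds a guide order from 3-mer composition
distances (average linkage) and merges profiles with a profile-profile
Needleman-Wunsch over BLOSUM62 expected scores and affine gaps (open 11,
extend 1; a gap of length L costs open + L*extend, matching the
convention of the alignment library used elsewhere in the package).
`poisson_distances()` applies pairwise deletion — each pair is scored
over the columns where both rows are ungapped — and the Poisson
correction d = -ln(1 - p); p = 1 is an error naming the offending pair,
as the distance is undefined there. `neighbor_joining()` is the package's
own Saitou-Nei implementation with a deterministic tie-break
(lexicographically smallest label pair) and negative branch lengths
clamped to zero; the test suite cross-checks its topologies against an
independent implementation (`ape::nj`) and against exhaustive recovery
of random additive trees. `bootstrap_consensus()` resamples columns,
discards (and counts) replicates in which any pair reaches p = 1, and
reports the majority-rule (>50%) consensus with support as the
percentage of retained replicates containing each bipartition. All
replicates are driven by one seeded RNG stream, which keeps the whole
run reproducible from a single integer.

# Pipeline and recovery scoring

`run_pipeline()` wires the stages in fixed order and logs a funnel of
record counts (ESTs, motif-positive ESTs, contigs, validated contigs,
full-length calls, genomic models, EST models, variants, unique
peptides). When a manifest is present, `recovery_report()` scores gene
discovery, full-length calls, exact exon-junction coordinates, splice
variants (by distinct non-primary peptide), and unique peptides, each as
precision and recall against the planted truth.

# Problem sizes and numerical choices

The bundled tests and the acceptance script run at desk scale: two to
three species with three to five genes each for end-to-end recovery
(roughly 50-70 ESTs, scaffolds of a few kb), eight species for the
catalog-counting and orthologue-identity analyses, and a 12-taxon
4-clade alignment with 1000 bootstrap replicates for the support
analysis. These sizes were chosen so the full suite exercises every
stage, including both strands, multi-exon genes, alternative variants,
and a tandem duplicate, while each run stays in the minutes range on a
single CPU. Determinism throughout comes from a single seed in the
config: generation, assembly tie-breaks, NJ tie-breaks and bootstrap
resampling are all either seeded or deterministic by construction.

# Known limitations

* The signal-peptide model is a deliberately simple hydropathy +
  (-3,-1) substitute; on real proteins it will not match a trained
  predictor's accuracy, and the recovery numbers quoted for it are
  against its own grammar.
* The assembler handles substitutions natively and indels via a
  per-member alignment fallback; high indel rates fragment contigs.
* `spliced_align` requires exact 16-mer anchors per exon, so exons
  shorter than ~16 nt or error-saturated exons are not recovered.
* Only canonical GT..AG introns are modelled.
* Variant models that duplicate exons into near-identical proteins are
  reported as separate variants (no merging of near-duplicates).
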