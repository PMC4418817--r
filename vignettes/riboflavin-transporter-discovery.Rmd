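---
title: "Riboswitch-guided discovery of riboflavin transporters: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Riboswitch-guided discovery of riboflavin transporters: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riboscout)
```

## The problem

Riboflavin (vitamin B2) is the precursor of the flavin cofactors FMN and
FAD. Bacteria obtain it either through the five-enzyme riboflavin
biosynthetic pathway (RBP) or through dedicated transporters
(RibU, RibM, RibN, RfuABCD and several candidates such as ImpX, RfnT,
RibZ, RibV and the RibXY system). Most known transporter genes were
first recognised not by sequence similarity but by a regulatory
signature: an FMN riboswitch — a cis-acting mRNA element that binds FMN
and throttles expression of downstream genes — sitting in the leader of
their transcriptional unit.

`riboscout` packages that discovery logic as a desk-scale, fully
testable pipeline:

1. **Transcriptional-unit (TU) prediction** from gene order, strand and
   intergenic distance (optionally functional-linkage scores).
2. **Riboswitch scanning** of each TU's upstream region with a
   position-wise log-odds profile under a bit-score cutoff.
3. **Prototype-anchored orthology**: local alignment of candidate
   proteins against one experimentally characterised prototype per
   transporter family, with identity/coverage thresholds,
   bi-directional best hits (BDBH) and Markov clustering of the
   similarity graph.
4. **Co-occurrence classification** of genomes by transporter and RBP
   presence, summarised per phylum.
5. A **neighbor-joining display phylogeny** from concatenated marker
   alignments.

Because the real inputs are hundreds of external genomes, the package
ships a **synthetic-cohort generator** that plants every signal the
pipeline looks for — riboswitches at controlled bit scores, transporter
genes at controlled identities, RBP markers, operon structure — with a
machine-readable truth table. Every stage can therefore be scored
end-to-end with no downloads.

## Models and procedures

### TU prediction

Genes on one replicon, sorted by start, are greedily merged: two
adjacent same-strand genes share a TU iff their intergenic distance is
at most `d_max` **or** their linkage score is at least `link_min`. A
strand change always breaks. Overlapping same-strand genes have
negative distance and merge — overlap is stronger evidence of
co-transcription than a short gap. Defaults are `d_max = 50` bp and
`link_min = 0.8`; no authoritative numeric thresholds exist for this
classic distance heuristic, so both are explicit configuration, echoed
in the run manifest. Minus-strand TUs report genes in transcription
order (right to left).

The upstream region of a TU is the `window` nucleotides ending
immediately before its first gene in transcription order,
reverse-complemented for minus-strand TUs, truncated at linear replicon
edges and wrapped for circular ones. The default window of 350 nt is
generous for a riboswitch of 120–160 nt plus spacer.

### Riboswitch profile and bit scores

The covariance-model search of a real riboswitch scan is replaced by an
ungapped position-wise log-odds profile: position *i* assigns
`log2(p_i(b) / q(b))` bits to base *b*, with match frequencies `p_i`
(pseudocounted, default Laplace `+1`) and background `q`. Scanning
takes the maximum over all ungapped placements; ambiguous bases
contribute 0 bits (the background expectation). This deliberately drops
secondary-structure scoring — the package preserves the *bit-score plus
cutoff contract* of the original search, not its statistics; that is
also why no E-values are reported.

The packaged `fmn_profile()` ("fmn-lite") is a synthetic stand-in, not
an Rfam derivative: 120 positions over a fixed consensus with 85%
per-position consensus probability and uniform background, giving a
maximum score of ~212 bits. Under this background a random 120-nt
window scores around −156 bits with a standard deviation near 19, so
the operating cutoff sits dozens of standard deviations above noise and
false hits on riboswitch-free windows are practically absent — a
property the test suite measures over 1000 windows.

The cutoff itself follows the published calibration rule: the lowest
score observed among riboswitches sitting on known riboflavin
biosynthetic operons (`calibrate_cutoff()` is simply that minimum). The
package's default operating point is 51.34 bits. Hits strictly below
the cutoff are suppressed; at most one hit (the best placement) is
reported per TU, since riboswitches are counted per transcriptional
unit.

### Orthology

Candidates are compared to one prototype per family by exact
affine-gap Smith–Waterman (Rcpp, BLOSUM62, gap open 11 / extend 1 —
BLAST-like conventions without the external binary). Tie-breaks are
pinned down (best cell at the smallest row/column; traceback prefers a
residue pair over a subject gap over a query gap over a fresh start) so
score, identity and coverage are bit-for-bit reproducible; the test
suite holds them equal to an independent brute-force dynamic program.

Definitions: **identity** is matching columns over all aligned columns
(gaps count as columns); **coverage** is the fraction of the
*prototype* spanned by the alignment. "Total sequence coverage" is
ambiguous in the field; prototype (subject) coverage is this package's
reading, and the alignment result also carries query coverage for
callers who want a different rule.

A candidate is accepted for a family iff identity is *strictly greater*
than the family's threshold ("more than 38%") and coverage is *at
least* the coverage threshold ("80% or more"). The RfnT family uses
the stricter 42%/90% because the generic rule is known to pull in
non-transporter homologs. Candidates within a small margin (default
0.03) below the identity threshold are rescued only when their TU
carries a riboswitch hit — the mechanised, flagged form of adjusting
thresholds on regulatory evidence; no silent adjustment is ever made.
Genes passing several families keep the higher-identity family.
Composite systems (RibXY, ECF-RibU, RfuABCD) are represented by their
substrate-binding components (RibY, RibU, RfuA) only.

BDBH evidence in the pipeline is computed between each proteome and the
prototype set (the search is prototype-anchored, so that is the
reciprocal comparison that matters); genome-pair BDBH is available as
its own operation. Similarity graphs are clustered by Markov clustering
(expansion 2, configurable inflation, pruning threshold `1e-5`), with
alignment scores normalised by self-score as edge weights in place of
e-values, which would require database-size statistics that are out of
scope.

The packaged family prototypes are **deterministic synthetic
stand-ins** (the experimentally characterised sequences are external
data); they carry realistic lengths and the RibV stand-in contains
exactly 5 tryptophans, mirroring the property that excludes RibV from
heterologous expression in E. coli (UGA encodes tryptophan in
Mollicutes but stop in E. coli). `count_tryptophans()` exposes that
feasibility check.

### Co-occurrence

A genome is RBP-positive iff it carries **both** marker families
encoding the last two pathway steps (COG0054-like and COG0307-like); a
single marker is reported as `partial_rbp = TRUE` but `rbp = FALSE`.
Each genome lands in exactly one of four categories — RBP+transporter,
transporter-only, RBP-only, neither — and the tallies satisfy
`transporter_total = both + transporter_only` by construction. The
phylum-level distribution matrix counts genomes per
(phylum, family, RBP±) cell; counts are genome-level, with no attempt
to deduplicate strains into species.

### Phylogeny

Marker alignments are masked by removing columns whose gap fraction is
0.75 **or more** (the boundary is inclusive on the removal side: 3 gaps
in 4 rows go, 74 in 100 stay). Distances use the Kimura protein
correction `d = −ln(1 − p − 0.2 p²)` on the mismatch fraction *p* over
mutually ungapped columns — a closed-form, dependency-free substitute
for maximum-likelihood distances that is adequate for a display tree;
saturated pairs are capped (default 5) and flagged. Trees come from
canonical neighbor joining (`ape::nj`), which is exact on additive
matrices; negative branch lengths are clamped to zero with a warning.
Bootstrap supports resample columns, rebuild the distance+NJ tree and
map bipartition frequencies onto the full-data tree.

## The synthetic generator

`cohort_config()` describes the cohort; `generate_cohort()` builds it.
Per genome (each with its own RNG stream derived from the master seed,
so generation is deterministic and order-independent):

* transporter genes are prototypes mutated to a target global identity
  (substitutions uniform over the 19 alternative residues; optional
  single-residue indels capped at 5% of length, off by default so the
  planted identity is exact);
* riboswitches are profile samples degraded from the consensus to a
  target bit score (greedy plus local refinement, accurate to ±2 bits
  by contract, typically much closer), placed a 30-nt spacer upstream
  of their TU's first gene, strand-aware;
* RBP-positive genomes get a two-gene marker operon; optionally a
  single-marker "partial" state exercises the dual-marker criterion;
* intergenic distances are drawn uniformly within ±40% of their means —
  20 bp within operons, 250 bp between them — so the default `d_max`
  of 50 bp separates the two regimes cleanly;
* background DNA is i.i.d. with configurable GC; coding sequences use
  one fixed codon per amino acid plus a stop, enough for coordinates,
  strand and translation to round-trip;
* a concatenated marker alignment (ancestor diverged ~10% per phylum,
  ~6% per genome, plus a block of gap-heavy columns) feeds the display
  tree.

What the generator does **not** emulate: realistic codon usage and GC
structure, phylogenetically correlated sequence evolution, genuine
covariance-model sampling, paralogy, horizontal transfer, assembly
artefacts. Passing tests therefore demonstrate the pipeline's decision
logic and bookkeeping under its stated assumptions, not recall on real
genomes.

`random_cohort_config()` fixes the cohorts used for evaluation: planted
identities drawn from 0.55–0.70 (clearly above threshold), riboswitch
scores at 60 bits or more, anchor riboswitches on RBP operons at 55–62
bits, RBP prevalence 0.7. With identities that far from the decision
boundary, truth recovery is expected to be exact; cohorts straddling
the boundary are exercised separately in the unit tests.

## Numerical choices and degenerate inputs

* Coordinates are 1-based inclusive throughout the R API (the
  Bioconductor convention); GFF3 is written 1-based inclusive, BED
  0-based half-open. One convention end-to-end avoids off-by-one
  churn.
* Frequencies are floored at `1e-9` before the log, so a zero
  pseudocount yields very negative but finite scores.
* A sequence shorter than the profile is scored over its single
  truncated placement; an empty upstream region (TU at the edge of a
  linear replicon) is an empty scan, not an error.
* Score ties in scanning and alignment resolve to the smallest offset
  / smallest cell; best-hit ties resolve to the lexicographically
  smallest subject id.
* An empty cohort is valid and produces empty outputs everywhere.

## Problem sizes

The shipped tests run the alignment oracle on 200 random pairs of up to
30 residues, BDBH on 20 toy proteome pairs, riboswitch recovery on a
20-genome cohort with 500 null windows, and the full pipeline on
cohorts of up to 30 genomes of 8 genes each; `scripts/acceptance.R`
re-runs the 30-genome pipeline plus 1000 null windows. These sizes were
chosen as the smallest cohorts in which every decision rule
(strand handling, operon structure, threshold boundaries, all four
co-occurrence categories) is exercised many times over.

## Known limitations

* The ungapped profile cannot model variable-length riboswitch stems;
  genuinely divergent riboswitches would be missed. The profile backend
  is a stand-in by design.
* Threshold adjustment "on synteny and operon structure" beyond the
  riboswitch-linked rescue is not mechanised; rescued calls are flagged
  so a reviewer can audit them.
* Kimura-corrected distances saturate near p ≈ 0.85; the display tree
  is not a substitute for model-based phylogenetics.
* Genome-level counts are not species-deduplicated.

## A worked example

```{r example, eval = FALSE}
cfg <- random_cohort_config(n_genomes = 10, seed = 1)
run <- run_pipeline(cfg, out_dir = tempfile("riboscout"))
run
evaluate_against_truth(run)[c("riboswitch_recall", "ortholog_accuracy",
                              "category_accuracy")]
```
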