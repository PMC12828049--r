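---
title: "Methods: conserved-TFBS footprinting and macrosynteny statistics"
author: "phylofoot"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: conserved-TFBS footprinting and macrosynteny statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

`phylofoot` implements comparative phylogenetic footprinting: it
predicts transcription-factor binding sites (TFBSs) that are plausibly
functional because they (i) sit inside non-coding sequence conserved
across several related species, (ii) optionally fall in open chromatin,
(iii) occupy the same relative position in every species' copy of the
conserved element, and (iv) belong to transcription factors expressed at
the developmental stage and in the cell types where the target gene is
active. It also provides the macrosynteny statistic used to pair
chromosomes between two species from a homology table.

The underlying assumptions are the standard ones of footprinting:
regulatory elements retain elevated sequence identity against a diverged
background; binding-site position within an element is approximately
preserved (here, after length normalization); and a regulator must be
expressed to be relevant. None of these is guaranteed for any individual
site — the output is a candidate list for experimental follow-up, not a
set of validated enhancers.

# Coordinate and orientation conventions

All intervals are 0-based half-open internally (BED compatible); 1-based
coordinates appear only in human-readable displays. Upstream regions are
always reported in *promoter orientation*: position increases toward the
start codon regardless of genomic strand (`extract_upstream()` reverse
complements minus-strand genes). This makes normalized positions
directly comparable across species and strands. `N` bases are allowed
and are treated as mismatching everything during alignment and as the
column-minimum contribution during motif scoring. Default upstream
length is 5000 bp and is a per-gene setting — genes with long 5'-UTRs
warrant a longer window (e.g. 7000 bp).

No masking of neighboring genes inside the upstream window is applied:
whether overlapping transcription units should be excluded is left to
input preparation, since a minimal 5-column gene table carries no exon
structure.

# CNCS detection

Each non-reference promoter is aligned globally to the reference
promoter with affine gap penalties (match +1, mismatch −1, gap open −5,
gap extend −0.5; `Biostrings::pairwiseAlignment`). Global alignment is
appropriate because the compared sequences are anchored at the same
biological landmark (the start codon) and have comparable lengths; it is
deterministic for fixed inputs, unlike a web alignment service.

Conservation is then called with a VISTA-style sliding window: a window
of `window = 100` alignment columns moves in steps of one column, and
the window's identity (matching columns / window; gap and `N` columns
count as mismatches) is **anchored at the window's center column**.
Center columns with identity ≥ `min_identity = 0.70` are marked; maximal
runs of marked reference positions become conserved segments, and
segments shorter than the window are dropped. Center anchoring is the
convention of VISTA conservation curves and is a deliberate numerical
choice: marking *every* column of a passing window inflates segment
boundaries outward by up to a full window when the background identity
is non-trivial (≈ 0.6 at the simulator's default divergence), whereas
center anchoring keeps boundaries within about half a window of the
underlying conserved block. The costs are symmetric: a fully conserved
sequence loses up to `window − 1` edge bases. When the alignment is
shorter than the window, the whole alignment is treated as a single
window and, if it passes, all its columns are marked.

The 100 bp / 70% defaults are the conventional conserved-element
criterion for this kind of analysis; both are configurable, as is the
minimum CNCS length (default 100 bp).

Per-pair segments are intersected across **all** non-reference species
(per-base AND over the reference coordinate line, via `IRanges`); only
intervals supported by every species survive. One species is designated
the reference and all CNCS coordinates are defined on its promoter, then
projected into each species through the alignment columns
(`project_to_species()`); endpoints landing in a gap slide inward to the
nearest aligned base, and a projection that collapses to zero length is
an error naming the species.

ATAC gating is optional: peaks from all developmental stages are pooled
and merged, and an interval passes if it overlaps the merged union by at
least `min_overlap = 1` bp. With no peak data, every interval passes
with `atac_supported = FALSE`. Gating is optional because open-chromatin
support is corroborating evidence in this design, available only for
species with ATAC data; requiring it for all species would silently
discard everything whenever peaks are missing.

# Motif scanning

PFM counts become PWMs with a pseudocount (default 0.8, added per cell)
and a uniform background; the score of a window is its summed log2-odds.
Scores are min–max normalized: `(S − s_min)/(s_max − s_min)`, where
`s_min`/`s_max` are the column-wise minimum/maximum attainable sums. A
window is a hit when its relative score is **at least** `1 − deficit`
(inclusive), with `deficit = 0.15` by default — the deficit convention
of relative-score scanners. Both strands are evaluated; minus-strand
hits are reported with coordinates on the promoter-orientation sequence.
A degenerate motif with `s_max = s_min` scores 1.0 with a warning. The
normalized position of a hit is its window midpoint divided by the CNCS
length; the midpoint is invariant to motif-width differences at element
edges, which matters when CNCS lengths differ across species.

Scanning runs per species on that species' projected CNCS sequence, not
on the reference: compensatory turnover can shift or regenerate sites,
and the per-species scan is what makes the positional comparison
meaningful. The vertebrate-centric matrices a user will typically supply
carry no lineage-specific correction; none is applied.

# Positional conservation

For each reference hit, every other species must have a hit of the same
motif identifier in the same CNCS with normalized-position difference
≤ `margin = 0.10`, inclusive. The nearest qualifying hit per species is
recorded (ties break to the smaller start coordinate, for determinism);
one non-reference hit may support several reference seeds. Strand is
*not* required to match — many factors bind degenerate or approximately
palindromic sites, and requiring strand agreement would silently halve
sensitivity for them; strands are recorded for inspection. Matching is
by exact motif identifier, not motif family: family collapsing would
require a curated family map and makes results harder to reproduce.

# Expression gating

Bulk filter: per-gene expression is averaged over the selected stages
(average first, then percentile), the threshold is the
linear-interpolation percentile (default 25th) of that stage-averaged
vector over the *whole* transcriptome including zero-count genes, and
the comparison is strict (`>`). The interpolated convention is `stats::
quantile` type 7 — e.g. the 25th percentile of 0…99 is 24.75 — so a gene
exactly at the threshold fails. Single-cell filter: raw counts are
summed per selected cluster (pseudobulk aggregation) and the per-cluster
sums averaged; the default threshold is the 50th percentile, again
strict. Both thresholds accept absolute overrides, because published
analyses often round their computed percentiles to fixed cutoffs and
exact reproduction then requires the override, not the percentile. A
motif mapped to several TF genes passes if *any* mapped gene passes —
the permissive reading appropriate for a candidate list. Unmapped motifs
are excluded but enumerated in the audit table.

# Macrosynteny statistics

From a hit table (geneA, geneB, score), the C-score of a hit is its
score divided by the larger of the two genes' best scores; filtering at
0.99 (inclusive) approximates reciprocal best hits, and 0.7 is the
relaxed setting for comparisons across whole-genome duplications. For
every chromosome pair sharing at least one ortholog pair, a 2×2 table
(shared / A-only / B-only / neither) is tested with a **one-sided**
(enrichment) Fisher exact test: correspondence means over-representation
of shared pairs, and a two-sided test would flag depletion
meaninglessly. Bonferroni correction uses the number of pairs actually
tested (those with at least one shared gene pair), the standard
practice; the full-grid factor is available as an option. Significance
is adjusted p < `alpha` (default 0.05; 0.2 is the lenient setting for
very distant comparisons). Degenerate inputs (a species with one
chromosome) yield p = 1 throughout. Excluding gene pairs outside the
significant chromosome pairs is a *reporting* filter
(`pairs_in_significant`), not a statistical step.

# Synthetic data: what it emulates and what it does not

`simulate_promoters()` draws a uniform-random reference promoter
(default 5000 bp) and derives each other species by per-site
substitution — 0.02/site inside three 300-bp conserved blocks,
0.40/site outside — plus indels (default 0.002/site, 1–3 bp) outside
planted motif footprints. These rates emulate deep divergence between
related genera with clearly conserved regulatory islands, and they make
block detection cleanly separable at the 100 bp / 70% criterion. Planted
motifs are written verbatim at the same within-block position in every
carrying species; species outside the carrier set get random sequence
over the footprint, so a "4-of-5" motif is genuinely absent, not merely
mutated, in the fifth species. Indel suppression inside motifs keeps
positional truth exact, deliberately separating positional-filter
correctness from alignment robustness.

The generator uses a star phylogeny (every species independently derived
from the reference), uniform base composition, no selection model, no
repeats, and no neighboring genes. Passing tests therefore demonstrate
algorithmic correctness under the stated statistical structure — not
performance on real assemblies, where GC heterogeneity, repeats,
lineage-specific indel regimes and annotation errors all degrade
alignment quality before the pipeline's own logic is exercised.

`simulate_expression()` builds a transcriptome of filler genes spanning
a wide lognormal range (20% zeros) so percentiles are well defined, and
places designated TFs above or below the bulk 25th percentile and on/off
in single-cell clusters (Poisson counts) by construction.
`simulate_orthologs()` emits one mutual-best hit per ortholog pair
(C-score exactly 1) with a configurable fraction of uniformly placed
noise pairs.

# Problem sizes and determinism

The shipped test suite exercises: 50 random PWM/sequence pairs against
an exhaustive scan oracle; 100 random five-species hit configurations
against an exhaustive positional-match oracle; 20 seeded end-to-end
replicates of the default five-species, 5000-bp design with three
all-species planted motifs and one four-of-five motif; calibrated
expression matrices whose 25th/50th percentiles are known exactly; a
noise-free 19×19-chromosome ortholog table plus 50 null replicates; and
byte-level comparison of rerun artifacts. The acceptance script uses 10
end-to-end replicates and 20 null replicates. These sizes were chosen so
the whole battery runs comfortably on a laptop while keeping the
binomial noise of the simulated checks small relative to their margins.

Every stochastic component takes an explicit seed; `run_footprint()`
itself is deterministic given its inputs, and `write_footprint_outputs()`
emits an MD5 manifest so reruns can be verified byte-for-byte.

# Known limitations

- Pairwise reference-anchored alignment, not simultaneous multiple
  alignment: a segment conserved in all species but rearranged in the
  reference is missed.
- Column identity weights all positions equally; no indel-aware or
  branch-length-aware conservation score.
- Motif hits are threshold calls, not calibrated p-values; no redundancy
  reduction across a motif library, so closely related matrices produce
  correlated candidates.
- The expression gate is binary at a percentile; a TF just under the
  threshold at the sampled stages is dropped even if expression peaks
  between them.
- Macrosynteny testing treats gene pairs as exchangeable; tandem arrays
  and segmental duplications violate that and can inflate counts.
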