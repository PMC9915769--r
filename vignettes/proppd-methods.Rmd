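---
title: "Methods and design choices in proppd"
author: "proppd authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design choices in proppd}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proppd)
```

## Overview

`proppd` implements the computational chain of a proteomic peptide phage
display (ProP-PD) screen: a display library of overlapping 16-mer peptides
tiled across intrinsically disordered proteome regions is selected against
a bait, the enriched pools are deep-sequenced, and the reads are distilled
into a degenerate binding motif whose proteome-wide instances are then
analysed for PTM crosstalk. The motivating biology is the recognition of a
`PxYx[I/L]` motif by the intervening domain of O-GlcNAc transferase (OGT),
where phosphorylation of the motif tyrosine switches binding off and
O-GlcNAc sites cluster within about 100 residues of the motif. This
vignette records the models, parameter choices and numerical conventions,
and what the synthetic benchmark does and does not demonstrate.

## Read processing model

Selection reads have a fixed architecture: `barcode | 5' adapter | 48-nt
insert | 3' adapter`. Because the architecture is fixed, adapters are
located by exact anchor match at their expected offsets rather than by
alignment; this is deterministic, fast, and appropriate for a library in
which every construct is built the same way. Barcode assignment is exact
prefix matching by default; an optional Hamming-distance-1 mode assigns a
read only when exactly one barcode is within distance 1. Translation uses
the standard genetic code in frame 1, and any in-frame stop codon fails
the read. Quality scores are ignored: no quality-based filter is part of
the processing model, and the simulator writes constant Phred+33 scores.

Every read receives exactly one outcome — `ok` or one of
`barcode_mismatch`, `adapter_mismatch`, `length_error`, `stop_codon`,
`unmapped` — and the per-replicate log preserves the identity
`ok + failures = total`. This conservation property is enforced by a
property-style test on deliberately corrupted inputs.

## Confidence criteria

Peptides are scored on four booleans per bait, and the stringent selection
keeps peptides meeting at least three:

* **replicated** — nonzero counts in ≥ 2 replicate selections of the same
  bait. Replication is assessed within bait; peptides enriched by more
  than one bait are additionally flagged `shared_across_baits` rather than
  pooled, so the within-bait and cross-bait evidence stay distinguishable.
* **overlapping** — another observed peptide from the same source protein
  overlaps it by ≥ 8 residues in source coordinates. Eight residues is the
  natural adjacent-tile overlap of a half-overlapping 16-mer tiling, and
  for a tiled library coordinate overlap of ≥ 8 is equivalent to sharing
  an identical 8-mer.
* **high_count** — the peptide's total for the bait reaches the 0.75
  quantile of nonzero totals. A quantile rather than an absolute count
  keeps the criterion scale-free across sequencing depths; 0.75 is a
  deliberate default exposed as `count_quantile`.
* **motif_match** — the peptide matches a supplied consensus. On a first
  pass (before discovery) no consensus exists and the criterion is
  `FALSE` for all peptides rather than an error, so a first-pass tier can
  be at most `medium`; re-calling with the discovered consensus upgrades
  consistent peptides to `high`.

The tier mapping is exact: 4 criteria = high, 3 = medium, ≤ 2 = low.
Adding counts to a peptide can only raise its tier (verified by a fuzzed
monotonicity test).

## Motif discovery

Candidates are generated by *seed-and-degenerate* enumeration: every
ungapped k-mer present in the peptide set (lengths 3–8, default 3–6)
seeds patterns in which interior positions are replaced by wildcards
(first and last positions stay fixed, at least three positions stay fixed
overall); a final merge pass combines pairs of patterns differing at one
fixed position into a candidate with a two-residue set there (`PxYxI` +
`PxYxL` → `PxYx[IL]`). Candidates carry at most one two-residue position.
This is a deliberate narrowing: it covers the `[I/L]`-type degeneracy that
hydrophobic-pocket recognition produces, keeps the candidate space finite,
and avoids a degeneracy arms race in which ever-looser patterns
accumulate matches. Positions allow at most two residues.

Scoring is a per-peptide binomial: with background residue frequencies
`f`, a window matches with probability `p_site = Π_j Σ_{a∈S_j} f(a)` over
the fixed positions, a peptide of length `W + L − 1` contains ≥ 1 match
with probability `p_bg = 1 − (1 − p_site)^W`, and the p-value is the
exact binomial upper tail of `k` matching peptides out of `N`. This
"peptide contains the motif or not" statistic is simpler than full
SLiMChance-style corrections but is exactly testable against a summation
oracle, and it matches how screen results are reported (so many of the
top peptides contain the motif). Benjamini–Hochberg correction is applied
across candidates; ranking is by p-value with ties broken by more fixed
positions and then pattern string, making results invariant to peptide
input order. p-values are floored at 1e-300 to avoid exact zeros from
degenerate backgrounds.

Two caveats matter in practice. First, the binomial model treats peptides
as independent, but a tiled library violates this: overlapping tiles from
one locus share flanking sequence, so feeding *all* selected peptides to
discovery can rank a locus-specific exact k-mer above the true consensus.
Discovery should therefore run on the most-enriched peptides (the worked
examples use the top 40 by total count), mirroring how screens report
their top-N. Second, the uniform background default matches the
simulator's residue model; for real data a composition table should be
supplied.

A "single amino acid variant" match mode (exactly one fixed position may
mismatch) is available via `max_mismatch = 1` in `motif_match_starts()`,
for variant-tolerant tallies of a consensus among top peptides.

## Proteome scanning filters

A raw match becomes a passing hit only if (i) every motif residue has
disorder score > 0.4, (ii) no wildcard position is proline, and (iii) the
protein is not secreted and the match is not in an extracellular domain.
The all-residue disorder rule is the default reading of a motif lying
"inside" a disordered region; a mean-over-span alternative is selectable
(`disorder_rule = "mean"`). The proline exclusion is implemented as a
filter on raw matches rather than folded into the search pattern so that
excluded matches remain visible with their failure flags — operationally
the two are identical. Topology is protein-level by default
(`intracellular` / `secreted`), with optional per-region extracellular
intervals. Overlapping matches are all retained; a protein counts once in
the motif-protein set regardless of its number of hits. All coordinates
are 1-based inclusive, matching residue numbering conventions such as
P145/Y147/I149.

The scanner is verified against an exhaustive position-by-position oracle
(`brute_force_scan()`) on a thousand random sequences, and disabling all
filters reproduces the raw regex match set exactly.

## Distance convention and crosstalk summaries

The distance between a PTM site and a motif is, by default, the number of
residues *strictly between* the site and the nearest motif residue,
minimised over the protein's passing hits, with 0 for sites inside or
adjacent to the span. This gap convention makes a site at residue 114
exactly 30 residues from a motif spanning 145–149, which is how such
distances are quoted in the literature ("30 amino acids upstream"); an
absolute-offset alternative (`convention = "nearest"`) is provided since
histogram conventions vary. Percentages in the summary are rounded
half-up to one decimal (base `round()` rounds half to even, which would
print some published-style ratios differently). The site-level
denominator counts assigned sites in motif-containing proteins only, and
"O-GlcNAcylated" is a database-membership flag that can be true for
proteins without positionally assigned sites — the two denominators
(proteins in the database vs. proteins with assigned sites) are tracked
separately.

Set enrichment is the exact hypergeometric upper tail per term with BH
correction across terms and significance at `q < 0.05`. Term databases
are plain named lists; no live database access is attempted.

## The synthetic generator

The generator's defaults describe the benchmark conditions:

* proteins of 250–600 residues, uniform residue composition, block-wise
  disorder (blocks of 25–60 residues, disordered with probability 0.5,
  scores fixed at 0.8/0.1 since only the 0.4 threshold is consumed
  downstream);
* the planted motif `PxYx[IL]` in 30% of proteins, placed inside a
  disordered block, wildcards drawn from the 19 non-proline residues so
  planted instances survive the proline filter;
* 16-mer tiles at step 8 over maximal disordered stretches, with a final
  right-aligned tile (the tiling step of real disorderome libraries is
  not published; 8 — half-overlapping — is the free-parameter default);
* O-GlcNAc sites on S/T with per-site probability 0.171 of lying within
  100 residues of the motif (the observed proximity rate this class of
  screen reports), overridable separately for motif-phosphorylated
  carriers (`oglcnac_near_motif_fraction_motif_ptyr`, e.g. 0.33) to plant
  the proximal enrichment of that subset; the default inherits the global
  fraction so parameter-recovery checks have a single ground truth;
* 30% of carriers phosphorylated on the motif tyrosine, plus Poisson(1)
  background pTyr sites on existing tyrosines;
* selection reads sampled with weight 1 for background peptides and
  `enrichment_factor` for motif-bearing ones, at `background_depth` reads
  per replicate; reverse translation uses a fixed common-codon table so
  identical peptides always yield identical inserts.

Identical spec and seed give byte-identical FASTA/FASTQ/TSV outputs.

What the generator does **not** emulate: avidity and amplification bias,
sequencing errors (an error-free read model; failures are exercised by
corrupting reads in tests), realistic disorder predictors, non-uniform
residue composition, and real PTM site densities. Passing the synthetic
benchmark therefore demonstrates correctness of the computational chain
and statistical calibration under a known null — not performance on real
screens, where background composition, overlapping-tile correlation and
database incompleteness dominate.

## Surface areas and interface burial

SASA uses the Shrake–Rupley algorithm: each atom's sphere of radius
`r + 1.4 Å` is sampled at 960 quasi-uniform points (a fixed golden-spiral
lattice, so results are deterministic and rotation sensitivity is below
0.5%), and the exposed fraction scales the sphere area. Radii are a
standard van der Waals table (C 1.70, N 1.55, O 1.52, S 1.80, P 1.80 Å);
hydrogens, waters and hetero ligands are excluded by default, since the
interface of interest is protein–peptide. A point lying exactly on
another atom's expanded sphere is claimed by the lower-indexed atom; this
tie-break makes exactly coincident duplicates contribute one sphere's
area in total instead of double-counting. Buried surface area for a
declared binary chain partition is
`BSA = SASA(A) + SASA(B) − SASA(AB)`, computed per asymmetric-unit
complex with explicit chain selection (crystals of peptide complexes
often carry several copies per asymmetric unit, and guessing the pairing
is not this module's job). The implementation is validated against the
isolated-sphere closed form, a Monte-Carlo point-sampling oracle (2%
agreement on contacting clusters), the additivity bound
`SASA(AB) ≤ SASA(A) + SASA(B)`, and < 1% drift between 240 and 960
sample points. Against a deposited OGT–peptide co-crystal with ligand and
waters excluded, the expected interface burial is in the ~1,250 Å² range
typical of transient peptide interactions; the coordinate file itself is
not bundled with the package and is fetched on demand where network
access exists.

## Problem sizes and numerical choices

The test suite and the acceptance script use deliberately small study
sizes chosen to give stable statistics: 60-protein proteomes with 3
replicates of 3,000 reads for the 20-seed motif-recovery benchmark
(50-fold enrichment, discovery on the top 40 selected peptides), and a
700-protein, ~2,800-site proteome for recovering the planted near-motif
fraction within three binomial standard errors. Quantile type is R's
default (type 7); the high-count threshold is therefore continuous in
the totals. Empty inputs follow a simple rule: impossible configurations
(empty peptide set, no motif match for a PFM, zero-radius atoms) are
errors; legitimate-but-empty results (no disordered stretch long enough
to tile, a term absent from the universe) are empty outputs with
warnings.

## Known limitations

* Discovery enumerates ungapped motifs only, with at most one
  two-residue position; gapped or highly degenerate motifs are out of
  scope.
* The binomial significance model ignores peptide non-independence from
  overlapping tiling (see above); it calibrates the ranking, not a
  genome-wide error rate.
* The scanner's topology model is interval-based; it does not predict
  signal peptides or membrane topology.
* SASA is atoms-in, areas-out: no hydrogen placement, symmetry expansion
  or electron-density handling.
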