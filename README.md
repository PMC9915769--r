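# proppd

Analysis pipeline for proteomic peptide phage display (ProP-PD) selections
and the short linear motifs (SLiMs) they discover.

ProP-PD libraries display overlapping 16-mer peptides tiled across the
intrinsically disordered regions of a proteome on filamentous phage. After
affinity selection against a bait protein (the motivating application is
O-GlcNAc transferase and the `PxYx[I/L]` motif recognised by its
intervening domain), the enriched phage pools are deep-sequenced. Turning
those reads into a binding motif and into proteome-wide biology requires a
chain of computational steps, all of which this package implements:

1. **`synthetic_data`** — a seeded generator for every input: an annotated
   toy proteome (disorder scores, O-GlcNAc and phosphotyrosine site tables,
   topology flags), a tiled peptide library, and selection FASTQ reads with
   a planted, enrichment-weighted motif. Every downstream stage is testable
   against known ground truth without downloads.
2. **`phage_seq`** — demultiplexing by barcode, adapter trimming,
   standard-code translation of the 48-nt insert, and tallying against the
   library into per-replicate peptide count tables with full read
   accounting (every read ends in exactly one outcome class).
3. **`peptide_confidence`** — four boolean criteria per peptide
   (replicated, overlapping peptides from the same protein, high counts,
   consensus-motif match); peptides meeting at least three form the
   medium/high-confidence selection.
4. **`motif_discovery`** — seed-and-degenerate enumeration of candidate
   motifs (wildcards at interior positions, two-residue sets such as
   `[IL]`), scored by a per-peptide binomial overrepresentation statistic
   with Benjamini–Hochberg correction, plus position frequency matrices for
   logo rendering.
5. **`proteome_scan`** — motif instances in a proteome under the
   biological filters: intrinsic disorder > 0.4 at every motif residue, no
   proline at the wildcard positions, exclusion of secreted proteins and
   extracellular domains.
6. **`ptm_crosstalk`** — distance statistics between O-GlcNAc sites and
   motif instances (gap convention: residues strictly between site and
   span), overlap sets among motif / O-GlcNAcylated / pTyr /
   motif-phosphorylated proteins, and generic hypergeometric set
   enrichment with FDR control.
7. **`interface_bsa`** — Shrake–Rupley solvent-accessible surface area and
   interface buried surface area, `BSA = SASA(A) + SASA(B) − SASA(AB)`,
   from PDB/mmCIF files.

## The statistics at the core

For a degenerate motif `m` of length `L` with allowed residue sets `S_j` at
its fixed positions, under a residue background `f`:

```
p_site = Π_j Σ_{a ∈ S_j} f(a)            probability a random window matches
p_bg   = 1 − (1 − p_site)^(W − L + 1)    probability a W-mer contains ≥ 1 match
p      = P(X ≥ k), X ~ Binomial(N, p_bg) exact upper tail for k of N peptides
```

Candidates are ranked by `p` (ties: more fixed positions, then pattern
string) and corrected across candidates by Benjamini–Hochberg. Set
enrichment uses the exact hypergeometric upper tail; SASA uses the
Shrake–Rupley sphere-sampling algorithm on a fixed golden-spiral point set
with standard van der Waals radii (C 1.70, N 1.55, O 1.52, S 1.80 Å) and a
1.4 Å probe.

## Worked example

A complete selection screen in a few lines (simulate → process reads →
confidence calls → motif discovery → proteome scan → crosstalk):

```r
library(proppd)

spec     <- synth_proteome_spec(n_proteins = 60, seed = 11)
proteome <- generate_proteome(spec)
tiles    <- generate_library(proteome)
design   <- selection_design(
  samples = tibble::tibble(barcode = "ACGTAC", bait = "OGT"),
  replicates_per_bait = 3, enrichment_factor = 50,
  background_depth = 3000, seed = 12)
reads  <- generate_reads(tiles, design, outdir = tempfile())
counts <- process_reads(reads$manifest, design, tiles)
counts
#> <proppd_counts> 2866 peptide x replicate cells, 9000 reads processed (9000 mapped)

calls  <- call_confidence(counts)
sel    <- selected_peptides(calls, "OGT")
motifs <- discover_motifs(head(sel$peptide, 40), L_range = 4:6)
head(motifs, 3)
#>   pattern  length n_fixed     k     N    p_bg        p        q
#> 1 PxYx[IL]      5       3    31    40 0.00300 1.58e-70 4.41e-67
#> 2 PxYxL         5       3    17    40 0.00150 8.36e-38 1.17e-34
#> 3 [EP]xYxL      5       3    18    40 0.00300 4.03e-35 2.81e-32

hits <- scan_proteome(proteome, motifs$pattern[1])
summarize_crosstalk(proteome, hits)
#> <crosstalk_summary> window = 100 residues
#>   motif-containing proteins:       22
#>   with O-GlcNAcylation:            18 (81.8%)
#>   assigned O-GlcNAc sites:         90 in 18 proteins
#>   sites within window:             15 (16.7%)
#>   with any pTyr site:              13 (59.1%)
#>   pTyr on the motif tyrosine:      6 (46.2%)
#>   of those, with O-GlcNAcylation:  5 (83.3%)
#>   motif-pTyr subset sites within:  2/24 (8.3%)
```

The generator planted `PxYx[IL]` in 30% of proteins at 50-fold enrichment;
discovery recovers it as the top-ranked motif (31 of the 40 most-enriched
selected peptides carry it), and the crosstalk summary reports each overlap
both as a count and as a percentage of its denominator.

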