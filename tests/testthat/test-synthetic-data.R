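test_that("proteome generation is byte-deterministic under a fixed seed", {
  spec <- synth_proteome_spec(n_proteins = 10, seed = 7)
  d1 <- file.path(tempdir(), "synth_run1")
  d2 <- file.path(tempdir(), "synth_run2")
  p1 <- write_proteome(generate_proteome(spec), d1)
  p2 <- write_proteome(generate_proteome(spec), d2)
  fa <- readLines(p1["fasta"])
  expect_length(grep("^>", fa), 10)
  for (f in names(p1)) {
    expect_identical(readLines(p1[f]), readLines(p2[f]))
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("spec validation rejects impossible geometry and bad fractions", {
  expect_error(synth_proteome_spec(motif_carrier_fraction = 1.2), "fractions")
  expect_error(synth_proteome_spec(length_range = c(10, 50)))
  expect_error(
    synth_proteome_spec(length_range = c(30, 40), planted_motif = "AxxAxxxA",
                        n_proteins = 5),
    NA)  # an 8-mer fits a 30-residue protein
})

test_that("every protein carries the planted motif at carrier fraction 1", {
  spec <- synth_proteome_spec(n_proteins = 25, motif_carrier_fraction = 1,
                              seed = 3)
  proteome <- generate_proteome(spec)
  m <- parse_motif(spec$planted_motif)
  hits <- scan_proteome(proteome, m)
  expect_setequal(motif_proteins(hits), names(proteome))
  # planted instances sit in disordered regions and avoid wildcard prolines
  planted <- vapply(proteome, `[[`, integer(1), "motif_start")
  expect_true(all(!is.na(planted)))
})

test_that("PTM site tables are in-bounds and residue-consistent", {
  spec <- synth_proteome_spec(n_proteins = 40, seed = 5)
  proteome <- generate_proteome(spec)
  for (p in proteome) {
    len <- nchar(p$seq)
    expect_true(all(p$oglcnac_sites >= 1 & p$oglcnac_sites <= len))
    expect_true(all(p$ptyr_sites >= 1 & p$ptyr_sites <= len))
    if (length(p$oglcnac_sites) > 0) {
      res <- substring(p$seq, p$oglcnac_sites, p$oglcnac_sites)
      expect_true(all(res %in% c("S", "T")))
    }
    if (length(p$ptyr_sites) > 0) {
      res <- substring(p$seq, p$ptyr_sites, p$ptyr_sites)
      expect_true(all(res == "Y"))
    }
  }
})

test_that("near-motif O-GlcNAc fraction is recovered within 3 standard errors", {
  f <- 0.171
  spec <- synth_proteome_spec(n_proteins = 150, motif_carrier_fraction = 1,
                              oglcnac_near_motif_fraction = f,
                              oglcnac_sites_per_protein = 4, seed = 21)
  proteome <- generate_proteome(spec)
  m <- parse_motif(spec$planted_motif)
  dists <- unlist(lapply(proteome, function(p) {
    span <- tibble::tibble(start = p$motif_start,
                           end = p$motif_start + motif_length(m) - 1L)
    site_motif_distance(p$oglcnac_sites, span)
  }))
  n <- length(dists)
  expect_gt(n, 400)
  se <- sqrt(f * (1 - f) / n)
  expect_lt(abs(mean(dists <= spec$proximity_window) - f), 3 * se)
})

test_that("proteome files round-trip through the TSV/FASTA readers", {
  spec <- synth_proteome_spec(n_proteins = 8, seed = 13)
  proteome <- generate_proteome(spec)
  d <- file.path(tempdir(), "synth_roundtrip")
  paths <- write_proteome(proteome, d)
  back <- read_proteome(paths["fasta"], paths["disorder"], paths["ptm"],
                        paths["topology"])
  expect_identical(names(back), names(proteome))
  for (id in names(proteome)) {
    expect_identical(back[[id]]$seq, proteome[[id]]$seq)
    expect_equal(back[[id]]$disorder, proteome[[id]]$disorder)
    expect_identical(back[[id]]$oglcnac_sites, proteome[[id]]$oglcnac_sites)
    expect_identical(back[[id]]$ptyr_sites, proteome[[id]]$ptyr_sites)
  }
  unlink(d, recursive = TRUE)
})

test_that("disordered blocks are tiled with a right-aligned final window", {
  # single 31-residue disordered block, step 8 -> tiles at 1, 9, 16
  p <- make_protein("T1", random_peptide(40),
                    disorder = c(rep(0.8, 31), rep(0.1, 9)))
  lib <- generate_library(make_proteome(p), tile_length = 16, step = 8)
  expect_identical(lib$start, c(1L, 9L, 16L))
  expect_identical(nchar(lib$peptide), rep(16L, 3))
  expect_identical(lib$peptide[3], substr(p$seq, 16, 31))

  # block of exactly tile length, step 16 -> one tile
  p2 <- make_protein("T2", random_peptide(30),
                     disorder = c(rep(0.8, 16), rep(0.1, 14)))
  lib2 <- generate_library(make_proteome(p2), tile_length = 16, step = 16)
  expect_identical(lib2$start, 1L)

  # fully ordered protein -> empty library with a warning
  p3 <- make_protein("T3", random_peptide(60), disorder = rep(0.1, 60))
  expect_warning(lib3 <- generate_library(make_proteome(p3)), "empty")
  expect_identical(nrow(lib3), 0L)
})

test_that("read generation writes the declared number of records per replicate", {
  lib <- tibble::tibble(peptide = replicate(30, random_peptide(16)),
                        protein_id = "P1", start = 1L)
  des <- selection_design(
    samples = tibble::tibble(barcode = "ACGTAC", bait = "OGT"),
    replicates_per_bait = 2, background_depth = 1000, seed = 4)
  out <- generate_reads(lib, des, outdir = file.path(tempdir(), "fq1"))
  expect_identical(nrow(out$manifest), 2L)
  for (f in out$manifest$file) {
    lines <- readLines(f)
    expect_identical(length(lines), 4000L)
    expect_true(all(startsWith(lines[seq(2, 4000, 4)], "ACGTAC")))
  }
  expect_identical(as.vector(tapply(out$truth$count, out$truth$replicate, sum)),
                   c(1000L, 1000L))
  unlink(file.path(tempdir(), "fq1"), recursive = TRUE)
})

test_that("motif-read enrichment follows the weighted-sampling closed form", {
  set.seed(42)
  # 10% motif-bearing library
  bg <- replicate(90, random_peptide(16))
  bg <- bg[!motif_matches_any(bg, parse_motif("PxYx[IL]"))]
  motif_peps <- vapply(seq_len(10), function(i) {
    paste0(random_peptide(5), "PAYAI", random_peptide(6))
  }, character(1))
  lib <- tibble::tibble(peptide = c(bg, motif_peps), protein_id = "P1",
                        start = 1L)
  frac_lib <- length(motif_peps) / nrow(lib)
  depth <- 5000

  for (ef in c(1, 50)) {
    des <- selection_design(
      samples = tibble::tibble(barcode = "ACGTAC", bait = "OGT"),
      replicates_per_bait = 1, enrichment_factor = ef,
      background_depth = depth, seed = 99)
    out <- generate_reads(lib, des, outdir = file.path(tempdir(), "fq2"))
    expected <- ef * frac_lib / (ef * frac_lib + (1 - frac_lib))
    is_m <- motif_matches_any(out$truth$peptide, parse_motif("PxYx[IL]"))
    observed <- sum(out$truth$count[is_m]) / depth
    se <- sqrt(expected * (1 - expected) / depth)
    expect_lt(abs(observed - expected), 3 * se)
  }
  unlink(file.path(tempdir(), "fq2"), recursive = TRUE)
})

test_that("reverse translation uses the fixed codon table deterministically", {
  expect_identical(reverse_translate("PVYQI"), "CCCGTGTACCAGATC")
  expect_identical(reverse_translate(c("AA", "AA")), c("GCCGCC", "GCCGCC"))
  expect_error(reverse_translate("AB*"), "standard alphabet")
})
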