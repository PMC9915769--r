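test_that("demultiplexing matches barcode prefixes exactly by default", {
  barcodes <- c(ACGT = "s1", TTTT = "s2")
  expect_identical(demultiplex("ACGTAAAA", barcodes), "s1")
  expect_identical(demultiplex("ACGAAAAA", barcodes), NA_character_)
  expect_identical(demultiplex(c("TTTTGG", "GGGGGG"), barcodes),
                   c("s2", NA))
  expect_error(demultiplex("ACGT", c(ACGT = "s1", ACGT = "s2")), "unique")
  expect_error(demultiplex("ACGT", c(ACGT = "s1", TT = "s2")), "equal length")
})

test_that("tolerant demultiplexing agrees with a Hamming-distance oracle", {
  barcodes <- c(ACGT = "s1", TTTT = "s2")
  expect_identical(demultiplex("ACGAGGGG", barcodes, mismatch_tolerance = 1),
                   "s1")
  expect_identical(demultiplex("ATTAGGGG", barcodes, mismatch_tolerance = 1),
                   NA_character_)  # distance 2 from both
  set.seed(101)
  reads <- vapply(seq_len(300), function(i) {
    paste(sample(c("A", "C", "G", "T"), 10, replace = TRUE), collapse = "")
  }, character(1))
  got <- demultiplex(reads, barcodes, mismatch_tolerance = 1)
  want <- vapply(reads, function(r) {
    d <- vapply(names(barcodes), function(b) hamming(substr(r, 1, 4), b),
                numeric(1))
    hit <- which(d <= 1)
    if (length(hit) == 1) unname(barcodes[hit]) else NA_character_
  }, character(1), USE.NAMES = FALSE)
  expect_identical(got, want)
})

test_that("trimming and translation enforce the fixed read architecture", {
  a5 <- "GGTGGAGGTTCG"
  a3 <- "TCCGGATGGTGG"
  bc <- "ACGTAC"
  insert <- paste0("CCTGTTTATCAAATT", strrep("GCA", 11))  # PVYQI + 11x Ala
  read <- paste0(bc, a5, insert, a3)
  out <- trim_and_translate(read, nchar(bc), a5, a3, 48)
  expect_identical(out$status, "ok")
  expect_identical(substr(out$peptide, 1, 5), "PVYQI")
  expect_identical(out$peptide, paste0("PVYQI", strrep("A", 11)))

  stop_read <- paste0(bc, a5, paste0("TAA", strrep("GCA", 15)), a3)
  expect_identical(trim_and_translate(stop_read, 6, a5, a3, 48)$status,
                   "stop_codon")

  short_insert <- paste0(bc, a5, substr(insert, 1, 47), a3)
  expect_identical(trim_and_translate(short_insert, 6, a5, a3, 48)$status,
                   "length_error")

  bad_adapter <- paste0(bc, "AAAAAAAAAAAA", insert, a3)
  expect_identical(trim_and_translate(bad_adapter, 6, a5, a3, 48)$status,
                   "adapter_mismatch")
})

test_that("translation agrees with an independent codon-table oracle", {
  skip_if_not_installed("seqinr")
  set.seed(7)
  a5 <- "GG"
  a3 <- "CC"
  for (i in 1:25) {
    insert <- paste(sample(c("A", "C", "G", "T"), 48, replace = TRUE),
                    collapse = "")
    read <- paste0("AAAA", a5, insert, a3)
    out <- trim_and_translate(read, 4, a5, a3, 48)
    oracle <- paste(seqinr::translate(strsplit(insert, "")[[1]]),
                    collapse = "")
    if (grepl("\\*", oracle)) {
      expect_identical(out$status, "stop_codon")
    } else {
      expect_identical(out$peptide, oracle)
    }
  }
})

test_that("every read is conserved across outcome classes", {
  set.seed(11)
  lib <- tibble::tibble(peptide = replicate(20, random_peptide(16)),
                        protein_id = "P1", start = 1L)
  des <- selection_design(
    samples = tibble::tibble(barcode = "ACGTAC", bait = "OGT"),
    replicates_per_bait = 1, background_depth = 300, seed = 8)
  out <- generate_reads(lib, des, outdir = file.path(tempdir(), "fqc"))
  # corrupt the file with every failure class
  f <- out$manifest$file[1]
  lines <- readLines(f)
  corrupt <- c("@bad_barcode", paste0("TTTTTT", strrep("A", 78)), "+",
               strrep("I", 84),
               "@bad_adapter", paste0("ACGTAC", strrep("T", 78)), "+",
               strrep("I", 84),
               "@too_short", "ACGTACGG", "+", "IIIIIIII",
               "@stop", paste0("ACGTAC", des$adapter_5p, "TAA",
                               strrep("GCA", 15), des$adapter_3p), "+",
               strrep("I", 78),
               "@unmapped", paste0("ACGTAC", des$adapter_5p,
                                   strrep("GCA", 16), des$adapter_3p), "+",
               strrep("I", 78))
  writeLines(c(lines, corrupt), f)
  pc <- process_reads(out$manifest, des, lib)
  log <- pc$log
  expect_identical(log$total, 305L)
  expect_identical(log$ok + log$barcode_mismatch + log$adapter_mismatch +
                     log$length_error + log$stop_codon + log$unmapped,
                   log$total)
  expect_identical(log$barcode_mismatch, 1L)
  expect_identical(log$adapter_mismatch, 1L)
  expect_identical(log$length_error, 1L)
  expect_identical(log$stop_codon, 1L)
  expect_identical(log$unmapped, 1L)
  # column-sum conservation: counts per replicate equal mapped reads
  expect_identical(sum(pc$counts$count), log$ok)
  unlink(file.path(tempdir(), "fqc"), recursive = TRUE)
})

test_that("counting aggregates per replicate and drops unmapped peptides", {
  lib <- tibble::tibble(peptide = c("AAAAAAAAAAAAAAAA", "CCCCCCCCCCCCCCCC"),
                        protein_id = c("P1", "P2"), start = c(1L, 1L))
  assignments <- tibble::tibble(
    bait = "OGT", replicate = 1L,
    peptide = c(rep("AAAAAAAAAAAAAAAA", 3), "GGGGGGGGGGGGGGGG"),
    status = "ok")
  out <- count_peptides(assignments, lib)
  expect_identical(nrow(out$counts), 1L)
  expect_identical(out$counts$count, 3L)
  expect_identical(out$counts$protein_id, "P1")
  expect_identical(sum(out$assignments$status == "unmapped"), 1L)
})

test_that("processing synthetic reads recovers the sampled multiset exactly", {
  spec <- synth_proteome_spec(n_proteins = 15, seed = 31)
  proteome <- generate_proteome(spec)
  lib <- generate_library(proteome)
  des <- selection_design(replicates_per_bait = 2, enrichment_factor = 5,
                          background_depth = 800, seed = 32)
  out <- generate_reads(lib, des, outdir = file.path(tempdir(), "fqr"))
  pc <- process_reads(out$manifest, des, lib)
  got <- dplyr::arrange(
    pc$counts[, c("bait", "replicate", "peptide", "count")],
    bait, replicate, peptide)
  want <- dplyr::arrange(out$truth, bait, replicate, peptide)
  expect_identical(as.data.frame(got), as.data.frame(want))
  unlink(file.path(tempdir(), "fqr"), recursive = TRUE)
})
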