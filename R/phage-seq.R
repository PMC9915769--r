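#' Assign a read to a sample by its barcode prefix
#'
#' Exact prefix matching by default; with `mismatch_tolerance = 1` a read is
#' assigned to the unique barcode within Hamming distance 1 (reads within
#' distance 1 of two barcodes, which cannot happen if all barcodes are at
#' pairwise distance >= 3, would be ambiguous and are rejected).
#'
#' @param reads Character vector of DNA reads.
#' @param barcodes Named character vector `barcode -> sample label`, all of
#'   equal length and unique.
#' @param mismatch_tolerance 0 (default) or 1.
#' @return Character vector of sample labels, `NA` for `barcode_mismatch`.
#' @export
demultiplex <- function(reads, barcodes, mismatch_tolerance = 0) {
  if (anyDuplicated(names(barcodes)) || is.null(names(barcodes))) {
    stop("barcodes must be a uniquely named vector (barcode -> sample)",
         call. = FALSE)
  }
  bl <- unique(nchar(names(barcodes)))
  if (length(bl) != 1) stop("barcodes must have equal length", call. = FALSE)
  prefix <- substr(reads, 1, bl)
  label <- unname(barcodes[prefix])
  if (mismatch_tolerance >= 1) {
    todo <- which(is.na(label) & nchar(reads) >= bl)
    if (length(todo) > 0) {
      bc_mat <- do.call(rbind, strsplit(names(barcodes), ""))
      for (i in todo) {
        p <- strsplit(prefix[i], "")[[1]]
        d <- rowSums(bc_mat != matrix(p, nrow(bc_mat), bl, byrow = TRUE))
        hit <- which(d <= mismatch_tolerance)
        if (length(hit) == 1) label[i] <- unname(barcodes[hit])
      }
    }
  }
  label
}

#' Trim a demultiplexed read and translate its insert
#'
#' The read architecture is fixed: `barcode | adapter_5p | insert |
#' adapter_3p`. Both adapters must match exactly at their expected offsets,
#' the insert must have exactly `insert_length_nt` nucleotides, and the
#' insert is translated in frame 1 with the standard genetic code. Any stop
#' codon fails the read.
#'
#' @param reads Character vector of DNA reads (barcode still attached).
#' @param barcode_length Length of the (already identified) barcode prefix.
#' @param adapter_5p,adapter_3p Fixed adapter sequences.
#' @param insert_length_nt Expected insert length (multiple of 3).
#' @return Tibble with columns `insert`, `peptide` and `status`
#'   (`"ok"`, `"adapter_mismatch"`, `"length_error"`, `"stop_codon"`).
#' @export
trim_and_translate <- function(reads, barcode_length, adapter_5p, adapter_3p,
                               insert_length_nt) {
  stopifnot(insert_length_nt %% 3 == 0)
  a5 <- nchar(adapter_5p)
  a3 <- nchar(adapter_3p)
  expected <- barcode_length + a5 + insert_length_nt + a3
  n <- length(reads)
  status <- rep("ok", n)
  insert <- rep(NA_character_, n)
  peptide <- rep(NA_character_, n)

  too_short <- nchar(reads) < expected
  status[too_short] <- "length_error"
  ok <- !too_short
  if (any(ok)) {
    got5 <- substr(reads[ok], barcode_length + 1, barcode_length + a5)
    got3 <- substr(reads[ok], barcode_length + a5 + insert_length_nt + 1,
                   expected)
    bad_ad <- got5 != adapter_5p | got3 != adapter_3p
    status[ok][bad_ad] <- "adapter_mismatch"
    keep <- which(ok)[!bad_ad]
    if (length(keep) > 0) {
      ins <- substr(reads[keep], barcode_length + a5 + 1,
                    barcode_length + a5 + insert_length_nt)
      insert[keep] <- ins
      aa <- as.character(Biostrings::translate(
        Biostrings::DNAStringSet(ins),
        genetic.code = Biostrings::GENETIC_CODE, no.init.codon = TRUE))
      has_stop <- grepl("\\*", aa)
      status[keep][has_stop] <- "stop_codon"
      peptide[keep][!has_stop] <- aa[!has_stop]
    }
  }
  tibble::tibble(insert = insert, peptide = peptide, status = status)
}

#' Process selection FASTQ files into a peptide count table
#'
#' Runs the full read-processing chain per replicate file: demultiplex by
#' barcode, trim the fixed adapters, translate the insert, and tally
#' peptides against the display library. Every read receives exactly one
#' outcome (`ok` or one of the failure classes), and per-replicate failure
#' counts are logged so that reads are conserved.
#'
#' @param manifest Tibble with columns `file`, `bait`, `replicate` (as
#'   returned by [generate_reads()], or built by hand for real runs).
#' @param design A [selection_design()] carrying barcodes, adapters and
#'   insert length.
#' @param library Library tibble (`peptide`, `protein_id`, `start`).
#' @param mismatch_tolerance Barcode mismatch tolerance (see
#'   [demultiplex()]).
#' @return A `proppd_counts` list: `counts` (tibble: peptide, protein_id,
#'   start, bait, replicate, count), `log` (tibble of per-replicate outcome
#'   counts: ok, barcode_mismatch, adapter_mismatch, length_error,
#'   stop_codon, unmapped, total).
#' @export
process_reads <- function(manifest, design, library, mismatch_tolerance = 0) {
  stopifnot(all(c("file", "bait", "replicate") %in% names(manifest)))
  barcodes <- setNames(design$samples$bait, design$samples$barcode)
  bl <- nchar(design$samples$barcode[1])

  assignments <- list()
  logs <- list()
  for (i in seq_len(nrow(manifest))) {
    reads <- read_fastq_sequences(manifest$file[i])
    sample_label <- demultiplex(reads, barcodes, mismatch_tolerance)
    status <- ifelse(is.na(sample_label), "barcode_mismatch", "pending")
    peptide <- rep(NA_character_, length(reads))
    todo <- !is.na(sample_label)
    tr <- trim_and_translate(reads[todo], bl, design$adapter_5p,
                             design$adapter_3p, design$insert_length_nt)
    status[todo] <- tr$status
    peptide[todo] <- tr$peptide
    assignments[[i]] <- tibble::tibble(
      bait = sample_label, replicate = manifest$replicate[i],
      peptide = peptide, status = status,
      file = manifest$file[i], total = length(reads))
  }
  assignments <- dplyr::bind_rows(assignments)
  tallied <- count_peptides(assignments, library)

  cls <- c("ok", "barcode_mismatch", "adapter_mismatch", "length_error",
           "stop_codon", "unmapped")
  logs <- dplyr::group_modify(
    dplyr::group_by(tallied$assignments, .data$file, .data$replicate),
    function(df, key) {
      st <- table(factor(df$status, levels = cls))
      tibble::tibble(bait = df$bait[!is.na(df$bait)][1],
                     !!!as.list(setNames(as.integer(st), cls)),
                     total = nrow(df))
    })
  structure(list(counts = tallied$counts, log = dplyr::ungroup(logs)),
            class = "proppd_counts")
}

#' Tally translated peptides against the display library
#'
#' Aggregates successfully translated read assignments into per
#' (bait, replicate) peptide counts. Peptides absent from the library are
#' reclassified `unmapped` and tallied in the margins only; no count row is
#' created for them. Rare peptide-sequence collisions in the library (one
#' 16-mer arising from two loci) keep the first record and note the
#' multiplicity in `n_source_records`.
#'
#' @param assignments Tibble with columns `bait`, `replicate`, `peptide`,
#'   `status` (one row per read; `status == "ok"` rows are counted).
#' @param library Library tibble (`peptide`, `protein_id`, `start`).
#' @return List with `counts` (tibble: peptide, protein_id, start, bait,
#'   replicate, count, n_source_records) and `assignments` (input with
#'   unmapped reads reclassified).
#' @export
count_peptides <- function(assignments, library) {
  lib <- dplyr::summarise(
    dplyr::group_by(library, .data$peptide),
    protein_id = .data$protein_id[1], start = .data$start[1],
    n_source_records = dplyr::n(), .groups = "drop")
  mapped <- assignments$status == "ok" & assignments$peptide %in% lib$peptide
  assignments$status[assignments$status == "ok" & !mapped] <- "unmapped"

  counted <- dplyr::summarise(
    dplyr::group_by(assignments[mapped, , drop = FALSE],
                    .data$bait, .data$replicate, .data$peptide),
    count = dplyr::n(), .groups = "drop")
  counts <- if (nrow(counted) > 0) {
    dplyr::left_join(counted, lib, by = "peptide")
  } else {
    tibble::tibble(bait = character(0), replicate = integer(0),
                   peptide = character(0), count = integer(0),
                   protein_id = character(0), start = integer(0),
                   n_source_records = integer(0))
  }
  counts$count <- as.integer(counts$count)
  counts <- counts[, c("peptide", "protein_id", "start", "bait", "replicate",
                       "count", "n_source_records")]
  list(counts = counts, assignments = assignments)
}

read_fastq_sequences <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  as.character(unname(x))
}

#' @export
print.proppd_counts <- function(x, ...) {
  cat("<proppd_counts> ", nrow(x$counts), " peptide x replicate cells, ",
      sum(x$log$total), " reads processed (", sum(x$log$ok), " mapped)\n",
      sep = "")
  invisible(x)
}

#' Aggregate per-peptide totals from a count table
#'
#' @param counts A `proppd_counts` or its `counts` tibble.
#' @param by_bait Aggregate within bait (default) or across all samples.
#' @return Tibble of totals per peptide (and bait).
#' @export
peptide_totals <- function(counts, by_bait = TRUE) {
  tab <- if (inherits(counts, "proppd_counts")) counts$counts else counts
  groups <- if (by_bait) c("peptide", "protein_id", "start", "bait")
            else c("peptide", "protein_id", "start")
  dplyr::summarise(dplyr::group_by(tab, dplyr::across(dplyr::all_of(groups))),
                   total = sum(.data$count),
                   n_replicates = dplyr::n_distinct(
                     .data$replicate[.data$count > 0]), .groups = "drop")
}
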