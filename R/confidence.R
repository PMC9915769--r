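#' Four-criteria confidence calling for enriched peptides
#'
#' Each peptide observed for a bait is scored on four boolean criteria:
#'
#' * `replicated` — nonzero count in at least two replicate selections of
#'   the same bait;
#' * `overlapping` — another observed peptide from the same source protein
#'   overlaps it by at least `min_overlap` residues (source-coordinate
#'   overlap; for a half-overlapping 16-mer tiling this is the natural
#'   adjacent-tile overlap of 8);
#' * `high_count` — the peptide's total count for the bait reaches the
#'   `count_quantile` quantile of all nonzero peptide totals for that bait;
#' * `motif_match` — the peptide matches the supplied consensus motif
#'   (always `FALSE` when no consensus is supplied, e.g. on a first pass
#'   before motif discovery).
#'
#' The tier is `high` when all four criteria hold, `medium` for exactly
#' three, `low` otherwise; the stringent selection used downstream keeps
#' peptides meeting at least three criteria (`selected`). Peptides observed
#' for more than one bait carry `shared_across_baits = TRUE`.
#'
#' @param counts A `proppd_counts` or its `counts` tibble.
#' @param consensus A `degenerate_motif`, pattern string, or `NULL`.
#' @param count_quantile Quantile of nonzero totals defining "high counts"
#'   (default 0.75).
#' @param min_overlap Minimum residue overlap for the overlapping-peptide
#'   criterion (default 8).
#' @param peptide_length Peptide length used for overlap intervals
#'   (default 16).
#' @return Tibble with one row per (bait, peptide): the four criteria,
#'   `n_met`, `tier` (factor high/medium/low), `selected`,
#'   `shared_across_baits`, plus `total` and `n_replicates`.
#' @export
call_confidence <- function(counts, consensus = NULL, count_quantile = 0.75,
                            min_overlap = 8L, peptide_length = 16L) {
  tab <- if (inherits(counts, "proppd_counts")) counts$counts else counts
  if (nrow(tab) == 0) stop("empty count table", call. = FALSE)
  if (is.character(consensus)) consensus <- parse_motif(consensus)

  totals <- peptide_totals(tab, by_bait = TRUE)
  observed_baits <- dplyr::summarise(
    dplyr::group_by(totals, .data$peptide),
    n_baits = dplyr::n_distinct(.data$bait), .groups = "drop")

  calls <- dplyr::group_modify(dplyr::group_by(totals, .data$bait),
                               function(df, key) {
    threshold <- quantile(df$total[df$total > 0], count_quantile, names = FALSE)
    df$replicated <- df$n_replicates >= 2
    df$overlapping <- overlapping_flags(df, min_overlap, peptide_length)
    df$high_count <- df$total >= threshold
    df$motif_match <- if (is.null(consensus)) {
      rep(FALSE, nrow(df))
    } else {
      motif_matches_any(df$peptide, consensus)
    }
    df
  })
  calls <- dplyr::ungroup(calls)
  calls$n_met <- as.integer(rowSums(
    calls[, c("replicated", "overlapping", "high_count", "motif_match")]))
  calls$tier <- factor(
    ifelse(calls$n_met == 4, "high", ifelse(calls$n_met == 3, "medium", "low")),
    levels = c("high", "medium", "low"))
  calls$selected <- calls$n_met >= 3
  calls <- dplyr::left_join(calls, observed_baits, by = "peptide")
  calls$shared_across_baits <- calls$n_baits >= 2
  calls$n_baits <- NULL
  calls[, c("bait", "peptide", "protein_id", "start", "total", "n_replicates",
            "replicated", "overlapping", "high_count", "motif_match",
            "n_met", "tier", "selected", "shared_across_baits")]
}

# TRUE for peptides with another observed peptide from the same protein whose
# source interval overlaps by >= min_overlap residues.
overlapping_flags <- function(df, min_overlap, peptide_length) {
  flag <- rep(FALSE, nrow(df))
  for (pid in unique(df$protein_id)) {
    idx <- which(df$protein_id == pid & !is.na(df$start))
    if (length(idx) < 2) next
    s <- df$start[idx]
    e <- s + peptide_length - 1L
    for (a in seq_along(idx)) {
      ov <- pmin(e[a], e[-a]) - pmax(s[a], s[-a]) + 1L
      if (any(ov >= min_overlap)) flag[idx[a]] <- TRUE
    }
  }
  flag
}

#' Peptides selected at medium/high confidence
#'
#' Convenience accessor for the stringent (>= 3 criteria) peptide set of one
#' bait, ranked by total count.
#'
#' @param calls Output of [call_confidence()].
#' @param bait Bait label; `NULL` pools all baits (a peptide is kept if
#'   selected for any bait).
#' @return Tibble of selected peptides, highest counts first.
#' @export
selected_peptides <- function(calls, bait = NULL) {
  if (!is.null(bait)) calls <- calls[calls$bait == bait, ]
  sel <- calls[calls$selected, ]
  sel <- sel[order(-sel$total, sel$peptide), ]
  sel[!duplicated(sel$peptide), ]
}
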