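#' Degenerate short linear motif patterns
#'
#' A degenerate motif is a fixed-length pattern over the 20 amino acids in
#' which each position is either a set of allowed residues (at most two, e.g.
#' `[IL]`) or a wildcard `x` matching any residue. The canonical example in
#' this package is `PxYx[IL]`: proline, any residue, tyrosine, any residue,
#' isoleucine or leucine. Wildcards may not dangle: the first and last
#' positions must be fixed, and at least three positions must be fixed
#' overall.
#'
#' @param pattern Pattern string, e.g. `"PxYx[IL]"`. Single residues are
#'   written bare, two-residue sets in square brackets, wildcards as `x`.
#' @return An object of class `degenerate_motif`: a list with elements
#'   `sets` (list of character vectors, `character(0)` for a wildcard),
#'   `pattern`, `length` and `n_fixed`.
#' @examples
#' m <- parse_motif("PxYx[IL]")
#' motif_length(m)
#' motif_regex(m)
#' @export
parse_motif <- function(pattern) {
  stopifnot(is.character(pattern), length(pattern) == 1, nzchar(pattern))
  aa <- "[ACDEFGHIKLMNPQRSTVWY]"
  tokens <- stringr::str_match_all(
    pattern, paste0("\\[(", aa, "+)\\]|(", aa, ")|(x)"))[[1]]
  consumed <- paste(tokens[, 1], collapse = "")
  if (!identical(consumed, pattern)) {
    stop("cannot parse motif pattern: ", pattern, call. = FALSE)
  }
  sets <- lapply(seq_len(nrow(tokens)), function(i) {
    if (!is.na(tokens[i, 4])) return(character(0))          # wildcard
    if (!is.na(tokens[i, 3])) return(tokens[i, 3])          # single residue
    sort(unique(strsplit(tokens[i, 2], "")[[1]]))           # bracketed set
  })
  new_motif(sets)
}

new_motif <- function(sets) {
  bad <- vapply(sets, function(s) length(s) > 2 || anyNA(s) ||
                  (length(s) > 0 && !all(s %in% AA_ALPHABET)), logical(1))
  if (any(bad)) {
    stop("motif positions must be wildcards or sets of at most two standard residues",
         call. = FALSE)
  }
  L <- length(sets)
  fixed <- vapply(sets, length, integer(1)) > 0
  if (L < 3 || L > 8) stop("motif length must be between 3 and 8", call. = FALSE)
  if (!fixed[1] || !fixed[L]) {
    stop("first and last motif positions must be fixed (no dangling wildcards)",
         call. = FALSE)
  }
  if (sum(fixed) < 3) stop("a motif needs at least 3 fixed positions", call. = FALSE)
  structure(
    list(sets = sets, pattern = format_motif_sets(sets), length = L,
         n_fixed = sum(fixed)),
    class = "degenerate_motif"
  )
}

format_motif_sets <- function(sets) {
  paste(vapply(sets, function(s) {
    if (length(s) == 0) "x"
    else if (length(s) == 1) s
    else paste0("[", paste(sort(s), collapse = ""), "]")
  }, character(1)), collapse = "")
}

#' @rdname parse_motif
#' @param m A `degenerate_motif`.
#' @export
motif_length <- function(m) m$length

#' @rdname parse_motif
#' @export
motif_regex <- function(m) {
  paste(vapply(m$sets, function(s) {
    if (length(s) == 0) "."
    else if (length(s) == 1) s
    else paste0("[", paste(s, collapse = ""), "]")
  }, character(1)), collapse = "")
}

#' @export
print.degenerate_motif <- function(x, ...) {
  cat("<degenerate_motif> ", x$pattern, "  (length ", x$length,
      ", ", x$n_fixed, " fixed)\n", sep = "")
  invisible(x)
}

#' @method format degenerate_motif
#' @export
format.degenerate_motif <- function(x, ...) x$pattern

#' Positions within the motif
#'
#' `motif_wildcard_positions()` returns the 1-based wildcard positions (for
#' `PxYx[IL]`: 2 and 4). `motif_tyr_position()` returns the 1-based position
#' of the single fixed tyrosine, or `NA` if the motif has no unambiguous Y
#' position.
#'
#' @param m A `degenerate_motif`.
#' @export
motif_wildcard_positions <- function(m) {
  which(vapply(m$sets, length, integer(1)) == 0)
}

#' @rdname motif_wildcard_positions
#' @export
motif_tyr_position <- function(m) {
  ypos <- which(vapply(m$sets, function(s) identical(s, "Y"), logical(1)))
  if (length(ypos) == 1) ypos else NA_integer_
}

#' Find motif matches in a sequence
#'
#' Returns the 1-based start positions of all (possibly overlapping) matches
#' of a degenerate motif in an amino-acid sequence. With
#' `max_mismatch = 1`, windows in which exactly one *fixed* position fails
#' its residue set are also counted (the "single amino acid variant"
#' convention used when tallying near-matches of a consensus).
#'
#' @param seq Character scalar amino-acid sequence.
#' @param m A `degenerate_motif`.
#' @param max_mismatch 0 (exact, default) or 1.
#' @return Integer vector of match start positions (possibly empty).
#' @export
motif_match_starts <- function(seq, m, max_mismatch = 0) {
  stopifnot(is.character(seq), length(seq) == 1)
  n <- nchar(seq)
  if (n < m$length) return(integer(0))
  if (max_mismatch == 0) {
    hits <- gregexpr(paste0("(?=", motif_regex(m), ")"), seq, perl = TRUE)[[1]]
    if (hits[1] == -1) return(integer(0))
    return(as.integer(hits))
  }
  # mismatch-tolerant path: explicit window check
  chars <- strsplit(seq, "")[[1]]
  starts <- integer(0)
  for (i in seq_len(n - m$length + 1)) {
    mm <- 0L
    for (j in seq_len(m$length)) {
      s <- m$sets[[j]]
      if (length(s) > 0 && !(chars[i + j - 1] %in% s)) mm <- mm + 1L
    }
    if (mm <= max_mismatch) starts <- c(starts, i)
  }
  starts
}

#' @rdname motif_match_starts
#' @description `motif_matches_any()` is a vectorised convenience: does each
#'   sequence contain at least one match?
#' @param seqs Character vector of sequences.
#' @export
motif_matches_any <- function(seqs, m, max_mismatch = 0) {
  if (max_mismatch == 0) {
    return(grepl(motif_regex(m), seqs))
  }
  vapply(seqs, function(s) length(motif_match_starts(s, m, max_mismatch)) > 0,
         logical(1), USE.NAMES = FALSE)
}
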