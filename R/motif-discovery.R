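#' Enumerate candidate degenerate motifs from a peptide set
#'
#' Seed-and-degenerate enumeration: every ungapped k-mer actually present in
#' the peptides (for each length in `L_range`) seeds candidates; wildcards
#' are introduced at interior positions (first and last stay fixed, at least
#' three positions stay fixed); finally, pairs of wildcard patterns that
#' differ at exactly one fixed position are merged into a candidate with a
#' two-residue set at that position (e.g. `PxYxI` + `PxYxL` ->
#' `PxYx[IL]`). Candidates carry at most one two-residue position, which
#' covers the `[I/L]`-style degeneracy this method targets while keeping the
#' candidate space finite.
#'
#' @param peptides Character vector of >= 3 peptide sequences.
#' @param L_range Integer vector of motif lengths to consider (within 3..8).
#' @return List of unique `degenerate_motif` objects.
#' @export
enumerate_motifs <- function(peptides, L_range = 3:6) {
  peptides <- unique(peptides)
  if (length(peptides) == 0) stop("empty peptide set", call. = FALSE)
  L_range <- intersect(L_range, 3:8)
  patterns <- character(0)
  for (L in L_range) {
    kmers <- unique(unlist(lapply(peptides, function(p) {
      n <- nchar(p)
      if (n < L) return(character(0))
      substring(p, 1:(n - L + 1), L:n)
    })))
    kmers <- kmers[grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", kmers)]
    if (length(kmers) == 0) next
    masks <- wildcard_masks(L)
    for (mask in masks) {
      masked <- vapply(kmers, function(k) {
        ch <- strsplit(k, "")[[1]]
        ch[mask] <- "x"
        paste(ch, collapse = "")
      }, character(1), USE.NAMES = FALSE)
      patterns <- c(patterns, unique(masked))
    }
  }
  patterns <- unique(patterns)
  merged <- merge_residue_pairs(patterns)
  lapply(c(patterns, merged), parse_motif)
}

# All subsets of interior positions usable as wildcards, keeping >= 3 fixed
# positions (the empty mask, i.e. the exact k-mer, included).
wildcard_masks <- function(L) {
  interior <- setdiff(seq_len(L), c(1L, L))
  masks <- list(integer(0))
  if (length(interior) > 0) {
    for (k in seq_len(min(length(interior), L - 3L))) {
      cmb <- utils::combn(interior, k, simplify = FALSE)
      masks <- c(masks, cmb)
    }
  }
  masks
}

# Merge pairs of single-residue patterns differing at exactly one fixed
# position into two-residue-set candidates.
merge_residue_pairs <- function(patterns) {
  if (length(patterns) < 2) return(character(0))
  toks <- strsplit(patterns, "")
  out <- character(0)
  by_len <- split(seq_along(patterns), lengths(toks))
  for (idx in by_len) {
    L <- length(toks[[idx[1]]])
    tok_mat <- do.call(rbind, toks[idx])
    for (pos in seq_len(L)) {
      fixed_here <- tok_mat[, pos] != "x"
      if (!any(fixed_here)) next
      key <- apply(tok_mat[fixed_here, -pos, drop = FALSE], 1, paste,
                   collapse = "")
      key <- paste0(key, "@", pos)
      res <- tok_mat[fixed_here, pos]
      for (grp in split(seq_along(key), key)) {
        u <- sort(unique(res[grp]))
        if (length(u) < 2) next
        pairs <- utils::combn(u, 2, simplify = FALSE)
        tmpl <- tok_mat[which(fixed_here)[grp[1]], ]
        for (pr in pairs) {
          tmpl2 <- as.list(tmpl)
          tmpl2[[pos]] <- pr
          sets <- lapply(tmpl2, function(t) if (identical(t, "x")) character(0) else t)
          out <- c(out, format_motif_sets(sets))
        }
      }
    }
  }
  unique(out)
}

#' Score a degenerate motif's overrepresentation in a peptide set
#'
#' Per-peptide binomial model: under a residue background, the probability
#' that a random window matches the motif is the product over fixed
#' positions of the summed background frequencies of the allowed residues
#' (`p_site`); the probability that a peptide of length `W + L - 1` contains
#' at least one match is `p_bg = 1 - (1 - p_site)^W`. The p-value is the
#' exact binomial upper tail `P(X >= k)` for `k` matching peptides out of
#' `N`.
#'
#' @param m A `degenerate_motif` (or pattern string).
#' @param peptides Character vector of peptides (a common length is assumed;
#'   the display library is 16-mers).
#' @param background Named residue frequency vector (default uniform).
#' @return A list of class `motif_score`: `pattern`, `k`, `N`, `p_site`,
#'   `p_bg`, `p_value`.
#' @export
score_motif <- function(m, peptides, background = uniform_background()) {
  if (is.character(m)) m <- parse_motif(m)
  N <- length(peptides)
  if (N == 0) stop("empty peptide set", call. = FALSE)
  k <- sum(motif_matches_any(peptides, m))
  fixed <- m$sets[vapply(m$sets, length, integer(1)) > 0]
  p_site <- prod(vapply(fixed, function(s) sum(background[s]), numeric(1)))
  w <- nchar(peptides) - m$length + 1L
  w <- max(unique(pmax(w, 0L)))
  p_bg <- 1 - (1 - p_site)^w
  p_value <- if (p_site <= 0 || p_bg <= 0) {
    if (k == 0) 1 else 1e-300
  } else {
    max(pbinom(k - 1, N, p_bg, lower.tail = FALSE), 1e-300)
  }
  structure(list(pattern = m$pattern, k = as.integer(k), N = as.integer(N),
                 p_site = p_site, p_bg = p_bg, p_value = p_value),
            class = "motif_score")
}

#' @export
print.motif_score <- function(x, ...) {
  cat(sprintf("<motif_score> %s: k=%d/%d, p_bg=%.3g, p=%.3g\n",
              x$pattern, x$k, x$N, x$p_bg, x$p_value))
  invisible(x)
}

#' Discover the consensus motif enriched in a peptide set
#'
#' Enumerates candidate degenerate motifs ([enumerate_motifs()]), scores
#' each with the binomial overrepresentation statistic ([score_motif()]),
#' applies Benjamini-Hochberg correction across candidates, and ranks by
#' p-value (ties broken by more fixed positions, then pattern string).
#'
#' @inheritParams enumerate_motifs
#' @inheritParams score_motif
#' @param min_k Drop candidates matching fewer than this many peptides
#'   before correction (default 3; sub-support patterns cannot be called
#'   consensus).
#' @return Tibble ranked best-first: `pattern`, `length`, `n_fixed`, `k`,
#'   `N`, `p_bg`, `p`, `q`. The corresponding `degenerate_motif` list is
#'   attached as attribute `motifs` (same order).
#' @export
discover_motifs <- function(peptides, L_range = 3:6,
                            background = uniform_background(), min_k = 3L) {
  if (length(peptides) < 3) stop("need at least 3 peptides", call. = FALSE)
  candidates <- enumerate_motifs(peptides, L_range)
  scores <- lapply(candidates, score_motif, peptides = peptides,
                   background = background)
  tab <- tibble::tibble(
    pattern = vapply(scores, `[[`, character(1), "pattern"),
    length = vapply(candidates, `[[`, integer(1), "length"),
    n_fixed = vapply(candidates, `[[`, integer(1), "n_fixed"),
    k = vapply(scores, `[[`, integer(1), "k"),
    N = vapply(scores, `[[`, integer(1), "N"),
    p_bg = vapply(scores, `[[`, numeric(1), "p_bg"),
    p = vapply(scores, `[[`, numeric(1), "p_value"))
  keep <- tab$k >= min_k
  tab <- tab[keep, ]
  candidates <- candidates[keep]
  tab$q <- p.adjust(tab$p, method = "BH")
  ord <- order(tab$p, -tab$n_fixed, tab$pattern)
  tab <- tab[ord, ]
  attr(tab, "motifs") <- candidates[ord]
  tab
}

#' Position frequency matrix of peptides aligned on a motif
#'
#' Aligns each matching peptide on its first motif match and tallies residue
#' frequencies over the motif span plus a flank on both sides. Column `j`
#' frequencies are computed over the peptides that actually cover column
#' `j`, so every column sums to 1.
#'
#' @param peptides Character vector; peptides without a match are dropped
#'   (error if none match).
#' @param m A `degenerate_motif` (or pattern string).
#' @param flank Flanking columns on each side of the motif (default 4).
#' @return A 20 x (L + 2*flank) matrix of class `proppd_pfm`; columns are
#'   named by offset from the motif start (0-based, so the motif occupies
#'   offsets `0 .. L-1`). Attribute `n_peptides` gives the number aligned.
#' @export
build_pfm <- function(peptides, m, flank = 4L) {
  if (is.character(m)) m <- parse_motif(m)
  starts <- vapply(peptides, function(p) {
    s <- motif_match_starts(p, m)
    if (length(s) == 0) NA_integer_ else s[1]
  }, integer(1), USE.NAMES = FALSE)
  keep <- !is.na(starts)
  if (!any(keep)) stop("no peptide matches the motif", call. = FALSE)
  peptides <- peptides[keep]
  starts <- starts[keep]
  offsets <- seq.int(-flank, m$length - 1L + flank)
  counts <- matrix(0L, nrow = 20, ncol = length(offsets),
                   dimnames = list(AA_ALPHABET, as.character(offsets)))
  for (i in seq_along(peptides)) {
    pos <- starts[i] + offsets
    inside <- pos >= 1 & pos <= nchar(peptides[i])
    res <- substring(peptides[i], pos[inside], pos[inside])
    for (j in which(inside)) {
      r <- substr(peptides[i], pos[j], pos[j])
      counts[r, j] <- counts[r, j] + 1L
    }
  }
  freq <- sweep(counts, 2, pmax(colSums(counts), 1L), "/")
  structure(freq, class = c("proppd_pfm", "matrix"),
            n_peptides = length(peptides), motif = m$pattern)
}

#' Tidy a position frequency matrix
#'
#' @param pfm A `proppd_pfm`.
#' @return Tibble with columns `offset`, `residue`, `frequency`.
#' @export
pfm_tidy <- function(pfm) {
  tibble::tibble(
    offset = rep(as.integer(colnames(pfm)), each = nrow(pfm)),
    residue = rep(rownames(pfm), times = ncol(pfm)),
    frequency = as.vector(unclass(pfm)))
}

#' Plot a position frequency matrix as a text-height logo
#'
#' Simple ggplot2 rendering (residue letters scaled by frequency); intended
#' for quick inspection rather than publication.
#'
#' @param pfm A `proppd_pfm`.
#' @param min_frequency Hide residues below this frequency (default 0.05).
#' @return A ggplot object.
#' @export
plot_pfm <- function(pfm, min_frequency = 0.05) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_pfm() needs the ggplot2 package", call. = FALSE)
  }
  df <- pfm_tidy(pfm)
  df <- df[df$frequency >= min_frequency, ]
  df <- df[order(df$offset, df$frequency), ]
  df$ymax <- stats::ave(df$frequency, df$offset, FUN = cumsum)
  df$y <- df$ymax - df$frequency / 2
  ggplot2::ggplot(df, ggplot2::aes(x = .data$offset, y = .data$y,
                                   label = .data$residue,
                                   size = .data$frequency)) +
    ggplot2::geom_text() +
    ggplot2::scale_size_continuous(range = c(2, 8), guide = "none") +
    ggplot2::labs(x = "offset from motif start", y = "stacked frequency") +
    ggplot2::theme_minimal()
}
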