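#' Distance between a PTM site and the nearest motif instance
#'
#' Default is the gap convention: 0 when the site falls within (or is
#' adjacent to) a motif span, otherwise the number of residues strictly
#' between the site and the nearest motif residue, minimised over all hits
#' in the protein. Under this convention a site at residue 114 relative to a
#' motif spanning 145-149 is 30 residues away. The alternative
#' `"nearest"` convention returns the absolute residue difference to the
#' nearest motif residue.
#'
#' @param sites Integer vector of 1-based site positions.
#' @param spans Tibble/data.frame with `start` and `end` columns for the
#'   protein's motif hits (>= 1 row).
#' @param convention `"gap"` (default) or `"nearest"`.
#' @return Integer vector of distances, one per site.
#' @export
site_motif_distance <- function(sites, spans, convention = c("gap", "nearest")) {
  convention <- match.arg(convention)
  if (nrow(spans) == 0) stop("no motif hits for this protein", call. = FALSE)
  vapply(sites, function(s) {
    d <- vapply(seq_len(nrow(spans)), function(i) {
      a <- spans$start[i]
      b <- spans$end[i]
      if (s >= a && s <= b) return(0L)
      if (convention == "gap") {
        if (s < a) a - s - 1L else s - b - 1L
      } else {
        if (s < a) a - s else s - b
      }
    }, integer(1))
    min(d)
  }, integer(1))
}

#' Summarise PTM crosstalk around motif instances
#'
#' Computes the overlap structure among motif-containing, O-GlcNAcylated,
#' tyrosine-phosphorylated and motif-phosphorylated proteins, and the
#' distance distribution of O-GlcNAc sites to the nearest passing motif:
#'
#' * proteins with >= 1 passing motif hit;
#' * of those, proteins with reported O-GlcNAcylation, and the subset with
#'   positionally assigned sites (the site-level denominator counts sites in
#'   motif-containing proteins only);
#' * sites within `window` residues of a motif (gap convention by default);
#' * proteins with any pTyr site; of those, proteins phosphorylated exactly
#'   on a motif tyrosine; of those, proteins with reported O-GlcNAcylation;
#' * the same within-window site fraction restricted to motif-phosphorylated
#'   proteins.
#'
#' @param proteome A `proppd_proteome`.
#' @param hits Hits tibble from [scan_proteome()] (only passing hits are
#'   used).
#' @param window Residue window (default 100).
#' @param convention Distance convention, see [site_motif_distance()].
#' @return A `crosstalk_summary` list with counts, fractions (percentages
#'   rounded half-up to 1 decimal), the per-site distance tibble `sites`
#'   (columns `protein_id`, `position`, `distance`, `motif_ptyr_protein`)
#'   and the `window` used.
#' @export
summarize_crosstalk <- function(proteome, hits, window = 100L,
                                convention = c("gap", "nearest")) {
  convention <- match.arg(convention)
  passing <- hits[hits$passed, , drop = FALSE]
  motif_ids <- unique(passing$protein_id)

  per_protein <- purrr::map_dfr(proteome[motif_ids], function(p) {
    ph <- passing[passing$protein_id == p$id, , drop = FALSE]
    ytp <- ph$motif_tyr_position[!is.na(ph$motif_tyr_position)]
    tibble::tibble(
      protein_id = p$id,
      has_oglcnac = isTRUE(p$oglcnac_reported) || length(p$oglcnac_sites) > 0,
      n_sites = length(p$oglcnac_sites),
      has_ptyr = length(p$ptyr_sites) > 0,
      motif_ptyr = length(intersect(p$ptyr_sites, ytp)) > 0)
  })
  if (nrow(per_protein) == 0) {
    per_protein <- tibble::tibble(protein_id = character(0),
                                  has_oglcnac = logical(0), n_sites = integer(0),
                                  has_ptyr = logical(0), motif_ptyr = logical(0))
  }

  sites <- purrr::map_dfr(proteome[motif_ids], function(p) {
    if (length(p$oglcnac_sites) == 0) return(NULL)
    ph <- passing[passing$protein_id == p$id, , drop = FALSE]
    tibble::tibble(
      protein_id = p$id, position = p$oglcnac_sites,
      distance = site_motif_distance(p$oglcnac_sites, ph, convention))
  })
  if (nrow(sites) == 0) {
    sites <- tibble::tibble(protein_id = character(0), position = integer(0),
                            distance = integer(0))
  }
  mp_ids <- per_protein$protein_id[per_protein$motif_ptyr]
  sites$motif_ptyr_protein <- sites$protein_id %in% mp_ids

  n_motif <- nrow(per_protein)
  n_oglc <- sum(per_protein$has_oglcnac)
  n_with_sites <- sum(per_protein$n_sites > 0)
  n_sites <- nrow(sites)
  n_within <- sum(sites$distance <= window)
  n_ptyr <- sum(per_protein$has_ptyr)
  n_motif_ptyr <- sum(per_protein$motif_ptyr)
  n_motif_ptyr_oglc <- sum(per_protein$motif_ptyr & per_protein$has_oglcnac)
  mp_sites <- sites[sites$motif_ptyr_protein, , drop = FALSE]

  structure(list(
    n_motif_proteins = n_motif,
    n_oglcnac_proteins = n_oglc,
    pct_oglcnac_proteins = round_half_up(100 * n_oglc / max(n_motif, 1), 1),
    n_proteins_with_sites = n_with_sites,
    n_sites_assigned = n_sites,
    n_sites_within_window = n_within,
    pct_sites_within_window = round_half_up(100 * n_within / max(n_sites, 1), 1),
    n_ptyr_proteins = n_ptyr,
    pct_ptyr_proteins = round_half_up(100 * n_ptyr / max(n_motif, 1), 1),
    n_motif_ptyr_proteins = n_motif_ptyr,
    pct_motif_ptyr_proteins = round_half_up(100 * n_motif_ptyr / max(n_ptyr, 1), 1),
    n_motif_ptyr_with_oglcnac = n_motif_ptyr_oglc,
    pct_motif_ptyr_with_oglcnac =
      round_half_up(100 * n_motif_ptyr_oglc / max(n_motif_ptyr, 1), 1),
    n_motif_ptyr_sites = nrow(mp_sites),
    n_motif_ptyr_sites_within = sum(mp_sites$distance <= window),
    pct_motif_ptyr_sites_within =
      round_half_up(100 * sum(mp_sites$distance <= window) /
                      max(nrow(mp_sites), 1), 1),
    window = as.integer(window),
    convention = convention,
    per_protein = per_protein,
    sites = sites
  ), class = "crosstalk_summary")
}

#' @export
print.crosstalk_summary <- function(x, ...) {
  cat("<crosstalk_summary> window =", x$window, "residues\n")
  cat(sprintf("  motif-containing proteins:       %d\n", x$n_motif_proteins))
  cat(sprintf("  with O-GlcNAcylation:            %d (%.1f%%)\n",
              x$n_oglcnac_proteins, x$pct_oglcnac_proteins))
  cat(sprintf("  assigned O-GlcNAc sites:         %d in %d proteins\n",
              x$n_sites_assigned, x$n_proteins_with_sites))
  cat(sprintf("  sites within window:             %d (%.1f%%)\n",
              x$n_sites_within_window, x$pct_sites_within_window))
  cat(sprintf("  with any pTyr site:              %d (%.1f%%)\n",
              x$n_ptyr_proteins, x$pct_ptyr_proteins))
  cat(sprintf("  pTyr on the motif tyrosine:      %d (%.1f%%)\n",
              x$n_motif_ptyr_proteins, x$pct_motif_ptyr_proteins))
  cat(sprintf("  of those, with O-GlcNAcylation:  %d (%.1f%%)\n",
              x$n_motif_ptyr_with_oglcnac, x$pct_motif_ptyr_with_oglcnac))
  cat(sprintf("  motif-pTyr subset sites within:  %d/%d (%.1f%%)\n",
              x$n_motif_ptyr_sites_within, x$n_motif_ptyr_sites,
              x$pct_motif_ptyr_sites_within))
  invisible(x)
}

#' Histogram of site-to-motif distances
#'
#' Bins the O-GlcNAc site distances of a [summarize_crosstalk()] result
#' (default bin width 10 residues, edges at 0, 10, 20, ...), for all
#' motif-containing proteins and for the motif-phosphorylated subset.
#'
#' @param summary A `crosstalk_summary`.
#' @param bin_width Bin width in residues (default 10).
#' @return Tibble: `bin_start`, `bin_end`, `n_all`, `n_motif_ptyr`.
#' @export
distance_histogram <- function(summary, bin_width = 10L) {
  bin_width <- as.integer(bin_width)
  d <- summary$sites$distance
  if (length(d) == 0) {
    return(tibble::tibble(bin_start = integer(0), bin_end = integer(0),
                          n_all = integer(0), n_motif_ptyr = integer(0)))
  }
  top <- (max(d) %/% bin_width + 1L) * bin_width
  edges <- seq.int(0L, top, by = bin_width)
  bin <- findInterval(d, edges, rightmost.closed = FALSE)
  mp <- summary$sites$motif_ptyr_protein
  tibble::tibble(
    bin_start = edges[-length(edges)],
    bin_end = edges[-1] - 1L,
    n_all = vapply(seq_len(length(edges) - 1),
                   function(i) sum(bin == i), integer(1)),
    n_motif_ptyr = vapply(seq_len(length(edges) - 1),
                          function(i) sum(bin == i & mp), integer(1)))
}

#' Hypergeometric set enrichment with BH-FDR control
#'
#' For each annotation term, tests whether the query protein set contains
#' more term members than expected by drawing `n = |query|` proteins from
#' the universe without replacement: exact hypergeometric upper tail
#' `P(X >= k)`, Benjamini-Hochberg correction across terms, significance at
#' `q < alpha`.
#'
#' @param query Character vector of protein ids (must be a subset of
#'   `universe`).
#' @param terms Named list of character vectors (term -> member ids).
#' @param universe Character vector of all protein ids under consideration.
#' @param alpha FDR threshold (default 0.05).
#' @return Tibble: `term`, `k`, `K`, `n`, `N`, `p`, `q`, `significant`,
#'   ordered by p. Terms with zero members in the universe are skipped with
#'   a warning.
#' @export
enrich_sets <- function(query, terms, universe, alpha = 0.05) {
  universe <- unique(universe)
  query <- unique(query)
  if (!all(query %in% universe)) {
    stop("query must be a subset of the universe", call. = FALSE)
  }
  N <- length(universe)
  n <- length(query)
  rows <- purrr::imap_dfr(terms, function(members, term) {
    members <- intersect(unique(members), universe)
    K <- length(members)
    if (K == 0) {
      warning("term '", term, "' has no members in the universe; skipped",
              call. = FALSE)
      return(NULL)
    }
    k <- length(intersect(query, members))
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    tibble::tibble(term = term, k = k, K = K, n = n, N = N, p = p)
  })
  if (nrow(rows) == 0) {
    return(tibble::tibble(term = character(0), k = integer(0), K = integer(0),
                          n = integer(0), N = integer(0), p = numeric(0),
                          q = numeric(0), significant = logical(0)))
  }
  rows$q <- p.adjust(rows$p, method = "BH")
  rows$significant <- rows$q < alpha
  rows[order(rows$p, rows$term), ]
}
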