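#' Scan a proteome for motif instances under disorder and topology filters
#'
#' Finds every (possibly overlapping) raw match of a degenerate motif in
#' each protein, then applies three independent predicates:
#'
#' * `passed_disorder` — the motif lies in an intrinsically disordered
#'   region: every motif residue has disorder score above
#'   `disorder_threshold` (with `disorder_rule = "mean"`, the mean over the
#'   span is used instead);
#' * `passed_proline` — no wildcard position of the motif is occupied by
#'   proline (for `PxYx[IL]`, positions 2 and 4);
#' * `passed_topology` — the protein is not secreted and the match does not
#'   fall in an extracellular domain.
#'
#' A hit passes overall iff all enabled filters pass; the motif-containing
#' protein set is the set of proteins with at least one passing hit.
#'
#' @param proteome A `proppd_proteome` (see [generate_proteome()] /
#'   [read_proteome()]).
#' @param m A `degenerate_motif` or pattern string.
#' @param disorder_threshold Disorder cutoff (default 0.4, exclusive).
#' @param exclude_P_at_x Apply the proline-exclusion filter (default TRUE).
#' @param topology_filter Apply the topology filter (default TRUE).
#' @param disorder_rule `"all"` (every residue, default) or `"mean"`.
#' @param extracellular_regions Optional tibble (`protein_id`, `start`,
#'   `end`) of extracellular domain intervals for per-region topology.
#' @return Tibble of hits: `protein_id`, `start`, `end` (1-based inclusive),
#'   `match`, `motif_tyr_position` (NA when the motif has no unambiguous Y),
#'   `passed_disorder`, `passed_proline`, `passed_topology`, `passed`.
#'   Attribute `motif_proteins` holds the passing protein-id set.
#' @export
scan_proteome <- function(proteome, m, disorder_threshold = 0.4,
                          exclude_P_at_x = TRUE, topology_filter = TRUE,
                          disorder_rule = c("all", "mean"),
                          extracellular_regions = NULL) {
  if (is.character(m)) m <- parse_motif(m)
  disorder_rule <- match.arg(disorder_rule)
  ytpos <- motif_tyr_position(m)
  xpos <- motif_wildcard_positions(m)

  hits <- purrr::map_dfr(proteome, function(p) {
    starts <- motif_match_starts(p$seq, m)
    if (length(starts) == 0) return(NULL)
    ends <- starts + m$length - 1L
    span_disorder <- vapply(seq_along(starts), function(i) {
      d <- p$disorder[starts[i]:ends[i]]
      if (disorder_rule == "all") all(d > disorder_threshold)
      else mean(d) > disorder_threshold
    }, logical(1))
    if (exclude_P_at_x && length(xpos) > 0) {
      no_proline <- vapply(starts, function(s) {
        !any(substring(p$seq, s + xpos - 1L, s + xpos - 1L) == "P")
      }, logical(1))
    } else {
      no_proline <- rep(TRUE, length(starts))
    }
    if (topology_filter) {
      topo_ok <- rep(!identical(p$topology, "secreted"), length(starts))
      if (!is.null(extracellular_regions)) {
        er <- extracellular_regions[
          extracellular_regions$protein_id == p$id, , drop = FALSE]
        if (nrow(er) > 0) {
          overlaps <- vapply(seq_along(starts), function(i) {
            any(starts[i] <= er$end & ends[i] >= er$start)
          }, logical(1))
          topo_ok <- topo_ok & !overlaps
        }
      }
      if (identical(p$topology, "extracellular_domain") &&
          is.null(extracellular_regions)) {
        # protein-granularity fallback: flag alone excludes the protein
        topo_ok <- rep(FALSE, length(starts))
      }
    } else {
      topo_ok <- rep(TRUE, length(starts))
    }
    tibble::tibble(
      protein_id = p$id, start = starts, end = ends,
      match = substring(p$seq, starts, ends),
      motif_tyr_position = if (is.na(ytpos)) NA_integer_
                           else starts + ytpos - 1L,
      passed_disorder = span_disorder,
      passed_proline = no_proline,
      passed_topology = topo_ok)
  })
  if (nrow(hits) == 0) {
    hits <- tibble::tibble(
      protein_id = character(0), start = integer(0), end = integer(0),
      match = character(0), motif_tyr_position = integer(0),
      passed_disorder = logical(0), passed_proline = logical(0),
      passed_topology = logical(0))
  }
  hits$passed <- hits$passed_disorder & hits$passed_proline &
    hits$passed_topology
  attr(hits, "motif_proteins") <- unique(hits$protein_id[hits$passed])
  hits
}

#' @rdname scan_proteome
#' @description `motif_proteins()` extracts the passing protein-id set from
#'   a hits table.
#' @param hits A hits tibble from [scan_proteome()].
#' @export
motif_proteins <- function(hits) {
  unique(hits$protein_id[hits$passed])
}

#' Exhaustive position-by-position motif scan (test oracle)
#'
#' Checks every window of every protein against the motif's per-position
#' residue sets with plain loops, applying the same three filters as
#' [scan_proteome()]. Intended as an independent correctness oracle; output
#' columns match `scan_proteome()`.
#'
#' @inheritParams scan_proteome
#' @export
brute_force_scan <- function(proteome, m, disorder_threshold = 0.4,
                             exclude_P_at_x = TRUE, topology_filter = TRUE) {
  if (is.character(m)) m <- parse_motif(m)
  ytpos <- motif_tyr_position(m)
  rows <- list()
  for (p in proteome) {
    chars <- strsplit(p$seq, "")[[1]]
    n <- length(chars)
    if (n < m$length) next
    for (s in seq_len(n - m$length + 1)) {
      ok <- TRUE
      for (j in seq_len(m$length)) {
        set <- m$sets[[j]]
        if (length(set) > 0 && !(chars[s + j - 1] %in% set)) {
          ok <- FALSE
          break
        }
      }
      if (!ok) next
      e <- s + m$length - 1L
      d_ok <- TRUE
      for (q in s:e) if (!(p$disorder[q] > disorder_threshold)) d_ok <- FALSE
      pr_ok <- TRUE
      if (exclude_P_at_x) {
        for (j in seq_len(m$length)) {
          if (length(m$sets[[j]]) == 0 && chars[s + j - 1] == "P") pr_ok <- FALSE
        }
      }
      t_ok <- !topology_filter ||
        !(p$topology %in% c("secreted", "extracellular_domain"))
      rows[[length(rows) + 1]] <- tibble::tibble(
        protein_id = p$id, start = as.integer(s), end = e,
        match = paste(chars[s:e], collapse = ""),
        motif_tyr_position = if (is.na(ytpos)) NA_integer_
                             else as.integer(s + ytpos - 1L),
        passed_disorder = d_ok, passed_proline = pr_ok,
        passed_topology = t_ok)
    }
  }
  hits <- if (length(rows) > 0) dplyr::bind_rows(rows) else tibble::tibble(
    protein_id = character(0), start = integer(0), end = integer(0),
    match = character(0), motif_tyr_position = integer(0),
    passed_disorder = logical(0), passed_proline = logical(0),
    passed_topology = logical(0))
  hits$passed <- hits$passed_disorder & hits$passed_proline &
    hits$passed_topology
  hits
}
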