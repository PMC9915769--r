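# Hand-built fixtures shared across test files.

# A minimal protein record in the proteome layout.
make_protein <- function(id, seq, disorder = rep(0.9, nchar(seq)),
                         topology = "intracellular",
                         oglcnac_sites = integer(0),
                         ptyr_sites = integer(0),
                         oglcnac_reported = length(oglcnac_sites) > 0) {
  list(id = id, seq = seq, disorder = disorder, topology = topology,
       oglcnac_reported = oglcnac_reported,
       oglcnac_sites = as.integer(oglcnac_sites),
       ptyr_sites = as.integer(ptyr_sites), motif_start = NA_integer_)
}

make_proteome <- function(...) {
  proteins <- list(...)
  names(proteins) <- vapply(proteins, `[[`, character(1), "id")
  structure(proteins, class = "proppd_proteome")
}

# A random proteome of short proteins for scan-vs-oracle property tests.
random_proteome <- function(n_proteins, len_range = c(30, 120)) {
  proteins <- lapply(seq_len(n_proteins), function(i) {
    len <- sample(len_range[1]:len_range[2], 1)
    make_protein(
      id = sprintf("RND%04d", i),
      seq = random_peptide(len),
      disorder = sample(c(0.1, 0.9), len, replace = TRUE),
      topology = sample(c("intracellular", "secreted"), 1, prob = c(0.8, 0.2)))
  })
  names(proteins) <- vapply(proteins, `[[`, character(1), "id")
  structure(proteins, class = "proppd_proteome")
}

# Crosstalk fixture reproducing a given overlap structure exactly:
#  n_motif motif proteins; proteins 1..n_motif_ptyr phosphorylated on the
#  motif tyrosine and (n_motif_ptyr+1)..n_ptyr phosphorylated elsewhere; an
#  explicit reported-O-GlcNAc set of size n_oglc whose overlap with the
#  motif-pTyr set is exactly n_motif_ptyr_oglc; n_with_sites reported
#  proteins carry n_sites positionally assigned sites, n_within of them
#  within the window of the motif.
make_overlap_fixture <- function(n_motif = 223, n_oglc = 126,
                                 n_with_sites = 89, n_sites = 374,
                                 n_within = 64, n_ptyr = 189,
                                 n_motif_ptyr = 61, n_motif_ptyr_oglc = 47,
                                 window = 100) {
  stopifnot(n_motif_ptyr_oglc <= n_motif_ptyr,
            n_oglc >= n_with_sites,
            n_motif >= n_ptyr, n_ptyr >= n_motif_ptyr)
  # index sets (motif-pTyr proteins come first, then other-pTyr, then rest)
  reported <- c(seq_len(n_motif_ptyr_oglc),
                n_motif_ptyr + seq_len(n_oglc - n_motif_ptyr_oglc))
  site_carriers <- reported[seq_len(n_with_sites)]

  # each protein: motif at 201..205 (PAYAI), long enough for far sites
  motif_start <- 201L
  motif_end <- 205L
  len <- 600L
  # distribute sites over the site carriers as evenly as possible
  per <- rep(n_sites %/% n_with_sites, n_with_sites)
  extra <- n_sites %% n_with_sites
  if (extra > 0) per[seq_len(extra)] <- per[seq_len(extra)] + 1
  within_left <- n_within

  proteins <- lapply(seq_len(n_motif), function(i) {
    s <- rep("A", len)
    s[motif_start:motif_end] <- c("P", "A", "Y", "A", "I")
    oglc <- integer(0)
    ci <- match(i, site_carriers)
    if (!is.na(ci)) {
      k <- per[ci]
      n_near <- min(k, within_left)
      within_left <<- within_left - n_near
      near <- if (n_near > 0) motif_end + 1 + seq_len(n_near) else integer(0)
      far <- if (k - n_near > 0) {
        motif_end + window + 50 + seq_len(k - n_near) * 2
      } else integer(0)
      oglc <- c(near, far)
      s[oglc] <- "S"
    }
    ptyr <- integer(0)
    if (i <= n_motif_ptyr) {
      ptyr <- motif_start + 2L               # the motif tyrosine
    } else if (i <= n_ptyr) {
      s[500] <- "Y"
      ptyr <- 500L
    }
    make_protein(
      id = sprintf("FIX%04d", i), seq = paste(s, collapse = ""),
      oglcnac_sites = oglc, ptyr_sites = ptyr,
      oglcnac_reported = i %in% reported)
  })
  names(proteins) <- vapply(proteins, `[[`, character(1), "id")
  structure(proteins, class = "proppd_proteome")
}
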