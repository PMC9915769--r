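#' Specification for a synthetic annotated proteome
#'
#' Describes a toy proteome used to benchmark the full selection pipeline:
#' random protein sequences with block-wise intrinsic-disorder scores, a
#' degenerate motif planted into disordered regions of a chosen fraction of
#' proteins, and O-GlcNAc / phosphotyrosine site tables whose spatial
#' relationship to the planted motif is controlled.
#'
#' Disorder is simulated as block-wise constants (0.8 in disordered blocks,
#' 0.1 in ordered blocks) since downstream logic only consumes the > 0.4
#' threshold. O-GlcNAc sites are placed on S/T residues; for each site in a
#' motif-carrying protein, a Bernoulli draw with probability
#' `oglcnac_near_motif_fraction` decides whether the site lands within
#' `proximity_window` residues of the motif (gap-distance convention) or
#' beyond it. A fraction `ptyr_on_motif_fraction` of motif carriers receive a
#' phosphotyrosine site exactly on the motif tyrosine.
#'
#' @param n_proteins Number of proteins (>= 1).
#' @param length_range Two-element integer vector, protein length bounds
#'   (lower bound >= 30).
#' @param disorder_block_fraction Probability that a sequence block is
#'   disordered.
#' @param planted_motif Degenerate pattern string planted into carriers.
#' @param motif_carrier_fraction Fraction of proteins carrying >= 1 planted
#'   motif instance inside a disordered region.
#' @param oglcnac_near_motif_fraction Per-site probability that an O-GlcNAc
#'   site in a carrier lies within `proximity_window` residues of the motif.
#' @param proximity_window Residue window for "near" (default 100).
#' @param ptyr_on_motif_fraction Fraction of carriers phosphorylated on the
#'   motif tyrosine.
#' @param oglcnac_near_motif_fraction_motif_ptyr Per-site near probability
#'   for carriers phosphorylated on the motif tyrosine; `NULL` (default)
#'   inherits `oglcnac_near_motif_fraction`. Setting it higher plants the
#'   proximal-O-GlcNAc enrichment of the motif-phosphorylated subset.
#' @param oglcnac_sites_per_protein Mean number of O-GlcNAc sites per carrier
#'   protein (Poisson, minimum 1 for carriers).
#' @param seed Integer seed; identical spec + seed gives byte-identical
#'   outputs.
#' @return A `synth_proteome_spec` list.
#' @export
synth_proteome_spec <- function(n_proteins = 200,
                                length_range = c(250L, 600L),
                                disorder_block_fraction = 0.5,
                                planted_motif = "PxYx[IL]",
                                motif_carrier_fraction = 0.3,
                                oglcnac_near_motif_fraction = 0.171,
                                proximity_window = 100L,
                                ptyr_on_motif_fraction = 0.3,
                                oglcnac_near_motif_fraction_motif_ptyr = NULL,
                                oglcnac_sites_per_protein = 4,
                                seed = 1L) {
  stopifnot(
    n_proteins >= 1,
    length(length_range) == 2, length_range[1] >= 30,
    length_range[1] <= length_range[2],
    proximity_window >= 1, oglcnac_sites_per_protein >= 0
  )
  for (f in c(disorder_block_fraction, motif_carrier_fraction,
              oglcnac_near_motif_fraction, ptyr_on_motif_fraction,
              oglcnac_near_motif_fraction_motif_ptyr)) {
    if (f < 0 || f > 1) stop("fractions must lie in [0, 1]", call. = FALSE)
  }
  m <- parse_motif(planted_motif)
  if (m$length > length_range[1]) {
    stop("impossible geometry: motif longer than the minimum protein length",
         call. = FALSE)
  }
  structure(
    list(
      n_proteins = as.integer(n_proteins),
      length_range = as.integer(length_range),
      disorder_block_fraction = disorder_block_fraction,
      planted_motif = planted_motif,
      motif_carrier_fraction = motif_carrier_fraction,
      oglcnac_near_motif_fraction = oglcnac_near_motif_fraction,
      proximity_window = as.integer(proximity_window),
      ptyr_on_motif_fraction = ptyr_on_motif_fraction,
      oglcnac_near_motif_fraction_motif_ptyr =
        oglcnac_near_motif_fraction_motif_ptyr %||% oglcnac_near_motif_fraction,
      oglcnac_sites_per_protein = oglcnac_sites_per_protein,
      seed = as.integer(seed)
    ),
    class = "synth_proteome_spec"
  )
}

DISORDER_HIGH <- 0.8
DISORDER_LOW <- 0.1

#' Generate a synthetic annotated proteome
#'
#' Draws protein sequences uniformly over the 20 standard residues, assigns
#' block-wise disorder scores, plants the spec's motif into disordered
#' regions of the chosen carrier fraction, and places O-GlcNAc and
#' phosphotyrosine sites according to the spec's proximity fractions.
#' Planted wildcard positions avoid proline so that planted instances
#' survive the proline-exclusion scan filter.
#'
#' @param spec A [synth_proteome_spec()].
#' @return A `proppd_proteome`: named list of protein records, each a list
#'   with `id`, `seq`, `disorder` (per-residue score), `topology`
#'   (`"intracellular"` here), `oglcnac_reported`, `oglcnac_sites`,
#'   `ptyr_sites`, `motif_start` (NA for non-carriers).
#' @export
generate_proteome <- function(spec) {
  stopifnot(inherits(spec, "synth_proteome_spec"))
  set.seed(spec$seed)
  m <- parse_motif(spec$planted_motif)
  n <- spec$n_proteins
  n_carriers <- round(spec$motif_carrier_fraction * n)
  carrier <- seq_len(n) <= n_carriers  # deterministic assignment, ids shuffled by naming
  ids <- sprintf("SYNP%04d", seq_len(n))

  proteins <- vector("list", n)
  for (i in seq_len(n)) {
    len <- sample(spec$length_range[1]:spec$length_range[2], 1)
    blocks <- sim_disorder_blocks(len, spec$disorder_block_fraction,
                                  force_long_disordered = carrier[i])
    seq_chars <- sample(AA_ALPHABET, len, replace = TRUE)
    disorder <- rep(ifelse(blocks$disordered, DISORDER_HIGH, DISORDER_LOW),
                    times = blocks$len)

    motif_start <- NA_integer_
    if (carrier[i]) {
      motif_start <- plant_motif(seq_chars, disorder, m)
      seq_chars <- attr(motif_start, "seq")
      attributes(motif_start) <- NULL
    }

    ann <- place_ptm_sites(seq_chars, motif_start, m, spec)
    proteins[[i]] <- list(
      id = ids[i],
      seq = paste(ann$seq, collapse = ""),
      disorder = disorder,
      topology = "intracellular",
      oglcnac_reported = length(ann$oglc) > 0,
      oglcnac_sites = ann$oglc,
      ptyr_sites = ann$ptyr,
      motif_start = motif_start
    )
  }
  names(proteins) <- ids
  structure(proteins, class = "proppd_proteome", spec = spec)
}

# Split a protein of length len into consecutive blocks of ~25-60 residues,
# each disordered with probability p. Carriers need one disordered block long
# enough to host motif + tiling, so the first block can be forced.
sim_disorder_blocks <- function(len, p, force_long_disordered = FALSE) {
  lens <- integer(0)
  remaining <- len
  while (remaining > 0) {
    b <- min(remaining, sample(25:60, 1))
    if (remaining - b < 25) b <- remaining  # absorb short tail
    lens <- c(lens, b)
    remaining <- remaining - b
  }
  disordered <- runif(length(lens)) < p
  if (force_long_disordered && !any(disordered & lens >= 40)) {
    k <- which(lens >= 40)
    if (length(k) == 0) k <- which.max(lens)
    disordered[k[1]] <- TRUE
  }
  list(len = lens, disordered = disordered)
}

# Write one motif instance into a disordered block; wildcards drawn from the
# alphabet minus proline. Returns the chosen 1-based start with the mutated
# sequence attached.
plant_motif <- function(seq_chars, disorder, m) {
  runs <- disorder_runs(disorder, threshold = 0.4)
  runs <- runs[runs$length >= max(m$length, 16), , drop = FALSE]
  if (nrow(runs) == 0) stop("no disordered block can host the motif", call. = FALSE)
  r <- runs[sample(nrow(runs), 1), ]
  start <- r$start + sample.int(r$length - m$length + 1, 1) - 1L
  for (j in seq_len(m$length)) {
    s <- m$sets[[j]]
    seq_chars[start + j - 1] <- if (length(s) == 0) {
      sample(setdiff(AA_ALPHABET, "P"), 1)
    } else {
      sample(s, 1)[1]
    }
  }
  structure(as.integer(start), seq = seq_chars)
}

# Maximal runs of residues with disorder > threshold.
disorder_runs <- function(disorder, threshold = 0.4) {
  r <- rle(disorder > threshold)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  tibble::tibble(start = starts[keep], end = ends[keep],
                 length = r$lengths[keep])
}

# Place O-GlcNAc sites (on S/T, forced by overwriting the residue) and pTyr
# sites for one protein. Near/far placement uses the gap-distance convention
# relative to the planted motif span.
place_ptm_sites <- function(seq_chars, motif_start, m, spec) {
  len <- length(seq_chars)
  oglc <- integer(0)
  ptyr <- integer(0)
  if (!is.na(motif_start)) {
    ytpos <- motif_tyr_position(m)
    motif_ptyr <- !is.na(ytpos) && runif(1) < spec$ptyr_on_motif_fraction
    if (motif_ptyr) ptyr <- c(ptyr, motif_start + ytpos - 1L)
    near_frac <- if (motif_ptyr) {
      spec$oglcnac_near_motif_fraction_motif_ptyr
    } else {
      spec$oglcnac_near_motif_fraction
    }
    span <- c(motif_start, motif_start + m$length - 1L)
    n_sites <- max(1L, rpois(1, spec$oglcnac_sites_per_protein))
    candidates <- setdiff(seq_len(len), span[1]:span[2])
    gap <- gap_distance(candidates, span[1], span[2])
    near_pool <- candidates[gap <= spec$proximity_window]
    far_pool <- candidates[gap > spec$proximity_window]
    for (s in seq_len(n_sites)) {
      near <- runif(1) < near_frac
      pool <- if (near) near_pool else far_pool
      if (length(pool) == 0) pool <- if (near) far_pool else near_pool
      pos <- pool[sample.int(length(pool), 1)]
      seq_chars[pos] <- sample(c("S", "T"), 1)
      oglc <- c(oglc, pos)
      near_pool <- setdiff(near_pool, pos)
      far_pool <- setdiff(far_pool, pos)
    }
  }
  # background pTyr on existing tyrosines anywhere
  ys <- setdiff(which(seq_chars == "Y"), ptyr)
  n_bg <- min(length(ys), rpois(1, 1))
  if (n_bg > 0) ptyr <- c(ptyr, sample(ys, n_bg))
  list(seq = seq_chars, oglc = sort(unique(oglc)), ptyr = sort(unique(ptyr)))
}

# Residues strictly between a position and a motif span (0 if inside or
# adjacent); vectorised over positions.
gap_distance <- function(pos, start, end) {
  d <- ifelse(pos < start, start - pos - 1L,
              ifelse(pos > end, pos - end - 1L, 0L))
  as.integer(d)
}

#' @export
print.proppd_proteome <- function(x, ...) {
  nc <- sum(!vapply(x, function(p) is.na(p$motif_start), logical(1)))
  cat("<proppd_proteome> ", length(x), " proteins (", nc,
      " planted motif carriers)\n", sep = "")
  invisible(x)
}

#' Tile a proteome's disordered regions into a peptide display library
#'
#' Emulates the design of a disorderome display library: each maximal
#' disordered stretch (score > 0.4) of at least `tile_length` residues is
#' covered by `tile_length`-mer windows advancing by `step` residues, with a
#' final window right-aligned to the end of the stretch so every disordered
#' residue is represented. Stretches shorter than `tile_length` are skipped.
#'
#' @param proteome A `proppd_proteome` (or any named list of records with
#'   `seq` and `disorder`).
#' @param tile_length Peptide length (default 16).
#' @param step Tiling step in residues (default 8, i.e. half-overlapping).
#' @param disorder_threshold Score above which a residue counts as
#'   disordered (default 0.4).
#' @return Tibble with columns `peptide`, `protein_id`, `start` (1-based).
#'   Zero rows (with a warning) if no disordered stretch is long enough.
#' @export
generate_library <- function(proteome, tile_length = 16L, step = 8L,
                             disorder_threshold = 0.4) {
  stopifnot(tile_length >= 1, step >= 1)
  rows <- purrr::map_dfr(proteome, function(p) {
    runs <- disorder_runs(p$disorder, disorder_threshold)
    runs <- runs[runs$length >= tile_length, , drop = FALSE]
    if (nrow(runs) == 0) return(NULL)
    starts <- unlist(lapply(seq_len(nrow(runs)), function(i) {
      tile_starts(runs$start[i], runs$end[i], tile_length, step)
    }))
    tibble::tibble(
      peptide = substring(p$seq, starts, starts + tile_length - 1L),
      protein_id = p$id,
      start = as.integer(starts)
    )
  })
  if (nrow(rows) == 0) {
    warning("no disordered region long enough to tile; empty library",
            call. = FALSE)
    return(tibble::tibble(peptide = character(0), protein_id = character(0),
                          start = integer(0)))
  }
  rows
}

tile_starts <- function(run_start, run_end, tile_length, step) {
  last <- run_end - tile_length + 1L
  s <- seq.int(run_start, last, by = step)
  if (s[length(s)] != last) s <- c(s, last)  # right-align final tile
  as.integer(s)
}

# ---- selection design and read generation ----------------------------------

#' Design of a phage selection sequencing run
#'
#' Describes the read architecture (sample barcodes, fixed adapter flanks, a
#' 48-nt insert encoding a 16-mer) and the sampling model for selection
#' reads: every library peptide has weight 1, motif-bearing peptides have
#' weight `enrichment_factor`, and each replicate draws `background_depth`
#' reads from the resulting multinomial.
#'
#' @param samples Tibble/data.frame with columns `barcode` (equal-length,
#'   unique DNA strings) and `bait` (label).
#' @param replicates_per_bait Number of replicate selections per bait.
#' @param adapter_5p,adapter_3p Fixed DNA flanks around the insert.
#' @param insert_length_nt Insert length; must be divisible by 3 (default 48).
#' @param enrichment_factor Sampling weight multiplier (>= 1, may be `Inf`)
#'   for motif-bearing peptides.
#' @param background_depth Reads per replicate.
#' @param seed Integer seed.
#' @return A `selection_design` list.
#' @export
selection_design <- function(samples = tibble::tibble(
                               barcode = c("ACGTAC", "TGCAGT"),
                               bait = c("OGT", "OGT4.5")),
                             replicates_per_bait = 3L,
                             adapter_5p = "GGTGGAGGTTCG",
                             adapter_3p = "TCCGGATGGTGG",
                             insert_length_nt = 48L,
                             enrichment_factor = 1,
                             background_depth = 5000L,
                             seed = 1L) {
  samples <- tibble::as_tibble(samples)
  stopifnot(all(c("barcode", "bait") %in% names(samples)),
            replicates_per_bait >= 1, background_depth >= 1,
            enrichment_factor >= 1)
  if (anyDuplicated(samples$barcode)) {
    stop("sample barcodes must be unique", call. = FALSE)
  }
  if (length(unique(nchar(samples$barcode))) != 1) {
    stop("sample barcodes must have equal length", call. = FALSE)
  }
  if (insert_length_nt %% 3 != 0) {
    stop("insert_length_nt must be divisible by 3", call. = FALSE)
  }
  check_dna <- function(x) all(grepl("^[ACGT]+$", x))
  if (!check_dna(samples$barcode) || !check_dna(c(adapter_5p, adapter_3p))) {
    stop("barcodes and adapters must be ACGT strings", call. = FALSE)
  }
  structure(
    list(samples = samples,
         replicates_per_bait = as.integer(replicates_per_bait),
         adapter_5p = adapter_5p, adapter_3p = adapter_3p,
         insert_length_nt = as.integer(insert_length_nt),
         enrichment_factor = enrichment_factor,
         background_depth = as.integer(background_depth),
         seed = as.integer(seed)),
    class = "selection_design"
  )
}

# Fixed reverse-translation table: one common human codon per residue, so a
# given peptide always yields the same insert.
CODON_CHOICE <- c(
  A = "GCC", C = "TGC", D = "GAC", E = "GAG", F = "TTC", G = "GGC",
  H = "CAC", I = "ATC", K = "AAG", L = "CTG", M = "ATG", N = "AAC",
  P = "CCC", Q = "CAG", R = "AGA", S = "AGC", T = "ACC", V = "GTG",
  W = "TGG", Y = "TAC"
)

#' Reverse-translate peptides with a fixed codon table
#'
#' @param peptides Character vector of amino-acid sequences.
#' @return Character vector of DNA inserts (3x peptide length).
#' @export
reverse_translate <- function(peptides) {
  vapply(strsplit(peptides, ""), function(ch) {
    if (!all(ch %in% names(CODON_CHOICE))) {
      stop("peptide contains a residue outside the standard alphabet",
           call. = FALSE)
    }
    paste(CODON_CHOICE[ch], collapse = "")
  }, character(1))
}

#' Simulate selection FASTQ reads with planted motif enrichment
#'
#' Writes one FASTQ file per (bait, replicate): each read is
#' `barcode + adapter_5p + insert + adapter_3p` with constant Phred+33
#' quality `"I"`. Peptides are sampled with replacement with weight 1, or
#' `enrichment_factor` when they match `motif`.
#'
#' @param library Library tibble from [generate_library()].
#' @param design A [selection_design()].
#' @param motif Pattern string or `degenerate_motif` marking enriched
#'   peptides (default `"PxYx[IL]"`).
#' @param outdir Output directory (created if needed).
#' @return List with `manifest` (tibble: file, bait, replicate, barcode) and
#'   `truth` (tibble of sampled peptide counts per replicate).
#' @export
generate_reads <- function(library, design, motif = "PxYx[IL]",
                           outdir = tempfile("reads")) {
  stopifnot(inherits(design, "selection_design"), nrow(library) > 0)
  if (is.character(motif)) motif <- parse_motif(motif)
  expected_nt <- design$insert_length_nt / 3L
  if (any(nchar(library$peptide) != expected_nt)) {
    stop("library peptides must encode exactly insert_length_nt/3 residues",
         call. = FALSE)
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  set.seed(design$seed)

  peptides <- unique(library$peptide)
  inserts <- reverse_translate(peptides)
  is_motif <- motif_matches_any(peptides, motif)
  w <- ifelse(is_motif, design$enrichment_factor, 1)
  if (is.infinite(design$enrichment_factor)) {
    w <- ifelse(is_motif, 1, 0)
    if (!any(is_motif)) stop("enrichment_factor = Inf but no motif-bearing peptide",
                             call. = FALSE)
  }

  manifest <- tidyr::expand_grid(
    design$samples, replicate = seq_len(design$replicates_per_bait))
  manifest$file <- file.path(
    outdir, sprintf("%s_rep%d.fastq", gsub("[^A-Za-z0-9]+", "-", manifest$bait),
                    manifest$replicate))

  truth <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    idx <- sample.int(length(peptides), design$background_depth,
                      replace = TRUE, prob = w)
    reads <- paste0(manifest$barcode[i], design$adapter_5p, inserts[idx],
                    design$adapter_3p)
    write_fastq(reads, manifest$file[i],
                id_prefix = sprintf("%s_r%d", manifest$bait[i],
                                    manifest$replicate[i]))
    tab <- table(peptides[idx])
    truth[[i]] <- tibble::tibble(
      bait = manifest$bait[i], replicate = manifest$replicate[i],
      peptide = names(tab), count = as.integer(tab))
  }
  list(manifest = manifest[, c("file", "bait", "replicate", "barcode")],
       truth = dplyr::bind_rows(truth))
}

write_fastq <- function(reads, path, id_prefix = "read") {
  qual <- strrep("I", nchar(reads))
  lines <- as.vector(rbind(
    sprintf("@%s_%06d", id_prefix, seq_along(reads)),
    reads, "+", qual))
  writeLines(lines, path)
}

# ---- file exports -----------------------------------------------------------

#' Write a synthetic proteome and its annotation tables to disk
#'
#' Produces `proteome.fasta`, `disorder.tsv` (protein_id, position, score),
#' `ptm_sites.tsv` (protein_id, site_position, ptm_type) and `topology.tsv`
#' (protein_id, flag). Coordinates are 1-based.
#'
#' @param proteome A `proppd_proteome`.
#' @param outdir Output directory.
#' @return Invisibly, the named vector of file paths.
#' @export
write_proteome <- function(proteome, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(fasta = file.path(outdir, "proteome.fasta"),
             disorder = file.path(outdir, "disorder.tsv"),
             ptm = file.path(outdir, "ptm_sites.tsv"),
             topology = file.path(outdir, "topology.tsv"))
  seqs <- Biostrings::AAStringSet(vapply(proteome, `[[`, character(1), "seq"))
  names(seqs) <- names(proteome)
  Biostrings::writeXStringSet(seqs, paths["fasta"])

  disorder <- purrr::map_dfr(proteome, function(p) tibble::tibble(
    protein_id = p$id, position = seq_along(p$disorder), score = p$disorder))
  readr::write_tsv(disorder, paths["disorder"])

  ptm <- purrr::map_dfr(proteome, function(p) dplyr::bind_rows(
    tibble::tibble(protein_id = p$id, site_position = p$oglcnac_sites,
                   ptm_type = "OGlcNAc"),
    tibble::tibble(protein_id = p$id, site_position = p$ptyr_sites,
                   ptm_type = "pTyr")))
  readr::write_tsv(ptm, paths["ptm"])

  topo <- purrr::map_dfr(proteome, function(p) tibble::tibble(
    protein_id = p$id, flag = p$topology))
  readr::write_tsv(topo, paths["topology"])
  invisible(paths)
}

#' Read a proteome with annotations back from disk
#'
#' Counterpart of [write_proteome()]; validates that all site and disorder
#' coordinates fall within the FASTA sequence lengths.
#'
#' @param fasta,disorder_tsv,ptm_tsv,topology_tsv File paths; the TSVs may be
#'   `NULL` (missing annotations default to empty / intracellular, disorder
#'   defaults to 1).
#' @return A `proppd_proteome`.
#' @export
read_proteome <- function(fasta, disorder_tsv = NULL, ptm_tsv = NULL,
                          topology_tsv = NULL) {
  seqs <- Biostrings::readAAStringSet(fasta)
  ids <- sub("\\s.*$", "", names(seqs))
  dis <- if (!is.null(disorder_tsv)) {
    readr::read_tsv(disorder_tsv, show_col_types = FALSE)
  }
  ptm <- if (!is.null(ptm_tsv)) readr::read_tsv(ptm_tsv, show_col_types = FALSE)
  topo <- if (!is.null(topology_tsv)) {
    readr::read_tsv(topology_tsv, show_col_types = FALSE)
  }
  proteome <- lapply(seq_along(seqs), function(i) {
    id <- ids[i]
    s <- as.character(seqs[[i]])
    len <- nchar(s)
    d <- rep(1, len)
    if (!is.null(dis)) {
      di <- dis[dis$protein_id == id, ]
      if (nrow(di) > 0) {
        if (any(di$position < 1 | di$position > len)) {
          stop("disorder position out of bounds for ", id, call. = FALSE)
        }
        d <- rep(0, len)
        d[di$position] <- di$score
      }
    }
    og <- pt <- integer(0)
    if (!is.null(ptm)) {
      pi <- ptm[ptm$protein_id == id, ]
      if (any(pi$site_position < 1 | pi$site_position > len)) {
        stop("PTM site position out of bounds for ", id, call. = FALSE)
      }
      og <- sort(pi$site_position[pi$ptm_type == "OGlcNAc"])
      pt <- sort(pi$site_position[pi$ptm_type == "pTyr"])
    }
    flag <- "intracellular"
    if (!is.null(topo)) {
      ti <- topo$flag[topo$protein_id == id]
      if (length(ti) > 0) flag <- ti[1]
    }
    list(id = id, seq = s, disorder = d, topology = flag,
         oglcnac_reported = length(og) > 0,
         oglcnac_sites = as.integer(og), ptyr_sites = as.integer(pt),
         motif_start = NA_integer_)
  })
  names(proteome) <- ids
  structure(proteome, class = "proppd_proteome")
}
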