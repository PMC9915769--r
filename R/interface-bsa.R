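#' Van der Waals radii used for surface calculations
#'
#' A standard element radii table (Angstrom): C 1.70, N 1.55, O 1.52,
#' S 1.80, P 1.80, H 1.20; halogens from the same compilation. Elements not
#' in the table fall back to `default_radius`.
#'
#' @param elements Character vector of element symbols (case-insensitive).
#' @param default_radius Fallback radius in Angstrom (default 1.70).
#' @return Numeric vector of radii.
#' @export
vdw_radius <- function(elements, default_radius = 1.70) {
  table <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
             F = 1.47, CL = 1.75, BR = 1.85, I = 1.98, SE = 1.90)
  r <- table[toupper(elements)]
  r[is.na(r)] <- default_radius
  unname(r)
}

# Deterministic quasi-uniform points on the unit sphere (golden-spiral /
# Fibonacci lattice).
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(x = sin(phi) * cos(theta),
        y = sin(phi) * sin(theta),
        z = cos(phi))
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Samples `n_points` quasi-uniform points on each atom's expanded sphere
#' (radius + probe) and counts the fraction not buried inside any other
#' atom's expanded sphere; the accessible area of atom i is that fraction
#' times `4*pi*(r_i + probe)^2`. The point set is a fixed golden-spiral
#' lattice, so results are deterministic. A point exactly on another
#' expanded sphere (within 1e-9) is claimed by the lower-indexed atom, so
#' exact duplicate atoms contribute a single sphere's area in total.
#' Neighbour candidates come from a spatial cell grid.
#'
#' @param atoms Data frame with numeric columns `x`, `y`, `z`, `radius`
#'   (Angstrom).
#' @param probe_radius Solvent probe radius (default 1.4).
#' @param n_points Sphere sample count per atom (default 960).
#' @return Numeric vector of per-atom accessible areas (Angstrom^2); the sum
#'   is the total SASA.
#' @export
sasa <- function(atoms, probe_radius = 1.4, n_points = 960L) {
  stopifnot(nrow(atoms) >= 1, all(c("x", "y", "z", "radius") %in% names(atoms)))
  if (any(atoms$radius <= 0)) stop("atom radii must be positive", call. = FALSE)
  n <- nrow(atoms)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  er <- atoms$radius + probe_radius            # expanded radii
  pts <- sphere_points(n_points)
  eps <- 1e-9

  neighbors <- neighbor_lists(xyz, er)
  areas <- numeric(n)
  for (i in seq_len(n)) {
    surf <- sweep(pts * er[i], 2, xyz[i, ], `+`)
    exposed <- rep(TRUE, n_points)
    for (j in neighbors[[i]]) {
      if (!any(exposed)) break
      d2 <- (surf[exposed, 1] - xyz[j, 1])^2 +
            (surf[exposed, 2] - xyz[j, 2])^2 +
            (surf[exposed, 3] - xyz[j, 3])^2
      lim <- er[j]^2
      buried <- d2 < lim - eps | (abs(d2 - lim) <= eps & j < i)
      exposed[exposed] <- !buried
    }
    areas[i] <- sum(exposed) / n_points * 4 * pi * er[i]^2
  }
  areas
}

# Cell-grid neighbour search: atoms whose expanded spheres can intersect.
neighbor_lists <- function(xyz, er) {
  n <- nrow(xyz)
  cell <- max(er) * 2
  key <- floor(sweep(xyz, 2, apply(xyz, 2, min)) / cell)
  id <- paste(key[, 1], key[, 2], key[, 3])
  index <- split(seq_len(n), id)
  offsets <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  lapply(seq_len(n), function(i) {
    cand <- unlist(lapply(seq_len(27), function(o) {
      index[[paste(key[i, 1] + offsets[o, 1], key[i, 2] + offsets[o, 2],
                   key[i, 3] + offsets[o, 3])]]
    }), use.names = FALSE)
    cand <- cand[cand != i]
    if (length(cand) == 0) return(integer(0))
    d2 <- (xyz[cand, 1] - xyz[i, 1])^2 + (xyz[cand, 2] - xyz[i, 2])^2 +
          (xyz[cand, 3] - xyz[i, 3])^2
    cand[d2 < (er[cand] + er[i])^2]
  })
}

#' Read a structure file into an atom table
#'
#' Thin wrapper over bio3d's PDB/mmCIF parsers producing the atom table
#' consumed by [sasa()] and [buried_surface_area()]. By default hydrogens,
#' waters and hetero atoms (ligands such as UDP-GlcNAc) are excluded,
#' leaving the protein/peptide chains.
#'
#' @param path Path to a `.pdb` or `.cif` file.
#' @param keep_hetero Keep non-water hetero atoms (default FALSE).
#' @param keep_hydrogens Keep hydrogens (default FALSE).
#' @return Tibble with columns `chain`, `resno`, `resid`, `element`, `x`,
#'   `y`, `z`, `radius`.
#' @export
read_structure <- function(path, keep_hetero = FALSE, keep_hydrogens = FALSE) {
  ext <- tolower(tools::file_ext(path))
  pdb <- if (ext %in% c("cif", "mmcif")) {
    bio3d::read.cif(path)
  } else {
    bio3d::read.pdb(path)
  }
  at <- pdb$atom
  element <- at$elesy
  if (is.null(element) || all(is.na(element)) || all(element == "")) {
    element <- bio3d::atom2ele(pdb)
  }
  keep <- rep(TRUE, nrow(at))
  keep <- keep & !(at$resid %in% c("HOH", "WAT", "DOD"))
  if (!keep_hetero) keep <- keep & at$type == "ATOM"
  if (!keep_hydrogens) keep <- keep & !(toupper(element) %in% c("H", "D"))
  at <- at[keep, ]
  element <- element[keep]
  tibble::tibble(
    chain = at$chain, resno = at$resno, resid = at$resid,
    element = toupper(element),
    x = at$x, y = at$y, z = at$z,
    radius = vdw_radius(element))
}

#' Buried surface area of a binary chain partition
#'
#' Computes SASA for group A alone, group B alone, and the A+B complex, and
#' reports the interface burial `bsa = sasa_A + sasa_B - sasa_AB`. For a
#' peptide bound in a surface groove this is the standard interface-size
#' measure (about 1200 Angstrom^2 is typical of transient peptide-protein
#' interactions).
#'
#' @param structure A structure file path or an atom tibble from
#'   [read_structure()].
#' @param group_a,group_b Character vectors of chain ids for the two sides.
#' @param probe_radius,n_points Passed to [sasa()].
#' @param ... Passed to [read_structure()] when `structure` is a path.
#' @return An `interface_result` list: `sasa_a`, `sasa_b`, `sasa_ab`, `bsa`
#'   (Angstrom^2), plus the chain groups.
#' @export
buried_surface_area <- function(structure, group_a, group_b,
                                probe_radius = 1.4, n_points = 960L, ...) {
  atoms <- if (is.character(structure)) read_structure(structure, ...)
           else tibble::as_tibble(structure)
  available <- unique(atoms$chain)
  missing <- setdiff(c(group_a, group_b), available)
  if (length(missing) > 0) {
    stop("unknown chain id(s): ", paste(missing, collapse = ", "),
         "; available chains: ", paste(available, collapse = ", "),
         call. = FALSE)
  }
  if (length(intersect(group_a, group_b)) > 0) {
    stop("chain groups must be disjoint", call. = FALSE)
  }
  a <- atoms[atoms$chain %in% group_a, ]
  b <- atoms[atoms$chain %in% group_b, ]
  if (nrow(a) == 0 || nrow(b) == 0) {
    stop("both chain groups must contain atoms after filtering", call. = FALSE)
  }
  ab <- rbind(a, b)
  sasa_a <- sum(sasa(a, probe_radius, n_points))
  sasa_b <- sum(sasa(b, probe_radius, n_points))
  sasa_ab <- sum(sasa(ab, probe_radius, n_points))
  structure(list(
    sasa_a = sasa_a, sasa_b = sasa_b, sasa_ab = sasa_ab,
    bsa = sasa_a + sasa_b - sasa_ab,
    group_a = group_a, group_b = group_b,
    probe_radius = probe_radius, n_points = as.integer(n_points)
  ), class = "interface_result")
}

#' @export
print.interface_result <- function(x, ...) {
  cat(sprintf(
    "<interface_result> A(%s): %.1f  B(%s): %.1f  AB: %.1f  BSA: %.1f A^2\n",
    paste(x$group_a, collapse = ","), x$sasa_a,
    paste(x$group_b, collapse = ","), x$sasa_b, x$sasa_ab, x$bsa))
  invisible(x)
}
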