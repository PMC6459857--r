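#' Structure model from a PDB file or atom table
#'
#' `read_structure()` parses a PDB file (via bio3d) into the flat atom
#' tibble the AV and SASA routines work on; `structure_model()` validates an
#' atom table built in code.  Only ATOM/HETATM records are used; alternate
#' locations resolve to the highest occupancy (ties to the first
#' encountered); missing occupancy/B-factor columns are tolerated.
#' Coordinates are Angstrom throughout and residue numbering follows the
#' file.
#'
#' @param path PDB file path.
#' @param atoms Data frame with columns `element`, `resid` (residue index),
#'   `resname`, `chain`, `atom_name`, `x`, `y`, `z` and optionally `radius`.
#' @return A tibble with class `structure_model`; van der Waals radii are
#'   filled from the element when absent.
#' @export
read_structure <- function(path) {
  pdb <- suppressWarnings(bio3d::read.pdb(path, verbose = FALSE,
                                          rm.alt = FALSE))
  a <- pdb$atom
  a <- a[a$type %in% c("ATOM", "HETATM"), , drop = FALSE]
  if (!is.null(a$alt) && any(!is.na(a$alt) & a$alt != "")) {
    occ <- if (!is.null(a$o)) ifelse(is.na(a$o), 1, a$o) else rep(1, nrow(a))
    key <- paste(a$chain, a$resno, a$elety)
    keep <- rep(TRUE, nrow(a))
    for (k in unique(key[duplicated(key)])) {
      idx <- which(key == k)
      best <- idx[which.max(occ[idx])]
      keep[setdiff(idx, best)] <- FALSE
    }
    a <- a[keep, , drop = FALSE]
  }
  elem <- a$elesy
  if (is.null(elem) || all(is.na(elem) | elem == ""))
    elem <- substr(trimws(a$elety), 1, 1)
  structure_model(tibble::tibble(
    element = trimws(elem), resid = a$resno,
    resname = trimws(a$resid), chain = a$chain,
    atom_name = trimws(a$elety),
    x = a$x, y = a$y, z = a$z))
}

#' @rdname read_structure
#' @export
structure_model <- function(atoms) {
  atoms <- tibble::as_tibble(atoms)
  need <- c("element", "resid", "x", "y", "z")
  if (!all(need %in% names(atoms)))
    stop("atom table needs columns: ", paste(need, collapse = ", "))
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("non-finite coordinates")
  if (!"resname" %in% names(atoms)) atoms$resname <- NA_character_
  if (!"chain" %in% names(atoms)) atoms$chain <- "A"
  if (!"atom_name" %in% names(atoms)) atoms$atom_name <- atoms$element
  if (!"radius" %in% names(atoms)) atoms$radius <- NA_real_
  miss_r <- !is.finite(atoms$radius)
  atoms$radius[miss_r] <- vdw_radius(atoms$element[miss_r])
  if (any(!is.finite(atoms$radius) | atoms$radius <= 0))
    stop("radii must be positive")
  structure(atoms, class = c("structure_model", class(atoms)))
}

#' Van der Waals radii by element
#' @param element Character vector of element symbols.
#' @return Radii in Angstrom (1.7 for unknown elements).
#' @export
vdw_radius <- function(element) {
  tab <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
           F = 1.47, CL = 1.75, BR = 1.85, I = 1.98, SE = 1.90)
  r <- tab[toupper(element)]
  r[is.na(r)] <- 1.70
  unname(r)
}

#' Dye and linker parameters for accessible-volume simulation
#'
#' @param linker_length Maximum attachment-to-dye-centre distance, Å.
#' @param linker_width Linker diameter for the path-clearance check, Å.
#' @param dye_radius Dye sphere radius, Å (single-sphere AV1 flavour; pass
#'   three radii to average three AV1 clouds, the three-radius option).
#' @export
dye_params <- function(linker_length = 20, linker_width = 4.5,
                       dye_radius = 3.5) {
  stopifnot(linker_length > 0, linker_width > 0, all(dye_radius > 0),
            length(dye_radius) %in% c(1, 3))
  structure(list(linker_length = linker_length, linker_width = linker_width,
                 dye_radius = dye_radius),
            class = "dye_params")
}

#' Coarse-grained accessible volume of a tethered dye
#'
#' Grid search within the linker length around the attachment atom: a grid
#' point is an allowed dye position when a straight path of the linker
#' width from the attachment is unobstructed (dial-out approximation) and
#' the dye sphere clashes with no atom.  Deterministic for a fixed grid.
#'
#' @param structure A `structure_model`.
#' @param dye A [dye_params].
#' @param attach_chain,attach_resid,attach_atom Attachment atom selector.
#' @param grid_spacing Grid spacing, Å.
#' @return An `av_cloud`: tibble of allowed points (`x`, `y`, `z`,
#'   `weight`), with the attachment point, grid spacing and dye parameters
#'   as attributes.  A fully buried attachment yields an empty, flagged
#'   cloud (with a warning).
#' @export
compute_av <- function(structure, dye, attach_chain, attach_resid,
                       attach_atom = "CB", grid_spacing = 0.9) {
  stopifnot(inherits(dye, "dye_params"), grid_spacing > 0)
  at <- structure[structure$chain == attach_chain &
                    structure$resid == attach_resid &
                    structure$atom_name == attach_atom, , drop = FALSE]
  if (nrow(at) != 1)
    stop(sprintf("attachment atom %s:%s:%s not found (or ambiguous)",
                 attach_chain, attach_resid, attach_atom))
  attach <- c(at$x, at$y, at$z)
  coords <- as.matrix(structure[, c("x", "y", "z")])
  radii <- structure$radius
  clouds <- lapply(dye$dye_radius, function(rd)
    compute_av_cpp(attach, coords, radii, dye$linker_length,
                   dye$linker_width, rd, grid_spacing))
  pts <- do.call(rbind, clouds)
  # three-radius option: each sub-cloud carries equal total weight
  w <- unlist(lapply(clouds, function(cl)
    rep(1 / (length(clouds) * max(nrow(cl), 1)), nrow(cl))))
  out <- tibble::tibble(x = pts[, 1], y = pts[, 2], z = pts[, 3],
                        weight = if (length(w)) w / sum(w) else numeric(0))
  if (!nrow(out))
    warning("attachment is fully buried: empty accessible volume")
  structure(out, attach = attach, grid_spacing = grid_spacing, dye = dye,
            empty = nrow(out) == 0,
            class = c("av_cloud", class(out)))
}

#' @export
print.av_cloud <- function(x, ...) {
  cat(sprintf("<av_cloud> %d allowed dye positions (grid %.2f A)\n",
              nrow(x), attr(x, "grid_spacing")))
  invisible(x)
}

#' Cloud volume implied by the grid
#' @param cloud An `av_cloud`.
#' @return Volume in Å^3 (points x grid cell volume).
#' @export
av_volume <- function(cloud) {
  nrow(cloud) * attr(cloud, "grid_spacing")^3
}

#' FRET-averaged distance between two accessible volumes
#'
#' Averages the Förster efficiency over (weighted) dye-position pairs and
#' converts back to a distance:
#' `<R_DA>_E = R0 * (1/<E> - 1)^(1/6)`; also reports the
#' distance between the mean dye positions, `R_mp`.  Above
#' `max_pairs` point pairs a seeded Monte-Carlo subsample is used.
#'
#' @param av1,av2 `av_cloud` objects (must be nonempty).
#' @param R0 Förster radius, Å.
#' @param max_pairs Pair budget before subsampling.
#' @param seed Seed for the subsample.
#' @return Tibble with `RDA_E`, `R_mp`, `mean_E`, `n_pairs`.
#' @export
mean_fret_distance <- function(av1, av2, R0 = 53.0, max_pairs = 2e6,
                               seed = 1) {
  if (!nrow(av1) || !nrow(av2))
    stop("both accessible volumes must be nonempty")
  n1 <- nrow(av1); n2 <- nrow(av2)
  p1 <- as.matrix(av1[, c("x", "y", "z")])
  p2 <- as.matrix(av2[, c("x", "y", "z")])
  w1 <- av1$weight / sum(av1$weight)
  w2 <- av2$weight / sum(av2$weight)
  npairs <- as.double(n1) * n2
  if (npairs <= max_pairs) {
    d2 <- outer(rowSums(p1^2), rowSums(p2^2), "+") - 2 * p1 %*% t(p2)
    d <- sqrt(pmax(d2, 0))
    E <- 1 / (1 + (d / R0)^6)
    W <- outer(w1, w2)
    mean_E <- sum(W * E)
    n_used <- npairs
  } else {
    set.seed(as.integer(seed))
    n_used <- max_pairs
    i1 <- sample.int(n1, n_used, replace = TRUE, prob = w1)
    i2 <- sample.int(n2, n_used, replace = TRUE, prob = w2)
    d <- sqrt(rowSums((p1[i1, , drop = FALSE] - p2[i2, , drop = FALSE])^2))
    mean_E <- mean(1 / (1 + (d / R0)^6))
  }
  mp1 <- colSums(p1 * w1); mp2 <- colSums(p2 * w2)
  tibble::tibble(
    RDA_E = R0 * (1 / mean_E - 1)^(1 / 6),
    R_mp = sqrt(sum((mp1 - mp2)^2)),
    mean_E = mean_E, n_pairs = n_used)
}

# Tien et al. theoretical Gly-X-Gly maximum accessible surface areas (A^2)
.SASA_REF <- c(
  ALA = 129.0, ARG = 274.0, ASN = 195.0, ASP = 193.0, CYS = 167.0,
  GLN = 225.0, GLU = 223.0, GLY = 104.0, HIS = 224.0, ILE = 197.0,
  LEU = 201.0, LYS = 236.0, MET = 224.0, PHE = 240.0, PRO = 159.0,
  SER = 155.0, THR = 172.0, TRP = 285.0, TYR = 263.0, VAL = 174.0)

#' Shrake-Rupley solvent-accessible surface area
#'
#' `sasa_atoms()` returns the per-atom solvent-accessible area of the whole
#' structure (1.4 Å probe, golden-spiral test points);
#' `relative_sasa()` normalises the summed area of one residue by its
#' extended Gly-X-Gly tripeptide reference area and reports percent.
#'
#' @param structure A `structure_model`.
#' @param probe Probe radius, Å.
#' @param n_points Sphere test points per atom.
#' @return `sasa_atoms()`: the structure with an `sasa` column.
#' @export
sasa_atoms <- function(structure, probe = 1.4, n_points = 480) {
  coords <- as.matrix(structure[, c("x", "y", "z")])
  structure$sasa <- as.numeric(
    sasa_cpp(coords, structure$radius, probe, as.integer(n_points)))
  structure
}

#' @rdname sasa_atoms
#' @param chain,resid Residue selector.
#' @param reference `"tripeptide"` normalises by the tabulated extended
#'   Gly-X-Gly maximum area (the convention for reporting buried-interface
#'   percentages); `"isolated"` normalises by the area of the residue's own
#'   atoms computed in isolation, so a free residue reads exactly 100%.
#' @return `relative_sasa()`: tibble with `sasa_A2`, `reference_A2`,
#'   `rel_sasa_percent` and a `flagged` note when atoms are missing or the
#'   residue type has no reference area.
#' @export
relative_sasa <- function(structure, chain, resid, probe = 1.4,
                          n_points = 480,
                          reference = c("tripeptide", "isolated")) {
  reference <- match.arg(reference)
  sel <- structure$chain == chain & structure$resid == resid
  if (!any(sel)) stop("residue not found")
  withsasa <- sasa_atoms(structure, probe = probe, n_points = n_points)
  area <- sum(withsasa$sasa[sel & withsasa$element != "H"])
  resname <- unique(structure$resname[sel])[1]
  ref <- if (reference == "tripeptide") {
    .SASA_REF[toupper(resname)]
  } else {
    iso <- sasa_atoms(structure[sel, , drop = FALSE], probe = probe,
                      n_points = n_points)
    c(sum(iso$sasa[iso$element != "H"]))
  }
  heavy_expected <- c(ALA = 5, ARG = 11, ASN = 8, ASP = 8, CYS = 6,
                      GLN = 9, GLU = 9, GLY = 4, HIS = 10, ILE = 8,
                      LEU = 8, LYS = 9, MET = 8, PHE = 11, PRO = 7,
                      SER = 6, THR = 7, TRP = 14, TYR = 12,
                      VAL = 7)[toupper(resname)]
  n_heavy <- sum(sel & structure$element != "H")
  flagged <- NA_character_
  if (is.na(ref)) flagged <- "no reference area for residue type"
  else if (!is.na(heavy_expected) && n_heavy < heavy_expected)
    flagged <- sprintf("missing atoms: %d of %d heavy atoms present",
                       n_heavy, heavy_expected)
  ref <- unname(ref)
  tibble::tibble(
    chain = chain, resid = resid, resname = resname,
    sasa_A2 = unname(area), reference_A2 = ref,
    rel_sasa_percent = if (is.na(ref)) NA_real_ else 100 * area / ref,
    flagged = flagged)
}
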