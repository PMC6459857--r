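test_that("free-space accessible volume is a ball of the linker length", {
  stru <- structure_model(tibble::tibble(
    element = "C", resid = 1, resname = "CYS", chain = "A",
    atom_name = "CB", x = 0, y = 0, z = 0))
  dye <- dye_params(linker_length = 12, linker_width = 4.5,
                    dye_radius = 3.5)
  av <- compute_av(stru, dye, "A", 1, "CB", grid_spacing = 0.6)
  analytic <- 4 / 3 * pi * 12^3
  expect_lt(abs(av_volume(av) - analytic) / analytic, 0.05)
  # every allowed point is within the linker length of the attachment
  d <- sqrt(av$x^2 + av$y^2 + av$z^2)
  expect_true(all(d <= 12 + 1e-9))
})

test_that("a plane of atoms carves the cloud to the analytic cap region", {
  plane <- expand.grid(x = seq(-20, 20, 1.2), y = seq(-20, 20, 1.2))
  stru <- structure_model(tibble::tibble(
    element = "C", resid = c(1, rep(2, nrow(plane))), resname = "CYS",
    chain = "A", atom_name = c("CB", rep("X", nrow(plane))),
    x = c(0, plane$x), y = c(0, plane$y), z = c(0, rep(-3.5, nrow(plane)))))
  # narrow linker width so the dye-sphere clash is the only constraint and
  # the allowed region is exactly ball(L) intersect {z >= z0}
  dye <- dye_params(linker_length = 12, linker_width = 0.2,
                    dye_radius = 3.5)
  av <- compute_av(stru, dye, "A", 1, "CB", grid_spacing = 0.5)
  L <- 12
  z0 <- (1.7 + 3.5) - 3.5       # clash clearance minus plane depth
  expect_gte(min(av$z), z0 - 0.5)
  num <- integrate(function(z) z * pi * (L^2 - z^2), z0, L)$value
  den <- integrate(function(z) pi * (L^2 - z^2), z0, L)$value
  expect_lt(abs(mean(av$z) - num / den), 0.3)
  expect_lt(abs(av_volume(av) - den) / den, 0.05)
  # adding obstructions can only shrink the volume
  free <- compute_av(structure_model(stru[1, ]), dye, "A", 1, "CB",
                     grid_spacing = 0.5)
  expect_lt(av_volume(av), av_volume(free))
})

test_that("grid refinement converges the mean dye position", {
  set.seed(12)
  blockers <- tibble::tibble(
    element = "C", resid = 2, resname = "ALA", chain = "A", atom_name = "X",
    x = rnorm(25, 4, 2), y = rnorm(25, -3, 2), z = rnorm(25, 0, 3))
  stru <- structure_model(dplyr::bind_rows(
    tibble::tibble(element = "C", resid = 1, resname = "CYS", chain = "A",
                   atom_name = "CB", x = 0, y = 0, z = 0), blockers))
  dye <- dye_params(linker_length = 10)
  av1 <- compute_av(stru, dye, "A", 1, "CB", grid_spacing = 1.0)
  av2 <- compute_av(stru, dye, "A", 1, "CB", grid_spacing = 0.5)
  m1 <- colMeans(as.matrix(av1[, c("x", "y", "z")]))
  m2 <- colMeans(as.matrix(av2[, c("x", "y", "z")]))
  expect_lt(sqrt(sum((m1 - m2)^2)), 0.5)
})

test_that("buried attachments yield an empty, flagged cloud", {
  # dense lattice cage engulfing the attachment
  shell <- expand.grid(x = seq(-4, 4, 1.4), y = seq(-4, 4, 1.4),
                       z = seq(-4, 4, 1.4))
  stru <- structure_model(dplyr::bind_rows(
    tibble::tibble(element = "C", resid = 1, resname = "CYS", chain = "A",
                   atom_name = "CB", x = 0, y = 0, z = 0),
    tibble::tibble(element = "C", resid = 2, resname = "ALA", chain = "A",
                   atom_name = "X", x = shell$x, y = shell$y, z = shell$z)))
  expect_warning(
    av <- compute_av(stru, dye_params(linker_length = 8), "A", 1, "CB"),
    "buried")
  expect_equal(nrow(av), 0)
  expect_error(compute_av(stru, dye_params(), "A", 99, "CB"), "not found")
})

test_that("mean FRET distance matches point clouds and brute force", {
  pt <- function(x) structure(
    tibble::tibble(x = x, y = 0, z = 0, weight = 1),
    class = c("av_cloud", "tbl_df", "tbl", "data.frame"),
    grid_spacing = 1, attach = c(x, 0, 0))
  # two single-point clouds at distance d: RDA_E = R_mp = d exactly
  mf <- mean_fret_distance(pt(0), pt(47), R0 = 53)
  expect_equal(mf$RDA_E, 47, tolerance = 1e-9)
  expect_equal(mf$R_mp, 47, tolerance = 1e-12)

  mkball <- function(cx, spacing = 0.7, r = 3.5) {
    g <- expand.grid(x = seq(-r, r, spacing), y = seq(-r, r, spacing),
                     z = seq(-r, r, spacing))
    g <- g[g$x^2 + g$y^2 + g$z^2 <= r^2, ]
    structure(tibble::tibble(x = g$x + cx, y = g$y, z = g$z,
                             weight = rep(1 / nrow(g), nrow(g))),
              class = c("av_cloud", "tbl_df", "tbl", "data.frame"),
              grid_spacing = spacing, attach = c(cx, 0, 0))
  }
  c1 <- mkball(0); c2 <- mkball(45)
  mf2 <- mean_fret_distance(c1, c2, 53)
  # brute force over all pairs, written independently
  p1 <- as.matrix(c1[, 1:3]); p2 <- as.matrix(c2[, 1:3])
  dd <- sqrt(outer(rowSums(p1^2), rowSums(p2^2), "+") - 2 * p1 %*% t(p2))
  Ebar <- mean(1 / (1 + (dd / 53)^6))
  expect_lt(abs(mf2$RDA_E - 53 * (1 / Ebar - 1)^(1 / 6)), 1)
  # identical overlapping clouds: sane bounds
  mfo <- mean_fret_distance(c1, mkball(0), 53)
  expect_gt(mfo$RDA_E, 0)
  expect_lt(mfo$RDA_E, mfo$R_mp + 2 * 3.5)   # within the cloud diameter

  # rigid rotation + translation leaves RDA_E invariant
  th <- 0.7; Rm <- matrix(c(cos(th), -sin(th), 0,
                            sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  rot <- function(cl) {
    p <- as.matrix(cl[, 1:3]) %*% Rm + matrix(c(5, -2, 8), nrow(cl), 3,
                                              byrow = TRUE)
    structure(tibble::tibble(x = p[, 1], y = p[, 2], z = p[, 3],
                             weight = cl$weight),
              class = class(cl), grid_spacing = attr(cl, "grid_spacing"),
              attach = c(0, 0, 0))
  }
  mf3 <- mean_fret_distance(rot(c1), rot(c2), 53)
  expect_equal(mf3$RDA_E, mf2$RDA_E, tolerance = 1e-9)
  expect_error(mean_fret_distance(c1[0, ], c2), "nonempty")
})

test_that("Shrake-Rupley SASA normalisation and burial behave correctly", {
  ala <- structure_model(tibble::tibble(
    element = c("N", "C", "C", "O", "C"), resid = 10, resname = "ALA",
    chain = "A", atom_name = c("N", "CA", "C", "O", "CB"),
    x = c(0, 1.45, 2.2, 1.7, 2.0), y = c(0, 0, 1.2, 2.3, -1.3),
    z = c(0, 0, 0, 0, 0.4)))
  # isolated residue: exactly its own reference area
  expect_equal(relative_sasa(ala, "A", 10,
                             reference = "isolated")$rel_sasa_percent, 100)
  # fully enclosed by a shell of atoms: zero accessibility
  sph <- expand.grid(x = seq(-8, 8, 0.9), y = seq(-8, 8, 0.9),
                     z = seq(-8, 8, 0.9))
  rr <- sqrt(sph$x^2 + sph$y^2 + sph$z^2)
  sph <- sph[rr > 5 & rr < 7.9, ]
  caged <- structure_model(dplyr::bind_rows(
    dplyr::mutate(tibble::as_tibble(ala), x = x - 1.2),
    tibble::tibble(element = "C", resid = 99, resname = "XXX", chain = "A",
                   atom_name = "X", x = sph$x, y = sph$y, z = sph$z)))
  burial <- relative_sasa(caged, "A", 10)
  expect_equal(burial$rel_sasa_percent, 0)
})

test_that("SASA is additive over distant chains", {
  mk <- function(chain, dx) tibble::tibble(
    element = c("N", "C", "C", "O", "C"), resid = 1, resname = "ALA",
    chain = chain, atom_name = c("N", "CA", "C", "O", "CB"),
    x = c(0, 1.45, 2.2, 1.7, 2.0) + dx, y = c(0, 0, 1.2, 2.3, -1.3),
    z = c(0, 0, 0, 0, 0.4))
  both <- structure_model(dplyr::bind_rows(mk("A", 0), mk("B", 500)))
  alone <- structure_model(mk("A", 0))
  sb <- sasa_atoms(both); sa <- sasa_atoms(alone)
  expect_equal(sum(sb$sasa[sb$chain == "A"]), sum(sa$sasa),
               tolerance = 1e-6)
  expect_equal(sum(sb$sasa[sb$chain == "B"]), sum(sa$sasa),
               tolerance = 1e-6)
})

test_that("buried-interface tyrosine SASA converges with point density", {
  # synthetic two-wall clamp around a tyrosine-sized side chain
  set.seed(5)
  ring <- tibble::tibble(
    element = "C", resid = 50, resname = "TYR", chain = "A",
    atom_name = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ", "OH"),
    x = c(0, 0.8, 1.6, 0.4, 2.4, 1.2, 2.0, 2.8),
    y = c(0, 1.2, 1.9, 2.0, 2.9, 3.0, 3.7, 4.7),
    z = 0)
  ring$element <- c(rep("C", 7), "O")
  wall <- expand.grid(x = seq(-3, 6, 1.5), y = seq(-2, 7, 1.5))
  clamp <- structure_model(dplyr::bind_rows(
    ring,
    tibble::tibble(element = "C", resid = 98, resname = "XXX", chain = "B",
                   atom_name = "X", x = wall$x, y = wall$y, z = 4.2),
    tibble::tibble(element = "C", resid = 99, resname = "XXX", chain = "C",
                   atom_name = "X", x = wall$x, y = wall$y, z = -4.2)))
  lo <- relative_sasa(clamp, "A", 50, n_points = 480)
  hi <- relative_sasa(clamp, "A", 50, n_points = 960)
  expect_lt(abs(lo$rel_sasa_percent - hi$rel_sasa_percent), 1)
  expect_lt(lo$rel_sasa_percent, 60)   # clamped: well below free exposure
})

test_that("PDB text parses into the atom table the AV/SASA routines use", {
  pdb <- c(
    "ATOM      1  N   ALA A  10       0.000   0.000   0.000  1.00 10.00           N",
    "ATOM      2  CA  ALA A  10       1.450   0.000   0.000  1.00 10.00           C",
    "ATOM      3  CB AALA A  10       2.000  -1.300   0.400  0.40 10.00           C",
    "ATOM      4  CB BALA A  10       2.100  -1.200   0.300  0.60 10.00           C",
    "END")
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(pdb, f)
  stru <- read_structure(f)
  expect_equal(nrow(stru), 3)            # altloc resolved to highest occupancy
  cb <- stru[stru$atom_name == "CB", ]
  expect_equal(cb$x, 2.1)
  expect_true(all(stru$radius > 0))
  av <- compute_av(stru, dye_params(linker_length = 8), "A", 10, "CB",
                   grid_spacing = 0.8)
  expect_gt(nrow(av), 100)
})
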