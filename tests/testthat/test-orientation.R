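test_that("helix axis recovers known directions with sign convention", {
  z_beads <- cbind(0, 0, seq(-1, 1, length.out = 8))
  ax <- helix_axis(z_beads)
  expect_equal(ax$direction, c(0, 0, 1), tolerance = 1e-9)
  expect_equal(ax$origin, c(0, 0, 0), tolerance = 1e-12)
  expect_equal(ax$axial_extent, c(-1, 1), tolerance = 1e-9)
  # equivariance under a known rotation
  th <- 0.5
  rot <- matrix(c(1, 0, 0,
                  0, cos(th), -sin(th),
                  0, sin(th), cos(th)), 3, byrow = TRUE)
  ax2 <- helix_axis(z_beads %*% t(rot))
  expect_equal(abs(sum(ax2$direction * (rot %*% c(0, 0, 1)))), 1,
               tolerance = 1e-9)
  # toy dimer is built along z
  s <- make_solute("helix_dimer", n_residues = 14)
  ax3 <- helix_axis(s$coords[s$role == "main_chain", ])
  expect_equal(abs(ax3$direction[3]), 1, tolerance = 1e-6)
  expect_error(helix_axis(diag(3) * 0), "degenerate")
})

test_that("cylindrical distribution is flat for uniform solvent", {
  # long dimer: the principal axis is the strand direction
  s <- make_solute("helix_dimer", n_residues = 14)
  sys <- prescribed_traj(list(cosolvent = NULL), c(cosolvent = 6),
                         box = c(5, 5, 5), n_frames = 150L, seed = 51L,
                         solute = s)
  tr <- sys$trajectory
  top <- tr$topology
  prof <- cylindrical_distribution(tr, which(top$role == "main_chain"),
                                   species_idx(tr, "cosolvent"),
                                   bin_width = 0.2, z_max = 2,
                                   bulk_density = 6)
  mid <- (prof$bin_edges[-1] + prof$bin_edges[-length(prof$bin_edges)]) / 2
  slab <- diff(prof$axis$axial_extent)
  counts_exp <- 6 * 2 * pi * mid * 0.2 * slab * prof$n_frames
  se <- sqrt(counts_exp) / counts_exp
  expect_true(all(abs(prof$g - 1) <= 3 * se + 0.05))
})

test_that("a prescribed cylindrical shell enhancement is recovered", {
  prof_target <- piecewise_profile(c(0, 0.8, 1.2), c(1, 3))
  s <- make_solute("helix_dimer", n_residues = 14)
  sys <- prescribed_traj(list(cosolvent = prof_target), c(cosolvent = 5),
                         box = c(5, 5, 5), n_frames = 200L, seed = 52L,
                         solute = s, mode = "cylindrical")
  tr <- sys$trajectory
  top <- tr$topology
  prof <- cylindrical_distribution(tr, which(top$role == "main_chain"),
                                   species_idx(tr, "cosolvent"),
                                   bin_width = 0.2, z_max = 2,
                                   bulk_density = 5)
  mid <- (prof$bin_edges[-1] + prof$bin_edges[-length(prof$bin_edges)]) / 2
  target <- profile_eval(prof_target, mid)
  slab <- diff(prof$axis$axial_extent)
  counts_exp <- 5 * target * 2 * pi * mid * 0.2 * slab * prof$n_frames
  se <- target * sqrt(counts_exp) / counts_exp
  expect_true(all(abs(prof$g - target) <= 3 * se + 0.1))
})

test_that("centroid radial distribution is flat for uniform solvent and rotation-invariant", {
  s <- make_solute("coil_monomer", n_residues = 6, seed = 3)
  sys <- prescribed_traj(list(cosolvent = NULL), c(cosolvent = 6),
                         box = c(5, 5, 5), n_frames = 100L, seed = 53L,
                         solute = s)
  tr <- sys$trajectory
  prot <- species_idx(tr, "protein")
  targ <- species_idx(tr, "cosolvent")
  prof <- centroid_radial_distribution(tr, prot, targ, bin_width = 0.2,
                                       r_max = 2, bulk_density = 6)
  mid <- (prof$bin_edges[-1] + prof$bin_edges[-length(prof$bin_edges)]) / 2
  counts_exp <- 6 * prof$shell_volumes * prof$n_frames
  se <- sqrt(counts_exp) / counts_exp
  expect_true(all(abs(prof$g - 1) <= 3 * se + 0.05))
  # 90-degree rotation about the box centre leaves the histogram unchanged
  rot <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, byrow = TRUE)
  coords <- tr$coords
  for (f in seq_len(n_frames(tr)))
    coords[, , f] <- sweep(sweep(coords[, , f], 2, c(2.5, 2.5, 2.5)) %*%
                             t(rot), 2, c(2.5, 2.5, 2.5), "+")
  tr2 <- kb_trajectory(tr$topology, coords, tr$box)
  prof2 <- centroid_radial_distribution(tr2, prot, targ, bin_width = 0.2,
                                        r_max = 2, bulk_density = 6)
  expect_equal(prof2$g, prof$g, tolerance = 1e-9)
})

test_that("orientation histograms are normalized and recover known laws", {
  s <- make_solute("coil_monomer", n_residues = 4, seed = 7)
  box <- c(5, 5, 5)
  run_hist <- function(law, seed, frames = 60L) {
    sys <- place_solvent_oriented(law, density = 4, box = box,
                                  n_frames = frames, seed = seed,
                                  solute = s)
    tr <- sys$trajectory
    top <- tr$topology
    orientation_histogram(tr, which(top$name == "C1"),
                          which(top$name == "O"),
                          reference = "centroid",
                          solute_atoms = which(top$species == "protein"),
                          distance_breaks = seq(0, 2, 0.5),
                          n_costheta_bins = 10L)
  }
  # isotropic: P flat at 0.5 within 3 SE per cell
  iso <- run_hist(NULL, 61L)
  dct <- diff(iso$cos_breaks)[1]
  for (d in which(iso$n > 500)) {
    p_exp <- dct / 2           # uniform over [-1, 1]
    se <- sqrt(iso$n[d] * p_exp * (1 - p_exp)) / (iso$n[d] * dct)
    expect_true(all(abs(iso$P[d, ] - 0.5) <= 3 * se + 0.02))
    expect_equal(sum(iso$P[d, ] * dct), 1, tolerance = 1e-9)
  }
  # degenerate inward law: all mass in the lowest cos-theta bin
  inward <- run_hist(orientation_point(-1), 62L, frames = 10L)
  for (d in which(inward$n > 0)) {
    expect_equal(inward$counts[d, 1], inward$n[d])
    expect_equal(sum(inward$P[d, ] * dct), 1, tolerance = 1e-9)
  }
  # linear law p(x) = (1 - x)/2, recovered per shell
  lin <- run_hist(orientation_density(function(x) (1 - x) / 2), 63L,
                  frames = 80L)
  mids <- (lin$cos_breaks[-1] + lin$cos_breaks[-11]) / 2
  p_target <- (1 - mids) / 2
  for (d in which(lin$n > 2000)) {
    p_cell <- p_target * dct
    se <- sqrt(lin$n[d] * p_cell * (1 - p_cell)) / (lin$n[d] * dct)
    expect_true(all(abs(lin$P[d, ] - p_target) <= 3 * se + 0.02))
  }
})

test_that("shell-restricted inward bias is recovered where prescribed", {
  s <- make_solute("helix_dimer", n_residues = 6)
  law <- orientation_shells(c(0, 0.75, 1.65),
                            list(orientation_point(1),
                                 orientation_density(function(x)
                                   (1 - x) / 2)))
  sys <- place_solvent_oriented(law, density = 4, box = c(5, 5, 5),
                                n_frames = 60L, seed = 64L, solute = s)
  tr <- sys$trajectory
  top <- tr$topology
  oh <- orientation_histogram(tr, which(top$name == "C1"),
                              which(top$name == "O"),
                              reference = "centroid",
                              solute_atoms = which(top$species ==
                                                   "protein"),
                              distance_breaks = c(0, 0.75, 1.65, 2.4),
                              n_costheta_bins = 10L)
  # inner shell: tails point at the protein (cos theta = +1)
  expect_gt(oh$mean_costheta[1], 0.9)
  # solvation shell: heads inward on average (E[cos] = -1/3 for (1-x)/2)
  expect_equal(oh$mean_costheta[2], -1 / 3,
               tolerance = 4 * oh$sd_costheta[2] / sqrt(oh$n[2]) + 0.02)
  # beyond the last prescribed shell: isotropic
  expect_lt(abs(oh$mean_costheta[3]),
            4 * oh$sd_costheta[3] / sqrt(oh$n[3]) + 0.02)
})

test_that("the reverse-micelle detector fires only on inward bias", {
  s <- make_solute("coil_monomer", n_residues = 4, seed = 8)
  mk <- function(law, seed) {
    sys <- place_solvent_oriented(law, density = 4, box = c(5, 5, 5),
                                  n_frames = 50L, seed = seed, solute = s)
    tr <- sys$trajectory
    top <- tr$topology
    oh <- orientation_histogram(tr, which(top$name == "C1"),
                                which(top$name == "O"),
                                reference = "centroid",
                                solute_atoms = which(top$species ==
                                                     "protein"),
                                distance_breaks = seq(0, 2, 0.5),
                                n_costheta_bins = 10L)
    reverse_micelle_test(oh)
  }
  biased <- mk(orientation_density(function(x) (1 - x) / 2), 71L)
  iso <- mk(NULL, 72L)
  expect_true(any(biased$inward[biased$n > 500]))
  expect_false(any(iso$inward[iso$n > 500]))
})

test_that("orientation histograms serialize to a TSV matrix", {
  s <- make_solute("coil_monomer", n_residues = 4, seed = 9)
  sys <- place_solvent_oriented(NULL, density = 3, box = c(5, 5, 5),
                                n_frames = 5L, seed = 73L, solute = s)
  tr <- sys$trajectory
  top <- tr$topology
  oh <- orientation_histogram(tr, which(top$name == "C1"),
                              which(top$name == "O"),
                              reference = "centroid",
                              solute_atoms = which(top$species ==
                                                   "protein"),
                              distance_breaks = seq(0, 2, 0.5),
                              n_costheta_bins = 8L)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_orientation_tsv(oh, path)
  m <- as.matrix(read.table(path, sep = "\t", comment.char = "#"))
  expect_equal(dim(m), dim(oh$P))
})
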