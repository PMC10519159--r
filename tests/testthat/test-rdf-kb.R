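test_that("a single fixed pair lands in exactly one bin", {
  top <- toy_topology(1L)
  coords <- array(c(1, 1.7, 1, 1, 1, 1), dim = c(2, 3, 1))
  # atoms at (1,1,1) and (1.7,1,1): distance 0.7 nm
  coords[, , 1] <- rbind(c(1, 1, 1), c(1.7, 1, 1))
  traj <- kb_trajectory(top, coords, c(5, 5, 5))
  p <- rdf_atomset(traj, 1L, 2L, bin_width = 0.1, r_max = 2)
  hits <- which(p$g > 0)
  expect_length(hits, 1L)
  expect_true(p$bin_edges[hits] <= 0.7 && 0.7 < p$bin_edges[hits + 1L])
})

test_that("rdf input contracts are enforced", {
  traj <- ideal_gas_traj(50L, 2L)
  expect_error(rdf_atomset(traj, 1L, 2:51, r_max = 3.0), "half-box")
  expect_error(rdf_atomset(traj, integer(0), 2:51, r_max = 2), "empty")
  expect_error(rdf_atomset(traj, 1:2, 2:51, r_max = 2), "disjoint")
})

test_that("uniform g gives a zero KB integral on the whole grid", {
  p <- radial_profile_from_function(function(r) rep(1, length(r)),
                                    bin_width = 0.01, r_max = 2)
  kb <- kb_running_integral(p, "helix_dimer")
  expect_true(all(abs(kb$G_of_R) < 1e-12))
})

test_that("hard-core quadrature hits the analytic value; coil doubles it", {
  p <- radial_profile_from_function(piecewise_profile(c(0, 0.5), 0),
                                    bin_width = 0.002, r_max = 2.5)
  kb_h <- plateau_estimate(kb_running_integral(p, "helix_dimer"))
  expect_equal(kb_h$G_infinity, -(4 / 3) * pi * 0.5^3, tolerance = 1e-3)
  expect_lt(abs(kb_h$G_infinity - (-0.5236)), 1e-3)
  kb_c <- plateau_estimate(kb_running_integral(p, "coil_monomer"))
  expect_equal(kb_c$G_infinity, 2 * kb_h$G_infinity, tolerance = 1e-12)
  expect_lt(abs(kb_c$G_infinity - (-1.0472)), 2e-3)
})

test_that("multiplicity is exactly linear in the integrand", {
  p <- radial_profile_from_function(piecewise_profile(c(0, 0.3, 1), c(0, 2)),
                                    bin_width = 0.01, r_max = 2)
  g1 <- kb_running_integral(p, "helix_dimer")$G_of_R
  g2 <- kb_running_integral(p, "coil_monomer")$G_of_R
  expect_equal(g2, 2 * g1, tolerance = 1e-14)
})

test_that("prescribed step profile is recovered within 3 SE end to end", {
  prof <- piecewise_profile(c(0, 1), 2)
  sys <- prescribed_traj(list(cosolvent = prof), c(cosolvent = 5),
                         box = c(5, 5, 5), n_frames = 150L, seed = 21L)
  tr <- sys$trajectory
  p <- rdf_atomset(tr, species_idx(tr, "protein"),
                   species_idx(tr, "cosolvent"), bin_width = 0.05,
                   r_max = 2, bulk_density = 5)
  mid <- (p$bin_edges[-1] + p$bin_edges[-length(p$bin_edges)]) / 2
  inside <- mid < 1
  counts_exp <- 5 * 2 * p$shell_volumes[inside] * p$n_frames
  se <- 2 * sqrt(counts_exp) / counts_exp
  expect_true(all(abs(p$g[inside] - 2) <= 3 * se))
  # and the plateau KB integral agrees with the stored analytic value
  kb <- plateau_estimate(kb_running_integral(p, "helix_dimer"))
  blocks <- vapply(1:5, function(b) {
    pb <- p
    pb$g <- kbsolv:::.block_g(p, ((b - 1) * 30 + 1):(b * 30))
    plateau_estimate(kb_running_integral(pb, "helix_dimer"))$G_infinity
  }, numeric(1))
  se_G <- block_se(sd(blocks))
  expect_lt(abs(kb$G_infinity - sys$truth$analytic_G[["cosolvent"]]),
            3 * se_G + 0.02)
})

test_that("plateau estimation handles constant, analytic and noisy tails", {
  # exactly constant tail
  p <- radial_profile_from_function(piecewise_profile(c(0, 0.5), 0),
                                    bin_width = 0.01, r_max = 2)
  kb <- plateau_estimate(kb_running_integral(p, "helix_dimer"))
  expect_equal(kb$max_abs_slope, 0, tolerance = 1e-10)
  expect_true(kb$converged)
  # iid noise on the tail: plateau mean within 3 sd/sqrt(n)
  set.seed(8)
  kb2 <- kb_running_integral(p, "helix_dimer")
  truth <- kb2$G_of_R[length(kb2$G_of_R)]
  noise <- rnorm(length(kb2$G_of_R), 0, 0.01)
  kb2$G_of_R <- kb2$G_of_R + noise
  est <- plateau_estimate(kb2, slope_threshold = 1e9)
  n_win <- sum(kb2$R_grid >= est$plateau_R)
  expect_lt(abs(est$G_infinity - truth), 3 * 0.01 / sqrt(n_win) + 0.01)
  # drifting tail is flagged
  kb3 <- kb_running_integral(p, "helix_dimer")
  kb3$G_of_R <- kb3$G_of_R + seq(0, 1, length.out = length(kb3$G_of_R))
  expect_false(plateau_estimate(kb3)$converged)
})

test_that("constant extrapolation freezes G beyond the trust radius", {
  p <- radial_profile_from_function(function(r) 1 + 0.5 * exp(-r),
                                    bin_width = 0.01, r_max = 3)
  kb <- kb_running_integral(p, "coil_monomer")
  est <- plateau_estimate(kb, trust_radius = 2.0)
  expect_equal(est$extrapolated_from, 2.0, tolerance = 1e-9)
  beyond <- est$R_grid > 2.0
  expect_true(all(abs(diff(est$G_of_R[beyond])) < 1e-14))
  i_tr <- max(which(est$R_grid <= 2.0))
  expect_equal(unique(est$G_of_R[beyond]), est$G_of_R[i_tr])
})

test_that("G(R) is invariant under rigid translation and frame relabeling", {
  sys <- prescribed_traj(list(cosolvent = piecewise_profile(c(0, 0.8), 2)),
                         c(cosolvent = 5), box = c(5, 5, 5),
                         n_frames = 20L, seed = 13L)
  tr <- sys$trajectory
  g0 <- rdf_atomset(tr, 1L, species_idx(tr, "cosolvent"),
                    bin_width = 0.05, r_max = 2, bulk_density = 5)
  # translate everything (with wrapping) by an arbitrary vector
  shift <- c(1.23, -0.71, 2.02)
  coords <- tr$coords
  for (f in seq_len(n_frames(tr)))
    coords[, , f] <- sweep(coords[, , f], 2, shift, "+") %% 5
  tr2 <- kb_trajectory(tr$topology, coords, tr$box)
  g1 <- rdf_atomset(tr2, 1L, species_idx(tr2, "cosolvent"),
                    bin_width = 0.05, r_max = 2, bulk_density = 5)
  expect_equal(g1$g, g0$g, tolerance = 1e-9)
  # relabel frames
  tr3 <- kb_trajectory(tr$topology,
                       tr$coords[, , rev(seq_len(n_frames(tr)))], tr$box)
  g2 <- rdf_atomset(tr3, 1L, species_idx(tr3, "cosolvent"),
                    bin_width = 0.05, r_max = 2, bulk_density = 5)
  expect_equal(g2$g, g0$g, tolerance = 1e-12)
  kb0 <- kb_running_integral(g0)$G_of_R
  kb1 <- kb_running_integral(g1)$G_of_R
  expect_equal(kb1, kb0, tolerance = 1e-9)
})

test_that("profile and KB serialization writes readable TSV", {
  p <- radial_profile_from_function(piecewise_profile(c(0, 0.5), 0),
                                    bin_width = 0.01, r_max = 1)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_profile_tsv(p, path)
  tab <- read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  expect_equal(nrow(tab), length(p$g))
  kb <- plateau_estimate(kb_running_integral(p, "helix_dimer"))
  write_profile_tsv(kb, path)
  tab2 <- read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  expect_equal(tab2$G_nm3, kb$G_of_R, tolerance = 1e-9)
})
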