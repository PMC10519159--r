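test_that("piecewise profiles have the stated closed-form KB integrals", {
  expect_equal(profile_G(piecewise_profile(c(0, 1), 2)), 4 * pi / 3,
               tolerance = 1e-12)
  expect_equal(profile_G(piecewise_profile(c(0, 0.5), 0)),
               -(4 / 3) * pi * 0.5^3, tolerance = 1e-12)
  expect_equal(profile_G(piecewise_profile(c(0, 0.5), 1)), 0)
})

test_that("closed-form G matches numerical quadrature of the stored profile", {
  for (p in list(piecewise_profile(c(0, 0.4, 0.9, 1.3), c(0, 2.5, 0.7)),
                 piecewise_profile(c(0, 0.5, 1.1), c(0, 3.0)))) {
    # integrate each smooth piece so the quadrature itself is exact
    num <- sum(vapply(seq_along(p$levels), function(k)
      integrate(function(r) (p$levels[k] - 1) * 4 * pi * r^2,
                p$breaks[k], p$breaks[k + 1], abs.tol = 1e-13,
                rel.tol = 1e-13)$value, numeric(1)))
    expect_equal(profile_G(p), num, tolerance = 1e-10)
  }
})

test_that("toy solutes have the prescribed geometry", {
  s <- make_solute("helix_dimer", n_residues = 8, axis_spacing = 1.0)
  expect_equal(sum(s$role == "main_chain"), 16)
  expect_equal(sum(s$role == "side_chain"), 16)
  # backbone beads collinear per strand: x and y constant along each chain
  for (ch in c("A", "B")) {
    mc <- s$coords[s$role == "main_chain" & s$chain == ch, ]
    expect_lt(max(apply(mc[, 1:2], 2, function(v) diff(range(v)))), 1e-12)
  }
  c1 <- make_solute("coil_monomer", n_residues = 16, step = 0.38,
                    seed = 5)
  mc <- c1$coords[c1$role == "main_chain", ]
  steps <- sqrt(rowSums(diff(mc)^2))
  expect_equal(steps, rep(0.38, 15), tolerance = 1e-9)
  # determinism
  c2 <- make_solute("coil_monomer", n_residues = 16, step = 0.38,
                    seed = 5)
  expect_identical(c1$coords, c2$coords)
  # min separation above 2x the step is geometrically impossible
  expect_error(make_solute("coil_monomer", n_residues = 20,
                           min_separation = 0.8, seed = 1),
               "self-avoiding")
})

test_that("ideal-gas placement recovers g = 1 within 3 Poisson SE", {
  sys <- prescribed_traj(list(cosolvent = NULL), c(cosolvent = 4),
                         box = c(5, 5, 5), n_frames = 200L, seed = 2L)
  tr <- sys$trajectory
  p <- rdf_atomset(tr, species_idx(tr, "protein"),
                   species_idx(tr, "cosolvent"), bin_width = 0.1,
                   r_max = 2.4, bulk_density = 4)
  # per-bin Poisson SE on the mean g
  counts_exp <- 4 * p$shell_volumes * p$n_frames
  se <- sqrt(counts_exp) / counts_exp
  expect_true(all(abs(p$g - 1) <= 3 * se + 1e-9))
})

test_that("shell counts follow the prescribed Poisson intensity (chi-square)", {
  prof <- piecewise_profile(c(0, 0.6, 1.2), c(0.5, 2))
  sys <- prescribed_traj(list(cosolvent = prof), c(cosolvent = 6),
                         box = c(5, 5, 5), n_frames = 120L, seed = 9L)
  tr <- sys$trajectory
  edges <- seq(0, 2, length.out = 51L)  # 50 radial bins
  ref <- tr$box[1, ] / 2
  obs <- numeric(50L)
  for (f in seq_len(n_frames(tr))) {
    rel <- sweep(matrix(tr$coords[-1, , f], ncol = 3), 2, ref)
    for (k in 1:3)
      rel[, k] <- rel[, k] - tr$box[f, k] * round(rel[, k] / tr$box[f, k])
    r <- sqrt(rowSums(rel^2))
    idx <- findInterval(r, edges)
    keep <- idx >= 1 & idx <= 50
    obs <- obs + tabulate(idx[keep], nbins = 50L)
  }
  mid <- (edges[-1] + edges[-51]) / 2
  vshell <- (4 * pi / 3) * diff(edges^3)
  expected <- 6 * profile_eval(prof, mid) * vshell * n_frames(tr)
  x2 <- sum((obs - expected)^2 / expected)
  expect_lt(x2, qchisq(0.99, df = 50L))
})

test_that("generation is bit-identical under a fixed seed", {
  prof <- list(cosolvent = piecewise_profile(c(0, 0.5), 2))
  a <- place_solvent_prescribed(prof, c(cosolvent = 3), c(5, 5, 5), 5L,
                                seed = 77L)
  b <- place_solvent_prescribed(prof, c(cosolvent = 3), c(5, 5, 5), 5L,
                                seed = 77L)
  expect_identical(a$trajectory$coords, b$trajectory$coords)
})

test_that("profiles reaching beyond the half-box are rejected", {
  expect_error(place_solvent_prescribed(
    list(cosolvent = piecewise_profile(c(0, 3.0), 2)),
    c(cosolvent = 3), box = c(5, 5, 5), n_frames = 2L), "half-box")
})

test_that("orientation laws validate normalization and sample as stated", {
  expect_error(orientation_density(function(x) rep(1, length(x))),
               "integral = 2")
  law <- orientation_point(-1)
  sys <- place_solvent_oriented(law, density = 3, box = c(5, 5, 5),
                                n_frames = 5L, seed = 4L)
  tr <- sys$trajectory
  top <- tr$topology
  tails <- which(top$name == "C1")
  heads <- which(top$name == "O")
  ref <- tr$box[1, ] / 2
  for (f in seq_len(n_frames(tr))) {
    tl <- matrix(tr$coords[tails, , f], ncol = 3)
    hd <- matrix(tr$coords[heads, , f], ncol = 3)
    u <- sweep(tl, 2, ref)
    for (k in 1:3)
      u[, k] <- u[, k] - tr$box[f, k] * round(u[, k] / tr$box[f, k])
    u <- u / sqrt(rowSums(u^2))
    v <- hd - tl
    for (k in 1:3)
      v[, k] <- v[, k] - tr$box[f, k] * round(v[, k] / tr$box[f, k])
    v <- v / sqrt(rowSums(v^2))
    expect_equal(rowSums(u * v), rep(-1, nrow(u)), tolerance = 1e-9)
  }
})

test_that("ground-truth sidecar round-trips through YAML", {
  prof <- list(water = piecewise_profile(c(0, 0.5), 0),
               cosolvent = piecewise_profile(c(0, 0.5, 1.1), c(0, 3)))
  sys <- place_solvent_prescribed(prof, c(water = 8, cosolvent = 2),
                                  c(5, 5, 5), 2L, seed = 12L)
  path <- withr::local_tempfile(fileext = ".yml")
  write_ground_truth(sys$truth, path)
  back <- read_ground_truth(path)
  expect_equal(back$analytic_G, sys$truth$analytic_G, tolerance = 1e-12)
  expect_equal(back$densities, sys$truth$densities)
  expect_equal(back$profiles$cosolvent$levels,
               prof$cosolvent$levels)
  expect_equal(back$seed, sys$truth$seed)
})
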