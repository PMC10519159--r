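test_that("unit conversions invert and match known anchors", {
  x <- c(0.1, 1, 12.34)
  expect_equal(nm_from_angstrom(angstrom_from_nm(x)), x, tolerance = 1e-12)
  expect_equal(molarity_from_density(density_from_molarity(x)), x,
               tolerance = 1e-12)
  # 1.2044 nm^-3 is 2.000 M
  expect_equal(molarity_from_density(1.2044), 2.0, tolerance = 1e-4)
  expect_equal(thermo_params(300)$beta, 1.6774, tolerance = 1e-4)
})

test_that("role classification follows the backbone-name rule and partitions", {
  top <- kb_topology(data.frame(
    name = c("N", "CA", "C", "O", "CB", "HA2", "OG", "OW"),
    residue_name = c(rep("ALA", 5), "GLY", "SER", "SOL"),
    residue_index = c(rep(1L, 5), 2L, 3L, 4L),
    species = c(rep("protein", 7), "water"),
    stringsAsFactors = FALSE))
  out <- classify_roles(top)
  expect_equal(out$role[out$name == "CB"], "side_chain")
  expect_equal(out$role[out$name == "HA2"], "main_chain")
  expect_equal(out$role[out$name == "OW"], "solvent")
  prot <- out$species == "protein"
  expect_true(all(out$role[prot] %in% c("main_chain", "side_chain")))
  # deterministic and total
  expect_identical(classify_roles(top), out)
  # strict mode errors on unknown names
  expect_error(classify_roles(top, side_chain = "CB", strict = TRUE), "OG")
})

test_that("role classification counts match enumeration on a toy chain", {
  # 5 residues x (N, CA, C, O) heavy backbone + one CB each
  top <- kb_topology(data.frame(
    name = rep(c("N", "CA", "C", "O", "CB"), 5),
    residue_name = "ALA", residue_index = rep(1:5, each = 5),
    species = "protein", stringsAsFactors = FALSE))
  out <- classify_roles(top)
  expect_equal(sum(out$role == "main_chain"), 5 * 4)
  expect_equal(sum(out$role == "side_chain"), 5)
})

test_that("composition reproduces the mole-fraction and molarity anchors", {
  # helix-dimer cosolvent box: 15310 water + 626 cosolvent molecules
  comp <- system_composition(15310, 626, box_volume = 8.1^3)
  expect_equal(comp$mole_fraction, 0.0393, tolerance = 1e-3)
  expect_equal(round(comp$mole_fraction, 2), 0.04)
  # coil box: 7655 water + 313 cosolvent
  expect_equal(system_composition(7655, 313, 6.5^3)$mole_fraction,
               0.0393, tolerance = 1e-3)
  expect_equal(system_composition(0, 1.2044 * 100, 100)$molarity, 2,
               tolerance = 1e-4)
  z <- system_composition(100, 0, 50)
  expect_equal(z$mole_fraction, 0)
  expect_equal(z$rho3, 0)
  expect_error(system_composition(1, 1, 0), "positive")
})

test_that("topology invariants are enforced", {
  base <- data.frame(name = "CA", residue_name = "ALA", residue_index = 1L,
                     species = "protein", stringsAsFactors = FALSE)
  expect_error(kb_topology(transform(base, charge = NaN)), "charge")
  expect_error(kb_topology(transform(base, lj_sigma = -1)), "sigma")
  expect_error(kb_topology(transform(base, role = "solvent")), "solvent")
  wat <- transform(base, species = "water")
  expect_error(kb_topology(transform(wat, role = "main_chain")), "solvent")
})

test_that("GRO write/read round-trips coordinates to format precision", {
  set.seed(42)
  n <- 25L
  top <- toy_topology(n - 1L, "water")
  frame <- list(box = c(4, 5, 6),
                coords = cbind(runif(n, 0, 4), runif(n, 0, 5),
                               runif(n, 0, 6)))
  path <- withr::local_tempfile(fileext = ".gro")
  write_gro(top, frame, path)
  back <- read_structure(path, "gro")
  expect_equal(back$frame$coords, unname(frame$coords), tolerance = 5e-4)
  expect_equal(back$frame$box, frame$box, tolerance = 1e-5)
  expect_equal(back$topology$name, top$name)  # atom order preserved
})

test_that("PDB coordinates are converted from Angstrom to nm", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "CRYST1   50.000   50.000   50.000  90.00  90.00  90.00 P 1",
    "ATOM      1  CA  ALA A   1      10.000  20.000  30.000  1.00  0.00           C",
    "END"), path)
  s <- read_structure(path, "pdb")
  expect_equal(s$frame$coords[1, ], c(1, 2, 3), tolerance = 1e-6)
  expect_equal(s$frame$box, c(5, 5, 5))
})

test_that("multi-model PDB reads as an ordered trajectory", {
  path <- withr::local_tempfile(fileext = ".pdb")
  model <- function(k, x) c(
    sprintf("MODEL     %4d", k),
    sprintf("ATOM      1  CA  ALA A   1    %8.3f   0.000   0.000  1.00  0.00           C", x),
    sprintf("ATOM      2  CB  ALA A   1    %8.3f   1.000   0.000  1.00  0.00           C", x),
    "ENDMDL")
  writeLines(c("CRYST1   40.000   40.000   40.000  90.00  90.00  90.00 P 1",
               model(1, 1), model(2, 2), model(3, 3), "END"), path)
  traj <- read_trajectory(path, "multi_model_pdb")
  expect_equal(n_frames(traj), 3L)
  expect_equal(traj$coords[1, 1, ], c(0.1, 0.2, 0.3), tolerance = 1e-6)
})

test_that("columnar trajectory round-trips and rejects malformed input", {
  traj <- ideal_gas_traj(n_solvent = 30L, n_frames = 4L, seed = 3L)
  path <- withr::local_tempfile(fileext = ".kbt")
  write_columnar_trajectory(traj, path)
  back <- read_columnar_trajectory(path)
  expect_equal(n_frames(back), 4L)
  expect_equal(back$coords, traj$coords, tolerance = 1e-9)
  expect_equal(back$topology$species, traj$topology$species)
  expect_equal(back$box, traj$box, tolerance = 1e-9)

  empty <- withr::local_tempfile()
  writeLines(character(0), empty)
  expect_error(read_columnar_trajectory(empty), "kbtraj")
})

test_that("gro_sequence reader flags atom-count mismatch with frame index", {
  top1 <- toy_topology(3L, "water")
  top2 <- toy_topology(2L, "water")
  f1 <- withr::local_tempfile(fileext = ".gro")
  f2 <- withr::local_tempfile(fileext = ".gro")
  write_gro(top1, list(box = c(3, 3, 3), coords = matrix(1, 4, 3)), f1)
  write_gro(top2, list(box = c(3, 3, 3), coords = matrix(1, 3, 3)), f2)
  expect_error(read_trajectory(c(f1, f2), "gro_sequence"), "frame 2")
})

test_that("parameter table application fills charges and LJ parameters", {
  top <- kb_topology(data.frame(
    name = c("CA", "CB"), residue_name = "ALA", residue_index = 1L,
    species = "protein", stringsAsFactors = FALSE))
  path <- withr::local_tempfile()
  writeLines(c("residue atom charge sigma_nm epsilon_kcal",
               "ALA CA 0.03 0.34 0.109",
               "ALA CB -0.18 0.34 0.109"), path)
  tab <- read_parameter_table(path)
  out <- apply_parameters(top, tab)
  expect_equal(out$charge, c(0.03, -0.18))
  expect_equal(out$lj_sigma, c(0.34, 0.34))
  expect_error(apply_parameters(
    kb_topology(data.frame(name = "CG", residue_name = "ALA",
                           residue_index = 1L, species = "protein")),
    tab), "ALA CG")
})

test_that("trajectories reject frame/topology mismatches and bad boxes", {
  top <- toy_topology(2L)
  expect_error(kb_trajectory(top, matrix(0, 2, 3), c(3, 3, 3)),
               "does not match")
  expect_error(kb_trajectory(top, matrix(0, 3, 3), c(3, 3, 0)),
               "positive")
})
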