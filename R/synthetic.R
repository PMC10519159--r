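#' Conformation multiplicity convention
#'
#' The unfolded reference state is *two* isolated coil monomers, so every
#' per-monomer KB integral or excluded volume for the coil is doubled
#' before it is compared with the helix dimer. `helix_dimer` has
#' multiplicity 1, `coil_monomer` multiplicity 2.
#'
#' @param conformation "helix_dimer" or "coil_monomer".
#' @return Integer multiplicity.
#' @export
conformation_multiplicity <- function(conformation) {
  conformation <- match.arg(conformation, c("helix_dimer", "coil_monomer"))
  if (conformation == "helix_dimer") 1L else 2L
}

#' Piecewise-constant target radial profile
#'
#' Defines a target g(r) that is `levels[k]` on `[breaks[k], breaks[k+1])`
#' and 1 beyond the last break. Used by the synthetic generator so KB
#' integrals have closed forms.
#'
#' @param breaks strictly increasing radii (nm) starting at 0.
#' @param levels non-negative levels, one fewer than `breaks`.
#' @return Object of class `piecewise_profile`.
#' @examples
#' p <- piecewise_profile(c(0, 1), 2)   # g = 2 inside 1 nm
#' profile_G(p)                         # 4*pi/3
#' @export
piecewise_profile <- function(breaks, levels) {
  stopifnot(length(breaks) == length(levels) + 1L,
            breaks[1] == 0, all(diff(breaks) > 0), all(levels >= 0))
  structure(list(breaks = as.numeric(breaks), levels = as.numeric(levels)),
            class = "piecewise_profile")
}

#' Evaluate a piecewise profile
#' @param profile `piecewise_profile`.
#' @param r radii (nm).
#' @return g(r) values (1 beyond the last break).
#' @export
profile_eval <- function(profile, r) {
  idx <- findInterval(r, profile$breaks, rightmost.closed = FALSE)
  out <- rep(1, length(r))
  inside <- idx >= 1L & idx <= length(profile$levels) & r >= 0
  out[inside] <- profile$levels[idx[inside]]
  out[r < 0] <- NA_real_
  out
}

#' Closed-form KB integral of a piecewise profile
#'
#' \eqn{G = \int_0^\infty (g(r)-1)\,4\pi r^2\,dr}; for a piecewise-constant
#' profile this is \eqn{\sum_k (l_k-1)\frac{4\pi}{3}(b_k^3 - b_{k-1}^3)}.
#'
#' @param profile `piecewise_profile`.
#' @return KB integral in nm^3.
#' @export
profile_G <- function(profile) {
  b <- profile$breaks
  sum((profile$levels - 1) * (4 * pi / 3) * diff(b^3))
}

#' Build a toy solute in one of two conformations
#'
#' `helix_dimer`: two parallel straight strands of main-chain beads along
#' z separated by `axis_spacing` along x, one side-chain bead per residue
#' pointing radially away from the dimer interface (so side chains are
#' solvent-exposed and main chains are buried, as in a coiled coil).
#' `coil_monomer`: a fixed-step self-avoiding random walk of main-chain
#' beads with one side-chain bead per residue (so the backbone is
#' solvent-exposed).
#'
#' @param conformation "helix_dimer" or "coil_monomer".
#' @param n_residues residues per strand (>= 2).
#' @param axis_spacing inter-axis distance of the dimer (nm).
#' @param rise axial rise per residue (nm).
#' @param step coil walk step length (nm).
#' @param side_offset side-chain bead offset from its main-chain bead (nm).
#' @param min_separation minimum distance between non-bonded coil beads (nm).
#' @param seed RNG seed (the dimer is deterministic; the coil walk is
#'   deterministic given the seed).
#' @return Object of class `solute_model`: `coords` (centroid-centred,
#'   nm), `name`, `role`, `chain`, `residue_index`, `conformation`.
#' @export
make_solute <- function(conformation = c("helix_dimer", "coil_monomer"),
                        n_residues = 8L, axis_spacing = 1.0, rise = 0.15,
                        step = 0.38, side_offset = 0.5,
                        min_separation = 0.3, seed = 20231001L) {
  conformation <- match.arg(conformation)
  stopifnot(n_residues >= 2L)
  set.seed(seed)
  if (conformation == "helix_dimer") {
    z <- (seq_len(n_residues) - (n_residues + 1) / 2) * rise
    coords <- rbind(
      cbind(-axis_spacing / 2, 0, z),                   # strand A backbone
      cbind(+axis_spacing / 2, 0, z),                   # strand B backbone
      cbind(-axis_spacing / 2 - side_offset, 0, z),     # strand A side chains
      cbind(+axis_spacing / 2 + side_offset, 0, z))
    role <- rep(c("main_chain", "side_chain"), each = 2L * n_residues)
    chain <- rep(c("A", "B", "A", "B"), each = n_residues)
    resi <- rep(c(seq_len(n_residues), seq_len(n_residues)), times = 2L)
  } else {
    main <- matrix(NA_real_, n_residues, 3L)
    main[1, ] <- 0
    for (i in 2:n_residues) {
      placed <- FALSE
      for (try in seq_len(2000L)) {
        v <- stats::rnorm(3)
        v <- v / sqrt(sum(v^2))
        cand <- main[i - 1, ] + step * v
        prev <- main[seq_len(i - 2), , drop = FALSE]
        if (!nrow(prev) ||
            min(sqrt(rowSums(sweep(prev, 2, cand)^2))) >= min_separation) {
          main[i, ] <- cand
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stop("self-avoiding walk failed after bounded retries; ",
             "reduce n_residues or min_separation (or enlarge the box)")
    }
    dirs <- matrix(stats::rnorm(3L * n_residues), ncol = 3L)
    dirs <- dirs / sqrt(rowSums(dirs^2))
    coords <- rbind(main, main + side_offset * dirs)
    role <- rep(c("main_chain", "side_chain"), each = n_residues)
    chain <- rep("A", 2L * n_residues)
    resi <- rep(seq_len(n_residues), times = 2L)
  }
  coords <- sweep(coords, 2L, colMeans(coords))
  structure(list(coords = coords,
                 name = ifelse(role == "main_chain", "CA", "CB"),
                 role = role, chain = chain, residue_index = resi,
                 conformation = conformation,
                 multiplicity = conformation_multiplicity(conformation)),
            class = "solute_model")
}

## Topology rows for a solute_model (charges/LJ zero unless supplied).
.solute_topology <- function(solute, charge = NULL, lj_sigma = NULL,
                             lj_epsilon = NULL) {
  n <- nrow(solute$coords)
  data.frame(
    name = solute$name, element = "C", residue_name = "BEA",
    residue_index = solute$residue_index, chain_id = solute$chain,
    species = "protein", role = solute$role,
    charge = if (is.null(charge)) 0 else charge,
    lj_sigma = if (is.null(lj_sigma)) 0.33 else lj_sigma,
    lj_epsilon = if (is.null(lj_epsilon)) 0 else lj_epsilon,
    stringsAsFactors = FALSE)
}

## Uniform points in a spherical shell [r0, r1).
.runif_shell <- function(n, r0, r1) {
  if (!n) return(matrix(numeric(0), 0L, 3L))
  r <- (stats::runif(n) * (r1^3 - r0^3) + r0^3)^(1 / 3)
  z <- stats::runif(n, -1, 1)
  phi <- stats::runif(n, 0, 2 * pi)
  s <- sqrt(1 - z^2)
  cbind(r * s * cos(phi), r * s * sin(phi), r * z)
}

## Uniform points in a cylindrical annulus [s0, s1) x full box height Lz,
## centred on the z-axis.
.runif_annulus <- function(n, s0, s1, lz) {
  if (!n) return(matrix(numeric(0), 0L, 3L))
  s <- sqrt(stats::runif(n) * (s1^2 - s0^2) + s0^2)
  phi <- stats::runif(n, 0, 2 * pi)
  cbind(s * cos(phi), s * sin(phi), stats::runif(n, -lz / 2, lz / 2))
}

## Random unit vectors.
.runif_sphere_dir <- function(n) {
  z <- stats::runif(n, -1, 1)
  phi <- stats::runif(n, 0, 2 * pi)
  s <- sqrt(1 - z^2)
  cbind(s * cos(phi), s * sin(phi), z)
}

#' Generate solvent configurations with prescribed radial structure
#'
#' Places solvent molecule centres around a fixed reference point (the
#' solute centroid when a solute is supplied) so that the one-particle
#' density is exactly `rho_bulk * g_target(r)`: piecewise-constant shells
#' inside the last profile break, uniform at `rho_bulk` beyond it. The
#' per-frame molecule count is held fixed at the total intensity (so all
#' frames share one topology); shell counts are then multinomial with the
#' exact Poisson means. Because KB estimators only see one-particle
#' densities relative to the solute, the deliberate absence of
#' solvent-solvent structure does not bias the preferential-binding
#' oracles.
#'
#' @param profiles named list with elements `water` and/or `cosolvent`,
#'   each a [piecewise_profile()] (NULL means uniform).
#' @param densities named numeric vector: bulk number densities
#'   (molecules/nm^3) for `water` and `cosolvent`.
#' @param box orthorhombic box edge lengths (nm); the reference point sits
#'   at the box centre.
#' @param n_frames number of frames.
#' @param seed RNG seed.
#' @param solute optional [make_solute()] model placed rigidly at the box
#'   centre (its beads enter the topology as protein atoms).
#' @param cosolvent_sites 1 (point molecule) or 2 (tail-head dumbbell; the
#'   *tail* carries the prescribed radial profile).
#' @param bond_length tail-head distance for 2-site cosolvent (nm).
#' @param orientation_law optional orientation law for the 2-site
#'   cosolvent (see [place_solvent_oriented()]); default random isotropic.
#' @param mode "spherical" (distance from reference point) or
#'   "cylindrical" (perpendicular distance from the z-axis through the
#'   reference; shells are full-height annuli).
#' @param conformation conformation label stored in the ground truth.
#' @return List with `trajectory` (a [kb_trajectory()]) and `truth`
#'   (class `synthetic_truth`: profiles, closed-form `analytic_G` per
#'   species in nm^3 — per monomer, *not* multiplicity-scaled — bulk
#'   densities, composition, seed, mode, conformation).
#' @export
place_solvent_prescribed <- function(profiles, densities, box, n_frames,
                                     seed = 20231001L, solute = NULL,
                                     cosolvent_sites = 1L,
                                     bond_length = 0.24,
                                     orientation_law = NULL,
                                     mode = c("spherical", "cylindrical"),
                                     conformation = "helix_dimer") {
  mode <- match.arg(mode)
  stopifnot(length(box) == 3L, all(box > 0), n_frames >= 1L)
  species <- intersect(c("water", "cosolvent"), names(densities))
  if (!length(species)) stop("densities must name water and/or cosolvent")
  half <- min(box) / 2
  for (sp in species) {
    pr <- profiles[[sp]]
    if (!is.null(pr) && max(pr$breaks) > half + 1e-12)
      stop("profile for ", sp, " extends beyond the half-box (",
           signif(half, 4), " nm); KB truncation would be silently biased")
  }
  set.seed(seed)
  centre <- box / 2
  vol <- prod(box)

  sample_species <- function(sp) {
    pr <- profiles[[sp]]
    rho <- densities[[sp]]
    if (is.null(pr)) pr <- piecewise_profile(c(0, min(1, half / 2)), 1)
    b <- pr$breaks; l <- pr$levels
    if (mode == "spherical") {
      vshell <- (4 * pi / 3) * diff(b^3)
      vout <- vol - (4 * pi / 3) * max(b)^3
    } else {
      vshell <- pi * diff(b^2) * box[3]
      vout <- vol - pi * max(b)^2 * box[3]
    }
    lambda <- rho * (sum(l * vshell) + vout)
    n_tot <- max(1L, round(lambda))
    p <- c(l * vshell, vout) * rho / lambda
    draw_frame <- function() {
      counts <- as.integer(stats::rmultinom(1L, n_tot, p))
      k <- length(l)
      pts <- vector("list", k + 1L)
      for (i in seq_len(k)) {
        pts[[i]] <- if (mode == "spherical")
          .runif_shell(counts[i], b[i], b[i + 1])
        else .runif_annulus(counts[i], b[i], b[i + 1], box[3])
      }
      # uniform remainder: rejection from the whole box
      m <- counts[k + 1L]
      acc <- matrix(numeric(0), 0L, 3L)
      while (nrow(acc) < m) {
        cand <- cbind(stats::runif(2L * m + 16L, -box[1] / 2, box[1] / 2),
                      stats::runif(2L * m + 16L, -box[2] / 2, box[2] / 2),
                      stats::runif(2L * m + 16L, -box[3] / 2, box[3] / 2))
        d <- if (mode == "spherical") sqrt(rowSums(cand^2))
             else sqrt(cand[, 1]^2 + cand[, 2]^2)
        acc <- rbind(acc, cand[d >= max(b), , drop = FALSE])
      }
      pts[[k + 1L]] <- acc[seq_len(m), , drop = FALSE]
      do.call(rbind, pts)
    }
    list(n = n_tot, draw = draw_frame)
  }

  gens <- lapply(stats::setNames(species, species), sample_species)
  n_cos <- if ("cosolvent" %in% species) gens$cosolvent$n else 0L
  n_wat <- if ("water" %in% species) gens$water$n else 0L

  # topology: solute beads, then water, then cosolvent
  tops <- list()
  if (!is.null(solute)) tops$solute <- .solute_topology(solute)
  if (n_wat) tops$water <- data.frame(
    name = "OW", element = "O", residue_name = "SOL",
    residue_index = seq_len(n_wat), chain_id = "W", species = "water",
    role = "solvent", charge = 0, lj_sigma = 0.315, lj_epsilon = 0.152,
    stringsAsFactors = FALSE)
  if (n_cos) {
    sites <- if (cosolvent_sites == 2L) c("C1", "O") else "C1"
    tops$cosolvent <- data.frame(
      name = rep(sites, n_cos), element = rep(substr(sites, 1, 1), n_cos),
      residue_name = "CSL",
      residue_index = rep(seq_len(n_cos), each = length(sites)),
      chain_id = "C", species = "cosolvent", role = "solvent",
      charge = 0, lj_sigma = 0.35, lj_epsilon = 0.1,
      stringsAsFactors = FALSE)
  }
  top <- do.call(rbind, tops)
  rownames(top) <- NULL
  top <- kb_topology(top)

  n_atoms <- nrow(top)
  coords <- array(NA_real_, dim = c(n_atoms, 3L, n_frames))
  for (f in seq_len(n_frames)) {
    rows <- list()
    if (!is.null(solute))
      rows$solute <- sweep(solute$coords, 2L, centre, "+")
    if (n_wat)
      rows$water <- .wrap_box(sweep(gens$water$draw(), 2L, centre, "+"), box)
    if (n_cos) {
      tails <- gens$cosolvent$draw()
      if (cosolvent_sites == 2L) {
        dist_t <- if (mode == "spherical") sqrt(rowSums(tails^2))
                  else sqrt(tails[, 1]^2 + tails[, 2]^2)
        u_out <- .outward_unit(tails, mode)
        v <- .sample_orientations(n_cos, dist_t, u_out, orientation_law)
        heads <- tails + bond_length * v
        both <- matrix(NA_real_, 2L * n_cos, 3L)
        both[seq(1L, 2L * n_cos, by = 2L), ] <- tails
        both[seq(2L, 2L * n_cos, by = 2L), ] <- heads
        rows$cosolvent <- .wrap_box(sweep(both, 2L, centre, "+"), box)
      } else {
        rows$cosolvent <- .wrap_box(sweep(tails, 2L, centre, "+"), box)
      }
    }
    coords[, , f] <- do.call(rbind, rows)
  }
  traj <- kb_trajectory(top, coords, box)
  analytic_G <- vapply(stats::setNames(species, species), function(sp) {
    pr <- profiles[[sp]]
    if (is.null(pr)) 0 else profile_G(pr)
  }, numeric(1))
  truth <- structure(list(
    profiles = profiles, analytic_G = analytic_G,
    densities = densities[species],
    composition = system_composition(n_wat, n_cos, vol),
    seed = seed, mode = mode, conformation = conformation,
    orientation_law = orientation_law,
    cosolvent_sites = cosolvent_sites, bond_length = bond_length),
    class = "synthetic_truth")
  list(trajectory = traj, truth = truth)
}

.wrap_box <- function(x, box) {
  for (k in 1:3) x[, k] <- x[, k] %% box[k]
  x
}

## outward radial (or axis-perpendicular) unit vectors for points relative
## to the reference at the origin.
.outward_unit <- function(pts, mode) {
  if (mode == "cylindrical") pts[, 3] <- 0
  n <- sqrt(rowSums(pts^2))
  n[n < 1e-12] <- 1
  pts / n
}

#' Orientation laws for the dipolar cosolvent
#'
#' An orientation law prescribes the density p(cos theta) of the angle
#' between the molecule's tail-to-head unit vector and the outward unit
#' vector from the reference, per distance shell. A law is either
#' `orientation_point(x0)` (all molecules at cos theta = x0) or
#' `orientation_density(f)` with `f` a density on \[-1, 1\] integrating
#' to 1. `orientation_shells(breaks, laws)` assigns one law per shell
#' (molecules beyond the last break are isotropic).
#'
#' @param x0 fixed cos theta value in \[-1, 1\].
#' @param f density function on \[-1, 1\].
#' @param breaks shell boundaries (nm), increasing, starting at 0.
#' @param laws list of laws, one per shell (length = length(breaks) - 1).
#' @return Law objects of class `orientation_law` /
#'   `orientation_shell_law`.
#' @name orientation_laws
#' @export
orientation_point <- function(x0) {
  stopifnot(x0 >= -1, x0 <= 1)
  structure(list(type = "point", x0 = x0), class = "orientation_law")
}

#' @rdname orientation_laws
#' @export
orientation_density <- function(f) {
  stopifnot(is.function(f))
  z <- stats::integrate(f, -1, 1, abs.tol = 1e-9)$value
  if (abs(z - 1) > 1e-6)
    stop(sprintf("orientation law is not normalized: integral = %.8g", z))
  grid <- seq(-1, 1, length.out = 513L)
  structure(list(type = "density", f = f, fmax = max(f(grid)) * 1.05),
            class = "orientation_law")
}

#' @rdname orientation_laws
#' @export
orientation_shells <- function(breaks, laws) {
  stopifnot(breaks[1] == 0, all(diff(breaks) > 0),
            length(laws) == length(breaks) - 1L)
  ok <- vapply(laws, inherits, logical(1), "orientation_law")
  if (!all(ok)) stop("all shell laws must be orientation_law objects")
  structure(list(breaks = breaks, laws = laws),
            class = "orientation_shell_law")
}

## Sample one cos theta per molecule given distances and a law object.
.sample_costheta <- function(n, law) {
  if (is.null(law)) return(stats::runif(n, -1, 1))
  if (law$type == "point") return(rep(law$x0, n))
  out <- numeric(0)
  while (length(out) < n) {
    m <- 2L * (n - length(out)) + 16L
    x <- stats::runif(m, -1, 1)
    keep <- stats::runif(m) * law$fmax <= law$f(x)
    out <- c(out, x[keep])
  }
  out[seq_len(n)]
}

## Build tail->head unit vectors with prescribed cos theta against outward
## unit vectors u, uniform azimuth.
.sample_orientations <- function(n, dist, u_out, law) {
  if (is.null(law)) return(.runif_sphere_dir(n))
  ct <- numeric(n)
  if (inherits(law, "orientation_shell_law")) {
    shell <- findInterval(dist, law$breaks)
    outside <- shell < 1L | shell > length(law$laws)
    ct[outside] <- stats::runif(sum(outside), -1, 1)
    for (s in unique(shell[!outside])) {
      idx <- which(shell == s & !outside)
      ct[idx] <- .sample_costheta(length(idx), law$laws[[s]])
    }
  } else {
    ct <- .sample_costheta(n, law)
  }
  # orthonormal frame around each outward vector
  ref <- matrix(rep(c(1, 0, 0), each = n), ncol = 3L)
  swap <- abs(u_out[, 1]) > 0.9
  ref[swap, ] <- matrix(rep(c(0, 1, 0), each = sum(swap)), ncol = 3L)
  e1 <- .cross(u_out, ref)
  e1 <- e1 / sqrt(rowSums(e1^2))
  e2 <- .cross(u_out, e1)
  phi <- stats::runif(n, 0, 2 * pi)
  st <- sqrt(pmax(0, 1 - ct^2))
  ct * u_out + st * (cos(phi) * e1 + sin(phi) * e2)
}

.cross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

#' Generate oriented two-site cosolvent configurations
#'
#' Places dumbbell cosolvent molecules at uniform bulk density and draws
#' their tail-to-head orientation from a prescribed per-shell law relative
#' to the outward direction from the reference, emulating (when the law
#' biases cos theta toward -1 in the solvation shell) the
#' reverse-micelle-like arrangement in which cosolvent head groups point
#' toward the protein.
#'
#' @inheritParams place_solvent_prescribed
#' @param law an `orientation_law` or [orientation_shells()] object.
#' @param density cosolvent bulk number density (molecules/nm^3).
#' @return As [place_solvent_prescribed()].
#' @export
place_solvent_oriented <- function(law, density, box, n_frames,
                                   seed = 20231001L, solute = NULL,
                                   bond_length = 0.24,
                                   mode = c("spherical", "cylindrical"),
                                   conformation = "helix_dimer") {
  mode <- match.arg(mode)
  place_solvent_prescribed(
    profiles = list(cosolvent = NULL),
    densities = c(cosolvent = density), box = box, n_frames = n_frames,
    seed = seed, solute = solute, cosolvent_sites = 2L,
    bond_length = bond_length, orientation_law = law, mode = mode,
    conformation = conformation)
}

#' Write / read the synthetic ground-truth sidecar
#'
#' Serializes a `synthetic_truth` object as YAML so tests can reload the
#' oracle values (profiles, closed-form KB integrals, bulk densities,
#' seed) alongside a columnar trajectory file.
#'
#' @param truth `synthetic_truth` object.
#' @param path file path.
#' @return `write_ground_truth()` returns `path` invisibly;
#'   `read_ground_truth()` the reconstructed object.
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "synthetic_truth"))
  payload <- list(
    seed = truth$seed, mode = truth$mode, conformation = truth$conformation,
    cosolvent_sites = truth$cosolvent_sites, bond_length = truth$bond_length,
    densities = as.list(truth$densities),
    analytic_G = as.list(truth$analytic_G),
    profiles = lapply(truth$profiles, function(p)
      if (is.null(p)) NULL else list(breaks = p$breaks, levels = p$levels)),
    composition = list(n_water = truth$composition$n_water,
                       n_cosolvent = truth$composition$n_cosolvent,
                       box_volume = truth$composition$box_volume))
  yaml::write_yaml(payload, path, precision = 15L)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  y <- yaml::read_yaml(path)
  profiles <- lapply(y$profiles, function(p)
    if (is.null(p)) NULL else piecewise_profile(unlist(p$breaks),
                                                unlist(p$levels)))
  structure(list(
    profiles = profiles,
    analytic_G = unlist(y$analytic_G),
    densities = unlist(y$densities),
    composition = system_composition(y$composition$n_water,
                                     y$composition$n_cosolvent,
                                     y$composition$box_volume),
    seed = y$seed, mode = y$mode, conformation = y$conformation,
    orientation_law = NULL, cosolvent_sites = y$cosolvent_sites,
    bond_length = y$bond_length), class = "synthetic_truth")
}
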