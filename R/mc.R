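#' Metropolis Monte Carlo sampling of an interacting solvent
#'
#' Canonical-ensemble single-particle Metropolis sampling of point solvent
#' molecules (water and cosolvent) around a rigid solute under periodic
#' boundary conditions, with pairwise Lennard-Jones plus real-space-cutoff
#' Coulomb interactions (Lorentz-Berthelot combining). This is the
#' interacting-fluid companion to the prescribed-profile generator: it
#' trades analytic oracles for genuine multi-atom solute correlations, so
#' end-to-end sign tests can run on data with real excluded volume and
#' attraction. It is a statistical stand-in, not an MD engine.
#'
#' Solvent molecules are single sites, so rotational moves are vacuous and
#' only translations are attempted. The maximum displacement is tuned
#' during burn-in toward 40% acceptance; if the final acceptance rate
#' falls outside (0.05, 0.95) a warning (not an error) is raised.
#'
#' @param solute a [make_solute()] model, held rigid at the box centre.
#' @param solute_params data frame with per-role interaction parameters of
#'   the solute beads: columns `role`, `charge`, `lj_sigma`, `lj_epsilon`.
#' @param n_water,n_cosolvent solvent molecule counts.
#' @param solvent_params named list with elements `water` and `cosolvent`,
#'   each `c(charge=, lj_sigma=, lj_epsilon=)`.
#' @param box box edge lengths (nm).
#' @param n_sweeps total MC sweeps (one attempted move per particle each).
#' @param n_frames frames to record (evenly strided after burn-in).
#' @param temperature temperature (K).
#' @param cutoff interaction cutoff (nm); must not exceed the half-box.
#' @param burn_in sweeps discarded before recording (default 25%).
#' @param seed RNG seed; identical seed + parameters give bit-identical
#'   trajectories.
#' @return A [kb_trajectory()] with attribute `acceptance_rate`.
#' @export
mc_sample <- function(solute, solute_params, n_water, n_cosolvent,
                      solvent_params, box, n_sweeps = 400L, n_frames = 50L,
                      temperature = 300, cutoff = 1.0,
                      burn_in = max(1L, n_sweeps %/% 4L),
                      seed = 20231001L) {
  stopifnot(length(box) == 3L, all(box > 0), n_frames >= 1L,
            n_sweeps > burn_in)
  if (cutoff > min(box) / 2 + 1e-12)
    stop("cutoff exceeds the half-box; minimum image invalid")
  set.seed(seed)
  centre <- box / 2
  sol_xyz <- sweep(solute$coords, 2L, centre, "+")
  pidx <- match(solute$role, solute_params$role)
  if (anyNA(pidx)) stop("solute_params must cover roles: ",
                        paste(unique(solute$role), collapse = ", "))
  sq <- solute_params$charge[pidx]
  ss <- solute_params$lj_sigma[pidx]
  se <- solute_params$lj_epsilon[pidx]

  n <- n_water + n_cosolvent
  sp <- c(rep("water", n_water), rep("cosolvent", n_cosolvent))
  q <- vapply(sp, function(s) solvent_params[[s]]["charge"], numeric(1))
  sg <- vapply(sp, function(s) solvent_params[[s]]["lj_sigma"], numeric(1))
  ep <- vapply(sp, function(s) solvent_params[[s]]["lj_epsilon"], numeric(1))

  pos <- cbind(stats::runif(n, 0, box[1]), stats::runif(n, 0, box[2]),
               stats::runif(n, 0, box[3]))
  beta <- 1 / (.R_KCAL * temperature)

  # energy of particle i at position x against all other particles + solute
  u_one <- function(i, x) {
    others <- pos[-i, , drop = FALSE]
    e <- 0
    if (nrow(others)) {
      d <- .mi_dist_vec(others, x, box)
      keep <- d <= cutoff
      if (any(d < 1e-4)) return(Inf)
      if (any(keep)) {
        dj <- d[keep]
        sij <- (sg[i] + sg[-i][keep]) / 2
        eij <- sqrt(ep[i] * ep[-i][keep])
        sr6 <- (sij / dj)^6
        e <- e + sum(4 * eij * (sr6^2 - sr6)) +
          .KE_COULOMB * q[i] * sum(q[-i][keep] / dj)
      }
    }
    d <- .mi_dist_vec(sol_xyz, x, box)
    keep <- d <= cutoff
    if (any(d < 1e-4)) return(Inf)
    if (any(keep)) {
      dj <- d[keep]
      sij <- (sg[i] + ss[keep]) / 2
      eij <- sqrt(ep[i] * se[keep])
      sr6 <- (sij / dj)^6
      e <- e + sum(4 * eij * (sr6^2 - sr6)) +
        .KE_COULOMB * q[i] * sum(sq[keep] / dj)
    }
    e
  }

  delta <- 0.3
  acc <- 0L; tried <- 0L
  record_at <- burn_in + round(seq_len(n_frames) *
                               (n_sweeps - burn_in) / n_frames)
  coords <- array(NA_real_, dim = c(nrow(sol_xyz) + n, 3L, n_frames))
  top <- rbind(
    .solute_topology(solute, charge = sq, lj_sigma = ss, lj_epsilon = se),
    data.frame(name = ifelse(sp == "water", "OW", "C1"),
               element = ifelse(sp == "water", "O", "C"),
               residue_name = ifelse(sp == "water", "SOL", "CSL"),
               residue_index = seq_len(n), chain_id = "S", species = sp,
               role = "solvent", charge = q, lj_sigma = sg, lj_epsilon = ep,
               stringsAsFactors = FALSE))
  rownames(top) <- NULL

  fi <- 0L
  for (sweep in seq_len(n_sweeps)) {
    for (i in seq_len(n)) {
      old <- pos[i, ]
      new <- (old + stats::runif(3, -delta, delta)) %% box
      du <- u_one(i, new) - u_one(i, old)
      tried <- tried + 1L
      if (du <= 0 || stats::runif(1) < exp(-beta * du)) {
        pos[i, ] <- new
        acc <- acc + 1L
      }
    }
    if (sweep <= burn_in && sweep %% 20L == 0L) {
      rate <- acc / tried
      delta <- max(0.02, min(min(box) / 4, delta * exp(rate - 0.4)))
    }
    if (fi < n_frames && sweep == record_at[fi + 1L]) {
      fi <- fi + 1L
      coords[, , fi] <- rbind(sol_xyz, pos)
    }
  }
  rate <- acc / tried
  if (rate <= 0.05 || rate >= 0.95)
    warning(sprintf("MC acceptance rate %.2f outside (0.05, 0.95)", rate))
  traj <- kb_trajectory(kb_topology(top), coords, box)
  attr(traj, "acceptance_rate") <- rate
  traj
}

## minimum-image distances from a point x to rows of a matrix m
.mi_dist_vec <- function(m, x, box) {
  d2 <- 0
  for (k in 1:3) {
    dx <- m[, k] - x[k]
    dx <- dx - box[k] * round(dx / box[k])
    d2 <- d2 + dx * dx
  }
  sqrt(d2)
}
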