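# Small fixture builders shared across test files. Everything is built in
# code at test time; nothing is stored on disk.

# A minimal topology with one protein atom and n single-site solvent
# molecules of one species.
toy_topology <- function(n_solvent, species = "cosolvent") {
  kb_topology(data.frame(
    name = c("CA", rep(if (species == "water") "OW" else "C1", n_solvent)),
    residue_name = c("ALA", rep(if (species == "water") "SOL" else "CSL",
                                n_solvent)),
    residue_index = c(1L, seq_len(n_solvent)),
    species = c("protein", rep(species, n_solvent)),
    stringsAsFactors = FALSE))
}

# Ideal-gas solvent around a central protein atom: uniform positions,
# fixed count per frame.
ideal_gas_traj <- function(n_solvent = 400L, n_frames = 20L,
                           box = c(5, 5, 5), species = "cosolvent",
                           seed = 1L) {
  set.seed(seed)
  top <- toy_topology(n_solvent, species)
  coords <- array(NA_real_, dim = c(n_solvent + 1L, 3L, n_frames))
  for (f in seq_len(n_frames)) {
    coords[1, , f] <- box / 2
    coords[-1, , f] <- cbind(runif(n_solvent, 0, box[1]),
                             runif(n_solvent, 0, box[2]),
                             runif(n_solvent, 0, box[3]))
  }
  kb_trajectory(top, coords, box)
}

# Prescribed-profile system about a point reference, with the reference
# atom prepended so selections work (mirrors synthetic_system but with
# free choice of profiles/densities for cheap tests).
prescribed_traj <- function(profiles, densities, box = c(5, 5, 5),
                            n_frames = 40L, seed = 1L, ...) {
  out <- place_solvent_prescribed(profiles, densities, box, n_frames,
                                  seed = seed, ...)
  ref <- data.frame(name = "REF", element = "X", residue_name = "REF",
                    residue_index = 0L, chain_id = "R",
                    species = "protein", role = "main_chain", charge = 0,
                    lj_sigma = 0, lj_epsilon = 0, stringsAsFactors = FALSE)
  top0 <- as.data.frame(out$trajectory$topology)
  top0$atom_id <- NULL
  top0$molecule_id <- NULL
  top <- kb_topology(rbind(ref, top0))
  nf <- n_frames(out$trajectory)
  coords <- array(NA_real_, dim = c(nrow(top), 3L, nf))
  for (f in seq_len(nf))
    coords[, , f] <- rbind(box / 2, out$trajectory$coords[, , f])
  out$trajectory <- kb_trajectory(top, coords, out$trajectory$box)
  out
}

species_idx <- function(traj, sp) which(traj$topology$species == sp)

# Standard error of a trajectory-mean quantity from its block sd.
block_se <- function(sd, n_blocks = 5L) sd / sqrt(n_blocks)

# Exact Poisson/counting standard error of a running KB integral at its
# outer radius, for a single reference site: Var(G) = sum_k w_k^2 Var(g_k)
# with w_k = 4 pi r_k^2 dr and Var(g_k) = g_k / (rho V_k n_frames).
poisson_se_G <- function(profile, rho, multiplicity = 1L) {
  edges <- profile$bin_edges
  mid <- (edges[-1] + edges[-length(edges)]) / 2
  w <- 4 * pi * mid^2 * diff(edges)
  v <- pmax(profile$g, 0.05) / (rho * profile$shell_volumes *
                                  max(profile$n_frames, 1))
  multiplicity * sqrt(sum(w^2 * v))
}

# measured-vs-truth KB recovery for one species of a prescribed system
recover_G <- function(sys, species, bin_width = 0.02, r_max = 1.8,
                      conformation = "helix_dimer") {
  tr <- sys$trajectory
  p <- rdf_atomset(tr, species_idx(tr, "protein"),
                   species_idx(tr, species), bin_width = bin_width,
                   r_max = r_max,
                   bulk_density = sys$truth$densities[[species]],
                   conformation = conformation)
  plateau_estimate(kb_running_integral(p, conformation))
}
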