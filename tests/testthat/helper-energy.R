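# Independent O(N^2) reference for pair energies: plain double loop.
brute_force_energy <- function(ca, cb, qa, qb, sa, sb, ea, eb, box,
                               cutoff = 1.0) {
  coul <- 0; lj <- 0
  for (i in seq_len(nrow(ca))) {
    for (j in seq_len(nrow(cb))) {
      dx <- ca[i, ] - cb[j, ]
      dx <- dx - box * round(dx / box)
      r <- sqrt(sum(dx^2))
      if (r > cutoff) next
      coul <- coul + 33.20637 * qa[i] * qb[j] / r
      sij <- (sa[i] + sb[j]) / 2
      eij <- sqrt(ea[i] * eb[j])
      lj <- lj + 4 * eij * ((sij / r)^12 - (sij / r)^6)
    }
  }
  c(coulomb = coul, lj = lj)
}

# Single-frame charged bead-solute + random cosolvent fixture.
decomp_fixture <- function(seed = 19L, n_cos = 40L) {
  set.seed(seed)
  s <- make_solute("helix_dimer", n_residues = 4)
  box <- c(5, 5, 5)
  sol <- sweep(s$coords, 2, box / 2, "+")
  cos_xyz <- cbind(runif(n_cos, 0, 5), runif(n_cos, 0, 5),
                   runif(n_cos, 0, 5))
  top <- kb_topology(data.frame(
    name = c(s$name, rep("C1", n_cos)),
    residue_name = c(rep("BEA", length(s$name)), rep("CSL", n_cos)),
    residue_index = c(s$residue_index, seq_len(n_cos)),
    species = c(rep("protein", length(s$name)), rep("cosolvent", n_cos)),
    role = c(s$role, rep("solvent", n_cos)),
    charge = c(ifelse(s$role == "main_chain", 0.1, -0.25),
               rep(0.15, n_cos)),
    lj_sigma = 0.33, lj_epsilon = 0.12, stringsAsFactors = FALSE))
  kb_trajectory(top, rbind(sol, cos_xyz), box)
}
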