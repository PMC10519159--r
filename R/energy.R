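#' Pairwise Coulomb and Lennard-Jones energy between two atom groups
#'
#' Sums over all minimum-image pairs within the real-space cutoff:
#' Coulomb \eqn{\sum k_e q_i q_j / r} (k_e = 33.20637 kcal nm mol^-1
#' e^-2) and LJ \eqn{\sum 4\epsilon_{ij}[(\sigma_{ij}/r)^{12} -
#' (\sigma_{ij}/r)^6]} with Lorentz-Berthelot combining (arithmetic
#' sigma, geometric epsilon; `combine = "geometric"` switches sigma to
#' geometric). Pairs beyond the cutoff contribute zero; no shifting, no
#' tail corrections — deliberately the plain truncated form used when
#' decomposing near-surface interactions.
#'
#' @param coords_a,coords_b coordinates of the two groups (`n x 3`, nm).
#' @param charge_a,charge_b partial charges (e).
#' @param sigma_a,sigma_b LJ sigma (nm).
#' @param epsilon_a,epsilon_b LJ epsilon (kcal/mol).
#' @param box box edge lengths (nm).
#' @param cutoff real-space cutoff (nm), default 1.0; at most the
#'   half-box.
#' @param combine "lorentz_berthelot" or "geometric" (sigma rule).
#' @return Named numeric `c(coulomb=, lj=)` in kcal/mol.
#' @examples
#' # two +1e charges at 0.5 nm: 66.41 kcal/mol
#' pair_energy(matrix(0, 1, 3), matrix(c(0.5, 0, 0), 1), 1, 1,
#'             0.3, 0.3, 0, 0, box = c(5, 5, 5))["coulomb"]
#' @export
pair_energy <- function(coords_a, coords_b, charge_a, charge_b,
                        sigma_a, sigma_b, epsilon_a, epsilon_b,
                        box, cutoff = 1.0,
                        combine = c("lorentz_berthelot", "geometric")) {
  combine <- match.arg(combine)
  coords_a <- matrix(coords_a, ncol = 3L)
  coords_b <- matrix(coords_b, ncol = 3L)
  na <- nrow(coords_a); nb <- nrow(coords_b)
  charge_a <- rep_len(charge_a, na); charge_b <- rep_len(charge_b, nb)
  sigma_a <- rep_len(sigma_a, na); sigma_b <- rep_len(sigma_b, nb)
  epsilon_a <- rep_len(epsilon_a, na); epsilon_b <- rep_len(epsilon_b, nb)
  if (cutoff > min(box) / 2 + 1e-12)
    stop("cutoff exceeds the half-box; minimum image invalid")
  d <- min_image_distances(coords_a, coords_b, box)
  if (any(d < 1e-4))
    stop("overlapping atoms: pair distance below 1e-4 nm")
  within <- d <= cutoff
  if (!any(within)) return(c(coulomb = 0, lj = 0))
  i <- row(d)[within]; j <- col(d)[within]; r <- d[within]
  coulomb <- .KE_COULOMB * sum(charge_a[i] * charge_b[j] / r)
  sij <- if (combine == "lorentz_berthelot")
    (sigma_a[i] + sigma_b[j]) / 2 else sqrt(sigma_a[i] * sigma_b[j])
  eij <- sqrt(epsilon_a[i] * epsilon_b[j])
  sr6 <- (sij / r)^6
  lj <- sum(4 * eij * (sr6^2 - sr6))
  c(coulomb = coulomb, lj = lj)
}

#' Protein-cosolvent interaction-energy decomposition
#'
#' Ensemble-averaged direct interaction energy between the protein and
#' all cosolvent molecules, decomposed by protein part (main chain /
#' side chain / total) and physics (Coulomb / LJ / total), with
#' five-block standard deviations. Energies are totals per simulation
#' cell, not per cosolvent molecule. The additivity identities
#' main + side = total (per column) and coulomb + lj = total (per row)
#' hold exactly.
#'
#' @param traj a [kb_trajectory()] with roles assigned and parameters
#'   present.
#' @param cutoff real-space cutoff (nm), default 1.0.
#' @param conformation optional label stored in the result.
#' @param n_blocks error blocks (default 5).
#' @param combine LJ combining rule (see [pair_energy()]).
#' @return Object of class `energy_decomposition`: `mean` and `sd`
#'   3 x 3 matrices (rows main_chain/side_chain/total, columns
#'   coulomb/lj/total, kcal/mol), `per_frame`, `cutoff`, `conformation`.
#' @export
decompose_energy <- function(traj, cutoff = 1.0, conformation = NULL,
                             n_blocks = 5L,
                             combine = "lorentz_berthelot") {
  stopifnot(inherits(traj, "kb_trajectory"))
  top <- traj$topology
  main <- which(top$role == "main_chain")
  side <- which(top$role == "side_chain")
  cos <- which(top$species == "cosolvent")
  if (!length(cos)) stop("no cosolvent atoms in trajectory")
  if (!length(main) && !length(side)) stop("no protein atoms with roles")
  nf <- n_frames(traj)
  per_frame <- array(0, dim = c(nf, 2L, 2L),
                     dimnames = list(NULL, c("main_chain", "side_chain"),
                                     c("coulomb", "lj")))
  for (f in seq_len(nf)) {
    box <- traj$box[f, ]
    for (part in c("main_chain", "side_chain")) {
      idx <- if (part == "main_chain") main else side
      if (!length(idx)) next
      e <- pair_energy(frame_coords(traj, idx, f),
                       frame_coords(traj, cos, f),
                       top$charge[idx], top$charge[cos],
                       top$lj_sigma[idx], top$lj_sigma[cos],
                       top$lj_epsilon[idx], top$lj_epsilon[cos],
                       box, cutoff, combine)
      per_frame[f, part, ] <- e
    }
  }
  full <- function(m2) {  # 2x2 -> 3x3 with exact totals
    m <- rbind(m2, total = colSums(m2))
    cbind(m, total = rowSums(m))
  }
  mean2 <- apply(per_frame, c(2L, 3L), mean)
  sd2 <- apply(per_frame, c(2L, 3L), function(x)
    if (nf >= n_blocks) block_uncertainty(x, n_blocks)$sd else NA_real_)
  # block sd of the derived totals from per-frame sums
  tot_rows <- matrix(per_frame[, "main_chain", ] +
                       per_frame[, "side_chain", ], nrow = nf)
  sd_row_tot <- apply(tot_rows, 2L, function(x)
    if (nf >= n_blocks) block_uncertainty(x, n_blocks)$sd else NA_real_)
  tot_cols <- matrix(per_frame[, , "coulomb"] + per_frame[, , "lj"],
                     nrow = nf)
  sd_col_tot <- apply(tot_cols, 2L, function(x)
    if (nf >= n_blocks) block_uncertainty(x, n_blocks)$sd else NA_real_)
  grand <- apply(per_frame, 1L, sum)
  sd_grand <- if (nf >= n_blocks) block_uncertainty(grand, n_blocks)$sd
              else NA_real_
  sdm <- rbind(cbind(sd2, total = sd_col_tot[c(1, 2)]),
               total = c(sd_row_tot, sd_grand))
  colnames(sdm) <- c("coulomb", "lj", "total")
  structure(list(mean = full(mean2), sd = sdm, per_frame = per_frame,
                 cutoff = cutoff, conformation = conformation,
                 n_blocks = n_blocks), class = "energy_decomposition")
}

#' @export
print.energy_decomposition <- function(x, ...) {
  cat(sprintf("Protein-cosolvent interaction energies (kcal/mol, cutoff %g nm%s):\n",
              x$cutoff,
              if (!is.null(x$conformation)) paste0(", ", x$conformation)
              else ""))
  print(round(x$mean, 3))
  invisible(x)
}

#' Serialize an energy decomposition to TSV
#' @param x an [decompose_energy()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_energy_tsv <- function(x, path) {
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(sprintf("# kbsolv energy_decomposition cutoff=%g conformation=%s",
                     x$cutoff,
                     if (is.null(x$conformation)) "NA" else x$conformation),
             con)
  df <- data.frame(part = rownames(x$mean), x$mean,
                   sd_coulomb = x$sd[, "coulomb"], sd_lj = x$sd[, "lj"],
                   sd_total = x$sd[, "total"])
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
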