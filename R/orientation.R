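#' Principal axis of the helix dimer
#'
#' The central axis is defined as the line through the centroid of the
#' main-chain atoms along the principal direction of largest coordinate
#' variance. Sign convention: positive dot product with +z, ties broken
#' toward +x. The axial extent covered by the main-chain atoms is
#' recorded for slab-restricted cylindrical histograms. (The axis
#' definition is a convention; it is recorded in output metadata so
#' alternatives can be compared.)
#'
#' @param coords main-chain atom coordinates (`n x 3`, nm), n >= 3.
#' @return Object of class `axis_frame`: `origin`, `direction` (unit),
#'   `axial_extent` (c(z_min, z_max) along the axis, relative to origin).
#' @export
helix_axis <- function(coords) {
  coords <- matrix(coords, ncol = 3L)
  if (nrow(coords) < 3L) stop("need at least 3 atoms to define an axis")
  origin <- colMeans(coords)
  cc <- sweep(coords, 2L, origin)
  ev <- eigen(crossprod(cc) / nrow(cc), symmetric = TRUE)
  if (ev$values[1] < 1e-10 ||
      (ev$values[1] - ev$values[2]) / max(ev$values[1], 1e-300) < 1e-6)
    stop("degenerate configuration: no unique principal axis")
  dir <- ev$vectors[, 1]
  if (abs(dir[3]) > 1e-12) {
    if (dir[3] < 0) dir <- -dir
  } else if (abs(dir[1]) > 1e-12) {
    if (dir[1] < 0) dir <- -dir
  } else if (dir[2] < 0) dir <- -dir
  proj <- drop(cc %*% dir)
  structure(list(origin = origin, direction = dir,
                 axial_extent = range(proj)), class = "axis_frame")
}

#' Cylindrical solvent distribution around the helix axis
#'
#' Histogram of target atoms by perpendicular distance z to the per-frame
#' helix axis, counting only atoms whose axial coordinate lies within the
#' instantaneous axial extent of the main-chain atoms (slab restriction).
#' Bin k is normalized by `rho_target * 2*pi*z_k*dz * L_slab * n_frames`.
#'
#' @param traj a [kb_trajectory()].
#' @param axis_atoms selection of main-chain atoms defining the axis.
#' @param target_atoms selection of atoms to histogram.
#' @param bin_width bin width (nm).
#' @param z_max histogram range (nm); at most the half-box.
#' @param bulk_density optional bulk density of the target atoms
#'   (atoms/nm^3); default in-box count / box volume.
#' @return Object of class `cylindrical_profile`: `bin_edges`, `g`,
#'   `n_frames`, `axis` (last frame's [helix_axis()]).
#' @export
cylindrical_distribution <- function(traj, axis_atoms, target_atoms,
                                     bin_width = 0.05, z_max,
                                     bulk_density = NULL) {
  stopifnot(inherits(traj, "kb_trajectory"))
  ia <- .resolve_selection(axis_atoms, nrow(traj$topology))
  it <- .resolve_selection(target_atoms, nrow(traj$topology))
  if (z_max > min(traj$box) / 2 + 1e-12)
    stop("z_max exceeds the half-box")
  nb <- ceiling(z_max / bin_width)
  edges <- seq(0, by = bin_width, length.out = nb + 1L)
  counts <- numeric(nb)
  norm <- 0
  ax <- NULL
  for (f in seq_len(n_frames(traj))) {
    box <- traj$box[f, ]
    ax <- helix_axis(frame_coords(traj, ia, f))
    L <- diff(ax$axial_extent)
    if (L <= 0) stop("zero slab length")
    rel <- .min_image_rel(frame_coords(traj, it, f), ax$origin, box)
    axial <- drop(rel %*% ax$direction)
    inside <- axial >= ax$axial_extent[1] & axial <= ax$axial_extent[2]
    perp <- rel[inside, , drop = FALSE] -
      outer(axial[inside], ax$direction)
    z <- sqrt(rowSums(perp^2))
    idx <- findInterval(z, edges)
    keep <- idx >= 1L & idx <= nb
    counts <- counts + tabulate(idx[keep], nbins = nb)
    rho <- if (is.null(bulk_density)) length(it) / prod(box) else bulk_density
    mid <- (edges[-1] + edges[-length(edges)]) / 2
    norm <- norm + rho * 2 * pi * mid * bin_width * L
  }
  structure(list(bin_edges = edges, g = counts / norm,
                 n_frames = n_frames(traj), axis = ax,
                 kind = "cylindrical"), class = "cylindrical_profile")
}

.min_image_rel <- function(coords, point, box) {
  dx <- sweep(coords, 2L, point, "-")
  for (k in 1:3) dx[, k] <- dx[, k] - box[k] * round(dx[, k] / box[k])
  dx
}

#' Radial solvent distribution about the solute centroid
#'
#' Per frame, the centroid of the selected solute atoms is taken as the
#' origin; target atoms are histogrammed by minimum-image radial
#' distance with spherical-shell normalization (the natural reference
#' frame for the roughly globular coil).
#'
#' @param traj a [kb_trajectory()].
#' @param solute_atoms selection whose centroid defines the origin.
#' @param target_atoms selection of atoms to histogram.
#' @param bin_width bin width (nm).
#' @param r_max histogram range (nm); at most the half-box.
#' @param bulk_density optional bulk target-atom density (atoms/nm^3).
#' @return Object of class `radial_profile` (centroid-referenced).
#' @export
centroid_radial_distribution <- function(traj, solute_atoms, target_atoms,
                                         bin_width = 0.05, r_max,
                                         bulk_density = NULL) {
  stopifnot(inherits(traj, "kb_trajectory"))
  is_ <- .resolve_selection(solute_atoms, nrow(traj$topology))
  it <- .resolve_selection(target_atoms, nrow(traj$topology))
  if (r_max > min(traj$box) / 2 + 1e-12)
    stop("r_max exceeds the half-box")
  nb <- ceiling(r_max / bin_width)
  edges <- seq(0, by = bin_width, length.out = nb + 1L)
  nf <- n_frames(traj)
  counts <- matrix(0, nf, nb)
  rho_b <- numeric(nf)
  for (f in seq_len(nf)) {
    box <- traj$box[f, ]
    centre <- colMeans(frame_coords(traj, is_, f))
    rel <- .min_image_rel(frame_coords(traj, it, f), centre, box)
    r <- sqrt(rowSums(rel^2))
    idx <- findInterval(r, edges)
    keep <- idx >= 1L & idx <= nb
    counts[f, ] <- tabulate(idx[keep], nbins = nb)
    rho_b[f] <- if (is.null(bulk_density)) length(it) / prod(box)
                else bulk_density
  }
  vshell <- (4 * pi / 3) * diff(edges^3)
  g <- colMeans(counts / outer(rho_b, vshell))
  structure(list(bin_edges = edges, g = g, counts = counts, n_a = 1L,
                 rho_b = rho_b, shell_volumes = vshell, n_frames = nf,
                 pair_label = c(a = "centroid", b = "target"),
                 conformation = NULL), class = "radial_profile")
}

#' Orientation histogram of a dipolar cosolvent versus distance
#'
#' For each cosolvent molecule, u is the unit vector from the reference
#' toward its tail atom (axis mode: the perpendicular foot-to-atom
#' direction) and v the tail-to-head unit vector; cos theta = u.v.
#' cos theta = +1 means the tail points at the protein, -1 means the head
#' group does (the reverse-micelle-like arrangement when the head is the
#' hydroxyl). Molecules are binned by the tail atom's distance and the
#' histogram is normalized to unit integral over cos theta within each
#' distance bin.
#'
#' @param traj a [kb_trajectory()].
#' @param tail_atoms,head_atoms equal-length selections: tail and head
#'   atom of each cosolvent molecule, in matching order.
#' @param reference "centroid" (of `solute_atoms`) or "axis" (helix axis
#'   from `solute_atoms`).
#' @param solute_atoms selection defining the reference.
#' @param distance_breaks distance bin edges (nm), default 0.15 nm bins
#'   up to 3 nm.
#' @param n_costheta_bins number of cos theta bins (default 40).
#' @return Object of class `orientation_histogram`: `distance_breaks`,
#'   `cos_breaks`, `counts` (distance x cos theta), `P` (per-distance-bin
#'   density over cos theta), `mean_costheta`, per-shell `n`, `sd`, and
#'   `skipped` (degenerate molecules).
#' @export
orientation_histogram <- function(traj, tail_atoms, head_atoms,
                                  reference = c("centroid", "axis"),
                                  solute_atoms,
                                  distance_breaks = seq(0, 3, by = 0.15),
                                  n_costheta_bins = 40L) {
  reference <- match.arg(reference)
  stopifnot(inherits(traj, "kb_trajectory"))
  it <- .resolve_selection(tail_atoms, nrow(traj$topology))
  ih <- .resolve_selection(head_atoms, nrow(traj$topology))
  if (length(it) != length(ih))
    stop("tail and head selections must pair up")
  is_ <- .resolve_selection(solute_atoms, nrow(traj$topology))
  nd <- length(distance_breaks) - 1L
  cos_breaks <- seq(-1, 1, length.out = n_costheta_bins + 1L)
  counts <- matrix(0, nd, n_costheta_bins)
  s1 <- numeric(nd); s2 <- numeric(nd); nsh <- numeric(nd)
  skipped <- 0L
  for (f in seq_len(n_frames(traj))) {
    box <- traj$box[f, ]
    tails <- frame_coords(traj, it, f)
    heads <- frame_coords(traj, ih, f)
    v <- heads - tails
    for (k in 1:3) v[, k] <- v[, k] - box[k] * round(v[, k] / box[k])
    vn <- sqrt(rowSums(v^2))
    ok <- vn > 1e-9
    skipped <- skipped + sum(!ok)
    sol <- frame_coords(traj, is_, f)
    if (reference == "centroid") {
      centre <- colMeans(sol)
      rel <- .min_image_rel(tails, centre, box)
    } else {
      ax <- helix_axis(sol)
      rel <- .min_image_rel(tails, ax$origin, box)
      axial <- drop(rel %*% ax$direction)
      rel <- rel - outer(axial, ax$direction)   # foot-to-atom direction
    }
    dist <- sqrt(rowSums(rel^2))
    u <- rel / pmax(dist, 1e-12)
    ct <- rowSums(u * (v / pmax(vn, 1e-12)))
    ct <- pmin(1, pmax(-1, ct))
    di <- findInterval(dist, distance_breaks, rightmost.closed = TRUE)
    ci <- findInterval(ct, cos_breaks, rightmost.closed = TRUE)
    keep <- ok & di >= 1L & di <= nd & ci >= 1L & ci <= n_costheta_bins
    if (any(keep)) {
      tab <- table(factor(di[keep], levels = seq_len(nd)),
                   factor(ci[keep], levels = seq_len(n_costheta_bins)))
      counts <- counts + unclass(tab)
      s1 <- s1 + vapply(seq_len(nd), function(d)
        sum(ct[keep & di == d]), numeric(1))
      s2 <- s2 + vapply(seq_len(nd), function(d)
        sum(ct[keep & di == d]^2), numeric(1))
      nsh <- nsh + vapply(seq_len(nd), function(d)
        sum(keep & di == d), numeric(1))
    }
  }
  dct <- diff(cos_breaks)[1]
  row_tot <- rowSums(counts)
  P <- counts / (pmax(row_tot, 1) * dct)
  P[row_tot == 0, ] <- NA_real_
  mean_ct <- ifelse(nsh > 0, s1 / nsh, NA_real_)
  var_ct <- ifelse(nsh > 1, (s2 - s1^2 / pmax(nsh, 1)) / pmax(nsh - 1, 1),
                   NA_real_)
  structure(list(distance_breaks = distance_breaks, cos_breaks = cos_breaks,
                 counts = counts, P = P, mean_costheta = mean_ct,
                 sd_costheta = sqrt(pmax(var_ct, 0)), n = nsh,
                 skipped = skipped, reference = reference),
            class = "orientation_histogram")
}

#' @export
print.orientation_histogram <- function(x, ...) {
  cat(sprintf(
    "Orientation histogram (%s reference): %d distance x %d cos-theta bins, %d molecules binned\n",
    x$reference, nrow(x$counts), ncol(x$counts), sum(x$n)))
  invisible(x)
}

#' Reverse-micelle orientation detector
#'
#' Per distance shell, tests whether the mean cos theta is below zero
#' (head groups pointing toward the protein) by a one-sided z-test at
#' significance `alpha`. Fires on inward-biased solvation shells, not on
#' isotropic ones.
#'
#' @param hist an [orientation_histogram()].
#' @param alpha significance level (default 0.01).
#' @param min_n minimum molecules per shell to test (default 50).
#' @return Data frame per shell: `d_lo`, `d_hi`, `n`, `mean_costheta`,
#'   `z`, `inward` (logical).
#' @export
reverse_micelle_test <- function(hist, alpha = 0.01, min_n = 50L) {
  nd <- length(hist$mean_costheta)
  se <- hist$sd_costheta / sqrt(pmax(hist$n, 1))
  z <- hist$mean_costheta / se
  crit <- stats::qnorm(alpha)
  data.frame(d_lo = hist$distance_breaks[-(nd + 1L)],
             d_hi = hist$distance_breaks[-1L],
             n = hist$n, mean_costheta = hist$mean_costheta, z = z,
             inward = hist$n >= min_n & is.finite(z) & z < crit)
}

#' Serialize an orientation histogram to a TSV matrix
#'
#' Rows are distance bins, columns cos-theta bins; `#` metadata lines
#' record the binning and reference convention.
#'
#' @param x an [orientation_histogram()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_orientation_tsv <- function(x, path) {
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(c(sprintf("# kbsolv orientation_histogram reference=%s",
                       x$reference),
               sprintf("# distance_breaks=%s",
                       paste(x$distance_breaks, collapse = ",")),
               sprintf("# cos_breaks=%s",
                       paste(signif(x$cos_breaks, 6), collapse = ","))), con)
  utils::write.table(x$P, con, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}
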