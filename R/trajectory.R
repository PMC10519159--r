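#' Trajectory container
#'
#' A trajectory couples one fixed topology with an ordered stack of frames.
#' Coordinates are stored as an `n_atoms x 3 x n_frames` array in nm and
#' boxes as an `n_frames x 3` matrix of orthorhombic edge lengths in nm
#' (triclinic cells are not supported).
#'
#' @param topology topology data frame (see [kb_topology()]).
#' @param coords numeric array `n_atoms x 3 x n_frames` (a plain
#'   `n_atoms x 3` matrix is promoted to a single frame).
#' @param box numeric `n_frames x 3` matrix or length-3 vector recycled to
#'   all frames.
#' @return Object of class `kb_trajectory`.
#' @export
kb_trajectory <- function(topology, coords, box) {
  topology <- kb_topology(topology)
  if (is.matrix(coords)) coords <- array(coords, dim = c(dim(coords), 1L))
  stopifnot(is.array(coords), length(dim(coords)) == 3L, dim(coords)[2] == 3L)
  n_atoms <- dim(coords)[1]
  n_frames <- dim(coords)[3]
  if (n_frames < 1L) stop("trajectory must contain at least one frame")
  if (n_atoms != nrow(topology))
    stop(sprintf("coordinate count (%d) does not match topology atom count (%d)",
                 n_atoms, nrow(topology)))
  if (is.null(dim(box))) box <- matrix(box, nrow = n_frames, ncol = 3L, byrow = TRUE)
  stopifnot(nrow(box) == n_frames, ncol(box) == 3L)
  if (any(!is.finite(box)) || any(box <= 0))
    stop("box edge lengths must be positive and finite")
  structure(list(topology = topology, coords = coords, box = box),
            class = "kb_trajectory")
}

#' @export
print.kb_trajectory <- function(x, ...) {
  cat(sprintf("Trajectory: %d atoms, %d frame(s), box %s nm\n",
              dim(x$coords)[1], n_frames(x),
              paste(signif(x$box[1, ], 4), collapse = " x ")))
  tab <- table(x$topology$species)
  cat("  atoms by species:",
      paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj `kb_trajectory`.
#' @return Integer frame count.
#' @export
n_frames <- function(traj) dim(traj$coords)[3]

#' Extract one frame
#' @param traj `kb_trajectory`.
#' @param i frame index.
#' @return List with `box` (length-3) and `coords` (`n_atoms x 3` matrix).
#' @export
get_frame <- function(traj, i) {
  stopifnot(i >= 1L, i <= n_frames(traj))
  list(box = traj$box[i, ], coords = traj$coords[, , i, drop = TRUE])
}

## Coordinates of selected atoms in frame f, always as an n x 3 matrix.
frame_coords <- function(traj, idx, f) {
  matrix(traj$coords[idx, , f], ncol = 3L)
}

## Minimum-image pairwise distances between two coordinate sets under an
## orthorhombic box. Returns an n_a x n_b matrix.
min_image_distances <- function(a, b, box) {
  stopifnot(ncol(a) == 3L, ncol(b) == 3L, length(box) == 3L)
  d2 <- 0
  for (k in 1:3) {
    dx <- outer(a[, k], b[, k], "-")
    dx <- dx - box[k] * round(dx / box[k])
    d2 <- d2 + dx * dx
  }
  sqrt(d2)
}

## Minimum-image displacement of one point set relative to a single point.
min_image_from_point <- function(coords, point, box) {
  dx <- sweep(coords, 2L, point, "-")
  for (k in 1:3) dx[, k] <- dx[, k] - box[k] * round(dx[, k] / box[k])
  dx
}
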