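#' @export
plot.radial_profile <- function(x, ..., xlab = "r (nm)", ylab = "g(r)") {
  mid <- (x$bin_edges[-1] + x$bin_edges[-length(x$bin_edges)]) / 2
  graphics::plot(mid, x$g, type = "l", xlab = xlab, ylab = ylab, ...)
  graphics::abline(h = 1, lty = 3)
  invisible(x)
}

#' @export
plot.kb_integral <- function(x, ..., xlab = "R (nm)",
                             ylab = expression(G(R) ~ (nm^3))) {
  graphics::plot(x$R_grid, x$G_of_R, type = "l", xlab = xlab, ylab = ylab,
                 ...)
  if (!is.na(x$G_infinity)) graphics::abline(h = x$G_infinity, lty = 3)
  invisible(x)
}

#' @export
plot.stability_model <- function(x, ..., xlab = "[cosolvent] (M)",
                                 ylab = expression(Delta * G ~ (kcal/mol))) {
  graphics::plot(x$curve$conc_M, x$curve$delta_g, type = "l", xlab = xlab,
                 ylab = ylab, ...)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}
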