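#' Concentration-fluctuation factor a33 from bulk KB integrals
#'
#' \eqn{a_{33} = 1 / (1 + \rho_3 (G_{33} - G_{31}))}. Values below 1
#' signal cosolvent clustering (large concentration fluctuations) and
#' amplify the excess preferential solvation at fixed m-value.
#'
#' @param rho3 cosolvent number density (nm^-3).
#' @param G33 cosolvent-cosolvent bulk KB integral (nm^3).
#' @param G31 cosolvent-water bulk KB integral (nm^3).
#' @return a33 (dimensionless).
#' @examples
#' a33_from_bulk(1, 4, 0)  # 0.2
#' @export
a33_from_bulk <- function(rho3, G33, G31) {
  den <- 1 + rho3 * (G33 - G31)
  if (any(den <= 0))
    stop("1 + rho3*(G33 - G31) <= 0: thermodynamically unstable input")
  1 / den
}

#' Bulk KB-integral table with a33
#'
#' Builds (or reads from TSV with columns `conc_M`, `G33_nm3`, `G31_nm3`)
#' a concentration grid of bulk KB integrals and the derived a33.
#'
#' @param conc_M cosolvent concentrations (mol/L), increasing.
#' @param G33,G31 bulk KB integrals (nm^3) on that grid.
#' @return Data frame of class `bulk_kb_table` with columns `conc_M`,
#'   `G33`, `G31`, `rho3`, `a33`.
#' @export
bulk_kb_table <- function(conc_M, G33, G31) {
  stopifnot(length(conc_M) == length(G33), length(G33) == length(G31),
            !is.unsorted(conc_M))
  rho3 <- density_from_molarity(conc_M)
  out <- data.frame(conc_M = conc_M, G33 = G33, G31 = G31, rho3 = rho3,
                    a33 = a33_from_bulk(rho3, G33, G31))
  class(out) <- c("bulk_kb_table", class(out))
  out
}

#' @rdname bulk_kb_table
#' @param path TSV path.
#' @export
read_bulk_kb_table <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           comment.char = "#")
  need <- c("conc_M", "G33_nm3", "G31_nm3")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("bulk KB table missing columns: ", paste(miss, collapse = ", "))
  bulk_kb_table(tab$conc_M, tab$G33_nm3, tab$G31_nm3)
}

## a33 evaluated on a concentration grid: constant, or linear
## interpolation in a bulk_kb_table (no extrapolation).
.a33_at <- function(a33, conc_M) {
  if (inherits(a33, "bulk_kb_table")) {
    rng <- range(a33$conc_M)
    out <- rep(NA_real_, length(conc_M))
    zero <- conc_M == 0
    out[zero] <- 1  # pure-water limit
    inside <- !zero & conc_M >= rng[1] & conc_M <= rng[2]
    if (any(!zero & !inside))
      stop("concentration outside the a33 table range [",
           rng[1], ", ", rng[2], "] M; no extrapolation")
    out[inside] <- stats::approx(a33$conc_M, a33$a33,
                                 xout = conc_M[inside])$y
    out
  } else {
    stopifnot(is.numeric(a33), all(a33 > 0))
    rep(a33, length.out = length(conc_M))
  }
}

#' m-value from the excess preferential solvation
#'
#' The linkage \eqn{m = \Delta\Gamma_{23}\, a_{33} / (\beta \rho_3)}
#' (equivalently \eqn{\Delta\Gamma_{23} = m \beta \rho_3 / a_{33}}, so an
#' a33 below 1 amplifies the excess solvation at fixed m). With m in
#' kcal mol^-1 M^-1, beta in mol/kcal and rho3 in mol/L the product is
#' dimensionless.
#'
#' @param delta_gamma excess preferential solvation (dimensionless), a
#'   number or a [delta_gamma()] result.
#' @param a33 concentration-fluctuation factor (> 0).
#' @param temperature temperature (K), used to form beta.
#' @param rho3_molar cosolvent concentration (mol/L), > 0.
#' @return m-value in kcal mol^-1 M^-1.
#' @examples
#' m_value(0.5032, a33 = 1, temperature = 300, rho3_molar = 2)  # ~0.15
#' @export
m_value <- function(delta_gamma, a33 = 1, temperature = 300, rho3_molar) {
  if (inherits(delta_gamma, "pbp_result"))
    delta_gamma <- delta_gamma$delta_gamma
  stopifnot(a33 > 0)
  if (rho3_molar <= 0) stop("rho3_molar must be positive")
  beta <- thermo_params(temperature)$beta
  delta_gamma * a33 / (beta * rho3_molar)
}

#' Project the excess preferential solvation across concentration
#'
#' Assuming a fixed m-value, \eqn{\Delta\Gamma_{23}(c) = m \beta c /
#' a_{33}(c)}: where a33 dips below 1 (cosolvent clustering) the excess
#' solvation is amplified.
#'
#' @param m m-value (kcal mol^-1 M^-1).
#' @param a33 constant a33 or a [bulk_kb_table()] (linear interpolation,
#'   no extrapolation).
#' @param temperature temperature (K).
#' @param c_grid concentrations (mol/L).
#' @return Data frame with `conc_M`, `a33`, `delta_gamma`.
#' @export
project_delta_gamma <- function(m, a33 = 1, temperature = 300, c_grid) {
  stopifnot(is.finite(m))
  beta <- thermo_params(temperature)$beta
  a <- .a33_at(a33, c_grid)
  data.frame(conc_M = c_grid, a33 = a, delta_gamma = m * beta * c_grid / a)
}

#' Linear cosolvent-dependence model of conformational stability
#'
#' \eqn{\Delta G_{helix}(c) = \Delta G_0 - m\,c}: the free-energy
#' difference (helix dimer minus two coils) as a linear function of
#' cosolvent molarity. A positive m stabilizes the helix with added
#' cosolvent (helix inducer); a negative m destabilizes it (denaturant).
#'
#' @param delta_g0 stability at zero cosolvent (kcal/mol).
#' @param m m-value (kcal mol^-1 M^-1).
#' @param c_grid concentrations (mol/L) at which to evaluate.
#' @return Object of class `stability_model` with `delta_g0`, `m_value`
#'   and the evaluated `curve` data frame.
#' @export
delta_g_curve <- function(delta_g0, m, c_grid = seq(0, 8, by = 0.5)) {
  structure(list(delta_g0 = delta_g0, m_value = m,
                 curve = data.frame(conc_M = c_grid,
                                    delta_g = delta_g0 - m * c_grid)),
            class = "stability_model")
}

#' @export
print.stability_model <- function(x, ...) {
  cat(sprintf("Stability model: dG(c) = %.4g - (%.4g) * c kcal/mol\n",
              x$delta_g0, x$m_value))
  cat(sprintf("  %s with added cosolvent\n",
              if (x$m_value > 0) "helix stabilized"
              else if (x$m_value < 0) "helix destabilized"
              else "no cosolvent dependence"))
  invisible(x)
}

#' @export
coef.stability_model <- function(object, ...) {
  c(delta_g0 = object$delta_g0, m_value = object$m_value)
}

#' @export
predict.stability_model <- function(object, conc_M = NULL, ...) {
  if (is.null(conc_M)) return(object$curve$delta_g)
  object$delta_g0 - object$m_value * conc_M
}
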