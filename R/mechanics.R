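#' Growth rate of in-plane bend modes
#'
#' Linear growth rate of a Fourier mode `exp(i q x)` of the in-plane
#' displacement u_y under the overdamped force balance:
#' sigma_y(q) = \[(zeta - mu) q^2 - K q^4\] / gamma.
#' Activity destabilises the mode once it exceeds the shear modulus; the
#' nematic elasticity K cuts growth off at large wavenumber.
#'
#' @param p an [elastomer_params()] object.
#' @param q wavenumber(s), um^-1, `q >= 0`.
#' @return Growth rate(s), s^-1 (vectorised over `q`).
#' @examples
#' p <- elastomer_params(zeta = 2, mu = 1, kappa = 0, K = 1)
#' growth_rate_in_plane(p, 1)   # marginal: exactly 0
#' @export
growth_rate_in_plane <- function(p, q) {
  stopifnot(inherits(p, "elastomer_params"))
  if (any(!is.finite(q))) stop("growth_rate_in_plane: q must be finite")
  if (any(q < 0)) stop("growth_rate_in_plane: q must be >= 0")
  ((p$zeta - p$mu) * q^2 - p$K * q^4) / p$gamma
}

#' Growth rate of out-of-plane buckling modes
#'
#' Linear growth rate of a height mode:
#' sigma_h(q) = \[zeta q^2 - (K + kappa) q^4\] / gamma.
#' Any non-zero activity destabilises long-wavelength height undulations --
#' the Euler-buckling analogue for an active sheet.
#'
#' @inheritParams growth_rate_in_plane
#' @return Growth rate(s), s^-1.
#' @examples
#' p <- elastomer_params(zeta = 2, mu = 1, kappa = 1, K = 1)
#' growth_rate_out_of_plane(p, 0.5)
#' @export
growth_rate_out_of_plane <- function(p, q) {
  stopifnot(inherits(p, "elastomer_params"))
  if (any(!is.finite(q))) stop("growth_rate_out_of_plane: q must be finite")
  if (any(q < 0)) stop("growth_rate_out_of_plane: q must be >= 0")
  (p$zeta * q^2 - (p$K + p$kappa) * q^4) / p$gamma
}

#' Most unstable mode of one instability branch
#'
#' Maximises the branch dispersion relation over wavenumber.  Closed forms:
#' in-plane, unstable iff zeta > mu, with `q* = sqrt((zeta - mu) / (2 K))`
#' and `sigma* = (zeta - mu)^2 / (4 gamma K)`; out-of-plane, unstable iff
#' zeta > 0, with `q* = sqrt(zeta / (2 (K + kappa)))` and
#' `sigma* = zeta^2 / (4 gamma (K + kappa))`.
#'
#' @param p an [elastomer_params()] object.
#' @param branch `"in_plane"` or `"out_of_plane"`.
#' @return An object of class `mode_result`: list with `branch`, `unstable`,
#'   `q_star` (um^-1), `lambda_star` (um), `sigma_star` (s^-1).  On a stable
#'   branch `q_star`/`lambda_star` are `NA` and `sigma_star` is 0 (the
#'   neutral q = 0 mode).
#' @examples
#' p <- elastomer_params(zeta = 2, mu = 1, kappa = 1, K = 1)
#' most_unstable_mode(p, "in_plane")
#' @export
most_unstable_mode <- function(p, branch = c("out_of_plane", "in_plane")) {
  stopifnot(inherits(p, "elastomer_params"))
  branch <- match.arg(branch)
  if (branch == "in_plane") {
    drive <- p$zeta - p$mu
    stiff <- p$K
  } else {
    drive <- p$zeta
    stiff <- p$K + p$kappa
  }
  if (drive <= 0) {
    res <- list(branch = branch, unstable = FALSE,
                q_star = NA_real_, lambda_star = NA_real_, sigma_star = 0)
  } else {
    if (stiff <= 0)
      stop("most_unstable_mode: unbounded growth at q -> Inf (vanishing ",
           "quartic stiffness on an unstable branch); no finite wavelength exists")
    q_star <- sqrt(drive / (2 * stiff))
    res <- list(branch = branch, unstable = TRUE,
                q_star = q_star,
                lambda_star = 2 * pi / q_star,
                sigma_star = drive^2 / (4 * p$gamma * stiff))
  }
  structure(res, class = "mode_result")
}

#' @export
print.mode_result <- function(x, ...) {
  if (x$unstable) {
    cat(sprintf("%s branch: unstable; q* = %.5g /um, lambda* = %.5g um, sigma* = %.5g /s\n",
                x$branch, x$q_star, x$lambda_star, x$sigma_star))
  } else {
    cat(sprintf("%s branch: stable (no growing mode)\n", x$branch))
  }
  invisible(x)
}

#' Critical activity-to-shear-modulus ratio for in-plane dominance
#'
#' The in-plane bend outgrows the out-of-plane buckle once
#' `zeta / mu > 1 / (1 - (1 + kappa/K)^(-1/2))`.  This is the boundary
#' between the regime where the sheet buckles out-of-plane even though both
#' branches are unstable, and the regime where it bends in-plane.  The
#' boundary diverges as kappa/K -> 0 (a floppy sheet always buckles) and
#' tends to 1 as kappa/K -> Inf.
#'
#' @param kappa_over_K ratio of bending to nematic elasticity,
#'   dimensionless, `> 0` and finite (vectorised).
#' @return The critical ratio zeta/mu (dimensionless), always `> 1` and
#'   strictly decreasing in `kappa_over_K`.
#' @examples
#' critical_activity_ratio(3)   # exactly 2
#' @export
critical_activity_ratio <- function(kappa_over_K) {
  if (any(!is.finite(kappa_over_K)))
    stop("critical_activity_ratio: kappa_over_K must be finite")
  if (any(kappa_over_K <= 0))
    stop("critical_activity_ratio: kappa_over_K must be > 0 ",
         "(the boundary diverges as kappa/K -> 0+)")
  1 / (1 - (1 + kappa_over_K)^(-0.5))
}

#' Classify the instability regime of the sheet
#'
#' Three regimes: (i) only out-of-plane modes are unstable
#' (`0 <= zeta/mu <= 1`); (ii) both branches are unstable but the
#' out-of-plane mode grows at least as fast
#' (`1 < zeta/mu <=` [critical_activity_ratio()]); (iii) the in-plane bend
#' grows faster (`zeta/mu` above the boundary).  Ties on the boundary
#' classify as out-of-plane, matching the strict inequality defining
#' regime iii.
#'
#' @param p an [elastomer_params()] object with `mu > 0` and `K > 0`.
#' @return An object of class `regime_label`: list with `regime` (one of
#'   `"i_out_only"`, `"ii_out_faster"`, `"iii_in_faster"`) and `direction`
#'   (`"out_of_plane"` or `"in_plane"`).
#' @examples
#' classify_regime(elastomer_params(zeta = 3, mu = 1, kappa = 3, K = 1))
#' @export
classify_regime <- function(p) {
  stopifnot(inherits(p, "elastomer_params"))
  if (p$mu <= 0)
    stop("classify_regime: fluid limit (mu = 0); the elastomer theory ",
         "becomes a fluid theory and the regimes are undefined")
  if (p$K <= 0)
    stop("classify_regime: K must be > 0")
  ratio <- p$zeta / p$mu
  if (ratio <= 1) {
    regime <- "i_out_only"
  } else if (ratio <= critical_activity_ratio(p$kappa / p$K)) {
    regime <- "ii_out_faster"
  } else {
    regime <- "iii_in_faster"
  }
  structure(list(regime = regime,
                 direction = if (regime == "iii_in_faster") "in_plane"
                             else "out_of_plane"),
            class = "regime_label")
}

#' @export
print.regime_label <- function(x, ...) {
  cat(sprintf("regime %s -> %s instability\n", x$regime, x$direction))
  invisible(x)
}

#' Deformation free energy of the sheet
#'
#' Discretised elastic free energy per unit width of a periodic 1D
#' deformation field (u_x, u_y, h):
#' F = 1/2 integral dx \[ nu (dx u_x)^2 + mu (dx u_y)^2 + kappa (dxx h)^2
#' + K ((dxx u_y)^2 + (dxx h)^2) \].
#' Derivatives are evaluated spectrally, so the quadrature is exact for
#' band-limited fields on the periodic grid.
#'
#' @param field a [deformation_field()] on a uniform periodic grid with at
#'   least 4 points.
#' @param p an [elastomer_params()] object.
#' @return Free energy, Pa um^3 per unit width; non-negative, zero for the
#'   flat state.
#' @examples
#' x <- seq(0, 2 * pi, length.out = 65)[-65]
#' f <- deformation_field(x, u_y = sin(x))
#' free_energy(f, elastomer_params(zeta = 0, mu = 1, kappa = 1, K = 1))  # pi
#' @export
free_energy <- function(field, p) {
  stopifnot(inherits(field, "deformation_field"),
            inherits(p, "elastomer_params"))
  n <- length(field$x)
  if (n < 4) stop("free_energy: grid must have at least 4 points")
  L <- field$L_dom
  q <- grid_wavenumbers(n, L)
  # Parseval: 1/2 int c (d^m f)^2 dx = (L/2) * sum_q c q^(2m) |f_hat|^2 / n^2
  pow <- function(f) Mod(fft(f))^2 / n^2
  uy <- pow(field$u_y)
  hh <- pow(field$h)
  ux <- pow(field$u_x)
  (L / 2) * sum(p$nu * q^2 * ux +
                p$mu * q^2 * uy +
                (p$kappa + p$K) * q^4 * hh +
                p$K * q^4 * uy)
}
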