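#' Coarse-grained mechanical state of the active sheet
#'
#' Bundles the continuum parameters of the thin active nematic elastomer:
#' the extensile activity, the elastic moduli penalising in-plane shear,
#' sheet curvature and director gradients, and the friction that sets the
#' relaxation timescale.
#'
#' @param zeta activity (coefficient of the dipolar active stress), Pa.
#'   Non-negative under the extensile convention used throughout.
#' @param mu shear modulus, Pa.
#' @param kappa effective bending modulus, Pa um^2.
#' @param K nematic (Frank) elasticity, Pa um^2.
#' @param nu effective bulk modulus, Pa.  Enters the deformation free energy
#'   through the axial mode only; that mode is never unstable, so `nu` does
#'   not affect stability results.
#' @param gamma friction coefficient, Pa s um^-2.  Sets the timescale of the
#'   overdamped dynamics; direction selection is independent of it.
#'
#' @return An object of class `elastomer_params`.
#' @examples
#' p <- elastomer_params(zeta = 2, mu = 1, kappa = 1, K = 1)
#' most_unstable_mode(p, "out_of_plane")
#' @export
elastomer_params <- function(zeta, mu, kappa, K, nu = 0, gamma = 1) {
  vals <- c(zeta = zeta, mu = mu, kappa = kappa, K = K, nu = nu, gamma = gamma)
  if (any(!is.finite(vals)))
    stop("elastomer_params: all parameters must be finite")
  if (zeta < 0) stop("elastomer_params: zeta must be >= 0 (extensile convention)")
  if (mu < 0 || kappa < 0 || K < 0 || nu < 0)
    stop("elastomer_params: moduli must be >= 0")
  if (gamma <= 0) stop("elastomer_params: gamma must be > 0")
  structure(list(zeta = zeta, mu = mu, kappa = kappa, K = K,
                 nu = nu, gamma = gamma),
            class = "elastomer_params")
}

#' @export
print.elastomer_params <- function(x, ...) {
  cat("Active elastomer parameters (Pa, um, s):\n")
  cat(sprintf("  zeta  = %g Pa (activity)\n", x$zeta))
  cat(sprintf("  mu    = %g Pa (shear modulus)\n", x$mu))
  cat(sprintf("  kappa = %g Pa.um^2 (bending modulus)\n", x$kappa))
  cat(sprintf("  K     = %g Pa.um^2 (nematic elasticity)\n", x$K))
  cat(sprintf("  nu    = %g Pa (bulk modulus), gamma = %g Pa.s/um^2\n",
              x$nu, x$gamma))
  invisible(x)
}

#' Molecular composition of the crosslinked network
#'
#' @param atp ATP concentration, uM.
#' @param motors kinesin motor-cluster concentration, nM.
#' @param prc1 PRC1 passive-crosslinker concentration, nM.
#' @param mt_length mean microtubule length, um.
#'
#' @return An object of class `composition`.  All fields may be vectors of a
#'   common length, which vectorises the downstream kinetics map.
#' @examples
#' composition(atp = 100, motors = 60, prc1 = 100, mt_length = 1.5)
#' @export
composition <- function(atp, motors, prc1, mt_length = 1.5) {
  n <- max(length(atp), length(motors), length(prc1), length(mt_length))
  atp <- rep_len(as.numeric(atp), n)
  motors <- rep_len(as.numeric(motors), n)
  prc1 <- rep_len(as.numeric(prc1), n)
  mt_length <- rep_len(as.numeric(mt_length), n)
  if (any(!is.finite(c(atp, motors, prc1, mt_length))))
    stop("composition: all fields must be finite")
  if (any(atp < 0) || any(motors < 0) || any(prc1 < 0))
    stop("composition: concentrations must be >= 0")
  if (any(mt_length <= 0))
    stop("composition: mt_length must be > 0")
  structure(list(atp = atp, motors = motors, prc1 = prc1,
                 mt_length = mt_length),
            class = "composition")
}

#' Kinetic constants mapping composition to mechanics
#'
#' Parameters of the reaction-kinetics map.  Only the three ratios
#' `zeta0/mu0`, `K0/kappa0`, `kappa0/zeta0` and the active-PRC1 fraction
#' `p0` affect which instability wins; the overall prefactor scale sets
#' absolute stresses only.
#'
#' @param zeta0 activity constant (efficiency of converting ATP hydrolysis
#'   into extensile stress), Pa nM^-1.
#' @param mu0 shear-modulus prefactor, Pa nM^-2.
#' @param kappa0 bending-modulus prefactor, Pa um^2 nM^-2.
#' @param K0 nematic-elasticity prefactor, Pa um^2 um^-a.
#' @param p0 fraction of PRC1 molecules that are functionally active, in
#'   \[0, 1\].
#' @param KM Michaelis constant (k_h + k_-)/k_b of motor stepping, uM.
#' @param length_exponent exponent `a` of the nematic-elasticity length law
#'   K = K0 * L^a.  The proper scaling for a microtubule nematic elastomer
#'   is ambiguous, so it is exposed as a parameter (default 2).
#'
#' @return An object of class `kinetic_constants`.
#' @examples
#' kinetic_constants(zeta0 = 1, mu0 = 2e-4, kappa0 = 0.5, K0 = 1000, p0 = 0.6)
#' @export
kinetic_constants <- function(zeta0, mu0, kappa0, K0, p0,
                              KM = 30, length_exponent = 2) {
  vals <- c(zeta0, mu0, kappa0, K0, p0, KM, length_exponent)
  if (any(!is.finite(vals))) stop("kinetic_constants: non-finite input")
  if (zeta0 < 0 || mu0 < 0 || kappa0 < 0 || K0 < 0)
    stop("kinetic_constants: prefactors must be >= 0")
  if (p0 < 0 || p0 > 1) stop("kinetic_constants: p0 must be in [0, 1]")
  if (KM <= 0) stop("kinetic_constants: KM must be > 0")
  structure(list(zeta0 = zeta0, mu0 = mu0, kappa0 = kappa0, K0 = K0,
                 p0 = p0, KM = KM, length_exponent = length_exponent),
            class = "kinetic_constants")
}

#' @export
print.kinetic_constants <- function(x, ...) {
  cat("Kinetic constants:\n")
  cat(sprintf("  zeta0 = %g Pa/nM, mu0 = %g Pa/nM^2\n", x$zeta0, x$mu0))
  cat(sprintf("  kappa0 = %g Pa.um^2/nM^2, K0 = %g Pa.um^2/um^%g\n",
              x$kappa0, x$K0, x$length_exponent))
  cat(sprintf("  p0 = %g, KM = %g uM\n", x$p0, x$KM))
  cat(sprintf("  identifiable ratios: zeta0/mu0 = %g, K0/kappa0 = %g, kappa0/zeta0 = %g\n",
              x$zeta0 / x$mu0, x$K0 / x$kappa0, x$kappa0 / x$zeta0))
  invisible(x)
}

#' Build kinetic constants from the identifiable ratios
#'
#' The direction of the instability depends on the prefactors only through
#' `zeta0/mu0`, `K0/kappa0`, `kappa0/zeta0` and `p0`; this helper fixes the
#' overall scale by `zeta0 = 1` and reconstructs the rest.
#'
#' @param r_zeta_mu ratio zeta0 / mu0.
#' @param r_K_kappa ratio K0 / kappa0.
#' @param r_kappa_zeta ratio kappa0 / zeta0.
#' @param p0,KM,length_exponent passed to [kinetic_constants()].
#' @param zeta0 overall stress scale (default 1).
#' @return A `kinetic_constants` object.
#' @examples
#' kinetic_constants_from_ratios(1200, 200, 0.5, p0 = 0.6)
#' @export
kinetic_constants_from_ratios <- function(r_zeta_mu, r_K_kappa, r_kappa_zeta,
                                          p0, KM = 30, length_exponent = 2,
                                          zeta0 = 1) {
  if (any(c(r_zeta_mu, r_K_kappa, r_kappa_zeta) <= 0))
    stop("ratios must be > 0")
  kappa0 <- r_kappa_zeta * zeta0
  kinetic_constants(zeta0 = zeta0,
                    mu0 = zeta0 / r_zeta_mu,
                    kappa0 = kappa0,
                    K0 = r_K_kappa * kappa0,
                    p0 = p0, KM = KM, length_exponent = length_exponent)
}
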