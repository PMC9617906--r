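#' Michaelis-Menten stepping fraction
#'
#' Fraction of motor clusters that are ATP-bound and stepping,
#' `[ATP] / (KM + [ATP])`, where the Michaelis constant
#' `KM = (k_h + k_-) / k_b` lumps the hydrolysis, unbinding and binding
#' rates of ATP on kinesin.
#'
#' @param atp ATP concentration, uM (vectorised), `>= 0`.
#' @param KM Michaelis constant, uM, `> 0`.
#' @return Stepping fraction in \[0, 1).
#' @examples
#' michaelis_menten_fraction(30, 30)   # half-saturation
#' @export
michaelis_menten_fraction <- function(atp, KM) {
  if (any(!is.finite(atp)) || !is.finite(KM))
    stop("michaelis_menten_fraction: non-finite input")
  if (any(atp < 0)) stop("michaelis_menten_fraction: atp must be >= 0")
  if (KM <= 0) stop("michaelis_menten_fraction: KM must be > 0")
  atp / (KM + atp)
}

#' Active stress from motor kinetics
#'
#' The extensile activity is proportional to the elongation rate of a
#' microtubule bundle, which depends linearly on the concentration of
#' stepping (ATP-bound) motor clusters:
#' `zeta = zeta0 * [motors] * [ATP] / (KM + [ATP])`.
#' Saturates at `zeta0 * [motors]` for abundant ATP and vanishes without
#' fuel.
#'
#' @param c a [composition()] object (fields may be vectors).
#' @param k a [kinetic_constants()] object.
#' @return Activity zeta, Pa (vectorised).
#' @examples
#' k <- kinetic_constants(1, 1, 1, 1, p0 = 0.6, KM = 30)
#' activity(composition(atp = 30, motors = 10, prc1 = 0), k)   # 5
#' @export
activity <- function(c, k) {
  stopifnot(inherits(c, "composition"), inherits(k, "kinetic_constants"))
  k$zeta0 * c$motors * michaelis_menten_fraction(c$atp, k$KM)
}

#' Effective crosslinker concentration
#'
#' Non-stepping motors act as passive crosslinkers, so the crosslinking
#' pool is `[XL] = p0 [PRC1] + [motors] (1 - f)` with `f` the
#' Michaelis-Menten stepping fraction: only the active fraction `p0` of
#' PRC1 counts, and every motor cluster not consuming ATP crosslinks
#' instead of sliding.  Decreases from `p0 [PRC1] + [motors]` at zero ATP
#' to `p0 [PRC1]` at saturating ATP.
#'
#' @inheritParams activity
#' @return Crosslinker concentration, nM (vectorised).
#' @examples
#' k <- kinetic_constants(1, 1, 1, 1, p0 = 0.6, KM = 30)
#' crosslinker_concentration(composition(atp = 0, motors = 60, prc1 = 100), k)
#' @export
crosslinker_concentration <- function(c, k) {
  stopifnot(inherits(c, "composition"), inherits(k, "kinetic_constants"))
  f <- michaelis_menten_fraction(c$atp, k$KM)
  k$p0 * c$prc1 + c$motors * (1 - f)
}

#' Elastic moduli from crosslinker density
#'
#' Above the isostatic transition the shear and bending moduli of a
#' crosslinked biopolymer network scale quadratically with crosslinker
#' concentration: `mu = mu0 [XL]^2`, `kappa = kappa0 [XL]^2`.  Their ratio
#' is therefore composition-independent.
#'
#' @inheritParams activity
#' @return A list with vectors `mu` (Pa) and `kappa` (Pa um^2).
#' @examples
#' k <- kinetic_constants(1, 1, 0.5, 1, p0 = 0.6)
#' moduli(composition(atp = 0, motors = 0, prc1 = 100), k)
#' @export
moduli <- function(c, k) {
  stopifnot(inherits(c, "composition"), inherits(k, "kinetic_constants"))
  xl <- crosslinker_concentration(c, k)
  list(mu = k$mu0 * xl^2, kappa = k$kappa0 * xl^2)
}

#' Nematic elasticity from filament length
#'
#' Longer microtubules stiffen the nematic: `K = K0 * L^a` with a
#' configurable exponent `a` (default 2), reflecting the acknowledged
#' ambiguity in the proper scaling for this material.
#'
#' @inheritParams activity
#' @return Nematic elasticity K, Pa um^2 (vectorised).
#' @examples
#' k <- kinetic_constants(1, 1, 1, K0 = 1, p0 = 0.6, length_exponent = 2)
#' nematic_elasticity(composition(1, 1, 1, mt_length = 1.5), k)   # 2.25
#' @export
nematic_elasticity <- function(c, k) {
  stopifnot(inherits(c, "composition"), inherits(k, "kinetic_constants"))
  k$K0 * c$mt_length^k$length_exponent
}

#' Map a molecular composition to coarse-grained mechanics
#'
#' Assembles the full mechanical state (zeta, mu, kappa, K, gamma) from a
#' single composition via the enzyme-kinetics map.  Downstream direction
#' predictions depend only on the ratios zeta0/mu0, K0/kappa0,
#' kappa0/zeta0 and on p0: rescaling all four prefactors by a common
#' factor rescales the stresses but leaves the regime unchanged.
#'
#' @param c a [composition()] with scalar fields (use
#'   [predict_grid()] for tables).
#' @param k a [kinetic_constants()] object.
#' @param gamma friction coefficient, Pa s um^-2 (free timescale).
#' @return An [elastomer_params()] object.
#' @examples
#' k <- kinetic_constants_from_ratios(1200, 200, 0.5, p0 = 0.6)
#' composition_to_mechanics(composition(1000, 60, 100), k)
#' @export
composition_to_mechanics <- function(c, k, gamma = 1) {
  stopifnot(inherits(c, "composition"), inherits(k, "kinetic_constants"))
  if (length(c$atp) != 1)
    stop("composition_to_mechanics: expects a scalar composition")
  m <- moduli(c, k)
  elastomer_params(zeta = activity(c, k),
                   mu = m$mu, kappa = m$kappa,
                   K = nematic_elasticity(c, k),
                   gamma = gamma)
}
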