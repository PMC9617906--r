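# Vectorised mechanics over a composition table: closed-form most-unstable
# growth rates and wavelengths for both branches, plus regime labels.
# Shared by the phase-diagram forward map and the inference likelihood.
mechanics_table <- function(c, k, gamma = 1) {
  zeta <- activity(c, k)
  m <- moduli(c, k)
  K <- nematic_elasticity(c, k)
  stiff_h <- K + m$kappa
  sigma_y <- ifelse(zeta > m$mu, (zeta - m$mu)^2 / (4 * gamma * K), 0)
  sigma_h <- ifelse(zeta > 0, zeta^2 / (4 * gamma * stiff_h), 0)
  lambda_y <- ifelse(zeta > m$mu,
                     2 * pi / sqrt(pmax(zeta - m$mu, 0) / (2 * K)), NA_real_)
  lambda_h <- ifelse(zeta > 0,
                     2 * pi / sqrt(pmax(zeta, 0) / (2 * stiff_h)), NA_real_)
  ratio <- zeta / m$mu
  bound <- critical_activity_ratio(m$kappa / K)
  regime <- ifelse(ratio <= 1, "i_out_only",
                   ifelse(ratio <= bound, "ii_out_faster", "iii_in_faster"))
  direction <- ifelse(zeta <= 0, "stable",
                      ifelse(regime == "iii_in_faster", "in_plane",
                             "out_of_plane"))
  lambda_star <- ifelse(direction == "in_plane", lambda_y,
                        ifelse(direction == "out_of_plane", lambda_h,
                               NA_real_))
  data.frame(zeta = zeta, mu = m$mu, kappa = m$kappa, K = K,
             zeta_over_mu = ratio,
             sigma_y_star = sigma_y, sigma_h_star = sigma_h,
             regime = regime, direction = direction,
             lambda_y = lambda_y, lambda_h = lambda_h,
             lambda_star = lambda_star)
}

# Build a (vector) composition from two scanned axes plus fixed fields.
cell_composition <- function(vals, fixed) {
  defaults <- list(atp = NA_real_, motors = NA_real_, prc1 = NA_real_,
                   mt_length = 1.5)
  fields <- utils::modifyList(defaults, c(fixed, vals))
  if (any(is.na(unlist(fields[c("atp", "motors", "prc1")]))))
    stop("composition underdetermined: supply atp, motors, prc1 via axes or fixed")
  composition(fields$atp, fields$motors, fields$prc1, fields$mt_length)
}

#' Predict instability direction over a composition grid
#'
#' Forward-maps every cell of the Cartesian product of two composition axes
#' through the kinetics map and the linear-stability classification -- the
#' computational twin of an experimental phase diagram.
#'
#' @param axes named list of exactly two numeric vectors; names must be
#'   among `atp`, `motors`, `prc1`, `mt_length` (units uM, nM, nM, um).
#' @param fixed named list giving the remaining composition fields.
#' @param k a [kinetic_constants()] object.
#' @param gamma friction coefficient (does not affect direction).
#' @return A `phase_grid` data frame: one row per cell with the axis
#'   values, mechanical parameters, `zeta_over_mu`, `regime`, `direction`
#'   (`"in_plane"`, `"out_of_plane"`, or `"stable"` where no branch grows,
#'   e.g. at zero ATP) and `lambda_star` (um) of the winning branch.
#' @examples
#' k <- kinetic_constants_from_ratios(1200, 200, 0.5, p0 = 0.6)
#' g <- predict_grid(list(atp = c(10, 100, 1000), prc1 = c(50, 200)),
#'                   fixed = list(motors = 60), k)
#' table(g$direction)
#' @export
predict_grid <- function(axes, fixed, k, gamma = 1) {
  stopifnot(inherits(k, "kinetic_constants"))
  if (length(axes) != 2 || is.null(names(axes)) || any(names(axes) == ""))
    stop("predict_grid: axes must be a named list of two numeric vectors")
  ok <- c("atp", "motors", "prc1", "mt_length")
  if (!all(names(axes) %in% ok))
    stop("predict_grid: axis names must be among ", paste(ok, collapse = ", "))
  if (any(lengths(axes) == 0)) stop("predict_grid: empty axis")
  cells <- expand.grid(axes, KEEP.OUT.ATTRS = FALSE)
  comp <- cell_composition(as.list(cells), fixed)
  out <- cbind(cells, mechanics_table(comp, k, gamma))
  attr(out, "axes") <- names(axes)
  attr(out, "fixed") <- fixed
  class(out) <- c("phase_grid", "data.frame")
  out
}

#' Extract the instability wavelength over a predicted grid
#'
#' @param grid a `phase_grid` from [predict_grid()].
#' @return Data frame with the axis columns, `direction` and `lambda_star`
#'   (um; `NA` for stable cells).  The wavelength is that of the
#'   faster-growing branch: `2 pi sqrt(2 (K + kappa) / zeta)` out-of-plane,
#'   `2 pi sqrt(2 K / (zeta - mu))` in-plane.
#' @examples
#' k <- kinetic_constants_from_ratios(1200, 200, 0.5, p0 = 0.6)
#' g <- predict_grid(list(atp = c(10, 1000), prc1 = c(50, 200)),
#'                   fixed = list(motors = 60), k)
#' wavelength_map(g)
#' @export
wavelength_map <- function(grid) {
  stopifnot(inherits(grid, "phase_grid"))
  ax <- attr(grid, "axes")
  out <- grid[, c(ax, "direction", "lambda_star")]
  class(out) <- "data.frame"
  out
}

#' Trace the in-plane/out-of-plane phase boundary
#'
#' For each value of the first axis, scans the second axis for sign changes
#' of the growth-rate difference `sigma_y* - sigma_h*` and refines each
#' crossing by bisection.  Supports up to `max_crossings` crossings per
#' scan line, which captures re-entrant boundaries (out -> in -> out).
#' Returned points satisfy `|sigma_y* - sigma_h*| <= tol * max(sigma_h*,
#' eps)` and, equivalently, the closed-form condition
#' `zeta/mu = ` [critical_activity_ratio()]`(kappa/K)` to the same
#' tolerance.
#'
#' @param axis1 list with `name` and `values`: scan-line positions.
#' @param axis2 list with `name` and `values`: range scanned for crossings
#'   (the values are used as bracketing knots; supply enough to resolve
#'   re-entrance).
#' @param fixed named list of the remaining composition fields.
#' @param k a [kinetic_constants()] object.
#' @param gamma friction coefficient.
#' @param tol relative tolerance on the growth-rate match.
#' @param max_crossings maximum crossings sought per scan line (default 2).
#' @return Data frame with columns `<axis1 name>`, `<axis2 name>` and
#'   `crossing` (1-based index along the scan line); zero rows if no line
#'   changes direction.
#' @examples
#' k <- kinetic_constants_from_ratios(1200, 200, 0.5, p0 = 0.6)
#' b <- boundary_trace(list(name = "prc1", values = c(50, 100, 200)),
#'                     list(name = "atp", values = 10^seq(0, 3.2, length.out = 60)),
#'                     fixed = list(motors = 60), k)
#' @export
boundary_trace <- function(axis1, axis2, fixed, k, gamma = 1,
                           tol = 1e-6, max_crossings = 2) {
  stopifnot(inherits(k, "kinetic_constants"))
  gdiff <- function(v1, v2) {
    vals <- stats::setNames(list(v1, v2), c(axis1$name, axis2$name))
    mt <- mechanics_table(cell_composition(vals, fixed), k, gamma)
    mt$sigma_y_star - mt$sigma_h_star
  }
  rows <- list()
  for (v1 in axis1$values) {
    g <- gdiff(v1, axis2$values)
    sgn <- sign(g)
    idx <- which(sgn[-1] * sgn[-length(sgn)] < 0 |
                 (sgn[-length(sgn)] != 0 & sgn[-1] == 0))
    if (length(idx) > max_crossings) idx <- idx[seq_len(max_crossings)]
    ci <- 0
    for (i in idx) {
      lo <- axis2$values[i]; hi <- axis2$values[i + 1]
      for (it in 1:200) {
        mid <- 0.5 * (lo + hi)
        gm <- gdiff(v1, mid)
        mt <- mechanics_table(
          cell_composition(stats::setNames(list(v1, mid),
                                           c(axis1$name, axis2$name)), fixed),
          k, gamma)
        if (abs(gm) <= tol * max(mt$sigma_h_star, .Machine$double.eps)) break
        if (sign(gm) == sign(gdiff(v1, lo))) lo <- mid else hi <- mid
      }
      ci <- ci + 1
      rows[[length(rows) + 1]] <-
        stats::setNames(data.frame(v1, mid, ci),
                        c(axis1$name, axis2$name, "crossing"))
    }
  }
  if (length(rows) == 0) {
    out <- stats::setNames(
      data.frame(numeric(0), numeric(0), integer(0)),
      c(axis1$name, axis2$name, "crossing"))
    return(out)
  }
  do.call(rbind, rows)
}
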