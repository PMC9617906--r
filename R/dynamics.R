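#' Discretised deformation field on a periodic 1D grid
#'
#' Holds the small-deformation fields (u_x, u_y, h) of the sheet sampled on
#' a uniform periodic grid along the initial alignment direction.
#'
#' @param x grid positions, um; must be uniformly spaced.  The domain length
#'   is inferred as `n * dx` (the point after the last wraps to the first).
#' @param u_y in-plane transverse displacement, um.
#' @param h out-of-plane height, um.
#' @param u_x axial displacement, um (passive mode; optional).
#' @param t time stamp, s.
#' @return An object of class `deformation_field`.
#' @examples
#' x <- seq(0, 512, length.out = 257)[-257]
#' deformation_field(x, u_y = 1e-4 * sin(2 * pi * x / 64))
#' @export
deformation_field <- function(x, u_y = numeric(length(x)),
                              h = numeric(length(x)),
                              u_x = numeric(length(x)), t = 0) {
  n <- length(x)
  if (n < 4) stop("deformation_field: need at least 4 grid points")
  dx <- diff(x)
  if (any(abs(dx - dx[1]) > 1e-9 * abs(dx[1])))
    stop("deformation_field: grid must be uniform")
  if (length(u_y) != n || length(h) != n || length(u_x) != n)
    stop("deformation_field: field lengths must match the grid")
  structure(list(x = x, u_y = as.numeric(u_y), h = as.numeric(h),
                 u_x = as.numeric(u_x), t = t,
                 L_dom = n * dx[1]),
            class = "deformation_field")
}

#' @export
print.deformation_field <- function(x, ...) {
  cat(sprintf("deformation field: %d points, L = %g um, t = %g s\n",
              length(x$x), x$L_dom, x$t))
  cat(sprintf("  rms u_y = %.4g um, rms h = %.4g um\n",
              sqrt(mean(x$u_y^2)), sqrt(mean(x$h^2))))
  invisible(x)
}

# FFT-ordered wavenumbers (absolute value) of an n-point periodic grid.
grid_wavenumbers <- function(n, L) {
  k <- c(0:(floor(n / 2)), -((ceiling(n / 2) - 1):1))
  abs(2 * pi * k / L)
}

#' Seed a deformation field with white noise
#'
#' Independent Gaussian noise per grid point and per field component, the
#' numerical stand-in for the thermal/experimental fluctuations that seed
#' the instability.  Reproducible for a given seed; the caller's RNG state
#' is left untouched.
#'
#' @param n_points number of grid points (powers of two keep the FFT fast).
#' @param L_dom domain length, um.
#' @param amplitude noise standard deviation, um.
#' @param seed integer seed (mandatory: the generators are contracts).
#' @return A `deformation_field` at `t = 0`.
#' @examples
#' f <- init_noise_field(256, 512, 1e-4, seed = 1)
#' @export
init_noise_field <- function(n_points = 1024, L_dom = 512,
                             amplitude = 1e-4, seed) {
  if (missing(seed)) stop("init_noise_field: seed is mandatory")
  if (n_points < 16) stop("init_noise_field: n_points must be >= 16")
  if (amplitude < 0) stop("init_noise_field: amplitude must be >= 0")
  x <- (0:(n_points - 1)) * (L_dom / n_points)
  with_preserved_seed(seed, {
    deformation_field(x,
                      u_y = rnorm(n_points, 0, amplitude),
                      h   = rnorm(n_points, 0, amplitude),
                      u_x = rnorm(n_points, 0, amplitude))
  })
}

# Run expr with a temporary RNG seed, restoring the caller's RNG state.
with_preserved_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Evolve a deformation field under the linear overdamped dynamics
#'
#' Each spatial Fourier mode is advanced exactly by its dispersion-relation
#' growth rate: `u_hat(q, t1) = u_hat(q, t0) * exp(sigma(q) (t1 - t0))`,
#' with sigma from [growth_rate_in_plane()] for u_y,
#' [growth_rate_out_of_plane()] for h, and the passive relaxation
#' `-nu q^2 / gamma` for u_x.  The dynamics are linear and diagonal in q,
#' so there is no time-discretisation error; this makes the simulator a
#' trustworthy numerical oracle for the closed-form stability results.
#'
#' @param field a [deformation_field()].
#' @param p an [elastomer_params()] object.
#' @param t_final target time, s; must be `>= field$t`.
#' @return The evolved `deformation_field` at `t_final`.
#' @examples
#' f <- init_noise_field(256, 512, 1e-4, seed = 7)
#' p <- elastomer_params(zeta = 2, mu = 1, kappa = 1, K = 1)
#' g <- evolve(f, p, t_final = 20)
#' @export
evolve <- function(field, p, t_final) {
  stopifnot(inherits(field, "deformation_field"),
            inherits(p, "elastomer_params"))
  dt <- t_final - field$t
  if (dt < 0) stop("evolve: t_final must be >= field$t")
  if (dt == 0) return(field)
  n <- length(field$x)
  q <- grid_wavenumbers(n, field$L_dom)
  sig_y <- growth_rate_in_plane(p, q)
  sig_h <- growth_rate_out_of_plane(p, q)
  sig_x <- -p$nu * q^2 / p$gamma
  # overflow guard: only modes actually present in a field can overflow
  prop <- function(f, sig) {
    fh <- fft(f)
    s <- sig * dt
    live <- Mod(fh) > 0
    if (any(s[live] > 700))
      stop("evolve: growth overflow; reduce t_final")
    s[!live] <- 0
    Re(fft(fh * exp(s), inverse = TRUE)) / n
  }
  deformation_field(field$x,
                    u_y = prop(field$u_y, sig_y),
                    h   = prop(field$h, sig_h),
                    u_x = prop(field$u_x, sig_x),
                    t = t_final)
}

#' Emergent wavelength of a branch from ensemble-averaged spectra
#'
#' Measures the wavelength selected by the linear instability the way a
#' repeated experiment would: seed the branch with white noise, let the
#' dynamics amplify it by a fixed factor (`exp(t_growth)` at the fastest
#' mode), average the power spectrum over `n_seeds` independent noise
#' realisations, and locate the spectral peak (parabolic interpolation on
#' log power).  Averaging suppresses the per-bin chi-squared noise that
#' can displace the peak of a single realisation when the dispersion
#' relation is nearly flat across neighbouring bins.
#'
#' @param p an [elastomer_params()] object; the branch must be unstable.
#' @param branch `"in_plane"` or `"out_of_plane"`.
#' @param seed integer seed (mandatory); realisation `i` uses `seed + i`.
#' @param n_seeds ensemble size.
#' @param n_points,L_dom,amplitude grid and noise settings, see
#'   [init_noise_field()].
#' @param t_growth log-amplification of the most unstable mode (capped by
#'   the overflow guard of [evolve()]).
#' @return Wavelength, um.
#' @examples
#' p <- elastomer_params(zeta = 2, mu = 1, kappa = 1, K = 1)
#' ensemble_dominant_wavelength(p, "out_of_plane", seed = 1, n_seeds = 4)
#' @export
ensemble_dominant_wavelength <- function(p, branch = c("out_of_plane",
                                                       "in_plane"),
                                         seed, n_seeds = 10,
                                         n_points = 512, L_dom = 256,
                                         amplitude = 1e-6, t_growth = 300) {
  branch <- match.arg(branch)
  if (missing(seed)) stop("ensemble_dominant_wavelength: seed is mandatory")
  m <- most_unstable_mode(p, branch)
  if (!m$unstable)
    stop("ensemble_dominant_wavelength: branch is stable; no wavelength selected")
  t_end <- t_growth / m$sigma_star
  x <- (0:(n_points - 1)) * (L_dom / n_points)
  fld <- if (branch == "in_plane") "u_y" else "h"
  acc <- numeric(n_points)
  for (i in seq_len(n_seeds)) {
    f0 <- init_noise_field(n_points, L_dom, amplitude, seed = seed + i)
    f <- if (branch == "in_plane") deformation_field(x, u_y = f0$u_y)
         else deformation_field(x, h = f0$h)
    g <- evolve(f, p, t_end)
    acc <- acc + Mod(fft(g[[fld]]))^2
  }
  spectral_peak_wavelength(acc, L_dom)
}

# Peak of a power spectrum (FFT order), q = 0 excluded, with parabolic
# interpolation of log power around the discrete maximum.
spectral_peak_wavelength <- function(pw, L_dom) {
  n <- length(pw)
  pw_pos <- pw[2:(floor(n / 2) + 1)]
  k <- which.max(pw_pos)
  dq <- 2 * pi / L_dom
  q_peak <- k * dq
  if (k > 1 && k < length(pw_pos)) {
    lp <- log(pmax(pw_pos[(k - 1):(k + 1)], .Machine$double.xmin))
    denom <- lp[1] - 2 * lp[2] + lp[3]
    if (is.finite(denom) && denom < 0) {
      delta <- 0.5 * (lp[1] - lp[3]) / denom
      q_peak <- (k + max(-0.5, min(0.5, delta))) * dq
    }
  }
  2 * pi / q_peak
}

#' Dominant wavelength of a deformation field component
#'
#' Locates the peak of the power spectrum (q = 0 excluded) and refines it
#' by parabolic interpolation of log-power over the peak and its two
#' neighbours, then returns `2 * pi / q_peak`.
#'
#' @param field a [deformation_field()].
#' @param which_field `"u_y"`, `"h"` or `"u_x"`.
#' @return Wavelength, um.
#' @examples
#' x <- seq(0, 512, length.out = 513)[-513]
#' f <- deformation_field(x, u_y = sin(2 * pi * x / 64))
#' dominant_wavelength(f, "u_y")   # 64 within a spectral bin
#' @export
dominant_wavelength <- function(field, which_field = c("u_y", "h", "u_x")) {
  stopifnot(inherits(field, "deformation_field"))
  which_field <- match.arg(which_field)
  f <- field[[which_field]]
  n <- length(f)
  if (max(abs(f - mean(f))) == 0)
    stop("dominant_wavelength: no dominant mode (flat field)")
  spectral_peak_wavelength(Mod(fft(f))^2, field$L_dom)
}
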