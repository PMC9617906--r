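# Periodic smooth Gaussian random field: white noise low-passed with a
# Gaussian spectral filter of correlation length `corr` (pixels), then
# standardised.  FFT-based, so cheap even for large correlation lengths.
smooth_field <- function(nx, ny, corr) {
  w <- matrix(rnorm(nx * ny), nx, ny)
  if (corr <= 0) return(w)
  kx <- grid_wavenumbers(nx, nx)      # 2*pi*freq in cycles/pixel
  ky <- grid_wavenumbers(ny, ny)
  filt <- exp(-outer(kx^2, ky^2, "+") * corr^2 / 2)
  f <- Re(fft(fft(w) * filt, inverse = TRUE)) / (nx * ny)
  (f - mean(f)) / max(sd(f), .Machine$double.eps)
}

# Aligned-bundle texture plus the smooth field used to carve defocus
# regions.  Consumes the current RNG stream.
bundle_texture_fields <- function(nx, ny, stripe_period = 9,
                                  undulation = 6, mask_corr = 48) {
  yy <- matrix(rep(seq_len(ny), each = nx), nx, ny)
  phase <- smooth_field(nx, ny, 24)
  amp <- 0.6 + 0.4 * stats::plogis(1.5 * smooth_field(nx, ny, 32))
  tex <- 0.5 + 0.28 * amp * sin(2 * pi * (yy + undulation * phase) / stripe_period)
  tex <- tex + 0.05 * smooth_field(nx, ny, 1)   # fine speckle
  tex <- pmin(pmax(tex, 0.02), 1)
  list(texture = tex, mask_field = smooth_field(nx, ny, mask_corr))
}

# Composite a sharp texture with its defocused copy inside a mask carved
# from a smooth field at the quantile matching `blurred_fraction`.
compose_defocus <- function(tex, mask_field, blurred_fraction,
                            defocus_sigma, noise_sd) {
  if (blurred_fraction <= 0) {
    mask <- matrix(FALSE, nrow(tex), ncol(tex))
    img <- tex
  } else if (blurred_fraction >= 1) {
    mask <- matrix(TRUE, nrow(tex), ncol(tex))
    img <- EBImage::gblur(tex, defocus_sigma)
  } else {
    lvl <- stats::quantile(mask_field, 1 - blurred_fraction, names = FALSE)
    mask <- mask_field >= lvl
    blurred <- EBImage::gblur(tex, defocus_sigma)
    w <- EBImage::gblur(mask + 0, 2)          # soft blend edge, ~2 px
    img <- tex * (1 - w) + blurred * w
  }
  if (noise_sd > 0)
    img <- img + noise_sd * sqrt(pmax(img, 0)) *
      matrix(rnorm(length(img)), nrow(img))
  list(image = pmax(img, 0), mask = mask)
}

#' Generate a microscopy-like image of aligned filament bundles
#'
#' Synthesises a widefield-fluorescence-like frame: an anisotropic striped
#' bundle texture with smooth undulations and fine speckle, with a random
#' smooth region of prescribed area fraction replaced by its Gaussian
#' defocused copy, plus Poisson-like shot noise.  The ground-truth defocus
#' mask is returned alongside, so image statistics can be scored exactly.
#'
#' @param blurred_fraction target out-of-focus area fraction in \[0, 1\].
#' @param seed integer seed (mandatory).
#' @param width,height image size in pixels (at least 64).
#' @param defocus_sigma Gaussian defocus kernel width, px.
#' @param noise_sd shot-noise scale (standard deviation at unit intensity).
#' @param stripe_period bundle spacing, px.
#' @param mask_corr correlation length of the defocus-region field, px;
#'   larger values give fewer, rounder out-of-focus domains.
#' @return An object of class `bundle_image`: list with `image` (matrix,
#'   arbitrary intensity units), `mask` (logical matrix, TRUE =
#'   out-of-focus) and `blurred_fraction` (realised mask area fraction,
#'   within 0.01 of the request).
#' @examples
#' bi <- generate_bundle_image(0.4, seed = 1, width = 128, height = 128)
#' mean(bi$mask)
#' @export
generate_bundle_image <- function(blurred_fraction, seed,
                                  width = 512, height = 512,
                                  defocus_sigma = 8, noise_sd = 0.01,
                                  stripe_period = 9, mask_corr = 48) {
  if (missing(seed)) stop("generate_bundle_image: seed is mandatory")
  if (blurred_fraction < 0 || blurred_fraction > 1)
    stop("generate_bundle_image: blurred_fraction must be in [0, 1]")
  if (width < 64 || height < 64)
    stop("generate_bundle_image: image must be at least 64x64")
  with_preserved_seed(seed, {
    tf <- bundle_texture_fields(width, height, stripe_period = stripe_period,
                                mask_corr = mask_corr)
    cd <- compose_defocus(tf$texture, tf$mask_field, blurred_fraction,
                          defocus_sigma, noise_sd)
    structure(list(image = cd$image, mask = cd$mask,
                   blurred_fraction = mean(cd$mask)),
              class = "bundle_image")
  })
}

#' Generate an image time series emulating a growing instability
#'
#' The out-of-focus area fraction follows logistic growth
#' `a(t) = a_max / (1 + exp(-(t - t0)/tau))`, emulating the progressive
#' escape of bundles out of the focal plane during out-of-plane buckling.
#' All frames share one texture and one defocus-region field, so the
#' out-of-focus domains grow in place (nested masks).
#'
#' @param times numeric vector of frame times, s (at least 3).
#' @param seed integer seed (mandatory).
#' @param a_max asymptotic blurred-area fraction.
#' @param t0 mid-growth time, s.
#' @param tau growth timescale, s.
#' @param width,height,defocus_sigma,noise_sd,stripe_period,mask_corr
#'   passed to the frame generator.
#' @return An object of class `bundle_series`: list with `times`, `frames`
#'   (list of intensity matrices), `masks`, and `fractions` (realised
#'   blurred-area fraction per frame, nondecreasing when `times` is
#'   increasing).
#' @examples
#' gs <- generate_growth_series(seq(0, 100, by = 25), seed = 2,
#'                              width = 96, height = 96)
#' gs$fractions
#' @export
generate_growth_series <- function(times, seed, a_max = 0.65, t0 = 50,
                                   tau = 15, width = 256, height = 256,
                                   defocus_sigma = 8, noise_sd = 0.01,
                                   stripe_period = 9, mask_corr = 48) {
  if (missing(seed)) stop("generate_growth_series: seed is mandatory")
  if (length(times) < 3) stop("generate_growth_series: need >= 3 frames")
  if (a_max < 0 || a_max > 1) stop("generate_growth_series: a_max in [0, 1]")
  fr <- a_max / (1 + exp(-(times - t0) / tau))
  with_preserved_seed(seed, {
    tf <- bundle_texture_fields(width, height, stripe_period = stripe_period,
                                mask_corr = mask_corr)
    frames <- vector("list", length(times))
    masks <- vector("list", length(times))
    for (i in seq_along(times)) {
      cd <- compose_defocus(tf$texture, tf$mask_field, fr[i],
                            defocus_sigma, noise_sd)
      frames[[i]] <- cd$image
      masks[[i]] <- cd$mask
    }
    structure(list(times = times, frames = frames, masks = masks,
                   fractions = vapply(masks, mean, numeric(1))),
              class = "bundle_series")
  })
}

#' Default synthetic-study configuration
#'
#' Ground truth and grid layout for the synthetic phase-diagram study.  The
#' four panels mirror the standard experimental scans of this system: ATP x
#' PRC1 at 60 nM motors, motors x PRC1 at 1 mM ATP, ATP x motors at 100 nM
#' PRC1, and microtubule length x motors at 8 uM ATP / 100 nM PRC1.  The
#' true kinetic ratios (zeta0/mu0 = 1200, K0/kappa0 = 200,
#' kappa0/zeta0 = 0.5, p0 = 0.6) place the in/out boundary inside the
#' scanned windows, give a re-entrant out-in-out band along the motor axis
#' at limiting ATP with the fluid extremum near 70 nM motors, and set
#' instability wavelengths of tens of micrometres.
#'
#' @param n1,n2 grid resolution per axis (default 10 x 10 per panel).
#' @param n_replicates replicates per grid cell.
#' @return A list: `k_true` ([kinetic_constants()]), `gamma`, `panels`
#'   (list of `axes` + `fixed` per panel), `n_replicates`,
#'   `b_concentration` (Beta concentration of blurriness noise), `b_means`
#'   (mean B for in-plane / mixed / out-of-plane draws), `mixed_band`
#'   (half-width on |log sigma-ratio| treated as near-boundary), and
#'   `lambda_sdlog` (lognormal wavelength noise).
#' @examples
#' cfg <- default_generator_config()
#' cfg$k_true
#' @export
default_generator_config <- function(n1 = 10, n2 = 10, n_replicates = 1) {
  list(
    k_true = kinetic_constants_from_ratios(1200, 200, 0.5, p0 = 0.6),
    gamma = 1,
    panels = list(
      atp_prc1 = list(axes = list(atp = 10^seq(0, log10(1500), length.out = n1),
                                  prc1 = seq(10, 500, length.out = n2)),
                      fixed = list(motors = 60, mt_length = 1.5)),
      motors_prc1 = list(axes = list(motors = seq(5, 200, length.out = n1),
                                     prc1 = seq(10, 500, length.out = n2)),
                         fixed = list(atp = 1000, mt_length = 1.5)),
      atp_motors = list(axes = list(atp = 10^seq(0, log10(1500), length.out = n1),
                                    motors = seq(5, 200, length.out = n2)),
                        fixed = list(prc1 = 100, mt_length = 1.5)),
      length_motors = list(axes = list(mt_length = seq(0.5, 10, length.out = n1),
                                       motors = seq(5, 200, length.out = n2)),
                           fixed = list(atp = 8, prc1 = 100))
    ),
    n_replicates = n_replicates,
    b_concentration = 50,
    b_means = c(in_plane = 0.02, mixed = 0.3, out_of_plane = 0.65),
    mixed_band = 0.4,
    lambda_sdlog = 0.2
  )
}

#' Generate synthetic phase-diagram observations
#'
#' For every cell of every configured panel (and replicate), computes the
#' true instability direction from the ground-truth kinetic constants,
#' then draws a noisy blurriness readout from a Beta distribution centred
#' at the regime-typical mean (0.02 in-plane, 0.65 out-of-plane); cells
#' whose most-unstable growth rates are nearly tied (|log sigma_h*/
#' sigma_y*| below `mixed_band`) draw from the mixed band instead.  A
#' wavelength observation with lognormal noise is attached wherever a
#' branch is unstable.  Ground-truth labels are stored alongside so every
#' downstream stage can be scored without external data.
#'
#' @param cfg configuration list as from [default_generator_config()].
#' @param seed integer seed (mandatory).
#' @return A data frame of class `phase_observations`: `panel`, `atp`,
#'   `motors`, `prc1`, `mt_length`, `replicate`, `B`, `lambda_obs` (um,
#'   `NA` for stable cells), plus ground truth `true_direction` and
#'   `true_log_sigma_ratio`.
#' @examples
#' obs <- generate_phase_observations(default_generator_config(4, 4), seed = 1)
#' table(obs$true_direction)
#' @export
generate_phase_observations <- function(cfg = default_generator_config(),
                                        seed) {
  if (missing(seed)) stop("generate_phase_observations: seed is mandatory")
  with_preserved_seed(seed, {
    rows <- lapply(names(cfg$panels), function(pn) {
      panel <- cfg$panels[[pn]]
      cells <- expand.grid(panel$axes, KEEP.OUT.ATTRS = FALSE)
      comp <- cell_composition(as.list(cells), panel$fixed)
      mt <- mechanics_table(comp, cfg$k_true, cfg$gamma)
      n <- nrow(cells)
      out <- do.call(rbind, lapply(seq_len(cfg$n_replicates), function(r) {
        lr <- log(mt$sigma_h_star / mt$sigma_y_star)   # +-Inf when one side stable
        band <- ifelse(mt$direction == "stable", "in_plane",
                ifelse(is.finite(lr) & abs(lr) < cfg$mixed_band, "mixed",
                ifelse(mt$direction == "out_of_plane", "out_of_plane",
                       "in_plane")))
        m <- cfg$b_means[band]
        conc <- cfg$b_concentration
        B <- rbeta(n, m * conc, (1 - m) * conc)
        lambda_obs <- ifelse(is.na(mt$lambda_star), NA_real_,
                             mt$lambda_star *
                               rlnorm(n, 0, cfg$lambda_sdlog))
        data.frame(panel = pn,
                   atp = comp$atp, motors = comp$motors,
                   prc1 = comp$prc1, mt_length = comp$mt_length,
                   replicate = r, B = B, lambda_obs = lambda_obs,
                   true_direction = mt$direction,
                   true_log_sigma_ratio = lr)
      }))
      out
    })
    res <- do.call(rbind, rows)
    rownames(res) <- NULL
    class(res) <- c("phase_observations", "data.frame")
    res
  })
}
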