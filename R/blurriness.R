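# Raw defocus score: variance of the Laplacian-of-Gaussian response in a
# w x w box window.  The sigma = 1 px pre-smoothing suppresses shot noise
# (which survives defocus and would otherwise dominate the Laplacian in
# blurred regions) while barely attenuating bundle-scale structure; the
# result is orders of magnitude higher where fine structure is in focus.
focus_map_raw <- function(image, window = 15, presmooth = 1) {
  if (!is.matrix(image) || any(!is.finite(image)))
    stop("focus_map: image must be a finite numeric matrix")
  if (nrow(image) < 64 || ncol(image) < 64)
    stop("focus_map: image must be at least 64x64")
  if (window < 3 || window %% 2 == 0)
    stop("focus_map: window must be an odd integer >= 3")
  s <- if (presmooth > 0) EBImage::gblur(image, presmooth) else image
  lap_kernel <- matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3)
  lap <- EBImage::filter2(s, lap_kernel, boundary = "replicate")
  box <- matrix(1 / window^2, window, window)
  m1 <- EBImage::filter2(lap, box, boundary = "replicate")
  m2 <- EBImage::filter2(lap^2, box, boundary = "replicate")
  pmax(m2 - m1^2, 0)
}

# Scale-invariant score: raw score over squared mean intensity.  The mean
# is preserved by defocus (a normalised kernel) and scales linearly with
# global intensity, so this is comparable across images and invariant to
# image -> c * image; normalising by the image *variance* would not be,
# since defocus collapses the variance itself.
focus_score_invariant <- function(v, image) {
  m <- mean(image)
  if (m <= 0) m <- sqrt(max(var(as.vector(image)), .Machine$double.xmin))
  v / m^2
}

#' Per-pixel focus score of a grayscale image
#'
#' Sliding-window variance of the (noise-suppressed) Laplacian, normalised
#' to \[0, 1\] by robust percentiles (1st/99th) of the raw score.  Higher
#' means sharper.  Invariant to global intensity rescaling.
#'
#' @param image numeric matrix (grayscale, any intensity scale), at least
#'   64 x 64, finite values.
#' @param window odd box-window side, px (default 15).
#' @return Matrix of focus scores in \[0, 1\], with attribute
#'   `raw_percentiles` (the 1st/99th raw-score percentiles used).  A
#'   constant image yields an all-zero map with a warning.
#' @examples
#' img <- generate_bundle_image(0, seed = 3, width = 96, height = 96)$image
#' range(focus_map(img))
#' @export
focus_map <- function(image, window = 15) {
  v <- focus_map_raw(image, window)
  p <- stats::quantile(v, c(0.01, 0.99), names = FALSE)
  if (var(as.vector(image)) == 0 || p[2] <= p[1]) {
    warning("focus_map: (near-)constant image; returning all-zero map")
    out <- matrix(0, nrow(image), ncol(image))
    attr(out, "raw_percentiles") <- p
    return(out)
  }
  out <- pmin(pmax((v - p[1]) / (p[2] - p[1]), 0), 1)
  attr(out, "raw_percentiles") <- p
  out
}

# Calibrated sharpness reference: median scale-invariant focus score of
# the package's own sharp and fully defocused bundle fixtures.  Resolves
# unimodal score histograms (all-sharp or all-blurred frames), where any
# relative threshold is meaningless.  Cached per (window, defocus).
.blur_cache <- new.env(parent = emptyenv())

sharpness_reference <- function(window = 15, defocus_sigma = 8) {
  key <- paste0("w", window, "s", defocus_sigma)
  if (!is.null(.blur_cache[[key]])) return(.blur_cache[[key]])
  sharp <- generate_bundle_image(0, seed = 196883, width = 192, height = 192,
                                 defocus_sigma = defocus_sigma)$image
  blurred <- generate_bundle_image(1, seed = 196883, width = 192, height = 192,
                                   defocus_sigma = defocus_sigma)$image
  s_ref <- median(focus_score_invariant(focus_map_raw(sharp, window), sharp))
  b_ref <- median(focus_score_invariant(focus_map_raw(blurred, window),
                                        blurred))
  ref <- list(sharp = s_ref, blurred = b_ref,
              cut = sqrt(s_ref * b_ref))   # geometric midpoint
  .blur_cache[[key]] <- ref
  ref
}

# A sharp/blurred composite spans orders of magnitude in focus score; a
# uniformly sharp or uniformly defocused frame stays within a
# texture-level spread.
is_unimodal_scores <- function(v, spread_ratio = 50) {
  q <- stats::quantile(v, c(0.02, 0.98), names = FALSE)
  q[2] <= spread_ratio * max(q[1], .Machine$double.xmin)
}

# Otsu threshold of the out-of-focus mask on log scores (the two score
# populations are roughly log-normal), then dilation by the box-window
# half-width: the sliding window calls any pixel within window/2 of sharp
# structure "in focus", dilating the sharp region; the morphological
# dilation of the mask undoes that bias.
segment_out_of_focus <- function(v, v_si, window, sharp_floor) {
  lv <- log(pmax(v, .Machine$double.xmin))
  p <- stats::quantile(lv, c(0.005, 0.995), names = FALSE)
  nl <- pmin(pmax((lv - p[1]) / (p[2] - p[1]), 0), 1)
  thr <- EBImage::otsu(nl, range = c(0, 1))
  m <- nl < thr & v_si < sharp_floor
  r <- floor(window / 2)
  mask <- EBImage::dilate(m + 0, EBImage::makeBrush(2 * r + 1, "disc")) > 0
  list(mask = mask, threshold = thr)
}

#' Blurriness coefficient of a fluorescence image
#'
#' Segments out-of-focus regions and reports the blurriness `B`: the area
#' fraction of the image that is out of focus.  `B = 0` indicates a purely
#' in-plane deformation (everything stays in the focal plane); `B > 0.5`
#' a purely out-of-plane buckle; intermediate values a superposition of
#' the two.
#'
#' The focus map is thresholded by Otsu's method on the log-score
#' histogram, with two guards: pixels whose scale-invariant score exceeds
#' the calibrated sharp reference are never called out-of-focus, and an
#' effectively unimodal histogram (an all-sharp or all-defocused frame,
#' where a relative threshold is meaningless) is resolved by comparing the
#' median score to the calibrated reference and flagged low-confidence.
#'
#' @inheritParams focus_map
#' @param b_in classification cutoff: `B <= b_in` is called in-plane
#'   (default 0.05, a noise floor standing in for "exactly zero").
#' @param b_out classification cutoff: `B > b_out` is called out-of-plane
#'   (default 0.5).
#' @return An object of class `blurriness_result`: list with `B`, `mask`
#'   (logical matrix, TRUE = out-of-focus; `B` is exactly its mean),
#'   `classification` (`"in_plane"`, `"mixed"`, `"out_of_plane"`),
#'   `threshold` (Otsu threshold on the normalised log score, `NA` on the
#'   degenerate path) and `low_confidence`.
#' @examples
#' bi <- generate_bundle_image(0.4, seed = 5, width = 192, height = 192)
#' blurriness(bi$image)$B
#' @export
blurriness <- function(image, window = 15, b_in = 0.05, b_out = 0.5) {
  v <- focus_map_raw(image, window)
  ref <- sharpness_reference(window)
  if (var(as.vector(image)) == 0) {
    warning("blurriness: constant image; B undefined, returning 0 (low confidence)")
    mask <- matrix(FALSE, nrow(image), ncol(image))
    return(new_blurriness_result(mask, NA_real_, TRUE, b_in, b_out))
  }
  v_si <- focus_score_invariant(v, image)
  if (is_unimodal_scores(v)) {
    all_blurred <- median(v_si) < ref$cut
    mask <- matrix(all_blurred, nrow(image), ncol(image))
    return(new_blurriness_result(mask, NA_real_, TRUE, b_in, b_out))
  }
  seg <- segment_out_of_focus(v, v_si, window, ref$sharp)
  new_blurriness_result(seg$mask, seg$threshold, FALSE, b_in, b_out)
}

new_blurriness_result <- function(mask, threshold, low_confidence,
                                  b_in, b_out) {
  B <- mean(mask)
  structure(list(B = B, mask = mask,
                 classification = if (B <= b_in) "in_plane"
                                  else if (B > b_out) "out_of_plane"
                                  else "mixed",
                 threshold = threshold,
                 low_confidence = low_confidence),
            class = "blurriness_result")
}

#' @export
print.blurriness_result <- function(x, ...) {
  cat(sprintf("blurriness B = %.3f -> %s%s\n", x$B, x$classification,
              if (x$low_confidence) " (low confidence)" else ""))
  invisible(x)
}

#' Blurriness time series of an image stack
#'
#' Per-frame blurriness with shared normalisation so `B(t)` is comparable
#' across frames: the Otsu threshold is computed once from the pooled
#' log scores of all frames (anchored on the first frame's percentiles)
#' and applied to every frame.  A stack whose pooled histogram is
#' degenerate (nothing ever defocuses, or everything is) falls back to
#' the per-frame calibrated-reference comparison of [blurriness()].
#'
#' @param stack list of grayscale matrices (all the same size, at least 2
#'   frames).
#' @param times optional numeric frame times, s (defaults to frame index).
#' @inheritParams blurriness
#' @return Data frame with columns `t`, `B` and `classification`.
#' @examples
#' gs <- generate_growth_series(seq(0, 100, by = 50), seed = 6,
#'                              width = 96, height = 96)
#' blurriness_series(gs$frames, gs$times)
#' @export
blurriness_series <- function(stack, times = seq_along(stack),
                              window = 15, b_in = 0.05, b_out = 0.5) {
  if (length(stack) < 2) stop("blurriness_series: need at least 2 frames")
  dims <- vapply(stack, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("blurriness_series: frame sizes differ")
  if (length(times) != length(stack))
    stop("blurriness_series: times must match the number of frames")
  ref <- sharpness_reference(window)
  vs <- lapply(stack, focus_map_raw, window = window)
  pooled <- unlist(vs)
  if (is_unimodal_scores(pooled)) {
    B <- vapply(seq_along(stack), function(i)
      blurriness(stack[[i]], window, b_in, b_out)$B, numeric(1))
  } else {
    lv <- log(pmax(pooled, .Machine$double.xmin))
    p <- stats::quantile(log(pmax(vs[[1]], .Machine$double.xmin)),
                         c(0.005, 0.995), names = FALSE)
    if (p[2] <= p[1])
      stop("blurriness_series: first frame is (near-)constant; cannot normalise")
    nl_pooled <- pmin(pmax((lv - p[1]) / (p[2] - p[1]), 0), 1)
    thr <- EBImage::otsu(matrix(nl_pooled, ncol = 1), range = c(0, 1))
    r <- floor(window / 2)
    brush <- EBImage::makeBrush(2 * r + 1, "disc")
    B <- vapply(seq_along(stack), function(i) {
      nl <- pmin(pmax((log(pmax(vs[[i]], .Machine$double.xmin)) - p[1]) /
                        (p[2] - p[1]), 0), 1)
      m <- nl < thr & focus_score_invariant(vs[[i]], stack[[i]]) < ref$sharp
      mean(EBImage::dilate(m + 0, brush) > 0)
    }, numeric(1))
  }
  data.frame(t = times, B = B,
             classification = ifelse(B <= b_in, "in_plane",
                                     ifelse(B > b_out, "out_of_plane",
                                            "mixed")))
}
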