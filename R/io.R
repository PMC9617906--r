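#' Read phase-diagram observations from CSV
#'
#' Expects columns `atp_uM`, `motors_nM`, `prc1_nM`, `mt_length_um`, `B`
#' and optionally `lambda_um` and `replicate` (the unit-suffixed header
#' convention used for composition tables).
#'
#' @param path CSV file path.
#' @return A `phase_observations` data frame with the package's internal
#'   column names (`atp`, `motors`, `prc1`, `mt_length`, `B`,
#'   `lambda_obs`, `replicate`).
#' @export
read_phase_observations <- function(path) {
  d <- utils::read.csv(path)
  need <- c("atp_uM", "motors_nM", "prc1_nM", "mt_length_um", "B")
  if (!all(need %in% names(d)))
    stop("read_phase_observations: missing columns: ",
         paste(setdiff(need, names(d)), collapse = ", "))
  out <- data.frame(atp = d$atp_uM, motors = d$motors_nM, prc1 = d$prc1_nM,
                    mt_length = d$mt_length_um, B = d$B,
                    lambda_obs = if ("lambda_um" %in% names(d)) d$lambda_um
                                 else NA_real_,
                    replicate = if ("replicate" %in% names(d)) d$replicate
                                else 1L)
  if (any(out$B < 0 | out$B > 1, na.rm = TRUE))
    stop("read_phase_observations: B must lie in [0, 1]")
  class(out) <- c("phase_observations", "data.frame")
  out
}

#' Write phase-diagram observations to CSV
#'
#' @param obs a `phase_observations` data frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_phase_observations <- function(obs, path) {
  d <- data.frame(atp_uM = obs$atp, motors_nM = obs$motors,
                  prc1_nM = obs$prc1, mt_length_um = obs$mt_length,
                  B = obs$B, lambda_um = obs$lambda_obs,
                  replicate = obs$replicate)
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Serialise kinetic constants to JSON or YAML
#'
#' @param k a [kinetic_constants()] object.
#' @param path output path; format chosen by extension (`.json`, `.yaml`
#'   or `.yml`).
#' @return `path`, invisibly.
#' @export
write_kinetic_constants <- function(k, path) {
  stopifnot(inherits(k, "kinetic_constants"))
  vals <- unclass(k)
  if (grepl("\\.json$", path)) {
    if (!requireNamespace("jsonlite", quietly = TRUE))
      stop("jsonlite is required to write JSON")
    jsonlite::write_json(vals, path, auto_unbox = TRUE, digits = NA)
  } else if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("yaml is required to write YAML")
    yaml::write_yaml(vals, path, precision = 12)
  } else stop("write_kinetic_constants: use a .json or .yaml path")
  invisible(path)
}

#' Read kinetic constants from JSON or YAML
#'
#' @param path file written by [write_kinetic_constants()].
#' @return A [kinetic_constants()] object.
#' @export
read_kinetic_constants <- function(path) {
  vals <- if (grepl("\\.json$", path)) {
    if (!requireNamespace("jsonlite", quietly = TRUE))
      stop("jsonlite is required to read JSON")
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("yaml is required to read YAML")
    yaml::read_yaml(path)
  } else stop("read_kinetic_constants: use a .json or .yaml path")
  do.call(kinetic_constants, vals[c("zeta0", "mu0", "kappa0", "K0", "p0",
                                    "KM", "length_exponent")])
}

#' Read a grayscale TIFF image or stack
#'
#' @param path single- or multi-page 8/16-bit grayscale TIFF.
#' @return A numeric matrix (single page) or list of matrices (stack),
#'   intensities in \[0, 1\].
#' @export
read_gray_tiff <- function(path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the tiff package is required to read TIFF files")
  pages <- tiff::readTIFF(path, all = TRUE)
  to_gray <- function(a) if (length(dim(a)) == 3) a[, , 1] else a
  pages <- lapply(pages, to_gray)
  if (length(pages) == 1) pages[[1]] else pages
}

#' Write a grayscale image or mask to TIFF
#'
#' @param image numeric matrix; rescaled to \[0, 1\] if needed.  Logical
#'   masks are written as 0/1.
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_gray_tiff <- function(image, path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the tiff package is required to write TIFF files")
  img <- image + 0
  rng <- range(img)
  if (rng[2] > 1 || rng[1] < 0)
    img <- (img - rng[1]) / max(rng[2] - rng[1], .Machine$double.eps)
  tiff::writeTIFF(img, path, bits.per.sample = 16)
  invisible(path)
}
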