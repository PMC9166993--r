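check_same_shape <- function(a, b) {
  if (!all(dim(a) == dim(b)))
    stop("image shapes differ: ", paste(dim(a), collapse = "x"), " vs ",
         paste(dim(b), collapse = "x"))
}

#' Mean squared error between two images
#'
#' @param reference,candidate matrices / [image_grid()]s of identical shape.
#' @return mean over pixels of the squared difference.
#' @export
mse <- function(reference, candidate) {
  check_same_shape(reference, candidate)
  mean((as.numeric(reference) - as.numeric(candidate))^2)
}

#' Root-mean-square error (EMSE)
#'
#' The square root of [mse()]; reported alongside MSE so errors are on the
#' intensity scale.
#'
#' @inheritParams mse
#' @return `sqrt(mse(reference, candidate))`.
#' @export
emse <- function(reference, candidate) sqrt(mse(reference, candidate))

#' Improvement in signal-to-noise ratio (dB)
#'
#' `10 * log10(mse_in / mse_out)`: how much a new reconstruction improves
#' on a baseline, where `mse_in` is the baseline's MSE against the
#' reference and `mse_out` the new method's. Positive values favor the new
#' method; each decade of MSE reduction adds 10 dB.
#'
#' @param mse_in,mse_out positive MSE values.
#' @return ISNR in decibels.
#' @export
isnr <- function(mse_in, mse_out) {
  if (mse_in <= 0) stop("mse_in must be > 0")
  if (mse_out <= 0)
    stop("mse_out is 0: perfect reconstruction, ISNR is unbounded")
  10 * log10(mse_in / mse_out)
}

#' Peak signal-to-noise ratio (dB)
#'
#' `10 * log10(peak^2 / mse)`. By default `peak` is the declared dynamic
#' range of the reference image (deterministic and independent of the
#' candidate); set `peak_mode = "observed"` to use the candidate's maximum
#' pixel value instead.
#'
#' @inheritParams mse
#' @param peak peak intensity; default taken from the reference's declared
#'   range (or the candidate's maximum under `"observed"`).
#' @param peak_mode `"declared"` or `"observed"`.
#' @return PSNR in decibels.
#' @export
psnr <- function(reference, candidate, peak = NULL,
                 peak_mode = c("declared", "observed")) {
  peak_mode <- match.arg(peak_mode)
  m <- mse(reference, candidate)
  if (m <= 0) stop("identical images: PSNR is unbounded")
  if (is.null(peak)) {
    peak <- if (peak_mode == "observed") max(candidate)
            else if (is_image_grid(reference)) diff(value_range(reference)) else 1
  }
  if (peak <= 0) stop("peak must be > 0")
  10 * log10(peak^2 / m)
}

# local window sums over all k x k windows via an integral image
window_sums <- function(m, k) {
  S <- matrix(0, nrow(m) + 1, ncol(m) + 1)
  cs <- apply(m, 2, cumsum)
  S[-1, -1] <- t(apply(cs, 1, cumsum))
  nr <- nrow(m) - k + 1; nc <- ncol(m) - k + 1
  S[(k + 1):(nrow(m) + 1), (k + 1):(ncol(m) + 1), drop = FALSE] -
    S[1:nr, (k + 1):(ncol(m) + 1), drop = FALSE] -
    S[(k + 1):(nrow(m) + 1), 1:nc, drop = FALSE] + S[1:nr, 1:nc, drop = FALSE]
}

#' Structural similarity index (SSIM)
#'
#' Windowed SSIM with a uniform k-by-k sliding window: per window
#' \deqn{\frac{(2\mu_a\mu_b + c_1)(2\sigma_{ab} + c_2)}
#'            {(\mu_a^2 + \mu_b^2 + c_1)(\sigma_a^2 + \sigma_b^2 + c_2)}}
#' with \eqn{c_1 = (k_1 L)^2}, \eqn{c_2 = (k_2 L)^2} for dynamic range L,
#' averaged over all windows. Variances and the covariance are sample
#' (n - 1 denominator) statistics. Returns 1 exactly for identical images;
#' values near 1 mean high structural similarity.
#'
#' @inheritParams mse
#' @param window window side (default 7); must not exceed the image.
#' @param k1,k2 the small stabilizing constants (defaults 0.01, 0.03).
#' @param dynamic_range L; default taken from the reference's declared
#'   range.
#' @return mean SSIM over windows, in [-1, 1].
#' @export
ssim <- function(reference, candidate, window = 7L, k1 = 0.01, k2 = 0.03,
                 dynamic_range = NULL) {
  check_same_shape(reference, candidate)
  a <- as.matrix(unclass(reference)); b <- as.matrix(unclass(candidate))
  k <- as.integer(window)
  if (k < 2 || k > min(dim(a))) stop("window must be in [2, image size]")
  if (is.null(dynamic_range))
    dynamic_range <- if (is_image_grid(reference)) diff(value_range(reference)) else 1
  c1 <- (k1 * dynamic_range)^2
  c2 <- (k2 * dynamic_range)^2
  np <- k * k
  sa <- window_sums(a, k); sb <- window_sums(b, k)
  saa <- window_sums(a * a, k); sbb <- window_sums(b * b, k)
  sab <- window_sums(a * b, k)
  mu_a <- sa / np; mu_b <- sb / np
  var_a <- (saa - sa^2 / np) / (np - 1)
  var_b <- (sbb - sb^2 / np) / (np - 1)
  cov_ab <- (sab - sa * sb / np) / (np - 1)
  s <- ((2 * mu_a * mu_b + c1) * (2 * cov_ab + c2)) /
       ((mu_a^2 + mu_b^2 + c1) * (var_a + var_b + c2))
  mean(s)
}

#' Extract a row or column profile
#'
#' Returns the pixel-value sequence along one row or column, used with
#' [total_variation()] to compare the stability of reconstructions along a
#' fixed cut through the image.
#'
#' @param img an image matrix / [image_grid()].
#' @param index row or column index.
#' @param axis `"row"` or `"column"`.
#' @return numeric vector of pixel values.
#' @export
line_profile <- function(img, index, axis = c("row", "column")) {
  axis <- match.arg(axis)
  m <- as.matrix(unclass(img))
  bound <- if (axis == "row") nrow(m) else ncol(m)
  if (index < 1 || index > bound)
    stop(axis, " index ", index, " out of range [1, ", bound, "]")
  if (axis == "row") m[index, ] else m[, index]
}

#' @rdname line_profile
#' @param x numeric vector.
#' @return `total_variation`: the sum of absolute successive differences.
#' @export
total_variation <- function(x) sum(abs(diff(as.numeric(x))))

#' Full image-quality report for one image pair
#'
#' Computes MSE, EMSE, PSNR and SSIM of a candidate against a reference,
#' plus ISNR when a baseline MSE is supplied.
#'
#' @inheritParams ssim
#' @param baseline_mse MSE of a comparison method against the same
#'   reference (enables ISNR), or `NULL`.
#' @return a `metrics_report`: list with `mse`, `emse`, `psnr`, `ssim`,
#'   `isnr` (NA without a baseline) and the SSIM parameters used.
#' @export
metrics_report <- function(reference, candidate, baseline_mse = NULL,
                           window = 7L, k1 = 0.01, k2 = 0.03,
                           dynamic_range = NULL) {
  m <- mse(reference, candidate)
  if (is.null(dynamic_range))
    dynamic_range <- if (is_image_grid(reference)) diff(value_range(reference)) else 1
  structure(list(
    mse = m,
    emse = sqrt(m),
    psnr = if (m > 0) 10 * log10(dynamic_range^2 / m) else Inf,
    ssim = ssim(reference, candidate, window, k1, k2, dynamic_range),
    isnr = if (!is.null(baseline_mse) && m > 0) isnr(baseline_mse, m) else NA_real_,
    ssim_params = list(window = window, k1 = k1, k2 = k2,
                       dynamic_range = dynamic_range)),
    class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("metrics_report: MSE %.4g | EMSE %.4g | PSNR %.2f dB | SSIM %.4f",
              x$mse, x$emse, x$psnr, x$ssim))
  if (!is.na(x$isnr)) cat(sprintf(" | ISNR %.2f dB", x$isnr))
  cat("\n")
  invisible(x)
}

#' @rdname metrics_report
#' @param report a `metrics_report`.
#' @param label row label.
#' @return `metrics_row`: one-row data frame suitable for CSV export.
#' @export
metrics_row <- function(report, label = "") {
  data.frame(label = label, mse = report$mse, emse = report$emse,
             psnr = report$psnr, ssim = report$ssim, isnr = report$isnr)
}

#' @rdname metrics_report
#' @param path output file path.
#' @return `write_metrics_json`: `path`, invisibly.
#' @export
write_metrics_json <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
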