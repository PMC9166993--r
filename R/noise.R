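#' Low-dose acquisition noise configuration
#'
#' Parameters of the photon-counting noise model: an incident photon count
#' per detector bin, a seed for the Mersenne-Twister generator, and a
#' minimum detected count guarding the log transform against photon
#' starvation.
#'
#' @param incident_count mean photon count \eqn{I_0} per bin at zero
#'   attenuation (> 0). Default 1e5, a low-dose acquisition where noise is
#'   clearly visible at chest-like attenuation levels.
#' @param seed integer RNG seed.
#' @param domain `"intensity"` (Poisson counts through the Beer-Lambert
#'   transform, the default) or `"additive-gaussian"` (a variance-matched
#'   Gaussian approximation on the line integrals, for cross-checks).
#' @param floor minimum detected count (>= 1); counts below it are clamped
#'   so the log stays finite.
#' @return object of class `noise_config`.
#' @export
noise_config <- function(incident_count = 1e5, seed = 1L,
                         domain = c("intensity", "additive-gaussian"),
                         floor = 1) {
  if (!is.numeric(incident_count) || incident_count <= 0)
    stop("incident_count must be positive")
  if (floor < 1) stop("floor must be >= 1")
  structure(list(incident_count = incident_count, seed = as.integer(seed),
                 domain = match.arg(domain), floor = floor),
            class = "noise_config")
}

#' Inject Poisson low-dose noise into a sinogram
#'
#' Simulates a low-dose acquisition of clean line integrals p via the
#' Beer-Lambert count model: each bin detects
#' \eqn{N \sim \mathrm{Poisson}(I_0 e^{-p})}, the count is clamped to at
#' least `floor`, and the noisy line integral is recovered as
#' \eqn{p' = -\ln(N / I_0)}. The perturbation realizes the measurement
#' error term of the discrete projection model p = Rx + e; its variance is
#' approximately \eqn{1/(I_0 e^{-p})} per bin, so noise grows with
#' attenuation and shrinks with dose. Strip-model sinograms are converted
#' to line-integral units (\eqn{\times\,\delta^2/\Delta s}, taking the
#' pixel size from `pixel_size`) before the count model and converted back
#' after, so the model always sees attenuation-times-length values. The
#' input is never modified; identical seeds give identical draws.
#'
#' @param sino a [sinogram()] with nonnegative values.
#' @param config a [noise_config()].
#' @param pixel_size pixel side of the grid the sinogram was projected
#'   from; only used to scale strip-model values (default 1).
#' @return a noisy [sinogram()] of the same shape and geometry.
#' @export
add_poisson_noise <- function(sino, config = noise_config(), pixel_size = 1) {
  stopifnot(inherits(sino, "sinogram"), inherits(config, "noise_config"))
  geom <- sino_geometry(sino)
  P <- unclass(sino)
  if (any(P < 0)) stop("sinogram has negative values; line integrals must be >= 0")
  scale <- if (geom$beam_model == "strip") pixel_size^2 / geom$detector_spacing else 1
  p_line <- P * scale
  I0 <- config$incident_count
  noisy <- with_seed(config$seed, {
    if (config$domain == "intensity") {
      counts <- rpois(length(p_line), I0 * exp(-p_line))
      counts <- pmax(counts, config$floor)
      -log(counts / I0)
    } else {
      # delta-method variance of p' under the count model: 1/(I0 e^-p)
      p_line + rnorm(length(p_line), sd = sqrt(exp(p_line) / I0))
    }
  })
  sinogram(matrix(noisy / scale, nrow(P), ncol(P)), geom)
}
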