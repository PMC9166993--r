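#' Parallel-beam projection geometry
#'
#' Describes one acquisition: the view angles, the detector array and the
#' beam model. The coordinate convention (fixed once for the whole package)
#' is: image centered at the origin, x right, y up; a view at angle
#' \eqn{\theta} (degrees, counterclockwise from +x) sends rays in direction
#' \eqn{(\cos\theta, \sin\theta)}; the detector axis is perpendicular, so a
#' point \eqn{(x, y)} projects to detector coordinate
#' \eqn{t = -x\sin\theta + y\cos\theta}. Detector bin centers are
#' `(k - 1/2 - detector_count/2) * detector_spacing`, i.e. the array is
#' centered on the origin.
#'
#' Two beam models are supported. `"strip"` (default): each ray is a strip
#' of width `detector_spacing` and the system-matrix weight of pixel j in
#' ray i is the intersection area divided by the pixel area \eqn{\delta^2}
#' (a dimensionless area ratio in [0, 1]). `"line"`: each ray is a
#' zero-width line and the weight is the chord length through the pixel (in
#' length units), the model under which projections approximate line
#' integrals directly.
#'
#' @param angles view angles in degrees, strictly increasing in [0, 360).
#' @param detector_count number of detector bins (>= 1).
#' @param detector_spacing bin pitch; defaults to 1 (set it to the grid's
#'   pixel size for tiling geometries).
#' @param beam_model `"strip"` or `"line"`.
#' @return object of class `proj_geometry`.
#' @export
proj_geometry <- function(angles, detector_count, detector_spacing = 1,
                          beam_model = c("strip", "line")) {
  beam_model <- match.arg(beam_model)
  angles <- as.numeric(angles)
  if (length(angles) == 0) stop("angles must be nonempty")
  if (any(angles < 0 | angles >= 360)) stop("angles must lie in [0, 360)")
  if (is.unsorted(angles, strictly = TRUE)) stop("angles must be strictly increasing")
  detector_count <- as.integer(detector_count)
  if (is.na(detector_count) || detector_count < 1) stop("detector_count must be >= 1")
  if (detector_spacing <= 0) stop("detector_spacing must be positive")
  structure(list(angles = angles, detector_count = detector_count,
                 detector_spacing = detector_spacing, beam_model = beam_model),
            class = "proj_geometry")
}

#' @rdname proj_geometry
#' @param grid an [image_grid()] (or its side length) for which to build a
#'   default geometry: detector pitch equal to the pixel size and enough
#'   bins to cover the grid diagonal.
#' @export
default_geometry <- function(grid, angles = seq(0, 179),
                             beam_model = c("strip", "line")) {
  n <- if (is_image_grid(grid)) grid_size(grid) else as.integer(grid)
  delta <- if (is_image_grid(grid)) pixel_size(grid) else 1
  nd <- ceiling(n * sqrt(2)) + 2L
  if (nd %% 2L == 0L) nd <- nd + 1L  # odd: center bin straddles the origin
  proj_geometry(angles, nd, detector_spacing = delta,
                beam_model = match.arg(beam_model))
}

detector_offsets <- function(geom) {
  (seq_len(geom$detector_count) - 0.5 - geom$detector_count / 2) *
    geom$detector_spacing
}

# CDF of U + V, U ~ Unif(-A, A), V ~ Unif(-B, B) (trapezoidal law); gives
# the area fraction of an axis-aligned pixel on one side of a line, which is
# what the strip weights reduce to. A >= B >= 0, A > 0.
trapezoid_cdf <- function(d, A, B) {
  if (B < .Machine$double.eps * A) return(pmin(pmax((d + A) / (2 * A), 0), 1))
  s1 <- A + B; s2 <- A - B
  out <- numeric(length(d))
  out[d >= s1] <- 1
  mid <- d > -s2 & d < s2
  out[mid] <- 0.5 + d[mid] / (2 * A)
  lo <- d > -s1 & d <= -s2
  out[lo] <- (d[lo] + s1)^2 / (8 * A * B)
  hi <- d >= s2 & d < s1
  out[hi] <- 1 - (s1 - d[hi])^2 / (8 * A * B)
  out
}

#' Build the sparse projection system matrix
#'
#' Computes the ray-by-pixel weight matrix R of the discrete projection
#' model p = R x. Rows are ordered angle-major then detector (row
#' `(a-1)*detector_count + k` is view a, bin k); columns follow R's native
#' column-major flattening of the image matrix (row index varies fastest),
#' the same order as [flatten_image()]. Both conventions are recorded in the
#' returned object so matrix, image vector and sinogram always agree.
#'
#' In strip mode each weight is the exact area of overlap between the strip
#' and the pixel square divided by \eqn{\delta^2}, evaluated in closed form
#' (the overlap area on one side of a line is the CDF of a trapezoidal
#' distribution); in line mode it is the exact chord length of the ray
#' through the pixel (slab clipping). Rays that miss the grid give all-zero
#' rows.
#'
#' @param grid an [image_grid()] or a bare grid side length (then
#'   `pixel_size` 1).
#' @param geom a [proj_geometry()].
#' @return object of class `system_matrix`: list with `R` (a
#'   `Matrix::dgCMatrix`), `geom`, `grid_size`, `pixel_size`, `pixel_order`
#'   (`"column-major"`), `ray_order` (`"angle-major"`).
#' @export
build_system_matrix <- function(grid, geom) {
  stopifnot(inherits(geom, "proj_geometry"))
  n <- if (is_image_grid(grid)) grid_size(grid) else as.integer(grid)
  delta <- if (is_image_grid(grid)) pixel_size(grid) else 1
  h <- delta / 2
  ctr <- pixel_centers(n, delta)
  ndet <- geom$detector_count
  w <- geom$detector_spacing
  offs <- detector_offsets(geom)
  trip_i <- vector("list", length(geom$angles))
  trip_j <- vector("list", length(geom$angles))
  trip_x <- vector("list", length(geom$angles))

  for (ai in seq_along(geom$angles)) {
    th <- geom$angles[ai] * pi / 180
    nx <- -sin(th); ny <- cos(th)          # detector-axis unit vector
    tc <- ctr$x * nx + ctr$y * ny          # detector coordinate of pixel centers
    A <- h * max(abs(nx), abs(ny)); B <- h * min(abs(nx), abs(ny))
    reach <- A + B                          # pixel half-extent along detector axis
    ord <- order(tc)
    tc_s <- tc[ord]
    ii <- jj <- xx <- vector("list", ndet)
    for (k in seq_len(ndet)) {
      s <- offs[k]
      lo_t <- s - (if (geom$beam_model == "strip") w / 2 else 0) - reach
      hi_t <- s + (if (geom$beam_model == "strip") w / 2 else 0) + reach
      i1 <- findInterval(lo_t, tc_s) + 1L
      i2 <- findInterval(hi_t, tc_s)
      if (i2 < i1) next
      sel <- ord[i1:i2]
      if (geom$beam_model == "strip") {
        wt <- trapezoid_cdf(s + w / 2 - tc[sel], A, B) -
              trapezoid_cdf(s - w / 2 - tc[sel], A, B)
      } else {
        dx <- cos(th); dy <- sin(th)
        ox <- s * nx; oy <- s * ny
        cx <- ctr$x[sel]; cy <- ctr$y[sel]
        if (abs(dx) > 1e-12) {
          u1 <- (cx - h - ox) / dx; u2 <- (cx + h - ox) / dx
          lo_x <- pmin(u1, u2); hi_x <- pmax(u1, u2)
        } else {
          inside <- abs(ox - cx) <= h
          lo_x <- ifelse(inside, -Inf, Inf); hi_x <- ifelse(inside, Inf, -Inf)
        }
        if (abs(dy) > 1e-12) {
          u1 <- (cy - h - oy) / dy; u2 <- (cy + h - oy) / dy
          lo_y <- pmin(u1, u2); hi_y <- pmax(u1, u2)
        } else {
          inside <- abs(oy - cy) <= h
          lo_y <- ifelse(inside, -Inf, Inf); hi_y <- ifelse(inside, Inf, -Inf)
        }
        wt <- pmax(0, pmin(hi_x, hi_y) - pmax(lo_x, lo_y))
      }
      keep <- wt > 0
      if (!any(keep)) next
      ii[[k]] <- rep.int((ai - 1L) * ndet + k, sum(keep))
      jj[[k]] <- sel[keep]
      xx[[k]] <- wt[keep]
    }
    trip_i[[ai]] <- unlist(ii); trip_j[[ai]] <- unlist(jj); trip_x[[ai]] <- unlist(xx)
  }

  R <- Matrix::sparseMatrix(i = unlist(trip_i), j = unlist(trip_j),
                            x = unlist(trip_x),
                            dims = c(length(geom$angles) * ndet, n * n))
  structure(list(R = R, geom = geom, grid_size = n, pixel_size = delta,
                 pixel_order = "column-major", ray_order = "angle-major"),
            class = "system_matrix")
}

#' @export
print.system_matrix <- function(x, ...) {
  cat(sprintf("system_matrix: %d rays x %d pixels (%s beam), %d angles x %d detectors, %.2f%% nonzero\n",
              nrow(x$R), ncol(x$R), x$geom$beam_model, length(x$geom$angles),
              x$geom$detector_count, 100 * Matrix::nnzero(x$R) / prod(dim(x$R))))
  invisible(x)
}

#' Sinogram container
#'
#' Projection measurements arranged angle (rows) by detector bin (columns),
#' carrying the [proj_geometry()] they were measured under. Strip-model
#' values are dimensionless weighted pixel sums; line-model values are in
#' attenuation-times-length units.
#'
#' @param values numeric matrix, `length(geom$angles)` x
#'   `geom$detector_count`.
#' @param geom a [proj_geometry()].
#' @return object of class `sinogram` (a matrix with a `geom` attribute).
#' @export
sinogram <- function(values, geom) {
  values <- as.matrix(values)
  if (nrow(values) != length(geom$angles) || ncol(values) != geom$detector_count)
    stop("sinogram shape ", nrow(values), "x", ncol(values),
         " does not match geometry ", length(geom$angles), "x", geom$detector_count)
  if (!all(is.finite(values))) stop("sinogram values must be finite")
  structure(values, geom = geom, class = c("sinogram", "matrix"))
}

#' @rdname sinogram
#' @param x a `sinogram`.
#' @export
sino_geometry <- function(x) attr(x, "geom")

#' @export
print.sinogram <- function(x, ...) {
  g <- sino_geometry(x)
  cat(sprintf("sinogram: %d angles x %d detectors (%s beam), values in [%.4g, %.4g]\n",
              nrow(x), ncol(x), g$beam_model, min(x), max(x)))
  invisible(x)
}

# flatten a sinogram to the angle-major ray vector p, and back
sino_to_vec <- function(sino) as.vector(t(unclass(sino)))
vec_to_sino <- function(v, geom) {
  sinogram(t(matrix(v, nrow = geom$detector_count)), geom)
}

#' Forward projection (discrete Radon transform)
#'
#' Applies the system matrix to an image: the sinogram value of ray i is the
#' weighted pixel sum \eqn{\sum_j r_{ij} x_j}. Linear in the image.
#'
#' @param img an [image_grid()] matching the grid the matrix was built for.
#' @param sm a [build_system_matrix()] result.
#' @return a [sinogram()].
#' @export
forward_project <- function(img, sm) {
  stopifnot(inherits(sm, "system_matrix"))
  if (!is_image_grid(img)) stop("img must be an image_grid")
  if (grid_size(img) != sm$grid_size)
    stop("image grid ", grid_size(img), "x", grid_size(img),
         " does not match system matrix grid ", sm$grid_size, "x", sm$grid_size)
  p <- as.numeric(sm$R %*% flatten_image(img))
  vec_to_sino(p, sm$geom)
}
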