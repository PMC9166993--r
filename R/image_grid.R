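#' @importFrom methods as is new
#' @importFrom stats fft rpois runif rnorm
#' @importFrom utils write.csv read.csv
NULL

#' Square attenuation image on a centered grid
#'
#' An `image_grid` is the discrete form of the attenuation function
#' \eqn{f(r,\phi)}: a square matrix of (dimensionless, nonnegative by
#' convention) attenuation coefficients, together with the physical pixel
#' side \eqn{\delta} and a declared value range used as the dynamic range by
#' the quality metrics. The grid is centered on the coordinate origin with
#' x to the right, y up; row 1 is the top row, so the pixel in row r,
#' column c of an n-by-n grid has center
#' \eqn{x = (c - 1/2 - n/2)\,\delta}, \eqn{y = (n/2 - r + 1/2)\,\delta}.
#'
#' @param values square numeric matrix of finite attenuation values.
#' @param pixel_size physical side length \eqn{\delta} of one pixel (> 0).
#' @param value_range declared dynamic range, length-2 numeric; defaults to
#'   `c(0, 1)`, the convention used by all bundled phantoms.
#' @return An object of class `image_grid`: the matrix with attributes
#'   `pixel_size` and `value_range`.
#' @examples
#' g <- image_grid(matrix(0, 8, 8))
#' grid_size(g)
#' @export
image_grid <- function(values, pixel_size = 1, value_range = c(0, 1)) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values))
    stop("image_grid must be square; got ", nrow(values), " x ", ncol(values))
  if (!all(is.finite(values)))
    stop("image_grid values must all be finite")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1 || pixel_size <= 0)
    stop("pixel_size must be a single positive number")
  structure(values,
            pixel_size = pixel_size,
            value_range = as.numeric(value_range),
            class = c("image_grid", "matrix"))
}

#' @export
#' @rdname image_grid
is_image_grid <- function(x) inherits(x, "image_grid")

#' @export
#' @rdname image_grid
#' @param x an `image_grid`.
grid_size <- function(x) nrow(x)

#' @export
#' @rdname image_grid
pixel_size <- function(x) attr(x, "pixel_size")

#' @export
#' @rdname image_grid
value_range <- function(x) attr(x, "value_range")

#' Pixel-center coordinates of a grid
#'
#' Returns the x and y coordinates of every pixel center in column-major
#' (R-native) order, the same order used to flatten images into the vector
#' x of the linear system R x = p.
#'
#' @param n grid side length in pixels.
#' @param delta pixel size.
#' @return list with numeric vectors `x` and `y`, each of length `n^2`.
#' @keywords internal
pixel_centers <- function(n, delta) {
  cols <- rep(seq_len(n), each = n)   # column-major: row varies fastest
  rows <- rep(seq_len(n), times = n)
  list(x = (cols - 0.5 - n / 2) * delta,
       y = (n / 2 - rows + 0.5) * delta)
}

#' Flatten an image to the solver vector / rebuild it
#'
#' Column-major flattening (R's native matrix order); the inverse wraps a
#' vector back into an `image_grid` with the metadata of a template grid.
#'
#' @param img an `image_grid`.
#' @return `flatten_image`: numeric vector of length `n^2`.
#' @export
flatten_image <- function(img) as.vector(unclass(img))

#' @rdname flatten_image
#' @param x numeric vector of length `grid_size(template)^2`.
#' @param template an `image_grid` supplying size, pixel size and range.
#' @export
unflatten_image <- function(x, template) {
  n <- grid_size(template)
  if (length(x) != n * n)
    stop("vector length ", length(x), " does not match grid ", n, "x", n)
  image_grid(matrix(x, n, n),
             pixel_size = pixel_size(template),
             value_range = value_range(template))
}

#' @export
print.image_grid <- function(x, ...) {
  cat(sprintf("image_grid: %d x %d, pixel_size = %g, values in [%.4g, %.4g], declared range [%g, %g]\n",
              nrow(x), ncol(x), pixel_size(x), min(x), max(x),
              value_range(x)[1], value_range(x)[2]))
  invisible(x)
}

# Run code with a temporary Mersenne-Twister seed, restoring the caller's
# RNG state afterwards. All stochastic pieces of the package draw through
# this, so results are reproducible given the documented generator.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister")
  force(code)
}

#' Write an image to PNG, TIFF and/or a raw text dump
#'
#' PNG/TIFF are written as 16-bit grayscale after affine mapping of the
#' declared value range to [0, 1] (values outside are clipped). The raw dump
#' is a lossless plain-text matrix (`write.table`, full double precision)
#' so reconstructions can be reloaded exactly.
#'
#' @param img an `image_grid`.
#' @param path output path; the extension selects the format (`.png`,
#'   `.tif`/`.tiff`, anything else gets the text dump).
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("png", "tif", "tiff")) {
    rng <- value_range(img)
    z <- (unclass(img) - rng[1]) / (rng[2] - rng[1])
    z <- pmin(pmax(z, 0), 1)
    if (ext == "png") png::writePNG(z, path) else tiff::writeTIFF(z, path, bits.per.sample = 16L)
  } else {
    utils::write.table(format(unclass(img), digits = 17),
                       path, row.names = FALSE, col.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' @rdname write_image
#' @param pixel_size,value_range metadata to attach when reading a raw dump.
#' @export
read_image <- function(path, pixel_size = 1, value_range = c(0, 1)) {
  ext <- tolower(tools::file_ext(path))
  m <- if (ext == "png") {
    png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::readTIFF(path)
  } else {
    as.matrix(utils::read.table(path))
  }
  if (length(dim(m)) == 3) m <- m[, , 1]
  dimnames(m) <- NULL
  image_grid(m, pixel_size = pixel_size, value_range = value_range)
}
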