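#' Phantom element primitives
#'
#' Builders for the geometric primitives a [phantom_spec()] is made of. All
#' coordinates and lengths are in physical units (the same units as
#' `pixel_size`), with the origin at the grid center, x right, y up.
#' Rotation angles are in degrees, counterclockwise.
#'
#' * `el_ellipse()` — filled ellipse.
#' * `el_annulus()` — filled ring between two radii (e.g. a thick-walled
#'   airway cross-section).
#' * `el_polyline()` — stroked open polyline of a given stroke width (e.g. a
#'   vessel).
#' * `el_blob()` — filled disk patch (e.g. a mosaic low-attenuation region).
#'
#' @param center length-2 numeric (x, y).
#' @param semi_axes length-2 numeric, semi-axis lengths (> 0).
#' @param rotation rotation in degrees.
#' @param value attenuation value painted by the element.
#' @param r_inner,r_outer annulus radii, `0 <= r_inner < r_outer`.
#' @param points k-by-2 matrix of vertices (k >= 2).
#' @param width stroke width (> 0).
#' @param radius disk radius (> 0).
#' @return A list describing the element, class `phantom_element`.
#' @name phantom_elements
NULL

#' @rdname phantom_elements
#' @export
el_ellipse <- function(center, semi_axes, value, rotation = 0) {
  structure(list(kind = "ellipse", center = as.numeric(center),
                 semi_axes = as.numeric(semi_axes),
                 rotation = rotation, value = value),
            class = "phantom_element")
}

#' @rdname phantom_elements
#' @export
el_annulus <- function(center, r_inner, r_outer, value) {
  structure(list(kind = "annulus", center = as.numeric(center),
                 r_inner = r_inner, r_outer = r_outer, value = value),
            class = "phantom_element")
}

#' @rdname phantom_elements
#' @export
el_polyline <- function(points, width, value) {
  structure(list(kind = "polyline", points = as.matrix(points),
                 width = width, value = value),
            class = "phantom_element")
}

#' @rdname phantom_elements
#' @export
el_blob <- function(center, radius, value) {
  structure(list(kind = "blob_patch", center = as.numeric(center),
                 radius = radius, value = value),
            class = "phantom_element")
}

validate_element <- function(el, idx) {
  bad <- function(msg) stop("phantom element ", idx, " (", el$kind, "): ", msg,
                            call. = FALSE)
  switch(el$kind,
    ellipse = {
      if (length(el$semi_axes) != 2 || any(!is.finite(el$semi_axes)) ||
          any(el$semi_axes <= 0)) bad("semi-axes must be positive")
    },
    annulus = {
      if (!is.finite(el$r_outer) || el$r_outer <= 0) bad("outer radius must be positive")
      if (el$r_inner < 0 || el$r_inner >= el$r_outer)
        bad("need 0 <= inner radius < outer radius")
    },
    polyline = {
      if (nrow(el$points) < 2) bad("needs at least 2 points")
      if (!is.finite(el$width) || el$width <= 0) bad("width must be positive")
    },
    blob_patch = {
      if (!is.finite(el$radius) || el$radius <= 0) bad("radius must be positive")
    },
    bad("unknown element kind"))
  invisible(el)
}

#' Phantom specification
#'
#' A deterministic recipe for a test image: grid size, pixel size, a
#' background attenuation and an ordered list of [phantom_elements]. The
#' spec renders the same image every time; any randomness (e.g. in the lung
#' phantom) happens when the element list is *composed*, never when it is
#' rendered.
#'
#' @param grid_size pixels per side (>= 2).
#' @param elements list of `phantom_element`s, painted in order.
#' @param pixel_size physical pixel side \eqn{\delta} (default 1).
#' @param background background attenuation value.
#' @param value_mode `"replace"` (later elements overwrite, the default) or
#'   `"additive"` (element values accumulate).
#' @param value_range declared dynamic range recorded on the rendered image.
#' @return object of class `phantom_spec`.
#' @seealso [render_phantom()], [make_lung_phantom()]
#' @export
phantom_spec <- function(grid_size, elements = list(), pixel_size = 1,
                         background = 0, value_mode = c("replace", "additive"),
                         value_range = c(0, 1)) {
  value_mode <- match.arg(value_mode)
  grid_size <- as.integer(grid_size)
  if (is.na(grid_size) || grid_size < 2) stop("grid_size must be an integer >= 2")
  if (pixel_size <= 0) stop("pixel_size must be positive")
  for (i in seq_along(elements)) validate_element(elements[[i]], i)
  structure(list(grid_size = grid_size, pixel_size = pixel_size,
                 background = background, value_mode = value_mode,
                 elements = elements, value_range = as.numeric(value_range)),
            class = "phantom_spec")
}

element_mask <- function(el, px, py) {
  dx <- px - if (el$kind == "polyline") 0 else el$center[1]
  dy <- py - if (el$kind == "polyline") 0 else el$center[2]
  switch(el$kind,
    ellipse = {
      phi <- el$rotation * pi / 180
      u <- dx * cos(phi) + dy * sin(phi)
      v <- -dx * sin(phi) + dy * cos(phi)
      (u / el$semi_axes[1])^2 + (v / el$semi_axes[2])^2 <= 1
    },
    annulus = {
      r2 <- dx^2 + dy^2
      r2 <= el$r_outer^2 & r2 >= el$r_inner^2
    },
    blob_patch = dx^2 + dy^2 <= el$radius^2,
    polyline = {
      hit <- rep(FALSE, length(px))
      hw2 <- (el$width / 2)^2
      P <- el$points
      for (s in seq_len(nrow(P) - 1)) {
        ax <- P[s, 1]; ay <- P[s, 2]
        bx <- P[s + 1, 1]; by <- P[s + 1, 2]
        vx <- bx - ax; vy <- by - ay
        L2 <- vx^2 + vy^2
        t <- if (L2 == 0) 0 else pmin(pmax(((px - ax) * vx + (py - ay) * vy) / L2, 0), 1)
        hit <- hit | ((px - (ax + t * vx))^2 + (py - (ay + t * vy))^2 <= hw2)
      }
      hit
    })
}

#' Render a phantom specification to an image
#'
#' Pixel membership is decided by pixel-center inclusion: a pixel takes an
#' element's value when its center lies inside the element. This matches the
#' discrete pixel model used by the projection system matrix and keeps
#' hand-enumeration oracles exact; there is no anti-aliasing. Elements are
#' painted in list order; in `"replace"` mode a later element overwrites, in
#' `"additive"` mode values accumulate.
#'
#' @param spec a [phantom_spec()].
#' @return an [image_grid()].
#' @examples
#' spec <- phantom_spec(64, list(el_blob(c(0, 0), 10, 1)))
#' img <- render_phantom(spec)
#' sum(img > 0)  # pixels whose centers fall inside the disk
#' @export
render_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  n <- spec$grid_size
  ctr <- pixel_centers(n, spec$pixel_size)
  vals <- rep(spec$background, n * n)
  for (i in seq_along(spec$elements)) {
    el <- spec$elements[[i]]
    m <- element_mask(el, ctr$x, ctr$y)
    if (spec$value_mode == "replace") vals[m] <- el$value
    else vals[m] <- vals[m] + el$value
  }
  image_grid(matrix(vals, n, n), pixel_size = spec$pixel_size,
             value_range = spec$value_range)
}

#' Classical ellipse head phantom
#'
#' The standard ten-ellipse head phantom (Shepp-Logan layout with the
#' commonly used high-contrast attenuation values, rescaled into [0, 1]),
#' rendered by pixel-center inclusion.
#'
#' @param grid_size pixels per side.
#' @param pixel_size physical pixel side; the phantom occupies the unit disk
#'   scaled to the grid, so the default puts its bounding box just inside
#'   the image.
#' @return an [image_grid()].
#' @export
make_head_phantom <- function(grid_size, pixel_size = 2 / grid_size) {
  a <- 1  # phantom defined on the unit disk
  tab <- rbind(   # x0, y0, A, B, rot(deg), value painted (replace mode)
    c( 0,      0,      0.69,   0.92,    0, 1.0),
    c( 0,     -0.0184, 0.6624, 0.874,   0, 0.2),
    c( 0.22,   0,      0.11,   0.31,  -18, 0.0),
    c(-0.22,   0,      0.16,   0.41,   18, 0.0),
    c( 0,      0.35,   0.21,   0.25,    0, 0.3),
    c( 0,      0.1,    0.046,  0.046,   0, 0.4),
    c( 0,     -0.1,    0.046,  0.046,   0, 0.4),
    c(-0.08,  -0.605,  0.046,  0.023,   0, 0.4),
    c( 0,     -0.605,  0.023,  0.023,   0, 0.4),
    c( 0.06,  -0.605,  0.023,  0.046,   0, 0.4))
  els <- lapply(seq_len(nrow(tab)), function(i)
    el_ellipse(center = tab[i, 1:2] * a, semi_axes = tab[i, 3:4] * a,
               value = tab[i, 6], rotation = tab[i, 5]))
  render_phantom(phantom_spec(grid_size, els, pixel_size = pixel_size))
}

#' Lung-slice phantom with small-airway disease signs
#'
#' Builds a thorax-like 2D attenuation map carrying the three imaging signs
#' of obliterative small-airway disease as they appear on expiratory
#' high-resolution CT: patchy regions of *decreased* lung attenuation
#' (mosaic perfusion / air trapping), ring-shaped airway cross-sections with
#' thickened walls, and thin bright vessel lines of reduced caliber. The
#' layout (patch positions, ring and vessel placement) is randomized from a
#' single explicit seed through R's Mersenne-Twister generator, so the same
#' seed reproduces the image bit for bit on any platform with that
#' generator. Attenuation values are normalized to [0, 1] (soft tissue 0.5,
#' aerated lung 0.08, trapped-air patches 0.03, airway walls 0.35, vessels
#' 0.30); the physical extent is fixed at 12 length units across the grid so
#' peak ray attenuation sits in the low-dose chest regime.
#'
#' @param grid_size pixels per side (>= 64; smaller grids cannot hold all
#'   three structure classes at >= 1 px wall thickness).
#' @param seed integer seed driving all placement draws.
#' @param pixel_size physical pixel side; default `12 / grid_size`.
#' @return an [image_grid()] with attribute `manifest`: a data frame with
#'   one row per placed element (`class`, `cx`, `cy`, `size`, `value`),
#'   retrievable with [phantom_manifest()].
#' @examples
#' ph <- make_lung_phantom(64, seed = 1)
#' head(phantom_manifest(ph))
#' @export
make_lung_phantom <- function(grid_size, seed, pixel_size = 12 / grid_size) {
  grid_size <- as.integer(grid_size)
  if (is.na(grid_size) || grid_size < 64)
    stop("grid_size must be >= 64 to place all structure classes")
  E <- grid_size * pixel_size   # physical extent
  a <- E / 2
  v_soft <- 0.5; v_lung <- 0.08; v_patch <- 0.03
  v_wall <- 0.35; v_lumen <- 0.02; v_vessel <- 0.30
  wall_min <- max(0.03 * a, 1.5 * pixel_size)  # wall thickness >= 1 px

  lungs <- list(list(c(-0.42, 0.02) * a, c(0.36, 0.58) * a, 8),
                list(c( 0.42, 0.02) * a, c(0.36, 0.58) * a, -8))
  els <- list(el_ellipse(c(0, 0), c(0.95, 0.74) * a, v_soft))
  man <- list(data.frame(class = "body", cx = 0, cy = 0,
                         size = 0.95 * a, value = v_soft))
  for (lg in lungs) {
    els[[length(els) + 1]] <- el_ellipse(lg[[1]], lg[[2]], v_lung, rotation = lg[[3]])
    man[[length(man) + 1]] <- data.frame(class = "lung_field", cx = lg[[1]][1],
                                         cy = lg[[1]][2], size = lg[[2]][1],
                                         value = v_lung)
  }

  # draw a point uniformly inside an (unrotated-frame) ellipse with margin
  rand_in_lung <- function(lg, margin) {
    repeat {
      u <- runif(2, -1, 1)
      if (sum(u^2) <= 1) break
    }
    phi <- lg[[3]] * pi / 180
    ax <- (lg[[2]] - margin) * u
    c(lg[[1]][1] + ax[1] * cos(phi) - ax[2] * sin(phi),
      lg[[1]][2] + ax[1] * sin(phi) + ax[2] * cos(phi))
  }

  with_seed(seed, {
    for (lg in lungs) {
      # mosaic low-attenuation patches
      for (k in seq_len(sample(3:5, 1))) {
        r <- runif(1, 0.07, 0.14) * a
        ctr <- rand_in_lung(lg, r + 0.02 * a)
        els[[length(els) + 1]] <- el_blob(ctr, r, v_patch)
        man[[length(man) + 1]] <- data.frame(class = "mosaic_patch", cx = ctr[1],
                                             cy = ctr[2], size = r, value = v_patch)
      }
      # thick-walled airway rings (air lumen + wall annulus)
      for (k in seq_len(sample(2:3, 1))) {
        r_out <- runif(1, 0.06, 0.10) * a
        r_in <- max(r_out - runif(1, wall_min, 1.6 * wall_min), 0.3 * r_out)
        ctr <- rand_in_lung(lg, r_out + 0.02 * a)
        els[[length(els) + 1]] <- el_blob(ctr, r_in, v_lumen)
        els[[length(els) + 1]] <- el_annulus(ctr, r_in, r_out, v_wall)
        man[[length(man) + 1]] <- data.frame(class = "airway_ring", cx = ctr[1],
                                             cy = ctr[2], size = r_out, value = v_wall)
      }
      # thin vessel lines drifting from a hilar point
      for (k in seq_len(sample(2:3, 1))) {
        p0 <- rand_in_lung(lg, 0.12 * a)
        nseg <- sample(2:3, 1)
        ang <- runif(1, 0, 2 * pi)
        pts <- matrix(p0, ncol = 2)
        for (s in seq_len(nseg)) {
          ang <- ang + runif(1, -0.6, 0.6)
          step <- runif(1, 0.12, 0.22) * a
          pts <- rbind(pts, pts[nrow(pts), ] + step * c(cos(ang), sin(ang)))
        }
        w <- runif(1, 1.2, 2.2) * pixel_size
        els[[length(els) + 1]] <- el_polyline(pts, w, v_vessel)
        man[[length(man) + 1]] <- data.frame(class = "vessel", cx = p0[1],
                                             cy = p0[2], size = w, value = v_vessel)
      }
    }
  })

  img <- render_phantom(phantom_spec(grid_size, els, pixel_size = pixel_size))
  attr(img, "manifest") <- do.call(rbind, man)
  img
}

#' @rdname make_lung_phantom
#' @param img a phantom produced by `make_lung_phantom()`.
#' @export
phantom_manifest <- function(img) attr(img, "manifest")

#' Write / read a phantom specification as YAML
#'
#' @param spec a [phantom_spec()].
#' @param path file path.
#' @return `write_phantom_spec` returns `path` invisibly;
#'   `read_phantom_spec` returns the reconstructed `phantom_spec`.
#' @export
write_phantom_spec <- function(spec, path) {
  lst <- unclass(spec)
  lst$elements <- lapply(lst$elements, function(el) {
    el <- unclass(el)
    if (!is.null(el$points)) el$points <- apply(el$points, 1, as.numeric, simplify = FALSE)
    el
  })
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname write_phantom_spec
#' @export
read_phantom_spec <- function(path) {
  lst <- yaml::read_yaml(path)
  els <- lapply(lst$elements, function(el) {
    if (!is.null(el$points)) el$points <- do.call(rbind, el$points)
    structure(el, class = "phantom_element")
  })
  phantom_spec(lst$grid_size, els, pixel_size = lst$pixel_size,
               background = lst$background, value_mode = lst$value_mode,
               value_range = unlist(lst$value_range))
}
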