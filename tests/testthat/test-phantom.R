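test_that("rendering handles the empty and full-cover edge cases", {
  empty <- render_phantom(phantom_spec(16, list(), background = 0))
  expect_true(all(unclass(empty) == 0))
  expect_equal(dim(empty), c(16L, 16L))

  big <- el_ellipse(c(0, 0), c(100, 100), value = 1)
  full <- render_phantom(phantom_spec(16, list(big)))
  expect_true(all(unclass(full) == 1))
})

test_that("disk pixel count matches brute-force center enumeration", {
  spec <- phantom_spec(64, list(el_blob(c(0, 0), 10, 1)))
  img <- render_phantom(spec)
  # brute force: count pixel centers inside the circle
  cnt <- 0
  for (r in 1:64) for (c in 1:64) {
    x <- (c - 0.5 - 32); y <- (32 - r + 0.5)
    if (x^2 + y^2 <= 100) cnt <- cnt + 1
  }
  expect_equal(sum(unclass(img) != 0), cnt)
})

test_that("rendering is deterministic and value modes behave", {
  spec <- phantom_spec(32, list(el_ellipse(c(0, 0), c(10, 6), 0.5, rotation = 20),
                                el_blob(c(2, 2), 3, 0.2)))
  expect_identical(unclass(render_phantom(spec)), unclass(render_phantom(spec)))

  add <- phantom_spec(32, list(el_blob(c(0, 0), 5, 0.3), el_blob(c(0, 0), 5, 0.2)),
                      value_mode = "additive")
  rep_ <- phantom_spec(32, list(el_blob(c(0, 0), 5, 0.3), el_blob(c(0, 0), 5, 0.2)))
  expect_equal(max(render_phantom(add)), 0.5)
  expect_equal(max(render_phantom(rep_)), 0.2)
})

test_that("degenerate primitives are rejected with the element index", {
  expect_error(phantom_spec(32, list(el_blob(c(0, 0), 5, 1),
                                     el_ellipse(c(0, 0), c(-1, 2), 1))),
               "element 2")
  expect_error(phantom_spec(32, list(el_annulus(c(0, 0), 3, 2, 1))), "element 1")
  expect_error(phantom_spec(32, list(el_polyline(rbind(c(0, 0), c(1, 1)), 0, 1))),
               "element 1")
})

test_that("lung phantom is seed-reproducible and seed-sensitive", {
  a1 <- make_lung_phantom(64, seed = 3)
  a2 <- make_lung_phantom(64, seed = 3)
  b <- make_lung_phantom(64, seed = 4)
  expect_identical(unclass(a1), unclass(a2))
  expect_false(identical(unclass(a1), unclass(b)))
  expect_error(make_lung_phantom(32, seed = 1), ">= 64")
})

test_that("lung phantom contains all three structure classes with plausible values", {
  ph <- make_lung_phantom(96, seed = 5)
  man <- phantom_manifest(ph)
  expect_true(all(c("mosaic_patch", "airway_ring", "vessel") %in% man$class))
  rng <- value_range(ph)
  expect_true(all(unclass(ph) >= rng[1] & unclass(ph) <= rng[2]))

  # mosaic patches must be darker than the surrounding lung field
  ctr <- expand.grid(row = 1:96, col = 1:96)
  px <- (ctr$col - 0.5 - 48) * pixel_size(ph)
  py <- (48 - ctr$row + 0.5) * pixel_size(ph)
  patches <- man[man$class == "mosaic_patch", ]
  in_patch <- rep(FALSE, 96 * 96)
  for (i in seq_len(nrow(patches)))
    in_patch <- in_patch | ((px - patches$cx[i])^2 + (py - patches$cy[i])^2
                            <= patches$size[i]^2)
  lungs <- man[man$class == "lung_field", ]
  vals <- as.vector(unclass(ph))
  lung_level <- lungs$value[1]
  in_lung_bg <- !in_patch & vals == lung_level
  expect_lt(mean(vals[in_patch]), mean(vals[in_lung_bg]))
})

test_that("phantom specs round-trip through YAML", {
  spec <- phantom_spec(32, list(el_ellipse(c(1, -2), c(8, 5), 0.7, rotation = 15),
                                el_polyline(rbind(c(-5, 0), c(5, 3)), 1.5, 0.4),
                                el_annulus(c(0, 0), 2, 4, 0.9)),
                       pixel_size = 0.5, background = 0.1)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_phantom_spec(spec, path)
  back <- read_phantom_spec(path)
  expect_equal(unclass(render_phantom(back)), unclass(render_phantom(spec)))
})

test_that("images round-trip through the lossless text dump", {
  ph <- make_lung_phantom(64, seed = 2)
  path <- withr::local_tempfile(fileext = ".txt")
  write_image(ph, path)
  back <- read_image(path, pixel_size = pixel_size(ph))
  expect_equal(unclass(back), unclass(ph), tolerance = 1e-15, ignore_attr = TRUE)
})
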