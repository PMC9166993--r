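test_that("a single Kaczmarz update solves its equation exactly at lambda = 1", {
  A <- matrix(c(1, 0), 1, 2)           # x1 = 5
  x <- kaczmarz_sweep(c(0, 0), A, 5, lambda = 1)
  expect_equal(x, c(5, 0))
  # lambda -> 0 leaves the iterate unchanged
  x0 <- c(0.3, -0.7)
  expect_equal(kaczmarz_sweep(x0, A, 5, lambda = 1e-300), x0)
})

test_that("Kaczmarz converges to the solution of a compatible 2x2 system", {
  A <- rbind(c(1, 1), c(1, -1))        # x + y = 2, x - y = 0
  p <- c(2, 0)
  x <- c(0, 0)
  for (s in 1:60) x <- kaczmarz_sweep(x, A, p, 1)
  expect_equal(x, solve(A, p), tolerance = 1e-8)
})

test_that("zero-norm rows are skipped rather than dividing by zero", {
  A <- rbind(c(0, 0), c(1, 0))
  x <- kaczmarz_sweep(c(0, 0), A, c(7, 3), 1)
  expect_equal(x, c(3, 0))
})

test_that("ART on consistent tomographic data converges and truth is a fixed point", {
  ph <- render_phantom(phantom_spec(24, list(el_blob(c(0, 0), 8, 0.8),
                                             el_blob(c(3, 3), 3, 0.3))))
  sm <- build_system_matrix(ph, default_geometry(ph, seq(0, 178, by = 2)))
  sino <- forward_project(ph, sm)
  res <- art_reconstruct(sino, sm, recon_config("ART", max_sweeps = 300,
                                                stop_tol = 0, row_threshold = 0))
  expect_lt(res$relative_residual, 1e-4)
  expect_equal(length(res$residual_history), 300L)

  # starting from the truth: residual already ~0, image returned unchanged
  res0 <- art_reconstruct(sino, sm,
                          recon_config("ART", max_sweeps = 1, initial_image = ph,
                                       row_threshold = 0))
  expect_lt(res0$relative_residual, 1e-10)
  expect_equal(unclass(res0$image), unclass(ph), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("zero-start Kaczmarz finds the minimum-norm solution of underdetermined systems", {
  set.seed(11)
  for (rep in 1:5) {
    sys <- random_consistent_system(sample(10:40, 1), underdetermined = TRUE)
    got <- kaczmarz_solve(sys$A, sys$p)
    xmn <- pinv_solve(sys$A, sys$p)
    expect_lt(sqrt(sum((got$x - xmn)^2)) / sqrt(sum(xmn^2)), 1e-4)
  }
})

test_that("cycle averaging lands closer to least squares on an incompatible system", {
  A <- rbind(c(1, 0), c(0, 1), c(1, 1))   # three mutually inconsistent lines
  p <- c(1, 0, 2)
  x_ls <- as.numeric(solve(crossprod(A), crossprod(A, p)))
  x <- c(0, 0)
  for (s in 1:200) x <- kaczmarz_sweep(x, A, p, 1)   # settle into the cycle
  # average the iterates over one further full sweep
  acc <- c(0, 0)
  xi <- x
  for (i in 1:3) {
    xi <- kaczmarz_sweep(xi, A, p, 1, order = i)
    acc <- acc + xi
  }
  avg <- acc / 3
  d_last <- sqrt(sum((xi - x_ls)^2))
  d_avg <- sqrt(sum((avg - x_ls)^2))
  expect_lt(d_avg, d_last)

  # the bundled cycle_average mode agrees with last_iterate's data but is
  # at least as close to the least-squares solution on tomographic data
  ph <- make_lung_phantom(64, seed = 7)
  sm <- build_system_matrix(ph, default_geometry(ph, seq(0, 89, by = 3)))
  noisy <- add_poisson_noise(forward_project(ph, sm), noise_config(1e4, seed = 2),
                             pixel_size = pixel_size(ph))
  r_last <- art_reconstruct(noisy, sm, recon_config("ART", max_sweeps = 15,
                                                    stop_tol = 0))
  r_avg <- art_reconstruct(noisy, sm,
                           recon_config("ART", max_sweeps = 15, stop_tol = 0,
                                        incompatible_mode = "cycle_average"))
  expect_false(identical(unclass(r_last$image), unclass(r_avg$image)))
})

test_that("SIRT reconstructs consistent data and its residual never increases", {
  expect_error(sirt_reconstruct(NULL, NULL, recon_config("ART")), "SIRT")
  ph <- render_phantom(phantom_spec(12, list(el_blob(c(0, 0), 4, 0.8),
                                             el_blob(c(2, 1), 2, 0.3))))
  sm <- build_system_matrix(ph, default_geometry(ph, seq(0, 174, by = 6)))
  sino <- forward_project(ph, sm)

  zero <- sinogram(matrix(0, nrow(sino), ncol(sino)), sino_geometry(sino))
  rz <- sirt_reconstruct(zero, sm, recon_config("SIRT", max_sweeps = 3, stop_tol = 0))
  expect_true(all(unclass(rz$image) == 0))

  rs <- sirt_reconstruct(sino, sm, recon_config("SIRT", max_sweeps = 10000,
                                                stop_tol = 0))
  expect_true(all(diff(rs$residual_history) <= 1e-10))
  ra <- art_reconstruct(sino, sm, recon_config("ART", max_sweeps = 400,
                                               stop_tol = 0, row_threshold = 0))
  expect_lt(mse(ra$image, rs$image), 1e-4)
})

test_that("regularized least squares matches its closed forms", {
  # 1x1 grid, identity system, w = 1, B = 0: minimize (p - x)^2 + x^2 -> p/2
  g <- proj_geometry(0, detector_count = 1, detector_spacing = 1)
  sm1 <- build_system_matrix(1, g)
  expect_equal(as.matrix(sm1$R), matrix(1, 1, 1))
  sino1 <- sinogram(matrix(5, 1, 1), g)
  r <- rls_reconstruct(sino1, sm1, recon_config("RLS", regularization_weight = 1))
  expect_equal(as.numeric(r$image), 2.5)

  # w = 0 on an overdetermined consistent system equals plain least squares
  ph <- render_phantom(phantom_spec(12, list(el_blob(c(0, 0), 4, 0.6))))
  sm <- build_system_matrix(ph, default_geometry(ph, seq(0, 165, by = 15)))
  sino <- forward_project(ph, sm)
  r0 <- rls_reconstruct(sino, sm, recon_config("RLS", regularization_weight = 0))
  expect_lt(mse(r0$image, ph), 1e-8)

  # the ridge limit: the solution norm shrinks monotonically in w
  norms <- sapply(c(0.01, 1, 100, 1e4), function(w) {
    sqrt(sum(as.numeric(rls_reconstruct(sino, sm,
      recon_config("RLS", regularization_weight = w))$image)^2))
  })
  expect_true(all(diff(norms) < 0))
})

test_that("recon_config validates its ranges", {
  expect_error(recon_config("ART", relaxation = 0), "relaxation")
  expect_error(recon_config("ART", relaxation = 2), "relaxation")
  expect_error(recon_config("ART", max_sweeps = 0), "max_sweeps")
  expect_error(recon_config("RLS", regularization_weight = -1), "regularization_weight")
})
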