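#' Reconstruction configuration
#'
#' Collects every knob of the iterative and analytic reconstructors.
#'
#' @param algorithm `"ART"` (Kaczmarz row-action), `"SIRT"` (simultaneous
#'   update), `"FBP"` (filtered back projection) or `"RLS"`
#'   (smoothness-regularized least squares).
#' @param relaxation Kaczmarz/SIRT relaxation factor \eqn{\lambda} in
#'   (0, 2); it scales each hyperplane projection step and so trades
#'   convergence speed against noise smoothing. Default 1 (full
#'   projection).
#' @param max_sweeps maximum number of sweeps; one sweep is one pass over
#'   all rays.
#' @param stop_tol stop when the relative change of the sweep residual
#'   \eqn{\|Rx - p\|} falls below this (default 1e-6).
#' @param incompatible_mode for inconsistent systems, where Kaczmarz cycles
#'   instead of converging: `"last_iterate"` returns the final iterate,
#'   `"cycle_average"` returns the mean of the iterates over one final full
#'   sweep (the averaging remedy for incompatible equation groups).
#' @param regularization_weight weight w of the uniformity/smoothness
#'   penalty in RLS; `NULL` picks `0.01 * trace(R'R)/n` (a trace proxy that
#'   scales the penalty to the data term).
#' @param fbp_filter `"ramp"`, `"shepp-logan"` or `"hann"`.
#' @param initial_image `"zeros"` or an [image_grid()] start.
#' @param ray_order `"cyclic"` (matrix row order) or `"shuffled"`
#'   (per-sweep random permutation drawn from `seed`).
#' @param seed integer seed for `ray_order = "shuffled"`.
#' @param snapshot_sweeps integer vector of sweeps after which to store the
#'   current image (for convergence curves).
#' @param row_threshold rays whose squared row norm is below
#'   `row_threshold * max(squared row norms)` are skipped by ART. Rays that
#'   barely graze a grid corner have near-zero norm, and dividing a noisy
#'   residual by it makes the Kaczmarz step arbitrarily large, so such rays
#'   inject noise while carrying almost no information. Default 1e-3; set 0
#'   to update on every nonzero row.
#' @return object of class `recon_config`.
#' @export
recon_config <- function(algorithm = c("ART", "SIRT", "FBP", "RLS"),
                         relaxation = 1.0, max_sweeps = 20L, stop_tol = 1e-6,
                         incompatible_mode = c("last_iterate", "cycle_average"),
                         regularization_weight = NULL,
                         fbp_filter = c("ramp", "shepp-logan", "hann"),
                         initial_image = "zeros",
                         ray_order = c("cyclic", "shuffled"), seed = 1L,
                         snapshot_sweeps = integer(0), row_threshold = 1e-3) {
  algorithm <- match.arg(algorithm)
  if (!is.numeric(relaxation) || relaxation <= 0 || relaxation >= 2)
    stop("relaxation must lie in (0, 2)")
  max_sweeps <- as.integer(max_sweeps)
  if (max_sweeps < 1) stop("max_sweeps must be >= 1")
  if (!is.null(regularization_weight) && regularization_weight < 0)
    stop("regularization_weight must be >= 0")
  structure(list(algorithm = algorithm, relaxation = relaxation,
                 max_sweeps = max_sweeps, stop_tol = stop_tol,
                 incompatible_mode = match.arg(incompatible_mode),
                 regularization_weight = regularization_weight,
                 fbp_filter = match.arg(fbp_filter),
                 initial_image = initial_image,
                 ray_order = match.arg(ray_order), seed = as.integer(seed),
                 snapshot_sweeps = as.integer(snapshot_sweeps),
                 row_threshold = row_threshold),
            class = "recon_config")
}

new_recon_result <- function(image, residual_history, snapshots, config,
                             converged, relative_residual) {
  structure(list(image = image, residual_history = residual_history,
                 iterate_snapshots = snapshots, config = config,
                 convergence_flag = converged,
                 relative_residual = relative_residual),
            class = "recon_result")
}

#' @export
print.recon_result <- function(x, ...) {
  cat(sprintf("recon_result (%s): %d sweeps, final relative residual %.3e, %s\n",
              x$config$algorithm, length(x$residual_history),
              x$relative_residual,
              if (isTRUE(x$convergence_flag)) "converged" else "stopped at max_sweeps"))
  invisible(x)
}

# row-access view of R: columns of t(R) are the rays. Rows with squared
# norm below row_threshold * max are marked zero and skipped by the sweep.
row_access <- function(R, row_threshold = 0) {
  Rt <- as(Matrix::t(R), "CsparseMatrix")
  n2 <- as.numeric(Matrix::rowSums(R^2))
  if (row_threshold > 0) n2[n2 < row_threshold * max(n2)] <- 0
  list(ptr = Rt@p, idx = Rt@i, val = Rt@x, norm2 = n2)
}

# one pass of the Kaczmarz update over the given ray order, optionally
# accumulating the running mean of the per-ray iterates (cycle averaging)
kaczmarz_pass <- function(xv, ra, p, lambda, order, average = FALSE) {
  acc <- if (average) numeric(length(xv))
  cnt <- 0L
  ptr <- ra$ptr; idx <- ra$idx; val <- ra$val; n2 <- ra$norm2
  for (i in order) {
    a <- ptr[i] + 1L; b <- ptr[i + 1L]
    if (b < a || n2[i] <= 0) next       # zero-norm rows are skipped
    j <- idx[a:b] + 1L
    w <- val[a:b]
    step <- lambda * (p[i] - sum(w * xv[j])) / n2[i]
    xv[j] <- xv[j] + step * w
    if (average) { acc <- acc + xv; cnt <- cnt + 1L }
  }
  if (average) list(x = xv, mean = if (cnt > 0) acc / cnt else xv) else list(x = xv)
}

#' One Kaczmarz sweep
#'
#' Applies the row-action update
#' \deqn{x \leftarrow x + \lambda \frac{p_i - \langle a_i, x\rangle}{\|a_i\|^2} a_i}
#' once per ray, in the given order: each step orthogonally projects
#' (relaxed by \eqn{\lambda}) the current estimate onto the hyperplane of
#' equation i, so with \eqn{\lambda = 1} that equation holds exactly after
#' its step. Rows with zero norm are skipped.
#'
#' @param x numeric image vector (length = number of pixels).
#' @param sm a [build_system_matrix()] result, or any matrix coercible to a
#'   sparse matrix with one row per ray.
#' @param p numeric measurement vector, or a [sinogram()].
#' @param lambda relaxation factor.
#' @param order ray visiting order (default: all rays in row order).
#' @return the updated image vector.
#' @export
kaczmarz_sweep <- function(x, sm, p, lambda = 1.0, order = NULL) {
  R <- if (inherits(sm, "system_matrix")) sm$R else {
    if (is.matrix(sm)) sm <- Matrix::Matrix(sm, sparse = TRUE)
    as(as(sm, "CsparseMatrix"), "generalMatrix")
  }
  if (inherits(p, "sinogram")) p <- sino_to_vec(p)
  if (length(x) != ncol(R)) stop("x length ", length(x), " != ", ncol(R), " pixels")
  if (length(p) != nrow(R)) stop("p length ", length(p), " != ", nrow(R), " rays")
  if (is.null(order)) order <- seq_len(nrow(R))
  kaczmarz_pass(x, row_access(R), p, lambda, order)$x
}

resolve_start <- function(config, sm) {
  n <- sm$grid_size
  if (is_image_grid(config$initial_image)) {
    if (grid_size(config$initial_image) != n)
      stop("initial image size does not match system matrix grid")
    flatten_image(config$initial_image)
  } else numeric(n * n)
}

template_grid <- function(sm) {
  image_grid(matrix(0, sm$grid_size, sm$grid_size), pixel_size = sm$pixel_size)
}

iterative_orders <- function(config, m, sweeps) {
  if (config$ray_order == "cyclic") {
    rep(list(seq_len(m)), sweeps)
  } else {
    with_seed(config$seed, replicate(sweeps, sample.int(m), simplify = FALSE))
  }
}

#' Algebraic reconstruction technique (Kaczmarz) reconstruction
#'
#' Runs [kaczmarz_sweep()] repeatedly until the relative change of the
#' residual \eqn{\|Rx - p\|} drops below `stop_tol` or `max_sweeps` is
#' reached. On consistent systems the iterates converge to a solution of
#' R x = p (from a zero start, to its minimum-norm solution); on
#' inconsistent systems they eventually cycle, and
#' `incompatible_mode = "cycle_average"` returns the mean of the iterates
#' over one additional full sweep, which lies near the center of the cycle.
#'
#' @param sino a [sinogram()].
#' @param sm the [build_system_matrix()] for the same geometry.
#' @param config a [recon_config()] with `algorithm = "ART"`.
#' @return a `recon_result`: `image` (the estimate), `residual_history`
#'   (one \eqn{\|Rx - p\|} per executed sweep), `iterate_snapshots`,
#'   `config`, `convergence_flag`, `relative_residual`.
#' @export
art_reconstruct <- function(sino, sm, config = recon_config("ART")) {
  if (config$algorithm != "ART") stop("config$algorithm must be ART")
  stopifnot(inherits(sm, "system_matrix"))
  p <- sino_to_vec(sino)
  ra <- row_access(sm$R, config$row_threshold)
  xv <- resolve_start(config, sm)
  tmpl <- template_grid(sm)
  p_norm <- max(sqrt(sum(p^2)), .Machine$double.eps)
  orders <- iterative_orders(config, nrow(sm$R), config$max_sweeps)
  res_hist <- numeric(0)
  snaps <- list()
  prev_res <- sqrt(sum((as.numeric(sm$R %*% xv) - p)^2))
  converged <- FALSE
  for (k in seq_len(config$max_sweeps)) {
    xv <- kaczmarz_pass(xv, ra, p, config$relaxation, orders[[k]])$x
    if (!all(is.finite(xv)))
      stop("non-finite iterate at sweep ", k, "; reduce relaxation or check data")
    res <- sqrt(sum((as.numeric(sm$R %*% xv) - p)^2))
    res_hist <- c(res_hist, res)
    if (k %in% config$snapshot_sweeps)
      snaps[[as.character(k)]] <- unflatten_image(xv, tmpl)
    if (abs(prev_res - res) <= config$stop_tol * max(prev_res, .Machine$double.eps)) {
      converged <- TRUE
      break
    }
    prev_res <- res
  }
  if (config$incompatible_mode == "cycle_average") {
    out <- kaczmarz_pass(xv, ra, p, config$relaxation,
                         orders[[length(res_hist)]], average = TRUE)
    xv <- out$mean
  }
  new_recon_result(unflatten_image(xv, tmpl), res_hist, snaps, config,
                   converged, res_hist[length(res_hist)] / p_norm)
}

#' Simultaneous iterative reconstruction (SIRT)
#'
#' The simultaneous counterpart of the Kaczmarz update: every sweep applies
#' all ray residuals at once,
#' \deqn{x \leftarrow x + \lambda\, C^{-1} R^T W^{-1} (p - Rx),}
#' with W the diagonal of row sums and C of column sums of R (the usual
#' SIRT normalization). Smoother and strictly sweep-parallel, at the price
#' of slower convergence than ART.
#'
#' @inheritParams art_reconstruct
#' @param config a [recon_config()] with `algorithm = "SIRT"`.
#' @return a `recon_result` (see [art_reconstruct()]).
#' @export
sirt_reconstruct <- function(sino, sm, config = recon_config("SIRT")) {
  if (config$algorithm != "SIRT") stop("config$algorithm must be SIRT")
  stopifnot(inherits(sm, "system_matrix"))
  p <- sino_to_vec(sino)
  R <- sm$R
  W <- as.numeric(Matrix::rowSums(R))
  C <- as.numeric(Matrix::colSums(R))
  Winv <- ifelse(W > 0, 1 / W, 0)
  Cinv <- ifelse(C > 0, 1 / C, 0)
  xv <- resolve_start(config, sm)
  tmpl <- template_grid(sm)
  p_norm <- max(sqrt(sum(p^2)), .Machine$double.eps)
  res_hist <- numeric(0)
  snaps <- list()
  prev_res <- sqrt(sum((as.numeric(R %*% xv) - p)^2))
  converged <- FALSE
  for (k in seq_len(config$max_sweeps)) {
    r <- p - as.numeric(R %*% xv)
    xv <- xv + config$relaxation * Cinv * as.numeric(Matrix::crossprod(R, Winv * r))
    if (!all(is.finite(xv)))
      stop("non-finite iterate at sweep ", k, "; reduce relaxation or check data")
    res <- sqrt(sum((as.numeric(R %*% xv) - p)^2))
    res_hist <- c(res_hist, res)
    if (k %in% config$snapshot_sweeps)
      snaps[[as.character(k)]] <- unflatten_image(xv, tmpl)
    if (abs(prev_res - res) <= config$stop_tol * max(prev_res, .Machine$double.eps)) {
      converged <- TRUE
      break
    }
    prev_res <- res
  }
  new_recon_result(unflatten_image(xv, tmpl), res_hist, snaps, config,
                   converged, res_hist[length(res_hist)] / p_norm)
}

# graph Laplacian of the 4-neighbour pixel grid, so x'Bx sums squared
# differences over horizontally and vertically adjacent pixel pairs
neighbor_laplacian <- function(n) {
  id <- matrix(seq_len(n * n), n, n)      # column-major pixel indices
  i_h <- as.vector(id[, -n]); j_h <- as.vector(id[, -1])
  i_v <- as.vector(id[-n, ]); j_v <- as.vector(id[-1, ])
  ii <- c(i_h, i_v); jj <- c(j_h, j_v)
  A <- Matrix::sparseMatrix(i = c(ii, jj), j = c(jj, ii),
                            x = 1, dims = c(n * n, n * n))
  Matrix::Diagonal(x = as.numeric(Matrix::rowSums(A))) - A
}

#' Regularized least-squares reconstruction
#'
#' Minimizes the combined objective
#' \deqn{\|p - Rx\|^2 + w\, x^T (B + I) x,}
#' the least-squares data criterion plus a uniformity/smoothness penalty:
#' B is the graph Laplacian of the 4-neighbour pixel grid, so
#' \eqn{x^T B x} sums squared differences between adjacent pixels (local
#' uniformity) and \eqn{x^T x} penalizes overall magnitude (global
#' uniformity). Solved exactly via the sparse normal equations
#' \eqn{(R^T R + w(B + I))x = R^T p}; with w = 0 this is the plain
#' least-squares solution.
#'
#' @inheritParams art_reconstruct
#' @param config a [recon_config()] with `algorithm = "RLS"`;
#'   `regularization_weight = NULL` defaults to `0.01 * trace(R'R)/n`.
#' @return a `recon_result` with a single-entry residual history.
#' @export
rls_reconstruct <- function(sino, sm, config = recon_config("RLS")) {
  if (config$algorithm != "RLS") stop("config$algorithm must be RLS")
  stopifnot(inherits(sm, "system_matrix"))
  p <- sino_to_vec(sino)
  R <- sm$R
  w <- config$regularization_weight
  if (is.null(w)) w <- 0.01 * sum(R@x^2) / ncol(R)
  B <- neighbor_laplacian(sm$grid_size)
  M <- Matrix::crossprod(R) + w * (B + Matrix::Diagonal(ncol(R)))
  rhs <- Matrix::crossprod(R, p)
  xv <- tryCatch(as.numeric(Matrix::solve(M, rhs)),
                 error = function(e) stop(
                   "normal system is singular (w = ", w,
                   "); set regularization_weight > 0", call. = FALSE))
  res <- sqrt(sum((as.numeric(R %*% xv) - p)^2))
  p_norm <- max(sqrt(sum(p^2)), .Machine$double.eps)
  new_recon_result(unflatten_image(xv, template_grid(sm)), res, list(),
                   config, TRUE, res / p_norm)
}
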