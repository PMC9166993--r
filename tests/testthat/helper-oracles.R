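# Independent brute-force oracles. These deliberately share no code with the
# package: the strip weights use Sutherland-Hodgman polygon clipping, the
# minimum-norm solutions use the SVD pseudoinverse, and SSIM is an explicit
# double loop over windows.

# clip a convex polygon (2-column matrix of vertices) against the half-plane
# n . v <= c
clip_halfplane <- function(poly, nvec, cval) {
  if (nrow(poly) == 0) return(poly)
  d <- poly %*% nvec - cval
  out <- matrix(numeric(0), ncol = 2)
  k <- nrow(poly)
  for (i in seq_len(k)) {
    j <- if (i == k) 1L else i + 1L
    pi_ <- poly[i, ]; pj <- poly[j, ]
    di <- d[i]; dj <- d[j]
    if (di <= 0) out <- rbind(out, pi_)
    if ((di < 0) != (dj < 0) && di != dj) {
      t <- di / (di - dj)
      out <- rbind(out, pi_ + t * (pj - pi_))
    }
  }
  out
}

polygon_area <- function(poly) {
  if (nrow(poly) < 3) return(0)
  x <- poly[, 1]; y <- poly[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

# area of (strip |t - s| <= w/2) intersect (pixel square), / delta^2,
# with t = -x sin(theta) + y cos(theta)
oracle_strip_weight <- function(cx, cy, delta, theta_deg, s, w) {
  h <- delta / 2
  sq <- rbind(c(cx - h, cy - h), c(cx + h, cy - h),
              c(cx + h, cy + h), c(cx - h, cy + h))
  th <- theta_deg * pi / 180
  nvec <- c(-sin(th), cos(th))
  poly <- clip_halfplane(sq, nvec, s + w / 2)
  poly <- clip_halfplane(poly, -nvec, -(s - w / 2))
  polygon_area(poly) / delta^2
}

# dense strip-mode system matrix by polygon clipping, same ray/pixel order
# as build_system_matrix (angle-major rays, column-major pixels)
oracle_system_matrix <- function(n, delta, angles, ndet, spacing) {
  offs <- (seq_len(ndet) - 0.5 - ndet / 2) * spacing
  cols <- rep(seq_len(n), each = n); rows <- rep(seq_len(n), times = n)
  cx <- (cols - 0.5 - n / 2) * delta
  cy <- (n / 2 - rows + 0.5) * delta
  R <- matrix(0, length(angles) * ndet, n * n)
  for (ai in seq_along(angles)) for (k in seq_len(ndet)) {
    i <- (ai - 1) * ndet + k
    for (j in seq_len(n * n))
      R[i, j] <- oracle_strip_weight(cx[j], cy[j], delta, angles[ai], offs[k], spacing)
  }
  R
}

pinv_solve <- function(A, b, tol = 1e-10) {
  sv <- svd(A)
  keep <- sv$d > tol * sv$d[1]
  sv$v[, keep, drop = FALSE] %*% (crossprod(sv$u[, keep, drop = FALSE], b) / sv$d[keep])
}

# explicit sliding-window SSIM (uniform window, sample moments)
oracle_ssim <- function(a, b, k = 7, k1 = 0.01, k2 = 0.03, L = 1) {
  c1 <- (k1 * L)^2; c2 <- (k2 * L)^2
  vals <- c()
  for (i in seq_len(nrow(a) - k + 1)) for (j in seq_len(ncol(a) - k + 1)) {
    wa <- as.vector(a[i:(i + k - 1), j:(j + k - 1)])
    wb <- as.vector(b[i:(i + k - 1), j:(j + k - 1)])
    vals <- c(vals, ((2 * mean(wa) * mean(wb) + c1) * (2 * cov(wa, wb) + c2)) /
                ((mean(wa)^2 + mean(wb)^2 + c1) * (var(wa) + var(wb) + c2)))
  }
  mean(vals)
}

# random consistent linear system with aspect ratio bounded away from 1
# (rectangular Gaussian matrices are well conditioned, so the Kaczmarz
# sweep budget stays modest)
random_consistent_system <- function(n, underdetermined) {
  m <- if (underdetermined) ceiling(0.7 * n) else ceiling(1.6 * n)
  A <- matrix(rnorm(m * n), m, n)
  list(A = A, p = as.numeric(A %*% rnorm(n)), m = m, n = n)
}

kaczmarz_solve <- function(A, p, max_sweeps = 2000, tol = 1e-7) {
  x <- numeric(ncol(A))
  pn <- sqrt(sum(p^2))
  for (s in seq_len(max_sweeps)) {
    x <- kaczmarz_sweep(x, A, p, 1.0)
    if (sqrt(sum((A %*% x - p)^2)) / pn < tol) break
  }
  list(x = x, rel_resid = sqrt(sum((A %*% x - p)^2)) / pn, sweeps = s)
}
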