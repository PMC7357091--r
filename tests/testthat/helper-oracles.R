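# Independent oracles. These deliberately avoid the package's own code
# paths: closed-form statistics coded from the textbook formulas, brute
# force rasterization, literal signal-model evaluation, and a
# projection-matrix grid search for the Dixon residual.

# two-sample t-test from the closed forms (Welch or pooled)
oracle_t_test <- function(x, y, var_equal = FALSE) {
  nx <- length(x); ny <- length(y)
  vx <- sum((x - mean(x))^2) / (nx - 1)
  vy <- sum((y - mean(y))^2) / (ny - 1)
  if (var_equal) {
    sp2 <- ((nx - 1) * vx + (ny - 1) * vy) / (nx + ny - 2)
    t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
    df <- nx + ny - 2
  } else {
    se2 <- vx / nx + vy / ny
    t <- (mean(x) - mean(y)) / sqrt(se2)
    df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  }
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

# Pearson r and its two-sided p from the covariance formula
oracle_pearson <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(t), n - 2))
}

# brute-force pixel census of a polygon via mgcv's point-in-polygon
oracle_polygon_pixels <- function(poly) {
  rs <- ceiling(min(poly[, 1])):floor(max(poly[, 1]))
  cs <- ceiling(min(poly[, 2])):floor(max(poly[, 2]))
  g <- expand.grid(row = rs, col = cs)
  # mgcv::in.out wants the boundary as an (x, y) matrix
  bnd <- cbind(poly[, 2], poly[, 1])
  keep <- mgcv::in.out(bnd, cbind(g$col, g$row))
  sum(keep)
}

# literal evaluation of the dual-echo Dixon signal model
oracle_dixon_signal <- function(W, F, psi_hz, te_ms, fat_shift_hz = -434) {
  te_s <- te_ms / 1000
  (W + exp(1i * 2 * pi * fat_shift_hz * te_s) * F) *
    exp(1i * 2 * pi * psi_hz * te_s)
}

# Exhaustive field-map grid search for the two-point Dixon problem.
# Residual route: demodulate, project onto the span of the real
# (water, fat) design with an explicitly constructed projection matrix,
# and profile the global phase by sampling the quadratic form at three
# angles (a sinusoid in 2*phi0 is determined by three samples).
# Returns the per-voxel minimum residual over the psi grid.
oracle_dixon_grid_min <- function(s1, s2, te_ms, fat_shift_hz = -434,
                                  n_psi = 256L) {
  te_s <- te_ms / 1000
  c1 <- exp(1i * 2 * pi * fat_shift_hz * te_s[1])
  c2 <- exp(1i * 2 * pi * fat_shift_hz * te_s[2])
  A <- matrix(c(1, 0, 1, 0, Re(c1), Im(c1), Re(c2), Im(c2)), 4, 2)
  M <- diag(4) - A %*% solve(crossprod(A)) %*% t(A)  # residual projector
  period <- 1 / abs(diff(te_s))
  psis <- seq(-period / 2, period / 2, length.out = n_psi + 1L)[1:n_psi]
  best <- rep(Inf, length(s1))
  for (psi in psis) {
    d1 <- s1 * exp(-2i * pi * psi * te_s[1])
    d2 <- s2 * exp(-2i * pi * psi * te_s[2])
    P <- rbind(Re(d1), Im(d1), Re(d2), Im(d2))
    Q <- rbind(Im(d1), -Re(d1), Im(d2), -Re(d2))
    MP <- M %*% P; MQ <- M %*% Q
    f0 <- colSums(MP^2); f90 <- colSums(MQ^2); x <- colSums(MP * MQ)
    res <- (f0 + f90) / 2 - sqrt(((f0 - f90) / 2)^2 + x^2)
    best <- pmin(best, res)
  }
  pmax(best, 0)
}

# Rayleigh mean of |complex Gaussian| by Monte Carlo
oracle_rayleigh_mean <- function(sigma, n = 1e5, seed = 42) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  mean(sqrt(stats::rnorm(n, 0, sigma)^2 + stats::rnorm(n, 0, sigma)^2))
}
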