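# --- two-point phase-constrained least squares -------------------------
#
# Model per voxel: s_n = exp(i*phi0) * (W + c_n * F) * exp(i*2*pi*psi*te_n)
# with W, F real nonnegative amplitudes, c_n = exp(i*2*pi*f_fat*te_n),
# phi0 an arbitrary coil phase, psi the off-resonance (Hz).
#
# For a trial psi we demodulate d_n = s_n * exp(-i*2*pi*psi*te_n) and
# minimize sum_n |d_n - exp(i*phi0)*(W + c_n F)|^2 over (W, F, phi0).
# Profiling out (W, F) for fixed phi0 leaves a quadratic form on the
# unit circle whose maximizer is closed-form, so the residual J(psi) and
# the amplitudes are evaluated in a handful of vectorized array ops.
# J is periodic in psi with period 1000/(TE2-TE1) Hz (the aliasing
# frequency of the echo spacing).

# residual J (and optionally amplitudes) for trial psi; s1, s2, psi are
# equal-length complex/numeric vectors, te_s echo times in seconds
.dixon_ls <- function(s1, s2, psi, te_s, c1, c2, amplitudes = FALSE) {
  d1 <- s1 * exp(-2i * pi * psi * te_s[1])
  d2 <- s2 * exp(-2i * pi * psi * te_s[2])
  u <- d1 + d2
  v <- Conj(c1) * d1 + Conj(c2) * d2
  sc <- Re(c1 + c2)
  det <- 4 - sc^2
  # quadratic form b'Pb on the phi0 circle: alpha = at phi0 = 0,
  # gamma = at phi0 = pi/2, beta = cross term
  qf <- function(x, y) (2 * x^2 - 2 * sc * x * y + 2 * y^2) / det
  alpha <- qf(Re(u), Re(v))
  gamma <- qf(Im(u), Im(v))
  beta <- (2 * Re(u) * Im(u) - sc * (Re(u) * Im(v) + Im(u) * Re(v)) +
             2 * Re(v) * Im(v)) / det
  tot <- Mod(d1)^2 + Mod(d2)^2
  half <- sqrt(((alpha - gamma) / 2)^2 + beta^2)
  proj <- (alpha + gamma) / 2 + half
  # single-species fallbacks (F = 0 or W = 0) cover amplitude clamping
  proj_w <- Mod(u)^2 / 2
  proj_f <- Mod(v)^2 / 2
  if (!amplitudes) return(pmax(tot - proj, 0))
  phi0 <- 0.5 * atan2(2 * beta, alpha - gamma)
  ru <- Re(u * exp(-1i * phi0)); rv <- Re(v * exp(-1i * phi0))
  w <- (2 * ru - sc * rv) / det
  f <- (-sc * ru + 2 * rv) / det
  neg <- w + f < 0
  w[neg] <- -w[neg]; f[neg] <- -f[neg]
  res <- tot - proj
  # clamp negative amplitudes to the better single-species solution
  bad <- which(w < 0 | f < 0)
  if (length(bad)) {
    use_w <- proj_w[bad] >= proj_f[bad]
    w[bad] <- ifelse(use_w, Mod(u[bad]) / 2, 0)
    f[bad] <- ifelse(use_w, 0, Mod(v[bad]) / 2)
    res[bad] <- tot[bad] - ifelse(use_w, proj_w[bad], proj_f[bad])
  }
  list(residual = pmax(res, 0), water = w, fat = f)
}

# unconstrained residual only (vector), used by candidates + refinement
.dixon_residual <- function(s1, s2, psi, te_s, c1, c2) {
  .dixon_ls(s1, s2, psi, te_s, c1, c2, amplitudes = FALSE)
}

# per-voxel candidate field maps: local minima of J on a circular grid
# spanning one aliasing period, refined by parabolic interpolation.
# Returns list(psi = V x K matrix, res = V x K) padded with NA.
.dixon_candidates <- function(s1, s2, te_s, c1, c2, n_grid, max_cand = 4L) {
  period <- 1 / abs(diff(te_s))
  grid <- seq(-period / 2, period / 2, length.out = n_grid + 1L)[1:n_grid]
  dpsi <- period / n_grid
  nv <- length(s1)
  J <- matrix(0, nv, n_grid)
  for (j in seq_len(n_grid))
    J[, j] <- .dixon_residual(s1, s2, rep(grid[j], nv), te_s, c1, c2)
  left <- c(n_grid, seq_len(n_grid - 1L))
  right <- c(seq_len(n_grid - 1L) + 1L, 1L)
  is_min <- J < J[, left, drop = FALSE] & J <= J[, right, drop = FALSE]
  psi_c <- matrix(NA_real_, nv, max_cand)
  res_c <- matrix(Inf, nv, max_cand)
  hits <- which(is_min, arr.ind = TRUE)
  # voxels with no strict local minimum (flat profiles) fall back to the
  # per-row global minimum
  flat <- which(tabulate(hits[, 1], nv) == 0L)
  if (length(flat)) {
    gm <- max.col(-J[flat, , drop = FALSE], ties.method = "first")
    hits <- rbind(hits, cbind(row = flat, col = gm))
  }
  v <- hits[, 1]; j <- hits[, 2]
  j0 <- J[hits]
  jl <- J[cbind(v, left[j])]; jr <- J[cbind(v, right[j])]
  den <- jl - 2 * j0 + jr
  shift <- ifelse(den > 0, 0.5 * (jl - jr) / den, 0)
  psi_h <- grid[j] + shift * dpsi
  # rank candidates within each voxel by residual, keep the best K
  ord <- order(v, j0)
  v <- v[ord]; j0 <- j0[ord]; psi_h <- psi_h[ord]
  rank <- sequence(rle(v)$lengths)
  keep <- rank <= max_cand
  psi_c[cbind(v[keep], rank[keep])] <- psi_h[keep]
  res_c[cbind(v[keep], rank[keep])] <- j0[keep]
  list(psi = psi_c, res = res_c)
}

# Resolve the water/fat ambiguity by breadth-first region growing over
# the tissue mask: the seed (highest-magnitude voxel, ties to the lowest
# linear index) takes its lowest-residual candidate; every subsequent
# voxel takes the candidate closest to the mean field map of its
# already-resolved 6-neighbors. Disconnected components restart at their
# own highest-magnitude voxel.
.dixon_region_grow <- function(cand, mag, mask_idx, dm) {
  nv <- length(mask_idx)
  ns <- dm[1]; nr <- dm[2]; nc <- dm[3]
  idx_of <- integer(prod(dm))          # full-volume -> masked row (0 = out)
  idx_of[mask_idx] <- seq_len(nv)
  co <- arrayInd(mask_idx, dm)
  offs <- c(-1L, 1L, -ns, ns, -ns * nr, ns * nr)
  # per-voxel masked neighbor lists (bounds-checked), built vectorized
  nbr <- matrix(0L, nv, 6L)
  okm <- cbind(co[, 1] > 1, co[, 1] < ns, co[, 2] > 1, co[, 2] < nr,
               co[, 3] > 1, co[, 3] < nc)
  for (k in 1:6) {
    cand_idx <- mask_idx + offs[k]
    val <- integer(nv)
    ok <- okm[, k]
    val[ok] <- idx_of[cand_idx[ok]]
    nbr[, k] <- val
  }
  chosen <- rep(NA_real_, nv)
  visited <- logical(nv)
  queued <- logical(nv)
  psum <- numeric(nv); pcnt <- integer(nv)
  queue <- integer(nv); head <- 1L; tail <- 0L
  order_mag <- order(-mag, seq_len(nv))
  next_seed <- 1L
  done <- 0L
  while (done < nv) {
    if (head > tail) {                 # (re)start a component
      while (visited[order_mag[next_seed]]) next_seed <- next_seed + 1L
      s <- order_mag[next_seed]
      tail <- tail + 1L; queue[tail] <- s; queued[s] <- TRUE
      # seed disambiguation: among near-tied residuals (the water/fat
      # swap is an exact tie on noiseless data) take the candidate with
      # the smallest |psi| — the field map is assumed shimmed near zero
      rmin <- min(cand$res[s, ])
      elig <- which(cand$res[s, ] <= rmin + 0.05 * mag[s]^2)
      k0 <- elig[which.min(abs(cand$psi[s, elig]))]
      psum[s] <- cand$psi[s, k0]; pcnt[s] <- 1L
    }
    v <- queue[head]; head <- head + 1L
    if (visited[v]) next
    ref <- psum[v] / pcnt[v]
    pc <- cand$psi[v, ]
    k <- which.min(abs(pc - ref))
    chosen[v] <- pc[k]
    visited[v] <- TRUE
    done <- done + 1L
    for (u in nbr[v, ]) {
      if (u > 0L && !visited[u]) {
        psum[u] <- psum[u] + chosen[v]
        pcnt[u] <- pcnt[u] + 1L
        if (!queued[u]) {
          tail <- tail + 1L
          if (tail > length(queue)) queue <- c(queue, integer(nv))
          queue[tail] <- u; queued[u] <- TRUE
        }
      }
    }
  }
  chosen
}

#' Two-point Dixon water/fat separation
#'
#' Separates dual-echo complex data into water and fat amplitude maps
#' with a per-voxel off-resonance field map, in three stages:
#' \enumerate{
#'   \item \emph{candidate enumeration}: the discrete local minimizers of
#'     the phase-constrained least-squares residual are found on a field
#'     map grid spanning one aliasing period (`n_fieldmap_candidates`
#'     grid points);
#'   \item \emph{region growing}: the water/fat ambiguity is resolved by
#'     growing from the highest-magnitude seed voxel, each voxel taking
#'     the candidate closest to the mean field map of its already
#'     resolved neighbors;
#'   \item \emph{refinement}: the field map is polished voxelwise by
#'     damped Newton steps on the least-squares residual until the
#'     update falls below `tol` Hz or `refine_iters` is reached
#'     (non-converged voxels keep their last iterate and are flagged).
#' }
#' Water and fat amplitudes are solved at the converged field map;
#' negative amplitudes are clamped to the better single-species fit.
#'
#' @param data a `dual_echo_complex` (see [simulate_dixon()]).
#' @param n_fieldmap_candidates grid points across one aliasing period.
#' @param refine_iters maximum Newton refinement iterations.
#' @param tol convergence tolerance on the field-map update (Hz).
#' @param mask optional logical array of voxels to solve; default:
#'   voxels with total magnitude above `1e-6 * max`.
#' @return A `water_fat_result`: arrays `water`, `fat`, `psi` (Hz),
#'   `residual`, logical `defined` and `converged`, plus
#'   `water_percent` (see [water_percent_map()]).
#' @export
separate_water_fat <- function(data, n_fieldmap_candidates = 64L,
                               refine_iters = 20L, tol = 0.01,
                               mask = NULL) {
  stopifnot(inherits(data, "dual_echo_complex"))
  dm <- dim(data$echo1)
  mag <- Mod(data$echo1) + Mod(data$echo2)
  thr <- 1e-6 * max(mag)
  if (is.null(mask)) mask <- mag > thr else stopifnot(identical(dim(mask), dm))
  empty <- array(NA_real_, dm)
  if (max(mag) == 0 || !any(mask)) {
    return(structure(list(water = empty, fat = empty, psi = empty,
                          residual = empty,
                          defined = array(FALSE, dm),
                          converged = array(FALSE, dm),
                          echo_times = data$echo_times,
                          fat_shift_hz = data$fat_shift_hz),
                     class = "water_fat_result"))
  }
  te_s <- data$echo_times / 1000
  c1 <- exp(2i * pi * data$fat_shift_hz * te_s[1])
  c2 <- exp(2i * pi * data$fat_shift_hz * te_s[2])
  mask_idx <- which(mask)
  s1 <- data$echo1[mask_idx]; s2 <- data$echo2[mask_idx]

  # stage 1: candidates (chunked to bound the V x P residual matrix)
  nvm <- length(mask_idx)
  chunk <- 65536L
  starts <- seq(1L, nvm, by = chunk)
  cand_psi <- matrix(NA_real_, nvm, 4L)
  cand_res <- matrix(Inf, nvm, 4L)
  for (st in starts) {
    en <- min(st + chunk - 1L, nvm)
    cc <- .dixon_candidates(s1[st:en], s2[st:en], te_s, c1, c2,
                            n_grid = n_fieldmap_candidates)
    cand_psi[st:en, ] <- cc$psi
    cand_res[st:en, ] <- cc$res
  }

  # stage 2: region growing
  psi <- .dixon_region_grow(list(psi = cand_psi, res = cand_res),
                            mag[mask_idx], mask_idx, dm)

  # stage 3: vectorized damped Newton refinement of psi
  delta <- 0.5  # Hz; finite-difference step
  active <- rep(TRUE, nvm)
  for (it in seq_len(refine_iters)) {
    if (!any(active)) break
    a <- which(active)
    j0 <- .dixon_residual(s1[a], s2[a], psi[a], te_s, c1, c2)
    jp <- .dixon_residual(s1[a], s2[a], psi[a] + delta, te_s, c1, c2)
    jm <- .dixon_residual(s1[a], s2[a], psi[a] - delta, te_s, c1, c2)
    g <- (jp - jm) / (2 * delta)
    h <- (jp - 2 * j0 + jm) / delta^2
    step <- ifelse(h > 0, -g / h, -sign(g) * delta)
    step <- pmax(pmin(step, 25), -25)
    psi[a] <- psi[a] + step
    active[a] <- abs(step) >= tol
  }
  fit <- .dixon_ls(s1, s2, psi, te_s, c1, c2, amplitudes = TRUE)

  water <- fat <- psi_a <- res_a <- empty
  water[mask_idx] <- fit$water
  fat[mask_idx] <- fit$fat
  psi_a[mask_idx] <- psi
  res_a[mask_idx] <- fit$residual
  defined <- array(FALSE, dm)
  defined[mask_idx] <- (fit$water + fit$fat) >= thr
  converged <- array(FALSE, dm)
  converged[mask_idx] <- !active
  structure(list(water = water, fat = fat, psi = psi_a, residual = res_a,
                 defined = defined, converged = converged,
                 echo_times = data$echo_times,
                 fat_shift_hz = data$fat_shift_hz),
            class = "water_fat_result")
}

#' Water-percentage map from a separation result
#'
#' `100 * |W| / (|W| + |F|)` per voxel, NA (undefined) where the
#' denominator is below the definition threshold recorded during
#' separation.
#'
#' @param result a `water_fat_result` from [separate_water_fat()].
#' @return 3D array of water percentages in `[0, 100]`, NA where
#'   undefined.
#' @export
water_percent_map <- function(result) {
  stopifnot(inherits(result, "water_fat_result"))
  wp <- array(NA_real_, dim = dim(result$water))
  ok <- result$defined & !is.na(result$water)
  wp[ok] <- 100 * result$water[ok] / (result$water[ok] + result$fat[ok])
  wp
}

#' @export
print.water_fat_result <- function(x, ...) {
  cat("<water_fat_result>", paste(dim(x$water), collapse = " x "),
      sprintf("| %d defined voxels | median water %% %.1f\n",
              sum(x$defined),
              stats::median(water_percent_map(x), na.rm = TRUE)))
  invisible(x)
}
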