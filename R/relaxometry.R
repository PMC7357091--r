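#' Voxelwise T2 mapping by log-linear least squares
#'
#' Fits the mono-exponential decay `S(TE) = S0 * exp(-TE / T2)` in each
#' voxel by ordinary least squares of `log(S)` against echo time:
#' `T2 = -1 / slope`, `S0 = exp(intercept)`. All echoes enter the fit
#' unweighted. A voxel is marked invalid (never silently zero) when any
#' echo intensity is at or below `min_intensity`, when the fitted slope
#' is nonnegative (no decay), or when fewer than two echoes are usable.
#' Valid T2 values are clamped to `(0, t2_clamp_ms]`.
#'
#' With exactly two echoes the OLS solution reduces to the closed form
#' `T2 = (TE2 - TE1) / log(S1 / S2)`.
#'
#' @param stack a `multiecho_stack` (see [simulate_multiecho()]), or a
#'   4D array with echo as the last dimension plus `echo_times`.
#' @param mask optional logical array restricting the fit.
#' @param echo_times echo times in ms (taken from the stack if absent).
#' @param min_intensity intensity floor guarding the log transform
#'   (default 1 signal unit).
#' @param t2_clamp_ms upper clamp for T2 (default 2000 ms).
#' @return A `t2_map`: list of arrays `t2` (ms, NA where invalid), `s0`,
#'   `r2` (log-domain coefficient of determination) and logical `valid`.
#' @export
fit_t2_map <- function(stack, mask = NULL, echo_times = NULL,
                       min_intensity = 1, t2_clamp_ms = 2000) {
  if (inherits(stack, "multiecho_stack")) {
    vol <- stack$volumes
    if (is.null(echo_times)) echo_times <- stack$echo_times
  } else vol <- stack
  nd <- length(dim(vol))
  if (is.null(echo_times)) stop("echo_times required")
  ne <- length(echo_times)
  if (ne < 2L) stop("need at least 2 echoes")
  if (any(duplicated(echo_times))) stop("echo times must be distinct")
  if (dim(vol)[nd] != ne) stop("echo count does not match volume count")
  dm <- dim(vol)[-nd]
  if (!is.null(mask) && !identical(dim(mask), dm))
    stop("mask shape does not match volumes")

  nv <- prod(dm)
  S <- matrix(vol, nrow = nv, ncol = ne)
  use <- if (is.null(mask)) rep(TRUE, nv) else as.vector(mask)
  usable <- use & rowSums(S <= min_intensity) == 0L

  t2 <- s0 <- r2 <- rep(NA_real_, nv)
  if (any(usable)) {
    Y <- log(S[usable, , drop = FALSE])
    tec <- echo_times - mean(echo_times)
    sxx <- sum(tec^2)
    ybar <- rowMeans(Y)
    slope <- as.vector(Y %*% tec) / sxx
    icpt <- ybar - slope * mean(echo_times)
    Yc <- Y - ybar  # recycles ybar along columns: centers each row
    ssr <- rowSums((Yc - outer(slope, tec))^2)
    sst <- rowSums(Yc^2)
    ok <- slope < 0
    t2v <- ifelse(ok, pmin(-1 / slope, t2_clamp_ms), NA_real_)
    t2[usable] <- t2v
    s0[usable] <- ifelse(ok, exp(icpt), NA_real_)
    r2[usable] <- ifelse(ok & sst > 0, 1 - ssr / sst, NA_real_)
  }
  valid <- !is.na(t2)
  structure(list(t2 = array(t2, dm), s0 = array(s0, dm),
                 r2 = array(r2, dm), valid = array(valid, dm),
                 echo_times = echo_times,
                 min_intensity = min_intensity, t2_clamp_ms = t2_clamp_ms),
            class = "t2_map")
}

#' @export
print.t2_map <- function(x, ...) {
  cat("<t2_map>", paste(dim(x$t2), collapse = " x "),
      sprintf("| %d/%d valid voxels | median T2 %.1f ms\n",
              sum(x$valid), length(x$valid),
              stats::median(x$t2[x$valid])))
  invisible(x)
}
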