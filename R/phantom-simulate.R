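# Map a label volume plus per-disc ground truth onto voxelwise parameter
# volumes (proton density, T2 in ms, water %). Vertebral bodies get
# fixed marrow-like defaults; background is zero signal.
.parameter_volumes <- function(labels, discs,
                               vb = list(pd = 600, t2 = 60, water = 40)) {
  lab <- labels$labels
  pd <- array(0, dim = dim(lab))
  t2 <- array(Inf, dim = dim(lab))  # background: no decay of zero signal
  water <- array(0, dim = dim(lab))
  is_vb <- lab == 1L
  pd[is_vb] <- vb$pd; t2[is_vb] <- vb$t2; water[is_vb] <- vb$water
  for (d in seq_along(labels$disc_ids)) {
    i <- match(labels$disc_ids[d], discs$disc_id)
    ann <- lab == labels$codes$annulus[d]
    nuc <- lab == labels$codes$nucleus[d]
    pd[ann] <- discs$pd_annulus[i]; pd[nuc] <- discs$pd_nucleus[i]
    t2[ann] <- discs$t2_annulus[i]; t2[nuc] <- discs$t2_nucleus[i]
    water[ann] <- discs$water_annulus[i]; water[nuc] <- discs$water_nucleus[i]
  }
  list(pd = pd, t2 = t2, water = water)
}

# Rician magnitude: |(S + n1) + i n2| with n1, n2 ~ N(0, sigma)
.rician <- function(signal, sigma) {
  if (sigma <= 0) return(signal)
  n <- length(signal)
  sqrt((signal + stats::rnorm(n, 0, sigma))^2 + stats::rnorm(n, 0, sigma)^2)
}

#' Generate a smooth off-resonance field map
#'
#' Random second-order polynomial in normalized coordinates, rescaled so
#' the maximum absolute off-resonance equals `amplitude_hz`. Intended to
#' stay well below the two-point Dixon aliasing frequency
#' `1000 / (2 * (TE2 - TE1))` Hz (about 410 Hz for TEs 2.45/3.67 ms).
#'
#' @param dim integer vector `(n_slices, n_rows, n_cols)`.
#' @param amplitude_hz peak |off-resonance| in Hz (default 40).
#' @param seed integer seed.
#' @return 3D array of off-resonance frequencies (Hz) with attribute
#'   `amplitude_hz`.
#' @export
field_map <- function(dim, amplitude_hz = 40, seed = NULL) {
  stopifnot(length(dim) == 3L)
  with_seed(seed, {
    co <- stats::rnorm(10)
    x <- seq(-1, 1, length.out = dim[1])
    y <- seq(-1, 1, length.out = dim[2])
    z <- seq(-1, 1, length.out = dim[3])
    g <- expand.grid(x = x, y = y, z = z)
    v <- co[1] + co[2] * g$x + co[3] * g$y + co[4] * g$z +
      co[5] * g$x * g$y + co[6] * g$x * g$z + co[7] * g$y * g$z +
      co[8] * g$x^2 + co[9] * g$y^2 + co[10] * g$z^2
    m <- max(abs(v))
    if (m > 0) v <- v / m * amplitude_hz
    psi <- array(v, dim = dim)
    attr(psi, "amplitude_hz") <- amplitude_hz
    psi
  })
}

#' Simulate a multi-echo spin-echo magnitude stack
#'
#' Per voxel the noiseless signal follows the mono-exponential decay
#' `S(TE) = PD * exp(-TE / T2)` of the labeled compartment; Rician noise
#' (magnitude of a complex Gaussian perturbation with per-channel
#' standard deviation `noise_sigma`) is applied when `noise_sigma > 0`.
#'
#' @param labels a `label_volume` from [rasterize_subject()].
#' @param discs matching `disc_truth` rows.
#' @param params multiecho [acquisition_params()].
#' @param noise_sigma magnitude-noise scale (signal units).
#' @param seed integer seed.
#' @return A `multiecho_stack`: list with `volumes` (4D array
#'   slice x row x col x echo) and `echo_times` (ms).
#' @export
simulate_multiecho <- function(labels, discs,
                               params = acquisition_params("multiecho"),
                               noise_sigma = 0, seed = NULL) {
  if (params$technique != "multiecho") stop("params$technique must be 'multiecho'")
  par <- .parameter_volumes(labels, discs)
  te <- params$echo_times
  dm <- dim(labels$labels)
  vol <- array(0, dim = c(dm, length(te)))
  with_seed(seed, {
    for (e in seq_along(te)) {
      s <- par$pd * exp(-te[e] / par$t2)
      vol[, , , e] <- .rician(s, noise_sigma)
    }
  })
  structure(list(volumes = vol, echo_times = te, params = params),
            class = "multiecho_stack")
}

#' Simulate a single-echo T2-weighted magnitude image
#'
#' Same signal model as [simulate_multiecho()] evaluated at the single
#' T2w echo time (default 70 ms).
#'
#' @inheritParams simulate_multiecho
#' @param params t2w [acquisition_params()].
#' @return 3D magnitude array with attribute `echo_time`.
#' @export
simulate_t2w <- function(labels, discs, params = acquisition_params("t2w"),
                         noise_sigma = 0, seed = NULL) {
  if (params$technique != "t2w") stop("params$technique must be 't2w'")
  par <- .parameter_volumes(labels, discs)
  s <- par$pd * exp(-params$echo_times[1] / par$t2)
  img <- with_seed(seed, array(.rician(s, noise_sigma), dim = dim(s)))
  attr(img, "echo_time") <- params$echo_times[1]
  img
}

#' Simulate dual-echo complex Dixon data
#'
#' Single-peak fat model: per voxel
#' `s(TE) = (W + c(TE) * F) * exp(i * 2 * pi * psi * TE)` with
#' `c(TE) = exp(i * 2 * pi * f_fat * TE)`, water amplitude
#' `W = PD * water% / 100` and fat amplitude `F = PD * (1 - water% / 100)`.
#' Independent complex Gaussian noise (sd `noise_sigma` per channel) is
#' added to each echo.
#'
#' @inheritParams simulate_multiecho
#' @param fieldmap off-resonance array (Hz) from [field_map()], or NULL
#'   for a homogeneous field.
#' @param params dixon [acquisition_params()].
#' @param fat_shift_hz fat chemical shift (Hz); default -434 (3.4 ppm at
#'   3 T).
#' @return A `dual_echo_complex`: list with complex arrays `echo1`,
#'   `echo2`, `echo_times` (ms) and `fat_shift_hz`.
#' @export
simulate_dixon <- function(labels, discs, fieldmap = NULL,
                           params = acquisition_params("dixon"),
                           noise_sigma = 0, seed = NULL,
                           fat_shift_hz = -434) {
  if (params$technique != "dixon") stop("params$technique must be 'dixon'")
  par <- .parameter_volumes(labels, discs)
  dm <- dim(labels$labels)
  if (is.null(fieldmap)) fieldmap <- array(0, dim = dm)
  te_s <- params$echo_times / 1000
  alias <- 1 / (2 * diff(te_s))
  if (max(abs(fieldmap)) >= alias)
    warning(sprintf("field map exceeds the aliasing bound %.1f Hz", alias))
  W <- par$pd * par$water / 100
  F <- par$pd * (1 - par$water / 100)
  echoes <- with_seed(seed, lapply(1:2, function(n) {
    cte <- exp(1i * 2 * pi * fat_shift_hz * te_s[n])
    s <- (W + cte * F) * exp(1i * 2 * pi * fieldmap * te_s[n])
    if (noise_sigma > 0)
      s <- s + complex(real = stats::rnorm(length(s), 0, noise_sigma),
                       imaginary = stats::rnorm(length(s), 0, noise_sigma))
    array(s, dim = dm)
  }))
  dual_echo_complex(echoes[[1]], echoes[[2]], params$echo_times, fat_shift_hz)
}

#' Construct a dual-echo complex container
#'
#' @param echo1,echo2 complex arrays of identical shape.
#' @param echo_times two echo times in ms, TE1 < TE2.
#' @param fat_shift_hz fat chemical shift in Hz.
#' @return A `dual_echo_complex` object.
#' @export
dual_echo_complex <- function(echo1, echo2, echo_times = c(2.45, 3.67),
                              fat_shift_hz = -434) {
  if (!identical(dim(echo1), dim(echo2))) stop("echo volumes differ in shape")
  if (length(echo_times) != 2L || echo_times[1] == echo_times[2])
    stop("need two distinct echo times")
  structure(list(echo1 = echo1, echo2 = echo2, echo_times = echo_times,
                 fat_shift_hz = fat_shift_hz),
            class = "dual_echo_complex")
}
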