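#' Acquisition parameters per technique
#'
#' Defaults follow the sagittal 3 T protocol the phantom emulates:
#' an 8-echo spin-echo T2-mapping sequence (echo times 15.75 to
#' 162.75 ms in 21 ms steps, TR 2000 ms, 12 slices), a single-echo
#' T2-weighted sequence (TE 70 ms, TR 2600 ms) and a dual-echo
#' asymmetric Dixon sequence (TEs 2.45/3.67 ms, TR 5.27 ms).
#'
#' The simulation matrix (`n_slices`, `n_rows`, `n_cols`) is a
#' desk-scaled grid shared by all techniques, i.e. the phantom's
#' acquisitions are perfectly co-registered; the printed field-of-view
#' and in-plane resolution of the emulated protocol are kept as
#' metadata. Rows run superior-inferior, columns anterior-posterior
#' (anterior = lower column index); indices are 0-based in the on-disk
#' ROI format and 1-based inside R arrays.
#'
#' @param technique one of `"multiecho"`, `"t2w"`, `"dixon"`.
#' @param echo_times echo times in ms.
#' @param repetition_time TR in ms (metadata only; no saturation model).
#' @param n_slices,n_rows,n_cols simulation grid.
#' @param slice_thickness_mm,fov_mm,resolution_mm protocol metadata.
#' @return An object of class `acquisition_params`.
#' @export
acquisition_params <- function(technique = c("multiecho", "t2w", "dixon"),
                               echo_times = NULL,
                               repetition_time = NULL,
                               n_slices = 12L, n_rows = 110L, n_cols = 48L,
                               slice_thickness_mm = 3,
                               fov_mm = NULL, resolution_mm = NULL) {
  technique <- match.arg(technique)
  defaults <- switch(technique,
    multiecho = list(te = c(15.75, 36.75, 57.75, 78.75, 99.75, 120.75,
                            141.75, 162.75),
                     tr = 2000, fov = 281, res = 0.366),
    t2w = list(te = 70, tr = 2600, fov = 357, res = 0.532),
    dixon = list(te = c(2.45, 3.67), tr = 5.27, fov = 400, res = 0.833))
  if (is.null(echo_times)) echo_times <- defaults$te
  if (is.null(repetition_time)) repetition_time <- defaults$tr
  if (is.null(fov_mm)) fov_mm <- defaults$fov
  if (is.null(resolution_mm)) resolution_mm <- defaults$res
  if (technique == "multiecho") {
    if (length(echo_times) != 8L || any(diff(echo_times) <= 0))
      stop("multiecho requires exactly 8 strictly increasing echo times")
  }
  if (technique == "dixon") {
    if (length(echo_times) != 2L || echo_times[1] >= echo_times[2])
      stop("dixon requires exactly 2 echo times with TE1 < TE2")
  }
  structure(list(technique = technique, echo_times = echo_times,
                 repetition_time = repetition_time,
                 n_slices = as.integer(n_slices), n_rows = as.integer(n_rows),
                 n_cols = as.integer(n_cols),
                 slice_thickness_mm = slice_thickness_mm,
                 fov_mm = fov_mm, resolution_mm = resolution_mm),
            class = "acquisition_params")
}

# label codes: 0 background, 1 vertebral body, 10*d+1 annulus of disc d,
# 10*d+2 nucleus of disc d
.annulus_code <- function(d) 10L * d + 1L
.nucleus_code <- function(d) 10L * d + 2L

#' Rasterize a subject's discs into a label volume
#'
#' Renders each disc as an ellipse per sagittal slice (identical across
#' slices), with an inner nucleus compartment spanning the central fifth
#' of the anteroposterior extent and annulus elsewhere. Vertebral bodies
#' are filled in as rectangles between consecutive discs so that the
#' tissue mask is spatially connected (needed by the Dixon region-growing
#' solver and realistic for marrow signal).
#'
#' @param discs `disc_truth` rows for one subject (must share
#'   `subject_id`).
#' @param params an [acquisition_params()] giving the grid.
#' @param vertebral_bodies logical; render vertebral bodies (default
#'   TRUE).
#' @return A `label_volume`: list with `labels` (integer array
#'   slice x row x col), `disc_ids`, `codes` (data frame mapping disc to
#'   annulus/nucleus code) and `params`.
#' @export
rasterize_subject <- function(discs, params = acquisition_params("multiecho"),
                              vertebral_bodies = TRUE) {
  stopifnot(nrow(discs) >= 1L)
  if (length(unique(discs$subject_id)) > 1L)
    stop("rasterize_subject expects discs from a single subject")
  ns <- params$n_slices; nr <- params$n_rows; nc <- params$n_cols
  if (any(discs$center_row + discs$height / 2 > nr) ||
      any(discs$center_col + discs$width / 2 > nc) ||
      any(discs$center_row - discs$height / 2 < 1) ||
      any(discs$center_col - discs$width / 2 < 1))
    stop("disc geometry does not fit inside the field of view")

  slice_plane <- matrix(0L, nr, nc)
  rr <- row(slice_plane); cc <- col(slice_plane)
  for (d in seq_len(nrow(discs))) {
    r0 <- discs$center_row[d]; c0 <- discs$center_col[d]
    a <- discs$width[d] / 2; b <- discs$height[d] / 2
    inside <- ((rr - r0) / b)^2 + ((cc - c0) / a)^2 <= 1
    if (any(slice_plane[inside] != 0L))
      stop("overlapping disc geometries")
    nuc <- inside & abs(cc - c0) <= discs$width[d] / 10
    slice_plane[inside] <- .annulus_code(d)
    slice_plane[nuc] <- .nucleus_code(d)
  }
  if (vertebral_bodies && nrow(discs) >= 1L) {
    ord <- order(discs$center_row)
    for (k in seq_len(nrow(discs) - 1L)) {
      d1 <- ord[k]; d2 <- ord[k + 1L]
      top <- ceiling(discs$center_row[d1] + discs$height[d1] / 2)
      bot <- floor(discs$center_row[d2] - discs$height[d2] / 2)
      if (bot >= top) {
        c0 <- mean(discs$center_col[c(d1, d2)])
        half_w <- 0.4 * min(discs$width[c(d1, d2)])
        vb <- rr >= top & rr <= bot & abs(cc - c0) <= half_w &
          slice_plane == 0L
        slice_plane[vb] <- 1L
      }
    }
  }
  labels <- array(0L, dim = c(ns, nr, nc))
  for (s in seq_len(ns)) labels[s, , ] <- slice_plane
  structure(list(labels = labels, disc_ids = discs$disc_id,
                 codes = data.frame(disc_id = discs$disc_id,
                                    annulus = .annulus_code(seq_len(nrow(discs))),
                                    nucleus = .nucleus_code(seq_len(nrow(discs))),
                                    stringsAsFactors = FALSE),
                 params = params),
            class = "label_volume")
}

#' Build polygon ROIs from disc ground-truth geometry
#'
#' One closed polygon per slice per disc, tracing the disc ellipse with
#' `n_vertices` vertices listed anterior-first (starting at the lowest
#' column index). Polygons are circumscribed about the ellipse (vertices
#' pushed out by `1/cos(pi/n)`) so every rasterized disc voxel center
#' falls inside the ROI.
#'
#' @param discs `disc_truth` rows.
#' @param params grid parameters (gives the slice range).
#' @param n_vertices vertices per polygon.
#' @return A list of `disc_roi` objects, one per disc.
#' @export
disc_rois <- function(discs, params = acquisition_params("multiecho"),
                      n_vertices = 48L) {
  lapply(seq_len(nrow(discs)), function(d) {
    r0 <- discs$center_row[d]; c0 <- discs$center_col[d]
    scale <- 1 / cos(pi / n_vertices)
    a <- scale * discs$width[d] / 2; b <- scale * discs$height[d] / 2
    th <- pi + (seq_len(n_vertices) - 1L) * 2 * pi / n_vertices
    poly <- cbind(row = r0 + b * sin(th), col = c0 + a * cos(th))
    slices <- seq_len(params$n_slices)
    disc_roi(discs$disc_id[d], slices,
             rep(list(poly), length(slices)))
  })
}
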