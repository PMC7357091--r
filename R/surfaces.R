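#' Interpolated disc surface from subregion means
#'
#' Builds the numeric grid behind the 3D disc plots: per slice, the five
#' subregion means are anchored at the subregion centers along the
#' anteroposterior axis (positions 0.1, 0.3, 0.5, 0.7, 0.9 of the disc
#' width) and interpolated piecewise-linearly across the width of the
#' disc; beyond the outer anchors the value is held constant, so the
#' surface is bounded by the anchor range (no overshoot).
#'
#' @param means matrix of subregion means, slices x subregions (a
#'   vector is treated as a single slice), NAs allowed per anchor.
#' @param grid_n grid resolution along the anteroposterior axis.
#' @return A `disc_surface_grid`: list with `values` (grid_n x slices
#'   matrix), `positions` (anteroposterior, in [0, 1]) and `anchors`.
#' @export
build_surface <- function(means, grid_n = 50L) {
  if (is.vector(means)) means <- matrix(means, nrow = 1L)
  if (all(is.na(means))) stop("all subregion means missing")
  k <- ncol(means)
  anchors <- (seq_len(k) - 0.5) / k
  pos <- seq(0, 1, length.out = grid_n)
  values <- vapply(seq_len(nrow(means)), function(s) {
    m <- means[s, ]
    ok <- !is.na(m)
    if (sum(ok) < 2L) {
      if (sum(ok) == 1L) return(rep(m[ok], grid_n))
      return(rep(NA_real_, grid_n))
    }
    stats::approx(anchors[ok], m[ok], xout = pos, rule = 2)$y
  }, numeric(grid_n))
  structure(list(values = values, positions = pos, anchors = anchors,
                 means = means),
            class = "disc_surface_grid")
}

#' @export
print.disc_surface_grid <- function(x, ...) {
  cat("<disc_surface_grid>", nrow(x$values), "positions x",
      ncol(x$values), "slices | range",
      sprintf("[%.3g, %.3g]\n", min(x$values, na.rm = TRUE),
              max(x$values, na.rm = TRUE)))
  invisible(x)
}

#' Export a disc surface grid as a data frame
#'
#' Long-format (position, slice, value) rows suitable for CSV export or
#' plotting with any graphics layer.
#'
#' @param surface a `disc_surface_grid`.
#' @return Data frame with columns `position`, `slice`, `value`.
#' @export
surface_as_data_frame <- function(surface) {
  data.frame(position = rep(surface$positions, ncol(surface$values)),
             slice = rep(seq_len(ncol(surface$values)),
                         each = nrow(surface$values)),
             value = as.vector(surface$values))
}
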