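# --- polygon primitives ------------------------------------------------
# Polygons are n x 2 matrices with columns (row, col), vertices in order,
# implicitly closed, 0- or 1-based as the caller chooses (everything here
# is affine-invariant). The on-disk ROI JSON is 0-based.

#' Polygon area by the shoelace formula
#' @param poly n x 2 vertex matrix (row, col).
#' @return Unsigned area in squared pixel units.
#' @export
polygon_area <- function(poly) abs(.polygon_signed_area(poly))

.polygon_signed_area <- function(poly) {
  x <- poly[, 2]; y <- poly[, 1]
  j <- c(seq_len(nrow(poly))[-1], 1L)
  0.5 * sum(x * y[j] - x[j] * y)
}

# centroid and normalized central second-moment (covariance) matrix of a
# simple polygon, by the standard shoelace-based closed forms
.polygon_moments <- function(poly) {
  x <- poly[, 2]; y <- poly[, 1]
  j <- c(seq_len(nrow(poly))[-1], 1L)
  w <- x * y[j] - x[j] * y
  A <- 0.5 * sum(w)
  if (abs(A) < 1e-12) stop("degenerate polygon (zero area)")
  cx <- sum((x + x[j]) * w) / (6 * A)
  cy <- sum((y + y[j]) * w) / (6 * A)
  sxx <- sum((x^2 + x * x[j] + x[j]^2) * w) / (12 * A) - cx^2
  syy <- sum((y^2 + y * y[j] + y[j]^2) * w) / (12 * A) - cy^2
  sxy <- sum((x * y[j] + 2 * x * y + 2 * x[j] * y[j] + x[j] * y) * w) /
    (24 * A) - cx * cy
  list(area = abs(A), centroid = c(row = cy, col = cx),
       cov = matrix(c(syy, sxy, sxy, sxx), 2, 2,
                    dimnames = list(c("row", "col"), c("row", "col"))))
}

# clip polygon to the half-plane {p : <p, n> <= d} (Sutherland-Hodgman)
.clip_halfplane <- function(poly, n, d, eps = 1e-9) {
  np <- nrow(poly)
  if (np == 0L) return(poly)
  proj <- poly %*% n
  out <- matrix(numeric(0), 0, 2)
  for (i in seq_len(np)) {
    j <- if (i == np) 1L else i + 1L
    pin <- proj[i] <= d + eps
    qin <- proj[j] <= d + eps
    if (pin) out <- rbind(out, poly[i, ])
    if (pin != qin) {
      t <- (d - proj[i]) / (proj[j] - proj[i])
      out <- rbind(out, poly[i, ] + t * (poly[j, ] - poly[i, ]))
    }
  }
  out
}

# even-odd point-in-polygon test, vectorized over points (pixel centers)
.points_in_polygon <- function(pr, pc, poly) {
  inside <- logical(length(pr))
  y <- poly[, 1]; x <- poly[, 2]
  np <- nrow(poly)
  j <- np
  for (i in seq_len(np)) {
    crosses <- ((y[i] > pr) != (y[j] > pr)) &
      (pc < (x[j] - x[i]) * (pr - y[i]) / (y[j] - y[i]) + x[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Rasterize a polygon to pixel centers
#'
#' A pixel belongs to the polygon when its center (integer coordinates)
#' lies inside under the even-odd rule.
#'
#' @param poly n x 2 vertex matrix (row, col).
#' @return Integer matrix of (row, col) pixel coordinates inside.
#' @export
rasterize_polygon <- function(poly) {
  rs <- ceiling(min(poly[, 1])):floor(max(poly[, 1]))
  cs <- ceiling(min(poly[, 2])):floor(max(poly[, 2]))
  if (!length(rs) || !length(cs))
    return(matrix(integer(0), 0, 2, dimnames = list(NULL, c("row", "col"))))
  g <- expand.grid(row = rs, col = cs)
  keep <- .points_in_polygon(g$row, g$col, poly)
  as.matrix(g[keep, , drop = FALSE])
}

# --- disc ROI containers ----------------------------------------------

#' Disc region of interest
#'
#' A per-slice set of closed polygons outlining one disc. Vertices are
#' listed anterior-first (the anterior aspect has the lower column
#' index).
#'
#' @param disc_id identifier string.
#' @param slices integer slice indices.
#' @param polygons list of n x 2 (row, col) vertex matrices, one per
#'   slice.
#' @return A `disc_roi` object.
#' @export
disc_roi <- function(disc_id, slices, polygons) {
  stopifnot(length(slices) == length(polygons))
  for (p in polygons) {
    if (!is.matrix(p) || ncol(p) != 2L || nrow(p) < 3L)
      stop("each polygon must be an n x 2 vertex matrix with n >= 3")
    if (polygon_area(p) <= 0) stop("polygon area must be > 0")
  }
  structure(list(disc_id = disc_id, slices = as.integer(slices),
                 polygons = polygons), class = "disc_roi")
}

#' Split a disc polygon into five anteroposterior subregions
#'
#' The principal (longest) axis of the polygon defines the
#' anteroposterior direction; its extent is divided into five
#' equal-length bins and the polygon is clipped to each bin's
#' perpendicular strip, giving subregions 1 (anterior) to 5 (posterior).
#' The axis is oriented so that subregion 1 contains the first-listed
#' (anterior) vertex.
#'
#' @param poly n x 2 (row, col) vertex matrix of a simple polygon.
#' @return A `subregion_set`: list of five polygons plus the axis unit
#'   vector, bin edges and parent polygon.
#' @export
split_subregions <- function(poly) {
  m <- .polygon_moments(poly)
  ev <- eigen(m$cov, symmetric = TRUE)
  u <- ev$vectors[, 1]          # largest-variance direction
  t <- as.vector(poly %*% u)
  # orient anterior-first: first vertex must project into the low end
  if (t[1] > mean(range(t))) { u <- -u; t <- -t }
  edges <- seq(min(t), max(t), length.out = 6L)
  subs <- lapply(seq_len(5L), function(j) {
    p <- .clip_halfplane(poly, u, edges[j + 1L])
    p <- .clip_halfplane(p, -u, -edges[j])
    p
  })
  structure(list(polygons = subs, axis = u, edges = edges, parent = poly),
            class = "subregion_set")
}

#' Select the central sagittal slices of an ROI
#'
#' Returns the `k` slice indices nearest the median of the ROI's slice
#' range (ties broken towards the lower index), emulating the use of the
#' central three sagittal slices to capture the most hydrated region of
#' the nucleus. If the ROI spans fewer than `k` slices, all available
#' slices are returned with a warning.
#'
#' @param roi a [disc_roi()] (or integer vector of slice indices).
#' @param k number of slices (default 3).
#' @return Sorted integer slice indices.
#' @export
select_central_slices <- function(roi, k = 3L) {
  slices <- if (inherits(roi, "disc_roi")) roi$slices else as.integer(roi)
  if (length(slices) < k) {
    warning("ROI spans fewer than ", k, " slices; using all ",
            length(slices))
    return(sort(slices))
  }
  med <- mean(range(slices))
  ord <- order(abs(slices - med), slices)
  sort(slices[ord[seq_len(k)]])
}

# coerce supported map objects to a plain 3D array with NA = invalid
.as_map_array <- function(map) {
  if (inherits(map, "t2_map")) {
    out <- map$t2; out[!map$valid] <- NA_real_; return(out)
  }
  if (inherits(map, "water_fat_result")) return(water_percent_map(map))
  if (is.array(map) && length(dim(map)) == 3L) return(map)
  stop("unsupported map type")
}

#' Extract whole-disc and subregion statistics from a quantitative map
#'
#' Pools voxels of the selected slices: per subregion, the mean/SD/count
#' of valid map voxels whose pixel centers fall in the subregion
#' polygon; the whole-disc row pools all ROI voxels of those slices.
#' Invalid (NA) voxels never enter the means; a subregion left empty
#' after masking yields an NA mean with zero count rather than zero.
#'
#' @param map 3D array (slice, row, col), `t2_map`, or
#'   `water_fat_result`.
#' @param roi a [disc_roi()] on the same grid (1-based polygon
#'   coordinates).
#' @param slices slice indices to pool; default
#'   `select_central_slices(roi)`.
#' @param subregions optional precomputed [split_subregions()] per slice.
#' @return A `region_stats` data frame with rows `whole`, `s1`..`s5` and
#'   columns `mean`, `sd`, `n`.
#' @export
extract_metrics <- function(map, roi, slices = NULL, subregions = NULL) {
  arr <- .as_map_array(map)
  if (is.null(slices)) slices <- select_central_slices(roi)
  vals <- vector("list", 6L)  # [[1]] whole, [[j+1]] subregion j
  for (s in slices) {
    i <- match(s, roi$slices)
    if (is.na(i)) stop("slice ", s, " not present in ROI")
    poly <- roi$polygons[[i]]
    sr <- if (is.null(subregions)) split_subregions(poly) else subregions[[i]]
    for (j in seq_len(5L)) {
      px <- rasterize_polygon(sr$polygons[[j]])
      if (nrow(px)) {
        v <- arr[cbind(s, px[, 1], px[, 2])]
        vals[[j + 1L]] <- c(vals[[j + 1L]], v[!is.na(v)])
      }
    }
    px <- rasterize_polygon(poly)
    if (nrow(px)) {
      v <- arr[cbind(s, px[, 1], px[, 2])]
      vals[[1L]] <- c(vals[[1L]], v[!is.na(v)])
    }
  }
  stat <- function(v) {
    if (!length(v)) return(c(NA_real_, NA_real_, 0))
    c(mean(v), stats::sd(v), length(v))
  }
  tab <- t(vapply(vals, stat, numeric(3)))
  out <- data.frame(region = c("whole", paste0("s", 1:5)),
                    mean = tab[, 1], sd = tab[, 2], n = as.integer(tab[, 3]),
                    stringsAsFactors = FALSE)
  attr(out, "slices") <- slices
  attr(out, "disc_id") <- roi$disc_id
  class(out) <- c("region_stats", "data.frame")
  out
}

#' Nucleus/annulus ratio of a region-statistics table
#'
#' Ratio of the nucleus subregion mean (subregion 3 by default) to the
#' voxel-pooled mean of the anterior and posterior subregions (1 and 5),
#' the semi-quantitative normalization used for T2-weighted signal
#' intensity. NA when the nucleus or the pooled annulus is missing or
#' the denominator is zero.
#'
#' @param stats a `region_stats` from [extract_metrics()].
#' @param nucleus_region subregion index treated as nucleus (default 3).
#' @param annulus_regions subregion indices pooled as annulus (default
#'   `c(1, 5)`).
#' @return Numeric ratio, or NA.
#' @export
nucleus_annulus_ratio <- function(stats, nucleus_region = 3L,
                                  annulus_regions = c(1L, 5L)) {
  nuc <- stats[stats$region == paste0("s", nucleus_region), ]
  ann <- stats[stats$region %in% paste0("s", annulus_regions), ]
  if (nrow(nuc) != 1L || any(ann$n == 0L) || nuc$n == 0L) return(NA_real_)
  denom <- sum(ann$mean * ann$n) / sum(ann$n)  # voxel-pooled mean
  if (!is.finite(denom) || denom == 0) return(NA_real_)
  nuc$mean / denom
}
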