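# --- plain-text interchange formats -----------------------------------
# ROI polygons travel as JSON ({disc_id, slices: [{index, vertices:
# [[row, col], ...]}]}, 0-based indices); configs as JSON; tables as
# CSV. Volumes stay in memory (see the methods vignette for why no
# binary volume format is written by default).

#' Write / read disc ROIs as JSON
#'
#' Vertices are stored 0-based (row, col); R-side polygons are 1-based.
#'
#' @param rois list of [disc_roi()] objects (or a single one).
#' @param path file path.
#' @return `read_roi_json` returns a list of `disc_roi` objects.
#' @export
write_roi_json <- function(rois, path) {
  if (inherits(rois, "disc_roi")) rois <- list(rois)
  payload <- lapply(rois, function(r) {
    list(disc_id = r$disc_id,
         slices = lapply(seq_along(r$slices), function(i) {
           list(index = r$slices[i] - 1L,
                vertices = unname(apply(r$polygons[[i]] - 1, 1,
                                        function(v) c(v[1], v[2]),
                                        simplify = FALSE)))
         }))
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_roi_json
#' @export
read_roi_json <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(payload, function(r) {
    slices <- vapply(r$slices, function(s) s$index, numeric(1)) + 1L
    polys <- lapply(r$slices, function(s) {
      m <- do.call(rbind, lapply(s$vertices, function(v)
        c(row = v[[1]], col = v[[2]])))
      m + 1
    })
    disc_roi(r$disc_id, slices, polys)
  })
}

#' Write a data frame as CSV with a provenance sidecar
#'
#' The CSV itself is deterministic for a fixed seed; run provenance
#' (seed, package version, configuration echo) goes to `<path>.json`.
#'
#' @param df data frame.
#' @param path CSV path.
#' @param provenance named list, or NULL to skip the sidecar.
#' @export
write_table_csv <- function(df, path, provenance = NULL) {
  utils::write.csv(df, path, row.names = FALSE)
  if (!is.null(provenance))
    jsonlite::write_json(provenance, paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
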