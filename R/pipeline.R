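# --- orchestration: simulate -> reconstruct -> measure -> report ------

#' Configure a full pipeline run
#'
#' @param cohort a [cohort_config()].
#' @param techniques subset of `c("t2map", "t2w", "dixon")` to simulate
#'   and measure; measures of skipped techniques are explicit NAs.
#' @param params named list of [acquisition_params()] per technique
#'   (defaults built from the standard protocol).
#' @param central_k central-slice count for metric extraction; `NULL`
#'   pools all ROI slices.
#' @param fieldmap_amplitude_hz peak off-resonance of the simulated
#'   Dixon field map.
#' @param dixon_options list passed to [separate_water_fat()].
#' @param referent_group referent for the group table.
#' @param out_dir output directory for CSV/JSON artifacts, or NULL.
#' @param seed master seed; cohort and per-subject simulation seeds are
#'   derived from it.
#' @return An object of class `run_config`.
#' @export
run_config <- function(cohort = cohort_config(),
                       techniques = c("t2map", "t2w", "dixon"),
                       params = list(multiecho = acquisition_params("multiecho"),
                                     t2w = acquisition_params("t2w"),
                                     dixon = acquisition_params("dixon")),
                       central_k = 3L,
                       fieldmap_amplitude_hz = 40,
                       dixon_options = list(),
                       referent_group = "sedentary",
                       out_dir = NULL,
                       seed = 1L) {
  stopifnot(all(techniques %in% c("t2map", "t2w", "dixon")))
  structure(list(cohort = cohort, techniques = techniques, params = params,
                 central_k = central_k,
                 fieldmap_amplitude_hz = fieldmap_amplitude_hz,
                 dixon_options = dixon_options,
                 referent_group = referent_group,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "run_config")
}

#' Single-disc phantom builder
#'
#' Convenience constructor for parameter-recovery experiments: one disc
#' on a small grid with explicit nucleus/annulus ground truth. Passing
#' scalar `t2`, `water`, `pd` makes the disc spatially uniform
#' (nucleus = annulus).
#'
#' @param t2,water,pd uniform ground truth (ms, %, signal units).
#' @param t2_nucleus,t2_annulus,water_nucleus,water_annulus,pd_nucleus,pd_annulus
#'   compartment-specific overrides.
#' @param params an [acquisition_params()]; default multiecho grid
#'   shrunk to 40 rows.
#' @param vertebral_bodies passed to [rasterize_subject()].
#' @return List with `discs` (1-row `disc_truth`), `labels`, `roi` and
#'   `params`.
#' @export
single_disc_phantom <- function(t2 = 100, water = 85, pd = 800,
                                t2_nucleus = t2, t2_annulus = t2,
                                water_nucleus = water, water_annulus = water,
                                pd_nucleus = pd, pd_annulus = pd,
                                params = acquisition_params("multiecho",
                                                            n_rows = 40L),
                                vertebral_bodies = FALSE) {
  discs <- data.frame(
    subject_id = "S001", level = "L4/L5", level_index = 1L,
    group = "sedentary", pfirrmann_grade = 1L,
    t2_nucleus = t2_nucleus, t2_annulus = t2_annulus,
    pd_nucleus = pd_nucleus, pd_annulus = pd_annulus,
    water_nucleus = water_nucleus, water_annulus = water_annulus,
    disc_id = "S001_D1",
    center_row = round(params$n_rows / 2), center_col = round(params$n_cols / 2),
    width = 30, height = 9, stringsAsFactors = FALSE)
  class(discs) <- c("disc_truth", "data.frame")
  labels <- rasterize_subject(discs, params,
                              vertebral_bodies = vertebral_bodies)
  list(discs = discs, labels = labels,
       roi = disc_rois(discs, params)[[1]], params = params)
}

# Measure one subject: simulate the requested techniques on its label
# volume and extract the nine per-disc measures. Returns the disc rows
# and the long per-subregion means (for surface building).
.measure_subject <- function(discs, labels, rois, config, seed) {
  n <- nrow(discs)
  rows <- discs[, c("subject_id", "level", "group", "pfirrmann_grade",
                    "disc_id")]
  for (m in .measure_cols) rows[[m]] <- NA_real_
  regions <- list()
  slices <- lapply(rois, function(r) {
    if (is.null(config$central_k)) r$slices
    else select_central_slices(r, config$central_k)
  })
  sig <- config$cohort$noise_sigma

  grab <- function(map, prefix) {
    for (d in seq_len(n)) {
      st <- extract_metrics(map, rois[[d]], slices = slices[[d]])
      rows[[paste0(prefix, "_whole")]][d] <<- st$mean[st$region == "whole"]
      rows[[paste0(prefix, "_nucleus")]][d] <<- st$mean[st$region == "s3"]
      rows[[paste0(prefix, "_ratio")]][d] <<- nucleus_annulus_ratio(st)
      st$disc_id <- rois[[d]]$disc_id
      st$technique <- prefix
      regions[[length(regions) + 1L]] <<- as.data.frame(st)
    }
  }

  if ("t2map" %in% config$techniques) {
    stack <- simulate_multiecho(labels, discs, config$params$multiecho,
                                noise_sigma = sig$multiecho, seed = seed)
    grab(fit_t2_map(stack), "t2")
  }
  if ("t2w" %in% config$techniques) {
    img <- simulate_t2w(labels, discs, config$params$t2w,
                        noise_sigma = sig$t2w, seed = seed + 1L)
    grab(array(img, dim = dim(img)), "t2w")
  }
  if ("dixon" %in% config$techniques) {
    fm <- field_map(dim(labels$labels), config$fieldmap_amplitude_hz,
                    seed = seed + 2L)
    dx <- simulate_dixon(labels, discs, fm, config$params$dixon,
                         noise_sigma = sig$dixon, seed = seed + 3L)
    wf <- do.call(separate_water_fat, c(list(dx), config$dixon_options))
    grab(wf, "dixon")
  }
  list(rows = rows, regions = do.call(rbind, regions))
}

#' Run the full simulate / reconstruct / measure / report pipeline
#'
#' Builds the synthetic cohort, simulates the configured acquisitions
#' subject by subject, reconstructs T2 and water-percentage maps,
#' extracts the nine per-disc measures through the five-subregion ROI
#' model, and assembles the statistical report tables plus per-grade
#' interpolated disc surfaces. Fixed seed implies byte-identical CSV
#' outputs.
#'
#' @param config a [run_config()].
#' @return List with `table` (the per-disc [disc_table()]), `summaries`
#'   (see [summarize_tables()]), `surfaces` (per technique, per grade),
#'   `regions` (long per-disc subregion means), `truth` (the generating
#'   cohort) and `provenance`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  cohort_cfg <- config$cohort
  cohort_cfg$seed <- config$seed
  truth <- build_cohort(cohort_cfg)

  subjects <- unique(truth$subject_id)
  # geometry is shared across subjects: rasterize and trace ROIs once
  first <- truth[truth$subject_id == subjects[1], ]
  labels0 <- rasterize_subject(first, config$params$multiecho)
  rois0 <- disc_rois(first, config$params$multiecho)

  out_rows <- vector("list", length(subjects))
  out_regions <- vector("list", length(subjects))
  for (i in seq_along(subjects)) {
    discs <- truth[truth$subject_id == subjects[i], ]
    labels <- labels0
    labels$disc_ids <- discs$disc_id
    labels$codes$disc_id <- discs$disc_id
    rois <- rois0
    for (d in seq_along(rois)) rois[[d]]$disc_id <- discs$disc_id[d]
    res <- .measure_subject(discs, labels, rois, config,
                            seed = config$seed + 7L + i * 11L)
    out_rows[[i]] <- res$rows
    out_regions[[i]] <- res$regions
  }
  table <- disc_table(merge(
    do.call(rbind, out_rows),
    truth[, c("disc_id", "level_index")], by = "disc_id"))
  table <- table[order(table$subject_id, table$level_index), ]
  rownames(table) <- NULL
  regions <- do.call(rbind, out_regions)

  summaries <- summarize_tables(table, config$referent_group)

  # per-grade mean subregion profile -> interpolated surface
  surfaces <- list()
  grade_of <- table$pfirrmann_grade[match(regions$disc_id, table$disc_id)]
  for (tech in unique(regions$technique)) {
    surfaces[[tech]] <- list()
    for (g in sort(unique(grade_of))) {
      sel <- regions$technique == tech & grade_of == g &
        regions$region != "whole" & !is.na(regions$mean)
      if (!any(sel)) next
      m <- stats::aggregate(mean ~ region, data = regions[sel, ], FUN = mean)
      m <- m$mean[match(paste0("s", 1:5), m$region)]
      surfaces[[tech]][[paste0("grade", g)]] <- build_surface(m)
    }
  }

  provenance <- list(seed = config$seed,
                     package_version = as.character(utils::packageVersion("discmri")),
                     techniques = config$techniques,
                     subjects = length(subjects), discs = nrow(table),
                     parameter_model = cohort_cfg$parameter_model,
                     noise_sigma = cohort_cfg$noise_sigma)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    od <- config$out_dir
    write_table_csv(as.data.frame(table), file.path(od, "disc_table.csv"),
                    provenance)
    write_table_csv(summaries$group$cells, file.path(od, "table_group.csv"))
    write_table_csv(summaries$group$wide, file.path(od, "table_group_wide.csv"))
    write_table_csv(summaries$grade$cells, file.path(od, "table_grade.csv"))
    write_table_csv(summaries$grade$wide, file.path(od, "table_grade_wide.csv"))
    utils::write.csv(summaries$correlations$r,
                     file.path(od, "correlations_r.csv"))
    utils::write.csv(summaries$correlations$p,
                     file.path(od, "correlations_p.csv"))
    for (tech in names(surfaces)) for (g in names(surfaces[[tech]]))
      write_table_csv(surface_as_data_frame(surfaces[[tech]][[g]]),
                      file.path(od, sprintf("surface_%s_%s.csv", tech, g)))
    jsonlite::write_json(provenance, file.path(od, "provenance.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  list(table = table, summaries = summaries, surfaces = surfaces,
       regions = regions, truth = truth, provenance = provenance)
}
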