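# shared small fixtures, built in code

# one subject, degenerate draws: every dispersion zero, all grade 1
degenerate_config <- function(seed = 1L) {
  gt <- grade_reference_table()
  gt[grep("_disp$", names(gt))] <- 0
  grp <- group_reference_table()
  grp[grep("_disp$", names(grp))] <- 0
  cohort_config(subjects_per_group = c(sedentary = 1L),
                levels = "L4/L5",
                grade_probabilities = c(1, 0, 0, 0),
                grade_table = gt, group_table = grp,
                seed = seed)
}

# tiny cohort for pipeline smoke runs: 2 subjects x 2 levels, grade-1
# only (the wide printed grade-2 dispersions can draw low-signal discs
# whose measures are legitimately flagged missing; the smoke test wants
# well-conditioned ones)
tiny_run_config <- function(seed = 1L, techniques = c("t2map", "t2w", "dixon"),
                            noise = list(multiecho = 8, t2w = 8, dixon = 8)) {
  cc <- cohort_config(subjects_per_group = c(sedentary = 1L, runner = 1L),
                      levels = c("L3/L4", "L4/L5"),
                      grade_probabilities = c(1, 0, 0, 0),
                      noise_sigma = noise, seed = seed)
  pars <- list(multiecho = acquisition_params("multiecho", n_rows = 48L),
               t2w = acquisition_params("t2w", n_rows = 48L),
               dixon = acquisition_params("dixon", n_rows = 48L))
  run_config(cohort = cc, techniques = techniques, params = pars, seed = seed)
}

# ellipse polygon (row, col) with n vertices, anterior-first; the
# default center is off the integer grid so no subregion edge passes
# exactly through a pixel center (rasterization conventions only differ
# on such degenerate ties)
ellipse_polygon <- function(center = c(20.3, 24.4), a = 15, b = 4.5, n = 64L) {
  th <- pi + (seq_len(n) - 1L) * 2 * pi / n
  cbind(row = center[1] + b * sin(th), col = center[2] + a * cos(th))
}
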