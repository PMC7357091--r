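# --- per-disc measurement table and the cohort statistical battery ----

.measure_cols <- c("t2_whole", "t2_nucleus", "t2_ratio",
                   "t2w_whole", "t2w_nucleus", "t2w_ratio",
                   "dixon_whole", "dixon_nucleus", "dixon_ratio")

#' Validate a per-disc measurement table
#'
#' One row per disc with identifiers (`subject_id`, `level`, `group`,
#' `pfirrmann_grade`) and the nine measures:
#' \{T2-mapping, T2w-SI, Dixon\} x \{whole IVD, nucleus,
#' nucleus/annulus ratio\}. Missing measurements must be explicit `NA`s.
#'
#' @param df data frame to validate.
#' @return The data frame with class `disc_table` prepended.
#' @export
disc_table <- function(df) {
  need <- c("subject_id", "level", "group", "pfirrmann_grade", .measure_cols)
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (!all(df$pfirrmann_grade %in% 1:4)) stop("grades must be in 1..4")
  if (!inherits(df, "disc_table")) class(df) <- c("disc_table", class(df))
  df
}

#' Significance tier for a p-value
#'
#' `ns` for p >= 0.05, `*` for p < 0.05, dagger for p < 0.01, double
#' dagger for p < 0.001.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return Character vector of tiers.
#' @export
significance_tier <- function(p) {
  out <- rep(NA_character_, length(p))
  ok <- !is.na(p)
  out[ok] <- ifelse(p[ok] < 0.001, "\u2021",
                    ifelse(p[ok] < 0.01, "\u2020",
                           ifelse(p[ok] < 0.05, "*", "ns")))
  out
}

# optional subject-level aggregation: mean per subject of each measure
.aggregate_observations <- function(table, observations) {
  if (observations == "disc") return(table)
  agg <- stats::aggregate(table[.measure_cols],
                          by = list(subject_id = table$subject_id,
                                    group = table$group),
                          FUN = mean, na.rm = TRUE)
  agg$pfirrmann_grade <- NA_integer_
  agg
}

.two_sample_row <- function(x, y, measure, contrast, var_equal) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  base <- data.frame(measure = measure, contrast = contrast,
                     n_ref = length(x), mean_ref = mean(x), sd_ref = stats::sd(x),
                     n = length(y), mean = mean(y), sd = stats::sd(y),
                     t = NA_real_, df = NA_real_, p = NA_real_,
                     tier = NA_character_, stringsAsFactors = FALSE)
  if (length(x) < 2L || length(y) < 2L) {
    message("comparison '", contrast, "' for ", measure,
            ": fewer than 2 observations in a cell; skipped")
    return(base)
  }
  tt <- tryCatch(stats::t.test(y, x, var.equal = var_equal),
                 error = function(e) NULL)
  if (is.null(tt)) {    # e.g. both cells constant
    message("comparison '", contrast, "' for ", measure,
            ": degenerate (constant) data; skipped")
    return(base)
  }
  base$t <- unname(tt$statistic)
  base$df <- unname(tt$parameter)
  base$p <- tt$p.value
  base$tier <- significance_tier(tt$p.value)
  base
}

#' Compare athletic groups to the sedentary referent
#'
#' Unpaired two-sided t-tests (Welch by default) of each non-referent
#' activity group against the referent, per measure, with disc-level
#' observations (each disc is one observation, matching the cell sizes
#' of the emulated study) or subject-mean aggregation.
#'
#' @param table a [disc_table()].
#' @param measure one of the nine measure columns.
#' @param referent_group referent group label (default `"sedentary"`).
#' @param var_equal FALSE (Welch, default) or TRUE (pooled variance).
#' @param observations `"disc"` (default) or `"subject"`.
#' @return A `comparison_result` data frame, one row per contrast, with
#'   cell means/SDs/ns, t, df, p and significance tier.
#' @export
compare_to_referent <- function(table, measure,
                                referent_group = "sedentary",
                                var_equal = FALSE,
                                observations = c("disc", "subject")) {
  observations <- match.arg(observations)
  stopifnot(measure %in% .measure_cols)
  tab <- .aggregate_observations(table, observations)
  ref <- tab[[measure]][tab$group == referent_group]
  others <- setdiff(unique(tab$group), referent_group)
  out <- do.call(rbind, lapply(others, function(g) {
    .two_sample_row(ref, tab[[measure]][tab$group == g], measure,
                    paste0(g, " vs ", referent_group), var_equal)
  }))
  if (is.null(out)) out <- .two_sample_row(1, 1, measure, "", FALSE)[0, ]
  class(out) <- c("comparison_result", class(out))
  out
}

#' Compare Pfirrmann grades 2-4 to grade 1
#'
#' Same contract as [compare_to_referent()] with Pfirrmann grade 1 discs
#' as the referent cell.
#'
#' @inheritParams compare_to_referent
#' @return A `comparison_result` data frame, one row per grade 2-4.
#' @export
compare_to_grade1 <- function(table, measure, var_equal = FALSE) {
  stopifnot(measure %in% .measure_cols)
  ref <- table[[measure]][table$pfirrmann_grade == 1L]
  grades <- sort(setdiff(unique(table$pfirrmann_grade), 1L))
  out <- do.call(rbind, lapply(grades, function(g) {
    .two_sample_row(ref, table[[measure]][table$pfirrmann_grade == g],
                    measure, paste0("grade ", g, " vs grade 1"), var_equal)
  }))
  if (is.null(out)) out <- .two_sample_row(1, 1, measure, "", FALSE)[0, ]
  class(out) <- c("comparison_result", class(out))
  out
}

#' Pairwise Pearson correlations of the nine measures
#'
#' Pearson's product-moment correlation with two-sided p-values on
#' pairwise-complete observations. Zero-variance columns yield NA with a
#' message.
#'
#' @param table a [disc_table()].
#' @param measures measure columns (default all nine).
#' @return List of matrices `r`, `p`, `n`, `tier`.
#' @export
correlation_matrix <- function(table, measures = .measure_cols) {
  k <- length(measures)
  r <- p <- matrix(NA_real_, k, k, dimnames = list(measures, measures))
  n <- matrix(0L, k, k, dimnames = list(measures, measures))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    x <- table[[measures[i]]]; y <- table[[measures[j]]]
    ok <- !is.na(x) & !is.na(y)
    n[i, j] <- sum(ok)
    if (n[i, j] < 3L) next
    if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
      message("zero-variance column in correlation: ",
              measures[i], " / ", measures[j])
      next
    }
    if (i == j) { r[i, j] <- 1; p[i, j] <- 0; next }
    ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
    r[i, j] <- unname(ct$estimate)
    p[i, j] <- ct$p.value
  }
  list(r = r, p = p, n = n,
       tier = matrix(significance_tier(p), k, k,
                     dimnames = dimnames(r)))
}

# mean (SD) cell summaries by an arbitrary grouping column
.summarize_by <- function(table, by, referent_value, compare_fun) {
  cells <- do.call(rbind, lapply(.measure_cols, function(m) {
    ag <- stats::aggregate(table[[m]], by = list(cell = table[[by]]),
                           FUN = function(v) c(mean = mean(v, na.rm = TRUE),
                                               sd = stats::sd(v, na.rm = TRUE),
                                               n = sum(!is.na(v))))
    data.frame(measure = m, cell = ag$cell,
               mean = ag$x[, "mean"], sd = ag$x[, "sd"],
               n = as.integer(ag$x[, "n"]), stringsAsFactors = FALSE)
  }))
  cells$p <- NA_real_
  for (m in .measure_cols) {
    cmp <- compare_fun(table, m)
    for (i in seq_len(nrow(cmp))) {
      cell <- sub(" vs .*$", "", cmp$contrast[i])
      cell <- sub("^grade ", "", cell)
      sel <- cells$measure == m & as.character(cells$cell) == cell
      cells$p[sel] <- cmp$p[i]
    }
  }
  cells$tier <- significance_tier(cells$p)
  cells$tier[as.character(cells$cell) == as.character(referent_value)] <- ""
  # wide formatted analogue: one row per measure, one column per cell
  lv <- unique(as.character(cells$cell))
  wide <- data.frame(measure = .measure_cols, stringsAsFactors = FALSE)
  for (cv in lv) {
    sel <- cells[as.character(cells$cell) == cv, ]
    sel <- sel[match(.measure_cols, sel$measure), ]
    mark <- ifelse(is.na(sel$tier) | sel$tier %in% c("", "ns"), "",
                   paste0(" ", sel$tier))
    wide[[cv]] <- sprintf("%.1f (%.1f)%s", sel$mean, sel$sd, mark)
  }
  list(cells = cells, wide = wide)
}

#' Summary-table analogues for the cohort
#'
#' Builds the three report tables of the statistical battery:
#' \describe{
#'   \item{group}{mean (SD) of each of the nine measures per activity
#'     group, with significance marks from unpaired t-tests against the
#'     sedentary referent;}
#'   \item{grade}{the same per Pfirrmann grade, tested against grade 1;}
#'   \item{correlations}{the 9 x 9 Pearson correlation grid with
#'     significance tiers.}
#' }
#'
#' @param table a [disc_table()].
#' @param referent_group referent activity group.
#' @return List with elements `group`, `grade` (each a list `cells`,
#'   `wide`) and `correlations`.
#' @export
summarize_tables <- function(table, referent_group = "sedentary") {
  list(
    group = .summarize_by(table, "group", referent_group,
                          function(t, m)
                            compare_to_referent(t, m, referent_group)),
    grade = .summarize_by(table, "pfirrmann_grade", 1L, compare_to_grade1),
    correlations = correlation_matrix(table)
  )
}
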