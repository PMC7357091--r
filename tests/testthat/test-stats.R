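# group/grade contrasts, correlations, summary tables

# a disc table straight from ground-truth draws (no imaging): cheap
# substrate for the statistical battery
truth_table <- function(config = cohort_config(seed = 5)) {
  co <- build_cohort(config)
  disc_table(data.frame(
    subject_id = co$subject_id, level = co$level, group = co$group,
    pfirrmann_grade = co$pfirrmann_grade,
    t2_whole = (co$t2_nucleus + co$t2_annulus) / 2,
    t2_nucleus = co$t2_nucleus,
    t2_ratio = co$t2_nucleus / co$t2_annulus,
    t2w_whole = (co$pd_nucleus * exp(-70 / co$t2_nucleus) +
                   co$pd_annulus * exp(-70 / co$t2_annulus)) / 2,
    t2w_nucleus = co$pd_nucleus * exp(-70 / co$t2_nucleus),
    t2w_ratio = exp(-70 / co$t2_nucleus) * co$pd_nucleus /
      (co$pd_annulus * exp(-70 / co$t2_annulus)),
    dixon_whole = (co$water_nucleus + co$water_annulus) / 2,
    dixon_nucleus = co$water_nucleus,
    dixon_ratio = co$water_nucleus / pmax(co$water_annulus, 1e-9)
  ))
}

test_that("disc_table validates its contract", {
  expect_error(disc_table(data.frame(subject_id = "a")), "missing columns")
  tt <- truth_table()
  bad <- tt; bad$pfirrmann_grade[1] <- 7L
  expect_error(disc_table(as.data.frame(bad)), "grades")
})

test_that("identical samples give the null identity", {
  df <- data.frame(subject_id = rep(c("a", "b"), each = 3),
                   level = "L", group = rep(c("sedentary", "runner"), each = 3),
                   pfirrmann_grade = 1L)
  for (m in discmri:::.measure_cols) df[[m]] <- rep(c(1, 2, 3), 2)
  cmp <- compare_to_referent(disc_table(df), "t2_whole")
  expect_equal(cmp$t, 0)
  expect_equal(cmp$p, 1)
  expect_equal(cmp$tier, "ns")
})

test_that("t statistics match the closed-form oracle", {
  x <- c(1, 2, 3); y <- c(4, 5, 6)
  df <- data.frame(subject_id = paste0("s", 1:6), level = "L",
                   group = rep(c("sedentary", "jogger"), each = 3),
                   pfirrmann_grade = rep(c(1L, 3L), each = 3))
  for (m in discmri:::.measure_cols) df[[m]] <- c(x, y)
  tab <- disc_table(df)
  for (ve in c(FALSE, TRUE)) {
    cmp <- compare_to_referent(tab, "t2_nucleus", var_equal = ve)
    want <- oracle_t_test(y, x, var_equal = ve)
    expect_equal(cmp$t, want$t, tolerance = 1e-12)
    expect_equal(cmp$p, want$p, tolerance = 1e-12)
    g <- compare_to_grade1(tab, "t2_nucleus", var_equal = ve)
    expect_equal(g$t, want$t, tolerance = 1e-12)
    expect_equal(g$p, want$p, tolerance = 1e-12)
  }
})

test_that("grade contrasts recover the configured monotone decline", {
  # nucleus T2 is the directly grade-configured measure; the emergent
  # whole-disc value mixes in heavy-tailed ratio draws (printed grade-2
  # dispersions are very wide) and is not guaranteed monotone
  tt <- truth_table(cohort_config(seed = 9))
  g <- compare_to_grade1(tt, "t2_nucleus")
  means <- c(mean(tt$t2_nucleus[tt$pfirrmann_grade == 1]), g$mean)
  expect_true(all(diff(means) < 0))   # grades 1 -> 4 decreasing
  expect_true(all(g$p < 0.05))
})

test_that("Pearson correlations match the covariance-formula oracle", {
  tt <- truth_table()
  cm <- correlation_matrix(tt)
  expect_equal(unname(diag(cm$r)), rep(1, 9))
  set.seed(8)
  x <- rnorm(10); y <- rnorm(10)
  df <- data.frame(subject_id = paste0("s", 1:10), level = "L",
                   group = "sedentary", pfirrmann_grade = 1L)
  for (m in discmri:::.measure_cols) df[[m]] <- x
  df$t2w_whole <- y
  df$t2_nucleus <- -x          # perfect anticorrelation
  cm2 <- correlation_matrix(disc_table(df))
  expect_equal(cm2$r["t2_whole", "t2_nucleus"], -1, tolerance = 1e-12)
  want <- oracle_pearson(x, y)
  expect_equal(cm2$r["t2_whole", "t2w_whole"], want$r, tolerance = 1e-12)
  expect_equal(cm2$p["t2_whole", "t2w_whole"], want$p, tolerance = 1e-12)
  # affine invariance (positive scale)
  df2 <- df; df2$t2w_whole <- 3 * y + 11; df2$t2_whole <- 0.5 * x - 2
  cm3 <- correlation_matrix(disc_table(df2))
  expect_equal(cm3$r["t2_whole", "t2w_whole"], want$r, tolerance = 1e-12)
  # zero-variance guard
  df3 <- df; df3$dixon_ratio <- 1
  expect_message(cm4 <- correlation_matrix(disc_table(df3)), "zero-variance")
  expect_true(is.na(cm4$r["t2_whole", "dixon_ratio"]))
})

test_that("significance tiers are a deterministic function of p", {
  expect_equal(significance_tier(c(0.5, 0.049, 0.009, 0.0009, 0.05, 0.01,
                                   0.001, NA)),
               c("ns", "*", "\u2020", "\u2021", "ns", "*", "\u2020", NA))
})

test_that("summary tables match a brute-force group-by oracle", {
  tt <- truth_table(cohort_config(seed = 3))
  s <- suppressMessages(summarize_tables(tt))
  cells <- s$group$cells
  for (g in unique(tt$group)) {
    sel <- cells[cells$measure == "t2_whole" & cells$cell == g, ]
    expect_equal(sel$mean, mean(tt$t2_whole[tt$group == g]),
                 tolerance = 1e-12)
    expect_equal(sel$n, sum(tt$group == g))
  }
  # grade cells likewise
  gcells <- s$grade$cells
  for (g in 1:4) {
    sel <- gcells[gcells$measure == "dixon_nucleus" & gcells$cell == g, ]
    expect_equal(sel$mean, mean(tt$dixon_nucleus[tt$pfirrmann_grade == g]),
                 tolerance = 1e-12)
  }
  # single-group degenerate table: one data column in the wide analogue
  one <- tt[tt$group == "sedentary", ]
  s1 <- suppressMessages(summarize_tables(one))
  expect_equal(ncol(s1$group$wide), 2L)  # measure + the single cell
})

test_that("subject aggregation changes n but not cell means", {
  tt <- truth_table(cohort_config(seed = 4))
  d <- compare_to_referent(tt, "t2_whole", observations = "disc")
  s <- compare_to_referent(tt, "t2_whole", observations = "subject")
  expect_equal(s$mean, d$mean, tolerance = 1e-12)   # balanced design
  expect_true(all(s$n < d$n))
})

test_that("null calibration: type-I rate inside the binomial envelope", {
  # quick version (200 replicates); the full 1000-replicate check runs
  # in the acceptance suite
  set.seed(17)
  reps <- 200L
  p <- vapply(seq_len(reps), function(i) {
    stats::t.test(rnorm(24, 100, 10), rnorm(30, 100, 10))$p.value
  }, numeric(1))
  rate <- mean(p < 0.05)
  env <- stats::qbinom(c(0.005, 0.995), reps, 0.05) / reps
  expect_gte(rate, env[1]); expect_lte(rate, env[2])
})
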