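# cohort generation, rasterization and signal simulation

test_that("default cohort reproduces the study bookkeeping", {
  co <- build_cohort(cohort_config(seed = 1))
  expect_equal(nrow(co), 606L)
  expect_equal(length(unique(co$subject_id)), 101L)
  counts <- table(co$group)
  expect_equal(unname(counts[c("sedentary", "cyclist", "jogger", "runner")]),
               c(144L, 132L, 180L, 150L), ignore_attr = TRUE)
  expect_true(all(co$t2_nucleus > 0 & co$t2_annulus > 0))
  expect_true(all(co$water_nucleus >= 0 & co$water_nucleus <= 100))
  expect_true(all(co$water_annulus >= 0 & co$water_annulus <= 100))
})

test_that("grade marginals stay inside the multinomial 95% envelope", {
  p <- grade_reference_table()$n / 606
  # oracle: direct binomial quantiles per grade; default seed inside the
  # 95% envelope, other seeds inside a 99.9% envelope (a 95% band is
  # expected to be missed for ~5% of seed x grade combinations)
  co <- build_cohort(cohort_config(seed = 1))
  counts <- tabulate(co$pfirrmann_grade, 4L)
  expect_true(all(counts >= stats::qbinom(0.025, 606, p) &
                    counts <= stats::qbinom(0.975, 606, p)),
              info = paste(counts, collapse = "/"))
  for (seed in 2:4) {
    co <- build_cohort(cohort_config(seed = seed))
    counts <- tabulate(co$pfirrmann_grade, 4L)
    expect_true(all(counts >= stats::qbinom(0.0005, 606, p) &
                      counts <= stats::qbinom(0.9995, 606, p)),
                info = paste("seed", seed, ":", paste(counts, collapse = "/")))
  }
})

test_that("degenerate config returns the configured means exactly", {
  co <- build_cohort(degenerate_config())
  expect_equal(nrow(co), 1L)
  gt <- grade_reference_table()
  grp <- group_reference_table()
  # all grade-1 mixture + zero SDs: the group-calibrated grade-1 mean is
  # exactly the group table's nucleus cell
  expect_equal(co$t2_nucleus, grp$t2_nucleus[grp$group == "sedentary"],
               tolerance = 1e-12)
  expect_equal(co$t2_annulus, co$t2_nucleus / gt$t2_ratio[1], tolerance = 1e-12)
  # T2w-SI target is honoured through the derived proton density
  expect_equal(co$pd_nucleus * exp(-70 / co$t2_nucleus),
               grp$t2w_nucleus[grp$group == "sedentary"],
               tolerance = 1e-9)
})

test_that("cohort draws are seed-reproducible and validated", {
  expect_identical(build_cohort(cohort_config(seed = 7)),
                   build_cohort(cohort_config(seed = 7)))
  expect_error(cohort_config(subjects_per_group = c(sedentary = -1L)),
               "negative")
  expect_error(cohort_config(grade_probabilities = c(0.5, 0.2, 0.2, 0.2)),
               "sum to 1")
  expect_error(cohort_config(grade_probabilities = c(-0.1, 0.6, 0.3, 0.2)),
               "negative")
})

test_that("rasterization builds disjoint, slice-complete labels", {
  ph <- single_disc_phantom()
  lab <- ph$labels$labels
  # nucleus voxels present on every slice the disc intersects
  for (s in seq_len(dim(lab)[1]))
    expect_gt(sum(lab[s, , ] == ph$labels$codes$nucleus[1]), 0)

  cc <- cohort_config(subjects_per_group = c(sedentary = 1L), seed = 2)
  co <- build_cohort(cc)
  vol <- rasterize_subject(co, acquisition_params("multiecho"))
  # brute-force census: six discs, each with annulus and nucleus labels,
  # pairwise disjoint by construction of the label coding
  codes <- sort(unique(as.vector(vol$labels)))
  expect_true(all(vol$codes$annulus %in% codes))
  expect_true(all(vol$codes$nucleus %in% codes))
  expect_equal(sum(codes > 1L), 12L)  # 6 discs x 2 compartments
  # nucleus enclosed by annulus along the anteroposterior axis
  sl <- vol$labels[1, , ]
  for (d in 1:6) {
    nuc_cols <- range(which(apply(sl == vol$codes$nucleus[d], 2, any)))
    ann_cols <- range(which(apply(sl == vol$codes$annulus[d], 2, any)))
    expect_true(ann_cols[1] < nuc_cols[1] && ann_cols[2] > nuc_cols[2])
  }
})

test_that("overlapping or out-of-view geometries are rejected", {
  ph <- single_disc_phantom()
  discs2 <- rbind(ph$discs, ph$discs)
  discs2$disc_id <- c("A", "B")
  discs2$center_row[2] <- discs2$center_row[1] + 2  # overlaps
  expect_error(rasterize_subject(discs2, ph$params), "overlapping")
  bad <- ph$discs
  bad$center_col <- 2
  expect_error(rasterize_subject(bad, ph$params), "field of view")
})

test_that("multi-echo signal follows the decay model", {
  ph <- single_disc_phantom(t2 = 100, pd = 1000)
  st <- simulate_multiecho(ph$labels, ph$discs, ph$params, 0)
  nuc <- which(ph$labels$labels == ph$labels$codes$nucleus[1], arr.ind = TRUE)
  v <- st$volumes[cbind(nuc[1, 1], nuc[1, 2], nuc[1, 3], 1)]
  expect_equal(v, 1000 * exp(-15.75 / 100), tolerance = 1e-12)
  # strictly decreasing across echoes for every in-disc voxel
  disc_idx <- which(ph$labels$labels > 1L)
  sig <- sapply(1:8, function(e) {
    as.vector(st$volumes[, , , e])[disc_idx]
  })
  expect_true(all(apply(sig, 1, function(x) all(diff(x) < 0))))
})

test_that("Rician background magnitude matches the Rayleigh oracle", {
  ph <- single_disc_phantom(params = acquisition_params("multiecho",
                                                        n_rows = 60L,
                                                        n_slices = 12L))
  st <- simulate_multiecho(ph$labels, ph$discs, ph$params,
                           noise_sigma = 20, seed = 9)
  bg <- st$volumes[, , , 1][ph$labels$labels == 0L]
  expect_gt(length(bg), 1e4)
  oracle <- oracle_rayleigh_mean(20)           # Monte-Carlo, 1e5 draws
  expect_equal(mean(bg), oracle, tolerance = 0.02)
  expect_equal(oracle, 20 * sqrt(pi / 2), tolerance = 0.01)
  expect_true(all(st$volumes >= 0))
})

test_that("T2w contrast behaves and nucleus beats annulus for grade 1", {
  ph <- single_disc_phantom(t2 = 100, pd = 1000,
                            params = acquisition_params("t2w", n_rows = 40L))
  img <- simulate_t2w(ph$labels, ph$discs, ph$params, 0)
  nuc1 <- which(ph$labels$labels == ph$labels$codes$nucleus[1])[1]
  expect_equal(img[nuc1], 1000 * exp(-0.70), tolerance = 1e-12)
  ph2 <- single_disc_phantom(t2 = 200, pd = 1000,
                             params = acquisition_params("t2w", n_rows = 40L))
  img2 <- simulate_t2w(ph2$labels, ph2$discs, ph2$params, 0)
  expect_gt(img2[nuc1], img[nuc1])

  # grade-1-like contrast: nucleus SI above annulus SI, checked against
  # a direct voxel-mean oracle on the label volume
  phg <- single_disc_phantom(t2_nucleus = 166, t2_annulus = 166 / 1.8,
                             pd_nucleus = 840, pd_annulus = 318,
                             params = acquisition_params("t2w", n_rows = 40L))
  im <- simulate_t2w(phg$labels, phg$discs, phg$params, 0)
  m_nuc <- mean(im[phg$labels$labels == phg$labels$codes$nucleus[1]])
  m_ann <- mean(im[phg$labels$labels == phg$labels$codes$annulus[1]])
  expect_gt(m_nuc, m_ann)
  expect_equal(m_nuc, 840 * exp(-70 / 166), tolerance = 1e-12)
})

test_that("Dixon signal matches the literal model oracle", {
  te <- c(2.45, 3.67)
  # pure water, no off-resonance: equal real echoes
  ph <- single_disc_phantom(water = 100, pd = 500,
                            params = acquisition_params("dixon", n_rows = 40L))
  dx <- simulate_dixon(ph$labels, ph$discs, NULL, ph$params, 0)
  nuc1 <- which(ph$labels$labels == ph$labels$codes$nucleus[1])[1]
  expect_equal(dx$echo1[nuc1], 500 + 0i, tolerance = 1e-9)
  expect_equal(dx$echo2[nuc1], 500 + 0i, tolerance = 1e-9)

  # opposed-phase cancellation: W = F and c(TE) = -1
  te_opp <- 1 / (2 * 434) * 1000  # ms such that fat phase = pi
  s <- oracle_dixon_signal(50, 50, 0, te_opp)
  expect_equal(Mod(s), 0, tolerance = 1e-9)

  # W = 87, F = 13, psi = 50 Hz against the closed-form oracle
  ph2 <- single_disc_phantom(water = 87, pd = 100,
                             params = acquisition_params("dixon", n_rows = 40L))
  fm <- array(50, dim = dim(ph2$labels$labels))
  dx2 <- simulate_dixon(ph2$labels, ph2$discs, fm, ph2$params, 0)
  for (e in 1:2) {
    want <- oracle_dixon_signal(87, 13, 50, te[e])
    expect_equal(dx2[[paste0("echo", e)]][nuc1], want, tolerance = 1e-9)
  }

  # aliasing guard
  fm_big <- array(500, dim = dim(ph2$labels$labels))
  expect_warning(simulate_dixon(ph2$labels, ph2$discs, fm_big, ph2$params, 0),
                 "aliasing")
})

test_that("simulation is bit-identical under a fixed seed", {
  ph <- single_disc_phantom()
  a <- simulate_multiecho(ph$labels, ph$discs, ph$params, 10, seed = 5)
  b <- simulate_multiecho(ph$labels, ph$discs, ph$params, 10, seed = 5)
  expect_identical(a, b)
  fm1 <- field_map(c(4, 8, 8), 40, seed = 3)
  fm2 <- field_map(c(4, 8, 8), 40, seed = 3)
  expect_identical(fm1, fm2)
  expect_lte(max(abs(fm1)), 40 + 1e-12)
})
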