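# burden endpoints and the accompanying statistics

test_that("percent change, normalization and AUC on hand examples", {
  s <- make_series(c(0, 7, 30), c(100, 50, 500), treatment_start = 0)
  expect_equal(percent_change(s, 0, 7), -50)
  expect_equal(percent_change(s, 0, 30), 400)
  s2 <- make_series(c(0, 10), c(50, 30))
  expect_equal(percent_change(s2, 0, 10), -40)
  expect_equal(percent_change(s2, 0, 0), 0)
  expect_error(percent_change(s, 0, 3), "not an observed")

  norm <- normalize_burden(s)
  expect_equal(norm$burden, c(1, 0.5, 5))
  expect_equal(normalize_burden(norm)$burden, norm$burden)  # idempotent

  tri <- make_series(c(0, 2), c(1, 3))
  expect_equal(auc_trapezoid(tri), 4)
  const <- make_series(c(0, 3, 10), c(2, 2, 2))
  expect_equal(auc_trapezoid(const), 20)
  # additivity over a split window
  s3 <- make_series(c(0, 3, 7, 12), c(1, 4, 2, 8))
  expect_equal(auc_trapezoid(s3, 0, 7) + auc_trapezoid(s3, 7, 12),
               auc_trapezoid(s3))
  expect_error(auc_trapezoid(s3, 0, 1), "at least 2")
})

test_that("BurdenSeries validates its invariants", {
  expect_error(make_series(c(0, 0, 1), c(1, 1, 1)), "increasing")
  expect_error(make_series(c(0, 1), c(1, -1)), "positive")
  expect_error(BurdenSeries("a", c(0, 1), c(1, 1), treatment_start = 5),
               "beyond")
})

test_that("Mann-Whitney: frozen example, oracle agreement, conservation", {
  mw <- mann_whitney(c(1, 2), c(3, 4))
  expect_equal(mw$U, 0)
  expect_equal(mw$p, 2 / 6)

  # identical multisets: U = n^2 / 2
  same <- mann_whitney(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$U, 9 / 2)

  set.seed(11)
  for (i in 1:40) {
    na <- sample(1:6, 1); nb <- sample(1:6, 1)
    # integer draws force ties regularly
    a <- sample(1:5, na, replace = TRUE)
    b <- sample(1:5, nb, replace = TRUE)
    got <- mann_whitney(a, b)
    expect_equal(got$p, oracle_mw_p(a, b), info = paste(i))
    # conservation
    expect_equal(got$U + mann_whitney(b, a)$U, na * nb)
  }
  # tie-free path agrees with the enumeration oracle too
  for (i in 1:20) {
    a <- rnorm(sample(2:6, 1)); b <- rnorm(sample(2:6, 1))
    expect_equal(mann_whitney(a, b)$p, oracle_mw_p(a, b))
  }
  expect_error(mann_whitney(numeric(0), 1), "nonempty")
})

test_that("KM estimator: product-limit steps and censoring-free reduction", {
  # 4 units, one death at t = 1 -> S(1) = 0.75
  km <- km_estimate(c(1, 5, 6, 7), c(1, 0, 0, 0))
  expect_equal(km$surv, 0.75)
  expect_equal(km$n_risk, 4L)

  # all censored -> flat at 1 (no event rows)
  km0 <- km_estimate(c(1, 2, 3), c(0, 0, 0))
  expect_equal(nrow(km0), 0L)

  # without censoring, KM equals 1 - ECDF at every event time
  set.seed(3)
  t <- sample(1:50, 30, replace = TRUE)
  km2 <- km_estimate(t, rep(1, 30))
  ecdf_surv <- 1 - ecdf(t)(km2$time)
  expect_equal(km2$surv, ecdf_surv, tolerance = 1e-12)
  expect_true(all(diff(km2$surv) <= 0))
})

test_that("log-rank: hand-tabulated grid, reference agreement, no-event case", {
  # 6 subjects: group 1 events at 1, 2 and censor at 3;
  # group 2 events at 1, 4 and censor at 5. Hand O-E table gives
  # O1 = 2, E1 = 1.5, V = 0.65 -> chisq = 0.25 / 0.65
  time <- c(1, 2, 3, 1, 4, 5)
  event <- c(1, 1, 0, 1, 1, 0)
  group <- rep(c("g1", "g2"), each = 3)
  lr <- logrank_test(time, event, group)
  expect_equal(lr$chisq, 0.25 / 0.65)
  expect_equal(lr$observed[1], 2)
  expect_equal(lr$expected[1], 1.5)

  # matches the survival package on random data
  set.seed(8)
  t2 <- rexp(40); e2 <- rbinom(40, 1, 0.7); g2 <- rep(c("a", "b"), 20)
  lr2 <- logrank_test(t2, e2, g2)
  ref <- survival::survdiff(survival::Surv(t2, e2) ~ g2)
  expect_equal(lr2$chisq, unname(ref$chisq), tolerance = 1e-10)

  # identical event-time multisets, no censoring -> statistic 0
  sym <- logrank_test(c(1, 2, 3, 1, 2, 3), rep(1, 6),
                      rep(c("a", "b"), each = 3))
  expect_equal(sym$chisq, 0)

  expect_warning(out <- logrank_test(c(1, 2), c(0, 0), c("a", "b")),
                 "no events")
  expect_equal(out$p, 1)
})

test_that("log-rank p is approximately uniform under label permutation", {
  set.seed(19)
  t <- rexp(40); e <- rbinom(40, 1, 0.8)
  ps <- replicate(200, {
    g <- sample(rep(c("a", "b"), 20))
    logrank_test(t, e, g)$p
  })
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("PFS: inclusive 2x crossing of the last pre-treatment burden", {
  s <- make_series(c(0, 7, 14, 21), c(100, 120, 180, 210),
                   treatment_start = 0)
  r <- pfs_time(s)
  expect_equal(r$time, 21)
  expect_equal(r$event, 1L)
  # exactly 2.0x counts as progression ("reaches")
  s2 <- make_series(c(0, 7), c(100, 200), treatment_start = 0)
  expect_equal(pfs_time(s2)$event, 1L)
  # never reaching 2x censors at the last observation
  s3 <- make_series(c(0, 7, 14), c(100, 120, 150), treatment_start = 0)
  r3 <- pfs_time(s3)
  expect_equal(r3$event, 0L)
  expect_equal(r3$time, 14)
  expect_error(pfs_time(make_series(c(5, 9), c(1, 1), treatment_start = 1)),
               "pre-treatment")
})

test_that("resistance: running-nadir scan with inclusive 10x rule", {
  s <- make_series(c(1, 2, 3, 4), c(100, 10, 50, 120), treatment_start = 1)
  r <- resistance_time(s)
  expect_true(r$resistant)
  expect_equal(r$time, 4)
  expect_equal(r$nadir, 10)
  # monotone decline never triggers
  dec <- make_series(1:5, c(100, 80, 60, 40, 20), treatment_start = 1)
  expect_false(resistance_time(dec)$resistant)
  # exactly 10x the nadir counts ("at least 10x")
  ex <- make_series(1:3, c(50, 10, 100), treatment_start = 1)
  expect_true(resistance_time(ex)$resistant)
  expect_equal(resistance_time(ex)$time, 3)
})

test_that("incidence requires persistence through two further timepoints", {
  inc <- make_series(c(14, 21, 28, 35), c(5, 6, 7, 2), treatment_start = 14,
                     threshold = 4)
  r <- incidence_call(inc)
  expect_true(r$incident)
  expect_equal(r$onset, 14)
  # one isolated detection is not incidence
  iso <- make_series(c(14, 21, 28), c(5, 2, 2), treatment_start = 14,
                     threshold = 4)
  expect_false(incidence_call(iso)$incident)
  # two detections then loss is not incidence
  two <- make_series(c(14, 21, 28), c(5, 6, 2), treatment_start = 14,
                     threshold = 4)
  expect_false(incidence_call(two)$incident)
  expect_warning(r2 <- incidence_call(
    make_series(c(1, 2), c(9, 9), treatment_start = 1, threshold = 4)),
    "fewer than 3")
  expect_false(r2$incident)
})

test_that("tumor volume: formula, boundary, cubic scaling", {
  expect_equal(tumor_volume(10, 5), 130)
  expect_equal(tumor_volume(1, 1), 0.52)
  expect_equal(tumor_volume(4, 2), 8 * tumor_volume(2, 1))
  expect_warning(tumor_volume(2, 3), "minor")
  expect_error(tumor_volume(0, 1), "positive")
})
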