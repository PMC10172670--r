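lay64 <- layout_1020()

test_that("gfp equals the population SD across channels", {
  lay <- random_layout(2, seed = 1)
  erp <- eeg_erp(matrix(c(1, 1, 1, -1), 2), 500, 1:2, lay)
  expect_equal(gfp(erp), c(0, 1))                       # flat sample, (+1,-1)
  set.seed(4)
  v <- rnorm(64)
  expect_equal(gfp(matrix(v, 64, 1)), pop_sd(v))
})

test_that("spatial correlation is polarity-invariant with sane edge cases", {
  set.seed(2)
  a <- rnorm(10)
  expect_equal(spatial_correlation(a, a), 1)
  expect_equal(spatial_correlation(a, -a), 1)
  expect_equal(spatial_correlation(a, -a, polarity_invariant = FALSE), -1)
  b <- c(1, -1, 0, 0); d <- c(0, 0, 1, -1)              # zero-mean orthogonal
  expect_equal(spatial_correlation(b, d), 0)
  expect_error(spatial_correlation(a, rep(1, 10)), "zero-variance")
  expect_error(spatial_correlation(a, rnorm(9)), "equal channel")
})

test_that("k-means attains perfect fit on noise-free data", {
  m <- make_prototype_maps(lay64, 1, seed = 5)
  sim <- simulate_epoch(m, 100, snr = Inf, seed = 6)
  fit <- microstates(average_erp(sim$epochs), K = 1, restarts = 3, seed = 7)
  expect_equal(fit$gev, 1, tolerance = 1e-9)

  # two orthogonalish maps recovered exactly
  m2 <- make_prototype_maps(lay64, 2, seed = 8)
  sim2 <- simulate_epoch(m2, c(100, 120), snr = Inf, seed = 9)
  fit2 <- microstates(average_erp(sim2$epochs), K = 2, restarts = 5, seed = 10)
  corr <- abs(crossprod(fit2$maps, m2))
  expect_gte(min(apply(corr, 2, max)), 0.999)
  expect_error(microstates(average_erp(sim2$epochs), K = 64), "channels - 1")
})

test_that("k-means recovers maps from noisy data (snr 5, 20 restarts)", {
  m <- make_prototype_maps(lay64, 2, seed = 11)
  sim <- simulate_epoch(m, c(100, 120), epoch_window = c(-200, 1800), snr = 5,
                        seed = 12)
  fit <- microstates(average_erp(sim$epochs), K = 2, restarts = 20, seed = 13)
  corr <- abs(crossprod(fit$maps, m))
  expect_gte(min(apply(corr, 2, max)), 0.99)
})

test_that("GEV matches its brute-force formula and partitions across classes", {
  x <- random_labeled_erp(C = 8, Tn = 40, K = 3, seed = 20)
  g <- gev_of_fit(x$V, x$maps, x$labels)
  expect_equal(g$total, brute_gev(x$V, x$maps, x$labels), tolerance = 1e-12)
  expect_equal(sum(g$per_class), g$total, tolerance = 1e-12)

  # random labels on random data (not the backfit argmax)
  set.seed(21)
  rl <- sample(0:3, 40, replace = TRUE)
  g2 <- gev_of_fit(x$V, x$maps, rl)
  expect_equal(g2$total, brute_gev(x$V, x$maps, rl), tolerance = 1e-12)
  expect_error(gev_of_fit(matrix(0, 8, 5), x$maps, rep(1, 5)), "all-zero")
})

test_that("CV criterion matches brute force, grows with K, and guards K = C-1", {
  x <- random_labeled_erp(C = 6, Tn = 30, K = 2, seed = 22)
  expect_equal(cv_criterion(x$V, x$maps, x$labels),
               brute_cv(x$V, x$maps, x$labels), tolerance = 1e-12)
  # same residual, larger K -> strictly larger penalty
  s2 <- brute_cv(x$V, x$maps, x$labels) / ((6 - 1) / (6 - 1 - 2))^2
  expect_gt(s2 * ((5) / (5 - 3))^2, s2 * ((5) / (5 - 2))^2)
  m4 <- cbind(x$maps, x$maps, x$maps[, 1], x$maps[, 2] * -1)[, 1:5]
  expect_error(cv_criterion(x$V, m4, rep(1, 30)), "divides by zero")

  # noise-free single-map data at K = 1 has zero residual
  m <- make_prototype_maps(lay64, 1, seed = 23)
  sim <- simulate_epoch(m, 100, snr = Inf, seed = 24)
  V <- average_erp(sim$epochs)$data
  expect_equal(cv_criterion(V, m), 0, tolerance = 1e-12)
})

test_that("backfitting is polarity-invariant with deterministic tie-breaking", {
  x <- random_labeled_erp(C = 8, Tn = 10, K = 3, seed = 25)
  m <- x$maps
  V <- cbind(-2 * m[, 2],                              # negated map 2
             m[, 1] + m[, 3],                          # tie between 1 and 3
             matrix(0, 8, 1))                          # flat sample
  lab <- backfit(V, m)
  expect_equal(lab[1], 2L)
  expect_equal(lab[2], 1L)                             # lowest index wins
  expect_equal(lab[3], 0L)
})

test_that("exhaustive search confirms the assignment maximizes GEV given final maps", {
  # tiny instances: all 2^T two-class labelings enumerated
  for (seed in 1:3) {
    set.seed(seed)
    Tn <- 10
    x <- random_labeled_erp(C = 4, Tn = Tn, K = 2, seed = seed + 30)
    fit <- microstates(x$V, K = 2, iterations = 200, restarts = 10,
                       seed = seed)
    best <- gev_of_fit(x$V, fit$maps, fit$labels)$total
    grid <- as.matrix(expand.grid(rep(list(1:2), Tn)))
    all_gev <- apply(grid, 1, function(lab) brute_gev(x$V, fit$maps, lab))
    expect_lte(max(all_gev), best + 1e-12)
  }
})

test_that("label smoothing absorbs short blips and respects the minimum", {
  x <- random_labeled_erp(C = 8, Tn = 50, K = 2, seed = 40)
  lab <- rep(1L, 50); lab[25] <- 2L
  sm <- smooth_labels(lab, 30, x$V, x$maps, rate = 500)
  expect_equal(sm, rep(1L, 50))
  expect_identical(smooth_labels(lab, 0, x$V, x$maps), lab)

  # generic labelings end with no interior segment below the minimum
  x2 <- random_labeled_erp(C = 8, Tn = 60, K = 2, seed = 41)
  for (seed in 1:5) {
    set.seed(seed)
    lab2 <- sample(1:2, 60, replace = TRUE)
    sm2 <- smooth_labels(lab2, 20, x2$V, x2$maps, rate = 500)
    r <- rle(sm2)
    interior <- r$lengths[-c(1, length(r$lengths))]
    if (length(interior)) expect_gte(min(interior), 10)  # 20 ms at 500 Hz
  }
})

test_that("temporal parameters match hand-computed counts and conventions", {
  lay <- random_layout(4, seed = 50)
  x <- random_labeled_erp(C = 4, Tn = 600, K = 2, seed = 50)
  lab <- c(rep(1L, 480), rep(2L, 120))
  p <- compute_parameters(lab, x$V, x$maps, rate = 500)
  expect_equal(p$coverage, c(0.8, 0.2))
  expect_equal(p$duration_ms, c(960, 240))
  expect_equal(p$occurrence, c(1, 1) / 1.2)

  # runs of 3 and 5 samples at 500 Hz -> mean duration 8 ms
  lab2 <- c(rep(1L, 3), rep(2L, 4), rep(1L, 5), rep(2L, 588))
  p2 <- compute_parameters(lab2, x$V, x$maps, rate = 500)
  expect_equal(p2$duration_ms[1], 8)
  expect_equal(p2$occurrence[1], 2 / 1.2)              # 2 segments in 1.2 s

  # unobserved class gets zeroes and an undefined duration
  p3 <- compute_parameters(rep(1L, 600), x$V, x$maps, rate = 500)
  expect_equal(p3$coverage[2], 0)
  expect_equal(p3$occurrence[2], 0)
  expect_true(is.na(p3$duration_ms[2]))
  expect_error(compute_parameters(rep(0L, 600), x$V, x$maps), "no assigned")
})

test_that("conservation identities hold on random labelings", {
  for (seed in 1:20) {
    x <- random_labeled_erp(C = 6, Tn = 120, K = 3, seed = 60 + seed)
    p <- compute_parameters(x$labels, x$V, x$maps, rate = 500)
    expect_equal(sum(p$coverage), 1, tolerance = 1e-9)
    expect_equal(sum(p$gev), attr(p, "total_gev"), tolerance = 1e-9)
    obs <- !is.na(p$duration_ms)
    expect_equal(p$occurrence[obs] * p$duration_ms[obs] / 1000,
                 p$coverage[obs], tolerance = 1e-9)
    # per-assigned-second convention rescales occurrence only
    p2 <- compute_parameters(x$labels, x$V, x$maps, rate = 500,
                             occurrence = "assigned")
    expect_equal(p2$coverage, p$coverage)
  }
})

test_that("negating the ERP changes neither labels nor parameters", {
  m <- make_prototype_maps(lay64, 3, seed = 70)
  sim <- simulate_epoch(m, 100, snr = 5, seed = 71)
  V <- average_erp(sim$epochs)$data
  lab <- backfit(V, m)
  expect_identical(backfit(-V, m), lab)
  p1 <- compute_parameters(lab, V, m, rate = 500)
  p2 <- compute_parameters(backfit(-V, m), -V, m, rate = 500)
  expect_equal(p1, p2, tolerance = 1e-12)
})

test_that("select_n_maps returns the CV minimizer and a coherent table", {
  m <- make_prototype_maps(lay64, 2, seed = 80)
  sim <- simulate_epoch(m, c(90, 110), snr = 20, seed = 81)
  erp <- average_erp(sim$epochs)
  sel <- select_n_maps(erp, K_range = c(2, 2), restarts = 5, seed = 82)
  expect_equal(sel$K_opt, 2L)                          # singleton range
  sel2 <- select_n_maps(erp, K_range = 2:4, restarts = 5, seed = 83)
  expect_equal(nrow(sel2$table), 3L)
  # GEV is non-decreasing in K on the same data (up to restart noise)
  expect_true(all(diff(sel2$table$gev) > -1e-6))
  expect_error(select_n_maps(erp, K_range = integer(0)), "empty")
})

test_that("msfit methods expose maps, labels, residuals and simulation", {
  m <- make_prototype_maps(lay64, 3, seed = 90)
  sim <- simulate_epoch(m, 100, snr = 10, seed = 91)
  erp <- average_erp(sim$epochs)
  fit <- microstates(erp, K = 3, restarts = 5, seed = 92)
  expect_s3_class(fit, "msfit")
  expect_equal(dim(coef(fit)), c(64L, 3L))
  expect_identical(predict(fit), fit$labels)
  expect_identical(predict(fit, erp), fit$labels)
  # fitted + residuals reconstruct the (referenced) data
  expect_equal(fitted(fit) + residuals(fit), fit$data, tolerance = 1e-12)
  # residuals are orthogonal to the assigned map at every sample
  r <- residuals(fit)
  for (t in c(1, 100, 300))
    expect_equal(sum(r[, t] * fit$maps[, fit$labels[t]]), 0, tolerance = 1e-9)
  s <- summary(fit)
  expect_s3_class(s, "summary.msfit")
  expect_equal(nrow(s$params), 3L)
  sim2 <- simulate(fit, nsim = 2, seed = 1, duration_means_ms = 100)
  expect_equal(dim(sim2$epochs$data)[1], 2L)
  expect_output(print(fit), "Microstate fit")
})

test_that("group parameter table has full cardinality and round-trips to disk", {
  design <- cohort_design(groups = c(HC = 2, MDD = 2),
                          conditions = c(neutral = 3, negative = 3), snr = Inf)
  sim <- simulate_cohort(design, seed = 100)
  erps <- lapply(sim$epochs, function(s) lapply(s, function(e)
    average_reference(average_erp(e))))
  tab <- group_parameter_table(erps, sim$ground_truth$mapset,
                               groups = sim$ground_truth$subjects)
  expect_equal(nrow(tab), 4 * 2 * 6)                   # subjects x cues x K
  expect_setequal(unique(tab$condition), c("neutral", "negative"))

  # noise-free cells: fitted parameters equal planted ground truth
  gt <- sim$ground_truth$params
  gt$class <- paste0("MS", gt$class)
  mm <- merge(tab, gt, by = c("subject_id", "condition", "class"))
  mm <- mm[!is.na(mm$duration_ms), ]
  expect_equal(mm$coverage, mm$planted_coverage, tolerance = 1e-9)
  expect_equal(mm$duration_ms, mm$planted_duration_ms, tolerance = 1e-9)

  tf <- tempfile(fileext = ".tsv")
  write.table(tab, tf, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read.table(tf, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  expect_equal(back$duration_ms, tab$duration_ms)
  expect_equal(back$subject_id, tab$subject_id)
})
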