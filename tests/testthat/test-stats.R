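# long-format 2 (cue) x 3 (group) data generator for the mixed designs
.mixed_data <- function(n_per_group = 30, effect = 0, seed = 1,
                        sd_subj = 30, sd_noise = 20) {
  set.seed(seed)
  g <- rep(c("HC", "MDD", "NSSI"), n_per_group)
  N <- length(g)
  id <- sprintf("s%03d", seq_len(N))
  b <- rnorm(N, 200, sd_subj)
  y1 <- b + rnorm(N, 0, sd_noise)
  y2 <- b + rnorm(N, 0, sd_noise) + effect * (g == "NSSI")
  data.frame(subject_id = rep(id, 2), group = rep(g, 2),
             condition = rep(c("neutral", "negative"), each = N),
             age = rep(rnorm(N, 15, 1.5), 2),
             sex = rep(sample(c("male", "female"), N, TRUE), 2),
             dv = c(y1, y2), stringsAsFactors = FALSE)
}

test_that("summary-statistic one-way ANOVA reproduces published group tests", {
  ref <- baseline_reference()
  hamd <- oneway_anova_from_summary(ref$HAMD$mean, ref$HAMD$sd, ref$n)
  expect_equal(hamd$df_num, 2L)
  expect_equal(hamd$df_den, 135L)
  expect_lt(abs(hamd$F - 295.378) / 295.378, 0.005)
  phq <- oneway_anova_from_summary(ref$PHQ9$mean, ref$PHQ9$sd, ref$n)
  expect_lt(abs(phq$F - 246.842) / 246.842, 0.005)
  age <- oneway_anova_from_summary(ref$age$mean, ref$age$sd, ref$n)
  expect_lt(abs(age$F - 6.464) / 6.464, 0.02)

  expect_equal(oneway_anova_from_summary(c(5, 5, 5), c(1, 2, 1),
                                         c(10, 10, 10))$F, 0)
  expect_error(oneway_anova_from_summary(c(1, 2), c(1, 1), c(1, 5)), "n >= 2")

  # two groups: F equals the squared pooled-variance t statistic
  set.seed(3)
  x <- rnorm(12); y <- rnorm(15, 0.8)
  a <- oneway_anova_from_summary(c(mean(x), mean(y)), c(sd(x), sd(y)),
                                 c(12, 15))
  tt <- t.test(x, y, var.equal = TRUE)
  expect_equal(a$F, unname(tt$statistic)^2, tolerance = 1e-9)
  expect_equal(a$p, tt$p.value, tolerance = 1e-9)
})

test_that("chi-square of independence matches published and hand values", {
  chi <- chi_square_independence(baseline_reference()$sex_counts)
  expect_equal(round(chi$chisq, 3), 7.190)
  expect_equal(chi$df, 2L)

  # proportional rows are independent
  expect_equal(chi_square_independence(rbind(c(10, 20), c(5, 10)))$chisq, 0,
               tolerance = 1e-12)
  # all expected counts 2: hand computation gives 2.0
  expect_equal(chi_square_independence(rbind(c(1, 3), c(3, 1)))$chisq, 2)
  expect_error(chi_square_independence(rbind(c(0, 0), c(1, 2))), "marginal")
})

test_that("Holm adjustment is the step-down procedure", {
  expect_equal(holm_bonferroni(0.04), 0.04)
  expect_equal(holm_bonferroni(c(0.01, 0.02, 0.04)), c(0.03, 0.04, 0.04))
  set.seed(5)
  p <- runif(12)
  expect_true(all(holm_bonferroni(p) >= p))
  expect_equal(holm_bonferroni(p), p.adjust(p, "holm"))
  # order restored
  expect_equal(holm_bonferroni(rev(c(0.01, 0.02, 0.04))),
               rev(c(0.03, 0.04, 0.04)))
  expect_error(holm_bonferroni(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("Greenhouse-Geisser epsilon has its analytic values and bounds", {
  expect_equal(greenhouse_geisser_epsilon(diag(2)), 1)
  # compound symmetry at any L
  for (L in 3:5) {
    S <- matrix(0.4, L, L); diag(S) <- 1
    expect_equal(greenhouse_geisser_epsilon(S), 1, tolerance = 1e-9)
  }
  # arbitrary PSD matrix against a direct evaluation via eigenvalues
  set.seed(6)
  A <- matrix(rnorm(9), 3); S <- crossprod(A)
  M <- qr.Q(qr(contr.helmert(3)))
  lam <- eigen(t(M) %*% S %*% M, symmetric = TRUE)$values
  expect_equal(greenhouse_geisser_epsilon(S),
               sum(lam)^2 / (2 * sum(lam^2)), tolerance = 1e-12)
  eps <- greenhouse_geisser_epsilon(S)
  expect_gt(eps, 1 / 2); expect_lte(eps, 1)
  expect_error(greenhouse_geisser_epsilon(matrix(c(1, 2, 2, 1), 2)),
               "semidefinite")
})

test_that("mixed ANOVA handles degenerate, between-only and covariate designs", {
  d <- .mixed_data(10, effect = 0, seed = 7)
  # constant dv -> all F 0
  dc <- d; dc$dv <- 5
  a0 <- suppressWarnings(
    mixed_anova(dc, "dv", within = "condition", between = "group",
                subject = "subject_id"))
  expect_true(all(a0$F == 0))
  expect_true(all(a0$p == 1))

  # between-only equals the summary-statistic one-way ANOVA
  d1 <- d[d$condition == "neutral", ]
  a1 <- mixed_anova(d1, "dv", between = "group", subject = "subject_id")
  m <- tapply(d1$dv, d1$group, mean); s <- tapply(d1$dv, d1$group, sd)
  n <- tapply(d1$dv, d1$group, length)
  a2 <- oneway_anova_from_summary(m, s, n)
  expect_equal(a1$F[a1$effect == "group"], a2$F, tolerance = 1e-9)
  expect_equal(a1$p[a1$effect == "group"], a2$p, tolerance = 1e-9)

  # covariates are absorbed into the between stratum (df bookkeeping)
  a3 <- mixed_anova(d, "dv", within = "condition", between = "group",
                    subject = "subject_id", covariates = c("age", "sex"))
  expect_equal(a3$df_den[a3$effect == "group"], 30 - 3 - 2)
  expect_true(all(c("age", "sex") %in% a3$effect))
  # two-level within factor: epsilon exactly 1
  expect_equal(a3$gg_epsilon[a3$effect == "condition"], 1)

  # row order of the input table does not matter
  sh <- d[sample(nrow(d)), ]
  a4 <- mixed_anova(sh, "dv", within = "condition", between = "group",
                    subject = "subject_id")
  a5 <- mixed_anova(d, "dv", within = "condition", between = "group",
                    subject = "subject_id")
  expect_equal(a4$F, a5$F, tolerance = 1e-9)

  # subjects missing a within cell are dropped listwise with a message
  dmiss <- d[-1, ]
  expect_message(
    a6 <- mixed_anova(dmiss, "dv", within = "condition", between = "group",
                      subject = "subject_id"),
    "dropped")
  expect_equal(attr(a6, "n_subjects"), 29)
})

test_that("mixed ANOVA partitions sums of squares within each stratum", {
  d <- .mixed_data(12, effect = 25, seed = 8)
  a <- mixed_anova(d, "dv", within = "condition", between = "group",
                   subject = "subject_id")
  st <- attr(a, "strata")
  # between stratum: group SS + subject error SS = total between-subject SS
  w <- tapply(d$dv, d$subject_id, mean)
  gl <- tapply(d$group, d$subject_id, function(x) x[1])
  ss_total_between <- 2 * sum((w - mean(w))^2)  # 2 observations per subject
  ss_group <- a$ss[a$effect == "group"]
  expect_equal(ss_group + st$between$ss, ss_total_between,
               tolerance = 1e-6 * ss_total_between)
})

test_that("planted interactions are detected and localized by simple effects", {
  d <- .mixed_data(20, effect = 35, seed = 9)
  a <- mixed_anova(d, "dv", within = "condition", between = "group",
                   subject = "subject_id")
  i <- a$effect == "group:condition"
  expect_lt(a$p_gg[i], 0.05)
  se <- simple_effects(a, "group:condition", "condition")
  expect_equal(nrow(se$effects), 2L)
  pneg <- se$effects$p[se$effects$slice == "negative"]
  pneu <- se$effects$p[se$effects$slice == "neutral"]
  expect_lt(pneg, 0.05)
  expect_gt(pneu, pneg)
  # pairwise Holm table covers the 3 group pairs per slice
  expect_equal(nrow(se$pairwise), 6L)
  expect_true(all(se$pairwise$p_holm >= se$pairwise$p))
  expect_error(simple_effects(a, "group:nope", "group"), "not in the fitted")
})

test_that("permuting group labels destroys a planted between-group effect", {
  d <- .mixed_data(15, effect = 0, seed = 10)
  d$dv <- d$dv + 40 * (d$group == "MDD")              # between-group shift
  a <- mixed_anova(d, "dv", within = "condition", between = "group",
                   subject = "subject_id")
  F_true <- a$F[a$effect == "group"]
  set.seed(11)
  Fs <- replicate(20, {
    perm <- d
    # permute at the subject level to keep within-subject pairing
    map <- tapply(d$group, d$subject_id, function(x) x[1])
    shuffled <- stats::setNames(sample(as.vector(map)), names(map))
    perm$group <- shuffled[perm$subject_id]
    mixed_anova(perm, "dv", within = "condition", between = "group",
                subject = "subject_id")$F[1]
  })
  expect_gt(F_true, 10 * stats::median(Fs))
  expect_lt(stats::median(Fs), 3)
})

test_that("pre/post difference correlations recover exact linear relations", {
  set.seed(12)
  n <- 20
  ids <- sprintf("s%02d", 1:n)
  dS <- rnorm(n, -8, 3)
  scales <- data.frame(subject_id = rep(ids, 2),
                       time = rep(c("before", "after"), each = n),
                       HAMD = c(rnorm(n, 23, 2), rnorm(n, 23, 2) + dS))
  scales$HAMD[(n + 1):(2 * n)] <- scales$HAMD[1:n] + dS
  base <- rnorm(n, 200, 30)
  params <- data.frame(subject_id = rep(ids, 2),
                       time = rep(c("before", "after"), each = n),
                       class = "MS3",
                       duration_ms = c(base, base + 2 * dS),   # delta = 2*dS
                       coverage = c(base, base - dS) / 1000)   # delta = -dS
  out <- prepost_difference_correlation(scales, params,
                                        scale_vars = "HAMD",
                                        param_vars = c("duration_ms",
                                                       "coverage"))
  expect_equal(out$r[out$parameter == "duration_ms"], 1, tolerance = 1e-9)
  expect_equal(out$r[out$parameter == "coverage"], -1, tolerance = 1e-9)

  # independent deltas: near-zero median |r|, Holm keeps the null quiet
  set.seed(13)
  reps <- replicate(60, {
    sc <- data.frame(subject_id = rep(ids, 2),
                     time = rep(c("before", "after"), each = n),
                     HAMD = rnorm(2 * n, 20, 4))
    pp <- data.frame(subject_id = rep(ids, 2),
                     time = rep(c("before", "after"), each = n),
                     class = "MS1", duration_ms = rnorm(2 * n, 100, 20))
    o <- prepost_difference_correlation(sc, pp, scale_vars = "HAMD",
                                        param_vars = "duration_ms")
    c(r = abs(o$r), sig = o$p_holm < 0.05)
  })
  expect_lt(stats::median(reps["r", ]), 0.25)
  expect_lte(mean(reps["sig", ]), 0.05 + 2 * sqrt(0.05 * 0.95 / 60))
  expect_error(prepost_difference_correlation(scales[c(1, n + 1), ],
                                              params[c(1, n + 1), ],
                                              scale_vars = "HAMD",
                                              param_vars = "duration_ms"),
               "3 paired")
})
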