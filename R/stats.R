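# Statistical designs: summary-statistic one-way ANOVA and chi-square,
# mixed repeated-measures ANOVA with covariates (Type III, Greenhouse-Geisser),
# simple effects, Holm adjustment, and pre/post difference correlations.
#
# The general-linear-model machinery for the mixed designs is delegated to
# car::Anova (multivariate linear model + within-subject design), the
# mainstream implementation of the SPSS-style univariate repeated-measures
# table; this file owns the interfaces, the summary-statistic reconstructions
# and the effect-size / epsilon bookkeeping.

#' One-way ANOVA reconstructed from group summaries
#'
#' Between- and within-group sums of squares are rebuilt from per-group means,
#' standard deviations and sizes, so published summary tables can be checked
#' without raw data. Inputs rounded to 2-3 decimals bound the achievable
#' agreement with published F values (about 1% for small effects).
#'
#' @param means,sds,ns Numeric vectors, one entry per group (`ns >= 2`).
#' @return A one-row data frame of class `"anova_result"`: `effect`, `F`,
#'   `df_num`, `df_den`, `p`, `partial_eta_sq`.
#' @examples
#' oneway_anova_from_summary(c(1.30, 22.62, 23.14), c(1.809, 3.448, 4.220),
#'                           c(20, 52, 66))
#' @export
oneway_anova_from_summary <- function(means, sds, ns) {
  if (length(means) < 2L) stop("need at least 2 groups")
  if (length(sds) != length(means) || length(ns) != length(means))
    stop("'means', 'sds' and 'ns' must have equal length")
  if (any(ns < 2)) stop("every group needs n >= 2")
  if (any(sds < 0)) stop("standard deviations must be >= 0")
  grand <- sum(ns * means) / sum(ns)
  ssb <- sum(ns * (means - grand)^2)
  ssw <- sum((ns - 1) * sds^2)
  df1 <- length(means) - 1L
  df2 <- sum(ns) - length(means)
  msb <- ssb / df1
  msw <- ssw / df2
  F <- if (msw == 0) { if (msb == 0) 0 else Inf } else msb / msw
  out <- data.frame(effect = "group", F = F, df_num = df1, df_den = df2,
                    p = stats::pf(F, df1, df2, lower.tail = FALSE),
                    partial_eta_sq = if (ssb + ssw == 0) 0 else ssb / (ssb + ssw),
                    stringsAsFactors = FALSE)
  class(out) <- c("anova_result", "data.frame")
  out
}

#' Pearson chi-square test of independence
#'
#' Without continuity correction, on an r x c count table.
#'
#' @param table Matrix (or coercible) of nonnegative counts.
#' @return Data frame with `chisq`, `df`, `p`.
#' @examples
#' chi_square_independence(rbind(c(8, 12), c(20, 32), c(12, 54)))
#' @export
chi_square_independence <- function(table) {
  m <- as.matrix(table)
  if (any(m < 0)) stop("counts must be nonnegative")
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stop("zero marginal: drop empty rows/columns first")
  res <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  if (any(res$expected <= 0)) stop("all expected counts must be > 0")
  data.frame(chisq = unname(res$statistic), df = unname(res$parameter),
             p = unname(res$p.value))
}

#' Greenhouse-Geisser epsilon
#'
#' The sphericity-correction factor for an L-level within-subject factor,
#' computed from the covariance of the repeated measures: with `A` the
#' covariance transformed by an orthonormal contrast basis,
#' `epsilon = tr(A)^2 / ((L-1) * sum(A^2))`. Degrees of freedom downstream are
#' multiplied by epsilon. Equals 1 under compound symmetry and for L = 2.
#'
#' @param within_cov Symmetric positive semidefinite `L x L` covariance.
#' @return Epsilon in `(1/(L-1), 1]`.
#' @export
greenhouse_geisser_epsilon <- function(within_cov) {
  S <- as.matrix(within_cov)
  L <- nrow(S)
  if (L < 2L || ncol(S) != L) stop("'within_cov' must be L x L with L >= 2")
  if (max(abs(S - t(S))) > 1e-8 * max(1, max(abs(S))))
    stop("'within_cov' must be symmetric")
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1))
    stop("'within_cov' must be positive semidefinite")
  M <- qr.Q(qr(stats::contr.helmert(L)))        # orthonormal contrasts
  A <- crossprod(M, S %*% M)
  sum(diag(A))^2 / ((L - 1) * sum(A^2))
}

#' Holm (step-down Bonferroni) adjustment
#'
#' @param pvalues Numeric vector of raw p values in `[0, 1]`.
#' @return Adjusted p values in the original order (monotone, capped at 1).
#' @export
holm_bonferroni <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop("p values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "holm")
}

# coerce a covariate column: character/factor/logical -> 0/1 indicator
.covariate_numeric <- function(v, name) {
  if (is.numeric(v)) return(v)
  u <- sort(unique(as.character(v)))
  if (length(u) != 2L)
    stop("non-numeric covariate '", name, "' must be binary")
  as.numeric(as.character(v) == u[2L])
}

#' Mixed repeated-measures ANOVA
#'
#' SPSS-style univariate repeated-measures table for designs with up to two
#' within-subject factors, one between-subject factor and between-subject
#' covariates: Type III sums of squares via a multivariate linear model on the
#' within-cell responses (car's `Anova`), covariates mean-centered and
#' absorbed into the between-subject stratum, partial eta squared
#' `SS / (SS + SS_error)` per effect, and Greenhouse-Geisser epsilon and
#' corrected p values for within factors with more than two levels (epsilon is
#' exactly 1 for two-level factors). Subjects missing any within cell are
#' dropped listwise with a message.
#'
#' @param data Long-format data frame.
#' @param dv Name of the numeric response column.
#' @param within Character vector (length 0-2) of within-subject factor
#'   columns.
#' @param between Optional between-subject factor column.
#' @param subject Subject-id column.
#' @param covariates Optional between-subject covariate columns (constant
#'   within subject; binary non-numeric columns are coded 0/1).
#' @return A data frame of class `"anova_result"`, one row per effect:
#'   `effect`, `ss`, `ss_error`, `df_num`, `df_den`, `F`, `p`,
#'   `partial_eta_sq`, `gg_epsilon`, `df_num_gg`, `df_den_gg`, `p_gg`.
#'   Attribute `"strata"` records the error SS/df per stratum (used by
#'   [simple_effects()]); `"design"` records the call layout; `"n_subjects"`
#'   the analyzed sample size.
#' @export
mixed_anova <- function(data, dv, within = NULL, between = NULL, subject,
                        covariates = NULL) {
  need <- c(dv, within, between, subject, covariates)
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (length(within) > 2L) stop("at most two within-subject factors")
  d <- data[, need, drop = FALSE]
  d[[subject]] <- as.character(d[[subject]])
  for (w in within) d[[w]] <- factor(d[[w]])
  if (!is.null(between)) d[[between]] <- factor(d[[between]])

  if (length(within) == 0L) {
    return(.between_anova(d, dv, between, subject, covariates))
  }

  # wide response matrix: one row per subject, one column per within cell
  lev <- lapply(within, function(w) levels(d[[w]]))
  cells <- expand.grid(lev, stringsAsFactors = TRUE)
  names(cells) <- within
  cell_id <- interaction(lapply(within, function(w) d[[w]]), drop = FALSE,
                         lex.order = FALSE)
  cell_key <- interaction(cells, drop = FALSE, lex.order = FALSE)
  subjects <- unique(d[[subject]])
  Y <- matrix(NA_real_, length(subjects), nrow(cells),
              dimnames = list(subjects, as.character(cell_key)))
  cnt <- matrix(0L, length(subjects), nrow(cells))
  si <- match(d[[subject]], subjects)
  ci <- match(as.character(cell_id), as.character(cell_key))
  for (r in seq_len(nrow(d))) {
    if (is.na(d[[dv]][r])) next
    if (cnt[si[r], ci[r]] > 0L)
      stop("duplicate observation for subject ", d[[subject]][r],
           " in one within cell")
    Y[si[r], ci[r]] <- d[[dv]][r]
    cnt[si[r], ci[r]] <- 1L
  }
  complete <- stats::complete.cases(Y)
  if (any(!complete))
    message(sum(!complete), " subject(s) dropped (incomplete within cells)")
  Y <- Y[complete, , drop = FALSE]
  keep <- subjects[complete]

  bt <- d[!duplicated(d[[subject]]), c(subject, between, covariates),
          drop = FALSE]
  bt <- bt[match(keep, bt[[subject]]), , drop = FALSE]
  rhs <- "1"
  if (!is.null(between)) rhs <- between
  for (cv in covariates) {
    bt[[cv]] <- .covariate_numeric(bt[[cv]], cv)
    bt[[cv]] <- bt[[cv]] - mean(bt[[cv]])
    rhs <- paste(rhs, "+", cv)
  }
  opts <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(opts))
  mlm <- stats::lm(stats::as.formula(paste("Y ~", rhs)), data = bt)
  if (!is.null(between) && length(covariates) &&
      mlm$rank < length(mlm$coefficients) / max(1, ncol(Y)))
    warning("covariate collinear with the between-subject factor")
  idesign <- stats::as.formula(paste("~", paste(within, collapse = "*")))
  aov3 <- car::Anova(mlm, idata = cells, idesign = idesign, type = 3)
  s <- summary(aov3, multivariate = FALSE)
  ut <- s$univariate.tests
  eff <- rownames(ut)
  tab <- data.frame(effect = eff,
                    ss = ut[, "Sum Sq"], ss_error = ut[, "Error SS"],
                    df_num = ut[, "num Df"], df_den = ut[, "den Df"],
                    F = ut[, "F value"], p = ut[, "Pr(>F)"],
                    stringsAsFactors = FALSE, row.names = NULL)
  tab <- tab[tab$effect != "(Intercept)", , drop = FALSE]
  tab$partial_eta_sq <- ifelse(tab$ss + tab$ss_error > 0,
                               tab$ss / (tab$ss + tab$ss_error), 0)
  # degenerate (zero-variance) strata: define F = 0, p = 1
  degen <- tab$ss < 1e-12 & tab$ss_error < 1e-12
  tab$F[degen] <- 0; tab$p[degen] <- 1
  tab$gg_epsilon <- NA_real_
  within_rows <- grepl(paste(within, collapse = "|"), tab$effect)
  tab$gg_epsilon[within_rows] <- 1
  pa <- s$pval.adjustments
  if (!is.null(pa) && nrow(pa) > 0) {
    hit <- rownames(pa) %in% tab$effect & is.finite(pa[, "GG eps"])
    if (any(hit))
      tab$gg_epsilon[match(rownames(pa)[hit], tab$effect)] <- pa[hit, "GG eps"]
  }
  tab$df_num_gg <- tab$df_num * ifelse(is.na(tab$gg_epsilon), 1, tab$gg_epsilon)
  tab$df_den_gg <- tab$df_den * ifelse(is.na(tab$gg_epsilon), 1, tab$gg_epsilon)
  tab$p_gg <- ifelse(degen, 1,
                     stats::pf(tab$F, tab$df_num_gg, tab$df_den_gg,
                               lower.tail = FALSE))
  rownames(tab) <- NULL
  class(tab) <- c("anova_result", "data.frame")
  strata <- list(between = list(ss = unname(ut["(Intercept)", "Error SS"]),
                                df = unname(ut["(Intercept)", "den Df"])))
  for (w in rownames(ut)) {
    if (w %in% c("(Intercept)")) next
    strata[[w]] <- list(ss = unname(ut[w, "Error SS"]),
                        df = unname(ut[w, "den Df"]))
  }
  attr(tab, "strata") <- strata
  attr(tab, "design") <- list(dv = dv, within = within, between = between,
                              subject = subject, covariates = covariates)
  attr(tab, "n_subjects") <- nrow(Y)
  attr(tab, "data") <- d[d[[subject]] %in% keep, , drop = FALSE]
  tab
}

# between-subjects-only ANOVA/ANCOVA (Type III) on subject-level data
.between_anova <- function(d, dv, between, subject, covariates) {
  if (is.null(between)) stop("need a between factor or within factors")
  agg <- stats::aggregate(d[[dv]], by = list(d[[subject]]), FUN = mean)
  names(agg) <- c(subject, dv)
  bt <- d[!duplicated(d[[subject]]), c(subject, between, covariates),
          drop = FALSE]
  m <- merge(agg, bt, by = subject)
  rhs <- between
  for (cv in covariates) {
    m[[cv]] <- .covariate_numeric(m[[cv]], cv)
    m[[cv]] <- m[[cv]] - mean(m[[cv]])
    rhs <- paste(rhs, "+", cv)
  }
  opts <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(opts))
  fit <- stats::lm(stats::as.formula(paste(dv, "~", rhs)), data = m)
  a3 <- car::Anova(fit, type = 3)
  ss_err <- a3["Residuals", "Sum Sq"]
  df_err <- a3["Residuals", "Df"]
  eff <- setdiff(rownames(a3), c("(Intercept)", "Residuals"))
  tab <- data.frame(effect = eff, ss = a3[eff, "Sum Sq"], ss_error = ss_err,
                    df_num = a3[eff, "Df"], df_den = df_err,
                    F = a3[eff, "F value"], p = a3[eff, "Pr(>F)"],
                    stringsAsFactors = FALSE, row.names = NULL)
  tab$partial_eta_sq <- ifelse(tab$ss + tab$ss_error > 0,
                               tab$ss / (tab$ss + tab$ss_error), 0)
  degen <- tab$ss < 1e-12 & tab$ss_error < 1e-12
  tab$F[degen] <- 0; tab$p[degen] <- 1
  tab$gg_epsilon <- NA_real_
  tab$df_num_gg <- tab$df_num; tab$df_den_gg <- tab$df_den; tab$p_gg <- tab$p
  class(tab) <- c("anova_result", "data.frame")
  attr(tab, "strata") <- list(between = list(ss = ss_err, df = df_err))
  attr(tab, "design") <- list(dv = dv, within = NULL, between = between,
                              subject = subject, covariates = covariates)
  attr(tab, "n_subjects") <- nrow(m)
  attr(tab, "data") <- d
  tab
}

#' @export
print.anova_result <- function(x, ...) {
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) signif(v, 4))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Simple-effects analysis of an interaction
#'
#' Tests the other factor of a fitted two-way interaction within each level of
#' `slice_by`, with pairwise follow-up comparisons Holm-adjusted within each
#' slice. With `error = "omnibus"` (default) the error term comes from the
#' omnibus fit's strata: the pooled between + interaction stratum when the
#' sliced factor is between-subject, the interaction stratum when it is
#' within-subject. `error = "slice"` refits the error within each slice.
#'
#' @param anova An `"anova_result"` from [mixed_anova()] (it carries the data
#'   and strata).
#' @param effect Interaction name as it appears in the result, e.g.
#'   `"group:cue"` (order-insensitive).
#' @param slice_by Factor fixed at each of its levels.
#' @param error Error-term convention, `"omnibus"` or `"slice"`.
#' @return A list with `effects` (one F test per slice level) and `pairwise`
#'   (per-slice pairwise mean differences with raw and Holm-adjusted p).
#' @export
simple_effects <- function(anova, effect, slice_by,
                           error = c("omnibus", "slice")) {
  error <- match.arg(error)
  design <- attr(anova, "design")
  d <- attr(anova, "data")
  if (is.null(design) || is.null(d))
    stop("'anova' must come from mixed_anova()")
  parts <- strsplit(effect, ":", fixed = TRUE)[[1]]
  hit <- vapply(anova$effect, function(e) {
    setequal(strsplit(e, ":", fixed = TRUE)[[1]], parts)
  }, logical(1))
  if (!any(hit)) stop("effect '", effect, "' is not in the fitted design")
  if (!slice_by %in% parts) stop("'slice_by' must be part of the interaction")
  other <- setdiff(parts, slice_by)
  if (length(other) != 1L) stop("simple effects slice two-way interactions")
  strata <- attr(anova, "strata")
  within <- design$within
  between_test <- identical(other, design$between)
  # omnibus error term for the sliced test
  if (between_test) {
    wterm <- names(strata)[vapply(names(strata), function(nm)
      setequal(strsplit(nm, ":", fixed = TRUE)[[1]], parts), logical(1))]
    ssb <- strata$between$ss; dfb <- strata$between$df
    ssw <- if (length(wterm)) strata[[wterm]]$ss else 0
    dfw <- if (length(wterm)) strata[[wterm]]$df else 0
    ms_omni <- (ssb + ssw) / (dfb + dfw)
    df_omni <- dfb + dfw
  } else {
    wname <- names(strata)[vapply(names(strata), function(nm)
      setequal(strsplit(nm, ":", fixed = TRUE)[[1]],
               intersect(parts, within)), logical(1))]
    if (!length(wname)) wname <- other
    ms_omni <- strata[[wname]]$ss / strata[[wname]]$df
    df_omni <- strata[[wname]]$df
  }
  sub <- design$subject
  lev_slice <- levels(factor(d[[slice_by]]))
  eff_rows <- list(); pair_rows <- list()
  for (lv in lev_slice) {
    ds <- d[d[[slice_by]] == lv, , drop = FALSE]
    # one value per subject x level of the tested factor
    agg <- stats::aggregate(ds[[design$dv]],
                            by = list(ds[[sub]], ds[[other]]), FUN = mean)
    names(agg) <- c(sub, other, "dv")
    cm <- tapply(agg$dv, agg[[other]], mean)
    nn <- tapply(agg$dv, agg[[other]], length)
    grand <- mean(agg$dv)
    ss_eff <- sum(nn * (tapply(agg$dv, agg[[other]], mean) - grand)^2)
    df_eff <- length(cm) - 1L
    if (error == "slice") {
      if (between_test) {
        ss_err <- sum(tapply(agg$dv, agg[[other]],
                             function(v) sum((v - mean(v))^2)))
        df_err <- nrow(agg) - length(cm)
      } else {
        # within-subject one-way on the slice: subject x factor residual
        sm <- tapply(agg$dv, agg[[sub]], mean)
        resid <- agg$dv - cm[as.character(agg[[other]])] -
          sm[as.character(agg[[sub]])] + grand
        ss_err <- sum(resid^2)
        df_err <- (length(unique(agg[[sub]])) - 1L) * df_eff
      }
      mse <- ss_err / df_err
    } else {
      mse <- ms_omni; df_err <- df_omni
    }
    Fv <- if (mse == 0) { if (ss_eff == 0) 0 else Inf } else (ss_eff / df_eff) / mse
    eff_rows[[lv]] <- data.frame(
      slice = lv, effect = other, F = Fv, df_num = df_eff, df_den = df_err,
      p = stats::pf(Fv, df_eff, df_err, lower.tail = FALSE),
      stringsAsFactors = FALSE)
    lv_other <- names(cm)
    if (length(lv_other) >= 2L) {
      cmb <- utils::combn(lv_other, 2)
      pr <- apply(cmb, 2, function(ab) {
        diff <- unname(cm[ab[1]] - cm[ab[2]])
        se <- unname(sqrt(mse * (1 / nn[ab[1]] + 1 / nn[ab[2]])))
        tv <- if (se == 0) { if (diff == 0) 0 else Inf } else diff / se
        c(diff = diff, t = tv,
          p = 2 * stats::pt(abs(tv), df_err, lower.tail = FALSE))
      })
      pair_rows[[lv]] <- data.frame(
        slice = lv, level1 = cmb[1, ], level2 = cmb[2, ],
        difference = pr["diff", ], t = pr["t", ], df = df_err,
        p = pr["p", ], p_holm = holm_bonferroni(pr["p", ]),
        stringsAsFactors = FALSE)
    }
  }
  list(effects = do.call(rbind, c(eff_rows, list(make.row.names = FALSE))),
       pairwise = if (length(pair_rows))
         do.call(rbind, c(pair_rows, list(make.row.names = FALSE))) else NULL)
}

#' Correlate pre/post changes in scales with changes in microstate parameters
#'
#' For paired subjects observed at both times, computes the Pearson
#' correlation between each scale-score difference (after minus before) and
#' each microstate-parameter difference, per class, with two-sided p values
#' Holm-adjusted across all pairs.
#'
#' @param scales Long scale table: `subject_id`, `time`, and the columns in
#'   `scale_vars`.
#' @param params Long parameter table: `subject_id`, `time`, `class`,
#'   optionally `condition`, and the columns in `param_vars`.
#' @param times Length-2 character vector, `c(before, after)`.
#' @param scale_vars,param_vars Columns to correlate.
#' @param group,condition Optional filters (e.g. one treatment arm, the
#'   negative-cue condition).
#' @return Data frame: `scale`, `class`, `parameter`, `n`, `r`, `p`,
#'   `p_holm`.
#' @export
prepost_difference_correlation <- function(scales, params,
                                           times = c("before", "after"),
                                           scale_vars = c("HAMD", "PHQ9",
                                                          "NSSI_score"),
                                           param_vars = c("duration_ms",
                                                          "coverage",
                                                          "occurrence"),
                                           group = NULL, condition = NULL) {
  if (!is.null(group)) {
    scales <- scales[scales$group %in% group, , drop = FALSE]
    if ("group" %in% names(params))
      params <- params[params$group %in% group, , drop = FALSE]
  }
  if (!is.null(condition) && "condition" %in% names(params))
    params <- params[params$condition %in% condition, , drop = FALSE]
  dscale <- .paired_delta(scales, "subject_id", "time", times, scale_vars)
  rows <- list()
  for (cl in unique(params$class)) {
    pcl <- params[params$class == cl, , drop = FALSE]
    if ("condition" %in% names(pcl) && length(unique(pcl$condition)) > 1) {
      agg <- stats::aggregate(pcl[param_vars],
                              by = pcl[c("subject_id", "time")], FUN = mean)
      pcl <- agg
    }
    dpar <- .paired_delta(pcl, "subject_id", "time", times, param_vars)
    m <- merge(dscale, dpar, by = "subject_id")
    if (nrow(m) < 3L) stop("fewer than 3 paired subjects")
    for (sv in scale_vars) for (pv in param_vars) {
      x <- m[[paste0("d_", sv)]]; y <- m[[paste0("d_", pv)]]
      ok <- is.finite(x) & is.finite(y)
      rows[[length(rows) + 1L]] <- if (sum(ok) >= 3L) {
        ct <- stats::cor.test(x[ok], y[ok])
        data.frame(scale = sv, class = cl, parameter = pv, n = sum(ok),
                   r = unname(ct$estimate), p = ct$p.value,
                   stringsAsFactors = FALSE)
      } else {
        # a class unobserved for most subjects has no usable differences
        data.frame(scale = sv, class = cl, parameter = pv, n = sum(ok),
                   r = NA_real_, p = NA_real_, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  out$p_holm <- NA_real_
  ok <- !is.na(out$p)
  out$p_holm[ok] <- holm_bonferroni(out$p[ok])
  rownames(out) <- NULL
  out
}

# after-minus-before differences per subject for the named columns
.paired_delta <- function(d, id, time, times, vars) {
  b <- d[d[[time]] == times[1], c(id, vars), drop = FALSE]
  a <- d[d[[time]] == times[2], c(id, vars), drop = FALSE]
  m <- merge(b, a, by = id, suffixes = c("_before", "_after"))
  out <- m[, id, drop = FALSE]
  for (v in vars)
    out[[paste0("d_", v)]] <- m[[paste0(v, "_after")]] - m[[paste0(v, "_before")]]
  out
}
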