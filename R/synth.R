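# Synthetic microstate-structured ERP cohorts and clinical-scale tables.
#
# The generator plants a known map set, per-cell mean segment durations and a
# condition-level canonical class order shared by all subjects, so that
# trial- and subject-averaging preserve the topographic structure the
# segmentation stage must recover. Ground truth (label sequences and the
# parameters they imply) is returned alongside the data.

# run code under a temporary RNG state seeded with `seed` (NULL = use current)
.with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# zero channel-mean, unit-norm topography
.norm_map <- function(a) {
  a <- a - mean(a)
  n <- sqrt(sum(a^2))
  if (n == 0) stop("degenerate (constant) topography cannot be normalized")
  a / n
}

#' Generate prototype microstate topographies
#'
#' Draws `K` smooth dipolar scalp patterns: each map is the field of a randomly
#' placed and oriented point dipole inside the sensor sphere, centered and
#' normalized. Candidates too similar to an already accepted map (polarity-
#' invariant spatial correlation above `max_corr`) are rejected and redrawn, so
#' the returned set is well separated.
#'
#' @param layout An [sensor_layout()].
#' @param K Number of maps (1 to `n_channels - 1`).
#' @param seed Integer seed for reproducibility.
#' @param max_corr Maximum allowed pairwise polarity-invariant correlation.
#' @param max_tries Rejection-sampling cap per map.
#' @return A `channels x K` matrix of zero-mean, unit-norm topographies
#'   (columns named `MS1..MSK`, rows named by channel), with the layout
#'   attached as attribute `"layout"`.
#' @export
make_prototype_maps <- function(layout, K, seed = NULL, max_corr = 0.7,
                                max_tries = 1000L) {
  stopifnot(inherits(layout, "eeg_layout"))
  C <- layout$n_channels
  if (!is.numeric(K) || length(K) != 1L || K < 1 || K > C - 1)
    stop("'K' must be between 1 and n_channels - 1")
  K <- as.integer(K)
  pos <- layout$positions
  .with_seed(seed, {
    M <- matrix(0, C, K)
    for (k in seq_len(K)) {
      ok <- FALSE
      for (try in seq_len(max_tries)) {
        r0 <- stats::rnorm(3)
        r0 <- 0.6 * r0 / sqrt(sum(r0^2))      # dipole location inside the sphere
        q <- stats::rnorm(3)                  # dipole moment
        d <- sweep(pos, 2, r0)
        v <- as.vector(d %*% q) / rowSums(d^2)^1.5
        v <- .norm_map(v)
        if (k == 1L ||
            max(abs(crossprod(M[, seq_len(k - 1L), drop = FALSE], v))) <= max_corr) {
          M[, k] <- v
          ok <- TRUE
          break
        }
      }
      if (!ok) stop("could not place ", K, " maps below pairwise correlation ",
                    max_corr)
    }
    dimnames(M) <- list(layout$channel_names, paste0("MS", seq_len(K)))
    attr(M, "layout") <- layout
    M
  })
}

# draw one label sequence of n samples; `order` cycles a canonical class order,
# otherwise classes follow a uniform no-immediate-repeat walk
.draw_labels <- function(K, duration_means_ms, n, rate, gamma_shape = 4,
                         order = NULL) {
  if (any(duration_means_ms <= 0)) stop("duration means must be positive")
  lab <- integer(0)
  pos <- 0L
  cur <- if (is.null(order)) sample.int(K, 1L) else order[1L]
  i <- 1L
  while (length(lab) < n) {
    mean_samp <- duration_means_ms[cur] * rate / 1000
    len <- max(1L, as.integer(round(stats::rgamma(1, shape = gamma_shape,
                                                  rate = gamma_shape / mean_samp))))
    lab <- c(lab, rep.int(cur, len))
    i <- i + 1L
    cur <- if (is.null(order)) {
      cand <- seq_len(K)[-cur]
      if (length(cand) == 0L) cur else cand[sample.int(length(cand), 1L)]
    } else order[(i - 1L) %% length(order) + 1L]
  }
  lab[seq_len(n)]
}

# visit-balanced label sequence: whole cycles of fresh random permutations,
# gamma segment lengths rescaled to fill exactly n samples. Every class is
# visited the same number of times, so planted coverage tracks the duration
# targets without visit-count or truncation noise.
.draw_labels_balanced <- function(K, duration_means_ms, n, rate,
                                  gamma_shape = 4) {
  if (any(duration_means_ms <= 0)) stop("duration means must be positive")
  mean_samp <- duration_means_ms * rate / 1000
  cycles <- max(1L, as.integer(round(n / sum(mean_samp))))
  cls <- integer(0)
  for (i in seq_len(cycles)) {
    p <- sample.int(K)
    # avoid an immediate repeat at the cycle boundary
    if (length(cls) && K > 1L && p[1L] == cls[length(cls)])
      p <- c(p[2L], p[1L], p[-(1:2)])
    cls <- c(cls, p)
  }
  len <- stats::rgamma(length(cls), shape = gamma_shape,
                       rate = gamma_shape / mean_samp[cls])
  len <- len / sum(len) * n
  seg <- pmax(1L, floor(len))
  frac <- len - floor(len)
  while (sum(seg) < n) {                     # largest-remainder top-up
    i <- which.max(frac)
    seg[i] <- seg[i] + 1L
    frac[i] <- -Inf
  }
  while (sum(seg) > n) {                     # shrink the most over-rounded
    cand <- which(seg > 1L)
    i <- cand[which.min(frac[cand])]
    seg[i] <- seg[i] - 1L
    frac[i] <- Inf
  }
  rep.int(cls, seg)
}

# half-sine GFP envelope over the runs of a label sequence
.segment_envelope <- function(labels) {
  r <- rle(labels)
  env <- numeric(length(labels))
  idx <- 1L
  for (j in seq_along(r$lengths)) {
    L <- r$lengths[j]
    env[idx:(idx + L - 1L)] <- sin(pi * (seq_len(L) - 0.5) / L)
    idx <- idx + L
  }
  env
}

.mean_gfp <- function(V) {
  mean(sqrt(colMeans(sweep(V, 2, colMeans(V))^2)))
}

#' Simulate one microstate-structured epoch
#'
#' Builds an epoch as a concatenation of microstate segments: segment lengths
#' are gamma-distributed (shape `gamma_shape`) around the requested per-class
#' mean durations, each segment is its class topography scaled by a smooth
#' half-sine global-field-power envelope, and spatially/temporally white noise
#' is added at the requested signal-to-noise ratio (mean signal GFP over mean
#' noise GFP). All trials of one call share the same signal (label sequence and
#' envelope) and differ only in noise, emulating stimulus-locked trials.
#'
#' @param maps `channels x K` prototype matrix (see [make_prototype_maps()]).
#' @param duration_means_ms Positive per-class mean segment durations (ms).
#' @param epoch_window Epoch limits in ms, `c(start, end)`; samples lie on the
#'   half-open grid `[start, end)`.
#' @param rate Sampling rate (Hz).
#' @param snr Signal-to-noise ratio; `Inf` disables noise.
#' @param n_trials Number of noisy realizations sharing the signal.
#' @param seed Integer seed.
#' @param labels Optional pre-specified label sequence (overrides the random
#'   draw; length must match the window).
#' @param order Optional canonical class order cycled to build the sequence.
#' @param gamma_shape Shape of the segment-length gamma law.
#' @param layout Layout for the returned object (default: taken from `maps`).
#' @param subject_id,condition Identifiers stamped on the result.
#' @return A list with `epochs` (an [eeg_epochs()]) and `labels` (integer
#'   per-sample class sequence of the generating signal).
#' @export
simulate_epoch <- function(maps, duration_means_ms,
                           epoch_window = c(-200, 1000), rate = 500,
                           snr = Inf, n_trials = 1L, seed = NULL,
                           labels = NULL, order = NULL, gamma_shape = 4,
                           layout = attr(maps, "layout"),
                           subject_id = NA_character_,
                           condition = NA_character_) {
  if (!is.numeric(rate) || rate <= 0) stop("'rate' must be positive")
  if (!is.numeric(snr) || snr < 0) stop("'snr' must be nonnegative")
  C <- nrow(maps); K <- ncol(maps)
  if (length(duration_means_ms) == 1L)
    duration_means_ms <- rep(duration_means_ms, K)
  if (length(duration_means_ms) != K)
    stop("'duration_means_ms' must have one entry per class")
  if (any(duration_means_ms <= 0)) stop("duration means must be positive")
  n <- as.integer(round((epoch_window[2] - epoch_window[1]) * rate / 1000))
  if (n < 1L) stop("'epoch_window' is empty")
  times <- epoch_window[1] + (seq_len(n) - 1L) * 1000 / rate
  .with_seed(seed, {
    if (is.null(labels))
      labels <- .draw_labels(K, duration_means_ms, n, rate, gamma_shape, order)
    else if (length(labels) != n)
      stop("'labels' length must match the epoch window")
    env <- .segment_envelope(labels)
    # unit-norm zero-mean map scaled by sqrt(C) has GFP 1, so GFP(t) = env(t)
    S <- maps[, labels, drop = FALSE] * rep(env, each = C) * sqrt(C)
    sig_gfp <- .mean_gfp(S)
    dat <- array(0, dim = c(n_trials, C, n))
    for (tr in seq_len(n_trials)) {
      X <- S
      if (is.finite(snr)) {
        N <- matrix(stats::rnorm(C * n), C, n)
        if (snr == 0) X <- N else X <- S + N * sig_gfp / (snr * .mean_gfp(N))
      }
      dat[tr, , ] <- X
    }
    if (is.null(layout))
      stop("no layout available; pass 'layout' or use maps from make_prototype_maps()")
    list(epochs = eeg_epochs(dat, rate = rate, times = times, layout = layout,
                             subject_id = subject_id, condition = condition),
         labels = labels)
  })
}

#' Cohort design for simulation
#'
#' Describes a simulated study: between-subject groups (clinical groups or
#' treatment arms) with sizes, within-subject cue conditions with trial counts,
#' optional repeated measurement times, epoch grid, SNR and the planted
#' per-cell mean segment durations.
#'
#' @param groups Named integer vector of group sizes.
#' @param conditions Named integer vector of trial counts per cue condition.
#' @param times Optional character vector of measurement times (e.g.
#'   `c("before", "after")`).
#' @param rate Sampling rate (Hz).
#' @param epoch_window Epoch limits in ms.
#' @param K Number of microstate classes to plant.
#' @param snr Signal-to-noise ratio of simulated trials.
#' @param subject_sd SD of the log-normal subject-level multiplier applied to
#'   cell duration targets (between-subject variability).
#' @param duration_targets Data frame with columns `group`, `condition`,
#'   optionally `time`, `class` (1..K) and `duration_ms`; defaults to built-in
#'   targets emulating the reference study's magnitudes (long class 3,
#'   shortened class 6 in the patient-with-self-injury group, amplified under
#'   negative cues).
#' @param gamma_shape Segment-length gamma shape.
#' @param jitter_ms SD of a per-trial latency jitter (ms); default 0.
#' @param layout Sensor layout (default [layout_1020()]).
#' @return An object of class `"cohort_design"`.
#' @export
cohort_design <- function(groups = c(HC = 20, MDD = 52, "MDD+NSSI" = 66),
                          conditions = c(neutral = 150, negative = 50),
                          times = NULL, rate = 500,
                          epoch_window = c(-200, 1000), K = 6, snr = 5,
                          subject_sd = 0.25, duration_targets = NULL,
                          gamma_shape = 4, jitter_ms = 0,
                          layout = layout_1020()) {
  if (is.null(names(groups)) || is.null(names(conditions)))
    stop("'groups' and 'conditions' must be named")
  if (any(groups < 1) || any(conditions < 1))
    stop("all group sizes and trial counts must be >= 1")
  if (!(epoch_window[1] < 0 && 0 < epoch_window[2]))
    stop("'epoch_window' must straddle stimulus onset (start < 0 < end)")
  if (rate <= 0) stop("'rate' must be positive")
  if (snr < 0) stop("'snr' must be nonnegative")
  if (is.null(duration_targets))
    duration_targets <- default_duration_targets(names(groups),
                                                 names(conditions), times, K)
  need <- c("group", "condition", "class", "duration_ms")
  if (!all(need %in% names(duration_targets)))
    stop("'duration_targets' needs columns ", paste(need, collapse = ", "))
  if (any(duration_targets$duration_ms <= 0))
    stop("planted durations must be positive")
  structure(
    list(groups = groups, conditions = conditions, times = times, rate = rate,
         epoch_window = epoch_window, K = as.integer(K), snr = snr,
         subject_sd = subject_sd, duration_targets = duration_targets,
         gamma_shape = gamma_shape, jitter_ms = jitter_ms, layout = layout),
    class = "cohort_design")
}

#' @export
print.cohort_design <- function(x, ...) {
  cat("<cohort_design> groups:",
      paste(sprintf("%s=%d", names(x$groups), x$groups), collapse = ", "),
      "| conditions:",
      paste(sprintf("%s=%d", names(x$conditions), x$conditions), collapse = ", "),
      if (!is.null(x$times)) paste("| times:", paste(x$times, collapse = "/")),
      sprintf("| K=%d snr=%g %g Hz [%g,%g) ms\n", x$K, x$snr, x$rate,
              x$epoch_window[1], x$epoch_window[2]))
  invisible(x)
}

#' Default planted duration targets
#'
#' Per-cell mean segment durations (ms) for up to 6 classes, emulating the
#' magnitudes and group/cue directionality of the reference cross-sectional
#' cohort: class 3 dwell time elevated in the two patient groups and further
#' under negative cues, class 6 shortened in the patient-with-self-injury
#' group, class 4 brief throughout. Unknown group/condition/time labels fall
#' back to the first row of built-in values.
#'
#' @param groups,conditions Character vectors of cell labels.
#' @param times Optional character vector of time labels.
#' @param K Number of classes (defaults built in for K <= 6; larger K recycles).
#' @return Data frame with columns `group`, `condition`, optionally `time`,
#'   `class`, `duration_ms`.
#' @export
default_duration_targets <- function(groups, conditions, times = NULL, K = 6) {
  base <- rbind(
    "HC.neutral"       = c(110, 120, 155, 60, 100, 102),
    "HC.negative"      = c(110, 120, 152, 62, 100, 137),
    "MDD.neutral"      = c(105, 115, 191, 62,  95,  97),
    "MDD.negative"     = c(105, 112, 213, 55,  95,  96),
    "MDD+NSSI.neutral" = c(100, 110, 205, 68,  90,  75),
    "MDD+NSSI.negative"= c( 98, 108, 224, 66,  90,  86))
  dur <- rep_len(colMeans(base), K)
  cells <- expand.grid(class = seq_len(K), condition = conditions,
                       group = groups, stringsAsFactors = FALSE)
  if (!is.null(times))
    cells <- merge(cells, data.frame(time = times), by = NULL)
  cells$duration_ms <- dur[cells$class]
  ri <- match(paste(cells$group, cells$condition, sep = "."), rownames(base))
  hit <- !is.na(ri)
  cells$duration_ms[hit] <- base[cbind(ri[hit], cells$class[hit])]
  cells[, c("group", "condition", if (!is.null(times)) "time", "class",
            "duration_ms"), drop = FALSE]
}

# look up the K duration targets for one cell
.cell_targets <- function(design, group, condition, time = NULL) {
  t <- design$duration_targets
  sel <- t$group == group & t$condition == condition
  if (!is.null(time) && "time" %in% names(t)) sel <- sel & t$time == time
  t <- t[sel, ]
  if (nrow(t) != design$K)
    stop("duration targets for cell ", group, "/", condition,
         if (!is.null(time)) paste0("/", time), " do not cover all classes")
  t$duration_ms[order(t$class)]
}

#' Simulate a full ERP cohort with ground truth
#'
#' Generates the designed number of subjects per group; every subject x
#' condition (x time) cell receives one planted label sequence — built by
#' cycling a subject-specific random permutation of the classes with gamma
#' segment lengths, so every class is visited evenly — and the designed number
#' of noisy trials sharing that signal. Subject-level variability enters as a
#' log-normal multiplier on the cell duration targets, drawn once per subject
#' and reused across times so that repeated measures are paired; the recorded
#' targets are these subject-level values.
#'
#' @param design A [cohort_design()].
#' @param seed Integer seed; the run is fully reproducible given it.
#' @param labels_only If `TRUE`, skip EEG generation and return ground truth
#'   only (fast; usable at full study scale).
#' @return A list with `epochs` (nested list `[[subject]][[cell]]` of
#'   [eeg_epochs()], `NULL` when `labels_only`), and `ground_truth`: a list
#'   with the planted `mapset`, `labels` (list keyed like `epochs`), a
#'   `params` data frame (per subject x cell x class planted duration,
#'   coverage and occurrence computed from the label sequence, plus the cell
#'   `target_duration_ms` and `target_coverage`), `subjects` (data frame of
#'   ids and groups), `snr` and `seed`.
#' @export
simulate_cohort <- function(design, seed = NULL, labels_only = FALSE) {
  stopifnot(inherits(design, "cohort_design"))
  .with_seed(seed, {
    K <- design$K
    layout <- design$layout
    maps <- make_prototype_maps(layout, K,
                                seed = sample.int(.Machine$integer.max, 1))
    n_samp <- as.integer(round(diff(design$epoch_window) * design$rate / 1000))
    epoch_s <- n_samp / design$rate
    conds <- names(design$conditions)
    times <- if (is.null(design$times)) NA_character_ else design$times
    subjects <- data.frame(
      subject_id = sprintf("S%03d", seq_len(sum(design$groups))),
      group = rep(names(design$groups), design$groups),
      stringsAsFactors = FALSE)
    epochs <- if (labels_only) NULL else list()
    labels <- list()
    rows <- list()
    for (si in seq_len(nrow(subjects))) {
      sid <- subjects$subject_id[si]
      grp <- subjects$group[si]
      mult <- exp(stats::rnorm(K, 0, design$subject_sd))  # persists across cells
      if (!labels_only) epochs[[sid]] <- list()
      labels[[sid]] <- list()
      for (tm in times) {
        for (cc in conds) {
          cell <- if (is.na(tm)) cc else paste(tm, cc, sep = ".")
          tgt <- .cell_targets(design, grp, cc, if (is.na(tm)) NULL else tm)
          subj_dur <- tgt * mult
          lab <- .draw_labels_balanced(K, subj_dur, n_samp, design$rate,
                                       design$gamma_shape)
          labels[[sid]][[cell]] <- lab
          if (!labels_only) {
            sim <- simulate_epoch(
              maps, subj_dur, epoch_window = design$epoch_window,
              rate = design$rate, snr = design$snr,
              n_trials = design$conditions[[cc]], labels = lab,
              layout = layout, subject_id = sid, condition = cell)
            if (design$jitter_ms > 0) {
              d <- sim$epochs$data
              for (tr in seq_len(dim(d)[1])) {
                sh <- as.integer(round(stats::rnorm(1, 0, design$jitter_ms) *
                                         design$rate / 1000))
                if (sh != 0) {
                  idx <- pmin(pmax(seq_len(n_samp) - sh, 1L), n_samp)
                  d[tr, , ] <- d[tr, , idx]
                }
              }
              sim$epochs$data <- d
            }
            epochs[[sid]][[cell]] <- sim$epochs
          }
          r <- rle(lab)
          cnt <- tabulate(lab, K)
          nseg <- tabulate(r$values, K)
          rows[[length(rows) + 1L]] <- data.frame(
            subject_id = sid, group = grp, time = tm, condition = cc,
            class = seq_len(K),
            target_duration_ms = subj_dur,
            target_coverage = subj_dur / sum(subj_dur),
            planted_duration_ms = ifelse(nseg > 0,
                                         cnt / pmax(nseg, 1L) * 1000 / design$rate,
                                         NA_real_),
            planted_coverage = cnt / n_samp,
            planted_occurrence = nseg / epoch_s,
            stringsAsFactors = FALSE)
        }
      }
    }
    params <- do.call(rbind, rows)
    rownames(params) <- NULL
    if (is.null(design$times)) params$time <- NULL
    list(epochs = epochs,
         ground_truth = list(mapset = maps, labels = labels, params = params,
                             subjects = subjects, snr = design$snr,
                             seed = seed))
  })
}

# instrument ranges for clinical scales
.scale_ranges <- list(HAMD = c(0, 52), PHQ9 = c(0, 27), NSSI = c(0, Inf),
                      age = c(12, 17))

# truncated-normal sampler via inverse CDF (exact, vectorized)
.rtruncnorm <- function(n, mean, sd, lo, hi) {
  if (sd < 0) stop("'sd' must be nonnegative")
  if (sd == 0) return(rep(mean, n))
  p <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(p, mean, sd)
}

#' Default clinical-scale targets
#'
#' `scale_targets_cross()` gives per-group baseline means/SDs for age, male
#' proportion, depression scales and self-injury count, emulating the
#' reference study's demographic table (healthy controls near-zero on the
#' depression scales, two elevated patient groups). `scale_targets_long()`
#' gives pre/post means/SDs per treatment arm for HAMD, PHQ-9 and the
#' self-injury score, with a larger drop in the combined-treatment arm.
#'
#' @return A data frame with columns `group`, optionally `time`, `variable`,
#'   `mean`, `sd`.
#' @export
scale_targets_cross <- function() {
  tab <- rbind(
    data.frame(group = "HC",       variable = c("age", "HAMD", "PHQ9", "NSSI", "sex_male"),
               mean = c(15.45, 1.30, 1.50, 0, 8 / 20),  sd = c(2.282, 1.809, 2.115, 0, NA)),
    data.frame(group = "MDD",      variable = c("age", "HAMD", "PHQ9", "NSSI", "sex_male"),
               mean = c(15.31, 22.62, 19.60, 0, 20 / 52), sd = c(1.449, 3.448, 3.610, 0, NA)),
    data.frame(group = "MDD+NSSI", variable = c("age", "HAMD", "PHQ9", "NSSI", "sex_male"),
               mean = c(14.33, 23.14, 20.14, 10.26, 12 / 66),
               sd = c(1.601, 4.220, 3.586, 3.763, NA)))
  rownames(tab) <- NULL
  tab
}

#' @rdname scale_targets_cross
#' @export
scale_targets_long <- function() {
  g1 <- "medication"; g2 <- "medication+rTMS"
  tab <- rbind(
    data.frame(group = g1, time = "before", variable = c("HAMD", "PHQ9", "NSSI"),
               mean = c(23.612, 20.290, 2.065), sd = c(4.248, 3.175, 0.250)),
    data.frame(group = g1, time = "after",  variable = c("HAMD", "PHQ9", "NSSI"),
               mean = c(12.936, 11.968, 0.871), sd = c(3.829, 4.167, 0.718)),
    data.frame(group = g2, time = "before", variable = c("HAMD", "PHQ9", "NSSI"),
               mean = c(23.000, 19.905, 2.143), sd = c(4.336, 3.780, 0.359)),
    data.frame(group = g2, time = "after",  variable = c("HAMD", "PHQ9", "NSSI"),
               mean = c(8.381, 7.667, 0.238), sd = c(5.084, 5.713, 0.539)),
    data.frame(group = c(g1, g2), time = "baseline", variable = "age",
               mean = c(14.3, 14.3), sd = c(1.6, 1.6)),
    data.frame(group = c(g1, g2), time = "baseline", variable = "sex_male",
               mean = c(12 / 66, 12 / 66), sd = c(NA, NA)))
  rownames(tab) <- NULL
  tab
}

#' Simulate clinical-scale records
#'
#' Draws subject-level scale scores from truncated normal distributions at the
#' requested cell means and SDs (truncation at the instrument ranges: HAMD
#' 0-52, PHQ-9 0-27, self-injury score >= 0, age 12-17). Sex is Bernoulli at
#' the cell's male proportion. For longitudinal targets (with a `time`
#' column), subjects get one age/sex draw and correlated pre/post scores
#' (shared subject rank within the cell distribution, so paired analyses see
#' realistic within-subject correlation).
#'
#' @param design A [cohort_design()]; group names and sizes must match the
#'   `group` column of `targets`.
#' @param targets Data frame as returned by [scale_targets_cross()] /
#'   [scale_targets_long()] (default chosen by whether the design has times).
#' @param seed Integer seed.
#' @param subject_rho Correlation of a subject's scores across repeated times.
#' @return A data frame of scale records: `subject_id`, `group`, `time`,
#'   `age`, `sex` ("male"/"female"), `HAMD`, `PHQ9`, `NSSI_score`.
#' @export
simulate_scales <- function(design, targets = NULL, seed = NULL,
                            subject_rho = 0.5) {
  stopifnot(inherits(design, "cohort_design"))
  if (is.null(targets))
    targets <- if (is.null(design$times)) scale_targets_cross()
               else scale_targets_long()
  for (v in intersect(unique(targets$variable), names(.scale_ranges))) {
    rng <- .scale_ranges[[v]]
    m <- targets$mean[targets$variable == v]
    if (any(m < rng[1] | m > rng[2]))
      stop("target mean for ", v, " outside the instrument range [",
           rng[1], ", ", rng[2], "]")
  }
  if (any(stats::na.omit(targets$sd) < 0)) stop("'sd' targets must be >= 0")
  .with_seed(seed, {
    times <- if (is.null(design$times)) "baseline" else design$times
    has_time <- "time" %in% names(targets)
    getcell <- function(grp, var, tm) {
      sel <- targets$group == grp & targets$variable == var
      if (has_time) {
        s2 <- sel & targets$time == tm
        if (!any(s2)) s2 <- sel & targets$time == "baseline"
        sel <- s2
      }
      if (!any(sel)) return(NULL)
      targets[which(sel)[1L], c("mean", "sd")]
    }
    recs <- list()
    sid0 <- 0L
    for (gi in seq_along(design$groups)) {
      grp <- names(design$groups)[gi]
      n <- design$groups[[gi]]
      ids <- sprintf("S%03d", sid0 + seq_len(n)); sid0 <- sid0 + n
      agec <- getcell(grp, "age", "baseline")
      age <- if (is.null(agec)) .rtruncnorm(n, 14.5, 1.5, 12, 17)
             else .rtruncnorm(n, agec$mean, agec$sd, 12, 17)
      sexc <- getcell(grp, "sex_male", "baseline")
      pmale <- if (is.null(sexc)) 0.4 else sexc$mean
      sex <- ifelse(stats::runif(n) < pmale, "male", "female")
      # latent subject quantile shared across times (within-subject pairing)
      zsub <- stats::rnorm(n)
      for (tm in times) {
        row <- data.frame(subject_id = ids, group = grp, time = tm,
                          age = age, sex = sex, stringsAsFactors = FALSE)
        for (v in c("HAMD", "PHQ9", "NSSI")) {
          cell <- getcell(grp, v, tm)
          if (is.null(cell)) { row[[v]] <- 0; next }
          rng <- .scale_ranges[[v]]
          if (cell$sd == 0) { row[[v]] <- rep(cell$mean, n); next }
          z <- subject_rho * zsub + sqrt(1 - subject_rho^2) * stats::rnorm(n)
          p <- stats::pnorm(z)
          plo <- stats::pnorm(rng[1], cell$mean, cell$sd)
          phi <- stats::pnorm(rng[2], cell$mean, cell$sd)
          row[[v]] <- stats::qnorm(plo + p * (phi - plo), cell$mean, cell$sd)
        }
        names(row)[names(row) == "NSSI"] <- "NSSI_score"
        recs[[length(recs) + 1L]] <- row
      }
    }
    out <- do.call(rbind, recs)
    rownames(out) <- NULL
    out
  })
}
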