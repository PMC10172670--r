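# Orchestration: full study replicas on synthetic data, cross-sectional
# (3 groups x 2 cues) and longitudinal (2 arms x 2 times x 2 cues), with
# reproducible seed fan-out and delimited outputs carrying a config hash.

# deterministic child seeds from one master seed
.child_seeds <- function(seed, n) {
  .with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# md5 of the canonical JSON serialization of a config list
.config_hash <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  keep <- config[order(names(config))]
  keep$out_dir <- NULL              # hash the analysis, not where it lands
  keep <- keep[!vapply(keep, is.function, logical(1))]
  jsonlite::write_json(keep, tf, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(tf))
}

.write_table <- function(d, path, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# config ", hash), con)
  utils::write.table(d, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Pipeline run configuration
#'
#' Collects all settings of a study replica. Defaults are a scaled-down
#' version of the reference design (10/12/15 subjects across the three
#' clinical groups, 30 trials per cue) that runs on one CPU in minutes;
#' `paper_scale = TRUE` switches to the full 138-subject cohort (memory- and
#' time-hungry: intended for offline runs). rTMS protocol constants (10 Hz
#' left-DLPFC, 5 s trains, 15 s intervals) are carried as metadata only; no
#' stimulation is simulated.
#'
#' @param groups Named group sizes for the cross-sectional arm of the study.
#' @param conditions Named trial counts per cue.
#' @param arms Named treatment-arm sizes for the longitudinal arm.
#' @param times Measurement times for the longitudinal arm.
#' @param rate Sampling rate (Hz) of the analysis.
#' @param band Band-pass edges (Hz).
#' @param epoch_window,baseline_window Epoch and baseline limits (ms).
#' @param ptp_limit Artifact peak-to-peak rejection limit (µV).
#' @param K Number of microstate classes fitted when `k_range` is `NULL`.
#' @param k_range Optional candidate range for CV-based selection of K.
#' @param iterations,restarts Modified k-means settings.
#' @param smooth_ms Minimum segment duration (0 disables smoothing).
#' @param occurrence Occurrence denominator convention.
#' @param snr Simulated signal-to-noise ratio.
#' @param covariates Covariate columns for the cross-sectional ANOVAs.
#' @param alpha Significance level used to trigger simple-effects follow-ups.
#' @param seed Master seed; every stage derives a child seed from it.
#' @param out_dir Optional output directory for delimited tables.
#' @param paper_scale Use the full published sample sizes and trial counts.
#' @return A list of class `"run_config"`.
#' @export
run_config <- function(groups = c(HC = 10, MDD = 12, "MDD+NSSI" = 15),
                       conditions = c(neutral = 30, negative = 30),
                       arms = c(medication = 8, "medication+rTMS" = 7),
                       times = c("before", "after"),
                       rate = 500, band = c(0.1, 30),
                       epoch_window = c(-200, 1000),
                       baseline_window = c(-200, 0), ptp_limit = 100,
                       K = 6, k_range = NULL, iterations = 1000L,
                       restarts = 20L, smooth_ms = 0,
                       occurrence = "epoch", snr = 5,
                       covariates = c("age", "sex"), alpha = 0.05,
                       seed = 1L, out_dir = NULL, paper_scale = FALSE) {
  if (paper_scale) {
    groups <- c(HC = 20, MDD = 52, "MDD+NSSI" = 66)
    conditions <- c(neutral = 150, negative = 50)
    arms <- c(medication = 31, "medication+rTMS" = 21)
  }
  cfg <- list(groups = groups, conditions = conditions, arms = arms,
              times = times, rate = rate, band = band,
              epoch_window = epoch_window, baseline_window = baseline_window,
              ptp_limit = ptp_limit, K = K, k_range = k_range,
              iterations = iterations, restarts = restarts,
              smooth_ms = smooth_ms, occurrence = occurrence, snr = snr,
              covariates = covariates, alpha = alpha, seed = seed,
              out_dir = out_dir, paper_scale = paper_scale,
              rtms_protocol = list(target = "left DLPFC (F3)",
                                   frequency_hz = 10, train_s = 5,
                                   interval_s = 15, sessions = "5/week x 4 weeks"))
  class(cfg) <- "run_config"
  cfg
}

# preprocess one cell's epochs into an averaged, filtered, referenced ERP.
# Filtering and epoching are linear, so they are applied after trial
# averaging: identical result (linearity), a fraction of the cost.
.preprocess_cell <- function(ep, config) {
  ep <- resample(ep, config$rate)
  rej <- reject_artifacts(ep, config$ptp_limit)
  erp <- average_erp(rej$epochs)
  erp <- bandpass(erp, config$band[1], config$band[2])
  erp <- epoch_and_baseline(erp, config$epoch_window, config$baseline_window)
  average_reference(erp)
}

# fit the shared template per config (fixed K or CV selection) on the
# sample-wise concatenation of all subject x cell ERPs; stacking preserves
# every subject's topographies, so one common template serves all cells and
# class indices stay comparable across groups, cues and times
.fit_template <- function(erps, config, seed) {
  stacked <- unlist(erps, recursive = FALSE)
  if (!is.null(config$k_range)) {
    sel <- select_n_maps(stacked, config$k_range,
                         iterations = config$iterations,
                         restarts = config$restarts, seed = seed)
    list(fit = sel$fits[[match(sel$K_opt, sel$table$K)]], selection = sel)
  } else {
    list(fit = microstates(stacked, config$K, iterations = config$iterations,
                           restarts = config$restarts, seed = seed),
         selection = NULL)
  }
}

# Table-2/4-style wide effect table from per-dv mixed ANOVAs
.effect_table <- function(params, dvs, within, between, subject, covariates) {
  rows <- list(); fits <- list()
  for (cl in unique(params$class)) {
    for (dv in dvs) {
      d <- params[params$class == cl, , drop = FALSE]
      a <- mixed_anova(d, dv, within = within, between = between,
                      subject = subject, covariates = covariates)
      fits[[paste(cl, dv, sep = ".")]] <- a
      r <- data.frame(class = cl, parameter = dv, stringsAsFactors = FALSE)
      for (i in seq_len(nrow(a))) {
        nm <- gsub(":", "_x_", a$effect[i])
        r[[paste0(nm, "_F")]] <- a$F[i]
        r[[paste0(nm, "_p")]] <- a$p_gg[i]
        r[[paste0(nm, "_pes")]] <- a$partial_eta_sq[i]
      }
      rows[[length(rows) + 1L]] <- r
    }
  }
  list(table = do.call(rbind, rows), fits = fits)
}

#' Run the cross-sectional study replica
#'
#' Simulate a three-group cohort and its clinical scales, preprocess trials
#' into per-subject cue-condition ERPs, fit one shared microstate template on
#' the stacked subject ERPs, backfit per subject x cue, extract the four microstate
#' parameters, and run the 2 (cue) x 3 (group) mixed ANOVAs with age/sex
#' covariates plus the demographics table (one-way ANOVAs reconstructed from
#' group summaries, chi-square on sex counts).
#'
#' @param config A [run_config()].
#' @return A list (the "bundle"): `params` (long parameter table), `effects`
#'   (wide Table-2-style effect table), `anovas` (named list of full
#'   [mixed_anova()] results), `simple_effects` (follow-ups for interactions
#'   below `alpha`), `demographics`, `scales`, `fit` (the shared `"msfit"`),
#'   `selection` (if a K range was given), `ground_truth`, `manifest`.
#'   Tables are also written under `config$out_dir` when set.
#' @export
run_cross_sectional <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  seeds <- .child_seeds(config$seed, 4L)
  hash <- .config_hash(config)
  design <- cohort_design(groups = config$groups,
                          conditions = config$conditions,
                          rate = config$rate,
                          epoch_window = config$epoch_window, K = config$K,
                          snr = config$snr)
  sim <- simulate_cohort(design, seed = seeds[1])
  scales <- simulate_scales(design, seed = seeds[2])
  erps <- lapply(sim$epochs, function(s) lapply(s, .preprocess_cell,
                                                config = config))
  tmpl <- .fit_template(erps, config, seeds[3])
  params <- group_parameter_table(erps, tmpl$fit$maps,
                                  groups = sim$ground_truth$subjects,
                                  smooth_ms = config$smooth_ms,
                                  occurrence = config$occurrence)
  params <- merge(params,
                  scales[, c("subject_id", "age", "sex", "HAMD", "PHQ9")],
                  by = "subject_id", sort = FALSE)
  params <- params[order(params$subject_id, params$condition, params$class), ]
  rownames(params) <- NULL
  et <- .effect_table(params, c("duration_ms", "coverage", "occurrence", "gev"),
                      within = "condition", between = "group",
                      subject = "subject_id", covariates = config$covariates)
  se <- .auto_simple_effects(et$fits, "condition:group", "condition",
                             config$alpha)
  demo <- .demographics_table(scales)
  manifest <- list(stage = "cross_sectional", config_hash = hash,
                   seed = config$seed, child_seeds = seeds,
                   n_subjects = nrow(sim$ground_truth$subjects),
                   K = tmpl$fit$K, gev = tmpl$fit$gev,
                   package_version = as.character(utils::packageVersion("taskstates")))
  bundle <- list(params = params, effects = et$table, anovas = et$fits,
                 simple_effects = se, demographics = demo, scales = scales,
                 fit = tmpl$fit, selection = tmpl$selection,
                 ground_truth = sim$ground_truth, manifest = manifest)
  .write_bundle(bundle, config, hash)
  bundle
}

#' Run the longitudinal (treatment) study replica
#'
#' Simulate the self-injury cohort split into two treatment arms with paired
#' pre/post recordings and scales (arm-specific planted shifts: both arms
#' normalize classes 3 and 6 after treatment, the combined medication + rTMS
#' arm additionally shifts classes 1, 2 and 4 and shows the larger scale
#' improvement), then run the 2 (time) x 2 (arm) scale ANOVAs, the 2 (cue) x
#' 2 (time) x 2 (arm) microstate ANOVAs, simple effects for interactions
#' below `alpha`, and the pre/post difference correlations.
#'
#' @param config A [run_config()]; `arms` and `times` define the design.
#' @return A bundle like [run_cross_sectional()]'s, plus `scale_effects` and
#'   `correlations`.
#' @export
run_longitudinal <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  seeds <- .child_seeds(config$seed + 1L, 4L)
  hash <- .config_hash(config)
  targets <- longitudinal_duration_targets(names(config$arms),
                                           names(config$conditions),
                                           config$times, config$K)
  design <- cohort_design(groups = config$arms,
                          conditions = config$conditions,
                          times = config$times, rate = config$rate,
                          epoch_window = config$epoch_window, K = config$K,
                          snr = config$snr, duration_targets = targets)
  sim <- simulate_cohort(design, seed = seeds[1])
  scales <- simulate_scales(design, seed = seeds[2])
  erps <- lapply(sim$epochs, function(s) lapply(s, .preprocess_cell,
                                                config = config))
  tmpl <- .fit_template(erps, config, seeds[3])
  params <- group_parameter_table(erps, tmpl$fit$maps,
                                  groups = sim$ground_truth$subjects,
                                  smooth_ms = config$smooth_ms,
                                  occurrence = config$occurrence)
  scale_fits <- list()
  srows <- list()
  for (sv in c("HAMD", "PHQ9", "NSSI_score")) {
    a <- mixed_anova(scales, sv, within = "time", between = "group",
                     subject = "subject_id")
    scale_fits[[sv]] <- a
    r <- data.frame(scale = sv, stringsAsFactors = FALSE)
    for (i in seq_len(nrow(a))) {
      nm <- gsub(":", "_x_", a$effect[i])
      r[[paste0(nm, "_F")]] <- a$F[i]
      r[[paste0(nm, "_p")]] <- a$p_gg[i]
      r[[paste0(nm, "_pes")]] <- a$partial_eta_sq[i]
    }
    srows[[sv]] <- r
  }
  scale_effects <- do.call(rbind, c(srows, list(make.row.names = FALSE)))
  et <- .effect_table(params, c("duration_ms", "coverage", "occurrence", "gev"),
                      within = c("condition", "time"), between = "group",
                      subject = "subject_id", covariates = NULL)
  se <- c(.auto_simple_effects(scale_fits, "time:group", "time", config$alpha),
          .auto_simple_effects(et$fits, "condition:group", "condition",
                               config$alpha))
  corr <- lapply(names(config$arms), function(arm)
    prepost_difference_correlation(scales, params, times = config$times,
                                   group = arm, condition = "negative"))
  names(corr) <- names(config$arms)
  manifest <- list(stage = "longitudinal", config_hash = hash,
                   seed = config$seed, child_seeds = seeds,
                   n_subjects = nrow(sim$ground_truth$subjects),
                   K = tmpl$fit$K, gev = tmpl$fit$gev,
                   package_version = as.character(utils::packageVersion("taskstates")))
  bundle <- list(params = params, effects = et$table, anovas = et$fits,
                 scale_effects = scale_effects, scale_anovas = scale_fits,
                 simple_effects = se, correlations = corr, scales = scales,
                 fit = tmpl$fit, selection = tmpl$selection,
                 ground_truth = sim$ground_truth, manifest = manifest)
  .write_bundle(bundle, config, hash)
  bundle
}

# run simple_effects for every fitted interaction below alpha
.auto_simple_effects <- function(fits, effect, slice_by, alpha) {
  out <- list()
  for (nm in names(fits)) {
    a <- fits[[nm]]
    parts <- strsplit(effect, ":", fixed = TRUE)[[1]]
    hit <- vapply(a$effect, function(e)
      setequal(strsplit(e, ":", fixed = TRUE)[[1]], parts), logical(1))
    if (any(hit) && any(a$p_gg[hit] < alpha, na.rm = TRUE))
      out[[nm]] <- simple_effects(a, effect, slice_by)
  }
  out
}

# Table-1-style demographics from simulated scales
.demographics_table <- function(scales) {
  g <- split(scales, scales$group)
  sumstat <- function(v) vapply(g, function(d) c(mean(d[[v]]), stats::sd(d[[v]]),
                                                 nrow(d)), numeric(3))
  rows <- list()
  for (v in c("age", "HAMD", "PHQ9")) {
    s <- sumstat(v)
    a <- oneway_anova_from_summary(s[1, ], s[2, ], s[3, ])
    rows[[v]] <- data.frame(
      variable = v,
      t(stats::setNames(as.vector(s[1:2, ]),
                        paste0(rep(names(g), each = 2), c("_mean", "_sd")))),
      statistic = a$F, df = paste(a$df_num, a$df_den, sep = ","), p = a$p,
      stringsAsFactors = FALSE, check.names = FALSE)
  }
  counts <- table(scales$group, scales$sex)
  chi <- chi_square_independence(counts)
  sex <- data.frame(variable = "sex_male_count",
                    t(stats::setNames(as.vector(rbind(counts[, "male"], NA)),
                                      paste0(rep(rownames(counts), each = 2),
                                             c("_mean", "_sd")))),
                    statistic = chi$chisq, df = as.character(chi$df),
                    p = chi$p, stringsAsFactors = FALSE, check.names = FALSE)
  out <- rbind(do.call(rbind, rows), sex)
  rownames(out) <- NULL
  out
}

.write_bundle <- function(bundle, config, hash) {
  dir <- config$out_dir
  if (is.null(dir)) return(invisible(NULL))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  pre <- bundle$manifest$stage
  .write_table(bundle$params, file.path(dir, paste0(pre, "_params.tsv")), hash)
  .write_table(bundle$effects, file.path(dir, paste0(pre, "_effects.tsv")), hash)
  .write_table(bundle$scales, file.path(dir, paste0(pre, "_scales.tsv")), hash)
  if (!is.null(bundle$demographics))
    .write_table(bundle$demographics,
                 file.path(dir, paste0(pre, "_demographics.tsv")), hash)
  if (!is.null(bundle$scale_effects))
    .write_table(bundle$scale_effects,
                 file.path(dir, paste0(pre, "_scale_effects.tsv")), hash)
  if (!is.null(bundle$ground_truth))
    .write_table(bundle$ground_truth$params,
                 file.path(dir, paste0(pre, "_ground_truth.tsv")), hash)
  maps <- as.data.frame(bundle$fit$maps)
  .write_table(cbind(channel = rownames(bundle$fit$maps), maps),
               file.path(dir, paste0(pre, "_maps.tsv")), hash)
  jsonlite::write_json(bundle$manifest,
                       file.path(dir, paste0(pre, "_manifest.json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Planted duration targets for the longitudinal replica
#'
#' Mean segment durations (ms) per arm x cue x time for 6 classes. Before
#' treatment both arms share the self-injury group's profile (long class 3,
#' short class 6, amplified under negative cues). After treatment both arms
#' normalize classes 3 and 6; the combined medication + rTMS arm additionally
#' shortens classes 1 and 4 and lengthens class 2, mirroring the reference
#' study's simple-effects directionality.
#'
#' @param arms,conditions,times Cell labels; the first arm is treated as
#'   medication-only, the second as the combined arm.
#' @param K Number of classes (defaults built in for K <= 6).
#' @return Data frame `group`, `condition`, `time`, `class`, `duration_ms`.
#' @export
longitudinal_duration_targets <- function(arms = c("medication",
                                                   "medication+rTMS"),
                                          conditions = c("neutral", "negative"),
                                          times = c("before", "after"),
                                          K = 6) {
  base <- list(
    before.neutral   = c(105,  95, 205, 68, 100,  85),
    before.negative  = c(100,  85, 230, 65,  95,  78),
    med.after.neutral  = c(105, 105, 160, 65, 100, 120),
    med.after.negative = c(100, 105, 150, 62,  95, 135),
    rtms.after.neutral  = c( 80, 130, 150, 55, 100, 115),
    rtms.after.negative = c( 55, 150, 124, 40,  95, 127))
  rows <- list()
  for (ai in seq_along(arms)) for (cc in conditions) for (tm in times) {
    key <- if (tm == times[1]) paste0("before.", cc)
           else paste0(if (ai == 1) "med" else "rtms", ".after.", cc)
    dur <- rep_len(base[[key]] %||% base$before.neutral, K)
    rows[[length(rows) + 1L]] <- data.frame(
      group = arms[ai], condition = cc, time = tm, class = seq_len(K),
      duration_ms = dur, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
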