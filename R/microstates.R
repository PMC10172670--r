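# Polarity-invariant modified k-means over scalp topographies, GEV/CV model
# selection, backfitting, and the four microstate parameters.
#
# Conventions used throughout:
#   * samples are channel-centered (average reference), maps are zero-mean
#     unit-norm column vectors;
#   * similarity is the absolute (polarity-invariant) spatial Pearson
#     correlation, which for centered vectors is |a'v| / (||a|| ||v||);
#   * GEV = sum_t (GFP_t * corr_t)^2 / sum_t GFP_t^2, which for unit-norm maps
#     reduces to sum_t (a_{L(t)}'v_t)^2 / sum_t ||v_t||^2.

#' Global field power
#'
#' GFP at a time point is the population standard deviation (divisor = number
#' of channels) of the voltage topography at that point.
#'
#' @param x An [eeg_erp()] or a `channels x samples` matrix.
#' @return Numeric vector, one nonnegative value per sample.
#' @export
gfp <- function(x) {
  V <- .voltage(x)
  if (nrow(V) < 2L) stop("GFP needs at least 2 channels")
  sqrt(colMeans(sweep(V, 2, colMeans(V))^2))
}

#' Spatial correlation of two topographies
#'
#' Pearson correlation across channels, taken in absolute value when
#' `polarity_invariant` (the microstate convention: a map and its sign-flip
#' are the same state).
#'
#' @param a,b Numeric channel vectors of equal length.
#' @param polarity_invariant Return `|r|` instead of signed `r`.
#' @return A value in `[0, 1]` (or `[-1, 1]` with the flag off).
#' @export
spatial_correlation <- function(a, b, polarity_invariant = TRUE) {
  if (length(a) != length(b)) stop("topographies must have equal channel counts")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("similarity undefined for a zero-variance topography")
  r <- stats::cor(a, b)
  if (polarity_invariant) abs(r) else r
}

# assemble the centered channels x samples data matrix from flexible input
.ms_data <- function(x) {
  V <- if (is.matrix(x)) x
  else if (inherits(x, "eeg_erp")) x$data
  else if (is.list(x)) do.call(cbind, lapply(x, .voltage))
  else stop("expected an ERP, a list of ERPs, or a channels x samples matrix")
  sweep(V, 2, colMeans(V))  # average reference (idempotent)
}

# local maxima of the GFP series (interior strict peaks)
.gfp_peaks <- function(g) {
  n <- length(g)
  if (n < 3L) return(seq_len(n))
  i <- which(g[2:(n - 1)] > g[1:(n - 2)] & g[2:(n - 1)] >= g[3:n]) + 1L
  if (length(i) == 0L) seq_len(n) else i
}

# one k-means run from given initial maps; V centered, A unit-norm zero-mean
.ms_kmeans_run <- function(V, A, iterations, tol) {
  Tn <- ncol(V)
  denom <- sum(V^2)
  vv <- colSums(V^2)
  K <- ncol(A)
  gev_old <- -Inf
  L <- integer(Tn)
  for (it in seq_len(iterations)) {
    P <- crossprod(A, V)                       # K x T inner products
    L <- max.col(t(P * P), ties.method = "first")
    for (k in seq_len(K)) {
      idx <- which(L == k)
      if (length(idx) == 0L) {
        # dead class: reseed from the worst-explained sample
        resid <- vv - P[cbind(L, seq_len(Tn))]^2
        A[, k] <- .norm_map(V[, which.max(resid)])
        next
      }
      S <- tcrossprod(V[, idx, drop = FALSE])
      A[, k] <- .norm_map(eigen(S, symmetric = TRUE)$vectors[, 1])
    }
    P <- crossprod(A, V)
    L <- max.col(t(P * P), ties.method = "first")
    gev <- sum(P[cbind(L, seq_len(Tn))]^2) / denom
    if (is.finite(gev_old) && abs(gev - gev_old) < tol * max(gev_old, 1e-12))
      break
    gev_old <- gev
  }
  list(maps = A, labels = L, gev = gev, iterations_used = it)
}

#' Fit microstate topographies by polarity-invariant modified k-means
#'
#' Segments EEG/ERP topographies into `K` classes. Each sample is assigned to
#' the prototype maximizing the squared (polarity-invariant) spatial
#' correlation; each prototype is updated as the dominant eigenvector of the
#' outer-product sum of its assigned samples (the polarity-invariant
#' centroid), re-normalized every update. Iteration stops when the relative
#' change in global explained variance falls below `tol` or at the iteration
#' cap. The best of `restarts` seeded random initializations (by GEV) is
#' returned.
#'
#' @param x An [eeg_erp()], a list of ERPs (stacked sample-wise, e.g. for a
#'   shared template across subjects), or a `channels x samples` matrix. Data
#'   are average-referenced internally.
#' @param K Number of classes, `1 <= K <= channels - 1`.
#' @param iterations Iteration cap per restart.
#' @param restarts Number of random initializations.
#' @param seed Integer seed making the fit reproducible.
#' @param tol Relative GEV change declaring convergence.
#' @param gfp_peaks If `TRUE`, cluster only local GFP maxima (labels and GEV
#'   are still computed over all samples afterwards).
#' @return An object of class `"msfit"`: list with `maps` (`channels x K`,
#'   zero-mean unit-norm columns), `K`, `labels` (training assignment),
#'   `gev` (total), `gev_class`, `cv` (cross-validation criterion, `NA` when
#'   `K >= channels - 1`), `rate`, `data` (centered training matrix) and
#'   provenance (`iterations`, `restarts`, `seed`, `converged_in`).
#' @seealso [predict.msfit()] for backfitting, [select_n_maps()] for choosing
#'   `K`, [compute_parameters()] for the temporal parameters.
#' @examples
#' lay <- layout_1020()
#' maps <- make_prototype_maps(lay, 3, seed = 1)
#' sim <- simulate_epoch(maps, c(120, 100, 80), snr = Inf, seed = 2)
#' fit <- microstates(average_erp(sim$epochs), K = 3, restarts = 5, seed = 3)
#' fit
#' @export
microstates <- function(x, K, iterations = 1000L, restarts = 50L, seed = NULL,
                        tol = 1e-6, gfp_peaks = FALSE) {
  V <- .ms_data(x)
  C <- nrow(V)
  if (!is.numeric(K) || length(K) != 1L || K < 1 || K > C - 1)
    stop("'K' must be between 1 and channels - 1")
  K <- as.integer(K)
  Vfit <- if (gfp_peaks) V[, .gfp_peaks(gfp(V)), drop = FALSE] else V
  if (ncol(Vfit) < K) stop("fewer samples than classes")
  best <- .with_seed(seed, {
    b <- NULL
    for (r in seq_len(restarts)) {
      A <- apply(Vfit[, sample.int(ncol(Vfit), K), drop = FALSE], 2, .norm_map)
      A <- matrix(A, C, K)
      run <- .ms_kmeans_run(Vfit, A, iterations, tol)
      if (is.null(b) || run$gev > b$gev) b <- run
    }
    b
  })
  maps <- best$maps
  dimnames(maps) <- list(rownames(V), paste0("MS", seq_len(K)))
  if (inherits(x, "eeg_erp")) attr(maps, "layout") <- x$layout
  else if (is.list(x) && inherits(x[[1]], "eeg_erp"))
    attr(maps, "layout") <- x[[1]]$layout
  labels <- backfit(V, maps)
  g <- gev_of_fit(V, maps, labels)
  fit <- structure(
    list(maps = maps, K = K, labels = labels, gev = g$total,
         gev_class = g$per_class,
         cv = if (K < C - 1) cv_criterion(V, maps, labels) else NA_real_,
         rate = if (inherits(x, "eeg_erp")) x$rate
                else if (is.list(x) && inherits(x[[1]], "eeg_erp")) x[[1]]$rate
                else NA_real_,
         data = V, n_samples = ncol(V), n_channels = C,
         iterations = iterations, restarts = restarts, seed = seed,
         converged_in = best$iterations_used, gfp_peaks = gfp_peaks,
         call = match.call()),
    class = "msfit")
  fit
}

#' Backfit template maps to data
#'
#' Labels every sample with the class of the map having maximal
#' polarity-invariant spatial correlation. Ties are broken toward the lowest
#' class index; zero-variance (flat) samples get label 0 (unassigned).
#'
#' @param x An [eeg_erp()] or `channels x samples` matrix.
#' @param maps `channels x K` template matrix (zero-mean unit-norm columns),
#'   e.g. `coef()` of an [microstates()] fit.
#' @return Integer vector of per-sample labels in `0..K`.
#' @export
backfit <- function(x, maps) {
  V <- .ms_data(x)
  if (nrow(V) != nrow(maps)) stop("channel counts of data and maps differ")
  P <- crossprod(maps, V)
  L <- max.col(t(P * P), ties.method = "first")
  L[colSums(V^2) == 0] <- 0L
  L
}

#' Global explained variance of a labeling
#'
#' GEV is the GFP-weighted fraction of topographic variance explained:
#' `sum_t (GFP(t) * corr(v_t, map_label(t)))^2 / sum_t GFP(t)^2`, with
#' polarity-invariant correlation. The per-class values restrict the numerator
#' to samples of that class and sum to the total.
#'
#' @param x Data as in [backfit()].
#' @param maps Template matrix.
#' @param labels Integer labels in `0..K` (0 contributes nothing).
#' @return List with `total` and `per_class` (named numeric, length K).
#' @export
gev_of_fit <- function(x, maps, labels) {
  V <- .ms_data(x)
  Tn <- ncol(V)
  if (length(labels) != Tn) stop("labels do not match the data")
  denom <- sum(V^2)
  if (denom == 0) stop("GEV undefined for all-zero data")
  K <- ncol(maps)
  P <- crossprod(maps, V)
  per <- numeric(K)
  idx <- which(labels > 0L)
  contrib <- numeric(Tn)
  contrib[idx] <- P[cbind(labels[idx], idx)]^2
  for (k in seq_len(K)) per[k] <- sum(contrib[labels == k]) / denom
  names(per) <- colnames(maps)
  list(total = sum(per), per_class = per)
}

#' Cross-validation criterion for a map set
#'
#' The predictive residual-variance criterion used to pick the number of
#' microstate classes: `CV = sigma2 * ((C - 1) / (C - 1 - K))^2` with
#' `sigma2 = sum_t (v_t'v_t - (a_{L(t)}'v_t)^2) / (T (C - 1))`, `C` channels
#' and unit-norm assigned maps. Smaller is better; the penalty factor diverges
#' as `K` approaches `C - 1`.
#'
#' @param x Data as in [backfit()].
#' @param maps Template matrix.
#' @param labels Optional labels; backfitted when `NULL`.
#' @return Nonnegative scalar.
#' @export
cv_criterion <- function(x, maps, labels = NULL) {
  V <- .ms_data(x)
  C <- nrow(V)
  K <- ncol(maps)
  if (K >= C - 1)
    stop("CV undefined at K = channels - 1: the penalty term (C-1)/(C-1-K) divides by zero")
  if (is.null(labels)) labels <- backfit(V, maps)
  Tn <- ncol(V)
  P <- crossprod(maps, V)
  expl <- numeric(Tn)
  idx <- which(labels > 0L)
  expl[idx] <- P[cbind(labels[idx], idx)]^2
  sigma2 <- sum(colSums(V^2) - expl) / (Tn * (C - 1))
  sigma2 * ((C - 1) / (C - 1 - K))^2
}

#' Choose the number of microstate classes
#'
#' Fits every `K` in `K_range` and tabulates GEV and the CV criterion. The
#' returned optimum is the CV minimizer; the full table supports the joint
#' "larger GEV, smaller CV" judgment.
#'
#' @inheritParams microstates
#' @param K_range Integer vector of candidate class counts.
#' @return An object of class `"ms_selection"`: list with `K_opt`, `table`
#'   (data frame `K`, `gev`, `cv`) and `fits` (list of `"msfit"` objects).
#' @export
select_n_maps <- function(x, K_range = 2:8, iterations = 1000L,
                          restarts = 50L, seed = NULL, tol = 1e-6,
                          gfp_peaks = FALSE) {
  K_range <- sort(unique(as.integer(K_range)))
  if (length(K_range) == 0L) stop("'K_range' is empty")
  V <- .ms_data(x)
  if (max(K_range) > nrow(V) - 2)
    stop("'K_range' must stay below channels - 1 for the CV criterion")
  seeds <- .with_seed(seed, sample.int(.Machine$integer.max, length(K_range)))
  fits <- lapply(seq_along(K_range), function(i)
    microstates(V, K_range[i], iterations = iterations, restarts = restarts,
                seed = seeds[i], tol = tol, gfp_peaks = gfp_peaks))
  tab <- data.frame(K = K_range,
                    gev = vapply(fits, `[[`, numeric(1), "gev"),
                    cv = vapply(fits, `[[`, numeric(1), "cv"))
  structure(list(K_opt = K_range[which.min(tab$cv)], table = tab, fits = fits),
            class = "ms_selection")
}

#' @export
print.ms_selection <- function(x, ...) {
  cat("Microstate class-count selection (CV minimizer: K =", x$K_opt, ")\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Absorb segments shorter than a minimum duration
#'
#' Samples inside a segment shorter than `min_duration_ms` are re-assigned,
#' sample by sample, to the neighboring segment's class with which they
#' correlate better, iterating until no interior short segment remains.
#' Segments touching the epoch edges are left alone. `min_duration_ms = 0` is
#' the identity (temporal smoothing is off by default throughout the package).
#'
#' @param labels Integer labels in `0..K`.
#' @param min_duration_ms Minimum segment duration (ms).
#' @param x Data the labels belong to.
#' @param maps Template matrix.
#' @param rate Sampling rate (Hz) used to convert ms to samples.
#' @return Relabeled integer vector.
#' @export
smooth_labels <- function(labels, min_duration_ms, x, maps, rate = 500) {
  if (min_duration_ms < 0) stop("'min_duration_ms' must be >= 0")
  if (min_duration_ms == 0) return(labels)
  V <- .ms_data(x)
  P <- crossprod(maps, V)
  min_len <- ceiling(min_duration_ms * rate / 1000)
  n <- length(labels)
  repeat {
    r <- rle(labels)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    short <- which(r$lengths < min_len & starts > 1L & ends < n & r$values > 0L)
    if (length(short) == 0L) break
    j <- short[which.min(r$lengths[short])]
    left <- r$values[j - 1L]
    right <- r$values[j + 1L]
    for (t in starts[j]:ends[j]) {
      labels[t] <- if (left == 0L) right
      else if (right == 0L) left
      else if (P[left, t]^2 >= P[right, t]^2) left else right
    }
  }
  labels
}

#' Microstate temporal parameters of a labeling
#'
#' Computes, per class: GEV share, mean segment duration (ms), coverage
#' (fraction of assigned samples) and occurrence (segments per second).
#' Segments are maximal runs of one class; runs touching the epoch edges
#' count. The occurrence denominator is the full epoch length by default
#' (`"epoch"`), which keeps `occurrence * duration / 1000 = coverage` exact
#' when every sample is assigned; `"assigned"` divides by assigned time
#' instead.
#'
#' @param labels Integer labels in `0..K`.
#' @param x Data as in [backfit()].
#' @param maps Template matrix.
#' @param rate Sampling rate (Hz).
#' @param occurrence Denominator convention, `"epoch"` or `"assigned"`.
#' @return A data frame of class `"ms_params"` with one row per class
#'   (`class`, `gev`, `duration_ms`, `coverage`, `occurrence`; unobserved
#'   classes get coverage/occurrence 0 and duration `NA`) and attributes
#'   `total_gev` and `epoch_length_s`.
#' @export
compute_parameters <- function(labels, x, maps, rate = 500,
                               occurrence = c("epoch", "assigned")) {
  occurrence <- match.arg(occurrence)
  V <- .ms_data(x)
  if (length(labels) != ncol(V)) stop("labels do not match the data")
  K <- ncol(maps)
  assigned <- sum(labels > 0L)
  if (assigned == 0L) stop("no assigned samples: all labels are 0")
  g <- gev_of_fit(V, maps, labels)
  r <- rle(labels)
  cnt <- tabulate(labels[labels > 0L], K)
  nseg <- tabulate(r$values[r$values > 0L], K)
  epoch_s <- ncol(V) / rate
  denom_s <- if (occurrence == "epoch") epoch_s else assigned / rate
  out <- data.frame(
    class = colnames(maps) %||% paste0("MS", seq_len(K)),
    gev = as.numeric(g$per_class),
    duration_ms = ifelse(nseg > 0, cnt / pmax(nseg, 1L) * 1000 / rate, NA_real_),
    coverage = cnt / assigned,
    occurrence = nseg / denom_s,
    stringsAsFactors = FALSE)
  attr(out, "total_gev") <- g$total
  attr(out, "epoch_length_s") <- epoch_s
  class(out) <- c("ms_params", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Long-format microstate parameter table for a cohort
#'
#' Backfits one shared template to every subject x cell ERP and stacks the
#' per-class parameters into the long table consumed by the statistics stage.
#'
#' @param erps Nested list `[[subject]][[cell]]` of [eeg_erp()] objects (cell
#'   names either `condition` or `time.condition`), as produced by the
#'   pipeline, or a flat list of ERPs carrying `subject_id`/`condition`.
#' @param maps Shared template matrix (or an `"msfit"`).
#' @param groups Optional data frame `subject_id`, `group` merged in.
#' @param smooth_ms Minimum segment duration passed to [smooth_labels()].
#' @param occurrence Occurrence convention, see [compute_parameters()].
#' @return Data frame: `subject_id`, `group` (if given), `time` (if present),
#'   `condition`, `class`, `gev`, `duration_ms`, `coverage`, `occurrence`,
#'   `total_gev`.
#' @export
group_parameter_table <- function(erps, maps, groups = NULL, smooth_ms = 0,
                                  occurrence = c("epoch", "assigned")) {
  occurrence <- match.arg(occurrence)
  if (inherits(maps, "msfit")) maps <- maps$maps
  if (length(erps) > 0 && inherits(erps[[1]], "eeg_erp")) {
    flat <- erps
    names(flat) <- vapply(flat, function(e)
      paste(e$subject_id, e$condition, sep = "\r"), character(1))
    erps <- list()
    for (nm in names(flat)) {
      p <- strsplit(nm, "\r", fixed = TRUE)[[1]]
      erps[[p[1]]][[p[2]]] <- flat[[nm]]
    }
  }
  rows <- list()
  for (sid in names(erps)) {
    for (cell in names(erps[[sid]])) {
      erp <- erps[[sid]][[cell]]
      lab <- backfit(erp, maps)
      if (smooth_ms > 0)
        lab <- smooth_labels(lab, smooth_ms, erp, maps, rate = erp$rate)
      pp <- compute_parameters(lab, erp, maps, rate = erp$rate,
                               occurrence = occurrence)
      parts <- strsplit(cell, ".", fixed = TRUE)[[1]]
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = sid,
        time = if (length(parts) == 2L) parts[1] else NA_character_,
        condition = parts[length(parts)],
        pp, total_gev = attr(pp, "total_gev"),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (all(is.na(out$time))) out$time <- NULL
  if (!is.null(groups)) out <- merge(groups, out, by = "subject_id", sort = FALSE)
  out
}
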