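# S3 methods for the "msfit" model object.

#' @export
print.msfit <- function(x, ...) {
  cat(sprintf("Microstate fit: K = %d classes, %d channels, %d samples\n",
              x$K, x$n_channels, x$n_samples))
  cat(sprintf("  GEV = %.4f, CV = %s, best of %d restart(s), converged in %d iteration(s)\n",
              x$gev, if (is.na(x$cv)) "NA" else sprintf("%.5g", x$cv),
              x$restarts, x$converged_in))
  invisible(x)
}

#' Summarize a microstate fit
#'
#' Per-class GEV share and the temporal parameters of the training labeling,
#' plus fit provenance.
#'
#' @param object An `"msfit"`.
#' @param rate Sampling rate for the temporal parameters (defaults to the
#'   rate recorded at fit time, else 500 Hz).
#' @param ... Unused.
#' @return An object of class `"summary.msfit"`.
#' @export
summary.msfit <- function(object, rate = NULL, ...) {
  rate <- rate %||% (if (is.finite(object$rate)) object$rate else 500)
  params <- compute_parameters(object$labels, object$data, object$maps,
                               rate = rate)
  structure(list(K = object$K, gev = object$gev, cv = object$cv,
                 params = params, restarts = object$restarts,
                 seed = object$seed, rate = rate),
            class = "summary.msfit")
}

#' @export
print.summary.msfit <- function(x, ...) {
  cat(sprintf("Microstate model with %d classes (GEV %.4f, CV %s)\n\n",
              x$K, x$gev, if (is.na(x$cv)) "NA" else sprintf("%.5g", x$cv)))
  print(as.data.frame(x$params), row.names = FALSE, digits = 4)
  cat(sprintf("\nTraining labeling at %g Hz; %d restart(s), seed %s\n",
              x$rate, x$restarts,
              if (is.null(x$seed)) "unset" else as.character(x$seed)))
  invisible(x)
}

#' @export
coef.msfit <- function(object, ...) object$maps

#' Backfit a fitted template to new data
#'
#' @param object An `"msfit"`.
#' @param newdata An [eeg_erp()] or `channels x samples` matrix; defaults to
#'   the training data.
#' @param smooth_ms Optional minimum segment duration (ms) applied with
#'   [smooth_labels()].
#' @param ... Unused.
#' @return Integer label vector in `0..K`.
#' @export
predict.msfit <- function(object, newdata = NULL, smooth_ms = 0, ...) {
  if (is.null(newdata)) newdata <- object$data
  lab <- backfit(newdata, object$maps)
  if (smooth_ms > 0) {
    rate <- if (inherits(newdata, "eeg_erp")) newdata$rate
            else if (is.finite(object$rate)) object$rate else 500
    lab <- smooth_labels(lab, smooth_ms, newdata, object$maps, rate = rate)
  }
  lab
}

#' @export
fitted.msfit <- function(object, ...) {
  V <- object$data
  A <- object$maps
  L <- object$labels
  F <- matrix(0, nrow(V), ncol(V), dimnames = dimnames(V))
  idx <- which(L > 0L)
  for (t in idx) F[, t] <- A[, L[t]] * sum(A[, L[t]] * V[, t])
  F
}

#' @export
residuals.msfit <- function(object, ...) object$data - fitted(object)

#' Simulate microstate-structured data from a fitted template
#'
#' Generates epochs whose segments are the fitted maps under a smooth GFP
#' envelope (see [simulate_epoch()]), e.g. for parametric-bootstrap checks.
#'
#' @param object An `"msfit"`.
#' @param nsim Number of trials.
#' @param seed Integer seed.
#' @param duration_means_ms Per-class mean segment durations; default 100 ms.
#' @param snr Signal-to-noise ratio.
#' @param ... Passed on to [simulate_epoch()].
#' @return See [simulate_epoch()].
#' @export
simulate.msfit <- function(object, nsim = 1, seed = NULL,
                           duration_means_ms = 100, snr = Inf, ...) {
  simulate_epoch(object$maps, duration_means_ms, n_trials = nsim, seed = seed,
                 snr = snr, ...)
}

#' Plot fitted microstate topographies
#'
#' Draws each class map as a color-coded sensor plot in an azimuthal
#' (top-view) projection of the montage.
#'
#' @param x An `"msfit"` or a bare `channels x K` map matrix with a layout
#'   attribute.
#' @param layout Layout override.
#' @param ... Unused.
#' @return Invisibly, `x`.
#' @export
plot.msfit <- function(x, layout = NULL, ...) {
  maps <- if (inherits(x, "msfit")) x$maps else x
  layout <- layout %||% attr(maps, "layout")
  if (is.null(layout)) stop("no layout available for plotting")
  p <- layout$positions
  # azimuthal equidistant projection, nose up
  r <- acos(pmin(pmax(p[, 3], -1), 1))
  az <- atan2(p[, 1], p[, 2])
  px <- r * sin(az); py <- r * cos(az)
  K <- ncol(maps)
  pal <- grDevices::colorRampPalette(c("#2166AC", "white", "#B2182B"))(101)
  op <- graphics::par(mfrow = c(1, K), mar = c(0.5, 0.5, 2, 0.5))
  on.exit(graphics::par(op))
  for (k in seq_len(K)) {
    v <- maps[, k]
    ci <- 1 + round(50 * (1 + v / max(abs(v))))
    graphics::plot(px, py, pch = 21, bg = pal[ci], cex = 2, axes = FALSE,
                   xlab = "", ylab = "", asp = 1,
                   main = colnames(maps)[k] %||% paste0("MS", k))
    theta <- seq(0, 2 * pi, length.out = 120)
    graphics::lines(max(r) * cos(theta), max(r) * sin(theta), col = "grey")
  }
  invisible(x)
}
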