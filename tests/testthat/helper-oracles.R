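# Shared fixtures and independent brute-force oracles. The oracles evaluate
# the published formulas sample by sample with stats::cor / population SD,
# deliberately avoiding the package's matrix-algebra code paths.

# small random layout on the unit sphere (upper hemisphere)
random_layout <- function(C, seed = 1) {
  set.seed(seed)
  p <- matrix(rnorm(C * 3), C)
  p[, 3] <- abs(p[, 3])
  p <- p / sqrt(rowSums(p^2))
  sensor_layout(sprintf("ch%02d", seq_len(C)), p)
}

# population (divisor = C) standard deviation
pop_sd <- function(v) sqrt(mean((v - mean(v))^2))

# GEV by direct per-sample evaluation of the GFP-weighted formula
brute_gev <- function(V, maps, labels) {
  num <- 0; den <- 0
  for (t in seq_len(ncol(V))) {
    v <- V[, t]
    g <- pop_sd(v)
    den <- den + g^2
    if (labels[t] > 0)
      num <- num + (g * abs(stats::cor(v, maps[, labels[t]])))^2
  }
  num / den
}

# CV criterion by direct evaluation: residual variance with the assigned
# unit-norm map, times the ((C-1)/(C-1-K))^2 penalty
brute_cv <- function(V, maps, labels) {
  C <- nrow(V); Tn <- ncol(V); K <- ncol(maps)
  s2 <- 0
  for (t in seq_len(Tn)) {
    v <- V[, t] - mean(V[, t])
    proj <- if (labels[t] > 0) sum(maps[, labels[t]] * v)^2 else 0
    s2 <- s2 + sum(v^2) - proj
  }
  s2 / (Tn * (C - 1)) * ((C - 1) / (C - 1 - K))^2
}

# match fitted classes to generating classes by polarity-invariant correlation
match_classes <- function(fitted_maps, true_maps) {
  apply(abs(crossprod(fitted_maps, true_maps)), 2, which.max)
}

# random centered data with a valid random labeling, for conservation checks
random_labeled_erp <- function(C = 8, Tn = 60, K = 3, seed = 1) {
  set.seed(seed)
  V <- matrix(rnorm(C * Tn), C, Tn)
  V <- sweep(V, 2, colMeans(V))
  maps <- matrix(rnorm(C * K), C, K)
  maps <- apply(maps, 2, function(a) { a <- a - mean(a); a / sqrt(sum(a^2)) })
  colnames(maps) <- paste0("MS", seq_len(K))
  list(V = V, maps = maps, labels = backfit(V, maps))
}
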