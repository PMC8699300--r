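# Independent brute-force oracles used to freeze expected values.
# These deliberately share no code with the implementation paths they check.

# exact two-sided Mann-Whitney p by full enumeration of label assignments:
# distance-from-the-mean rule on the rank-sum statistic with mid-ranks
brute_mw_p <- function(x, y) {
  n1 <- length(x)
  r <- rank(c(x, y))
  N <- length(r)
  mu <- n1 * (N + 1) / 2
  obs <- sum(r[seq_len(n1)])
  sums <- apply(utils::combn(N, n1), 2, function(idx) sum(r[idx]))
  mean(abs(sums - mu) >= abs(obs - mu) - 1e-9)
}

# proportion of reads matching a variable, by direct looping over reads
brute_proportion <- function(patterns, counts, i, status_i,
                             j = NULL, status_j = NULL) {
  hits <- 0; total <- 0
  for (r in seq_along(patterns)) {
    chars <- strsplit(patterns[r], "")[[1]]
    ok <- chars[i] == status_i
    if (!is.null(j)) ok <- ok && chars[j] == status_j
    hits <- hits + ok * counts[r]
    total <- total + counts[r]
  }
  hits / total
}

# AUC by pairwise counting (ties half)
brute_auc <- function(pred, labels) {
  px <- pred[labels == 1]; py <- pred[labels == 0]
  s <- 0
  for (a in px) for (b in py) s <- s + (a > b) + 0.5 * (a == b)
  s / (length(px) * length(py))
}

# exhaustive threshold scan over all midpoints and both orientations
brute_separation <- function(pos, neg) {
  vals <- sort(unique(c(pos, neg)))
  thr <- c(min(vals) - 1, (vals[-1] + vals[-length(vals)]) / 2,
           max(vals) + 1)
  best_sens <- 0; best_spec <- 0; complete <- FALSE
  best_youden <- -Inf; youden_thr <- NA_real_
  for (t in thr) {
    for (dir in c(1, -1)) {
      if (dir == 1) {
        sens <- mean(pos > t); spec <- mean(neg <= t)
      } else {
        sens <- mean(pos < t); spec <- mean(neg >= t)
      }
      if (spec == 1) best_sens <- max(best_sens, sens)
      if (sens == 1) best_spec <- max(best_spec, spec)
      if (sens == 1 && spec == 1) complete <- TRUE
      if (sens + spec > best_youden) {
        best_youden <- sens + spec; youden_thr <- t
      }
    }
  }
  list(sens_at_spec100 = 100 * best_sens, spec_at_sens100 = 100 * best_spec,
       complete = complete, youden = best_youden)
}

# a model with every noise source off (for exact-recovery tests)
noiseless_model <- function(design) {
  m <- default_calibrated_model(design)
  m$conversion_failure_rate <- 0
  m$inappropriate_conversion_rate <- 0
  m$sequencing_error_rate <- 0
  m$chimera_rate <- 0
  m$dispersion_sdlog <- 0
  m
}

# small two-class pattern table fixture: explicit reads, known counts
tiny_pattern_table <- function(patterns, sample_id = "S1", group = "HD",
                               locus = "GSTP1") {
  tb <- table(patterns)
  pattern_table(tibble::tibble(
    sample_id = sample_id, group = group, locus = locus,
    pattern = names(tb), count = as.integer(tb)))
}
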