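#' Separation metrics of one variable between two groups
#'
#' Scans all thresholds (midpoints between adjacent distinct values plus the
#' extremes) in both orientations -- the positive class may sit above or
#' below the threshold -- and reports the best achievable sensitivity at
#' 100% specificity and specificity at 100% sensitivity.  Complete
#' separation means some threshold classifies both groups perfectly.
#'
#' @param pos,neg numeric values of the positive and negative group.
#' @return list: `sens_at_spec100`, `spec_at_sens100` (percent, 0-100),
#'   `complete_separation` (logical), `direction` (+1 when the positive
#'   group sits high, -1 otherwise).
#' @export
separation_metrics <- function(pos, neg) {
  stopifnot(length(pos) >= 1, length(neg) >= 1)
  # positive high: spec 100 -> threshold above max(neg)
  sens_high <- 100 * mean(pos > max(neg))
  sens_low <- 100 * mean(pos < min(neg))
  spec_high <- 100 * mean(neg < min(pos))  # sens 100 -> threshold below min(pos)
  spec_low <- 100 * mean(neg > max(pos))
  direction <- if (max(sens_high, spec_high) >= max(sens_low, spec_low)) 1 else -1
  sens <- max(sens_high, sens_low)
  spec <- max(spec_high, spec_low)
  complete <- (sens_high == 100 && spec_high == 100) ||
    (sens_low == 100 && spec_low == 100)
  list(sens_at_spec100 = sens, spec_at_sens100 = spec,
       complete_separation = complete, direction = direction)
}

#' Estimate the discrimination cutoff (and ratio) of one variable
#'
#' Under complete separation the cutoff is the geometric mean of the two
#' closest cross-group values (the arithmetic mean when one of them is
#' zero), and the ratio of the larger to the smaller of that pair is
#' reported when both are nonzero.  Without complete separation the cutoff
#' is the midpoint threshold maximising sensitivity + specificity (Youden),
#' and no ratio is reported.
#'
#' @inheritParams separation_metrics
#' @return list: `cutoff`, `ratio` (`NA` unless completely separated with
#'   both boundary values nonzero), `complete_separation`.
#' @export
estimate_cutoff <- function(pos, neg) {
  sep <- separation_metrics(pos, neg)
  if (sep$complete_separation) {
    if (min(pos) > max(neg)) {
      lo <- max(neg); hi <- min(pos)
    } else {
      lo <- max(pos); hi <- min(neg)
    }
    cutoff <- if (lo == 0) (lo + hi) / 2 else sqrt(lo * hi)
    ratio <- if (lo > 0) hi / lo else NA_real_
    return(list(cutoff = cutoff, ratio = ratio, complete_separation = TRUE))
  }
  vals <- sort(unique(c(pos, neg)))
  thr <- if (length(vals) == 1) vals else
    (vals[-1] + vals[-length(vals)]) / 2
  best <- -Inf; best_thr <- vals[1]
  for (t in thr) {
    # positive high
    j_hi <- mean(pos > t) + mean(neg <= t)
    j_lo <- mean(pos < t) + mean(neg >= t)
    if (max(j_hi, j_lo) > best) {
      best <- max(j_hi, j_lo); best_thr <- t
    }
  }
  list(cutoff = best_thr, ratio = NA_real_, complete_separation = FALSE)
}
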