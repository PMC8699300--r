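# Re-screen of the variable family on low-coverage per-read WGBS call
# tables.  Short reads cover only a subset of a locus's CpGs, so the
# variables become binary per read (pattern present / absent) and reads are
# pooled across samples within the normal and cancer groups; association is
# tested per variable on the pooled 2x2 table.

parse_covered <- function(covered) {
  lapply(strsplit(covered, ",", fixed = TRUE), as.integer)
}

#' Tally one binary pattern variable over WGBS reads
#'
#' A read is evaluable for a variable iff it covers all of the variable's
#' CpG positions; it is "present" iff its state matches the variable's
#' status at each of those positions (other covered positions are
#' ignored).  Counts are tallied per group over evaluable reads only.
#'
#' @param obs per-read call table (see [simulate_wgbs_reads()] /
#'   [read_wgbs_table()]): columns `read_id`, `group`, `covered`, `states`.
#' @param spec variable name or a row from [enumerate_variables()].
#' @param groups the two group labels, negative (reference) first.
#' @return 2x2 integer matrix: rows present/absent, columns groups.
#' @export
evaluate_binary_variable <- function(obs, spec,
                                     groups = c("normal", "cancer")) {
  if (is.character(spec)) spec <- parse_variable_name(spec)
  pos_needed <- c(spec$i, if (identical(spec$kind, "pair")) spec$j)
  st_needed <- c(spec$status_i, if (identical(spec$kind, "pair")) spec$status_j)
  cov <- parse_covered(obs$covered)
  counts <- matrix(0L, nrow = 2, ncol = 2,
                   dimnames = list(c("present", "absent"), groups))
  for (r in seq_len(nrow(obs))) {
    idx <- match(pos_needed, cov[[r]])
    if (anyNA(idx)) next
    st <- substring(obs$states[r], idx, idx)
    present <- all(st == st_needed)
    g <- match(obs$group[r], groups)
    if (is.na(g)) next
    counts[if (present) 1L else 2L, g] <- counts[if (present) 1L else 2L, g] + 1L
  }
  counts
}

#' Test a 2x2 pattern-by-group table for association
#'
#' Follows the all-expected-at-least-5 rule: the Pearson chi-square test
#' (no continuity correction by default) when every expected count is at
#' least 5, the two-sided Fisher exact test otherwise.  A table with a zero
#' margin carries no information and is reported as p = 1 with a degenerate
#' flag.
#'
#' @param counts 2x2 matrix of counts.
#' @param correct apply Yates continuity correction in the chi-square
#'   branch (off by default).
#' @return list: `test` (`"chi-square"`, `"fisher"` or `"degenerate"`),
#'   `p`, `expected` (matrix of expected counts).
#' @export
test_association <- function(counts, correct = FALSE) {
  stopifnot(all(dim(counts) == c(2, 2)), all(counts >= 0))
  rs <- rowSums(counts); cs <- colSums(counts); n <- sum(counts)
  if (any(rs == 0) || any(cs == 0)) {
    return(list(test = "degenerate", p = 1,
                expected = outer(rs, cs) / max(n, 1)))
  }
  expected <- outer(rs, cs) / n
  if (all(expected >= 5)) {
    p <- suppressWarnings(
      chisq.test(counts, correct = correct)$p.value)
    list(test = "chi-square", p = p, expected = expected)
  } else {
    p <- fisher.test(counts)$p.value
    list(test = "fisher", p = p, expected = expected)
  }
}

#' Screen every variable of a locus on pooled WGBS reads
#'
#' One binary-variable association test per enumerated variable of the
#' locus; p-values are Bonferroni-adjusted by the locus's enumeration count
#' (561 for a 17-CpG locus), capped at 1.
#'
#' @param obs per-read call table restricted to one locus.
#' @param locus a [locus_spec()] (or an [amplicon_design()] plus
#'   `locus_name`).
#' @param locus_name locus name when `locus` is a design.
#' @param groups the two group labels, negative first.
#' @return tibble: `variable`, `n_normal`, `n_cancer` (evaluable reads),
#'   `present_normal`, `present_cancer`, `test`, `p`, `p_adj`.
#' @export
screen_locus <- function(obs, locus, locus_name = NULL,
                         groups = c("normal", "cancer")) {
  if (inherits(locus, "amplicon_design")) {
    stopifnot(!is.null(locus_name))
    locus <- locus$loci[[locus_name]]
  }
  n_cpg <- length(locus$cpg_positions)
  vars <- enumerate_variables(setNames(n_cpg, locus$name))
  m <- nrow(vars)
  # per-read state matrix (NA where a CpG is not covered), built once
  cov <- parse_covered(obs$covered)
  S <- matrix(NA_character_, nrow = nrow(obs), ncol = n_cpg)
  for (r in seq_len(nrow(obs))) {
    S[r, cov[[r]]] <- strsplit(obs$states[r], "")[[1]]
  }
  g <- match(obs$group, groups)
  rows <- vector("list", m)
  for (k in seq_len(m)) {
    v <- vars[k, ]
    if (v$kind == "single") {
      evaluable <- !is.na(S[, v$i]) & !is.na(g)
      present <- evaluable & S[, v$i] == v$status_i
    } else {
      evaluable <- !is.na(S[, v$i]) & !is.na(S[, v$j]) & !is.na(g)
      present <- evaluable & S[, v$i] == v$status_i & S[, v$j] == v$status_j
    }
    counts <- matrix(0L, 2, 2, dimnames = list(c("present", "absent"), groups))
    for (gi in 1:2) {
      counts[1, gi] <- sum(present & g == gi, na.rm = TRUE)
      counts[2, gi] <- sum(evaluable & !present & g == gi, na.rm = TRUE)
    }
    tst <- test_association(counts)
    rows[[k]] <- tibble(
      variable = v$variable,
      n_normal = sum(counts[, 1]), n_cancer = sum(counts[, 2]),
      present_normal = counts[1, 1], present_cancer = counts[1, 2],
      test = tst$test, p = tst$p, p_adj = bonferroni_adjust(tst$p, m)
    )
  }
  bind_rows(rows)
}
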