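wgbs_fixture <- function() {
  # hand-built reads over a 5-CpG locus with partial coverage
  tibble::tibble(
    read_id = sprintf("r%d", 1:6),
    sample_id = "s",
    group = c("normal", "normal", "normal", "cancer", "cancer", "cancer"),
    covered = c("1,2,3", "2,3,4", "4,5", "1,2,3,4", "3,4,5", "2,3"),
    states = c("CTC", "TCT", "CT", "CCCT", "TTC", "CC"))
}

test_that("binary variables count only evaluable reads", {
  obs <- wgbs_fixture()
  # spec on (4,5): only reads 3, 5 cover both
  counts <- evaluate_binary_variable(obs, "GSTP1.C4.T5")
  expect_equal(sum(counts), 2)
  expect_equal(counts["present", "normal"], 1L)  # read 3: C4, T5
  expect_equal(counts["present", "cancer"], 0L)  # read 5: T4 fails
  # a read covering 1-3 is never evaluable for positions beyond 3
  counts <- evaluate_binary_variable(obs, "GSTP1.C1.C4")
  expect_equal(sum(counts[, "normal"]), 0L)
  expect_equal(sum(counts[, "cancer"]), 1L)
  # single-position variable: every read except r3 covers position 3
  counts <- evaluate_binary_variable(obs, "GSTP1.C3")
  expect_equal(sum(counts), 5L)
  expect_equal(counts["present", "normal"], 2L)   # r1, r2 read C at 3
  expect_equal(counts["present", "cancer"], 2L)   # r4, r6 read C at 3

})

test_that("binary-variable counts equal a brute-force recount", {
  d <- demo_design()
  set.seed(701)
  obs <- simulate_wgbs_reads(default_calibrated_model(d), d$loci$KIAA1539,
                             read_length_bp = 25, n_fragments = 30,
                             n_samples = c(normal = 3, cancer = 3),
                             seed = 702)
  vars <- enumerate_variables(c(KIAA1539 = 5))
  cov_list <- lapply(strsplit(obs$covered, ","), as.integer)
  for (k in sample.int(nrow(vars), 15)) {
    v <- vars[k, ]
    want <- matrix(0L, 2, 2,
                   dimnames = list(c("present", "absent"),
                                   c("normal", "cancer")))
    for (r in seq_len(nrow(obs))) {
      pos <- c(v$i, if (v$kind == "pair") v$j)
      idx <- match(pos, cov_list[[r]])
      if (anyNA(idx)) next
      st <- substring(obs$states[r], idx, idx)
      present <- all(st == c(v$status_i,
                             if (v$kind == "pair") v$status_j))
      want[if (present) 1 else 2, obs$group[r]] <-
        want[if (present) 1 else 2, obs$group[r]] + 1L
    }
    expect_equal(evaluate_binary_variable(obs, v), want)
  }
})

test_that("association testing follows the expected-count branch rule", {
  # balanced null table: chi-square branch, p = 1
  r <- test_association(matrix(c(10, 10, 10, 10), 2))
  expect_equal(r$test, "chi-square")
  expect_equal(r$p, 1)
  # small diagonal table: all expected 2.5 < 5, Fisher branch
  r <- test_association(matrix(c(5, 0, 0, 5), 2))
  expect_equal(r$test, "fisher")
  expect_equal(r$p, 2 / 252, tolerance = 1e-12)
  # large table: all expected 30, chi-square branch
  r <- test_association(matrix(c(50, 10, 10, 50), 2))
  expect_equal(r$test, "chi-square")
  expect_equal(unique(as.vector(r$expected)), 30)
  # zero margin: degenerate, p = 1
  r <- test_association(matrix(c(0, 0, 7, 9), 2, byrow = TRUE))
  expect_equal(r$test, "degenerate")
  expect_equal(r$p, 1)
})

test_that("the Fisher branch equals hypergeometric enumeration on small tables", {
  set.seed(703)
  for (rep in 1:15) {
    tab <- matrix(rpois(4, 4), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    exp_counts <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (all(exp_counts >= 5)) next
    # enumerate all tables with these margins
    rs <- rowSums(tab); cs <- colSums(tab)
    a_range <- max(0, cs[1] - rs[2]):min(rs[1], cs[1])
    probs <- vapply(a_range, function(a) {
      stats::dhyper(a, rs[1], rs[2], cs[1])
    }, numeric(1))
    p_obs <- stats::dhyper(tab[1, 1], rs[1], rs[2], cs[1])
    want <- sum(probs[probs <= p_obs + 1e-12])
    expect_equal(test_association(tab)$p, want, tolerance = 1e-9)
  }
})

test_that("locus screening emits the full enumeration with the locus-family adjustment", {
  d <- demo_design()
  m0 <- noiseless_model(d)
  obs <- simulate_wgbs_reads(m0, d$loci$GSTP1, read_length_bp = 40,
                             n_fragments = 20,
                             n_samples = c(normal = 3, cancer = 5),
                             seed = 704)
  res <- screen_locus(obs, d$loci$GSTP1)
  expect_equal(nrow(res), 561L)
  expect_true(all(res$p_adj <= 1))
  expect_equal(res$p_adj, pmin(1, res$p * 561))
  obs5 <- simulate_wgbs_reads(m0, d$loci$KIAA1539, read_length_bp = 25,
                              n_fragments = 10,
                              n_samples = c(normal = 2, cancer = 2),
                              seed = 705)
  res5 <- screen_locus(obs5, d$loci$KIAA1539)
  expect_equal(nrow(res5), 45L)
  expect_equal(res5$p_adj, pmin(1, res5$p * 45))
})

test_that("an all-normal input yields degenerate tests with p = 1", {
  d <- demo_design()
  obs <- simulate_wgbs_reads(noiseless_model(d), d$loci$KIAA1539,
                             read_length_bp = 25, n_fragments = 10,
                             n_samples = c(normal = 3, cancer = 0),
                             seed = 706)
  res <- screen_locus(obs, d$loci$KIAA1539)
  expect_true(all(res$p == 1))
  expect_true(all(res$p_adj == 1))
})

test_that("fully covering WGBS reads agree with amplicon proportions", {
  d <- demo_design()
  loc <- d$loci$KIAA1539
  set.seed(707)
  n <- 400
  patterns <- replicate(n, paste(sample(c("C", "T"), 5, replace = TRUE,
                                        prob = c(.3, .7)), collapse = ""))
  obs <- tibble::tibble(
    read_id = sprintf("r%d", 1:n), sample_id = "s", group = "cancer",
    covered = "1,2,3,4,5", states = patterns)
  tb <- tiny_pattern_table(patterns, sample_id = "s", locus = "KIAA1539")
  res <- screen_locus(obs, loc)
  vars <- enumerate_variables(c(KIAA1539 = 5))
  for (k in sample.int(nrow(vars), 10)) {
    v <- vars[k, ]
    row <- res[res$variable == v$variable, ]
    expect_equal(row$present_cancer / row$n_cancer,
                 compute_variable(tb, "s", v))
  }
})
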