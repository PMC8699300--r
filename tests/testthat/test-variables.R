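test_that("variable enumeration reproduces the published family sizes", {
  expect_equal(nrow(enumerate_variables(c(GSTP1 = 17))), 561L)
  expect_equal(nrow(enumerate_variables(demo_design())), 1167L)
  expect_equal(nrow(enumerate_variables(c(X = 1))), 1L)
  # n + 2n(n-1) against explicit enumeration for a range of n
  for (n in c(2, 3, 5, 10, 17, 20)) {
    expect_equal(nrow(enumerate_variables(setNames(n, "L"))),
                 n + 2 * n * (n - 1))
  }
})

test_that("enumeration order is deterministic and names round-trip", {
  v <- enumerate_variables(c(AB = 3))
  expect_equal(v$variable[1:3], c("AB.C1", "AB.C2", "AB.C3"))
  expect_equal(v$variable[4:7], c("AB.C1.C2", "AB.C1.T2", "AB.T1.C2",
                                  "AB.T1.T2"))
  for (nm in v$variable) {
    p <- parse_variable_name(nm)
    expect_equal(p$variable, nm)
    expect_false(p$complement)
  }
  p <- parse_variable_name("GSTP1.T3")
  expect_true(p$complement)
  expect_error(parse_variable_name("GSTP1.C3.C3x"),
               class = "epialleler_error_schema")
})

test_that("proportions match direct counting on explicit reads", {
  tb <- tiny_pattern_table(c("CC", "CT", "TC", "TT"), locus = "L2")
  for (nm in c("L2.C1.C2", "L2.C1.T2", "L2.T1.C2", "L2.T1.T2")) {
    expect_equal(compute_variable(tb, "S1", nm), 0.25)
  }
  all_meth <- tiny_pattern_table(rep(strrep("C", 17), 10))
  expect_equal(compute_variable(all_meth, "S1", "GSTP1.C9"), 1.0)
  expect_equal(compute_variable(all_meth, "S1", "GSTP1.C9.T17"), 0.0)
  expect_equal(compute_variable(all_meth, "S1", "GSTP1.T9"), 0.0)
  empty <- tiny_pattern_table("CC", locus = "L2")
  expect_error(compute_variable(empty, "S2", "L2.C1"),
               class = "epialleler_error_empty_denominator")
})

test_that("a random 200-read fixture equals the brute-force recount", {
  set.seed(401)
  n <- 5
  patterns <- replicate(200, paste(sample(c("C", "T"), n, replace = TRUE),
                                   collapse = ""))
  tb <- tiny_pattern_table(patterns, locus = "KIAA1539")
  rows <- tibble::as_tibble(tb)
  vars <- enumerate_variables(c(KIAA1539 = 5))
  for (k in seq_len(nrow(vars))) {
    v <- vars[k, ]
    want <- brute_proportion(rows$pattern, rows$count, v$i, v$status_i,
                             if (v$kind == "pair") v$j else NULL,
                             if (v$kind == "pair") v$status_j else NULL)
    expect_equal(compute_variable(tb, "S1", v), want, tolerance = 1e-12)
  }
})

test_that("variable matrices satisfy normalisation and marginal identities", {
  d <- demo_design()
  sc <- simulate_pattern_cohort(noiseless_model(d), d,
                                reads_per_sample = 300, seed = 17)
  vm <- build_variable_matrix(sc$table, d)
  vals <- as.matrix(tibble::as_tibble(vm)[, variable_names(vm)])
  expect_true(all(vals >= 0 & vals <= 1))
  vars <- attr(vm, "variables")
  pairs <- dplyr::distinct(vars[vars$kind == "pair", c("locus", "i", "j")])
  set.seed(1)
  pairs <- pairs[sample.int(nrow(pairs), 40), ]
  for (k in seq_len(nrow(pairs))) {
    loc <- pairs$locus[k]; i <- pairs$i[k]; j <- pairs$j[k]
    cc <- vals[, sprintf("%s.C%d.C%d", loc, i, j)]
    ct <- vals[, sprintf("%s.C%d.T%d", loc, i, j)]
    tc <- vals[, sprintf("%s.T%d.C%d", loc, i, j)]
    tt <- vals[, sprintf("%s.T%d.T%d", loc, i, j)]
    expect_equal(cc + ct + tc + tt, rep(1, nrow(vals)), tolerance = 1e-9)
    expect_equal(cc + ct, vals[, sprintf("%s.C%d", loc, i)],
                 tolerance = 1e-9)
  }
})

test_that("read order never changes a proportion", {
  set.seed(402)
  patterns <- replicate(100, paste(sample(c("C", "T"), 5, replace = TRUE),
                                   collapse = ""))
  tb1 <- tiny_pattern_table(patterns, locus = "KIAA1539")
  tb2 <- tiny_pattern_table(rev(patterns), locus = "KIAA1539")
  for (nm in c("KIAA1539.C2", "KIAA1539.C1.T4", "KIAA1539.T3.T5")) {
    expect_equal(compute_variable(tb1, "S1", nm),
                 compute_variable(tb2, "S1", nm))
  }
})

test_that("noiseless cohorts reproduce truth-table proportions exactly", {
  d <- demo_design()
  sc <- simulate_pattern_cohort(noiseless_model(d), d,
                                reads_per_sample = 400, seed = 23)
  vm <- build_variable_matrix(sc$table, d)
  truth_tb <- pattern_table(sc$truth)
  set.seed(2)
  some_vars <- sample(variable_names(vm), 25)
  for (s in sample(vm$sample_id, 5)) {
    for (nm in some_vars) {
      expect_equal(vm[[nm]][vm$sample_id == s],
                   compute_variable(truth_tb, s, nm))
    }
  }
})

test_that("group summaries match direct quantile and correlation recomputation", {
  d <- demo_design()
  sc <- simulate_pattern_cohort(default_calibrated_model(d), d,
                                reads_per_sample = 500, seed = 31)
  vm <- build_variable_matrix(sc$table, d)
  s <- summarize_groups(vm)
  # median / quartiles on a hand-made value set
  row <- s$quartiles[s$quartiles$variable == "GSTP1.C1" &
                       s$quartiles$group == "HD", ]
  vals <- vm$GSTP1.C1[vm$group == "HD"]
  expect_equal(row$median, median(vals))
  expect_equal(row$q1, quantile(vals, 0.25, names = FALSE))
  expect_equal(row$q3, quantile(vals, 0.75, names = FALSE))
  # correlations: recompute one pair directly on finite log2 values
  cr <- s$correlations
  one <- cr[cr$group == "PCa" & cr$var_a == "GSTP1.C3" &
              cr$var_b == "GSTP1.C9", ]
  a <- log2(vm$GSTP1.C3[vm$group == "PCa"])
  b <- log2(vm$GSTP1.C9[vm$group == "PCa"])
  ok <- is.finite(a) & is.finite(b)
  expect_equal(one$r, cor(a[ok], b[ok]))
  expect_equal(one$n_used, sum(ok))
})

test_that("quartile summaries match a worked example", {
  # five samples with proportions 1..5%: median 3%, quartiles 2% and 4%
  vm <- structure(
    tibble::tibble(sample_id = sprintf("S%d", 1:5), group = "HD",
                   L1.C1 = c(0.01, 0.02, 0.03, 0.04, 0.05)),
    variables = tibble::tibble(variable = "L1.C1", locus = "L1",
                               kind = "single", i = 1L, j = NA_integer_,
                               status_i = "C", status_j = NA_character_),
    class = c("variable_matrix", class(tibble::tibble())))
  q <- summarize_groups(vm)$quartiles
  expect_equal(q$median, 0.03)
  expect_equal(q$q1, 0.02)
  expect_equal(q$q3, 0.04)
})
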