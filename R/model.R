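#' Generative epiallele mixture model
#'
#' Each (group, locus) carries a mixture of epiallele classes; a class is a
#' per-CpG methylation probability vector (0/1 entries give deterministic
#' patterns) with a mixture weight.  Reads are molecules drawn from the
#' mixture, then passed through independent per-base noise: bisulfite
#' conversion failure at non-CpG cytosines, inappropriate conversion of
#' methylated CpGs, and sequencing substitution errors.
#'
#' @param classes tibble with columns `group`, `locus`, `class_id`, `weight`
#'   and a list-column `probs` (numeric vector, one entry per CpG).
#' @param conversion_failure_rate probability a non-CpG cytosine stays
#'   unconverted (reads C instead of T).  Default 0.01.
#' @param inappropriate_conversion_rate probability a methylated CpG
#'   cytosine is converted anyway (reads T).  Default 0.005.
#' @param sequencing_error_rate per-base substitution probability.
#'   Default 0.001.
#' @param coverage_range integer range; reads per sample x locus are drawn
#'   uniformly from it.  Default `c(5000, 20000)`.
#' @param chimera_rate fraction of extra reads emitted with an unused
#'   barcode pair.  Default 0.01.
#' @param dispersion_sdlog per-sample log-normal jitter (sd on the log
#'   scale) applied multiplicatively to class weights, which are then
#'   renormalised; models between-patient heterogeneity.  Default 0.2.
#' @return object of class `epiallele_model`.
#' @export
epiallele_model <- function(classes,
                            conversion_failure_rate = 0.01,
                            inappropriate_conversion_rate = 0.005,
                            sequencing_error_rate = 0.001,
                            coverage_range = c(5000L, 20000L),
                            chimera_rate = 0.01,
                            dispersion_sdlog = 0.2) {
  classes <- as_tibble(classes)
  stopifnot(all(c("group", "locus", "class_id", "weight", "probs") %in%
                  names(classes)))
  rates <- c(conversion_failure_rate, inappropriate_conversion_rate,
             sequencing_error_rate, chimera_rate)
  if (any(rates < 0 | rates > 1)) abort_schema("rates must lie in [0, 1]")
  sums <- classes |>
    group_by(group, locus) |>
    summarise(s = sum(weight), .groups = "drop")
  if (any(abs(sums$s - 1) > 1e-9)) {
    abort_schema("mixture weights must sum to 1 per (group, locus)")
  }
  if (any(unlist(classes$probs) < 0 | unlist(classes$probs) > 1)) {
    abort_schema("per-CpG methylation probabilities must lie in [0, 1]")
  }
  structure(
    list(classes = classes,
         conversion_failure_rate = conversion_failure_rate,
         inappropriate_conversion_rate = inappropriate_conversion_rate,
         sequencing_error_rate = sequencing_error_rate,
         coverage_range = as.integer(coverage_range),
         chimera_rate = chimera_rate,
         dispersion_sdlog = dispersion_sdlog),
    class = "epiallele_model"
  )
}

# helper: class with a fixed set of methylated positions
.cls <- function(group, locus, id, weight, n, meth_at = integer(0)) {
  p <- rep(0, n); p[meth_at] <- 1
  tibble(group = group, locus = locus, class_id = id,
         weight = weight, probs = list(p))
}

#' Default cohort model calibrated to the published group means
#'
#' Builds the mixture the synthetic cohort is simulated from.  Per locus:
#'
#' * **GSTP1** -- mostly unmethylated molecules everywhere; a fully
#'   methylated class and a C3+C9 marker class give the PCa group an
#'   expected `GSTP1.C9` of 8.35% against 0.16% elsewhere; classes
#'   methylated at C3 or C13 bring `GSTP1.T3.T13` to 99.5% in HD and 88.5%
#'   in the tumor groups (BPH and PCa).
#' * **RNF219** -- a 1% scattered single-position class at every CpG in all
#'   groups (so single-position variables do not discriminate) plus a fully
#'   methylated class at weight 0.2% in HD/PCa but only 0.005% in BPH, so
#'   every pairwise-CC variable separates BPH from the rest in the
#'   0.005-0.2% regime.
#' * **KIAA1539** -- identical mixture in all groups (a null locus).
#'
#' @param design an [amplicon_design()] (CpG counts are taken from it).
#' @return an [epiallele_model()].
#' @export
default_calibrated_model <- function(design) {
  n <- vapply(design$loci, function(l) length(l$cpg_positions), integer(1))
  ng <- n[["GSTP1"]]; nr <- n[["RNF219"]]; nk <- n[["KIAA1539"]]
  cl <- list()

  # GSTP1: M = fully methylated; A39 = C3+C9 marker; B13 = C13-only
  cl$g_hd <- bind_rows(
    .cls("HD", "GSTP1", "M", 0.0016, ng, seq_len(ng)),
    .cls("HD", "GSTP1", "B13", 0.0034, ng, 13),
    .cls("HD", "GSTP1", "U", 1 - 0.0016 - 0.0034, ng)
  )
  cl$g_bph <- bind_rows(
    .cls("BPH", "GSTP1", "M", 0.0016, ng, seq_len(ng)),
    .cls("BPH", "GSTP1", "B13", 0.1134, ng, 13),
    .cls("BPH", "GSTP1", "U", 1 - 0.0016 - 0.1134, ng)
  )
  cl$g_pca <- bind_rows(
    .cls("PCa", "GSTP1", "M", 0.06, ng, seq_len(ng)),
    .cls("PCa", "GSTP1", "A39", 0.0235, ng, c(3, 9)),
    .cls("PCa", "GSTP1", "B13", 0.0315, ng, 13),
    .cls("PCa", "GSTP1", "U", 1 - 0.06 - 0.0235 - 0.0315, ng)
  )

  # RNF219: scattered singles everywhere + rare fully methylated class
  rnf <- function(group, w_m) {
    singles <- bind_rows(lapply(seq_len(nr), function(i) {
      .cls(group, "RNF219", paste0("S", i), 0.01, nr, i)
    }))
    bind_rows(
      singles,
      .cls(group, "RNF219", "M", w_m, nr, seq_len(nr)),
      .cls(group, "RNF219", "U", 1 - 0.01 * nr - w_m, nr)
    )
  }
  cl$r_hd <- rnf("HD", 0.002)
  cl$r_pca <- rnf("PCa", 0.002)
  cl$r_bph <- rnf("BPH", 0.00005)

  # KIAA1539: identical in all groups
  kiaa <- function(group) {
    singles <- bind_rows(lapply(seq_len(nk), function(i) {
      .cls(group, "KIAA1539", paste0("S", i), 0.004, nk, i)
    }))
    bind_rows(
      singles,
      .cls(group, "KIAA1539", "M", 0.002, nk, seq_len(nk)),
      .cls(group, "KIAA1539", "U", 1 - 0.004 * nk - 0.002, nk)
    )
  }
  cl$k <- bind_rows(kiaa("HD"), kiaa("BPH"), kiaa("PCa"))

  epiallele_model(bind_rows(cl))
}

#' Expected value of a variable under an epiallele model
#'
#' The model-level expectation (no sampling, no noise): CpG states are
#' independent within a class, so a joint-status expectation is the
#' weight-averaged product of per-position probabilities.
#'
#' @param model an [epiallele_model()].
#' @param group group label.
#' @param spec variable name or a row from [enumerate_variables()].
#' @return expected proportion in `[0, 1]`.
#' @export
expected_variable_value <- function(model, group, spec) {
  if (is.character(spec)) spec <- parse_variable_name(spec)
  cls <- model$classes[model$classes$group == group &
                         model$classes$locus == spec$locus, ]
  if (nrow(cls) == 0) abort_schema("no classes for that group/locus")
  pr <- function(p, pos, status) if (status == "C") p[pos] else 1 - p[pos]
  contrib <- vapply(seq_len(nrow(cls)), function(k) {
    p <- cls$probs[[k]]
    v <- pr(p, spec$i, spec$status_i)
    if (identical(spec$kind, "pair")) v <- v * pr(p, spec$j, spec$status_j)
    cls$weight[k] * v
  }, numeric(1))
  val <- sum(contrib)
  if (isTRUE(spec[["complement"]])) 1 - val else val
}

#' Collapse a model to a null (no group differences) version
#'
#' Replaces every group's mixture at every locus by the mixture of one
#' reference group, so all between-group differences vanish while the
#' noise model, coverage and dispersion stay as configured.  Used for
#' type-I-error control experiments.
#'
#' @param model an [epiallele_model()].
#' @param reference_group group whose mixtures are copied to all groups.
#' @return an [epiallele_model()].
#' @export
null_model <- function(model, reference_group = "HD") {
  ref <- model$classes[model$classes$group == reference_group, ]
  groups <- unique(model$classes$group)
  classes <- bind_rows(lapply(groups, function(g) {
    out <- ref
    out$group <- g
    out
  }))
  model$classes <- classes
  model
}

#' Simulate a PSA covariate for the cohort
#'
#' Draws per-sample total PSA (ng/mL) from group-specific log-normal
#' distributions whose mean and SD match the cohort description: 17.5 +/-
#' 12.3 in PCa, 10.7 +/- 8.5 in BPH, 1.2 +/- 0.7 in HD.  Returned in the
#' covariate format accepted by [build_variable_matrix()].
#'
#' @param design an [amplicon_design()].
#' @param params named list of `c(mean, sd)` per group.
#' @return tibble with columns `sample_id`, `PSA`.
#' @export
simulate_psa_covariate <- function(design,
                                   params = list(PCa = c(17.5, 12.3),
                                                 BPH = c(10.7, 8.5),
                                                 HD = c(1.2, 0.7))) {
  s <- design$scheme$samples
  psa <- vapply(seq_len(nrow(s)), function(r) {
    p <- params[[s$group[r]]]
    sdlog <- sqrt(log(1 + (p[2] / p[1])^2))
    meanlog <- log(p[1]) - sdlog^2 / 2
    stats::rlnorm(1, meanlog, sdlog)
  }, numeric(1))
  tibble(sample_id = s$sample_id, PSA = round(psa, 1))
}
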