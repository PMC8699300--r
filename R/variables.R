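#' Enumerate the single- and joint-position methylation-status variables
#'
#' For a locus with n CpGs the family contains the n single-position
#' methylated-proportion variables (`GENE.Ci`) and, for every unordered pair
#' i < j, the four joint-status proportions (`GENE.Ci.Cj`, `GENE.Ci.Tj`,
#' `GENE.Ti.Cj`, `GENE.Ti.Tj`): n + 2n(n-1) variables per locus.  Across the
#' three-locus assay (17, 17 and 5 CpGs) this yields the full 1167-variable
#' family.  Single-position unmethylated variables are not enumerated (they
#' are the complements `1 - Ci`), but [parse_variable_name()] accepts them.
#'
#' Order is deterministic: loci in design order, singles by position, then
#' pairs lexicographically by (i, j) with statuses in the order CC, CT, TC,
#' TT.
#'
#' @param design an [amplicon_design()], or a named integer vector of CpG
#'   counts per locus.
#' @return tibble with columns `variable`, `locus`, `kind` (`"single"` or
#'   `"pair"`), `i`, `j`, `status_i`, `status_j` (`NA` for singles).
#' @export
#' @examples
#' nrow(enumerate_variables(c(GSTP1 = 17)))  # 561
enumerate_variables <- function(design) {
  n_cpg <- if (inherits(design, "amplicon_design")) {
    vapply(design$loci, function(l) length(l$cpg_positions), integer(1))
  } else {
    stopifnot(!is.null(names(design)))
    as.integer(design) |> setNames(names(design))
  }
  per_locus <- lapply(names(n_cpg), function(nm) {
    n <- n_cpg[[nm]]
    singles <- tibble(
      locus = nm, kind = "single", i = seq_len(n), j = NA_integer_,
      status_i = "C", status_j = NA_character_
    )
    if (n < 2) {
      pairs <- tibble(locus = character(), kind = character(),
                      i = integer(), j = integer(),
                      status_i = character(), status_j = character())
    } else {
      ij <- tidyr::expand_grid(i = seq_len(n), j = seq_len(n)) |>
        filter(i < j)
      st <- tibble(status_i = c("C", "C", "T", "T"),
                   status_j = c("C", "T", "C", "T"))
      pairs <- tidyr::expand_grid(ij, st) |>
        mutate(locus = nm, kind = "pair") |>
        arrange(i, j, status_i, status_j)
    }
    bind_rows(singles, pairs[, names(singles)])
  })
  out <- bind_rows(per_locus)
  out$variable <- ifelse(
    out$kind == "single",
    sprintf("%s.%s%d", out$locus, out$status_i, out$i),
    sprintf("%s.%s%d.%s%d", out$locus, out$status_i, out$i,
            out$status_j, out$j)
  )
  out[, c("variable", "locus", "kind", "i", "j", "status_i", "status_j")]
}

#' Parse a variable name such as "GSTP1.C9" or "RNF219.C4.T10"
#'
#' Single-position T names (e.g. `"GSTP1.T3"`) are accepted and flagged as
#' complements of the corresponding C variable.
#'
#' @param name character scalar.
#' @return one-row tibble like [enumerate_variables()] plus a logical
#'   `complement` column (`TRUE` for single-T names).
#' @export
parse_variable_name <- function(name) {
  m <- stringr::str_match(
    name, "^([^.]+)\\.([CT])(\\d+)(?:\\.([CT])(\\d+))?$"
  )
  if (is.na(m[1, 1])) {
    abort_schema(sprintf("cannot parse variable name '%s'", name))
  }
  locus <- m[1, 2]
  i <- as.integer(m[1, 4]); si <- m[1, 3]
  if (is.na(m[1, 5])) {
    tibble(variable = name, locus = locus, kind = "single",
           i = i, j = NA_integer_,
           status_i = "C", status_j = NA_character_,
           complement = si == "T")
  } else {
    j <- as.integer(m[1, 6]); sj <- m[1, 5]
    if (i >= j) abort_schema(sprintf("pair variable '%s' needs i < j", name))
    tibble(variable = name, locus = locus, kind = "pair",
           i = i, j = j, status_i = si, status_j = sj, complement = FALSE)
  }
}

#' Per-molecule pattern table
#'
#' Counts of retained reads per full-length methylation pattern, with
#' exclusion tallies.  Produced by [filter_reads()], [process_reads()] or
#' [simulate_pattern_cohort()].
#'
#' @param counts tibble with columns `sample_id`, `group`, `locus`,
#'   `pattern` (string over C/T, one character per CpG), `count`.
#' @param exclusions tibble with columns `locus`, `sample_id` (`NA` when the
#'   read could not be assigned), `disposition`, `n`.
#' @return object of class `pattern_table` (a tibble).
#' @export
pattern_table <- function(counts, exclusions = NULL) {
  counts <- as_tibble(counts)
  stopifnot(all(c("sample_id", "group", "locus", "pattern", "count") %in%
                  names(counts)))
  if (any(counts$count < 0)) abort_schema("pattern counts must be >= 0")
  exclusions <- exclusions %||%
    tibble(locus = character(), sample_id = character(),
           disposition = character(), n = integer())
  structure(counts, exclusions = as_tibble(exclusions),
            class = c("pattern_table", class(counts)))
}

#' Exclusion tallies of a pattern table
#' @param table a [pattern_table()].
#' @return tibble with columns `locus`, `sample_id`, `disposition`, `n`.
#' @export
exclusion_tallies <- function(table) attr(table, "exclusions")

#' Compute one variable for one sample from a pattern table
#'
#' The proportion of retained molecules whose CpG state matches the variable
#' statuses at its position(s), out of all retained molecules at the locus
#' (a single shared denominator, because reads with unrecognized sites were
#' excluded upstream).
#'
#' @param table a [pattern_table()].
#' @param sample sample id.
#' @param spec one-row tibble from [enumerate_variables()] or
#'   [parse_variable_name()], or a variable name string.
#' @return proportion in `[0, 1]`.
#' @export
compute_variable <- function(table, sample, spec) {
  if (is.character(spec)) spec <- parse_variable_name(spec)
  rows <- table[table$sample_id == sample & table$locus == spec$locus, ]
  total <- sum(rows$count)
  if (total < 1) {
    rlang::abort(sprintf("sample %s has no retained reads at locus %s",
                         sample, spec$locus),
                 class = "epialleler_error_empty_denominator")
  }
  ci <- substr(rows$pattern, spec$i, spec$i)
  hit <- ci == spec$status_i
  if (identical(spec$kind, "pair")) {
    hit <- hit & substr(rows$pattern, spec$j, spec$j) == spec$status_j
  }
  p <- sum(rows$count[hit]) / total
  if (isTRUE(spec[["complement"]])) 1 - p else p
}

# proportions of all enumerated variables of one locus for one vector of
# pattern counts; vectorised over patterns via indicator algebra
locus_variable_values <- function(patterns, counts, n_cpg, vars) {
  total <- sum(counts)
  C <- chars_at(patterns, seq_len(n_cpg)) == "C"
  w <- counts / total
  pC <- as.vector(crossprod(C, w))             # single Ci
  WC <- C * w
  CC <- crossprod(C, WC)                       # sum w over reads C at i and j
  Ct <- crossprod(C, (!C) * w)                 # C at i, T at j
  Tc <- crossprod(!C, WC)
  TT <- crossprod(!C, (!C) * w)
  val <- numeric(nrow(vars))
  sing <- vars$kind == "single"
  val[sing] <- pC[vars$i[sing]]
  st <- paste0(vars$status_i, vars$status_j)
  for (s in c("CC", "CT", "TC", "TT")) {
    rows <- which(!sing & st == s)
    if (length(rows) == 0) next
    mat <- switch(s, CC = CC, CT = Ct, TC = Tc, TT = TT)
    val[rows] <- mat[cbind(vars$i[rows], vars$j[rows])]
  }
  val
}

#' Build the samples-by-variables proportion matrix
#'
#' @param table a [pattern_table()] covering every sample and locus.
#' @param design an [amplicon_design()].
#' @param covariates optional data frame with column `sample_id` plus numeric
#'   covariate columns (e.g. `PSA`); appended and flagged as non-proportion.
#' @return a tibble of class `variable_matrix`: `sample_id`, `group`, then
#'   one column per enumerated variable (proportions in `[0, 1]`), then any
#'   covariates.  Attributes: `variables` (the enumeration), `denominators`
#'   (per sample x locus retained totals), `covariate_names`.
#' @export
build_variable_matrix <- function(table, design, covariates = NULL) {
  vars <- enumerate_variables(design)
  samples <- design$scheme$samples
  present <- unique(table$sample_id)
  denom <- table |>
    group_by(sample_id, locus) |>
    summarise(retained_total = sum(count), .groups = "drop")
  # a usable sample needs retained reads at every locus
  full <- denom |>
    filter(retained_total >= 1) |>
    count(sample_id) |>
    filter(n == length(design$loci)) |>
    pull(sample_id)
  dropped <- setdiff(present, full)
  if (length(dropped) > 0) {
    rlang::warn(sprintf("dropping %d sample(s) without reads at every locus: %s",
                        length(dropped), paste(dropped, collapse = ", ")))
  }
  keep <- samples$sample_id[samples$sample_id %in% full]
  if (length(keep) == 0) abort_schema("no sample has reads at every locus")
  if (anyDuplicated(keep)) abort_duplicate_assignment("duplicate sample id")

  mat <- matrix(NA_real_, nrow = length(keep), ncol = nrow(vars),
                dimnames = list(keep, vars$variable))
  for (loc in names(design$loci)) {
    n_cpg <- length(design$loci[[loc]]$cpg_positions)
    v_loc <- vars[vars$locus == loc, ]
    for (s in keep) {
      rows <- table[table$sample_id == s & table$locus == loc, ]
      mat[s, v_loc$variable] <-
        locus_variable_values(rows$pattern, rows$count, n_cpg, v_loc)
    }
  }
  out <- bind_cols(
    tibble(sample_id = keep,
           group = samples$group[match(keep, samples$sample_id)]),
    as_tibble(mat)
  )
  cov_names <- character(0)
  if (!is.null(covariates)) {
    covariates <- as_tibble(covariates)
    stopifnot("sample_id" %in% names(covariates))
    cov_names <- setdiff(names(covariates), "sample_id")
    out <- left_join(out, covariates, by = "sample_id")
  }
  structure(out,
            variables = vars,
            denominators = denom[denom$sample_id %in% keep, ],
            covariate_names = cov_names,
            class = c("variable_matrix", class(out)))
}

#' Names of the methylation variables in a variable matrix
#' @param vm a [build_variable_matrix()] result.
#' @return character vector.
#' @export
variable_names <- function(vm) attr(vm, "variables")$variable

#' Per-group summaries backing box-plot and correlation displays
#'
#' Medians and quartiles of every variable per group, and per-group Pearson
#' correlation matrices of the binary logarithms of the single-position
#' variables.  log2 of a zero proportion is non-finite and is excluded
#' pairwise from the correlations; a correlation with fewer than two finite
#' complete pairs (e.g. a variable constant within a group) is `NA`.
#'
#' @param vm a [build_variable_matrix()] result.
#' @return list with `quartiles` (tibble: variable, group, q1, median, q3)
#'   and `correlations` (tibble: locus, group, var_a, var_b, r, n_used).
#' @export
summarize_groups <- function(vm) {
  vars <- attr(vm, "variables")
  long <- tidyr::pivot_longer(as_tibble(vm)[, c("sample_id", "group", vars$variable)],
                              -c(sample_id, group),
                              names_to = "variable", values_to = "value")
  quart <- long |>
    group_by(variable, group) |>
    summarise(q1 = quantile(value, 0.25, names = FALSE),
              median = median(value),
              q3 = quantile(value, 0.75, names = FALSE),
              .groups = "drop")

  singles <- vars[vars$kind == "single", ]
  cors <- list()
  for (loc in unique(singles$locus)) {
    v <- singles$variable[singles$locus == loc]
    if (length(v) < 2) next
    for (g in unique(vm$group)) {
      x <- log2(as.matrix(as_tibble(vm)[vm$group == g, v]))
      x[!is.finite(x)] <- NA
      pairs <- utils::combn(v, 2)
      for (k in seq_len(ncol(pairs))) {
        a <- x[, pairs[1, k]]; b <- x[, pairs[2, k]]
        ok <- is.finite(a) & is.finite(b)
        r <- if (sum(ok) >= 2 && stats::sd(a[ok]) > 0 && stats::sd(b[ok]) > 0) {
          cor(a[ok], b[ok])
        } else {
          NA_real_
        }
        cors[[length(cors) + 1L]] <- tibble(
          locus = loc, group = g,
          var_a = pairs[1, k], var_b = pairs[2, k],
          r = r, n_used = sum(ok))
      }
    }
  }
  list(quartiles = quart, correlations = bind_rows(cors))
}
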