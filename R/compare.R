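#' Screen every variable for group discrimination
#'
#' Runs the full comparison machinery for one-vs-rest contrasts: exact
#' Mann-Whitney p with Bonferroni adjustment over the whole family,
#' group means, sensitivity at 100% specificity and the converse,
#' separation cutoff (with ratio under complete separation), and optionally
#' balanced-weight LOOCV logistic metrics with the DeLong AUC interval.
#'
#' Proportions are reported in percent; covariate columns (e.g. PSA) pass
#' through the identical machinery on their raw scale and do not enlarge
#' the Bonferroni family.
#'
#' @param vm a [build_variable_matrix()] result.
#' @param contrasts positive group labels to screen, each against the pool
#'   of the remaining groups.
#' @param cv compute the cross-validation block (LOOCV logistic + DeLong)?
#'   Skipping it makes large screens much faster.
#' @param mw one of `"exact"` (exact test for every variable) or
#'   `"screened"`: a conservative normal-approximation prescreen, with the
#'   exact test recomputed for every variable whose approximate p falls
#'   below `screen_cutoff` (far above any significance boundary in use, so
#'   decisions at conventional thresholds are unchanged); the `p_method`
#'   column records which p each row carries.
#' @param screen_cutoff prescreen boundary used when `mw = "screened"`.
#' @param m_adjust Bonferroni family size; defaults to
#'   `length(contrasts) * <number of methylation variables>`.
#' @return tibble of class `epi_comparison`: one row per contrast x
#'   variable with columns `contrast`, `variable`, `is_covariate`, `p`,
#'   `p_method`, `p_adj`, `mean_pos`, `mean_neg`, `sens_at_spec100`,
#'   `spec_at_sens100`, `cutoff`, `ratio`, `complete_separation`,
#'   `cv_accuracy`, `cv_sensitivity`, `cv_specificity`, `cv_auc`,
#'   `cv_auc_lo`, `cv_auc_hi`.
#' @export
compare_all <- function(vm, contrasts = c("PCa", "HD", "BPH"), cv = TRUE,
                        mw = c("exact", "screened"), screen_cutoff = 1e-3,
                        m_adjust = NULL) {
  mw <- match.arg(mw)
  meth_vars <- variable_names(vm)
  cov_vars <- attr(vm, "covariate_names") %||% character(0)
  m <- m_adjust %||% (length(contrasts) * length(meth_vars))
  all_vars <- c(meth_vars, cov_vars)
  rows <- vector("list", length(contrasts) * length(all_vars))
  at <- 0L
  for (ct in contrasts) {
    is_pos <- vm$group == ct
    stopifnot(any(is_pos), any(!is_pos))
    for (v in all_vars) {
      vals <- vm[[v]]
      pos <- vals[is_pos]; neg <- vals[!is_pos]
      is_cov <- v %in% cov_vars
      if (mw == "screened") {
        p_apx <- mw_normal_p(pos, neg)
        if (p_apx < screen_cutoff) {
          p <- exact_mann_whitney(pos, neg); p_method <- "exact"
        } else {
          p <- p_apx; p_method <- "normal_approx"
        }
      } else {
        p <- exact_mann_whitney(pos, neg); p_method <- "exact"
      }
      sep <- separation_metrics(pos, neg)
      cut <- estimate_cutoff(pos, neg)
      scale <- if (is_cov) 1 else 100
      cvb <- list(accuracy = NA_real_, sensitivity = NA_real_,
                  specificity = NA_real_, auc = NA_real_, auc_ci = NULL)
      if (cv) cvb <- loocv_logistic(vm, ct, v)
      at <- at + 1L
      rows[[at]] <- tibble(
        contrast = ct, variable = v, is_covariate = is_cov,
        p = p, p_method = p_method, p_adj = bonferroni_adjust(p, m),
        mean_pos = scale * mean(pos), mean_neg = scale * mean(neg),
        sens_at_spec100 = sep$sens_at_spec100,
        spec_at_sens100 = sep$spec_at_sens100,
        cutoff = scale * cut$cutoff, ratio = cut$ratio,
        complete_separation = cut$complete_separation,
        cv_accuracy = cvb$accuracy, cv_sensitivity = cvb$sensitivity,
        cv_specificity = cvb$specificity, cv_auc = cvb$auc,
        cv_auc_lo = if (is.null(cvb$auc_ci)) NA_real_ else cvb$auc_ci[1],
        cv_auc_hi = if (is.null(cvb$auc_ci)) NA_real_ else cvb$auc_ci[2]
      )
    }
  }
  out <- bind_rows(rows)
  structure(out, m_adjust = m,
            class = c("epi_comparison", class(out)))
}

#' Filter a comparison table with the published report presets
#'
#' `"table4"` keeps adjusted p < 0.005 with sensitivity (at 100%
#' specificity) above 70%; `"table5"` keeps adjusted p < 1e-10 with
#' complete separation; `"table6"` keeps adjusted p < 3.5e-8; `"none"`
#' returns the table unchanged.  Covariate rows are always kept for
#' context.
#'
#' @param cmp an [compare_all()] result.
#' @param preset filter preset name.
#' @return filtered tibble, sorted by adjusted p.
#' @export
filter_report <- function(cmp, preset = c("none", "table4", "table5",
                                          "table6")) {
  preset <- match.arg(preset)
  keep <- switch(preset,
    none = rep(TRUE, nrow(cmp)),
    table4 = cmp$p_adj < 0.005 & cmp$sens_at_spec100 > 70,
    table5 = cmp$p_adj < 1e-10 & cmp$complete_separation,
    table6 = cmp$p_adj < 3.5e-8
  )
  out <- cmp[keep | cmp$is_covariate, ]
  out[order(out$p_adj), ]
}

#' @export
print.epi_comparison <- function(x, ...) {
  cat(sprintf("<epi_comparison> %d rows, Bonferroni m = %d\n",
              nrow(x), attr(x, "m_adjust")))
  NextMethod()
}

#' Tidy a comparison table
#'
#' Returns the per-variable statistics in a tibble (the object already is
#' one; `tidy()` strips the class and attributes for downstream use).
#'
#' @param x an `epi_comparison` object.
#' @param ... unused.
#' @return a plain tibble.
#' @method tidy epi_comparison
#' @export
tidy.epi_comparison <- function(x, ...) {
  as_tibble(x)
}

#' One-row summary of a comparison screen
#'
#' @param x an `epi_comparison` object.
#' @param ... unused.
#' @return tibble with the number of variables tested, the Bonferroni
#'   family size, and per-screen significant / completely separated counts.
#' @method glance epi_comparison
#' @export
glance.epi_comparison <- function(x, ...) {
  x |>
    filter(!is_covariate) |>
    group_by(contrast) |>
    summarise(
      n_variables = dplyr::n(),
      n_significant = sum(p_adj < 0.05),
      n_complete_separation = sum(complete_separation),
      .groups = "drop"
    ) |>
    mutate(m_adjust = attr(x, "m_adjust"))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Volcano-style overview of a comparison screen
#'
#' Plots -log10 adjusted p against the sensitivity achievable at 100%
#' specificity, faceted by contrast; completely separated variables are
#' highlighted.
#'
#' @param object an `epi_comparison` object.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot epi_comparison
#' @export
autoplot.epi_comparison <- function(object, ...) {
  dat <- filter(as_tibble(object), !is_covariate)
  ggplot2::ggplot(dat, ggplot2::aes(
    x = sens_at_spec100, y = -log10(pmax(p_adj, 1e-300)),
    colour = complete_separation)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_hline(yintercept = -log10(0.05), linetype = 2) +
    ggplot2::facet_wrap(~contrast) +
    ggplot2::labs(x = "sensitivity at 100% specificity (%)",
                  y = "-log10 adjusted p", colour = "complete\nseparation") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Group-wise scatter of two variables on the log2 scale
#'
#' Mirrors the published scatter displays: both axes are binary logarithms
#' of the proportion variables, and samples with a zero proportion (whose
#' log2 is non-finite) are flagged and plotted at the axis margin.
#'
#' @param vm a [build_variable_matrix()] result.
#' @param var_x,var_y variable names.
#' @return a ggplot object.
#' @export
plot_variable_scatter <- function(vm, var_x, var_y) {
  px <- predictor_frame(vm, var_x)[[1]]
  py <- predictor_frame(vm, var_y)[[1]]
  dat <- tibble(group = vm$group, x = log2(px), y = log2(py))
  fin <- dat |> filter(is.finite(x) & is.finite(y))
  inf <- dat |> filter(!is.finite(x) | !is.finite(y))
  floor_x <- min(fin$x, na.rm = TRUE) - 1
  floor_y <- min(fin$y, na.rm = TRUE) - 1
  inf <- mutate(inf,
                x = ifelse(is.finite(x), x, floor_x),
                y = ifelse(is.finite(y), y, floor_y))
  ggplot2::ggplot(fin, ggplot2::aes(x, y, colour = group)) +
    ggplot2::geom_point() +
    ggplot2::geom_point(data = inf, shape = 4) +
    ggplot2::labs(x = paste0("log2(", var_x, ")"),
                  y = paste0("log2(", var_y, ")")) +
    ggplot2::theme_minimal()
}

#' Box plots of single-position methylation levels by group
#'
#' @param vm a [build_variable_matrix()] result.
#' @param locus locus name to display.
#' @return a ggplot object.
#' @export
plot_single_positions <- function(vm, locus) {
  vars <- attr(vm, "variables")
  v <- vars$variable[vars$kind == "single" & vars$locus == locus]
  long <- tidyr::pivot_longer(
    as_tibble(vm)[, c("sample_id", "group", v)], -c(sample_id, group),
    names_to = "variable", values_to = "value")
  long$position <- factor(as.integer(sub(".*\\.C", "", long$variable)))
  ggplot2::ggplot(long, ggplot2::aes(position, 100 * value, fill = group)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::labs(x = "CpG position", y = "methylated (%)", title = locus) +
    ggplot2::theme_minimal()
}

#' Count Bonferroni-significant variables, quickly and exactly
#'
#' For bulk type-I-error experiments: a conservative tie-corrected normal
#' approximation prescreens every variable, and the exact Mann-Whitney test
#' is recomputed for each variable whose approximate p falls within two
#' orders of magnitude of the significance boundary, so the count of
#' adjusted p < `alpha` decisions equals the all-exact count.
#'
#' @param vm a [build_variable_matrix()] result.
#' @param contrasts positive group labels.
#' @param alpha significance level on the adjusted scale.
#' @param m_adjust Bonferroni family size (default: contrasts x variables).
#' @return integer: number of (contrast, variable) pairs with adjusted
#'   p < `alpha`.
#' @export
count_significant <- function(vm, contrasts = c("PCa", "HD", "BPH"),
                              alpha = 0.05, m_adjust = NULL) {
  vars <- variable_names(vm)
  m <- m_adjust %||% (length(contrasts) * length(vars))
  boundary <- alpha / m
  X <- as.matrix(as_tibble(vm)[, vars])
  total <- 0L
  for (ct in contrasts) {
    is_pos <- vm$group == ct
    for (v in vars) {
      p_apx <- mw_normal_p(X[is_pos, v], X[!is_pos, v])
      if (p_apx < 100 * boundary) {
        p <- exact_mann_whitney(X[is_pos, v], X[!is_pos, v])
        if (p < boundary) total <- total + 1L
      }
    }
  }
  total
}
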