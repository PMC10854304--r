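#' Shapiro-Wilk normality test
#'
#' Standard Royston-approximation Shapiro-Wilk test (via
#' [stats::shapiro.test()]), with the contract used throughout the package:
#' 3 <= n <= 5000 and non-constant input. In the cohort workflow normality
#' informs only how descriptives are formatted (mean +/- SD for parametric
#' data, median and IQR otherwise); inference always uses the
#' covariate-adjusted linear model and Pearson trends.
#'
#' @param values Numeric vector.
#' @return A tibble with `W` and `p_value`.
#' @export
shapiro_wilk <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 3 || n > 5000) stop("Shapiro-Wilk requires 3 <= n <= 5000")
  if (stats::sd(values) == 0) stop("values are constant; no normality test")
  res <- stats::shapiro.test(values)
  tibble::tibble(W = unname(res$statistic), p_value = res$p.value)
}

#' Covariate-adjusted group comparison (ANCOVA)
#'
#' Ordinary least squares of the outcome on an intercept, a group indicator
#' and the continuous covariates (gestational age and maternal age by
#' default), with a partial 1-df F-test on the group indicator: the group
#' comparison "after accounting for" the covariates. Deterministic; errors
#' on rank-deficient designs.
#'
#' @param table Cohort tibble; must contain `group` (two levels) plus the
#'   outcome and covariate columns with no missing values.
#' @param outcome Name of the outcome column.
#' @param covariates Character vector of covariate columns.
#' @return A `dr_ancova` object; `tidy()` and `glance()` methods apply.
#'   Fields: `group_effect` (CHD minus reference, outcome units), `f_stat`,
#'   `p_value`, `df_num`, `df_den`, `coefficients`, `outcome`, `n`.
#' @export
ancova_group_effect <- function(table, outcome,
                                covariates = c("ga_weeks", "maternal_age")) {
  cols <- c(outcome, "group", covariates)
  missing <- setdiff(cols, names(table))
  if (length(missing) > 0) {
    stop("table is missing columns: ", paste(missing, collapse = ", "))
  }
  if (anyNA(table[cols])) stop("missing values in model columns")
  grp <- factor(table$group)
  if (nlevels(grp) != 2) stop("group must have exactly two levels")
  # the control group, when present, is the reference: the effect reads as
  # case minus control
  if ("control" %in% levels(grp)) grp <- stats::relevel(grp, "control")
  n <- nrow(table)
  if (n <= length(covariates) + 2) stop("too few rows for the model")
  df <- as.data.frame(table)
  df$.group <- grp
  fml <- stats::as.formula(paste(
    outcome, "~ .group +", paste(covariates, collapse = " + ")
  ))
  fit <- stats::lm(fml, data = df)
  if (fit$rank < length(covariates) + 2) {
    stop("rank-deficient design (collinear covariates)")
  }
  reduced <- stats::lm(stats::as.formula(paste(
    outcome, "~", paste(covariates, collapse = " + ")
  )), data = df)
  an <- stats::anova(reduced, fit)
  co <- stats::coef(fit)
  grp_col <- grep("^\\.group", names(co), value = TRUE)
  structure(
    list(group_effect = unname(co[grp_col]),
         f_stat = an$F[2], p_value = an$`Pr(>F)`[2],
         df_num = an$Df[2], df_den = an$Res.Df[2],
         coefficients = co, outcome = outcome, n = n, fit = fit),
    class = "dr_ancova"
  )
}

#' @export
print.dr_ancova <- function(x, ...) {
  cat("ANCOVA group effect on", x$outcome, "\n")
  cat(sprintf("  effect = %.4g, F(%d, %d) = %.3f, p = %.4g\n",
              x$group_effect, x$df_num, x$df_den, x$f_stat, x$p_value))
  invisible(x)
}

#' Pearson trend of an outcome across gestation
#'
#' Sample Pearson correlation of the outcome with gestational age within one
#' group, with the two-sided p-value from the t transform on n - 2 degrees
#' of freedom. Invariant to sign-preserving affine rescaling of either
#' variable.
#'
#' @param table Cohort tibble.
#' @param outcome Outcome column name.
#' @param group Group level to subset to, or NULL for all rows.
#' @return One-row tibble: `group`, `outcome`, `pearson_r`, `p_value`, `n`.
#' @export
pearson_trend <- function(table, outcome, group = NULL) {
  df <- if (is.null(group)) table else table[table$group == group, ]
  x <- df$ga_weeks
  y <- df[[outcome]]
  if (length(x) < 3) stop("need at least 3 rows for a trend")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("constant series")
  ct <- stats::cor.test(x, y, method = "pearson")
  tibble::tibble(group = if (is.null(group)) "all" else group,
                 outcome = outcome,
                 pearson_r = unname(ct$estimate),
                 p_value = ct$p.value, n = length(x))
}

#' Benjamini-Hochberg false-discovery-rate correction
#'
#' Step-up adjusted p-values, p_(i) -> min over j >= i of m * p_(j) / j
#' capped at 1 (via [stats::p.adjust()]), with significance flags at the
#' given threshold.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @param threshold Significance threshold on the adjusted values (0.05).
#' @return Tibble: `p_raw`, `p_fdr`, `significant`.
#' @examples
#' bh_fdr(c(0.005, 0.011, 0.02, 0.04, 0.1))
#' @export
bh_fdr <- function(p_values, threshold = 0.05) {
  if (any(is.na(p_values)) || any(p_values < 0) || any(p_values > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  adj <- stats::p.adjust(p_values, method = "BH")
  tibble::tibble(p_raw = p_values, p_fdr = adj,
                 significant = adj < threshold)
}

#' Component-weighting cohort analysis
#'
#' The full statistical treatment of per-scan mean component weightings:
#' three analysis families, each corrected across the K components by
#' Benjamini-Hochberg at `threshold` --
#' (1) the covariate-adjusted group comparison per component,
#' (2) Pearson GA trends within the control group, and
#' (3) Pearson GA trends within the CHD group.
#' Weightings are analysed on the raw fraction scale.
#'
#' @param table Cohort tibble with `weight_1..K`, `group`, `ga_weeks` and
#'   the covariates.
#' @param K Number of components.
#' @param covariates Covariates for the group comparison.
#' @param threshold FDR significance threshold (0.05).
#' @return Tidy tibble with 3 * K rows: `family`, `component`, `effect`
#'   (group effect or Pearson r), `statistic`, `p_raw`, `p_fdr`,
#'   `significant`.
#' @export
component_weighting_analysis <- function(table, K,
                                         covariates = c("ga_weeks",
                                                        "maternal_age"),
                                         threshold = 0.05) {
  wcols <- paste0("weight_", seq_len(K))
  missing <- setdiff(wcols, names(table))
  if (length(missing) > 0) {
    stop("table is missing weighting columns: ",
         paste(missing, collapse = ", "))
  }
  fam1 <- purrr::map_dfr(seq_len(K), function(k) {
    a <- ancova_group_effect(table, wcols[k], covariates)
    tibble::tibble(family = "group_comparison", component = k,
                   effect = a$group_effect, statistic = a$f_stat,
                   p_raw = a$p_value)
  })
  trend_fam <- function(grp, fam) {
    purrr::map_dfr(seq_len(K), function(k) {
      tr <- pearson_trend(table, wcols[k], grp)
      tibble::tibble(family = fam, component = k, effect = tr$pearson_r,
                     statistic = tr$pearson_r, p_raw = tr$p_value)
    })
  }
  fam2 <- trend_fam("control", "control_trend")
  fam3 <- trend_fam("chd", "chd_trend")
  dplyr::bind_rows(fam1, fam2, fam3) |>
    dplyr::group_by(.data$family) |>
    dplyr::mutate(p_fdr = stats::p.adjust(.data$p_raw, method = "BH"),
                  significant = .data$p_fdr < threshold) |>
    dplyr::ungroup()
}

#' Descriptive summary with normality-driven formatting
#'
#' Per-group descriptives for a cohort column: mean +/- SD when the
#' Shapiro-Wilk test does not reject normality at 0.05, otherwise median and
#' interquartile range, mirroring conventional demographics tables.
#'
#' @param table Cohort tibble.
#' @param outcome Column to summarise.
#' @return Tibble with one row per group: `group`, `n`, `normal`,
#'   `location`, `spread_low`, `spread_high`, `label`.
#' @export
describe_by_group <- function(table, outcome) {
  purrr::map_dfr(unique(table$group), function(g) {
    x <- table[[outcome]][table$group == g]
    normal <- shapiro_wilk(x)$p_value >= 0.05
    if (normal) {
      tibble::tibble(group = g, n = length(x), normal = TRUE,
                     location = mean(x),
                     spread_low = mean(x) - stats::sd(x),
                     spread_high = mean(x) + stats::sd(x),
                     label = sprintf("%.3g (+/- %.3g)", mean(x),
                                     stats::sd(x)))
    } else {
      q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
      tibble::tibble(group = g, n = length(x), normal = FALSE,
                     location = q[2], spread_low = q[1], spread_high = q[3],
                     label = sprintf("%.3g (%.3g-%.3g)", q[2], q[1], q[3]))
    }
  })
}
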