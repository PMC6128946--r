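# Model evaluation: RMSE / NRMSE / RPIQ, rank statistics, group
# comparisons, arthroscopic prediction aggregation, and report building.

#' Root mean square error
#'
#' @param y_true,y_pred Numeric vectors of equal nonzero length.
#' @return Scalar RMSE.
#' @export
rmse <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred) || length(y_true) == 0) {
    stopf("y_true and y_pred must have equal nonzero length")
  }
  sqrt(mean((y_true - y_pred)^2))
}

#' Normalised RMSE in percent
#'
#' RMSE relative to the reference parameter range (the max - min of the
#' measured values over the full reference dataset, all sets pooled).
#'
#' @param y_true,y_pred Numeric vectors.
#' @param reference_range Positive scalar range of the measured
#'   parameter.
#' @return NRMSE in percent.
#' @export
nrmse <- function(y_true, y_pred, reference_range) {
  if (!is.finite(reference_range) || reference_range <= 0) {
    stopf("reference_range must be positive")
  }
  100 * rmse(y_true, y_pred) / reference_range
}

#' Ratio of performance to inter-quartile range
#'
#' RPIQ = IQR(measured) / RMSE, with the inter-quartile range computed
#' by linear-interpolation (type 7) quantiles. Models with RPIQ >= 2
#' are flagged reliable. A zero RMSE yields `Inf` with the flag set.
#'
#' @param y_true_measured Measured values (length >= 4).
#' @param rmse_value Non-negative RMSE of the predictions.
#' @return Scalar RPIQ with attribute `reliable` (logical).
#' @export
rpiq <- function(y_true_measured, rmse_value) {
  if (length(y_true_measured) < 4) stopf("need >= 4 measured values")
  if (rmse_value < 0) stopf("rmse_value must be >= 0")
  iqr <- IQR(y_true_measured, type = 7)
  val <- if (rmse_value == 0) Inf else iqr / rmse_value
  structure(val, reliable = val >= 2)
}

#' Aggregate per-spectrum predictions to one location value
#'
#' The final arthroscopic prediction at a location is the average of
#' the non-negative per-spectrum predictions; if all predictions are
#' negative the location is reported missing (excluded from error
#' metrics rather than clamped to zero).
#'
#' @param predictions Numeric vector of per-spectrum predictions.
#' @return Scalar mean of the non-negative predictions, or `NA` with
#'   attribute `all_negative = TRUE`.
#' @export
aggregate_location_prediction <- function(predictions) {
  if (length(predictions) == 0) stopf("no predictions to aggregate")
  keep <- predictions >= 0
  if (!any(keep)) {
    return(structure(NA_real_, all_negative = TRUE))
  }
  mean(predictions[keep])
}

# vectorised location aggregation
aggregate_by_location <- function(predictions, loc_id) {
  ids <- unique(loc_id)
  pred <- vapply(ids, function(id) {
    as.numeric(aggregate_location_prediction(predictions[loc_id == id]))
  }, numeric(1))
  list(loc_id = ids, pred = pred)
}

#' Spearman rank correlation with two-tailed p-value
#'
#' Rank correlation using average ranks for ties. The p-value is exact
#' (distribution of the rank statistic) for n <= 9 without ties, and a
#' t-approximation with n - 2 degrees of freedom otherwise.
#'
#' @param x,y Numeric vectors, length >= 3.
#' @return List with `rho` and `p`.
#' @export
spearman_cor <- function(x, y) {
  n <- length(x)
  if (n < 3 || length(y) != n) stopf("need paired vectors of length >= 3")
  if (sd(x) == 0 || sd(y) == 0) {
    warning("constant vector: Spearman correlation undefined")
    return(list(rho = NA_real_, p = NA_real_))
  }
  rho <- cor(rank(x), rank(y))
  ties <- anyDuplicated(x) > 0 || anyDuplicated(y) > 0
  p <- if (n <= 9 && !ties) {
    suppressWarnings(cor.test(x, y, method = "spearman",
                              exact = TRUE)$p.value)
  } else {
    tt <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    2 * pt(-abs(tt), n - 2)
  }
  list(rho = rho, p = min(p, 1))
}

#' Mann-Whitney U test
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test. The U statistic is
#' for the first sample; the p-value is exact for small tie-free
#' samples and uses the tie-corrected normal approximation otherwise
#' (stats::wilcox.test underneath).
#'
#' @param a,b Numeric samples (both nonempty).
#' @return List with `U` (first sample), `p` (two-tailed).
#' @export
mann_whitney_u <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) stopf("both samples must be nonempty")
  wt <- suppressWarnings(wilcox.test(a, b, exact = NULL,
                                     correct = TRUE))
  list(U = unname(wt$statistic), p = wt$p.value)
}

#' Normality gate for the statistical pipeline
#'
#' Shapiro-Wilk test deciding between parametric and nonparametric
#' follow-up tests; returns `"nonparametric"` when p < 0.05. The group
#' comparisons in this package default to nonparametric tests
#' regardless (the emulated study's reference data were non-normal);
#' the gate is informational.
#'
#' @param values Numeric sample with 3 <= n <= 5000.
#' @return `"parametric"` or `"nonparametric"`, with attribute `p`.
#' @export
shapiro_wilk_gate <- function(values) {
  n <- length(values)
  if (n < 3 || n > 5000) stopf("Shapiro-Wilk requires 3 <= n <= 5000")
  p <- shapiro.test(values)$p.value
  structure(if (p < 0.05) "nonparametric" else "parametric", p = p)
}

#' Evaluate one fitted model on one set
#'
#' @param y_true Measured values for the set.
#' @param y_pred Predicted values.
#' @param reference_range Range of the measured parameter over the full
#'   reference dataset.
#' @return One-row data frame: `n`, `rho`, `p`, `nrmse_pct`, `rpiq`,
#'   `reliable_flag`.
#' @export
evaluate_set <- function(y_true, y_pred, reference_range) {
  r <- rmse(y_true, y_pred)
  sp <- if (length(y_true) >= 3 && sd(y_true) > 0 && sd(y_pred) > 0) {
    spearman_cor(y_true, y_pred)
  } else list(rho = NA_real_, p = NA_real_)
  rp <- if (length(y_true) >= 4) rpiq(y_true, r) else
    structure(NA_real_, reliable = NA)
  data.frame(n = length(y_true), rho = sp$rho, p = sp$p,
             nrmse_pct = nrmse(y_true, y_pred, reference_range),
             rpiq = as.numeric(rp),
             reliable_flag = isTRUE(attr(rp, "reliable")))
}

#' Build a Table-1-shaped evaluation report
#'
#' One row per (parameter, variant, set) with Spearman rho and p,
#' NRMSE (percent of the pooled reference range) and RPIQ, for the
#' pooled calibration+validation set, the independent test set, and
#' (for variants evaluated arthroscopically) the per-location
#' aggregated arthroscopic predictions.
#'
#' @param results List of per-(parameter, variant) results as produced
#'   by [run_full()]'s internal fitting step: each element has
#'   `parameter`, `variant`, `region`, `n_variables` and a named list
#'   `sets` of `(y_true, y_pred)` pairs.
#' @param reference_ranges Named numeric: pooled measured range per
#'   parameter.
#' @return Data frame with columns `parameter, variant, region_um,
#'   n_variables, set, n, rho, p, nrmse_pct, rpiq, reliable_flag`.
#' @export
build_report <- function(results, reference_ranges) {
  rows <- list()
  for (res in results) {
    for (set_name in names(res$sets)) {
      s <- res$sets[[set_name]]
      if (length(s$y_true) == 0) {
        message("set ", set_name, " missing for ", res$parameter, "/",
                res$variant, "; row omitted")
        next
      }
      ev <- evaluate_set(s$y_true, s$y_pred,
                         reference_ranges[[res$parameter]])
      rows[[length(rows) + 1L]] <- data.frame(
        parameter = res$parameter, variant = res$variant,
        region_um = paste(sprintf("%.2f", res$region), collapse = "-"),
        n_variables = res$n_variables, set = set_name, ev)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(parameter = character(0), variant = character(0),
                      region_um = character(0), n_variables = integer(0),
                      set = character(0), n = integer(0), rho = numeric(0),
                      p = numeric(0), nrmse_pct = numeric(0),
                      rpiq = numeric(0), reliable_flag = logical(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-group distribution summary by distance class
#'
#' Boxplot-style summary (median, quartiles, outliers by the 1.5 IQR
#' rule) of a measured or predicted parameter per distance class and
#' group, mirroring the repair-vs-control boxplot figures.
#'
#' @param values Numeric values (one per location).
#' @param group Group labels (`"repair"`/`"control"`).
#' @param distance_class Integer classes 1-4.
#' @param parameter Parameter name recorded in the output.
#' @return Data frame: `parameter, distance_class, group, n, median,
#'   q25, q75, n_outliers`.
#' @export
group_summary <- function(values, group, distance_class,
                          parameter = "value") {
  stopifnot(length(values) == length(group),
            length(values) == length(distance_class))
  combos <- expand.grid(distance_class = sort(unique(distance_class)),
                        group = sort(unique(group)),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    sel <- group == combos$group[i] &
      distance_class == combos$distance_class[i]
    v <- values[sel & !is.na(values)]
    if (length(v) == 0) return(NULL)
    q <- quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    iqr <- q[3] - q[1]
    data.frame(parameter = parameter,
               distance_class = combos$distance_class[i],
               group = combos$group[i], n = length(v),
               median = q[2], q25 = q[1], q75 = q[3],
               n_outliers = sum(v < q[1] - 1.5 * iqr | v > q[3] + 1.5 * iqr))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
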