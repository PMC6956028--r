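#' Group summary
#'
#' @param n Group size (>= 2).
#' @param mean Group mean.
#' @param sd Group standard deviation (>= 0).
#' @return An object of class `nm_group_summary`.
#' @export
group_summary <- function(n, mean, sd) {
  if (n < 2) stop("group size must be at least 2", call. = FALSE)
  if (sd < 0) stop("standard deviation must be non-negative",
                   call. = FALSE)
  structure(list(n = as.integer(n), mean = mean, sd = sd),
            class = "nm_group_summary")
}

as_group_summary <- function(x) {
  if (inherits(x, "nm_group_summary")) return(x)
  if (is.numeric(x) && length(x) >= 2L)
    return(group_summary(length(x), mean(x), sd(x)))
  stop("supply a numeric sample of length >= 2 or a group_summary()",
       call. = FALSE)
}

#' Two-sample t-test from samples or summaries
#'
#' Welch's unequal-variance t statistic with Welch-Satterthwaite degrees
#' of freedom and a two-sided p-value, computable from either raw samples
#' or (n, mean, sd) summaries; a pooled-variance Student test is available
#' via `var_equal = TRUE`. Welch is the default because the group spreads
#' this method compares are typically unequal.
#'
#' @param a,b Numeric samples (length >= 2) or [group_summary()] objects.
#' @param var_equal Use the pooled-variance test instead of Welch.
#' @return A list with `t`, `df` and `p`.
#' @examples
#' welch_t(group_summary(20, 37.7, 8.0), group_summary(12, 56.9, 6.6))
#' @export
welch_t <- function(a, b, var_equal = FALSE) {
  a <- as_group_summary(a)
  b <- as_group_summary(b)
  if (a$sd == 0 && b$sd == 0)
    stop("both groups have zero variance", call. = FALSE)
  if (var_equal) {
    sp2 <- ((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / (a$n + b$n - 2)
    se <- sqrt(sp2 * (1 / a$n + 1 / b$n))
    df <- a$n + b$n - 2
  } else {
    va <- a$sd^2 / a$n
    vb <- b$sd^2 / b$n
    se <- sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (a$n - 1) + vb^2 / (b$n - 1))
  }
  t <- (a$mean - b$mean) / se
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

#' Relative reduction in percent
#'
#' `100 * (reference - reduced) / reference`: how much lower the reduced
#' group's mean is, as a percentage of the reference group's mean.
#'
#' @param reference_mean Reference (e.g. control) mean, > 0.
#' @param reduced_mean Reduced (e.g. patient) mean.
#' @return The reduction in percent.
#' @examples
#' relative_reduction(56.9, 37.7)  # 33.7 percent lower surface
#' @export
relative_reduction <- function(reference_mean, reduced_mean) {
  if (reference_mean <= 0)
    stop("`reference_mean` must be positive", call. = FALSE)
  100 * (reference_mean - reduced_mean) / reference_mean
}

#' ROC analysis with a Youden-optimal cutoff
#'
#' Sweeps cutoffs placed at the midpoints between consecutive distinct
#' scores (plus -Inf and +Inf): with `orientation = "lower_is_positive"`
#' (the case for nucleus surface and volume, which are reduced in
#' disease) a subject is test-positive when its score is *below* the
#' cutoff. Sensitivity is the true-positive fraction among
#' condition-positives (`positive_label`), specificity the true-negative
#' fraction among the rest. The AUC is computed by pair counting
#' (Mann-Whitney; ties count 1/2) and the operating cutoff maximizes
#' Youden's J = sensitivity + specificity - 1, ties resolved toward the
#' lower cutoff. Because which group a printed "sensitivity" refers to is
#' a convention, the swapped convention (condition-positive and
#' orientation both flipped) is reported alongside under `$swapped`.
#'
#' @param scores Numeric scores, one per subject.
#' @param labels Group labels, same length as `scores`; exactly the
#'   condition-positive and condition-negative classes must both occur.
#' @param positive_label The condition-positive class (default `"PD"`).
#' @param orientation `"lower_is_positive"` (default) or
#'   `"higher_is_positive"`.
#' @return An object of class `nm_roc`: list with `cutoffs`,
#'   `sensitivity`, `specificity`, `auc`, `best_cutoff`, `best_sens`,
#'   `best_spec`, `orientation` and `swapped` (best sens/spec under the
#'   flipped convention).
#' @examples
#' roc_analysis(c(1, 2, 3, 2.5, 3.5, 4),
#'              c("PD", "PD", "PD", "HC", "HC", "HC"))$auc  # 8/9
#' @export
roc_analysis <- function(scores, labels, positive_label = "PD",
                         orientation = c("lower_is_positive",
                                         "higher_is_positive")) {
  orientation <- match.arg(orientation)
  if (length(scores) != length(labels))
    stop("`scores` and `labels` lengths differ", call. = FALSE)
  pos <- labels == positive_label
  if (!any(pos) || all(pos))
    stop("both classes must be present in `labels`", call. = FALSE)
  # reduce to the canonical sweep: smaller transformed score = positive
  s <- if (orientation == "lower_is_positive") scores else -scores
  xs <- sort(unique(s))
  cutoffs <- c(-Inf, if (length(xs) > 1)
    (xs[-1] + xs[-length(xs)]) / 2, Inf)
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  sens <- vapply(cutoffs, function(ct) sum(s[pos] < ct) / n_pos,
                 numeric(1))
  spec <- vapply(cutoffs, function(ct) sum(s[!pos] >= ct) / n_neg,
                 numeric(1))

  # pair-counting AUC: fraction of (positive, negative) pairs ordered
  # correctly, ties worth 1/2
  cmp <- outer(s[pos], s[!pos], "-")
  auc <- (sum(cmp < 0) + 0.5 * sum(cmp == 0)) / (n_pos * n_neg)

  j <- sens + spec - 1
  k <- which.max(j)  # first (lowest cutoff) on ties
  best_cut <- cutoffs[k]
  if (orientation == "higher_is_positive") {
    # map back to the original score scale, keeping cutoffs ascending
    ord <- length(cutoffs):1L
    cutoffs <- -cutoffs[ord]
    sens_out <- sens[ord]
    spec_out <- spec[ord]
    best_cut <- -best_cut
  } else {
    sens_out <- sens
    spec_out <- spec
  }

  swapped <- list(best_sens = spec[k], best_spec = sens[k],
                  auc = auc,
                  positive_label = paste0("not ", positive_label))

  structure(list(cutoffs = cutoffs, sensitivity = sens_out,
                 specificity = spec_out, auc = auc, best_cutoff = best_cut,
                 best_sens = sens[k], best_spec = spec[k],
                 orientation = orientation, swapped = swapped),
            class = "nm_roc")
}

#' @export
print.nm_roc <- function(x, ...) {
  cat(sprintf(
    paste0("<ROC> AUC %.3f (%s)\n",
           "  Youden cutoff %.4g: sensitivity %.3f, specificity %.3f\n",
           "  swapped convention: sensitivity %.3f, specificity %.3f\n"),
    x$auc, x$orientation, x$best_cutoff, x$best_sens, x$best_spec,
    x$swapped$best_sens, x$swapped$best_spec))
  invisible(x)
}

#' Group comparison of a quantification table
#'
#' Runs the Welch t-test, the relative reduction of the patient mean
#' versus the control mean, and the ROC analysis for one endpoint column
#' of a quantification report table (as written by [write_report()]).
#'
#' @param reports A data.frame with at least `group` and the endpoint
#'   column, or a list of `nm_quant_report` objects.
#' @param endpoint Column to analyze (e.g. `"volume_mm3"`,
#'   `"surface_mm2"`, `"volume_norm"`).
#' @param positive_label,reference_label Condition-positive (default
#'   `"PD"`) and reference (default `"HC"`) groups.
#' @return A list with `endpoint`, per-group [group_summary()] objects,
#'   `t_test`, `reduction_pct` and `roc`.
#' @export
compare_groups <- function(reports, endpoint = "volume_mm3",
                           positive_label = "PD",
                           reference_label = "HC") {
  if (!is.data.frame(reports)) reports <- bind_reports(reports)
  if (!endpoint %in% names(reports))
    stop(sprintf("no column `%s` in the report table", endpoint),
         call. = FALSE)
  x <- reports[[endpoint]]
  g <- reports$group
  a <- x[g == positive_label]
  b <- x[g == reference_label]
  if (length(a) < 2 || length(b) < 2)
    stop("need at least 2 subjects per group", call. = FALSE)
  list(endpoint = endpoint,
       positive = group_summary(length(a), mean(a), sd(a)),
       reference = group_summary(length(b), mean(b), sd(b)),
       t_test = welch_t(a, b),
       reduction_pct = relative_reduction(mean(b), mean(a)),
       roc = roc_analysis(x[g %in% c(positive_label, reference_label)],
                          g[g %in% c(positive_label, reference_label)],
                          positive_label = positive_label))
}
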