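# Two-group statistics: pooled-variance Student's t-tests (from raw
# samples or from printed summary statistics), noncentral-t power, and
# minimal sample size at a target power.

#' Unpaired two-tailed Student's t-test from summary statistics
#'
#' Pooled-variance form: \eqn{s_p^2 = ((n_1-1)s_1^2 + (n_2-1)s_2^2) /
#' (n_1+n_2-2)}, \eqn{t = (\bar x_1 - \bar x_2) / (s_p \sqrt{1/n_1 +
#' 1/n_2})}, with \eqn{df = n_1 + n_2 - 2} and a two-tailed p from the
#' central t distribution. This matches figure-caption p-values computed
#' from mean, SD and n alone. When both SDs are zero the test degenerates:
#' equal means give t = 0, p = 1; unequal means give an infinite statistic
#' and p is reported at the smallest positive double.
#'
#' @param mean1,sd1,n1 First group summary (mean, standard deviation, n).
#' @param mean2,sd2,n2 Second group summary.
#' @param alpha Significance level used for the \code{significant} flag.
#' @param feature Optional feature name carried into the result.
#' @return Object of class \code{vasc_ttest}: list with \code{t},
#'   \code{df}, \code{p}, \code{significant}, and the input summaries.
#' @export
#' @examples
#' ttest_from_summary(3.444, 0.7265, 9, 4.0, 1.936, 9)$p  # ~0.432
ttest_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2,
                               alpha = 0.05, feature = NA_character_) {
  if (!(n1 >= 2 && n2 >= 2)) {
    stop("both groups need n >= 2", call. = FALSE)
  }
  if (sd1 < 0 || sd2 < 0) stop("standard deviations must be >= 0",
                               call. = FALSE)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  if (sp2 == 0) {
    if (mean1 == mean2) {
      t <- 0; p <- 1
    } else {
      t <- sign(mean1 - mean2) * Inf
      p <- .Machine$double.xmin
    }
  } else {
    t <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
    p <- 2 * stats::pt(-abs(t), df)
  }
  structure(
    list(feature = feature, t = t, df = df, p = p,
         significant = p < alpha,
         group1 = c(mean = mean1, sd = sd1, n = n1),
         group2 = c(mean = mean2, sd = sd2, n = n2),
         alpha = alpha),
    class = "vasc_ttest"
  )
}

#' Unpaired two-tailed Student's t-test from raw samples
#'
#' Exactly equivalent to \code{\link{ttest_from_summary}} applied to the
#' samples' own means, standard deviations and sizes.
#'
#' @param samples1,samples2 Numeric vectors (each at least 2 finite
#'   values).
#' @inheritParams ttest_from_summary
#' @return A \code{vasc_ttest} object.
#' @export
ttest_from_samples <- function(samples1, samples2, alpha = 0.05,
                               feature = NA_character_) {
  for (s in list(samples1, samples2)) {
    if (length(s) < 2L || any(!is.finite(s))) {
      stop("each group needs at least 2 finite values", call. = FALSE)
    }
  }
  ttest_from_summary(mean(samples1), stats::sd(samples1), length(samples1),
                     mean(samples2), stats::sd(samples2), length(samples2),
                     alpha = alpha, feature = feature)
}

#' @export
print.vasc_ttest <- function(x, ...) {
  cat(sprintf("Student's unpaired t-test (two-tailed)%s\n",
              if (is.na(x$feature)) "" else paste0(" - ", x$feature)))
  cat(sprintf("  group 1: %.4g +/- %.4g (n = %d)\n",
              x$group1["mean"], x$group1["sd"], as.integer(x$group1["n"])))
  cat(sprintf("  group 2: %.4g +/- %.4g (n = %d)\n",
              x$group2["mean"], x$group2["sd"], as.integer(x$group2["n"])))
  cat(sprintf("  t = %.4f, df = %d, P = %.4f%s\n", x$t, as.integer(x$df),
              x$p, if (x$significant) " *" else ""))
  invisible(x)
}

#' Power of the two-sided two-sample t-test (noncentral t, exact)
#'
#' \eqn{power = P(|T'| > t_{crit})} where \eqn{T'} follows a noncentral t
#' distribution with \eqn{df = n_1 + n_2 - 2} and noncentrality
#' \eqn{\delta = d \sqrt{n_1 n_2 / (n_1 + n_2)}}, and \eqn{t_{crit}} is
#' the two-sided central-t critical value at \code{alpha}. At d = 0 the
#' power equals \code{alpha} (the type-I error rate).
#'
#' @param d Cohen's d (standardized mean difference), >= 0.
#' @param n1,n2 Per-group sample sizes (>= 2).
#' @param alpha Two-sided significance level.
#' @return Achieved power (scalar in \[alpha, 1\]).
#' @export
#' @examples
#' power_two_sample_t(1.5, 9, 9, 0.05)  # 0.8476
power_two_sample_t <- function(d, n1, n2, alpha = 0.05) {
  if (d < 0) stop("d must be >= 0", call. = FALSE)
  if (n1 < 2 || n2 < 2) stop("n1 and n2 must be >= 2", call. = FALSE)
  df <- n1 + n2 - 2
  ncp <- d * sqrt(n1 * n2 / (n1 + n2))
  tcrit <- stats::qt(1 - alpha / 2, df)
  stats::pt(-tcrit, df, ncp = ncp) + 1 - stats::pt(tcrit, df, ncp = ncp)
}

#' Minimal sample sizes reaching a target power
#'
#' Smallest \code{n1} (with \code{n2 = round(ratio * n1)}, floored at 2)
#' such that \code{\link{power_two_sample_t}} meets the target.
#'
#' @param d Cohen's d, > 0.
#' @param alpha Two-sided significance level.
#' @param target_power Target power in (alpha, 1).
#' @param ratio Allocation ratio n2 / n1.
#' @return List with \code{n1}, \code{n2}, \code{total} and
#'   \code{achieved_power}.
#' @export
#' @examples
#' required_sample_size(1.5, 0.05, 0.8, 1)  # n = 9 per group, power 0.8476
required_sample_size <- function(d, alpha = 0.05, target_power = 0.8,
                                 ratio = 1) {
  if (d <= 0) stop("no finite sample size for d = 0", call. = FALSE)
  if (!(target_power > alpha && target_power < 1)) {
    stop("target_power must be in (alpha, 1)", call. = FALSE)
  }
  n1 <- 2L
  repeat {
    n2 <- max(2L, as.integer(round(ratio * n1)))
    pw <- power_two_sample_t(d, n1, n2, alpha)
    if (pw >= target_power) {
      return(list(n1 = n1, n2 = n2, total = n1 + n2, achieved_power = pw))
    }
    n1 <- n1 + 1L
    if (n1 > 1e6) stop("sample size search did not converge", call. = FALSE)
  }
}

#' Per-feature comparison of two feature tables
#'
#' One unpaired two-tailed Student's t-test per canonical feature column,
#' with group summaries (mean, SD, n) as printed in figure captions.
#' No multiple-testing correction is applied by default (set
#' \code{adjust = "holm"} to enable Holm adjustment of the p-values).
#'
#' @param tableA,tableB Feature tables (see
#'   \code{\link{read_feature_table}}); both must carry the canonical
#'   feature columns.
#' @param alpha Significance level.
#' @param adjust \code{"none"} (default) or \code{"holm"}.
#' @return Object of class \code{vasc_comparison}: a data frame with one
#'   row per feature (group means/SDs/ns, t, df, p, significant), plus
#'   attributes \code{alpha} and \code{adjust}.
#' @export
compare_feature_tables <- function(tableA, tableB, alpha = 0.05,
                                   adjust = c("none", "holm")) {
  adjust <- match.arg(adjust)
  fn <- feature_names()
  for (tb in list(tableA, tableB)) {
    missing_cols <- setdiff(fn, names(tb))
    if (length(missing_cols)) {
      stop("feature table is missing columns: ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    }
  }
  rows <- lapply(fn, function(f) {
    tt <- ttest_from_samples(tableA[[f]], tableB[[f]], alpha = alpha,
                             feature = f)
    data.frame(feature = f,
               mean_a = unname(tt$group1["mean"]), sd_a = unname(tt$group1["sd"]),
               n_a = unname(tt$group1["n"]),
               mean_b = unname(tt$group2["mean"]), sd_b = unname(tt$group2["sd"]),
               n_b = unname(tt$group2["n"]),
               t = tt$t, df = tt$df, p = tt$p)
  })
  out <- do.call(rbind, rows)
  if (adjust == "holm") out$p <- stats::p.adjust(out$p, "holm")
  out$significant <- out$p < alpha
  structure(out, class = c("vasc_comparison", "data.frame"),
            alpha = alpha, adjust = adjust)
}

#' @export
print.vasc_comparison <- function(x, ...) {
  cat(sprintf("Two-group feature comparison (alpha = %g, adjust = %s)\n",
              attr(x, "alpha"), attr(x, "adjust")))
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %-22s A: %.4g +/- %.4g, B: %.4g +/- %.4g (P = %.4f)%s\n",
                x$feature[i], x$mean_a[i], x$sd_a[i], x$mean_b[i], x$sd_b[i],
                x$p[i], if (x$significant[i]) " *" else ""))
  }
  invisible(x)
}

#' Write a comparison report as JSON
#'
#' @param comparison A \code{vasc_comparison}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_comparison_json <- function(comparison, path) {
  payload <- list(
    alpha = attr(comparison, "alpha"),
    adjust = attr(comparison, "adjust"),
    results = as.data.frame(comparison)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
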