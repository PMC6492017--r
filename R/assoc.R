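#' Kaplan-Meier survival estimate
#'
#' Product-limit estimator with right censoring, per group. Groups with
#' fewer than 2 samples are dropped with a warning.
#'
#' @param time follow-up time in days (>= 0).
#' @param event 1 = death observed, 0 = censored.
#' @param group optional group labels (one curve per group).
#' @return data.frame: `group`, `time`, `n_risk`, `n_event`, `n_censor`,
#'   `surv`; the underlying [survival::survfit] object is in attribute
#'   `fit`.
#' @export
km_estimate <- function(time, event, group = NULL) {
  .check_surv(time, event)
  if (is.null(group)) group <- rep("all", length(time))
  keep <- .drop_small_groups(group)
  time <- time[keep]; event <- event[keep]; group <- group[keep]
  fit <- survival::survfit(survival::Surv(time, event) ~ group)
  strata <- if (is.null(fit$strata)) setNames(length(fit$time),
                                              unique(group)) else fit$strata
  out <- data.frame(
    group = rep(sub("^group=", "", names(strata)), strata),
    time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
    n_censor = fit$n.censor, surv = fit$surv, row.names = NULL
  )
  structure(out, fit = fit)
}

.check_surv <- function(time, event) {
  if (any(is.na(time)) || any(time < 0))
    loy_usage_error("survival times must be non-negative and non-missing")
  if (!all(event %in% c(0, 1)))
    loy_usage_error("event flags must be 0/1")
}

.drop_small_groups <- function(group) {
  tab <- table(group)
  small <- names(tab)[tab < 2]
  if (length(small))
    warning("dropping group(s) with < 2 samples: ",
            paste(small, collapse = ", "), call. = FALSE)
  !(group %in% small)
}

.test_result <- function(statistic, df, p, method, n) {
  structure(list(statistic = unname(statistic), df = df,
                 p_value = unname(min(1, max(0, p))), method = method,
                 n = n),
            class = "loy_test")
}

#' @export
print.loy_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g%s, p = %.4g (n = %d)\n", x$method,
              x$statistic,
              if (!is.null(x$df) && !is.na(x$df))
                sprintf(", df = %g", x$df) else "",
              x$p_value, x$n))
  invisible(x)
}

#' Log-rank test of survival curves
#'
#' k-group log-rank chi-square statistic with k - 1 degrees of freedom;
#' invariant to group relabeling.
#'
#' @inheritParams km_estimate
#' @param group group labels (>= 2 groups after dropping singletons).
#' @return a `loy_test`.
#' @export
logrank_test <- function(time, event, group) {
  .check_surv(time, event)
  keep <- .drop_small_groups(group)
  time <- time[keep]; event <- event[keep]
  group <- as.character(group[keep])
  if (length(unique(group)) < 2L)
    loy_usage_error("log-rank test needs at least 2 groups")
  if (sum(event) < 1L)
    loy_usage_error("log-rank test needs at least one event")
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  df <- length(sd$n) - 1L
  .test_result(sd$chisq, df, stats::pchisq(sd$chisq, df, lower.tail = FALSE),
               "log-rank", length(time))
}

#' Cox proportional hazards regression
#'
#' Partial-likelihood fit with Efron tie handling; per-covariate Wald
#' tests. Factor covariates are one-hot encoded by the model matrix.
#'
#' @inheritParams km_estimate
#' @param covariates data.frame (or named vector/matrix) of covariates,
#'   rows aligned with `time`.
#' @return data.frame of class `loy_cox`: `term`, `coef`, `hazard_ratio`,
#'   `se`, `z`, `p_value`; attributes `n`, `n_event`, `fit`.
#' @export
cox_fit <- function(time, event, covariates) {
  .check_surv(time, event)
  if (sum(event) < 1L) loy_usage_error("Cox fit needs at least one event")
  if (!is.data.frame(covariates))
    covariates <- as.data.frame(covariates)
  dat <- cbind(data.frame(.time = time, .event = event), covariates)
  dat <- dat[complete.cases(dat), , drop = FALSE]
  fit <- tryCatch(
    survival::coxph(
      survival::Surv(.time, .event) ~ .,
      data = dat, ties = "efron",
      control = survival::coxph.control(iter.max = 50, eps = 1e-9)),
    warning = function(w) {
      if (grepl("converge|infinite|beta may be infinite", conditionMessage(w)))
        loy_error(paste0("Cox fit failed: ", conditionMessage(w)),
                  "loy_fit_error")
      suppressWarnings(survival::coxph(
        survival::Surv(.time, .event) ~ ., data = dat, ties = "efron",
        control = survival::coxph.control(iter.max = 50, eps = 1e-9)))
    })
  if (any(is.na(coef(fit))))
    loy_error("Cox fit failed: inestimable coefficient", "loy_fit_error")
  s <- summary(fit)$coefficients
  out <- data.frame(term = rownames(s), coef = s[, "coef"],
                    hazard_ratio = s[, "exp(coef)"], se = s[, "se(coef)"],
                    z = s[, "z"], p_value = s[, "Pr(>|z|)"],
                    row.names = NULL)
  structure(out, class = c("loy_cox", "data.frame"),
            n = fit$n, n_event = fit$nevent, fit = fit)
}

#' @importFrom stats coef
NULL

#' Kruskal-Wallis rank test
#'
#' Rank-based k-group comparison with tie correction (average ranks).
#' Degenerate all-equal inputs return statistic 0, p = 1.
#'
#' @param values numeric vector.
#' @param groups group labels.
#' @return a `loy_test`.
#' @export
kruskal_wallis <- function(values, groups) {
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]; groups <- factor(groups[keep])
  if (nlevels(groups) < 2L || any(table(groups) == 0))
    loy_usage_error("kruskal_wallis needs >= 2 non-empty groups")
  if (length(unique(values)) == 1L)
    return(.test_result(0, nlevels(groups) - 1L, 1, "Kruskal-Wallis",
                        length(values)))
  kt <- kruskal.test(values, groups)
  .test_result(kt$statistic, unname(kt$parameter), kt$p.value,
               "Kruskal-Wallis", length(values))
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Exact null distribution when both groups have at most 25 observations
#' and there are no ties; otherwise the normal approximation with tie
#' correction and continuity correction.
#'
#' @param a,b numeric vectors.
#' @return a `loy_test`.
#' @export
wilcoxon_rank_sum <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (!length(a) || !length(b))
    loy_usage_error("both groups must be non-empty")
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- length(a) <= 25 && length(b) <= 25 && !ties
  wt <- suppressWarnings(wilcox.test(a, b, exact = exact, correct = TRUE))
  .test_result(wt$statistic, NA_real_, wt$p.value, "Wilcoxon rank-sum",
               length(a) + length(b))
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks on ties; p-value from the t
#' approximation (the rank statistic makes it invariant to monotone
#' transforms of either variable).
#'
#' @param x,y numeric vectors.
#' @return a `loy_test` with extra element `rho`.
#' @export
spearman_test <- function(x, y) {
  keep <- complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) loy_usage_error("need at least 3 complete pairs")
  ct <- suppressWarnings(cor.test(x, y, method = "spearman",
                                  exact = FALSE))
  out <- .test_result(ct$statistic, NA_real_, ct$p.value,
                      "Spearman correlation", length(x))
  out$rho <- unname(ct$estimate)
  out
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p by the minimum-likelihood convention: conditioning on the
#' margins, the p-value is the sum of the probabilities of all tables whose
#' hypergeometric probability does not exceed that of the observed table
#' (within a 1 + 1e-7 relative tolerance).
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @return a `loy_test` with extra element `odds_ratio` (sample odds
#'   ratio).
#' @examples
#' fisher_exact(matrix(c(5, 5, 5, 5), 2))$p_value # 1
#' @export
fisher_exact <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L)))
    loy_usage_error("fisher_exact expects a 2x2 table")
  if (any(is.na(tab)) || any(tab < 0) || any(tab != round(tab)))
    loy_usage_error("counts must be non-negative integers")
  r1 <- sum(tab[1L, ]); c1 <- sum(tab[, 1L]); n <- sum(tab)
  if (n == 0L) loy_usage_error("empty table")
  support <- max(0L, r1 + c1 - n):min(r1, c1)
  d <- dhyper(support, c1, n - c1, r1)
  d_obs <- d[match(tab[1L, 1L], support)]
  p <- min(1, sum(d[d <= d_obs * (1 + 1e-7)]))
  out <- .test_result(tab[1L, 1L], NA_real_, p, "Fisher's exact", n)
  out$odds_ratio <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  out
}
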