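#' Fit the bimodal Y-index density and locate its two peaks
#'
#' Gaussian kernel density estimate on a 512-point grid padded 10% beyond
#' the data range; the two peaks are the two highest local maxima of the
#' fitted density separated by at least `min_separation`. In a male tumor
#' cohort the lower mode sits near the purity-mixed LoY copy number and the
#' higher mode near 1 (retained Y).
#'
#' @param y_indices numeric vector of Y indices (or PC1 scores); at least 20
#'   finite values required.
#' @param bandwidth a bandwidth rule understood by [stats::density()]
#'   (default `"nrd0"`, Silverman) or a numeric bandwidth.
#' @param min_separation minimum distance between the two reported peaks.
#' @return object of class `loy_bimodal_fit`: `peak_low`, `peak_high`,
#'   `bandwidth`, `grid` (data.frame `x`, `density`), `n`,
#'   `min_separation`.
#' @section Errors: fewer than two qualifying maxima raises a condition of
#'   class `loy_unimodal_error` carrying the single `mode`.
#' @export
fit_bimodal <- function(y_indices, bandwidth = "nrd0",
                        min_separation = 0.2) {
  x <- y_indices[is.finite(y_indices)]
  if (length(x) < 20L)
    loy_usage_error("fit_bimodal needs at least 20 finite values")
  .assert_pos(min_separation, "min_separation")
  pad <- 0.1 * diff(range(x))
  if (pad == 0) loy_usage_error("all values identical: no density to fit")
  d <- density(x, bw = bandwidth, n = 512L,
               from = min(x) - pad, to = max(x) + pad)
  dy <- d$y
  is_max <- c(FALSE, dy[2:511] > dy[1:510] & dy[2:511] >= dy[3:512], FALSE)
  mx <- data.frame(x = d$x[is_max], y = dy[is_max])
  mx <- mx[order(-mx$y), , drop = FALSE]
  if (nrow(mx) == 0L)
    loy_error("no local maximum found", "loy_unimodal_error", mode = NA_real_)
  second <- which(abs(mx$x - mx$x[1L]) >= min_separation)
  if (nrow(mx) < 2L || !length(second))
    loy_error(sprintf(
      "density is unimodal (single qualifying mode at %.4g)", mx$x[1L]),
      "loy_unimodal_error", mode = mx$x[1L])
  peaks <- sort(c(mx$x[1L], mx$x[second[1L]]))
  structure(list(peak_low = peaks[1L], peak_high = peaks[2L],
                 bandwidth = d$bw,
                 grid = data.frame(x = d$x, density = dy),
                 n = length(x), min_separation = min_separation),
            class = "loy_bimodal_fit")
}

#' @export
print.loy_bimodal_fit <- function(x, ...) {
  cat(sprintf(
    "Bimodal density fit (n = %d): peaks at %.3f and %.3f (bw = %.4f)\n",
    x$n, x$peak_low, x$peak_high, x$bandwidth))
  invisible(x)
}

#' Classify samples against a bimodal fit
#'
#' Three-way split by the fitted peak positions with strict inequalities:
#' `LOY` below the lower peak, `RETAINED` above the higher peak,
#' `UNCERTAIN` in between (including values exactly at a peak, and missing
#' indices). Downstream analyses compare LOY against RETAINED and drop the
#' uncertain middle.
#'
#' @param y_indices numeric vector, optionally named by sample.
#' @param fit a `loy_bimodal_fit`.
#' @return data.frame of class `loy_calls`: `sample`, `y_index`, `label`
#'   (factor LOY/UNCERTAIN/RETAINED), with the fit in attribute `fit`.
#' @export
classify_loy <- function(y_indices, fit) {
  if (!inherits(fit, "loy_bimodal_fit"))
    loy_usage_error("'fit' must come from fit_bimodal()")
  lab <- rep("UNCERTAIN", length(y_indices))
  lab[!is.na(y_indices) & y_indices < fit$peak_low] <- "LOY"
  lab[!is.na(y_indices) & y_indices > fit$peak_high] <- "RETAINED"
  out <- data.frame(
    sample = names(y_indices) %||% sprintf("S%d", seq_along(y_indices)),
    y_index = unname(y_indices),
    label = factor(lab, levels = c("LOY", "UNCERTAIN", "RETAINED")),
    row.names = NULL
  )
  structure(out, fit = fit, class = c("loy_calls", "data.frame"))
}

#' Expression ratios against female background and male-normal reference
#'
#' For each discriminating probe: (1) the mean intensity across all female
#' samples is taken as the measurement background; (2) that background is
#' subtracted from every male sample; (3) the background-adjusted value is
#' divided by the mean background-adjusted value of the male normal
#' samples. A non-LoY male therefore has expected ratio 1 and a female-like
#' (fully lost) signal gives 0.
#'
#' @param intensity probe x sample numeric matrix.
#' @param sex per-column `"male"`/`"female"` labels.
#' @param group per-column group labels; `"normal"` marks the reference
#'   males.
#' @param probes optional character vector restricting to the
#'   discriminating probe set (row names).
#' @return object of class `loy_ratio`: `ratios` (probe x male-sample),
#'   `female_mean`, `male_normal_adjusted_mean`, `male_sex`/`male_group`
#'   bookkeeping, `dropped` probes.
#' @export
expression_ratio <- function(intensity, sex, group, probes = NULL) {
  if (length(sex) != ncol(intensity) || length(group) != ncol(intensity))
    loy_usage_error("'sex' and 'group' must match the intensity columns")
  if (!any(sex == "female"))
    loy_usage_error("at least one female sample is required")
  if (!any(sex == "male" & group == "normal"))
    loy_usage_error("at least one male normal sample is required")
  if (!is.null(probes)) {
    missing <- setdiff(probes, rownames(intensity))
    if (length(missing))
      loy_usage_error(sprintf("probe(s) not in matrix: %s",
                              paste(missing, collapse = ", ")))
    intensity <- intensity[probes, , drop = FALSE]
  }
  fmean <- rowMeans(intensity[, sex == "female", drop = FALSE])
  adj <- intensity - fmean
  ref <- rowMeans(adj[, sex == "male" & group == "normal", drop = FALSE])
  drop <- ref <= 0
  if (any(drop)) {
    warning("dropping probe(s) with non-positive male-normal adjusted mean: ",
            paste(rownames(intensity)[drop], collapse = ", "), call. = FALSE)
    if (all(drop))
      loy_usage_error("no usable probes left after reference filtering")
  }
  male <- sex == "male"
  ratios <- (adj[!drop, male, drop = FALSE]) / ref[!drop]
  structure(list(
    ratios = ratios,
    female_mean = fmean[!drop],
    male_normal_adjusted_mean = ref[!drop],
    male_group = group[male],
    dropped = rownames(intensity)[drop]
  ), class = "loy_ratio")
}

#' Principal-component LoY caller for expression ratios
#'
#' Combines the per-probe expression ratios of male samples into a single
#' LoY score: probes are mean-centered (not scaled, the ratios share a
#' scale by construction), the first principal component is extracted, and
#' its sign is oriented so the male-normal mean score is positive (high
#' score = retained Y). [fit_bimodal()] and [classify_loy()] are then
#' applied to the PC1 scores.
#'
#' @param ratio a `loy_ratio` from [expression_ratio()].
#' @param bandwidth,min_separation passed to [fit_bimodal()].
#' @return list of class `loy_pc`: `scores` (named), `var_explained`,
#'   `fit`, `calls`.
#' @export
pc_loy <- function(ratio, bandwidth = "nrd0", min_separation = 0.2) {
  if (!inherits(ratio, "loy_ratio"))
    loy_usage_error("'ratio' must come from expression_ratio()")
  x <- t(ratio$ratios)  # samples x probes
  if (ncol(x) < 2L) loy_usage_error("pc_loy needs at least 2 probes")
  if (nrow(x) < 20L) loy_usage_error("pc_loy needs at least 20 male samples")
  if (all(apply(x, 2, sd) < .Machine$double.eps^0.5))
    loy_usage_error("degenerate input: all ratios constant")
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  scores <- pc$x[, 1L]
  is_normal <- ratio$male_group == "normal"
  flip <- if (any(is_normal)) mean(scores[is_normal]) < 0 else
    cor(scores, rowMeans(x)) < 0
  if (flip) scores <- -scores
  fit <- fit_bimodal(scores, bandwidth, min_separation)
  calls <- classify_loy(scores, fit)
  structure(list(scores = scores,
                 var_explained = pc$sdev[1L]^2 / sum(pc$sdev^2),
                 fit = fit, calls = calls),
            class = "loy_pc")
}
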