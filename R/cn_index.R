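#' Length-weighted copy-number index for one arm
#'
#' The arm index is the average linear copy number across the whole
#' (exclusion-masked) arm: the overlap-length-weighted mean of the segment
#' copy numbers intersecting the arm. Exclusion intervals (e.g. PARs) are
#' removed from both the arm length and the segment overlaps.
#'
#' @param start,end,cn parallel vectors describing the segments of one
#'   sample on the arm's chromosome (0-based half-open, linear CN).
#' @param arm_start,arm_end arm boundaries (0-based half-open).
#' @param excl_start,excl_end optional exclusion intervals (disjoint).
#' @return list with `index` (NA when nothing overlaps) and
#'   `covered_fraction` of the masked arm length.
#' @examples
#' arm_index(0, 100, 2, 0, 100)          # index 2, covered 1
#' arm_index(c(0, 50), c(50, 100), c(1, 3), 0, 100)  # index 2
#' @export
arm_index <- function(start, end, cn, arm_start, arm_end,
                      excl_start = numeric(), excl_end = numeric()) {
  stopifnot(length(start) == length(end), length(start) == length(cn))
  mlen <- .masked_length(arm_start, arm_end, excl_start, excl_end)
  if (mlen <= 0) return(list(index = NA_real_, covered_fraction = 0))
  ov <- .masked_overlap(start, end, arm_start, arm_end, excl_start, excl_end)
  tot <- sum(ov)
  if (tot <= 0) return(list(index = NA_real_, covered_fraction = 0))
  list(index = sum(ov * cn) / tot, covered_fraction = tot / mlen)
}

#' Sample-by-arm copy-number index matrix
#'
#' Computes [arm_index()] for every sample and every arm of the genome
#' table. PAR exclusion intervals are applied to the arms of X and Y.
#' Indices are unadjusted for purity (see [purity_adjust()] /
#' [sample_indices()]).
#'
#' @param segments a `loy_segments` data.frame (see [read_seg()]).
#' @param genome a `loy_genome` from [genome_arms()].
#' @param value_scale override of the segments' value scale attribute.
#' @return list of class `loy_arm_matrix`: `index` and `covered`
#'   (sample x arm matrices), `genome`, and `purity_adjusted = FALSE`.
#' @export
arm_index_matrix <- function(segments, genome = genome_arms(),
                             value_scale = NULL) {
  cn <- .seg_linear(segments, value_scale)
  samples <- unique(segments$sample)
  arms <- genome$arms
  idx <- cov <- matrix(NA_real_, length(samples), nrow(arms),
                       dimnames = list(samples, arms$arm_id))
  by_chrom <- split(seq_len(nrow(segments)), segments$chrom)
  for (j in seq_len(nrow(arms))) {
    rows <- by_chrom[[arms$chrom[j]]]
    if (is.null(rows)) next
    excl <- genome$par[genome$par$chrom == arms$chrom[j], , drop = FALSE]
    ov <- .masked_overlap(segments$start[rows], segments$end[rows],
                          arms$start[j], arms$end[j],
                          excl$start, excl$end)
    keep <- ov > 0
    if (!any(keep)) next
    rows <- rows[keep]; ov <- ov[keep]
    tot <- rowsum(ov, segments$sample[rows])
    wcn <- rowsum(ov * cn[rows], segments$sample[rows])
    mlen <- .masked_length(arms$start[j], arms$end[j], excl$start, excl$end)
    idx[rownames(tot), j] <- wcn[, 1L] / tot[, 1L]
    cov[rownames(tot), j] <- tot[, 1L] / mlen
  }
  cov[is.na(cov)] <- 0
  structure(list(index = idx, covered = cov, genome = genome,
                 purity_adjusted = FALSE),
            class = "loy_arm_matrix")
}

#' Adjust an observed copy-number index for tumor purity
#'
#' Assumes the observed index is a two-component mixture of tumor and
#' contaminating normal cells, `observed = p * tumor + (1 - p) * normal_cn`,
#' and solves for the tumor copy number, floored at 0. Samples with missing
#' purity are returned unchanged (callers flag them as unadjusted); in real
#' cohorts purity is the clinical `tumor_nuclei_percent` / 100.
#'
#' @param observed observed index (linear CN), vectorized.
#' @param purity tumor purity in (0, 1]; `NA` passes `observed` through.
#' @param normal_cn copy number of the normal component: 1 for the male Y
#'   (and male X), 2 for autosomes.
#' @return adjusted index, `max(0, (observed - (1 - p) * normal_cn) / p)`.
#' @examples
#' purity_adjust(0.75, 0.5, 1) # 0.5
#' @export
purity_adjust <- function(observed, purity, normal_cn) {
  if (!all(normal_cn %in% c(1, 2)))
    loy_param_error("'normal_cn' must be 1 or 2", field = "normal_cn")
  bad <- !is.na(purity) & (purity <= 0 | purity > 1)
  if (any(bad))
    loy_param_error("'purity' must be in (0, 1] (0 is not identifiable)",
                    field = "purity")
  k <- max(length(observed), length(purity))
  observed <- rep_len(observed, k)
  purity <- rep_len(purity, k)
  normal_cn <- rep_len(normal_cn, k)
  adj <- pmax(0, (observed - (1 - purity) * normal_cn) / purity)
  adj[is.na(purity)] <- observed[is.na(purity)]
  adj
}

#' Y chromosome copy-number index over the male-specific region
#'
#' Length-weighted linear copy number of the Y segments outside the
#' pseudoautosomal regions, purity-adjusted with a normal copy number of 1
#' (one Y per normal male cell). A retained Y gives an index near 1; loss
#' in all tumor cells of a pure sample gives 0. Samples without any Y
#' coverage get `NA` with a warning (real SEG emissions omit absent
#' chromosomes).
#'
#' @param segments a `loy_segments` data.frame; only male samples may carry
#'   Y segments.
#' @param purity named vector of purities (fractions) or `NULL`.
#' @param sex optional named vector (`"male"`/`"female"`); female samples
#'   are a usage error, this operation is male-specific.
#' @param genome a `loy_genome`.
#' @param value_scale override of the segments' scale attribute.
#' @return data.frame: `sample`, `y_index`, `covered_fraction`,
#'   `purity_adjusted`.
#' @export
y_index <- function(segments, purity = NULL, sex = NULL,
                    genome = genome_arms(), value_scale = NULL) {
  samples <- unique(segments$sample)
  if (!is.null(sex)) {
    fem <- samples[samples %in% names(sex)[sex == "female"]]
    if (length(fem))
      loy_usage_error(sprintf(
        "y_index is defined for male samples only; female sample(s): %s",
        paste(utils::head(fem, 3), collapse = ", ")))
  }
  cn <- .seg_linear(segments, value_scale)
  yarms <- genome$arms[genome$arms$chrom == "Y", , drop = FALSE]
  excl <- genome$par[genome$par$chrom == "Y", , drop = FALSE]
  on_y <- which(segments$chrom == "Y")
  wsum <- csum <- setNames(numeric(length(samples)), samples)
  msy_len <- 0
  for (j in seq_len(nrow(yarms))) {
    msy_len <- msy_len +
      .masked_length(yarms$start[j], yarms$end[j], excl$start, excl$end)
    if (!length(on_y)) next
    ov <- .masked_overlap(segments$start[on_y], segments$end[on_y],
                          yarms$start[j], yarms$end[j],
                          excl$start, excl$end)
    keep <- ov > 0
    if (!any(keep)) next
    sid <- segments$sample[on_y[keep]]
    wsum[unique(sid)] <- wsum[unique(sid)] +
      rowsum(ov[keep] * cn[on_y[keep]], sid)[unique(sid), 1L]
    csum[unique(sid)] <- csum[unique(sid)] +
      rowsum(ov[keep], sid)[unique(sid), 1L]
  }
  raw <- ifelse(csum > 0, wsum / csum, NA_real_)
  if (any(csum == 0))
    warning(sum(csum == 0), " sample(s) without Y coverage: y_index absent",
            call. = FALSE)
  p <- if (is.null(purity)) rep(NA_real_, length(samples)) else
    unname(purity[samples])
  data.frame(
    sample = samples,
    y_index = purity_adjust(raw, p, 1),
    covered_fraction = unname(csum) / msy_len,
    purity_adjusted = !is.na(p),
    row.names = NULL
  )
}

#' Total autosomal aneuploidy index
#'
#' Sum over the included autosomal arms of the absolute difference between 2
#' and the (purity-adjusted, normal CN 2) arm index. The short arms of the
#' acrocentric chromosomes 13, 14, 15 and 22 are excluded (no array
#' coverage); arms with no segment coverage are skipped and counted.
#'
#' @param arm_values named numeric vector of one sample's autosomal arm
#'   indices (names are `arm_id`s such as `"3p"`), unadjusted linear CN.
#' @param purity scalar purity or `NA` (no adjustment).
#' @param excluded_arms character vector of `arm_id`s to drop.
#' @return list: `aneuploidy_index`, `n_arms_used`, `n_arms_missing`.
#' @examples
#' v <- setNames(rep(2, 4), c("1p", "1q", "2p", "2q"))
#' aneuploidy_index(v)$aneuploidy_index # 0
#' @export
aneuploidy_index <- function(arm_values, purity = NA_real_,
                             excluded_arms = genome_arms()$excluded_arms) {
  sex_arms <- grepl("^[XY]", names(arm_values))
  arm_values <- arm_values[!sex_arms & !names(arm_values) %in% excluded_arms]
  miss <- is.na(arm_values)
  adj <- purity_adjust(arm_values[!miss], purity, 2)
  list(aneuploidy_index = sum(abs(2 - adj)),
       n_arms_used = sum(!miss), n_arms_missing = sum(miss))
}

#' Per-sample Y and aneuploidy indices from segments
#'
#' Convenience wrapper computing, per sample: the purity-adjusted Y index
#' over the male-specific region (males only), the total autosomal
#' aneuploidy index, and coverage diagnostics. Arms covered on less than
#' half of their masked length are counted as low-confidence but still used
#' (no coverage filter is applied).
#'
#' @param segments a `loy_segments` data.frame.
#' @param clinical optional data.frame with `sample_id`, `sex` and
#'   `tumor_nuclei_percent` (purity in percent; `NA` allowed).
#' @param genome a `loy_genome`.
#' @param value_scale override of the segments' scale attribute.
#' @return data.frame of class `loy_sample_indices`: `sample`, `sex`,
#'   `y_index`, `y_covered_fraction`, `aneuploidy_index`, `n_arms_used`,
#'   `n_arms_missing`, `n_arms_low_coverage`, `purity`, `purity_adjusted`.
#' @export
sample_indices <- function(segments, clinical = NULL,
                           genome = genome_arms(), value_scale = NULL) {
  # resolve the scale once: data.frame subsetting below drops attributes
  value_scale <- value_scale %||% attr(segments, "value_scale") %||%
    "log2ratio"
  am <- arm_index_matrix(segments, genome, value_scale)
  samples <- rownames(am$index)
  purity <- sex <- NULL
  if (!is.null(clinical)) {
    m <- match(samples, clinical$sample_id)
    if ("tumor_nuclei_percent" %in% names(clinical))
      purity <- setNames(clinical$tumor_nuclei_percent[m] / 100, samples)
    if ("sex" %in% names(clinical))
      sex <- setNames(as.character(clinical$sex[m]), samples)
  }
  if (is.null(purity)) purity <- setNames(rep(NA_real_, length(samples)),
                                          samples)
  is_male <- if (is.null(sex)) rep(TRUE, length(samples)) else
    !is.na(sex) & sex == "male"
  yi <- rep(NA_real_, length(samples)); ycov <- rep(NA_real_, length(samples))
  if (any(is_male)) {
    male_seg <- segments[segments$sample %in% samples[is_male], , drop = FALSE]
    if (nrow(male_seg)) {
      ytab <- suppressWarnings(
        y_index(male_seg, purity, sex = NULL, genome, value_scale))
      m <- match(samples, ytab$sample)
      yi <- ytab$y_index[m]
      ycov <- ytab$covered_fraction[m]
    }
  }
  aneu <- t(vapply(seq_along(samples), function(i) {
    a <- aneuploidy_index(am$index[i, ], purity[i], genome$excluded_arms)
    c(a$aneuploidy_index, a$n_arms_used, a$n_arms_missing)
  }, numeric(3)))
  auto <- !grepl("^[XY]", colnames(am$covered)) &
    !colnames(am$covered) %in% genome$excluded_arms
  low <- rowSums(am$covered[, auto, drop = FALSE] < 0.5 &
                   am$covered[, auto, drop = FALSE] > 0)
  structure(data.frame(
    sample = samples,
    sex = if (is.null(sex)) NA_character_ else unname(sex),
    y_index = yi,
    y_covered_fraction = ycov,
    aneuploidy_index = aneu[, 1L],
    n_arms_used = as.integer(aneu[, 2L]),
    n_arms_missing = as.integer(aneu[, 3L]),
    n_arms_low_coverage = as.integer(unname(low)),
    purity = unname(purity),
    purity_adjusted = !is.na(unname(purity)),
    row.names = NULL
  ), class = c("loy_sample_indices", "data.frame"))
}
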