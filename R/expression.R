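#' Counts-per-million normalization
#'
#' Converts a gene x sample count matrix to CPM, either with plain library
#' sizes or with TMM (trimmed mean of M-values) effective library sizes.
#'
#' @param counts non-negative integer matrix, genes in rows.
#' @param method `"library_size"` or `"tmm"`.
#' @return CPM matrix with attribute `norm_factors` (all 1 for
#'   `library_size`).
#' @examples
#' m <- matrix(c(10, 90, 20, 180), 2, dimnames = list(c("g1", "g2"), NULL))
#' colSums(cpm_normalize(m)) # both 1e6
#' @export
cpm_normalize <- function(counts, method = c("library_size", "tmm")) {
  method <- match.arg(method)
  counts <- as.matrix(counts)
  if (any(counts < 0)) loy_usage_error("counts must be non-negative")
  lib <- colSums(counts)
  zero <- lib == 0
  if (any(zero))
    loy_usage_error(sprintf("all-zero sample(s): %s",
                            paste(colnames(counts)[zero] %||%
                                    which(zero), collapse = ", ")))
  f <- if (method == "tmm") tmm_factors(counts) else
    setNames(rep(1, ncol(counts)), colnames(counts))
  cpm <- sweep(counts, 2, lib * f, `/`) * 1e6
  attr(cpm, "norm_factors") <- f
  cpm
}

#' TMM normalization factors
#'
#' Weighted trimmed mean of M-values between each sample and a reference
#' sample: genes with zero counts in either sample are removed, log ratios
#' (M) are trimmed 30% from each tail and log abundances (A) 5% from each
#' tail, and the remaining M values are averaged with inverse asymptotic
#' variance weights. The reference is the sample whose 75th count
#' percentile (scaled by library size) is nearest the mean across samples;
#' factors are normalized to geometric mean 1.
#'
#' @param counts gene x sample count matrix.
#' @param logratio_trim,abundance_trim tail-trim fractions for M and A.
#' @return named vector of normalization factors.
#' @export
tmm_factors <- function(counts, logratio_trim = 0.3, abundance_trim = 0.05) {
  counts <- as.matrix(counts)
  lib <- colSums(counts)
  f75 <- apply(counts, 2, function(x) quantile(x, 0.75)) / lib
  ref <- which.min(abs(f75 - mean(f75)))
  yr <- counts[, ref]; nr <- lib[ref]
  f <- vapply(seq_len(ncol(counts)), function(k) {
    yk <- counts[, k]; nk <- lib[k]
    if (k == ref) return(1)
    keep <- yk > 0 & yr > 0
    y1 <- yk[keep]; y2 <- yr[keep]
    m <- log2((y1 / nk) / (y2 / nr))
    a <- 0.5 * log2((y1 / nk) * (y2 / nr))
    w <- 1 / ((nk - y1) / (nk * y1) + (nr - y2) / (nr * y2))
    fin <- is.finite(m) & is.finite(a)
    m <- m[fin]; a <- a[fin]; w <- w[fin]
    n <- length(m)
    if (n == 0L) return(1)
    if (max(abs(m)) < 1e-6) return(1)  # edgeR's early exit for equal samples
    lo_m <- floor(n * logratio_trim) + 1; hi_m <- n + 1 - lo_m
    lo_a <- floor(n * abundance_trim) + 1; hi_a <- n + 1 - lo_a
    rm_ <- rank(m, ties.method = "first")
    ra_ <- rank(a, ties.method = "first")
    keep2 <- rm_ >= lo_m & rm_ <= hi_m & ra_ >= lo_a & ra_ <= hi_a
    if (!any(keep2)) return(1)
    2^(sum(w[keep2] * m[keep2]) / sum(w[keep2]))
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  setNames(f, colnames(counts))
}

#' Screen genes whose expression tracks the Y index
#'
#' Per-gene Spearman correlation (average ranks on ties) between expression
#' and the per-sample Y copy-number index. In a male tumor cohort only
#' Y-linked dosage-sensitive genes are expected to exceed rho 0.5.
#'
#' @param cpm gene x sample expression matrix (any monotone unit: the
#'   statistic is rank-based).
#' @param y_indices named numeric vector of Y indices; at least 10 samples
#'   must overlap the matrix columns.
#' @param rho_threshold report genes with rho strictly above this value.
#' @return data.frame `gene`, `rho`, sorted by decreasing rho, restricted
#'   to `rho > rho_threshold`; the full table is in attribute `all_genes`.
#' @export
y_gene_screen <- function(cpm, y_indices, rho_threshold = 0.5) {
  common <- intersect(colnames(cpm), names(y_indices))
  common <- common[!is.na(y_indices[common])]
  if (length(common) < 10L)
    loy_usage_error("need at least 10 overlapping samples with a Y index")
  yr <- rank(y_indices[common])
  xr <- t(apply(cpm[, common, drop = FALSE], 1, rank))
  rho <- as.numeric(cor(t(xr), yr))
  all <- data.frame(gene = rownames(cpm), rho = rho)
  all <- all[order(-all$rho), , drop = FALSE]
  rownames(all) <- NULL
  hits <- all[!is.na(all$rho) & all$rho > rho_threshold, , drop = FALSE]
  structure(hits, all_genes = all, n = length(common))
}

#' Filtered differential expression between two sample groups
#'
#' Implements the study-style DE filter on a CPM matrix: a per-gene
#' two-sample test (Welch t on `log2(CPM + 0.5)` by default, Wilcoxon
#' rank-sum as an alternative), fold change from group mean CPM with a 0.5
#' pseudo-count, and a three-part pass flag: `|fold change| >= fc_threshold`
#' and `p < p_threshold` and `CPM > cpm_floor` in at least as many samples
#' as the smaller group. No multiple-testing correction is applied here by
#' design; the filter operates on raw p plus the fold-change and expression
#' floors.
#'
#' @param cpm gene x sample CPM matrix.
#' @param group_a,group_b disjoint character vectors of column names (each
#'   of size >= 3). Fold change is a over b.
#' @param p_threshold raw p-value cut.
#' @param fc_threshold fold-change cut (linear, default 1.5).
#' @param cpm_floor expression floor (default 1).
#' @param test `"welch"` or `"wilcoxon"`.
#' @return data.frame of class `loy_de`: `gene`, `log2_fc`, `p_value`,
#'   `mean_cpm_a`, `mean_cpm_b`, `n_expressed`, `passes_filters`, sorted by
#'   p.
#' @export
de_test <- function(cpm, group_a, group_b, p_threshold = 0.05,
                    fc_threshold = 1.5, cpm_floor = 1,
                    test = c("welch", "wilcoxon")) {
  test <- match.arg(test)
  if (length(intersect(group_a, group_b)))
    loy_usage_error("groups overlap")
  if (length(group_a) < 3L || length(group_b) < 3L)
    loy_usage_error("both groups need at least 3 samples")
  missing <- setdiff(c(group_a, group_b), colnames(cpm))
  if (length(missing))
    loy_usage_error(sprintf("sample(s) not in matrix: %s",
                            paste(utils::head(missing, 3), collapse = ", ")))
  a <- cpm[, group_a, drop = FALSE]
  b <- cpm[, group_b, drop = FALSE]
  la <- log2(a + 0.5); lb <- log2(b + 0.5)
  n1 <- ncol(a); n2 <- ncol(b)
  if (test == "welch") {
    m1 <- rowMeans(la); m2 <- rowMeans(lb)
    v1 <- rowSums((la - m1)^2) / (n1 - 1)
    v2 <- rowSums((lb - m2)^2) / (n2 - 1)
    se2 <- v1 / n1 + v2 / n2
    tt <- (m1 - m2) / sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    p <- 2 * pt(-abs(tt), df)
    p[!is.finite(tt)] <- 1  # zero variance, equal means
  } else {
    p <- apply(cpm[, c(group_a, group_b), drop = FALSE], 1, function(x)
      suppressWarnings(wilcox.test(x[seq_len(n1)], x[-seq_len(n1)])$p.value))
    p[is.na(p)] <- 1
  }
  ma <- rowMeans(a); mb <- rowMeans(b)
  log2_fc <- log2((ma + 0.5) / (mb + 0.5))
  n_expressed <- rowSums(cbind(a, b) > cpm_floor)
  passes <- abs(log2_fc) >= log2(fc_threshold) & p < p_threshold &
    n_expressed >= min(n1, n2)
  out <- data.frame(gene = rownames(cpm), log2_fc = log2_fc, p_value = p,
                    mean_cpm_a = ma, mean_cpm_b = mb,
                    n_expressed = n_expressed, passes_filters = passes,
                    row.names = NULL)
  out <- out[order(out$p_value), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("loy_de", "data.frame"),
            n_a = n1, n_b = n2, p_threshold = p_threshold)
}

#' Flag samples whose reported sex contradicts Y-marker expression
#'
#' Computes a per-sample Y-marker score (mean `log2(CPM + 0.5)` over the
#' marker genes) and flags samples falling on the wrong side of the
#' midpoint between the male and female group means.
#'
#' @param cpm gene x sample expression matrix.
#' @param sex named or column-aligned `"male"`/`"female"` vector.
#' @param y_markers character vector of Y-linked marker genes present in
#'   the matrix.
#' @return data.frame `sample`, `reported_sex`, `y_score`, `flagged`.
#' @export
sex_concordance <- function(cpm, sex, y_markers) {
  y_markers <- intersect(y_markers, rownames(cpm))
  if (!length(y_markers)) loy_usage_error("no Y marker genes in the matrix")
  if (length(unique(sex)) < 2L)
    loy_usage_error("both sexes must be present")
  score <- colMeans(log2(cpm[y_markers, , drop = FALSE] + 0.5))
  mid <- (mean(score[sex == "male"]) + mean(score[sex == "female"])) / 2
  flagged <- (sex == "male" & score < mid) | (sex == "female" & score > mid)
  data.frame(sample = colnames(cpm), reported_sex = sex,
             y_score = unname(score), flagged = unname(flagged),
             row.names = NULL)
}

#' Read gene sets in GMT format
#'
#' @param path GMT file (term, description, genes..., tab-separated).
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[`, character(1), 1L)
  sets
}

#' Hypergeometric gene-set enrichment
#'
#' One-sided hypergeometric test of each gene set against a hit list, with
#' fold enrichment `(k/n) / (K/N)` (k = hits in term, n = hits, K = term
#' size in universe, N = universe size) and Benjamini-Hochberg adjustment
#' across the tested terms. Terms with no hits are reported with fold
#' enrichment 0 and p = 1.
#'
#' @param hits character vector of significant genes (subset of universe).
#' @param universe character vector of all tested genes.
#' @param gene_sets named list of character vectors (e.g. [read_gmt()]);
#'   each set is intersected with the universe first.
#' @return data.frame of class `loy_enrichment`: `term`, `k`, `term_size`,
#'   `n_hits`, `universe_size`, `fold_enrichment`, `p_value`,
#'   `p_adjusted`, sorted by p.
#' @export
enrich <- function(hits, universe, gene_sets) {
  universe <- unique(universe)
  if (!length(universe)) loy_usage_error("empty universe")
  hits <- unique(hits)
  if (length(setdiff(hits, universe)))
    loy_usage_error("hits must be a subset of the universe")
  n <- length(hits); N <- length(universe)
  rows <- lapply(names(gene_sets), function(term) {
    set <- intersect(gene_sets[[term]], universe)
    K <- length(set)
    if (K == 0L) return(NULL)  # term absent from the universe: untestable
    k <- length(intersect(hits, set))
    p <- if (k == 0L) 1 else phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    fe <- if (k == 0L || n == 0L) 0 else (k / n) / (K / N)
    data.frame(term = term, k = k, term_size = K, n_hits = n,
               universe_size = N, fold_enrichment = fe, p_value = p)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(term = character(), k = integer(),
                      term_size = integer(), n_hits = integer(),
                      universe_size = integer(),
                      fold_enrichment = numeric(), p_value = numeric())
  out$p_adjusted <- p.adjust(out$p_value, "BH")
  out <- out[order(out$p_value), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("loy_enrichment", "data.frame"))
}
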