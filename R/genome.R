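#' Chromosome-arm and pseudoautosomal-region tables
#'
#' Returns the packaged GRCh37/hg19 cytoband-derived arm boundaries together
#' with the pseudoautosomal regions (PARs) as exclusion intervals and the
#' default excluded-arm set for the aneuploidy index. All coordinates are
#' 0-based half-open; arms within a chromosome are disjoint with p before q
#' (the intervening centromere belongs to neither arm).
#'
#' The short arms of the acrocentric chromosomes 13, 14, 15 and 22 carry no
#' usable SNP-array probes and are excluded from the aneuploidy index by
#' default. 21p (also acrocentric) is included by default but can be
#' excluded via `include_21p = FALSE`.
#'
#' @param include_21p logical; keep 21p in the aneuploidy arm set
#'   (default `TRUE`).
#' @param arm_file,par_file optional paths overriding the packaged tables
#'   (tab-separated, columns `chrom`, `arm`/`name`, `start`, `end`).
#' @return A list of class `loy_genome` with elements `arms` (data.frame:
#'   `chrom`, `arm`, `start`, `end`, `arm_id`), `par` (data.frame of
#'   exclusion intervals), and `excluded_arms` (character vector of
#'   `arm_id`s excluded from the aneuploidy index).
#' @examples
#' g <- genome_arms()
#' subset(g$arms, chrom == "Y")
#' @export
genome_arms <- function(include_21p = TRUE, arm_file = NULL,
                        par_file = NULL) {
  if (is.null(arm_file))
    arm_file <- system.file("extdata", "grch37_arms.tsv", package = "loyscan",
                            mustWork = TRUE)
  if (is.null(par_file))
    par_file <- system.file("extdata", "grch37_par.tsv", package = "loyscan",
                            mustWork = TRUE)
  arms <- read.delim(arm_file, colClasses = c("character", "character",
                                              "numeric", "numeric"))
  par <- read.delim(par_file, colClasses = c("character", "character",
                                             "numeric", "numeric"))
  arms$arm_id <- paste0(arms$chrom, arms$arm)
  excluded <- c("13p", "14p", "15p", "22p")
  if (!include_21p) excluded <- c(excluded, "21p")
  structure(list(arms = arms, par = par, excluded_arms = excluded),
            class = "loy_genome")
}

# Total overlap of segments [s, e) with window [a, b), minus any overlap
# with the (pairwise disjoint) exclusion intervals. Vectorized over s/e.
.masked_overlap <- function(s, e, a, b, excl_start = numeric(),
                            excl_end = numeric()) {
  ov <- pmax(0, pmin(e, b) - pmax(s, a))
  if (length(excl_start)) {
    for (i in seq_along(excl_start)) {
      xs <- max(a, excl_start[i]); xe <- min(b, excl_end[i])
      if (xe > xs) ov <- ov - pmax(0, pmin(e, xe) - pmax(s, xs))
    }
  }
  ov
}

# Arm length after removing exclusion intervals.
.masked_length <- function(a, b, excl_start = numeric(),
                           excl_end = numeric()) {
  len <- b - a
  if (length(excl_start))
    len <- len - sum(pmax(0, pmin(b, excl_end) - pmax(a, excl_start)))
  len
}
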