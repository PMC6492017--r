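#' Read a SEG file of segmented copy-number data
#'
#' Parses the tab-separated SEG dialect used for SNP-array level-3 segmented
#' data: columns Sample, Chromosome, Start, End, Num_Probes, Segment_Mean
#' with 1-based inclusive coordinates. Coordinates are converted to the
#' package's internal 0-based half-open convention and `chr` prefixes are
#' stripped from chromosome names.
#'
#' @param path file path.
#' @param value_scale scale of the Segment_Mean column: `"log2ratio"`
#'   (log2(CN/2), the SNP-array convention) or `"linear"` (copy number).
#' @return A data.frame of class `loy_segments` with columns `sample`,
#'   `chrom`, `start`, `end`, `n_markers`, `value` and attribute
#'   `value_scale`.
#' @seealso [to_linear_cn()], [arm_index_matrix()]
#' @export
read_seg <- function(path, value_scale = c("log2ratio", "linear")) {
  value_scale <- match.arg(value_scale)
  if (!file.exists(path))
    loy_usage_error(sprintf("SEG file not found: %s", path))
  raw <- read.delim(path, colClasses = "character", check.names = FALSE)
  if (ncol(raw) < 5L)
    loy_parse_error("SEG file must have at least 5 columns")
  has_markers <- ncol(raw) >= 6L
  seg <- data.frame(
    sample = raw[[1L]],
    chrom = sub("^chr", "", raw[[2L]]),
    start = suppressWarnings(as.numeric(raw[[3L]])),
    end = suppressWarnings(as.numeric(raw[[4L]])),
    n_markers = if (has_markers)
      suppressWarnings(as.numeric(raw[[5L]])) else NA_real_,
    value = suppressWarnings(as.numeric(raw[[if (has_markers) 6L else 5L]])),
    stringsAsFactors = FALSE
  )
  if (nrow(seg) == 0L) {
    warning("empty SEG file: ", path, call. = FALSE)
    return(structure(seg, value_scale = value_scale,
                     class = c("loy_segments", "data.frame")))
  }
  valid_chrom <- c(as.character(1:22), "X", "Y")
  # +1 for the header line when reporting positions
  bad <- which(!seg$chrom %in% valid_chrom)
  if (length(bad))
    loy_parse_error(sprintf("unknown chromosome '%s' at line %d",
                            seg$chrom[bad[1L]], bad[1L] + 1L))
  bad <- which(is.na(seg$start) | is.na(seg$end) | is.na(seg$value))
  if (length(bad))
    loy_parse_error(sprintf("non-numeric coordinate or value at line %d",
                            bad[1L] + 1L))
  # 1-based inclusive -> 0-based half-open
  seg$start <- seg$start - 1
  bad <- which(seg$start >= seg$end)
  if (length(bad))
    loy_parse_error(sprintf("start >= end at line %d", bad[1L] + 1L))
  if (any(!is.finite(seg$value)))
    loy_parse_error("non-finite segment value")
  structure(seg, value_scale = value_scale,
            class = c("loy_segments", "data.frame"))
}

#' Write segments as a SEG file
#'
#' Inverse of [read_seg()]: emits 1-based inclusive coordinates with the
#' standard header.
#'
#' @param segments a `loy_segments` data.frame (0-based half-open).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_seg <- function(segments, path) {
  out <- data.frame(
    Sample = segments$sample,
    Chromosome = segments$chrom,
    Start = segments$start + 1,
    End = segments$end,
    Num_Probes = segments$n_markers,
    Segment_Mean = segments$value
  )
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Convert segment values to linear copy number
#'
#' Copy-number indices in this package live on a linear scale where a
#' diploid autosome is 2 and a single Y copy is 1. SNP-array segment means
#' are conventionally log2(CN/2), so `log2ratio` values v map to `2 * 2^v`;
#' `linear` values pass through unchanged.
#'
#' @param value numeric vector of segment values.
#' @param value_scale `"log2ratio"` or `"linear"`.
#' @return numeric vector of linear copy numbers.
#' @examples
#' to_linear_cn(c(0, -1), "log2ratio") # 2, 1
#' @export
to_linear_cn <- function(value, value_scale = c("log2ratio", "linear")) {
  value_scale <- match.arg(value_scale)
  if (value_scale == "linear") value else 2 * 2^value
}

# Internal: segments -> linear CN values using the object's scale attribute
# (overridable).
.seg_linear <- function(segments, value_scale = NULL) {
  if (is.null(value_scale))
    value_scale <- attr(segments, "value_scale") %||% "log2ratio"
  to_linear_cn(segments$value, value_scale)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
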