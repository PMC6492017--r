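#' Pipeline configuration
#'
#' Bundles the input paths and tuning parameters of [run_analysis()].
#' Configuration files for the command line may be JSON or YAML with the
#' same field names.
#'
#' @param seg path to the SEG file (required).
#' @param clinical path to the clinical TSV (required; columns `sample_id`,
#'   `sex`, `hpv_status` plus optional `age`, `smoking_category`,
#'   `tp53_mutated`, `tumor_nuclei_percent`, `survival_time`,
#'   `survival_event`, `pathologic_t`, `pathologic_n`, `site`).
#' @param counts optional gene x sample counts TSV (first column = gene).
#' @param gmt optional GMT gene-set file for enrichment.
#' @param value_scale scale of the SEG segment means.
#' @param bandwidth,min_separation passed to [fit_bimodal()].
#' @param p_threshold_hpv_negative,p_threshold_hpv_positive DE p cuts per
#'   stratum (defaults 0.01 and 0.05).
#' @param fc_threshold DE fold-change cut.
#' @param include_21p keep 21p in the aneuploidy index.
#' @param out_dir output directory for [write_report()].
#' @param seed integer seed for any randomized step.
#' @return validated list of class `loy_pipeline_config`.
#' @export
loy_config <- function(seg, clinical, counts = NULL, gmt = NULL,
                       value_scale = c("log2ratio", "linear"),
                       bandwidth = "nrd0", min_separation = 0.2,
                       p_threshold_hpv_negative = 0.01,
                       p_threshold_hpv_positive = 0.05,
                       fc_threshold = 1.5, include_21p = TRUE,
                       out_dir = "loyscan_out", seed = 1L) {
  for (thr in c(p_threshold_hpv_negative, p_threshold_hpv_positive))
    if (!is.numeric(thr) || thr <= 0 || thr >= 1)
      loy_param_error("DE p thresholds must lie in (0, 1)",
                      field = "p_threshold")
  structure(list(
    seg = seg, clinical = clinical, counts = counts, gmt = gmt,
    value_scale = match.arg(value_scale), bandwidth = bandwidth,
    min_separation = min_separation,
    p_threshold_hpv_negative = p_threshold_hpv_negative,
    p_threshold_hpv_positive = p_threshold_hpv_positive,
    fc_threshold = fc_threshold, include_21p = include_21p,
    out_dir = out_dir, seed = .assert_count(seed, "seed")
  ), class = "loy_pipeline_config")
}

#' Read a pipeline configuration file (JSON or YAML)
#'
#' @param path configuration file; keys are the arguments of [loy_config()].
#' @return a `loy_pipeline_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) loy_usage_error(sprintf("config not found: %s",
                                                  path))
  vals <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      loy_usage_error("YAML config requires the 'yaml' package; use JSON")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(loy_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    loy_param_error(sprintf("unknown config field(s): %s",
                            paste(unknown, collapse = ", ")))
  do.call(loy_config, vals)
}

#' Run the full LoY study on one cohort
#'
#' Per HPV stratum (negative / positive): computes purity-adjusted sample
#' indices, fits the bimodal Y-index density on the stratum's males,
#' classifies LOY / RETAINED / UNCERTAIN, and runs the association battery
#' on the confident calls: LoY-vs-retained overall survival (Kaplan-Meier +
#' log-rank), univariate Cox on the Y index, smoking (Kruskal-Wallis on the
#' Y index), age (Spearman), aneuploidy (Wilcoxon LoY vs retained and
#' Kruskal-Wallis on pathologic T), and TP53 (Fisher). With a counts matrix
#' it adds the filtered DE comparisons (LoY vs retained; top vs bottom
#' aneuploidy terciles) and, with gene sets, hypergeometric enrichment of
#' the up/down lists. Strata whose Y-index density is unimodal are skipped
#' with an annotation; missing clinical columns degrade gracefully.
#'
#' @param config a `loy_pipeline_config`, or arguments for [loy_config()].
#' @return list of class `loy_report`: `indices`, per-stratum results under
#'   `strata`, `exclusions`, and `metadata`.
#' @export
run_analysis <- function(config) {
  if (!inherits(config, "loy_pipeline_config"))
    loy_usage_error("'config' must come from loy_config()/read_config()")
  set.seed(config$seed)
  genome <- genome_arms(include_21p = config$include_21p)
  segments <- read_seg(config$seg, config$value_scale)
  clinical <- read.delim(config$clinical, stringsAsFactors = FALSE)
  need <- c("sample_id", "sex", "hpv_status")
  if (length(setdiff(need, names(clinical))))
    loy_error(sprintf("clinical table lacks required column(s): %s",
                      paste(setdiff(need, names(clinical)), collapse = ", ")),
              "loy_config_error")
  counts <- NULL
  if (!is.null(config$counts)) {
    tab <- read.delim(config$counts, check.names = FALSE)
    counts <- as.matrix(tab[, -1, drop = FALSE])
    rownames(counts) <- tab[[1L]]
  }
  gene_sets <- if (!is.null(config$gmt)) read_gmt(config$gmt) else NULL

  idx <- sample_indices(segments, clinical, genome)
  idx <- merge(idx, clinical[, intersect(names(clinical),
                                         c("sample_id", "hpv_status")),
                             drop = FALSE],
               by.x = "sample", by.y = "sample_id", all.x = TRUE)
  cpm <- if (!is.null(counts)) cpm_normalize(counts, "tmm") else NULL
  exclusions <- data.frame(sample = character(), reason = character())
  strata <- list()
  for (stratum in c("negative", "positive")) {
    res <- .run_stratum(stratum, idx, clinical, cpm, gene_sets, config)
    strata[[stratum]] <- res$result
    exclusions <- rbind(exclusions, res$exclusions)
  }
  structure(list(
    indices = idx, strata = strata, exclusions = exclusions,
    metadata = list(
      package = "loyscan",
      version = as.character(packageVersion("loyscan")),
      seed = config$seed,
      config = unclass(config),
      n_samples = nrow(idx),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    )
  ), class = "loy_report")
}

.run_stratum <- function(stratum, idx, clinical, cpm, gene_sets, config) {
  cl <- clinical[!is.na(clinical$hpv_status) &
                   clinical$hpv_status == stratum, , drop = FALSE]
  sub <- idx[idx$sample %in% cl$sample_id, , drop = FALSE]
  males <- sub[!is.na(sub$sex) & sub$sex == "male" & !is.na(sub$y_index), ,
               drop = FALSE]
  excl <- data.frame(sample = character(), reason = character())
  out <- list(stratum = stratum, n = nrow(sub), n_males = nrow(males))
  fit <- tryCatch(
    fit_bimodal(males$y_index, config$bandwidth, config$min_separation),
    loy_unimodal_error = function(e) e,
    loy_usage_error = function(e) e)
  if (inherits(fit, "condition")) {
    out$skipped <- conditionMessage(fit)
    return(list(result = out, exclusions = excl))
  }
  calls <- classify_loy(setNames(males$y_index, males$sample), fit)
  out$fit <- fit
  out$calls <- cbind(calls, stratum = stratum)
  out$density <- cbind(fit$grid, stratum = stratum)
  m <- merge(calls, cl, by.x = "sample", by.y = "sample_id")
  m <- merge(m, males[, c("sample", "aneuploidy_index")], by = "sample")
  conf <- m[m$label != "UNCERTAIN", , drop = FALSE]
  excl <- rbind(excl, data.frame(
    sample = m$sample[m$label == "UNCERTAIN"],
    reason = sprintf("between-peak Y index (%s stratum)", stratum)))
  tests <- list()
  has <- function(col) col %in% names(m) && any(!is.na(m[[col]]))

  if (has("survival_time") && has("survival_event")) {
    ok <- !is.na(conf$survival_time) & !is.na(conf$survival_event)
    if (sum(ok) >= 4 && length(unique(conf$label[ok])) == 2) {
      tests$logrank_loy <- logrank_test(conf$survival_time[ok],
                                        conf$survival_event[ok],
                                        droplevels(conf$label[ok]))
      out$km <- km_estimate(conf$survival_time[ok], conf$survival_event[ok],
                            as.character(conf$label[ok]))
    }
    ok2 <- !is.na(m$survival_time) & !is.na(m$survival_event) &
      !is.na(m$y_index)
    if (sum(m$survival_event[ok2]) >= 2)
      tests$cox_y_index <- tryCatch(
        cox_fit(m$survival_time[ok2], m$survival_event[ok2],
                data.frame(y_index = m$y_index[ok2])),
        loy_fit_error = function(e) NULL)
  } else out$survival_note <- "survival columns absent: section skipped"

  if (has("smoking_category"))
    tests$kruskal_smoking <- tryCatch(
      kruskal_wallis(m$y_index, m$smoking_category),
      loy_usage_error = function(e) NULL)
  if (has("age"))
    tests$spearman_age <- spearman_test(m$age, m$y_index)
  if (has("pathologic_t"))
    tests$kruskal_pathologic_t <- tryCatch(
      kruskal_wallis(m$y_index, m$pathologic_t),
      loy_usage_error = function(e) NULL)
  if (nrow(conf) >= 4 && length(unique(conf$label)) == 2)
    tests$wilcoxon_aneuploidy <- wilcoxon_rank_sum(
      conf$aneuploidy_index[conf$label == "LOY"],
      conf$aneuploidy_index[conf$label == "RETAINED"])
  if (has("tp53_mutated")) {
    tab <- table(factor(conf$label %in% "LOY", levels = c(TRUE, FALSE)),
                 factor(conf$tp53_mutated > 0, levels = c(TRUE, FALSE)))
    if (all(dim(tab) == 2) && sum(tab) > 0)
      tests$fisher_tp53 <- fisher_exact(tab)
  }
  out$tests <- tests

  if (!is.null(cpm)) {
    p_thr <- if (stratum == "negative") config$p_threshold_hpv_negative
             else config$p_threshold_hpv_positive
    loy_s <- conf$sample[conf$label == "LOY"]
    ret_s <- conf$sample[conf$label == "RETAINED"]
    loy_s <- intersect(loy_s, colnames(cpm))
    ret_s <- intersect(ret_s, colnames(cpm))
    if (length(loy_s) >= 3 && length(ret_s) >= 3)
      out$de_loy <- de_test(cpm, loy_s, ret_s, p_thr, config$fc_threshold)
    ord <- m$sample[order(m$aneuploidy_index)]
    ord <- intersect(ord, colnames(cpm))
    third <- floor(length(ord) / 3)
    if (third >= 3) {
      bottom <- ord[seq_len(third)]
      top <- ord[seq.int(length(ord) - third + 1L, length(ord))]
      out$de_aneuploidy <- de_test(cpm, top, bottom, p_thr,
                                   config$fc_threshold)
    }
    if (!is.null(gene_sets) && !is.null(out$de_loy)) {
      de <- out$de_loy
      up <- de$gene[de$passes_filters & de$log2_fc > 0]
      down <- de$gene[de$passes_filters & de$log2_fc < 0]
      if (length(up))
        out$enrich_up <- enrich(up, de$gene, gene_sets)
      if (length(down))
        out$enrich_down <- enrich(down, de$gene, gene_sets)
    }
  }
  list(result = out, exclusions = excl)
}

#' Write a pipeline report to disk
#'
#' Emits per-stratum TSV tables (calls, density grid, test results, DE,
#' enrichment, KM curves) under `out_dir/<stratum>/`, the cohort index
#' table, a machine-readable `run_metadata.json` and a human-readable
#' `summary.txt`. Files are written atomically (temp file + rename), so
#' re-running overwrites cleanly.
#'
#' @param report a `loy_report` from [run_analysis()].
#' @param out_dir output directory (default: the config's `out_dir`).
#' @return character vector of written files, invisibly.
#' @export
write_report <- function(report, out_dir = NULL) {
  if (!inherits(report, "loy_report"))
    loy_usage_error("'report' must come from run_analysis()")
  out_dir <- out_dir %||% report$metadata$config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(out_dir, 2) != 0)
    loy_error(sprintf("output directory not writable: %s", out_dir),
              "loy_io_error")
  written <- character()
  wtsv <- function(df, path) {
    tmp <- paste0(path, ".tmp")
    write.table(df, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
    file.rename(tmp, path)
    written <<- c(written, path)
  }
  if (!is.null(report$indices))
    wtsv(report$indices, file.path(out_dir, "sample_indices.tsv"))
  if (nrow(report$exclusions))
    wtsv(report$exclusions, file.path(out_dir, "exclusions.tsv"))
  for (stratum in names(report$strata)) {
    s <- report$strata[[stratum]]
    if (is.null(s) || !is.null(s$skipped)) next
    sd <- file.path(out_dir, stratum)
    dir.create(sd, showWarnings = FALSE)
    wtsv(s$calls, file.path(sd, "loy_calls.tsv"))
    wtsv(s$density, file.path(sd, "density.tsv"))
    if (length(s$tests)) {
      tt <- do.call(rbind, lapply(names(s$tests), function(nm) {
        t <- s$tests[[nm]]
        if (is.null(t)) return(NULL)
        if (inherits(t, "loy_cox"))
          data.frame(test = nm, statistic = t$z[1L], df = NA,
                     p_value = t$p_value[1L], n = attr(t, "n"),
                     stratum = stratum)
        else
          data.frame(test = nm, statistic = t$statistic,
                     df = t$df %||% NA, p_value = t$p_value, n = t$n,
                     stratum = stratum)
      }))
      if (!is.null(tt)) wtsv(tt, file.path(sd, "tests.tsv"))
    }
    if (!is.null(s$km)) wtsv(s$km, file.path(sd, "km_curves.tsv"))
    for (nm in c("de_loy", "de_aneuploidy", "enrich_up", "enrich_down"))
      if (!is.null(s[[nm]]))
        wtsv(cbind(s[[nm]], stratum = stratum),
             file.path(sd, paste0(nm, ".tsv")))
  }
  meta_path <- file.path(out_dir, "run_metadata.json")
  jsonlite::write_json(report$metadata, meta_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  written <- c(written, meta_path)
  sm <- file.path(out_dir, "summary.txt")
  lines <- c(sprintf("loyscan %s run, seed %d, %d samples",
                     report$metadata$version, report$metadata$seed,
                     report$metadata$n_samples))
  for (stratum in names(report$strata)) {
    s <- report$strata[[stratum]]
    if (!is.null(s$skipped)) {
      lines <- c(lines, sprintf("HPV-%s: skipped (%s)", stratum, s$skipped))
      next
    }
    tab <- table(s$calls$label)
    lines <- c(lines, sprintf(
      "HPV-%s: n=%d males=%d peaks=(%.3f, %.3f) LOY=%d UNCERTAIN=%d RETAINED=%d",
      stratum, s$n, s$n_males, s$fit$peak_low, s$fit$peak_high,
      tab[["LOY"]], tab[["UNCERTAIN"]], tab[["RETAINED"]]))
  }
  writeLines(lines, sm)
  written <- c(written, sm)
  invisible(written)
}
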