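#' Configuration for the synthetic cohort generator
#'
#' Collects every generative parameter of [simulate_cohort()] /
#' [simulate_microarray()] with validation. Defaults describe a head-and-neck
#' style cohort: ~27% female samples, LoY prevalence 0.25 among males, tumor
#' purity Beta(8, 2) (mean 0.8), LoY carried by half of the tumor cells
#' (`subclonal_loy_fraction = 0.5`, which puts the purity-adjusted LoY mode
#' at 0.5 and the retained mode at 1.0), more autosomal arm events in LoY
#' tumors, an LoY survival hazard ratio of 2, and an RNA-seq matrix with
#' Y-linked dosage genes, immune genes downregulated with aneuploidy and
#' redox genes upregulated with LoY.
#'
#' @param n_samples cohort size.
#' @param female_fraction proportion of female samples.
#' @param loy_prevalence proportion of males with true LoY.
#' @param subclonal_loy_fraction mean fraction of tumor cells carrying the
#'   loss in LoY samples; each LoY sample draws its own fraction from
#'   Beta(8f, 8(1 - f)) (degenerate at 0 or 1), so Y dosage varies
#'   continuously across LoY tumors.
#' @param purity_alpha,purity_beta Beta(a, b) law for tumor purity
#'   (`tumor_nuclei_percent` / 100).
#' @param arm_event_rate_loy,arm_event_rate_nonloy expected autosomal
#'   arm gains/losses per sample by LoY status.
#' @param segment_noise_sd SD of additive Gaussian noise on linear segment
#'   means.
#' @param hpv_positive_fraction proportion of HPV-positive samples.
#' @param baseline_hazard death hazard per day for non-LoY samples.
#' @param loy_hazard_ratio multiplicative hazard for LoY samples.
#' @param censoring_rate independent exponential censoring hazard per day.
#' @param n_genes,n_y_genes,n_immune_genes,n_redox_genes gene counts for the
#'   count matrix.
#' @param nb_dispersion negative-binomial dispersion of counts.
#' @param redox_log2fc log2 fold change of redox genes in LoY samples.
#' @param immune_log2fc log2 fold change of immune genes per unit of scaled
#'   aneuploidy (negative = downregulated in aneuploid tumors).
#' @param value_scale scale on which segment means are emitted.
#' @param array_noise_frac array-intensity noise SD as a fraction of the
#'   probe signal.
#' @param seed root seed; all substreams derive from it.
#' @return validated list of class `loy_sim_config`.
#' @export
simulation_config <- function(n_samples = 500L,
                              female_fraction = 0.27,
                              loy_prevalence = 0.25,
                              subclonal_loy_fraction = 0.5,
                              purity_alpha = 8,
                              purity_beta = 2,
                              arm_event_rate_loy = 10,
                              arm_event_rate_nonloy = 5,
                              segment_noise_sd = 0.05,
                              hpv_positive_fraction = 0.23,
                              baseline_hazard = 5e-4,
                              loy_hazard_ratio = 2,
                              censoring_rate = 5e-4,
                              n_genes = 2000L,
                              n_y_genes = 19L,
                              n_immune_genes = 100L,
                              n_redox_genes = 40L,
                              nb_dispersion = 0.05,
                              redox_log2fc = 1,
                              immune_log2fc = -1,
                              value_scale = c("log2ratio", "linear"),
                              array_noise_frac = 0.1,
                              seed = 1L) {
  cfg <- list(
    n_samples = .assert_count(n_samples, "n_samples", 1L),
    female_fraction = .assert_prop(female_fraction, "female_fraction"),
    loy_prevalence = .assert_prop(loy_prevalence, "loy_prevalence"),
    subclonal_loy_fraction = .assert_prop(subclonal_loy_fraction,
                                          "subclonal_loy_fraction"),
    purity_alpha = .assert_pos(purity_alpha, "purity_alpha"),
    # purity_beta = 0 is the degenerate Beta(a, 0) limit: purity exactly 1
    purity_beta = .assert_pos(purity_beta, "purity_beta", strict = FALSE),
    arm_event_rate_loy = .assert_pos(arm_event_rate_loy,
                                     "arm_event_rate_loy", strict = FALSE),
    arm_event_rate_nonloy = .assert_pos(arm_event_rate_nonloy,
                                        "arm_event_rate_nonloy",
                                        strict = FALSE),
    segment_noise_sd = .assert_pos(segment_noise_sd, "segment_noise_sd",
                                   strict = FALSE),
    hpv_positive_fraction = .assert_prop(hpv_positive_fraction,
                                         "hpv_positive_fraction"),
    baseline_hazard = .assert_pos(baseline_hazard, "baseline_hazard"),
    loy_hazard_ratio = .assert_pos(loy_hazard_ratio, "loy_hazard_ratio"),
    censoring_rate = .assert_pos(censoring_rate, "censoring_rate",
                                 strict = FALSE),
    n_genes = .assert_count(n_genes, "n_genes", 1L),
    n_y_genes = .assert_count(n_y_genes, "n_y_genes"),
    n_immune_genes = .assert_count(n_immune_genes, "n_immune_genes"),
    n_redox_genes = .assert_count(n_redox_genes, "n_redox_genes"),
    nb_dispersion = .assert_pos(nb_dispersion, "nb_dispersion"),
    redox_log2fc = redox_log2fc,
    immune_log2fc = immune_log2fc,
    value_scale = match.arg(value_scale),
    array_noise_frac = .assert_pos(array_noise_frac, "array_noise_frac",
                                   strict = FALSE),
    seed = .assert_count(seed, "seed")
  )
  if (cfg$n_y_genes + cfg$n_immune_genes + cfg$n_redox_genes > cfg$n_genes)
    loy_param_error(
      "n_y_genes + n_immune_genes + n_redox_genes must be <= n_genes",
      field = "n_genes")
  structure(cfg, class = "loy_sim_config")
}

# Named substreams off the root seed so the segment, clinical and count
# blocks can be regenerated independently and deterministically.
.substream <- function(seed, name) {
  offs <- c(segments = 101L, clinical = 211L, counts = 307L, array = 401L)
  set.seed((as.integer(seed) %% 1000000L) * 1009L + offs[[name]])
}

# Per-sample subclonal LoY cell fractions: one fraction per LoY sample,
# Beta-distributed around the configured mean (degenerate at 0 or 1), so the
# Y dosage varies continuously across LoY tumors.
.draw_loy_fraction <- function(n, f) {
  if (f == 0 || f == 1) rep(f, n) else rbeta(n, 8 * f, 8 * (1 - f))
}

# Linear observed value for a segment: purity mixture plus noise, then
# converted to the configured emission scale. log2 emission clamps at a
# small positive CN so noise cannot produce log(<=0).
.emit_value <- function(linear_obs, value_scale) {
  if (value_scale == "linear") return(linear_obs)
  log2(pmax(linear_obs, 0.01) / 2)
}

#' Simulate a matched synthetic cohort
#'
#' Generates segmented copy-number data, a clinical table, an RNA-seq count
#' matrix and the latent truth for `config$n_samples` tumor samples.
#'
#' Per male sample, the tumor Y copy number is `1 - f_i` on LoY samples
#' (`f_i` the sample's subclonal fraction; 1 otherwise) and the observed
#' linear
#' segment value is the purity mixture `p * CN_tumor + (1 - p) * CN_normal`
#' plus Gaussian noise (`CN_normal` = 1 for the male Y and male X, 2
#' otherwise). Autosomal arm gains/losses are drawn Poisson with the
#' LoY-dependent rate. Female samples carry no Y segments. Survival times
#' are exponential with hazard `baseline_hazard * loy_hazard_ratio^LoY`,
#' censored by an independent exponential. Y-gene counts have mean
#' proportional to the purity-mixed Y copy number; immune genes scale with
#' aneuploidy, redox genes with LoY.
#'
#' @param config a `loy_sim_config` from [simulation_config()].
#' @param genome a `loy_genome`.
#' @return list of class `loy_cohort`: `segments`, `clinical`, `counts`,
#'   `truth`, `gene_info`, `config`.
#' @examples
#' b <- simulate_cohort(simulation_config(n_samples = 40, n_genes = 200,
#'                                        n_immune_genes = 20,
#'                                        n_redox_genes = 10))
#' table(b$truth$true_loy, b$truth$sex)
#' @export
simulate_cohort <- function(config = simulation_config(),
                            genome = genome_arms()) {
  if (!inherits(config, "loy_sim_config"))
    loy_param_error("'config' must come from simulation_config()")
  n <- config$n_samples
  ids <- sprintf("S%04d", seq_len(n))
  arms <- genome$arms
  auto_arms <- arms[!arms$chrom %in% c("X", "Y"), , drop = FALSE]

  .substream(config$seed, "clinical")
  sex <- ifelse(runif(n) < config$female_fraction, "female", "male")
  purity <- if (config$purity_beta == 0) rep(1, n) else
    rbeta(n, config$purity_alpha, config$purity_beta)
  loy <- sex == "male" & runif(n) < config$loy_prevalence
  loy_fraction <- ifelse(loy,
                         .draw_loy_fraction(n, config$subclonal_loy_fraction),
                         0)
  hpv <- ifelse(runif(n) < config$hpv_positive_fraction, "positive",
                "negative")
  age <- round(rnorm(n, 61, 11))
  smoking_levels <- c("never_smoked", "stopped_gt15y", "stopped_lt15y",
                      "current_smoker")
  # LoY shifts smoking mass toward current smokers (configured association)
  smoking <- vapply(loy, function(l)
    sample(smoking_levels, 1L,
           prob = if (l) c(0.10, 0.15, 0.30, 0.45)
                  else c(0.25, 0.25, 0.25, 0.25)),
    character(1))
  tp53 <- runif(n) < ifelse(hpv == "negative", 0.845, 0.259)
  path_t <- vapply(loy, function(l)
    sample(paste0("T", 1:4), 1L,
           prob = if (l) c(0.1, 0.2, 0.3, 0.4) else c(0.25, 0.3, 0.25, 0.2)),
    character(1))
  path_n <- sample(paste0("N", 0:3), n, replace = TRUE,
                   prob = c(0.4, 0.2, 0.3, 0.1))
  site <- sample(c("oral_cavity", "larynx", "oropharynx", "hypopharynx"),
                 n, replace = TRUE, prob = c(0.54, 0.26, 0.18, 0.02))
  hazard <- config$baseline_hazard *
    ifelse(loy, config$loy_hazard_ratio, 1)
  t_event <- rexp(n, hazard)
  t_cens <- if (config$censoring_rate > 0) rexp(n, config$censoring_rate)
            else rep(Inf, n)
  time <- pmin(t_event, t_cens)
  event <- as.integer(t_event <= t_cens)

  .substream(config$seed, "segments")
  f <- config$subclonal_loy_fraction
  seg_list <- vector("list", n)
  n_arm_events <- integer(n)
  true_aneuploidy <- numeric(n)
  xarms <- arms[arms$chrom == "X", , drop = FALSE]
  yarms <- arms[arms$chrom == "Y", , drop = FALSE]
  for (i in seq_len(n)) {
    p <- purity[i]
    rate <- if (loy[i]) config$arm_event_rate_loy else
      config$arm_event_rate_nonloy
    k <- min(rpois(1L, rate), nrow(auto_arms))
    hit <- sample.int(nrow(auto_arms), k)
    cn_t <- rep(2, nrow(auto_arms))
    cn_t[hit] <- 2 + sample(c(-1, 1), k, replace = TRUE)
    obs <- p * cn_t + (1 - p) * 2
    if (config$segment_noise_sd > 0)
      obs <- obs + rnorm(length(obs), 0, config$segment_noise_sd)
    seg <- data.frame(
      sample = ids[i], chrom = auto_arms$chrom, start = auto_arms$start,
      end = auto_arms$end,
      n_markers = pmax(10, round((auto_arms$end - auto_arms$start) / 5e4)),
      value = .emit_value(obs, config$value_scale)
    )
    # sex chromosomes: females diploid X and no Y rows; males one X, one Y
    # (tumor Y = 1 - f on the LoY subclone)
    if (sex[i] == "female") {
      xobs <- p * 2 + (1 - p) * 2
      if (config$segment_noise_sd > 0)
        xobs <- xobs + rnorm(nrow(xarms), 0, config$segment_noise_sd)
      seg <- rbind(seg, data.frame(
        sample = ids[i], chrom = xarms$chrom, start = xarms$start,
        end = xarms$end, n_markers = 1000,
        value = .emit_value(xobs, config$value_scale)))
    } else {
      cn_y <- if (loy[i]) 1 - loy_fraction[i] else 1
      xobs <- p * 1 + (1 - p) * 1
      yobs <- p * cn_y + (1 - p) * 1
      sx <- rbind(
        data.frame(chrom = xarms$chrom, start = xarms$start,
                   end = xarms$end, o = xobs),
        data.frame(chrom = yarms$chrom, start = yarms$start,
                   end = yarms$end, o = yobs))
      if (config$segment_noise_sd > 0)
        sx$o <- sx$o + rnorm(nrow(sx), 0, config$segment_noise_sd)
      seg <- rbind(seg, data.frame(
        sample = ids[i], chrom = sx$chrom, start = sx$start, end = sx$end,
        n_markers = 1000, value = .emit_value(sx$o, config$value_scale)))
    }
    seg_list[[i]] <- seg
    n_arm_events[i] <- k
    incl <- !auto_arms$arm_id %in% genome$excluded_arms
    true_aneuploidy[i] <- sum(abs(2 - cn_t[incl]))
  }
  segments <- structure(do.call(rbind, seg_list),
                        value_scale = config$value_scale,
                        class = c("loy_segments", "data.frame"))

  .substream(config$seed, "counts")
  gi <- .gene_table(config)
  base <- rlnorm(config$n_genes, log(50), 1.2)
  # Y-linked dosage genes are well expressed (their real counterparts are
  # among the higher-expressed genes in male tissue), so the dosage signal
  # is not drowned by shot noise
  base[gi$class == "y_linked"] <- rlnorm(config$n_y_genes, log(200), 0.5)
  libfac <- rlnorm(n, 0, 0.15)
  # percentile rank in [0, 1]: immune_log2fc is then the approximate
  # realized contrast between the top and bottom aneuploidy terciles
  aneu_scaled <- if (n > 1) (rank(true_aneuploidy) - 1) / (n - 1) else 0.5
  mu <- matrix(base, config$n_genes, n)
  y_dosage <- ifelse(sex == "male",
                     purity * (1 - loy_fraction) + (1 - purity) * 1, 0)
  mu[gi$class == "y_linked", ] <- outer(base[gi$class == "y_linked"],
                                        y_dosage)
  mu[gi$class == "immune", ] <-
    outer(base[gi$class == "immune"], 2^(config$immune_log2fc * aneu_scaled))
  mu[gi$class == "redox", ] <-
    outer(base[gi$class == "redox"], 2^(config$redox_log2fc * loy))
  mu <- sweep(mu, 2, libfac, `*`)
  counts <- matrix(rnbinom(length(mu), mu = mu,
                           size = 1 / config$nb_dispersion),
                   nrow = config$n_genes,
                   dimnames = list(gi$gene, ids))

  clinical <- data.frame(
    sample_id = ids, sex = sex, hpv_status = hpv, age = age,
    smoking_category = smoking, tp53_mutated = as.integer(tp53),
    tumor_nuclei_percent = round(purity * 100, 1),
    survival_time = round(time, 1), survival_event = event,
    pathologic_t = path_t, pathologic_n = path_n, site = site
  )
  truth <- data.frame(
    sample_id = ids, sex = sex, true_loy = loy,
    true_loy_fraction = loy_fraction, true_purity = purity,
    n_arm_events = n_arm_events, true_aneuploidy = true_aneuploidy,
    hpv_status = hpv
  )
  structure(list(segments = segments, clinical = clinical, counts = counts,
                 truth = truth, gene_info = gi, config = config),
            class = "loy_cohort")
}

.gene_table <- function(config) {
  cls <- rep("null", config$n_genes)
  i <- 0L
  cls[seq_len(config$n_y_genes)] <- "y_linked"
  i <- config$n_y_genes
  cls[i + seq_len(config$n_immune_genes)] <- "immune"
  i <- i + config$n_immune_genes
  cls[i + seq_len(config$n_redox_genes)] <- "redox"
  data.frame(gene = sprintf("G%05d", seq_len(config$n_genes)), class = cls)
}

#' Simulate a sex-discriminating probe microarray experiment
#'
#' Emulates an oral-cancer style array cohort with normal, dysplasia and
#' tumor groups and a small set of Y-linked discriminating probes. Female
#' intensities are a probe-specific background plus noise; male intensities
#' add a signal proportional to Y dosage, which is `1 - f * purity` in LoY
#' tumors (`f = subclonal_loy_fraction`) and 1 otherwise.
#'
#' @param config a `loy_sim_config`; `loy_prevalence` applies to male
#'   tumors, `array_noise_frac` scales the intensity noise.
#' @param n_probes number of discriminating probes.
#' @return list of class `loy_array`: `intensity` (probe x sample),
#'   `samples` (sample_id, sex, group, true_loy, true_purity), `background`
#'   and `signal` per probe, `config`.
#' @export
simulate_microarray <- function(config = simulation_config(),
                                n_probes = 7L) {
  if (!inherits(config, "loy_sim_config"))
    loy_param_error("'config' must come from simulation_config()")
  n <- config$n_samples
  .substream(config$seed, "array")
  group <- sample(c("tumor", "dysplasia", "normal"), n, replace = TRUE,
                  prob = c(0.6, 0.1, 0.3))
  sex <- ifelse(runif(n) < config$female_fraction, "female", "male")
  if (sum(sex == "female") < 2L)
    loy_param_error("need at least 2 female samples", field = "n_samples")
  if (sum(sex == "male" & group == "normal") < 2L)
    loy_param_error("need at least 2 male normal samples",
                    field = "n_samples")
  purity <- if (config$purity_beta == 0) rep(1, n) else
    rbeta(n, config$purity_alpha, config$purity_beta)
  purity[group != "tumor"] <- 1
  loy <- sex == "male" & group == "tumor" &
    runif(n) < config$loy_prevalence
  loy_fraction <- ifelse(loy,
                         .draw_loy_fraction(n, config$subclonal_loy_fraction),
                         0)
  dosage <- ifelse(sex == "female", 0, 1 - loy_fraction * purity)
  background <- rlnorm(n_probes, log(100), 0.2)
  signal <- rlnorm(n_probes, log(1000), 0.3)
  mu <- background + outer(signal, dosage)
  noise <- if (config$array_noise_frac > 0)
    matrix(rnorm(n_probes * n, 0, config$array_noise_frac * signal),
           n_probes, n)
  else 0
  ids <- sprintf("A%04d", seq_len(n))
  intensity <- mu + noise
  dimnames(intensity) <- list(sprintf("Y_probe_%d", seq_len(n_probes)), ids)
  structure(list(
    intensity = intensity,
    samples = data.frame(sample_id = ids, sex = sex, group = group,
                         true_loy = loy, true_loy_fraction = loy_fraction,
                         true_purity = purity),
    background = background, signal = signal, config = config
  ), class = "loy_array")
}

#' Write a simulated cohort to disk
#'
#' Emits the SEG file (1-based inclusive), clinical TSV, counts TSV and
#' truth TSV of a [simulate_cohort()] bundle.
#'
#' @param bundle a `loy_cohort`.
#' @param dir output directory (created if needed).
#' @return named vector of the written paths, invisibly.
#' @export
write_cohort <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    segments = file.path(dir, "segments.seg"),
    clinical = file.path(dir, "clinical.tsv"),
    counts = file.path(dir, "counts.tsv"),
    truth = file.path(dir, "truth.tsv")
  )
  write_seg(bundle$segments, paths["segments"])
  write.table(bundle$clinical, paths["clinical"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(data.frame(gene = rownames(bundle$counts), bundle$counts,
                         check.names = FALSE),
              paths["counts"], sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(bundle$truth, paths["truth"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(paths)
}
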