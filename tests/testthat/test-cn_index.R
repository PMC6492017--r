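test_that("read_seg converts coordinates, normalizes chromosomes, and reports parse errors", {
  f <- withr::local_tempfile(fileext = ".seg")
  writeLines(c("Sample\tChromosome\tStart\tEnd\tNum_Probes\tSegment_Mean",
               "S1\tchrY\t1\t100\t10\t0.0",
               "S1\t17\t5\t50\t4\t-0.31"), f)
  seg <- read_seg(f, "log2ratio")
  expect_s3_class(seg, "loy_segments")
  expect_equal(seg$start, c(0, 4))
  expect_equal(seg$end, c(100, 50))
  expect_equal(seg$chrom, c("Y", "17"))
  expect_identical(attr(seg, "value_scale"), "log2ratio")

  writeLines(c("S\tC\tSt\tEn\tN\tV", "S1\tMT\t1\t10\t2\t0"), f)
  expect_error(read_seg(f), class = "loy_parse_error")
  writeLines(c("S\tC\tSt\tEn\tN\tV", "S1\t1\t100\t10\t2\t0"), f)
  expect_error(read_seg(f), class = "loy_parse_error")
  writeLines(c("S\tC\tSt\tEn\tN\tV", "S1\t1\t1\t10\t2\tabc"), f)
  expect_error(read_seg(f), class = "loy_parse_error")
  writeLines("S\tC\tSt\tEn\tN\tV", f)
  expect_warning(empty <- read_seg(f), "empty")
  expect_identical(nrow(empty), 0L)
})

test_that("write_seg round-trips through read_seg", {
  b <- simulate_cohort(simulation_config(n_samples = 6, n_genes = 30,
                                         n_immune_genes = 3,
                                         n_redox_genes = 3, seed = 5))
  f <- withr::local_tempfile(fileext = ".seg")
  write_seg(b$segments, f)
  back <- read_seg(f, "log2ratio")
  expect_equal(back$start, b$segments$start)
  expect_equal(back$end, b$segments$end)
  expect_equal(back$value, b$segments$value, tolerance = 1e-12)
})

test_that("to_linear_cn maps log2 ratios to linear copy number", {
  expect_equal(to_linear_cn(0, "log2ratio"), 2)
  expect_equal(to_linear_cn(-1, "log2ratio"), 1)
  # frozen from 2 * 2^0.585 = 2^1.585
  expect_equal(to_linear_cn(0.585, "log2ratio"), 3.00007797857164,
               tolerance = 1e-9)
  expect_identical(to_linear_cn(c(0, 3.7), "linear"), c(0, 3.7))
})

test_that("arm_index matches its spec examples", {
  expect_equal(arm_index(0, 100, 2, 0, 100),
               list(index = 2, covered_fraction = 1))
  expect_equal(arm_index(c(0, 50), c(50, 100), c(1, 3), 0, 100)$index, 2)
  # 30% of arm at CN 1, 70% at CN 2 -> 1.7
  got <- arm_index(c(0, 30), c(30, 100), c(1, 2), 0, 100)
  expect_equal(got$index, 1.7)
  expect_equal(got$covered_fraction, 1)
  expect_equal(arm_index(numeric(), numeric(), numeric(), 0, 100),
               list(index = NA_real_, covered_fraction = 0))
})

test_that("arm_index equals the per-base brute-force oracle on random genomes", {
  set.seed(401)
  for (rep in 1:60) {
    case <- random_genome_case()
    for (j in seq_len(nrow(case$arms))) {
      a <- case$arms[j, ]
      # random exclusion inside the arm in a third of the cases
      ex_s <- ex_e <- numeric()
      if (runif(1) < 1 / 3) {
        ex_s <- a$arm_start + sample.int(20, 1)
        ex_e <- min(a$arm_end, ex_s + sample.int(30, 1))
      }
      got <- arm_index(case$segments$start, case$segments$end,
                       case$segments$cn, a$arm_start, a$arm_end, ex_s, ex_e)
      want <- oracle_arm_index(case$segments$start, case$segments$end,
                               case$segments$cn, a$arm_start, a$arm_end,
                               ex_s, ex_e)
      expect_equal(got$index, want$index, tolerance = 1e-9)
      expect_equal(got$covered_fraction, want$covered_fraction,
                   tolerance = 1e-9)
    }
  }
})

test_that("purity_adjust inverts the two-component mixture and floors at zero", {
  expect_equal(purity_adjust(1.0, 1.0, 1), 1.0)
  expect_equal(purity_adjust(0.75, 0.5, 1), 0.5)
  expect_equal(purity_adjust(0.3, 0.5, 1), 0.0)
  # exact inversion over a grid
  for (p in seq(0.1, 1, by = 0.1))
    for (c_n in c(1, 2))
      for (t_cn in 0:4)
        expect_equal(purity_adjust(p * t_cn + (1 - p) * c_n, p, c_n), t_cn)
  # missing purity passes through; invalid purity errors
  expect_equal(purity_adjust(1.3, NA, 2), 1.3)
  expect_error(purity_adjust(1, 0, 1), class = "loy_param_error")
  expect_error(purity_adjust(1, 1.2, 1), class = "loy_param_error")
  # vectorized over observations with scalar purity
  expect_equal(purity_adjust(c(2, 2.5, 1.5), 0.5, 2), c(2, 3, 1))
})

test_that("y_index averages the male-specific region and respects PARs", {
  g <- genome_arms()
  ya <- g$arms[g$arms$chrom == "Y", ]
  par_y <- g$par[g$par$chrom == "Y", ]
  seg1 <- structure(
    data.frame(sample = "M1", chrom = "Y", start = 0, end = max(ya$end),
               n_markers = 10, value = 1),
    value_scale = "linear", class = c("loy_segments", "data.frame"))
  yi <- y_index(seg1, purity = c(M1 = 1))
  expect_equal(yi$y_index, 1)
  expect_equal(yi$covered_fraction, 1)

  # Yp at CN 1, Yq at CN 0 -> masked Yp length / masked MSY length
  seg2 <- structure(
    data.frame(sample = "M1", chrom = "Y",
               start = ya$start, end = ya$end,
               n_markers = 10, value = c(1, 0)),
    value_scale = "linear", class = c("loy_segments", "data.frame"))
  mask_len <- function(a, b) {
    (b - a) - sum(pmax(0, pmin(b, par_y$end) - pmax(a, par_y$start)))
  }
  lp <- mask_len(ya$start[1], ya$end[1])
  lq <- mask_len(ya$start[2], ya$end[2])
  expect_equal(y_index(seg2, purity = c(M1 = 1))$y_index, lp / (lp + lq))

  # female samples are rejected; absent Y coverage yields NA + warning
  expect_error(y_index(seg1, sex = c(M1 = "female")),
               class = "loy_usage_error")
  seg3 <- structure(
    data.frame(sample = "M2", chrom = "1", start = 0, end = 1e6,
               n_markers = 10, value = 2),
    value_scale = "linear", class = c("loy_segments", "data.frame"))
  expect_warning(yi3 <- y_index(seg3), "without Y coverage")
  expect_true(is.na(yi3$y_index))
})

test_that("aneuploidy_index sums |2 - index| over included autosomal arms", {
  arms <- c("1p", "1q", "2p", "2q", "13p", "Xq")
  v <- setNames(c(2, 2, 2, 2, 3, 5), arms)
  expect_equal(aneuploidy_index(v)$aneuploidy_index, 0)  # 13p excluded, Xq sex
  v["1q"] <- 3
  expect_equal(aneuploidy_index(v)$aneuploidy_index, 1)
  v["2p"] <- 1.5; v["2q"] <- 2.5
  expect_equal(aneuploidy_index(v)$aneuploidy_index, 2)
  v["1p"] <- NA
  a <- aneuploidy_index(v)
  expect_equal(a$n_arms_missing, 1L)
  expect_equal(a$n_arms_used, 3L)
})

test_that("aneuploidy_index never decreases when an arm drops below 2", {
  set.seed(77)
  arms <- paste0(rep(1:5, each = 2), c("p", "q"))
  for (i in 1:25) {
    v <- setNames(runif(10, 1, 3), arms)
    j <- sample(10, 1)
    v[j] <- min(v[j], 2)  # invariant applies below the diploid baseline
    base <- aneuploidy_index(v)$aneuploidy_index
    v[j] <- v[j] - runif(1, 0, 1)
    expect_gte(aneuploidy_index(v)$aneuploidy_index, base - 1e-12)
  }
})

test_that("indices are invariant to the input value scale", {
  b <- simulate_cohort(simulation_config(n_samples = 20, n_genes = 30,
                                         n_immune_genes = 3,
                                         n_redox_genes = 3, seed = 9))
  seg_log <- b$segments
  seg_lin <- seg_log
  seg_lin$value <- to_linear_cn(seg_log$value, "log2ratio")
  attr(seg_lin, "value_scale") <- "linear"
  i1 <- sample_indices(seg_log, b$clinical)
  i2 <- sample_indices(seg_lin, b$clinical)
  expect_equal(i1$y_index, i2$y_index, tolerance = 1e-10)
  expect_equal(i1$aneuploidy_index, i2$aneuploidy_index, tolerance = 1e-10)
})

test_that("sample_indices integrates purity, sex, and coverage bookkeeping", {
  b <- tiny_cohort()
  idx <- sample_indices(b$segments, b$clinical)
  expect_setequal(idx$sample, b$truth$sample_id)
  expect_true(all(is.na(idx$y_index[idx$sex == "female"])))
  expect_true(all(idx$aneuploidy_index >= 0))
  expect_true(all(idx$purity_adjusted))
  # with zero noise the mixture inversion is exact: check one LoY male
  b0 <- simulate_cohort(simulation_config(n_samples = 40, n_genes = 30,
                                          n_immune_genes = 3,
                                          n_redox_genes = 3,
                                          segment_noise_sd = 0, seed = 3))
  idx0 <- sample_indices(b0$segments, b0$truth |>
    transform(sample_id = sample_id,
              tumor_nuclei_percent = true_purity * 100))
  tr <- b0$truth[match(idx0$sample, b0$truth$sample_id), ]
  male <- tr$sex == "male"
  # zero-noise mixture inversion: y_index recovers 1 - f_i exactly
  expect_equal(idx0$y_index[male], 1 - tr$true_loy_fraction[male],
               tolerance = 1e-9)
})
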