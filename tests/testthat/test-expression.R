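test_that("library-size CPM sums to 1e6 and is scale invariant", {
  set.seed(201)
  counts <- matrix(rnbinom(200 * 8, mu = 50, size = 10), 200, 8,
                   dimnames = list(sprintf("g%03d", 1:200), paste0("s", 1:8)))
  cpm <- cpm_normalize(counts)
  expect_equal(unname(colSums(cpm)), rep(1e6, 8))
  doubled <- counts
  doubled[, 3] <- counts[, 3] * 2
  expect_equal(cpm_normalize(doubled)[, 3], cpm[, 3])
  counts0 <- counts; counts0[, "s5"] <- 0
  expect_error(cpm_normalize(counts0), "s5", class = "loy_usage_error")
})

test_that("TMM factors are near 1 for null genes and match edgeR", {
  set.seed(202)
  n <- 100
  base <- rlnorm(n, log(100), 1)
  counts <- cbind(s1 = rpois(n, base), s2 = rpois(n, base))
  counts[1, 2] <- counts[1, 1] * 4 + 40  # one true 4-fold gene
  rownames(counts) <- sprintf("g%03d", 1:n)
  f <- tmm_factors(counts)
  expect_true(all(abs(f - 1) < 0.05))

  skip_if_not_installed("edgeR")
  set.seed(203)
  counts2 <- matrix(rnbinom(500 * 6, mu = rlnorm(500, log(80), 1.2),
                            size = 5), 500, 6,
                    dimnames = list(NULL, paste0("s", 1:6)))
  counts2[1:30, 1:3] <- counts2[1:30, 1:3] * 6  # asymmetric DE block
  ours <- tmm_factors(counts2)
  theirs <- edgeR::calcNormFactors(counts2, method = "TMM")
  expect_equal(unname(ours), unname(theirs), tolerance = 0.02)
})

test_that("y_gene_screen ranks dosage genes by Spearman rho", {
  set.seed(204)
  n <- 200
  y <- runif(n, 0, 1.2)
  expr <- rbind(
    mono = exp(2 * y),                   # strictly increasing transform
    noise = rnorm(n),
    anti = -y + rnorm(n, 0, 0.01)
  )
  colnames(expr) <- paste0("s", 1:n)
  res <- y_gene_screen(expr, setNames(y, colnames(expr)))
  expect_identical(res$gene[1], "mono")
  expect_equal(res$rho[1], 1)
  expect_false("noise" %in% res$gene)
  expect_false("anti" %in% res$gene)
  # rank invariance under monotone transforms of either variable
  res2 <- y_gene_screen(log(expr - min(expr) + 1),
                        setNames(y^3, colnames(expr)))
  all1 <- attr(res, "all_genes"); all2 <- attr(res2, "all_genes")
  expect_equal(all1$rho[order(all1$gene)], all2$rho[order(all2$gene)],
               tolerance = 1e-12)
  expect_error(y_gene_screen(expr[, 1:5], setNames(y[1:5], paste0("s", 1:5))),
               class = "loy_usage_error")
})

test_that("y_gene_screen recovers injected dosage genes from the cohort", {
  b <- simulate_cohort(simulation_config(n_samples = 300, n_genes = 600,
                                         n_y_genes = 12,
                                         n_immune_genes = 40,
                                         n_redox_genes = 20, seed = 14))
  idx <- sample_indices(b$segments, b$clinical)
  males <- idx[idx$sex == "male" & !is.na(idx$y_index), ]
  cpm <- cpm_normalize(b$counts[, males$sample])
  res <- y_gene_screen(cpm, setNames(males$y_index, males$sample))
  y_genes <- b$gene_info$gene[b$gene_info$class == "y_linked"]
  all_rho <- attr(res, "all_genes")
  # every dosage gene ranks above every non-dosage gene (perfect recovery
  # of the injected set by the rank statistic) ...
  expect_setequal(all_rho$gene[seq_along(y_genes)], y_genes)
  # ... with no false positive at the operational rho > 0.5 cut, and the
  # dosage genes clearing it in bulk. (A binary 25%-prevalence cohort caps
  # Spearman near 3 * pi * (1 - pi) + the within-LoY continuum term, so a
  # tail of the injected set can sit just under 0.5 by sampling noise.)
  expect_true(all(res$gene %in% y_genes))
  expect_gte(sum(y_genes %in% res$gene), length(y_genes) * 0.75)
  expect_lt(max(all_rho$rho[!all_rho$gene %in% y_genes]), 0.5)
})

test_that("de_test applies the three-part filter", {
  set.seed(205)
  cpm <- matrix(rlnorm(50 * 20, log(20), 0.3), 50, 20,
                dimnames = list(sprintf("g%02d", 1:50), paste0("s", 1:20)))
  a <- paste0("s", 1:10); b <- paste0("s", 11:20)
  # identical group means: fold-change filter fails even at tiny p
  cpm["g01", ] <- rep(c(5, 10), 10)[order(rep(1:2, 10))]
  cpm["g01", a] <- 8; cpm["g01", b] <- 8
  # strong fold change but expressed in only 2 samples
  cpm["g02", ] <- 0.01
  cpm["g02", c("s1", "s2")] <- 50
  de <- de_test(cpm, a, b, p_threshold = 0.05)
  expect_false(de$passes_filters[de$gene == "g01"])
  expect_false(de$passes_filters[de$gene == "g02"])
  expect_true(all(diff(de$p_value) >= 0))
  expect_error(de_test(cpm, a, c(a[1], b)), class = "loy_usage_error")
  expect_error(de_test(cpm, a[1:2], b), class = "loy_usage_error")
})

test_that("de_test detects injected fold changes with calibrated nulls", {
  set.seed(206)
  n_genes <- 2000; n_eff <- 100
  mu <- rlnorm(n_genes, log(100), 0.8)
  grp <- rep(c("A", "B"), each = 40)
  mm <- matrix(mu, n_genes, 80)
  mm[seq_len(n_eff), grp == "A"] <- mm[seq_len(n_eff), grp == "A"] * 2
  counts <- matrix(rnbinom(length(mm), mu = mm, size = 10), n_genes, 80,
                   dimnames = list(sprintf("g%04d", seq_len(n_genes)),
                                   sprintf("s%02d", 1:80)))
  # TMM: the asymmetric injected block shifts library composition, which
  # plain library-size CPM would propagate into every null gene
  cpm <- cpm_normalize(counts, "tmm")
  de <- de_test(cpm, colnames(cpm)[grp == "A"], colnames(cpm)[grp == "B"],
                p_threshold = 0.05)
  hit <- de$gene[de$passes_filters]
  injected <- sprintf("g%04d", seq_len(n_eff))
  expect_gte(mean(injected %in% hit), 0.9)
  # null genes: p below threshold at roughly the nominal rate
  null_p <- de$p_value[!de$gene %in% injected]
  expect_lt(abs(mean(null_p < 0.05) - 0.05), 0.02)
  # wilcoxon alternative agrees on the strong effects
  de_w <- de_test(cpm, colnames(cpm)[grp == "A"],
                  colnames(cpm)[grp == "B"],
                  p_threshold = 0.05, test = "wilcoxon")
  expect_gte(mean(injected %in% de_w$gene[de_w$passes_filters]), 0.9)
})

test_that("sex_concordance flags exactly the swapped labels", {
  b <- tiny_cohort()
  cpm <- cpm_normalize(b$counts)
  sex <- setNames(b$truth$sex, b$truth$sample_id)[colnames(cpm)]
  y_markers <- b$gene_info$gene[b$gene_info$class == "y_linked"]
  clean <- sex_concordance(cpm, sex, y_markers)
  expect_false(any(clean$flagged))
  swapped <- sex
  males <- which(unname(swapped) == "male")[1:2]
  fem <- which(unname(swapped) == "female")[1]
  swapped[c(males, fem)] <- c("female", "female", "male")
  res <- sex_concordance(cpm, swapped, y_markers)
  expect_setequal(res$sample[res$flagged],
                  colnames(cpm)[c(males, fem)])
  expect_error(sex_concordance(cpm, rep("male", ncol(cpm)), y_markers),
               class = "loy_usage_error")
})

test_that("enrich matches hypergeometric tail enumeration and its examples", {
  universe <- sprintf("g%03d", 1:1000)
  sets <- list(term_a = universe[1:10], term_b = universe[11:60])
  # hits = one entire 10-gene term: fold enrichment (10/10)/(10/1000) = 100
  res <- enrich(universe[1:10], universe, sets)
  row_a <- res[res$term == "term_a", ]
  expect_equal(row_a$fold_enrichment, 100)
  expect_lt(row_a$p_value, 1e-10)
  row_b <- res[res$term == "term_b", ]
  expect_equal(row_b$fold_enrichment, 0)
  expect_equal(row_b$p_value, 1)
  # hits = universe: fold enrichment 1 everywhere
  res2 <- enrich(universe, universe, sets)
  expect_equal(res2$fold_enrichment, c(1, 1))
  # enumeration oracle on small universes
  set.seed(207)
  for (i in 1:30) {
    N <- sample(10:50, 1)
    uni <- sprintf("u%02d", seq_len(N))
    K <- sample(2:(N - 1), 1)
    n <- sample(2:(N - 1), 1)
    set <- sample(uni, K)
    hits <- sample(uni, n)
    k <- length(intersect(hits, set))
    r <- enrich(hits, uni, list(t = set))
    want <- if (k == 0) 1 else oracle_hyper_tail(k, K, n, N)
    expect_equal(r$p_value, want, tolerance = 1e-12)
  }
  expect_error(enrich("g001", character(), sets), class = "loy_usage_error")
  expect_error(enrich("zzz", universe, sets), class = "loy_usage_error")
})

test_that("read_gmt parses term/description/genes lines", {
  f <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("setA\tdesc\tg1\tg2\tg3", "setB\tna\tg2\tg4"), f)
  sets <- read_gmt(f)
  expect_identical(names(sets), c("setA", "setB"))
  expect_identical(sets$setA, c("g1", "g2", "g3"))
})
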