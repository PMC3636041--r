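test_that("the randomization median test matches exhaustive subset enumeration", {
  # 8-gene universe, module of 3: all C(8,3) = 56 subsets enumerable
  omega <- setNames(c(0.05, 0.08, 0.10, 0.15, 0.20, 0.40, 0.55, 0.90),
                    sprintf("g%d", 1:8))
  module <- c("g1", "g2", "g3")
  res <- randomization_median_test(omega, module, n_samples = 1e5,
                                   rng_seed = 43L, module_label = "low")
  p_exact <- enum_median_test_p(unname(omega), 1:3)
  expect_lt(abs(res$p_raw - p_exact), 0.01)
  expect_equal(res$statistic, 0.08)
  expect_identical(res$n_used, 3L)
  expect_equal(res$p_bonferroni, min(1, 7 * res$p_raw))
})

test_that("a module equal to the whole universe has p = 1; missing omegas are excluded", {
  omega <- setNames(c(0.1, 0.2, 0.3, NA, 0.4), sprintf("g%d", 1:5))
  res <- randomization_median_test(omega, sprintf("g%d", 1:5), n_samples = 200,
                                   rng_seed = 45L)
  expect_equal(res$p_raw, 1)
  expect_identical(res$n_used, 4L)   # the NA gene is outside the universe
  expect_error(randomization_median_test(omega, "g4"), "no gene")
})

test_that("a strongly skewed module is detected below alpha = 0.01", {
  # a continuous universe makes the null median continuous, so a module of
  # the 10 smallest omegas is genuinely extreme (a two-point universe would
  # leave large probability atoms on the median and mask the skew)
  set.seed(47)
  omega <- setNames(sort(rlnorm(100, log(0.15), 0.5)), sprintf("g%03d", 1:100))
  res <- randomization_median_test(omega, sprintf("g%03d", 1:10),
                                   n_samples = 10000, rng_seed = 47L)
  expect_lt(res$p_raw, 0.01)
  expect_lt(res$statistic, res$null_ci[1])   # outside the null interval
})

test_that("chi-square GOF reproduces hand-computed statistics and guards small expectations", {
  classes <- setNames(rep(c("A", "B"), each = 50), sprintf("g%03d", 1:100))
  # observed (10, 30) against expected proportions (0.5, 0.5): stat = 10
  module <- c(names(classes)[classes == "A"][1:10],
              names(classes)[classes == "B"][1:30])
  res <- chisq_gof(module, classes)
  expect_equal(res$statistic, 10)
  expect_equal(res$p_raw, pchisq(10, df = 1, lower.tail = FALSE))
  expect_equal(res$observed_expected$diff, c(-10, 10))
  # module proportions identical to the universe: statistic 0, p 1
  balanced <- c(names(classes)[classes == "A"][1:20],
                names(classes)[classes == "B"][1:20])
  res0 <- chisq_gof(balanced, classes)
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p_raw, 1)
  # class relabeling leaves the statistic unchanged
  relabeled <- setNames(chartr("AB", "BA", classes), names(classes))
  expect_equal(chisq_gof(module, relabeled)$statistic, res$statistic)
  # doubling observed and expected doubles the statistic
  classes2 <- setNames(rep(c("A", "B"), each = 100), sprintf("h%03d", 1:200))
  module2 <- c(names(classes2)[classes2 == "A"][1:20],
               names(classes2)[classes2 == "B"][1:60])
  expect_equal(chisq_gof(module2, classes2)$statistic, 20)
  # expected count <= 5 must error with merge advice
  expect_error(chisq_gof(names(classes)[1:8], classes), "merge classes")
})

test_that("the chi-square p approximates the exact multinomial tail on a small module", {
  # universe with three equally likely classes; module of 24 keeps every
  # expected count at 8 (> 5)
  classes <- setNames(rep(c("A", "B", "C"), each = 200), sprintf("g%04d", 1:600))
  module <- c(names(classes)[classes == "A"][1:13],
              names(classes)[classes == "B"][1:7],
              names(classes)[classes == "C"][1:4])
  res <- chisq_gof(module, classes)
  p_exact <- enum_multinomial_chisq_p(c(13, 7, 4), rep(1 / 3, 3))
  expect_lt(abs(res$p_raw - p_exact), 0.02)
})

test_that("hypergeometric enrichment matches direct combinatorics", {
  uni <- sprintf("g%02d", 1:10)
  res <- hypergeom_enrichment(uni[1:4], uni[1:5], uni)
  expect_equal(res$p_raw, 5 / 210)               # C(5,4) C(5,0) / C(10,4)
  expect_equal(res$statistic, 4)
  # random configurations on N <= 30 against summed point masses
  set.seed(49)
  for (i in 1:20) {
    N <- sample(10:30, 1)
    uni <- sprintf("u%02d", 1:N)
    K <- sample(2:(N - 2), 1); m <- sample(2:(N - 2), 1)
    prop <- sample(uni, K); mod <- sample(uni, m)
    k <- length(intersect(mod, prop))
    res <- hypergeom_enrichment(mod, prop, uni)
    expect_equal(res$p_raw, enum_hyper_p(k, N, K, m), tolerance = 1e-12)
    expect_equal(res$observed_expected$expected, m * K / N)
  }
  # property = universe: full overlap, p = 1
  res1 <- hypergeom_enrichment(uni[1:7], uni, uni)
  expect_equal(res1$statistic, 7)
  expect_equal(res1$p_raw, 1)
  # the expected-overlap formula at survey scale
  res2 <- hypergeom_enrichment(sprintf("x%05d", 1:444),
                               sprintf("x%05d", seq_len(612)),
                               sprintf("x%05d", 1:14293))
  expect_equal(res2$observed_expected$expected, 444 * 612 / 14293)
  expect_lt(abs(res2$observed_expected$expected - 19.0), 0.05)
})

test_that("upstream HCNE counting respects strand, window and half-open boundaries", {
  tss <- data.frame(gene_id = c("gp", "gm"), chrom = c("chr1", "chr1"),
                    tss = c(1000L, 5000L), strand = c("+", "-"),
                    stringsAsFactors = FALSE)
  # + strand window is [500, 1000); - strand window is [5000, 5500)
  hcne <- data.frame(chrom = "chr1",
                     start = c(400L, 0L, 999L, 1000L, 5499L, 5500L, 4900L),
                     end = c(600L, 500L, 1000L, 1100L, 5500L, 5600L, 5000L))
  counts <- count_hcne_upstream(tss, hcne, window_bp = 500L)
  # gp: [400,600) overlaps; [0,500) abuts the window start -> no; [999,1000)
  # overlaps by 1 bp; [1000,1100) is outside the half-open window
  expect_identical(counts[["gp"]], 3L - 1L)
  # gm: [5499,5500) overlaps by 1 bp; [5500,5600) abuts -> no; [4900,5000) -> no
  expect_identical(counts[["gm"]], 1L)
  # no interval on the gene's chromosome -> 0, with a warning for unknowns
  tss2 <- data.frame(gene_id = "g1", chrom = "chr2", tss = 1000L, strand = "+")
  expect_warning(c2 <- count_hcne_upstream(tss2, hcne), "unknown chromosome")
  expect_identical(unname(c2), 0L)
})

test_that("HCNE counting is symmetric under coordinate reflection with strand flip", {
  set.seed(51)
  n <- 40
  tss <- data.frame(gene_id = sprintf("g%02d", 1:n),
                    chrom = sample(paste0("chr", 1:3), n, TRUE),
                    tss = sample(2000:50000, n),
                    strand = sample(c("+", "-"), n, TRUE),
                    stringsAsFactors = FALSE)
  hcne <- data.frame(chrom = sample(paste0("chr", 1:3), 60, TRUE),
                     start = sample(1000:52000, 60))
  hcne$end <- hcne$start + sample(20:200, 60, TRUE)
  M <- 100000L
  refl_tss <- transform(tss, tss = M - tss,
                        strand = ifelse(strand == "+", "-", "+"))
  refl_hcne <- data.frame(chrom = hcne$chrom, start = M - hcne$end,
                          end = M - hcne$start)
  expect_identical(count_hcne_upstream(tss, hcne, 500L),
                   count_hcne_upstream(refl_tss, refl_hcne, 500L))
})

test_that("intron mode counts overlaps with supplied intervals instead", {
  tss <- data.frame(gene_id = "g1", chrom = "chr1", tss = 1000L, strand = "+")
  introns <- data.frame(gene_id = c("g1", "g1"), chrom = "chr1",
                        start = c(2000L, 4000L), end = c(2500L, 4200L))
  hcne <- data.frame(chrom = "chr1", start = c(2100L, 4100L, 600L),
                     end = c(2200L, 4150L, 700L))
  counts <- count_hcne_upstream(tss, hcne, introns = introns)
  expect_identical(counts[["g1"]], 2L)   # the upstream hit is not counted
})

test_that("TF regulatory fractions match a brute-force recount on a simulated fixture", {
  cfg <- sim_config(n_genes = 200, module_sizes = rep(15L, 7L), rng_seed = 53L)
  sim <- simulate_timecourse(cfg)
  ann <- simulate_annotations(sim$truth, cfg)$annotation
  mem <- sim$truth$planted_membership
  modules <- split(names(mem)[!is.na(mem)], mem[!is.na(mem)])
  out <- tf_regulatory_fractions(modules, ann)
  for (nm in names(modules)) {
    sub <- ann[ann$gene_id %in% modules[[nm]] & ann$is_tf, ]
    row <- out$table[out$table$module == nm, ]
    expect_identical(row$n_tf, nrow(sub))
    if (nrow(sub)) {
      expect_equal(row$frac_tf_hcne, mean(sub$hcne_count > 0))
      expect_equal(row$frac_tf_tfr, mean(sub$has_tfr))
    } else {
      expect_true(is.na(row$frac_tf_hcne) && is.na(row$frac_tf_tfr))
    }
  }
  all_tf <- ann[ann$is_tf, ]
  expect_equal(out$overall$frac_tf_hcne, mean(all_tf$hcne_count > 0))
  # degenerate module without TFs reports missing fractions
  no_tf <- ann$gene_id[!ann$is_tf][1:5]
  out2 <- tf_regulatory_fractions(list(none = no_tf), ann)
  expect_true(is.na(out2$table$frac_tf_hcne))
})

test_that("metastage profiles pool values within metastages in canonical order", {
  v <- matrix(1:24, 2, 12, dimnames = list(c("a", "b"), NULL))
  map <- c("zygote", "zygote", "cleavage", "cleavage", "blastula", "blastula",
           "neurula", "neurula", "organogenesis", "organogenesis",
           "post-embryonic", "post-embryonic")
  prof <- metastage_profiles(v, map, c("a", "b"))
  expect_identical(names(prof), c("zygote", "cleavage", "blastula", "neurula",
                                  "organogenesis", "post-embryonic"))
  expect_equal(unname(prof[1]), mean(v[, 1:2]))
  # a single constant gene gives a constant profile
  vc <- matrix(3, 1, 12, dimnames = list("a", NULL))
  expect_equal(unname(metastage_profiles(vc, map, "a")), rep(3, 6))
  # two time points with module means 1 and 3 average to 2
  v2 <- matrix(c(1, 3), 1, 2, dimnames = list("a", NULL))
  expect_equal(unname(metastage_profiles(v2, c("zygote", "zygote"), "a")[1]), 2)
  # unmapped time points are excluded, absent metastages are NA
  map2 <- c("zygote", NA, rep("cleavage", 10))
  prof2 <- metastage_profiles(v, map2, c("a", "b"))
  expect_equal(unname(prof2["zygote"]), mean(v[, 1]))
  expect_true(is.na(prof2["neurula"]))
  expect_error(metastage_profiles(v, map, "zz"), "empty module")
  expect_error(metastage_profiles(v, c(map[-1], "gastrula"), "a"),
               "outside the allowed set")
})

test_that("pooled metastage means agree with two-step averaging when stage counts are balanced", {
  set.seed(55)
  v <- matrix(rnorm(60), 5, 12, dimnames = list(sprintf("g%d", 1:5), NULL))
  map <- rep(c("zygote", "cleavage", "blastula", "neurula", "organogenesis",
               "post-embryonic"), each = 2)
  genes <- sprintf("g%d", 1:3)
  pooled <- metastage_profiles(v, map, genes)
  two_step <- sapply(unique(map), function(ms)
    mean(rowMeans(v[genes, map == ms, drop = FALSE])))
  expect_equal(pooled[unique(map)], two_step)
})

test_that("expression conservation is the Pearson correlation over shared metastages", {
  a <- c(zygote = 1, cleavage = 2, blastula = 3, neurula = 4,
         organogenesis = 5, `post-embryonic` = 6)
  expect_equal(expression_conservation(a, a)$r, 1)
  expect_equal(expression_conservation(a, 2 * a)$r, 1)       # affine invariance
  expect_equal(expression_conservation(a, -a)$r, -1)
  ec <- expression_conservation(a, c(a[1:4], organogenesis = NA,
                                     `post-embryonic` = NA))
  expect_identical(ec$n, 4L)
  flat <- a; flat[] <- 2
  z <- expression_conservation(a, flat)
  expect_false(z$defined)
  expect_true(is.na(z$r))
  expect_error(expression_conservation(a[1:2], a[1:2]), ">=3")
})
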