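make_raw <- function(...) {
  cfg <- sim_config(...)
  list(cfg = cfg, sim = simulate_timecourse(cfg))
}

test_that("log10 transform is exact and round-trips; nonpositive values are named", {
  m <- expr_matrix(matrix(c(1, 1000, 10, 100), 2, 2,
                          dimnames = list(c("a", "b"), NULL)),
                   stage = 1:2, replicate = 1L)
  lt <- log10_transform(m)
  expect_equal(unname(lt$values), matrix(c(0, 3, 1, 2), 2, 2))
  expect_true(lt$log_scale)
  expect_error(log10_transform(lt), "already")
  bad <- m; bad$values["b", 2] <- 0
  expect_error(log10_transform(bad), "gene 'b' on array 2")

  x <- make_raw(n_genes = 30, n_stages = 10, n_sex_split_stages = 2,
                module_sizes = rep(2L, 7L), noise_sd = 0,
                array_effects = list(enabled = FALSE), rng_seed = 2L)
  lt2 <- log10_transform(x$sim$matrix)
  expect_equal(10^lt2$values, x$sim$matrix$values, tolerance = 1e-12)
})

test_that("quantile normalization maps columns onto the per-rank mean", {
  two <- cbind(a = c(1, 2, 3), b = c(4, 5, 6))
  qn <- quantile_normalize(two)
  expect_equal(unname(qn[, 1]), c(2.5, 3.5, 4.5))
  expect_equal(unname(qn[, 2]), c(2.5, 3.5, 4.5))

  same <- cbind(c(5, 1, 3), c(5, 1, 3))
  expect_equal(quantile_normalize(same), same)

  set.seed(4)
  m <- matrix(rnorm(200), 40, 5)
  qn <- quantile_normalize(m)
  ref <- sort(qn[, 1])
  for (j in 2:5) expect_equal(sort(qn[, j]), ref)          # identical multiset
  for (j in 1:5) expect_equal(rank(qn[, j]), rank(m[, j])) # order preserved
  expect_equal(quantile_normalize(qn), qn)                 # idempotent
  perm <- c(3, 1, 5, 2, 4)
  expect_equal(quantile_normalize(m[, perm]), qn[, perm])  # column equivariance
})

test_that("piecewise-linear maps interpolate anchors and extrapolate terminal slopes", {
  id <- pw_map(c(1, 2, 3), c(1, 2, 3))
  expect_equal(pw_apply(id, c(0.5, 1.7, 3.9)), c(0.5, 1.7, 3.9))
  mp <- pw_map(c(0, 1, 3), c(0, 2, 4))
  expect_equal(pw_apply(mp, c(0, 1, 3)), c(0, 2, 4))  # anchors map exactly
  expect_equal(pw_apply(mp, 0.5), 1)                  # midpoint of segment
  expect_equal(pw_apply(mp, 2), 3)
  expect_equal(pw_apply(mp, -1), -2)                  # first-segment slope
  expect_equal(pw_apply(mp, 4), 5)                    # last-segment slope
  expect_error(pw_map(c(2, 2), c(1, 5)), "<2 distinct")
  expect_warning(pw_map(c(1, 2, 3), c(0, 5, 2)), "non-monotone")
})

test_that("spike-in maps have one anchor per level and invert known affine distortions", {
  x <- make_raw(n_genes = 40, n_stages = 10, n_sex_split_stages = 2,
                module_sizes = rep(0L, 7L), noise_sd = 0, sex_effect = 0,
                rng_seed = 6L)
  lt <- log10_transform(x$sim$matrix)
  maps <- build_spikein_maps(lt)
  expect_length(maps, ncol(lt$values))
  expect_length(maps[[1]]$x, x$cfg$spike_in_levels)    # 10 anchor pairs
  a <- x$sim$truth$array_slope; b <- x$sim$truth$array_offset
  ladder <- unname(x$sim$truth$spike_in_true_levels)
  for (j in seq_along(maps)) {
    # anchor x is the distorted ladder; anchor y recovers the true ladder,
    # i.e. y = (x - b) / a
    expect_equal(maps[[j]]$x, sort(a[j] * ladder + b[j]), tolerance = 1e-9)
    expect_equal(maps[[j]]$y, (maps[[j]]$x - b[j]) / a[j], tolerance = 1e-9)
  }
  # arrays already identical on spike-ins -> identity map at anchors
  x0 <- make_raw(n_genes = 40, n_stages = 10, n_sex_split_stages = 2,
                 module_sizes = rep(0L, 7L), noise_sd = 0, sex_effect = 0,
                 array_effects = list(enabled = FALSE), rng_seed = 6L)
  maps0 <- build_spikein_maps(log10_transform(x0$sim$matrix))
  for (mp in maps0) expect_equal(mp$y, mp$x, tolerance = 1e-12)
})

test_that("after equalization the per-level spike-in medians agree across arrays of a replicate", {
  x <- make_raw(n_genes = 60, n_stages = 12, n_sex_split_stages = 2,
                module_sizes = rep(4L, 7L), noise_sd = 0, rng_seed = 8L)
  lt <- log10_transform(x$sim$matrix)
  eq <- apply_maps(lt, build_spikein_maps(lt))
  sp <- eq$values[eq$is_spike, ]
  lev <- sub("^SPIKE_L([0-9]+)_.*$", "\\1", rownames(sp))
  for (r in unique(eq$meta$replicate)) {
    cols <- which(eq$meta$replicate == r)
    med <- sapply(unique(lev), function(l)
      apply(sp[lev == l, cols, drop = FALSE], 2, median))
    expect_true(all(abs(sweep(med, 2, colMeans(med))) < 1e-9))
  }
})

test_that("replicate and sex averaging reduce the design to one column per stage", {
  x <- make_raw(rng_seed = 10L, n_genes = 50, module_sizes = rep(2L, 7L))
  lt <- log10_transform(x$sim$matrix)
  ar <- average_replicates(lt)
  expect_identical(ncol(ar$values), 50L + 2L * 10L)   # per (stage, sex)
  as_ <- average_sexes(ar)
  expect_identical(ncol(as_$values), 60L)             # one per stage
  expect_identical(as_$meta$stage, 1:60)

  # identical replicates pass through unchanged; [2,4] -> 3
  v <- matrix(c(2, 2, 4, 4), 1, 4,
              dimnames = list("g", NULL))
  em <- expr_matrix(v[, c(1, 3, 2, 4), drop = FALSE], stage = c(1, 2, 1, 2),
                    replicate = c(1, 1, 2, 2))
  av <- average_replicates(em)
  expect_equal(unname(av$values["g", ]), c(2, 4))
  em2 <- expr_matrix(matrix(c(2, 4), 1, 2, dimnames = list("g", NULL)),
                     stage = c(1, 1), replicate = c(1, 2))
  expect_equal(unname(average_replicates(em2)$values["g", 1]), 3)

  orphan <- expr_matrix(matrix(1:3, 1, 3, dimnames = list("g", NULL)),
                        stage = c(1, 1, 2), replicate = c(1, 2, 1))
  expect_error(average_replicates(orphan), "missing replicate partner")
})

test_that("the full chain inverts zero-noise affine distortions to 1e-9", {
  # no planted modules: every step including within-replicate quantile
  # normalization is distortion-free, so planted baselines return exactly
  x <- make_raw(n_genes = 80, n_stages = 12, n_sex_split_stages = 2,
                module_sizes = rep(0L, 7L), noise_sd = 0, sex_effect = 0,
                baseline_mean = 2.2, baseline_sd = 0.25, rng_seed = 12L)
  norm <- normalize_chain(x$sim$matrix)
  base <- x$sim$truth$baseline_log10
  ladder <- range(x$sim$truth$spike_in_true_levels)
  inside <- base > ladder[1] & base < ladder[2]   # anchor-spanned intensities
  recovered <- norm$values[names(base)[inside], ]
  expect_true(max(abs(recovered - base[inside])) < 1e-9)

  # with planted modules the spike-anchored map still inverts exactly once
  # the distribution-equalizing QN step is toggled off
  y <- make_raw(n_genes = 80, n_stages = 12, n_sex_split_stages = 2,
                module_sizes = rep(5L, 7L), noise_sd = 0, sex_effect = 0,
                baseline_mean = 2.2, baseline_sd = 0.25, rng_seed = 14L)
  norm2 <- normalize_chain(y$sim$matrix, quantile_within_replicates = FALSE)
  mem <- y$sim$truth$planted_membership
  base2 <- y$sim$truth$baseline_log10
  w <- y$cfg$stage_windows
  expected <- outer(base2, rep(1, 12))
  for (k in seq_len(nrow(w))) {
    rows <- which(mem == w$stage_label[k])
    expected[rows, w$start[k]:w$end[k]] <-
      expected[rows, w$start[k]:w$end[k]] + y$cfg$overexpression_effect
  }
  lad2 <- range(y$sim$truth$spike_in_true_levels)
  ok <- expected > lad2[1] & expected < lad2[2]
  expect_true(max(abs((norm2$values[names(base2), ] - expected)[ok])) < 1e-9)
})
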