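# Independent oracles and fixture builders used across the suite.
# Everything here is deliberately written with plain loops / direct
# combinatorics, independent of the package's vectorized implementations.

# exact two-sided randomization p for a median test: enumerate all subsets
# of size m of the universe, compute each median, and apply the same
# two-sided tail definition (without Monte-Carlo, so no add-one correction)
enum_median_test_p <- function(values, module_idx) {
  m <- length(module_idx)
  obs <- median(values[module_idx])
  subsets <- combn(length(values), m)
  meds <- apply(subsets, 2L, function(i) median(values[i]))
  lo <- mean(meds <= obs)
  hi <- mean(meds >= obs)
  min(1, 2 * min(lo, hi))
}

# direct combinatorial upper-tail hypergeometric probability
enum_hyper_p <- function(k, N, K, m) {
  js <- k:min(K, m)
  sum(choose(K, js) * choose(N - K, m - js)) / choose(N, m)
}

# exact multinomial tail probability of the chi-square GOF statistic:
# enumerate all compositions of n into the classes
enum_multinomial_chisq_p <- function(obs, props) {
  n <- sum(obs)
  k <- length(props)
  expected <- n * props
  stat_of <- function(o) sum((o - expected)^2 / expected)
  obs_stat <- stat_of(obs)
  comps <- compositions_of(n, k)
  p <- 0
  for (i in seq_len(nrow(comps))) {
    o <- comps[i, ]
    if (stat_of(o) >= obs_stat - 1e-9)
      p <- p + exp(lgamma(n + 1) - sum(lgamma(o + 1)) + sum(o * log(props)))
  }
  p
}

compositions_of <- function(n, k) {
  if (k == 1L) return(matrix(n, 1L, 1L))
  out <- NULL
  for (first in 0:n) {
    rest <- compositions_of(n - first, k - 1L)
    out <- rbind(out, cbind(first, rest))
  }
  unname(out)
}

# loop-based re-implementation of the seeded ISA (one run), used as a
# dual-route oracle on tiny matrices
loop_isa <- function(m, seed, t_g, t_c, max_iter = 100L, conv = 0.99) {
  m2 <- rbind(m, seed)
  rownames(m2)[nrow(m2)] <- ".seed."
  # row standardization
  Eg <- m2
  for (i in seq_len(nrow(m2))) {
    mu <- mean(m2[i, ]); s <- sd(m2[i, ])
    Eg[i, ] <- (m2[i, ] - mu) / s
  }
  # column standardization of the row-standardized matrix
  Ec <- Eg
  for (j in seq_len(ncol(Eg))) {
    mu <- mean(Eg[, j]); s <- sd(Eg[, j])
    Ec[, j] <- (Eg[, j] - mu) / s
  }
  genes <- rownames(m2)
  g_scores <- setNames(numeric(length(genes)), genes)
  g_scores[".seed."] <- 1
  g_set <- ".seed."
  for (it in seq_len(max_iter)) {
    c_raw <- numeric(ncol(m2))
    for (j in seq_len(ncol(m2))) {
      num <- 0; den <- 0
      for (g in g_set) { num <- num + g_scores[g] * Eg[g, j]; den <- den + g_scores[g] }
      c_raw[j] <- num / den
    }
    keep_c <- which(c_raw > t_c * sd(c_raw))
    if (!length(keep_c)) return(NULL)
    c_scores <- c_raw[keep_c] / max(c_raw[keep_c])
    g_raw <- setNames(numeric(length(genes)), genes)
    for (g in genes) {
      num <- 0; den <- 0
      for (jj in seq_along(keep_c)) {
        num <- num + c_scores[jj] * Ec[g, keep_c[jj]]; den <- den + c_scores[jj]
      }
      g_raw[g] <- num / den
    }
    keep_g <- which(g_raw > t_g * sd(g_raw))
    if (!length(keep_g)) return(NULL)
    new_set <- genes[keep_g]
    jac <- length(intersect(new_set, g_set)) / length(union(new_set, g_set))
    new_scores <- setNames(numeric(length(genes)), genes)
    new_scores[new_set] <- g_raw[new_set] / max(g_raw[new_set])
    g_set <- new_set
    g_scores <- new_scores
    if (jac >= conv) break
  }
  list(genes = sort(setdiff(g_set, ".seed.")), time_points = keep_c,
       gene_scores = g_scores)
}

# small deterministic matrix with one planted block and non-constant
# background (fixed jitter, no RNG)
block_matrix <- function(n_genes = 10L, n_cond = 6L, block_genes = 1:4,
                         block_cond = 2:4, effect = 2, jitter_amp = 0.05) {
  jit <- outer(seq_len(n_genes), seq_len(n_cond),
               function(i, j) jitter_amp * sin(3.7 * i + 1.3 * j))
  m <- 2 + jit
  m[block_genes, block_cond] <- m[block_genes, block_cond] + effect
  rownames(m) <- sprintf("g%02d", seq_len(n_genes))
  colnames(m) <- sprintf("t%02d", seq_len(n_cond))
  m
}

# Jaccard of recovered modules against the planted membership of a fit
recovery_jaccard <- function(fit, membership) {
  truth <- split(names(membership), membership)
  vapply(fit$modules, function(m) {
    tg <- truth[[m$stage_label]]
    length(intersect(m$genes, tg)) / length(union(m$genes, tg))
  }, numeric(1))
}
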