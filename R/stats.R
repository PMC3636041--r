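#' @export
print.module_test <- function(x, ...) {
  cat(sprintf("%s [module '%s']\n", x$method, x$module_label))
  cat(sprintf("  statistic = %.4g; p = %.4g (Bonferroni %.4g); n = %d\n",
              x$statistic, x$p_raw, x$p_bonferroni, x$n_used))
  cat("  null:", x$null_description, "\n")
  if (!is.null(x$observed_expected)) {
    cat("  observed vs expected:\n")
    print(x$observed_expected)
  }
  invisible(x)
}

.module_test <- function(method, module_label, statistic, null_description,
                         p_raw, family, observed_expected = NULL, n_used = NA_integer_,
                         extra = list()) {
  structure(c(list(method = method, module_label = module_label,
                   statistic = statistic, null_description = null_description,
                   p_raw = p_raw, p_bonferroni = min(1, family * p_raw),
                   observed_expected = observed_expected,
                   n_used = as.integer(n_used)), extra),
            class = "module_test")
}

#' Randomization test on a module's median omega (dN/dS)
#'
#' Draws `n_samples` random gene sets of the module's size (each without
#' replacement) from the universe of genes with a non-missing omega and
#' computes each set's median, giving a sampling distribution of the median
#' for a random set of that size. The two-sided empirical p-value uses the
#' add-one correction `(r + 1) / (n + 1)` on each tail, doubled and capped
#' at 1. The percentile interval of the null medians at level `alpha` is
#' also returned.
#'
#' @param omega named numeric vector of per-gene mean dN/dS over the
#'   universe; `NA` allowed (those genes are outside the null universe).
#' @param module_genes gene ids of the module.
#' @param n_samples number of random sets.
#' @param rng_seed optional integer seed.
#' @param alpha significance level used for the null percentile interval.
#' @param family Bonferroni family size (number of modules compared).
#' @param module_label label carried into the result.
#' @return a `module_test` with the observed median as statistic and the
#'   null interval in `$null_ci`.
#' @export
randomization_median_test <- function(omega, module_genes, n_samples = 10000L,
                                      rng_seed = NULL, alpha = 0.01,
                                      family = 7L, module_label = NA_character_) {
  if (!is.null(rng_seed)) set.seed(rng_seed)
  universe <- names(omega)[!is.na(omega)]
  vals <- omega[universe]
  mod <- intersect(module_genes, universe)
  m <- length(mod)
  if (m < 1L) stop("module has no gene with a non-missing omega")
  obs <- stats::median(vals[mod])
  null_medians <- .null_medians(as.numeric(vals), m, n_samples)
  lo <- (sum(null_medians <= obs) + 1) / (n_samples + 1)
  hi <- (sum(null_medians >= obs) + 1) / (n_samples + 1)
  p <- min(1, 2 * min(lo, hi))
  ci <- stats::quantile(null_medians, c(alpha / 2, 1 - alpha / 2), names = FALSE)
  .module_test("Randomization test on median omega", module_label,
               statistic = obs,
               null_description = sprintf(
                 "medians of %d random sets of %d genes drawn from %d genes with omega",
                 n_samples, m, length(universe)),
               p_raw = p, family = family,
               observed_expected = data.frame(observed = obs,
                                              expected = stats::median(null_medians)),
               n_used = m,
               extra = list(null_ci = ci, n_samples = n_samples))
}

# medians of n_samples random subsets of size m (vectorized over samples)
.null_medians <- function(vals, m, n_samples) {
  if (m == length(vals)) return(rep(stats::median(vals), n_samples))
  idx <- vapply(seq_len(n_samples), function(i) sample.int(length(vals), m),
                integer(m))
  sub <- matrix(vals[idx], nrow = m)
  sub <- apply(sub, 2L, sort)
  if (m %% 2L == 1L) sub[(m + 1L) %/% 2L, ]
  else (sub[m %/% 2L, ] + sub[m %/% 2L + 1L, ]) / 2
}

#' Chi-square goodness of fit of a module's class distribution
#'
#' Compares the observed class counts of the module's genes against the
#' expectation under the universe-wide class proportions (expected count =
#' module size x universe proportion). Classes whose expected count is not
#' greater than 5 trigger an error instructing the caller to merge classes.
#'
#' @param module_genes gene ids.
#' @param classes named factor/character vector: class per universe gene.
#' @param family Bonferroni family size.
#' @param module_label label.
#' @return a `module_test`; `observed_expected` holds per-class observed,
#'   expected and their difference (the bar heights of an
#'   observed-minus-expected plot).
#' @export
chisq_gof <- function(module_genes, classes, family = 7L,
                      module_label = NA_character_) {
  classes <- factor(classes[!is.na(classes)])
  lev <- levels(classes)
  mod <- intersect(module_genes, names(classes))
  if (!length(mod)) stop("no module gene has a class")
  obs <- table(factor(classes[mod], levels = lev))
  props <- as.numeric(table(classes)) / length(classes)
  if (any(props == 0)) stop("class absent from the universe")
  expected <- length(mod) * props
  if (any(expected <= 5))
    stop("expected count <= 5 for class(es) ",
         paste(lev[expected <= 5], collapse = ", "),
         "; merge classes before testing")
  ct <- stats::chisq.test(as.numeric(obs), p = props)
  .module_test("Chi-square goodness of fit", module_label,
               statistic = unname(ct$statistic),
               null_description = sprintf(
                 "multinomial with universe proportions over %d classes, df = %d",
                 length(lev), length(lev) - 1L),
               p_raw = unname(ct$p.value), family = family,
               observed_expected = data.frame(class = lev,
                                              observed = as.numeric(obs),
                                              expected = expected,
                                              diff = as.numeric(obs) - expected),
               n_used = length(mod))
}

#' Hypergeometric enrichment of a property gene set in a module
#'
#' Upper-tail test of the overlap between a module and a property set
#' within a finite universe: `P(X >= k)` for `X` hypergeometric. The
#' expected overlap `m * K / N` is reported alongside.
#'
#' @param module_genes module gene ids.
#' @param property_genes property gene ids (e.g. maternal genes, TFs).
#' @param universe all gene ids.
#' @param family Bonferroni family size.
#' @param module_label label.
#' @return a `module_test` with the overlap as statistic.
#' @export
hypergeom_enrichment <- function(module_genes, property_genes, universe,
                                 family = 7L, module_label = NA_character_) {
  if (!length(universe)) stop("empty universe")
  mod <- intersect(module_genes, universe)
  prop <- intersect(property_genes, universe)
  k <- length(intersect(mod, prop))
  N <- length(universe); K <- length(prop); m <- length(mod)
  p <- stats::phyper(k - 1, K, N - K, m, lower.tail = FALSE)
  .module_test("Hypergeometric enrichment", module_label,
               statistic = k,
               null_description = sprintf(
                 "hypergeometric(N = %d, K = %d, draws = %d), upper tail", N, K, m),
               p_raw = p, family = family,
               observed_expected = data.frame(observed = k,
                                              expected = m * K / N),
               n_used = m)
}

#' Count conserved non-coding elements in gene upstream windows
#'
#' For each gene, counts the HCNE intervals overlapping (by at least 1 bp)
#' the `window_bp` window upstream of the transcription start site:
#' `[TSS - window, TSS)` on the + strand, `[TSS, TSS + window)` on the -
#' strand. All coordinates are 0-based half-open. With `introns` supplied,
#' overlaps with each gene's intron intervals are counted instead.
#'
#' @param tss data.frame with `gene_id`, `chrom`, `tss` (0-based), `strand`
#'   (`"+"`/`"-"`).
#' @param hcne data.frame with `chrom`, `start`, `end` (0-based half-open).
#' @param window_bp upstream window size.
#' @param introns optional data.frame with `gene_id`, `chrom`, `start`,
#'   `end` (0-based half-open) replacing the upstream windows.
#' @return named integer vector: HCNE count per gene.
#' @export
count_hcne_upstream <- function(tss, hcne, window_bp = 500L, introns = NULL) {
  stopifnot(all(c("gene_id", "chrom", "tss", "strand") %in% names(tss)),
            all(tss$strand %in% c("+", "-")))
  if (is.null(introns)) {
    start0 <- ifelse(tss$strand == "+", tss$tss - window_bp, tss$tss)
    end0 <- start0 + window_bp
    win <- data.frame(gene_id = tss$gene_id, chrom = tss$chrom,
                      start = pmax(start0, 0L), end = end0,
                      stringsAsFactors = FALSE)
  } else {
    stopifnot(all(c("gene_id", "chrom", "start", "end") %in% names(introns)))
    win <- introns
  }
  counts <- stats::setNames(integer(nrow(tss)), tss$gene_id)
  if (!nrow(hcne) || !nrow(win)) return(counts)
  unknown <- setdiff(unique(hcne$chrom), unique(tss$chrom))
  if (length(unknown)) {
    warning("ignoring HCNE interval(s) on unknown chromosome(s): ",
            paste(unknown, collapse = ", "))
    hcne <- hcne[!hcne$chrom %in% unknown, , drop = FALSE]
    if (!nrow(hcne)) return(counts)
  }
  # 0-based half-open [s, e) -> 1-based closed [s + 1, e]
  g_win <- GenomicRanges::GRanges(win$chrom,
                                  IRanges::IRanges(win$start + 1L, win$end))
  g_hcne <- GenomicRanges::GRanges(hcne$chrom,
                                   IRanges::IRanges(hcne$start + 1L, hcne$end))
  ov <- GenomicRanges::countOverlaps(g_win, g_hcne, minoverlap = 1L)
  per_gene <- rowsum(ov, win$gene_id)
  counts[rownames(per_gene)] <- as.integer(per_gene)
  counts
}

#' Transcription-factor counts and regulatory-element fractions per module
#'
#' For each module: the number of its transcription factors, the fraction
#' of those TFs with at least one upstream HCNE, the fraction with an
#' associated transposon-free region, and the hypergeometric enrichment of
#' TFs in the module and of HCNE-bearing / TFR-bearing TFs among the
#' module's TFs (against all TFs). The same fractions over all TFs are
#' attached for reference.
#'
#' @param modules named list of gene-id vectors.
#' @param annotation data.frame with `gene_id`, `is_tf`, `hcne_count`,
#'   `has_tfr`.
#' @param family Bonferroni family size.
#' @return list with `table` (per-module data.frame; fractions `NA` for
#'   modules without TFs), `overall` and `tests` (per-module list of
#'   `module_test`s).
#' @export
tf_regulatory_fractions <- function(modules, annotation, family = 7L) {
  stopifnot(all(c("gene_id", "is_tf", "hcne_count", "has_tfr") %in% names(annotation)))
  all_tf <- annotation$gene_id[annotation$is_tf]
  tf_hcne <- annotation$gene_id[annotation$is_tf & annotation$hcne_count > 0]
  tf_tfr <- annotation$gene_id[annotation$is_tf & annotation$has_tfr]
  universe <- annotation$gene_id
  rows <- list(); tests <- list()
  for (nm in names(modules)) {
    g <- intersect(modules[[nm]], universe)
    mtf <- intersect(g, all_tf)
    n_tf <- length(mtf)
    rows[[nm]] <- data.frame(
      module = nm, n_genes = length(g), n_tf = n_tf,
      frac_tf_hcne = if (n_tf) length(intersect(mtf, tf_hcne)) / n_tf else NA_real_,
      frac_tf_tfr = if (n_tf) length(intersect(mtf, tf_tfr)) / n_tf else NA_real_,
      stringsAsFactors = FALSE)
    tst <- list(tf = hypergeom_enrichment(g, all_tf, universe, family, nm))
    if (n_tf) {
      tst$tf_hcne <- hypergeom_enrichment(mtf, tf_hcne, all_tf, family, nm)
      tst$tf_tfr <- hypergeom_enrichment(mtf, tf_tfr, all_tf, family, nm)
    }
    tests[[nm]] <- tst
  }
  overall <- data.frame(
    n_tf = length(all_tf),
    frac_tf_hcne = if (length(all_tf)) length(tf_hcne) / length(all_tf) else NA_real_,
    frac_tf_tfr = if (length(all_tf)) length(tf_tfr) / length(all_tf) else NA_real_)
  list(table = do.call(rbind, rows), overall = overall, tests = tests)
}

#' Mean module expression per developmental metastage
#'
#' Pools all (gene, time point) expression values of the module's genes
#' within each metastage and returns the mean, in canonical metastage
#' order. Metastages with no mapped time point are `NA`.
#'
#' @param values numeric matrix, genes x time points.
#' @param metastage_map character vector: metastage per time point (column),
#'   `NA` for unmapped time points.
#' @param module_genes gene ids.
#' @param metastages the metastage order; defaults to the canonical six.
#' @return named numeric vector of length `length(metastages)`.
#' @export
metastage_profiles <- function(values, metastage_map, module_genes,
                               metastages = c("zygote", "cleavage", "blastula",
                                              "neurula", "organogenesis",
                                              "post-embryonic")) {
  values <- as.matrix(values)
  stopifnot(length(metastage_map) == ncol(values))
  mapped <- !is.na(metastage_map)
  if (!all(metastage_map[mapped] %in% metastages))
    stop("metastage(s) outside the allowed set: ",
         paste(setdiff(metastage_map[mapped], metastages), collapse = ", "))
  g <- intersect(module_genes, rownames(values))
  if (!length(g)) stop("empty module (no gene present in the matrix)")
  out <- stats::setNames(rep(NA_real_, length(metastages)), metastages)
  for (ms in unique(metastage_map[mapped])) {
    cols <- which(!is.na(metastage_map) & metastage_map == ms)
    out[ms] <- mean(values[g, cols, drop = FALSE])
  }
  out
}

#' Expression conservation between two metastage profiles
#'
#' Pearson correlation over the shared non-missing metastages.
#' @param profile_a,profile_b named numeric vectors (e.g. from
#'   [metastage_profiles()] for a module and its orthologs).
#' @return list with `r`, `n` and `defined` (`FALSE` when a profile has
#'   zero variance, with `r = NA`).
#' @export
expression_conservation <- function(profile_a, profile_b) {
  shared <- intersect(names(profile_a)[!is.na(profile_a)],
                      names(profile_b)[!is.na(profile_b)])
  if (length(shared) < 3L) stop("need >=3 shared non-missing metastages")
  a <- profile_a[shared]; b <- profile_b[shared]
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    return(list(r = NA_real_, n = length(shared), defined = FALSE))
  list(r = stats::cor(a, b), n = length(shared), defined = TRUE)
}
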