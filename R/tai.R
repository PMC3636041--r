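#' Transcriptome age index (TAI) per developmental stage
#'
#' The TAI at a stage is the mean of the genes' phylostratum ranks weighted
#' by their expression at that stage: `sum(rank * w) / sum(w)`. The weight
#' transform is the audit's central knob: `"raw"` uses linear intensities,
#' `"log10"` uses log10 intensities (values below 0, i.e. intensities below
#' 1, clipped to 0 so weights stay nonnegative), `"binary"` recodes
#' expression as present/absent (log10 intensity strictly above
#' `threshold`), making the TAI the plain mean rank of expressed genes.
#' `NA` entries (e.g. masked by [remove_top_expressed()]) contribute zero
#' weight.
#'
#' @param values numeric matrix, genes x stages, linear-scale intensities
#'   (or an [expr_matrix()]; its scale flag is honoured).
#' @param ranks named vector of positive integer phylostratum ranks, one
#'   per gene (names matched against rownames).
#' @param transform `"raw"`, `"log10"` or `"binary"`.
#' @param threshold log10 presence threshold for `"binary"`.
#' @return an object of class `tai_profile`: data.frame with `stage`,
#'   `tai`, `n_used`; stages where all weights vanish get `NA` and are
#'   flagged.
#' @export
compute_tai <- function(values, ranks, transform = c("log10", "raw", "binary"),
                        threshold = 1) {
  transform <- match.arg(transform)
  lin <- .as_linear_values(values)
  stopifnot(!is.null(rownames(lin)))
  common <- intersect(rownames(lin), names(ranks))
  if (!length(common)) stop("no gene shared between matrix and ranks")
  lin <- lin[common, , drop = FALSE]
  r <- as.numeric(ranks[common])
  if (any(r <= 0 | r != round(r), na.rm = TRUE))
    stop("ranks must be positive integers")
  w <- switch(transform,
              raw = lin,
              log10 = pmax(log10(lin), 0),
              binary = (log10(lin) > threshold) * 1)
  w[is.na(w)] <- 0
  tot <- colSums(w)
  tai <- as.numeric(crossprod(w, r)) / tot
  tai[tot == 0] <- NA_real_
  out <- data.frame(stage = seq_len(ncol(lin)), tai = tai,
                    n_used = colSums(w > 0))
  structure(out, class = c("tai_profile", "data.frame"),
            transform = transform)
}

.as_linear_values <- function(values) {
  if (inherits(values, "expr_matrix")) {
    v <- values$values[!values$is_spike, , drop = FALSE]
    if (values$log_scale) v <- 10^v
    v
  } else as.matrix(values)
}

#' @export
print.tai_profile <- function(x, ...) {
  cat(sprintf("tai_profile (%s weights), %d stages, range %.3f..%.3f\n",
              attr(x, "transform"), nrow(x),
              min(x$tai, na.rm = TRUE), max(x$tai, na.rm = TRUE)))
  invisible(x)
}

#' @export
plot.tai_profile <- function(x, ...) {
  graphics::plot(x$stage, x$tai, type = "l", xlab = "developmental stage",
                 ylab = "TAI",
                 main = sprintf("Transcriptome age index (%s weights)",
                                attr(x, "transform")), ...)
  invisible(x)
}

#' Mask the top expressed genes at every stage
#'
#' At each stage independently, the `ceiling(fraction * n)` genes with the
#' highest intensity are set to `NA` so they contribute zero weight to any
#' downstream weighted mean. Ties at the cutoff are broken by gene order.
#'
#' @param values numeric matrix, genes x stages.
#' @param fraction fraction of genes to mask, in (0, 1).
#' @return the matrix with masked entries set to `NA`.
#' @export
remove_top_expressed <- function(values, fraction) {
  values <- as.matrix(values)
  stopifnot(fraction > 0, fraction < 1)
  k <- ceiling(fraction * nrow(values))
  for (j in seq_len(ncol(values))) {
    ord <- order(values[, j], decreasing = TRUE)
    values[ord[seq_len(k)], j] <- NA_real_
  }
  values
}

#' Recode a log10 expression matrix as present/absent
#'
#' A gene is scored as expressed (1) at a stage when its log10 intensity is
#' strictly above `threshold`, otherwise 0.
#' @param log10_values numeric matrix of log10 intensities.
#' @param threshold presence threshold (default 1).
#' @export
presence_absence <- function(log10_values, threshold = 1) {
  (as.matrix(log10_values) > threshold) * 1
}

#' Mean age of expressed genes per stage
#'
#' Ages are arbitrary nonnegative numbers (e.g. divergence-time estimates);
#' a gene counts as expressed when its log10 intensity is strictly above
#' `threshold`.
#' @param log10_values numeric matrix of log10 intensities.
#' @param ages named numeric vector of per-gene ages.
#' @param threshold presence threshold.
#' @return numeric vector, one mean age per stage (`NA` where no gene is
#'   expressed).
#' @export
mean_age_expressed <- function(log10_values, ages, threshold = 1) {
  m <- as.matrix(log10_values)
  common <- intersect(rownames(m), names(ages))
  if (!length(common)) stop("no gene shared between matrix and ages")
  m <- m[common, , drop = FALSE]
  a <- as.numeric(ages[common])
  pres <- m > threshold
  n <- colSums(pres)
  out <- as.numeric(crossprod(pres, a)) / n
  out[n == 0] <- NA_real_
  out
}

#' Per-stage difference between old-gene and young-gene median expression
#'
#' @param values numeric matrix, genes x stages.
#' @param old_set,young_set disjoint, nonempty gene-id sets.
#' @return numeric vector: `median(values[old, s]) - median(values[young, s])`
#'   per stage.
#' @export
old_young_median_diff <- function(values, old_set, young_set) {
  values <- as.matrix(values)
  old_set <- intersect(old_set, rownames(values))
  young_set <- intersect(young_set, rownames(values))
  if (!length(old_set) || !length(young_set)) stop("empty gene set")
  if (length(intersect(old_set, young_set))) stop("gene sets must be disjoint")
  apply(values[old_set, , drop = FALSE], 2L, stats::median) -
    apply(values[young_set, , drop = FALSE], 2L, stats::median)
}

#' Influence of a single gene on the TAI profile
#'
#' @param values numeric matrix, genes x stages.
#' @param ranks named phylostratum ranks.
#' @param gene gene id to drop.
#' @inheritParams compute_tai
#' @return list with `with`, `without` (both `tai_profile`s) and `diff`
#'   (per-stage difference with minus without).
#' @export
probe_influence <- function(values, ranks, gene,
                            transform = c("log10", "raw", "binary"),
                            threshold = 1) {
  transform <- match.arg(transform)
  values <- as.matrix(values)
  if (!gene %in% rownames(values)) stop("gene not present: ", gene)
  with_g <- compute_tai(values, ranks, transform, threshold)
  without_g <- compute_tai(values[setdiff(rownames(values), gene), , drop = FALSE],
                           ranks, transform, threshold)
  list(with = with_g, without = without_g, diff = with_g$tai - without_g$tai)
}
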