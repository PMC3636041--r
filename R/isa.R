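#' Double standardization for the Iterative Signature Algorithm
#'
#' Produces the two standardized copies of the expression matrix the ISA
#' iterates between: `Eg`, in which every gene row has mean 0 and sd 1
#' (used when scoring time points against the genes' own profiles), and
#' `Ec`, in which every time-point column of the row-standardized matrix
#' has mean 0 and sd 1 (used when scoring genes against the other genes at
#' those time points). Standardizing columns on top of the row
#' standardization matters for absolute-intensity data: it stops per-gene
#' baseline differences from leaking into the gene scores, so a gene
#' scores highly only where it is overexpressed relative to its own
#' profile. Constant rows carry no profile information and are dropped
#' with a warning.
#'
#' @param m numeric matrix, genes x time points (gene ids as rownames).
#' @return list with `Eg` and `Ec` (same dimensions, same rownames).
#' @export
isa_standardize <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) < 2L || ncol(m) < 2L) stop("need >=2 genes and >=2 time points")
  rsd <- apply(m, 1L, stats::sd)
  if (all(rsd == 0)) stop("all rows are constant")
  if (any(rsd == 0)) {
    warning(sum(rsd == 0), " constant row(s) dropped")
    m <- m[rsd > 0, , drop = FALSE]
    rsd <- rsd[rsd > 0]
  }
  Eg <- (m - rowMeans(m)) / rsd
  csd <- apply(Eg, 2L, stats::sd)
  if (any(csd == 0)) stop("constant time-point column(s)")
  Ec <- sweep(sweep(Eg, 2L, colMeans(Eg)), 2L, csd, `/`)
  list(Eg = Eg, Ec = Ec)
}

#' Artificial seed profiles, one per stage window
#'
#' Each seed is an idealized expression profile: 1 inside the stage window,
#' 0 outside (a boxcar).
#' @param stage_windows data.frame with `stage_label`, `start`, `end`.
#' @param n_stages number of time points.
#' @return named list of profiles (numeric vectors of length `n_stages`).
#' @export
seed_profiles <- function(stage_windows, n_stages) {
  stopifnot(all(stage_windows$start >= 1L), all(stage_windows$end <= n_stages))
  out <- lapply(seq_len(nrow(stage_windows)), function(k) {
    p <- numeric(n_stages)
    p[stage_windows$start[k]:stage_windows$end[k]] <- 1
    p
  })
  stats::setNames(out, stage_windows$stage_label)
}

.jaccard <- function(a, b) {
  if (!length(a) && !length(b)) return(1)
  length(intersect(a, b)) / length(union(a, b))
}

#' One seeded ISA run
#'
#' The seed profile is appended to the matrix as an artificial gene row and
#' standardized like a real gene. Starting from a gene set holding only the
#' seed, the run alternates: time-point scores are the gene-score-weighted
#' mean over the current gene set of the row-standardized expression,
#' thresholded at `t_c` standard deviations (computed over all time
#' points), positive side only; gene scores are the time-point-score-
#' weighted mean over the current time points of the column-standardized
#' expression, thresholded at `t_g` standard deviations (over all genes),
#' positive side only. Score vectors are rescaled each iteration so the
#' maximum score is 1. Iteration stops when two successive gene sets have
#' Jaccard similarity at least `convergence_overlap` or after
#' `max_iterations`. The artificial row's final (rescaled) gene score is
#' recorded and the row is stripped from the reported membership.
#'
#' @param m numeric matrix, genes x time points.
#' @param seed numeric seed profile of length `ncol(m)`.
#' @param t_g,t_c gene and time-point score thresholds, in multiples of the
#'   score standard deviation.
#' @param max_iterations iteration cap.
#' @param convergence_overlap minimal Jaccard similarity between successive
#'   gene sets declaring convergence.
#' @param stage_label label carried into the module.
#' @return an object of class `isa_module`, or `NULL` if the gene or
#'   time-point set empties.
#' @export
isa_iterate <- function(m, seed, t_g = 3, t_c = 2, max_iterations = 100L,
                        convergence_overlap = 0.99, stage_label = NA_character_) {
  stopifnot(t_g > 0, t_c > 0, convergence_overlap > 0, convergence_overlap <= 1,
            length(seed) == ncol(m), any(seed != 0))
  seed_id <- ".isa_seed."
  m2 <- rbind(m, matrix(seed, 1L, ncol(m), dimnames = list(seed_id, colnames(m))))
  std <- isa_standardize(m2)
  Eg <- std$Eg; Ec <- std$Ec
  genes <- rownames(Eg)
  if (!seed_id %in% genes) return(NULL)     # constant seed row was dropped

  g_scores <- stats::setNames(numeric(length(genes)), genes)
  g_scores[seed_id] <- 1
  g_set <- seed_id
  it <- 0L; converged <- FALSE
  c_scores <- NULL; c_set <- integer()
  g_raw_scaled <- NULL
  repeat {
    it <- it + 1L
    # time-point scores from the row-standardized matrix
    w <- g_scores[g_set]
    c_raw <- as.numeric(crossprod(Eg[g_set, , drop = FALSE], w)) / sum(w)
    keep_c <- which(c_raw > t_c * stats::sd(c_raw))
    if (!length(keep_c)) return(NULL)
    c_scores <- c_raw[keep_c] / max(c_raw[keep_c])
    c_set <- keep_c
    # gene scores from the column-standardized matrix
    g_raw <- as.numeric(Ec[, c_set, drop = FALSE] %*% c_scores) / sum(c_scores)
    names(g_raw) <- genes
    keep_g <- which(g_raw > t_g * stats::sd(g_raw))
    if (!length(keep_g)) return(NULL)
    top <- max(g_raw[keep_g])
    g_raw_scaled <- g_raw / top
    new_set <- genes[keep_g]
    new_scores <- stats::setNames(numeric(length(genes)), genes)
    new_scores[new_set] <- g_raw[new_set] / top
    done <- .jaccard(new_set, g_set) >= convergence_overlap
    g_set <- new_set
    g_scores <- new_scores
    if (done) { converged <- TRUE; break }
    if (it >= max_iterations) break
  }
  members <- setdiff(g_set, seed_id)
  structure(list(stage_label = stage_label,
                 genes = members,
                 gene_scores = g_scores[members],
                 time_points = c_set,
                 condition_scores = stats::setNames(c_scores, c_set),
                 threshold_pair = c(t_g = t_g, t_c = t_c),
                 seed_gene_score = unname(g_raw_scaled[seed_id]),
                 converged = converged,
                 iterations = it),
            class = "isa_module")
}

#' @export
print.isa_module <- function(x, ...) {
  cat(sprintf("isa_module '%s': %d genes, %d time points (t_g=%.2f, t_c=%.2f, seed score %.3f%s)\n",
              x$stage_label, length(x$genes), length(x$time_points),
              x$threshold_pair["t_g"], x$threshold_pair["t_c"],
              x$seed_gene_score, if (x$converged) "" else ", NOT converged"))
  invisible(x)
}

#' Resolve module overlaps into disjoint gene sets
#'
#' A gene belonging to several modules is kept in the one where its ISA
#' gene score is largest; exact score ties go to the earlier stage in
#' developmental order. The count of genes that had to be reassigned (were
#' members of two or more modules) is recorded in the `n_reassigned`
#' attribute.
#'
#' @param modules list of `isa_module`s in developmental order.
#' @return the list with overlapping genes removed from all but one module.
#' @export
resolve_overlaps <- function(modules) {
  modules <- Filter(Negate(is.null), modules)
  tab <- do.call(rbind, lapply(seq_along(modules), function(k) {
    m <- modules[[k]]
    if (!length(m$genes)) return(NULL)
    data.frame(gene = m$genes, module = k, score = unname(m$gene_scores[m$genes]),
               stringsAsFactors = FALSE)
  }))
  n_reassigned <- 0L
  if (!is.null(tab)) {
    dup_genes <- unique(tab$gene[duplicated(tab$gene)])
    n_reassigned <- length(dup_genes)
    for (g in dup_genes) {
      rows <- tab[tab$gene == g, ]
      # max score wins; ties go to the earliest module (stable order)
      winner <- rows$module[which.max(rows$score)]
      for (k in setdiff(rows$module, winner)) {
        m <- modules[[k]]
        m$genes <- setdiff(m$genes, g)
        m$gene_scores <- m$gene_scores[m$genes]
        modules[[k]] <- m
      }
    }
  }
  attr(modules, "n_reassigned") <- n_reassigned
  modules
}

#' Fit stage-specific transcription modules with the seeded ISA
#'
#' The central fitting function. For each of the seven (by default) stage
#' windows an artificial boxcar expression profile seeds the ISA; each seed
#' is run once per threshold pair, and per stage the module in which the
#' seed profile attained the higher gene score is retained. Overlapping
#' genes are then resolved to the module where their gene score is largest,
#' yielding disjoint stage modules.
#'
#' @param m numeric matrix (genes x time points) or a time-point level
#'   [expr_matrix()]; typically the output of [normalize_chain()].
#' @param stage_windows data.frame defining the seeds; defaults to
#'   [default_stage_windows()] over the matrix's time axis.
#' @param threshold_pairs list of `c(t_g, t_c)` pairs; the ISA is run once
#'   per pair.
#' @param max_iterations,convergence_overlap see [isa_iterate()].
#' @param resolve resolve overlaps into disjoint modules.
#' @return an object of class `isa_fit`: a list with `modules` (disjoint,
#'   in developmental order), `selected_pair` per stage, `missing` stage
#'   labels with no module, and `n_reassigned`.
#' @export
find_modules <- function(m, stage_windows = NULL,
                         threshold_pairs = list(c(2.5, 2.0), c(2.0, 2.0)),
                         max_iterations = 100L, convergence_overlap = 0.99,
                         resolve = TRUE) {
  if (inherits(m, "expr_matrix")) {
    vals <- m$values[!m$is_spike, , drop = FALSE]
    colnames(vals) <- paste0("t", m$meta$stage)
  } else vals <- as.matrix(m)
  if (is.null(stage_windows)) stage_windows <- default_stage_windows(ncol(vals))
  seeds <- seed_profiles(stage_windows, ncol(vals))

  per_stage <- vector("list", length(seeds))
  names(per_stage) <- names(seeds)
  selected_pair <- stats::setNames(rep(NA_integer_, length(seeds)), names(seeds))
  for (k in seq_along(seeds)) {
    runs <- lapply(threshold_pairs, function(tp)
      suppressWarnings(isa_iterate(vals, seeds[[k]], t_g = tp[1], t_c = tp[2],
                                   max_iterations = max_iterations,
                                   convergence_overlap = convergence_overlap,
                                   stage_label = names(seeds)[k])))
    ok <- !vapply(runs, is.null, TRUE)
    if (!any(ok)) next
    scores <- vapply(runs, function(r) if (is.null(r)) -Inf else r$seed_gene_score, 0)
    best <- which.max(scores)
    per_stage[[k]] <- runs[[best]]
    selected_pair[k] <- best
  }
  missing <- names(per_stage)[vapply(per_stage, is.null, TRUE)]
  modules <- Filter(Negate(is.null), per_stage)
  n_reassigned <- 0L
  if (resolve) {
    modules <- resolve_overlaps(modules)
    n_reassigned <- attr(modules, "n_reassigned")
  }
  structure(list(modules = modules, selected_pair = selected_pair,
                 missing = missing, n_reassigned = n_reassigned,
                 threshold_pairs = threshold_pairs,
                 stage_windows = stage_windows),
            class = "isa_fit")
}

#' @export
print.isa_fit <- function(x, ...) {
  cat(sprintf("isa_fit: %d stage modules (%d genes total, %d reassigned from overlaps)\n",
              length(x$modules), sum(lengths(lapply(x$modules, `[[`, "genes"))),
              x$n_reassigned))
  if (length(x$missing))
    cat("  missing stages:", paste(x$missing, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.isa_fit <- function(object, ...) {
  df <- do.call(rbind, lapply(object$modules, function(m) {
    data.frame(stage = m$stage_label,
               n_genes = length(m$genes),
               n_time_points = length(m$time_points),
               t_g = unname(m$threshold_pair["t_g"]),
               t_c = unname(m$threshold_pair["t_c"]),
               seed_score = m$seed_gene_score,
               converged = m$converged,
               stringsAsFactors = FALSE)
  }))
  rownames(df) <- NULL
  df
}

#' @export
plot.isa_fit <- function(x, ...) {
  n <- length(x$modules)
  if (!n) stop("no modules to plot")
  tp_max <- max(unlist(lapply(x$modules, `[[`, "time_points")))
  graphics::plot(NULL, xlim = c(1, tp_max), ylim = c(0.5, n + 0.5),
                 xlab = "time point", ylab = "", yaxt = "n",
                 main = "ISA module time-point scores", ...)
  graphics::axis(2, at = seq_len(n),
                 labels = vapply(x$modules, `[[`, "", "stage_label"), las = 1)
  for (k in seq_len(n)) {
    m <- x$modules[[k]]
    graphics::segments(m$time_points, k - 0.4 * m$condition_scores,
                       m$time_points, k + 0.4 * m$condition_scores, lwd = 3)
  }
  invisible(x)
}

#' Per-stage module gene lists as plain-text files
#'
#' @param fit an `isa_fit`.
#' @param dir output directory (created if needed).
#' @return invisibly, the written paths.
#' @export
write_module_gene_lists <- function(fit, dir) {
  stopifnot(inherits(fit, "isa_fit"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(fit$modules, function(m) {
    p <- file.path(dir, paste0("module_", m$stage_label, ".txt"))
    writeLines(m$genes, p)
    p
  }, "")
  invisible(paths)
}
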