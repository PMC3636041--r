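#' Log10-transform a raw-intensity expression matrix
#'
#' @param x an [expr_matrix()] on the linear scale with strictly positive
#'   values.
#' @return the matrix with elementwise log10 values and the scale flag set.
#' @export
log10_transform <- function(x) {
  stopifnot(inherits(x, "expr_matrix"))
  if (x$log_scale) stop("matrix is already on the log10 scale")
  bad <- which(x$values <= 0, arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("nonpositive intensity for gene '%s' on array %d",
                 rownames(x$values)[bad[1L, 1L]], bad[1L, 2L]))
  }
  x$values <- log10(x$values)
  x$log_scale <- TRUE
  x
}

#' Quantile normalization
#'
#' Forces every column to the same distribution: the per-rank mean of the
#' input columns. Tied values receive the mean of their ranks' reference
#' values. Rank order within each column is preserved.
#'
#' @param m numeric matrix (columns are arrays).
#' @return matrix of the same shape.
#' @export
quantile_normalize <- function(m) {
  m <- as.matrix(m)
  if (ncol(m) < 1L || nrow(m) < 1L) stop("empty matrix")
  limma::normalizeQuantiles(m, ties = TRUE)
}

#' Piecewise-linear intensity map anchored on spike-in medians
#'
#' @param x,y ordered anchor coordinates; `x` must be strictly increasing
#'   after sorting. Values beyond the terminal anchors are mapped by
#'   extending the first/last segment's slope linearly.
#' @return an object of class `pw_map`.
#' @export
pw_map <- function(x, y) {
  o <- order(x)
  x <- x[o]; y <- y[o]
  if (anyDuplicated(x)) {          # coincident anchors: average their y
    y <- as.numeric(tapply(y, match(x, unique(x)), mean))
    x <- unique(x)
  }
  if (length(x) < 2L) stop("piecewise map undefined: <2 distinct anchor x values")
  if (is.unsorted(y))
    warning("non-monotone anchors: interpolating anyway")
  structure(list(x = x, y = y), class = "pw_map")
}

#' Apply a piecewise-linear map to values
#' @param map a [pw_map()].
#' @param v numeric values.
#' @export
pw_apply <- function(map, v) {
  x <- map$x; y <- map$y
  n <- length(x)
  out <- stats::approx(x, y, xout = v, rule = 2, ties = "ordered")$y
  lo <- v < x[1L]
  hi <- v > x[n]
  if (any(lo)) {
    s <- (y[2L] - y[1L]) / (x[2L] - x[1L])
    out[lo] <- y[1L] + s * (v[lo] - x[1L])
  }
  if (any(hi)) {
    s <- (y[n] - y[n - 1L]) / (x[n] - x[n - 1L])
    out[hi] <- y[n] + s * (v[hi] - x[n])
  }
  out
}

# spike-in level per spike row, parsed from ids SPIKE_L<level>_<probe>
.spike_levels <- function(ids) {
  lv <- sub("^SPIKE_L([0-9]+)_.*$", "\\1", ids)
  as.integer(lv)
}

#' Build per-array spike-in equalization maps
#'
#' Separately for each replicate series, the spike-in rows of all arrays in
#' the series are quantile normalized; for each spike-in level and each
#' array the anchor is (median signal before, median signal after)
#' normalization. Linear interpolation between the anchors defines the
#' per-array correction curve.
#'
#' @param x a log10-scale [expr_matrix()] containing spike-in rows.
#' @return list of [pw_map()]s, one per array (column).
#' @export
build_spikein_maps <- function(x) {
  stopifnot(inherits(x, "expr_matrix"), x$log_scale)
  if (!any(x$is_spike)) stop("no spike-in rows in the matrix")
  spikes <- x$values[x$is_spike, , drop = FALSE]
  levels <- .spike_levels(rownames(spikes))
  if (length(unique(levels)) < 2L) stop("need >=2 spike-in levels")
  maps <- vector("list", ncol(spikes))
  for (r in unique(x$meta$replicate)) {
    cols <- which(x$meta$replicate %in% r)
    before <- spikes[, cols, drop = FALSE]
    after <- quantile_normalize(before)
    for (j in seq_along(cols)) {
      ax <- tapply(before[, j], levels, stats::median)
      ay <- tapply(after[, j], levels, stats::median)
      maps[[cols[j]]] <- pw_map(as.numeric(ax), as.numeric(ay))
    }
  }
  maps
}

#' Apply per-array maps to every value of the matrix
#'
#' @param x a log10-scale [expr_matrix()].
#' @param maps list of [pw_map()]s, one per column.
#' @export
apply_maps <- function(x, maps) {
  stopifnot(inherits(x, "expr_matrix"), length(maps) == ncol(x$values))
  for (j in seq_along(maps)) x$values[, j] <- pw_apply(maps[[j]], x$values[, j])
  x
}

# mean columns of an expr_matrix over groups; returns new expr_matrix
.average_columns <- function(x, group, new_meta) {
  vals <- x$values
  g <- factor(group, levels = unique(group))
  out <- do.call(cbind, lapply(levels(g), function(l)
    rowMeans(vals[, g == l, drop = FALSE])))
  dimnames(out) <- list(rownames(vals), levels(g))
  em <- expr_matrix(out, new_meta$stage, new_meta$replicate, new_meta$sex,
                    is_spike = x$is_spike, log_scale = x$log_scale)
  em
}

#' Average replicate arrays per (stage, sex)
#'
#' Arithmetic mean on the stored scale. Errors if a (stage, sex) group does
#' not contain one array per replicate series, listing the orphan arrays.
#' @param x an [expr_matrix()] with replicate metadata.
#' @export
average_replicates <- function(x) {
  stopifnot(inherits(x, "expr_matrix"))
  if (all(is.na(x$meta$replicate))) stop("no replicate metadata present")
  key <- paste(x$meta$stage, ifelse(is.na(x$meta$sex), "U", x$meta$sex), sep = "|")
  n_rep <- length(unique(x$meta$replicate))
  sizes <- table(key)
  orphan <- names(sizes)[sizes != n_rep]
  if (length(orphan))
    stop("missing replicate partner for array group(s): ",
         paste(orphan, collapse = ", "))
  first <- !duplicated(key)
  meta <- data.frame(stage = x$meta$stage[first],
                     replicate = NA_integer_,
                     sex = x$meta$sex[first], stringsAsFactors = FALSE)
  .average_columns(x, key, meta)
}

#' Average male and female arrays per stage
#'
#' Applied only to sex-split stages; unsexed columns pass through.
#' @param x an [expr_matrix()] (typically after [average_replicates()]).
#' @export
average_sexes <- function(x) {
  stopifnot(inherits(x, "expr_matrix"))
  key <- paste0("s", x$meta$stage)
  first <- !duplicated(key)
  meta <- data.frame(stage = x$meta$stage[first], replicate = NA_integer_,
                     sex = NA_character_, stringsAsFactors = FALSE)
  .average_columns(x, key, meta)
}

#' The full normalization chain
#'
#' log10 transform, spike-in-anchored between-array equalization (computed
#' separately per replicate series), quantile normalization of the gene
#' rows within replicates, replicate averaging, and sex averaging. Each
#' step can be toggled; steps are logged to standard error.
#'
#' @param x a raw-scale [expr_matrix()].
#' @param log10 take log10 first.
#' @param spikein_equalize build and apply the spike-in piecewise-linear maps.
#' @param quantile_within_replicates quantile normalize gene rows within each
#'   replicate series.
#' @param avg_replicates,avg_sexes averaging steps.
#' @param drop_spikes drop spike-in rows from the result.
#' @param verbose log each step with array counts.
#' @return an [expr_matrix()]; with all steps on, one column per stage.
#' @export
normalize_chain <- function(x, log10 = TRUE, spikein_equalize = TRUE,
                            quantile_within_replicates = TRUE,
                            avg_replicates = TRUE, avg_sexes = TRUE,
                            drop_spikes = TRUE, verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  if (log10) {
    x <- log10_transform(x)
    say("log10 transform: %d arrays", ncol(x$values))
  }
  if (spikein_equalize) {
    maps <- build_spikein_maps(x)
    x <- apply_maps(x, maps)
    say("spike-in equalization: %d maps applied", length(maps))
  }
  if (quantile_within_replicates) {
    for (r in unique(x$meta$replicate)) {
      cols <- which(x$meta$replicate %in% r)
      x$values[!x$is_spike, cols] <-
        quantile_normalize(x$values[!x$is_spike, cols, drop = FALSE])
    }
    say("quantile normalization within %d replicate series",
        length(unique(x$meta$replicate)))
  }
  if (avg_replicates) {
    x <- average_replicates(x)
    say("replicate averaging: %d columns", ncol(x$values))
  }
  if (avg_sexes) {
    x <- average_sexes(x)
    say("sex averaging: %d time points", ncol(x$values))
  }
  if (drop_spikes) {
    keep <- !x$is_spike
    x$values <- x$values[keep, , drop = FALSE]
    x$is_spike <- x$is_spike[keep]
  }
  x
}
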