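#' Expression matrix container
#'
#' A light S3 container for a gene x array (or gene x time-point) intensity
#' matrix together with per-array metadata (developmental stage index,
#' replicate id, sex) and per-row spike-in flags.
#'
#' @param values numeric matrix, genes as rows (rownames are gene ids),
#'   arrays/time points as columns.
#' @param stage integer vector, stage index per column.
#' @param replicate integer vector or NA, replicate id per column.
#' @param sex character vector per column: `"F"`, `"M"` or `NA` for arrays
#'   not split by sex.
#' @param is_spike logical vector per row flagging spike-in control rows.
#' @param log_scale logical flag: are the values log10 intensities?
#' @return An object of class `expr_matrix`.
#' @export
expr_matrix <- function(values, stage, replicate = NA_integer_, sex = NA_character_,
                        is_spike = NULL, log_scale = FALSE) {
  values <- as.matrix(values)
  if (is.null(rownames(values))) stop("'values' must have gene ids as rownames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene ids: ", paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  nc <- ncol(values)
  stage <- rep_len(as.integer(stage), nc)
  replicate <- rep_len(as.integer(replicate), nc)
  sex <- rep_len(as.character(sex), nc)
  if (is.null(is_spike)) is_spike <- rep(FALSE, nrow(values))
  stopifnot(length(is_spike) == nrow(values))
  meta <- data.frame(stage = stage, replicate = replicate, sex = sex,
                     stringsAsFactors = FALSE)
  colnames(values) <- .encode_array_labels(meta)
  structure(
    list(values = values,
         meta = meta,
         is_spike = as.logical(is_spike),
         log_scale = isTRUE(log_scale)),
    class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes (+%d spike-in rows) x %d arrays [%s scale]\n",
              sum(!x$is_spike), sum(x$is_spike), ncol(x$values),
              if (x$log_scale) "log10" else "linear"))
  cat(sprintf("  stages %d..%d; replicates: %s; sex-split arrays: %d\n",
              min(x$meta$stage), max(x$meta$stage),
              paste(sort(unique(stats::na.omit(x$meta$replicate))), collapse = ","),
              sum(!is.na(x$meta$sex))))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

# column label encoding used in the TSV dialect: s<stage>_r<rep>_<sex>
.encode_array_labels <- function(meta) {
  sex <- ifelse(is.na(meta$sex), "U", meta$sex)
  rep <- ifelse(is.na(meta$replicate), "0", meta$replicate)
  sprintf("s%02d_r%s_%s", meta$stage, rep, sex)
}

.decode_array_labels <- function(labels) {
  m <- regmatches(labels, regexec("^s([0-9]+)_r([0-9]+)_([FMU])$", labels))
  bad <- vapply(m, length, 1L) != 4L
  if (any(bad))
    stop("malformed array header label(s): ", paste(labels[bad], collapse = ", "))
  stage <- as.integer(vapply(m, `[`, "", 2L))
  repl <- as.integer(vapply(m, `[`, "", 3L))
  sex <- vapply(m, `[`, "", 4L)
  data.frame(stage = stage,
             replicate = ifelse(repl == 0L, NA_integer_, repl),
             sex = ifelse(sex == "U", NA_character_, sex),
             stringsAsFactors = FALSE)
}

#' Write / read the expression matrix TSV dialect
#'
#' Tab-delimited, genes as rows; first column `gene_id`; remaining column
#' names encode the array metadata triplet as `s<stage>_r<replicate>_<sex>`
#' (replicate `0` and sex `U` mean "not applicable"). Spike-in rows are
#' recognized on read by an id prefix.
#'
#' @param x an `expr_matrix`.
#' @param path file path.
#' @rdname expression_tsv
#' @export
write_expression_tsv <- function(x, path) {
  stopifnot(inherits(x, "expr_matrix"))
  df <- data.frame(gene_id = rownames(x$values), x$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[-1] <- .encode_array_labels(x$meta)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @param spike_prefix gene-id prefix marking spike-in rows.
#' @param log_scale whether the stored values are log10 intensities.
#' @rdname expression_tsv
#' @export
read_expression_tsv <- function(path, spike_prefix = "SPIKE", log_scale = FALSE) {
  lines <- readLines(path)
  if (length(lines) < 2L) stop("empty expression table body: ", path)
  nfield <- lengths(regmatches(lines, gregexpr("\t", lines))) + 1L
  if (any(nfield != nfield[1L]))
    stop("ragged row(s) at line(s): ",
         paste(which(nfield != nfield[1L]), collapse = ", "))
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop("duplicate gene id(s): ", paste(dup, collapse = ", "))
  }
  vals <- as.matrix(df[, -1L, drop = FALSE])
  rownames(vals) <- ids
  meta <- .decode_array_labels(colnames(vals))
  expr_matrix(vals, meta$stage, meta$replicate, meta$sex,
              is_spike = startsWith(ids, spike_prefix), log_scale = log_scale)
}

#' Aggregate probe-level rows to gene level
#'
#' Probes mapping ambiguously (one probe listed for several genes) are
#' dropped with a message; genes measured by several probes get the mean
#' signal across their probes.
#'
#' @param values numeric matrix with probe ids as rownames.
#' @param map data.frame with columns `probe_id`, `gene_id`.
#' @return numeric matrix with gene ids as rownames.
#' @export
aggregate_probes <- function(values, map) {
  values <- as.matrix(values)
  if (nrow(map) == 0L) stop("empty probe-to-gene mapping")
  stopifnot(all(c("probe_id", "gene_id") %in% names(map)))
  ambiguous <- unique(map$probe_id[duplicated(map$probe_id)])
  if (length(ambiguous)) {
    message(length(ambiguous), " ambiguous probe(s) dropped")
    map <- map[!map$probe_id %in% ambiguous, , drop = FALSE]
  }
  map <- map[map$probe_id %in% rownames(values), , drop = FALSE]
  if (nrow(map) == 0L) stop("no probe in the mapping matches the matrix")
  sub <- values[map$probe_id, , drop = FALSE]
  out <- rowsum(sub, group = map$gene_id)
  counts <- table(map$gene_id)
  out / as.vector(counts[rownames(out)])
}
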