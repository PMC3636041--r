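#' Read / write 4-column BED (0-based, half-open)
#' @param path file path.
#' @rdname bed_io
#' @export
read_bed <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stop("BED needs at least 3 columns")
  names(df)[1:3] <- c("chrom", "start", "end")
  if (ncol(df) >= 4L) names(df)[4L] <- "name"
  df
}

#' @param bed data.frame with `chrom`, `start`, `end` and optionally `name`.
#' @rdname bed_io
#' @export
write_bed <- function(bed, path) {
  cols <- intersect(c("chrom", "start", "end", "name"), names(bed))
  utils::write.table(bed[, cols, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write plain-text gene lists (one id per line)
#' @param path file path.
#' @rdname gene_list_io
#' @export
read_gene_list <- function(path) {
  x <- readLines(path)
  x[nzchar(x)]
}

#' @param genes character vector of gene ids.
#' @rdname gene_list_io
#' @export
write_gene_list <- function(genes, path) {
  writeLines(genes, path)
  invisible(path)
}

#' Read a time-point to metastage mapping table
#'
#' Tab-delimited with columns `stage` (time-point index) and `metastage`;
#' unmapped time points may be absent or empty.
#' @param path file path.
#' @param n_stages length of the time axis.
#' @return character vector of length `n_stages` (`NA` where unmapped).
#' @export
read_metastage_map <- function(path, n_stages) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("stage", "metastage") %in% names(df)))
  out <- rep(NA_character_, n_stages)
  ok <- df$stage >= 1 & df$stage <= n_stages & nzchar(df$metastage)
  out[df$stage[ok]] <- df$metastage[ok]
  out
}

#' Default metastage assignment for a simulated time axis
#'
#' Maps the beginning of the axis to zygote/cleavage/blastula, the
#' mid-development windows to neurula and organogenesis, and the rest to
#' the post-embryonic metastage.
#' @param n_stages length of the time axis.
#' @export
default_metastage_map <- function(n_stages = 60L) {
  b <- as.integer(floor(cumsum(c(0.02, 0.06, 0.14, 0.26, 0.50, 1.00)) * n_stages))
  b[1L] <- max(b[1L], 1L)
  out <- character(n_stages)
  lab <- c("zygote", "cleavage", "blastula", "neurula", "organogenesis",
           "post-embryonic")
  prev <- 0L
  for (k in seq_along(b)) {
    if (b[k] > prev) out[(prev + 1L):b[k]] <- lab[k]
    prev <- max(prev, b[k])
  }
  out
}

#' Run the whole analysis pipeline on simulated (or supplied) data
#'
#' Composes the stages in order: simulation (or a supplied raw matrix),
#' normalization, seeded ISA module detection, the TAI audit, and the
#' cross-module statistics battery. Deterministic given the config seed.
#'
#' @param config a [sim_config()].
#' @param raw optional raw [expr_matrix()] to use instead of simulating
#'   expression (annotations are still simulated from the config).
#' @param run_stats compute the cross-module statistics.
#' @param n_samples randomization samples for the median omega test.
#' @param alpha significance level.
#' @param verbose log stages to standard error.
#' @return an object of class `devmod_pipeline`: list with `fit` (the
#'   [find_modules()] result), `normalized`, `tai` (raw/log10 profiles),
#'   `stats` (per-module tests), `truth`, `annotation` and `provenance`.
#' @export
run_pipeline <- function(config = sim_config(), raw = NULL, run_stats = TRUE,
                         n_samples = 10000L, alpha = 0.01, verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  sim <- simulate_timecourse(config)
  if (!is.null(raw)) sim$matrix <- raw
  say("simulated %d x %d raw matrix", nrow(sim$matrix$values), ncol(sim$matrix$values))
  ann <- simulate_annotations(sim$truth, config)
  norm <- normalize_chain(sim$matrix, verbose = verbose)
  fit <- find_modules(norm, stage_windows = config$stage_windows)
  say("ISA: %d modules, %d genes reassigned", length(fit$modules), fit$n_reassigned)

  ranks <- stats::setNames(match(ann$annotation$age_class,
                                 names(config$annotation_model$background$age_probs)),
                           ann$annotation$gene_id)
  lin <- 10^norm$values
  tai <- list(raw = compute_tai(lin, ranks, "raw"),
              log10 = compute_tai(lin, ranks, "log10"))

  stats_out <- NULL
  if (run_stats) {
    omega <- stats::setNames(ann$annotation$omega, ann$annotation$gene_id)
    ages <- stats::setNames(ann$annotation$age_class, ann$annotation$gene_id)
    orth <- stats::setNames(ann$annotation$orthology_class, ann$annotation$gene_id)
    universe <- ann$annotation$gene_id
    mods <- stats::setNames(lapply(fit$modules, `[[`, "genes"),
                            vapply(fit$modules, `[[`, "", "stage_label"))
    fam <- length(mods)
    stats_out <- list()
    for (nm in names(mods)) {
      g <- mods[[nm]]
      stats_out[[nm]] <- list(
        omega = randomization_median_test(omega, g, n_samples = n_samples,
                                          alpha = alpha, family = fam,
                                          module_label = nm),
        age = tryCatch(chisq_gof(g, ages, family = fam, module_label = nm),
                       error = function(e) e),
        orthology = tryCatch(chisq_gof(g, orth, family = fam, module_label = nm),
                             error = function(e) e),
        tf = hypergeom_enrichment(g, universe[ann$annotation$is_tf], universe,
                                  family = fam, module_label = nm),
        hcne = hypergeom_enrichment(g, universe[ann$annotation$hcne_count > 0],
                                    universe, family = fam, module_label = nm),
        tfr = hypergeom_enrichment(g, universe[ann$annotation$has_tfr], universe,
                                   family = fam, module_label = nm))
    }
    say("statistics computed for %d modules", length(mods))
  }

  structure(list(fit = fit, normalized = norm, tai = tai, stats = stats_out,
                 truth = sim$truth, annotation = ann,
                 provenance = list(rng_seed = config$rng_seed,
                                   n_genes = config$n_genes,
                                   n_stages = config$n_stages,
                                   n_samples = n_samples, alpha = alpha,
                                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))),
            class = "devmod_pipeline")
}

#' @export
print.devmod_pipeline <- function(x, ...) {
  cat("devmod_pipeline\n")
  print(x$fit)
  cat(sprintf("  normalized matrix: %d genes x %d time points\n",
              nrow(x$normalized$values), ncol(x$normalized$values)))
  if (!is.null(x$stats))
    cat(sprintf("  statistics: %d modules x %d tests\n",
                length(x$stats), length(x$stats[[1L]])))
  invisible(x)
}

#' Write a pipeline result bundle to a directory
#'
#' Emits the module gene lists, a module summary TSV, the TAI profiles,
#' a JSON file of the statistical tests, and a provenance JSON.
#' @param x a `devmod_pipeline`.
#' @param dir output directory.
#' @export
write_pipeline_bundle <- function(x, dir) {
  stopifnot(inherits(x, "devmod_pipeline"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_module_gene_lists(x$fit, file.path(dir, "modules"))
  utils::write.table(summary(x$fit), file.path(dir, "modules_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (nm in names(x$tai))
    utils::write.table(as.data.frame(x$tai[[nm]]),
                       file.path(dir, paste0("tai_", nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(x$stats)) {
    flat <- lapply(x$stats, function(tests)
      lapply(tests, function(t) {
        if (inherits(t, "error")) return(list(error = conditionMessage(t)))
        list(statistic = t$statistic, p_raw = t$p_raw,
             p_bonferroni = t$p_bonferroni, n_used = t$n_used)
      }))
    jsonlite::write_json(flat, file.path(dir, "stats.json"), auto_unbox = TRUE,
                         digits = NA)
  }
  jsonlite::write_json(x$provenance, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}
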