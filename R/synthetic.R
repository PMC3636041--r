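#' Simulation configuration for a developmental expression time course
#'
#' Encodes the design of the emulated experiment: a log-normal intensity
#' time course over `n_stages` developmental stages, measured in
#' `n_replicates` replicate series, with the terminal `n_sex_split_stages`
#' stages measured separately per sex, a ladder of `spike_in_levels`
#' spike-in control levels shared by all arrays, and seven stage windows in
#' which planted modules of genes are overexpressed by an additive log10
#' shift.
#'
#' @param n_genes number of (non-spike-in) genes.
#' @param n_stages number of developmental stages on the time axis.
#' @param n_replicates replicate series per array.
#' @param n_sex_split_stages terminal stages measured separately for males
#'   and females.
#' @param spike_in_levels number of spike-in concentration levels.
#' @param spike_rows_per_level spike-in probes per level.
#' @param spike_ladder log10 intensities of the levels; defaults to an even
#'   ladder in log10 space.
#' @param stage_windows data.frame with columns `stage_label`, `start`,
#'   `end` (1-based, inclusive stage indices); windows must be disjoint and
#'   ordered. Defaults to seven windows covering the axis.
#' @param module_sizes integer vector, one planted module size per window.
#' @param overexpression_effect additive log10 shift of planted genes
#'   inside their window.
#' @param baseline_mean,baseline_sd log10-scale Gaussian parameters of the
#'   per-gene baseline intensity.
#' @param noise_sd log10-scale Gaussian measurement noise sd.
#' @param sex_effect additive log10 offset between male and female arrays
#'   of the sex-split stages.
#' @param array_effects list with `enabled`, `slope_range`, `offset_range`,
#'   `center`: each array distorts the log10 signal by `a*x + b`; when
#'   `center` is TRUE the slopes/offsets are centred within each replicate
#'   series (mean slope 1, mean offset 0).
#' @param annotation_model per-module class probabilities and effect sizes
#'   for the annotation generator; see [default_annotation_model()].
#' @param rng_seed integer seed making the whole simulation reproducible.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000L,
                       n_stages = 60L,
                       n_replicates = 2L,
                       n_sex_split_stages = 10L,
                       spike_in_levels = 10L,
                       spike_rows_per_level = 5L,
                       spike_ladder = NULL,
                       stage_windows = NULL,
                       module_sizes = rep(100L, 7L),
                       overexpression_effect = 0.5,
                       baseline_mean = 2.0,
                       baseline_sd = 0.5,
                       noise_sd = 0.25,
                       sex_effect = 0.05,
                       array_effects = list(enabled = TRUE,
                                            slope_range = c(0.9, 1.1),
                                            offset_range = c(-0.2, 0.2),
                                            center = TRUE),
                       annotation_model = default_annotation_model(),
                       rng_seed = 1L) {
  if (is.null(stage_windows)) stage_windows <- default_stage_windows(n_stages)
  if (is.null(spike_ladder))
    spike_ladder <- seq(0.5, 4.5, length.out = spike_in_levels)
  stopifnot(n_stages >= 2L, n_replicates >= 1L,
            n_sex_split_stages >= 0L, n_sex_split_stages <= n_stages,
            spike_in_levels >= 2L,
            length(spike_ladder) == spike_in_levels,
            length(module_sizes) == nrow(stage_windows),
            noise_sd >= 0, baseline_sd >= 0)
  w <- stage_windows
  if (any(w$start > w$end) || any(w$start < 1L) || any(w$end > n_stages))
    stop("stage window outside the time axis")
  if (is.unsorted(w$start, strictly = TRUE) || any(w$start[-1L] <= w$end[-nrow(w)]))
    stop("stage windows must be ordered and disjoint")
  if (sum(module_sizes) > n_genes)
    stop("module sizes sum exceeds n_genes")
  .validate_annotation_model(annotation_model, w$stage_label)
  structure(list(n_genes = as.integer(n_genes), n_stages = as.integer(n_stages),
                 n_replicates = as.integer(n_replicates),
                 n_sex_split_stages = as.integer(n_sex_split_stages),
                 spike_in_levels = as.integer(spike_in_levels),
                 spike_rows_per_level = as.integer(spike_rows_per_level),
                 spike_ladder = spike_ladder,
                 stage_windows = w,
                 module_sizes = as.integer(module_sizes),
                 overexpression_effect = overexpression_effect,
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 noise_sd = noise_sd, sex_effect = sex_effect,
                 array_effects = array_effects,
                 annotation_model = annotation_model,
                 rng_seed = as.integer(rng_seed)),
            class = "sim_config")
}

#' Default seven stage windows covering the time axis
#'
#' Labels follow the canonical zebrafish periods; boundaries split the axis
#' roughly as in a 60-stage egg-to-adult course (early periods short, adult
#' long).
#' @param n_stages length of the time axis (>= 14).
#' @export
default_stage_windows <- function(n_stages = 60L) {
  props <- c(0.13, 0.10, 0.13, 0.13, 0.17, 0.17, 0.17)
  end <- as.integer(floor(cumsum(props) * n_stages))
  end[7L] <- as.integer(n_stages)
  start <- c(1L, end[-7L] + 1L)
  if (any(start > end)) stop("n_stages too small for seven windows")
  data.frame(stage_label = c("cleavage_blastula", "gastrula", "segmentation",
                             "pharyngula", "larva", "juvenile", "adult"),
             start = start, end = end, stringsAsFactors = FALSE)
}

#' Default per-module annotation model
#'
#' Class probabilities for the five gene-age classes and four orthology
#' classes, a transcription-factor probability, a mean Poisson rate of
#' upstream conserved non-coding elements (HCNEs), a transposon-free-region
#' probability, and log-normal parameters of the per-gene mean dN/dS
#' (omega). The `background` entry describes unplanted genes; module
#' entries skew the classes in the directions expected for genes expressed
#' in the corresponding period (older genes early, younger genes and
#' duplicates late, more transcription factors and regulatory conservation
#' mid-development).
#' @export
default_annotation_model <- function() {
  age_classes <- c("Fungi/Metazoa", "Bilateria", "Coelomata+Chordata",
                   "Euteleostomi", "Clupeocephala+Danio rerio")
  orth_classes <- c("one-to-one", "one-to-many", "many-to-many", "none")
  mk <- function(age, orth, tf, hcne, tfr, mlog) {
    list(age_probs = stats::setNames(age, age_classes),
         orthology_probs = stats::setNames(orth, orth_classes),
         tf_prob = tf, hcne_lambda = hcne, tfr_prob = tfr,
         omega_meanlog = mlog, omega_sdlog = 0.5)
  }
  bg_age <- c(0.257, 0.344, 0.120, 0.180, 0.099)
  bg_orth <- c(0.454, 0.303, 0.039, 0.204)
  list(
    background = mk(bg_age, bg_orth, 0.067, 0.05, 0.10, log(0.15)),
    cleavage_blastula = mk(bg_age, c(0.546, 0.250, 0.030, 0.174),
                           0.067, 0.05, 0.10, log(0.15)),
    gastrula = mk(c(0.367, 0.310, 0.100, 0.150, 0.073), bg_orth,
                  0.067, 0.05, 0.10, log(0.12)),
    segmentation = mk(c(0.220, 0.455, 0.095, 0.140, 0.090), bg_orth,
                      0.120, 0.20, 0.20, log(0.14)),
    pharyngula = mk(c(0.190, 0.521, 0.080, 0.130, 0.079), bg_orth,
                    0.120, 0.25, 0.25, log(0.12)),
    larva = mk(c(0.210, 0.300, 0.100, 0.257, 0.133),
               c(0.330, 0.456, 0.050, 0.164), 0.067, 0.05, 0.10, log(0.12)),
    juvenile = mk(c(0.180, 0.250, 0.090, 0.351, 0.129),
                  c(0.300, 0.214, 0.104, 0.382), 0.067, 0.03, 0.08, log(0.20)),
    adult = mk(c(0.180, 0.250, 0.080, 0.356, 0.134),
               c(0.300, 0.238, 0.078, 0.384), 0.067, 0.03, 0.08, log(0.18)),
    omega_missing_prob = 0.2)
}

.validate_annotation_model <- function(model, stage_labels) {
  needed <- c("background", stage_labels)
  missing <- setdiff(needed, names(model))
  if (length(missing))
    stop("annotation model lacks entries for: ", paste(missing, collapse = ", "))
  for (nm in needed) {
    m <- model[[nm]]
    for (p in list(m$age_probs, m$orthology_probs)) {
      if (any(p < 0) || any(p > 1) || abs(sum(p) - 1) > 1e-8)
        stop("class probabilities for '", nm, "' must lie in [0,1] and sum to 1")
    }
    if (m$tf_prob < 0 || m$tf_prob > 1 || m$tfr_prob < 0 || m$tfr_prob > 1 ||
        m$hcne_lambda < 0)
      stop("invalid rates for '", nm, "'")
  }
  invisible(TRUE)
}

.array_design <- function(config) {
  plain <- config$n_stages - config$n_sex_split_stages
  rows <- list()
  for (s in seq_len(config$n_stages)) {
    sexes <- if (s > plain) c("F", "M") else NA_character_
    for (r in seq_len(config$n_replicates))
      for (sx in sexes)
        rows[[length(rows) + 1L]] <- data.frame(stage = s, replicate = r,
                                                sex = sx, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Simulate a raw per-array expression time course with planted modules
#'
#' Generates one intensity column per (stage, replicate[, sex]) array.
#' Gene baselines are log-normal; genes planted in a module get an additive
#' log10 shift inside their stage window (a boxcar profile). Spike-in rows
#' carry an array-independent intensity ladder. Each array optionally
#' distorts the log10 signal by a monotone affine map, and Gaussian log10
#' noise is added per measurement. Fully reproducible from the config seed.
#'
#' @param config a [sim_config()].
#' @return list with `matrix` (a raw-scale [expr_matrix()]) and `truth`
#'   (planted membership, spike-in truth, per-array affine effects).
#' @export
simulate_timecourse <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$rng_seed)
  design <- .array_design(config)
  n_arr <- nrow(design)
  gene_ids <- sprintf("g%05d", seq_len(config$n_genes))

  membership <- rep(NA_character_, config$n_genes)
  idx <- 1L
  for (k in seq_along(config$module_sizes)) {
    sz <- config$module_sizes[k]
    if (sz > 0L) {
      membership[idx:(idx + sz - 1L)] <- config$stage_windows$stage_label[k]
      idx <- idx + sz
    }
  }
  names(membership) <- gene_ids

  baseline <- stats::rnorm(config$n_genes, config$baseline_mean, config$baseline_sd)
  in_window <- matrix(0, config$n_genes, config$n_stages)
  for (k in seq_along(config$module_sizes)) {
    w <- config$stage_windows[k, ]
    rows <- which(membership == w$stage_label)
    if (length(rows)) in_window[rows, w$start:w$end] <- 1
  }

  # clean (pre-distortion) log10 signal per gene x array
  signal <- baseline + config$overexpression_effect * in_window[, design$stage, drop = FALSE]
  sex_off <- ifelse(is.na(design$sex), 0,
                    ifelse(design$sex == "M", config$sex_effect / 2,
                           -config$sex_effect / 2))
  signal <- sweep(signal, 2L, sex_off, `+`)

  spike_ids <- sprintf("SPIKE_L%02d_%02d",
                       rep(seq_len(config$spike_in_levels), each = config$spike_rows_per_level),
                       rep(seq_len(config$spike_rows_per_level), config$spike_in_levels))
  spike_truth <- rep(config$spike_ladder, each = config$spike_rows_per_level)
  spike_signal <- matrix(spike_truth, length(spike_ids), n_arr)

  full <- rbind(signal, spike_signal)
  rownames(full) <- c(gene_ids, spike_ids)
  if (config$noise_sd > 0)
    full <- full + matrix(stats::rnorm(length(full), 0, config$noise_sd),
                          nrow(full), n_arr)

  ae <- config$array_effects
  if (isTRUE(ae$enabled)) {
    a <- stats::runif(n_arr, ae$slope_range[1], ae$slope_range[2])
    b <- stats::runif(n_arr, ae$offset_range[1], ae$offset_range[2])
    if (isTRUE(ae$center)) {
      for (r in unique(design$replicate)) {
        j <- design$replicate == r
        a[j] <- a[j] / mean(a[j])
        b[j] <- b[j] - mean(b[j])
      }
    }
    full <- sweep(sweep(full, 2L, a, `*`), 2L, b, `+`)
  } else {
    a <- rep(1, n_arr); b <- rep(0, n_arr)
  }

  mat <- expr_matrix(10^full, design$stage, design$replicate, design$sex,
                     is_spike = c(rep(FALSE, config$n_genes), rep(TRUE, length(spike_ids))),
                     log_scale = FALSE)
  truth <- list(planted_membership = membership,
                baseline_log10 = stats::setNames(baseline, gene_ids),
                spike_in_true_levels = stats::setNames(config$spike_ladder,
                                                       sprintf("L%02d", seq_len(config$spike_in_levels))),
                array_slope = a, array_offset = b,
                stage_windows = config$stage_windows)
  list(matrix = mat, truth = truth)
}

#' Sample per-gene evolutionary annotations with planted module effects
#'
#' Draws age class, orthology class, transcription-factor flag, mean dN/dS
#' (omega, log-normal; missing for a configurable fraction of genes),
#' upstream-HCNE count (Poisson) and transposon-free-region flag per gene,
#' using the per-module probabilities of the annotation model. Also lays
#' genes out on synthetic chromosomes and emits an HCNE interval table
#' (BED, 0-based half-open) placed inside each gene's upstream window so
#' that window counting recovers the sampled counts, a gene-TFR
#' association table, and planted gene-list files (maternal-like,
#' post-MBT-like, Hox-like, core-developmental-like sets drawn from the
#' corresponding planted modules).
#'
#' @param truth the `truth` element of [simulate_timecourse()].
#' @param config the same [sim_config()].
#' @param upstream_bp upstream window the HCNE intervals are placed in.
#' @return list with `annotation`, `tss`, `hcne_bed`, `tfr`, `gene_lists`.
#' @export
simulate_annotations <- function(truth, config, upstream_bp = 500L) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$rng_seed + 7919L)
  membership <- truth$planted_membership
  genes <- names(membership)
  model <- config$annotation_model
  labels <- ifelse(is.na(membership), "background", membership)
  unknown <- setdiff(unique(labels), names(model))
  if (length(unknown))
    stop("unknown stage label(s) in membership: ", paste(unknown, collapse = ", "))

  n <- length(genes)
  age <- character(n); orth <- character(n); tf <- logical(n)
  omega <- numeric(n); hcne <- integer(n); tfr <- logical(n)
  for (lab in unique(labels)) {
    i <- which(labels == lab)
    m <- model[[lab]]
    age[i] <- sample(names(m$age_probs), length(i), TRUE, m$age_probs)
    orth[i] <- sample(names(m$orthology_probs), length(i), TRUE, m$orthology_probs)
    tf[i] <- stats::runif(length(i)) < m$tf_prob
    omega[i] <- stats::rlnorm(length(i), m$omega_meanlog, m$omega_sdlog)
    hcne[i] <- stats::rpois(length(i), m$hcne_lambda)
    tfr[i] <- stats::runif(length(i)) < m$tfr_prob
  }
  miss <- stats::runif(n) < model$omega_missing_prob
  omega[miss] <- NA_real_

  # synthetic gene layout: 25 chromosomes, genes 10 kb apart, alternating strand
  chrom <- paste0("chr", ((seq_len(n) - 1L) %% 25L) + 1L)
  tss <- 10000L * (((seq_len(n) - 1L) %/% 25L) + 1L)
  strand <- rep(c("+", "-"), length.out = n)
  tss_tab <- data.frame(gene_id = genes, chrom = chrom, tss = tss,
                        strand = strand, stringsAsFactors = FALSE)

  # place hcne[i] intervals of width 50 inside the upstream window
  cap <- max(1L, upstream_bp %/% 60L)
  hcne <- pmin(hcne, cap)
  bed <- NULL
  has <- which(hcne > 0L)
  if (length(has)) {
    reps <- hcne[has]
    gi <- rep(has, reps)
    k <- unlist(lapply(reps, seq_len))
    off <- (k - 1L) * 60L
    start0 <- ifelse(strand[gi] == "+", tss[gi] - upstream_bp + off, tss[gi] + off)
    bed <- data.frame(chrom = chrom[gi], start = start0, end = start0 + 50L,
                      name = sprintf("hcne_%05d", seq_along(gi)),
                      stringsAsFactors = FALSE)
  } else {
    bed <- data.frame(chrom = character(), start = integer(), end = integer(),
                      name = character(), stringsAsFactors = FALSE)
  }

  tfr_tab <- data.frame(gene_id = genes[tfr],
                        tfr_id = sprintf("tfr_%05d", seq_len(sum(tfr))),
                        stringsAsFactors = FALSE)

  pick <- function(lab, frac, cap = Inf) {
    g <- genes[labels == lab]
    if (!length(g)) return(character())
    sample(g, min(length(g), cap, max(1L, round(frac * length(g)))))
  }
  gene_lists <- list(maternal = pick("cleavage_blastula", 0.5),
                     post_mbt = pick("gastrula", 0.5),
                     hox = pick("segmentation", 0.25, cap = 24L),
                     core_dev = pick("pharyngula", 0.25))

  ann <- data.frame(gene_id = genes,
                    module = labels,
                    age_class = age,
                    orthology_class = orth,
                    omega = omega,
                    is_tf = tf,
                    hcne_count = hcne,
                    has_tfr = tfr,
                    stringsAsFactors = FALSE)
  list(annotation = ann, tss = tss_tab, hcne_bed = bed, tfr = tfr_tab,
       gene_lists = gene_lists)
}

#' Simulate the transcriptome-age-index confound of raw intensity weights
#'
#' Builds a time course in which a handful of very highly expressed young
#' genes dominate the raw-intensity weights in early and late development,
#' while the underlying log-scale signal has old genes broadly more
#' expressed early. Raw-weighted TAI then dips in mid-development (an
#' hourglass-like shape) although the log-weighted TAI increases from early
#' to mid development — the transformation-sensitivity the TAI audit
#' demonstrates.
#'
#' @param n_genes background genes.
#' @param n_stages stages.
#' @param n_confound very highly expressed young genes.
#' @param noise_sd log10 measurement noise.
#' @param rng_seed seed.
#' @return list: `values` (linear intensities), `ranks` (phylostratum per
#'   gene), `early`, `mid`, `late` (stage index sets).
#' @export
simulate_tai_confound <- function(n_genes = 2000L, n_stages = 60L,
                                  n_confound = 20L, noise_sd = 0.05,
                                  rng_seed = 1L) {
  set.seed(rng_seed)
  third <- n_stages %/% 3L
  early <- seq_len(third)
  mid <- (third + 1L):(2L * third)
  late <- (2L * third + 1L):n_stages
  ranks <- sample(1:10, n_genes, TRUE)
  old <- ranks <= 3L
  # old genes are broadly more expressed early; the boost fades out within
  # the first third so mid-development carries none of it
  decay <- pmax(0, 1 - (seq_len(n_stages) - 1L) / third)
  logv <- matrix(2, n_genes, n_stages)
  logv[old, ] <- 2 + 0.5 * matrix(decay, sum(old), n_stages, byrow = TRUE)
  conf <- matrix(1, n_confound, n_stages)
  conf[, early] <- 5
  conf[, late] <- 5
  logv <- rbind(logv, conf)
  ranks <- c(ranks, rep(10L, n_confound))
  if (noise_sd > 0)
    logv <- logv + matrix(stats::rnorm(length(logv), 0, noise_sd),
                          nrow(logv), n_stages)
  rownames(logv) <- sprintf("g%05d", seq_len(nrow(logv)))
  names(ranks) <- rownames(logv)
  list(values = 10^logv, ranks = ranks, early = early, mid = mid, late = late)
}
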