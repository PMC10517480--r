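#' Simulation configuration
#'
#' Parameters of the mechanistic cfMeDIP-seq cohort simulator. The model
#' encodes how methylation shapes fragmentation: windows carry a methylation
#' level `m` in \[0, 1\]; fragments released from a window are "short"
#' (100-150 bp) with probability `pi_base + kappa * (1 - m)` (plus `gamma`
#' for tumor-derived fragments), so hypomethylated, accessible chromatin
#' yields more sub-mononucleosomal fragments. Each fragment carries a
#' methylated flag; 5mC immunoprecipitation retains methylated fragments
#' with probability `p_cap` and unmethylated ones with `p_bg`. Short
#' fragments, being products of digestion within accessible nucleosomes,
#' are hypomethylated at the fragment level: their methylated-flag
#' probability is `lambda_short * m` (see the methods vignette for the
#' calibration of `lambda_short`).
#'
#' @param layout Genome layout; default two 10-Mb chromosomes.
#' @param window_bp Methylation window size in bp (default 10 kb).
#' @param n_healthy,n_cancer Samples per cohort (default 3 and 3).
#' @param n_input Fragments per Input library (default 200,000).
#' @param mu_short,sd_short Truncated-normal parameters of the short
#'   (sub-mononucleosomal) size component on \[100, 150\] bp.
#' @param mu_long,sd_long Parameters of the long (mononucleosomal) component
#'   on \[151, 220\] bp; the ~167 bp mode is the mononucleosomal peak.
#' @param pi_base Baseline short-fragment probability.
#' @param kappa Methylation-to-short coupling: short probability rises by
#'   `kappa * (1 - m)`.
#' @param gamma Global short-fraction boost of tumor-derived fragments.
#' @param tumor_fraction Probability that a cancer-sample fragment is
#'   tumor-derived.
#' @param delta_hypo,delta_hyper Planted effect sizes: hypomethylated windows
#'   get `m' = m * (1 - delta_hypo)`, hypermethylated windows
#'   `m' = min(1, m + delta_hyper * (1 - m))`.
#' @param n_hypo,n_hyper Numbers of planted hypo-/hypermethylated windows.
#' @param p_cap,p_bg IP capture probability of methylated / unmethylated
#'   fragments.
#' @param lambda_short Fragment-level hypomethylation of short fragments:
#'   a short fragment from a window with methylation `m` is methylated with
#'   probability `lambda_short * m` (long fragments: `m`).
#' @param beta_shape1,beta_shape2 Beta parameters of the healthy per-window
#'   methylation distribution (default Beta(8, 2), mean 0.8).
#' @param size_range Analysis size range in bp.
#' @param short_max Largest length counted as "short" (150 bp; 151 bp is
#'   "long").
#' @param seed Base random seed; sample `i` of a cohort uses stream
#'   `seed + i` so runs are reproducible sample-by-sample.
#' @return A `sim_config` object (validated list).
#' @export
sim_config <- function(layout = genome_layout(c(chr1 = 1e7, chr2 = 1e7)),
                       window_bp = 10000L,
                       n_healthy = 3L, n_cancer = 3L,
                       n_input = 200000L,
                       mu_short = 135, sd_short = 10,
                       mu_long = 167, sd_long = 12,
                       pi_base = 0.145, kappa = 0.15, gamma = 0.02,
                       tumor_fraction = 0.2,
                       delta_hypo = 0.5, delta_hyper = 0.4,
                       n_hypo = 200L, n_hyper = 200L,
                       p_cap = 0.8, p_bg = 0.05,
                       lambda_short = 0.7,
                       beta_shape1 = 8, beta_shape2 = 2,
                       size_range = c(100L, 220L), short_max = 150L,
                       seed = 1L) {
  cfg <- list(layout = layout, window_bp = as.integer(window_bp),
              n_healthy = as.integer(n_healthy), n_cancer = as.integer(n_cancer),
              n_input = as.integer(n_input),
              mu_short = mu_short, sd_short = sd_short,
              mu_long = mu_long, sd_long = sd_long,
              pi_base = pi_base, kappa = kappa, gamma = gamma,
              tumor_fraction = tumor_fraction,
              delta_hypo = delta_hypo, delta_hyper = delta_hyper,
              n_hypo = as.integer(n_hypo), n_hyper = as.integer(n_hyper),
              p_cap = p_cap, p_bg = p_bg, lambda_short = lambda_short,
              beta_shape1 = beta_shape1, beta_shape2 = beta_shape2,
              size_range = as.integer(size_range),
              short_max = as.integer(short_max),
              seed = as.integer(seed))
  probs <- c(pi_base, kappa, gamma, tumor_fraction, delta_hypo, delta_hyper,
             p_cap, p_bg, lambda_short)
  if (any(probs < 0 | probs > 1))
    stop("all probabilities must lie in [0, 1]")
  if (pi_base + kappa + gamma > 1)
    stop("pi_base + kappa + gamma must not exceed 1")
  if (cfg$n_input <= 0) stop("n_input must be positive")
  structure(cfg, class = "sim_config")
}

#' Strong-effect simulation preset
#'
#' A high tumor-burden, deeply sequenced configuration emulating newly
#' diagnosed, untreated patients: a compact genome (2 x 2.5 Mb, 500 windows)
#' sequenced to 500,000 Input fragments per sample, tumor fraction 0.7,
#' near-complete demethylation of planted hypo windows (`delta_hypo = 0.9`)
#' and stronger methylation-fragmentation coupling (`kappa = 0.25`). Chosen
#' by power analysis so planted hypomethylated windows reach |log2FC| > 1 in
#' IP counts and per-window ratio profiles are estimated precisely enough
#' for correlation-based classification (see the methods vignette).
#'
#' @param ... Overrides passed to [sim_config()] (e.g. `n_healthy`,
#'   `n_cancer`, `seed`).
#' @return A `sim_config`.
#' @export
strong_effect_config <- function(...) {
  defaults <- list(layout = genome_layout(c(chr1 = 2.5e6, chr2 = 2.5e6)),
                   n_input = 500000L, n_hypo = 60L, n_hyper = 60L,
                   tumor_fraction = 0.7, delta_hypo = 0.9, kappa = 0.25)
  over <- list(...)
  do.call(sim_config, utils::modifyList(defaults, over))
}

#' Build the per-window methylation landscape
#'
#' Draws healthy methylation levels `m_w ~ Beta(shape1, shape2)` per window,
#' picks disjoint sets of planted hypo- and hypermethylated windows
#' uniformly at random, and derives the tumor state `m'_w` (lower exactly on
#' the hypo set, higher exactly on the hyper set, equal elsewhere).
#'
#' @param cfg A [sim_config()].
#' @return A `methylation_landscape`: `m`, `m_tumor` (numeric per window),
#'   `hypo`, `hyper` (integer window indices), and the [window_grid()] used.
#' @export
build_landscape <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  grid <- window_grid(cfg$layout, cfg$window_bp)
  W <- grid$n_windows
  if (cfg$n_hypo + cfg$n_hyper > W)
    stop("planted window counts exceed total windows")
  set.seed(cfg$seed)
  m <- stats::rbeta(W, cfg$beta_shape1, cfg$beta_shape2)
  planted <- sample.int(W, cfg$n_hypo + cfg$n_hyper)
  hypo <- sort(planted[seq_len(cfg$n_hypo)])
  hyper <- sort(planted[cfg$n_hypo + seq_len(cfg$n_hyper)])
  m_tumor <- m
  m_tumor[hypo] <- m[hypo] * (1 - cfg$delta_hypo)
  m_tumor[hyper] <- pmin(1, m[hyper] + cfg$delta_hyper * (1 - m[hyper]))
  structure(list(m = m, m_tumor = m_tumor, hypo = hypo, hyper = hyper,
                 grid = grid),
            class = "methylation_landscape")
}

#' @export
print.methylation_landscape <- function(x, ...) {
  cat("<methylation_landscape> ", length(x$m), " windows; ",
      length(x$hypo), " planted hypo, ", length(x$hyper),
      " planted hyper; mean m = ", round(mean(x$m), 3), "\n", sep = "")
  invisible(x)
}

# integer truncated-normal lengths on [lo, hi]: continuous truncated normal
# on [lo, hi + 1) then floor
rtrunc_len <- function(n, mu, sd, lo, hi) {
  if (n == 0) return(integer(0))
  plo <- stats::pnorm(lo, mu, sd)
  phi <- stats::pnorm(hi + 1, mu, sd)
  as.integer(pmin(hi, pmax(lo, floor(stats::qnorm(
    stats::runif(n, plo, phi), mu, sd)))))
}

#' Draw the Input library of one simulated sample
#'
#' Generates `n_input` fragments. Each fragment picks a source window
#' uniformly; in cancer samples it is tumor-derived with probability
#' `tumor_fraction` (methylation state `m'`) and otherwise healthy-derived
#' (`m`). The fragment is short with probability
#' `clip(pi_base + kappa * (1 - m_source) + gamma * tumor, 0, 1)`; lengths
#' come from the truncated-normal mixture; starts are uniform within the
#' window subject to the fragment lying inside the chromosome; barcodes are
#' unique serial strings. The methylated flag is Bernoulli with probability
#' `m_source` for long fragments and `lambda_short * m_source` for short
#' ones. Latent labels (source window, tumor origin, methylated, short) are
#' retained for testing.
#'
#' @param cfg A [sim_config()].
#' @param landscape A [build_landscape()] result.
#' @param group `"healthy"` or `"cancer"`.
#' @param sample_id Sample name.
#' @param seed Seed for this sample's stream; `NULL` continues the current
#'   RNG state.
#' @return A `simulated_sample` with the Input [fragment_set()], a `latent`
#'   data.frame aligned row-by-row, and `ip = NULL` until
#'   [apply_ip_capture()] is called.
#' @export
sample_input_fragments <- function(cfg, landscape, group = c("healthy", "cancer"),
                                   sample_id = "S1", seed = NULL) {
  stopifnot(inherits(cfg, "sim_config"),
            inherits(landscape, "methylation_landscape"))
  group <- match.arg(group)
  if (!is.null(seed)) set.seed(seed)
  n <- cfg$n_input
  grid <- landscape$grid
  win <- sample.int(grid$n_windows, n, replace = TRUE)
  tumor <- if (group == "cancer")
    stats::runif(n) < cfg$tumor_fraction else rep(FALSE, n)
  m_src <- ifelse(tumor, landscape$m_tumor[win], landscape$m[win])
  p_short <- pmin(1, pmax(0, cfg$pi_base + cfg$kappa * (1 - m_src) +
                            cfg$gamma * tumor))
  short <- stats::runif(n) < p_short
  len <- integer(n)
  len[short] <- rtrunc_len(sum(short), cfg$mu_short, cfg$sd_short,
                           cfg$size_range[1], cfg$short_max)
  len[!short] <- rtrunc_len(sum(!short), cfg$mu_long, cfg$sd_long,
                            cfg$short_max + 1L, cfg$size_range[2])
  w <- grid$windows[win, ]
  chr_len <- cfg$layout$length[match(w$chrom, cfg$layout$chrom)]
  lo <- w$start
  hi <- pmin(w$end - 1L, chr_len - len)
  start <- as.integer(lo + floor(stats::runif(n) * (hi - lo + 1)))
  p_meth <- ifelse(short, cfg$lambda_short * m_src, m_src)
  methylated <- stats::runif(n) < p_meth
  input <- fragment_set(
    data.frame(chrom = w$chrom, start = start, end = start + len,
               barcode = sprintf("%s-%07d", sample_id, seq_len(n)),
               stringsAsFactors = FALSE),
    sample_id = sample_id, library = "INPUT", dedup_applied = TRUE
  )
  latent <- data.frame(window = win, tumor = tumor, short = short,
                       methylated = methylated)
  structure(list(sample_id = sample_id, group = group, input = input,
                 ip = NULL, latent = latent, ip_kept = NULL),
            class = "simulated_sample")
}

#' Apply 5mC immunoprecipitation capture
#'
#' Thins the Input molecule pool per fragment: a methylated fragment is
#' retained in the IP library with probability `p_cap`, an unmethylated one
#' with `p_bg`. Retained IP records share coordinates and barcodes with
#' their Input molecules (the paired Input/IP design).
#'
#' @param sample A `simulated_sample` with the Input part generated.
#' @param cfg The [sim_config()] used to generate it.
#' @return The sample with `ip` filled in and `ip_kept` (logical per Input
#'   molecule).
#' @export
apply_ip_capture <- function(sample, cfg) {
  stopifnot(inherits(sample, "simulated_sample"), inherits(cfg, "sim_config"))
  p <- ifelse(sample$latent$methylated, cfg$p_cap, cfg$p_bg)
  kept <- stats::runif(nrow(sample$latent)) < p
  sample$ip <- fragment_set(sample$input$records[kept, , drop = FALSE],
                            sample$sample_id, "IP", dedup_applied = TRUE)
  sample$ip_kept <- kept
  sample
}

#' @export
print.simulated_sample <- function(x, ...) {
  cat("<simulated_sample> ", x$sample_id, " (", x$group, "): ",
      format(n_fragments(x$input), big.mark = ","), " Input fragments",
      if (!is.null(x$ip))
        paste0(", ", format(n_fragments(x$ip), big.mark = ","), " IP"),
      "\n", sep = "")
  invisible(x)
}

# simulate one sample end to end on its own seeded stream
simulate_sample <- function(cfg, landscape, group, sample_id, index) {
  s <- sample_input_fragments(cfg, landscape, group, sample_id,
                              seed = cfg$seed + index)
  apply_ip_capture(s, cfg)
}

#' Simulate a paired Input/IP cohort
#'
#' Generates `n_healthy` healthy samples (H1, H2, ...) and `n_cancer` cancer
#' samples (P1, P2, ...), each with paired Input and IP fragment sets, from
#' one shared methylation landscape. Sample `i` uses the seeded stream
#' `seed + i`, so cohorts are reproducible and samples independent.
#'
#' @param cfg A [sim_config()].
#' @param landscape Optional pre-built [build_landscape()] result, e.g. to
#'   share one landscape between discovery and validation cohorts. Built
#'   from `cfg` when `NULL`.
#' @param index_offset Offset added to sample stream indices, so a second
#'   cohort drawn on the same landscape uses fresh streams.
#' @return A `sim_cohort`: list with `config`, `landscape` and `samples`
#'   (list of `simulated_sample`).
#' @export
simulate_cohort <- function(cfg, landscape = NULL, index_offset = 0L) {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.null(landscape)) landscape <- build_landscape(cfg)
  groups <- c(rep("healthy", cfg$n_healthy), rep("cancer", cfg$n_cancer))
  ids <- c(sprintf("H%d", seq_len(cfg$n_healthy)),
           sprintf("P%d", seq_len(cfg$n_cancer)))
  samples <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    samples[[i]] <- simulate_sample(cfg, landscape, groups[i], ids[i],
                                    index = index_offset + i)
  }
  names(samples) <- ids
  structure(list(config = cfg, landscape = landscape, samples = samples),
            class = "sim_cohort")
}

#' Write a simulated cohort to disk
#'
#' Writes one fragment TSV per library
#' (`<sample>_{input,ip}.fragments.tsv`), a ground-truth manifest JSON
#' (planted windows, per-sample latent summaries) and, when the yaml package
#' is available, the configuration as YAML.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "sim_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  grid <- cohort$landscape$grid
  for (s in cohort$samples) {
    write_fragment_table(s$input, file.path(dir,
      paste0(s$sample_id, "_input.fragments.tsv")))
    write_fragment_table(s$ip, file.path(dir,
      paste0(s$sample_id, "_ip.fragments.tsv")))
  }
  manifest <- list(
    seed = cohort$config$seed,
    window_bp = cohort$config$window_bp,
    chromosomes = as.list(stats::setNames(cohort$config$layout$length,
                                          cohort$config$layout$chrom)),
    planted_hypo = grid$windows$id[cohort$landscape$hypo],
    planted_hyper = grid$windows$id[cohort$landscape$hyper],
    samples = lapply(cohort$samples, function(s) list(
      sample_id = s$sample_id, group = s$group,
      n_input = n_fragments(s$input), n_ip = n_fragments(s$ip),
      n_tumor = sum(s$latent$tumor), n_short = sum(s$latent$short),
      n_methylated = sum(s$latent$methylated)))
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (requireNamespace("yaml", quietly = TRUE)) {
    cfg <- cohort$config
    cfg$layout <- as.list(stats::setNames(cfg$layout$length, cfg$layout$chrom))
    yaml::write_yaml(unclass(cfg), file.path(dir, "config.yaml"))
  }
  invisible(dir)
}
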