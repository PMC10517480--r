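#' Window-by-sample IP count matrix
#'
#' Deduplicated, size-filtered IP fragment counts per genome window
#' (midpoint assignment), the input to differential-methylation calling.
#' Windows with zero counts everywhere are retained until filtering.
#'
#' @param samples List of `sample_summary` objects (see
#'   [summarize_sample()]), or list of IP [fragment_set()]s together with
#'   `groups`.
#' @param grid The [window_grid()] the samples were summarized on.
#' @param groups Character vector of `"healthy"`/`"cancer"` labels, required
#'   when `samples` are fragment sets (summaries carry their own).
#' @return A `count_matrix`: integer matrix windows x samples, window
#'   coordinate table, and per-sample group labels.
#' @export
build_count_matrix <- function(samples, grid, groups = NULL) {
  stopifnot(inherits(grid, "window_grid"))
  if (length(samples) == 0) stop("no samples given")
  if (inherits(samples[[1]], "sample_summary")) {
    ids <- vapply(samples, `[[`, character(1), "sample_id")
    groups <- vapply(samples, `[[`, character(1), "group")
    counts <- vapply(samples, function(s) s$win$short_ip + s$win$long_ip,
                     integer(grid$n_windows))
  } else {
    if (is.null(groups) || length(groups) != length(samples))
      stop("groups must be given, one per fragment set")
    ids <- vapply(samples, `[[`, character(1), "sample_id")
    counts <- vapply(samples, function(fs) {
      fs <- filter_size_range(if (fs$dedup_applied) fs else deduplicate(fs))
      idx <- window_index(fs$records$chrom, fs$records$start,
                          fs$records$end, grid)
      tabulate(idx, nbins = grid$n_windows)
    }, integer(grid$n_windows))
  }
  if (anyDuplicated(ids)) stop("duplicate sample ids: ",
                               paste(ids[duplicated(ids)], collapse = ", "))
  if (!all(groups %in% c("healthy", "cancer")))
    stop("groups must be 'healthy' or 'cancer'")
  dimnames(counts) <- list(grid$windows$id, ids)
  structure(list(counts = counts, windows = grid$windows,
                 groups = stats::setNames(groups, ids)),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("<count_matrix> ", nrow(x$counts), " windows x ", ncol(x$counts),
      " samples (", sum(x$groups == "cancer"), " cancer / ",
      sum(x$groups == "healthy"), " healthy)\n", sep = "")
  invisible(x)
}

#' Drop low-count windows
#'
#' Keeps windows whose mean count across all samples (both groups pooled) is
#' at least `min_mean` (default 10, i.e. windows with mean counts less than
#' 10 are filtered out).
#'
#' @param cm A [build_count_matrix()] result.
#' @param min_mean Minimum mean count.
#' @return Filtered `count_matrix`.
#' @export
filter_low_count_windows <- function(cm, min_mean = 10) {
  stopifnot(inherits(cm, "count_matrix"))
  keep <- rowMeans(cm$counts) >= min_mean
  structure(list(counts = cm$counts[keep, , drop = FALSE],
                 windows = cm$windows[keep, , drop = FALSE],
                 groups = cm$groups),
            class = "count_matrix")
}

#' Median-of-ratios size factors
#'
#' Per-sample normalization factor: the median, over windows with
#' all-positive counts, of the ratio of the sample's count to the window's
#' geometric mean across samples. No rescaling is applied beyond the
#' median-of-ratios definition.
#'
#' @param cm A `count_matrix`.
#' @param fallback_pseudo When no window has all-positive counts, compute the
#'   geometric-mean reference over positive counts only instead of erroring.
#' @return Named numeric vector of positive size factors, one per sample.
#' @export
estimate_size_factors <- function(cm, fallback_pseudo = FALSE) {
  stopifnot(inherits(cm, "count_matrix"))
  counts <- cm$counts
  if (ncol(counts) == 1) return(stats::setNames(1, colnames(counts)))
  all_pos <- rowSums(counts == 0) == 0
  if (!any(all_pos)) {
    if (!fallback_pseudo)
      stop("no window has all-positive counts; consider the pseudo-reference ",
           "fallback (fallback_pseudo = TRUE)")
    logg <- apply(counts, 1, function(y) mean(log(y[y > 0])))
    use <- is.finite(logg)
    ref <- exp(logg[use])
    sf <- apply(counts[use, , drop = FALSE], 2,
                function(y) stats::median((y / ref)[y > 0]))
  } else {
    sub <- counts[all_pos, , drop = FALSE]
    ref <- exp(rowMeans(log(sub)))
    sf <- apply(sub, 2, function(y) stats::median(y / ref))
  }
  if (any(!is.finite(sf) | sf <= 0))
    stop("size factor estimation failed (nonpositive factor)")
  sf
}

#' Negative-binomial Wald test per window
#'
#' For each window, counts are modeled as negative binomial with
#' sample-specific size factors as offsets and a cancer-vs-healthy group
#' effect on the log scale. The per-window dispersion is estimated by
#' method of moments on normalized counts, shrunk 50/50 toward a
#' mean-dispersion trend `a0 + a1/mu` fitted across windows, and floored at
#' 1e-8; the group effect is tested by a Wald z on the NB GLM fit with the
#' dispersion held fixed. The reported fold change is
#' `log2((mu_cancer + c0) / (mu_healthy + c0))` on normalized group means
#' with pseudocount `c0 = 0.5` to bound zero-count windows.
#'
#' @param cm A filtered `count_matrix`.
#' @param sf Size factors from [estimate_size_factors()].
#' @param pseudocount Pseudocount `c0` for the fold-change estimate.
#' @return data.frame with window id, coordinates, `baseMean` (mean
#'   normalized count), `log2fc` (cancer vs healthy), `dispersion`, `p`
#'   (two-sided Wald; `NA` when a group has a single sample or the fit
#'   fails).
#' @export
nb_window_test <- function(cm, sf, pseudocount = 0.5) {
  stopifnot(inherits(cm, "count_matrix"))
  counts <- cm$counts
  groups <- cm$groups[colnames(counts)]
  n_c <- sum(groups == "cancer"); n_h <- sum(groups == "healthy")
  if (n_c == 0 || n_h == 0)
    stop("both groups must be present (empty group: ",
         if (n_c == 0) "cancer" else "healthy", ")")
  if (!is.null(names(sf))) sf <- sf[colnames(counts)]
  if (length(sf) != ncol(counts) || any(!is.finite(sf) | sf <= 0))
    stop("size factors must be positive, one per sample")
  norm <- sweep(counts, 2, sf, "/")
  is_c <- groups == "cancer"
  mu_c <- rowMeans(norm[, is_c, drop = FALSE])
  mu_h <- rowMeans(norm[, !is_c, drop = FALSE])
  base_mean <- rowMeans(norm)
  log2fc <- log2((mu_c + pseudocount) / (mu_h + pseudocount))

  # method-of-moments dispersion: Var(y/s) ~ mu * mean(1/s) + alpha * mu^2
  xi <- mean(1 / sf)
  within_var <- function(x, grp) {
    v <- 0; df <- 0
    for (g in unique(grp)) {
      sub <- x[, grp == g, drop = FALSE]
      if (ncol(sub) >= 2) {
        v <- v + rowSums((sub - rowMeans(sub))^2)
        df <- df + ncol(sub) - 1
      }
    }
    if (df == 0) return(rep(NA_real_, nrow(x)))
    v / df
  }
  v_w <- within_var(norm, groups)
  alpha_raw <- (v_w - base_mean * xi) / base_mean^2
  alpha_raw[!is.finite(alpha_raw)] <- NA_real_
  alpha_mom <- pmax(alpha_raw, 0)
  # mean-dispersion trend alpha(mu) = a0 + a1 / mu, fitted across all
  # windows on the raw (unfloored) moment estimates so that pure sampling
  # noise averages out; coefficients floored at zero. Flat zero trend when
  # too few windows support the fit.
  trend <- rep(0, length(base_mean))
  fit_ok <- which(!is.na(alpha_raw) & base_mean > 0)
  if (length(fit_ok) >= 10) {
    co <- tryCatch(stats::coef(stats::lm(alpha_raw[fit_ok] ~ I(1 / base_mean[fit_ok]))),
                   error = function(e) c(0, 0))
    co[!is.finite(co)] <- 0
    co <- pmax(co, 0)
    trend <- co[1] + co[2] / pmax(base_mean, 1e-8)
  }
  dispersion <- pmax(1e-8, 0.5 * ifelse(is.na(alpha_mom), 0, alpha_mom) +
                       0.5 * trend)

  p <- rep(NA_real_, nrow(counts))
  if (n_c >= 2 && n_h >= 2) {
    X <- cbind(1, as.numeric(is_c))
    off <- log(sf)
    for (w in seq_len(nrow(counts))) {
      y <- counts[w, ]
      if (all(y == 0)) { p[w] <- 1; next }
      fam <- MASS::negative.binomial(theta = 1 / dispersion[w], link = "log")
      fit <- tryCatch(
        suppressWarnings(stats::glm.fit(X, y, offset = off, family = fam)),
        error = function(e) NULL)
      if (is.null(fit) || !fit$converged) next
      Wt <- fit$weights
      info <- crossprod(X, Wt * X)
      cov2 <- tryCatch(solve(info)[2, 2], error = function(e) NA_real_)
      if (!is.finite(cov2) || cov2 <= 0) next
      z <- fit$coefficients[2] / sqrt(cov2)
      p[w] <- 2 * stats::pnorm(-abs(z))
    }
  }
  data.frame(id = rownames(counts),
             chrom = cm$windows$chrom, start = cm$windows$start,
             end = cm$windows$end,
             baseMean = base_mean, log2fc = log2fc,
             dispersion = dispersion, p = p,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjusted p-values (monotone, capped at 1).
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Classify windows as hyper-/hypomethylated
#'
#' Adds BH-adjusted p-values and the DMR class: `HYPER` when
#' `padj < alpha` and `log2fc > lfc`, `HYPO` when `padj < alpha` and
#' `log2fc < -lfc`, otherwise `NONE`. With `use_padj = FALSE` the raw
#' p-value is thresholded instead (the mode used for cohorts analyzed
#' without the multiplicity adjustment).
#'
#' @param res Result of [nb_window_test()].
#' @param alpha Significance threshold (default 0.05).
#' @param lfc Absolute log2 fold-change threshold (default 1).
#' @param use_padj Threshold the BH-adjusted p-value (default) or the raw one.
#' @return `dmr_result` data.frame: the input plus `padj` and `class`.
#' @export
classify_dmrs <- function(res, alpha = 0.05, lfc = 1, use_padj = TRUE) {
  res$padj <- bh_adjust(res$p)
  crit <- if (use_padj) res$padj else res$p
  cls <- rep("NONE", nrow(res))
  sig <- !is.na(crit) & crit < alpha
  cls[sig & res$log2fc > lfc] <- "HYPER"
  cls[sig & res$log2fc < -lfc] <- "HYPO"
  res$class <- cls
  class(res) <- c("dmr_result", "data.frame")
  res
}

#' Call differentially methylated windows
#'
#' Convenience wrapper: low-count filtering, median-of-ratios size factors,
#' the negative-binomial Wald test and classification.
#'
#' @param cm A `count_matrix`.
#' @inheritParams filter_low_count_windows
#' @inheritParams classify_dmrs
#' @param fallback_pseudo Passed to [estimate_size_factors()].
#' @return A `dmr_result` data.frame over the retained windows.
#' @export
call_dmrs <- function(cm, min_mean = 10, alpha = 0.05, lfc = 1,
                      use_padj = TRUE, fallback_pseudo = FALSE) {
  cm <- filter_low_count_windows(cm, min_mean)
  if (nrow(cm$counts) == 0) stop("no windows pass the mean-count filter")
  sf <- estimate_size_factors(cm, fallback_pseudo = fallback_pseudo)
  classify_dmrs(nb_window_test(cm, sf), alpha = alpha, lfc = lfc,
                use_padj = use_padj)
}
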