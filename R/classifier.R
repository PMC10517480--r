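#' Healthy median baseline profile
#'
#' Per-window median of healthy samples' input-adjusted short fragments
#' ratios: the reference fragmentation profile that cancer samples deviate
#' from. Even sample counts take the mean of the two middle values.
#'
#' @param profiles An `adjusted_ratio_matrix` (samples x windows, see
#'   [build_profile_matrix()]).
#' @param healthy_ids Sample ids (row names) of the healthy contributors.
#' @return A `baseline_profile`: named numeric vector over the window set,
#'   with the contributing sample ids as attribute `samples`.
#' @export
healthy_median_baseline <- function(profiles, healthy_ids) {
  stopifnot(inherits(profiles, "adjusted_ratio_matrix"))
  if (length(healthy_ids) == 0) stop("at least one healthy sample is required")
  miss <- setdiff(healthy_ids, rownames(profiles))
  if (length(miss) > 0) stop("unknown sample id(s): ", paste(miss, collapse = ", "))
  b <- apply(profiles[healthy_ids, , drop = FALSE], 2, stats::median)
  structure(b, samples = healthy_ids, class = "baseline_profile")
}

#' Pearson correlation of a profile to the baseline
#'
#' The classifier score: standard Pearson correlation between a sample's
#' per-window adjusted-ratio profile and the healthy median baseline.
#' Requires at least 3 windows; with zero variance on either side the score
#' is undefined and flagged.
#'
#' @param profile Numeric vector of the sample's adjusted ratios, aligned
#'   with the baseline's windows.
#' @param baseline A [healthy_median_baseline()] result (or aligned numeric
#'   vector).
#' @return List with `r` (the correlation, `NA` when undefined) and
#'   `defined`.
#' @export
pearson_score <- function(profile, baseline) {
  if (length(profile) != length(baseline))
    stop("profile and baseline must have the same length")
  if (length(profile) < 3) stop("at least 3 windows are required")
  if (stats::sd(profile) == 0 || stats::sd(baseline) == 0)
    return(list(r = NA_real_, defined = FALSE))
  list(r = stats::cor(profile, as.numeric(baseline)), defined = TRUE)
}

#' Score all samples against a baseline
#'
#' @param profiles An `adjusted_ratio_matrix`.
#' @param baseline A [healthy_median_baseline()] result; required unless
#'   `leave_one_out` recomputes it.
#' @param leave_one_out Recompute the baseline without the scored sample
#'   when that sample is one of the healthy contributors (off by default:
#'   all healthy samples contribute to every baseline).
#' @param healthy_ids Healthy sample ids, needed for `leave_one_out`.
#' @return data.frame with `sample`, `group`, `r`.
#' @export
score_samples <- function(profiles, baseline = NULL, leave_one_out = FALSE,
                          healthy_ids = NULL) {
  stopifnot(inherits(profiles, "adjusted_ratio_matrix"))
  groups <- attr(profiles, "groups")
  if (is.null(healthy_ids)) healthy_ids <- names(groups)[groups == "healthy"]
  if (is.null(baseline))
    baseline <- healthy_median_baseline(profiles, healthy_ids)
  r <- vapply(rownames(profiles), function(id) {
    b <- if (leave_one_out && id %in% healthy_ids) {
      others <- setdiff(healthy_ids, id)
      if (length(others) == 0) stop("leave-one-out needs >= 2 healthy samples")
      healthy_median_baseline(profiles, others)
    } else baseline
    pearson_score(profiles[id, ], b)$r
  }, numeric(1))
  data.frame(sample = rownames(profiles),
             group = unname(groups[rownames(profiles)]),
             r = unname(r), stringsAsFactors = FALSE)
}

#' Classify a score against a cutoff
#'
#' Low correlation to the healthy baseline indicates cancer: the predicted
#' label is `"cancer"` when `r < cutoff` (strict), `"healthy"` otherwise.
#'
#' @param r Correlation score(s).
#' @param cutoff Decision threshold on r.
#' @return Character label(s).
#' @export
classify_score <- function(r, cutoff) {
  ifelse(r < cutoff, "cancer", "healthy")
}

#' Sensitivity/specificity at given cutoffs
#'
#' Sensitivity is the percentage of cancer samples with `r < cutoff`;
#' specificity the percentage of healthy samples with `r >= cutoff`.
#' Percentages are reported to one decimal.
#'
#' @param scores Numeric correlation scores.
#' @param labels `"healthy"`/`"cancer"` per score; both classes must be
#'   present.
#' @param cutoffs Cutoff values on r.
#' @return data.frame with `cutoff`, `sensitivity`, `specificity` (percent).
#' @export
cutoff_table <- function(scores, labels, cutoffs) {
  check_two_classes(labels)
  canc <- scores[labels == "cancer"]
  heal <- scores[labels == "healthy"]
  data.frame(
    cutoff = cutoffs,
    sensitivity = round(100 * vapply(cutoffs, function(t) mean(canc < t),
                                     numeric(1)), 1),
    specificity = round(100 * vapply(cutoffs, function(t) mean(heal >= t),
                                     numeric(1)), 1)
  )
}

check_two_classes <- function(labels) {
  if (!all(labels %in% c("healthy", "cancer")))
    stop("labels must be 'healthy' or 'cancer'")
  for (cls in c("healthy", "cancer"))
    if (!any(labels == cls)) stop("no '", cls, "' samples present")
  invisible(TRUE)
}

#' Choose the operating cutoff
#'
#' Maximizes sensitivity + specificity (Youden's J) over candidate cutoffs:
#' the midpoints between adjacent distinct observed scores plus one
#' candidate below the minimum and one above the maximum. Ties are broken
#' toward higher specificity, then toward the lower cutoff.
#'
#' @inheritParams cutoff_table
#' @return The selected cutoff on r.
#' @export
choose_cutoff <- function(scores, labels) {
  check_two_classes(labels)
  s <- sort(unique(scores))
  mids <- if (length(s) > 1) (s[-length(s)] + s[-1]) / 2 else numeric(0)
  cand <- c(s[1] - 1, mids, s[length(s)] + 1)
  canc <- scores[labels == "cancer"]; heal <- scores[labels == "healthy"]
  sens <- vapply(cand, function(t) mean(canc < t), numeric(1))
  spec <- vapply(cand, function(t) mean(heal >= t), numeric(1))
  j <- sens + spec
  best <- which(j >= max(j) - 1e-12)
  best <- best[spec[best] >= max(spec[best]) - 1e-12]
  cand[best[1]]   # candidates ascending: first = lowest cutoff
}

#' ROC curve and AUC
#'
#' Sweeps all thresholds of the rule "cancer if r < t" and computes the AUC
#' as the Mann-Whitney statistic `P(r_cancer < r_healthy) + 0.5 P(tie)`
#' (equivalently, the trapezoidal integral of the curve). Lower scores are
#' more cancer-like; cancer is the positive class.
#'
#' @inheritParams cutoff_table
#' @return A `roc_curve`: `points` data.frame (`cutoff`, `fpr` = 1 -
#'   specificity, `tpr` = sensitivity) ordered from (0, 0) to (1, 1), and
#'   `auc`.
#' @export
roc_auc <- function(scores, labels) {
  check_two_classes(labels)
  n_h <- sum(labels == "healthy"); n_c <- sum(labels == "cancer")
  rk <- rank(scores)   # ties get average ranks
  auc <- (sum(rk[labels == "healthy"]) - n_h * (n_h + 1) / 2) / (n_h * n_c)
  thr <- c(sort(unique(scores)), Inf)
  pts <- data.frame(
    cutoff = c(-Inf, thr),
    fpr = c(0, vapply(thr, function(t) mean(scores[labels == "healthy"] < t),
                      numeric(1))),
    tpr = c(0, vapply(thr, function(t) mean(scores[labels == "cancer"] < t),
                      numeric(1)))
  )
  structure(list(points = pts, auc = auc), class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat("<roc_curve> AUC = ", format(x$auc, digits = 4), " (",
      nrow(x$points), " points)\n", sep = "")
  invisible(x)
}

#' Stratified bootstrap confidence interval for the AUC
#'
#' Percentile interval from `n_boot` bootstrap replicates resampling within
#' each class.
#'
#' @inheritParams cutoff_table
#' @param n_boot Number of replicates (default 2000).
#' @param conf Confidence level.
#' @param seed Optional seed for the resampling.
#' @return Named vector `lower`, `upper`.
#' @export
auc_ci <- function(scores, labels, n_boot = 2000, conf = 0.95, seed = NULL) {
  check_two_classes(labels)
  if (!is.null(seed)) set.seed(seed)
  ih <- which(labels == "healthy"); ic <- which(labels == "cancer")
  reps <- vapply(seq_len(n_boot), function(b) {
    i <- c(sample(ih, replace = TRUE), sample(ic, replace = TRUE))
    roc_auc(scores[i], labels[i])$auc
  }, numeric(1))
  q <- stats::quantile(reps, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                       names = FALSE)
  c(lower = q[1], upper = q[2])
}
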