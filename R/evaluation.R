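# Sample- and event-based detection metrics, inter-rater agreement,
# inter-burst-interval summaries and paired statistical comparisons.

#' Sample-wise AUC of a continuous detector output
#'
#' Rank-based (Mann-Whitney) area under the ROC with midrank tie handling;
#' burst is the signal-of-interest. Undefined reference samples must be
#' excluded by the caller or are dropped here.
#'
#' @param d continuous scores.
#' @param reference per-sample labels (1/0/NA) or an `annotation`.
#' @return AUC in `[0, 1]`; `NA` with a warning if a class is absent.
#' @export
auc_samplewise <- function(d, reference) {
  if (inherits(reference, "annotation")) reference <- reference$labels
  keep <- !is.na(reference)
  d <- d[keep]; y <- reference[keep]
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == 0 || n0 == 0) {
    warning("AUC undefined: one class absent")
    return(NA_real_)
  }
  r <- rank(d)                      # midranks
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

confusion_counts <- function(detected, reference) {
  if (inherits(detected, "annotation")) detected <- detected$labels
  if (inherits(reference, "annotation")) reference <- reference$labels
  if (length(detected) != length(reference))
    stop("annotations have different lengths")
  keep <- !is.na(reference) & !is.na(detected)
  list(det = detected[keep], ref = reference[keep])
}

#' Time-based (per-sample) sensitivity and specificity
#'
#' Sensitivity over samples the reference labels burst, specificity over
#' samples it labels inter-burst; undefined samples excluded.
#'
#' @param detected,reference `annotation`s (or label vectors) of equal length.
#' @return named vector `c(sens =, spec =)` in percent.
#' @export
sens_spec_time <- function(detected, reference) {
  cc <- confusion_counts(detected, reference)
  nb <- sum(cc$ref == 1L); ni <- sum(cc$ref == 0L)
  sens <- if (nb == 0) { warning("no burst samples"); NA_real_ } else
    100 * sum(cc$det == 1L & cc$ref == 1L) / nb
  spec <- if (ni == 0) { warning("no inter-burst samples"); NA_real_ } else
    100 * sum(cc$det == 0L & cc$ref == 0L) / ni
  c(sens = sens, spec = spec)
}

#' Event-based sensitivity and specificity (75% coverage rule)
#'
#' A reference burst event counts as detected when strictly more than
#' `coverage` of its duration is labelled burst by the detector (coverage is
#' pooled across fragmented detections). Specificity applies the same rule to
#' reference inter-burst events. Duration-independent by construction.
#'
#' @param detected,reference `annotation`s of equal length and rate.
#' @param coverage required covered fraction (default 0.75, strict).
#' @return named vector `c(sens =, spec =)` in percent.
#' @export
sens_spec_event <- function(detected, reference, coverage = 0.75) {
  if (inherits(detected, "annotation")) detected <- detected$labels
  ref_a <- if (inherits(reference, "annotation")) reference else annotation(reference, 1)
  if (length(detected) != length(ref_a$labels))
    stop("annotations have different lengths")
  runs <- annotation_runs(ref_a)
  event_rate <- function(class) {
    ev <- runs[!is.na(runs$label) & runs$label == class, , drop = FALSE]
    if (!nrow(ev)) {
      warning("no reference events of class ", class)
      return(NA_real_)
    }
    hit <- vapply(seq_len(nrow(ev)), function(j) {
      idx <- (ev$start[j] + 1L):ev$end[j]
      mean(detected[idx] == class, na.rm = TRUE) > coverage
    }, TRUE)
    100 * mean(hit)
  }
  c(sens = event_rate(1L), spec = event_rate(0L))
}

#' Cohen's kappa with bias and prevalence indices
#'
#' Agreement between two per-sample annotations over their jointly defined
#' samples. From the 2x2 table (a = agreed bursts, d = agreed inter-bursts,
#' b/c = disagreements): kappa = (p_o - p_e)/(1 - p_e), bias index
#' `|b - c|/n`, prevalence index `|a - d|/n`.
#'
#' @param a1,a2 `annotation`s (or label vectors) of equal length.
#' @return named vector `c(kappa =, bias =, prevalence =)`.
#' @export
cohens_kappa <- function(a1, a2) {
  cc <- confusion_counts(a1, a2)
  n <- length(cc$ref)
  if (n == 0) stop("no jointly defined samples")
  a <- sum(cc$det == 1L & cc$ref == 1L)
  b <- sum(cc$det == 1L & cc$ref == 0L)
  cx <- sum(cc$det == 0L & cc$ref == 1L)
  dd <- sum(cc$det == 0L & cc$ref == 0L)
  po <- (a + dd) / n
  pe <- ((a + b) * (a + cx) + (cx + dd) * (b + dd)) / n^2
  kap <- if (pe == 1) {
    warning("kappa undefined: expected agreement is 1")
    NA_real_
  } else (po - pe) / (1 - pe)
  c(kappa = kap, bias = abs(b - cx) / n, prevalence = abs(a - dd) / n)
}

#' Inter-burst-interval summary measures
#'
#' Median and maximum duration of complete inter-burst intervals (segments
#' flanked by bursts on both sides; stretches truncated by the record edge or
#' by undefined samples are excluded, their true duration being unknown), and
#' the burst-to-inter-burst ratio: percent of defined time labelled burst.
#'
#' @param a an `annotation`.
#' @return list with `median_ibi_s`, `max_ibi_s`, `burst_ratio_pct`.
#' @export
ibi_summary <- function(a) {
  stopifnot(inherits(a, "annotation"))
  runs <- annotation_runs(a)
  k <- nrow(runs)
  ibis <- numeric(0)
  for (j in seq_len(k)) {
    if (is.na(runs$label[j]) || runs$label[j] != 0L) next
    if (j == 1 || j == k) next
    if (is.na(runs$label[j - 1]) || is.na(runs$label[j + 1])) next
    ibis <- c(ibis, runs$end_s[j] - runs$start_s[j])
  }
  nb <- sum(a$labels == 1L, na.rm = TRUE)
  ni <- sum(a$labels == 0L, na.rm = TRUE)
  ratio <- if (nb + ni == 0) NA_real_ else 100 * nb / (nb + ni)
  if (!length(ibis)) {
    warning("no complete inter-burst segments; IBI measures undefined")
    return(list(median_ibi_s = NA_real_, max_ibi_s = NA_real_,
                burst_ratio_pct = ratio))
  }
  list(median_ibi_s = stats::median(ibis), max_ibi_s = max(ibis),
       burst_ratio_pct = ratio)
}

#' Paired comparison of per-record measures
#'
#' Wilcoxon signed-rank test on paired values plus a seeded percentile
#' bootstrap (1000 resamples) CI of the median difference `y - x`.
#'
#' @param x,y paired per-record values (length >= 5).
#' @param n_boot bootstrap iterations.
#' @param seed RNG seed for the bootstrap.
#' @return list with `median_diff`, `ci` (length 2), `p`, `n`.
#' @export
paired_comparison <- function(x, y, n_boot = 1000, seed = 1) {
  stopifnot(length(x) == length(y), length(x) >= 5)
  d <- y - x
  p <- if (all(d == 0)) {
    warning("all paired differences are zero")
    1
  } else {
    suppressWarnings(stats::wilcox.test(y, x, paired = TRUE)$p.value)
  }
  set.seed(seed)
  bs <- replicate(n_boot, stats::median(sample(d, replace = TRUE)))
  list(median_diff = stats::median(d),
       ci = stats::quantile(bs, c(0.025, 0.975), names = FALSE, type = 7),
       p = p, n = length(d))
}

#' Evaluate a detection against a reference annotation
#'
#' Bundles the sample-based AUC (when a continuous score is supplied),
#' time- and event-based sensitivity/specificity, Cohen's kappa with bias and
#' prevalence, and the IBI summary of the detection.
#'
#' @param detected detection `annotation` (64 Hz grid).
#' @param reference reference `annotation` at the same rate/length.
#' @param decision optional continuous discriminant aligned with `detected`.
#' @return an `evaluation_report` list.
#' @export
evaluation_report <- function(detected, reference, decision = NULL) {
  st <- sens_spec_time(detected, reference)
  se <- sens_spec_event(detected, reference)
  kp <- cohens_kappa(detected, reference)
  auc <- if (!is.null(decision)) {
    auc_samplewise(decision, reference)
  } else NA_real_
  structure(list(
    auc = auc,
    sens_time = st[["sens"]], spec_time = st[["spec"]],
    sens_event = se[["sens"]], spec_event = se[["spec"]],
    kappa = kp[["kappa"]], bias = kp[["bias"]], prevalence = kp[["prevalence"]],
    ibi = ibi_summary(detected)), class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> AUC %.3f | time %.1f/%.1f%% | event %.1f/%.1f%% | kappa %.2f\n",
              x$auc, x$sens_time, x$spec_time, x$sens_event, x$spec_event,
              x$kappa))
  cat(sprintf("  IBI median %.2f s, max %.2f s, burst ratio %.1f%%\n",
              x$ibi$median_ibi_s, x$ibi$max_ibi_s, x$ibi$burst_ratio_pct))
  invisible(x)
}

#' Write an evaluation report to JSON
#' @param report an `evaluation_report`.
#' @param path output path.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
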