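# Feature selection (mRMR filter + backwards-elimination wrapper), linear SVM
# training, thresholding and duration-limit post-processing, plus the nested
# leave-one-out cross-validation harness.

#' Detector configuration defaults
#'
#' @param n_keep filter-stage size of the mRMR candidate set.
#' @param svm_cost SVM regularisation constant C.
#' @param svm_tolerance libsvm termination tolerance.
#' @param threshold_mode `"static"` (cut at 0) or `"adaptive"` (cut at the
#'   per-record mean of the discriminant).
#' @param step training subsampling step (every `step`-th defined sample).
#' @param mi_bins equal-frequency bins for mutual-information estimation.
#' @param k_max Higuchi scale limit.
#' @param n_boot bootstrap iterations for aggregate confidence intervals.
#' @param seed RNG seed for the bootstrap.
#' @param inner_eval_step decimation step for the inner-CV evaluation grid
#'   (every `inner_eval_step`-th defined sample of the held-out record scores
#'   candidate feature subsets; training always uses the 1-in-`step` rows).
#' @return a named list.
#' @export
detector_config <- function(n_keep = 16, svm_cost = 1, svm_tolerance = 1e-4,
                            threshold_mode = c("static", "adaptive"),
                            step = 500, mi_bins = 10, k_max = 8,
                            n_boot = 1000, seed = 1, inner_eval_step = 10) {
  list(n_keep = n_keep, svm_cost = svm_cost, svm_tolerance = svm_tolerance,
       threshold_mode = match.arg(threshold_mode), step = step,
       mi_bins = mi_bins, k_max = k_max, n_boot = n_boot, seed = seed,
       inner_eval_step = inner_eval_step)
}

#' Deterministic 1-in-step training subsample
#'
#' Removes rows with undefined labels, then keeps every `step`-th remaining
#' row (rows 1, step+1, 2*step+1, ... of the defined rows).
#'
#' @param values numeric matrix of feature rows.
#' @param labels per-row labels (1/0/NA).
#' @param step subsampling step (500 keeps 1/500th of the data).
#' @return list with `values`, `labels`.
#' @export
subsample_training <- function(values, labels, step = 500) {
  keep <- which(!is.na(labels))
  idx <- keep[seq(1L, length(keep), by = step)]
  out <- list(values = values[idx, , drop = FALSE], labels = labels[idx])
  if (length(unique(out$labels)) < 2)
    stop("subsample contains a single class; use a smaller `step`")
  out
}

# equal-frequency discretisation into at most `bins` bins
discretize_ef <- function(x, bins = 10) {
  br <- unique(stats::quantile(x, probs = seq(0, 1, length.out = bins + 1),
                               names = FALSE, type = 7))
  if (length(br) < 2) return(rep(1L, length(x)))
  findInterval(x, br, rightmost.closed = TRUE, all.inside = TRUE)
}

# mutual information (nats) between two discrete vectors
mi_discrete <- function(a, b) {
  tab <- table(a, b)
  p <- tab / sum(tab)
  pa <- rowSums(p); pb <- colSums(p)
  nz <- p > 0
  sum(p[nz] * log(p[nz] / outer(pa, pb)[nz]))
}

#' Mutual information between a continuous feature and labels
#' @param x continuous feature values.
#' @param y discrete labels.
#' @param bins equal-frequency bins for `x`.
#' @return MI estimate in nats.
#' @export
mutual_information <- function(x, y, bins = 10) {
  mi_discrete(discretize_ef(x, bins), y)
}

#' mRMR filter-stage feature ranking
#'
#' Greedy maximum-relevance minimum-redundancy ranking in the difference
#' (MID) form: the first feature maximises MI with the labels; each further
#' feature maximises relevance minus the mean MI with the already-selected
#' set. Continuous features are discretised by equal-frequency binning.
#'
#' @param values feature matrix (columns named).
#' @param labels class labels (1/0), no NA.
#' @param n_keep number of features to retain (clipped to the feature count
#'   with a warning).
#' @param bins discretisation bins.
#' @return character vector of selected feature names, in rank order.
#' @export
mrmr_filter <- function(values, labels, n_keep = 16, bins = 10) {
  if (length(unique(labels)) < 2) stop("need two classes for mRMR")
  p <- ncol(values)
  if (n_keep > p) {
    warning("n_keep exceeds feature count; using all features")
    n_keep <- p
  }
  disc <- apply(values, 2, discretize_ef, bins = bins)
  rel <- apply(disc, 2, mi_discrete, b = labels)
  selected <- integer(0)
  remaining <- seq_len(p)
  red <- matrix(NA_real_, p, p)   # pairwise MI cache
  for (step in seq_len(n_keep)) {
    score <- if (!length(selected)) rel[remaining] else {
      vapply(remaining, function(j) {
        for (s in selected) if (is.na(red[j, s])) {
          red[j, s] <<- red[s, j] <<- mi_discrete(disc[, j], disc[, s])
        }
        rel[j] - mean(red[j, selected])
      }, 0)
    }
    pick <- remaining[which.max(score)]
    selected <- c(selected, pick)
    remaining <- setdiff(remaining, pick)
  }
  colnames(values)[selected]
}

#' Train the linear-kernel SVM
#'
#' Fits a linear SVM (class-balanced weights) and reduces it to the primal
#' decision function `D[x] = sum_p w_p x_p + b`, oriented so `D > 0` predicts
#' burst.
#'
#' @param values z-scored feature matrix.
#' @param labels 1 (burst) / 0 (inter-burst), no NA.
#' @param cost regularisation constant C.
#' @param tolerance solver tolerance.
#' @return list with `weights` (named), `bias`.
#' @export
train_svm <- function(values, labels, cost = 1, tolerance = 1e-4) {
  if (any(!is.finite(values))) stop("non-finite feature values")
  if (length(unique(labels)) < 2) stop("need two classes to train")
  y <- factor(ifelse(labels == 1L, "burst", "inter_burst"),
              levels = c("burst", "inter_burst"))
  n <- length(y)
  cw <- n / (2 * table(y))
  m <- e1071::svm(values, y, kernel = "linear", cost = cost, scale = FALSE,
                  tolerance = tolerance, class.weights = cw)
  w <- drop(t(m$coefs) %*% m$SV)
  b <- -m$rho
  # libsvm orients decision values toward the class it saw first in the
  # data (m$labels[1]), not factor level 1; align so positive = burst
  if (m$levels[m$labels[1]] != "burst") {
    w <- -w; b <- -b
  }
  names(w) <- colnames(values)
  list(weights = w, bias = b)
}

svm_decision <- function(model, values) {
  drop(values[, names(model$weights), drop = FALSE] %*% model$weights) +
    model$bias
}

# mean sample-wise AUC over leave-one-group-out folds for one feature
# subset; eval_data optionally supplies denser per-group test rows than the
# subsampled training rows
inner_cv_auc <- function(values, labels, groups, subset, config,
                         eval_data = NULL) {
  aucs <- c()
  for (g in unique(groups)) {
    tr <- groups != g
    ev <- if (is.null(eval_data)) {
      list(values = values[!tr, , drop = FALSE], labels = labels[!tr])
    } else eval_data[[as.character(g)]]
    if (length(unique(labels[tr])) < 2 || length(unique(ev$labels)) < 2) {
      warning("skipping degenerate inner fold (single class)")
      next
    }
    m <- train_svm(values[tr, subset, drop = FALSE], labels[tr],
                   cost = config$svm_cost, tolerance = config$svm_tolerance)
    d <- svm_decision(m, ev$values[, subset, drop = FALSE])
    aucs <- c(aucs, auc_samplewise(d, ev$labels))
  }
  mean(aucs)
}

#' Backwards-elimination wrapper
#'
#' Starting from the mRMR candidate set, iteratively removes the feature
#' whose removal maximises the inner leave-one-record-out CV AUC, and returns
#' the subset with the highest AUC seen along the elimination path. Ties
#' prefer the smaller subset, then earlier (lexicographic) feature order.
#'
#' @param values z-scored training rows (subsampled).
#' @param labels 1/0 labels.
#' @param groups record id per row (defines the inner LOO folds).
#' @param candidates character vector of candidate feature names.
#' @param config a [detector_config()].
#' @param eval_data optional named list (one entry per group) of
#'   `list(values, labels)` evaluation rows at a denser sampling than the
#'   training rows; defaults to scoring on the training-row grid.
#' @return character vector of selected feature names.
#' @export
backwards_elimination <- function(values, labels, groups, candidates,
                                  config = detector_config(),
                                  eval_data = NULL) {
  current <- sort(candidates)
  best <- current
  best_auc <- inner_cv_auc(values, labels, groups, current, config, eval_data)
  while (length(current) > 1) {
    step_auc <- vapply(current, function(f) {
      inner_cv_auc(values, labels, groups, setdiff(current, f), config,
                   eval_data)
    }, 0)
    drop_f <- names(step_auc)[which.max(step_auc)]
    current <- setdiff(current, drop_f)
    if (max(step_auc) >= best_auc) {   # equal AUC: prefer the smaller subset
      best_auc <- max(step_auc)
      best <- current
    }
  }
  best
}

#' Class-wise lower duration limits from annotations
#'
#' 2.5th percentile (linear-interpolation rule) of the pooled burst and
#' inter-burst segment durations across all supplied annotations.
#'
#' @param annotations list of `annotation` objects (or a single one).
#' @return list with `min_burst_s`, `min_inter_burst_s`.
#' @export
estimate_duration_limits <- function(annotations) {
  if (inherits(annotations, "annotation")) annotations <- list(annotations)
  durs <- lapply(annotations, function(a) {
    runs <- annotation_runs(a)
    runs <- runs[!is.na(runs$label), ]
    split(runs$end_s - runs$start_s, runs$label)
  })
  b <- unlist(lapply(durs, function(d) d[["1"]]))
  i <- unlist(lapply(durs, function(d) d[["0"]]))
  if (!length(b) || !length(i))
    stop("need at least one labelled segment of each class")
  list(min_burst_s = unname(stats::quantile(b, 0.025, type = 7)),
       min_inter_burst_s = unname(stats::quantile(i, 0.025, type = 7)))
}

#' Threshold the SVM discriminant
#'
#' @param d continuous decision values.
#' @param mode `"static"` (threshold 0) or `"adaptive"` (threshold
#'   `mean(d)` over the current record).
#' @return integer vector, 1 = burst, 0 = inter-burst.
#' @export
apply_threshold <- function(d, mode = c("static", "adaptive")) {
  mode <- match.arg(mode)
  thr <- if (mode == "static") 0 else mean(d)
  as.integer(d > thr)
}

#' Remove segments shorter than the class duration limits
#'
#' Interior segments shorter than their class minimum are relabelled to the
#' flanking class, shortest first (bursts before inter-bursts on ties).
#' Segments touching the record edges are truncated, not complete, and are
#' exempt. Idempotent.
#'
#' @param labels integer 1/0 vector (no NA).
#' @param fs label rate in Hz.
#' @param min_burst_s,min_inter_burst_s class minima in seconds.
#' @return integer vector of the same length.
#' @export
enforce_duration_limits <- function(labels, fs, min_burst_s, min_inter_burst_s) {
  stopifnot(!anyNA(labels))
  lim <- c(`0` = min_inter_burst_s, `1` = min_burst_s)
  repeat {
    r <- rle(labels)
    k <- length(r$lengths)
    if (k < 3) break
    dur <- r$lengths / fs
    interior <- seq_len(k) > 1 & seq_len(k) < k
    short <- interior & dur < lim[as.character(r$values)]
    if (!any(short)) break
    cand <- which(short)
    cand <- cand[order(dur[cand], -r$values[cand])]  # shortest, bursts first
    target <- cand[1]
    r$values[target] <- 1L - r$values[target]
    labels <- inverse.rle(r)
  }
  labels
}

# ---- trained detector -----------------------------------------------------

new_trained_detector <- function(selected, stats, weights, bias, config,
                                 limits) {
  structure(list(
    version = "1",
    selected_features = selected,
    zscore_stats = stats,
    weights = weights, bias = bias,
    threshold_mode = config$threshold_mode,
    min_burst_s = limits$min_burst_s,
    min_inter_burst_s = limits$min_inter_burst_s,
    config = config), class = "trained_detector")
}

#' @export
print.trained_detector <- function(x, ...) {
  cat(sprintf("<trained_detector> %d features, %s threshold, limits %.2f/%.2f s\n",
              length(x$selected_features), x$threshold_mode,
              x$min_burst_s, x$min_inter_burst_s))
  cat("  features:", paste(x$selected_features, collapse = ", "), "\n")
  invisible(x)
}

# shared fitting core: records/annotations -> selected features + SVM,
# given pre-computed log-transformed feature values and 64 Hz labels
fit_fold <- function(logvals, labels64, train_ids, config) {
  tr_rows <- lapply(train_ids, function(r) which(!is.na(labels64[[r]])))
  n_feat <- ncol(logvals[[train_ids[1]]])
  # pooled training mean/sd without materialising the pooled matrix
  s1 <- numeric(n_feat); s2 <- numeric(n_feat); n <- 0
  for (j in seq_along(train_ids)) {
    v <- logvals[[train_ids[j]]][tr_rows[[j]], , drop = FALSE]
    s1 <- s1 + colSums(v); s2 <- s2 + colSums(v^2); n <- n + nrow(v)
  }
  mu <- s1 / n
  sdv <- sqrt(pmax((s2 - n * mu^2) / (n - 1), 0))
  if (any(sdv == 0))
    stop("zero-variance feature column(s) in training fold: ",
         paste(colnames(logvals[[train_ids[1]]])[sdv == 0], collapse = ", "))
  stats <- list(mean = mu, sd = sdv)
  # per-record 1/step subsample of defined rows, z-scored and pooled
  sub <- lapply(seq_along(train_ids), function(j) {
    rows <- tr_rows[[j]][seq(1L, length(tr_rows[[j]]), by = config$step)]
    v <- logvals[[train_ids[j]]][rows, , drop = FALSE]
    v <- sweep(sweep(v, 2, mu), 2, sdv, "/")
    list(v = v, y = labels64[[train_ids[j]]][rows],
         g = rep(train_ids[j], length(rows)))
  })
  values <- do.call(rbind, lapply(sub, `[[`, "v"))
  labels <- unlist(lapply(sub, `[[`, "y"))
  groups <- unlist(lapply(sub, `[[`, "g"))
  # denser per-record rows for scoring candidate subsets in the inner CV
  eval_data <- stats::setNames(lapply(seq_along(train_ids), function(j) {
    rows <- tr_rows[[j]][seq(1L, length(tr_rows[[j]]),
                             by = config$inner_eval_step)]
    v <- logvals[[train_ids[j]]][rows, , drop = FALSE]
    list(values = sweep(sweep(v, 2, mu), 2, sdv, "/"),
         labels = labels64[[train_ids[j]]][rows])
  }), train_ids)
  candidates <- mrmr_filter(values, labels, config$n_keep, config$mi_bins)
  selected <- if (length(train_ids) >= 2) {
    backwards_elimination(values, labels, groups, candidates, config,
                          eval_data)
  } else candidates
  model <- train_svm(values[, selected, drop = FALSE], labels,
                     cost = config$svm_cost, tolerance = config$svm_tolerance)
  list(stats = stats, selected = selected, model = model)
}

prepare_inputs <- function(records, annotations, config) {
  fms <- lapply(records, function(r) compute_features(r, k_max = config$k_max))
  logv <- lapply(fms, function(fm) {
    v <- fm$values
    lc <- fm$specs$name[fm$specs$log_transformed]
    v[, lc] <- log(pmax(v[, lc, drop = FALSE], 1e-12))
    v
  })
  labels64 <- mapply(function(fm, a) {
    resample_annotation(a, 64, n_out = nrow(fm$values))$labels
  }, fms, annotations, SIMPLIFY = FALSE)
  list(logvals = logv, labels64 = labels64)
}

#' Train a prototype detector on all records
#'
#' Runs the full training pipeline (z-scoring, mRMR filter, backwards
#' elimination with leave-one-record-out inner CV, linear SVM, duration
#' limits from the annotations) on every supplied record.
#'
#' @param records list of single-channel `eeg_record`s.
#' @param annotations list of matching `annotation`s.
#' @param config a [detector_config()].
#' @return a `trained_detector`.
#' @export
train_detector <- function(records, annotations, config = detector_config()) {
  stopifnot(length(records) == length(annotations))
  prep <- prepare_inputs(records, annotations, config)
  fit <- fit_fold(prep$logvals, prep$labels64, seq_along(records), config)
  limits <- estimate_duration_limits(annotations)
  new_trained_detector(fit$selected, fit$stats, fit$model$weights,
                       fit$model$bias, config, limits)
}

# z-score a record's log-transformed values with a detector's training stats
apply_stats <- function(logvals, stats) {
  sweep(sweep(logvals, 2, stats$mean), 2, stats$sd, "/")
}

#' Continuous SVM discriminant for a record
#'
#' @param record an `eeg_record`.
#' @param detector a `trained_detector`.
#' @param channel channel index or label.
#' @return numeric decision values on the 64 Hz grid.
#' @export
decision_values <- function(record, detector, channel = 1) {
  fm <- compute_features(record, channel, k_max = detector$config$k_max)
  v <- fm$values
  lc <- fm$specs$name[fm$specs$log_transformed]
  v[, lc] <- log(pmax(v[, lc, drop = FALSE], 1e-12))
  v <- apply_stats(v, detector$zscore_stats)
  drop(v[, detector$selected_features, drop = FALSE] %*% detector$weights) +
    detector$bias
}

#' Detect bursts in a record
#'
#' Computes the discriminant, thresholds it (static or adaptive) and applies
#' the stored duration limits.
#'
#' @inheritParams decision_values
#' @param threshold_mode overrides the detector's stored mode if given.
#' @return an `annotation` at 64 Hz; the continuous discriminant is attached
#'   as attribute `"decision"`.
#' @export
detect_bursts <- function(record, detector, channel = 1,
                          threshold_mode = NULL) {
  d <- decision_values(record, detector, channel)
  mode <- if (is.null(threshold_mode)) detector$threshold_mode else threshold_mode
  y <- apply_threshold(d, mode)
  y <- enforce_duration_limits(y, 64, detector$min_burst_s,
                               detector$min_inter_burst_s)
  out <- annotation(y, 64)
  attr(out, "decision") <- d
  out
}

#' Persist / restore a trained detector as JSON
#'
#' Full-precision serialisation; a round-tripped detector produces
#' bit-identical detection output.
#'
#' @param detector a `trained_detector`.
#' @param path JSON file path.
#' @export
write_detector <- function(detector, path) {
  obj <- unclass(detector)
  obj$zscore_stats <- list(
    feature = names(detector$zscore_stats$mean),
    mean = unname(detector$zscore_stats$mean),
    sd = unname(detector$zscore_stats$sd))
  obj$weights <- list(feature = names(detector$weights),
                      value = unname(detector$weights))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)            # 17 significant digits
  invisible(path)                                # round-trip doubles exactly
}

#' @rdname write_detector
#' @export
read_detector <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  stats <- list(mean = stats::setNames(obj$zscore_stats$mean, obj$zscore_stats$feature),
                sd = stats::setNames(obj$zscore_stats$sd, obj$zscore_stats$feature))
  w <- stats::setNames(obj$weights$value, obj$weights$feature)
  cfg <- obj$config
  structure(list(version = obj$version,
                 selected_features = obj$selected_features,
                 zscore_stats = stats, weights = w, bias = obj$bias,
                 threshold_mode = obj$threshold_mode,
                 min_burst_s = obj$min_burst_s,
                 min_inter_burst_s = obj$min_inter_burst_s,
                 config = cfg), class = "trained_detector")
}

#' Nested leave-one-out cross-validation
#'
#' Outer folds leave one record (one infant) out; all parameters -- z-score
#' stats, mRMR + wrapper feature selection (inner leave-one-record-out CV),
#' SVM weights and duration limits -- are fitted on the training fold only.
#' The held-out record is scored on its consensus-defined samples with every
#' available sample (no subsampling at test time).
#'
#' @param records list of single-channel `eeg_record`s (>= 3).
#' @param annotations matching list of `annotation`s.
#' @param config a [detector_config()].
#' @return a `cv_result`: per-fold data.frame `folds` (record, auc,
#'   sens/spec time and event), list `selected` of per-fold feature sets, and
#'   `aggregate` medians with bootstrap 95% CIs.
#' @export
nested_cv <- function(records, annotations, config = detector_config()) {
  stopifnot(length(records) == length(annotations))
  if (length(records) < 3) stop("need at least 3 records for nested CV")
  prep <- prepare_inputs(records, annotations, config)
  usable <- which(vapply(prep$labels64, function(l)
    length(unique(l[!is.na(l)])) == 2, TRUE))
  if (length(usable) < length(records))
    warning("excluding record(s) without both label classes: ",
            paste(setdiff(seq_along(records), usable), collapse = ", "))
  folds <- data.frame()
  selected <- list()
  for (i in usable) {
    train_ids <- setdiff(usable, i)
    stopifnot(!i %in% train_ids)       # leakage guard
    fit <- fit_fold(prep$logvals, prep$labels64, train_ids, config)
    limits <- estimate_duration_limits(annotations[train_ids])
    v <- apply_stats(prep$logvals[[i]], fit$stats)
    d <- svm_decision(fit$model, v)
    ref <- prep$labels64[[i]]
    defined <- !is.na(ref)
    auc <- auc_samplewise(d[defined], ref[defined])
    y <- enforce_duration_limits(apply_threshold(d, config$threshold_mode),
                                 64, limits$min_burst_s,
                                 limits$min_inter_burst_s)
    st <- sens_spec_time(annotation(y, 64), annotation(ref, 64))
    se <- sens_spec_event(annotation(y, 64), annotation(ref, 64))
    folds <- rbind(folds, data.frame(
      record = i, auc = auc, sens_time = st[["sens"]], spec_time = st[["spec"]],
      sens_event = se[["sens"]], spec_event = se[["spec"]]))
    selected[[as.character(i)]] <- fit$selected
  }
  boot_ci <- function(x) {
    set.seed(config$seed)
    bs <- replicate(config$n_boot, stats::median(sample(x, replace = TRUE)))
    stats::quantile(bs, c(0.025, 0.975), names = FALSE, type = 7)
  }
  agg <- lapply(folds[-1], function(x)
    list(median = stats::median(x), ci = boot_ci(x)))
  structure(list(folds = folds, selected = selected, aggregate = agg,
                 config = config), class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  a <- x$aggregate
  cat(sprintf("<cv_result> %d folds | median AUC %.3f (95%% CI %.3f-%.3f)\n",
              nrow(x$folds), a$auc$median, a$auc$ci[1], a$auc$ci[2]))
  cat(sprintf("  time sens/spec %.1f%%/%.1f%%, event sens/spec %.1f%%/%.1f%%\n",
              a$sens_time$median, a$spec_time$median,
              a$sens_event$median, a$spec_event$median))
  invisible(x)
}
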