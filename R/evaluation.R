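# Average precision, cutoff selection and subject-grouped cross-validation.

as_binary_labels <- function(labels) {
  if (is.logical(labels)) return(as.integer(labels))
  if (is.numeric(labels)) {
    if (!all(labels %in% c(0, 1))) stop_fmt("numeric labels must be 0/1")
    return(as.integer(labels))
  }
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.character(labels)) {
    if (!all(labels %in% c("control", "EG")))
      stop_fmt("character labels must be 'control'/'EG'")
    return(as.integer(labels == "EG"))
  }
  stop_fmt("cannot interpret labels of class %s", class(labels)[1])
}

#' Average precision of a ranking
#'
#' Step-wise average precision over descending unique score thresholds:
#' `sum((R_k - R_{k-1}) * P_k)` with tied scores entering the confusion counts
#' together. Equals 1 exactly when every positive outranks every negative, and
#' is invariant under strictly monotone transforms of the scores.
#'
#' @param scores numeric scores, higher = more glaucomatous.
#' @param labels 0/1, logical, or `"control"`/`"EG"`; both classes required.
#' @return AP in `[0, 1]`.
#' @examples
#' average_precision(c(0.9, 0.8, 0.7, 0.1), c(1, 0, 1, 0))  # 0.8333...
#' @export
average_precision <- function(scores, labels) {
  y <- as_binary_labels(labels)
  if (length(scores) != length(y)) stop_fmt("scores and labels differ in length")
  if (!all(is.finite(scores))) stop_fmt("scores must be finite")
  P <- sum(y)
  if (P == 0 || P == length(y))
    stop_fmt("average precision needs both classes present")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  yy <- y[ord]
  tp <- cumsum(yy)
  fp <- cumsum(1 - yy)
  cuts <- c(which(diff(s) != 0), length(s))  # last index of each tie group
  recall <- tp[cuts] / P
  precision <- tp[cuts] / (tp[cuts] + fp[cuts])
  sum(diff(c(0, recall)) * precision)
}

#' Threshold-integral variant of average precision
#'
#' Literal integral of the product `PPV(t) * TPR(t)` over the classification
#' threshold `t` in `[0, 1]` (predict positive when `score >= t`). This is a
#' different functional from standard average precision and is provided for
#' comparison; [average_precision()] is the primary metric. Scores outside
#' `[0, 1]` are min-max rescaled into the unit interval first.
#'
#' @inheritParams average_precision
#' @return the integral value in `[0, 1]`.
#' @export
ap_threshold_integral <- function(scores, labels) {
  y <- as_binary_labels(labels)
  if (sum(y) == 0 || sum(y) == length(y))
    stop_fmt("both classes must be present")
  if (min(scores) < 0 || max(scores) > 1) {
    rng <- range(scores)
    scores <- if (rng[1] == rng[2]) rep(0.5, length(scores))
              else (scores - rng[1]) / (rng[2] - rng[1])
  }
  breaks <- sort(unique(c(0, scores, 1)))
  total <- 0
  for (m in seq_len(length(breaks) - 1)) {
    a <- breaks[m]; b <- breaks[m + 1]
    pred <- scores >= b  # constant over t in (a, b]
    tp <- sum(pred & y == 1)
    fppos <- sum(pred)
    ppv <- if (fppos > 0) tp / fppos else 0
    tpr <- tp / sum(y)
    total <- total + (b - a) * ppv * tpr
  }
  total
}

#' F1-style cutoff selection
#'
#' Scans the observed unique scores as candidate thresholds (predict EG when
#' `score >= t`) and returns the one maximizing `PPV * TPR / (PPV + TPR)` —
#' half the standard F1, hence the same argmax. Ties resolve to the smallest
#' threshold.
#'
#' @inheritParams average_precision
#' @return list with `threshold` and `objective` (the achieved
#'   `PPV*TPR/(PPV+TPR)`).
#' @export
f1_cutoff <- function(scores, labels) {
  y <- as_binary_labels(labels)
  if (sum(y) == 0 || sum(y) == length(y))
    stop_fmt("both classes must be present")
  ts <- sort(unique(scores))
  best <- list(threshold = ts[1], objective = -Inf)
  for (t in ts) {
    pred <- scores >= t
    tp <- sum(pred & y == 1)
    ppv_den <- sum(pred)
    ppv <- if (ppv_den > 0) tp / ppv_den else 0
    tpr <- tp / sum(y)
    obj <- if (ppv + tpr > 0) ppv * tpr / (ppv + tpr) else 0
    if (obj > best$objective) best <- list(threshold = t, objective = obj)
  }
  best
}

#' Subject-grouped fold assignment
#'
#' Every subject (with all examinations of both eyes) is assigned wholly to
#' one fold, so no individual can contribute to both training and test sets.
#' Folds are balanced by subject count (sizes differ by at most one) under a
#' seeded shuffle; when all records are labelled the shuffle is stratified by
#' group, so each test fold keeps both classes whenever the cohort allows it.
#'
#' @param records a `"vf_table"`.
#' @param k number of folds.
#' @param seed shuffle seed.
#' @return list of `k` fold splits, each `list(fold_id, train_subjects,
#'   test_subjects)`.
#' @export
make_folds <- function(records, k = 10, seed = 1) {
  if (!is_count(k) || k < 2) stop_fmt("k must be an integer >= 2")
  subjects <- unique(records$subject_id)
  if (length(subjects) < k)
    stop_fmt("%d subjects cannot be split into %d folds", length(subjects), k)
  strata <- if (!anyNA(records$group)) {
    grp <- records$group[match(subjects, records$subject_id)]
    split(subjects, grp)
  } else list(all = subjects)
  fold_of <- integer(0)
  names_of <- character(0)
  with_seed(seed, {
    offset <- 0L
    for (s in strata) {
      sh <- sample(s)
      fold_of <- c(fold_of, ((seq_along(sh) - 1L + offset) %% k) + 1L)
      names_of <- c(names_of, sh)
      offset <- offset + length(sh)
    }
  })
  lapply(seq_len(k), function(f) {
    test <- names_of[fold_of == f]
    list(fold_id = f, train_subjects = setdiff(subjects, test),
         test_subjects = test)
  })
}

#' Cross-validated comparison of all classifiers
#'
#' Runs subject-grouped k-fold cross-validation of any subset of the five
#' methods. Index methods (MD, sLV, MD+sLV) are deterministic and scored once
#' per fold; neural methods (NN, CNN) are trained `repeats` times per fold
#' with distinct seeds (each training holds out an internal subject-grouped
#' validation split for checkpoint selection) and scored on the untouched test
#' fold. Per-method performance is summarized by the median and standard
#' deviation over all cumulated average-precision entries. Subject leakage is
#' asserted inside the run, not just in tests.
#'
#' @param records labelled `"vf_table"`.
#' @param pattern the associated [test_pattern()].
#' @param methods subset of `c("MD", "sLV", "MD+sLV", "NN", "CNN")`.
#' @param k folds (default 10).
#' @param repeats trainings per fold for neural methods (default 5).
#' @param seed master seed (folds, initializations, shuffling).
#' @param epochs,batch_size,lr training settings for the neural methods.
#' @param val_fraction internal validation fraction of training subjects.
#' @param verbose print fold progress.
#' @return An object of class `"vf_cv_report"`: `entries` (method, fold,
#'   repeat, ap) and `aggregates` (median, sd, n per method).
#' @export
run_cv <- function(records, pattern, methods = c("MD", "sLV", "MD+sLV", "NN", "CNN"),
                   k = 10, repeats = 5, seed = 1, epochs = 30, batch_size = 32,
                   lr = 1e-3, val_fraction = 0.1, verbose = FALSE) {
  methods <- match.arg(methods, several.ok = TRUE)
  if (anyNA(records$group)) stop_fmt("run_cv needs labelled records")
  y_all <- as_binary_labels(records$group)
  folds <- make_folds(records, k = k, seed = derive_seed(seed, 11))
  neural <- intersect(methods, c("NN", "CNN"))
  if ("CNN" %in% neural) {
    rmap <- region_assignment(pattern)
    images <- voronoi_image_matrix(records, rmap, pattern)
  }
  if ("NN" %in% neural) feats <- nn_features(records, pattern)

  entries <- list()
  add <- function(method, fold, rep, ap)
    entries[[length(entries) + 1]] <<- data.frame(method = method, fold = fold,
                                                  rep = rep, ap = ap)
  for (fs in folds) {
    if (length(intersect(fs$train_subjects, fs$test_subjects)))
      stop_fmt("protocol violation: fold %d has subject leakage", fs$fold_id)
    in_test <- records$subject_id %in% fs$test_subjects
    tr <- records[!in_test, , drop = FALSE]
    te <- records[in_test, , drop = FALSE]
    if (length(unique(te$group)) < 2) {
      stop_fmt("fold %d test set has a single class; use more subjects or fewer folds",
               fs$fold_id)
    }
    if (any(c("MD", "sLV", "MD+sLV") %in% methods)) {
      sc <- index_scores(te, pattern, train_records = tr, fusion = "logistic")
      if ("MD" %in% methods) add("MD", fs$fold_id, 1L, average_precision(sc$md, te$group))
      if ("sLV" %in% methods) add("sLV", fs$fold_id, 1L, average_precision(sc$slv, te$group))
      if ("MD+sLV" %in% methods) add("MD+sLV", fs$fold_id, 1L,
                                     average_precision(sc$md_slv, te$group))
    }
    for (method in neural) {
      for (r in seq_len(repeats)) {
        sd_r <- derive_seed(seed, fs$fold_id * 1000 + r * 10 +
                              (if (method == "CNN") 1 else 2))
        val_subj <- validation_subjects(tr, val_fraction, derive_seed(sd_r, 5))
        is_val <- tr$subject_id %in% val_subj
        idx_tr_all <- which(!in_test)
        mk <- function(rows) {
          x <- if (method == "CNN") images[, rows, drop = FALSE]
               else feats[rows, , drop = FALSE]
          list(x = x, y = y_all[rows], subjects = records$subject_id[rows])
        }
        spec <- model_spec(if (method == "CNN") "CNN" else "NN",
                           batch_size = batch_size, lr = lr, epochs = epochs,
                           seed = derive_seed(sd_r, 7))
        net <- if (method == "CNN") build_cnn(spec) else build_nn(spec, pattern$L + 2L)
        fit <- train_model(net, mk(idx_tr_all[!is_val]), mk(idx_tr_all[is_val]),
                           seed = derive_seed(sd_r, 9))
        x_te <- if (method == "CNN") images[, in_test, drop = FALSE]
                else feats[in_test, , drop = FALSE]
        add(method, fs$fold_id, r,
            average_precision(predict(fit, x_te), te$group))
      }
    }
    if (verbose) message(sprintf("fold %d/%d done", fs$fold_id, k))
  }
  entries <- do.call(rbind, entries)
  aggregates <- do.call(rbind, lapply(split(entries, entries$method), function(d)
    data.frame(method = d$method[1], median = stats::median(d$ap),
               std = stats::sd(d$ap), n = nrow(d))))
  rownames(aggregates) <- NULL
  structure(list(entries = entries, aggregates = aggregates, k = k,
                 repeats = repeats, seed = seed, methods = methods),
            class = "vf_cv_report")
}

#' @export
print.vf_cv_report <- function(x, ...) {
  cat(sprintf("Cross-validation report: %d folds x %d repeat(s), seed %s\n",
              x$k, x$repeats, format(x$seed)))
  agg <- x$aggregates
  for (i in seq_len(nrow(agg)))
    cat(sprintf("  %-7s AP median %.3f +/- %.3f  (n = %d)\n",
                agg$method[i], agg$median[i], agg$std[i], agg$n[i]))
  invisible(x)
}

#' @export
summary.vf_cv_report <- function(object, ...) print(object, ...)

#' @export
plot.vf_cv_report <- function(x, ...) {
  graphics::boxplot(ap ~ method, data = x$entries, ylab = "average precision",
                    xlab = "", col = "grey90", ...)
  invisible(x)
}

#' Write a cross-validation report as JSON
#'
#' Schema: `{method: {entries: [...], median: x, std: y}}`.
#'
#' @param report a `"vf_cv_report"`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_cv_report <- function(report, path) {
  out <- lapply(split(report$entries, report$entries$method), function(d)
    list(entries = d$ap, median = stats::median(d$ap), std = stats::sd(d$ap)))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
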