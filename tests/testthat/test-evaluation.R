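test_that("average precision reproduces worked examples", {
  expect_equal(average_precision(c(0.9, 0.2, 0.8), c(1, 0, 1)), 1.0)
  # thresholds 0.9 (P=1, R=1/2) then 0.7 (P=2/3, R=1)
  expect_equal(average_precision(c(0.9, 0.8, 0.7, 0.1), c(1, 0, 1, 0)),
               0.5 * 1 + 0.5 * 2 / 3)
  # perfectly wrong ranking: brute-force value of the worst arrangement
  sc <- c(0.1, 0.2, 0.9, 0.8)
  y <- c(1, 1, 0, 0)
  expect_equal(average_precision(sc, y), oracle_ap(sc, y))
  expect_error(average_precision(c(1, 2), c(1, 1)), "both classes")
})

test_that("average precision matches the brute-force oracle over all small label arrangements", {
  set.seed(70)
  for (n in 2:6) {
    for (mask in 1:(2^n - 2)) {
      y <- as.integer(intToBits(mask)[1:n])
      scores <- runif(n)
      expect_equal(average_precision(scores, y), oracle_ap(scores, y),
                   tolerance = 1e-12)
      # and with heavy ties
      tied <- sample(c(0.2, 0.5, 0.8), n, replace = TRUE)
      expect_equal(average_precision(tied, y), oracle_ap(tied, y),
                   tolerance = 1e-12)
    }
  }
})

test_that("average precision is invariant under strictly monotone score transforms", {
  set.seed(71)
  for (case in 1:25) {
    n <- sample(4:40, 1)
    y <- sample(c(0, 1), n, replace = TRUE)
    if (length(unique(y)) < 2) next
    s <- rnorm(n)
    base <- average_precision(s, y)
    expect_equal(average_precision(3 * s + 2, y), base)
    expect_equal(average_precision(exp(s), y), base)
    expect_equal(average_precision(plogis(s), y), base)
  }
})

test_that("threshold-integral variant behaves on canonical cases", {
  # product PPV*TPR is 0.5 on (0, 0.1], 1 on (0.1, 0.9], 0 on (0.9, 1]
  sc <- c(0.9, 0.9, 0.1, 0.1)
  y <- c(1, 1, 0, 0)
  expect_equal(ap_threshold_integral(sc, y), 0.1 * 0.5 + 0.8 * 1 + 0.1 * 0)
  # numeric cross-check on a random case via a fine Riemann grid
  set.seed(72)
  s2 <- runif(12)
  y2 <- rep(c(0, 1), 6)
  grid <- seq(1e-6, 1, length.out = 20001)
  riemann <- mean(sapply(grid, function(t) {
    pred <- s2 >= t
    tp <- sum(pred & y2 == 1)
    ppv <- if (sum(pred) > 0) tp / sum(pred) else 0
    ppv * tp / sum(y2 == 1)
  }))
  expect_equal(ap_threshold_integral(s2, y2), riemann, tolerance = 1e-3)
})

test_that("F1-style cutoff matches exhaustive scans and standard F1", {
  res <- f1_cutoff(c(0.9, 0.9, 0.1, 0.1), c(1, 1, 0, 0))
  expect_equal(res$threshold, 0.9)
  expect_equal(res$objective, 0.5)  # PPV = TPR = 1 -> 1/(1+1)

  set.seed(73)
  for (case in 1:20) {
    n <- sample(6:25, 1)
    y <- sample(c(0, 1), n, replace = TRUE)
    if (length(unique(y)) < 2) next
    s <- round(runif(n), 2)  # ties likely
    res <- f1_cutoff(s, y)
    ref <- oracle_f1_cutoff(s, y)
    expect_equal(res$objective, ref$objective, tolerance = 1e-12)
    # the objective is F1/2: same argmax as standard F1
    f1 <- function(t) {
      pred <- s >= t
      tp <- sum(pred & y == 1)
      prec <- if (sum(pred) > 0) tp / sum(pred) else 0
      rec <- tp / sum(y == 1)
      if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    }
    expect_equal(f1(res$threshold), max(sapply(unique(s), f1)),
                 tolerance = 1e-12)
  }

  # one mislabeled score in a 6-record worked set
  s6 <- c(0.95, 0.8, 0.6, 0.55, 0.3, 0.1)
  y6 <- c(1, 1, 0, 1, 0, 0)
  expect_equal(f1_cutoff(s6, y6)$threshold, oracle_f1_cutoff(s6, y6)$threshold)

  # ties in the objective resolve to the smallest threshold
  res_tie <- f1_cutoff(c(0.2, 0.8), c(0, 1))
  expect_equal(res_tie$threshold, 0.8)
})

test_that("grouped folds partition subjects without leakage", {
  ds <- small_cohort(n_subjects = 11, visits = 2, seed = 80)
  folds <- make_folds(ds$records, k = 5, seed = 4)
  expect_length(folds, 5)
  all_test <- unlist(lapply(folds, `[[`, "test_subjects"))
  expect_setequal(all_test, unique(ds$records$subject_id))
  expect_false(any(duplicated(all_test)))
  for (f in folds) {
    expect_length(intersect(f$train_subjects, f$test_subjects), 0)
    expect_setequal(c(f$train_subjects, f$test_subjects),
                    unique(ds$records$subject_id))
  }
  # every record lands in exactly one test fold
  counts <- rowSums(sapply(folds, function(f)
    ds$records$subject_id %in% f$test_subjects))
  expect_true(all(counts == 1))

  expect_identical(make_folds(ds$records, k = 5, seed = 4), folds)
  expect_error(make_folds(ds$records[1:2, ], k = 5), "folds")
})

test_that("cross-validation produces the expected entry counts and honest aggregates", {
  ds <- small_cohort(n_subjects = 9, visits = 2, seed = 90)
  p <- builtin_pattern("24-2")
  rep <- run_cv(ds$records, p, k = 3, repeats = 2, seed = 5, epochs = 2)
  ent <- rep$entries
  expect_equal(sum(ent$method == "CNN"), 3 * 2)   # repeats x folds
  expect_equal(sum(ent$method == "NN"), 3 * 2)
  expect_equal(sum(ent$method == "MD"), 3)        # deterministic, once per fold
  expect_equal(sum(ent$method == "sLV"), 3)
  expect_equal(sum(ent$method == "MD+sLV"), 3)
  expect_true(all(ent$ap >= 0 & ent$ap <= 1))
  # aggregates recomputed from entries match the stored values exactly
  for (m in unique(ent$method)) {
    expect_equal(rep$aggregates$median[rep$aggregates$method == m],
                 median(ent$ap[ent$method == m]))
    expect_equal(rep$aggregates$std[rep$aggregates$method == m],
                 sd(ent$ap[ent$method == m]))
  }

  tmp <- withr::local_tempfile(fileext = ".json")
  save_cv_report(rep, tmp)
  js <- jsonlite::read_json(tmp, simplifyVector = TRUE)
  expect_setequal(names(js), unique(ent$method))
  expect_equal(js$CNN$median, median(ent$ap[ent$method == "CNN"]))

  # identical seeds reproduce the full report
  rep2 <- run_cv(ds$records, p, k = 3, repeats = 2, seed = 5, epochs = 2)
  expect_equal(rep$entries, rep2$entries)
})

test_that("cross-validation rejects unlabeled cohorts", {
  ds <- small_cohort(n_subjects = 6, visits = 1, seed = 91)
  rec <- ds$records
  rec$group[1] <- NA
  expect_error(run_cv(rec, builtin_pattern("24-2"), k = 2, repeats = 1),
               "labelled")
})
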