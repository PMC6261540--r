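test_that("generator configuration validates its inputs", {
  p <- builtin_pattern("24-2")
  expect_error(synth_config(p, control_noise_sd = -1), "non-negative")
  expect_error(synth_config(p, eyes_per_subject = 3), "1 or 2")
  expect_error(synth_config(p, visits_per_eye = c(3, 1)), "range")
  expect_error(synth_config(p, defect_archetypes = list(a = c(0L))),
               "out-of-range")
  expect_error(synth_config(p, defect_archetypes = list()), "archetype")
  arch <- default_archetypes(p)
  expect_setequal(names(arch), c("superior_arcuate", "inferior_arcuate",
                                 "nasal_step", "paracentral", "diffuse"))
  for (a in arch) expect_gt(length(a), 0)
  # archetypes avoid blind-spot locations
  bs <- which(p$locations$blind_spot)
  for (a in arch) expect_length(intersect(a, bs), 0)
})

test_that("noise-free draws are exact constructions", {
  p <- builtin_pattern("24-2")
  cfg <- synth_config(p, control_noise_sd = 0, control_offset_sd = 0,
                      control_offset_mean = 0, defect_depth_sd = 0, seed = 1)
  r <- sample_control_vf(cfg)
  expect_equal(r, rep(0, p$L))
  expect_equal(mean_defect(r), 0)

  r_eg <- sample_eg_vf(cfg, archetype = "superior_arcuate", depth = 5)
  idx <- cfg$defect_archetypes$superior_arcuate
  expect_true(all(r_eg[idx] == -5))
  expect_true(all(r_eg[-idx] == 0))
  expect_error(sample_eg_vf(cfg, archetype = "no_such"), "unknown archetype")
})

test_that("control draws are calibrated to the configured cohort statistics", {
  p <- builtin_pattern("24-2")
  cfg <- synth_config(p)
  usable <- !p$locations$blind_spot
  set.seed(123)
  n <- 10000
  mds <- numeric(n)
  slvs <- numeric(n)
  for (i in seq_len(n)) {
    r <- sample_control_vf(cfg)[usable]
    mds[i] <- mean_defect(r)
    slvs[i] <- slv(r)
  }
  target_md <- -cfg$control_offset_mean
  se <- sd(mds) / sqrt(n)
  expect_lt(abs(mean(mds) - target_md), 3 * se)
  # noise SD was chosen so the mean sLV sits near the configured 1.85 dB scale
  expect_lt(abs(mean(slvs) - cfg$control_noise_sd), 0.1)
  expect_true(all(mds < cfg$md_cap))
})

test_that("focal defects inflate sLV relative to controls and respect the MD cap", {
  p <- builtin_pattern("24-2")
  cfg <- synth_config(p, seed = 2)
  usable <- !p$locations$blind_spot
  set.seed(321)
  n <- 2000
  slv_ct <- numeric(n)
  slv_eg <- numeric(n)
  md_eg <- numeric(n)
  for (i in seq_len(n)) {
    slv_ct[i] <- slv(sample_control_vf(cfg)[usable])
    r <- sample_eg_vf(cfg, archetype = "superior_arcuate")[usable]
    slv_eg[i] <- slv(r)
    md_eg[i] <- mean_defect(r)
  }
  expect_gt(mean(slv_eg), mean(slv_ct))
  expect_true(all(md_eg < cfg$md_cap))
})

test_that("dataset generation is deterministic, longitudinal and correctly sized", {
  p <- builtin_pattern("24-2")
  cfg <- synth_config(p, n_subjects = 10, visits_per_eye = c(3, 3),
                      eyes_per_subject = 1, seed = 11)
  ds <- generate_dataset(cfg)
  expect_equal(nrow(ds$records), 10 * 2 * 3)     # subjects x groups x visits
  expect_equal(length(unique(ds$records$subject_id)), 20)
  expect_true(all(table(ds$records$subject_id) == 3))
  expect_s3_class(ds$records, "vf_table")
  # per-eye archetype is persistent across visits (recorded in the roster)
  expect_true(all(!is.na(ds$roster$archetype[ds$roster$group == "EG"])))
  expect_true(all(is.na(ds$roster$archetype[ds$roster$group == "control"])))

  # every emitted record satisfies the MD cap
  gi <- global_indices(ds$records, p)
  expect_true(all(gi$md < cfg$md_cap))

  # same seed -> byte-identical output file
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_vf_table(generate_dataset(cfg)$records, f1)
  write_vf_table(generate_dataset(cfg)$records, f2)
  expect_identical(readLines(f1), readLines(f2))

  # grouped folds built on the cohort never split a subject
  folds <- make_folds(ds$records, k = 4, seed = 1)
  for (f in folds)
    expect_length(intersect(f$train_subjects, f$test_subjects), 0)
})

test_that("defect depth controls separability of the generated cohorts", {
  p <- builtin_pattern("24-2")
  # deep defects: the MD baseline alone reaches essentially perfect ranking
  deep <- generate_dataset(synth_config(p, n_subjects = 12,
                                        defect_depth_mean = 18, seed = 5))
  sc <- index_scores(deep$records, p)
  expect_gte(average_precision(sc$md, deep$records$group), 0.95)

  # zero depth: scores carry no signal, AP falls to the prevalence regime
  null <- generate_dataset(synth_config(p, n_subjects = 12,
                                        defect_depth_mean = 0,
                                        defect_depth_sd = 0, seed = 6))
  prevalence <- mean(null$records$group == "EG")
  ap_null <- average_precision(index_scores(null$records, p)$md,
                               null$records$group)
  expect_lt(abs(ap_null - prevalence), 0.25)
})
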