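# Synthetic visual-field cohorts with the statistical structure the
# classifier assumes: control fields near zero deviation, early-glaucoma
# fields with localized negative clusters (arcuate, nasal step, paracentral)
# or mild diffuse loss, longitudinal visits per eye, and the MD < 6 dB
# inclusion cap enforced on every emitted record.

#' Default defect archetypes for a test pattern
#'
#' Geometric index sets over the pattern's locations following the classical
#' early-glaucoma defect morphologies (right-eye orientation: blind spot
#' temporal at positive x, nasal field at negative x): superior and inferior
#' arcuate bands (annulus 8-22 degrees around fixation, sparing the far
#' temporal wedge), a nasal-step wedge, a paracentral cluster, and a diffuse
#' set covering every non-blind-spot location.
#'
#' @param pattern a [test_pattern()].
#' @return named list of integer location-index vectors.
#' @export
default_archetypes <- function(pattern) {
  loc <- pattern$locations
  ecc <- sqrt(loc$x^2 + loc$y^2)
  usable <- !loc$blind_spot
  arc <- usable & ecc >= 8 & ecc <= 22 & loc$x < 18
  list(
    superior_arcuate = which(arc & loc$y > 0),
    inferior_arcuate = which(arc & loc$y < 0),
    nasal_step = which(usable & loc$x <= -15 & loc$y > 0 & loc$y <= 15),
    paracentral = which(usable & ecc <= 8),
    diffuse = which(usable)
  )
}

#' Configuration of the synthetic cohort generator
#'
#' Defaults target the descriptive statistics of a mixed clinical cohort of
#' control and early-glaucoma fields: control deviations are a per-eye offset
#' (mean 0.31 dB, so the cohort mean MD is about -0.31 dB) plus per-location
#' noise of 1.85 dB (mean sLV about 1.84 dB); early-glaucoma fields add a
#' focal loss of about 12 dB at one archetype's locations (diffuse archetype:
#' a quarter of that depth everywhere). Both groups are rejection-sampled to
#' satisfy MD < 6 dB, the early-glaucoma inclusion cap.
#'
#' @param pattern a [test_pattern()].
#' @param n_subjects subjects per group.
#' @param eyes_per_subject 1 or 2.
#' @param visits_per_eye integer range `c(min, max)` of longitudinal visits.
#' @param control_noise_sd per-location noise SD, dB.
#' @param control_offset_sd per-eye offset SD, dB.
#' @param control_offset_mean per-eye offset mean, dB (positive = slightly
#'   supranormal control fields, yielding negative cohort MD).
#' @param defect_archetypes named list of location index sets; defaults to
#'   [default_archetypes()] of the pattern. The `diffuse` entry, when present,
#'   is applied at `diffuse_scale` times the focal depth.
#' @param defect_depth_mean,defect_depth_sd focal loss depth distribution, dB.
#' @param diffuse_scale depth multiplier for the diffuse archetype.
#' @param depth_drift_sd per-visit random-walk SD of an eye's defect depth,
#'   dB (longitudinal consistency: same archetype, slowly drifting depth).
#' @param md_cap records are resampled until MD is below this bound, dB.
#' @param seed generator seed.
#' @return list of class `"synth_config"`.
#' @export
synth_config <- function(pattern, n_subjects = 20, eyes_per_subject = 1,
                         visits_per_eye = c(3, 3), control_noise_sd = 1.85,
                         control_offset_sd = 0.5, control_offset_mean = 0.31,
                         defect_archetypes = default_archetypes(pattern),
                         defect_depth_mean = 12, defect_depth_sd = 3,
                         diffuse_scale = 0.25, depth_drift_sd = 0.5,
                         md_cap = 6.0, seed = 1) {
  stopifnot(inherits(pattern, "test_pattern"))
  if (control_noise_sd < 0 || control_offset_sd < 0 || defect_depth_sd < 0 ||
      depth_drift_sd < 0)
    stop_fmt("standard deviations must be non-negative")
  if (!eyes_per_subject %in% 1:2) stop_fmt("eyes_per_subject must be 1 or 2")
  if (length(visits_per_eye) != 2 || visits_per_eye[1] > visits_per_eye[2] ||
      visits_per_eye[1] < 1)
    stop_fmt("visits_per_eye must be an increasing integer range")
  if (length(defect_archetypes) == 0)
    stop_fmt("at least one defect archetype is required")
  for (nm in names(defect_archetypes)) {
    idx <- defect_archetypes[[nm]]
    if (length(idx) == 0 || any(idx < 1 | idx > pattern$L))
      stop_fmt("archetype '%s' has empty or out-of-range location indices", nm)
  }
  structure(list(pattern = pattern, n_subjects = n_subjects,
                 eyes_per_subject = eyes_per_subject,
                 visits_per_eye = as.integer(visits_per_eye),
                 control_noise_sd = control_noise_sd,
                 control_offset_sd = control_offset_sd,
                 control_offset_mean = control_offset_mean,
                 defect_archetypes = defect_archetypes,
                 defect_depth_mean = defect_depth_mean,
                 defect_depth_sd = defect_depth_sd,
                 diffuse_scale = diffuse_scale,
                 depth_drift_sd = depth_drift_sd,
                 md_cap = md_cap, seed = as.integer(seed)),
            class = "synth_config")
}

control_background <- function(config, offset) {
  offset + stats::rnorm(config$pattern$L, sd = config$control_noise_sd)
}

reject_md <- function(config, draw_fn) {
  usable <- !config$pattern$locations$blind_spot
  for (i in 1:1000) {
    r <- round(draw_fn(), 1)  # perimeters report 0.1 dB resolution
    if (mean_defect(r[usable]) < config$md_cap) return(r)
  }
  stop_fmt("rejection sampling failed to satisfy MD < %g", config$md_cap)
}

#' Draw one synthetic control examination
#'
#' Deviations are a per-eye offset `N(control_offset_mean,
#' control_offset_sd^2)` plus iid per-location noise `N(0,
#' control_noise_sd^2)`, resampled until MD (blind spot excluded) is below the
#' cap. Uses the current RNG state; seed management belongs to the caller
#' (see [generate_dataset()]).
#'
#' @param config a [synth_config()].
#' @param offset optional fixed per-eye offset (drawn if `NULL`).
#' @return numeric deviation vector of length `L`, rounded to 0.1 dB.
#' @export
sample_control_vf <- function(config, offset = NULL) {
  offset <- offset %||% stats::rnorm(1, config$control_offset_mean,
                                     config$control_offset_sd)
  reject_md(config, function() control_background(config, offset))
}

#' Draw one synthetic early-glaucoma examination
#'
#' A control-style background plus additional loss at one archetype's
#' locations, `N(-depth, defect_depth_sd^2)` per location (negative = loss);
#' the `diffuse` archetype applies `diffuse_scale * depth` to every location.
#' MD < cap is enforced by rejection.
#'
#' @inheritParams sample_control_vf
#' @param archetype archetype name (drawn uniformly if `NULL`).
#' @param depth focal depth in dB (drawn from the config if `NULL`).
#' @return numeric deviation vector of length `L`, rounded to 0.1 dB.
#' @export
sample_eg_vf <- function(config, archetype = NULL, depth = NULL, offset = NULL) {
  archetype <- archetype %||% sample(names(config$defect_archetypes), 1)
  if (!archetype %in% names(config$defect_archetypes))
    stop_fmt("unknown archetype '%s'", archetype)
  offset <- offset %||% stats::rnorm(1, config$control_offset_mean,
                                     config$control_offset_sd)
  idx <- config$defect_archetypes[[archetype]]
  scale <- if (archetype == "diffuse") config$diffuse_scale else 1
  reject_md(config, function() {
    # a fresh eye-level depth per attempt, so rejection explores the part of
    # the defect distribution compatible with the inclusion cap
    d <- depth %||% stats::rnorm(1, config$defect_depth_mean,
                                 config$defect_depth_sd)
    r <- control_background(config, offset)
    r[idx] <- r[idx] + stats::rnorm(length(idx), -scale * d,
                                    config$defect_depth_sd)
    r
  })
}

# Largest eye-level defect depth whose expected MD stays a margin below the
# inclusion cap: deeper eyes would no longer qualify as early glaucoma.
eligible_depth_cap <- function(config, archetype, margin = 1) {
  idx <- config$defect_archetypes[[archetype]]
  scale <- if (archetype == "diffuse") config$diffuse_scale else 1
  usable <- sum(!config$pattern$locations$blind_spot)
  (config$md_cap - margin + config$control_offset_mean) * usable /
    (scale * length(idx))
}

#' Generate a labelled synthetic cohort
#'
#' Each subject contributes `eyes_per_subject` eyes with a random laterality
#' and a per-eye number of visits drawn from the configured range. An
#' early-glaucoma eye keeps one archetype across its visits while its defect
#' depth drifts as a slow random walk, giving longitudinally consistent
#' records. Deterministic under the config seed.
#'
#' @param config a [synth_config()].
#' @return list with `records` (a `"vf_table"`), `roster` (one row per
#'   subject/eye with group and archetype) and `config`.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  pattern <- config$pattern
  with_seed(config$seed, {
    rows <- list()
    roster <- list()
    for (group in c("control", "EG")) {
      for (s in seq_len(config$n_subjects)) {
        subject_id <- sprintf("%s_%03d", ifelse(group == "EG", "eg", "ct"), s)
        eyes <- if (config$eyes_per_subject == 2) c("OD", "OS")
                else sample(c("OD", "OS"), 1)
        for (eye in eyes) {
          visit_choices <- seq(config$visits_per_eye[1], config$visits_per_eye[2])
          n_visits <- visit_choices[sample.int(length(visit_choices), 1)]
          offset <- stats::rnorm(1, config$control_offset_mean,
                                 config$control_offset_sd)
          archetype <- NA_character_
          if (group == "EG") {
            archetype <- sample(names(config$defect_archetypes), 1)
            depth_cap <- eligible_depth_cap(config, archetype)
            depth <- min(stats::rnorm(1, config$defect_depth_mean,
                                      config$defect_depth_sd), depth_cap)
          }
          for (v in seq_len(n_visits)) {
            r <- if (group == "control") sample_control_vf(config, offset = offset)
                 else sample_eg_vf(config, archetype = archetype,
                                   depth = depth, offset = offset)
            if (group == "EG")
              depth <- min(depth + stats::rnorm(1, 0, config$depth_drift_sd),
                           depth_cap)
            row <- data.frame(subject_id = subject_id, eye = eye, group = group,
                              pattern_id = pattern$pattern_id,
                              stringsAsFactors = FALSE)
            row[vf_dev_cols(pattern$L)] <- as.list(r)
            rows[[length(rows) + 1]] <- row
          }
          roster[[length(roster) + 1]] <-
            data.frame(subject_id = subject_id, eye = eye, group = group,
                       archetype = archetype, n_visits = n_visits,
                       stringsAsFactors = FALSE)
        }
      }
    }
    records <- do.call(rbind, rows)
    class(records) <- c("vf_table", "data.frame")
    list(records = records, roster = do.call(rbind, roster), config = config)
  })
}
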