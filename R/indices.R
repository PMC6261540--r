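#' Mean defect (MD)
#'
#' The negative of the arithmetic mean of the sensitivity deviations, so that
#' loss (negative deviations) yields a positive MD. Blind-spot entries are
#' expected to be excluded upstream (see [global_indices()]).
#'
#' @param r numeric vector of sensitivity deviations in dB.
#' @return MD in dB.
#' @examples
#' mean_defect(c(-1, -2, -3))  # 2
#' @export
mean_defect <- function(r) {
  if (length(r) < 1) stop_fmt("mean_defect needs at least one deviation")
  if (!all(is.finite(r))) stop_fmt("mean_defect: deviations must be finite")
  -mean(r)
}

#' Square-root loss variance (sLV)
#'
#' The sample standard deviation (n - 1 denominator) of the sensitivity
#' deviations; a measure of visual-field inhomogeneity.
#'
#' @inheritParams mean_defect
#' @return sLV in dB (non-negative).
#' @export
slv <- function(r) {
  if (length(r) < 2) stop_fmt("slv needs at least two deviations")
  if (!all(is.finite(r))) stop_fmt("slv: deviations must be finite")
  stats::sd(r)
}

#' Global indices for every examination in a VF table
#'
#' Blind-spot locations are dropped before computing MD and sLV, matching
#' standard perimetric practice.
#'
#' @param records a `"vf_table"` data frame.
#' @param pattern the associated [test_pattern()].
#' @return data frame with columns `subject_id`, `eye`, `group`, `md`, `slv`
#'   and `r_bar` (the mean deviation before negation, `md = -r_bar`).
#' @export
global_indices <- function(records, pattern) {
  m <- vf_deviations(records, pattern, drop_blind_spot = TRUE)
  r_bar <- rowMeans(m)
  data.frame(subject_id = records$subject_id, eye = records$eye,
             group = records$group, md = -r_bar, slv = apply(m, 1, stats::sd),
             r_bar = r_bar, stringsAsFactors = FALSE)
}

#' Baseline classifier scores from global indices
#'
#' Returns per-record scores for the three index-based classifiers: MD, sLV
#' (raw index values; higher = more glaucomatous) and their combination
#' MD+sLV. The combination is a two-feature logistic model fitted on a
#' labelled training table when one is supplied; without labels a
#' parameter-free rank-sum of the two indices is used instead.
#'
#' @param records `"vf_table"` to score.
#' @param pattern the associated [test_pattern()].
#' @param train_records optional labelled `"vf_table"` used to fit the
#'   logistic MD+sLV fusion.
#' @param fusion `"logistic"` (needs `train_records`) or `"ranksum"`.
#' @return data frame with columns `md`, `slv`, `md_slv`.
#' @export
index_scores <- function(records, pattern, train_records = NULL,
                         fusion = c("logistic", "ranksum")) {
  fusion <- match.arg(fusion)
  gi <- global_indices(records, pattern)
  if (fusion == "logistic" && is.null(train_records)) fusion <- "ranksum"
  if (fusion == "logistic") {
    tr <- global_indices(train_records, pattern)
    if (anyNA(tr$group)) stop_fmt("index_scores: training records must be labelled")
    y <- as.integer(tr$group == "EG")
    if (length(unique(y)) < 2)
      stop_fmt("index_scores: training records must contain both classes")
    fit <- suppressWarnings(
      stats::glm(y ~ md + slv, data = cbind(tr, y = y), family = stats::binomial()))
    md_slv <- as.numeric(stats::predict(fit, newdata = gi, type = "response"))
  } else {
    md_slv <- rank(gi$md) + rank(gi$slv)
  }
  data.frame(md = gi$md, slv = gi$slv, md_slv = md_slv)
}
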