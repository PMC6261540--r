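# Fixtures are built in code at test time.

toy_pattern <- function(L = 5, seed = 1, blind = 0, integer_coords = FALSE) {
  set.seed(seed)
  repeat {
    if (integer_coords) {
      x <- sample(-29:29, L, replace = TRUE)
      y <- sample(-29:29, L, replace = TRUE)
    } else {
      x <- round(stats::runif(L, -29, 29), 2)
      y <- round(stats::runif(L, -29, 29), 2)
    }
    if (!any(duplicated(paste(x, y)))) break
  }
  bs <- rep(FALSE, L)
  if (blind > 0) bs[seq_len(blind)] <- TRUE
  test_pattern("toy", x, y, bs)
}

make_record <- function(r, subject = "s1", eye = "OD", group = "control",
                        pattern_id = "toy") {
  df <- data.frame(subject_id = subject, eye = eye, group = group,
                   pattern_id = pattern_id, stringsAsFactors = FALSE)
  df[paste0("d_", seq_along(r) - 1)] <- as.list(as.numeric(r))
  class(df) <- c("vf_table", "data.frame")
  df
}

# O(VI) = sum(w * VI): a differentiable scorer with a closed-form gradient.
linear_scorer <- function(w) {
  side <- as.integer(sqrt(length(w)))
  stopifnot(side * side == length(w))
  lin <- vorofield:::layer_dense(length(w), 1, head = TRUE)
  lin$W[, 1] <- as.vector(w)
  lin$b <- 0
  vorofield:::new_network(list(vorofield:::layer_flatten(length(w)), lin),
                          input = list(type = "image", side = side),
                          head = "linear")
}

# Separable image cohort: flat controls vs deep fixed scotoma, small noise.
separable_images <- function(n, seed = 1, depth = 20, noise = 0.5) {
  set.seed(seed)
  scotoma <- rep(FALSE, 3721)
  scotoma[sample(3721, 400)] <- TRUE
  y <- rep(c(0, 1), length.out = n)
  X <- matrix(stats::rnorm(3721 * n, sd = noise), 3721, n)
  for (i in which(y == 1)) X[scotoma, i] <- X[scotoma, i] - depth
  list(x = X, y = y, scotoma = scotoma)
}

small_cohort <- function(n_subjects = 6, visits = 2, seed = 7, depth = 12,
                         pattern = builtin_pattern("24-2")) {
  cfg <- synth_config(pattern, n_subjects = n_subjects,
                      visits_per_eye = c(visits, visits),
                      defect_depth_mean = depth, seed = seed)
  generate_dataset(cfg)
}
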