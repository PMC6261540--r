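# Saliency maps: which regions of a voronoi image drive the classifier score.

as_saliency <- function(values, kind, normalized = FALSE) {
  structure(list(values = values, kind = kind, normalized = normalized),
            class = "vf_saliency")
}

resolve_net <- function(model) {
  if (inherits(model, "vf_model")) model$network
  else if (inherits(model, "vf_network")) model
  else stop_fmt("model must be a vf_model or vf_network")
}

vi_values <- function(vi) {
  v <- if (inherits(vi, "voronoi_image")) vi$values else vi
  if (!is.matrix(v)) stop_fmt("expected a voronoi image or a numeric matrix")
  v
}

#' Gradient saliency map
#'
#' The per-pixel partial derivative of the model's output score (the
#' early-glaucoma probability) with respect to the input image, evaluated in
#' inference mode. Raw and signed: positive values mark pixels whose increase
#' raises the score.
#'
#' @param model a trained `"vf_model"` (or a `"vf_network"`).
#' @param vi a `"voronoi_image"` or 61x61 numeric matrix.
#' @return A `"vf_saliency"` object with the same dimensions as the input,
#'   `kind = "gradient"`, unnormalized.
#' @export
gradient_map <- function(model, vi) {
  net <- resolve_net(model)
  if (net$input$type != "image")
    stop_fmt("gradient maps are defined for image-input models")
  v <- vi_values(vi)
  g <- net_input_gradient(net, matrix(as.vector(v), ncol = 1))
  as_saliency(matrix(g, nrow(v), ncol(v)), "gradient")
}

#' SmoothGrad saliency map
#'
#' Averages `n` gradient maps computed at Gaussian-perturbed copies of the
#' input. The noise scale adapts to the image: `sigma = sigma_r * (max(VI) -
#' min(VI))`, so a constant image degenerates to the plain gradient.
#'
#' @inheritParams gradient_map
#' @param n number of noise samples (default 500).
#' @param sigma_r noise level ratio (default 0.05).
#' @param seed seeds the noise for bit-reproducible maps.
#' @param batch internal batch size for the perturbed forward/backward passes.
#' @return A `"vf_saliency"` with `kind = "smoothgrad"`, unnormalized.
#' @export
smoothgrad <- function(model, vi, n = 500, sigma_r = 0.05, seed = 1,
                       batch = 64L) {
  if (!is_count(n)) stop_fmt("n must be a positive integer")
  if (sigma_r < 0) stop_fmt("sigma_r must be non-negative")
  net <- resolve_net(model)
  v <- vi_values(vi)
  sigma <- sigma_r * (max(v) - min(v))
  if (sigma == 0) {
    g <- gradient_map(model, vi)
    return(as_saliency(g$values, "smoothgrad"))
  }
  npix <- length(v)
  acc <- numeric(npix)
  with_seed(seed, {
    done <- 0L
    while (done < n) {
      b <- min(batch, n - done)
      X <- matrix(as.vector(v), npix, b) +
        matrix(stats::rnorm(npix * b, sd = sigma), npix, b)
      G <- net_input_gradient(net, X)
      acc <- acc + rowSums(G)
      done <- done + b
    }
  })
  as_saliency(matrix(acc / n, nrow(v), ncol(v)), "smoothgrad")
}

#' Piece-wise saliency map
#'
#' Replaces every pixel of a saliency map by the mean over its voronoi region,
#' giving one value per tested location. Idempotent; the result is constant
#' within regions.
#'
#' @param map a `"vf_saliency"` (typically a SmoothGrad map).
#' @param region_map the [region_assignment()] the image was built with.
#' @return A `"vf_saliency"` with `kind = "piecewise"`, same normalization
#'   state as the input.
#' @export
piecewise_map <- function(map, region_map) {
  stopifnot(inherits(map, "vf_saliency"), inherits(region_map, "vf_region_map"))
  if (!all(dim(map$values) == dim(region_map$assignment)))
    stop_fmt("saliency map (%dx%d) and region map (%dx%d) dimensions differ",
             nrow(map$values), ncol(map$values),
             nrow(region_map$assignment), ncol(region_map$assignment))
  f <- factor(as.vector(region_map$assignment))
  means <- tapply(as.vector(map$values), f, mean)
  out <- matrix(as.numeric(means[as.character(f)]), nrow(map$values),
                ncol(map$values))
  as_saliency(out, "piecewise", normalized = map$normalized)
}

#' Min-max normalize a saliency map to the unit interval
#'
#' 0 marks no influence and 1 maximal influence within this map. A constant
#' raw map normalizes to all zeros (no pixel is more influential than any
#' other).
#'
#' @param map a `"vf_saliency"`.
#' @return The map rescaled to `[0, 1]` with `normalized = TRUE`.
#' @export
normalize_map <- function(map) {
  stopifnot(inherits(map, "vf_saliency"))
  v <- map$values
  if (!all(is.finite(v))) stop_fmt("saliency values must be finite")
  rng <- range(v)
  v <- if (rng[1] == rng[2]) v * 0 else (v - rng[1]) / (rng[2] - rng[1])
  as_saliency(v, map$kind, normalized = TRUE)
}

#' Full saliency pipeline for one examination
#'
#' Convenience wrapper: SmoothGrad, then region averaging, then min-max
#' normalization of both maps.
#'
#' @inheritParams smoothgrad
#' @param region_map the [region_assignment()] used for the piece-wise map.
#' @return list with normalized `smoothgrad` and `piecewise` maps.
#' @export
saliency_maps <- function(model, vi, region_map, n = 500, sigma_r = 0.05,
                          seed = 1) {
  sg <- smoothgrad(model, vi, n = n, sigma_r = sigma_r, seed = seed)
  list(smoothgrad = normalize_map(sg),
       piecewise = normalize_map(piecewise_map(sg, region_map)))
}

#' @export
print.vf_saliency <- function(x, ...) {
  cat(sprintf("%s saliency map (%dx%d), %s, range [%.4g, %.4g]\n",
              x$kind, nrow(x$values), ncol(x$values),
              if (x$normalized) "normalized" else "raw",
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
plot.vf_saliency <- function(x, main = NULL, ...) {
  plot_field_matrix(x$values,
                    main = main %||% sprintf("%s saliency", x$kind),
                    col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE), ...)
}
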