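# Minimal sequential neural-network engine used by the CNN and the flat NN.
#
# Spatial activations are stored as (npix * B) x C matrices with row index
# b * npix + p (p column-major within the square image), vector activations as
# B x D matrices. 3x3 convolutions use "same" padding; max pooling is 2x2,
# stride 2, ceil semantics (61 -> 31 -> 16). Heavy kernels live in src/.

.nn_maps <- new.env(parent = emptyenv())

# Column-wise affine ops without sweep()'s aperm overhead.
scale_cols <- function(A, s) A * rep(s, each = nrow(A))
shift_cols <- function(A, s) A + rep(s, each = nrow(A))

conv_neighbors <- function(side) {
  key <- paste0("nb", side)
  if (!is.null(.nn_maps[[key]])) return(.nn_maps[[key]])
  i <- rep(seq_len(side), times = side)
  j <- rep(seq_len(side), each = side)
  nb <- matrix(0L, side * side, 9L)
  k <- 0L
  for (dj in -1:1) for (di in -1:1) {
    k <- k + 1L
    ii <- i + di; jj <- j + dj
    ok <- ii >= 1 & ii <= side & jj >= 1 & jj <= side
    nb[ok, k] <- (jj[ok] - 1L) * side + ii[ok]
  }
  .nn_maps[[key]] <- nb
  nb
}

pool_members <- function(side_in) {
  key <- paste0("pm", side_in)
  if (!is.null(.nn_maps[[key]])) return(.nn_maps[[key]])
  side_out <- ceiling(side_in / 2)
  pm <- matrix(0L, side_out * side_out, 4L)
  q <- 0L
  for (oj in seq_len(side_out)) for (oi in seq_len(side_out)) {
    q <- q + 1L
    m <- 0L
    for (dj in 0:1) for (di in 0:1) {
      ii <- 2L * oi - 1L + di; jj <- 2L * oj - 1L + dj
      if (ii <= side_in && jj <= side_in) {
        m <- m + 1L
        pm[q, m] <- (jj - 1L) * side_in + ii
      }
    }
  }
  .nn_maps[[key]] <- pm
  pm
}

# ---- layer constructors (He init for ReLU layers, Glorot for the head) ----

layer_conv <- function(cin, cout, side) {
  list(type = "conv", side = side, cin = cin, cout = cout,
       W = array(stats::rnorm(9 * cin * cout, sd = sqrt(2 / (9 * cin))),
                 dim = c(9, cin, cout)),
       b = rep(0, cout))
}

layer_bn <- function(c) {
  list(type = "bn", c = c, gamma = rep(1, c), beta = rep(0, c),
       run_mean = rep(0, c), run_var = rep(1, c), eps = 1e-5, momentum = 0.1)
}

layer_relu <- function() list(type = "relu")

layer_pool <- function(side_in) {
  list(type = "pool", side_in = side_in, side_out = as.integer(ceiling(side_in / 2)))
}

layer_gap <- function(side) list(type = "gap", side = side)

# Reshapes (npix * B) x 1 spatial activations to B x npix rows (used by
# models that apply dense layers directly to the raster).
layer_flatten <- function(npix) list(type = "flatten", npix = npix)

layer_dense <- function(din, dout, head = FALSE) {
  sd <- if (head) sqrt(2 / (din + dout)) else sqrt(2 / din)
  list(type = "dense", din = din, dout = dout,
       W = matrix(stats::rnorm(din * dout, sd = sd), din, dout),
       b = rep(0, dout))
}

layer_dropout <- function(p) list(type = "dropout", p = p)

new_network <- function(layers, input, head = c("sigmoid", "linear"), kind = "custom") {
  structure(list(layers = layers, input = input, head = match.arg(head),
                 kind = kind),
            class = "vf_network")
}

n_params <- function(net) {
  sum(vapply(net$layers, function(l) switch(l$type,
    conv = length(l$W) + length(l$b),
    dense = length(l$W) + length(l$b),
    bn = length(l$gamma) + length(l$beta),
    0L), numeric(1)))
}

#' @export
print.vf_network <- function(x, ...) {
  cat(sprintf("vf_network (%s): %d layers, %d trainable parameters, %s head\n",
              x$kind, length(x$layers), n_params(x), x$head))
  invisible(x)
}

# ---- forward ----

# X: (npix x B) matrix for image input, (B x D) for vector input.
net_forward <- function(net, X, training = FALSE, want_cache = FALSE) {
  if (net$input$type == "image") {
    B <- ncol(X)
    A <- matrix(as.vector(X), ncol = 1L)
  } else {
    B <- nrow(X)
    A <- X
  }
  caches <- if (want_cache) vector("list", length(net$layers)) else NULL
  for (li in seq_along(net$layers)) {
    l <- net$layers[[li]]
    if (l$type == "conv") {
      Y <- conv2d_fwd_cpp(A, l$side, as.numeric(l$W), l$b, B)
      if (want_cache) caches[[li]] <- list(A = A)
    } else if (l$type == "bn") {
      if (training) {
        res <- bn_fwd_train_cpp(A, l$gamma, l$beta, l$eps)
        Y <- res$Y
        m <- l$momentum
        net$layers[[li]]$run_mean <- (1 - m) * l$run_mean + m * res$mu
        net$layers[[li]]$run_var <- (1 - m) * l$run_var + m * res$v
        if (want_cache) caches[[li]] <- list(xhat = res$xhat, istd = res$istd)
      } else {
        scale <- l$gamma / sqrt(l$run_var + l$eps)
        Y <- affine_cols_cpp(A, scale, l$beta - l$run_mean * scale)
        if (want_cache) caches[[li]] <- list(scale = scale)
      }
    } else if (l$type == "relu") {
      Y <- relu_fwd_cpp(A)
      if (want_cache) caches[[li]] <- list(out = Y)
    } else if (l$type == "pool") {
      res <- maxpool_fwd_cpp(A, pool_members(l$side_in), l$side_in^2, B)
      Y <- res$Y
      if (want_cache) caches[[li]] <- list(arg = res$arg)
    } else if (l$type == "gap") {
      npix <- l$side^2
      Y <- rowsum(A, rep(seq_len(B), each = npix), reorder = FALSE) / npix
      dimnames(Y) <- NULL
    } else if (l$type == "flatten") {
      Y <- t(matrix(A, l$npix, B))
    } else if (l$type == "dense") {
      Y <- shift_cols(A %*% l$W, l$b)
      if (want_cache) caches[[li]] <- list(A = A)
    } else if (l$type == "dropout") {
      if (training) {
        keep <- matrix(stats::runif(length(A)) >= l$p, nrow(A)) / (1 - l$p)
        Y <- A * keep
        if (want_cache) caches[[li]] <- list(keep = keep)
      } else Y <- A
    } else stop_fmt("unknown layer type '%s'", l$type)
    A <- Y
  }
  z <- as.numeric(A)
  score <- if (net$head == "sigmoid") stats::plogis(z) else z
  list(z = z, score = score, caches = caches, B = B, net = net)
}

# ---- backward (training): parameter gradients + optional input gradient ----

net_backward <- function(net, fw, dZ, want_input_grad = FALSE) {
  B <- fw$B
  grads <- vector("list", length(net$layers))
  dY <- matrix(dZ, ncol = 1L)
  for (li in rev(seq_along(net$layers))) {
    l <- net$layers[[li]]
    cc <- fw$caches[[li]]
    if (l$type == "dense") {
      grads[[li]] <- list(W = crossprod(cc$A, dY), b = colSums(dY))
      dY <- dY %*% t(l$W)
    } else if (l$type == "dropout") {
      if (!is.null(cc)) dY <- dY * cc$keep
    } else if (l$type == "flatten") {
      dY <- matrix(t(dY), ncol = 1L)
    } else if (l$type == "gap") {
      npix <- l$side^2
      dY <- (dY / npix)[rep(seq_len(B), each = npix), , drop = FALSE]
    } else if (l$type == "pool") {
      dY <- maxpool_bwd_cpp(dY, cc$arg, l$side_in^2, B)
    } else if (l$type == "relu") {
      dY <- relu_bwd_cpp(dY, cc$out)
    } else if (l$type == "bn") {
      if (!is.null(cc$xhat)) {
        res <- bn_bwd_train_cpp(dY, cc$xhat, cc$istd, l$gamma)
        grads[[li]] <- list(gamma = res$dgamma, beta = res$dbeta)
        dY <- res$dX
      } else {
        dY <- scale_cols(dY, cc$scale)
      }
    } else if (l$type == "conv") {
      res <- conv2d_bwd_cpp(cc$A, l$side, as.numeric(l$W), dY, B)
      grads[[li]] <- list(W = array(res$dW, dim = dim(l$W)), b = res$db)
      dY <- res$dA
    }
  }
  list(grads = grads, dX = dY)
}

# Input gradient of the head score in inference mode (frozen model).
net_input_gradient <- function(net, X) {
  fw <- net_forward(net, X, training = FALSE, want_cache = TRUE)
  dZ <- if (net$head == "sigmoid") fw$score * (1 - fw$score) else rep(1, length(fw$z))
  B <- fw$B
  dY <- matrix(dZ, ncol = 1L)
  for (li in rev(seq_along(net$layers))) {
    l <- net$layers[[li]]
    cc <- fw$caches[[li]]
    if (l$type == "dense") dY <- dY %*% t(l$W)
    else if (l$type == "flatten") dY <- matrix(t(dY), ncol = 1L)
    else if (l$type == "dropout") NULL
    else if (l$type == "gap") {
      npix <- l$side^2
      dY <- (dY / npix)[rep(seq_len(B), each = npix), , drop = FALSE]
    } else if (l$type == "pool") dY <- maxpool_bwd_cpp(dY, cc$arg, l$side_in^2, B)
    else if (l$type == "relu") dY <- relu_bwd_cpp(dY, cc$out)
    else if (l$type == "bn") dY <- scale_cols(dY, cc$scale)
    else if (l$type == "conv")
      dY <- conv2d_bwd_input_cpp(l$side, as.numeric(l$W), dY, l$cin, B)
  }
  if (net$input$type == "image") matrix(as.numeric(dY), ncol = B) else dY
}

# ---- Adam ----

adam_init <- function(net) {
  lapply(net$layers, function(l) {
    nm <- switch(l$type, conv = c("W", "b"), dense = c("W", "b"),
                 bn = c("gamma", "beta"), NULL)
    if (is.null(nm)) return(NULL)
    st <- lapply(nm, function(p) list(m = l[[p]] * 0, v = l[[p]] * 0))
    names(st) <- nm
    st
  })
}

adam_step <- function(net, grads, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  for (li in seq_along(net$layers)) {
    g <- grads[[li]]
    if (is.null(g)) next
    for (p in names(state[[li]])) {
      gp <- g[[p]]
      st <- state[[li]][[p]]
      st$m <- beta1 * st$m + (1 - beta1) * gp
      st$v <- beta2 * st$v + (1 - beta2) * gp^2
      net$layers[[li]][[p]] <- net$layers[[li]][[p]] -
        lr * (st$m / bc1) / (sqrt(st$v / bc2) + eps)
      state[[li]][[p]] <- st
    }
  }
  list(net = net, state = state)
}

# ---- loss / scoring helpers ----

bce_loss <- function(score, y) {
  p <- pmin(pmax(score, 1e-12), 1 - 1e-12)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

# Inference scores in chunks so memory stays flat for large tables.
predict_network <- function(net, X, chunk = 256L) {
  n <- if (net$input$type == "image") ncol(X) else nrow(X)
  out <- numeric(n)
  for (s in seq(1, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    Xi <- if (net$input$type == "image") X[, s:e, drop = FALSE]
          else X[s:e, , drop = FALSE]
    out[s:e] <- net_forward(net, Xi, training = FALSE)$score
  }
  out
}

# ---- training loop with best-validation-loss checkpointing ----

train_network <- function(net, X, y, Xval, yval, epochs = 100, batch_size = 32,
                          lr = 1e-3, seed = 1, verbose = FALSE) {
  n <- if (net$input$type == "image") ncol(X) else nrow(X)
  state <- adam_init(net)
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric())
  best <- list(loss = Inf, layers = net$layers, epoch = 0L)
  t <- 0L
  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      perm <- sample.int(n)
      tr_loss <- 0
      nb <- 0L
      for (s in seq(1, n, by = batch_size)) {
        idx <- perm[s:min(s + batch_size - 1L, n)]
        Xi <- if (net$input$type == "image") X[, idx, drop = FALSE]
              else X[idx, , drop = FALSE]
        yi <- y[idx]
        fw <- net_forward(net, Xi, training = TRUE, want_cache = TRUE)
        net <- fw$net  # batch-norm running stats advanced
        tr_loss <- tr_loss + bce_loss(fw$score, yi)
        nb <- nb + 1L
        dZ <- (fw$score - yi) / length(yi)
        bw <- net_backward(net, fw, dZ)
        t <- t + 1L
        upd <- adam_step(net, bw$grads, state, lr, t)
        net <- upd$net
        state <- upd$state
      }
      val_loss <- bce_loss(predict_network(net, Xval), yval)
      history <- rbind(history, data.frame(epoch = ep, train_loss = tr_loss / nb,
                                           val_loss = val_loss))
      if (val_loss < best$loss)
        best <- list(loss = val_loss, layers = net$layers, epoch = ep)
      if (verbose)
        message(sprintf("epoch %3d  train %.4f  val %.4f", ep, tr_loss / nb,
                        val_loss))
    }
  })
  net$layers <- best$layers
  list(network = net, history = history, selected_epoch = best$epoch)
}
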