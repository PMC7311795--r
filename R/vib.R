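# Deep variational information bottleneck (VIB) crop classifier and its
# matched cross-entropy baseline.
#
# The encoder maps a crop x to a diagonal Gaussian posterior
# p(z|x) = N(mu(x), diag(sigma(x)^2)): it outputs a 2K vector whose first K
# entries are mu and whose last K entries pass through a softplus to give
# sigma. The decoder is a linear map from z to 2 class logits followed by a
# softmax. Training minimizes the variational classification bound (a
# Monte-Carlo estimate of E[-log q(y|z)] via the reparameterization trick)
# plus beta times the rate term KL(p(z|x) || r(z)) with r(z) = N(0, I).
# The baseline shares the encoder backbone and linear head but decodes the
# mean deterministically with plain cross-entropy: the only difference is
# the bottleneck (sampling + KL).

#' Classifier configuration
#'
#' @param use_vib `TRUE` for the VIB model, `FALSE` for the matched
#'   cross-entropy baseline.
#' @param K bottleneck dimension.
#' @param beta Lagrange multiplier on the rate term (ignored by the
#'   baseline).
#' @param encoder `"conv"` for the small convolutional encoder (two
#'   valid-padding conv + mean-pool blocks, then a linear map to 2K),
#'   `"mlp"` for a one-hidden-layer fully-connected encoder.
#' @param hidden encoder hidden-layer width (`"mlp"` encoder only).
#' @param conv_filters filter counts of the two conv blocks.
#' @param conv_kernels kernel sizes of the two conv blocks.
#' @param epochs,lr,batch_size Adam training settings.
#' @param n_mc Monte-Carlo samples per example during training.
#' @param crop_size classifier input side length in pixels (crops are
#'   resized to `crop_size x crop_size`).
#' @return A `classifier_config` list.
#' @export
classifier_config <- function(use_vib = FALSE, K = 32, beta = 1e-3,
                              encoder = c("conv", "mlp"), hidden = 64,
                              conv_filters = c(8L, 16L),
                              conv_kernels = c(5L, 3L),
                              epochs = 40, lr = 1e-3,
                              batch_size = 32, n_mc = 1, crop_size = 32) {
  encoder <- match.arg(encoder)
  stop_if_not(beta >= 0, "beta must be non-negative")
  stop_if_not(n_mc >= 1, "n_mc must be at least 1")
  structure(as.list(environment()), class = "classifier_config")
}

# Precomputed geometry (index maps) of the conv encoder for one crop size.
conv_geometry <- function(S, filters, kernels) {
  h1 <- S - kernels[1] + 1L
  stop_if_not(h1 %% 2L == 0L, "conv1 output must be even for 2x2 pooling")
  p1 <- h1 %/% 2L
  h2 <- p1 - kernels[2] + 1L
  stop_if_not(h2 %% 2L == 0L, "conv2 output must be even for 2x2 pooling")
  p2 <- h2 %/% 2L
  list(
    idx1 = im2col_index(S, S, 1L, kernels[1]),
    pool1 = pool_index(h1, h1, filters[1]),
    idx2 = im2col_index(p1, p1, filters[1], kernels[2]),
    pool2 = pool_index(h2, h2, filters[2]),
    n1 = h1 * h1 * filters[1], np1 = p1 * p1 * filters[1],
    n2 = h2 * h2 * filters[2], flat = p2 * p2 * filters[2]
  )
}

# Encoder forward pass. X is n x D in [0,1]; features are centred at 0.5.
encoder_forward <- function(model, X) {
  p <- model$params
  XC <- X - 0.5
  K <- model$K
  if (model$encoder == "conv") {
    g <- model$geometry
    fw1 <- conv_forward(XC, p$C1, p$c1, g$idx1)
    P1 <- mean_pool(fw1$act, g$pool1)
    fw2 <- conv_forward(P1, p$C2, p$c2, g$idx2)
    P2 <- mean_pool(fw2$act, g$pool2)
    O <- sweep(P2 %*% p$W2, 2, p$b2, "+")
    list(XC = XC, fw1 = fw1, P1 = P1, fw2 = fw2, P2 = P2, O = O,
         mu = O[, 1:K, drop = FALSE],
         sp = O[, (K + 1):(2 * K), drop = FALSE])
  } else {
    H <- relu(sweep(XC %*% p$W1, 2, p$b1, "+"))
    O <- sweep(H %*% p$W2, 2, p$b2, "+")
    list(XC = XC, H = H, O = O,
         mu = O[, 1:K, drop = FALSE],
         sp = O[, (K + 1):(2 * K), drop = FALSE])
  }
}

# Gradients of the encoder parameters given dLoss/dO.
encoder_backward <- function(model, fw, dO) {
  p <- model$params
  if (model$encoder == "conv") {
    g <- model$geometry
    dP2 <- dO %*% t(p$W2)
    gW2 <- crossprod(fw$P2, dO)
    gb2 <- colSums(dO)
    dA2 <- mean_unpool(dP2, g$pool2, g$n2)
    bk2 <- conv_backward(dA2, fw$fw2, p$C2, g$idx2, g$np1, need_dX = TRUE)
    dA1 <- mean_unpool(bk2$dX, g$pool1, g$n1)
    bk1 <- conv_backward(dA1, fw$fw1, p$C1, g$idx1, ncol(fw$XC),
                         need_dX = FALSE)
    list(C1 = bk1$gW, c1 = bk1$gb, C2 = bk2$gW, c2 = bk2$gb,
         W2 = gW2, b2 = gb2)
  } else {
    gW2 <- crossprod(fw$H, dO)
    gb2 <- colSums(dO)
    dH <- (dO %*% t(p$W2)) * (fw$H > 0)
    list(W1 = crossprod(fw$XC, dH), b1 = colSums(dH),
         W2 = gW2, b2 = gb2)
  }
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

#' Encode a crop into its Gaussian posterior
#'
#' @param model a trained classifier (VIB or baseline; both expose the same
#'   2K-output encoder contract).
#' @param crop a `crop_size x crop_size` matrix or a numeric vector of
#'   length `crop_size^2`.
#' @return A `sono_posterior`: list with `mu` and `sigma` (K-vectors,
#'   `sigma > 0` elementwise).
#' @export
encode <- function(model, crop) {
  x <- as.numeric(crop)
  stop_if_not(length(x) == model$input_dim,
              sprintf("crop must have %d pixels (%d x %d)", model$input_dim,
                      model$crop_size, model$crop_size))
  fw <- encoder_forward(model, matrix(x, nrow = 1))
  structure(list(mu = as.numeric(fw$mu),
                 sigma = as.numeric(softplus(fw$sp))),
            class = "sono_posterior")
}

#' KL divergence from a diagonal Gaussian posterior to N(0, I)
#'
#' Closed form: `0.5 * sum(mu^2 + sigma^2 - 1 - 2*log(sigma))`. This is the
#' per-sample rate term of the VIB objective, with the variational marginal
#' `r(z) = N(0, I)`.
#'
#' @param post a `sono_posterior` (or any list with `mu`, `sigma`).
#' @return Non-negative scalar.
#' @export
kl_to_standard_normal <- function(post) {
  stop_if_not(all(post$sigma > 0), "sigma must be strictly positive")
  0.5 * sum(post$mu^2 + post$sigma^2 - 1 - 2 * log(post$sigma))
}

# Per-row KL for matrices mu, sigma.
kl_rows <- function(mu, sigma) {
  0.5 * rowSums(mu^2 + sigma^2 - 1 - 2 * log(sigma))
}

#' Evaluate the VIB loss terms on a batch
#'
#' `class_term` is the Monte-Carlo estimate (over `n_mc` reparameterized
#' samples) of the expected negative log-likelihood `E[-log q(y|z)]`;
#' `rate_term` is the batch-mean KL to `N(0, I)`; `total` is exactly
#' `class_term + beta * rate_term`.
#'
#' @param model a trained or freshly initialized classifier.
#' @param x `n x D` crop matrix; `y` integer labels in `{0, 1}`.
#' @param n_mc Monte-Carlo samples (at least 1).
#' @param seed integer seed for the reparameterization draws.
#' @return A `VIBLossTerms` list: `class_term`, `rate_term`, `beta`,
#'   `total`.
#' @export
vib_loss <- function(model, x, y, n_mc = 1L, seed = 1L) {
  stop_if_not(NROW(x) > 0, "batch must be non-empty")
  stop_if_not(n_mc >= 1, "n_mc must be at least 1")
  fw <- encoder_forward(model, x)
  sigma <- softplus(fw$sp)
  n <- nrow(x); K <- model$K
  p <- model$params
  ce <- with_seed(seed, {
    tot <- 0
    for (s in seq_len(n_mc)) {
      z <- if (model$type == "vib") {
        fw$mu + sigma * matrix(rnorm(n * K), n, K)
      } else {
        fw$mu
      }
      P <- softmax_rows(sweep(z %*% p$W3, 2, p$b3, "+"))
      tot <- tot + mean(-log(pmax(P[cbind(seq_len(n), y + 1L)], 1e-12)))
    }
    tot / n_mc
  })
  rate <- mean(kl_rows(fw$mu, sigma))
  beta <- if (model$type == "vib") model$beta else 0
  structure(list(class_term = ce, rate_term = rate, beta = beta,
                 total = ce + beta * rate), class = "sono_vib_loss")
}

#' Train a VIB or baseline crop classifier
#'
#' Both model kinds share the encoder backbone (input -> hidden ReLU ->
#' 2K linear) and a linear decoder head to 2 logits. The VIB model samples
#' `z = mu + sigma * eps` through the reparameterization trick and adds
#' `beta * KL(p(z|x) || N(0, I))` to the cross-entropy; the baseline
#' decodes `z = mu` deterministically with plain cross-entropy.
#'
#' @param x `n x D` matrix of crops in `[0, 1]` (`D = crop_size^2`).
#' @param y integer labels in `{0, 1}`; both classes must be present.
#' @param config a [classifier_config()].
#' @param seed integer seed.
#' @return A `sono_classifier` with fitted `params` and a per-batch
#'   `loss_log` data frame (`epoch`, `batch`, `class_term`, `rate_term`,
#'   `total`).
#' @export
train_classifier <- function(x, y, config = classifier_config(), seed = 1L) {
  stop_if_not(length(unique(y)) == 2, "both classes must be present in training data")
  n <- nrow(x); D <- ncol(x); K <- config$K
  stop_if_not(D == config$crop_size^2, "x columns must equal crop_size^2")
  seeds <- child_seeds(seed, 2L)
  geometry <- NULL
  if (config$encoder == "conv") {
    geometry <- conv_geometry(config$crop_size, config$conv_filters,
                              config$conv_kernels)
    k1 <- config$conv_kernels[1]; k2 <- config$conv_kernels[2]
    f1 <- config$conv_filters[1]; f2 <- config$conv_filters[2]
    params <- with_seed(seeds[1], list(
      C1 = matrix(rnorm(k1^2 * f1) * sqrt(2 / k1^2), k1^2, f1),
      c1 = numeric(f1),
      C2 = matrix(rnorm(k2^2 * f1 * f2) * sqrt(2 / (k2^2 * f1)),
                  k2^2 * f1, f2),
      c2 = numeric(f2),
      W2 = matrix(rnorm(geometry$flat * 2 * K) * sqrt(2 / geometry$flat),
                  geometry$flat, 2 * K),
      b2 = numeric(2 * K),
      W3 = matrix(rnorm(K * 2) * sqrt(1 / K), K, 2),
      b3 = numeric(2)
    ))
  } else {
    init <- mlp_init(c(D, config$hidden, 2 * K), seeds[1])
    dec <- with_seed(seeds[1] + 1L, list(
      W3 = matrix(rnorm(K * 2) * sqrt(1 / K), K, 2),
      b3 = numeric(2)
    ))
    params <- c(init[c("W1", "b1", "W2", "b2")], dec)
    names(params) <- c("W1", "b1", "W2", "b2", "W3", "b3")
  }
  model <- structure(list(
    type = if (config$use_vib) "vib" else "baseline",
    K = K, beta = if (config$use_vib) config$beta else 0,
    encoder = config$encoder, geometry = geometry,
    hidden = config$hidden, input_dim = D, crop_size = config$crop_size,
    params = params, config = config
  ), class = "sono_classifier")

  state <- adam_init(params)
  log_rows <- list()
  with_seed(seeds[2], {
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      bi <- 0L
      for (start in seq(1, n, by = config$batch_size)) {
        bidx <- ord[start:min(start + config$batch_size - 1, n)]
        upd <- classifier_batch_step(model, x[bidx, , drop = FALSE],
                                     y[bidx], config$n_mc)
        state <- adam_step(model$params, upd$grads, state, config$lr)
        model$params <- state$params
        bi <- bi + 1L
        log_rows[[length(log_rows) + 1L]] <-
          c(epoch = ep, batch = bi, class_term = upd$class_term,
            rate_term = upd$rate_term, total = upd$total)
      }
    }
  })
  model$loss_log <- as.data.frame(do.call(rbind, log_rows))
  model
}

# One forward/backward pass on a minibatch. Uses the caller's RNG stream.
classifier_batch_step <- function(model, X, y, n_mc) {
  p <- model$params
  K <- model$K
  n <- nrow(X)
  fw <- encoder_forward(model, X)
  Y <- matrix(0, n, 2); Y[cbind(seq_len(n), y + 1L)] <- 1

  if (model$type == "vib") {
    sigma <- softplus(fw$sp)
    dW3 <- p$W3 * 0; db3 <- p$b3 * 0
    dmu <- fw$mu * 0; dsigma <- sigma * 0
    ce <- 0
    for (s in seq_len(n_mc)) {
      eps <- matrix(rnorm(n * K), n, K)
      z <- fw$mu + sigma * eps
      P <- softmax_rows(sweep(z %*% p$W3, 2, p$b3, "+"))
      ce <- ce + mean(-log(pmax(P[cbind(seq_len(n), y + 1L)], 1e-12)))
      dlogits <- (P - Y) / (n * n_mc)
      dW3 <- dW3 + crossprod(z, dlogits)
      db3 <- db3 + colSums(dlogits)
      dz <- dlogits %*% t(p$W3)
      dmu <- dmu + dz
      dsigma <- dsigma + dz * eps
    }
    ce <- ce / n_mc
    rate <- mean(kl_rows(fw$mu, sigma))
    dmu <- dmu + model$beta * fw$mu / n
    dsigma <- dsigma + model$beta * (sigma - 1 / sigma) / n
    dsp <- dsigma * sigmoid(fw$sp)
    dO <- cbind(dmu, dsp)
    total <- ce + model$beta * rate
  } else {
    feat <- fw$mu
    P <- softmax_rows(sweep(feat %*% p$W3, 2, p$b3, "+"))
    ce <- mean(-log(pmax(P[cbind(seq_len(n), y + 1L)], 1e-12)))
    dlogits <- (P - Y) / n
    dW3 <- crossprod(feat, dlogits)
    db3 <- colSums(dlogits)
    dfeat <- dlogits %*% t(p$W3)
    dO <- cbind(dfeat, matrix(0, n, K))
    rate <- 0
    total <- ce
  }

  enc <- encoder_backward(model, fw, dO)
  list(grads = c(enc, list(W3 = dW3, b3 = db3)),
       class_term = ce, rate_term = rate, total = total)
}

#' Predict class probabilities for crops
#'
#' @param model a trained `sono_classifier`.
#' @param x `n x D` crop matrix.
#' @param mode `"mean"` decodes deterministically at `z = mu`; `"sample"`
#'   averages softmax outputs over `n_samples` posterior draws.
#' @param n_samples draws for `mode = "sample"`.
#' @param seed integer seed for sampling mode.
#' @return `n x 2` matrix of class probabilities (rows sum to 1); column 2
#'   is the positive (nodule) class.
#' @export
predict_classifier <- function(model, x, mode = c("mean", "sample"),
                               n_samples = 64L, seed = 1L) {
  mode <- match.arg(mode)
  p <- model$params
  fw <- encoder_forward(model, x)
  n <- nrow(x); K <- model$K
  if (mode == "mean" || model$type == "baseline") {
    if (mode == "sample" && model$type == "baseline") mode <- "mean"
    z <- fw$mu
    return(softmax_rows(sweep(z %*% p$W3, 2, p$b3, "+")))
  }
  stop_if_not(n_samples >= 1, "n_samples must be at least 1")
  sigma <- softplus(fw$sp)
  with_seed(seed, {
    acc <- matrix(0, n, 2)
    for (s in seq_len(n_samples)) {
      z <- fw$mu + sigma * matrix(rnorm(n * K), n, K)
      acc <- acc + softmax_rows(sweep(z %*% p$W3, 2, p$b3, "+"))
    }
    acc / n_samples
  })
}
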