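## Per-organ binary 2D encoder-decoder segmentation network.
##
## The network is a U-shaped fully convolutional model: five conv+ReLU+pool
## encoder stages, a bottleneck conv, and a decoder of exactly five nearest-
## neighbour upsampling stages, each followed by a skip concatenation and a
## conv+ReLU, closing with a 1x1 conv and a sigmoid. Forward and backward
## passes run through the compiled im2col/GEMM kernels in src/nnet.cpp;
## tensors are (H, W, C, N) arrays.

.NET_DEPTH <- 5L

.presetChannels <- function(preset) {
  switch(preset,
         tiny = list(input_size = 64L, enc = c(8L, 12L, 16L, 16L, 16L),
                     bottleneck = 16L, dec = c(16L, 16L, 12L, 12L, 8L)),
         default = list(input_size = 512L, enc = c(16L, 24L, 32L, 48L, 64L),
                        bottleneck = 64L, dec = c(48L, 32L, 24L, 16L, 16L)),
         stop("unknown preset: ", preset))
}

#' Build an untrained per-organ segmentation network
#'
#' Single-channel input, single-channel sigmoid probability output, encoder
#' depth matched to a decoder of exactly five upsampling stages. The
#' `"default"` preset targets 512x512 slices; the `"tiny"` preset is a
#' CPU-scale network for 64x64 slices with the identical topology.
#'
#' @param organ organ class ("kidney", "spleen" or "liver").
#' @param preset `"default"` or `"tiny"`.
#' @param seed RNG seed for the (He-normal) weight initialization.
#' @return A list of class `"OrganModel"` with elements `arch`, `params` and
#'   `layers` (layer-type vector usable for introspection, e.g. counting
#'   upsampling stages).
#' @export
#' @examples
#' m <- buildOrganModel("kidney", preset = "tiny")
#' sum(m$layers == "upsample")  # decoder upsampling stages
buildOrganModel <- function(organ = "kidney", preset = "default", seed = 1L) {
  ch <- .presetChannels(preset)
  if (ch$input_size %% 2^.NET_DEPTH != 0)
    stop("input size must be divisible by 2^depth")
  set.seed(seed)
  params <- list()
  layers <- character(0)
  heInit <- function(k, cin, cout) {
    array(rnorm(k * k * cin * cout, 0, sqrt(2 / (k * k * cin))),
          dim = c(k, k, cin, cout))
  }
  cin <- 1L
  for (i in seq_len(.NET_DEPTH)) {
    params[[sprintf("enc%d.w", i)]] <- heInit(3, cin, ch$enc[i])
    params[[sprintf("enc%d.b", i)]] <- numeric(ch$enc[i])
    layers <- c(layers, "conv", "relu", "maxpool")
    cin <- ch$enc[i]
  }
  params[["bott.w"]] <- heInit(3, cin, ch$bottleneck)
  params[["bott.b"]] <- numeric(ch$bottleneck)
  layers <- c(layers, "conv", "relu")
  cin <- ch$bottleneck
  for (j in seq_len(.NET_DEPTH)) {
    skip_ch <- ch$enc[.NET_DEPTH + 1L - j]
    params[[sprintf("dec%d.w", j)]] <- heInit(3, cin + skip_ch, ch$dec[j])
    params[[sprintf("dec%d.b", j)]] <- numeric(ch$dec[j])
    layers <- c(layers, "upsample", "concat", "conv", "relu")
    cin <- ch$dec[j]
  }
  params[["head.w"]] <- heInit(1, cin, 1L)
  params[["head.b"]] <- numeric(1)
  layers <- c(layers, "conv", "sigmoid")
  structure(list(arch = c(list(preset = preset, organ = organ,
                               depth = .NET_DEPTH), ch),
                 params = params, layers = layers),
            class = "OrganModel")
}

#' Number of decoder upsampling stages of a model
#'
#' @param model an `"OrganModel"` (or the `arch`/`layers` of a checkpoint).
#' @return Integer count of upsampling layers.
#' @export
nUpsamplingStages <- function(model) {
  sum(model$layers == "upsample")
}

.relu <- function(z) {
  z[z < 0] <- 0
  z
}

.concatChannels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

## forward pass; returns probabilities and (optionally) the cache needed for
## backprop
.netForward <- function(params, x, keep = FALSE) {
  cache <- if (keep) list(x = x) else NULL
  h <- x
  skips <- vector("list", .NET_DEPTH)
  for (i in seq_len(.NET_DEPTH)) {
    z <- .cpp_conv2d_fwd(h, params[[sprintf("enc%d.w", i)]],
                         params[[sprintf("enc%d.b", i)]])
    a <- .relu(z)
    skips[[i]] <- a
    mp <- .cpp_maxpool2_fwd(a)
    if (keep) {
      cache[[sprintf("enc%d.in", i)]] <- h
      cache[[sprintf("enc%d.z", i)]] <- z
      cache[[sprintf("enc%d.idx", i)]] <- mp$idx
      cache[[sprintf("enc%d.adim", i)]] <- dim(a)
    }
    h <- mp$y
  }
  zb <- .cpp_conv2d_fwd(h, params[["bott.w"]], params[["bott.b"]])
  ab <- .relu(zb)
  if (keep) {
    cache[["bott.in"]] <- h
    cache[["bott.z"]] <- zb
  }
  h <- ab
  for (j in seq_len(.NET_DEPTH)) {
    up <- .cpp_upsample2_fwd(h)
    skip <- skips[[.NET_DEPTH + 1L - j]]
    cat_in <- .concatChannels(up, skip)
    z <- .cpp_conv2d_fwd(cat_in, params[[sprintf("dec%d.w", j)]],
                         params[[sprintf("dec%d.b", j)]])
    a <- .relu(z)
    if (keep) {
      cache[[sprintf("dec%d.updim", j)]] <- dim(up)
      cache[[sprintf("dec%d.in", j)]] <- cat_in
      cache[[sprintf("dec%d.z", j)]] <- z
    }
    h <- a
  }
  zh <- .cpp_conv2d_fwd(h, params[["head.w"]], params[["head.b"]])
  p <- 1 / (1 + exp(-zh))
  if (keep) {
    cache[["head.in"]] <- h
    cache[["prob"]] <- p
  }
  list(prob = p, cache = cache)
}

## backward pass from dL/dz_head; returns gradient list keyed like params
.netBackward <- function(params, cache, dzh) {
  grads <- list()
  g <- .cpp_conv2d_bwd(cache[["head.in"]], params[["head.w"]], dzh)
  grads[["head.w"]] <- g$dw
  grads[["head.b"]] <- g$db
  dh <- g$dx
  dskips <- vector("list", .NET_DEPTH)
  for (j in rev(seq_len(.NET_DEPTH))) {
    z <- cache[[sprintf("dec%d.z", j)]]
    dz <- dh * (z > 0)
    g <- .cpp_conv2d_bwd(cache[[sprintf("dec%d.in", j)]],
                         params[[sprintf("dec%d.w", j)]], dz)
    grads[[sprintf("dec%d.w", j)]] <- g$dw
    grads[[sprintf("dec%d.b", j)]] <- g$db
    updim <- cache[[sprintf("dec%d.updim", j)]]
    dcat <- g$dx
    dup <- dcat[, , seq_len(updim[3]), , drop = FALSE]
    dskips[[.NET_DEPTH + 1L - j]] <-
      dcat[, , updim[3] + seq_len(dim(dcat)[3] - updim[3]), , drop = FALSE]
    dim(dup) <- updim
    dh <- .cpp_upsample2_bwd(dup)
  }
  dz <- dh * (cache[["bott.z"]] > 0)
  g <- .cpp_conv2d_bwd(cache[["bott.in"]], params[["bott.w"]], dz)
  grads[["bott.w"]] <- g$dw
  grads[["bott.b"]] <- g$db
  dh <- g$dx
  for (i in rev(seq_len(.NET_DEPTH))) {
    adim <- cache[[sprintf("enc%d.adim", i)]]
    da <- .cpp_maxpool2_bwd(dh, cache[[sprintf("enc%d.idx", i)]],
                            adim[1], adim[2])
    da <- da + dskips[[i]]
    dz <- da * (cache[[sprintf("enc%d.z", i)]] > 0)
    g <- .cpp_conv2d_bwd(cache[[sprintf("enc%d.in", i)]],
                         params[[sprintf("enc%d.w", i)]], dz)
    grads[[sprintf("enc%d.w", i)]] <- g$dw
    grads[[sprintf("enc%d.b", i)]] <- g$db
    dh <- g$dx
  }
  grads
}

#' Combined soft-Dice + cross-entropy segmentation loss
#'
#' `loss = w_dice * (1 - (2*sum(p*g) + eps) / (sum(p) + sum(g) + eps)) +
#' w_ce * mean(binary cross-entropy)`. The smoothing term `eps` appears in
#' numerator and denominator, which keeps the Dice term stable on empty
#' masks. With binary predictions and `eps -> 0` the Dice term equals
#' `1 - dsc(pred, target)`.
#'
#' @param pred predicted probabilities in `[0, 1]` (any shape).
#' @param target binary target of the same shape.
#' @param w_dice,w_ce loss weights.
#' @param eps Dice smoothing constant.
#' @return Scalar loss.
#' @export
combinedLoss <- function(pred, target, w_dice = 1, w_ce = 1, eps = 1) {
  if (!identical(dim(pred), dim(target)) &&
      length(pred) != length(target))
    stop("pred and target must be congruent")
  if (min(pred) < 0 || max(pred) > 1)
    stop("predicted probabilities must lie in [0, 1]")
  dice <- 1 - (2 * sum(pred * target) + eps) /
    (sum(pred) + sum(target) + eps)
  pc <- pmin(pmax(pred, 1e-7), 1 - 1e-7)
  ce <- -mean(target * log(pc) + (1 - target) * log(1 - pc))
  w_dice * dice + w_ce * ce
}

## loss value and gradient w.r.t. the pre-sigmoid logits
.lossGrad <- function(prob, target, w_dice = 1, w_ce = 1, eps = 1) {
  n <- length(prob)
  num <- 2 * sum(prob * target) + eps
  den <- sum(prob) + sum(target) + eps
  dice <- 1 - num / den
  pc <- pmin(pmax(prob, 1e-7), 1 - 1e-7)
  ce <- -mean(target * log(pc) + (1 - target) * log(1 - pc))
  ## d(dice)/dp = (num - 2*g*den) / den^2 ; chain through sigmoid: * p(1-p)
  ddice_dp <- (num - 2 * target * den) / den^2
  dz <- w_dice * ddice_dp * prob * (1 - prob) + w_ce * (prob - target) / n
  dim(dz) <- dim(prob)
  list(loss = w_dice * dice + w_ce * ce, dz = dz)
}

## ---- rectified Adam wrapped in Lookahead -----------------------------------

.radamInit <- function(params) {
  list(t = 0L,
       m = lapply(params, function(p) array(0, dim(p) %||% length(p))),
       v = lapply(params, function(p) array(0, dim(p) %||% length(p))))
}

.radamStep <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                       beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  rho_inf <- 2 / (1 - beta2) - 1
  rho_t <- rho_inf - 2 * t * beta2^t / (1 - beta2^t)
  for (k in names(params)) {
    g <- grads[[k]]
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * g
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * g^2
    mhat <- state$m[[k]] / (1 - beta1^t)
    if (rho_t > 4) {
      vhat <- sqrt(state$v[[k]] / (1 - beta2^t))
      r <- sqrt(((rho_t - 4) * (rho_t - 2) * rho_inf) /
                  ((rho_inf - 4) * (rho_inf - 2) * rho_t))
      params[[k]] <- params[[k]] - lr * r * mhat / (vhat + eps)
    } else {
      params[[k]] <- params[[k]] - lr * mhat
    }
  }
  list(params = params, state = state)
}

.lookaheadSync <- function(fast, slow, alpha = 0.5) {
  for (k in names(fast)) slow[[k]] <- slow[[k]] + alpha * (fast[[k]] - slow[[k]])
  list(fast = slow, slow = slow)
}
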