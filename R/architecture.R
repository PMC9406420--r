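# The Connected-SegNets architecture: two SegNet encoder-decoder networks in
# series.  The first decoder's multi-scale features are injected into the
# second encoder through 3x3 convolutional skip connections; both decoders
# upsample with the max-pooling indices recorded by their own encoder; the
# head is a rate-3 dilated convolution followed by a capped ReLU and a 1x1
# output convolution.

#' Model configuration
#'
#' @param input_size Input side length in pixels; must be divisible by 32
#'   (five pooling stages).  Default 256.
#' @param base_channels Channels of the first encoder block (default 64;
#'   the channel schedule is `base_channels * c(1, 2, 4, 8, 8)`).
#' @param width_multiplier Fraction scaling every channel count, for
#'   desk-scale variants (e.g. `1/8` gives a base of 8 channels with
#'   identical topology).
#' @param dilation_rate Dilation of the head convolution (default 3).
#' @param final_activation `"sigmoid"` (default; guarantees outputs in
#'   `(0, 1)` for the IoU loss) or `"advanced_relu"`.
#' @param bn_order `"act_bn"` applies conv -> ReLU -> batch norm (the
#'   published block order); `"bn_act"` swaps the last two for ablation.
#' @param n_segnets 2 for the full twin architecture, 1 for a plain
#'   single-SegNet baseline (encoder/decoder + head only).
#' @param seed Seed for He-normal weight initialization.
#' @return Object of class `model_config`.
#' @export
model_config <- function(input_size = 256L, base_channels = 64L,
                         width_multiplier = 1, dilation_rate = 3L,
                         final_activation = c("sigmoid", "advanced_relu"),
                         bn_order = c("act_bn", "bn_act"),
                         n_segnets = 2L, seed = 42L) {
  input_size <- as.integer(input_size)
  if (input_size %% 32L != 0L || input_size < 32L)
    csn_config_error("input_size must be a positive multiple of 32")
  if (dilation_rate < 1) csn_config_error("dilation_rate must be >= 1")
  if (!n_segnets %in% 1:2) csn_config_error("n_segnets must be 1 or 2")
  ch <- pmax(1L, as.integer(round(base_channels * width_multiplier *
                                    c(1, 2, 4, 8, 8))))
  structure(list(input_size = input_size,
                 base_channels = as.integer(base_channels),
                 width_multiplier = width_multiplier,
                 channel_schedule = ch,
                 dilation_rate = as.integer(dilation_rate),
                 final_activation = match.arg(final_activation),
                 bn_order = match.arg(bn_order),
                 n_segnets = as.integer(n_segnets),
                 seed = as.integer(seed)),
            class = "model_config")
}

#' Desk-scale ("tiny") model configuration
#'
#' The reference topology at 1/8 width on 64 x 64 inputs: identical layer
#' graph and stage counts, small enough to train on a CPU in minutes.
#'
#' @param seed Weight-initialization seed.
#' @export
tiny_model_config <- function(seed = 42L) {
  model_config(input_size = 64L, width_multiplier = 1 / 8, seed = seed)
}

# one conv unit: weights + batch-norm parameters + Adam state
new_conv_unit <- function(kh, kw, cin, cout, bn) {
  u <- new.env(parent = emptyenv())
  u$W <- he_init(kh, kw, cin, cout)
  u$b <- numeric(cout)
  u$bn <- bn
  if (bn) {
    u$gamma <- rep(1, cout)
    u$beta <- numeric(cout)
    u$rmean <- numeric(cout)
    u$rvar <- rep(1, cout)
  }
  u$opt <- NULL
  u
}

new_node <- function(id, kind, inputs = character(), name = id,
                     subnet = "segnet1", table_row = NA_integer_,
                     filters = NA_integer_, repeats = 0L, dilation = 1L,
                     act = "relu", bn = TRUE, kernel = 3L, idx_from = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$id <- id; nd$kind <- kind; nd$inputs <- inputs; nd$name <- name
  nd$subnet <- subnet; nd$table_row <- table_row
  nd$filters <- filters; nd$repeats <- repeats; nd$dilation <- dilation
  nd$act <- act; nd$bn <- bn; nd$kernel <- kernel; nd$idx_from <- idx_from
  nd$units <- list()
  nd
}

#' Build the Connected-SegNets layer graph
#'
#' Constructs the full two-SegNet architecture: a VGG13-style encoder with
#' pooling-index recording, a mirrored index-unpooling decoder, a bridge
#' that concatenates the first decoder's output with a convolved copy of
#' itself, a second encoder with four convolutional skip concatenations
#' from the first decoder, a second index-unpooling decoder and the
#' dilated-convolution head.  Weights are He-normal, deterministic in
#' `config$seed`.
#'
#' @param config A [model_config()].
#' @return Object of class `segnet_model`.
#' @seealso [segnet_forward()], [count_stages()], [connected_segnet_schedule()]
#' @export
build_architecture <- function(config = model_config()) {
  ch <- config$channel_schedule
  c1 <- ch[1]; c2 <- ch[2]; c3 <- ch[3]; c4 <- ch[4]; c5 <- ch[5]
  nodes <- list()
  chan <- list()  # output channels per node id
  add <- function(nd, out_ch) {
    nodes[[nd$id]] <<- nd
    chan[[nd$id]] <<- out_ch
  }
  conv_block_node <- function(id, input, filters, repeats, name, subnet, row,
                              act = "relu", bn = TRUE, dilation = 1L,
                              kernel = 3L) {
    nd <- new_node(id, "conv_block", input, name = name, subnet = subnet,
                   table_row = row, filters = filters, repeats = repeats,
                   dilation = dilation, act = act, bn = bn, kernel = kernel)
    cin <- chan[[input]]
    for (r in seq_len(repeats)) {
      nd$units[[r]] <- new_conv_unit(kernel, kernel, cin, filters, bn)
      cin <- filters
    }
    add(nd, filters)
    nd
  }
  pool_node <- function(id, input, name, subnet, row) {
    add(new_node(id, "pool", input, name = name, subnet = subnet,
                 table_row = row, bn = FALSE), chan[[input]])
  }
  unpool_node <- function(id, input, idx_from, name, subnet, row) {
    add(new_node(id, "unpool", input, name = name, subnet = subnet,
                 table_row = row, bn = FALSE, idx_from = idx_from),
        chan[[input]])
  }
  concat_node <- function(id, a, b, name, subnet, row) {
    add(new_node(id, "concat", c(a, b), name = name, subnet = subnet,
                 table_row = row, bn = FALSE), chan[[a]] + chan[[b]])
  }

  with_seed(config$seed, {
    add(new_node("in", "input", character(), name = "Input", table_row = 1L,
                 bn = FALSE), 1L)

    # ---- SegNet1 encoder ----
    conv_block_node("s1e_conv1", "in", c1, 2L, "Conv1", "segnet1", 2L)
    pool_node("s1e_pool1", "s1e_conv1", "Maxpool", "segnet1", 3L)
    conv_block_node("s1e_conv2", "s1e_pool1", c2, 2L, "Conv2", "segnet1", 4L)
    pool_node("s1e_pool2", "s1e_conv2", "Maxpool", "segnet1", 5L)
    conv_block_node("s1e_conv3", "s1e_pool2", c3, 3L, "Conv3", "segnet1", 6L)
    pool_node("s1e_pool3", "s1e_conv3", "Maxpool", "segnet1", 7L)
    conv_block_node("s1e_conv4", "s1e_pool3", c4, 3L, "Conv4", "segnet1", 8L)
    pool_node("s1e_pool4", "s1e_conv4", "Maxpool", "segnet1", 9L)
    conv_block_node("s1e_conv5", "s1e_pool4", c5, 3L, "Conv5", "segnet1", 10L)
    pool_node("s1e_pool5", "s1e_conv5", "Maxpool", "segnet1", 11L)

    # ---- SegNet1 decoder (mirrored, channel reductions per schedule) ----
    unpool_node("s1d_up1", "s1e_pool5", "s1e_pool5", "Upsampling", "segnet1", 12L)
    conv_block_node("s1d_conv6", "s1d_up1", c5, 3L, "Conv6", "segnet1", 13L)
    unpool_node("s1d_up2", "s1d_conv6", "s1e_pool4", "Upsampling", "segnet1", 14L)
    conv_block_node("s1d_conv7", "s1d_up2", c4, 2L, "Conv7", "segnet1", 15L)
    conv_block_node("s1d_conv8", "s1d_conv7", c3, 1L, "Conv8", "segnet1", 16L)
    unpool_node("s1d_up3", "s1d_conv8", "s1e_pool3", "Upsampling", "segnet1", 17L)
    conv_block_node("s1d_conv9", "s1d_up3", c3, 2L, "Conv9", "segnet1", 18L)
    conv_block_node("s1d_conv10", "s1d_conv9", c2, 1L, "Conv10", "segnet1", 19L)
    unpool_node("s1d_up4", "s1d_conv10", "s1e_pool2", "Upsampling", "segnet1", 20L)
    conv_block_node("s1d_conv11", "s1d_up4", c2, 2L, "Conv11", "segnet1", 21L)
    conv_block_node("s1d_conv12", "s1d_conv11", c1, 1L, "Conv12", "segnet1", 22L)
    unpool_node("s1d_up5", "s1d_conv12", "s1e_pool1", "Upsampling", "segnet1", 23L)
    conv_block_node("s1d_conv13", "s1d_up5", c1, 1L, "Conv13", "segnet1", 24L)

    last <- "s1d_conv13"
    if (config$n_segnets == 2L) {
      # ---- bridge: concat Conv13 with a convolved copy of itself ----
      conv_block_node("br_conv", "s1d_conv13", c1, 1L, "BridgeConv", "segnet2",
                      NA_integer_)
      concat_node("br_concat", "s1d_conv13", "br_conv", "Concatenate",
                  "segnet2", NA_integer_)
      conv_block_node("s2e_conv14", "br_concat", c1, 2L, "Conv14", "segnet2", 26L)

      # ---- SegNet2 encoder with skip concatenations ----
      pool_node("s2e_pool1", "s2e_conv14", "Maxpool", "segnet2", 27L)
      conv_block_node("skip1", "s1d_conv12", c1, 1L, "SkipConv1", "segnet2",
                      NA_integer_)
      concat_node("s2e_concat1", "s2e_pool1", "skip1", "Concatenate",
                  "segnet2", 28L)
      conv_block_node("s2e_conv15", "s2e_concat1", c2, 2L, "Conv15", "segnet2", 29L)
      pool_node("s2e_pool2", "s2e_conv15", "Maxpool", "segnet2", 30L)
      conv_block_node("skip2", "s1d_conv10", c2, 1L, "SkipConv2", "segnet2",
                      NA_integer_)
      concat_node("s2e_concat2", "s2e_pool2", "skip2", "Concatenate",
                  "segnet2", 31L)
      conv_block_node("s2e_conv16", "s2e_concat2", c3, 3L, "Conv16", "segnet2", 32L)
      pool_node("s2e_pool3", "s2e_conv16", "Maxpool", "segnet2", 33L)
      conv_block_node("skip3", "s1d_conv8", c3, 1L, "SkipConv3", "segnet2",
                      NA_integer_)
      concat_node("s2e_concat3", "s2e_pool3", "skip3", "Concatenate",
                  "segnet2", 34L)
      conv_block_node("s2e_conv17", "s2e_concat3", c4, 3L, "Conv17", "segnet2", 35L)
      pool_node("s2e_pool4", "s2e_conv17", "Maxpool", "segnet2", 36L)
      conv_block_node("skip4", "s1d_conv6", c4, 1L, "SkipConv4", "segnet2",
                      NA_integer_)
      concat_node("s2e_concat4", "s2e_pool4", "skip4", "Concatenate",
                  "segnet2", 37L)
      conv_block_node("s2e_conv18", "s2e_concat4", c5, 3L, "Conv18", "segnet2", 38L)
      pool_node("s2e_pool5", "s2e_conv18", "Maxpool", "segnet2", 39L)

      # ---- SegNet2 decoder ----
      unpool_node("s2d_up1", "s2e_pool5", "s2e_pool5", "Upsampling", "segnet2", 40L)
      conv_block_node("s2d_conv19", "s2d_up1", c5, 3L, "Conv19", "segnet2", 41L)
      unpool_node("s2d_up2", "s2d_conv19", "s2e_pool4", "Upsampling", "segnet2", 42L)
      conv_block_node("s2d_conv20", "s2d_up2", c4, 2L, "Conv20", "segnet2", 43L)
      conv_block_node("s2d_conv21", "s2d_conv20", c3, 1L, "Conv21", "segnet2", 44L)
      unpool_node("s2d_up3", "s2d_conv21", "s2e_pool3", "Upsampling", "segnet2", 45L)
      conv_block_node("s2d_conv22", "s2d_up3", c3, 2L, "Conv22", "segnet2", 46L)
      conv_block_node("s2d_conv23", "s2d_conv22", c2, 1L, "Conv23", "segnet2", 47L)
      unpool_node("s2d_up4", "s2d_conv23", "s2e_pool2", "Upsampling", "segnet2", 48L)
      conv_block_node("s2d_conv24", "s2d_up4", c2, 2L, "Conv24", "segnet2", 49L)
      conv_block_node("s2d_conv25", "s2d_conv24", c1, 1L, "Conv25", "segnet2", 50L)
      unpool_node("s2d_up5", "s2d_conv25", "s2e_pool1", "Upsampling", "segnet2", 51L)
      conv_block_node("s2d_conv26", "s2d_up5", c1, 1L, "Conv26", "segnet2", 52L)
      last <- "s2d_conv26"
    }

    # ---- head: dilated conv -> capped ReLU -> 1x1 conv ----
    conv_block_node("head_conv27", last, c1, 1L, "Conv27", "head", 53L,
                    act = "advanced_relu", bn = FALSE,
                    dilation = config$dilation_rate)
    conv_block_node("out", "head_conv27", 1L, 1L, "Output", "head", 54L,
                    act = config$final_activation, bn = FALSE, kernel = 1L)
  })

  structure(list(config = config, nodes = nodes), class = "segnet_model")
}

# number of times each value (node output or recorded pooling index) is
# consumed downstream, for memory release during inference
value_consumers <- function(nodes) {
  cnt <- list()
  bump <- function(k) cnt[[k]] <<- (cnt[[k]] %||% 0L) + 1L
  for (nd in nodes) {
    for (inp in nd$inputs) bump(inp)
    if (identical(nd$kind, "unpool")) bump(paste0(nd$idx_from, "#idx"))
  }
  cnt
}

conv_unit_forward <- function(x, u, act, dilation, bn_order, training) {
  z <- nn_conv2d(x, u$W, u$b, dilation)
  cache <- list(x = x, z = z)
  if (u$bn && bn_order == "bn_act") {
    bf <- bn_forward(z, u$gamma, u$beta, training, u$rmean, u$rvar)
    if (training) {
      u$rmean <- 0.9 * u$rmean + 0.1 * bf$mu
      u$rvar <- 0.9 * u$rvar + 0.1 * bf$var
    }
    y <- act_forward(bf$y, act)
    cache$mu <- bf$mu; cache$var <- bf$var; cache$preact <- bf$y
  } else {
    a <- act_forward(z, act)
    if (u$bn) {
      bf <- bn_forward(a, u$gamma, u$beta, training, u$rmean, u$rvar)
      if (training) {
        u$rmean <- 0.9 * u$rmean + 0.1 * bf$mu
        u$rvar <- 0.9 * u$rvar + 0.1 * bf$var
      }
      y <- bf$y
      cache$a <- a; cache$mu <- bf$mu; cache$var <- bf$var
    } else y <- a
  }
  cache$out <- if (act == "sigmoid") y else NULL
  list(y = y, cache = if (training) cache else NULL)
}

conv_unit_backward <- function(dy, u, cache, act, dilation, bn_order) {
  if (u$bn && bn_order == "bn_act") {
    da <- act_backward(dy, cache$preact, NULL, act)
    bb <- bn_backward(cache$z, da, u$gamma, cache$mu, cache$var)
    dz <- bb$dx
    u$dgamma <- bb$dgamma; u$dbeta <- bb$dbeta
  } else if (u$bn) {
    bb <- bn_backward(cache$a, dy, u$gamma, cache$mu, cache$var)
    dz <- act_backward(bb$dx, cache$z, cache$out, act)
    u$dgamma <- bb$dgamma; u$dbeta <- bb$dbeta
  } else {
    dz <- act_backward(dy, cache$z, cache$out, act)
  }
  cb <- nn_conv2d_backward(cache$x, u$W, dz, dilation)
  u$dW <- cb$dw; u$db <- cb$db
  cb$dx
}

#' Run the network forward
#'
#' @param model A [build_architecture()] model.
#' @param x Input batch: `(H, W, 1, N)` array, `(H, W)` matrix or a list of
#'   matrices, with values in `[0, 1]` and `H = W = config$input_size`.
#' @param training If `TRUE`, batch statistics are used for normalization,
#'   running statistics are updated, and all intermediate activations are
#'   cached for [segnet_backward()].  Inference mode is deterministic.
#' @return List with `pred` (`(H, W, 1, N)` array in `[0, 1]`), `shapes`
#'   (named list of realized output dims per layer) and, when training,
#'   `ctx` (the cache consumed by the backward pass).
#' @export
segnet_forward <- function(model, x, training = FALSE) {
  if (is.list(x) && !is.array(x)) x <- stack_batch(x)
  x <- as_tensor(x)
  d <- dim(x)
  sz <- model$config$input_size
  if (d[1] != sz || d[2] != sz)
    csn_error(sprintf("input is %dx%d but the model expects %dx%d",
                      d[1], d[2], sz, sz), "csn_shape_error")
  nodes <- model$nodes
  remaining <- if (training) NULL else value_consumers(nodes)
  vals <- new.env(parent = emptyenv())
  idxs <- new.env(parent = emptyenv())
  caches <- if (training) new.env(parent = emptyenv()) else NULL
  shapes <- list()
  release <- function(key, env) {
    if (training) return(invisible())
    n <- (remaining[[key]] %||% 0L) - 1L
    remaining[[key]] <<- n
    if (n <= 0L && exists(key, envir = env, inherits = FALSE))
      rm(list = key, envir = env)
  }
  for (nd in nodes) {
    out <- switch(nd$kind,
      input = x,
      conv_block = {
        v <- get(nd$inputs, envir = vals)
        release(nd$inputs, vals)
        ucaches <- vector("list", nd$repeats)
        for (r in seq_len(nd$repeats)) {
          uf <- conv_unit_forward(v, nd$units[[r]], nd$act, nd$dilation,
                                  model$config$bn_order, training)
          v <- uf$y
          ucaches[[r]] <- uf$cache
        }
        if (training) assign(nd$id, ucaches, envir = caches)
        v
      },
      pool = {
        v <- get(nd$inputs, envir = vals)
        release(nd$inputs, vals)
        pl <- max_pool_indices(v)
        assign(paste0(nd$id, "#idx"), pl$idx, envir = idxs)
        pl$y
      },
      unpool = {
        v <- get(nd$inputs, envir = vals)
        release(nd$inputs, vals)
        ik <- paste0(nd$idx_from, "#idx")
        y <- unpool_indices(v, get(ik, envir = idxs))
        release(ik, idxs)
        y
      },
      concat = {
        a <- get(nd$inputs[1], envir = vals)
        b <- get(nd$inputs[2], envir = vals)
        release(nd$inputs[1], vals); release(nd$inputs[2], vals)
        da <- dim(a); db <- dim(b)
        y <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
        y[, , seq_len(da[3]), ] <- a
        y[, , da[3] + seq_len(db[3]), ] <- b
        if (training) assign(nd$id, da[3], envir = caches)  # split point
        y
      },
      csn_config_error(sprintf("unknown node kind '%s'", nd$kind)))
    assign(nd$id, out, envir = vals)
    shapes[[nd$id]] <- dim(out)
  }
  list(pred = get("out", envir = vals), shapes = shapes,
       ctx = if (training) list(vals = vals, idxs = idxs, caches = caches)
             else NULL)
}

#' Backward pass: gradients of a scalar loss
#'
#' Walks the graph in reverse, accumulating parameter gradients into the
#' model's layers (consumed by the Adam step in [train_segnet()]).
#'
#' @param model The model used in the forward pass.
#' @param ctx The `ctx` returned by `segnet_forward(..., training = TRUE)`.
#' @param dpred Gradient of the loss w.r.t. the network output, same shape
#'   as the prediction.
#' @return Invisibly, the gradient w.r.t. the input batch.
#' @export
segnet_backward <- function(model, ctx, dpred) {
  nodes <- model$nodes
  grads <- new.env(parent = emptyenv())
  addg <- function(id, g) {
    if (exists(id, envir = grads, inherits = FALSE))
      assign(id, get(id, envir = grads) + g, envir = grads)
    else assign(id, g, envir = grads)
  }
  assign("out", dpred, envir = grads)
  for (nd in rev(nodes)) {
    if (!exists(nd$id, envir = grads, inherits = FALSE)) next
    dy <- get(nd$id, envir = grads)
    rm(list = nd$id, envir = grads)
    switch(nd$kind,
      input = { grads$input <- dy },
      conv_block = {
        ucaches <- get(nd$id, envir = ctx$caches)
        for (r in rev(seq_len(nd$repeats)))
          dy <- conv_unit_backward(dy, nd$units[[r]], ucaches[[r]], nd$act,
                                   nd$dilation, model$config$bn_order)
        addg(nd$inputs, dy)
      },
      pool = {
        idx <- get(paste0(nd$id, "#idx"), envir = ctx$idxs)
        addg(nd$inputs, max_pool_backward(dy, idx))
      },
      unpool = {
        idx <- get(paste0(nd$idx_from, "#idx"), envir = ctx$idxs)
        addg(nd$inputs, unpool_backward(dy, idx))
      },
      concat = {
        ca <- get(nd$id, envir = ctx$caches)
        addg(nd$inputs[1], dy[, , seq_len(ca), , drop = FALSE])
        addg(nd$inputs[2],
             dy[, , (ca + 1L):dim(dy)[3], , drop = FALSE])
      })
  }
  invisible(grads$input)
}

#' Stage counts per sub-network
#'
#' @param model A `segnet_model`.
#' @return Named list per sub-network with `pools`, `unpools`, `concats`
#'   (the bridge concatenation counts toward SegNet2).
#' @export
count_stages <- function(model) {
  out <- list()
  for (nd in model$nodes) {
    sn <- nd$subnet
    if (sn == "head") next
    if (is.null(out[[sn]]))
      out[[sn]] <- c(pools = 0L, unpools = 0L, concats = 0L)
    k <- switch(nd$kind, pool = "pools", unpool = "unpools",
                concat = "concats", NULL)
    if (!is.null(k)) out[[sn]][k] <- out[[sn]][k] + 1L
  }
  out
}
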