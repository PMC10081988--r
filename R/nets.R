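#' Architecture hyperparameters for the 3D DCGAN family
#'
#' Collects every constant that fixes the generator, discriminator,
#' discriminator-derived classifier and the VGG-like baseline.  The defaults
#' are the full-scale architecture: a generator that maps a 100-dimensional
#' Gaussian latent vector through a fully-connected reshape to a
#' 4x4x4x128 seed volume and four upsampling blocks (channel widths 64, 32,
#' 16, 1) to a 64^3 single-channel volume in \[0,1\]; and a residual
#' discriminator with a 16-channel convolution stem, four residual blocks of
#' widths 16/32/32/64 (blocks 2 and 4 are stride-2 bottlenecks), average
#' pooling and a 512-wide output block with dropout.
#'
#' @param input_size voxels per axis of the (cubic) input volume; must be
#'   divisible by 16 (one stem pool, two stride-2 blocks, one final pool).
#' @param latent_dim length of the generator's latent input (default 100).
#' @param g_fc_shape 4-vector: spatial seed size (3 axes) and channel count
#'   of the generator's fully-connected reshape.  The spatial seed times
#'   2^4 must equal `input_size`.
#' @param g_channels filter counts of the four upsampling blocks; the last
#'   entry must be 1 (single-channel output).
#' @param d_stem_channels filters in the discriminator's convolution stem.
#' @param d_block_channels filter counts of residual blocks 1-4.
#' @param output_fc_widths widths of the discriminator output block; the
#'   last entry must be 1.
#' @param dropout_rate dropout fraction in the output/classification block,
#'   in \[0,1).
#' @param classifier_fc_widths widths of the three fully-connected layers of
#'   the classification block; the last entry must be 1.
#' @return An object of class `network_spec`.
#' @seealso [network_spec_desk()] for CPU-sized variants,
#'   [build_generator()], [build_discriminator()].
#' @export
network_spec <- function(input_size = 64L,
                         latent_dim = 100L,
                         g_fc_shape = c(4L, 4L, 4L, 128L),
                         g_channels = c(64L, 32L, 16L, 1L),
                         d_stem_channels = 16L,
                         d_block_channels = c(16L, 32L, 32L, 64L),
                         output_fc_widths = c(512L, 1L),
                         dropout_rate = 0.5,
                         classifier_fc_widths = c(512L, 64L, 1L)) {
  spec <- list(input_size = as.integer(input_size),
               latent_dim = as.integer(latent_dim),
               g_fc_shape = as.integer(g_fc_shape),
               g_channels = as.integer(g_channels),
               d_stem_channels = as.integer(d_stem_channels),
               d_block_channels = as.integer(d_block_channels),
               output_fc_widths = as.integer(output_fc_widths),
               dropout_rate = dropout_rate,
               classifier_fc_widths = as.integer(classifier_fc_widths))
  class(spec) <- "network_spec"
  validate_network_spec(spec)
  spec
}

validate_network_spec <- function(spec) {
  stopifnot(spec$latent_dim >= 1L,
            spec$dropout_rate >= 0, spec$dropout_rate < 1,
            length(spec$g_fc_shape) == 4L,
            length(spec$g_channels) == 4L,
            length(spec$d_block_channels) == 4L)
  if (spec$input_size %% 16L != 0L)
    stop("input_size must be divisible by 16 for the default discriminator ",
         "(one stem pool, two stride-2 blocks, one final pool)")
  if (spec$g_fc_shape[1] * 2L^4L != spec$input_size ||
      any(spec$g_fc_shape[1:3] != spec$g_fc_shape[1]))
    stop("inconsistent spec: generator seed volume ", spec$g_fc_shape[1],
         "^3 times 2^4 upsampling blocks does not reach input_size ",
         spec$input_size)
  if (spec$g_channels[4] != 1L)
    stop("generator must end in a single channel")
  if (utils::tail(spec$output_fc_widths, 1) != 1L ||
      utils::tail(spec$classifier_fc_widths, 1) != 1L)
    stop("output and classification blocks must end in a single unit")
  invisible(spec)
}

#' Desk-scale architecture presets
#'
#' Narrow variants of the full architecture sized for single-CPU runs on
#' synthetic phantoms.  Block structure, strides and block names are
#' identical to [network_spec()]; only the spatial resolution and channel
#' widths shrink.  The widths were fixed once from a FLOP budget for a
#' commodity CPU core and are not tuning knobs.
#'
#' @param input_size voxels per axis, divisible by 16 (16 or 32 are the
#'   intended desk sizes).
#' @return A `network_spec`.
#' @export
network_spec_desk <- function(input_size = 32L) {
  input_size <- as.integer(input_size)
  # 16^3 volumes are ~8x cheaper per convolution, so that profile can
  # afford twice the channel width of the 32^3 one on a single CPU core
  wide <- input_size <= 16L
  network_spec(input_size = input_size,
               latent_dim = 100L,
               g_fc_shape = c(rep(input_size %/% 16L, 3L),
                              if (wide) 32L else 16L),
               g_channels = if (wide) c(16L, 8L, 4L, 1L) else
                 c(8L, 4L, 2L, 1L),
               d_stem_channels = if (wide) 4L else 2L,
               d_block_channels = if (wide) c(4L, 8L, 8L, 16L) else
                 c(2L, 4L, 4L, 8L),
               output_fc_widths = c(32L, 1L),
               dropout_rate = 0.5,
               classifier_fc_widths = c(32L, 16L, 1L))
}

#' @export
print.network_spec <- function(x, ...) {
  cat("3D DCGAN architecture spec\n")
  cat("  input volume :", paste(rep(x$input_size, 3), collapse = " x "),
      "(single channel)\n")
  cat("  generator    : latent", x$latent_dim, "-> seed",
      paste(x$g_fc_shape, collapse = "x"), "-> channels",
      paste(x$g_channels, collapse = ", "), "\n")
  cat("  discriminator: stem", x$d_stem_channels, "ch; residual blocks",
      paste(x$d_block_channels, collapse = ", "),
      "; output FC", paste(x$output_fc_widths, collapse = ", "), "\n")
  cat("  classifier FC:", paste(x$classifier_fc_widths, collapse = ", "),
      " dropout", x$dropout_rate, "\n")
  invisible(x)
}

new_voxnet <- function(blocks, spec, kind) {
  structure(list(blocks = blocks, spec = spec, kind = kind),
            class = "voxnet")
}

new_block <- function(name, layers) {
  e <- new.env(parent = emptyenv())
  e$name <- name
  e$layers <- layers
  e$trainable <- TRUE
  e
}

#' Build the 3D DCGAN generator
#'
#' The generator maps a latent Gaussian vector to a single-channel volume:
#' a fully-connected layer reshaped to the seed volume (block `g_fc`),
#' then four upsampling blocks (`up1`..`up4`), each a nearest-neighbour x2
#' upsample followed by a 3^3 convolution; batch normalisation and ReLU
#' everywhere except the final block, which ends in a logistic activation so
#' outputs stay in \[0,1\] like gray-matter density values.
#'
#' @param spec a [network_spec()].
#' @return A `voxnet` of kind `"generator"`.  Use [generate_volumes()] or
#'   `simulate()` on a fitted GAN to sample from it.
#' @export
build_generator <- function(spec) {
  validate_network_spec(spec)
  s <- spec$g_fc_shape
  ch <- c(s[4], spec$g_channels)
  blocks <- list(
    g_fc = new_block("g_fc", list(
      ly_dense(spec$latent_dim, prod(s)),
      ly_reshape(s),
      ly_bn(s[4]),
      ly_relu()
    ))
  )
  for (i in 1:4) {
    last <- i == 4L
    layers <- list(ly_upsample(2L),
                   ly_conv3d(ch[i], ch[i + 1], k = 3L, stride = 1L, pad = 1L))
    layers <- if (last) c(layers, list(ly_sigmoid()))
    else c(layers, list(ly_bn(ch[i + 1]), ly_relu()))
    blocks[[paste0("up", i)]] <- new_block(paste0("up", i), layers)
  }
  new_voxnet(blocks, spec, "generator")
}

std_resblock <- function(cin, cout) {
  main <- list(ly_conv3d(cin, cout), ly_bn(cout), ly_lrelu(0.2),
               ly_conv3d(cout, cout), ly_bn(cout))
  shortcut <- if (cin == cout) NULL else
    list(ly_conv3d(cin, cout, k = 1L, stride = 1L, pad = 0L), ly_bn(cout))
  ly_resblock(main, shortcut)
}

bottleneck_resblock <- function(cin, cout) {
  # 1^3 -> 3^3 stride 2 -> 1^3, all at cout channels; projection shortcut
  main <- list(ly_conv3d(cin, cout, k = 1L, stride = 1L, pad = 0L),
               ly_bn(cout), ly_lrelu(0.2),
               ly_conv3d(cout, cout, k = 3L, stride = 2L, pad = 1L),
               ly_bn(cout), ly_lrelu(0.2),
               ly_conv3d(cout, cout, k = 1L, stride = 1L, pad = 0L),
               ly_bn(cout))
  shortcut <- list(ly_conv3d(cin, cout, k = 1L, stride = 2L, pad = 0L),
                   ly_bn(cout))
  ly_resblock(main, shortcut)
}

d_flat_len <- function(spec) {
  (spec$input_size %/% 16L)^3 * spec$d_block_channels[4]
}

#' Build the residual 3D discriminator
#'
#' Structure: a convolution stem (3^3 conv, stride 1, leaky ReLU, 2^3
#' max-pool stride 2), four residual blocks -- blocks 1 and 3 are standard
#' two-convolution blocks, blocks 2 and 4 are stride-2 bottlenecks
#' (1^3 -> 3^3 stride 2 -> 1^3) -- then 2^3 average pooling and an output
#' block (fully connected, dropout, single unit).  Shortcuts use a 1^3
#' projection convolution whenever channels or stride change.  The network
#' returns the pre-sigmoid score; [predict.voxnet()] applies the logistic
#' map to give a probability in (0,1).
#'
#' @param spec a [network_spec()].
#' @return A `voxnet` of kind `"discriminator"` with named blocks
#'   `stem`, `rb1`..`rb4`, `head`.
#' @export
build_discriminator <- function(spec) {
  validate_network_spec(spec)
  c0 <- spec$d_stem_channels
  cb <- spec$d_block_channels
  w <- spec$output_fc_widths
  flat <- d_flat_len(spec)
  blocks <- list(
    stem = new_block("stem", list(
      ly_conv3d(1L, c0), ly_lrelu(0.2), ly_maxpool(2L, 2L))),
    rb1 = new_block("rb1", list(std_resblock(c0, cb[1]))),
    rb2 = new_block("rb2", list(bottleneck_resblock(cb[1], cb[2]))),
    rb3 = new_block("rb3", list(std_resblock(cb[2], cb[3]))),
    rb4 = new_block("rb4", list(bottleneck_resblock(cb[3], cb[4]))),
    head = new_block("head", list(
      ly_avgpool(2L, 2L), ly_flatten(),
      ly_dense(flat, w[1]), ly_lrelu(0.2),
      ly_dropout(spec$dropout_rate),
      ly_dense(w[1], w[2])))
  )
  new_voxnet(blocks, spec, "discriminator")
}

#' Convert a trained discriminator into a classifier
#'
#' The convolutional blocks (`stem`, `rb1`..`rb4`) keep the discriminator's
#' learned parameters (deep-copied, so further fine-tuning does not touch
#' the original network); the real-vs-synthetic output block is replaced by
#' a freshly initialised classification block of three fully-connected
#' layers ending in a single unit.
#'
#' @param d a `voxnet` built by [build_discriminator()] (trained or not).
#' @param spec the `network_spec` used to build `d`.
#' @return A `voxnet` of kind `"classifier"`.
#' @export
to_classifier <- function(d, spec = d$spec) {
  if (!inherits(d, "voxnet") || d$kind != "discriminator")
    stop("to_classifier() expects a discriminator voxnet")
  if (!identical(spec$d_block_channels, d$spec$d_block_channels) ||
      spec$input_size != d$spec$input_size)
    stop("spec does not match the discriminator it claims to describe")
  cw <- spec$classifier_fc_widths
  flat <- d_flat_len(spec)
  conv <- lapply(d$blocks[c("stem", "rb1", "rb2", "rb3", "rb4")],
                 clone_block)
  head <- new_block("head", list(
    ly_avgpool(2L, 2L), ly_flatten(),
    ly_dense(flat, cw[1]), ly_lrelu(0.2),
    ly_dropout(spec$dropout_rate),
    ly_dense(cw[1], cw[2]), ly_lrelu(0.2),
    ly_dense(cw[2], cw[3])))
  new_voxnet(c(conv, list(head = head)), spec, "classifier")
}

#' Build the VGG-like from-scratch baseline
#'
#' A plain stacked-convolution network of comparable depth to the
#' discriminator but with no shortcut connections: four stages of two 3^3
#' convolutions plus max-pooling (channel ladder stem, rb2, rb4, rb4 widths;
#' 16/32/64/64 at full scale), then the same classification block as the
#' discriminator-derived classifier.  Used only as an ablation baseline.
#'
#' @param spec a [network_spec()].
#' @return A `voxnet` of kind `"vgg"`.
#' @export
build_vgg_baseline <- function(spec) {
  validate_network_spec(spec)
  ch <- c(1L, spec$d_stem_channels, spec$d_block_channels[2],
          spec$d_block_channels[4], spec$d_block_channels[4])
  cw <- spec$classifier_fc_widths
  blocks <- list()
  for (i in 1:4) {
    blocks[[paste0("stage", i)]] <- new_block(paste0("stage", i), list(
      ly_conv3d(ch[i], ch[i + 1]), ly_bn(ch[i + 1]), ly_relu(),
      ly_conv3d(ch[i + 1], ch[i + 1]), ly_bn(ch[i + 1]), ly_relu(),
      ly_maxpool(2L, 2L)))
  }
  flat <- (spec$input_size %/% 16L)^3 * ch[5]
  blocks$head <- new_block("head", list(
    ly_flatten(),
    ly_dense(flat, cw[1]), ly_lrelu(0.2),
    ly_dropout(spec$dropout_rate),
    ly_dense(cw[1], cw[2]), ly_lrelu(0.2),
    ly_dense(cw[2], cw[3])))
  new_voxnet(blocks, spec, "vgg")
}

# ---- forward / backward over whole networks --------------------------------

net_forward <- function(net, x, training = FALSE) {
  for (b in net$blocks) {
    tr <- training && b$trainable
    x <- seq_fwd(b$layers, x, tr)
  }
  x
}

# backward from the output gradient; stops below the lowest trainable block.
# input_grad = FALSE lets the bottom-most convolution skip its (unused)
# gradient with respect to the input volume.
net_backward <- function(net, g, input_grad = TRUE) {
  bs <- net$blocks
  tr <- vapply(bs, function(b) b$trainable, logical(1))
  if (!any(tr)) return(invisible(NULL))
  lowest <- min(which(tr))
  for (i in rev(seq_along(bs))) {
    if (i < lowest) break
    g <- seq_bwd(bs[[i]]$layers, g, bottom = (i == lowest && !input_grad))
  }
  invisible(g)
}

# forward recording each block's output (for shape checks and Grad-CAM)
net_forward_trace <- function(net, x, training = FALSE) {
  out <- vector("list", length(net$blocks))
  names(out) <- names(net$blocks)
  for (i in seq_along(net$blocks)) {
    x <- seq_fwd(net$blocks[[i]]$layers, x, training && net$blocks[[i]]$trainable)
    out[[i]] <- x
  }
  list(output = x, blocks = out)
}

#' Predicted probabilities from a network
#'
#' Runs the network in evaluation mode (batch normalisation uses running
#' statistics, dropout disabled) and applies the logistic map to the scalar
#' score, giving a probability strictly in (0,1).
#'
#' @param object a `voxnet` of kind discriminator, classifier or vgg.
#' @param newdata a 5-d array (x, y, z, 1, n), a list of [volume_grid()]
#'   objects, or a single `volume_grid`.
#' @param type `"prob"` (default) or `"score"` for the pre-sigmoid score.
#' @param ... unused.
#' @return Numeric vector of length n.
#' @export
predict.voxnet <- function(object, newdata, type = c("prob", "score"), ...) {
  type <- match.arg(type)
  if (object$kind == "generator")
    stop("use generate_volumes() to sample from a generator")
  x <- as_batch(newdata)
  s <- as.numeric(net_forward(object, x, training = FALSE))
  if (type == "prob") stats::plogis(s) else s
}

# coerce volume_grid / list of volume_grid / array into a (x,y,z,1,n) batch
as_batch <- function(v) {
  if (inherits(v, "volume_grid")) v <- list(v)
  if (is.list(v)) {
    d <- dim(v[[1]]$data)
    x <- array(0, dim = c(d, 1L, length(v)))
    for (i in seq_along(v)) x[, , , 1L, i] <- v[[i]]$data
    return(x)
  }
  if (length(dim(v)) == 3L) dim(v) <- c(dim(v), 1L, 1L)
  if (length(dim(v)) == 4L) dim(v) <- c(dim(v), 1L)
  v
}

#' Sample volumes from a generator
#'
#' @param g a generator `voxnet`.
#' @param n number of volumes.
#' @param latent optional latent matrix (latent_dim x n); drawn from a
#'   standard normal when missing (uses the current RNG state).
#' @return 5-d array (x, y, z, 1, n) with values in \[0,1\].
#' @export
generate_volumes <- function(g, n, latent = NULL) {
  if (g$kind != "generator") stop("not a generator")
  if (is.null(latent))
    latent <- matrix(stats::rnorm(g$spec$latent_dim * n), g$spec$latent_dim, n)
  net_forward(g, latent, training = FALSE)
}

# ---- parameters, state, freezing -------------------------------------------

net_primitive_layers <- function(net, trainable_only = FALSE) {
  out <- list()
  for (b in net$blocks) {
    if (trainable_only && !b$trainable) next
    out <- c(out, primitive_layers(b$layers))
  }
  out
}

#' Number of trainable parameters
#'
#' @param net a `voxnet`.
#' @param by_block return a named per-block count instead of the total.
#' @return Integer-valued numeric.
#' @export
n_params <- function(net, by_block = FALSE) {
  counts <- vapply(net$blocks, function(b) {
    sum(vapply(primitive_layers(b$layers), layer_n_params, numeric(1)))
  }, numeric(1))
  if (by_block) counts else sum(counts)
}

#' @export
print.voxnet <- function(x, ...) {
  cat("voxnet", x$kind, "(", x$spec$input_size, "^3 input )\n", sep = " ")
  cnt <- n_params(x, by_block = TRUE)
  tr <- vapply(x$blocks, function(b) b$trainable, logical(1))
  for (i in seq_along(cnt))
    cat(sprintf("  %-7s %8d params %s\n", names(cnt)[i], cnt[i],
                if (tr[i]) "" else "[frozen]"))
  cat("  total  ", format(sum(cnt), big.mark = ","), "params\n")
  invisible(x)
}

# nested list of all stateful arrays (trainable params + BN running stats)
net_state <- function(net) {
  lapply(net$blocks, function(b) {
    lapply(primitive_layers(b$layers), function(l) {
      s <- lapply(l$pnames, function(p) l[[p]])
      names(s) <- l$pnames
      if (identical(l$kind, "bn")) {
        s$running_mean <- l$running_mean
        s$running_var <- l$running_var
      }
      s
    })
  })
}

net_set_state <- function(net, state) {
  stopifnot(identical(names(state), names(net$blocks)))
  for (bn in names(state)) {
    prim <- primitive_layers(net$blocks[[bn]]$layers)
    stopifnot(length(prim) == length(state[[bn]]))
    for (i in seq_along(prim)) {
      l <- prim[[i]]
      for (p in names(state[[bn]][[i]])) l[[p]] <- state[[bn]][[i]][[p]]
    }
  }
  invisible(net)
}

clone_block <- function(b) {
  nb <- new_block(b$name, clone_layers(b$layers))
  nb$trainable <- b$trainable
  nb
}

clone_layers <- function(layers) lapply(layers, clone_layer)

clone_layer <- function(l) {
  if (identical(l$kind, "resblock")) {
    nl <- ly_resblock(clone_layers(l$main),
                      if (is.null(l$shortcut)) NULL else
                        clone_layers(l$shortcut),
                      l$slope)
    return(nl)
  }
  nl <- switch(l$kind,
    conv3d = ly_conv3d(dim(l$W)[4], dim(l$W)[5], dim(l$W)[1], l$stride, l$pad),
    bn = ly_bn(length(l$gamma), l$eps, l$momentum),
    lrelu = ly_lrelu(l$slope),
    sigmoid = ly_sigmoid(),
    maxpool = ly_maxpool(l$k, l$stride),
    avgpool = ly_avgpool(l$k, l$stride),
    upsample = ly_upsample(l$f),
    flatten = ly_flatten(),
    reshape = ly_reshape(l$shape),
    dense = ly_dense(nrow(l$W), ncol(l$W)),
    dropout = ly_dropout(l$rate),
    stop("unknown layer kind: ", l$kind))
  for (p in l$pnames) nl[[p]] <- l[[p]]
  if (identical(l$kind, "bn")) {
    nl$running_mean <- l$running_mean
    nl$running_var <- l$running_var
  }
  nl
}

clone_network <- function(net) {
  new_voxnet(lapply(net$blocks, clone_block), net$spec, net$kind)
}

#' Save / load a network checkpoint
#'
#' Writes the named-block weights plus a JSON manifest listing block names
#' and parameter counts.
#'
#' @param net a `voxnet`.
#' @param dir checkpoint directory (created if needed).
#' @return `save_network` returns `dir` invisibly; `load_network` returns
#'   the restored `voxnet`.
#' @export
save_network <- function(net, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  saveRDS(list(kind = net$kind, spec = unclass(net$spec),
               state = net_state(net),
               trainable = vapply(net$blocks, function(b) b$trainable,
                                  logical(1))),
          file.path(dir, "network.rds"))
  manifest <- list(kind = net$kind,
                   blocks = as.list(n_params(net, by_block = TRUE)))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' @rdname save_network
#' @export
load_network <- function(dir) {
  obj <- readRDS(file.path(dir, "network.rds"))
  spec <- do.call(network_spec, obj$spec)
  net <- switch(obj$kind,
    generator = build_generator(spec),
    discriminator = build_discriminator(spec),
    classifier = to_classifier(build_discriminator(spec), spec),
    vgg = build_vgg_baseline(spec),
    stop("unknown network kind: ", obj$kind))
  net_set_state(net, obj$state)
  for (bn in names(net$blocks))
    net$blocks[[bn]]$trainable <- obj$trainable[[bn]]
  net
}

# ---- Adam ------------------------------------------------------------------

adam_new <- function(lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  e <- new.env(parent = emptyenv())
  e$lr <- lr; e$beta1 <- beta1; e$beta2 <- beta2; e$eps <- eps
  e$t <- 0L
  e$m <- list(); e$v <- list()
  e
}

# one Adam update over every trainable parameter of `net`; gradients must
# have been populated by a backward pass
adam_step <- function(opt, net) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - opt$beta1^opt$t
  bc2 <- 1 - opt$beta2^opt$t
  li <- 0L
  for (b in net$blocks) {
    if (!b$trainable) next
    for (l in primitive_layers(b$layers)) {
      li <- li + 1L
      for (p in l$pnames) {
        key <- paste0(b$name, ".", li, ".", p)
        g <- l[[paste0("g_", p)]]
        if (is.null(g)) next
        m <- opt$m[[key]]; v <- opt$v[[key]]
        if (is.null(m)) { m <- g * 0; v <- g * 0 }
        m <- opt$beta1 * m + (1 - opt$beta1) * g
        v <- opt$beta2 * v + (1 - opt$beta2) * g * g
        opt$m[[key]] <- m; opt$v[[key]] <- v
        l[[p]] <- l[[p]] - opt$lr * (m / bc1) / (sqrt(v / bc2) + opt$eps)
      }
    }
  }
  invisible(opt)
}
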