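# Layer objects for the 3D CNN engine.
#
# Every primitive layer is an environment with fields
#   kind        layer type tag
#   pnames      names of trainable parameter fields ("W", "b", "gamma", ...)
#   forward(x, training)   -> output (caches whatever backward needs)
#   backward(g)            -> gradient w.r.t. the layer input; parameter
#                             gradients are stored in fields g_<pname>
# Volumes travel as 5-d arrays (x, y, z, channel, sample); dense layers see
# matrices (feature, sample).

trunc_normal <- function(n, sd = 0.02) {
  # truncated at 2 sd, the DCGAN initialisation convention
  u <- stats::runif(n, stats::pnorm(-2), stats::pnorm(2))
  sd * stats::qnorm(u)
}

new_layer <- function(kind) {
  e <- new.env(parent = emptyenv())
  e$kind <- kind
  e$pnames <- character()
  e
}

ly_conv3d <- function(cin, cout, k = 3L, stride = 1L, pad = 1L,
                      init_sd = 0.02) {
  self <- new_layer("conv3d")
  self$k <- as.integer(k); self$stride <- as.integer(stride)
  self$pad <- as.integer(pad)
  self$W <- array(trunc_normal(k^3 * cin * cout, init_sd),
                  dim = c(k, k, k, cin, cout))
  self$b <- numeric(cout)
  self$pnames <- c("W", "b")
  self$forward <- function(x, training = FALSE) {
    self$x <- x
    conv3d_fwd(x, self$W, self$b, self$stride, self$pad)
  }
  self$backward <- function(g, need_gx = TRUE) {
    r <- conv3d_bwd(self$x, self$W, g, self$stride, self$pad, need_gx)
    self$g_W <- r$gw
    self$g_b <- r$gb
    r$gx
  }
  self
}

ly_bn <- function(c, eps = 1e-5, momentum = 0.9) {
  self <- new_layer("bn")
  self$eps <- eps; self$momentum <- momentum
  self$gamma <- rep(1, c); self$beta <- numeric(c)
  self$running_mean <- numeric(c); self$running_var <- rep(1, c)
  self$pnames <- c("gamma", "beta")
  self$forward <- function(x, training = FALSE) {
    if (training) {
      r <- bn_fwd(x, self$gamma, self$beta, self$eps)
      self$x <- x; self$mean <- r$mean; self$invstd <- r$invstd
      self$mode <- "train"
      m <- self$momentum
      self$running_mean <- m * self$running_mean + (1 - m) * r$mean
      self$running_var <- m * self$running_var +
        (1 - m) * (1 / r$invstd^2 - self$eps)
      r$y
    } else {
      self$mode <- "eval"
      bn_eval(x, self$gamma, self$beta, self$running_mean, self$running_var,
              self$eps)
    }
  }
  self$backward <- function(g) {
    if (identical(self$mode, "train")) {
      r <- bn_bwd(self$x, g, self$gamma, self$mean, self$invstd)
      self$g_gamma <- r$ggamma
      self$g_beta <- r$gbeta
      r$gx
    } else {
      # eval-mode normalisation is a fixed per-channel affine map
      a <- self$gamma / sqrt(self$running_var + self$eps)
      d <- dim(g)
      sweep_channel(g, a, d)
    }
  }
  self
}

# multiply a 5-d array by a per-channel factor (axis 4)
sweep_channel <- function(x, a, d = dim(x)) {
  scale <- rep(rep(a, each = prod(d[1:3])), times = d[5])
  y <- x * scale
  dim(y) <- d
  y
}

ly_lrelu <- function(slope = 0.2) {
  self <- new_layer("lrelu")
  self$slope <- slope
  self$forward <- function(x, training = FALSE) {
    self$y <- lrelu_fwd(x, self$slope)
  }
  self$backward <- function(g) lrelu_bwd(self$y, g, self$slope)
  self
}

ly_relu <- function() ly_lrelu(0)

ly_sigmoid <- function() {
  self <- new_layer("sigmoid")
  self$forward <- function(x, training = FALSE) {
    y <- 1 / (1 + exp(-x))
    if (!is.null(dim(x))) dim(y) <- dim(x)
    self$y <- y
  }
  self$backward <- function(g) g * self$y * (1 - self$y)
  self
}

ly_maxpool <- function(k = 2L, stride = 2L) {
  self <- new_layer("maxpool")
  self$k <- as.integer(k); self$stride <- as.integer(stride)
  self$forward <- function(x, training = FALSE) {
    self$in_dim <- dim(x)
    r <- maxpool3d_fwd(x, self$k, self$stride)
    self$idx <- r$idx
    r$out
  }
  self$backward <- function(g) maxpool3d_bwd(g, self$idx, self$in_dim)
  self
}

ly_avgpool <- function(k = 2L, stride = 2L) {
  self <- new_layer("avgpool")
  self$k <- as.integer(k); self$stride <- as.integer(stride)
  self$forward <- function(x, training = FALSE) {
    self$in_dim <- dim(x)
    avgpool3d_fwd(x, self$k, self$stride)
  }
  self$backward <- function(g) avgpool3d_bwd(g, self$in_dim, self$k,
                                             self$stride)
  self
}

ly_upsample <- function(f = 2L) {
  self <- new_layer("upsample")
  self$f <- as.integer(f)
  self$forward <- function(x, training = FALSE) upsample3d_fwd(x, self$f)
  self$backward <- function(g) upsample3d_bwd(g, self$f)
  self
}

ly_flatten <- function() {
  self <- new_layer("flatten")
  self$forward <- function(x, training = FALSE) {
    self$in_dim <- dim(x)
    n <- self$in_dim[length(self$in_dim)]
    dim(x) <- c(length(x) / n, n)
    x
  }
  self$backward <- function(g) {
    dim(g) <- self$in_dim
    g
  }
  self
}

ly_reshape <- function(shape) {
  # matrix (feature, sample) -> array c(shape, sample)
  self <- new_layer("reshape")
  self$shape <- shape
  self$forward <- function(x, training = FALSE) {
    n <- ncol(x)
    dim(x) <- c(self$shape, n)
    x
  }
  self$backward <- function(g) {
    n <- dim(g)[length(dim(g))]
    dim(g) <- c(prod(self$shape), n)
    g
  }
  self
}

ly_dense <- function(nin, nout, init_sd = 0.02) {
  self <- new_layer("dense")
  self$W <- matrix(trunc_normal(nin * nout, init_sd), nin, nout)
  self$b <- numeric(nout)
  self$pnames <- c("W", "b")
  self$forward <- function(x, training = FALSE) {
    self$x <- x
    crossprod(self$W, x) + self$b
  }
  self$backward <- function(g) {
    self$g_W <- self$x %*% t(g)
    self$g_b <- rowSums(g)
    self$W %*% g
  }
  self
}

ly_dropout <- function(rate = 0.5) {
  self <- new_layer("dropout")
  self$rate <- rate
  self$forward <- function(x, training = FALSE) {
    if (training && self$rate > 0) {
      m <- (stats::runif(length(x)) >= self$rate) / (1 - self$rate)
      if (!is.null(dim(x))) dim(m) <- dim(x)
      self$mask <- m
      x * m
    } else {
      self$mask <- NULL
      x
    }
  }
  self$backward <- function(g) {
    if (is.null(self$mask)) g else g * self$mask
  }
  self
}

seq_fwd <- function(layers, x, training = FALSE) {
  for (l in layers) x <- l$forward(x, training)
  x
}

seq_bwd <- function(layers, g, bottom = FALSE) {
  for (i in rev(seq_along(layers))) {
    l <- layers[[i]]
    # the network's lowest convolution can skip its (unused) input gradient
    if (bottom && i == 1L && identical(l$kind, "conv3d"))
      g <- l$backward(g, need_gx = FALSE)
    else
      g <- l$backward(g)
  }
  g
}

# Residual block: y = act(main(x) + shortcut(x)); shortcut NULL => identity.
ly_resblock <- function(main, shortcut = NULL, slope = 0.2) {
  self <- new_layer("resblock")
  self$main <- main; self$shortcut <- shortcut; self$slope <- slope
  self$forward <- function(x, training = FALSE) {
    a <- seq_fwd(self$main, x, training)
    s <- if (is.null(self$shortcut)) x else
      seq_fwd(self$shortcut, x, training)
    self$y <- lrelu_fwd(a + s, self$slope)
  }
  self$backward <- function(g) {
    gy <- lrelu_bwd(self$y, g, self$slope)
    gm <- seq_bwd(self$main, gy)
    gs <- if (is.null(self$shortcut)) gy else seq_bwd(self$shortcut, gy)
    gm + gs
  }
  self
}

# flatten a block's layer list down to primitive layers (recursing into
# residual blocks), used by the optimiser and (de)serialisation
primitive_layers <- function(layers) {
  out <- list()
  for (l in layers) {
    if (identical(l$kind, "resblock")) {
      out <- c(out, primitive_layers(l$main),
               if (!is.null(l$shortcut)) primitive_layers(l$shortcut))
    } else {
      out <- c(out, list(l))
    }
  }
  out
}

layer_n_params <- function(l) {
  sum(vapply(l$pnames, function(p) length(l[[p]]), numeric(1)))
}

# forward pass that re-estimates every batch-norm layer's running
# statistics from the given activations (dropout disabled, trainable flags
# ignored); used when a trunk trained on one input distribution is
# transferred to another
refresh_fwd <- function(layers, x) {
  for (l in layers) {
    x <- switch(l$kind,
      bn = {
        r <- bn_fwd(x, l$gamma, l$beta, l$eps)
        l$running_mean <- r$mean
        l$running_var <- 1 / r$invstd^2 - l$eps
        r$y
      },
      dropout = x,
      resblock = {
        a <- refresh_fwd(l$main, x)
        s0 <- if (is.null(l$shortcut)) x else refresh_fwd(l$shortcut, x)
        lrelu_fwd(a + s0, l$slope)
      },
      l$forward(x, training = FALSE))
  }
  x
}
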