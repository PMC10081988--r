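# The convolutional engine itself: kernels against naive R oracles and
# finite-difference gradients through whole networks.

naive_conv3d <- function(x, w, b, stride, pad) {
  dx <- dim(x); dw <- dim(w)
  X <- dx[1]; Cin <- dx[4]; N <- dx[5]; k <- dw[1]; Cout <- dw[5]
  Xo <- (X + 2 * pad - k) %/% stride + 1
  out <- array(0, unname(c(Xo, Xo, Xo, Cout, N)))
  for (n in 1:N) for (co in 1:Cout) {
    o <- array(b[co], c(Xo, Xo, Xo))
    for (ci in 1:Cin) for (dz in 1:k) for (dy in 1:k) for (dxx in 1:k) {
      wv <- w[dxx, dy, dz, ci, co]
      for (zo in 1:Xo) {
        zi <- (zo - 1) * stride + dz - pad
        if (zi < 1 || zi > X) next
        for (yo in 1:Xo) {
          yi <- (yo - 1) * stride + dy - pad
          if (yi < 1 || yi > X) next
          for (xo in 1:Xo) {
            xi <- (xo - 1) * stride + dxx - pad
            if (xi < 1 || xi > X) next
            o[xo, yo, zo] <- o[xo, yo, zo] + wv * x[xi, yi, zi, ci, n]
          }
        }
      }
    }
    out[, , , co, n] <- o
  }
  out
}

test_that("conv3d forward matches a naive oracle on every dispatch path", {
  set.seed(3)
  cases <- list(c(k = 3, s = 1, p = 1, X = 8, ci = 2, co = 3),
                c(k = 3, s = 2, p = 1, X = 8, ci = 3, co = 2),
                c(k = 1, s = 1, p = 0, X = 6, ci = 2, co = 4),
                c(k = 1, s = 2, p = 0, X = 6, ci = 3, co = 2),
                c(k = 5, s = 1, p = 2, X = 7, ci = 2, co = 2))
  for (cf in cases) {
    cf <- unname(cf)  # (k, s, p, X, ci, co)
    names(cf) <- c("k", "s", "p", "X", "ci", "co")
    x <- array(rnorm(cf["X"]^3 * cf["ci"] * 2),
               unname(c(rep(cf["X"], 3), cf["ci"], 2)))
    w <- array(rnorm(cf["k"]^3 * cf["ci"] * cf["co"]),
               unname(c(rep(cf["k"], 3), cf["ci"], cf["co"])))
    b <- rnorm(cf["co"])
    got <- voxgan:::conv3d_fwd(x, w, b, cf["s"], cf["p"])
    expect_equal(got, naive_conv3d(x, w, b, cf["s"], cf["p"]),
                 tolerance = 1e-12,
                 label = paste0("k=", cf["k"], " s=", cf["s"]))
  }
})

test_that("conv3d backward matches finite differences", {
  set.seed(4)
  for (cf in list(c(k = 3, s = 1, p = 1, X = 6, ci = 2, co = 2),
                  c(k = 3, s = 2, p = 1, X = 6, ci = 2, co = 2),
                  c(k = 1, s = 2, p = 0, X = 6, ci = 2, co = 2))) {
    x <- array(rnorm(cf["X"]^3 * cf["ci"]),
               unname(c(rep(cf["X"], 3), cf["ci"], 1)))
    w <- array(rnorm(cf["k"]^3 * cf["ci"] * cf["co"]),
               unname(c(rep(cf["k"], 3), cf["ci"], cf["co"])))
    b <- rnorm(cf["co"])
    out <- voxgan:::conv3d_fwd(x, w, b, cf["s"], cf["p"])
    r <- array(rnorm(length(out)), dim(out))
    bw <- voxgan:::conv3d_bwd(x, w, r, cf["s"], cf["p"], TRUE)
    eps <- 1e-6
    proj <- function(xx, ww) sum(voxgan:::conv3d_fwd(xx, ww, b, cf["s"],
                                                     cf["p"]) * r)
    for (i in sample(length(w), 3)) {
      w2 <- w; w2[i] <- w[i] + eps; up <- proj(x, w2)
      w2[i] <- w[i] - eps; dn <- proj(x, w2)
      expect_equal(bw$gw[i], (up - dn) / (2 * eps), tolerance = 1e-5)
    }
    for (i in sample(length(x), 3)) {
      x2 <- x; x2[i] <- x[i] + eps; up <- proj(x2, w)
      x2[i] <- x[i] - eps; dn <- proj(x2, w)
      expect_equal(bw$gx[i], (up - dn) / (2 * eps), tolerance = 1e-5)
    }
  }
})

test_that("pooling and upsampling kernels invert/aggregate correctly", {
  set.seed(5)
  x <- array(rnorm(8^3 * 2 * 2), c(8, 8, 8, 2, 2))
  mp <- voxgan:::maxpool3d_fwd(x, 2L, 2L)
  expect_equal(mp$out[1, 1, 1, 1, 1], max(x[1:2, 1:2, 1:2, 1, 1]))
  expect_equal(mp$out[4, 3, 2, 2, 1], max(x[7:8, 5:6, 3:4, 2, 1]))
  g <- array(rnorm(length(mp$out)), dim(mp$out))
  gx <- voxgan:::maxpool3d_bwd(g, mp$idx, dim(x))
  expect_equal(sum(gx), sum(g))              # routes every gradient once
  ap <- voxgan:::avgpool3d_fwd(x, 2L, 2L)
  expect_equal(ap[2, 1, 1, 1, 1], mean(x[3:4, 1:2, 1:2, 1, 1]))
  up <- voxgan:::upsample3d_fwd(ap, 2L)
  expect_identical(dim(up), dim(x))
  expect_equal(up[1, 1, 1, 1, 1], up[2, 2, 2, 1, 1])
  gu <- voxgan:::upsample3d_bwd(up, 2L)
  expect_equal(gu[1, 1, 1, 1, 1], 8 * ap[1, 1, 1, 1, 1])
})

test_that("batch normalisation normalises and back-propagates exactly", {
  set.seed(6)
  x <- array(rnorm(4^3 * 3 * 5, mean = 2, sd = 3), c(4, 4, 4, 3, 5))
  gamma <- runif(3, 0.5, 2); beta <- rnorm(3)
  f <- voxgan:::bn_fwd(x, gamma, beta, 1e-5)
  y1 <- f$y[, , , 1, ]
  expect_equal(mean(y1), beta[1], tolerance = 1e-8)
  expect_equal(stats::sd(as.numeric(y1)) / gamma[1], 1, tolerance = 1e-2)
  gy <- array(rnorm(length(x)), dim(x))
  bw <- voxgan:::bn_bwd(x, gy, gamma, f$mean, f$invstd)
  eps <- 1e-5
  proj <- function(xx) sum(voxgan:::bn_fwd(xx, gamma, beta, 1e-5)$y * gy)
  for (i in sample(length(x), 3)) {
    x2 <- x; x2[i] <- x[i] + eps; up <- proj(x2)
    x2[i] <- x[i] - eps; dn <- proj(x2)
    expect_equal(bw$gx[i], (up - dn) / (2 * eps), tolerance = 1e-4)
  }
})

test_that("whole-network gradients agree with finite differences", {
  set.seed(8)
  spec <- desk16()
  d <- build_discriminator(spec)
  x <- array(runif(16^3 * 2), c(16, 16, 16, 1, 2))
  s <- voxgan:::net_forward(d, x, training = FALSE)
  p <- stats::plogis(as.numeric(s))
  voxgan:::net_backward(d, matrix(p * (1 - p), 1))
  loss <- function() {
    sum(stats::plogis(as.numeric(voxgan:::net_forward(d, x, FALSE))))
  }
  eps <- 1e-6
  for (bn in c("stem", "rb2", "head")) {
    l <- voxgan:::primitive_layers(d$blocks[[bn]]$layers)
    l <- l[[which(vapply(l, function(z) length(z$pnames) > 0,
                         logical(1)))[1]]]
    i <- 2L
    w0 <- l$W[i]
    l$W[i] <- w0 + eps; up <- loss()
    l$W[i] <- w0 - eps; dn <- loss()
    l$W[i] <- w0
    expect_equal(l$g_W[i], (up - dn) / (2 * eps), tolerance = 1e-3,
                 label = paste("block", bn))
  }
})
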