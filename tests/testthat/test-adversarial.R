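# Adversarial round: training loop contracts, accuracy rule, equilibrium
# detection.  Training runs here are deliberately tiny (16^3, few epochs).

gan_fixture <- function(epochs, seed = 1L) {
  fixture(paste0("gan16_", epochs, "_", seed), function() {
    co <- tiny_cohort(grid = 16L, n = 12L, delta = 0.5, seed = 2L)
    set.seed(seed)
    spec <- desk16()
    g <- build_generator(spec)
    d <- build_discriminator(spec)
    list(fit = fit_dcgan(g, d, co$volumes[1:20], co$volumes[21:24],
                         gan_control(epochs = epochs, seed = seed,
                                     batch_size = 8L)),
         g = g, d = d, co = co)
  })
}

test_that("zero epochs returns the networks unchanged with empty history", {
  co <- tiny_cohort(grid = 16L, n = 3L)
  set.seed(1)
  spec <- desk16()
  g <- build_generator(spec)
  d <- build_discriminator(spec)
  fit <- fit_dcgan(g, d, co$volumes[1:4], co$volumes[5:6],
                   gan_control(epochs = 0L))
  expect_identical(nrow(fit$history), 0L)
  expect_identical(net_state_vec(fit$generator), net_state_vec(g))
  expect_identical(net_state_vec(fit$discriminator), net_state_vec(d))
})

test_that("training is bit-reproducible under the seed and leaves inputs alone", {
  fx <- gan_fixture(epochs = 3L)
  before_g <- net_state_vec(fx$g)
  co <- fx$co
  set.seed(99)  # ambient RNG state must not matter
  fit2 <- fit_dcgan(fx$g, fx$d, co$volumes[1:20], co$volumes[21:24],
                    gan_control(epochs = 3L, seed = 1L, batch_size = 8L))
  expect_identical(fx$fit$history, fit2$history)
  expect_identical(net_state_vec(fx$fit$generator),
                   net_state_vec(fit2$generator))
  expect_identical(net_state_vec(fx$g), before_g)  # inputs untouched
})

test_that("re-evaluating the frozen fit reproduces the last history row", {
  fx <- gan_fixture(epochs = 3L)
  ev <- evaluate_dcgan(fx$fit, fx$co$volumes[21:24])
  last <- fx$fit$history[3, c("g_loss", "d_loss", "d_accuracy")]
  rownames(last) <- NULL
  expect_equal(ev, last, tolerance = 1e-12)
})

test_that("discriminator accuracy counts ties as incorrect", {
  spec <- desk16()
  set.seed(3)
  d <- build_discriminator(spec)
  head_dense <- voxgan:::primitive_layers(d$blocks$head$layers)
  out_l <- head_dense[[length(head_dense)]]
  out_l$W[] <- 0; out_l$b[] <- 0        # every score exactly 0.5
  co <- tiny_cohort(grid = 16L, n = 3L)
  expect_equal(d_accuracy(d, co$volumes[1:3], co$volumes[4:6]), 0)
  out_l$b[] <- 5                        # everything called "real"
  expect_equal(d_accuracy(d, co$volumes[1:3], co$volumes[4:6]), 0.5)
  expect_error(d_accuracy(d, list(), co$volumes[1:2]), "at least one")
})

test_that("equilibrium rule uses a closed interval on the window mean", {
  ctl <- gan_control(equilibrium_window = 5L, equilibrium_tol = 0.1)
  h <- function(acc) data.frame(epoch = seq_along(acc), g_loss = 0,
                                d_loss = 0, d_accuracy = acc)
  expect_true(reached_equilibrium(h(rep(0.5, 10)), ctl))
  expect_false(reached_equilibrium(h(rep(1.0, 10)), ctl))
  expect_true(reached_equilibrium(h(rep(0.6, 10)), ctl))   # exactly at tol
  expect_false(reached_equilibrium(h(rep(0.6 + 1e-9, 10)), ctl))
  expect_true(reached_equilibrium(h(c(rep(1, 5), rep(0.45, 5))), ctl))
  expect_error(reached_equilibrium(h(rep(0.5, 3)), ctl), "window")
})

test_that("generated cohort statistics drift toward the real data", {
  # the 16^3 generator's spatial seed is degenerate (1 voxel), so the
  # drift property is checked at 32^3, scaled to a small cohort
  co <- tiny_cohort(grid = 32L, n = 15L, delta = 0.5, seed = 4L)
  drift <- vapply(1:3, function(s) {
    set.seed(s)
    spec <- network_spec_desk(32L)
    g0 <- build_generator(spec)
    d0 <- build_discriminator(spec)
    real_mean <- Reduce(`+`, lapply(co$volumes[1:24],
                                    function(v) v$data)) / 24
    gap <- function(gen) {
      fake <- generate_volumes(gen, 16L,
                               latent = matrix(voxgan:::with_seed(123L,
                                 rnorm(100 * 16)), 100, 16))
      mean(abs(apply(fake[, , , 1, ], 1:3, mean) - real_mean))
    }
    g_before <- gap(g0)
    fit <- fit_dcgan(g0, d0, co$volumes[1:24], co$volumes[25:30],
                     gan_control(epochs = 40L, seed = s))
    g_before - gap(fit$generator)
  }, numeric(1))
  expect_gt(mean(drift), 0)
})

test_that("fitted GANs expose simulate/print/plot methods", {
  fx <- gan_fixture(epochs = 3L)
  sims <- simulate(fx$fit, nsim = 2, seed = 11L)
  expect_length(sims, 2L)
  expect_identical(dim(sims[[1]]$data), rep(16L, 3))
  expect_true(all(sims[[1]]$data >= 0 & sims[[1]]$data <= 1))
  expect_output(print(fx$fit), "DCGAN fit")
  f <- withr::local_tempfile(fileext = ".png")
  grDevices::png(f); plot(fx$fit); grDevices::dev.off()
  expect_gt(file.info(f)$size, 0)
})
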