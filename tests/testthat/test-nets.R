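# Architecture contracts: block shapes, parameter counts, conversion and
# baseline structure.

test_that("desk generator doubles its seed volume four times into [0,1]", {
  spec <- network_spec_desk(32L)
  set.seed(1)
  g <- build_generator(spec)
  z <- matrix(rnorm(100 * 2), 100, 2)
  tr <- voxgan:::net_forward_trace(g, z)
  expect_identical(dim(tr$blocks$g_fc)[1:4], c(2L, 2L, 2L, 16L))
  expect_identical(dim(tr$blocks$up1)[1:3], rep(4L, 3))
  expect_identical(dim(tr$blocks$up4)[1:4], c(32L, 32L, 32L, 1L))
  expect_true(all(tr$output >= 0 & tr$output <= 1))
  # extreme latents stay bounded
  ext <- voxgan:::net_forward(g, matrix(50, 100, 1))
  expect_true(all(ext >= 0 & ext <= 1))
})

test_that("inconsistent generator seed volume is a configuration error", {
  expect_error(network_spec(input_size = 64L,
                            g_fc_shape = c(2L, 2L, 2L, 128L)),
               "inconsistent spec")
  expect_error(network_spec(input_size = 40L), "divisible by 16")
})

test_that("discriminator blocks have the documented shapes and head", {
  spec <- network_spec_desk(32L)
  set.seed(2)
  d <- build_discriminator(spec)
  x <- array(runif(32^3), c(32, 32, 32, 1, 1))
  tr <- voxgan:::net_forward_trace(d, x)
  expect_identical(dim(tr$blocks$stem)[1:4], c(16L, 16L, 16L, 2L))
  expect_identical(dim(tr$blocks$rb1)[1:4], c(16L, 16L, 16L, 2L))
  expect_identical(dim(tr$blocks$rb2)[1:4], c(8L, 8L, 8L, 4L))
  expect_identical(dim(tr$blocks$rb3)[1:4], c(8L, 8L, 8L, 4L))
  expect_identical(dim(tr$blocks$rb4)[1:4], c(4L, 4L, 4L, 8L))
  expect_length(tr$output, 1L)
  p <- predict(d, x)
  expect_true(p > 0 && p < 1)
})

test_that("halving the input preserves channel counts and structure", {
  s32 <- network_spec(input_size = 32L, g_fc_shape = c(2L, 2L, 2L, 128L))
  s64 <- network_spec()
  expect_identical(s32$d_block_channels, s64$d_block_channels)
  set.seed(3)
  d32 <- build_discriminator(s32)
  d64 <- build_discriminator(s64)
  expect_identical(names(d32$blocks), names(d64$blocks))
  cnt <- function(net) {
    vapply(net$blocks, function(b)
      length(voxgan:::primitive_layers(b$layers)), integer(1))
  }
  expect_identical(cnt(d32), cnt(d64))
})

test_that("classifier conversion copies conv weights and re-heads", {
  spec <- desk16()
  set.seed(4)
  d <- build_discriminator(spec)
  cls <- to_classifier(d)
  for (bn in c("stem", "rb1", "rb2", "rb3", "rb4")) {
    expect_identical(voxgan:::net_state(cls)[[bn]],
                     voxgan:::net_state(d)[[bn]])
  }
  x <- array(runif(16^3), c(16, 16, 16, 1, 1))
  p <- predict(cls, x)
  expect_true(p > 0 && p < 1)
  # fine-tuning the copy must not touch the original discriminator
  before <- net_state_vec(d)
  co <- tiny_cohort(n = 8L)
  fine_tune(cls, co$volumes, co$volumes,
            fine_tune_control(epochs = 1L, seed = 1L))
  expect_identical(net_state_vec(d), before)
  expect_error(to_classifier(build_vgg_baseline(spec)), "discriminator")
})

test_that("classification head parameter count matches the closed form", {
  set.seed(5)
  cls <- to_classifier(build_discriminator(network_spec()))
  # widths (512, 64, 1) on a flattened length of 4*4*4*64 = 4096
  expect_equal(unname(n_params(cls, by_block = TRUE)["head"]),
               4096 * 512 + 512 + 512 * 64 + 64 + 64 * 1 + 1)
})

test_that("the VGG-like baseline is shortcut-free and deterministic", {
  spec <- desk16()
  set.seed(6)
  v <- build_vgg_baseline(spec)
  kinds <- unlist(lapply(v$blocks, function(b)
    vapply(b$layers, function(l) l$kind, character(1))))
  expect_false(any(kinds == "resblock"))
  p <- predict(v, array(runif(16^3), c(16, 16, 16, 1, 1)))
  expect_true(p > 0 && p < 1)
  set.seed(6)
  v2 <- build_vgg_baseline(spec)
  expect_identical(n_params(v), n_params(v2))
  expect_identical(net_state_vec(v), net_state_vec(v2))
})

test_that("checkpoints round-trip through save_network/load_network", {
  dir <- withr::local_tempdir()
  set.seed(7)
  spec <- desk16()
  d <- build_discriminator(spec)
  save_network(d, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_named(man$blocks, names(d$blocks))
  back <- load_network(dir)
  expect_identical(net_state_vec(back), net_state_vec(d))
  x <- array(runif(16^3), c(16, 16, 16, 1, 1))
  expect_identical(predict(back, x), predict(d, x))
})
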