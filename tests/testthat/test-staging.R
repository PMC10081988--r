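# Transfer rounds: freeze policies, class weights, fine-tuning, pipeline
# chaining.

test_that("freeze policies are nested and the head is never frozen", {
  pols <- freeze_policies()
  sets <- lapply(pols, voxgan:::frozen_blocks_for)
  for (i in seq_len(length(sets) - 1))
    expect_true(all(sets[[i]] %in% sets[[i + 1]]))
  expect_false(any(vapply(sets, function(s) "head" %in% s, logical(1))))
  expect_identical(voxgan:::frozen_blocks_for("through_rb2"),
                   c("stem", "rb1", "rb2"))
})

test_that("apply_freeze sets trainability flags as documented", {
  set.seed(1)
  cls <- to_classifier(build_discriminator(desk16()))
  apply_freeze(cls, "through_rb2")
  tr <- vapply(cls$blocks, function(b) b$trainable, logical(1))
  expect_identical(tr, c(stem = FALSE, rb1 = FALSE, rb2 = FALSE,
                         rb3 = TRUE, rb4 = TRUE, head = TRUE))
  apply_freeze(cls, "none")
  expect_true(all(vapply(cls$blocks, function(b) b$trainable, logical(1))))
  expect_error(apply_freeze(build_vgg_baseline(desk16()), "stem"),
               "lacks named block")
})

test_that("no parameter or statistic in a frozen block moves during training", {
  set.seed(2)
  cls <- to_classifier(build_discriminator(desk16()))
  apply_freeze(cls, "through_rb3")
  co <- tiny_cohort(grid = 16L, n = 10L)
  # recalibration off isolates the training-step contract
  fit <- fine_tune(cls, co$volumes, co$volumes[1:6],
                   fine_tune_control(epochs = 2L, seed = 3L,
                                     recalibrate_bn = FALSE))
  s0 <- voxgan:::net_state(cls)
  s1 <- voxgan:::net_state(fit$classifier)
  for (bn in c("stem", "rb1", "rb2", "rb3"))
    expect_identical(s1[[bn]], s0[[bn]], label = paste("frozen", bn))
  expect_false(identical(s1$head, s0$head))
  expect_false(identical(s1$rb4, s0$rb4))
  # with recalibration on, only batch-norm running statistics may differ
  fit2 <- fine_tune(cls, co$volumes, co$volumes[1:6],
                    fine_tune_control(epochs = 2L, seed = 3L))
  s2 <- voxgan:::net_state(fit2$classifier)
  drop_stats <- function(b) lapply(b, function(l)
    l[setdiff(names(l), c("running_mean", "running_var"))])
  for (bn in c("stem", "rb1", "rb2", "rb3"))
    expect_identical(drop_stats(s2[[bn]]), drop_stats(s0[[bn]]),
                     label = paste("frozen weights", bn))
})

test_that("class weights follow total/count with mean-1 normalisation", {
  expect_equal(class_weights_from_counts(c(100, 100)), c(1, 1))
  expect_equal(class_weights_from_counts(c(150, 50)), c(0.5, 1.5))
  expect_equal(class_weights_from_counts(c(300, 100)),
               class_weights_from_counts(c(150, 50)))
  expect_error(class_weights_from_counts(c(10, 0)), "positive")
})

test_that("balanced data makes the weighted loss equal the unweighted one", {
  set.seed(4)
  cls <- to_classifier(build_discriminator(desk16()))
  co <- tiny_cohort(grid = 16L, n = 8L)
  ctl_auto <- fine_tune_control(epochs = 2L, seed = 5L)
  ctl_unit <- fine_tune_control(epochs = 2L, seed = 5L,
                                class_weights = c(1, 1))
  f1 <- fine_tune(cls, co$volumes, co$volumes[1:4], ctl_auto)
  f2 <- fine_tune(cls, co$volumes, co$volumes[1:4], ctl_unit)
  expect_identical(f1$history, f2$history)
})

test_that("fine_tune honours epochs = 0, determinism and preconditions", {
  set.seed(6)
  cls <- to_classifier(build_discriminator(desk16()))
  co <- tiny_cohort(grid = 16L, n = 8L)
  f0 <- fine_tune(cls, co$volumes, co$volumes[1:4],
                  fine_tune_control(epochs = 0L, recalibrate_bn = FALSE))
  expect_identical(net_state_vec(f0$classifier), net_state_vec(cls))
  fa <- fine_tune(cls, co$volumes, co$volumes[1:4],
                  fine_tune_control(epochs = 3L, seed = 7L))
  fb <- fine_tune(cls, co$volumes, co$volumes[1:4],
                  fine_tune_control(epochs = 3L, seed = 7L))
  expect_identical(fa$best_epoch, fb$best_epoch)
  expect_identical(fa$history, fb$history)
  only0 <- co$volumes[vapply(co$volumes, function(v) v$label == 0L,
                             logical(1))]
  expect_error(fine_tune(cls, only0, co$volumes[1:2],
                         fine_tune_control(epochs = 1L)), "single class")
})

test_that("a GAN-pre-trained classifier learns the phantom task", {
  co <- tiny_cohort(grid = 16L, n = 30L, delta = 0.6, noise = 0.05,
                    seed = 8L)
  accs <- vapply(1:3, function(s) {
    set.seed(s)
    spec <- desk16()
    gan <- fit_dcgan(build_generator(spec), build_discriminator(spec),
                     co$volumes[1:50], co$volumes[51:60],
                     gan_control(epochs = 40L, seed = s))
    cls <- to_classifier(gan$discriminator)
    apply_freeze(cls, "through_rb2")
    parts <- voxgan:::split_cohort(co, c(6, 2, 2), seed = s)
    fit <- fine_tune(cls, parts$train, parts$validation,
                     fine_tune_control(epochs = 20L, seed = s))
    max(fit$history$val_accuracy)
  }, numeric(1))
  expect_gt(mean(accs), 0.8)
})

test_that("the three-round pipeline chains weights and reports per task", {
  co <- tiny_cohort(grid = 16L, n = 16L, delta = 0.6, seed = 9L)
  co2 <- tiny_cohort(grid = 16L, n = 12L, delta = 0.3, noise = 0.05,
                     seed = 10L)
  task <- voxgan:::split_cohort(co, c(6, 2, 2), seed = 1L)
  task2 <- voxgan:::split_cohort(co2, c(6, 2, 2), seed = 1L)
  mk_task <- function(p) list(train = p$train, validation = p$validation,
                              test = p$test)
  fit <- three_round_pipeline(
    co$volumes, mk_task(task), list(secondary = mk_task(task2)),
    spec = desk16(),
    gan_control = gan_control(epochs = 4L, seed = 1L),
    ft_control = fine_tune_control(epochs = 3L, seed = 1L))
  expect_identical(fit$reports$task, c("primary", "secondary"))
  expect_true(all(fit$reports$accuracy >= 0 & fit$reports$accuracy <= 1))
  # round 3 froze stem and rb1: their parameters must equal round 2's
  # exactly (batch-norm running statistics are re-estimated per task)
  drop_stats <- function(b) lapply(b, function(l)
    l[setdiff(names(l), c("running_mean", "running_var"))])
  s2 <- voxgan:::net_state(fit$primary_fit$classifier)
  s3 <- voxgan:::net_state(fit$secondary_fits$secondary$classifier)
  expect_identical(drop_stats(s3$stem), drop_stats(s2$stem))
  expect_identical(drop_stats(s3$rb1), drop_stats(s2$rb1))

  # degenerate zero-epoch run still completes and reports
  fit0 <- three_round_pipeline(
    co$volumes[1:10], mk_task(task), list(),
    spec = desk16(),
    gan_control = gan_control(epochs = 0L, seed = 1L),
    ft_control = fine_tune_control(epochs = 0L, seed = 1L))
  expect_equal(nrow(fit0$reports), 1L)
  expect_true(is.finite(fit0$reports$accuracy))
})
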