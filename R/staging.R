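# Rounds 2 and 3: discriminator-to-classifier transfer with staged layer
# freezing and class-weighted fine-tuning.

#' Freeze policies for the discriminator-derived classifier
#'
#' The six policies freeze nested prefixes of the convolutional trunk:
#' `"none"` trains everything; `"stem"` freezes the convolution stem;
#' `"through_rb1"` .. `"through_rb4"` freeze the stem plus residual blocks
#' up to the named one.  The classification head is always fully trained.
#' Round 2 of the standard pipeline uses `"through_rb2"` (stem and first
#' two residual blocks kept unchanged); round 3 uses `"through_rb1"`.
#'
#' @return Character vector of the six policy names, in nesting order.
#' @export
freeze_policies <- function() {
  c("none", "stem", "through_rb1", "through_rb2", "through_rb3",
    "through_rb4")
}

frozen_blocks_for <- function(policy) {
  policy <- match.arg(policy, freeze_policies())
  switch(policy,
         none = character(0),
         stem = "stem",
         through_rb1 = c("stem", "rb1"),
         through_rb2 = c("stem", "rb1", "rb2"),
         through_rb3 = c("stem", "rb1", "rb2", "rb3"),
         through_rb4 = c("stem", "rb1", "rb2", "rb3", "rb4"))
}

#' Apply a freeze policy to a classifier
#'
#' Frozen blocks are excluded from gradient updates (their batch
#' normalisation also runs in inference mode during training, so no
#' statistic inside a frozen block changes); the remaining convolutional
#' blocks are fine-tuned and the head is always fully trained.  The
#' network is modified in place and returned invisibly.
#'
#' @param classifier a classifier `voxnet` with blocks `stem`,
#'   `rb1`..`rb4`, `head`.
#' @param policy one of [freeze_policies()].
#' @return The classifier, invisibly.
#' @export
apply_freeze <- function(classifier, policy) {
  frozen <- frozen_blocks_for(policy)
  need <- c("stem", "rb1", "rb2", "rb3", "rb4", "head")
  missing <- setdiff(need, names(classifier$blocks))
  if (length(missing))
    stop("classifier lacks named block(s): ",
         paste(missing, collapse = ", "))
  for (bn in need)
    classifier$blocks[[bn]]$trainable <- !(bn %in% frozen)
  invisible(classifier)
}

#' Class weights from per-class counts
#'
#' Weight for class c proportional to total/count_c, normalised to mean 1,
#' so the weighted binary cross-entropy reduces to the unweighted loss for
#' balanced classes.
#'
#' @param n_per_class counts for classes 0 and 1 (both >= 1).
#' @return Numeric weights of length 2 with mean 1.
#' @export
class_weights_from_counts <- function(n_per_class) {
  if (length(n_per_class) != 2L || any(n_per_class < 1))
    stop("need two positive class counts")
  w <- sum(n_per_class) / n_per_class
  w / mean(w)
}

#' Fine-tuning configuration
#'
#' @param lr Adam learning rate (default 1e-3, the reference recipe).
#' @param batch_size minibatch size.
#' @param epochs fine-tuning epochs.
#' @param seed integer seed governing all randomness of the run.
#' @param class_weights optional per-class loss weights (classes 0, 1);
#'   computed from the training counts via [class_weights_from_counts()]
#'   when `NULL`.
#' @param recalibrate_bn re-estimate every batch-normalisation layer's
#'   running statistics on the fine-tuning training set before training
#'   (default TRUE).  A trunk pre-trained adversarially carries running
#'   statistics blended over real and generated batches; frozen blocks
#'   would otherwise mis-normalise real volumes at evaluation time.
#' @return An object of class `fine_tune_control`.
#' @export
fine_tune_control <- function(lr = 1e-3, batch_size = 16L, epochs = 30L,
                              seed = 1L, class_weights = NULL,
                              recalibrate_bn = TRUE) {
  stopifnot(lr > 0, batch_size >= 1L, epochs >= 0L,
            is.null(class_weights) ||
              (length(class_weights) == 2L && all(class_weights > 0)))
  structure(list(lr = lr, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 class_weights = class_weights,
                 recalibrate_bn = isTRUE(recalibrate_bn)),
            class = "fine_tune_control")
}

vol_labels <- function(vols) {
  y <- vapply(vols, function(v) v$label, integer(1))
  if (anyNA(y) || !all(y %in% c(0L, 1L)))
    stop("all volumes must carry binary labels (0/1)")
  y
}

#' Fine-tune a classifier with class-weighted binary cross-entropy
#'
#' Minimises the class-weighted binary cross-entropy with Adam, honouring
#' whatever freeze policy is set on the network.  After every epoch the
#' validation accuracy (threshold 0.5) is recorded and the parameter state
#' with the best validation accuracy is retained (ties resolved toward the
#' earlier epoch).  The input network is left untouched; a trained copy is
#' returned.
#'
#' @param classifier a classifier (or baseline) `voxnet`; labels are taken
#'   from the volumes.
#' @param train_vols,val_vols labeled [volume_grid()] lists; the training
#'   set must contain both classes.
#' @param control a [fine_tune_control()].
#' @return An object of class `voxnet_fit`: `classifier` (best-epoch
#'   state), `history` (`epoch`, `train_loss`, `val_accuracy`),
#'   `best_epoch`, `control`.
#' @export
fine_tune <- function(classifier, train_vols, val_vols,
                      control = fine_tune_control()) {
  stopifnot(inherits(classifier, "voxnet"),
            classifier$kind %in% c("classifier", "vgg"),
            inherits(control, "fine_tune_control"))
  size <- classifier$spec$input_size
  check_volume_sizes(train_vols, size)
  check_volume_sizes(val_vols, size)
  y_train <- vol_labels(train_vols)
  if (length(unique(y_train)) < 2L)
    stop("training set contains a single class; cannot fine-tune")
  y_val <- vol_labels(val_vols)
  w <- control$class_weights %||%
    class_weights_from_counts(c(sum(y_train == 0L), sum(y_train == 1L)))

  net <- clone_network(classifier)
  x_train <- as_batch(train_vols)
  x_val <- as_batch(val_vols)
  n <- length(train_vols)
  b <- control$batch_size

  hist <- list(train_loss = numeric(control$epochs),
               val_accuracy = numeric(control$epochs))
  best <- list(acc = -Inf, epoch = 0L, state = net_state(net))

  if (control$recalibrate_bn %||% TRUE) {
    for (blk in net$blocks) {
      x_train <- refresh_fwd(blk$layers, x_train)
    }
    x_train <- as_batch(train_vols)
  }
  best$state <- net_state(net)

  with_seed(control$seed, {
    opt <- adam_new(control$lr)
    epoch <- 0L
    while (epoch < control$epochs) {
      epoch <- epoch + 1L
      ord <- sample.int(n)
      loss_sum <- 0
      for (s0 in seq(1L, n, by = b)) {
        idx <- ord[s0:min(s0 + b - 1L, n)]
        xb <- x_train[, , , , idx, drop = FALSE]
        yb <- y_train[idx]
        wb <- w[yb + 1L]
        sc <- net_forward(net, xb, training = TRUE)
        p <- stats::plogis(as.numeric(sc))
        pc <- pmin(pmax(p, 1e-7), 1 - 1e-7)
        loss_sum <- loss_sum -
          sum(wb * (yb * log(pc) + (1 - yb) * log(1 - pc)))
        gs <- matrix(wb * (p - yb) / length(yb), 1L)
        net_backward(net, gs, input_grad = FALSE)
        adam_step(opt, net)
      }
      p_val <- stats::plogis(
        as.numeric(net_forward(net, x_val, training = FALSE)))
      acc <- mean((p_val > 0.5) == (y_val == 1L))
      hist$train_loss[epoch] <- loss_sum / n
      hist$val_accuracy[epoch] <- acc
      if (acc > best$acc) {
        best$acc <- acc
        best$epoch <- epoch
        best$state <- net_state(net)
      }
    }
  })

  net_set_state(net, best$state)
  structure(list(classifier = net,
                 history = data.frame(epoch = seq_len(control$epochs),
                                      train_loss = hist$train_loss,
                                      val_accuracy = hist$val_accuracy),
                 best_epoch = best$epoch, control = control),
            class = "voxnet_fit")
}

#' @export
print.voxnet_fit <- function(x, ...) {
  cat("fine-tuned", x$classifier$kind, "(", nrow(x$history), "epochs )\n")
  if (nrow(x$history) > 0)
    cat(sprintf("  best validation accuracy %.3f at epoch %d\n",
                max(x$history$val_accuracy), x$best_epoch))
  frozen <- names(x$classifier$blocks)[!vapply(x$classifier$blocks,
                                               function(b) b$trainable,
                                               logical(1))]
  if (length(frozen))
    cat("  frozen blocks:", paste(frozen, collapse = ", "), "\n")
  invisible(x)
}

#' @export
predict.voxnet_fit <- function(object, newdata, ...) {
  predict(object$classifier, newdata, ...)
}

#' @export
plot.voxnet_fit <- function(x, ...) {
  h <- x$history
  graphics::plot(h$epoch, h$val_accuracy, type = "l", ylim = c(0, 1),
                 xlab = "epoch", ylab = "validation accuracy", ...)
  graphics::abline(v = x$best_epoch, lty = 2)
  invisible(x)
}

# fresh classification head on the conv trunk of an existing classifier
# (round 3 re-heading: conv weights copied, head re-initialised)
re_head <- function(classifier, spec = classifier$spec) {
  cw <- spec$classifier_fc_widths
  flat <- d_flat_len(spec)
  conv <- lapply(classifier$blocks[c("stem", "rb1", "rb2", "rb3", "rb4")],
                 clone_block)
  head <- new_block("head", list(
    ly_avgpool(2L, 2L), ly_flatten(),
    ly_dense(flat, cw[1]), ly_lrelu(0.2),
    ly_dropout(spec$dropout_rate),
    ly_dense(cw[1], cw[2]), ly_lrelu(0.2),
    ly_dense(cw[2], cw[3])))
  new_voxnet(c(conv, list(head = head)), spec, "classifier")
}

#' Run the full three-round learning pipeline
#'
#' Round 1 trains the DCGAN on all unlabeled volumes (a fraction is held
#' out for equilibrium monitoring).  Round 2 converts the trained
#' discriminator to a classifier, freezes the stem and first two residual
#' blocks (`"through_rb2"`) and fine-tunes on the primary task.  Round 3
#' copies the round-2 convolutional weights into a freshly-headed
#' classifier per secondary task, freezes the stem and first residual
#' block (`"through_rb1"`) and fine-tunes.  A metrics report (threshold
#' 0.5) is produced for every task's test partition.
#'
#' @param unlabeled_vols volumes for adversarial pre-training.
#' @param primary_task,secondary_tasks a task is a named list with
#'   `train`, `validation`, `test` lists of labeled volumes;
#'   `secondary_tasks` is a named list of such tasks (possibly empty).
#' @param spec the [network_spec()] shared by all rounds.
#' @param gan_control,ft_control configurations for round 1 and the
#'   fine-tuning rounds.
#' @param gan_val_fraction fraction of `unlabeled_vols` held out for GAN
#'   monitoring.
#' @return An object of class `three_round_fit`: `gan` (the `dcgan_fit`),
#'   `primary_fit`, `secondary_fits`, and `reports`, a data frame with one
#'   row per task (accuracy, sensitivity, precision, AUC on test).
#' @export
three_round_pipeline <- function(unlabeled_vols, primary_task,
                                 secondary_tasks = list(),
                                 spec = network_spec_desk(),
                                 gan_control = voxgan::gan_control(),
                                 ft_control = fine_tune_control(),
                                 gan_val_fraction = 0.1) {
  n <- length(unlabeled_vols)
  n_val <- max(1L, floor(n * gan_val_fraction))
  ord <- with_seed(derive_seed(gan_control$seed, "gan_split"),
                   sample.int(n))
  gan_val <- unlabeled_vols[ord[seq_len(n_val)]]
  gan_train <- unlabeled_vols[ord[-seq_len(n_val)]]

  g <- with_seed(derive_seed(gan_control$seed, "g_init"),
                 build_generator(spec))
  d <- with_seed(derive_seed(gan_control$seed, "d_init"),
                 build_discriminator(spec))
  gan <- tryCatch(
    fit_dcgan(g, d, gan_train, gan_val, gan_control),
    error = function(e) stop("round 1 (adversarial): ",
                             conditionMessage(e), call. = FALSE))

  cls <- with_seed(derive_seed(ft_control$seed, "head2"),
                   to_classifier(gan$discriminator, spec))
  apply_freeze(cls, "through_rb2")
  ctl2 <- ft_control
  ctl2$seed <- derive_seed(ft_control$seed, "round2")
  primary_fit <- tryCatch(
    fine_tune(cls, primary_task$train, primary_task$validation, ctl2),
    error = function(e) stop("round 2 (primary fine-tune): ",
                             conditionMessage(e), call. = FALSE))

  task_report <- function(fit, task) {
    compute_metrics(predict(fit, task$test), vol_labels(task$test))
  }
  reports <- list(primary = task_report(primary_fit, primary_task))

  secondary_fits <- list()
  for (tn in names(secondary_tasks)) {
    cls3 <- with_seed(derive_seed(ft_control$seed, "head3", tn),
                      re_head(primary_fit$classifier, spec))
    apply_freeze(cls3, "through_rb1")
    ctl3 <- ft_control
    ctl3$seed <- derive_seed(ft_control$seed, "round3", tn)
    fit3 <- tryCatch(
      fine_tune(cls3, secondary_tasks[[tn]]$train,
                secondary_tasks[[tn]]$validation, ctl3),
      error = function(e) stop("round 3 (", tn, "): ",
                               conditionMessage(e), call. = FALSE))
    secondary_fits[[tn]] <- fit3
    reports[[tn]] <- task_report(fit3, secondary_tasks[[tn]])
  }

  rep_df <- do.call(rbind, lapply(names(reports), function(tn) {
    m <- reports[[tn]]
    data.frame(task = tn, accuracy = m$accuracy,
               sensitivity = m$sensitivity, precision = m$precision,
               auc = m$auc, stringsAsFactors = FALSE)
  }))
  structure(list(gan = gan, primary_fit = primary_fit,
                 secondary_fits = secondary_fits, reports = rep_df),
            class = "three_round_fit")
}

#' @export
print.three_round_fit <- function(x, ...) {
  cat("three-round learning pipeline\n")
  cat("  round 1:", nrow(x$gan$history), "GAN epochs",
      if (nrow(x$gan$history) >= x$gan$control$equilibrium_window &&
          reached_equilibrium(x$gan, x$gan$control))
        "(reached equilibrium)" else "", "\n")
  cat("  test-set metrics per task:\n")
  print(x$reports, row.names = FALSE, digits = 3)
  invisible(x)
}
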