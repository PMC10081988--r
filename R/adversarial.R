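# Round 1: unsupervised adversarial pre-training of the 3D DCGAN.

#' Training configuration for the 3D DCGAN
#'
#' Defaults follow the reference training recipe: batch size 16, Adam with
#' initial learning rates 2e-3 for the generator and 2e-4 for the
#' discriminator, binary cross-entropy losses.  `epochs` defaults to the
#' desk-scale figure of 200 (the full-scale run uses 1000).  Equilibrium is
#' declared when the moving average of the discriminator's held-out
#' real-vs-fake accuracy over `equilibrium_window` epochs lies within
#' `0.5 +/- equilibrium_tol` -- the operational form of "the discriminator
#' hovers around 50% at the Nash equilibrium".
#'
#' @param batch_size minibatch size (>= 1).
#' @param lr_g,lr_d initial Adam learning rates for generator and
#'   discriminator.
#' @param lr_decay `"linear"` (default) anneals both learning rates
#'   linearly to zero over the scheduled epochs -- the standard DCGAN
#'   stabilisation, and what "initial learning rate" implies; `"none"`
#'   keeps them constant.
#' @param epochs training epochs.
#' @param seed integer seed governing all randomness of the run.
#' @param equilibrium_window epochs in the moving average.
#' @param equilibrium_tol allowed deviation of discriminator accuracy
#'   from 0.5.
#' @return An object of class `gan_control`.
#' @export
gan_control <- function(batch_size = 16L, lr_g = 2e-3, lr_d = 2e-4,
                        lr_decay = c("linear", "none"),
                        epochs = 200L, seed = 1L,
                        equilibrium_window = 20L, equilibrium_tol = 0.1) {
  stopifnot(batch_size >= 1L, lr_g > 0, lr_d > 0, epochs >= 0L,
            equilibrium_window >= 1L, equilibrium_tol >= 0)
  structure(list(batch_size = as.integer(batch_size), lr_g = lr_g,
                 lr_d = lr_d, lr_decay = match.arg(lr_decay),
                 epochs = as.integer(epochs),
                 seed = as.integer(seed),
                 equilibrium_window = as.integer(equilibrium_window),
                 equilibrium_tol = equilibrium_tol),
            class = "gan_control")
}

check_volume_sizes <- function(vols, input_size) {
  ok <- vapply(vols, function(v) all(dim(v$data) == input_size), logical(1))
  if (!all(ok))
    stop("all volumes must be ", input_size, "^3 voxels; found ",
         paste(dim(vols[[which(!ok)[1]]]$data), collapse = " x "))
}

bce_loss <- function(p, y) {
  p <- pmin(pmax(p, 1e-7), 1 - 1e-7)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Adversarially train a 3D DCGAN
#'
#' Alternating minibatch updates under binary cross-entropy: one
#' discriminator step on an equal mix of real and freshly generated
#' volumes (labels 1/0, no smoothing), then one non-saturating generator
#' step (generated volumes against label 1).  After every epoch the
#' generator loss, discriminator loss and discriminator real-vs-fake
#' accuracy are evaluated on the held-out volumes against a fixed, seeded
#' set of evaluation latents, decoupling the monitoring from training
#' noise.  All randomness derives from `control$seed`; the input networks
#' are left untouched and trained copies are returned.
#'
#' @param g,d generator and discriminator from [build_generator()] /
#'   [build_discriminator()].
#' @param train_vols,val_vols lists of [volume_grid()]s at the spec's
#'   input size.
#' @param control a [gan_control()].
#' @return An object of class `dcgan_fit` with elements `generator`,
#'   `discriminator`, `history` (one row per epoch: `epoch`, `g_loss`,
#'   `d_loss`, `d_accuracy`), `eval_latent` and `control`.
#' @seealso [reached_equilibrium()], [d_accuracy()],
#'   [simulate.dcgan_fit()].
#' @export
fit_dcgan <- function(g, d, train_vols, val_vols, control = gan_control()) {
  stopifnot(inherits(g, "voxnet"), g$kind == "generator",
            inherits(d, "voxnet"), d$kind == "discriminator",
            inherits(control, "gan_control"))
  size <- d$spec$input_size
  check_volume_sizes(train_vols, size)
  check_volume_sizes(val_vols, size)
  g <- clone_network(g)
  d <- clone_network(d)

  x_train <- as_batch(train_vols)
  x_val <- as_batch(val_vols)
  n_train <- length(train_vols)
  n_val <- length(val_vols)
  latent_dim <- g$spec$latent_dim
  b <- control$batch_size

  hist <- list(g_loss = numeric(control$epochs),
               d_loss = numeric(control$epochs),
               d_accuracy = numeric(control$epochs))
  eval_latent <- NULL

  with_seed(control$seed, {
    eval_latent <- matrix(stats::rnorm(latent_dim * n_val), latent_dim,
                          n_val)
    opt_g <- adam_new(control$lr_g)
    opt_d <- adam_new(control$lr_d)
    iter <- 0L
    epoch <- 0L
    while (epoch < control$epochs) {
      epoch <- epoch + 1L
      if (identical(control$lr_decay, "linear")) {
        anneal <- 1 - (epoch - 1L) / control$epochs
        opt_g$lr <- control$lr_g * anneal
        opt_d$lr <- control$lr_d * anneal
      }
      ord <- sample.int(n_train)
      starts <- seq(1L, n_train, by = b)
      for (s0 in starts) {
        idx <- ord[s0:min(s0 + b - 1L, n_train)]
        bb <- length(idx)
        # --- discriminator step: two half-batches, real then generated
        # (the standard DCGAN recipe; with batch normalisation in D each
        # half-batch self-normalises during training) ---
        xr <- x_train[, , , , idx, drop = FALSE]
        sc <- net_forward(d, xr, training = TRUE)
        p <- stats::plogis(as.numeric(sc))
        gs <- matrix((p - 1) / bb, 1L)
        net_backward(d, gs, input_grad = FALSE)
        adam_step(opt_d, d)
        z <- matrix(stats::rnorm(latent_dim * bb), latent_dim, bb)
        fake <- net_forward(g, z, training = TRUE)
        sc <- net_forward(d, fake, training = TRUE)
        p <- stats::plogis(as.numeric(sc))
        gs <- matrix(p / bb, 1L)
        net_backward(d, gs, input_grad = FALSE)
        adam_step(opt_d, d)
        # --- generator step: non-saturating, labels 1.  The view of D
        # alternates between training mode (batch statistics) and
        # inference mode (running statistics): the inference view ties the
        # generator to the same discriminator that held-out monitoring
        # sees, the training view keeps it from over-fooling it ---
        iter <- iter + 1L
        z <- matrix(stats::rnorm(latent_dim * bb), latent_dim, bb)
        fake <- net_forward(g, z, training = TRUE)
        sc <- net_forward(d, fake, training = iter %% 2L == 0L)
        p <- stats::plogis(as.numeric(sc))
        gs <- matrix((p - 1) / bb, 1L)
        gx <- net_backward(d, gs)      # gradient w.r.t. generated volumes
        net_backward(g, gx, input_grad = FALSE)
        adam_step(opt_g, g)
      }
      ev <- eval_dcgan_epoch(g, d, x_val, eval_latent)
      if (!all(is.finite(c(ev$g_loss, ev$d_loss))))
        stop("non-finite GAN loss at epoch ", epoch,
             " (mode collapse / divergence)")
      hist$g_loss[epoch] <- ev$g_loss
      hist$d_loss[epoch] <- ev$d_loss
      hist$d_accuracy[epoch] <- ev$d_accuracy
    }
  })

  history <- data.frame(epoch = seq_len(control$epochs),
                        g_loss = hist$g_loss, d_loss = hist$d_loss,
                        d_accuracy = hist$d_accuracy)
  structure(list(generator = g, discriminator = d, history = history,
                 eval_latent = eval_latent, control = control),
            class = "dcgan_fit")
}

# evaluation-mode losses and discriminator accuracy on held-out volumes
eval_dcgan_epoch <- function(g, d, x_val, eval_latent) {
  fake <- net_forward(g, eval_latent, training = FALSE)
  s_r <- stats::plogis(as.numeric(net_forward(d, x_val, training = FALSE)))
  s_f <- stats::plogis(as.numeric(net_forward(d, fake, training = FALSE)))
  list(d_loss = bce_loss(c(s_r, s_f),
                         c(rep(1, length(s_r)), rep(0, length(s_f)))),
       g_loss = bce_loss(s_f, rep(1, length(s_f))),
       d_accuracy = mean(c(s_r > 0.5, s_f < 0.5)))
}

#' Re-evaluate a fitted DCGAN on held-out volumes
#'
#' Recomputes the last history row (losses and discriminator accuracy)
#' from the frozen networks and the stored evaluation latents; useful as a
#' reproducibility check.
#'
#' @param fit a `dcgan_fit`.
#' @param val_vols the held-out volumes used during fitting.
#' @return A one-row data frame with `g_loss`, `d_loss`, `d_accuracy`.
#' @export
evaluate_dcgan <- function(fit, val_vols) {
  ev <- eval_dcgan_epoch(fit$generator, fit$discriminator,
                         as_batch(val_vols), fit$eval_latent)
  data.frame(g_loss = ev$g_loss, d_loss = ev$d_loss,
             d_accuracy = ev$d_accuracy)
}

#' Discriminator real-vs-fake accuracy
#'
#' Fraction of correct decisions at probability threshold 0.5: a real
#' volume counts as correct when its probability exceeds 0.5, a fake when
#' it falls below; exact ties count as incorrect.
#'
#' @param d a discriminator `voxnet`.
#' @param real_vols,fake_vols non-empty lists of volumes (or 5-d arrays).
#' @return Fraction in \[0,1\].
#' @export
d_accuracy <- function(d, real_vols, fake_vols) {
  n_r <- if (is.list(real_vols)) length(real_vols) else
    dim(as_batch(real_vols))[5]
  n_f <- if (is.list(fake_vols)) length(fake_vols) else
    dim(as_batch(fake_vols))[5]
  if (n_r < 1L || n_f < 1L)
    stop("need at least one real and one fake volume")
  p_r <- predict(d, real_vols)
  p_f <- predict(d, fake_vols)
  mean(c(p_r > 0.5, p_f < 0.5))
}

#' Has the DCGAN reached (approximate) Nash equilibrium?
#'
#' TRUE iff the moving average of held-out discriminator accuracy over the
#' final `equilibrium_window` epochs lies within
#' `0.5 +/- equilibrium_tol` (closed interval).
#'
#' @param history a `dcgan_fit` or its `history` data frame.
#' @param control the [gan_control()] holding window and tolerance.
#' @return Logical.
#' @export
reached_equilibrium <- function(history, control = gan_control()) {
  if (inherits(history, "dcgan_fit")) history <- history$history
  w <- control$equilibrium_window
  if (nrow(history) < w)
    stop("history has ", nrow(history), " epochs but the equilibrium ",
         "window is ", w)
  m <- mean(utils::tail(history$d_accuracy, w))
  abs(m - 0.5) <= control$equilibrium_tol
}

#' @export
print.dcgan_fit <- function(x, ...) {
  cat("3D DCGAN fit:", nrow(x$history), "epochs, batch",
      x$control$batch_size, "\n")
  if (nrow(x$history) > 0) {
    last <- utils::tail(x$history, 1)
    w <- min(x$control$equilibrium_window, nrow(x$history))
    cat(sprintf("  final losses: G %.4f, D %.4f\n", last$g_loss,
                last$d_loss))
    cat(sprintf("  held-out D accuracy, last-%d-epoch mean: %.3f %s\n", w,
                mean(utils::tail(x$history$d_accuracy, w)),
                if (nrow(x$history) >= x$control$equilibrium_window &&
                    reached_equilibrium(x, x$control))
                  "(~ Nash equilibrium)" else ""))
  }
  invisible(x)
}

#' Sample synthetic volumes from a fitted DCGAN
#'
#' @param object a `dcgan_fit`.
#' @param nsim number of volumes.
#' @param seed optional seed for the latent draw.
#' @param ... unused.
#' @return A list of [volume_grid()]s.
#' @export
simulate.dcgan_fit <- function(object, nsim = 1, seed = NULL, ...) {
  draw <- function() generate_volumes(object$generator, nsim)
  x <- if (is.null(seed)) draw() else with_seed(seed, draw())
  lapply(seq_len(nsim), function(i)
    volume_grid(x[, , , 1L, i], spacing_mm = 3,
                subject_id = sprintf("synthetic%03d", i)))
}

#' Plot DCGAN training curves
#'
#' Two panels: generator/discriminator held-out losses, and discriminator
#' accuracy with the 0.5 equilibrium line.
#'
#' @param x a `dcgan_fit`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.dcgan_fit <- function(x, ...) {
  h <- x$history
  if (nrow(h) == 0) {
    warning("empty history; nothing to plot")
    return(invisible(x))
  }
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::matplot(h$epoch, cbind(h$g_loss, h$d_loss), type = "l",
                    lty = 1, col = c("firebrick", "steelblue"),
                    xlab = "epoch", ylab = "held-out loss", ...)
  graphics::legend("topright", c("G", "D"), lty = 1,
                   col = c("firebrick", "steelblue"), bty = "n")
  graphics::plot(h$epoch, h$d_accuracy, type = "l", ylim = c(0, 1),
                 xlab = "epoch", ylab = "D accuracy")
  graphics::abline(h = 0.5, lty = 2)
  invisible(x)
}
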