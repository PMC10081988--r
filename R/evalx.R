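# Confusion/ROC metrics and the three desk-scale ablation harnesses
# (freeze depth, training strategy, sample size).

#' Classification metrics from scores and labels
#'
#' Confusion counts at a probability threshold plus accuracy
#' `(TP+TN)/n`, sensitivity `TP/(TP+FN)`, precision `TP/(TP+FP)` and AUC.
#' AUC is the area under the empirical ROC curve by the trapezoidal rule,
#' which handles tied scores by the midpoint rule (a tie between a
#' positive and a negative counts one half), so it coincides with the
#' pairwise-concordance definition.  A ratio with a zero denominator is
#' reported as `NA`, not 0.
#'
#' @param scores per-case probabilities (or any monotone scores for AUC).
#' @param labels binary labels, 0/1 (or logical).
#' @param threshold decision threshold; a case is called positive when its
#'   score strictly exceeds it.
#' @return An object of class `metrics_report` with fields `TP`, `FP`,
#'   `TN`, `FN`, `accuracy`, `sensitivity`, `precision`, `auc`, `n`.
#' @export
compute_metrics <- function(scores, labels, threshold = 0.5) {
  if (is.logical(labels)) labels <- as.integer(labels)
  if (length(scores) != length(labels) || length(scores) < 1L)
    stop("scores and labels must have equal length >= 1")
  if (!all(labels %in% c(0, 1)))
    stop("labels must be binary (0/1)")
  pred <- scores > threshold
  pos <- labels == 1
  TP <- sum(pred & pos); FP <- sum(pred & !pos)
  FN <- sum(!pred & pos); TN <- sum(!pred & !pos)
  n <- length(labels)
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  structure(list(TP = TP, FP = FP, TN = TN, FN = FN,
                 accuracy = (TP + TN) / n,
                 sensitivity = ratio(TP, TP + FN),
                 precision = ratio(TP, TP + FP),
                 auc = roc_auc(scores, labels),
                 n = n),
            class = "metrics_report")
}

# trapezoidal area under the empirical ROC; NA when one class is absent
roc_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  if (length(pos) == 0L || length(neg) == 0L) return(NA_real_)
  th <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(th, function(t) mean(pos >= t), numeric(1))
  fpr <- vapply(th, function(t) mean(neg >= t), numeric(1))
  fpr <- c(0, fpr); tpr <- c(0, tpr)
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("n = %d   TP %d  FP %d  TN %d  FN %d\n", x$n, x$TP, x$FP,
              x$TN, x$FN))
  fmt <- function(v) if (is.na(v)) "NA" else sprintf("%.1f%%", 100 * v)
  cat("  accuracy", fmt(x$accuracy), "  sensitivity", fmt(x$sensitivity),
      "  precision", fmt(x$precision), "  AUC", fmt(x$auc), "\n")
  invisible(x)
}

#' @export
as.data.frame.metrics_report <- function(x, ...) {
  data.frame(TP = x$TP, FP = x$FP, TN = x$TN, FN = x$FN,
             accuracy = x$accuracy, sensitivity = x$sensitivity,
             precision = x$precision, auc = x$auc, n = x$n)
}

# ---- shared harness plumbing -----------------------------------------------

# stratified nested training subset: the fraction-f subset of each class is
# the first ceil(f * n_c) ids of a per-seed shuffled order, so smaller
# fractions are contained in larger ones
subset_train <- function(train_vols, fraction, seed) {
  if (fraction >= 1) return(train_vols)
  y <- vol_labels(train_vols)
  keep <- logical(length(train_vols))
  for (cl in c(0L, 1L)) {
    idx <- which(y == cl)
    m <- ceiling(fraction * length(idx))
    if (m < 2L)
      stop("fraction ", fraction, " leaves fewer than 2 cases of class ",
           cl, " in the training set")
    ord <- with_seed(derive_seed(seed, "subset", cl), sample(idx))
    keep[ord[seq_len(m)]] <- TRUE
  }
  train_vols[keep]
}

metrics_row <- function(fit, test_vols) {
  as.data.frame(compute_metrics(predict(fit, test_vols),
                                vol_labels(test_vols)))
}

#' Freeze-depth ablation
#'
#' For every freeze policy, converts the pre-trained discriminator to a
#' classifier, applies the policy, fine-tunes and evaluates on the test
#' partition -- with identical data splits across policies -- then averages
#' the metrics over seeds.
#'
#' @param d a (GAN-pre-trained) discriminator `voxnet`.
#' @param cohort a labeled `phantom_cohort` (or compatible list).
#' @param control a [fine_tune_control()]; its seed fixes the split.
#' @param policies freeze policies to compare (default all six).
#' @param seeds integer seeds for repeated runs.
#' @param ratios train/validation/test ratios.
#' @return A data frame, one row per policy, with seed-averaged accuracy,
#'   sensitivity, precision and AUC; per-seed accuracies are kept in
#'   `attr(, "per_seed")`.
#' @export
frozen_ablation <- function(d, cohort, control = fine_tune_control(),
                            policies = freeze_policies(),
                            seeds = c(1L, 2L, 3L), ratios = c(7, 1, 2)) {
  task <- split_cohort(cohort, ratios, derive_seed(control$seed, "split"))
  per_seed <- array(NA_real_, dim = c(length(policies), length(seeds)),
                    dimnames = list(policies, paste0("seed", seeds)))
  rows <- NULL
  for (pi in seq_along(policies)) {
    pol <- policies[pi]
    ms <- vector("list", length(seeds))
    for (si in seq_along(seeds)) {
      cls <- with_seed(derive_seed(control$seed, "head", seeds[si]),
                       to_classifier(d))
      apply_freeze(cls, pol)
      ctl <- control
      ctl$seed <- derive_seed(control$seed, "ft", seeds[si], pol)
      fit <- fine_tune(cls, task$train, task$validation, ctl)
      ms[[si]] <- metrics_row(fit, task$test)
      per_seed[pi, si] <- ms[[si]]$accuracy
    }
    m <- do.call(rbind, ms)
    rows <- rbind(rows, data.frame(policy = pol, accuracy = mean(m$accuracy),
                                   sensitivity = mean(m$sensitivity),
                                   precision = mean(m$precision),
                                   auc = mean(m$auc)))
  }
  attr(rows, "per_seed") <- per_seed
  rows
}

#' Training-strategy comparison
#'
#' Three arms sharing splits and seeds, reported in this fixed order:
#' `"vgg_scratch"` (VGG-like network trained from scratch),
#' `"dclassifier_scratch"` (the residual classifier architecture trained
#' from scratch), `"three_round"` (adversarial pre-training, conversion,
#' staged fine-tuning).  Mean test accuracy over seeds per arm.
#'
#' @inheritParams sample_size_sweep
#' @return Data frame with columns `model` and `accuracy`; per-seed values
#'   in `attr(, "per_seed")`.
#' @export
strategy_comparison <- function(cohort, spec = network_spec_desk(16L),
                                gan_control = voxgan::gan_control(epochs = 60L),
                                ft_control = fine_tune_control(),
                                seeds = c(1L, 2L, 3L), ratios = c(7, 1, 2),
                                pretrained_d = NULL) {
  sw <- sample_size_sweep(cohort, spec, gan_control, ft_control,
                          fractions = 1, seeds = seeds, ratios = ratios,
                          pretrained_d = pretrained_d)
  out <- sw[, c("model", "accuracy")]
  attr(out, "per_seed") <- attr(sw, "per_seed")[, 1L, ]
  out
}

strategy_arms <- function() c("vgg_scratch", "dclassifier_scratch",
                              "three_round")

#' Sample-size sensitivity sweep
#'
#' Re-runs the three training arms of [strategy_comparison()] while the
#' training partition is reduced to nested, stratified fractions of its
#' original size (validation and test partitions stay fixed), averaging
#' test accuracy over seeds.  The three-round arm pre-trains its GAN once
#' per seed on the full unlabeled train+validation pool.
#'
#' @param cohort a labeled `phantom_cohort`.
#' @param spec the [network_spec()] for all arms.
#' @param gan_control round-1 configuration for the three-round arm.
#' @param ft_control fine-tuning configuration shared by all arms.
#' @param fractions training-set fractions, largest first
#'   (default 1, 2/3, 1/2).
#' @param seeds integer seeds for repeated runs.
#' @param ratios train/validation/test ratios.
#' @param pretrained_d optional discriminator from an already-fitted DCGAN;
#'   when supplied, the three-round arm reuses it across seeds (round 1 is
#'   trained once in the reference procedure) instead of re-training a GAN
#'   per seed.
#' @return Data frame with columns `model`, `fraction`, `accuracy`
#'   (seed-averaged); the full model x fraction x seed accuracy array in
#'   `attr(, "per_seed")`.
#' @export
sample_size_sweep <- function(cohort, spec = network_spec_desk(16L),
                              gan_control = voxgan::gan_control(epochs = 60L),
                              ft_control = fine_tune_control(),
                              fractions = c(1, 2 / 3, 0.5),
                              seeds = c(1L, 2L, 3L), ratios = c(7, 1, 2),
                              pretrained_d = NULL) {
  arms <- strategy_arms()
  acc <- array(NA_real_,
               dim = c(length(arms), length(fractions), length(seeds)),
               dimnames = list(arms, paste0("f", round(100 * fractions)),
                               paste0("seed", seeds)))
  for (si in seq_along(seeds)) {
    s <- seeds[si]
    task <- split_cohort(cohort, ratios, derive_seed(ft_control$seed,
                                                     "split", s))
    # round-1 pre-training shared by every fraction of the three_round arm
    if (is.null(pretrained_d)) {
      gctl <- gan_control
      gctl$seed <- derive_seed(gan_control$seed, "gan", s)
      g <- with_seed(derive_seed(gctl$seed, "g_init"), build_generator(spec))
      d0 <- with_seed(derive_seed(gctl$seed, "d_init"),
                      build_discriminator(spec))
      unlabeled <- c(task$train, task$validation)
      n_gval <- max(1L, length(unlabeled) %/% 10L)
      gval <- unlabeled[seq_len(n_gval)]
      gtrain <- unlabeled[-seq_len(n_gval)]
      gan <- fit_dcgan(g, d0, gtrain, gval, gctl)
    } else {
      gan <- list(discriminator = pretrained_d)
    }
    for (fi in seq_along(fractions)) {
      f <- fractions[fi]
      ftag <- round(100 * f)
      tr <- subset_train(task$train, f,
                         derive_seed(ft_control$seed, "frac", s))
      for (arm in arms) {
        seed_key <- derive_seed(ft_control$seed, "arm", arm, ftag, s)
        net <- switch(arm,
          vgg_scratch = with_seed(seed_key, build_vgg_baseline(spec)),
          dclassifier_scratch = with_seed(seed_key, {
            dd <- build_discriminator(spec)
            to_classifier(dd)
          }),
          three_round = {
            cls <- with_seed(seed_key, to_classifier(gan$discriminator))
            apply_freeze(cls, "through_rb2")
            cls
          })
        ctl <- ft_control
        ctl$seed <- derive_seed(seed_key, "ft")
        fit <- fine_tune(net, tr, task$validation, ctl)
        acc[arm, fi, si] <- metrics_row(fit, task$test)$accuracy
      }
    }
  }
  out <- expand.grid(model = arms, fraction = fractions,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$accuracy <- mapply(function(m, f) {
    mean(acc[m, paste0("f", round(100 * f)), ])
  }, out$model, out$fraction)
  attr(out, "per_seed") <- acc
  out
}
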