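# 3D Grad-CAM relevance maps with probability-thresholded cohort averaging.

#' Saliency configuration
#'
#' @param target_block named block whose output supplies the activations
#'   (default `"rb3"`, the second standard residual block; `"rb1"` is the
#'   other defensible reading and is selectable here).
#' @param prob_threshold predicted-probability cutoff for inclusion in a
#'   cohort-average map (default 0.7), in (0,1).
#' @param upsample `"trilinear"` (default) or `"nearest"` interpolation to
#'   the input grid.
#' @return An object of class `saliency_config`.
#' @export
saliency_config <- function(target_block = "rb3", prob_threshold = 0.7,
                            upsample = c("trilinear", "nearest")) {
  stopifnot(prob_threshold > 0, prob_threshold < 1)
  structure(list(target_block = target_block,
                 prob_threshold = prob_threshold,
                 upsample = match.arg(upsample)),
            class = "saliency_config")
}

#' 3D Grad-CAM relevance map for one volume
#'
#' Channel weights are the spatial means of the gradient of the
#' target-class score with respect to each activation channel of the
#' target block; the map is the rectified weighted sum of channels,
#' upsampled to the input grid and normalised so its maximum is 1 (an
#' identically zero map stays zero).  Gradients are taken of the
#' pre-sigmoid score (class 1: `+score`; class 0: `-score`), the standard
#' Grad-CAM practice that avoids vanishing gradients at saturated
#' outputs.
#'
#' @param model a discriminator or classifier `voxnet` (evaluation mode).
#' @param vol a [volume_grid()] (or 3-d array) at the model's input size.
#' @param target_class 0 or 1; for a discriminator, 1 means "real".
#' @param cfg a [saliency_config()].
#' @return An object of class `heatmap`: `data` (non-negative 3-d array on
#'   the input grid, max 1 unless identically 0), `source_class`,
#'   `n_cases = 1`.
#' @export
grad_cam <- function(model, vol, target_class = 1L,
                     cfg = saliency_config()) {
  stopifnot(inherits(model, "voxnet"), model$kind != "generator",
            target_class %in% c(0L, 1L))
  bn <- cfg$target_block
  ti <- match(bn, names(model$blocks))
  if (is.na(ti))
    stop("model has no block named '", bn, "'")
  x <- as_batch(vol)
  tr <- net_forward_trace(model, x, training = FALSE)
  act <- tr$blocks[[ti]]
  if (length(dim(act)) != 5L)
    stop("block '", bn, "' does not produce a convolutional feature map")
  # backward from the score through the blocks above the target block
  g <- matrix(if (target_class == 1L) 1 else -1, 1L, 1L)
  for (i in rev(seq_along(model$blocks))) {
    if (i == ti) break
    g <- seq_bwd(model$blocks[[i]]$layers, g)
  }
  d <- dim(act)
  nchan <- d[4]
  amat <- matrix(act, ncol = nchan * d[5])
  gmat <- matrix(g, ncol = nchan * d[5])
  w <- colMeans(gmat)                      # one weight per channel
  cam <- amat %*% w
  dim(cam) <- d[1:3]
  cam <- pmax(cam, 0)
  dim(cam) <- d[1:3]
  full <- dim(x)[1:3]
  if (!all(dim(cam) == full))
    cam <- upsample_to(cam, full, cfg$upsample)
  if (max(cam) > 0) cam <- cam / max(cam)
  structure(list(data = cam, source_class = as.integer(target_class),
                 n_cases = 1L),
            class = "heatmap")
}

# resize a 3-d array to `target` dims by separable interpolation
upsample_to <- function(x, target, method = "trilinear") {
  for (ax in 1:3) {
    m <- dim(x)[ax]
    n <- target[ax]
    if (m != n) {
      # align voxel centers: output center i maps to input coordinate ci
      ci <- (seq_len(n) - 0.5) * m / n - 0.5
      Tm <- matrix(0, n, m)
      if (method == "nearest") {
        j <- pmin(pmax(round(ci) + 1, 1), m)
        Tm[cbind(seq_len(n), j)] <- 1
      } else {
        lo <- floor(ci)
        fr <- ci - lo
        j0 <- pmin(pmax(lo + 1, 1), m)
        j1 <- pmin(pmax(lo + 2, 1), m)
        for (i in seq_len(n)) {
          Tm[i, j0[i]] <- Tm[i, j0[i]] + (1 - fr[i])
          Tm[i, j1[i]] <- Tm[i, j1[i]] + fr[i]
        }
      }
      perm <- c(ax, setdiff(1:3, ax))
      xp <- aperm(x, perm)
      dp <- dim(xp)
      dim(xp) <- c(dp[1], prod(dp[2:3]))
      xp <- Tm %*% xp
      dim(xp) <- c(n, dp[2], dp[3])
      x <- aperm(xp, order(perm))
    }
  }
  x
}

#' @export
print.heatmap <- function(x, ...) {
  cat("Grad-CAM heatmap,", paste(dim(x$data), collapse = " x "),
      "voxels, class", x$source_class, "(", x$n_cases, "case(s) )\n")
  invisible(x)
}

#' Probability-thresholded average heatmap over a cohort
#'
#' Averages the per-case normalised Grad-CAM maps of the cases whose
#' predicted probability for the target class exceeds
#' `cfg$prob_threshold`.  Per-map normalisation before averaging prevents
#' single high-amplitude cases from dominating.
#'
#' @param model a discriminator or classifier `voxnet`.
#' @param vols list of [volume_grid()]s.
#' @param target_class 0 or 1.
#' @param cfg a [saliency_config()].
#' @return A `heatmap` with `n_cases` the number of qualifying cases.
#' @export
average_heatmap <- function(model, vols, target_class = 1L,
                            cfg = saliency_config()) {
  p <- predict(model, vols)
  p_target <- if (target_class == 1L) p else 1 - p
  keep <- which(p_target > cfg$prob_threshold)
  if (length(keep) == 0L)
    stop("no case has predicted probability above the threshold ",
         cfg$prob_threshold, " for class ", target_class)
  acc <- NULL
  for (i in keep) {
    h <- grad_cam(model, vols[[i]], target_class, cfg)
    acc <- if (is.null(acc)) h$data else acc + h$data
  }
  structure(list(data = acc / length(keep),
                 source_class = as.integer(target_class),
                 n_cases = length(keep)),
            class = "heatmap")
}

#' Export a heatmap as NIfTI (and optional mid-slice montage)
#'
#' @param h a `heatmap`.
#' @param reference a [volume_grid()] on the same grid; supplies the voxel
#'   spacing.
#' @param path output NIfTI path (`.nii` / `.nii.gz`).
#' @param montage_path optional PNG path for a three-panel montage of the
#'   mid-slices in the three anatomical planes (requires the `png`
#'   device).
#' @return `path`, invisibly.
#' @export
export_heatmap <- function(h, reference, path, montage_path = NULL) {
  stopifnot(inherits(h, "heatmap"), inherits(reference, "volume_grid"))
  if (!all(dim(h$data) == dim(reference$data)))
    stop("heatmap grid ", paste(dim(h$data), collapse = "x"),
         " does not match reference grid ",
         paste(dim(reference$data), collapse = "x"))
  write_volume(volume_grid(h$data, spacing_mm = reference$spacing_mm),
               path)
  if (!is.null(montage_path)) {
    d <- dim(h$data)
    mid <- (d + 1L) %/% 2L
    grDevices::png(montage_path, width = 900, height = 320)
    op <- graphics::par(mfrow = c(1, 3), mar = c(1, 1, 2, 1))
    panels <- list(sagittal = h$data[mid[1], , ],
                   coronal = h$data[, mid[2], ],
                   axial = h$data[, , mid[3]])
    for (nm in names(panels))
      graphics::image(panels[[nm]], axes = FALSE, main = nm,
                      col = grDevices::hcl.colors(64, "inferno"),
                      zlim = c(0, max(1e-12, max(h$data))))
    graphics::par(op)
    grDevices::dev.off()
  }
  invisible(path)
}
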