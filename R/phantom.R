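# Synthetic brain-phantom cohort generator.
#
# Each subject is a smooth, bounded-intensity "gray-matter density" volume:
# an ellipsoidal support mask times a constant base level plus smoothed
# subject-specific texture, with class-dependent intensity reduction
# ("atrophy") inside a set of spherical loci, additive noise, and clipping
# to [0,1].  The generator stands in for real GM density maps so that the
# whole training pipeline can be exercised without any imaging download.

#' Specification of a synthetic phantom cohort
#'
#' @param grid_size voxels per axis (power of two; default 32).
#' @param brain_axes ellipsoid semi-axes as fractions of the grid.
#' @param texture_smoothness Gaussian smoothing length (voxels) of the
#'   subject-specific texture field.
#' @param texture_sd standard deviation of the smoothed texture field.
#' @param atrophy_loci list of loci, each `list(center = <3 fractional
#'   coordinates>, radius = <voxels>)`.  Defaults to three spheres placed
#'   asymmetrically (a crude analogue of temporal/hippocampal asymmetry),
#'   giving saliency maps a ground-truth localisation target.
#' @param effect_size fractional intensity reduction inside the loci for
#'   the affected class (delta, in \[0,1\]); 0 makes the classes identical
#'   in law.
#' @param noise_sd standard deviation of additive voxel noise.
#' @param n_per_class subjects per class.
#' @param seed integer master seed; per-subject seeds are hashed from it.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_size = 32L,
                         brain_axes = c(0.42, 0.46, 0.42),
                         texture_smoothness = 2.0,
                         texture_sd = 0.1,
                         atrophy_loci = NULL,
                         effect_size = 0.5,
                         noise_sd = 0.05,
                         n_per_class = 50L,
                         seed = 1L) {
  grid_size <- as.integer(grid_size)
  if (is.null(atrophy_loci)) {
    r <- grid_size / 32
    atrophy_loci <- list(
      list(center = c(0.32, 0.40, 0.42), radius = 3.0 * r),
      list(center = c(0.66, 0.36, 0.40), radius = 2.5 * r),
      list(center = c(0.44, 0.62, 0.55), radius = 2.0 * r))
  }
  spec <- list(grid_size = grid_size, brain_axes = brain_axes,
               texture_smoothness = texture_smoothness,
               texture_sd = texture_sd,
               atrophy_loci = atrophy_loci,
               effect_size = effect_size, noise_sd = noise_sd,
               n_per_class = as.integer(n_per_class),
               seed = as.integer(seed))
  class(spec) <- "phantom_spec"
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  stopifnot(spec$grid_size >= 8L,
            length(spec$brain_axes) == 3L, all(spec$brain_axes > 0),
            spec$effect_size >= 0, spec$effect_size <= 1,
            spec$noise_sd >= 0, spec$texture_smoothness > 0,
            spec$n_per_class >= 1L)
  mask <- ellipsoid_mask(spec)
  for (i in seq_along(spec$atrophy_loci)) {
    loc <- locus_mask(spec$atrophy_loci[[i]], spec$grid_size)
    if (any(loc & !mask))
      stop("atrophy locus ", i, " (center ",
           paste(spec$atrophy_loci[[i]]$center, collapse = ", "),
           ", radius ", spec$atrophy_loci[[i]]$radius,
           " voxels) extends outside the brain ellipsoid")
  }
  invisible(spec)
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat("phantom cohort spec:", x$grid_size, "^3 voxels,",
      2L * x$n_per_class, "subjects (", x$n_per_class, "per class )\n")
  cat("  effect size delta =", x$effect_size, ", noise sd =", x$noise_sd,
      ",", length(x$atrophy_loci), "atrophy loci\n")
  invisible(x)
}

# 0-based voxel center coordinates scaled to [0,1)
ellipsoid_mask <- function(spec) {
  n <- spec$grid_size
  fr <- (seq_len(n) - 0.5) / n
  dx <- (fr - 0.5) / spec$brain_axes[1]
  dy <- (fr - 0.5) / spec$brain_axes[2]
  dz <- (fr - 0.5) / spec$brain_axes[3]
  o <- outer(outer(dx^2, dy^2, `+`), dz^2, `+`)
  o <= 1
}

locus_mask <- function(locus, n) {
  fr <- (seq_len(n) - 0.5) / n
  r2 <- (locus$radius / n)^2
  dx <- fr - locus$center[1]
  dy <- fr - locus$center[2]
  dz <- fr - locus$center[3]
  outer(outer(dx^2, dy^2, `+`), dz^2, `+`) <= r2
}

# union of all atrophy loci as a logical array
loci_mask <- function(spec) {
  m <- array(FALSE, dim = rep(spec$grid_size, 3))
  for (l in spec$atrophy_loci) m <- m | locus_mask(l, spec$grid_size)
  m
}

# separable Gaussian smoothing with an edge-renormalised truncated kernel
gaussian_smooth3d <- function(x, sigma) {
  n <- dim(x)
  r <- max(1L, ceiling(3 * sigma))
  for (ax in 1:3) {
    m <- n[ax]
    B <- matrix(0, m, m)
    for (i in seq_len(m)) {
      j <- max(1, i - r):min(m, i + r)
      w <- stats::dnorm(j - i, sd = sigma)
      B[i, j] <- w / sum(w)
    }
    perm <- c(ax, setdiff(1:3, ax))
    xp <- aperm(x, perm)
    dp <- dim(xp)
    dim(xp) <- c(dp[1], prod(dp[2:3]))
    xp <- B %*% xp
    dim(xp) <- dp
    x <- aperm(xp, order(perm))
  }
  x
}

#' A 3D scalar-field volume
#'
#' The unit of all image I/O in the package: a 3-axis array of finite
#' values with isotropic voxel spacing, an optional class label (0 =
#' control-like, 1 = affected-like) and a subject identifier.
#'
#' @param data 3-d numeric array.
#' @param spacing_mm isotropic voxel size in millimetres (> 0).
#' @param label optional class tag, 0 or 1.
#' @param subject_id identifier string.
#' @return An object of class `volume_grid`.
#' @export
volume_grid <- function(data, spacing_mm = 1, label = NA_integer_,
                        subject_id = "") {
  if (length(dim(data)) != 3L)
    stop("volume data must have exactly 3 axes, got ",
         length(dim(data)))
  if (!all(is.finite(data))) stop("volume contains non-finite values")
  if (!is.numeric(spacing_mm) || spacing_mm <= 0)
    stop("spacing_mm must be a positive number")
  structure(list(data = data, spacing_mm = spacing_mm,
                 label = as.integer(label), subject_id = subject_id),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat("volume_grid", paste(dim(x$data), collapse = " x "), "voxels @",
      x$spacing_mm, "mm")
  if (!is.na(x$label)) cat(", label", x$label)
  if (nzchar(x$subject_id)) cat(", subject", x$subject_id)
  cat("\n  intensity range [", format(min(x$data), digits = 4), ",",
      format(max(x$data), digits = 4), "]\n")
  invisible(x)
}

#' Generate one synthetic subject volume
#'
#' The volume is `mask * clip(base + texture, atrophied inside loci, plus
#' noise)`: an ellipsoid support mask times a constant base level of 0.6
#' plus Gaussian-smoothed subject texture; for the affected class
#' (`class_label = 1`) intensity inside each atrophy locus is multiplied by
#' `(1 - effect_size)`; additive noise is applied and the result clipped to
#' \[0,1\].  Texture and noise depend only on `subject_seed`, never on the
#' label, so with `effect_size = 0` the two classes are identical in law
#' (and identical realisation-by-realisation at fixed seed).
#'
#' @param spec a [phantom_spec()].
#' @param class_label 0 (control-like) or 1 (affected-like).
#' @param subject_seed integer seed for this subject's texture and noise.
#' @return A [volume_grid()] with `spacing_mm = 3`.
#' @export
generate_subject <- function(spec, class_label, subject_seed) {
  validate_phantom_spec(spec)
  stopifnot(class_label %in% c(0L, 1L))
  n <- spec$grid_size
  mask <- ellipsoid_mask(spec)
  with_seed(subject_seed, {
    tex <- array(stats::rnorm(n^3), dim = rep(n, 3))
    tex <- gaussian_smooth3d(tex, spec$texture_smoothness)
    tex <- tex / stats::sd(tex) * spec$texture_sd
    v <- 0.6 + tex
    if (class_label == 1L && spec$effect_size > 0) {
      lm <- loci_mask(spec)
      v[lm] <- v[lm] * (1 - spec$effect_size)
    }
    if (spec$noise_sd > 0)
      v <- v + array(stats::rnorm(n^3, sd = spec$noise_sd), dim = rep(n, 3))
    v <- clamp01(v)
    v[!mask] <- 0
    volume_grid(v, spacing_mm = 3,
                label = as.integer(class_label),
                subject_id = sprintf("S%04d", subject_seed %% 10000L))
  })
}

subject_seed_for <- function(spec, index) derive_seed(spec$seed, "subject", index)

#' Generate a labeled phantom cohort
#'
#' Produces `2 * n_per_class` volumes (class 0 first, then class 1) with
#' per-subject seeds hashed deterministically from `spec$seed`, so the same
#' spec always yields a bit-identical cohort regardless of generation
#' order.
#'
#' @param spec a [phantom_spec()].
#' @return An object of class `phantom_cohort`: a list with elements
#'   `volumes` (list of [volume_grid()]) and `labels` (data frame with
#'   `subject_id`, `label`).
#' @seealso [write_cohort()] to store it as NIfTI files plus a label
#'   manifest.
#' @export
generate_cohort <- function(spec) {
  validate_phantom_spec(spec)
  n <- spec$n_per_class
  vols <- vector("list", 2L * n)
  labels <- integer(2L * n)
  ids <- character(2L * n)
  for (i in seq_len(2L * n)) {
    lab <- if (i <= n) 0L else 1L
    v <- generate_subject(spec, lab, subject_seed_for(spec, i))
    v$subject_id <- sprintf("S%04d", i)
    vols[[i]] <- v
    labels[i] <- lab
    ids[i] <- v$subject_id
  }
  structure(list(volumes = vols,
                 labels = data.frame(subject_id = ids, label = labels,
                                     stringsAsFactors = FALSE),
                 spec = spec),
            class = "phantom_cohort")
}

#' @export
print.phantom_cohort <- function(x, ...) {
  cat("phantom cohort:", length(x$volumes), "volumes,",
      sum(x$labels$label == 0L), "control /", sum(x$labels$label == 1L),
      "affected,", x$spec$grid_size, "^3 voxels\n")
  invisible(x)
}

#' Write a cohort as NIfTI files plus a label manifest
#'
#' One `.nii.gz` per subject and a tab-separated `labels.tsv`
#' (`subject_id`, `label`).
#'
#' @param cohort a `phantom_cohort` (or any list of labeled
#'   [volume_grid()]s in the same structure).
#' @param dir output directory, created if needed.
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (v in cohort$volumes)
    write_volume(v, file.path(dir, paste0(v$subject_id, ".nii.gz")))
  manifest <- file.path(dir, "labels.tsv")
  utils::write.table(cohort$labels, manifest, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(manifest)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir directory containing `labels.tsv` and one NIfTI per subject.
#' @return A `phantom_cohort`-shaped list (without the generating spec).
#' @export
read_cohort <- function(dir) {
  manifest <- file.path(dir, "labels.tsv")
  if (!file.exists(manifest)) stop("no labels.tsv manifest in ", dir)
  labels <- utils::read.table(manifest, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
  vols <- lapply(seq_len(nrow(labels)), function(i) {
    v <- read_volume(file.path(dir, paste0(labels$subject_id[i], ".nii.gz")))
    v$label <- as.integer(labels$label[i])
    v$subject_id <- labels$subject_id[i]
    v
  })
  structure(list(volumes = vols, labels = labels, spec = NULL),
            class = "phantom_cohort")
}
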