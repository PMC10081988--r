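# Deterministic preprocessing chain and dataset split.
#
# Full-scale density maps arrive as 121 x 145 x 121 voxels at 1.5 mm; the
# network consumes cubes.  The chain is: center crop/pad to a target cube
# (128^3 at full scale), then block-mean downsampling by an integer factor
# (2 at full scale, giving 64^3 at 3.0 mm).

#' Center crop / zero-pad a volume to a cubic target
#'
#' Each axis is center-cropped when longer than `target` and symmetrically
#' zero-padded when shorter; interior values are untouched.  When the
#' difference is odd the extra voxel is cropped from / padded onto the
#' high-index side.
#'
#' @param vol a [volume_grid()].
#' @param target voxels per axis of the output cube (>= 1).
#' @return A [volume_grid()] with `target^3` voxels and unchanged spacing.
#' @export
crop_pad <- function(vol, target) {
  stopifnot(inherits(vol, "volume_grid"), target >= 1)
  target <- as.integer(target)
  d <- dim(vol$data)
  out <- array(0, dim = rep(target, 3))
  src <- dst <- vector("list", 3)
  for (ax in 1:3) {
    n <- d[ax]
    if (n >= target) {
      lo <- (n - target) %/% 2L
      src[[ax]] <- (lo + 1L):(lo + target)
      dst[[ax]] <- seq_len(target)
    } else {
      lo <- (target - n) %/% 2L
      src[[ax]] <- seq_len(n)
      dst[[ax]] <- (lo + 1L):(lo + n)
    }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <-
    vol$data[src[[1]], src[[2]], src[[3]]]
  volume_grid(out, spacing_mm = vol$spacing_mm, label = vol$label,
              subject_id = vol$subject_id)
}

#' Block-mean downsampling
#'
#' Each output voxel is the mean of its `factor^3` input block (an
#' anti-aliasing, fully deterministic reduction); the voxel spacing is
#' multiplied by `factor`.
#'
#' @param vol a [volume_grid()]; every axis must be divisible by `factor`.
#' @param factor integer reduction factor.
#' @return A [volume_grid()].
#' @export
downsample <- function(vol, factor) {
  stopifnot(inherits(vol, "volume_grid"))
  f <- as.integer(factor)
  d <- dim(vol$data)
  if (any(d %% f != 0L))
    stop("volume axes (", paste(d, collapse = ", "),
         ") are not divisible by the downsampling factor ", f)
  m <- d %/% f
  x <- vol$data
  dim(x) <- c(f, m[1], f, m[2], f, m[3])
  x <- aperm(x, c(1, 3, 5, 2, 4, 6))
  dim(x) <- c(f^3, prod(m))
  y <- colMeans(x)
  dim(y) <- m
  volume_grid(y, spacing_mm = vol$spacing_mm * f, label = vol$label,
              subject_id = vol$subject_id)
}

#' Standard preprocessing chain
#'
#' [crop_pad()] to `target` voxels per axis followed by [downsample()] by
#' `factor`; the full-scale defaults turn a 121 x 145 x 121 map at 1.5 mm
#' into a 64^3 cube at 3.0 mm.
#'
#' @param vol a [volume_grid()].
#' @param target crop/pad target (default 128).
#' @param factor downsampling factor (default 2).
#' @return A [volume_grid()].
#' @export
preprocess_volume <- function(vol, target = 128L, factor = 2L) {
  downsample(crop_pad(vol, target), factor)
}

#' Random train/validation/test split
#'
#' Subjects are shuffled by `seed` and assigned so that partition sizes are
#' the floors of the exact shares, with the remainder given to partitions
#' in the order train, validation, test.  When `labels` are supplied the
#' policy is applied within each class (stratified split).
#'
#' @param ids unique subject identifiers.
#' @param ratios three non-negative numbers (default `c(7, 1, 2)`).
#' @param seed integer seed.
#' @param labels optional class labels parallel to `ids`.
#' @return An object of class `split_assignment`: a data frame with
#'   columns `subject_id` and `partition` (factor: train / validation /
#'   test), with the ratios and seed as attributes.
#' @export
split_subjects <- function(ids, ratios = c(7, 1, 2), seed = 1L,
                           labels = NULL) {
  if (anyDuplicated(ids))
    stop("subject ids must be unique")
  if (length(ratios) != 3L || any(ratios < 0) || sum(ratios) <= 0)
    stop("ratios must be three non-negative numbers with a positive sum")
  parts <- c("train", "validation", "test")
  assign_one <- function(ids_g, seed_g) {
    n <- length(ids_g)
    share <- n * ratios / sum(ratios)
    sizes <- floor(share)
    rem <- n - sum(sizes)
    if (rem > 0)
      sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1
    ord <- with_seed(seed_g, sample.int(n))
    data.frame(subject_id = ids_g[ord],
               partition = rep(parts, times = sizes),
               stringsAsFactors = FALSE)
  }
  if (is.null(labels)) {
    out <- assign_one(ids, seed)
  } else {
    stopifnot(length(labels) == length(ids))
    grp <- split(seq_along(ids), labels)
    out <- do.call(rbind, lapply(seq_along(grp), function(k) {
      assign_one(ids[grp[[k]]], derive_seed(seed, "stratum", k))
    }))
    rownames(out) <- NULL
  }
  out$partition <- factor(out$partition, levels = parts)
  out <- out[match(ids[ids %in% out$subject_id], out$subject_id), ,
             drop = FALSE]
  rownames(out) <- NULL
  attr(out, "ratios") <- ratios
  attr(out, "seed") <- seed
  class(out) <- c("split_assignment", "data.frame")
  out
}

#' @export
print.split_assignment <- function(x, ...) {
  cat("split assignment (", paste(attr(x, "ratios"), collapse = ":"),
      ", seed ", attr(x, "seed"), "):\n", sep = "")
  print(table(x$partition))
  invisible(x)
}

# partition a cohort's volumes with split_subjects, returning
# list(train, validation, test) of volume lists
split_cohort <- function(cohort, ratios = c(7, 1, 2), seed = 1L) {
  asg <- split_subjects(cohort$labels$subject_id, ratios, seed,
                        labels = cohort$labels$label)
  out <- lapply(levels(asg$partition), function(p) {
    keep <- asg$subject_id[asg$partition == p]
    cohort$volumes[match(keep, cohort$labels$subject_id)]
  })
  names(out) <- levels(asg$partition)
  out$assignment <- asg
  out
}
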