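# NIfTI I/O, the crop/pad + block-mean downsampling chain, and the
# train/validation/test split.

test_that("NIfTI write/read round trip is lossless", {
  f <- withr::local_tempfile(fileext = ".nii.gz")
  v <- generate_subject(phantom_spec(grid_size = 16L), 1L, 4L)
  write_volume(v, f)
  back <- read_volume(f)
  expect_identical(max(abs(back$data - v$data)), 0)
  expect_equal(back$spacing_mm, v$spacing_mm)

  f2 <- withr::local_tempfile(fileext = ".nii")  # uncompressed too
  write_volume(volume_grid(v$data, spacing_mm = 1.5), f2)
  expect_equal(read_volume(f2)$spacing_mm, 1.5)
})

test_that("float32 storage round-trips within single precision", {
  f <- withr::local_tempfile(fileext = ".nii")
  v <- volume_grid(array(runif(4^3), rep(4, 3)))
  write_volume(v, f, dtype = "float32")
  expect_lt(max(abs(read_volume(f)$data - v$data)), 1e-7)
})

test_that("non-3D or malformed NIfTI input is a format error", {
  f <- withr::local_tempfile(fileext = ".nii")
  v <- volume_grid(array(runif(4^3), rep(4, 3)))
  write_volume(v, f)
  raw <- readBin(f, "raw", file.info(f)$size)
  raw[41:42] <- writeBin(2L, raw(), size = 2, endian = "little")  # dim[0]=2
  writeBin(raw, f)
  expect_error(read_volume(f), "3-d volume")
  g <- withr::local_tempfile(fileext = ".nii")
  writeBin(raw(100), g)
  expect_error(read_volume(g), "malformed")
  expect_error(read_volume(file.path(tempdir(), "nope.nii")), "no such file")
})

test_that("reader agrees with an independent NIfTI implementation", {
  # nibabel (Python) as the oracle in both directions
  py <- Sys.which("python")
  skip_if(py == "", "python not on PATH")
  dir <- withr::local_tempdir()
  f1 <- file.path(dir, "ours.nii.gz")
  v <- generate_subject(phantom_spec(grid_size = 16L), 0L, 2L)
  write_volume(v, f1)
  script <- file.path(dir, "check.py")
  writeLines(c(
    "import sys, numpy as np, nibabel as nib",
    sprintf("img = nib.load('%s')", f1),
    "d = np.asarray(img.dataobj)",
    "print(d.shape[0], float(np.abs(d).sum()), img.header['pixdim'][1])",
    sprintf("out = nib.Nifti1Image(np.arange(27.).reshape(3,3,3), np.diag([2.,2.,2.,1.]))"),
    "out.header.set_zooms((2.,2.,2.))",
    sprintf("nib.save(out, '%s')", file.path(dir, "theirs.nii.gz"))
  ), script)
  res <- system2(py, script, stdout = TRUE)
  parts <- strsplit(res[length(res)], " ")[[1]]
  expect_equal(as.integer(parts[1]), 16L)
  expect_equal(as.numeric(parts[2]), sum(abs(v$data)), tolerance = 1e-10)
  expect_equal(as.numeric(parts[3]), 3)
  theirs <- read_volume(file.path(dir, "theirs.nii.gz"))
  # numpy's reshape is C-ordered, so the R (Fortran) view is transposed
  expect_equal(theirs$data, aperm(array(as.numeric(0:26), c(3, 3, 3)), 3:1))
  expect_equal(theirs$spacing_mm, 2)
})

test_that("crop_pad centers, pads with zeros and crops to the target", {
  v <- volume_grid(array(1, c(3, 3, 3)))
  out <- crop_pad(v, 5L)
  expect_identical(dim(out$data), rep(5L, 3))
  expect_equal(sum(out$data), 27)            # padding adds only zeros
  expect_equal(out$data[2:4, 2:4, 2:4], v$data)

  same <- crop_pad(out, 5L)
  expect_identical(same$data, out$data)      # identity at target size

  big <- volume_grid(array(seq_len(7^3), c(7, 7, 7)))
  cr <- crop_pad(big, 3L)
  expect_equal(cr$data, big$data[3:5, 3:5, 3:5])
})

test_that("downsample takes exact block means and scales the spacing", {
  v <- volume_grid(array(as.numeric(0:7), c(2, 2, 2)), spacing_mm = 1.5)
  d <- downsample(v, 2L)
  expect_equal(as.numeric(d$data), 3.5)
  expect_equal(d$spacing_mm, 3)

  cv <- volume_grid(array(0.42, c(6, 6, 6)))
  expect_true(all(downsample(cv, 3L)$data == 0.42))
  expect_error(downsample(volume_grid(array(0, c(5, 5, 5))), 2L),
               "divisible")
})

test_that("the full-resolution chain lands on a 64-cube at twice the spacing", {
  v <- volume_grid(array(stats::runif(121 * 145 * 121),
                         c(121L, 145L, 121L)), spacing_mm = 1.5)
  cp <- crop_pad(v, 128L)
  expect_identical(dim(cp$data), rep(128L, 3))
  out <- downsample(cp, 2L)
  expect_identical(dim(out$data), rep(64L, 3))
  expect_equal(out$spacing_mm, 3)
  expect_identical(preprocess_volume(v)$data, out$data)
})

test_that("split sizes follow floor-plus-remainder in train/val/test order", {
  s10 <- split_subjects(paste0("s", 1:10), c(7, 1, 2), seed = 1L)
  expect_equal(as.vector(table(s10$partition)), c(7L, 1L, 2L))
  s798 <- split_subjects(paste0("s", 1:798), c(7, 1, 2), seed = 1L)
  expect_equal(as.vector(table(s798$partition)), c(559L, 80L, 159L))
})

test_that("splits are deterministic, disjoint and exhaustive", {
  ids <- paste0("s", 1:37)
  a <- split_subjects(ids, seed = 5L)
  b <- split_subjects(ids, seed = 5L)
  expect_identical(a$partition, b$partition)
  for (seed in c(1L, 99L)) {
    s <- split_subjects(ids, seed = seed)
    expect_setequal(s$subject_id, ids)
    expect_equal(nrow(s), length(ids))   # each id exactly once
  }
  expect_error(split_subjects(c("a", "a", "b")), "unique")
  expect_error(split_subjects(ids, ratios = c(0, 0, 0)), "positive sum")
})

test_that("labels stratify the split", {
  ids <- paste0("s", 1:40)
  labs <- rep(c(0L, 1L), each = 20L)
  s <- split_subjects(ids, c(2, 1, 1), seed = 3L, labels = labs)
  tab <- table(s$partition, labs[match(s$subject_id, ids)])
  expect_equal(as.vector(tab[, "0"]), as.vector(tab[, "1"]))
})
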