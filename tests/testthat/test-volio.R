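test_that("NIfTI round trip is lossless for volumes and label maps", {
  ph <- generate_phantom(small_phantom_spec(seed = 4))
  f <- tempfile(fileext = ".nii.gz")
  write_volume(ph$volume, f)
  back <- read_volume(f)
  expect_identical(dim(back$intensities), dim(ph$volume$intensities))
  expect_equal(back$intensities, ph$volume$intensities, tolerance = 0)
  expect_lt(max(abs(back$spacing - ph$volume$spacing)), 1e-6)
  fl <- tempfile(fileext = ".nii.gz")
  write_volume(ph$labels, fl)
  labs <- read_labelmap(fl)
  expect_identical(labs$labels, ph$labels$labels)
})

test_that("DICOM round trip is exact up to integer quantization", {
  ph <- generate_phantom(small_phantom_spec(seed = 6))
  dir <- tempfile()
  files <- write_focused_dicom(ph$volume, series_meta(), dir)
  expect_length(files, dim(ph$volume$intensities)[3])
  back <- read_dicom_series(dir)
  expect_lte(max(abs(back$intensities - ph$volume$intensities)), 0.5)
  expect_lt(max(abs(back$spacing - ph$volume$spacing)), 1e-6)
})

test_that("masked -1000 voxels survive the DICOM round trip exactly", {
  ph <- generate_phantom(small_phantom_spec(seed = 8))
  focused <- apply_focus_mask(ph$volume, ph$labels)
  dir <- tempfile()
  write_focused_dicom(focused, series_meta(), dir)
  back <- read_dicom_series(dir)
  bg <- ph$labels$labels == 0L
  expect_true(all(back$intensities[bg] == -1000))
})

test_that("degenerate volumes are handled: zero slices error, one slice ok", {
  v0 <- cta_volume(array(0, c(4, 4, 1)))
  v0$intensities <- v0$intensities[, , 0, drop = FALSE]  # force 0 slices
  expect_error(write_focused_dicom(v0, series_meta(), tempfile()),
               "zero slices")
  v1 <- cta_volume(array(c(-1000, 0, 500, 80), c(2, 2, 1)),
                   spacing = c(0.7, 0.7, 5))
  dir <- tempfile()
  files <- write_focused_dicom(v1, series_meta(), dir)
  expect_length(files, 1L)
  back <- read_dicom_series(dir)
  expect_lte(max(abs(back$intensities - v1$intensities)), 0.5)
})

test_that("interleaved series and non-uniform spacing are rejected", {
  a <- cta_volume(array(0, c(4, 4, 2)))
  b <- cta_volume(array(100, c(4, 4, 2)))
  dir <- tempfile()
  write_focused_dicom(a, series_meta(), dir)
  f2 <- write_focused_dicom(b, series_meta(), tempfile())
  file.copy(f2, file.path(dir, paste0("other_", basename(f2))))
  expect_error(read_dicom_series(dir), "interleaved")

  # missing slice -> non-uniform spacing
  c3 <- cta_volume(array(0, c(4, 4, 4)))
  dir3 <- tempfile()
  files <- write_focused_dicom(c3, series_meta(), dir3)
  file.remove(files[2])
  expect_error(read_dicom_series(dir3), "spacing")
})

test_that("a new series UID is generated, distinct from the template", {
  v <- cta_volume(array(0, c(4, 4, 2)))
  dir <- tempfile()
  write_focused_dicom(v, series_meta(series_uid = "1.2.3.4"), dir)
  back <- focusedcta:::read_dicom_elements(list.files(dir, full.names = TRUE)[1])
  uid <- focusedcta:::dcm_str(back[["0020000E"]])
  expect_false(identical(uid, "1.2.3.4"))
})

test_that("pydicom independently reads our DICOM output with matching HU", {
  skip_if(Sys.which("python") == "", "python not on PATH")
  ph <- generate_phantom(phantom_spec(grid_shape = c(24, 24, 16), seed = 2))
  dir <- tempfile()
  write_focused_dicom(ph$volume, series_meta(), dir)
  script <- tempfile(fileext = ".py")
  writeLines(c(
    "import sys, glob",
    "import numpy as np",
    "import pydicom",
    "files = sorted(glob.glob(sys.argv[1] + '/*.dcm'))",
    "vols = []",
    "for f in files:",
    "    d = pydicom.dcmread(f)",
    "    hu = d.pixel_array.astype('float64') * float(d.RescaleSlope) + float(d.RescaleIntercept)",
    "    vols.append(hu)",
    "v = np.stack(vols)",
    "print(v.shape, v.min(), v.max(), float(np.abs(v).sum()))"), script)
  out <- system2("python", c(script, dir), stdout = TRUE, stderr = TRUE)
  status <- attr(out, "status")
  expect_true(is.null(status) || status == 0,
              info = paste(out, collapse = "\n"))
  # pydicom array is (z, rows=y, cols=x); compare the summary numbers
  v <- ph$volume$intensities
  got <- as.numeric(strsplit(sub(".*\\) ", "", out[length(out)]), " ")[[1]])
  expect_equal(got[1], round(min(v)), tolerance = 0.51)
  expect_equal(got[2], round(max(v)), tolerance = 0.51)
  expect_equal(got[3], sum(abs(round(v))), tolerance = 1e-6 * got[3])
})
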