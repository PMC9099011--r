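test_that("DICOM series round-trip preserves dims, spacing and intensities", {
  set.seed(41)
  vol <- VoxelVolume(array(sample(0:2000, 7 * 9 * 4, TRUE), c(7, 9, 4)),
                     spacing = c(0.9, 1.1, 2.5))
  d <- withr::local_tempdir()
  writeDicomSeries(vol, d)
  back <- readDicomSeries(d)
  expect_identical(dim(back), dim(vol))
  expect_equal(spacing(back), spacing(vol))
  expect_equal(intensities(back), intensities(vol))
})

test_that("slice order is recovered from image positions, not file names", {
  set.seed(42)
  vol <- VoxelVolume(array(sample(0:500, 6 * 6 * 5, TRUE), c(6, 6, 5)))
  d <- withr::local_tempdir()
  writeDicomSeries(vol, d)
  files <- list.files(d, full.names = TRUE)
  # scramble the lexicographic file order
  for (i in seq_along(files))
    file.rename(files[i], file.path(d, sprintf("z_%s.dcm",
                                               letters[length(files) - i + 1])))
  back <- readDicomSeries(d)
  expect_equal(intensities(back), intensities(vol))
})

test_that("degenerate and inconsistent series are handled", {
  vol1 <- VoxelVolume(array(1:36, c(6, 6, 1)))
  d <- withr::local_tempdir()
  writeDicomSeries(vol1, d)
  back <- readDicomSeries(d)
  expect_identical(dim(back), c(6L, 6L, 1L))

  # mix in a slice with different row count
  d2 <- withr::local_tempdir()
  writeDicomSeries(VoxelVolume(array(0, c(8, 6, 1))), d2)
  file.copy(list.files(d2, full.names = TRUE),
            file.path(d, "other.dcm"))
  expect_error(readDicomSeries(d), "inconsistent slice dimensions")

  expect_error(readDicomSeries(withr::local_tempdir()), "empty directory")
})

test_that("pydicom reads our series and we read pydicom's (cross-oracle)", {
  d <- withr::local_tempdir()
  set.seed(7)
  vol <- VoxelVolume(array(sample(0:999, 5 * 4 * 3, TRUE), c(5, 4, 3)),
                     spacing = c(0.7, 0.8, 2))
  writeDicomSeries(vol, d)
  # direction 1: pydicom reads our files
  rd <- file.path(d, "ours.csv")
  script1 <- file.path(d, "read_ours.py")
  writeLines(c(
    "import pydicom, glob, sys, numpy as np",
    sprintf("fs = glob.glob('%s/*.dcm')", d),
    "ds = sorted((pydicom.dcmread(f) for f in fs),",
    "            key=lambda x: float(x.ImagePositionPatient[2]))",
    "arr = np.stack([x.pixel_array for x in ds])",
    sprintf("np.savetxt('%s', arr.reshape(len(ds), -1), fmt='%%d', delimiter=',')", rd)
  ), script1)
  out <- system2("python", script1, stdout = TRUE, stderr = TRUE)
  expect_true(file.exists(rd), info = paste(out, collapse = "\n"))
  truth <- as.matrix(utils::read.csv(rd, header = FALSE))
  for (s in 1:3) {
    m <- matrix(truth[s, ], nrow = 5, byrow = TRUE)
    expect_equal(unname(m), intensities(vol)[, , s])
  }

  # direction 2: pydicom writes a series our reader must decode
  d2 <- file.path(d, "pyseries")
  dir.create(d2)
  td <- file.path(d, "truth.csv")
  script2 <- file.path(d, "write_py.py")
  writeLines(c(
    "import os, numpy as np, pydicom",
    "from pydicom.dataset import Dataset, FileDataset, FileMetaDataset",
    "from pydicom.uid import ExplicitVRLittleEndian, generate_uid, MRImageStorage",
    "rng = np.random.default_rng(1)",
    "arr = rng.integers(0, 1200, size=(3, 6, 4)).astype(np.uint16)",
    "for i in range(3):",
    "    meta = FileMetaDataset()",
    "    meta.MediaStorageSOPClassUID = MRImageStorage",
    "    meta.MediaStorageSOPInstanceUID = generate_uid()",
    "    meta.TransferSyntaxUID = ExplicitVRLittleEndian",
    "    ds = FileDataset(None, {}, file_meta=meta, preamble=b'\\x00'*128)",
    "    ds.SOPClassUID = MRImageStorage",
    "    ds.SOPInstanceUID = meta.MediaStorageSOPInstanceUID",
    "    ds.Rows, ds.Columns = 6, 4",
    "    ds.BitsAllocated = 16; ds.BitsStored = 16; ds.HighBit = 15",
    "    ds.PixelRepresentation = 0; ds.SamplesPerPixel = 1",
    "    ds.PhotometricInterpretation = 'MONOCHROME2'",
    "    ds.PixelSpacing = [0.5, 0.6]",
    "    ds.ImagePositionPatient = [0, 0, 3.0 * i]",
    "    ds.ImageOrientationPatient = [1, 0, 0, 0, 1, 0]",
    "    ds.InstanceNumber = i + 1",
    "    ds.PixelData = arr[i].tobytes()",
    sprintf("    ds.save_as(os.path.join('%s', 'py_%%d.dcm' %% i), enforce_file_format=True)", d2),
    sprintf("np.savetxt('%s', arr.reshape(3, -1), fmt='%%d', delimiter=',')", td)
  ), script2)
  out <- system2("python", script2, stdout = TRUE, stderr = TRUE)
  expect_true(file.exists(td), info = paste(out, collapse = "\n"))
  truth <- as.matrix(utils::read.csv(td, header = FALSE))
  back <- readDicomSeries(d2)
  expect_identical(dim(back), c(6L, 4L, 3L))
  expect_equal(spacing(back), c(0.5, 0.6, 3))
  for (s in 1:3)
    expect_equal(intensities(back)[, , s],
                 unname(matrix(truth[s, ], nrow = 6, byrow = TRUE)))
})

test_that("NIfTI round-trip preserves the volume and DICOM agrees with it", {
  set.seed(9)
  vol <- VoxelVolume(array(sample(0:3000, 10 * 12 * 6, TRUE), c(10, 12, 6)),
                     spacing = c(1.2, 1.2, 3))
  f <- withr::local_tempfile(fileext = ".nii.gz")
  writeNiftiVolume(vol, f)
  back <- readNiftiVolume(f)
  expect_identical(dim(back), dim(vol))
  expect_equal(spacing(back), spacing(vol), tolerance = 1e-6)
  expect_equal(intensities(back), intensities(vol))

  d <- withr::local_tempdir()
  writeDicomSeries(vol, d)
  viaDicom <- readDicomSeries(d)
  expect_equal(intensities(viaDicom), intensities(back))
  expect_equal(spacing(viaDicom), spacing(back), tolerance = 1e-6)
})

test_that("label maps survive the NIfTI round trip", {
  lm <- tinyWorld()
  f <- withr::local_tempfile(fileext = ".nii.gz")
  writeNiftiLabels(lm, f)
  expect_identical(labels3d(readNiftiLabels(f)), labels3d(lm))
})

test_that("trajectory JSON round-trips losslessly and rejects empty paths", {
  tr <- new("TrajectoryResult",
            path = matrix(c(1L, 2L, 3L, 2L, 3L, 4L, 3L, 4L, 5L), 3, 3,
                          byrow = TRUE),
            totalReturn = 12.625, cause = "terminal", start = c(1L, 2L, 3L))
  f <- withr::local_tempfile(fileext = ".json")
  writeTrajectory(tr, f, tinyWorld())
  back <- readTrajectory(f)
  expect_identical(back$coords, tr@path)
  expect_identical(back$total_return, 12.625)
  expect_identical(back$type, "qlearning")
  expect_length(back$labels, 3L)

  expect_error(new("TrajectoryResult", path = matrix(integer(0), 0, 3),
                   totalReturn = 0, cause = "terminal",
                   start = c(1L, 1L, 1L)), "empty path")

  lp <- new("LinearPath", face = "z_min", u = 1L, v = 1L, n = 1L,
            entry = c(1L, 1L, 1L), goalPoint = c(1L, 1L, 3L),
            centerLine = matrix(c(1L, 1L, 1L, 1L, 1L, 2L, 1L, 1L, 3L), 3, 3,
                                byrow = TRUE),
            corridor = matrix(c(1L, 1L, 1L, 1L, 1L, 2L, 1L, 1L, 3L), 3, 3,
                              byrow = TRUE),
            penalty = 0, lengthVoxels = 3L)
  f2 <- withr::local_tempfile(fileext = ".json")
  writeTrajectory(lp, f2)
  expect_true(readTrajectory(f2)$penalty == 0)
})

test_that("burnOverlay changes exactly the requested voxels", {
  set.seed(5)
  vol <- VoxelVolume(array(sample(0:100, 64^2 * 4, TRUE), c(64, 64, 4)))
  vox <- cbind(sample(64, 10), sample(64, 10), sample(4, 10, TRUE))
  f <- withr::local_tempfile(fileext = ".nii.gz")
  burnOverlay(vol, vox, f, "nifti")
  back <- readNiftiVolume(f)
  diff <- which(abs(intensities(back) - intensities(vol)) > 1e-6, arr.ind = TRUE)
  expect_identical(nrow(diff), nrow(unique(vox)))

  f2 <- withr::local_tempfile(fileext = ".nii.gz")
  burnOverlay(vol, matrix(integer(0), 0, 3), f2, "nifti")
  expect_equal(intensities(readNiftiVolume(f2)), intensities(vol))

  expect_error(burnOverlay(vol, matrix(c(65L, 1L, 1L), 1, 3), f2), "out of bounds")
})
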