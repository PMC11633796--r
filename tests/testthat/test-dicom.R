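test_that("write/read round-trips pixels, spacing and photometric exactly", {
  set.seed(7)
  px <- matrix(sample(0:65535, 120 * 90, replace = TRUE), 120, 90)
  img <- phantom_image(px, 0.05, source = "synthetic")
  path <- withr::local_tempfile(fileext = ".dcm")
  write_synthetic_dicom(img, path)
  back <- read_phantom_image(path)
  expect_identical(back$pixels, px)
  expect_equal(back$pixel_spacing_mm, c(0.05, 0.05))
  expect_equal(back$photometric, "MONOCHROME2")
  expect_equal(back$source, "dicom")
})

test_that("MONOCHROME1 and MONOCHROME2 encodings normalize to the same image", {
  set.seed(8)
  px <- matrix(sample(0:65535, 60 * 40, replace = TRUE), 60, 40)
  f2 <- withr::local_tempfile(fileext = ".dcm")
  f1 <- withr::local_tempfile(fileext = ".dcm")
  write_synthetic_dicom(phantom_image(px, 0.07), f2)
  write_synthetic_dicom(phantom_image(65535 - px, 0.07,
                                      photometric = "MONOCHROME1"), f1)
  a <- read_phantom_image(f2)
  b <- read_phantom_image(f1)
  expect_identical(a$pixels, b$pixels)
})

test_that("stored PixelSpacing strings and chest-wall tags follow the contract", {
  px <- matrix(100, 20, 30)
  f <- withr::local_tempfile(fileext = ".dcm")
  write_synthetic_dicom(phantom_image(px, 0.05), f)
  buf <- readBin(f, "raw", file.size(f))
  expect_true(grepl("0.05\\0.05", rawToChar(buf[buf != as.raw(0)]),
                    fixed = TRUE, useBytes = TRUE))
  back <- read_phantom_image(f)
  expect_equal(back$pixel_spacing_mm, c(0.05, 0.05))
  expect_equal(back$chest_wall_edge, "left")   # laterality R -> left edge

  fr <- withr::local_tempfile(fileext = ".dcm")
  write_synthetic_dicom(phantom_image(px, 0.05, chest_wall_edge = "right"), fr)
  expect_equal(read_phantom_image(fr)$chest_wall_edge, "right")
  expect_equal(read_phantom_image(fr, chest_wall = "left")$chest_wall_edge,
               "left")
})

test_that("out-of-range intensities and missing spacing are hard errors", {
  expect_error(
    write_synthetic_dicom(phantom_image(matrix(70000, 5, 5), 0.05),
                          tempfile(fileext = ".dcm")),
    "65535")

  # craft a file whose dataset lacks any pixel-spacing tag
  f <- withr::local_tempfile(fileext = ".dcm")
  con <- file(f, "wb")
  writeBin(raw(128), con)
  writeBin(charToRaw("DICM"), con)
  meta_body <- c(
    mammoqc:::dicom_str_el(0x0002, 0x0002, "UI", mammoqc:::UID_SC_STORAGE),
    mammoqc:::dicom_str_el(0x0002, 0x0010, "UI", mammoqc:::TS_EXPLICIT_LE)
  )
  writeBin(c(
    mammoqc:::element_raw(0x0002, 0x0000, "UL",
                          mammoqc:::uint32_raw(length(meta_body))),
    meta_body,
    mammoqc:::dicom_us_el(0x0028, 0x0010, 4),
    mammoqc:::dicom_us_el(0x0028, 0x0011, 4),
    mammoqc:::element_raw(0x7FE0, 0x0010, "OW",
                          mammoqc:::uint16_raw(rep(1, 16)))
  ), con)
  close(con)
  expect_error(read_phantom_image(f), "PixelSpacing")
})

test_that("files interoperate with an independent DICOM implementation", {
  set.seed(9)
  px <- matrix(sample(0:4095, 50 * 40, replace = TRUE), 50, 40)
  f <- file.path(tempdir(), "interop_out.dcm")
  write_synthetic_dicom(phantom_image(px, 0.05), f)

  py <- file.path(tempdir(), "interop.py")
  out <- file.path(tempdir(), "interop_py.dcm")
  writeLines(c(
    "import sys, numpy as np, pydicom",
    "from pydicom.dataset import Dataset, FileMetaDataset, FileDataset",
    "from pydicom.uid import ImplicitVRLittleEndian",
    sprintf("ds = pydicom.dcmread(r'%s')", f),
    "arr = ds.pixel_array.astype('int64')",
    "print('READSUM', int(arr.sum()), ds.PixelSpacing[0])",
    "d = Dataset()",
    "d.SOPClassUID = '1.2.840.10008.5.1.4.1.1.7'",
    "d.SOPInstanceUID = pydicom.uid.generate_uid()",
    "d.Rows, d.Columns = 30, 20",
    "d.SamplesPerPixel = 1; d.PhotometricInterpretation = 'MONOCHROME2'",
    "d.BitsAllocated = 16; d.BitsStored = 16; d.HighBit = 15",
    "d.PixelRepresentation = 0; d.PixelSpacing = ['0.07', '0.07']",
    "d.ImageLaterality = 'L'",
    "a = np.arange(600, dtype=np.uint16).reshape(30, 20)",
    "d.PixelData = a.tobytes()",
    "meta = FileMetaDataset()",
    "meta.MediaStorageSOPClassUID = d.SOPClassUID",
    "meta.MediaStorageSOPInstanceUID = d.SOPInstanceUID",
    "meta.TransferSyntaxUID = ImplicitVRLittleEndian",
    sprintf("fds = FileDataset(r'%s', d, file_meta=meta, preamble=b'\\x00'*128)", out),
    sprintf("fds.save_as(r'%s')", out)
  ), py)
  res <- system2("python", py, stdout = TRUE)
  read_line <- grep("^READSUM", res, value = TRUE)
  expect_equal(as.numeric(strsplit(read_line, " ")[[1]][2]), sum(px))

  back <- read_phantom_image(out)   # implicit VR, written by pydicom
  expect_equal(sum(back$pixels), sum(0:599))
  expect_equal(back$pixel_spacing_mm, c(0.07, 0.07))
  expect_equal(back$chest_wall_edge, "right")
})
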