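# Minimal DICOM codec for single-frame grayscale images.
#
# Scope: reading Explicit and Implicit VR Little Endian datasets with
# uncompressed 8/16-bit grayscale pixel data, and writing Explicit VR
# Little Endian secondary-capture-style files. Compressed transfer
# syntaxes, multi-frame objects and pixel data inside sequences are
# rejected with a clear error. This is deliberately small: the pipeline
# needs pixels, PixelSpacing, PhotometricInterpretation and a couple of
# orientation tags, nothing more.

TS_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
TS_IMPLICIT_LE <- "1.2.840.10008.1.2"
UID_SC_STORAGE <- "1.2.840.10008.5.1.4.1.1.7"
UID_ROOT <- "1.2.826.0.1.3680043.10.1462."

.uid_counter <- local({ i <- 0L; function() { i <<- i + 1L; i } })

new_uid <- function() {
  paste0(UID_ROOT,
         format(as.integer(Sys.time()) %% 1000000000L, scientific = FALSE),
         ".", Sys.getpid() %% 10000L, ".", .uid_counter())
}

uint16_raw <- function(v) {
  v <- as.integer(round(v))
  writeBin(ifelse(v > 32767L, v - 65536L, v), raw(), size = 2,
           endian = "little")
}

uint32_raw <- function(v) {
  writeBin(as.integer(v), raw(), size = 4, endian = "little")
}

str_value_raw <- function(s, pad = as.raw(0x20)) {
  b <- charToRaw(s)
  if (length(b) %% 2 == 1) b <- c(b, pad)
  b
}

# One data element, Explicit VR Little Endian.
element_raw <- function(group, element, vr, value_raw) {
  long_vr <- vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")
  c(uint16_raw(group), uint16_raw(element), charToRaw(vr),
    if (long_vr) c(as.raw(c(0, 0)), uint32_raw(length(value_raw)))
    else uint16_raw(length(value_raw)),
    value_raw)
}

dicom_str_el <- function(group, element, vr, s) {
  element_raw(group, element, vr,
              str_value_raw(s, if (vr == "UI") as.raw(0) else as.raw(0x20)))
}

dicom_us_el <- function(group, element, v) {
  element_raw(group, element, "US", uint16_raw(v))
}

#' Write a phantom image as a DICOM file
#'
#' Emits a standards-conformant secondary-capture-style single-frame
#' grayscale DICOM (Explicit VR Little Endian, 16 bits stored) carrying
#' `PixelSpacing`, `ImagerPixelSpacing`, `PhotometricInterpretation` and an
#' `ImageLaterality` tag encoding the chest-wall side (`left` edge ->
#' laterality `"R"`, `right` -> `"L"`).
#'
#' @param image a `phantom_image` (see [read_phantom_image()]); pixels must
#'   be non-negative and fit the 16-bit unsigned range.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_synthetic_dicom <- function(image, path) {
  px <- image$pixels
  stopifnot(is.matrix(px))
  if (any(px < 0) || any(px > 65535))
    stop("pixel intensities must lie in [0, 65535] for 16-bit storage")
  spacing <- rep_len(image$pixel_spacing_mm, 2)
  photometric <- image$photometric %||% "MONOCHROME2"
  laterality <- if (identical(image$chest_wall_edge, "right")) "L" else "R"
  sop_uid <- new_uid()

  spacing_str <- paste(format(spacing, trim = TRUE, scientific = FALSE),
                       collapse = "\\")
  meta_body <- c(
    element_raw(0x0002, 0x0001, "OB", as.raw(c(0x00, 0x01))),
    dicom_str_el(0x0002, 0x0002, "UI", UID_SC_STORAGE),
    dicom_str_el(0x0002, 0x0003, "UI", sop_uid),
    dicom_str_el(0x0002, 0x0010, "UI", TS_EXPLICIT_LE),
    dicom_str_el(0x0002, 0x0012, "UI", paste0(UID_ROOT, "1"))
  )
  meta <- c(element_raw(0x0002, 0x0000, "UL", uint32_raw(length(meta_body))),
            meta_body)

  pixel_raw <- uint16_raw(as.vector(t(px)))  # row-major, per DICOM
  dataset <- c(
    dicom_str_el(0x0008, 0x0016, "UI", UID_SC_STORAGE),
    dicom_str_el(0x0008, 0x0018, "UI", sop_uid),
    dicom_str_el(0x0008, 0x0020, "DA", "20260101"),
    dicom_str_el(0x0008, 0x0060, "CS", "MG"),
    dicom_str_el(0x0008, 0x0064, "CS", "SYN"),
    dicom_str_el(0x0008, 0x0070, "LO", "mammoqc synthetic"),
    dicom_str_el(0x0018, 0x1164, "DS", spacing_str),
    dicom_str_el(0x0020, 0x000D, "UI", new_uid()),
    dicom_str_el(0x0020, 0x000E, "UI", new_uid()),
    dicom_str_el(0x0020, 0x0062, "CS", laterality),
    dicom_us_el(0x0028, 0x0002, 1),
    dicom_str_el(0x0028, 0x0004, "CS", photometric),
    dicom_us_el(0x0028, 0x0010, nrow(px)),
    dicom_us_el(0x0028, 0x0011, ncol(px)),
    dicom_str_el(0x0028, 0x0030, "DS", spacing_str),
    dicom_us_el(0x0028, 0x0100, 16),
    dicom_us_el(0x0028, 0x0101, 16),
    dicom_us_el(0x0028, 0x0102, 15),
    dicom_us_el(0x0028, 0x0103, 0),
    element_raw(0x7FE0, 0x0010, "OW", pixel_raw)
  )

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(meta, dataset), con)
  invisible(path)
}

# --- reading ---------------------------------------------------------------

read_u16 <- function(buf, pos) {
  readBin(buf[pos:(pos + 1)], "integer", size = 2, signed = FALSE,
          endian = "little")
}

read_u32 <- function(buf, pos) {
  v <- readBin(buf[pos:(pos + 3)], "integer", size = 4, endian = "little")
  if (v < 0) v + 2^32 else v
}

# Scan forward past an undefined-length sequence: find the sequence
# delimitation item (FFFE,E0DD). Items are not recursed into; nested
# undefined-length sequences inside vendor private blocks are not supported.
skip_undefined <- function(buf, pos) {
  pat <- as.raw(c(0xFE, 0xFF, 0xDD, 0xE0, 0x00, 0x00, 0x00, 0x00))
  n <- length(buf)
  while (pos + 7 <= n) {
    if (identical(buf[pos:(pos + 7)], pat)) return(pos + 8)
    pos <- pos + 2
  }
  stop("unterminated undefined-length sequence in DICOM stream")
}

parse_elements <- function(buf, pos, explicit, stop_group = NULL) {
  n <- length(buf)
  out <- list()
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  while (pos + 7 <= n) {
    group <- read_u16(buf, pos)
    element <- read_u16(buf, pos + 2)
    if (!is.null(stop_group) && group != stop_group) break
    if (explicit) {
      vr <- rawToChar(buf[(pos + 4):(pos + 5)])
      if (vr %in% long_vrs) {
        len <- read_u32(buf, pos + 8)
        vstart <- pos + 12
      } else {
        len <- read_u16(buf, pos + 6)
        vstart <- pos + 8
      }
    } else {
      vr <- NA_character_
      len <- read_u32(buf, pos + 4)
      vstart <- pos + 8
    }
    key <- sprintf("%04X,%04X", group, element)
    if (len == 4294967295) {           # undefined length (sequence)
      pos <- skip_undefined(buf, vstart)
      next
    }
    if (vstart + len - 1 > n)
      stop("truncated DICOM element ", key)
    if (identical(vr, "SQ")) {         # defined-length sequence: skip
      pos <- vstart + len
      next
    }
    out[[key]] <- list(vr = vr, value = buf[seq_len(len) + vstart - 1])
    pos <- vstart + len
  }
  list(elements = out, pos = pos)
}

el_string <- function(els, key) {
  e <- els[[key]]
  if (is.null(e)) return(NULL)
  trimws(rawToChar(e$value[e$value != as.raw(0)]))
}

el_u16 <- function(els, key) {
  e <- els[[key]]
  if (is.null(e)) return(NULL)
  read_u16(e$value, 1)
}

#' Read a phantom DICOM image
#'
#' Parses Explicit or Implicit VR Little Endian single-frame grayscale
#' DICOM and normalizes it to the analysis convention: higher pixel value =
#' higher attenuation (objects brighter than background). `MONOCHROME1`
#' data are inverted as `(2^BitsStored - 1) - stored`, so the two
#' photometric encodings of the same scene yield identical normalized
#' images.
#'
#' The chest-wall side is inferred from `ImageLaterality` (`"R"` -> left
#' image edge, `"L"` -> right), flipped when `FieldOfViewHorizontalFlip` is
#' `"YES"`; when both tags are absent a warning is emitted and the side
#' defaults to `chest_wall` (or `"left"`).
#'
#' @param path DICOM file path.
#' @param chest_wall `"auto"` (use tags), `"left"` or `"right"` (override).
#' @return a `phantom_image`: list with `pixels` (matrix, `[row, col]`),
#'   `pixel_spacing_mm` (length-2, row/col), `photometric`,
#'   `chest_wall_edge`, `source`, `metadata`.
#' @export
read_phantom_image <- function(path, chest_wall = c("auto", "left", "right")) {
  chest_wall <- match.arg(chest_wall)
  buf <- readBin(path, "raw", file.size(path))
  if (length(buf) < 140 || rawToChar(buf[129:132]) != "DICM")
    stop("not a DICOM file (missing DICM magic): ", path)
  meta <- parse_elements(buf, 133, explicit = TRUE, stop_group = 0x0002)
  ts <- el_string(meta$elements, "0002,0010") %||% TS_EXPLICIT_LE
  explicit <- switch(ts,
    "1.2.840.10008.1.2.1" = TRUE,
    "1.2.840.10008.1.2" = FALSE,
    stop("unsupported transfer syntax: ", ts,
         " (only uncompressed little-endian is supported)")
  )
  els <- parse_elements(buf, meta$pos, explicit = explicit)$elements

  nframes <- el_string(els, "0028,0008")
  if (!is.null(nframes) && as.integer(nframes) > 1)
    stop("multi-frame DICOM objects (e.g. tomosynthesis) are not supported")

  spacing_str <- el_string(els, "0028,0030") %||% el_string(els, "0018,1164")
  if (is.null(spacing_str))
    stop("missing PixelSpacing (0028,0030) and ImagerPixelSpacing ",
         "(0018,1164); pixel pitch is required for analysis")
  spacing <- as.numeric(strsplit(spacing_str, "\\\\")[[1]])
  spacing <- rep_len(spacing, 2)

  rows <- el_u16(els, "0028,0010")
  cols <- el_u16(els, "0028,0011")
  bits_alloc <- el_u16(els, "0028,0100") %||% 16L
  bits_stored <- el_u16(els, "0028,0101") %||% bits_alloc
  photometric <- el_string(els, "0028,0004") %||% "MONOCHROME2"
  pix <- els[["7FE0,0010"]]
  if (is.null(pix)) stop("no PixelData (7FE0,0010) in ", path)
  if (bits_alloc == 16) {
    v <- readBin(pix$value, "integer", n = rows * cols, size = 2,
                 signed = FALSE, endian = "little")
  } else if (bits_alloc == 8) {
    v <- as.integer(pix$value[seq_len(rows * cols)])
  } else stop("unsupported BitsAllocated: ", bits_alloc)
  px <- matrix(v, nrow = rows, ncol = cols, byrow = TRUE)

  if (photometric == "MONOCHROME1") {
    px <- as.integer(2^bits_stored - 1) - px
  } else if (photometric != "MONOCHROME2") {
    stop("unsupported PhotometricInterpretation: ", photometric)
  }

  laterality <- el_string(els, "0020,0062")
  flip <- el_string(els, "0018,7034")
  if (chest_wall != "auto") {
    side <- chest_wall
  } else if (!is.null(laterality) && laterality %in% c("L", "R")) {
    side <- if (laterality == "R") "left" else "right"
    if (identical(flip, "YES")) side <- setdiff(c("left", "right"), side)
  } else {
    warning("no ImageLaterality/FieldOfViewHorizontalFlip tags; ",
            "assuming chest wall at the left image edge")
    side <- "left"
  }

  phantom_image(
    pixels = px, pixel_spacing_mm = spacing, photometric = photometric,
    chest_wall_edge = side, source = "dicom",
    metadata = list(
      manufacturer = el_string(els, "0008,0070"),
      modality = el_string(els, "0008,0060"),
      software_versions = el_string(els, "0018,1020"),
      kvp = el_string(els, "0018,0060"),
      exposure_mas = el_string(els, "0018,1152"),
      transfer_syntax = ts,
      bits_stored = bits_stored
    )
  )
}

#' Construct a phantom image container
#'
#' @param pixels numeric matrix `[row, col]` of non-negative intensities,
#'   objects-bright convention.
#' @param pixel_spacing_mm pixel pitch, scalar or `(row, col)` pair, mm.
#' @param photometric stored photometric interpretation.
#' @param chest_wall_edge image side touching the chest-wall edge.
#' @param source `"dicom"` or `"synthetic"`.
#' @param metadata free-form tag list.
#' @return a `phantom_image` list.
#' @export
phantom_image <- function(pixels, pixel_spacing_mm,
                          photometric = "MONOCHROME2",
                          chest_wall_edge = "left",
                          source = "synthetic", metadata = list()) {
  spacing <- rep_len(as.numeric(pixel_spacing_mm), 2)
  if (any(spacing < 0.01) || any(spacing > 0.2))
    stop("pixel spacing ", paste(spacing, collapse = "/"),
         " mm outside the supported 0.01-0.2 mm range")
  structure(list(
    pixels = pixels,
    pixel_spacing_mm = spacing,
    photometric = photometric,
    chest_wall_edge = match.arg(chest_wall_edge, c("left", "right")),
    source = match.arg(source, c("dicom", "synthetic")),
    metadata = metadata
  ), class = "phantom_image")
}
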