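# Minimal DICOM codec: Explicit VR Little Endian, single-frame and multiframe
# grayscale images. Covers the attribute subset used by mammography /
# tomosynthesis cases (geometry, laterality/view, pixel spacing, UIDs) plus
# unsigned 16-bit pixel data. Sequences (SQ) with defined length are skipped;
# undefined-length elements are not supported (never written by this package).

.DCM_IMPLICIT_TS <- "1.2.840.10008.1.2"
.DCM_EXPLICIT_LE_TS <- "1.2.840.10008.1.2.1"
.DCM_SC_SOP_CLASS <- "1.2.840.10008.5.1.4.1.1.7"
.DCM_UID_ROOT <- "1.2.826.0.1.3680043.10.1432"

# tag dictionary: keyword -> c(group, element, VR)
.dcm_dict <- list(
  MediaStorageSOPClassUID    = c(0x0002L, 0x0002L, "UI"),
  MediaStorageSOPInstanceUID = c(0x0002L, 0x0003L, "UI"),
  TransferSyntaxUID          = c(0x0002L, 0x0010L, "UI"),
  ImplementationClassUID     = c(0x0002L, 0x0012L, "UI"),
  SOPClassUID                = c(0x0008L, 0x0016L, "UI"),
  SOPInstanceUID             = c(0x0008L, 0x0018L, "UI"),
  StudyDate                  = c(0x0008L, 0x0020L, "DA"),
  StudyTime                  = c(0x0008L, 0x0030L, "TM"),
  Modality                   = c(0x0008L, 0x0060L, "CS"),
  SeriesDescription          = c(0x0008L, 0x103EL, "LO"),
  PatientName                = c(0x0010L, 0x0010L, "PN"),
  PatientID                  = c(0x0010L, 0x0020L, "LO"),
  ViewPosition               = c(0x0018L, 0x5101L, "CS"),
  Laterality                 = c(0x0020L, 0x0060L, "CS"),
  StudyInstanceUID           = c(0x0020L, 0x000DL, "UI"),
  SeriesInstanceUID          = c(0x0020L, 0x000EL, "UI"),
  SeriesNumber               = c(0x0020L, 0x0011L, "IS"),
  InstanceNumber             = c(0x0020L, 0x0013L, "IS"),
  ImageLaterality            = c(0x0020L, 0x0062L, "CS"),
  SliceLocation              = c(0x0020L, 0x1041L, "DS"),
  SamplesPerPixel            = c(0x0028L, 0x0002L, "US"),
  PhotometricInterpretation  = c(0x0028L, 0x0004L, "CS"),
  NumberOfFrames             = c(0x0028L, 0x0008L, "IS"),
  Rows                       = c(0x0028L, 0x0010L, "US"),
  Columns                    = c(0x0028L, 0x0011L, "US"),
  PixelSpacing               = c(0x0028L, 0x0030L, "DS"),
  BitsAllocated              = c(0x0028L, 0x0100L, "US"),
  BitsStored                 = c(0x0028L, 0x0101L, "US"),
  HighBit                    = c(0x0028L, 0x0102L, "US"),
  PixelRepresentation        = c(0x0028L, 0x0103L, "US"),
  PixelData                  = c(0x7FE0L, 0x0010L, "OW")
)

.dcm_keyword_by_tag <- local({
  keys <- vapply(.dcm_dict, function(d) sprintf("%04X%04X", as.integer(d[1]), as.integer(d[2])), "")
  stats::setNames(names(.dcm_dict), keys)
})

.dcm_u16 <- function(x) {
  x <- as.integer(x)
  as.raw(c(bitwAnd(x, 0xFFL), bitwAnd(bitwShiftR(x, 8L), 0xFFL)))
}

.dcm_u32 <- function(x) {
  x <- as.numeric(x)
  as.raw(c(x %% 256, (x %/% 256) %% 256, (x %/% 65536) %% 256, (x %/% 16777216) %% 256))
}

.dcm_pad_string <- function(s, vr) {
  b <- charToRaw(s)
  if (length(b) %% 2L == 1L) b <- c(b, if (vr == "UI") as.raw(0L) else charToRaw(" "))
  b
}

# encode one data element (explicit VR little endian)
.dcm_element <- function(group, element, vr, value) {
  if (vr %in% c("OB", "OW")) {
    body <- value  # raw vector
    header <- c(.dcm_u16(group), .dcm_u16(element), charToRaw(vr), as.raw(c(0, 0)),
                .dcm_u32(length(body)))
  } else if (vr == "US") {
    body <- unlist(lapply(as.integer(value), .dcm_u16))
    header <- c(.dcm_u16(group), .dcm_u16(element), charToRaw(vr), .dcm_u16(length(body)))
  } else if (vr == "UL") {
    body <- unlist(lapply(value, .dcm_u32))
    header <- c(.dcm_u16(group), .dcm_u16(element), charToRaw(vr), .dcm_u16(length(body)))
  } else {
    s <- paste(as.character(value), collapse = "\\")
    body <- .dcm_pad_string(s, vr)
    header <- c(.dcm_u16(group), .dcm_u16(element), charToRaw(vr), .dcm_u16(length(body)))
  }
  c(header, body)
}

#' Write a DICOM file (Explicit VR Little Endian)
#'
#' Serializes a grayscale image (or slice stack) plus a named attribute list
#' to a standards-conformant single- or multiframe DICOM file. Pixel values
#' must be integers in [0, 65535]; they are stored as unsigned 16-bit.
#'
#' @param path output file path.
#' @param pixel integer matrix (rows x cols) or 3-D array (rows x cols x
#'   frames) of stored pixel values.
#' @param tags named list of DICOM attributes (dictionary keywords, e.g.
#'   `Modality`, `ImageLaterality`, `ViewPosition`, `PixelSpacing`).
#'   Geometry tags (Rows, Columns, BitsAllocated, ...) are filled in
#'   automatically from `pixel`.
#' @return `path`, invisibly.
#' @keywords internal
dcm_write <- function(path, pixel, tags = list()) {
  if (is.matrix(pixel)) pixel <- array(pixel, dim = c(dim(pixel), 1L))
  stopifnot(length(dim(pixel)) == 3L)
  nr <- dim(pixel)[1]; nc <- dim(pixel)[2]; nf <- dim(pixel)[3]
  if (any(pixel < 0 | pixel > 65535)) stop("pixel values outside unsigned 16-bit range")

  sop_uid <- tags$SOPInstanceUID %||% paste0(.DCM_UID_ROOT, ".0.0")
  defaults <- list(
    SOPClassUID = .DCM_SC_SOP_CLASS, SOPInstanceUID = sop_uid,
    StudyDate = "20000101", StudyTime = "000000",
    Modality = "MG", PatientName = "PHANTOM", PatientID = "PHANTOM",
    SamplesPerPixel = 1L, PhotometricInterpretation = "MONOCHROME2",
    Rows = nr, Columns = nc, BitsAllocated = 16L, BitsStored = 16L,
    HighBit = 15L, PixelRepresentation = 0L
  )
  tags <- utils::modifyList(defaults, tags)
  tags$Rows <- nr; tags$Columns <- nc
  if (nf > 1L) tags$NumberOfFrames <- nf

  # file meta group (0002)
  meta_tags <- list(
    MediaStorageSOPClassUID = tags$SOPClassUID,
    MediaStorageSOPInstanceUID = tags$SOPInstanceUID,
    TransferSyntaxUID = .DCM_EXPLICIT_LE_TS,
    ImplementationClassUID = paste0(.DCM_UID_ROOT, ".1")
  )
  meta_raw <- c(
    .dcm_element(0x0002L, 0x0001L, "OB", as.raw(c(0, 1))),
    unlist(lapply(names(meta_tags), function(k) {
      d <- .dcm_dict[[k]]
      .dcm_element(as.integer(d[1]), as.integer(d[2]), d[3], meta_tags[[k]])
    }))
  )

  # dataset elements sorted by (group, element); pixel data last by tag order
  ds_names <- setdiff(names(tags), names(meta_tags))
  ds_names <- ds_names[ds_names %in% names(.dcm_dict)]
  ord <- order(vapply(ds_names, function(k) {
    d <- .dcm_dict[[k]]; as.integer(d[1]) * 65536 + as.integer(d[2])
  }, 0))
  ds_names <- ds_names[ord]

  # pixel data: row-major within each frame, frames concatenated
  px <- integer(0)
  for (f in seq_len(nf)) px <- c(px, as.integer(t(pixel[, , f])))
  # writeBin size=2 takes signed shorts; map the upper half via two's complement
  px_big <- px > 32767L
  if (any(px_big)) px[px_big] <- px[px_big] - 65536L
  px_raw <- writeBin(px, raw(), size = 2L, endian = "little")

  body <- unlist(lapply(ds_names, function(k) {
    d <- .dcm_dict[[k]]
    .dcm_element(as.integer(d[1]), as.integer(d[2]), d[3], tags[[k]])
  }))
  body <- c(body, .dcm_element(0x7FE0L, 0x0010L, "OW", px_raw))

  out <- c(
    raw(128), charToRaw("DICM"),
    .dcm_element(0x0002L, 0x0000L, "UL", length(meta_raw)),
    meta_raw, body
  )
  writeBin(out, path)
  invisible(path)
}

.dcm_read_u16 <- function(b, i) as.integer(b[i]) + 256L * as.integer(b[i + 1L])
.dcm_read_u32 <- function(b, i) {
  as.numeric(b[i]) + 256 * as.numeric(b[i + 1L]) +
    65536 * as.numeric(b[i + 2L]) + 16777216 * as.numeric(b[i + 3L])
}

#' Test whether a file looks like a DICOM file
#'
#' Checks for the 128-byte preamble followed by the "DICM" magic.
#'
#' @param path file path.
#' @return logical scalar.
#' @keywords internal
dcm_is_dicom <- function(path) {
  if (!file.exists(path) || dir.exists(path)) return(FALSE)
  sz <- file.size(path)
  if (is.na(sz) || sz < 136) return(FALSE)
  con <- file(path, "rb"); on.exit(close(con))
  b <- readBin(con, raw(), 132L)
  length(b) == 132L && rawToChar(b[129:132]) == "DICM"
}

#' Read a DICOM file written in Explicit VR Little Endian
#'
#' Parses the attribute subset in the package dictionary into a named list and
#' (optionally) decodes unsigned 16-bit pixel data. Unknown attributes are
#' skipped; defined-length sequences are skipped whole.
#'
#' @param path file path.
#' @param pixel if `TRUE` decode PixelData into a matrix (single frame) or
#'   rows x cols x frames array.
#' @return list with `meta` (named list keyed by dictionary keyword; numeric
#'   VRs decoded to numeric, `PixelSpacing` to a length-2 numeric) and
#'   `pixel` (or `NULL`).
#' @keywords internal
dcm_read <- function(path, pixel = TRUE) {
  if (!dcm_is_dicom(path)) stop("not a DICOM file: ", path)
  b <- readBin(path, raw(), file.size(path))
  i <- 133L  # after preamble + DICM
  n <- length(b)
  meta <- list()
  px_raw <- NULL
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  while (i + 7L <= n) {
    group <- .dcm_read_u16(b, i); element <- .dcm_read_u16(b, i + 2L)
    vr <- rawToChar(b[(i + 4L):(i + 5L)])
    if (vr %in% long_vrs) {
      len <- .dcm_read_u32(b, i + 8L)
      hdr <- 12L
    } else if (grepl("^[A-Z]{2}$", vr)) {
      len <- .dcm_read_u16(b, i + 6L)
      hdr <- 8L
    } else stop(sprintf("unsupported encoding at byte %d in %s (implicit VR?)", i, path))
    if (len == 4294967295) stop("undefined-length element at byte ", i, " in ", path)
    val_start <- i + hdr
    if (val_start + len - 1L > n) stop("truncated DICOM element at byte ", i, " in ", path)
    key <- sprintf("%04X%04X", group, element)
    kw <- .dcm_keyword_by_tag[key]
    if (!is.na(kw)) {
      if (kw == "PixelData") {
        px_raw <- b[val_start:(val_start + len - 1L)]
      } else {
        d <- .dcm_dict[[kw]]
        raw_val <- b[seq_len(len) + val_start - 1L]
        meta[[kw]] <- switch(d[3],
          US = .dcm_read_u16(raw_val, 1L),
          UL = .dcm_read_u32(raw_val, 1L),
          DS = as.numeric(strsplit(trimws(rawToChar(raw_val)), "\\\\")[[1]]),
          IS = as.integer(trimws(rawToChar(raw_val))),
          {
            s <- rawToChar(raw_val[raw_val != as.raw(0L)])
            trimws(s)
          })
      }
    }
    i <- val_start + len
  }
  out <- list(meta = meta, pixel = NULL)
  if (pixel && !is.null(px_raw)) {
    nr <- meta$Rows; nc <- meta$Columns
    nf <- if (!is.null(meta$NumberOfFrames)) meta$NumberOfFrames else 1L
    vals <- readBin(px_raw, integer(), n = length(px_raw) / 2L, size = 2L,
                    endian = "little", signed = FALSE)
    if (length(vals) != nr * nc * nf)
      stop("pixel data length mismatch in ", path)
    arr <- array(0L, dim = c(nr, nc, nf))
    for (f in seq_len(nf)) {
      # stored row-major per frame
      arr[, , f] <- matrix(vals[seq_len(nr * nc) + (f - 1L) * nr * nc],
                           nrow = nr, ncol = nc, byrow = TRUE)
    }
    out$pixel <- if (nf == 1L) arr[, , 1L] else arr
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
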