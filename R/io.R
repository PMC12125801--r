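# Image/mask I/O.  Three carriers:
#   * PGM (plain or raw): dependency-free grayscale, 8- or 16-bit.
#   * Single-slice NIfTI-1 (.nii / .nii.gz): minimal reader/writer for
#     float32 / int16 / uint8 data, little-endian, no extensions.  Written
#     here because no NIfTI package is available in the target R stack.
#   * PNG (16-bit image / 8-bit mask) when the optional `png` package is
#     installed.
# A JSON sidecar records the generating phantom_spec and, for integer
# carriers, the affine (slope, intercept) mapping stored units back to HU.

#' Write a grayscale matrix as PGM
#'
#' @param mat Numeric matrix of non-negative integers up to `maxval`.
#' @param path Output path.
#' @param maxval 255 (8-bit) or 65535 (16-bit big-endian).
#' @param ascii Write plain (P2) instead of raw (P5) format.
#' @return `path`, invisibly.
#' @export
write_pgm <- function(mat, path, maxval = 255L, ascii = FALSE) {
  v <- round(t(mat)) # PGM is row-major
  if (min(v) < 0 || max(v) > maxval) stop("values outside [0, maxval]")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c(if (ascii) "P2" else "P5",
               paste(ncol(mat), nrow(mat)), as.character(maxval)), con)
  if (ascii) {
    writeLines(paste(as.integer(v), collapse = " "), con)
  } else {
    writeBin(as.integer(v), con, size = if (maxval > 255L) 2L else 1L,
             endian = "big")
  }
  invisible(path)
}

#' Read a PGM file
#'
#' @param path PGM file (P2 or P5).
#' @return Numeric matrix.
#' @export
read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  tok <- character(0)
  while (length(tok) < 4L) {
    line <- readLines(con, 1L)
    line <- sub("#.*", "", line)
    tok <- c(tok, strsplit(trimws(line), "\\s+")[[1]])
  }
  magic <- tok[1L]
  w <- as.integer(tok[2L])
  h <- as.integer(tok[3L])
  maxval <- as.integer(tok[4L])
  if (magic == "P5") {
    v <- readBin(con, "integer", w * h, size = if (maxval > 255L) 2L else 1L,
                 signed = FALSE, endian = "big")
  } else if (magic == "P2") {
    v <- scan(con, what = integer(), n = w * h, quiet = TRUE)
  } else {
    stop("not a PGM file: ", path)
  }
  matrix(v, h, w, byrow = TRUE)
}

# ---- minimal single-slice NIfTI-1 ------------------------------------------

nifti_datatypes <- list(uint8 = c(code = 2L, bitpix = 8L),
                        int16 = c(code = 4L, bitpix = 16L),
                        float32 = c(code = 16L, bitpix = 32L),
                        float64 = c(code = 64L, bitpix = 64L))

#' Write a 2-D slice as a NIfTI-1 file
#'
#' Minimal little-endian NIfTI-1 writer (no extensions, identity
#' orientation).  `.gz` paths are compressed transparently.
#'
#' @param mat Numeric matrix (stored as a 2-D NIfTI image).
#' @param path Output path ending in `.nii` or `.nii.gz`.
#' @param datatype One of `"float32"`, `"float64"`, `"int16"`, `"uint8"`.
#' @param pixdim Length-2 in-plane pixel spacing.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(mat, path, datatype = "float32", pixdim = c(1, 1)) {
  dt <- nifti_datatypes[[datatype]]
  if (is.null(dt)) stop("unsupported datatype: ", datatype)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  le <- "little"
  wi <- function(x, size) writeBin(as.integer(x), con, size = size, endian = le)
  wf <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = le)
  pad <- function(n) writeBin(raw(n), con)

  wi(348L, 4L)                       # sizeof_hdr
  pad(10L + 18L + 4L + 2L + 1L + 1L) # data_type..dim_info
  wi(c(2L, nrow(mat), ncol(mat), 1L, 1L, 1L, 1L, 1L), 2L) # dim
  wf(c(0, 0, 0))                     # intent_p1..p3
  wi(0L, 2L)                         # intent_code
  wi(dt[["code"]], 2L)               # datatype
  wi(dt[["bitpix"]], 2L)             # bitpix
  wi(0L, 2L)                         # slice_start
  wf(c(1, pixdim[1L], pixdim[2L], 1, 1, 1, 1, 1)) # pixdim
  wf(352)                            # vox_offset
  wf(c(1, 0))                        # scl_slope, scl_inter
  wi(0L, 2L)                         # slice_end
  pad(2L)                            # slice_code, xyzt_units
  wf(c(0, 0, 0, 0))                  # cal_max..toffset
  wi(c(0L, 0L), 4L)                  # glmax, glmin
  pad(80L + 24L)                     # descrip, aux_file
  wi(c(0L, 1L), 2L)                  # qform_code, sform_code
  wf(c(0, 0, 0, 0, 0, 0))            # quatern, qoffset
  wf(c(1, 0, 0, 0))                  # srow_x
  wf(c(0, 1, 0, 0))                  # srow_y
  wf(c(0, 0, 1, 0))                  # srow_z
  pad(16L)                           # intent_name
  writeBin(c(charToRaw("n+1"), raw(1L)), con) # magic
  pad(4L)                            # extension flag
  v <- as.vector(mat)
  switch(datatype,
         float32 = writeBin(as.numeric(v), con, size = 4L, endian = le),
         float64 = writeBin(as.numeric(v), con, size = 8L, endian = le),
         int16 = wi(v, 2L),
         uint8 = writeBin(as.raw(v), con))
  invisible(path)
}

#' Read a 2-D NIfTI-1 file
#'
#' Supports the subset written by [write_nifti()] plus any little-endian
#' uncompressed/gzipped NIfTI-1 with datatype uint8, int16, float32 or
#' float64; the first 2-D slice is returned with `scl_slope`/`scl_inter`
#' applied.
#'
#' @param path `.nii` or `.nii.gz` file.
#' @return Numeric matrix.
#' @export
read_nifti <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rb") else file(path, "rb")
  on.exit(close(con))
  le <- "little"
  hdr <- readBin(con, "raw", 348L)
  ri <- function(off, size, n = 1L) {
    readBin(hdr[(off + 1L):(off + size * n)], "integer", n, size = size,
            endian = le)
  }
  rf <- function(off, n = 1L) {
    readBin(hdr[(off + 1L):(off + 4L * n)], "numeric", n, size = 4L,
            endian = le)
  }
  if (ri(0L, 4L) != 348L) stop("not a NIfTI-1 file: ", path)
  dims <- ri(40L, 2L, 8L)
  h <- dims[2L]
  w <- dims[3L]
  datatype <- ri(70L, 2L)
  vox_offset <- rf(108L)
  scl_slope <- rf(112L)
  scl_inter <- rf(116L)
  skip <- vox_offset - 348L
  if (skip > 0) readBin(con, "raw", skip)
  n <- h * w
  v <- switch(as.character(datatype),
              "2" = as.integer(readBin(con, "raw", n)),
              "4" = readBin(con, "integer", n, size = 2L, endian = le),
              "16" = readBin(con, "numeric", n, size = 4L, endian = le),
              "64" = readBin(con, "numeric", n, size = 8L, endian = le),
              stop("unsupported NIfTI datatype: ", datatype))
  if (scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0)) {
    v <- v * scl_slope + scl_inter
  }
  matrix(v, h, w)
}

# ---- phantom pair persistence ----------------------------------------------

#' Write a phantom image/mask pair with a JSON sidecar
#'
#' `nifti` stores the HU image as float32 `.nii.gz` and the mask as uint8;
#' `pgm` stores the image as 16-bit PGM in affine-coded stored units
#' (slope/intercept recorded in the sidecar, so [hu_convert()] restores
#' HU) and the mask as 8-bit PGM; `png` (needs the optional `png` package)
#' does the same with 16-bit/8-bit PNG.
#'
#' @param pair A `phantom_pair`.
#' @param dir Output directory (created if needed).
#' @param name Basename for the three files.
#' @param format `"nifti"`, `"pgm"` or `"png"`.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_phantom_pair <- function(pair, dir, name = "phantom",
                               format = c("nifti", "pgm", "png")) {
  format <- match.arg(format)
  stopifnot(inherits(pair, "phantom_pair"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sidecar <- file.path(dir, paste0(name, ".json"))
  meta <- list(spec = unclass(pair$spec), format = format)

  if (format == "nifti") {
    img_path <- file.path(dir, paste0(name, "_img.nii.gz"))
    msk_path <- file.path(dir, paste0(name, "_mask.nii.gz"))
    write_nifti(pair$image, img_path, "float32")
    write_nifti(pair$mask, msk_path, "uint8")
  } else {
    # affine-code HU into unsigned ints: stored = (hu - intercept) / slope
    maxint <- if (format == "pgm") 65535 else 255
    rng <- range(pair$image)
    slope <- max((rng[2L] - rng[1L]) / maxint, 1e-6)
    intercept <- rng[1L]
    stored <- round((pair$image - intercept) / slope)
    meta$rescale <- list(slope = slope, intercept = intercept)
    ext <- if (format == "pgm") ".pgm" else ".png"
    img_path <- file.path(dir, paste0(name, "_img", ext))
    msk_path <- file.path(dir, paste0(name, "_mask", ext))
    if (format == "pgm") {
      write_pgm(stored, img_path, 65535L)
      write_pgm(pair$mask, msk_path, 255L)
    } else {
      if (!requireNamespace("png", quietly = TRUE)) {
        stop("the `png` package is required for format = \"png\"")
      }
      png::writePNG(stored / maxint, img_path)
      png::writePNG(pair$mask, msk_path)
    }
  }
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA)
  invisible(c(image = img_path, mask = msk_path, sidecar = sidecar))
}

#' Read a phantom pair written by [write_phantom_pair()]
#'
#' @param dir Directory containing the files.
#' @param name Basename used at write time.
#' @return List with `image` (HU matrix), `mask` (binary matrix), `spec`
#'   (a [phantom_spec()]).
#' @export
read_phantom_pair <- function(dir, name = "phantom") {
  meta <- jsonlite::read_json(file.path(dir, paste0(name, ".json")),
                              simplifyVector = TRUE)
  format <- meta$format
  if (format == "nifti") {
    image <- read_nifti(file.path(dir, paste0(name, "_img.nii.gz")))
    mask <- read_nifti(file.path(dir, paste0(name, "_mask.nii.gz")))
  } else {
    ext <- if (format == "pgm") ".pgm" else ".png"
    stored <- if (format == "pgm") {
      read_pgm(file.path(dir, paste0(name, "_img", ext)))
    } else {
      png::readPNG(file.path(dir, paste0(name, "_img", ext))) * 255
    }
    mask_raw <- if (format == "pgm") {
      read_pgm(file.path(dir, paste0(name, "_mask", ext)))
    } else {
      png::readPNG(file.path(dir, paste0(name, "_mask", ext))) * 255
    }
    image <- hu_convert(stored, meta$rescale$slope, meta$rescale$intercept)
    mask <- (mask_raw > 0) * 1
  }
  spec_args <- meta$spec
  spec <- do.call(phantom_spec, spec_args)
  list(image = image, mask = (mask > 0) * 1, spec = spec)
}
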