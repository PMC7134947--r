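# ENVI header + flat-binary hypercube I/O.
#
# Dialect: classic ENVI text header (.hdr) next to a raw binary file.
# Header keys used: samples, lines, bands, data type, interleave, byte order,
# wavelength units, wavelength = { ... }, plus user keys `unit` and
# `camera id`. Data types supported: 4 (float32), 5 (float64), 12 (uint16).
# Byte order is always written little-endian (0).

ENVI_DTYPES <- list(
  `4` = list(what = "double", size = 4L, signed = TRUE),
  `5` = list(what = "double", size = 8L, signed = TRUE),
  `12` = list(what = "integer", size = 2L, signed = FALSE)
)

envi_binary_path <- function(header_path) {
  base <- sub("\\.hdr$", "", header_path)
  cands <- c(base, paste0(base, c(".dat", ".img", ".raw", ".bil", ".bip", ".bsq")))
  hit <- cands[file.exists(cands) & cands != header_path]
  if (length(hit) == 0L) {
    stop("no binary image file found next to header '", header_path, "'",
         call. = FALSE)
  }
  hit[[1L]]
}

parse_envi_header <- function(header_path) {
  txt <- readLines(header_path, warn = FALSE)
  if (length(txt) == 0L || !grepl("^ENVI", txt[[1L]])) {
    stop("'", header_path, "' is not an ENVI header (missing ENVI magic)",
         call. = FALSE)
  }
  # split into "key = value" records; a value may span lines inside { }
  recs <- list()
  buf <- ""
  for (line in txt[-1L]) {
    buf <- if (nzchar(buf)) paste(buf, line) else line
    nopen <- lengths(regmatches(buf, gregexpr("\\{", buf)))
    nclose <- lengths(regmatches(buf, gregexpr("\\}", buf)))
    if (nopen == nclose) {
      if (nzchar(trimws(buf))) recs[[length(recs) + 1L]] <- buf
      buf <- ""
    }
  }
  out <- list()
  for (r in recs) {
    m <- regexpr("=", r, fixed = TRUE)
    if (m < 0) next
    key <- tolower(trimws(substr(r, 1L, m - 1L)))
    val <- trimws(substr(r, m + 1L, nchar(r)))
    out[[key]] <- val
  }
  out
}

header_num <- function(h, key) {
  if (is.null(h[[key]])) stop("ENVI header missing required key '", key, "'",
                              call. = FALSE)
  as.numeric(h[[key]])
}

#' Read an ENVI hypercube
#'
#' Reads an ENVI text header and its companion flat binary image into a
#' [hypercube]. The wavelength list is taken verbatim from the header; the
#' unit defaults to `"DN"` unless the header carries a `unit` user key.
#'
#' @param header_path Path to the `.hdr` file. The binary is located next to
#'   it (same basename, optionally with a `.dat`/`.img`/`.raw` extension).
#' @return A [hypercube].
#' @export
read_envi_cube <- function(header_path) {
  h <- parse_envi_header(header_path)
  samples <- header_num(h, "samples")
  lines <- header_num(h, "lines")
  bands <- header_num(h, "bands")
  dtype <- as.character(header_num(h, "data type"))
  interleave <- toupper(if (is.null(h[["interleave"]])) "BIL" else h[["interleave"]])
  if (is.null(h[["wavelength"]])) {
    stop("ENVI header carries no wavelength list", call. = FALSE)
  }
  wl <- as.numeric(strsplit(gsub("[{}]", "", h[["wavelength"]]), ",")[[1L]])
  if (length(wl) != bands) {
    stop(sprintf("corrupt file: header declares %d bands but lists %d wavelengths",
                 bands, length(wl)), call. = FALSE)
  }
  spec <- ENVI_DTYPES[[dtype]]
  if (is.null(spec)) stop("unsupported ENVI data type ", dtype, call. = FALSE)
  bin <- envi_binary_path(header_path)
  n <- samples * lines * bands
  expect_bytes <- n * spec$size
  if (file.info(bin)$size != expect_bytes) {
    stop(sprintf("corrupt file: '%s' has %d bytes, expected %d for %dx%dx%d %s",
                 bin, file.info(bin)$size, expect_bytes, lines, samples, bands,
                 interleave), call. = FALSE)
  }
  v <- readBin(bin, what = spec$what, n = n, size = spec$size,
               signed = spec$signed, endian = "little")
  data <- switch(interleave,
    BIL = aperm(array(v, c(samples, bands, lines)), c(3L, 1L, 2L)),
    BIP = aperm(array(v, c(bands, samples, lines)), c(3L, 2L, 1L)),
    BSQ = aperm(array(v, c(samples, lines, bands)), c(2L, 1L, 3L)),
    stop("unsupported interleave '", interleave, "'", call. = FALSE)
  )
  unit <- if (is.null(h[["unit"]])) "DN" else h[["unit"]]
  camera <- if (is.null(h[["camera id"]])) "camera" else h[["camera id"]]
  hypercube(data, wl, unit = unit, camera_id = camera, interleave = interleave)
}

#' Write a hypercube as ENVI header + flat binary
#'
#' Raw digital-number cubes are stored as unsigned 16-bit integers; radiance
#' and reflectance cubes as 32-bit floats (lossless round trip at float32
#' precision; use `data_type = 5` for float64 exactness).
#'
#' @param cube A [hypercube].
#' @param header_path Output `.hdr` path; the binary is written next to it
#'   with a `.dat` extension.
#' @param data_type ENVI data type code: 4 (float32), 5 (float64) or
#'   12 (uint16). Default: 12 for DN cubes, 5 otherwise.
#' @return `header_path`, invisibly.
#' @export
write_envi_cube <- function(cube, header_path, data_type = NULL) {
  stopifnot(inherits(cube, "hypercube"))
  if (is.null(data_type)) data_type <- if (cube$unit == "DN") 12L else 5L
  spec <- ENVI_DTYPES[[as.character(data_type)]]
  if (is.null(spec)) stop("unsupported ENVI data type ", data_type, call. = FALSE)
  d <- dim(cube$data)
  bin <- paste0(sub("\\.hdr$", "", header_path), ".dat")
  v <- switch(cube$interleave,
    BIL = as.vector(aperm(cube$data, c(2L, 3L, 1L))),
    BIP = as.vector(aperm(cube$data, c(3L, 2L, 1L))),
    BSQ = as.vector(aperm(cube$data, c(2L, 1L, 3L)))
  )
  con <- tryCatch(file(bin, "wb"), error = function(e) {
    stop("cannot open '", bin, "' for writing: ", conditionMessage(e), call. = FALSE)
  })
  on.exit(close(con), add = TRUE)
  if (data_type == 12L) {
    iv <- as.integer(round(v))
    if (any(iv < 0 | iv > 65535)) {
      stop("DN values outside uint16 range; write as float instead", call. = FALSE)
    }
    iv[iv > 32767L] <- iv[iv > 32767L] - 65536L  # two's-complement packing
    writeBin(iv, con, size = 2L, endian = "little")
  } else {
    writeBin(v, con, size = spec$size, endian = "little")
  }
  hdr <- c(
    "ENVI",
    sprintf("samples = %d", d[2L]),
    sprintf("lines = %d", d[1L]),
    sprintf("bands = %d", d[3L]),
    "header offset = 0",
    "file type = ENVI Standard",
    sprintf("data type = %d", data_type),
    sprintf("interleave = %s", tolower(cube$interleave)),
    "byte order = 0",
    "wavelength units = Nanometers",
    sprintf("unit = %s", cube$unit),
    sprintf("camera id = %s", cube$camera_id),
    sprintf("wavelength = { %s }",
            paste(format(cube$wavelengths_nm, trim = TRUE, digits = 15),
                  collapse = ", "))
  )
  writeLines(hdr, header_path)
  invisible(header_path)
}
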