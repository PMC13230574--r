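# Minimal MAT level-5 (the consumer-tool dialect) reader/writer for real and
# complex numeric matrices. Implemented in-package because no installed R
# package reads this container; only the subset the dataset uses is covered:
# one or more named 2-D numeric matrices, little-endian, uncompressed on the
# write side, with zlib-compressed elements accepted on the read side where
# the running R build can inflate them.

MI_TYPES <- c(miINT8 = 1, miUINT8 = 2, miINT16 = 3, miUINT16 = 4,
              miINT32 = 5, miUINT32 = 6, miSINGLE = 7, miDOUBLE = 9,
              miINT64 = 12, miUINT64 = 13, miMATRIX = 14, miCOMPRESSED = 15,
              miUTF8 = 16)

mat5_pad <- function(n) (8 - n %% 8) %% 8

mat5_element <- function(type, payload_raw) {
  c(writeBin(c(as.integer(type), length(payload_raw)), raw(),
             size = 4, endian = "little"),
    payload_raw, raw(mat5_pad(length(payload_raw))))
}

#' Write a named numeric matrix to a MAT level-5 file
#'
#' Writes a single real or complex double matrix under `name`. Values are
#' stored at full double precision; complex matrices carry separate real and
#' imaginary parts.
#'
#' @param path Output file path.
#' @param m Numeric or complex matrix.
#' @param name Variable name inside the file (e.g. `"adcData"`).
#' @export
write_mat5 <- function(path, m, name) {
  stopifnot(is.matrix(m), nzchar(name))
  is_cplx <- is.complex(m)
  header <- charToRaw(sprintf("%-116s", "MATLAB 5.0 MAT-file, written by emowave"))
  header <- c(header, raw(8),
              writeBin(0x0100L, raw(), size = 2, endian = "little"),
              charToRaw("IM"))
  flags <- bitwOr(6L, if (is_cplx) bitwShiftL(8L, 8) else 0L)  # mxDOUBLE | complex
  sub <- c(mat5_element(MI_TYPES["miUINT32"],
                        writeBin(c(flags, 0L), raw(), size = 4, endian = "little")),
           mat5_element(MI_TYPES["miINT32"],
                        writeBin(as.integer(dim(m)), raw(), size = 4,
                                 endian = "little")),
           mat5_element(MI_TYPES["miINT8"], charToRaw(name)),
           mat5_element(MI_TYPES["miDOUBLE"],
                        writeBin(as.numeric(Re(m)), raw(), size = 8,
                                 endian = "little")))
  if (is_cplx)
    sub <- c(sub, mat5_element(MI_TYPES["miDOUBLE"],
                               writeBin(as.numeric(Im(m)), raw(), size = 8,
                                        endian = "little")))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(header, con)
  writeBin(writeBin(as.integer(c(MI_TYPES[["miMATRIX"]], length(sub))),
                    raw(), size = 4, endian = "little"), con)
  writeBin(sub, con)
  invisible(path)
}

# decode a numeric payload of a given mi type
mat5_decode_numeric <- function(payload, type) {
  spec <- switch(as.character(type),
    "1" = list(what = "integer", size = 1, signed = TRUE),
    "2" = list(what = "integer", size = 1, signed = FALSE),
    "3" = list(what = "integer", size = 2, signed = TRUE),
    "4" = list(what = "integer", size = 2, signed = FALSE),
    "5" = list(what = "integer", size = 4, signed = TRUE),
    "6" = list(what = "integer", size = 4, signed = TRUE),
    "7" = list(what = "double", size = 4, signed = TRUE),
    "9" = list(what = "double", size = 8, signed = TRUE),
    stop(sprintf("unsupported MAT data type %d", type)))
  as.numeric(readBin(payload, spec$what, n = length(payload) %/% spec$size,
                     size = spec$size, signed = spec$signed,
                     endian = "little"))
}

# read one (type, payload) sub-element starting at offset `pos` in raw
# vector `r`; handles the packed small-data-element format
mat5_read_sub <- function(r, pos) {
  tag <- readBin(r[pos:(pos + 3)], "integer", size = 4, endian = "little")
  small_len <- bitwShiftR(bitwAnd(tag, -65536L), 16)
  if (small_len != 0) {
    type <- bitwAnd(tag, 65535L)
    nb <- small_len
    payload <- if (nb > 0) r[(pos + 4):(pos + 3 + nb)] else raw(0)
    list(type = type, payload = payload, next_pos = pos + 8)
  } else {
    type <- tag
    nb <- readBin(r[(pos + 4):(pos + 7)], "integer", size = 4,
                  endian = "little")
    payload <- if (nb > 0) r[(pos + 8):(pos + 7 + nb)] else raw(0)
    list(type = type, payload = payload,
         next_pos = pos + 8 + nb + mat5_pad(nb))
  }
}

mat5_parse_matrix <- function(payload) {
  p <- 1
  flags <- mat5_read_sub(payload, p)
  fw <- readBin(flags$payload[1:4], "integer", size = 4, endian = "little")
  is_cplx <- bitwAnd(bitwShiftR(fw, 8), 8L) != 0
  p <- flags$next_pos
  dims_el <- mat5_read_sub(payload, p)
  dims <- readBin(dims_el$payload, "integer",
                  n = length(dims_el$payload) %/% 4, size = 4,
                  endian = "little")
  p <- dims_el$next_pos
  name_el <- mat5_read_sub(payload, p)
  name <- rawToChar(name_el$payload)
  p <- name_el$next_pos
  re_el <- mat5_read_sub(payload, p)
  re <- mat5_decode_numeric(re_el$payload, re_el$type)
  val <- re
  if (is_cplx) {
    im_el <- mat5_read_sub(payload, re_el$next_pos)
    val <- complex(real = re,
                   imaginary = mat5_decode_numeric(im_el$payload, im_el$type))
  }
  if (length(dims) != 2)
    stop("only 2-D matrices are supported")
  list(name = name, value = matrix(val, dims[1], dims[2]))
}

#' Read all matrices from a MAT level-5 file
#'
#' Supports uncompressed and (where the R build can inflate zlib streams)
#' compressed elements holding real or complex 2-D numeric matrices.
#' HDF5-based MAT variants (v7.3) are rejected with an informative error.
#'
#' @param path File path.
#' @return Named list of matrices.
#' @export
read_mat5 <- function(path) {
  r <- readBin(path, "raw", n = file.info(path)$size)
  if (length(r) < 128) stop("file too short to be a MAT level-5 file")
  if (grepl("MATLAB 7.3", rawToChar(r[1:19]), fixed = TRUE))
    stop("HDF5-based MAT (v7.3) files are not supported by this reader")
  endian <- rawToChar(r[127:128])
  if (endian != "IM") stop("big-endian MAT files are not supported")
  out <- list()
  pos <- 129
  while (pos + 7 <= length(r)) {
    el <- mat5_read_sub(r, pos)
    payload <- el$payload
    type <- el$type
    if (type == MI_TYPES[["miCOMPRESSED"]]) {
      payload <- tryCatch(
        memDecompress(payload, type = "gzip"),
        error = function(e) stop("cannot inflate compressed MAT element: ",
                                 conditionMessage(e)))
      inner <- mat5_read_sub(payload, 1)
      type <- inner$type
      payload <- inner$payload
    }
    if (type == MI_TYPES[["miMATRIX"]] && length(payload) > 0) {
      m <- mat5_parse_matrix(payload)
      out[[m$name]] <- m$value
    }
    pos <- el$next_pos
  }
  out
}
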