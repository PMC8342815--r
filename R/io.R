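#' Read a 3D volume from TIFF, NRRD or Avizo ASCII
#'
#' Supported formats, chosen by file extension:
#' * multi-page grayscale TIFF (`.tif`, `.tiff`), 8- or 16-bit;
#' * NRRD (`.nrrd`), 3D scalar, `ascii` or little-endian `raw` encoding,
#'   `uchar`/`ushort` types;
#' * Avizo AmiraMesh ASCII uniform lattice (`.am`), single scalar `byte` or
#'   `ushort` field (the documented FlyCircuit export subset); binary or
#'   RLE-encoded `.am` files are rejected with a clear error.
#'
#' Bit depth is inferred from the stored values: a maximum above 255 means
#' 12-bit data (stored in a 16-bit container), otherwise 8-bit, unless
#' overridden.
#'
#' @param path input file.
#' @param bit_depth optional override (8 or 12).
#' @return A [volume_image()].
#' @export
read_volume <- function(path, bit_depth = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  a <- switch(ext,
    tif = , tiff = read_tiff_volume(path),
    nrrd = read_nrrd(path),
    am = read_avizo_am(path),
    stop("unsupported volume format: .", ext)
  )
  volume_image(a, bit_depth = bit_depth)
}

#' Write a 3D volume to TIFF or NRRD
#'
#' TIFF output is multi-page grayscale, 8-bit for 8-bit volumes and 16-bit
#' otherwise (12-bit data is stored as its raw values in a 16-bit
#' container). NRRD output uses ascii encoding by default.
#'
#' @param volume a [volume_image()] or a bare integer array (e.g. a BRS
#'   field's values, written 16-bit).
#' @param path destination file (`.tif`/`.tiff` or `.nrrd`).
#' @param encoding NRRD encoding, `"ascii"` or `"raw"`.
#' @export
write_volume <- function(volume, path, encoding = "ascii") {
  a <- if (inherits(volume, "volume_image")) volume$data else volume
  bits <- if (max(a) > 255L) 16L else 8L
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    tif = , tiff = write_tiff_volume(a, path, bits),
    nrrd = write_nrrd(a, path, bits, encoding),
    stop("unsupported output format: .", ext)
  )
  invisible(path)
}

read_tiff_volume <- function(path) {
  pages <- tiff::readTIFF(path, as.is = TRUE, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (any(vapply(pages, function(p) length(dim(p)) != 2L, logical(1))))
    stop("multi-channel TIFF not supported; extract one channel first")
  d <- dim(pages[[1L]])
  if (!all(vapply(pages, function(p) identical(dim(p), d), logical(1))))
    stop("TIFF pages have inconsistent dimensions")
  a <- array(0L, c(length(pages), d[1L], d[2L]))
  for (z in seq_along(pages)) a[z, , ] <- pages[[z]]
  a
}

write_tiff_volume <- function(a, path, bits) {
  scale <- 2^bits - 1
  pages <- lapply(seq_len(dim(a)[1L]), function(z)
    a[z, , ] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = bits)
  invisible(path)
}

# Minimal NRRD: 3D scalar, ascii or little-endian raw, uchar/ushort.
# Sizes are written fastest-axis-first in this package's (z, y, x) memory
# order.
read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!startsWith(magic, "NRRD")) stop("not an NRRD file")
  fields <- list()
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L || line == "") break
    if (startsWith(line, "#")) next
    kv <- strsplit(line, ":\\s*")[[1L]]
    fields[[tolower(kv[1L])]] <- kv[2L]
  }
  sizes <- as.integer(strsplit(fields$sizes, "\\s+")[[1L]])
  if (!identical(as.integer(fields$dimension), 3L) || length(sizes) != 3L)
    stop("only 3D NRRD volumes are supported")
  n <- prod(sizes)
  type <- fields$type
  enc <- fields$encoding
  vals <- if (enc == "ascii") {
    scan(con, what = integer(), n = n, quiet = TRUE)
  } else if (enc == "raw") {
    sz <- if (type %in% c("uchar", "unsigned char", "uint8")) 1L else 2L
    readBin(con, "integer", n = n, size = sz, signed = FALSE,
            endian = "little")
  } else stop("unsupported NRRD encoding: ", enc)
  if (length(vals) != n) stop("NRRD data shorter than header sizes")
  array(as.integer(vals), sizes)
}

write_nrrd <- function(a, path, bits, encoding = "ascii") {
  type <- if (bits <= 8L) "uchar" else "ushort"
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c("NRRD0004",
           paste0("type: ", type),
           "dimension: 3",
           paste0("sizes: ", paste(dim(a), collapse = " ")),
           paste0("encoding: ", encoding),
           if (encoding == "raw") "endian: little",
           "")
  writeLines(hdr, con)
  if (encoding == "ascii") {
    writeLines(paste(as.integer(a), collapse = " "), con)
  } else {
    writeBin(as.integer(a), con, size = if (bits <= 8L) 1L else 2L,
             endian = "little")
  }
  invisible(path)
}

# Avizo AmiraMesh ASCII uniform lattice, single scalar data section.
read_avizo_am <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!grepl("AmiraMesh", lines[1L]))
    stop("not an AmiraMesh (.am) file")
  if (grepl("BINARY", lines[1L], ignore.case = TRUE))
    stop("binary/RLE AmiraMesh encoding not supported; export as 3D ASCII")
  defl <- grep("^\\s*define\\s+Lattice\\s+", lines, value = TRUE)
  if (length(defl) == 0L) stop("no 'define Lattice' in .am file")
  sizes <- as.integer(strsplit(trimws(sub(".*define\\s+Lattice", "",
                                          defl[1L])), "\\s+")[[1L]])
  if (length(sizes) != 3L) stop(".am lattice is not 3D")
  if (!any(grepl("Lattice\\s*\\{\\s*(byte|ushort|short|float)\\s+Data",
                 lines)))
    stop("no scalar 'Lattice { <type> Data }' declaration in .am file")
  at <- grep("^\\s*@1\\s*$", lines)
  if (length(at) == 0L) stop("no @1 data section in .am file")
  data_lines <- lines[(at[length(at)] + 1L):length(lines)]
  data_lines <- data_lines[!grepl("^\\s*(@|$)", data_lines)]
  vals <- as.numeric(unlist(strsplit(trimws(data_lines), "\\s+")))
  n <- prod(sizes)
  if (length(vals) < n) stop(".am data section shorter than the lattice")
  # Avizo stores x fastest; repack into this package's (z, y, x) layout
  a <- array(as.integer(vals[seq_len(n)]), sizes)  # (x, y, z)
  aperm(a, c(3L, 2L, 1L))
}
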