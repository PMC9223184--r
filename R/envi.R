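# ENVI-style cube I/O: a plain-text header (.hdr) describing dimensions,
# interleave and the wavelength axis, next to a flat binary of 32-bit floats.
# Cubes are written band-sequential (BSQ); BIL and BIP are converted on read.

#' Write a hypercube as ENVI header + binary
#'
#' @param cube a [hypercube].
#' @param path base path; `.hdr` and `.dat` are appended.
#' @return Invisibly, the two file paths.
#' @export
write_cube <- function(cube, path) {
  stopifnot(inherits(cube, "hypercube"))
  d <- dim(cube$values)
  hdr <- c(
    "ENVI",
    "description = {maizemold hypercube}",
    paste0("samples = ", d[2]),
    paste0("lines = ", d[1]),
    paste0("bands = ", d[3]),
    "header offset = 0",
    "file type = ENVI Standard",
    "data type = 4",
    "interleave = bsq",
    "byte order = 0",
    paste0("sensor type = ", cube$sensor),
    paste0("calibrated = ", as.integer(cube$calibrated)),
    paste0("wavelength units = nm"),
    paste0("wavelength = {", paste(format(cube$wavelengths, trim = TRUE),
                                   collapse = ", "), "}"))
  hdr_path <- paste0(path, ".hdr")
  dat_path <- paste0(path, ".dat")
  writeLines(hdr, hdr_path)
  # BSQ: band-major; within a band ENVI stores line by line (line = image
  # row, sample = column), so each band is written transposed
  con <- file(dat_path, "wb")
  on.exit(close(con))
  for (b in seq_len(d[3]))
    writeBin(as.numeric(t(cube$values[, , b])), con, size = 4)
  invisible(c(hdr_path, dat_path))
}

# internal: parse an ENVI header into a named list of strings; multi-line
# { ... } blocks are joined before key = value splitting
parse_envi_header <- function(hdr_path) {
  txt <- paste(readLines(hdr_path, warn = FALSE), collapse = "\n")
  # collapse newlines inside { } blocks so each key = value is one line
  while (grepl("\\{[^}]*\n", txt))
    txt <- sub("(\\{[^}]*)\n", "\\1 ", txt)
  res <- list()
  for (ln in strsplit(txt, "\n")[[1]]) {
    if (!grepl("=", ln)) next
    key <- tolower(trimws(sub("=.*$", "", ln)))
    val <- trimws(sub("^[^=]+=", "", ln))
    res[[key]] <- val
  }
  res
}

#' Read an ENVI header + binary cube
#'
#' Requires the `samples`, `lines`, `bands` and `wavelength` header fields;
#' accepts BSQ, BIL or BIP interleave (converted to the in-memory
#' height x width x bands layout) and 32- or 64-bit float data.
#'
#' @param path base path (as given to [write_cube()]) or the `.hdr` path.
#' @return A [hypercube].
#' @export
read_cube <- function(path) {
  hdr_path <- if (grepl("\\.hdr$", path)) path else paste0(path, ".hdr")
  dat_path <- sub("\\.hdr$", ".dat", hdr_path)
  if (!file.exists(hdr_path)) stop("missing header: ", hdr_path)
  h <- parse_envi_header(hdr_path)
  need <- c("samples", "lines", "bands")
  if (!all(need %in% names(h)))
    stop("malformed header: need samples/lines/bands")
  w <- as.integer(h[["samples"]]); ht <- as.integer(h[["lines"]])
  B <- as.integer(h[["bands"]])
  if (is.null(h[["wavelength"]]))
    stop("malformed header: missing wavelength block")
  wl <- as.numeric(strsplit(gsub("[{}]", "", h[["wavelength"]]), ",")[[1]])
  if (length(wl) != B)
    stop("wavelength count (", length(wl), ") does not match bands (", B, ")")
  dtype <- if (is.null(h[["data type"]])) 4L else as.integer(h[["data type"]])
  size <- switch(as.character(dtype), "4" = 4L, "5" = 8L,
                 stop("unsupported ENVI data type: ", dtype))
  interleave <- tolower(if (is.null(h[["interleave"]])) "bsq"
                        else h[["interleave"]])
  vals <- readBin(dat_path, "numeric", n = w * ht * B, size = size)
  if (length(vals) != w * ht * B) stop("binary size does not match header")
  arr <- array(NA_real_, dim = c(ht, w, B))
  if (interleave == "bsq") {
    a <- array(vals, dim = c(w, ht, B))     # sample fastest, then line
    arr <- aperm(a, c(2, 1, 3))
  } else if (interleave == "bil") {
    a <- array(vals, dim = c(w, B, ht))     # sample, band, line
    arr <- aperm(a, c(3, 1, 2))
  } else if (interleave == "bip") {
    a <- array(vals, dim = c(B, w, ht))     # band fastest
    arr <- aperm(a, c(3, 2, 1))
  } else stop("unsupported interleave: ", interleave)
  sensor <- if (!is.null(h[["sensor type"]]) &&
                grepl("LWNIR", h[["sensor type"]])) "LWNIR" else "VIS_SWNIR"
  calibrated <- !is.null(h[["calibrated"]]) && h[["calibrated"]] == "1"
  hypercube(arr, wl, sensor, calibrated = calibrated)
}
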