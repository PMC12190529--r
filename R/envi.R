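#' Write / read a hypercube in ENVI format
#'
#' Minimal ENVI support: a text `.hdr` alongside a raw little-endian
#' 32-bit float binary, band-sequential (BSQ), with the wavelength list in
#' the header. Enough for exchange with the common hyperspectral viewers.
#'
#' @param cube A `hypercube`.
#' @param path Path without extension; `.hdr` and `.dat` are appended.
#' @export
write_envi <- function(cube, path) {
  stopifnot(inherits(cube, "hypercube"))
  d <- dim(cube$values)
  hdr <- c(
    "ENVI",
    "description = {reflectance hypercube}",
    sprintf("samples = %d", d[2]),
    sprintf("lines = %d", d[1]),
    sprintf("bands = %d", d[3]),
    "header offset = 0",
    "file type = ENVI Standard",
    "data type = 4",
    "interleave = bsq",
    "byte order = 0",
    "wavelength units = Nanometers",
    sprintf("wavelength = {%s}",
            paste(format(wavelengths(cube$grid), trim = TRUE), collapse = ", "))
  )
  writeLines(hdr, paste0(path, ".hdr"))
  con <- file(paste0(path, ".dat"), "wb")
  on.exit(close(con))
  # BSQ: band-major, row-major within band
  v <- aperm(cube$values, c(2, 1, 3))
  writeBin(as.vector(v), con, size = 4, endian = "little")
  invisible(path)
}

#' @rdname write_envi
#' @export
read_envi <- function(path) {
  hdr <- readLines(paste0(path, ".hdr"))
  getv <- function(key) {
    ln <- grep(sprintf("^%s\\s*=", key), hdr, value = TRUE)
    if (!length(ln)) rlang::abort(sprintf("ENVI header missing '%s'", key))
    trimws(sub("^[^=]*=", "", ln[1]))
  }
  samples <- as.integer(getv("samples"))
  lines <- as.integer(getv("lines"))
  bands <- as.integer(getv("bands"))
  if (getv("interleave") != "bsq" || getv("data type") != "4") {
    rlang::abort("only BSQ float32 ENVI files are supported")
  }
  wl_line <- paste(hdr[grep("wavelength = \\{", hdr):length(hdr)], collapse = " ")
  wl <- as.numeric(strsplit(gsub(".*\\{|\\}.*", "", wl_line), ",")[[1]])
  con <- file(paste0(path, ".dat"), "rb")
  on.exit(close(con))
  v <- readBin(con, "numeric", n = samples * lines * bands, size = 4,
               endian = "little")
  arr <- aperm(array(v, dim = c(samples, lines, bands)), c(2, 1, 3))
  step <- unique(round(diff(wl), 9))
  grid <- spectral_grid(min(wl), max(wl), step[1])
  structure(list(values = arr, grid = grid, n_clamped = 0L),
            class = "hypercube")
}
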