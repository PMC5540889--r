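#' Raw hyperspectral image cube
#'
#' A 3-D array of 16-bit digital numbers (DN) indexed `[line, sample, band]`
#' together with its wavelength grid, chamber geometry, and scan role. The
#' role distinguishes plant scans from the blank-chamber reference scans
#' acquired immediately after each plant; reference scans divide out the lamp
#' spectrum and illumination non-uniformity during normalization.
#'
#' @param values numeric or integer 3-D array, dimensions
#'   `c(n_lines, n_samples, n_bands)`, all values integers in `[0, 65535]`.
#' @param grid a [build_wavelength_grid()] result matching the third dimension.
#' @param geometry a [cube_geometry()] matching the first two dimensions.
#' @param role `"plant-scan"` or `"reference-scan"`.
#' @return A `raw_cube` object.
#' @export
raw_cube <- function(values, grid, geometry, role = c("plant-scan", "reference-scan")) {
  role <- match.arg(role)
  validate_grid(grid)
  stopifnot(inherits(geometry, "cube_geometry"))
  if (!is.array(values) || length(dim(values)) != 3L) {
    stop("values must be a 3-D array [line, sample, band]", call. = FALSE)
  }
  d <- dim(values)
  if (d[1L] != geometry$n_lines || d[2L] != geometry$n_samples || d[3L] != grid$n_bands) {
    stop(sprintf(
      "cube shape %dx%dx%d inconsistent with geometry %dx%d and %d bands",
      d[1L], d[2L], d[3L], geometry$n_lines, geometry$n_samples, grid$n_bands
    ), call. = FALSE)
  }
  if (anyNA(values) || min(values) < 0 || max(values) > 65535 ||
      any(values != trunc(values))) {
    stop("intensities must be integers representable in 16 bits (0..65535)",
         call. = FALSE)
  }
  structure(
    list(values = values, grid = grid, geometry = geometry, role = role),
    class = "raw_cube"
  )
}

#' @export
print.raw_cube <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<raw_cube> %s, %d lines x %d samples x %d bands\n",
              x$role, d[1L], d[2L], d[3L]))
  invisible(x)
}

# ---- ENVI header ----------------------------------------------------------

#' Read a minimal ENVI text header
#'
#' Parses the `key = value` sidecar that accompanies a BIL payload. Values in
#' `{braces}` may span lines (the wavelength list does). Keys this package
#' does not interpret are preserved verbatim in `$extra` and written back by
#' [write_envi_header()].
#'
#' @param path path to the `.hdr` file.
#' @return Named list with canonical fields (`samples`, `lines`, `bands`,
#'   `interleave`, `data_type`, `byte_order`, `wavelength`, `scan_role`,
#'   `pixel_size_mm`) plus `extra`.
#' @export
read_envi_header <- function(path) {
  if (!file.exists(path)) stop("header file not found: ", path, call. = FALSE)
  txt <- readLines(path, warn = FALSE)
  if (length(txt) == 0L || !grepl("^\\s*ENVI\\s*$", txt[1L])) {
    stop("not an ENVI header (missing ENVI magic line): ", path, call. = FALSE)
  }
  # merge continuation lines of brace-delimited values, then parse key = value
  lines <- txt[-1L]
  merged <- character(0)
  buf <- ""
  for (ln in lines) {
    buf <- if (nzchar(buf)) paste(buf, ln) else ln
    n_open <- lengths(regmatches(buf, gregexpr("\\{", buf)))
    n_close <- lengths(regmatches(buf, gregexpr("\\}", buf)))
    if (n_open == n_close) {
      if (nzchar(trimws(buf))) merged <- c(merged, buf)
      buf <- ""
    }
  }
  if (nzchar(trimws(buf))) merged <- c(merged, buf)
  entries <- list()
  for (ln in merged) {
    eq <- regexpr("=", ln, fixed = TRUE)
    if (eq == -1L) next
    key <- tolower(trimws(substr(ln, 1L, eq - 1L)))
    val <- trimws(substr(ln, eq + 1L, nchar(ln)))
    entries[[key]] <- val
  }
  if (!length(entries)) stop("empty ENVI header: ", path, call. = FALSE)
  num <- function(k) if (!is.null(entries[[k]])) as.numeric(entries[[k]]) else NULL
  parse_braces <- function(v) {
    v <- gsub("[{}]", "", v)
    as.numeric(strsplit(v, ",")[[1L]])
  }
  known <- c("samples", "lines", "bands", "interleave", "data type",
             "byte order", "wavelength", "scan role", "pixel size mm",
             "header offset")
  hdr <- list(
    samples = as.integer(num("samples")),
    lines = as.integer(num("lines")),
    bands = as.integer(num("bands")),
    interleave = tolower(entries[["interleave"]] %||% ""),
    data_type = as.integer(num("data type")),
    byte_order = as.integer(num("byte order") %||% 0),
    wavelength = if (!is.null(entries[["wavelength"]])) parse_braces(entries[["wavelength"]]) else NULL,
    scan_role = entries[["scan role"]] %||% "plant-scan",
    pixel_size_mm = num("pixel size mm") %||% 5,
    extra = entries[setdiff(names(entries), known)]
  )
  for (f in c("samples", "lines", "bands")) {
    if (is.null(hdr[[f]]) || is.na(hdr[[f]])) {
      stop("ENVI header missing required field: ", f, call. = FALSE)
    }
  }
  hdr
}

#' Write a minimal ENVI text header
#' @param hdr header list as returned by [read_envi_header()].
#' @param path output `.hdr` path.
#' @return `path`, invisibly.
#' @export
write_envi_header <- function(hdr, path) {
  wl <- paste(formatC(hdr$wavelength, format = "fg", digits = 15), collapse = ", ")
  lines <- c(
    "ENVI",
    paste0("samples = ", hdr$samples),
    paste0("lines = ", hdr$lines),
    paste0("bands = ", hdr$bands),
    "header offset = 0",
    "file type = ENVI Standard",
    paste0("data type = ", hdr$data_type %||% 12L),
    paste0("interleave = ", hdr$interleave %||% "bil"),
    paste0("byte order = ", hdr$byte_order %||% 0L),
    paste0("scan role = ", hdr$scan_role %||% "plant-scan"),
    paste0("pixel size mm = ", format(hdr$pixel_size_mm %||% 5)),
    paste0("wavelength = {", wl, "}")
  )
  if (length(hdr$extra)) {
    lines <- c(lines, vapply(names(hdr$extra),
                             function(k) paste0(k, " = ", hdr$extra[[k]]),
                             character(1L)))
  }
  writeLines(lines, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

hdr_path_for <- function(data_path) paste0(tools::file_path_sans_ext(data_path), ".hdr")

# ---- BIL payload ----------------------------------------------------------

#' Read a BIL hyperspectral cube
#'
#' Reads a 16-bit unsigned band-interleaved-by-line payload described by its
#' ENVI-style header into a [raw_cube()]. BIL stores, for each scan line, all
#' samples of band 1, then all samples of band 2, and so on.
#'
#' @param data_path path to the `.bil` payload.
#' @param header parsed header list, or `NULL` to read `<data_path>.hdr`.
#' @return A [raw_cube()] indexed `[line, sample, band]`.
#' @export
read_bil <- function(data_path, header = NULL) {
  if (is.null(header)) header <- read_envi_header(hdr_path_for(data_path))
  if (!identical(header$interleave, "bil")) {
    stop("unsupported interleave '", header$interleave, "': only BIL is supported",
         call. = FALSE)
  }
  if (!identical(header$data_type, 12L)) {
    stop("unsupported data type ", header$data_type,
         ": only 16-bit unsigned (ENVI type 12) is supported", call. = FALSE)
  }
  n_vox <- as.double(header$lines) * header$samples * header$bands
  expected_bytes <- 2 * n_vox
  actual_bytes <- file.size(data_path)
  if (is.na(actual_bytes) || actual_bytes != expected_bytes) {
    stop(sprintf(
      "corrupt BIL file: header declares %d x %d x %d (%.0f bytes) but payload has %.0f bytes",
      header$lines, header$samples, header$bands, expected_bytes,
      if (is.na(actual_bytes)) 0 else actual_bytes
    ), call. = FALSE)
  }
  endian <- if (identical(header$byte_order, 1L)) "big" else "little"
  con <- file(data_path, "rb")
  on.exit(close(con))
  raw_vals <- readBin(con, what = "integer", n = n_vox, size = 2L,
                      signed = FALSE, endian = endian)
  # payload order: sample fastest, then band, then line
  arr <- array(as.double(raw_vals),
               dim = c(header$samples, header$bands, header$lines))
  values <- aperm(arr, c(3L, 1L, 2L))
  wl <- header$wavelength
  if (is.null(wl)) {
    stop("ENVI header lacks a wavelength list", call. = FALSE)
  }
  grid <- build_wavelength_grid(wl[1L], wl[length(wl)], length(wl))
  geometry <- cube_geometry(header$lines, header$samples, header$pixel_size_mm)
  role <- if (identical(header$scan_role, "reference-scan")) "reference-scan" else "plant-scan"
  raw_cube(values, grid, geometry, role)
}

#' Write a BIL hyperspectral cube
#'
#' Writes the payload and its ENVI-style header; `read_bil()` of the result
#' reproduces the cube bit-exactly (values, grid, geometry, role).
#'
#' @param cube a [raw_cube()].
#' @param data_path output `.bil` path; the header goes to the matching `.hdr`.
#' @return `data_path`, invisibly.
#' @export
write_bil <- function(cube, data_path) {
  stopifnot(inherits(cube, "raw_cube"))
  v <- cube$values
  if (min(v) < 0 || max(v) > 65535) {
    stop("intensity outside the 16-bit range", call. = FALSE)
  }
  d <- dim(v)
  hdr <- list(
    samples = d[2L], lines = d[1L], bands = d[3L],
    interleave = "bil", data_type = 12L, byte_order = 0L,
    wavelength = cube$grid$band_centers_nm,
    scan_role = cube$role,
    pixel_size_mm = cube$geometry$pixel_size_mm,
    extra = list()
  )
  write_envi_header(hdr, hdr_path_for(data_path))
  payload <- aperm(v, c(2L, 3L, 1L)) # sample fastest, then band, then line
  con <- file(data_path, "wb")
  on.exit(close(con))
  writeBin(as.integer(payload), con, size = 2L, endian = "little")
  invisible(data_path)
}
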