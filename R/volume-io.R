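#' Read a 3-D attenuation volume
#'
#' Supports NRRD (`.nrrd`, self-describing, lossless) and multi-page TIFF
#' stacks (`.tif`/`.tiff`, one image per z slice, 32-bit float). TIFF carries
#' no spacing metadata, so `spacing` must be supplied when reading TIFF.
#'
#' @param path file path.
#' @param format `"nrrd"`, `"tiff"`, or `NULL` to infer from the extension.
#' @param spacing voxel spacing, required for TIFF input.
#' @return A [voxel_volume()].
#' @export
read_volume <- function(path, format = NULL, spacing = NULL) {
  if (!file.exists(path)) of_abort(sprintf("file not found: %s", path))
  format <- format %||% infer_volume_format(path)
  switch(format,
    nrrd = read_nrrd(path),
    tiff = {
      if (is.null(spacing))
        of_abort(paste0("TIFF stacks carry no spacing metadata; pass ",
                        "`spacing = <voxel edge length>` to read_volume(), ",
                        "or use NRRD which stores spacing in its header"))
      slices <- tiff::readTIFF(path, all = TRUE)
      if (!is.list(slices)) slices <- list(slices)
      d <- dim(slices[[1]])
      data <- array(0, c(d[1], d[2], length(slices)))
      for (k in seq_along(slices)) data[, , k] <- slices[[k]]
      voxel_volume(data, spacing)
    },
    of_abort(sprintf("unsupported volume format: %s", format))
  )
}

#' Write a 3-D attenuation volume
#'
#' NRRD round-trips doubles bit-exactly (raw little-endian encoding). TIFF
#' writes one 32-bit page per z slice and requires values in `[0, 1]`
#' (samples quantized at 32-bit precision); rescale first or use NRRD for
#' unbounded attenuation values.
#'
#' @param volume a [voxel_volume()].
#' @param path output path.
#' @param format `"nrrd"`, `"tiff"`, or `NULL` to infer from the extension.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path, format = NULL) {
  stopifnot(inherits(volume, "voxel_volume"))
  format <- format %||% infer_volume_format(path)
  switch(format,
    nrrd = write_nrrd(volume, path),
    tiff = {
      if (min(volume$data) < 0 || max(volume$data) > 1)
        of_abort(paste0("TIFF output stores 32-bit floats in [0, 1]; ",
                        "rescale the volume or write NRRD instead"))
      slices <- lapply(seq_len(dim(volume$data)[3]),
                       function(k) volume$data[, , k])
      tiff::writeTIFF(slices, path, bits.per.sample = 32L)
    },
    of_abort(sprintf("unsupported volume format: %s", format))
  )
  invisible(path)
}

infer_volume_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    nrrd = "nrrd",
    tif = "tiff",
    tiff = "tiff",
    of_abort(sprintf("cannot infer volume format from extension '.%s'", ext))
  )
}

# --- minimal NRRD0004 reader/writer ----------------------------------------
# Raw little-endian doubles by default; ascii ("text") encoding also read.
# Only 3-D volumes with isotropic spacing are accepted, per the container's
# invariants.

write_nrrd <- function(volume, path, encoding = c("raw", "ascii")) {
  encoding <- match.arg(encoding)
  d <- dim(volume$data)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c(
    "NRRD0004",
    "# osteoflow voxel volume",
    "type: double",
    "dimension: 3",
    sprintf("sizes: %d %d %d", d[1], d[2], d[3]),
    sprintf("spacings: %.17g %.17g %.17g",
            volume$spacing, volume$spacing, volume$spacing),
    "endian: little",
    sprintf("encoding: %s", encoding),
    ""
  )
  writeLines(hdr, con, sep = "\n")
  if (encoding == "raw") {
    writeBin(as.numeric(volume$data), con, size = 8L, endian = "little")
  } else {
    writeLines(paste(sprintf("%.17g", as.numeric(volume$data)),
                     collapse = " "), con)
  }
  invisible(path)
}

read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!grepl("^NRRD", magic))
    of_abort(sprintf("%s is not an NRRD file", path))
  fields <- list()
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L)
      of_abort("unexpected end of NRRD header")
    if (line == "") break
    if (grepl("^#", line)) next
    kv <- regmatches(line, regexec("^([^:]+): *(.*)$", line))[[1]]
    if (length(kv) == 3L) fields[[trimws(kv[2])]] <- trimws(kv[3])
  }
  need <- function(key, hint) {
    if (is.null(fields[[key]]))
      of_abort(sprintf("NRRD header missing '%s'; %s", key, hint))
    fields[[key]]
  }
  dimension <- as.integer(need("dimension", "expected a 3-D volume"))
  if (dimension != 3L) of_abort("only 3-D NRRD volumes are supported")
  sizes <- as.integer(strsplit(need("sizes", "voxel counts required"),
                               "\\s+")[[1]])
  spacing <- nrrd_spacing(fields)
  type <- need("type", "expected 'double' or 'float'")
  encoding <- need("encoding", "expected 'raw' or 'ascii'")
  n <- prod(sizes)
  vals <- switch(encoding,
    raw = {
      endian <- fields[["endian"]] %||% "little"
      size <- switch(type, double = 8L, float = 4L,
                     of_abort(sprintf("unsupported NRRD type: %s", type)))
      readBin(con, "numeric", n = n, size = size, endian = endian)
    },
    ascii = ,
    text = as.numeric(scan(con, what = numeric(), n = n, quiet = TRUE)),
    of_abort(sprintf("unsupported NRRD encoding: %s", encoding))
  )
  voxel_volume(array(vals, dim = sizes), spacing)
}

nrrd_spacing <- function(fields) {
  if (!is.null(fields[["spacings"]])) {
    sp <- as.numeric(strsplit(fields[["spacings"]], "\\s+")[[1]])
  } else if (!is.null(fields[["space directions"]])) {
    rows <- regmatches(fields[["space directions"]],
                       gregexpr("\\(([^)]*)\\)", fields[["space directions"]]))[[1]]
    mat <- t(vapply(rows, function(r) {
      as.numeric(strsplit(gsub("[()]", "", r), ",")[[1]])
    }, numeric(3)))
    sp <- sqrt(rowSums(mat^2))
  } else {
    of_abort(paste0("NRRD header has no spacing information; add a ",
                    "'spacings: s s s' field with the voxel edge length"))
  }
  if (length(unique(signif(sp, 12))) != 1L)
    of_abort(sprintf(
      "anisotropic voxel spacing (%s) is not supported; resample to isotropic voxels first",
      paste(signif(sp, 6), collapse = " x ")))
  sp[1]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
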