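#' Write a label mask to disk
#'
#' Indexed 8-bit PNG is the canonical interchange format (one file per
#' frame); because PNG carries no reliable physical-units field, the pixel
#' spacing is written to a YAML sidecar \code{<path>.yaml}. Uncompressed
#' NIfTI-1 (\code{.nii}) is supported as an alternative that stores the
#' spacing in its own header.
#'
#' @param frame an [oct_frame()].
#' @param path output path; format chosen by extension (\code{.png} or
#'   \code{.nii}).
#' @return \code{path}, invisibly.
#' @export
write_mask <- function(frame, path) {
  stopifnot(inherits(frame, "oct_frame"))
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(frame$labels / 255, target = path)
    yaml::write_yaml(list(spacing_mm = frame$geometry$spacing_mm,
                          frame_index = frame$frame_index),
                     paste0(path, ".yaml"))
  } else if (ext == "nii") {
    .write_nifti1(frame$labels, frame$geometry$spacing_mm, path)
  } else {
    stop("FormatError: unsupported mask extension '", ext, "'",
         call. = FALSE)
  }
  invisible(path)
}

#' Read a label mask from disk
#'
#' Reads indexed PNG (spacing from the YAML sidecar unless given
#' explicitly) or uncompressed NIfTI-1 (spacing from the header; anisotropic
#' spacing is rejected). Labels are validated against the ten-class schema.
#'
#' @param path mask file (\code{.png} or \code{.nii}).
#' @param spacing_mm pixel spacing override; required for PNG when no
#'   sidecar exists.
#' @param frame_index ordinal stored in the frame (default from sidecar or
#'   1).
#' @return an [oct_frame()].
#' @export
read_mask <- function(path, spacing_mm = NULL, frame_index = NULL) {
  if (!file.exists(path)) {
    stop("FormatError: no such file: ", path, call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    img <- png::readPNG(path)
    if (length(dim(img)) == 3L) img <- img[, , 1L]
    labels <- matrix(as.integer(round(img * 255)), nrow(img), ncol(img))
    sidecar <- paste0(path, ".yaml")
    if (is.null(spacing_mm)) {
      if (!file.exists(sidecar)) {
        stop("MissingSpacingError: no spacing_mm given and no sidecar ",
             sidecar, call. = FALSE)
      }
      meta <- yaml::read_yaml(sidecar)
      spacing_mm <- meta$spacing_mm
      if (is.null(frame_index)) frame_index <- meta$frame_index
    }
  } else if (ext == "nii") {
    nb <- .read_nifti1(path)
    labels <- nb$data
    if (is.null(spacing_mm)) spacing_mm <- nb$spacing_mm
  } else {
    stop("FormatError: unsupported mask extension '", ext, "'",
         call. = FALSE)
  }
  if (is.null(frame_index)) frame_index <- 1L
  if (any(labels < 0L | labels > 9L)) {
    bad <- unique(labels[labels < 0L | labels > 9L])
    stop("UnknownLabelError: values outside 0..9: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  oct_frame(labels, spacing_mm = spacing_mm, frame_index = frame_index)
}

# --- minimal uncompressed NIfTI-1 (.nii, int16, single 2D slice) ---------
# No NIfTI R package is assumed; only the fields this package needs are
# written/parsed. Data are stored column-major exactly as the R matrix.

.write_nifti1 <- function(labels, spacing_mm, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size,
                                   endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4L,
                             endian = "little")
  wi(348L, 4L)                               # sizeof_hdr
  writeBin(raw(36L), con)                    # unused data_type..dim_info
  wi(c(2L, nrow(labels), ncol(labels), 1L, 1L, 1L, 1L, 1L), 2L)  # dim[8]
  writeBin(raw(14L), con)                    # intent_p1..intent_code
  wi(4L, 2L)                                 # datatype = int16
  wi(16L, 2L)                                # bitpix
  wi(0L, 2L)                                 # slice_start
  wf(c(1, spacing_mm, spacing_mm, 1, 1, 1, 1, 1))                # pixdim[8]
  wf(352)                                    # vox_offset
  wf(c(1, 0))                                # scl_slope, scl_inter
  writeBin(raw(224L), con)                   # pad to magic at offset 344
  writeBin(c(charToRaw("n+1"), as.raw(0L)), con)
  writeBin(raw(4L), con)                     # extension indicator
  writeBin(as.integer(labels), con, size = 2L, endian = "little")
  invisible(path)
}

.read_nifti1 <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 352L)
  ri <- function(off, size, n = 1L) {
    readBin(hdr[(off + 1L):(off + size * n)], "integer", n = n, size = size,
            endian = "little")
  }
  rf <- function(off, n = 1L) {
    readBin(hdr[(off + 1L):(off + 4L * n)], "numeric", n = n, size = 4L,
            endian = "little")
  }
  if (ri(0L, 4L) != 348L || rawToChar(hdr[345:347]) != "n+1") {
    stop("FormatError: not an uncompressed NIfTI-1 file", call. = FALSE)
  }
  dims <- ri(40L, 2L, 8L)
  nr <- dims[2L]; nc <- dims[3L]
  datatype <- ri(70L, 2L)
  pixdim <- rf(76L, 8L)
  if (abs(pixdim[2L] - pixdim[3L]) > 1e-6 * pixdim[2L]) {
    stop("MissingSpacingError: anisotropic pixel spacing is not supported",
         call. = FALSE)
  }
  size <- switch(as.character(datatype), "2" = 1L, "4" = 2L, "8" = 4L,
                 stop("FormatError: unsupported NIfTI datatype ", datatype,
                      call. = FALSE))
  vals <- readBin(con, "integer", n = nr * nc, size = size,
                  endian = "little", signed = size > 1L)
  list(data = matrix(vals, nr, nc), spacing_mm = pixdim[2L])
}

#' Write a per-frame metrics report
#'
#' Deterministic column order and fixed numeric precision so that reruns
#' under the same configuration are byte-identical: arcs to 0.1 degree,
#' micrometre measures to 0.1 um, areas to 1e-4 mm^2, ratios to 1e-6, scores
#' to 3 decimals.
#'
#' @param rows non-empty data.frame (e.g. from [quantify_pullback()]).
#' @param path output path.
#' @param format \code{"csv"} or \code{"json"}.
#' @return \code{path}, invisibly.
#' @export
write_report <- function(rows, path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (!is.data.frame(rows) || nrow(rows) == 0L) {
    stop("IOError: report rows must be a non-empty data.frame",
         call. = FALSE)
  }
  digits_for <- function(name) {
    if (grepl("_deg$", name)) return(1L)
    if (grepl("_um$", name)) return(1L)
    if (grepl("_mm2_per_deg$", name)) return(6L)
    if (grepl("_mm2$", name)) return(4L)
    if (grepl("score|dice|kappa|icc|estimate|ci_", name)) return(3L)
    NA_integer_
  }
  for (nm in names(rows)) {
    d <- digits_for(nm)
    if (!is.na(d) && is.numeric(rows[[nm]])) rows[[nm]] <- round(rows[[nm]], d)
  }
  if (format == "csv") {
    write.csv(rows, path, row.names = FALSE)
  } else {
    jsonlite::write_json(rows, path, auto_unbox = TRUE, digits = NA,
                         na = "null", pretty = TRUE)
  }
  invisible(path)
}

#' Read a phantom specification from a YAML or JSON config file
#'
#' The config mirrors the [phantom_spec()] arguments; \code{sectors} is a
#' list of records with the [plaque_sector()] fields. See
#' \code{system.file("extdata", "phantom_example.yaml", package =
#' "octquant")} for a template.
#'
#' @param path config file (\code{.yaml}/\code{.yml}/\code{.json}).
#' @return a [phantom_spec()].
#' @export
read_phantom_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("FormatError: config must be YAML or JSON", call. = FALSE)
  }
  sectors <- lapply(cfg$sectors, function(s) {
    plaque_sector(s$plaque_class, s$theta_start_deg, s$extent_deg,
                  s$cap_thickness_mm, s$plaque_thickness_mm)
  })
  phantom_spec(
    spacing_mm = cfg$spacing_mm %||% 0.01,
    frame_shape = unlist(cfg$frame_shape %||% c(448L, 448L)),
    lumen_center_px = if (!is.null(cfg$lumen_center_px))
      unlist(cfg$lumen_center_px) else NULL,
    lumen_radius_mm = cfg$lumen_radius_mm %||% 1.0,
    intima_thickness_mm = cfg$intima_thickness_mm %||% 0.2,
    media_thickness_mm = cfg$media_thickness_mm %||% 0.1,
    sectors = sectors,
    guidewire = if (!is.null(cfg$guidewire)) unlist(cfg$guidewire) else NULL,
    side_branch = if (!is.null(cfg$side_branch))
      unlist(cfg$side_branch) else NULL,
    speckle = cfg$speckle,
    seed = cfg$seed %||% 1L
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
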