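#' Pixel geometry of an OCT cross-section
#'
#' Isotropic pixel spacing in millimetres plus the frame shape. Anisotropic
#' spacing is rejected at construction: all quantification assumes square
#' pixels, which holds for Cartesian OCT exports.
#'
#' @param spacing_mm physical edge length of one pixel in mm (> 0).
#' @param frame_shape integer vector \code{c(rows, cols)}, each >= 32.
#' @return object of class \code{pixel_geometry}.
#' @export
pixel_geometry <- function(spacing_mm, frame_shape) {
  stopifnot(is.numeric(spacing_mm), length(spacing_mm) == 1L, spacing_mm > 0)
  frame_shape <- as.integer(frame_shape)
  stopifnot(length(frame_shape) == 2L, all(frame_shape >= 32L))
  structure(
    list(spacing_mm = as.numeric(spacing_mm), frame_shape = frame_shape),
    class = "pixel_geometry"
  )
}

#' A single OCT cross-sectional label frame
#'
#' The universal currency of the pipeline: a 2D integer matrix of class codes
#' (see [label_schema()]) with its pixel geometry. Pixel coordinates are
#' (row, col), 1-based as usual in R, with pixel centers at integer
#' coordinates.
#'
#' @param labels integer matrix of class codes.
#' @param geometry a [pixel_geometry()]; when missing, built from
#'   \code{spacing_mm} and \code{dim(labels)}.
#' @param spacing_mm convenience alternative to \code{geometry}.
#' @param frame_index ordinal of the frame within its pullback (default 1).
#' @return object of class \code{oct_frame} with fields \code{labels},
#'   \code{geometry}, \code{frame_index}.
#' @export
oct_frame <- function(labels, geometry = NULL, spacing_mm = NULL,
                      frame_index = 1L) {
  labels <- as.matrix(labels)
  storage.mode(labels) <- "integer"
  if (is.null(geometry)) {
    if (is.null(spacing_mm)) {
      stop("either geometry or spacing_mm must be given", call. = FALSE)
    }
    geometry <- pixel_geometry(spacing_mm, dim(labels))
  }
  stopifnot(inherits(geometry, "pixel_geometry"))
  if (!all(dim(labels) == geometry$frame_shape)) {
    stop("labels shape does not match geometry$frame_shape", call. = FALSE)
  }
  structure(
    list(labels = labels, geometry = geometry,
         frame_index = as.integer(frame_index)),
    class = "oct_frame"
  )
}

#' @export
print.oct_frame <- function(x, ...) {
  sh <- x$geometry$frame_shape
  cat(sprintf("<oct_frame %dx%d px, %.4g mm/px, frame %d>\n",
              sh[1], sh[2], x$geometry$spacing_mm, x$frame_index))
  tab <- table(factor(x$labels, levels = 0:9,
                      labels = names(label_schema()$class_ids)))
  present <- tab[tab > 0]
  cat("  classes:",
      paste(sprintf("%s=%d", names(present), present), collapse = ", "), "\n")
  invisible(x)
}

#' An ordered pullback of OCT frames
#'
#' @param frames list of [oct_frame()] objects sharing one geometry.
#' @param pullback_id identifier string.
#' @param frame_pitch_mm longitudinal spacing between frames (mm/frame).
#' @return object of class \code{oct_pullback}.
#' @export
oct_pullback <- function(frames, pullback_id = "pullback",
                         frame_pitch_mm = 0.1) {
  if (length(frames) < 1L) {
    stop("a pullback needs at least one frame", call. = FALSE)
  }
  stopifnot(all(vapply(frames, inherits, logical(1), "oct_frame")))
  g0 <- frames[[1L]]$geometry
  same <- vapply(frames, function(f) {
    identical(f$geometry$frame_shape, g0$frame_shape) &&
      isTRUE(all.equal(f$geometry$spacing_mm, g0$spacing_mm))
  }, logical(1))
  if (!all(same)) {
    stop("GeometryMismatchError: all frames must share geometry",
         call. = FALSE)
  }
  for (i in seq_along(frames)) frames[[i]]$frame_index <- i
  structure(
    list(frames = frames, pullback_id = pullback_id,
         frame_pitch_mm = frame_pitch_mm),
    class = "oct_pullback"
  )
}

#' @export
print.oct_pullback <- function(x, ...) {
  cat(sprintf("<oct_pullback '%s': %d frames, pitch %.3g mm>\n",
              x$pullback_id, length(x$frames), x$frame_pitch_mm))
  invisible(x)
}

#' Extract a centered stack of consecutive frames
#'
#' Returns \code{k} consecutive frames centered on \code{center_index},
#' replicating the first/last frame at the pullback edges. This is the input
#' contract of pseudo-3D segmentation backends that consume a channel stack
#' of neighbouring cross-sections.
#'
#' @param pullback an [oct_pullback()].
#' @param center_index 1-based index of the central frame.
#' @param k odd stack size (default 7).
#' @return list of \code{k} [oct_frame()] objects.
#' @export
stack_frames <- function(pullback, center_index, k = 7L) {
  stopifnot(inherits(pullback, "oct_pullback"))
  k <- as.integer(k)
  if (k < 1L || k %% 2L == 0L) stop("k must be odd and >= 1", call. = FALSE)
  n <- length(pullback$frames)
  if (center_index < 1L || center_index > n) {
    stop("center_index out of range", call. = FALSE)
  }
  half <- (k - 1L) %/% 2L
  idx <- pmin(pmax(center_index + seq.int(-half, half), 1L), n)
  pullback$frames[idx]
}
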