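#' Centroid of the lumen
#'
#' Arithmetic mean of the pixel-center coordinates of the largest 8-connected
#' lumen component. Disjoint satellite lumen blobs (speckle, unfiltered
#' noise) are ignored here; removing them is the job of
#' [filter_small_components()].
#'
#' @param frame an [oct_frame()].
#' @return numeric \code{c(row, col)}, sub-pixel, 1-based.
#' @export
lumen_centroid <- function(frame) {
  stopifnot(inherits(frame, "oct_frame"))
  mask <- frame$labels == .CODES[["lumen"]]
  if (!any(mask)) {
    stop("NoLumenError: frame contains no lumen pixels", call. = FALSE)
  }
  lab <- .label_components8(mask)
  sizes <- tabulate(lab[lab > 0L])
  biggest <- which.max(sizes)
  idx <- which(lab == biggest, arr.ind = TRUE)
  c(row = mean(idx[, 1L]), col = mean(idx[, 2L]))
}

#' Cast equiangular rays from an origin and profile the classes along them
#'
#' Ray \code{k} (k = 1..n_rays) points at angle
#' \code{(k-1) * 360 / n_rays} degrees, measured counterclockwise from the
#' +x (column) axis with y pointing up (i.e. towards decreasing row).
#' Labels are sampled every half pixel with nearest-neighbour lookup —
#' categorical labels are never interpolated — and consecutive identical
#' classes are merged into radial intervals in mm.
#'
#' @param frame an [oct_frame()].
#' @param origin numeric \code{c(row, col)}; defaults to [lumen_centroid()].
#' @param n_rays number of rays, >= 90 (default 720, i.e. 0.5 degree bins).
#' @return object of class \code{ray_profiles}: a list with \code{n_rays},
#'   \code{origin}, \code{angles_deg}, \code{spacing_mm}, \code{frame} (the
#'   source frame, kept for sub-bin sector refinement) and
#'   \code{intervals}, a data.frame with columns \code{ray},
#'   \code{class_code}, \code{r_start_mm}, \code{r_end_mm}. Within a ray the
#'   intervals tile \code{[0, edge]} without gaps.
#' @export
cast_rays <- function(frame, origin = NULL, n_rays = 720L) {
  stopifnot(inherits(frame, "oct_frame"))
  n_rays <- as.integer(n_rays)
  if (n_rays < 90L) stop("n_rays must be >= 90", call. = FALSE)
  if (is.null(origin)) origin <- lumen_centroid(frame)
  sh <- frame$geometry$frame_shape
  if (origin[1L] < 1 || origin[1L] > sh[1L] ||
      origin[2L] < 1 || origin[2L] > sh[2L]) {
    stop("OriginOutOfBoundsError: origin outside frame", call. = FALSE)
  }
  spacing <- frame$geometry$spacing_mm
  step_px <- 0.25   # fine radial step sharpens interval boundaries
  # farthest corner distance bounds the sample count for every ray
  rmax_px <- sqrt(max(origin[1L] - 1, sh[1L] - origin[1L])^2 +
                  max(origin[2L] - 1, sh[2L] - origin[2L])^2)
  r_px <- seq(0, rmax_px + step_px, by = step_px)
  theta <- (seq_len(n_rays) - 1L) * 2 * pi / n_rays
  # sample grid: rows = radii, cols = rays
  rows <- round(origin[1L] - outer(r_px, sin(theta)))
  cols <- round(origin[2L] + outer(r_px, cos(theta)))
  inb <- rows >= 1 & rows <= sh[1L] & cols >= 1 & cols <= sh[2L]
  cls <- matrix(NA_integer_, nrow(rows), ncol(rows))
  cls[inb] <- frame$labels[cbind(rows[inb], cols[inb])]

  half_mm <- step_px * spacing / 2
  per_ray <- lapply(seq_len(n_rays), function(k) {
    v <- cls[, k]
    n_in <- which(is.na(v))[1L]
    n_in <- if (is.na(n_in)) length(v) else n_in - 1L
    if (n_in == 0L) return(NULL)
    rl <- rle(v[seq_len(n_in)])
    ends_idx <- cumsum(rl$lengths)
    starts_idx <- c(1L, head(ends_idx, -1L) + 1L)
    # interval boundaries at midpoints between adjacent samples; the first
    # interval starts at the origin, the last ends half a step past the
    # final in-bounds sample
    r_start <- ifelse(starts_idx == 1L, 0,
                      r_px[starts_idx] * spacing - half_mm)
    r_end <- r_px[ends_idx] * spacing + half_mm
    data.frame(ray = k, class_code = rl$values,
               r_start_mm = r_start, r_end_mm = r_end)
  })
  intervals <- do.call(rbind, per_ray)
  structure(
    list(n_rays = n_rays, origin = origin,
         angles_deg = (seq_len(n_rays) - 1L) * 360 / n_rays,
         spacing_mm = spacing, intervals = intervals, frame = frame),
    class = "ray_profiles"
  )
}

#' @export
print.ray_profiles <- function(x, ...) {
  cat(sprintf("<ray_profiles: %d rays from (%.1f, %.1f), %d intervals>\n",
              x$n_rays, x$origin[1L], x$origin[2L], nrow(x$intervals)))
  invisible(x)
}
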