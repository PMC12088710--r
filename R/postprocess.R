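#' Connected components of one class
#'
#' Components are computed under 8-connectivity (diagonal neighbours touch),
#' the standard choice for blob cleanup of segmentation masks.
#'
#' @param frame an [oct_frame()].
#' @param class_code integer class code (see [label_schema()]) or class name.
#' @return data.frame with one row per component: \code{component_id},
#'   \code{class_code}, \code{area_px}, \code{area_mm2}, \code{row_min},
#'   \code{row_max}, \code{col_min}, \code{col_max}. Zero rows when the
#'   class is absent. The label matrix itself is attached as attribute
#'   \code{"label_matrix"} (0 outside the class).
#' @export
connected_components <- function(frame, class_code) {
  stopifnot(inherits(frame, "oct_frame"))
  if (is.character(class_code)) class_code <- .CODES[[class_code]]
  mask <- frame$labels == class_code
  lab <- .label_components8(mask)
  n <- max(lab)
  spacing2 <- frame$geometry$spacing_mm^2
  if (n == 0L) {
    out <- data.frame(component_id = integer(0), class_code = integer(0),
                      area_px = integer(0), area_mm2 = numeric(0),
                      row_min = integer(0), row_max = integer(0),
                      col_min = integer(0), col_max = integer(0))
    attr(out, "label_matrix") <- lab
    return(out)
  }
  idx <- which(lab > 0L, arr.ind = TRUE)
  ids <- lab[lab > 0L]
  area <- tabulate(ids, n)
  out <- data.frame(
    component_id = seq_len(n),
    class_code = as.integer(class_code),
    area_px = area,
    area_mm2 = area * spacing2,
    row_min = as.integer(tapply(idx[, 1L], ids, min)),
    row_max = as.integer(tapply(idx[, 1L], ids, max)),
    col_min = as.integer(tapply(idx[, 2L], ids, min)),
    col_max = as.integer(tapply(idx[, 2L], ids, max))
  )
  attr(out, "label_matrix") <- lab
  out
}

# relabel all sub-threshold components of one class at once: each component
# takes the modal class of the 8-neighbourhood just outside its pixel set
# (background when there is no outside neighbour or when the vote is tied)
.relabel_small <- function(labels, lab, small_ids) {
  sh <- dim(labels)
  pix <- which(array(lab %in% small_ids, dim(lab)), arr.ind = TRUE)
  own <- lab[pix]
  comp_v <- integer(0)
  class_v <- integer(0)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    nr <- pix[, 1L] + dr
    nc <- pix[, 2L] + dc
    ok <- nr >= 1L & nr <= sh[1L] & nc >= 1L & nc <= sh[2L]
    if (!any(ok)) next
    nb <- cbind(nr[ok], nc[ok])
    outside <- lab[nb] != own[ok]   # 8-connectivity: same class => same id
    if (!any(outside)) next
    comp_v <- c(comp_v, own[ok][outside])
    class_v <- c(class_v, labels[nb[outside, , drop = FALSE]])
  }
  target <- vapply(small_ids, function(id) {
    votes <- tabulate(class_v[comp_v == id] + 1L, 10L)
    if (sum(votes) == 0L) return(.CODES[["background"]])
    mx <- max(votes)
    if (sum(votes == mx) > 1L) return(.CODES[["background"]])
    as.integer(which.max(votes) - 1L)
  }, integer(1))
  labels[pix] <- target[match(own, small_ids)]
  labels
}

#' Remove small isolated predictions by connected-component analysis
#'
#' Every class except background, thrombus and plaque rupture has its
#' 8-connected components smaller than \code{min_area_mm2} relabelled to the
#' majority class of the component's outer border neighbourhood (background
#' when there is none). Thrombus and plaque rupture are exempt because small
#' genuine specks of those classes are diagnostically meaningful. The filter
#' iterates to a fixed point, so it is idempotent and the output contains no
#' non-exempt component below the threshold.
#'
#' @param frame an [oct_frame()].
#' @param min_area_mm2 area threshold in mm^2 (default 0.005; components with
#'   \code{area < min_area_mm2} are relabelled). The threshold is expressed
#'   physically so it is resolution-independent.
#' @return the filtered [oct_frame()].
#' @export
filter_small_components <- function(frame, min_area_mm2 = 0.005) {
  stopifnot(inherits(frame, "oct_frame"), min_area_mm2 >= 0)
  if (min_area_mm2 == 0) return(frame)
  exempt <- c(.CODES[["background"]], .CODES[["thrombus"]],
              .CODES[["plaque_rupture"]])
  spacing2 <- frame$geometry$spacing_mm^2
  labels <- frame$labels
  for (pass in seq_len(100L)) {
    changed <- FALSE
    for (code in setdiff(0:9, exempt)) {
      if (!any(labels == code)) next
      lab <- .label_components8(labels == code)
      n <- max(lab)
      if (n == 0L) next
      area <- tabulate(lab[lab > 0L], n)
      small <- which(area * spacing2 < min_area_mm2)
      if (length(small)) {
        labels <- .relabel_small(labels, lab, small)
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  oct_frame(labels, geometry = frame$geometry,
            frame_index = frame$frame_index)
}
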