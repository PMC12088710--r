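#' Minimum radial gap between the lumen and a plaque class
#'
#' Along every ray on which the target class appears, the gap between the
#' abluminal lumen border and the adluminal plaque border is the radial
#' distance \code{r_start(first target interval) - r_end(lumen interval)};
#' the minimum over rays implements the minimum fibrous cap thickness
#' (target lipid) and the calcium depth (target calcium). Rays whose
#' profiles contain guidewire artefact are excluded: no tissue is measurable
#' behind the wire shadow.
#'
#' @param profiles a [cast_rays()] result.
#' @param target_class class code or name (\code{"lipid"} or
#'   \code{"calcium"}).
#' @return gap in micrometres, or \code{NA} when no qualifying ray exists.
#' @export
min_radial_gap <- function(profiles, target_class) {
  stopifnot(inherits(profiles, "ray_profiles"))
  if (is.character(target_class)) target_class <- .CODES[[target_class]]
  iv <- profiles$intervals
  gw_rays <- unique(iv$ray[iv$class_code == .CODES[["guidewire_artefact"]]])
  gaps <- vapply(setdiff(unique(iv$ray[iv$class_code == target_class]),
                         gw_rays), function(k) {
    ray <- iv[iv$ray == k, ]
    lum_end <- ray$r_end_mm[ray$class_code == .CODES[["lumen"]]]
    if (length(lum_end) == 0L) return(NA_real_)
    tgt_start <- ray$r_start_mm[ray$class_code == target_class][1L]
    tgt_start - lum_end[1L]
  }, numeric(1))
  gaps <- gaps[!is.na(gaps)]
  if (length(gaps) == 0L) return(NA_real_)
  1000 * max(min(gaps), 0)
}

#' Maximum radial thickness of a plaque class
#'
#' On each ray, the summed radial extent of the target-class intervals
#' (adluminal to abluminal border, measured from the lumen centroid);
#' the maximum over rays is reported. Implements the calcium thickness.
#'
#' @param profiles a [cast_rays()] result.
#' @param target_class class code or name (default \code{"calcium"}).
#' @return thickness in micrometres, or \code{NA} when the class is absent.
#' @export
max_radial_thickness <- function(profiles, target_class = "calcium") {
  stopifnot(inherits(profiles, "ray_profiles"))
  if (is.character(target_class)) target_class <- .CODES[[target_class]]
  iv <- profiles$intervals[profiles$intervals$class_code == target_class, ]
  if (nrow(iv) == 0L) return(NA_real_)
  per_ray <- tapply(iv$r_end_mm - iv$r_start_mm, iv$ray, sum)
  1000 * max(per_ray)
}

#' Fibrous cap area
#'
#' Total area labelled intima within the lipid arc: intima pixels whose
#' angular coordinate about the lumen centroid falls inside a lipid sector,
#' times the pixel area. Guidewire-bridged spans contribute nothing: no
#' tissue pixels exist behind the shadow.
#'
#' @param frame the (post-processed) [oct_frame()] the sectors came from.
#' @param lipid_sectors an [angular_sectors()] from [class_sectors()] on the
#'   same frame (carries the centroid used as angular origin).
#' @return area in mm^2.
#' @export
fibrous_cap_area <- function(frame, lipid_sectors) {
  stopifnot(inherits(frame, "oct_frame"),
            inherits(lipid_sectors, "angular_sectors"))
  if (is.null(lipid_sectors$origin)) {
    stop("lipid_sectors must come from class_sectors() (origin missing)",
         call. = FALSE)
  }
  if (nrow(lipid_sectors$sectors) == 0L) return(0)
  origin <- lipid_sectors$origin
  idx <- which(frame$labels == .CODES[["intima"]], arr.ind = TRUE)
  if (nrow(idx) == 0L) return(0)
  theta <- (atan2(origin[1L] - idx[, 1L], idx[, 2L] - origin[2L]) *
              180 / pi) %% 360
  iv <- .split_intervals(lipid_sectors)
  inside <- rep(FALSE, length(theta))
  for (i in seq_len(nrow(iv))) {
    inside <- inside | (theta >= iv[i, 1L] & theta < iv[i, 2L])
  }
  sum(inside) * frame$geometry$spacing_mm^2
}

#' Fibrous cap ratio
#'
#' Fibrous cap area divided by the lipid arc.
#'
#' @param area_mm2 cap area (mm^2).
#' @param arc_deg lipid arc (degrees, > 0).
#' @return ratio in mm^2 per degree.
#' @export
fibrous_cap_ratio <- function(area_mm2, arc_deg) {
  if (arc_deg == 0) {
    stop("ZeroArcError: lipid arc is zero", call. = FALSE)
  }
  area_mm2 / arc_deg
}

#' Lipid-rich plaque classification
#'
#' A lipid plaque with an arc of at least 90 degrees (boundary inclusive).
#'
#' @param lipid_arc_deg cumulative lipid arc in degrees.
#' @return logical flag.
#' @export
classify_lrp <- function(lipid_arc_deg) {
  isTRUE(lipid_arc_deg >= 90)
}

#' Frame-wise presence of a class
#'
#' Presence means at least one pixel of the class remains after
#' post-processing; the component-area threshold is thus the de facto
#' minimum detection size.
#'
#' @param frame an [oct_frame()].
#' @param class_code class code or name.
#' @return logical flag.
#' @export
frame_presence <- function(frame, class_code) {
  stopifnot(inherits(frame, "oct_frame"))
  if (is.character(class_code)) class_code <- .CODES[[class_code]]
  any(frame$labels == class_code)
}

# shortest-distance (rather than radial) lumen-to-plaque gap: minimum
# Euclidean distance between abluminal lumen border pixels and adluminal
# target pixels, minus one pixel (adjacent pixels -> ~0 thickness);
# sensitivity-analysis variant of min_radial_gap
.edt_gap <- function(frame, target_class) {
  lum <- frame$labels == .CODES[["lumen"]]
  tgt <- frame$labels == target_class
  if (!any(lum) || !any(tgt)) return(NA_real_)
  border <- function(mask) {
    sh <- dim(mask)
    inner <- mask
    inner[2:(sh[1L] - 1L), 2:(sh[2L] - 1L)] <-
      mask[2:(sh[1L] - 1L), 2:(sh[2L] - 1L)] &
      mask[1:(sh[1L] - 2L), 2:(sh[2L] - 1L)] &
      mask[3:sh[1L], 2:(sh[2L] - 1L)] &
      mask[2:(sh[1L] - 1L), 1:(sh[2L] - 2L)] &
      mask[2:(sh[1L] - 1L), 3:sh[2L]]
    which(mask & !inner, arr.ind = TRUE)
  }
  a <- border(lum)
  b <- border(tgt)
  dmin <- Inf
  chunk <- 2000L
  for (i0 in seq(1L, nrow(a), by = chunk)) {
    ii <- i0:min(i0 + chunk - 1L, nrow(a))
    d2 <- outer(a[ii, 1L], b[, 1L], `-`)^2 + outer(a[ii, 2L], b[, 2L], `-`)^2
    dmin <- min(dmin, sqrt(min(d2)))
  }
  1000 * max(dmin - 1, 0) * frame$geometry$spacing_mm
}

#' Quantify a frame into plaque metrics
#'
#' Orchestrates the full per-frame quantification: lumen centroid, ray
#' casting, angular sectors with guidewire bridging, arcs, minimum fibrous
#' cap thickness, calcium depth and thickness, fibrous cap area and ratio,
#' presence flags and the lipid-rich-plaque classification. The frame is
#' expected to be post-processed (see [filter_small_components()]).
#'
#' @param frame an [oct_frame()] containing lumen.
#' @param n_rays number of rays (default 720, i.e. 0.5 degree bins).
#' @param bridge_guidewire measure arcs continuously across the guidewire
#'   shadow (default TRUE).
#' @param fct_mode \code{"radial"} (default; gap measured along centroid
#'   rays) or \code{"edt"} (shortest Euclidean distance, sensitivity
#'   variant) for minimum FCT and calcium depth.
#' @return object of class \code{plaque_metrics}: a list with
#'   \code{lipid_arc_deg}, \code{calcium_arc_deg}, \code{min_fct_um},
#'   \code{fibrous_cap_area_mm2}, \code{fibrous_cap_ratio_mm2_per_deg},
#'   \code{calcium_depth_um}, \code{calcium_thickness_um},
#'   \code{lipid_present}, \code{calcium_present}, \code{thrombus_present},
#'   \code{plaque_rupture_present}, \code{side_branch_present},
#'   \code{is_lrp}. Absent measures are \code{NA}.
#' @export
quantify_frame <- function(frame, n_rays = 720L, bridge_guidewire = TRUE,
                           fct_mode = c("radial", "edt")) {
  stopifnot(inherits(frame, "oct_frame"))
  fct_mode <- match.arg(fct_mode)
  origin <- lumen_centroid(frame)
  profiles <- cast_rays(frame, origin, n_rays)
  lip <- class_sectors(profiles, "lipid", bridge_guidewire)
  cal <- class_sectors(profiles, "calcium", bridge_guidewire)
  lipid_arc <- arc_degrees(lip)
  calcium_arc <- arc_degrees(cal)
  lipid_present <- frame_presence(frame, "lipid")
  calcium_present <- frame_presence(frame, "calcium")
  if (fct_mode == "radial") {
    fct <- min_radial_gap(profiles, "lipid")
    depth <- min_radial_gap(profiles, "calcium")
  } else {
    fct <- if (lipid_present) .edt_gap(frame, .CODES[["lipid"]]) else NA_real_
    depth <- if (calcium_present) .edt_gap(frame, .CODES[["calcium"]]) else NA_real_
  }
  cap_area <- if (lipid_present) fibrous_cap_area(frame, lip) else 0
  structure(list(
    lipid_arc_deg = lipid_arc,
    calcium_arc_deg = calcium_arc,
    min_fct_um = fct,
    fibrous_cap_area_mm2 = cap_area,
    fibrous_cap_ratio_mm2_per_deg = if (lipid_arc > 0)
      fibrous_cap_ratio(cap_area, lipid_arc) else NA_real_,
    calcium_depth_um = depth,
    calcium_thickness_um = max_radial_thickness(profiles, "calcium"),
    lipid_present = lipid_present,
    calcium_present = calcium_present,
    thrombus_present = frame_presence(frame, "thrombus"),
    plaque_rupture_present = frame_presence(frame, "plaque_rupture"),
    side_branch_present = frame_presence(frame, "side_branch"),
    is_lrp = lipid_present && classify_lrp(lipid_arc)
  ), class = "plaque_metrics")
}

#' @export
print.plaque_metrics <- function(x, ...) {
  cat("<plaque_metrics>\n")
  cat(sprintf("  lipid arc %.1f deg (LRP: %s), calcium arc %.1f deg\n",
              x$lipid_arc_deg, x$is_lrp, x$calcium_arc_deg))
  cat(sprintf("  min FCT %.1f um, cap area %.4f mm2, cap ratio %.4g mm2/deg\n",
              x$min_fct_um, x$fibrous_cap_area_mm2,
              x$fibrous_cap_ratio_mm2_per_deg))
  cat(sprintf("  calcium depth %.1f um, thickness %.1f um\n",
              x$calcium_depth_um, x$calcium_thickness_um))
  invisible(x)
}

#' @export
as.data.frame.plaque_metrics <- function(x, row.names = NULL,
                                         optional = FALSE, ...) {
  as.data.frame(unclass(x), row.names = row.names, optional = optional, ...)
}

#' Quantify every frame of a pullback
#'
#' @param pullback an [oct_pullback()].
#' @param ... arguments passed to [quantify_frame()].
#' @return data.frame with one row per frame, first column
#'   \code{frame_index}, then the [quantify_frame()] fields in declaration
#'   order.
#' @export
quantify_pullback <- function(pullback, ...) {
  stopifnot(inherits(pullback, "oct_pullback"))
  rows <- lapply(pullback$frames, function(f)
    cbind(frame_index = f$frame_index,
          as.data.frame(quantify_frame(f, ...))))
  do.call(rbind, rows)
}
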