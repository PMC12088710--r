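#' Angular plaque sector of a synthetic vessel phantom
#'
#' @param plaque_class \code{"lipid"} or \code{"calcium"}.
#' @param theta_start_deg start angle of the sector (degrees, mod 360,
#'   counterclockwise from the +x axis as in [cast_rays()]).
#' @param extent_deg angular extent in (0, 360].
#' @param cap_thickness_mm radial intima (cap) thickness between the lumen
#'   border and the adluminal plaque border within the sector, >= 0.
#' @param plaque_thickness_mm radial extent of the plaque, > 0.
#' @return object of class \code{plaque_sector}.
#' @export
plaque_sector <- function(plaque_class, theta_start_deg, extent_deg,
                          cap_thickness_mm, plaque_thickness_mm) {
  stopifnot(plaque_class %in% c("lipid", "calcium"),
            extent_deg > 0, extent_deg <= 360,
            cap_thickness_mm >= 0, plaque_thickness_mm > 0)
  structure(
    list(plaque_class = plaque_class,
         theta_start_deg = theta_start_deg %% 360,
         extent_deg = extent_deg,
         cap_thickness_mm = cap_thickness_mm,
         plaque_thickness_mm = plaque_thickness_mm),
    class = "plaque_sector"
  )
}

# angular half-open interval membership, mod 360
.in_sector <- function(theta_deg, start_deg, extent_deg) {
  d <- (theta_deg - start_deg) %% 360
  d < extent_deg
}

# do two half-open angular intervals (start, extent) overlap (mod 360)?
.sectors_overlap <- function(s1, e1, s2, e2) {
  ((s2 - s1) %% 360) < e1 || ((s1 - s2) %% 360) < e2
}

#' Parametric specification of a synthetic vessel cross-section
#'
#' Describes a concentric vessel wall (lumen disc, intima annulus, media
#' annulus) with angular plaque sectors, an optional guidewire shadow wedge,
#' an optional side-branch wedge, and optional isolated speckle blobs. Every
#' quantification metric of the rendered frame is known in closed form from
#' this description (see [phantom_ground_truth()]), which makes the phantom
#' the test oracle of the package.
#'
#' @param spacing_mm isotropic pixel spacing (mm).
#' @param frame_shape \code{c(rows, cols)}.
#' @param lumen_center_px \code{c(row, col)} of the lumen center; defaults to
#'   the frame center. Off-center values emulate eccentric catheter position.
#' @param lumen_radius_mm lumen radius.
#' @param intima_thickness_mm baseline intima thickness outside plaque
#'   sectors.
#' @param media_thickness_mm media thickness outside plaque sectors.
#' @param sectors list of [plaque_sector()] objects; same-class sectors must
#'   not overlap angularly, and no sector may overlap the wedges.
#' @param guidewire optional \code{c(theta_center_deg, width_deg)} wedge that
#'   replaces every label from the lumen border outward with
#'   guidewire_artefact (the shadow cast by the wire).
#' @param side_branch optional \code{c(theta_center_deg, width_deg)} wedge
#'   where the wall (intima + media) is replaced by side_branch.
#' @param speckle optional list \code{(class, n_components,
#'   component_area_px)}: isolated noise blobs of that class dropped on the
#'   background at least 5 px away from all structures.
#' @param seed RNG seed for speckle placement (default 1).
#' @return object of class \code{phantom_spec}.
#' @export
phantom_spec <- function(spacing_mm = 0.01, frame_shape = c(448L, 448L),
                         lumen_center_px = NULL,
                         lumen_radius_mm = 1.0,
                         intima_thickness_mm = 0.2,
                         media_thickness_mm = 0.1,
                         sectors = list(),
                         guidewire = NULL, side_branch = NULL,
                         speckle = NULL, seed = 1L) {
  geometry <- pixel_geometry(spacing_mm, frame_shape)
  if (is.null(lumen_center_px)) {
    lumen_center_px <- (frame_shape + 1) / 2
  }
  stopifnot(all(vapply(sectors, inherits, logical(1), "plaque_sector")))
  # same-class sectors must not overlap angularly
  for (cl in c("lipid", "calcium")) {
    ss <- Filter(function(s) s$plaque_class == cl, sectors)
    if (length(ss) > 1L) {
      for (i in seq_len(length(ss) - 1L)) for (j in seq.int(i + 1L, length(ss))) {
        if (.sectors_overlap(ss[[i]]$theta_start_deg, ss[[i]]$extent_deg,
                             ss[[j]]$theta_start_deg, ss[[j]]$extent_deg)) {
          stop("plaque sectors of class ", cl, " overlap angularly",
               call. = FALSE)
        }
      }
    }
  }
  wedges <- Filter(Negate(is.null), list(guidewire = guidewire,
                                         side_branch = side_branch))
  for (w in wedges) {
    ws <- (w[1L] - w[2L] / 2) %% 360
    for (s in sectors) {
      if (.sectors_overlap(ws, w[2L], s$theta_start_deg, s$extent_deg)) {
        stop("guidewire/side-branch wedge overlaps a plaque sector",
             call. = FALSE)
      }
    }
  }
  spec <- structure(
    list(geometry = geometry, lumen_center_px = lumen_center_px,
         lumen_radius_mm = lumen_radius_mm,
         intima_thickness_mm = intima_thickness_mm,
         media_thickness_mm = media_thickness_mm,
         sectors = sectors, guidewire = guidewire,
         side_branch = side_branch, speckle = speckle,
         seed = as.integer(seed)),
    class = "phantom_spec"
  )
  # annuli (including plaque sectors) must fit inside the frame
  max_r_mm <- lumen_radius_mm + max(
    intima_thickness_mm + media_thickness_mm,
    if (length(sectors)) max(vapply(sectors, function(s)
      s$cap_thickness_mm + s$plaque_thickness_mm, numeric(1))) else 0)
  edge_mm <- min(lumen_center_px[1L] - 1, frame_shape[1L] - lumen_center_px[1L],
                 lumen_center_px[2L] - 1, frame_shape[2L] - lumen_center_px[2L]) *
    spacing_mm
  if (max_r_mm >= edge_mm) {
    stop("SpecInfeasibleError: vessel annuli do not fit inside the frame",
         call. = FALSE)
  }
  spec
}

#' Closed-form fibrous cap area of a phantom
#'
#' Sum over the lipid sectors of the annulus-sector area between the lumen
#' border and the adluminal plaque border:
#' \deqn{\sum_s \frac{E_s}{360}\,\pi\,[(r_l + c_s)^2 - r_l^2]}
#' with extent \eqn{E_s} (degrees), lumen radius \eqn{r_l} and cap thickness
#' \eqn{c_s}.
#'
#' @param spec a [phantom_spec()].
#' @return area in mm^2.
#' @export
analytic_cap_area <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  rl <- spec$lumen_radius_mm
  areas <- vapply(spec$sectors, function(s) {
    if (s$plaque_class != "lipid") return(0)
    (s$extent_deg / 360) * pi * ((rl + s$cap_thickness_mm)^2 - rl^2)
  }, numeric(1))
  sum(areas)
}

# guidewire bridging credit for the analytic arc: the wedge width is added
# when the wedge is angularly adjacent (touching) to sectors of the class on
# both sides, which is when the ray-cast arc is measured continuously across
# the shadow
.bridged_wedge_deg <- function(spec, cl) {
  gw <- spec$guidewire
  if (is.null(gw)) return(0)
  ss <- Filter(function(s) s$plaque_class == cl, spec$sectors)
  if (length(ss) == 0L) return(0)
  w_start <- (gw[1L] - gw[2L] / 2) %% 360
  w_end <- (gw[1L] + gw[2L] / 2) %% 360
  ang_eq <- function(a, b) {
    d <- abs((a - b) %% 360)
    min(d, 360 - d) < 1e-9
  }
  left <- any(vapply(ss, function(s)
    ang_eq(s$theta_start_deg + s$extent_deg, w_start), logical(1)))
  right <- any(vapply(ss, function(s)
    ang_eq(s$theta_start_deg, w_end), logical(1)))
  if (left && right) gw[2L] else 0
}

#' Closed-form quantification metrics of a phantom
#'
#' The analytically known counterpart of [quantify_frame()] for a rendered
#' phantom: arcs are sums of sector extents per class (plus the guidewire
#' wedge width when the wedge touches sectors of the class on both sides),
#' the minimum fibrous cap thickness / calcium depth are the smallest sector
#' cap thicknesses, the calcium thickness is the largest calcium sector
#' thickness, and the cap area is [analytic_cap_area()].
#'
#' @param spec a [phantom_spec()].
#' @return list with the [plaque_metrics] fields; absent measures are
#'   \code{NA}.
#' @export
phantom_ground_truth <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  sec_of <- function(cl) Filter(function(s) s$plaque_class == cl, spec$sectors)
  arc_of <- function(cl) {
    ss <- sec_of(cl)
    if (!length(ss)) return(0)
    sum(vapply(ss, `[[`, numeric(1), "extent_deg")) +
      .bridged_wedge_deg(spec, cl)
  }
  lip <- sec_of("lipid"); cal <- sec_of("calcium")
  lipid_arc <- arc_of("lipid"); calcium_arc <- arc_of("calcium")
  cap_area <- analytic_cap_area(spec)
  speckle_class <- if (is.null(spec$speckle)) NULL else spec$speckle$class
  list(
    lipid_arc_deg = lipid_arc,
    calcium_arc_deg = calcium_arc,
    min_fct_um = if (length(lip))
      1000 * min(vapply(lip, `[[`, numeric(1), "cap_thickness_mm")) else NA_real_,
    fibrous_cap_area_mm2 = cap_area,
    fibrous_cap_ratio_mm2_per_deg = if (lipid_arc > 0)
      cap_area / lipid_arc else NA_real_,
    calcium_depth_um = if (length(cal))
      1000 * min(vapply(cal, `[[`, numeric(1), "cap_thickness_mm")) else NA_real_,
    calcium_thickness_um = if (length(cal))
      1000 * max(vapply(cal, `[[`, numeric(1), "plaque_thickness_mm")) else NA_real_,
    lipid_present = length(lip) > 0,
    calcium_present = length(cal) > 0,
    thrombus_present = identical(speckle_class, "thrombus"),
    plaque_rupture_present = identical(speckle_class, "plaque_rupture"),
    side_branch_present = !is.null(spec$side_branch),
    is_lrp = length(lip) > 0 && lipid_arc >= 90
  )
}

#' Render a phantom specification into a label frame
#'
#' Concentric rendering from the lumen outward; within a plaque sector the
#' plaque annulus starts at lumen_radius + cap_thickness, the intima fills
#' the cap, and the media is interrupted (mimicking signal loss behind
#' plaque). The guidewire wedge overwrites every label from the lumen border
#' outward; the side-branch wedge replaces the wall. Speckle blobs are placed
#' on background at least 5 px from all structures by rejection sampling,
#' reproducibly under the spec seed.
#'
#' @param spec a [phantom_spec()].
#' @param frame_index ordinal stored in the returned frame.
#' @return list with components \code{frame} (an [oct_frame()]) and
#'   \code{truth} ([phantom_ground_truth()] of the spec).
#' @export
render_phantom <- function(spec, frame_index = 1L) {
  stopifnot(inherits(spec, "phantom_spec"))
  sh <- spec$geometry$frame_shape
  spacing <- spec$geometry$spacing_mm
  or <- spec$lumen_center_px[1L]; oc <- spec$lumen_center_px[2L]
  rr <- matrix(seq_len(sh[1L]), sh[1L], sh[2L])
  cc <- matrix(seq_len(sh[2L]), sh[1L], sh[2L], byrow = TRUE)
  dy <- or - rr          # y axis points up (towards smaller row)
  dx <- cc - oc
  r_mm <- sqrt(dy^2 + dx^2) * spacing
  theta <- (atan2(dy, dx) * 180 / pi) %% 360

  rl <- spec$lumen_radius_mm
  ri <- rl + spec$intima_thickness_mm
  rm <- ri + spec$media_thickness_mm
  lab <- matrix(.CODES[["background"]], sh[1L], sh[2L])
  lab[r_mm > rl & r_mm <= ri] <- .CODES[["intima"]]
  lab[r_mm > ri & r_mm <= rm] <- .CODES[["media"]]
  lab[r_mm <= rl] <- .CODES[["lumen"]]

  for (s in spec$sectors) {
    insec <- .in_sector(theta, s$theta_start_deg, s$extent_deg) & r_mm > rl
    r_cap <- rl + s$cap_thickness_mm
    r_out <- r_cap + s$plaque_thickness_mm
    lab[insec & r_mm <= r_cap] <- .CODES[["intima"]]
    lab[insec & r_mm > r_cap & r_mm <= r_out] <- .CODES[[s$plaque_class]]
    lab[insec & r_mm > r_out] <- .CODES[["background"]]
  }
  if (!is.null(spec$side_branch)) {
    sb <- spec$side_branch
    inw <- .in_sector(theta, (sb[1L] - sb[2L] / 2) %% 360, sb[2L])
    lab[inw & r_mm > rl & r_mm <= rm] <- .CODES[["side_branch"]]
  }
  if (!is.null(spec$guidewire)) {
    gw <- spec$guidewire
    inw <- .in_sector(theta, (gw[1L] - gw[2L] / 2) %% 360, gw[2L])
    lab[inw & r_mm > rl] <- .CODES[["guidewire_artefact"]]
  }
  if (!is.null(spec$speckle)) {
    lab <- .add_speckle(lab, spec$speckle, spec$seed)
  }
  frame <- oct_frame(lab, geometry = spec$geometry, frame_index = frame_index)
  list(frame = frame, truth = phantom_ground_truth(spec))
}

# drop n_components compact blobs of `class` on background, >= 5 px away
# from every non-background pixel; seeded rejection sampling
.add_speckle <- function(lab, speckle, seed) {
  n_blob <- speckle$n_components
  area <- speckle$component_area_px
  code <- .CODES[[speckle$class]]
  blob_r <- ceiling(sqrt(area / pi)) + 1L
  margin <- blob_r + 5L
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(seed)
  sh <- dim(lab)
  structure_mask <- lab != .CODES[["background"]]
  for (b in seq_len(n_blob)) {
    placed <- FALSE
    for (try in seq_len(2000L)) {
      cr <- sample.int(sh[1L] - 2L * margin, 1L) + margin
      cl <- sample.int(sh[2L] - 2L * margin, 1L) + margin
      win_r <- seq.int(cr - margin, cr + margin)
      win_c <- seq.int(cl - margin, cl + margin)
      if (any(structure_mask[win_r, win_c])) next
      # fill the `area` pixels nearest the blob center (a digital disc)
      wr <- seq.int(cr - blob_r, cr + blob_r)
      wc <- seq.int(cl - blob_r, cl + blob_r)
      d2 <- outer((wr - cr)^2, (wc - cl)^2, `+`)
      ord <- order(d2)[seq_len(area)]
      pix <- cbind(rep(wr, times = length(wc))[ord],
                   rep(wc, each = length(wr))[ord])
      lab[pix] <- code
      structure_mask[pix] <- TRUE
      placed <- TRUE
      break
    }
    if (!placed) {
      stop("SpecInfeasibleError: could not place speckle blob ", b,
           call. = FALSE)
    }
  }
  lab
}

#' Render a pullback of phantoms
#'
#' @param specs list of [phantom_spec()] objects sharing one geometry.
#' @param pitch_mm longitudinal frame spacing.
#' @param pullback_id identifier.
#' @return list with \code{pullback} (an [oct_pullback()]) and \code{truth}
#'   (list of per-frame ground-truth metric lists).
#' @export
render_pullback <- function(specs, pitch_mm = 0.1,
                            pullback_id = "phantom_pullback") {
  if (length(specs) < 1L) {
    stop("GeometryMismatchError: need at least one phantom spec",
         call. = FALSE)
  }
  g0 <- specs[[1L]]$geometry
  ok <- vapply(specs, function(s)
    identical(s$geometry$frame_shape, g0$frame_shape) &&
      isTRUE(all.equal(s$geometry$spacing_mm, g0$spacing_mm)), logical(1))
  if (!all(ok)) {
    stop("GeometryMismatchError: phantom specs differ in geometry",
         call. = FALSE)
  }
  rendered <- lapply(seq_along(specs), function(i)
    render_phantom(specs[[i]], frame_index = i))
  list(
    pullback = oct_pullback(lapply(rendered, `[[`, "frame"),
                            pullback_id = pullback_id,
                            frame_pitch_mm = pitch_mm),
    truth = lapply(rendered, `[[`, "truth")
  )
}

#' Draw a randomized phantom specification
#'
#' Samples a plausible vessel anatomy for property-based testing: lumen
#' radius 0.8--1.2 mm, intima 0.15--0.25 mm, media 0.08--0.12 mm, up to two
#' lipid and up to two calcium sectors with extents 20--110 degrees, cap
#' thicknesses 0.05--0.15 mm and plaque thicknesses 0.25--0.5 mm, an
#' optional guidewire wedge, and a lumen center jittered up to 20 px off the
#' frame center. Sectors and the wedge are placed with at least 6 degrees of
#' angular separation so that every metric stays in closed form. Uses the
#' current RNG state; seed with [set.seed()].
#'
#' @param spacing_mm pixel spacing (default 0.01 mm, i.e. 10 um/px).
#' @param frame_shape frame shape (default 448 x 448).
#' @param p_guidewire probability of including a guidewire wedge.
#' @return a [phantom_spec()].
#' @export
random_phantom_spec <- function(spacing_mm = 0.01,
                                frame_shape = c(448L, 448L),
                                p_guidewire = 0.5) {
  n_lip <- sample(0:2, 1L, prob = c(0.2, 0.5, 0.3))
  n_cal <- sample(0:2, 1L, prob = c(0.3, 0.5, 0.2))
  has_gw <- stats::runif(1) < p_guidewire
  n_items <- n_lip + n_cal + as.integer(has_gw)
  if (n_items == 0L) n_lip <- 1L
  n_items <- max(n_items, 1L)
  # angular layout: random extents + >= 6 degree gaps, then a random offset
  extents <- stats::runif(n_items, 20, 110)
  if (has_gw) extents[n_items] <- stats::runif(1, 15, 30)  # wedge is last
  while (sum(extents) > 360 - 6 * n_items) extents <- extents * 0.8
  gaps <- stats::runif(n_items, 6, 20)
  gaps <- gaps * (360 - sum(extents)) / sum(gaps) # close the circle
  starts <- (cumsum(c(0, head(extents + gaps, -1L))) + stats::runif(1, 0, 360)) %% 360
  classes <- c(rep("lipid", n_lip), rep("calcium", n_cal))
  sectors <- lapply(seq_len(n_lip + n_cal), function(i) {
    plaque_sector(classes[i], starts[i], extents[i],
                  cap_thickness_mm = stats::runif(1, 0.05, 0.15),
                  plaque_thickness_mm = stats::runif(1, 0.25, 0.5))
  })
  gw <- if (has_gw) {
    k <- n_items
    c((starts[k] + extents[k] / 2) %% 360, extents[k])
  } else NULL
  phantom_spec(
    spacing_mm = spacing_mm, frame_shape = frame_shape,
    lumen_center_px = (frame_shape + 1) / 2 +
      round(stats::runif(2, -20, 20)),
    lumen_radius_mm = stats::runif(1, 0.8, 1.2),
    intima_thickness_mm = stats::runif(1, 0.15, 0.25),
    media_thickness_mm = stats::runif(1, 0.08, 0.12),
    sectors = sectors, guidewire = gw
  )
}
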