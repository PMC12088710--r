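#' Construct an angular sector set directly
#'
#' Sector sets are usually produced by [class_sectors()]; this constructor
#' exists for composing known geometries (tests, worked examples).
#' Sectors are half-open \code{[start, start + extent)} intervals mod 360
#' and must be disjoint.
#'
#' @param class_code integer class code or class name.
#' @param starts_deg numeric vector of sector start angles (degrees).
#' @param extents_deg numeric vector of sector extents (degrees, > 0).
#' @param bridged logical vector flagging guidewire-bridged sectors
#'   (recycled).
#' @return object of class \code{angular_sectors}.
#' @export
angular_sectors <- function(class_code, starts_deg = numeric(0),
                            extents_deg = numeric(0), bridged = FALSE) {
  if (is.character(class_code)) class_code <- .CODES[[class_code]]
  stopifnot(length(starts_deg) == length(extents_deg),
            all(extents_deg > 0), all(extents_deg <= 360))
  n <- length(starts_deg)
  bridged <- rep_len(bridged, n)
  sectors <- data.frame(theta_start_deg = starts_deg %% 360,
                        extent_deg = extents_deg,
                        bridged = bridged)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
      if (.sectors_overlap(sectors$theta_start_deg[i], sectors$extent_deg[i],
                           sectors$theta_start_deg[j], sectors$extent_deg[j]))
        stop("sectors overlap after normalization", call. = FALSE)
    }
  }
  if (sum(extents_deg) > 360 + 1e-9) {
    stop("total sector coverage exceeds 360 degrees", call. = FALSE)
  }
  structure(list(class_code = as.integer(class_code), sectors = sectors,
                 positive_bins = NULL, n_rays = NULL, origin = NULL),
            class = "angular_sectors")
}

#' @export
print.angular_sectors <- function(x, ...) {
  cat(sprintf("<angular_sectors class %d: %d sector(s), %.1f deg total>\n",
              x$class_code, nrow(x$sectors), arc_degrees(x)))
  invisible(x)
}

# split a sector set into [start, end) pieces fully inside [0, 360)
.split_intervals <- function(x) {
  s <- x$sectors$theta_start_deg
  e <- s + x$sectors$extent_deg
  out <- cbind(s, pmin(e, 360))
  wrap <- e > 360
  if (any(wrap)) out <- rbind(out, cbind(0, e[wrap] - 360))
  out[out[, 2L] > out[, 1L], , drop = FALSE]
}

# pixel-center votes of a class: each pixel of `code` votes for the ray
# nearest its center angle about the origin. Voting (rather than testing
# the sampled digital ray against pixel areas) keeps sector topology free
# of staircase corner artefacts; sector edges are refined afterwards from
# the extreme pixel angles, giving sub-bin precision.
.class_votes <- function(frame, origin, n_rays, code) {
  idx <- which(frame$labels == code, arr.ind = TRUE)
  if (nrow(idx) == 0L) {
    return(list(hits = logical(n_rays), th = numeric(0)))
  }
  dy <- origin[1L] - idx[, 1L]
  dx <- idx[, 2L] - origin[2L]
  th <- (atan2(dy, dx) * 180 / pi) %% 360
  k <- as.integer(round(th * n_rays / 360)) %% n_rays
  hits <- logical(n_rays)
  hits[k + 1L] <- TRUE
  list(hits = hits, th = th, bin = k + 1L)
}

#' Angular sectors occupied by a class, with guidewire bridging
#'
#' A ray contributes its angular bin when it passes within half a pixel of
#' a pixel of the requested class; maximal runs of positive bins
#' (circularly) form sectors. When \code{bridge_guidewire} is set, a
#' maximal run of rays that hit guidewire artefact (and not the class
#' itself), flanked immediately on both sides by class-positive rays, is
#' absorbed into one continuous sector and flagged \code{bridged}: a plaque
#' visible on both sides of the wire shadow is measured continuously across
#' it.
#'
#' @param profiles a [cast_rays()] result.
#' @param class_code integer class code or class name.
#' @param bridge_guidewire absorb flanked guidewire runs (default TRUE).
#' @return an \code{angular_sectors} object; \code{positive_bins} carries
#'   the per-ray class-positive indicator (bridged guidewire bins excluded),
#'   used by [fibrous_cap_area()].
#' @export
class_sectors <- function(profiles, class_code, bridge_guidewire = TRUE) {
  stopifnot(inherits(profiles, "ray_profiles"))
  if (is.character(class_code)) class_code <- .CODES[[class_code]]
  n <- profiles$n_rays
  votes <- .class_votes(profiles$frame, profiles$origin, n, class_code)
  pos <- .close_single_gaps(votes$hits)
  gw <- .close_single_gaps(
    .class_votes(profiles$frame, profiles$origin, n,
                 .CODES[["guidewire_artefact"]])$hits) & !pos
  eff <- pos
  bridged_bins <- logical(n)
  if (bridge_guidewire && any(gw) && any(pos)) {
    runs <- .circular_runs(gw)
    for (r in runs) {
      before <- (r[1L] - 2L) %% n + 1L
      after <- r[length(r)] %% n + 1L
      if (pos[before] && pos[after]) {
        eff[r] <- TRUE
        bridged_bins[r] <- TRUE
      }
    }
  }
  bin_w <- 360 / n
  runs <- .circular_runs(eff)
  if (length(runs) == 0L) {
    out <- angular_sectors(class_code)
  } else if (length(runs) == 1L && length(runs[[1L]]) == n) {
    out <- angular_sectors(class_code, 0, 360, any(bridged_bins))
  } else {
    # refine each run's edges from the extreme pixel-center angles of the
    # class pixels voting into it: the bin grid only fixes the topology
    run_id <- integer(n)
    for (i in seq_along(runs)) run_id[runs[[i]]] <- i
    refined <- lapply(seq_along(runs), function(i) {
      r <- runs[[i]]
      a0 <- ((r[1L] - 1L) - 0.5) * bin_w   # lower edge of first bin
      sel <- run_id[votes$bin] == i
      if (!any(sel)) {                      # pure-bridge run cannot occur,
        return(c(a0, length(r) * bin_w))    # but stay defensive
      }
      psi <- (votes$th[sel] - a0) %% 360
      c(a0 + min(psi), max(max(psi) - min(psi), bin_w))
    })
    starts <- vapply(refined, `[[`, numeric(1), 1L)
    extents <- vapply(refined, `[[`, numeric(1), 2L)
    brid <- vapply(runs, function(r) any(bridged_bins[r]), logical(1))
    out <- angular_sectors(class_code, starts, extents, brid)
  }
  out$positive_bins <- pos
  out$n_rays <- n
  out$origin <- profiles$origin
  out
}

# fill single-bin FALSE holes flanked by TRUE (circularly): at radii where
# a pixel's angular footprint exceeds one bin, a ray through the exact gap
# between two pixel columns would otherwise receive no vote and split the
# sector. One bin (0.5 degrees by default) is below the angular resolution
# of the pixel grid at vessel radii, so closing it is lossless.
.close_single_gaps <- function(x) {
  n <- length(x)
  if (n < 3L || !any(x)) return(x)
  left <- x[c(n, seq_len(n - 1L))]
  right <- x[c(seq.int(2L, n), 1L)]
  x | (left & right)
}

# maximal runs of TRUE in a circular logical vector, each run an index
# vector in circular order
.circular_runs <- function(x) {
  n <- length(x)
  if (!any(x)) return(list())
  if (all(x)) return(list(seq_len(n)))
  # rotate so the vector starts just after a FALSE, making runs linear
  first_false <- which(!x)[1L]
  rot <- c(seq.int(first_false, n), seq_len(first_false - 1L))
  xr <- x[rot]
  rl <- rle(xr)
  ends <- cumsum(rl$lengths)
  starts <- c(1L, head(ends, -1L) + 1L)
  idx <- which(rl$values)
  lapply(idx, function(i) rot[seq.int(starts[i], ends[i])])
}

#' Cumulative arc of a sector set
#'
#' Sum of sector extents; when a plaque occupies multiple non-overlapping
#' sectors the cumulative arc is reported.
#'
#' @param sectors an [angular_sectors()] object.
#' @return degrees in \code{[0, 360]}.
#' @export
arc_degrees <- function(sectors) {
  stopifnot(inherits(sectors, "angular_sectors"))
  min(sum(sectors$sectors$extent_deg), 360)
}

#' Arc correspondence score between two sector sets
#'
#' Twice the angular intersection divided by the sum of the two arcs:
#' the Dice coefficient of the two angular indicator sets. 1 means identical
#' arc locations, 0 means disjoint.
#'
#' @param ref,pred [angular_sectors()] of the same class.
#' @return score in \code{[0, 1]}.
#' @export
correspondence_score <- function(ref, pred) {
  stopifnot(inherits(ref, "angular_sectors"),
            inherits(pred, "angular_sectors"))
  a_ref <- arc_degrees(ref)
  a_pred <- arc_degrees(pred)
  if (a_ref + a_pred == 0) {
    stop("UndefinedScoreError: both arcs are zero", call. = FALSE)
  }
  iv1 <- .split_intervals(ref)
  iv2 <- .split_intervals(pred)
  inter <- 0
  if (nrow(iv1) && nrow(iv2)) {
    for (i in seq_len(nrow(iv1))) {
      lo <- pmax(iv1[i, 1L], iv2[, 1L])
      hi <- pmin(iv1[i, 2L], iv2[, 2L])
      inter <- inter + sum(pmax(hi - lo, 0))
    }
  }
  2 * inter / (a_ref + a_pred)
}
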