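# Shared phantom fixtures, built in code. Unit tests use a small 256 px
# frame for speed; the acceptance suite uses the 448 px default geometry.

small_geometry <- function() list(spacing_mm = 0.01, frame_shape = c(256L, 256L))

# one lipid sector (30-120 deg, 65 um cap) on a small frame
simple_lipid_spec <- function(...) {
  g <- small_geometry()
  phantom_spec(
    spacing_mm = g$spacing_mm, frame_shape = g$frame_shape,
    lumen_radius_mm = 0.6, intima_thickness_mm = 0.15,
    media_thickness_mm = 0.08,
    sectors = list(plaque_sector("lipid", 30, 90, 0.065, 0.3)),
    ...
  )
}

# lipid + calcium two-plaque phantom on a small frame
two_plaque_spec <- function(...) {
  g <- small_geometry()
  phantom_spec(
    spacing_mm = g$spacing_mm, frame_shape = g$frame_shape,
    lumen_radius_mm = 0.6, intima_thickness_mm = 0.15,
    media_thickness_mm = 0.08,
    sectors = list(plaque_sector("lipid", 30, 90, 0.08, 0.3),
                   plaque_sector("calcium", 200, 60, 0.2, 0.35)),
    ...
  )
}

# plain vessel wall, no plaque
wall_only_spec <- function(...) {
  g <- small_geometry()
  phantom_spec(
    spacing_mm = g$spacing_mm, frame_shape = g$frame_shape,
    lumen_radius_mm = 0.6, intima_thickness_mm = 0.15,
    media_thickness_mm = 0.08, ...
  )
}

# rotate a label matrix by k*90 degrees counterclockwise (exact on the grid)
rotate_labels_90 <- function(labels, k = 1L) {
  k <- k %% 4L
  for (i in seq_len(k)) labels <- t(labels)[rev(seq_len(ncol(labels))), ]
  labels
}
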