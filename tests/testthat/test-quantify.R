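test_that("class_sectors finds sector extents and counts", {
  ph <- render_phantom(simple_lipid_spec())
  pr <- cast_rays(ph$frame)
  lip <- class_sectors(pr, "lipid")
  expect_identical(nrow(lip$sectors), 1L)
  expect_equal(arc_degrees(lip), 90, tolerance = 1)

  g <- small_geometry()
  spec2 <- phantom_spec(
    spacing_mm = g$spacing_mm, frame_shape = g$frame_shape,
    lumen_radius_mm = 0.6, intima_thickness_mm = 0.15,
    media_thickness_mm = 0.08,
    sectors = list(plaque_sector("lipid", 30, 30, 0.08, 0.3),
                   plaque_sector("lipid", 200, 40, 0.08, 0.3)))
  pr2 <- cast_rays(render_phantom(spec2)$frame)
  lip2 <- class_sectors(pr2, "lipid")
  expect_identical(nrow(lip2$sectors), 2L)
  expect_equal(sort(lip2$sectors$extent_deg), c(30, 40), tolerance = 1)
})

test_that("arcs bridge the guidewire shadow when flanked by plaque", {
  g <- small_geometry()
  spec <- phantom_spec(
    spacing_mm = g$spacing_mm, frame_shape = g$frame_shape,
    lumen_radius_mm = 0.6, intima_thickness_mm = 0.15,
    media_thickness_mm = 0.08,
    sectors = list(plaque_sector("lipid", 30, 30, 0.08, 0.3),
                   plaque_sector("lipid", 80, 25, 0.08, 0.3)),
    guidewire = c(70, 20))
  pr <- cast_rays(render_phantom(spec)$frame)
  bridged <- class_sectors(pr, "lipid", bridge_guidewire = TRUE)
  expect_identical(nrow(bridged$sectors), 1L)
  expect_true(bridged$sectors$bridged)
  expect_equal(arc_degrees(bridged), 75, tolerance = 1)
  # without bridging the two sectors stay separate
  split <- class_sectors(pr, "lipid", bridge_guidewire = FALSE)
  expect_identical(nrow(split$sectors), 2L)
  expect_equal(arc_degrees(split), 55, tolerance = 1)
})

test_that("a guidewire without plaque on both sides is not bridged", {
  g <- small_geometry()
  spec <- phantom_spec(
    spacing_mm = g$spacing_mm, frame_shape = g$frame_shape,
    lumen_radius_mm = 0.6, intima_thickness_mm = 0.15,
    media_thickness_mm = 0.08,
    sectors = list(plaque_sector("lipid", 30, 30, 0.08, 0.3)),
    guidewire = c(70, 20))
  pr <- cast_rays(render_phantom(spec)$frame)
  lip <- class_sectors(pr, "lipid", bridge_guidewire = TRUE)
  expect_equal(arc_degrees(lip), 30, tolerance = 1)
  expect_false(any(lip$sectors$bridged))
})

test_that("arc_degrees is cumulative over disjoint sectors", {
  s <- angular_sectors("lipid", c(10, 100), c(30, 40))
  expect_equal(arc_degrees(s), 70)
  expect_equal(arc_degrees(angular_sectors("lipid")), 0)
  expect_equal(arc_degrees(angular_sectors("lipid", 0, 360)), 360)
})

test_that("min_radial_gap measures cap thickness and calcium depth", {
  ph <- render_phantom(simple_lipid_spec())       # cap 65 um
  pr <- cast_rays(ph$frame)
  expect_equal(min_radial_gap(pr, "lipid"), 65, tolerance = 15)
  expect_true(is.na(min_radial_gap(pr, "calcium")))

  ph2 <- render_phantom(two_plaque_spec())        # calcium cap 200 um
  pr2 <- cast_rays(ph2$frame)
  expect_equal(min_radial_gap(pr2, "calcium"), 200, tolerance = 15)
})

test_that("guidewire rays are excluded from the minimum-gap search", {
  g <- small_geometry()
  # thin-cap lipid hidden entirely behind the guidewire wedge would bias
  # the minimum; the wedge must simply be skipped
  spec <- phantom_spec(
    spacing_mm = g$spacing_mm, frame_shape = g$frame_shape,
    lumen_radius_mm = 0.6, intima_thickness_mm = 0.15,
    media_thickness_mm = 0.08,
    sectors = list(plaque_sector("lipid", 30, 60, 0.10, 0.3)),
    guidewire = c(120, 20))
  pr <- cast_rays(render_phantom(spec)$frame)
  expect_equal(min_radial_gap(pr, "lipid"), 100, tolerance = 15)
})

test_that("max_radial_thickness reports the thickest calcium column", {
  ph <- render_phantom(two_plaque_spec())         # thickness 350 um
  pr <- cast_rays(ph$frame)
  expect_equal(max_radial_thickness(pr, "calcium"), 350, tolerance = 15)
  ph0 <- render_phantom(simple_lipid_spec())
  expect_true(is.na(max_radial_thickness(cast_rays(ph0$frame), "calcium")))
})

test_that("fibrous_cap_area matches the closed form and is monotone", {
  g <- small_geometry()
  mk <- function(cap) phantom_spec(
    spacing_mm = g$spacing_mm, frame_shape = g$frame_shape,
    lumen_radius_mm = 0.6, intima_thickness_mm = 0.15,
    media_thickness_mm = 0.08,
    sectors = list(plaque_sector("lipid", 30, 90, cap, 0.3)))
  for (cap in c(0.06, 0.12)) {
    spec <- mk(cap)
    ph <- render_phantom(spec)
    pr <- cast_rays(ph$frame)
    lip <- class_sectors(pr, "lipid")
    got <- fibrous_cap_area(ph$frame, lip)
    expect_equal(got, analytic_cap_area(spec), tolerance = 0.03)
  }
  # doubling the cap thickness at fixed arc strictly increases the area
  a1 <- local({
    ph <- render_phantom(mk(0.06))
    fibrous_cap_area(ph$frame, class_sectors(cast_rays(ph$frame), "lipid"))
  })
  a2 <- local({
    ph <- render_phantom(mk(0.12))
    fibrous_cap_area(ph$frame, class_sectors(cast_rays(ph$frame), "lipid"))
  })
  expect_gt(a2, a1)

  # no lipid -> zero area
  ph0 <- render_phantom(wall_only_spec())
  pr0 <- cast_rays(ph0$frame)
  expect_identical(fibrous_cap_area(ph0$frame,
                                    class_sectors(pr0, "lipid")), 0)
})

test_that("fibrous_cap_ratio and the LRP rule follow their definitions", {
  expect_equal(fibrous_cap_ratio(0.18, 90), 0.002)
  expect_equal(fibrous_cap_ratio(0, 45), 0)
  expect_equal(fibrous_cap_ratio(0.2, 50), 2 * fibrous_cap_ratio(0.1, 50))
  expect_error(fibrous_cap_ratio(0.1, 0), "ZeroArc")

  expect_true(classify_lrp(90))      # boundary inclusive
  expect_false(classify_lrp(89.5))
  expect_false(classify_lrp(0))
})

test_that("correspondence_score reproduces the worked example", {
  ref <- angular_sectors("lipid", 0, 112)
  pred <- angular_sectors("lipid", -6, 118)   # overlap is exactly 112
  expect_equal(round(correspondence_score(ref, pred), 3), 0.974)
  # symmetry
  expect_equal(correspondence_score(ref, pred),
               correspondence_score(pred, ref))
  # identity and disjoint cases
  expect_equal(correspondence_score(ref, ref), 1)
  far <- angular_sectors("lipid", 200, 40)
  expect_equal(correspondence_score(ref, far), 0)
  e <- angular_sectors("lipid")
  expect_error(correspondence_score(e, e), "UndefinedScore")
})

test_that("correspondence_score equals the angular Dice coefficient", {
  # brute-force oracle: indicator functions on a fine angular grid
  set.seed(4)
  grid <- seq(0, 360, by = 0.01)[-1]
  for (i in 1:10) {
    s1 <- runif(1, 0, 360); e1 <- runif(1, 10, 170)
    s2 <- runif(1, 0, 360); e2 <- runif(1, 10, 170)
    a <- angular_sectors("lipid", s1, e1)
    b <- angular_sectors("lipid", s2, e2)
    in1 <- ((grid - s1) %% 360) < e1
    in2 <- ((grid - s2) %% 360) < e2
    dice <- 2 * sum(in1 & in2) / (sum(in1) + sum(in2))
    expect_equal(correspondence_score(a, b), dice, tolerance = 1e-3)
  }
})

test_that("frame_presence reflects post-processed pixels", {
  ph <- render_phantom(simple_lipid_spec())
  expect_true(frame_presence(ph$frame, "lipid"))
  expect_false(frame_presence(ph$frame, "thrombus"))

  spec <- simple_lipid_spec(
    speckle = list(class = "calcium", n_components = 1,
                   component_area_px = 8),
    seed = 2L)
  f <- render_phantom(spec)$frame
  expect_true(frame_presence(f, "calcium"))
  expect_false(frame_presence(filter_small_components(f, 0.005), "calcium"))
})

test_that("quantify_frame handles a plaque-free wall", {
  ph <- render_phantom(wall_only_spec())
  m <- quantify_frame(ph$frame)
  expect_equal(m$lipid_arc_deg, 0)
  expect_equal(m$calcium_arc_deg, 0)
  expect_true(is.na(m$min_fct_um))
  expect_true(is.na(m$calcium_depth_um))
  expect_identical(m$fibrous_cap_area_mm2, 0)
  expect_false(m$lipid_present)
  expect_false(m$is_lrp)
})

test_that("quantify_frame is invariant to 90-degree rotation", {
  ph <- render_phantom(two_plaque_spec())
  m0 <- quantify_frame(ph$frame)
  rot <- oct_frame(rotate_labels_90(ph$frame$labels, 1),
                   spacing_mm = 0.01)
  m1 <- quantify_frame(rot)
  expect_equal(m1$lipid_arc_deg, m0$lipid_arc_deg, tolerance = 1)
  expect_equal(m1$calcium_arc_deg, m0$calcium_arc_deg, tolerance = 1)
  expect_equal(m1$min_fct_um, m0$min_fct_um, tolerance = 15)
  expect_equal(m1$calcium_thickness_um, m0$calcium_thickness_um,
               tolerance = 15)
  expect_equal(m1$fibrous_cap_area_mm2, m0$fibrous_cap_area_mm2,
               tolerance = 0.03 * m0$fibrous_cap_area_mm2)
})

test_that("the EDT fibrous-cap variant agrees with the radial default", {
  ph <- render_phantom(simple_lipid_spec())
  m_rad <- quantify_frame(ph$frame, fct_mode = "radial")
  m_edt <- quantify_frame(ph$frame, fct_mode = "edt")
  # for a concentric phantom the shortest distance is radial
  expect_equal(m_edt$min_fct_um, m_rad$min_fct_um, tolerance = 15)
  # shortest distance can never exceed the radial gap materially
  expect_lte(m_edt$min_fct_um, m_rad$min_fct_um + 15)
})

test_that("quantify_pullback emits one ordered row per frame", {
  specs <- list(simple_lipid_spec(), wall_only_spec())
  pl <- render_pullback(specs)
  tab <- quantify_pullback(pl$pullback)
  expect_identical(nrow(tab), 2L)
  expect_identical(tab$frame_index, 1:2)
  expect_identical(names(tab)[1], "frame_index")
  expect_gt(tab$lipid_arc_deg[1], 80)
  expect_equal(tab$lipid_arc_deg[2], 0)
})
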