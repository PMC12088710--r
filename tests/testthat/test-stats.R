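make_class_frame <- function(pixels, shape = c(48L, 48L), code = 6L) {
  m <- matrix(0L, shape[1], shape[2])
  m[1, 1] <- 1L  # lumen pixel keeps the frame well-formed
  if (length(pixels)) m[pixels] <- code
  oct_frame(m, spacing_mm = 0.01)
}

test_that("dice_frame scores overlap and categorizes frames", {
  a <- make_class_frame(101:200)            # 100 px
  b <- make_class_frame(151:250)            # 100 px, 50 shared
  rec <- dice_frame(a, b, "lipid")
  expect_equal(rec$dice, 0.5)
  expect_identical(rec$category, "TP")

  expect_equal(dice_frame(a, a, "lipid")$dice, 1)
  # symmetric
  expect_equal(dice_frame(b, a, "lipid")$dice, 0.5)

  empty <- make_class_frame(integer(0))
  fn <- dice_frame(a, empty, "lipid")
  expect_identical(fn$category, "FN"); expect_equal(fn$dice, 0)
  fp <- dice_frame(empty, a, "lipid")
  expect_identical(fp$category, "FP"); expect_equal(fp$dice, 0)
  tn <- dice_frame(empty, empty, "lipid")
  expect_identical(tn$category, "TN"); expect_true(is.na(tn$dice))

  other <- oct_frame(matrix(1L, 32, 32), spacing_mm = 0.01)
  expect_error(dice_frame(a, other, "lipid"), "GeometryMismatch")
})

test_that("aggregate_dice follows the all / tp_only conventions", {
  a <- make_class_frame(101:200)
  b80 <- make_class_frame(c(101:180, 301:320))  # dice 0.8 vs a
  empty <- make_class_frame(integer(0))
  recs <- list(dice_frame(a, b80, "lipid"),      # TP, dice 0.8
               dice_frame(a, empty, "lipid"),    # FN, dice 0
               dice_frame(empty, empty, "lipid")) # TN, excluded
  all_m <- aggregate_dice(recs, "all")
  expect_equal(all_m$mean, 0.4)
  expect_identical(all_m$n, 2L)
  tp_m <- aggregate_dice(recs, "tp_only")
  expect_equal(tp_m$mean, 0.8)

  expect_error(aggregate_dice(list(dice_frame(empty, empty, "lipid")),
                              "all"), "EmptySet")

  same <- list(dice_frame(a, a, "lipid"), dice_frame(b80, b80, "lipid"))
  agg <- aggregate_dice(same, "all")
  expect_equal(agg$mean, 1); expect_equal(agg$sd, 0)
})

test_that("clopper_pearson matches printed intervals and basic bounds", {
  expect_equal(round(100 * clopper_pearson(5, 14), 1), c(12.8, 64.9))
  expect_equal(round(100 * clopper_pearson(100, 102), 1), c(93.1, 99.8))
  expect_identical(clopper_pearson(0, 10)[1], 0)
  expect_identical(clopper_pearson(10, 10)[2], 1)
  expect_error(clopper_pearson(5, 0), "DomainError")
  expect_error(clopper_pearson(-1, 10), "DomainError")
})

test_that("clopper_pearson intervals contain k/n and tighten with n", {
  set.seed(21)
  for (i in 1:25) {
    n <- sample(1:500, 1)
    k <- sample(0:n, 1)
    ci <- clopper_pearson(k, n)
    expect_lte(ci[1], k / n + 1e-12)
    expect_gte(ci[2], k / n - 1e-12)
  }
  w1 <- diff(clopper_pearson(10, 20))
  w2 <- diff(clopper_pearson(100, 200))
  expect_lt(w2, w1)
})

test_that("binary_metrics reproduces the internal-test fixture table", {
  fixture <- read.csv(system.file("extdata", "internal_test_confusion.csv",
                                  package = "octquant"))
  for (i in seq_len(nrow(fixture))) {
    row <- fixture[i, ]
    bm <- binary_metrics(confusion_table(row$tp, row$fp, row$fn, row$tn))
    expect_equal(100 * bm$accuracy$estimate, row$accuracy_pct,
                 tolerance = 0.05 / row$accuracy_pct)
    expect_equal(100 * bm$sensitivity$estimate, row$sensitivity_pct,
                 tolerance = 0.05 / row$sensitivity_pct)
    expect_equal(100 * bm$specificity$estimate, row$specificity_pct,
                 tolerance = 0.05 / row$specificity_pct)
    expect_equal(100 * bm$ppv$estimate, row$ppv_pct,
                 tolerance = 0.05 / row$ppv_pct)
    expect_equal(100 * bm$npv$estimate, row$npv_pct,
                 tolerance = 0.05 / row$npv_pct)
    kap <- cohens_kappa(confusion_table(row$tp, row$fp, row$fn, row$tn))
    expect_equal(kap$estimate, row$kappa, tolerance = 0.001 / row$kappa)
  }
})

test_that("binary_metrics produces exact CI bounds and handles perfection", {
  bm <- binary_metrics(confusion_table(5, 9, 1, 203))
  expect_equal(round(100 * bm$ppv$estimate, 1), 35.7)
  expect_equal(round(100 * c(bm$ppv$ci_low, bm$ppv$ci_high), 1),
               c(12.8, 64.9))
  # all-correct table: accuracy 100% with a non-degenerate exact CI
  bm2 <- binary_metrics(confusion_table(20, 0, 0, 0))
  expect_equal(bm2$accuracy$estimate, 1)
  expect_gt(bm2$accuracy$ci_low, 0)
  expect_equal(bm2$accuracy$ci_high, 1)
  expect_null(bm2$specificity)  # zero denominator
})

test_that("cohens_kappa matches closed forms and flags degeneracy", {
  # perfect agreement
  expect_equal(cohens_kappa(confusion_table(10, 0, 0, 10))$estimate, 1)
  # independence
  expect_equal(cohens_kappa(confusion_table(25, 25, 25, 25))$estimate, 0)
  # all frames positive in both -> pe = 1
  expect_error(cohens_kappa(confusion_table(50, 0, 0, 0)),
               "DegenerateTable")
})

test_that("cohens_kappa equals the brute-force definition on random tables", {
  brute <- function(tp, fp, fn, tn) {
    n <- tp + fp + fn + tn
    po <- (tp + tn) / n
    pe <- ((tp + fp) * (tp + fn) + (fn + tn) * (fp + tn)) / n^2
    (po - pe) / (1 - pe)
  }
  set.seed(8)
  for (i in 1:200) {
    cnt <- as.vector(stats::rmultinom(1, sample(2:50, 1), rep(0.25, 4)))
    pe1 <- ((cnt[1] + cnt[2]) * (cnt[1] + cnt[3]) +
              (cnt[3] + cnt[4]) * (cnt[2] + cnt[4])) / sum(cnt)^2
    if (abs(1 - pe1) < 1e-9) next
    expect_equal(cohens_kappa(confusion_table(cnt[1], cnt[2], cnt[3],
                                              cnt[4]))$estimate,
                 brute(cnt[1], cnt[2], cnt[3], cnt[4]), tolerance = 1e-12)
  }
})

test_that("icc_absolute is exact on degenerate input and penalizes bias", {
  x <- c(10, 12, 15, 18, 22, 25, 31, 40)
  r <- icc_absolute(x, x)
  expect_equal(r$estimate, 1)

  # constant offset: absolute agreement < consistency on the same data.
  # Consistency oracle computed from the same mean squares.
  y <- x + 10
  r2 <- icc_absolute(x, y)
  m <- cbind(x, y); n <- nrow(m); k <- 2
  grand <- mean(m); row_m <- rowMeans(m); col_m <- colMeans(m)
  msr <- k * sum((row_m - grand)^2) / (n - 1)
  sse <- sum((m - outer(row_m, rep(1, k)) - outer(rep(1, n), col_m) +
                grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  icc_consistency <- (msr - mse) / (msr + (k - 1) * mse)
  expect_lt(r2$estimate, icc_consistency)
  expect_equal(icc_consistency, 1)  # offset is perfectly consistent

  expect_error(icc_absolute(1:3, 2:4), "TooFewPairs")
  expect_error(icc_absolute(1:10, 1:9), "LengthMismatch")
})

test_that("icc_absolute reproduces an independent reference implementation", {
  # 12-subject two-rater fixture; expected values frozen from an
  # independent ICC implementation (two-way random, absolute agreement,
  # single measures) run on the same numbers
  a <- c(104.9, 90.0, 113.6, 109.8, 72.5, 75.7, 106.3, 95.1, 98.8, 83.8,
         119.3, 110.9)
  b <- c(106.5, 86.6, 118.0, 119.9, 76.8, 86.7, 116.6, 97.3, 101.1, 87.1,
         120.3, 121.3)
  r <- icc_absolute(a, b)
  expect_equal(r$estimate, 0.9166719, tolerance = 1e-6)
  expect_equal(round(c(r$ci_low, r$ci_high), 2), c(0.42, 0.98))
})

test_that("bland_altman recovers bias and limits of agreement", {
  x <- c(10, 20, 30, 40)
  expect_equal(bland_altman(x, x),
               list(mean_diff = 0, sd_diff = 0, loa_low = 0, loa_high = 0,
                    n = 4L))
  off <- bland_altman(x, x + 5)
  expect_equal(off$mean_diff, 5)
  expect_equal(off$sd_diff, 0)

  set.seed(31)
  ref <- runif(1e4, 50, 150)
  pred <- ref + rnorm(1e4, mean = 2, sd = 4)
  ba <- bland_altman(ref, pred)
  expect_equal(ba$mean_diff, 2, tolerance = 0.1)
  expect_equal(ba$sd_diff, 4, tolerance = 0.05)
  expect_equal(ba$loa_low, ba$mean_diff - 1.96 * ba$sd_diff)

  expect_error(bland_altman(1, 2), "TooFewPairs")
  expect_error(bland_altman(1:3, 1:4), "LengthMismatch")
})

test_that("consensus_frames keeps only frames with agreement", {
  set.seed(5)
  n <- 392L
  p1 <- runif(n) < 0.4
  flip <- runif(n) < 0.22
  obs1 <- data.frame(frame_index = 1:n, lipid = p1)
  obs2 <- data.frame(frame_index = 1:n, lipid = xor(p1, flip))
  cons <- consensus_frames(obs1, obs2, "lipid")
  expect_identical(nrow(cons), sum(!flip))
  expect_identical(cons$consensus, p1[!flip])

  # full agreement and full disagreement
  expect_identical(nrow(consensus_frames(obs1, obs1, "lipid")), n)
  obs3 <- obs1; obs3$lipid <- !obs1$lipid
  expect_identical(nrow(consensus_frames(obs1, obs3, "lipid")), 0L)

  expect_error(consensus_frames(obs1, obs2[-1, ], "lipid"),
               "IndexMismatch")
})

test_that("mean_reference averages the two observers element-wise", {
  expect_equal(mean_reference(100, 120), 110)
  expect_equal(mean_reference(c(1, 2), c(1, 2)), c(1, 2))
  expect_equal(mean_reference(3, 8), (3 + 8) / 2)
  expect_error(mean_reference(1:3, 1:2), "LengthMismatch")
})
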