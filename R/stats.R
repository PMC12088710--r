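#' Frame-wise 2x2 confusion table
#'
#' Counts of frames where a class is present/absent in reference vs
#' prediction.
#'
#' @param tp,fp,fn,tn non-negative frame counts, total > 0.
#' @return object of class \code{confusion_table}.
#' @export
confusion_table <- function(tp, fp, fn, tn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0, tn >= 0, tp + fp + fn + tn > 0)
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn,
                 n = tp + fp + fn + tn),
            class = "confusion_table")
}

#' @export
print.confusion_table <- function(x, ...) {
  cat(sprintf("<confusion_table n=%d: TP=%d FP=%d FN=%d TN=%d>\n",
              x$n, x$tp, x$fp, x$fn, x$tn))
  invisible(x)
}

# estimate + 95% CI + bookkeeping, the common result currency of this module
.agreement_result <- function(estimate, ci_low, ci_high, n, method) {
  structure(list(estimate = estimate, ci_low = ci_low, ci_high = ci_high,
                 n = n, method = method),
            class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf("%s: %.3f (95%% CI %.3f-%.3f), n=%d\n",
              x$method, x$estimate, x$ci_low, x$ci_high, x$n))
  invisible(x)
}

#' Per-frame Dice score with TP/FP/FN/TN category
#'
#' The Dice similarity coefficient \eqn{2|A \cap B|/(|A|+|B|)} of one class
#' between a reference and a predicted mask. When the class is present in
#' exactly one of the two masks the frame is a false positive/negative and
#' is awarded a score of 0; when absent from both it is a true negative and
#' carries no score.
#'
#' @param ref,pred [oct_frame()] objects with identical geometry.
#' @param class_code class code or name.
#' @return list with \code{class_code}, \code{frame_index}, \code{dice}
#'   (\code{NA} for TN) and \code{category} (\code{"TP"}, \code{"FP"},
#'   \code{"FN"} or \code{"TN"}).
#' @export
dice_frame <- function(ref, pred, class_code) {
  stopifnot(inherits(ref, "oct_frame"), inherits(pred, "oct_frame"))
  if (!identical(ref$geometry$frame_shape, pred$geometry$frame_shape)) {
    stop("GeometryMismatchError: reference and prediction shapes differ",
         call. = FALSE)
  }
  if (is.character(class_code)) class_code <- .CODES[[class_code]]
  a <- ref$labels == class_code
  b <- pred$labels == class_code
  na <- sum(a); nb <- sum(b)
  if (na == 0L && nb == 0L) {
    cat_ <- "TN"; dice <- NA_real_
  } else if (na > 0L && nb == 0L) {
    cat_ <- "FN"; dice <- 0
  } else if (na == 0L && nb > 0L) {
    cat_ <- "FP"; dice <- 0
  } else {
    cat_ <- "TP"; dice <- 2 * sum(a & b) / (na + nb)
  }
  list(class_code = as.integer(class_code),
       frame_index = ref$frame_index, dice = dice, category = cat_)
}

#' Aggregate per-frame Dice records
#'
#' \code{mode = "all"} averages over TP, FP and FN frames (TN frames carry
#' no score and are excluded); \code{mode = "tp_only"} averages over TP
#' frames only. Both conventions are reported because published Dice scores
#' are not always explicit about which frames enter the average.
#'
#' @param records list of [dice_frame()] results (one class).
#' @param mode \code{"all"} or \code{"tp_only"}.
#' @return list with \code{mean}, \code{sd}, \code{n}.
#' @export
aggregate_dice <- function(records, mode = c("all", "tp_only")) {
  mode <- match.arg(mode)
  cats <- vapply(records, `[[`, character(1), "category")
  keep <- if (mode == "all") cats %in% c("TP", "FP", "FN") else cats == "TP"
  if (!any(keep)) {
    stop("EmptySetError: no qualifying frames for mode ", mode, call. = FALSE)
  }
  d <- vapply(records[keep], `[[`, numeric(1), "dice")
  list(mean = mean(d), sd = if (length(d) > 1L) sd(d) else 0, n = length(d))
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Computed from beta-distribution quantiles; the lower bound is 0 when
#' k = 0 and the upper bound is 1 when k = n.
#'
#' @param k number of successes (0 <= k <= n).
#' @param n number of trials (>= 1).
#' @param level confidence level (default 0.95).
#' @return numeric \code{c(lo, hi)} on the proportion scale.
#' @export
clopper_pearson <- function(k, n, level = 0.95) {
  if (n < 1 || k < 0 || k > n) {
    stop("DomainError: need 0 <= k <= n, n >= 1", call. = FALSE)
  }
  alpha <- 1 - level
  lo <- if (k == 0) 0 else qbeta(alpha / 2, k, n - k + 1)
  hi <- if (k == n) 1 else qbeta(1 - alpha / 2, k + 1, n - k)
  c(lo, hi)
}

#' Frame-wise identification metrics with exact confidence intervals
#'
#' Accuracy, sensitivity, specificity, positive and negative predictive
#' value as proportions with Clopper-Pearson 95% intervals. A metric whose
#' denominator is zero is returned as \code{NULL} inside the list.
#'
#' @param t a [confusion_table()].
#' @param level confidence level (default 0.95).
#' @return named list of \code{agreement_result} objects (proportion scale;
#'   multiply by 100 for percentages).
#' @export
binary_metrics <- function(t, level = 0.95) {
  stopifnot(inherits(t, "confusion_table"))
  one <- function(k, n, method) {
    if (n == 0) return(NULL)
    ci <- clopper_pearson(k, n, level)
    .agreement_result(k / n, ci[1L], ci[2L], n, method)
  }
  list(
    accuracy    = one(t$tp + t$tn, t$n, "accuracy"),
    sensitivity = one(t$tp, t$tp + t$fn, "sensitivity"),
    specificity = one(t$tn, t$tn + t$fp, "specificity"),
    ppv         = one(t$tp, t$tp + t$fp, "ppv"),
    npv         = one(t$tn, t$tn + t$fn, "npv")
  )
}

#' Cohen's kappa for a 2x2 frame-wise agreement table
#'
#' Chance-corrected agreement \eqn{\kappa = (p_o - p_e)/(1 - p_e)} with
#' observed agreement \eqn{p_o = (TP+TN)/n} and expected agreement
#' \eqn{p_e} from the marginals. The 95% CI is Wald-type using the
#' large-sample standard error of Fleiss, Cohen and Everitt.
#'
#' @param t a [confusion_table()].
#' @param level confidence level (default 0.95).
#' @return an \code{agreement_result}.
#' @export
cohens_kappa <- function(t, level = 0.95) {
  stopifnot(inherits(t, "confusion_table"))
  n <- t$n
  p11 <- t$tp / n; p12 <- t$fn / n; p21 <- t$fp / n; p22 <- t$tn / n
  r1 <- p11 + p12; r2 <- p21 + p22   # reference marginals
  c1 <- p11 + p21; c2 <- p12 + p22   # prediction marginals
  po <- p11 + p22
  pe <- r1 * c1 + r2 * c2
  if (abs(1 - pe) < .Machine$double.eps^0.5) {
    stop("DegenerateTableError: expected agreement is 1", call. = FALSE)
  }
  k <- (po - pe) / (1 - pe)
  # Fleiss-Cohen-Everitt (1969) large-sample variance
  A <- p11 * (1 - (r1 + c1) * (1 - k))^2 + p22 * (1 - (r2 + c2) * (1 - k))^2
  B <- (1 - k)^2 * (p12 * (c1 + r2)^2 + p21 * (c2 + r1)^2)
  C <- (k - pe * (1 - k))^2
  se <- sqrt(max(A + B - C, 0) / (n * (1 - pe)^2))
  z <- qnorm(1 - (1 - level) / 2)
  .agreement_result(k, k - z * se, k + z * se, n, "cohens_kappa")
}

#' Intraclass correlation for absolute agreement, two-way random model
#'
#' Single-measures ICC(2,1) from the two-way random-effects ANOVA mean
#' squares (subjects x raters), with the F-based confidence interval of
#' McGraw and Wong. Absolute agreement: a constant rater offset lowers the
#' coefficient, unlike the consistency variant.
#'
#' @param x,y paired measurements by the two raters (same length, >= 5
#'   pairs, finite).
#' @param level confidence level (default 0.95).
#' @return an \code{agreement_result}.
#' @export
icc_absolute <- function(x, y, level = 0.95) {
  if (length(x) != length(y)) {
    stop("LengthMismatchError: raters measured different numbers of subjects",
         call. = FALSE)
  }
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 5L) stop("TooFewPairsError: need >= 5 complete pairs", call. = FALSE)
  k <- 2
  m <- cbind(x, y)
  grand <- mean(m)
  row_m <- rowMeans(m)
  col_m <- colMeans(m)
  msr <- k * sum((row_m - grand)^2) / (n - 1)            # subjects
  msc <- n * sum((col_m - grand)^2) / (k - 1)            # raters
  sse <- sum((m - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  # McGraw-Wong F-based interval via Satterthwaite degrees of freedom
  alpha <- 1 - level
  a <- k * icc / (n * (1 - icc))
  b <- 1 + k * icc * (n - 1) / (n * (1 - icc))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  f_l <- qf(1 - alpha / 2, n - 1, v)
  f_u <- qf(1 - alpha / 2, v, n - 1)
  lo <- n * (msr - f_l * mse) /
    (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
  hi <- n * (f_u * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * f_u * msr)
  .agreement_result(icc, lo, hi, n, "icc_2_1")
}

#' Bland-Altman bias and limits of agreement
#'
#' Differences are prediction minus reference; limits of agreement are the
#' mean difference plus/minus 1.96 standard deviations.
#'
#' @param reference,prediction paired measurements (same length, >= 2
#'   complete pairs).
#' @return list with \code{mean_diff}, \code{sd_diff}, \code{loa_low},
#'   \code{loa_high}, \code{n}.
#' @export
bland_altman <- function(reference, prediction) {
  if (length(reference) != length(prediction)) {
    stop("LengthMismatchError: paired vectors differ in length",
         call. = FALSE)
  }
  ok <- is.finite(reference) & is.finite(prediction)
  d <- prediction[ok] - reference[ok]
  if (length(d) < 2L) {
    stop("TooFewPairsError: need >= 2 complete pairs", call. = FALSE)
  }
  m <- mean(d); s <- sd(d)
  list(mean_diff = m, sd_diff = s,
       loa_low = m - 1.96 * s, loa_high = m + 1.96 * s, n = length(d))
}

#' Consensus frames between two observers
#'
#' For external testing without pixel-wise labels, evaluation is restricted
#' to frames in which both observers agree on the presence or absence of
#' the class; their shared call is the consensus label.
#'
#' @param obs1,obs2 data.frames with a \code{frame_index} column and one
#'   logical/0-1 presence column per class.
#' @param class_code class column name present in both tables.
#' @return data.frame with \code{frame_index} and \code{consensus} (logical)
#'   for the agreeing frames only.
#' @export
consensus_frames <- function(obs1, obs2, class_code) {
  stopifnot(is.data.frame(obs1), is.data.frame(obs2))
  if (!setequal(obs1$frame_index, obs2$frame_index)) {
    stop("IndexMismatchError: observers scored different frame sets",
         call. = FALSE)
  }
  o1 <- obs1[order(obs1$frame_index), ]
  o2 <- obs2[order(obs2$frame_index), ]
  p1 <- as.logical(o1[[class_code]])
  p2 <- as.logical(o2[[class_code]])
  agree <- p1 == p2
  data.frame(frame_index = o1$frame_index[agree],
             consensus = p1[agree])
}

#' Mean of two observers as reference
#'
#' For continuous quantification measures in external testing, the
#' element-wise mean of the two independent assessors serves as the
#' reference value.
#'
#' @param obs1,obs2 paired numeric vectors of equal length.
#' @return numeric vector of means.
#' @export
mean_reference <- function(obs1, obs2) {
  if (length(obs1) != length(obs2)) {
    stop("LengthMismatchError: paired vectors differ in length",
         call. = FALSE)
  }
  (obs1 + obs2) / 2
}
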