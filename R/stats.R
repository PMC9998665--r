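#' Segmentation overlap metrics
#'
#' Computes the pixel confusion counts between a predicted and a true binary
#' mask and the four standard overlap metrics:
#' `dice = 2TP / (FP + 2TP + FN)`, `iou = TP / (TP + FN + FP)`,
#' `precision = TP / (TP + FP)`, `recall = TP / (TP + FN)`.
#' A zero denominator yields 0 with a warning, so corpus averages stay
#' total. Dice and IoU are tied by `dice = 2*iou / (1 + iou)`.
#'
#' @param pred,truth Logical mask matrices on the same grid.
#' @return A one-row tibble: `tp`, `fp`, `fn`, `tn`, `dice`, `iou`,
#'   `precision`, `recall`.
#' @export
overlap_metrics <- function(pred, truth) {
  pred <- stopifnot_mask(pred, "pred")
  truth <- stopifnot_mask(truth, "truth")
  same_shape(pred, truth, c("pred", "truth"))
  tp <- sum(pred & truth); fp <- sum(pred & !truth)
  fn <- sum(!pred & truth); tn <- sum(!pred & !truth)
  safe_div <- function(num, den, what) {
    if (den == 0) {
      warn(sprintf("%s undefined (zero denominator); returning 0", what))
      return(0)
    }
    num / den
  }
  tibble(tp = tp, fp = fp, fn = fn, tn = tn,
         dice = safe_div(2 * tp, fp + 2 * tp + fn, "dice"),
         iou = safe_div(tp, tp + fn + fp, "iou"),
         precision = safe_div(tp, tp + fp, "precision"),
         recall = safe_div(tp, tp + fn, "recall"))
}

#' Lin's concordance correlation coefficient
#'
#' Moment estimator `2*s_xy / (s_x^2 + s_y^2 + (mean(x) - mean(y))^2)` with
#' the 1/n (biased) variance convention of Lin's original estimator. CCC
#' penalizes both loss of correlation and location/scale shift, so
#' `|ccc| <= |pearson r|` always holds.
#'
#' @param x,y Paired numeric measurements of equal length, `n >= 2`.
#' @return Scalar in \[-1, 1\].
#' @export
ccc <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  n <- length(x)
  if (n < 2) abort("degenerate input: need n >= 2 pairs")
  mx <- mean(x); my <- mean(y)
  sxy <- mean((x - mx) * (y - my))
  sx2 <- mean((x - mx)^2); sy2 <- mean((y - my)^2)
  den <- sx2 + sy2 + (mx - my)^2
  if (den == 0) abort("degenerate input: zero variance and equal means")
  2 * sxy / den
}

#' Two-way absolute-agreement intraclass correlation, single measurement
#'
#' ICC(A,1) in McGraw-Wong terms: from the two-way ANOVA decomposition of
#' the n-subject by k-rater table,
#' `(MSR - MSE) / (MSR + (k-1)*MSE + (k/n)*(MSC - MSE))`,
#' where MSR, MSC, MSE are the subject, rater and residual mean squares.
#' This is the "two-way model, absolute agreement, single rater" ICC used
#' to compare an automatic method against a human rater; its point estimate
#' coincides for the random- and mixed-effects versions of the model.
#'
#' @param x,y Paired measurements (rater 1, rater 2) for `n >= 2` subjects.
#' @return Scalar ICC estimate.
#' @export
icc <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  n <- length(x); k <- 2
  if (n < 2) abort("degenerate input: need n >= 2 subjects")
  m <- cbind(x, y)
  grand <- mean(m)
  row_means <- rowMeans(m); col_means <- colMeans(m)
  ssr <- k * sum((row_means - grand)^2)
  ssc <- n * sum((col_means - grand)^2)
  sse <- sum((m - outer(row_means, rep(1, k)) -
                outer(rep(1, n), col_means) + grand)^2)
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  den <- msr + (k - 1) * mse + (k / n) * (msc - mse)
  if (den == 0) abort("degenerate input: zero between-subject variance")
  (msr - mse) / den
}

#' Bland-Altman bias and limits of agreement
#'
#' Differences `d = x - y`; bias is `mean(d)` and the limits of agreement
#' are `bias +/- 1.96 * sd(d)` (sample SD, n-1 denominator).
#'
#' @param x,y Paired measurements, `n >= 2`.
#' @return A one-row tibble: `n`, `bias`, `sd_diff`, `loa_low`, `loa_high`.
#' @export
bland_altman <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  if (length(x) < 2) abort("need n >= 2 pairs")
  d <- x - y
  bias <- mean(d); s <- sd(d)
  tibble(n = length(d), bias = bias, sd_diff = s,
         loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s)
}

#' Agreement between two measurement methods
#'
#' Bundles the paired-measurement statistics used to compare an automatic
#' exophthalmometry method against manual readings: Lin's CCC, the two-way
#' absolute-agreement ICC, Pearson's r, and Bland-Altman bias and limits.
#'
#' @param data A data frame of paired measurements.
#' @param x,y Column names (strings or tidy-selected bare names via `...`
#'   are not supported; pass strings) holding method 1 and method 2 values;
#'   defaults `"manual"` and `"auto"`.
#' @return Object of class `exo_agreement` with [tidy()] and [glance()]
#'   methods and an [autoplot()] (Bland-Altman / scatter).
#' @export
#' @examples
#' df <- tibble::tibble(manual = c(17, 18, 20, 16), auto = c(17.2, 18.1, 19.7, 16.4))
#' glance(agreement_report(df))
agreement_report <- function(data, x = "manual", y = "auto") {
  if (!all(c(x, y) %in% names(data)))
    abort(sprintf("columns `%s` and `%s` not found", x, y))
  xv <- data[[x]]; yv <- data[[y]]
  ok <- is.finite(xv) & is.finite(yv)
  xv <- xv[ok]; yv <- yv[ok]
  ba <- bland_altman(xv, yv)
  structure(
    list(n_pairs = length(xv), ccc = ccc(xv, yv), icc = icc(xv, yv),
         pearson_r = cor(xv, yv), bland_altman = ba,
         x = xv, y = yv, labels = c(x, y),
         conventions = list(ccc_variance = "1/n (Lin)",
                            icc_model = "two-way, absolute agreement, single measurement",
                            loa_multiplier = 1.96)),
    class = "exo_agreement")
}

#' @export
print.exo_agreement <- function(x, ...) {
  cat(sprintf("<exo_agreement> n = %d pairs (%s vs %s)\n",
              x$n_pairs, x$labels[1], x$labels[2]))
  cat(sprintf("  CCC %.4f | ICC(A,1) %.4f | r %.4f\n", x$ccc, x$icc, x$pearson_r))
  cat(sprintf("  Bland-Altman bias %.4f, LoA [%.4f, %.4f]\n",
              x$bland_altman$bias, x$bland_altman$loa_low, x$bland_altman$loa_high))
  invisible(x)
}

#' Tidy / summarize an agreement report
#'
#' `tidy()` returns one row per statistic; `glance()` one wide row.
#'
#' @param x An `exo_agreement`.
#' @param ... Unused.
#' @export
tidy.exo_agreement <- function(x, ...) {
  tibble(statistic = c("ccc", "icc", "pearson_r", "bias", "loa_low", "loa_high"),
         estimate = c(x$ccc, x$icc, x$pearson_r, x$bland_altman$bias,
                      x$bland_altman$loa_low, x$bland_altman$loa_high))
}

#' @rdname tidy.exo_agreement
#' @export
glance.exo_agreement <- function(x, ...) {
  tibble(n_pairs = x$n_pairs, ccc = x$ccc, icc = x$icc,
         pearson_r = x$pearson_r, bias = x$bland_altman$bias,
         sd_diff = x$bland_altman$sd_diff,
         loa_low = x$bland_altman$loa_low,
         loa_high = x$bland_altman$loa_high)
}

#' Evaluate segmentation over a corpus
#'
#' Applies [overlap_metrics()] to each (pred, truth) mask pair and stacks
#' the per-image rows, mirroring the usual mean (SD) reporting layout.
#'
#' @param preds,truths Lists of logical masks, pairwise on the same grid.
#' @param ids Optional character ids (defaults to the index).
#' @return Tibble with one row per image plus columns `id`.
#' @export
evaluate_segmentation <- function(preds, truths, ids = NULL) {
  if (length(preds) != length(truths))
    abort("preds and truths must have equal length")
  ids <- ids %||% as.character(seq_along(preds))
  purrr::map2(preds, truths, overlap_metrics) |>
    purrr::list_rbind() |>
    dplyr::mutate(id = ids, .before = 1)
}
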