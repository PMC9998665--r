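test_that("overlap metrics match the confusion-count formulas", {
  t1 <- matrix(FALSE, 10, 10); t1[3:7, 3:7] <- TRUE
  r <- overlap_metrics(t1, t1)
  expect_equal(unlist(r[c("dice", "iou", "precision", "recall")]),
               c(dice = 1, iou = 1, precision = 1, recall = 1))
  # TP=2, FP=2, FN=2 hand case
  pred <- matrix(FALSE, 2, 3); truth <- matrix(FALSE, 2, 3)
  truth[1, ] <- TRUE; truth[2, 1] <- TRUE       # |Y| = 4
  pred[1, 1:2] <- TRUE; pred[2, 2:3] <- TRUE    # TP 2, FP 2, FN 2
  r2 <- overlap_metrics(pred, truth)
  expect_equal(r2$dice, 0.5)
  expect_equal(r2$iou, 1 / 3)
  expect_equal(r2$precision, 0.5)
  expect_equal(r2$recall, 0.5)
  # degenerate empty prediction
  expect_warning(r3 <- overlap_metrics(matrix(FALSE, 4, 4), t1[1:4, 1:4]),
                 "precision")
  expect_equal(r3$recall, 0)
  expect_equal(r3$dice, 0)
  expect_error(overlap_metrics(matrix(TRUE, 2, 2), matrix(TRUE, 3, 3)),
               "shape mismatch")
})

test_that("dice and iou satisfy dice = 2*iou/(1+iou) on random masks", {
  set.seed(11)
  for (i in 1:500) {
    a <- matrix(runif(64) > runif(1, 0.2, 0.8), 8, 8)
    b <- matrix(runif(64) > runif(1, 0.2, 0.8), 8, 8)
    if (!any(a) && !any(b)) next
    r <- suppressWarnings(overlap_metrics(a, b))
    expect_equal(r$dice, 2 * r$iou / (1 + r$iou), tolerance = 1e-12)
  }
})

test_that("ccc implements Lin's moment estimator with 1/n variances", {
  x <- c(1, 2, 3, 4)
  expect_equal(ccc(x, x), 1)
  # frozen hand evaluation of Lin's formula
  expect_equal(ccc(x, c(1.1, 2.1, 2.9, 4.2)), 0.993117010816,
               tolerance = 1e-10)
  # location shift is penalized although correlation is perfect
  y <- x + 10
  expect_lt(ccc(x, y), 1)
  expect_equal(cor(x, y), 1)
  # symmetry and common-shift invariance
  set.seed(2)
  for (i in 1:25) {
    a <- rnorm(15); b <- rnorm(15, a)
    expect_equal(ccc(a, b), ccc(b, a), tolerance = 1e-12)
    expect_equal(ccc(a + 3.7, b + 3.7), ccc(a, b), tolerance = 1e-9)
    expect_lte(abs(ccc(a, b)), abs(cor(a, b)) + 1e-12)
  }
  expect_error(ccc(1, 1), "n >= 2")
  expect_error(ccc(c(2, 2), c(2, 2)), "degenerate")
})

test_that("icc matches an independent two-way ANOVA computed via aov", {
  expect_equal(icc(1:8, 1:8), 1)
  icc_aov <- function(x, y) {
    n <- length(x)
    df <- data.frame(score = c(x, y),
                     subject = factor(rep(seq_len(n), 2)),
                     rater = factor(rep(1:2, each = n)))
    ms <- summary(stats::aov(score ~ subject + rater, data = df))[[1]][, "Mean Sq"]
    msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
    (msr - mse) / (msr + mse + (2 / n) * (msc - mse))
  }
  set.seed(5)
  for (i in 1:20) {
    x <- rnorm(10, 10, 3)
    y <- x + rnorm(10, 0.5, 1)
    expect_equal(icc(x, y), icc_aov(x, y), tolerance = 1e-10)
  }
})

test_that("icc matches frozen external ICC(A,1) reference values", {
  # reference values computed once with an independent implementation of
  # the two-way absolute-agreement single-measurement ICC
  x1 <- c(11.30654604856193, 11.536951353522728, 14.649970868181921,
          11.277855739781607, 9.5037328439754081, 14.765522514218716,
          8.4504005955054353, 12.318299007933833, 7.3412186532983368,
          9.6744483223650235)
  y1 <- c(10.916303046540481, 12.224366416796171, 14.815367915155827,
          12.787141016132445, 9.1582480752231561, 14.528413608572915,
          7.686988312181283, 12.944587083587928, 6.3531793000673833,
          12.131224473218147)
  expect_equal(icc(x1, y1), 0.919886617694773, tolerance = 1e-8)
  x2 <- c(6.3903448626906991, 6.1004315338715838, 9.3864933755124547,
          7.6286940088625856, 6.4570220584078619, 14.122362127776377,
          12.043849092818981, 11.083300764328071, 12.864217046071982,
          10.297672281296455)
  y2 <- c(5.8332033686945381, 6.8964339243817134, 8.7983176491195323,
          7.1101028533851958, 5.8764961867130197, 13.975196419887938,
          12.890161111693407, 10.661876901453883, 13.30728353853045,
          11.109427110939981)
  expect_equal(icc(x2, y2), 0.980005537867440, tolerance = 1e-8)
  x3 <- c(12.692828146597469, 9.6425012592253356, 11.969143829777627,
          5.8146817950897578, 10.660407953061451, 14.374263985362852,
          6.0613602853001431, 8.9907155191198438, 11.377431603413902,
          16.681294707618445)
  y3 <- c(12.778844644637083, 9.0760638807962302, 12.326590854576017,
          5.5176722506351892, 11.150349662946661, 13.236337609203385,
          6.3399245331174816, 9.9989641658954227, 12.028818756886578,
          18.535785942618002)
  expect_equal(icc(x3, y3), 0.972319615592017, tolerance = 1e-8)
})

test_that("icc behaves like an absolute-agreement index", {
  # independent raters: near-zero ICC under the null
  set.seed(99)
  x <- rnorm(1000); y <- rnorm(1000)
  expect_lt(abs(icc(x, y)), 0.1)
  # growing inter-rater bias lowers ICC at fixed noise
  set.seed(17)
  base <- rnorm(50, 20, 4)
  noise <- rnorm(50, 0, 0.5)
  iccs <- sapply(c(0, 2, 4, 8), function(b) icc(base, base + noise + b))
  expect_true(all(diff(iccs) < 0))
  expect_error(icc(c(1, 1), c(1, 1)), "degenerate")
})

test_that("bland_altman returns bias and 1.96-sd limits", {
  x <- c(1, 2, 3); y <- c(0, 2, 4)
  ba <- bland_altman(x, y)
  expect_equal(ba$bias, 0)
  expect_equal(ba$sd_diff, 1)
  expect_equal(c(ba$loa_low, ba$loa_high), c(-1.96, 1.96))
  ba2 <- bland_altman(c(1, 2, 3), c(0.5, 1.5, 2.5))
  expect_equal(ba2$bias, 0.5)
  expect_equal(c(ba2$loa_low, ba2$loa_high), c(0.5, 0.5))
  ba3 <- bland_altman(x, x)
  expect_equal(unlist(ba3[c("bias", "loa_low", "loa_high")]),
               c(bias = 0, loa_low = 0, loa_high = 0))
  expect_error(bland_altman(1, 2), "n >= 2")
})

test_that("agreement_report bundles the statistics with tidy methods", {
  set.seed(4)
  manual <- rnorm(30, 18, 2.8)
  df <- tibble::tibble(manual = manual, auto = manual + rnorm(30, 0.5, 0.4))
  rep <- agreement_report(df)
  g <- glance(rep)
  expect_equal(g$n_pairs, 30)
  expect_equal(g$ccc, ccc(df$manual, df$auto))
  expect_equal(g$icc, icc(df$manual, df$auto))
  expect_lte(abs(g$ccc), abs(g$pearson_r) + 1e-12)
  expect_true(g$loa_low <= g$bias && g$bias <= g$loa_high)
  td <- tidy(rep)
  expect_named(td, c("statistic", "estimate"))
  expect_equal(nrow(td), 6)
  p <- autoplot(rep)
  expect_s3_class(p, "ggplot")
  expect_s3_class(autoplot(rep, type = "scatter"), "ggplot")
})
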