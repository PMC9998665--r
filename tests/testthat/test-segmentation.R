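test_that("dice_loss implements the soft Dice relaxation", {
  t <- matrix(FALSE, 10, 10); t[3:7, 3:7] <- TRUE
  expect_equal(dice_loss(t * 1, t), 0)                  # identity
  p <- matrix(0, 10, 10); p[8:10, 8:10] <- 1            # disjoint, nonempty
  expect_equal(dice_loss(p, t), 1)
  # |X|=4, |Y|=4, |X∩Y|=2 -> 1 - 4/8 = 0.5
  truth <- matrix(0, 2, 3); truth[1, ] <- 1; truth[2, 1] <- 1
  pred <- matrix(0, 2, 3); pred[1, 1:2] <- 1; pred[2, 2:3] <- 1
  expect_equal(dice_loss(pred, truth > 0), 0.5)
  expect_error(dice_loss(matrix(0.5, 2, 2), matrix(TRUE, 3, 3)),
               "shape mismatch")
  expect_warning(z <- dice_loss(matrix(0, 4, 4), matrix(FALSE, 4, 4)),
                 "empty")
  expect_equal(z, 0)
})

test_that("dice_loss on hard masks equals 1 - Dice and is symmetric", {
  set.seed(8)
  for (i in 1:50) {
    a <- matrix(runif(100) > 0.6, 10, 10)
    b <- matrix(runif(100) > 0.6, 10, 10)
    if (!any(a) || !any(b)) next
    expect_equal(dice_loss(a * 1, b), 1 - overlap_metrics(a, b)$dice,
                 tolerance = 1e-12)
    expect_equal(dice_loss(a * 1, b), dice_loss(b * 1, a), tolerance = 1e-12)
  }
})

test_that("build_unetpp is seed-deterministic with a fixed parameter count", {
  cfg <- seg_train_config(depth = 3, base_channels = 8, seed = 7)
  m1 <- build_unetpp(cfg)
  m2 <- build_unetpp(cfg)
  expect_identical(m1$params, m2$params)
  expect_identical(m1$n_parameters, m2$n_parameters)
  m3 <- build_unetpp(seg_train_config(depth = 3, base_channels = 8, seed = 8))
  expect_false(identical(m1$params$x_0_0$s1$W, m3$params$x_0_0$s1$W))
  expect_identical(m3$n_parameters, m1$n_parameters)
  expect_error(seg_train_config(depth = 1), "depth")
  expect_error(seg_train_config(learning_rate = 0), "learning_rate")
  expect_error(seg_train_config(lr_decay_per_epoch = 1.5), "decay")
  expect_error(seg_train_config(deep_supervision = TRUE), "not supported")
})

test_that("forward pass maps any 64x64 input to probabilities on its grid", {
  cfg <- seg_train_config(depth = 3, base_channels = 8, seed = 7)
  model <- build_unetpp(cfg)
  sl <- ct_slice(matrix(0, 64, 64), "axial")
  sr <- segment_eyes(sl, model)
  expect_equal(dim(sr$probability), c(64, 64))
  expect_true(all(sr$probability >= 0 & sr$probability <= 1))
  expect_equal(sr$mask, sr$probability >= 0.5)
  expect_equal(sr$source, "unetpp")
  # non-divisible input is reflection-padded and cropped back
  sl2 <- ct_slice(matrix(runif(60 * 50) * 255, 60, 50), "axial")
  sr2 <- segment_eyes(sl2, model)
  expect_equal(dim(sr2$probability), c(60, 50))
  # the raw forward refuses non-divisible grids with advice
  expect_error(
    exoct:::unetpp_fwd(model$params, matrix(0, 60 * 50, 1), 60, 50, 3, FALSE),
    "divisible")
})

test_that("backpropagation matches numerical gradients on a tiny net", {
  cfg <- seg_train_config(depth = 2, base_channels = 2, seed = 5)
  model <- build_unetpp(cfg)
  h <- 8; w <- 8
  set.seed(42)
  x <- matrix(runif(h * w), h * w, 1)
  t <- matrix(runif(h * w) > 0.6, h, w)
  lossfun <- function(params) {
    fwd <- exoct:::unetpp_fwd(params, x, h, w, 2, TRUE)
    exoct:::dice_loss_grad(fwd$p, as.numeric(t))$loss
  }
  fwd <- exoct:::unetpp_fwd(model$params, x, h, w, 2, TRUE)
  lg <- exoct:::dice_loss_grad(fwd$p, as.numeric(t))
  g <- exoct:::unetpp_bwd(model$params, fwd, matrix(lg$grad, ncol = 1),
                          h, w, 2)
  eps <- 1e-6
  for (nm in c("x_0_0", "x_1_0", "x_0_1")) for (s in c("s1", "s2")) {
    for (field in c("W", "gamma", "beta")) {
      v <- model$params[[nm]][[s]][[field]]
      for (k in sample(length(v), min(3, length(v)))) {
        pp <- model$params
        pp[[nm]][[s]][[field]][k] <- pp[[nm]][[s]][[field]][k] + eps
        lp <- lossfun(pp)
        pp[[nm]][[s]][[field]][k] <- pp[[nm]][[s]][[field]][k] - 2 * eps
        lm <- lossfun(pp)
        num <- (lp - lm) / (2 * eps)
        expect_equal(g[[nm]][[s]][[field]][k], num, tolerance = 1e-4)
      }
    }
  }
})

test_that("training bookkeeping: history length, determinism, loss trend", {
  mk <- function(seeds) lapply(seeds, function(s) {
    ph <- render_phantom(random_phantom_spec("axial", seed = s, size = 32,
                                             noise_sd = 0))
    list(image = ph$slice, mask = ph$eye_mask_true)
  })
  train <- mk(1:6)
  cfg1 <- seg_train_config(learning_rate = 0.01, depth = 2, base_channels = 4,
                           epochs = 1, batch_size = 2, seed = 3)
  expect_warning(fit1 <- train_segmenter(train, list(), cfg1),
                 "validation set empty")
  expect_equal(nrow(fit1$history), 1)
  cfg <- seg_train_config(learning_rate = 0.02, depth = 2, base_channels = 4,
                          epochs = 10, batch_size = 2, seed = 3)
  fit_a <- train_segmenter(train, mk(50), cfg)
  fit_b <- train_segmenter(train, mk(50), cfg)
  expect_identical(fit_a$history, fit_b$history)
  expect_equal(fit_a$history$lr,
               0.02 * 0.99^(0:9), tolerance = 1e-12)
  # loss trend decreases on noise-free phantoms
  expect_lt(median(utils::tail(fit_a$history$train_loss, 3)),
            median(utils::head(fit_a$history$train_loss, 3)))
})

test_that("oracle and threshold segmenters pass through as documented", {
  s <- render_phantom(random_phantom_spec("axial", seed = 12, size = 64,
                                          noise_sd = 0))
  sr <- segment_eyes(s$slice, oracle_segmenter(s$eye_mask_true))
  expect_identical(sr$mask, s$eye_mask_true)
  expect_equal(sr$source, "oracle")
  # measurement with the oracle mask hits the truth within the pixel budget
  m <- measure_slice(s$slice, sr$mask,
                     rim_config(min_component_area = 6))
  expect_lt(max(abs(m$distances$distance_px - unname(s$distance_true_px))), 3)
  # degenerate: empty oracle mask fails downstream with a clear error
  empty <- matrix(FALSE, 64, 64)
  sr0 <- segment_eyes(s$slice, oracle_segmenter(empty))
  expect_error(measure_slice(s$slice, sr0$mask,
                             rim_config(min_component_area = 6)),
               "no eye|expected two eyes")
  # threshold fallback recovers the globe band on noise-free phantoms
  srt <- segment_eyes(s$slice, threshold_segmenter(149, 151))
  expect_equal(srt$source, "threshold_fallback")
  expect_gt(overlap_metrics(srt$mask, s$eye_mask_true)$dice, 0.99)
})
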