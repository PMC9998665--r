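#!/usr/bin/env Rscript
# exoct — automatic exophthalmometry on 2D orbital CT slices.
# Usage: exoct <verb> [options]; verbs: phantom train rim measure agree evalseg

suppressPackageStartupMessages({
  library(optparse)
  library(exoct)
})

argv <- commandArgs(trailingOnly = TRUE)
if (length(argv) >= 1 && argv[1] %in% c("--version", "-V")) {
  cat("exoct", as.character(packageVersion("exoct")), "\n")
  quit(status = 0)
}
verbs <- c("phantom", "train", "rim", "measure", "agree", "evalseg")
if (length(argv) < 1 || !argv[1] %in% verbs) {
  cat("usage: exoct <", paste(verbs, collapse = "|"), "> [options]\n")
  quit(status = if (length(argv) && argv[1] %in% c("-h", "--help")) 0 else 2)
}
verb <- argv[1]
rest <- argv[-1]

opt_view <- make_option("--view", default = "axial",
                        help = "axial or sagittal [%default]")
opt_seed <- make_option("--seed", type = "integer", default = 1)
opt_out <- make_option("--out", default = NULL, help = "output path")

run <- switch(verb,
  phantom = function() {
    o <- parse_args(OptionParser(option_list = list(
      opt_view, opt_seed, opt_out,
      make_option("--n", type = "integer", default = 20),
      make_option("--size", type = "integer", default = 256),
      make_option("--noise-sd", type = "double", default = 5, dest = "noise_sd"),
      make_option("--watermarks", type = "integer", default = 0))), rest)
    stopifnot(!is.null(o$out))
    samples <- phantom_corpus(o$n, o$view, seed = o$seed, size = o$size,
                              noise_sd = o$noise_sd, watermarks = o$watermarks)
    for (i in seq_along(samples))
      write_phantom(samples[[i]], o$out, sprintf("%s_%03d", o$view, i))
    cat("wrote", length(samples), "phantoms to", o$out, "\n")
  },
  train = function() {
    o <- parse_args(OptionParser(option_list = list(
      opt_view, opt_seed, opt_out,
      make_option("--manifest", default = NULL,
                  help = "CSV with image_path, mask_path columns"),
      make_option("--epochs", type = "integer", default = 200),
      make_option("--lr", type = "double", default = 1e-4),
      make_option("--depth", type = "integer", default = 5),
      make_option("--base-channels", type = "integer", default = 32,
                  dest = "base_channels"),
      make_option("--val-frac", type = "double", default = 0.2,
                  dest = "val_frac"))), rest)
    stopifnot(!is.null(o$manifest), !is.null(o$out))
    man <- read.csv(o$manifest)
    pairs <- lapply(seq_len(nrow(man)), function(i) list(
      image = read_ct_png(man$image_path[i], o$view)$pixels,
      mask = read_mask_png(man$mask_path[i])))
    n_val <- max(1, round(o$val_frac * length(pairs)))
    idx <- seq_along(pairs)
    val <- pairs[utils::tail(idx, n_val)]
    fit <- train_segmenter(pairs[utils::head(idx, -n_val)], val,
                           seg_train_config(learning_rate = o$lr,
                                            epochs = o$epochs,
                                            depth = o$depth,
                                            base_channels = o$base_channels,
                                            seed = o$seed))
    saveRDS(fit, o$out)
    cat("checkpoint written to", o$out, "; best val loss",
        format(min(fit$history$val_loss)), "\n")
  },
  rim = function() {
    o <- parse_args(OptionParser(option_list = list(
      opt_view, opt_out,
      make_option("--image", default = NULL),
      make_option("--threshold", type = "double", default = 200),
      make_option("--min-area", type = "double", default = 100,
                  dest = "min_area"),
      make_option("--opening-radius", type = "integer", default = 1,
                  dest = "opening_radius"))), rest)
    stopifnot(!is.null(o$image), !is.null(o$out))
    sl <- read_ct_png(o$image, o$view)
    cfg <- rim_config(o$threshold, o$opening_radius, o$min_area)
    rim <- extract_rim_mask(sl, cfg)
    ap <- if (o$view == "axial") axial_rim_apexes(rim) else sagittal_rim_apexes(rim)
    write_png8(rim, o$out)
    jsonlite::write_json(
      list(apex_a = ap$apex_a, apex_b = ap$apex_b,
           region_a = ap$region_a, region_b = ap$region_b,
           config = unclass(cfg)),
      sub("\\.png$", ".json", o$out), auto_unbox = TRUE, digits = NA)
    cat("rim mask:", o$out, "\n")
  },
  measure = function() {
    o <- parse_args(OptionParser(option_list = list(
      opt_view, opt_out,
      make_option("--image", default = NULL),
      make_option("--model", default = NULL, help = "trained checkpoint (rds)"),
      make_option("--eye-mask", default = NULL, dest = "eye_mask"),
      make_option("--spacing", type = "double", default = NA),
      make_option("--overlay", default = NULL))), rest)
    stopifnot(!is.null(o$image), !is.null(o$out))
    sl <- read_ct_png(o$image, o$view,
                      pixel_spacing_mm = if (is.na(o$spacing)) NULL else o$spacing)
    mask <- if (!is.null(o$eye_mask)) read_mask_png(o$eye_mask)
            else segment_eyes(sl, readRDS(o$model))$mask
    m <- measure_slice(sl, mask)
    write_measurement_json(m, o$out)
    if (!is.null(o$overlay)) {
      p <- autoplot(m)
      ggplot2::ggsave(o$overlay, p, width = 6, height = 6, dpi = 120)
    }
    print(m)
  },
  agree = function() {
    o <- parse_args(OptionParser(option_list = list(
      opt_out,
      make_option("--pairs", default = NULL,
                  help = "CSV with id, manual_mm, auto_mm"))), rest)
    stopifnot(!is.null(o$pairs), !is.null(o$out))
    df <- read.csv(o$pairs)
    rep <- agreement_report(df, x = "manual_mm", y = "auto_mm")
    out <- c(as.list(glance(rep)), list(conventions = rep$conventions))
    jsonlite::write_json(out, o$out, auto_unbox = TRUE, digits = NA)
    print(rep)
  },
  evalseg = function() {
    o <- parse_args(OptionParser(option_list = list(
      opt_out,
      make_option("--pred-dir", default = NULL, dest = "pred_dir"),
      make_option("--truth-dir", default = NULL, dest = "truth_dir"))), rest)
    stopifnot(!is.null(o$pred_dir), !is.null(o$truth_dir), !is.null(o$out))
    files <- sort(list.files(o$pred_dir, "\\.png$"))
    preds <- lapply(file.path(o$pred_dir, files), read_mask_png)
    truths <- lapply(file.path(o$truth_dir, files), read_mask_png)
    res <- evaluate_segmentation(preds, truths, ids = files)
    write.csv(res, o$out, row.names = FALSE)
    means <- colMeans(res[c("dice", "iou", "precision", "recall")])
    sds <- apply(res[c("dice", "iou", "precision", "recall")], 2, sd)
    cat(sprintf("%s: %.4f (%.4f)\n", names(means), means, sds), sep = "")
  })

run()
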