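#' Two-stage pipeline configuration
#'
#' Controls the coarse-to-fine inference procedure: the common stage grid
#' resolution (144^3 at scan scale, 48^3 at desk scale), the 5 mm padding of
#' region-of-interest boxes, and the iterative border-correction rule — if
#' any predicted voxel lies within `border_margin_voxels` of the stage-2 grid
#' border, a mesh is extracted from the voxel prediction, its world bounds
#' padded by `roi_pad_mm`, and the crop-predict step repeated until the mesh
#' bounds change by less than `convergence_mm` on every coordinate or
#' `max_refinement_iterations` is reached.
#'
#' @param stage_resolution integer length-3 stage grid.
#' @param roi_pad_mm padding around detected bounds, mm.
#' @param border_margin_voxels border proximity that triggers refinement.
#' @param convergence_mm bound-change convergence threshold, mm (max absolute
#'   change over the six bound coordinates).
#' @param max_refinement_iterations hard iteration cap (>= 1).
#' @param threshold probability binarization threshold.
#' @param hu_window intensity normalization window.
#' @return a `PipelineConfig`.
#' @export
pipeline_config <- function(stage_resolution = c(144L, 144L, 144L),
                            roi_pad_mm = 5, border_margin_voxels = 5L,
                            convergence_mm = 2, max_refinement_iterations = 20L,
                            threshold = 0.5, hu_window = c(-200, 2500)) {
  if (roi_pad_mm <= 0 || convergence_mm <= 0 || border_margin_voxels <= 0)
    stop("pipeline thresholds must be positive")
  if (max_refinement_iterations < 1L)
    stop("max_refinement_iterations must be >= 1")
  structure(list(stage_resolution = as.integer(stage_resolution),
                 roi_pad_mm = roi_pad_mm,
                 border_margin_voxels = as.integer(border_margin_voxels),
                 convergence_mm = convergence_mm,
                 max_refinement_iterations = as.integer(max_refinement_iterations),
                 threshold = threshold, hu_window = hu_window),
            class = "PipelineConfig")
}

#' Desk-scale pipeline configuration (48^3 stages)
#' @param ... overrides passed to [pipeline_config()].
#' @export
pipeline_config_desk <- function(...) {
  pipeline_config(stage_resolution = c(48L, 48L, 48L), ...)
}

#' Stratified train/validation/test split
#'
#' Assigns cases to train/validation/test with the target ratios applied
#' separately inside every stratum (dental status), so each status is
#' represented in each split. Rounding rule: `round(validation_ratio * n)`
#' cases to validation, `round(test_ratio * n)` to test (each with a floor of
#' one case, so small strata still reach every split), remainder to train.
#' The assignment is deterministic for a given seed and is reused across the
#' O / Class III / Class V variants of a case (the split is on cases, not on
#' variants).
#'
#' @param case_table data.frame with columns `case` (id) and `stratum`.
#' @param ratios length-3 (train, validation, test) fractions summing to 1.
#' @param seed integer seed.
#' @return a `SplitAssignment` data.frame with columns `case`, `stratum`,
#'   `split`.
#' @export
stratified_split <- function(case_table, ratios = c(0.7, 0.1, 0.2),
                             seed = 1L) {
  stopifnot(all(c("case", "stratum") %in% names(case_table)))
  if (abs(sum(ratios) - 1) > 1e-6) stop("ratios must sum to 1")
  set.seed(seed)
  out <- lapply(split(case_table, case_table$stratum), function(tb) {
    n <- nrow(tb)
    n_val <- max(1L, as.integer(round(ratios[2] * n)))
    n_test <- max(1L, as.integer(round(ratios[3] * n)))
    n_train <- n - n_val - n_test
    if (n_train < 1L || n_val < 1L || n_test < 1L)
      stop("stratum '", tb$stratum[1], "' has too few cases (", n,
           ") to appear in every split")
    lab <- sample(c(rep("train", n_train), rep("validation", n_val),
                    rep("test", n_test)))
    data.frame(case = tb$case, stratum = tb$stratum, split = lab)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res <- res[order(match(res$case, case_table$case)), ]
  rownames(res) <- NULL
  class(res) <- c("SplitAssignment", "data.frame")
  res
}

# run a predictor (UNet3D or function) on a normalized stage-grid image
run_predictor <- function(predictor, image, threshold) {
  if (inherits(predictor, "UNet3D"))
    return(predict_volume(predictor, image, threshold = threshold))
  res <- predictor(image)
  stopifnot(is_label(res))
  res
}

union_channels <- function(mask) {
  d <- mask$data
  if (length(dim(d)) == 4L) d <- apply(d, 1:3, max)
  label_volume(d, spacing = mask$spacing, origin = mask$origin)
}

touches_border <- function(mask, margin) {
  d <- mask$data
  if (length(dim(d)) == 4L) d <- apply(d, 1:3, max)
  dm <- dim(d)
  idx <- which(d != 0L, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(FALSE)
  any(idx <= margin) ||
    any(sweep(idx, 2, dm, "-") >= -(margin - 1L))
}

not_detected <- function(stage, message) {
  structure(list(detected = FALSE, stage = stage, message = message,
                 labels = NULL, refinement_iterations = 0L, final_box = NULL,
                 log = list()),
            class = "InferenceResult")
}

#' @export
print.InferenceResult <- function(x, ...) {
  if (!x$detected) {
    cat("InferenceResult: no mandible detected (", x$stage, "): ",
        x$message, "\n", sep = "")
  } else {
    cat(sprintf("InferenceResult: detected, %d refinement iteration(s)\n",
                x$refinement_iterations))
  }
  invisible(x)
}

#' Two-stage coarse-to-fine inference
#'
#' Stage 1 predicts on the whole field of view resampled to the stage
#' resolution; the world bounding box of its prediction, padded by
#' `roi_pad_mm`, defines the region of interest. Stage 2 predicts on the
#' cropped, resampled region; if foreground touches the grid border the
#' box is iteratively refined from the predicted mesh bounds (see
#' [pipeline_config()]). The final prediction is resampled back onto the
#' native grid of the input image. An empty prediction at either stage
#' yields a structured "not detected" result rather than an error.
#'
#' The initial stage-1 box is computed once, so it is identical whichever
#' second-stage variant model is applied.
#'
#' @param image native-resolution `ImageVolume`.
#' @param stage1,stage2 predictors: either trained `UNet3D` networks or
#'   functions mapping a normalized stage-grid `ImageVolume` to a
#'   `LabelVolume` (useful as stubs when testing the control flow).
#' @param config a [pipeline_config()].
#' @return an `InferenceResult`: `detected`, `labels` (native-grid
#'   `LabelVolume`, possibly multi-channel), `labels_roi` (stage-grid),
#'   `refinement_iterations`, `final_box`, and a per-iteration `log`.
#' @export
run_two_stage <- function(image, stage1, stage2,
                          config = pipeline_config_desk()) {
  res <- config$stage_resolution
  norm1 <- resample(normalize_intensity(image, config$hu_window), res,
                    mode = "trilinear")
  m1 <- run_predictor(stage1, norm1, config$threshold)
  if (sum(m1$data) == 0L)
    return(not_detected("stage1", "empty first-stage prediction"))
  box <- pad_box(world_bounds(union_channels(m1)), config$roi_pad_mm)

  iter <- 0L
  prev_bounds <- NULL
  pred <- NULL
  logs <- list()
  repeat {
    iter <- iter + 1L
    crop <- crop_world(image, box)
    norm2 <- resample(normalize_intensity(crop, config$hu_window), res,
                      mode = "trilinear")
    pred <- run_predictor(stage2, norm2, config$threshold)
    if (sum(pred$data) == 0L)
      return(not_detected("stage2", "empty second-stage prediction"))
    touches <- touches_border(pred, config$border_margin_voxels)
    logs[[iter]] <- list(iteration = iter, box = box,
                         touches_border = touches)
    if (!touches) break
    mesh <- extract_mesh(union_channels(pred))
    b <- c(apply(mesh$vertices, 2, min), apply(mesh$vertices, 2, max))
    logs[[iter]]$mesh_bounds <- b
    if (!is.null(prev_bounds) &&
        max(abs(b - prev_bounds)) < config$convergence_mm) break
    if (iter >= config$max_refinement_iterations) break
    prev_bounds <- b
    box <- pad_box(world_box(b[1:3], b[4:6]), config$roi_pad_mm)
  }
  native <- resample_to_grid(pred, image)
  structure(list(detected = TRUE, labels = native, labels_roi = pred,
                 refinement_iterations = iter, final_box = box,
                 stage1_mask = m1, log = logs),
            class = "InferenceResult")
}

#' Train the full two-stage pipeline on a cohort
#'
#' Convenience wrapper: trains the first-stage localization model (original
#' ground truth, whole field of view) and one second-stage model of the
#' requested variant, both with the same seed and the same split.
#'
#' @param cases list of phantom cases.
#' @param split a `SplitAssignment`.
#' @param variant second-stage variant (`"O"`, `"cl3"`, `"cl5"`, `"multi"`).
#' @param config a `NetConfig` for the shared trunk architecture (its
#'   `out_channels` is adapted per stage).
#' @param tc a [train_config()].
#' @param ac optional [augment_config()].
#' @param seed integer seed.
#' @return list with `stage1`, `stage2` (trained nets) and their histories.
#' @export
train_two_stage <- function(cases, split, variant = "multi",
                            config = net_config_desk(), tc = train_config(),
                            ac = NULL, seed = 1L) {
  cfg1 <- net_config(config$input_shape, config$depth, config$base_channels,
                     out_channels = 1L,
                     convs_per_block = config$convs_per_block)
  cfg2 <- net_config(config$input_shape, config$depth, config$base_channels,
                     out_channels = if (variant == "multi") 3L else 1L,
                     convs_per_block = config$convs_per_block)
  # the first stage only localizes the mandible for the crop box, so it can
  # stop at a lower validation Dice than the detail stage
  tc1 <- tc
  tc1$stop_target <- min(tc$stop_target, 0.85)
  s1 <- train_stage(cases, split, stage = "first", variant = "O",
                    config = cfg1, tc = tc1, ac = ac, seed = seed)
  s2 <- train_stage(cases, split, stage = "second", variant = variant,
                    config = cfg2, tc = tc, ac = ac, seed = seed + 1L)
  list(stage1 = s1$net, stage2 = s2$net, history_stage1 = s1$history,
       history_stage2 = s2$history)
}
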