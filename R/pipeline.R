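# ---------------------------------------------------------------------------
# End-to-end orchestration: phantom cohort -> scan-level split -> scale fit
# -> training -> prediction on test scans -> inverse normalization ->
# strain tables (predicted vs reference) -> agreement report.
# ---------------------------------------------------------------------------

# pack a phantom scan into network tensors: input (1,T,H,W), target
# (2,T,H,W) normalized through `scale`
pack_sample <- function(scan, scale) {
  m <- scan$cine$frames                       # (H, W, T)
  d <- dim(m)
  input <- array(aperm(m, c(3, 1, 2)), dim = c(1, d[3], d[1], d[2]))
  disp <- attach_scale(scan$displacement, scale)
  tg <- array(0, dim = c(2, d[3], d[1], d[2]))
  tg[1, , , ] <- aperm(disp$normalized_x, c(3, 1, 2))
  tg[2, , , ] <- aperm(disp$normalized_y, c(3, 1, 2))
  list(input = input, target = tg, scan_id = scan$cine$scan_id)
}

#' Default phantom specification for desk-scale experiments
#'
#' A 32x32, 8-frame miniature of the full-resolution annulus phantom: same
#' physical radii (6-12 mm) at 1 mm/px instead of 0.25 mm/px.
#'
#' @param grid_size,n_frames image size and frame count.
#' @param ... further [phantom_spec] overrides.
#' @return a [phantom_spec].
#' @export
small_phantom_spec <- function(grid_size = 32, n_frames = 8, ...) {
  phantom_spec(grid_size = grid_size, n_frames = n_frames,
               pixel_spacing = 128 / grid_size * 0.25,
               peak_frame = round((n_frames - 1) / 2), ...)
}

#' Run the full phantom-to-agreement pipeline
#'
#' Generates a cohort of synthetic cine scans with analytic reference
#' displacement, splits them at the scan level, fits the displacement
#' normalization on the training scans, trains the requested network,
#' predicts the held-out test scans, inverts the normalization, computes
#' segment strain for prediction and reference, and assembles the agreement
#' report. With `out_dir` set, volumes (NIfTI), tables (CSV), the training
#' history and the report (JSON) are written there.
#'
#' @param n_scans cohort size (>= 3).
#' @param base_spec [phantom_spec] for the cohort; default
#'   [small_phantom_spec()].
#' @param variant `"myonet"` or `"resmyonet"`.
#' @param base_channels first-level channels.
#' @param epochs training epochs.
#' @param seed master seed (phantom cohort, split, initialization, training).
#' @param scale_margin relative pad on the fitted `d_max`.
#' @param out_dir optional output directory.
#' @param train_cfg optional [train_config] overriding the defaults derived
#'   from `epochs`/`seed`.
#' @return list: `report` ([agreement_report]), `history`, `best_epoch`,
#'   `model`, `scale`, `split`, `test` (per-test-scan detail with predicted
#'   and reference strain tables and the analytic truth).
#' @export
run_pipeline <- function(n_scans = 8, base_spec = small_phantom_spec(),
                         variant = c("myonet", "resmyonet"),
                         base_channels = 8, epochs = 30, seed = 1L,
                         scale_margin = 0.1, out_dir = NULL,
                         train_cfg = NULL) {
  variant <- match.arg(variant)
  scans <- make_phantom_cohort(n_scans, base_spec, seed = seed)
  ids <- vapply(scans, function(s) s$cine$scan_id, character(1))
  split <- split_scans(ids, seed = seed)
  by_set <- function(set) scans[ids %in% split[[set]]]
  scale <- fit_scale(lapply(by_set("train"), `[[`, "displacement"),
                     margin = scale_margin)
  data <- list(train = lapply(by_set("train"), pack_sample, scale = scale),
               val = lapply(by_set("val"), pack_sample, scale = scale),
               scale = scale)
  cfg <- if (is.null(train_cfg))
    train_config(epochs = epochs, seed = seed) else train_cfg
  net_cfg <- network_config(variant, base_channels = base_channels, seed = seed)
  model <- build_network(net_cfg)
  fit <- train_model(model, data, cfg)

  test_detail <- lapply(by_set("test"), function(scan) {
    ref <- attach_scale(scan$displacement, scale)
    pred <- predict_displacement(fit$model, scan$cine, scale)
    mask <- ref$foreground_mask[, , 1] * 1
    strain_pred <- strain_analysis(pred, mask = mask)
    strain_ref <- strain_analysis(ref, mask = mask)
    pk <- scan$spec$peak_frame
    list(scan_id = scan$cine$scan_id,
         displacement = pred, reference = ref,
         strain = strain_pred, strain_ref = strain_ref,
         strain_peak = strain_pred[strain_pred$frame == pk, ],
         truth = scan$truth$segment_strain, spec = scan$spec)
  })
  pred_side <- lapply(test_detail, function(d)
    list(displacement = d$displacement, strain = d$strain,
         strain_peak = d$strain_peak))
  ref_side <- lapply(test_detail, function(d)
    list(displacement = d$reference, strain = d$strain_ref,
         strain_peak = d$strain_ref[d$strain_ref$frame == d$spec$peak_frame, ]))
  report <- agreement_report(pred_side, ref_side)

  out <- list(report = report, history = fit$history, best_epoch = fit$best_epoch,
              model = fit$model, scale = scale, split = split, test = test_detail,
              seed = seed, variant = variant)
  if (!is.null(out_dir)) write_pipeline_outputs(out, out_dir)
  out
}

write_pipeline_outputs <- function(out, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(out$history, file.path(out_dir, "training_log.csv"),
                   row.names = FALSE)
  save_checkpoint(out$model, file.path(out_dir, "checkpoint.rds"),
                  scale = out$scale,
                  meta = list(seed = out$seed, variant = out$variant,
                              best_epoch = out$best_epoch))
  for (d in out$test) {
    base <- file.path(out_dir, d$scan_id)
    write_volume(d$displacement, paste0(base, "_pred.nii.gz"))
    write_volume(d$reference, paste0(base, "_ref.nii.gz"))
    utils::write.csv(d$strain, paste0(base, "_strain_pred.csv"), row.names = FALSE)
    utils::write.csv(d$strain_ref, paste0(base, "_strain_ref.csv"), row.names = FALSE)
    utils::write.csv(d$truth, paste0(base, "_strain_truth.csv"), row.names = FALSE)
  }
  rep <- out$report
  rep$ttests <- if (is.null(rep$ttests)) NULL else as.data.frame(rep$ttests)
  jsonlite::write_json(unclass(rep), file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(out_dir)
}

#' Pool predicted vs analytic segment strains of the test scans
#'
#' Pairs the network-derived per-frame per-segment Ecc/Err (percent) of
#' every test scan with the phantom's closed-form values, pooled across
#' frames, segments and both strain components; used for recovery checks
#' against analytic ground truth.
#'
#' @param result a [run_pipeline()] result.
#' @return tibble: `scan_id`, `frame`, `segment`, `component`, `predicted`,
#'   `analytic` (percent).
#' @export
pooled_strain_pairs <- function(result) {
  rows <- lapply(result$test, function(d) {
    seg <- d$strain[d$strain$segment != "global", ]
    tru <- d$truth
    key <- paste(seg$frame, seg$segment)
    tkey <- paste(tru$frame, tru$segment)
    m <- match(key, tkey)
    dplyr::bind_rows(
      tibble::tibble(scan_id = d$scan_id, frame = seg$frame, segment = seg$segment,
                     component = "Ecc", predicted = seg$Ecc_percent,
                     analytic = tru$Ecc_percent[m]),
      tibble::tibble(scan_id = d$scan_id, frame = seg$frame, segment = seg$segment,
                     component = "Err", predicted = seg$Err_percent,
                     analytic = tru$Err_percent[m]))
  })
  out <- dplyr::bind_rows(rows)
  out[!is.na(out$predicted) & !is.na(out$analytic), ]
}
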