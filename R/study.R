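#' Study configuration
#'
#' Bundles everything [run_study()] needs: the phantom, the acquisition
#' presets (count levels crossed with image types), the segmentation methods,
#' the VOI/image combinations for quantification, the recovery-calibration
#' volumes, the initialization margin and the master seed. The default
#' configuration is the package's benchmark: three tumours of 2.75, 8.89 and
#' 40.0 cm^3 on a 2.5 mm grid, 30 noise realizations, an "early" (high-count)
#' and a "late" (1/50 count) preset, each reconstructed AS-like (no edge
#' enhancement) and ASR-like (narrower PSF with edge overshoot).
#'
#' @param phantom A [phantom_spec()].
#' @param presets Named list; each element is a named list of
#'   [acquisition_spec()]s keyed by image type (e.g. `AS`, `ASR`).
#' @param methods Subset of `c("FT", "OM", "FS")`.
#' @param combinations Character vector of `"source/target"` VOI/image
#'   combinations for the concentration estimation.
#' @param rc_volumes_cm3 Sphere volumes for the recovery calibration.
#' @param init_margin_mm Margin of the shared initialization VOIs (mm).
#' @param seed Master seed; every stochastic stage derives its seed from it.
#' @param fraction FT threshold fraction.
#' @param opt,cfg Fourier-surface [optimizer_config()] / [objective_config()].
#' @return An object of class `study_config`.
#' @export
study_config <- function(phantom, presets, methods = c("FT", "OM", "FS"),
                         combinations = c("AS/AS", "AS/ASR", "ASR/ASR"),
                         rc_volumes_cm3 = c(1, 2, 5, 10, 20, 40),
                         init_margin_mm = 10, seed = 1L, fraction = 0.42,
                         opt = optimizer_config(), cfg = objective_config()) {
  methods <- match.arg(methods, several.ok = TRUE)
  if (length(presets) == 0 || length(methods) == 0) {
    stop("need at least one acquisition preset and one method")
  }
  if (is.null(names(presets))) stop("presets must be named")
  structure(list(phantom = phantom, presets = presets, methods = methods,
                 combinations = combinations,
                 rc_volumes_cm3 = rc_volumes_cm3,
                 init_margin_mm = init_margin_mm, seed = as.integer(seed),
                 fraction = fraction, opt = opt, cfg = cfg),
            class = "study_config")
}

#' @rdname study_config
#' @param n_realizations Noise realizations per preset/image type.
#' @export
default_study_config <- function(seed = 1L, n_realizations = 30L,
                                 methods = c("FT", "OM", "FS")) {
  grid <- voxel_grid(c(96, 40, 40), spacing = 2.5, origin = c(0, 0, 0))
  tumours <- list(
    tumour_spec(centre = c(100, 48.75, 48.75), volume_cm3 = 2.75,
                shape = "lumpy", lumpy_amplitude = 0.12, lumpy_seed = 11L),
    tumour_spec(centre = c(160, 48.75, 48.75), volume_cm3 = 8.89,
                shape = "ellipsoid", axis_ratios = c(1.4, 1, 0.9)),
    tumour_spec(centre = c(47.5, 48.75, 48.75), volume_cm3 = 40.0,
                shape = "lumpy", lumpy_amplitude = 0.15, lumpy_seed = 7L)
  )
  phantom <- phantom_spec(tumours, grid, background = 0.1)
  # early: ~1e5 expected counts in the 40 cm^3 tumour; late: 1/50 of that
  early_scale <- 1e5 / (40 / voxel_volume_cm3(grid))
  mk <- function(fwhm, scale, edge) {
    acquisition_spec(fwhm_mm = fwhm, count_scale = scale,
                     edge_enhancement = edge,
                     n_realizations = n_realizations, seed = 0L)
  }
  presets <- list(
    early = list(AS = mk(12, early_scale, 0), ASR = mk(8, early_scale, 0.5)),
    late = list(AS = mk(12, early_scale / 50, 0),
                ASR = mk(8, early_scale / 50, 0.5))
  )
  study_config(phantom, presets, methods = methods, seed = seed)
}

# derived deterministic sub-seed (kept within 32-bit integer range)
study_seed <- function(seed, preset_i, type_i) {
  as.integer((as.numeric(seed) * 7919 + preset_i * 1009 + type_i * 101) %%
               2147483647)
}

segment_one <- function(method, image, init_voi, cfg_obj) {
  switch(method,
         FT = fixed_threshold_segment(image, init_voi,
                                      cfg_obj$fraction)$mask,
         OM = otsu_segment(image, init_voi)$mask,
         FS = fs_segment(image, init_voi, cfg_obj$opt, cfg_obj$cfg,
                         gradient = cfg_obj$gradient),
         stop("unknown method: ", method))
}

#' Run the full synthetic segmentation/quantification study
#'
#' Builds the phantom, derives one shared initialization VOI per tumour
#' (identical for all noise realizations, presets and methods), simulates
#' `n_realizations` noisy reconstructions per preset and image type, runs
#' each requested segmentation method on every realization, calibrates a
#' recovery curve per preset/image type from noise-free sphere phantoms,
#' estimates activity concentrations for each VOI/image combination, and
#' summarizes volume errors, DSC percentiles and concentration errors.
#' Per-case failures are caught, logged and reported rather than aborting the
#' study. The whole run is a pure function of `(cfg, cfg$seed)`.
#'
#' @param cfg A [study_config()].
#' @param verbose Print progress.
#' @return An object of class `spect_study`: list with `summary` (tidy
#'   tibble), `cases` (per-realization tibble), `rc_curves`, `truth`,
#'   `init_vois`, `report` (character lines) and `config`.
#' @export
run_study <- function(cfg, verbose = FALSE) {
  ph <- build_phantom(cfg$phantom)
  truth <- ph$truth
  n_t <- length(truth$masks)
  init_vois <- lapply(truth$masks, make_initialization_voi,
                      margin = cfg$init_margin_mm)
  truth_idx <- lapply(truth$masks, function(m) which(m$member))
  grid <- cfg$phantom$grid
  v_vox <- voxel_volume_cm3(grid)

  cases <- list()
  conc_rows <- list()
  rc_curves <- list()
  for (p_i in seq_along(cfg$presets)) {
    preset <- names(cfg$presets)[p_i]
    types <- names(cfg$presets[[p_i]])
    acqs <- list()
    expecteds <- list()
    cals <- list()
    for (t_i in seq_along(types)) {
      acq <- cfg$presets[[p_i]][[t_i]]
      acq$seed <- study_seed(cfg$seed, p_i, t_i)
      acqs[[types[t_i]]] <- acq
      expecteds[[types[t_i]]] <- expected_reconstruction(ph$activity, acq)
      cals[[types[t_i]]] <- calibration_from_acquisition(acq, grid)
      if (verbose) message("calibrating RC curve: ", preset, "/", types[t_i])
      rc_curves[[preset]][[types[t_i]]] <-
        calibrate_rc_for_acquisition(cfg$rc_volumes_cm3, acq)
    }
    n_real <- max(vapply(acqs, function(a) a$n_realizations, integer(1)))
    for (i in seq_len(n_real)) {
      if (verbose) message(sprintf("preset %s realization %d/%d", preset, i,
                                   n_real))
      imgs <- lapply(acqs, simulate_reconstruction, activity = ph$activity,
                     realization_index = i)
      grads <- if ("FS" %in% cfg$methods) {
        lapply(imgs, image_gradient)
      } else NULL
      masks_idx <- list()
      for (type in types) {
        for (method in cfg$methods) {
          for (j in seq_len(n_t)) {
            res <- tryCatch({
              m <- segment_one(method, imgs[[type]], init_vois[[j]],
                               list(fraction = cfg$fraction, opt = cfg$opt,
                                    cfg = cfg$cfg,
                                    gradient = grads[[type]]))
              idx <- which(m$member)
              ov <- length(intersect(idx, truth_idx[[j]]))
              list(idx = idx, volume = length(idx) * v_vox,
                   dsc = 2 * ov / (length(idx) + length(truth_idx[[j]])),
                   failed = FALSE, error = NA_character_)
            }, error = function(e) {
              list(idx = integer(0), volume = NA_real_, dsc = NA_real_,
                   failed = TRUE, error = conditionMessage(e))
            })
            masks_idx[[paste(type, method, j)]] <- res$idx
            cases[[length(cases) + 1]] <- tibble::tibble(
              preset = preset, image = type, method = method, tumour = j,
              realization = i, volume_cm3 = res$volume, dsc = res$dsc,
              failed = res$failed, error = res$error)
          }
        }
      }
      for (combo in cfg$combinations) {
        st <- strsplit(combo, "/", fixed = TRUE)[[1]]
        if (!all(st %in% types)) next
        for (method in cfg$methods) {
          for (j in seq_len(n_t)) {
            idx <- masks_idx[[paste(st[1], method, j)]]
            C <- if (length(idx) == 0) NA_real_ else {
              mem <- logical(prod(grid$shape))
              mem[idx] <- TRUE
              voi <- binary_mask(array(mem, grid$shape), grid)
              est <- tryCatch(
                estimate_concentration(imgs[[st[2]]], voi,
                                       rc_curves[[preset]][[st[2]]],
                                       cals[[st[2]]]),
                error = function(e) NULL)
              if (is.null(est)) NA_real_ else est$C
            }
            conc_rows[[length(conc_rows) + 1]] <- tibble::tibble(
              preset = preset, combo = combo, method = method, tumour = j,
              realization = i, concentration = C)
          }
        }
      }
    }
  }
  cases <- do.call(rbind, cases)
  conc <- if (length(conc_rows)) do.call(rbind, conc_rows) else NULL

  summary <- summarize_study(cases, conc, truth)
  report <- study_report(summary, cases, cfg)
  structure(list(summary = summary, cases = cases, concentrations = conc,
                 rc_curves = rc_curves, truth = truth, init_vois = init_vois,
                 report = report, config = cfg),
            class = "spect_study")
}

calibrate_rc_for_acquisition <- function(volumes, acq) {
  phs <- rc_phantom(volumes)
  cal <- calibration_from_acquisition(acq, phs[[1]]$activity$grid)
  rcs <- vapply(phs, function(p) {
    recon <- expected_reconstruction(p$activity, acq)
    measure_rc(recon, p$true_mask, 1, cal)
  }, numeric(1))
  fit_rc_curve(vapply(phs, function(p) p$volume_cm3, numeric(1)), rcs)
}

summarize_study <- function(cases, conc, truth) {
  rows <- list()
  for (key in unique(paste(cases$preset, cases$image, cases$method,
                           cases$tumour))) {
    sub <- cases[paste(cases$preset, cases$image, cases$method,
                       cases$tumour) == key, ]
    ref <- truth$table$volume_cm3[sub$tumour[1]]
    ok <- !sub$failed & !is.na(sub$volume_cm3) & sub$volume_cm3 > 0
    vol <- if (any(ok)) error_stats(sub$volume_cm3[ok], ref) else NULL
    dsc <- if (any(ok)) summarize_dsc(sub$dsc[ok]) else c(p50 = NA_real_,
                                                          p10 = NA_real_,
                                                          p90 = NA_real_)
    rows[[length(rows) + 1]] <- tibble::tibble(
      preset = sub$preset[1], image = sub$image[1], method = sub$method[1],
      tumour = sub$tumour[1], quantity = "volume",
      reference = ref,
      mean_error = if (is.null(vol)) NA_real_ else vol$mean_error,
      rsd = if (is.null(vol)) NA_real_ else vol$rsd,
      rrmse = if (is.null(vol)) NA_real_ else vol$rrmse,
      dsc_p50 = dsc["p50"], dsc_p10 = dsc["p10"], dsc_p90 = dsc["p90"],
      n_ok = sum(ok), n_failed = sum(sub$failed))
  }
  if (!is.null(conc)) {
    for (key in unique(paste(conc$preset, conc$combo, conc$method,
                             conc$tumour))) {
      sub <- conc[paste(conc$preset, conc$combo, conc$method,
                        conc$tumour) == key, ]
      ref <- truth$table$concentration[sub$tumour[1]]
      ok <- !is.na(sub$concentration)
      st <- if (any(ok)) error_stats(sub$concentration[ok], ref) else NULL
      rows[[length(rows) + 1]] <- tibble::tibble(
        preset = sub$preset[1], image = sub$combo[1], method = sub$method[1],
        tumour = sub$tumour[1], quantity = "concentration",
        reference = ref,
        mean_error = if (is.null(st)) NA_real_ else st$mean_error,
        rsd = if (is.null(st)) NA_real_ else st$rsd,
        rrmse = if (is.null(st)) NA_real_ else st$rrmse,
        dsc_p50 = NA_real_, dsc_p10 = NA_real_, dsc_p90 = NA_real_,
        n_ok = sum(ok), n_failed = sum(!ok))
    }
  }
  do.call(rbind, rows)
}

study_report <- function(summary, cases, cfg, min_dsc_report = 0.5) {
  lines <- c("# Synthetic SPECT segmentation study",
             "",
             sprintf("Seed: %d. Methods: %s. Presets: %s.", cfg$seed,
                     paste(cfg$methods, collapse = ", "),
                     paste(names(cfg$presets), collapse = ", ")),
             sprintf("Tumours: %s cm^3.",
                     paste(format(vapply(cfg$phantom$tumours,
                                         function(t) t$volume_cm3,
                                         numeric(1))), collapse = ", ")),
             "")
  fails <- cases[cases$failed, ]
  if (nrow(fails) > 0) {
    lines <- c(lines, sprintf("%d segmentation case(s) failed:", nrow(fails)),
               sprintf("- %s/%s %s tumour %d realization %d: %s",
                       fails$preset, fails$image, fails$method, fails$tumour,
                       fails$realization, fails$error), "")
  }
  vol <- summary[summary$quantity == "volume", ]
  poor <- vol[!is.na(vol$dsc_p50) & vol$dsc_p50 < min_dsc_report, ]
  if (nrow(poor) > 0) {
    lines <- c(lines, "Flagged (median DSC below threshold; interpret volume",
               "and concentration results with care):",
               sprintf("- %s/%s %s tumour %d: median DSC %.2f", poor$preset,
                       poor$image, poor$method, poor$tumour, poor$dsc_p50),
               "")
  }
  for (q in unique(summary$quantity)) {
    sub <- summary[summary$quantity == q, ]
    lines <- c(lines, sprintf("## %s", q))
    lines <- c(lines, sprintf(
      "- %s/%s %s tumour %d (ref %.3g): E %+.1f%% +/- %.1f%% (rRMSE %.1f%%)%s",
      sub$preset, sub$image, sub$method, sub$tumour, sub$reference,
      100 * sub$mean_error, 100 * sub$rsd, 100 * sub$rrmse,
      ifelse(is.na(sub$dsc_p50), "",
             sprintf("; DSC %.2f (%.2f, %.2f)", sub$dsc_p50, sub$dsc_p10,
                     sub$dsc_p90))), "")
  }
  lines
}

#' @export
print.spect_study <- function(x, ...) {
  cat(sprintf("<spect_study> %d summary rows, %d cases (%d failed)\n",
              nrow(x$summary), nrow(x$cases), sum(x$cases$failed)))
  invisible(x)
}

#' @export
tidy.spect_study <- function(x, ...) x$summary

#' @export
glance.spect_study <- function(x, ...) {
  tibble::tibble(n_cases = nrow(x$cases), n_failed = sum(x$cases$failed),
                 n_tumours = length(x$truth$masks),
                 seed = x$config$seed)
}

#' Write study outputs to a directory
#'
#' Emits `results.csv` (the tidy summary), `cases.csv` and `report.md`.
#'
#' @param study A `spect_study`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_study_outputs <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(study$summary, file.path(dir, "results.csv"),
                   row.names = FALSE)
  utils::write.csv(study$cases, file.path(dir, "cases.csv"),
                   row.names = FALSE)
  writeLines(study$report, file.path(dir, "report.md"))
  invisible(dir)
}

#' Compare two masks from files
#'
#' Cross-grid Dice between two mask files plus the relative volume difference
#' `(V_A - V_B) / V_B` (the operator-variability / SPECT-vs-morphology
#' workflow).
#'
#' @param path_a,path_b Mask file paths (NIfTI or MetaImage).
#' @return A `dsc_result` with an extra element `volume_ratio`.
#' @export
compare_masks <- function(path_a, path_b) {
  a <- read_mask(path_a)
  b <- read_mask(path_b)
  res <- dice_cross_grid(a, b)
  res$volume_ratio <- (res$volume_a_cm3 - res$volume_b_cm3) / res$volume_b_cm3
  res
}
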