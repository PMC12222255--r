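#' Configuration for the end-to-end low-dose experiment
#'
#' @param bundle A [default_phantom()] bundle (phantom, input function,
#'   subject metadata, ground truth).
#' @param schedule A [frame_schedule()]; default the 39-frame 60-min
#'   protocol.
#' @param dose_factors Dose ladder, each in (0, 1].
#' @param methods Subset of `"non_dn"`, `"dl_dn"`, `"gaussian"`.
#' @param replicates Thinning replicates per dose (>= 1).
#' @param bank A [train_bank()] result; required when `"dl_dn"` is run.
#' @param gaussian_fwhm_mm FWHM of the classical baseline (mm).
#' @param fit_opts [fit_options()] used for all compartment fits; the
#'   default here uses a coarser delay grid and fewer restarts than the
#'   single-fit default, to keep the full grid of fits tractable.
#' @param regions_2tcm Regions fit with the irreversible 2-tissue model.
#' @param regions_1tcm Regions fit with the 1-tissue model (VT readout).
#' @param tstar_patlak_min,tstar_logan_min Equilibrium times (minutes).
#' @param lesion_threshold Fractional-maximum threshold defining the lesion
#'   VOI inside its parent mask.
#' @param do_fits,do_maps Toggle compartment fits / parametric maps.
#' @param keep_maps Keep each arm's Patlak map in the result (memory
#'   permitting) in addition to the reference map.
#' @param zero_noise Skip Poisson noise (noiseless self-reference check).
#' @param seed Master seed; every stochastic stage derives its own stream.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(bundle = default_phantom("small"),
                              schedule = parse_schedule_spec(tibble(
                                count = c(12, 6, 3, 2, 6, 10),
                                duration_s = c(5, 10, 20, 30, 60, 300))),
                              dose_factors = c(1, 1/2, 1/5, 1/10, 1/20),
                              methods = c("non_dn", "dl_dn"),
                              replicates = 1,
                              bank = NULL,
                              gaussian_fwhm_mm = 6,
                              fit_opts = fit_options(
                                delay_grid_s = seq(-10, 20, by = 2),
                                multistart = 3),
                              regions_2tcm = c("liver", "lung", "muscle",
                                               "thalamus"),
                              regions_1tcm = "lesion",
                              tstar_patlak_min = 25,
                              tstar_logan_min = 2,
                              lesion_threshold = 0.6,
                              do_fits = TRUE, do_maps = TRUE,
                              keep_maps = FALSE,
                              zero_noise = FALSE, seed = 1) {
  methods <- match.arg(methods, c("non_dn", "dl_dn", "gaussian"),
                       several.ok = TRUE)
  if ("dl_dn" %in% methods && is.null(bank)) {
    abort_dynapet("`dl_dn` requires a trained `bank`.")
  }
  if (any(dose_factors <= 0 | dose_factors > 1)) {
    abort_dynapet("Dose factors must lie in (0, 1].")
  }
  structure(as.list(environment()), class = "experiment_config")
}

process_image <- function(image, method, cfg) {
  switch(method,
    non_dn = image,
    dl_dn = denoise_dynamic(image, cfg$bank),
    gaussian = {
      out <- image$voxels
      for (f in seq_len(dim(out)[4])) {
        out[, , , f] <- gaussian_denoise(out[, , , f], cfg$gaussian_fwhm_mm,
                                         image$voxel_size_mm)
      }
      dynamic_image(out, image$voxel_size_mm, image$schedule,
                    image$calibration)
    })
}

# quantities extracted from one processed image, given fixed VOIs
quantify_arm <- function(image, vois, cfg) {
  tacs <- lapply(vois$tacs, function(m) roi_extract(image, m))
  idif_da <- roi_extract(image, vois$da)
  idif_rv <- roi_extract(image, vois$rv)
  t_s <- seq(0, max(image$schedule$end_s), by = 1)
  cp_da <- tibble(t_s = t_s,
                  value = stats::approx(c(0, idif_da$mid_s), c(0, idif_da$mean),
                                        t_s, rule = 2)$y)
  cp_rv <- tibble(t_s = t_s,
                  value = stats::approx(c(0, idif_rv$mid_s), c(0, idif_rv$mean),
                                        t_s, rule = 2)$y)
  out <- list(tacs = tacs, idif_da = idif_da, idif_rv = idif_rv,
              auc = c(
                setNames(vapply(tacs, auc_trapezoid, 0), names(tacs)),
                idif_da = auc_trapezoid(idif_da),
                idif_rv = auc_trapezoid(idif_rv)))
  if (cfg$do_fits) {
    fits <- list()
    for (rg in intersect(cfg$regions_2tcm, names(tacs))) {
      cp <- if (rg == "lung") cp_rv else cp_da
      cp_use <- if (rg == "liver") {
        tibble(t_s = t_s, value = dual_input(cp$value, t_s))
      } else cp
      fits[[rg]] <- fit_compartment(tacs[[rg]], cp_use, model = "2tcm_irr",
                                    opts = cfg$fit_opts,
                                    schedule = image$schedule)
    }
    for (rg in intersect(cfg$regions_1tcm, names(tacs))) {
      fits[[rg]] <- fit_compartment(tacs[[rg]], cp_da, model = "1tcm",
                                    opts = cfg$fit_opts,
                                    schedule = image$schedule)
    }
    out$fits <- fits
  }
  if (cfg$do_maps) {
    out$patlak <- patlak_image(image, cp_da, cfg$tstar_patlak_min,
                               mask = vois$body)
  }
  out
}

#' Run the end-to-end low-dose quantification experiment
#'
#' For each dose x method x replicate: thin the full-dose acquisition's
#' counts, reconstruct the low-dose image, optionally denoise, extract
#' image-derived input functions (descending aorta, right ventricle) and
#' tissue TACs through VOIs frozen on the full-dose non-denoised reference,
#' fit compartment models, build Patlak parametric maps, and tabulate
#' percent bias in AUC, Ki, VT and K1 against the full-dose non-denoised
#' reference (plus ground-truth-referenced bias as a labelled extension),
#' with RMSE/SSIM of parametric maps against the reference map.
#'
#' @param cfg An [experiment_config()].
#' @return A list of class `low_dose_experiment`: `records` (tidy tibble of
#'   bias values), `quality` (map RMSE/SSIM), `reference` (the reference
#'   quantities), and `manifest` (seeds, configuration hash).
#' @export
run_low_dose_experiment <- function(cfg = experiment_config()) {
  stopifnot(inherits(cfg, "experiment_config"))
  bundle <- cfg$bundle
  clean <- render_dynamic(bundle$phantom, bundle$if_params, cfg$schedule)
  counts <- expected_counts(clean)
  obs <- if (cfg$zero_noise) round(counts)
         else add_poisson_noise(counts, derive_seed(cfg$seed, 0))
  ref_img <- counts_to_image(obs, clean)

  masks <- region_masks(bundle$phantom)
  # VOIs frozen on the full-dose non-denoised reference
  lesion_parent <- masks$lesion | masks$lesion_core
  lesion_voi <- threshold_voi(static_summary(ref_img), lesion_parent,
                              cfg$lesion_threshold)
  tac_regions <- unique(c(cfg$regions_2tcm, cfg$regions_1tcm))
  vois <- list(
    tacs = c(masks[setdiff(tac_regions, "lesion")],
             if ("lesion" %in% tac_regions) list(lesion = lesion_voi)),
    da = masks$descending_aorta,
    rv = masks$right_ventricle,
    body = Reduce(`|`, masks)
  )

  ref <- quantify_arm(ref_img, vois, cfg)
  truth <- bundle$truth

  recs <- list()
  qual <- list()
  kept <- list()
  push <- function(lst, x) c(lst, list(x))
  for (f in cfg$dose_factors) {
    for (r in seq_len(cfg$replicates)) {
      sub_seed <- derive_seed(cfg$seed, round(1e4 / f) + r)
      thinned <- thin_counts(obs, f, seed = sub_seed)
      low <- counts_to_image(thinned, clean, dose_fraction = f)
      for (m in cfg$methods) {
        arm <- quantify_arm(process_image(low, m, cfg), vois, cfg)
        for (nm in names(arm$auc)) {
          recs <- push(recs, tibble(
            region = nm, dose = f, method = m, metric = "auc_bias",
            replicate = r, value = percent_bias(arm$auc[[nm]], ref$auc[[nm]]),
            reference = "full_dose_non_dn"))
        }
        if (cfg$do_fits) {
          for (nm in names(arm$fits)) {
            fit <- arm$fits[[nm]]
            mac <- names(fit$macro)
            metric <- if (mac == "Ki") "ki_bias" else "vt_bias"
            recs <- push(recs, tibble(
              region = nm, dose = f, method = m, metric = metric,
              replicate = r,
              value = percent_bias(fit$macro[[1]], ref$fits[[nm]]$macro[[1]]),
              reference = "full_dose_non_dn"))
            recs <- push(recs, tibble(
              region = nm, dose = f, method = m, metric = "k1_bias",
              replicate = r,
              value = percent_bias(fit$params$K1, ref$fits[[nm]]$params$K1),
              reference = "full_dose_non_dn"))
            tv <- truth[truth$region == nm, ]
            if (nrow(tv) == 1) {
              tval <- if (mac == "Ki") tv$Ki else tv$VT
              recs <- push(recs, tibble(
                region = nm, dose = f, method = m, metric = metric,
                replicate = r, value = percent_bias(fit$macro[[1]], tval),
                reference = "ground_truth"))
            }
          }
        }
        if (cfg$do_maps) {
          if (isTRUE(cfg$keep_maps)) {
            kept[[sprintf("dose_%g_%s_rep%d", f, m, r)]] <- arm$patlak
          }
          qual <- push(qual, tibble(
            dose = f, method = m, replicate = r, map = "patlak_ki",
            rmse = rmse_image(arm$patlak$slope, ref$patlak$slope,
                              mask = vois$body),
            ssim = as.numeric(ssim_image(arm$patlak$slope, ref$patlak$slope))))
        }
      }
    }
  }
  structure(list(
    records = dplyr::bind_rows(recs),
    quality = dplyr::bind_rows(qual),
    maps = kept,
    reference = ref,
    manifest = list(
      seed = cfg$seed,
      noise_seed = derive_seed(cfg$seed, 0),
      dose_factors = cfg$dose_factors,
      methods = cfg$methods,
      replicates = cfg$replicates,
      config_hash = rlang::hash(cfg[setdiff(names(cfg), "bank")]),
      timestamp = format(Sys.time(), tz = "UTC"))
  ), class = "low_dose_experiment")
}

#' Per-frame image fidelity against a reference dynamic image
#'
#' @param image,reference [dynamic_image()]s on the same grid.
#' @param mask Optional RMSE mask.
#' @return Tibble: frame, rmse, ssim.
#' @export
frame_quality <- function(image, reference, mask = NULL) {
  d <- dim(image$voxels)
  purrr::map_dfr(seq_len(d[4]), function(f) {
    refv <- reference$voxels[, , , f]
    tibble(frame = f,
           rmse = rmse_image(image$voxels[, , , f], refv, mask = mask),
           ssim = if (max(refv) > 0) {
             as.numeric(ssim_image(image$voxels[, , , f], refv))
           } else NA_real_)
  })
}
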