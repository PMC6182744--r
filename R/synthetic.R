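# Synthetic trabecular-texture studies. The texture model is a thresholded
# Gaussian random field: the correlation length of the field is a single
# interpretable "spatial organization" knob (progressors are emulated as less
# spatially organised / more homogeneous bone via a shorter correlation
# length). Magnitude-MRI noise is Rician. This is a texture phantom, not a
# claim about trabecular physics.

#' Texture-generator parameters
#'
#' @param correlation_length Gaussian smoothing scale of the underlying field
#'   in pixels; larger values give larger, more organised trabecular plates.
#' @param trabecular_threshold field quantile separating plate from marrow
#'   (in (0, 1)).
#' @param noise_sigma Rician noise scale relative to the unit signal range.
#' @param blur_sigma point-spread blur (pixels) applied to the binary pattern.
#' @param image_size square image side in pixels (default 256; a desk-scale
#'   stand-in for 1024x1024 interpolated acquisitions).
#' @param slice_count slices per knee/timepoint (default 5).
#' @param roi_depth ROI band depth in pixels (default scales the ~1 cm depth
#'   at the acquisition matrix to `image_size`).
#' @param roi_gap joint-space gap between the femoral and tibial bands.
#' @return list of class `texture_params`.
#' @export
texture_params <- function(correlation_length = 6, trabecular_threshold = 0.5,
                           noise_sigma = 0.05, blur_sigma = 0.7,
                           image_size = 256L, slice_count = 5L,
                           roi_depth = NULL, roi_gap = NULL) {
  stopifnot(correlation_length > 0, trabecular_threshold > 0,
            trabecular_threshold < 1, slice_count >= 1)
  if (is.null(roi_depth)) roi_depth <- max(10L, round(image_size * 84 / 1024))
  if (is.null(roi_gap)) roi_gap <- max(4L, round(image_size / 32))
  structure(list(correlation_length = correlation_length,
                 trabecular_threshold = trabecular_threshold,
                 noise_sigma = noise_sigma, blur_sigma = blur_sigma,
                 image_size = as.integer(image_size),
                 slice_count = as.integer(slice_count),
                 roi_depth = as.integer(roi_depth),
                 roi_gap = as.integer(roi_gap)),
            class = "texture_params")
}

# circular Gaussian smoothing via FFT; sigma in pixels
.gauss_smooth <- function(z, sigma) {
  if (sigma <= 0) return(z)
  n <- nrow(z); m <- ncol(z)
  fx <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1)) / n
  fy <- c(0:(m %/% 2), -((m - m %/% 2 - 1):1)) / m
  # Gaussian kernel transfer function (FT of exp(-x^2 / (2 sigma^2)))
  gx <- exp(-2 * pi^2 * sigma^2 * fx^2)
  gy <- exp(-2 * pi^2 * sigma^2 * fy^2)
  H <- outer(gx, gy)
  Re(stats::fft(stats::fft(z) * H, inverse = TRUE)) / (n * m)
}

#' Generate one synthetic trabecular slice with its two ROI bands
#'
#' White noise is smoothed at the correlation length, thresholded at the
#' given quantile into a binary plate/marrow pattern, blurred by the
#' point-spread scale, and corrupted with Rician noise. Two rectangular-band
#' ROIs of the configured depth sit above ("medial_femur") and below
#' ("medial_tibia") a synthetic joint line at mid-image.
#'
#' @param params a [texture_params()].
#' @param seed integer seed; the same (params, seed) always yields the same
#'   slice.
#' @return list: `image` (`gray_image`), `masks` (named list of `roi_mask`).
#' @export
make_trabecular_slice <- function(params, seed) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  n <- params$image_size
  z <- matrix(rnorm(n * n), n, n)
  f <- .gauss_smooth(z, params$correlation_length)
  pattern <- (f > quantile(f, params$trabecular_threshold)) * 1
  img <- 0.25 + 0.6 * .gauss_smooth(pattern, params$blur_sigma)
  s <- params$noise_sigma
  if (s > 0) {
    img <- sqrt((img + s * matrix(rnorm(n * n), n, n))^2 +
                (s * matrix(rnorm(n * n), n, n))^2)
  }
  image <- gray_image(img)
  list(image = image, masks = .band_masks(params))
}

# rectangular-band ROIs around the synthetic joint line; edge offsets allow
# rater-jitter perturbation
.band_masks <- function(params, offsets = NULL) {
  n <- params$image_size
  mid <- n %/% 2L
  half_gap <- params$roi_gap %/% 2L
  c0 <- max(1L, round(0.15 * n)); c1 <- min(n, round(0.85 * n))
  o <- if (is.null(offsets)) rep(0L, 8L) else as.integer(offsets)
  band <- function(r0, r1, cc0, cc1) {
    m <- matrix(FALSE, n, n)
    m[max(1L, r0):min(n, r1), max(1L, cc0):min(n, cc1)] <- TRUE
    m
  }
  fem <- band(mid - half_gap - params$roi_depth + 1L + o[1L],
              mid - half_gap + o[2L], c0 + o[3L], c1 + o[4L])
  tib <- band(mid + half_gap + o[5L],
              mid + half_gap + params$roi_depth - 1L + o[6L],
              c0 + o[7L], c1 + o[8L])
  list(medial_tibia = roi_mask(tib, "medial_tibia"),
       medial_femur = roi_mask(fem, "medial_femur"))
}

#' Duplicate-analyst ROI perturbation
#'
#' Emulates a second analyst re-drawing the band ROIs: each band edge is
#' shifted independently by a uniform integer in `[-jitter, jitter]` pixels.
#'
#' @param params a [texture_params()].
#' @param jitter maximum edge displacement in pixels.
#' @param seed integer seed.
#' @return named list of `roi_mask` (`medial_tibia`, `medial_femur`).
#' @export
jitter_masks <- function(params, jitter, seed) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  o <- if (jitter > 0) sample(-jitter:jitter, 8L, replace = TRUE)
       else rep(0L, 8L)
  .band_masks(params, offsets = o)
}

#' Cohort-generator parameters
#'
#' Covariate defaults are calibrated to the initial-timepoint characteristics
#' of the motivating progression cohort: age ~64 years, ~42% female, BMI
#' 31.2 (4.7) kg/m2, initial minJSW 3.8 (1.2) mm; 36-month minJSW change
#' N(-1.29, 0.63) mm for cases and N(0, 0.44) mm for controls. Texture effect
#' sizes (differences in generative correlation length) default to a modest
#' effect consistent with the modest discrimination reported for real knees;
#' `effect = "null"` and `effect = "strong"` give the zero-effect and
#' strong-effect study conditions used for calibration and recovery checks.
#'
#' @param n_cases number of cases (default 61).
#' @param n_controls_pool control pool size before matching (default 120).
#' @param effect `"modest"` (default), `"null"` or `"strong"` texture effect
#'   preset; individual `ell_*` arguments override the preset.
#' @param ell_control mean generative correlation length, controls.
#' @param ell_sd between-subject SD of correlation length.
#' @param ell_case_initial_shift reduction in case correlation length at the
#'   initial timepoint.
#' @param ell_case_longitudinal_shift additional reduction in case
#'   correlation length at follow-up (the change signal).
#' @param ell_drift_sd SD of subject-level longitudinal drift common to both
#'   groups.
#' @param age_mean,age_sd,female_fraction,bmi_mean,bmi_sd,minjsw_mean,minjsw_sd
#'   covariate distribution parameters.
#' @param case_change_mean,case_change_sd,control_change_mean,control_change_sd
#'   36-month minJSW change distributions (mm).
#' @param strict_labels resample minJSW change until it satisfies the 0.7 mm
#'   rule for the assigned group, so case/control counts are exact.
#' @param p_initial_excluded,p_followup_excluded probabilities of image-based
#'   exclusion flags (motion artefact / unavailable MRI / cyst or surgery),
#'   matching the attrition observed in the motivating study.
#' @param rater_jitter duplicate-analyst ROI edge jitter in pixels.
#' @param n_duplicate_rated subjects analysed in duplicate (default 23).
#' @return list of class `cohort_params`.
#' @export
cohort_params <- function(n_cases = 61L, n_controls_pool = 120L,
                          effect = c("modest", "null", "strong"),
                          ell_control = NULL, ell_sd = NULL,
                          ell_case_initial_shift = NULL,
                          ell_case_longitudinal_shift = NULL,
                          ell_drift_sd = 0.15,
                          age_mean = 64.5, age_sd = 8,
                          female_fraction = 0.42,
                          bmi_mean = 31.2, bmi_sd = 4.7,
                          minjsw_mean = 3.8, minjsw_sd = 1.2,
                          case_change_mean = -1.29, case_change_sd = 0.63,
                          control_change_mean = 0, control_change_sd = 0.44,
                          strict_labels = TRUE,
                          p_initial_excluded = 0.09,
                          p_followup_excluded = 0.15,
                          rater_jitter = 1L, n_duplicate_rated = 23L) {
  effect <- match.arg(effect)
  preset <- switch(effect,
    modest = list(ell_control = 6, ell_sd = 1.0,
                  ell_case_initial_shift = 0.4,
                  ell_case_longitudinal_shift = 0.8),
    null = list(ell_control = 6, ell_sd = 1.0,
                ell_case_initial_shift = 0,
                ell_case_longitudinal_shift = 0),
    strong = list(ell_control = 7, ell_sd = 0.5,
                  ell_case_initial_shift = 0.5,
                  ell_case_longitudinal_shift = 3))
  if (is.null(ell_control)) ell_control <- preset$ell_control
  if (is.null(ell_sd)) ell_sd <- preset$ell_sd
  if (is.null(ell_case_initial_shift))
    ell_case_initial_shift <- preset$ell_case_initial_shift
  if (is.null(ell_case_longitudinal_shift))
    ell_case_longitudinal_shift <- preset$ell_case_longitudinal_shift
  structure(as.list(environment())[c(
    "n_cases", "n_controls_pool", "effect", "ell_control", "ell_sd",
    "ell_case_initial_shift", "ell_case_longitudinal_shift", "ell_drift_sd",
    "age_mean", "age_sd", "female_fraction", "bmi_mean", "bmi_sd",
    "minjsw_mean", "minjsw_sd", "case_change_mean", "case_change_sd",
    "control_change_mean", "control_change_sd", "strict_labels",
    "p_initial_excluded", "p_followup_excluded", "rater_jitter",
    "n_duplicate_rated")], class = "cohort_params")
}

# one subject's covariates + truth; assumes the RNG state is already seeded
.draw_subject <- function(group, cp) {
  is_case <- group == "case"
  minjsw36 <- max(0.6, rnorm(1, cp$minjsw_mean, cp$minjsw_sd))
  draw_change <- function() {
    if (is_case) rnorm(1, cp$case_change_mean, cp$case_change_sd)
    else rnorm(1, cp$control_change_mean, cp$control_change_sd)
  }
  change <- draw_change()
  ok <- function(ch) {
    cls <- (minjsw36 - max(0.05, minjsw36 + ch)) >= 0.7
    if (is_case) cls else !cls
  }
  if (cp$strict_labels) {
    tries <- 0L
    while (!ok(change) && tries < 1000L) { change <- draw_change(); tries <- tries + 1L }
  }
  minjsw72 <- max(0.05, minjsw36 + change)
  kl <- sample(0:3, 1L, prob = c(15, 20, 45, 42))
  med <- sample(0:2, 1L, prob = c(40, 40, 42))
  lat <- if (med == 0L) 0L else sample(0:1, 1L, prob = c(0.96, 0.04))
  ell_ini <- max(1.5, rnorm(1, cp$ell_control -
                              (if (is_case) cp$ell_case_initial_shift else 0),
                            cp$ell_sd))
  drift <- rnorm(1, 0, cp$ell_drift_sd)
  ell_fup <- max(1.2, ell_ini + drift -
                   (if (is_case) cp$ell_case_longitudinal_shift else 0))
  u <- runif(2)
  list(
    group = group,
    age = round(rnorm(1, cp$age_mean, cp$age_sd)),
    sex = if (runif(1) < cp$female_fraction) "F" else "M",
    bmi = rnorm(1, cp$bmi_mean, cp$bmi_sd),
    kl_grade_36m = kl,
    oarsi_jsn_medial_36m = med, oarsi_jsn_lateral_36m = lat,
    alignment = rnorm(1, -5.85, 2.0),
    minjsw_36m = minjsw36, minjsw_72m = minjsw72,
    excl_initial = if (u[1] < cp$p_initial_excluded)
      sample(c("motion", "unavailable_mri", "cyst"), 1L) else "none",
    excl_followup = if (u[2] < cp$p_followup_excluded)
      sample(c("motion", "unavailable_mri", "surgery"), 1L) else "none",
    ell_initial = ell_ini, ell_followup = ell_fup)
}

#' Generate a complete synthetic study
#'
#' Draws covariates, minJSW trajectories, exclusion flags, and per-subject
#' generative correlation lengths for `n_cases` cases and a control pool,
#' together with per-slice image seeds. Images themselves are regenerated on
#' demand from the stored seeds (see [subject_series()]), so the study object
#' stays small and fully deterministic in (params, seed).
#'
#' @param cp a [cohort_params()].
#' @param tp a [texture_params()].
#' @param seed integer master seed.
#' @return object of class `synthetic_study`: `cohort` (data frame), `truth`
#'   (per-subject generative correlation lengths), `slice_seeds`, `params`,
#'   `seed`.
#' @export
make_study <- function(cp = cohort_params(), tp = texture_params(),
                       seed = 1L) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  groups <- c(rep("case", cp$n_cases), rep("control", cp$n_controls_pool))
  ids <- sprintf("S%03d", seq_along(groups))
  subs <- lapply(groups, .draw_subject, cp = cp)
  cohort <- do.call(rbind, lapply(seq_along(subs), function(i) {
    s <- subs[[i]]
    data.frame(subject_id = ids[i], group = s$group, age = s$age,
               sex = s$sex, bmi = s$bmi, kl_grade_36m = s$kl_grade_36m,
               oarsi_jsn_medial_36m = s$oarsi_jsn_medial_36m,
               oarsi_jsn_lateral_36m = s$oarsi_jsn_lateral_36m,
               alignment = s$alignment,
               minjsw_36m = s$minjsw_36m, minjsw_72m = s$minjsw_72m,
               excl_initial = s$excl_initial,
               excl_followup = s$excl_followup,
               stringsAsFactors = FALSE)
  }))
  truth <- data.frame(
    subject_id = ids,
    ell_initial = vapply(subs, `[[`, numeric(1), "ell_initial"),
    ell_followup = vapply(subs, `[[`, numeric(1), "ell_followup"),
    stringsAsFactors = FALSE)
  n_sl <- tp$slice_count
  slice_seeds <- matrix(sample.int(.Machine$integer.max - 1L,
                                   length(ids) * 2L * n_sl),
                        nrow = length(ids))
  rownames(slice_seeds) <- ids
  rater_seeds <- setNames(sample.int(.Machine$integer.max - 1L, length(ids)),
                          ids)
  structure(list(cohort = cohort, truth = truth, slice_seeds = slice_seeds,
                 rater_seeds = rater_seeds, cohort_params = cp,
                 texture_params = tp, seed = seed),
            class = "synthetic_study")
}

#' Regenerate one subject/timepoint slice series of a synthetic study
#'
#' @param study a `synthetic_study`.
#' @param subject_id subject id.
#' @param timepoint `"initial"` or `"followup"`.
#' @param rater 1 for the original ROIs, 2 for the duplicate-analyst
#'   (jittered) ROIs.
#' @return a `slice_series`.
#' @export
subject_series <- function(study, subject_id,
                           timepoint = c("initial", "followup"), rater = 1L) {
  timepoint <- match.arg(timepoint)
  tp <- study$texture_params
  ell <- study$truth[study$truth$subject_id == subject_id,
                     paste0("ell_", timepoint)]
  if (length(ell) != 1L) stop("unknown subject: ", subject_id)
  pars <- tp
  pars$correlation_length <- ell
  n_sl <- tp$slice_count
  col0 <- if (timepoint == "initial") 0L else n_sl
  slices <- lapply(seq_len(n_sl), function(k) {
    sl <- make_trabecular_slice(pars, study$slice_seeds[subject_id, col0 + k])
    if (rater == 2L) {
      sl$masks <- jitter_masks(tp, study$cohort_params$rater_jitter,
                               study$rater_seeds[[subject_id]] %% 100000L +
                                 1000L * k)
    }
    sl
  })
  slice_series(slices, n_expected = n_sl)
}

#' Write a synthetic study to disk
#'
#' Renders every slice image and mask as 16-bit grayscale PNG and writes
#' `manifest.csv` (subject_id, timepoint, slice_index, region, image_path,
#' mask_path), `cohort.csv` and `truth.csv`, in the layout consumed by
#' [load_slice_series()].
#'
#' @param study a `synthetic_study`.
#' @param dir output directory (created if needed).
#' @param subject_ids subjects to render (default: all).
#' @return the manifest data frame, invisibly.
#' @export
write_study <- function(study, dir, subject_ids = study$cohort$subject_id) {
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (id in subject_ids) {
    for (tpnt in c("initial", "followup")) {
      ser <- subject_series(study, id, tpnt)
      for (k in seq_len(ser$n_slices)) {
        img <- ser$slices[[k]]$image$pixels
        ipath <- file.path(dir, "images",
                           sprintf("%s_%s_s%d.png", id, tpnt, k))
        png::writePNG(img / max(img), ipath)
        for (rg in names(ser$slices[[k]]$masks)) {
          mpath <- file.path(dir, "masks",
                             sprintf("%s_%s_s%d_%s.png", id, tpnt, k, rg))
          png::writePNG(ser$slices[[k]]$masks[[rg]]$mask * 1, mpath)
          rows[[length(rows) + 1L]] <- data.frame(
            subject_id = id, timepoint = tpnt, slice_index = k, region = rg,
            image_path = ipath, mask_path = mpath, stringsAsFactors = FALSE)
        }
      }
    }
  }
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  write.csv(study$cohort, file.path(dir, "cohort.csv"), row.names = FALSE)
  write.csv(study$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  invisible(manifest)
}
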