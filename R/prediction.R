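#' Predict body mass from a shape volume
#'
#' Applies the calibrated allometric equation: `mass = exp(a + b *
#' ln(volume))`. By default no back-transform (smearing) correction is
#' applied, matching the convention of the reference calibration; the
#' multiplicative correction `exp(mse / 2)` is available behind
#' `correct_bias`.
#'
#' @param model a `mass_model` (from [fit_loglog_ols()],
#'   [select_optimal_k()] or [read_model()]).
#' @param volume positive shape volume(s), cubic metres.
#' @param correct_bias apply the log-normal smearing factor
#'   `exp(mse / 2)`? Default `FALSE`.
#' @return predicted mass(es) in kg.
#' @export
#' @examples
#' m <- structure(list(a = 6.922, b = 0.988, mse = 0.025),
#'                class = "mass_model")
#' predict_mass(m, 3.629)
predict_mass <- function(model, volume, correct_bias = FALSE) {
  stopifnot(inherits(model, "mass_model"))
  if (length(volume) == 0L || anyNA(volume) || any(volume <= 0))
    stop("`volume` must be positive")
  out <- exp(model$a + model$b * log(volume))
  if (correct_bias) out <- out * exp((model$mse %||% 0) / 2)
  out
}

#' Predict body mass from a point cloud
#'
#' Runs the same protocol used in calibration on a new skeleton: `n_reps`
#' seeded downsamples to `n_points`, one alpha-complex each, alpha-shape
#' volume at `alpha = l_ref * k` with the model's refinement coefficient,
#' repeat volumes averaged, and the averaged volume passed through
#' [predict_mass()]. A model without a stored `k` (a convex-hull
#' calibration) uses the hull volume instead.
#'
#' For consistency the cloud must be downsampled to the same `n_points`
#' the model was calibrated with; a differing `n_points` argument
#' triggers a warning, as does a cloud with fewer points than requested
#' (which is then used in full).
#'
#' @param model a `mass_model` carrying `k` (and ideally `n_points`).
#' @param cloud a [point_cloud()].
#' @param n_points downsampling target; defaults to the model's.
#' @param n_reps downsampling repeats.
#' @param seed master seed.
#' @param correct_bias see [predict_mass()].
#' @return an object of class `mass_prediction`: `specimen_id`, `volume`
#'   (mean over repeats, m^3), `mass` (kg), `per_rep_masses`, `model_k`,
#'   `n_points`, `small_cloud` (flag: cloud had fewer points than
#'   requested).
#' @export
predict_from_cloud <- function(model, cloud, n_points = NULL, n_reps = 10L,
                               seed = 1L, correct_bias = FALSE) {
  stopifnot(inherits(model, "mass_model"))
  check_cloud(cloud)
  if (is.null(n_points)) {
    n_points <- model$n_points
    if (is.null(n_points))
      stop("`n_points` not given and not stored in the model")
  } else if (!is.null(model$n_points) && n_points != model$n_points) {
    warning(sprintf(
      "n_points = %d differs from the model's calibration n_points = %d",
      n_points, model$n_points))
  }
  small <- n_points(cloud) < n_points
  eff_reps <- if (small) 1L else as.integer(n_reps)
  vols <- numeric(eff_reps)
  for (r in seq_len(eff_reps)) {
    sub <- if (small) {
      downsample_cloud(cloud, n_points, derive_seed(seed, cloud$id, r))
    } else {
      suppressWarnings(
        downsample_cloud(cloud, n_points, derive_seed(seed, cloud$id, r)))
    }
    ac <- alpha_complex(sub)
    vols[r] <- if (is.null(model$k)) ac$hull_volume
               else alpha_volume(ac, ac$l_ref * model$k)
  }
  vbar <- mean(vols)
  structure(list(specimen_id = cloud$id, volume = vbar,
                 mass = predict_mass(model, vbar, correct_bias),
                 per_rep_masses = predict_mass(model, vols, correct_bias),
                 model_k = model$k, n_points = as.integer(n_points),
                 n_reps = as.integer(n_reps), seed = as.integer(seed),
                 small_cloud = small),
            class = "mass_prediction")
}

#' @export
print.mass_prediction <- function(x, ...) {
  cat(sprintf("<mass_prediction> '%s': volume %.4g m^3 -> mass %.1f kg\n",
              x$specimen_id, x$volume, x$mass))
  if (length(x$per_rep_masses) > 1L)
    cat(sprintf("  repeat spread: %.1f .. %.1f kg (sd %.2f, %d repeats)\n",
                min(x$per_rep_masses), max(x$per_rep_masses),
                sd(x$per_rep_masses), x$n_reps))
  if (x$small_cloud)
    cat("  note: cloud smaller than the downsampling target; used in full\n")
  invisible(x)
}
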