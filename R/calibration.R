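#' Grid of refinement coefficients
#'
#' The refinement coefficient `k` is the dimensionless multiplier that
#' sets the alpha radius per specimen, `alpha = l_ref * k`, so that one
#' `k` gives a comparable "refinement of fit" across differently sized
#' skeletons. The default grid (200 values, 0.01 to 100) spans four
#' decades, from shapes that fragment inside the bones to the convex-hull
#' limit, and is logarithmically spaced by default.
#'
#' @param k_min,k_max positive endpoints (included exactly).
#' @param n_k number of grid values (>= 2).
#' @param spacing `"log"` (geometric progression) or `"linear"`.
#' @return an object of class `k_grid`: list with `k`, `spacing`,
#'   `k_min`, `k_max`, `n_k`.
#' @export
k_grid <- function(k_min = 0.01, k_max = 100, n_k = 200L,
                   spacing = c("log", "linear")) {
  spacing <- match.arg(spacing)
  if (!(k_min > 0) || !(k_max > k_min)) stop("need 0 < k_min < k_max")
  if (n_k < 2L) stop("`n_k` must be at least 2")
  k <- if (spacing == "log") exp(seq(log(k_min), log(k_max), length.out = n_k))
       else seq(k_min, k_max, length.out = n_k)
  k[1] <- k_min; k[n_k] <- k_max  # endpoints exact
  structure(list(k = k, spacing = spacing, k_min = k_min, k_max = k_max,
                 n_k = as.integer(n_k)), class = "k_grid")
}

#' Alpha radius for a cloud at a refinement coefficient
#'
#' `alpha = l_ref * k`, with `l_ref` the mean point-to-centroid distance
#' of the cloud ([size_metrics()]).
#'
#' @param cloud a [point_cloud()].
#' @param k positive refinement coefficient(s).
#' @return alpha radius (metres), same length as `k`.
#' @export
alpha_for <- function(cloud, k) {
  if (any(k <= 0)) stop("`k` must be positive")
  size_metrics(cloud)$l_ref * k
}

#' Log-log OLS calibration of mass on shape volume
#'
#' Ordinary least squares of `ln(mass)` on `ln(volume)`: the allometric
#' model `mass = exp(a) * volume^b`. The reported mean square error is
#' `SSE / n` (the convention of the reference calibration tables in this
#' field), while the 95% confidence intervals use the unbiased residual
#' variance `SSE / (n - 2)` with a t(n - 2) quantile.
#'
#' @param volumes shape volumes (m^3), all positive.
#' @param masses body masses (kg), all positive, same length (n >= 3).
#' @param k optional refinement coefficient the volumes were computed at
#'   (recorded in the model; absent for convex-hull fits).
#' @return an object of class `mass_model`: `a`, `b`, `a_ci95`, `b_ci95`,
#'   `r2`, `mse`, `n`, `k`.
#' @export
#' @examples
#' v <- c(1, exp(1), exp(2))
#' fit_loglog_ols(v, 1000 * v)  # slope 1, r2 = 1
fit_loglog_ols <- function(volumes, masses, k = NULL) {
  if (length(volumes) != length(masses))
    stop("`volumes` and `masses` must have equal length")
  n <- length(volumes)
  if (n < 3L) stop("need at least 3 specimens")
  if (any(!is.finite(volumes)) || any(volumes <= 0))
    stop("all volumes must be finite and positive")
  if (any(!is.finite(masses)) || any(masses <= 0))
    stop("all masses must be finite and positive")
  lv <- log(volumes)
  if (sd(lv) == 0) stop("zero variance in log-volumes; cannot fit")
  fit <- lm(log(masses) ~ lv)
  ci <- confint(fit, level = 0.95)
  sse <- sum(resid(fit)^2)
  sst <- sum((log(masses) - mean(log(masses)))^2)
  structure(list(a = unname(coef(fit)[1]), b = unname(coef(fit)[2]),
                 a_ci95 = unname(ci[1, ]), b_ci95 = unname(ci[2, ]),
                 r2 = if (sst > 0) 1 - sse / sst else NA_real_,
                 mse = sse / n, n = n, k = k),
            class = "mass_model")
}

#' @export
print.mass_model <- function(x, ...) {
  cat(sprintf("<mass_model> ln(mass) = %.4f + %.4f ln(volume)   (n = %d%s)\n",
              x$a, x$b, x$n,
              if (!is.null(x$k)) sprintf(", k = %.4g", x$k) else ""))
  cat(sprintf("  a 95%% CI [%.4f, %.4f]   b 95%% CI [%.4f, %.4f]\n",
              x$a_ci95[1], x$a_ci95[2], x$b_ci95[1], x$b_ci95[2]))
  cat(sprintf("  r2 = %.4f   m.s.e. = %.4f\n", x$r2, x$mse))
  invisible(x)
}

check_specimens <- function(clouds, masses) {
  if (!is.list(clouds) || is.null(names(clouds)) ||
      any(!nzchar(names(clouds))))
    stop("`clouds` must be a named list of point_cloud objects")
  if (anyDuplicated(names(clouds)))
    stop("duplicate specimen ids in `clouds`")
  if (!is.data.frame(masses) ||
      !all(c("specimen_id", "mass_kg") %in% names(masses)))
    stop("`masses` must be a data.frame with columns specimen_id, mass_kg")
  if (any(masses$mass_kg <= 0)) stop("all masses must be positive")
  miss_cloud <- setdiff(masses$specimen_id, names(clouds))
  miss_mass <- setdiff(names(clouds), masses$specimen_id)
  if (length(miss_cloud) || length(miss_mass))
    stop("specimen mismatch between clouds and masses; ",
         if (length(miss_cloud))
           paste0("no cloud for: ", paste(miss_cloud, collapse = ", "), "; "),
         if (length(miss_mass))
           paste0("no mass for: ", paste(miss_mass, collapse = ", ")))
  lapply(clouds, check_cloud)
  invisible(TRUE)
}

#' Sweep the refinement coefficient across a calibration sample
#'
#' For every specimen and every downsampling repeat, the cloud is
#' subsampled to `n_points` (seeded reproducibly per specimen and
#' repeat), one alpha-complex is built, and the alpha-shape volume is
#' queried at every `k` of the grid (`alpha = l_ref * k` with `l_ref`
#' from the subsampled cloud). Volumes are averaged across repeats
#' (arithmetic mean before the log transform by default), and a log-log
#' OLS model of mass on mean volume is fitted at every `k`
#' ([fit_loglog_ols()]). At a given `k` the fit is skipped (model `NULL`)
#' when any specimen has zero alpha-volume, as happens when small alphas
#' fragment the shape away entirely.
#'
#' @param clouds named list of [point_cloud()] objects (names are
#'   specimen ids).
#' @param masses data.frame with columns `specimen_id`, `mass_kg`.
#' @param grid a [k_grid()].
#' @param n_points common downsampling target per specimen.
#' @param n_reps downsampling repeats averaged per specimen.
#' @param seed master seed; every repeat's subsample derives
#'   deterministically from it and the specimen id, so the whole sweep is
#'   reproducible bitwise.
#' @param average `"volume"` (arithmetic mean of repeat volumes, default)
#'   or `"log"` (geometric mean).
#' @return an object of class `sweep_result`: per-(specimen, k) mean
#'   volumes and repeat standard deviations, per-k models and r-squared
#'   values, the optimal k and model, and the run parameters.
#' @seealso [select_optimal_k()], [refit_sweep()], [write_sweep_csv()]
#' @export
calibrate_sweep <- function(clouds, masses, grid = k_grid(),
                            n_points = 500000L, n_reps = 10L, seed = 1L,
                            average = c("volume", "log")) {
  average <- match.arg(average)
  stopifnot(inherits(grid, "k_grid"), n_reps >= 1L)
  check_specimens(clouds, masses)
  if (length(clouds) < 3L) stop("need at least 3 specimens")
  ids <- masses$specimen_id
  S <- length(ids); K <- grid$n_k
  vols <- matrix(NA_real_, S, K, dimnames = list(ids, NULL))
  sds <- matrix(NA_real_, S, K, dimnames = list(ids, NULL))
  for (s in seq_len(S)) {
    cl <- clouds[[ids[s]]]
    rep_vols <- matrix(NA_real_, n_reps, K)
    for (r in seq_len(n_reps)) {
      sub <- withCallingHandlers(
        downsample_cloud(cl, n_points, derive_seed(seed, ids[s], r)),
        warning = function(w) {
          if (r > 1L) invokeRestart("muffleWarning")
        })
      ac <- tryCatch(alpha_complex(sub),
                     error = function(e)
                       stop(sprintf("specimen '%s': %s", ids[s],
                                    conditionMessage(e)), call. = FALSE))
      rep_vols[r, ] <- alpha_volume(ac, ac$l_ref * grid$k)
    }
    vols[s, ] <- if (average == "volume") colMeans(rep_vols)
                 else exp(colMeans(log(pmax(rep_vols, .Machine$double.xmin))))
    sds[s, ] <- apply(rep_vols, 2, sd)
  }
  sw <- structure(list(grid = grid, specimen_ids = ids,
                       masses = masses$mass_kg, volumes = vols,
                       volume_sd = sds, n_points = as.integer(n_points),
                       n_reps = as.integer(n_reps), seed = as.integer(seed),
                       average = average),
                  class = "sweep_result")
  refit_sweep(sw, masses$mass_kg)
}

#' Refit the per-k models of a sweep against (new) masses
#'
#' Reuses the stored per-(specimen, k) mean volumes of a
#' [calibrate_sweep()] result and refits the log-log OLS model at every
#' `k`. Useful to explore alternative mass assignments (e.g. noise
#' perturbations of the mass table) without recomputing any geometry.
#'
#' @param sweep a `sweep_result`.
#' @param masses numeric vector of masses (kg), in `sweep$specimen_ids`
#'   order.
#' @return the sweep with `models`, `r2`, `optimal_k` and `optimal_model`
#'   recomputed.
#' @export
refit_sweep <- function(sweep, masses) {
  stopifnot(inherits(sweep, "sweep_result"),
            length(masses) == length(sweep$specimen_ids))
  K <- sweep$grid$n_k
  models <- vector("list", K)
  for (j in seq_len(K)) {
    v <- sweep$volumes[, j]
    models[[j]] <- if (all(v > 0) && sd(log(v)) > 0)
      fit_loglog_ols(v, masses, k = sweep$grid$k[j]) else NULL
  }
  sweep$masses <- masses
  sweep$models <- models
  sweep$r2 <- vapply(models, function(m) if (is.null(m)) NA_real_ else m$r2,
                     numeric(1))
  opt <- select_optimal_k(sweep)
  sweep$optimal_k <- opt$k
  sweep$optimal_model <- opt$model
  sweep
}

#' Select the optimal refinement coefficient
#'
#' Returns the grid `k` whose per-k regression attains the highest
#' r-squared, the "optimum" predictive equation. Ties are broken toward
#' the smaller `k` (the tighter fit, less sensitive to outlying points
#' such as uncertainly mounted extremities).
#'
#' @param sweep a `sweep_result` with fitted models.
#' @return list with elements `k` and `model` (a `mass_model`).
#' @export
select_optimal_k <- function(sweep) {
  stopifnot(inherits(sweep, "sweep_result"))
  r2 <- sweep$r2
  if (all(is.na(r2))) stop("no valid fit at any k (all fits degenerate)")
  j <- which(r2 == max(r2, na.rm = TRUE))[1L]  # grid ascending: first = smallest k
  list(k = sweep$grid$k[j], model = sweep$models[[j]])
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("<sweep_result> %d specimens x %d k values (%s grid %.3g..%.3g)\n",
              length(x$specimen_ids), x$grid$n_k, x$grid$spacing,
              x$grid$k_min, x$grid$k_max))
  cat(sprintf("  n_points = %d, n_reps = %d, seed = %d\n",
              x$n_points, x$n_reps, x$seed))
  if (!is.null(x$optimal_model))
    cat(sprintf("  optimal k = %.4g (r2 = %.4f, b = %.4f)\n", x$optimal_k,
                x$optimal_model$r2, x$optimal_model$b))
  invisible(x)
}

#' Write sweep results as long-format CSV
#'
#' Two files: `<stem>_volumes.csv` (`k, specimen_id, mean_volume_m3,
#' sd_volume_m3`) and `<stem>_fits.csv` (`k, a, b, r2, mse`), convenient
#' for plotting r-squared-versus-k and downsampling-stability curves.
#'
#' @param sweep a `sweep_result`.
#' @param stem output path stem.
#' @return invisibly, the two file paths.
#' @export
write_sweep_csv <- function(sweep, stem) {
  stopifnot(inherits(sweep, "sweep_result"))
  kv <- sweep$grid$k
  vol <- data.frame(
    k = rep(kv, each = length(sweep$specimen_ids)),
    specimen_id = rep(sweep$specimen_ids, times = length(kv)),
    mean_volume_m3 = as.vector(sweep$volumes),
    sd_volume_m3 = as.vector(sweep$volume_sd))
  fits <- data.frame(
    k = kv,
    a = vapply(sweep$models, function(m) m$a %||% NA_real_, numeric(1)),
    b = vapply(sweep$models, function(m) m$b %||% NA_real_, numeric(1)),
    r2 = sweep$r2,
    mse = vapply(sweep$models, function(m) m$mse %||% NA_real_, numeric(1)))
  p1 <- paste0(stem, "_volumes.csv"); p2 <- paste0(stem, "_fits.csv")
  write.csv(vol, p1, row.names = FALSE)
  write.csv(fits, p2, row.names = FALSE)
  invisible(c(p1, p2))
}

#' Write a fitted mass model to a JSON file
#'
#' Stores the coefficients, their confidence intervals, fit statistics
#' and the provenance needed to apply the model consistently (`k`,
#' `n_points`, `seed`, specimen ids).
#'
#' @param model a `mass_model`.
#' @param path output file.
#' @param n_points,seed,specimen_ids optional provenance (taken from a
#'   sweep when calling via [cli_calibrate()]).
#' @export
write_model <- function(model, path, n_points = NULL, seed = NULL,
                        specimen_ids = NULL) {
  stopifnot(inherits(model, "mass_model"))
  obj <- list(a = model$a, b = model$b, a_ci95 = model$a_ci95,
              b_ci95 = model$b_ci95, r2 = model$r2, mse = model$mse,
              n = model$n, k = model$k, n_points = n_points, seed = seed,
              specimen_ids = specimen_ids)
  jsonlite::write_json(obj[!vapply(obj, is.null, TRUE)], path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a mass model from a JSON file
#' @param path file written by [write_model()].
#' @return a `mass_model` (with `n_points` attached when present).
#' @export
read_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) stop("corrupt model file: ", path,
                                           " (", conditionMessage(e), ")"))
  if (!all(c("a", "b") %in% names(obj)))
    stop("corrupt model file (missing coefficients): ", path)
  structure(list(a = obj$a, b = obj$b,
                 a_ci95 = obj$a_ci95 %||% c(NA_real_, NA_real_),
                 b_ci95 = obj$b_ci95 %||% c(NA_real_, NA_real_),
                 r2 = obj$r2 %||% NA_real_, mse = obj$mse %||% NA_real_,
                 n = obj$n %||% NA_integer_, k = obj$k,
                 n_points = obj$n_points),
            class = "mass_model")
}
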