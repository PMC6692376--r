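#' Five-band functionalization-quality thresholds
#'
#' Band edges for the two quality metrics, ordered dark_green < light_green
#' < yellow < orange < dark_red (a value below the first edge falls in the
#' best band). The light_green upper edges are the conventional key values
#' 0.5 for `C_v,FUNCD` and 0.05 for `f_nonfunctionalized`: crossing either
#' disqualifies a product from a "green" label. The remaining edges are
#' package defaults (the exact intermediate boundaries are a presentation
#' convention, not a physical constant) and are fully configurable.
#'
#' @param cv_edges Increasing band edges for the coefficient of variation.
#' @param f_edges Increasing band edges for the non-functionalized fraction.
#' @return A `quality_thresholds` object.
#' @export
quality_thresholds <- function(cv_edges = c(0.38, 0.5, 0.65, 0.8),
                               f_edges = c(0.01, 0.05, 0.10, 0.25)) {
  for (e in list(cv_edges, f_edges)) {
    if (length(e) != 4 || any(diff(e) <= 0) || any(e < 0)) {
      abort("band edges must be four strictly increasing non-negative values")
    }
  }
  structure(list(cv_edges = cv_edges, f_edges = f_edges),
            class = "quality_thresholds")
}

.QUALITY_LEVELS <- c("dark_green", "light_green", "yellow", "orange", "dark_red")

#' Classify functionalization quality
#'
#' Each metric is assigned its band by its edges; the overall label is the
#' worse of the two bands, so increasing either metric never improves the
#' label. An undefined coefficient of variation (entirely non-functional
#' population) maps to `dark_red`.
#'
#' @param cv Coefficient(s) of variation of the FUNCD (`NA` for undefined).
#' @param f_nonfunc Fraction(s) of non-functionalized chains.
#' @param thresholds A [quality_thresholds()] object.
#' @return Ordered factor with levels dark_green < light_green < yellow <
#'   orange < dark_red, vectorized over the inputs.
#' @examples
#' classify_quality(cv = c(0, 0.6, 0.3), f_nonfunc = c(0, 0.01, 0.30))
#' @export
classify_quality <- function(cv, f_nonfunc, thresholds = quality_thresholds()) {
  if (any(stats::na.omit(c(cv, f_nonfunc)) < 0)) {
    abort("quality metrics must be non-negative")
  }
  n <- max(length(cv), length(f_nonfunc))
  cv <- rep_len(cv, n)
  f_nonfunc <- rep_len(f_nonfunc, n)
  band_cv <- ifelse(is.na(cv), 5L,
                    findInterval(cv, thresholds$cv_edges) + 1L)
  band_f <- ifelse(is.na(f_nonfunc), 5L,
                   findInterval(f_nonfunc, thresholds$f_edges) + 1L)
  factor(.QUALITY_LEVELS[pmax(band_cv, band_f)],
         levels = .QUALITY_LEVELS, ordered = TRUE)
}

#' Quality metrics and label for a final chain population
#'
#' @param population Population tibble or `kmc_trajectory`.
#' @param thresholds A [quality_thresholds()].
#' @return One-row tibble: `cv_funcd`, `f_nonfunctionalized`, `label`,
#'   `cv_defined`.
#' @export
quality_metrics <- function(population, thresholds = quality_thresholds()) {
  funcd <- marginal_funcd(build_func_cld(population))
  m <- funcd_moments(funcd)
  cv <- if (m$mu > 0) m$sigma / m$mu else NA_real_
  f0 <- fraction_nonfunctionalized(funcd)
  tibble(cv_funcd = cv, f_nonfunctionalized = f0,
         label = classify_quality(cv, f0, thresholds),
         cv_defined = m$mu > 0)
}

#' Scan reaction conditions for functionalization quality
#'
#' Runs a full simulate-then-score pipeline for every row of a condition
#' grid, optionally with replicate seeds. Metrics are averaged over
#' replicates (spread reported as a standard deviation) and the color label
#' is assigned to the replicate-mean metrics. Failed runs produce a row
#' with `error` filled in; the scan continues.
#'
#' @param grid Tibble/data frame with columns `preset` (chemistry preset
#'   name, see [preset_names()]) or `model` (list column of
#'   [kinetic_model()]s), `target_dp`, `f2_0`, `temperature` (degrees C).
#' @param n_chains Chains per run.
#' @param replicates Replicate runs per condition; replicate `r` of row `g`
#'   uses seed `seed + (g - 1) * replicates + (r - 1)`.
#' @param seed Base seed.
#' @param thresholds A [quality_thresholds()].
#' @param stop_conversion Overall conversion at which the product is scored.
#' @param ... Passed to [run_config()].
#' @return Tibble, one row per grid condition, in grid order: condition
#'   columns, `cv_funcd`, `f_nonfunctionalized` (replicate means),
#'   `cv_sd`, `f_sd`, `label`, `seeds`, `error`.
#' @export
design_scan <- function(grid, n_chains = 1e4, replicates = 1, seed = 1,
                        thresholds = quality_thresholds(),
                        stop_conversion = 0.995, ...) {
  grid <- as_tibble(grid)
  need <- c("target_dp", "f2_0", "temperature")
  if (!all(need %in% names(grid))) {
    abort("`grid` needs columns target_dp, f2_0, temperature and preset (or model)")
  }
  if (!("preset" %in% names(grid)) && !("model" %in% names(grid))) {
    abort("`grid` needs a `preset` or `model` column")
  }
  rows <- purrr::map(seq_len(nrow(grid)), function(g) {
    cond <- grid[g, ]
    seeds <- seed + (g - 1) * replicates + seq_len(replicates) - 1
    res <- tryCatch({
      model <- if ("model" %in% names(grid)) cond$model[[1]] else {
        preset_model(cond$preset)
      }
      run <- run_config(temperature = cond$temperature,
                        target_dp = cond$target_dp, f2_0 = cond$f2_0,
                        n_chains = n_chains,
                        stop_conversion = stop_conversion, ...)
      reps <- purrr::map(seeds, function(s) {
        traj <- kmc_simulate(model, run, seed = s)
        quality_metrics(traj, thresholds)
      })
      reps <- dplyr::bind_rows(reps)
      cv_mean <- if (all(is.na(reps$cv_funcd))) NA_real_ else {
        mean(reps$cv_funcd, na.rm = TRUE)
      }
      f_mean <- mean(reps$f_nonfunctionalized)
      tibble(cv_funcd = cv_mean, f_nonfunctionalized = f_mean,
             cv_sd = sd(reps$cv_funcd), f_sd = sd(reps$f_nonfunctionalized),
             label = classify_quality(cv_mean, f_mean, thresholds),
             error = NA_character_)
    }, error = function(e) {
      tibble(cv_funcd = NA_real_, f_nonfunctionalized = NA_real_,
             cv_sd = NA_real_, f_sd = NA_real_,
             label = factor(NA, levels = .QUALITY_LEVELS, ordered = TRUE),
             error = conditionMessage(e))
    })
    cond_out <- dplyr::select(cond, -dplyr::any_of("model"))
    dplyr::bind_cols(cond_out, res,
                     tibble(seeds = paste(seeds, collapse = ",")))
  })
  dplyr::bind_rows(rows)
}
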