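#' Agreement summary table by vegetation type, representativeness, and phase
#'
#' Computes, for every (vegetation type) x (apples/oranges) x
#' (rising/falling) cell: the pair count, per-source date SDs, Pearson r,
#' mean bias +/- SD (satellite minus camera), Deming slope and intercept
#' with jackknife SEs, and the RMS perpendicular regression distance with
#' n - 2 degrees of freedom. Deming columns are blanked (`NA`) when the
#' slope is not significantly different from 0 at p < 0.05 or n < 10.
#' Rising dates after DOY 270 and falling dates before DOY 90 are wrapped
#' onto a continuous axis (see [wrap_doy()]) before the statistics are
#' computed, unless `wrap = FALSE`.
#'
#' All cells are returned; the column `meets_min_n` marks the vegetation
#' type x representativeness combinations with at least `min_n` pairs in
#' both phases — the subset a headline report would print, the remainder
#' forming the full supplementary-style matrix.
#'
#' @param pairs Paired-transition tibble from [pair_transitions()]; a
#'   `comparison` column is added via [classify_comparison()] if absent.
#' @param lambda Deming error-variance ratio (default 1).
#' @param min_n Minimum pairs per phase for headline inclusion (default 25).
#' @param wrap Wrap DOY values across the year boundary (default TRUE).
#' @param table Apples mapping, see [apples_table()].
#' @return A tibble with one row per group and columns `roi_veg_type`,
#'   `comparison`, `direction`, `n`, `sd_phenocam`, `sd_modis`,
#'   `pearson_r`, `bias_mean`, `bias_sd`, `slope`, `slope_se`, `intercept`,
#'   `intercept_se`, `rms_distance`, `meets_min_n`.
#' @export
agreement_summary <- function(pairs, lambda = 1, min_n = 25, wrap = TRUE,
                              table = apples_table()) {
  pairs <- as_tibble(pairs)
  if (!"comparison" %in% names(pairs)) {
    pairs$comparison <- classify_comparison(pairs$roi_veg_type,
                                            pairs$igbp_code, table)
  }
  if (wrap) {
    pairs$phenocam_doy <- wrap_doy(pairs$phenocam_doy, pairs$direction)
    pairs$modis_doy <- wrap_doy(pairs$modis_doy, pairs$direction)
  }
  groups <- pairs |>
    dplyr::group_by(.data$roi_veg_type, .data$comparison, .data$direction)
  out <- groups |>
    dplyr::group_modify(function(g, key) {
      b <- bias_stats(g)
      row <- tibble(n = nrow(g),
                    sd_phenocam = b$sd_phenocam, sd_modis = b$sd_modis,
                    pearson_r = if (nrow(g) >= 3 &&
                                    sd(g$phenocam_doy) > 0 &&
                                    sd(g$modis_doy) > 0)
                      cor(g$phenocam_doy, g$modis_doy) else NA_real_,
                    bias_mean = b$bias_mean, bias_sd = b$bias_sd,
                    slope = NA_real_, slope_se = NA_real_,
                    intercept = NA_real_, intercept_se = NA_real_,
                    rms_distance = NA_real_)
      if (nrow(g) >= 3) {
        fit <- try(deming_fit(g, lambda = lambda), silent = TRUE)
        if (!inherits(fit, "try-error")) {
          row$rms_distance <- fit$rms_distance
          if (fit$reportable) {
            row$slope <- unname(fit$coefficients["slope"])
            row$slope_se <- unname(fit$se["slope"])
            row$intercept <- unname(fit$coefficients["intercept"])
            row$intercept_se <- unname(fit$se["intercept"])
          }
        }
      }
      row
    }) |>
    dplyr::ungroup()
  # headline eligibility: >= min_n pairs in both phases for the veg x class
  elig <- out |>
    dplyr::group_by(.data$roi_veg_type, .data$comparison) |>
    dplyr::summarise(
      meets_min_n = dplyr::n_distinct(.data$direction) >= 2 &&
        all(.data$n >= min_n),
      .groups = "drop")
  dplyr::left_join(out, elig, by = c("roi_veg_type", "comparison"))
}
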