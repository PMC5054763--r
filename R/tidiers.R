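# broom-style tidiers for the package's result objects.

#' Tidy a Bland-Altman analysis
#'
#' One row per measurement pair: the pair mean and the difference
#' (tracker minus comparator).
#'
#' @param x a `bland_altman` object.
#' @param ... unused.
#' @export
tidy.bland_altman <- function(x, ...) {
  x$pairs
}

#' One-row summary of a Bland-Altman analysis
#' @param x a `bland_altman` object.
#' @param ... unused.
#' @export
glance.bland_altman <- function(x, ...) {
  tibble::tibble(bias_deg = x$bias_deg, loa_low_deg = x$loa_low_deg,
                 loa_high_deg = x$loa_high_deg, sd_diff_deg = x$sd_diff_deg,
                 loa_multiplier = x$loa_multiplier, n = x$n)
}

#' Tidy an ICC result (one row per reported form)
#' @param x an `icc_result`.
#' @param ... unused.
#' @export
tidy.icc_result <- function(x, ...) {
  tibble::tibble(
    measure = c("single_measures", "average_measures"),
    icc = c(x$icc_single_measures, x$icc_average_measures),
    type = x$type
  )
}

#' One-row summary of an ICC result
#' @param x an `icc_result`.
#' @param ... unused.
#' @export
glance.icc_result <- function(x, ...) {
  tibble::tibble(icc_single_measures = x$icc_single_measures,
                 icc_average_measures = x$icc_average_measures,
                 n_poses = x$n_poses, n_repeats = x$n_repeats,
                 type = x$type,
                 ms_rows = x$mean_squares$msr,
                 ms_cols = x$mean_squares$msc,
                 ms_error = x$mean_squares$mse)
}

#' Per-axis agreement statistics as a tibble
#' @param x an `agreement_result`.
#' @param ... unused.
#' @export
tidy.agreement_result <- function(x, ...) {
  x$summary
}

#' One-row overview of an agreement analysis
#' @param x an `agreement_result`.
#' @param ... unused.
#' @export
glance.agreement_result <- function(x, ...) {
  tibble::tibble(n_axes = nrow(x$summary), n_pairs = sum(x$summary$n_pairs),
                 min_r = min(x$summary$pearson_r),
                 min_r_squared = min(x$summary$r_squared))
}
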