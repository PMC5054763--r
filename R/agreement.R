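# Method-comparison statistics between two paired measurement series:
# correlation, ordinary least squares, Bland-Altman limits of agreement,
# and two-way random-effects intraclass correlation.

#' Pearson correlation with exact t-based p-value
#'
#' @param x,y paired numeric series (degrees), n >= 3, finite,
#'   non-constant.
#' @return one-row tibble `r`, `p_value`, `n`.
#' @export
pearson <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop("need at least 3 pairs")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("series must be finite")
  if (sd(x) == 0 || sd(y) == 0) {
    stop("undefined correlation: a series has zero variance")
  }
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  tibble::tibble(r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Ordinary least squares of y on x
#'
#' @inheritParams pearson
#' @return one-row tibble `gradient`, `intercept_deg`, `r_squared`, `n`.
#' @export
linear_regression <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop("need at least 3 pairs")
  if (sd(x) == 0) stop("singular design: x is constant")
  fit <- lm(y ~ x)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - sum(fit$residuals^2) / ss_tot else 1
  tibble::tibble(gradient = unname(coef(fit)[2]),
                 intercept_deg = unname(coef(fit)[1]),
                 r_squared = r2,
                 n = length(x))
}

#' Bland-Altman agreement analysis
#'
#' Differences are taken as `y - x` (tracker minus comparator); the bias is
#' their mean and the limits of agreement are
#' `bias +/- loa_multiplier * SD(diff)` with the sample (n-1) SD. The
#' per-pair means and differences are kept for plotting.
#'
#' @inheritParams pearson
#' @param loa_multiplier multiplier for the limits of agreement (1.96 gives
#'   nominal 95% limits for Gaussian differences).
#' @return object of class `bland_altman`; see [glance.bland_altman()] and
#'   [tidy.bland_altman()].
#' @export
bland_altman <- function(x, y, loa_multiplier = 1.96) {
  stopifnot(length(x) == length(y))
  if (length(x) < 2) stop("need at least 2 pairs")
  d <- y - x
  bias <- mean(d)
  s <- sd(d)
  structure(
    list(bias_deg = bias,
         loa_low_deg = bias - loa_multiplier * s,
         loa_high_deg = bias + loa_multiplier * s,
         sd_diff_deg = s, loa_multiplier = loa_multiplier, n = length(d),
         pairs = tibble::tibble(mean_deg = (x + y) / 2, diff_deg = d)),
    class = "bland_altman"
  )
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("<bland_altman> bias %.3f deg, %g%% limits [%.3f, %.3f], n = %d\n",
              x$bias_deg, round(200 * pnorm(x$loa_multiplier) - 100, 1),
              x$loa_low_deg, x$loa_high_deg, x$n))
  invisible(x)
}

#' @importFrom stats pnorm
NULL

#' Restrict paired measurements to the tracker's operational range
#'
#' Keeps pairs whose comparator (reference instrument) reading lies within
#' the symmetric bound for their axis; the comparator is the natural
#' reference since it is independent of the instrument under test. The
#' numbers of kept and discarded pairs are attached as attributes.
#'
#' @param pairs tibble with columns `axis` and `instrument_a_deg`
#'   (comparator) at minimum.
#' @param range_bounds_deg named vector of per-axis bounds, degrees, e.g.
#'   `c(yaw = 30, pitch = 20, roll = 50)`.
#' @return filtered tibble with attributes `n_kept`, `n_discarded`.
#' @export
restrict_to_operational_range <- function(pairs,
                                          range_bounds_deg = c(yaw = 30, pitch = 20, roll = 50)) {
  stopifnot(all(range_bounds_deg >= 0),
            all(c("axis", "instrument_a_deg") %in% names(pairs)))
  bound <- range_bounds_deg[pairs$axis]
  keep <- !is.na(bound) & abs(pairs$instrument_a_deg) <= bound
  out <- pairs[keep, ]
  attr(out, "n_kept") <- sum(keep)
  attr(out, "n_discarded") <- sum(!keep)
  out
}

# two-way ANOVA mean squares for a complete poses x repeats matrix
anova_mean_squares <- function(mat) {
  n <- nrow(mat); k <- ncol(mat)
  grand <- mean(mat)
  row_m <- rowMeans(mat); col_m <- colMeans(mat)
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sst <- sum((mat - grand)^2)
  sse <- sst - ssr - ssc
  list(msr = ssr / (n - 1), msc = ssc / (k - 1),
       mse = sse / ((n - 1) * (k - 1)), n = n, k = k)
}

#' Intraclass correlation coefficient (two-way random effects)
#'
#' Computes single-measures and average-measures ICC from the classical
#' two-way ANOVA mean-squares decomposition of a complete poses x repeats
#' matrix (rows = targets/poses, columns = repeats/raters). The default
#' absolute-agreement form charges systematic differences between repeats
#' against reliability; the consistency form ignores them.
#'
#' @param mat numeric matrix, >= 2 rows and >= 2 columns, no missing
#'   cells.
#' @param type `"agreement"` (default) or `"consistency"`.
#' @return object of class `icc_result` with fields
#'   `icc_single_measures`, `icc_average_measures`, `n_poses`,
#'   `n_repeats`, `type`, and the mean squares.
#' @export
icc <- function(mat, type = c("agreement", "consistency")) {
  type <- match.arg(type)
  mat <- as.matrix(mat)
  if (anyNA(mat)) stop("missing cell: the repeats matrix must be complete")
  if (nrow(mat) < 2 || ncol(mat) < 2) stop("need >= 2 poses and >= 2 repeats")
  ms <- anova_mean_squares(mat)
  if (ms$msr == 0 && ms$mse == 0 && ms$msc == 0) {
    stop("undefined ICC: zero total variance")
  }
  n <- ms$n; k <- ms$k
  if (type == "agreement") {
    single <- (ms$msr - ms$mse) /
      (ms$msr + (k - 1) * ms$mse + (k / n) * (ms$msc - ms$mse))
    average <- (ms$msr - ms$mse) / (ms$msr + (ms$msc - ms$mse) / n)
  } else {
    single <- (ms$msr - ms$mse) / (ms$msr + (k - 1) * ms$mse)
    average <- (ms$msr - ms$mse) / ms$msr
  }
  structure(
    list(icc_single_measures = single, icc_average_measures = average,
         n_poses = n, n_repeats = k, type = type,
         mean_squares = ms[c("msr", "msc", "mse")]),
    class = "icc_result"
  )
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("<icc_result> %s: average measures %.4f, single measures %.4f (%d poses x %d repeats)\n",
              x$type, x$icc_average_measures, x$icc_single_measures,
              x$n_poses, x$n_repeats))
  invisible(x)
}

#' Full per-axis agreement analysis of a paired measurement table
#'
#' Runs correlation, regression, and Bland-Altman per axis on a paired
#' two-instrument table (such as [simulate_protocol_study()] output),
#' optionally after restricting to the operational range.
#'
#' @param pairs tibble with columns `axis`, `instrument_a_deg`,
#'   `instrument_b_deg`.
#' @param restrict optional named per-axis bounds passed to
#'   [restrict_to_operational_range()]; `NULL` keeps everything.
#' @param loa_multiplier see [bland_altman()].
#' @return object of class `agreement_result`: per-axis tibble plus the
#'   retained Bland-Altman pair sets.
#' @export
agreement_analysis <- function(pairs, restrict = NULL, loa_multiplier = 1.96) {
  if (!is.null(restrict)) pairs <- restrict_to_operational_range(pairs, restrict)
  split_ax <- split(pairs, pairs$axis)
  rows <- purrr::imap(split_ax, function(df, ax) {
    x <- df$instrument_a_deg; y <- df$instrument_b_deg
    pr <- pearson(x, y)
    lr <- linear_regression(x, y)
    ba <- bland_altman(x, y, loa_multiplier)
    tibble::tibble(
      axis = ax, n_pairs = nrow(df),
      pearson_r = pr$r, p_value = pr$p_value,
      gradient = lr$gradient, intercept_deg = lr$intercept_deg,
      r_squared = lr$r_squared,
      bias_deg = ba$bias_deg, loa_low_deg = ba$loa_low_deg,
      loa_high_deg = ba$loa_high_deg
    )
  })
  structure(
    list(summary = dplyr::bind_rows(rows)[order(match(names(split_ax), axis_names)), ],
         pairs = pairs, loa_multiplier = loa_multiplier),
    class = "agreement_result"
  )
}

#' @export
print.agreement_result <- function(x, ...) {
  cat("<agreement_result>\n")
  print(as.data.frame(x$summary), digits = 4, row.names = FALSE)
  invisible(x)
}
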