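#' Windowed area under an electropherogram trace
#'
#' Trapezoidal integral of RFU over fragment size on the window
#' `[lo, hi]` intersected with the observed size range. Window boundaries
#' that fall between grid points are handled by linear interpolation of
#' the signal at the cut point, which makes the integral exactly additive
#' over adjacent windows. The default `lo = 250` excludes sub-250 bp
#' signal, which on real traces is confounded by residual RNA.
#'
#' @param size_bp Strictly increasing sizes in bp.
#' @param rfu Signal values, same length (NAs dropped pairwise).
#' @param lo,hi Window bounds in bp (`hi = Inf` for the full upper range).
#' @return Area in RFU x bp; 0 (with a warning) if the window does not
#'   intersect the observed range.
#' @export
trace_auc <- function(size_bp, rfu, lo = 250, hi = Inf) {
  stopifnot(length(size_bp) == length(rfu), lo < hi)
  keep <- !is.na(rfu) & !is.na(size_bp)
  s <- size_bp[keep]
  y <- rfu[keep]
  if (length(s) < 2) return(0)
  if (any(diff(s) <= 0)) stop("sizes must be strictly increasing", call. = FALSE)
  lo <- max(lo, min(s))
  hi <- min(hi, max(s))
  if (lo >= hi) {
    warning(warningCondition(
      "integration window does not intersect the observed size range",
      class = "epg_window_warning"))
    return(0)
  }
  inner <- s > lo & s < hi
  xs <- c(lo, s[inner], hi)
  ys <- c(stats::approx(s, y, lo, ties = "ordered")$y,
          y[inner],
          stats::approx(s, y, hi, ties = "ordered")$y)
  pracma::trapz(xs, ys)
}

#' High-molecular-weight DNA report per group and time point
#'
#' For each group x time mean trace, computes the total AUC at or above
#' `min_size`, the HMW AUC at or above `hmw_threshold`, the raw HMW
#' percentage `100 * hmw_auc / total_auc`, and the standardized HMW
#' percentage `100 * hmw_auc / max(hmw_auc)` where the reference is the
#' single group x time entry with the globally largest HMW AUC (ties are
#' broken by table order and reported). The reference row has
#' `std_pct = 100` exactly.
#'
#' @param summaries Output of [summarize_group()] (mean traces), or any
#'   tibble with grouping columns, `time_days`, `size_bp` and `mean_rfu`.
#' @param hmw_threshold HMW size boundary in bp (default 20,000, inclusive).
#' @param min_size Lower size cutoff in bp (default 250, inclusive).
#' @return Tibble with the grouping columns, `time_days`, `total_auc`,
#'   `hmw_auc`, `raw_pct`, `std_pct`, `is_reference`.
#' @export
hmw_report <- function(summaries, hmw_threshold = 20000, min_size = 250) {
  stopifnot(hmw_threshold > min_size)
  group_cols <- intersect(c("solution", "heat", "temperature", "group"),
                          names(summaries))
  key_cols <- c(setdiff(group_cols, "group"), "time_days")
  span <- range(summaries$size_bp)
  if (span[1] > min_size || span[2] < hmw_threshold) {
    warning("summary grid does not span [", min_size, ", ", hmw_threshold,
            "] bp; AUC windows are truncated to the observed range")
  }
  rep <- summaries |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(group_cols, "time_days")))) |>
    dplyr::summarise(
      total_auc = trace_auc(.data$size_bp, .data$mean_rfu, lo = min_size),
      hmw_auc = trace_auc(.data$size_bp, .data$mean_rfu, lo = hmw_threshold),
      .groups = "drop"
    )
  rep$raw_pct <- ifelse(rep$total_auc > 0, 100 * rep$hmw_auc / rep$total_auc,
                        NA_real_)
  max_auc <- max(rep$hmw_auc)
  ref_idx <- which(rep$hmw_auc == max_auc)
  if (length(ref_idx) > 1) {
    message("HMW reference tie between ", length(ref_idx),
            " entries; using the first in table order")
  }
  ref_idx <- ref_idx[1]
  rep$std_pct <- if (max_auc > 0) 100 * rep$hmw_auc / max_auc else NA_real_
  rep$is_reference <- seq_len(nrow(rep)) == ref_idx
  attr(rep, "reference") <- rep[ref_idx, c(key_cols)]
  rep
}

#' DESS/ETOH scale factors per time point
#'
#' From a solution-pooled HMW report, tabulates the raw and standardized
#' HMW percentages per solution and the scale factor
#' `std_pct_DESS / std_pct_ETOH` at each time point. Ratios are kept at
#' full precision; [format_scale_factors()] rounds to 1 decimal for
#' reporting.
#'
#' @param reports Tibble with columns `solution`, `time_days`, `std_pct`
#'   (and optionally `raw_pct`), one row per solution x time.
#' @return Tibble: `time_days`, `raw_pct_DESS`, `raw_pct_ETOH`,
#'   `std_pct_DESS`, `std_pct_ETOH`, `scale_factor`. A missing solution or
#'   a zero ETOH denominator yields a missing ratio.
#' @export
scale_factors <- function(reports) {
  stopifnot(all(c("solution", "time_days", "std_pct") %in% names(reports)))
  check_levels(reports$solution, c("DESS", "ETOH"), "solution")
  if (anyDuplicated(reports[, c("solution", "time_days")])) {
    stop("reports must have one row per solution x time point ",
         "(pool groups by solution first)", call. = FALSE)
  }
  if (!"raw_pct" %in% names(reports)) reports$raw_pct <- NA_real_
  wide <- tidyr::pivot_wider(
    reports[, c("solution", "time_days", "raw_pct", "std_pct")],
    names_from = "solution", values_from = c("raw_pct", "std_pct")
  )
  for (col in c("raw_pct_DESS", "raw_pct_ETOH", "std_pct_DESS", "std_pct_ETOH")) {
    if (!col %in% names(wide)) wide[[col]] <- NA_real_
  }
  wide$scale_factor <- ifelse(
    !is.na(wide$std_pct_ETOH) & wide$std_pct_ETOH > 0,
    wide$std_pct_DESS / wide$std_pct_ETOH, NA_real_)
  dplyr::arrange(
    wide[, c("time_days", "raw_pct_DESS", "raw_pct_ETOH",
             "std_pct_DESS", "std_pct_ETOH", "scale_factor")],
    .data$time_days)
}

#' Round a scale-factor table for reporting
#'
#' Percentages and DESS/ETOH ratios are conventionally reported to one
#' decimal place.
#'
#' @param sf Output of [scale_factors()].
#' @param digits Decimal places (default 1).
#' @return Rounded copy of `sf`.
#' @export
format_scale_factors <- function(sf, digits = 1) {
  num <- setdiff(names(sf), "time_days")
  sf[num] <- lapply(sf[num], round, digits = digits)
  sf
}
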