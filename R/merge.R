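#' Size-binning rule for cross-run harmonization
#'
#' Instrument runs disagree slightly in their size calibration at large
#' fragment sizes, so traces from different runs rarely share exact size
#' points. Binning creates overlapping points: sizes up to 1 kbp are kept
#' as-is, sizes in (1 kbp, 10 kbp] are rounded up (ceiling) to the next
#' multiple of 10 bp, and sizes above 10 kbp are rounded half-up to the
#' nearest multiple of 100 bp.
#'
#' @param size Numeric vector of fragment sizes in bp, all > 0.
#' @return Binned sizes. Idempotent and monotone non-decreasing.
#' @export
bin_size <- function(size) {
  if (any(size <= 0)) stop("fragment sizes must be > 0", call. = FALSE)
  out <- size
  mid <- size > 1000 & size <= 10000
  out[mid] <- ceiling(size[mid] / 10) * 10
  hi <- size > 10000
  out[hi] <- floor(size[hi] / 100 + 0.5) * 100
  out
}

#' Bin sizes and average RFU within bins
#'
#' Applies [bin_size()] to every size, averages RFU values that fall in
#' the same bin within a sample, then clips negative averages to zero
#' (with `clip = "before"`, raw negative RFUs are clipped before
#' averaging instead). Point count never increases.
#'
#' @param traces Long trace tibble (`sample_id`, `run_id`, `size_bp`, `rfu`).
#' @param clip `"after"` (default) to clip the within-bin averages, or
#'   `"before"` to clip raw values first.
#' @return Long tibble with binned, strictly increasing `size_bp` per
#'   sample and nonnegative `rfu`.
#' @export
merge_traces <- function(traces, clip = c("after", "before")) {
  clip <- match.arg(clip)
  if (clip == "before") traces$rfu <- pmax(traces$rfu, 0)
  merged <- traces |>
    dplyr::mutate(size_bp = bin_size(.data$size_bp)) |>
    dplyr::group_by(.data$sample_id, .data$run_id, .data$size_bp) |>
    dplyr::summarise(rfu = mean(.data$rfu), .groups = "drop") |>
    dplyr::mutate(rfu = pmax(.data$rfu, 0)) |>
    dplyr::arrange(.data$run_id, .data$sample_id, .data$size_bp)
  merged
}

#' Align merged traces from several runs onto a common size grid
#'
#' The common grid is the union of binned sizes over all traces. Within a
#' trace's own observed range, values at grid points it does not itself
#' carry are filled by linear interpolation and flagged; outside its range
#' values are left missing (`NA`) — no extrapolation. Traces with fewer
#' than two points are excluded with a message.
#'
#' @param merged Output of [merge_traces()].
#' @return Long tibble `sample_id`, `run_id`, `size_bp`, `rfu`,
#'   `interpolated` (logical) on the common grid.
#' @export
align_runs <- function(merged) {
  grid <- sort(unique(merged$size_bp))
  keys <- dplyr::distinct(merged, .data$sample_id, .data$run_id)
  out <- vector("list", nrow(keys))
  dropped <- character(0)
  for (i in seq_len(nrow(keys))) {
    tr <- merged[merged$sample_id == keys$sample_id[i], ]
    if (nrow(tr) < 2) {
      dropped <- c(dropped, keys$sample_id[i])
      next
    }
    inside <- grid >= min(tr$size_bp) & grid <= max(tr$size_bp)
    vals <- rep(NA_real_, length(grid))
    vals[inside] <- stats::approx(tr$size_bp, tr$rfu, xout = grid[inside],
                                  method = "linear", ties = "ordered")$y
    out[[i]] <- tibble::tibble(
      sample_id = keys$sample_id[i],
      run_id = keys$run_id[i],
      size_bp = grid,
      rfu = vals,
      interpolated = inside & !(grid %in% tr$size_bp)
    )
  }
  if (length(dropped) > 0) {
    message("excluded ", length(dropped), " trace(s) with <2 points: ",
            paste(dropped, collapse = ", "))
  }
  dplyr::bind_rows(out)
}

#' Per-group mean traces with confidence bands
#'
#' Groups aligned traces by a subset of the treatment factors (time is
#' always a grouping variable) and computes, at every grid point, the mean
#' RFU and a two-sided confidence interval: mean +/- t(1-alpha/2, n-1) *
#' SD/sqrt(n) by default (`ci = "normal"` uses the normal quantile).
#' Groups with a single trace at a point get a degenerate interval equal
#' to the mean. Grid points with no observations in a group are dropped,
#' so only factor combinations actually present in the data are emitted.
#'
#' @param aligned Output of [align_runs()] (or any long trace tibble).
#' @param design Design tibble with one row per sample.
#' @param group_by Character subset of `c("solution","heat","temperature")`.
#' @param conf_level Confidence level (default 0.95).
#' @param ci `"t"` (default) or `"normal"`.
#' @return Tibble with the grouping columns, `group` label, `time_days`,
#'   `size_bp`, `mean_rfu`, `ci_low`, `ci_high`, `n_samples` (member
#'   traces in the group) and `n` (non-missing traces at the point).
#' @export
summarize_group <- function(aligned, design,
                            group_by = c("solution", "heat", "temperature"),
                            conf_level = 0.95, ci = c("t", "normal")) {
  ci <- match.arg(ci)
  stopifnot(all(group_by %in% c("solution", "heat", "temperature")))
  rec <- reconcile_samples(aligned, design)
  if (length(rec$traces_only) > 0) {
    stop("traces without a design row: ",
         paste(utils::head(rec$traces_only, 5), collapse = ", "), call. = FALSE)
  }
  df <- dplyr::inner_join(
    aligned,
    design[, c("sample_id", group_by, "time_days")],
    by = "sample_id"
  )
  alpha <- 1 - conf_level
  members <- df |>
    dplyr::distinct(.data$sample_id, dplyr::across(dplyr::all_of(c(group_by, "time_days")))) |>
    dplyr::count(dplyr::across(dplyr::all_of(c(group_by, "time_days"))),
                 name = "n_samples")
  out <- df |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(group_by, "time_days", "size_bp")))) |>
    dplyr::summarise(
      n = sum(!is.na(.data$rfu)),
      mean_rfu = mean(.data$rfu, na.rm = TRUE),
      sd_rfu = stats::sd(.data$rfu, na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$n >= 1)
  q <- if (ci == "t") {
    ifelse(out$n > 1, stats::qt(1 - alpha / 2, out$n - 1), 0)
  } else {
    ifelse(out$n > 1, stats::qnorm(1 - alpha / 2), 0)
  }
  half <- ifelse(out$n > 1, q * out$sd_rfu / sqrt(out$n), 0)
  out$ci_low <- out$mean_rfu - half
  out$ci_high <- out$mean_rfu + half
  out$sd_rfu <- NULL
  out <- dplyr::left_join(out, members, by = c(group_by, "time_days"))
  out$group <- do.call(paste, c(lapply(group_by, function(g) out[[g]]), sep = "."))
  dplyr::arrange(out, dplyr::across(dplyr::all_of(c(group_by, "time_days", "size_bp"))))
}
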