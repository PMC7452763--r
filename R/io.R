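#' Read electropherogram CSV exports
#'
#' Reads one or more wide-format trace files (one per instrument run): a
#' size axis column plus one RFU column per sample, comma separated with a
#' header row, as produced by PROsize-style instrument software exports.
#' Negative RFU values are preserved; clipping is a merge-stage concern.
#'
#' @param paths Character vector of file paths, one per run.
#' @param size_col Name of the size-axis column (default `"Size (bp)"`).
#' @param run_ids Optional run identifiers, one per path; defaults to the
#'   file names without extension.
#' @return Long tibble with columns `sample_id`, `run_id`, `size_bp`,
#'   `rfu`; sizes strictly increasing within each sample.
#' @export
read_traces <- function(paths, size_col = "Size (bp)", run_ids = NULL) {
  stopifnot(length(paths) >= 1)
  if (is.null(run_ids)) run_ids <- tools::file_path_sans_ext(basename(paths))
  stopifnot(length(run_ids) == length(paths))
  out <- vector("list", length(paths))
  for (i in seq_along(paths)) {
    path <- paths[i]
    if (!file.exists(path)) stop("trace file not found: ", path, call. = FALSE)
    # base parser: reads decimal doubles correctly rounded, so written
    # traces round-trip bit-exactly
    df <- utils::read.csv(path, check.names = FALSE, comment.char = "#")
    if (!size_col %in% names(df)) {
      stop("size column '", size_col, "' not found in ", path,
           " (columns: ", paste(names(df), collapse = ", "), ")", call. = FALSE)
    }
    sizes <- df[[size_col]]
    if (!is.numeric(sizes) || anyNA(sizes)) {
      stop("non-numeric values in size column of ", path, call. = FALSE)
    }
    bad <- which(diff(sizes) <= 0)
    if (length(bad) > 0) {
      stop("size axis not strictly increasing in ", path,
           " at row ", bad[1] + 1, " (", sizes[bad[1]], " -> ", sizes[bad[1] + 1],
           ")", call. = FALSE)
    }
    if (any(sizes <= 0)) stop("nonpositive fragment size in ", path, call. = FALSE)
    sample_cols <- setdiff(names(df), size_col)
    if (length(sample_cols) == 0) stop("no sample columns in ", path, call. = FALSE)
    for (sc in sample_cols) {
      if (!is.numeric(df[[sc]]) || anyNA(df[[sc]])) {
        stop("non-numeric RFU values in column '", sc, "' of ", path, call. = FALSE)
      }
    }
    out[[i]] <- tidyr::pivot_longer(df, cols = dplyr::all_of(sample_cols),
                                    names_to = "sample_id", values_to = "rfu")
    out[[i]] <- tibble::tibble(
      sample_id = out[[i]]$sample_id,
      run_id = run_ids[i],
      size_bp = out[[i]][[size_col]],
      rfu = out[[i]]$rfu
    )
  }
  traces <- dplyr::bind_rows(out)
  dup <- traces |>
    dplyr::distinct(.data$sample_id, .data$run_id) |>
    dplyr::count(.data$sample_id) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    stop("sample IDs appear in more than one run: ",
         paste(dup$sample_id, collapse = ", "), call. = FALSE)
  }
  dplyr::arrange(traces, .data$run_id, .data$sample_id, .data$size_bp)
}

#' Write electropherogram traces as per-run CSV files
#'
#' Inverse of [read_traces()]: one wide CSV per run, full precision.
#'
#' @param traces Long trace tibble (`sample_id`, `run_id`, `size_bp`, `rfu`).
#' @param dir Output directory (created if needed).
#' @param size_col Size-axis column name.
#' @return Invisibly, the paths written (named by run).
#' @export
write_traces <- function(traces, dir, size_col = "Size (bp)") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  runs <- unique(traces$run_id)
  paths <- character(length(runs))
  for (i in seq_along(runs)) {
    tr <- dplyr::filter(traces, .data$run_id == runs[i])
    wide <- tidyr::pivot_wider(tr[, c("sample_id", "size_bp", "rfu")],
                               names_from = "sample_id", values_from = "rfu")
    names(wide)[names(wide) == "size_bp"] <- size_col
    # 17 significant digits: lossless for IEEE doubles
    wide[] <- lapply(wide, function(x) sprintf("%.17g", x))
    paths[i] <- file.path(dir, paste0(runs[i], ".csv"))
    readr::write_csv(wide, paths[i])
  }
  invisible(stats::setNames(paths, runs))
}

design_levels <- list(
  solution = c("DESS", "ETOH"),
  heat = c("treated", "untreated"),
  temperature = c("cold", "room")
)

#' Read and validate a sample-design metadata table
#'
#' The design maps sample IDs to the factors of the preservation
#' experiment: fish, solution (DESS/ETOH), heat treatment, storage
#' temperature, storage time in days, and instrument run.
#'
#' @param path CSV path with columns `sample_id`, `fish`, `solution`,
#'   `heat`, `temperature`, `time_days`, `run_id`.
#' @return Validated design tibble with a `"balance"` attribute, see
#'   [design_balance()].
#' @export
read_design <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, comment = "#")
  validate_design(df)
}

#' Validate a design tibble
#'
#' Checks required columns, factor level membership and sample ID
#' uniqueness; attaches the balance report (see [design_balance()]).
#'
#' @param design Design tibble.
#' @return The validated tibble (invisible errors are never silent: every
#'   rejection names the offending value).
#' @export
validate_design <- function(design) {
  required <- c("sample_id", "fish", "solution", "heat", "temperature",
                "time_days", "run_id")
  missing <- setdiff(required, names(design))
  if (length(missing) > 0) {
    stop("design is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  for (col in names(design_levels)) {
    bad <- setdiff(unique(as.character(design[[col]])), design_levels[[col]])
    if (length(bad) > 0) {
      stop("unknown ", col, " level '", bad[1], "'; allowed: {",
           paste(design_levels[[col]], collapse = ", "), "}", call. = FALSE)
    }
  }
  if (!is.numeric(design$time_days) || any(design$time_days <= 0) ||
      any(design$time_days != round(design$time_days))) {
    stop("time_days must be positive integers", call. = FALSE)
  }
  if (anyDuplicated(design$sample_id)) {
    stop("duplicate sample_id in design: ",
         design$sample_id[duplicated(design$sample_id)][1], call. = FALSE)
  }
  design <- tibble::as_tibble(design)
  attr(design, "balance") <- design_balance(design)
  design
}

#' Report whether a design is a complete balanced crossing
#'
#' A complete balanced design (every solution x heat x temperature x time
#' cell present with equal replication) is what justifies sequential sums
#' of squares being invariant to term order in the factorial ANOVA.
#'
#' @param design Design tibble.
#' @return List with `balanced` (logical), `n_cells`, `n_per_cell` (NA if
#'   unbalanced) and `cell_counts` (tibble).
#' @export
design_balance <- function(design) {
  counts <- dplyr::count(design, .data$solution, .data$heat, .data$temperature,
                         .data$time_days)
  n_expected <- 2L * 2L * 2L * dplyr::n_distinct(design$time_days)
  balanced <- nrow(counts) == n_expected && dplyr::n_distinct(counts$n) == 1L
  list(
    balanced = balanced,
    n_cells = nrow(counts),
    n_per_cell = if (balanced) counts$n[1] else NA_integer_,
    cell_counts = counts
  )
}

#' Write a design table to CSV
#'
#' @param design Design tibble.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_design <- function(design, path) {
  readr::write_csv(design, path)
  invisible(path)
}

#' Reconcile trace and design sample IDs
#'
#' @param traces Long trace tibble.
#' @param design Design tibble.
#' @return List with `matched`, `traces_only` and `design_only` sample IDs.
#' @export
reconcile_samples <- function(traces, design) {
  tr_ids <- unique(traces$sample_id)
  ds_ids <- unique(design$sample_id)
  list(
    matched = intersect(tr_ids, ds_ids),
    traces_only = setdiff(tr_ids, ds_ids),
    design_only = setdiff(ds_ids, tr_ids)
  )
}
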