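#' GQN-style fragmentation score
#'
#' A Genomic Quality Number style score in [0, 10]: 10 times the fraction
#' of integrated signal at or above a user-set size threshold, among
#' signal at or above `min_size`. 10 means all (counted) DNA mass sits
#' above the threshold; 0 means none does. The instrument vendors'
#' proprietary scores depend on a user-set threshold in the same way; the
#' threshold used here is recorded in the output.
#'
#' @param traces Long trace tibble (`sample_id`, `size_bp`, `rfu`).
#' @param threshold Size threshold in bp (default 10,000).
#' @param min_size Lower cutoff in bp (default 250; sub-250 bp signal is
#'   excluded as RNA-confounded).
#' @return Tibble `sample_id`, `gqn`, `threshold`, `min_size`. Samples
#'   with zero total signal get a missing score, with a warning.
#' @export
gqn_surrogate <- function(traces, threshold = 10000, min_size = 250) {
  stopifnot(threshold >= min_size)
  # a window with no observed sizes is a legitimate zero here, not a
  # reportable condition
  quiet_auc <- function(...) withCallingHandlers(
    trace_auc(...),
    epg_window_warning = function(w) invokeRestart("muffleWarning"))
  out <- traces |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(
      total = quiet_auc(.data$size_bp, .data$rfu, lo = min_size),
      above = quiet_auc(.data$size_bp, .data$rfu, lo = threshold),
      .groups = "drop"
    )
  zero <- out$total <= 0
  if (any(zero)) {
    warning(sum(zero), " sample(s) with zero total signal; score set to NA")
  }
  tibble::tibble(
    sample_id = out$sample_id,
    gqn = ifelse(zero, NA_real_, 10 * out$above / out$total),
    threshold = threshold,
    min_size = min_size
  )
}

anova_factor_data <- function(scores, design, response) {
  if (!response %in% names(scores)) {
    stop("response column '", response, "' not found in scores", call. = FALSE)
  }
  df <- dplyr::inner_join(scores[, c("sample_id", response)], design,
                          by = "sample_id")
  if (nrow(df) < nrow(scores)) {
    stop("scored samples without a design row: ",
         paste(utils::head(setdiff(scores$sample_id, design$sample_id), 5),
               collapse = ", "), call. = FALSE)
  }
  if (anyNA(df[[response]])) {
    stop("missing values in response '", response, "'", call. = FALSE)
  }
  tibble::tibble(
    sample_id = df$sample_id,
    y = df[[response]],
    solution = factor(df$solution, levels = c("DESS", "ETOH")),
    heat = factor(df$heat, levels = c("treated", "untreated")),
    temperature = factor(df$temperature, levels = c("cold", "room")),
    time = factor(df$time_days, levels = sort(unique(df$time_days)))
  )
}

full_term_labels <- function() {
  attr(stats::terms(~ solution * heat * temperature * time), "term.labels")
}

# Effect-coded (sum-to-zero) columns for one factor, expanded to rows.
effect_columns <- function(x) {
  C <- stats::contr.sum(nlevels(x))
  C[as.integer(x), , drop = FALSE]
}

# Effect-coded column block for one model term ("solution",
# "solution:time", ...): row-wise products of the factors' contrast
# columns, giving prod(levels - 1) columns. Coding a term this way is
# independent of where it sits in the term list, so sequential fits under
# any ordering use the same column space.
term_block <- function(data, label) {
  vars <- strsplit(label, ":")[[1]]
  unknown <- setdiff(vars, c("solution", "heat", "temperature", "time"))
  if (length(unknown) > 0) {
    stop("unknown model term variable '", unknown[1],
         "'; allowed: solution, heat, temperature, time", call. = FALSE)
  }
  mats <- lapply(data[vars], effect_columns)
  block <- mats[[1]]
  for (m in mats[-1]) {
    block <- do.call(cbind, lapply(seq_len(ncol(m)), function(j) block * m[, j]))
  }
  block
}

# Sequential (type-I) sums of squares by incremental least squares on
# effect-coded design matrices.
sequential_ss <- function(data, term_labels) {
  if (anyDuplicated(term_labels)) stop("duplicated model terms", call. = FALSE)
  blocks <- lapply(term_labels, term_block, data = data)
  X <- cbind(`(Intercept)` = 1, do.call(cbind, blocks))
  if (qr(X)$rank < ncol(X)) {
    stop("design matrix is rank deficient (missing cells with these ",
         "interaction terms); reduce the term list", call. = FALSE)
  }
  asgn <- c(0L, rep(seq_along(blocks), vapply(blocks, ncol, 1L)))
  y <- data$y
  n <- length(y)
  rss_prev <- sum((y - mean(y))^2)
  total_ss <- rss_prev
  k <- length(term_labels)
  ss <- df <- numeric(k)
  for (j in seq_len(k)) {
    cols <- asgn <= j
    fit <- stats::lm.fit(X[, cols, drop = FALSE], y)
    rss_j <- sum(fit$residuals^2)
    ss[j] <- rss_prev - rss_j
    df[j] <- sum(asgn == j)
    rss_prev <- rss_j
  }
  list(term = term_labels, df = df, ss = pmax(ss, 0),
       rss = rss_prev, df_resid = n - ncol(X), total_ss = total_ss, n = n)
}

#' Factorial ANOVA over the preservation design
#'
#' Fits, by least squares on effect-coded design matrices, the linear
#' model for a per-sample response over the storage factors and computes
#' sequential (type-I) sums of squares in the canonical order: main
#' effects solution, heat, temperature, time, then interactions of
#' ascending order. `F = MS_term / MS_residual`, with unadjusted p-values.
#' On a complete balanced design the sequential decomposition is invariant
#' to term order (equivalently, coincides with type-II/III); by default
#' this is verified by refitting with the term order reversed.
#'
#' @param scores Tibble with `sample_id` and the response column.
#' @param design Design tibble.
#' @param terms `"full"` (all 15 terms), `"solution"` (solution only), or
#'   a character vector of term labels over
#'   `solution`, `heat`, `temperature`, `time` (e.g. `"solution:time"`).
#' @param response Name of the response column in `scores` (default
#'   `"gqn"`).
#' @param verify_order_invariance Logical; on balanced designs, assert
#'   that reversing the term order leaves every SS unchanged.
#' @return Object of class `epg_anova`: a list with `table` (tibble:
#'   `term`, `df`, `sumsq`, `meansq`, `statistic`, `p_value`, `stars`),
#'   `residual` (df, sumsq), `total_ss`, `terms`, `response`, and the
#'   fitted response vector (used by [compare_models()]).
#' @export
factorial_anova <- function(scores, design, terms = "full", response = "gqn",
                            verify_order_invariance = TRUE) {
  term_labels <- if (identical(terms, "full")) {
    full_term_labels()
  } else if (identical(terms, "solution")) {
    "solution"
  } else {
    as.character(terms)
  }
  data <- anova_factor_data(scores, design, response)
  res <- sequential_ss(data, term_labels)

  balance <- design_balance(design[design$sample_id %in% data$sample_id, ])
  if (verify_order_invariance && balance$balanced && length(term_labels) > 1) {
    res_rev <- sequential_ss(data, rev(term_labels))
    ord <- match(res$term, res_rev$term)
    scale <- max(res$total_ss, .Machine$double.eps)
    if (max(abs(res$ss - res_rev$ss[ord])) > 1e-8 * scale) {
      stop("sequential SS not order-invariant on a balanced design; ",
           "this indicates a numerical problem", call. = FALSE)
    }
  }

  ms_resid <- if (res$df_resid > 0) res$rss / res$df_resid else NA_real_
  degenerate <- !is.finite(ms_resid) || ms_resid <= 1e-12 * max(res$total_ss, 1e-300)
  if (res$total_ss <= 0) degenerate <- TRUE
  statistic <- if (degenerate) rep(NA_real_, length(res$ss)) else
    (res$ss / res$df) / ms_resid
  p_value <- if (degenerate) rep(NA_real_, length(res$ss)) else
    stats::pf(statistic, res$df, res$df_resid, lower.tail = FALSE)

  table <- tibble::tibble(
    term = res$term,
    df = as.integer(res$df),
    sumsq = res$ss,
    meansq = res$ss / res$df,
    statistic = statistic,
    p_value = p_value,
    stars = significance_stars(p_value)
  )
  structure(
    list(table = table,
         residual = list(df = as.integer(res$df_resid), sumsq = res$rss),
         total_ss = res$total_ss,
         terms = term_labels,
         response = response,
         balanced = balance$balanced,
         sample_id = data$sample_id,
         y = data$y),
    class = "epg_anova"
  )
}

#' Significance stars at the conventional .05/.01/.001 levels
#'
#' @param p Numeric vector of p-values.
#' @return Character vector: `***` below .001, `**` below .01, `*` below
#'   .05, empty otherwise (NA-safe).
#' @export
significance_stars <- function(p) {
  out <- rep("", length(p))
  out[!is.na(p) & p < 0.05] <- "*"
  out[!is.na(p) & p < 0.01] <- "**"
  out[!is.na(p) & p < 0.001] <- "***"
  out
}

#' @export
print.epg_anova <- function(x, ...) {
  cat("Factorial ANOVA (sequential SS), response:", x$response, "\n")
  tab <- x$table
  df <- data.frame(
    term = tab$term, df = tab$df,
    sumsq = signif(tab$sumsq, 5),
    F = signif(tab$statistic, 4),
    p = signif(tab$p_value, 3),
    ` ` = tab$stars, check.names = FALSE
  )
  print(df, row.names = FALSE)
  cat("Residuals: df =", x$residual$df, ", SS =", signif(x$residual$sumsq, 5), "\n")
  cat("Signif. codes: *** p<.001, ** p<.01, * p<.05\n")
  invisible(x)
}

#' Partial F test between nested factorial models
#'
#' Compares a reduced model (its terms a subset of the full model's) with
#' the full model on the same response:
#' `F = ((RSS_reduced - RSS_full) / (df_reduced - df_full)) / MS_residual_full`.
#' Identical models give `F = 0`, `p = 1`.
#'
#' @param full,reduced `epg_anova` objects from [factorial_anova()] fitted
#'   to the same samples and response.
#' @return Tibble: `statistic`, `df_num`, `df_den`, `p_value`.
#' @export
compare_models <- function(full, reduced) {
  stopifnot(inherits(full, "epg_anova"), inherits(reduced, "epg_anova"))
  if (length(setdiff(reduced$terms, full$terms)) > 0) {
    stop("models are not nested: reduced terms must be a subset of the ",
         "full model's terms", call. = FALSE)
  }
  if (!identical(reduced$sample_id, full$sample_id) ||
      !isTRUE(all.equal(reduced$y, full$y))) {
    stop("models were not fitted to the same response vector", call. = FALSE)
  }
  df_num <- reduced$residual$df - full$residual$df
  if (df_num < 0) stop("reduced model has fewer residual df than the full model",
                       call. = FALSE)
  if (df_num == 0) {
    return(tibble::tibble(statistic = 0, df_num = 0L,
                          df_den = full$residual$df, p_value = 1))
  }
  ms_full <- full$residual$sumsq / full$residual$df
  statistic <- max((reduced$residual$sumsq - full$residual$sumsq) / df_num, 0) /
    ms_full
  tibble::tibble(
    statistic = statistic,
    df_num = as.integer(df_num),
    df_den = full$residual$df,
    p_value = stats::pf(statistic, df_num, full$residual$df, lower.tail = FALSE)
  )
}
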