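#' Default lognormal size components for simulated electropherograms
#'
#' Three components on the log-size axis: a low-molecular-weight (LMW)
#' component below 250 bp (residual RNA and very short fragments), a
#' degraded smear centred near 1 kbp, and a high-molecular-weight (HMW)
#' component centred near 40 kbp. `meanlog`/`sdlog` parameterize a
#' lognormal density over fragment size in bp.
#'
#' @return A tibble with columns `component`, `meanlog`, `sdlog`.
#' @export
default_components <- function() {
  tibble::tibble(
    component = c("lmw", "degraded", "hmw"),
    meanlog   = log(c(150, 1000, 40000)),
    sdlog     = c(0.30, 0.55, 0.30)
  )
}

#' Default log-spaced size grid
#'
#' @param min_bp,max_bp Grid range in bp.
#' @param n Number of grid points.
#' @return Strictly increasing numeric vector of sizes in bp.
#' @export
default_size_grid <- function(min_bp = 75, max_bp = 60000, n = 500) {
  exp(seq(log(min_bp), log(max_bp), length.out = n))
}

#' Configuration for the synthetic electropherogram experiment
#'
#' Describes a preservation experiment in which tissue samples from
#' `n_fish` individuals are stored in one of two solutions (DESS or
#' ethanol), with or without a brief heat treatment, at cold (~5 degC) or
#' room (~20 degC) temperature, and extracted after each of
#' `time_points_days`. Each sample's trace is a mixture of three lognormal
#' size components whose HMW weight decays exponentially at a
#' treatment-dependent rate; mass lost from the HMW component accrues to
#' the ~1 kbp degraded smear.
#'
#' The per-day decay rate for a sample is
#' `decay_base_rate * solution_multiplier^[ETOH] * temp_multiplier^[room] *
#' heat_multiplier^[untreated]`, so the reference cell (DESS, cold,
#' heat-treated) decays at exactly `decay_base_rate`.
#'
#' @param n_fish Number of individual fish (default 5).
#' @param replicates_per_cell Samples per factor cell; fish are assigned
#'   cyclically within a cell, so the default (`n_fish`) gives each fish
#'   exactly one sample per cell, the classical 200-sample design.
#' @param time_points_days Integer storage durations in days.
#' @param size_grid Strictly increasing sizes in bp; must start below
#'   250 bp and extend beyond 20 kbp.
#' @param component_params Tibble as from [default_components()].
#' @param initial_weights Named nonnegative weights (`lmw`, `degraded`,
#'   `hmw`) summing to 1 at time zero.
#' @param decay_base_rate Per-day HMW decay rate of the reference cell.
#' @param solution_multiplier,temp_multiplier,heat_multiplier Positive rate
#'   multipliers applied for ETOH, room temperature, and no heat treatment.
#' @param fish_effect_sd Log-scale SD of the per-fish amplitude effect.
#' @param noise_sd SD of additive Gaussian detector noise, RFU units
#'   (noise can drive signal below zero, as on real instruments).
#' @param size_jitter_frac SD of the per-run multiplicative size-axis
#'   perturbation (run-to-run calibration drift).
#' @param total_signal Expected integrated signal per trace, RFU x bp.
#' @param seed Integer seed; fixes the whole simulated dataset.
#' @return A list of class `epg_config`.
#' @export
simulation_config <- function(n_fish = 5,
                              replicates_per_cell = n_fish,
                              time_points_days = c(1, 7, 14, 30, 90),
                              size_grid = default_size_grid(),
                              component_params = default_components(),
                              initial_weights = c(lmw = 0.22, degraded = 0.60, hmw = 0.18),
                              decay_base_rate = 0.0075,
                              solution_multiplier = 250,
                              temp_multiplier = 2,
                              heat_multiplier = 1.5,
                              fish_effect_sd = 0.2,
                              noise_sd = 0.1,
                              size_jitter_frac = 0.01,
                              total_signal = 5e4,
                              seed = 1L) {
  cfg <- list(
    n_fish = as.integer(n_fish),
    replicates_per_cell = as.integer(replicates_per_cell),
    time_points_days = as.integer(sort(unique(time_points_days))),
    size_grid = as.numeric(size_grid),
    component_params = component_params,
    initial_weights = initial_weights[c("lmw", "degraded", "hmw")],
    decay_base_rate = decay_base_rate,
    solution_multiplier = solution_multiplier,
    temp_multiplier = temp_multiplier,
    heat_multiplier = heat_multiplier,
    fish_effect_sd = fish_effect_sd,
    noise_sd = noise_sd,
    size_jitter_frac = size_jitter_frac,
    total_signal = total_signal,
    seed = as.integer(seed)
  )
  validate_simulation_config(cfg)
  structure(cfg, class = "epg_config")
}

validate_simulation_config <- function(cfg) {
  w <- cfg$initial_weights
  if (anyNA(w) || !setequal(names(w), c("lmw", "degraded", "hmw"))) {
    stop("initial_weights must be named 'lmw', 'degraded', 'hmw'", call. = FALSE)
  }
  if (any(w < 0)) stop("initial_weights must be nonnegative", call. = FALSE)
  if (abs(sum(w) - 1) > 1e-9) {
    stop("initial_weights must sum to 1 (got ", format(sum(w), digits = 12), ")",
         call. = FALSE)
  }
  mult <- c(solution = cfg$solution_multiplier, temp = cfg$temp_multiplier,
            heat = cfg$heat_multiplier)
  if (any(mult <= 0)) stop("rate multipliers must be > 0", call. = FALSE)
  if (cfg$decay_base_rate < 0) stop("decay_base_rate must be >= 0", call. = FALSE)
  g <- cfg$size_grid
  if (length(g) < 2 || any(diff(g) <= 0)) {
    stop("size_grid must be strictly increasing", call. = FALSE)
  }
  if (min(g) >= 250 || max(g) <= 20000) {
    stop("size_grid must start below 250 bp and extend beyond 20,000 bp",
         call. = FALSE)
  }
  if (cfg$n_fish < 1 || cfg$replicates_per_cell < 1) {
    stop("n_fish and replicates_per_cell must be >= 1", call. = FALSE)
  }
  if (cfg$noise_sd < 0 || cfg$fish_effect_sd < 0 || cfg$size_jitter_frac < 0) {
    stop("noise_sd, fish_effect_sd and size_jitter_frac must be >= 0", call. = FALSE)
  }
  invisible(cfg)
}

#' Treatment-specific HMW decay rate
#'
#' @param config An [simulation_config()] object.
#' @param solution `"DESS"` or `"ETOH"`.
#' @param heat `"treated"` or `"untreated"`.
#' @param temperature `"cold"` or `"room"`.
#' @return Per-day decay rate (vectorized over the factor arguments).
#' @export
decay_rate <- function(config, solution, heat, temperature) {
  check_levels(solution, c("DESS", "ETOH"), "solution")
  check_levels(heat, c("treated", "untreated"), "heat")
  check_levels(temperature, c("cold", "room"), "temperature")
  config$decay_base_rate *
    ifelse(solution == "ETOH", config$solution_multiplier, 1) *
    ifelse(temperature == "room", config$temp_multiplier, 1) *
    ifelse(heat == "untreated", config$heat_multiplier, 1)
}

check_levels <- function(x, levels, field) {
  bad <- setdiff(unique(as.character(x)), levels)
  if (length(bad) > 0) {
    stop("unknown ", field, " level ", paste0("'", bad, "'", collapse = ", "),
         "; allowed: {", paste(levels, collapse = ", "), "}", call. = FALSE)
  }
  invisible(x)
}

#' Mixture component weights after t days of storage
#'
#' HMW weight decays as `w_hmw(0) * exp(-rate * t)`; the lost mass is
#' transferred to the degraded ~1 kbp component; the LMW weight is
#' constant. Weights always sum to 1.
#'
#' @param config An [simulation_config()] object.
#' @param rate Per-day decay rate (from [decay_rate()]).
#' @param time_days Days of storage.
#' @return Named numeric vector (`lmw`, `degraded`, `hmw`).
#' @export
weights_at_time <- function(config, rate, time_days) {
  w0 <- config$initial_weights
  hmw <- unname(w0["hmw"]) * exp(-rate * time_days)
  c(lmw = unname(w0["lmw"]),
    degraded = unname(w0["degraded"]) + unname(w0["hmw"]) - hmw,
    hmw = hmw)
}

# Analytic fraction of signal mass in [hmw_threshold, window_max] among
# mass in [min_size, window_max], from the lognormal component CDFs.
# This is exactly what a windowed AUC on the trace measures (up to
# quadrature error), and is the ground truth used by recovery tests.
true_hmw_fraction <- function(config, weights, window_min = 250,
                              window_max = max(config$size_grid),
                              hmw_threshold = 20000) {
  cp <- config$component_params
  w <- weights[cp$component]
  p_win <- stats::plnorm(window_max, cp$meanlog, cp$sdlog) -
    stats::plnorm(window_min, cp$meanlog, cp$sdlog)
  p_hmw <- stats::plnorm(window_max, cp$meanlog, cp$sdlog) -
    stats::plnorm(hmw_threshold, cp$meanlog, cp$sdlog)
  sum(w * pmax(p_hmw, 0)) / sum(w * pmax(p_win, 0))
}

#' Simulate one electropherogram trace
#'
#' Evaluates the lognormal mixture on the (optionally jittered) size grid,
#' scales it by the fish amplitude effect, and adds i.i.d. Gaussian
#' detector noise. Uses the current RNG state for the noise draw;
#' [simulate_experiment()] manages seeding for whole datasets.
#'
#' @param config An [simulation_config()] object.
#' @param design One-row design: named list/tibble row with `sample_id`,
#'   `fish`, `solution`, `heat`, `temperature`, `time_days`, `run_id`.
#' @param fish_effect Log-scale amplitude offset for this fish.
#' @param run_jitter Multiplicative size-axis factor for this run.
#' @return Tibble with columns `sample_id`, `run_id`, `size_bp`, `rfu`.
#' @export
simulate_trace <- function(config, design, fish_effect = 0, run_jitter = 1) {
  rate <- decay_rate(config, design$solution, design$heat, design$temperature)
  w <- weights_at_time(config, rate, design$time_days)
  sizes <- config$size_grid * run_jitter
  cp <- config$component_params
  dens <- rep(0, length(sizes))
  for (i in seq_len(nrow(cp))) {
    dens <- dens + w[[cp$component[i]]] *
      stats::dlnorm(sizes, cp$meanlog[i], cp$sdlog[i])
  }
  amp <- config$total_signal * exp(fish_effect)
  rfu <- amp * dens
  if (config$noise_sd > 0) {
    rfu <- rfu + stats::rnorm(length(sizes), 0, config$noise_sd)
  }
  tibble::tibble(
    sample_id = design$sample_id,
    run_id = design$run_id,
    size_bp = sizes,
    rfu = rfu
  )
}

#' Simulate a full preservation experiment
#'
#' Builds the complete crossing fish x solution x heat x temperature x
#' time (200 samples at the defaults), assigns one instrument run per
#' extraction time point (run-specific size-axis jitter makes cross-run
#' merging non-trivial, as with real multi-run datasets), and records
#' ground truth per sample.
#'
#' @param config An [simulation_config()] object.
#' @param runs Either `"per_time"` (default: one simulated run per
#'   extraction time point) or an integer number of runs over which time
#'   points are distributed round-robin.
#' @return A list of class `epg_simulation` with elements `traces` (long
#'   tibble: `sample_id`, `run_id`, `size_bp`, `rfu`), `design` (one row
#'   per sample), `truth` (per-sample decay rate, component weights,
#'   analytic HMW signal fraction), and `config`.
#' @export
simulate_experiment <- function(config, runs = "per_time") {
  validate_simulation_config(config)
  times <- config$time_points_days
  if (identical(runs, "per_time")) {
    run_of_time <- stats::setNames(paste0("run", sprintf("%02d", times)), times)
  } else {
    nr <- as.integer(runs)
    stopifnot(nr >= 1)
    run_of_time <- stats::setNames(
      paste0("run", sprintf("%02d", ((seq_along(times) - 1) %% nr) + 1)), times)
  }

  cells <- tidyr::expand_grid(
    solution = c("DESS", "ETOH"),
    heat = c("treated", "untreated"),
    temperature = c("cold", "room"),
    time_days = times
  )
  design <- tidyr::expand_grid(cells, replicate = seq_len(config$replicates_per_cell))
  design$fish <- paste0("fish", ((design$replicate - 1) %% config$n_fish) + 1)
  design$run_id <- unname(run_of_time[as.character(design$time_days)])
  design$sample_id <- sprintf(
    "S%03d_%s_%s_%s_%s_t%02d", seq_len(nrow(design)), design$fish,
    substr(design$solution, 1, 4), substr(design$heat, 1, 2),
    substr(design$temperature, 1, 4), design$time_days
  )
  design <- design[, c("sample_id", "fish", "solution", "heat", "temperature",
                       "time_days", "replicate", "run_id")]

  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(config$seed)

  fish_ids <- paste0("fish", seq_len(config$n_fish))
  fish_eff <- stats::setNames(stats::rnorm(config$n_fish, 0, config$fish_effect_sd),
                              fish_ids)
  run_ids <- unique(design$run_id)
  run_jit <- stats::setNames(
    exp(stats::rnorm(length(run_ids), 0, config$size_jitter_frac)), run_ids)

  rate <- decay_rate(config, design$solution, design$heat, design$temperature)
  w0 <- config$initial_weights
  w_hmw <- unname(w0["hmw"]) * exp(-rate * design$time_days)
  W <- cbind(lmw = rep(unname(w0["lmw"]), nrow(design)),
             degraded = unname(w0["degraded"]) + unname(w0["hmw"]) - w_hmw,
             hmw = w_hmw)
  amp <- config$total_signal * exp(fish_eff[design$fish])
  cp <- config$component_params

  # one density basis per run (samples in a run share the jittered axis)
  traces <- vector("list", length(run_ids))
  truth_frac <- numeric(nrow(design))
  for (r in seq_along(run_ids)) {
    idx <- which(design$run_id == run_ids[r])
    sizes <- config$size_grid * run_jit[[run_ids[r]]]
    basis <- vapply(seq_len(nrow(cp)),
                    function(i) stats::dlnorm(sizes, cp$meanlog[i], cp$sdlog[i]),
                    numeric(length(sizes)))  # ngrid x ncomp
    rfu <- basis %*% t(W[idx, cp$component, drop = FALSE])  # ngrid x nidx
    rfu <- sweep(rfu, 2, amp[idx], `*`)
    if (config$noise_sd > 0) {
      rfu <- rfu + matrix(stats::rnorm(length(rfu), 0, config$noise_sd),
                          nrow = nrow(rfu))
    }
    traces[[r]] <- tibble::tibble(
      sample_id = rep(design$sample_id[idx], each = length(sizes)),
      run_id = run_ids[r],
      size_bp = rep(sizes, times = length(idx)),
      rfu = as.vector(rfu)
    )
    wmax <- max(sizes)
    p_win <- stats::plnorm(wmax, cp$meanlog, cp$sdlog) -
      stats::plnorm(250, cp$meanlog, cp$sdlog)
    p_hmw <- stats::plnorm(wmax, cp$meanlog, cp$sdlog) -
      stats::plnorm(20000, cp$meanlog, cp$sdlog)
    Wr <- W[idx, cp$component, drop = FALSE]
    truth_frac[idx] <- as.vector(Wr %*% pmax(p_hmw, 0)) /
      as.vector(Wr %*% pmax(p_win, 0))
  }
  truth <- list(tibble::tibble(
    sample_id = design$sample_id,
    decay_rate = rate,
    w_lmw = W[, "lmw"], w_degraded = W[, "degraded"], w_hmw = W[, "hmw"],
    hmw_signal_fraction = truth_frac,
    fish_effect = unname(fish_eff[design$fish]),
    run_jitter = unname(run_jit[design$run_id])
  ))

  structure(
    list(traces = dplyr::bind_rows(traces),
         design = design,
         truth = dplyr::bind_rows(truth),
         config = config),
    class = "epg_simulation"
  )
}

#' @export
print.epg_simulation <- function(x, ...) {
  n <- nrow(x$design)
  cells <- dplyr::n_distinct(x$design[c("solution", "heat", "temperature", "time_days")])
  cat("Simulated electropherogram experiment\n")
  cat("  samples:", n, " factor cells:", cells,
      " runs:", dplyr::n_distinct(x$design$run_id), "\n")
  cat("  grid:", length(x$config$size_grid), "points,",
      round(min(x$config$size_grid)), "-", round(max(x$config$size_grid)), "bp\n")
  invisible(x)
}
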