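# Shared fixtures and independent oracles.

# Small-grid config: full 200-sample design on a 120-point size axis,
# keeping simulation-heavy tests fast without touching the science knobs.
small_config <- function(...) {
  simulation_config(size_grid = default_size_grid(n = 120), ...)
}

# Hand-built long trace tibble.
make_trace <- function(sample_id, size_bp, rfu, run_id = "runA") {
  tibble::tibble(sample_id = sample_id, run_id = run_id,
                 size_bp = size_bp, rfu = rfu)
}

# Independent AUC oracle: midpoint Riemann sum of the piecewise-linear
# integrand on a grid refined 100x relative to the observed points.
riemann_auc <- function(size_bp, rfu, lo = 250, hi = Inf, refine = 100) {
  lo <- max(lo, min(size_bp))
  hi <- min(hi, max(size_bp))
  xs <- seq(lo, hi, length.out = refine * length(size_bp))
  mids <- (xs[-1] + xs[-length(xs)]) / 2
  sum(stats::approx(size_bp, rfu, xout = mids)$y * diff(xs))
}

# Independent sequential-SS oracle for a balanced two-level factorial:
# squared projections of the response onto +/-1 contrast vectors.
projection_ss <- function(y, contrast) {
  sum(y * contrast)^2 / sum(contrast^2)
}

# Minimal valid design rows for hand-built datasets.
make_design <- function(sample_id, solution = "DESS", heat = "treated",
                        temperature = "cold", time_days = 1,
                        fish = "fish1", run_id = "runA") {
  tibble::tibble(sample_id = sample_id, fish = fish, solution = solution,
                 heat = heat, temperature = temperature,
                 time_days = time_days, run_id = run_id)
}
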