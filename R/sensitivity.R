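#' Deterministic incremental comparison of the two referral scenarios
#'
#' Runs the full deterministic pipeline for the reference (late, p = 1)
#' and comparator (timely, p = 0) scenarios and returns the incremental
#' result on the per-patient annual scale.
#'
#' @param cfg An `rrt_config`.
#' @param discount_rate Optional override of the configured rate.
#' @param reference,comparator [scenario_spec()]s.
#' @param renormalize Passed to the matrix assembly.
#' @return An [incremental()] result with the two annualized summaries
#'   attached as `$reference_summary` / `$comparator_summary`.
#' @export
deterministic_comparison <- function(cfg, discount_rate = NULL,
                                     reference = scenario_spec(1),
                                     comparator = scenario_spec(0),
                                     renormalize = FALSE) {
  ref <- run_scenario(cfg, reference, discount_rate = discount_rate,
                      renormalize = renormalize)
  cmp <- run_scenario(cfg, comparator, discount_rate = discount_rate,
                      renormalize = renormalize)
  inc <- incremental(ref, cmp, wtpt = cfg$model$wtpt)
  inc$reference_summary <- ref
  inc$comparator_summary <- cmp
  inc
}

#' One-way (tornado) sensitivity analysis
#'
#' Recomputes the incremental cost-effectiveness ratio with each scalar
#' parameter in turn moved down and up by `delta` (default 10%),
#' everything else held at base. Utilities are capped at 1; transition
#' rows whose perturbed exits exceed one are renormalized with stay
#' probability zero. Entries are sorted by the larger absolute percentage
#' ICER change.
#'
#' @param cfg An `rrt_config`.
#' @param delta Relative perturbation (0.10 for +/-10%).
#' @param discount_rate Optional override of the configured rate.
#' @param exclude Parameter ids to leave out (e.g. the scenario-defining
#'   transplant-exit probabilities).
#' @return A `tornado` data.frame: `parameter`, `base_value`, `icer_low`,
#'   `icer_high`, `pct_change_low`, `pct_change_high`,
#'   `max_abs_pct_change`, `infeasible`, with the base ICER as attribute
#'   `base_icer`.
#' @export
univariate_tornado <- function(cfg, delta = 0.10, discount_rate = NULL,
                               exclude = character()) {
  base <- deterministic_comparison(cfg, discount_rate = discount_rate)
  if (is.na(base$icer)) stop("base ICER undefined (zero delta QALY)",
                             call. = FALSE)
  registry <- parameter_registry(cfg)
  registry <- registry[setdiff(names(registry), exclude)]

  perturbed_icer <- function(path, family, value) {
    if (family %in% c("beta", "normal")) value <- min(1, value)
    work <- config_set(cfg, path, value)
    tryCatch(
      deterministic_comparison(work, discount_rate = discount_rate,
                               renormalize = TRUE)$icer,
      error = function(e) NA_real_)
  }

  rows <- lapply(registry, function(e) {
    v <- config_get(cfg, e$path)
    lo <- perturbed_icer(e$path, e$family, v * (1 - delta))
    hi <- perturbed_icer(e$path, e$family, v * (1 + delta))
    pct <- function(icer) if (is.na(icer)) NA_real_ else
      100 * (icer - base$icer) / abs(base$icer)
    data.frame(parameter = e$id, base_value = v,
               icer_low = lo, icer_high = hi,
               pct_change_low = pct(lo), pct_change_high = pct(hi),
               max_abs_pct_change = max(abs(c(pct(lo), pct(hi))), na.rm = TRUE),
               infeasible = is.na(lo) || is.na(hi))
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$max_abs_pct_change), ]
  rownames(out) <- NULL
  attr(out, "base_icer") <- base$icer
  class(out) <- c("tornado", "data.frame")
  out
}

#' ICER under alternative discount rates
#'
#' Reruns the full deterministic pipeline for both scenarios at each
#' requested annual discount rate (duplicates removed, order preserved).
#'
#' @param cfg An `rrt_config`.
#' @param rates Non-negative annual rates; default 0%, 3%, 5%.
#' @return Data frame with columns `discount_rate`, `delta_cost`,
#'   `delta_qaly`, `icer`.
#' @export
discount_rate_scenarios <- function(cfg, rates = c(0, 0.03, 0.05)) {
  if (any(rates < 0)) stop("rates must be >= 0", call. = FALSE)
  rates <- rates[!duplicated(rates)]
  rows <- lapply(rates, function(r) {
    inc <- deterministic_comparison(cfg, discount_rate = r)
    data.frame(discount_rate = r, delta_cost = inc$delta_cost,
               delta_qaly = inc$delta_qaly, icer = inc$icer)
  })
  do.call(rbind, rows)
}

#' ICER as a function of the late-referral proportion
#'
#' Sweeps the proportion `p` of transplant-failure patients referred late
#' and compares each mixed scenario against full timely referral (p = 0).
#' `p = 1` reproduces the baseline late-vs-timely comparison exactly.
#' Grid values of 0 are excluded with a warning (zero effectiveness
#' difference, ICER undefined).
#'
#' @param cfg An `rrt_config`.
#' @param p_grid Late-referral proportions in (0, 1\].
#' @param discount_rate Optional override of the configured rate.
#' @return Data frame with columns `late_fraction`, `delta_cost`,
#'   `delta_qaly`, `icer` (timely minus the mixed scenario).
#' @export
sweep_late_referral_proportion <- function(cfg, p_grid,
                                           discount_rate = NULL) {
  if (any(p_grid == 0)) {
    warning("p = 0 excluded from the sweep: the comparison against ",
            "timely referral is degenerate (ICER undefined)")
    p_grid <- p_grid[p_grid != 0]
  }
  if (!length(p_grid) || any(p_grid < 0) || any(p_grid > 1)) {
    stop("p_grid must contain values in (0, 1]", call. = FALSE)
  }
  rows <- lapply(p_grid, function(p) {
    inc <- deterministic_comparison(cfg, discount_rate = discount_rate,
                                    reference = scenario_spec(p),
                                    comparator = scenario_spec(0))
    data.frame(late_fraction = p, delta_cost = inc$delta_cost,
               delta_qaly = inc$delta_qaly, icer = inc$icer)
  })
  do.call(rbind, rows)
}
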