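#' Deterministic cohort simulation
#'
#' Propagates the expected state occupancy of a closed cohort through a
#' sequence of per-cycle transition matrices and records, for every cycle,
#' the entrant flow into each state (inflow from other states). The
#' initial cohort is counted as entrants at cycle 0.
#'
#' `markov_trace()` is the state-count engine for an arbitrary state space;
#' [run_cohort()] wraps it for the six-state renal replacement therapy
#' model configured in an `rrt_config`.
#'
#' @param matrices Either a 3-d array `(n, n, horizon)` or a list of
#'   `horizon` row-stochastic `n x n` matrices, one per cycle.
#' @param init Numeric vector of initial state counts (length `n`).
#' @param absorbing Optional character or integer vector of absorbing
#'   states checked for non-decreasing occupancy.
#' @return A `cohort_trace`: list with `occupancy` (`(horizon+1) x n`
#'   matrix, rows = cycle boundaries 0..horizon) and `entrants`
#'   (same shape; row `t` holds inflows during cycle `t`, row 0 the
#'   initial cohort).
#' @export
markov_trace <- function(matrices, init, absorbing = NULL) {
  if (is.array(matrices) && length(dim(matrices)) == 3) {
    matrices <- lapply(seq_len(dim(matrices)[3]), function(i) matrices[, , i])
  }
  horizon <- length(matrices)
  n <- length(init)
  if (any(init < 0)) stop("negative initial occupancy", call. = FALSE)
  states <- colnames(matrices[[1]]) %||% names(init) %||%
    paste0("S", seq_len(n))

  occupancy <- matrix(0, horizon + 1, n, dimnames = list(0:horizon, states))
  entrants <- matrix(0, horizon + 1, n, dimnames = list(0:horizon, states))
  occupancy[1, ] <- init
  entrants[1, ] <- init
  for (t in seq_len(horizon)) {
    M <- matrices[[t]]
    if (!all(dim(M) == c(n, n))) {
      stop("matrix for cycle ", t, " has wrong dimensions", call. = FALSE)
    }
    if (any(M < -1e-12) || any(abs(rowSums(M) - 1) > 1e-9)) {
      stop("matrix for cycle ", t, " is not row-stochastic", call. = FALSE)
    }
    prev <- occupancy[t, ]
    occupancy[t + 1, ] <- as.numeric(prev %*% M)
    inflow <- M
    diag(inflow) <- 0
    entrants[t + 1, ] <- as.numeric(prev %*% inflow)
  }
  trace <- structure(list(occupancy = occupancy, entrants = entrants,
                          cohort_size = sum(init)),
                     class = "cohort_trace")
  if (!is.null(absorbing)) {
    for (s in absorbing) {
      if (any(diff(occupancy[, s]) < -1e-9)) {
        stop("absorbing state ", s, " lost occupancy", call. = FALSE)
      }
    }
  }
  trace
}

#' @rdname markov_trace
#' @param cfg An `rrt_config`.
#' @param scenario A [scenario_spec()] (or a bare late fraction).
#' @param base Optional transitions section overriding `cfg$transitions`.
#' @param mortality Optional [mortality_schedule()] override.
#' @param renormalize Passed to [assemble_matrix()].
#' @export
run_cohort <- function(cfg, scenario, base = NULL, mortality = NULL,
                       renormalize = FALSE) {
  if (!inherits(scenario, "scenario_spec")) scenario <- scenario_spec(scenario)
  work <- cfg
  if (!is.null(base)) work$transitions <- base
  arr <- transition_array(work, scenario, mortality = mortality,
                          renormalize = renormalize)
  init <- cfg$model$cohort_size * state_vector(cfg$model$initial_occupancy)
  trace <- markov_trace(arr, init, absorbing = "D")
  trace$scenario <- scenario$name
  trace$start_age <- cfg$model$start_age
  trace
}

#' @export
print.cohort_trace <- function(x, ...) {
  h <- nrow(x$occupancy) - 1
  cat("<cohort_trace>", if (!is.null(x$scenario)) paste0(" scenario: ", x$scenario), "\n")
  cat(sprintf("  %d cycles, cohort %.6g; alive at horizon: %.2f\n", h,
              x$cohort_size, sum(x$occupancy[h + 1, colnames(x$occupancy) != "D"])))
  invisible(x)
}

#' @rdname markov_trace
#' @param trace A `cohort_trace`.
#' @param path Output CSV path: one row per cycle boundary, one column per
#'   state, plus the entrant flows.
#' @export
write_trace <- function(trace, path) {
  df <- data.frame(cycle = as.integer(rownames(trace$occupancy)),
                   trace$occupancy,
                   entrants = I(trace$entrants), check.names = FALSE)
  out <- cbind(df["cycle"], as.data.frame(trace$occupancy),
               stats::setNames(as.data.frame(trace$entrants),
                               paste0("entrants_", colnames(trace$entrants))))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Accumulate half-cycle-corrected costs and QALYs over a trace
#'
#' Recurring (prevalence) costs and utility-weighted survival are accrued
#' with the trapezoidal half-cycle correction — cycle `t` uses the mean of
#' the occupancy at its two boundaries — while one-off first-year
#' (transition) costs attach in full to the entrants of the cycle.
#' Accruals of cycle `t` are discounted by `(1 + r)^-t` (end-of-cycle
#' convention, annual compounding); entrant costs of the initial cohort at
#' cycle 0 are undiscounted. A zero rate reduces to plain sums.
#'
#' @param trace A [markov_trace()] / [run_cohort()] result.
#' @param first_year Named euro vector of one-off entry costs per state.
#' @param prevalence Named euro vector of annual recurring costs per state.
#' @param utilities Named QALY weight vector per state (death 0).
#' @param discount_rate Annual discount rate, >= 0.
#' @param alive Character vector of non-death states (for life-years).
#' @return An `outcome_summary`: totals (discounted and undiscounted) for
#'   cost, QALY and life-years.
#' @export
accumulate_outcomes <- function(trace, first_year, prevalence, utilities,
                                discount_rate,
                                alive = setdiff(colnames(trace$occupancy), "D")) {
  stopifnot(inherits(trace, "cohort_trace"))
  if (discount_rate < 0) stop("discount_rate must be >= 0", call. = FALSE)
  occ <- trace$occupancy
  ent <- trace$entrants
  if (any(occ < -1e-9)) stop("negative occupancy in trace", call. = FALSE)
  states <- colnames(occ)
  horizon <- nrow(occ) - 1L
  fy <- unlist(first_year)[states]
  pv <- unlist(prevalence)[states]
  u <- unlist(utilities)[states]
  if (anyNA(fy) || anyNA(pv) || anyNA(u)) {
    stop("first_year, prevalence and utilities must cover every state",
         call. = FALSE)
  }
  disc <- discount_factors(discount_rate, horizon)

  mid <- (occ[-(horizon + 1L), , drop = FALSE] +
            occ[-1L, , drop = FALSE]) / 2          # horizon x n, cycles 1..H
  per_cycle_prev_cost <- as.numeric(mid %*% pv)
  per_cycle_qaly <- as.numeric(mid %*% u)
  per_cycle_ly <- rowSums(mid[, alive, drop = FALSE])
  per_cycle_entry_cost <- as.numeric(ent %*% fy)   # index 1 = cycle 0

  cost_cycles <- per_cycle_prev_cost + per_cycle_entry_cost[-1L]
  total <- function(x, d) sum(x * d)
  summary <- structure(list(
    cost = total(cost_cycles, disc[-1L]) + per_cycle_entry_cost[1L],
    cost_undiscounted = sum(cost_cycles) + per_cycle_entry_cost[1L],
    qaly = total(per_cycle_qaly, disc[-1L]),
    qaly_undiscounted = sum(per_cycle_qaly),
    life_years = total(per_cycle_ly, disc[-1L]),
    life_years_undiscounted = sum(per_cycle_ly),
    discount_rate = discount_rate,
    cohort_size = trace$cohort_size,
    horizon = horizon,
    scenario = trace$scenario
  ), class = "outcome_summary")
  summary
}

#' Per-patient annual outcome figures
#'
#' Totals divided by cohort size times horizon, the annualization used for
#' the headline per-patient annual cost and QALY figures.
#'
#' @param summary An [accumulate_outcomes()] result.
#' @param cohort_size,horizon Denominator terms; default from the summary.
#' @return The summary with `per_patient_annual_cost`,
#'   `per_patient_annual_qaly` (discounted, at the summary's rate) and
#'   their undiscounted twins added.
#' @export
annualize <- function(summary, cohort_size = summary$cohort_size,
                      horizon = summary$horizon) {
  stopifnot(inherits(summary, "outcome_summary"))
  if (is.null(horizon) || horizon == 0) stop("horizon must be nonzero",
                                             call. = FALSE)
  denom <- cohort_size * horizon
  summary$per_patient_annual_cost <- summary$cost / denom
  summary$per_patient_annual_qaly <- summary$qaly / denom
  summary$per_patient_annual_cost_undiscounted <-
    summary$cost_undiscounted / denom
  summary$per_patient_annual_qaly_undiscounted <-
    summary$qaly_undiscounted / denom
  summary
}

#' @export
print.outcome_summary <- function(x, ...) {
  cat("<outcome_summary>",
      if (!is.null(x$scenario)) paste0(" scenario: ", x$scenario), "\n")
  cat(sprintf("  discount rate: %.1f%%\n", 100 * x$discount_rate))
  cat(sprintf("  total cost: %.0f euro (undiscounted %.0f)\n",
              x$cost, x$cost_undiscounted))
  cat(sprintf("  total QALY: %.1f (undiscounted %.1f); life-years %.1f\n",
              x$qaly, x$qaly_undiscounted, x$life_years_undiscounted))
  if (!is.null(x$per_patient_annual_cost)) {
    cat(sprintf("  per patient-year: %.0f euro, %.4f QALY\n",
                x$per_patient_annual_cost, x$per_patient_annual_qaly))
  }
  invisible(x)
}

#' Run one scenario end to end
#'
#' Convenience wrapper: cohort trace, outcome accumulation at the
#' configured (or overridden) discount rate, annualization, and the
#' optional productivity-loss extension.
#'
#' @param cfg An `rrt_config`.
#' @param scenario A [scenario_spec()] or bare late fraction.
#' @param discount_rate Optional override of the configured rate.
#' @param base,mortality,renormalize Passed to [run_cohort()].
#' @return An annualized `outcome_summary`, with `productivity_loss`
#'   attached when the societal extension is enabled in the config.
#' @export
run_scenario <- function(cfg, scenario, discount_rate = NULL,
                         base = NULL, mortality = NULL, renormalize = FALSE) {
  rate <- discount_rate %||% cfg$model$discount_rate
  trace <- run_cohort(cfg, scenario, base = base, mortality = mortality,
                      renormalize = renormalize)
  out <- accumulate_outcomes(trace, first_year_costs(cfg),
                             prevalence_costs(cfg), utility_weights(cfg),
                             discount_rate = rate)
  out <- annualize(out, cfg$model$cohort_size, cfg$model$horizon)
  if (isTRUE(cfg$productivity$enabled)) {
    out$productivity_loss <- productivity_loss(trace, cfg,
                                               discount_rate = rate)
  }
  out$trace <- trace
  out
}
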