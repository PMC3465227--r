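#' Referral scenarios
#'
#' A scenario is defined by the proportion `p` of transplant-failure
#' patients who restart dialysis late (unplanned, at low kidney function).
#' `p = 1` is the current-practice scenario in which every graft-failure
#' patient is referred late; `p = 0` is the ideal scenario in which every
#' patient is referred in a timely, planned manner.
#'
#' @param late_fraction Proportion of late-referred transplant-failure
#'   patients, in \[0, 1\].
#' @param name Optional label; defaults to "late" at `p = 1`, "timely" at
#'   `p = 0`, and `"p=<value>"` otherwise.
#' @return A `scenario_spec` list with elements `name` and `late_fraction`.
#' @export
#' @examples
#' scenario_spec(0)   # timely referral
#' scenario_spec(1)   # late referral (current practice)
scenario_spec <- function(late_fraction, name = NULL) {
  if (!is.numeric(late_fraction) || length(late_fraction) != 1 ||
      is.na(late_fraction) || late_fraction < 0 || late_fraction > 1) {
    stop("late_fraction must be a single number in [0, 1]", call. = FALSE)
  }
  if (is.null(name)) {
    name <- if (late_fraction == 1) "late" else if (late_fraction == 0) {
      "timely"
    } else sprintf("p=%g", late_fraction)
  }
  structure(list(name = name, late_fraction = late_fraction),
            class = "scenario_spec")
}

#' Transplant-exit transition probabilities under a referral scenario
#'
#' The annual probability of returning from a functioning transplant to
#' dialysis is fixed (0.0350 to hemodialysis, 0.0035 to peritoneal
#' dialysis); the scenario only routes that exit mass between the timely
#' states (HD, PD) and the late-referral states (LRHD, LRPD):
#' Tx->HD = (1-p) q_HD, Tx->PD = (1-p) q_PD, Tx->LRHD = p q_HD,
#' Tx->LRPD = p q_PD. Total exit mass is therefore invariant in p.
#'
#' @param base Transitions section of an `rrt_config` (or any list with
#'   `tx_exit_to_hd`, `tx_exit_to_pd`).
#' @param scenario A [scenario_spec()].
#' @return Named vector with elements `HD`, `PD`, `LRHD`, `LRPD`.
#' @export
#' @examples
#' tr <- list(tx_exit_to_hd = 0.0350, tx_exit_to_pd = 0.0035)
#' build_tx_row(tr, scenario_spec(0))
#' build_tx_row(tr, scenario_spec(0.5))
build_tx_row <- function(base, scenario) {
  if (!inherits(scenario, "scenario_spec")) scenario <- scenario_spec(scenario)
  p <- scenario$late_fraction
  check_prob(base$tx_exit_to_hd, "tx_exit_to_hd")
  check_prob(base$tx_exit_to_pd, "tx_exit_to_pd")
  c(HD = (1 - p) * base$tx_exit_to_hd,
    PD = (1 - p) * base$tx_exit_to_pd,
    LRHD = p * base$tx_exit_to_hd,
    LRPD = p * base$tx_exit_to_pd)
}

#' Assemble the one-cycle transition matrix at a given age
#'
#' Builds the 6x6 row-stochastic matrix over (HD, PD, Tx, LRHD, LRPD, D)
#' for one annual cycle. Death probabilities come from the age-dependent
#' mortality schedule (`q_std` for HD/PD/Tx, `q_lr` for the late-referral
#' states); each alive state's stay probability is the residual after its
#' exits and death. With the tunnel parameterization (`lr_tunnel = TRUE`,
#' the default) late-referral states last one cycle: survivors move to the
#' corresponding maintenance dialysis state.
#'
#' @param base Transitions section of an `rrt_config`.
#' @param scenario A [scenario_spec()].
#' @param mortality A [mortality_schedule()].
#' @param age Age (years) at the start of the cycle.
#' @param renormalize If `TRUE`, a row whose off-diagonal mass exceeds 1 is
#'   rescaled to sum to 1 with stay probability 0 (used when sampling
#'   perturbed parameters); if `FALSE` (default) such a row is an error.
#' @return 6x6 numeric matrix with dimnames over the states; rows sum to 1.
#' @export
assemble_matrix <- function(base, scenario, mortality, age,
                            renormalize = FALSE) {
  states <- rrt_states()
  q_std <- mortality$q_std(age)
  q_lr <- mortality$q_lr(age)
  tx <- build_tx_row(base, scenario)

  M <- matrix(0, 6, 6, dimnames = list(states, states))
  M["HD", c("PD", "Tx", "D")] <- c(base$hd_pd, base$hd_tx, q_std)
  M["PD", c("HD", "Tx", "D")] <- c(base$pd_hd, base$pd_tx, q_std)
  M["Tx", c("HD", "PD", "LRHD", "LRPD", "D")] <- c(tx, q_std)
  if (isTRUE(base$lr_tunnel)) {
    M["LRHD", c("HD", "D")] <- c(1 - q_lr, q_lr)
    M["LRPD", c("PD", "D")] <- c(1 - q_lr, q_lr)
  } else {
    M["LRHD", "D"] <- q_lr
    M["LRPD", "D"] <- q_lr
  }
  M["D", "D"] <- 1

  for (s in rrt_alive_states()) {
    off <- sum(M[s, ]) - M[s, s]
    if (off > 1 + 1e-12) {
      if (renormalize) {
        M[s, ] <- M[s, ] / off
        M[s, s] <- 0
      } else {
        stop(sprintf(
          "infeasible transition row '%s' at age %g: exits + death = %.6f > 1",
          s, age, off), call. = FALSE)
      }
    } else {
      M[s, s] <- max(0, 1 - off)
    }
  }
  M
}

# one matrix per cycle, ages start_age .. start_age + horizon - 1
transition_array <- function(cfg, scenario, mortality = NULL,
                             renormalize = FALSE) {
  mortality <- mortality %||% mortality_schedule(cfg)
  ages <- cfg$model$start_age + seq_len(cfg$model$horizon) - 1
  arr <- array(0, dim = c(6, 6, length(ages)),
               dimnames = list(rrt_states(), rrt_states(), NULL))
  for (i in seq_along(ages)) {
    arr[, , i] <- assemble_matrix(cfg$transitions, scenario, mortality,
                                  ages[i], renormalize = renormalize)
  }
  arr
}
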