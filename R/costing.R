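#' Late-referral first-year cost from a component breakdown
#'
#' Late (unplanned) dialysis restart is costed by uplifting the relevant
#' components of the timely first-year cost: hospitalization days due to
#' access complications +97%, recombinant human erythropoietin +69%,
#' intravenous iron +47%; the remaining components (access or surgery,
#' other) are carried unchanged, and a configurable surcharge captures the
#' extra cost of a non-scheduled start.
#'
#' @param components Named euro vector with elements `hospitalization_days`,
#'   `rHuEPO`, `iv_iron`, `access_or_surgery`, `other` (see
#'   [generate_cost_components()]).
#' @param uplifts List with fractions `hospitalization`, `rhuepo`,
#'   `iv_iron` (defaults 0.97, 0.69, 0.47).
#' @param surcharge Non-scheduled start surcharge in euro (default 0).
#' @return The late-referral first-year total in euro (never below the
#'   base total for non-negative uplifts and surcharge).
#' @export
#' @examples
#' comp <- c(hospitalization_days = 100, rHuEPO = 0, iv_iron = 0,
#'           access_or_surgery = 0, other = 0)
#' apply_late_referral_uplifts(comp)  # 197
apply_late_referral_uplifts <- function(components,
                                        uplifts = list(hospitalization = 0.97,
                                                       rhuepo = 0.69,
                                                       iv_iron = 0.47),
                                        surcharge = 0) {
  comp <- unlist(components)
  needed <- c("hospitalization_days", "rHuEPO", "iv_iron",
              "access_or_surgery", "other")
  missing <- setdiff(needed, names(comp))
  if (length(missing)) {
    stop("missing cost component(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (any(comp < 0)) stop("negative cost component", call. = FALSE)
  if (any(unlist(uplifts) < 0) || surcharge < 0) {
    stop("uplifts and surcharge must be >= 0", call. = FALSE)
  }
  comp[["hospitalization_days"]] * (1 + uplifts$hospitalization) +
    comp[["rHuEPO"]] * (1 + uplifts$rhuepo) +
    comp[["iv_iron"]] * (1 + uplifts$iv_iron) +
    comp[["access_or_surgery"]] + comp[["other"]] + surcharge
}

#' Costing report for the late-referral calibration
#'
#' @param cfg An `rrt_config`.
#' @param path Optional path; when given the report is written as JSON.
#' @return A list (per timely state HD, PD) with the base components, the
#'   applied uplifts, the surcharge and the resulting late-referral total.
#' @export
costing_report <- function(cfg, path = NULL) {
  up <- uplift_spec(cfg)
  rep <- lapply(stats::setNames(c("HD", "PD"), c("HD", "PD")), function(s) {
    comp <- cost_components(cfg, s)
    sur <- cfg$uplifts$nonscheduled_surcharge[[s]]
    list(base_components = as.list(comp),
         base_total = sum(comp),
         uplifts = up,
         nonscheduled_surcharge = sur,
         late_referral_total = apply_late_referral_uplifts(comp, up, sur))
  })
  if (!is.null(path)) {
    jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  rep
}

#' Productivity loss from premature mortality (societal perspective)
#'
#' An exploratory extension: each death before the working-age limit
#' (default 67 years) costs the configured annual productivity loss
#' (default 29,345 euro) for every year between the death cycle and the
#' cycle at which the limit would have been reached, discounted with the
#' same end-of-cycle convention as the medical costs. Deaths at or beyond
#' the limit contribute nothing. When enabled, the loss enters the
#' incremental comparison as an offset (the scenario with fewer premature
#' deaths is credited).
#'
#' @param trace A [run_cohort()] trace.
#' @param cfg An `rrt_config`.
#' @param loss_per_death_year Euro per death and year
#'   (default from the config).
#' @param working_age_limit Retirement age in years (default from the
#'   config).
#' @param discount_rate Annual discount rate (default from the config).
#' @return Total discounted productivity loss in euro.
#' @export
productivity_loss <- function(trace, cfg,
                              loss_per_death_year =
                                cfg$productivity$loss_per_death_year,
                              working_age_limit =
                                cfg$productivity$working_age_limit,
                              discount_rate = cfg$model$discount_rate) {
  stopifnot(inherits(trace, "cohort_trace"))
  if (loss_per_death_year < 0) stop("loss_per_death_year must be >= 0")
  horizon <- nrow(trace$occupancy) - 1L
  deaths <- unname(trace$entrants[-1, "D"])  # incident deaths, cycles 1..horizon
  total <- 0
  for (t in seq_len(horizon)) {
    death_age <- cfg$model$start_age + t - 1L  # age during the death cycle
    years_lost <- working_age_limit - death_age
    if (years_lost <= 0) next
    disc <- (1 + discount_rate)^-(t + seq_len(years_lost) - 1L)
    total <- total + deaths[t] * loss_per_death_year * sum(disc)
  }
  total
}
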