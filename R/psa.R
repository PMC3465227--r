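#' Moment-matched sampling distributions
#'
#' Parameter uncertainty is propagated with distributions chosen by
#' parameter type — beta for transition probabilities, normal for
#' utilities, log-normal for costs, uniform for the discount rate — each
#' parameterized by moment matching so its analytic mean and standard
#' deviation equal the requested values:
#' beta `nu = m(1-m)/s^2 - 1`, `alpha = m nu`, `beta = (1-m) nu`;
#' log-normal `sigma^2 = log(1 + s^2/m^2)`, `mu = log(m) - sigma^2/2`;
#' uniform bounds `m +/- s sqrt(3)`; normal direct.
#'
#' @param family One of `"beta"`, `"normal"`, `"lognormal"`, `"uniform"`.
#' @param mean,sd Target moments on the parameter scale (`sd > 0`).
#' @return A `distribution_spec` with the family, target moments and the
#'   family's natural parameters.
#' @export
#' @examples
#' make_distribution("beta", 0.5, 0.05)       # alpha = beta = 49.5
#' make_distribution("uniform", 0.03, 0.003)  # bounds 0.03 +/- 0.003*sqrt(3)
make_distribution <- function(family = c("beta", "normal", "lognormal",
                                         "uniform"),
                              mean, sd) {
  family <- match.arg(family)
  if (!is.finite(mean) || !is.finite(sd) || sd <= 0) {
    stop("mean must be finite and sd > 0", call. = FALSE)
  }
  natural <- switch(
    family,
    beta = {
      if (mean <= 0 || mean >= 1) stop("beta requires mean in (0, 1)",
                                       call. = FALSE)
      if (sd^2 >= mean * (1 - mean)) {
        stop("infeasible beta moments: sd^2 >= mean*(1-mean)", call. = FALSE)
      }
      nu <- mean * (1 - mean) / sd^2 - 1
      list(alpha = mean * nu, beta = (1 - mean) * nu)
    },
    normal = list(mean = mean, sd = sd),
    lognormal = {
      if (mean <= 0) stop("lognormal requires mean > 0", call. = FALSE)
      sigma2 <- log(1 + sd^2 / mean^2)
      list(meanlog = log(mean) - sigma2 / 2, sdlog = sqrt(sigma2))
    },
    uniform = list(min = mean - sd * sqrt(3), max = mean + sd * sqrt(3))
  )
  structure(list(family = family, mean = mean, sd = sd,
                 natural_params = natural),
            class = "distribution_spec")
}

#' @rdname make_distribution
#' @param spec A `distribution_spec`.
#' @param n Number of draws.
#' @return `draw_distribution()`: numeric vector of `n` draws (uses the
#'   current RNG state).
#' @export
draw_distribution <- function(spec, n = 1) {
  p <- spec$natural_params
  switch(spec$family,
         beta = stats::rbeta(n, p$alpha, p$beta),
         normal = stats::rnorm(n, p$mean, p$sd),
         lognormal = stats::rlnorm(n, p$meanlog, p$sdlog),
         uniform = stats::runif(n, p$min, p$max))
}

#' @rdname make_distribution
#' @return `distribution_moments()`: named vector with the analytic mean
#'   and sd implied by the natural parameters (a moment-matching check).
#' @export
distribution_moments <- function(spec) {
  p <- spec$natural_params
  switch(spec$family,
         beta = {
           m <- p$alpha / (p$alpha + p$beta)
           v <- p$alpha * p$beta /
             ((p$alpha + p$beta)^2 * (p$alpha + p$beta + 1))
           c(mean = m, sd = sqrt(v))
         },
         normal = c(mean = p$mean, sd = p$sd),
         lognormal = {
           m <- exp(p$meanlog + p$sdlog^2 / 2)
           c(mean = m, sd = m * sqrt(exp(p$sdlog^2) - 1))
         },
         uniform = c(mean = (p$min + p$max) / 2,
                     sd = (p$max - p$min) / sqrt(12)))
}

# registry of the scalar parameters subject to sampling and one-way
# perturbation; structural constants (cohort size, start age, horizon,
# WTPT, uplift percentages) are never entered here
parameter_registry <- function(cfg) {
  entries <- list()
  add <- function(id, family, path) {
    entries[[length(entries) + 1]] <<- list(id = id, family = family,
                                            path = path)
  }
  add("trans_hd_pd", "beta", c("transitions", "hd_pd"))
  add("trans_hd_tx", "beta", c("transitions", "hd_tx"))
  add("trans_pd_hd", "beta", c("transitions", "pd_hd"))
  add("trans_pd_tx", "beta", c("transitions", "pd_tx"))
  add("trans_tx_exit_to_hd", "beta", c("transitions", "tx_exit_to_hd"))
  add("trans_tx_exit_to_pd", "beta", c("transitions", "tx_exit_to_pd"))
  add("mort_q0", "beta", c("mortality", "q0"))
  add("mort_lr_first_year_survival", "beta",
      c("mortality", "lr_first_year_survival"))
  for (s in rrt_alive_states()) {
    add(paste0("cost_first_year_", s), "lognormal",
        c("costs", "first_year", s))
  }
  for (s in rrt_alive_states()) {
    add(paste0("cost_prevalence_", s), "lognormal",
        c("costs", "prevalence", s))
  }
  for (s in rrt_alive_states()) {
    add(paste0("utility_", s), "normal", c("utilities", s))
  }
  add("discount_rate", "uniform", c("model", "discount_rate"))
  if (cfg$transitions$tx_exit_to_hd == 0) {
    entries <- Filter(function(e) e$id != "trans_tx_exit_to_hd", entries)
  }
  if (cfg$transitions$tx_exit_to_pd == 0) {
    entries <- Filter(function(e) e$id != "trans_tx_exit_to_pd", entries)
  }
  names(entries) <- vapply(entries, `[[`, "", "id")
  entries
}

config_get <- function(cfg, path) {
  out <- cfg
  for (k in path) out <- out[[k]]
  out
}

config_set <- function(cfg, path, value) {
  cfg[[path]] <- value
  cfg
}

#' Draw one joint parameter set for the probabilistic analysis
#'
#' Every registered scalar parameter (transition probabilities, mortality
#' anchors, per-state first-year and prevalence costs, utilities, discount
#' rate) is drawn independently from its moment-matched distribution with
#' standard deviation `relative_sd` times the configured mean. Utilities
#' are clamped to \[0, 1\]. Uses the current RNG state; seed externally
#' for reproducibility. When `cfg$psa$pair_lr_costs` is `TRUE`, the
#' late-referral prevalence costs reuse the HD/PD draws instead of being
#' sampled separately.
#'
#' @param cfg An `rrt_config`.
#' @param relative_sd Standard deviation as a fraction of each mean
#'   (default from the config, 0.10).
#' @return A list: `config` (the perturbed configuration) and `draws`
#'   (named numeric vector of the sampled values).
#' @export
sample_parameter_set <- function(cfg, relative_sd = cfg$psa$relative_sd) {
  registry <- parameter_registry(cfg)
  draws <- numeric(length(registry))
  names(draws) <- names(registry)
  out <- cfg
  pair_lr <- isTRUE(cfg$psa$pair_lr_costs)
  for (e in registry) {
    mean_val <- config_get(cfg, e$path)
    if (pair_lr && e$id %in% c("cost_prevalence_LRHD", "cost_prevalence_LRPD")) {
      src <- if (e$id == "cost_prevalence_LRHD") "cost_prevalence_HD" else
        "cost_prevalence_PD"
      val <- draws[[src]]
    } else if (mean_val == 0) {
      val <- 0  # zero-mean parameters stay at zero (no dispersion rule)
    } else {
      spec <- make_distribution(e$family, mean_val, relative_sd * mean_val)
      val <- draw_distribution(spec, 1)
      if (e$family == "normal") val <- min(1, max(0, val))
    }
    draws[[e$id]] <- val
    out <- config_set(out, e$path, val)
  }
  list(config = out, draws = draws)
}

#' Probabilistic sensitivity analysis
#'
#' Monte-Carlo propagation of parameter uncertainty: each replicate draws
#' one joint parameter set (see [sample_parameter_set()]), runs both
#' referral scenarios under that same set (only the transplant-exit
#' routing differs between scenarios), and records per-patient annual
#' cost and QALY at the drawn discount rate together with the incremental
#' pair. Transition rows whose sampled exits exceed one are renormalized
#' with stay probability zero. Replicates that fail are logged and
#' redrawn (capped), never silently dropped.
#'
#' @param cfg An `rrt_config`.
#' @param n Number of replicates (default from the config, 1,000).
#' @param seed Master seed (default from the config); identical seeds give
#'   identical output.
#' @param wtpt Threshold for the per-replicate category (default from the
#'   config).
#' @param reference,comparator [scenario_spec()]s; defaults late (p = 1)
#'   vs timely (p = 0).
#' @param max_retries Cap on redraws after failed replicates.
#' @return A `psa_result`: list with `samples` (one row per replicate:
#'   draws, per-scenario outcomes, `delta_cost`, `delta_qaly`, `category`),
#'   `summary` (means and 95% percentile intervals), `category_freq`
#'   (per-scenario category frequencies at the threshold), `acceptance`,
#'   `restricted` and the run metadata.
#' @export
run_psa <- function(cfg, n = cfg$psa$replicates, seed = cfg$psa$seed,
                    wtpt = cfg$model$wtpt,
                    reference = scenario_spec(1), comparator = scenario_spec(0),
                    max_retries = 100L) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  rows <- vector("list", n)
  failures <- 0L
  withr::with_seed(stage_seed(seed, "psa"), {
    i <- 1L
    while (i <= n) {
      drawn <- sample_parameter_set(cfg)
      res <- tryCatch({
        rate <- drawn$config$model$discount_rate
        ref <- run_scenario(drawn$config, reference, discount_rate = rate,
                            renormalize = TRUE)
        cmp <- run_scenario(drawn$config, comparator, discount_rate = rate,
                            renormalize = TRUE)
        inc <- incremental(ref, cmp, wtpt = wtpt)
        c(list(replicate = i, discount_rate = rate),
          as.list(drawn$draws),
          list(cost_reference = ref$per_patient_annual_cost,
               qaly_reference = ref$per_patient_annual_qaly,
               cost_comparator = cmp$per_patient_annual_cost,
               qaly_comparator = cmp$per_patient_annual_qaly,
               delta_cost = inc$delta_cost,
               delta_qaly = inc$delta_qaly,
               category = inc$category))
      }, error = function(err) err)
      if (inherits(res, "error")) {
        failures <- failures + 1L
        if (failures > max_retries) {
          stop("probabilistic analysis exceeded the retry cap: ",
               conditionMessage(res), call. = FALSE)
        }
        message("replicate ", i, " infeasible, redrawing: ",
                conditionMessage(res))
        next
      }
      rows[[i]] <- res
      i <- i + 1L
    }
  })
  samples <- do.call(rbind, lapply(rows, function(r) {
    as.data.frame(r, stringsAsFactors = FALSE)
  }))

  pct <- function(x) stats::quantile(x, c(0.025, 0.975), names = FALSE)
  summarize <- function(x) c(mean = mean(x), lower = pct(x)[1],
                             upper = pct(x)[2])
  summary <- rbind(
    cost_reference = summarize(samples$cost_reference),
    cost_comparator = summarize(samples$cost_comparator),
    qaly_reference = summarize(samples$qaly_reference),
    qaly_comparator = summarize(samples$qaly_comparator),
    delta_cost = summarize(samples$delta_cost),
    delta_qaly = summarize(samples$delta_qaly)
  )

  cats <- c(acceptable_categories(), "dominated", "not_acceptable")
  freq <- function(dc, de) {
    cl <- factor(classify(dc, de, wtpt), levels = cats)
    table(cl) / length(cl)
  }
  category_freq <- list(comparator = freq(samples$delta_cost,
                                          samples$delta_qaly),
                        reference = freq(-samples$delta_cost,
                                         -samples$delta_qaly))
  nmb <- wtpt * samples$delta_qaly - samples$delta_cost
  acceptance <- c(mean((nmb > 0) + 0.5 * (nmb == 0)))
  acceptance <- stats::setNames(c(acceptance, 1 - acceptance),
                                c(comparator$name, reference$name))
  restricted <- tryCatch(
    restricted_acceptance(samples, wtpt, comparator$name, reference$name),
    error = function(e) NULL)

  structure(list(samples = samples, summary = summary,
                 category_freq = category_freq,
                 acceptance = acceptance, restricted = restricted,
                 wtpt = wtpt, n = n, seed = seed, failures = failures,
                 reference = reference$name, comparator = comparator$name),
            class = "psa_result")
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf("<psa_result> %d replicates (seed %d), %s vs %s\n",
              x$n, x$seed, x$comparator, x$reference))
  cat(sprintf("  delta cost: %.1f euro [%.1f; %.1f]; delta QALY: %.4f [%.4f; %.4f]\n",
              x$summary["delta_cost", 1], x$summary["delta_cost", 2],
              x$summary["delta_cost", 3], x$summary["delta_qaly", 1],
              x$summary["delta_qaly", 2], x$summary["delta_qaly", 3]))
  cat(sprintf("  acceptance at %s euro/QALY: %s %.1f%%, %s %.1f%%\n",
              format(x$wtpt, big.mark = ","),
              names(x$acceptance)[1], 100 * x$acceptance[1],
              names(x$acceptance)[2], 100 * x$acceptance[2]))
  invisible(x)
}

#' @rdname run_psa
#' @param psa A `psa_result`.
#' @param path Output CSV path for the replicate-level table.
#' @export
write_psa_samples <- function(psa, path) {
  utils::write.csv(psa$samples, path, row.names = FALSE)
  invisible(path)
}
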