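#' Full run report: deterministic and probabilistic blocks
#'
#' Assembles the headline results table: per-scenario per-patient annual
#' cost and QALY undiscounted and at the configured discount rate with
#' the two ICERs (deterministic block), and the probabilistic block
#' (means, 95% percentile intervals, category frequencies at the
#' willingness-to-pay threshold, acceptance and restricted acceptance
#' probabilities), plus provenance (configuration fingerprint, seed,
#' package version) that makes the run reproducible from the
#' configuration and seed alone.
#'
#' @param cfg An `rrt_config`.
#' @param seed Master seed for the probabilistic stage (default from the
#'   config).
#' @param n_psa Number of probabilistic replicates (default from the
#'   config); `0` skips the probabilistic block.
#' @return A `run_report` list with elements `deterministic`,
#'   `probabilistic` (or `NULL`) and `provenance`.
#' @export
run_report <- function(cfg, seed = cfg$psa$seed, n_psa = cfg$psa$replicates) {
  undisc <- deterministic_comparison(cfg, discount_rate = 0)
  disc <- deterministic_comparison(cfg)
  det <- list(
    discount_rate = cfg$model$discount_rate,
    table = data.frame(
      quantity = c("per_patient_annual_cost", "per_patient_annual_cost_disc",
                   "per_patient_annual_qaly", "per_patient_annual_qaly_disc"),
      reference = c(undisc$reference_summary$per_patient_annual_cost,
                    disc$reference_summary$per_patient_annual_cost,
                    undisc$reference_summary$per_patient_annual_qaly,
                    disc$reference_summary$per_patient_annual_qaly),
      comparator = c(undisc$comparator_summary$per_patient_annual_cost,
                     disc$comparator_summary$per_patient_annual_cost,
                     undisc$comparator_summary$per_patient_annual_qaly,
                     disc$comparator_summary$per_patient_annual_qaly)
    ),
    icer_undiscounted = undisc$icer,
    icer_discounted = disc$icer,
    category = disc$category
  )
  det$table$comparative <- det$table$comparator - det$table$reference

  prob <- NULL
  if (n_psa > 0) {
    psa <- run_psa(cfg, n = n_psa, seed = seed)
    prob <- list(summary = psa$summary,
                 category_freq = psa$category_freq,
                 acceptance = psa$acceptance,
                 restricted = psa$restricted,
                 n = psa$n, failures = psa$failures)
  }

  structure(list(
    deterministic = det,
    probabilistic = prob,
    provenance = list(config_fingerprint = object_fingerprint(unclass(cfg)),
                      seed = seed,
                      package_version =
                        as.character(utils::packageVersion("renalcea")))
  ), class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  d <- x$deterministic
  cat("<run_report>\n  Deterministic analysis (per patient and year)\n")
  tab <- d$table
  tab[tab$quantity %in% c("per_patient_annual_cost",
                          "per_patient_annual_cost_disc"), -1] <-
    round(tab[tab$quantity %in% c("per_patient_annual_cost",
                                  "per_patient_annual_cost_disc"), -1])
  tab[grepl("qaly", tab$quantity), -1] <-
    round(tab[grepl("qaly", tab$quantity), -1], 4)
  print(tab, row.names = FALSE)
  cat(sprintf("  ICER: %.0f euro/QALY (undiscounted), %.0f euro/QALY (%.0f%% discount)\n",
              d$icer_undiscounted, d$icer_discounted,
              100 * d$discount_rate))
  if (!is.null(x$probabilistic)) {
    p <- x$probabilistic
    cat(sprintf("  Probabilistic analysis (%d replicates)\n", p$n))
    cat(sprintf("    acceptance: %s\n",
                paste(sprintf("%s %.1f%%", names(p$acceptance),
                              100 * p$acceptance), collapse = ", ")))
    if (!is.null(p$restricted)) {
      cat(sprintf("    without effectiveness loss: %s\n",
                  paste(sprintf("%s %.1f%%", names(p$restricted),
                                100 * p$restricted), collapse = ", ")))
    }
  }
  cat(sprintf("  provenance: config %s, seed %s, version %s\n",
              x$provenance$config_fingerprint, x$provenance$seed,
              x$provenance$package_version))
  invisible(x)
}

# shared plumbing for the cmd_* entry points: load + apply overrides,
# run `body(cfg)`, convert errors into a nonzero status on stderr
cmd_wrapper <- function(config_path, out_dir, body,
                        discount = NULL, wtpt = NULL, societal = FALSE) {
  status <- tryCatch({
    cfg <- load_config(config_path)
    if (!is.null(discount)) cfg$model$discount_rate <- discount
    if (!is.null(wtpt)) cfg$model$wtpt <- wtpt
    if (societal) cfg$productivity$enabled <- TRUE
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    body(cfg)
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}

#' Command-style entry points
#'
#' Thin wrappers that load a configuration, run one analysis stage and
#' write its artifacts to an output directory. They return an exit status
#' (0 success, 1 failure with a diagnostic on the message stream) so a
#' shell wrapper can forward it; see `inst/cli/renal-cea.R` for the
#' installed Rscript front end.
#'
#' @param config_path Path to a YAML/JSON configuration.
#' @param out_dir Output directory (created if needed).
#' @param discount,wtpt Optional overrides of the configured discount rate
#'   and willingness-to-pay threshold.
#' @param societal Enable the productivity-loss extension.
#' @param seed Master seed for stochastic stages.
#' @param n Replicate count for [cmd_psa()].
#' @param delta Perturbation size for [cmd_tornado()].
#' @param p_grid Late-referral proportions for [cmd_sweep()].
#' @return Exit status, invisibly.
#' @export
cmd_run <- function(config_path, out_dir, discount = NULL, wtpt = NULL,
                    societal = FALSE) {
  cmd_wrapper(config_path, out_dir, discount = discount, wtpt = wtpt,
              societal = societal, body = function(cfg) {
    report <- run_report(cfg, n_psa = 0)
    inc <- deterministic_comparison(cfg)
    write_trace(inc$reference_summary$trace,
                file.path(out_dir, "trace_late.csv"))
    write_trace(inc$comparator_summary$trace,
                file.path(out_dir, "trace_timely.csv"))
    utils::write.csv(report$deterministic$table,
                     file.path(out_dir, "deterministic.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(deterministic = list(
             icer_undiscounted = report$deterministic$icer_undiscounted,
             icer_discounted = report$deterministic$icer_discounted,
             category = report$deterministic$category),
           provenance = report$provenance),
      file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
    print(report)
  })
}

#' @rdname cmd_run
#' @export
cmd_psa <- function(config_path, out_dir, n = NULL, seed = NULL,
                    discount = NULL, wtpt = NULL, societal = FALSE) {
  cmd_wrapper(config_path, out_dir, discount = discount, wtpt = wtpt,
              societal = societal, body = function(cfg) {
    if (!is.null(n) && n < 1) stop("n must be >= 1")
    psa <- run_psa(cfg, n = n %||% cfg$psa$replicates,
                   seed = seed %||% cfg$psa$seed)
    write_psa_samples(psa, file.path(out_dir, "psa_samples.csv"))
    ell <- confidence_ellipse(psa$samples)
    utils::write.csv(ellipse_boundary(ell),
                     file.path(out_dir, "ce_plane_ellipse.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(acceptance = as.list(psa$acceptance),
           restricted = as.list(psa$restricted),
           category_freq = lapply(psa$category_freq, function(t) {
             as.list(stats::setNames(as.numeric(t), names(t)))
           }),
           n = psa$n, seed = psa$seed),
      file.path(out_dir, "psa_summary.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
  })
}

#' @rdname cmd_run
#' @export
cmd_ceac <- function(config_path, out_dir, n = NULL, seed = NULL,
                     discount = NULL, wtpt = NULL) {
  cmd_wrapper(config_path, out_dir, discount = discount, wtpt = wtpt,
              body = function(cfg) {
    psa <- run_psa(cfg, n = n %||% cfg$psa$replicates,
                   seed = seed %||% cfg$psa$seed)
    curve <- ceac(psa$samples, cfg$psa$wtpt_grid)
    utils::write.csv(curve, file.path(out_dir, "ceac.csv"),
                     row.names = FALSE)
  })
}

#' @rdname cmd_run
#' @export
cmd_tornado <- function(config_path, out_dir, delta = 0.10,
                        discount = NULL, wtpt = NULL) {
  cmd_wrapper(config_path, out_dir, discount = discount, wtpt = wtpt,
              body = function(cfg) {
    tor <- univariate_tornado(cfg, delta = delta)
    utils::write.csv(as.data.frame(tor), file.path(out_dir, "tornado.csv"),
                     row.names = FALSE)
  })
}

#' @rdname cmd_run
#' @export
cmd_sweep <- function(config_path, out_dir,
                      p_grid = seq(0.01, 1, by = 0.01),
                      discount = NULL, wtpt = NULL) {
  cmd_wrapper(config_path, out_dir, discount = discount, wtpt = wtpt,
              body = function(cfg) {
    sweep <- sweep_late_referral_proportion(cfg, p_grid)
    utils::write.csv(sweep, file.path(out_dir, "late_fraction_sweep.csv"),
                     row.names = FALSE)
  })
}
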