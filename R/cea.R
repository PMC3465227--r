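#' Incremental cost-effectiveness comparison
#'
#' Differences are comparator minus reference on the per-patient annual
#' scale; the incremental cost-effectiveness ratio (ICER) is
#' `delta_cost / delta_qaly`, undefined (`NA`) when the effectiveness
#' difference is zero. When the societal productivity extension is active
#' on both summaries, the (negative of the) incremental productivity loss
#' is added to the incremental cost as an offset.
#'
#' @param reference,comparator Annualized [accumulate_outcomes()] results
#'   on the same annualization basis.
#' @param wtpt Willingness-to-pay threshold (euro/QALY) used for the
#'   category label.
#' @return An `incremental_result`: list with `delta_cost`, `delta_qaly`,
#'   `icer`, `category` and the two scenario labels.
#' @export
incremental <- function(reference, comparator, wtpt = 45000) {
  stopifnot(inherits(reference, "outcome_summary"),
            inherits(comparator, "outcome_summary"))
  if (is.null(reference$per_patient_annual_cost) ||
      is.null(comparator$per_patient_annual_cost)) {
    stop("summaries must be annualized (see annualize())", call. = FALSE)
  }
  dc <- comparator$per_patient_annual_cost - reference$per_patient_annual_cost
  de <- comparator$per_patient_annual_qaly - reference$per_patient_annual_qaly
  if (!is.null(reference$productivity_loss) &&
      !is.null(comparator$productivity_loss)) {
    denom <- reference$cohort_size * reference$horizon
    dc <- dc + (comparator$productivity_loss -
                  reference$productivity_loss) / denom
  }
  structure(list(
    reference = reference$scenario %||% "reference",
    comparator = comparator$scenario %||% "comparator",
    delta_cost = dc,
    delta_qaly = de,
    icer = if (de != 0) dc / de else NA_real_,
    category = classify(dc, de, wtpt),
    wtpt = wtpt
  ), class = "incremental_result")
}

#' @export
print.incremental_result <- function(x, ...) {
  cat(sprintf("<incremental_result> %s vs %s\n", x$comparator, x$reference))
  cat(sprintf("  delta cost: %.2f euro/patient-year; delta QALY: %.5f\n",
              x$delta_cost, x$delta_qaly))
  cat(sprintf("  ICER: %s euro/QALY; category at WTPT %s: %s\n",
              if (is.na(x$icer)) "undefined" else format(round(x$icer)),
              format(x$wtpt, big.mark = ","), x$category))
  invisible(x)
}

#' Classify an incremental outcome on the cost-effectiveness plane
#'
#' Exactly one category is assigned to every (delta cost, delta
#' effectiveness, threshold) triple: `dominant` (no more costly, more
#' effective — or cheaper, no less effective), `efficient_higher_effectiveness`
#' (more costly and more effective with ICER at or below the threshold),
#' `efficient_lower_cost` (cheaper and less effective, saving at least the
#' threshold per QALY forgone), `dominated` (no cheaper and less
#' effective, strictly worse on at least one axis), and `not_acceptable`
#' otherwise. "Acceptable" is dominant or either efficient category.
#'
#' @param delta_cost,delta_qaly Incremental cost (euro) and effectiveness
#'   (QALY); vectors recycle.
#' @param wtpt Willingness-to-pay threshold (euro/QALY), >= 0.
#' @return Character vector of categories.
#' @export
#' @examples
#' classify(-1, 0.1, 45000)       # dominant
#' classify(100, 0.01, 45000)     # efficient_higher_effectiveness
#' classify(-1000, -0.01, 45000)  # efficient_lower_cost
classify <- function(delta_cost, delta_qaly, wtpt) {
  if (any(wtpt < 0)) stop("wtpt must be >= 0", call. = FALSE)
  n <- max(length(delta_cost), length(delta_qaly))
  dc <- rep_len(delta_cost, n)
  de <- rep_len(delta_qaly, n)
  out <- character(n)
  for (i in seq_len(n)) {
    out[i] <- if ((dc[i] <= 0 && de[i] > 0) || (dc[i] < 0 && de[i] >= 0)) {
      "dominant"
    } else if (dc[i] > 0 && de[i] > 0 && dc[i] / de[i] <= wtpt) {
      "efficient_higher_effectiveness"
    } else if (dc[i] < 0 && de[i] < 0 && abs(dc[i]) / abs(de[i]) >= wtpt) {
      "efficient_lower_cost"
    } else if (dc[i] >= 0 && de[i] < 0) {
      "dominated"
    } else {
      "not_acceptable"
    }
  }
  out
}

#' @rdname classify
#' @export
acceptable_categories <- function() {
  c("dominant", "efficient_higher_effectiveness", "efficient_lower_cost")
}

#' Cost-effectiveness acceptability curves
#'
#' For each willingness-to-pay value, the comparator's acceptance
#' probability is the fraction of Monte-Carlo replicates with positive net
#' monetary benefit `wtpt * delta_qaly - delta_cost` (ties counted half);
#' the reference receives the complement, so the two curves sum to one
#' everywhere.
#'
#' @param samples Data frame (or list) with numeric columns `delta_cost`
#'   and `delta_qaly`, one row per replicate.
#' @param wtpt_grid Numeric vector of thresholds (euro/QALY).
#' @param comparator,reference Labels for the two scenarios.
#' @return A `ceac_curve` data.frame with columns `wtpt`, `scenario`,
#'   `acceptance`.
#' @export
ceac <- function(samples, wtpt_grid, comparator = "timely",
                 reference = "late") {
  dc <- samples$delta_cost
  de <- samples$delta_qaly
  if (is.null(dc) || is.null(de) || !length(dc)) {
    stop("samples must contain delta_cost and delta_qaly", call. = FALSE)
  }
  if (!length(wtpt_grid)) stop("wtpt_grid must be non-empty", call. = FALSE)
  acc <- vapply(wtpt_grid, function(w) {
    nmb <- w * de - dc
    mean((nmb > 0) + 0.5 * (nmb == 0))
  }, numeric(1))
  out <- rbind(
    data.frame(wtpt = wtpt_grid, scenario = comparator, acceptance = acc),
    data.frame(wtpt = wtpt_grid, scenario = reference, acceptance = 1 - acc)
  )
  class(out) <- c("ceac_curve", "data.frame")
  out
}

#' Acceptance restricted to outcomes without effectiveness loss
#'
#' Renormalizes the scenario acceptance probabilities over the replicates
#' in which the accepted scenario does not lose effectiveness — i.e. the
#' comparator is dominant or efficient with higher effectiveness, or the
#' reference is (equivalently, the comparator loses effectiveness while
#' the reference gains it). The two probabilities sum to one over that
#' subset.
#'
#' @inheritParams ceac
#' @param wtpt Single willingness-to-pay threshold (euro/QALY).
#' @return Named numeric vector of the two renormalized probabilities.
#' @export
restricted_acceptance <- function(samples, wtpt, comparator = "timely",
                                  reference = "late") {
  dc <- samples$delta_cost
  de <- samples$delta_qaly
  no_loss <- c("dominant", "efficient_higher_effectiveness")
  comp_fav <- classify(dc, de, wtpt) %in% no_loss
  ref_fav <- classify(-dc, -de, wtpt) %in% no_loss
  n <- sum(comp_fav) + sum(ref_fav)
  if (n == 0) {
    stop("no replicate without effectiveness loss for either scenario",
         call. = FALSE)
  }
  out <- c(sum(comp_fav) / n, sum(ref_fav) / n)
  names(out) <- c(comparator, reference)
  out
}

#' Normal-theory confidence ellipse on the cost-effectiveness plane
#'
#' Centers at the sample means of (delta effectiveness, delta cost) and
#' bounds the region where the Mahalanobis distance under the sample
#' covariance is at most the chi-square quantile with two degrees of
#' freedom at the given level (5.9915 at 95%).
#'
#' @param samples Data frame with columns `delta_cost`, `delta_qaly`.
#' @param level Confidence level in (0, 1), default 0.95.
#' @return An `ellipse_spec`: list with `center` (named: `delta_qaly`,
#'   `delta_cost`), `covariance`, `level` and `chi2_quantile`.
#' @export
confidence_ellipse <- function(samples, level = 0.95) {
  x <- cbind(delta_qaly = samples$delta_qaly, delta_cost = samples$delta_cost)
  if (nrow(x) < 3) stop("need at least 3 samples for an ellipse",
                        call. = FALSE)
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)", call. = FALSE)
  center <- colMeans(x)
  covariance <- stats::cov(x)
  if (!all(is.finite(covariance)) ||
      abs(det(covariance)) < .Machine$double.eps^2 * prod(diag(covariance) + 1)) {
    stop("degenerate (singular) sample covariance", call. = FALSE)
  }
  structure(list(center = center, covariance = covariance, level = level,
                 chi2_quantile = stats::qchisq(level, df = 2),
                 n = nrow(x)),
            class = "ellipse_spec")
}

#' @rdname confidence_ellipse
#' @param ellipse An `ellipse_spec`.
#' @param delta_qaly,delta_cost Points to test (vectors recycle).
#' @return `in_ellipse()`: logical vector, `TRUE` inside or on the
#'   boundary.
#' @export
in_ellipse <- function(ellipse, delta_qaly, delta_cost) {
  pts <- cbind(delta_qaly, delta_cost)
  d2 <- stats::mahalanobis(pts, ellipse$center, ellipse$covariance)
  d2 <= ellipse$chi2_quantile
}

#' @rdname confidence_ellipse
#' @param n_points Number of boundary vertices.
#' @return `ellipse_boundary()`: data.frame polyline (`delta_qaly`,
#'   `delta_cost`) tracing the boundary.
#' @export
ellipse_boundary <- function(ellipse, n_points = 200) {
  theta <- seq(0, 2 * pi, length.out = n_points)
  circle <- rbind(cos(theta), sin(theta)) * sqrt(ellipse$chi2_quantile)
  L <- chol(ellipse$covariance)
  pts <- t(t(L) %*% circle + ellipse$center)
  data.frame(delta_qaly = pts[, 1], delta_cost = pts[, 2])
}

#' @export
print.ellipse_spec <- function(x, ...) {
  cat(sprintf("<ellipse_spec> %.0f%% confidence, n = %d\n",
              100 * x$level, x$n))
  cat(sprintf("  center: delta QALY %.5f, delta cost %.2f euro\n",
              x$center[["delta_qaly"]], x$center[["delta_cost"]]))
  cat(sprintf("  chi-square quantile (2 df): %.4f\n", x$chi2_quantile))
  invisible(x)
}
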