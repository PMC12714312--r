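#' Per-track economic outcomes from a cohort trace
#'
#' Combines a cohort trace with the treatment cost of the track's modality:
#' the treatment cost accrues once at model entry (T0, never discounted),
#' annual clinical costs and QALYs follow the trace's accrual columns
#' (discounted when the parameter policy says so), and lifetime values are
#' their sums.
#'
#' @param trace a `cohort_trace` from [run_cohort()] or [microsimulate()].
#' @param params a [model_parameters()] object.
#' @param track track id `"T1"`-`"T9"`.
#' @return an object of class `track_outcome`: list with `track`,
#'   `treatment_cost`, `annual_costs` (per cycle, per discounting policy),
#'   `lifetime_cost` and `lifetime_qalys`.
#' @export
accumulate_outcomes <- function(trace, params, track) {
  stopifnot(inherits(trace, "cohort_trace"))
  disc <- params$discounting_enabled
  annual <- if (disc) trace$cost_disc[-1] else trace$cost_undisc[-1]
  qalys <- if (disc) trace$qaly_disc[-1] else trace$qaly_undisc[-1]
  t0 <- unname(params$c_treat[track_modality(track)])
  structure(list(
    track = track,
    treatment_cost = t0,
    annual_costs = annual,
    lifetime_cost = t0 + sum(annual),
    lifetime_qalys = sum(qalys)
  ), class = "track_outcome")
}

#' Aggregate track outcomes into an arm outcome
#'
#' Weighted sum of per-track outcomes by the arm's track weights; the
#' assay-guided arm additionally accrues the test cost once at T0.
#'
#' @param track_outcomes named list of [accumulate_outcomes()] results,
#'   covering every track with nonzero weight.
#' @param weights a [compute_track_weights()] result for the same arm.
#' @param params a [model_parameters()] object.
#' @return an object of class `arm_outcome`: list with `arm`, `t0_cost`
#'   (weighted treatment costs, plus the test cost for the assay-guided arm),
#'   `annual_costs` (weighted per-year stream), `cumulative_costs` (years
#'   0..T), `lifetime_cost` and `lifetime_qalys`.
#' @export
aggregate_arm <- function(track_outcomes, weights, params) {
  stopifnot(inherits(weights, "track_weights"))
  w <- weights$weights
  active <- names(w)[w > 0]
  missing <- setdiff(active, names(track_outcomes))
  if (length(missing)) {
    stop("missing track outcome(s) for weighted track(s): ",
         paste(missing, collapse = ", "))
  }
  horizon <- max(vapply(track_outcomes[active],
                        function(o) length(o$annual_costs), integer(1)))
  annual <- numeric(horizon)
  t0 <- 0; qalys <- 0
  for (tk in active) {
    o <- track_outcomes[[tk]]
    stopifnot(length(o$annual_costs) == horizon)
    annual <- annual + w[tk] * o$annual_costs
    t0 <- t0 + w[tk] * o$treatment_cost
    qalys <- qalys + w[tk] * o$lifetime_qalys
  }
  if (weights$arm == "PROSTOX") t0 <- t0 + params$c_test
  cumulative <- t0 + c(0, cumsum(annual))
  structure(list(
    arm = weights$arm,
    t0_cost = unname(t0),
    annual_costs = unname(annual),
    cumulative_costs = unname(cumulative),
    lifetime_cost = unname(cumulative[length(cumulative)]),
    lifetime_qalys = unname(qalys)
  ), class = "arm_outcome")
}

#' @export
print.arm_outcome <- function(x, ...) {
  cat("Arm outcome: ", x$arm, "\n", sep = "")
  cat(sprintf("  T0 cost           : $%s\n", format(round(x$t0_cost), big.mark = ",")))
  cat(sprintf("  5-year cumulative : $%s\n",
              format(round(x$cumulative_costs[min(6, length(x$cumulative_costs))]),
                     big.mark = ",")))
  cat(sprintf("  lifetime cost     : $%s\n", format(round(x$lifetime_cost), big.mark = ",")))
  cat(sprintf("  lifetime QALYs    : %.2f\n", x$lifetime_qalys))
  invisible(x)
}

#' Full-pipeline arm outcomes
#'
#' Convenience driver: derives track weights for both arms, runs the Markov
#' cohort model for every track with nonzero weight, and aggregates into
#' per-arm outcomes.
#'
#' @param params a [model_parameters()] object.
#' @param life_table background mortality; default [default_life_table()].
#' @param soc_shares optional raw SOC modality mix (named over `SBRT`,
#'   `CFRT`, `prostatectomy`) replacing `params$soc_utilization` for the SOC
#'   arm only. The vector is used as-is, without renormalization — the
#'   spreadsheet-style semantics of the one-way sensitivity analysis, where a
#'   single utilization row is perturbed while the other rows keep their
#'   printed values. Leave `NULL` for the validated base-case mix.
#' @return named list with `PROSTOX` and `SOC` [aggregate_arm()] outcomes.
#' @export
#' @examples
#' arms <- evaluate_arms(model_parameters())
#' arms$PROSTOX
evaluate_arms <- function(params, life_table = default_life_table(),
                          soc_shares = NULL) {
  validate_parameters(params)
  out <- list()
  for (arm in c("PROSTOX", "SOC")) {
    w <- compute_track_weights(params, arm)
    if (arm == "SOC" && !is.null(soc_shares)) {
      stopifnot(all(MODALITIES %in% names(soc_shares)))
      w$weights[c("T7", "T8", "T9")] <- soc_shares[MODALITIES]
    }
    active <- names(w$weights)[w$weights > 0]
    tos <- lapply(active, function(tk) {
      accumulate_outcomes(run_cohort(params, tk, life_table), params, tk)
    })
    names(tos) <- active
    out[[arm]] <- aggregate_arm(tos, w, params)
  }
  out
}

#' Worked-example aggregation of the published per-track table
#'
#' Reproduces the published arm-level arithmetic from the printed per-track
#' cells: weighted year-k cost = sum over tracks of weight x printed year-k
#' cell; the 5-year cumulative adds the weighted T0 treatment costs (plus the
#' test cost for the assay-guided arm); weighted lifetime QALYs use the
#' printed per-track QALYs (zero-weight tracks drop out). Because the printed
#' annual cells already carry the track weight, this deliberately repeats the
#' published sum-product ("double-weighting") rather than re-deriving
#' per-patient values; use [evaluate_arms()] for the genuine pipeline.
#'
#' @param tab a [load_printed_table()] data frame.
#' @param params a [model_parameters()] object (supplies the test cost).
#' @return list with per-arm components (`annual_costs` years 1-5, `t0_cost`,
#'   `cumulative_5yr`, `lifetime_qalys`) and `savings_5yr` (SOC minus
#'   assay-guided) plus `incremental_qalys`.
#' @export
#' @examples
#' agg <- aggregate_printed_table(load_printed_table(), model_parameters())
#' round(agg$SOC$annual_costs[5])   # year-5 SOC weighted cost
#' round(agg$savings_5yr)
aggregate_printed_table <- function(tab, params = model_parameters()) {
  stopifnot(inherits(tab, "printed_track_table"))
  out <- list()
  for (a in c("PROSTOX", "SOC")) {
    rows <- tab[tab$track %in% TRACKS$track[TRACKS$arm == a], , drop = FALSE]
    w <- rows$weight_pct / 100
    annual <- vapply(1:5, function(k) sum(w * rows[[paste0("cost_y", k)]]),
                     numeric(1))
    t0 <- sum(w * rows$cost_t0) + if (a == "PROSTOX") params$c_test else 0
    out[[a]] <- list(
      annual_costs = annual,
      t0_cost = t0,
      cumulative_5yr = t0 + sum(annual),
      lifetime_qalys = sum(w * rows$lifetime_qalys)
    )
  }
  out$savings_5yr <- out$SOC$cumulative_5yr - out$PROSTOX$cumulative_5yr
  out$incremental_qalys <- out$PROSTOX$lifetime_qalys - out$SOC$lifetime_qalys
  out
}

#' Per-year cost impact of one arm versus another
#'
#' @param arm_a the intervention arm outcome (e.g. assay-guided).
#' @param arm_b the comparator arm outcome (e.g. SOC).
#' @param horizon_years number of years beyond T0 to report.
#' @return data frame with columns `year` (0..horizon), per-arm cumulative
#'   costs, and `savings` = comparator minus intervention cumulative cost.
#' @export
cost_impact <- function(arm_a, arm_b, horizon_years = 5) {
  stopifnot(inherits(arm_a, "arm_outcome"), inherits(arm_b, "arm_outcome"))
  n <- horizon_years + 1
  if (n > length(arm_a$cumulative_costs) || n > length(arm_b$cumulative_costs)) {
    stop("horizon exceeds the computed cost streams")
  }
  data.frame(
    year = 0:horizon_years,
    cumulative_a = arm_a$cumulative_costs[seq_len(n)],
    cumulative_b = arm_b$cumulative_costs[seq_len(n)],
    savings = arm_b$cumulative_costs[seq_len(n)] - arm_a$cumulative_costs[seq_len(n)]
  )
}

# Scalar: 5-year cumulative savings of the assay-guided arm vs SOC under the
# full pipeline. The unit varied by the DSA and the price sweep.
five_year_savings <- function(params, life_table = default_life_table(),
                              horizon_years = 5, soc_shares = NULL) {
  arms <- evaluate_arms(params, life_table, soc_shares = soc_shares)
  ci <- cost_impact(arms$PROSTOX, arms$SOC, horizon_years)
  ci$savings[nrow(ci)]
}

#' Incremental cost-effectiveness of one arm versus another
#'
#' Computes incremental lifetime cost and QALYs and classifies the result on
#' the cost-effectiveness plane: `dominant` (cheaper and more effective),
#' `dominated` (dearer and less effective), or a `tradeoff` with an ICER
#' (incremental cost per QALY). When the QALY difference is zero the ICER is
#' flagged undefined rather than divided.
#'
#' @param arm_a intervention arm outcome.
#' @param arm_b comparator arm outcome.
#' @param wtp willingness-to-pay threshold used for labelling (USD/QALY).
#' @return an object of class `cea_result`: list with `delta_cost`,
#'   `delta_qalys`, `icer` (NA unless a tradeoff), `dominance`
#'   (`"dominant"`, `"dominated"`, `"tradeoff"` or `"undefined"`), and `wtp`.
#' @export
icer <- function(arm_a, arm_b, wtp = 100000) {
  stopifnot(inherits(arm_a, "arm_outcome"), inherits(arm_b, "arm_outcome"))
  dC <- arm_a$lifetime_cost - arm_b$lifetime_cost
  dE <- arm_a$lifetime_qalys - arm_b$lifetime_qalys
  if (dE == 0) {
    dominance <- "undefined"; ratio <- NA_real_
  } else if (dC < 0 && dE > 0) {
    dominance <- "dominant"; ratio <- NA_real_
  } else if (dC > 0 && dE < 0) {
    dominance <- "dominated"; ratio <- NA_real_
  } else {
    dominance <- "tradeoff"; ratio <- dC / dE
  }
  structure(list(delta_cost = dC, delta_qalys = dE, icer = ratio,
                 dominance = dominance, wtp = wtp),
            class = "cea_result")
}

#' @export
print.cea_result <- function(x, ...) {
  cat("Incremental cost-effectiveness\n")
  cat(sprintf("  delta cost  : $%s\n", format(round(x$delta_cost), big.mark = ",")))
  cat(sprintf("  delta QALYs : %.3f\n", x$delta_qalys))
  if (x$dominance == "tradeoff") {
    cat(sprintf("  ICER        : $%s per QALY (WTP $%s)\n",
                format(round(x$icer), big.mark = ","),
                format(x$wtp, big.mark = ",")))
  } else {
    cat("  verdict     : ", x$dominance, "\n", sep = "")
  }
  invisible(x)
}

#' Five-year savings across candidate test prices
#'
#' Re-runs the full pipeline at each candidate assay price and reports the
#' 5-year cumulative savings versus SOC. Because the test cost enters the
#' assay-guided arm exactly once at T0, savings are affine in the price with
#' slope -1.
#'
#' @param prices numeric vector of candidate test prices (USD, >= 0).
#' @param params a [model_parameters()] object (its `c_test` is replaced).
#' @param life_table background mortality.
#' @param horizon_years cost-impact horizon.
#' @return data frame with columns `price` and `savings`.
#' @export
price_threshold_sweep <- function(prices, params = model_parameters(),
                                  life_table = default_life_table(),
                                  horizon_years = 5) {
  stopifnot(all(prices >= 0))
  savings <- vapply(prices, function(p) {
    pp <- params
    pp$c_test <- p
    five_year_savings(pp, life_table, horizon_years)
  }, numeric(1))
  data.frame(price = prices, savings = savings)
}
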