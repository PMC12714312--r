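#' Cycle-specific toxicity transition probability
#'
#' Probability that a patient in the no-toxicity state develops late GU
#' toxicity during the given annual cycle. Radiation tracks hold the cycle-1
#' probability through cycle 4, after which the annual development taper
#' applies geometrically (`p1 * taper^(cycle - 4)`). Prostatectomy tracks
#' (T3, T6, T9) admit toxicity only in cycle 1; surgical GU complications are
#' fully manifest within the first year.
#'
#' @param params a [model_parameters()] object.
#' @param track track id, `"T1"`-`"T9"`.
#' @param cycle 1-based cycle index (vectorised).
#' @return probability (numeric, same length as `cycle`).
#' @export
#' @examples
#' toxicity_probability(model_parameters(), "T7", 1:6)
toxicity_probability <- function(params, track, cycle) {
  if (length(track) != 1L || !track %in% TRACKS$track) {
    stop("unknown track: ", paste(track, collapse = ", "))
  }
  stopifnot(all(cycle >= 1))
  p1 <- unname(params$tox_p1[track])
  if (is_prostatectomy_track(track)) {
    ifelse(cycle == 1, p1, 0)
  } else {
    ifelse(cycle <= 4, p1, p1 * params$taper^(cycle - 4))
  }
}

# Vectorised three-state cohort recursion shared by the cohort model, the
# full pipeline and the PSA. All parameter arguments may be vectors of a
# common length n (one cohort per element); q is the fixed per-cycle death
# probability schedule. Within a cycle, death is applied first (identical q
# in both living states), then survivors in no-toxicity may transition to
# toxicity; both toxicity and death are absorbing.
#
# Returns per-element totals, and per-cycle matrices when keep_trace = TRUE.
cohort_engine <- function(p1, taper, prost, q,
                          c_notox, c_tox, u_notox, u_tox,
                          d_cost, d_util, discounting = TRUE,
                          keep_trace = FALSE) {
  n <- max(length(p1), length(taper), length(c_notox), length(c_tox),
           length(u_notox), length(u_tox))
  p1 <- rep_len(p1, n); taper <- rep_len(taper, n)
  c_notox <- rep_len(c_notox, n); c_tox <- rep_len(c_tox, n)
  u_notox <- rep_len(u_notox, n); u_tox <- rep_len(u_tox, n)
  horizon <- length(q)
  s_no <- rep(1, n); s_tox <- rep(0, n); s_dead <- rep(0, n)
  cum_tox <- rep(0, n)
  cost_disc <- rep(0, n); qaly_disc <- rep(0, n)
  cost_undisc <- rep(0, n); qaly_undisc <- rep(0, n)
  cost5 <- rep(0, n)
  annual_cost <- if (keep_trace) matrix(0, n, horizon) else NULL
  tr <- if (keep_trace) {
    list(s_no = matrix(0, n, horizon + 1), s_tox = matrix(0, n, horizon + 1),
         s_dead = matrix(0, n, horizon + 1), cum_tox = matrix(0, n, horizon + 1))
  } else NULL
  if (keep_trace) tr$s_no[, 1] <- 1
  for (t in seq_len(horizon)) {
    qt <- q[t]
    s_dead <- s_dead + (s_no + s_tox) * qt
    s_no <- s_no * (1 - qt)
    s_tox <- s_tox * (1 - qt)
    pt <- if (prost) {
      if (t == 1) p1 else 0
    } else if (t <= 4) p1 else p1 * taper^(t - 4)
    inflow <- s_no * pt
    s_no <- s_no - inflow
    s_tox <- s_tox + inflow
    cum_tox <- cum_tox + inflow
    dfc <- if (discounting) (1 + d_cost)^(-t) else 1
    dfu <- if (discounting) (1 + d_util)^(-t) else 1
    ct <- s_no * c_notox + s_tox * c_tox
    ut <- s_no * u_notox + s_tox * u_tox
    cost_undisc <- cost_undisc + ct
    qaly_undisc <- qaly_undisc + ut
    cost_disc <- cost_disc + ct * dfc
    qaly_disc <- qaly_disc + ut * dfu
    if (t <= 5) cost5 <- cost5 + ct * dfc
    if (keep_trace) {
      annual_cost[, t] <- ct * dfc
      tr$s_no[, t + 1] <- s_no; tr$s_tox[, t + 1] <- s_tox
      tr$s_dead[, t + 1] <- s_dead; tr$cum_tox[, t + 1] <- cum_tox
    }
  }
  list(lifetime_cost = if (discounting) cost_disc else cost_undisc,
       lifetime_qalys = if (discounting) qaly_disc else qaly_undisc,
       cost_disc = cost_disc, qaly_disc = qaly_disc,
       cost_undisc = cost_undisc, qaly_undisc = qaly_undisc,
       cost5 = cost5, annual_cost = annual_cost, trace = tr)
}

# Build a cohort_trace data frame from occupancy vectors over cycles 0..T.
# Accrual columns follow end-of-cycle state membership (no half-cycle
# correction): cycle-t cost/QALY use the occupancies after that cycle's
# transitions, discounted by (1 + d)^-t.
build_trace <- function(s_no, s_tox, s_dead, cum_tox, params, track) {
  horizon <- length(s_no) - 1L
  t <- seq_len(horizon)
  dfc <- (1 + params$d_cost)^(-t)
  dfu <- (1 + params$d_util)^(-t)
  if (!params$discounting_enabled) dfc[] <- dfu[] <- 1
  ct <- s_no[-1] * params$c_notox + s_tox[-1] * params$c_tox
  ut <- s_no[-1] * params$u_notox + s_tox[-1] * params$u_tox
  out <- data.frame(
    cycle = 0:horizon,
    age = params$start_age + 0:horizon,
    s_notox = s_no, s_tox = s_tox, s_dead = s_dead,
    cum_tox = cum_tox,
    cost_undisc = c(NA, ct),
    cost_disc = c(NA, ct * dfc),
    qaly_undisc = c(NA, ut),
    qaly_disc = c(NA, ut * dfu)
  )
  structure(out, class = c("cohort_trace", "data.frame"),
            track = track, discounting = params$discounting_enabled)
}

#' Run the three-state Markov cohort model for one track
#'
#' Deterministic cohort recursion over annual cycles. The whole cohort enters
#' at cycle 0 in the no-toxicity state. Each cycle applies, in order:
#' age-specific background mortality (identical in both living states — the
#' model carries no toxicity effect on survival), then toxicity development
#' among surviving no-toxicity patients at the [toxicity_probability()] for
#' that cycle. Toxicity is absorbing among the living; death is absorbing.
#' Costs and QALYs accrue on end-of-cycle state membership and are discounted
#' per the parameter policy.
#'
#' @param params a [model_parameters()] object.
#' @param track track id `"T1"`-`"T9"`.
#' @param life_table a `life_table` data frame covering `params$start_age`
#'   onward, ending in q = 1.
#' @param max_cycles optional cap on the number of cycles; default runs to
#'   the end of the life table (full absorption).
#' @return a `cohort_trace` data frame: per cycle, occupancies of the three
#'   states, cumulative toxicity incidence, and (un)discounted per-patient
#'   cost and QALY accrual.
#' @export
#' @examples
#' tr <- run_cohort(model_parameters(), "T7", default_life_table())
#' head(tr)
run_cohort <- function(params, track, life_table, max_cycles = NULL) {
  validate_parameters(params)
  validate_life_table(life_table)
  q <- q_schedule(params, life_table, max_cycles)
  eng <- cohort_engine(
    p1 = unname(params$tox_p1[track]), taper = params$taper,
    prost = is_prostatectomy_track(track), q = q,
    c_notox = params$c_notox, c_tox = params$c_tox,
    u_notox = params$u_notox, u_tox = params$u_tox,
    d_cost = params$d_cost, d_util = params$d_util,
    discounting = params$discounting_enabled, keep_trace = TRUE
  )
  build_trace(drop(eng$trace$s_no), drop(eng$trace$s_tox),
              drop(eng$trace$s_dead), drop(eng$trace$cum_tox), params, track)
}

# Death-probability schedule for cycles 1..T starting at params$start_age.
q_schedule <- function(params, life_table, max_cycles = NULL) {
  i0 <- match(params$start_age, life_table$age)
  if (is.na(i0)) {
    stop("start age ", params$start_age, " not present in the life table")
  }
  q <- life_table$q[i0:nrow(life_table)]
  if (!is.null(max_cycles)) {
    if (max_cycles < 1) stop("max_cycles must be >= 1")
    q <- q[seq_len(min(max_cycles, length(q)))]
  }
  q
}

#' @export
print.cohort_trace <- function(x, ...) {
  cat("Cohort trace, track ", attr(x, "track") %||% "?",
      ", ", nrow(x) - 1, " cycles, discounting ",
      if (isTRUE(attr(x, "discounting"))) "on" else "off", "\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 4))
  cat("  ...\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Patient-level microsimulation oracle
#'
#' Simulates `n` independent patients through the identical transition rules
#' as [run_cohort()] (death first, then toxicity; both absorbing) and returns
#' the empirical occupancy trace in the same `cohort_trace` layout. Used as a
#' Monte-Carlo cross-check of the deterministic cohort recursion.
#'
#' @inheritParams run_cohort
#' @param n number of simulated patients.
#' @param seed integer seed; randomness is local to this call.
#' @return a `cohort_trace` data frame of empirical occupancy fractions with
#'   accrual columns computed from them; attribute `n` records the sample
#'   size.
#' @export
microsimulate <- function(params, track, life_table, n, seed, max_cycles = NULL) {
  stopifnot(n >= 1)
  validate_parameters(params)
  validate_life_table(life_table)
  q <- q_schedule(params, life_table, max_cycles)
  horizon <- length(q)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  # states: 1 no-toxicity, 2 toxicity, 3 dead
  state <- rep(1L, n)
  s_no <- s_tox <- s_dead <- cum_tox <- numeric(horizon + 1)
  s_no[1] <- 1
  cum <- 0
  for (t in seq_len(horizon)) {
    alive <- state != 3L
    dies <- alive & (stats::runif(n) < q[t])
    state[dies] <- 3L
    pt <- toxicity_probability(params, track, t)
    at_risk <- state == 1L
    tox <- at_risk & (stats::runif(n) < pt)
    state[tox] <- 2L
    cum <- cum + sum(tox) / n
    s_no[t + 1] <- mean(state == 1L)
    s_tox[t + 1] <- mean(state == 2L)
    s_dead[t + 1] <- mean(state == 3L)
    cum_tox[t + 1] <- cum
  }
  out <- build_trace(s_no, s_tox, s_dead, cum_tox, params, track)
  attr(out, "n") <- n
  attr(out, "seed") <- seed
  out
}
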