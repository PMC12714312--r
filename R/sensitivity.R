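# One-way deterministic sensitivity analysis and probabilistic sensitivity
# analysis. Both operate on the full pipeline (decision tree -> Markov ->
# economics); the DSA outcome is the 5-year cumulative savings, the PSA
# records lifetime incremental cost and QALY pairs.

clip_prob <- function(x, name) {
  if (any(x < 0) || any(x > 1)) {
    warning("perturbed '", name, "' clipped to [0, 1]", call. = FALSE)
    x <- pmin(pmax(x, 0), 1)
  }
  x
}

# Perturb one SOC utilization share and renormalize the other two so the mix
# still sums to 1 and the parameter set stays valid. Used when the DSA is run
# with a user-supplied outcome evaluator that only accepts a parameter set.
set_soc_share <- function(params, modality, value) {
  value <- clip_prob(value, paste0("soc_utilization[", modality, "]"))
  s <- params$soc_utilization
  others <- setdiff(MODALITIES, modality)
  rem_old <- sum(s[others])
  rem_new <- 1 - value
  s[others] <- if (rem_old > 0) s[others] * rem_new / rem_old else rem_new / 2
  s[modality] <- value
  params$soc_utilization <- s
  params
}

set_tox_group <- function(params, tracks, value, name) {
  params$tox_p1[tracks] <- clip_prob(value, name)
  params
}

# The varied parameter set: every scalar model input plus the two scenario
# knobs. Each entry carries the base value and a setter that re-derives any
# dependent shares; Table-style rows are varied independently of one another
# (the SOC prostatectomy share does not propagate into the tested strata,
# which have their own rows).
dsa_parameters <- function(params) {
  setp <- function(field, prob = FALSE) {
    force(field); force(prob)
    function(p, v) {
      if (prob) v <- clip_prob(v, field)
      p[[field]] <- v
      p
    }
  }
  list(
    list(name = "p_high", base = params$p_high, set = setp("p_high", TRUE)),
    list(name = "soc_share_SBRT", base = unname(params$soc_utilization["SBRT"]),
         soc_modality = "SBRT",
         set = function(p, v) set_soc_share(p, "SBRT", v)),
    list(name = "soc_share_CFRT", base = unname(params$soc_utilization["CFRT"]),
         soc_modality = "CFRT",
         set = function(p, v) set_soc_share(p, "CFRT", v)),
    list(name = "soc_share_prostatectomy",
         base = unname(params$soc_utilization["prostatectomy"]),
         soc_modality = "prostatectomy",
         set = function(p, v) set_soc_share(p, "prostatectomy", v)),
    list(name = "prost_share_high", base = params$prost_share_high,
         set = setp("prost_share_high", TRUE)),
    list(name = "surgery_diversion", base = params$surgery_diversion,
         set = setp("surgery_diversion", TRUE)),
    list(name = "radiation_adherence", base = params$radiation_adherence,
         set = setp("radiation_adherence", TRUE)),
    list(name = "tox_p1_highrisk_SBRT", base = unname(params$tox_p1["T1"]),
         set = function(p, v) set_tox_group(p, "T1", v, "tox_p1_highrisk_SBRT")),
    list(name = "tox_p1_CFRT", base = unname(params$tox_p1["T2"]),
         set = function(p, v) set_tox_group(p, c("T2", "T5", "T8"), v, "tox_p1_CFRT")),
    list(name = "tox_p1_prostatectomy", base = unname(params$tox_p1["T3"]),
         set = function(p, v) set_tox_group(p, c("T3", "T6", "T9"), v,
                                            "tox_p1_prostatectomy")),
    list(name = "tox_p1_lowrisk_SBRT", base = unname(params$tox_p1["T4"]),
         set = function(p, v) set_tox_group(p, "T4", v, "tox_p1_lowrisk_SBRT")),
    list(name = "tox_p1_SOC_SBRT", base = unname(params$tox_p1["T7"]),
         set = function(p, v) set_tox_group(p, "T7", v, "tox_p1_SOC_SBRT")),
    list(name = "taper", base = params$taper,
         set = function(p, v) { p$taper <- min(max(v, 1e-9), 1); p }),
    list(name = "u_notox", base = params$u_notox, set = setp("u_notox", TRUE)),
    list(name = "u_tox", base = params$u_tox, set = setp("u_tox", TRUE)),
    list(name = "d_cost", base = params$d_cost, set = setp("d_cost", TRUE)),
    list(name = "d_util", base = params$d_util, set = setp("d_util", TRUE)),
    list(name = "c_SBRT", base = unname(params$c_treat["SBRT"]),
         set = function(p, v) { p$c_treat["SBRT"] <- v; p }),
    list(name = "c_CFRT", base = unname(params$c_treat["CFRT"]),
         set = function(p, v) { p$c_treat["CFRT"] <- v; p }),
    list(name = "c_prostatectomy", base = unname(params$c_treat["prostatectomy"]),
         set = function(p, v) { p$c_treat["prostatectomy"] <- v; p }),
    list(name = "c_test", base = params$c_test, set = setp("c_test")),
    list(name = "c_notox", base = params$c_notox, set = setp("c_notox")),
    list(name = "c_tox", base = params$c_tox, set = setp("c_tox"))
  )
}

#' One-way deterministic sensitivity analysis (tornado)
#'
#' Varies each model parameter alone by the relative `delta` in both
#' directions (probabilities and utilities are clipped to \[0, 1\] with a
#' warning), recomputes the outcome through the full pipeline, and ranks
#' parameters by the width of the resulting outcome range. The default
#' outcome is the 5-year cumulative savings of the assay-guided arm vs SOC.
#'
#' Each input row is varied independently of the others, spreadsheet-style:
#' a perturbed SOC utilization share leaves the other two utilization rows
#' at their base values (the arm mix is used as-is, not renormalized), and
#' it does not propagate into the tested strata, whose prostatectomy shares
#' are their own rows. When a custom `outcome_fn` is supplied the SOC-share
#' rows fall back to renormalizing the remaining shares, since an arbitrary
#' evaluator only sees a validated parameter set.
#'
#' @param params a [model_parameters()] object.
#' @param delta relative perturbation in (0, 1); default
#'   `params$dsa_delta` (0.20).
#' @param life_table background mortality passed to the pipeline.
#' @param outcome_fn function of a parameter set returning the scalar
#'   outcome; default 5-year savings.
#' @return a data frame of class `dsa_result`, one row per parameter with
#'   `base_value`, `low_value`, `high_value`, `outcome_low`, `outcome_high`
#'   and `range`, sorted by descending range; the base-case outcome is the
#'   attribute `base_outcome`.
#' @export
#' @examples
#' \donttest{
#' dsa <- run_dsa(model_parameters())
#' head(dsa, 3)
#' }
run_dsa <- function(params, delta = params$dsa_delta,
                    life_table = default_life_table(),
                    outcome_fn = NULL) {
  stopifnot(delta >= 0, delta < 1)
  validate_parameters(params)
  default_eval <- is.null(outcome_fn)
  if (default_eval) {
    outcome_fn <- function(p) five_year_savings(p, life_table)
  }
  base_outcome <- outcome_fn(params)
  specs <- dsa_parameters(params)
  rows <- lapply(specs, function(sp) {
    lo <- sp$base * (1 - delta)
    hi <- sp$base * (1 + delta)
    if (default_eval && !is.null(sp$soc_modality)) {
      eval_at <- function(v) {
        s <- params$soc_utilization
        s[sp$soc_modality] <- clip_prob(v, sp$name)
        five_year_savings(params, life_table, soc_shares = s)
      }
      out_lo <- eval_at(lo)
      out_hi <- eval_at(hi)
    } else {
      out_lo <- outcome_fn(sp$set(params, lo))
      out_hi <- outcome_fn(sp$set(params, hi))
    }
    data.frame(parameter = sp$name, base_value = sp$base,
               low_value = lo, high_value = hi,
               outcome_low = out_lo, outcome_high = out_hi,
               range = abs(out_hi - out_lo))
  })
  res <- do.call(rbind, rows)
  res <- res[order(-res$range), , drop = FALSE]
  rownames(res) <- NULL
  structure(res, class = c("dsa_result", "data.frame"),
            base_outcome = base_outcome, delta = delta)
}

#' Moment-matched distribution for a PSA parameter
#'
#' Calibrates the sampling distribution used in the probabilistic
#' sensitivity analysis so that its mean and standard error match the
#' specification: gamma (`shape = (mean/se)^2`, `scale = se^2/mean`) for
#' non-negative costs, beta (`alpha = mean * (mean(1-mean)/se^2 - 1)`,
#' `beta = alpha * (1-mean)/mean`) for quantities bounded in \[0, 1\], or a
#' point mass for fixed parameters.
#'
#' @param spec list with `name`, `family` (`"gamma"`, `"beta"` or
#'   `"fixed"`), `mean` and `se`.
#' @return the spec augmented with the internal distribution parameters
#'   (`shape`/`scale` or `alpha`/`beta`).
#' @export
#' @examples
#' calibrate_distribution(list(name = "c", family = "gamma", mean = 100, se = 10))
calibrate_distribution <- function(spec) {
  stopifnot(is.list(spec), spec$family %in% c("gamma", "beta", "fixed"))
  if (spec$family == "fixed") return(spec)
  if (!is.numeric(spec$se) || spec$se <= 0) {
    stop("parameter '", spec$name, "': SE must be > 0 unless fixed")
  }
  if (spec$family == "gamma") {
    if (spec$mean <= 0) stop("parameter '", spec$name, "': gamma mean must be > 0")
    spec$shape <- (spec$mean / spec$se)^2
    spec$scale <- spec$se^2 / spec$mean
  } else {
    m <- spec$mean
    if (m <= 0 || m >= 1) {
      stop("parameter '", spec$name, "': beta mean must lie in (0, 1)")
    }
    if (spec$se^2 >= m * (1 - m)) {
      stop("parameter '", spec$name, "': beta variance infeasible for mean ", m)
    }
    spec$alpha <- m * (m * (1 - m) / spec$se^2 - 1)
    spec$beta <- spec$alpha * (1 - m) / m
  }
  spec
}

draw_distribution <- function(spec, n) {
  spec <- calibrate_distribution(spec)
  switch(spec$family,
         fixed = rep(spec$mean, n),
         gamma = stats::rgamma(n, shape = spec$shape, scale = spec$scale),
         beta = stats::rbeta(n, spec$alpha, spec$beta))
}

#' Default PSA distribution specifications
#'
#' One spec per varied model input: beta for probabilities, shares,
#' utilities and the taper; gamma for costs; the adherence scenario knob
#' (mean 1, no feasible beta variance) and the discount rates are held
#' fixed. Standard errors default to `psa_default_se_frac` (10\%) of the
#' mean, the stated fallback where no error datum exists.
#'
#' @param params a [model_parameters()] object.
#' @return list of distribution specs consumable by [run_psa()].
#' @export
psa_default_specs <- function(params) {
  sef <- params$psa_default_se_frac
  beta_spec <- function(name, mean) {
    list(name = name, family = "beta", mean = mean, se = sef * mean)
  }
  gamma_spec <- function(name, mean) {
    list(name = name, family = "gamma", mean = mean, se = sef * mean)
  }
  fixed_spec <- function(name, mean) {
    list(name = name, family = "fixed", mean = mean, se = 0)
  }
  list(
    beta_spec("p_high", params$p_high),
    beta_spec("soc_share_SBRT", unname(params$soc_utilization["SBRT"])),
    beta_spec("soc_share_CFRT", unname(params$soc_utilization["CFRT"])),
    beta_spec("soc_share_prostatectomy",
              unname(params$soc_utilization["prostatectomy"])),
    beta_spec("prost_share_high", params$prost_share_high),
    beta_spec("surgery_diversion", params$surgery_diversion),
    fixed_spec("radiation_adherence", params$radiation_adherence),
    beta_spec("tox_p1_highrisk_SBRT", unname(params$tox_p1["T1"])),
    beta_spec("tox_p1_CFRT", unname(params$tox_p1["T2"])),
    beta_spec("tox_p1_prostatectomy", unname(params$tox_p1["T3"])),
    beta_spec("tox_p1_lowrisk_SBRT", unname(params$tox_p1["T4"])),
    beta_spec("tox_p1_SOC_SBRT", unname(params$tox_p1["T7"])),
    beta_spec("taper", params$taper),
    beta_spec("u_notox", params$u_notox),
    beta_spec("u_tox", params$u_tox),
    fixed_spec("d_cost", params$d_cost),
    fixed_spec("d_util", params$d_util),
    gamma_spec("c_SBRT", unname(params$c_treat["SBRT"])),
    gamma_spec("c_CFRT", unname(params$c_treat["CFRT"])),
    gamma_spec("c_prostatectomy", unname(params$c_treat["prostatectomy"])),
    gamma_spec("c_test", params$c_test),
    gamma_spec("c_notox", params$c_notox),
    gamma_spec("c_tox", params$c_tox)
  )
}

#' Cost-effectiveness plane quadrant
#'
#' Classifies incremental (cost, QALY) pairs into the four quadrants of the
#' cost-effectiveness plane: `SE` (cheaper, more effective — dominant), `NE`
#' (dearer, more effective), `SW` (cheaper, less effective), `NW` (dearer,
#' less effective — dominated). Exact zeros are assigned to the adjacent
#' cost-effective side (zero cost difference counts as "cheaper", zero QALY
#' difference as "more effective").
#'
#' @param delta_cost incremental cost(s), USD.
#' @param delta_qalys incremental effectiveness, QALYs.
#' @return character vector of quadrant labels.
#' @export
#' @examples
#' classify_quadrant(c(-1, 1), c(0.1, -0.1))
classify_quadrant <- function(delta_cost, delta_qalys) {
  ifelse(delta_qalys >= 0,
         ifelse(delta_cost <= 0, "SE", "NE"),
         ifelse(delta_cost <= 0, "SW", "NW"))
}

#' Probabilistic sensitivity analysis
#'
#' Monte-Carlo re-evaluation of the lifetime cost-effectiveness comparison:
#' in each iteration every varied parameter is drawn independently from its
#' moment-matched distribution (see [psa_default_specs()]), the decision
#' tree, Markov cohort model and economic aggregation are re-run for both
#' arms against the fixed base-case life table, and the incremental lifetime
#' cost and QALYs are recorded with their cost-effectiveness-plane quadrant.
#' Draws are made parameter-major from a single seeded generator, so results
#' are reproducible bit-for-bit given the seed.
#'
#' @param params a [model_parameters()] object.
#' @param specs distribution specs; default [psa_default_specs()].
#' @param n iterations; default `params$psa_iterations` (10,000).
#' @param seed integer seed (randomness is local to this call).
#' @param life_table background mortality, held fixed across iterations.
#' @return an object of class `psa_result`: list with `n`, `seed`, `draws`
#'   (data frame of the sampled parameter values) and `results` (data frame
#'   `iteration`, `delta_cost`, `delta_qaly`, `quadrant`).
#' @export
#' @examples
#' psa <- run_psa(model_parameters(), n = 200, seed = 7)
#' mean(psa$results$quadrant == "SE")
run_psa <- function(params, specs = psa_default_specs(params),
                    n = params$psa_iterations, seed = 1,
                    life_table = default_life_table()) {
  stopifnot(n >= 1)
  validate_parameters(params)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  draws <- as.data.frame(lapply(specs, draw_distribution, n = n))
  names(draws) <- vapply(specs, `[[`, character(1), "name")
  g <- function(nm) {
    if (nm %in% names(draws)) draws[[nm]] else stop("missing draw: ", nm)
  }
  # decision tree, vectorised over iterations
  soc_tot <- g("soc_share_SBRT") + g("soc_share_CFRT") + g("soc_share_prostatectomy")
  soc <- list(SBRT = g("soc_share_SBRT") / soc_tot,
              CFRT = g("soc_share_CFRT") / soc_tot,
              prostatectomy = g("soc_share_prostatectomy") / soc_tot)
  adh <- g("radiation_adherence")
  ph <- g("p_high")
  prost_h <- g("prost_share_high")
  rad_h <- 1 - prost_h
  prost_l <- soc$prostatectomy * (1 - g("surgery_diversion"))
  rad_l <- 1 - prost_l
  w <- list(
    T1 = ph * (1 - adh) * rad_h, T2 = ph * adh * rad_h, T3 = ph * prost_h,
    T4 = (1 - ph) * adh * rad_l, T5 = (1 - ph) * (1 - adh) * rad_l,
    T6 = (1 - ph) * prost_l,
    T7 = soc$SBRT, T8 = soc$CFRT, T9 = soc$prostatectomy
  )
  p1_of <- c(T1 = "tox_p1_highrisk_SBRT", T2 = "tox_p1_CFRT",
             T3 = "tox_p1_prostatectomy", T4 = "tox_p1_lowrisk_SBRT",
             T5 = "tox_p1_CFRT", T6 = "tox_p1_prostatectomy",
             T7 = "tox_p1_SOC_SBRT", T8 = "tox_p1_CFRT",
             T9 = "tox_p1_prostatectomy")
  c_mod <- c(SBRT = "c_SBRT", CFRT = "c_CFRT", prostatectomy = "c_prostatectomy")
  q <- q_schedule(params, life_table)
  cost_arm <- list(PROSTOX = rep(0, n), SOC = rep(0, n))
  qaly_arm <- list(PROSTOX = rep(0, n), SOC = rep(0, n))
  for (i in seq_len(9)) {
    tk <- TRACKS$track[i]
    arm <- TRACKS$arm[i]
    if (all(w[[tk]] == 0)) next
    eng <- cohort_engine(
      p1 = g(p1_of[[tk]]), taper = g("taper"),
      prost = TRACKS$modality[i] == "prostatectomy", q = q,
      c_notox = g("c_notox"), c_tox = g("c_tox"),
      u_notox = g("u_notox"), u_tox = g("u_tox"),
      d_cost = mean(g("d_cost")), d_util = mean(g("d_util")),
      discounting = params$discounting_enabled
    )
    track_cost <- g(c_mod[[TRACKS$modality[i]]]) + eng$lifetime_cost
    cost_arm[[arm]] <- cost_arm[[arm]] + w[[tk]] * track_cost
    qaly_arm[[arm]] <- qaly_arm[[arm]] + w[[tk]] * eng$lifetime_qalys
  }
  cost_arm$PROSTOX <- cost_arm$PROSTOX + g("c_test")
  dC <- cost_arm$PROSTOX - cost_arm$SOC
  dE <- qaly_arm$PROSTOX - qaly_arm$SOC
  structure(list(
    n = n, seed = seed,
    draws = draws,
    results = data.frame(iteration = seq_len(n), delta_cost = dC,
                         delta_qaly = dE,
                         quadrant = classify_quadrant(dC, dE))
  ), class = "psa_result")
}

#' @export
print.psa_result <- function(x, ...) {
  cat("PSA: ", x$n, " iterations (seed ", x$seed, ")\n", sep = "")
  cat(sprintf("  mean delta cost  : $%s\n",
              format(round(mean(x$results$delta_cost)), big.mark = ",")))
  cat(sprintf("  mean delta QALYs : %.3f\n", mean(x$results$delta_qaly)))
  tab <- table(factor(x$results$quadrant, levels = c("SE", "NE", "SW", "NW")))
  cat("  quadrants        : ",
      paste(sprintf("%s %.1f%%", names(tab), 100 * tab / x$n), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay threshold, the probability that the
#' intervention is cost-effective: the fraction of PSA iterations with
#' non-negative net monetary benefit, `wtp * delta_qaly - delta_cost >= 0`.
#'
#' @param psa a [run_psa()] result.
#' @param wtp_grid increasing non-negative thresholds (USD/QALY).
#' @return data frame of class `ceac_curve` with columns `wtp` and
#'   `probability`.
#' @export
ceac <- function(psa, wtp_grid = seq(0, 150000, by = 5000)) {
  stopifnot(inherits(psa, "psa_result"), length(wtp_grid) >= 1,
            all(wtp_grid >= 0), !is.unsorted(wtp_grid))
  prob <- vapply(wtp_grid, function(l) {
    mean(l * psa$results$delta_qaly - psa$results$delta_cost >= 0)
  }, numeric(1))
  structure(data.frame(wtp = wtp_grid, probability = prob),
            class = c("ceac_curve", "data.frame"))
}
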