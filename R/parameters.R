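#' prostoxcea: decision-tree + Markov cost-effectiveness model of
#' toxicity-risk-guided radiation therapy in prostate cancer
#'
#' The package evaluates a germline microRNA assay that classifies prostate
#' cancer patients as high or low risk for late genitourinary (GU) toxicity
#' from stereotactic body radiation therapy (SBRT). The assay result steers
#' patients between SBRT, conventionally fractionated radiotherapy (CFRT) and
#' prostatectomy; each of the nine resulting treatment tracks feeds a
#' three-state (no-toxicity, toxicity, death) annual-cycle Markov cohort
#' model. Arm-level costs and quality-adjusted life-years (QALYs) are compared
#' between assay-guided care and standard of care (SOC) over a 5-year
#' cost-impact horizon and over the cohort lifetime.
#'
#' Start with [model_parameters()], [compute_track_weights()],
#' [evaluate_arms()] and [run_full_analysis()].
#'
#' @keywords internal
"_PACKAGE"

# Modality labels used throughout. Order is meaningful only for display.
MODALITIES <- c("SBRT", "CFRT", "prostatectomy")

# The nine decision-tree end nodes ("tracks"). T1-T6 belong to the
# assay-guided (PROSTOX) arm, T7-T9 to SOC. Prostatectomy tracks admit
# toxicity inflow only in cycle 1; radiation tracks taper from cycle 5.
TRACKS <- data.frame(
  track    = paste0("T", 1:9),
  arm      = c(rep("PROSTOX", 6), rep("SOC", 3)),
  stratum  = c("high", "high", "high", "low", "low", "low", NA, NA, NA),
  modality = rep(c("SBRT", "CFRT", "prostatectomy"), 3),
  stringsAsFactors = FALSE
)

track_modality <- function(track) {
  i <- match(track, TRACKS$track)
  if (anyNA(i)) stop("unknown track: ", paste(track[is.na(i)], collapse = ", "))
  TRACKS$modality[i]
}

is_prostatectomy_track <- function(track) {
  track_modality(track) == "prostatectomy"
}

#' Default model parameters
#'
#' Returns the complete clinical and economic input set of the base-case
#' analysis: the high-risk fraction of tested patients, per-arm modality
#' utilization shares, cycle-1 no-toxicity to toxicity transition
#' probabilities per track, the annual toxicity-development taper applied to
#' radiation tracks from cycle 5, health-state utilities, discount rates,
#' treatment and annual care costs (2024 USD), and simulation settings.
#'
#' @details
#' Scenario knobs beyond the printed inputs:
#' \describe{
#'   \item{`radiation_adherence`}{fraction of tested radiation patients who
#'     follow the modality recommended by their risk result (default 1:
#'     no high-risk patient receives SBRT, no low-risk patient CFRT).}
#'   \item{`surgery_diversion`}{reduction of the prostatectomy share among
#'     low-risk tested patients relative to SOC (default 0.80, i.e. the SOC
#'     share of about 49\% falls to about 10\%); diverted patients use SBRT.}
#'   \item{`prost_share_high`}{prostatectomy share among high-risk tested
#'     patients; defaults to the SOC prostatectomy share, but is kept as its
#'     own field so sensitivity analyses can vary the SOC share and the
#'     high-risk share independently.}
#'   \item{`discounting_enabled`}{both 3\% rates are listed as inputs and the
#'     lifetime QALY scale of the base case implies they are applied; set to
#'     `FALSE` to run fully undiscounted.}
#' }
#'
#' @param ... named overrides of any default field, e.g.
#'   `model_parameters(c_test = 10000)`.
#' @return A validated object of class `model_parameters` (a named list).
#' @export
#' @examples
#' p <- model_parameters()
#' p$p_high
#' model_parameters(c_test = 10000)$c_test
model_parameters <- function(...) {
  defaults <- list(
    p_high = 0.1872,
    soc_utilization = c(SBRT = 0.3830, CFRT = 0.1235, prostatectomy = 0.4935),
    prost_share_high = 0.4935,
    surgery_diversion = 0.80,
    radiation_adherence = 1.0,
    tox_p1 = c(T1 = 0.2778, T2 = 0.0396, T3 = 0.1189,
               T4 = 0.0124, T5 = 0.0396, T6 = 0.1189,
               T7 = 0.0499, T8 = 0.0396, T9 = 0.1189),
    taper = 0.7013,
    u_notox = 0.90,
    u_tox = 0.70,
    d_cost = 0.03,
    d_util = 0.03,
    discounting_enabled = TRUE,
    c_treat = c(SBRT = 20670.28, CFRT = 42642.68, prostatectomy = 97782.37),
    c_test = 4000.00,
    c_notox = 2914.90,
    c_tox = 5774.58,
    cohort_size = 10000L,
    start_age = 67L,
    cycle_length = 1,
    wtp_default = 100000,
    psa_iterations = 10000L,
    psa_default_se_frac = 0.10,
    dsa_delta = 0.20
  )
  overrides <- list(...)
  if (length(overrides)) {
    bad <- setdiff(names(overrides), names(defaults))
    if (length(bad)) {
      stop("unknown parameter field(s): ", paste(bad, collapse = ", "))
    }
    for (nm in names(overrides)) {
      if (is.list(defaults[[nm]]) || length(defaults[[nm]]) > 1) {
        # partial override of a named vector keeps unmentioned entries
        v <- defaults[[nm]]
        o <- unlist(overrides[[nm]])
        unknown <- setdiff(names(o), names(v))
        if (length(unknown)) {
          stop("unknown entries in '", nm, "': ", paste(unknown, collapse = ", "))
        }
        v[names(o)] <- o
        defaults[[nm]] <- v
      } else {
        defaults[[nm]] <- overrides[[nm]]
      }
    }
  }
  # canonical storage types, so configs round-trip bit-identically
  int_fields <- c("cohort_size", "start_age", "psa_iterations")
  for (nm in setdiff(names(defaults), c(int_fields, "discounting_enabled"))) {
    v <- defaults[[nm]]
    defaults[[nm]] <- stats::setNames(as.numeric(v), names(v))
  }
  for (nm in int_fields) defaults[[nm]] <- as.integer(defaults[[nm]])
  defaults$discounting_enabled <- as.logical(defaults$discounting_enabled)
  params <- structure(defaults, class = "model_parameters")
  validate_parameters(params)
  params
}

#' Validate a model parameter set
#'
#' Checks the structural invariants of the parameter set: probabilities,
#' utilities, shares and fractions in \[0, 1\]; SOC utilization shares summing
#' to 1 (within 1e-9); non-negative costs; taper in (0, 1]; positive cohort
#' size and cycle length. Errors name the offending field.
#'
#' @param params a `model_parameters` object (or compatible named list).
#' @return invisibly `TRUE`; stops with an informative error otherwise.
#' @export
validate_parameters <- function(params) {
  chk01 <- function(x, nm) {
    if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x > 1)) {
      stop("parameter '", nm, "' must lie in [0, 1]", call. = FALSE)
    }
  }
  chk01(params$p_high, "p_high")
  chk01(params$soc_utilization, "soc_utilization")
  if (!setequal(names(params$soc_utilization), MODALITIES)) {
    stop("parameter 'soc_utilization' must name ",
         paste(MODALITIES, collapse = ", "), call. = FALSE)
  }
  if (abs(sum(params$soc_utilization) - 1) > 1e-9) {
    stop("parameter 'soc_utilization' shares must sum to 1", call. = FALSE)
  }
  chk01(params$prost_share_high, "prost_share_high")
  chk01(params$surgery_diversion, "surgery_diversion")
  chk01(params$radiation_adherence, "radiation_adherence")
  chk01(params$tox_p1, "tox_p1")
  if (!setequal(names(params$tox_p1), TRACKS$track)) {
    stop("parameter 'tox_p1' must name tracks T1-T9", call. = FALSE)
  }
  if (!is.numeric(params$taper) || params$taper <= 0 || params$taper > 1) {
    stop("parameter 'taper' must lie in (0, 1]", call. = FALSE)
  }
  chk01(params$u_notox, "u_notox")
  chk01(params$u_tox, "u_tox")
  chk01(params$d_cost, "d_cost")
  chk01(params$d_util, "d_util")
  if (!is.logical(params$discounting_enabled) || is.na(params$discounting_enabled)) {
    stop("parameter 'discounting_enabled' must be TRUE or FALSE", call. = FALSE)
  }
  for (nm in c("c_treat", "c_test", "c_notox", "c_tox")) {
    x <- params[[nm]]
    if (!is.numeric(x) || anyNA(x) || any(x < 0)) {
      stop("parameter '", nm, "' must be a non-negative cost", call. = FALSE)
    }
  }
  if (!setequal(names(params$c_treat), MODALITIES)) {
    stop("parameter 'c_treat' must name ", paste(MODALITIES, collapse = ", "),
         call. = FALSE)
  }
  if (params$cohort_size < 1) stop("parameter 'cohort_size' must be >= 1", call. = FALSE)
  if (params$cycle_length <= 0) stop("parameter 'cycle_length' must be > 0", call. = FALSE)
  chk01(params$psa_default_se_frac, "psa_default_se_frac")
  invisible(TRUE)
}

#' @export
print.model_parameters <- function(x, ...) {
  cat("Model parameters (", length(unlist(x)), " values)\n", sep = "")
  cat("  tested high-risk fraction : ", x$p_high, "\n", sep = "")
  cat("  SOC utilization           : ",
      paste(sprintf("%s %.4f", names(x$soc_utilization), x$soc_utilization),
            collapse = ", "), "\n", sep = "")
  cat("  utilities (no-tox / tox)  : ", x$u_notox, " / ", x$u_tox, "\n", sep = "")
  cat("  discounting               : ",
      if (x$discounting_enabled) sprintf("on (%.2f%% costs, %.2f%% utilities)",
                                         100 * x$d_cost, 100 * x$d_util)
      else "off", "\n", sep = "")
  cat("  start age ", x$start_age, ", cohort ", x$cohort_size,
      ", cycle ", x$cycle_length, " y\n", sep = "")
  cat("  hash ", param_hash(x), "\n", sep = "")
  invisible(x)
}

#' Hash of a resolved parameter set
#'
#' Stable content hash of the numeric parameter values, used in logs and run
#' manifests so that outputs can be traced to the exact inputs.
#'
#' @param params a `model_parameters` object.
#' @return a character scalar.
#' @export
param_hash <- function(params) {
  rlang::hash(lapply(unclass(params), unname))
}

#' Load model parameters from a JSON configuration file
#'
#' The configuration is a flat JSON document whose fields mirror
#' [model_parameters()]; any omitted field falls back to its default. Named
#' mappings (`soc_utilization`, `tox_p1`, `c_treat`) may also be given
#' partially. Numeric fields round-trip bit-identically through
#' [save_config()].
#'
#' @param path path to a JSON configuration file.
#' @param quiet suppress the log message (source path and parameter hash).
#' @return a validated `model_parameters` object.
#' @export
load_config <- function(path, quiet = FALSE) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.list(raw)) stop("config must be a JSON object")
  params <- do.call(model_parameters, raw)
  if (!quiet) {
    message("loaded parameters from ", path, " [hash ", param_hash(params), "]")
  }
  params
}

#' Save model parameters to a JSON configuration file
#'
#' @param params a `model_parameters` object.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
save_config <- function(params, path) {
  validate_parameters(params)
  ready <- lapply(unclass(params), function(x) {
    if (length(x) > 1 && !is.null(names(x))) as.list(x) else x
  })
  jsonlite::write_json(ready, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
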