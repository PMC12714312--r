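#' Per-stratum treatment utilization shares
#'
#' Derives the modality mix (SBRT / CFRT / prostatectomy) within one risk
#' stratum of the assay-guided arm.
#'
#' High-risk patients keep the SOC-scale prostatectomy share
#' (`prost_share_high`); the radiation remainder is steered away from SBRT,
#' so with full adherence it all goes to CFRT. Low-risk patients see the
#' prostatectomy share reduced by `surgery_diversion` (diverted patients use
#' SBRT); the radiation remainder is steered away from CFRT, so with full
#' adherence it all goes to SBRT. A non-adherent radiation patient stays on
#' the modality SOC would have favoured for that stratum (SBRT if high risk,
#' CFRT if low risk).
#'
#' @param params a [model_parameters()] object.
#' @param stratum `"high"` or `"low"`.
#' @return named numeric vector of shares over `SBRT`, `CFRT`,
#'   `prostatectomy`, summing to 1.
#' @export
#' @examples
#' derive_stratum_utilization(model_parameters(), "high")
#' derive_stratum_utilization(model_parameters(), "low")
derive_stratum_utilization <- function(params, stratum = c("high", "low")) {
  stratum <- match.arg(stratum)
  adh <- params$radiation_adherence
  if (stratum == "high") {
    prost <- params$prost_share_high
    rad <- 1 - prost
    c(SBRT = (1 - adh) * rad, CFRT = adh * rad, prostatectomy = prost)
  } else {
    prost <- unname(params$soc_utilization["prostatectomy"]) *
      (1 - params$surgery_diversion)
    rad <- 1 - prost
    c(SBRT = adh * rad, CFRT = (1 - adh) * rad, prostatectomy = prost)
  }
}

#' Decision-tree track weights for one arm
#'
#' Maps the decision tree onto the nine treatment tracks. In the assay-guided
#' arm the high-risk fraction `p_high` is distributed over T1-T3 by the
#' high-stratum utilization and the remainder over T4-T6 by the low-stratum
#' utilization; SOC puts its population on T7-T9 according to the literature
#' utilization shares. Tracks belonging to the other arm carry weight zero.
#'
#' @param params a [model_parameters()] object.
#' @param arm `"PROSTOX"` (assay-guided) or `"SOC"`.
#' @return an object of class `track_weights`: list with `arm` and a named
#'   numeric `weights` vector over T1-T9 summing to 1.
#' @export
#' @examples
#' w <- compute_track_weights(model_parameters(), "PROSTOX")
#' round(100 * w$weights, 2)
compute_track_weights <- function(params, arm = c("PROSTOX", "SOC")) {
  arm <- match.arg(arm)
  validate_parameters(params)
  w <- stats::setNames(numeric(9), TRACKS$track)
  if (arm == "PROSTOX") {
    high <- derive_stratum_utilization(params, "high")
    low <- derive_stratum_utilization(params, "low")
    w[c("T1", "T2", "T3")] <- params$p_high * high[MODALITIES]
    w[c("T4", "T5", "T6")] <- (1 - params$p_high) * low[MODALITIES]
  } else {
    w[c("T7", "T8", "T9")] <- params$soc_utilization[MODALITIES]
  }
  structure(list(arm = arm, weights = w), class = "track_weights")
}

#' @export
print.track_weights <- function(x, ...) {
  cat("Track weights, arm ", x$arm, "\n", sep = "")
  nz <- x$weights[x$weights > 0]
  for (t in names(nz)) {
    cat(sprintf("  %s (%s): %6.2f%%\n", t, track_modality(t), 100 * nz[t]))
  }
  invisible(x)
}

#' Treatment-modality shares implied by track weights
#'
#' Collapses track weights by treatment modality, e.g. to report the total
#' fraction of an arm receiving SBRT.
#'
#' @param weights a [compute_track_weights()] result.
#' @return named numeric vector over `SBRT`, `CFRT`, `prostatectomy`,
#'   summing to 1.
#' @export
modality_shares <- function(weights) {
  stopifnot(inherits(weights, "track_weights"))
  out <- vapply(MODALITIES, function(m) {
    sum(weights$weights[TRACKS$track[TRACKS$modality == m]])
  }, numeric(1))
  out
}
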