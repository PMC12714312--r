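# Background mortality. The model needs an age-indexed schedule of annual
# death probabilities q(x); none is bundled with the published inputs, so the
# default is a synthetic Gompertz-Makeham table calibrated to a target life
# expectancy at the cohort entry age. Users can substitute a real life table
# CSV (columns age,q) via load_life_table().

#' Gompertz-Makeham annual death probabilities
#'
#' Annual probability of death at integer age x under the Gompertz-Makeham
#' hazard \eqn{h(x) = \lambda + a e^{b x}}, converted to a one-year
#' probability \eqn{q(x) = 1 - \exp(-h(x))}.
#'
#' @param age integer vector of ages (years).
#' @param lambda Makeham age-independent hazard component (per year, >= 0).
#' @param a Gompertz scale (per year, > 0).
#' @param b Gompertz shape (per year, > 0).
#' @return numeric vector of probabilities in \[0, 1\], non-decreasing in age.
#' @export
gompertz_makeham_q <- function(age, lambda = 0, a = 5e-5, b = 0.095) {
  if (lambda < 0 || a <= 0 || b <= 0) {
    stop("require lambda >= 0, a > 0, b > 0")
  }
  1 - exp(-(lambda + a * exp(b * age)))
}

#' Generate a synthetic life table
#'
#' Builds a life table from `start_age` to `terminal_age` using the
#' Gompertz-Makeham hazard; the terminal age is forced to q = 1 so that the
#' cohort is fully absorbed into death by the end of the horizon.
#'
#' @param start_age first age in the table (years).
#' @param terminal_age last age; its q is set to 1 (default 110).
#' @inheritParams gompertz_makeham_q
#' @return a data frame of class `life_table` with columns `age` and `q`.
#' @export
#' @examples
#' lt <- generate_life_table(67)
#' head(lt)
generate_life_table <- function(start_age = 67, terminal_age = 110,
                                lambda = 0, a = 5e-5, b = 0.095) {
  stopifnot(terminal_age > start_age)
  age <- seq(start_age, terminal_age)
  q <- gompertz_makeham_q(age, lambda, a, b)
  q[length(q)] <- 1
  structure(data.frame(age = age, q = q),
            class = c("life_table", "data.frame"))
}

validate_life_table <- function(lt) {
  if (!all(c("age", "q") %in% names(lt))) stop("life table needs columns age, q")
  if (any(diff(lt$age) != 1)) stop("life-table ages must increase by exactly 1")
  if (any(lt$q < 0 | lt$q > 1)) stop("life-table q must lie in [0, 1]")
  if (lt$q[nrow(lt)] != 1) stop("life table must end with a terminal q = 1")
  invisible(TRUE)
}

#' Load a life table from CSV
#'
#' @param path CSV with header `age,q`: integer ages increasing by one and
#'   annual death probabilities, ending in a terminal q = 1.
#' @return a `life_table` data frame.
#' @export
load_life_table <- function(path) {
  if (!file.exists(path)) stop("life-table file not found: ", path)
  lt <- utils::read.csv(path)
  validate_life_table(lt)
  structure(lt, class = c("life_table", "data.frame"))
}

#' Undiscounted life expectancy implied by a life table
#'
#' Curtate expectation from the first tabulated age: the sum over cycles of
#' the probability of being alive at the end of each annual cycle,
#' \eqn{\sum_t \prod_{k \le t} (1 - q_k)}.
#'
#' @param life_table a `life_table` data frame.
#' @return expected whole years of remaining life (numeric scalar).
#' @export
life_expectancy <- function(life_table) {
  validate_life_table(life_table)
  sum(cumprod(1 - life_table$q))
}

#' Calibrate a synthetic life table to a target life expectancy
#'
#' One-dimensional root finding on the Gompertz scale `a` (with `b` fixed and
#' no Makeham term) so that the undiscounted life expectancy at `start_age`
#' hits `target_le`. Deterministic; the same target always yields the same
#' table.
#'
#' @param target_le target undiscounted life expectancy at `start_age`
#'   (years).
#' @param start_age cohort entry age.
#' @param terminal_age end of the table (q forced to 1).
#' @param b fixed Gompertz shape.
#' @param tol calibration tolerance on life expectancy (years).
#' @return a `life_table` data frame with attributes `a` and `target_le`.
#' @export
#' @examples
#' lt <- calibrate_life_table(16.5, 67)
#' life_expectancy(lt)
calibrate_life_table <- function(target_le, start_age = 67,
                                 terminal_age = 110, b = 0.095, tol = 0.01) {
  le_of <- function(log_a) {
    life_expectancy(generate_life_table(start_age, terminal_age,
                                        lambda = 0, a = exp(log_a), b = b))
  }
  lo <- log(1e-9); hi <- log(0.5)
  if (target_le > le_of(lo) || target_le < le_of(hi)) {
    stop("target life expectancy ", target_le,
         " is outside the achievable range at age ", start_age)
  }
  root <- stats::uniroot(function(x) le_of(x) - target_le,
                         lower = lo, upper = hi, tol = 1e-10)
  a <- exp(root$root)
  lt <- generate_life_table(start_age, terminal_age, lambda = 0, a = a, b = b)
  if (abs(life_expectancy(lt) - target_le) > tol) {
    stop("calibration failed to reach the target within ", tol, " years")
  }
  attr(lt, "a") <- a
  attr(lt, "target_le") <- target_le
  lt
}

.pkg_cache <- new.env(parent = emptyenv())

#' Default background-mortality table
#'
#' The package's base-case life table: a synthetic Gompertz-Makeham schedule
#' calibrated so that undiscounted life expectancy at age 67 is 16.5 years
#' (a round figure consistent with US male period life expectancy at that
#' age). This is a documented stand-in — the base-case analysis does not
#' specify its mortality source — and can be replaced by any real life table
#' via [load_life_table()].
#'
#' @param start_age cohort entry age (years).
#' @param target_le calibration target (undiscounted years at `start_age`).
#' @return a `life_table` data frame.
#' @export
default_life_table <- function(start_age = 67, target_le = 16.5) {
  key <- paste0("lt_", start_age, "_", target_le)
  if (is.null(.pkg_cache[[key]])) {
    .pkg_cache[[key]] <- calibrate_life_table(target_le, start_age)
  }
  .pkg_cache[[key]]
}

#' Random valid parameter set
#'
#' Jitters the default parameters multiplicatively by uniform +/- `jitter`,
#' clips probabilities and utilities to \[0, 1\], keeps the taper in (0, 1],
#' and renormalizes the SOC utilization shares; the result always passes
#' [validate_parameters()]. Intended as fuel for property-style tests.
#'
#' @param seed integer seed (all randomness is local to this call).
#' @param jitter relative perturbation half-width in \[0, 0.5\].
#' @return a validated `model_parameters` object.
#' @export
random_parameter_set <- function(seed, jitter = 0.2) {
  stopifnot(jitter >= 0, jitter <= 0.5)
  rng <- function(n) stats::runif(n, 1 - jitter, 1 + jitter)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  p <- unclass(model_parameters())
  clip01 <- function(x) pmin(pmax(x, 0), 1)
  p$p_high <- clip01(p$p_high * rng(1))
  soc <- p$soc_utilization * rng(3)
  p$soc_utilization <- soc / sum(soc)
  p$prost_share_high <- clip01(p$prost_share_high * rng(1))
  p$surgery_diversion <- clip01(p$surgery_diversion * rng(1))
  p$radiation_adherence <- clip01(p$radiation_adherence * rng(1))
  p$tox_p1 <- clip01(p$tox_p1 * rng(9))
  p$taper <- min(max(p$taper * rng(1), 1e-6), 1)
  p$u_notox <- clip01(p$u_notox * rng(1))
  p$u_tox <- clip01(p$u_tox * rng(1))
  p$c_treat <- p$c_treat * rng(3)
  p$c_test <- p$c_test * rng(1)
  p$c_notox <- p$c_notox * rng(1)
  p$c_tox <- p$c_tox * rng(1)
  params <- structure(p, class = "model_parameters")
  validate_parameters(params)
  params
}
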