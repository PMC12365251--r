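# Dose-fraction mass-balance accounting and biokinetic summaries.

#' Percent of dose
#'
#' `100 * mass / dose`. Values above 100 % are legal (they occur in measured
#' data through counting noise) and are flagged via the `over_100` attribute.
#'
#' @param mass_ug Measured Pd mass (ug), vectorized.
#' @param dose_ug Applied or daily Pd dose (ug, > 0).
#' @return Percentages; attribute `over_100` marks entries exceeding 100.
#' @export
#' @examples
#' percent_of_dose(9.976, 9.976)  # 100
percent_of_dose <- function(mass_ug, dose_ug) {
  if (!(dose_ug > 0)) stop("dose_ug must be positive")
  pct <- 100 * mass_ug / dose_ug
  attr(pct, "over_100") <- pct > 100
  pct
}

#' Assemble a study ledger
#'
#' Collects the tables needed for recovery accounting: the dosing regimen,
#' per-organ measured masses (with method tag, unit and censoring status) and
#' the excretion time series.
#'
#' @param regimen A [dose_regimen()].
#' @param organ_masses Data frame with columns `mouse`, `organ`, `method`
#'   (`"XFI"`, `"ICPMS"` or `"IMC"`), `mass`, `unit` (`"ng"` or `"ug"`), and
#'   optionally `status` (censoring; default `"quantified"`).
#' @param excretion Data frame with columns `mouse` (or group), `time_h`,
#'   `pd_mass_ug`, `method`, optionally `status`.
#' @return Object of class `study_ledger`.
#' @export
study_ledger <- function(regimen, organ_masses = NULL, excretion = NULL) {
  stopifnot(inherits(regimen, "dose_regimen"))
  if (!is.null(organ_masses)) {
    need <- c("mouse", "organ", "method", "mass", "unit")
    if (!all(need %in% names(organ_masses)))
      stop("organ_masses must have columns: ", paste(need, collapse = ", "))
    if (!all(organ_masses$unit %in% c("ng", "ug")))
      stop("organ mass units must be 'ng' or 'ug'")
    if (is.null(organ_masses$status)) organ_masses$status <- "quantified"
  }
  if (!is.null(excretion)) {
    need <- c("mouse", "time_h", "pd_mass_ug")
    if (!all(need %in% names(excretion)))
      stop("excretion must have columns: ", paste(need, collapse = ", "))
    if (is.null(excretion$status)) excretion$status <- "quantified"
  }
  structure(list(regimen = regimen, organ_masses = organ_masses,
                 excretion = excretion),
            class = "study_ledger")
}

# Censored-value contribution used in all ledger sums: bdl -> 0, between ->
# the stored LOD value, quantified -> the value.
censored_contribution <- function(mass, status) {
  ifelse(status == "below_detection", 0, ifelse(is.na(mass), 0, mass))
}

#' Cumulative excretion curve
#'
#' Running sum of per-interval excreted masses converted to percent of dose.
#' Censored entries contribute per the ICP-MS accounting rule (bdl as 0,
#' between-LOD/LOQ as the LOD value already stored in the mass column).
#'
#' @param series Data frame with sorted `time_h` and per-interval
#'   `pd_mass_ug` (optionally `status`).
#' @param dose_ug Dose used as denominator (ug, > 0).
#' @return Data frame `time_h`, `cum_mass_ug`, `cum_pct`, `n_censored`.
#' @export
#' @examples
#' cumulative_excretion(data.frame(time_h = c(2, 4), pd_mass_ug = c(1, 2)), 10)
cumulative_excretion <- function(series, dose_ug) {
  if (!(dose_ug > 0)) stop("dose_ug must be positive")
  if (is.unsorted(series$time_h)) stop("time_h must be sorted")
  status <- if (is.null(series$status)) rep("quantified", nrow(series))
  else series$status
  contrib <- censored_contribution(series$pd_mass_ug, status)
  data.frame(time_h = series$time_h,
             cum_mass_ug = cumsum(contrib),
             cum_pct = 100 * cumsum(contrib) / dose_ug,
             n_censored = cumsum(status != "quantified"))
}

#' Total recovery of one mouse
#'
#' Sum of whole-organ percent-of-dose values for one mouse and one method.
#' Mixed units are rejected; censored rows are flagged in the result.
#'
#' @param ledger A `study_ledger` with `organ_masses`.
#' @param mouse Mouse id.
#' @param method Method tag to sum over (default `"ICPMS"`).
#' @return List: `recovery_pct`, `per_organ` (data frame `organ`, `pct`,
#'   `status`), `n_censored`.
#' @export
total_recovery <- function(ledger, mouse, method = "ICPMS") {
  stopifnot(inherits(ledger, "study_ledger"))
  om <- ledger$organ_masses
  rows <- om[om$mouse == mouse & om$method == method, , drop = FALSE]
  if (nrow(rows) == 0) stop("no rows for mouse ", mouse, " / method ", method)
  if (length(unique(rows$unit)) > 1)
    stop("mixed mass units for mouse ", mouse, "; convert before summing")
  mass_ug <- censored_contribution(rows$mass, rows$status)
  if (rows$unit[1] == "ng") mass_ug <- mass_ug / 1000
  pct <- as.numeric(percent_of_dose(mass_ug, ledger$regimen$daily_pd_mass_ug))
  list(recovery_pct = sum(pct),
       per_organ = data.frame(organ = rows$organ, pct = pct,
                              status = rows$status),
       n_censored = sum(rows$status != "quantified"))
}

#' Compare two treatment groups
#'
#' Unpaired Student's t-test with pooled variance (Welch's correction behind
#' `var_equal = FALSE`). Two groups with zero variance and equal means return
#' `t = 0, p = 1` by convention.
#'
#' @param values_a,values_b Numeric vectors, each of length >= 2.
#' @param var_equal Pool the variances (default `TRUE`).
#' @return List `t`, `p`, `df`, `mean_a`, `mean_b`.
#' @export
#' @examples
#' compare_groups(c(1, 2, 3), c(4, 5, 6))
compare_groups <- function(values_a, values_b, var_equal = TRUE) {
  if (length(values_a) < 2 || length(values_b) < 2)
    stop("each group needs n >= 2")
  if (stats::sd(values_a) == 0 && stats::sd(values_b) == 0) {
    if (mean(values_a) == mean(values_b))
      return(list(t = 0, p = 1,
                  df = length(values_a) + length(values_b) - 2,
                  mean_a = mean(values_a), mean_b = mean(values_b)))
    stop("both groups are constant with different means; t is undefined")
  }
  ht <- stats::t.test(values_a, values_b, var.equal = var_equal)
  list(t = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter),
       mean_a = mean(values_a), mean_b = mean(values_b))
}

#' Cross-method agreement on paired measurements
#'
#' Agreement statistics between two methods measured on the same samples:
#' per-pair ratios, mean relative difference
#' `mean((m2 - m1) / m1)`, and the concordance slope through the origin
#' `sum(m1 * m2) / sum(m1^2)`. Pairs with a censored member are excluded and
#' counted.
#'
#' @param paired Data frame with columns `sample`, `mass_method1`,
#'   `mass_method2`, optionally `status_method1`/`status_method2`.
#' @return List `slope`, `mean_relative_difference`, `ratio_mean`,
#'   `ratio_sd`, `n_pairs`, `n_excluded`.
#' @export
#' @examples
#' method_agreement(data.frame(sample = 1:3, mass_method1 = c(1, 2, 3),
#'                             mass_method2 = c(0.8, 1.6, 2.4)))
method_agreement <- function(paired) {
  need <- c("sample", "mass_method1", "mass_method2")
  if (!all(need %in% names(paired)))
    stop("paired must have columns: ", paste(need, collapse = ", "))
  s1 <- if (is.null(paired$status_method1)) "quantified" else paired$status_method1
  s2 <- if (is.null(paired$status_method2)) "quantified" else paired$status_method2
  ok <- s1 == "quantified" & s2 == "quantified" &
    is.finite(paired$mass_method1) & is.finite(paired$mass_method2) &
    paired$mass_method1 > 0
  n_excluded <- sum(!ok)
  p <- paired[ok, , drop = FALSE]
  if (nrow(p) < 3) stop("need >= 3 uncensored pairs; have ", nrow(p))
  ratio <- p$mass_method2 / p$mass_method1
  list(slope = sum(p$mass_method1 * p$mass_method2) / sum(p$mass_method1^2),
       mean_relative_difference =
         mean((p$mass_method2 - p$mass_method1) / p$mass_method1),
       ratio_mean = mean(ratio), ratio_sd = stats::sd(ratio),
       n_pairs = nrow(p), n_excluded = n_excluded)
}

#' Recover transit rates from observed transit/excretion curves
#'
#' Levenberg-Marquardt least-squares fit of the first-order chain rate
#' constants (single bolus, no systemic uptake) to observed compartment time
#' series. Any subset of the chain compartments (including `feces`) may be
#' supplied; residuals pool all provided columns. Fitting from the fecal
#' curve alone is supported but weakly identified: the fecal output of a
#' linear chain is nearly invariant under exchanges of the rate constants, so
#' individual rates are then only loosely constrained. Observing the
#' compartment curves themselves (as a GI-organ time series does) makes each
#' rate directly identifiable.
#'
#' @param observations Data frame with column `time_h` plus one column per
#'   observed compartment (`stomach`, `small_intestine`, `cecum`, `colon`,
#'   `feces`), masses in ug.
#' @param dose_ug Administered bolus (ug, > 0).
#' @param init Starting rates (1/h), length 4.
#' @return List `rates` (named, chain order), `deviance` (residual sum of
#'   squares), `converged`.
#' @export
fit_transit_rates <- function(observations, dose_ug,
                              init = c(1, 0.9, 0.6, 0.4)) {
  stopifnot(is.data.frame(observations), "time_h" %in% names(observations),
            dose_ug > 0, length(init) == 4)
  comp_names <- c("stomach", "small_intestine", "cecum", "colon", "feces")
  observed <- intersect(comp_names, names(observations))
  if (length(observed) == 0)
    stop("observations must contain at least one compartment column")
  times_h <- observations$time_h
  obs <- as.matrix(observations[observed])
  reg <- dose_regimen(1, dose_ug, schedule_h = 0)
  resid_fn <- function(logk) {
    k <- pmin(pmax(exp(logk), 1e-3), 50)  # keep the ODE well-conditioned
    names(k) <- comp_names[1:4]
    m <- simulate_biodistribution(reg, rates = k, uptake_fraction = 0,
                                  times_h = times_h)$masses
    as.vector(as.matrix(m[observed]) - obs)
  }
  fit <- minpack.lm::nls.lm(log(init), fn = resid_fn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 200, ftol = 1e-14, ptol = 1e-12))
  rates <- pmin(pmax(exp(fit$par), 1e-3), 50)
  names(rates) <- comp_names[1:4]
  list(rates = rates, deviance = fit$deviance,
       converged = fit$info %in% 1:4)
}
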