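#' Concentration-response and dose-response pharmacology
#'
#' Four-parameter logistic (4PL) fits of BRET concentration-response data
#' (Emax as percent of the reference agonist maximum, EC50/pEC50, Hill
#' slope), reference-agonist normalization, two-parameter log-logistic
#' ED50 estimation for percent-maximum-possible-effect (%MPE)
#' antinociception data, and the brain:plasma exposure ratio.
#'
#' @name pharmacology
NULL

#' Four-parameter logistic response
#'
#' `baseline + (emax - baseline) / (1 + 10^((log10(EC50) - log10(conc)) * hill))`
#' with `log10(EC50) = -pec50`: the response is half-maximal at the EC50
#' and approaches `emax` at saturating concentration.
#'
#' @param conc concentration, molar
#' @param emax maximal response (percent of reference)
#' @param pec50 -log10 molar EC50
#' @param hill Hill slope
#' @param baseline response at zero concentration
#' @export
fourpl <- function(conc, emax, pec50, hill = 1, baseline = 0) {
  baseline + (emax - baseline) / (1 + 10^((-pec50 - log10(conc)) * hill))
}

#' Fit a 4PL concentration-response model
#'
#' Nonlinear least squares with a multi-start over a pEC50 grid spanning
#' the observed concentration range (guarding against local minima), Hill
#' slope bounded in `hill_bounds`, and the baseline fixed at 0 by default,
#' the convention for agonist-mode data already normalized to a reference
#' agonist maximum. Standard errors come from the covariance at the
#' optimum; 95% CIs are Wald intervals. EC50 is reported in nM alongside
#' pEC50 (`ec50_nM = 10^(9 - pec50)`).
#'
#' An efficacy `status` field distinguishes `"ok"` from
#' `"no_detectable_activity"` (fitted span indistinguishable from noise:
#' the Emax CI includes 0, or the fitted span is below 3x the residual
#' noise estimate) and `"not_converged"`.
#'
#' @param data data frame with columns `conc_M` and `response_pct`
#' @param baseline fixed baseline (default 0); set `fix_baseline = FALSE`
#'   to estimate it
#' @param fix_baseline logical
#' @param hill_bounds length-2 bounds for the Hill slope
#' @param n_starts number of pEC50 grid starts
#' @return object of class `fit_4pl`: a list with `emax`, `pec50`,
#'   `ec50_nM`, `hill`, `baseline`, `se` (named), `ci` (named list of
#'   length-2 vectors), `sigma`, `converged`, `status`
#' @export
fit_4pl <- function(data, baseline = 0, fix_baseline = TRUE,
                    hill_bounds = c(0.3, 5), n_starts = 7L) {
  stopifnot(all(c("conc_M", "response_pct") %in% names(data)))
  conc <- data$conc_M
  resp <- data$response_pct
  if (any(conc <= 0)) stop("concentrations must be positive", call. = FALSE)
  if (length(unique(conc)) < 4L) {
    stop("need at least 4 distinct concentrations", call. = FALSE)
  }
  lc <- log10(conc)
  starts <- seq(min(lc), max(lc), length.out = n_starts)
  emax0 <- max(abs(resp)) * sign(stats::median(resp[rank(conc) > length(conc) / 2]))
  if (emax0 == 0) emax0 <- 1

  best <- NULL; best_ssr <- Inf
  for (s in starts) {
    fit <- tryCatch({
      if (fix_baseline) {
        minpack.lm::nlsLM(
          response_pct ~ fourpl(conc_M, emax, pec50, hill, baseline),
          data = data.frame(conc_M = conc, response_pct = resp),
          start = list(emax = emax0, pec50 = -s, hill = 1),
          lower = c(emax = -Inf, pec50 = -log10(max(conc)) - 3,
                    hill = hill_bounds[1]),
          upper = c(emax = Inf, pec50 = -log10(min(conc)) + 3,
                    hill = hill_bounds[2]),
          control = minpack.lm::nls.lm.control(maxiter = 200))
      } else {
        minpack.lm::nlsLM(
          response_pct ~ fourpl(conc_M, emax, pec50, hill, b0),
          data = data.frame(conc_M = conc, response_pct = resp),
          start = list(emax = emax0, pec50 = -s, hill = 1, b0 = 0),
          lower = c(emax = -Inf, pec50 = -log10(max(conc)) - 3,
                    hill = hill_bounds[1], b0 = -Inf),
          upper = c(emax = Inf, pec50 = -log10(min(conc)) + 3,
                    hill = hill_bounds[2], b0 = Inf),
          control = minpack.lm::nls.lm.control(maxiter = 200))
      }
    }, error = function(e) NULL)
    if (is.null(fit)) next
    ssr <- sum(stats::residuals(fit)^2)
    if (ssr < best_ssr) { best <- fit; best_ssr <- ssr }
  }

  if (is.null(best)) {
    return(structure(list(emax = NA_real_, pec50 = NA_real_,
                          ec50_nM = NA_real_, hill = NA_real_,
                          baseline = baseline, se = NULL, ci = NULL,
                          sigma = NA_real_, converged = FALSE,
                          status = "not_converged"),
                     class = "fit_4pl"))
  }
  cf <- stats::coef(best)
  se <- tryCatch(sqrt(diag(stats::vcov(best))), error = function(e) {
    stats::setNames(rep(NA_real_, length(cf)), names(cf))
  })
  sigma <- sqrt(best_ssr / max(1L, length(resp) - length(cf)))
  ci <- lapply(names(cf), function(p) cf[[p]] + c(-1, 1) * 1.96 * se[[p]])
  names(ci) <- names(cf)
  b0 <- if (fix_baseline) baseline else unname(cf["b0"])
  span <- abs(cf[["emax"]] - b0)
  status <- "ok"
  emax_ci <- ci[["emax"]]
  if ((is.finite(emax_ci[1]) && emax_ci[1] <= 0 && emax_ci[2] >= 0) ||
      span < 3 * sigma) {
    status <- "no_detectable_activity"
  }
  structure(list(emax = unname(cf["emax"]), pec50 = unname(cf["pec50"]),
                 ec50_nM = 10^(9 - unname(cf["pec50"])),
                 hill = unname(cf["hill"]), baseline = b0,
                 se = se, ci = ci, sigma = sigma,
                 converged = TRUE, status = status),
            class = "fit_4pl")
}

#' @export
print.fit_4pl <- function(x, ...) {
  cat("4PL fit (", x$status, ")\n", sep = "")
  if (x$converged) {
    cat(sprintf("  Emax  %.2f%%   pEC50 %.3f   EC50 %.1f nM   hill %.2f\n",
                x$emax, x$pec50, x$ec50_nM, x$hill))
  }
  invisible(x)
}

#' Normalize raw responses to a reference-agonist maximum
#'
#' `100 * raw / reference_max`. Values above 100 are allowed: a test
#' ligand may exceed the reference maximum.
#'
#' @param raw numeric raw responses
#' @param reference_max positive scalar, the reference agonist's maximum
#' @export
normalize_to_reference <- function(raw, reference_max) {
  if (!is.numeric(reference_max) || length(reference_max) != 1L ||
      reference_max <= 0) {
    stop("reference_max must be a positive scalar", call. = FALSE)
  }
  100 * raw / reference_max
}

#' Fit a two-parameter log-logistic ED50 model to %MPE data
#'
#' %MPE is bounded by definition, so the floor is fixed at 0 and the
#' ceiling at 100: `mpe = 100 / (1 + (ed50 / dose)^slope)`. The fit is
#' performed on log10(ED50); the 95% CI is a delta-method Wald interval on
#' log10(ED50) back-transformed to mg/kg (the method used is recorded in
#' the result).
#'
#' @param data data frame with columns `dose_mg_kg` and `mpe_pct`
#' @return list with `ed50`, `slope`, `ci` (length-2, mg/kg),
#'   `se_log10_ed50`, `ci_method`, `converged`
#' @export
fit_ed50 <- function(data) {
  stopifnot(all(c("dose_mg_kg", "mpe_pct") %in% names(data)))
  dose <- data$dose_mg_kg
  mpe <- data$mpe_pct
  if (any(dose <= 0)) stop("doses must be positive", call. = FALSE)
  if (length(unique(dose)) < 3L) stop("need at least 3 doses", call. = FALSE)
  rng <- range(mpe)
  if (diff(rng) < 1e-8 && (rng[1] <= 1e-8 || rng[1] >= 100 - 1e-8)) {
    stop("no intermediate response: all %MPE at the floor or ceiling",
         call. = FALSE)
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(
      mpe_pct ~ 100 / (1 + 10^(slope * (led50 - log10(dose_mg_kg)))),
      data = data.frame(dose_mg_kg = dose, mpe_pct = mpe),
      start = list(led50 = stats::median(log10(dose)), slope = 1),
      lower = c(led50 = log10(min(dose)) - 3, slope = 0.05),
      upper = c(led50 = log10(max(dose)) + 3, slope = 20),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(list(ed50 = NA_real_, slope = NA_real_, ci = c(NA_real_, NA_real_),
                se_log10_ed50 = NA_real_, ci_method = "delta_log10_ed50",
                converged = FALSE))
  }
  cf <- stats::coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit))), error = function(e) {
    stats::setNames(rep(NA_real_, length(cf)), names(cf))
  })
  led <- unname(cf["led50"])
  se_led <- unname(se["led50"])
  list(ed50 = 10^led, slope = unname(cf["slope"]),
       ci = 10^(led + c(-1, 1) * 1.96 * se_led),
       se_log10_ed50 = se_led, ci_method = "delta_log10_ed50",
       converged = TRUE)
}

#' Brain:plasma exposure ratio
#'
#' @param brain brain concentration (same units as plasma, e.g. uM)
#' @param plasma plasma concentration, must be positive
#' @return list with `ratio` (full precision) and `ratio_1dp` (rounded to
#'   1 decimal, the reporting convention)
#' @export
brain_plasma_ratio <- function(brain, plasma) {
  if (!is.numeric(plasma) || plasma <= 0) {
    stop("plasma concentration must be positive", call. = FALSE)
  }
  if (brain < 0) stop("brain concentration must be nonnegative", call. = FALSE)
  r <- brain / plasma
  list(ratio = r, ratio_1dp = round(r, 1))
}
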