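#' Symmetric prediction error
#'
#' `PE = (Y_OBS - Y_PRED) / ((Y_OBS + Y_PRED) / 2)`: the difference relative
#' to the mean of observation and prediction, bounded in \[-2, 2\] and
#' antisymmetric under exchange of the two arguments.
#'
#' @param obs,pred observed and predicted concentrations (ng/mL), with
#'   `obs + pred > 0` elementwise.
#' @return Unitless prediction errors.
#' @examples
#' prediction_error(3, 1)  # 1
#' @export
prediction_error <- function(obs, pred) {
  if (any(obs + pred <= 0))
    stop("prediction error undefined where obs + pred <= 0")
  (obs - pred) / ((obs + pred) / 2)
}

#' Symmetric mean absolute percentage error
#'
#' `SMAPE = 100 * mean(|PE|)` with the symmetric [prediction_error()];
#' bounded by 200%, symmetric in its arguments and invariant to a common
#' rescaling of observations and predictions.
#'
#' @param observations,predictions equal-length positive vectors (ng/mL).
#' @return SMAPE in percent.
#' @examples
#' smape(c(3, 1), c(1, 3))  # 100
#' @export
smape <- function(observations, predictions) {
  if (length(observations) == 0) stop("smape of an empty vector is undefined")
  if (length(observations) != length(predictions))
    stop("observations and predictions must have equal length")
  mean(abs(prediction_error(observations, predictions))) * 100
}

#' Simulation-based 95% prediction interval
#'
#' Replicates the dosing regimen `n_reps` times; each replicate draws
#' subject-level parameters from the log-normal inter-individual model
#' ([iiv_realize()]) and a residual error realisation from the
#' [error_model()], then records the simulated (noisy) concentrations. The
#' bands are the empirical 2.5th, 50th and 97.5th percentiles per time point
#' and compartment, computed with linear interpolation between order
#' statistics (`stats::quantile` type 7), so they are reproducible
#' bit-for-bit for a given seed.
#'
#' @param structure,params,system model triple.
#' @param doses a [dose_event()] or list of them (the regimen).
#' @param times output time grid (min).
#' @param err an [error_model()], or `NULL` for no residual noise.
#' @param iiv named numeric vector of log-normal SDs per parameter name
#'   (e.g. `c(cl_pl = 0.49)`), or `NULL` for no inter-individual
#'   variability.
#' @param n_reps number of replicates (>= 2; 200 by default).
#' @param seed RNG seed.
#' @param compartments compartments to report (default: all enabled).
#' @param keep_sims also return the full replicate array.
#' @return An object of class `cns_bands`: data frame with `time`,
#'   `compartment`, `lo` (2.5%), `med` (50%), `hi` (97.5%); when
#'   `keep_sims = TRUE` the `rep x time x compartment` array is attached as
#'   attribute `"sims"`.
#' @export
simulate_prediction_interval <- function(structure, params, system, doses,
                                         times, err = NULL, iiv = NULL,
                                         n_reps = 200, seed = NULL,
                                         compartments = NULL,
                                         keep_sims = FALSE) {
  if (n_reps < 2) stop("n_reps must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(compartments))  # sampling sites, not disposition compartments
    compartments <- setdiff(structure$compartments, c("per1", "per2"))
  sims <- array(NA_real_, c(n_reps, length(times), length(compartments)),
                dimnames = list(NULL, NULL, compartments))
  for (r in seq_len(n_reps)) {
    p_r <- params
    if (!is.null(iiv))
      for (nm in names(iiv))
        p_r[[nm]] <- iiv_realize(params[[nm]], iiv[[nm]], 1)
    prof <- solve_profile(structure, p_r, system, doses, times)
    cc <- prof$conc[, compartments, drop = FALSE]
    if (!is.null(err)) {
      for (j in seq_along(compartments)) {
        s <- unname(err$sigma[compartments[j]])
        if (is.na(s)) s <- 0
        eps <- stats::rnorm(length(times), 0, s)
        cc[, j] <- cc[, j] * (1 + eps)
        if (err$kind == "mixed")
          cc[, j] <- cc[, j] + stats::rnorm(length(times), 0, err$sigma_add)
      }
    }
    sims[r, , ] <- cc
  }
  qs <- apply(sims, c(2, 3), stats::quantile,
              probs = c(0.025, 0.5, 0.975), type = 7, names = FALSE)
  out <- data.frame(
    time = rep(times, length(compartments)),
    compartment = rep(compartments, each = length(times)),
    lo = as.vector(qs[1, , ]), med = as.vector(qs[2, , ]),
    hi = as.vector(qs[3, , ]), stringsAsFactors = FALSE)
  class(out) <- c("cns_bands", "data.frame")
  if (keep_sims) attr(out, "sims") <- sims
  out
}

#' External validation against an independent dataset
#'
#' The external-validation workflow: (1) re-estimate the plasma-related
#' parameters (clearance, peripheral exchange, volumes) from the external
#' plasma data, (2) hold the brain-related parameters (BBB clearance,
#' dispersion flow, BCSFB/ICF exchange and the physiological volumes) fixed
#' at their previously estimated values, (3) predict the brain ECF / CSF
#' concentrations and score them with per-compartment SMAPE.
#'
#' @param plasma_data a `cns_study` containing only plasma observations.
#' @param brain_fixed a [drug_parameters()] object supplying the fixed
#'   brain-related parameters (`q_pl_ecf`, `q_diff` and, where enabled,
#'   `q_lv_pl`, `q_ecf_icf`) plus starting values for the plasma refit.
#' @param structure,system model structure and physiological volumes.
#' @param brain_obs a `cns_study` with the external brain/CSF observations.
#' @param ... passed to [fit_naive_pooled()] (e.g. `seed`, `n_starts`).
#' @return An object of class `cns_validation`: `plasma_fit` (`cns_fit`),
#'   `pe` (per-observation data frame with predictions and prediction
#'   errors), `smape` (named vector, % per compartment).
#' @export
external_validation <- function(plasma_data, brain_fixed, structure, system,
                                brain_obs, ...) {
  if (is.null(brain_obs) || !nrow(brain_obs$observations))
    stop("no external brain observations supplied")
  if (any(plasma_data$observations$compartment != "plasma"))
    stop("plasma_data must contain plasma observations only")
  brain_par <- c("q_pl_ecf", "q_diff", "q_lv_pl", "q_ecf_icf", "fraction",
                 grep("^theta_", .free_params(structure, brain_fixed,
                                              plasma_data), value = TRUE))
  fit <- fit_naive_pooled(plasma_data, structure, system, init = brain_fixed,
                          fixed = brain_par, ...)
  obs <- brain_obs$observations
  pred <- .predict_study(brain_obs, fit$params, structure, system)
  pe <- prediction_error(obs$conc, pred)
  sm <- vapply(split(seq_len(nrow(obs)), obs$compartment),
               function(i) smape(obs$conc[i], pred[i]), 0)
  structure(list(plasma_fit = fit,
                 pe = data.frame(obs[c("subject", "time", "compartment")],
                                 obs = obs$conc, pred = pred, pe = pe),
                 smape = sm),
            class = "cns_validation")
}

#' @export
print.cns_validation <- function(x, ...) {
  cat("External validation\n  SMAPE per compartment (%):\n")
  for (nm in names(x$smape)) cat(sprintf("    %-10s %.1f\n", nm, x$smape[nm]))
  invisible(x)
}
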