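#' Residual error model
#'
#' Proportional or mixed (proportional + additive) residual error on the
#' concentration scale: `C = pred * (1 + eps1) [+ eps2]`. One proportional
#' SD per observation stream (compartment label), a single additive SD for
#' the mixed model.
#'
#' @param sigma named numeric vector of proportional SDs per stream, e.g.
#'   `c(plasma = 0.341, brain_ecf = 1.88)`.
#' @param kind `"proportional"` or `"mixed"`.
#' @param sigma_add additive SD (ng/mL), required > 0 for `"mixed"`.
#' @return An object of class `cns_error`.
#' @export
error_model <- function(sigma, kind = c("proportional", "mixed"),
                        sigma_add = 0) {
  kind <- match.arg(kind)
  if (any(sigma < 0) || sigma_add < 0) stop("sigma values must be >= 0")
  if (kind == "mixed" && sigma_add <= 0)
    stop("the mixed error model requires sigma_add > 0")
  if (is.null(names(sigma))) stop("sigma must be named by observation stream")
  structure(list(kind = kind, sigma = sigma, sigma_add = sigma_add),
            class = "cns_error")
}

#' Categorical covariate effect on a transport parameter
#'
#' `P = P_PAT * (1 + theta * Cov)` with `Cov` 0/1 (e.g. presence of a
#' transporter inhibitor): `theta` is the fractional change of the net
#' transport parameter when the covariate is on.
#'
#' @param p_pat parameter value without the covariate (net transport).
#' @param theta_cov covariate coefficient, > -1.
#' @param cov covariate value (0 or 1).
#' @return The covariate-adjusted parameter.
#' @examples
#' apply_covariate(0.00458, 1.62, 1)  # morphine BBB clearance under P-gp block
#' @export
apply_covariate <- function(p_pat, theta_cov, cov) {
  if (any(p_pat <= 0)) stop("p_pat must be > 0")
  out <- p_pat * (1 + theta_cov * cov)
  if (any(out <= 0)) stop("covariate effect drove the parameter non-positive")
  out
}

#' Residual variance of an observation
#'
#' @param pred model-predicted concentration (ng/mL), >= 0.
#' @param error_model an [error_model()].
#' @param stream observation stream label used to pick the proportional SD;
#'   defaults to the first.
#' @return Variance (ng/mL)^2.
#' @examples
#' residual_variance(100, error_model(c(plasma = 0.3)))  # 900
#' @export
residual_variance <- function(pred, error_model, stream = NULL) {
  s <- if (is.null(stream)) error_model$sigma[[1]] else {
    if (!stream %in% names(error_model$sigma))
      stop(sprintf("no sigma for stream '%s'", stream))
    error_model$sigma[[stream]]
  }
  v <- s^2 * pred^2
  if (error_model$kind == "mixed") v <- v + error_model$sigma_add^2
  v
}

# Covariate-adjusted parameters for one subject (arm). INHIBITOR covariates
# switch on with the subject's inhibitor flag; DOSEGRP<g> covariates switch
# on when the subject's dose-group label equals <g>.
.subject_params <- function(params, inhibitor = 0, dosegrp = "") {
  tc <- params$theta_cov
  if (is.null(tc) || !nrow(tc)) return(params)
  for (i in seq_len(nrow(tc))) {
    cov <- if (tc$covariate[i] == "INHIBITOR") {
      as.numeric(inhibitor)
    } else if (startsWith(tc$covariate[i], "DOSEGRP")) {
      as.numeric(sub("DOSEGRP", "", tc$covariate[i]) == dosegrp)
    } else stop(sprintf("unknown covariate '%s'", tc$covariate[i]))
    if (cov != 0)
      params[[tc$parameter[i]]] <-
        apply_covariate(params[[tc$parameter[i]]], tc$theta[i], cov)
  }
  params
}

# Model predictions aligned with dataset$observations. Subjects sharing
# dose regimen, covariate arm and sampling grid are solved once.
.predict_study <- function(dataset, params, structure, system) {
  obs <- dataset$observations
  if (!nrow(obs)) stop("dataset contains no observations")
  first <- !duplicated(obs$subject)
  arm <- data.frame(subject = obs$subject[first],
                    inhibitor = obs$inhibitor[first],
                    dosegrp = obs$dosegrp[first], stringsAsFactors = FALSE)
  dose_key <- vapply(dataset$doses[arm$subject], function(dl)
    paste(vapply(dl, function(d)
      sprintf("%g/%g/%g", d$amount, d$duration, d$start), ""),
      collapse = ";"), "")
  arm$key <- paste(dose_key, arm$inhibitor, arm$dosegrp, sep = "|")
  key_of <- setNames(arm$key, arm$subject)
  pred <- numeric(nrow(obs))
  for (k in unique(arm$key)) {
    subj <- arm$subject[arm$key == k]
    rows <- obs$subject %in% subj
    tt <- sort(unique(obs$time[rows]))
    p_i <- .subject_params(params, arm$inhibitor[arm$key == k][1],
                           arm$dosegrp[arm$key == k][1])
    prof <- solve_profile(structure, p_i, system,
                          dataset$doses[[subj[1]]], tt)
    idx <- cbind(match(obs$time[rows], tt),
                 match(obs$compartment[rows], prof$compartments))
    if (anyNA(idx[, 2]))
      stop(sprintf("observation in compartment absent from the model: %s",
                   paste(unique(obs$compartment[rows][is.na(idx[, 2])]),
                         collapse = ", ")))
    p <- prof$conc[idx]
    unb <- obs$compartment[rows] == "plasma" & obs$assay[rows] == "unbound"
    p[unb] <- p[unb] * params$f_p
    pred[rows] <- p
  }
  if (any(!is.finite(pred))) {
    bad <- which(!is.finite(pred))[1]
    stop(sprintf("non-finite prediction for subject %s at t = %g min (%s)",
                 obs$subject[bad], obs$time[bad], obs$compartment[bad]))
  }
  pred
}

#' Extended least squares objective function
#'
#' Naive-pooled ELS objective: `OFV = sum over observations of
#' (Y_OBS - Y_PRED)^2 / var + log(var)`, with `var` from the residual error
#' model. This equals -2 log likelihood up to an additive constant under a
#' normal residual model with mean `Y_PRED` and the stated variance. No
#' per-subject random effects enter (naive pooling). Variances are floored
#' at `(1e-6 * max(Y_OBS))^2` so predictions approaching zero cannot drive
#' `log(var)` to minus infinity.
#'
#' @param dataset a `cns_study` from [assemble_dataset()].
#' @param params a [drug_parameters()] object.
#' @param error_model an [error_model()] covering every observed stream.
#' @param structure a [model_structure()].
#' @param system a [system_parameters()].
#' @return The scalar OFV.
#' @export
els_objective <- function(dataset, params, error_model, structure, system) {
  obs <- dataset$observations
  pred <- .predict_study(dataset, params, structure, system)
  v <- vapply(seq_len(nrow(obs)), function(i)
    residual_variance(pred[i], error_model, obs$compartment[i]), 0)
  floor <- (1e-6 * max(obs$conc))^2
  v <- pmax(v, floor)
  sum((obs$conc - pred)^2 / v + log(v))
}

# Concentrated ELS objective for the proportional error model: for each
# stream the maximising sigma^2 has the closed form mean(res^2 / pred^2),
# giving OFV_s = n_s (1 + log sigma_s^2) + sum log pred^2. Returns the OFV
# with the profiled sigmas as an attribute.
.els_concentrated <- function(dataset, params, structure, system) {
  obs <- dataset$observations
  pred <- .predict_study(dataset, params, structure, system)
  floor <- (1e-6 * max(obs$conc))^2
  w <- pmax(pred^2, floor)
  z <- (obs$conc - pred)^2 / w
  ofv <- 0
  sig <- c()
  for (s in unique(obs$compartment)) {
    i <- obs$compartment == s
    s2 <- max(mean(z[i]), 1e-12)
    ofv <- ofv + sum(i) * (1 + log(s2)) + sum(log(w[i]))
    sig[s] <- sqrt(s2)
  }
  attr(ofv, "sigma") <- sig
  ofv
}

# Default free-parameter set for a structure, plus any covariate
# coefficients whose covariate actually varies in the data.
.free_params <- function(structure, params, dataset, fixed = character(0)) {
  cand <- c("cl_pl", "q_pl_ecf", "q_diff", "v_pl",
            if (structure$per1) c("q_pl_per1", "v_per1"),
            if (structure$per2) c("q_pl_per2", "v_per2"),
            if (structure$bcsfb_efflux_enabled) "q_lv_pl",
            if (structure$icf_enabled) "q_ecf_icf")
  tc <- params$theta_cov
  thetas <- character(0)
  if (!is.null(tc) && nrow(tc)) {
    obs <- dataset$observations
    active <- vapply(seq_len(nrow(tc)), function(i) {
      if (tc$covariate[i] == "INHIBITOR") any(obs$inhibitor == 1)
      else any(obs$dosegrp == sub("DOSEGRP", "", tc$covariate[i]))
    }, TRUE)
    thetas <- paste0("theta_", seq_len(nrow(tc)))[active]
  }
  setdiff(c(cand, thetas), fixed)
}

.set_free <- function(params, free, logval) {
  for (j in seq_along(free)) {
    nm <- free[j]
    if (startsWith(nm, "theta_")) {
      i <- as.integer(sub("theta_", "", nm))
      params$theta_cov$theta[i] <- unname(expm1(logval[j]))
    } else {
      params[[nm]] <- unname(exp(logval[j]))
    }
  }
  params
}

.get_free <- function(params, free) {
  vapply(free, function(nm) {
    if (startsWith(nm, "theta_")) {
      i <- as.integer(sub("theta_", "", nm))
      log1p(params$theta_cov$theta[i])
    } else log(params[[nm]])
  }, 0)
}

#' Fit the model by naive-pooled extended least squares
#'
#' Minimises [els_objective()] over log-transformed free parameters
#' (covariate coefficients over `log(1 + theta)`), pooling all subjects
#' without inter-individual random effects. With a proportional error model
#' the per-stream residual SDs are profiled out in closed form at every
#' objective evaluation; with a fixed [error_model()]
#' (`estimate_sigma = FALSE`) only the structural parameters move. Multiple
#' jittered starts guard against local minima. Relative standard errors are
#' derived from the inverse Hessian of the objective at the optimum (the
#' log-scale standard error is the relative standard error to first order),
#' together with the parameter correlation matrix for identifiability
#' assessment.
#'
#' @param dataset a `cns_study`.
#' @param structure a [model_structure()].
#' @param system a [system_parameters()]; the physiological volumes are
#'   always fixed.
#' @param init a [drug_parameters()] object giving starting values (and the
#'   values at which fixed parameters are held).
#' @param fixed names of parameters to hold at their `init` values (e.g.
#'   `"fraction"`, or brain parameters during a plasma-only refit).
#' @param error_model optional fixed [error_model()]; when `NULL`
#'   (default) a proportional model is estimated by profiling.
#' @param estimate_sigma estimate residual SDs (default `TRUE` when
#'   `error_model` is `NULL`).
#' @param n_starts number of optimisation starts (first = `init`, others
#'   log-normally jittered).
#' @param jitter_sd SD of the log-scale jitter for the extra starts.
#' @param seed RNG seed for the jitter.
#' @param free optional explicit character vector of free parameter names,
#'   overriding the structure-implied default.
#' @return An object of class `cns_fit`: `params` (estimates as
#'   `cns_drug`), `sigma`, `ofv`, `rse` (named, %), `cor` (correlation
#'   matrix), `free`, `convergence`, `diagnostics`, `n_obs`.
#' @export
fit_naive_pooled <- function(dataset, structure, system, init,
                             fixed = character(0), error_model = NULL,
                             estimate_sigma = is.null(error_model),
                             n_starts = 3, jitter_sd = 0.3, seed = NULL,
                             free = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(free))
    free <- .free_params(structure, init, dataset, fixed)
  if (!length(free)) stop("no free parameters to estimate")
  if (!estimate_sigma && is.null(error_model))
    stop("estimate_sigma = FALSE requires an explicit error_model")

  lv0 <- .get_free(init, free)
  # Smooth trust region of +-6 log units around the starting values keeps
  # the search inside a physiologically conceivable range (x/÷ ~400) and
  # away from parameter regimes that defeat the integrator.
  fn <- function(lv) {
    pen <- sum(pmax(abs(lv - lv0) - 6, 0)^2)
    if (pen > 4) return(1e9 * (1 + pen))
    p <- .set_free(init, free, lv)
    val <- tryCatch({
      if (estimate_sigma) as.numeric(.els_concentrated(dataset, p, structure, system))
      else els_objective(dataset, p, error_model, structure, system)
    }, error = function(e) NA_real_)
    if (!is.finite(val)) 1e10 else val + 1e4 * pen
  }

  starts <- list(lv0)
  if (n_starts > 1)
    for (k in seq_len(n_starts - 1))
      starts[[k + 1]] <- lv0 + stats::rnorm(length(lv0), 0, jitter_sd)
  best <- NULL
  for (s in starts) {
    o <- tryCatch(stats::optim(s, fn, method = "BFGS",
                               control = list(maxit = 500, reltol = 1e-10)),
                  error = function(e) NULL)
    # restart from the optimum until BFGS makes no further progress; a
    # reset Hessian approximation often escapes premature line-search stops
    for (r in 1:3) {
      if (is.null(o)) break
      o2 <- tryCatch(stats::optim(o$par, fn, method = "BFGS",
                                  control = list(maxit = 500,
                                                 reltol = 1e-10)),
                     error = function(e) NULL)
      if (is.null(o2) || o$value - o2$value < 1e-7 * (abs(o$value) + 1)) {
        if (!is.null(o2) && o2$value < o$value) o <- o2
        break
      }
      o <- o2
    }
    if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
  }
  if (is.null(best)) stop("all optimisation starts failed")
  est <- .set_free(init, free, best$par)

  if (estimate_sigma) {
    cofv <- .els_concentrated(dataset, est, structure, system)
    sigma <- attr(cofv, "sigma")
    em <- error_model(sigma)
  } else {
    em <- error_model
    sigma <- em$sigma
  }
  ofv <- els_objective(dataset, est, em, structure, system)

  diagnostics <- character(0)
  if (best$convergence != 0)
    diagnostics <- c(diagnostics,
                     sprintf("optimiser did not report convergence (code %d)",
                             best$convergence))
  at_bound <- abs(best$par) > 20
  if (any(at_bound))
    diagnostics <- c(diagnostics,
                     sprintf("parameter(s) at extreme values: %s",
                             paste(free[at_bound], collapse = ", ")))
  pred <- .predict_study(dataset, est, structure, system)
  obs <- dataset$observations
  for (s in unique(obs$compartment)) {
    i <- obs$compartment == s
    if (max(pred[i]) <= 1e-6 * max(obs$conc))
      diagnostics <- c(diagnostics, sprintf(
        "stream '%s' has observations but near-zero predictions (structural boundary)", s))
  }

  rse <- setNames(rep(NA_real_, length(free)), free)
  cor_mat <- NULL
  H <- tryCatch(stats::optimHess(best$par, fn), error = function(e) NULL)
  if (!is.null(H)) {
    cov <- tryCatch(2 * solve(H), error = function(e) NULL)
    if (!is.null(cov) && all(diag(cov) > 0)) {
      rse <- setNames(100 * sqrt(diag(cov)), free)
      cor_mat <- stats::cov2cor(cov)
      dimnames(cor_mat) <- list(free, free)
    } else {
      diagnostics <- c(diagnostics,
                       "Hessian not positive definite; RSE unavailable")
    }
  }

  structure(list(params = est, sigma = sigma, ofv = ofv, rse = rse,
                 cor = cor_mat, free = free,
                 convergence = best$convergence, diagnostics = diagnostics,
                 n_obs = nrow(dataset$observations), error_model = em),
            class = "cns_fit")
}

#' @export
print.cns_fit <- function(x, ...) {
  cat(sprintf("Naive-pooled ELS fit: %d observations, OFV = %.3f\n",
              x$n_obs, x$ofv))
  for (nm in x$free) {
    val <- if (startsWith(nm, "theta_")) {
      i <- as.integer(sub("theta_", "", nm))
      x$params$theta_cov$theta[i]
    } else x$params[[nm]]
    cat(sprintf("  %-10s %#.4g  (RSE %.1f%%)\n", nm, val, x$rse[[nm]]))
  }
  cat("  sigma:", paste(sprintf("%s=%.3g", names(x$sigma), x$sigma),
                        collapse = ", "), "\n")
  if (length(x$diagnostics))
    cat("  diagnostics:", paste(x$diagnostics, collapse = "; "), "\n")
  invisible(x)
}

#' Likelihood-ratio comparison of nested models
#'
#' A drop in OFV (-2 log likelihood) of at least the chi-square 95th
#' percentile at the added degrees of freedom is significant at p < 0.05
#' (3.84 for one degree of freedom).
#'
#' @param ofv_full,ofv_reduced objective function values of the full and the
#'   reduced (nested) model.
#' @param ddf difference in number of estimated parameters, >= 1.
#' @param tol numerical tolerance before a negative drop is treated as a
#'   nesting violation.
#' @return List with `delta_ofv`, `critical` and `significant`.
#' @examples
#' lrt_compare(100, 103.85, 1)$significant  # TRUE
#' @export
lrt_compare <- function(ofv_full, ofv_reduced, ddf = 1, tol = 1e-6) {
  if (ddf < 1) stop("ddf must be >= 1")
  delta <- ofv_reduced - ofv_full
  if (delta < -tol)
    stop("full model has higher OFV than the reduced model: nesting violation")
  crit <- stats::qchisq(0.95, ddf)
  list(delta_ofv = delta, critical = crit, significant = delta >= crit)
}

#' Realise subject-level parameters under log-normal variability
#'
#' `theta_i = theta * exp(eta)` with `eta ~ N(0, omega^2)`: multiplicative
#' inter-individual deviations whose median is the population value.
#'
#' @param theta population parameter value.
#' @param omega SD of the log-normal random effect, >= 0.
#' @param n number of subjects to draw.
#' @return Numeric vector of `n` subject-level values.
#' @export
iiv_realize <- function(theta, omega, n = 1) {
  if (omega < 0) stop("omega must be >= 0")
  theta * exp(stats::rnorm(n, 0, omega))
}
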