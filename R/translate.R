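#' Allometric interspecies scaling of a clearance or flow
#'
#' `P_human = P_rat * (BW_human / BW_rat)^exponent` with the classic 0.75
#' exponent for flow-like parameters.
#'
#' @param p_rat rat parameter value (mL/min).
#' @param bw_human,bw_rat body weights (kg); defaults 70 and 0.25.
#' @param exponent allometric exponent in (0, 1].
#' @return Scaled parameter (mL/min).
#' @examples
#' signif(allometric_scale(0.0281), 3)  # 1.92
#' @export
allometric_scale <- function(p_rat, bw_human = 70, bw_rat = 0.25,
                             exponent = 0.75) {
  if (any(p_rat <= 0) || bw_human <= 0 || bw_rat <= 0)
    stop("allometric scaling requires positive inputs")
  if (exponent <= 0 || exponent > 1) stop("exponent must lie in (0, 1]")
  p_rat * (bw_human / bw_rat)^exponent
}

#' Translation configuration
#'
#' Bundles the constants of the rat-to-human translation: reference body
#' weights, the allometric exponent, the human physiological volumes, the
#' per-patient external-ventricular-drain records and the plasma model
#' order.
#'
#' @param bw_rat,bw_human reference body weights (kg).
#' @param exponent allometric exponent.
#' @param system human [system_parameters()].
#' @param evd optional data frame with columns `q_lv_evd` (mL/min) and
#'   `v_evd` (mL), one row per patient; `NULL` disables the EVD
#'   compartment.
#' @param plasma_order number of plasma disposition compartments (1-3).
#' @return An object of class `cns_translation`.
#' @export
translation_config <- function(bw_rat = 0.25, bw_human = 70,
                               exponent = 0.75,
                               system = system_parameters("human"),
                               evd = NULL, plasma_order = 2) {
  if (bw_rat <= 0 || bw_human <= 0) stop("body weights must be positive")
  if (!plasma_order %in% 1:3) stop("plasma_order must be 1, 2 or 3")
  if (!is.null(evd))
    stopifnot(is.data.frame(evd),
              all(c("q_lv_evd", "v_evd") %in% names(evd)))
  structure(list(bw_rat = bw_rat, bw_human = bw_human, exponent = exponent,
                 system = system, evd = evd, plasma_order = plasma_order),
            class = "cns_translation")
}

.subset_study <- function(study, subjects) {
  obs <- study$observations
  structure(list(observations = obs[obs$subject %in% subjects, , drop = FALSE],
                 doses = study$doses[as.character(subjects)],
                 species = study$species,
                 bw = study$bw[as.character(subjects)]),
            class = "cns_study")
}

.plasma_structure <- function(order, species = "human") {
  model_structure(switch(order, character(0), "per1", c("per1", "per2")),
                  species = species)
}

.plasma_free <- function(order) {
  c("cl_pl", "v_pl",
    if (order >= 2) c("q_pl_per1", "v_per1"),
    if (order >= 3) c("q_pl_per2", "v_per2"))
}

# Heuristic initial plasma parameters from non-compartmental summaries:
# clearance from dose/AUC (trapezoid), central volume from dose/Cmax.
.plasma_init <- function(study, order, f_p = 1) {
  obs <- study$observations
  o <- obs[order(obs$time), , drop = FALSE]
  agg <- tapply(o$conc, o$time, mean)
  tt <- as.numeric(names(agg))
  auc <- sum(diff(tt) * (utils::head(agg, -1) + utils::tail(agg, -1)) / 2)
  dose <- mean(vapply(study$doses, function(dl)
    sum(vapply(dl, `[[`, 0, "amount")), 0))
  cl <- dose * f_p / max(auc, 1e-12)
  v <- dose * f_p / max(agg)
  drug_parameters(cl_pl = cl, v_pl = v,
                  q_pl_per1 = if (order >= 2) cl else NA_real_,
                  v_per1 = if (order >= 2) 3 * v else NA_real_,
                  q_pl_per2 = if (order >= 3) cl / 2 else NA_real_,
                  v_per2 = if (order >= 3) 3 * v else NA_real_,
                  q_pl_ecf = 0, q_diff = 0, f_p = f_p)
}

#' Fit human (or external rat) plasma data with inter-individual variability
#'
#' Mammillary plasma models of one to three compartments are fitted to
#' plasma-only data by naive-pooled ELS; the model order is chosen by
#' sequential likelihood-ratio tests ([lrt_compare()], two added parameters
#' per extra compartment). Inter-individual variability is then quantified
#' by a two-stage approach: each subject is refitted from the pooled
#' estimates and the subject-level estimates are pooled in the log domain
#' (`theta = exp(mean(log theta_i))`, `omega = sd(log theta_i)`).
#'
#' @param plasma_study a `cns_study` with plasma observations only.
#' @param orders candidate compartment numbers (subset of 1:3).
#' @param f_p unbound plasma fraction applied in prediction of unbound
#'   observations.
#' @param seed RNG seed for the pooled fit's multi-start jitter.
#' @param ... further arguments to [fit_naive_pooled()].
#' @return A `cns_fit` with extra elements `order` (selected model order),
#'   `iiv` (named vector of omega SDs) and `subject_params` (matrix of
#'   per-subject log estimates).
#' @export
fit_human_plasma <- function(plasma_study, orders = 1:3, f_p = 1,
                             seed = NULL, ...) {
  if (!all(orders %in% 1:3)) stop("model order must be in {1, 2, 3}")
  if (any(plasma_study$observations$compartment != "plasma"))
    stop("plasma_study must contain plasma observations only")
  orders <- sort(orders)
  fits <- list()
  for (k in orders) {
    st <- .plasma_structure(k, plasma_study$species)
    init <- .plasma_init(plasma_study, k, f_p)
    fits[[as.character(k)]] <- fit_naive_pooled(
      plasma_study, st, system_parameters(plasma_study$species),
      init = init, free = .plasma_free(k), seed = seed, ...)
  }
  sel <- orders[1]
  for (k in orders[-1]) {
    # an imperfectly converged richer fit that lands above the reduced one
    # is simply no improvement, not an error
    cmp <- tryCatch(
      lrt_compare(fits[[as.character(k)]]$ofv, fits[[as.character(sel)]]$ofv,
                  ddf = length(.plasma_free(k)) - length(.plasma_free(sel))),
      error = function(e) list(significant = FALSE))
    if (cmp$significant) sel <- k else break
  }
  best <- fits[[as.character(sel)]]
  st <- .plasma_structure(sel, plasma_study$species)
  free <- .plasma_free(sel)

  subjects <- names(plasma_study$doses)
  logs <- matrix(NA_real_, length(subjects), length(free),
                 dimnames = list(subjects, free))
  for (s in subjects) {
    sub <- .subset_study(plasma_study, s)
    fi <- tryCatch(
      fit_naive_pooled(sub, st, system_parameters(plasma_study$species),
                       init = best$params, free = free, n_starts = 1),
      error = function(e) NULL)
    if (!is.null(fi)) logs[s, ] <- .get_free(fi$params, free)
  }
  ok <- stats::complete.cases(logs)
  if (sum(ok) >= 2) {
    pooled_log <- colMeans(logs[ok, , drop = FALSE])
    omega <- apply(logs[ok, , drop = FALSE], 2, stats::sd)
    best$params <- .set_free(best$params, free, pooled_log)
    best$iiv <- omega
  } else {
    best$iiv <- setNames(rep(NA_real_, length(free)), free)
    best$diagnostics <- c(best$diagnostics,
      "fewer than two subject-level fits converged; IIV not quantified")
  }
  best$order <- sel
  best$subject_params <- logs
  best$ofv_by_order <- vapply(fits, `[[`, 0, "ofv")
  best
}

#' Assemble the translated human model
#'
#' Builds the human model triple from a rat fit: the drug-specific brain
#' parameters (BBB transfer clearance and dispersion flow) are allometrically
#' scaled from the rat estimates and fixed (rounded to 3 significant figures
#' for reporting, matching the translational convention), the system-specific
#' volumes are replaced by the human physiological values, the plasma
#' parameters are taken from the human plasma fit, and the EVD sampling
#' compartment is attached when patient drain records are supplied.
#'
#' @param rat_fit a `cns_fit` from the rat brain model (or a
#'   [drug_parameters()] object holding the rat estimates).
#' @param cfg a [translation_config()].
#' @param human_plasma_fit a `cns_fit` from [fit_human_plasma()] (or a
#'   `cns_drug` with the human plasma parameters).
#' @param dose_group optional dose-group label selecting a dose-group
#'   specific rat BBB clearance via its categorical covariate (e.g. `"4"`
#'   for the morphine 4 mg/kg group) before scaling.
#' @param patient row of `cfg$evd` to use when the EVD drain is attached.
#' @return An object of class `cns_human_model`: list with `structure`,
#'   `params`, `system`.
#' @export
build_human_model <- function(rat_fit, cfg, human_plasma_fit,
                              dose_group = NULL, patient = 1) {
  rat <- if (inherits(rat_fit, "cns_fit")) rat_fit$params else rat_fit
  hum <- if (inherits(human_plasma_fit, "cns_fit"))
    human_plasma_fit$params else human_plasma_fit
  if (is.na(rat$q_pl_ecf) || is.na(rat$q_diff))
    stop("rat fit must provide q_pl_ecf and q_diff")
  if (!is.null(dose_group))
    rat <- .subject_params(rat, inhibitor = 0, dosegrp = dose_group)
  sc <- function(p) signif(allometric_scale(p, cfg$bw_human, cfg$bw_rat,
                                            cfg$exponent), 3)
  has_evd <- !is.null(cfg$evd)
  feats <- c(if (!is.na(hum$q_pl_per1)) "per1",
             if (!is.na(hum$q_pl_per2)) "per2",
             if (has_evd) "evd")
  st <- model_structure(feats, species = "human",
                        q_lv_evd = if (has_evd) cfg$evd$q_lv_evd[patient]
                                   else NA_real_,
                        v_evd = if (has_evd) cfg$evd$v_evd[patient]
                                else NA_real_)
  params <- drug_parameters(
    cl_pl = hum$cl_pl, v_pl = hum$v_pl,
    q_pl_per1 = hum$q_pl_per1, v_per1 = hum$v_per1,
    q_pl_per2 = hum$q_pl_per2, v_per2 = hum$v_per2,
    q_pl_ecf = sc(rat$q_pl_ecf), q_diff = sc(rat$q_diff),
    f_p = hum$f_p)
  structure(list(structure = st, params = params, system = cfg$system),
            class = "cns_human_model")
}

#' Predict human brain and CSF concentration-time profiles
#'
#' Simulation-based prediction for a translated human model: replicates with
#' inter-individual variability on the plasma parameters and residual error,
#' summarised as median and 95% prediction interval per compartment
#' ([simulate_prediction_interval()]). When observations are supplied the
#' deterministic population prediction is scored per compartment with
#' [smape()].
#'
#' @param model a `cns_human_model` from [build_human_model()].
#' @param doses regimen ([dose_event()] or list).
#' @param times output grid (min).
#' @param err residual [error_model()] (or `NULL`).
#' @param iiv named omega vector (or `NULL`).
#' @param n_reps,seed replicates and seed for the interval.
#' @param observations optional `cns_study` with human observations.
#' @return List of class `cns_prediction`: `bands` (`cns_bands`) and,
#'   when observations were given, `smape` (named %) and `pe`.
#' @export
predict_human_profiles <- function(model, doses, times, err = NULL,
                                   iiv = NULL, n_reps = 200, seed = NULL,
                                   observations = NULL) {
  bands <- simulate_prediction_interval(model$structure, model$params,
                                        model$system, doses, times,
                                        err = err, iiv = iiv,
                                        n_reps = n_reps, seed = seed)
  out <- list(bands = bands)
  if (!is.null(observations) && nrow(observations$observations)) {
    obs <- observations$observations
    pred <- .predict_study(observations, model$params, model$structure,
                           model$system)
    out$pe <- data.frame(obs[c("subject", "time", "compartment")],
                         obs = obs$conc, pred = pred,
                         pe = prediction_error(obs$conc, pred))
    out$smape <- vapply(split(seq_len(nrow(obs)), obs$compartment),
                        function(i) smape(obs$conc[i], pred[i]), 0)
  }
  class(out) <- "cns_prediction"
  out
}

#' @export
print.cns_prediction <- function(x, ...) {
  cat(sprintf("Human prediction bands: %d time points, compartments: %s\n",
              length(unique(x$bands$time)),
              paste(unique(x$bands$compartment), collapse = " ")))
  if (!is.null(x$smape)) {
    cat("  SMAPE per compartment (%):\n")
    for (nm in names(x$smape)) cat(sprintf("    %-10s %.1f\n", nm, x$smape[nm]))
  }
  invisible(x)
}
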