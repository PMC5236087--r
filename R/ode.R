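#' Create an intravenous infusion event
#'
#' Doses enter plasma as zero-order infusions; a bolus is represented as a
#' short infusion (e.g. 1 min) so the input is always a finite rate.
#'
#' @param amount dose amount (ng).
#' @param duration infusion duration (min), strictly positive.
#' @param start infusion start time (min).
#' @return An object of class `cns_dose`.
#' @export
dose_event <- function(amount, duration, start = 0) {
  if (duration <= 0) stop("infusion duration must be > 0 (bolus = short infusion)")
  if (amount < 0) stop("dose amount must be non-negative")
  if (start < 0) stop("dose start time must be non-negative")
  structure(list(amount = amount, duration = duration, start = start),
            class = "cns_dose")
}

# Full 20-element parameter vector for the C right-hand side. Disabled
# features get zero flows and a placeholder unit volume; their compartments
# never receive mass.
.param_vector <- function(structure, params, system, rate = 0) {
  na0 <- function(x) if (is.na(x)) 0 else x
  na1 <- function(x) if (is.na(x)) 1 else x
  cl_eff <- params$cl_pl *
    (1 - if (structure$enterohepatic_enabled) na0(params$fraction) else 0)
  c(cl_pl = cl_eff,
    q_per1 = if (structure$per1) na0(params$q_pl_per1) else 0,
    q_per2 = if (structure$per2) na0(params$q_pl_per2) else 0,
    q_ecf = params$q_pl_ecf,
    q_lv_pl = if (structure$bcsfb_efflux_enabled) na0(params$q_lv_pl) else 0,
    q_ecf_icf = if (structure$icf_enabled) na0(params$q_ecf_icf) else 0,
    q_diff = params$q_diff,
    q_evd = if (structure$evd_enabled) na0(structure$q_lv_evd) else 0,
    f_p = params$f_p,
    v_pl = params$v_pl,
    v_per1 = if (structure$per1) na1(params$v_per1) else 1,
    v_per2 = if (structure$per2) na1(params$v_per2) else 1,
    v_ecf = system$v_ecf,
    v_icf = if (structure$icf_enabled) na1(system$v_icf) else 1,
    v_lv = system$v_lv, v_tfv = system$v_tfv, v_cm = system$v_cm,
    v_sas = system$v_sas,
    v_evd = if (structure$evd_enabled) structure$v_evd else 1,
    rate = rate)
}

#' Mass-balance derivatives of the CNS distribution model
#'
#' The pure-R right-hand side of the model ODEs, exposed for inspection and
#' testing; [solve_profile()] integrates the identical equations in compiled
#' form. Amounts are ng, flows mL/min, so derivatives are ng/min.
#' Concentration in each compartment is amount divided by its volume; the
#' unbound plasma concentration (`f_p * C_PL`) drives the BBB flux.
#'
#' @param amounts named or unnamed numeric vector of amounts (ng) over the
#'   full compartment layout `plasma, per1, per2, brain_ecf, brain_icf,
#'   csf_lv, csf_tfv, csf_cm, csf_sas, csf_evd`.
#' @param t time (min); unused (the system is autonomous between infusion
#'   events) but kept for the standard signature.
#' @param params a [drug_parameters()] object.
#' @param system a [system_parameters()] object.
#' @param structure a [model_structure()] object.
#' @param rate current infusion rate into plasma (ng/min).
#' @return Named numeric vector of derivatives (ng/min).
#' @export
ode_rhs <- function(amounts, t, params, system, structure, rate = 0) {
  if (length(amounts) != length(.all_compartments))
    stop(sprintf("state vector must have length %d (full compartment layout)",
                 length(.all_compartments)))
  p <- .param_vector(structure, params, system, rate)
  conc <- amounts / p[c("v_pl", "v_per1", "v_per2", "v_ecf", "v_icf",
                        "v_lv", "v_tfv", "v_cm", "v_sas", "v_evd")]
  names(conc) <- .all_compartments
  j_bbb <- p[["q_ecf"]] * (p[["f_p"]] * conc[["plasma"]] - conc[["brain_ecf"]])
  j_icf <- p[["q_ecf_icf"]] * (conc[["brain_ecf"]] - conc[["brain_icf"]])
  d <- c(
    plasma = p[["rate"]] +
      p[["q_per1"]] * (conc[["per1"]] - conc[["plasma"]]) +
      p[["q_per2"]] * (conc[["per2"]] - conc[["plasma"]]) -
      p[["cl_pl"]] * conc[["plasma"]] - j_bbb +
      p[["q_diff"]] * conc[["csf_sas"]] +
      p[["q_lv_pl"]] * conc[["csf_lv"]],
    per1 = p[["q_per1"]] * (conc[["plasma"]] - conc[["per1"]]),
    per2 = p[["q_per2"]] * (conc[["plasma"]] - conc[["per2"]]),
    brain_ecf = j_bbb - p[["q_diff"]] * conc[["brain_ecf"]] - j_icf,
    brain_icf = j_icf,
    csf_lv = p[["q_diff"]] * conc[["brain_ecf"]] -
      (p[["q_diff"]] + p[["q_lv_pl"]] + p[["q_evd"]]) * conc[["csf_lv"]],
    csf_tfv = p[["q_diff"]] * (conc[["csf_lv"]] - conc[["csf_tfv"]]),
    csf_cm = p[["q_diff"]] * (conc[["csf_tfv"]] - conc[["csf_cm"]]),
    csf_sas = p[["q_diff"]] * (conc[["csf_cm"]] - conc[["csf_sas"]]),
    csf_evd = p[["q_evd"]] * (conc[["csf_lv"]] - conc[["csf_evd"]]))
  d
}

#' Simulate a concentration-time profile
#'
#' Integrates the model for an arbitrary set of infusion events. Infusion
#' starts and stops are treated as exact event times: the system is
#' integrated piecewise between event boundaries with a constant input rate
#' within each segment, so no discontinuity falls inside an integrator step.
#' Integration uses `deSolve::lsoda` (stiff-capable) with relative tolerance
#' 1e-10.
#'
#' @param structure a [model_structure()].
#' @param params a [drug_parameters()].
#' @param system a [system_parameters()].
#' @param doses a single [dose_event()] or a list of them (at least one).
#' @param times numeric vector of output times (min), sorted, non-negative.
#' @param compiled integrate with the compiled right-hand side (default) or
#'   the R reference implementation [ode_rhs()] (slower; used for
#'   cross-checking).
#' @return An object of class `cns_profile`: list with `time`, `conc`
#'   (time x compartment matrix, ng/mL), `amounts` (ng) and `compartments`
#'   (the enabled compartment labels).
#' @examples
#' pre <- drug_preset("atenolol")
#' prof <- solve_profile(pre$structure, pre$params, system_parameters("rat"),
#'                       dose_event(2.5e6, 1), times = 0:120)
#' @export
solve_profile <- function(structure, params, system, doses, times,
                          compiled = TRUE) {
  if (inherits(doses, "cns_dose")) doses <- list(doses)
  if (!length(doses)) stop("at least one dose event is required")
  if (is.unsorted(times) || any(times < 0))
    stop("output times must be sorted and non-negative")
  starts <- vapply(doses, `[[`, 0, "start")
  ends <- starts + vapply(doses, `[[`, 0, "duration")
  rates <- vapply(doses, function(d) d$amount / d$duration, 0)
  tmax <- max(times)
  bounds <- sort(unique(c(0, times, starts[starts < tmax],
                          ends[ends < tmax], tmax)))
  atol <- max(1e-12, 1e-12 * sum(vapply(doses, `[[`, 0, "amount")))
  y <- setNames(numeric(length(.all_compartments)), .all_compartments)
  out_amt <- matrix(NA_real_, length(times), length(.all_compartments),
                    dimnames = list(NULL, .all_compartments))
  if (any(times == 0)) out_amt[times == 0, ] <- rep(y, each = sum(times == 0))
  seg_start <- bounds[-length(bounds)]
  seg_end <- bounds[-1]
  for (k in seq_along(seg_start)) {
    rate <- sum(rates[starts <= seg_start[k] & ends > seg_start[k]])
    want <- times[times > seg_start[k] & times <= seg_end[k]]
    tt <- sort(unique(c(seg_start[k], want, seg_end[k])))
    p <- .param_vector(structure, params, system, rate)
    if (compiled) {
      sol <- deSolve::lsoda(y, tt, func = "cnspk_derivs", parms = p,
                            dllname = "cnspk", initfunc = "cnspk_init",
                            rtol = 1e-10, atol = atol)
    } else {
      rfun <- function(t, y, parms)
        list(ode_rhs(y, t, params, system, structure, rate = rate))
      sol <- deSolve::lsoda(y, tt, func = rfun, parms = NULL,
                            rtol = 1e-10, atol = atol)
    }
    if (attr(sol, "istate")[1] < 0)
      stop(sprintf("ODE integration failed in segment [%g, %g] min (lsoda istate %d)",
                   seg_start[k], seg_end[k], attr(sol, "istate")[1]))
    m <- unname(sol[, -1, drop = FALSE])
    if (length(want))
      out_amt[match(want, times), ] <- m[match(want, tt), , drop = FALSE]
    y <- setNames(m[nrow(m), ], .all_compartments)
  }
  vols <- .param_vector(structure, params, system)[
    c("v_pl", "v_per1", "v_per2", "v_ecf", "v_icf", "v_lv", "v_tfv",
      "v_cm", "v_sas", "v_evd")]
  conc <- sweep(out_amt, 2, vols, "/")
  keep <- structure$compartments
  structure(list(time = times,
                 conc = conc[, keep, drop = FALSE],
                 amounts = out_amt[, keep, drop = FALSE],
                 compartments = keep),
            class = "cns_profile")
}

#' @export
as.data.frame.cns_profile <- function(x, ...) {
  data.frame(time = rep(x$time, length(x$compartments)),
             compartment = rep(x$compartments, each = length(x$time)),
             conc = as.vector(x$conc),
             amount = as.vector(x$amounts))
}

#' @export
print.cns_profile <- function(x, ...) {
  cat(sprintf("CNS concentration profile: %d time points (%g-%g min), %s\n",
              length(x$time), min(x$time), max(x$time),
              paste(x$compartments, collapse = " ")))
  invisible(x)
}

#' Closed-form steady-state brain ECF partitioning
#'
#' Under the reduced structure (no ICF exchange, no BCSFB efflux, no EVD)
#' the steady-state ratio of brain ECF concentration to unbound plasma
#' concentration during a constant-rate infusion has the closed form
#' `Q_PL_ECF / (Q_PL_ECF + Q_DIFF)`: BBB delivery competes with dispersion
#' into the CSF chain. Used as an analytic oracle for the ODE solver.
#'
#' @param params a [drug_parameters()] object (only `q_pl_ecf` and `q_diff`
#'   are used).
#' @return The unitless ratio C_ECF / (f_p * C_PL) at steady state.
#' @examples
#' steady_state_ecf_ratio(drug_parameters(1, 0.0281, 0.0556, 1))  # 0.3357
#' @export
steady_state_ecf_ratio <- function(params) {
  q <- params$q_pl_ecf
  d <- params$q_diff
  if (q + d <= 0) stop("q_pl_ecf + q_diff must be positive")
  q / (q + d)
}
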