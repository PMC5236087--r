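#' Physiological CNS system parameters
#'
#' Species-specific volumes of the brain fluid compartments and the reference
#' body weight. These are system parameters in the PBPK sense: they belong to
#' the species, not to the drug, and are fixed (never estimated). Rat values
#' are literature physiological volumes; human values are the corresponding
#' literature volumes used for translational prediction.
#'
#' @param species `"rat"` or `"human"`, selecting the built-in defaults.
#' @param v_ecf,v_icf,v_lv,v_tfv,v_cm,v_sas compartment volumes (mL):
#'   brain extracellular fluid, brain intracellular fluid, lateral-ventricle
#'   CSF, third+fourth-ventricle CSF, cisterna-magna CSF, subarachnoid-space
#'   CSF. Override the species default if supplied.
#' @param bw body weight (kg).
#' @return An object of class `cns_system`: a named list of volumes (mL),
#'   body weight (kg) and the species label.
#' @examples
#' system_parameters("rat")$v_ecf    # 0.29 mL
#' system_parameters("human")$v_sas  # 90 mL
#' @export
system_parameters <- function(species = c("rat", "human"),
                              v_ecf = NULL, v_icf = NULL, v_lv = NULL,
                              v_tfv = NULL, v_cm = NULL, v_sas = NULL,
                              bw = NULL) {
  species <- match.arg(species)
  def <- switch(species,
    rat = list(v_ecf = 0.29, v_icf = 1.44, v_lv = 0.05, v_tfv = 0.05,
               v_cm = 0.017, v_sas = 0.18, bw = 0.25),
    # human brain ICF volume is not part of the translational parameter set;
    # it is only needed when the ICF feature is enabled (neither human drug
    # requires it) and is carried as NA.
    human = list(v_ecf = 240, v_icf = NA_real_, v_lv = 22.5, v_tfv = 22.5,
                 v_cm = 7.5, v_sas = 90, bw = 70))
  out <- list(
    v_ecf = v_ecf %||% def$v_ecf, v_icf = v_icf %||% def$v_icf,
    v_lv = v_lv %||% def$v_lv, v_tfv = v_tfv %||% def$v_tfv,
    v_cm = v_cm %||% def$v_cm, v_sas = v_sas %||% def$v_sas,
    bw = bw %||% def$bw, species = species)
  vols <- unlist(out[c("v_ecf", "v_lv", "v_tfv", "v_cm", "v_sas")])
  if (any(!is.finite(vols)) || any(vols <= 0))
    stop("all CNS volumes must be strictly positive")
  if (!is.na(out$v_icf) && out$v_icf <= 0)
    stop("v_icf must be strictly positive when supplied")
  if (out$bw <= 0) stop("body weight must be strictly positive")
  structure(out, class = "cns_system")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Drug-specific model parameters
#'
#' Rates (mL/min), volumes (mL) and covariate coefficients for one drug.
#' Optional parameters are `NA` unless the corresponding structural feature
#' is enabled. Covariate coefficients follow the categorical model
#' `P = P * (1 + theta * Cov)` and are supplied as a data frame with columns
#' `parameter`, `covariate`, `theta`.
#'
#' @param cl_pl plasma clearance (mL/min).
#' @param q_pl_ecf blood-brain-barrier transfer clearance (mL/min).
#' @param q_diff drug dispersion flow through brain ECF and CSF (mL/min).
#' @param v_pl central (plasma) volume of distribution (mL).
#' @param q_pl_per1,q_pl_per2 inter-compartmental clearances to the
#'   peripheral compartments (mL/min); `NA` when absent.
#' @param q_lv_pl BCSFB efflux clearance, lateral ventricle to plasma
#'   (mL/min); `NA` unless BCSFB efflux is enabled.
#' @param q_ecf_icf brain ECF/ICF exchange clearance (mL/min).
#' @param v_per1,v_per2 peripheral volumes (mL).
#' @param fraction fraction of eliminated drug returned by enterohepatic
#'   recirculation (0-1); `NA` unless the feature is enabled.
#' @param f_p unbound fraction in plasma, in (0, 1].
#' @param theta_cov data frame of covariate coefficients
#'   (`parameter`, `covariate`, `theta`), or `NULL`.
#' @return An object of class `cns_drug` (named list).
#' @export
drug_parameters <- function(cl_pl, q_pl_ecf, q_diff, v_pl,
                            q_pl_per1 = NA_real_, q_pl_per2 = NA_real_,
                            q_lv_pl = NA_real_, q_ecf_icf = NA_real_,
                            v_per1 = NA_real_, v_per2 = NA_real_,
                            fraction = NA_real_, f_p = 1,
                            theta_cov = NULL) {
  p <- list(cl_pl = cl_pl, q_pl_per1 = q_pl_per1, q_pl_per2 = q_pl_per2,
            q_pl_ecf = q_pl_ecf, q_lv_pl = q_lv_pl, q_ecf_icf = q_ecf_icf,
            q_diff = q_diff, v_pl = v_pl, v_per1 = v_per1, v_per2 = v_per2,
            fraction = fraction, f_p = f_p, theta_cov = theta_cov)
  num <- unlist(p[c("cl_pl", "q_pl_per1", "q_pl_per2", "q_pl_ecf",
                    "q_lv_pl", "q_ecf_icf", "q_diff", "v_pl",
                    "v_per1", "v_per2")])
  if (any(num < 0, na.rm = TRUE))
    stop("rates and volumes must be non-negative")
  if (!is.na(fraction) && (fraction < 0 || fraction > 1))
    stop("enterohepatic fraction must lie in [0, 1]")
  if (f_p <= 0 || f_p > 1) stop("f_p must lie in (0, 1]")
  if (!is.null(theta_cov)) {
    stopifnot(is.data.frame(theta_cov),
              all(c("parameter", "covariate", "theta") %in% names(theta_cov)))
    if (any(theta_cov$theta <= -1))
      stop("covariate coefficients must exceed -1 (parameter must stay positive)")
  }
  structure(p, class = "cns_drug")
}

# The nine rat compounds: point estimates, residual-error SDs per observation
# stream, structural features and covariate coefficients. Morphine's BBB
# clearance is dose-group dependent (categorical): the base value applies to
# the 10 and 40 mg/kg groups, the 4 mg/kg group value is expressed through a
# DOSEGRP4 covariate so that 0.00458 * (1 + theta) = 0.00750 exactly.
.rat_presets <- function() {
  th <- function(...) {
    m <- rbind(...)
    data.frame(parameter = m[, 1], covariate = m[, 2],
               theta = as.numeric(m[, 3]), stringsAsFactors = FALSE)
  }
  list(
    acetaminophen = list(
      features = c("per1", "enterohepatic"),
      params = drug_parameters(cl_pl = 15.9, q_pl_per1 = 29.2,
        q_pl_ecf = 0.0281, q_diff = 0.0556, v_pl = 65.7, v_per1 = 219,
        fraction = 0.933),
      sigma = c(plasma = 0.341, brain_ecf = 1.88, csf_lv = 0.607,
                csf_cm = 0.640)),
    atenolol = list(
      features = "per1",
      params = drug_parameters(cl_pl = 6.09, q_pl_per1 = 6.55,
        q_pl_ecf = 0.00749, q_diff = 0.0205, v_pl = 115, v_per1 = 280),
      sigma = c(plasma = 0.218, brain_ecf = 0.480)),
    methotrexate = list(
      features = c("per1", "per2", "bcsfb_efflux"),
      params = drug_parameters(cl_pl = 8.12, q_pl_per1 = 28.1,
        q_pl_per2 = 1.50, q_pl_ecf = 0.00109, q_lv_pl = 0.105,
        q_diff = 0.0598, v_pl = 51.2, v_per1 = 210, v_per2 = 114,
        theta_cov = th(c("q_pl_ecf", "INHIBITOR", 4.09),
                       c("q_lv_pl", "INHIBITOR", 0.410))),
      sigma = c(plasma = 0.522, brain_ecf = 0.529, csf_lv = 0.663,
                csf_cm = 1.00)),
    morphine = list(
      features = c("per1", "per2"),
      params = drug_parameters(cl_pl = 21.6, q_pl_per1 = 8.72,
        q_pl_per2 = 53.3, q_pl_ecf = 0.00458, q_diff = 0.0200,
        v_pl = 118, v_per1 = 1210, v_per2 = 570,
        theta_cov = th(c("q_pl_ecf", "INHIBITOR", 1.62),
                       c("q_pl_ecf", "DOSEGRP4", 0.00750 / 0.00458 - 1))),
      sigma = c(plasma = 0.647, brain_ecf = 0.779)),
    paliperidone = list(
      features = "icf",
      params = drug_parameters(cl_pl = 192, q_pl_ecf = 0.0123,
        q_ecf_icf = 0.0126, q_diff = 0.0248, v_pl = 28400,
        theta_cov = th(c("q_pl_ecf", "INHIBITOR", 0.434))),
      sigma = c(plasma = 0.631, brain_ecf = 0.946, csf_cm = 0.770)),
    phenytoin = list(
      features = "per1",
      params = drug_parameters(cl_pl = 44.7, q_pl_per1 = 133,
        q_pl_ecf = 0.00340, q_diff = 0.0133, v_pl = 2890, v_per1 = 5320,
        f_p = 0.09,   # 91% protein bound
        theta_cov = th(c("q_pl_ecf", "INHIBITOR", 0.355))),
      sigma = c(plasma = 0.444, brain_ecf = 0.415)),
    quinidine = list(
      features = c("per1", "icf"),
      params = drug_parameters(cl_pl = 152, q_pl_per1 = 1070,
        q_pl_ecf = 0.0354, q_ecf_icf = 0.0250, q_diff = 0.0237,
        v_pl = 194, v_per1 = 13300,
        theta_cov = th(c("q_pl_ecf", "INHIBITOR", 4.43))),
      sigma = c(plasma = 0.418, brain_ecf = 0.628, csf_lv = 0.629,
                csf_cm = 0.466)),
    remoxipride = list(
      features = "per1",
      params = drug_parameters(cl_pl = 114, q_pl_per1 = 105,
        q_pl_ecf = 0.0141, q_diff = 0.0176, v_pl = 286, v_per1 = 2310,
        f_p = 0.74),  # 26% protein bound
      sigma = c(plasma = 0.348, brain_ecf = 0.673)),
    risperidone = list(
      features = character(0),
      params = drug_parameters(cl_pl = 465, q_pl_ecf = 0.0247,
        q_diff = 0.0254, v_pl = 60000,
        theta_cov = th(c("q_pl_ecf", "INHIBITOR", 1.24))),
      sigma = c(plasma = 1.44, brain_ecf = 0.911, csf_cm = 0.827)))
}

# Human plasma parameter sets for the two translated drugs: point estimates,
# inter-individual variability SDs (log scale) and residual-error SDs.
.human_presets <- function() {
  list(
    acetaminophen = list(
      params = drug_parameters(cl_pl = 562, q_pl_per1 = 2060,
        q_pl_ecf = 0, q_diff = 0, v_pl = 9880, v_per1 = 51900,
        f_p = 0.85),
      omega = c(cl_pl = 0.490, v_per1 = 0.235),
      sigma = c(plasma = 0.250)),
    morphine = list(
      params = drug_parameters(cl_pl = 3070, q_pl_per1 = 3030,
        q_pl_ecf = 0, q_diff = 0, v_pl = 16000, v_per1 = 95400),
      omega = c(cl_pl = 0.271, v_pl = 0.596),
      sigma = c(plasma = 0.0960)))
}

#' Built-in drug presets
#'
#' Returns the reference parameterisation for one of the nine rat compounds
#' (`species = "rat"`) or the human plasma parameter set for acetaminophen or
#' morphine (`species = "human"`). Rat presets contain the drug parameters,
#' the structural features supported by the data, and the residual-error SDs
#' per observation stream; human presets additionally carry the
#' inter-individual variability SDs.
#'
#' @param drug drug name (lower case).
#' @param species `"rat"` or `"human"`.
#' @return A list with elements `drug`, `species`, `params` (`cns_drug`),
#'   `structure` (`cns_structure`), `sigma` and, for human presets, `omega`.
#' @examples
#' drug_preset("acetaminophen")$params$q_pl_ecf  # 0.0281 mL/min
#' @export
drug_preset <- function(drug, species = c("rat", "human")) {
  species <- match.arg(species)
  pool <- if (species == "rat") .rat_presets() else .human_presets()
  if (!drug %in% names(pool))
    stop(sprintf("no %s preset for drug '%s' (available: %s)",
                 species, drug, paste(names(pool), collapse = ", ")))
  p <- pool[[drug]]
  feats <- if (species == "rat") p$features else "per1"
  c(list(drug = drug, species = species,
         structure = model_structure(features = feats, species = species)),
    p[setdiff(names(p), "features")])
}

#' @export
print.cns_drug <- function(x, ...) {
  cat("CNS drug parameters\n")
  num <- x[!vapply(x, is.null, TRUE)]
  num$theta_cov <- NULL
  v <- unlist(num)
  v <- v[!is.na(v)]
  for (n in names(v)) cat(sprintf("  %-10s %g\n", n, v[[n]]))
  if (!is.null(x$theta_cov) && nrow(x$theta_cov)) {
    cat("  covariate effects:\n")
    for (i in seq_len(nrow(x$theta_cov)))
      cat(sprintf("    %s x (1 + %g * %s)\n", x$theta_cov$parameter[i],
                  x$theta_cov$theta[i], x$theta_cov$covariate[i]))
  }
  invisible(x)
}
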