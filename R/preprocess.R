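#' Free fraction in plasma from ultrafiltration
#'
#' Ratio of the drug concentration in the plasma ultrafiltrate to the
#' concentration in the pooled plasma sample.
#'
#' @param ultrafiltrate_conc ultrafiltrate concentration (ng/mL).
#' @param pooled_plasma_conc pooled plasma concentration (ng/mL), > 0.
#' @param tol tolerance on ratios marginally above 1 (assay noise).
#' @return Unbound fraction in (0, 1].
#' @examples
#' free_fraction(15, 100)  # 0.15
#' @export
free_fraction <- function(ultrafiltrate_conc, pooled_plasma_conc,
                          tol = 1e-8) {
  if (any(pooled_plasma_conc <= 0))
    stop("pooled plasma concentration must be > 0")
  if (any(ultrafiltrate_conc < 0))
    stop("ultrafiltrate concentration must be >= 0")
  r <- ultrafiltrate_conc / pooled_plasma_conc
  if (any(r > 1 + tol))
    stop("free fraction exceeds 1: ultrafiltrate above pooled plasma")
  pmin(r, 1)
}

#' In-vivo microdialysis recovery by retrodialysis
#'
#' Relative loss of drug from the perfusion fluid across the probe membrane:
#' `(C_in - C_dial) / C_in`, where `C_in` is the concentration perfused into
#' the probe and `C_dial` the concentration recovered in the dialysate. By
#' the assumption of symmetric probe transport this loss equals the recovery
#' of tissue drug during sampling.
#'
#' @param c_in perfusate concentration (ng/mL), > 0.
#' @param c_dial dialysate concentration during retrodialysis (ng/mL).
#' @return Recovery in \[0, 1\].
#' @examples
#' in_vivo_recovery(100, 40)  # 0.6
#' @export
in_vivo_recovery <- function(c_in, c_dial) {
  if (any(c_in <= 0)) stop("perfusate concentration must be > 0")
  if (any(c_dial < 0)) stop("dialysate concentration must be >= 0")
  if (any(c_dial > c_in))
    stop("dialysate exceeds perfusate concentration: retrodialysis failure")
  (c_in - c_dial) / c_in
}

#' Correct a dialysate concentration for probe recovery
#'
#' Microdialysis understates the unbound tissue concentration by the probe
#' recovery; division by the recovery restores it.
#'
#' @param c_dial measured dialysate concentration (ng/mL).
#' @param recovery probe recovery in (0, 1], e.g. from
#'   [in_vivo_recovery()].
#' @return Unbound tissue concentration (ng/mL).
#' @examples
#' correct_dialysate(25, 0.75)  # 33.33
#' @export
correct_dialysate <- function(c_dial, recovery) {
  if (any(recovery <= 0) || any(recovery > 1))
    stop("recovery must lie in (0, 1]")
  c_dial / recovery
}

.csv_columns <- c("SUBJECT", "DRUG", "SPECIES", "BW_KG", "TIME_MIN", "CMT",
                  "DV_NGML", "ASSAY", "AMT_MGKG", "INF_MIN", "INHIBITOR",
                  "DOSEGRP", "LLOQ_NGML")

#' Read a study dataset CSV
#'
#' Reads the event-record dataset dialect: one row per observation plus one
#' dosing row per infusion (dosing rows have `AMT_MGKG`/`INF_MIN` set and
#' missing `DV_NGML`). See [assemble_dataset()] for the column meanings.
#'
#' @param path CSV file path.
#' @return A raw records data frame (not yet model-ready).
#' @export
read_study_csv <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(.csv_columns, names(raw))
  if (length(miss))
    stop(sprintf("dataset is missing required column(s): %s",
                 paste(miss, collapse = ", ")))
  raw$DOSEGRP <- as.character(raw$DOSEGRP)
  raw
}

#' Assemble a model-ready study dataset
#'
#' Converts raw event records into model-ready unbound concentrations:
#' doses are converted from mg/kg to ng via the subject body weight,
#' dialysate rows are corrected for in-vivo recovery using the per-drug
#' recovery constants in the drug configuration, total-plasma rows are
#' converted to unbound concentrations via the unbound fraction `f_p`, and
#' rows below the lower limit of quantification are flagged and (by default)
#' excluded from fitting.
#'
#' @param raw a raw records data frame from [read_study_csv()] or
#'   [generate_rat_study()]/[generate_human_study()]. Required columns:
#'   `SUBJECT`, `DRUG`, `SPECIES`, `BW_KG`, `TIME_MIN`, `CMT` (one of
#'   `plasma, brain_ecf, csf_lv, csf_tfv, csf_cm, csf_sas, csf_evd`),
#'   `DV_NGML`, `ASSAY` (`total | unbound | dialysate | corrected_unbound`),
#'   `AMT_MGKG`, `INF_MIN`, `INHIBITOR` (0/1), `DOSEGRP`, `LLOQ_NGML`.
#' @param drug_config list with at least `params` (for `f_p`) and, when the
#'   data contain dialysate rows, `recovery` (named vector of probe
#'   recoveries per compartment). [drug_preset()] output plus a `recovery`
#'   element is sufficient.
#' @param lloq_rule `"exclude"` (default) drops below-LLOQ rows from the
#'   fitting set; `"half"` substitutes LLOQ/2.
#' @return An object of class `cns_study`: list with `observations` (data
#'   frame: `subject, drug, time, compartment, conc, assay, blq, inhibitor,
#'   dosegrp`), `doses` (named list of [dose_event()] lists per subject),
#'   `species` and `bw` (named per subject, kg).
#' @examples
#' # 1 mg/kg into a 0.25 kg rat is a 250,000 ng dose
#' @export
assemble_dataset <- function(raw, drug_config,
                             lloq_rule = c("exclude", "half")) {
  lloq_rule <- match.arg(lloq_rule)
  miss <- setdiff(.csv_columns, names(raw))
  if (length(miss))
    stop(sprintf("dataset is missing required column(s): %s",
                 paste(miss, collapse = ", ")))
  ok_cmt <- c(.all_compartments, "")
  if (any(!raw$CMT %in% ok_cmt))
    stop(sprintf("unknown compartment label(s): %s",
                 paste(unique(setdiff(raw$CMT, ok_cmt)), collapse = ", ")))
  f_p <- drug_config$params$f_p %||% 1
  recovery <- drug_config$recovery

  is_dose <- !is.na(raw$AMT_MGKG) & raw$AMT_MGKG > 0
  obs <- raw[!is_dose & !is.na(raw$DV_NGML), , drop = FALSE]
  dos <- raw[is_dose, , drop = FALSE]

  subjects <- unique(raw$SUBJECT)
  no_dose <- setdiff(unique(obs$SUBJECT), unique(dos$SUBJECT))
  if (length(no_dose))
    stop(sprintf("subject(s) without any dose event: %s",
                 paste(no_dose, collapse = ", ")))

  conc <- obs$DV_NGML
  assay <- obs$ASSAY
  # dialysate -> recovery-corrected unbound tissue concentration
  dial <- assay == "dialysate"
  if (any(dial)) {
    if (is.null(recovery))
      stop("dialysate rows present but drug_config carries no recovery constants")
    r <- recovery[obs$CMT[dial]]
    if (any(is.na(r)))
      stop("missing recovery constant for a sampled compartment")
    conc[dial] <- correct_dialysate(conc[dial], r)
    assay[dial] <- "corrected_unbound"
  }
  # total plasma -> unbound plasma
  tot <- assay == "total"
  if (any(tot)) {
    conc[tot] <- conc[tot] * f_p
    assay[tot] <- "unbound"
  }
  blq <- !is.na(obs$LLOQ_NGML) & obs$LLOQ_NGML > 0 & conc < obs$LLOQ_NGML
  if (lloq_rule == "half") {
    conc[blq] <- obs$LLOQ_NGML[blq] / 2
    keep <- rep(TRUE, length(conc))
  } else {
    keep <- !blq
  }
  observations <- data.frame(
    subject = obs$SUBJECT, drug = obs$DRUG, time = obs$TIME_MIN,
    compartment = obs$CMT, conc = conc, assay = assay, blq = blq,
    inhibitor = obs$INHIBITOR, dosegrp = as.character(obs$DOSEGRP),
    stringsAsFactors = FALSE)[keep, , drop = FALSE]
  rownames(observations) <- NULL

  bw <- tapply(raw$BW_KG, raw$SUBJECT, function(x) x[1])
  doses <- lapply(split(dos, dos$SUBJECT), function(d) {
    lapply(seq_len(nrow(d)), function(i)
      dose_event(amount = d$AMT_MGKG[i] * d$BW_KG[i] * 1e6,  # mg/kg -> ng
                 duration = d$INF_MIN[i], start = d$TIME_MIN[i]))
  })
  structure(list(observations = observations, doses = doses,
                 species = raw$SPECIES[1], bw = bw),
            class = "cns_study")
}

#' @export
print.cns_study <- function(x, ...) {
  o <- x$observations
  cat(sprintf("CNS study dataset (%s): %d subjects, %d observations\n",
              x$species, length(x$doses), nrow(o)))
  print(table(o$compartment))
  invisible(x)
}
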