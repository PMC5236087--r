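# Printed study designs: animals, doses (mg/kg unless noted), infusion
# minutes, per-stream sampling counts per subject (printed totals divided by
# the number of animals) and windows, inhibitor availability. Exact
# per-animal schedules are not published; evenly spaced grids are used.
.rat_designs <- function() {
  list(
    acetaminophen = list(n = 16, doses = 16, infusion = 10, inhibitor = FALSE,
      streams = list(plasma = list(n = 4, window = 240),
                     brain_ecf = list(n = 12, window = 240),
                     csf_lv = list(n = 12, window = 240),
                     csf_cm = list(n = 12, window = 240))),
    atenolol = list(n = 5, doses = 10, infusion = 1, inhibitor = FALSE,
      streams = list(plasma = list(n = 6, window = 120),
                     brain_ecf = list(n = 21, window = 120))),
    methotrexate = list(n = 23, doses = c(40, 80), infusion = 10,
      inhibitor = TRUE,
      streams = list(plasma = list(n = 8, window = 300),
                     brain_ecf = list(n = 15, window = 300),
                     csf_lv = list(n = 15, window = 300),
                     csf_cm = list(n = 15, window = 300))),
    morphine = list(n = 65, doses = c(4, 10, 40), infusion = 10,
      inhibitor = TRUE,
      streams = list(plasma = list(n = 13, window = 360),
                     brain_ecf = list(n = 4, window = 360))),
    paliperidone = list(n = 21, doses = 0.5, infusion = 20, inhibitor = TRUE,
      streams = list(plasma = list(n = 9, window = 360),
                     brain_ecf = list(n = 16, window = 240),
                     csf_cm = list(n = 16, window = 240))),
    phenytoin = list(n = 14, doses = c(20, 30, 40), infusion = 10,
      inhibitor = TRUE,
      streams = list(plasma = list(n = 8, window = 480),
                     brain_ecf = list(n = 11, window = 480))),
    quinidine = list(n = 41, doses = c(10, 20), infusion = 10,
      inhibitor = TRUE,
      streams = list(plasma = list(n = 8, window = 360),
                     brain_ecf = list(n = 14, window = 360),
                     csf_lv = list(n = 14, window = 360),
                     csf_cm = list(n = 14, window = 360))),
    remoxipride = list(n = 29, doses = c(4, 8, 16), infusion = 30,
      inhibitor = FALSE,
      streams = list(plasma = list(n = 7, window = 240),
                     brain_ecf = list(n = 4, window = 240))),
    risperidone = list(n = 16, doses = 2, infusion = 20, inhibitor = TRUE,
      streams = list(plasma = list(n = 8, window = 360),
                     brain_ecf = list(n = 14, window = 240),
                     csf_cm = list(n = 14, window = 240))))
}

# Human designs (doses in mg, converted to mg/kg at the 70 kg reference
# weight). Acetaminophen: 7 TBI patients, EVD-sampled CSF; morphine: 2 TBI
# patients, microdialysis brain ECF ("normal" tissue).
.human_designs <- function() {
  list(
    acetaminophen = list(n = 7, dose_mg = 1000, infusion = 30,
      streams = list(plasma = list(n = 5, window = 360),
                     csf_evd = list(n = 8, window = 330)),
      evd = data.frame(q_lv_evd = 0.15, v_evd = 10),  # synthetic defaults
      stream_sigma = c(plasma = 0.250, csf_evd = 0.640)),
    morphine = list(n = 2, dose_mg = 10, infusion = 10,
      streams = list(plasma = list(n = 12, window = 180),
                     brain_ecf = list(n = 37, window = 180)),
      evd = NULL,
      stream_sigma = c(plasma = 0.0960, brain_ecf = 0.779)))
}

# Microdialysis probe recoveries used by the generator (plausible in-vivo
# range); recorded in the design so correction is exactly invertible.
.default_recovery <- c(brain_ecf = 0.4, csf_lv = 0.5, csf_cm = 0.5)

#' Built-in study design for a drug/species pair
#'
#' Returns the published experimental design realised as a simulation
#' design: subjects, dose levels and infusion durations, per-stream sampling
#' grids (evenly spaced within the printed sampling windows at the printed
#' per-stream sample counts), observed compartments, inhibitor arms,
#' residual-error SDs, inter-individual SDs (human), probe recoveries and
#' body weight.
#'
#' @param drug one of the nine rat compounds, or `"acetaminophen"` /
#'   `"morphine"` for `species = "human"`.
#' @param species `"rat"` or `"human"`.
#' @return An object of class `cns_design`.
#' @examples
#' default_design("acetaminophen", "rat")$doses  # 16 mg/kg
#' @export
default_design <- function(drug, species = c("rat", "human")) {
  species <- match.arg(species)
  pre <- drug_preset(drug, species)  # errors on unknown pairs
  if (species == "rat") {
    d <- .rat_designs()[[drug]]
    rec <- .default_recovery[intersect(names(.default_recovery),
                                       names(d$streams))]
    out <- list(drug = drug, species = "rat", n = d$n, doses = d$doses,
                infusion = d$infusion, inhibitor = d$inhibitor,
                streams = d$streams, sigma = pre$sigma, omega = NULL,
                recovery = rec, f_p = pre$params$f_p, bw = 0.25, lloq = 0)
  } else {
    d <- .human_designs()[[drug]]
    out <- list(drug = drug, species = "human", n = d$n,
                doses = d$dose_mg / 70, infusion = d$infusion,
                inhibitor = FALSE, streams = d$streams,
                sigma = d$stream_sigma, omega = pre$omega,
                recovery = .default_recovery["brain_ecf"],
                f_p = pre$params$f_p, bw = 70, lloq = 0, evd = d$evd)
  }
  structure(out, class = "cns_design")
}

# Plasma is serial blood sampling: geometrically spaced from 2 min so the
# distribution phase is observed. Dialysate streams are contiguous
# collection bins time-stamped at the bin midpoint (the usual microdialysis
# convention), with short bins over the first third of the window — the
# first midpoint falls inside the brain/CSF equilibration transient — and
# longer bins after.
.stream_times <- function(stream, name = "") {
  n <- stream$n
  w <- stream$window
  if (name == "plasma")
    return(round(exp(seq(log(2), log(w), length.out = n)), 1))
  mid <- function(edges) (utils::head(edges, -1) + utils::tail(edges, -1)) / 2
  if (n < 4) return(mid(seq(0, w, length.out = n + 1)))
  n1 <- ceiling(2 * n / 3)
  c(mid(seq(0, w / 3, length.out = n1 + 1)),
    mid(seq(w / 3, w, length.out = n - n1 + 1)))
}

.design_arms <- function(design) {
  inh <- if (isTRUE(design$inhibitor)) c(0, 1) else 0
  expand.grid(dose = design$doses, inhibitor = inh,
              KEEP.OUT.ATTRS = FALSE)
}

.noisy <- function(true_conc, sigma, err_kind = "proportional",
                   sigma_add = 0) {
  dv <- true_conc * (1 + stats::rnorm(length(true_conc), 0, sigma))
  if (err_kind == "mixed")
    dv <- dv + stats::rnorm(length(true_conc), 0, sigma_add)
  dv
}

.study_rows <- function(subject, drug, species, bw, time, cmt, dv, assay,
                        amt = NA_real_, inf = NA_real_, inhibitor = 0,
                        dosegrp = "", lloq = 0) {
  data.frame(SUBJECT = subject, DRUG = drug, SPECIES = species, BW_KG = bw,
             TIME_MIN = time, CMT = cmt, DV_NGML = dv, ASSAY = assay,
             AMT_MGKG = amt, INF_MIN = inf, INHIBITOR = inhibitor,
             DOSEGRP = dosegrp, LLOQ_NGML = lloq, stringsAsFactors = FALSE)
}

#' Generate a synthetic rat microdialysis study
#'
#' Simulates the event-record dataset a rat brain-distribution experiment
#' would yield under the model: true profiles per dose/inhibitor arm (with
#' the categorical covariate effects applied), probe loss applied to
#' dialysate streams (raw dialysate is recorded so the preprocessing step
#' has to invert it), plasma recorded as total or unbound according to the
#' drug's protein binding, and proportional residual error per stream. Noisy
#' values are kept as drawn (the proportional error model can produce
#' negative values at high noise; censoring them would bias refitting).
#' Deterministic for a given seed.
#'
#' @param design a `cns_design` from [default_design()].
#' @param params true [drug_parameters()]; defaults to the drug preset.
#' @param seed RNG seed.
#' @param sigma named per-stream residual SDs; defaults to the design's.
#' @param recovery named per-stream probe recoveries; defaults to the
#'   design's.
#' @return A raw records data frame (the dataset CSV dialect) with the truth
#'   (parameters, sigma, recovery, design) attached as attribute
#'   `"truth"`. Feed to [assemble_dataset()].
#' @export
generate_rat_study <- function(design, params = NULL, seed = 1,
                               sigma = design$sigma,
                               recovery = design$recovery) {
  pre <- drug_preset(design$drug, "rat")
  if (is.null(params)) params <- pre$params
  structure_ <- pre$structure
  system <- system_parameters("rat", bw = design$bw)
  set.seed(seed)
  arms <- .design_arms(design)
  rows <- vector("list", 2 * design$n)
  plasma_assay <- if (params$f_p < 1) "total" else "unbound"
  # solve once per arm; subjects within an arm share regimen and grid
  arm_prof <- vector("list", nrow(arms))
  all_times <- sort(unique(unlist(Map(.stream_times, design$streams, names(design$streams)))))
  for (a in seq_len(nrow(arms))) {
    p_a <- .subject_params(params, arms$inhibitor[a],
                           as.character(arms$dose[a]))
    dose <- dose_event(arms$dose[a] * design$bw * 1e6, design$infusion)
    arm_prof[[a]] <- solve_profile(structure_, p_a, system, dose, all_times)
  }
  for (i in seq_len(design$n)) {
    a <- ((i - 1) %% nrow(arms)) + 1
    id <- sprintf("R%03d", i)
    prof <- arm_prof[[a]]
    dg <- as.character(arms$dose[a])
    sub_rows <- list(.study_rows(id, design$drug, "rat", design$bw,
                                 time = 0, cmt = "", dv = NA_real_,
                                 assay = "", amt = arms$dose[a],
                                 inf = design$infusion,
                                 inhibitor = arms$inhibitor[a], dosegrp = dg,
                                 lloq = design$lloq))
    for (s in names(design$streams)) {
      tt <- .stream_times(design$streams[[s]], s)
      true_c <- prof$conc[match(tt, all_times), s]
      if (s == "plasma") {
        dv <- .noisy(true_c, sigma[["plasma"]])
        assay <- plasma_assay
      } else {
        dv <- .noisy(true_c * recovery[[s]], sigma[[s]])
        assay <- "dialysate"
      }
      sub_rows[[length(sub_rows) + 1]] <-
        .study_rows(id, design$drug, "rat", design$bw, tt, s, dv, assay,
                    inhibitor = arms$inhibitor[a], dosegrp = dg,
                    lloq = design$lloq)
    }
    rows[[i]] <- do.call(rbind, sub_rows)
  }
  out <- do.call(rbind, rows[seq_len(design$n)])
  rownames(out) <- NULL
  attr(out, "truth") <- list(params = params, sigma = sigma,
                             recovery = recovery, design = design)
  out
}

#' Generate a synthetic human study
#'
#' Simulates clinical concentration data for a translated human model:
#' subject-level plasma parameters are drawn from the log-normal
#' inter-individual model, profiles are solved with the human system volumes
#' and allometrically scaled brain parameters, and each observed stream
#' (plasma, EVD-drained CSF or microdialysis brain ECF) receives its
#' residual error. Brain ECF is recorded as raw dialysate via the probe
#' recovery; EVD CSF is sampled directly.
#'
#' @param design a human `cns_design` from [default_design()].
#' @param model optional `cns_human_model` ([build_human_model()]) supplying
#'   structure and parameters; defaults to the built-in human plasma preset
#'   with brain parameters scaled from the rat preset (for morphine, the
#'   4 mg/kg dose-group estimate).
#' @param seed RNG seed.
#' @param omega named inter-individual SDs; defaults to the design's.
#' @param sigma named per-stream residual SDs; defaults to the design's.
#' @return Raw records data frame with attribute `"truth"`.
#' @export
generate_human_study <- function(design, model = NULL, seed = 1,
                                 omega = design$omega,
                                 sigma = design$sigma) {
  if (design$species != "human") stop("design must be a human design")
  if (is.null(model)) {
    hum <- drug_preset(design$drug, "human")
    rat <- drug_preset(design$drug, "rat")
    cfg <- translation_config(evd = design$evd)
    model <- build_human_model(rat$params, cfg, hum$params,
      dose_group = if (design$drug == "morphine") "4" else NULL)
  }
  set.seed(seed)
  rows <- vector("list", design$n)
  all_times <- sort(unique(unlist(Map(.stream_times, design$streams, names(design$streams)))))
  dose <- dose_event(design$doses * design$bw * 1e6, design$infusion)
  plasma_assay <- if (model$params$f_p < 1) "total" else "unbound"
  realized <- matrix(NA_real_, design$n, length(omega),
                     dimnames = list(NULL, names(omega)))
  for (i in seq_len(design$n)) {
    id <- sprintf("H%03d", i)
    p_i <- model$params
    if (!is.null(omega))
      for (nm in names(omega)) {
        p_i[[nm]] <- iiv_realize(model$params[[nm]], omega[[nm]], 1)
        realized[i, nm] <- p_i[[nm]]
      }
    prof <- solve_profile(model$structure, p_i, model$system, dose,
                          all_times)
    sub_rows <- list(.study_rows(id, design$drug, "human", design$bw,
                                 time = 0, cmt = "", dv = NA_real_,
                                 assay = "", amt = design$doses,
                                 inf = design$infusion, lloq = design$lloq))
    for (s in names(design$streams)) {
      tt <- .stream_times(design$streams[[s]], s)
      true_c <- prof$conc[match(tt, all_times), s]
      if (s == "plasma") {
        dv <- .noisy(true_c, sigma[["plasma"]])
        assay <- plasma_assay
      } else if (s == "brain_ecf") {
        dv <- .noisy(true_c * design$recovery[["brain_ecf"]], sigma[[s]])
        assay <- "dialysate"
      } else {
        dv <- .noisy(true_c, sigma[[s]])
        assay <- "unbound"
      }
      sub_rows[[length(sub_rows) + 1]] <-
        .study_rows(id, design$drug, "human", design$bw, tt, s, dv, assay,
                    lloq = design$lloq)
    }
    rows[[i]] <- do.call(rbind, sub_rows)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "truth") <- list(model = model, omega = omega, sigma = sigma,
                             design = design,
                             subject_params = as.data.frame(realized))
  out
}

#' Write a generated study to CSV (with companion truth metadata)
#'
#' @param raw a raw records data frame from the generators.
#' @param path CSV output path.
#' @param metadata_path optional JSON path for the generating truth
#'   (parameters, residual SDs, recoveries, design).
#' @return `path`, invisibly.
#' @export
write_study_csv <- function(raw, path, metadata_path = NULL) {
  utils::write.csv(raw, path, row.names = FALSE, quote = FALSE)
  if (!is.null(metadata_path)) {
    tr <- attr(raw, "truth")
    jsonlite::write_json(tr, metadata_path, auto_unbox = TRUE, digits = NA,
                         na = "null", null = "null", force = TRUE)
  }
  invisible(path)
}
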