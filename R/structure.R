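#' @keywords internal
.all_compartments <- c("plasma", "per1", "per2", "brain_ecf", "brain_icf",
                       "csf_lv", "csf_tfv", "csf_cm", "csf_sas", "csf_evd")

.core_compartments <- c("plasma", "brain_ecf", "csf_lv", "csf_tfv",
                        "csf_cm", "csf_sas")

.known_features <- c("per1", "per2", "icf", "bcsfb_efflux",
                     "enterohepatic", "evd")

#' Define a model topology
#'
#' The model always contains plasma, brain ECF and the four CSF compartments
#' in series (lateral ventricle, third+fourth ventricle, cisterna magna,
#' subarachnoid space), linked by a single drug dispersion flow. Optional
#' features add peripheral compartments, brain ICF exchange, BCSFB efflux
#' from the lateral ventricle back to plasma, enterohepatic recirculation of
#' eliminated drug, and (human only) an external ventricular drain sampling
#' compartment.
#'
#' @param features character vector drawn from `"per1"`, `"per2"`, `"icf"`,
#'   `"bcsfb_efflux"`, `"enterohepatic"`, `"evd"`.
#' @param species `"rat"` or `"human"`; the EVD feature is clinical and only
#'   valid for humans.
#' @param q_lv_evd,v_evd EVD drainage flow (mL/min) and reservoir volume
#'   (mL); required when `"evd"` is enabled.
#' @return An object of class `cns_structure`.
#' @examples
#' model_structure(c("per1", "per2", "bcsfb_efflux"))
#' @export
model_structure <- function(features = character(0),
                            species = c("rat", "human"),
                            q_lv_evd = NA_real_, v_evd = NA_real_) {
  species <- match.arg(species)
  bad <- setdiff(features, .known_features)
  if (length(bad))
    stop(sprintf("unknown structural feature(s): %s",
                 paste(bad, collapse = ", ")))
  has <- function(f) f %in% features
  if (has("per2") && !has("per1"))
    stop("a second peripheral compartment requires the first (per2 without per1)")
  if (has("evd") && species != "human")
    stop("the EVD sampling compartment is a clinical feature (species must be human)")
  if (has("evd") && (is.na(q_lv_evd) || is.na(v_evd) ||
                     q_lv_evd < 0 || v_evd <= 0))
    stop("evd requires q_lv_evd >= 0 and v_evd > 0")
  cmts <- c("plasma",
            if (has("per1")) "per1", if (has("per2")) "per2",
            "brain_ecf", if (has("icf")) "brain_icf",
            "csf_lv", "csf_tfv", "csf_cm", "csf_sas",
            if (has("evd")) "csf_evd")
  structure(list(
    compartments = cmts,
    per1 = has("per1"), per2 = has("per2"), icf_enabled = has("icf"),
    bcsfb_efflux_enabled = has("bcsfb_efflux"),
    enterohepatic_enabled = has("enterohepatic"),
    evd_enabled = has("evd"),
    species = species, q_lv_evd = q_lv_evd, v_evd = v_evd),
    class = "cns_structure")
}

#' Build a model structure from a drug configuration
#'
#' Accepts either the name of one of the nine built-in rat presets (feature
#' sets implied by which parameters could be identified for each drug) or an
#' explicit configuration list with elements `features`, `species` and, when
#' the EVD drain is enabled, `q_lv_evd` / `v_evd`.
#'
#' @param drug_config a drug name (character) or a configuration list.
#' @return A `cns_structure`.
#' @examples
#' build_structure("methotrexate")$bcsfb_efflux_enabled  # TRUE
#' build_structure(list(features = "per1", species = "rat"))
#' @export
build_structure <- function(drug_config) {
  if (is.character(drug_config) && length(drug_config) == 1)
    return(drug_preset(drug_config, "rat")$structure)
  stopifnot(is.list(drug_config))
  model_structure(features = drug_config$features %||% character(0),
                  species = drug_config$species %||% "rat",
                  q_lv_evd = drug_config$q_lv_evd %||% NA_real_,
                  v_evd = drug_config$v_evd %||% NA_real_)
}

#' @export
print.cns_structure <- function(x, ...) {
  cat(sprintf("CNS model structure (%s): %s\n", x$species,
              paste(x$compartments, collapse = " ")))
  flags <- c(bcsfb_efflux = x$bcsfb_efflux_enabled, icf = x$icf_enabled,
             enterohepatic = x$enterohepatic_enabled, evd = x$evd_enabled)
  cat("  features:", if (any(flags)) paste(names(flags)[flags],
                                           collapse = ", ") else "none", "\n")
  invisible(x)
}

#' Read or write a drug/model configuration as JSON
#'
#' Serialises a drug configuration (structure flags, parameter values,
#' covariate coefficient table, species) so a fitted or preset model
#' round-trips losslessly through a text file.
#'
#' @param config a list as returned by [drug_preset()] (elements `drug`,
#'   `species`, `structure`, `params`, optionally `sigma`, `omega`).
#' @param path file path.
#' @return `read_drug_config()` returns the configuration list;
#'   `write_drug_config()` returns `path` invisibly.
#' @export
write_drug_config <- function(config, path) {
  st <- config$structure
  feats <- c("per1", "per2")[c(st$per1, st$per2)]
  if (st$icf_enabled) feats <- c(feats, "icf")
  if (st$bcsfb_efflux_enabled) feats <- c(feats, "bcsfb_efflux")
  if (st$enterohepatic_enabled) feats <- c(feats, "enterohepatic")
  if (st$evd_enabled) feats <- c(feats, "evd")
  par <- config$params
  out <- list(
    drug = config$drug, species = config$species,
    features = as.list(feats),
    q_lv_evd = st$q_lv_evd, v_evd = st$v_evd,
    params = par[setdiff(names(par), "theta_cov")],
    theta_cov = par$theta_cov,
    sigma = as.list(config$sigma), omega = as.list(config$omega))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       na = "null", null = "null")
  invisible(path)
}

#' @rdname write_drug_config
#' @export
read_drug_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  num <- function(x) if (is.null(x)) NA_real_ else as.numeric(x)
  pr <- raw$params
  tc <- raw$theta_cov
  if (!is.null(tc) && !is.data.frame(tc)) tc <- as.data.frame(tc)
  if (is.data.frame(tc) && nrow(tc) == 0) tc <- NULL
  params <- drug_parameters(
    cl_pl = num(pr$cl_pl), q_pl_ecf = num(pr$q_pl_ecf),
    q_diff = num(pr$q_diff), v_pl = num(pr$v_pl),
    q_pl_per1 = num(pr$q_pl_per1), q_pl_per2 = num(pr$q_pl_per2),
    q_lv_pl = num(pr$q_lv_pl), q_ecf_icf = num(pr$q_ecf_icf),
    v_per1 = num(pr$v_per1), v_per2 = num(pr$v_per2),
    fraction = num(pr$fraction), f_p = num(pr$f_p) %|na|% 1,
    theta_cov = tc)
  st <- model_structure(features = unlist(raw$features) %||% character(0),
                        species = raw$species,
                        q_lv_evd = num(raw$q_lv_evd),
                        v_evd = num(raw$v_evd))
  out <- list(drug = raw$drug, species = raw$species, structure = st,
              params = params)
  if (length(raw$sigma)) out$sigma <- unlist(raw$sigma)
  if (length(raw$omega)) out$omega <- unlist(raw$omega)
  out
}

`%|na|%` <- function(a, b) if (length(a) == 0 || is.na(a)) b else a
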