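test_that("free fraction is the ultrafiltrate / pooled plasma ratio", {
  expect_equal(free_fraction(15, 100), 0.15)
  expect_equal(free_fraction(80, 80), 1.0)
  expect_error(free_fraction(10, 0), "> 0")
  expect_error(free_fraction(120, 100), "exceeds 1")
})

test_that("retrodialysis recovery is the relative probe loss", {
  expect_equal(in_vivo_recovery(100, 40), 0.60)
  expect_equal(in_vivo_recovery(100, 0), 1.0)
  expect_equal(in_vivo_recovery(100, 100), 0.0)
  expect_error(in_vivo_recovery(100, 110), "retrodialysis failure")
  expect_error(in_vivo_recovery(0, 0), "> 0")
})

test_that("recovery correction inverts the probe loss exactly", {
  expect_equal(correct_dialysate(25, 0.75), 25 / 0.75)
  expect_equal(correct_dialysate(42, 1.0), 42)
  expect_error(correct_dialysate(25, 0), "\\(0, 1\\]")
  expect_error(correct_dialysate(25, 1.2), "\\(0, 1\\]")

  set.seed(3)
  for (k in 1:25) {
    conc <- runif(1, 0.1, 1e4)
    r <- runif(1, 0.05, 1)
    expect_equal(correct_dialysate(conc * r, r), conc, tolerance = 1e-12)
  }
})

test_that("dataset assembly converts doses, recoveries and protein binding", {
  raw <- data.frame(
    SUBJECT = c("r1", "r1", "r1", "r1"), DRUG = "phenytoin",
    SPECIES = "rat", BW_KG = 0.25,
    TIME_MIN = c(0, 30, 60, 60),
    CMT = c("", "plasma", "brain_ecf", "csf_lv"),
    DV_NGML = c(NA, 1000, 20, 10),
    ASSAY = c("", "total", "dialysate", "dialysate"),
    AMT_MGKG = c(1, NA, NA, NA), INF_MIN = c(10, NA, NA, NA),
    INHIBITOR = 0, DOSEGRP = "1", LLOQ_NGML = 0,
    stringsAsFactors = FALSE)
  cfg <- list(params = drug_preset("phenytoin")$params,
              recovery = c(brain_ecf = 0.4, csf_lv = 0.5))
  ds <- assemble_dataset(raw, cfg)

  # 1 mg/kg into 0.25 kg -> 250,000 ng
  expect_equal(ds$doses$r1[[1]]$amount, 250000)
  expect_equal(ds$doses$r1[[1]]$duration, 10)
  # 91% protein binding: total 1000 -> unbound 90
  obs <- ds$observations
  expect_equal(obs$conc[obs$compartment == "plasma"], 90)
  expect_equal(obs$assay[obs$compartment == "plasma"], "unbound")
  # dialysate corrected by the per-compartment recovery
  expect_equal(obs$conc[obs$compartment == "brain_ecf"], 20 / 0.4)
  expect_equal(obs$conc[obs$compartment == "csf_lv"], 10 / 0.5)
  expect_true(all(obs$assay[obs$compartment != "plasma"] ==
                  "corrected_unbound"))
})

test_that("remoxipride plasma converts with 26% binding", {
  raw <- data.frame(
    SUBJECT = "r1", DRUG = "remoxipride", SPECIES = "rat", BW_KG = 0.25,
    TIME_MIN = c(0, 30), CMT = c("", "plasma"), DV_NGML = c(NA, 1000),
    ASSAY = c("", "total"), AMT_MGKG = c(1, NA), INF_MIN = c(10, NA),
    INHIBITOR = 0, DOSEGRP = "1", LLOQ_NGML = 0, stringsAsFactors = FALSE)
  ds <- assemble_dataset(raw, list(params = drug_preset("remoxipride")$params))
  expect_equal(ds$observations$conc, 740)
})

test_that("assembly is idempotent on already-corrected data", {
  des <- small_design()
  raw <- generate_rat_study(des, seed = 5)
  cfg <- preset_config("atenolol", des)
  ds1 <- assemble_dataset(raw, cfg)
  # re-encode the model-ready observations as records and assemble again
  o <- ds1$observations
  raw2 <- data.frame(
    SUBJECT = o$subject, DRUG = o$drug, SPECIES = "rat", BW_KG = 0.25,
    TIME_MIN = o$time, CMT = o$compartment, DV_NGML = o$conc,
    ASSAY = o$assay, AMT_MGKG = NA_real_, INF_MIN = NA_real_,
    INHIBITOR = o$inhibitor, DOSEGRP = o$dosegrp, LLOQ_NGML = 0,
    stringsAsFactors = FALSE)
  dose_rows <- raw[!is.na(raw$AMT_MGKG) & raw$AMT_MGKG > 0, ]
  ds2 <- assemble_dataset(rbind(dose_rows, raw2), cfg)
  o2 <- ds2$observations[order(ds2$observations$subject,
                               ds2$observations$compartment,
                               ds2$observations$time), ]
  o1 <- o[order(o$subject, o$compartment, o$time), ]
  expect_equal(o2$conc, o1$conc)
  expect_equal(o2$assay, o1$assay)
})

test_that("assembly rejects malformed records", {
  raw <- data.frame(
    SUBJECT = "r9", DRUG = "atenolol", SPECIES = "rat", BW_KG = 0.25,
    TIME_MIN = 30, CMT = "plasma", DV_NGML = 10, ASSAY = "unbound",
    AMT_MGKG = NA_real_, INF_MIN = NA_real_, INHIBITOR = 0, DOSEGRP = "1",
    LLOQ_NGML = 0, stringsAsFactors = FALSE)
  expect_error(assemble_dataset(raw, list(params = reduced_params())),
               "without any dose")
  raw$CMT <- "cortex"
  expect_error(assemble_dataset(raw, list(params = reduced_params())),
               "unknown compartment")
  expect_error(assemble_dataset(raw[, -1], list(params = reduced_params())),
               "missing required column")
})

test_that("below-LLOQ rows are excluded or substituted as configured", {
  raw <- data.frame(
    SUBJECT = "r1", DRUG = "atenolol", SPECIES = "rat", BW_KG = 0.25,
    TIME_MIN = c(0, 30, 60), CMT = c("", "plasma", "plasma"),
    DV_NGML = c(NA, 100, 2), ASSAY = c("", "unbound", "unbound"),
    AMT_MGKG = c(1, NA, NA), INF_MIN = c(10, NA, NA), INHIBITOR = 0,
    DOSEGRP = "1", LLOQ_NGML = 5, stringsAsFactors = FALSE)
  cfg <- list(params = reduced_params())
  excl <- assemble_dataset(raw, cfg)
  expect_equal(nrow(excl$observations), 1)
  half <- assemble_dataset(raw, cfg, lloq_rule = "half")
  expect_equal(nrow(half$observations), 2)
  expect_equal(half$observations$conc[2], 2.5)
  expect_true(half$observations$blq[2])
})

test_that("the CSV round trip preserves a generated study", {
  des <- small_design(n = 2, plasma_n = 4, dial_n = 4)
  raw <- generate_rat_study(des, seed = 8)
  path <- withr::local_tempfile(fileext = ".csv")
  write_study_csv(raw, path)
  back <- read_study_csv(path)
  expect_equal(back$DV_NGML, raw$DV_NGML, tolerance = 1e-12)
  expect_equal(back$CMT, raw$CMT)
  expect_equal(nrow(back), nrow(raw))
})
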