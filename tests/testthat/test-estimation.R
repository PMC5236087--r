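test_that("the categorical covariate model reproduces the printed effects", {
  expect_equal(apply_covariate(5, 0.3, 0), 5)
  expect_equal(apply_covariate(0.00458, 1.62, 1), 0.0120, tolerance = 1e-3)

  # percent increases implied by the coefficient: 100 * theta
  printed <- c(morphine = 162, paliperidone = 43.4, phenytoin = 35.5,
               quinidine = 443, risperidone = 124, methotrexate = 409)
  for (d in names(printed)) {
    tc <- drug_preset(d)$params$theta_cov
    th <- tc$theta[tc$parameter == "q_pl_ecf" & tc$covariate == "INHIBITOR"]
    expect_equal(100 * th, printed[[d]])
  }
  expect_equal(apply_covariate(2, -0.5, 1), 1)
  expect_error(apply_covariate(1, -1.5, 1), "non-positive")
  expect_error(apply_covariate(0, 0.5, 1), "> 0")
})

test_that("residual variance follows the proportional and mixed models", {
  expect_equal(residual_variance(100, error_model(c(plasma = 0.3)),
                                 "plasma"), 900)
  em_mixed <- error_model(c(plasma = 0.3), "mixed", sigma_add = 2)
  expect_equal(residual_variance(0, em_mixed, "plasma"), 4)
  expect_equal(residual_variance(0, error_model(c(plasma = 0.3)),
                                 "plasma"), 0)
  expect_error(error_model(c(plasma = 0.3), "mixed", sigma_add = 0),
               "sigma_add > 0")
  expect_error(residual_variance(10, error_model(c(plasma = 0.3)), "csf_lv"),
               "no sigma")
})

test_that("the ELS objective matches a brute-force record-by-record oracle", {
  des <- small_design("quinidine", n = 4, plasma_n = 6, dial_n = 6)
  raw <- generate_rat_study(des, seed = 21)
  pre <- drug_preset("quinidine")
  ds <- assemble_dataset(raw, preset_config("quinidine", des))
  em <- error_model(pre$sigma)

  ofv <- els_objective(ds, pre$params, em, pre$structure, rat_sys)

  # independent summation: per-record simulation and variance
  obs <- ds$observations
  floor <- (1e-6 * max(obs$conc))^2
  brute <- 0
  for (i in seq_len(nrow(obs))) {
    p_i <- cnspk:::.subject_params(pre$params, obs$inhibitor[i],
                                   obs$dosegrp[i])
    prof <- solve_profile(pre$structure, p_i, rat_sys,
                          ds$doses[[obs$subject[i]]], c(0, obs$time[i]))
    pred <- prof$conc[2, obs$compartment[i]]
    if (obs$compartment[i] == "plasma" && obs$assay[i] == "unbound")
      pred <- pred * pre$params$f_p
    v <- max(pre$sigma[[obs$compartment[i]]]^2 * pred^2, floor)
    brute <- brute + (obs$conc[i] - pred)^2 / v + log(v)
  }
  expect_rel_equal(ofv, brute, 1e-8)
})

test_that("simple ELS identities hold", {
  # perfect fit with unit variance gives OFV 0; one residual of 2 at
  # variance 4 gives 1 + log 4
  raw <- data.frame(
    SUBJECT = "r1", DRUG = "x", SPECIES = "rat", BW_KG = 0.25,
    TIME_MIN = c(0, 50, 100), CMT = c("", "plasma", "plasma"),
    DV_NGML = c(NA, 1, 1), ASSAY = c("", "unbound", "unbound"),
    AMT_MGKG = c(1, NA, NA), INF_MIN = c(10, NA, NA), INHIBITOR = 0,
    DOSEGRP = "1", LLOQ_NGML = 0, stringsAsFactors = FALSE)
  p <- reduced_params(cl_pl = 1e-9, v_pl = 250000)  # C_PL ~ 1 after dosing
  ds <- assemble_dataset(raw, list(params = p))
  em_unit <- error_model(c(plasma = 0), "mixed", sigma_add = 1)
  ofv <- els_objective(ds, p, em_unit, reduced_structure, rat_sys)
  expect_lt(abs(ofv), 1e-3)  # predictions equal observations, var = 1

  raw$DV_NGML[2:3] <- c(3, 1)  # one residual of 2
  ds2 <- assemble_dataset(raw, list(params = p))
  em4 <- error_model(c(plasma = 0), "mixed", sigma_add = 2)
  ofv2 <- els_objective(ds2, p, em4, reduced_structure, rat_sys)
  expect_equal(ofv2, (2^2 / 4 + log(4)) + (0 / 4 + log(4)), tolerance = 1e-3)
})

test_that("rescaling concentrations leaves nested OFV differences unchanged", {
  des <- small_design(n = 3, plasma_n = 6, dial_n = 6)
  raw <- generate_rat_study(des, seed = 13)
  pre <- drug_preset("atenolol")
  ds <- assemble_dataset(raw, preset_config("atenolol", des))
  em <- error_model(pre$sigma)
  p_full <- pre$params
  p_red <- pre$params
  p_red$q_diff <- p_red$q_diff * 2  # a nested alternative

  d0 <- els_objective(ds, p_red, em, pre$structure, rat_sys) -
        els_objective(ds, p_full, em, pre$structure, rat_sys)
  # a change of concentration units scales observations and dose amounts
  # alike; the model is linear in dose, so every prediction scales too
  k <- 1000
  ds_k <- ds
  ds_k$observations$conc <- ds_k$observations$conc * k
  ds_k$doses <- lapply(ds_k$doses, function(dl) lapply(dl, function(d) {
    d$amount <- d$amount * k
    d
  }))
  dk <- els_objective(ds_k, p_red, em, pre$structure, rat_sys) -
        els_objective(ds_k, p_full, em, pre$structure, rat_sys)
  expect_equal(dk, d0, tolerance = 1e-6)
})

test_that("noise-free data are recovered essentially exactly", {
  des <- small_design(n = 3, plasma_n = 8, dial_n = 8)
  zero_sigma <- setNames(rep(0, length(des$sigma)), names(des$sigma))
  raw <- generate_rat_study(des, seed = 1, sigma = zero_sigma)
  pre <- drug_preset("atenolol")
  ds <- assemble_dataset(raw, preset_config("atenolol", des))

  init <- pre$params
  set.seed(2)
  for (nm in c("cl_pl", "q_pl_per1", "q_pl_ecf", "q_diff", "v_pl", "v_per1"))
    init[[nm]] <- init[[nm]] * exp(rnorm(1, 0, 0.2))
  # the assumed residual SD must be small on noise-free data: the ELS
  # log-variance term shifts the prediction scale by ~sigma^2 otherwise
  fit <- suppressWarnings(fit_naive_pooled(
    ds, pre$structure, rat_sys, init,
    error_model = error_model(c(plasma = 0.01, brain_ecf = 0.01)),
    estimate_sigma = FALSE, n_starts = 1))
  for (nm in c("cl_pl", "q_pl_per1", "q_pl_ecf", "q_diff", "v_pl", "v_per1"))
    expect_rel_equal(fit$params[[nm]], pre$params[[nm]], 1e-3)
})

test_that("a structurally impossible fit is flagged", {
  des <- small_design(n = 2, plasma_n = 4, dial_n = 6)
  raw <- generate_rat_study(des, seed = 3)
  pre <- drug_preset("atenolol")
  ds <- assemble_dataset(raw, preset_config("atenolol", des))
  init <- pre$params
  init$q_pl_ecf <- 0  # brain observations but no BBB transfer
  res <- tryCatch(
    suppressWarnings(fit_naive_pooled(ds, pre$structure, rat_sys, init,
                                      fixed = "q_pl_ecf", n_starts = 1)),
    error = function(e) e)
  if (inherits(res, "cns_fit")) {
    expect_true(any(grepl("near-zero predictions", res$diagnostics)))
  } else {
    expect_s3_class(res, "error")
  }
})

test_that("likelihood-ratio comparison uses the chi-square 95% threshold", {
  expect_true(lrt_compare(100, 103.85, 1)$significant)
  expect_false(lrt_compare(100, 103.83, 1)$significant)
  expect_false(lrt_compare(100, 105.0, 2)$significant)  # threshold 5.99
  expect_true(lrt_compare(100, 106.0, 2)$significant)
  expect_error(lrt_compare(100, 99, 1), "nesting violation")
})

test_that("log-normal inter-individual realisation has the stated moments", {
  expect_identical(iiv_realize(3.7, 0, 1), 3.7)
  set.seed(99)
  draws <- iiv_realize(2.5, 0.5, 10000)
  expect_rel_equal(sd(log(draws)), 0.5, 0.03)
  expect_rel_equal(median(draws), 2.5, 0.03)
  expect_error(iiv_realize(1, -0.1), ">= 0")
})
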