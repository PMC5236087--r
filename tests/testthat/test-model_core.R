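test_that("drug presets reproduce the identified structural feature sets", {
  expect_true(build_structure("methotrexate")$bcsfb_efflux_enabled)
  expect_true(build_structure("methotrexate")$per2)

  at <- build_structure("atenolol")
  expect_true(at$per1)
  expect_false(at$per2)
  expect_false(at$icf_enabled)
  expect_false(at$bcsfb_efflux_enabled)

  expect_true(build_structure("quinidine")$icf_enabled)
  expect_true(build_structure("paliperidone")$icf_enabled)
  expect_true(build_structure("acetaminophen")$enterohepatic_enabled)
  for (d in c("paliperidone", "risperidone"))
    expect_false(build_structure(d)$per1)

  # core compartments always present
  for (d in c("acetaminophen", "risperidone", "methotrexate"))
    expect_true(all(c("plasma", "brain_ecf", "csf_lv", "csf_tfv", "csf_cm",
                      "csf_sas") %in% build_structure(d)$compartments))
})

test_that("invalid structures are rejected", {
  expect_error(model_structure("per2"), "per2 without per1")
  expect_error(model_structure("evd", species = "rat"), "human")
  expect_error(model_structure("warp_drive"), "unknown structural feature")
  expect_error(build_structure(list(features = "per2", species = "rat")),
               "per2 without per1")
  expect_error(model_structure("evd", species = "human"), "q_lv_evd")
})

test_that("ode_rhs satisfies the elementary mass-balance identities", {
  st <- build_structure("methotrexate")
  p <- drug_preset("methotrexate")$params
  zero <- numeric(10)

  expect_equal(ode_rhs(zero, 0, p, rat_sys, st), setNames(zero,
    c("plasma", "per1", "per2", "brain_ecf", "brain_icf", "csf_lv",
      "csf_tfv", "csf_cm", "csf_sas", "csf_evd")))

  d <- ode_rhs(zero, 0, p, rat_sys, st, rate = 7.5)
  expect_equal(unname(d[1]), 7.5)
  expect_equal(unname(d[-1]), numeric(9))

  # with elimination, BCSFB efflux returns mass to plasma, so the total
  # drain is exactly CL * C_PL
  set.seed(11)
  for (k in 1:20) {
    amt <- runif(10, 0, 1e5)
    amt[10] <- 0  # rat model: EVD absent
    d <- ode_rhs(amt, 0, p, rat_sys, st, rate = 0)
    cl_eff <- p$cl_pl  # methotrexate: no enterohepatic recirculation
    expect_equal(sum(d), -cl_eff * amt[1] / p$v_pl, tolerance = 1e-10)
  }

  # no elimination: closed system
  p0 <- p
  p0$cl_pl <- 0
  p0$q_lv_pl <- 0.2  # efflux recirculates, still conservative
  for (k in 1:5) {
    amt <- runif(10, 0, 1e5)
    amt[10] <- 0
    d <- ode_rhs(amt, 0, p0, rat_sys, st, rate = 0)
    expect_lt(abs(sum(d)) / max(abs(d)), 1e-12)
  }

  expect_error(ode_rhs(numeric(4), 0, p, rat_sys, st), "length")
})

test_that("solve_profile matches closed-form steady states", {
  # degenerate plasma-only model: C_ss = rate / CL
  p <- drug_parameters(cl_pl = 10, q_pl_ecf = 0, q_diff = 0, v_pl = 100)
  prof <- solve_profile(reduced_structure, p, rat_sys,
                        dose_event(1e6, 5000), times = c(0, 4999))
  expect_equal(unname(prof$conc[2, "plasma"]), (1e6 / 5000) / 10,
               tolerance = 1e-6)

  # full acetaminophen structure: all loops return to plasma, so the
  # steady state sees only the net clearance CL * (1 - fraction)
  pre <- drug_preset("acetaminophen")
  prof <- solve_profile(pre$structure, pre$params, rat_sys,
                        dose_event(1e7, 3e4), times = c(0, 29990))
  cl_net <- pre$params$cl_pl * (1 - pre$params$fraction)
  expect_equal(unname(prof$conc[2, "plasma"]), (1e7 / 3e4) / cl_net,
               tolerance = 1e-4)
})

test_that("steady-state brain ECF partitioning matches the closed form", {
  expect_equal(
    steady_state_ecf_ratio(reduced_params(0.0281, 0.0556)),
    0.0281 / (0.0281 + 0.0556), tolerance = 1e-12)
  expect_equal(round(steady_state_ecf_ratio(reduced_params(0.0281, 0.0556)), 4),
               0.3357)
  expect_equal(steady_state_ecf_ratio(reduced_params(0.02, 0)), 1.0)
  expect_equal(steady_state_ecf_ratio(reduced_params(0, 0.02)), 0.0)
  expect_error(steady_state_ecf_ratio(reduced_params(0, 0)), "positive")

  # simulated ratio converges to the closed form for random parameter draws
  set.seed(42)
  for (k in 1:20) {
    p <- reduced_params(q_pl_ecf = runif(1, 0.001, 0.1),
                        q_diff = runif(1, 0.005, 0.1),
                        cl_pl = runif(1, 1, 50),
                        f_p = runif(1, 0.1, 1))
    t_ss <- 5e4
    prof <- solve_profile(reduced_structure, p, rat_sys,
                          dose_event(1e8, t_ss), times = c(0, t_ss - 1))
    ratio <- prof$conc[2, "brain_ecf"] / (p$f_p * prof$conc[2, "plasma"])
    expect_rel_equal(ratio, steady_state_ecf_ratio(p), 1e-3)
  }
})

test_that("the unidirectional equal-flow CSF chain equilibrates in series", {
  p <- reduced_params()
  prof <- solve_profile(reduced_structure, p, rat_sys,
                        dose_event(1e8, 5e4), times = c(0, 49990))
  csf <- prof$conc[2, c("csf_lv", "csf_tfv", "csf_cm", "csf_sas")]
  expect_rel_equal(csf, rep(prof$conc[2, "brain_ecf"], 4), 1e-3)
})

test_that("mass is conserved to 1e-8 once elimination is disabled", {
  p <- reduced_params(cl_pl = 0)
  prof <- solve_profile(reduced_structure, p, rat_sys, dose_event(1234, 10),
                        times = seq(10, 600, by = 10))
  expect_rel_equal(total_amount(prof), rep(1234, length(prof$time)), 1e-8)

  # also with peripherals and ICF active
  st <- model_structure(c("per1", "per2", "icf"))
  p2 <- drug_parameters(cl_pl = 0, q_pl_ecf = 0.03, q_diff = 0.05,
                        v_pl = 100, q_pl_per1 = 5, v_per1 = 300,
                        q_pl_per2 = 1, v_per2 = 150, q_ecf_icf = 0.02)
  prof2 <- solve_profile(st, p2, rat_sys, dose_event(1234, 10),
                         times = seq(10, 600, by = 10))
  expect_rel_equal(total_amount(prof2), rep(1234, length(prof2$time)), 1e-8)
})

test_that("simulated concentrations stay non-negative", {
  set.seed(9)
  for (k in 1:5) {
    p <- reduced_params(q_pl_ecf = runif(1, 0, 0.1), q_diff = runif(1, 0, 0.1),
                        cl_pl = runif(1, 0, 100), v_pl = runif(1, 50, 5000))
    prof <- solve_profile(reduced_structure, p, rat_sys, dose_event(1e6, 10),
                          times = seq(0, 360, by = 5))
    expect_gte(min(prof$conc), -1e-12 * max(prof$conc))
  }
})

test_that("brain ECF exposure is non-decreasing in the BBB clearance", {
  auc <- vapply(c(0.005, 0.01, 0.02, 0.04, 0.08), function(q) {
    p <- reduced_params(q_pl_ecf = q)
    prof <- solve_profile(reduced_structure, p, rat_sys, dose_event(1e6, 10),
                          times = seq(0, 360, by = 5))
    sum(diff(prof$time) * (head(prof$conc[, "brain_ecf"], -1) +
                           tail(prof$conc[, "brain_ecf"], -1)) / 2)
  }, 0)
  expect_true(all(diff(auc) > 0))
})

test_that("compiled and R right-hand sides integrate identically", {
  pre <- drug_preset("methotrexate")
  doses <- list(dose_event(5e5, 10), dose_event(2e5, 15, start = 120))
  tt <- seq(0, 300, by = 20)
  a <- solve_profile(pre$structure, pre$params, rat_sys, doses, tt)
  b <- solve_profile(pre$structure, pre$params, rat_sys, doses, tt,
                     compiled = FALSE)
  # compare on the scale of each compartment's profile: near-zero early
  # CSF values are tolerance-dominated, and the two integrations take
  # different adaptive step sequences
  scale <- matrix(apply(abs(b$conc), 2, max), nrow(b$conc),
                  ncol(b$conc), byrow = TRUE)
  expect_lt(max(abs(a$conc - b$conc) / scale), 1e-5)
})

test_that("overlapping infusions superpose at event boundaries", {
  # two overlapping constant infusions == one infusion at the summed rate
  p <- drug_parameters(cl_pl = 10, q_pl_ecf = 0, q_diff = 0, v_pl = 100)
  tt <- c(0, 5, 10, 20, 40)
  two <- solve_profile(reduced_structure, p, rat_sys,
                       list(dose_event(1000, 20), dose_event(500, 10, start = 5)),
                       tt)
  expect_equal(two$conc[2, "plasma"],
               solve_profile(reduced_structure, p, rat_sys,
                             dose_event(250, 5), tt)$conc[2, "plasma"],
               tolerance = 1e-8)
})

test_that("a drug configuration round-trips losslessly through JSON", {
  path <- withr::local_tempfile(fileext = ".json")
  cfg <- drug_preset("morphine")
  write_drug_config(cfg, path)
  back <- read_drug_config(path)
  expect_equal(back$drug, "morphine")
  expect_equal(unclass(back$params)[names(back$params) != "theta_cov"],
               unclass(cfg$params)[names(cfg$params) != "theta_cov"])
  expect_equal(back$params$theta_cov$theta, cfg$params$theta_cov$theta)
  expect_equal(back$sigma, cfg$sigma)
  expect_equal(back$structure$compartments, cfg$structure$compartments)
})
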