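# Shared fixtures: small parameter sets and designs kept cheap enough for
# unit tests; study-scale runs live in the acceptance tests.

rat_sys <- system_parameters("rat")

# reduced structure: BBB + dispersion chain only
reduced_params <- function(q_pl_ecf = 0.03, q_diff = 0.05, cl_pl = 10,
                           v_pl = 100, f_p = 1) {
  drug_parameters(cl_pl = cl_pl, q_pl_ecf = q_pl_ecf, q_diff = q_diff,
                  v_pl = v_pl, f_p = f_p)
}

reduced_structure <- model_structure()

# a scaled-down design for fast generate/fit round trips
small_design <- function(drug = "atenolol", n = 4, plasma_n = 8,
                         dial_n = 8) {
  d <- default_design(drug, "rat")
  d$n <- n
  for (s in names(d$streams))
    d$streams[[s]]$n <- if (s == "plasma") plasma_n else dial_n
  d
}

# dataset assembly shortcut: preset config plus the design's recoveries
preset_config <- function(drug, design) {
  c(drug_preset(drug, "rat"), list(recovery = design$recovery))
}

# total amount in the system over time for conservation checks
total_amount <- function(profile) rowSums(profile$amounts)

expect_rel_equal <- function(object, expected, tol) {
  expect_lt(max(abs(object - expected) / pmax(abs(expected), 1e-300)), tol)
}
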