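test_that("hill_effect matches its closed form", {
  expect_equal(hill_effect(0, 50, 1, 2), 0)
  expect_equal(hill_effect(50, 50, 0.8, 1.7), 0.4)   # emax/2 at ec50
  expect_equal(hill_effect(10, 1, 1, 1), 10 / 11)
  expect_error(hill_effect(-1, 50, 1, 1), ">= 0")
  # monotone non-decreasing in dose
  d <- sort(stats::runif(50, 0, 1e4))
  expect_true(all(diff(hill_effect(d, 123, 0.9, 1.3)) >= 0))
})

test_that("make_pulse has the stated peak, asymptote and crossing times", {
  p <- noiseless_params()
  expect_equal(make_pulse(p$upstroke_time, p),
               p$baseline_level + p$amplitude)
  expect_equal(make_pulse(50, p), p$baseline_level, tolerance = 1e-8)
  expect_equal(make_pulse(-1, p), p$baseline_level)
  # analytic width at recovery vs brute-force scan of a dense evaluation
  for (r in c(0.8, 0.5, 0.2)) {
    tt <- seq(0, 4, by = 1e-4)
    v <- make_pulse(tt, p)
    w <- brute_force_width(tt, v, which.max(v), p$baseline_level,
                           p$baseline_level + p$amplitude, r)
    expect_equal(w, pulse_width_analytic(p, r), tolerance = 1e-3)
  }
})

test_that("apply_drug_effect follows the Hill oracle and flags", {
  profs <- default_cell_profiles()
  drug <- list(compound = "toy", ec50_p80 = 100, emax_p80 = 0.4,
               hill_p80 = 1, ec50_amp = 1000, emax_amp = 0.2,
               ead_onset_dose = NA, ead_probability_at_top = 0,
               cessation_dose = 500, irregularity_gain = 0, top_dose = 1000)
  base <- profs$control$baseline
  # dose 0: identity
  e0 <- apply_drug_effect(profs$control, drug, 0)
  expect_identical(e0$params, base)
  expect_false(e0$ead); expect_false(e0$ceased)
  # dose = ec50, emax 0.4, sensitivity 1 -> plateau and tau scaled by 1.2
  e1 <- apply_drug_effect(profs$control, drug, 100)
  expect_equal(e1$params$plateau_time, base$plateau_time * 1.2)
  expect_equal(e1$params$decay_tau, base$decay_tau * 1.2)
  # cessation is deterministic at the threshold
  expect_true(apply_drug_effect(profs$control, drug, 500)$ceased)
  expect_false(apply_drug_effect(profs$control, drug, 499)$ceased)
  # the progeria line scales the fractional effect by its sensitivity
  e2 <- apply_drug_effect(profs$progeria, drug, 100)
  expect_equal(e2$params$plateau_time / profs$progeria$baseline$plateau_time,
               1 + 0.2 * profs$progeria$sensitivity)
  expect_error(apply_drug_effect(profs$control, drug, -5), ">= 0")
})

test_that("simulate_trace emits floor(duration/CL) pulses and is seeded", {
  p <- noiseless_params(cl = 1.2)
  tr <- simulate_trace(NULL, params_override = p, duration = 60, fs = 50,
                       seed = 1)
  expect_equal(tr$meta$n_pulses, 50L)
  tr2 <- simulate_trace(NULL, params_override = p, duration = 60, fs = 50,
                        seed = 1)
  expect_identical(tr$values, tr2$values)
  expect_error(simulate_trace(NULL, params_override = p, fs = 10),
               "sampling rate")
})

test_that("ceased wells render baseline only and phenotype to the sentinel", {
  reg <- load_registry()
  profs <- default_cell_profiles()
  eff <- default_drug_effects(reg)
  drug <- drug_effect(eff, "Dofetilide")   # ceases at its top dose, 10 nM
  tr <- simulate_trace(profs$control, drug = drug, dose = 10, seed = 2)
  expect_true(tr$meta$ceased)
  expect_equal(tr$meta$n_pulses, 0L)
  ph <- phenotype(tr)
  expect_equal(ph$pn, 0L)
  expect_true(all(is.na(c(ph$p80, ph$r82, ph$cl, ph$amp, ph$csd))))
})

test_that("simulate_plate lays out the stated replicate structure", {
  reg <- load_registry()
  profs <- noiseless_profiles()
  plate <- simulate_plate(reg, profiles = profs["control"],
                          replicates = c(control = 1L), seed = 5,
                          duration = 12)
  # 11 compounds x 4 doses + 1 DMSO well, each with a pre and a post trace
  expect_equal(length(plate$traces), 2L * (11L * 4L + 1L))
  expect_equal(nrow(plate$platemap), 2L * (11L * 4L + 1L))
  expect_setequal(unique(plate$platemap$phase), c("pre", "post"))
  # full two-line default layout: 6 and 4 replicate wells per dose
  counts <- table(plate$platemap$compound == "DMSO", plate$platemap$phase)
  expect_true(all(counts["TRUE", ] == 1L))
  # determinism under the master seed
  plate2 <- simulate_plate(reg, profiles = profs["control"],
                           replicates = c(control = 1L), seed = 5,
                           duration = 12)
  expect_identical(lapply(plate$traces, `[[`, "values"),
                   lapply(plate2$traces, `[[`, "values"))
})

test_that("P80 is non-decreasing across doses for a prolonging drug", {
  reg <- load_registry()
  profs <- noiseless_profiles()
  eff <- default_drug_effects(reg)
  for (cmpd in c("Cisapride", "Chlorpromazine")) {
    drug <- drug_effect(eff, cmpd)
    p80 <- vapply(registry_doses(reg, cmpd), function(d) {
      phenotype(simulate_trace(profs$control, drug = drug, dose = d,
                               seed = 1))$p80
    }, numeric(1))
    expect_true(all(diff(p80) >= -1e-9))
  }
})

test_that("DMSO percent changes are exactly zero in noiseless mode", {
  reg <- load_registry()[1, ]
  plate <- simulate_plate(reg, profiles = noiseless_profiles()["control"],
                          replicates = c(control = 2L), seed = 9,
                          duration = 12, jitter_sd = 0)
  wt <- phenotype_wells(plate$traces)
  dmso <- wt[wt$compound == "DMSO", ]
  expect_equal(nrow(dmso), 2L)
  for (col in paste0("pct_", c("p80", "r82", "cl", "amp", "pn", "csd"))) {
    expect_identical(unname(unlist(dmso[[col]])), c(0, 0))
  }
})

test_that("default baseline calibration hits the two cell-line targets", {
  # the full-scale check (>= 100 wells) runs in test-acceptance.R; this is
  # a fast sanity check at reduced n
  profs <- default_cell_profiles()
  m_c <- measure_baseline_p80(profs$control, n_wells = 40, seed = 7)
  m_p <- measure_baseline_p80(profs$progeria, n_wells = 40, seed = 7)
  expect_lt(abs(m_c$mean_p80 - 0.70), 0.04)
  expect_lt(abs(m_p$mean_p80 - 0.98), 0.05)
  expect_gt(m_p$mean_p80, m_c$mean_p80)
})
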