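pred_table <- function(post_r82, pct_p80, ceased = FALSE, amp_frac = 1,
                       compound = "X", line = "control", wells_per_dose = 6) {
  n <- 4 * wells_per_dose
  rep4 <- function(x) rep(x, length.out = n)
  data.frame(
    well_id = sprintf("W%02d", seq_len(n)), cell_line = line,
    compound = compound, dose_index = rep(1:4, each = wells_per_dose),
    pre_amp = 1, post_amp = rep4(amp_frac), post_r82 = rep4(post_r82),
    pct_p80 = rep4(pct_p80), pct_r82 = 0, pct_cl = 0, pct_amp = 0,
    pct_pn = 0, pct_csd = 0, ceased = rep4(ceased),
    stringsAsFactors = FALSE)
}

test_that("classify_arrhythmia applies its decision rules and precedence", {
  # DMSO-like: no change anywhere -> NONE
  t0 <- pred_table(post_r82 = 2.5, pct_p80 = 0)
  expect_equal(as.character(classify_arrhythmia(t0, "X", "control")$value),
               "NONE")
  # all top-dose wells ceased -> OTHER
  t1 <- pred_table(post_r82 = 2.5, pct_p80 = 10)
  t1$ceased[t1$dose_index == 4] <- TRUE
  r1 <- classify_arrhythmia(t1, "X", "control")
  expect_equal(as.character(r1$value), "OTHER")
  expect_equal(r1$ordinal_score, 1L)
  # strong mean prolongation alone -> OTHER
  t2 <- pred_table(post_r82 = 2.5, pct_p80 = c(10, 20, 50, 150))
  t2$pct_p80 <- rep(c(10, 20, 50, 150), each = 6)
  expect_equal(as.character(classify_arrhythmia(t2, "X", "control")$value),
               "OTHER")
  # EAD wells take precedence over cessation
  t3 <- t1
  t3$post_r82[t3$dose_index == 3] <- 3.6
  r3 <- classify_arrhythmia(t3, "X", "control")
  expect_equal(as.character(r3$value), "TYPE_A")
  expect_equal(r3$ordinal_score, 2L)
  # amplitude-collapsed wells cannot carry an EAD call
  t4 <- pred_table(post_r82 = 3.6, pct_p80 = 0, amp_frac = 0.2)
  expect_equal(as.character(classify_arrhythmia(t4, "X", "control")$value),
               "NONE")
})

test_that("a dofetilide-like synthetic run classifies TYPE_A from flags", {
  reg <- load_registry()
  profs <- default_cell_profiles()
  eff <- default_drug_effects(reg)
  drug <- drug_effect(eff, "Dofetilide")
  traces <- list()
  set.seed(301)
  for (w in 1:4) for (d in c(1, 3)) {
    pre <- simulate_trace(profs$progeria)
    post <- simulate_trace(profs$progeria, drug = drug,
                           dose = registry_doses(reg, "Dofetilide")[d])
    wid <- sprintf("W%d%d", w, d)
    pre$meta <- utils::modifyList(pre$meta, list(
      well_id = wid, cell_line = "progeria", compound = "Dofetilide",
      dose_index = d, phase = "pre"))
    post$meta <- utils::modifyList(post$meta, list(
      well_id = wid, cell_line = "progeria", compound = "Dofetilide",
      dose_index = d, phase = "post"))
    traces <- c(traces, list(pre, post))
  }
  wt <- phenotype_wells(traces)
  res <- classify_arrhythmia(wt, "Dofetilide", "progeria")
  expect_equal(as.character(res$value), "TYPE_A")
})

test_that("p80_at_cmax interpolates in log-dose with endpoint clamping", {
  # grid-point identity
  r <- p80_at_cmax(c(1, 10, 100, 1000), c(0, 10, 40, 80), cmax = 10)
  expect_equal(r$value, 10); expect_false(r$extrapolated)
  # geometric midpoint of a decade is the arithmetic mean in log-dose
  r2 <- p80_at_cmax(c(1, 10, 100, 1000), c(0, 100, 100, 100),
                    cmax = sqrt(10))
  expect_equal(r2$value, 50)
  # diltiazem: Cmax 128 nM above its 90 nM top dose -> clamp + flag
  reg <- load_registry()
  dil <- reg[reg$name == "Diltiazem", ]
  r3 <- p80_at_cmax(unlist(dil[paste0("dose", 1:4)]), c(1, 2, 3, 4),
                    cmax = dil$cmax)
  expect_equal(r3$value, 4)
  expect_true(r3$extrapolated)
  # ceased top dose dropped before interpolating; all ceased -> sentinel
  r4 <- p80_at_cmax(c(1, 10, 100, 1000), c(0, 10, 40, NA), cmax = 1000)
  expect_equal(r4$value, 40); expect_true(r4$extrapolated)
  r5 <- p80_at_cmax(c(1, 10), c(NA, NA), cmax = 5)
  expect_false(r5$defined); expect_true(is.na(r5$value))
})

test_that("p80_at_cmax equals a dense sampling of the log-linear interpolant", {
  doses <- c(2, 30, 250, 4000); chg <- c(3, 25, 90, 60)
  dense_x <- seq(log10(2), log10(4000), length.out = 20001)
  dense_y <- stats::approx(log10(doses), chg, xout = dense_x)$y
  for (cmax in c(2.7, 55, 900, 3999)) {
    oracle <- dense_y[which.min(abs(dense_x - log10(cmax)))]
    expect_equal(p80_at_cmax(doses, chg, cmax)$value, oracle,
                 tolerance = 1e-2)
  }
})

test_that("p80_max takes the maximum defined dose mean", {
  expect_equal(p80_max(c(5, 20, 80, 40))$value, 80)
  expect_equal(p80_max(c(NA, NA, 33, NA))$value, 33)
  expect_false(p80_max(c(NA_real_, NA))$defined)
})

test_that("normalize_panel min-max scales within the panel", {
  ps <- data.frame(compound = c("a", "b", "c"), cell_line = "control",
                   risk_label = c("high", "intermediate", "low"),
                   atype = "NONE", atype_score = 0L,
                   p80_at_cmax = c(0, 50, 100), p80_max = c(10, 20, 30),
                   extrapolated = FALSE, stringsAsFactors = FALSE)
  out <- normalize_panel(ps)
  expect_equal(out$p80_at_cmax_norm, c(0, 0.5, 1))
  expect_equal(out$p80_max_norm, c(0, 0.5, 1))
  # invariant to affine rescaling of the raw values
  ps2 <- ps
  ps2$p80_at_cmax <- 3.7 * ps2$p80_at_cmax - 12
  expect_equal(normalize_panel(ps2)$p80_at_cmax_norm, out$p80_at_cmax_norm)
  # zero range -> 0.5 with a warning; single compound -> error
  ps3 <- ps; ps3$p80_max <- 7
  expect_warning(out3 <- normalize_panel(ps3), "zero range")
  expect_equal(out3$p80_max_norm, rep(0.5, 3))
  expect_error(normalize_panel(ps[1, ]), "at least 2")
})

test_that("predictor panels order risk tiers and favor the progeria range", {
  res <- pipeline_fixture()
  for (line in c("control", "progeria")) {
    ps <- res$predictors[[line]]
    expect_equal(nrow(ps), 11L)
    expect_true(all(ps$p80_at_cmax_norm >= 0 & ps$p80_at_cmax_norm <= 1))
    score_by <- tapply(ps$atype_score, ps$risk_label, mean)
    expect_true(score_by["high"] >= score_by["intermediate"])
    expect_true(score_by["intermediate"] >= score_by["low"])
    # cmax outside the grid flagged for the known Table-1 cases
    expect_true(ps$extrapolated[ps$compound == "Diltiazem"])
  }
  spread <- vapply(res$predictors,
                   function(ps) diff(range(ps$p80_max, na.rm = TRUE)),
                   numeric(1))
  expect_gt(spread[["progeria"]], spread[["control"]])
})
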