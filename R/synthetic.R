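# Seeded synthetic calcium-transient generator. Emulates plate recordings of
# spontaneously beating cardiomyocyte wells: a canonical pulse shape (linear
# upstroke, plateau, exponential decay), lognormal cycle-length variability,
# Gaussian noise, optional linear drift, and per-compound dose-dependent drug
# effects (Hill-type prolongation and amplitude suppression, EAD humps,
# cycle irregularity, beat cessation).

#' Waveform parameters of the synthetic calcium-transient pulse train
#'
#' The canonical pulse rises linearly from `baseline_level` to
#' `baseline_level + amplitude` over `upstroke_time`, holds a plateau for
#' `plateau_time`, then decays exponentially with time constant `decay_tau`.
#' Cycle lengths are drawn lognormally with mean `cycle_length_mean` and
#' coefficient of variation `cycle_length_cv`.
#'
#' @param cycle_length_mean Mean beat-to-beat interval (s).
#' @param cycle_length_cv Coefficient of variation of cycle lengths.
#' @param amplitude Pulse amplitude above baseline (a.u.).
#' @param upstroke_time Upstroke duration (s).
#' @param plateau_time Plateau duration (s).
#' @param decay_tau Exponential decay time constant (s).
#' @param baseline_level Diastolic fluorescence level (a.u.).
#' @param noise_sd Additive Gaussian noise SD (a.u.).
#' @param drift_per_s Linear baseline drift (a.u./s).
#' @return A `waveform_params` list.
#' @export
waveform_params <- function(cycle_length_mean, cycle_length_cv = 0,
                            amplitude = 1, upstroke_time = 0.15,
                            plateau_time = 0.18, decay_tau = 0.25,
                            baseline_level = 0.1, noise_sd = 0,
                            drift_per_s = 0) {
  p <- list(cycle_length_mean = cycle_length_mean,
            cycle_length_cv = cycle_length_cv,
            amplitude = amplitude, upstroke_time = upstroke_time,
            plateau_time = plateau_time, decay_tau = decay_tau,
            baseline_level = baseline_level, noise_sd = noise_sd,
            drift_per_s = drift_per_s)
  with(p, {
    if (any(c(cycle_length_mean, amplitude, upstroke_time, plateau_time,
              decay_tau) <= 0)) {
      stop("durations and amplitude must be > 0")
    }
    if (cycle_length_mean <= upstroke_time + plateau_time) {
      stop("cycle_length_mean must exceed upstroke_time + plateau_time")
    }
    if (cycle_length_cv < 0 || noise_sd < 0) stop("cv and noise_sd must be >= 0")
  })
  structure(p, class = "waveform_params")
}

#' Default cell-line baseline profiles
#'
#' Two synthetic cardiomyocyte lines: `control` and `progeria` (the
#' aged-phenotype line). The shape parameters are calibrated so that the
#' extracted mean 80%-recovery peak width (P80) of undosed wells is about
#' 0.70 s for control and 0.98 s for progeria; the closed-form width is
#' `0.8*upstroke_time + plateau_time + decay_tau*log(5)` (see
#' [pulse_width_analytic()]). `sensitivity` scales the fractional drug
#' effects (prolongation, amplitude suppression, EAD probability,
#' irregularity): the progeria line responds more strongly to every
#' compound, emulating its greater proarrhythmia susceptibility.
#'
#' @return Named list of two `cell_line_profile` objects.
#' @export
default_cell_profiles <- function() {
  list(
    control = cell_line_profile(
      "control",
      waveform_params(cycle_length_mean = 1.3, cycle_length_cv = 0.05,
                      amplitude = 1, upstroke_time = 0.15,
                      plateau_time = 0.178, decay_tau = 0.247,
                      baseline_level = 0.1, noise_sd = 0.02),
      sensitivity = 1.0),
    progeria = cell_line_profile(
      "progeria",
      waveform_params(cycle_length_mean = 1.6, cycle_length_cv = 0.05,
                      amplitude = 1, upstroke_time = 0.18,
                      plateau_time = 0.269, decay_tau = 0.379,
                      baseline_level = 0.1, noise_sd = 0.02),
      sensitivity = 1.5)
  )
}

#' @rdname default_cell_profiles
#' @param line `"control"` or `"progeria"`.
#' @param baseline A `waveform_params` object.
#' @param sensitivity Multiplier on fractional drug effects (>= 0).
#' @export
cell_line_profile <- function(line, baseline, sensitivity = 1) {
  line <- match.arg(line, CELL_LINES)
  stopifnot(inherits(baseline, "waveform_params"), sensitivity >= 0)
  structure(list(line = line, baseline = baseline, sensitivity = sensitivity),
            class = "cell_line_profile")
}

#' Default per-compound drug-effect models
#'
#' Loads the bundled synthetic calibration table (see
#' `inst/extdata/drug_effects_synthetic.csv`; these are design values, not
#' measured data) and attaches each compound's top test dose from the
#' registry, which anchors the EAD-probability ramp and the irregularity
#' scaling.
#'
#' @param registry A `cat_registry` (defaults to the bundled CiPA panel).
#' @return Data frame of class `drug_effect_table`, one row per compound.
#' @export
default_drug_effects <- function(registry = load_registry()) {
  path <- system.file("extdata", "drug_effects_synthetic.csv",
                      package = "catrisk", mustWork = TRUE)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  missing <- setdiff(registry$name, df$compound)
  if (length(missing) > 0L) {
    stop("no effect model for registry compound(s): ",
         paste(missing, collapse = ", "))
  }
  df <- df[df$compound %in% registry$name, , drop = FALSE]
  df$top_dose <- registry$dose4[match(df$compound, registry$name)]
  bad <- with(df, ec50_p80 <= 0 | ec50_amp <= 0 | emax_amp < 0 | emax_amp > 1 |
                ead_probability_at_top < 0 | ead_probability_at_top > 1)
  if (any(bad)) stop("invalid effect-model row(s): ",
                     paste(df$compound[bad], collapse = ", "))
  class(df) <- c("drug_effect_table", "data.frame")
  df
}

#' @rdname default_drug_effects
#' @param effects A `drug_effect_table`.
#' @param compound Compound name.
#' @export
drug_effect <- function(effects, compound) {
  i <- match(compound, effects$compound)
  if (is.na(i)) stop("no effect model for compound '", compound, "'")
  as.list(effects[i, ])
}

#' Hill dose-response
#'
#' Standard Hill equation `emax * dose^h / (dose^h + ec50^h)`; monotone
#' non-decreasing in dose, 0 at dose 0, `emax/2` at `dose = ec50`.
#'
#' @param dose Dose (nM), >= 0; vectorized.
#' @param ec50 Half-maximal dose (nM), > 0.
#' @param emax Maximal fractional effect.
#' @param h Hill coefficient, > 0.
#' @return Fractional effect, same length as `dose`.
#' @export
hill_effect <- function(dose, ec50, emax, h = 1) {
  if (any(dose < 0)) stop("dose must be >= 0")
  if (ec50 <= 0 || h <= 0) stop("ec50 and h must be > 0")
  dh <- dose^h
  emax * dh / (dh + ec50^h)
}

#' Evaluate the canonical pulse shape
#'
#' @param t_rel Time since cycle start (s); vectorized, values outside the
#'   pulse support clamp to `baseline_level`.
#' @param params A `waveform_params`.
#' @param ead If `TRUE`, render an early-afterdepolarization-like secondary
#'   hump on the decay phase.
#' @param ead_cfg EAD rendering configuration, see [ead_config()].
#' @return Fluorescence values (a.u.), noise-free.
#' @export
make_pulse <- function(t_rel, params, ead = FALSE, ead_cfg = ead_config()) {
  u <- params$upstroke_time; p <- params$plateau_time
  tau <- params$decay_tau; A <- params$amplitude; b <- params$baseline_level
  v <- rep(b, length(t_rel))
  up <- t_rel >= 0 & t_rel < u
  v[up] <- b + A * t_rel[up] / u
  pl <- t_rel >= u & t_rel < u + p
  v[pl] <- b + A
  de <- t_rel >= u + p
  v[de] <- b + A * exp(-(t_rel[de] - u - p) / tau)
  if (ead) {
    centre <- u + p + ead_cfg$center_frac * ead_cfg$span_frac * tau
    sigma <- ead_cfg$sigma_frac * tau
    v[de] <- v[de] + ead_cfg$amp_frac * A *
      exp(-(t_rel[de] - centre)^2 / (2 * sigma^2))
  }
  v
}

#' @rdname make_pulse
#' @param amp_frac EAD hump amplitude as a fraction of the main amplitude.
#' @param center_frac Hump centre position as a fraction of the decay span.
#' @param sigma_frac Hump Gaussian SD as a fraction of `decay_tau`.
#' @param span_frac Decay-span definition in units of `decay_tau`.
#' @export
ead_config <- function(amp_frac = 0.3, center_frac = 0.7, sigma_frac = 0.3,
                       span_frac = 2.6) {
  list(amp_frac = amp_frac, center_frac = center_frac,
       sigma_frac = sigma_frac, span_frac = span_frac)
}

#' Closed-form pulse width at fractional recovery
#'
#' For the noise-free canonical pulse the width at recovery fraction `r`
#' (level `baseline + (1-r)*amplitude`) is
#' `(1-(1-r))*upstroke_time + plateau_time + decay_tau*log(1/(1-r))`,
#' e.g. `0.8*u + p + tau*log(5)` at 80% recovery. Used as the analytic
#' oracle for the width-measurement code.
#'
#' @param params A `waveform_params`.
#' @param recovery_frac Recovery fraction in (0, 1).
#' @return Width in seconds.
#' @export
pulse_width_analytic <- function(params, recovery_frac = 0.8) {
  stopifnot(recovery_frac > 0, recovery_frac < 1)
  lambda <- 1 - recovery_frac
  (1 - lambda) * params$upstroke_time + params$plateau_time +
    params$decay_tau * log(1 / lambda)
}

#' Apply a drug-effect model to a cell-line baseline
#'
#' Prolongation scales `plateau_time` and `decay_tau` by
#' `1 + sensitivity * hill_effect(dose, ec50_p80, emax_p80, hill_p80)`.
#' Amplitude is suppressed by the Hill fraction of the amplitude model
#' (capped at 95%). Cycle-length CV gains
#' `sensitivity * irregularity_gain * dose/top_dose`. The EAD flag is drawn
#' with probability ramping linearly from 0 at `ead_onset_dose` to
#' `sensitivity * ead_probability_at_top` at the top dose. Cessation is
#' deterministic at `dose >= cessation_dose` and suppresses the EAD flag.
#' The mean cycle length is extended when the prolonged pulse would no
#' longer fit inside the baseline cycle (repolarization-limited rate).
#'
#' @param profile A `cell_line_profile`.
#' @param drug One row of a `drug_effect_table` as a list (see
#'   [drug_effect()]).
#' @param dose Dose in nM (>= 0). Uses the R random stream for the EAD draw.
#' @return List with elements `params` (modified `waveform_params`), `ead`,
#'   `ceased`, `f_p80`, `f_amp`.
#' @export
apply_drug_effect <- function(profile, drug, dose) {
  if (dose < 0) stop("dose must be >= 0")
  base <- profile$baseline
  sens <- profile$sensitivity
  if (dose == 0) {
    return(list(params = base, ead = FALSE, ceased = FALSE,
                f_p80 = 0, f_amp = 0))
  }
  f_p80 <- sens * hill_effect(dose, drug$ec50_p80, drug$emax_p80, drug$hill_p80)
  f_amp <- min(0.95, sens * hill_effect(dose, drug$ec50_amp, drug$emax_amp, 1))
  p <- base
  p$plateau_time <- base$plateau_time * (1 + f_p80)
  p$decay_tau <- base$decay_tau * (1 + f_p80)
  p$amplitude <- base$amplitude * (1 - f_amp)
  p$cycle_length_cv <- min(0.5, base$cycle_length_cv +
                             sens * drug$irregularity_gain * dose / drug$top_dose)
  p$cycle_length_mean <- max(base$cycle_length_mean,
                             1.15 * (p$upstroke_time + p$plateau_time +
                                       2.2 * p$decay_tau))
  ceased <- !is.na(drug$cessation_dose) && dose >= drug$cessation_dose
  ead <- FALSE
  if (!ceased && !is.na(drug$ead_onset_dose) &&
      drug$ead_probability_at_top > 0) {
    ramp <- if (drug$top_dose > drug$ead_onset_dose) {
      min(1, max(0, (dose - drug$ead_onset_dose) /
                   (drug$top_dose - drug$ead_onset_dose)))
    } else as.numeric(dose >= drug$ead_onset_dose)
    prob <- min(1, sens * drug$ead_probability_at_top * ramp)
    ead <- stats::runif(1) < prob
  }
  list(params = p, ead = ead, ceased = ceased, f_p80 = f_p80, f_amp = f_amp)
}

#' Simulate one well recording
#'
#' Renders a pulse train with lognormal per-cycle lengths, additive Gaussian
#' noise and linear drift. A well flagged `ceased` renders baseline + noise
#' only. A pulse is emitted only when its peak lies inside the record, so in
#' noise-free constant-rate mode the emitted count is
#' `floor(duration / cycle_length)`. Fully reproducible for a fixed `seed`.
#'
#' @param profile A `cell_line_profile`.
#' @param drug Optional drug-effect row (list); `NULL` = undosed.
#' @param dose Dose in nM when `drug` is given.
#' @param duration Recording length (s); >= 10 s recommended.
#' @param fs Sampling rate (Hz); must satisfy `fs * upstroke_time >= 4`.
#' @param seed Optional integer seed (sets the R random stream).
#' @param ead_cfg EAD rendering configuration.
#' @param params_override Optional `waveform_params` to use directly
#'   (bypasses `profile`/`drug`; used for per-well jitter).
#' @return A `cat_trace`; `meta` carries `n_pulses`, `ead`, `ceased`.
#' @export
simulate_trace <- function(profile, drug = NULL, dose = NULL, duration = 30,
                           fs = 50, seed = NULL, ead_cfg = ead_config(),
                           params_override = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(params_override)) {
    params <- params_override; ead <- FALSE; ceased <- FALSE
  } else if (is.null(drug)) {
    params <- profile$baseline; ead <- FALSE; ceased <- FALSE
  } else {
    if (is.null(dose)) stop("dose required when drug is given")
    eff <- apply_drug_effect(profile, drug, dose)
    params <- eff$params; ead <- eff$ead; ceased <- eff$ceased
  }
  if (fs * params$upstroke_time < 4) {
    stop("sampling rate too low to resolve the upstroke (fs*upstroke < 4)")
  }
  n <- round(duration * fs)
  times <- (seq_len(n) - 1) / fs
  meta <- list(cell_line = if (!is.null(profile)) profile$line else NA,
               compound = if (is.null(drug)) NA_character_ else drug$compound,
               dose = if (is.null(dose)) NA_real_ else dose,
               ead = ead, ceased = ceased)
  if (ceased) {
    values <- params$baseline_level + stats::rnorm(n, 0, params$noise_sd) +
      params$drift_per_s * times
    meta$n_pulses <- 0L
    return(cat_trace(times, values, meta))
  }
  cl <- params$cycle_length_mean; cv <- params$cycle_length_cv
  m <- ceiling(duration / cl * 2) + 10L
  lens <- if (cv == 0) rep(cl, m) else {
    sdlog <- sqrt(log(1 + cv^2))
    stats::rlnorm(m, meanlog = log(cl / sqrt(1 + cv^2)), sdlog = sdlog)
  }
  starts <- cumsum(c(0, lens[-1L]))
  starts <- starts[starts < duration]
  # additive superposition: each pulse's decay tail carries into the next
  # cycle (incomplete clearance elevates the diastolic level slightly). The
  # record starts mid-rhythm: a virtual pulse one cycle before t = 0
  # supplies the tail under the first recorded beat.
  emitted <- starts + params$upstroke_time < duration
  starts_ext <- c(-lens[1L], starts)
  emitted_ext <- c(TRUE, emitted)
  idx <- findInterval(times, starts_ext)
  b <- params$baseline_level
  shape <- function(i_off) {
    j <- idx - i_off
    v <- numeric(length(times))
    ok <- j >= 1L & emitted_ext[pmax(j, 1L)]
    v[ok] <- make_pulse(times[ok] - starts_ext[j[ok]], params, ead = ead,
                        ead_cfg = ead_cfg) - b
    v
  }
  values <- b + shape(0L) + shape(1L)
  values <- values + stats::rnorm(n, 0, params$noise_sd) +
    params$drift_per_s * times
  meta$n_pulses <- sum(emitted)
  cat_trace(times, values, meta)
}

# deterministic per-well seed below 2^31
well_seed <- function(master, idx) {
  (as.numeric(master) * 1000003 + idx * 7919) %% 2147483629
}

# per-well biological jitter: one lognormal factor on plateau_time and
# decay_tau, shared by the pre and post recordings of the same well
jitter_params <- function(base, jitter_sd) {
  g <- exp(stats::rnorm(1, 0, jitter_sd))
  base$plateau_time <- base$plateau_time * g
  base$decay_tau <- base$decay_tau * g
  base
}

#' Simulate a full dosing plate
#'
#' Lays out, per cell line, `replicates[line]` wells for each of the four
#' doses of every registry compound plus the same number of DMSO (vehicle)
#' wells, and renders a paired pre (baseline, drug-free) and post (dosed)
#' recording for each well. Per-well seeds derive deterministically from the
#' master seed, and a per-well lognormal jitter on the pulse duration is
#' shared between the pre and post recording, so percent changes from
#' baseline reflect the drug effect rather than well-to-well variation.
#'
#' @param registry A `cat_registry`.
#' @param profiles Named list of `cell_line_profile` (default both lines).
#' @param effects A `drug_effect_table`.
#' @param replicates Named integer vector of wells per dose per line
#'   (default `c(control = 6, progeria = 4)`, the plate layout the analysis
#'   assumes).
#' @param duration,fs Recording length (s) and sampling rate (Hz).
#' @param seed Master integer seed.
#' @param jitter_sd SD of the lognormal per-well duration jitter.
#' @param ead_cfg EAD rendering configuration.
#' @return List with `traces` (list of `cat_trace`, pre and post) and
#'   `platemap` (a `cat_platemap`).
#' @export
simulate_plate <- function(registry, profiles = default_cell_profiles(),
                           effects = default_drug_effects(registry),
                           replicates = c(control = 6L, progeria = 4L),
                           duration = 30, fs = 50, seed = 1,
                           jitter_sd = 0.05, ead_cfg = ead_config()) {
  stopifnot(nrow(registry) >= 1L)
  traces <- list()
  pm <- list()
  widx <- 0L
  for (line in names(profiles)) {
    profile <- profiles[[line]]
    nrep <- as.integer(replicates[[line]])
    plate_tag <- toupper(substr(line, 1, 1))
    layout <- rbind(
      expand.grid(compound = registry$name, dose_index = 1:4, rep = seq_len(nrep),
                  stringsAsFactors = FALSE),
      expand.grid(compound = "DMSO", dose_index = NA_integer_, rep = seq_len(nrep),
                  stringsAsFactors = FALSE)
    )
    for (k in seq_len(nrow(layout))) {
      widx <- widx + 1L
      cmpd <- layout$compound[k]
      di <- layout$dose_index[k]
      row_lab <- LETTERS[((k - 1L) %/% 24L) %% 26L + 1L]
      wid <- sprintf("%s-%s%02d", plate_tag, row_lab, (k - 1L) %% 24L + 1L)
      set.seed(well_seed(seed, widx))
      base_j <- jitter_params(profile$baseline, jitter_sd)
      pre <- simulate_trace(profile, params_override = base_j,
                            duration = duration, fs = fs, ead_cfg = ead_cfg)
      pre$meta <- utils::modifyList(pre$meta, list(
        well_id = wid, cell_line = line, compound = cmpd,
        dose_index = di, phase = "pre"))
      if (cmpd == "DMSO") {
        post <- simulate_trace(profile, params_override = base_j,
                               duration = duration, fs = fs, ead_cfg = ead_cfg)
      } else {
        drug <- drug_effect(effects, cmpd)
        dose <- registry_doses(registry, cmpd)[di]
        prof_j <- profile
        prof_j$baseline <- base_j
        post <- simulate_trace(prof_j, drug = drug, dose = dose,
                               duration = duration, fs = fs, ead_cfg = ead_cfg)
      }
      post$meta <- utils::modifyList(post$meta, list(
        well_id = wid, cell_line = line, compound = cmpd,
        dose_index = di, phase = "post"))
      traces[[length(traces) + 1L]] <- pre
      traces[[length(traces) + 1L]] <- post
      pm[[length(pm) + 1L]] <- data.frame(
        well_id = wid, cell_line = line, compound = cmpd,
        dose_index = if (is.na(di)) NA_integer_ else as.integer(di),
        phase = c("pre", "post"), stringsAsFactors = FALSE)
    }
  }
  platemap <- validate_platemap(do.call(rbind, pm))
  list(traces = traces, platemap = platemap)
}

#' Mean extracted P80 of undosed synthetic wells
#'
#' Simulates `n_wells` drug-free wells of one cell line (with the default
#' per-well jitter and noise) and returns the mean extracted P80; the
#' calibration check behind the 0.70 s (control) and 0.98 s (progeria)
#' baseline targets.
#'
#' @param profile A `cell_line_profile`.
#' @param n_wells Number of wells (>= 100 for the calibration criterion).
#' @param duration,fs Recording parameters.
#' @param seed Master seed.
#' @param cfg Detection configuration, see [detection_config()].
#' @param jitter_sd Per-well duration jitter SD.
#' @return List with `mean_p80`, `sd_p80` and the per-well vector `p80`.
#' @export
measure_baseline_p80 <- function(profile, n_wells = 120L, duration = 30,
                                 fs = 50, seed = 1,
                                 cfg = detection_config(), jitter_sd = 0.05) {
  p80 <- vapply(seq_len(n_wells), function(i) {
    set.seed(well_seed(seed, i))
    pj <- jitter_params(profile$baseline, jitter_sd)
    tr <- simulate_trace(profile, params_override = pj,
                         duration = duration, fs = fs)
    phenotype(tr, cfg)$p80
  }, numeric(1))
  list(mean_p80 = mean(p80, na.rm = TRUE), sd_p80 = stats::sd(p80, na.rm = TRUE),
       p80 = p80)
}
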