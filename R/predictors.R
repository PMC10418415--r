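# The three regression predictors, per compound x cell line:
#   1. arrhythmia waveform type (NONE / OTHER / TYPE_A, ordinal 0/1/2)
#   2. P80 percent change interpolated at the clinical Cmax
#   3. maximum P80 percent change over the dose grid
# plus min-max normalization of the two P80 predictors across the panel.

#' Arrhythmia-type classification thresholds
#'
#' @param ead_indicator_cut Per-well [ead_indicator()] value above which a
#'   well counts as EAD-positive.
#' @param ead_well_fraction Minimum fraction of EAD-positive wells at any
#'   dose for a TYPE_A call.
#' @param cease_well_fraction Minimum fraction of ceased wells at any dose
#'   for an OTHER call.
#' @param other_p80_cutoff Mean P80 percent change at any dose above which
#'   the waveform counts as OTHER (extended duration).
#' @param min_amp_frac Signal-quality gate: a well whose post-dose amplitude
#'   fell below this fraction of its own baseline amplitude is excluded from
#'   the EAD count (the 20%-recovery width, hence the 8/2 ratio, is
#'   noise-dominated on such wells).
#' @return Named list.
#' @export
classifier_config <- function(ead_indicator_cut = 0.5,
                              ead_well_fraction = 0.25,
                              cease_well_fraction = 0.5,
                              other_p80_cutoff = 100,
                              min_amp_frac = 0.35) {
  list(ead_indicator_cut = ead_indicator_cut,
       ead_well_fraction = ead_well_fraction,
       cease_well_fraction = cease_well_fraction,
       other_p80_cutoff = other_p80_cutoff,
       min_amp_frac = min_amp_frac)
}

ATYPE_LEVELS <- c("NONE", "OTHER", "TYPE_A")

#' Classify the proarrhythmia waveform type of one compound
#'
#' TYPE_A (EAD-like) when at any dose the fraction of wells whose raw
#' post-dose 8/2 ratio maps above the indicator cut is at least
#' `ead_well_fraction`; otherwise OTHER (extended duration / beat
#' cessation) when any dose has at least `cease_well_fraction` ceased wells
#' or a mean P80 change of at least `other_p80_cutoff` percent; otherwise
#' NONE. Precedence TYPE_A > OTHER > NONE; assessed per compound over all
#' doses.
#'
#' @param well_table Per-well table from [phenotype_wells()] restricted (or
#'   restrictable) to one compound and cell line.
#' @param compound,cell_line Selection within `well_table`.
#' @param cfg A [classifier_config()].
#' @return List with `value` (factor NONE/OTHER/TYPE_A) and `ordinal_score`
#'   (0/1/2).
#' @export
classify_arrhythmia <- function(well_table, compound, cell_line,
                                cfg = classifier_config()) {
  tab <- well_table[well_table$compound == compound &
                      well_table$cell_line == cell_line, , drop = FALSE]
  if (nrow(tab) == 0L) stop("no wells for ", compound, " / ", cell_line)
  type_a <- FALSE; other <- FALSE
  for (d in sort(unique(tab$dose_index))) {
    sub <- tab[!is.na(tab$dose_index) & tab$dose_index == d, , drop = FALSE]
    if (nrow(sub) == 0L) next
    ind <- ead_indicator(sub$post_r82)
    quality <- !sub$ceased & sub$post_amp / sub$pre_amp >= cfg$min_amp_frac
    ead_frac <- sum(quality & !is.na(ind) & ind > cfg$ead_indicator_cut) /
      nrow(sub)
    if (ead_frac >= cfg$ead_well_fraction) type_a <- TRUE
    cease_frac <- mean(sub$ceased)
    mean_p80 <- if (any(!sub$ceased)) mean(sub$pct_p80[!sub$ceased]) else NA
    if (cease_frac >= cfg$cease_well_fraction ||
        (!is.na(mean_p80) && mean_p80 >= cfg$other_p80_cutoff)) other <- TRUE
  }
  value <- if (type_a) "TYPE_A" else if (other) "OTHER" else "NONE"
  list(value = factor(value, levels = ATYPE_LEVELS),
       ordinal_score = match(value, ATYPE_LEVELS) - 1L)
}

#' Interpolate the P80 change at Cmax
#'
#' Piecewise-linear interpolation of the per-dose mean P80 percent changes
#' in log10(dose); a Cmax outside the tested grid clamps to the nearest
#' endpoint and sets the `extrapolated` flag. Doses where every well ceased
#' (NA means) are dropped before interpolating.
#'
#' @param doses Four increasing doses (nM).
#' @param p80_changes Per-dose mean P80 percent changes (NA = dose ceased).
#' @param cmax Clinical Cmax (nM).
#' @return List with `value` (percent), `extrapolated`, `defined`.
#' @export
p80_at_cmax <- function(doses, p80_changes, cmax) {
  stopifnot(length(doses) == length(p80_changes), all(diff(doses) > 0),
            cmax > 0)
  ok <- !is.na(p80_changes)
  if (!any(ok)) {
    return(list(value = NA_real_, extrapolated = FALSE, defined = FALSE))
  }
  ld <- log10(doses[ok]); y <- p80_changes[ok]
  lx <- log10(cmax)
  extrap <- lx < min(ld) || lx > max(ld)
  value <- if (length(y) == 1L) y
           else stats::approx(ld, y, xout = lx, rule = 2)$y
  if (length(y) == 1L) extrap <- lx != ld
  list(value = value, extrapolated = extrap, defined = TRUE)
}

#' Maximum P80 change over the dose grid
#'
#' @param p80_changes Per-dose mean P80 percent changes (NA = dose ceased).
#' @return List with `value` (max of the defined means; NA sentinel when
#'   none is defined) and `defined`.
#' @export
p80_max <- function(p80_changes) {
  ok <- !is.na(p80_changes)
  if (!any(ok)) return(list(value = NA_real_, defined = FALSE))
  list(value = max(p80_changes[ok]), defined = TRUE)
}

#' Assemble the predictor set for one cell line
#'
#' @param well_table Per-well table from [phenotype_wells()].
#' @param registry A `cat_registry`.
#' @param cell_line `"control"` or `"progeria"`.
#' @param cfg A [classifier_config()].
#' @return Data frame of class `predictor_set`: per compound, `atype`,
#'   `atype_score`, `p80_at_cmax`, `p80_max`, `extrapolated` and (after
#'   [normalize_panel()]) `p80_at_cmax_norm`, `p80_max_norm`.
#' @export
build_predictor_set <- function(well_table, registry, cell_line,
                                cfg = classifier_config()) {
  rows <- lapply(seq_len(nrow(registry)), function(i) {
    cmpd <- registry$name[i]
    doses <- registry_doses(registry, cmpd)
    tab <- well_table[well_table$compound == cmpd &
                        well_table$cell_line == cell_line, , drop = FALSE]
    if (nrow(tab) == 0L) stop("no wells for ", cmpd, " / ", cell_line)
    means <- vapply(1:4, function(d) {
      sub <- tab[!is.na(tab$dose_index) & tab$dose_index == d, , drop = FALSE]
      surv <- !sub$ceased
      if (any(surv)) mean(sub$pct_p80[surv]) else NA_real_
    }, numeric(1))
    at <- classify_arrhythmia(well_table, cmpd, cell_line, cfg)
    pc <- p80_at_cmax(doses, means, registry$cmax[i])
    pm <- p80_max(means)
    data.frame(compound = cmpd, cell_line = cell_line,
               risk_label = as.character(registry$risk_label[i]),
               atype = as.character(at$value), atype_score = at$ordinal_score,
               p80_at_cmax = pc$value, p80_max = pm$value,
               extrapolated = pc$extrapolated, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("predictor_set", "data.frame")
  out
}

#' Normalize a predictor panel within one cell line
#'
#' Min-max scales `p80_at_cmax` and `p80_max` to `[0, 1]` across the
#' compound panel (the arrhythmia-type score stays on its 0/1/2 scale). A
#' zero-range column maps to 0.5 everywhere with a warning. Alternative:
#' `method = "zscore"` standardizes instead (values then not confined to
#' `[0, 1]`).
#'
#' @param predictors A `predictor_set` for one cell line.
#' @param method `"minmax"` (default) or `"zscore"`.
#' @return The same data frame with `p80_at_cmax_norm` and `p80_max_norm`
#'   columns added.
#' @export
normalize_panel <- function(predictors, method = c("minmax", "zscore")) {
  method <- match.arg(method)
  ok <- !is.na(predictors$p80_at_cmax) | !is.na(predictors$p80_max)
  if (sum(ok) < 2L) stop("need at least 2 compounds with defined predictors")
  scale1 <- function(x) {
    if (method == "zscore") {
      s <- stats::sd(x, na.rm = TRUE)
      if (!is.finite(s) || s == 0) {
        warning("zero spread; normalized values set to 0.5")
        return(rep(0.5, length(x)))
      }
      return((x - mean(x, na.rm = TRUE)) / s)
    }
    lo <- min(x, na.rm = TRUE); hi <- max(x, na.rm = TRUE)
    if (hi == lo) {
      warning("zero range; normalized values set to 0.5")
      return(rep(0.5, length(x)))
    }
    (x - lo) / (hi - lo)
  }
  predictors$p80_at_cmax_norm <- scale1(predictors$p80_at_cmax)
  predictors$p80_max_norm <- scale1(predictors$p80_max)
  predictors
}
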