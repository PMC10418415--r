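# Transforms used for the dose-dependent radial ("spider") profiles:
# a logistic EAD indicator on the 8/2 ratio and the log-modulus transform
# on the remaining percent-change axes.

#' Logistic EAD indicator of the 8/2 ratio
#'
#' `1 / (1 + exp(-9 * (x - 3)))`: a sigmoid centred at an 8/2 ratio of 3
#' with slope 9, mapping the ratio into (0, 1) so that late-decay
#' distortions (EAD-like humps, which push 8/2 past ~3) saturate the axis
#' while normal transients (8/2 around 2.5) stay near 0.
#'
#' @param x 8/2 ratio (or, via configuration, its percent change); finite,
#'   vectorized.
#' @return Values in (0, 1), strictly increasing in `x`.
#' @export
ead_indicator <- function(x) {
  1 / (1 + exp(-9 * (x - 3)))
}

#' Log-modulus transform
#'
#' `L(x) = sign(x) * log10(|x| + 1)`: an odd, monotone compression that is
#' defined (and 0) at 0, used to show percent changes spanning decades on
#' one radial axis.
#'
#' @param x Finite numeric, vectorized.
#' @return Transformed values.
#' @export
log_modulus <- function(x) {
  sign(x) * log10(abs(x) + 1)
}

PARAM_AXES <- c("p80", "r82", "cl", "amp", "pn", "csd")

#' Build a radial dose-response profile for one compound and cell line
#'
#' Per dose, the six parameters are averaged over replicate wells; the 8/2
#' axis is the [ead_indicator()] of the mean raw post-dose 8/2 ratio (an
#' absolute EAD signature), the remaining five axes are the [log_modulus()]
#' of the mean percent change. Ceased wells contribute to the PN axis only;
#' the continuous axes average the surviving wells, and a dose where every
#' well ceased carries `NA` (rendered as a gap).
#'
#' @param well_table Per-well table from [phenotype_wells()].
#' @param compound Compound name (`"DMSO"` builds the vehicle profile, one
#'   pseudo-dose row).
#' @param cell_line `"control"` or `"progeria"`.
#' @param r82_input Either `"raw"` (default: sigmoid of the raw post-dose
#'   8/2 ratio) or `"pct"` (sigmoid of the 8/2 percent change).
#' @return A `radial_profile`: list with `compound`, `cell_line`,
#'   `per_dose` (doses x 6 matrix, axis order P80, 8/2, CL, AMP, PN, CSD)
#'   and `n_surviving` (wells contributing to the continuous axes per dose).
#' @export
build_radial_profile <- function(well_table, compound, cell_line,
                                 r82_input = c("raw", "pct")) {
  r82_input <- match.arg(r82_input)
  tab <- well_table[well_table$compound == compound &
                      well_table$cell_line == cell_line, , drop = FALSE]
  if (nrow(tab) == 0L) stop("no wells for ", compound, " / ", cell_line)
  doses <- if (compound == "DMSO") NA_integer_ else 1:4
  per_dose <- matrix(NA_real_, nrow = length(doses), ncol = 6L,
                     dimnames = list(NULL, toupper(PARAM_AXES)))
  colnames(per_dose) <- c("P80", "8/2", "CL", "AMP", "PN", "CSD")
  n_surv <- integer(length(doses))
  for (d in seq_along(doses)) {
    sel <- if (compound == "DMSO") rep(TRUE, nrow(tab))
           else !is.na(tab$dose_index) & tab$dose_index == doses[d]
    sub <- tab[sel, , drop = FALSE]
    if (nrow(sub) == 0L) stop("no wells at dose index ", doses[d],
                              " for ", compound, " / ", cell_line)
    surv <- !sub$ceased
    n_surv[d] <- sum(surv)
    per_dose[d, "PN"] <- log_modulus(mean(sub$pct_pn))
    if (any(surv)) {
      per_dose[d, "P80"] <- log_modulus(mean(sub$pct_p80[surv]))
      per_dose[d, "CL"] <- log_modulus(mean(sub$pct_cl[surv]))
      per_dose[d, "AMP"] <- log_modulus(mean(sub$pct_amp[surv]))
      per_dose[d, "CSD"] <- log_modulus(mean(sub$pct_csd[surv]))
      per_dose[d, "8/2"] <- if (r82_input == "raw") {
        ead_indicator(mean(sub$post_r82[surv]))
      } else {
        ead_indicator(mean(sub$pct_r82[surv]))
      }
    }
  }
  structure(list(compound = compound, cell_line = cell_line,
                 per_dose = per_dose, n_surviving = n_surv),
            class = "radial_profile")
}

#' Draw a radial profile
#'
#' Six-axis radial chart with one polygon per dose in the conventional
#' order blue, orange, green, red (doses 1-4). A dose whose continuous axes
#' are `NA` (all wells ceased) is omitted. Output is deterministic for a
#' fixed profile.
#'
#' @param profile A `radial_profile`.
#' @param path Output file; `.svg` (cairo) or `.pdf`.
#' @param axis_max Radial scale limit; defaults to the data range.
#' @return `path`, invisibly.
#' @export
plot_radial <- function(profile, path, axis_max = NULL) {
  mat <- profile$per_dose
  ndose <- nrow(mat)
  cols <- c("#1f77b4", "#ff7f0e", "#2ca02c", "#d62728")[seq_len(ndose)]
  if (is.null(axis_max)) {
    axis_max <- max(1, abs(mat), na.rm = TRUE)
  }
  open_device(path, width = 6, height = 6)
  on.exit(grDevices::dev.off(), add = TRUE)
  ang <- pi / 2 - (seq_len(6L) - 1L) * 2 * pi / 6
  graphics::par(mar = c(1, 1, 3, 1))
  graphics::plot(NA, xlim = c(-1.3, 1.3), ylim = c(-1.3, 1.3), asp = 1,
                 axes = FALSE, xlab = "", ylab = "",
                 main = sprintf("%s (%s)", profile$compound, profile$cell_line))
  for (r in c(0.25, 0.5, 0.75, 1)) {
    graphics::polygon(r * cos(ang), r * sin(ang), border = "grey80")
  }
  graphics::segments(0, 0, cos(ang), sin(ang), col = "grey80")
  graphics::text(1.18 * cos(ang), 1.18 * sin(ang), colnames(mat), cex = 0.9)
  for (d in seq_len(ndose)) {
    v <- mat[d, ]
    if (anyNA(v)) next
    r <- pmin(1, pmax(0, abs(v) / axis_max))
    graphics::polygon(r * cos(ang), r * sin(ang), border = cols[d],
                      col = grDevices::adjustcolor(cols[d], alpha.f = 0.15),
                      lwd = 2)
  }
  invisible(path)
}

open_device <- function(path, width, height) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "svg") {
    grDevices::svg(path, width = width, height = height)
  } else if (ext == "pdf") {
    grDevices::pdf(path, width = width, height = height)
  } else {
    stop("unsupported figure format: .", ext, " (use .svg or .pdf)")
  }
}
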