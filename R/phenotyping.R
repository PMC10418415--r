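# Calcium-transient cycle detection and the six-parameter phenotype:
#   P80  width at 80% recovery (s)
#   R82  "8/2" ratio: width at 80% recovery / width at 20% recovery
#   CL   mean cycle length (s)
#   AMP  mean peak amplitude above the per-cycle baseline (a.u.)
#   PN   number of detected cycles
#   CSD  sample SD of cycle lengths (s)

#' Cycle-detection configuration
#'
#' Peaks are found on a moving-average-smoothed copy of the signal; widths
#' are measured on the raw signal. A candidate peak is kept when its
#' prominence is at least `prominence_frac` of the smoothed signal range and
#' it is at least `min_spacing` seconds from any taller kept peak; this
#' rejects EAD humps as separate peaks, so an EAD inflates P80 (and the 8/2
#' ratio) rather than PN. A trace whose smoothed range is below
#' `noise_floor` is treated as beat-free (ceased).
#'
#' @param smooth_window Moving-average window (s).
#' @param prominence_frac Minimum peak prominence as a fraction of the
#'   smoothed signal range.
#' @param min_spacing Minimum peak separation (s).
#' @param noise_floor Minimum smoothed signal range (a.u.) for a trace to
#'   count as beating.
#' @param crossing_debounce Hold time (s) a level crossing must persist to
#'   count when measuring widths; rejects single-sample noise dips near the
#'   plateau of amplitude-suppressed wells without smoothing the signal.
#' @return Named list of class `detection_config`.
#' @export
detection_config <- function(smooth_window = 0.1, prominence_frac = 0.3,
                             min_spacing = 0.25, noise_floor = 0.1,
                             crossing_debounce = 0.06) {
  structure(list(smooth_window = smooth_window,
                 prominence_frac = prominence_frac,
                 min_spacing = min_spacing, noise_floor = noise_floor,
                 crossing_debounce = crossing_debounce),
            class = "detection_config")
}

moving_average <- function(x, k) {
  if (k <= 1L) return(x)
  n <- length(x)
  cs <- cumsum(c(0, x))
  half <- k %/% 2L
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# prominence of local maxima: drop to the highest of the two minima found
# before meeting a taller sample on each side (record edge counts as a wall)
peak_prominence <- function(x, peaks) {
  vapply(peaks, function(p) {
    h <- x[p]
    i <- p
    left_min <- h
    while (i > 1L && x[i - 1L] <= h) {
      i <- i - 1L
      if (x[i] < left_min) left_min <- x[i]
    }
    i <- p
    right_min <- h
    n <- length(x)
    while (i < n && x[i + 1L] <= h) {
      i <- i + 1L
      if (x[i] < right_min) right_min <- x[i]
    }
    h - max(left_min, right_min)
  }, numeric(1))
}

#' Detect calcium-transient cycles in a trace
#'
#' @param trace A `cat_trace`.
#' @param cfg A [detection_config()].
#' @return A data frame of class `cat_cycles`, one row per cycle, with
#'   columns `peak_index`, `peak_time`, `peak_value`, `baseline_value`
#'   (minimum of the raw signal since the previous peak, or since the record
#'   start for the first cycle), `width80`, `width20`, `trunc80`, `trunc20`
#'   (width truncated at the cycle boundary) and `cycle_length` (NA for the
#'   last cycle). A flat / beat-free trace yields zero rows, never an error.
#' @export
detect_cycles <- function(trace, cfg = detection_config()) {
  x <- trace$values
  n <- length(x)
  k <- max(1L, round(cfg$smooth_window * trace$fs))
  if (k %% 2L == 0L) k <- k + 1L
  s <- moving_average(x, k)
  rng <- diff(range(s))
  empty <- data.frame(peak_index = integer(), peak_time = numeric(),
                      peak_value = numeric(), baseline_value = numeric(),
                      width80 = numeric(), width20 = numeric(),
                      trunc80 = logical(), trunc20 = logical(),
                      cycle_length = numeric())
  class(empty) <- c("cat_cycles", "data.frame")
  if (!is.finite(rng) || rng < cfg$noise_floor) return(empty)
  cand <- which(diff(sign(diff(s))) < 0) + 1L
  if (length(cand) == 0L) return(empty)
  prom <- peak_prominence(s, cand)
  cand <- cand[prom >= cfg$prominence_frac * rng]
  if (length(cand) == 0L) return(empty)
  # enforce minimum spacing, keeping taller peaks first
  ord <- cand[order(s[cand], decreasing = TRUE)]
  min_gap <- cfg$min_spacing * trace$fs
  kept <- integer()
  for (p in ord) {
    if (all(abs(kept - p) >= min_gap)) kept <- c(kept, p)
  }
  peaks <- sort(kept)
  # refine on the raw signal: centre of the tied maximal run near the
  # smoothed peak (a flat plateau otherwise quantizes peak times arbitrarily)
  half <- max(k %/% 2L, as.integer(round(0.5 * cfg$min_spacing * trace$fs)))
  peaks <- vapply(peaks, function(p) {
    lo <- max(1L, p - half); hi <- min(n, p + half)
    w <- x[lo:hi]
    jmax <- which.max(w)
    tol <- 1e-9 * max(1, abs(w[jmax]))
    tie <- w >= w[jmax] - tol
    run_lo <- jmax; run_hi <- jmax
    while (run_lo > 1L && tie[run_lo - 1L]) run_lo <- run_lo - 1L
    while (run_hi < length(w) && tie[run_hi + 1L]) run_hi <- run_hi + 1L
    as.integer(lo + (run_lo + run_hi) %/% 2L - 1L)
  }, integer(1))
  peaks <- sort(unique(peaks))
  nc <- length(peaks)
  baseline <- numeric(nc)
  for (i in seq_len(nc)) {
    lo <- if (i == 1L) 1L else peaks[i - 1L]
    baseline[i] <- min(x[lo:peaks[i]])
  }
  cyc <- data.frame(
    peak_index = peaks,
    peak_time = trace$times[peaks],
    peak_value = x[peaks],
    baseline_value = baseline,
    width80 = NA_real_, width20 = NA_real_,
    trunc80 = FALSE, trunc20 = FALSE,
    cycle_length = c(diff(trace$times[peaks]), NA_real_)
  )
  class(cyc) <- c("cat_cycles", "data.frame")
  for (i in seq_len(nc)) {
    w80 <- width_at_recovery(trace, cyc, i, 0.8, cfg$crossing_debounce)
    w20 <- width_at_recovery(trace, cyc, i, 0.2, cfg$crossing_debounce)
    cyc$width80[i] <- w80$width; cyc$trunc80[i] <- w80$truncated
    cyc$width20[i] <- w20$width; cyc$trunc20[i] <- w20$truncated
  }
  cyc
}

#' Width of one cycle at a fractional recovery level
#'
#' The level is `baseline + (1 - recovery_frac) * (peak - baseline)`; the
#' width runs from the last upward crossing of that level before the peak to
#' the first downward crossing after it, each located by linear
#' interpolation between the bracketing samples. A crossing only counts when
#' the signal stays on the far side of the level for at least `debounce`
#' seconds (or until the cycle boundary), which rejects single-sample noise
#' dips on amplitude-suppressed wells. A crossing that does not occur before
#' the cycle boundary (previous/next peak, or the record edge) truncates the
#' width there and sets `truncated`.
#'
#' @param trace A `cat_trace`.
#' @param cycles A `cat_cycles` table from [detect_cycles()].
#' @param i Cycle row index.
#' @param recovery_frac Recovery fraction in (0, 1); 0.8 gives P80.
#' @param debounce Crossing hold time (s).
#' @return List with `width` (s) and `truncated` (logical).
#' @export
width_at_recovery <- function(trace, cycles, i, recovery_frac = 0.8,
                              debounce = 0.06) {
  stopifnot(recovery_frac > 0, recovery_frac < 1)
  x <- trace$values; tt <- trace$times
  p <- cycles$peak_index[i]
  level <- cycles$baseline_value[i] +
    (1 - recovery_frac) * (cycles$peak_value[i] - cycles$baseline_value[i])
  lo <- if (i == 1L) 1L else cycles$peak_index[i - 1L]
  hi <- if (i == nrow(cycles)) length(x) else cycles$peak_index[i + 1L]
  db <- max(1L, as.integer(round(debounce * trace$fs)))
  truncated <- FALSE
  # last upward crossing before the peak that holds above the level
  left_t <- tt[lo]
  cand <- if (p > lo) {
    which(x[lo:(p - 1L)] < level & x[(lo + 1L):p] >= level) + lo - 1L
  } else integer()
  cand <- cand[vapply(cand, function(j) {
    all(x[(j + 1L):min(j + db, p)] >= level)
  }, logical(1))]
  if (length(cand) == 0L) {
    truncated <- TRUE
  } else {
    j <- max(cand)
    left_t <- tt[j] + (level - x[j]) / (x[j + 1L] - x[j]) * (tt[j + 1L] - tt[j])
  }
  # first downward crossing after the peak that holds below the level
  right_t <- tt[hi]
  cand <- if (hi > p) {
    which(x[p:(hi - 1L)] >= level & x[(p + 1L):hi] < level) + p - 1L
  } else integer()
  cand <- cand[vapply(cand, function(j) {
    all(x[(j + 1L):min(j + db, hi)] < level)
  }, logical(1))]
  if (length(cand) == 0L) {
    truncated <- TRUE
  } else {
    j <- min(cand)
    right_t <- tt[j] + (level - x[j]) / (x[j + 1L] - x[j]) * (tt[j + 1L] - tt[j])
  }
  list(width = right_t - left_t, truncated = truncated)
}

#' Six-parameter phenotype of one trace
#'
#' @param trace A `cat_trace`.
#' @param cfg A [detection_config()].
#' @return A `phenotype_vector`: named list `p80`, `r82`, `cl`, `amp`, `pn`,
#'   `csd`. With no detected cycles (`pn = 0`) the continuous entries are
#'   `NA` (the undefined sentinel). Cycles with a truncated width are
#'   excluded from the P80 and 8/2 means but still count toward PN; CSD is 0
#'   when fewer than 3 peaks are found.
#' @export
phenotype <- function(trace, cfg = detection_config()) {
  cyc <- detect_cycles(trace, cfg)
  pn <- nrow(cyc)
  if (pn == 0L) {
    return(structure(list(p80 = NA_real_, r82 = NA_real_, cl = NA_real_,
                          amp = NA_real_, pn = 0L, csd = NA_real_),
                     class = "phenotype_vector"))
  }
  ok <- !cyc$trunc80 & !cyc$trunc20
  p80 <- if (any(!cyc$trunc80)) mean(cyc$width80[!cyc$trunc80]) else NA_real_
  r82 <- if (any(ok)) mean(cyc$width80[ok] / cyc$width20[ok]) else NA_real_
  ints <- cyc$cycle_length[!is.na(cyc$cycle_length)]
  cl <- if (length(ints)) mean(ints) else NA_real_
  csd <- if (pn >= 3L) stats::sd(ints) else 0
  amp <- mean(cyc$peak_value - cyc$baseline_value)
  structure(list(p80 = p80, r82 = r82, cl = cl, amp = amp, pn = pn, csd = csd),
            class = "phenotype_vector")
}

#' @export
print.phenotype_vector <- function(x, ...) {
  cat(sprintf(
    "<phenotype> P80=%.3fs 8/2=%.2f CL=%.3fs AMP=%.3f PN=%d CSD=%.3fs\n",
    x$p80, x$r82, x$cl, x$amp, x$pn, x$csd))
  invisible(x)
}

#' Percent change of a phenotype from its baseline
#'
#' `100 * (post - pre) / pre` per parameter; the PN change is computed from
#' the integer peak counts. A post recording with no beats flags the well
#' `ceased`: its PN change is computed (-100% when the baseline beat) and
#' the continuous parameters carry the `NA` sentinel. A `pre` with `pn = 0`
#' is uninterpretable and raises an error (callers exclude such wells with a
#' warning). A parameter that is 0 in both phases (e.g. CSD of a perfectly
#' regular well) has change 0.
#'
#' @param post,pre `phenotype_vector`s of the post- and pre-dosing recording.
#' @return Named list: `p80`, `r82`, `cl`, `amp`, `pn`, `csd` (percent) and
#'   `ceased` (logical).
#' @export
percent_change <- function(post, pre) {
  if (pre$pn == 0L) stop("baseline recording has no beats (pre.pn = 0)")
  pct1 <- function(a, b) {
    if (is.na(a) || is.na(b)) return(NA_real_)
    if (b == 0) return(if (a == 0) 0 else NA_real_)
    100 * (a - b) / b
  }
  ceased <- post$pn == 0L
  out <- list(
    p80 = if (ceased) NA_real_ else pct1(post$p80, pre$p80),
    r82 = if (ceased) NA_real_ else pct1(post$r82, pre$r82),
    cl  = if (ceased) NA_real_ else pct1(post$cl, pre$cl),
    amp = if (ceased) NA_real_ else pct1(post$amp, pre$amp),
    pn  = 100 * (post$pn - pre$pn) / pre$pn,
    csd = if (ceased) NA_real_ else pct1(post$csd, pre$csd),
    ceased = ceased
  )
  out
}

#' Phenotype every well of a plate
#'
#' Pairs each well's pre and post recording, extracts both phenotypes and
#' the percent changes, and returns one row per well. Wells whose baseline
#' shows no beats are dropped with a warning.
#'
#' @param traces List of `cat_trace` with plate metadata (as produced by
#'   [simulate_plate()] or [read_traces()]).
#' @param cfg A [detection_config()].
#' @return Data frame with well metadata, `pre_*` and `post_*` phenotype
#'   columns, `pct_*` percent changes, `post_r82` (raw post 8/2 ratio, used
#'   by the EAD indicator) and `ceased`.
#' @export
phenotype_wells <- function(traces, cfg = detection_config()) {
  key <- vapply(traces, function(tr) paste0(tr$meta$well_id, "|", tr$meta$phase), "")
  wells <- unique(vapply(traces, function(tr) tr$meta$well_id, ""))
  rows <- list()
  dropped <- character()
  for (w in wells) {
    i_pre <- match(paste0(w, "|pre"), key)
    i_post <- match(paste0(w, "|post"), key)
    if (is.na(i_pre) || is.na(i_post)) {
      stop("well ", w, " lacks a pre or post recording")
    }
    pre <- phenotype(traces[[i_pre]], cfg)
    post <- phenotype(traces[[i_post]], cfg)
    if (pre$pn == 0L) { dropped <- c(dropped, w); next }
    pc <- percent_change(post, pre)
    m <- traces[[i_post]]$meta
    rows[[length(rows) + 1L]] <- data.frame(
      well_id = w, cell_line = m$cell_line %||% NA_character_,
      compound = m$compound %||% NA_character_,
      dose_index = if (is.null(m$dose_index) || is.na(m$dose_index))
        NA_integer_ else as.integer(m$dose_index),
      pre_p80 = pre$p80, pre_r82 = pre$r82, pre_cl = pre$cl,
      pre_amp = pre$amp, pre_pn = pre$pn, pre_csd = pre$csd,
      post_p80 = post$p80, post_r82 = post$r82, post_cl = post$cl,
      post_amp = post$amp, post_pn = post$pn, post_csd = post$csd,
      pct_p80 = pc$p80, pct_r82 = pc$r82, pct_cl = pc$cl,
      pct_amp = pc$amp, pct_pn = pc$pn, pct_csd = pc$csd,
      ceased = pc$ceased, stringsAsFactors = FALSE)
  }
  if (length(dropped)) {
    warning("dropped ", length(dropped),
            " well(s) with beat-free baseline: ",
            paste(utils::head(dropped, 5L), collapse = ", "))
  }
  do.call(rbind, rows)
}
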