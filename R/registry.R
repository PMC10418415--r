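RISK_LEVELS <- c("high", "intermediate", "low")
PHENO_PARAMS <- c("p80", "r82", "cl", "amp", "pn", "csd")
CELL_LINES <- c("control", "progeria")

#' Load a compound registry
#'
#' Reads a comma-separated registry of reference compounds with their clinical
#' Torsade-de-Pointes (TdP) risk category, maximum free plasma concentration
#' (Cmax) and the four-dose test grid, all in nM. The bundled default registry
#' (`system.file("extdata", "cipa_compounds.csv", package = "catrisk")`)
#' holds the 11-compound CiPA reference panel used throughout the package.
#'
#' @param path Path to a registry CSV with header columns
#'   `name, category, cmax_nM, dose1_nM, dose2_nM, dose3_nM, dose4_nM`.
#'   Defaults to the bundled CiPA panel.
#' @return A data frame of class `cat_registry`, one row per compound, with
#'   columns `name`, `risk_label` (factor high/intermediate/low), `cmax` and
#'   `dose1`..`dose4` (nM).
#' @examples
#' reg <- load_registry()
#' nrow(reg)                       # 11
#' reg[reg$name == "Dofetilide", ] # cmax 2.14 nM, doses 0.3, 1, 3, 10
#' @export
load_registry <- function(path = default_registry_path()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, strip.white = TRUE)
  need <- c("name", "category", "cmax_nM", paste0("dose", 1:4, "_nM"))
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0L) {
    stop("registry file is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  cat_norm <- tolower(trimws(df$category))
  cat_norm[cat_norm == "mid"] <- "intermediate"  # Table synonym
  bad <- !(cat_norm %in% RISK_LEVELS)
  if (any(bad)) {
    stop("unknown risk category for row(s): ",
         paste(df$name[bad], collapse = ", "))
  }
  out <- data.frame(
    name = as.character(df$name),
    risk_label = factor(cat_norm, levels = RISK_LEVELS),
    cmax = as.numeric(df$cmax_nM),
    dose1 = as.numeric(df$dose1_nM),
    dose2 = as.numeric(df$dose2_nM),
    dose3 = as.numeric(df$dose3_nM),
    dose4 = as.numeric(df$dose4_nM),
    stringsAsFactors = FALSE
  )
  for (i in seq_len(nrow(out))) {
    rec <- out[i, ]
    conc <- c(rec$cmax, rec$dose1, rec$dose2, rec$dose3, rec$dose4)
    if (any(!is.finite(conc)) || any(conc <= 0)) {
      stop("non-positive or malformed concentration in row '", rec$name, "'")
    }
    d <- unlist(rec[paste0("dose", 1:4)])
    if (any(diff(d) <= 0)) {
      stop("doses not strictly increasing in row '", rec$name, "'")
    }
  }
  if (anyDuplicated(out$name)) stop("duplicate compound names in registry")
  class(out) <- c("cat_registry", "data.frame")
  out
}

#' @rdname load_registry
#' @export
default_registry_path <- function() {
  system.file("extdata", "cipa_compounds.csv", package = "catrisk",
              mustWork = TRUE)
}

#' Write a compound registry
#'
#' Inverse of [load_registry()]; a write followed by a re-load reproduces the
#' records bit-identically (plain decimal notation, no thousands separators).
#'
#' @param registry A `cat_registry` data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_registry <- function(registry, path) {
  df <- data.frame(
    name = registry$name,
    category = as.character(registry$risk_label),
    cmax_nM = format(registry$cmax, scientific = FALSE, trim = TRUE),
    dose1_nM = format(registry$dose1, scientific = FALSE, trim = TRUE),
    dose2_nM = format(registry$dose2, scientific = FALSE, trim = TRUE),
    dose3_nM = format(registry$dose3, scientific = FALSE, trim = TRUE),
    dose4_nM = format(registry$dose4, scientific = FALSE, trim = TRUE),
    stringsAsFactors = FALSE
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Dose grid of one registry row
#' @param registry A `cat_registry`.
#' @param compound Compound name.
#' @return Numeric vector of the four doses (nM), increasing.
#' @export
registry_doses <- function(registry, compound) {
  i <- match(compound, registry$name)
  if (is.na(i)) stop("compound '", compound, "' not in registry")
  as.numeric(registry[i, paste0("dose", 1:4)])
}

# ---- plate maps -----------------------------------------------------------

#' Read or write a plate map
#'
#' A plate map assigns each well a cell line, a compound (or `"DMSO"` for
#' vehicle controls), a dose index 1-4 (absent for DMSO) and a recording
#' phase (`pre` = baseline, `post` = after compound addition). Every `post`
#' entry must have a matching `pre` entry for the same well.
#'
#' @param path CSV path with columns `well_id, cell_line, compound,
#'   dose_index, phase` (`dose_index` empty for DMSO wells).
#' @return A data frame of class `cat_platemap`.
#' @export
read_platemap <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, strip.white = TRUE,
                        colClasses = c(well_id = "character"))
  validate_platemap(df)
}

#' @rdname read_platemap
#' @param platemap A `cat_platemap` data frame.
#' @export
write_platemap <- function(platemap, path) {
  utils::write.csv(platemap, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

validate_platemap <- function(df) {
  need <- c("well_id", "cell_line", "compound", "dose_index", "phase")
  if (!all(need %in% names(df))) {
    stop("plate map must have columns: ", paste(need, collapse = ", "))
  }
  if (!all(df$cell_line %in% CELL_LINES)) stop("unknown cell_line in plate map")
  if (!all(df$phase %in% c("pre", "post"))) stop("phase must be 'pre' or 'post'")
  df$dose_index <- suppressWarnings(as.integer(df$dose_index))
  is_dmso <- df$compound == "DMSO"
  if (any(is_dmso & !is.na(df$dose_index))) {
    stop("DMSO wells must not carry a dose_index")
  }
  if (any(!is_dmso & (is.na(df$dose_index) | df$dose_index < 1L |
                      df$dose_index > 4L))) {
    stop("compound wells need a dose_index in 1..4")
  }
  pre <- df$well_id[df$phase == "pre"]
  post <- df$well_id[df$phase == "post"]
  orphan <- setdiff(post, pre)
  if (length(orphan) > 0L) {
    stop("post wells without a matching pre recording: ",
         paste(utils::head(orphan, 5L), collapse = ", "))
  }
  class(df) <- c("cat_platemap", "data.frame")
  df
}

# ---- traces ---------------------------------------------------------------

#' Construct a calcium-transient trace
#'
#' @param times Sample times in seconds, a strictly increasing uniform grid.
#' @param values Fluorescence values (arbitrary units), finite.
#' @param meta Optional named list of plate metadata (well, line, compound,
#'   dose_index, phase, ...).
#' @return An object of class `cat_trace`: list with `times`, `values`,
#'   `fs` (sampling rate, Hz) and `meta`.
#' @export
cat_trace <- function(times, values, meta = list()) {
  if (length(times) < 2L) stop("a trace needs at least 2 samples")
  if (length(times) != length(values)) stop("times/values length mismatch")
  dt <- diff(times)
  if (any(dt <= 0)) stop("times must be strictly increasing")
  if (max(dt) - min(dt) > 1e-9) stop("non-uniform time grid (tolerance 1e-9 s)")
  if (any(!is.finite(values))) stop("trace contains non-finite values")
  structure(list(times = as.numeric(times), values = as.numeric(values),
                 fs = 1 / mean(dt), meta = meta),
            class = "cat_trace")
}

#' @export
print.cat_trace <- function(x, ...) {
  cat(sprintf("<cat_trace> %d samples @ %.6g Hz (%.3g s)",
              length(x$times), x$fs, diff(range(x$times))))
  if (!is.null(x$meta$well_id)) {
    cat(sprintf("  well %s [%s/%s]", x$meta$well_id,
                x$meta$cell_line %||% "?", x$meta$phase %||% "?"))
  }
  cat("\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a multi-well trace file
#'
#' The trace file is delimited text whose first column is `time_s` and whose
#' remaining columns are fluorescence signals named by well id. Metadata is
#' joined from the plate map; a well present in only one file is an error.
#' A plate map row key is (well_id, phase), so the same physical well appears
#' once per recording phase; trace files are per phase.
#'
#' @param trace_path CSV of `time_s` + one column per well.
#' @param platemap_path Plate-map CSV (see [read_platemap()]).
#' @param phase Which phase this trace file records, `"pre"` or `"post"`.
#' @return List of `cat_trace`, one per well column.
#' @export
read_traces <- function(trace_path, platemap_path, phase = "post") {
  df <- utils::read.csv(trace_path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1] != "time_s") stop("first trace column must be 'time_s'")
  pm <- read_platemap(platemap_path)
  pm <- pm[pm$phase == phase, , drop = FALSE]
  wells <- names(df)[-1]
  missing_pm <- setdiff(wells, pm$well_id)
  missing_tr <- setdiff(pm$well_id, wells)
  if (length(missing_pm) || length(missing_tr)) {
    stop("well mismatch between trace file and plate map; only in traces: [",
         paste(missing_pm, collapse = ","), "] only in plate map: [",
         paste(missing_tr, collapse = ","), "]")
  }
  if (anyNA(df)) stop("trace file contains NA values")
  lapply(wells, function(w) {
    row <- pm[match(w, pm$well_id), ]
    cat_trace(df$time_s, df[[w]],
              meta = list(well_id = w, cell_line = row$cell_line,
                          compound = row$compound,
                          dose_index = row$dose_index, phase = row$phase))
  })
}

#' Write a multi-well trace file
#'
#' @param traces List of `cat_trace` sharing one time grid.
#' @param path Output CSV path.
#' @param digits Decimal digits of the serialized values.
#' @return `path`, invisibly.
#' @export
write_traces <- function(traces, path, digits = 6L) {
  stopifnot(length(traces) >= 1L)
  t0 <- traces[[1]]$times
  for (tr in traces) {
    if (length(tr$times) != length(t0) || max(abs(tr$times - t0)) > 1e-9) {
      stop("all traces in one file must share the time grid")
    }
  }
  cols <- lapply(traces, function(tr) round(tr$values, digits))
  names(cols) <- vapply(traces, function(tr) tr$meta$well_id %||% "", "")
  if (any(names(cols) == "") || anyDuplicated(names(cols))) {
    stop("every trace needs a unique well_id in its meta")
  }
  df <- data.frame(time_s = round(t0, 9L), cols, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- flat config ----------------------------------------------------------

#' Read a flat key-value configuration file
#'
#' Parses a minimal YAML dialect: one `key: value` pair per line, `#`
#' comments, blank lines ignored, no nesting. Values are coerced to numeric
#' or logical where unambiguous. Used by the command-line interface to
#' override detection/classification defaults.
#'
#' @param path Config file path.
#' @return Named list.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z0-9_.]+)\\s*:\\s*(.*)$", ln))[[1]]
    if (length(m) != 3L) stop("cannot parse config line: '", ln, "'")
    key <- m[2]; val <- trimws(m[3])
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num
      else if (tolower(val) %in% c("true", "false")) as.logical(toupper(val))
      else val
  }
  out
}
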