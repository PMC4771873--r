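# Plain-text exchange formats: trace CSVs with JSON sidecars, protocol and
# bath-condition JSON, and flat results JSON. Desk-scale, dependency-light,
# diffable; numeric round-trips are lossless at double precision.

.TRACE_COLS <- c("time_ms", "voltage_mV", "current_pA")

.sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path), ".json")

#' Write a current trace to CSV (plus JSON metadata sidecar)
#'
#' @param trace A [current_trace()].
#' @param path Output CSV path; metadata goes to `<path-sans-ext>.json`.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "current_trace"))
  # %.17g round-trips IEEE doubles exactly
  txt <- data.frame(lapply(as.data.frame(trace),
                           function(x) sprintf("%.17g", x)),
                    check.names = FALSE)
  utils::write.csv(txt, path, row.names = FALSE, quote = FALSE)
  meta <- attr(trace, "meta")
  if (length(meta))
    jsonlite::write_json(meta, .sidecar_path(path), auto_unbox = TRUE,
                         digits = NA, null = "null")
  invisible(path)
}

#' Read a current trace from CSV
#'
#' Requires columns `time_ms`, `voltage_mV`, `current_pA`; malformed numeric
#' fields raise a parse error naming the offending file line. Extra columns
#' are preserved in the `extra` attribute, and a JSON sidecar (if present)
#' is restored as the trace metadata.
#'
#' @param path CSV path written by [write_trace()] (or compatible).
#' @return A [current_trace()].
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0) stop("parse error in ", path, ": file is empty")
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                 error = function(e)
                   stop("parse error in ", path, ": ", conditionMessage(e)))
  if (nrow(df) == 0) stop("parse error in ", path, ": no data rows")
  missing <- setdiff(.TRACE_COLS, names(df))
  if (length(missing))
    stop("parse error in ", path, ": missing column(s) ",
         paste(missing, collapse = ", "))
  for (col in .TRACE_COLS) {
    x <- df[[col]]
    num <- suppressWarnings(as.numeric(x))
    bad <- which(is.na(num) & !(is.na(x) | x == ""))
    if (length(bad))
      stop("parse error in ", path, " line ", bad[1] + 1,
           ": non-numeric value '", x[bad[1]], "' in column ", col)
    if (anyNA(num))
      stop("parse error in ", path, " line ", which(is.na(num))[1] + 1,
           ": missing value in column ", col)
    df[[col]] <- num
  }
  extra <- df[setdiff(names(df), .TRACE_COLS)]
  meta <- list()
  sc <- .sidecar_path(path)
  if (file.exists(sc)) meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  tr <- current_trace(df$time_ms, df$voltage_mV, df$current_pA, meta = meta)
  if (ncol(extra)) attr(tr, "extra") <- extra
  tr
}

conditions_to_list <- function(cond) {
  list(int = as.list(cond$int), ext = as.list(cond$ext),
       temperature_K = cond$temperature,
       permeabilities = as.list(cond$permeabilities))
}

list_to_conditions <- function(x) {
  perm <- if (is.null(x$permeabilities)) ion_permeabilities()
          else unlist(x$permeabilities)
  bath_conditions(int = unlist(x$int), ext = unlist(x$ext),
                  temperature = x$temperature_K, permeabilities = perm)
}

#' Read/write bath conditions as JSON
#'
#' Format: `{"int": {"K": 120}, "ext": {"K": 4}, "temperature_K": 294,
#' "permeabilities": {...}}`.
#'
#' @param conditions A [bath_conditions()] object.
#' @param path JSON path.
#' @return `write_conditions` returns the path invisibly; `read_conditions`
#'   a [bath_conditions()] object.
#' @export
write_conditions <- function(conditions, path) {
  jsonlite::write_json(conditions_to_list(conditions), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_conditions
#' @export
read_conditions <- function(path) {
  list_to_conditions(jsonlite::read_json(path, simplifyVector = FALSE))
}

#' Read/write a voltage protocol as JSON
#'
#' Format: `{"dt_ms": 0.05, "segments": [{"ms": 50, "mV": -80}, ...]}`;
#' ramp segments may carry `mV_end`.
#'
#' @param protocol A [voltage_protocol()].
#' @param path JSON path.
#' @return `write_protocol` returns the path invisibly; `read_protocol` a
#'   [voltage_protocol()].
#' @export
write_protocol <- function(protocol, path) {
  stopifnot(inherits(protocol, "voltage_protocol"))
  seg <- protocol$segments
  segs <- lapply(seq_len(nrow(seg)), function(i) {
    s <- list(ms = seg$ms[i], mV = seg$mV[i])
    if (!is.na(seg$mV_end[i])) s$mV_end <- seg$mV_end[i]
    s
  })
  jsonlite::write_json(list(dt_ms = protocol$dt, segments = segs), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_protocol
#' @export
read_protocol <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  seg <- do.call(rbind, lapply(x$segments, function(s)
    data.frame(ms = s$ms, mV = s$mV,
               mV_end = if (is.null(s$mV_end)) NA_real_ else s$mV_end)))
  voltage_protocol(seg, dt = x$dt_ms)
}

#' Write a trace family to a directory
#'
#' One CSV per step voltage plus a `family.json` manifest (preset, voltages,
#' timing, conditions, seed).
#'
#' @param family A `trace_family`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_family <- function(family, dir) {
  stopifnot(inherits(family, "trace_family"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- sprintf("trace_%+04d mV.csv", round(family$step_mV))
  files <- gsub(" ", "", files)
  for (i in seq_along(family$traces))
    write_trace(family$traces[[i]], file.path(dir, files[i]))
  manifest <- list(
    preset = family$preset, step_mV = family$step_mV, files = files,
    hold_mV = family$hold_mV, tail_mV = family$tail_mV,
    step_start_ms = family$step_start_ms,
    tail_start_ms = family$tail_start_ms, dt = family$dt,
    temperature = family$temperature, noise = family$noise,
    seed = family$seed, conditions = conditions_to_list(family$conditions))
  jsonlite::write_json(manifest, file.path(dir, "family.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read a trace family from a directory written by [write_family()]
#'
#' @param dir Directory containing `family.json` and the trace CSVs.
#' @return A `trace_family`.
#' @export
read_family <- function(dir) {
  mf_path <- file.path(dir, "family.json")
  if (!file.exists(mf_path)) stop("no family.json in ", dir)
  mf <- jsonlite::read_json(mf_path, simplifyVector = TRUE)
  traces <- lapply(file.path(dir, mf$files), read_trace)
  names(traces) <- paste0(mf$step_mV, "mV")
  structure(
    list(traces = traces, step_mV = mf$step_mV, preset = mf$preset,
         hold_mV = mf$hold_mV, tail_mV = mf$tail_mV,
         step_start_ms = mf$step_start_ms, tail_start_ms = mf$tail_start_ms,
         dt = mf$dt, temperature = mf$temperature,
         conditions = list_to_conditions(mf$conditions), params = NULL,
         noise = mf$noise, seed = mf$seed),
    class = "trace_family")
}

#' Write/read flat analysis results as JSON
#'
#' Numeric round-trips are exact (doubles serialised at full precision).
#'
#' @param x A (possibly nested) list of results.
#' @param path JSON path.
#' @return `write_results` returns the path invisibly; `read_results` the
#'   parsed list.
#' @export
write_results <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
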