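#' Write a recording to a delimited text file
#'
#' Plain CSV with the metadata in `#`-prefixed `key: value` header lines,
#' followed by a `time,value` header and full-precision samples. The round
#' trip through [read_trace()] is lossless.
#'
#' @param rec A [recording()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(rec, path) {
  stopifnot(inherits(rec, "synapse_recording"))
  meta <- attr(rec, "meta")
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(meta)) {
    writeLines(sprintf("# %s: %s", nm, format(meta[[nm]], digits = 17)), con)
  }
  writeLines("time,value", con)
  writeLines(paste(format(rec$time, digits = 17, trim = TRUE, scientific = FALSE),
                   format(rec$value, digits = 17, trim = TRUE),
                   sep = ","), con)
  invisible(path)
}

#' Read a recording from a delimited text file
#'
#' @param path File written by [write_trace()] (or any `time,value` CSV with
#'   optional `# key: value` metadata header lines).
#' @return A [recording()] object.
#' @export
read_trace <- function(path) {
  lines <- readLines(path)
  is_meta <- startsWith(lines, "#")
  meta <- list()
  for (ln in lines[is_meta]) {
    m <- regmatches(ln, regexec("^#\\s*([^:]+):\\s*(.*)$", ln))[[1]]
    if (length(m) != 3) rlang::abort(paste("malformed metadata line:", ln))
    key <- trimws(m[2]); val <- trimws(m[3])
    num <- suppressWarnings(as.numeric(val))
    meta[[key]] <- if (!is.na(num)) num else if (val == "NA") NA_real_ else val
  }
  body <- lines[!is_meta]
  if (!length(body) || !grepl("time", body[1])) {
    rlang::abort("missing 'time,value' header line")
  }
  header <- strsplit(body[1], ",")[[1]]
  if (!"value" %in% header) rlang::abort("missing column: value")
  dat <- utils::read.csv(text = body, header = TRUE)
  if (is.unsorted(dat$time, strictly = TRUE)) {
    rlang::abort("time column must be strictly increasing")
  }
  dt <- diff(dat$time)
  if (max(abs(dt - dt[1])) > 1e-6 * dt[1]) {
    rlang::abort("time column must be uniformly sampled")
  }
  if (!is.null(meta$compartments)) meta$compartments <- as.integer(meta$compartments)
  recording(dat$time, dat$value, meta)
}

#' Load a model configuration file
#'
#' YAML file with optional sections `neuron`, `receptor`, `transport`,
#' `plasticity` (keys named as the constructor arguments, values in the
#' package units: ms, nS, mV, uM, mM) plus optional `protocol`, `clamp` and
#' `condition` sections. Durations may be given in seconds with a `_s` key
#' suffix (e.g. `tau_diff_s: 1.17`); they are converted to ms on load.
#'
#' @param path Path to the YAML file.
#' @return List with `params` ([synapse_params()]), and (when present)
#'   `protocol`, `clamp`, `condition_name`.
#' @export
load_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    rlang::abort("the 'yaml' package is required to read config files")
  }
  cfg <- yaml::read_yaml(path)
  norm <- function(x) {
    if (is.null(x)) return(list())
    sec <- grepl("_s$", names(x))
    for (nm in names(x)[sec]) {
      x[[sub("_s$", "", nm)]] <- to_ms(x[[nm]], "s")
      x[[nm]] <- NULL
    }
    x
  }
  params <- synapse_params(
    neuron = do.call(neuron_params, norm(cfg$neuron)),
    receptor = do.call(receptor_params, norm(cfg$receptor)),
    transport = do.call(transport_params, norm(cfg$transport)),
    plasticity = do.call(plasticity_params, norm(cfg$plasticity))
  )
  out <- list(params = params)
  if (!is.null(cfg$protocol)) {
    out$protocol <- do.call(stim_train, cfg$protocol)
  }
  if (!is.null(cfg$clamp)) {
    out$clamp <- do.call(clamp_spec, cfg$clamp)
  }
  if (!is.null(cfg$condition)) out$condition_name <- cfg$condition
  out
}
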