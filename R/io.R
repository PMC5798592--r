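pack_array <- function(x) {
  if (is.list(x)) return(lapply(x, pack_array))
  list(data = as.numeric(x), dim = if (is.null(dim(x))) length(x) else dim(x))
}

unpack_array <- function(x) {
  if (!is.null(x$data)) {
    return(array(as.numeric(unlist(x$data)), unlist(x$dim)))
  }
  lapply(x, unpack_array)
}

#' Write a discrete model specification to JSON or YAML
#'
#' Serializes the named arrays of a [discrete_model()] (A, B, C, D,
#' policies, T) to a plain-text document; arrays are stored flat together
#' with their dimensions.
#'
#' @param model A [discrete_model()].
#' @param path Output file; format chosen by extension (`.json`, `.yaml` /
#'   `.yml`) unless `format` is given.
#' @param format `"json"` or `"yaml"`.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path, format = NULL) {
  format <- format %||% if (grepl("\\.ya?ml$", path)) "yaml" else "json"
  doc <- list(
    A = pack_array(model$A), B = pack_array(model$B),
    C = pack_array(model$C), D = pack_array(model$D),
    policies = pack_array(model$policies),
    control = model$control, T = model$T, label = model$label
  )
  if (format == "yaml") {
    yaml::write_yaml(doc, path, precision = 15L)
  } else {
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a discrete model specification from JSON or YAML
#'
#' @param path File written by [write_model()] (or hand-authored in the
#'   same layout).
#' @return A [discrete_model()].
#' @export
read_model <- function(path) {
  doc <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path) else
    jsonlite::read_json(path, simplifyVector = FALSE)
  pol <- unpack_array(doc$policies)
  if (is.list(pol)) pol <- pol[[1L]]
  discrete_model(
    A = unpack_array(doc$A),
    B = unpack_array(doc$B),
    C = unpack_array(doc$C),
    D = lapply(unpack_array(doc$D), as.numeric),
    policies = array(as.integer(pol), dim(pol) %||% length(pol)),
    control = as.integer(unlist(doc$control)),
    T = as.integer(doc$T),
    label = doc$label
  )
}

#' Export a trial record to JSON metadata plus CSV traces
#'
#' Writes the policy posterior, expected free energy and free-energy traces
#' of a trial to `<stem>_traces.csv` (one row per epoch x policy, ready for
#' plotting) and the remaining metadata (outcomes, actions, true states,
#' scheme) to `<stem>.json`.
#'
#' @param trial A `bp_trial` from [run_trial()].
#' @param stem Output path stem (no extension).
#' @return Named character vector of the files written, invisibly.
#' @export
write_trial_record <- function(trial, stem) {
  traces <- tidy(trial)
  csv <- paste0(stem, "_traces.csv")
  utils::write.csv(traces, csv, row.names = FALSE)
  meta <- list(
    T = trial$T, scheme = trial$scheme %||% "gradient",
    actions = trial$actions, true_states = trial$true_states,
    outcomes = lapply(trial$outcomes, function(o)
      lapply(o, function(x) as.numeric(x))),
    bma = pack_array(trial$bma)
  )
  json <- paste0(stem, ".json")
  jsonlite::write_json(meta, json, auto_unbox = TRUE, digits = NA)
  invisible(c(traces = csv, metadata = json))
}

#' Export a continuous trajectory to CSV
#'
#' One row per integration step: time, true states, state and cause
#' expectations, action and free energy.
#'
#' @param traj A `bp_trajectory` from [integrate_active()].
#' @param path Output CSV file.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  utils::write.csv(tidy(traj), path, row.names = FALSE)
  invisible(path)
}
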