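#' Load model parameters from a config file or preset name
#'
#' Accepts either the name of a built-in preset (see [fhn_presets()]) or
#' the path to a JSON or YAML file with keys `tau_m`, `R_I`, `b`,
#' optionally `u_1` (default 1), and either `tau_k` or `epsilon`, and
#' either `R_w` or `r`. Unknown keys are rejected.
#'
#' @param source Preset name or file path. Files ending in `.json` are
#'   parsed with jsonlite, anything else with yaml (which also reads
#'   JSON-style scalars).
#' @return A validated `fhn_model`.
#' @export
load_config <- function(source) {
  if (!is.character(source) || length(source) != 1L)
    stop("'source' must be a preset name or a file path", call. = FALSE)
  if (source %in% fhn_presets()) return(fhn_preset(source))
  if (!file.exists(source))
    stop(sprintf("'%s' is neither a preset (%s) nor an existing file",
                 source, paste(fhn_presets(), collapse = ", ")),
         call. = FALSE)
  cfg <- if (grepl("\\.json$", source, ignore.case = TRUE))
    jsonlite::read_json(source, simplifyVector = TRUE)
  else yaml::read_yaml(source)
  if (!is.list(cfg)) stop("config must be a key-value mapping", call. = FALSE)
  allowed <- c("tau_m", "tau_k", "epsilon", "R_I", "R_w", "r", "b", "u_1")
  extra <- setdiff(names(cfg), allowed)
  if (length(extra))
    stop("unknown config key(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  missing_req <- setdiff(c("tau_m", "R_I", "b"), names(cfg))
  if (length(missing_req))
    stop("missing config key(s): ", paste(missing_req, collapse = ", "),
         call. = FALSE)
  do.call(fhn_model, cfg)
}

#' Write model parameters to a config file
#'
#' Serializes the six independent parameters so that [load_config()]
#' round-trips them bit-exactly (17 significant digits).
#'
#' @param model An `fhn_model` or preset name.
#' @param path Output path; `.json` selects JSON, anything else YAML.
#' @return `path`, invisibly.
#' @export
write_config <- function(model, path) {
  m <- as_fhn_model(model)
  fields <- m[c("tau_m", "tau_k", "R_I", "R_w", "b", "u_1")]
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(fields, path, auto_unbox = TRUE, digits = I(17))
  } else {
    lines <- vapply(names(fields), function(k)
      sprintf("%s: %.17g", k, fields[[k]]), "")
    writeLines(lines, path)
  }
  invisible(path)
}

#' Hopf voltages of the built-in models
#'
#' Runs [bifurcation_summary()] on presets A--F and tabulates the positive
#' Hopf voltage for each (NA where the fixed point never destabilizes,
#' i.e. `epsilon * b >= 1`).
#'
#' @return A data frame with columns `model` and `u_hopf`.
#' @examples
#' hopf_table()
#' @export
hopf_table <- function() {
  models <- c("A", "B", "C", "D", "E", "F")
  u_h <- vapply(models, function(nm)
    bifurcation_summary(fhn_preset(nm))$hopf_voltage, numeric(1))
  data.frame(model = models, u_hopf = unname(u_h))
}

#' Write a data frame as CSV at full precision
#'
#' All floats are serialized with 17 significant digits so re-reading the
#' file reproduces the in-memory values exactly.
#'
#' @param x A data frame (e.g. from [steady_state_table()],
#'   [stability_scan()], or `as.data.frame()` on a spectrum/trajectory).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_csv_exact <- function(x, path) {
  stopifnot(is.data.frame(x))
  num <- vapply(x, is.double, TRUE)
  x[num] <- lapply(x[num], function(col) sprintf("%.17g", col))
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
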