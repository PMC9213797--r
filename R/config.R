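.config_defaults <- function() {
  list(
    physics = list(temperature = 298, dielectric = 78.4,
                   viscosity = 0.89, scaling_factor = 0.786,
                   ionic_strength = NULL, debye_length = NULL),
    bd = list(dt = NULL, max_steps = 1000L, snapshot_stride = 100L,
              seed = NULL, constraints_on = FALSE, hi_on = FALSE,
              hi_update_interval = 400L, force_update_interval = 1L),
    paths = list(system = NULL, forcefield = NULL, output = NULL),
    observables = list())
}

#' Parse a run configuration
#'
#' YAML configuration with sections `paths` (system, forcefield, output),
#' `physics` (temperature 298 K, dielectric 78.4, viscosity 0.89 cP,
#' scaling_factor 0.786 by default; exactly one of `ionic_strength`
#' (mol/m^3) or `debye_length` (A) — when both are given they must agree
#' through [debye_length()]), `bd` (any [bd_params()] field) and
#' `observables`. Unknown keys are rejected; defaults are applied and the
#' result echoes verbatim into run provenance.
#'
#' @param x Path to a YAML file, or YAML text.
#' @return A validated `bd_config` list with `debye_length` resolved.
#' @export
parse_config <- function(x) {
  raw <- if (length(x) == 1L && file.exists(x)) yaml::read_yaml(x)
         else yaml::yaml.load(paste(x, collapse = "\n"))
  if (is.null(raw)) raw <- list()
  defaults <- .config_defaults()
  bad <- setdiff(names(raw), names(defaults))
  if (length(bad) > 0) {
    stop("unknown config section(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  cfg <- defaults
  for (sec in names(raw)) {
    bad <- setdiff(names(raw[[sec]]), names(defaults[[sec]]))
    if (sec != "observables" && length(bad) > 0) {
      stop("unknown key(s) in '", sec, "': ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    cfg[[sec]][names(raw[[sec]])] <- raw[[sec]]
  }
  ph <- cfg$physics
  if (!is.null(ph$ionic_strength) && !is.null(ph$debye_length)) {
    implied <- debye_length(ph$ionic_strength, ph$temperature,
                            ph$dielectric)
    if (abs(implied - ph$debye_length) > 0.01 * ph$debye_length) {
      stop("inconsistent ionic_strength and debye_length: ",
           ph$ionic_strength, " mol/m^3 implies ", signif(implied, 4),
           " A, not ", ph$debye_length, " A", call. = FALSE)
    }
  }
  if (is.null(ph$debye_length)) {
    cfg$physics$debye_length <- if (!is.null(ph$ionic_strength)) {
      debye_length(ph$ionic_strength, ph$temperature, ph$dielectric)
    } else 7.85
  }
  if (is.null(cfg$bd$dt)) {
    cfg$bd$dt <- if (isTRUE(cfg$bd$constraints_on)) 0.2 else 0.05
  }
  structure(cfg, class = "bd_config")
}

#' Emit a configuration as YAML
#'
#' Round trip: `parse_config(emit_config(cfg))` reproduces `cfg`.
#'
#' @param cfg A `bd_config`.
#' @param path Optional output file.
#' @return YAML text, invisibly when writing.
#' @export
emit_config <- function(cfg, path = NULL) {
  txt <- yaml::as.yaml(unclass(cfg))
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}
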