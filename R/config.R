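# Flat key-value configuration files. Keys mirror the parameter-set field
# names; values are either plain SI numbers or strings with an explicit
# unit, e.g. "15.9 GPa", "50 um", "1e-18 m^2". Everything is converted to SI
# once, at this boundary.

unit_factors <- c(
  "Pa" = 1, "kPa" = 1e3, "MPa" = 1e6, "GPa" = 1e9,
  "m" = 1, "mm" = 1e-3, "um" = 1e-6, "nm" = 1e-9,
  "m^2" = 1, "m2" = 1,
  "Pa.s" = 1, "Pa s" = 1, "Pas" = 1,
  "kg/m^3" = 1, "kg m-3" = 1,
  "Hz" = 1, "1" = 1, "1/s" = 1, "s-1" = 1
)

parse_quantity <- function(x, key) {
  if (is.numeric(x)) return(as.numeric(x))
  x <- trimws(as.character(x))
  m <- regmatches(x, regexec("^([-+0-9.eE]+)\\s*(.*)$", x))[[1]]
  if (length(m) != 3 || m[2] == "")
    stop("cannot parse config value '", x, "' for key '", key, "'",
         call. = FALSE)
  val <- as.numeric(m[2])
  unit <- m[3]
  if (unit == "") return(val)
  if (!unit %in% names(unit_factors))
    stop("unknown unit '", unit, "' for key '", key, "'; known units: ",
         paste(names(unit_factors), collapse = ", "), call. = FALSE)
  val * unit_factors[[unit]]
}

#' Read a parameter set from a configuration file
#'
#' Reads a flat YAML file whose keys are [osteon_params()] argument names.
#' Numeric values are taken as SI; character values may carry a unit string
#' (`"15.9 GPa"`, `"50 um"`). Unknown keys are an error. `...` overrides
#' take precedence over the file, mirroring command-line flags.
#'
#' @param path path to the YAML file.
#' @param ... overrides passed on to [osteon_params()].
#' @return an `osteon_params` object.
#' @export
read_osteon_config <- function(path, ...) {
  raw <- yaml::read_yaml(path)
  if (!is.list(raw)) stop("config file must be a key-value mapping",
                          call. = FALSE)
  valid <- setdiff(names(formals(osteon_params)), "...")
  bad <- setdiff(names(raw), valid)
  if (length(bad))
    stop("unknown config keys: ", paste(bad, collapse = ", "),
         "; valid keys: ", paste(valid, collapse = ", "), call. = FALSE)
  chr_keys <- c("case", "beta_form", "outer_restraint")
  args <- lapply(stats::setNames(names(raw), names(raw)), function(k) {
    if (k %in% chr_keys) as.character(raw[[k]]) else parse_quantity(raw[[k]], k)
  })
  over <- list(...)
  args[names(over)] <- over
  do.call(osteon_params, args)
}
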