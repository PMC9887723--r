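#' Read a kinetic parameter configuration file
#'
#' Flat key-value text format, one parameter per line (\code{key = value}),
#' with \code{#} comments carrying the units. Missing keys take the
#' reference defaults; unknown keys are errors (no silent typos). A file
#' written by [write_config()] reads back bit-exactly.
#'
#' @param path file path.
#' @param base parameter set supplying defaults for keys absent from the
#'   file.
#' @return a [kinetic_parameters()] set.
#' @export
read_config <- function(path, base = kinetic_parameters()) {
  if (!file.exists(path))
    stop("configuration file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  p <- validate_parameters(base)
  for (i in seq_along(lines)) {
    line <- sub("#.*$", "", lines[i])
    line <- trimws(line)
    if (!nzchar(line)) next
    m <- regmatches(line, regexec("^([A-Za-z_][A-Za-z0-9_]*)\\s*=\\s*(.+)$",
                                  line))[[1L]]
    if (length(m) != 3L)
      stop("malformed configuration at line ", i, ": '", lines[i], "'",
           call. = FALSE)
    key <- m[2L]; value <- trimws(m[3L])
    if (!key %in% names(.default_parameters))
      stop("unknown configuration key '", key, "' at line ", i,
           call. = FALSE)
    if (key == "ec_mode") {
      p[[key]] <- value
    } else {
      num <- suppressWarnings(as.numeric(gsub("−", "-", value)))
      if (is.na(num) && !identical(value, "NA"))
        stop("non-numeric value for '", key, "' at line ", i, call. = FALSE)
      p[[key]] <- num
    }
  }
  validate_parameters(p)
}

.param_units <- c(
  kp = "pmol/mm^3/h", k21 = "1/h", k23 = "1/(pmol/mm^3)/h", k32 = "1/h",
  kDNA_DG = "1/h", kDNA_DPX = "1/h", krep_DG = "1/h", krep_DPX = "1/h",
  Vmax = "pmol/mm^3/h", Km = "pmol/mm^3", thick = "mm",
  endoF_init = "pmol/mm^3", GSH_init = "pmol/mm^3",
  endoF_GSH_init = "pmol/mm^3", endoDG_init = "pmol/mm^3",
  endoDPX_init = "pmol/mm^3", ec_mode = "off|zero_order|saturable",
  ec_rate = "pmol/mm^3/h", ec_Vmax = "pmol/mm^3/h", ec_Km = "pmol/mm^3")

#' Write a kinetic parameter configuration file
#'
#' @param params a [kinetic_parameters()] set.
#' @param path output path.
#' @return the path, invisibly.
#' @rdname read_config
#' @export
write_config <- function(params, path) {
  params <- validate_parameters(params)
  fmt <- function(key) {
    v <- params[[key]]
    val <- if (is.character(v)) v else format(v, digits = 17)
    sprintf("%s = %s  # %s", key, val, .param_units[[key]])
  }
  writeLines(vapply(names(.default_parameters), fmt, ""), path)
  invisible(path)
}
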