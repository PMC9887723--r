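#' Kinetic parameters of the nasal mucosa dosimetry model
#'
#' Constructs the full kinetic parameter set for the nine-state formaldehyde
#' dosimetry model. With no arguments it returns the reference calibration for
#' the F344 rat nasal mucosa; any parameter can be overridden by name.
#'
#' Units are hours for time and pmol/mm^3 for concentration throughout
#' (1 pmol/mm^3 = 1 uM).
#'
#' @param ... named overrides of individual parameters. Valid names:
#'   \describe{
#'     \item{kp}{zero-order endogenous formaldehyde production (pmol/mm^3/h).}
#'     \item{k21}{first-order formaldehyde loss (1/h).}
#'     \item{k23}{second-order formaldehyde + GSH association
#'       (1/(pmol/mm^3)/h).}
#'     \item{k32}{first-order dissociation of the formaldehyde-GSH complex
#'       (1/h).}
#'     \item{kDNA_DG}{first-order DG monoadduct formation (1/h).}
#'     \item{kDNA_DPX}{first-order DPX formation (1/h).}
#'     \item{krep_DG}{first-order DG adduct repair/loss (1/h).}
#'     \item{krep_DPX}{first-order DPX repair/loss (1/h).}
#'     \item{Vmax}{maximum formaldehyde-dehydrogenase oxidation rate of the
#'       GSH complex (pmol/mm^3/h).}
#'     \item{Km}{affinity constant of the complex for the enzyme (pmol/mm^3).}
#'     \item{thick}{mucosal thickness (mm).}
#'     \item{endoF_init, GSH_init, endoF_GSH_init, endoDG_init,
#'       endoDPX_init}{initial concentrations (pmol/mm^3).}
#'     \item{ec_mode}{extracellular clearance variant: \code{"off"} (default),
#'       \code{"zero_order"} or \code{"saturable"}.}
#'     \item{ec_rate}{zero-order extracellular clearance rate (pmol/mm^3/h),
#'       used when \code{ec_mode = "zero_order"}.}
#'     \item{ec_Vmax, ec_Km}{saturable extracellular clearance parameters,
#'       used when \code{ec_mode = "saturable"}.}
#'   }
#' @return an object of class \code{kinetic_parameters} (a named list).
#' @examples
#' p <- kinetic_parameters()
#' p$kp
#' kinetic_parameters(kp = 4200)$kp
#' @export
kinetic_parameters <- function(...) {
  p <- .default_parameters
  overrides <- list(...)
  if (length(overrides)) {
    if (is.null(names(overrides)) || any(names(overrides) == ""))
      stop("all parameter overrides must be named", call. = FALSE)
    unknown <- setdiff(names(overrides), names(p))
    if (length(unknown))
      stop("unknown parameter(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    p[names(overrides)] <- overrides
  }
  validate_parameters(p)
}

# Reference calibration for the F344 rat nasal mucosa.
.default_parameters <- list(
  kp             = 10835,
  k21            = 16.57,
  k23            = 0.35,
  k32            = 200,
  kDNA_DG        = 9.5183e-8,
  kDNA_DPX       = 1.8183e-4,
  krep_DG        = 0.0063,
  krep_DPX       = 0.39,
  Vmax           = 74156,
  Km             = 1935,
  thick          = 0.1138,
  endoF_init     = 20.0,
  GSH_init       = 4506,
  endoF_GSH_init = 120,
  endoDG_init    = 7.42e-4,
  endoDPX_init   = 0.01,
  ec_mode        = "off",
  ec_rate        = 2.02e3,
  ec_Vmax        = NA_real_,
  ec_Km          = NA_real_
)

.rate_names <- c("kp", "k21", "k23", "k32", "kDNA_DG", "kDNA_DPX",
                 "krep_DG", "krep_DPX", "Vmax", "Km", "thick")
.init_names <- c("endoF_init", "GSH_init", "endoF_GSH_init",
                 "endoDG_init", "endoDPX_init")

#' Validate a kinetic parameter set
#'
#' Checks positivity of rate constants, capacities and thickness,
#' non-negativity of initial concentrations, and the extracellular clearance
#' variant settings.
#'
#' @param p a list of parameters as produced by [kinetic_parameters()].
#' @return \code{p}, classed as \code{kinetic_parameters}, invisibly valid.
#' @export
validate_parameters <- function(p) {
  stopifnot(is.list(p))
  missing <- setdiff(names(.default_parameters), names(p))
  if (length(missing))
    stop("missing parameter(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  for (nm in c(.rate_names, .init_names, "ec_rate")) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("parameter '", nm, "' must be a single finite number",
           call. = FALSE)
    p[[nm]] <- as.numeric(v)
  }
  bad <- .rate_names[vapply(.rate_names, function(nm) p[[nm]] <= 0,
                            logical(1))]
  if (length(bad))
    stop("parameter(s) must be strictly positive: ",
         paste(bad, collapse = ", "), call. = FALSE)
  bad <- .init_names[vapply(.init_names, function(nm) p[[nm]] < 0,
                            logical(1))]
  if (length(bad))
    stop("initial concentration(s) must be non-negative: ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (!p$ec_mode %in% c("off", "zero_order", "saturable"))
    stop("ec_mode must be one of 'off', 'zero_order', 'saturable'",
         call. = FALSE)
  if (p$ec_mode == "zero_order" && p$ec_rate < 0)
    stop("ec_rate must be non-negative", call. = FALSE)
  if (p$ec_mode == "saturable" &&
      (!is.finite(p$ec_Vmax) || !is.finite(p$ec_Km) ||
       p$ec_Vmax <= 0 || p$ec_Km <= 0))
    stop("saturable clearance requires positive ec_Vmax and ec_Km",
         call. = FALSE)
  structure(p, class = "kinetic_parameters")
}

#' @export
print.kinetic_parameters <- function(x, ...) {
  cat("<kinetic_parameters> (pmol/mm^3, h)\n")
  num <- unlist(x[c(.rate_names, .init_names)])
  print(num)
  cat("ec_mode:", x$ec_mode)
  if (x$ec_mode == "zero_order") cat("  ec_rate:", x$ec_rate)
  if (x$ec_mode == "saturable")
    cat("  ec_Vmax:", x$ec_Vmax, " ec_Km:", x$ec_Km)
  cat("\n")
  invisible(x)
}

#' CFD-derived site flux constants
#'
#' Wall mass flux of inhaled formaldehyde into tissue at 1 ppm, predicted by
#' computational fluid dynamics for the two nasal sampling sites: the anterior
#' "high tumor" region where DPX were measured, and the larger respiratory
#' epithelium region where DG monoadducts were measured. Flux is assumed
#' linear in the inhaled concentration.
#'
#' @param site \code{"DPX"} or \code{"DG"} to select a built-in site, ignored
#'   when \code{flux_per_ppm} is supplied.
#' @param flux_per_ppm custom wall flux at 1 ppm (pmol/mm^2/h/ppm).
#' @param site_label label for a custom site.
#' @param surface_area_mm2 informational site surface area (mm^2, both sides
#'   of the nose).
#' @return an object of class \code{site_flux}.
#' @examples
#' site_flux("DG")$flux_per_ppm   # 776.6
#' site_flux("DPX")$flux_per_ppm  # 800.3
#' @export
site_flux <- function(site = c("DPX", "DG"), flux_per_ppm = NULL,
                      site_label = NULL, surface_area_mm2 = NA_real_) {
  if (is.null(flux_per_ppm)) {
    site <- match.arg(site)
    out <- switch(site,
      DPX = list(site_label = "DPX_high_tumor", flux_per_ppm = 800.3,
                 surface_area_mm2 = 171.6),
      DG  = list(site_label = "DG_site", flux_per_ppm = 776.6,
                 surface_area_mm2 = 419.9))
  } else {
    if (!is.numeric(flux_per_ppm) || length(flux_per_ppm) != 1L ||
        !is.finite(flux_per_ppm) || flux_per_ppm <= 0)
      stop("flux_per_ppm must be a single positive number", call. = FALSE)
    out <- list(site_label = if (is.null(site_label)) "custom" else site_label,
                flux_per_ppm = as.numeric(flux_per_ppm),
                surface_area_mm2 = as.numeric(surface_area_mm2))
  }
  structure(out, class = "site_flux")
}

.as_site <- function(site) {
  if (inherits(site, "site_flux")) return(site)
  if (is.character(site) && length(site) == 1L) return(site_flux(site))
  stop("site must be a site_flux object or \"DPX\"/\"DG\"", call. = FALSE)
}

# Short provenance hash of a parameter set (polynomial rolling hash over the
# formatted values; stable across sessions, used only for run provenance).
param_hash <- function(p) {
  s <- paste(vapply(names(.default_parameters), function(nm)
    paste0(nm, "=", format(p[[nm]], digits = 17)), ""), collapse = ";")
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
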