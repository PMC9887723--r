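#' Compiled rat nasal adduct observations
#'
#' Loads the packaged dataset of measured DNA adduct concentrations in F344
#' rat nasal mucosa: DG monoadducts (endogenous and exogenous) from a single
#' 6-h exposure study (Lu 2011) and a 28-day time-course study (Yu 2015),
#' deoxyguanosine-specific DNA-protein crosslinks (DPC) from Moeller 2011 and
#' Leng 2019, and total DNA-protein crosslinks (DPX) from Casanova 1989/1994.
#' One row per measured species, in pmol adduct per mm^3 tissue. Non-detect
#' rows (the Leng low-dose exogDPC measurements) carry \code{below_lod = TRUE}
#' and a missing value; the reported limit of detection is
#' \code{5.26e-7} pmol/mm^3 ([exog_dg_lod()]).
#'
#' DPC rows are carried for completeness but are not modelled; model
#' calibration uses the DG monoadduct and exogDPX data (see
#' [calibration_observations()]).
#'
#' @param study optional character vector of studies to keep
#'   (\code{"Lu2011"}, \code{"Yu2015"}, \code{"Moeller2011"},
#'   \code{"Leng2019"}, \code{"Casanova1989"}, \code{"Casanova1994"}).
#' @param species optional character vector of species to keep
#'   (\code{"endoDG"}, \code{"exogDG"}, \code{"endoDPC"}, \code{"exogDPC"},
#'   \code{"exogDPX"}).
#' @return a data frame with columns \code{study}, \code{ppm}, \code{time_h},
#'   \code{species}, \code{value_pmol_mm3}, \code{below_lod}.
#' @examples
#' nrow(adduct_observations(species = "exogDPX"))  # 5
#' @export
adduct_observations <- function(study = NULL, species = NULL) {
  path <- system.file("extdata", "adduct_observations.tsv",
                      package = "nasaldosim", mustWork = TRUE)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- gsub("−", "-", lines)  # tolerate unicode minus
  obs <- utils::read.table(textConnection(lines), header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, comment.char = "#")
  obs$below_lod <- as.logical(obs$below_lod)
  known_studies <- c("Lu2011", "Yu2015", "Moeller2011", "Leng2019",
                     "Casanova1989", "Casanova1994")
  known_species <- c("endoDG", "exogDG", "endoDPC", "exogDPC", "exogDPX")
  if (!is.null(study)) {
    bad <- setdiff(study, known_studies)
    if (length(bad))
      stop("unknown study: ", paste(bad, collapse = ", "), call. = FALSE)
    obs <- obs[obs$study %in% study, , drop = FALSE]
  }
  if (!is.null(species)) {
    bad <- setdiff(species, known_species)
    if (length(bad))
      stop("unknown species: ", paste(bad, collapse = ", "), call. = FALSE)
    obs <- obs[obs$species %in% species, , drop = FALSE]
  }
  rownames(obs) <- NULL
  obs
}

#' Limit of detection for exogenous DG adducts
#'
#' The reported limit of detection of the low-dose exogDG assay,
#' 5.26e-7 pmol/mm^3.
#'
#' @return a single number (pmol/mm^3).
#' @export
exog_dg_lod <- function() 5.26e-7

#' Constants for the adducts-per-deoxyguanosine units conversion
#'
#' DG monoadduct measurements are reported as adducts per 10^7
#' deoxyguanosine (DPC as adducts per 10^8); model currency is pmol adduct
#' per mm^3 tissue. The conversion uses the rat genome size, the G:C
#' fraction of the genome, the nuclear genome copy number (diploid by
#' default; the one genuinely ambiguous factor, kept explicit and
#' switchable), and a representative cell volume.
#'
#' @param genome_bp base pairs per haploid genome (default 3.024e9, rat).
#' @param g_fraction fraction of base pairs that are G:C (default 0.41).
#' @param cell_volume_mm3 cell volume (default 7.5e-7 mm^3).
#' @param ploidy genome copies per nucleus (default 2).
#' @param per_dg_basis denominator of the reported ratio: 1e7 for DG
#'   monoadduct data, 1e8 for DPC data.
#' @return an object of class \code{conversion_constants}.
#' @export
conversion_constants <- function(genome_bp = 3.024e9, g_fraction = 0.41,
                                 cell_volume_mm3 = 7.5e-7, ploidy = 2,
                                 per_dg_basis = 1e7) {
  vals <- c(genome_bp = genome_bp, g_fraction = g_fraction,
            cell_volume_mm3 = cell_volume_mm3, ploidy = ploidy,
            per_dg_basis = per_dg_basis)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all conversion constants must be positive and finite",
         call. = FALSE)
  structure(as.list(vals), class = "conversion_constants")
}

.AVOGADRO <- 6.022e23

#' Convert adducts-per-deoxyguanosine to tissue concentration
#'
#' \code{per_dg_to_conc()} maps a measurement of \code{x} adducts per
#' \code{per_dg_basis} deoxyguanosine to pmol adduct per mm^3 tissue:
#' adducts per cell = \code{x * ploidy * genome_bp * g_fraction /
#' per_dg_basis}; divided by cell volume and Avogadro's number, scaled to
#' pmol. \code{conc_to_per_dg()} is the exact inverse. Both are strictly
#' linear.
#'
#' @param x adducts per \code{per_dg_basis} deoxyguanosine (>= 0).
#' @param v concentration (pmol/mm^3, >= 0).
#' @param constants a [conversion_constants()] object.
#' @return the converted value(s).
#' @examples
#' per_dg_to_conc(1)            # about 5.49e-4 pmol/mm^3
#' conc_to_per_dg(per_dg_to_conc(2.5))  # 2.5
#' @export
per_dg_to_conc <- function(x, constants = conversion_constants()) {
  stopifnot(inherits(constants, "conversion_constants"))
  if (any(x < 0)) stop("x must be non-negative", call. = FALSE)
  adducts_per_cell <- x * constants$ploidy * constants$genome_bp *
    constants$g_fraction / constants$per_dg_basis
  adducts_per_cell / constants$cell_volume_mm3 / .AVOGADRO * 1e12
}

#' @rdname per_dg_to_conc
#' @export
conc_to_per_dg <- function(v, constants = conversion_constants()) {
  stopifnot(inherits(constants, "conversion_constants"))
  if (any(v < 0)) stop("v must be non-negative", call. = FALSE)
  adducts_per_cell <- v * constants$cell_volume_mm3 * .AVOGADRO / 1e12
  adducts_per_cell * constants$per_dg_basis /
    (constants$ploidy * constants$genome_bp * constants$g_fraction)
}

#' Observed fold changes across the measured dose range
#'
#' Exact arithmetic on the packaged observations: the fold increase in
#' exogDPX between 0.72 and 15.8 ppm, the fold increase in exogDG between
#' 0.7 and 15.2 ppm, and the corresponding spans in inhaled concentration.
#'
#' @param observations the adduct dataset; defaults to
#'   [adduct_observations()].
#' @return a named list with \code{exogDPX_fold}, \code{exogDG_fold},
#'   \code{ppm_fold_dpx}, \code{ppm_fold_dg}.
#' @export
observed_fold_changes <- function(observations = adduct_observations()) {
  val <- function(study, species, ppm) {
    r <- observations[observations$study == study &
                        observations$species == species &
                        observations$ppm == ppm, "value_pmol_mm3"]
    if (length(r) != 1L)
      stop("expected exactly one observation for ", study, "/", species,
           "/", ppm, " ppm", call. = FALSE)
    r
  }
  list(
    exogDPX_fold = val("Casanova1994", "exogDPX", 15.8) /
      val("Casanova1994", "exogDPX", 0.72),
    exogDG_fold = val("Lu2011", "exogDG", 15.2) /
      val("Lu2011", "exogDG", 0.7),
    ppm_fold_dpx = 15.8 / 0.72,
    ppm_fold_dg = 15.2 / 0.7)
}
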