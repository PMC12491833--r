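#' Land-use class vocabulary
#'
#' The fixed 20-entry land-use class vocabulary used by every
#' \linkS4class{LandUseSeries}. Classes are grouped into agriculture
#' (cropland, intensive grassland, biofuel cropland), extensive grassland
#' (semi-natural grazing land, tracked as its own pool), and natural
#' vegetation (everything else, including the two regrowth-forest classes).
#'
#' @return A data.frame with columns \code{id} (integer 1..20), \code{name},
#'   and \code{group} (one of \code{"agriculture"}, \code{"extensive"},
#'   \code{"natural"}).
#' @examples
#' landUseClasses()
#' @export
landUseClasses <- function() {
    data.frame(
        id = 1:20,
        name = c(
            "cropland", "intensive grassland", "biofuel cropland",
            "extensive grassland",
            "regrowth forest (abandoning)", "regrowth forest (timber)",
            "tropical forest", "tropical woodland", "savanna", "scrubland",
            "steppe", "warm mixed forest", "temperate deciduous forest",
            "temperate mixed forest", "cool conifer forest", "boreal forest",
            "tundra", "wooded tundra", "hot desert", "ice"
        ),
        group = c(
            rep("agriculture", 3L), "extensive",
            rep("natural", 16L)
        ),
        stringsAsFactors = FALSE
    )
}

#' Crop-category vocabulary
#'
#' The fixed 17-entry attribution vocabulary: 16 crop categories plus
#' pastureland (the non-crop agricultural category). Crop-fraction stacks,
#' attribution weights, and the emission ledger all use this vocabulary.
#'
#' @return Character vector of length 17.
#' @examples
#' cropCategories()
#' @export
cropCategories <- function() {
    c(
        "wheat", "rice", "maize", "tropical cereals", "temperate cereals",
        "pulses", "soybeans", "temperate oil crops", "tropical oil crops",
        "temperate roots and tubers", "tropical roots and tubers",
        "sugar crops", "palm oil", "vegetables and fruits",
        "non-food and luxury and spices", "plant-based fibers", "pasture"
    )
}

#' Emission-source vocabulary of the ledger
#'
#' Sources appearing in an \code{EmissionLedger}: the two attributable
#' land-use-change (LUC) biomass categories, the seven agricultural
#' management / non-CO2 LUC sources, and the optional soil-carbon extension.
#'
#' @return A data.frame with columns \code{source} (ledger label),
#'   \code{management_id} (1..7 for the gridded management sources, NA for
#'   biomass LUC and soil), and \code{routing} (\code{"biomass"},
#'   \code{"luc-linked"}, \code{"residue"}, \code{"pass-through"},
#'   \code{"soil"}).
#' @examples
#' emissionSources()
#' @export
emissionSources <- function() {
    data.frame(
        source = c(
            "luc_natural_to_agriculture", "luc_agricultural_transitions",
            "clearing_n2o", "peat", "manure", "residues",
            "synthetic_fertilizer", "waste_burning", "rice_ch4", "soil"
        ),
        management_id = c(NA, NA, 1L, 2L, 3L, 4L, 5L, 6L, 7L, NA),
        routing = c(
            "biomass", "biomass", "luc-linked", "luc-linked", "luc-linked",
            "residue", "pass-through", "pass-through", "pass-through", "soil"
        ),
        stringsAsFactors = FALSE
    )
}

## ledger source label for a management source id
.managementSourceName <- function(id) {
    src <- emissionSources()
    src$source[match(id, src$management_id)]
}

#' Physical constants and CO2-equivalent factors
#'
#' Bundles the stoichiometric C-to-CO2 mass ratio (exactly 44/12) and the
#' global-warming-potential (GWP) table used for CO2-equivalent aggregation
#' of CH4 and N2O. Defaults are the AR5 100-year values (CH4 = 28,
#' N2O = 265); both are configurable and the horizon label is carried into
#' all run metadata.
#'
#' @param co2PerC CO2/C mass ratio; defaults to 44/12 and there is no
#'   physical reason to change it.
#' @param gwp Named numeric vector of CO2-eq factors per gas; must contain
#'   \code{CO2 = 1} and positive entries for \code{CH4} and \code{N2O}.
#' @param gwpHorizon Label recorded in output metadata.
#' @return An object of class \code{"lucConstants"} (a validated list).
#' @examples
#' lucConstants()
#' lucConstants(gwp = c(CO2 = 1, CH4 = 27.2, N2O = 273), gwpHorizon = "AR6-100yr")
#' @export
lucConstants <- function(co2PerC = 44 / 12,
                         gwp = c(CO2 = 1, CH4 = 28, N2O = 265),
                         gwpHorizon = "AR5-100yr") {
    if (!isTRUE(all.equal(co2PerC, 44 / 12)) && !(is.numeric(co2PerC) && co2PerC > 0))
        stop("co2PerC must be a positive mass ratio")
    if (is.null(names(gwp)) || !all(c("CO2", "CH4", "N2O") %in% names(gwp)))
        stop("gwp must name CO2, CH4 and N2O")
    if (gwp[["CO2"]] != 1)
        stop("gwp for CO2 must be exactly 1")
    if (any(gwp <= 0))
        stop("all GWP factors must be > 0")
    structure(
        list(co2PerC = co2PerC, gwp = gwp, gwpHorizon = gwpHorizon),
        class = "lucConstants"
    )
}

#' @export
print.lucConstants <- function(x, ...) {
    cat("lucConstants: CO2/C =", format(x$co2PerC, digits = 10),
        "| GWP(", x$gwpHorizon, "):",
        paste(names(x$gwp), x$gwp, sep = "=", collapse = " "), "\n")
    invisible(x)
}
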