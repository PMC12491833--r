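#' @import methods
NULL

## ---- GridGeometry -----------------------------------------------------

#' GridGeometry: the spatial frame of all gridded layers
#'
#' A regular latitude/longitude raster with cell-center registration,
#' latitude rows ordered north to south, and per-row spherical-band cell
#' areas. All gridded series in the package share one GridGeometry; layers
#' on mismatched frames are rejected.
#'
#' @slot nLat,nLon Integer grid dimensions.
#' @slot resolution Cell size in degrees (nominal 5 arc-min = 1/12 degree).
#' @slot latCenters,lonCenters Cell-center coordinates in degrees;
#'   \code{latCenters} is strictly decreasing (north to south).
#' @slot cellAreaRow Cell area in km2 per latitude row (area depends only on
#'   latitude for a regular lon spacing).
#' @slot earthRadius Authalic Earth radius in km (default 6371.0072).
#'
#' @seealso [gridGeometry()], [cellAreas()]
#' @export
setClass("GridGeometry",
    representation(
        nLat = "integer", nLon = "integer", resolution = "numeric",
        latCenters = "numeric", lonCenters = "numeric",
        cellAreaRow = "numeric", earthRadius = "numeric"
    )
)

setValidity("GridGeometry", function(object) {
    msg <- character()
    if (object@nLat < 1L || object@nLon < 1L)
        msg <- c(msg, "grid must have at least one row and one column")
    if (object@resolution <= 0)
        msg <- c(msg, "resolution must be > 0")
    if (length(object@latCenters) != object@nLat)
        msg <- c(msg, "latCenters length must equal nLat")
    if (length(object@lonCenters) != object@nLon)
        msg <- c(msg, "lonCenters length must equal nLon")
    if (object@nLat > 1L && any(diff(object@latCenters) >= 0))
        msg <- c(msg, "latCenters must decrease (north to south ordering)")
    if (any(object@cellAreaRow <= 0))
        msg <- c(msg, "all cell areas must be > 0")
    if (length(msg)) msg else TRUE
})

## ---- gridded series ---------------------------------------------------

#' Virtual parent of gridded time series
#'
#' Shared frame (a \linkS4class{GridGeometry}) and an ordered vector of
#' step years with constant 5-year (configurable) spacing.
#'
#' @slot geometry The spatial frame.
#' @slot steps Integer years, strictly increasing with constant spacing.
#' @export
setClass("GridSeries",
    representation("VIRTUAL", geometry = "GridGeometry", steps = "integer")
)

.checkSteps <- function(steps) {
    if (length(steps) < 1L) return("at least one step required")
    if (length(steps) > 1L) {
        d <- diff(steps)
        if (any(d <= 0L)) return("steps must be strictly increasing")
        if (length(unique(d)) > 1L) return("steps must be evenly spaced")
    }
    TRUE
}

#' LandUseSeries: dominant land-use class per cell per step
#'
#' One integer class id per cell per step, drawn from the fixed 20-entry
#' vocabulary of [landUseClasses()]. Each cell carries a single dominant
#' class; fractional crop composition inside agricultural cells lives in a
#' \linkS4class{CropFractionSeries}. \code{NA} marks ocean / no-data cells.
#'
#' @slot classMap Integer array \code{[nLat, nLon, nStep]}.
#' @slot classes The class vocabulary data.frame (id, name, group).
#' @export
setClass("LandUseSeries",
    contains = "GridSeries",
    representation(classMap = "array", classes = "data.frame")
)

setValidity("LandUseSeries", function(object) {
    msg <- character()
    st <- .checkSteps(object@steps)
    if (!isTRUE(st)) msg <- c(msg, st)
    dm <- dim(object@classMap)
    if (length(dm) != 3L ||
        !all(dm == c(object@geometry@nLat, object@geometry@nLon,
                     length(object@steps))))
        msg <- c(msg, "classMap must be [nLat, nLon, nStep]")
    if (nrow(object@classes) != 20L)
        msg <- c(msg, "class vocabulary must have exactly 20 entries")
    bad <- !is.na(object@classMap) & !(object@classMap %in% object@classes$id)
    if (any(bad)) {
        i <- which(bad, arr.ind = TRUE)[1L, ]
        msg <- c(msg, sprintf(
            "class id %d outside vocabulary at cell (%d,%d) step %d",
            object@classMap[i[1L], i[2L], i[3L]], i[1L], i[2L],
            object@steps[i[3L]]))
    }
    if (length(msg)) msg else TRUE
})

#' CropFractionSeries: per-crop fraction of cell area
#'
#' Fraction of each cell occupied by each of the 17 attribution categories
#' (16 crops + pasture, [cropCategories()]), per step. Fractions are in
#' [0, 1] and sum to at most 1 per cell.
#'
#' @slot fraction Numeric array \code{[nLat, nLon, nCategory, nStep]}.
#' @slot categories The 17-entry category vocabulary.
#' @export
setClass("CropFractionSeries",
    contains = "GridSeries",
    representation(fraction = "array", categories = "character")
)

setValidity("CropFractionSeries", function(object) {
    msg <- character()
    st <- .checkSteps(object@steps)
    if (!isTRUE(st)) msg <- c(msg, st)
    if (!identical(object@categories, cropCategories()))
        msg <- c(msg, "categories must match the fixed 17-entry vocabulary")
    dm <- dim(object@fraction)
    if (length(dm) != 4L ||
        !all(dm == c(object@geometry@nLat, object@geometry@nLon,
                     length(object@categories), length(object@steps))))
        msg <- c(msg, "fraction must be [nLat, nLon, nCategory, nStep]")
    else {
        if (any(object@fraction < 0 | object@fraction > 1, na.rm = TRUE))
            msg <- c(msg, "fractions must lie in [0, 1]")
        tot <- apply(object@fraction, c(1L, 2L, 4L), sum)
        bad <- which(tot > 1 + 1e-9, arr.ind = TRUE)
        if (nrow(bad)) {
            i <- bad[1L, ]
            msg <- c(msg, sprintf(
                "crop fractions sum to %.12f > 1 at cell (%d,%d) step %d",
                tot[i[1L], i[2L], i[3L]], i[1L], i[2L], object@steps[i[3L]]))
        }
    }
    if (length(msg)) msg else TRUE
})

#' CarbonDensitySeries: aboveground carbon density
#'
#' Aboveground biomass carbon density in Mg C per km2, per cell per step.
#' The same class holds the optional soil-carbon pool used by the
#' first-order soil extension.
#'
#' @slot density Numeric array \code{[nLat, nLon, nStep]}, non-negative.
#' @slot pool Either \code{"aboveground"} or \code{"soil"}.
#' @export
setClass("CarbonDensitySeries",
    contains = "GridSeries",
    representation(density = "array", pool = "character")
)

setValidity("CarbonDensitySeries", function(object) {
    msg <- character()
    st <- .checkSteps(object@steps)
    if (!isTRUE(st)) msg <- c(msg, st)
    dm <- dim(object@density)
    if (length(dm) != 3L ||
        !all(dm == c(object@geometry@nLat, object@geometry@nLon,
                     length(object@steps))))
        msg <- c(msg, "density must be [nLat, nLon, nStep]")
    else if (any(object@density < 0, na.rm = TRUE)) {
        i <- which(object@density < 0, arr.ind = TRUE)[1L, ]
        msg <- c(msg, sprintf(
            "negative carbon density at cell (%d,%d) step %d",
            i[1L], i[2L], object@steps[i[3L]]))
    }
    if (!object@pool %in% c("aboveground", "soil"))
        msg <- c(msg, "pool must be 'aboveground' or 'soil'")
    if (length(msg)) msg else TRUE
})

#' RegionMap: cell-to-region assignment
#'
#' One region id per land cell (nominally the 26 world regions used for
#' reporting); \code{NA} marks ocean / no-data cells.
#'
#' @slot geometry The spatial frame.
#' @slot regionId Integer matrix \code{[nLat, nLon]} with values in
#'   \code{1..length(regionNames)} or NA.
#' @slot regionNames Region labels.
#' @export
setClass("RegionMap",
    representation(geometry = "GridGeometry", regionId = "matrix",
                   regionNames = "character")
)

setValidity("RegionMap", function(object) {
    msg <- character()
    if (!all(dim(object@regionId) == c(object@geometry@nLat,
                                       object@geometry@nLon)))
        msg <- c(msg, "regionId must be [nLat, nLon]")
    ids <- object@regionId[!is.na(object@regionId)]
    if (length(ids) && (any(ids < 1L) || any(ids > length(object@regionNames))))
        msg <- c(msg, "region ids must index regionNames")
    if (!length(object@regionNames))
        msg <- c(msg, "at least one region required")
    if (length(msg)) msg else TRUE
})

#' ManagementLayer: one gridded management-emission source
#'
#' Per-cell gas mass (Mg of the named gas) for one of the seven management /
#' non-CO2 LUC sources, integrated over each 5-year step interval. Values
#' are indexed by the interval's end year. Sources 5-7 are natively
#' crop-specific and carry a category dimension; a source with several gases
#' (peatland drainage: CO2, N2O, CH4) is represented as one layer per gas so
#' gas-level breakdowns stay reportable until CO2-eq conversion.
#'
#' @slot geometry,steps Frame and interval end years.
#' @slot sourceId Integer 1..7: (1) N2O land clearing, (2) peatland
#'   drainage, (3) N2O manure on cropland, (4) N2O agricultural residues,
#'   (5) N2O synthetic fertilizer, (6) waste burning, (7) CH4 wetland rice.
#' @slot gas \code{"CO2"}, \code{"N2O"} or \code{"CH4"}.
#' @slot values Numeric array \code{[nLat, nLon, nStep]} or, when
#'   \code{cropSpecific}, \code{[nLat, nLon, nCategory, nStep]}; Mg gas.
#' @slot cropSpecific TRUE for sources 5-7.
#' @slot categories The 17-entry vocabulary (crop-specific layers only).
#' @export
setClass("ManagementLayer",
    contains = "GridSeries",
    representation(sourceId = "integer", gas = "character",
                   values = "array", cropSpecific = "logical",
                   categories = "character")
)

setValidity("ManagementLayer", function(object) {
    msg <- character()
    if (!(object@sourceId %in% 1:7))
        msg <- c(msg, "sourceId must be in 1..7")
    if (!object@gas %in% c("CO2", "N2O", "CH4"))
        msg <- c(msg, "gas must be CO2, N2O or CH4")
    if (any(object@values < 0, na.rm = TRUE))
        msg <- c(msg, "management masses must be >= 0")
    dm <- dim(object@values)
    g <- object@geometry
    if (object@cropSpecific) {
        if (!(object@sourceId %in% 5:7))
            msg <- c(msg, "only sources 5-7 are crop-specific")
        if (length(dm) != 4L ||
            !all(dm == c(g@nLat, g@nLon, length(object@categories),
                         length(object@steps))))
            msg <- c(msg, "crop-specific values must be [nLat, nLon, nCategory, nStep]")
        if (!identical(object@categories, cropCategories()))
            msg <- c(msg, "categories must match the fixed vocabulary")
    } else {
        if (length(dm) != 3L ||
            !all(dm == c(g@nLat, g@nLon, length(object@steps))))
            msg <- c(msg, "values must be [nLat, nLon, nStep]")
    }
    if (length(msg)) msg else TRUE
})

#' StockChangeGrid: per-cell carbon-stock change between consecutive steps
#'
#' Stock differences \code{stock(t-1) - stock(t)} in Mg C for each
#' consecutive step pair; positive values are stock loss (the emission
#' sign convention used throughout). Indexed by the pair's end year.
#'
#' @slot deltaC Numeric array \code{[nLat, nLon, nPairs]}, Mg C.
#' @export
setClass("StockChangeGrid",
    contains = "GridSeries",
    representation(deltaC = "array")
)

setValidity("StockChangeGrid", function(object) {
    msg <- character()
    dm <- dim(object@deltaC)
    if (length(dm) != 3L ||
        !all(dm == c(object@geometry@nLat, object@geometry@nLon,
                     length(object@steps))))
        msg <- c(msg, "deltaC must be [nLat, nLon, nPairs]")
    if (any(!is.finite(object@deltaC) & !is.na(object@deltaC)))
        msg <- c(msg, "deltaC must be finite")
    if (length(msg)) msg else TRUE
})
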