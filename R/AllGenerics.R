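#' @include AllClasses.R
NULL

#' Accessors for gridded objects
#'
#' @param x A gridded object.
#' @return \code{geometry} returns the \linkS4class{GridGeometry};
#'   \code{stepYears} the integer step (or interval-end) years;
#'   \code{classMap}, \code{cropFractions}, \code{carbonDensity},
#'   \code{layerValues} and \code{deltaC} the underlying arrays;
#'   \code{regionIds} the region-id matrix and \code{regionNames} the
#'   region labels.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("geometry", function(x) standardGeneric("geometry"))
#' @rdname accessors
#' @export
setGeneric("stepYears", function(x) standardGeneric("stepYears"))
#' @rdname accessors
#' @export
setGeneric("classMap", function(x) standardGeneric("classMap"))
#' @rdname accessors
#' @export
setGeneric("cropFractions", function(x) standardGeneric("cropFractions"))
#' @rdname accessors
#' @export
setGeneric("carbonDensity", function(x) standardGeneric("carbonDensity"))
#' @rdname accessors
#' @export
setGeneric("layerValues", function(x) standardGeneric("layerValues"))
#' @rdname accessors
#' @export
setGeneric("deltaC", function(x) standardGeneric("deltaC"))
#' @rdname accessors
#' @export
setGeneric("regionIds", function(x) standardGeneric("regionIds"))
#' @rdname accessors
#' @export
setGeneric("regionNames", function(x) standardGeneric("regionNames"))

#' Write a gridded layer to a NetCDF file
#'
#' @param object A gridded series object.
#' @param path Output file path.
#' @param variable NetCDF variable name.
#' @return \code{path}, invisibly.
#' @seealso [readLayer()]
#' @export
setGeneric("writeLayer", function(object, path, variable)
    standardGeneric("writeLayer"))

#' @rdname accessors
#' @export
setMethod("geometry", "GridSeries", function(x) x@geometry)
#' @rdname accessors
#' @export
setMethod("geometry", "RegionMap", function(x) x@geometry)
#' @rdname accessors
#' @export
setMethod("stepYears", "GridSeries", function(x) x@steps)
#' @rdname accessors
#' @export
setMethod("classMap", "LandUseSeries", function(x) x@classMap)
#' @rdname accessors
#' @export
setMethod("cropFractions", "CropFractionSeries", function(x) x@fraction)
#' @rdname accessors
#' @export
setMethod("carbonDensity", "CarbonDensitySeries", function(x) x@density)
#' @rdname accessors
#' @export
setMethod("layerValues", "ManagementLayer", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("deltaC", "StockChangeGrid", function(x) x@deltaC)
#' @rdname accessors
#' @export
setMethod("regionIds", "RegionMap", function(x) x@regionId)
#' @rdname accessors
#' @export
setMethod("regionNames", "RegionMap", function(x) x@regionNames)

setMethod("show", "GridGeometry", function(object) {
    cat(sprintf(
        "GridGeometry: %d x %d cells at %.6g deg, lat %.3f..%.3f, R = %.4f km\n",
        object@nLat, object@nLon, object@resolution,
        max(object@latCenters), min(object@latCenters), object@earthRadius))
})

setMethod("show", "LandUseSeries", function(object) {
    cat(sprintf("LandUseSeries: %d x %d cells, %d steps (%d..%d), %d classes\n",
        object@geometry@nLat, object@geometry@nLon, length(object@steps),
        min(object@steps), max(object@steps), nrow(object@classes)))
})

setMethod("show", "CropFractionSeries", function(object) {
    cat(sprintf("CropFractionSeries: %d x %d cells, %d categories, %d steps (%d..%d)\n",
        object@geometry@nLat, object@geometry@nLon,
        length(object@categories), length(object@steps),
        min(object@steps), max(object@steps)))
})

setMethod("show", "CarbonDensitySeries", function(object) {
    cat(sprintf("CarbonDensitySeries (%s): %d x %d cells, %d steps, range %.4g..%.4g Mg C/km2\n",
        object@pool, object@geometry@nLat, object@geometry@nLon,
        length(object@steps), min(object@density, na.rm = TRUE),
        max(object@density, na.rm = TRUE)))
})

setMethod("show", "RegionMap", function(object) {
    cat(sprintf("RegionMap: %d x %d cells, %d regions\n",
        object@geometry@nLat, object@geometry@nLon,
        length(object@regionNames)))
})

setMethod("show", "ManagementLayer", function(object) {
    cat(sprintf("ManagementLayer source %d (%s, %s): %d x %d cells, %d intervals, total %.4g Mg\n",
        object@sourceId, .managementSourceName(object@sourceId), object@gas,
        object@geometry@nLat, object@geometry@nLon, length(object@steps),
        sum(object@values, na.rm = TRUE)))
})

setMethod("show", "StockChangeGrid", function(object) {
    cat(sprintf("StockChangeGrid: %d x %d cells, %d step pairs, net change %.4g Mg C\n",
        object@geometry@nLat, object@geometry@nLon, length(object@steps),
        sum(object@deltaC, na.rm = TRUE)))
})
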