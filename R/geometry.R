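#' Construct a grid geometry
#'
#' Defines the regular lat/lon raster all layers share: cell-center
#' registration, latitude rows ordered north to south, 0-based internal cell
#' identity \code{(row, col)} exposed 1-based in R. Per-cell areas use the
#' spherical-band formula
#' \deqn{A = R^2 \, \Delta\lambda \, (\sin\varphi_{top} - \sin\varphi_{bottom})}
#' with the authalic Earth radius, so a full global grid sums to
#' \eqn{4\pi R^2} up to numerical rounding. At 5 arc-min resolution an
#' equatorial cell covers about 85 km2.
#'
#' By default the grid is centered on the equator and prime meridian; pass
#' \code{latTop}/\code{lonLeft} (the northern and western outer edges) to
#' place it elsewhere. \code{globalGrid()} builds the full-sphere grid at a
#' given resolution.
#'
#' @param nLat,nLon Number of rows and columns.
#' @param resolution Cell size in degrees; the nominal grid is 5 arc-min
#'   (1/12 degree), the default.
#' @param latTop Latitude of the northern edge of the first row (degrees);
#'   default centers the grid on the equator.
#' @param lonLeft Longitude of the western edge of the first column;
#'   default centers on the prime meridian.
#' @param earthRadius Radius in km; default authalic 6371.0072.
#' @return A \linkS4class{GridGeometry}.
#' @examples
#' g <- gridGeometry(12, 12)           # toy world near the equator
#' cellAreas(g)[6, 1]                   # ~85.5 km2
#' sum(cellAreas(globalGrid(2)))        # ~4 pi R^2
#' @export
gridGeometry <- function(nLat, nLon, resolution = 1 / 12,
                         latTop = nLat * resolution / 2,
                         lonLeft = -nLon * resolution / 2,
                         earthRadius = 6371.0072) {
    if (resolution <= 0) stop("resolution must be > 0")
    nLat <- as.integer(nLat); nLon <- as.integer(nLon)
    if (latTop > 90 + 1e-9 || latTop - nLat * resolution < -90 - 1e-9)
        stop("grid extends beyond the poles")
    latCenters <- latTop - (seq_len(nLat) - 0.5) * resolution
    lonCenters <- lonLeft + (seq_len(nLon) - 0.5) * resolution
    phiTop <- (latTop - (seq_len(nLat) - 1L) * resolution) * pi / 180
    phiBot <- (latTop - seq_len(nLat) * resolution) * pi / 180
    dLambda <- resolution * pi / 180
    areaRow <- earthRadius^2 * dLambda * (sin(phiTop) - sin(phiBot))
    new("GridGeometry",
        nLat = nLat, nLon = nLon, resolution = resolution,
        latCenters = latCenters, lonCenters = lonCenters,
        cellAreaRow = areaRow, earthRadius = earthRadius)
}

#' @rdname gridGeometry
#' @export
globalGrid <- function(resolution = 1 / 12, earthRadius = 6371.0072) {
    gridGeometry(round(180 / resolution), round(360 / resolution),
                 resolution, latTop = 90, lonLeft = -180,
                 earthRadius = earthRadius)
}

#' Per-cell areas of a grid
#'
#' @param geometry A \linkS4class{GridGeometry}.
#' @return Numeric matrix \code{[nLat, nLon]} of areas in km2; constant
#'   along each latitude row.
#' @seealso [gridGeometry()] for the area formula.
#' @export
cellAreas <- function(geometry) {
    stopifnot(is(geometry, "GridGeometry"))
    validObject(geometry)
    matrix(geometry@cellAreaRow, nrow = geometry@nLat, ncol = geometry@nLon)
}

## shared-frame check used by every cross-layer operation
.sameFrame <- function(a, b) {
    isTRUE(all.equal(a@latCenters, b@latCenters)) &&
        isTRUE(all.equal(a@lonCenters, b@lonCenters)) &&
        isTRUE(all.equal(a@earthRadius, b@earthRadius))
}

.assertFrame <- function(a, b, what = "layers") {
    if (!.sameFrame(a, b))
        stop(what, " are not on the same spatial frame", call. = FALSE)
    invisible(TRUE)
}
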