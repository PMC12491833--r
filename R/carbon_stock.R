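#' Per-cell carbon stock from density
#'
#' Multiplies aboveground (or soil) carbon density (Mg C/km2) by the cell
#' area (km2), elementwise per step, giving the per-cell stock in Mg C.
#'
#' @param density A \linkS4class{CarbonDensitySeries}.
#' @param geometry The shared \linkS4class{GridGeometry}; defaults to the
#'   frame of \code{density} and must match it when supplied.
#' @return Numeric array \code{[nLat, nLon, nStep]} of Mg C, with the step
#'   years as \code{dimnames} on the third dimension.
#' @examples
#' g <- gridGeometry(2, 2, resolution = 1)
#' d <- new("CarbonDensitySeries", geometry = g, steps = c(2000L, 2005L),
#'          density = array(10000, c(2, 2, 2)), pool = "aboveground")
#' carbonStock(d)[1, 1, 1] / cellAreas(g)[1, 1]   # recovers 10000
#' @export
carbonStock <- function(density, geometry = NULL) {
    stopifnot(is(density, "CarbonDensitySeries"))
    validObject(density)
    if (is.null(geometry)) geometry <- density@geometry
    .assertFrame(density@geometry, geometry, "density and geometry")
    a <- cellAreas(geometry)
    stock <- density@density * as.vector(a)   # area recycles over steps
    dimnames(stock) <- list(NULL, NULL, density@steps)
    stock
}

#' Carbon-stock change between consecutive steps
#'
#' For each consecutive step pair, \eqn{\Delta C(t) = stock(t-1) - stock(t)}
#' per cell, so positive values are stock LOSS and map to positive CO2
#' emissions. The result is indexed by the pair's end year.
#'
#' @param stock Array \code{[nLat, nLon, nStep]} from [carbonStock()], with
#'   step years in \code{dimnames[[3]]}, or a
#'   \linkS4class{CarbonDensitySeries} (converted internally).
#' @param geometry The frame (required when \code{stock} is a bare array
#'   without one attached).
#' @return A \linkS4class{StockChangeGrid}.
#' @export
stockChange <- function(stock, geometry = NULL) {
    if (is(stock, "CarbonDensitySeries")) {
        geometry <- stock@geometry
        steps <- stock@steps
        stock <- carbonStock(stock)
    } else {
        steps <- as.integer(dimnames(stock)[[3L]])
        if (is.null(geometry))
            stop("geometry required when stock is a bare array")
    }
    n <- dim(stock)[3L]
    if (n < 2L) stop("at least two steps required to difference stocks")
    dc <- stock[, , -n, drop = FALSE] - stock[, , -1L, drop = FALSE]
    dimnames(dc) <- NULL
    new("StockChangeGrid", geometry = geometry, steps = steps[-1L],
        deltaC = dc)
}

#' Convert carbon mass to CO2 mass
#'
#' Stoichiometric conversion by the 44/12 molar-mass ratio; sign-preserving
#' and linear, so it can be applied before or after any summation.
#'
#' @param massC Carbon mass (Mg C), any numeric shape.
#' @param constants A [lucConstants()] object.
#' @return CO2 mass (Mg), same shape.
#' @examples
#' cToCO2(12)   # 44
#' @export
cToCO2 <- function(massC, constants = lucConstants()) {
    massC * constants$co2PerC
}
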