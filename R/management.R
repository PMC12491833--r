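#' Convert a management layer to CO2-equivalents
#'
#' Multiplies the layer's gas mass by the configured global-warming
#' potential: CO2 passes through with factor 1, CH4 and N2O use the factors
#' in \code{constants$gwp}. Linear, so layers may be converted before or
#' after summation.
#'
#' @param layer A \linkS4class{ManagementLayer}.
#' @param constants [lucConstants()].
#' @return Numeric array of Mg CO2-eq with the same shape as
#'   \code{layerValues(layer)}.
#' @export
toCO2eq <- function(layer, constants = lucConstants()) {
    stopifnot(is(layer, "ManagementLayer"))
    if (!layer@gas %in% names(constants$gwp))
        stop("no GWP factor configured for gas ", layer@gas)
    layer@values * constants$gwp[[layer@gas]]
}

#' Split a bulk emission grid across crops by residue shares
#'
#' Attributes the agricultural-residue source (source 4) to crops in
#' proportion to their aboveground residue mass per cell: crop share =
#' residue_crop / sum(residues). Where the bulk grid is positive but all
#' residue shares are zero, the configured fallback applies: split
#' proportional to non-pasture crop fractions (default, preserves mass), or
#' error.
#'
#' @param bulk Numeric array \code{[nLat, nLon, nStep]} of CO2-eq (or any
#'   mass) to split.
#' @param residues Numeric array \code{[nLat, nLon, nCategory, nStep]} of
#'   residue mass or relative shares (>= 0).
#' @param fractions \linkS4class{CropFractionSeries} used by the fallback;
#'   its last \code{dim(bulk)[3]} steps are aligned with \code{bulk}.
#' @param fallback \code{"fractions"} (default) or \code{"error"}.
#' @return Numeric array \code{[nLat, nLon, nCategory, nStep]}; sums over
#'   crops reproduce \code{bulk} exactly wherever \code{bulk > 0}.
#' @export
splitByResidue <- function(bulk, residues, fractions = NULL,
                           fallback = c("fractions", "error")) {
    fallback <- match.arg(fallback)
    if (any(residues < 0, na.rm = TRUE)) stop("residue shares must be >= 0")
    dm <- dim(residues)
    if (!all(dim(bulk) == dm[-3L]))
        stop("bulk and residues are on different frames")
    nCat <- dm[3L]
    totals <- apply(residues, c(1L, 2L, 4L), sum)
    needFallback <- bulk > 0 & totals <= 0
    ## work with crop as the trailing dimension so (cell, step) linear
    ## indices line up with the 3-d bulk/totals arrays
    res3 <- aperm(residues, c(1L, 2L, 4L, 3L))
    if (any(needFallback, na.rm = TRUE)) {
        if (fallback == "error")
            stop("positive residue-source emissions where residue shares are all zero")
        if (is.null(fractions))
            stop("fractions required for the residue fallback")
        fr <- fractions@fraction
        fr <- fr[, , , dim(fr)[4L] - dm[4L] + seq_len(dm[4L]), drop = FALSE]
        fr[, , match("pasture", fractions@categories), ] <- 0
        fr3 <- aperm(fr, c(1L, 2L, 4L, 3L))
        nCell <- prod(dm[-3L])
        fbIdx <- which(needFallback)
        for (c in seq_len(nCat))
            res3[fbIdx + (c - 1L) * nCell] <- fr3[fbIdx + (c - 1L) * nCell]
        totals <- apply(res3, 1:3, sum)
        if (any(bulk > 0 & totals <= 0, na.rm = TRUE))
            stop("residue fallback failed: no crop present under positive emissions")
    }
    safeTot <- ifelse(totals > 0, totals, 1)
    out3 <- array(0, dim(res3))
    for (c in seq_len(nCat))
        out3[, , , c] <- bulk * res3[, , , c] / safeTot
    aperm(out3, c(1L, 2L, 4L, 3L))
}

#' Route the seven management sources to their attribution rules
#'
#' Converts every supplied \linkS4class{ManagementLayer} to CO2-eq, then:
#' sources 1-3 (land-clearing N2O, peatland drainage, manure) are merged
#' into the land-use-change attribution pool, keeping per-source identity;
#' source 4 (residue N2O) is split across crops by residue shares; sources
#' 5-7 pass through with their native crop dimension. Missing sources are
#' treated as zero. Routing conserves CO2-eq mass exactly.
#'
#' @param layers List of \linkS4class{ManagementLayer} objects (several
#'   layers may share a source id when a source has several gases).
#' @param fractions \linkS4class{CropFractionSeries} (residue fallback).
#' @param residues Residue-share array \code{[nLat, nLon, nCategory,
#'   nPairs]}; required when a source-4 layer is present.
#' @param constants [lucConstants()].
#' @return List with \code{lucPool} (named list of \code{[nLat, nLon,
#'   nPairs]} CO2-eq arrays for the luc-linked sources present),
#'   \code{cropResolved} (named list of \code{[nLat, nLon, nCategory,
#'   nPairs]} arrays), \code{steps} (interval end years) and
#'   \code{totalCO2eq} (grand total for conservation checks).
#' @export
routeSources <- function(layers, fractions, residues = NULL,
                         constants = lucConstants()) {
    if (length(layers) == 0L)
        return(list(lucPool = list(), cropResolved = list(), steps = integer(),
                    totalCO2eq = 0))
    g <- layers[[1L]]@geometry
    steps <- layers[[1L]]@steps
    for (l in layers) {
        stopifnot(is(l, "ManagementLayer"))
        validObject(l)
        .assertFrame(l@geometry, g, "management layers")
        if (!identical(l@steps, steps))
            stop("management layers disagree on step intervals")
    }
    nPair <- length(steps)
    cats <- cropCategories()
    riceIdx <- match("rice", cats)
    lucPool <- list()
    cropResolved <- list()
    total <- 0
    for (l in layers) {
        eq <- toCO2eq(l, constants)
        total <- total + sum(eq, na.rm = TRUE)
        nm <- .managementSourceName(l@sourceId)
        if (l@sourceId %in% 1:3) {
            if (l@cropSpecific) stop("sources 1-3 must not be crop-specific")
            lucPool[[nm]] <- if (is.null(lucPool[[nm]])) eq else lucPool[[nm]] + eq
        } else if (l@sourceId == 4L) {
            if (is.null(residues))
                stop("residue shares required to route source 4")
            sp <- splitByResidue(eq, residues, fractions)
            cropResolved[[nm]] <- if (is.null(cropResolved[[nm]])) sp
                                  else cropResolved[[nm]] + sp
        } else {
            if (!l@cropSpecific)
                stop("sources 5-7 must carry a crop dimension")
            if (l@sourceId == 7L) {
                offRice <- eq[, , -riceIdx, , drop = FALSE]
                if (any(offRice > 0, na.rm = TRUE))
                    stop("wetland-rice CH4 (source 7) must be zero outside the rice category")
            }
            cropResolved[[nm]] <- if (is.null(cropResolved[[nm]])) eq
                                  else cropResolved[[nm]] + eq
        }
    }
    list(lucPool = lucPool, cropResolved = cropResolved, steps = steps,
         totalCO2eq = total)
}
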