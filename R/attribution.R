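#' Attribution weights from crop-fraction change
#'
#' The central allocation rule: land-use-change emissions in a cell are
#' attributed to categories proportional to the INCREASE in their area
#' fraction over the step, \eqn{w_i \propto \max(f_i(t) - f_i(t-1), 0)},
#' normalized to sum to 1. When no category increased, the fallback
#' attributes proportional to the current fractions (the crops actually
#' present); when those are all zero too, the weights are all zero and the
#' attribute \code{"unallocated"} is set, so callers can book the mass to
#' the unallocated pseudo-category rather than drop it.
#'
#' @param fractionPrev,fractionNow Numeric vectors on the 17-category
#'   vocabulary (previous and current step fractions for one cell).
#' @return Numeric weights of the same length, summing to 1 (or all zero
#'   with \code{attr(w, "unallocated") = TRUE} in the degenerate case).
#' @examples
#' w <- attributionWeights(c(0.1, 0.2, 0), c(0.3, 0.3, 0))
#' w   # 1, 0, 0: only the first category expanded
#' @export
attributionWeights <- function(fractionPrev, fractionNow) {
    stopifnot(length(fractionPrev) == length(fractionNow))
    inc <- pmax(fractionNow - fractionPrev, 0)
    s <- sum(inc)
    if (s > 0) return(inc / s)
    s2 <- sum(fractionNow)
    if (s2 > 0) return(fractionNow / s2)
    w <- rep(0, length(fractionNow))
    attr(w, "unallocated") <- TRUE
    w
}

#' Allocate one cell's emissions across categories
#'
#' Multiplies a positive CO2-eq mass by a weight vector summing to 1; the
#' outputs sum to the input exactly. Only attributable emission events
#' (categories 2 and 5 with positive CO2) may be allocated.
#'
#' @param co2eq Scalar t CO2-eq, must be >= 0.
#' @param weights Weights from [attributionWeights()].
#' @return Per-category t CO2-eq.
#' @export
attributeCell <- function(co2eq, weights) {
    if (co2eq < 0)
        stop("sequestration never enters the attribution step")
    co2eq * weights
}

## Weight array W[nLat, nLon, nCat, nPair] plus unallocated indicator
## U[nLat, nLon, nPair]; vectorized twin of attributionWeights().
.weightArray <- function(fractions) {
    fr <- fractions@fraction
    dm <- dim(fr)
    nPair <- dm[4L] - 1L
    if (nPair < 1L) stop("at least two fraction steps required")
    inc <- pmax(fr[, , , -1L, drop = FALSE] - fr[, , , -dm[4L], drop = FALSE], 0)
    now <- fr[, , , -1L, drop = FALSE]
    sInc <- apply(inc, c(1L, 2L, 4L), sum)
    sNow <- apply(now, c(1L, 2L, 4L), sum)
    useInc <- sInc > 0
    useNow <- !useInc & sNow > 0
    U <- !useInc & !useNow
    denom <- ifelse(useInc, sInc, ifelse(useNow, sNow, 1))
    W <- array(0, c(dm[1:3], nPair))
    for (c in seq_len(dm[3L]))
        W[, , c, ] <- ifelse(useInc, inc[, , c, ], ifelse(useNow, now[, , c, ], 0)) / denom
    list(W = W, U = U)
}

#' Per-crop area tables from the fraction stack
#'
#' \code{cropAreaTable()} aggregates crop areas (fraction x cell area, in
#' ha) to (region, category, step); \code{basis} selects the area of the
#' interval's end step, its start step, or the total-footprint basis
#' "prior area plus newly established area"
#' (\code{start} + positive increment). \code{convertedAreaTable()}
#' attributes the area of natural-vegetation-to-agriculture conversion
#' events to categories with the same increase-proportional weights used
#' for emissions, giving the newly-converted-area denominator of the
#' marginal footprint.
#'
#' @param fractions \linkS4class{CropFractionSeries}.
#' @param regions \linkS4class{RegionMap}.
#' @param basis \code{"end"}, \code{"start"} or \code{"prior_plus_new"}.
#' @return Data.frame (region, crop, step_start, step_end, area_ha).
#' @export
cropAreaTable <- function(fractions, regions,
                          basis = c("end", "start", "prior_plus_new")) {
    basis <- match.arg(basis)
    .assertFrame(fractions@geometry, regions@geometry, "fractions and regions")
    fr <- fractions@fraction
    dm <- dim(fr)
    steps <- fractions@steps
    nPair <- dm[4L] - 1L
    a <- cellAreas(fractions@geometry) * 100
    frUse <- switch(basis,
        end = fr[, , , -1L, drop = FALSE],
        start = fr[, , , -dm[4L], drop = FALSE],
        prior_plus_new = fr[, , , -dm[4L], drop = FALSE] +
            pmax(fr[, , , -1L, drop = FALSE] - fr[, , , -dm[4L], drop = FALSE], 0))
    rid <- as.vector(regions@regionId)
    keep <- !is.na(rid)
    out <- vector("list", nPair * dm[3L])
    i <- 1L
    for (k in seq_len(nPair)) {
        for (c in seq_len(dm[3L])) {
            v <- as.vector(frUse[, , c, k]) * as.vector(a)
            s <- rowsum(v[keep], rid[keep])
            out[[i]] <- data.frame(
                region = regions@regionNames[as.integer(rownames(s))],
                crop = fractions@categories[c],
                step_start = steps[k], step_end = steps[k + 1L],
                area_ha = s[, 1L])
            i <- i + 1L
        }
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}

#' @rdname cropAreaTable
#' @param events Classified event table ([classifyTransitions()]).
#' @export
convertedAreaTable <- function(events, fractions, regions) {
    ev <- events[!is.na(events$category) & events$category == 2L, , drop = FALSE]
    wa <- .weightArray(fractions)
    steps <- fractions@steps
    cats <- fractions@categories
    rows <- list()
    for (i in seq_len(nrow(ev))) {
        k <- match(ev$step_end[i], steps) - 1L
        w <- wa$W[ev$row[i], ev$col[i], , k]
        unalloc <- wa$U[ev$row[i], ev$col[i], k]
        rid <- regions@regionId[ev$row[i], ev$col[i]]
        if (is.na(rid)) stop("converted cell without region id")
        if (unalloc) {
            rows[[length(rows) + 1L]] <- data.frame(
                region = regions@regionNames[rid], crop = "unallocated",
                step_start = ev$step_start[i], step_end = ev$step_end[i],
                area_ha = ev$area_ha[i])
        } else {
            nz <- which(w > 0)
            rows[[length(rows) + 1L]] <- data.frame(
                region = regions@regionNames[rid], crop = cats[nz],
                step_start = ev$step_start[i], step_end = ev$step_end[i],
                area_ha = ev$area_ha[i] * w[nz])
        }
    }
    if (!length(rows))
        return(data.frame(region = character(), crop = character(),
                          step_start = integer(), step_end = integer(),
                          area_ha = numeric()))
    res <- do.call(rbind, rows)
    res <- stats::aggregate(area_ha ~ region + crop + step_start + step_end,
                            data = res, FUN = sum)
    res[order(res$step_end, res$region, res$crop), , drop = FALSE]
}

#' Assemble the region x crop x step x source emission ledger
#'
#' The pipeline's central accounting step. Attributable biomass emission
#' events (categories 2 and 5 with positive CO2) and the luc-linked
#' management pool (sources 1-3) are allocated to categories per cell with
#' the increase-proportional weights; residue-split and natively
#' crop-specific sources are summed into their categories directly; all
#' contributions are then aggregated to the reporting regions.
#' Sequestration events never enter. Mass is conserved exactly: the ledger
#' total equals attributable biomass CO2 plus routed management CO2-eq (the
#' check is run on every call and stored in \code{attr(, "conservation")}).
#'
#' @param events Event table with carbon attached ([attachCarbon()]).
#' @param routed Output of [routeSources()] (may be the empty routing).
#' @param fractions \linkS4class{CropFractionSeries}.
#' @param regions \linkS4class{RegionMap}.
#' @param constants [lucConstants()].
#' @return Data.frame (region, crop, step_start, step_end, source,
#'   co2eq_t) with only positive entries; attributes \code{"conservation"}
#'   (input total, ledger total, relative error) and \code{"gwpHorizon"}.
#' @export
buildLedger <- function(events, routed, fractions, regions,
                        constants = lucConstants()) {
    .assertFrame(fractions@geometry, regions@geometry, "fractions and regions")
    g <- fractions@geometry
    steps <- fractions@steps
    nPair <- length(steps) - 1L
    cats <- fractions@categories
    nCat <- length(cats)
    wa <- .weightArray(fractions)
    rid <- as.vector(regions@regionId)
    keep <- which(!is.na(rid))
    ridK <- rid[keep]
    nRegion <- length(regions@regionNames)

    ## per-source cell grids of attributable pool mass [nLat, nLon, nPair]
    pools <- list()
    ev <- events[!is.na(events$attributable) & events$attributable &
                     events$co2_t > 0, , drop = FALSE]
    if (nrow(ev)) {
        if (anyNA(regions@regionId[cbind(ev$row, ev$col)]))
            stop("emission event in a cell without region id")
        for (srcCat in c(2L, 5L)) {
            sub <- ev[ev$category == srcCat, , drop = FALSE]
            if (!nrow(sub)) next
            arr <- array(0, c(g@nLat, g@nLon, nPair))
            k <- match(sub$step_end, steps) - 1L
            arr[cbind(sub$row, sub$col, k)] <-
                arr[cbind(sub$row, sub$col, k)] + sub$co2_t
            nm <- if (srcCat == 2L) "luc_natural_to_agriculture"
                  else "luc_agricultural_transitions"
            pools[[nm]] <- arr
        }
    }
    for (nm in names(routed$lucPool)) {
        arr <- routed$lucPool[[nm]]
        if (length(routed$steps) != nPair ||
            !identical(as.integer(routed$steps), steps[-1L]))
            stop("management intervals do not match the fraction steps")
        pools[[nm]] <- if (is.null(pools[[nm]])) arr else pools[[nm]] + arr
    }

    acc <- list()
    addRows <- function(regionIdx, crop, k, source, mass) {
        pos <- mass > 0
        if (!any(pos)) return(invisible())
        acc[[length(acc) + 1L]] <<- data.frame(
            region = regions@regionNames[regionIdx[pos]], crop = crop,
            step_start = steps[k], step_end = steps[k + 1L],
            source = source, co2eq_t = mass[pos])
    }
    ## attribute pooled sources with the weight array
    for (nm in names(pools)) {
        arr <- pools[[nm]]
        for (k in seq_len(nPair)) {
            slab <- arr[, , k]
            if (!any(slab > 0)) next
            v <- as.vector(slab)[keep]
            for (c in seq_len(nCat)) {
                w <- as.vector(wa$W[, , c, k])[keep]
                s <- rowsum(v * w, ridK)
                addRows(as.integer(rownames(s)), cats[c], k, nm, s[, 1L])
            }
            u <- as.vector(wa$U[, , k])[keep]
            if (any(u & v > 0)) {
                s <- rowsum(v * u, ridK)
                addRows(as.integer(rownames(s)), "unallocated", k, nm, s[, 1L])
            }
        }
    }
    ## crop-resolved sources aggregate directly
    for (nm in names(routed$cropResolved)) {
        arr <- routed$cropResolved[[nm]]
        for (k in seq_len(nPair)) {
            for (c in seq_len(nCat)) {
                v <- as.vector(arr[, , c, k])[keep]
                if (!any(v > 0)) next
                s <- rowsum(v, ridK)
                addRows(as.integer(rownames(s)), cats[c], k, nm, s[, 1L])
            }
        }
    }
    ledger <- if (length(acc)) do.call(rbind, acc) else
        data.frame(region = character(), crop = character(),
                   step_start = integer(), step_end = integer(),
                   source = character(), co2eq_t = numeric())
    if (nrow(ledger)) {
        ledger <- stats::aggregate(co2eq_t ~ region + crop + step_start +
                                       step_end + source, data = ledger,
                                   FUN = sum)
        ledger <- ledger[order(ledger$step_end, ledger$region, ledger$source,
                               ledger$crop), , drop = FALSE]
        rownames(ledger) <- NULL
    }

    inputTotal <- sum(ev$co2_t) + routed$totalCO2eq
    ledgerTotal <- sum(ledger$co2eq_t)
    relErr <- if (inputTotal > 0) abs(ledgerTotal - inputTotal) / inputTotal
              else abs(ledgerTotal)
    if (relErr > 1e-9)
        stop(sprintf(
            "attribution lost mass: ledger %.6g vs inputs %.6g (rel err %.3g)",
            ledgerTotal, inputTotal, relErr))
    attr(ledger, "conservation") <- list(input = inputTotal,
                                         ledger = ledgerTotal,
                                         rel_err = relErr)
    attr(ledger, "gwpHorizon") <- constants$gwpHorizon
    ledger
}
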