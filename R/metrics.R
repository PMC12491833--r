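#' Centered moving average with truncated edges
#'
#' Smooths an annual series with a centered window (default 5 years); at
#' the series edges the window truncates to the available years. Constant
#' series are unchanged.
#'
#' @param x Numeric series (chronological order).
#' @param window Odd window length >= 1, in years.
#' @return Smoothed series, same length.
#' @examples
#' movingAverage(1:10)[5]   # 5: interior mean of 3..7
#' @export
movingAverage <- function(x, window = 5L) {
    if (!length(x)) stop("empty series")
    if (window < 1L || window %% 2L == 0L)
        stop("window must be odd and >= 1")
    h <- (window - 1L) %/% 2L
    n <- length(x)
    vapply(seq_len(n), function(i) {
        mean(x[max(1L, i - h):min(n, i + h)])
    }, numeric(1))
}

#' Weighted average over defined values
#'
#' \eqn{\sum w v / \sum w} over the entries where the value is defined;
#' missing values are excluded and the weights renormalized. With
#' production weights applied to emission intensities, the weighted mean
#' equals total emissions over total production — the consistency property
#' that motivates the default weight choices in [computeMetrics()].
#'
#' @param values Numeric, may contain NA.
#' @param weights Non-negative, not all zero over defined values.
#' @return Scalar, or NA when every value is missing.
#' @export
weightedAverage <- function(values, weights) {
    if (any(weights < 0, na.rm = TRUE)) stop("weights must be >= 0")
    ok <- !is.na(values) & !is.na(weights)
    if (!any(ok)) return(NA_real_)
    if (sum(weights[ok]) == 0) return(NA_real_)
    sum(values[ok] * weights[ok]) / sum(weights[ok])
}

## safe ratio: missing (NA) where the denominator is 0, never Inf
.ratio <- function(num, den) {
    ifelse(is.na(den) | den <= 0, NA_real_, num / den)
}

#' Marginal emissions footprint (t CO2/ha)
#'
#' Natural-vegetation-to-agriculture emissions divided by the newly
#' converted area, per (region, crop, step): the emissions cost of
#' expansion. Missing (not zero, not infinite) where nothing was converted.
#'
#' @param ledger An emission ledger ([buildLedger()]).
#' @param convertedArea Converted-area table ([convertedAreaTable()]).
#' @return Data.frame (region, crop, step_start, step_end,
#'   marginal_footprint).
#' @export
marginalFootprint <- function(ledger, convertedArea) {
    if (any(convertedArea$area_ha < 0)) stop("negative converted area")
    em <- ledger[ledger$source == "luc_natural_to_agriculture", ,
                 drop = FALSE]
    em <- .sumBy(em, "co2eq_t")
    out <- merge(convertedArea, em, all = TRUE)
    out$co2eq_t[is.na(out$co2eq_t)] <- 0
    out$marginal_footprint <- .ratio(out$co2eq_t, out$area_ha)
    out[c("region", "crop", "step_start", "step_end", "marginal_footprint")]
}

#' Total emissions footprint (t CO2-eq/ha)
#'
#' All land-use emissions (land-use change plus agricultural management)
#' divided by the total crop area — by default the prior step's area plus
#' newly established area. Missing where the crop has no area.
#'
#' @param ledger Emission ledger (all sources).
#' @param totalArea Area table ([cropAreaTable()], basis
#'   \code{"prior_plus_new"} for the headline definition or
#'   \code{"harvested"}-like external tables for the decomposition).
#' @return Data.frame (region, crop, step_start, step_end,
#'   total_footprint).
#' @export
totalFootprint <- function(ledger, totalArea) {
    if (any(totalArea$area_ha < 0)) stop("negative area")
    em <- .sumBy(ledger, "co2eq_t")
    out <- merge(totalArea, em, all = TRUE)
    out$co2eq_t[is.na(out$co2eq_t)] <- 0
    out$total_footprint <- .ratio(out$co2eq_t, out$area_ha)
    out[c("region", "crop", "step_start", "step_end", "total_footprint")]
}

#' Emission intensity (t CO2-eq/ton)
#'
#' Total land-use emissions divided by total primary production over each
#' step interval; production is the 5-year moving-averaged annual series
#' summed over the interval's years. Missing where production is zero (a
#' positive-emission / zero-production combination is additionally
#' reported in \code{attr(, "anomalies")}).
#'
#' @param ledger Emission ledger.
#' @param production Production table with annual rows; smoothed
#'   internally via [movingAverage()] unless \code{smooth = FALSE}.
#' @param window Moving-average window (years).
#' @param smooth Apply the moving average.
#' @return Data.frame (region, crop, step_start, step_end, intensity,
#'   production_t).
#' @export
emissionIntensity <- function(ledger, production, window = 5L,
                              smooth = TRUE) {
    if (any(production$production_t < 0)) stop("negative production")
    prod <- .intervalProduction(production, ledger, window, smooth)
    em <- .sumBy(ledger, "co2eq_t")
    out <- merge(prod, em, all = TRUE)
    out$co2eq_t[is.na(out$co2eq_t)] <- 0
    out$production_t[is.na(out$production_t)] <- 0
    out$intensity <- .ratio(out$co2eq_t, out$production_t)
    anom <- out[out$co2eq_t > 0 & out$production_t <= 0, , drop = FALSE]
    res <- out[c("region", "crop", "step_start", "step_end", "intensity",
                 "production_t")]
    attr(res, "anomalies") <- anom
    res
}

#' Land requirement (ha/ton): the inverse of yield
#'
#' Harvested area summed per (region, crop, interval) divided by the
#' matching production sum. Missing where production is zero.
#'
#' @param production Production table with \code{harvested_area_ha}.
#' @param ledger Ledger whose step intervals define the aggregation.
#' @param window,smooth Moving-average settings applied to both production
#'   and harvested area.
#' @return Data.frame (region, crop, step_start, step_end,
#'   land_requirement, harvested_area_ha).
#' @export
landRequirement <- function(production, ledger, window = 5L, smooth = TRUE) {
    if (any(production$production_t < 0)) stop("negative production")
    if (any(production$harvested_area_ha < 0)) stop("negative harvested area")
    prod <- .intervalProduction(production, ledger, window, smooth)
    prod$land_requirement <- .ratio(prod$harvested_area_ha,
                                    prod$production_t)
    prod[c("region", "crop", "step_start", "step_end", "land_requirement",
           "harvested_area_ha")]
}

## interval (region, crop, step-pair) sums of the annual production table
.intervalProduction <- function(production, ledger, window, smooth) {
    pairs <- unique(ledger[c("step_start", "step_end")])
    if (!nrow(pairs))
        stop("ledger defines no step intervals")
    keys <- unique(production[c("region", "crop")])
    rows <- list()
    for (i in seq_len(nrow(keys))) {
        sub <- production[production$region == keys$region[i] &
                              production$crop == keys$crop[i], ,
                          drop = FALSE]
        sub <- sub[order(sub$year), , drop = FALSE]
        p <- sub$production_t
        h <- sub$harvested_area_ha
        if (smooth) {
            p <- movingAverage(p, window)
            h <- movingAverage(h, window)
        }
        for (j in seq_len(nrow(pairs))) {
            yrs <- sub$year > pairs$step_start[j] &
                sub$year <= pairs$step_end[j]
            rows[[length(rows) + 1L]] <- data.frame(
                region = keys$region[i], crop = keys$crop[i],
                step_start = pairs$step_start[j],
                step_end = pairs$step_end[j],
                production_t = sum(p[yrs]),
                harvested_area_ha = sum(h[yrs]))
        }
    }
    do.call(rbind, rows)
}

.sumBy <- function(df, value) {
    if (!nrow(df)) {
        out <- data.frame(region = character(), crop = character(),
                          step_start = integer(), step_end = integer(),
                          value = numeric())
        names(out)[5L] <- value
        return(out)
    }
    f <- stats::as.formula(paste(value,
                                 "~ region + crop + step_start + step_end"))
    stats::aggregate(f, data = df, FUN = sum)
}

#' Classify a crop-region pairing into the three clusters
#'
#' Bands on the total footprint and land requirement define three
#' archetypes: (i) high footprint with efficient land use (footprint at or
#' above the high band, land requirement at or below the low band),
#' (ii) low footprint with inefficient land use (the mirror case), and
#' (iii) moderate footprint and moderately efficient land use (both
#' metrics strictly inside their bands). Anything else, including missing
#' inputs, is unclassified.
#'
#' @param totalFootprint t CO2-eq/ha (vectorized).
#' @param landRequirement ha/ton (vectorized).
#' @param thresholds List with \code{footprint = c(low, high)} and
#'   \code{land = c(low, high)}.
#' @return Character vector: \code{"i"}, \code{"ii"}, \code{"iii"} or
#'   \code{"unclassified"}.
#' @export
classifyCluster <- function(totalFootprint, landRequirement,
                            thresholds = clusterThresholds()) {
    fp <- totalFootprint; lr <- landRequirement
    fb <- thresholds$footprint; lb <- thresholds$land
    if (fb[1L] > fb[2L] || lb[1L] > lb[2L])
        stop("thresholds must satisfy low <= high")
    out <- rep("unclassified", length(fp))
    ok <- !is.na(fp) & !is.na(lr)
    out[ok & fp >= fb[2L] & lr <= lb[1L]] <- "i"
    out[ok & fp <= fb[1L] & lr >= lb[2L]] <- "ii"
    out[ok & fp > fb[1L] & fp < fb[2L] & lr > lb[1L] & lr < lb[2L]] <- "iii"
    out
}

#' @rdname classifyCluster
#' @param footprint,land Numeric \code{c(low, high)} band edges, in
#'   t CO2-eq/ha and ha/ton. Defaults bracket the synthetic demo world.
#' @export
clusterThresholds <- function(footprint = c(5, 50), land = c(0.15, 0.5)) {
    list(footprint = footprint, land = land)
}

#' First-order soil-carbon share of land-use-change emissions
#'
#' For each attributable conversion, takes the soil-carbon stock change of
#' the 5-year period AFTER the conversion at the converted cell, converts
#' it to CO2, attributes it with the same increase-proportional weights as
#' the aboveground biomass, and reports its share of total (soil +
#' aboveground) LUC emissions. A short-horizon, lower-bound approximation
#' of the soil pool left out of the core accounting. Conversions in the
#' final step have no post-conversion interval and are excluded.
#'
#' @param soilDensity \linkS4class{CarbonDensitySeries} with
#'   \code{pool = "soil"}, or NULL (feature disabled; returns NULL).
#' @param events Event table with carbon attached.
#' @param fractions,regions Attribution inputs as for [buildLedger()].
#' @param constants [lucConstants()].
#' @return NULL, or a list with \code{byRegionCrop} (region, crop,
#'   soil_co2_t), \code{soilTotal}, \code{abovegroundTotal} and
#'   \code{share} (soil / (soil + aboveground), in [0, 1]).
#' @export
soilCarbonFirstOrder <- function(soilDensity, events, fractions, regions,
                                 constants = lucConstants()) {
    if (is.null(soilDensity)) return(NULL)
    stopifnot(is(soilDensity, "CarbonDensitySeries"))
    if (soilDensity@pool != "soil")
        stop("soilDensity must carry the soil pool")
    dcSoil <- stockChange(soilDensity)
    steps <- soilDensity@steps
    ev <- events[!is.na(events$attributable) & events$attributable &
                     events$co2_t > 0, , drop = FALSE]
    wa <- .weightArray(fractions)
    cats <- fractions@categories
    rows <- list()
    soilTotal <- 0
    for (i in seq_len(nrow(ev))) {
        kNext <- match(ev$step_end[i], dcSoil@steps) + 1L
        if (kNext > length(dcSoil@steps)) next  # no post-conversion interval
        dC <- dcSoil@deltaC[ev$row[i], ev$col[i], kNext]
        co2 <- max(cToCO2(dC, constants), 0)
        if (co2 <= 0) next
        soilTotal <- soilTotal + co2
        k <- match(ev$step_end[i], steps) - 1L
        w <- wa$W[ev$row[i], ev$col[i], , k]
        rid <- regions@regionId[ev$row[i], ev$col[i]]
        crop <- if (wa$U[ev$row[i], ev$col[i], k]) "unallocated"
                else cats[which(w > 0)]
        mass <- if (identical(crop, "unallocated")) co2 else co2 * w[w > 0]
        rows[[length(rows) + 1L]] <- data.frame(
            region = regions@regionNames[rid], crop = crop,
            soil_co2_t = mass)
    }
    byRC <- if (length(rows)) {
        x <- do.call(rbind, rows)
        stats::aggregate(soil_co2_t ~ region + crop, data = x, FUN = sum)
    } else data.frame(region = character(), crop = character(),
                      soil_co2_t = numeric())
    aboveTotal <- sum(ev$co2_t)
    denom <- soilTotal + aboveTotal
    list(byRegionCrop = byRC, soilTotal = soilTotal,
         abovegroundTotal = aboveTotal,
         share = if (denom > 0) soilTotal / denom else 0)
}

#' Assemble the per-pairing metrics table
#'
#' Joins the marginal footprint, total footprint, emission intensity and
#' land requirement per (region, crop, step interval), adds the cluster
#' label from the period-average footprint and land requirement, and
#' returns the period summary alongside. Weighted period averages use the
#' weights that make each mean equal the corresponding global ratio:
#' converted area for marginal footprints, total area for total
#' footprints, production for intensities and land requirements.
#'
#' @param ledger Emission ledger.
#' @param convertedArea,totalArea Area tables ([convertedAreaTable()],
#'   [cropAreaTable()]).
#' @param production Annual production table.
#' @param thresholds [clusterThresholds()].
#' @param window,smooth Moving-average settings.
#' @return List with \code{byStep} (the MetricsTable: region, crop,
#'   step_start, step_end, marginal_footprint, total_footprint, intensity,
#'   land_requirement) and \code{summary} (region, crop, period-average
#'   metrics and \code{cluster}).
#' @export
computeMetrics <- function(ledger, convertedArea, totalArea, production,
                           thresholds = clusterThresholds(),
                           window = 5L, smooth = TRUE) {
    mf <- marginalFootprint(ledger, convertedArea)
    tf <- totalFootprint(ledger, totalArea)
    ei <- emissionIntensity(ledger, production, window, smooth)
    lr <- landRequirement(production, ledger, window, smooth)
    key <- c("region", "crop", "step_start", "step_end")
    byStep <- Reduce(function(a, b) merge(a, b, by = key, all = TRUE),
                     list(mf, tf, ei[c(key, "intensity")],
                          lr[c(key, "land_requirement")]))
    byStep <- byStep[order(byStep$step_end, byStep$region, byStep$crop), ,
                     drop = FALSE]
    rownames(byStep) <- NULL

    ## period averages with ratio-consistent weights
    em <- .sumBy(ledger, "co2eq_t")
    full <- merge(merge(byStep, em, by = key, all.x = TRUE),
                  merge(convertedArea, totalArea, by = key, all = TRUE,
                        suffixes = c("_conv", "_tot")),
                  by = key, all.x = TRUE)
    full <- merge(full, ei[c(key, "production_t")], by = key, all.x = TRUE)
    keys <- unique(full[c("region", "crop")])
    summ <- do.call(rbind, lapply(seq_len(nrow(keys)), function(i) {
        s <- full[full$region == keys$region[i] & full$crop == keys$crop[i], ]
        data.frame(
            region = keys$region[i], crop = keys$crop[i],
            marginal_footprint = weightedAverage(s$marginal_footprint,
                                                 .z(s$area_ha_conv)),
            total_footprint = weightedAverage(s$total_footprint,
                                              .z(s$area_ha_tot)),
            intensity = weightedAverage(s$intensity, .z(s$production_t)),
            land_requirement = weightedAverage(s$land_requirement,
                                               .z(s$production_t)))
    }))
    summ$cluster <- classifyCluster(summ$total_footprint,
                                    summ$land_requirement, thresholds)
    rownames(summ) <- NULL
    list(byStep = byStep, summary = summ)
}

.z <- function(x) ifelse(is.na(x), 0, x)
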