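#' Configure a synthetic world
#'
#' Builds the configuration for a small gridded world with known, scripted
#' land-use transitions, class-typical carbon densities, management-emission
#' rates, and production trajectories. The scripted schedule makes every
#' downstream quantity computable in closed form ([expectedLedger()]), so
#' the whole pipeline is testable without external data. Optional random
#' components (random transitions, density jitter, production noise) stress
#' the pipeline beyond the scripted cases; they are driven entirely by
#' \code{seed}.
#'
#' The default world is a 12 x 12 grid of 5 arc-min cells near the equator
#' (about 85 km2 each), 3 regions split by longitude, 11 steps from 1970 to
#' 2020, four natural classes (tropical forest, tropical woodland, savanna,
#' scrubland), three agricultural classes, five active crops plus pasture,
#' and a nine-entry transition schedule covering all six transition
#' categories. Densities are class-typical aboveground values (e.g.,
#' tropical forest 15,000 Mg C/km2 = 150 Mg C/ha, cropland 500 Mg C/km2);
#' management rates are of realistic magnitude per source (e.g., synthetic
#' fertilizer about 1.6 kg N2O/ha/yr, wetland rice about 0.3 Mg
#' CH4/ha/yr). The soil pool uses a one-step lag of class-typical soil
#' densities, so the soil flux of a converted cell falls in the 5-year
#' period after the conversion.
#'
#' @param nLat,nLon Grid size.
#' @param resolution Cell size in degrees.
#' @param steps Step years (constant spacing).
#' @param regionNames Region labels; regions split the grid into
#'   equal-width longitude bands.
#' @param initialClasses Integer \code{[nLat, nLon]} matrix of start
#'   classes; default described above.
#' @param schedule List of scripted transitions, each
#'   \code{list(row, col, step_end, to_class, alloc = c(crop = fraction,
#'   ...))}; \code{alloc} sets the cell's crop fractions from that step on
#'   (required for agricultural targets, ignored for natural targets).
#' @param classDensity,soilClassDensity Named (by class id) Mg C/km2 means.
#' @param baselineAlloc,pastureAlloc Crop fractions of cells that start as
#'   cropland / intensive grassland.
#' @param managementRates Data.frame \code{source_id, gas, rate, basis};
#'   rate in Mg gas per ha per yr, basis one of \code{"converted"} (newly
#'   converted agricultural area), \code{"agri"} (total agricultural
#'   area), \code{"crop"} (per-crop area, pasture excluded; bulk for
#'   source 4), \code{"rice"} (rice area only).
#' @param residueCoef Named relative aboveground-residue coefficients per
#'   category (pasture 0).
#' @param production Data.frame \code{region, crop, base_t, growth} of
#'   annual production trajectories \code{base_t * (1 + growth)^(year -
#'   startYear)}.
#' @param yields Named t/ha used to derive harvested area.
#' @param randomTransitionRate Per-cell per-step probability of an
#'   unscripted transition (natural cells convert to agriculture;
#'   agricultural cells abandon at half the rate).
#' @param densityJitterSd,productionNoiseSd Relative (lognormal) spreads.
#' @param soil Generate the soil-carbon pool series.
#' @param seed Seed for all random components.
#' @return A validated \code{"WorldConfig"} list.
#' @seealso [generateWorld()], [expectedLedger()]
#' @export
worldConfig <- function(nLat = 12L, nLon = 12L, resolution = 1 / 12,
                        steps = seq(1970L, 2020L, by = 5L),
                        regionNames = c("region_1", "region_2", "region_3"),
                        initialClasses = NULL,
                        schedule = NULL,
                        classDensity = .defaultClassDensity(),
                        soilClassDensity = .defaultSoilDensity(),
                        baselineAlloc = c("wheat" = 0.3, "rice" = 0.2,
                                          "maize" = 0.3, "soybeans" = 0.1),
                        pastureAlloc = c("pasture" = 0.9),
                        managementRates = .defaultManagementRates(),
                        residueCoef = NULL,
                        production = NULL,
                        yields = c("wheat" = 3, "rice" = 4, "maize" = 5,
                                   "soybeans" = 2.5, "palm oil" = 15),
                        randomTransitionRate = 0,
                        densityJitterSd = 0,
                        productionNoiseSd = 0,
                        soil = TRUE,
                        seed = 1L) {
    nLat <- as.integer(nLat); nLon <- as.integer(nLon)
    steps <- as.integer(steps)
    cats <- cropCategories()
    cls <- landUseClasses()
    if (is.null(initialClasses))
        initialClasses <- .defaultInitialClasses(nLat, nLon)
    if (is.null(schedule))
        schedule <- .defaultSchedule(nLat, nLon, steps)
    if (is.null(residueCoef)) {
        residueCoef <- stats::setNames(rep(1, length(cats)), cats)
        residueCoef["pasture"] <- 0
    }
    if (is.null(production))
        production <- .defaultProduction(regionNames, names(yields))
    cfg <- structure(list(
        nLat = nLat, nLon = nLon, resolution = resolution, steps = steps,
        regionNames = regionNames, initialClasses = initialClasses,
        schedule = schedule, classDensity = classDensity,
        soilClassDensity = soilClassDensity,
        baselineAlloc = baselineAlloc, pastureAlloc = pastureAlloc,
        managementRates = managementRates, residueCoef = residueCoef,
        production = production, yields = yields,
        randomTransitionRate = randomTransitionRate,
        densityJitterSd = densityJitterSd,
        productionNoiseSd = productionNoiseSd,
        soil = soil, seed = as.integer(seed)), class = "WorldConfig")
    .validateWorldConfig(cfg)
    cfg
}

.validateWorldConfig <- function(cfg) {
    cls <- landUseClasses()
    cats <- cropCategories()
    stopifnot(all(dim(cfg$initialClasses) == c(cfg$nLat, cfg$nLon)))
    if (!all(cfg$initialClasses %in% cls$id))
        stop("config error: initial class outside the vocabulary")
    if (is.null(names(cfg$classDensity)) ||
        !all(as.character(cls$id) %in% names(cfg$classDensity)))
        stop("config error: classDensity must name every class id")
    if (any(cfg$classDensity < 0) || any(cfg$soilClassDensity < 0))
        stop("config error: densities must be >= 0")
    for (e in cfg$schedule) {
        if (e$row < 1L || e$row > cfg$nLat || e$col < 1L || e$col > cfg$nLon)
            stop("config error: schedule references cell outside the grid")
        if (!e$step_end %in% cfg$steps[-1L])
            stop("config error: schedule step ", e$step_end,
                 " is not a (non-initial) step year")
        if (!e$to_class %in% cls$id)
            stop("config error: schedule target class outside the vocabulary")
        if (!is.null(e$alloc)) {
            if (!all(names(e$alloc) %in% cats))
                stop("config error: alloc names outside the crop vocabulary")
            if (sum(e$alloc) > 1 + 1e-9)
                stop("config error: cell crop fractions over-subscribed (> 1)")
        }
    }
    if (sum(cfg$baselineAlloc) > 1 + 1e-9 || sum(cfg$pastureAlloc) > 1 + 1e-9)
        stop("config error: baseline fractions over-subscribed (> 1)")
    if (!all(cfg$managementRates$basis %in%
             c("converted", "agri", "crop", "rice")))
        stop("config error: unknown management basis")
    invisible(cfg)
}

.defaultClassDensity <- function() {
    stats::setNames(c(
        500, 300, 800,          # cropland, intensive grassland, biofuel
        800,                    # extensive grassland
        3000, 6000,             # regrowth (abandoning), regrowth (timber)
        15000, 9000, 3000, 2000, 1000,  # trop forest/woodland, savanna, scrub, steppe
        10000, 10000, 10000, 9000, 8000,  # warm mixed .. boreal
        500, 2000, 50, 0), as.character(1:20))
}

.defaultSoilDensity <- function() {
    stats::setNames(c(
        7000, 7500, 7000, 8000, 9000, 9500,
        10000, 9000, 8500, 8000, 8000,
        10000, 11000, 11000, 12000, 13000,
        14000, 13000, 2000, 0), as.character(1:20))
}

.defaultManagementRates <- function() {
    data.frame(
        source_id = c(1L, 2L, 2L, 2L, 3L, 4L, 5L, 6L, 6L, 7L),
        gas = c("N2O", "CO2", "N2O", "CH4", "N2O", "N2O", "N2O", "N2O",
                "CH4", "CH4"),
        rate = c(0.002, 0.5, 5e-4, 0.001, 3e-4, 6e-4, 0.0016, 1e-4,
                 8e-4, 0.3),
        basis = c("converted", "agri", "agri", "agri", "agri", "crop",
                  "crop", "crop", "crop", "rice"),
        stringsAsFactors = FALSE
    )
}

.defaultInitialClasses <- function(nLat, nLon) {
    m <- matrix(0L, nLat, nLon)
    bands <- ceiling(seq_len(nLat) / (nLat / 4))
    m[bands == 1L, ] <- 7L   # tropical forest
    m[bands == 2L, ] <- 8L   # tropical woodland
    m[bands == 3L, ] <- 9L   # savanna
    m[bands >= 4L, ] <- 10L  # scrubland
    ## a few cells start agricultural
    r <- pmin(nLat, 5:8); c1 <- pmin(nLon, 1:2)
    m[r, c1] <- 1L                       # cropland
    m[pmin(nLat, 5:6), pmin(nLon, 3)] <- 2L  # intensive grassland
    m
}

.defaultSchedule <- function(nLat, nLon, steps) {
    ## clamp to grid so small custom grids stay valid
    cc <- function(r, c) list(r = min(r, nLat), c = min(c, nLon))
    s <- function(i) steps[min(i, length(steps))]
    list(
        list(row = cc(1, 5)$r, col = cc(1, 5)$c, step_end = s(2),
             to_class = 1L, alloc = c("palm oil" = 0.6, "soybeans" = 0.3)),
        list(row = cc(2, 9)$r, col = cc(2, 9)$c, step_end = s(3),
             to_class = 1L, alloc = c("palm oil" = 0.8)),
        list(row = cc(4, 2)$r, col = cc(4, 2)$c, step_end = s(4),
             to_class = 1L, alloc = c("maize" = 0.5, "soybeans" = 0.4)),
        list(row = cc(7, 6)$r, col = cc(7, 6)$c, step_end = s(5),
             to_class = 1L, alloc = c("maize" = 0.4, "rice" = 0.5)),
        list(row = cc(10, 10)$r, col = cc(10, 10)$c, step_end = s(6),
             to_class = 2L, alloc = c("pasture" = 0.85)),
        list(row = cc(5, 1)$r, col = cc(5, 1)$c, step_end = s(7),
             to_class = 2L, alloc = c("pasture" = 0.9)),
        list(row = cc(8, 8)$r, col = cc(8, 8)$c, step_end = s(8),
             to_class = 4L, alloc = NULL),
        list(row = cc(3, 11)$r, col = cc(3, 11)$c, step_end = s(9),
             to_class = 6L, alloc = NULL),
        list(row = cc(6, 2)$r, col = cc(6, 2)$c, step_end = s(10),
             to_class = 5L, alloc = NULL)
    )
}

.defaultProduction <- function(regionNames, crops) {
    g <- expand.grid(region = regionNames, crop = crops,
                     stringsAsFactors = FALSE)
    g$base_t <- 5e4 + 1e4 * (seq_len(nrow(g)) %% 7)
    g$growth <- 0.02
    g
}

## class and fraction trajectories implied by the scripted schedule alone
.scriptedState <- function(cfg) {
    nT <- length(cfg$steps)
    cats <- cropCategories()
    classArr <- array(rep(cfg$initialClasses, nT),
                      c(cfg$nLat, cfg$nLon, nT))
    fracArr <- array(0, c(cfg$nLat, cfg$nLon, length(cats), nT))
    agri <- landUseClasses()$id[landUseClasses()$group == "agriculture"]
    setAlloc <- function(arr, r, c, fromStep, alloc) {
        arr[r, c, , fromStep:nT] <- 0
        for (nm in names(alloc))
            arr[r, c, match(nm, cats), fromStep:nT] <- alloc[[nm]]
        arr
    }
    crop0 <- which(cfg$initialClasses == 1L | cfg$initialClasses == 3L,
                   arr.ind = TRUE)
    for (i in seq_len(nrow(crop0)))
        fracArr <- setAlloc(fracArr, crop0[i, 1L], crop0[i, 2L], 1L,
                            cfg$baselineAlloc)
    past0 <- which(cfg$initialClasses == 2L, arr.ind = TRUE)
    for (i in seq_len(nrow(past0)))
        fracArr <- setAlloc(fracArr, past0[i, 1L], past0[i, 2L], 1L,
                            cfg$pastureAlloc)
    ord <- order(vapply(cfg$schedule, function(e) e$step_end, numeric(1)))
    for (e in cfg$schedule[ord]) {
        k <- match(e$step_end, cfg$steps)
        classArr[e$row, e$col, k:nT] <- e$to_class
        if (e$to_class %in% agri) {
            alloc <- e$alloc
            if (is.null(alloc))
                alloc <- if (e$to_class == 2L) cfg$pastureAlloc
                         else cfg$baselineAlloc
            fracArr <- setAlloc(fracArr, e$row, e$col, k, alloc)
        } else {
            fracArr[e$row, e$col, , k:nT] <- 0
        }
    }
    list(classArr = classArr, fracArr = fracArr)
}

#' Generate a synthetic world
#'
#' Realizes a [worldConfig()] as a full set of pipeline inputs: land-use
#' series, crop-fraction series, aboveground (and optional soil) carbon
#' density, the management-emission layers, residue shares, region map,
#' and production table. Deterministic given the seed; scripted
#' transitions are realized exactly, random components only add to them.
#'
#' @param config A \code{"WorldConfig"}.
#' @param seed Overrides \code{config$seed}.
#' @return List of class \code{"lucWorld"} with elements \code{geometry},
#'   \code{landUse}, \code{fractions}, \code{density}, \code{soilDensity}
#'   (or NULL), \code{management} (list of \linkS4class{ManagementLayer}),
#'   \code{residues}, \code{regions}, \code{production}, \code{config}.
#' @export
generateWorld <- function(config, seed = config$seed) {
    .validateWorldConfig(config)
    set.seed(seed)
    cfg <- config
    nT <- length(cfg$steps)
    cats <- cropCategories()
    nCat <- length(cats)
    stepSpan <- if (nT > 1L) diff(cfg$steps)[1L] else 5L
    geom <- gridGeometry(cfg$nLat, cfg$nLon, cfg$resolution)
    areaHa <- cellAreas(geom) * 100
    cls <- landUseClasses()
    agri <- cls$id[cls$group == "agriculture"]

    st <- .scriptedState(cfg)
    classArr <- st$classArr
    fracArr <- st$fracArr

    ## random, unscripted transitions on top of the script
    if (cfg$randomTransitionRate > 0) {
        scheduled <- matrix(FALSE, cfg$nLat, cfg$nLon)
        for (e in cfg$schedule) scheduled[e$row, e$col] <- TRUE
        active <- names(cfg$yields)
        for (k in 2:nT) {
            for (r in seq_len(cfg$nLat)) for (c in seq_len(cfg$nLon)) {
                if (scheduled[r, c]) next
                cur <- classArr[r, c, k - 1L]
                if (!(cur %in% agri) &&
                    stats::runif(1) < cfg$randomTransitionRate) {
                    to <- sample(c(1L, 2L, 3L), 1L, prob = c(0.6, 0.3, 0.1))
                    classArr[r, c, k:nT] <- to
                    if (to == 2L) {
                        alloc <- c("pasture" = stats::runif(1, 0.5, 0.95))
                    } else {
                        w <- stats::runif(length(active))
                        alloc <- stats::setNames(
                            w / sum(w) * stats::runif(1, 0.5, 0.95), active)
                    }
                    fracArr[r, c, , k:nT] <- 0
                    for (nm in names(alloc))
                        fracArr[r, c, match(nm, cats), k:nT] <- alloc[[nm]]
                } else if (cur %in% agri &&
                           stats::runif(1) < cfg$randomTransitionRate / 2) {
                    classArr[r, c, k:nT] <- 5L  # abandonment to regrowth
                    fracArr[r, c, , k:nT] <- 0
                }
            }
        }
    }

    lu <- new("LandUseSeries", geometry = geom, steps = cfg$steps,
              classMap = classArr, classes = cls)
    fractions <- new("CropFractionSeries", geometry = geom,
                     steps = cfg$steps, fraction = fracArr,
                     categories = cats)

    dens <- array(cfg$classDensity[as.character(classArr)],
                  dim(classArr))
    if (cfg$densityJitterSd > 0)
        dens <- dens * exp(stats::rnorm(length(dens), 0,
                                        cfg$densityJitterSd))
    density <- new("CarbonDensitySeries", geometry = geom,
                   steps = cfg$steps, density = dens, pool = "aboveground")

    soilDensity <- NULL
    if (isTRUE(cfg$soil)) {
        ## soil responds with a one-step lag: the flux of a conversion
        ## falls in the 5-year period after it
        lagged <- classArr
        if (nT > 1L) lagged[, , 2:nT] <- classArr[, , 1:(nT - 1L)]
        soil <- array(cfg$soilClassDensity[as.character(lagged)],
                      dim(classArr))
        soilDensity <- new("CarbonDensitySeries", geometry = geom,
                           steps = cfg$steps, density = soil, pool = "soil")
    }

    regions <- new("RegionMap", geometry = geom,
                   regionId = .regionMatrix(cfg),
                   regionNames = cfg$regionNames)

    ## management layers per configured rate and basis, 5-year sums
    nPair <- nT - 1L
    pairSteps <- cfg$steps[-1L]
    convertedHa <- array(0, c(cfg$nLat, cfg$nLon, nPair))
    for (k in seq_len(nPair)) {
        was <- classArr[, , k]; now <- classArr[, , k + 1L]
        convertedHa[, , k] <- areaHa * (!(was %in% agri) & (now %in% agri))
    }
    totFrac <- apply(fracArr, c(1L, 2L, 4L), sum)
    agriHa <- array(0, c(cfg$nLat, cfg$nLon, nPair))
    cropHa <- array(0, c(cfg$nLat, cfg$nLon, nCat, nPair))
    for (k in seq_len(nPair)) {
        agriHa[, , k] <- totFrac[, , k + 1L] * areaHa
        for (c in seq_len(nCat))
            cropHa[, , c, k] <- fracArr[, , c, k + 1L] * areaHa
    }
    pastureIdx <- match("pasture", cats)
    riceIdx <- match("rice", cats)
    cropHaNoPast <- cropHa
    cropHaNoPast[, , pastureIdx, ] <- 0

    management <- list()
    for (i in seq_len(nrow(cfg$managementRates))) {
        rr <- cfg$managementRates[i, ]
        if (rr$basis == "crop" && rr$source_id >= 5L) {
            vals <- cropHaNoPast * rr$rate * stepSpan
            layer <- new("ManagementLayer", geometry = geom,
                         steps = pairSteps, sourceId = rr$source_id,
                         gas = rr$gas, values = vals, cropSpecific = TRUE,
                         categories = cats)
        } else if (rr$basis == "rice") {
            vals <- array(0, c(cfg$nLat, cfg$nLon, nCat, nPair))
            vals[, , riceIdx, ] <- cropHa[, , riceIdx, ] * rr$rate * stepSpan
            layer <- new("ManagementLayer", geometry = geom,
                         steps = pairSteps, sourceId = rr$source_id,
                         gas = rr$gas, values = vals, cropSpecific = TRUE,
                         categories = cats)
        } else {
            base <- switch(rr$basis,
                converted = convertedHa,
                agri = agriHa,
                crop = apply(cropHaNoPast, c(1L, 2L, 4L), sum))
            if (rr$basis == "crop")
                base <- array(base, c(cfg$nLat, cfg$nLon, nPair))
            layer <- new("ManagementLayer", geometry = geom,
                         steps = pairSteps, sourceId = rr$source_id,
                         gas = rr$gas, values = base * rr$rate * stepSpan,
                         cropSpecific = FALSE, categories = character())
        }
        management[[length(management) + 1L]] <- layer
    }

    residues <- array(0, c(cfg$nLat, cfg$nLon, nCat, nPair))
    for (c in seq_len(nCat))
        residues[, , c, ] <- cropHa[, , c, ] * cfg$residueCoef[[cats[c]]]

    production <- .syntheticProduction(cfg)

    structure(list(geometry = geom, landUse = lu, fractions = fractions,
                   density = density, soilDensity = soilDensity,
                   management = management, residues = residues,
                   regions = regions, production = production,
                   config = cfg), class = "lucWorld")
}

.regionMatrix <- function(cfg) {
    nR <- length(cfg$regionNames)
    band <- pmin(ceiling(seq_len(cfg$nLon) / (cfg$nLon / nR)), nR)
    matrix(rep(as.integer(band), each = cfg$nLat), cfg$nLat, cfg$nLon)
}

.syntheticProduction <- function(cfg) {
    years <- seq(min(cfg$steps), max(cfg$steps))
    p <- cfg$production
    rows <- vector("list", nrow(p))
    for (i in seq_len(nrow(p))) {
        prod <- p$base_t[i] * (1 + p$growth[i])^(years - years[1L])
        if (cfg$productionNoiseSd > 0)
            prod <- prod * exp(stats::rnorm(length(prod), 0,
                                            cfg$productionNoiseSd))
        yld <- cfg$yields[[p$crop[i]]]
        rows[[i]] <- data.frame(
            region = p$region[i], crop = p$crop[i], year = years,
            production_t = prod, harvested_area_ha = prod / yld)
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Closed-form expected emission ledger of a scripted world
#'
#' Computes, by direct arithmetic on the configuration (no transition
#' detection, no routing machinery), the ledger the pipeline must produce
#' on the generated world: for each scripted conversion, the biomass CO2 is
#' \code{(density_from - density_to) * cell_area * 44/12} (booked only when
#' positive and the transition category is attributable), allocated to
#' categories by the configured fraction increments; management sources are
#' integrated as rate x basis area x years x GWP and routed by the same
#' rules the pipeline implements. Refuses configurations with random
#' transitions or density jitter, which break exactness.
#'
#' @param config A scripted \code{"WorldConfig"}.
#' @param constants [lucConstants()].
#' @param taxonomy Transition taxonomy (category lookup).
#' @return Data.frame (region, crop, step_start, step_end, source,
#'   co2eq_t), positive entries only, sorted like [buildLedger()] output.
#' @export
expectedLedger <- function(config, constants = lucConstants(),
                           taxonomy = defaultTaxonomy()) {
    .validateWorldConfig(config)
    if (config$randomTransitionRate > 0)
        stop("exact expected ledger requires a fully scripted config ",
             "(randomTransitionRate = 0)")
    if (config$densityJitterSd > 0)
        stop("exact expected ledger requires densityJitterSd = 0")
    cfg <- config
    nT <- length(cfg$steps)
    stepSpan <- if (nT > 1L) diff(cfg$steps)[1L] else 5L
    cats <- cropCategories()
    nCat <- length(cats)
    geom <- gridGeometry(cfg$nLat, cfg$nLon, cfg$resolution)
    areaHa <- cellAreas(geom) * 100
    areaKm2 <- cellAreas(geom)
    cls <- landUseClasses()
    agri <- cls$id[cls$group == "agriculture"]
    regionId <- .regionMatrix(cfg)
    st <- .scriptedState(cfg)
    classArr <- st$classArr
    fracArr <- st$fracArr
    txKey <- paste(taxonomy$from_class, taxonomy$to_class)
    gwp <- constants$gwp
    pastureIdx <- match("pasture", cats)
    riceIdx <- match("rice", cats)

    rows <- list()
    book <- function(region, crop, k, source, t) {
        if (t <= 0) return(invisible())
        rows[[length(rows) + 1L]] <<- data.frame(
            region = cfg$regionNames[region], crop = crop,
            step_start = cfg$steps[k], step_end = cfg$steps[k + 1L],
            source = source, co2eq_t = t)
    }
    cellWeights <- function(r, c, k) {
        attributionWeights(fracArr[r, c, , k], fracArr[r, c, , k + 1L])
    }
    bookWeighted <- function(r, c, k, source, mass) {
        w <- cellWeights(r, c, k)
        if (isTRUE(attr(w, "unallocated"))) {
            book(regionId[r, c], "unallocated", k, source, mass)
        } else {
            for (ci in which(w > 0))
                book(regionId[r, c], cats[ci], k, source, mass * w[ci])
        }
    }

    for (k in seq_len(nT - 1L)) {
        for (r in seq_len(cfg$nLat)) for (c in seq_len(cfg$nLon)) {
            from <- classArr[r, c, k]; to <- classArr[r, c, k + 1L]
            ## biomass LUC of scripted conversions
            if (from != to) {
                cat6 <- taxonomy$category[match(paste(from, to), txKey)]
                if (!is.na(cat6) && cat6 %in% c(2L, 5L)) {
                    dC <- (cfg$classDensity[[as.character(from)]] -
                           cfg$classDensity[[as.character(to)]]) *
                        areaKm2[r, c]
                    co2 <- cToCO2(dC, constants)
                    if (co2 > 0) {
                        src <- if (cat6 == 2L) "luc_natural_to_agriculture"
                               else "luc_agricultural_transitions"
                        bookWeighted(r, c, k, src, co2)
                    }
                }
            }
            ## management sources
            conv <- (!(from %in% agri)) && (to %in% agri)
            fracNow <- fracArr[r, c, , k + 1L]
            agriHa <- sum(fracNow) * areaHa[r, c]
            cropHa <- fracNow * areaHa[r, c]
            cropHa[pastureIdx] <- 0
            for (i in seq_len(nrow(cfg$managementRates))) {
                rr <- cfg$managementRates[i, ]
                eqFactor <- gwp[[rr$gas]] * rr$rate * stepSpan
                srcName <- .managementSourceName(rr$source_id)
                if (rr$basis == "converted") {
                    if (conv)
                        bookWeighted(r, c, k, srcName,
                                     eqFactor * areaHa[r, c])
                } else if (rr$basis == "agri") {
                    if (agriHa > 0)
                        bookWeighted(r, c, k, srcName, eqFactor * agriHa)
                } else if (rr$basis == "crop" && rr$source_id == 4L) {
                    ## residue split of the bulk mass
                    bulk <- eqFactor * sum(cropHa)
                    if (bulk > 0) {
                        shares <- cropHa *
                            cfg$residueCoef[cats]
                        shares <- shares / sum(shares)
                        for (ci in which(shares > 0))
                            book(regionId[r, c], cats[ci], k, srcName,
                                 bulk * shares[ci])
                    }
                } else if (rr$basis == "crop") {
                    for (ci in which(cropHa > 0))
                        book(regionId[r, c], cats[ci], k, srcName,
                             eqFactor * cropHa[ci])
                } else if (rr$basis == "rice") {
                    if (cropHa[riceIdx] > 0)
                        book(regionId[r, c], "rice", k, srcName,
                             eqFactor * cropHa[riceIdx])
                }
            }
        }
    }
    if (!length(rows))
        return(data.frame(region = character(), crop = character(),
                          step_start = integer(), step_end = integer(),
                          source = character(), co2eq_t = numeric()))
    out <- do.call(rbind, rows)
    out <- stats::aggregate(co2eq_t ~ region + crop + step_start +
                                step_end + source, data = out, FUN = sum)
    out <- out[order(out$step_end, out$region, out$source, out$crop), ,
               drop = FALSE]
    rownames(out) <- NULL
    out
}
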