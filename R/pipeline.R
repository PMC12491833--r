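#' Write or read a full world to/from a directory
#'
#' Persists every gridded input of a world in the package's NetCDF
#' conventions plus delimited tables (production, management manifest), so
#' a generated world can be re-read and analyzed identically to the
#' in-memory original.
#'
#' @param world A \code{"lucWorld"} ([generateWorld()]).
#' @param dir Target directory (created if needed).
#' @return \code{dir} (write) / a \code{"lucWorld"} list (read),
#'   without the config element.
#' @export
writeWorld <- function(world, dir) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    writeLayer(world$landUse, file.path(dir, "land_use.nc"), "land_use")
    writeLayer(world$fractions, file.path(dir, "crop_fractions.nc"),
               "crop_fraction")
    writeLayer(world$density, file.path(dir, "carbon_density.nc"),
               "carbon_density")
    if (!is.null(world$soilDensity))
        writeLayer(world$soilDensity, file.path(dir, "soil_density.nc"),
                   "carbon_density")
    writeLayer(world$regions, file.path(dir, "regions.nc"), "region")
    manifest <- data.frame(source_id = integer(), gas = character(),
                           path = character(), crop_specific = logical())
    for (i in seq_along(world$management)) {
        l <- world$management[[i]]
        fn <- sprintf("management_%d_%s.nc", l@sourceId, l@gas)
        writeLayer(l, file.path(dir, fn), "emission")
        manifest <- rbind(manifest, data.frame(
            source_id = l@sourceId, gas = l@gas, path = fn,
            crop_specific = l@cropSpecific))
    }
    utils::write.csv(manifest, file.path(dir, "management_manifest.csv"),
                     row.names = FALSE)
    ## residue shares: crop-dimensioned mass grid on the step intervals
    g <- world$geometry
    steps <- stepYears(world$landUse)[-1L]
    dims <- .ncDims(g, steps, cropCategories())
    .ncPut(file.path(dir, "residues.nc"), "residue_shares", dims,
           .toNc(world$residues), "Mg", "double", "residue_shares",
           list(categories = paste(cropCategories(), collapse = ";"),
                earth_radius_km = g@earthRadius))
    writeProductionTable(world$production, file.path(dir, "production.csv"))
    invisible(dir)
}

#' @rdname writeWorld
#' @export
readWorld <- function(dir) {
    lu <- readLayer(file.path(dir, "land_use.nc"), "land_use")
    fractions <- readLayer(file.path(dir, "crop_fractions.nc"),
                           "crop_fraction")
    density <- readLayer(file.path(dir, "carbon_density.nc"),
                         "carbon_density")
    soilPath <- file.path(dir, "soil_density.nc")
    soilDensity <- if (file.exists(soilPath))
        readLayer(soilPath, "carbon_density") else NULL
    regions <- readLayer(file.path(dir, "regions.nc"), "region")
    manifest <- utils::read.csv(file.path(dir, "management_manifest.csv"),
                                stringsAsFactors = FALSE)
    management <- lapply(manifest$path, function(p)
        readLayer(file.path(dir, p), "emission"))
    residues <- .readResidues(file.path(dir, "residues.nc"))
    production <- readProductionTable(file.path(dir, "production.csv"))
    structure(list(geometry = geometry(lu), landUse = lu,
                   fractions = fractions, density = density,
                   soilDensity = soilDensity, management = management,
                   residues = residues, regions = regions,
                   production = production, config = NULL),
              class = "lucWorld")
}

.readResidues <- function(path) {
    nc <- ncdf4::nc_open(path)
    on.exit(ncdf4::nc_close(nc))
    vals <- ncdf4::ncvar_get(nc, "residue_shares", collapse_degen = FALSE)
    vals[vals == .FILL] <- NA
    .fromNc(vals)
}

#' Run the attribution stages on a world
#'
#' The end-to-end computation: carbon stocks and stock changes, transition
#' detection, classification and carbon attachment, management routing,
#' ledger assembly, the area denominators, the flow table, and (when a
#' soil pool is present) the first-order soil-carbon share. The
#' end-to-end conservation check is asserted inside [buildLedger()] on
#' every run.
#'
#' @param world A \code{"lucWorld"}.
#' @param constants [lucConstants()].
#' @param taxonomy [defaultTaxonomy()] or a custom table.
#' @param strict Error on unclassified transitions.
#' @return List: \code{events}, \code{stockChange}, \code{routed},
#'   \code{ledger}, \code{convertedArea}, \code{totalArea}, \code{flows},
#'   \code{soil}.
#' @export
runAttribution <- function(world, constants = lucConstants(),
                           taxonomy = defaultTaxonomy(), strict = TRUE) {
    dc <- stockChange(world$density)
    events <- detectTransitions(world$landUse)
    events <- classifyTransitions(events, taxonomy, strict)
    events <- attachCarbon(events, dc, world$geometry, constants)
    routed <- routeSources(world$management, world$fractions,
                           world$residues, constants)
    ledger <- buildLedger(events, routed, world$fractions, world$regions,
                          constants)
    convertedArea <- convertedAreaTable(events, world$fractions,
                                        world$regions)
    totalArea <- cropAreaTable(world$fractions, world$regions,
                               "prior_plus_new")
    flows <- transitionMatrix(events)
    soil <- soilCarbonFirstOrder(world$soilDensity, events,
                                 world$fractions, world$regions, constants)
    list(events = events, stockChange = dc, routed = routed,
         ledger = ledger, convertedArea = convertedArea,
         totalArea = totalArea, flows = flows, soil = soil)
}

#' Run configuration
#'
#' Read a YAML run configuration or build one programmatically. Fields
#' (all optional, shown with defaults): \code{seed} (1), \code{strict}
#' (TRUE), \code{moving_average_window} (5), \code{gwp} (CH4 28, N2O 265),
#' \code{gwp_horizon}, \code{cluster_thresholds} (\code{footprint},
#' \code{land} low/high pairs), \code{taxonomy} (path; NULL = shipped
#' default), \code{world} (\code{"synthetic"} or a directory written by
#' [writeWorld()]), \code{world_config} (overrides passed to
#' [worldConfig()] for synthetic runs), \code{output_dir}.
#'
#' @param path YAML file.
#' @return A \code{"RunConfig"} list.
#' @export
readRunConfig <- function(path) {
    if (!file.exists(path)) stop("config file not found: ", path)
    cfg <- yaml::read_yaml(path)
    cfg$.path <- path
    class(cfg) <- "RunConfig"
    cfg
}

#' @rdname readRunConfig
#' @param ... Fields as above.
#' @export
runConfig <- function(...) {
    cfg <- list(...)
    class(cfg) <- "RunConfig"
    cfg
}

#' @rdname readRunConfig
#' @param config A \code{"RunConfig"}; validated before any computation:
#'   referenced paths must exist, thresholds and window must be sane.
#' @export
validateRunConfig <- function(config) {
    w <- config$world
    if (!is.null(w) && !identical(w, "synthetic") && !dir.exists(w))
        stop("config validation: world directory not found: ", w)
    if (!is.null(config$taxonomy) && !file.exists(config$taxonomy))
        stop("config validation: taxonomy file not found: ", config$taxonomy)
    win <- config$moving_average_window
    if (!is.null(win) && (win < 1 || win %% 2 == 0))
        stop("config validation: moving_average_window must be odd >= 1")
    th <- config$cluster_thresholds
    if (!is.null(th)) {
        if (th$footprint[1] > th$footprint[2] || th$land[1] > th$land[2])
            stop("config validation: cluster thresholds must be low <= high")
    }
    if (!is.null(config$gwp) && any(unlist(config$gwp) <= 0))
        stop("config validation: GWP factors must be > 0")
    invisible(config)
}

.configConstants <- function(config) {
    gwp <- c(CO2 = 1, CH4 = 28, N2O = 265)
    for (nm in names(config$gwp)) gwp[[nm]] <- config$gwp[[nm]]
    lucConstants(gwp = gwp,
                 gwpHorizon = config$gwp_horizon %||% "AR5-100yr")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' One-command end-to-end run
#'
#' Validates the configuration, obtains the world (generating the
#' synthetic one or reading a directory), runs [runAttribution()] and
#' [computeMetrics()], and writes the output bundle: \code{ledger.csv},
#' \code{metrics_by_step.csv}, \code{metrics_summary.csv},
#' \code{flows.csv}, \code{events.csv} and \code{run_metadata.json}
#' (constants, GWP horizon, seed, config hash, conservation result, soil
#' share). Deterministic given config + seed; all tabular outputs are
#' byte-stable across reruns.
#'
#' @param config \code{"RunConfig"} or path to a YAML file.
#' @param outDir Overrides \code{config$output_dir}.
#' @return Invisibly, the list from [runAttribution()] plus
#'   \code{metrics}, \code{world} and \code{metadata}.
#' @export
runPipeline <- function(config = runConfig(), outDir = NULL) {
    if (is.character(config)) config <- readRunConfig(config)
    validateRunConfig(config)
    seed <- as.integer(config$seed %||% 1L)
    constants <- .configConstants(config)
    taxonomy <- if (is.null(config$taxonomy)) defaultTaxonomy()
                else readTaxonomy(config$taxonomy)
    w <- config$world %||% "synthetic"
    world <- if (identical(w, "synthetic")) {
        wc <- do.call(worldConfig, c(config$world_config %||% list(),
                                     list(seed = seed)))
        generateWorld(wc)
    } else readWorld(w)
    res <- runAttribution(world, constants, taxonomy,
                          strict = config$strict %||% TRUE)
    th <- config$cluster_thresholds
    thresholds <- if (is.null(th)) clusterThresholds()
                  else clusterThresholds(unlist(th$footprint),
                                         unlist(th$land))
    metrics <- computeMetrics(res$ledger, res$convertedArea, res$totalArea,
                              world$production, thresholds,
                              window = as.integer(
                                  config$moving_average_window %||% 5L))
    cons <- attr(res$ledger, "conservation")
    metadata <- list(
        seed = seed,
        co2_per_c = constants$co2PerC,
        gwp = as.list(constants$gwp),
        gwp_horizon = constants$gwpHorizon,
        config_hash = .configHash(config),
        conservation = cons,
        unique_transitions = res$flows$uniqueTransitions,
        soil_share = if (is.null(res$soil)) NULL else res$soil$share)

    outDir <- outDir %||% config$output_dir
    if (!is.null(outDir)) {
        dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
        wr <- function(df, fn) utils::write.csv(
            df, file.path(outDir, fn), row.names = FALSE)
        wr(res$ledger, "ledger.csv")
        wr(metrics$byStep, "metrics_by_step.csv")
        wr(metrics$summary, "metrics_summary.csv")
        wr(res$flows$flows, "flows.csv")
        wr(res$events, "events.csv")
        jsonlite::write_json(metadata,
                             file.path(outDir, "run_metadata.json"),
                             auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
    invisible(c(res, list(metrics = metrics, world = world,
                          metadata = metadata)))
}

## stable hash of the configuration (paths and class dropped)
.configHash <- function(config) {
    cfg <- unclass(config)
    cfg$.path <- NULL
    tmp <- tempfile()
    on.exit(unlink(tmp))
    saveRDS(cfg, tmp)  # scratch only; hashed then deleted
    unname(tools::md5sum(tmp))
}
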