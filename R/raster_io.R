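## NetCDF conventions used by all gridded layers:
##   dims (lon, lat[, category], time); cell-center coordinates, latitudes
##   north->south; ocean / no-data as the fill value -9999 (class maps and
##   region maps use integer fill); units attributes "Mg C km-2" for
##   densities, "1" for fractions and class ids, "Mg" for management
##   masses. A global attribute lucattr_type names the layer kind so
##   readLayer() can rebuild the right class.

.FILL <- -9999

.ncDims <- function(geometry, steps = NULL, categories = NULL) {
    dims <- list(
        lon = ncdf4::ncdim_def("lon", "degrees_east", geometry@lonCenters),
        lat = ncdf4::ncdim_def("lat", "degrees_north", geometry@latCenters)
    )
    if (!is.null(categories))
        dims$category <- ncdf4::ncdim_def("category", "1",
                                          seq_along(categories))
    if (!is.null(steps))
        dims$time <- ncdf4::ncdim_def("time", "years", steps)
    dims
}

.ncPut <- function(path, variable, dims, values, units, prec, type,
                   extra = list()) {
    v <- ncdf4::ncvar_def(variable, units, unname(dims), missval = .FILL,
                          prec = prec)
    nc <- ncdf4::nc_create(path, list(v))
    on.exit(ncdf4::nc_close(nc))
    ncdf4::ncvar_put(nc, v, values)
    ncdf4::ncatt_put(nc, 0, "lucattr_type", type)
    for (nm in names(extra)) ncdf4::ncatt_put(nc, 0, nm, extra[[nm]])
    invisible(path)
}

## [lat, lon, ...] array -> ncdf4 [lon, lat, ...] layout and back
.toNc <- function(a) aperm(a, c(2L, 1L, seq_along(dim(a))[-(1:2)]))
.fromNc <- function(a) aperm(a, c(2L, 1L, seq_along(dim(a))[-(1:2)]))

#' @describeIn writeLayer land-use class maps (integer ids).
#' @export
setMethod("writeLayer", "LandUseSeries", function(object, path, variable) {
    validObject(object)
    dims <- .ncDims(object@geometry, object@steps)
    vals <- object@classMap
    vals[is.na(vals)] <- .FILL
    .ncPut(path, variable, dims, .toNc(vals), "1", "integer", "land_use",
           list(class_names = paste(object@classes$name, collapse = ";"),
                class_groups = paste(object@classes$group, collapse = ";"),
                earth_radius_km = object@geometry@earthRadius))
    invisible(path)
})

#' @describeIn writeLayer crop-fraction stacks (dimensionless).
#' @export
setMethod("writeLayer", "CropFractionSeries", function(object, path, variable) {
    validObject(object)
    dims <- .ncDims(object@geometry, object@steps, object@categories)
    vals <- object@fraction
    vals[is.na(vals)] <- .FILL
    .ncPut(path, variable, dims, .toNc(vals), "1", "double", "crop_fraction",
           list(categories = paste(object@categories, collapse = ";"),
                earth_radius_km = object@geometry@earthRadius))
    invisible(path)
})

#' @describeIn writeLayer carbon-density series (Mg C km-2).
#' @export
setMethod("writeLayer", "CarbonDensitySeries", function(object, path, variable) {
    validObject(object)
    dims <- .ncDims(object@geometry, object@steps)
    vals <- object@density
    vals[is.na(vals)] <- .FILL
    .ncPut(path, variable, dims, .toNc(vals), "Mg C km-2", "double",
           "carbon_density",
           list(pool = object@pool,
                earth_radius_km = object@geometry@earthRadius))
    invisible(path)
})

#' @describeIn writeLayer region maps (integer region ids, no time axis).
#' @export
setMethod("writeLayer", "RegionMap", function(object, path, variable) {
    validObject(object)
    dims <- .ncDims(object@geometry)
    vals <- object@regionId
    vals[is.na(vals)] <- .FILL
    .ncPut(path, variable, dims, .toNc(vals), "1", "integer", "region_map",
           list(region_names = paste(object@regionNames, collapse = ";"),
                earth_radius_km = object@geometry@earthRadius))
    invisible(path)
})

#' @describeIn writeLayer management-emission layers (Mg gas per interval).
#' @export
setMethod("writeLayer", "ManagementLayer", function(object, path, variable) {
    validObject(object)
    dims <- .ncDims(object@geometry, object@steps,
                    if (object@cropSpecific) object@categories)
    vals <- object@values
    vals[is.na(vals)] <- .FILL
    .ncPut(path, variable, dims, .toNc(vals), "Mg", "double", "management",
           list(source_id = object@sourceId, gas = object@gas,
                crop_specific = as.integer(object@cropSpecific),
                categories = paste(cropCategories(), collapse = ";"),
                earth_radius_km = object@geometry@earthRadius))
    invisible(path)
})

#' Read a gridded layer from a NetCDF file
#'
#' Reads a layer written by [writeLayer()] (or any file following the same
#' conventions) and rebuilds the matching S4 object; type invariants are
#' validated on read and violations raise an error naming the offending
#' cell and step rather than silently coercing.
#'
#' @param path NetCDF file path.
#' @param variable Variable name; a missing variable is a format error.
#' @return One of \linkS4class{LandUseSeries},
#'   \linkS4class{CropFractionSeries}, \linkS4class{CarbonDensitySeries},
#'   \linkS4class{RegionMap}, \linkS4class{ManagementLayer}.
#' @export
readLayer <- function(path, variable) {
    if (!file.exists(path)) stop("no such file: ", path)
    nc <- ncdf4::nc_open(path)
    on.exit(ncdf4::nc_close(nc))
    if (!variable %in% names(nc$var))
        stop("format error: variable '", variable, "' not found in ", path)
    type <- ncdf4::ncatt_get(nc, 0, "lucattr_type")$value
    lon <- as.numeric(ncdf4::ncvar_get(nc, "lon"))
    lat <- as.numeric(ncdf4::ncvar_get(nc, "lat"))
    res <- if (length(lat) > 1L) abs(lat[1L] - lat[2L]) else
        if (length(lon) > 1L) abs(lon[2L] - lon[1L]) else 1 / 12
    rAttr <- ncdf4::ncatt_get(nc, 0, "earth_radius_km")
    radius <- if (rAttr$hasatt) rAttr$value else 6371.0072
    geom <- gridGeometry(length(lat), length(lon), res,
                         latTop = lat[1L] + res / 2,
                         lonLeft = lon[1L] - res / 2,
                         earthRadius = radius)
    vals <- ncdf4::ncvar_get(nc, variable, collapse_degen = FALSE)
    vals[vals == .FILL] <- NA
    vals <- .fromNc(vals)
    steps <- if ("time" %in% names(nc$dim))
        as.integer(ncdf4::ncvar_get(nc, "time")) else NULL
    gattr <- function(nm) ncdf4::ncatt_get(nc, 0, nm)$value
    obj <- switch(type,
        land_use = {
            cls <- landUseClasses()
            nm <- strsplit(gattr("class_names"), ";")[[1L]]
            gr <- strsplit(gattr("class_groups"), ";")[[1L]]
            if (length(nm) == nrow(cls)) { cls$name <- nm; cls$group <- gr }
            storage.mode(vals) <- "integer"
            new("LandUseSeries", geometry = geom, steps = steps,
                classMap = vals, classes = cls)
        },
        crop_fraction = new("CropFractionSeries", geometry = geom,
            steps = steps, fraction = vals,
            categories = strsplit(gattr("categories"), ";")[[1L]]),
        carbon_density = new("CarbonDensitySeries", geometry = geom,
            steps = steps, density = vals, pool = gattr("pool")),
        region_map = {
            storage.mode(vals) <- "integer"
            dim(vals) <- dim(vals)[1:2]
            new("RegionMap", geometry = geom, regionId = vals,
                regionNames = strsplit(gattr("region_names"), ";")[[1L]])
        },
        management = {
            cs <- as.logical(gattr("crop_specific"))
            new("ManagementLayer", geometry = geom, steps = steps,
                sourceId = as.integer(gattr("source_id")), gas = gattr("gas"),
                values = vals, cropSpecific = cs,
                categories = if (cs) strsplit(gattr("categories"), ";")[[1L]]
                             else character())
        },
        stop("format error: unknown or missing lucattr_type attribute")
    )
    validObject(obj)
    obj
}

## ---- tabular inputs ---------------------------------------------------

#' Read or write a production table
#'
#' Delimited text with header
#' \code{region,crop,year,production_t,harvested_area_ha}. Production and
#' harvested area must be non-negative and crops must be in the fixed
#' vocabulary (plus "unallocated").
#'
#' @param path File path.
#' @return Data.frame with the five columns above.
#' @export
readProductionTable <- function(path) {
    tb <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("region", "crop", "year", "production_t", "harvested_area_ha")
    if (!all(need %in% names(tb)))
        stop("production table must have columns ",
             paste(need, collapse = ","))
    if (any(tb$production_t < 0)) stop("negative production")
    if (any(tb$harvested_area_ha < 0)) stop("negative harvested area")
    bad <- setdiff(unique(tb$crop), c(cropCategories(), "unallocated"))
    if (length(bad))
        stop("crops outside the vocabulary: ", paste(bad, collapse = ", "))
    tb[need]
}

#' @rdname readProductionTable
#' @param table A production table.
#' @export
writeProductionTable <- function(table, path) {
    utils::write.csv(table, path, row.names = FALSE, quote = TRUE)
    invisible(path)
}

#' Map raw country x crop production to region x category
#'
#' Aggregates a FAOSTAT-style table (country, raw crop, year, production,
#' harvested area) onto the reporting regions and the fixed crop-category
#' vocabulary, summing within (region, category, year). Raw crops mapped to
#' the reserved category \code{"DROP"} are dropped explicitly; in strict
#' mode any raw crop or country missing from the mappings is an error
#' listing the offenders, in lenient mode such rows are dropped and
#' reported. Total tonnage is conserved minus the explicitly dropped rows.
#'
#' @param raw Data.frame \code{country, crop, year, production_t,
#'   harvested_area_ha}.
#' @param cropMapping Data.frame \code{crop, category} (raw crop to
#'   category; category \code{"DROP"} discards).
#' @param regionLookup Data.frame \code{country, region}.
#' @param strict Error on unmapped rows (default) instead of dropping.
#' @return Production table (region, crop, year, production_t,
#'   harvested_area_ha); attribute \code{"dropped"} reports the number of
#'   dropped rows and their tonnage.
#' @export
mapProduction <- function(raw, cropMapping, regionLookup, strict = TRUE) {
    if (any(raw$production_t < 0, na.rm = TRUE))
        stop("negative production")
    cat <- cropMapping$category[match(raw$crop, cropMapping$crop)]
    reg <- regionLookup$region[match(raw$country, regionLookup$country)]
    unmappedCrop <- is.na(cat)
    unmappedRegion <- is.na(reg)
    if (strict) {
        if (any(unmappedCrop))
            stop("unmapped crops: ",
                 paste(sort(unique(raw$crop[unmappedCrop])), collapse = ", "))
        if (any(unmappedRegion))
            stop("unmapped countries: ",
                 paste(sort(unique(raw$country[unmappedRegion])), collapse = ", "))
    }
    drop <- unmappedCrop | unmappedRegion | (!is.na(cat) & cat == "DROP")
    dropped <- list(rows = sum(drop), production_t = sum(raw$production_t[drop]))
    keep <- raw[!drop, , drop = FALSE]
    cat <- cat[!drop]; reg <- reg[!drop]
    bad <- setdiff(unique(cat), cropCategories())
    if (length(bad))
        stop("mapping targets outside the category vocabulary: ",
             paste(bad, collapse = ", "))
    if (!nrow(keep)) {
        out <- data.frame(region = character(), crop = character(),
                          year = integer(), production_t = numeric(),
                          harvested_area_ha = numeric())
    } else {
        out <- stats::aggregate(
            cbind(production_t, harvested_area_ha) ~ region + crop + year,
            data = data.frame(region = reg, crop = cat, year = keep$year,
                              production_t = keep$production_t,
                              harvested_area_ha = keep$harvested_area_ha),
            FUN = sum)
        out <- out[order(out$year, out$region, out$crop), , drop = FALSE]
        rownames(out) <- NULL
    }
    attr(out, "dropped") <- dropped
    out
}
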