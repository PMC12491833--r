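test_that("every layer type survives a NetCDF round trip", {
    w <- generateWorld(worldConfig())
    d <- withr::local_tempdir()
    lu2 <- {
        writeLayer(w$landUse, file.path(d, "lu.nc"), "land_use")
        readLayer(file.path(d, "lu.nc"), "land_use")
    }
    expect_equal(classMap(lu2), classMap(w$landUse))
    expect_equal(stepYears(lu2), stepYears(w$landUse))
    fr2 <- {
        writeLayer(w$fractions, file.path(d, "fr.nc"), "crop_fraction")
        readLayer(file.path(d, "fr.nc"), "crop_fraction")
    }
    expect_equal(cropFractions(fr2), cropFractions(w$fractions))
    de2 <- {
        writeLayer(w$density, file.path(d, "de.nc"), "carbon_density")
        readLayer(file.path(d, "de.nc"), "carbon_density")
    }
    expect_equal(carbonDensity(de2), carbonDensity(w$density))
    expect_equal(de2@pool, "aboveground")
    rm2 <- {
        writeLayer(w$regions, file.path(d, "rm.nc"), "region")
        readLayer(file.path(d, "rm.nc"), "region")
    }
    expect_equal(regionIds(rm2), regionIds(w$regions))
    expect_equal(regionNames(rm2), regionNames(w$regions))
    ml <- w$management[[1]]
    ml2 <- {
        writeLayer(ml, file.path(d, "ml.nc"), "emission")
        readLayer(file.path(d, "ml.nc"), "emission")
    }
    expect_equal(layerValues(ml2), layerValues(ml))
    expect_equal(ml2@sourceId, ml@sourceId)
    expect_equal(ml2@gas, ml@gas)
})

test_that("missing variables and invariant violations are rejected on read", {
    w <- generateWorld(worldConfig())
    d <- withr::local_tempdir()
    p <- file.path(d, "lu.nc")
    writeLayer(w$landUse, p, "land_use")
    expect_error(readLayer(p, "no_such_var"), "format error")
    expect_error(readLayer(file.path(d, "absent.nc"), "x"), "no such file")
    # corrupt one cell to a class id outside the 20-entry vocabulary
    nc <- ncdf4::nc_open(p, write = TRUE)
    ncdf4::ncvar_put(nc, "land_use", 25L, start = c(1, 1, 1),
                     count = c(1, 1, 1))
    ncdf4::nc_close(nc)
    expect_error(readLayer(p, "land_use"), "25")
})

test_that("a world re-read from disk reproduces the pipeline output", {
    w <- generateWorld(worldConfig(randomTransitionRate = 0.04, seed = 8))
    d <- withr::local_tempdir()
    writeWorld(w, d)
    w2 <- readWorld(d)
    a <- runAttribution(w)$ledger
    b <- runAttribution(w2)$ledger
    expect_lt(ledgerMaxRelErr(a, b), 1e-12)
})

test_that("production mapping aggregates, conserves and reports drops", {
    raw <- data.frame(
        country = c("A", "B", "A", "C", "C"),
        crop = c("Wheat", "Wheat", "Durum wheat", "Oil palm fruit",
                 "Coffee, green"),
        year = 2000L,
        production_t = c(10, 20, 5, 7, 3),
        harvested_area_ha = c(4, 8, 2, 1, 1))
    cm <- data.frame(crop = c("Wheat", "Durum wheat", "Oil palm fruit",
                              "Coffee, green"),
                     category = c("wheat", "wheat", "palm oil", "DROP"))
    rl <- data.frame(country = c("A", "B", "C"),
                     region = c("r1", "r1", "r2"))
    out <- mapProduction(raw, cm, rl)
    # two countries in one region sum; two raw crops merge into one category
    expect_equal(out$production_t[out$region == "r1" & out$crop == "wheat"],
                 35)
    expect_equal(out$production_t[out$region == "r2" &
                                      out$crop == "palm oil"], 7)
    # tonnage conserved minus the explicit drop
    expect_equal(sum(out$production_t),
                 sum(raw$production_t) - attr(out, "dropped")$production_t)
    expect_equal(attr(out, "dropped")$rows, 1)
    # row order cannot matter
    shuf <- raw[c(4, 2, 5, 1, 3), ]
    expect_equal(mapProduction(shuf, cm, rl), out, ignore_attr = TRUE)
    # strict mode lists offenders
    raw2 <- rbind(raw, data.frame(country = "A", crop = "Yams", year = 2000L,
                                  production_t = 1, harvested_area_ha = 1))
    expect_error(mapProduction(raw2, cm, rl), "Yams")
    lenient <- mapProduction(raw2, cm, rl, strict = FALSE)
    expect_equal(sum(lenient$production_t), sum(out$production_t))
})
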