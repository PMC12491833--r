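mkLayer <- function(vals, sourceId, gas, g, cropSpecific = FALSE,
                    steps = seq(1975L, by = 5L,
                                length.out = dim(vals)[length(dim(vals))])) {
    new("ManagementLayer", geometry = g, steps = steps,
        sourceId = as.integer(sourceId), gas = gas, values = vals,
        cropSpecific = cropSpecific,
        categories = if (cropSpecific) cropCategories() else character())
}

test_that("CO2-eq conversion applies the configured GWP and is linear", {
    g <- gridGeometry(1, 1, resolution = 1)
    ch4 <- mkLayer(array(1, c(1, 1, 1)), 7, "CH4", g)
    expect_error(toCO2eq(ch4, lucConstants()), NA)
    # crop-specific check needs the 4-d shape for source 7; use source 2/3
    ch4b <- mkLayer(array(1, c(1, 1, 1)), 2, "CH4", g)
    n2o <- mkLayer(array(2, c(1, 1, 1)), 3, "N2O", g)
    co2 <- mkLayer(array(5, c(1, 1, 1)), 2, "CO2", g)
    expect_equal(as.vector(toCO2eq(ch4b, lucConstants())), 28)
    expect_equal(as.vector(toCO2eq(n2o, lucConstants())), 530)
    expect_equal(as.vector(toCO2eq(co2, lucConstants())), 5)
    # custom factors pass straight through
    k <- lucConstants(gwp = c(CO2 = 1, CH4 = 56, N2O = 100))
    expect_equal(as.vector(toCO2eq(ch4b, k)), 56)
    # linearity: converting a summed layer equals summing conversions
    expect_equal(toCO2eq(ch4b, k) + toCO2eq(co2, k),
                 layerValues(ch4b) * 56 + layerValues(co2))
})

test_that("residue split is proportional and conserves mass", {
    nCat <- length(cropCategories())
    bulk <- array(100, c(1, 1, 1))
    res <- array(0, c(1, 1, nCat, 1))
    res[1, 1, 1, 1] <- 3; res[1, 1, 2, 1] <- 1   # 3:1 between two crops
    sp <- splitByResidue(bulk, res)
    expect_equal(sp[1, 1, 1, 1], 75)
    expect_equal(sp[1, 1, 2, 1], 25)
    # single crop with residue receives everything
    res1 <- array(0, c(1, 1, nCat, 1)); res1[1, 1, 5, 1] <- 2
    expect_equal(splitByResidue(bulk, res1)[1, 1, 5, 1], 100)
    # conservation on random fields
    set.seed(21)
    bulkR <- array(runif(3 * 3 * 2, 0, 50), c(3, 3, 2))
    resR <- array(runif(3 * 3 * nCat * 2), c(3, 3, nCat, 2))
    spR <- splitByResidue(bulkR, resR)
    expect_equal(apply(spR, c(1, 2, 4), sum), bulkR)
})

test_that("zero-residue cells under positive mass use the crop-fraction fallback", {
    nCat <- length(cropCategories())
    g <- gridGeometry(1, 1, resolution = 1)
    bulk <- array(60, c(1, 1, 1))
    res <- array(0, c(1, 1, nCat, 1))
    fr <- array(0, c(1, 1, nCat, 2))
    fr[1, 1, 3, 2] <- 0.2; fr[1, 1, 7, 2] <- 0.1
    fr[1, 1, nCat, 2] <- 0.5  # pasture must not receive the fallback
    fractions <- new("CropFractionSeries", geometry = g,
                     steps = c(1970L, 1975L), fraction = fr,
                     categories = cropCategories())
    sp <- splitByResidue(bulk, res, fractions)
    expect_equal(sp[1, 1, 3, 1], 40)
    expect_equal(sp[1, 1, 7, 1], 20)
    expect_equal(sp[1, 1, nCat, 1], 0)
    expect_error(splitByResidue(bulk, res, fractions, fallback = "error"),
                 "residue")
})

test_that("routing merges sources 1-3, splits 4, passes 5-7, conserving mass", {
    w <- generateWorld(worldConfig())
    routed <- routeSources(w$management, w$fractions, w$residues)
    expect_setequal(names(routed$lucPool),
                    c("clearing_n2o", "peat", "manure"))
    expect_setequal(names(routed$cropResolved),
                    c("residues", "synthetic_fertilizer", "waste_burning",
                      "rice_ch4"))
    inTotal <- sum(vapply(w$management, function(l)
        sum(toCO2eq(l, lucConstants())), numeric(1)))
    outTotal <- sum(vapply(routed$lucPool, sum, numeric(1))) +
        sum(vapply(routed$cropResolved, sum, numeric(1)))
    expect_equal(outTotal, inTotal)
    expect_equal(routed$totalCO2eq, inTotal)
    # wetland-rice CH4 stays on the rice category
    rice <- routed$cropResolved$rice_ch4
    riceIdx <- match("rice", cropCategories())
    expect_true(all(rice[, , -riceIdx, ] == 0))
    expect_gt(sum(rice[, , riceIdx, ]), 0)
})

test_that("a source-7 layer with mass outside rice is rejected", {
    g <- gridGeometry(1, 1, resolution = 1)
    nCat <- length(cropCategories())
    vals <- array(0, c(1, 1, nCat, 1))
    vals[1, 1, 1, 1] <- 5  # wheat, not rice
    bad <- mkLayer(vals, 7, "CH4", g, cropSpecific = TRUE)
    fr <- new("CropFractionSeries", geometry = g, steps = c(1970L, 1975L),
              fraction = array(0, c(1, 1, nCat, 2)),
              categories = cropCategories())
    expect_error(routeSources(list(bad), fr), "rice")
})

test_that("gases without a configured GWP are refused", {
    expect_error(lucConstants(gwp = c(CO2 = 1, CH4 = -2, N2O = 265)), "> 0")
    g <- gridGeometry(1, 1, resolution = 1)
    l <- mkLayer(array(1, c(1, 1, 1)), 3, "N2O", g)
    k <- lucConstants()
    k$gwp <- k$gwp[c("CO2", "CH4")]
    expect_error(toCO2eq(l, k), "GWP")
})
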