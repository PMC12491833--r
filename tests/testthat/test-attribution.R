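test_that("weights are proportional to positive fraction increases", {
    cats <- cropCategories()
    prev <- setNames(rep(0, 17), cats)
    now <- prev
    now["maize"] <- 0.2; now["soybeans"] <- 0.1
    prev["wheat"] <- 0.3; now["wheat"] <- 0.2  # a decrease never counts
    w <- attributionWeights(prev, now)
    expect_equal(unname(w[match("maize", cats)]), 2 / 3)
    expect_equal(unname(w[match("soybeans", cats)]), 1 / 3)
    expect_equal(unname(w[match("wheat", cats)]), 0)
    expect_equal(sum(w), 1)
    # single expanding category takes everything
    w1 <- attributionWeights(rep(0, 17), replace(rep(0, 17), 13, 0.4))
    expect_equal(w1[13], 1)
})

test_that("fallbacks: current fractions, then the unallocated bucket", {
    now <- rep(0, 17); now[2] <- 0.5; now[1] <- 0.5
    w <- attributionWeights(now, now)  # no category increased
    expect_equal(w[1], 0.5)
    expect_equal(w[2], 0.5)
    w0 <- attributionWeights(rep(0, 17), rep(0, 17))
    expect_true(all(w0 == 0))
    expect_true(attr(w0, "unallocated"))
})

test_that("cell allocation conserves mass and rejects sequestration", {
    w <- c(2 / 3, 1 / 3)
    expect_equal(attributeCell(300, w), c(200, 100))
    expect_equal(attributeCell(0, w), c(0, 0))
    expect_error(attributeCell(-5, w), "sequestration")
    set.seed(31)
    for (i in 1:25) {
        raw <- runif(17)
        ww <- raw / sum(raw)
        mass <- runif(1, 0, 1e6)
        expect_equal(sum(attributeCell(mass, ww)), mass)
    }
})

test_that("a minimal one-cell world books exactly the closed-form CO2", {
    cfg <- worldConfig(
        nLat = 1, nLon = 1, regionNames = "r1",
        initialClasses = matrix(7L, 1, 1),
        schedule = list(list(row = 1, col = 1, step_end = 1975L,
                             to_class = 1L, alloc = c("maize" = 0.5))),
        managementRates = data.frame(source_id = integer(),
                                     gas = character(), rate = numeric(),
                                     basis = character()),
        soil = FALSE)
    w <- generateWorld(cfg)
    res <- runAttribution(w)
    led <- res$ledger
    expect_equal(nrow(led), 1)
    a <- cellAreas(w$geometry)[1, 1]
    expect_equal(led$co2eq_t, (15000 - 500) * a * 44 / 12)
    expect_equal(led$crop, "maize")
    expect_equal(led$source, "luc_natural_to_agriculture")
    expect_equal(led$region, "r1")
    expect_equal(led$step_end, 1975)
})

test_that("region labels only permute the ledger rows", {
    cfg <- worldConfig()
    w <- generateWorld(cfg)
    res1 <- runAttribution(w)
    w2 <- w
    w2$regions <- new("RegionMap", geometry = w$geometry,
                      regionId = regionIds(w$regions),
                      regionNames = c("zulu", "alpha", "mike"))
    res2 <- runAttribution(w2)
    relab <- res2$ledger
    relab$region <- c(zulu = "region_1", alpha = "region_2",
                      mike = "region_3")[relab$region]
    expect_equal(ledgerMaxRelErr(res1$ledger, relab), 0)
})

test_that("vectorized ledger equals the per-cell per-crop brute force", {
    for (seed in c(2, 9)) {
        w <- generateWorld(worldConfig(randomTransitionRate = 0.06,
                                       densityJitterSd = 0.1, seed = seed))
        res <- runAttribution(w)
        bf <- bruteForceLedger(w)
        expect_lt(ledgerMaxRelErr(res$ledger, bf), 1e-9)
    }
})

test_that("pasture can take LUC attribution but no crop-management source", {
    w <- generateWorld(worldConfig())
    led <- runAttribution(w)$ledger
    past <- led[led$crop == "pasture", ]
    expect_gt(sum(past$co2eq_t[past$source == "luc_natural_to_agriculture"]),
              0)
    cropOnly <- c("residues", "synthetic_fertilizer", "waste_burning",
                  "rice_ch4")
    expect_equal(sum(past$co2eq_t[past$source %in% cropOnly]), 0)
})

test_that("adding an emission event never decreases any ledger total", {
    cfg <- worldConfig()
    w <- generateWorld(cfg)
    base <- runAttribution(w)$ledger
    cfg2 <- cfg
    cfg2$schedule <- c(cfg$schedule,
                       list(list(row = 12, col = 12, step_end = 2015L,
                                 to_class = 1L, alloc = c("wheat" = 0.5))))
    more <- runAttribution(generateWorld(cfg2))$ledger
    key <- c("region", "crop", "step_start", "step_end", "source")
    m <- merge(base, more, by = key, all.x = TRUE)
    expect_true(all(m$co2eq_t.y >= m$co2eq_t.x - 1e-9 * abs(m$co2eq_t.x)))
})
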