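mkLandUse <- function(maps, g = gridGeometry(dim(maps)[1], dim(maps)[2]),
                      steps = seq(1970L, by = 5L,
                                  length.out = dim(maps)[3])) {
    new("LandUseSeries", geometry = g, steps = steps, classMap = maps,
        classes = landUseClasses())
}

test_that("unchanged maps yield no events; a scripted change yields one", {
    maps <- array(7L, c(3, 3, 3))
    expect_equal(nrow(detectTransitions(mkLandUse(maps))), 0)
    maps[2, 3, 2:3] <- 1L  # forest -> cropland at the second step
    ev <- detectTransitions(mkLandUse(maps))
    expect_equal(nrow(ev), 1)
    expect_equal(ev$from_class, 7L)
    expect_equal(ev$to_class, 1L)
    expect_equal(ev$step_end, 1975L)
    expect_equal(ev$row, 2L)
    expect_equal(ev$col, 3L)
})

test_that("vectorized detection equals the per-cell loop on random worlds", {
    for (seed in c(3, 14)) {
        w <- generateWorld(worldConfig(randomTransitionRate = 0.08,
                                       seed = seed))
        ev <- detectTransitions(w$landUse)
        bf <- bruteForceEvents(w$landUse)
        key <- function(d) paste(d$row, d$col, d$step_end, d$from_class,
                                 d$to_class)
        expect_equal(nrow(ev), nrow(bf))
        expect_setequal(key(ev), key(bf))
    }
})

test_that("taxonomy covers every pair once and classifies the canon cases", {
    tx <- defaultTaxonomy()
    expect_equal(nrow(tx), 20 * 19)
    expect_equal(anyDuplicated(paste(tx$from_class, tx$to_class)), 0)
    cls <- landUseClasses()
    id <- function(nm) cls$id[cls$name == nm]
    ev <- data.frame(row = 1L, col = 1L, step_start = 1970L,
                     step_end = 1975L,
                     from_class = c(id("tropical forest"), id("cropland"),
                                    id("cropland"), id("savanna"),
                                    id("tropical forest"),
                                    id("tropical forest")),
                     to_class = c(id("cropland"),
                                  id("intensive grassland"),
                                  id("regrowth forest (abandoning)"),
                                  id("extensive grassland"),
                                  id("biofuel cropland"),
                                  id("tropical woodland")),
                     area_ha = 1)
    cl <- classifyTransitions(ev, tx)
    expect_equal(cl$category, c(2L, 5L, 6L, 4L, 3L, 1L))
    expect_equal(cl$attributable, c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE))
})

test_that("strict mode rejects pairs missing from the taxonomy", {
    tx <- defaultTaxonomy()
    txCut <- tx[!(tx$from_class == 7 & tx$to_class == 1), ]
    ev <- data.frame(row = 1L, col = 1L, step_start = 1970L,
                     step_end = 1975L, from_class = 7L, to_class = 1L,
                     area_ha = 1)
    expect_error(classifyTransitions(ev, txCut, strict = TRUE),
                 "unclassified")
    lenient <- classifyTransitions(ev, txCut, strict = FALSE)
    expect_true(is.na(lenient$category))
    expect_false(lenient$attributable)
})

test_that("attached carbon carries the 44/12 CO2 and the sign rule", {
    g <- gridGeometry(1, 1, resolution = 1)
    steps <- c(1970L, 1975L)
    mk <- function(dcVal) new("StockChangeGrid", geometry = g,
                              steps = 1975L,
                              deltaC = array(dcVal, c(1, 1, 1)))
    ev <- data.frame(row = 1L, col = 1L, step_start = 1970L,
                     step_end = 1975L, from_class = 7L, to_class = 1L,
                     area_ha = 100, category = 2L, attributable = TRUE)
    out <- attachCarbon(ev, mk(765000))
    expect_equal(out$co2_t, 765000 * 44 / 12)  # 2,805,000
    expect_equal(out$kind, "emission")
    expect_equal(attachCarbon(ev, mk(-100))$kind, "sequestration")
    zero <- attachCarbon(ev, mk(0))
    expect_equal(zero$co2_t, 0)
    expect_equal(zero$kind, "emission")  # zero-loss boundary
})

test_that("flow table conserves area and counts unique transitions", {
    empty <- transitionMatrix(detectTransitions(
        mkLandUse(array(9L, c(2, 2, 2)))))
    expect_equal(nrow(empty$flows), 0)
    expect_equal(empty$uniqueTransitions, 0)

    w <- generateWorld(worldConfig(randomTransitionRate = 0.1, seed = 5))
    ev <- detectTransitions(w$landUse)
    tm <- transitionMatrix(ev)
    expect_equal(sum(tm$flows$area_ha), sum(ev$area_ha))
    expect_equal(tm$uniqueTransitions,
                 nrow(unique(ev[c("from_class", "to_class")])))
    # outflow per class and step equals the area of cells leaving it
    for (s in unique(ev$step_end)) {
        for (f in unique(ev$from_class[ev$step_end == s])) {
            expect_equal(
                sum(tm$flows$area_ha[tm$flows$step_end == s &
                                         tm$flows$from_class == f]),
                sum(ev$area_ha[ev$step_end == s & ev$from_class == f]))
        }
    }
})

test_that("class ids outside the vocabulary are rejected", {
    maps <- array(7L, c(2, 2, 2))
    maps[1, 1, 2] <- 25L
    expect_error(mkLandUse(maps), "25")
})
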