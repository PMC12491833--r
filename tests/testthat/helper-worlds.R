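# Independent oracles and world builders shared by the tests. The oracles
# are deliberately written as naive per-cell / per-crop loops, separate
# from both the vectorized pipeline and the config-based closed form.

# per-cell double-loop transition detection
bruteForceEvents <- function(lu) {
    cm <- classMap(lu)
    steps <- stepYears(lu)
    areaHa <- cellAreas(geometry(lu)) * 100
    out <- list()
    for (k in 2:length(steps)) {
        for (r in seq_len(dim(cm)[1])) {
            for (c in seq_len(dim(cm)[2])) {
                a <- cm[r, c, k - 1]; b <- cm[r, c, k]
                if (!is.na(a) && !is.na(b) && a != b) {
                    out[[length(out) + 1]] <- data.frame(
                        row = r, col = c, step_start = steps[k - 1],
                        step_end = steps[k], from_class = a, to_class = b,
                        area_ha = areaHa[r, c])
                }
            }
        }
    }
    if (!length(out))
        return(data.frame(row = integer(), col = integer(),
                          step_start = integer(), step_end = integer(),
                          from_class = integer(), to_class = integer(),
                          area_ha = numeric()))
    do.call(rbind, out)
}

# naive per-cell, per-crop ledger from the generated world arrays
bruteForceLedger <- function(world, constants = lucConstants(),
                             taxonomy = defaultTaxonomy()) {
    g <- world$geometry
    cm <- classMap(world$landUse)
    fr <- cropFractions(world$fractions)
    dens <- carbonDensity(world$density)
    steps <- stepYears(world$landUse)
    areaKm2 <- cellAreas(g)
    cats <- cropCategories()
    rid <- regionIds(world$regions)
    rnames <- regionNames(world$regions)
    txKey <- paste(taxonomy$from_class, taxonomy$to_class)
    srcTab <- emissionSources()
    rows <- list()
    book <- function(r, c, k, crop, source, t) {
        if (t <= 0) return()
        rows[[length(rows) + 1]] <<- data.frame(
            region = rnames[rid[r, c]], crop = crop,
            step_start = steps[k], step_end = steps[k + 1],
            source = source, co2eq_t = t)
    }
    weightsAt <- function(r, c, k) {
        # increase-proportional with the two fallbacks, written out plainly
        prev <- fr[r, c, , k]; now <- fr[r, c, , k + 1]
        inc <- now - prev
        inc[inc < 0] <- 0
        if (sum(inc) > 0) return(list(w = inc / sum(inc), unalloc = FALSE))
        if (sum(now) > 0) return(list(w = now / sum(now), unalloc = FALSE))
        list(w = rep(0, length(cats)), unalloc = TRUE)
    }
    bookW <- function(r, c, k, source, mass) {
        wt <- weightsAt(r, c, k)
        if (wt$unalloc) {
            book(r, c, k, "unallocated", source, mass)
        } else {
            for (ci in seq_along(cats))
                if (wt$w[ci] > 0)
                    book(r, c, k, cats[ci], source, mass * wt$w[ci])
        }
    }
    nPair <- length(steps) - 1
    for (k in seq_len(nPair)) {
        for (r in seq_len(g@nLat)) for (c in seq_len(g@nLon)) {
            from <- cm[r, c, k]; to <- cm[r, c, k + 1]
            if (!is.na(from) && !is.na(to) && from != to) {
                cat6 <- taxonomy$category[match(paste(from, to), txKey)]
                if (!is.na(cat6) && cat6 %in% c(2, 5)) {
                    dC <- (dens[r, c, k] - dens[r, c, k + 1]) * areaKm2[r, c]
                    co2 <- dC * constants$co2PerC
                    if (co2 > 0) {
                        src <- if (cat6 == 2) "luc_natural_to_agriculture"
                               else "luc_agricultural_transitions"
                        bookW(r, c, k, src, co2)
                    }
                }
            }
            for (l in world$management) {
                gwpF <- constants$gwp[[l@gas]]
                nm <- srcTab$source[match(l@sourceId, srcTab$management_id)]
                if (l@sourceId %in% 1:3) {
                    mass <- layerValues(l)[r, c, k] * gwpF
                    if (mass > 0) bookW(r, c, k, nm, mass)
                } else if (l@sourceId == 4) {
                    mass <- layerValues(l)[r, c, k] * gwpF
                    if (mass > 0) {
                        shares <- world$residues[r, c, , k]
                        if (sum(shares) <= 0) {
                            shares <- fr[r, c, , k + 1]
                            shares[match("pasture", cats)] <- 0
                        }
                        shares <- shares / sum(shares)
                        for (ci in seq_along(cats))
                            if (shares[ci] > 0)
                                book(r, c, k, cats[ci], nm, mass * shares[ci])
                    }
                } else {
                    for (ci in seq_along(cats)) {
                        mass <- layerValues(l)[r, c, ci, k] * gwpF
                        if (mass > 0) book(r, c, k, cats[ci], nm, mass)
                    }
                }
            }
        }
    }
    if (!length(rows))
        return(data.frame(region = character(), crop = character(),
                          step_start = integer(), step_end = integer(),
                          source = character(), co2eq_t = numeric()))
    out <- do.call(rbind, rows)
    aggregate(co2eq_t ~ region + crop + step_start + step_end + source,
              data = out, FUN = sum)
}

# compare two ledgers entry-by-entry on the full key
ledgerMaxRelErr <- function(a, b) {
    key <- c("region", "crop", "step_start", "step_end", "source")
    m <- merge(a, b, by = key, all = TRUE)
    x <- ifelse(is.na(m$co2eq_t.x), 0, m$co2eq_t.x)
    y <- ifelse(is.na(m$co2eq_t.y), 0, m$co2eq_t.y)
    if (!nrow(m)) return(0)
    max(abs(x - y) / pmax(pmax(abs(x), abs(y)), 1e-12))
}

# scripted configs of varying size/schedule for the equivalence sweep;
# randomness only chooses the script, the resulting config is fully scripted
randomScriptedConfig <- function(seed, nLat = 12, nLon = 12) {
    set.seed(seed)
    steps <- seq(1970L, 2020L, by = 5L)
    cls <- landUseClasses()
    naturalIds <- cls$id[cls$group %in% c("natural", "extensive")]
    init <- matrix(sample(c(7L, 8L, 9L, 10L, 11L), nLat * nLon,
                          replace = TRUE), nLat, nLon)
    nAgri <- max(2L, round(0.05 * nLat * nLon))
    agriCells <- sample(nLat * nLon, nAgri)
    init[agriCells] <- sample(c(1L, 2L), nAgri, replace = TRUE)
    crops <- c("wheat", "rice", "maize", "soybeans", "palm oil")
    nSched <- sample(5:15, 1)
    free <- setdiff(seq_len(nLat * nLon), agriCells)
    cells <- sample(free, nSched)
    sched <- lapply(seq_len(nSched), function(i) {
        r <- (cells[i] - 1L) %% nLat + 1L
        c <- (cells[i] - 1L) %/% nLat + 1L
        to <- sample(c(1L, 2L, 3L, 4L, 5L), 1,
                     prob = c(0.4, 0.25, 0.1, 0.15, 0.1))
        alloc <- NULL
        if (to %in% c(1L, 3L)) {
            w <- runif(length(crops))
            alloc <- setNames(w / sum(w) * runif(1, 0.5, 0.95), crops)
        } else if (to == 2L) {
            alloc <- c("pasture" = runif(1, 0.5, 0.95))
        }
        list(row = r, col = c, step_end = sample(steps[-1], 1),
             to_class = to, alloc = alloc)
    })
    worldConfig(nLat = nLat, nLon = nLon, steps = steps,
                initialClasses = init, schedule = sched, seed = seed)
}
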