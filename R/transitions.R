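#' Transition taxonomy: six categories over class pairs
#'
#' Every ordered pair of distinct land-use classes maps to exactly one of
#' six transition categories: (1) natural vegetation transitions,
#' (2) natural vegetation to agriculture, (3) natural vegetation to
#' biofuel, (4) natural vegetation to extensive grassland,
#' (5) agricultural transitions, (6) land abandonment to natural
#' vegetation. Only categories 2 and 5 are attributable to crops; biomass
#' carbon changes of the other categories are tracked but never allocated.
#'
#' The taxonomy is data, not code: a delimited table with columns
#' \code{from_class,to_class,category,attributable}. The shipped default
#' (\code{defaultTaxonomy()}) covers all 380 ordered pairs of the 20-class
#' vocabulary, derived from the class groups: conversions out of extensive
#' grassland into cropland/pasture count as category 2 (and into biofuel as
#' category 3), while flows from agriculture into extensive grassland or
#' natural classes are abandonment (category 6).
#'
#' @param path Delimited taxonomy file.
#' @return A data.frame with the four columns above; attribute
#'   \code{"vocabulary"} holds the class table.
#' @seealso [classifyTransitions()]
#' @export
readTaxonomy <- function(path) {
    tx <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("from_class", "to_class", "category", "attributable")
    if (!all(need %in% names(tx)))
        stop("taxonomy must have columns ", paste(need, collapse = ","))
    tx$attributable <- as.logical(tx$attributable)
    key <- paste(tx$from_class, tx$to_class)
    if (anyDuplicated(key))
        stop("taxonomy maps some (from,to) pair to more than one category")
    if (any(tx$from_class == tx$to_class))
        stop("taxonomy must not contain identity pairs")
    bad <- tx$attributable != (tx$category %in% c(2L, 5L))
    if (any(bad))
        stop("attributable flag must be TRUE exactly for categories 2 and 5")
    attr(tx, "vocabulary") <- landUseClasses()
    tx
}

#' @rdname readTaxonomy
#' @export
defaultTaxonomy <- function() {
    readTaxonomy(system.file("extdata", "default_taxonomy.csv",
                             package = "lucattr", mustWork = TRUE))
}

#' Names of the six transition categories
#' @return Character vector indexed by category id 1..6.
#' @export
transitionCategories <- function() {
    c("natural vegetation transitions",
      "natural vegetation to agriculture",
      "natural vegetation to biofuel",
      "natural vegetation to extensive grassland",
      "agricultural transitions",
      "land abandonment to natural vegetation")
}

#' Detect per-cell land-use transitions
#'
#' One event per (cell, consecutive step pair) whose dominant class
#' changed; unchanged cells and cells that are NA in either step produce no
#' event. The event's area is the full cell area (dominant-class
#' convention), in hectares.
#'
#' @param lu A \linkS4class{LandUseSeries} with at least two steps.
#' @return A data.frame with columns \code{row}, \code{col},
#'   \code{step_start}, \code{step_end}, \code{from_class},
#'   \code{to_class}, \code{area_ha}.
#' @export
detectTransitions <- function(lu) {
    stopifnot(is(lu, "LandUseSeries"))
    validObject(lu)
    n <- length(lu@steps)
    if (n < 2L) stop("at least two steps required to detect transitions")
    areaHa <- cellAreas(lu@geometry) * 100   # km2 -> ha
    out <- vector("list", n - 1L)
    for (k in 2:n) {
        prev <- lu@classMap[, , k - 1L, drop = FALSE]
        dim(prev) <- dim(prev)[1:2]
        cur <- lu@classMap[, , k, drop = FALSE]
        dim(cur) <- dim(cur)[1:2]
        idx <- which(!is.na(prev) & !is.na(cur) & prev != cur,
                     arr.ind = TRUE)
        if (nrow(idx) == 0L) next
        out[[k - 1L]] <- data.frame(
            row = idx[, 1L], col = idx[, 2L],
            step_start = lu@steps[k - 1L], step_end = lu@steps[k],
            from_class = prev[idx], to_class = cur[idx],
            area_ha = areaHa[idx]
        )
    }
    out <- do.call(rbind, out)
    if (is.null(out))
        out <- data.frame(row = integer(), col = integer(),
                          step_start = integer(), step_end = integer(),
                          from_class = integer(), to_class = integer(),
                          area_ha = numeric())
    rownames(out) <- NULL
    out
}

#' Classify transition events into the six categories
#'
#' Joins each event's (from, to) pair against a taxonomy table, adding
#' \code{category} (1..6) and \code{attributable} (TRUE only for categories
#' 2 and 5).
#'
#' @param events Event table from [detectTransitions()].
#' @param taxonomy Taxonomy from [readTaxonomy()]/[defaultTaxonomy()].
#' @param strict If TRUE (default), an unlisted (from, to) pair is an
#'   error; if FALSE it gets \code{category = NA} and
#'   \code{attributable = FALSE} (the "unclassified" bucket).
#' @return \code{events} with \code{category} and \code{attributable}
#'   columns added.
#' @export
classifyTransitions <- function(events, taxonomy = defaultTaxonomy(),
                                strict = TRUE) {
    if (nrow(events) && any(events$from_class == events$to_class))
        stop("events must have from_class != to_class")
    m <- match(paste(events$from_class, events$to_class),
               paste(taxonomy$from_class, taxonomy$to_class))
    if (strict && anyNA(m)) {
        bad <- unique(paste0(events$from_class[is.na(m)], "->",
                             events$to_class[is.na(m)]))
        stop("unclassified transitions: ", paste(bad, collapse = ", "))
    }
    events$category <- taxonomy$category[m]
    events$attributable <- taxonomy$attributable[m]
    events$attributable[is.na(events$attributable)] <- FALSE
    events
}

#' Attach carbon-stock change to transition events
#'
#' Reads the per-cell stock difference at each event's cell and step pair,
#' converts it to CO2, and labels the event an emission (stock loss,
#' \code{delta_c >= 0}) or sequestration (stock gain) event. The whole cell
#' difference is assigned to the cell's single event (dominant-class
#' convention, no sub-cell apportionment). Cells whose class did not change
#' contribute no event regardless of their stock change.
#'
#' @param events Classified event table.
#' @param dc A \linkS4class{StockChangeGrid}.
#' @param geometry Frame check against \code{dc} (optional).
#' @param constants [lucConstants()].
#' @return \code{events} with \code{delta_c_mg} (Mg C, positive = loss),
#'   \code{co2_t} (t CO2, same sign) and \code{kind} columns.
#' @export
attachCarbon <- function(events, dc, geometry = NULL,
                         constants = lucConstants()) {
    stopifnot(is(dc, "StockChangeGrid"))
    if (!is.null(geometry)) .assertFrame(dc@geometry, geometry, "frames")
    k <- match(events$step_end, dc@steps)
    if (nrow(events) && anyNA(k))
        stop("events reference step pairs absent from the stock-change grid")
    ii <- cbind(events$row, events$col, k)
    events$delta_c_mg <- if (nrow(events)) dc@deltaC[ii] else numeric()
    events$co2_t <- cToCO2(events$delta_c_mg, constants)  # Mg CO2 == t CO2
    events$kind <- ifelse(events$delta_c_mg >= 0, "emission", "sequestration")
    events
}

#' Land-use flow table and unique-transition count
#'
#' Aggregates event areas into a (from class, to class, step) flow table
#' suitable for Sankey-style plotting, and counts the distinct (from, to)
#' pairs observed over the whole series.
#'
#' @param events Event table (any stage).
#' @return List with \code{flows} (data.frame \code{from_class},
#'   \code{to_class}, \code{step_end}, \code{area_ha}) and
#'   \code{uniqueTransitions} (integer count).
#' @export
transitionMatrix <- function(events) {
    if (nrow(events) == 0L)
        return(list(flows = data.frame(from_class = integer(),
                                       to_class = integer(),
                                       step_end = integer(),
                                       area_ha = numeric()),
                    uniqueTransitions = 0L))
    flows <- stats::aggregate(area_ha ~ from_class + to_class + step_end,
                              data = events, FUN = sum)
    flows <- flows[order(flows$step_end, flows$from_class, flows$to_class), ]
    rownames(flows) <- NULL
    list(flows = flows,
         uniqueTransitions = nrow(unique(events[c("from_class", "to_class")])))
}
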