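# Analog series = connected components of the compound-RMMP graph.

#' Extract analog series
#'
#' Builds the compound-RMMP relationship graph and returns its connected
#' components with at least `minSeriesSize` members as analog series.
#' Compounds participating in no RMMP are singletons; they are excluded from
#' series and reported separately. Series ids are assigned by decreasing size,
#' ties broken by the smallest member id, so the numbering is invariant to
#' input order.
#'
#' @param compounds a [CompoundSet-class].
#' @param rmmps data.frame from [generateRmmps()].
#' @param config a [PipelineConfig-class].
#' @return An [AnalogSeriesSet-class].
#' @export
extractAnalogSeries <- function(compounds, rmmps, config = pipelineConfig()) {
  ids <- compounds@ids
  bad <- setdiff(unique(c(rmmps$compound_a, rmmps$compound_b)), ids)
  if (length(bad))
    stop("RMMP references unknown compound id(s): ",
         paste(bad, collapse = ", "))
  if (nrow(rmmps) == 0L)
    return(methods::new("AnalogSeriesSet", series = list(),
                        singletonIds = ids,
                        smallComponentIds = character()))
  g <- igraph::graph_from_data_frame(
    rmmps[, c("compound_a", "compound_b")], directed = FALSE,
    vertices = data.frame(name = ids))
  memb <- igraph::components(g)$membership[ids]
  sizes <- table(memb)
  singletons <- ids[sizes[as.character(memb)] == 1L]
  small <- ids[sizes[as.character(memb)] > 1L &
               sizes[as.character(memb)] < config@minSeriesSize]
  comp_ids <- names(sizes)[sizes >= max(2L, config@minSeriesSize)]

  series <- lapply(comp_ids, function(cp) {
    members <- ids[memb == as.integer(cp)]
    members <- members[.corder(members)]
    edges <- rmmps[rmmps$compound_a %in% members &
                   rmmps$compound_b %in% members, , drop = FALSE]
    rownames(edges) <- NULL
    methods::new("AnalogSeries", seriesId = NA_integer_,
                 memberIds = members, edges = edges)
  })
  if (length(series)) {
    nmem <- vapply(series, function(s) length(s@memberIds), integer(1))
    first <- vapply(series, function(s) s@memberIds[1], character(1))
    ord <- .corder(-nmem, first)
    series <- series[ord]
    for (i in seq_along(series)) series[[i]]@seriesId <- i
  }
  methods::new("AnalogSeriesSet", series = series, singletonIds = singletons,
               smallComponentIds = small)
}

#' Export a series membership table
#'
#' @param seriesSet an [AnalogSeriesSet-class].
#' @param path output file (TSV: `series_id`, `compound_id`).
#' @return `path`, invisibly.
#' @export
writeSeriesTable <- function(seriesSet, path) {
  rows <- unlist(lapply(seriesSet@series, function(s)
    sprintf("%d\t%s", s@seriesId, s@memberIds)))
  writeLines(c("series_id\tcompound_id", rows), path)
  invisible(path)
}

#' Accessors for analog series
#'
#' @param x an [AnalogSeries-class] or [AnalogSeriesSet-class].
#' @name AnalogSeries-accessors
NULL

#' @rdname AnalogSeries-accessors
#' @export
setMethod("seriesId", "AnalogSeries", function(x) x@seriesId)
#' @rdname AnalogSeries-accessors
#' @export
setMethod("memberIds", "AnalogSeries", function(x) x@memberIds)
#' @rdname AnalogSeries-accessors
#' @export
setMethod("rmmpEdges", "AnalogSeries", function(x) x@edges)
#' @rdname AnalogSeries-accessors
#' @export
setMethod("analogSeries", "AnalogSeriesSet", function(x) x@series)
#' @rdname AnalogSeries-accessors
#' @export
setMethod("singletonIds", "AnalogSeriesSet", function(x) x@singletonIds)

#' @describeIn AnalogSeriesSet-class number of series
#' @param x,object an `AnalogSeriesSet`
#' @export
setMethod("length", "AnalogSeriesSet", function(x) length(x@series))

#' @describeIn AnalogSeriesSet-class compact display
#' @export
setMethod("show", "AnalogSeriesSet", function(object) {
  cat(sprintf("AnalogSeriesSet: %d series, %d singleton(s), %d in undersized component(s)\n",
              length(object@series), length(object@singletonIds),
              length(object@smallComponentIds)))
})

#' @describeIn AnalogSeries-class compact display
#' @param object an `AnalogSeries`
#' @export
setMethod("show", "AnalogSeries", function(object) {
  cat(sprintf("AnalogSeries #%d: %d member(s), %d RMMP edge(s)\n",
              object@seriesId, length(object@memberIds), nrow(object@edges)))
})
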