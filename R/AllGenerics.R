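# Generics. Implementations live next to their class or module.

#' @rdname canonicalForm
#' @export
setGeneric("canonicalForm", function(structure) standardGeneric("canonicalForm"))

#' @rdname standardizeStructure
#' @export
setGeneric("standardizeStructure", function(raw, config = pipelineConfig())
  standardGeneric("standardizeStructure"))

#' @rdname normalizeSiteNumbering
#' @export
setGeneric("normalizeSiteNumbering", function(structure)
  standardGeneric("normalizeSiteNumbering"))

#' @rdname CompoundSet-accessors
#' @export
setGeneric("compoundIds", function(x) standardGeneric("compoundIds"))
#' @rdname CompoundSet-accessors
#' @export
setGeneric("compoundSmiles", function(x) standardGeneric("compoundSmiles"))
#' @rdname CompoundSet-accessors
#' @export
setGeneric("sourceLabel", function(x) standardGeneric("sourceLabel"))
#' @rdname CompoundSet-accessors
#' @export
setGeneric("parseFailures", function(x) standardGeneric("parseFailures"))
#' @rdname CompoundSet-accessors
#' @export
setGeneric("duplicateLog", function(x) standardGeneric("duplicateLog"))
#' @rdname CompoundSet-accessors
#' @export
setGeneric("targetAnnotations", function(x) standardGeneric("targetAnnotations"))
#' @rdname CompoundSet-accessors
#' @export
setGeneric("classAnnotations", function(x) standardGeneric("classAnnotations"))
#' @rdname CompoundSet-accessors
#' @export
setGeneric("getCompound", function(x, id) standardGeneric("getCompound"))

#' @rdname CoreIndex-class
#' @export
setGeneric("coreEntries", function(x) standardGeneric("coreEntries"))

#' @rdname AnalogSeries-accessors
#' @export
setGeneric("seriesId", function(x) standardGeneric("seriesId"))
#' @rdname AnalogSeries-accessors
#' @export
setGeneric("memberIds", function(x) standardGeneric("memberIds"))
#' @rdname AnalogSeries-accessors
#' @export
setGeneric("rmmpEdges", function(x) standardGeneric("rmmpEdges"))
#' @rdname AnalogSeries-accessors
#' @export
setGeneric("analogSeries", function(x) standardGeneric("analogSeries"))
#' @rdname AnalogSeries-accessors
#' @export
setGeneric("singletonIds", function(x) standardGeneric("singletonIds"))

#' @rdname ASBScaffold-accessors
#' @export
setGeneric("scaffoldSmiles", function(x) standardGeneric("scaffoldSmiles"))
#' @rdname ASBScaffold-accessors
#' @export
setGeneric("nSites", function(x) standardGeneric("nSites"))
#' @rdname ASBScaffold-accessors
#' @export
setGeneric("analogCount", function(x) standardGeneric("analogCount"))
#' @rdname ASBScaffold-accessors
#' @export
setGeneric("analogIds", function(x) standardGeneric("analogIds"))
#' @rdname ASBScaffold-accessors
#' @export
setGeneric("scaffoldSource", function(x) standardGeneric("scaffoldSource"))
#' @rdname ASBScaffold-accessors
#' @export
setGeneric("targetIds", function(x) standardGeneric("targetIds"))
#' @rdname ASBScaffold-accessors
#' @export
setGeneric("classLabels", function(x) standardGeneric("classLabels"))

#' @rdname DerivationResult-accessors
#' @export
setGeneric("outcome", function(x) standardGeneric("outcome"))
#' @rdname DerivationResult-accessors
#' @export
setGeneric("scaffold", function(x) standardGeneric("scaffold"))
#' @rdname DerivationResult-accessors
#' @export
setGeneric("failureReason", function(x) standardGeneric("failureReason"))

#' @rdname ScaffoldCollection-accessors
#' @export
setGeneric("scaffolds", function(x) standardGeneric("scaffolds"))
#' @rdname ScaffoldCollection-accessors
#' @export
setGeneric("isRanked", function(x) standardGeneric("isRanked"))
#' @rdname ScaffoldCollection-accessors
#' @export
setGeneric("scaffoldRanks", function(x) standardGeneric("scaffoldRanks"))
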