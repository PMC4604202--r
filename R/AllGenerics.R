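#' @rdname readRecords
#' @export
setGeneric("readRecords", function(x, n = NULL) standardGeneric("readRecords"))

#' @rdname readPairs
#' @export
setGeneric("readPairs", function(x, n = NULL) standardGeneric("readPairs"))

#' @rdname ReadSetStats-accessors
#' @export
setGeneric("nReads", function(x) standardGeneric("nReads"))

#' @rdname ReadSetStats-accessors
#' @export
setGeneric("nBases", function(x) standardGeneric("nBases"))

#' @rdname ReadSetStats-accessors
#' @export
setGeneric("q20Bases", function(x) standardGeneric("q20Bases"))

#' @rdname ReadSetStats-accessors
#' @export
setGeneric("q30Bases", function(x) standardGeneric("q30Bases"))

#' @rdname ReadSetStats-accessors
#' @export
setGeneric("baseCounts", function(x) standardGeneric("baseCounts"))

#' @rdname ReadSetStats-accessors
#' @export
setGeneric("gcPercent", function(x) standardGeneric("gcPercent"))

#' @rdname ReadSetStats-accessors
#' @export
setGeneric("meanReadLength", function(x) standardGeneric("meanReadLength"))

#' @rdname ReadSetStats-accessors
#' @export
setGeneric("lengthRange", function(x) standardGeneric("lengthRange"))

#' @rdname ReadSetStats-accessors
#' @export
setGeneric("qualityRange", function(x) standardGeneric("qualityRange"))

#' @rdname ReadSetStats-accessors
#' @export
setGeneric("qualityCharRange", function(x) standardGeneric("qualityCharRange"))

#' @rdname ReadSetStats-accessors
#' @export
setGeneric("lengthHistogram", function(x) standardGeneric("lengthHistogram"))

#' @rdname ReadSetStats-accessors
#' @export
setGeneric("phredOffset", function(x) standardGeneric("phredOffset"))

#' @rdname mergeStats
#' @export
setGeneric("mergeStats", function(x, y) standardGeneric("mergeStats"))

#' @rdname TrimOutcome-accessors
#' @export
setGeneric("pairsIn", function(x) standardGeneric("pairsIn"))

#' @rdname TrimOutcome-accessors
#' @export
setGeneric("pairsKept", function(x) standardGeneric("pairsKept"))

#' @rdname TrimOutcome-accessors
#' @export
setGeneric("singletons", function(x) standardGeneric("singletons"))

#' @rdname TrimOutcome-accessors
#' @export
setGeneric("readsDiscarded", function(x) standardGeneric("readsDiscarded"))

#' @rdname TrimOutcome-accessors
#' @export
setGeneric("basesBefore", function(x) standardGeneric("basesBefore"))

#' @rdname TrimOutcome-accessors
#' @export
setGeneric("basesAfter", function(x) standardGeneric("basesAfter"))

#' @rdname CoverageSummary-accessors
#' @export
setGeneric("genomeSize", function(x) standardGeneric("genomeSize"))

#' @rdname CoverageSummary-accessors
#' @export
setGeneric("meanDepth", function(x) standardGeneric("meanDepth"))

#' @rdname CoverageSummary-accessors
#' @export
setGeneric("breadth", function(x) standardGeneric("breadth"))
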