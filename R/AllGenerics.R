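# Generics and accessors. Slot access goes through these everywhere.

#' @rdname ContigSet-class
#' @param x,object an object of the documented class.
#' @export
setGeneric("contigIds", function(x) standardGeneric("contigIds"))
#' @rdname ContigSet-class
#' @export
setGeneric("contigLengths", function(x) standardGeneric("contigLengths"))
#' @rdname ContigSet-class
#' @export
setGeneric("contigSequences", function(x) standardGeneric("contigSequences"))
#' @rdname ContigSet-class
#' @export
setGeneric("virsorterScores", function(x) standardGeneric("virsorterScores"))
#' @rdname ContigSet-class
#' @export
setGeneric("classifierScores", function(x) standardGeneric("classifierScores"))
#' @rdname ContigSet-class
#' @export
setGeneric("viralRegions", function(x) standardGeneric("viralRegions"))
#' @rdname ContigSet-class
#' @export
setGeneric("contigInfo", function(x) standardGeneric("contigInfo"))

#' @rdname VirusPopulations-class
#' @param x an object.
#' @export
setGeneric("populationMembership",
           function(x) standardGeneric("populationMembership"))
#' @rdname VirusPopulations-class
#' @export
setGeneric("nPopulations", function(x) standardGeneric("nPopulations"))
#' @rdname VirusPopulations-class
#' @export
setGeneric("representatives", function(x) standardGeneric("representatives"))

#' @rdname AmgCatalog-class
#' @param x an object.
#' @export
setGeneric("amgCandidates", function(x) standardGeneric("amgCandidates"))
#' @rdname AmgCatalog-class
#' @export
setGeneric("amgDecisions", function(x) standardGeneric("amgDecisions"))
#' @rdname AmgCatalog-class
#' @export
setGeneric("conservativeSet", function(x) standardGeneric("conservativeSet"))
#' @rdname AmgCatalog-class
#' @export
setGeneric("permissiveSet", function(x) standardGeneric("permissiveSet"))

#' @rdname MockCommunity-class
#' @param x an object.
#' @export
setGeneric("genomeSequences", function(x) standardGeneric("genomeSequences"))
#' @rdname MockCommunity-class
#' @export
setGeneric("genomeGenes", function(x) standardGeneric("genomeGenes"))
#' @rdname MockCommunity-class
#' @export
setGeneric("genomePopulations",
           function(x) standardGeneric("genomePopulations"))

#' @rdname FragmentSet-class
#' @param x an object.
#' @export
setGeneric("fragmentTable", function(x) standardGeneric("fragmentTable"))
#' @rdname FragmentSet-class
#' @export
setGeneric("excludedPopulations",
           function(x) standardGeneric("excludedPopulations"))
#' @rdname FragmentSet-class
#' @export
setGeneric("fragmentBounds", function(x) standardGeneric("fragmentBounds"))

#' @rdname ConversionEstimate-class
#' @param x an object.
#' @export
setGeneric("conversionFactor", function(x) standardGeneric("conversionFactor"))
#' @rdname ConversionEstimate-class
#' @export
setGeneric("observedFraction", function(x) standardGeneric("observedFraction"))
#' @rdname ConversionEstimate-class
#' @export
setGeneric("trueFraction", function(x) standardGeneric("trueFraction"))
#' @rdname ConversionEstimate-class
#' @export
setGeneric("factorCI", function(x) standardGeneric("factorCI"))

#' @rdname ModuleDefinition-class
#' @param x an object.
#' @export
setGeneric("moduleSteps", function(x) standardGeneric("moduleSteps"))
#' @rdname ModuleDefinition-class
#' @export
setGeneric("nSteps", function(x) standardGeneric("nSteps"))

#' @rdname DepthProfileSet-class
#' @param x an object.
#' @export
setGeneric("depthProfiles", function(x) standardGeneric("depthProfiles"))
#' @rdname DepthProfileSet-class
#' @export
setGeneric("profileInfo", function(x) standardGeneric("profileInfo"))

#' @rdname GeneClusters-class
#' @param x an object.
#' @export
setGeneric("clusterMembership",
           function(x) standardGeneric("clusterMembership"))
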