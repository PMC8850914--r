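#' @rdname GenotypeMatrix-class
#' @param x,object a \code{GenotypeMatrix}
#' @export
setGeneric("sites", function(x) standardGeneric("sites"))

#' @rdname GenotypeMatrix-class
#' @export
setGeneric("genoCalls", function(x) standardGeneric("genoCalls"))

#' @rdname GenotypeMatrix-class
#' @export
setGeneric("accessions", function(x) standardGeneric("accessions"))

#' @rdname GenotypeMatrix-class
#' @export
setGeneric("genoDepth", function(x) standardGeneric("genoDepth"))

#' @rdname PedigreeGraph-class
#' @param x a \code{PedigreeGraph}
#' @export
setGeneric("founders", function(x) standardGeneric("founders"))

#' @rdname PedigreeGraph-class
#' @export
setGeneric("pedTarget", function(x) standardGeneric("pedTarget"))

#' @rdname PedigreeGraph-class
#' @export
setGeneric("pedEdges", function(x) standardGeneric("pedEdges"))

#' @rdname GeneModelSet-class
#' @param x a \code{GeneModelSet}
#' @export
setGeneric("geneRanges", function(x) standardGeneric("geneRanges"))

#' @rdname GeneModelSet-class
#' @export
setGeneric("geneExons", function(x) standardGeneric("geneExons"))

#' @rdname GeneModelSet-class
#' @export
setGeneric("geneCds", function(x) standardGeneric("geneCds"))

#' @rdname HaplotypeTable-class
#' @param x a \code{HaplotypeTable}
#' @export
setGeneric("hapAlleles", function(x) standardGeneric("hapAlleles"))

#' @rdname HaplotypeTable-class
#' @export
setGeneric("hapFreqs", function(x) standardGeneric("hapFreqs"))

#' @rdname HaplotypeTable-class
#' @export
setGeneric("mainHaplotypes", function(x) standardGeneric("mainHaplotypes"))

#' @rdname InteractionDecomposition-class
#' @param x an \code{InteractionDecomposition}
#' @export
setGeneric("comboMeans", function(x) standardGeneric("comboMeans"))

#' @rdname InteractionDecomposition-class
#' @export
setGeneric("conditionalEffects",
           function(x) standardGeneric("conditionalEffects"))

#' @rdname InteractionDecomposition-class
#' @export
setGeneric("totalTransition", function(x) standardGeneric("totalTransition"))

#' @rdname InteractionDecomposition-class
#' @param which \code{"combos"} or \code{"marginals"}
#' @export
setGeneric("synergy", function(x, which = c("combos", "marginals"))
           standardGeneric("synergy"))

#' @rdname HubReport-class
#' @param x a \code{HubReport}
#' @export
setGeneric("hubConsensusRanks", function(x) standardGeneric("hubConsensusRanks"))

#' @rdname HubReport-class
#' @export
setGeneric("topHubs", function(x) standardGeneric("topHubs"))
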