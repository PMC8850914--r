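#' Construct a GenotypeMatrix
#'
#' @param sites width-1 \code{GRanges} with mcols \code{ref}, \code{alt} and
#'   optionally \code{qual} (phred-scaled site quality; filled with \code{NA}
#'   when absent)
#' @param geno integer matrix of genotype codes (0 hom ref, 1 het, 2 hom alt,
#'   \code{NA} missing); rows follow \code{sites}, columns are accessions
#' @param depth optional numeric matrix of per-genotype read depth, same
#'   shape as \code{geno}
#' @return a sorted, validated \code{GenotypeMatrix}
#' @examples
#' gr <- GenomicRanges::GRanges("A01", IRanges::IRanges(c(100, 50), width = 1),
#'   ref = c("A", "G"), alt = c("T", "C"), qual = c(50, 60))
#' g <- matrix(c(0L, 2L, 1L, NA), 2, 2,
#'   dimnames = list(NULL, c("acc1", "acc2")))
#' gm <- GenotypeMatrix(gr, g)   # sites get sorted by position
#' nSites(gm)
#' @export
GenotypeMatrix <- function(sites, geno, depth = NULL) {
  if (is.null(S4Vectors::mcols(sites)$qual))
    S4Vectors::mcols(sites)$qual <- NA_real_
  o <- order(as.character(GenomeInfoDb::seqnames(sites)),
             BiocGenerics::start(sites))
  sites <- sites[o]
  geno <- geno[o, , drop = FALSE]
  storage.mode(geno) <- "integer"
  if (!is.null(depth)) depth <- depth[o, , drop = FALSE]
  new("GenotypeMatrix", sites = sites, geno = geno, depth = depth)
}

#' @rdname GenotypeMatrix-class
#' @export
setMethod("sites", "GenotypeMatrix", function(x) x@sites)

#' @rdname GenotypeMatrix-class
#' @export
setMethod("genoCalls", "GenotypeMatrix", function(x) x@geno)

#' @rdname GenotypeMatrix-class
#' @export
setMethod("accessions", "GenotypeMatrix", function(x) colnames(x@geno))

#' @rdname GenotypeMatrix-class
#' @export
setMethod("genoDepth", "GenotypeMatrix", function(x) x@depth)

#' Number of sites in a GenotypeMatrix
#' @param x a \code{GenotypeMatrix}
#' @export
nSites <- function(x) length(x@sites)

#' @rdname GenotypeMatrix-class
#' @param i site indices (numeric/logical)
#' @param j accession names or indices
#' @param drop ignored
#' @param ... ignored
#' @export
setMethod("[", "GenotypeMatrix", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nrow(x@geno))
  if (missing(j)) j <- seq_len(ncol(x@geno))
  GenotypeMatrix(x@sites[i], x@geno[i, j, drop = FALSE],
                 if (is.null(x@depth)) NULL else x@depth[i, j, drop = FALSE])
})

setMethod("show", "GenotypeMatrix", function(object) {
  cat("GenotypeMatrix:", length(object@sites), "sites x",
      ncol(object@geno), "accessions\n")
  sq <- table(as.character(GenomeInfoDb::seqnames(object@sites)))
  cat("  chromosomes:",
      paste(sprintf("%s (%d)", names(sq), as.integer(sq)), collapse = ", "),
      "\n")
  nmiss <- sum(is.na(object@geno))
  cat(sprintf("  missing calls: %d (%.2f%%)\n", nmiss,
              100 * nmiss / length(object@geno)))
  cat("  depth:", if (is.null(object@depth)) "absent" else "present", "\n")
})

#' Pedigree graph constructor
#'
#' @param edges data.frame with columns \code{parent}, \code{child}
#' @param target designated target accession (the traced descendant)
#' @return a validated \code{PedigreeGraph}
#' @export
PedigreeGraph <- function(edges, target) {
  edges$parent <- as.character(edges$parent)
  edges$child <- as.character(edges$child)
  new("PedigreeGraph", edges = edges[, c("parent", "child")],
      target = as.character(target))
}

#' @rdname PedigreeGraph-class
#' @export
setMethod("founders", "PedigreeGraph", function(x)
  sort(setdiff(x@edges$parent, x@edges$child)))

#' @rdname PedigreeGraph-class
#' @export
setMethod("pedTarget", "PedigreeGraph", function(x) x@target)

#' @rdname PedigreeGraph-class
#' @export
setMethod("pedEdges", "PedigreeGraph", function(x) x@edges)

#' Accessions of a pedigree, in topological (breeding) order
#' @param x a \code{PedigreeGraph}
#' @export
pedAccessions <- function(x) {
  g <- igraph::graph_from_data_frame(x@edges)
  names(igraph::topo_sort(g, mode = "out"))
}

#' Candidate ancestors of the target accession
#'
#' All pedigree members from which the target is reachable, i.e. the set the
#' transmission scan should sweep. The target itself is excluded.
#' @param x a \code{PedigreeGraph}
#' @export
candidateAncestors <- function(x) {
  g <- igraph::graph_from_data_frame(x@edges)
  anc <- names(igraph::subcomponent(g, x@target, mode = "in"))
  sort(setdiff(anc, x@target))
}

setMethod("show", "PedigreeGraph", function(object) {
  cat("PedigreeGraph:", length(unique(c(object@edges$parent,
      object@edges$child))), "accessions,", nrow(object@edges), "edges\n")
  cat("  founders:", paste(founders(object), collapse = ", "), "\n")
  cat("  target:", object@target, "\n")
})

#' @rdname GeneModelSet-class
#' @export
setMethod("geneRanges", "GeneModelSet", function(x) x@genes)

#' @rdname GeneModelSet-class
#' @export
setMethod("geneExons", "GeneModelSet", function(x) x@exons)

#' @rdname GeneModelSet-class
#' @export
setMethod("geneCds", "GeneModelSet", function(x) x@cds)

#' Gene ids of a GeneModelSet
#' @param x a \code{GeneModelSet}
#' @export
geneIds <- function(x) x@genes$gene_id

setMethod("show", "GeneModelSet", function(object) {
  cat("GeneModelSet:", length(object@genes), "genes,",
      length(object@cds), "with CDS\n")
})

#' @rdname HaplotypeTable-class
#' @export
setMethod("hapAlleles", "HaplotypeTable", function(x) x@alleles)

#' @rdname HaplotypeTable-class
#' @export
setMethod("hapFreqs", "HaplotypeTable", function(x) x@freqs)

#' @rdname HaplotypeTable-class
#' @export
setMethod("mainHaplotypes", "HaplotypeTable", function(x) x@mainPair)

setMethod("show", "HaplotypeTable", function(object) {
  cat("HaplotypeTable for", object@geneID, "-", length(object@snps),
      "SNPs,", sum(object@alleles != "unassigned"), "assigned of",
      length(object@alleles), "accessions\n")
  if (length(object@mainPair))
    cat("  main haplotypes:", paste(object@mainPair, collapse = " / "), "\n")
})

#' @rdname InteractionDecomposition-class
#' @export
setMethod("comboMeans", "InteractionDecomposition", function(x) x@comboMeans)

#' @rdname InteractionDecomposition-class
#' @export
setMethod("conditionalEffects", "InteractionDecomposition",
          function(x) x@conditionals)

#' @rdname InteractionDecomposition-class
#' @export
setMethod("totalTransition", "InteractionDecomposition", function(x) x@total)

#' @rdname InteractionDecomposition-class
#' @export
setMethod("synergy", "InteractionDecomposition",
  function(x, which = c("combos", "marginals")) {
    which <- match.arg(which)
    if (which == "combos") x@synergyCombos else x@synergyMarginals
  })

setMethod("show", "InteractionDecomposition", function(object) {
  cat("InteractionDecomposition:", object@loci["A"], "x",
      object@loci["B"], "\n")
  cat("  combination means:\n")
  print(round(object@comboMeans, 4))
  cond <- object@conditionals
  cat(sprintf("  %s | %s=%s : %+.4g\n", object@loci["A"], object@loci["B"],
              c(object@hapLevels$B["ref"], object@hapLevels$B["elite"]),
              cond[c("A.refB", "A.eliteB")]), sep = "")
  cat(sprintf("  %s | %s=%s : %+.4g\n", object@loci["B"], object@loci["A"],
              c(object@hapLevels$A["ref"], object@hapLevels$A["elite"]),
              cond[c("B.refA", "B.eliteA")]), sep = "")
  cat(sprintf("  total transition : %+.4g\n", object@total))
  cat(sprintf("  synergy (vs reference-context conditionals): %+.4g\n",
              object@synergyCombos))
  if (!any(is.na(object@marginals)))
    cat(sprintf("  synergy (vs marginals): %+.4g\n", object@synergyMarginals))
})

#' @rdname HubReport-class
#' @export
setMethod("hubConsensusRanks", "HubReport", function(x) x@consensus)

#' @rdname HubReport-class
#' @export
setMethod("topHubs", "HubReport", function(x) x@topHubs)

setMethod("show", "HubReport", function(object) {
  cat("HubReport:", nrow(object@scores), "genes x",
      ncol(object@scores), "methods;", length(object@topHubs),
      "hubs flagged\n")
  if (length(object@consensus)) {
    top <- sort(object@consensus)[seq_len(min(5, length(object@consensus)))]
    cat("  best consensus ranks:",
        paste(sprintf("%s (%.2f)", names(top), top), collapse = ", "), "\n")
  }
})
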