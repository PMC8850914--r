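#' @import methods
#' @import GenomicRanges
#' @import IRanges
#' @import S4Vectors
NULL

GT_LEVELS <- c(hom_ref = 0L, het = 1L, hom_alt = 2L)

#' GenotypeMatrix: biallelic diploid genotype calls, sites x accessions
#'
#' Central container for the pipeline. Sites are width-1 \code{GRanges}
#' (1-based positions) carrying \code{ref}, \code{alt} and \code{qual}
#' metadata columns; calls are stored as an integer matrix with codes
#' 0 = homozygous reference, 1 = heterozygous, 2 = homozygous alternate and
#' \code{NA} = missing. An optional per-sample read-depth matrix of the same
#' shape supports depth-based genotype masking during filtering.
#'
#' Sites are always kept sorted by (chromosome, position); chromosome order
#' is lexicographic so that containers compare reproducibly.
#'
#' @slot sites width-1 \code{GRanges}, mcols \code{ref}, \code{alt},
#'   \code{qual}
#' @slot geno integer matrix, rows = sites, columns = accessions
#' @slot depth numeric matrix of per-genotype read depth, or \code{NULL}
#' @exportClass GenotypeMatrix
setClass("GenotypeMatrix",
  representation(sites = "GRanges", geno = "matrix", depth = "ANY"))

setValidity("GenotypeMatrix", function(object) {
  msg <- character()
  gr <- object@sites
  g <- object@geno
  if (length(gr) != nrow(g))
    msg <- c(msg, "number of sites must equal nrow(geno)")
  if (is.null(colnames(g)) || anyDuplicated(colnames(g)))
    msg <- c(msg, "accession names must be present and unique")
  mc <- S4Vectors::mcols(gr)
  if (!all(c("ref", "alt") %in% colnames(mc))) {
    msg <- c(msg, "sites must carry 'ref' and 'alt' metadata columns")
  } else {
    bad <- !(mc$ref %in% c("A", "C", "G", "T")) |
           !(mc$alt %in% c("A", "C", "G", "T")) | mc$ref == mc$alt
    if (any(bad))
      msg <- c(msg, "ref/alt must be distinct single bases in {A,C,G,T}")
  }
  if (length(gr)) {
    if (any(BiocGenerics::width(gr) != 1L))
      msg <- c(msg, "sites must be width-1 positions")
    key <- paste(as.character(GenomeInfoDb::seqnames(gr)),
                 BiocGenerics::start(gr))
    if (anyDuplicated(key))
      msg <- c(msg, "duplicated (chrom, pos) site")
    o <- order(as.character(GenomeInfoDb::seqnames(gr)),
               BiocGenerics::start(gr))
    if (!identical(o, seq_along(gr)))
      msg <- c(msg, "sites must be sorted by (chrom, pos)")
  }
  if (!all(g[!is.na(g)] %in% 0:2))
    msg <- c(msg, "genotype codes must be 0, 1, 2 or NA")
  if (!is.null(object@depth) &&
      !identical(dim(object@depth), dim(g)))
    msg <- c(msg, "depth matrix must match geno dimensions")
  if (length(msg)) msg else TRUE
})

#' PedigreeGraph: directed acyclic pedigree with a designated target
#'
#' @slot edges data.frame with columns \code{parent}, \code{child}
#' @slot target the accession whose genome is traced through the pedigree
#' @exportClass PedigreeGraph
setClass("PedigreeGraph",
  representation(edges = "data.frame", target = "character"))

setValidity("PedigreeGraph", function(object) {
  ed <- object@edges
  if (!all(c("parent", "child") %in% colnames(ed)))
    return("edges must have 'parent' and 'child' columns")
  g <- igraph::graph_from_data_frame(ed[, c("parent", "child")])
  if (!igraph::is_dag(g))
    return("pedigree must be acyclic")
  if (length(object@target) != 1L ||
      !(object@target %in% c(ed$parent, ed$child)))
    return("target must be a single accession present in the pedigree")
  fo <- setdiff(ed$parent, ed$child)
  anc <- names(igraph::subcomponent(g, object@target, mode = "in"))
  if (!any(fo %in% anc))
    return("target must be reachable from at least one founder")
  TRUE
})

#' GeneModelSet: gene models parsed from GFF3
#'
#' @slot genes \code{GRanges} of transcript spans with mcol \code{gene_id};
#'   strand taken from \code{strand()}
#' @slot exons \code{GRangesList} named by gene id
#' @slot cds \code{GRangesList} named by gene id (may lack non-coding genes)
#' @exportClass GeneModelSet
setClass("GeneModelSet",
  representation(genes = "GRanges", exons = "GRangesList",
                 cds = "GRangesList"))

setValidity("GeneModelSet", function(object) {
  ids <- object@genes$gene_id
  if (is.null(ids) || anyDuplicated(ids))
    return("genes must carry unique 'gene_id' mcol")
  if (!all(names(object@exons) %in% ids))
    return("exon group names must be gene ids")
  if (!all(names(object@cds) %in% ids))
    return("cds group names must be gene ids")
  TRUE
})

#' HaplotypeTable: per-gene allele strings and the two main haplotypes
#'
#' Haplotypes concatenate the homozygous alleles (sense-strand) of the
#' selected SNPs of one gene, accession by accession; any heterozygous or
#' missing call makes the accession "unassigned".
#'
#' @slot geneID gene identifier
#' @slot snps selected SNPs (width-1 \code{GRanges}) with mcols \code{ref},
#'   \code{alt}, \code{inPromoter}
#' @slot alleles named character vector, accession -> allele string or
#'   \code{"unassigned"}
#' @slot freqs named numeric, haplotype string -> frequency among assigned
#' @slot mainPair the two most frequent haplotypes (most frequent first);
#'   may be shorter when fewer haplotypes exist
#' @exportClass HaplotypeTable
setClass("HaplotypeTable",
  representation(geneID = "character", snps = "GRanges",
                 alleles = "character", freqs = "numeric",
                 mainPair = "character"))

setValidity("HaplotypeTable", function(object) {
  ok <- object@alleles == "unassigned" |
        nchar(object@alleles) == length(object@snps)
  if (!all(ok))
    return("allele strings must have one base per selected SNP")
  if (sum(object@freqs) > 1 + 1e-8)
    return("haplotype frequencies must sum to <= 1")
  if (length(object@mainPair) == 2 &&
      object@freqs[object@mainPair[1]] < object@freqs[object@mainPair[2]])
    return("mainPair must be ordered by decreasing frequency")
  TRUE
})

#' InteractionDecomposition: two-locus haplotype synergy ledger
#'
#' Holds the 2x2 table of combination means over (reference, elite) levels of
#' two loci, the conditional effects of switching one locus at a fixed level
#' of the other, the total transition from the double-reference to the
#' double-elite combination, externally supplied or data-derived marginal
#' effects, and two synergy readings: total minus the sum of marginals, and
#' total minus the sum of the two reference-context conditionals.
#'
#' @slot loci named character, \code{c(A=, B=)} locus labels
#' @slot hapLevels list with elements \code{A}, \code{B}, each
#'   \code{c(ref=, elite=)}
#' @slot comboMeans 2x2 matrix, rows = locus A levels, cols = locus B levels
#' @slot comboN integer 2x2 matrix of group sizes (0 when built from a pure
#'   mean table)
#' @slot comboSd numeric 2x2 matrix of group standard deviations (NA when
#'   unavailable)
#' @slot conditionals named numeric: \code{A.refB}, \code{A.eliteB},
#'   \code{B.refA}, \code{B.eliteA}
#' @slot total numeric, m(eliteA, eliteB) - m(refA, refB)
#' @slot marginals named numeric \code{c(A=, B=)}, possibly NA
#' @slot synergyMarginals total - (marginalA + marginalB)
#' @slot synergyCombos total - (A.refB + B.refA)
#' @exportClass InteractionDecomposition
setClass("InteractionDecomposition",
  representation(loci = "character", hapLevels = "list",
                 comboMeans = "matrix", comboN = "matrix", comboSd = "matrix",
                 conditionals = "numeric", total = "numeric",
                 marginals = "numeric", synergyMarginals = "numeric",
                 synergyCombos = "numeric"))

#' HubReport: co-expression hub consensus ranking
#'
#' @slot graph undirected weighted \code{igraph} co-expression network
#' @slot scores genes x methods matrix of raw centrality scores
#' @slot ranks genes x methods matrix of dense ranks (best = 1)
#' @slot consensus named numeric mean rank across enabled methods
#' @slot topHubs gene ids flagged as hubs (top-k by consensus)
#' @exportClass HubReport
setClass("HubReport",
  representation(graph = "ANY", scores = "matrix", ranks = "matrix",
                 consensus = "numeric", topHubs = "character"))
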