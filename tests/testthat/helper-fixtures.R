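# fixtures are built in code; nothing is read from disk

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
  library(Biostrings)
  library(igraph)
})

# small genotype matrix from a code matrix (rows = sites)
toyGM <- function(codes, chrom = "A01", pos = NULL, ref = NULL, alt = NULL,
                  qual = 50, depth = NULL) {
  n <- nrow(codes)
  if (is.null(pos)) pos <- seq_len(n) * 100L
  if (is.null(ref)) ref <- rep_len(c("A", "C", "G", "T"), n)
  if (is.null(alt)) alt <- rep_len(c("G", "T", "A", "C"), n)
  if (is.null(colnames(codes)))
    colnames(codes) <- sprintf("acc%02d", seq_len(ncol(codes)))
  gr <- GRanges(rep_len(chrom, n), IRanges(pos, width = 1),
                ref = ref, alt = alt, qual = rep_len(qual, n))
  GenotypeMatrix(gr, codes, depth)
}

# a GeneModelSet from a list of gene specs:
#   list(id=, chrom=, strand=, exons=cbind(start,end), cds=exons)
toyGenes <- function(specs) {
  ids <- vapply(specs, `[[`, character(1), "id")
  genes <- GRanges(
    vapply(specs, `[[`, character(1), "chrom"),
    IRanges(vapply(specs, function(s) min(s$exons[, 1]), numeric(1)),
            vapply(specs, function(s) max(s$exons[, 2]), numeric(1))),
    strand = vapply(specs, `[[`, character(1), "strand"),
    gene_id = ids)
  names(genes) <- ids
  exons <- GRangesList(lapply(specs, function(s)
    GRanges(s$chrom, IRanges(s$exons[, 1], s$exons[, 2]))))
  names(exons) <- ids
  cds <- GRangesList(lapply(specs, function(s) {
    cc <- if (is.null(s$cds)) s$exons else s$cds
    GRanges(s$chrom, IRanges(cc[, 1], cc[, 2]))
  }))
  names(cds) <- ids
  # drop cds for genes marked noncoding
  nocds <- vapply(specs, function(s) isTRUE(s$noncoding), logical(1))
  new("GeneModelSet", genes = genes, exons = exons, cds = cds[!nocds])
}

# pooled bp Jaccard between detected unique fragments and founder-origin
# truth of the pedigree target
truthJaccard <- function(study) {
  ped <- study$pedigree
  tgt <- pedTarget(ped)
  frags <- suppressMessages(suppressWarnings(
    scanPedigreeTransmission(study$genotypes, ped,
                             ancestors = founders(ped))))
  uniq <- attributeUnique(frags)
  orig <- study$truth$founderOrigin[[tgt]]
  truthGr <- suppressWarnings(
    do.call(c, unname(lapply(names(orig), function(ch)
      GRanges(ch, IRanges(orig[[ch]]$start, orig[[ch]]$end),
              founder = orig[[ch]]$founder)))))
  num <- 0; den <- 0
  for (f in founders(ped)) {
    det <- reduce(uniq[uniq$ancestor == f])
    tru <- reduce(truthGr[truthGr$founder == f])
    num <- num + sum(width(suppressWarnings(
      GenomicRanges::intersect(det, tru))))
    den <- den + sum(width(suppressWarnings(
      GenomicRanges::union(det, tru))))
  }
  num / den
}

# run the haplotype pipeline on a simulated population: returns the
# interaction decomposition fitted from genotypes + phenotypes
popDecomposition <- function(pop) {
  gm <- pop$genotypes
  hs <- sites(gm)
  tA <- assignHaplotypes(gm, hs[1:3], "geneA")
  tB <- assignHaplotypes(gm, hs[4], "geneB")
  suppressMessages(interactionDecomposition(pop$phenotypes, tA, tB, "FS"))
}
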