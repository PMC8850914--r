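#' Genotype identity ratio between two accessions
#'
#' Fraction of sites at which the two accessions carry the same genotype
#' class (hom ref / het / hom alt), over the sites where both are called.
#' Sites with a missing genotype in either accession are excluded from
#' numerator and denominator. Returns \code{NA} when no site is jointly
#' called.
#'
#' @param gtAncestor,gtDescendant integer genotype-code vectors
#' @param siteIndices optional subset of site indices to compare
#' @return ratio in [0, 1], or \code{NA}
#' @export
identityRatio <- function(gtAncestor, gtDescendant,
                          siteIndices = seq_along(gtAncestor)) {
  a <- gtAncestor[siteIndices]
  d <- gtDescendant[siteIndices]
  both <- !is.na(a) & !is.na(d)
  if (!any(both)) return(NA_real_)
  sum(a[both] == d[both]) / sum(both)
}

#' Sliding-window IBD transmission scan between an ancestor and a descendant
#'
#' Slides windows of \code{windowSnps} consecutive SNPs advanced by
#' \code{stepSnps} (SNP-index space, not bp) along each chromosome and keeps
#' windows whose genotype identity ratio is at least \code{minIdentity}.
#' Qualifying windows sharing at least one SNP index are merged into maximal
#' fragments; a fragment spans the first to the last SNP of its merged
#' windows. Chromosomes with fewer than \code{windowSnps} SNPs are skipped
#' with a warning (no partial windows). Windows without jointly called sites
#' are skipped and counted in a message.
#'
#' @param gm a \code{GenotypeMatrix}
#' @param ancestor,descendant accession names present in \code{gm}
#' @param windowSnps,stepSnps,minIdentity scan parameters (defaults 200 / 20
#'   / 0.99)
#' @return \code{GRanges} of transmitted fragments with mcols
#'   \code{ancestor}, \code{descendant}, \code{n_snps},
#'   \code{mean_identity} (mean ratio of the qualifying windows, hence always
#'   >= \code{minIdentity})
#' @export
scanTransmission <- function(gm, ancestor, descendant,
                             windowSnps = 200L, stepSnps = 20L,
                             minIdentity = 0.99) {
  stopifnot(windowSnps > 0, stepSnps > 0, stepSnps <= windowSnps,
            minIdentity > 0, minIdentity <= 1)
  acc <- accessions(gm)
  if (!all(c(ancestor, descendant) %in% acc))
    stop("both accessions must be present in the genotype matrix")
  g <- genoCalls(gm)
  gr <- sites(gm)
  chrom <- as.character(GenomeInfoDb::seqnames(gr))
  pos <- BiocGenerics::start(gr)
  nEmpty <- 0L

  frags <- lapply(sort(unique(chrom)), function(ch) {
    sel <- which(chrom == ch)
    n <- length(sel)
    if (n < windowSnps) {
      warning("chromosome ", ch, " has fewer than ", windowSnps,
              " SNPs; skipped")
      return(NULL)
    }
    a <- g[sel, ancestor]
    d <- g[sel, descendant]
    called <- !is.na(a) & !is.na(d)
    eq <- called & !is.na(a == d) & (a == d)
    eq[is.na(eq)] <- FALSE
    cumEq <- c(0, cumsum(eq))
    cumCalled <- c(0, cumsum(called))
    wStart <- seq(1L, n - windowSnps + 1L, by = stepSnps)
    wEnd <- wStart + windowSnps - 1L
    num <- cumEq[wEnd + 1L] - cumEq[wStart]
    den <- cumCalled[wEnd + 1L] - cumCalled[wStart]
    nEmpty <<- nEmpty + sum(den == 0)
    ratio <- ifelse(den > 0, num / den, NA_real_)
    hit <- which(!is.na(ratio) & ratio >= minIdentity)
    if (!length(hit)) return(NULL)
    # merge qualifying windows that overlap in SNP-index space
    runBreak <- c(TRUE, wStart[hit][-1] > wEnd[hit][-length(hit)] + 0L)
    runId <- cumsum(runBreak)
    do.call(rbind, lapply(split(hit, runId), function(h) {
      i1 <- wStart[h[1]]
      i2 <- wEnd[h[length(h)]]
      data.frame(chrom = ch, start = pos[sel][i1], end = pos[sel][i2],
                 n_snps = i2 - i1 + 1L,
                 mean_identity = mean(ratio[h]))
    }))
  })
  if (nEmpty > 0)
    .msg("%d window(s) without jointly called sites skipped", nEmpty)
  frags <- do.call(rbind, frags)
  if (is.null(frags) || !nrow(frags))
    return(GenomicRanges::GRanges(ancestor = character(),
             descendant = character(), n_snps = integer(),
             mean_identity = numeric()))
  GenomicRanges::GRanges(frags$chrom,
    IRanges::IRanges(frags$start, frags$end),
    ancestor = ancestor, descendant = descendant,
    n_snps = frags$n_snps, mean_identity = frags$mean_identity)
}

#' Scan all candidate ancestors of the pedigree target
#'
#' Convenience wrapper running \code{\link{scanTransmission}} of the target
#' against each candidate ancestor.
#'
#' @param gm a \code{GenotypeMatrix}
#' @param pedigree a \code{PedigreeGraph}; the candidate set is every
#'   accession from which the target descends (or \code{ancestors} when
#'   given)
#' @param ancestors optional explicit candidate-ancestor vector
#' @param ... scan parameters passed on
#' @return named list of fragment \code{GRanges}, one per ancestor
#' @export
scanPedigreeTransmission <- function(gm, pedigree, ancestors = NULL, ...) {
  target <- pedTarget(pedigree)
  if (is.null(ancestors)) ancestors <- candidateAncestors(pedigree)
  ancestors <- intersect(ancestors, accessions(gm))
  stats::setNames(lapply(ancestors, function(a)
    scanTransmission(gm, a, target, ...)), ancestors)
}

#' Attribute genomic regions to unique ancestors
#'
#' Partitions the genome at fragment boundaries; a region is attributed to an
#' ancestor if and only if that ancestor's scan covers it and no other
#' candidate's does. Regions covered by several ancestors are labelled
#' \code{"shared"} and excluded from per-ancestor unique totals.
#'
#' @param fragmentsByAncestor named list of fragment \code{GRanges} (one per
#'   candidate ancestor, all against the same descendant)
#' @return \code{GRanges} with mcol \code{ancestor} (an ancestor name or
#'   \code{"shared"})
#' @export
attributeUnique <- function(fragmentsByAncestor) {
  keep <- vapply(fragmentsByAncestor, length, integer(1)) > 0
  fragmentsByAncestor <- fragmentsByAncestor[keep]
  if (!length(fragmentsByAncestor))
    return(GenomicRanges::GRanges(ancestor = character()))
  anc <- rep(names(fragmentsByAncestor),
             vapply(fragmentsByAncestor, length, integer(1)))
  # combining per-ancestor fragment sets can merge disjoint seqlevel sets;
  # that is expected, not a data problem
  all <- suppressWarnings(
    do.call(c, unname(lapply(fragmentsByAncestor, function(x) {
      S4Vectors::mcols(x) <- NULL
      x
    }))))
  pieces <- GenomicRanges::disjoin(all)
  hits <- GenomicRanges::findOverlaps(pieces, all)
  lab <- vapply(split(anc[S4Vectors::subjectHits(hits)],
                      factor(S4Vectors::queryHits(hits),
                             levels = seq_along(pieces))),
                function(a) {
                  u <- unique(a)
                  if (length(u) == 1L) u else "shared"
                }, character(1))
  covered <- !is.na(lab) & lengths(split(S4Vectors::subjectHits(hits),
      factor(S4Vectors::queryHits(hits), levels = seq_along(pieces)))) > 0
  pieces <- pieces[covered]
  lab <- lab[covered]
  # merge adjacent pieces with the same label
  out <- lapply(unique(lab), function(l) {
    r <- GenomicRanges::reduce(pieces[lab == l], min.gapwidth = 1L)
    r$ancestor <- l
    r
  })
  sort(unname(do.call(c, out)))
}

#' Summarise attributed transmission
#'
#' Totals the uniquely attributed sequence per ancestor, per chromosome and
#' per subgenome (chromosome-name prefix A = At, D = Dt), reports each
#' ancestor's share of the assembled genome, lists the genes overlapped by
#' unique fragments (any bp overlap with the transcript span) and reports the
#' amount and percentage of attributed sequence lying within genes.
#'
#' @param fragments \code{GRanges} with mcol \code{ancestor} (from
#'   \code{\link{attributeUnique}}); \code{"shared"} regions are excluded
#'   from unique totals
#' @param genes a \code{GeneModelSet}, or a \code{GRanges} of gene spans with
#'   mcol \code{gene_id}, or \code{NULL}
#' @param chromLengths named vector of assembled chromosome lengths; default
#'   is the max fragment end per chromosome
#' @return list with elements \code{perAncestor} (data.frame: ancestor, bp,
#'   pct_genome, bp_At, bp_Dt), \code{perChromosome} (data.frame),
#'   \code{genes} (character), \code{bpWithinGenes}, \code{pctWithinGenes},
#'   \code{totalAttributed}
#' @export
summarizeTransmission <- function(fragments, genes = NULL,
                                  chromLengths = NULL) {
  if (!length(fragments)) {
    return(list(perAncestor = data.frame(ancestor = character(),
        bp = numeric(), pct_genome = numeric(), bp_At = numeric(),
        bp_Dt = numeric()),
      perChromosome = data.frame(chrom = character(), bp = numeric()),
      genes = character(), bpWithinGenes = 0, pctWithinGenes = NA_real_,
      totalAttributed = 0))
  }
  uniq <- fragments[fragments$ancestor != "shared"]
  chrom <- as.character(GenomeInfoDb::seqnames(uniq))
  w <- BiocGenerics::width(uniq)
  if (is.null(chromLengths)) {
    chromLengths <- tapply(BiocGenerics::end(fragments),
      as.character(GenomeInfoDb::seqnames(fragments)), max)
  }
  genomeBp <- sum(chromLengths)

  perAnc <- do.call(rbind, lapply(sort(unique(uniq$ancestor)), function(a) {
    s <- uniq$ancestor == a
    data.frame(ancestor = a, bp = sum(w[s]),
               pct_genome = 100 * sum(w[s]) / genomeBp,
               bp_At = sum(w[s & startsWith(chrom, "A")]),
               bp_Dt = sum(w[s & startsWith(chrom, "D")]))
  }))
  if (is.null(perAnc))
    perAnc <- data.frame(ancestor = character(), bp = numeric(),
                         pct_genome = numeric(), bp_At = numeric(),
                         bp_Dt = numeric())
  perChrom <- if (length(uniq))
    stats::aggregate(list(bp = w), list(chrom = chrom), sum)
  else data.frame(chrom = character(), bp = numeric())

  geneIdsHit <- character()
  bpWithin <- 0
  pctWithin <- NA_real_
  if (!is.null(genes)) {
    spans <- if (is(genes, "GeneModelSet")) geneRanges(genes) else genes
    hits <- suppressWarnings(
      GenomicRanges::findOverlaps(spans, uniq, ignore.strand = TRUE))
    geneIdsHit <- sort(unique(spans$gene_id[S4Vectors::queryHits(hits)]))
    ov <- suppressWarnings(GenomicRanges::intersect(
      GenomicRanges::reduce(uniq, ignore.strand = TRUE),
      GenomicRanges::reduce(spans, ignore.strand = TRUE),
      ignore.strand = TRUE))
    bpWithin <- sum(BiocGenerics::width(ov))
    if (sum(w) > 0) pctWithin <- 100 * bpWithin / sum(w)
  }
  list(perAncestor = perAnc, perChromosome = perChrom,
       genes = geneIdsHit, bpWithinGenes = bpWithin,
       pctWithinGenes = pctWithin, totalAttributed = sum(w))
}
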