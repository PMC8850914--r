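#' Select the haplotype-defining SNPs of a gene
#'
#' The haplotype of a gene concatenates (a) the large-effect SNPs
#' (nonsynonymous / stop-gain / stop-loss) inside the transcript span and
#' (b) every SNP in the promoter, defined as the \code{promoterBp} bases
#' upstream of the transcription start on the coding strand. SNPs are
#' returned ordered by position.
#'
#' @param geneId gene identifier
#' @param effects annotation data.frame from \code{\link{annotateVariants}}
#' @param gm a \code{GenotypeMatrix} providing the SNP universe
#' @param geneModels a \code{GeneModelSet}
#' @param promoterBp promoter length, default 2,000 bp
#' @return width-1 \code{GRanges} with mcols \code{ref}, \code{alt},
#'   \code{inPromoter}; empty when no SNP qualifies (logged)
#' @export
selectHapSnps <- function(geneId, effects, gm, geneModels,
                          promoterBp = 2000L) {
  genes <- geneRanges(geneModels)
  gIdx <- match(geneId, genes$gene_id)
  if (is.na(gIdx)) stop("unknown gene: ", geneId)
  strand <- as.character(BiocGenerics::strand(genes))[gIdx]
  txS <- BiocGenerics::start(genes)[gIdx]
  txE <- BiocGenerics::end(genes)[gIdx]
  ch <- as.character(GenomeInfoDb::seqnames(genes))[gIdx]
  prom <- if (strand == "+") c(txS - promoterBp, txS - 1L)
          else c(txE + 1L, txE + promoterBp)

  gr <- sites(gm)
  chrom <- as.character(GenomeInfoDb::seqnames(gr))
  pos <- BiocGenerics::start(gr)

  eff <- effects[!is.na(effects$gene_id) & effects$gene_id == geneId &
                 isLargeEffect(effects), , drop = FALSE]
  bodyKey <- paste(eff$chrom, eff$pos, sep = ":")
  inBody <- chrom == ch & pos >= txS & pos <= txE &
    .siteKey(gr) %in% bodyKey
  inProm <- chrom == ch & pos >= prom[1] & pos <= prom[2]

  sel <- which(inBody | inProm)
  if (!length(sel)) {
    .msg("no haplotype-defining SNPs for %s; gene skipped", geneId)
    return(GenomicRanges::GRanges(ref = character(), alt = character(),
                                  inPromoter = logical()))
  }
  out <- gr[sel]
  S4Vectors::mcols(out) <-
    S4Vectors::DataFrame(ref = S4Vectors::mcols(out)$ref,
                         alt = S4Vectors::mcols(out)$alt,
                         inPromoter = inProm[sel])
  out[order(BiocGenerics::start(out))]
}

#' Assign gene haplotypes to accessions
#'
#' Each accession's haplotype is the concatenation of its homozygous alleles
#' at the selected SNPs (sense strand, in position order). Any heterozygous
#' or missing call makes the accession \code{"unassigned"} - the material is
#' near-inbred and accessions are grouped discretely. The two most frequent
#' strings form the main pair, ties broken lexicographically.
#'
#' @param gm a \code{GenotypeMatrix}
#' @param snps selected SNPs from \code{\link{selectHapSnps}}
#' @param geneId gene label carried into the table
#' @return a \code{HaplotypeTable}
#' @export
assignHaplotypes <- function(gm, snps, geneId = "gene") {
  if (!length(snps)) stop("no SNPs to assign haplotypes from")
  idx <- match(.siteKey(snps), .siteKey(sites(gm)))
  if (anyNA(idx)) stop("selected SNPs missing from the genotype matrix")
  g <- genoCalls(gm)[idx, , drop = FALSE]
  ref <- S4Vectors::mcols(snps)$ref
  alt <- S4Vectors::mcols(snps)$alt
  strings <- apply(g, 2, function(col) {
    if (anyNA(col) || any(col == 1L)) "unassigned"
    else paste(ifelse(col == 0L, ref, alt), collapse = "")
  })
  assigned <- strings[strings != "unassigned"]
  if (!length(assigned)) {
    warning("all accessions unassigned for ", geneId)
    return(new("HaplotypeTable", geneID = geneId, snps = snps,
               alleles = strings, freqs = numeric(0),
               mainPair = character(0)))
  }
  counts <- table(assigned)
  ord <- order(-as.integer(counts), names(counts))
  freqs <- as.numeric(counts[ord]) / length(strings)
  names(freqs) <- names(counts)[ord]
  mainPair <- names(freqs)[seq_len(min(2L, length(freqs)))]
  new("HaplotypeTable", geneID = geneId, snps = snps, alleles = strings,
      freqs = freqs, mainPair = mainPair)
}

# per-accession trait means (accession is the experimental unit; values are
# averaged across environments and replicates first)
.accessionMeans <- function(phenotypes, trait) {
  ph <- phenotypes[phenotypes$trait == trait, , drop = FALSE]
  if (!nrow(ph)) return(NULL)
  tapply(ph$value, ph$accession, mean)
}

#' Haplotype effect on a trait
#'
#' Compares the two main haplotype groups of a gene: per-accession trait
#' values are averaged across environments/replicates first, then the group
#' difference (elite = second-most-frequent minus reference = most frequent),
#' the percent effect relative to the reference mean, and a Welch two-tailed
#' t-test are reported. With degenerate variance in both groups the p-value
#' is \code{NA} but the effect is still reported.
#'
#' @param phenotypes phenotype data.frame (accession, trait, environment,
#'   value)
#' @param table a \code{HaplotypeTable}
#' @param trait trait code, e.g. \code{"FS"}
#' @return one-row data.frame: gene, trait, hap_ref, hap_elite, n_ref,
#'   n_elite, mean_ref, mean_elite, delta, percent, t, p
#' @export
haplotypeEffect <- function(phenotypes, table, trait) {
  if (length(mainHaplotypes(table)) < 2)
    stop("need two main haplotypes for an effect estimate")
  am <- .accessionMeans(phenotypes, trait)
  if (is.null(am)) stop("trait ", trait, " absent from phenotypes")
  hap <- hapAlleles(table)
  refH <- mainHaplotypes(table)[1]
  eliteH <- mainHaplotypes(table)[2]
  gRef <- am[names(hap)[hap == refH]]
  gElite <- am[names(hap)[hap == eliteH]]
  gRef <- gRef[!is.na(gRef)]
  gElite <- gElite[!is.na(gElite)]
  if (length(gRef) < 2 || length(gElite) < 2)
    stop("both haplotype groups need >= 2 accessions with trait values")
  m1 <- mean(gRef); m2 <- mean(gElite)
  delta <- m2 - m1
  tt <- tryCatch(stats::t.test(gElite, gRef, var.equal = FALSE),
                 error = function(e) NULL)
  data.frame(gene = table@geneID, trait = trait,
             hap_ref = refH, hap_elite = eliteH,
             n_ref = length(gRef), n_elite = length(gElite),
             mean_ref = m1, mean_elite = m2, delta = delta,
             percent = if (m1 != 0) 100 * delta / m1 else NA_real_,
             t = if (is.null(tt)) NA_real_ else unname(tt$statistic),
             p = if (is.null(tt)) NA_real_ else tt$p.value,
             stringsAsFactors = FALSE)
}

#' Two-locus haplotype interaction decomposition
#'
#' Decomposes the trait effect of the four combinations of two genes'
#' (reference, elite) haplotypes into combination means, conditional effects
#' (switching one locus at a fixed level of the other), the total transition
#' from double-reference to double-elite, and two synergy readings:
#' \code{total - (marginalA + marginalB)} and
#' \code{total - (condA|refB + condB|refA)}. The path-additivity identity
#' \code{condA|refB + condB|eliteA = total = condB|refA + condA|eliteB}
#' holds exactly by construction. Combinations with fewer than two
#' accessions are flagged; conditional effects requiring an empty
#' combination are \code{NA}, never imputed.
#'
#' Either supply phenotype data plus two \code{HaplotypeTable}s, or a pure
#' 2x2 combination-mean table (rows = locus A reference/elite, columns =
#' locus B reference/elite) for worked examples.
#'
#' @param phenotypes phenotype data.frame (ignored when \code{comboMeans}
#'   is given)
#' @param tableA,tableB \code{HaplotypeTable}s of the two genes
#' @param trait trait code
#' @param comboMeans optional 2x2 matrix of combination means
#' @param comboN optional 2x2 matrix of group sizes accompanying
#'   \code{comboMeans}
#' @param marginals named numeric \code{c(A=, B=)}: each locus's two-group
#'   effect ignoring the other. Computed from the data when phenotypes are
#'   supplied; may be given externally with a mean table.
#' @param loci locus labels \code{c(A=, B=)}
#' @param hapLevels list of \code{c(ref=, elite=)} labels per locus (derived
#'   from the tables when present)
#' @return an \code{InteractionDecomposition}
#' @export
interactionDecomposition <- function(phenotypes = NULL, tableA = NULL,
    tableB = NULL, trait = NULL, comboMeans = NULL, comboN = NULL,
    marginals = c(A = NA_real_, B = NA_real_),
    loci = c(A = "geneA", B = "geneB"),
    hapLevels = list(A = c(ref = "ref", elite = "elite"),
                     B = c(ref = "ref", elite = "elite"))) {
  comboSd <- matrix(NA_real_, 2, 2)
  if (is.null(comboMeans)) {
    stopifnot(!is.null(phenotypes), !is.null(tableA), !is.null(tableB),
              !is.null(trait))
    loci <- c(A = tableA@geneID, B = tableB@geneID)
    hapLevels <- list(
      A = c(ref = mainHaplotypes(tableA)[1], elite = mainHaplotypes(tableA)[2]),
      B = c(ref = mainHaplotypes(tableB)[1], elite = mainHaplotypes(tableB)[2]))
    am <- .accessionMeans(phenotypes, trait)
    hapA <- hapAlleles(tableA)
    hapB <- hapAlleles(tableB)
    accs <- intersect(names(am), intersect(names(hapA), names(hapB)))
    comboMeans <- matrix(NA_real_, 2, 2)
    comboN <- matrix(0L, 2, 2)
    for (ia in 1:2) for (ib in 1:2) {
      grp <- accs[hapA[accs] == hapLevels$A[ia] &
                  hapB[accs] == hapLevels$B[ib]]
      vals <- am[grp]
      comboN[ia, ib] <- length(vals)
      if (length(vals)) comboMeans[ia, ib] <- mean(vals)
      if (length(vals) > 1) comboSd[ia, ib] <- stats::sd(vals)
    }
    if (any(is.na(marginals))) {
      mA <- mean(am[accs][hapA[accs] == hapLevels$A["elite"]]) -
            mean(am[accs][hapA[accs] == hapLevels$A["ref"]])
      mB <- mean(am[accs][hapB[accs] == hapLevels$B["elite"]]) -
            mean(am[accs][hapB[accs] == hapLevels$B["ref"]])
      marginals <- c(A = mA, B = mB)
    }
  } else {
    comboMeans <- as.matrix(comboMeans)
    stopifnot(identical(dim(comboMeans), c(2L, 2L)))
    if (is.null(comboN)) comboN <- matrix(0L, 2, 2)
  }
  if (sum(!is.na(comboMeans)) < 2)
    stop("need at least 2 populated haplotype combinations")
  if (any(comboN > 0 & comboN < 2))
    .msg("combination(s) with fewer than 2 accessions flagged: %s",
         paste(which(comboN > 0 & comboN < 2), collapse = ","))
  dimnames(comboMeans) <- dimnames(comboN) <- dimnames(comboSd) <-
    list(unname(hapLevels$A), unname(hapLevels$B))

  cond <- c(A.refB = comboMeans[2, 1] - comboMeans[1, 1],
            A.eliteB = comboMeans[2, 2] - comboMeans[1, 2],
            B.refA = comboMeans[1, 2] - comboMeans[1, 1],
            B.eliteA = comboMeans[2, 2] - comboMeans[2, 1])
  total <- comboMeans[2, 2] - comboMeans[1, 1]
  marginals <- marginals[c("A", "B")]
  names(marginals) <- c("A", "B")
  new("InteractionDecomposition", loci = loci, hapLevels = hapLevels,
      comboMeans = comboMeans, comboN = matrix(as.integer(comboN), 2, 2,
        dimnames = dimnames(comboN)),
      comboSd = comboSd, conditionals = cond, total = unname(total),
      marginals = marginals,
      synergyMarginals = unname(total - sum(marginals)),
      synergyCombos = unname(total - cond[["A.refB"]] - cond[["B.refA"]]))
}

#' Context dependence of one locus's effect
#'
#' Relates a locus's conditional effects inside the decomposition to its
#' marginal (single-locus) effect: the percent reduction of its effect in
#' the partner's reference context, and the fold change (ratio) plus
#' fold-excess ((conditional - marginal)/marginal) of its effect in the
#' partner's elite context.
#'
#' @param x an \code{InteractionDecomposition} with marginals available
#' @param locus \code{"A"} or \code{"B"}
#' @return named list: marginal, condRef, condElite, reductionPct, fold,
#'   foldExcess
#' @export
effectContext <- function(x, locus = c("B", "A")) {
  locus <- match.arg(locus)
  m <- x@marginals[[locus]]
  if (is.na(m)) stop("marginal effect of locus ", locus, " unavailable")
  condRef <- x@conditionals[[paste0(locus, ".ref", setdiff(c("A", "B"),
                                                           locus))]]
  condElite <- x@conditionals[[paste0(locus, ".elite", setdiff(c("A", "B"),
                                                               locus))]]
  list(marginal = m, condRef = condRef, condElite = condElite,
       reductionPct = 100 * (m - condRef) / m,
       fold = condElite / m,
       foldExcess = (condElite - m) / m)
}

#' Haplotype effects across many traits
#'
#' Applies \code{\link{haplotypeEffect}} to each trait, skipping (with a
#' log message) traits that are absent or whose groups are too small;
#' results are ordered by decreasing absolute percent effect.
#'
#' @param phenotypes phenotype data.frame
#' @param table a \code{HaplotypeTable}
#' @param traits trait codes; defaults to all traits present
#' @return data.frame of effect estimates
#' @export
multiTraitEffects <- function(phenotypes, table,
                              traits = unique(phenotypes$trait)) {
  rows <- lapply(traits, function(tr) {
    tryCatch(haplotypeEffect(phenotypes, table, tr),
             error = function(e) {
               .msg("trait %s skipped: %s", tr, conditionMessage(e))
               NULL
             })
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(NULL)
  out <- out[order(-abs(out$percent)), ]
  rownames(out) <- NULL
  out
}
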