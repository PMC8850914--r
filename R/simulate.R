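#' Simulation configuration
#'
#' Bundles every tunable of the synthetic pedigree generator. The defaults
#' emulate the study conditions the pipeline targets: a ~19-accession Sea
#' Island cotton style pedigree (12 founder varieties, 7 serial selections),
#' SNP density 0.6 per kb, Poisson recombination with on average one
#' crossover per chromosome per meiosis, directed selection fixing the elite
#' target-gene haplotype (GAG to AGT) from the third breeding stage onward,
#' a quantitative trait (fiber strength, cN/tex) controlled by a main-effect
#' gene, a minor-effect partner gene and a positive synergy between their
#' elite haplotypes, phenotyping over 3 locations x 2 years, and a
#' 2-accession x 6-timepoint x 3-replicate fiber expression experiment with
#' a planted co-expression hub and late-stage differential expression.
#'
#' @param seed integer master seed; all stage seeds derive from it
#' @param nFounders number of founder varieties
#' @param nDerived number of serially bred (non-founder) accessions
#' @param chromNames chromosome names; prefixes A/D mark the subgenomes
#' @param chromLenBp chromosome length in bp (>= 4e6 so the fixed gene
#'   layout fits)
#' @param snpDensity SNPs per kb
#' @param recombMean Poisson mean crossovers per chromosome per meiosis
#' @param selectFromGen breeding stage from which the elite target-gene
#'   haplotype is forced (Inf disables selection)
#' @param envLocations,envYears phenotyping environments (crossed)
#' @param selectionDragBp length of flanking sequence dragged along with the
#'   forced haplotype on each side (linkage drag)
#' @param envShiftSd SD of the common environment shift per (trait,
#'   environment)
#' @param residSd residual phenotype SD (trait units)
#' @param traitBaselines named baseline per trait
#' @param effects per-trait effect sizes: \code{betaA} (elite main-gene
#'   haplotype), \code{betaB} (elite partner allele), \code{gamma}
#'   (synergy when both are elite)
#' @param exprReps replicates per (accession, stage) in the expression
#'   experiment
#' @param exprNoiseSd residual SD on the log2(FPKM+1) scale
#' @param deShift planted log2 shift of the hub module at 20/25 DPA in the
#'   high-FS accession
#' @param moduleSize planted co-expression module size (hub + members)
#' @param nStageDe number of additional stage-specific DE genes
#' @param nFsPanel size of the trait-related expression panel
#' @return a list of class \code{SimConfig}
#' @export
simConfig <- function(seed = 1L, nFounders = 12L, nDerived = 7L,
    chromNames = c("A01", "D01"), chromLenBp = 1e7, snpDensity = 0.6,
    recombMean = 1, selectFromGen = 3L,
    envLocations = c("Alar", "Awat", "Korla"), envYears = c("Y1", "Y2"),
    envShiftSd = 1.0, residSd = 2.0,
    traitBaselines = c(FS = 38.05, FL = 36.5, FU = 85, FM = 4.0, FE = 6.5,
                       FBN = 16, BN = 7.0, SBW = 3.0, LP = 35, SI = 11.5,
                       LY = 1500, SY = 4000),
    effects = list(FS = c(betaA = 4.56, betaB = 0.15, gamma = 2.30),
                   BN = c(betaA = 1.34, betaB = 0, gamma = 0)),
    selectionDragBp = 5e5,
    exprReps = 3L, exprNoiseSd = 0.3, deShift = 3.0, moduleSize = 12L,
    nStageDe = 2L, nFsPanel = 69L) {
  stopifnot(chromLenBp >= 4e6, nFounders >= 2, snpDensity > 0,
            recombMean >= 0, selectionDragBp >= 0,
            selectionDragBp <= 1.49e6)
  cfg <- list(seed = as.integer(seed), nFounders = as.integer(nFounders),
    nDerived = as.integer(nDerived), chromNames = chromNames,
    chromLenBp = chromLenBp, snpDensity = snpDensity,
    recombMean = recombMean, selectFromGen = selectFromGen,
    envLocations = envLocations, envYears = envYears,
    envShiftSd = envShiftSd, residSd = residSd,
    selectionDragBp = selectionDragBp,
    traitBaselines = traitBaselines, effects = effects,
    exprReps = as.integer(exprReps), exprNoiseSd = exprNoiseSd,
    deShift = deShift, moduleSize = as.integer(moduleSize),
    nStageDe = as.integer(nStageDe), nFsPanel = as.integer(nFsPanel))
  class(cfg) <- "SimConfig"
  cfg
}

# fixed layout of the two focal genes and their haplotype-defining SNPs.
# The target gene is a 3-exon model on the A chromosome whose elite
# haplotype AGT carries one promoter SNP, one Arg->Gly nonsynonymous SNP
# (AGA -> GGA) and one Glu->stop stop-gain SNP (GAA -> TAA); the partner
# gene carries one Ala->Thr SNP (GCC -> ACC).
.simLayout <- function(cfg) {
  chA <- cfg$chromNames[1]
  chB <- cfg$chromNames[length(cfg$chromNames)]
  list(
    targetId = sprintf("Gsim_%sG000200", chA),
    partnerId = sprintf("Gsim_%sG000300", chB),
    target = list(chrom = chA, strand = "+", txStart = 2000001L,
      txEnd = 2003000L,
      exons = cbind(start = c(2000001L, 2001001L, 2002401L),
                    end = c(2000300L, 2001600L, 2003000L)),
      promoter = c(1998001L, 2000000L)),
    partner = list(chrom = chB, strand = "+", txStart = 3000001L,
      txEnd = 3001200L,
      exons = cbind(start = 3000001L, end = 3001200L),
      promoter = c(2998001L, 3000000L)),
    hapSnps = data.frame(
      chrom = c(chA, chA, chA, chB),
      pos = c(1999500L, 2001199L, 2002500L, 3000301L),
      ref = c("G", "A", "G", "G"),
      alt = c("A", "G", "T", "A"),
      inPromoter = c(TRUE, FALSE, FALSE, FALSE),
      stringsAsFactors = FALSE),
    # codon contexts planted in the genome (genomic plus strand)
    codonPlants = data.frame(
      chrom = c(chA, chA, chB),
      start = c(2001199L, 2002500L, 3000301L),
      seq = c("AGA", "GAA", "GCC"), stringsAsFactors = FALSE),
    # selection fixes the target haplotype together with a flanking
    # linkage-drag block, as directed selection does in practice
    forcedRegion = c(1998001L - cfg$selectionDragBp,
                     2003000L + cfg$selectionDragBp),
    excludeZones = stats::setNames(
      list(c(1995001L, 2006000L), c(2995001L, 3004000L)), c(chA, chB)),
    eliteHap = "AGT", refHap = "GAG")
}

#' Gene models of the simulated genome
#'
#' Deterministic (no RNG): the 3-exon target gene and single-exon partner
#' gene at fixed positions, plus single-exon decoy genes tiled every 250 kb.
#'
#' @param cfg a \code{SimConfig}
#' @return a \code{GeneModelSet}
#' @export
simGeneModels <- function(cfg) {
  lay <- .simLayout(cfg)
  rows <- list()
  addGene <- function(id, chrom, strand, exons) {
    rows[[length(rows) + 1L]] <<- list(id = id, chrom = chrom,
      strand = strand, exons = exons)
  }
  addGene(lay$targetId, lay$target$chrom, lay$target$strand,
          lay$target$exons)
  addGene(lay$partnerId, lay$partner$chrom, lay$partner$strand,
          lay$partner$exons)
  for (ch in cfg$chromNames) {
    zone <- lay$excludeZones[[ch]]
    starts <- seq(100001L, cfg$chromLenBp - 5000L, by = 250000L)
    if (!is.null(zone))
      starts <- starts[starts + 2999L < zone[1] | starts > zone[2]]
    for (i in seq_along(starts)) {
      addGene(sprintf("Gsim_%sG%06d", ch, 1000L + i), ch, "+",
              cbind(start = starts[i], end = starts[i] + 2999L))
    }
  }
  ids <- vapply(rows, `[[`, character(1), "id")
  genes <- GenomicRanges::GRanges(
    vapply(rows, `[[`, character(1), "chrom"),
    IRanges::IRanges(vapply(rows, function(r) min(r$exons[, "start"]),
                            numeric(1)),
                     vapply(rows, function(r) max(r$exons[, "end"]),
                            numeric(1))),
    strand = vapply(rows, `[[`, character(1), "strand"),
    gene_id = ids)
  names(genes) <- ids
  grl <- lapply(rows, function(r)
    GenomicRanges::GRanges(r$chrom,
      IRanges::IRanges(r$exons[, "start"], r$exons[, "end"])))
  names(grl) <- ids
  grl <- GenomicRanges::GRangesList(grl)
  new("GeneModelSet", genes = genes, exons = grl, cds = grl)
}

#' Default serial-breeding pedigree
#'
#' Founders P01, P02, ... feed a chain of derived accessions D1..Dk
#' (D1 = P01 x P02, then each Dk = D(k-1) x the next founder, wrapping when
#' founders run out); the last derived accession is the target. Founders
#' beyond those used remain panel members without descendants.
#'
#' @param cfg a \code{SimConfig}
#' @return a \code{PedigreeGraph}
#' @export
simPedigree <- function(cfg) {
  fo <- sprintf("P%02d", seq_len(cfg$nFounders))
  edges <- data.frame(parent = character(), child = character())
  for (k in seq_len(cfg$nDerived)) {
    child <- sprintf("D%d", k)
    p1 <- if (k == 1) fo[1] else sprintf("D%d", k - 1)
    p2 <- fo[(k %% cfg$nFounders) + 1L]
    edges <- rbind(edges, data.frame(parent = c(p1, p2), child = child))
  }
  PedigreeGraph(edges, sprintf("D%d", cfg$nDerived))
}

#' Simulate founder genotypes
#'
#' Background SNP positions are drawn uniformly per chromosome at the
#' configured density (excluding the focal-gene neighborhoods, where only
#' the planted haplotype SNPs segregate); alternate-allele frequencies are
#' uniform on [0.05, 0.5]; founders are fully homozygous (inbred lines) and
#' every site is polymorphic among founders by construction (monomorphic
#' draws get one founder flipped). The elite target haplotype is carried by
#' founder P04 only; the elite partner allele by the odd-numbered founders.
#'
#' @param cfg a \code{SimConfig}
#' @return a \code{GenotypeMatrix} of the founders
#' @export
simulateFounders <- function(cfg) {
  set.seed(cfg$seed + 101L)
  lay <- .simLayout(cfg)
  fo <- sprintf("P%02d", seq_len(cfg$nFounders))
  sitesList <- list()
  for (ch in cfg$chromNames) {
    n <- round(cfg$chromLenBp / 1000 * cfg$snpDensity)
    pos <- sort(sample.int(cfg$chromLenBp, n))
    zone <- lay$excludeZones[[ch]]
    if (!is.null(zone)) pos <- pos[pos < zone[1] | pos > zone[2]]
    ref <- sample(c("A", "C", "G", "T"), length(pos), replace = TRUE)
    alt <- vapply(ref, function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1),
      USE.NAMES = FALSE)
    df <- data.frame(chrom = ch, pos = pos, ref = ref, alt = alt,
                     planted = FALSE, stringsAsFactors = FALSE)
    hs <- lay$hapSnps[lay$hapSnps$chrom == ch, , drop = FALSE]
    if (nrow(hs))
      df <- rbind(df, data.frame(chrom = ch, pos = hs$pos, ref = hs$ref,
                                 alt = hs$alt, planted = TRUE,
                                 stringsAsFactors = FALSE))
    df <- df[order(df$pos), ]
    sitesList[[ch]] <- df
  }
  siteDf <- do.call(rbind, sitesList)
  nS <- nrow(siteDf)
  p <- stats::runif(nS, 0.05, 0.5)
  alle <- matrix(stats::rbinom(nS * cfg$nFounders, 1L, p), nS,
                 cfg$nFounders, dimnames = list(NULL, fo))
  mono <- rowSums(alle) %in% c(0L, cfg$nFounders)
  if (any(mono)) {
    flip <- sample.int(cfg$nFounders, sum(mono), replace = TRUE)
    alle[cbind(which(mono), flip)] <- 1L - alle[cbind(which(mono), flip)]
  }
  # planted haplotype SNPs: target-gene SNPs elite only in P04 (when
  # present), partner SNP elite in odd founders
  hk <- paste(siteDf$chrom, siteDf$pos)
  donor <- if (cfg$nFounders >= 4L) "P04" else fo[cfg$nFounders]
  for (i in seq_len(nrow(lay$hapSnps))) {
    row <- match(paste(lay$hapSnps$chrom[i], lay$hapSnps$pos[i]), hk)
    if (i < 4) {
      alle[row, ] <- 0L
      alle[row, donor] <- 1L
    } else {
      alle[row, ] <- as.integer(seq_len(cfg$nFounders) %% 2L == 1L)
    }
  }
  gr <- GenomicRanges::GRanges(siteDf$chrom,
    IRanges::IRanges(siteDf$pos, width = 1), ref = siteDf$ref,
    alt = siteDf$alt, qual = round(stats::runif(nS, 30, 90), 1))
  GenotypeMatrix(gr, 2L * alle)
}

# one meiosis: mosaic of two parental chromosomes with Poisson crossovers
.crossoverSegments <- function(len, parents, recombMean) {
  if (length(parents) == 1L)
    return(data.frame(start = 1, end = len, donor = parents,
                      stringsAsFactors = FALSE))
  k <- stats::rpois(1, recombMean)
  bps <- sort(unique(floor(stats::runif(k, 1, len))))
  bps <- bps[bps >= 1 & bps < len]
  starts <- c(1, bps + 1)
  ends <- c(bps, len)
  first <- sample(parents, 1)
  donors <- rep_len(c(first, setdiff(parents, first)), length(starts))
  data.frame(start = starts, end = ends, donor = donors,
             stringsAsFactors = FALSE)
}

#' Simulate descent through the pedigree
#'
#' Each derived accession's chromosome is a mosaic of parental segments
#' (Poisson crossover count, uniform breakpoints, no interference) that is
#' then fixed by selfing, so every accession stays homozygous. From breeding
#' stage \code{selectFromGen} onward the segment spanning the target gene
#' (promoter through transcript end) is forced to come from a parent
#' carrying the elite haplotype, emulating directed selection; a config
#' error is raised when no parent carries it. The returned truth records
#' every segment's immediate donor and its founder origin.
#'
#' @param founders \code{GenotypeMatrix} from \code{\link{simulateFounders}}
#' @param pedigree a \code{PedigreeGraph}
#' @param cfg a \code{SimConfig}
#' @return list with \code{genotypes} (all accessions), \code{truth} (class
#'   \code{SimTruth}: \code{parentSegments}, \code{founderOrigin},
#'   \code{hapTarget}, \code{eliteA}, \code{eliteB}, \code{effects},
#'   \code{targetId}, \code{partnerId})
#' @export
simulateDescent <- function(founders, pedigree, cfg) {
  set.seed(cfg$seed + 202L)
  lay <- .simLayout(cfg)
  gr <- sites(founders)
  chrom <- as.character(GenomeInfoDb::seqnames(gr))
  pos <- BiocGenerics::start(gr)
  chroms <- cfg$chromNames
  len <- cfg$chromLenBp
  alle <- genoCalls(founders) / 2L
  fo <- accessions(founders)

  ed <- pedEdges(pedigree)
  order <- pedAccessions(pedigree)
  children <- setdiff(order, fo)
  gen <- stats::setNames(rep(0L, length(order)), order)
  for (acc in order) {
    ps <- ed$parent[ed$child == acc]
    if (length(ps)) gen[acc] <- max(gen[ps]) + 1L
  }

  hk <- paste(lay$hapSnps$chrom, lay$hapSnps$pos)
  hapRows <- match(hk, paste(chrom, pos))
  origins <- list()
  for (f in fo)
    origins[[f]] <- lapply(stats::setNames(chroms, chroms), function(ch)
      data.frame(start = 1, end = len, founder = f,
                 stringsAsFactors = FALSE))

  allAlle <- alle
  segRows <- list()
  for (acc in children) {
    ps <- ed$parent[ed$child == acc]
    accAlle <- integer(nrow(alle))
    accOrigin <- list()
    for (ch in chroms) {
      segs <- .crossoverSegments(len, ps, cfg$recombMean)
      if (ch == lay$target$chrom && gen[acc] >= cfg$selectFromGen) {
        eliteP <- ps[vapply(ps, function(p)
          all(allAlle[hapRows[1:3], p] == 1L), logical(1))]
        if (!length(eliteP))
          stop("forced elite haplotype absent from the parents of ", acc)
        reg <- lay$forcedRegion
        segs <- .clipIntervals(segs, 1, reg[1] - 1)
        segs <- rbind(segs,
          data.frame(start = reg[1], end = reg[2], donor = eliteP[1],
                     stringsAsFactors = FALSE),
          .clipIntervals(.crossoverSegments(len, ps, cfg$recombMean),
                         reg[2] + 1, len))
        segs <- segs[segs$start <= segs$end, ]
        segs <- segs[order(segs$start), ]
      }
      segs <- .mergeIntervals(segs, "donor")
      idx <- which(chrom == ch)
      orig <- list()
      for (si in seq_len(nrow(segs))) {
        s <- segs[si, ]
        rows <- idx[pos[idx] >= s$start & pos[idx] <= s$end]
        accAlle[rows] <- allAlle[rows, s$donor]
        po <- .clipIntervals(origins[[s$donor]][[ch]], s$start, s$end)
        orig[[length(orig) + 1L]] <- po
      }
      accOrigin[[ch]] <- .mergeIntervals(do.call(rbind, orig), "founder")
      segRows[[length(segRows) + 1L]] <- cbind(
        data.frame(descendant = acc, chrom = ch, stringsAsFactors = FALSE),
        segs)
    }
    origins[[acc]] <- accOrigin
    allAlle <- cbind(allAlle, stats::setNames(data.frame(accAlle), acc))
    allAlle <- as.matrix(allAlle)
  }

  gm <- GenotypeMatrix(gr, 2L * allAlle)
  hapChar <- apply(allAlle[hapRows[1:3], , drop = FALSE], 2, function(a)
    paste(ifelse(a == 1L, lay$hapSnps$alt[1:3], lay$hapSnps$ref[1:3]),
          collapse = ""))
  truth <- list(
    parentSegments = do.call(rbind, segRows),
    founderOrigin = origins,
    hapTarget = hapChar,
    eliteA = hapChar == lay$eliteHap,
    eliteB = allAlle[hapRows[4], ] == 1L,
    effects = cfg$effects,
    targetId = lay$targetId, partnerId = lay$partnerId,
    forcedRegion = lay$forcedRegion)
  class(truth) <- "SimTruth"
  list(genotypes = gm, truth = truth)
}

#' Elite-status table from simulation truth
#'
#' @param truth a \code{SimTruth}
#' @return data.frame: accession, eliteA, eliteB
#' @export
eliteStatus <- function(truth) {
  data.frame(accession = names(truth$eliteA),
             eliteA = unname(truth$eliteA),
             eliteB = unname(truth$eliteB), stringsAsFactors = FALSE)
}

#' Simulate replicated multi-environment phenotypes
#'
#' value = baseline + betaA [elite main haplotype] + betaB [elite partner]
#' + gamma [both elite] + environment shift + N(0, residSd^2), one value per
#' (accession, trait, environment); environments are the crossed locations
#' and years. Environment shifts are common to all accessions, so group
#' differences recover the configured effects exactly when residSd = 0.
#'
#' @param status data.frame (accession, eliteA, eliteB) or a \code{SimTruth}
#' @param cfg a \code{SimConfig}
#' @return phenotype data.frame (accession, trait, environment, value)
#' @export
simulatePhenotypes <- function(status, cfg) {
  set.seed(cfg$seed + 303L)
  if (inherits(status, "SimTruth")) status <- eliteStatus(status)
  envs <- as.vector(outer(cfg$envLocations, cfg$envYears, paste, sep = "_"))
  rows <- list()
  for (tr in names(cfg$traitBaselines)) {
    eff <- cfg$effects[[tr]]
    bA <- if (is.null(eff)) 0 else eff[["betaA"]]
    bB <- if (is.null(eff)) 0 else eff[["betaB"]]
    gg <- if (is.null(eff)) 0 else eff[["gamma"]]
    shift <- stats::setNames(stats::rnorm(length(envs), 0, cfg$envShiftSd),
                             envs)
    g <- cfg$traitBaselines[[tr]] + bA * status$eliteA +
      bB * status$eliteB + gg * (status$eliteA & status$eliteB)
    df <- expand.grid(accession = status$accession, environment = envs,
                      stringsAsFactors = FALSE)
    df$trait <- tr
    df$value <- g[match(df$accession, status$accession)] +
      shift[df$environment] +
      stats::rnorm(nrow(df), 0, cfg$residSd)
    rows[[tr]] <- df[, c("accession", "trait", "environment", "value")]
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate the fiber expression experiment
#'
#' Two accessions (highFS / lowFS) x six stages (0..25 DPA) x replicates,
#' on the log2(FPKM + 1) scale. A co-expression module is planted with
#' exact sample correlations: the hub profile carries the late-stage
#' (20/25 DPA) up-shift in the high-FS accession plus noise, and each
#' member is 0.85 x the standardized hub profile plus an orthogonalized
#' residual, so hub-member correlations are exactly 0.85 (edges at the
#' usual |r| >= 0.8) while member-member correlations are exactly 0.7225
#' (no edge): the hub has maximal degree by construction. Additional
#' stage-specific DE genes (one per sign x stage pattern, |log2FC| drawn
#' from [1.5, 3]) and null genes complete the trait panel.
#'
#' @param cfg a \code{SimConfig}
#' @return list: \code{se} (a \code{SummarizedExperiment}), \code{truth}
#'   (hub, members, candidates, degTruth data.frame, panel)
#' @export
simulateExpression <- function(cfg) {
  set.seed(cfg$seed + 404L)
  gmods <- simGeneModels(cfg)
  lay <- .simLayout(cfg)
  ids <- geneIds(gmods)
  decoys <- setdiff(ids, c(lay$targetId, lay$partnerId))
  nMembers <- cfg$moduleSize - 1L
  panel <- c(lay$targetId, lay$partnerId, decoys)
  panel <- panel[seq_len(min(cfg$nFsPanel, length(panel)))]
  hub <- lay$targetId
  members <- setdiff(panel, hub)[seq_len(nMembers)]
  stageDe <- setdiff(panel, c(hub, members))
  stageDe <- stageDe[seq_len(min(cfg$nStageDe, length(stageDe)))]
  nulls <- setdiff(panel, c(hub, members, stageDe))

  samples <- expand.grid(replicate = seq_len(cfg$exprReps),
    stage = c(0, 5, 10, 15, 20, 25), accession = c("highFS", "lowFS"),
    stringsAsFactors = FALSE)[, c("accession", "stage", "replicate")]
  n <- nrow(samples)
  late <- as.numeric(samples$accession == "highFS" & samples$stage >= 20)

  uRaw <- cfg$deShift * late + stats::rnorm(n, 0, cfg$exprNoiseSd)
  uC <- uRaw - mean(uRaw)
  uNorm <- sqrt(sum(uC^2))
  uN <- uC / uNorm
  # member residuals: orthonormal directions supported on the early-stage
  # samples only, so the 20/25 DPA contrasts of every member carry the
  # shared hub profile and nothing else (planted fold changes stay exact
  # up to the hub noise) while pairwise correlations are exact by
  # construction
  V <- matrix(stats::rnorm(n * nMembers), n, nMembers)
  V[samples$stage >= 20, ] <- 0
  V <- scale(V, center = TRUE, scale = FALSE)
  Q <- qr.Q(qr(cbind(uC, V)))[, 1 + seq_len(nMembers), drop = FALSE]

  y <- matrix(0, length(panel), n,
              dimnames = list(panel, sprintf("S%02d", seq_len(n))))
  base <- stats::setNames(stats::runif(length(panel), 4.5, 7), panel)
  y[hub, ] <- base[hub] + uC
  for (i in seq_along(members))
    y[members[i], ] <- base[members[i]] +
      uNorm * (0.85 * uN + sqrt(1 - 0.85^2) * Q[, i])
  degTruth <- data.frame(gene = rep(c(hub, members), each = 2),
    stage = rep(c(20, 25), cfg$moduleSize),
    true_shift = rep(c(cfg$deShift, rep(0.85 * cfg$deShift, nMembers)),
                     each = 2), stringsAsFactors = FALSE)
  # disjoint stage/sign patterns keep stage-specific genes uncorrelated
  # with one another and with the module
  patterns <- data.frame(stage = c(20, 25), sign = c(1, -1))
  for (i in seq_along(stageDe)) {
    pt <- patterns[((i - 1) %% nrow(patterns)) + 1, ]
    lfc <- pt$sign * stats::runif(1, 1.5, 3)
    pat <- as.numeric(samples$accession == "highFS" &
                      samples$stage == pt$stage)
    y[stageDe[i], ] <- base[stageDe[i]] + lfc * pat +
      stats::rnorm(n, 0, cfg$exprNoiseSd)
    degTruth <- rbind(degTruth, data.frame(gene = stageDe[i],
      stage = pt$stage, true_shift = lfc, stringsAsFactors = FALSE))
  }
  for (g in nulls)
    y[g, ] <- base[g] + stats::rnorm(n, 0, cfg$exprNoiseSd)

  fpkm <- pmax(2^y - 1, 0)
  se <- makeExpressionExperiment(fpkm, samples)
  list(se = se,
       truth = list(hub = hub, members = members,
                    candidates = c(hub, members), stageDe = stageDe,
                    degTruth = degTruth, panel = panel))
}

# deterministic trait -> gene GWAS lists fabricated from truth genes plus
# decoys (GWAS itself is consumed, not computed)
.simGwasSets <- function(cfg) {
  gmods <- simGeneModels(cfg)
  lay <- .simLayout(cfg)
  ids <- geneIds(gmods)
  decoys <- setdiff(ids, c(lay$targetId, lay$partnerId))
  slice <- function(from, k) {
    if (from >= length(decoys)) return(character(0))
    decoys[seq(from + 1, min(from + k, length(decoys)))]
  }
  list(FS = c(lay$targetId, lay$partnerId, slice(0, 80)),
       BN = c(lay$targetId, slice(10, 25)),
       FL = slice(4, 15),
       FU = slice(8, 15))
}

#' Simulate the reference genome sequence
#'
#' Random sequence per chromosome with the focal codon contexts planted and
#' the reference allele of every SNP written in, so variant annotation
#' ref-checks pass.
#'
#' @param cfg a \code{SimConfig}
#' @param gm the simulated \code{GenotypeMatrix} (for SNP reference alleles)
#' @return a named \code{DNAStringSet}
#' @export
simGenome <- function(cfg, gm) {
  set.seed(cfg$seed + 505L)
  lay <- .simLayout(cfg)
  gr <- sites(gm)
  chrom <- as.character(GenomeInfoDb::seqnames(gr))
  out <- lapply(cfg$chromNames, function(ch) {
    s <- sample(c("A", "C", "G", "T"), cfg$chromLenBp, replace = TRUE)
    cp <- lay$codonPlants[lay$codonPlants$chrom == ch, , drop = FALSE]
    for (i in seq_len(nrow(cp)))
      s[cp$start[i] + 0:2] <- strsplit(cp$seq[i], "")[[1]]
    hs <- lay$hapSnps[lay$hapSnps$chrom == ch, , drop = FALSE]
    if (nrow(hs)) s[hs$pos] <- hs$ref
    sel <- chrom == ch
    s[BiocGenerics::start(gr)[sel]] <- S4Vectors::mcols(gr)$ref[sel]
    paste(s, collapse = "")
  })
  names(out) <- cfg$chromNames
  Biostrings::DNAStringSet(unlist(out))
}

#' Run the full synthetic study
#'
#' Founders, pedigree descent, genome, gene models, phenotypes, expression
#' and GWAS lists under one seed. Byte-identical outputs for a fixed
#' configuration.
#'
#' @param cfg a \code{SimConfig}
#' @param genome also build the genome sequence (slowest part)
#' @return named list of all study components
#' @export
simulateStudy <- function(cfg = simConfig(), genome = TRUE) {
  founders <- simulateFounders(cfg)
  ped <- simPedigree(cfg)
  desc <- simulateDescent(founders, ped, cfg)
  phen <- simulatePhenotypes(desc$truth, cfg)
  expr <- simulateExpression(cfg)
  list(config = cfg, founders = founders, pedigree = ped,
       genotypes = desc$genotypes, truth = desc$truth,
       phenotypes = phen, expression = expr,
       geneModels = simGeneModels(cfg),
       gwasSets = .simGwasSets(cfg),
       genome = if (genome) simGenome(cfg, desc$genotypes) else NULL)
}

#' Simulate a natural-population haplotype panel
#'
#' A panel of accessions genotyped at the four haplotype-defining SNPs,
#' with configurable haplotype composition (defaults mimic a 336-accession
#' panel: 193 GAG, 60 AGT, minor variants, the remainder heterozygous and
#' hence unassigned) plus phenotypes under the configured effect model.
#'
#' @param cfg a \code{SimConfig}
#' @param n panel size
#' @param hapCounts named counts of homozygous target-gene haplotypes
#' @param pEliteB probability of the elite partner allele
#' @return list: genotypes, phenotypes, status (accession, eliteA, eliteB,
#'   hapTarget)
#' @export
simulatePopulation <- function(cfg = simConfig(), n = 336L,
    hapCounts = c(GAG = 193L, AGT = 60L, GAT = 30L, AAG = 25L),
    pEliteB = 0.35) {
  set.seed(cfg$seed + 606L)
  stopifnot(sum(hapCounts) <= n)
  lay <- .simLayout(cfg)
  acc <- sprintf("acc%03d", seq_len(n))
  haps <- c(rep(names(hapCounts), hapCounts),
            rep("het", n - sum(hapCounts)))
  haps <- sample(haps)
  hs <- lay$hapSnps
  codes <- matrix(NA_integer_, 4, n, dimnames = list(NULL, acc))
  for (j in seq_len(n)) {
    h <- haps[j]
    base <- if (h == "het") sample(names(hapCounts), 1) else h
    ch <- strsplit(base, "")[[1]]
    codes[1:3, j] <- ifelse(ch == hs$ref[1:3], 0L, 2L)
    if (h == "het") codes[sample(1:3, 1), j] <- 1L
  }
  codes[4, ] <- 2L * stats::rbinom(n, 1, pEliteB)
  gr <- GenomicRanges::GRanges(hs$chrom, IRanges::IRanges(hs$pos, width = 1),
                               ref = hs$ref, alt = hs$alt, qual = 60)
  gm <- GenotypeMatrix(gr, codes)
  status <- data.frame(accession = acc,
    eliteA = haps == lay$eliteHap,
    eliteB = codes[4, ] == 2L, hapTarget = haps, stringsAsFactors = FALSE)
  phen <- simulatePhenotypes(status, cfg)
  list(genotypes = gm, phenotypes = phen, status = status)
}

#' Write a simulated study to disk
#'
#' Emits sim.vcf, sim.gff3, sim.fa, phenotypes.tsv, expression.tsv,
#' samples.tsv, pedigree.tsv, gwas_genes.tsv and truth.json (all plain
#' text; deterministic for a fixed configuration).
#'
#' @param study list from \code{\link{simulateStudy}}
#' @param dir output directory (created)
#' @return the directory, invisibly
#' @export
writeSimulation <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeVcfGenotypes(study$genotypes, file.path(dir, "sim.vcf"))
  if (!is.null(study$genome))
    Biostrings::writeXStringSet(study$genome, file.path(dir, "sim.fa"))

  gm <- study$geneModels
  genes <- geneRanges(gm)
  rows <- list()
  addFeat <- function(chrom, start, end, strand, type, id, parent, phase) {
    rows[[length(rows) + 1L]] <<- data.frame(chrom = chrom, start = start,
      end = end, strand = strand, type = type, ID = id, Parent = parent,
      phase = phase, stringsAsFactors = FALSE)
  }
  for (i in seq_along(genes)) {
    gid <- genes$gene_id[i]
    ch <- as.character(GenomeInfoDb::seqnames(genes))[i]
    std <- as.character(BiocGenerics::strand(genes))[i]
    ex <- geneExons(gm)[[gid]]
    txid <- paste0(gid, ".t1")
    gs <- BiocGenerics::start(genes)[i]
    ge <- BiocGenerics::end(genes)[i]
    addFeat(ch, gs, ge, std, "gene", gid, NA_character_, NA_integer_)
    addFeat(ch, gs, ge, std, "mRNA", txid, gid, NA_integer_)
    es <- BiocGenerics::start(ex)
    ee <- BiocGenerics::end(ex)
    w <- ee - es + 1L
    ph <- as.integer((3 - (cumsum(c(0L, w[-length(w)])) %% 3L)) %% 3L)
    for (k in seq_along(ex)) {
      addFeat(ch, es[k], ee[k], std, "exon", paste0(txid, ".exon", k),
              txid, NA_integer_)
      addFeat(ch, es[k], ee[k], std, "CDS", paste0(txid, ".cds", k),
              txid, ph[k])
    }
  }
  feat <- do.call(rbind, rows)
  gff <- GenomicRanges::GRanges(feat$chrom,
    IRanges::IRanges(feat$start, feat$end), strand = feat$strand,
    type = feat$type, ID = feat$ID,
    Parent = IRanges::CharacterList(lapply(feat$Parent, function(p)
      if (is.na(p)) character(0) else p)),
    phase = feat$phase)
  rtracklayer::export(gff, file.path(dir, "sim.gff3"), format = "gff3")

  utils::write.table(study$phenotypes, file.path(dir, "phenotypes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  se <- study$expression$se
  mat <- SummarizedExperiment::assay(se, "fpkm")
  utils::write.table(cbind(gene = rownames(mat), as.data.frame(mat)),
                     file.path(dir, "expression.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  sm <- as.data.frame(SummarizedExperiment::colData(se))
  sm <- cbind(sample = colnames(mat), sm)
  utils::write.table(sm, file.path(dir, "samples.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(pedEdges(study$pedigree),
                     file.path(dir, "pedigree.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  gw <- do.call(rbind, lapply(names(study$gwasSets), function(tr)
    data.frame(trait = tr, gene_id = study$gwasSets[[tr]],
               stringsAsFactors = FALSE)))
  utils::write.table(gw, file.path(dir, "gwas_genes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  tr <- study$truth
  jsonlite::write_json(list(
    parentSegments = tr$parentSegments,
    founderOrigin = tr$founderOrigin,
    hapTarget = as.list(tr$hapTarget),
    eliteA = as.list(tr$eliteA), eliteB = as.list(tr$eliteB),
    effects = tr$effects, targetId = tr$targetId,
    partnerId = tr$partnerId,
    expressionTruth = study$expression$truth),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "rows")
  invisible(dir)
}
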