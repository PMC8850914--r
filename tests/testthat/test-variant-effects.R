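# build a one-gene genome whose CDS is an arbitrary base string
cdsFixture <- function(cdsSeq, strand = "+", pad = 50L) {
  gseq <- if (strand == "+") {
    paste0(strrep("A", pad), cdsSeq, strrep("A", pad))
  } else {
    paste0(strrep("A", pad),
           as.character(Biostrings::reverseComplement(
             Biostrings::DNAString(cdsSeq))), strrep("A", pad))
  }
  lo <- pad + 1L
  hi <- pad + nchar(cdsSeq)
  gms <- toyGenes(list(list(id = "g1", chrom = "chr1", strand = strand,
                            exons = cbind(lo, hi))))
  list(genome = Biostrings::DNAStringSet(c(chr1 = gseq)),
       gms = gms, lo = lo, hi = hi)
}

snpAt <- function(pos, ref, alt) {
  GenomicRanges::GRanges("chr1", IRanges(pos, width = 1), ref = ref,
                         alt = alt)
}

test_that("codon substitutions from the breeding narrative classify right", {
  # Gly -> Arg: GGA with G->A at the first base
  fx <- cdsFixture("GGATTT")
  ann <- annotateVariants(snpAt(fx$lo, "G", "A"), fx$gms, fx$genome)
  expect_equal(ann$category, "nonsynonymous")
  expect_equal(ann$aa_change, "G1R")
  # stop-gain: GAA (Glu) with G->T in the sense strand
  fx <- cdsFixture("GAATTT")
  ann <- annotateVariants(snpAt(fx$lo, "G", "T"), fx$gms, fx$genome)
  expect_equal(ann$category, "stopgain")
  expect_equal(ann$aa_change, "E1*")
  # Arg -> Gly: AGA with A->G in the sense strand
  fx <- cdsFixture("AGATTT")
  ann <- annotateVariants(snpAt(fx$lo, "A", "G"), fx$gms, fx$genome)
  expect_equal(ann$category, "nonsynonymous")
  expect_equal(ann$aa_change, "R1G")
  # 4-fold degenerate third position: GGT -> GGC stays Gly
  fx <- cdsFixture("GGTTTT")
  ann <- annotateVariants(snpAt(fx$lo + 2L, "T", "C"), fx$gms, fx$genome)
  expect_equal(ann$category, "synonymous")
  # stop-loss: TAA -> CAA
  fx <- cdsFixture("ATGTAA")
  ann <- annotateVariants(snpAt(fx$lo + 3L, "T", "C"), fx$gms, fx$genome)
  expect_equal(ann$category, "stoploss")
})

test_that("classification agrees with brute-force translation for all 3456 strand/codon/position/alternate cases", {
  bases <- c("A", "C", "G", "T")
  codons <- apply(expand.grid(bases, bases, bases)[, 3:1], 1, paste,
                  collapse = "")
  cdsSeq <- paste(codons, collapse = "")     # 64 codons, 192 bp
  for (strand in c("+", "-")) {
    fx <- cdsFixture(cdsSeq, strand)
    poss <- fx$lo:fx$hi
    gchars <- strsplit(as.character(fx$genome[[1]]), "")[[1]]
    refs <- gchars[poss]
    snps <- do.call(c, unname(lapply(seq_along(poss), function(i) {
      alts <- setdiff(bases, refs[i])
      GenomicRanges::GRanges("chr1", IRanges(rep(poss[i], 3), width = 1),
                             ref = refs[i], alt = alts)
    })))
    ann <- annotateVariants(snps, fx$gms, fx$genome)
    expect_equal(nrow(ann), 576L)
    # oracle: coding coordinate arithmetic done from scratch
    cdsPos <- if (strand == "+") ann$pos - fx$lo + 1L else
      fx$hi - ann$pos + 1L
    ci <- (cdsPos - 1L) %/% 3L + 1L
    pic <- (cdsPos - 1L) %% 3L + 1L
    refCodon <- substr(rep(cdsSeq, length(ci)), 3L * ci - 2L, 3L * ci)
    altSense <- if (strand == "+") ann$alt else
      chartr("ACGT", "TGCA", ann$alt)
    expect_identical(ann$category, codonOracle(refCodon, pic, altSense))
    expect_identical(ann$codon_index, ci)
  }
})

test_that("codons are reconstructed across exon junctions on both strands", {
  # CDS = GGA|TTT split 2+4 across an intron
  gseq <- paste0(strrep("C", 50), "GG", strrep("C", 20), "ATTT",
                 strrep("C", 50))
  genome <- Biostrings::DNAStringSet(c(chr1 = gseq))
  gms <- toyGenes(list(list(id = "g1", chrom = "chr1", strand = "+",
    exons = rbind(c(51, 52), c(73, 76)))))
  ann <- annotateVariants(snpAt(51, "G", "A"), gms, genome)
  expect_equal(ann$category, "nonsynonymous")   # GGA -> AGA, G -> R
  expect_equal(ann$aa_change, "G1R")
  # the third base of the junction codon lies in exon 2: GGA -> GGG, Gly
  ann2 <- annotateVariants(snpAt(73, "A", "G"), gms, genome)
  expect_equal(ann2$category, "synonymous")
  expect_equal(ann2$codon_index, 1L)
  # same construct on the minus strand (strand involution)
  gseqM <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(gseq)))
  genomeM <- Biostrings::DNAStringSet(c(chr1 = gseqM))
  L <- nchar(gseq)
  gmsM <- toyGenes(list(list(id = "g1", chrom = "chr1", strand = "-",
    exons = rbind(c(L - 76 + 1, L - 73 + 1), c(L - 52 + 1, L - 51 + 1)))))
  annM <- annotateVariants(snpAt(L - 51 + 1, "C", "T"), gmsM, genomeM)
  expect_equal(annM$category, "nonsynonymous")  # sense G -> A again
  expect_equal(annM$aa_change, "G1R")
})

test_that("non-coding precedence: splicing > UTR > intronic > flank", {
  # gene with UTRs: exon1 [51,100] (UTR5 51-70, CDS 71-100),
  # intron [101,150], exon2 [151,210] (CDS 151-190, UTR3 191-210)
  gseq <- strrep("A", 400)
  genome <- Biostrings::DNAStringSet(c(chr1 = gseq))
  gms <- toyGenes(list(list(id = "g1", chrom = "chr1", strand = "+",
    exons = rbind(c(51, 100), c(151, 210)),
    cds = rbind(c(71, 100), c(151, 190)))))
  cat1 <- function(p) annotateVariants(snpAt(p, "A", "G"), gms,
                                       genome)$category
  expect_equal(cat1(60), "UTR5")
  expect_equal(cat1(200), "UTR3")
  expect_equal(cat1(101), "splicing")   # first intron base
  expect_equal(cat1(102), "splicing")   # second intron base
  expect_equal(cat1(103), "intronic")
  expect_equal(cat1(149), "splicing")
  expect_equal(cat1(125), "intronic")
  expect_equal(cat1(40), "upstream")    # within 2 kb upstream flank
  expect_equal(cat1(250), "downstream")
  # far away from every gene
  expect_equal(annotateVariants(snpAt(3000, "A", "G"), gms,
    Biostrings::DNAStringSet(c(chr1 = strrep("A", 4000))))$category,
    "intergenic")
  # minus-strand gene swaps the flanks
  gmsM <- toyGenes(list(list(id = "g1", chrom = "chr1", strand = "-",
    exons = rbind(c(51, 100), c(151, 210)),
    cds = rbind(c(71, 100), c(151, 190)))))
  expect_equal(annotateVariants(snpAt(40, "A", "G"), gmsM,
                                genome)$category, "downstream")
  expect_equal(annotateVariants(snpAt(250, "A", "G"), gmsM,
                                genome)$category, "upstream")
})

test_that("data errors are caught: ref mismatch and broken frames", {
  fx <- cdsFixture("GGATTT")
  expect_error(annotateVariants(snpAt(fx$lo, "C", "A"), fx$gms, fx$genome),
               "does not match genome")
  # CDS length not divisible by 3: flagged, variants unknown
  gms <- toyGenes(list(list(id = "g1", chrom = "chr1", strand = "+",
                            exons = cbind(51, 54))))
  genome <- Biostrings::DNAStringSet(c(chr1 = strrep("A", 200)))
  expect_warning(ann <- annotateVariants(snpAt(52, "A", "G"), gms, genome),
                 "not a multiple of 3")
  expect_equal(ann$category, "unknown")
})

test_that("the large-effect predicate covers exactly the coding classes", {
  expect_false(isLargeEffect("synonymous"))
  expect_true(isLargeEffect("stoploss"))
  expect_true(isLargeEffect("stopgain"))
  expect_true(isLargeEffect("nonsynonymous"))
  expect_false(isLargeEffect("splicing"))
  expect_false(isLargeEffect("upstream"))
  expect_equal(isLargeEffect(data.frame(category = c("synonymous",
    "nonsynonymous"))), c(FALSE, TRUE))
})

test_that("planted SNP effects in the simulated study match generator truth", {
  cfg <- simConfig(seed = 21, chromLenBp = 4e6)
  st <- simulateStudy(cfg, genome = TRUE)
  hs <- sites(st$genotypes)
  planted <- hs[start(hs) %in% c(1999500L, 2001199L, 2002500L, 3000301L)]
  ann <- annotateVariants(planted, st$geneModels, st$genome)
  ann <- ann[!is.na(ann$gene_id) &
             ann$gene_id %in% c(st$truth$targetId, st$truth$partnerId), ]
  byPos <- setNames(ann$category, ann$pos)
  expect_equal(unname(byPos["1999500"]), "upstream")
  expect_equal(unname(byPos["2001199"]), "nonsynonymous")
  expect_equal(unname(byPos["2002500"]), "stopgain")
  expect_equal(unname(byPos["3000301"]), "nonsynonymous")
  expect_equal(ann$aa_change[ann$pos == 3000301], "A101T")
})
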