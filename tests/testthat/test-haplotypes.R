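test_that("haplotype SNP selection unions gene-body large-effect and promoter SNPs", {
  # + strand gene [5001, 8000]: promoter is [3001, 5000]
  gms <- toyGenes(list(list(id = "g1", chrom = "A01", strand = "+",
                            exons = cbind(5001, 8000))))
  pos <- c(3500L, 5500L, 6000L, 6500L, 9000L)
  codes <- matrix(0L, 5, 4)
  gm <- toyGM(codes, pos = pos)
  eff <- data.frame(chrom = "A01", pos = pos,
    gene_id = c(NA, "g1", "g1", "g1", NA),
    category = c("upstream", "nonsynonymous", "synonymous", "stopgain",
                 "intergenic"), stringsAsFactors = FALSE)
  snps <- selectHapSnps("g1", eff, gm, gms)
  expect_equal(start(snps), c(3500L, 5500L, 6500L))   # syn excluded
  expect_equal(snps$inPromoter, c(TRUE, FALSE, FALSE))
  # - strand: promoter flips to [8001, 10000]
  gmsM <- toyGenes(list(list(id = "g1", chrom = "A01", strand = "-",
                             exons = cbind(5001, 8000))))
  snpsM <- selectHapSnps("g1", eff, gm, gmsM)
  expect_equal(start(snpsM), c(5500L, 6500L, 9000L))
  expect_true(snpsM$inPromoter[3])
  # no qualifying SNPs: empty, logged
  effNone <- eff[eff$category == "synonymous", ]
  expect_message(out <- selectHapSnps("g1", effNone,
    toyGM(matrix(0L, 1, 2), pos = 12000L), gms), "skipped")
  expect_length(out, 0)
})

test_that("haplotype strings concatenate homozygous sense-strand alleles", {
  codes <- matrix(c(0L, 0L, 0L,    # acc1: all hom ref
                    2L, 2L, 2L,    # acc2: all hom alt
                    0L, 1L, 0L,    # acc3: het -> unassigned
                    0L, NA, 0L),   # acc4: missing -> unassigned
                  nrow = 3)
  gm <- toyGM(codes, ref = c("G", "A", "G"), alt = c("A", "G", "T"))
  snps <- sites(gm)
  tab <- assignHaplotypes(gm, snps, "g1")
  al <- hapAlleles(tab)
  expect_equal(unname(al), c("GAG", "AGT", "unassigned", "unassigned"))
  expect_equal(unname(hapFreqs(tab)[c("GAG", "AGT")]), c(0.25, 0.25))
  # ties broken lexicographically: AGT before GAG
  expect_equal(mainHaplotypes(tab), c("AGT", "GAG"))
})

test_that("a simulated panel recovers the two main haplotypes", {
  pop <- simulatePopulation(simConfig(seed = 31))
  gm <- pop$genotypes
  tab <- assignHaplotypes(gm, sites(gm)[1:3], "target")
  expect_equal(mainHaplotypes(tab), c("GAG", "AGT"))
  counts <- table(pop$status$hapTarget)
  expect_equal(sum(hapAlleles(tab) == "GAG"), unname(counts["GAG"]))
  expect_equal(sum(hapAlleles(tab) == "AGT"), unname(counts["AGT"]))
  expect_equal(sum(hapAlleles(tab) == "unassigned"),
               unname(counts["het"]))
})

test_that("haplotype effects report delta, percent and a Welch test", {
  mkPheno <- function(vals1, vals2) {
    data.frame(
      accession = c(sprintf("r%02d", seq_along(vals1)),
                    sprintf("e%02d", seq_along(vals2))),
      trait = "FS", environment = "E1", value = c(vals1, vals2))
  }
  mkTab <- function(n1, n2) {
    snps <- GenomicRanges::GRanges("A01", IRanges(1:3, width = 1),
      ref = c("G", "A", "G"), alt = c("A", "G", "T"), inPromoter = FALSE)
    al <- c(setNames(rep("GAG", n1), sprintf("r%02d", 1:n1)),
            setNames(rep("AGT", n2), sprintf("e%02d", 1:n2)))
    new("HaplotypeTable", geneID = "g1", snps = snps, alleles = al,
        freqs = c(GAG = n1, AGT = n2) / (n1 + n2),
        mainPair = c("GAG", "AGT"))
  }
  # identical groups: no effect
  ph <- mkPheno(c(10, 11, 12), c(10, 11, 12))
  e0 <- haplotypeEffect(ph, mkTab(3, 3), "FS")
  expect_equal(e0$delta, 0)
  expect_equal(e0$percent, 0)
  # constructed group means 38.05 vs 44.66: the printed 6.61 / 17.37%
  ph2 <- mkPheno(c(37.05, 38.05, 39.05), c(43.66, 44.66, 45.66))
  e2 <- haplotypeEffect(ph2, mkTab(3, 3), "FS")
  expect_equal(e2$delta, 6.61)
  expect_equal(round(e2$percent, 2), 17.37)
  expect_equal(e2$p,
    t.test(c(43.66, 44.66, 45.66), c(37.05, 38.05, 39.05))$p.value)
  # degenerate variance: effect reported, p undefined
  ph3 <- mkPheno(c(10, 10), c(12, 12))
  e3 <- haplotypeEffect(ph3, mkTab(2, 2), "FS")
  expect_equal(e3$delta, 2)
  expect_true(is.na(e3$p))
  # environments are averaged within accession first
  ph4 <- rbind(mkPheno(c(10, 11), c(20, 21)),
               transform(mkPheno(c(30, 31), c(40, 41)),
                         environment = "E2"))
  e4 <- haplotypeEffect(ph4, mkTab(2, 2), "FS")
  expect_equal(e4$delta, 10)
})

test_that("noiseless simulations recover the main effect exactly", {
  cfg <- simConfig(seed = 33, residSd = 0,
    effects = list(FS = c(betaA = 5, betaB = 0, gamma = 0)))
  pop <- simulatePopulation(cfg, n = 100,
                            hapCounts = c(GAG = 60, AGT = 30))
  gm <- pop$genotypes
  tab <- assignHaplotypes(gm, sites(gm)[1:3], "target")
  e <- haplotypeEffect(pop$phenotypes, tab, "FS")
  expect_equal(e$delta, 5)
})

test_that("the decomposition reproduces a printed combination ledger", {
  cm <- matrix(c(0, 4.56, 0.15, 7.01), 2, 2)
  dec <- interactionDecomposition(comboMeans = cm,
    marginals = c(A = 6.61, B = 0.25),
    loci = c(A = "mainGene", B = "partnerGene"),
    hapLevels = list(A = c(ref = "GAG", elite = "AGT"),
                     B = c(ref = "G", elite = "A")))
  cond <- conditionalEffects(dec)
  expect_equal(unname(cond["A.refB"]), 4.56)
  expect_equal(unname(cond["A.eliteB"]), 6.86)
  expect_equal(unname(cond["B.refA"]), 0.15)
  expect_equal(unname(cond["B.eliteA"]), 2.45)
  expect_equal(totalTransition(dec), 7.01)
  ec <- effectContext(dec, "B")
  expect_equal(ec$reductionPct, 40)
  expect_equal(ec$foldExcess, 8.8)
  expect_equal(ec$fold, 9.8)
})

test_that("an additive mean table has zero synergy both ways", {
  a <- 3.2; b <- 1.1
  cm <- matrix(c(0, a, b, a + b), 2, 2)
  dec <- interactionDecomposition(comboMeans = cm,
                                  marginals = c(A = a, B = b))
  expect_equal(synergy(dec, "combos"), 0)
  expect_equal(synergy(dec, "marginals"), 0)
})

test_that("noiseless two-locus simulations recover gamma exactly", {
  cfg <- simConfig(seed = 35, residSd = 0)
  pop <- simulatePopulation(cfg, n = 200,
                            hapCounts = c(GAG = 120, AGT = 60))
  dec <- popDecomposition(pop)
  expect_equal(unname(conditionalEffects(dec)["A.refB"]), 4.56)
  expect_equal(unname(conditionalEffects(dec)["B.refA"]), 0.15)
  expect_equal(synergy(dec), 2.30)
  expect_equal(totalTransition(dec), 4.56 + 0.15 + 2.30)
})

test_that("path additivity holds exactly for arbitrary mean tables", {
  set.seed(20250922)
  for (i in 1:50) {
    cm <- matrix(rnorm(4, 0, 10), 2, 2)
    dec <- interactionDecomposition(comboMeans = cm)
    cond <- conditionalEffects(dec)
    expect_equal(unname(cond["A.refB"] + cond["B.eliteA"]),
                 totalTransition(dec), tolerance = 1e-12)
    expect_equal(unname(cond["B.refA"] + cond["A.eliteB"]),
                 totalTransition(dec), tolerance = 1e-12)
  }
})

test_that("decompositions are baseline-invariant and locus-symmetric", {
  cfg <- simConfig(seed = 37)
  pop <- simulatePopulation(cfg, n = 150,
                            hapCounts = c(GAG = 80, AGT = 50))
  dec <- popDecomposition(pop)
  # add a constant to every phenotype value
  pop2 <- pop
  pop2$phenotypes$value <- pop2$phenotypes$value + 100
  dec2 <- popDecomposition(pop2)
  expect_equal(conditionalEffects(dec2), conditionalEffects(dec))
  expect_equal(totalTransition(dec2), totalTransition(dec))
  expect_equal(synergy(dec2), synergy(dec))
  expect_equal(synergy(dec2, "marginals"), synergy(dec, "marginals"))
  # swapping loci permutes labels but preserves total and synergy
  gm <- pop$genotypes
  tA <- assignHaplotypes(gm, sites(gm)[1:3], "geneA")
  tB <- assignHaplotypes(gm, sites(gm)[4], "geneB")
  dAB <- suppressMessages(
    interactionDecomposition(pop$phenotypes, tA, tB, "FS"))
  dBA <- suppressMessages(
    interactionDecomposition(pop$phenotypes, tB, tA, "FS"))
  expect_equal(totalTransition(dBA), totalTransition(dAB))
  expect_equal(synergy(dBA), synergy(dAB))
  expect_equal(unname(conditionalEffects(dBA)["A.refB"]),
               unname(conditionalEffects(dAB)["B.refA"]))
})

test_that("missing combinations yield NA conditionals, never imputations", {
  cm <- matrix(c(0, 4.56, NA, 7.01), 2, 2)
  dec <- interactionDecomposition(comboMeans = cm)
  cond <- conditionalEffects(dec)
  expect_true(is.na(cond["A.eliteB"]))
  expect_true(is.na(cond["B.refA"]))
  expect_equal(unname(cond["A.refB"]), 4.56)
  expect_equal(totalTransition(dec), 7.01)
  expect_error(interactionDecomposition(
    comboMeans = matrix(c(0, NA, NA, NA), 2, 2)), "at least 2")
})

test_that("multi-trait screens find the pleiotropic effects and only those", {
  cfg <- simConfig(seed = 39, residSd = 0, envShiftSd = 0)
  pop <- simulatePopulation(cfg, n = 100,
                            hapCounts = c(GAG = 60, AGT = 30))
  gm <- pop$genotypes
  tab <- assignHaplotypes(gm, sites(gm)[1:3], "target")
  me <- multiTraitEffects(pop$phenotypes, tab)
  expect_equal(nrow(me), 12L)
  nz <- me$trait[abs(me$delta) > 1e-9]
  # effects on FS and BN only at sigma = 0 (partner/epistasis absent in
  # the marginal only through the eliteB mix; eliteB is independent of the
  # haplotype so deltas on other traits are exactly zero)
  expect_setequal(nz, c("FS", "BN"))
  # sorted by |percent|; single-trait call agrees with haplotypeEffect
  expect_equal(me$percent, me$percent[order(-abs(me$percent))])
  one <- multiTraitEffects(pop$phenotypes, tab, "FS")
  expect_equal(one, haplotypeEffect(pop$phenotypes, tab, "FS"))
  # absent traits are skipped with a log message
  expect_message(multiTraitEffects(pop$phenotypes, tab, c("FS", "XX")),
                 "skipped")
})

test_that("effect signs are recovered under realistic noise", {
  hits <- sapply(1:30, function(s) {
    cfg <- simConfig(seed = 1000 + s)
    pop <- simulatePopulation(cfg, n = 250,
                              hapCounts = c(GAG = 150, AGT = 80))
    gm <- pop$genotypes
    tab <- assignHaplotypes(gm, sites(gm)[1:3], "target")
    c(haplotypeEffect(pop$phenotypes, tab, "FS")$delta > 0,
      haplotypeEffect(pop$phenotypes, tab, "BN")$delta > 0)
  })
  # |effect|/sigma is ~5.6 (FS) and ~1.6 (BN) on accession means: the sign
  # must essentially always be right
  expect_gte(mean(hits[1, ]), 0.95)
  expect_gte(mean(hits[2, ]), 0.95)
})
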