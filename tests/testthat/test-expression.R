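mkSE <- function(fpkm, stages = rep(c(0, 20), each = 6),
                 acc = rep(rep(c("highFS", "lowFS"), each = 3), 2)) {
  makeExpressionExperiment(fpkm,
    data.frame(accession = acc, stage = stages,
               replicate = rep(1:3, length(stages) / 3)))
}

test_that("the DEG screen applies the compound fold-change/p criterion", {
  # gene A: high 30 vs low 9.33 FPKM -> log2(31/10.33) ~ 1.585
  fpkm <- rbind(
    A = c(5, 5, 5, 5, 5, 5, 29, 30, 31, 9, 9.33, 9.66),
    B = c(5, 5, 5, 5, 5, 5, 20, 20, 20, 20, 20, 20),
    C = c(5, 5, 5, 5, 5, 5, 40, 41, 42, 22, 21, 20))
  se <- mkSE(fpkm)
  d <- degTest(se, 20)
  a <- d[d$gene == "A", ]
  expect_equal(a$log2fc, log2(31 / ((9 + 9.33 + 9.66) / 3 + 1)),
               tolerance = 1e-9)
  expect_true(a$is_deg)
  # equal means: zero fold change, not a DEG
  expect_equal(d$log2fc[d$gene == "B"], 0)
  expect_false(d$is_deg[d$gene == "B"])
  # |log2fc| < 1 fails even with a small p
  expect_false(d$is_deg[d$gene == "C"])
  # the p-value is a Welch t-test on log2(FPKM + 1)
  expect_equal(a$p, t.test(log2(c(29, 30, 31) + 1),
                           log2(c(9, 9.33, 9.66) + 1))$p.value)
  expect_error(degTest(se, 15), "absent")
  # permutation of gene order never changes flags
  se2 <- mkSE(fpkm[c(3, 1, 2), ])
  d2 <- degTest(se2, 20)
  expect_equal(d2$is_deg[match(d$gene, d2$gene)], d$is_deg)
})

test_that("fold change is still reported when replicates are missing", {
  fpkm <- matrix(c(10, 40), 1, 2, dimnames = list("A", NULL))
  se <- makeExpressionExperiment(fpkm,
    data.frame(accession = c("highFS", "lowFS"), stage = 20,
               replicate = 1))
  d <- degTest(se, 20)
  expect_true(is.na(d$p))
  expect_false(d$is_deg)
  expect_equal(d$log2fc, log2(11 / 41))
})

test_that("the correlation network matches a naive double loop", {
  set.seed(20250922)
  fpkm <- matrix(rexp(20 * 12, 1 / 20), 20, 12,
                 dimnames = list(sprintf("g%02d", 1:20), NULL))
  se <- mkSE(fpkm)
  g <- buildCoexpression(se, minAbsR = 0.5)
  ref <- bruteEdges(fpkm, 0.5)
  el <- igraph::as_edgelist(g)
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  expect_setequal(if (nrow(el)) key(el[, 1], el[, 2]) else character(0),
                  if (is.null(ref)) character(0) else key(ref$a, ref$b))
  # a duplicated gene produces a perfect edge; a negated pattern is caught
  # by the |r| rule with weight -1
  y <- log2(fpkm[1, ] + 1)
  fpkm2 <- rbind(fpkm[1:2, ], dup = fpkm[1, ], neg = 2^(max(y) + 1 - y) - 1)
  g2 <- buildCoexpression(mkSE(fpkm2), minAbsR = 0.99)
  el2 <- igraph::as_edgelist(g2)
  pairs <- key(el2[, 1], el2[, 2])
  expect_true(key("g01", "dup") %in% pairs)
  expect_true(key("g01", "neg") %in% pairs)
  w <- igraph::E(g2)$weight[match(key("g01", "neg"),
                                  key(el2[, 1], el2[, 2]))]
  expect_equal(w, -1, tolerance = 1e-9)
  # zero-variance genes are excluded with a message
  fpkm3 <- rbind(fpkm[1:3, ], flat = rep(7, 12))
  expect_message(g3 <- buildCoexpression(mkSE(fpkm3), minAbsR = 0.5),
                 "zero-variance")
  expect_false("flat" %in% igraph::V(g3)$name)
})

test_that("hub centralities behave canonically on reference graphs", {
  # star K1,5: the center tops every method that can rank it
  star <- igraph::make_star(6, mode = "undirected", center = 1)
  igraph::V(star)$name <- c("hub", paste0("leaf", 1:5))
  hr <- hubConsensus(star, topK = 2)
  expect_equal(names(sort(hubConsensusRanks(hr)))[1], "hub")
  expect_equal(topHubs(hr)[1], "hub")
  sc <- hubScores(star)
  expect_equal(unname(sc["hub", "Degree"]), 5)
  expect_equal(unname(sc["hub", "MNC"]), 1)      # neighbors are isolated
  expect_equal(unname(sc["hub", "MCC"]), 5)      # five maximal 2-cliques
  expect_equal(unname(sc["hub", "Stress"]), 10)  # C(5,2) paths through it
  expect_equal(unname(sc["hub", "Closeness"]), 1)
  # clique of 4 plus a pendant: the pendant ranks last
  g <- igraph::make_full_graph(4)
  g <- igraph::add_vertices(g, 1)
  g <- igraph::add_edges(g, c(4, 5))
  igraph::V(g)$name <- c(paste0("c", 1:4), "pendant")
  hr2 <- hubConsensus(g, topK = 4)
  expect_equal(names(sort(hubConsensusRanks(hr2), decreasing = TRUE))[1],
               "pendant")
  expect_false("pendant" %in% topHubs(hr2))
  sc2 <- hubScores(g)
  expect_equal(unname(sc2[, "MCC"]), c(6, 6, 6, 7, 1))  # 3! clique + edge
  expect_equal(unname(sc2[, "MNC"]), c(3, 3, 3, 3, 1))
  expect_equal(unname(sc2["c4", "DMNC"]), 3 / 3^1.7)
  # empty network: empty report
  e <- hubConsensus(igraph::make_empty_graph(0, directed = FALSE))
  expect_length(topHubs(e), 0)
})

test_that("raising thresholds is monotone for edges and candidates", {
  cfg <- simConfig(seed = 41)
  ex <- simulateExpression(cfg)
  es <- sapply(c(0.5, 0.7, 0.9), function(r)
    igraph::ecount(suppressMessages(
      buildCoexpression(ex$se, ex$truth$panel, minAbsR = r))))
  expect_true(all(diff(es) <= 0))
  g <- suppressMessages(buildCoexpression(ex$se, ex$truth$panel,
                                          minAbsR = 0.8))
  d <- rbind(degTest(ex$se, 20), degTest(ex$se, 25))
  cands <- lapply(c(5, 12, 20), function(k)
    prioritizeCandidates(d, hubConsensus(g, topK = k))$gene)
  expect_true(all(cands[[1]] %in% cands[[2]]))
  expect_true(all(cands[[2]] %in% cands[[3]]))
})

test_that("hub-and-late-DEG candidates mirror the planted module", {
  cfg <- simConfig(seed = 43, exprNoiseSd = 0.1)
  ex <- simulateExpression(cfg)
  tr <- ex$truth
  g <- suppressMessages(buildCoexpression(ex$se, tr$panel, minAbsR = 0.8))
  hr <- hubConsensus(g, topK = cfg$moduleSize)
  d20 <- degTest(ex$se, 20)
  d25 <- degTest(ex$se, 25)
  cand <- prioritizeCandidates(list(d20, d25), hr)
  expect_setequal(cand$gene, tr$candidates)
  # module genes are shifted at both late stages
  expect_true(all(cand$two_stage[cand$gene %in% tr$candidates]))
  expect_equal(unique(cand$stages), "20;25")
  # a hub without DEG status is excluded
  noDeg <- d20; noDeg$is_deg <- FALSE
  noDeg25 <- d25; noDeg25$is_deg <- FALSE
  expect_equal(nrow(prioritizeCandidates(list(noDeg, noDeg25), hr)), 0L)
  # a DEG that is not a hub is excluded
  stage <- tr$stageDe[1]
  expect_false(stage %in% cand$gene)
  expect_true(any(d20$is_deg[d20$gene == stage] |
                  d25$is_deg[d25$gene == stage]))
})
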