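#' Assemble an expression experiment
#'
#' Wraps an FPKM matrix and its sample metadata in a
#' \code{SummarizedExperiment} (assay \code{"fpkm"}; colData columns
#' \code{accession} in \{highFS, lowFS\}, \code{stage} in days post anthesis,
#' \code{replicate}).
#'
#' @param fpkm genes x samples numeric matrix, FPKM >= 0
#' @param samples data.frame with columns \code{accession}, \code{stage},
#'   \code{replicate}; rows follow the matrix columns
#' @return a \code{SummarizedExperiment}
#' @export
makeExpressionExperiment <- function(fpkm, samples) {
  stopifnot(ncol(fpkm) == nrow(samples), all(fpkm >= 0))
  need <- c("accession", "stage", "replicate")
  stopifnot(all(need %in% colnames(samples)))
  SummarizedExperiment::SummarizedExperiment(
    assays = list(fpkm = as.matrix(fpkm)),
    colData = S4Vectors::DataFrame(samples[, need]))
}

#' Read an expression matrix and sample sheet
#'
#' @param exprPath TSV of FPKM values, first column \code{gene}
#' @param samplesPath TSV with columns \code{sample}, \code{accession},
#'   \code{stage}, \code{replicate}
#' @return a \code{SummarizedExperiment}
#' @export
readExpressionExperiment <- function(exprPath, samplesPath) {
  ex <- utils::read.delim(exprPath, check.names = FALSE)
  mat <- as.matrix(ex[, -1, drop = FALSE])
  rownames(mat) <- ex[[1]]
  sm <- utils::read.delim(samplesPath, stringsAsFactors = FALSE)
  sm <- sm[match(colnames(mat), sm$sample), ]
  makeExpressionExperiment(mat, sm)
}

#' Differential expression screen at one developmental stage
#'
#' For every gene, the fold change between the high- and low-FS accessions
#' at the given stage is log2((mean FPKM_high + 1)/(mean FPKM_low + 1)); the
#' p-value is a Welch two-tailed t-test on log2(FPKM + 1) across replicates
#' (undefined when either accession has < 2 replicates; the fold change is
#' still reported). A gene is a DEG iff p < 0.05 and |log2FC| > 1.
#'
#' @param se a \code{SummarizedExperiment} from
#'   \code{\link{makeExpressionExperiment}}
#' @param stage stage (DPA) to test
#' @param pCutoff,lfcCutoff the compound DEG criterion (defaults 0.05 and 1)
#' @return data.frame: gene, stage, log2fc, p, is_deg
#' @export
degTest <- function(se, stage, pCutoff = 0.05, lfcCutoff = 1) {
  cd <- SummarizedExperiment::colData(se)
  if (!stage %in% cd$stage) stop("stage ", stage, " absent from experiment")
  sel <- cd$stage == stage
  acc <- cd$accession[sel]
  mat <- SummarizedExperiment::assay(se, "fpkm")[, sel, drop = FALSE]
  hi <- mat[, acc == "highFS", drop = FALSE]
  lo <- mat[, acc == "lowFS", drop = FALSE]
  lfc <- log2((rowMeans(hi) + 1) / (rowMeans(lo) + 1))
  p <- rep(NA_real_, nrow(mat))
  if (ncol(hi) >= 2 && ncol(lo) >= 2) {
    lh <- log2(hi + 1)
    ll <- log2(lo + 1)
    p <- vapply(seq_len(nrow(mat)), function(i) {
      tryCatch(stats::t.test(lh[i, ], ll[i, ], var.equal = FALSE)$p.value,
               error = function(e) NA_real_)
    }, numeric(1))
  }
  data.frame(gene = rownames(mat), stage = stage, log2fc = lfc, p = p,
             is_deg = !is.na(p) & p < pCutoff & abs(lfc) > lfcCutoff,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Build a correlation co-expression network
#'
#' Pearson correlation of log2(FPKM + 1) over all samples (all stages,
#' accessions and replicates); an undirected edge joins genes i and j iff
#' |r| >= \code{minAbsR}, with the signed correlation as edge weight. Genes
#' with zero variance are excluded with a log message.
#'
#' @param se a \code{SummarizedExperiment}
#' @param geneSet optional subset of genes to network (e.g. the
#'   trait-related panel)
#' @param minAbsR absolute-correlation threshold for an edge (no default is
#'   asserted as canonical; it must be chosen)
#' @return an undirected weighted \code{igraph} graph whose vertices are the
#'   (variable) genes
#' @export
buildCoexpression <- function(se, geneSet = NULL, minAbsR) {
  mat <- SummarizedExperiment::assay(se, "fpkm")
  if (!is.null(geneSet)) {
    missing <- setdiff(geneSet, rownames(mat))
    if (length(missing))
      warning(length(missing), " gene(s) absent from expression matrix")
    mat <- mat[intersect(geneSet, rownames(mat)), , drop = FALSE]
  }
  if (ncol(mat) < 3) stop("need >= 3 samples for a correlation network")
  lm2 <- log2(mat + 1)
  v <- apply(lm2, 1, stats::var)
  if (any(v == 0)) {
    .msg("%d zero-variance gene(s) excluded from the network", sum(v == 0))
    lm2 <- lm2[v > 0, , drop = FALSE]
  }
  r <- stats::cor(t(lm2))
  adj <- abs(r) >= minAbsR
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  ends <- igraph::as_edgelist(g)
  igraph::E(g)$weight <- r[cbind(ends[, 1], ends[, 2])]
  g
}

# ---- cytoHubba-style centralities -----------------------------------------

# stress centrality: number of shortest paths passing through each vertex
# (enumerated per connected component; intended for modest networks)
.stressCentrality <- function(g) {
  n <- igraph::vcount(g)
  stress <- stats::setNames(numeric(n), igraph::V(g)$name)
  comp <- igraph::components(g)
  for (cid in seq_len(comp$no)) {
    vs <- which(comp$membership == cid)
    if (length(vs) < 3) next
    sub <- igraph::induced_subgraph(g, vs)
    nm <- igraph::V(sub)$name
    for (si in seq_len(length(nm) - 1)) {
      ap <- igraph::all_shortest_paths(sub, from = si,
                                       to = (si + 1):length(nm),
                                       weights = NA)$res
      for (pth in ap) {
        if (length(pth) > 2) {
          inner <- nm[as.integer(pth)[-c(1, length(pth))]]
          stress[inner] <- stress[inner] + 1
        }
      }
    }
  }
  stress
}

# maximum neighborhood component: the largest connected component of the
# subgraph induced by v's neighbors; returns its vertex count and edge count
.mncParts <- function(g, v) {
  nb <- igraph::neighbors(g, v)
  if (!length(nb)) return(c(n = 0, e = 0))
  sub <- igraph::induced_subgraph(g, nb)
  comp <- igraph::components(sub)
  best <- which.max(comp$csize)
  vs <- which(comp$membership == best)
  bc <- igraph::induced_subgraph(sub, vs)
  c(n = igraph::vcount(bc), e = igraph::ecount(bc))
}

#' Hub centrality scores of a co-expression network
#'
#' Computes the clique- and distance-based centralities used for hub-gene
#' consensus ranking: MCC (sum over maximal cliques containing the vertex of
#' (|clique|-1)!), MNC (size of the maximum neighborhood component), DMNC
#' (edges of that component divided by its size to the power 1.7), Degree,
#' Closeness, Betweenness, EcCentricity (reciprocal eccentricity),
#' Radiality, Stress and the local ClusteringCoefficient. Distance-based
#' scores are computed within connected components.
#'
#' @param g an undirected \code{igraph} graph with named vertices
#' @param methods which scores to compute
#' @return genes x methods numeric matrix
#' @export
hubScores <- function(g, methods = c("MCC", "DMNC", "MNC", "Degree",
    "EcCentricity", "Closeness", "Radiality", "Betweenness", "Stress",
    "ClusteringCoefficient")) {
  n <- igraph::vcount(g)
  nm <- igraph::V(g)$name
  out <- matrix(0, n, length(methods), dimnames = list(nm, methods))
  deg <- igraph::degree(g)

  if (any(c("MNC", "DMNC") %in% methods)) {
    parts <- vapply(seq_len(n), function(v) .mncParts(g, v), numeric(2))
    if ("MNC" %in% methods) out[, "MNC"] <- parts["n", ]
    if ("DMNC" %in% methods)
      out[, "DMNC"] <- ifelse(parts["n", ] >= 2,
                              parts["e", ] / parts["n", ]^1.7, 0)
  }
  if ("MCC" %in% methods) {
    mcc <- stats::setNames(numeric(n), nm)
    if (igraph::ecount(g) > 0) {
      for (cl in igraph::max_cliques(g, min = 2)) {
        sz <- length(cl)
        mcc[nm[as.integer(cl)]] <- mcc[nm[as.integer(cl)]] + factorial(sz - 1)
      }
    }
    out[, "MCC"] <- mcc
  }
  if ("Degree" %in% methods) out[, "Degree"] <- deg
  if ("Betweenness" %in% methods)
    out[, "Betweenness"] <- igraph::betweenness(g, weights = NA)
  if ("ClusteringCoefficient" %in% methods) {
    cc <- igraph::transitivity(g, type = "local")
    cc[!is.finite(cc)] <- 0
    out[, "ClusteringCoefficient"] <- cc
  }
  if ("Stress" %in% methods) out[, "Stress"] <- .stressCentrality(g)

  if (any(c("Closeness", "EcCentricity", "Radiality") %in% methods)) {
    comp <- igraph::components(g)
    for (cid in seq_len(comp$no)) {
      vs <- which(comp$membership == cid)
      if (length(vs) < 2) next
      sub <- igraph::induced_subgraph(g, vs)
      d <- igraph::distances(sub, weights = NA)
      nc <- length(vs)
      diam <- max(d)
      if ("Closeness" %in% methods)
        out[nm[vs], "Closeness"] <- (nc - 1) / rowSums(d)
      if ("EcCentricity" %in% methods)
        out[nm[vs], "EcCentricity"] <- 1 / apply(d, 1, max)
      if ("Radiality" %in% methods)
        out[nm[vs], "Radiality"] <- rowSums(diam + 1 - d) / (nc - 1) -
          (diam + 1) / (nc - 1)  # remove self term d=0
    }
  }
  out
}

#' Consensus hub ranking
#'
#' Ranks every gene under each enabled centrality (dense ranks, best = 1),
#' averages the ranks into a consensus, and flags the top-k genes as hubs;
#' consensus ties are broken by Degree rank, then lexicographic gene id.
#'
#' @param g an undirected \code{igraph} co-expression network
#' @param methods centralities to enable (see \code{\link{hubScores}})
#' @param topK number of hub genes to flag
#' @return a \code{HubReport}
#' @export
hubConsensus <- function(g, methods = c("MCC", "DMNC", "MNC", "Degree",
    "EcCentricity", "Closeness", "Radiality", "Betweenness", "Stress",
    "ClusteringCoefficient"), topK = 10L) {
  if (igraph::vcount(g) == 0)
    return(new("HubReport", graph = g,
               scores = matrix(numeric(), 0, length(methods),
                               dimnames = list(NULL, methods)),
               ranks = matrix(numeric(), 0, length(methods),
                              dimnames = list(NULL, methods)),
               consensus = stats::setNames(numeric(0), character(0)),
               topHubs = character(0)))
  sc <- hubScores(g, methods)
  ranks <- apply(sc, 2, function(x)
    match(x, sort(unique(x), decreasing = TRUE)))
  if (is.null(dim(ranks)))
    ranks <- matrix(ranks, nrow = 1)
  dimnames(ranks) <- dimnames(sc)
  consensus <- rowMeans(ranks)
  degRank <- if ("Degree" %in% methods) ranks[, "Degree"] else consensus
  ord <- order(consensus, degRank, rownames(sc))
  top <- rownames(sc)[ord][seq_len(min(topK, nrow(sc)))]
  new("HubReport", graph = g, scores = sc, ranks = ranks,
      consensus = consensus, topHubs = top)
}

#' Candidate screen: hub genes differentially expressed at late stages
#'
#' Candidates are genes flagged as consensus hubs AND differentially
#' expressed at 20 and/or 25 DPA (the window of secondary cell-wall
#' thickening); each record carries the stages at which the gene was
#' significant, distinguishing one-stage from two-stage candidates.
#'
#' @param degRecords list (or rbind-ed data.frame) of \code{\link{degTest}}
#'   outputs at the late stages
#' @param hubReport a \code{HubReport}
#' @param geneSet optional restriction of the candidate universe
#' @return data.frame: gene, stages, n_stages, two_stage
#' @export
prioritizeCandidates <- function(degRecords, hubReport, geneSet = NULL) {
  if (is.list(degRecords) && !is.data.frame(degRecords))
    degRecords <- do.call(rbind, degRecords)
  deg <- degRecords[degRecords$is_deg, , drop = FALSE]
  hubs <- topHubs(hubReport)
  if (!is.null(geneSet)) hubs <- intersect(hubs, geneSet)
  cand <- intersect(hubs, unique(deg$gene))
  if (!length(cand))
    return(data.frame(gene = character(), stages = character(),
                      n_stages = integer(), two_stage = logical(),
                      stringsAsFactors = FALSE))
  st <- vapply(cand, function(g)
    paste(sort(unique(deg$stage[deg$gene == g])), collapse = ";"),
    character(1))
  ns <- vapply(cand, function(g)
    length(unique(deg$stage[deg$gene == g])), integer(1))
  out <- data.frame(gene = cand, stages = st, n_stages = ns,
                    two_stage = ns >= 2, stringsAsFactors = FALSE)
  out <- out[order(-out$n_stages, out$gene), ]
  rownames(out) <- NULL
  out
}
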