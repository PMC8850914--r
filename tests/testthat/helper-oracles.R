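# independent brute-force oracles, kept free of the implementation paths
# they check

# average pairwise allele difference over all C(n,2) sampled allele pairs
brutePi <- function(n0, n1, n2) {
  alleles <- c(rep(0, 2 * n0 + n1), rep(1, 2 * n2 + n1))
  n <- length(alleles)
  if (n < 2) return(0)
  diff <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    diff <- diff + (alleles[i] != alleles[j])
  diff / choose(n, 2)
}

# naive per-site genotype comparison loop
bruteIdentity <- function(a, d) {
  num <- 0; den <- 0
  for (i in seq_along(a)) {
    if (!is.na(a[i]) && !is.na(d[i])) {
      den <- den + 1
      if (a[i] == d[i]) num <- num + 1
    }
  }
  if (den == 0) NA_real_ else num / den
}

# naive double-loop correlation edge set on log2(FPKM + 1)
bruteEdges <- function(fpkm, minAbsR) {
  y <- log2(fpkm + 1)
  g <- rownames(y)
  out <- NULL
  for (i in seq_len(nrow(y) - 1)) for (j in (i + 1):nrow(y)) {
    r <- stats::cor(y[i, ], y[j, ])
    if (!is.na(r) && abs(r) >= minAbsR)
      out <- rbind(out, data.frame(a = g[i], b = g[j]))
  }
  out
}

# brute-force clique statistics by subset enumeration on the adjacency
# matrix; component detection via reachability matrix powers
bruteCliqueStats <- function(A) {
  n <- nrow(A)
  subsets <- lapply(1:(2^n - 1), function(m)
    which(bitwAnd(m, 2^(0:(n - 1))) > 0))
  isClique <- function(S) length(S) >= 2 &&
    all(A[S, S][upper.tri(diag(length(S)))] == 1)
  cliques <- Filter(isClique, subsets)
  isMaximal <- function(S) !any(vapply(setdiff(1:n, S), function(v)
    all(A[v, S] == 1), logical(1)))
  maxCl <- Filter(isMaximal, cliques)
  mcc <- vapply(1:n, function(v)
    sum(vapply(maxCl, function(S)
      if (v %in% S) factorial(length(S) - 1) else 0, numeric(1))),
    numeric(1))
  mnc <- dmnc <- numeric(n)
  for (v in 1:n) {
    nb <- which(A[v, ] == 1)
    if (!length(nb)) next
    B <- A[nb, nb, drop = FALSE]
    R <- diag(length(nb)) + B
    for (i in seq_len(length(nb))) R <- (R %*% R > 0) * 1
    comps <- unique(apply(R > 0, 1, function(r)
      paste(which(r), collapse = ",")))
    memb <- as.integer(strsplit(
      comps[which.max(lengths(strsplit(comps, ",")))], ",")[[1]])
    mnc[v] <- length(memb)
    e <- sum(B[memb, memb]) / 2
    dmnc[v] <- if (length(memb) >= 2) e / length(memb)^1.7 else 0
  }
  list(mcc = mcc, mnc = mnc, dmnc = dmnc)
}

# expected effect category from direct codon substitution + translation
# (vectorised; coordinate arithmetic done independently of the package)
codonOracle <- function(refCodon, posInCodon, altBase) {
  altCodon <- refCodon
  substr(altCodon, posInCodon, posInCodon) <- altBase
  code <- Biostrings::GENETIC_CODE
  aaR <- unname(code[refCodon])
  aaA <- unname(code[altCodon])
  ifelse(aaR == aaA, "synonymous",
    ifelse(aaA == "*", "stopgain",
      ifelse(aaR == "*", "stoploss", "nonsynonymous")))
}
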