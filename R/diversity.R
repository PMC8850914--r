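#' Per-site nucleotide diversity from diploid call counts
#'
#' For a biallelic site with \code{n0} homozygous-reference, \code{n1}
#' heterozygous and \code{n2} homozygous-alternate called samples, the allele
#' counts are cR = 2 n0 + n1 and cA = 2 n2 + n1, and the site's contribution
#' to theta-pi is the average pairwise difference over all C(n, 2) sampled
#' allele pairs, 2 cR cA / (n (n - 1)) with n = cR + cA. Returns 0 when
#' fewer than two alleles are called. Vectorised over sites.
#'
#' @param n0,n1,n2 call counts (hom ref / het / hom alt)
#' @return per-site diversity in [0, 1]
#' @examples
#' sitePi(1, 0, 1)  # one hom-ref vs one hom-alt sample: 2*2*2/(4*3) = 2/3
#' sitePi(0, 1, 0)  # a single heterozygote: 1
#' @export
sitePi <- function(n0, n1, n2) {
  if (any(c(n0, n1, n2) < 0)) stop("call counts must be non-negative")
  cR <- 2 * n0 + n1
  cA <- 2 * n2 + n1
  n <- cR + cA
  ifelse(n < 2, 0, 2 * cR * cA / (n * (n - 1)))
}

#' Windowed nucleotide diversity (theta-pi per bp)
#'
#' Tiles each chromosome with non-overlapping windows of \code{windowBp}
#' (the final window may be short and is flagged \code{incomplete}); within a
#' window, pi is the sum of per-site diversities of the variant sites divided
#' by the window span in bp, monomorphic positions contributing zero.
#' Windows without SNPs are retained with pi = 0.
#'
#' @param gm a \code{GenotypeMatrix}
#' @param windowBp window (and step) size in bp; default 1 Mb
#' @param chromLengths optional named vector of chromosome lengths; defaults
#'   to the last SNP position per chromosome
#' @return \code{GRanges} of windows with mcols \code{n_snps}, \code{pi},
#'   \code{incomplete}
#' @export
windowedPi <- function(gm, windowBp = 1e6, chromLengths = NULL) {
  if (windowBp <= 0) stop("windowBp must be positive")
  g <- genoCalls(gm)
  gr <- sites(gm)
  n0 <- rowSums(g == 0L, na.rm = TRUE)
  n1 <- rowSums(g == 1L, na.rm = TRUE)
  n2 <- rowSums(g == 2L, na.rm = TRUE)
  pis <- sitePi(n0, n1, n2)
  chrom <- as.character(GenomeInfoDb::seqnames(gr))
  pos <- BiocGenerics::start(gr)

  out <- lapply(sort(unique(chrom)), function(ch) {
    sel <- chrom == ch
    len <- if (!is.null(chromLengths) && ch %in% names(chromLengths))
      chromLengths[[ch]] else max(pos[sel])
    starts <- seq(1, len, by = windowBp)
    ends <- pmin(starts + windowBp - 1, len)
    win <- findInterval(pos[sel], starts)
    nsnp <- tabulate(win, nbins = length(starts))
    sums <- vapply(seq_along(starts), function(w)
      sum(pis[sel][win == w]), numeric(1))
    GenomicRanges::GRanges(ch, IRanges::IRanges(starts, ends),
      n_snps = nsnp, pi = sums / (ends - starts + 1),
      incomplete = (ends - starts + 1) < windowBp)
  })
  do.call(c, out)
}

#' Call low-diversity blocks from windowed pi
#'
#' Flags windows whose pi is at or below the empirical \code{quantile} of all
#' window values (linear-interpolation order statistic; flagging on <= is
#' conservative on ties) and merges adjacent flagged windows on the same
#' chromosome into maximal blocks. These blocks mark regions of depleted
#' diversity, the classic footprint of directional selection during breeding.
#'
#' @param windows \code{GRanges} from \code{\link{windowedPi}}
#' @param quantile flagging quantile, default the lowest 5\%
#' @return \code{GRanges} of blocks with mcols \code{mean_pi},
#'   \code{n_windows}; the pi threshold used is carried in
#'   \code{metadata(x)$threshold}
#' @export
callLowDiversityBlocks <- function(windows, quantile = 0.05) {
  if (!length(windows)) stop("empty window list")
  if (length(windows) < 20)
    warning("fewer than 20 windows: quantile threshold is degenerate")
  pi <- windows$pi
  thr <- stats::quantile(pi, quantile, names = FALSE, type = 7)
  flagged <- windows[pi <= thr]
  if (!length(flagged)) {
    out <- GenomicRanges::GRanges()
  } else {
    out <- GenomicRanges::reduce(flagged, min.gapwidth = 1L)
    hits <- GenomicRanges::findOverlaps(out, flagged)
    out$mean_pi <- as.numeric(tapply(flagged$pi[S4Vectors::subjectHits(hits)],
                                     S4Vectors::queryHits(hits), mean))
    out$n_windows <- as.integer(table(S4Vectors::queryHits(hits)))
  }
  S4Vectors::metadata(out)$threshold <- thr
  out
}
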