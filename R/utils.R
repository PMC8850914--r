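# internal helpers shared across modules

.msg <- function(...) message("pedscan: ", sprintf(...))

# sort a width-1 site GRanges lexicographically by (chrom, pos); chromosome
# order is plain character sort so containers compare reproducibly
.sortSites <- function(gr) {
  gr[order(as.character(GenomeInfoDb::seqnames(gr)), BiocGenerics::start(gr))]
}

.siteKey <- function(gr) {
  paste(as.character(GenomeInfoDb::seqnames(gr)), BiocGenerics::start(gr),
        sep = ":")
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

.revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(COMPLEMENT[strsplit(s, "")[[1]]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# clip a (start, end, label) interval data.frame to [lo, hi]
.clipIntervals <- function(df, lo, hi) {
  keep <- df$end >= lo & df$start <= hi
  df <- df[keep, , drop = FALSE]
  if (nrow(df)) {
    df$start <- pmax(df$start, lo)
    df$end <- pmin(df$end, hi)
  }
  df
}

# merge adjacent intervals sharing the same label column
.mergeIntervals <- function(df, label = "donor") {
  if (nrow(df) < 2) return(df)
  df <- df[order(df$start), , drop = FALSE]
  out <- df[1, , drop = FALSE]
  for (i in 2:nrow(df)) {
    j <- nrow(out)
    if (df$start[i] <= out$end[j] + 1 && df[[label]][i] == out[[label]][j]) {
      out$end[j] <- max(out$end[j], df$end[i])
    } else {
      out <- rbind(out, df[i, , drop = FALSE])
    }
  }
  rownames(out) <- NULL
  out
}

.traits <- c("FS", "FL", "FU", "FM", "FE", "FBN", "BN", "SBW", "LP", "SI",
             "LY", "SY")

.fiberTraits <- c("FS", "FL", "FU", "FM", "FE")
.yieldTraits <- c("FBN", "BN", "SBW", "LP", "SI", "LY", "SY")
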