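#' Read a VCF into a GenotypeMatrix
#'
#' Parses a VCF v4.x with \code{vcfR}, keeping only biallelic SNP records
#' (single-base REF and ALT). Indel and multiallelic records are dropped with
#' a logged count. Genotypes are read from the GT field irrespective of the
#' phasing separator; any genotype containing a missing allele becomes a
#' missing call. Per-genotype read depth is taken from the DP FORMAT field
#' when present.
#'
#' @param path VCF file (plain text or gzipped)
#' @return a \code{GenotypeMatrix}, sites in genome order
#' @export
readVcfGenotypes <- function(path) {
  lines <- readLines(path)
  hdr <- which(startsWith(lines, "#CHROM"))
  if (length(hdr) != 1L)
    stop("malformed VCF header: expected exactly one #CHROM line in ", path)
  nfield <- length(strsplit(lines[hdr], "\t", fixed = TRUE)[[1]])
  if (nfield < 10L)
    stop("malformed VCF header: no sample columns in ", path)
  recs <- which(!startsWith(lines, "#"))
  recs <- recs[recs > hdr]
  nf <- lengths(strsplit(lines[recs], "\t", fixed = TRUE))
  bad <- which(nf != nfield)
  if (length(bad))
    stop("VCF record at line ", recs[bad[1]], " has ", nf[bad[1]],
         " fields, expected ", nfield)

  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  ref <- toupper(fix[, "REF"])
  alt <- toupper(fix[, "ALT"])
  snp <- ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  if (any(!snp))
    .msg("dropped %d non-biallelic-SNP record(s)", sum(!snp))

  gt <- vcfR::extract.gt(vcf, element = "GT")
  gt <- gsub("|", "/", gt, fixed = TRUE)
  code <- matrix(NA_integer_, nrow(gt), ncol(gt),
                 dimnames = list(NULL, colnames(gt)))
  code[gt == "0/0"] <- 0L
  code[gt == "0/1" | gt == "1/0"] <- 1L
  code[gt == "1/1"] <- 2L

  depth <- NULL
  fmt <- vcf@gt[, "FORMAT"]
  if (any(grepl("(^|:)DP(:|$)", fmt)))
    depth <- suppressWarnings(
      vcfR::extract.gt(vcf, element = "DP", as.numeric = TRUE))

  qual <- suppressWarnings(as.numeric(fix[, "QUAL"]))
  gr <- GenomicRanges::GRanges(fix[snp, "CHROM"],
          IRanges::IRanges(as.integer(fix[snp, "POS"]), width = 1),
          ref = ref[snp], alt = alt[snp], qual = qual[snp])
  GenotypeMatrix(gr, code[snp, , drop = FALSE],
                 if (is.null(depth)) NULL else depth[snp, , drop = FALSE])
}

#' Write a GenotypeMatrix as a plain-text VCF
#'
#' Emits a minimal VCF v4.2 with GT (and DP when depth is present). The
#' written file round-trips through \code{readVcfGenotypes} preserving site
#' count, order and every genotype call.
#'
#' @param gm a \code{GenotypeMatrix}
#' @param path output file
#' @export
writeVcfGenotypes <- function(gm, path) {
  gr <- sites(gm)
  g <- genoCalls(gm)
  dp <- genoDepth(gm)
  gtstr <- matrix(".\\.", nrow(g), ncol(g))
  gtstr[] <- c("0/0", "0/1", "1/1")[g + 1L]
  gtstr[is.na(g)] <- "./."
  if (!is.null(dp)) {
    d <- ifelse(is.na(dp), ".", format(dp, trim = TRUE, scientific = FALSE))
    gtstr <- matrix(paste(gtstr, d, sep = ":"), nrow(g), ncol(g))
  }
  qual <- S4Vectors::mcols(gr)$qual
  qualstr <- ifelse(is.na(qual), ".", sprintf("%g", qual))
  recs <- paste(as.character(GenomeInfoDb::seqnames(gr)),
                BiocGenerics::start(gr), ".",
                S4Vectors::mcols(gr)$ref, S4Vectors::mcols(gr)$alt,
                qualstr, "PASS", ".",
                if (is.null(dp)) "GT" else "GT:DP",
                sep = "\t")
  body <- do.call(paste, c(list(recs), asplit(gtstr, 2), list(sep = "\t")))
  hdr <- c("##fileformat=VCFv4.2",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           if (!is.null(dp))
             '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", colnames(g)), collapse = "\t"))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Apply resequencing-grade variant quality filters
#'
#' The default thresholds are those of standard pedigree resequencing
#' pipelines: site quality >= 20, per-genotype depth >= 4 (genotypes below are
#' set missing when depth is available), per-site missing fraction <= 20%,
#' and minor allele frequency > 0.05 computed from called alleles only
#' (heterozygotes contribute one allele of each class). Filtering is
#' idempotent: a filtered matrix passes through unchanged.
#'
#' @param gm a \code{GenotypeMatrix}
#' @param minQual minimum phred site quality (sites with lower quality are
#'   dropped; sites with unknown quality are kept)
#' @param minDepth genotypes with read depth below this are set missing
#' @param maxMissing maximum tolerated fraction of missing calls per site
#' @param minMaf sites with MAF <= this are dropped
#' @return the filtered \code{GenotypeMatrix}
#' @export
filterVariants <- function(gm, minQual = 20, minDepth = 4,
                           maxMissing = 0.20, minMaf = 0.05) {
  stopifnot(nSites(gm) > 0)
  g <- genoCalls(gm)
  dp <- genoDepth(gm)
  if (!is.null(dp))
    g[!is.na(dp) & dp < minDepth] <- NA_integer_
  qual <- S4Vectors::mcols(sites(gm))$qual
  keep <- is.na(qual) | qual >= minQual

  nmiss <- rowSums(is.na(g))
  keep <- keep & (nmiss / ncol(g)) <= maxMissing

  n0 <- rowSums(g == 0L, na.rm = TRUE)
  n1 <- rowSums(g == 1L, na.rm = TRUE)
  n2 <- rowSums(g == 2L, na.rm = TRUE)
  called <- n0 + n1 + n2
  af <- ifelse(called > 0, (2 * n2 + n1) / (2 * called), 0)
  maf <- pmin(af, 1 - af)
  keep <- keep & maf > minMaf

  if (!any(keep))
    warning("all sites removed by filtering")
  GenotypeMatrix(sites(gm)[keep], g[keep, , drop = FALSE],
                 if (is.null(dp)) NULL else dp[keep, , drop = FALSE])
}

#' Read gene models from a GFF3 file
#'
#' Parses gene / mRNA / exon / CDS features. When a gene has several mRNAs
#' the first one is used. CDS or exon features whose parent cannot be traced
#' to a gene are skipped with a warning.
#'
#' @param path GFF3 file
#' @return a \code{GeneModelSet}
#' @export
readGff3Genes <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  genes <- gr[type == "gene"]
  gid <- as.character(genes$ID)
  S4Vectors::mcols(genes) <- S4Vectors::DataFrame(gene_id = gid)
  names(genes) <- gid

  tx <- gr[type %in% c("mRNA", "transcript")]
  txParent <- vapply(as.list(tx$Parent), function(p)
    if (length(p)) p[[1]] else NA_character_, character(1))
  txid <- as.character(tx$ID)
  # first transcript per gene, in file order
  firstTx <- txid[!duplicated(txParent)]
  tx2gene <- stats::setNames(txParent[match(firstTx, txid)], firstTx)

  pickChildren <- function(what) {
    feat <- gr[type == what]
    if (!length(feat)) return(GenomicRanges::GRangesList())
    par <- vapply(as.list(feat$Parent), function(p)
      if (length(p)) p[[1]] else NA_character_, character(1))
    gene_of <- ifelse(par %in% names(tx2gene), tx2gene[par],
                      ifelse(par %in% gid, par, NA_character_))
    orphan <- is.na(gene_of)
    if (any(orphan))
      warning(sum(orphan), " ", what,
              " feature(s) without a parent gene skipped")
    # keep only features of the chosen transcript (or direct gene children)
    keep <- !orphan & (par %in% c(names(tx2gene), gid))
    feat <- feat[keep]
    gene_of <- gene_of[keep]
    S4Vectors::mcols(feat) <- NULL
    grl <- GenomicRanges::split(feat, gene_of)
    grl <- S4Vectors::endoapply(grl, function(x) x[order(BiocGenerics::start(x))])
    grl
  }

  new("GeneModelSet", genes = genes,
      exons = pickChildren("exon"), cds = pickChildren("CDS"))
}

#' Read a reference genome FASTA
#'
#' Sequence names are truncated at the first whitespace and bases are
#' upper-cased.
#'
#' @param path FASTA file
#' @return a named \code{DNAStringSet}
#' @export
readGenomeFasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  names(ss) <- sub("\\s.*$", "", names(ss))
  Biostrings::DNAStringSet(toupper(as.character(ss)))
}

#' Read a phenotype table
#'
#' Expects a TSV with columns \code{accession}, \code{trait},
#' \code{environment}, \code{value}. Rows may repeat (replicates).
#'
#' @param path TSV file
#' @return a data.frame
#' @export
readPhenotypeTable <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("accession", "trait", "environment", "value")
  if (!all(need %in% colnames(df)))
    stop("phenotype table must have columns: ", paste(need, collapse = ", "))
  if (!all(is.finite(df$value)))
    stop("phenotype values must be finite")
  df[, need]
}

#' Read a pedigree edge list
#'
#' TSV with columns \code{parent}, \code{child}. When \code{target} is not
#' given, the unique accession without descendants is used.
#'
#' @param path TSV file
#' @param target target accession, or \code{NULL} to infer the unique sink
#' @return a \code{PedigreeGraph}
#' @export
readPedigreeGraph <- function(path, target = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("parent", "child") %in% colnames(df)))
    stop("pedigree file must have columns parent, child")
  if (is.null(target)) {
    sinks <- setdiff(df$child, df$parent)
    if (length(sinks) != 1L)
      stop("cannot infer target: ", length(sinks),
           " terminal accessions; pass target=")
    target <- sinks
  }
  PedigreeGraph(df, target)
}

#' Write genomic intervals as BED
#'
#' Internal coordinates are 1-based inclusive; BED output is the usual
#' 0-based half-open convention (a gene at 1-based [101, 200] becomes
#' start=100, end=200).
#'
#' @param gr a \code{GRanges}
#' @param path output BED file
#' @export
writeBed <- function(gr, path) {
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}
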