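EFFECT_CATEGORIES <- c("intergenic", "upstream", "downstream", "UTR5", "UTR3",
                       "intronic", "splicing", "synonymous", "nonsynonymous",
                       "stopgain", "stoploss", "unknown")

LARGE_EFFECT_CATEGORIES <- c("nonsynonymous", "stopgain", "stoploss")

# spliced CDS sequence (5'->3' on the coding strand) and cumulative widths
.cdsModel <- function(cdsGr, strand, genome) {
  ch <- as.character(GenomeInfoDb::seqnames(cdsGr))[1]
  seqs <- substring(as.character(genome[[ch]]),
                    BiocGenerics::start(cdsGr), BiocGenerics::end(cdsGr))
  if (strand == "-") {
    seqs <- rev(.revcomp(seqs))
  }
  list(seq = paste(seqs, collapse = ""),
       widths = BiocGenerics::width(cdsGr))
}

# position of a genomic coordinate within the spliced CDS (1-based), or NA
.cdsPosition <- function(pos, cdsGr, strand) {
  st <- BiocGenerics::start(cdsGr)
  en <- BiocGenerics::end(cdsGr)
  k <- which(pos >= st & pos <= en)[1]
  if (is.na(k)) return(NA_integer_)
  plusPos <- sum(en[seq_len(k - 1)] - st[seq_len(k - 1)] + 1L) +
    (pos - st[k] + 1L)
  if (strand == "+") plusPos else sum(en - st + 1L) - plusPos + 1L
}

.translateCodon <- function(codon) {
  unname(Biostrings::GENETIC_CODE[codon])
}

.classifyCodon <- function(refCodon, altCodon) {
  refAa <- .translateCodon(refCodon)
  altAa <- .translateCodon(altCodon)
  if (is.na(refAa) || is.na(altAa)) return(list(cat = "unknown",
                                               ref = NA, alt = NA))
  cat <- if (refAa == altAa) "synonymous"
    else if (altAa == "*" && refAa != "*") "stopgain"
    else if (refAa == "*" && altAa != "*") "stoploss"
    else "nonsynonymous"
  list(cat = cat, ref = refAa, alt = altAa)
}

#' Classify SNP functional effects against gene models
#'
#' Codon-level, strand-aware annotation. For a SNP inside a coding exon the
#' codon is reconstructed across exon junctions honouring frame and strand
#' (reverse-complemented for minus-strand genes; reported alleles stay on the
#' sense = coding strand), translated with the standard nuclear code and
#' classified as synonymous, nonsynonymous, stop-gain or stop-loss.
#' Non-coding positions get, in order of precedence per gene:
#' splicing (within \code{spliceBp} of an intron boundary) > UTR5/UTR3 >
#' intronic > upstream/downstream (within \code{flankBp} of the transcript,
#' strand-aware) > intergenic. A SNP overlapping several genes yields one
#' record per gene. Genes whose CDS length is not a multiple of 3 are
#' flagged with a warning and their coding variants labelled
#' \code{"unknown"}.
#'
#' @param snps width-1 \code{GRanges} with mcols \code{ref}, \code{alt}, or a
#'   \code{GenotypeMatrix}
#' @param geneModels a \code{GeneModelSet}
#' @param genome named \code{DNAStringSet}
#' @param flankBp upstream/downstream flank (default 2,000 bp, matching the
#'   promoter definition of the haplotype screen)
#' @param spliceBp splice-site margin inside the intron (default 2 bp)
#' @return data.frame with columns \code{chrom}, \code{pos}, \code{ref},
#'   \code{alt}, \code{gene_id}, \code{category}, \code{aa_change},
#'   \code{codon_index}
#' @export
annotateVariants <- function(snps, geneModels, genome, flankBp = 2000L,
                             spliceBp = 2L) {
  if (is(snps, "GenotypeMatrix")) snps <- sites(snps)
  chrom <- as.character(GenomeInfoDb::seqnames(snps))
  pos <- BiocGenerics::start(snps)
  ref <- S4Vectors::mcols(snps)$ref
  alt <- S4Vectors::mcols(snps)$alt

  gbase <- vapply(seq_along(snps), function(i)
    substring(as.character(genome[[chrom[i]]]), pos[i], pos[i]), character(1))
  bad <- which(gbase != ref)
  if (length(bad))
    stop("SNP ref allele does not match genome at ",
         chrom[bad[1]], ":", pos[bad[1]],
         " (genome ", gbase[bad[1]], ", ref ", ref[bad[1]], ")")

  genes <- geneRanges(geneModels)
  strandOf <- as.character(BiocGenerics::strand(genes))
  exonsL <- geneExons(geneModels)
  cdsL <- geneCds(geneModels)

  # gene-level caches, built lazily
  cdsCache <- new.env(parent = emptyenv())
  frameWarned <- character()

  flanked <- GenomicRanges::resize(genes, BiocGenerics::width(genes) +
                                   2L * flankBp, fix = "center")
  hits <- GenomicRanges::findOverlaps(snps, flanked, ignore.strand = TRUE)

  rows <- list()
  addRow <- function(i, gid, cat, aaChange = NA_character_,
                     codonIdx = NA_integer_) {
    rows[[length(rows) + 1L]] <<- data.frame(chrom = chrom[i], pos = pos[i],
      ref = ref[i], alt = alt[i], gene_id = gid, category = cat,
      aa_change = aaChange, codon_index = codonIdx,
      stringsAsFactors = FALSE)
  }

  for (h in seq_along(hits)) {
    i <- S4Vectors::queryHits(hits)[h]
    gIdx <- S4Vectors::subjectHits(hits)[h]
    gid <- genes$gene_id[gIdx]
    strand <- strandOf[gIdx]
    txS <- BiocGenerics::start(genes)[gIdx]
    txE <- BiocGenerics::end(genes)[gIdx]
    p <- pos[i]

    if (p < txS || p > txE) {
      side <- if (p < txS) "left" else "right"
      cat <- if ((strand == "+") == (side == "left")) "upstream"
             else "downstream"
      addRow(i, gid, cat)
      next
    }

    cds <- if (gid %in% names(cdsL)) cdsL[[gid]] else NULL
    exons <- if (gid %in% names(exonsL)) exonsL[[gid]] else NULL
    inCds <- !is.null(cds) && length(cds) &&
      any(p >= BiocGenerics::start(cds) & p <= BiocGenerics::end(cds))

    if (inCds) {
      if (!gid %in% ls(cdsCache))
        assign(gid, .cdsModel(cds, strand, genome), envir = cdsCache)
      model <- get(gid, envir = cdsCache)
      if (nchar(model$seq) %% 3 != 0) {
        if (!gid %in% frameWarned) {
          warning("CDS length of ", gid,
                  " is not a multiple of 3; variants labelled unknown")
          frameWarned <- c(frameWarned, gid)
        }
        addRow(i, gid, "unknown")
        next
      }
      cdsPos <- .cdsPosition(p, cds, strand)
      codonIdx <- (cdsPos - 1L) %/% 3L + 1L
      posInCodon <- (cdsPos - 1L) %% 3L + 1L
      codon <- substring(model$seq, 3L * codonIdx - 2L, 3L * codonIdx)
      refBase <- if (strand == "+") ref[i] else COMPLEMENT[[ref[i]]]
      altBase <- if (strand == "+") alt[i] else COMPLEMENT[[alt[i]]]
      stopifnot(substring(codon, posInCodon, posInCodon) == refBase)
      altCodon <- codon
      substring(altCodon, posInCodon, posInCodon) <- altBase
      cls <- .classifyCodon(codon, altCodon)
      aaChange <- if (cls$cat == "unknown") NA_character_ else
        paste0(cls$ref, codonIdx, cls$alt)
      addRow(i, gid, cls$cat, aaChange, codonIdx)
      next
    }

    inExon <- !is.null(exons) && length(exons) &&
      any(p >= BiocGenerics::start(exons) & p <= BiocGenerics::end(exons))
    if (!inExon && !is.null(exons) && length(exons) > 1) {
      # intron; splice site = within spliceBp of an exon edge
      edges <- c(BiocGenerics::start(exons)[-1] - 1L,
                 BiocGenerics::end(exons)[-length(exons)] + 1L)
      if (any(abs(p - edges) < spliceBp)) {
        addRow(i, gid, "splicing")
        next
      }
    }
    if (inExon) {
      if (is.null(cds) || !length(cds)) {
        addRow(i, gid, "unknown")
      } else {
        cdsLo <- min(BiocGenerics::start(cds))
        cdsHi <- max(BiocGenerics::end(cds))
        fivePrime <- if (strand == "+") p < cdsLo else p > cdsHi
        addRow(i, gid, if (fivePrime) "UTR5" else "UTR3")
      }
    } else {
      addRow(i, gid, "intronic")
    }
  }

  ann <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(), pos = integer(), ref = character(),
               alt = character(), gene_id = character(),
               category = character(), aa_change = character(),
               codon_index = integer(), stringsAsFactors = FALSE)
  # SNPs hitting no gene or flank are intergenic
  orphan <- setdiff(seq_along(snps), unique(S4Vectors::queryHits(hits)))
  if (length(orphan)) {
    ann <- rbind(ann, data.frame(chrom = chrom[orphan], pos = pos[orphan],
      ref = ref[orphan], alt = alt[orphan], gene_id = NA_character_,
      category = "intergenic", aa_change = NA_character_,
      codon_index = NA_integer_, stringsAsFactors = FALSE))
  }
  ann <- ann[order(ann$chrom, ann$pos, ann$gene_id), ]
  rownames(ann) <- NULL
  ann
}

#' Large-effect predicate for annotated variants
#'
#' A variant is large-effect when its category is nonsynonymous, stop-gain
#' or stop-loss; everything else (including splicing) is not.
#'
#' @param effect a data.frame from \code{\link{annotateVariants}}, or a
#'   character vector of categories
#' @return logical vector
#' @export
isLargeEffect <- function(effect) {
  cat <- if (is.data.frame(effect)) effect$category else effect
  cat %in% LARGE_EFFECT_CATEGORIES
}
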