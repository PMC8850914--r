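#' Intersect pedigree-transmitted genes with a trait's GWAS gene list
#'
#' @param transmittedGenes character vector of genes overlapped by
#'   transmitted fragments
#' @param gwasGenes character vector of GWAS-significant genes for one trait
#' @param universe optional gene-id universe; ids outside it are retained
#'   but flagged with a warning (id-space mismatch)
#' @return sorted character vector of the intersection
#' @export
intersectTrait <- function(transmittedGenes, gwasGenes, universe = NULL) {
  transmittedGenes <- unique(transmittedGenes)
  gwasGenes <- unique(gwasGenes)
  if (!is.null(universe)) {
    unknown <- setdiff(c(transmittedGenes, gwasGenes), universe)
    if (length(unknown))
      warning(length(unknown), " gene id(s) outside the model universe ",
              "(id-space mismatch?): ", paste(utils::head(unknown, 3),
                                              collapse = ", "))
  }
  sort(intersect(transmittedGenes, gwasGenes))
}

#' Putative pleiotropic genes across trait gene sets
#'
#' Genes present in at least \code{minTraits} of the given per-trait gene
#' sets, with their trait memberships. With \code{crossQualityYield = TRUE}
#' only genes linked to at least one fiber-quality trait (FS, FL, FU, FM,
#' FE) and at least one yield trait (FBN, BN, SBW, LP, SI, LY, SY) are
#' reported.
#'
#' @param traitSets named list, trait -> character vector of gene ids
#' @param minTraits minimum number of trait memberships (default 2)
#' @param crossQualityYield apply the quality x yield cross filter
#' @return data.frame: gene, traits (";"-collapsed), n_traits
#' @export
pleiotropy <- function(traitSets, minTraits = 2L,
                       crossQualityYield = FALSE) {
  if (length(traitSets) < 2 && minTraits >= 2)
    stop("need gene sets for >= 2 traits")
  traitSets <- lapply(traitSets, unique)
  genes <- sort(unique(unlist(traitSets)))
  memb <- lapply(genes, function(g)
    sort(names(traitSets)[vapply(traitSets, function(s) g %in% s,
                                 logical(1))]))
  names(memb) <- genes
  keep <- lengths(memb) >= minTraits
  if (crossQualityYield)
    keep <- keep & vapply(memb, function(tr)
      any(tr %in% .fiberTraits) && any(tr %in% .yieldTraits), logical(1))
  genes <- genes[keep]
  data.frame(gene = genes,
             traits = vapply(memb[keep], paste, character(1),
                             collapse = ";"),
             n_traits = unname(lengths(memb[keep])),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Assemble the final per-gene candidate dossier
#'
#' Collates, for every gene mentioned by any stage of the pipeline, whether
#' it was transmitted through the pedigree, its GWAS trait memberships, the
#' functional classes of its SNPs, haplotype effect estimates, hub / DEG /
#' candidate status and pleiotropy. Stages not supplied are marked
#' \code{"not computed"}. The report is deterministic for fixed inputs
#' (genes and fields sorted), so the emitted JSON is byte-identical across
#' runs.
#'
#' @param transmittedGenes genes overlapped by unique transmitted fragments
#' @param gwasSets named list trait -> genes
#' @param effects annotation data.frame (or NULL)
#' @param hapEffects data.frame of haplotype effect estimates (or NULL)
#' @param candidates data.frame from \code{\link{prioritizeCandidates}}
#'   (or NULL)
#' @param hubReport a \code{HubReport} (or NULL)
#' @param degRecords DEG data.frame(s) (or NULL)
#' @param pleiotropyTable data.frame from \code{\link{pleiotropy}} (or NULL)
#' @return named list (one dossier per gene), class \code{candidateReport}
#' @export
candidateReport <- function(transmittedGenes = NULL, gwasSets = NULL,
    effects = NULL, hapEffects = NULL, candidates = NULL, hubReport = NULL,
    degRecords = NULL, pleiotropyTable = NULL) {
  if (is.list(degRecords) && !is.data.frame(degRecords))
    degRecords <- do.call(rbind, degRecords)
  genes <- sort(unique(c(transmittedGenes, unlist(gwasSets),
    if (!is.null(effects)) stats::na.omit(effects$gene_id),
    if (!is.null(hapEffects)) hapEffects$gene,
    if (!is.null(candidates)) candidates$gene,
    if (!is.null(degRecords)) degRecords$gene[degRecords$is_deg],
    if (!is.null(hubReport)) topHubs(hubReport),
    if (!is.null(pleiotropyTable)) pleiotropyTable$gene)))
  nc <- "not computed"
  dossiers <- lapply(genes, function(g) {
    list(
      transmitted = if (is.null(transmittedGenes)) nc else
        g %in% transmittedGenes,
      gwas_traits = if (is.null(gwasSets)) nc else
        sort(names(gwasSets)[vapply(gwasSets, function(s) g %in% s,
                                    logical(1))]),
      effect_classes = if (is.null(effects)) nc else
        sort(unique(effects$category[!is.na(effects$gene_id) &
                                     effects$gene_id == g])),
      haplotype_effects = if (is.null(hapEffects)) nc else {
        he <- hapEffects[hapEffects$gene == g, , drop = FALSE]
        he <- he[order(he$trait), c("trait", "delta", "percent", "p")]
        rownames(he) <- NULL
        he
      },
      hub = if (is.null(hubReport)) nc else g %in% topHubs(hubReport),
      deg_stages = if (is.null(degRecords)) nc else
        sort(unique(degRecords$stage[degRecords$gene == g &
                                     degRecords$is_deg])),
      candidate = if (is.null(candidates)) nc else g %in% candidates$gene,
      pleiotropy_traits = if (is.null(pleiotropyTable)) nc else {
        i <- match(g, pleiotropyTable$gene)
        if (is.na(i)) character(0) else
          strsplit(pleiotropyTable$traits[i], ";")[[1]]
      })
  })
  names(dossiers) <- genes
  class(dossiers) <- "candidateReport"
  dossiers
}

#' Write a candidate report as JSON and TSV
#'
#' @param report a \code{candidateReport}
#' @param jsonPath,tsvPath output files (either may be NULL)
#' @export
writeCandidateReport <- function(report, jsonPath = NULL, tsvPath = NULL) {
  if (!is.null(jsonPath)) {
    unclass_report <- unclass(report)
    jsonlite::write_json(unclass_report, jsonPath, auto_unbox = TRUE,
                         digits = NA, dataframe = "rows", null = "null")
  }
  if (!is.null(tsvPath)) {
    flat <- do.call(rbind, lapply(names(report), function(g) {
      d <- report[[g]]
      fm <- function(x) if (is.character(x) && length(x) == 1 &&
                            x == "not computed") "NA" else
        if (is.data.frame(x)) paste(x$trait, round(x$delta, 4), sep = ":",
                                    collapse = ";") else
        paste(x, collapse = ";")
      data.frame(gene = g, transmitted = fm(d$transmitted),
                 gwas_traits = fm(d$gwas_traits),
                 effect_classes = fm(d$effect_classes),
                 haplotype_effects = fm(d$haplotype_effects),
                 hub = fm(d$hub), deg_stages = fm(d$deg_stages),
                 candidate = fm(d$candidate),
                 pleiotropy_traits = fm(d$pleiotropy_traits),
                 stringsAsFactors = FALSE)
    }))
    utils::write.table(flat, tsvPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(report)
}
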