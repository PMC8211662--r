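#' Default lineage marker sets
#'
#' The four major lineages of the post-implantation embryo and their
#' cluster-defining genes: epiblast (EPI; core pluripotency plus its most
#' enriched genes), hypoblast (HYP; extra-embryonic endoderm), and the two
#' trophoblast sub-lineages, cytotrophoblast (CTB) and syncytiotrophoblast
#' (STB). A custom list (e.g. a full differential-expression table) can be
#' passed to [score_signatures] instead.
#'
#' @return Named list of character vectors, names `EPI`, `HYP`, `CTB`, `STB`.
#' @export
lineage_markers <- function() {
  list(
    EPI = c("POU5F1", "NANOG", "SOX2", "DPPA5", "KHDC1L", "MT1X",
            "KHDC3L", "MT1G"),
    HYP = c("PDGFRA", "GATA6", "APOA1", "FN1", "S100A14", "COL4A1", "APOA2"),
    CTB = c("PEG10", "FABP5", "HIST1H4C", "KRT19", "TPM1", "CDH1", "ITGA6"),
    STB = c("CGA", "PRR9", "ANXA1", "LGALS16", "ATF3")
  )
}

#' Default pluripotency marker panels
#'
#' Panels of naive, primed and core pluripotency markers used to summarise
#' the epiblast's pluripotency-state transition across developmental stages.
#'
#' @return Named list of character vectors (`naive`, `primed`, `core`).
#' @export
pluripotency_panels <- function() {
  list(
    naive = c("KLF4", "KLF17", "PRDM14", "DNMT3L", "SOX15", "TFCP2L1", "ZFP42"),
    primed = c("FGF2", "DNMT3B", "SOX11", "SFRP2", "SALL2"),
    core = c("POU5F1", "NANOG", "SOX2")
  )
}

#' Default antagonist co-expression panel
#'
#' Secreted WNT/BMP/NODAL antagonists screened for co-expression with CER1
#' in the hypoblast, the candidate markers of an anterior signalling centre.
#'
#' @return Character vector of gene symbols.
#' @export
ave_antagonist_panel <- function() {
  c("LEFTY1", "LEFTY2", "HHEX", "NOG", "DKK4", "DKK1", "SFRP1",
    "NCLN", "CHRD", "SOSTDC1")
}

# Human mitochondrial protein/rRNA gene symbols (GRCh38 "MT-" convention).
mito_gene_symbols <- function() {
  c("MT-ND1", "MT-ND2", "MT-CO1", "MT-CO2", "MT-ATP8", "MT-ATP6", "MT-CO3",
    "MT-ND3", "MT-ND4L", "MT-ND4", "MT-ND5", "MT-ND6", "MT-CYB")
}
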