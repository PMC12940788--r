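#' Immune marker and panel gene catalogues
#'
#' `chs_markers()` lists the 20 immunohistochemistry markers assessed as
#' positive cells per mm2 in the central and peripheral tumour regions
#' (two CD68 clones distinguish M1-like PG-M1 from M2-like KP1 staining;
#' PD-L1 additionally carries a percent-positive call used for ordinal
#' scoring). `density_features()` returns the canonical 40 column names
#' `<marker>_<region>`. `panel_genes()` returns the targeted sequencing
#' panel gene table with approximate genomic intervals used to place
#' synthetic variants.
#'
#' @return Character vector, or for `panel_genes()` a data.frame with
#'   columns `gene`, `chrom`, `start`, `end`.
#' @export
chs_markers <- function() {
  c("CD45", "CD3", "CD4", "CD8", "FOXP3", "CD20",
    "CD68_PGM1", "CD68_KP1", "CD163", "CD14", "CD80", "HLADR",
    "CD1A", "CD141", "LAMP3", "PD1", "TIM3", "LAG3", "GAL9", "PDL1")
}

#' @rdname chs_markers
#' @export
tumor_regions <- function() c("central", "peripheral")

#' @rdname chs_markers
#' @export
density_features <- function() {
  as.vector(outer(chs_markers(), tumor_regions(), paste, sep = "_"))
}

.panel_gene_table <- local({
  g <- rbind(
    c("IDH1",   "2", 209100951, 209119806),
    c("IDH2",  "15",  90626277,  90645736),
    c("TP53",  "17",   7571720,   7590868),
    c("RNF213","17",  78234667,  78372586),
    c("TAF1",   "X",  70586114,  70685855),
    c("MN1",   "22",  28143000,  28197486),
    c("UBR5",   "8", 103265624, 103425043),
    c("EPHA7",  "6",  93952656,  94132005),
    c("PTCH1",  "9",  98205264,  98279339),
    c("RB1",   "13",  48877887,  49056026),
    c("ATRX",   "X",  76760356,  77041719),
    c("KMT2D", "12",  49412758,  49449107),
    c("ARID1A", "1",  27022522,  27108601),
    c("SETD2",  "3",  47057898,  47205457),
    c("NF1",   "17",  29421945,  29709134),
    c("EGFR",   "7",  55086714,  55324313),
    c("PIK3CA", "3", 178866311, 178952497),
    c("BRAF",   "7", 140419127, 140624564),
    c("KIT",    "4",  55524095,  55606881),
    c("MET",    "7", 116312444, 116438440),
    c("CDKN2A", "9",  21967751,  21995300),
    c("MYC",    "8", 128748315, 128753680),
    c("MDM2",  "12",  69201956,  69239214),
    c("PTEN",  "10",  89623195,  89728532),
    c("FLT3",  "13",  28577411,  28674729),
    c("MAP2K2","19",   4090321,   4124126),
    c("FGFR1",  "8",  38268656,  38326352),
    c("AKT2",  "19",  40736224,  40791443),
    c("STK11", "19",   1205798,   1228434),
    c("NOTCH1", "9", 139388896, 139440314),
    c("PDGFRA", "4",  55095264,  55164414))
  data.frame(gene = g[, 1], chrom = g[, 2],
             start = as.integer(g[, 3]), end = as.integer(g[, 4]))
})

#' @rdname chs_markers
#' @export
panel_genes <- function() .panel_gene_table

# genes eligible for synthetic CNV events (kept disjoint from IDH1/2 so
# SNV-derived mutation frequencies are not inflated by CNV flags)
cnv_gene_pool <- function() {
  c("CDKN2A", "RB1", "MYC", "EGFR", "MDM2", "PTEN", "FLT3", "BRAF", "MET",
    "MAP2K2", "FGFR1", "KIT", "AKT2", "STK11", "NOTCH1", "PDGFRA", "MN1",
    "UBR5", "PTCH1")
}
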