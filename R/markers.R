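#' The bundled tumor-infiltrating-leukocyte marker set
#'
#' Returns the curated marker set shipped with the package: 60 genes
#' measuring 14 immune cell populations, plus a derived CD4 cell score
#' defined as the T-cell score minus the CD8 T-cell score.  Three
#' populations (CD45, Th1 cells, Treg) are measured by a single canonical
#' gene whose quality cannot be assessed from co-expression alone.  The
#' `info` slot carries, per cell type, the number of literature-derived
#' candidate genes screened and the mean pairwise similarity of the
#' selected markers in the large pan-cancer cohort used to validate them.
#'
#' @return A [MarkerSet-class].
#' @examples
#' ms <- bundledMarkerSet()
#' cellTypes(ms)
#' markerGenes(ms, "CD8 T cells")
#' @export
bundledMarkerSet <- function() {
  gf <- system.file("extdata", "marker_genes.tsv", package = "TILscore")
  inf <- system.file("extdata", "cell_type_info.tsv", package = "TILscore")
  genes <- utils::read.delim(gf, stringsAsFactors = FALSE)
  info <- utils::read.delim(inf, stringsAsFactors = FALSE, fill = TRUE)
  markers <- split(genes$gene, factor(genes$cell_type,
                                      levels = unique(genes$cell_type)))
  sg <- structure(info$single_gene, names = info$cell_type)[names(markers)]
  MarkerSet(markers,
            singleGene = sg,
            derived = list(
              "CD4 cells" = list(from = "T-cells", minus = "CD8 T cells")),
            info = info)
}

#' Read a marker set from a file
#'
#' Accepts either a two-column TSV/CSV (`cell_type`, `gene`; one row per
#' marker gene) or a JSON/YAML mapping of cell type to gene list.  An
#' optional top-level `derived` entry in JSON/YAML defines derived scores,
#' e.g. `{"derived": {"CD4 cells": {"from": "T-cells", "minus":
#' "CD8 T cells"}}}`.
#'
#' @param path Path to the marker file (`.tsv`, `.csv`, `.json`, `.yml`,
#'   `.yaml`).
#' @return A [MarkerSet-class].
#' @export
readMarkerSet <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("json", "yml", "yaml")) {
    obj <- if (ext == "json") jsonlite::fromJSON(path, simplifyVector = TRUE)
           else yaml::read_yaml(path)
    derived <- obj[["derived"]]
    obj[["derived"]] <- NULL
    markers <- lapply(obj, function(g) as.character(unlist(g)))
    if (!length(markers)) stop("no cell types found in ", path)
    return(MarkerSet(markers,
                     derived = if (is.null(derived)) list() else derived))
  }
  sep <- if (ext == "csv") "," else "\t"
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("cell_type", "gene")
  if (!all(need %in% names(df)))
    stop("marker table must have columns: ", paste(need, collapse = ", "))
  if (!nrow(df)) stop("marker table is empty")
  MarkerSet(split(df$gene, factor(df$cell_type,
                                  levels = unique(df$cell_type))))
}
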