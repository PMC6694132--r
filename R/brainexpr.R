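#' Per-region mean expression of each probe
#'
#' For one region-annotated expression data set (one donor brain), computes
#' the arithmetic mean of every probe over the samples of each region.
#' Regions without samples in the data set are absent from the output.
#'
#' @param dataset region-annotated \code{SummarizedExperiment} (colData
#'   column \code{region}) or a matrix plus a \code{regions} vector.
#' @param regions per-sample region labels (required when \code{dataset}
#'   is a plain matrix).
#' @return numeric matrix, probes x regions.
#' @export
regionMeans <- function(dataset, regions = NULL) {
  if (methods::is(dataset, "SummarizedExperiment")) {
    regions <- SummarizedExperiment::colData(dataset)$region
    m <- SummarizedExperiment::assay(dataset)
  } else {
    m <- as.matrix(dataset)
  }
  if (is.null(regions) || length(regions) != ncol(m))
    stop("every sample must carry a region label")
  regs <- unique(regions)
  out <- matrix(NA_real_, nrow(m), length(regs),
                dimnames = list(rownames(m), regs))
  for (r in regs)
    out[, r] <- rowMeans(m[, regions == r, drop = FALSE])
  out
}

#' Z-score region means and collapse probes to genes
#'
#' Within each data set and each region, probe means are standardized
#' across probes (column-wise: mean 0, sd 1 per region). Per-probe Z-scores
#' are then averaged across the data sets in which the probe/region is
#' present. Finally probes are collapsed to genes: for each gene the entire
#' regional profile of the probe whose maximum absolute Z-score over
#' regions is largest is kept. Regions with zero within-region dispersion
#' in a data set are dropped from that data set with a message. The
#' alternative standardization axis (across regions within each probe) is
#' available via \code{axis = "within_probe"}; the choice is recorded in
#' the output attributes.
#'
#' @param meanTables list of probe x region mean matrices (one per data
#'   set), as produced by \code{\link{regionMeans}}.
#' @param probeMap \code{data.frame(probe_id, ensg)}.
#' @param axis standardization axis, \code{"within_region"} (default) or
#'   \code{"within_probe"}.
#' @return gene x region Z-score matrix with attributes \code{provenance}
#'   (chosen probe per gene) and \code{zscore_axis}.
#' @export
zscoreAndCollapse <- function(meanTables, probeMap,
                              axis = c("within_region", "within_probe")) {
  axis <- match.arg(axis)
  zTables <- lapply(meanTables, function(tab) {
    if (axis == "within_region") {
      sds <- apply(tab, 2, sd)
      drop <- sds == 0 | is.na(sds)
      if (any(drop))
        message("dropping ", sum(drop), " region(s) with zero dispersion")
      tab <- tab[, !drop, drop = FALSE]
      scale(tab)
    } else {
      t(scale(t(tab)))
    }
  })
  allProbes <- unique(unlist(lapply(zTables, rownames)))
  allRegions <- unique(unlist(lapply(zTables, colnames)))
  sumZ <- matrix(0, length(allProbes), length(allRegions),
                 dimnames = list(allProbes, allRegions))
  cnt <- sumZ
  for (z in zTables) {
    sumZ[rownames(z), colnames(z)] <- sumZ[rownames(z), colnames(z)] + z
    cnt[rownames(z), colnames(z)] <- cnt[rownames(z), colnames(z)] + 1
  }
  avg <- sumZ / cnt
  avg[cnt == 0] <- NA

  pm <- probeMap[probeMap$probe_id %in% rownames(avg), , drop = FALSE]
  genes <- unique(pm$ensg)
  chosen <- vapply(genes, function(g) {
    probes <- pm$probe_id[pm$ensg == g]
    if (length(probes) == 1) return(probes)
    best <- vapply(probes, function(p) max(abs(avg[p, ]), na.rm = TRUE),
                   numeric(1))
    probes[which.max(best)]
  }, character(1))
  out <- avg[chosen, , drop = FALSE]
  rownames(out) <- genes
  attr(out, "provenance") <- setNames(chosen, genes)
  attr(out, "zscore_axis") <- axis
  out
}
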