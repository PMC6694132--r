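# Tab-separated writers and readers for the generated inputs and the
# assembled network. All files are plain text with a header row.

#' Write and read the assembled edge list
#'
#' Header columns: \code{ENSG.A}, \code{ENSG.B}, \code{score},
#' \code{interaction_type}, \code{data_source}.
#'
#' @param edges edge table.
#' @param path file path.
#' @return \code{readHenaEdges} returns the edge \code{data.frame} with
#'   the package's internal column names.
#' @export
writeHenaEdges <- function(edges, path) {
  out <- edges
  colnames(out)[colnames(out) == "ensg_a"] <- "ENSG.A"
  colnames(out)[colnames(out) == "ensg_b"] <- "ENSG.B"
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeHenaEdges
#' @export
readHenaEdges <- function(path) {
  tab <- read.delim(path, check.names = FALSE)
  colnames(tab)[colnames(tab) == "ENSG.A"] <- "ensg_a"
  colnames(tab)[colnames(tab) == "ENSG.B"] <- "ensg_b"
  tab
}

#' Write and read the node attribute table
#'
#' @param nodes flattened node attribute table (237 columns by default).
#' @param path file path.
#' @export
writeNodeAttributes <- function(nodes, path) {
  write.table(nodes, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeNodeAttributes
#' @export
readNodeAttributes <- function(path) {
  read.delim(path, check.names = FALSE)
}

#' Write an expression data set as a TSV matrix
#'
#' First column \code{probe_id}, remaining columns one per sample; sample
#' annotations go to a companion \code{<path>.samples} file.
#'
#' @param dataset a \code{SummarizedExperiment}.
#' @param path file path.
#' @export
writeExpressionTsv <- function(dataset, path) {
  m <- SummarizedExperiment::assay(dataset)
  out <- data.frame(probe_id = rownames(m), m, check.names = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  cd <- as.data.frame(SummarizedExperiment::colData(dataset))
  cd <- cbind(sample_id = rownames(cd), cd)
  write.table(cd, paste0(path, ".samples"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Write a genotype matrix as dosage TSV plus SNP map TSV
#'
#' The dosage file holds individuals in rows (first column
#' \code{individual}) and SNPs in columns in 0/1/2 coding; the map file
#' mirrors PLINK .map columns (chromosome, snp_id, position).
#'
#' @param genotypes a \linkS4class{GenotypeMatrix}.
#' @param path dosage file path; the map is written to \code{<path>.map}.
#' @export
writeGenotypeTsv <- function(genotypes, path) {
  d <- dosages(genotypes)
  out <- data.frame(individual = rownames(d), d, check.names = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  s <- snpInfo(genotypes)
  write.table(s[, c("chromosome", "snp_id", "position")],
              paste0(path, ".map"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Write a gene annotation as TSV
#'
#' @param annotation annotation list from \code{\link{genGeneAnnotation}}
#'   or a \code{GRanges} of gene models.
#' @param path file path.
#' @export
writeAnnotationTsv <- function(annotation, path) {
  genes <- if (is.list(annotation) && !methods::is(annotation, "GRanges"))
    annotation$genes else annotation
  out <- data.frame(ensg_id = genes$ensg_id,
                    gene_name = genes$gene_name,
                    chromosome = as.character(GenomicRanges::seqnames(genes)),
                    start = GenomicRanges::start(genes),
                    end = GenomicRanges::end(genes),
                    biotype = genes$biotype)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export the heterogeneous graph as GraphML
#'
#' Edge attributes carried: interaction type, score, data source.
#'
#' @param graph a \linkS4class{HeterogeneousGraph}.
#' @param path file path.
#' @export
writeGraphML <- function(graph, path) {
  e <- edgeTable(graph)
  g <- igraph::graph_from_data_frame(
    data.frame(from = e$ensg_a, to = e$ensg_b, type = e$interaction_type,
               score = e$score, source = e$data_source),
    directed = FALSE,
    vertices = data.frame(name = graphNodes(graph)))
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
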