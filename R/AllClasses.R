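#' @import methods
#' @importFrom stats aggregate anova as.formula complete.cases cor lm loess
#'   lm.fit median p.adjust pbeta pchisq pf pnorm predict pt qnorm quantile
#'   rbinom rnorm runif sd setNames
#' @importFrom utils head read.delim write.table
NULL

#' Genotype matrix with SNP metadata
#'
#' Container for an individuals-by-SNPs dosage matrix in 0/1/2 coding
#' (\code{NA} for missing calls) together with the per-SNP metadata
#' (identifier, chromosome, 1-based position, generating minor allele
#' frequency where known).
#'
#' @slot dosages numeric matrix, individuals in rows, SNPs in columns;
#'   entries restricted to 0, 1, 2 or \code{NA}.
#' @slot snps \code{data.frame} with columns \code{snp_id},
#'   \code{chromosome}, \code{position} and optionally \code{maf}; one row
#'   per column of \code{dosages}.
#'
#' @aliases GenotypeMatrix-class
#' @exportClass GenotypeMatrix
setClass("GenotypeMatrix",
  representation(dosages = "matrix", snps = "data.frame"))

setValidity("GenotypeMatrix", function(object) {
  msg <- character()
  d <- object@dosages
  if (ncol(d) != nrow(object@snps))
    msg <- c(msg, "number of dosage columns must equal number of SNP records")
  if (!all(c("snp_id", "chromosome", "position") %in% colnames(object@snps)))
    msg <- c(msg, "snps must have columns snp_id, chromosome, position")
  if (anyDuplicated(object@snps$snp_id))
    msg <- c(msg, "snp_id values must be unique")
  vals <- d[!is.na(d)]
  if (length(vals) && !all(vals %in% c(0, 1, 2)))
    msg <- c(msg, "dosages must be 0, 1, 2 or NA")
  if (length(msg)) msg else TRUE
})

#' Construct a GenotypeMatrix
#'
#' @param dosages individuals x SNPs matrix with entries in \{0, 1, 2, NA\};
#'   column names must match \code{snps$snp_id}.
#' @param snps per-SNP metadata \code{data.frame} (columns \code{snp_id},
#'   \code{chromosome}, \code{position}, optional \code{maf}).
#' @return A \linkS4class{GenotypeMatrix}.
#' @export
GenotypeMatrix <- function(dosages, snps) {
  dosages <- as.matrix(dosages)
  if (is.null(colnames(dosages))) colnames(dosages) <- snps$snp_id
  snps <- as.data.frame(snps)
  rownames(snps) <- NULL
  new("GenotypeMatrix", dosages = dosages, snps = snps)
}

#' @describeIn GenotypeMatrix dosage matrix accessor
#' @param x a \code{GenotypeMatrix}
#' @export
dosages <- function(x) x@dosages

#' @describeIn GenotypeMatrix SNP metadata accessor
#' @export
snpInfo <- function(x) x@snps

setMethod("show", "GenotypeMatrix", function(object) {
  cat("GenotypeMatrix:", nrow(object@dosages), "individuals x",
      ncol(object@dosages), "SNPs\n")
  miss <- mean(is.na(object@dosages))
  cat("  missing fraction:", format(miss, digits = 3), "\n")
})

#' @describeIn GenotypeMatrix number of individuals and SNPs
#' @export
setMethod("dim", "GenotypeMatrix", function(x) dim(x@dosages))

#' Heterogeneous interaction graph over ENSG nodes
#'
#' A multi-edge-type undirected graph in which nodes are Ensembl gene
#' identifiers and each edge carries an interaction type (PPI,
#' co-expression, epistasis, IGRI), a score and a data-source identifier.
#' Per-type subgraph views are stored as \pkg{igraph} objects.
#'
#' @slot edges \code{data.frame} with columns \code{ensg_a}, \code{ensg_b},
#'   \code{score}, \code{interaction_type}, \code{data_source}.
#' @slot nodes character vector of node identifiers (union of endpoints).
#' @slot subgraphs named list of \pkg{igraph} graphs, one per interaction
#'   type present.
#'
#' @aliases HeterogeneousGraph-class
#' @exportClass HeterogeneousGraph
setClass("HeterogeneousGraph",
  representation(edges = "data.frame", nodes = "character",
                 subgraphs = "list"))

setValidity("HeterogeneousGraph", function(object) {
  msg <- character()
  need <- c("ensg_a", "ensg_b", "score", "interaction_type", "data_source")
  if (!all(need %in% colnames(object@edges)))
    msg <- c(msg, paste("edges must have columns:", paste(need, collapse = ", ")))
  if (nrow(object@edges) &&
      !all(c(object@edges$ensg_a, object@edges$ensg_b) %in% object@nodes))
    msg <- c(msg, "all edge endpoints must be in the node set")
  if (length(msg)) msg else TRUE
})

#' Construct a HeterogeneousGraph from an assembled edge table
#'
#' @param edges edge \code{data.frame} with columns \code{ensg_a},
#'   \code{ensg_b}, \code{score}, \code{interaction_type},
#'   \code{data_source}.
#' @param nodes optional node universe; defaults to the union of edge
#'   endpoints, but may be a superset so that isolated genes stay in the
#'   graph.
#' @return A \linkS4class{HeterogeneousGraph} with one igraph subgraph per
#'   interaction type.
#' @export
HeterogeneousGraph <- function(edges, nodes = NULL) {
  edges <- as.data.frame(edges)
  nodes <- sort(union(nodes, unique(c(edges$ensg_a, edges$ensg_b))))
  types <- unique(edges$interaction_type)
  subs <- lapply(setNames(types, types), function(tp) {
    e <- edges[edges$interaction_type == tp, , drop = FALSE]
    g <- igraph::graph_from_data_frame(
      e[, c("ensg_a", "ensg_b")], directed = FALSE,
      vertices = data.frame(name = nodes))
    igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  })
  new("HeterogeneousGraph", edges = edges, nodes = nodes, subgraphs = subs)
}

#' @describeIn HeterogeneousGraph edge table accessor
#' @param x a \code{HeterogeneousGraph}
#' @export
edgeTable <- function(x) x@edges

#' @describeIn HeterogeneousGraph node identifier accessor
#' @export
graphNodes <- function(x) x@nodes

#' @describeIn HeterogeneousGraph typed subgraph accessor
#' @param type interaction type of the requested subgraph
#' @export
subgraph <- function(x, type) {
  if (!type %in% names(x@subgraphs))
    stop("unknown edge type: ", type)
  x@subgraphs[[type]]
}

#' @describeIn HeterogeneousGraph interaction types present
#' @export
edgeTypes <- function(x) names(x@subgraphs)

setMethod("show", "HeterogeneousGraph", function(object) {
  cat("HeterogeneousGraph:", length(object@nodes), "nodes,",
      nrow(object@edges), "edges\n")
  tab <- table(object@edges$interaction_type)
  for (tp in names(tab)) cat("  ", tp, ": ", tab[[tp]], "\n", sep = "")
})
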