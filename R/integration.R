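#' Map identifiers of a table onto the ENSG name space
#'
#' Expands each row by every ENSG its identifier maps to (one output row
#' per input-row/ENSG combination for one-to-many maps) and drops rows with
#' unmapped identifiers, counting the drops.
#'
#' @param records \code{data.frame} carrying identifier columns.
#' @param mapping two-column \code{data.frame}; first column the source
#'   identifier, second the ENSG id.
#' @param idCols names of the columns of \code{records} to map (each is
#'   replaced by the mapped ENSG values).
#' @return list with \code{mapped} (the mapped table) and \code{report}
#'   (input, mapped and dropped row counts).
#' @export
mapIdentifiers <- function(records, mapping, idCols) {
  if (nrow(mapping) == 0)
    warning("empty identifier mapping: all records will be dropped")
  colnames(mapping)[1:2] <- c(".from", ".to")
  out <- records
  out$.row <- seq_len(nrow(records))
  for (col in idCols) {
    tmp <- merge(out, mapping, by.x = col, by.y = ".from")
    tmp[[col]] <- tmp$.to
    tmp$.to <- NULL
    out <- tmp[, c(colnames(records), ".row"), drop = FALSE]
  }
  dropped <- nrow(records) - length(unique(out$.row))
  out$.row <- NULL
  rownames(out) <- NULL
  list(mapped = out,
       report = list(input = nrow(records), mapped = nrow(out),
                     dropped = dropped))
}

#' Filter MI-scored protein-protein interactions by confidence
#'
#' Keeps interactions whose IntAct-style MI score is at or above the
#' medium-confidence cut-off (boundary inclusive).
#'
#' @param edges PPI table with a \code{score} column.
#' @param minMi minimum MI score (default 0.45).
#' @return the filtered table.
#' @export
filterPpiByScore <- function(edges, minMi = 0.45) {
  edges[edges$score >= minMi, , drop = FALSE]
}

#' Assemble typed, scored edge records from stage outputs
#'
#' Each stage output table becomes a set of edge records with its
#' interaction type and data-source identifier; multi-edges between the
#' same node pair from different sources are preserved. Sources must exist
#' in the data-set registry.
#'
#' @param stageOutputs list of \code{list(table = <data.frame with ensg_a,
#'   ensg_b, score [, interaction_type]>, type = <interaction type>,
#'   source = <data_source_id>)}; when the table carries its own
#'   \code{interaction_type} column (bin-pair epistasis output), that
#'   column wins row-wise.
#' @param registry data-set registry (default the packaged 64-entry one).
#' @return edge \code{data.frame(ensg_a, ensg_b, score, interaction_type,
#'   data_source)}.
#' @export
assembleEdges <- function(stageOutputs, registry = henaDatasetRegistry()) {
  parts <- lapply(stageOutputs, function(st) {
    if (!st$source %in% registry$data_source_id)
      stop("unknown data_source_id: ", st$source)
    tab <- st$table
    if (nrow(tab) == 0) return(NULL)
    type <- if ("interaction_type" %in% colnames(tab))
      tab$interaction_type else st$type
    data.frame(ensg_a = tab$ensg_a, ensg_b = tab$ensg_b,
               score = tab$score, interaction_type = type,
               data_source = st$source)
  })
  out <- do.call(rbind, parts)
  if (is.null(out))
    out <- data.frame(ensg_a = character(), ensg_b = character(),
                      score = numeric(), interaction_type = character(),
                      data_source = character())
  rownames(out) <- NULL
  out
}

#' Assemble the 237-field node attribute table
#'
#' Merges, per ENSG id, the gene name and biotype from the annotation, the
#' GWAS SNP association (SNPs filtered to p at or below \code{gwasAlpha}
#' first), the positive-selection p-value and the brain-region Z-score
#' profile. Genes with several qualifying GWAS SNPs produce multiple
#' records in the long form; the flattened one-row-per-gene view keeps the
#' minimum p-value and its SNP id. Missing attributes are left \code{NA};
#' every vector has 6 scalar fields plus one field per region.
#'
#' @param gwas \code{data.frame(snp_id, ensg, p)}.
#' @param ps \code{data.frame(ensg, p)}.
#' @param zscores gene x region matrix from
#'   \code{\link{zscoreAndCollapse}} (or any matrix with ENSG rownames).
#' @param annotation gene models (\code{GRanges} with \code{ensg_id},
#'   \code{gene_name}, \code{biotype} or the \code{genes} element of a
#'   generated annotation).
#' @param gwasAlpha GWAS inclusion threshold (default 0.05).
#' @return list with \code{nodes} (flattened wide table, one row per gene)
#'   and \code{long} (one row per gene/SNP record).
#' @export
assembleNodeAttributes <- function(gwas, ps, zscores, annotation,
                                   gwasAlpha = 0.05) {
  genes <- if (is.list(annotation) && !methods::is(annotation, "GRanges"))
    annotation$genes else annotation
  base <- data.frame(ensg = genes$ensg_id, gene_name = genes$gene_name,
                     biotype = genes$biotype)
  gwas <- gwas[gwas$p <= gwasAlpha, , drop = FALSE]
  long <- merge(base, gwas[, c("ensg", "snp_id", "p")], by = "ensg",
                all.x = TRUE)
  names(long)[names(long) == "p"] <- "gwas_p"

  flatGwas <- do.call(rbind, lapply(split(gwas, gwas$ensg), function(grp) {
    i <- which.min(grp$p)
    data.frame(ensg = grp$ensg[i], snp_id = grp$snp_id[i], gwas_p = grp$p[i])
  }))
  nodes <- merge(base, flatGwas, by = "ensg", all.x = TRUE)
  psTab <- data.frame(ensg = ps$ensg, ps_p = ps$p)
  nodes <- merge(nodes, psTab, by = "ensg", all.x = TRUE)
  regionCols <- colnames(zscores)
  zdf <- as.data.frame(zscores)
  zdf$ensg <- rownames(zscores)
  nodes <- merge(nodes, zdf, by = "ensg", all.x = TRUE)
  nodes <- nodes[, c("ensg", "gene_name", "biotype", "snp_id", "gwas_p",
                     "ps_p", regionCols)]
  if (ncol(nodes) != 6 + length(regionCols))
    stop("schema error: node attribute width mismatch")
  rownames(nodes) <- NULL
  list(nodes = nodes, long = long)
}

#' Remove pseudogene nodes and their interactions
#'
#' Nodes whose biotype is any pseudogene category are removed from the node
#' table, and every edge touching a removed node is removed from the edge
#' list.
#'
#' @param edges assembled edge table.
#' @param nodes flattened node attribute table (column \code{biotype}).
#' @return list with \code{edges}, \code{nodes} and a removal
#'   \code{report}.
#' @export
filterPseudogenes <- function(edges, nodes) {
  isPseudo <- grepl("pseudogene", nodes$biotype)
  removedIds <- nodes$ensg[isPseudo]
  edgeHit <- edges$ensg_a %in% removedIds | edges$ensg_b %in% removedIds
  list(edges = edges[!edgeHit, , drop = FALSE],
       nodes = nodes[!isPseudo, , drop = FALSE],
       report = list(nodes_removed = sum(isPseudo),
                     edges_removed = sum(edgeHit)))
}

#' Summarize an assembled heterogeneous network
#'
#' Reports per-data-source edge counts, per-interaction-type subgraph node
#' and edge counts, overall counts, and the counts of the reduced version
#' in which region co-expression edges are restricted to absolute
#' correlation at or above 0.8.
#'
#' @param edges assembled edge table.
#' @param nodes node attribute table.
#' @return list of summary tables.
#' @export
summarizeHena <- function(edges, nodes) {
  perSource <- as.data.frame(table(edges$data_source),
                             stringsAsFactors = FALSE)
  colnames(perSource) <- c("data_source", "n_edges")
  perType <- do.call(rbind, lapply(split(edges, edges$interaction_type),
                                   function(grp)
    data.frame(interaction_type = grp$interaction_type[1],
               n_nodes = length(unique(c(grp$ensg_a, grp$ensg_b))),
               n_edges = nrow(grp))))
  rownames(perType) <- NULL
  red <- reducedEdges(edges)
  list(per_source = perSource, per_type = perType,
       full = list(n_nodes = length(unique(c(edges$ensg_a, edges$ensg_b))),
                   n_edges = nrow(edges)),
       reduced = list(n_edges = nrow(red)),
       n_node_records = nrow(nodes))
}

#' @describeIn summarizeHena apply the reduced-version filter: region
#'   co-expression edges (data sources \code{ABA_*}) are kept only when the
#'   correlation is <= -0.8 or >= 0.8; all other edges pass unchanged.
#' @param threshold absolute-correlation cut-off (default 0.8).
#' @export
reducedEdges <- function(edges, threshold = 0.8) {
  regionCoexpr <- edges$interaction_type == "co-expression" &
    startsWith(edges$data_source, "ABA_")
  keep <- !regionCoexpr | edges$score <= -threshold |
    edges$score >= threshold
  edges[keep, , drop = FALSE]
}

#' Exclusive intersection sizes of edge sets
#'
#' Canonicalizes each input set to unordered pairs and reports, for every
#' non-empty combination of sets, the number of pairs present in exactly
#' those sets (UpSet-style exclusive regions).
#'
#' @param ... named edge tables (\code{data.frame}s with \code{ensg_a},
#'   \code{ensg_b} or two-column pair tables).
#' @return \code{data.frame(combination, size)}; region sizes sum to the
#'   size of the union.
#' @export
compareEdgeSets <- function(...) {
  sets <- list(...)
  if (is.null(names(sets)) || any(names(sets) == ""))
    names(sets) <- paste0("set", seq_along(sets))
  keys <- lapply(sets, function(s) {
    a <- s[[1]]; b <- s[[2]]
    unique(pairKey(a, b))
  })
  universe <- unique(unlist(keys))
  member <- vapply(keys, function(k) universe %in% k,
                   logical(length(universe)))
  if (length(universe) == 1) member <- matrix(member, nrow = 1,
                                              dimnames = list(NULL, names(sets)))
  combo <- apply(member, 1, function(row)
    paste(names(sets)[row], collapse = "&"))
  tab <- table(combo)
  data.frame(combination = names(tab), size = as.integer(tab),
             row.names = NULL)
}
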