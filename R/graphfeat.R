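#' Prepare the case-study heterogeneous graph
#'
#' Filters an assembled edge list for the disease-gene prioritization use
#' case: IGRI edges (interactions touching intergenic regions) are
#' excluded, and region co-expression edges with absolute correlation
#' below \code{coexprMin} are excluded (negative correlations of magnitude
#' at or above the cut are kept). The remaining edges are grouped into
#' PPI / co-expression / epistasis subgraphs.
#'
#' @param edges assembled edge table.
#' @param coexprMin minimum absolute region co-expression value (default
#'   0.5).
#' @return a \linkS4class{HeterogeneousGraph}.
#' @export
prepareCaseStudyGraph <- function(edges, coexprMin = 0.5) {
  edges <- edges[edges$interaction_type != "IGRI", , drop = FALSE]
  regionCoexpr <- edges$interaction_type == "co-expression" &
    startsWith(edges$data_source, "ABA_")
  edges <- edges[!regionCoexpr | abs(edges$score) >= coexprMin, ,
                 drop = FALSE]
  HeterogeneousGraph(edges)
}

#' Assemble disease-association labels for the node set
#'
#' Positive labels are the GWAS-associated genes united with the
#' disease-related PPI genes (restricted to the graph's node set);
#' negative labels come from an externally supplied essential non-disease
#' gene list. Genes appearing in both lists resolve positive-over-negative
#' with a warning; all remaining nodes are labelled unknown. The three
#' classes partition the node set.
#'
#' @param gwasGenes,adPpiGenes character vectors of disease-associated
#'   gene ids.
#' @param negativeList externally supplied non-disease gene ids.
#' @param allNodes the graph's node identifiers.
#' @return list with \code{positive}, \code{negative}, \code{unknown}.
#' @export
assembleLabels <- function(gwasGenes, adPpiGenes, negativeList, allNodes) {
  positive <- intersect(union(gwasGenes, adPpiGenes), allNodes)
  conflict <- intersect(positive, negativeList)
  if (length(conflict))
    warning(length(conflict),
            " gene(s) in both positive and negative lists; kept positive")
  negative <- setdiff(intersect(negativeList, allNodes), positive)
  unknown <- setdiff(allNodes, c(positive, negative))
  if (length(positive) == 0 || length(negative) == 0)
    stop("degenerate label classes: positive and negative must be non-empty")
  list(positive = positive, negative = negative, unknown = unknown)
}

#' Fraction of disease-labelled genes in a node's exact-hop neighborhood
#'
#' Within the subgraph of one interaction type, computes the fraction of
#' positively labelled nodes among the nodes at shortest-path distance
#' exactly \code{hop} from the query node (the node itself excluded).
#' Nodes with an empty neighborhood return 0.
#'
#' @param graph a \linkS4class{HeterogeneousGraph}.
#' @param node node identifier.
#' @param labels label set from \code{\link{assembleLabels}} (or any list
#'   with a \code{positive} component).
#' @param hop 1 or 2.
#' @param edgeType which typed subgraph to use.
#' @return fraction in [0, 1].
#' @export
neighborhoodLabelFraction <- function(graph, node, labels, hop = 1,
                                      edgeType) {
  if (!edgeType %in% edgeTypes(graph))
    stop("unknown edge type: ", edgeType)
  if (!hop %in% c(1, 2)) stop("hop must be 1 or 2")
  g <- subgraph(graph, edgeType)
  d <- igraph::distances(g, v = node)[1, ]
  nbr <- names(d)[is.finite(d) & d == hop]
  if (length(nbr) == 0) return(0)
  mean(nbr %in% labels$positive)
}

#' Disease-region expression contrast for one gene
#'
#' Two-sample Wilcoxon rank-sum comparison of a gene's Z-scores in the
#' disease-associated brain regions against the remaining regions, using
#' the normal approximation with tie correction. The signed standardized
#' statistic (positive when disease-region expression is higher) enters
#' the biological feature block.
#'
#' @param zrow named numeric vector of region Z-scores for one gene.
#' @param diseaseRegions region ids forming the disease group.
#' @return list with \code{statistic} (Mann-Whitney U of the disease
#'   group), \code{z} (signed standardized statistic) and \code{p_value}
#'   (two-sided).
#' @export
diseaseRegionContrast <- function(zrow, diseaseRegions) {
  x <- zrow[names(zrow) %in% diseaseRegions]
  y <- zrow[!names(zrow) %in% diseaseRegions]
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) == 0 || length(y) == 0)
    return(list(statistic = NA_real_, z = NA_real_, p_value = NA_real_))
  m <- length(x); n <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  mu <- m * n / 2
  ties <- table(r)
  sigma2 <- m * n / 12 * ((m + n + 1) -
    sum(ties^3 - ties) / ((m + n) * (m + n - 1)))
  if (sigma2 <= 0)
    return(list(statistic = U, z = 0, p_value = 1))
  z <- (U - mu) / sqrt(sigma2)
  list(statistic = U, z = z, p_value = 2 * pnorm(-abs(z)))
}

#' Build the node feature table for disease-gene prioritization
#'
#' The biological block holds each node's brain-region Z-score profile plus
#' the disease-region contrast statistic; the graph block holds the
#' positive-label fraction in the exact 1-hop and 2-hop neighborhood of
#' every typed subgraph. Missing Z-scores are imputed as 0 (region-average
#' expression).
#'
#' @param graph a \linkS4class{HeterogeneousGraph}.
#' @param zscores gene x region Z-score matrix.
#' @param labels label set (its \code{positive} component defines the
#'   neighborhood fractions).
#' @param diseaseRegions disease-region ids (default the packaged seven).
#' @return \code{data.frame} keyed by \code{ensg} with feature columns;
#'   attribute \code{blocks} names the columns of each block.
#' @export
buildFeatureTable <- function(graph, zscores, labels,
                              diseaseRegions = henaDiseaseRegions()) {
  nodes <- graphNodes(graph)
  regions <- colnames(zscores)
  z <- matrix(0, length(nodes), length(regions),
              dimnames = list(nodes, regions))
  common <- intersect(nodes, rownames(zscores))
  z[common, ] <- zscores[common, ]
  z[is.na(z)] <- 0
  contrast <- vapply(nodes, function(nd)
    diseaseRegionContrast(z[nd, ], diseaseRegions)$z, numeric(1))
  bio <- cbind(as.data.frame(z), disease_region_contrast = contrast)

  graphCols <- list()
  for (tp in edgeTypes(graph)) {
    g <- subgraph(graph, tp)
    d <- igraph::distances(g, v = nodes)
    posMask <- colnames(d) %in% labels$positive
    for (hop in c(1, 2)) {
      frac <- vapply(seq_along(nodes), function(i) {
        nbr <- is.finite(d[i, ]) & d[i, ] == hop
        if (!any(nbr)) return(0)
        mean(posMask[nbr])
      }, numeric(1))
      graphCols[[paste0("frac_pos_", gsub("-", "_", tp), "_hop", hop)]] <- frac
    }
  }
  gb <- as.data.frame(graphCols)
  out <- cbind(data.frame(ensg = nodes), bio, gb)
  rownames(out) <- NULL
  attr(out, "blocks") <- list(biological = colnames(bio),
                              graph = colnames(gb))
  out
}

#' Reference random-forest scorer
#'
#' Fits a random forest on the labelled nodes of a feature table and
#' returns a disease-association probability for every node. This is the
#' packaged reference scorer; any fit/score function over the feature
#' table can be substituted.
#'
#' @param features feature table from \code{\link{buildFeatureTable}}.
#' @param labels label set.
#' @param featureCols which feature columns to use (default all).
#' @param trainIds optional subset of labelled nodes to train on (holdout
#'   evaluation); defaults to all labelled nodes.
#' @param ntree forest size (default 200).
#' @param seed RNG seed for the forest.
#' @return named numeric vector of probabilities for every node.
#' @export
scoreGenesRF <- function(features, labels, featureCols = NULL,
                         trainIds = NULL, ntree = 200, seed = 1) {
  if (is.null(featureCols))
    featureCols <- setdiff(colnames(features), "ensg")
  labelled <- c(labels$positive, labels$negative)
  if (is.null(trainIds)) trainIds <- labelled
  trainIdx <- features$ensg %in% trainIds
  yTrain <- factor(ifelse(features$ensg[trainIdx] %in% labels$positive,
                          "pos", "neg"), levels = c("neg", "pos"))
  X <- features[, featureCols, drop = FALSE]
  fit <- withSeed(seed, randomForest::randomForest(
    x = X[trainIdx, , drop = FALSE], y = yTrain, ntree = ntree))
  prob <- predict(fit, X, type = "prob")[, "pos"]
  setNames(as.numeric(prob), features$ensg)
}

#' Evaluate a node classifier on the labelled nodes
#'
#' Precision, recall and F1 at the given probability threshold, and ROC
#' AUC by the rank statistic, computed on positively and negatively
#' labelled nodes only.
#'
#' @param scores named per-node probabilities.
#' @param labels label set.
#' @param threshold classification threshold (default 0.5; scores at or
#'   above it predict positive).
#' @return list with \code{precision}, \code{recall}, \code{f1},
#'   \code{auc}, and the confusion counts.
#' @export
evaluateClassifier <- function(scores, labels, threshold = 0.5) {
  ids <- c(labels$positive, labels$negative)
  missing <- setdiff(ids, names(scores))
  if (length(missing))
    stop("scores missing for ", length(missing), " labelled node(s)")
  if (length(labels$positive) == 0 || length(labels$negative) == 0)
    stop("AUC undefined: need both label classes")
  s <- scores[ids]
  truth <- ids %in% labels$positive
  pred <- s >= threshold
  tp <- sum(pred & truth); fp <- sum(pred & !truth)
  fn <- sum(!pred & truth)
  precision <- if (tp + fp == 0) NA_real_ else tp / (tp + fp)
  recall <- if (tp + fn == 0) NA_real_ else tp / (tp + fn)
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0)
    NA_real_ else 2 * precision * recall / (precision + recall)
  r <- rank(s)
  nPos <- sum(truth); nNeg <- sum(!truth)
  auc <- (sum(r[truth]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
  list(precision = precision, recall = recall, f1 = f1, auc = auc,
       tp = tp, fp = fp, fn = fn, tn = sum(!pred & !truth))
}

#' Rank unknown nodes by disease-association probability
#'
#' @param scores named per-node probabilities.
#' @param labels label set (its \code{unknown} component is ranked).
#' @return \code{data.frame(ensg, score)} sorted by descending score, ties
#'   broken lexicographically by gene id.
#' @export
rankUnknowns <- function(scores, labels) {
  s <- scores[names(scores) %in% labels$unknown]
  ord <- order(-s, names(s))
  data.frame(ensg = names(s)[ord], score = as.numeric(s[ord]),
             row.names = NULL)
}
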