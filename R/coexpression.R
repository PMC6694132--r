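#' Spearman correlation for all probe pairs
#'
#' Computes the Spearman rank correlation between every unordered pair of
#' probes of an expression data set, optionally with two-sided p-values
#' from the t-approximation of Spearman's statistic. Probes with zero rank
#' variance (constant across samples) are excluded with a message.
#'
#' @param dataset a \code{SummarizedExperiment} (probes x samples) or a
#'   plain numeric matrix.
#' @param withPvalues if \code{TRUE}, add a \code{p_value} column.
#' @return \code{data.frame} with columns \code{id_a}, \code{id_b} (pairs
#'   canonicalized so \code{id_a < id_b}), \code{value} (rho) and
#'   optionally \code{p_value}; attribute \code{value_kind} is
#'   \code{"spearman_rho"}, attribute \code{n_samples} records the sample
#'   count.
#' @export
spearmanAllPairs <- function(dataset, withPvalues = FALSE) {
  m <- if (methods::is(dataset, "SummarizedExperiment"))
    SummarizedExperiment::assay(dataset) else as.matrix(dataset)
  if (ncol(m) < 3) stop("need >= 3 samples")
  if (nrow(m) < 2) stop("need >= 2 probes")
  constant <- apply(m, 1, function(x) length(unique(x)) == 1)
  if (any(constant)) {
    message("excluding ", sum(constant), " constant probe(s): ",
            paste(head(rownames(m)[constant], 5), collapse = ", "))
    m <- m[!constant, , drop = FALSE]
  }
  if (nrow(m) < 2) stop("fewer than 2 non-constant probes")
  rho <- cor(t(m), method = "spearman")
  idx <- which(upper.tri(rho), arr.ind = TRUE)
  out <- data.frame(id_a = rownames(rho)[idx[, 1]],
                    id_b = rownames(rho)[idx[, 2]],
                    value = rho[idx])
  n <- ncol(m)
  if (withPvalues) {
    r <- pmin(pmax(out$value, -1), 1)
    tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
    out$p_value <- 2 * pt(-abs(tstat), df = n - 2)
    out$p_value[abs(r) == 1] <- 0
  }
  out <- canonicalizePairs(out)
  attr(out, "value_kind") <- "spearman_rho"
  attr(out, "n_samples") <- n
  out
}

#' Rank correlation pairs within one data set
#'
#' Assigns rank 1 to the pair with the strongest correlation and normalizes
#' by the number of pairs, yielding normalized ranks in (0, 1]. "Strongest"
#' is by default the largest absolute correlation (capturing negative
#' co-regulation); \code{rankBy = "signed"} ranks by signed descending
#' value. Ties receive average ranks.
#'
#' @param correlations output of \code{\link{spearmanAllPairs}}.
#' @param rankBy \code{"abs"} (default) or \code{"signed"}.
#' @return the input with columns \code{rank} and \code{normalized_rank}
#'   added.
#' @export
rankPairs <- function(correlations, rankBy = c("abs", "signed")) {
  rankBy <- match.arg(rankBy)
  if (nrow(correlations) == 0) {
    correlations$rank <- numeric(0)
    correlations$normalized_rank <- numeric(0)
    return(correlations)
  }
  key <- if (rankBy == "abs") -abs(correlations$value) else -correlations$value
  r <- rank(key, ties.method = "average")
  correlations$rank <- r
  correlations$normalized_rank <- r / nrow(correlations)
  correlations
}

#' Robust Rank Aggregation score
#'
#' For normalized ranks \eqn{r_{(1)} \le \dots \le r_{(k)}} from \eqn{k}
#' data sets, computes \eqn{\rho = \min_j P(\mathrm{Beta}(j, k-j+1) \le
#' r_{(j)})} -- the probability under the null of independent uniform
#' rankings that the j-th smallest rank is at least as extreme as observed
#' -- and returns the Bonferroni-style corrected score
#' \eqn{\min(k\rho, 1)}. Lower scores indicate stronger cross-study
#' agreement.
#'
#' @param ranks numeric vector of normalized ranks in (0, 1].
#' @return score in (0, 1].
#' @export
rraScore <- function(ranks) {
  if (length(ranks) < 1) stop("need at least one rank")
  if (any(ranks <= 0 | ranks > 1)) stop("ranks must lie in (0, 1]")
  k <- length(ranks)
  r <- sort(ranks)
  rho <- min(pbeta(r, seq_len(k), k - seq_len(k) + 1))
  min(k * rho, 1)
}

#' Cross-study rank-aggregated co-expression
#'
#' The full co-expression pipeline over a panel of expression cohorts:
#' per-data-set Spearman correlation of all probe pairs, rank
#' normalization, Robust Rank Aggregation across data sets (pairs absent
#' from a data set contribute normalized rank 1), Benjamini-Hochberg
#' adjustment of the RRA scores, thresholding of the adjusted score, probe
#' to ENSG mapping (unmapped probes dropped with a message, self-pairs
#' after mapping dropped), and collapse of duplicate gene pairs and A-B /
#' B-A orientations by the maximum (most conservative) score.
#'
#' @param datasets list of \code{SummarizedExperiment}s or matrices.
#' @param probeMap \code{data.frame(probe_id, ensg)}.
#' @param alpha keep pairs with adjusted score below this (default 1e-5).
#' @param rankBy passed to \code{\link{rankPairs}}.
#' @return \code{data.frame(ensg_a, ensg_b, score)} with attribute
#'   \code{value_kind = "rra_score"}; empty (with a message) when nothing
#'   survives.
#' @export
aggregateGlobalCoexpression <- function(datasets, probeMap, alpha = 1e-5,
                                        rankBy = "abs") {
  if (length(datasets) < 1) stop("need at least one dataset")
  k <- length(datasets)
  perDataset <- lapply(datasets, function(d)
    rankPairs(spearmanAllPairs(d), rankBy = rankBy))
  keys <- lapply(perDataset, function(tb) pairKey(tb$id_a, tb$id_b))
  allKeys <- unique(unlist(keys))
  rankMat <- matrix(1, nrow = length(allKeys), ncol = k,
                    dimnames = list(allKeys, NULL))
  for (i in seq_len(k))
    rankMat[keys[[i]], i] <- perDataset[[i]]$normalized_rank
  scores <- apply(rankMat, 1, rraScore)
  adj <- p.adjust(scores, method = "BH")
  keep <- adj < alpha
  if (!any(keep)) {
    message("no probe pairs survive the RRA threshold of ", alpha)
    out <- data.frame(ensg_a = character(), ensg_b = character(),
                      score = numeric())
    attr(out, "value_kind") <- "rra_score"
    return(out)
  }
  parts <- strsplit(allKeys[keep], "\r", fixed = TRUE)
  probeTab <- data.frame(id_a = vapply(parts, `[`, "", 1),
                         id_b = vapply(parts, `[`, "", 2),
                         score = adj[keep])
  mapProbePairsToGenes(probeTab, probeMap, valueKind = "rra_score",
                       collapse = "max")
}

# Map a probe-pair score table to the gene level: expand one-to-many maps,
# drop unmapped probes and self-pairs, canonicalize, collapse duplicates.
mapProbePairsToGenes <- function(tab, probeMap, valueKind,
                                 collapse = c("max", "maxabs")) {
  collapse <- match.arg(collapse)
  emptyOut <- function() {
    out <- data.frame(ensg_a = character(), ensg_b = character(),
                      score = numeric())
    attr(out, "value_kind") <- valueKind
    out
  }
  if (nrow(tab) == 0) return(emptyOut())
  mapped <- merge(tab, probeMap, by.x = "id_a", by.y = "probe_id")
  names(mapped)[names(mapped) == "ensg"] <- "ensg_a"
  nA <- length(unique(tab$id_a[!tab$id_a %in% probeMap$probe_id]))
  mapped <- merge(mapped, probeMap, by.x = "id_b", by.y = "probe_id")
  names(mapped)[names(mapped) == "ensg"] <- "ensg_b"
  nB <- length(unique(tab$id_b[!tab$id_b %in% probeMap$probe_id]))
  if (nA + nB > 0)
    message("dropped pairs involving ", nA + nB, " unmapped probe(s)")
  mapped <- mapped[mapped$ensg_a != mapped$ensg_b, , drop = FALSE]
  if (nrow(mapped) == 0) return(emptyOut())
  mapped <- canonicalizePairs(mapped, a = "ensg_a", b = "ensg_b")
  key <- paste(mapped$ensg_a, mapped$ensg_b, sep = "\r")
  pick <- if (collapse == "max")
    tapply(mapped$score, key, max)
  else
    tapply(seq_len(nrow(mapped)), key,
           function(ii) mapped$score[ii][which.max(abs(mapped$score[ii]))])
  parts <- strsplit(names(pick), "\r", fixed = TRUE)
  out <- data.frame(ensg_a = vapply(parts, `[`, "", 1),
                    ensg_b = vapply(parts, `[`, "", 2),
                    score = as.numeric(pick))
  out <- out[order(out$ensg_a, out$ensg_b), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "value_kind") <- valueKind
  out
}

#' Region-specific quartile-filtered co-expression
#'
#' Restricts a region-annotated expression data set to the samples of one
#' brain region, computes Spearman correlations with p-values for all probe
#' pairs, keeps pairs with Benjamini-Hochberg adjusted p-value at or below
#' \code{pThreshold}, then applies the quartile filter: retained positive
#' correlations must be at or above the first quartile of the positive
#' correlation distribution, retained negative correlations at or below
#' the third quartile of the negative distribution (quartiles by linear
#' interpolation between order statistics). The surviving pairs are mapped
#' to the gene level (duplicates collapsed by largest absolute
#' correlation).
#'
#' @param dataset region-annotated \code{SummarizedExperiment} (colData
#'   column \code{region}).
#' @param region region identifier to analyse.
#' @param pThreshold adjusted-p cut-off (default 0.01).
#' @param probeMap \code{data.frame(probe_id, ensg)}.
#' @return gene-level \code{data.frame(ensg_a, ensg_b, score)} with
#'   attributes \code{value_kind = "spearman_rho"} and \code{data_source =
#'   "ABA_<region>"}.
#' @export
regionCoexpression <- function(dataset, region, pThreshold = 0.01, probeMap) {
  cd <- SummarizedExperiment::colData(dataset)
  if (!"region" %in% colnames(cd)) stop("dataset has no region annotation")
  sel <- cd$region == region
  if (!any(sel)) stop("region not present in the dataset: ", region)
  if (sum(sel) < 3)
    stop("insufficient data: region ", region, " has fewer than 3 samples")
  sub <- dataset[, sel]
  tab <- spearmanAllPairs(sub, withPvalues = TRUE)
  tab$p_adj <- p.adjust(tab$p_value, method = "BH")
  tab <- tab[tab$p_adj <= pThreshold, , drop = FALSE]
  tab <- applyQuartileFilter(tab)
  out <- mapProbePairsToGenes(tab[, c("id_a", "id_b", "value")] |>
                                (\(x) {names(x)[3] <- "score"; x})(),
                              probeMap, valueKind = "spearman_rho",
                              collapse = "maxabs")
  attr(out, "data_source") <- paste0("ABA_", region)
  out
}

# Quartile filter on the signed correlation distribution of the surviving
# pairs: keep rho >= Q1 of the positive subset or rho <= Q3 of the negative
# subset. Type-7 (linear interpolation) quantiles.
applyQuartileFilter <- function(tab, valueCol = "value") {
  v <- tab[[valueCol]]
  posQ1 <- if (any(v > 0)) quantile(v[v > 0], 0.25, names = FALSE) else Inf
  negQ3 <- if (any(v < 0)) quantile(v[v < 0], 0.75, names = FALSE) else -Inf
  tab[(v > 0 & v >= posQ1) | (v < 0 & v <= negQ3), , drop = FALSE]
}
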