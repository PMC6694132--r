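#' Derive latest-value and slope phenotypes from longitudinal trait series
#'
#' For every cognitive trait, two per-individual phenotypes are derived:
#' the last assessed value (\code{<trait>_latest}) and the slope of an
#' ordinary least-squares line of value on time (\code{<trait>_slope}).
#' Individuals with fewer than two observations of a trait receive a
#' missing slope.
#'
#' @param series long \code{data.frame} with columns \code{individual},
#'   \code{trait}, \code{time}, \code{value}.
#' @return wide \code{data.frame} keyed by \code{individual} with two
#'   derived columns per trait.
#' @export
deriveTraitValues <- function(series) {
  stopifnot(all(c("individual", "trait", "time", "value") %in%
                  colnames(series)))
  individuals <- sort(unique(series$individual))
  traits <- unique(series$trait)
  out <- data.frame(individual = individuals)
  for (tr in traits) {
    sub <- series[series$trait == tr, , drop = FALSE]
    latest <- rep(NA_real_, length(individuals))
    slope <- rep(NA_real_, length(individuals))
    for (grp in split(sub, sub$individual)) {
      i <- match(grp$individual[1], individuals)
      if (nrow(grp) == 0) next
      ord <- order(grp$time)
      latest[i] <- grp$value[ord[length(ord)]]
      if (nrow(grp) >= 2) {
        t <- grp$time; v <- grp$value
        slope[i] <- sum((t - mean(t)) * (v - mean(v))) / sum((t - mean(t))^2)
      }
    }
    out[[paste0(tr, "_latest")]] <- latest
    out[[paste0(tr, "_slope")]] <- slope
  }
  out
}

#' Age-adjust an ordinal Braak-like score
#'
#' The Braak stage (1-6) increases with age even in cognitively normal
#' individuals; the age effect is estimated by loess regression of score on
#' age and subtracted, and the residual score is the phenotype used for
#' epistasis scanning. If all ages are identical the scores are
#' mean-centered instead (with a warning).
#'
#' @param scores per-individual ordinal scores in [1, 6] (named by
#'   individual where available).
#' @param ages per-individual ages.
#' @param span loess smoothing span (default 0.75).
#' @return named numeric vector of residuals.
#' @export
adjustBraak <- function(scores, ages, span = 0.75) {
  if (length(scores) != length(ages)) stop("scores and ages differ in length")
  if (length(scores) < 10) stop("need n >= 10 for the loess fit")
  if (any(scores < 1 | scores > 6)) stop("scores must lie in [1, 6]")
  if (length(unique(ages)) == 1) {
    warning("all ages identical; falling back to mean-centering")
    res <- scores - mean(scores)
  } else {
    fit <- loess(scores ~ ages, span = span, degree = 2)
    res <- scores - predict(fit, ages)
  }
  names(res) <- names(scores)
  res
}

#' Covariate-adjust the rate of ventricular-volume change
#'
#' Stage 1 fits a per-individual OLS slope to the longitudinal volume
#' series (individuals with fewer than two time points are excluded with a
#' message). Stage 2 regresses the slopes on age, sex and baseline disease
#' status and returns the residuals, the phenotype unexplained by those
#' covariates.
#'
#' @param series \code{data.frame(individual, time, volume)}.
#' @param covariates \code{data.frame(individual, age, sex,
#'   baseline_status)}.
#' @return named numeric vector of residual slopes.
#' @export
adjustVentricle <- function(series, covariates) {
  counts <- table(series$individual)
  ok <- names(counts)[counts >= 2]
  dropped <- setdiff(names(counts), ok)
  if (length(dropped))
    message("excluding ", length(dropped),
            " individual(s) with < 2 time points")
  slopes <- vapply(ok, function(id) {
    grp <- series[series$individual == id, ]
    t <- grp$time; v <- grp$volume
    sum((t - mean(t)) * (v - mean(v))) / sum((t - mean(t))^2)
  }, numeric(1))
  dat <- merge(data.frame(individual = ok, slope = slopes), covariates,
               by = "individual")
  fit <- lm(slope ~ age + sex + baseline_status, data = dat)
  setNames(stats::residuals(fit), dat$individual)
}

#' Genotype marker quality control
#'
#' Removes SNPs with missing-call fraction above \code{maxMissing}, minor
#' allele frequency below \code{minMaf}, or departure from Hardy-Weinberg
#' equilibrium at \code{hweAlpha} by a 1-df chi-square test on the genotype
#' counts. Each exclusion is recorded with its (first-failing) reason, in
#' the order missing, maf, hwe.
#'
#' @param genotypes a \linkS4class{GenotypeMatrix}.
#' @param maxMissing maximum tolerated missing fraction (default 0.1).
#' @param minMaf minimum minor allele frequency (default 0.05; exclusion is
#'   strict: MAF < 0.05 fails).
#' @param hweAlpha HWE exclusion level (default 1e-3; p <= alpha fails).
#' @return list with \code{genotypes} (filtered) and \code{report}
#'   (\code{data.frame(snp_id, reason)}).
#' @export
qcFilter <- function(genotypes, maxMissing = 0.1, minMaf = 0.05,
                     hweAlpha = 1e-3) {
  d <- dosages(genotypes)
  missFrac <- colMeans(is.na(d))
  maf <- apply(d, 2, function(g) {
    p <- mean(g, na.rm = TRUE) / 2
    min(p, 1 - p)
  })
  hweP <- apply(d, 2, hweChisqP)
  reason <- rep(NA_character_, ncol(d))
  reason[is.na(reason) & missFrac > maxMissing] <- "missing"
  reason[is.na(reason) & maf < minMaf] <- "maf"
  reason[is.na(reason) & hweP <= hweAlpha] <- "hwe"
  keep <- is.na(reason)
  if (!any(keep)) stop("all SNPs removed by quality control")
  report <- data.frame(snp_id = colnames(d)[!keep],
                       reason = reason[!keep])
  list(genotypes = GenotypeMatrix(d[, keep, drop = FALSE],
                                  snpInfo(genotypes)[keep, , drop = FALSE]),
       report = report)
}

# 1-df chi-square Hardy-Weinberg test on 0/1/2 genotype counts.
hweChisqP <- function(g) {
  g <- g[!is.na(g)]
  n <- length(g)
  if (n == 0) return(1)
  obs <- c(sum(g == 0), sum(g == 1), sum(g == 2))
  p <- (2 * obs[3] + obs[2]) / (2 * n)
  expct <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
  if (any(expct == 0)) return(1)
  chisq <- sum((obs - expct)^2 / expct)
  pchisq(chisq, df = 1, lower.tail = FALSE)
}

#' Pairwise-SNP epistasis test
#'
#' Fits \eqn{y = \beta_0 + \beta_A g_A + \beta_B g_B + \beta_{AB} g_A g_B
#' + \epsilon} by OLS on the allele dosages of two SNPs and tests the
#' multiplicative term against zero: \eqn{F = t^2} of the interaction
#' coefficient with (1, n-4) degrees of freedom, upper-tail p-value.
#' Missing dosages are removed pairwise (complete cases over the two SNPs
#' and the phenotype).
#'
#' @param gA,gB dosage vectors (0/1/2, NA allowed).
#' @param y phenotype values.
#' @return list with \code{beta} (interaction coefficient), \code{f},
#'   \code{p}, \code{n} (complete cases) and \code{ok}; when the design is
#'   collinear or degenerate, \code{ok = FALSE} with a \code{reason} and NA
#'   statistics.
#' @export
epistasisTest <- function(gA, gB, y) {
  cc <- complete.cases(gA, gB, y)
  gA <- gA[cc]; gB <- gB[cc]; y <- y[cc]
  n <- length(y)
  bad <- function(reason) list(beta = NA_real_, f = NA_real_, p = NA_real_,
                               n = n, ok = FALSE, reason = reason)
  if (n < 5) return(bad("fewer than 5 complete cases"))
  if (length(unique(gA)) == 1 || length(unique(gB)) == 1)
    return(bad("constant genotype"))
  X <- cbind(1, gA, gB, gA * gB)
  qrx <- qr(X)
  if (qrx$rank < 4) return(bad("collinear design"))
  beta <- qr.coef(qrx, y)
  res <- y - X %*% beta
  df <- n - 4
  s2 <- sum(res^2) / df
  xtxInv <- chol2inv(qr.R(qrx))
  se <- sqrt(s2 * xtxInv[4, 4])
  f <- (beta[4] / se)^2
  list(beta = unname(beta[4]), f = unname(f),
       p = pf(f, 1, df, lower.tail = FALSE), n = n, ok = TRUE)
}

#' Exhaustive pairwise epistasis scan
#'
#' Tests every unordered SNP pair whose MAF product exceeds
#' \code{mafProductMin} (computed on the QC'd panel) with
#' \code{\link{epistasisTest}} and returns the results below
#' \code{pThreshold}, sorted by ascending p-value. Collinear or degenerate
#' pairs are skipped with a message.
#'
#' @param genotypes a QC'd \linkS4class{GenotypeMatrix}.
#' @param phenotype named numeric vector (names matched against
#'   individuals; unnamed vectors are taken in row order).
#' @param mafProductMin MAF-product prefilter (default 0.01; pairs must
#'   exceed it).
#' @param pThreshold retain results with p below this (phenotype-family
#'   dependent: 1e-8 for ventricular volume and Braak score, 1e-5 for
#'   cognitive traits).
#' @return \code{data.frame(snp_a, snp_b, beta, f, p, n)} sorted by p.
#' @export
scanPairs <- function(genotypes, phenotype, mafProductMin = 0.01,
                      pThreshold = 1e-5) {
  d <- dosages(genotypes)
  if (!is.null(names(phenotype))) {
    common <- intersect(rownames(d), names(phenotype))
    d <- d[common, , drop = FALSE]
    phenotype <- phenotype[common]
  }
  maf <- apply(d, 2, function(g) {
    p <- mean(g, na.rm = TRUE) / 2
    min(p, 1 - p)
  })
  ids <- colnames(d)
  nSnp <- length(ids)
  rows <- vector("list", nSnp * (nSnp - 1) / 2)
  ri <- 0L
  skipped <- 0L
  for (i in seq_len(nSnp - 1)) {
    for (j in seq((i + 1), nSnp)) {
      if (maf[i] * maf[j] <= mafProductMin) next
      fit <- epistasisTest(d[, i], d[, j], phenotype)
      if (!fit$ok) { skipped <- skipped + 1L; next }
      ri <- ri + 1L
      rows[[ri]] <- data.frame(snp_a = ids[i], snp_b = ids[j],
                               beta = fit$beta, f = fit$f, p = fit$p,
                               n = fit$n)
    }
  }
  if (skipped > 0) message("skipped ", skipped, " degenerate pair(s)")
  out <- if (ri == 0)
    data.frame(snp_a = character(), snp_b = character(), beta = numeric(),
               f = numeric(), p = numeric(), n = integer())
  else do.call(rbind, rows[seq_len(ri)])
  out <- out[out$p < pThreshold, , drop = FALSE]
  out <- out[order(out$p), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Map SNPs to genic and intergenic bins
#'
#' A SNP inside a gene's boundaries extended by \code{margin} base pairs on
#' each side (inclusive) is assigned to that gene (to every such gene when
#' genes overlap). A SNP outside every extended gene is assigned to exactly
#' one intergenic region (IGR) identified by the dash-joined ENSG ids of
#' its two flanking genes; chromosome-terminal SNPs get a half-open
#' terminal IGR with the single flanking gene and a \code{*} sentinel.
#' SNPs on chromosomes without genes are left unassigned with a message.
#'
#' @param snps \code{data.frame(snp_id, chromosome, position)} or a
#'   \linkS4class{GenotypeMatrix}.
#' @param annotation gene models as a \code{GRanges} with metadata column
#'   \code{ensg_id}, or the list returned by
#'   \code{\link{genGeneAnnotation}}.
#' @param margin extension in base pairs (default 5000).
#' @return \code{data.frame(snp_id, bin_id, kind)} with \code{kind} in
#'   \code{genic}/\code{igr}; genic multi-assignments occupy multiple rows,
#'   IGR assignments exactly one.
#' @export
mapSnpsToBins <- function(snps, annotation, margin = 5000) {
  if (methods::is(snps, "GenotypeMatrix")) snps <- snpInfo(snps)
  genes <- if (is.list(annotation) && !methods::is(annotation, "GRanges"))
    annotation$genes else annotation
  snpGr <- GenomicRanges::GRanges(
    seqnames = as.character(snps$chromosome),
    ranges = IRanges::IRanges(start = snps$position, width = 1))
  ext <- genes
  GenomicRanges::start(ext) <- pmax(1, GenomicRanges::start(genes) - margin)
  GenomicRanges::end(ext) <- GenomicRanges::end(genes) + margin
  hits <- GenomicRanges::findOverlaps(snpGr, ext, ignore.strand = TRUE)
  genic <- data.frame(
    snp_id = snps$snp_id[S4Vectors::queryHits(hits)],
    bin_id = genes$ensg_id[S4Vectors::subjectHits(hits)],
    kind = "genic")
  rest <- setdiff(seq_len(nrow(snps)), unique(S4Vectors::queryHits(hits)))
  igrRows <- list()
  unassigned <- character()
  for (i in rest) {
    chr <- as.character(snps$chromosome[i])
    onChr <- which(as.character(GenomicRanges::seqnames(genes)) == chr)
    if (length(onChr) == 0) {
      unassigned <- c(unassigned, snps$snp_id[i])
      next
    }
    gs <- GenomicRanges::start(genes)[onChr]
    ge <- GenomicRanges::end(genes)[onChr]
    ids <- genes$ensg_id[onChr]
    pos <- snps$position[i]
    leftIdx <- which(ge < pos)
    rightIdx <- which(gs > pos)
    left <- if (length(leftIdx)) ids[leftIdx[which.max(ge[leftIdx])]] else "*"
    right <- if (length(rightIdx)) ids[rightIdx[which.min(gs[rightIdx])]] else "*"
    igrRows[[length(igrRows) + 1L]] <- data.frame(
      snp_id = snps$snp_id[i],
      bin_id = paste(left, right, sep = "-"),
      kind = "igr")
  }
  if (length(unassigned))
    message("unassigned SNP(s) on gene-free chromosome: ",
            paste(unassigned, collapse = ", "))
  out <- rbind(genic, do.call(rbind, igrRows))
  if (is.null(out))
    out <- data.frame(snp_id = character(), bin_id = character(),
                      kind = character())
  rownames(out) <- NULL
  out
}

#' Region-wise Bonferroni aggregation of an epistasis scan into bin pairs
#'
#' For a pair of bins with m and n member SNPs, the significance level is
#' adjusted to \code{alpha / (m * n)} -- the number of SNP pairs the two
#' bins can form. A bin pair is reported when any of its member SNP-pair
#' p-values falls below that threshold; the reported score is the minimum
#' member p-value. Bin pairs where both bins are genic are typed
#' \code{epistasis}; pairs touching an intergenic bin are typed
#' \code{IGRI}.
#'
#' @param results scan output of \code{\link{scanPairs}} (run with
#'   \code{pThreshold = 1} if full aggregation is wanted).
#' @param bins assignment table from \code{\link{mapSnpsToBins}}.
#' @param alpha family-wise level before correction (default 0.05).
#' @return \code{data.frame(bin_a, bin_b, score, n_tests, threshold,
#'   interaction_type)}.
#' @export
binwiseBonferroni <- function(results, bins, alpha = 0.05) {
  if (nrow(results) == 0)
    return(data.frame(bin_a = character(), bin_b = character(),
                      score = numeric(), n_tests = integer(),
                      threshold = numeric(), interaction_type = character()))
  if (!all(c(results$snp_a, results$snp_b) %in% bins$snp_id))
    stop("every scanned SNP must have a bin assignment")
  memberCount <- table(bins$bin_id)
  binKind <- setNames(bins$kind, bins$bin_id)
  binList <- split(bins$bin_id, bins$snp_id)
  expanded <- do.call(rbind, lapply(seq_len(nrow(results)), function(r) {
    ba <- binList[[results$snp_a[r]]]
    bb <- binList[[results$snp_b[r]]]
    grid <- expand.grid(bin_a = ba, bin_b = bb, stringsAsFactors = FALSE)
    grid$p <- results$p[r]
    grid
  }))
  expanded <- canonicalizePairs(expanded, a = "bin_a", b = "bin_b")
  key <- paste(expanded$bin_a, expanded$bin_b, sep = "\r")
  out <- do.call(rbind, lapply(split(expanded, key), function(grp) {
    m <- as.integer(memberCount[grp$bin_a[1]])
    n <- as.integer(memberCount[grp$bin_b[1]])
    thr <- alpha / (m * n)
    best <- min(grp$p)
    if (best >= thr) return(NULL)
    tp <- if (binKind[grp$bin_a[1]] == "igr" ||
              binKind[grp$bin_b[1]] == "igr") "IGRI" else "epistasis"
    data.frame(bin_a = grp$bin_a[1], bin_b = grp$bin_b[1], score = best,
               n_tests = m * n, threshold = thr, interaction_type = tp)
  }))
  if (is.null(out))
    out <- data.frame(bin_a = character(), bin_b = character(),
                      score = numeric(), n_tests = integer(),
                      threshold = numeric(), interaction_type = character())
  out <- out[order(out$score), , drop = FALSE]
  rownames(out) <- NULL
  out
}
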