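#' Generate a synthetic gene annotation
#'
#' Lays out gene models on a single synthetic chromosome using 1-based
#' inclusive coordinates (Ensembl convention). A configurable fraction of
#' adjacent gene pairs overlap, a configurable number of genes carry a
#' pseudogene biotype, and the accompanying probe map contains at least one
#' gene measured by two probes so that one-to-many probe collapsing is
#' exercised downstream.
#'
#' @param nGenes number of gene models (>= 2).
#' @param nPseudogenes how many genes receive biotype
#'   \code{processed_pseudogene}.
#' @param overlapFraction fraction in [0, 1) of adjacent gene pairs whose
#'   intervals overlap.
#' @param seed RNG seed (mandatory; generation is deterministic given the
#'   seed).
#' @return list with components \code{genes} (a
#'   \link[GenomicRanges]{GRanges} with metadata columns \code{ensg_id},
#'   \code{gene_name}, \code{biotype}), \code{probeMap}
#'   (\code{data.frame(probe_id, ensg)}) and \code{proteinMap}
#'   (\code{data.frame(protein_id, ensg)}).
#' @export
genGeneAnnotation <- function(nGenes, nPseudogenes = 0, overlapFraction = 0,
                              seed) {
  if (!is.numeric(nGenes) || nGenes < 2)
    stop("nGenes must be >= 2")
  if (overlapFraction < 0 || overlapFraction >= 1)
    stop("overlapFraction must be in [0, 1)")
  if (nPseudogenes > nGenes) stop("nPseudogenes cannot exceed nGenes")
  withSeed(seed, {
    lens <- round(runif(nGenes, 5000, 30000))
    gaps <- round(runif(nGenes, 15000, 60000))
    overlaps <- runif(nGenes) < overlapFraction
    start <- numeric(nGenes)
    start[1] <- 10000
    for (i in seq_len(nGenes)[-1]) {
      prevEnd <- start[i - 1] + lens[i - 1] - 1
      if (overlaps[i]) {
        depth <- round(runif(1, 500, min(3000, lens[i - 1] - 1, lens[i] - 1)))
        start[i] <- prevEnd - depth + 1
      } else {
        start[i] <- prevEnd + gaps[i]
      }
    }
    ensg <- sprintf("ENSG%011d", seq_len(nGenes))
    biotype <- rep("protein_coding", nGenes)
    nLinc <- max(0, round(0.1 * (nGenes - nPseudogenes)))
    nonPseudo <- seq_len(nGenes)
    if (nPseudogenes > 0) {
      pseudoIdx <- sample(seq_len(nGenes), nPseudogenes)
      biotype[pseudoIdx] <- "processed_pseudogene"
      nonPseudo <- setdiff(nonPseudo, pseudoIdx)
    }
    if (nLinc > 0 && length(nonPseudo) > nLinc)
      biotype[sample(nonPseudo, nLinc)] <- "lincRNA"
    genes <- GenomicRanges::GRanges(
      seqnames = "1",
      ranges = IRanges::IRanges(start = start, width = lens),
      ensg_id = ensg,
      gene_name = paste0("GENE", seq_len(nGenes)),
      biotype = biotype)
    nTwoProbe <- max(1, round(0.1 * nGenes))
    probeMap <- rbind(
      data.frame(probe_id = paste0("PR", seq_len(nGenes), "_1"), ensg = ensg),
      data.frame(probe_id = paste0("PR", seq_len(nTwoProbe), "_2"),
                 ensg = ensg[seq_len(nTwoProbe)]))
    coding <- biotype == "protein_coding"
    proteinMap <- data.frame(
      protein_id = paste0("PROT", seq_len(nGenes))[coding],
      ensg = ensg[coding])
    list(genes = genes, probeMap = probeMap, proteinMap = proteinMap)
  })
}

#' Generate expression cohorts with planted co-expression modules
#'
#' Emulates a panel of case/control microarray studies. Within each planted
#' module, probes of the member genes load on a shared latent factor
#' (\eqn{y = \lambda f + \sqrt{1-\lambda^2}\,\epsilon}) with the loading
#' chosen so that pairwise Spearman correlation is approximately the
#' requested target (via the bivariate-normal relation
#' \eqn{\rho_{Pearson} = 2\sin(\pi \rho_{Spearman}/6)}). Probes outside
#' modules carry independent unit-variance variation. \code{noiseSd}
#' adds measurement noise on top of everything, attenuating the planted
#' correlation; the target is attained at \code{noiseSd = 0} (the default).
#'
#' @param annotation output of \code{\link{genGeneAnnotation}}.
#' @param nDatasets number of cohorts (the modelled panel has six).
#' @param samplesPerDataset samples per cohort (recycled).
#' @param modules list of planted modules, each
#'   \code{list(genes = <ensg ids>, rho = <target Spearman in (-1, 1)>)}.
#' @param noiseSd standard deviation of additional measurement noise.
#' @param seed RNG seed.
#' @return list with \code{datasets} (list of
#'   \link[SummarizedExperiment]{SummarizedExperiment}s with per-sample
#'   \code{condition} labels AD/HI) and \code{groundTruth}.
#' @export
genExpressionCohorts <- function(annotation, nDatasets = 6,
                                 samplesPerDataset = 50, modules = list(),
                                 noiseSd = 0, seed) {
  probeMap <- annotation$probeMap
  ensgAll <- annotation$genes$ensg_id
  for (m in modules) {
    if (length(m$genes) < 2) stop("each module must list >= 2 genes")
    if (!all(m$genes %in% ensgAll))
      stop("module gene not present in the annotation")
    if (abs(m$rho) >= 1) stop("target correlation must be in (-1, 1)")
  }
  nSamp <- rep_len(samplesPerDataset, nDatasets)
  withSeed(seed, {
    datasets <- vector("list", nDatasets)
    for (d in seq_len(nDatasets)) {
      n <- nSamp[d]
      probes <- probeMap$probe_id
      base <- runif(length(probes), 5, 9)
      mat <- matrix(rnorm(length(probes) * n), nrow = length(probes),
                    dimnames = list(probes,
                                    sprintf("DS%d_S%03d", d, seq_len(n))))
      for (m in modules) {
        f <- rnorm(n)
        rp <- 2 * sin(pi * m$rho / 6)
        # negative targets only make sense for 2-gene modules: alternate the
        # loading sign across member genes
        memberGenes <- unique(probeMap$ensg[probeMap$ensg %in% m$genes])
        for (gi in seq_along(memberGenes)) {
          sgn <- if (rp < 0 && gi %% 2 == 0) -1 else 1
          for (p in probeMap$probe_id[probeMap$ensg == memberGenes[gi]])
            mat[p, ] <- sgn * sqrt(abs(rp)) * f + sqrt(1 - abs(rp)) * rnorm(n)
        }
      }
      if (noiseSd > 0)
        mat <- mat + matrix(rnorm(length(mat), sd = noiseSd), nrow = nrow(mat))
      mat <- mat + base
      cond <- sample(rep_len(c("AD", "HI"), n))
      se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(exprs = mat),
        colData = S4Vectors::DataFrame(condition = cond,
                                       row.names = colnames(mat)))
      S4Vectors::metadata(se)$dataset_id <- sprintf("DS%d", d)
      datasets[[d]] <- se
    }
    list(datasets = datasets,
         groundTruth = list(coexpressedModules = modules))
  })
}

#' Generate region-annotated brain expression data
#'
#' Emulates a whole-brain microarray data set in which every sample carries
#' a brain-region label (231 regions by default, seven of them the
#' disease-associated hippocampal-circuit regions). A chosen gene set is
#' upregulated by \code{effect} in the disease regions; optional planted
#' modules add correlated structure across samples for region co-expression
#' analysis.
#'
#' @param annotation output of \code{\link{genGeneAnnotation}}.
#' @param regions region identifiers (default \code{henaRegions(231)}).
#' @param diseaseRegions subset of \code{regions} flagged as
#'   disease-associated.
#' @param upregulatedGenes ensg ids upregulated in disease regions.
#' @param effect mean expression increase in disease regions.
#' @param samplesPerRegion samples generated per region.
#' @param modules planted co-expression modules as in
#'   \code{\link{genExpressionCohorts}} (latent factor drawn per sample
#'   across all regions).
#' @param seed RNG seed.
#' @return list with \code{dataset} (region-annotated
#'   \code{SummarizedExperiment}) and \code{groundTruth}.
#' @export
genRegionExpression <- function(annotation, regions = henaRegions(231),
                                diseaseRegions = henaDiseaseRegions(),
                                upregulatedGenes = character(), effect = 1,
                                samplesPerRegion = 3, modules = list(),
                                seed) {
  if (!all(diseaseRegions %in% regions))
    stop("disease region not in region list")
  ensgAll <- annotation$genes$ensg_id
  if (!all(upregulatedGenes %in% ensgAll))
    stop("upregulated gene not present in the annotation")
  probeMap <- annotation$probeMap
  withSeed(seed, {
    region <- rep(regions, each = samplesPerRegion)
    n <- length(region)
    probes <- probeMap$probe_id
    base <- runif(length(probes), 5, 9)
    mat <- matrix(rnorm(length(probes) * n), nrow = length(probes),
                  dimnames = list(probes, sprintf("ABA_S%04d", seq_len(n))))
    for (m in modules) {
      f <- rnorm(n)
      rp <- 2 * sin(pi * m$rho / 6)
      memberGenes <- unique(probeMap$ensg[probeMap$ensg %in% m$genes])
      for (gi in seq_along(memberGenes)) {
        sgn <- if (rp < 0 && gi %% 2 == 0) -1 else 1
        for (p in probeMap$probe_id[probeMap$ensg == memberGenes[gi]])
          mat[p, ] <- sgn * sqrt(abs(rp)) * f + sqrt(1 - abs(rp)) * rnorm(n)
      }
    }
    mat <- mat + base
    if (length(upregulatedGenes) && effect != 0) {
      upProbes <- probeMap$probe_id[probeMap$ensg %in% upregulatedGenes]
      disCols <- region %in% diseaseRegions
      mat[upProbes, disCols] <- mat[upProbes, disCols] + effect
    }
    se <- SummarizedExperiment::SummarizedExperiment(
      assays = list(exprs = mat),
      colData = S4Vectors::DataFrame(region = region,
                                     row.names = colnames(mat)))
    S4Vectors::metadata(se)$regions <- regions
    S4Vectors::metadata(se)$disease_regions <- diseaseRegions
    list(dataset = se,
         groundTruth = list(diseaseRegionGenes = upregulatedGenes))
  })
}

#' Generate genotypes, longitudinal traits and adjusted-phenotype inputs
#'
#' Produces a Hardy-Weinberg genotype matrix with per-SNP minor allele
#' frequencies, a quantitative phenotype carrying planted epistatic SNP
#' pairs (\eqn{y = \beta_0 + \beta_A g_A + \beta_B g_B +
#' \beta_{AB} g_A g_B + \epsilon}), longitudinal cognitive-trait series,
#' age-trending Braak-like ordinal scores, and ventricular-volume series
#' confounded by age, sex and baseline disease status. SNP positions are
#' placed both inside gene bodies and in intergenic space beyond the 5 kb
#' margins so that genic and intergenic bins are both exercised.
#'
#' @param annotation output of \code{\link{genGeneAnnotation}}.
#' @param nIndividuals cohort size (>= 10).
#' @param nSnps number of SNPs.
#' @param epistaticPairs list of planted pairs, each
#'   \code{list(a = <snp index>, b = <snp index>, beta = <interaction
#'   effect>, betaMain = <additive effect, default 0.25>)}.
#' @param traitRegistry trait names (default the packaged 23-trait
#'   registry).
#' @param missingRate fraction of dosage calls set missing uniformly at
#'   random.
#' @param phenotypeSd residual standard deviation of the planted
#'   quantitative phenotype.
#' @param seed RNG seed.
#' @return list with \code{genotypes} (\linkS4class{GenotypeMatrix}),
#'   \code{phenotype} (named numeric, the planted-scan phenotype),
#'   \code{traits} (long \code{data.frame}: individual, trait, time,
#'   value), \code{braak} (\code{data.frame}: individual, age, score),
#'   \code{ventricle} (list of \code{series} and \code{covariates}) and
#'   \code{groundTruth}.
#' @export
genGenotypesAndTraits <- function(annotation, nIndividuals = 500,
                                  nSnps = 100, epistaticPairs = list(),
                                  traitRegistry = henaTraits(),
                                  missingRate = 0, phenotypeSd = 0.5, seed) {
  if (nIndividuals < 10)
    stop("nIndividuals must be >= 10 (degenerate regression otherwise)")
  genes <- annotation$genes
  withSeed(seed, {
    nGenic <- ceiling(0.6 * nSnps)
    gi <- sample(length(genes), nGenic, replace = TRUE)
    posGenic <- round(runif(nGenic, GenomicRanges::start(genes)[gi],
                            GenomicRanges::end(genes)[gi]))
    ext <- GenomicRanges::resize(genes, GenomicRanges::width(genes) + 2 * 5000,
                                 fix = "center")
    gaps <- GenomicRanges::gaps(GenomicRanges::reduce(ext))
    gaps <- gaps[GenomicRanges::width(gaps) > 2000 &
                   as.character(GenomicRanges::strand(gaps)) == "*"]
    nIgr <- nSnps - nGenic
    gj <- sample(length(gaps), nIgr, replace = TRUE)
    posIgr <- round(runif(nIgr,
                          GenomicRanges::start(gaps)[gj] + 1000,
                          GenomicRanges::end(gaps)[gj] - 1000))
    pos <- c(posGenic, posIgr)
    ord <- order(pos)
    pos <- pos[ord]
    maf <- runif(nSnps, 0.05, 0.5)
    snps <- data.frame(snp_id = sprintf("rs%06d", seq_len(nSnps)),
                       chromosome = "1", position = pos, maf = maf)
    dos <- vapply(seq_len(nSnps),
                  function(j) rbinom(nIndividuals, 2, maf[j]),
                  numeric(nIndividuals))
    colnames(dos) <- snps$snp_id
    individuals <- sprintf("IND%04d", seq_len(nIndividuals))
    rownames(dos) <- individuals

    y <- rnorm(nIndividuals, sd = phenotypeSd)
    planted <- list()
    for (p in epistaticPairs) {
      a <- snps$snp_id[p$a]; b <- snps$snp_id[p$b]
      bm <- p$betaMain %||% 0.25
      y <- y + bm * dos[, a] + bm * dos[, b] + p$beta * dos[, a] * dos[, b]
      planted <- c(planted, list(list(snp_a = a, snp_b = b, beta = p$beta)))
    }
    names(y) <- individuals

    traits <- do.call(rbind, lapply(traitRegistry, function(tr) {
      nObs <- sample(2:4, nIndividuals, replace = TRUE)
      do.call(rbind, lapply(seq_len(nIndividuals), function(i) {
        t <- sort(runif(nObs[i], 0, 3))
        data.frame(individual = individuals[i], trait = tr, time = t,
                   value = rnorm(1, 20, 5) + rnorm(1, 0, 1) * t +
                     rnorm(nObs[i], 0, 0.5))
      }))
    }))

    age <- runif(nIndividuals, 60, 95)
    score <- round(pmin(6, pmax(1, 1 + 4 * (age - 60) / 35 +
                                  rnorm(nIndividuals, 0, 0.8))))
    braak <- data.frame(individual = individuals, age = age, score = score)

    sex <- rbinom(nIndividuals, 1, 0.5)
    status <- rbinom(nIndividuals, 1, 0.4)
    trueSlope <- 100 + 5 * (age - 75) + 200 * status + 50 * sex +
      rnorm(nIndividuals, 0, 30)
    ventSeries <- do.call(rbind, lapply(seq_len(nIndividuals), function(i) {
      k <- sample(2:5, 1)
      t <- seq(0, by = 0.5, length.out = k)
      data.frame(individual = individuals[i], time = t,
                 volume = rnorm(1, 30000, 3000) + trueSlope[i] * t +
                   rnorm(k, 0, 20))
    }))
    covariates <- data.frame(individual = individuals, age = age, sex = sex,
                             baseline_status = status)

    if (missingRate > 0) {
      nMiss <- rbinom(1, length(dos), missingRate)
      dos[sample(length(dos), nMiss)] <- NA
    }
    list(genotypes = GenotypeMatrix(dos, snps),
         phenotype = y,
         traits = traits,
         braak = braak,
         ventricle = list(series = ventSeries, covariates = covariates),
         groundTruth = list(epistaticPairs = planted))
  })
}

#' Generate PPI edge lists, a GWAS SNP table and a positive-selection table
#'
#' PPI edges are scored either with a yeast two-hybrid Predicted Biological
#' Score (PBS, 0-10, lower = more specific) or an IntAct-style molecular
#' interaction (MI) confidence score in [0, 1]. Some interaction partners
#' map to pseudogenes so that pseudogene filtering is exercised. The GWAS
#' table attaches p-values to SNP ids mapped to genes, with a configurable
#' enriched fraction below 0.05 whose ids are recorded in the ground truth.
#'
#' @param annotation output of \code{\link{genGeneAnnotation}}.
#' @param nPpi number of PPI edges.
#' @param pbsFraction fraction of edges carrying a PBS score (the rest are
#'   MI-scored).
#' @param gwasNSnps number of GWAS SNP rows.
#' @param psNGenes number of genes with a positive-selection p-value.
#' @param gwasEnrichedFraction fraction of GWAS SNPs planted below p = 0.05.
#' @param seed RNG seed.
#' @return list with \code{ppi} (\code{data.frame(ensg_a, ensg_b, score,
#'   score_type)}), \code{gwas} (\code{data.frame(snp_id, ensg, p)}),
#'   \code{ps} (\code{data.frame(ensg, p)}) and \code{groundTruth}.
#' @export
genPpiAndTables <- function(annotation, nPpi = 200, pbsFraction = 0.5,
                            gwasNSnps = 100, psNGenes = 23,
                            gwasEnrichedFraction = 0.3, seed) {
  if (pbsFraction < 0 || pbsFraction > 1)
    stop("pbsFraction must be in [0, 1]")
  if (gwasEnrichedFraction < 0 || gwasEnrichedFraction > 1)
    stop("gwasEnrichedFraction must be in [0, 1]")
  ensg <- annotation$genes$ensg_id
  withSeed(seed, {
    a <- sample(ensg, 3 * nPpi, replace = TRUE)
    b <- sample(ensg, 3 * nPpi, replace = TRUE)
    keep <- a != b
    key <- pairKey(a[keep], b[keep])
    idx <- which(keep)[!duplicated(key)]
    idx <- head(idx, nPpi)
    nPbs <- round(pbsFraction * length(idx))
    scoreType <- c(rep("PBS", nPbs), rep("MI", length(idx) - nPbs))
    score <- c(runif(nPbs, 0, 10), runif(length(idx) - nPbs, 0.2, 1))
    ppi <- canonicalizePairs(
      data.frame(ensg_a = a[idx], ensg_b = b[idx], score = score,
                 score_type = scoreType),
      a = "ensg_a", b = "ensg_b")

    nEnr <- round(gwasEnrichedFraction * gwasNSnps)
    gwas <- data.frame(
      snp_id = sprintf("gwrs%05d", seq_len(gwasNSnps)),
      ensg = sample(ensg, gwasNSnps, replace = TRUE),
      p = c(runif(nEnr, 1e-6, 0.04), runif(gwasNSnps - nEnr, 0.05, 1)))
    ps <- data.frame(ensg = sample(ensg, min(psNGenes, length(ensg))),
                     p = runif(min(psNGenes, length(ensg)), 1e-4, 0.1))
    list(ppi = ppi, gwas = gwas, ps = ps,
         groundTruth = list(gwasEnriched = gwas$snp_id[seq_len(nEnr)]))
  })
}

#' Generate a labelled graph with clustered disease genes
#'
#' Builds a synthetic PPI-type graph in which positively labelled
#' (disease-associated) nodes attach preferentially to each other, plus a
#' brain-region Z-score matrix in which positives carry a configurable
#' shift in the disease-associated regions. Used to study whether graph
#' neighborhood features discriminate disease genes beyond expression
#' features.
#'
#' @param nNodes total number of genes.
#' @param nPos,nNeg sizes of the positive and negative label classes.
#' @param pWithin edge probability between two positive nodes.
#' @param pBetween edge probability for all other pairs.
#' @param bioEffect Z-score shift of positives in the seven disease
#'   regions.
#' @param nRegions number of region columns in the Z-score matrix.
#' @param seed RNG seed.
#' @return list with \code{edges}, \code{labels} (list of positive /
#'   negative / unknown id vectors) and \code{zscores}.
#' @export
genLabeledGraphExample <- function(nNodes = 300, nPos = 60, nNeg = 60,
                                   pWithin = 0.08, pBetween = 0.01,
                                   bioEffect = 0.5, nRegions = 231, seed) {
  withSeed(seed, {
    ids <- sprintf("ENSG%011d", seq_len(nNodes))
    pos <- ids[seq_len(nPos)]
    neg <- ids[nPos + seq_len(nNeg)]
    unk <- setdiff(ids, c(pos, neg))
    comb <- t(utils::combn(nNodes, 2))
    bothPos <- comb[, 1] <= nPos & comb[, 2] <= nPos
    pEdge <- ifelse(bothPos, pWithin, pBetween)
    keep <- runif(nrow(comb)) < pEdge
    edges <- data.frame(ensg_a = ids[comb[keep, 1]],
                        ensg_b = ids[comb[keep, 2]],
                        score = runif(sum(keep), 0.45, 1),
                        interaction_type = "PPI",
                        data_source = "IAH")
    z <- matrix(rnorm(nNodes * nRegions), nrow = nNodes,
                dimnames = list(ids, henaRegions(nRegions)))
    z[pos, henaDiseaseRegions()] <- z[pos, henaDiseaseRegions()] + bioEffect
    list(edges = edges,
         labels = list(positive = pos, negative = neg, unknown = unk),
         zscores = z)
  })
}
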