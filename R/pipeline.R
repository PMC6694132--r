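#' Default pipeline configuration
#'
#' Returns the nested parameter blocks of the synthetic end-to-end run.
#' All thresholds default to the published analysis values: RRA score
#' cut 1e-5, region co-expression FDR 0.01, epistasis significance 1e-8
#' (volume / Braak family) and 1e-5 (cognitive traits), MI score 0.45,
#' GWAS p 0.05, 5000 bp bin margin, MAF product 0.01, reduced-version
#' co-expression cut 0.8, case-study co-expression cut 0.5. Problem sizes
#' are desk-scale so the full run completes in minutes.
#'
#' @param seed mandatory RNG seed for the whole run.
#' @return nested configuration list.
#' @export
henaDefaultConfig <- function(seed) {
  if (missing(seed)) stop("seed is mandatory")
  list(
    seed = as.integer(seed),
    synth = list(
      n_genes = 150, n_pseudogenes = 8, overlap_fraction = 0.1,
      n_datasets = 6, samples_per_dataset = 40,
      module_genes = 5, module_rho = 0.9,
      region_samples = 20,
      n_upregulated = 8, region_effect = 1.5,
      n_individuals = 400, n_snps = 40, planted_beta = 1,
      phenotype_sd = 0.5, missing_rate = 0.02,
      n_ppi = 200, pbs_fraction = 0.5, adia_fraction = 0.2,
      gwas_n_snps = 100, ps_n_genes = 15,
      n_negative = 40),
    coexpression = list(alpha = 1e-5, rank_by = "abs"),
    region = list(p_threshold = 0.01),
    epistasis = list(max_missing = 0.1, min_maf = 0.05, hwe_alpha = 1e-3,
                     maf_product_min = 0.01, margin = 5000,
                     p_threshold_volume = 1e-8, p_threshold_ct = 1e-5,
                     bin_alpha = 0.05),
    ppi = list(min_mi = 0.45),
    gwas = list(alpha = 0.05),
    features = list(coexpr_min = 0.5, ntree = 200, train_fraction = 0.7),
    reduced = list(threshold = 0.8))
}

#' Read a pipeline configuration file
#'
#' YAML with nested sections mirroring \code{\link{henaDefaultConfig}};
#' unspecified values fall back to the defaults. The seed is mandatory.
#'
#' @param path YAML file path.
#' @return configuration list.
#' @export
readPipelineConfig <- function(path) {
  user <- yaml::read_yaml(path)
  if (is.null(user$seed)) stop("config must specify a seed")
  cfg <- henaDefaultConfig(user$seed)
  for (section in names(user)) {
    if (section == "seed") next
    for (key in names(user[[section]]))
      cfg[[section]][[key]] <- user[[section]][[key]]
  }
  cfg
}

configHash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(config), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the synthetic end-to-end pipeline
#'
#' Executes the stages in dependency order: synthetic-data generation, then
#' cross-study and region co-expression, the epistasis scan with bin
#' mapping, brain-region Z-score aggregation, integration into the edge
#' list and node attribute table with pseudogene filtering, and the
#' disease-gene prioritization use case (feature table, random-forest
#' scoring, metrics, candidate ranking). When \code{outDir} is given, the
#' artifact bundle (edge list, node table, feature table, metrics, summary,
#' provenance manifest) is written as tab-separated files.
#'
#' @param config configuration from \code{\link{henaDefaultConfig}} or
#'   \code{\link{readPipelineConfig}}.
#' @param outDir optional output directory.
#' @return list with the assembled objects: \code{edges}, \code{nodes},
#'   \code{summary}, \code{features}, \code{metrics}, \code{ranking},
#'   \code{manifest} plus the intermediate stage outputs.
#' @export
runPipeline <- function(config, outDir = NULL) {
  if (is.null(config$seed)) stop("config must specify a seed")
  seed <- config$seed
  sy <- config$synth

  ann <- genGeneAnnotation(sy$n_genes, sy$n_pseudogenes,
                           sy$overlap_fraction, seed = seed)
  coding <- ann$genes$ensg_id[ann$genes$biotype == "protein_coding"]
  moduleGenes <- coding[seq_len(sy$module_genes)]
  modules <- list(list(genes = moduleGenes, rho = sy$module_rho))

  cohorts <- genExpressionCohorts(ann, nDatasets = sy$n_datasets,
                                  samplesPerDataset = sy$samples_per_dataset,
                                  modules = modules, seed = seed + 1)
  adn <- aggregateGlobalCoexpression(cohorts$datasets, ann$probeMap,
                                     alpha = config$coexpression$alpha,
                                     rankBy = config$coexpression$rank_by)

  disRegions <- henaDiseaseRegions()
  regionData <- genRegionExpression(
    ann, regions = disRegions, diseaseRegions = disRegions,
    samplesPerRegion = sy$region_samples, modules = modules,
    seed = seed + 2)
  regionTables <- lapply(disRegions, function(r)
    regionCoexpression(regionData$dataset, r,
                       pThreshold = config$region$p_threshold,
                       probeMap = ann$probeMap))
  names(regionTables) <- disRegions

  upGenes <- coding[seq(sy$module_genes + 1,
                        length.out = sy$n_upregulated)]
  brainSets <- lapply(seq_len(6), function(i)
    genRegionExpression(ann, regions = henaRegions(231),
                        diseaseRegions = disRegions,
                        upregulatedGenes = upGenes,
                        effect = sy$region_effect, samplesPerRegion = 1,
                        seed = seed + 10 + i)$dataset)
  zscores <- zscoreAndCollapse(lapply(brainSets, regionMeans), ann$probeMap)

  geno <- genGenotypesAndTraits(
    ann, nIndividuals = sy$n_individuals, nSnps = sy$n_snps,
    epistaticPairs = list(list(a = 1, b = 2, beta = sy$planted_beta)),
    missingRate = sy$missing_rate, phenotypeSd = sy$phenotype_sd,
    seed = seed + 3)
  ep <- config$epistasis
  qc <- qcFilter(geno$genotypes, maxMissing = ep$max_missing,
                 minMaf = ep$min_maf, hweAlpha = ep$hwe_alpha)
  bins <- mapSnpsToBins(qc$genotypes, ann, margin = ep$margin)
  scan <- scanPairs(qc$genotypes, geno$phenotype,
                    mafProductMin = ep$maf_product_min,
                    pThreshold = ep$p_threshold_volume)
  scan <- scan[scan$snp_a %in% bins$snp_id & scan$snp_b %in% bins$snp_id, ,
               drop = FALSE]
  epiBinPairs <- binwiseBonferroni(scan, bins, alpha = ep$bin_alpha)
  braakAdj <- adjustBraak(geno$braak$score, geno$braak$age)
  ventAdj <- adjustVentricle(geno$ventricle$series,
                             geno$ventricle$covariates)
  ctPhenotypes <- deriveTraitValues(geno$traits)

  tables <- genPpiAndTables(ann, nPpi = sy$n_ppi,
                            pbsFraction = sy$pbs_fraction,
                            gwasNSnps = sy$gwas_n_snps,
                            psNGenes = sy$ps_n_genes, seed = seed + 4)
  pba <- tables$ppi[tables$ppi$score_type == "PBS", , drop = FALSE]
  mi <- filterPpiByScore(tables$ppi[tables$ppi$score_type == "MI", ,
                                    drop = FALSE],
                         minMi = config$ppi$min_mi)
  nAdia <- round((sy$adia_fraction %||% 0.2) * nrow(mi))
  adia <- mi[seq_len(nAdia), , drop = FALSE]
  iah <- mi[-seq_len(nAdia), , drop = FALSE]

  stageOutputs <- c(
    list(list(table = adn, type = "co-expression", source = "ADN")),
    lapply(disRegions, function(r)
      list(table = regionTables[[r]], type = "co-expression",
           source = paste0("ABA_", r))),
    list(list(table = data.frame(ensg_a = epiBinPairs$bin_a,
                                 ensg_b = epiBinPairs$bin_b,
                                 score = epiBinPairs$score,
                                 interaction_type =
                                   epiBinPairs$interaction_type),
              type = "epistasis", source = "ADNI_VER"),
         list(table = pba[, c("ensg_a", "ensg_b", "score")],
              type = "PPI", source = "PBA"),
         list(table = iah[, c("ensg_a", "ensg_b", "score")],
              type = "PPI", source = "IAH"),
         list(table = adia[, c("ensg_a", "ensg_b", "score")],
              type = "PPI", source = "ADIA")))
  edges <- assembleEdges(stageOutputs)

  nodeAttrs <- assembleNodeAttributes(tables$gwas, tables$ps, zscores, ann,
                                      gwasAlpha = config$gwas$alpha)
  filtered <- filterPseudogenes(edges, nodeAttrs$nodes)
  edges <- filtered$edges
  nodes <- filtered$nodes
  summary <- summarizeHena(edges, nodes)

  graph <- prepareCaseStudyGraph(edges,
                                 coexprMin = config$features$coexpr_min)
  gwasGenes <- unique(tables$gwas$ensg[tables$gwas$p <= config$gwas$alpha])
  ppiGenes <- unique(c(adia$ensg_a, adia$ensg_b))
  candidateNeg <- setdiff(graphNodes(graph), c(gwasGenes, ppiGenes))
  negativeList <- withSeed(seed + 5,
    sample(candidateNeg, min(sy$n_negative, length(candidateNeg))))
  labels <- assembleLabels(gwasGenes, ppiGenes, negativeList,
                           graphNodes(graph))
  features <- buildFeatureTable(graph, zscores, labels)
  labelled <- c(labels$positive, labels$negative)
  trainIds <- withSeed(seed + 6,
    sample(labelled, round(config$features$train_fraction *
                             length(labelled))))
  scores <- scoreGenesRF(features, labels, trainIds = trainIds,
                         ntree = config$features$ntree, seed = seed + 7)
  holdout <- list(positive = setdiff(labels$positive, trainIds),
                  negative = setdiff(labels$negative, trainIds),
                  unknown = labels$unknown)
  metrics <- tryCatch(evaluateClassifier(scores, holdout),
                      error = function(e) NULL)
  ranking <- rankUnknowns(scores, labels)

  manifest <- list(
    config_hash = configHash(config), seed = seed,
    n_genes = length(ann$genes), n_edges = nrow(edges),
    n_nodes = nrow(nodes),
    edges_adn = sum(edges$data_source == "ADN"),
    edges_region_coexpr = sum(startsWith(edges$data_source, "ABA_")),
    edges_epistasis = sum(edges$data_source == "ADNI_VER"),
    edges_ppi = sum(edges$data_source %in% c("PBA", "IAH", "ADIA")),
    n_unknown_ranked = nrow(ranking))

  result <- list(annotation = ann, edges = edges, nodes = nodes,
                 regionTables = regionTables,
                 nodeAttributesLong = nodeAttrs$long, summary = summary,
                 zscores = zscores, bins = bins, scan = scan,
                 epiBinPairs = epiBinPairs, braakAdjusted = braakAdj,
                 ventricleAdjusted = ventAdj, ctPhenotypes = ctPhenotypes,
                 qcReport = qc$report, graph = graph, labels = labels,
                 features = features, scores = scores, metrics = metrics,
                 ranking = ranking, manifest = manifest,
                 groundTruth = list(coexpression =
                                      cohorts$groundTruth,
                                    epistasis = geno$groundTruth,
                                    gwas = tables$groundTruth))
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    writeHenaEdges(edges, file.path(outDir, "hena_edges.tsv"))
    writeNodeAttributes(nodes, file.path(outDir, "hena_nodes.tsv"))
    write.table(features, file.path(outDir, "features.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(ranking, file.path(outDir, "candidate_ranking.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(metrics))
      write.table(data.frame(Precision = metrics$precision,
                             Recall = metrics$recall,
                             `F1 score` = metrics$f1,
                             `ROC AUC` = metrics$auc,
                             check.names = FALSE),
                  file.path(outDir, "metrics.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    manifestDf <- data.frame(key = names(manifest),
                             value = vapply(manifest, as.character, ""))
    write.table(manifestDf, file.path(outDir, "manifest.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  result
}

#' Validate assembled network files
#'
#' Checks the edge-list and node-table files against the schema: column
#' names, interaction types, per-data-source score domains (RRA and
#' epistasis p-values in (0, 1]; region co-expression in [-1, 1]; PBS in
#' [0, 10]; post-filter MI in [0.45, 1]), 237-field node width, absence of
#' pseudogene biotypes, and intergenic-region composite id syntax.
#'
#' @param edgesPath path to the edge-list TSV.
#' @param nodesPath path to the node-attribute TSV.
#' @param nRegions expected region-column count (default 231).
#' @return \code{data.frame(file, line, rule, detail)} of violations
#'   (zero rows when the files conform).
#' @export
validateHenaFiles <- function(edgesPath, nodesPath, nRegions = 231) {
  if (!file.exists(edgesPath)) stop("cannot read ", edgesPath)
  if (!file.exists(nodesPath)) stop("cannot read ", nodesPath)
  v <- list()
  note <- function(file, line, rule, detail)
    v[[length(v) + 1]] <<- data.frame(file = file, line = line,
                                      rule = rule, detail = detail)
  edges <- read.delim(edgesPath, check.names = FALSE)
  needE <- c("ENSG.A", "ENSG.B", "score", "interaction_type", "data_source")
  if (!identical(colnames(edges)[seq_along(needE)], needE)) {
    note(edgesPath, 1, "edge_columns",
         paste("expected header:", paste(needE, collapse = ", ")))
  } else {
    reg <- henaDatasetRegistry()
    igrPat <- "^(ENSG[0-9]+|\\*)-(ENSG[0-9]+|\\*)$"
    for (i in seq_len(nrow(edges))) {
      ln <- i + 1
      src <- edges$data_source[i]
      sc <- edges$score[i]
      tp <- edges$interaction_type[i]
      if (!src %in% reg$data_source_id)
        note(edgesPath, ln, "registry", paste("unknown data source", src))
      if (!tp %in% c("PPI", "co-expression", "epistasis", "IGRI"))
        note(edgesPath, ln, "interaction_type", tp)
      bad <- if (src == "ADN" || grepl("^(ADNI|TGEN|HBTRC)", src))
        sc <= 0 || sc > 1
      else if (startsWith(src, "ABA_")) sc < -1 || sc > 1
      else if (src == "PBA") sc < 0 || sc > 10
      else if (src %in% c("IAH", "ADIA", "SIA")) sc < 0.45 || sc > 1
      else FALSE
      if (isTRUE(bad))
        note(edgesPath, ln, "score_domain",
             paste0(src, " score ", sc, " out of range"))
      for (id in c(edges$ENSG.A[i], edges$ENSG.B[i])) {
        if (grepl("-", id, fixed = TRUE)) {
          if (!grepl(igrPat, id))
            note(edgesPath, ln, "igr_syntax", id)
          else if (!tp %in% c("IGRI", "epistasis"))
            note(edgesPath, ln, "igr_type",
                 paste("IGR id in", tp, "row"))
        }
      }
    }
  }
  nodeLines <- readLines(nodesPath)
  widths <- lengths(strsplit(nodeLines, "\t", fixed = TRUE))
  expectWidth <- 6 + nRegions
  for (i in which(widths != expectWidth))
    note(nodesPath, i, "node_width",
         paste0(widths[i], " fields, expected ", expectWidth))
  nodes <- read.delim(nodesPath, check.names = FALSE)
  if ("biotype" %in% colnames(nodes)) {
    for (i in which(grepl("pseudogene", nodes$biotype)))
      note(nodesPath, i + 1, "pseudogene", nodes$ensg[i])
  }
  if (length(v) == 0)
    return(data.frame(file = character(), line = integer(),
                      rule = character(), detail = character()))
  out <- do.call(rbind, v)
  rownames(out) <- NULL
  out
}
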