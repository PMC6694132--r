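test_that("latest and slope phenotypes are derived exactly", {
  series <- data.frame(
    individual = c("i1", "i1", "i1", "i2"),
    trait = "ADAS11",
    time = c(0, 1, 2, 4),
    value = c(1, 3, 5, 7.5))
  out <- deriveTraitValues(series)
  expect_equal(out$ADAS11_latest, c(5, 7.5))
  expect_equal(out$ADAS11_slope, c(2, NA))
})

test_that("the 23-trait registry yields 46 derived phenotype columns", {
  ann <- smallAnnotation()
  g <- genGenotypesAndTraits(ann, nIndividuals = 12, nSnps = 5, seed = 2)
  wide <- deriveTraitValues(g$traits)
  expect_length(henaTraits(), 23)
  expect_equal(ncol(wide) - 1, 46)
})

test_that("Braak age adjustment removes the age trend", {
  set.seed(5)
  age <- runif(200, 60, 95)
  # exactly linear scores: residuals essentially zero
  linear <- 1 + 5 * (age - 60) / 35
  resLin <- adjustBraak(linear, age)
  expect_lt(max(abs(resLin)), 0.05)
  # age-independent scores: residuals essentially the centered scores
  # (loess edge wiggle bounds the residual-vs-centered RMS difference)
  indep <- sample(1:6, 200, replace = TRUE)
  resInd <- adjustBraak(indep, age)
  centered <- indep - mean(indep)
  expect_gt(cor(resInd, centered), 0.95)
  expect_lt(sqrt(mean((resInd - centered)^2)), 0.3)
  expect_lt(abs(mean(resInd)), 0.05)
  # constant scores
  expect_equal(unname(adjustBraak(rep(3, 50), runif(50, 60, 90))),
               rep(0, 50), tolerance = 1e-8)
  # degenerate ages fall back to centering
  expect_warning(resDeg <- adjustBraak(indep[1:20], rep(70, 20)),
                 "mean-centering")
  expect_equal(unname(resDeg), indep[1:20] - mean(indep[1:20]))
  expect_error(adjustBraak(c(0, 3), c(60, 70)), "n >= 10|\\[1, 6\\]")
})

test_that("ventricle adjustment fits slopes then removes covariate effects", {
  # stage-1 slope agrees with the lm oracle; short series are excluded
  series <- do.call(rbind, lapply(1:12, function(i)
    data.frame(individual = sprintf("i%02d", i), time = c(0, 1, 2),
               volume = 10 + i * c(0, 1, 2) + c(0, 0.5, -0.5))))
  series <- rbind(series,
                  data.frame(individual = "short", time = 0, volume = 5))
  cov <- data.frame(individual = c(sprintf("i%02d", 1:12), "short"),
                    age = rnorm(13, 75, 5), sex = rep(0:1, length.out = 13),
                    baseline_status = rep(c(0, 1), length.out = 13))
  expect_message(res <- adjustVentricle(series, cov), "excluding 1")
  expect_false("short" %in% names(res))
  slopes <- vapply(1:12, function(i) {
    grp <- series[series$individual == sprintf("i%02d", i), ]
    coef(lm(volume ~ time, grp))[["time"]]
  }, numeric(1))
  oracle <- residuals(lm(slopes ~ cov$age[1:12] + cov$sex[1:12] +
                           cov$baseline_status[1:12]))
  expect_equal(unname(res[sprintf("i%02d", 1:12)]), unname(oracle),
               tolerance = 1e-10)
})

test_that("planted covariate effects are removed from ventricle slopes", {
  set.seed(8)
  n <- 300
  ids <- sprintf("i%03d", 1:n)
  age <- runif(n, 60, 90)
  slope <- 3 * age + rnorm(n)
  series <- data.frame(individual = rep(ids, each = 2),
                       time = rep(c(0, 1), n),
                       volume = as.vector(rbind(0, slope)))
  cov <- data.frame(individual = ids, age = age,
                    sex = rbinom(n, 1, 0.5),
                    baseline_status = rbinom(n, 1, 0.5))
  res <- adjustVentricle(series, cov)
  expect_lt(abs(cor(res[ids], age)), 0.1)
  expect_lt(abs(mean(res)), 1e-8)
})

test_that("marker QC excludes SNPs for the stated reasons", {
  n <- 100
  hwe <- c(rep(0, 25), rep(1, 50), rep(2, 25))        # exact HWE
  lowMaf <- c(rep(1, 4), rep(0, 96))                  # MAF 0.02
  missing <- c(rep(NA, 20), rep(1, 40), rep(0, 30), rep(2, 10))
  d <- cbind(s_hwe = hwe, s_maf = lowMaf, s_mis = missing)
  snps <- data.frame(snp_id = colnames(d), chromosome = "1",
                     position = c(100, 200, 300))
  qc <- qcFilter(GenotypeMatrix(d, snps))
  expect_equal(snpInfo(qc$genotypes)$snp_id, "s_hwe")
  expect_equal(qc$report$reason[qc$report$snp_id == "s_maf"], "maf")
  expect_equal(qc$report$reason[qc$report$snp_id == "s_mis"], "missing")
  expect_equal(hena:::hweChisqP(hwe), 1)
  # everything removed is an explicit error
  expect_error(qcFilter(GenotypeMatrix(cbind(s1 = lowMaf),
                                       snps[2, , drop = FALSE])),
               "all SNPs removed")
})

test_that("the epistasis F test matches the full-vs-reduced ANOVA oracle", {
  set.seed(3)
  for (rep in 1:10) {
    n <- 80
    gA <- rbinom(n, 2, 0.3)
    gB <- rbinom(n, 2, 0.4)
    y <- 0.5 * gA - 0.2 * gB + 0.3 * gA * gB + rnorm(n)
    fit <- epistasisTest(gA, gB, y)
    oracle <- anovaInteractionOracle(gA, gB, y)
    expect_lt(abs(fit$f - oracle$f) / oracle$f, 1e-10)
    expect_lt(abs(fit$p - oracle$p) / max(oracle$p, 1e-300), 1e-10)
  }
})

test_that("the epistasis test is symmetric and affine-invariant", {
  set.seed(4)
  gA <- rbinom(60, 2, 0.3); gB <- rbinom(60, 2, 0.4)
  y <- gA * gB + rnorm(60)
  f1 <- epistasisTest(gA, gB, y)
  f2 <- epistasisTest(gB, gA, y)
  expect_equal(f1$f, f2$f)
  expect_equal(f1$p, f2$p)
  f3 <- epistasisTest(gA, gB, 10 + 3 * y)
  expect_equal(f3$f, f1$f, tolerance = 1e-10)
  expect_equal(f3$p, f1$p, tolerance = 1e-10)
  expect_equal(f3$beta, 3 * f1$beta, tolerance = 1e-10)
})

test_that("a strong planted interaction is recovered", {
  set.seed(6)
  gA <- rbinom(200, 2, 0.4); gB <- rbinom(200, 2, 0.4)
  y <- gA * gB + rnorm(200, sd = 0.1)
  fit <- epistasisTest(gA, gB, y)
  expect_lt(abs(fit$beta - 1), 0.1)
  expect_lt(fit$p, 1e-8)
})

test_that("degenerate designs are flagged instead of tested", {
  gA <- rbinom(50, 2, 0.4)
  y <- rnorm(50)
  expect_false(epistasisTest(gA, gA * 0 + 1, y)$ok)   # constant SNP
  expect_false(epistasisTest(gA, gA, y)$ok)           # collinear
  expect_false(epistasisTest(gA[1:4], gA[1:4], y[1:4])$ok)  # too few
})

test_that("the scan honours the MAF-product prefilter and threshold", {
  set.seed(7)
  n <- 60
  # MAFs 0.05 and 0.1: product 0.005 <= 0.01, pair must be skipped
  d <- cbind(s1 = rbinom(n, 2, 0.05), s2 = rbinom(n, 2, 0.1),
             s3 = rbinom(n, 2, 0.4), s4 = rbinom(n, 2, 0.45))
  # force empirical MAFs
  gm <- GenotypeMatrix(d, data.frame(snp_id = colnames(d),
                                     chromosome = "1",
                                     position = 1:4 * 100))
  y <- setNames(rnorm(n), rownames(dosages(gm)))
  names(y) <- NULL
  res <- scanPairs(gm, y, pThreshold = 1)
  pairs <- paste(res$snp_a, res$snp_b)
  maf <- apply(d, 2, function(g) min(mean(g) / 2, 1 - mean(g) / 2))
  expect_false(any(pairs == "s1 s2") && maf["s1"] * maf["s2"] <= 0.01)
  # with pThreshold = 1 every tested pair is returned, sorted by p
  expect_true(all(diff(res$p) >= 0))
  expect_true(all(res$p <= 1))
})

test_that("SNPs map to genic bins, IGRs and terminal IGRs correctly", {
  genes <- GenomicRanges::GRanges(
    "1", IRanges::IRanges(start = c(10000, 50000), end = c(20000, 60000)),
    ensg_id = c("ENSG01", "ENSG02"),
    gene_name = c("A", "B"), biotype = "protein_coding")
  snps <- data.frame(
    snp_id = c("inMargin", "beforeMargin", "between", "after", "noGenes"),
    chromosome = c("1", "1", "1", "1", "2"),
    position = c(5000, 4999, 30000, 70000, 100))
  expect_message(bins <- mapSnpsToBins(snps, genes), "unassigned")
  get <- function(id) bins[bins$snp_id == id, ]
  expect_equal(get("inMargin")$bin_id, "ENSG01")   # boundary inclusive
  expect_equal(get("inMargin")$kind, "genic")
  expect_equal(get("beforeMargin")$bin_id, "*-ENSG01")
  expect_equal(get("between")$bin_id, "ENSG01-ENSG02")
  expect_equal(get("between")$kind, "igr")
  expect_equal(get("after")$bin_id, "ENSG02-*")
  expect_false("noGenes" %in% bins$snp_id)
})

test_that("overlapping genes give multiple genic assignments", {
  genes <- GenomicRanges::GRanges(
    "1", IRanges::IRanges(start = c(1000, 1500), end = c(3000, 4000)),
    ensg_id = c("ENSG01", "ENSG02"),
    gene_name = c("A", "B"), biotype = "protein_coding")
  bins <- mapSnpsToBins(data.frame(snp_id = "s", chromosome = "1",
                                   position = 2000), genes)
  expect_equal(nrow(bins), 2)
  expect_setequal(bins$bin_id, c("ENSG01", "ENSG02"))
})

test_that("bin mapping partitions SNPs with unique IGR assignment", {
  ann <- genGeneAnnotation(30, 2, overlapFraction = 0.2, seed = 13)
  g <- genGenotypesAndTraits(ann, nIndividuals = 20, nSnps = 60, seed = 13)
  bins <- mapSnpsToBins(g$genotypes, ann)
  byKind <- split(bins, bins$snp_id)
  for (grp in byKind) {
    if (any(grp$kind == "igr")) {
      expect_equal(nrow(grp), 1)  # IGR assignment is unique
    } else {
      expect_gte(nrow(grp), 1)
    }
  }
  expect_setequal(bins$snp_id, snpInfo(g$genotypes)$snp_id)
})

test_that("region-wise Bonferroni applies the m-by-n correction", {
  # bins with 10 and 20 members: threshold 0.05 / 200 = 2.5e-4
  bins <- rbind(
    data.frame(snp_id = sprintf("a%02d", 1:10), bin_id = "ENSGA",
               kind = "genic"),
    data.frame(snp_id = sprintf("b%02d", 1:20), bin_id = "ENSGB",
               kind = "genic"),
    data.frame(snp_id = "c1", bin_id = "ENSGC", kind = "genic"),
    data.frame(snp_id = "d1", bin_id = "ENSGC-ENSGD", kind = "igr"))
  results <- data.frame(snp_a = c("a01", "a02", "c1", "c1"),
                        snp_b = c("b01", "b02", "a01", "d1"),
                        beta = 1, f = 1,
                        p = c(2e-4, 3e-4, 0.004, 0.01), n = 100)
  out <- binwiseBonferroni(results, bins, alpha = 0.05)
  ab <- out[out$bin_a == "ENSGA" & out$bin_b == "ENSGB", ]
  expect_equal(ab$threshold, 0.05 / 200)
  expect_equal(ab$score, 2e-4)            # min member p-value
  expect_equal(ab$n_tests, 200L)
  # single-member bins: threshold = alpha / (1 * m)
  ca <- out[out$bin_a == "ENSGA" & out$bin_b == "ENSGC", ]
  expect_equal(ca$threshold, 0.05 / 10)
  expect_equal(ca$interaction_type, "epistasis")
  igr <- out[out$bin_b == "ENSGC-ENSGD", ]
  expect_equal(igr$interaction_type, "IGRI")
  expect_equal(igr$threshold, 0.05)       # 1x1 bins: no correction
  # never reports a bin pair whose best p misses its threshold
  expect_true(all(out$score < out$threshold))
  # missing assignment is a consistency error
  expect_error(binwiseBonferroni(data.frame(snp_a = "zz", snp_b = "a01",
                                            p = 0.001),
                                 bins), "bin assignment")
})
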