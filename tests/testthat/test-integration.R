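test_that("identifier mapping expands one-to-many and reports drops", {
  mapping <- data.frame(from = c("P1", "PR2", "PR2"),
                        to = c("ENSG1", "ENSG2", "ENSG3"))
  records <- data.frame(id = c("P1", "PR2", "UNKNOWN"), score = 1:3)
  out <- mapIdentifiers(records, mapping, "id")
  expect_equal(nrow(out$mapped), 3)          # 1 + 2 expanded rows
  expect_setequal(out$mapped$id[out$mapped$score == 2],
                  c("ENSG2", "ENSG3"))
  expect_equal(out$report$dropped, 1)
  expect_equal(out$report$input, 3)
  expect_warning(mapIdentifiers(records, mapping[0, ], "id"), "empty")
})

test_that("PPI confidence filtering is boundary-inclusive", {
  edges <- data.frame(ensg_a = "A", ensg_b = "B",
                      score = c(0.44, 0.45, 0.9))
  expect_equal(nrow(filterPpiByScore(edges)), 2)
  expect_equal(nrow(filterPpiByScore(edges, minMi = 0)), 3)
  expect_equal(nrow(filterPpiByScore(edges, minMi = 1.01)), 0)
})

test_that("the packaged registry enumerates 64 data sets of six types", {
  reg <- henaDatasetRegistry()
  expect_equal(nrow(reg), 64)
  expect_equal(length(unique(reg$data_type)), 6)
  expect_false(anyDuplicated(reg$data_source_id) > 0)
  expect_equal(sum(reg$data_type == "epistasis"), 49)
  expect_equal(sum(reg$data_type == "co-expression"), 8)
  expect_equal(sum(reg$data_type == "PPI"), 4)
})

test_that("edge assembly preserves multi-edges and validates sources", {
  ppi <- data.frame(ensg_a = "ENSG00000129484",
                    ensg_b = "ENSG00000167972", score = 0.0001)
  coexpr <- data.frame(ensg_a = "ENSG00000129484",
                       ensg_b = "ENSG00000167972", score = 0.9)
  edges <- assembleEdges(list(
    list(table = ppi, type = "PPI", source = "PBA"),
    list(table = coexpr, type = "co-expression", source = "ABA_CA1"),
    list(table = ppi[0, ], type = "PPI", source = "IAH")))
  expect_equal(nrow(edges), 2)   # same pair, two sources, both retained
  expect_error(assembleEdges(list(list(table = ppi, type = "PPI",
                                       source = "NOPE"))),
               "unknown data_source_id")
})

test_that("an edge row survives the writer/reader round trip field-for-field", {
  edges <- data.frame(ensg_a = "ENSG00000129484",
                      ensg_b = "ENSG00000167972",
                      score = 0.0001, interaction_type = "PPI",
                      data_source = "PBA")
  path <- tempfile(fileext = ".tsv")
  writeHenaEdges(edges, path)
  back <- readHenaEdges(path)
  expect_equal(back$ensg_a, "ENSG00000129484")
  expect_equal(back$ensg_b, "ENSG00000167972")
  expect_equal(back$score, 0.0001)
  expect_equal(back$interaction_type, "PPI")
  expect_equal(back$data_source, "PBA")
  header <- readLines(path, n = 1)
  expect_equal(header,
               "ENSG.A\tENSG.B\tscore\tinteraction_type\tdata_source")
})

test_that("node attributes form 237-field vectors with the stated rules", {
  ann <- smallAnnotation()
  regions <- henaRegions(231)
  z <- matrix(rnorm(3 * 231), nrow = 3,
              dimnames = list(ann$genes$ensg_id[1:3], regions))
  gwas <- data.frame(snp_id = c("rs1", "rs2", "rs3"),
                     ensg = c(ann$genes$ensg_id[1], ann$genes$ensg_id[1],
                              ann$genes$ensg_id[2]),
                     p = c(0.04, 0.001, 0.06))
  ps <- data.frame(ensg = ann$genes$ensg_id[2], p = 0.01)
  out <- assembleNodeAttributes(gwas, ps, z, ann)
  expect_equal(ncol(out$nodes), 237)
  # p = 0.06 SNP excluded by the 0.05 rule
  expect_false("rs3" %in% out$nodes$snp_id)
  expect_false("rs3" %in% out$long$snp_id)
  # flattened view keeps the minimum p and its SNP
  g1 <- out$nodes[out$nodes$ensg == ann$genes$ensg_id[1], ]
  expect_equal(g1$snp_id, "rs2")
  expect_equal(g1$gwas_p, 0.001)
  # the long view keeps both qualifying records
  expect_equal(sum(out$long$ensg == ann$genes$ensg_id[1], na.rm = TRUE), 2)
  # a gene with no attributes still has the full slot width
  bare <- out$nodes[out$nodes$ensg == ann$genes$ensg_id[5], ]
  expect_equal(ncol(bare), 237)
  expect_true(is.na(bare$gwas_p) && is.na(bare$ps_p))
})

test_that("pseudogene filtering removes nodes with their edges, idempotently", {
  nodes <- data.frame(ensg = c("G1", "G2", "G3", "G4"),
                      gene_name = paste0("N", 1:4),
                      biotype = c("protein_coding", "processed_pseudogene",
                                  "unprocessed_pseudogene", "lincRNA"))
  edges <- data.frame(ensg_a = c("G1", "G2", "G2", "G2", "G2"),
                      ensg_b = c("G4", "G1", "G4", "G4", "G3"),
                      score = 1, interaction_type = "PPI",
                      data_source = "IAH")
  out <- filterPseudogenes(edges, nodes)
  expect_equal(out$report$nodes_removed, 2)
  expect_equal(out$report$edges_removed, 4)  # pseudo-pseudo edge counted once
  expect_equal(nrow(out$edges), 1)
  expect_false(any(grepl("pseudogene", out$nodes$biotype)))
  again <- filterPseudogenes(out$edges, out$nodes)
  expect_equal(again$report$nodes_removed, 0)
  expect_identical(again$edges, out$edges)
})

test_that("network summaries count per type and apply the reduced filter", {
  edges <- data.frame(
    ensg_a = c("A", "A", "B", "C", "D", "D", "D"),
    ensg_b = c("B", "C", "C", "D", "E", "F", "G"),
    score = c(0.7, 0.9, 1e-9, 0.9, 0.9, 0.5, -0.85),
    interaction_type = c("PPI", "PPI", "epistasis", "co-expression",
                         "co-expression", "co-expression", "co-expression"),
    data_source = c("IAH", "PBA", "TGEN", "ADN",
                    "ABA_CA1", "ABA_CA1", "ABA_DG"))
  s <- summarizeHena(edges, data.frame(ensg = LETTERS[1:7]))
  perType <- setNames(s$per_type$n_edges, s$per_type$interaction_type)
  expect_equal(perType[["PPI"]], 2)
  expect_equal(perType[["epistasis"]], 1)
  expect_equal(perType[["co-expression"]], 4)
  ppiNodes <- s$per_type$n_nodes[s$per_type$interaction_type == "PPI"]
  expect_equal(ppiNodes, 3)  # distinct endpoints A, B, C
  # reduced rule hits region co-expression only: 0.9 and -0.85 stay, 0.5 drops
  red <- reducedEdges(edges)
  aba <- red[startsWith(red$data_source, "ABA_"), ]
  expect_setequal(aba$score, c(0.9, -0.85))
  # non-region edges untouched even with small scores
  expect_true(any(red$data_source == "TGEN"))
  expect_equal(s$reduced$n_edges, nrow(red))
})

test_that("edge-set comparison is orientation-insensitive and exhaustive", {
  a <- data.frame(x = c("A", "B"), y = c("B", "C"))
  b <- data.frame(x = c("B", "C"), y = c("A", "D"))
  out <- compareEdgeSets(hena = a, string = b)
  sizes <- setNames(out$size, out$combination)
  expect_equal(sizes[["hena&string"]], 1)   # A-B vs B-A shared
  expect_equal(sizes[["hena"]], 1)
  expect_equal(sizes[["string"]], 1)
  same <- compareEdgeSets(s1 = a, s2 = a)
  expect_equal(same$combination, "s1&s2")
  expect_equal(same$size, 2)
  # inclusion-exclusion: exclusive regions partition the union
  set.seed(12)
  rnd <- lapply(1:3, function(i) {
    p <- t(combn(LETTERS[1:8], 2))
    idx <- sample(nrow(p), 12)
    data.frame(x = p[idx, 1], y = p[idx, 2])
  })
  out3 <- do.call(compareEdgeSets, setNames(rnd, c("u", "v", "w")))
  unionSize <- length(unique(unlist(lapply(rnd, function(s)
    paste(pmin(s$x, s$y), pmax(s$x, s$y))))))
  expect_equal(sum(out3$size), unionSize)
})

test_that("node attribute tables round-trip through the TSV writers", {
  nodes <- data.frame(ensg = c("G1", "G2"), gene_name = c("N1", "N2"),
                      biotype = "protein_coding",
                      snp_id = c("rs1", NA), gwas_p = c(0.01, NA),
                      ps_p = c(NA, 0.2),
                      r1 = c(0.5, -1.2), r2 = c(0, 2.5))
  path <- tempfile(fileext = ".tsv")
  writeNodeAttributes(nodes, path)
  back <- readNodeAttributes(path)
  expect_equal(back$ensg, nodes$ensg)
  expect_equal(back$gwas_p, nodes$gwas_p)
  expect_equal(back$r2, nodes$r2)
})
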