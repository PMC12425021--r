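test_that("confidence stratification is cumulative and nested", {
  ann <- annotationFixture()
  syms <- unique(ann$gene)
  net <- interactomeFromEdges(cbind(syms, "hub"))
  # gene at confidence 2 appears from level 2 on, never at level 1
  s1 <- suppressWarnings(buildHallmarkSets(ann, net, 1L))
  s2 <- buildHallmarkSets(ann, net, 2L)
  expect_false("g1" %in% s1[["Cell senescence"]])
  expect_true("g1" %in% s2[["Cell senescence"]])
  # monotone nesting across all levels and hallmarks
  prev <- s1
  for (lv in 2:5) {
    cur <- suppressWarnings(buildHallmarkSets(ann, net, lv))
    for (h in names(cur)) expect_true(all(prev[[h]] %in% cur[[h]]))
    prev <- cur
  }
  # a hallmark with no level-1 genes: empty set plus a warning
  expect_warning(buildHallmarkSets(ann, net, 1L), "Genomic instability")
  expect_length(s1[["Genomic instability"]], 0L)
  # unknown hallmark names are rejected, listing the valid ones
  bad <- ann; bad$hallmark[1L] <- "Telomere shortening"
  expect_error(buildHallmarkSets(bad, net, 3L), "Telomere attrition")
})

test_that("per-level GMT files load as cumulative annotations", {
  g1 <- tempfile(fileext = ".gmt"); g2 <- tempfile(fileext = ".gmt")
  writeLines("Cell senescence\tdesc\tg1\tg2", g1)
  writeLines(c("Cell senescence\tdesc\tg3", "Genomic instability\tdesc\tg4"), g2)
  ann <- readHallmarkGMT(c("1" = g1, "3" = g2))
  expect_identical(sort(ann$gene[ann$confidence == 1L]), c("g1", "g2"))
  expect_identical(ann$hallmark[ann$gene == "g4"], "Genomic instability")
  net <- interactomeFromEdges(cbind(c("g1", "g2", "g3", "g4"), "hub"))
  s1 <- suppressWarnings(buildHallmarkSets(ann, net, 1L))
  expect_setequal(s1[["Cell senescence"]], c("g1", "g2"))
  s3 <- buildHallmarkSets(ann, net, 3L)
  expect_setequal(s3[["Cell senescence"]], c("g1", "g2", "g3"))
})

test_that("per-level set sizes match a brute-force filter oracle", {
  set.seed(77)
  marks <- hallmarkNames()[1:4]
  ann <- data.frame(gene = sprintf("g%03d", sample(100, 180, replace = TRUE)),
                    hallmark = sample(marks, 180, replace = TRUE),
                    confidence = sample(1:5, 180, replace = TRUE),
                    stringsAsFactors = FALSE)
  ann <- ann[!duplicated(ann[, 1:2]), ]
  net <- interactomeFromEdges(cbind(sprintf("g%03d", 1:100), "hub"))
  for (lv in 1:5) {
    sets <- suppressWarnings(buildHallmarkSets(ann, net, lv))
    for (h in marks) {
      oracle <- unique(ann$gene[ann$hallmark == h & ann$confidence <= lv])
      expect_setequal(sets[[h]], oracle)
    }
  }
})

test_that("largest connected component matches a union-find oracle", {
  # clique: everything
  cl <- interactomeFromEdges(cliqueEdges(paste0("c", 1:6)))
  expect_setequal(largestConnectedComponent(cl, nodes(cl)), nodes(cl))
  # no induced edges: singleton, lexicographically first
  p <- pathNet()
  expect_identical(largestConnectedComponent(p, c("d", "a")), "a")
  expect_identical(largestConnectedComponent(p, character(0)), character(0))
  # random induced subgraphs vs union-find
  for (seed in 1:6) {
    edges <- randomEdges(40, 70, seed)
    net <- interactomeFromEdges(edges)
    set.seed(seed + 40)
    genes <- sample(nodes(net), 18L)
    indEdges <- edges[edges[, 1L] %in% genes & edges[, 2L] %in% genes, ,
                      drop = FALSE]
    indEdges <- indEdges[indEdges[, 1L] != indEdges[, 2L], , drop = FALSE]
    comps <- unionFindComponents(genes, indEdges)
    sizes <- lengths(comps)
    best <- comps[sizes == max(sizes)]
    best <- best[order(vapply(best, paste, "", collapse = " "))][[1L]]
    expect_identical(largestConnectedComponent(net, genes), best)
  }
})

test_that("a planted module is detected as a significant LCC", {
  w <- .smallWorld()
  bins <- buildDegreeBins(w$net, 100L)
  res <- lccSignificance(w$net, w$modules[[1L]], bins = bins,
                         nRandom = 300L, seed = 7L)
  expect_gt(res@z, 1.96)
  expect_lt(res@empiricalP, 0.01)
  expect_identical(res@observedSize, length(res@members))
  # determinism under the master seed
  res2 <- lccSignificance(w$net, w$modules[[1L]], bins = bins,
                          nRandom = 300L, seed = 7L)
  expect_identical(res@z, res2@z)
})

test_that("LCC null degenerates gracefully when genes = all nodes", {
  cl <- interactomeFromEdges(cliqueEdges(paste0("c", 1:8)))
  bins <- suppressWarnings(buildDegreeBins(cl, 8L))
  res <- lccSignificance(cl, nodes(cl), bins = bins, nRandom = 50L, seed = 1L)
  expect_true(is.na(res@z))         # null sd is 0: z undefined
  expect_true(res@empiricalP <= 1 && res@empiricalP > 0)
})

test_that("separation follows its convention and matches the oracle", {
  p <- pathNet()
  # hand example: singletons at the path ends
  s <- separation(p, "a", "d")
  expect_equal(s@dAA, 0); expect_equal(s@dBB, 0)
  expect_equal(s@dAB, 3); expect_equal(s@sAB, 3)
  # identical sets separate by exactly zero
  bc <- bridgedCliques()
  expect_equal(separation(bc$net, bc$A, bc$A)@sAB, 0)
  # bridged cliques vs the exhaustive BFS oracle
  expect_equal(separation(bc$net, bc$A, bc$B)@sAB,
               separationOracle(bc$edges, bc$A, bc$B))
  # symmetry on random instances
  for (seed in 1:5) {
    edges <- randomEdges(45, 90, seed)
    net <- interactomeFromEdges(edges)
    set.seed(seed)
    A <- sample(nodes(net), 6L); B <- sample(nodes(net), 5L)
    ab <- separation(net, A, B); ba <- separation(net, B, A)
    expect_equal(ab@sAB, ba@sAB)
    expect_equal(ab@sAB, separationOracle(edges, A, B))
  }
})

test_that("jaccard overlap and its resampling p behave", {
  u <- sprintf("u%03d", 1:200)
  expect_equal(jaccardOverlap(u[1:20], u[1:20], u, 100, seed = 1)@jaccard, 1)
  expect_equal(jaccardOverlap(u[1:10], u[11:20], u, 100, seed = 1)@jaccard, 0)
  ov <- jaccardOverlap(u[1:20], u[11:40], u, 400, seed = 2)
  expect_equal(ov@jaccard, 10 / 40)
  expect_identical(ov@nCommon, 10L)
  expect_lt(ov@pValue, 0.05)  # 25% overlap of 20/30 from 200 is far from null
  expect_error(jaccardOverlap(c(u[1], "zzz"), u[1:3], u), "universe")
})

test_that("LCC z is calibrated for degree-matched random gene sets", {
  # gene sets drawn from the null itself must score as unremarkable
  w <- synthInteractome(synthSpec(seed = 2024L))
  bins <- buildDegreeBins(w$net, 100L)
  ref <- w$modules[[1L]]
  zs <- vapply(1:200, function(i) {
    gs <- sampleDegreeMatched(w$net, bins, ref, seed = 9000 + i)
    lccSignificance(w$net, gs, bins = bins, nRandom = 300L,
                    seed = 100 + i)@z
  }, numeric(1))
  zs <- zs[!is.na(zs)]
  expect_lte(abs(mean(zs)), 0.15)
  expect_gte(sd(zs), 0.8); expect_lte(sd(zs), 1.2)
})

test_that("the longevity module unions overlapping hallmark modules", {
  # two cliques sharing a connector gene
  A <- c(paste0("a", 1:4), "link"); B <- c(paste0("b", 1:4), "link")
  net <- interactomeFromEdges(rbind(cliqueEdges(A), cliqueEdges(B)))
  lm <- longevityModule(net, list(h1 = A, h2 = B))
  expect_setequal(lm$genes, union(A, B))
  expect_identical(unname(lm$membership["link"]), 2L)
  expect_identical(unname(lm$membership["a1"]), 1L)
  # single hallmark handed twice degenerates to that hallmark's LCC
  lm2 <- longevityModule(net, list(h1 = A, h1b = A))
  expect_setequal(lm2$genes, largestConnectedComponent(net, A))
  expect_error(longevityModule(net, list(h1 = A)), "two hallmark sets")
})
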