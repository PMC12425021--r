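test_that("loading cleans self-loops, duplicates and whitespace", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("# interactome fixture", "A\tB", "B\tA", "A\tA", " B \tC"), f)
  net <- loadInteractome(f)
  expect_setequal(nodes(net), c("A", "B", "C"))
  expect_equal(numEdges(net), 2)
  rp <- loadReport(net)
  expect_equal(rp$selfLoopsDropped, 1)
  expect_equal(rp$duplicatesCollapsed, 1)

  # 4-row path file: degrees as expected
  p <- pathNet()
  expect_equal(nodeDegrees(p), c(a = 1L, b = 2L, c = 2L, d = 1L))

  # malformed row errors with the line number
  g <- tempfile(fileext = ".tsv")
  writeLines(c("A\tB", "Conly"), g)
  expect_error(loadInteractome(g), "line 2")
})

test_that("loaded counts agree with an independent set-dedup oracle", {
  edges <- randomEdges(60, 500, seed = 91)
  f <- tempfile(fileext = ".tsv")
  writeLines(paste(edges[, 1L], edges[, 2L], sep = "\t"), f)
  net <- loadInteractome(f)
  # oracle: canonicalise and dedup with plain set operations
  key <- unique(paste(pmin(edges[, 1], edges[, 2]),
                      pmax(edges[, 1], edges[, 2])))
  expect_equal(numEdges(net), length(key))
  expect_setequal(nodes(net), unique(c(edges[, 1], edges[, 2])))

  # SIF format parses the same graph
  s <- tempfile(fileext = ".sif")
  writeLines(paste(edges[, 1L], "interacts", edges[, 2L], sep = "\t"), s)
  net2 <- loadInteractome(s, fmt = "sif")
  expect_identical(numEdges(net2), numEdges(net))
})

test_that("degree bins partition the nodes and respect the occupancy floor", {
  # regular graph (a cycle): one bin
  n <- 30L
  syms <- sprintf("v%02d", 1:n)
  cyc <- interactomeFromEdges(cbind(syms, syms[c(2:n, 1L)]))
  b1 <- buildDegreeBins(cyc, 5L)
  expect_length(b1@bins, 1L)

  # minOccupancy >= node count: single bin with a warning
  p <- pathNet()
  expect_warning(b2 <- buildDegreeBins(p, 10L), "single bin")
  expect_length(b2@bins, 1L)
  expect_setequal(b2@bins[[1L]], nodes(p))

  # heavy-tailed graph: every bin >= 100, bins partition the node set
  w <- .smallWorld()
  bins <- buildDegreeBins(w$net, 100L)
  expect_true(all(lengths(bins@bins) >= 100L))
  expect_setequal(unlist(bins@bins), nodes(w$net))
  expect_false(anyDuplicated(unlist(bins@bins)) > 0L)
  # bin index consistent with the degree intervals
  deg <- nodeDegrees(w$net)
  for (i in seq_along(bins@bins)) {
    d <- deg[bins@bins[[i]]]
    expect_true(all(d >= bins@breaks[i] & d < bins@breaks[i + 1L]))
  }
})

test_that("degree-matched sampling preserves the binned degree histogram", {
  w <- .smallWorld()
  bins <- buildDegreeBins(w$net, 100L)
  ref <- w$modules[[1L]]
  for (s in 1:25) {
    smp <- sampleDegreeMatched(w$net, bins, ref, seed = s)
    expect_length(smp, length(ref))
    expect_false(anyDuplicated(smp) > 0L)
    expect_equal(tabulate(bins@nodeBin[smp], length(bins@bins)),
                 tabulate(bins@nodeBin[ref], length(bins@bins)))
  }

  # reference = whole node set forces the fallback and returns everything
  p <- pathNet()
  pb <- suppressWarnings(buildDegreeBins(p, 4L))
  smp <- sampleDegreeMatched(p, pb, nodes(p), seed = 1)
  expect_setequal(smp, nodes(p))

  # two-bin contract: a reference of 3 low-degree and 2 high-degree genes
  # always samples exactly 3 low-bin and 2 high-bin members
  hubs <- sprintf("h%02d", 1:10); leaves <- sprintf("s%03d", 1:200)
  bip <- interactomeFromEdges(cbind(rep(hubs, each = 200), rep(leaves, 10)))
  sb <- buildDegreeBins(bip, 10L)
  expect_gte(length(sb@bins), 2L)
  ref <- c(leaves[1:3], hubs[1:2])
  for (s in 1:10) {
    smp2 <- sampleDegreeMatched(bip, sb, ref, seed = s)
    expect_equal(sum(smp2 %in% leaves), 3L)
    expect_equal(sum(smp2 %in% hubs), 2L)
  }
})

test_that("single-bin inclusion frequencies are uniform", {
  n <- 30L
  syms <- sprintf("v%02d", 1:n)
  cyc <- interactomeFromEdges(cbind(syms, syms[c(2:n, 1L)]))
  bins <- buildDegreeBins(cyc, 5L)
  ref <- syms[1:5]
  hits <- integer(n); names(hits) <- syms
  nDraw <- 2000L
  for (s in seq_len(nDraw)) {
    smp <- sampleDegreeMatched(cyc, bins, ref, seed = s)
    hits[smp] <- hits[smp] + 1L
  }
  # each node's inclusion frequency ~ Binomial(nDraw, 5/30); a 4 SD bound
  # keeps the familywise false-alarm rate over 30 nodes below ~0.2%
  p0 <- 5 / 30
  tol <- 4 * sqrt(p0 * (1 - p0) / nDraw)
  expect_true(all(abs(hits / nDraw - p0) <= tol))
  expect_equal(mean(hits / nDraw), p0)  # exact: every draw has size 5
})

test_that("minDistToSet equals the BFS oracle and distances are symmetric", {
  for (seed in 1:8) {
    edges <- randomEdges(50, 120, seed)
    net <- interactomeFromEdges(edges)
    adj <- adjList(edges)
    nds <- nodes(net)
    set.seed(seed + 500)
    tgt <- sample(nds, 4L)
    for (src in sample(nds, 6L)) {
      oracle <- min(bfsOracle(adj, src)[tgt])
      expect_equal(minDistToSet(net, src, tgt), oracle)
    }
    # symmetry on sampled pairs
    pr <- matrix(sample(nds, 10L, replace = TRUE), ncol = 2L)
    for (i in seq_len(nrow(pr))) {
      expect_equal(minDistToSet(net, pr[i, 1L], pr[i, 2L]),
                   minDistToSet(net, pr[i, 2L], pr[i, 1L]))
    }
  }
  # membership and error contracts
  p <- pathNet()
  expect_equal(minDistToSet(p, "a", c("a", "d")), 0)
  expect_equal(minDistToSet(p, "a", "d"), 3)
  expect_error(minDistToSet(p, "a", "zz"), "no target")
})
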