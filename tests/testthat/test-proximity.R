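test_that("raw proximity follows the closest-distance definition", {
  p <- pathNet()
  # targets inside the module contribute distance 0
  expect_equal(as.numeric(proximityRaw(p, c("a", "b"), c("a", "b"))), 0)
  # hand BFS: S = {a}, T = {c, d} -> (2 + 3)/2
  expect_equal(as.numeric(proximityRaw(p, "a", c("c", "d"))), 2.5)
  expect_error(proximityRaw(p, "a", "zz"), "no network-mapped target")
  # unmapped targets are dropped and counted, not fatal
  pr <- proximityRaw(p, "a", c("d", "zz"))
  expect_equal(as.numeric(pr), 3)
  expect_equal(attr(pr, "nTargetsDropped"), 1L)
})

test_that("raw proximity equals the exhaustive BFS oracle on random graphs", {
  for (seed in 1:20) {
    edges <- randomEdges(60, 140, seed)
    net <- interactomeFromEdges(edges)
    set.seed(seed + 999)
    S <- sample(nodes(net), 8L)
    T_ <- sample(nodes(net), 4L)
    expect_equal(as.numeric(proximityRaw(net, S, T_)),
                 proximityOracle(edges, S, T_))
  }
})

test_that("growing the module never increases raw proximity", {
  for (seed in 1:10) {
    edges <- randomEdges(50, 110, seed)
    net <- interactomeFromEdges(edges)
    set.seed(seed)
    S <- sample(nodes(net), 6L)
    T_ <- sample(nodes(net), 4L)
    extra <- sample(setdiff(nodes(net), S), 5L)
    p0 <- as.numeric(proximityRaw(net, S, T_))
    for (k in 1:5) {
      pk <- as.numeric(proximityRaw(net, c(S, extra[1:k]), T_))
      expect_lte(pk, p0 + 1e-12)
      p0 <- pk
    }
  }
})

test_that("proximity is zero iff every usable target lies in the module", {
  bc <- bridgedCliques()
  expect_equal(as.numeric(proximityRaw(bc$net, bc$A, bc$A[1:3])), 0)
  expect_gt(as.numeric(proximityRaw(bc$net, bc$A, c(bc$A[1], "b2"))), 0)
})

test_that("significance classes follow the fixed z thresholds", {
  w <- .smallWorld()
  bins <- buildDegreeBins(w$net, 100L)
  mod <- w$modules[[1L]]
  inside <- synthDrug(w$net, mod, 5L, hop = 0, seed = 3)
  res <- proximitySignificance(w$net, mod, inside$targets, bins = bins,
                               nRandom = 300L, seed = 11L)
  expect_lt(res@z, -1.96)
  expect_identical(res@significance, "significant")
  expect_equal(res@pRaw, 0)
  # determinism: identical master seed reproduces z exactly
  res2 <- proximitySignificance(w$net, mod, inside$targets, bins = bins,
                                nRandom = 300L, seed = 11L)
  expect_identical(res@z, res2@z)
  # classification boundaries (unit-level, synthetic z values)
  expect_identical(sharpr:::classifySignificance(-2.0), "significant")
  expect_identical(sharpr:::classifySignificance(-1.96), "marginal")
  expect_identical(sharpr:::classifySignificance(-1.7), "marginal")
  expect_identical(sharpr:::classifySignificance(-1.645), "ns")
  expect_identical(sharpr:::classifySignificance(NA_real_), "ns")
})

test_that("the screen table has the contracted shape and NA semantics", {
  w <- .smallWorld()
  net <- w$net
  mod <- w$modules[[1L]]
  ann <- w$annotations
  # add a second hallmark with genes only at levels 3-5
  others <- setdiff(nodes(net), mod)[1:12]
  ann2 <- rbind(ann, data.frame(gene = others, hallmark = "Genomic instability",
                                confidence = sample(3:5, 12, replace = TRUE)))
  setsByLevel <- lapply(setNames(1:5, 1:5), function(lv)
    suppressWarnings(buildHallmarkSets(ann2, net, lv)))
  drugs <- list(
    d1 = synthDrug(net, mod, 5L, hop = 0, seed = 1, drugId = "d1"),
    d2 = synthDrug(net, mod, 5L, hop = "random", seed = 2, drugId = "d2"),
    d3 = list(drug_id = "d3", name = "unmapped", targets = c("NOPE1", "NOPE2")))
  tab <- screenDrugs(net, drugs, setsByLevel, nRandom = 150L, seed = 5L)
  expect_identical(nrow(tab), 3L * 2L * 5L)
  # empty level sets yield NA rows flagged empty_set
  empt <- tab$status == "empty_set"
  expect_true(all(is.na(tab$z[empt])))
  expect_true(any(empt))
  # unmapped drug rows carry status but do not abort the screen
  expect_true(all(tab$status[tab$drug_id == "d3"] %in%
                  c("unmapped", "empty_set")))
  # planted drug is consistently significant; its flag spans usable levels
  d1rows <- tab[tab$drug_id == "d1" & tab$hallmark == names(setsByLevel[[1]])[1] &
                tab$status == "ok", ]
  expect_true(all(d1rows$significance == "significant"))
  # identical master seed reproduces every z byte for byte
  tab2 <- screenDrugs(net, drugs, setsByLevel, nRandom = 150L, seed = 5L)
  expect_identical(tab$z, tab2$z)
})

test_that("consistency filtering ranks drugs by cross-level evidence", {
  mk <- function(drug, zs, status = "ok") {
    data.frame(drug_id = drug, hallmark = "Cell senescence", level = 1:5,
               z = zs,
               significance = ifelse(is.na(zs), NA,
                                     ifelse(zs < -1.96, "significant", "ns")),
               status = ifelse(is.na(zs), "empty_set", status),
               stringsAsFactors = FALSE)
  }
  tab <- rbind(
    mk("allsig", c(-3, -2.5, -2.2, -2.1, -2.0)),
    mk("lvl1empty", c(NA, -2.5, -2.2, -2.1, -2.0)),
    mk("fourof5", c(-0.5, -2.5, -2.2, -2.1, -2.0)),
    mk("none", c(0.1, 0.3, -1, -0.2, 0)))
  allAvail <- consistencyFilter(tab, rule = "all-available")
  got <- allAvail[["Cell senescence"]]$drug_id
  expect_true(all(c("allsig", "lvl1empty") %in% got))  # empty level 1 ignored
  expect_false("fourof5" %in% got)
  atLeast4 <- consistencyFilter(tab, minLevels = 4L, rule = "at-least-k")
  expect_true("fourof5" %in% atLeast4[["Cell senescence"]]$drug_id)
  expect_false("none" %in% atLeast4[["Cell senescence"]]$drug_id)
  # ranked by best (most negative) z
  expect_equal(got[1L], "allsig")
  expect_length(consistencyFilter(tab[0, ], rule = "all-available"), 0L)
})
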