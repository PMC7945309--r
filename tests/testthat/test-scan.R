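# Ultrametric trees, quintet enumeration, the exhaustive scan, and
# aggregation.

test_that("makeUltrametric: require validates or fails with the worst pair", {
  ok <- ape::read.tree(text = "((a:1,b:1):1,c:2);")
  ut <- makeUltrametric(ok, "require")
  expect_s4_class(ut, "UltrametricTree")
  expect_identical(ut@tree$edge.length, ok$edge.length)
  expect_equal(max(nodeDepths(ut)), 2)

  bad <- ape::read.tree(text = "((a:1,b:3):1,c:2);")
  expect_error(makeUltrametric(bad, "require"), "not ultrametric.*b.*c|not ultrametric")
})

test_that("makeUltrametric: equal_terminals equalizes tip depths", {
  # internal length 1 above (a,b); terminals assigned so tip depths equalize
  tr <- ape::read.tree(text = "((a:1,b:1):1,c:1);")
  ut <- makeUltrametric(tr, "equal_terminals")
  d <- nodeDepths(ut)
  expect_true(all(abs(d[1:3]) < 1e-9))
  n <- ape::Ntip(ut@tree)
  mrcaAB <- ape::getMRCA(ut@tree, c("a", "b"))
  root <- n + 1L
  expect_lt(d[mrcaAB], d[root])
  expect_equal(d[root] - d[mrcaAB], 1)  # the internal branch is preserved
})

test_that("makeUltrametric: mean_path smooths and stays monotone", {
  tr <- ape::read.tree(text = "((a:1,b:3):1,(c:2,d:2.5):1.5);")
  ut <- makeUltrametric(tr, "mean_path")
  fromRoot <- ape::node.depth.edgelength(ut@tree)
  tipd <- fromRoot[1:4]
  expect_lt(max(tipd) - min(tipd), 1e-6)
  expect_true(all(ut@tree$edge.length >= 0))
})

test_that("enumerateQuartets: balanced quartet, caterpillar, ladder cases", {
  ut <- makeUltrametric(
    ape::read.tree(text = "(((a:1,b:1):2,(c:2,d:2):1):2,O:5);"), "require")
  q <- enumerateQuartets(ut, "O")
  expect_identical(nrow(q), 1L)
  expect_identical(unlist(q[1, 1:4], use.names = FALSE), c("a", "b", "c", "d"))

  # caterpillar: no two disjoint pairs both younger than the four-taxon MRCA
  cat4 <- makeUltrametric(
    ape::read.tree(text = "((((a:1,b:1):1,c:2):1,d:3):1,O:4);"), "require")
  expect_identical(nrow(enumerateQuartets(cat4, "O")), 0L)

  expect_error(enumerateQuartets(ut, "zzz"), "not a tip")
  ut3 <- makeUltrametric(ape::read.tree(text = "(((a:1,b:1):1,c:2):1,O:3);"),
                         "require")
  expect_error(enumerateQuartets(ut3, "O"), "four ingroup")
})

test_that("enumeration matches the brute-force filter on random trees", {
  set.seed(55)
  for (r in 1:20) {
    n <- sample(5:12, 1)
    tr <- ape::rcoal(n)
    tr$tip.label <- sprintf("t%02d", seq_len(n))
    ut <- makeUltrametric(tr, "require", tolerance = 1e-8)
    got <- enumerateQuartets(ut, "t01")
    got <- got[order(got$P1, got$P2, got$P3, got$P4), 1:4]
    rownames(got) <- NULL
    want <- naiveQuartets(tr, "t01", tol = 1e-8)
    rownames(want) <- NULL
    expect_identical(got, want)
  }
})

test_that("enumeration count is invariant under tip relabeling", {
  set.seed(66)
  tr <- ape::rcoal(9)
  tr$tip.label <- sprintf("t%d", 1:9)
  ut <- makeUltrametric(tr, "require", tolerance = 1e-8)
  n1 <- nrow(enumerateQuartets(ut, "t1"))
  perm <- tr
  # relabel tips 2..9 by a permutation (outgroup label kept)
  set.seed(1)
  newlab <- c("t1", sample(sprintf("x%d", 1:8)))
  perm$tip.label <- newlab[match(perm$tip.label, c("t1", sprintf("t%d", 2:9)))]
  up <- makeUltrametric(perm, "require", tolerance = 1e-8)
  expect_identical(nrow(enumerateQuartets(up, "t1")), n1)
})

test_that("runScan: identical sequences give all-none calls; count matches", {
  tr <- ape::read.tree(text = "(((a:1,b:1):2,(c:2,d:2):1):2,O:5);")
  ut <- makeUltrametric(tr, "require")
  sm <- new("Supermatrix",
            sequences = setNames(rep(paste(rep("ACGT", 10), collapse = ""), 5),
                                 c("a", "b", "c", "d", "O")),
            partitions = data.frame(locus = "L1", start = 1L, end = 40L))
  scan <- runScan(sm, ut, "O")
  expect_identical(nrow(scan), nrow(enumerateQuartets(ut, "O")))
  expect_true(all(scan$category == "none"))
  expect_false(any(scan$anySig))
  expect_true(all(scan$nUsed == 40L))

  smBad <- new("Supermatrix", sequences = sm@sequences[1:4],
               partitions = sm@partitions)
  expect_error(runScan(smBad, ut, "O"), "missing from the supermatrix")
})

test_that("scan on a synthetic six-taxon system flags the true pair", {
  tree6 <- ape::read.tree(text = paste0(
    "((((A:0.2,B:0.2):0.3,(C:0.35,D:0.35):0.15):0.2,(E:0.4,F:0.4):0.3):0.3,",
    "OUT:1.0);"))
  cfg <- simConfig(tree = tree6, popsPerTaxon = 1L, indsPerPop = 2L,
                   nLoci = 300L, events = list(introgressionEvent("C", "A", 0.5, 0.05)),
                   dropout = 0.1, seed = 71)
  sim <- simulateGBS(cfg, reads = FALSE)
  ds <- buildDataset(truthMatrix(sim$truth), "population", sim$truth@grouping)
  sm <- toSupermatrix(ds, seed = 71)
  ptree <- populationTree(tree6, 1L)
  ut <- makeUltrametric(ape::keep.tip(ptree, names(sm@sequences)), "require")
  scan <- runScan(sm, ut, "OUT.1")
  agg <- aggregateScan(scan, setNames(sim$truth@grouping$taxon,
                                      sim$truth@grouping$population))
  top <- agg$pairs[which.max(agg$pairs$proportion), ]
  expect_identical(top$pair, "A|C")
  expect_gt(top$proportion, 0.05)
  # polarization: majority of directed calls name C as the donor
  dirs <- scan[scan$category != "none" & !is.na(scan$donor), ]
  dirs <- dirs[startsWith(dirs$donor, "C.") & startsWith(dirs$recipient, "A.") |
               startsWith(dirs$donor, "A.") & startsWith(dirs$recipient, "C."), ]
  expect_gt(mean(startsWith(dirs$donor, "C.")), 0.5)
})

test_that("aggregateScan: hand-built table and per-unit report", {
  tab <- data.frame(P1 = "u1", P2 = "u2", P3 = "u3", P4 = "u4",
                    category = c(rep("none", 9), "P1-P3"),
                    donor = c(rep(NA, 9), "u1"),
                    recipient = c(rep(NA, 9), "u3"),
                    anySig = c(rep(FALSE, 9), TRUE),
                    stringsAsFactors = FALSE)
  grp <- c(u1 = "A", u2 = "B", u3 = "C", u4 = "D")
  agg <- aggregateScan(tab, grp, config = scanConfig(pairReportProp = 0.05))
  ac <- agg$pairs[agg$pairs$pair == "A|C", ]
  expect_identical(ac$nTests, 10L)
  expect_identical(ac$nEvents, 1L)
  expect_equal(ac$proportion, 0.1)
  expect_true(ac$flagProportion)
  expect_false(ac$flagDetail)
  expect_identical(ac$directions, "A=>C:1")
  # pairs never callable have no rows; callable-but-empty pairs have 0 events
  bd <- agg$pairs[agg$pairs$pair == "B|D", ]
  expect_identical(bd$nEvents, 0L)
  expect_false(bd$flagProportion)
  # per-unit report: each unit participated in all 10 tests, 1 significant
  expect_true(all(agg$units$nTests == 10L))
  expect_true(all(agg$units$proportion == 0.1))

  expect_error(aggregateScan(tab, grp[1:3]), "not covered")
})

test_that("scan outputs are written and re-readable", {
  tr <- ape::read.tree(text = "(((a:1,b:1):2,(c:2,d:2):1):2,O:5);")
  ut <- makeUltrametric(tr, "require")
  set.seed(2)
  sm <- new("Supermatrix",
            sequences = setNames(vapply(1:5, function(i) randDNA(60), character(1)),
                                 c("a", "b", "c", "d", "O")),
            partitions = data.frame(locus = c("L1", "L2"), start = c(1L, 31L),
                                    end = c(30L, 60L)))
  scan <- runScan(sm, ut, "O")
  agg <- aggregateScan(scan, c(a = "A", b = "B", c = "C", d = "D", O = "O"))
  d <- tempfile(); writeScanOutputs(scan, agg, d)
  expect_true(all(file.exists(file.path(d, c("scan_tests.tsv", "pair_summary.tsv",
                                             "unit_summary.tsv", "summary.txt")))))
  back <- read.delim(file.path(d, "scan_tests.tsv"))
  expect_identical(nrow(back), nrow(scan))
})
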