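# Filtering rules, dataset construction, SNP/supermatrix reduction,
# bootstrap, and the format writers.

test_that("locusVariability: trivial cases and brute-force agreement", {
  expect_identical(locusVariability(rep("ACGTACGTAC", 4)), 0)
  aln <- c("AAAAAAAAAA", "AAAAAAAAAT")  # one variable column of ten
  expect_identical(locusVariability(aln), 0.1)
  expect_error(locusVariability(character(0)), "empty alignment")
  expect_error(locusVariability(c("", "")), "empty alignment")

  # missing states do not create variability
  expect_identical(locusVariability(c("ACGT", "ACGN")), 0)

  set.seed(7)
  for (r in 1:20) {
    n <- sample(2:6, 1); L <- sample(5:40, 1)
    aln <- replicate(n, randDNA(L))
    naive <- mean(vapply(seq_len(L), function(k) {
      col <- substr(aln, k, k)
      length(unique(col[col %in% c("A", "C", "G", "T")])) >= 2
    }, logical(1)))
    expect_equal(locusVariability(aln), naive)
  }
})

test_that("filterHypervariable: IQR rule removes the hand-computed outlier", {
  # v = {0.02 x10, 0.04 x10, 0.90 x1}: mean = 1.5/21, IQR = 0.02 (type-7
  # quantiles), threshold = 0.0714 + 3 * 0.02 = 0.1314 -> only 0.90 removed
  L <- 100L
  mkAln <- function(nvar) {
    base <- randDNA(L)
    alt <- base
    for (k in seq_len(nvar))
      substr(alt, k, k) <- setdiff(c("A", "C", "G", "T"), substr(base, k, k))[1]
    c(i1 = base, i2 = alt)
  }
  set.seed(11)
  spec <- c(lapply(1:10, function(i) as.list(mkAln(2))),
            lapply(1:10, function(i) as.list(mkAln(4))),
            list(as.list(mkAln(90))))
  names(spec) <- sprintf("L%02d", seq_along(spec))
  m <- makeMatrix(spec)
  v <- vapply(seq_len(nLoci(m)), function(i)
    locusVariability(unlist(alleleSets(m)[i, ])), numeric(1))
  expect_equal(sort(unique(v)), c(0.02, 0.04, 0.90))
  expect_equal(mean(v) + 3 * IQR(v), mean(v) + 3 * 0.02)
  f <- filterHypervariable(m, varK = 3)
  expect_identical(nLoci(f), 20L)
  expect_false("L21" %in% lociNames(f))

  # equal variabilities: IQR = 0, nothing exceeds the mean -> nothing removed
  eq <- makeMatrix(setNames(lapply(1:5, function(i) as.list(mkAln(3))),
                            sprintf("E%d", 1:5)))
  expect_identical(nLoci(filterHypervariable(eq, 3)), 5L)
})

test_that("simulated paralog-merged loci are removed at >= 90% sensitivity", {
  cfg <- simConfig(nLoci = 100L, indsPerPop = 2L, paralogRate = 0.2,
                   dropout = 0.1, seed = 13)
  sim <- simulateGBS(cfg, reads = FALSE)
  tm <- truthMatrix(sim$truth)
  lab <- truthLabels(sim$truth)
  composites <- lab$locus[lab$label == "paralog" & is.na(lab$mergedInto)]
  f <- filterHypervariable(tm, varK = 3)
  removed <- setdiff(lociNames(tm), lociNames(f))
  expect_gte(mean(composites %in% removed), 0.9)
})

test_that("filterMissingness: strict 10%/70% boundaries", {
  # 20 loci; individual 'low' has 1/20 = 5% -> dropped; 'edge' has exactly
  # 10% -> kept
  inds <- c("a", "b", "c", "d", "e", "f", "g", "h", "i", "j", "low", "edge")
  spec <- lapply(1:20, function(i) {
    s <- randDNA(8)
    cell <- setNames(rep(list(s), 10), inds[1:10])
    if (i == 1) cell$low <- s
    if (i <= 2) cell$edge <- s
    cell
  })
  names(spec) <- sprintf("L%02d", 1:20)
  set.seed(3)
  m <- makeMatrix(spec, inds)
  f <- filterMissingness(m, thetaInd = 0.10, thetaLoc = 0.70)
  expect_false("low" %in% unitNames(f))
  expect_true("edge" %in% unitNames(f))

  # locus at 69% of individuals dropped, at exactly 70% kept
  inds2 <- sprintf("i%03d", 1:100)
  spec2 <- list(
    full = setNames(rep(list("ACGTACGT"), 100), inds2),
    l69  = setNames(rep(list("ACGTACGT"), 69), inds2[1:69]),
    l70  = setNames(rep(list("ACGTACGT"), 70), inds2[1:70]))
  m2 <- makeMatrix(spec2, inds2)
  f2 <- filterMissingness(m2)
  expect_identical(sort(lociNames(f2)), c("full", "l70"))

  # complete matrix passes unchanged
  cm <- completeMatrix(c("x", "y", "z"))
  expect_identical(alleleSets(filterMissingness(cm)), alleleSets(cm))

  # everything filtered -> diagnostic errors naming the offending threshold
  m3 <- makeMatrix(list(L1 = list(a = "ACGT"), L2 = list(b = "ACGT")),
                   c("a", "b", "c"))
  expect_error(filterMissingness(m3, thetaInd = 0.9), "thetaInd")
  m4 <- makeMatrix(list(L1 = list(a = "ACGT", b = "ACGT"),
                        L2 = list(c = "ACGT", d = "ACGT")),
                   c("a", "b", "c", "d"))
  expect_error(filterMissingness(m4, thetaInd = 0.4, thetaLoc = 0.7),
               "thetaLoc")
})

test_that("selectBestUnit: loci, then reads, then id", {
  spec <- list(
    L1 = list(A = "ACGT", B = "ACGT", C = "ACGT"),
    L2 = list(A = "ACGT", B = "ACGT", C = "ACGT"),
    L3 = list(A = "ACGT", B = "ACGT"))
  m <- makeMatrix(spec, c("A", "B", "C"))
  expect_identical(selectBestUnit(m, c("A", "C")), "A")      # 3 vs 2 loci
  expect_identical(selectBestUnit(m, c("A", "B"),
                                  reads = c(A = 1e6, B = 1e5)), "A")
  expect_identical(selectBestUnit(m, c("B", "A"),
                                  reads = c(A = 1e5, B = 1e6)), "B")
  expect_identical(selectBestUnit(m, c("B", "A")), "A")      # lexicographic
  expect_identical(selectBestUnit(m, "C"), "C")
})

test_that("buildDataset: taxon level on the packaged grouping has 13 units", {
  g <- cherleriaGrouping()
  expect_identical(length(unique(g$taxon)), 13L)
  set.seed(5)
  m <- completeMatrix(g$individual, nloci = 4L)
  ds <- buildDataset(m, "taxon", g)
  expect_identical(nUnits(ds), 13L)
  expect_true("capillacea_albanian" %in% unitNames(ds))
  expect_identical(ds@level, "taxon")
})

test_that("buildDataset: population level and composite fill-in", {
  # single population -> dataset is its best individual
  g <- data.frame(individual = c("a1", "a2"), population = "p1", taxon = "t1")
  spec <- list(L1 = list(a1 = "ACGT", a2 = "ACGT"),
               L2 = list(a1 = "ACGT", a2 = "ACGT"),
               L3 = list(a2 = "AAAA"))
  m <- makeMatrix(spec, c("a1", "a2"))
  dp <- buildDataset(m, "population", g, thetaLoc = 0.5)
  expect_identical(unitNames(dp), "p1")
  # a2 has 3 loci vs a1's 2: best individual is a2
  expect_identical(alleleSets(dp)[["L3", "p1"]], "AAAA")

  # composite fill-in: best individual lacks L3, its pop-mate has it
  g2 <- data.frame(individual = c("b1", "b2", "b3"),
                   population = c("p1", "p1", "p2"), taxon = "t1")
  spec2 <- list(L1 = list(b1 = "ACGT", b2 = "ACGT", b3 = "ACGT"),
                L2 = list(b1 = "ACGT", b2 = "ACGT", b3 = "ACGT"),
                L3 = list(b1 = "ACGT", b2 = "ACGT", b3 = "ACGT"),
                L4 = list(b2 = "TTTT", b3 = "GGGG"))
  m2 <- makeMatrix(spec2, c("b1", "b2", "b3"))
  dt <- buildDataset(m2, "taxon", g2, thetaLoc = 0.5)
  # best individual is b1 or b2 (b2 has 4 loci -> best); composite gets L4
  expect_identical(unitNames(dt), "t1")
  expect_identical(alleleSets(dt)[["L4", "t1"]], "TTTT")

  # same fixture but best individual = b1 (forced by reads): L4 filled from b2
  dt2 <- buildDataset(m2, "taxon", g2, thetaLoc = 0.5,
                      reads = c(b1 = 100, b2 = 1, b3 = 1))
  expect_identical(alleleSets(dt2)[["L4", "t1"]], "TTTT")

  expect_error(buildDataset(m2, "taxon",
                            g2[g2$individual != "b3", ]), "missing from grouping")
})

test_that("post-filter guarantee and thetaLoc monotonicity", {
  cfg <- simConfig(nLoci = 60L, indsPerPop = 2L, dropout = 0.3, seed = 17)
  sim <- simulateGBS(cfg, reads = FALSE)
  tm <- truthMatrix(sim$truth)
  counts <- integer(0)
  for (tl in c(0.3, 0.5, 0.7)) {
    ds <- buildDataset(tm, "population", sim$truth@grouping, thetaLoc = tl)
    expect_true(all(rowMeans(presenceMatrix(ds)) >= tl))
    counts <- c(counts, nLoci(ds))
  }
  expect_true(all(diff(counts) <= 0))
})

test_that("toSupermatrix: lengths, partitions, determinism", {
  g <- data.frame(individual = c("u1", "u2"), population = c("p1", "p2"),
                  taxon = c("t1", "t2"))
  spec <- list(L1 = list(u1 = c("ACGT", "ACGA"), u2 = "ACGT"),
               L2 = list(u1 = "GGGGGG", u2 = "GGGGGG"),
               L3 = list(u2 = "TTTTT"))
  m <- makeMatrix(spec, c("u1", "u2"))
  ds <- buildDataset(m, "individual", g, thetaInd = 0.1, thetaLoc = 0.5)
  sm <- toSupermatrix(ds, seed = 1)
  p <- sm@partitions
  expect_identical(sum(p$end - p$start + 1L), nchar(sm@sequences[[1]]))
  expect_identical(nchar(sm@sequences[["u1"]]), nchar(sm@sequences[["u2"]]))
  # missing locus filled with N
  expect_identical(substr(sm@sequences[["u1"]], p$start[p$locus == "L3"],
                          p$end[p$locus == "L3"]), "NNNNN")
  # same seed -> identical; homozygous cells are seed-independent
  expect_identical(toSupermatrix(ds, seed = 1)@sequences, sm@sequences)
  s2 <- toSupermatrix(ds, seed = 99)@sequences
  expect_identical(substr(s2[["u2"]], 1, 4), substr(sm@sequences[["u2"]], 1, 4))
})

test_that("toSNPMatrix: biallelic kept, triallelic reduced, reproducible", {
  g <- data.frame(individual = c("u1", "u2", "u3"),
                  population = c("p1", "p2", "p3"), taxon = c("t1", "t2", "t3"))
  spec <- list(L1 = list(u1 = "AAAA", u2 = "AAAT", u3 = "AAAC"),
               L2 = list(u1 = "GGGG", u2 = "GGGC", u3 = "GGGG"))
  m <- makeMatrix(spec, c("u1", "u2", "u3"))
  ds <- buildDataset(m, "individual", g, thetaLoc = 0.5)
  sn <- toSNPMatrix(ds, seed = 2)
  expect_identical(ncol(sn@genotypes), 2L)           # monomorphic cols dropped
  # biallelic site: both states coded, none missing
  biallelic <- sn@genotypes[, sn@siteMap$locus == "L2"]
  expect_false(anyNA(biallelic))
  expect_setequal(unique(biallelic), c(0L, 1L))
  # triallelic site: exactly one unit becomes missing
  tri <- sn@genotypes[, sn@siteMap$locus == "L1"]
  expect_identical(sum(is.na(tri)), 1L)
  expect_identical(unname(tri[!is.na(tri)])[1], 0L)          # first retained unit is 0
  expect_identical(toSNPMatrix(ds, seed = 2)@genotypes, sn@genotypes)
})

test_that("bootstrapLoci: replicate count, size, degenerate one-locus case", {
  g <- data.frame(individual = c("u1", "u2"), population = c("p1", "p2"),
                  taxon = c("t1", "t2"))
  m <- completeMatrix(c("u1", "u2"), nloci = 6L)
  ds <- buildDataset(m, "individual", g)
  expect_identical(bootstrapLoci(ds, 0), list())
  reps <- bootstrapLoci(ds, 5, seed = 4)
  expect_length(reps, 5L)
  expect_true(all(vapply(reps, nLoci, integer(1)) == 6L))

  one <- buildDataset(completeMatrix(c("u1", "u2"), nloci = 1L),
                      "individual", g)
  r1 <- bootstrapLoci(one, 3, seed = 1)
  for (r in r1)
    expect_identical(unname(alleleSets(r)), unname(alleleSets(one)))
})

test_that("writers produce parseable files", {
  g <- data.frame(individual = c("u1", "u2", "u3"),
                  population = c("p1", "p2", "p3"), taxon = c("t1", "t2", "t3"))
  set.seed(8)
  m <- completeMatrix(c("u1", "u2", "u3"), nloci = 3L, L = 10L)
  # introduce one het and one variable site
  m@cells[[1, 1]] <- c(m@cells[[1, 1]], paste0("T", substr(m@cells[[1, 1]], 2, 10)))
  ds <- buildDataset(m, "individual", g)
  sm <- toSupermatrix(ds, seed = 1)
  d <- tempfile(); dir.create(d)

  writePhylip(sm, file.path(d, "s.phy"))
  phy <- readLines(file.path(d, "s.phy"))
  expect_length(phy, 4L)
  expect_identical(strsplit(trimws(phy[1]), " +")[[1]], c("3", "30"))

  writeFastaAlignment(sm, file.path(d, "s.fasta"))
  fas <- Biostrings::readDNAStringSet(file.path(d, "s.fasta"))
  expect_identical(sort(names(fas)), c("u1", "u2", "u3"))
  expect_identical(unname(as.character(fas["u2"])), unname(sm@sequences[["u2"]]))

  writePartitions(sm, file.path(d, "s.part"))
  expect_match(readLines(file.path(d, "s.part"))[1], "^DNA, L01 = 1-10$")

  writeNexus(sm, file.path(d, "s.nex"))
  nex <- readLines(file.path(d, "s.nex"))
  expect_identical(nex[1], "#NEXUS")
  expect_true(any(grepl("DIMENSIONS NCHAR=30", nex)))

  writeHaplotypeMatrix(ds, file.path(d, "hap.tsv"))
  hap <- read.delim(file.path(d, "hap.tsv"), check.names = FALSE)
  expect_identical(dim(hap), c(3L, 4L))
  expect_match(hap[hap[[1]] == "u1", "L01"], ",")  # het cell has two haplotypes

  sn <- toSNPMatrix(ds, seed = 1)
  writeSNPTable(sn, file.path(d, "snp.tsv"))
  snp <- read.delim(file.path(d, "snp.tsv"))
  expect_identical(nrow(snp), 3L)

  writeStructure(ds, file.path(d, "str.tsv"), seed = 1)
  str <- readLines(file.path(d, "str.tsv"))
  expect_length(str, 6L)  # two rows per unit

  writePresenceTable(ds, file.path(d, "pres.tsv"))
  pres <- read.delim(file.path(d, "pres.tsv"))
  expect_identical(nrow(pres), 3L)
})
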