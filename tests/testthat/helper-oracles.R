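# Independent brute-force oracles and small fixture builders used across the
# suite. These deliberately share no code with the implementation.

# naive per-column site-pattern counter (reference for countSitePatterns)
naiveCountPatterns <- function(seqs) {
  chars <- lapply(seqs, function(s) strsplit(s, "")[[1]])
  L <- length(chars[[1]])
  counts <- setNames(rep(0L, 16L), NULL)
  used <- 0L
  for (k in seq_len(L)) {
    col <- toupper(vapply(chars, `[`, character(1), k))
    if (any(!col %in% c("A", "C", "G", "T"))) next
    if (length(unique(col)) > 2L) next
    used <- used + 1L
    der <- as.integer(col[1:4] != col[5])
    idx <- der[1] * 8L + der[2] * 4L + der[3] * 2L + der[4]
    counts[idx + 1L] <- counts[idx + 1L] + 1L
  }
  list(counts = counts, used = used, skipped = L - used)
}

# naive tree-compatible quintet enumeration (reference for enumerateQuartets)
naiveQuartets <- function(tree, outgroup, tol = 1e-6) {
  fromRoot <- ape::node.depth.edgelength(tree)
  depth <- max(fromRoot[seq_len(ape::Ntip(tree))]) - fromRoot
  ing <- sort(setdiff(tree$tip.label, outgroup))
  out <- list()
  for (set in utils::combn(ing, 4L, simplify = FALSE)) {
    # all 3 splits of the four tips into two pairs
    splits <- list(c(1, 2, 3, 4), c(1, 3, 2, 4), c(1, 4, 2, 3))
    for (sp in splits) {
      p <- sort(set[sp[1:2]]); q <- sort(set[sp[3:4]])
      dp <- depth[ape::getMRCA(tree, p)]
      dq <- depth[ape::getMRCA(tree, q)]
      dAll <- depth[ape::getMRCA(tree, set)]
      if (dp >= dAll - tol || dq >= dAll - tol) next
      if (abs(dp - dq) <= tol) {
        if (paste(q, collapse = " ") < paste(p, collapse = " ")) {
          tmp <- p; p <- q; q <- tmp
        }
      } else if (dp > dq) {
        tmp <- p; p <- q; q <- tmp
      }
      out[[length(out) + 1L]] <- c(p, q)
    }
  }
  if (!length(out))
    return(data.frame(P1 = character(0), P2 = character(0),
                      P3 = character(0), P4 = character(0)))
  m <- unique(do.call(rbind, out))
  df <- data.frame(P1 = m[, 1], P2 = m[, 2], P3 = m[, 3], P4 = m[, 4],
                   stringsAsFactors = FALSE)
  df[order(df$P1, df$P2, df$P3, df$P4), ]
}

# LocusMatrix from explicit per-locus named allele lists
# cells: list(locus = list(ind = c("ACG", ...), ...), ...)
makeMatrix <- function(cellSpec, individuals = NULL) {
  loci <- names(cellSpec)
  if (is.null(individuals))
    individuals <- sort(unique(unlist(lapply(cellSpec, names))))
  cm <- matrix(vector("list", length(loci) * length(individuals)),
               length(loci), length(individuals),
               dimnames = list(loci, individuals))
  lens <- integer(length(loci))
  for (i in seq_along(loci)) {
    for (ind in names(cellSpec[[i]]))
      cm[[i, ind]] <- cellSpec[[i]][[ind]]
    lens[i] <- nchar(unlist(cellSpec[[i]])[1])
  }
  new("LocusMatrix", cells = cm, lociLength = setNames(lens, loci),
      provenance = list())
}

# random DNA string
randDNA <- function(L) paste(sample(c("A", "C", "G", "T"), L, TRUE), collapse = "")

# a complete (no missing data) matrix for a set of individuals
completeMatrix <- function(individuals, nloci = 5L, L = 12L) {
  spec <- lapply(seq_len(nloci), function(i) {
    base <- randDNA(L)
    setNames(rep(list(base), length(individuals)), individuals)
  })
  names(spec) <- sprintf("L%02d", seq_len(nloci))
  makeMatrix(spec, individuals)
}

# symmetric five-taxon clock tree used by DFOIL-level simulations:
# t(P1,P2) = 0.2, t(P3,P4) = 0.35, ingroup root 0.7, outgroup 1.0
fiveTaxonTree <- function() {
  ape::read.tree(text = "(((P1:0.2,P2:0.2):0.5,(P3:0.35,P4:0.35):0.35):0.3,O:1.0);")
}

# simulate a five-taxon system and run one DFOIL test on its supermatrix
dfoilOnSim <- function(events, seed, nLoci = 300L, gamma = NULL,
                       mode = "dfoil", alpha = 0.01) {
  cfg <- simConfig(tree = fiveTaxonTree(), popsPerTaxon = 1L, indsPerPop = 1L,
                   nLoci = nLoci, mu = 0.02, popTheta = 0.002,
                   events = events, dropout = 0, paralogRate = 0, seed = seed)
  sim <- simulateGBS(cfg, reads = FALSE)
  tm <- truthMatrix(sim$truth)
  ds <- buildDataset(tm, "individual", sim$truth@grouping)
  sm <- toSupermatrix(ds, seed = seed)
  seqs <- sm@sequences[paste0(c("P1", "P2", "P3", "P4", "O"), ".1_i1")]
  dfoilTest(countSitePatterns(unname(seqs)), alpha = alpha, mode = mode)
}
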