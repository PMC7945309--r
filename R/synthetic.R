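# Synthetic GBS systems with known species trees, introgression, missingness,
# paralogy and sequencing error. Sequences evolve by Jukes-Cantor along an
# ultrametric species/population tree; introgression is modeled as locus-wise
# genealogy replacement (the recipient lineage is re-attached to the donor
# lineage at the admixture time); individuals are diploid.

#' Default 13-taxon ultrametric species tree
#'
#' A fixed, rooted, ultrametric species tree with twelve ingroup taxa
#' (\code{T01}..\code{T12}, three nested clades of unequal divergence times)
#' and an outgroup \code{OUT} attached at the root (depth 1 time unit). This
#' mirrors the sampling design of a typical GBS study of a small plant clade:
#' about a dozen taxa plus one outgroup used to polarize site patterns.
#'
#' @return an \code{ape::phylo} tree.
#' @export
#' @examples
#' tr <- defaultSpeciesTree()
#' ape::Ntip(tr)  # 13
defaultSpeciesTree <- function() {
  ape::read.tree(text = paste0(
    "(((((T01:0.10,T02:0.10):0.25,(T03:0.20,T04:0.20):0.15):0.20,",
    "((T05:0.12,T06:0.12):0.18,T07:0.30):0.25):0.15,",
    "(((T08:0.08,T09:0.08):0.17,T10:0.25):0.20,",
    "(T11:0.22,T12:0.22):0.23):0.25):0.30,OUT:1.00);"))
}

#' Specify an introgression event
#'
#' @param donor donor taxon id.
#' @param recipient recipient taxon or population id.
#' @param gamma fraction of loci affected, in [0, 1].
#' @param tAdmix attachment time before present; must be more recent than the
#'   divergence of donor and recipient.
#' @return an \linkS4class{IntrogressionEvent}.
#' @export
#' @examples
#' introgressionEvent("T03", "T08", gamma = 0.3)
introgressionEvent <- function(donor, recipient, gamma, tAdmix = 0.05) {
  new("IntrogressionEvent", donor = as.character(donor),
      recipient = as.character(recipient), gamma = as.numeric(gamma),
      tAdmix = as.numeric(tAdmix))
}

#' Build a simulation configuration
#'
#' Defaults describe the emulated study design: 13 taxa (including the
#' outgroup), two populations per taxon, five diploid individuals per
#' population, 500 short loci of 30 bp, a substitution rate giving on the
#' order of 2-5 variable sites per locus across the system, roughly 20\%
#' locus dropout, and desk-scale sequencing coverage.
#'
#' @param tree rooted species tree with branch lengths
#'   (default \code{\link{defaultSpeciesTree}()}).
#' @param popsPerTaxon populations per taxon.
#' @param indsPerPop diploid individuals per population.
#' @param nLoci number of loci.
#' @param locusLength locus length (bp).
#' @param mu substitution rate per site per unit tree depth.
#' @param popTheta within-population per-site polymorphism rate.
#' @param popSplitDepth divergence time of populations within a taxon; must
#'   be smaller than every terminal branch of \code{tree}.
#' @param events list of \code{\link{introgressionEvent}} objects.
#' @param dropout probability an (individual, locus) read stack is lost.
#' @param paralogRate fraction of loci merged pairwise into composite loci.
#' @param coverage mean reads per allele (Poisson).
#' @param baseError per-base sequencing error probability.
#' @param seed integer seed.
#' @return a \linkS4class{SimConfig}.
#' @export
#' @examples
#' cfg <- simConfig(nLoci = 20, indsPerPop = 2, seed = 7)
simConfig <- function(tree = defaultSpeciesTree(), popsPerTaxon = 2L,
                      indsPerPop = 5L, nLoci = 500L, locusLength = 30L,
                      mu = 0.02, popTheta = 0.002, popSplitDepth = 0.02,
                      events = list(), dropout = 0.2, paralogRate = 0,
                      coverage = 5, baseError = 0.001, seed = 1L) {
  if (popsPerTaxon > 1L) {
    term <- tree$edge.length[tree$edge[, 2] <= ape::Ntip(tree)]
    if (any(term <= popSplitDepth))
      stop("popSplitDepth must be smaller than every terminal branch")
  }
  new("SimConfig", tree = tree, popsPerTaxon = as.integer(popsPerTaxon),
      indsPerPop = as.integer(indsPerPop), nLoci = as.integer(nLoci),
      locusLength = as.integer(locusLength), mu = mu, popTheta = popTheta,
      popSplitDepth = popSplitDepth, events = events, dropout = dropout,
      paralogRate = paralogRate, coverage = coverage, baseError = baseError,
      seed = as.integer(seed))
}

# depth (time before present) of every node, assuming the tree is ultrametric
.depthsToPresent <- function(tree) {
  fromRoot <- ape::node.depth.edgelength(tree)
  max(fromRoot) - fromRoot
}

#' Expand a species tree into a population tree
#'
#' Each taxon tip is replaced by \code{popsPerTaxon} population tips named
#' \code{<taxon>.<k>}, diverging from each other at \code{popSplitDepth}.
#'
#' @param tree rooted ultrametric species tree.
#' @param popsPerTaxon populations per taxon.
#' @param popSplitDepth population divergence depth.
#' @return an \code{ape::phylo} tree with taxa expanded into populations.
#' @export
populationTree <- function(tree, popsPerTaxon = 2L, popSplitDepth = 0.02) {
  if (popsPerTaxon == 1L) {
    tree$tip.label <- paste0(tree$tip.label, ".1")
    return(tree)
  }
  labs <- tree$tip.label
  term <- match(seq_along(labs), tree$edge[, 2])
  if (any(tree$edge.length[term] <= popSplitDepth))
    stop("popSplitDepth must be smaller than every terminal branch")
  tr <- tree
  tr$edge.length[term] <- tr$edge.length[term] - popSplitDepth
  tr$tip.label <- sprintf("@@%d@@", seq_along(labs))
  nwk <- ape::write.tree(tr)
  for (i in seq_along(labs)) {
    sub <- paste0("(", paste0(labs[i], ".", seq_len(popsPerTaxon), ":",
                              popSplitDepth, collapse = ","), ")")
    nwk <- sub(sprintf("@@%d@@", i), sub, nwk, fixed = TRUE)
  }
  ape::read.tree(text = nwk)
}

# ---------------------------------------------------------------------------
# locus evolution

# preorder edge table for repeated traversal
.edgeOrder <- function(tree) {
  rev(ape::postorder(tree))
}

# evolve one locus: integer matrix (all nodes x L), returns tips x L
.evolveInt <- function(tree, mu, L, ord = .edgeOrder(tree), rootSeq = NULL) {
  n <- ape::Ntip(tree)
  seqs <- matrix(0L, n + tree$Nnode, L)
  seqs[n + 1L, ] <- if (is.null(rootSeq)) .randSeq(L) else rootSeq
  for (e in ord) {
    par <- tree$edge[e, 1L]; ch <- tree$edge[e, 2L]
    p <- 1 - exp(-mu * tree$edge.length[e])
    seqs[ch, ] <- .mutate(seqs[par, ], p)
  }
  out <- seqs[seq_len(n), , drop = FALSE]
  rownames(out) <- tree$tip.label
  out
}

#' Evolve one locus along a tree
#'
#' Jukes-Cantor evolution: starting from a random (or supplied) root
#' sequence, each site substitutes along a branch of length \eqn{b} with
#' probability \eqn{1 - e^{-\mu b}}, the new base uniform over the other
#' three.
#'
#' @param tree rooted \code{ape::phylo} tree with non-negative branch lengths.
#' @param mu substitution rate per site per unit branch length.
#' @param length number of sites.
#' @param rootSeq optional root sequence (character scalar).
#' @return named character vector of tip haplotypes.
#' @export
#' @examples
#' set.seed(1)
#' evolveLocus(defaultSpeciesTree(), mu = 0.02, length = 30)
evolveLocus <- function(tree, mu, length, rootSeq = NULL) {
  if (is.null(tree) || ape::Ntip(tree) < 1L) stop("empty tree")
  if (any(tree$edge.length < 0)) stop("branch lengths must be >= 0")
  rs <- if (is.null(rootSeq)) NULL else as.vector(.enc(rootSeq))
  .dec(.evolveInt(tree, mu, as.integer(length), rootSeq = rs))
}

# ---------------------------------------------------------------------------
# introgression: re-attach the recipient clade to the donor lineage

# tips belonging to a taxon or population id in a population tree
.unitTips <- function(tree, id) {
  hit <- tree$tip.label == id
  if (!any(hit)) hit <- startsWith(tree$tip.label, paste0(id, "."))
  if (!any(hit)) stop(sprintf("'%s' matches no tip of the tree", id))
  tree$tip.label[hit]
}

# single-tip phylo whose tip hangs 'stem' below its attachment point
.tipTree <- function(label, stem) {
  structure(list(edge = matrix(c(2L, 1L), 1L, 2L), tip.label = label,
                 edge.length = stem, Nnode = 1L),
            class = "phylo", order = "cladewise")
}

# build the genealogy of an introgressed locus
.reattach <- function(tree, recipientTips, donorTips, tAdmix) {
  d <- .depthsToPresent(tree)
  div <- d[ape::getMRCA(tree, c(recipientTips[1], donorTips[1]))]
  if (tAdmix >= div)
    stop(sprintf("tAdmix (%g) must be more recent than the donor/recipient divergence (%g)",
                 tAdmix, div))
  if (length(recipientTips) > 1L) {
    node <- ape::getMRCA(tree, recipientTips)
    desc <- ape::extract.clade(tree, node)
    if (ape::Ntip(desc) != length(recipientTips))
      stop("recipient tips must form a clade")
    if (d[node] >= tAdmix)
      stop("tAdmix must be older than the recipient clade's crown")
    desc$root.edge <- tAdmix - d[node]
    sub <- desc
  } else {
    sub <- .tipTree(recipientTips, tAdmix)
  }
  base <- ape::drop.tip(tree, recipientTips)
  db <- .depthsToPresent(base)
  # walk up the donor lineage to the edge spanning tAdmix
  v <- which(base$tip.label == donorTips[1])
  repeat {
    pe <- which(base$edge[, 2] == v)
    if (!length(pe))
      stop("tAdmix is older than the root of the remaining tree")
    par <- base$edge[pe, 1]
    if (db[par] > tAdmix) break
    v <- par
  }
  out <- ape::bind.tree(base, sub, where = v, position = tAdmix - db[v])
  ape::read.tree(text = ape::write.tree(out))  # renumber cleanly
}

#' Apply an introgression event to simulated loci
#'
#' Each locus is independently affected with probability \code{gamma}; an
#' affected locus is re-simulated on a genealogy in which the recipient
#' lineage is attached to the donor lineage at \code{tAdmix}.
#'
#' @param loci list of per-locus tip haplotype maps (named character vectors,
#'   as returned by \code{\link{evolveLocus}} on \code{tree}).
#' @param tree the (population) tree the loci were simulated on.
#' @param event an \code{\link{introgressionEvent}}.
#' @param mu substitution rate used for the re-simulation.
#' @return list with elements \code{loci} (modified list) and \code{affected}
#'   (logical vector of truth labels).
#' @export
applyIntrogression <- function(loci, tree, event, mu) {
  recTips <- .unitTips(tree, event@recipient)
  donTips <- .unitTips(tree, event@donor)
  mtree <- .reattach(tree, recTips, donTips, event@tAdmix)
  ord <- .edgeOrder(mtree)
  affected <- runif(length(loci)) < event@gamma
  L <- nchar(loci[[1]][1])
  for (j in which(affected))
    loci[[j]] <- .dec(.evolveInt(mtree, mu, L, ord))[names(loci[[j]])]
  list(loci = loci, affected = affected)
}

# ---------------------------------------------------------------------------
# reads

#' Generate reads for one individual
#'
#' For every allele, a Poisson(\code{coverage}) number of full-length reads
#' is produced; each base is flipped independently with probability
#' \code{baseError} to a uniformly chosen other base.
#'
#' @param alleles character vector of allele sequences, named by locus id
#'   (a diploid individual contributes two entries per locus).
#' @param coverage mean reads per allele (> 0).
#' @param baseError per-base error probability in [0, 1).
#' @param individual individual id stored in the result.
#' @return a \linkS4class{GBSReadSet}.
#' @export
generateReads <- function(alleles, coverage, baseError, individual = "ind") {
  stopifnot(coverage > 0, baseError >= 0, baseError < 1)
  nrep <- rpois(length(alleles), coverage)
  reads <- rep(unname(alleles), nrep)
  locus <- rep(names(alleles), nrep)
  if (length(reads) && baseError > 0) {
    L <- nchar(reads[1])
    nerr <- rbinom(length(reads), L, baseError)
    for (i in which(nerr > 0L)) {
      m <- .enc(reads[i])
      reads[i] <- .dec(matrix(.mutateK(as.vector(m), nerr[i]), nrow = 1L))
    }
  }
  new("GBSReadSet", individual = individual, reads = reads,
      locus = if (length(locus)) locus else character(0))
}

#' Apply dropout and paralog merging to simulated read sets
#'
#' Every (individual, locus) read stack is deleted with probability
#' \code{dropout}; a fraction \code{paralogRate} of loci is merged pairwise
#' (reads of the second locus relabeled to the first), producing
#' hypervariable composite loci that mimic multi-copy regions.
#'
#' @param readsets list of \linkS4class{GBSReadSet} with locus tags.
#' @param dropout per-cell dropout probability.
#' @param paralogRate fraction of loci merged pairwise.
#' @param lociIds locus ids of the system (defaults to those seen in reads).
#' @return list with elements \code{readsets}, \code{dropped} (logical loci x
#'   individuals matrix) and \code{merges} (data.frame from, into).
#' @export
corruptReadSets <- function(readsets, dropout, paralogRate,
                            lociIds = sort(unique(unlist(lapply(readsets, slot, "locus"))))) {
  .checkProb(dropout, "dropout"); .checkProb(paralogRate, "paralogRate")
  inds <- vapply(readsets, slot, character(1), "individual")
  dropped <- matrix(runif(length(lociIds) * length(inds)) < dropout,
                    length(lociIds), length(inds),
                    dimnames = list(lociIds, inds))
  nPair <- floor(paralogRate * length(lociIds) / 2)
  merges <- data.frame(from = character(0), into = character(0))
  if (nPair > 0) {
    pick <- sample(lociIds, 2L * nPair)
    merges <- data.frame(from = pick[seq_len(nPair) * 2L],
                         into = pick[seq_len(nPair) * 2L - 1L])
  }
  relabel <- setNames(lociIds, lociIds)
  relabel[merges$from] <- merges$into
  for (i in seq_along(readsets)) {
    rs <- readsets[[i]]
    keep <- !dropped[rs@locus, i]
    rs@reads <- rs@reads[keep]
    rs@locus <- unname(relabel[rs@locus[keep]])
    readsets[[i]] <- rs
  }
  list(readsets = readsets, dropped = dropped, merges = merges)
}

# ---------------------------------------------------------------------------
# orchestrator

#' Simulate a complete GBS system
#'
#' Runs the full generator: population-tree expansion, per-locus Jukes-Cantor
#' evolution, introgression events, diploid allele sampling with
#' within-population polymorphism, locus dropout, paralog merging, and read
#' generation. Fully deterministic given \code{config@seed}.
#'
#' @param config a \linkS4class{SimConfig}.
#' @param reads if \code{FALSE}, skip read generation (truth only); dropout
#'   and paralog corruption are then applied directly to the truth.
#' @return list with elements \code{readsets} (list of
#'   \linkS4class{GBSReadSet}; empty when \code{reads = FALSE}) and
#'   \code{truth} (\linkS4class{SyntheticTruth}).
#' @export
#' @examples
#' sim <- simulateGBS(simConfig(nLoci = 5, indsPerPop = 1, seed = 3),
#'                    reads = FALSE)
#' truthLabels(sim$truth)
simulateGBS <- function(config, reads = TRUE) {
  set.seed(config@seed)
  ptree <- populationTree(config@tree, config@popsPerTaxon, config@popSplitDepth)
  pops <- ptree$tip.label
  taxa <- sub("\\.[0-9]+$", "", pops)
  inds <- unlist(lapply(pops, function(p) sprintf("%s_i%d", p, seq_len(config@indsPerPop))))
  grouping <- data.frame(individual = inds,
                         population = rep(pops, each = config@indsPerPop),
                         taxon = rep(taxa, each = config@indsPerPop),
                         stringsAsFactors = FALSE)
  L <- config@locusLength
  lociIds <- sprintf("L%04d", seq_len(config@nLoci))

  # per-locus genealogy: base tree, or re-attached tree(s) for event-hit loci
  ord0 <- .edgeOrder(ptree)
  hitBy <- matrix(FALSE, config@nLoci, length(config@events))
  for (k in seq_along(config@events))
    hitBy[, k] <- runif(config@nLoci) < config@events[[k]]@gamma
  combos <- unique(hitBy)
  if (!nrow(combos)) combos <- matrix(FALSE, 1L, 0L)
  treeOf <- list()
  for (r in seq_len(nrow(combos))) {
    key <- paste(c("k", combos[r, ]), collapse = "")
    tr <- ptree
    for (k in which(combos[r, ])) {
      ev <- config@events[[k]]
      tr <- .reattach(tr, .unitTips(tr, ev@recipient), .unitTips(tr, ev@donor),
                      ev@tAdmix)
    }
    treeOf[[key]] <- list(tree = tr, ord = .edgeOrder(tr))
  }

  # evolve population haplotypes and draw diploid alleles
  alleles <- vector("list", config@nLoci)
  names(alleles) <- lociIds
  tipIdx <- setNames(seq_along(pops), pops)
  for (j in seq_len(config@nLoci)) {
    key <- paste(c("k", hitBy[j, ]), collapse = "")
    tt <- treeOf[[key]]
    haps <- .evolveInt(tt$tree, config@mu, L, tt$ord)
    M <- haps[rep(grouping$population, each = 2L), , drop = FALSE]
    nExtra <- rpois(nrow(M), config@popTheta * L)
    for (r in which(nExtra > 0L))
      M[r, ] <- .mutateK(M[r, ], nExtra[r])
    am <- matrix(unname(.dec(M)), nrow = 2L, ncol = length(inds),
                 dimnames = list(NULL, inds))
    alleles[[j]] <- am
  }

  labels <- data.frame(locus = lociIds, label = "clean",
                       donor = NA_character_, recipient = NA_character_,
                       mergedInto = NA_character_, stringsAsFactors = FALSE)
  for (k in seq_along(config@events)) {
    ev <- config@events[[k]]
    hit <- hitBy[, k] & labels$label == "clean"
    labels$label[hit] <- "introgressed"
    labels$donor[hit] <- ev@donor
    labels$recipient[hit] <- ev@recipient
  }

  readsets <- list()
  if (reads) {
    for (i in seq_along(inds)) {
      av <- setNames(as.vector(t(vapply(alleles, function(m) m[, i], character(2)))),
                     rep(lociIds, each = 2L))
      readsets[[i]] <- generateReads(av, config@coverage, config@baseError,
                                     individual = inds[i])
    }
    cr <- corruptReadSets(readsets, config@dropout, config@paralogRate, lociIds)
    readsets <- cr$readsets
    dropped <- cr$dropped
    merges <- cr$merges
  } else {
    dropped <- matrix(runif(config@nLoci * length(inds)) < config@dropout,
                      config@nLoci, length(inds),
                      dimnames = list(lociIds, inds))
    nPair <- floor(config@paralogRate * config@nLoci / 2)
    merges <- data.frame(from = character(0), into = character(0))
    if (nPair > 0) {
      pick <- sample(lociIds, 2L * nPair)
      merges <- data.frame(from = pick[seq_len(nPair) * 2L],
                           into = pick[seq_len(nPair) * 2L - 1L])
    }
  }
  if (nrow(merges)) {
    labels$label[labels$locus %in% c(merges$from, merges$into)] <- "paralog"
    labels$mergedInto[match(merges$from, labels$locus)] <- merges$into
  }

  truth <- new("SyntheticTruth", labels = labels, alleles = alleles,
               dropout = dropped, grouping = grouping, config = config)
  list(readsets = readsets, truth = truth)
}

#' Build a LocusMatrix directly from simulation truth
#'
#' Bypasses read generation and assembly: cells hold the true allele
#' sequences, with dropout applied and merged paralog pairs pooled into their
#' composite locus. Useful for validating the filtering and scanning stages
#' in isolation from assembly noise.
#'
#' @param truth a \linkS4class{SyntheticTruth}.
#' @param applyDropout blank cells whose read stack was lost?
#' @return a \linkS4class{LocusMatrix}.
#' @export
truthMatrix <- function(truth, applyDropout = TRUE) {
  lab <- truth@labels
  keep <- lab$locus[is.na(lab$mergedInto)]
  inds <- truth@grouping$individual
  cells <- matrix(vector("list", length(keep) * length(inds)),
                  length(keep), length(inds), dimnames = list(keep, inds))
  mergedFrom <- split(lab$locus[!is.na(lab$mergedInto)],
                      lab$mergedInto[!is.na(lab$mergedInto)])
  for (l in keep) {
    sources <- c(l, mergedFrom[[l]])
    for (i in seq_along(inds)) {
      al <- character(0)
      for (s in sources) {
        if (applyDropout && truth@dropout[s, i]) next
        al <- c(al, truth@alleles[[s]][, i])
      }
      cells[[l, i]] <- unique(al)
    }
  }
  new("LocusMatrix", cells = cells,
      lociLength = setNames(rep(truth@config@locusLength, length(keep)), keep),
      provenance = list(source = "simulation truth",
                        applyDropout = applyDropout))
}

#' Write read sets as FASTQ files
#'
#' One file \code{<individual>.fastq} per read set, constant Sanger quality.
#'
#' @param readsets list of \linkS4class{GBSReadSet}.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
writeReadSets <- function(readsets, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(length(readsets))
  for (i in seq_along(readsets)) {
    rs <- readsets[[i]]
    paths[i] <- file.path(dir, paste0(rs@individual, ".fastq"))
    sr <- Biostrings::DNAStringSet(rs@reads)
    names(sr) <- sprintf("%s_r%06d", rs@individual, seq_along(rs@reads))
    qual <- Biostrings::BStringSet(vapply(nchar(rs@reads), function(n)
      paste(rep("I", n), collapse = ""), character(1)))
    Biostrings::writeXStringSet(sr, paths[i], format = "fastq", qualities = qual)
  }
  invisible(paths)
}

#' Read per-individual FASTQ/FASTA files into read sets
#'
#' @param files paths to FASTQ or FASTA files, one individual per file; the
#'   individual id is the file name without extension.
#' @param format \code{"fastq"} or \code{"fasta"}.
#' @return list of \linkS4class{GBSReadSet} (locus tags are \code{NA}).
#' @export
readReadSets <- function(files, format = c("fastq", "fasta")) {
  format <- match.arg(format)
  lapply(files, function(f) {
    sr <- Biostrings::readDNAStringSet(f, format = format)
    reads <- as.character(sr)
    new("GBSReadSet",
        individual = sub("\\.(fastq|fq|fasta|fa)$", "", basename(f)),
        reads = unname(reads), locus = rep(NA_character_, length(reads)))
  })
}
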