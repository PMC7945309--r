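# Two-step de novo locus construction: (1) cluster the reads of a small set
# of representative individuals into reference loci; (2) assign every
# individual's reads to those loci by best-hit identity search and call
# per-individual alleles. Replaces the clustering pipeline + BLASTn search of
# typical GBS workflows with explicit, testable contracts.

#' Construct a read set
#'
#' @param reads character vector of read sequences.
#' @param individual individual id.
#' @return a \linkS4class{GBSReadSet}.
#' @export
readSet <- function(reads, individual = "ind") {
  new("GBSReadSet", individual = individual, reads = as.character(reads),
      locus = rep(NA_character_, length(reads)))
}

# unique reads of a set with their depths
.uniqueReads <- function(rs) {
  tab <- table(rs@reads)
  list(seq = names(tab), depth = as.integer(tab))
}

#' Pick representative individuals
#'
#' Helper for choosing the representative set run through reference-locus
#' clustering: the individual with the most unique reads in each taxon.
#'
#' @param readsets list of \linkS4class{GBSReadSet}.
#' @param grouping data.frame with columns individual, taxon (see
#'   \code{\link{readGrouping}}).
#' @return character vector of individual ids.
#' @export
pickRepresentatives <- function(readsets, grouping) {
  inds <- vapply(readsets, slot, character(1), "individual")
  nuniq <- vapply(readsets, function(rs) length(unique(rs@reads)), integer(1))
  tax <- grouping$taxon[match(inds, grouping$individual)]
  unlist(lapply(split(seq_along(inds), tax), function(ii) {
    ii <- ii[order(-nuniq[ii], inds[ii])]
    inds[ii[1]]
  }), use.names = FALSE)
}

#' Cluster representative reads into reference loci
#'
#' Unique reads pooled over the representative individuals are single-linkage
#' clustered at identity >= \code{tauId}; clusters with summed read depth
#' below \code{minDepth} are discarded; the consensus is the per-column
#' depth-weighted majority base (ties to the lexicographically smallest
#' base).
#'
#' @param representatives list of \linkS4class{GBSReadSet}; all reads must
#'   share one length (apply a trim policy first).
#' @param tauId identity threshold in (0, 1].
#' @param minDepth minimum summed depth for a cluster to become a locus.
#' @return a \linkS4class{ReferenceLoci}.
#' @export
buildReferenceLoci <- function(representatives, tauId = 0.90, minDepth = 3L) {
  if (!length(representatives)) stop("need at least one representative read set")
  if (tauId <= 0 || tauId > 1) stop("tauId must be in (0, 1]")
  seqs <- unlist(lapply(representatives, slot, "reads"))
  if (!length(seqs)) stop("representatives contain no reads")
  if (length(unique(nchar(seqs))) != 1L)
    stop("mixed read lengths: apply a pad/trim policy before clustering")
  tab <- table(seqs)
  uniq <- names(tab); depth <- as.integer(tab)
  M <- .enc(uniq)
  sim <- .identity(M, M)
  comp <- .components(sim >= tauId)
  keepIds <- which(vapply(split(depth, comp), sum, numeric(1)) >= minDepth)
  consensus <- character(0); members <- list(); depths <- numeric(0)
  k <- 0L
  for (cid in sort(as.integer(names(keepIds)))) {
    sel <- comp == cid
    k <- k + 1L
    consensus[k] <- .dec(matrix(.consensus(M[sel, , drop = FALSE], depth[sel]), 1L))
    members[[k]] <- uniq[sel]
    depths[k] <- sum(depth[sel])
  }
  ids <- sprintf("ref%04d", seq_len(k))
  new("ReferenceLoci", consensus = setNames(consensus, ids),
      members = setNames(members, ids), depths = setNames(depths, ids),
      parameters = list(tauId = tauId, minDepth = minDepth,
                        nRepresentatives = length(representatives)))
}

#' Assign one individual's reads to reference loci and call alleles
#'
#' Each unique read goes to the reference locus of maximal consensus identity
#' if that identity is >= \code{tauAssign} and exceeds the second-best hit by
#' at least \code{margin}. Within a locus, unique sequences with read depth
#' >= \code{minDepth} become allele candidates; shallower sequences are
#' error-corrected into (absorbed by) the closest candidate when within
#' \code{tauAssign} identity, otherwise dropped. At most \code{aMax} deepest
#' alleles are kept (ties broken by sequence order).
#'
#' @param readset a \linkS4class{GBSReadSet}.
#' @param reference a \linkS4class{ReferenceLoci}.
#' @param tauAssign identity threshold for assignment.
#' @param margin required identity gap between best and second-best hit.
#' @param minDepth minimum read depth for an allele candidate.
#' @param aMax maximum alleles kept per locus.
#' @return list with \code{alleles} (named list locus -> character vector of
#'   allele sequences) and \code{unassigned} (count of unique reads without a
#'   qualifying hit).
#' @export
assignToLoci <- function(readset, reference, tauAssign = 0.90, margin = 0.02,
                         minDepth = 3L, aMax = 4L) {
  if (!length(reference@consensus)) stop("reference is empty")
  u <- .uniqueReads(readset)
  if (!length(u$seq))
    return(list(alleles = setNames(list(), character(0)), unassigned = 0L))
  R <- .enc(u$seq)
  C <- .enc(unname(reference@consensus))
  sim <- .identity(R, C)
  best <- max.col(sim, ties.method = "first")
  bestId <- sim[cbind(seq_len(nrow(sim)), best)]
  second <- if (ncol(sim) > 1L)
    apply(sim, 1L, function(r) max(r[-which.max(r)])) else rep(0, nrow(sim))
  ok <- bestId >= tauAssign & (bestId - second) >= margin
  unassigned <- sum(!ok)
  alleles <- list()
  for (li in sort(unique(best[ok]))) {
    sel <- which(ok & best == li)
    sq <- u$seq[sel]; dp <- u$depth[sel]
    cand <- dp >= minDepth
    if (!any(cand)) next
    if (any(!cand)) {
      Mc <- .enc(sq[cand]); Ml <- .enc(sq[!cand])
      s2 <- .identity(Ml, Mc)
      nb <- max.col(s2, ties.method = "first")
      absorb <- s2[cbind(seq_len(nrow(s2)), nb)] >= tauAssign
      add <- vapply(seq_len(sum(cand)), function(k)
        sum(dp[!cand][absorb & nb == k]), numeric(1))
      dp <- dp[cand] + add
      sq <- sq[cand]
    } else {
      dp <- dp[cand]; sq <- sq[cand]
    }
    o <- order(-dp, sq)
    keep <- o[seq_len(min(aMax, length(o)))]
    alleles[[names(reference@consensus)[li]]] <- sq[sort(keep)]
  }
  list(alleles = alleles, unassigned = unassigned)
}

#' Compile per-individual genotypes into a locus matrix
#'
#' @param genotypes named list (individual -> result of
#'   \code{\link{assignToLoci}} or its \code{alleles} element).
#' @param reference a \linkS4class{ReferenceLoci} defining the locus set.
#' @param provenance optional list of assembly parameters to record.
#' @return a \linkS4class{LocusMatrix} over (reference loci x individuals);
#'   cells without assigned reads are missing.
#' @export
compileLocusMatrix <- function(genotypes, reference, provenance = list()) {
  loci <- names(reference@consensus)
  inds <- names(genotypes)
  if (is.null(inds)) stop("genotypes must be a named list (individual ids)")
  cells <- matrix(vector("list", length(loci) * length(inds)),
                  length(loci), length(inds), dimnames = list(loci, inds))
  for (i in seq_along(inds)) {
    g <- genotypes[[i]]
    if (is.list(g) && !is.null(g$alleles)) g <- g$alleles
    for (l in names(g)) {
      n <- nchar(g[[l]])
      if (any(n != nchar(reference@consensus[[l]])))
        stop(sprintf("locus '%s', individual '%s': allele length conflicts with the locus alignment",
                     l, inds[i]))
      cells[[l, i]] <- g[[l]]
    }
  }
  new("LocusMatrix", cells = cells,
      lociLength = setNames(nchar(unname(reference@consensus)), loci),
      provenance = c(list(reference = reference@parameters), provenance))
}

#' Run the full two-step assembly
#'
#' Convenience wrapper: build reference loci from the representative read
#' sets, assign every read set, and compile the locus matrix.
#'
#' @param readsets list of \linkS4class{GBSReadSet} (all individuals).
#' @param representatives individual ids to cluster into reference loci
#'   (default: all).
#' @param tauId,minDepth see \code{\link{buildReferenceLoci}}.
#' @param tauAssign,margin,aMax see \code{\link{assignToLoci}}.
#' @return list with elements \code{reference} (\linkS4class{ReferenceLoci})
#'   and \code{matrix} (\linkS4class{LocusMatrix}).
#' @export
assembleLoci <- function(readsets,
                         representatives = vapply(readsets, slot, character(1), "individual"),
                         tauId = 0.90, tauAssign = 0.90, margin = 0.02,
                         minDepth = 3L, aMax = 4L) {
  inds <- vapply(readsets, slot, character(1), "individual")
  reps <- readsets[inds %in% representatives]
  if (!length(reps)) stop("no read set matches the representative ids")
  ref <- buildReferenceLoci(reps, tauId = tauId, minDepth = minDepth)
  genos <- lapply(readsets, assignToLoci, reference = ref,
                  tauAssign = tauAssign, margin = margin,
                  minDepth = minDepth, aMax = aMax)
  names(genos) <- inds
  mat <- compileLocusMatrix(genos, ref,
                            provenance = list(tauAssign = tauAssign,
                                              margin = margin, aMax = aMax))
  list(reference = ref, matrix = mat)
}
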