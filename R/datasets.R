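# Filtering rules and construction of the Individual / Population / Taxon
# working datasets, plus SNP and concatenated-sequence representations and
# locus-level bootstrap replicates.

#' Proportion of variable columns in a locus alignment
#'
#' Variability of a locus is the fraction of alignment columns with at least
#' two distinct non-missing states. The proportion (rather than a raw SNP
#' count) makes the hypervariability rule invariant to locus length.
#'
#' @param alignment character vector of equal-length sequences.
#' @return a proportion in [0, 1].
#' @export
#' @examples
#' locusVariability(c("ACGT", "ACGA"))  # 0.25
locusVariability <- function(alignment) {
  if (!length(alignment) || any(nchar(alignment) == 0))
    stop("empty alignment")
  m <- .enc(alignment)
  v <- vapply(seq_len(ncol(m)), function(k) {
    s <- unique(m[, k]); length(s[s > 0L]) >= 2L
  }, logical(1))
  mean(v)
}

# variability per locus of a cells matrix (0 for loci with no sequences)
.variabilities <- function(cells) {
  vapply(seq_len(nrow(cells)), function(i) {
    al <- unlist(cells[i, ])
    if (!length(al)) 0 else locusVariability(al)
  }, numeric(1))
}

#' Remove hypervariable loci
#'
#' Loci whose variability exceeds mean(v) + \code{varK} * IQR(v) are removed;
#' such loci typically represent reads from multiple genomic locations
#' (merged paralogs) collapsed into one cluster.
#'
#' @param x a \linkS4class{LocusMatrix} or \linkS4class{LocusDataset}.
#' @param varK IQR multiplier (default 3).
#' @return the object with offending loci removed.
#' @export
filterHypervariable <- function(x, varK = 3) {
  if (varK < 0) stop("varK must be >= 0")
  if (!nrow(x@cells)) stop("need at least one locus")
  v <- .variabilities(x@cells)
  thr <- mean(v) + varK * IQR(v)
  keep <- v <= thr
  x@cells <- x@cells[keep, , drop = FALSE]
  x@lociLength <- x@lociLength[keep]
  x
}

#' Remove underrepresented individuals, then sparse loci
#'
#' One pass, in order: (1) drop individuals present at fewer than
#' \code{thetaInd} of the current loci; (2) drop loci present in fewer than
#' \code{thetaLoc} of the remaining individuals. Inequalities are strict
#' ("fewer than"): an individual at exactly \code{thetaInd} and a locus at
#' exactly \code{thetaLoc} are kept.
#'
#' @param x a \linkS4class{LocusMatrix}.
#' @param thetaInd minimum per-individual locus fraction (default 0.10).
#' @param thetaLoc minimum per-locus individual fraction (default 0.70).
#' @return the filtered \linkS4class{LocusMatrix}.
#' @export
filterMissingness <- function(x, thetaInd = 0.10, thetaLoc = 0.70) {
  .checkProb(thetaInd, "thetaInd"); .checkProb(thetaLoc, "thetaLoc")
  if (!nrow(x@cells) || !ncol(x@cells)) stop("need >= 1 locus and >= 1 individual")
  pres <- .presence(x@cells)
  keepInd <- colMeans(pres) >= thetaInd
  if (!any(keepInd))
    stop(sprintf("all %d individuals fall below thetaInd = %g (max presence %.3f)",
                 ncol(pres), thetaInd, max(colMeans(pres))))
  pres <- pres[, keepInd, drop = FALSE]
  keepLoc <- rowMeans(pres) >= thetaLoc
  if (!any(keepLoc))
    stop(sprintf("all %d loci fall below thetaLoc = %g (max presence %.3f)",
                 nrow(pres), thetaLoc, max(rowMeans(pres))))
  x@cells <- x@cells[keepLoc, keepInd, drop = FALSE]
  x@lociLength <- x@lociLength[keepLoc]
  x
}

#' Select the best unit among candidate members
#'
#' "Best" = most retained loci; ties broken by most total reads (when read
#' counts are supplied), then by the lexicographically smallest id.
#'
#' @param x a \linkS4class{LocusMatrix}.
#' @param members candidate individual ids (columns of \code{x}).
#' @param reads optional named numeric vector of total read counts.
#' @return a single member id.
#' @export
selectBestUnit <- function(x, members, reads = NULL) {
  members <- intersect(members, colnames(x@cells))
  if (!length(members)) stop("no member is present in the matrix")
  nloc <- colSums(.presence(x@cells)[, members, drop = FALSE])
  nr <- if (is.null(reads)) rep(0, length(members)) else
    ifelse(is.na(reads[members]), 0, reads[members])
  members[order(-nloc, -nr, members)][1]
}

#' Read an individual -> population -> taxon grouping table
#'
#' @param path TSV file with columns individual, population, taxon.
#' @return data.frame with those three character columns.
#' @export
readGrouping <- function(path) {
  g <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("individual", "population", "taxon")
  if (!all(need %in% names(g)))
    stop("grouping table needs columns: ", paste(need, collapse = ", "))
  g[need]
}

#' Packaged example grouping: a 13-taxon alpine plant study design
#'
#' The sampling design of a published GBS study of an alpine *Cherleria*
#' clade: 62 populations across 13 taxa (one taxon, Albanian *C.
#' capillacea*, is a single population treated as its own taxon; the two
#' subspecies of *C. laricifolia* are separate taxa; *C. rupestris* is the
#' outgroup), with up to five individuals per population.
#'
#' @return data.frame with columns individual, population, taxon.
#' @export
cherleriaGrouping <- function() {
  readGrouping(system.file("extdata", "cherleria_grouping.tsv",
                           package = "gbsfoil", mustWork = TRUE))
}

#' Build a level-specific working dataset
#'
#' Applies the hypervariability filter and then the missingness filters to
#' the (optionally taxon-subset) matrix, then selects units by level:
#' \describe{
#'   \item{individual}{all retained individuals.}
#'   \item{population}{the best individual of each population.}
#'   \item{taxon}{a composite unit per taxon: the taxon's best individual,
#'     with loci it lacks filled in from members of the same population that
#'     have them.}
#' }
#' After unit selection the per-locus presence rule is re-applied so that
#' every retained locus is present in at least \code{thetaLoc} of units.
#'
#' @param x a \linkS4class{LocusMatrix}.
#' @param level \code{"individual"}, \code{"population"} or \code{"taxon"}.
#' @param grouping data.frame (individual, population, taxon) covering all
#'   individuals of \code{x}.
#' @param varK,thetaInd,thetaLoc filter thresholds.
#' @param reads optional named total-read counts for best-unit tie-breaks.
#' @param taxa optional subset of taxa to restrict the working dataset to.
#' @return a \linkS4class{LocusDataset}.
#' @export
buildDataset <- function(x, level = c("individual", "population", "taxon"),
                         grouping, varK = 3, thetaInd = 0.10, thetaLoc = 0.70,
                         reads = NULL, taxa = NULL) {
  level <- match.arg(level)
  unknown <- setdiff(colnames(x@cells), grouping$individual)
  if (length(unknown))
    stop("individuals missing from grouping: ", paste(unknown, collapse = ", "))
  if (!is.null(taxa)) {
    keep <- grouping$individual[grouping$taxon %in% taxa]
    x@cells <- x@cells[, colnames(x@cells) %in% keep, drop = FALSE]
  }
  x <- filterHypervariable(x, varK)
  x <- filterMissingness(x, thetaInd, thetaLoc)
  g <- grouping[match(colnames(x@cells), grouping$individual), ]

  if (level == "individual") {
    cells <- x@cells
  } else if (level == "population") {
    popIds <- sort(unique(g$population))
    cols <- vapply(popIds, function(p)
      selectBestUnit(x, g$individual[g$population == p], reads), character(1))
    cells <- x@cells[, cols, drop = FALSE]
    colnames(cells) <- popIds
  } else {
    taxIds <- sort(unique(g$taxon))
    cells <- matrix(vector("list", nrow(x@cells) * length(taxIds)),
                    nrow(x@cells), length(taxIds),
                    dimnames = list(rownames(x@cells), taxIds))
    pres <- .presence(x@cells)
    for (tx in taxIds) {
      best <- selectBestUnit(x, g$individual[g$taxon == tx], reads)
      mates <- g$individual[g$population == g$population[g$individual == best]]
      mates <- setdiff(mates, best)
      if (length(mates) > 1L)  # deterministic fill-in order: best mates first
        mates <- mates[order(-colSums(pres[, mates, drop = FALSE]), mates)]
      for (l in rownames(cells)) {
        al <- x@cells[[l, best]]
        if (!length(al))
          for (m in mates) {
            if (length(x@cells[[l, m]])) { al <- x@cells[[l, m]]; break }
          }
        cells[[l, tx]] <- al
      }
    }
  }
  pres <- .presence(cells)
  keepLoc <- rowMeans(pres) >= thetaLoc
  cells <- cells[keepLoc, , drop = FALSE]
  new("LocusDataset", level = level, cells = cells,
      lociLength = x@lociLength[keepLoc], grouping = grouping,
      thresholds = list(varK = varK, thetaInd = thetaInd, thetaLoc = thetaLoc))
}

# choose one allele per (unit, locus) uniformly at random; NA when missing
.chooseAlleles <- function(cells) {
  out <- matrix(NA_character_, nrow(cells), ncol(cells),
                dimnames = dimnames(cells))
  for (i in seq_len(nrow(cells)))
    for (j in seq_len(ncol(cells))) {
      al <- cells[[i, j]]
      if (length(al))
        out[i, j] <- if (length(al) == 1L) al else al[sample.int(length(al), 1L)]
    }
  out
}

#' Concatenate a dataset into a supermatrix
#'
#' One allele per unit per locus is chosen uniformly at random (sequence
#' datasets use a single haplotype per unit); missing loci are filled with
#' \code{N}. Deterministic under \code{seed}.
#'
#' @param dataset a \linkS4class{LocusDataset}.
#' @param seed optional integer seed.
#' @return a \linkS4class{Supermatrix}.
#' @export
toSupermatrix <- function(dataset, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  chosen <- .chooseAlleles(dataset@cells)
  lens <- dataset@lociLength
  ends <- cumsum(lens)
  parts <- data.frame(locus = names(lens),
                      start = as.integer(ends - lens + 1L),
                      end = as.integer(ends), stringsAsFactors = FALSE)
  fill <- vapply(lens, function(n) paste(rep("N", n), collapse = ""), character(1))
  seqs <- vapply(seq_len(ncol(chosen)), function(j) {
    s <- chosen[, j]
    s[is.na(s)] <- fill[is.na(s)]
    paste(s, collapse = "")
  }, character(1))
  new("Supermatrix", sequences = setNames(seqs, colnames(chosen)),
      partitions = parts)
}

#' Reduce a dataset to a biallelic 0/1 SNP matrix
#'
#' One allele per unit per locus is chosen at random, variable columns are
#' extracted, and columns with more than two states are reduced to two states
#' chosen uniformly at random (other states become missing). Genotypes are
#' coded 0/1 with 0 the state of the first retained (non-missing) unit.
#'
#' @param dataset a \linkS4class{LocusDataset}.
#' @param seed optional integer seed.
#' @return a \linkS4class{SNPMatrix}.
#' @export
toSNPMatrix <- function(dataset, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  chosen <- .chooseAlleles(dataset@cells)
  units <- colnames(chosen)
  genoCols <- list(); mapRows <- list()
  for (i in seq_len(nrow(chosen))) {
    s <- chosen[i, ]
    L <- dataset@lociLength[i]
    m <- matrix(0L, length(units), L)
    ok <- !is.na(s)
    if (sum(ok) < 2L) next
    m[ok, ] <- .enc(s[ok])
    for (k in seq_len(L)) {
      col <- m[, k]
      states <- sort(unique(col[col > 0L]))
      if (length(states) < 2L) next
      if (length(states) > 2L) states <- sort(sample(states, 2L))
      g <- rep(NA_integer_, length(units))
      inSt <- col %in% states
      firstUnit <- which(inSt)[1]
      g[inSt] <- as.integer(col[inSt] != col[firstUnit])
      genoCols[[length(genoCols) + 1L]] <- g
      mapRows[[length(mapRows) + 1L]] <-
        data.frame(locus = rownames(chosen)[i], column = k)
    }
  }
  geno <- if (length(genoCols))
    matrix(unlist(genoCols), nrow = length(units),
           dimnames = list(units, NULL)) else
    matrix(integer(0), length(units), 0, dimnames = list(units, NULL))
  map <- if (length(mapRows)) do.call(rbind, mapRows) else
    data.frame(locus = character(0), column = integer(0))
  map$site <- seq_len(nrow(map))
  new("SNPMatrix", genotypes = geno, siteMap = map[c("site", "locus", "column")])
}

#' Locus-level bootstrap replicates
#'
#' Bootstrap replicates resample loci (not sites) with replacement, each
#' replicate keeping the original locus count; concatenation and partitions
#' are rebuilt downstream by \code{\link{toSupermatrix}}.
#'
#' @param dataset a \linkS4class{LocusDataset}.
#' @param B number of replicates (>= 0).
#' @param seed optional integer seed.
#' @return list of \code{B} \linkS4class{LocusDataset} objects.
#' @export
bootstrapLoci <- function(dataset, B, seed = NULL) {
  if (B < 0) stop("B must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(dataset@cells)
  lapply(seq_len(B), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    d <- dataset
    d@cells <- d@cells[idx, , drop = FALSE]
    d@lociLength <- d@lociLength[idx]
    ids <- sprintf("%s.b%03d", rownames(dataset@cells)[idx], seq_len(n))
    rownames(d@cells) <- ids
    names(d@lociLength) <- ids
    d
  })
}
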