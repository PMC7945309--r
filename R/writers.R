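# Writers for downstream phylogenetic and population-genetic software:
# relaxed PHYLIP / FASTA supermatrices with RAxML-style partition files,
# NEXUS (SVDQuartets-ready), SNP tables, STRUCTURE-like two-row genotype
# files, and the fineRADstructure tag-haplotype matrix.

#' Write a supermatrix in relaxed PHYLIP format
#' @param x a \linkS4class{Supermatrix}.
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
writePhylip <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf(" %d %d", length(x@sequences), nchar(x@sequences[1])), con)
  writeLines(sprintf("%s  %s", names(x@sequences), unname(x@sequences)), con)
  invisible(path)
}

#' Write a supermatrix (or any named sequences) as FASTA
#' @param x a \linkS4class{Supermatrix} or named character vector.
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
writeFastaAlignment <- function(x, path) {
  seqs <- if (is(x, "Supermatrix")) x@sequences else x
  dss <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(dss, path)
  invisible(path)
}

#' Write a RAxML-style partition file
#' @param x a \linkS4class{Supermatrix}.
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
writePartitions <- function(x, path) {
  p <- x@partitions
  writeLines(sprintf("DNA, %s = %d-%d", p$locus, p$start, p$end), path)
  invisible(path)
}

#' Write a supermatrix as a NEXUS data file
#'
#' Taxa and characters blocks with datatype DNA and missing state N, ready
#' for quartet-based species-tree software.
#'
#' @param x a \linkS4class{Supermatrix}.
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
writeNexus <- function(x, path) {
  n <- length(x@sequences); L <- nchar(x@sequences[1])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("#NEXUS", "", "BEGIN TAXA;",
               sprintf("  DIMENSIONS NTAX=%d;", n), "  TAXLABELS",
               sprintf("    %s", names(x@sequences)), "  ;", "END;", "",
               "BEGIN CHARACTERS;", sprintf("  DIMENSIONS NCHAR=%d;", L),
               "  FORMAT DATATYPE=DNA MISSING=N GAP=-;", "  MATRIX"), con)
  writeLines(sprintf("    %s  %s", names(x@sequences), unname(x@sequences)), con)
  writeLines(c("  ;", "END;"), con)
  invisible(path)
}

#' Write a SNP matrix as TSV
#' @param x a \linkS4class{SNPMatrix}.
#' @param path output file (sites as columns named locus.column).
#' @return invisibly, \code{path}.
#' @export
writeSNPTable <- function(x, path) {
  g <- x@genotypes
  colnames(g) <- sprintf("%s.%d", x@siteMap$locus, x@siteMap$column)
  df <- data.frame(unit = rownames(g), g, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a STRUCTURE-like two-row genotype file
#'
#' Two rows per unit (up to two alleles per locus site); bases coded 1-4,
#' missing -9. Sites are the columns of the dataset's SNP reduction applied
#' to each allele independently, so heterozygous sites are preserved.
#'
#' @param dataset a \linkS4class{LocusDataset}.
#' @param path output file.
#' @param seed optional seed (site reduction draws random states).
#' @return invisibly, \code{path}.
#' @export
writeStructure <- function(dataset, path, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  units <- colnames(dataset@cells)
  rows <- matrix(list(), 2L, length(units))
  for (j in seq_along(units))
    for (a in 1:2) {
      al <- vapply(seq_len(nrow(dataset@cells)), function(i) {
        x <- dataset@cells[[i, j]]
        if (!length(x)) NA_character_ else x[min(a, length(x))]
      }, character(1))
      rows[[a, j]] <- al
    }
  # variable columns across all alleles
  lens <- dataset@lociLength
  out <- NULL
  for (i in seq_len(nrow(dataset@cells))) {
    m <- matrix(0L, 2L * length(units), lens[i])
    for (j in seq_along(units))
      for (a in 1:2) {
        s <- rows[[a, j]][i]
        if (!is.na(s)) m[(j - 1L) * 2L + a, ] <- as.vector(.enc(s))
      }
    keep <- vapply(seq_len(ncol(m)), function(k) {
      s <- unique(m[, k]); length(s[s > 0L]) >= 2L
    }, logical(1))
    out <- cbind(out, m[, keep, drop = FALSE])
  }
  out[out == 0L] <- -9L
  con <- file(path, "w")
  on.exit(close(con))
  for (j in seq_along(units))
    for (a in 1:2)
      writeLines(paste(c(units[j], out[(j - 1L) * 2L + a, ]), collapse = "\t"), con)
  invisible(path)
}

#' Write a fineRADstructure tag-haplotype matrix
#'
#' One column per locus, one row per unit, comma-separated haplotypes in a
#' cell (empty when missing) -- the input format used by RADpainter for
#' unmapped RAD/GBS data.
#'
#' @param dataset a \linkS4class{LocusDataset}.
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
writeHaplotypeMatrix <- function(dataset, path) {
  units <- colnames(dataset@cells)
  loci <- rownames(dataset@cells)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("", loci), collapse = "\t"), con)
  for (j in seq_along(units)) {
    cells <- vapply(seq_along(loci), function(i)
      paste(dataset@cells[[i, j]], collapse = ","), character(1))
    writeLines(paste(c(units[j], cells), collapse = "\t"), con)
  }
  invisible(path)
}

#' Write reference locus consensus sequences as FASTA
#' @param reference a \linkS4class{ReferenceLoci}.
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
writeReferenceLoci <- function(reference, path) {
  writeFastaAlignment(reference@consensus, path)
}

#' Write per-locus alignments as FASTA files
#'
#' One file per locus containing every unit's alleles (allele index appended
#' to the unit id).
#'
#' @param x a \linkS4class{LocusMatrix} or \linkS4class{LocusDataset}.
#' @param dir output directory.
#' @return invisibly, the paths written.
#' @export
writeLocusAlignments <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  loci <- rownames(x@cells)
  paths <- character(length(loci))
  for (i in seq_along(loci)) {
    seqs <- character(0)
    for (j in seq_len(ncol(x@cells))) {
      al <- x@cells[[i, j]]
      if (length(al))
        seqs <- c(seqs, setNames(al, sprintf("%s_a%d", colnames(x@cells)[j],
                                             seq_along(al))))
    }
    paths[i] <- file.path(dir, paste0(loci[i], ".fasta"))
    writeFastaAlignment(seqs, paths[i])
  }
  invisible(paths)
}

#' Write the presence/allele-count matrix as TSV
#' @param x a \linkS4class{LocusMatrix} or \linkS4class{LocusDataset}.
#' @param path output file (cells hold allele counts; 0 = missing).
#' @return invisibly, \code{path}.
#' @export
writePresenceTable <- function(x, path) {
  cnt <- matrix(lengths(x@cells), nrow(x@cells), dimnames = dimnames(x@cells))
  df <- data.frame(locus = rownames(cnt), cnt, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write simulation truth as TSV
#' @param truth a \linkS4class{SyntheticTruth}.
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
writeTruth <- function(truth, path) {
  write.table(truth@labels, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write scan outputs
#'
#' Writes the per-test table, the pair summary, the per-unit report and a
#' short plain-text summary into a directory.
#'
#' @param table scan table from \code{\link{runScan}}.
#' @param aggregated result of \code{\link{aggregateScan}}.
#' @param dir output directory.
#' @return invisibly, the directory.
#' @export
writeScanOutputs <- function(table, aggregated, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.table(table, file.path(dir, "scan_tests.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(aggregated$pairs, file.path(dir, "pair_summary.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(aggregated$units, file.path(dir, "unit_summary.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  fl <- aggregated$pairs[aggregated$pairs$flagProportion, , drop = FALSE]
  txt <- c(sprintf("tests: %d", nrow(table)),
           sprintf("tests with any significant statistic: %d (%.2f%%)",
                   sum(table$anySig), 100 * mean(table$anySig)),
           sprintf("flagged pairs (proportion >= threshold): %d", nrow(fl)),
           sprintf("  %s: %d/%d (%.1f%%)", fl$pair, fl$nEvents, fl$nTests,
                   100 * fl$proportion))
  writeLines(txt, file.path(dir, "summary.txt"))
  invisible(dir)
}
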