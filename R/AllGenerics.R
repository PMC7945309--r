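#' @name gbsfoil-accessors
#' @title Accessors for gbsfoil containers
#'
#' @description Small accessor generics shared by the containers:
#' \code{lociNames} / \code{nLoci} for the locus dimension, \code{unitNames}
#' / \code{nUnits} for the individual (or population / taxon) dimension,
#' \code{alleleSets} for the cell contents, \code{presenceMatrix} for the
#' logical presence map and \code{missingFraction} for its complement's mean.
#'
#' @param x a \linkS4class{LocusMatrix}, \linkS4class{LocusDataset},
#'   \linkS4class{ReferenceLoci} or \linkS4class{SyntheticTruth}.
#' @return \code{lociNames}, \code{unitNames}: character vectors;
#'   \code{nLoci}, \code{nUnits}: integers; \code{alleleSets}: a list-matrix
#'   of character vectors; \code{presenceMatrix}: a logical matrix;
#'   \code{missingFraction}: a number in [0, 1].
NULL

#' @rdname gbsfoil-accessors
#' @export
setGeneric("lociNames", function(x) standardGeneric("lociNames"))
#' @rdname gbsfoil-accessors
#' @export
setGeneric("nLoci", function(x) standardGeneric("nLoci"))
#' @rdname gbsfoil-accessors
#' @export
setGeneric("unitNames", function(x) standardGeneric("unitNames"))
#' @rdname gbsfoil-accessors
#' @export
setGeneric("nUnits", function(x) standardGeneric("nUnits"))
#' @rdname gbsfoil-accessors
#' @export
setGeneric("alleleSets", function(x) standardGeneric("alleleSets"))
#' @rdname gbsfoil-accessors
#' @export
setGeneric("presenceMatrix", function(x) standardGeneric("presenceMatrix"))
#' @rdname gbsfoil-accessors
#' @export
setGeneric("missingFraction", function(x) standardGeneric("missingFraction"))

#' @rdname gbsfoil-accessors
#' @export
setMethod("lociNames", "LocusMatrix", function(x) rownames(x@cells))
#' @rdname gbsfoil-accessors
#' @export
setMethod("lociNames", "LocusDataset", function(x) rownames(x@cells))
#' @rdname gbsfoil-accessors
#' @export
setMethod("lociNames", "ReferenceLoci", function(x) names(x@consensus))
#' @rdname gbsfoil-accessors
#' @export
setMethod("lociNames", "SyntheticTruth", function(x) x@labels$locus)

#' @rdname gbsfoil-accessors
#' @export
setMethod("nLoci", "LocusMatrix", function(x) nrow(x@cells))
#' @rdname gbsfoil-accessors
#' @export
setMethod("nLoci", "LocusDataset", function(x) nrow(x@cells))
#' @rdname gbsfoil-accessors
#' @export
setMethod("nLoci", "ReferenceLoci", function(x) length(x@consensus))

#' @rdname gbsfoil-accessors
#' @export
setMethod("unitNames", "LocusMatrix", function(x) colnames(x@cells))
#' @rdname gbsfoil-accessors
#' @export
setMethod("unitNames", "LocusDataset", function(x) colnames(x@cells))

#' @rdname gbsfoil-accessors
#' @export
setMethod("nUnits", "LocusMatrix", function(x) ncol(x@cells))
#' @rdname gbsfoil-accessors
#' @export
setMethod("nUnits", "LocusDataset", function(x) ncol(x@cells))

#' @rdname gbsfoil-accessors
#' @export
setMethod("alleleSets", "LocusMatrix", function(x) x@cells)
#' @rdname gbsfoil-accessors
#' @export
setMethod("alleleSets", "LocusDataset", function(x) x@cells)

.presence <- function(cells)
  matrix(lengths(cells) > 0, nrow(cells), ncol(cells), dimnames = dimnames(cells))

#' @rdname gbsfoil-accessors
#' @export
setMethod("presenceMatrix", "LocusMatrix", function(x) .presence(x@cells))
#' @rdname gbsfoil-accessors
#' @export
setMethod("presenceMatrix", "LocusDataset", function(x) .presence(x@cells))

#' @rdname gbsfoil-accessors
#' @export
setMethod("missingFraction", "LocusMatrix", function(x) 1 - mean(.presence(x@cells)))
#' @rdname gbsfoil-accessors
#' @export
setMethod("missingFraction", "LocusDataset", function(x) 1 - mean(.presence(x@cells)))

#' Consensus sequences of reference loci
#' @param x a \linkS4class{ReferenceLoci}.
#' @return named character vector of consensus sequences.
#' @export
setGeneric("consensusSeqs", function(x) standardGeneric("consensusSeqs"))
#' @rdname consensusSeqs
#' @export
setMethod("consensusSeqs", "ReferenceLoci", function(x) x@consensus)

#' Per-locus truth labels of a simulated system
#' @param x a \linkS4class{SyntheticTruth}.
#' @return data.frame with columns locus, label, donor, recipient, mergedInto.
#' @export
setGeneric("truthLabels", function(x) standardGeneric("truthLabels"))
#' @rdname truthLabels
#' @export
setMethod("truthLabels", "SyntheticTruth", function(x) x@labels)

setMethod("show", "LocusMatrix", function(object) {
  cat(sprintf("LocusMatrix: %d loci x %d individuals (%.1f%% missing)\n",
              nrow(object@cells), ncol(object@cells),
              100 * (1 - mean(.presence(object@cells)))))
})

setMethod("show", "LocusDataset", function(object) {
  cat(sprintf("LocusDataset (%s level): %d loci x %d units (%.1f%% missing)\n",
              object@level, nrow(object@cells), ncol(object@cells),
              100 * (1 - mean(.presence(object@cells)))))
})

setMethod("show", "ReferenceLoci", function(object) {
  cat(sprintf("ReferenceLoci: %d loci (mean depth %.1f)\n",
              length(object@consensus),
              if (length(object@depths)) mean(object@depths) else NA_real_))
})

setMethod("show", "SimConfig", function(object) {
  cat(sprintf(paste0("SimConfig: %d taxa x %d pops x %d inds, %d loci x %d bp\n",
                     "  mu=%g theta=%g dropout=%g paralog=%g coverage=%g ",
                     "error=%g events=%d seed=%d\n"),
              ape::Ntip(object@tree), object@popsPerTaxon, object@indsPerPop,
              object@nLoci, object@locusLength, object@mu, object@popTheta,
              object@dropout, object@paralogRate, object@coverage,
              object@baseError, length(object@events), object@seed))
})

setMethod("show", "SyntheticTruth", function(object) {
  tab <- table(object@labels$label)
  cat("SyntheticTruth:", nrow(object@labels), "loci (",
      paste(names(tab), as.integer(tab), collapse = ", "), ")\n")
})

setMethod("show", "GBSReadSet", function(object) {
  cat(sprintf("GBSReadSet '%s': %d reads (%d unique)\n", object@individual,
              length(object@reads), length(unique(object@reads))))
})

setMethod("show", "PatternCounts", function(object) {
  cat(sprintf("PatternCounts: %d sites used, %d skipped\n",
              object@nUsed, object@nSkipped))
  print(object@counts)
})

setMethod("show", "DfoilResult", function(object) {
  cat(sprintf("DfoilResult [%s, alpha=%g] P1=%s P2=%s P3=%s P4=%s O=%s\n",
              object@mode, object@alpha, object@taxa[1], object@taxa[2],
              object@taxa[3], object@taxa[4], object@taxa[5]))
  print(object@stats, row.names = FALSE)
  cat(sprintf("call: %s", object@call$category))
  if (!is.na(object@call$donor))
    cat(sprintf(" (%s => %s)", object@call$donor, object@call$recipient))
  cat("\n")
})

setMethod("show", "UltrametricTree", function(object) {
  cat(sprintf("UltrametricTree: %d tips, root depth %.4g\n",
              ape::Ntip(object@tree), max(object@depths)))
})

setMethod("show", "Supermatrix", function(object) {
  cat(sprintf("Supermatrix: %d units x %d sites (%d loci)\n",
              length(object@sequences),
              if (nrow(object@partitions)) object@partitions$end[nrow(object@partitions)] else 0L,
              nrow(object@partitions)))
})

setMethod("show", "SNPMatrix", function(object) {
  cat(sprintf("SNPMatrix: %d units x %d biallelic sites\n",
              nrow(object@genotypes), ncol(object@genotypes)))
})
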