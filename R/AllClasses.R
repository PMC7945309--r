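setOldClass("phylo")

#' Introgression event specification
#'
#' One directed gene-flow event used by the simulator: a fraction
#' \code{gamma} of loci in the recipient lineage is replaced by copies that
#' coalesce with the donor lineage at time \code{tAdmix} before present.
#'
#' @slot donor donor taxon id.
#' @slot recipient recipient taxon or population id.
#' @slot gamma fraction of loci affected, in [0, 1].
#' @slot tAdmix attachment time before present (same units as the species
#'   tree); must be more recent than the divergence of donor and recipient.
#' @exportClass IntrogressionEvent
setClass("IntrogressionEvent",
  representation(donor = "character", recipient = "character",
                 gamma = "numeric", tAdmix = "numeric"),
  validity = function(object) {
    if (object@donor == object@recipient) return("donor must differ from recipient")
    if (object@gamma < 0 || object@gamma > 1) return("gamma must be in [0, 1]")
    if (object@tAdmix < 0) return("tAdmix must be >= 0")
    TRUE
  })

#' Simulation configuration for a synthetic GBS system
#'
#' Parameters of the generator: a rooted, ultrametric species tree whose
#' tips are taxa; populations nested within taxa; diploid individuals within
#' populations; Jukes-Cantor substitutions along branches; within-population
#' polymorphism; optional introgression events; and the GBS artifact layer
#' (locus dropout, paralog merging, sequencing coverage and base error).
#'
#' @slot tree rooted species tree (\code{ape::phylo}) with branch lengths.
#' @slot popsPerTaxon populations per taxon (>= 1).
#' @slot indsPerPop diploid individuals per population (>= 1).
#' @slot nLoci number of GBS loci.
#' @slot locusLength locus length in bp (>= 10).
#' @slot mu substitution rate per site per unit tree depth.
#' @slot popTheta within-population per-site polymorphism rate.
#' @slot popSplitDepth depth (time before present) at which populations of a
#'   taxon diverge from each other.
#' @slot events list of \linkS4class{IntrogressionEvent}.
#' @slot dropout probability that an (individual, locus) read stack is lost.
#' @slot paralogRate fraction of loci merged pairwise into composite
#'   (paralog-like) loci.
#' @slot coverage mean reads per allele (Poisson).
#' @slot baseError per-base sequencing error probability.
#' @slot seed integer seed making the whole simulation reproducible.
#' @exportClass SimConfig
setClass("SimConfig",
  representation(tree = "phylo", popsPerTaxon = "integer", indsPerPop = "integer",
                 nLoci = "integer", locusLength = "integer", mu = "numeric",
                 popTheta = "numeric", popSplitDepth = "numeric", events = "list",
                 dropout = "numeric", paralogRate = "numeric", coverage = "numeric",
                 baseError = "numeric", seed = "integer"),
  validity = function(object) {
    msg <- character(0)
    if (ape::Ntip(object@tree) < 2) msg <- c(msg, "species tree needs >= 2 tips")
    if (is.null(object@tree$edge.length) || any(object@tree$edge.length < 0))
      msg <- c(msg, "species tree must have non-negative branch lengths")
    if (object@popsPerTaxon < 1L) msg <- c(msg, "popsPerTaxon must be >= 1")
    if (object@indsPerPop < 1L) msg <- c(msg, "indsPerPop must be >= 1")
    if (object@nLoci < 1L) msg <- c(msg, "nLoci must be >= 1")
    if (object@locusLength < 10L) msg <- c(msg, "locusLength must be >= 10")
    if (object@mu < 0 || object@popTheta < 0) msg <- c(msg, "rates must be >= 0")
    for (p in c("dropout", "paralogRate", "baseError")) {
      v <- slot(object, p)
      if (v < 0 || v > 1) msg <- c(msg, sprintf("%s must be in [0, 1]", p))
    }
    if (object@baseError >= 1) msg <- c(msg, "baseError must be < 1")
    if (object@coverage <= 0) msg <- c(msg, "coverage must be > 0")
    if (!all(vapply(object@events, is, logical(1), "IntrogressionEvent")))
      msg <- c(msg, "events must be IntrogressionEvent objects")
    if (length(msg)) msg else TRUE
  })

#' Reads of one individual
#'
#' Container for the demultiplexed reads of a single individual. The
#' \code{locus} slot carries the generating locus id for simulated reads
#' (plumbing for truth-aware tests) and is \code{NA} for real data.
#'
#' @slot individual individual id.
#' @slot reads read sequences.
#' @slot locus generating locus of each read, or \code{NA}.
#' @exportClass GBSReadSet
setClass("GBSReadSet",
  representation(individual = "character", reads = "character", locus = "character"),
  validity = function(object) {
    if (length(object@locus) != length(object@reads))
      return("locus must be parallel to reads")
    if (length(object@reads) && any(nchar(object@reads) == 0))
      return("reads must be non-empty sequences")
    TRUE
  })

#' Ground truth of a simulated GBS system
#'
#' @slot labels one row per simulated locus: \code{locus}, \code{label}
#'   (\code{clean}, \code{introgressed} or \code{paralog}), \code{donor},
#'   \code{recipient}, and \code{mergedInto} (composite locus id for merged
#'   paralog pairs).
#' @slot alleles per-locus allele matrices (rows = alleles per individual,
#'   columns = individuals).
#' @slot dropout logical loci x individuals matrix marking lost read stacks.
#' @slot grouping data.frame with columns individual, population, taxon.
#' @slot config the \linkS4class{SimConfig} used.
#' @exportClass SyntheticTruth
setClass("SyntheticTruth",
  representation(labels = "data.frame", alleles = "list", dropout = "matrix",
                 grouping = "data.frame", config = "SimConfig"))

#' Reference loci from representative-read clustering
#'
#' @slot consensus named character vector of per-locus consensus sequences.
#' @slot members per-locus unique member reads.
#' @slot depths per-locus total read depth.
#' @slot parameters clustering parameters used.
#' @exportClass ReferenceLoci
setClass("ReferenceLoci",
  representation(consensus = "character", members = "list", depths = "numeric",
                 parameters = "list"),
  validity = function(object) {
    if (length(object@members) != length(object@consensus) ||
        length(object@depths) != length(object@consensus))
      return("consensus, members and depths must be parallel")
    TRUE
  })

#' Loci-by-individuals allele matrix
#'
#' The central container: for every (locus, individual) cell, the set of
#' allele sequences called for that individual at that locus (possibly
#' empty = missing). All sequences at a locus share one alignment length
#' (GBS fragments are restriction-site anchored, so alignment is positional).
#'
#' @slot cells loci x individuals matrix of character vectors.
#' @slot lociLength named integer vector of per-locus alignment lengths.
#' @slot provenance list of assembly parameters / origin notes.
#' @exportClass LocusMatrix
setClass("LocusMatrix",
  representation(cells = "matrix", lociLength = "integer", provenance = "list"),
  validity = function(object) {
    if (!is.list(object@cells[1]) && length(object@cells))
      return("cells must be a list-matrix")
    if (nrow(object@cells) != length(object@lociLength))
      return("lociLength must have one entry per locus")
    if (!identical(rownames(object@cells), names(object@lociLength)))
      return("locus names of cells and lociLength must agree")
    for (i in seq_len(nrow(object@cells))) {
      n <- nchar(unlist(object@cells[i, ]))
      if (length(n) && any(n != object@lociLength[i]))
        return(sprintf("locus '%s': sequence lengths differ from alignment length",
                       rownames(object@cells)[i]))
    }
    TRUE
  })

#' A filtered, level-specific working dataset
#'
#' @slot level one of \code{"individual"}, \code{"population"}, \code{"taxon"}.
#' @slot cells loci x units matrix of allele-sequence sets.
#' @slot lociLength named integer vector of locus alignment lengths.
#' @slot grouping data.frame (individual, population, taxon) covering the
#'   source individuals.
#' @slot thresholds filter thresholds used (varK, thetaInd, thetaLoc).
#' @exportClass LocusDataset
setClass("LocusDataset",
  representation(level = "character", cells = "matrix", lociLength = "integer",
                 grouping = "data.frame", thresholds = "list"),
  validity = function(object) {
    if (!object@level %in% c("individual", "population", "taxon"))
      return("level must be individual, population or taxon")
    if (nrow(object@cells) != length(object@lociLength))
      return("lociLength must have one entry per locus")
    thetaLoc <- object@thresholds$thetaLoc
    if (!is.null(thetaLoc) && ncol(object@cells) > 0) {
      pres <- matrix(lengths(object@cells) > 0, nrow(object@cells))
      if (any(rowMeans(pres) < thetaLoc))
        return("a retained locus is present in fewer than thetaLoc of units")
    }
    TRUE
  })

#' Biallelic 0/1 SNP matrix
#'
#' @slot genotypes units x sites matrix coded 0/1 (NA = missing or removed
#'   third state).
#' @slot siteMap data.frame mapping each site to (locus, column).
#' @exportClass SNPMatrix
setClass("SNPMatrix",
  representation(genotypes = "matrix", siteMap = "data.frame"),
  validity = function(object) {
    if (nrow(object@siteMap) != ncol(object@genotypes))
      return("siteMap must have one row per site")
    TRUE
  })

#' Concatenated supermatrix with partition map
#'
#' @slot sequences named character vector, one concatenated sequence per unit
#'   (missing loci filled with N).
#' @slot partitions data.frame (locus, start, end), 1-based inclusive,
#'   disjoint and ordered.
#' @exportClass Supermatrix
setClass("Supermatrix",
  representation(sequences = "character", partitions = "data.frame"),
  validity = function(object) {
    p <- object@partitions
    if (nrow(p)) {
      if (any(p$start > p$end)) return("partition start must be <= end")
      if (any(diff(p$start) <= 0)) return("partitions must be ordered")
      if (any(p$start[-1] != p$end[-nrow(p)] + 1))
        return("partitions must be contiguous and disjoint")
      if (length(object@sequences) &&
          any(nchar(object@sequences) != p$end[nrow(p)]))
        return("sequence length must equal total partition length")
    }
    TRUE
  })

#' Polarized site-pattern counts for one five-taxon test
#'
#' Counts of derived/ancestral site patterns over (P1, P2, P3, P4) polarized
#' by the outgroup, indexed by the 16 patterns 0000..1111 (1 = derived).
#'
#' @slot counts named integer vector of length 16.
#' @slot nUsed number of biallelic, fully resolved columns counted.
#' @slot nSkipped number of columns skipped (missing data, more than two
#'   states).
#' @exportClass PatternCounts
setClass("PatternCounts",
  representation(counts = "integer", nUsed = "integer", nSkipped = "integer"),
  validity = function(object) {
    if (length(object@counts) != 16L) return("counts must have 16 cells")
    if (any(object@counts < 0L)) return("counts must be >= 0")
    if (sum(object@counts) != object@nUsed)
      return("counts must sum to nUsed")
    TRUE
  })

#' Result of one DFOIL test
#'
#' @slot taxa named character vector (P1, P2, P3, P4, O) of unit ids.
#' @slot stats data.frame with one row per statistic (DFO, DIL, DFI, DOL):
#'   left/right pattern sums, D, chi-square, p, sign.
#' @slot mode \code{"dfoil"} or \code{"dfoil_alt"}.
#' @slot alpha significance level used for the signs.
#' @slot call list with elements category, donor, recipient.
#' @exportClass DfoilResult
setClass("DfoilResult",
  representation(taxa = "character", stats = "data.frame", mode = "character",
                 alpha = "numeric", call = "list"))

#' Rooted ultrametric tree with node depths
#'
#' @slot tree rooted \code{ape::phylo} tree.
#' @slot depths numeric vector of node depths (time before present), indexed
#'   by ape node number; tips have depth ~0.
#' @slot tolerance maximum allowed root-to-tip path spread.
#' @exportClass UltrametricTree
setClass("UltrametricTree",
  representation(tree = "phylo", depths = "numeric", tolerance = "numeric"),
  validity = function(object) {
    tr <- object@tree
    n <- ape::Ntip(tr)
    if (length(object@depths) != n + tr$Nnode)
      return("depths must cover all nodes")
    if (any(abs(object@depths[seq_len(n)]) > object@tolerance))
      return("tip depths must be 0 within tolerance")
    kids <- tr$edge[, 2]; pars <- tr$edge[, 1]
    if (any(object@depths[pars] <= object@depths[kids] - object@tolerance))
      return("node depths must increase toward the root")
    TRUE
  })
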