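# The five-taxon DFOIL system of D-statistics (Pease & Hahn 2015, Syst. Biol.
# 64:651-662): polarized biallelic site-pattern counts over a symmetric tree
# (((P1,P2),(P3,P4)),O) with t(P1,P2) <= t(P3,P4), four chi-square-tested
# asymmetry statistics, and a sign-pattern table that both detects and
# polarizes introgression.
#
# Site patterns are indexed 0..15 by the derived (= different from outgroup)
# states of P1..P4: index = 8*b1 + 4*b2 + 2*b3 + b4. In the conventional
# A/B notation (A = ancestral), index 10 = BABAA, 5 = ABABA, etc.

# left/right pattern subsets of the four statistics (0-based indices)
.DFOIL_DEF <- list(
  DFO = list(L = c(10L, 14L, 5L, 1L), R = c(9L, 13L, 6L, 2L)),
  DIL = list(L = c(6L, 14L, 9L, 1L), R = c(5L, 13L, 10L, 2L)),
  DFI = list(L = c(10L, 11L, 5L, 4L), R = c(6L, 7L, 9L, 8L)),
  DOL = list(L = c(9L, 11L, 6L, 4L), R = c(5L, 7L, 10L, 8L))
)
# singleton-derived patterns excluded in dfoil_alt mode
.DFOIL_SINGLETONS <- c(1L, 2L, 4L, 8L)

# sign vector (DFO, DIL, DFI, DOL) -> introgression call
.SIGN_TABLE <- rbind(
  data.frame(k = "0,0,0,0",   category = "none",    donor = NA, recipient = NA),
  data.frame(k = "1,1,1,0",   category = "P1-P3",   donor = "P1", recipient = "P3"),
  data.frame(k = "1,0,1,1",   category = "P1-P3",   donor = "P3", recipient = "P1"),
  data.frame(k = "1,1,-1,0",  category = "P2-P3",   donor = "P2", recipient = "P3"),
  data.frame(k = "0,1,-1,-1", category = "P2-P3",   donor = "P3", recipient = "P2"),
  data.frame(k = "-1,-1,0,1", category = "P1-P4",   donor = "P1", recipient = "P4"),
  data.frame(k = "-1,0,1,1",  category = "P1-P4",   donor = "P4", recipient = "P1"),
  data.frame(k = "-1,-1,0,-1", category = "P2-P4",  donor = "P2", recipient = "P4"),
  data.frame(k = "0,-1,-1,-1", category = "P2-P4",  donor = "P4", recipient = "P2"),
  data.frame(k = "1,1,0,0",   category = "anc-P3",  donor = NA, recipient = NA),
  data.frame(k = "-1,-1,0,0", category = "anc-P4",  donor = NA, recipient = NA)
)

.PATTERN_NAMES <- vapply(0:15, function(i) {
  b <- c("A", "B")[1 + (bitwAnd(i, c(8L, 4L, 2L, 1L)) > 0L)]
  paste(c(b, "A"), collapse = "")
}, character(1))

#' The DFOIL pattern subsets and sign table
#'
#' Returns the left/right site-pattern subsets of each statistic (in
#' five-letter A/B notation, outgroup last, B = derived) and the sign-pattern
#' table used by \code{\link{classifySigns}}.
#'
#' @return list with elements \code{subsets} and \code{signTable}.
#' @export
dfoilPatterns <- function() {
  subsets <- lapply(.DFOIL_DEF, function(dd)
    list(L = .PATTERN_NAMES[dd$L + 1L], R = .PATTERN_NAMES[dd$R + 1L]))
  st <- .SIGN_TABLE
  st$signs <- st$k; st$k <- NULL
  list(subsets = subsets, signTable = st)
}

# fast path: 5 x nSites integer matrix (rows P1, P2, P3, P4, O) -> counts
.countPatternsInt <- function(m) {
  a <- m[1L, ]; b <- m[2L, ]; c_ <- m[3L, ]; d <- m[4L, ]; e <- m[5L, ]
  present <- a > 0L & b > 0L & c_ > 0L & d > 0L & e > 0L
  nStates <- 1L + (b != a) + (c_ != a & c_ != b) +
    (d != a & d != b & d != c_) +
    (e != a & e != b & e != c_ & e != d)
  use <- present & nStates <= 2L
  idx <- 8L * (a != e) + 4L * (b != e) + 2L * (c_ != e) + (d != e)
  counts <- tabulate(idx[use] + 1L, 16L)
  list(counts = as.integer(counts), used = sum(use),
       skipped = length(a) - sum(use))
}

#' Count polarized site patterns for one five-taxon test
#'
#' Per column: skipped if any sequence has a missing base (N or gap) or if
#' more than two states are present; otherwise the derived state of each of
#' P1..P4 relative to the outgroup increments one of the 16 pattern cells
#' (monomorphic columns count in cell AAAAA).
#'
#' @param seqs character vector of five equal-length sequences, ordered
#'   P1, P2, P3, P4, outgroup.
#' @return a \linkS4class{PatternCounts}.
#' @export
#' @examples
#' countSitePatterns(c("ACGT", "ACGT", "ACTT", "ACGT", "ACGT"))
countSitePatterns <- function(seqs) {
  if (length(seqs) != 5L) stop("need exactly five sequences (P1, P2, P3, P4, O)")
  if (length(unique(nchar(seqs))) != 1L) stop("sequences must have equal length")
  r <- .countPatternsInt(.enc(seqs))
  new("PatternCounts", counts = setNames(r$counts, .PATTERN_NAMES),
      nUsed = as.integer(r$used), nSkipped = as.integer(r$skipped))
}

#' A single D-statistic with chi-square significance
#'
#' D = (L - R) / (L + R) with chi2 = (L - R)^2 / (L + R) tested against the
#' 1-df chi-square upper tail; the sign is 0 unless p <= alpha. The
#' convention D = 0, sign = 0 applies when L + R = 0.
#'
#' @param L,R non-negative left/right pattern sums.
#' @param alpha significance level (default 0.01).
#' @return list with elements L, R, D, chi2, p, sign.
#' @export
#' @examples
#' dStat(30, 10)  # D = 0.5, chi2 = 10, p ~ 0.00157
dStat <- function(L, R, alpha = 0.01) {
  stopifnot(L >= 0, R >= 0)
  if (L + R == 0)
    return(list(L = L, R = R, D = 0, chi2 = 0, p = 1, sign = 0L))
  D <- (L - R) / (L + R)
  chi2 <- (L - R)^2 / (L + R)
  p <- pchisq(chi2, df = 1, lower.tail = FALSE)
  sgn <- if (p > alpha) 0L else as.integer(sign(L - R))
  list(L = L, R = R, D = D, chi2 = chi2, p = p, sign = sgn)
}

#' Classify a DFOIL sign vector into an introgression call
#'
#' Exact match against the DFOIL sign-pattern table: terminal-pair rows are
#' polarized (donor -> recipient); introgression with the ancestor of
#' (P1, P2) is undirected; the all-zero vector is \code{none}; any other
#' vector is \code{ambiguous}.
#'
#' @param signs integer vector of the four signs (DFO, DIL, DFI, DOL) in
#'   \{-1, 0, 1\}.
#' @return list with elements category, donor, recipient.
#' @export
#' @examples
#' classifySigns(c(1, 1, 1, 0))  # P1 => P3
classifySigns <- function(signs) {
  stopifnot(length(signs) == 4L, all(signs %in% c(-1L, 0L, 1L)))
  key <- paste(as.integer(signs), collapse = ",")
  hit <- match(key, .SIGN_TABLE$k)
  if (is.na(hit))
    return(list(category = "ambiguous", donor = NA_character_,
                recipient = NA_character_))
  list(category = .SIGN_TABLE$category[hit],
       donor = .SIGN_TABLE$donor[hit],
       recipient = .SIGN_TABLE$recipient[hit])
}

# assemble the four statistics from counts (internal fast path)
.dfoilStats <- function(counts, alpha, mode) {
  rows <- lapply(names(.DFOIL_DEF), function(nm) {
    dd <- .DFOIL_DEF[[nm]]
    li <- dd$L; ri <- dd$R
    if (mode == "dfoil_alt") {
      li <- setdiff(li, .DFOIL_SINGLETONS)
      ri <- setdiff(ri, .DFOIL_SINGLETONS)
    }
    s <- dStat(sum(counts[li + 1L]), sum(counts[ri + 1L]), alpha)
    data.frame(stat = nm, L = s$L, R = s$R, D = s$D, chi2 = s$chi2,
               p = s$p, sign = s$sign, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Run the DFOIL test on pattern counts
#'
#' Computes DFO, DIL, DFI and DOL from the pattern subsets, tests each with
#' the 1-df chi-square, and classifies the sign vector. \code{mode
#' = "dfoil_alt"} excludes the singleton-derived patterns (ABAAA, BAAAA,
#' AABAA, AAABA) from every sum, for datasets where terminal-branch signal is
#' unreliable; \code{mode = "auto"} picks \code{dfoil_alt} when the smallest
#' singleton-pattern count falls below \code{primeMin}.
#'
#' @param counts a \linkS4class{PatternCounts}.
#' @param alpha significance level (default 0.01).
#' @param mode \code{"dfoil"}, \code{"dfoil_alt"} or \code{"auto"}.
#' @param primeMin minimum singleton-pattern count for \code{"auto"} to use
#'   the full statistics.
#' @param taxa optional names of (P1, P2, P3, P4, O) recorded in the result.
#' @return a \linkS4class{DfoilResult}.
#' @export
dfoilTest <- function(counts, alpha = 0.01,
                      mode = c("dfoil", "dfoil_alt", "auto"), primeMin = 10L,
                      taxa = c(P1 = "P1", P2 = "P2", P3 = "P3", P4 = "P4", O = "O")) {
  mode <- match.arg(mode)
  cnt <- counts@counts
  if (mode == "auto")
    mode <- if (min(cnt[.DFOIL_SINGLETONS + 1L]) < primeMin) "dfoil_alt" else "dfoil"
  stats <- .dfoilStats(cnt, alpha, mode)
  call <- classifySigns(stats$sign)
  new("DfoilResult", taxa = taxa, stats = stats, mode = mode, alpha = alpha,
      call = call)
}
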