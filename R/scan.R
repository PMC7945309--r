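# Exhaustive five-taxon DFOIL scan constrained by an ultrametric guide tree:
# enumerate every tree-compatible quintet (P1, P2; P3, P4; outgroup), test
# each against the supermatrix, and aggregate significant tests into
# taxon-pair summaries.

#' Make (or validate) an ultrametric tree
#'
#' @param tree rooted \code{ape::phylo} with branch lengths.
#' @param method \describe{
#'   \item{require}{validate that the tree is already ultrametric within
#'     \code{tolerance}; fail otherwise, reporting the worst tip pair.}
#'   \item{equal_terminals}{keep internal branch lengths and set every
#'     terminal branch so all tip depths equalize (the terminal branches all
#'     of equal meaning: each terminal is stretched/shrunk individually so
#'     root-to-tip paths match).}
#'   \item{mean_path}{recursive mean-path-length smoothing: each node depth
#'     becomes the mean root-to-tip path length below it, clipped to remain
#'     monotone.}}
#' @param tolerance maximum allowed root-to-tip spread.
#' @return an \linkS4class{UltrametricTree}.
#' @export
makeUltrametric <- function(tree, method = c("require", "equal_terminals", "mean_path"),
                            tolerance = 1e-6) {
  method <- match.arg(method)
  if (is.null(tree$edge.length) && method != "equal_terminals")
    stop("tree has no branch lengths")
  n <- ape::Ntip(tree)
  if (method == "require") {
    fromRoot <- ape::node.depth.edgelength(tree)
    tipd <- fromRoot[seq_len(n)]
    if (max(tipd) - min(tipd) > tolerance)
      stop(sprintf("tree is not ultrametric: root-to-tip spread %.6g between '%s' and '%s'",
                   max(tipd) - min(tipd), tree$tip.label[which.max(tipd)],
                   tree$tip.label[which.min(tipd)]))
    out <- tree
  } else if (method == "equal_terminals") {
    out <- tree
    if (is.null(out$edge.length)) out$edge.length <- rep(1, nrow(out$edge))
    term <- out$edge[, 2] <= n
    inner <- out
    inner$edge.length[term] <- 0
    fromRoot <- ape::node.depth.edgelength(inner)
    pad <- if (any(term) && any(tree$edge.length[term] > 0))
      mean(tree$edge.length[term]) else 1
    D <- max(fromRoot[out$edge[term, 1]]) + pad
    out$edge.length[term] <- D - fromRoot[out$edge[term, 1]]
  } else {
    out <- tree
    # mean path length per node, bottom-up
    cnt <- numeric(n + tree$Nnode); sm <- numeric(n + tree$Nnode)
    cnt[seq_len(n)] <- 1
    for (e in ape::postorder(tree)) {
      par <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
      cnt[par] <- cnt[par] + cnt[ch]
      sm[par] <- sm[par] + sm[ch] + cnt[ch] * tree$edge.length[e]
    }
    depth <- ifelse(cnt > 0, sm / pmax(cnt, 1), 0)
    depth[seq_len(n)] <- 0
    # enforce monotonicity toward the root
    for (e in ape::postorder(tree)) {
      par <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
      if (depth[par] <= depth[ch])
        depth[par] <- depth[ch] + max(depth) * 1e-9 + 1e-12
    }
    out$edge.length <- depth[tree$edge[, 1]] - depth[tree$edge[, 2]]
  }
  fromRoot <- ape::node.depth.edgelength(out)
  depths <- max(fromRoot[seq_len(n)]) - fromRoot
  depths[seq_len(n)] <- 0
  new("UltrametricTree", tree = out, depths = depths, tolerance = tolerance)
}

#' Node depths of an ultrametric tree
#' @param x an \linkS4class{UltrametricTree}.
#' @return numeric vector of depths (time before present) indexed by ape node
#'   number.
#' @export
nodeDepths <- function(x) x@depths

#' Scan configuration
#'
#' @param alpha per-statistic significance level.
#' @param mode DFOIL mode passed to \code{\link{dfoilTest}}.
#' @param pairReportProp proportion of eligible tests above which a taxon
#'   pair is flagged as showing introgression (default 0.05).
#' @param detailCount number of predicted introgression events above which a
#'   pair is flagged for detailed examination (default 50).
#' @param tiePolicy for quintets whose two pair divergences are equal:
#'   \code{"lexicographic"} keeps them with the lexicographically smaller
#'   pair as (P1, P2); \code{"drop"} excludes them.
#' @param primeMin singleton-count threshold for \code{mode = "auto"}.
#' @return a named list of settings.
#' @export
scanConfig <- function(alpha = 0.01, mode = "dfoil", pairReportProp = 0.05,
                       detailCount = 50L, tiePolicy = c("lexicographic", "drop"),
                       primeMin = 10L) {
  stopifnot(alpha > 0, alpha < 1, pairReportProp >= 0, pairReportProp <= 1,
            detailCount >= 0)
  list(alpha = alpha, mode = match.arg(mode, c("dfoil", "dfoil_alt", "auto")),
       pairReportProp = pairReportProp, detailCount = as.integer(detailCount),
       tiePolicy = match.arg(tiePolicy), primeMin = as.integer(primeMin))
}

#' Enumerate all tree-compatible five-taxon tests
#'
#' All unordered pairs of disjoint ingroup tip pairs \{\{P1,P2\},\{P3,P4\}\}
#' such that both pair divergences are more recent than the divergence of
#' the two pairs from each other, with (P1, P2) the more recently diverged
#' pair (DFOIL applicability: t(P1,P2) <= t(P3,P4)). Within-pair order is
#' lexicographic; equal-depth pair ties follow \code{tiePolicy}.
#'
#' @param utree an \linkS4class{UltrametricTree}.
#' @param outgroup outgroup tip label (excluded from the enumeration).
#' @param tiePolicy see \code{\link{scanConfig}}.
#' @return data.frame with columns P1, P2, P3, P4, t12, t34.
#' @export
enumerateQuartets <- function(utree, outgroup,
                              tiePolicy = c("lexicographic", "drop")) {
  tiePolicy <- match.arg(tiePolicy)
  tr <- utree@tree
  if (!outgroup %in% tr$tip.label) stop("outgroup is not a tip of the tree")
  ing <- setdiff(tr$tip.label, outgroup)
  if (length(ing) < 4L) stop("need at least four ingroup tips")
  idx <- match(ing, tr$tip.label)
  mrcaMat <- ape::mrca(tr)[idx, idx, drop = FALSE]
  MD <- matrix(utree@depths[mrcaMat], length(ing), length(ing),
               dimnames = list(ing, ing))
  eps <- utree@tolerance
  prs <- combn(length(ing), 2L)
  np <- ncol(prs)
  pd <- MD[t(prs)]
  out <- vector("list", 1000L); nout <- 0L
  for (i in seq_len(np - 1L)) {
    a <- prs[1L, i]; b <- prs[2L, i]
    for (j in (i + 1L):np) {
      c_ <- prs[1L, j]; d <- prs[2L, j]
      if (c_ == a || c_ == b || d == a || d == b) next
      dAll <- max(pd[i], pd[j], MD[a, c_], MD[a, d], MD[b, c_], MD[b, d])
      if (pd[i] >= dAll - eps || pd[j] >= dAll - eps) next
      if (abs(pd[i] - pd[j]) <= eps) {
        if (tiePolicy == "drop") next
        p1 <- sort(c(ing[a], ing[b])); p2 <- sort(c(ing[c_], ing[d]))
        if (paste(p2, collapse = "\r") < paste(p1, collapse = "\r")) {
          tmp <- p1; p1 <- p2; p2 <- tmp
        }
        q <- c(p1, p2); t12 <- pd[i]; t34 <- pd[j]
      } else if (pd[i] < pd[j]) {
        q <- c(sort(c(ing[a], ing[b])), sort(c(ing[c_], ing[d])))
        t12 <- pd[i]; t34 <- pd[j]
      } else {
        q <- c(sort(c(ing[c_], ing[d])), sort(c(ing[a], ing[b])))
        t12 <- pd[j]; t34 <- pd[i]
      }
      nout <- nout + 1L
      if (nout > length(out)) out <- c(out, vector("list", length(out)))
      out[[nout]] <- c(q, t12, t34)
    }
  }
  if (!nout)
    return(data.frame(P1 = character(0), P2 = character(0), P3 = character(0),
                      P4 = character(0), t12 = numeric(0), t34 = numeric(0)))
  m <- do.call(rbind, out[seq_len(nout)])
  data.frame(P1 = m[, 1], P2 = m[, 2], P3 = m[, 3], P4 = m[, 4],
             t12 = as.numeric(m[, 5]), t34 = as.numeric(m[, 6]),
             stringsAsFactors = FALSE)
}

#' Run the exhaustive DFOIL scan
#'
#' One DFOIL test per enumerated quintet, with sequences drawn from the
#' supermatrix. Deterministic given its inputs.
#'
#' @param supermatrix a \linkS4class{Supermatrix} whose units include every
#'   tree tip.
#' @param utree an \linkS4class{UltrametricTree} whose tips are scan units.
#' @param outgroup outgroup unit id (tree tip and supermatrix unit).
#' @param config a \code{\link{scanConfig}} list.
#' @return data.frame (one row per test): P1..P4, mode, nUsed, nSkipped, per
#'   statistic L/R/D/chi2/p/sign, anySig, category, donor, recipient (donor
#'   and recipient are unit ids for polarized terminal calls).
#' @export
runScan <- function(supermatrix, utree, outgroup, config = scanConfig()) {
  units <- names(supermatrix@sequences)
  missingUnits <- setdiff(utree@tree$tip.label, units)
  if (length(missingUnits))
    stop("units missing from the supermatrix: ", paste(missingUnits, collapse = ", "))
  if (!outgroup %in% units) stop("outgroup missing from the supermatrix")
  qs <- enumerateQuartets(utree, outgroup, config$tiePolicy)
  S <- .enc(supermatrix@sequences)
  rownames(S) <- units
  n <- nrow(qs)
  statNames <- names(.DFOIL_DEF)
  res <- data.frame(qs[c("P1", "P2", "P3", "P4")],
                    mode = character(n), nUsed = integer(n),
                    nSkipped = integer(n), stringsAsFactors = FALSE)
  for (s in statNames)
    for (f in c("L", "R", "D", "chi2", "p", "sign"))
      res[[paste(s, f, sep = "_")]] <- numeric(n)
  res$anySig <- logical(n)
  res$category <- character(n)
  res$donor <- NA_character_
  res$recipient <- NA_character_
  oi <- match(outgroup, units)
  ri <- cbind(match(qs$P1, units), match(qs$P2, units),
              match(qs$P3, units), match(qs$P4, units))
  for (r in seq_len(n)) {
    pc <- .countPatternsInt(S[c(ri[r, ], oi), , drop = FALSE])
    mode <- config$mode
    if (mode == "auto")
      mode <- if (min(pc$counts[.DFOIL_SINGLETONS + 1L]) < config$primeMin)
        "dfoil_alt" else "dfoil"
    st <- .dfoilStats(pc$counts, config$alpha, mode)
    res$mode[r] <- mode
    res$nUsed[r] <- pc$used; res$nSkipped[r] <- pc$skipped
    for (k in seq_along(statNames)) {
      s <- statNames[k]
      res[[paste0(s, "_L")]][r] <- st$L[k]
      res[[paste0(s, "_R")]][r] <- st$R[k]
      res[[paste0(s, "_D")]][r] <- st$D[k]
      res[[paste0(s, "_chi2")]][r] <- st$chi2[k]
      res[[paste0(s, "_p")]][r] <- st$p[k]
      res[[paste0(s, "_sign")]][r] <- st$sign[k]
    }
    res$anySig[r] <- any(st$sign != 0L)
    call <- classifySigns(st$sign)
    res$category[r] <- call$category
    if (!is.na(call$donor)) {
      roles <- c(P1 = qs$P1[r], P2 = qs$P2[r], P3 = qs$P3[r], P4 = qs$P4[r])
      res$donor[r] <- roles[[call$donor]]
      res$recipient[r] <- roles[[call$recipient]]
    }
  }
  res
}

# canonical key for an unordered taxon pair; same-taxon "ancestral" pairs
# collapse to the taxon itself
.pairKey <- function(x, y) {
  ifelse(x == y, x, paste(pmin(x, y), pmax(x, y), sep = "|"))
}
.ancKey <- function(x, y) ifelse(x == y, x, sprintf("anc(%s,%s)", pmin(x, y), pmax(x, y)))

#' Aggregate a scan table into taxon-pair and per-unit summaries
#'
#' For every taxon pair (including ancestral pseudo-taxa \code{anc(X,Y)} for
#' calls involving the common ancestor of P1 and P2), counts the tests in
#' which the pair was callable (appeared in callable positions), the tests
#' whose call involves the pair, their ratio, and per-direction counts for
#' polarized calls. Pairs are flagged when the proportion reaches
#' \code{pairReportProp} or the event count reaches \code{detailCount}.
#'
#' @param table scan table from \code{\link{runScan}}.
#' @param grouping named character vector mapping scan unit -> taxon (or a
#'   data.frame with columns individual/population/taxon from which the map
#'   is built for the appropriate level).
#' @param level when \code{grouping} is a data.frame: which column names the
#'   scan units.
#' @param config a \code{\link{scanConfig}} list.
#' @return list with elements \code{pairs} (data.frame: pair, taxonA, taxonB,
#'   nTests, nEvents, proportion, per-direction counts, flags) and
#'   \code{units} (data.frame: unit, nTests, nSig, proportion).
#' @export
aggregateScan <- function(table, grouping, level = c("population", "individual", "taxon"),
                          config = scanConfig()) {
  if (is.data.frame(grouping)) {
    level <- match.arg(level)
    grouping <- setNames(grouping$taxon, grouping[[level]])
    grouping <- grouping[!duplicated(names(grouping))]
  }
  unitsSeen <- unique(c(table$P1, table$P2, table$P3, table$P4))
  unknown <- setdiff(unitsSeen, names(grouping))
  if (length(unknown))
    stop("units not covered by grouping: ", paste(unknown, collapse = ", "))
  g1 <- grouping[table$P1]; g2 <- grouping[table$P2]
  g3 <- grouping[table$P3]; g4 <- grouping[table$P4]

  # callable pairs per record (deduplicated within record)
  callable <- cbind(.pairKey(g1, g3), .pairKey(g1, g4),
                    .pairKey(g2, g3), .pairKey(g2, g4),
                    .pairKey(.ancKey(g1, g2), g3), .pairKey(.ancKey(g1, g2), g4))
  nTests <- table(unlist(lapply(seq_len(nrow(callable)), function(r)
    unique(callable[r, ]))))

  # event pair + direction per record
  evPair <- rep(NA_character_, nrow(table))
  evDir <- rep(NA_character_, nrow(table))
  cat <- table$category
  sel <- cat %in% c("P1-P3", "P1-P4", "P2-P3", "P2-P4")
  if (any(sel)) {
    gm <- cbind(g1, g2, g3, g4)[sel, , drop = FALSE]
    a <- substr(cat[sel], 2, 2); b <- substr(cat[sel], 5, 5)
    ga <- gm[cbind(seq_len(nrow(gm)), as.integer(a))]
    gb <- gm[cbind(seq_len(nrow(gm)), as.integer(b))]
    evPair[sel] <- .pairKey(ga, gb)
    gd <- grouping[table$donor[sel]]; gr <- grouping[table$recipient[sel]]
    evDir[sel] <- paste(gd, gr, sep = "=>")
  }
  sel <- cat %in% c("anc-P3", "anc-P4")
  if (any(sel)) {
    anc <- .ancKey(g1[sel], g2[sel])
    other <- ifelse(cat[sel] == "anc-P3", g3[sel], g4[sel])
    evPair[sel] <- .pairKey(anc, other)
  }

  allPairs <- sort(unique(c(names(nTests), evPair[!is.na(evPair)])))
  nT <- as.integer(nTests[allPairs]); nT[is.na(nT)] <- 0L
  nE <- as.integer(table(factor(evPair, levels = allPairs)))
  prop <- ifelse(nT > 0, nE / nT, 0)
  dirTab <- vapply(allPairs, function(p) {
    d <- evDir[!is.na(evPair) & evPair == p & !is.na(evDir)]
    if (!length(d)) return(NA_character_)
    t <- sort(table(d), decreasing = TRUE)
    paste(sprintf("%s:%d", names(t), as.integer(t)), collapse = ";")
  }, character(1))
  ab <- strsplit(allPairs, "|", fixed = TRUE)
  pairs <- data.frame(pair = allPairs,
                      taxonA = vapply(ab, `[`, character(1), 1L),
                      taxonB = vapply(ab, function(x) if (length(x) > 1L) x[2] else x[1],
                                      character(1)),
                      nTests = nT, nEvents = nE, proportion = prop,
                      directions = unname(dirTab),
                      flagProportion = prop >= config$pairReportProp & nE > 0L,
                      flagDetail = nE >= config$detailCount,
                      stringsAsFactors = FALSE)
  pairs <- pairs[order(-pairs$proportion, -pairs$nEvents, pairs$pair), ]
  rownames(pairs) <- NULL

  unitIds <- sort(unitsSeen)
  inTest <- vapply(unitIds, function(u)
    sum(table$P1 == u | table$P2 == u | table$P3 == u | table$P4 == u),
    numeric(1))
  sig <- table$category != "none"
  nSig <- vapply(unitIds, function(u)
    sum(sig & (table$P1 == u | table$P2 == u | table$P3 == u | table$P4 == u)),
    numeric(1))
  units <- data.frame(unit = unitIds, taxon = unname(grouping[unitIds]),
                      nTests = as.integer(inTest), nSig = as.integer(nSig),
                      proportion = ifelse(inTest > 0, nSig / inTest, 0),
                      stringsAsFactors = FALSE)
  list(pairs = pairs, units = units)
}
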