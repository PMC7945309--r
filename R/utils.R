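# Internal helpers: sequence encoding, identity computation, clustering.
# Bases are coded A=1, C=2, G=3, T=4; anything else (N, -, ?) codes 0 and is
# treated as missing.

.BASES <- c("A", "C", "G", "T")

# character vector of equal-length sequences -> integer matrix (n x L)
.enc <- function(x) {
  if (!length(x)) return(matrix(integer(0), 0, 0))
  L <- unique(nchar(x))
  if (length(L) != 1L)
    stop("sequences must all have the same length")
  v <- strsplit(toupper(paste(x, collapse = "")), "", fixed = TRUE)[[1L]]
  m <- match(v, .BASES)
  m[is.na(m)] <- 0L
  matrix(as.integer(m), nrow = length(x), ncol = L, byrow = TRUE,
         dimnames = list(names(x), NULL))
}

# integer matrix -> character vector of sequences
.dec <- function(m) {
  if (!nrow(m)) return(setNames(character(0), character(0)))
  ch <- c("N", .BASES)[m + 1L]
  out <- apply(matrix(ch, nrow(m), ncol(m)), 1L, paste, collapse = "")
  names(out) <- rownames(m)
  out
}

# pairwise fraction-identical-positions between rows of A and rows of B
# (both n x L integer matrices with identical L); missing counts as mismatch
.identity <- function(A, B) {
  L <- ncol(A)
  stopifnot(ncol(B) == L)
  S <- matrix(0L, nrow(A), nrow(B))
  for (k in seq_len(L))
    S <- S + outer(A[, k], B[, k], "==")
  S / L
}

# single-linkage connected components of an n x n logical adjacency
# (union-find); returns integer component labels 1..k in order of appearance
.components <- function(adj) {
  n <- nrow(adj)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (i in seq_len(n)) {
    js <- which(adj[i, ])
    for (j in js[js > i]) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

# majority base per column of an integer matrix, weighted by depth; ties go
# to the lexicographically smallest base; missing (0) is ignored
.consensus <- function(m, depth = rep(1L, nrow(m))) {
  L <- ncol(m)
  out <- integer(L)
  for (k in seq_len(L)) {
    w <- vapply(1:4, function(b) sum(depth[m[, k] == b]), numeric(1))
    out[k] <- which.max(w)  # which.max takes the first (smallest base) on ties
  }
  out
}

# random DNA integer vector
.randSeq <- function(L) sample.int(4L, L, replace = TRUE)

# mutate each site of integer vector s with probability p (new base uniform
# over the other three)
.mutate <- function(s, p) {
  hit <- which(runif(length(s)) < p)
  if (length(hit))
    s[hit] <- ((s[hit] - 1L + sample.int(3L, length(hit), replace = TRUE)) %% 4L) + 1L
  s
}

# place k substitutions at uniformly chosen sites of integer vector s
.mutateK <- function(s, k) {
  if (k <= 0L) return(s)
  pos <- sample.int(length(s), min(k, length(s)))
  s[pos] <- ((s[pos] - 1L + sample.int(3L, length(pos), replace = TRUE)) %% 4L) + 1L
  s
}

.checkProb <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop(sprintf("'%s' must be a single probability in [0, 1]", what))
  x
}
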