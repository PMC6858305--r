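## fixtures and independent oracles used across the suite

GAP <- "---"
SENSE <- setdiff(names(Biostrings::GENETIC_CODE), c("TAA", "TAG", "TGA"))

## build a CodonAlignment from a list of codon-token vectors
makeAln <- function(rows) {
  m <- do.call(rbind, rows)
  rownames(m) <- names(rows)
  methods::new("CodonAlignment", codons = m)
}

## random gapped codon alignment (gap runs in whole codons by construction)
randomAln <- function(n_rows, n_cols, gap_prob = 0.1) {
  rows <- lapply(seq_len(n_rows), function(i) {
    r <- sample(SENSE, n_cols, replace = TRUE)
    r[stats::runif(n_cols) < gap_prob] <- GAP
    r
  })
  names(rows) <- sprintf("r%02d", seq_len(n_rows))
  makeAln(rows)
}

## brute-force nucleotide identity between two codon rows
bruteIdentity <- function(rowA, rowB) {
  a <- unlist(strsplit(rowA, "")); b <- unlist(strsplit(rowB, ""))
  m <- 0L; cmp <- 0L
  for (i in seq_along(a)) {
    if (a[i] != "-" && b[i] != "-") {
      cmp <- cmp + 1L
      if (a[i] == b[i]) m <- m + 1L
    }
  }
  if (cmp == 0L) NA_real_ else m / cmp
}

bruteIdentityMatrix <- function(aln) {
  m <- codonMatrix(aln)
  n <- nrow(m)
  out <- diag(1, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
    out[i, j] <- out[j, i] <- bruteIdentity(m[i, ], m[j, ])
  dimnames(out) <- list(rownames(m), rownames(m))
  out
}

## naive O(L*W) sliding-window conserved-region oracle
naiveConservedRegions <- function(a, b, pct, W) {
  a <- strsplit(a, "")[[1L]]; b <- strsplit(b, "")[[1L]]
  L <- length(a)
  mt <- as.integer(a != "-" & b != "-" & a == b)
  pass <- rep(TRUE, L)
  for (i in seq_len(L)) {
    for (s in max(1L, i - W + 1L):min(i, L - W + 1L)) {
      if (sum(mt[s:(s + W - 1L)]) < pct / 100 * W) {
        pass[i] <- FALSE
        break
      }
    }
  }
  r <- rle(pass)
  ends <- cumsum(r$lengths); begs <- ends - r$lengths + 1L
  data.frame(start = begs[r$values], end = ends[r$values])
}

## brute-force per-position interval membership count
coverageOracle <- function(L, intervals) {
  depth <- integer(L)
  for (i in seq_len(L))
    depth[i] <- sum(intervals$start <= i & intervals$end >= i)
  depth
}

## enumeration oracle for PROSITE-like motifs: expand every combination
## of variable-wildcard spans into fixed offsets and test every start
motifOracle <- function(aa_string, pattern) {
  els <- parseMotif(pattern)
  aa <- strsplit(aa_string, "")[[1L]]
  L <- length(aa)
  spans <- lapply(els, function(e) e$min:e$max)
  combos <- expand.grid(spans)
  hits <- list()
  for (s in seq_len(L)) {
    for (ci in seq_len(nrow(combos))) {
      lens <- as.integer(combos[ci, ])
      pos <- s; ok <- TRUE
      for (k in seq_along(els)) {
        ln <- lens[k]
        if (pos + ln - 1L > L) { ok <- FALSE; break }
        res <- els[[k]]$residues
        if (!is.null(res) && !all(aa[pos:(pos + ln - 1L)] %in% res)) {
          ok <- FALSE; break
        }
        pos <- pos + ln
      }
      if (ok) hits[[length(hits) + 1L]] <- c(s, pos - 1L)
    }
  }
  if (!length(hits)) return(data.frame(start = integer(), end = integer()))
  m <- unique(do.call(rbind, hits))
  m <- m[order(m[, 1L], m[, 2L]), , drop = FALSE]
  data.frame(start = m[, 1L], end = m[, 2L])
}

## OLS branch lengths and tree length for a fixed topology
olsTreeLength <- function(topology, dm) {
  labs <- topology$tip.label
  n <- length(labs)
  pairs <- t(combn(n, 2L))
  A <- matrix(0, nrow(pairs), nrow(topology$edge))
  for (p in seq_len(nrow(pairs))) {
    path <- ape::nodepath(topology, pairs[p, 1L], pairs[p, 2L])
    for (k in seq_len(length(path) - 1L)) {
      e <- which((topology$edge[, 1L] == path[k] & topology$edge[, 2L] == path[k + 1L]) |
                 (topology$edge[, 2L] == path[k] & topology$edge[, 1L] == path[k + 1L]))
      A[p, e] <- 1
    }
  }
  y <- dm[cbind(match(labs[pairs[, 1L]], rownames(dm)),
                match(labs[pairs[, 2L]], rownames(dm)))]
  b <- stats::lm.fit(A, y)$coefficients
  b[is.na(b)] <- 0
  sum(pmax(b, 0))
}

## best OLS tree length over all unrooted topologies (phangorn enumeration)
bestOlsLength <- function(dm) {
  tops <- phangorn::allTrees(nrow(dm), rooted = FALSE,
                             tip.label = rownames(dm))
  min(vapply(tops, olsTreeLength, 0, dm = dm))
}

## canonical unrooted-topology comparison
sameTopology <- function(t1, t2) {
  ape::dist.topo(ape::unroot(t1), ape::unroot(t2)) == 0
}

## small valid random CDS (no internal stops), optionally with terminal stop
randomCdsString <- function(n_codons, terminal_stop = TRUE) {
  paste0(paste(sample(SENSE, n_codons, replace = TRUE), collapse = ""),
         if (terminal_stop) "TAA" else "")
}
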