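#' @importFrom ape nj write.tree read.tree prop.part
NULL

#' Distance matrix from a codon alignment
#'
#' Nucleotide-level evolutionary distances under pairwise deletion.
#' \code{p_distance} is simply 1 minus the pairwise identity;
#' \code{jukes_cantor} applies the usual correction
#' d = -(3/4) ln(1 - (4/3) p).  The maximum-composite-likelihood distance
#' used by some tree programs is deliberately not offered: cluster-level
#' classification is robust to the substitution, which is disclosed in
#' run reports.
#'
#' @param aln A \linkS4class{CodonAlignment} with at least 3 rows.
#' @param model \code{"p_distance"} (default) or \code{"jukes_cantor"}.
#' @return Symmetric distance matrix with zero diagonal and a logical
#'   \code{"saturated"} attribute flagging pairs with p >= 0.75, for
#'   which the Jukes-Cantor correction is undefined and the p-distance
#'   is substituted (with a warning).
#' @export
distanceFromAlignment <- function(aln,
                                  model = c("p_distance", "jukes_cantor")) {
  model <- match.arg(model)
  if (nrow(codonMatrix(aln)) < 3L) stop("need at least 3 rows")
  p <- 1 - identityMatrix(aln)
  saturated <- matrix(FALSE, nrow(p), ncol(p), dimnames = dimnames(p))
  d <- p
  if (model == "jukes_cantor") {
    saturated <- !is.na(p) & p >= 0.75
    diag(saturated) <- FALSE
    d[!saturated] <- -0.75 * log(1 - 4 / 3 * p[!saturated])
    if (any(saturated)) {
      warning(sprintf(
        "%d pair(s) saturated (p >= 0.75); p-distance substituted",
        sum(saturated) / 2))
      d[saturated] <- p[saturated]
    }
  }
  diag(d) <- 0
  attr(d, "saturated") <- saturated
  attr(d, "model") <- model
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor-joining agglomeration (the canonical greedy
#' heuristic for the minimum-evolution criterion); negative branch-length
#' estimates are clamped to zero.  Deterministic given the input.
#'
#' @param dm Symmetric, labeled distance matrix (>= 3 taxa, zero
#'   diagonal, non-negative entries).
#' @return An unrooted \code{phylo} tree.
#' @export
njTree <- function(dm) {
  dm <- as.matrix(dm)
  if (is.null(rownames(dm))) stop("distance matrix must be labeled")
  if (!isSymmetric(unname(dm), tol = 1e-8))
    stop("distance matrix must be symmetric")
  if (any(dm < 0) || any(diag(dm) != 0))
    stop("distances must be non-negative with zero diagonal")
  if (nrow(dm) < 3L) stop("need at least 3 taxa")
  tr <- ape::nj(dm)
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

## canonical keys for the non-trivial bipartitions of an unrooted tree:
## each split keyed by its side containing the reference tip (the
## alphabetically first label), tips sorted and pipe-joined
treeSplits <- function(tree) {
  labs <- tree$tip.label
  refTip <- sort(labs)[1L]
  n <- length(labs)
  pp <- ape::prop.part(tree)
  keys <- character(0)
  for (cl in pp) {
    side <- labs[cl]
    if (length(side) < 2L || length(side) > n - 2L) next
    if (!(refTip %in% side)) side <- setdiff(labs, side)
    keys <- c(keys, paste(sort(side), collapse = "|"))
  }
  unique(keys)
}

## split key for each internal node of `tree` (NA for trivial splits)
nodeSplitKeys <- function(tree) {
  labs <- tree$tip.label
  refTip <- sort(labs)[1L]
  n <- length(labs)
  pp <- ape::prop.part(tree)
  vapply(pp, function(cl) {
    side <- labs[cl]
    if (length(side) < 2L || length(side) > n - 2L) return(NA_character_)
    if (!(refTip %in% side)) side <- setdiff(labs, side)
    paste(sort(side), collapse = "|")
  }, "")
}

#' Neighbor-joining tree with codon-column bootstrap support
#'
#' Builds the tree from the full alignment, then resamples codon columns
#' with replacement (the alignment is codon-structured, so the codon
#' column is the resampling unit); the support of each internal edge is
#' the percentage of replicate trees containing the same bipartition.
#' All supports are retained in the returned object; rendering functions
#' suppress values below the display threshold.
#'
#' @param aln A \linkS4class{CodonAlignment}.
#' @param n_replicates Number of bootstrap replicates (default 1000).
#' @param seed Integer seed fixing the resampling.
#' @param model Distance model, see [distanceFromAlignment()].
#' @param display_threshold_pct Threshold below which rendered output
#'   suppresses supports (default 50); data are never suppressed.
#' @return A list: \code{tree} (phylo, \code{node.label} = support %,
#'   NA on trivial splits), \code{n_replicates},
#'   \code{display_threshold_pct}, \code{model}.
#' @export
bootstrapSupport <- function(aln, n_replicates = 1000, seed = NULL,
                             model = c("p_distance", "jukes_cantor"),
                             display_threshold_pct = 50) {
  model <- match.arg(model)
  stopifnot(n_replicates >= 1)
  if (!is.null(seed)) set.seed(seed)
  M <- alnToNtMatrix(aln)
  L <- ncol(M) %/% 3L
  treeFromNt <- function(Mi) {
    p <- 1 - identityFromNt(Mi)
    if (anyNA(p)) p[is.na(p)] <- 1   # incomparable under resampling: maximal
    d <- if (model == "jukes_cantor") {
      sat <- p >= 0.75
      out <- p
      out[!sat] <- -0.75 * log(1 - 4 / 3 * p[!sat])
      out
    } else p
    diag(d) <- 0
    njTree(d)
  }
  orig <- treeFromNt(M)
  keys <- nodeSplitKeys(orig)
  counts <- setNames(numeric(length(keys)), keys)
  for (r in seq_len(n_replicates)) {
    cols <- sample.int(L, L, replace = TRUE)
    ntcols <- as.vector(rbind(3L * cols - 2L, 3L * cols - 1L, 3L * cols))
    rkeys <- treeSplits(treeFromNt(M[, ntcols, drop = FALSE]))
    hit <- keys %in% rkeys
    counts[hit] <- counts[hit] + 1
  }
  support <- 100 * counts / n_replicates
  support[is.na(keys)] <- NA_real_
  orig$node.label <- ifelse(is.na(keys), "", formatC(support, format = "fg"))
  list(tree = orig, support = support, n_replicates = n_replicates,
       display_threshold_pct = display_threshold_pct, model = model)
}

#' Per-cluster monophyly report from a tree
#'
#' For every cluster label, reports whether its leaves form a clade of
#' the unrooted tree (a side of some bipartition; single-leaf clusters
#' are trivially monophyletic) and, when available, the bootstrap
#' support of the defining edge.
#'
#' @param tree A \code{phylo} tree (optionally with numeric
#'   \code{node.label} supports as produced by [bootstrapSupport()]).
#' @param labels Named character vector: cluster label per leaf (names =
#'   tip labels).
#' @return A list: \code{report} (data.frame cluster_label, n_leaves,
#'   monophyletic, support) and \code{recovered_cluster_count}.
#' @export
clustersFromTree <- function(tree, labels) {
  if (!all(tree$tip.label %in% names(labels)))
    stop("every leaf must be labeled")
  labels <- labels[tree$tip.label]
  n <- length(tree$tip.label)
  keys <- nodeSplitKeys(tree)
  supports <- if (!is.null(tree$node.label))
    suppressWarnings(as.numeric(tree$node.label)) else rep(NA_real_, length(keys))
  refTip <- sort(tree$tip.label)[1L]
  rows <- lapply(sort(unique(labels)), function(cl) {
    tips <- tree$tip.label[labels == cl]
    mono <- FALSE; supp <- NA_real_
    if (length(tips) == 1L || length(tips) == n - 1L) {
      mono <- TRUE
    } else {
      side <- if (refTip %in% tips) tips else setdiff(tree$tip.label, tips)
      key <- paste(sort(side), collapse = "|")
      hit <- which(!is.na(keys) & keys == key)
      if (length(hit)) {
        mono <- TRUE
        supp <- supports[hit[1L]]
      }
    }
    data.frame(cluster_label = cl, n_leaves = length(tips),
               monophyletic = mono, support = supp)
  })
  report <- do.call(rbind, rows)
  list(report = report,
       recovered_cluster_count = nrow(report))
}

#' Write a tree in Newick format with displayed supports
#'
#' Supports below the display threshold are blanked in the rendered file
#' (they remain in the data); branch lengths are written with six
#' significant digits.
#'
#' @param bs Result of [bootstrapSupport()], or a plain \code{phylo}.
#' @param path Output file.
#' @param display_threshold_pct Override of the display threshold.
#' @export
writeNewickTree <- function(bs, path, display_threshold_pct = NULL) {
  if (inherits(bs, "phylo")) {
    tree <- bs
    thr <- display_threshold_pct
  } else {
    tree <- bs$tree
    thr <- if (is.null(display_threshold_pct))
      bs$display_threshold_pct else display_threshold_pct
    supp <- bs$support
    lab <- ifelse(!is.na(supp) & supp >= thr,
                  formatC(supp, format = "fg"), "")
    tree$node.label <- lab
  }
  tree$edge.length <- signif(tree$edge.length, 6)
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Write / read a labeled square distance matrix TSV
#'
#' @param d Distance (or identity) matrix with dimnames.
#' @param path TSV path.
#' @export
writeDistanceTsv <- function(d, path) {
  utils::write.table(cbind(label = rownames(d), as.data.frame(d)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeDistanceTsv
#' @export
readDistanceTsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(m) <- tab[[1L]]
  storage.mode(m) <- "double"
  m
}
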