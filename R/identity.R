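NT_LEVELS <- c("A", "C", "G", "T")

## expand a codon alignment into an integer nucleotide matrix
## (A=1 C=2 G=3 T=4, gap=0), n rows x 3*ncol columns
alnToNtMatrix <- function(aln) {
  m <- codonMatrix(aln)
  n <- nrow(m); L <- ncol(m)
  out <- matrix(0L, n, 3L * L, dimnames = list(rownames(m), NULL))
  for (k in 1:3) {
    ch <- substring(m, k, k)
    ch[m == GAP_CODON] <- "-"
    out[, seq.int(k, 3L * L, by = 3L)] <-
      matrix(match(ch, NT_LEVELS, nomatch = 0L), n, L)
  }
  out
}

ntVector <- function(row) {
  if (length(row) == 1L) row <- strsplit(row, "")[[1L]]
  else if (all(nchar(row) == 3L))
    row <- unlist(strsplit(row, ""), use.names = FALSE)
  row[!row %in% NT_LEVELS] <- "-"
  row
}

#' Pairwise nucleotide sequence identity of two aligned rows
#'
#' Identity a = matching columns / compared columns, where compared
#' columns are those with a non-gap nucleotide in both rows (pairwise
#' deletion).  Computed at full precision; round only for reporting.
#'
#' @param rowA,rowB Aligned rows: nucleotide strings, per-nucleotide
#'   character vectors, or codon-token vectors (gap \code{"---"}).
#' @return Identity in [0,1]; NA (with a warning) if no column is
#'   comparable.
#' @export
pairwiseIdentity <- function(rowA, rowB) {
  a <- ntVector(rowA); b <- ntVector(rowB)
  if (length(a) != length(b)) stop("rows must have equal column counts")
  cmp <- a != "-" & b != "-"
  if (!any(cmp)) {
    warning("no comparable columns; identity indeterminate")
    return(NA_real_)
  }
  sum(a[cmp] == b[cmp]) / sum(cmp)
}

#' Pairwise identity matrix of a codon alignment
#'
#' Applies [pairwiseIdentity()] to every pair of rows at the nucleotide
#' level under pairwise deletion.  Pairs with zero comparable columns are
#' flagged as NA.
#'
#' @param aln A \linkS4class{CodonAlignment}.
#' @return Symmetric numeric matrix with unit diagonal, dimnames =
#'   record ids.
#' @export
identityMatrix <- function(aln) {
  a <- identityFromNt(alnToNtMatrix(aln))
  if (anyNA(a)) warning("pair(s) with zero comparable columns flagged NA")
  a
}

## identity matrix from an integer nucleotide matrix (0 = gap); no warnings
identityFromNt <- function(M) {
  nong <- M > 0L
  storage.mode(nong) <- "double"
  compared <- tcrossprod(nong)
  matches <- matrix(0, nrow(M), nrow(M))
  for (b in 1:4) {
    X <- M == b
    storage.mode(X) <- "double"
    matches <- matches + tcrossprod(X)
  }
  a <- matches / compared
  a[compared == 0] <- NA_real_
  diag(a) <- ifelse(diag(compared) > 0, 1, NA_real_)
  dimnames(a) <- list(rownames(M), rownames(M))
  a
}

#' Summary statistics of pairwise identities
#'
#' Mean pairwise identity (a_bar), its average absolute deviation
#' (a_bar_ad), and the largest/smallest identities over the selected
#' off-diagonal pairs, each pair counted once.
#'
#' @param m Identity matrix as from [identityMatrix()].
#' @param subset Optional selector of pairs: a character vector of labels
#'   (pairs within that set) or a logical matrix the shape of \code{m}.
#' @return One-row data.frame with columns \code{a_bar}, \code{a_bar_ad},
#'   \code{a_max}, \code{a_min}, \code{n_pairs}.
#' @export
identityStats <- function(m, subset = NULL) {
  sel <- upper.tri(m)
  if (is.character(subset)) {
    keep <- dimnames(m)[[1L]] %in% subset
    sel <- sel & outer(keep, keep, `&`)
  } else if (is.matrix(subset)) {
    sel <- (subset | t(subset)) & upper.tri(m)
  }
  vals <- m[sel]
  vals <- vals[!is.na(vals)]
  if (!length(vals)) stop("no off-diagonal pairs selected")
  a_bar <- mean(vals)
  data.frame(a_bar = a_bar, a_bar_ad = mean(abs(vals - a_bar)),
             a_max = max(vals), a_min = min(vals), n_pairs = length(vals))
}

#' Homologue band of a pairwise identity
#'
#' Classifies identities into the five homologue bands used for eutherian
#' gene families: very distant [0, 0.15), distant [0.15, 0.25), typical
#' [0.25, 0.35), close [0.35, 0.5) and very close [0.5, 1].  Boundaries
#' are half-open with the lower bound inclusive.
#'
#' @param a Numeric vector of identities in [0,1].
#' @return Factor with levels very_distant < distant < typical < close <
#'   very_close.
#' @export
classifyBand <- function(a) {
  stopifnot(all(a >= 0 & a <= 1, na.rm = TRUE))
  cut(a, breaks = c(0, 0.15, 0.25, 0.35, 0.5, 1 + 1e-9),
      labels = c("very_distant", "distant", "typical", "close", "very_close"),
      right = FALSE, ordered_result = TRUE)
}

#' Detect conserved regions between two aligned rows
#'
#' Sliding-window percent-identity criterion: an alignment position is
#' conserved when every window of \code{window_bp} columns covering it
#' has at least \code{min_identity_pct} percent matching columns (a
#' column matches when both rows carry the same non-gap nucleotide).
#' Maximal runs of conserved positions are reported in 1-based inclusive
#' alignment coordinates with their mean column identity.
#'
#' @param rowA,rowB Aligned nucleotide rows (strings or character
#'   vectors; gap \code{"-"}).
#' @param min_identity_pct Window identity threshold in percent
#'   (default 95, the strictest cut-off used for closely related
#'   genomes; 60 reproduces the relaxed cut-off used for divergent
#'   paralogues).
#' @param window_bp Window width in alignment columns (default 100).
#' @return data.frame with columns \code{start}, \code{end},
#'   \code{mean_identity}; zero rows when nothing passes.
#' @export
detectConservedRegions <- function(rowA, rowB, min_identity_pct = 95,
                                   window_bp = 100) {
  stopifnot(min_identity_pct > 0, min_identity_pct <= 100, window_bp >= 1)
  a <- ntVector(rowA); b <- ntVector(rowB)
  if (length(a) != length(b)) stop("rows must have equal column counts")
  L <- length(a)
  if (window_bp > L) stop("window_bp exceeds alignment length")
  match <- as.integer(a != "-" & b != "-" & a == b)
  cs <- c(0L, cumsum(match))
  starts <- seq_len(L - window_bp + 1L)
  winmatch <- cs[starts + window_bp] - cs[starts]
  pass <- winmatch >= min_identity_pct / 100 * window_bp
  conserved <- rep(TRUE, L)
  for (s in starts[!pass]) conserved[s:(s + window_bp - 1L)] <- FALSE
  if (!any(conserved))
    return(data.frame(start = integer(), end = integer(),
                      mean_identity = numeric()))
  r <- rle(conserved)
  ends <- cumsum(r$lengths)
  begs <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = begs[keep], end = ends[keep],
             mean_identity = mapply(function(s, e) mean(match[s:e]),
                                    begs[keep], ends[keep]))
}

#' Per-cluster per-species member counts and expansion evidence
#'
#' A cluster shows evidence of differential gene expansion when at least
#' one species carries two or more members.
#'
#' @param cds A \linkS4class{CdsSet}.
#' @return A list: \code{counts} (data.frame cluster_label, species,
#'   member_count) and \code{expanded_clusters} (character vector).
#' @export
expansionEvidence <- function(cds) {
  tab <- as.data.frame(table(cluster_label = clusterLabels(cds),
                             species = speciesNames(cds)),
                       stringsAsFactors = FALSE)
  tab <- tab[tab$Freq >= 1L, ]
  names(tab)[3L] <- "member_count"
  tab <- tab[order(tab$cluster_label, tab$species), ]
  rownames(tab) <- NULL
  expanded <- sort(unique(tab$cluster_label[tab$member_count >= 2L]))
  list(counts = tab, expanded_clusters = expanded)
}

#' Duplication timing relative to speciation
#'
#' Compares the identity between within-species paralogues with the
#' identity between cross-species orthologues.  If orthologues are more
#' similar than paralogues, the duplication predates the speciation;
#' if paralogues are more similar, it postdates it.
#'
#' @param a_paralogue_within Identity between the two paralogues within
#'   one species.
#' @param a_orthologue_cross Identity between orthologues across the two
#'   species.
#' @param margin Non-negative tolerance; verdicts inside the margin are
#'   indeterminate (default 0, raw comparison).
#' @return "predates_speciation", "postdates_speciation" or
#'   "indeterminate".
#' @export
duplicationTiming <- function(a_paralogue_within, a_orthologue_cross,
                              margin = 0) {
  stopifnot(margin >= 0,
            a_paralogue_within >= 0, a_paralogue_within <= 1,
            a_orthologue_cross >= 0, a_orthologue_cross <= 1)
  if (a_orthologue_cross > a_paralogue_within + margin)
    "predates_speciation"
  else if (a_paralogue_within > a_orthologue_cross + margin)
    "postdates_speciation"
  else "indeterminate"
}
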