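#' @importFrom Biostrings GENETIC_CODE
NULL

REGION_GROUPS <- list(extracellular = c("E1", "E2"),
                      transmembrane = c("M1", "M2", "M3", "M4"),
                      cytoplasmic = c("N", "L", "C"))

## synonymous families of the standard code: amino acid (or "*") -> codons
codonFamilies <- function(include_stop_family = TRUE) {
  fam <- split(names(GENETIC_CODE), GENETIC_CODE)
  if (!include_stop_family) fam[["*"]] <- NULL
  fam
}

#' Relative synonymous codon usage of a coding-sequence data set
#'
#' Pools codon counts over all sequences of the data set, computes
#' expected counts under uniform usage within each standard-code
#' synonymous family (family total / family size) and the ratio
#' R = observed / expected.  Codons with R at or below the threshold are
#' flagged "not preferable".  The three stop codons form one family when
#' included (the default); single-codon families (ATG, TGG) have R = 1
#' whenever observed.  An unobserved family yields undefined (NA) R.
#'
#' @param cds A \linkS4class{CdsSet}.
#' @param include_stop_family Include the stop-codon family (default
#'   TRUE).
#' @param threshold Inclusive "not preferable" cut-off on R (default
#'   0.7).
#' @return A \linkS4class{CodonUsageTable}.
#' @export
rscu <- function(cds, include_stop_family = TRUE, threshold = 0.7) {
  if (length(cds) == 0L) stop("empty coding-sequence set")
  all_codons <- unlist(lapply(as.character(cds@seqs), codonsOf),
                       use.names = FALSE)
  fam <- codonFamilies(include_stop_family)
  if (!include_stop_family)
    all_codons <- all_codons[!all_codons %in% STOP_CODONS]
  cnt <- table(factor(all_codons, levels = unlist(fam, use.names = FALSE)))
  rows <- lapply(names(fam), function(aa) {
    cods <- fam[[aa]]
    counts <- as.integer(cnt[cods])
    expected <- sum(counts) / length(cods)
    R <- if (sum(counts) > 0L) counts / expected else rep(NA_real_, length(cods))
    data.frame(codon = cods, aa = aa, family_size = length(cods),
               count = counts, expected = expected, R = R,
               not_preferable = !is.na(R) & R <= threshold)
  })
  u <- do.call(rbind, rows)
  u <- u[order(u$codon), ]
  rownames(u) <- NULL
  new("CodonUsageTable", usage = u, threshold = threshold,
      total_codons = sum(u$count))
}

#' Not-preferable codon set
#'
#' Codons whose relative synonymous codon usage R is at or below the
#' table's threshold (inclusive comparison).
#'
#' @param table A \linkS4class{CodonUsageTable}.
#' @return Character vector of codons.
#' @export
notPreferableSet <- function(table) {
  u <- usageTable(table)
  sort(u$codon[u$not_preferable])
}

#' Classify reference-anchored alignment sites
#'
#' For each reference residue's alignment column: \emph{invariant} if all
#' non-gap amino acids at the column are identical; otherwise
#' \emph{forward} if no non-gap codon at the column belongs to the
#' not-preferable set; otherwise \emph{compensatory}.  Classification is
#' at amino-acid level (sites are amino acid sites); the codon content of
#' the column only separates forward from compensatory.
#' \code{n_calculated} is the number of non-gap sequences at the column;
#' columns with fewer than \code{min_calculated} are flagged.
#'
#' @param aln A \linkS4class{CodonAlignment}.
#' @param ref A \linkS4class{ReferenceIndex} for \code{aln}.
#' @param npc Character vector of not-preferable codons (see
#'   [notPreferableSet()]).
#' @param min_calculated Minimum non-gap count for an unflagged call
#'   (default 2).
#' @return data.frame with one row per reference residue: \code{position},
#'   \code{reference_residue}, \code{class}, \code{n_calculated},
#'   \code{flagged}.
#' @export
classifySites <- function(aln, ref, npc, min_calculated = 2L) {
  m <- codonMatrix(aln)
  if (!referenceId(ref) %in% rownames(m))
    stop("reference row absent from alignment")
  col2res <- columnToResidue(ref)
  if (length(col2res) != ncol(m))
    stop("reference index does not match alignment width")
  cols <- which(!is.na(col2res))
  aa_of <- function(cod) unname(GENETIC_CODE[cod])
  rows <- lapply(cols, function(j) {
    codons <- m[, j]
    codons <- codons[codons != GAP_CODON]
    aas <- aa_of(codons)
    refres <- aa_of(m[referenceId(ref), j])
    cls <- if (length(unique(aas)) == 1L) "invariant"
      else if (!any(codons %in% npc)) "forward"
      else "compensatory"
    data.frame(position = col2res[j], reference_residue = refres,
               class = cls, n_calculated = length(codons),
               flagged = length(codons) < min_calculated)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

## ---- PROSITE-like motif patterns ----------------------------------------

#' Parse a PROSITE-like motif pattern
#'
#' Supported subset: elements separated by "-", each a literal residue
#' (one of the 20 amino-acid letters), a residue set \code{[ST]}, the
#' wildcard \code{x}, or a repeated wildcard \code{x(n)} / \code{x(n,m)}.
#'
#' @param pattern Pattern string, e.g. \code{"C-x(4,5)-C-x(5)-C"}.
#' @return List of elements, each with \code{residues} (NULL for
#'   wildcard) and \code{min}/\code{max} repeat counts; class
#'   \code{"motif_pattern"}.
#' @export
parseMotif <- function(pattern) {
  toks <- strsplit(pattern, "-", fixed = TRUE)[[1L]]
  if (!length(toks)) stop("empty motif pattern")
  els <- lapply(seq_along(toks), function(i) {
    t <- toks[i]
    if (grepl("^[ACDEFGHIKLMNPQRSTVWY]$", t))
      return(list(residues = t, min = 1L, max = 1L))
    if (grepl("^\\[[ACDEFGHIKLMNPQRSTVWY]+\\]$", t))
      return(list(residues = strsplit(substr(t, 2L, nchar(t) - 1L), "")[[1L]],
                  min = 1L, max = 1L))
    if (t == "x") return(list(residues = NULL, min = 1L, max = 1L))
    g <- regmatches(t, regexec("^x\\(([0-9]+)(,([0-9]+))?\\)$", t))[[1L]]
    if (length(g)) {
      lo <- as.integer(g[2L])
      hi <- if (nzchar(g[4L])) as.integer(g[4L]) else lo
      if (hi < lo) stop(sprintf("motif grammar error at element %d: '%s' (max < min)", i, t))
      return(list(residues = NULL, min = lo, max = hi))
    }
    stop(sprintf("motif grammar error at element %d: '%s'", i, t))
  })
  structure(els, class = "motif_pattern", pattern = pattern)
}

#' Scan a protein sequence for a motif
#'
#' Reports all (possibly overlapping) matches, leftmost-first; where a
#' variable-length wildcard \code{x(n,m)} allows alternatives, shorter
#' spans are expanded first.
#'
#' @param protein Amino-acid sequence (string, or \code{AAString}-like
#'   coercible with \code{as.character}).
#' @param pattern Pattern string or result of [parseMotif()].
#' @return data.frame of 1-based inclusive match intervals
#'   (\code{start}, \code{end}); zero rows when nothing matches.
#' @export
scanMotif <- function(protein, pattern) {
  if (!inherits(pattern, "motif_pattern")) pattern <- parseMotif(pattern)
  aa <- strsplit(as.character(protein), "")[[1L]]
  L <- length(aa)
  matchFrom <- function(pos, k) {
    if (k > length(pattern)) return(pos - 1L)   # end positions (inclusive)
    el <- pattern[[k]]
    ends <- integer(0)
    for (len in el$min:el$max) {
      if (pos + len - 1L > L) break
      if (!is.null(el$residues) && !all(aa[pos:(pos + len - 1L)] %in% el$residues))
        next
      ends <- c(ends, matchFrom(pos + len, k + 1L))
    }
    ends
  }
  out <- list()
  for (s in seq_len(L)) {
    ends <- matchFrom(s, 1L)
    if (length(ends))
      out[[length(out) + 1L]] <- data.frame(start = s, end = unique(ends))
  }
  if (!length(out))
    return(data.frame(start = integer(), end = integer()))
  unique(do.call(rbind, out))
}

## ---- alignment-level annotations ----------------------------------------

alnRows <- function(proteins_aligned) {
  prot <- if (is(proteins_aligned, "AAStringSet"))
    as.character(proteins_aligned) else proteins_aligned
  rows <- strsplit(prot, "")
  if (length(unique(lengths(rows))) > 1L)
    stop("alignment rows must have equal widths")
  rows
}

#' Common predicted N-glycosylation sequon columns of a cluster alignment
#'
#' A column carries a common sequon when every sequence that is non-gap
#' at the column has an N-x-[ST] motif starting at that residue in its
#' own (ungapped) sequence; rows gapped at the column do not veto.
#'
#' @param proteins_aligned Aligned proteins of one cluster
#'   (\code{AAStringSet} or named character vector; gap "-").
#' @param exclude_proline_x If TRUE apply the common refinement x != P
#'   (default FALSE: the bare motif).
#' @return Integer vector of 1-based alignment columns carrying a common
#'   sequon.
#' @export
annotateNglyc <- function(proteins_aligned, exclude_proline_x = FALSE) {
  rows <- alnRows(proteins_aligned)
  L <- length(rows[[1L]])
  seqs <- lapply(rows, function(r) r[r != "-"])
  idx <- lapply(rows, function(r) cumsum(r != "-"))
  hasSequon <- function(s, i) {
    i + 2L <= length(s) && s[i] == "N" && s[i + 2L] %in% c("S", "T") &&
      (!exclude_proline_x || s[i + 1L] != "P")
  }
  common <- vapply(seq_len(L), function(c) {
    nong <- vapply(rows, function(r) r[c] != "-", TRUE)
    if (!any(nong)) return(FALSE)
    all(vapply(which(nong), function(k)
      hasSequon(seqs[[k]], idx[[k]][c]), TRUE))
  }, TRUE)
  which(common)
}

#' Common cysteine columns of a cluster alignment
#'
#' Columns at which every non-gap residue is a cysteine; rows gapped at
#' the column do not veto.
#'
#' @inheritParams annotateNglyc
#' @return Integer vector of 1-based alignment columns.
#' @export
commonCysteines <- function(proteins_aligned) {
  rows <- alnRows(proteins_aligned)
  mat <- do.call(rbind, rows)
  which(apply(mat, 2L, function(col) {
    nong <- col != "-"
    any(nong) && all(col[nong] == "C")
  }))
}

## ---- region-partitioned statistics ---------------------------------------

#' Read a region map TSV
#'
#' @param path TSV with columns \code{label}, \code{start}, \code{end}
#'   (1-based inclusive reference residue coordinates; labels from
#'   N, M1, E1, M2, L, M3, E2, M4, C).
#' @param reference_length Optional check that the map covers exactly
#'   1..reference_length.
#' @return A \linkS4class{RegionMap}.
#' @export
readRegionMap <- function(path, reference_length = NULL) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  RegionMap(tab, reference_length)
}

#' @rdname readRegionMap
#' @param regions data.frame with columns label/start/end.
#' @export
RegionMap <- function(regions, reference_length = NULL) {
  regions <- regions[order(regions$start), c("label", "start", "end")]
  rownames(regions) <- NULL
  obj <- new("RegionMap", regions = regions)
  if (!is.null(reference_length) && max(regions$end) != reference_length)
    stop(sprintf("region map covers 1-%d but reference has %d residues",
                 max(regions$end), reference_length))
  obj
}

## label of each reference residue 1..len under a RegionMap
residueRegions <- function(region_map, len = NULL) {
  r <- regionTable(region_map)
  if (is.null(len)) len <- max(r$end)
  out <- rep(NA_character_, len)
  for (i in seq_len(nrow(r)))
    out[r$start[i]:min(r$end[i], len)] <- r$label[i]
  out
}

#' Identity statistics restricted to protein regions
#'
#' Restricts the codon alignment to the columns whose reference residues
#' fall in each region group (extracellular = E1+E2, transmembrane =
#' M1-M4, cytoplasmic = N+L+C, or each region separately), then computes
#' the pairwise identity matrix and its summary statistics on the
#' restriction.
#'
#' @param aln A \linkS4class{CodonAlignment}.
#' @param ref A \linkS4class{ReferenceIndex} for \code{aln}.
#' @param region_map A \linkS4class{RegionMap} covering the reference.
#' @param grouping \code{"extracellular"}, \code{"transmembrane"},
#'   \code{"cytoplasmic"} or \code{"per_region"}.
#' @return data.frame with a \code{group} column plus the columns of
#'   [identityStats()].
#' @export
regionIdentityStats <- function(aln, ref, region_map,
                                grouping = c("extracellular", "transmembrane",
                                             "cytoplasmic", "per_region")) {
  grouping <- match.arg(grouping)
  col2res <- columnToResidue(ref)
  reflen <- sum(!is.na(col2res))
  if (max(regionTable(region_map)$end) != reflen)
    stop("region map does not cover the reference")
  reg <- residueRegions(region_map, reflen)
  groups <- if (grouping == "per_region")
    split(REGION_LABELS[REGION_LABELS %in% reg],
          REGION_LABELS[REGION_LABELS %in% reg])
  else REGION_GROUPS[grouping]
  m <- codonMatrix(aln)
  out <- lapply(names(groups), function(g) {
    residues <- which(reg %in% groups[[g]])
    cols <- which(!is.na(col2res) & col2res %in% residues)
    if (!length(cols)) stop(sprintf("no alignment columns in group '%s'", g))
    sub <- new("CodonAlignment", codons = m[, cols, drop = FALSE])
    cbind(group = g, identityStats(suppressWarnings(identityMatrix(sub))))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write a codon usage table / site report / TSV helper
#'
#' @param x data.frame-like object (e.g. [usageTable()], a site report
#'   or motif matches).
#' @param path Output TSV path.
#' @export
writeTsv <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
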