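#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

GAP_CODON <- "---"

#' CdsSet: a set of in-frame coding sequences with record metadata
#'
#' Container for complete coding sequences (CDSs) of one gene family.
#' Each record carries a unique identifier, the species it was annotated
#' in, a major-cluster label (the family subdivision used throughout the
#' analyses) and an optional gene name.  Sequence data live in a
#' \linkS4class{DNAStringSet}; every sequence must be in frame (length a
#' multiple of three), fully resolved (A/C/G/T only; ambiguity codes are
#' rejected because the completeness test requires every nucleotide
#' supported) and free of internal stop codons.
#'
#' @slot seqs A \linkS4class{DNAStringSet}, names = record ids.
#' @slot meta A \linkS4class{DataFrame} with columns \code{record_id},
#'   \code{species}, \code{cluster_label}, \code{gene_name}.
#'
#' @seealso [readCdsFasta()], [translateCds()], [buildCodonAlignment()]
#' @export
setClass("CdsSet",
  representation(seqs = "DNAStringSet", meta = "DataFrame"))

setValidity("CdsSet", function(object) {
  msgs <- character()
  n <- length(object@seqs)
  if (nrow(object@meta) != n)
    msgs <- c(msgs, "meta must have one row per sequence")
  need <- c("record_id", "species", "cluster_label", "gene_name")
  if (!all(need %in% colnames(object@meta)))
    msgs <- c(msgs, paste("meta must have columns:", paste(need, collapse = ", ")))
  else {
    ids <- object@meta$record_id
    if (anyDuplicated(ids)) msgs <- c(msgs, "record_id values must be unique")
    if (!identical(names(object@seqs), as.character(ids)))
      msgs <- c(msgs, "names(seqs) must equal meta$record_id")
    probs <- cdsProblems(object@seqs)
    if (nrow(probs) > 0L)
      msgs <- c(msgs, sprintf("invalid CDS record(s): %s",
        paste(sprintf("%s (%s)", probs$record_id, probs$problem), collapse = "; ")))
  }
  if (length(msgs)) msgs else TRUE
})

#' CodonAlignment: gap-aware codon matrix
#'
#' A codon-structured multiple alignment: one row per record, one column
#' per aligned codon.  Cells are three-letter codons or the whole-codon
#' gap token \code{"---"}; gaps only ever occur in whole-codon units
#' because the alignment is back-translated from a protein alignment.
#' Degapping a row reproduces that record's codon list (terminal stop
#' codons, which have no aligned protein residue, are excluded).
#'
#' @slot codons Character matrix of codon tokens; rownames = record ids.
#'
#' @seealso [buildCodonAlignment()], [identityMatrix()],
#'   [distanceFromAlignment()], [classifySites()]
#' @export
setClass("CodonAlignment", representation(codons = "matrix"))

setValidity("CodonAlignment", function(object) {
  m <- object@codons
  if (!is.character(m)) return("codons must be a character matrix")
  if (is.null(rownames(m)) || anyDuplicated(rownames(m)))
    return("codons must have unique rownames (record ids)")
  ok <- m == GAP_CODON | grepl("^[ACGT]{3}$", m)
  if (!all(ok)) {
    bad <- which(!ok, arr.ind = TRUE)[1L, ]
    return(sprintf("invalid codon token '%s' at row %d column %d",
                   m[bad[1L], bad[2L]], bad[1L], bad[2L]))
  }
  TRUE
})

#' ReferenceIndex: alignment column to reference residue map
#'
#' Anchors alignment columns to 1-based residue numbers of a chosen
#' reference record, so that sites can be reported in the field's usual
#' "W44" style.  Columns where the reference is gapped map to NA.
#'
#' @slot reference_id Record id of the reference row.
#' @slot column_to_residue Integer vector, one entry per alignment
#'   column; NA at reference-gap columns, otherwise the 1-based residue
#'   number, strictly increasing over non-gap columns.
#'
#' @seealso [referenceIndex()], [classifySites()], [regionIdentityStats()]
#' @export
setClass("ReferenceIndex",
  representation(reference_id = "character", column_to_residue = "integer"))

setValidity("ReferenceIndex", function(object) {
  v <- object@column_to_residue[!is.na(object@column_to_residue)]
  if (length(v) && (any(diff(v) <= 0L) || v[1L] != 1L ||
      !identical(v, seq_len(length(v)))))
    return("residue numbers must run 1..reference length over non-gap columns")
  TRUE
})

#' RegionMap: labeled topological segments over reference residues
#'
#' Partition of the reference protein into contiguous labeled intervals:
#' cytoplasmic N-terminus (N), four transmembrane helices (M1-M4), two
#' extracellular loops (E1, E2), cytoplasmic loop (L) and C-terminal
#' domain (C).  Intervals are 1-based, inclusive, non-overlapping and
#' must cover residues 1..reference length without holes.
#'
#' @slot regions data.frame with columns \code{label}, \code{start},
#'   \code{end} (1-based inclusive reference residue coordinates).
#'
#' @seealso [readRegionMap()], [regionIdentityStats()]
#' @export
setClass("RegionMap", representation(regions = "data.frame"))

REGION_LABELS <- c("N", "M1", "E1", "M2", "L", "M3", "E2", "M4", "C")

setValidity("RegionMap", function(object) {
  r <- object@regions
  need <- c("label", "start", "end")
  if (!all(need %in% colnames(r))) return("regions needs label/start/end columns")
  if (!all(r$label %in% REGION_LABELS))
    return(sprintf("unknown region label(s): %s",
                   paste(setdiff(r$label, REGION_LABELS), collapse = ", ")))
  r <- r[order(r$start), ]
  if (r$start[1L] != 1L) return("regions must start at residue 1")
  if (any(r$end < r$start)) return("region end < start")
  if (nrow(r) > 1L && any(r$start[-1L] != r$end[-nrow(r)] + 1L))
    return("regions must be contiguous and non-overlapping")
  TRUE
})

#' CodonUsageTable: pooled relative synonymous codon usage
#'
#' Per-codon observed counts pooled over a coding-sequence data set,
#' expected counts under uniform usage within each synonymous family
#' (family total / family size), their ratio R, and the "not preferable"
#' flag R <= threshold.  Synonymous families are the standard-code amino
#' acid families; the three stop codons form one family when included.
#'
#' @slot usage data.frame with columns \code{codon}, \code{aa},
#'   \code{family_size}, \code{count}, \code{expected}, \code{R},
#'   \code{not_preferable}.
#' @slot threshold Numeric, the inclusive R cut-off (default 0.7).
#' @slot total_codons Integer, total codons pooled.
#'
#' @seealso [rscu()], [notPreferableSet()], [classifySites()]
#' @export
setClass("CodonUsageTable",
  representation(usage = "data.frame", threshold = "numeric",
                 total_codons = "integer"))

setValidity("CodonUsageTable", function(object) {
  u <- object@usage
  need <- c("codon", "aa", "family_size", "count", "expected", "R",
            "not_preferable")
  if (!all(need %in% colnames(u)))
    return(paste("usage needs columns:", paste(need, collapse = ", ")))
  if (sum(u$count) != object@total_codons)
    return("sum of counts must equal total_codons")
  TRUE
})
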