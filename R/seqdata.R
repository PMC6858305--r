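#' @importFrom Biostrings DNAStringSet AAStringSet readDNAStringSet
#'   readAAStringSet writeXStringSet translate GENETIC_CODE
#' @importFrom S4Vectors DataFrame
NULL

STOP_CODONS <- c("TAA", "TAG", "TGA")

## per-record invariant check used by the CdsSet validity method and by
## readCdsFasta error reporting; returns a data.frame of problems
cdsProblems <- function(seqs) {
  ids <- names(seqs)
  if (is.null(ids)) ids <- as.character(seq_along(seqs))
  out <- list()
  ss <- as.character(seqs)
  for (i in seq_along(ss)) {
    s <- ss[[i]]
    if (grepl("[^ACGT]", s)) {
      out[[length(out) + 1L]] <- c(ids[i], "non-ACGT character (ambiguity codes rejected)")
      next
    }
    if (nchar(s) %% 3L != 0L) {
      out[[length(out) + 1L]] <- c(ids[i], sprintf("length %d not divisible by 3", nchar(s)))
      next
    }
    cods <- codonsOf(s)
    internal <- cods[-length(cods)]
    hit <- which(internal %in% STOP_CODONS)
    if (length(hit))
      out[[length(out) + 1L]] <-
        c(ids[i], sprintf("internal stop codon at codon %d", hit[1L]))
  }
  if (!length(out))
    return(data.frame(record_id = character(), problem = character()))
  m <- do.call(rbind, out)
  data.frame(record_id = m[, 1L], problem = m[, 2L])
}

codonsOf <- function(s) {
  n <- nchar(s) %/% 3L
  if (n == 0L) return(character(0))
  substring(s, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

#' Construct a CdsSet
#'
#' @param nt Named character vector or \code{DNAStringSet} of in-frame
#'   coding sequences.
#' @param species,cluster_label,gene_name Character vectors recycled to
#'   the number of records.
#' @return A \linkS4class{CdsSet}.
#' @export
CdsSet <- function(nt, species, cluster_label, gene_name = NA_character_) {
  seqs <- if (is(nt, "DNAStringSet")) nt else DNAStringSet(nt)
  n <- length(seqs)
  meta <- DataFrame(record_id = names(seqs),
                    species = rep_len(species, n),
                    cluster_label = rep_len(cluster_label, n),
                    gene_name = rep_len(gene_name, n))
  new("CdsSet", seqs = seqs, meta = meta)
}

#' Read coding sequences with metadata from FASTA
#'
#' Reads a FASTA file of in-frame coding sequences and attaches per-record
#' metadata using one of two conventions: pipe-delimited headers
#' (\code{id|species|cluster} or \code{id|species|cluster|gene}) or a
#' sidecar TSV (columns \code{record_id}, \code{species},
#' \code{cluster_label}, optional \code{gene_name}) keyed by the FASTA id.
#' All CdsSet invariants are enforced: records violating them are reported
#' by id with the reason, never silently dropped.
#'
#' @param path FASTA file of coding sequences.
#' @param metadata_convention \code{"pipe_header"} (default) or
#'   \code{"sidecar_tsv"}.
#' @param sidecar Path to the metadata TSV when
#'   \code{metadata_convention = "sidecar_tsv"}.
#' @param strict If TRUE (default) any invalid record aborts with an error
#'   naming every offending record; if FALSE invalid records are dropped
#'   with a warning listing them.
#' @return A \linkS4class{CdsSet}.
#' @export
readCdsFasta <- function(path,
                         metadata_convention = c("pipe_header", "sidecar_tsv"),
                         sidecar = NULL, strict = TRUE) {
  metadata_convention <- match.arg(metadata_convention)
  seqs <- readDNAStringSet(path)
  headers <- names(seqs)
  if (metadata_convention == "pipe_header") {
    parts <- strsplit(sub(" .*$", "", headers), "|", fixed = TRUE)
    nf <- lengths(parts)
    if (any(nf < 3L))
      stop(sprintf("malformed header (need id|species|cluster): '%s'",
                   headers[which(nf < 3L)[1L]]))
    meta <- DataFrame(
      record_id = vapply(parts, `[`, "", 1L),
      species = vapply(parts, `[`, "", 2L),
      cluster_label = vapply(parts, `[`, "", 3L),
      gene_name = vapply(parts, function(p)
        if (length(p) >= 4L) p[[4L]] else NA_character_, ""))
  } else {
    if (is.null(sidecar)) stop("sidecar_tsv convention requires 'sidecar'")
    tab <- utils::read.delim(sidecar, stringsAsFactors = FALSE)
    need <- c("record_id", "species", "cluster_label")
    if (!all(need %in% colnames(tab)))
      stop("sidecar TSV needs columns record_id, species, cluster_label")
    ids <- sub(" .*$", "", headers)
    hit <- match(ids, tab$record_id)
    if (anyNA(hit))
      stop(sprintf("no sidecar metadata for record(s): %s",
                   paste(ids[is.na(hit)], collapse = ", ")))
    meta <- DataFrame(
      record_id = ids,
      species = tab$species[hit],
      cluster_label = tab$cluster_label[hit],
      gene_name = if ("gene_name" %in% colnames(tab))
        tab$gene_name[hit] else NA_character_)
  }
  if (anyDuplicated(meta$record_id))
    stop(sprintf("duplicate record id(s): %s",
      paste(unique(meta$record_id[duplicated(meta$record_id)]), collapse = ", ")))
  names(seqs) <- meta$record_id
  probs <- cdsProblems(seqs)
  if (nrow(probs) > 0L) {
    txt <- paste(sprintf("%s: %s", probs$record_id, probs$problem),
                 collapse = "; ")
    if (strict) stop("invalid CDS record(s): ", txt)
    warning("dropping invalid CDS record(s): ", txt)
    keep <- !(meta$record_id %in% probs$record_id)
    seqs <- seqs[keep]
    meta <- meta[keep, ]
  }
  new("CdsSet", seqs = seqs, meta = meta)
}

#' Write a CdsSet to FASTA
#'
#' Inverse of [readCdsFasta()] under the pipe-header convention, so that
#' a read/write/read round trip is the identity on records.
#'
#' @param x A \linkS4class{CdsSet}.
#' @param path Output file.
#' @export
writeCdsFasta <- function(x, path) {
  out <- x@seqs
  gene <- ifelse(is.na(x@meta$gene_name), "", paste0("|", x@meta$gene_name))
  names(out) <- paste0(x@meta$record_id, "|", x@meta$species, "|",
                       x@meta$cluster_label, gene)
  writeXStringSet(out, path)
  invisible(path)
}

#' Translate coding sequences
#'
#' Standard nuclear genetic code; a terminal stop codon is dropped, so a
#' CDS ending in a stop yields codon count minus one residues.
#'
#' @param x A \linkS4class{CdsSet}.
#' @return An \code{AAStringSet} named by record id.
#' @export
translateCds <- function(x) {
  aa <- translate(x@seqs, if.fuzzy.codon = "error")
  chr <- as.character(aa)
  chr <- sub("\\*$", "", chr)
  if (any(grepl("\\*", chr)))
    stop("internal stop codon after translation (corrupt CdsSet)")
  out <- AAStringSet(chr)
  names(out) <- names(x@seqs)
  out
}

#' Back-translate a protein alignment into a codon alignment
#'
#' The protein aligner is pluggable input (alignments of this kind are
#' typically hand-corrected); this function only verifies consistency and
#' back-translates.  Each aligned protein row, degapped, must equal the
#' translation of the matching CDS; every amino-acid column then maps to
#' exactly one codon column and protein gaps become whole-codon gaps.
#'
#' @param proteins_aligned Aligned proteins (\code{AAStringSet} of equal
#'   widths, or named character vector); gap character \code{"-"}.
#' @param cds A \linkS4class{CdsSet} holding a CDS for every row.
#' @return A \linkS4class{CodonAlignment} with rows in alignment order.
#' @export
buildCodonAlignment <- function(proteins_aligned, cds) {
  prot <- if (is(proteins_aligned, "AAStringSet"))
    as.character(proteins_aligned) else proteins_aligned
  if (is.null(names(prot))) stop("protein alignment rows must be named")
  if (length(unique(nchar(prot))) != 1L)
    stop("protein alignment rows must have equal widths")
  hit <- match(names(prot), recordIds(cds))
  if (anyNA(hit))
    stop(sprintf("no CDS for aligned record(s): %s",
                 paste(names(prot)[is.na(hit)], collapse = ", ")))
  trans <- as.character(translateCds(cds))[hit]
  ntall <- as.character(cds@seqs)[hit]
  ncol <- nchar(prot[[1L]])
  m <- matrix(GAP_CODON, nrow = length(prot), ncol = ncol,
              dimnames = list(names(prot), NULL))
  for (i in seq_along(prot)) {
    row <- strsplit(prot[[i]], "")[[1L]]
    nong <- which(row != "-")
    deg <- paste(row[nong], collapse = "")
    if (deg != trans[[i]]) {
      d <- which(strsplit(deg, "")[[1L]] != strsplit(trans[[i]], "")[[1L]])
      stop(sprintf(
        "aligned protein for '%s' does not match translated CDS (first discrepancy at residue %d)",
        names(prot)[i], if (length(d)) d[1L] else min(nchar(deg), nchar(trans[[i]])) + 1L))
    }
    cods <- codonsOf(ntall[[i]])
    if (length(cods) == length(nong) + 1L && cods[length(cods)] %in% STOP_CODONS)
      cods <- cods[-length(cods)]
    if (length(cods) != length(nong))
      stop(sprintf("codon count mismatch for '%s'", names(prot)[i]))
    m[i, nong] <- cods
  }
  new("CodonAlignment", codons = m)
}

#' Build a reference index for a codon alignment
#'
#' @param aln A \linkS4class{CodonAlignment}.
#' @param reference_id Record id of the reference row.
#' @return A \linkS4class{ReferenceIndex} mapping alignment columns to
#'   1-based reference residue numbers (NA at reference-gap columns).
#' @export
referenceIndex <- function(aln, reference_id) {
  m <- aln@codons
  if (!reference_id %in% rownames(m))
    stop(sprintf("reference record '%s' not in alignment", reference_id))
  ref <- m[reference_id, ]
  col2res <- rep(NA_integer_, length(ref))
  col2res[ref != GAP_CODON] <- seq_len(sum(ref != GAP_CODON))
  new("ReferenceIndex", reference_id = reference_id,
      column_to_residue = col2res)
}

## degapped codon list of one alignment row
degapRow <- function(aln, id) {
  row <- aln@codons[id, ]
  unname(row[row != GAP_CODON])
}

#' Read an aligned protein FASTA
#'
#' @param path Aligned FASTA (equal-width rows, gap character "-").
#' @return Named character vector of aligned rows.
#' @export
readProteinAlignment <- function(path) {
  aa <- readAAStringSet(path)
  out <- as.character(aa)
  names(out) <- sub(" .*$", "", names(aa))
  if (length(unique(nchar(out))) > 1L)
    stop("alignment rows have unequal widths")
  out
}

## ---- accessors & show methods -------------------------------------------

#' @rdname CdsSet-class
#' @export
setMethod("recordIds", "CdsSet", function(x) as.character(x@meta$record_id))
#' @rdname CdsSet-class
#' @export
setMethod("speciesNames", "CdsSet", function(x) as.character(x@meta$species))
#' @rdname CdsSet-class
#' @export
setMethod("clusterLabels", "CdsSet", function(x) as.character(x@meta$cluster_label))
#' @rdname CdsSet-class
#' @export
setMethod("geneNames", "CdsSet", function(x) as.character(x@meta$gene_name))
#' @rdname CdsSet-class
#' @export
setMethod("length", "CdsSet", function(x) length(x@seqs))

#' @rdname CdsSet-class
#' @param i Index (logical, integer or record-id character vector).
#' @export
setMethod("[", "CdsSet", function(x, i) {
  if (is.character(i)) i <- match(i, recordIds(x))
  new("CdsSet", seqs = x@seqs[i], meta = x@meta[i, , drop = FALSE])
})

#' @rdname CdsSet-class
#' @export
sequencesOf <- function(x) x@seqs

setMethod("show", "CdsSet", function(object) {
  cat(sprintf("CdsSet with %d coding sequence(s): %d cluster(s), %d species\n",
              length(object@seqs),
              length(unique(object@meta$cluster_label)),
              length(unique(object@meta$species))))
})

#' @rdname CodonAlignment-class
#' @export
setMethod("codonMatrix", "CodonAlignment", function(x) x@codons)
#' @rdname CodonAlignment-class
#' @export
setMethod("nCodonColumns", "CodonAlignment", function(x) ncol(x@codons))
#' @rdname CodonAlignment-class
#' @export
setMethod("recordIds", "CodonAlignment", function(x) rownames(x@codons))

setMethod("show", "CodonAlignment", function(object) {
  cat(sprintf("CodonAlignment: %d row(s) x %d codon column(s)\n",
              nrow(object@codons), ncol(object@codons)))
})

#' @rdname ReferenceIndex-class
#' @export
setMethod("referenceId", "ReferenceIndex", function(x) x@reference_id)
#' @rdname ReferenceIndex-class
#' @export
setMethod("columnToResidue", "ReferenceIndex", function(x) x@column_to_residue)

setMethod("show", "ReferenceIndex", function(object) {
  cat(sprintf("ReferenceIndex on '%s': %d residues over %d columns\n",
              object@reference_id,
              sum(!is.na(object@column_to_residue)),
              length(object@column_to_residue)))
})

#' @rdname RegionMap-class
#' @export
setMethod("regionTable", "RegionMap", function(x) x@regions)

setMethod("show", "RegionMap", function(object) {
  r <- object@regions
  cat(sprintf("RegionMap covering residues 1-%d: %s\n", max(r$end),
              paste(sprintf("%s[%d-%d]", r$label, r$start, r$end),
                    collapse = " ")))
})

#' @rdname CodonUsageTable-class
#' @export
setMethod("usageTable", "CodonUsageTable", function(x) x@usage)

setMethod("show", "CodonUsageTable", function(object) {
  cat(sprintf(
    "CodonUsageTable: %d codons pooled; %d not-preferable codon(s) at R <= %g\n",
    object@total_codons, sum(object@usage$not_preferable, na.rm = TRUE),
    object@threshold))
})
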