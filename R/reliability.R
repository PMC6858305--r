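#' @importFrom IRanges IRanges coverage
NULL

#' Per-nucleotide read coverage from alignment intervals
#'
#' The reliability test for public genomic sequence asks whether every
#' nucleotide of a candidate coding sequence is supported by at least one
#' sequencing read.  Read support arrives as a table of 1-based inclusive
#' alignment intervals on the candidate CDS.
#'
#' @param cds_length Length of the candidate CDS in nucleotides.
#' @param intervals data.frame with columns \code{read_id}, \code{start},
#'   \code{end} (1-based inclusive); may have zero rows.
#' @return Integer vector of per-position depths, length
#'   \code{cds_length}.
#' @export
coverageFromIntervals <- function(cds_length, intervals) {
  stopifnot(is.numeric(cds_length), cds_length >= 1)
  if (is.null(intervals) || nrow(intervals) == 0L)
    return(integer(cds_length))
  bad <- intervals$start < 1L | intervals$end > cds_length |
    intervals$start > intervals$end
  if (any(bad))
    stop(sprintf("interval out of bounds for read(s): %s",
                 paste(intervals$read_id[bad], collapse = ", ")))
  ir <- IRanges(start = intervals$start, end = intervals$end)
  as.integer(coverage(ir, width = cds_length))
}

#' Classify a coverage profile as complete or putative
#'
#' A candidate is a complete coding sequence only if read coverage is
#' available for every nucleotide (depth >= \code{min_depth} at every
#' position); otherwise it is putative and excluded from downstream
#' analyses.
#'
#' @param depth Integer vector of per-position depths.
#' @param min_depth Depth threshold, default 1.
#' @return A list with \code{status} ("complete"/"putative"),
#'   \code{first_uncovered} (position or NA) and \code{uncovered_count}.
#' @export
classifyCompleteness <- function(depth, min_depth = 1L) {
  unc <- which(depth < min_depth)
  list(status = if (length(unc)) "putative" else "complete",
       first_uncovered = if (length(unc)) unc[1L] else NA_integer_,
       uncovered_count = length(unc))
}

#' Read a read-interval TSV
#'
#' @param path TSV with columns \code{record_id}, \code{read_id},
#'   \code{start}, \code{end}.
#' @return data.frame of intervals.
#' @export
readReadIntervals <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("record_id", "read_id", "start", "end")
  if (!all(need %in% colnames(tab)))
    stop("interval TSV needs columns record_id, read_id, start, end")
  tab
}

#' Batch reliability verdicts for a set of candidates
#'
#' @param cds_lengths Named integer vector of candidate CDS lengths
#'   (names = record ids).
#' @param intervals Interval data.frame as from [readReadIntervals()].
#' @param min_depth Depth threshold, default 1.
#' @return data.frame with one row per candidate: \code{record_id},
#'   \code{status}, \code{first_uncovered}, \code{uncovered_count}.
#' @export
reliabilityVerdicts <- function(cds_lengths, intervals, min_depth = 1L) {
  ids <- names(cds_lengths)
  out <- lapply(ids, function(id) {
    iv <- intervals[intervals$record_id == id, , drop = FALSE]
    v <- classifyCompleteness(
      coverageFromIntervals(cds_lengths[[id]], iv), min_depth)
    data.frame(record_id = id, status = v$status,
               first_uncovered = v$first_uncovered,
               uncovered_count = v$uncovered_count)
  })
  do.call(rbind, out)
}
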