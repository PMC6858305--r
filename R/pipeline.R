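#' @importFrom jsonlite write_json
#' @importFrom yaml read_yaml
NULL

CYS_MOTIFS <- c("C-x(6)-C-x(3)-C", "C-x(10)-C",
                "C-x(4,5)-C-x(5)-C", "C-x(12,13)-C")

#' Run the full comparative-genomic analysis pipeline
#'
#' Orchestrates the stages in order: reliability classification (putative
#' candidates are excluded from everything downstream), alignment
#' consistency and codon-alignment construction, pairwise identity
#' analysis (matrix, summary statistics, cluster-pair bands, expansion
#' evidence), distance tree with bootstrap and per-cluster monophyly, and
#' the protein molecular-evolution test (codon usage, not-preferable set,
#' reference-anchored site classification, cysteine/sequon annotation,
#' region-partitioned statistics).  Emits one TSV per table, a Newick
#' tree and a machine-readable JSON run report whose every number is
#' recomputable from the emitted tables.  Deterministic given the seed.
#'
#' @param config Path to a YAML config file, or an equivalent named list.
#'   Recognised fields: \code{cds_fasta}, \code{metadata_convention},
#'   \code{sidecar}, \code{protein_alignment}, \code{intervals_tsv},
#'   \code{reference_id}, \code{region_map}, \code{distance_model},
#'   \code{bootstrap_replicates}, \code{display_threshold_pct},
#'   \code{rscu_threshold}, \code{seed}.
#' @param out_dir Output directory (created if needed).
#' @return The run report, invisibly (also written as
#'   \code{run_report.json}).
#' @export
runPipeline <- function(config, out_dir) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  if (is.null(cfg$cds_fasta)) stop("configuration error: 'cds_fasta' missing")
  cds <- readCdsFasta(cfg$cds_fasta,
                      metadata_convention = cfg$metadata_convention %||% "pipe_header",
                      sidecar = cfg$sidecar)
  prot <- if (!is.null(cfg$protein_alignment))
    readProteinAlignment(cfg$protein_alignment) else NULL
  intervals <- if (!is.null(cfg$intervals_tsv))
    readReadIntervals(cfg$intervals_tsv) else NULL
  region_map <- if (!is.null(cfg$region_map))
    readRegionMap(cfg$region_map) else NULL
  runPipelineData(cds, proteins_aligned = prot, intervals = intervals,
                  reference_id = cfg$reference_id, region_map = region_map,
                  distance_model = cfg$distance_model %||% "p_distance",
                  bootstrap_replicates = cfg$bootstrap_replicates %||% 1000,
                  display_threshold_pct = cfg$display_threshold_pct %||% 50,
                  rscu_threshold = cfg$rscu_threshold %||% 0.7,
                  seed = cfg$seed %||% 1,
                  out_dir = out_dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname runPipeline
#' @param cds A \linkS4class{CdsSet} of candidate coding sequences.
#' @param proteins_aligned Aligned proteins (named character /
#'   AAStringSet); if NULL the translations must already be of equal
#'   length (no-indel family) and are used as a trivial alignment.
#' @param intervals Read-interval data.frame for the reliability stage
#'   (NULL skips the stage: all records treated as complete).
#' @param reference_id Reference record for site classification (NULL
#'   skips reference-anchored outputs).
#' @param region_map A \linkS4class{RegionMap} (NULL skips region
#'   statistics).
#' @param distance_model,bootstrap_replicates,display_threshold_pct
#'   Tree-stage settings.
#' @param rscu_threshold Inclusive not-preferable cut-off on R.
#' @param seed Integer seed for all randomness (bootstrap).
#' @export
runPipelineData <- function(cds, proteins_aligned = NULL, intervals = NULL,
                            reference_id = NULL, region_map = NULL,
                            distance_model = "p_distance",
                            bootstrap_replicates = 1000,
                            display_threshold_pct = 50,
                            rscu_threshold = 0.7, seed = 1, out_dir) {
  if (length(cds) == 0L) stop("configuration error: empty input")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(software = "famevol",
                 version = as.character(utils::packageVersion("famevol")),
                 seed = seed,
                 config = list(distance_model = distance_model,
                               bootstrap_replicates = bootstrap_replicates,
                               display_threshold_pct = display_threshold_pct,
                               rscu_threshold = rscu_threshold,
                               reference_id = reference_id))
  stageFail <- function(stage, e)
    stop(sprintf("pipeline halted at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)

  ## stage 1: reliability -----------------------------------------------
  n_in <- length(cds)
  if (!is.null(intervals)) {
    verdicts <- tryCatch({
      lens <- setNames(Biostrings::width(sequencesOf(cds)), recordIds(cds))
      reliabilityVerdicts(lens, intervals)
    }, error = function(e) stageFail("reliability", e))
    writeTsv(verdicts, file.path(out_dir, "reliability_verdicts.tsv"))
    keep <- verdicts$record_id[verdicts$status == "complete"]
    cds <- cds[recordIds(cds) %in% keep]
    if (length(cds) == 0L)
      stop("pipeline halted at stage 'reliability': no complete sequences")
  }
  message(sprintf("[reliability] in=%d complete=%d putative=%d",
                  n_in, length(cds), n_in - length(cds)))
  report$reliability <- list(candidates = n_in, complete = length(cds),
                             putative = n_in - length(cds))

  ## stage 2: alignment consistency --------------------------------------
  aln <- tryCatch({
    if (is.null(proteins_aligned)) {
      tr <- translateCds(cds)
      if (length(unique(nchar(as.character(tr)))) != 1L)
        stop("translations have unequal lengths; a protein alignment is required")
      proteins_aligned <- as.character(tr)
    } else {
      proteins_aligned <- proteins_aligned[
        names(proteins_aligned) %in% recordIds(cds)]
    }
    buildCodonAlignment(proteins_aligned, cds)
  }, error = function(e) stageFail("alignment", e))
  cds <- cds[recordIds(aln)]
  message(sprintf("[alignment] rows=%d codon_columns=%d",
                  nrow(codonMatrix(aln)), nCodonColumns(aln)))
  report$alignment <- list(rows = nrow(codonMatrix(aln)),
                           codon_columns = nCodonColumns(aln))

  ## stage 3: identity ----------------------------------------------------
  idm <- tryCatch(suppressWarnings(identityMatrix(aln)),
                  error = function(e) stageFail("identity", e))
  writeDistanceTsv(round(idm, 3), file.path(out_dir, "identity_matrix.tsv"))
  stats <- identityStats(idm)
  writeTsv(stats, file.path(out_dir, "identity_summary.tsv"))
  cl <- clusterLabels(cds)[match(rownames(idm), recordIds(cds))]
  pairs <- expand.grid(cluster_i = unique(cl), cluster_j = unique(cl),
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$cluster_i < pairs$cluster_j, ]
  if (nrow(pairs)) {
    pairs$a_bar <- mapply(function(ci, cj) {
      mean(idm[cl == ci, cl == cj], na.rm = TRUE)
    }, pairs$cluster_i, pairs$cluster_j)
    pairs$band <- as.character(classifyBand(pairs$a_bar))
    writeTsv(pairs, file.path(out_dir, "cluster_band_table.tsv"))
  }
  exp_rep <- expansionEvidence(cds)
  writeTsv(exp_rep$counts, file.path(out_dir, "expansion_report.tsv"))
  message(sprintf("[identity] pairs=%d a_bar=%.3f expanded_clusters=%d",
                  stats$n_pairs, stats$a_bar,
                  length(exp_rep$expanded_clusters)))
  report$identity <- list(a_bar = stats$a_bar, a_bar_ad = stats$a_bar_ad,
                          a_max = stats$a_max, a_min = stats$a_min,
                          n_pairs = stats$n_pairs,
                          expanded_clusters = exp_rep$expanded_clusters)

  ## stage 4: tree --------------------------------------------------------
  tree_res <- tryCatch({
    if (bootstrap_replicates >= 1) {
      bs <- bootstrapSupport(aln, n_replicates = bootstrap_replicates,
                             seed = seed, model = distance_model,
                             display_threshold_pct = display_threshold_pct)
      writeNewickTree(bs, file.path(out_dir, "tree.nwk"))
      bs
    } else {
      tr <- njTree(distanceFromAlignment(aln, model = distance_model))
      writeNewickTree(tr, file.path(out_dir, "tree.nwk"))
      list(tree = tr)
    }
  }, error = function(e) stageFail("tree", e))
  labels <- setNames(cl, rownames(idm))
  mono <- clustersFromTree(tree_res$tree, labels)
  writeTsv(mono$report, file.path(out_dir, "cluster_monophyly.tsv"))
  message(sprintf("[tree] clusters=%d monophyletic=%d (distance model: %s substitutes maximum composite likelihood)",
                  mono$recovered_cluster_count,
                  sum(mono$report$monophyletic), distance_model))
  report$tree <- list(recovered_cluster_count = mono$recovered_cluster_count,
                      monophyletic = sum(mono$report$monophyletic),
                      distance_model = distance_model,
                      model_note = "maximum composite likelihood substituted by p-distance/Jukes-Cantor")

  ## stage 5: protein molecular evolution ---------------------------------
  pe <- tryCatch({
    usage <- rscu(cds, threshold = rscu_threshold)
    writeTsv(usageTable(usage), file.path(out_dir, "rscu_table.tsv"))
    npc <- notPreferableSet(usage)
    out <- list(total_codons = usage@total_codons,
                n_not_preferable = length(npc))
    if (!is.null(reference_id)) {
      ridx <- referenceIndex(aln, reference_id)
      sites <- classifySites(aln, ridx, npc)
      writeTsv(sites, file.path(out_dir, "site_report.tsv"))
      out$site_classes <- as.list(table(sites$class))
      refprot <- proteins_aligned[[reference_id]]
      refprot <- gsub("-", "", refprot)
      motifs <- do.call(rbind, lapply(CYS_MOTIFS, function(p) {
        m <- scanMotif(refprot, p)
        if (nrow(m)) cbind(pattern = p, m) else NULL
      }))
      if (!is.null(motifs))
        writeTsv(motifs, file.path(out_dir, "motif_matches.tsv"))
      if (!is.null(region_map)) {
        rs <- do.call(rbind, lapply(
          c("extracellular", "transmembrane", "cytoplasmic"),
          function(g) regionIdentityStats(aln, ridx, region_map, g)))
        writeTsv(rs, file.path(out_dir, "region_identity_stats.tsv"))
        out$region_stats <- setNames(as.list(rs$a_bar), rs$group)
      }
    }
    cys <- lapply(split(proteins_aligned, clusterLabels(cds)),
                  commonCysteines)
    seqons <- lapply(split(proteins_aligned, clusterLabels(cds)),
                     annotateNglyc)
    landmarks <- data.frame(cluster_label = names(cys),
                            common_cysteines = lengths(cys),
                            common_sequons = lengths(seqons))
    writeTsv(landmarks, file.path(out_dir, "cluster_landmarks.tsv"))
    out$common_cysteine_range <- range(lengths(cys))
    out$common_sequon_range <- range(lengths(seqons))
    out
  }, error = function(e) stageFail("protevol", e))
  message(sprintf("[protevol] codons=%d not_preferable=%d",
                  pe$total_codons, pe$n_not_preferable))
  report$protevol <- pe

  jsonlite::write_json(report, file.path(out_dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
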