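#' @importFrom ape rcoal node.depth.edgelength
#' @importFrom stats rpois setNames
NULL

SENSE_CODONS <- setdiff(names(Biostrings::GENETIC_CODE), STOP_CODONS)

## default codon sampling weights: GC-ending codons favoured, the usual
## mammalian third-position bias; creates a clear not-preferable codon set
defaultCodonBias <- function() {
  third <- substring(SENSE_CODONS, 3L, 3L)
  w <- ifelse(third %in% c("C", "G"), 1.0, 0.45)
  setNames(w, SENSE_CODONS)
}

## approximate topological map for a connexin-like protein of `len`
## residues, scaled from a 273-residue reference layout
scaledRegionMap <- function(len) {
  base <- data.frame(
    label = c("N", "M1", "E1", "M2", "L", "M3", "E2", "M4", "C"),
    start = c(1, 20, 41, 76, 99, 131, 154, 191, 214),
    end   = c(19, 40, 75, 98, 130, 153, 190, 213, 273))
  sc <- len / 273
  start <- pmax(1L, round((base$start - 1L) * sc) + 1L)
  end <- c(start[-1L] - 1L, len)
  RegionMap(data.frame(label = base$label, start = start, end = end), len)
}

#' Configuration for the gene-family simulator
#'
#' Defaults are sized to the shape of a typical curated eutherian gene
#' family data set: 35 species, 21 major clusters, 327 codons per
#' sequence, four clusters carrying duplications, region-dependent
#' conservation (extracellular slowest, cytoplasmic fastest), designated
#' invariant columns including signature cysteines and two sequons, and
#' biased synonymous codon usage.
#'
#' @param n_species,n_clusters,n_codons Data-set shape.
#' @param within_height Height of the species tree (substitutions per
#'   codon site); controls orthologue identities.
#' @param cluster_depth_range Range of root-to-cluster-ancestor branch
#'   lengths; controls between-cluster identities.
#' @param rate_multipliers Named per-region-group rate multipliers.
#' @param codon_bias Sampling weights over the 61 sense codons.
#' @param p_nonsyn Probability that a substitution event changes the
#'   amino acid.
#' @param duplications Data.frame with columns \code{cluster},
#'   \code{type} ("predates"/"postdates"), \code{n_species},
#'   \code{t_dup}; NULL = default four events.
#' @param n_invariant Number of designated invariant residue columns in
#'   addition to the cysteine/sequon landmarks.
#' @param seed Integer seed fixing all randomness.
#' @return A list of class \code{family_sim_config}.
#' @export
familySimConfig <- function(n_species = 35, n_clusters = 21, n_codons = 327,
                            within_height = 0.5,
                            cluster_depth_range = c(0.5, 3),
                            rate_multipliers = c(extracellular = 0.25,
                                                 transmembrane = 0.6,
                                                 cytoplasmic = 1.7),
                            codon_bias = defaultCodonBias(),
                            p_nonsyn = 0.5,
                            duplications = NULL,
                            n_invariant = 6,
                            seed = 1) {
  stopifnot(n_species >= 2, n_clusters >= 1, n_codons >= 60,
            all(rate_multipliers >= 0))
  if (is.null(duplications) && n_clusters >= 4) {
    cl <- paste0("CL", LETTERS[seq_len(n_clusters)])
    pick <- cl[round(seq(2, n_clusters - 1, length.out = 4))]
    duplications <- data.frame(
      cluster = pick,
      type = c("predates", "predates", "predates", "postdates"),
      n_species = c(3L, 4L, 2L, 1L),
      t_dup = c(0.6, 0.45, 0.8, 0.08))
  }
  structure(list(n_species = n_species, n_clusters = n_clusters,
                 n_codons = n_codons, within_height = within_height,
                 cluster_depth_range = cluster_depth_range,
                 rate_multipliers = rate_multipliers,
                 codon_bias = codon_bias, p_nonsyn = p_nonsyn,
                 duplications = duplications, n_invariant = n_invariant,
                 seed = seed),
            class = "family_sim_config")
}

## one substitution event on a codon; never creates a stop codon and
## never returns the input codon unchanged
substituteCodon <- function(codon, p_nonsyn, bias) {
  aa <- Biostrings::GENETIC_CODE[[codon]]
  fam <- SENSE_CODONS[Biostrings::GENETIC_CODE[SENSE_CODONS] == aa]
  syn <- setdiff(fam, codon)
  if (length(syn) && stats::runif(1) > p_nonsyn) {
    w <- bias[syn]
    return(sample(syn, 1L, prob = w))
  }
  other <- SENSE_CODONS[Biostrings::GENETIC_CODE[SENSE_CODONS] != aa]
  sample(other, 1L, prob = bias[other])
}

## evolve a codon vector along a branch of length t; rates per site
evolveBranch <- function(codons, t, site_rates, p_nonsyn, bias) {
  nev <- rpois(length(codons), t * site_rates)
  for (i in which(nev > 0L))
    for (k in seq_len(nev[i]))
      codons[i] <- substituteCodon(codons[i], p_nonsyn, bias)
  codons
}

## evolve root codons down a phylo tree; returns matrix tips x sites
evolveAlongTree <- function(tree, root, site_rates, p_nonsyn, bias) {
  ntip <- length(tree$tip.label)
  rootNode <- ntip + 1L
  seqs <- vector("list", ntip + tree$Nnode)
  seqs[[rootNode]] <- root
  ord <- reorder(tree, "cladewise")
  for (e in seq_len(nrow(ord$edge))) {
    from <- ord$edge[e, 1L]; to <- ord$edge[e, 2L]
    seqs[[to]] <- evolveBranch(seqs[[from]], ord$edge.length[e],
                               site_rates, p_nonsyn, bias)
  }
  out <- do.call(rbind, seqs[seq_len(ntip)])
  rownames(out) <- tree$tip.label
  out
}

#' Simulate a gene family with known truth
#'
#' Evolves codon sequences from a family root: each cluster ancestor
#' diverges from the root by its own depth (spreading between-cluster
#' identities over the homologue bands), then evolves along a shared
#' coalescent species tree (within-cluster orthologue identities).
#' Designated invariant columns (including signature cysteines and two
#' sequons) are never substituted; synonymous choices follow the codon
#' bias; substitution rates vary by protein region.  Duplications of
#' type "predates" split a cluster ancestor before the species-tree root
#' and place the second copy in a subset of species; "postdates"
#' duplicates one species' gene on its terminal branch.  All randomness
#' is fixed by the config seed.
#'
#' @param cfg A [familySimConfig()].
#' @return A list: \code{cds} (\linkS4class{CdsSet}), \code{proteins_aligned}
#'   (named character; no indels are simulated, so the alignment is the
#'   translation), and \code{truth} (designated invariant/cysteine/sequon
#'   residue positions, per-record cluster/species/copy, duplication
#'   table, species tree, region map).
#' @export
simulateFamily <- function(cfg) {
  stopifnot(inherits(cfg, "family_sim_config"))
  set.seed(cfg$seed)
  L <- cfg$n_codons
  rmap <- scaledRegionMap(L)
  reg <- residueRegions(rmap, L)
  group_of <- setNames(rep(names(REGION_GROUPS), lengths(REGION_GROUPS)),
                       unlist(REGION_GROUPS, use.names = FALSE))
  site_rates <- unname(cfg$rate_multipliers[group_of[reg]])

  ## landmark columns: cysteine motifs C-x(6)-C-x(3)-C in E1 and
  ## C-x(4)-C-x(5)-C in E2, one sequon in each extracellular loop
  rt <- regionTable(rmap)
  e1 <- rt[rt$label == "E1", ]; e2 <- rt[rt$label == "E2", ]
  cys <- c(e1$start + 10L, e1$start + 17L, e1$start + 21L,
           e2$start + 8L, e2$start + 13L, e2$start + 19L)
  seqN <- c(e1$start + 2L, e2$start + 2L)
  sequon <- cbind(n = seqN, s = seqN + 2L)
  extra <- round(seq(5, L - 5, length.out = cfg$n_invariant))
  invariant <- sort(unique(c(cys, seqN, seqN + 2L, extra)))
  site_rates[invariant] <- 0

  root <- sample(SENSE_CODONS, L, replace = TRUE, prob = cfg$codon_bias)
  root[cys] <- "TGC"
  root[seqN] <- "AAC"
  root[seqN + 2L] <- "AGC"

  sptree <- ape::rcoal(cfg$n_species,
                       tip.label = sprintf("sp%02d", seq_len(cfg$n_species)))
  sptree$edge.length <- sptree$edge.length *
    (cfg$within_height / max(ape::node.depth.edgelength(sptree)))

  clusters <- paste0("CL", LETTERS[seq_len(cfg$n_clusters)])
  depth <- seq(cfg$cluster_depth_range[1L], cfg$cluster_depth_range[2L],
               length.out = cfg$n_clusters)
  dup <- cfg$duplications

  recs <- list(); meta <- list()
  addRecords <- function(tipmat, cluster, copy, sp_keep = NULL) {
    tips <- rownames(tipmat)
    if (!is.null(sp_keep)) tips <- intersect(tips, sp_keep)
    for (tp in tips) {
      id <- if (copy == 1L) paste0(cluster, "_", tp)
        else paste0(cluster, "_", tp, "_", copy)
      recs[[id]] <<- paste0(paste(tipmat[tp, ], collapse = ""), "TAA")
      meta[[id]] <<- data.frame(record_id = id, species = tp,
                                cluster_label = cluster,
                                gene_name = paste0(cluster, copy))
    }
  }

  dup_truth <- list()
  for (k in seq_len(cfg$n_clusters)) {
    cl <- clusters[k]
    anc <- evolveBranch(root, depth[k], site_rates, cfg$p_nonsyn,
                        cfg$codon_bias)
    tips1 <- evolveAlongTree(sptree, anc, site_rates, cfg$p_nonsyn,
                             cfg$codon_bias)
    addRecords(tips1, cl, 1L)
    if (!is.null(dup) && cl %in% dup$cluster) {
      d <- dup[dup$cluster == cl, ][1L, ]
      if (d$type == "predates") {
        anc2 <- evolveBranch(anc, d$t_dup, site_rates, cfg$p_nonsyn,
                             cfg$codon_bias)
        tips2 <- evolveAlongTree(sptree, anc2, site_rates, cfg$p_nonsyn,
                                 cfg$codon_bias)
        sp2 <- sptree$tip.label[seq_len(d$n_species)]
        addRecords(tips2, cl, 2L, sp_keep = sp2)
        dup_truth[[cl]] <- data.frame(cluster = cl, type = "predates",
                                      species = sp2)
      } else {
        sp2 <- sptree$tip.label[1L]
        copy2 <- evolveBranch(tips1[sp2, ], d$t_dup, site_rates,
                              cfg$p_nonsyn, cfg$codon_bias)
        recs[[paste0(cl, "_", sp2, "_2")]] <-
          paste0(paste(copy2, collapse = ""), "TAA")
        meta[[paste0(cl, "_", sp2, "_2")]] <-
          data.frame(record_id = paste0(cl, "_", sp2, "_2"), species = sp2,
                     cluster_label = cl, gene_name = paste0(cl, "2"))
        dup_truth[[cl]] <- data.frame(cluster = cl, type = "postdates",
                                      species = sp2)
      }
    }
  }

  metadf <- do.call(rbind, meta)
  cds <- CdsSet(setNames(unlist(recs), names(recs)),
                species = metadf$species,
                cluster_label = metadf$cluster_label,
                gene_name = metadf$gene_name)
  prot <- as.character(translateCds(cds))
  truth <- list(cluster_of = setNames(metadf$cluster_label, metadf$record_id),
                species_of = setNames(metadf$species, metadf$record_id),
                invariant_residues = invariant,
                cysteine_residues = cys,
                sequon_start_residues = sequon[, "n"],
                duplications = if (length(dup_truth))
                  do.call(rbind, dup_truth) else NULL,
                species_tree = sptree,
                cluster_depths = setNames(depth, clusters),
                region_map = rmap)
  list(cds = cds, proteins_aligned = prot, truth = truth)
}

#' Simulate read coverage over a candidate coding sequence
#'
#' Places reads of fixed length uniformly over the candidate, except that
#' reads overlapping designated dropout intervals are never placed (so
#' dropout positions are guaranteed uncovered).  The true verdict is
#' "complete" only when no dropout was requested and the realized
#' coverage reaches every nucleotide.
#'
#' @param cds_length Candidate length in nucleotides.
#' @param mean_depth Target mean coverage depth.
#' @param read_length Read length (<= cds_length).
#' @param dropout Optional list of c(start, end) 1-based inclusive
#'   intervals with no read support.
#' @param seed Integer seed.
#' @return A list: \code{intervals} (data.frame read_id/start/end),
#'   \code{true_status} ("complete"/"putative").
#' @export
simulateReadCoverage <- function(cds_length, mean_depth, read_length,
                                 dropout = NULL, seed = 1) {
  stopifnot(read_length >= 1, read_length <= cds_length, mean_depth >= 0)
  set.seed(seed)
  ## reads may start before position 1 or run past the end of the
  ## candidate and are clipped to it, as local read alignments would be;
  ## placement is then uniform in coverage over the whole candidate
  starts_all <- seq.int(2L - read_length, cds_length)
  clip_s <- pmax(starts_all, 1L)
  clip_e <- pmin(starts_all + read_length - 1L, cds_length)
  ok <- rep(TRUE, length(starts_all))
  for (iv in dropout) ok <- ok & (clip_e < iv[1L] | clip_s > iv[2L])
  n <- rpois(1L, mean_depth * length(starts_all) / read_length)
  pick <- if (n > 0L && any(ok))
    sample.int(length(starts_all), n, replace = TRUE,
               prob = as.numeric(ok)) else integer(0)
  intervals <- data.frame(
    read_id = sprintf("read%04d", seq_along(pick)),
    start = clip_s[pick], end = clip_e[pick])
  depth <- coverageFromIntervals(cds_length, intervals)
  true_status <- if (length(dropout) == 0L && all(depth >= 1L))
    "complete" else "putative"
  list(intervals = intervals, true_status = true_status, depth = depth)
}
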