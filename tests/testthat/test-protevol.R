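## CDS with an exact codon composition (valid frame, terminal stop)
cdsFromCounts <- function(counts) {
  cods <- rep(names(counts), counts)
  CdsSet(setNames(paste0(paste(cods, collapse = ""), "TAA"), "z"),
         "sp", "CL")
}

test_that("RSCU is observed over expected within synonymous families", {
  u <- usageTable(rscu(cdsFromCounts(c(GAA = 10, GAG = 10))))
  glu <- u[u$aa == "E", ]
  expect_equal(glu$R, c(1, 1))
  u2 <- usageTable(rscu(cdsFromCounts(c(GAA = 5, GAG = 15))))
  glu2 <- u2[u2$aa == "E", ]
  expect_equal(glu2$R[glu2$codon == "GAA"], 0.5)
  expect_equal(glu2$R[glu2$codon == "GAG"], 1.5)
  # single-codon families have R = 1 when observed
  u3 <- usageTable(rscu(cdsFromCounts(c(ATG = 3, TGG = 2))))
  expect_equal(u3$R[u3$codon %in% c("ATG", "TGG")], c(1, 1))
  # stop codons form one 3-codon family when included
  stops <- u3[u3$aa == "*", ]
  expect_identical(nrow(stops), 3L)
  expect_equal(stops$R[stops$codon == "TAA"], 3)  # only TAA observed
  u4 <- usageTable(rscu(cdsFromCounts(c(ATG = 3)), include_stop_family = FALSE))
  expect_false("*" %in% u4$aa)
})

test_that("R sums to family size over each observed family (property)", {
  set.seed(23)
  for (rep in 1:10) {
    cds <- CdsSet(setNames(vapply(1:3, function(i)
      randomCdsString(sample(20:60, 1)), ""), paste0("s", 1:3)), "sp", "CL")
    u <- usageTable(rscu(cds))
    for (aa in unique(u$aa)) {
      fam <- u[u$aa == aa, ]
      if (sum(fam$count) > 0)
        expect_equal(sum(fam$R), fam$family_size[1])
      expect_equal(fam$expected, rep(sum(fam$count) / nrow(fam), nrow(fam)))
    }
    expect_identical(sum(u$count), rscu(cds)@total_codons)
  }
})

test_that("not-preferable set uses an inclusive threshold and matches raw counts", {
  # balanced usage: nothing flagged (stop family excluded: the crafted
  # CDS carries a single TAA, which would flag the unobserved TAG/TGA)
  u <- rscu(cdsFromCounts(c(GAA = 10, GAG = 10)),
            include_stop_family = FALSE)
  expect_length(notPreferableSet(u), 0L)
  # crafted counts giving R = 0.7 exactly: 7 vs 13 in a 2-codon family
  u2 <- rscu(cdsFromCounts(c(GAA = 7, GAG = 13)))
  expect_true("GAA" %in% notPreferableSet(u2))
  expect_equal(usageTable(u2)$R[usageTable(u2)$codon == "GAA"], 0.7)
  # biased synthetic family equals brute-force recomputation from raw counts
  sim <- simulateFamily(familySimConfig(n_species = 4, n_clusters = 3,
                                        n_codons = 100, seed = 5))
  u3 <- rscu(sim$cds)
  cods <- unlist(lapply(as.character(sequencesOf(sim$cds)), function(s)
    substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))))
  tab <- table(cods)
  gc <- Biostrings::GENETIC_CODE
  brute <- vapply(usageTable(u3)$codon, function(cod) {
    fam <- names(gc)[gc == gc[[cod]]]
    tot <- sum(tab[fam], na.rm = TRUE)
    obs <- if (cod %in% names(tab)) as.numeric(tab[[cod]]) else 0
    if (tot == 0) NA_real_ else obs / (tot / length(fam))
  }, 0)
  expect_equal(usageTable(u3)$R, unname(brute))
  expect_identical(notPreferableSet(u3),
                   sort(names(brute)[!is.na(brute) & brute <= 0.7]))
})

test_that("site classification partitions reference residues", {
  # columns: invariant / forward (no npc codon) / compensatory (npc codon)
  npc <- c("GAT", "TGT")
  aln <- makeAln(list(ref = c("ATG", "TGG", "GAG", "AAA"),
                      s2  = c("ATG", "GAC", "GAT", GAP),
                      s3  = c("ATG", "GAC", "GAG", "AAA")))
  ridx <- referenceIndex(aln, "ref")
  rep1 <- classifySites(aln, ridx, npc)
  expect_identical(rep1$class, c("invariant", "forward", "compensatory",
                                 "invariant"))
  expect_identical(rep1$n_calculated, c(3L, 3L, 3L, 2L))
  expect_identical(rep1$reference_residue, c("M", "W", "E", "K"))
  expect_false(any(rep1$flagged))
  # npc = empty turns compensatory into forward, invariant unchanged
  rep2 <- classifySites(aln, ridx, character(0))
  expect_identical(rep2$class, c("invariant", "forward", "forward",
                                 "invariant"))
  # sites are amino acid sites: synonymous-only variation is invariant
  syn <- makeAln(list(ref = c("GAG", "GAG"), s2 = c("GAA", "GAG")))
  rep_syn <- classifySites(syn, referenceIndex(syn, "ref"), npc)
  expect_identical(rep_syn$class, c("invariant", "invariant"))
  # reference-only column is classified but flagged
  aln2 <- makeAln(list(ref = c("ATG", "TGC"), s2 = c("ATG", GAP)))
  rep3 <- classifySites(aln2, referenceIndex(aln2, "ref"), npc)
  expect_identical(rep3$n_calculated[2], 1L)
  expect_true(rep3$flagged[2])
  expect_identical(rep3$class[2], "invariant")
})

test_that("motif parsing covers the PROSITE subset and rejects bad grammar", {
  p <- parseMotif("C-x(4,5)-C-x(5)-C")
  expect_length(p, 5L)
  expect_identical(p[[2]]$min, 4L)
  expect_identical(p[[2]]$max, 5L)
  expect_identical(p[[1]]$residues, "C")
  expect_error(parseMotif("C-x(5,4)-C"), "element 2")
  expect_error(parseMotif("C-foo-C"), "element 2")
  expect_identical(parseMotif("N-x-[ST]")[[3]]$residues, c("S", "T"))
})

test_that("motif scanning finds all overlapping matches, shortest-first", {
  m <- scanMotif("CAAAAAACAAAC", "C-x(6)-C-x(3)-C")
  expect_identical(c(m$start, m$end), c(1L, 12L))
  expect_identical(nrow(scanMotif("NAS", "N-x-[ST]")), 1L)
  expect_identical(scanMotif("NAS", "N-x-[ST]")$start, 1L)
  expect_identical(nrow(scanMotif("NAA", "N-x-[ST]")), 0L)
  # equality with the enumeration oracle on random strings
  set.seed(33)
  alpha <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]
  for (pat in c("C-x(6)-C-x(3)-C", "C-x(4,5)-C-x(5)-C", "N-x-[ST]")) {
    for (rep in 1:30) {
      s <- paste(sample(c(alpha, rep(c("C", "N", "S", "T"), 8)), 300,
                        replace = TRUE), collapse = "")
      expect_identical(scanMotif(s, pat), motifOracle(s, pat))
    }
  }
})

test_that("common sequon and cysteine columns require every non-gap row", {
  aln <- c(r1 = "MNASW", r2 = "MNTSW", r3 = "MN-SW")
  # r3 is gapped at column 3 (the sequon x) but its own sequence N-S-W
  # no longer has a sequon at residue 2: N,S,W -> N-x-[ST]? N S W: x=S, [ST]=W no.
  expect_identical(annotateNglyc(c(r1 = "MNASW", r2 = "MNTSW")), 2L)
  expect_length(annotateNglyc(c(r1 = "MNASW", r2 = "MNAAW")), 0L)
  # gapped rows do not veto
  expect_true(2L %in% annotateNglyc(c(r1 = "MNASW", r2 = "-NASW")))
  # proline refinement is optional and off by default
  expect_identical(annotateNglyc(c(r1 = "NPS")), 1L)
  expect_length(annotateNglyc(c(r1 = "NPS"), exclude_proline_x = TRUE), 0L)
  cysaln <- c(r1 = "ACWCA", r2 = "GCWC-", r3 = "TCWCT")
  expect_identical(commonCysteines(cysaln), c(2L, 4L))
})

test_that("generator-designated cysteines and sequons are recovered exactly", {
  sim <- simulateFamily(familySimConfig(n_species = 6, n_clusters = 2,
                                        n_codons = 120, seed = 9))
  cl <- clusterLabels(sim$cds)
  prot <- sim$proteins_aligned
  for (c1 in unique(cl)) {
    cys <- commonCysteines(prot[cl == c1])
    expect_true(all(sim$truth$cysteine_residues %in% cys))
    seqons <- annotateNglyc(prot[cl == c1])
    expect_true(all(sim$truth$sequon_start_residues %in% seqons))
  }
})

test_that("region-restricted identity statistics partition the alignment", {
  # single-region toy alignment equals global statistics
  aln <- randomAln(4, 30, gap_prob = 0)
  ridx <- referenceIndex(aln, recordIds(aln)[1])
  rm1 <- RegionMap(data.frame(label = "C", start = 1, end = 30))
  got <- regionIdentityStats(aln, ridx, rm1, "cytoplasmic")
  glob <- identityStats(identityMatrix(aln))
  expect_equal(got$a_bar, glob$a_bar)
  expect_equal(got$a_max, glob$a_max)
  # map not covering the reference is a validation error
  rm2 <- RegionMap(data.frame(label = "C", start = 1, end = 20))
  expect_error(regionIdentityStats(aln, ridx, rm2, "cytoplasmic"),
               "cover")
  # groups use disjoint column sets whose union is the alignment
  rm3 <- RegionMap(data.frame(label = c("N", "M1", "E1", "M2", "L", "M3",
                                        "E2", "M4", "C"),
                              start = c(1, 4, 7, 10, 13, 16, 19, 22, 25),
                              end = c(3, 6, 9, 12, 15, 18, 21, 24, 30)))
  per <- do.call(rbind, lapply(c("extracellular", "transmembrane",
                                 "cytoplasmic"),
                 function(g) regionIdentityStats(aln, ridx, rm3, g)))
  expect_identical(nrow(per), 3L)
  expect_true(all(per$a_min >= 0 & per$a_max <= 1))
})

test_that("the shipped approximate region map loads and is contiguous", {
  f <- system.file("extdata", "connexin_region_map_approx.tsv",
                   package = "famevol")
  rm <- readRegionMap(f, reference_length = 273)
  expect_identical(max(regionTable(rm)$end), 273L)
  expect_error(RegionMap(data.frame(label = c("N", "C"),
                                    start = c(1, 10), end = c(5, 20))),
               "contiguous")
})
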