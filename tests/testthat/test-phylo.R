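test_that("distances derive from identities; Jukes-Cantor handles saturation", {
  aln <- makeAln(list(a = rep("ATG", 10), b = rep("ATG", 10),
                      c = rep("ATG", 10)))
  expect_true(all(distanceFromAlignment(aln) == 0))
  # closed form: p = 0.1 under JC -> 0.1073
  expect_equal(-0.75 * log(1 - 4 / 3 * 0.1), 0.1073, tolerance = 1e-3)
  set.seed(4)
  raln <- randomAln(5, 20, gap_prob = 0.1)
  idm <- suppressWarnings(identityMatrix(raln))
  d <- suppressWarnings(distanceFromAlignment(raln, "p_distance"))
  expect_equal(unname(d + idm), matrix(1, 5, 5), ignore_attr = TRUE)
  # saturated pairs flagged and fall back to p-distance
  sat <- makeAln(list(a = c("AAA", "AAA", "AAA", "AAA"),
                      b = c("CCC", "CCC", "CCC", "CCC"),
                      c = c("GGG", "GGG", "GGG", "GGG")))
  expect_warning(dj <- distanceFromAlignment(sat, "jukes_cantor"), "saturated")
  expect_true(all(attr(dj, "saturated")[upper.tri(dj)]))
  expect_equal(unname(dj["a", "b"]), 1)
})

test_that("neighbor joining solves the 3-taxon case in closed form", {
  d <- matrix(c(0, 0.2, 0.4, 0.2, 0, 0.4, 0.4, 0.4, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- njTree(d)
  bl <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(sort(unname(bl[c("A", "B", "C")])), c(0.1, 0.1, 0.3))
  expect_error(njTree(matrix(c(0, 1, 2, 0), 2,
                             dimnames = list(c("a","b"), c("a","b")))),
               "symmetric|3 taxa")
  dbad <- d; dbad["A", "B"] <- 0.5
  expect_error(njTree(dbad), "symmetric")
})

test_that("NJ recovers the generating tree from additive distances", {
  set.seed(21)
  for (rep in 1:12) {
    n <- sample(4:8, 1)
    tr <- ape::rtree(n, br = function(k) runif(k, 0.05, 0.5))
    dm <- ape::cophenetic.phylo(tr)
    got <- njTree(dm)
    expect_true(sameTopology(got, tr))
    expect_equal(ape::cophenetic.phylo(got)[rownames(dm), colnames(dm)], dm,
                 tolerance = 1e-8)
  }
})

test_that("NJ is near-optimal against the exhaustive-topology OLS oracle", {
  set.seed(31)
  wins <- 0L; trials <- 25L
  for (rep in seq_len(trials)) {
    n <- 5L
    m <- matrix(runif(n * n, 0.05, 1), n)
    m <- (m + t(m)) / 2
    diag(m) <- 0
    dimnames(m) <- list(letters[1:n], letters[1:n])
    njlen <- sum(njTree(m)$edge.length)
    best <- bestOlsLength(m)
    if (njlen <= best * 1.05 + 1e-9) wins <- wins + 1L
  }
  expect_gte(wins / trials, 0.9)
})

test_that("bootstrap support is seeded, codon-resampled and split-based", {
  # two blocks of near-identical rows: the block split is fully supported
  set.seed(8)
  blockA <- sample(SENSE, 60, replace = TRUE)
  blockB <- sample(SENSE, 60, replace = TRUE)
  jitter <- function(r, k) { r[k] <- sample(SENSE, length(k), TRUE); r }
  aln <- makeAln(list(a1 = blockA, a2 = jitter(blockA, 1:2),
                      a3 = jitter(blockA, 3:4),
                      b1 = blockB, b2 = jitter(blockB, 5:6),
                      b3 = jitter(blockB, 7:8)))
  bs <- bootstrapSupport(aln, n_replicates = 100, seed = 99)
  key <- paste(sort(c("a1", "a2", "a3")), collapse = "|")
  keys <- famevol:::nodeSplitKeys(bs$tree)
  expect_true(key %in% keys)
  expect_gte(bs$support[which(keys == key)], 99)
  bs2 <- bootstrapSupport(aln, n_replicates = 100, seed = 99)
  expect_identical(bs$support, bs2$support)
  bs3 <- bootstrapSupport(aln, n_replicates = 1, seed = 7)
  expect_true(all(bs3$support[!is.na(keys)] %in% c(0, 100)))
})

test_that("bipartition support is invariant to leaf order of the input", {
  set.seed(15)
  aln <- randomAln(6, 50, gap_prob = 0)
  m <- codonMatrix(aln)
  perm <- makeAln(setNames(lapply(c(4, 1, 6, 3, 2, 5),
                                  function(i) m[i, ]),
                           rownames(m)[c(4, 1, 6, 3, 2, 5)]))
  b1 <- bootstrapSupport(aln, n_replicates = 50, seed = 3)
  b2 <- bootstrapSupport(perm, n_replicates = 50, seed = 3)
  k1 <- famevol:::nodeSplitKeys(b1$tree)
  k2 <- famevol:::nodeSplitKeys(b2$tree)
  shared <- intersect(k1[!is.na(k1)], k2[!is.na(k2)])
  expect_gt(length(shared), 0L)
  for (k in shared)
    expect_equal(b1$support[which(k1 == k)], b2$support[which(k2 == k)],
                 tolerance = 15)  # same resampling law, independent draws
})

test_that("cluster monophyly is read off tree bipartitions", {
  sim <- simulateFamily(familySimConfig(n_species = 5, n_clusters = 4,
                                        n_codons = 90, seed = 2))
  aln <- buildCodonAlignment(sim$proteins_aligned, sim$cds)
  tr <- njTree(distanceFromAlignment(aln))
  labels <- sim$truth$cluster_of[tr$tip.label]
  rep1 <- clustersFromTree(tr, labels)
  expect_identical(rep1$recovered_cluster_count, 4L)
  expect_true(all(rep1$report$monophyletic))
  # one relabeled leaf breaks monophyly of both affected clusters
  labels2 <- labels
  swap <- which(labels2 == "CLA")[1]
  labels2[swap] <- "CLB"
  rep2 <- clustersFromTree(tr, labels2)
  expect_false(rep2$report$monophyletic[rep2$report$cluster_label == "CLB"])
  expect_error(clustersFromTree(tr, labels[-1]), "labeled")
})

test_that("newick output suppresses sub-threshold supports but keeps data", {
  set.seed(16)
  aln <- randomAln(5, 40, gap_prob = 0)
  bs <- bootstrapSupport(aln, n_replicates = 20, seed = 1)
  f <- tempfile(fileext = ".nwk")
  writeNewickTree(bs, f, display_threshold_pct = 101)  # suppress everything
  txt <- readLines(f)
  reread <- ape::read.tree(f)
  expect_identical(sort(reread$tip.label), sort(recordIds(aln)))
  expect_false(grepl(")[0-9]", txt))
  expect_length(bs$support, bs$tree$Nnode)  # data retained regardless
})

test_that("distance matrix TSV round trip preserves values", {
  set.seed(2)
  aln <- randomAln(4, 30, gap_prob = 0)
  d <- distanceFromAlignment(aln)
  f <- tempfile(fileext = ".tsv")
  writeDistanceTsv(d, f)
  d2 <- readDistanceTsv(f)
  expect_equal(d2, unclass(d)[rownames(d2), colnames(d2)],
               ignore_attr = TRUE)
})
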