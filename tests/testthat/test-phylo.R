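# K2P distances, neighbor-joining, bootstrap, monophyly

test_that("K2P distance handles identity, gaps, and its closed form", {
  expect_equal(k2p_distance("ACGTACGTAC", "ACGTACGTAC")$d, 0)
  r <- k2p_distance("AC-TACG--C", "ACGTAC-TAC")  # differences only at gaps
  expect_equal(r$d, 0)
  expect_equal(r$n, 6)

  # n = 100 with 10 transitions and 5 transversions
  a <- paste(rep("A", 100), collapse = "")
  b <- paste(c(rep("G", 10), rep("C", 5), rep("A", 85)), collapse = "")
  r <- k2p_distance(a, b)
  expect_equal(r$P, 0.10)
  expect_equal(r$Q, 0.05)
  expect_equal(r$n, 100)
  expect_equal(r$d, -0.5 * log((1 - 2 * 0.10 - 0.05) * sqrt(1 - 2 * 0.05)))
})

test_that("K2P errors on undefined and saturated pairs", {
  expect_error(k2p_distance("----", "ACGT"), class = "scar_distance_error")
  a <- paste(rep("A", 50), collapse = "")
  b <- paste(rep("G", 50), collapse = "")
  expect_error(k2p_distance(a, b), class = "scar_distance_error")
  expect_error(k2p_distance("ACG", "ACGT"), class = "scar_precondition_error")
})

test_that("ambiguity codes are deleted pairwise like gaps", {
  r <- k2p_distance("ACGTN", "ACGTA")
  expect_equal(r$n, 4)
  r2 <- k2p_distance("ACGTR", "ACGTA")
  expect_equal(r2$n, 4)
})

test_that("K2P approaches P + Q in the small-distance limit", {
  a <- paste(rep("A", 10000), collapse = "")
  b <- paste(c(rep("G", 5), rep("C", 5), rep("A", 9990)), collapse = "")
  r <- k2p_distance(a, b)
  expect_lt(abs(r$d - (r$P + r$Q)), 1e-6)
})

test_that("the distance matrix agrees with an independent implementation", {
  fx <- small_panel()
  m <- k2p_matrix(fx$aln)
  bin <- ape::as.DNAbin(do.call(rbind, strsplit(tolower(fx$aln$seq), "")))
  rownames(bin) <- fx$aln$id
  ref <- as.matrix(ape::dist.dna(bin, model = "K80", pairwise.deletion = TRUE))
  expect_equal(m$d, ref[rownames(m$d), colnames(m$d)], tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("three-taxon NJ solves the three-point formulas", {
  dm <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tree <- nj_tree(dm)
  bl <- setNames(tree$edge.length, tree$tip.label[tree$edge[, 2]])
  expect_equal(bl[["a"]], 1)
  expect_equal(bl[["b"]], 2)
  expect_equal(bl[["c"]], 3)
})

test_that("NJ is exact on additive matrices", {
  withr::local_seed(17)
  for (i in 1:5) {
    true <- ape::rtree(5, br = function(n) runif(n, 0.05, 0.5))
    dm <- ape::cophenetic.phylo(true)
    got <- nj_tree(dm)
    expect_equal(ape::dist.topo(ape::unroot(true), got), 0, ignore_attr = TRUE)
    # recovered path lengths reproduce the generating matrix
    expect_equal(ape::cophenetic.phylo(got)[rownames(dm), colnames(dm)], dm,
                 tolerance = 1e-9)
  }
})

test_that("six-taxon NJ matches brute-force minimum evolution over all 105 topologies", {
  withr::local_seed(23)
  topos <- enumerate_topologies(6)
  expect_equal(length(topos), 105)
  for (i in 1:3) {
    true <- ape::rtree(6, br = function(n) runif(n, 0.05, 0.4))
    dm <- ape::cophenetic.phylo(true)
    best <- brute_force_me_tree(dm)
    got <- nj_tree(dm)
    expect_equal(ape::dist.topo(ape::unroot(best), got), 0, ignore_attr = TRUE)
  }
})

test_that("NJ agrees with an independent implementation on noisy matrices", {
  withr::local_seed(29)
  for (i in 1:5) {
    true <- ape::rtree(7, br = function(n) runif(n, 0.05, 0.4))
    dm <- ape::cophenetic.phylo(true)
    noise <- matrix(runif(49, 0, 0.01), 7); noise <- (noise + t(noise)) / 2
    diag(noise) <- 0
    dm <- dm + noise
    got <- nj_tree(dm, clamp_negative = FALSE)
    ref <- ape::nj(stats::as.dist(dm))
    expect_equal(ape::dist.topo(got, ref), 0, ignore_attr = TRUE)
    expect_equal(sum(got$edge.length), sum(ref$edge.length), tolerance = 1e-9)
  }
})

test_that("negative branch lengths are clamped with the raw tree retained", {
  dm <- matrix(c(0, 0.965, 0.357, 0.832,
                 0.965, 0, 0.543, 0.271,
                 0.357, 0.543, 0, 0.461,
                 0.832, 0.271, 0.461, 0), 4,
               dimnames = list(letters[1:4], letters[1:4]))
  tree <- nj_tree(dm)
  expect_true(all(tree$edge.length >= 0))
  raw <- attr(tree, "raw_tree")
  expect_true(any(raw$edge.length < 0))
})

test_that("bootstrap supports are reproducible and permutation-invariant", {
  fx <- small_panel()
  b1 <- bootstrap_support(fx$aln, B = 50, seed = 7)
  b2 <- bootstrap_support(fx$aln, B = 50, seed = 7)
  expect_identical(b1$support, b2$support)
  expect_identical(ape::write.tree(b1$tree), ape::write.tree(b2$tree))

  og <- fx$panel$id[fx$panel$role == "outgroup"]
  perm <- fx$aln[rev(seq_len(nrow(fx$aln))), ]
  b3 <- bootstrap_support(perm, B = 50, seed = 7)
  for (sp in unique(fx$panel$species[fx$panel$role == "target_panel"])) {
    tips <- fx$panel$id[fx$panel$species == sp]
    expect_equal(clade_support(b1, tips, og), clade_support(b3, tips, og))
  }
})

test_that("an invariant alignment yields full support everywhere", {
  s <- random_seq(120)
  aln <- toy_alignment(rep(s, 5), letters[1:5])
  bt <- bootstrap_support(aln, B = 20, seed = 3)
  expect_true(all(bt$support[!is.na(bt$support)] == 100))
})

test_that("monophyly testing covers the trivial and panel cases", {
  fx <- small_panel()
  tree <- nj_tree(k2p_matrix(fx$aln))
  og <- fx$panel$id[fx$panel$role == "outgroup"]
  one <- fx$panel$id[fx$panel$role == "target_panel"][1]
  expect_true(is_monophyletic(tree, one, og))                       # singleton
  all_t <- fx$panel$id[fx$panel$role == "target_panel"]
  expect_true(is_monophyletic(tree, all_t, og))                     # everything
  expect_error(is_monophyletic(tree, "no-such-tip", og), class = "scar_lookup_error")

  mono <- species_monophyly(tree, fx$panel)
  expect_true(all(mono$monophyletic))
})

test_that("tidy and glance expose distance and support summaries", {
  fx <- small_panel()
  m <- k2p_matrix(fx$aln)
  td <- tidy(m)
  expect_equal(nrow(td), choose(nrow(fx$aln), 2))
  expect_true(all(td$d >= 0))
  bt <- bootstrap_support(fx$aln, B = 20, seed = 5)
  expect_equal(glance(bt)$B, 20)
  expect_true(all(stats::na.omit(tidy(bt)$support) >= 0))
})
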