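test_that("Jukes-Cantor distances follow the 20-state closed form with pairwise deletion", {
  a <- msa(c(x = "ACDEFGHIKL", y = "ACDEFGHIKL"))
  expect_equal(jc_distance(a)$d["x", "y"], 0)

  # pairwise deletion: "AC-D" vs "AC-E" compares 3 sites, 1 mismatch
  d <- jc_distance(msa(c(x = "AC-D", y = "AC-E")))
  expect_equal(d$comparable_sites["x", "y"], 3)
  p <- 1 / 3
  expect_equal(d$d["x", "y"], -(19 / 20) * log(1 - (20 / 19) * p))

  # p = 0.1 plugged into the closed form; correction always exceeds p
  rows <- c(x = strrep("A", 10), y = paste0(strrep("A", 9), "C"))
  d2 <- jc_distance(msa(rows))$d["x", "y"]
  expect_equal(d2, -(19 / 20) * log(1 - (20 / 19) * 0.1))
  expect_gt(d2, 0.1)

  # X is treated as missing
  d3 <- jc_distance(msa(c(x = "AXCD", y = "AACD")))
  expect_equal(d3$comparable_sites["x", "y"], 3)

  expect_error(jc_distance(msa(c(x = "A---", y = "-CCC"))),
               "no comparable sites")

  # saturation: all-different rows hit the ceiling and are flagged
  d4 <- jc_distance(msa(c(x = "ACDEFGHIKL", y = "MNPQRSTVWY")), ceiling = 5)
  expect_equal(d4$d["x", "y"], 5)
  expect_true(d4$saturated["x", "y"])
})

test_that("monotonicity of the JC correction in p", {
  p <- seq(0.01, 0.9, by = 0.05)
  d <- -(19 / 20) * log(1 - (20 / 19) * p)
  expect_true(all(diff(d) > 0))
  expect_true(all(d >= p))
})

test_that("neighbor joining reproduces additive distances exactly", {
  # 4 taxa from a known tree: recover ((a,b),(c,d))
  tr <- ape::read.tree(text = "((a:1,b:2):1,(c:3,d:1):2);")
  D <- ape::cophenetic.phylo(tr)
  out <- nj_tree(D)
  expect_equal(ape::dist.topo(ape::unroot(tr), out), 0,
               ignore_attr = TRUE)
  expect_lt(max(abs(ape::cophenetic.phylo(out)[rownames(D), colnames(D)] - D)),
            1e-9)

  # 3 taxa: closed-form branch lengths
  D3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  t3 <- nj_tree(D3)
  expect_equal(newick_string(t3), "(a:1,b:2,c:3);")

  # 8-taxon additive matrix: path lengths match the input within 1e-9
  set.seed(71)
  tr8 <- ape::rtree(8)
  tr8$edge.length <- runif(nrow(tr8$edge), 0.1, 2)
  D8 <- ape::cophenetic.phylo(tr8)
  out8 <- nj_tree(D8)
  expect_lt(max(abs(ape::cophenetic.phylo(out8)[rownames(D8), colnames(D8)] -
                      D8)), 1e-9)
})

test_that("NJ is consistent on random additive trees and agrees with ape::nj", {
  set.seed(72)
  for (k in 1:10) {
    nt <- sample(5:10, 1)
    tr <- ape::rtree(nt)
    tr$edge.length <- runif(nrow(tr$edge), 0.05, 1.5)
    D <- ape::cophenetic.phylo(tr)
    out <- nj_tree(D)
    expect_equal(ape::dist.topo(ape::unroot(tr), out), 0, ignore_attr = TRUE)
    # independent route: ape's NJ must give the same unrooted topology
    expect_equal(ape::dist.topo(ape::nj(as.dist(D)), out), 0,
                 ignore_attr = TRUE)
  }
})

test_that("NJ rejects malformed matrices and clamps negative branches", {
  D <- matrix(c(0, 1, 1, 0), 2)
  expect_error(nj_tree(D), ">= 3 taxa")
  D3 <- matrix(c(0, -1, 1, -1, 0, 1, 1, 1, 0), 3,
               dimnames = list(letters[1:3], letters[1:3]))
  expect_error(nj_tree(D3), "negative")
  D4 <- matrix(runif(16), 4, dimnames = list(letters[1:4], letters[1:4]))
  expect_error(nj_tree(D4), "symmetric")
  # star-like distances can induce negative NJ estimates; clamped to >= 0
  Dst <- matrix(1, 5, 5, dimnames = list(letters[1:5], letters[1:5]))
  diag(Dst) <- 0
  out <- nj_tree(Dst)
  expect_true(all(out$edge.length >= 0))
})

test_that("bootstrap gives 100% support to a fixed deep split and is reproducible", {
  set.seed(73)
  base <- random_aa_string(60)
  mut <- function(s, pos, to) {
    ch <- strsplit(s, "")[[1]]; ch[pos] <- to; paste(ch, collapse = "")
  }
  cladeA <- base
  cladeB <- mut(base, 1:50, sample(c("W", "Y"), 50, TRUE))
  rows <- c(a1 = cladeA, a2 = mut(cladeA, 55, "C"), a3 = mut(cladeA, 56, "D"),
            b1 = cladeB, b2 = mut(cladeB, 57, "E"), b3 = mut(cladeB, 58, "F"))
  aln <- msa(rows)
  tr <- bootstrap_support(aln, replicates = 100, seed = 5)
  sup <- tr$node.label[!is.na(tr$node.label)]
  expect_true(all(sup >= 0 & sup <= 100))
  # the a|b split is present in every resample (50 fixed differences)
  labs <- lapply((ape::Ntip(tr) + 1):(ape::Ntip(tr) + tr$Nnode), function(n)
    sort(ankevol:::tips_of(tr, n)))
  deep <- which(vapply(labs, function(x)
    identical(x, c("a1", "a2", "a3")) || identical(x, c("b1", "b2", "b3")),
    TRUE))
  expect_true(all(tr$node.label[deep] == 100))

  tr2 <- bootstrap_support(aln, replicates = 100, seed = 5)
  expect_identical(tr$node.label, tr2$node.label)
  tr3 <- bootstrap_support(aln, replicates = 100, seed = 6)
  strip <- function(x) { x$node.label <- NULL; newick_string(ape::ladderize(x)) }
  expect_equal(strip(tr3), strip(tr))  # point tree independent of the seed
})

test_that("supports are invariant under taxon reordering", {
  set.seed(74)
  tree <- study_tree(4)
  fam <- simulate_family(tree, 200, alpha = 1, seed = 4)
  aln1 <- fam$alignment
  perm <- sample(length(aln1$sequences))
  aln2 <- msa(aln1$sequences[perm])
  t1 <- bootstrap_support(aln1, 50, seed = 2)
  t2 <- bootstrap_support(aln2, 50, seed = 2)
  key <- function(tr) {
    nt <- ape::Ntip(tr)
    labs <- vapply((nt + 1):(nt + tr$Nnode), function(n)
      paste(sort(ankevol:::tips_of(tr, n)), collapse = ","), "")
    setNames(tr$node.label, labs)
  }
  k1 <- key(t1); k2 <- key(t2)
  shared <- intersect(names(k1), names(k2))
  expect_gt(length(shared), 2)
  expect_equal(k1[shared], k2[shared])
})

test_that("pure-noise alignments get low supports", {
  set.seed(75)
  rows <- setNames(replicate(10, random_aa_string(100)), paste0("t", 1:10))
  tr <- bootstrap_support(msa(rows), replicates = 200, seed = 11)
  sup <- tr$node.label[!is.na(tr$node.label)]
  # noise splits sit far below the 70% display threshold
  expect_lt(mean(sup), 50)
  expect_true(all(sup < 70))
})

test_that("outgroup rooting bisects the subtending edge and round-trips", {
  t4 <- ape::unroot(ape::read.tree(text = "(a:1,(b:1,(c:1,d:1):1):1);"))
  rt <- root_with_outgroup(t4, "a")
  expect_true(ape::is.rooted(rt))
  root_children <- which(rt$edge[, 1] == ape::Ntip(rt) + 1L)
  expect_equal(rt$edge.length[root_children],
               rep(sum(rt$edge.length[root_children]) / 2, 2))
  # rooting then unrooting preserves the bipartition set
  expect_setequal(ankevol:::bipartitions(ape::unroot(rt)),
                  ankevol:::bipartitions(t4))

  expect_error(root_with_outgroup(t4, letters[1:4]), "all taxa")
  expect_error(root_with_outgroup(t4, "zz"), "not in tree")

  # non-monophyletic outgroup is refused with the offending taxa listed
  t6 <- ape::read.tree(text = "((a:1,b:1):1,((c:1,d:1):1,(e:1,f:1):1):1);")
  expect_error(root_with_outgroup(t6, c("a", "c")), "not monophyletic")
  # multi-leaf clade outgroup works
  rt2 <- root_with_outgroup(t6, c("e", "f"))
  expect_true(ape::is.monophyletic(rt2, c("e", "f")))
})
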