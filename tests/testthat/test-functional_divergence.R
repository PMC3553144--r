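make_pair <- function(L = 40, seed = 1, tree = study_tree(4)) {
  fam <- simulate_family(tree, L, alpha = 1, seed = seed)
  cluster_pair(fam$alignment, tree,
               grep("^a", tree$tip.label, value = TRUE),
               grep("^b", tree$tip.label, value = TRUE))
}

test_that("cluster pairs enforce size, disjointness and monophyly", {
  tree <- study_tree(4)
  fam <- simulate_family(tree, 30, seed = 2)
  expect_error(cluster_pair(fam$alignment, tree, paste0("a", 1:3),
                            paste0("b", 1:4)), "at least 4")
  expect_error(cluster_pair(fam$alignment, tree, paste0("a", 1:4),
                            c("a4", "b1", "b2", "b3")), "disjoint")
  expect_error(cluster_pair(fam$alignment, tree,
                            c("a1", "a2", "b1", "b2"),
                            c("a3", "a4", "b3", "b4")), "not monophyletic")
})

test_that("Fitch counts match textbook cases and the brute-force oracle", {
  tree <- study_tree(4)
  m <- msa_matrix(simulate_family(tree, 4, seed = 3)$alignment)
  # invariant column
  m[, 1] <- "A"
  # 4-taxon cluster ((a1,a2),(a3,a4)) with states A,A,T,T: one change
  m[paste0("a", 1:4), 2] <- c("A", "A", "T", "T")
  # all-missing column in cluster A
  m[paste0("a", 1:4), 3] <- "-"
  aln <- msa(apply(m, 1, paste, collapse = ""))
  pair <- cluster_pair(aln, tree, paste0("a", 1:4), paste0("b", 1:4))
  cnt <- fitch_counts(pair)
  expect_equal(cnt$X_A[1], 0)
  expect_equal(cnt$X_B[1], 0)
  expect_equal(cnt$X_A[2], 1)
  expect_equal(cnt$X_A[3], 0)
  expect_true(cnt$mask_A[3])
  expect_false(cnt$mask_B[3])
  expect_true(all(cnt$X_A <= 2 * 3))  # counts bounded by 2(n-1)

  # random 6-taxon columns vs exhaustive minimisation
  tr6 <- ape::read.tree(text = "(((x1:1,x2:1):1,(x3:1,x4:1):1):1,(x5:1,x6:1):1);")
  set.seed(81)
  for (k in 1:20) {
    states <- sample(c("A", "C", "D", "E", NA), 6, replace = TRUE)
    rows <- setNames(ifelse(is.na(states), "-", states), paste0("x", 1:6))
    rows2 <- setNames(sample(c("A", "C"), 6, TRUE), paste0("y", 1:6))
    aln6 <- msa(c(rows, rows2))
    tr12 <- ape::read.tree(text = paste0(
      "((((x1:1,x2:1):1,(x3:1,x4:1):1):1,(x5:1,x6:1):1):1,",
      "(((y1:1,y2:1):1,(y3:1,y4:1):1):1,(y5:1,y6:1):1):1);"))
    pair6 <- cluster_pair(aln6, tr12, paste0("x", 1:6), paste0("y", 1:6))
    cnt6 <- fitch_counts(pair6)
    sub <- ape::keep.tip(tr12, paste0("x", 1:6))
    expect_equal(cnt6$X_A[1],
                 oracle_fitch(sub, setNames(states, paste0("x", 1:6))),
                 info = paste(states, collapse = ""))
  }
})

test_that("type I estimate is near zero without rate decoupling", {
  counts <- sample_type1_counts(500, 0, 0.5, seed = 91)
  counts$X_B <- counts$X_A  # identical count vectors
  est <- estimate_type1(counts, seed = 1)
  expect_lt(est$theta, 0.1)
  expect_gt(est$p_value, 0.05)
  expect_true(all(est$posterior >= 0 & est$posterior <= 1))
  expect_gte(est$lrt, -1e-8)
})

test_that("type I recovery on the model's own sampler", {
  est <- estimate_type1(sample_type1_counts(1000, 0.6, 0.5, seed = 92),
                        seed = 1)
  expect_lt(abs(est$theta - 0.6), 0.15)
  expect_lt(est$p_value, 0.05)
  expect_false(is.na(est$se))
  expect_gt(est$se, 0)
})

test_that("type I result is invariant under cluster swap", {
  cnt <- sample_type1_counts(600, 0.4, 0.5, T_A = 1.0, T_B = 1.8, seed = 93)
  swapped <- cnt
  swapped$X_A <- cnt$X_B; swapped$X_B <- cnt$X_A
  swapped$mask_A <- cnt$mask_B; swapped$mask_B <- cnt$mask_A
  e1 <- estimate_type1(cnt, seed = 1)
  e2 <- estimate_type1(swapped, seed = 1)
  expect_equal(e1$theta, e2$theta, tolerance = 1e-3)
  expect_equal(e1$lrt, e2$lrt, tolerance = 1e-2)
  expect_equal(e1$alpha_A, e2$alpha_B, tolerance = 1e-2)
  c1 <- candidate_sites_type1(e1)$column
  c2 <- candidate_sites_type1(e2)$column
  expect_identical(c1, c2)
})

test_that("candidate sites use a strict posterior cutoff and gap-aware mapping", {
  res <- structure(list(posterior = c(0.2, 0.86, 0.85)),
                   class = "type1_result")
  expect_identical(candidate_sites_type1(res, cutoff = 0.85)$column, 2L)
  expect_identical(candidate_sites_type1(
    structure(list(posterior = rep(0, 5)), class = "type1_result"))$column,
    integer(0))

  aln <- msa(c(ref = "A-C", other = "AAC"))
  out <- candidate_sites_type1(
    structure(list(posterior = c(0, 0, 0.9)), class = "type1_result"),
    aln = aln, reference = "ref")
  expect_equal(out$column, 3)
  expect_equal(out$ref_pos, 2)  # reference gap at column 2 is skipped
})

test_that("type II flags planted frozen fixed differences and their property classes", {
  tree <- study_tree(8, tip = 0.3, internal = 0.15, separation = 0.15)
  A <- paste0("a", 1:8); B <- paste0("b", 1:8)
  fam <- simulate_family(tree, 100, alpha = 2, seed = 7)
  m <- msa_matrix(fam$alignment)
  planted <- 1:25
  pairs_aa <- list(c("Q", "K"), c("D", "F"), c("Y", "N"), c("A", "S"),
                   c("E", "K"))
  for (k in seq_along(planted)) {
    pq <- pairs_aa[[(k - 1) %% 5 + 1]]
    m[A, planted[k]] <- pq[1]
    m[B, planted[k]] <- pq[2]
  }
  aln <- msa(apply(m, 1, paste, collapse = ""))
  pair <- cluster_pair(aln, tree, A, B)
  t2 <- estimate_type2(pair)
  expect_gt(t2$theta2, 0)
  expect_true(all(t2$site_score[planted] > 17))
  # Q->K is a Hydrophilic/+ radical change; Y->N stays within hydrophilic
  pc <- t2$property_change
  expect_equal(unique(pc$label[pc$consensusA == "Q" & pc$consensusB == "K"]),
               "Hydrophilic/+")
  expect_equal(unique(pc$label[pc$consensusA == "Y" & pc$consensusB == "N"]),
               "Hydrophilic/Hydrophilic")
  yn <- planted[seq_along(planted) %% 5 == 3]   # the planted Y->N columns
  expect_false(any(yn %in% t2$radical_sites))
  expect_true(all(setdiff(planted, yn) %in% t2$radical_sites))
})

test_that("identical consensuses give zero radical sites; ties are excluded", {
  tree <- study_tree(4)
  A <- paste0("a", 1:4); B <- paste0("b", 1:4)
  m <- msa_matrix(simulate_family(tree, 20, seed = 5)$alignment)
  for (j in 1:20) m[, j] <- m[1, j]        # all rows identical
  m[A, 1] <- c("A", "A", "C", "C")         # tie in cluster A: no consensus
  aln <- msa(apply(m, 1, paste, collapse = ""))
  pair <- cluster_pair(aln, tree, A, B)
  t2 <- estimate_type2(pair)
  expect_length(t2$radical_sites, 0)
  expect_true(1 %in% t2$excluded)
})

test_that("taxonomic grouping emits all unordered pairs and drops small groups", {
  set.seed(101)
  taxa <- paste0("t", 1:40)
  rows <- setNames(replicate(40, random_aa_string(20)), taxa)
  aln <- msa(rows)
  tree <- ape::rtree(40)
  tree$tip.label <- taxa
  labels <- setNames(rep(paste0("G", 1:10), each = 4), taxa)
  pairs <- taxonomic_grouping(aln, labels, tree)
  expect_length(pairs, 45)   # 10 choose 2

  labels2 <- setNames(rep(c("G1", "G2"), each = 20), taxa)
  expect_length(taxonomic_grouping(aln, labels2, tree), 1)

  labels3 <- labels
  labels3[labels3 == "G1"][1] <- "G2"  # G1 now has 3 taxa
  expect_warning(p3 <- taxonomic_grouping(aln, labels3, tree),
                 "fewer than 4")
  expect_length(p3, 36)      # 9 choose 2
})
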