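test_that("self-alignment gives 100% identity and the diagonal score sum", {
  r <- global_align("ACD", "ACD")
  m <- substitution_matrix("BLOSUM62")
  expect_equal(r$score, m["A", "A"] + m["C", "C"] + m["D", "D"])
  expect_equal(r$identity_pct, 100)
  expect_false(grepl("-", paste0(r$aligned_a, r$aligned_b)))

  set.seed(21)
  s <- random_aa_string(40)
  expect_equal(global_align(s, s)$identity_pct, 100)
})

test_that("alignment score equals exhaustive enumeration on short pairs", {
  m <- substitution_matrix("BLOSUM62")
  set.seed(31)
  for (k in 1:10) {
    a <- random_aa_string(sample(3:6, 1))
    b <- random_aa_string(sample(2:6, 1))
    expect_equal(global_align(a, b)$score,
                 oracle_global_score(a, b, m),
                 info = paste(a, b))
  }
})

test_that("alignment score is symmetric and identity is 100 iff equal", {
  set.seed(32)
  for (k in 1:5) {
    a <- random_aa_string(12); b <- random_aa_string(10)
    expect_equal(global_align(a, b)$score, global_align(b, a)$score)
    expect_lt(global_align(a, b)$identity_pct, 100)
  }
  expect_error(global_align("", "ACD"), "non-empty|empty")
})

test_that("X scores zero against everything and never counts as identical", {
  r <- global_align("AXA", "AXA")
  m <- substitution_matrix("BLOSUM62")
  expect_equal(r$score, 2 * m["A", "A"])
  expect_equal(r$identity_pct, 100 * 2 / 3)
})

test_that("group range matrix matches brute-force pair enumeration", {
  # identical copies: every range collapses to (100, 100)
  g <- list(G1 = sl(c(s1 = "MKVA", s2 = "MKVA")),
            G2 = sl(c(s3 = "MKVA")))
  gr <- group_range_matrix(g, metric = "identity")
  expect_equal(gr$min_pct["G1", "G2"], 100)
  expect_equal(gr$max_pct["G1", "G1"], 100)
  expect_true(is.na(gr$min_pct["G2", "G2"]))  # singleton intra undefined

  gr2 <- group_range_matrix(list(A = sl(c(x = "AAAA")),
                                 B = sl(c(y = "AAAT"))),
                            metric = "identity")
  expect_equal(gr2$min_pct["A", "B"], 75)
  expect_equal(gr2$max_pct["A", "B"], 75)

  set.seed(41)
  groups <- lapply(1:3, function(i)
    sl(setNames(replicate(3, random_aa_string(15)),
                paste0("g", i, "_", 1:3))))
  names(groups) <- c("A", "B", "C")
  gr3 <- group_range_matrix(groups, metric = "similarity")
  # brute force over explicit pairs
  val <- function(x, y) global_align(x, y)$similarity_pct
  inter <- sapply(groups$A, function(x) sapply(groups$B, function(y) val(x, y)))
  expect_equal(gr3$min_pct["A", "B"], min(inter))
  expect_equal(gr3$max_pct["A", "B"], max(inter))
  intra <- c(val(groups$C[[1]], groups$C[[2]]),
             val(groups$C[[1]], groups$C[[3]]),
             val(groups$C[[2]], groups$C[[3]]))
  expect_equal(gr3$min_pct["C", "C"], min(intra))
  expect_equal(gr3$max_pct["C", "C"], max(intra))
})

test_that("homolog filter applies exclusive length bounds then identity", {
  set.seed(51)
  query <- seq_record("q", random_aa_string(300))
  inside <- seq_record("hit_ok", query$residues)
  at349 <- seq_record("hit_349", paste0(query$residues, strrep("G", 49)))
  at350 <- seq_record("hit_350", paste0(query$residues, strrep("G", 50)))
  res <- filter_homologs(list(inside, at349, at350), query,
                         identity_min = 35, length_window = c(250, 350))
  expect_true(res$log$kept[res$log$id == "hit_ok"])
  # length 349 passes the window and identity; 350 falls on the strict bound
  expect_true(res$log$kept[res$log$id == "hit_349"])
  expect_match(res$log$reason[res$log$id == "hit_350"], "length 350")
  expect_false(res$log$kept[res$log$id == "hit_350"])

  # 20 synthetic hits vs hand-applied rules
  hits <- lapply(1:20, function(k) {
    len <- sample(240:360, 1)
    if (k %% 2 == 0) {
      base <- strsplit(query$residues, "")[[1]]
      n <- min(len, 300)
      mut <- sample(n, round(n * 0.3))
      base[mut] <- sample(c("G", "P"), length(mut), replace = TRUE)
      s <- paste(c(base[1:n], rep("W", max(0, len - 300))), collapse = "")
    } else s <- random_aa_string(len)
    seq_record(paste0("h", k), s)
  })
  res2 <- filter_homologs(hits, query, 35, c(250, 350))
  manual <- vapply(hits, function(h) {
    len <- nchar(h$residues)
    len > 250 && len < 350 &&
      global_align(h, query)$identity_pct > 35
  }, TRUE)
  expect_equal(res2$log$kept, manual)
})

test_that("PEST candidates obey composition and length rules", {
  expect_equal(nrow(find_pest(strrep("A", 40))), 0)

  p <- find_pest(paste0("K", "EPSTEPSTEPST", "K"))
  expect_equal(nrow(p), 1)
  expect_equal(p$start, 2)
  expect_equal(p$end, 13)
  expect_equal(p$length, 12)

  # no K/R/H inside any candidate; all spans >= 12
  set.seed(61)
  for (k in 1:5) {
    s <- random_aa_string(120)
    cand <- find_pest(s, threshold = -100)
    if (!nrow(cand)) next
    for (i in seq_len(nrow(cand))) {
      span <- substr(s, cand$start[i], cand$end[i])
      expect_false(grepl("[KRH]", span))
      expect_gte(nchar(span), 12)
      expect_true(grepl("[DE]", span) && grepl("P", span) &&
                    grepl("[ST]", span))
    }
  }
})

test_that("PEST score matches independent hand arithmetic", {
  span <- "EPSTEPSTEPST"
  p <- find_pest(paste0("K", span, "K"), threshold = 5)
  # independent arithmetic: masses and Kyte-Doolittle values typed afresh
  mass <- c(E = 129.1155, P = 97.1167, S = 87.0782, T = 101.1051)
  kd <- c(E = -3.5, P = -1.6, S = -0.8, T = -0.7)
  chars <- strsplit(span, "")[[1]]
  total <- sum(mass[chars])
  pest_mass <- total - (mass[["E"]] + mass[["P"]] + mass[["S"]])
  hyd <- mean(10 * kd[chars] + 45)
  expected <- 0.55 * (100 * pest_mass / total) - 0.5 * hyd
  expect_equal(p$score, expected, tolerance = 1e-10)
  expect_equal(p$valid, expected >= 5)
})
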