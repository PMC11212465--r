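test_that("coverage score reproduces the hand-computed toy matrix", {
  st <- recovery_stats(toy_recovery())
  expect_equal(unname(st$representedness), 0.5)
  expect_equal(unname(st$completeness["g1", c("acc1", "acc2")]),
               c(1.0, 0.5))
  even <- exp(-(2 / 3) * log(2 / 3) - (1 / 3) * log(1 / 3)) / 2
  expect_equal(unname(st$evenness), even, tolerance = 1e-12)
  expect_equal(unname(st$sequence_score["g1", c("acc1", "acc2")]),
               c(1.0 * 0.5 * even, 0.5 * 0.5 * even), tolerance = 1e-12)
  expect_equal(unname(st$gene_score), stats::median(c(0.5, 0.25) * even),
               tolerance = 1e-12)
})

test_that("perfect recovery and total absence hit the score boundaries", {
  full <- recovery_matrix(matrix(100L, 3, 4, dimnames = list(paste0("g", 1:3),
                                                             paste0("a", 1:4))),
                          target_length = rep(100L, 3))
  st <- recovery_stats(full)
  expect_true(all(st$representedness == 1))
  expect_true(all(st$evenness == 1))
  expect_true(all(st$gene_score == 1))
  gone <- recovery_matrix(rbind(g1 = c(100L, 100L), g2 = c(0L, 0L)),
                          target_length = c(100L, 100L))
  expect_equal(unname(recovery_stats(gone)$gene_score["g2"]), 0)
})

test_that("scores are invariant to ordering and to common length scaling", {
  set.seed(11)
  rl <- matrix(sample(0:120, 40, TRUE), 5, 8,
               dimnames = list(paste0("g", 1:5), paste0("a", 1:8)))
  tl <- sample(80:120, 5)
  st <- recovery_stats(recovery_matrix(rl, tl))
  perm_g <- sample(5); perm_a <- sample(8)
  st_p <- recovery_stats(recovery_matrix(rl[perm_g, perm_a], tl[perm_g]))
  expect_equal(unname(st_p$gene_score), unname(st$gene_score[perm_g]))
  st_s <- recovery_stats(recovery_matrix(rl * 7L, tl * 7L))
  expect_equal(st_s$gene_score, st$gene_score)
  expect_equal(st_s$evenness, st$evenness)
})

test_that("paralog and 2/3-median filters fire exactly at their boundaries", {
  # gene with >= 2 copies in exactly 3 accessions is removed; 2 is kept
  rl <- matrix(100L, 3, 4, dimnames = list(c("par3", "par2", "ok"),
                                           paste0("a", 1:4)))
  cc <- matrix(1L, 3, 4, dimnames = dimnames(rl))
  cc["par3", 1:3] <- 2L
  cc["par2", 1:2] <- 2L
  m <- recovery_matrix(rl, rep(100L, 3), cc)
  f <- filter_genes(recovery_stats(m), m)
  expect_false("par3" %in% f$retained)
  expect_true(all(c("par2", "ok") %in% f$retained))
  expect_equal(f$log$rule[f$log$gene == "par3"], "paralog")

  # five genes with scores (1.0, .9, .9, .9, .5): median .9, cut .6
  rl2 <- rbind(g1 = c(100L, 100L), g2 = c(90L, 90L), g3 = c(90L, 90L),
               g4 = c(90L, 90L), g5 = c(50L, 50L))
  colnames(rl2) <- c("a1", "a2")
  m2 <- recovery_matrix(rl2, rep(100L, 5))
  st2 <- recovery_stats(m2)
  expect_equal(unname(st2$gene_score), c(1, 0.9, 0.9, 0.9, 0.5))
  f2 <- filter_genes(st2, m2)
  expect_setequal(f2$retained, c("g1", "g2", "g3", "g4"))
  # a gene at the median is retained (median >= 2/3 median)
  expect_true("g2" %in% f2$retained)
})

test_that("filtering the retained set again removes nothing on strict data", {
  rl <- rbind(g1 = c(100L, 100L), g2 = c(95L, 95L), g3 = c(90L, 90L),
              g4 = c(85L, 85L))
  colnames(rl) <- c("a1", "a2")
  m <- recovery_matrix(rl, rep(100L, 4))
  f1 <- filter_genes(recovery_stats(m), m)
  keep <- match(f1$retained, rownames(rl))
  m2 <- recovery_matrix(rl[keep, , drop = FALSE], rep(100L, length(keep)))
  f2 <- filter_genes(recovery_stats(m2), m2)
  expect_identical(sort(f2$retained), sort(f1$retained))
})

test_that("all genes removed yields a warning and an empty list", {
  rl <- rbind(g1 = c(100L, 100L, 100L))
  colnames(rl) <- paste0("a", 1:3)
  cc <- rl * 0L + 2L
  m <- recovery_matrix(rl, 100L, cc)
  expect_warning(f <- filter_genes(recovery_stats(m), m), "all genes")
  expect_length(f$retained, 0)
})

test_that("k-medoids selection covers tight clusters and matches brute force", {
  # single sequence: its own medoid
  one <- matrix(c("A", "C", "G"), 1, 3, dimnames = list("s1", NULL))
  r1 <- select_targets_kmedoids(one)
  expect_equal(r1$k, 1L)
  expect_equal(r1$medoids, "s1")
  # ten identical sequences: k = 1
  ten <- matrix("A", 10, 20, dimnames = list(paste0("s", 1:10), NULL))
  expect_equal(select_targets_kmedoids(ten)$k, 1L)
  # two tight clusters 0.4 apart, within-cluster distance <= 0.05
  base1 <- rep(c("A", "C", "G", "T"), 25)
  base2 <- base1
  base2[1:40] <- ifelse(base1[1:40] == "A", "C", "A")  # 40% different
  seqs <- rbind(c1a = base1, c1b = replace(base1, 1:4, "T"),
                c2a = base2, c2b = replace(base2, 97:100, "T"))
  r2 <- select_targets_kmedoids(seqs, radius = 0.15)
  expect_equal(r2$k, 2L)
  expect_length(r2$uncovered, 0)
  # brute force over all C(4,2) medoid pairs: some pair must cover at r=0.15
  D <- symcord:::pairwise_identity_dist(seqs)
  pairs <- utils::combn(4, 2)
  best_cover <- min(apply(pairs, 2, function(p) {
    max(apply(D[, p, drop = FALSE], 1, min))
  }))
  expect_lte(max(apply(D[, match(r2$medoids, rownames(seqs)), drop = FALSE],
                       1, min)), best_cover + 1e-12)
  # k = n with radius 0 is always feasible
  rn <- select_targets_kmedoids(seqs, max_k = 4, radius = 0)
  expect_length(rn$uncovered, 0)
})
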