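test_that("simulated species trees are ultrametric, seeded and outgrouped", {
  tr <- simulate_species_tree(8, 2, 187.0, seed = 7)
  expect_equal(ape::Ntip(tr$tree), 10)
  ages <- node_ages(tr$tree)
  expect_lt(max(abs(ages[1:10])), 1e-9)
  expect_equal(max(ages), 187.0)
  # ingroup crown strictly younger than the root
  ig <- grep("^IG", tr$tree$tip.label, value = TRUE)
  expect_lt(ages[ape::getMRCA(tr$tree, ig)], 187.0)
  # outgroup is monophyletic and sister to the ingroup
  expect_true(ape::is.monophyletic(tr$tree, grep("^OG", tr$tree$tip.label,
                                                 value = TRUE)))
  a <- simulate_species_tree(5, 1, 100, seed = 3)
  b <- simulate_species_tree(5, 1, 100, seed = 3)
  expect_identical(ape::write.tree(a$tree), ape::write.tree(b$tree))
  expect_error(simulate_species_tree(1, 1, 100), "invalid")
  expect_error(simulate_species_tree(4, 1, -5), "invalid")
})

test_that("gene-tree concordance matches the closed-form MSC probability", {
  n <- 1500
  for (d in c(0.5, 2)) {
    gt <- simulate_gene_trees(caterpillar_truth(d), n, seed = 100 + d * 10)
    p <- 1 - (2 / 3) * exp(-d)
    se <- sqrt(p * (1 - p) / n)
    expect_lt(abs(fraction_concordant(gt) - p), 3 * se)
  }
  # d -> infinity: every gene tree matches
  gt <- simulate_gene_trees(caterpillar_truth(50), 200, seed = 5)
  expect_equal(fraction_concordant(gt), 1)
})

test_that("introgression with gamma 1 regrafts every gene; gamma 0 changes nothing", {
  truth <- scenario_preset("baseline", seed = 1)$truth
  ev1 <- introgression_event(c("C1", "C2"), c("R1", "R2"), gamma = 1,
                             time = 20, affects = "nuclear")
  gt <- simulate_gene_trees(truth, 40, event = ev1, seed = 9)
  expect_true(all(attr(gt, "followed")))
  # in every gene, R coalesces inside the C+D side, with C rather than D
  for (g in gt) {
    D <- ape::cophenetic.phylo(g)
    expect_lt(D["R1", "C1"], D["R1", "D1"])
    expect_lt(D["R1", "C1"], D["R1", "A1"])
  }
  ev0 <- introgression_event(c("C1", "C2"), c("R1", "R2"), gamma = 0,
                             time = 20, affects = "nuclear")
  g0 <- simulate_gene_trees(truth, 15, event = ev0, seed = 77)
  gn <- simulate_gene_trees(truth, 15, event = NULL, seed = 77)
  expect_identical(ape::write.tree(g0), ape::write.tree(gn))
  expect_error(simulate_gene_trees(truth, 2, event =
    introgression_event("nope", c("R1", "R2"), 0.5, 20, affects = "nuclear"),
    seed = 1), "not present")
})

test_that("plastid c-gene follows the captured history deterministically", {
  truth <- scenario_preset("baseline", seed = 1)$truth
  ev <- introgression_event(c("C1", "C2"), c("R1", "R2"), gamma = 0.9,
                            time = 20, affects = "plastid")
  pt <- simulate_plastid_tree(truth, ev, follow = "expected")
  expect_true(attr(pt, "followed"))
  expect_equal(rf_distance(pt, truth$tree)$rf, 2)
  pn <- simulate_plastid_tree(truth, NULL)
  expect_false(attr(pn, "followed"))
  expect_equal(rf_distance(pn, truth$tree)$rf, 0)
})

test_that("sequence simulation honors the JC69 closed form and the seed", {
  two <- ape::read.tree(text = "(A:0.05,B:0.05);")
  aln <- simulate_alignments(two, 40000, seed = 3)[[1]]
  p_obs <- mean(aln["A", ] != aln["B", ])
  d <- 0.1
  p_exp <- 0.75 * (1 - exp(-4 * d / 3))
  se <- sqrt(p_exp * (1 - p_exp) / 40000)
  expect_lt(abs(p_obs - p_exp), 3 * se)
  # zero-length branches give identical sequences
  z <- ape::read.tree(text = "(A:0,B:0);")
  alz <- simulate_alignments(z, 500, seed = 1)[[1]]
  expect_identical(alz["A", ], alz["B", ])
  # byte-level determinism
  a1 <- simulate_alignments(two, 100, seed = 8)[[1]]
  a2 <- simulate_alignments(two, 100, seed = 8)[[1]]
  expect_identical(a1, a2)
  expect_error(simulate_alignments(two, 100, model = list(name = "GTR")),
               "unknown model")
})

test_that("HKY simulation respects its stationary base frequencies", {
  tr <- ape::read.tree(text = "(A:0.3,B:0.3);")
  bf <- c(0.4, 0.3, 0.2, 0.1)
  aln <- simulate_alignments(tr, 30000, seed = 4,
                             model = list(name = "HKY", kappa = 3, bf = bf))[[1]]
  freq <- table(factor(aln, levels = c("A", "C", "G", "T"))) / length(aln)
  expect_lt(max(abs(as.numeric(freq) - bf)), 0.02)
})

test_that("degradation produces the requested missingness and paralog counts", {
  truth <- simulate_species_tree(10, 2, 50, seed = 2)
  gt <- simulate_gene_trees(truth, 40, seed = 3)
  aln <- simulate_alignments(gt, 60, seed = 4)
  deg <- degrade_recovery(aln, missing_rate = 0.1,
                          truncation = list(kind = "fixed", value = 1),
                          paralog_rate = 0, seed = 5)
  m <- deg$matrix
  frac_absent <- mean(m$recovered_length == 0)
  se <- sqrt(0.1 * 0.9 / length(m$recovered_length))
  expect_lt(abs(frac_absent - 0.1), 3 * se)
  expect_true(all(m$copy_count[m$recovered_length > 0] == 1L))
  # no degradation at all: completeness 1 everywhere
  none <- degrade_recovery(aln, missing_rate = 0,
                           truncation = list(kind = "fixed", value = 1),
                           paralog_rate = 0, seed = 6)
  st <- recovery_stats(none$matrix)
  expect_true(all(st$completeness == 1))
  expect_true(all(st$gene_score == 1))
  # everything missing: empty matrix allowed
  all_gone <- degrade_recovery(aln, missing_rate = 1,
                               truncation = list(kind = "fixed", value = 1),
                               paralog_rate = 0, seed = 7)
  expect_true(all(all_gone$matrix$recovered_length == 0))
})

test_that("Mk character simulation matches the ER closed form", {
  # two tips separated by total path 2t: P(equal) = 1/3 + (2/3) e^(-3 q 2t)
  tr <- ape::read.tree(text = "(A:2,B:2);")
  truth <- species_tree_truth(tr, cu_per_my = 1)
  q <- 0.15
  n <- 3000
  eq <- logical(n)
  for (i in seq_len(n)) {
    s <- simulate_character(truth, q, seed = i)
    eq[i] <- s$states["A"] == s$states["B"]
  }
  p <- 1 / 3 + (2 / 3) * exp(-3 * q * 4)
  se <- sqrt(p * (1 - p) / n)
  expect_lt(abs(mean(eq) - p), 3 * se)
  # rate 0: all tips share the root state
  s0 <- simulate_character(caterpillar_truth(1), 0, seed = 2)
  expect_equal(length(unique(s0$states)), 1L)
  expect_equal(unname(s0$ancestral[1]), unname(s0$states[1]))
  # determinism
  s1 <- simulate_character(caterpillar_truth(1), 0.1, seed = 4)
  s2 <- simulate_character(caterpillar_truth(1), 0.1, seed = 4)
  expect_identical(s1$states, s2$states)
})

test_that("a single-tip recipient can be regrafted onto the donor lineage", {
  truth <- scenario_preset("baseline", seed = 1)$truth
  ev <- introgression_event(donor = c("C1", "C2"), recipient = "A1",
                            gamma = 1, time = 30, affects = "nuclear")
  gt <- simulate_gene_trees(truth, 5, event = ev, seed = 3)
  for (g in gt) {
    D <- ape::cophenetic.phylo(g)
    expect_lt(D["A1", "C1"], D["A1", "A2"])
  }
  # infeasible event times are refused
  too_old <- introgression_event(c("C1", "C2"), c("R1", "R2"), 1, 90,
                                 affects = "nuclear")
  expect_error(simulate_gene_trees(truth, 2, event = too_old, seed = 1),
               "younger than")
  too_young <- introgression_event(c("C1", "C2"), c("R1", "R2"), 1, 5,
                                   affects = "nuclear")
  expect_error(simulate_gene_trees(truth, 2, event = too_young, seed = 1),
               "older than")
})
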