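test_that("pruning tips merges branches and preserves total length elsewhere", {
  tr <- ape::read.tree(text = "((A:1,B:1):2,(C:1.5,D:1.5):1.5);")
  expect_identical(ape::write.tree(prune_tips(tr, character(0))),
                   ape::write.tree(tr))
  p <- prune_tips(tr, "A")
  expect_equal(ape::Ntip(p), 3)
  # B's new pendant branch is the sum of the two merged edges
  expect_equal(p$edge.length[p$edge[, 2] == match("B", p$tip.label)], 3)
  # random-tree length audit: pruning a tip not adjacent to the root removes
  # its pendant length only (the degree-2 merge preserves the rest)
  for (s in 1:5) {
    r <- random_binary_tree(7, s)
    root <- ape::Ntip(r) + 1L
    tips <- which(r$edge[, 2] <= 7 & r$edge[, 1] != root)
    tip_node <- r$edge[tips[1], 2]
    pend <- r$edge.length[tips[1]]
    pr <- prune_tips(r, r$tip.label[tip_node])
    expect_equal(sum(pr$edge.length), sum(r$edge.length) - pend,
                 tolerance = 1e-12)
  }
  expect_error(prune_tips(tr, c("A", "B")), "fewer than 3")
})

test_that("symmetry coding applies the study's override rules", {
  taxa <- c("Delphinium_gracile", "Euptelea_pleiosperma_A",
            "Hypecoum_procumbens_A", "Papaver_rhoeas", "Capnoides_sempervirens",
            "Dicentra_cucullaria", "Ranunculus_bulbosus")
  st <- code_symmetry(taxa)
  expect_equal(unname(st["Delphinium_gracile"]), "zygomorphic")
  expect_equal(unname(st["Euptelea_pleiosperma_A"]), "missing")
  expect_equal(unname(st["Hypecoum_procumbens_A"]), "disymmetric")
  expect_equal(unname(st["Capnoides_sempervirens"]), "zygomorphic")
  expect_equal(unname(st["Dicentra_cucullaria"]), "disymmetric")
  expect_equal(unname(st["Papaver_rhoeas"]), "actinomorphic")
  expect_equal(unname(st["Ranunculus_bulbosus"]), "actinomorphic")
  expect_error(code_symmetry(taxa, c(Papaver = "spiral")), "unknown state")
})

test_that("pruning likelihood and marginals match brute-force enumeration", {
  tree5 <- ape::read.tree(text = "((A:1,B:1):1,((C:1,D:1):0.5,E:1.5):0.5);")
  chars <- c(A = "actinomorphic", B = "disymmetric", C = "zygomorphic",
             D = "zygomorphic", E = "actinomorphic")
  states <- c("actinomorphic", "disymmetric", "zygomorphic")
  for (q in c(0.05, 0.3, 2)) {
    ref <- brute_mk(tree5, chars, q, states)
    expect_lt(abs(symcord:::mk_loglik(tree5, chars, q) - ref$logLik), 1e-10)
    asr <- marginal_asr(tree5, chars, q)
    expect_lt(max(abs(asr$prob - ref$marginals)), 1e-10)
    expect_equal(unname(rowSums(asr$prob)), rep(1, 4), tolerance = 1e-9)
  }
  # missing data as all-ones conditionals, still matching brute force
  chars_m <- replace(chars, "E", "missing")
  ref_m <- brute_mk(tree5, chars_m, 0.3, states)
  expect_lt(abs(symcord:::mk_loglik(tree5, chars_m, 0.3) - ref_m$logLik),
            1e-10)
})

test_that("two-tip closed form and degenerate cases behave", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  # A and B differ; C missing so only the A-B path (2t = 2) informs
  chars <- c(A = "actinomorphic", B = "zygomorphic", C = "missing")
  q <- 0.2
  p_change_pair <- (1 - (1 / 3 + (2 / 3) * exp(-3 * q * 2))) / 2
  expect_equal(symcord:::mk_loglik(tr, chars, q),
               log((1 / 3) * p_change_pair), tolerance = 1e-10)
  # all tips in one state: rate collapses to the lower bound
  mono <- c(A = "actinomorphic", B = "actinomorphic", C = "actinomorphic")
  fit <- fit_mk(tr, mono)
  expect_lt(fit$rate, 1e-4)
  expect_equal(fit$logLik, log(1 / 3), tolerance = 1e-4)
  # rate 0 with uniform tips: ancestral probability 1 everywhere
  asr0 <- marginal_asr(tr, mono, 0)
  expect_equal(unname(asr0$prob[, "actinomorphic"]), rep(1, 2))
  expect_error(fit_mk(tr, c(A = "missing", B = "missing", C = "missing")),
               "all tips missing")
})

test_that("fit and ancestral marginals agree with the reference implementation", {
  set.seed(31)
  tr <- ape::rcoal(12)
  truth <- species_tree_truth(tr, cu_per_my = 1)
  sim <- simulate_character(truth, rate = 0.8, seed = 32)
  fit <- fit_mk(tr, sim$states)
  ref <- ape::ace(factor(sim$states[tr$tip.label],
                         levels = fit$states), tr,
                  type = "discrete", model = "ER")
  expect_equal(fit$rate, unname(ref$rates), tolerance = 1e-3)
  # ace omits the uniform root prior constant log(1/k)
  expect_equal(fit$logLik, ref$loglik - log(3), tolerance = 1e-5)
})

test_that("marginals are equivariant under state relabeling", {
  tree5 <- ape::read.tree(text = "((A:1,B:1):1,((C:1,D:1):0.5,E:1.5):0.5);")
  chars <- c(A = "actinomorphic", B = "disymmetric", C = "zygomorphic",
             D = "zygomorphic", E = "actinomorphic")
  asr <- marginal_asr(tree5, chars, 0.4)
  swap <- c(actinomorphic = "zygomorphic", disymmetric = "disymmetric",
            zygomorphic = "actinomorphic", missing = "missing")
  asr2 <- marginal_asr(tree5, stats::setNames(swap[chars], names(chars)), 0.4)
  expect_equal(asr$prob[, "actinomorphic"], asr2$prob[, "zygomorphic"],
               tolerance = 1e-12)
})

test_that("rate recovery stays inside the likelihood-ratio interval", {
  truth <- simulate_species_tree(60, 2, 100, seed = 41)
  hits <- 0L
  n_rep <- 10L
  for (i in seq_len(n_rep)) {
    sim <- simulate_character(truth, rate = 0.01, seed = 500 + i)
    f <- fit_mk(truth$tree, sim$states)
    lr <- 2 * (f$logLik - symcord:::mk_loglik(truth$tree, sim$states, 0.01))
    hits <- hits + (lr <= stats::qchisq(0.95, 1))
  }
  expect_gte(hits, ceiling(0.7 * n_rep))
})
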