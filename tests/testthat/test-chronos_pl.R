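test_that("the penalized objective matches hand arithmetic on a 3-branch toy", {
  # ((A,B):root) with branches A, B and one child pair at the root
  tr <- ape::read.tree(text = "((A:0.1,B:0.2):0.05,C:0.3);")
  ntip <- 3
  ages <- c(0, 0, 0, 10, 4)  # tips, root, AB node
  rates <- c(0.02, 0.03, 0.01, 0.015)  # in tree$edge order
  sites <- 1000
  lambda <- 1
  x <- tr$edge.length * sites
  parent <- tr$edge[, 1]; child <- tr$edge[, 2]
  t_b <- ages[parent] - ages[child]
  ll <- sum(x * log(rates * t_b) - rates * t_b)
  # penalty: child edges of non-root parents + variance at the root
  pe <- match(parent, child)
  phi <- sum((rates[!is.na(pe)] - rates[pe[!is.na(pe)]])^2) +
    stats::var(rates[parent == ntip + 1])
  expect_equal(pl_objective(tr, ages, rates, lambda, sites),
               ll - lambda * phi, tolerance = 1e-12)
  # saturation: r*t = x and lambda = 0 gives the Poisson maximum
  r_sat <- x / t_b
  expect_equal(pl_objective(tr, ages, r_sat, 0, sites),
               sum(x * log(x) - x), tolerance = 1e-10)
  # equal rates: penalty vanishes for any lambda
  r_eq <- rep(0.02, 4)
  expect_equal(pl_objective(tr, ages, r_eq, 0, sites),
               pl_objective(tr, ages, r_eq, 1e6, sites))
  bad_ages <- c(0, 0, 0, 10, 11)
  expect_error(pl_objective(tr, bad_ages, rates, 1, sites), "invalid ages")
})

test_that("the packaged fossil ledger carries the study's constraints", {
  calib <- load_calibrations()
  root <- calib[calib$label == "root", ]
  expect_equal(root$min_age, 125)
  expect_equal(root$max_age, 201.5)
  expect_equal(calib$min_age[calib$label == "ranunculales_crown"], 125)
  expect_equal(calib$max_age[calib$label == "ranunculales_crown"], 201.5)
  expect_equal(calib$min_age[calib$label == "sabiaceae_crown"], 83.4)
  expect_equal(calib$min_age[calib$label == "lardizabalaceae_stem"], 110)
  expect_equal(calib$min_age[calib$label == "lardizabalaceae_crown"], 41.2)
  expect_equal(calib$min_age[calib$label == "menispermaceae_stem"], 91)
  expect_equal(calib$min_age[calib$label == "menispermaceae_crown"], 64.67)
  expect_equal(calib$min_age[calib$label ==
                               "coptidoideae_ranunculoideae_crown"], 56)
  tips <- grep("_tip$", calib$label)
  expect_length(tips, 3)
  expect_true(all(calib$max_age[tips] == 1))
  # every row resolves on the exemplar tree and its ages are feasible
  ex <- ranunculales_exemplar_tree()
  res <- resolve_calibrations(ex, calib)
  expect_equal(nrow(res), nrow(calib))
  ages <- node_ages(ex)
  expect_true(all(ages[res$node] >= res$min_age - 1e-9))
  expect_true(all(ages[res$node] <= res$max_age + 1e-9))
})

test_that("a fully constrained two-tip tree dates exactly", {
  tr <- ape::read.tree(text = "(A:0.1,B:0.3);")
  calib <- data.frame(label = "root", tip_a = "root", tip_b = NA,
                      min_age = 100, max_age = 100)
  ch <- date_tree(tr, calib, dating_config(smoothing = 0, site_count = 1000),
                  seed = 1)
  expect_equal(max(ch$ages), 100, tolerance = 1e-4)
  # saturation: r t = x, i.e. r = branch length / root age when lambda = 0
  expect_equal(ch$rates, tr$edge.length / 100, tolerance = 0.05)
})

test_that("strict-clock simulation is recovered within 5% at 10k sites", {
  clock <- clock_test_tree()
  sites <- 10000
  tr <- clock
  set.seed(4)
  tr$edge.length <- stats::rpois(nrow(tr$edge),
                                 clock$edge.length * 0.005 * sites) / sites
  calib <- data.frame(label = "root", tip_a = "root", tip_b = NA,
                      min_age = 100, max_age = 100)
  ch <- date_tree(tr, calib, dating_config(smoothing = 0.01,
                                           site_count = sites), seed = 2)
  ii <- (ape::Ntip(tr) + 1):(ape::Ntip(tr) + tr$Nnode)
  true_ages <- node_ages(clock)
  expect_lt(max(abs(ch$ages[ii] - true_ages[ii]) / true_ages[ii]), 0.05)
  # chronogram invariants
  tip_ages <- ch$ages[1:ape::Ntip(tr)]
  expect_lt(max(abs(tip_ages)), 1e-9 * max(ch$ages))
  expect_true(all(ch$tree$edge.length > 0))
  expect_true(all(ch$rates > 0))
})

test_that("infeasible or unidentifiable constraint sets are refused", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  no_max <- data.frame(label = "root", tip_a = "root", tip_b = NA,
                       min_age = 10, max_age = NA)
  expect_error(date_tree(tr, no_max, dating_config(site_count = 100)),
               "maximum")
  clash <- data.frame(label = c("root", "ab"),
                      tip_a = c("root", "A"), tip_b = c(NA, "B"),
                      min_age = c(NA, 50), max_age = c(40, NA))
  expect_error(date_tree(tr, clash, dating_config(site_count = 100)),
               "infeasible")
  ghost <- data.frame(label = "x", tip_a = "A", tip_b = "Z",
                      min_age = 1, max_age = 2)
  expect_error(resolve_calibrations(tr, ghost), "row 1")
})

test_that("cross-validation scores every lambda and prefers smoothing on clock data", {
  truth <- simulate_species_tree(5, 1, 100, seed = 19)
  sites <- 5000
  tr <- truth$tree
  set.seed(6)
  tr$edge.length <- stats::rpois(nrow(tr$edge),
                                 truth$tree$edge.length * 0.002 * sites) / sites
  calib <- data.frame(label = "root", tip_a = "root", tip_b = NA,
                      min_age = 100, max_age = 100)
  cfg <- dating_config(cv_grid = c(1e-6, 1e-2, 1e2), site_count = sites,
                       priming_iterations = 2L, cv_iterations = 2L)
  cv <- cross_validate(tr, calib, cfg, seed = 3)
  expect_equal(nrow(cv$table), 3)
  expect_true(cv$lambda %in% cfg$cv_grid)
  # on clock data heavy smoothing must not hurt relative to almost none
  expect_lte(cv$table$score[3], cv$table$score[1] * 1.5)
  # a single-value grid returns that value
  cfg1 <- dating_config(cv_grid = 0.01, site_count = sites,
                        priming_iterations = 2L, cv_iterations = 2L)
  expect_equal(cross_validate(tr, calib, cfg1, seed = 3)$lambda, 0.01)
  expect_error(cross_validate(tr, calib,
                              dating_config(cv_grid = numeric(0),
                                            site_count = sites)),
               "empty")
})
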