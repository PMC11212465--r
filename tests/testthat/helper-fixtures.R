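# Shared fixtures, built in code.

# Rooted caterpillar (((A,B),C),D) whose only ILS-relevant internal branch
# (the AB stem) has d coalescent units; the branch above MRCA(ABC) is long
# enough that all lineages coalesce before the root, so the gene-tree
# concordance probability is exactly 1 - (2/3) exp(-d).
caterpillar_truth <- function(d) {
  tree <- ape::read.tree(text = "(((A:1,B:1):1,C:2):1,D:3);")
  cu <- rep(1, nrow(tree$edge))
  ab <- ape::getMRCA(tree, c("A", "B"))
  abc <- ape::getMRCA(tree, c("A", "B", "C"))
  cu[tree$edge[, 2] == ab] <- d
  cu[tree$edge[, 2] == abc] <- 50
  species_tree_truth(tree, cu_per_my = cu)
}

# does a 4-taxon gene tree display AB|CD?
shows_ab_cd <- function(g, a = "A", b = "B", c = "C", d = "D") {
  D <- ape::cophenetic.phylo(g)
  (D[a, b] + D[c, d]) < min(D[a, c] + D[b, d], D[a, d] + D[b, c]) - 1e-12
}

fraction_concordant <- function(gene_trees) {
  mean(vapply(gene_trees, shows_ab_cd, logical(1)))
}

# balanced 5-state test alignment matrix builders
toy_recovery <- function() {
  recovery_matrix(
    matrix(c(100, 50, 0, 0), 1, 4,
           dimnames = list("g1", paste0("acc", 1:4))),
    target_length = 100)
}

random_binary_tree <- function(n, seed) {
  set.seed(seed)
  ape::rtree(n)
}

# brute-force ER Mk likelihood + marginals by enumerating internal states
brute_mk <- function(tree, chars, q, states) {
  k <- length(states)
  er_p <- function(t) {
    e <- exp(-k * q * t)
    p <- matrix((1 - e) / k, k, k)
    diag(p) <- 1 / k + (1 - 1 / k) * e
    p
  }
  ntip <- ape::Ntip(tree)
  nint <- tree$Nnode
  grid <- expand.grid(rep(list(seq_len(k)), nint))
  tot <- 0
  marg <- matrix(0, nint, k)
  tipidx <- match(chars[tree$tip.label], states)
  for (i in seq_len(nrow(grid))) {
    asgn <- c(tipidx, as.integer(grid[i, ]))
    pr <- 1 / k
    for (e in seq_len(nrow(tree$edge))) {
      a <- asgn[tree$edge[e, 1]]
      b <- asgn[tree$edge[e, 2]]
      if (is.na(b)) next  # missing tip: sum over states = row sum = 1
      pr <- pr * er_p(tree$edge.length[e])[a, b]
    }
    tot <- tot + pr
    for (v in seq_len(nint)) {
      marg[v, asgn[ntip + v]] <- marg[v, asgn[ntip + v]] + pr
    }
  }
  list(logLik = log(tot), marginals = marg / rowSums(marg))
}

# brute-force quartet tally: enumerate every 4-subset of the topology's taxa
# and every gene tree directly
brute_quartet_tally <- function(gene_trees, topology) {
  taxa <- sort(topology$tip.label)
  quartets <- utils::combn(taxa, 4)
  res_of <- function(tr, q) {
    if (!all(q %in% tr$tip.label)) return(NA_integer_)
    t2 <- tr
    t2$edge.length <- rep(1, nrow(t2$edge))
    D <- ape::cophenetic.phylo(t2)
    s <- c(D[q[1], q[2]] + D[q[3], q[4]],
           D[q[1], q[3]] + D[q[2], q[4]],
           D[q[1], q[4]] + D[q[2], q[3]])
    w <- which(s <= min(s) + 1e-9)
    if (length(w) == 1L) w else 0L
  }
  out <- list()
  for (i in seq_len(ncol(quartets))) {
    q <- quartets[, i]
    sp <- res_of(topology, q)
    z <- c(0, 0, 0)
    for (g in gene_trees) {
      r <- res_of(g, q)
      if (is.na(r)) next
      if (r == 0L) z <- z + 1 / 3 else z[r] <- z[r] + 1
    }
    out[[i]] <- list(quartet = q, species_res = sp, z = z)
  }
  out
}

# Fixed 10-tip strict-clock tree for dating recovery: node ages are well
# separated (every branch >= 7 My) so that at 10,000 sites each age carries
# enough expected substitutions for a 5% relative-error check to have power.
clock_test_tree <- function() {
  ape::read.tree(text = paste0(
    "(t1:100,(t2:86,(t3:73,(t4:61,(t5:50,(t6:40,(t7:31,(t8:23,",
    "(t9:16,t10:16):7):8):9):10):11):12):13):14);"))
}
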