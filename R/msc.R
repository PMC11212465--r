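# Quartet-based species-tree estimation under the multispecies coalescent:
# per-branch quartet tallies, local posterior probabilities, coalescent-unit
# branch lengths, exhaustive and NNI hill-climbing searches.

# All 4-subsets of seq_len(n), columns sorted; plus a key lookup.
quartet_table <- function(n) {
  q <- t(utils::combn(n, 4L))
  key <- paste(q[, 1L], q[, 2L], q[, 3L], q[, 4L])
  list(q = q, index = stats::setNames(seq_len(nrow(q)), key))
}

# Per-quartet resolution counts aggregated over gene trees. Rows follow
# quartet_table(length(taxa)); columns are the three resolutions
# (1 = ab|cd, 2 = ac|bd, 3 = ad|bc on sorted taxa); a polytomy contributes
# 1/3 to each. Quartets with a missing member in a gene are skipped there.
gene_quartet_counts <- function(gene_trees, taxa = NULL) {
  if (inherits(gene_trees, "phylo")) {
    gene_trees <- structure(list(gene_trees), class = "multiPhylo")
  }
  if (is.null(taxa)) {
    taxa <- sort(unique(unlist(lapply(gene_trees, `[[`, "tip.label"))))
  }
  n <- length(taxa)
  qt <- quartet_table(n)
  counts <- matrix(0, nrow(qt$q), 3L)
  for (tr in gene_trees) {
    pos <- match(taxa, tr$tip.label)  # NA where missing
    D <- topo_dist(tr)
    ord <- match(tr$tip.label, colnames(D))
    for (r in seq_len(nrow(qt$q))) {
      idx <- pos[qt$q[r, ]]
      if (anyNA(idx)) next
      res <- quartet_resolution(D, ord[idx[1L]], ord[idx[2L]],
                                ord[idx[3L]], ord[idx[4L]])
      if (res == 0L) counts[r, ] <- counts[r, ] + 1 / 3
      else counts[r, res] <- counts[r, res] + 1
    }
  }
  structure(list(taxa = taxa, quartets = qt$q, index = qt$index,
                 counts = counts),
            class = "quartet_counts")
}

# Resolution of every quartet induced by a (binary) topology, as a vector of
# 1/2/3 aligned with qc$quartets.
topology_resolutions <- function(topology, qc) {
  pos <- match(qc$taxa, topology$tip.label)
  if (anyNA(pos)) stop("topology is missing taxa")
  D <- topo_dist(topology)
  ord <- match(topology$tip.label, colnames(D))
  vapply(seq_len(nrow(qc$quartets)), function(r) {
    idx <- pos[qc$quartets[r, ]]
    quartet_resolution(D, ord[idx[1L]], ord[idx[2L]], ord[idx[3L]], ord[idx[4L]])
  }, integer(1))
}

# Total quartet agreement score of a candidate species topology.
quartet_score <- function(topology, qc) {
  res <- topology_resolutions(topology, qc)
  resolved <- res > 0L
  sum(qc$counts[cbind(which(resolved), res[resolved])]) +
    sum(qc$counts[!resolved, ]) / 3
}

# The four tip sets around each internal edge of an unrooted binary tree:
# removing edge (u, v) and its endpoints leaves subtrees A1, A2 (at u) and
# B1, B2 (at v).
edge_quadripartitions <- function(topology) {
  tr <- ape::unroot(topology)
  ntip <- ape::Ntip(tr)
  nb <- vector("list", ntip + tr$Nnode)
  for (e in seq_len(nrow(tr$edge))) {
    u <- tr$edge[e, 1L]; v <- tr$edge[e, 2L]
    nb[[u]] <- c(nb[[u]], v)
    nb[[v]] <- c(nb[[v]], u)
  }
  tips_from <- function(start, blocked) {
    seen <- c(blocked)
    stack <- start
    tips <- integer(0)
    while (length(stack)) {
      x <- stack[[1L]]; stack <- stack[-1L]
      if (x %in% seen) next
      seen <- c(seen, x)
      if (x <= ntip) tips <- c(tips, x)
      stack <- c(stack, setdiff(nb[[x]], seen))
    }
    tips
  }
  internal <- which(tr$edge[, 2L] > ntip)
  out <- list()
  for (e in internal) {
    u <- tr$edge[e, 1L]; v <- tr$edge[e, 2L]
    au <- setdiff(nb[[u]], v)
    av <- setdiff(nb[[v]], u)
    if (length(au) != 2L || length(av) != 2L) {
      stop("topology is not binary around an internal edge")
    }
    out[[length(out) + 1L]] <- list(
      edge = e, child = v,
      A = lapply(au, function(w) tr$tip.label[tips_from(w, u)]),
      B = lapply(av, function(w) tr$tip.label[tips_from(w, v)]))
  }
  attr(out, "tree") <- tr
  out
}

#' Tally gene-tree quartets around each internal branch of a species tree
#'
#' For every internal branch, aggregates over genes and over all quartets
#' with one taxon drawn from each of the four subtrees the branch separates:
#' z1 counts gene-tree quartets matching the species-tree resolution, z2 and
#' z3 its two alternatives; polytomous gene-tree quartets contribute 1/3 to
#' each.
#'
#' @param gene_trees `multiPhylo` (tips a subset of the topology's tips).
#' @param topology Unrooted binary species-tree `phylo`.
#' @return Data frame with one row per internal edge: `child` (ape node id
#'   in the unrooted topology), `z1`, `z2`, `z3`, `n_eff`, `q1`, `q2`, `q3`.
#' @export
quartet_tally <- function(gene_trees, topology) {
  qc <- if (inherits(gene_trees, "quartet_counts")) gene_trees
        else gene_quartet_counts(gene_trees, sort(topology$tip.label))
  quads <- edge_quadripartitions(topology)
  rows <- lapply(quads, function(qd) {
    z <- c(0, 0, 0)
    for (a1 in qd$A[[1L]]) for (a2 in qd$A[[2L]]) {
      for (b1 in qd$B[[1L]]) for (b2 in qd$B[[2L]]) {
        tip_idx <- sort(match(c(a1, a2, b1, b2), qc$taxa))
        row <- qc$index[[paste(tip_idx[1L], tip_idx[2L], tip_idx[3L],
                               tip_idx[4L])]]
        # which sorted-pairing corresponds to {a1,a2}|{b1,b2}?
        pair <- sort(match(c(a1, a2), qc$taxa))
        first <- qc$quartets[row, 1L]
        res <- if (first %in% pair) {
          other <- setdiff(pair, first)
          match(other, qc$quartets[row, 2:4])
        } else {
          # first taxon sits with the b side; pairing of the remaining trio
          b_pair <- sort(match(c(b1, b2), qc$taxa))
          other <- setdiff(b_pair, first)
          match(other, qc$quartets[row, 2:4])
        }
        perm <- c(res, sort(setdiff(1:3, res)))
        z <- z + qc$counts[row, perm]
      }
    }
    n_eff <- sum(z)
    q <- if (n_eff > 0) z / n_eff else rep(1 / 3, 3L)
    data.frame(child = qd$child, z1 = z[1L], z2 = z[2L], z3 = z[3L],
               n_eff = n_eff, q1 = q[1L], q2 = q[2L], q3 = q[3L])
  })
  out <- do.call(rbind, rows)
  attr(out, "tree") <- attr(quads, "tree")
  out
}

#' Local posterior probability from quartet counts
#'
#' Posterior of each resolution under a binomial mixture with a flat prior
#' on the quartet frequency theta in (1/3, 1\] and equal 1/3 priors over the
#' three resolutions: P(T_i) is proportional to
#' integral over theta of theta^{z_i} ((1-theta)/2)^{n-z_i}.
#'
#' @param z1,z2,z3 Weighted quartet counts for the three resolutions.
#' @param n_eff Total (defaults to `z1+z2+z3`).
#' @return Numeric vector of the three posteriors (first = `z1`'s
#'   resolution); all 1/3 when `n_eff` is 0.
#' @export
local_pp <- function(z1, z2, z3, n_eff = z1 + z2 + z3) {
  z <- c(z1, z2, z3)
  if (any(z < 0)) stop("counts must be non-negative")
  if (n_eff <= 0) return(rep(1 / 3, 3L))
  logm <- vapply(z, function(zi) {
    a <- zi + 1
    b <- n_eff - zi + 1
    # log of B(a,b) * P(Beta(a,b) > 1/3), stable for extreme counts
    lbeta(a, b) - (n_eff - zi) * log(2) +
      stats::pbeta(1 / 3, a, b, lower.tail = FALSE, log.p = TRUE)
  }, numeric(1))
  w <- exp(logm - max(logm))
  w / sum(w)
}

#' Coalescent-unit branch length from the main quartet frequency
#'
#' Inverts the MSC concordance formula q1 = 1 - (2/3) exp(-d):
#' d = -ln((3/2)(1 - q1)) for q1 > 1/3, 0 otherwise, capped at `cap`.
#'
#' @param q1 Frequency of the species-tree resolution, in \[0, 1\].
#' @param cap Maximum returned length (default 10).
#' @return Length in coalescent units, with attribute `saturated` when the
#'   cap was hit.
#' @export
cu_branch_length <- function(q1, cap = 10) {
  if (any(q1 < 0 | q1 > 1)) stop("q1 must be in [0, 1]")
  d <- ifelse(q1 <= 1 / 3, 0, -log(1.5 * (1 - q1)))
  sat <- !is.finite(d) | d > cap
  d[sat] <- cap
  attr(d, "saturated") <- sat
  d
}

# NJ starting tree on quartet-affinity distances.
quartet_start_tree <- function(qc) {
  n <- length(qc$taxa)
  tot <- rowSums(qc$counts)
  aff <- matrix(0, n, n)
  cnt <- matrix(0, n, n)
  pair_of <- rbind(c(1L, 2L), c(1L, 3L), c(1L, 4L))  # resolution -> paired cols
  for (r in seq_len(nrow(qc$quartets))) {
    if (tot[r] <= 0) next
    for (res in 1:3) {
      i <- qc$quartets[r, pair_of[res, 1L]]
      j <- qc$quartets[r, pair_of[res, 2L]]
      k <- setdiff(qc$quartets[r, ], c(i, j))
      f <- qc$counts[r, res] / tot[r]
      aff[i, j] <- aff[i, j] + f
      cnt[i, j] <- cnt[i, j] + 1
      aff[k[1L], k[2L]] <- aff[k[1L], k[2L]] + f
      cnt[k[1L], k[2L]] <- cnt[k[1L], k[2L]] + 1
    }
  }
  aff <- aff + t(aff); cnt <- cnt + t(cnt)
  D <- 1 - ifelse(cnt > 0, aff / cnt, 0)
  diag(D) <- 0
  dimnames(D) <- list(qc$taxa, qc$taxa)
  ape::unroot(ape::nj(stats::as.dist(D)))
}

#' Estimate the species tree by maximum quartet agreement
#'
#' Exhaustive mode scores every unrooted topology (feasible for <= 8 taxa);
#' heuristic mode starts from neighbor joining on quartet-affinity distances
#' and hill-climbs over NNI moves. Branches of the winning topology are
#' annotated with normalized quartet support, local posterior probability
#' and coalescent-unit lengths.
#'
#' @param gene_trees `multiPhylo`.
#' @param mode `"auto"` (exhaustive up to 8 taxa), `"exhaustive"`, or
#'   `"heuristic"`.
#' @param seed Integer seed.
#' @return Object of class `species_tree_estimate`: list with `tree`
#'   (unrooted `phylo`), `branches` (the [quartet_tally()] table extended
#'   with `lpp` and `cu`), `score`, `mode`.
#' @export
infer_species_tree <- function(gene_trees, mode = c("auto", "exhaustive",
                                                    "heuristic"), seed = 1L) {
  mode <- match.arg(mode)
  set.seed(seed)
  taxa <- sort(unique(unlist(lapply(gene_trees, `[[`, "tip.label"))))
  if (length(taxa) < 4L) stop("need at least 4 taxa")
  qc <- gene_quartet_counts(gene_trees, taxa)
  n <- length(qc$taxa)
  if (mode == "auto") mode <- if (n <= 8L) "exhaustive" else "heuristic"
  if (mode == "exhaustive") {
    if (n > 8L) stop("exhaustive search is limited to 8 taxa")
    cand <- phangorn::allTrees(n, rooted = FALSE, tip.label = qc$taxa)
    scores <- vapply(cand, quartet_score, numeric(1), qc = qc)
    best <- cand[[which.max(scores)]]
    best_score <- max(scores)
  } else {
    cur <- quartet_start_tree(qc)
    cur$edge.length <- NULL
    cur_score <- quartet_score(cur, qc)
    repeat {
      nbs <- phangorn::nni(cur)
      sc <- vapply(nbs, quartet_score, numeric(1), qc = qc)
      if (max(sc) <= cur_score + 1e-12) break
      cur <- nbs[[which.max(sc)]]
      cur_score <- max(sc)
    }
    best <- cur
    best_score <- cur_score
  }
  tally <- quartet_tally(qc, best)
  tally$lpp <- vapply(seq_len(nrow(tally)), function(i) {
    local_pp(tally$z1[i], tally$z2[i], tally$z3[i])[1L]
  }, numeric(1))
  cu <- cu_branch_length(tally$q1)
  tally$cu <- as.numeric(cu)
  tally$saturated <- attr(cu, "saturated")
  structure(list(tree = attr(tally, "tree"), branches = tally,
                 score = best_score, mode = mode),
            class = "species_tree_estimate")
}

#' @export
print.species_tree_estimate <- function(x, ...) {
  cat("species_tree_estimate (", x$mode, " search): ",
      ape::Ntip(x$tree), " taxa, quartet score ",
      format(x$score, digits = 6), "\n", sep = "")
  cat("  branches with LPP >= 0.7: ", sum(x$branches$lpp >= 0.7), "/",
      nrow(x$branches), "\n", sep = "")
  invisible(x)
}

#' Write a species-tree estimate as annotated newick
#'
#' Each internal node label carries `lpp`, `q1..q3` and `cu` in the
#' `'[&...]'`-style free-text form used by quartet-support annotations.
#'
#' @param est A `species_tree_estimate`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_species_tree <- function(est, path) {
  tr <- est$tree
  ntip <- ape::Ntip(tr)
  lab <- rep("", tr$Nnode)
  for (i in seq_len(nrow(est$branches))) {
    b <- est$branches[i, ]
    lab[b$child - ntip] <- sprintf("'lpp=%.4f;q1=%.4f;q2=%.4f;q3=%.4f;cu=%.4f'",
                                   b$lpp, b$q1, b$q2, b$q3, b$cu)
  }
  tr$node.label <- lab
  ape::write.tree(tr, file = path)
  invisible(path)
}
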