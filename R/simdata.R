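# Synthetic-data generators: species trees, multispecies-coalescent (MSC)
# gene trees with optional post-hybridization introgression, a plastid
# c-gene, aligned sequences, degraded recovery matrices, and an Mk character.

#' Species-tree ground truth
#'
#' Wraps a rooted ultrametric time tree (branch lengths in Mya) together with
#' the coalescent-unit (CU) length of every branch. ILS intensity is governed
#' by CU lengths directly: a branch of d CU yields gene-tree concordance
#' probability 1 - (2/3) exp(-d) for the quartet around it.
#'
#' @param tree Rooted ultrametric `phylo`, branch lengths in Mya.
#' @param cu_per_my Coalescent units per My, either a single value applied to
#'   every branch or a vector with one entry per edge of `tree`.
#' @param root_cu_per_my CU-per-My conversion used for lineages persisting
#'   above the root (defaults to the mean of `cu_per_my`).
#' @return An object of class `species_tree_truth` with fields `tree`,
#'   `ages` (per ape node id), `cu` (per edge), `root_cu_per_my`.
#' @export
species_tree_truth <- function(tree, cu_per_my = 0.1, root_cu_per_my = NULL) {
  if (!inherits(tree, "phylo")) stop("tree must be a 'phylo'")
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  tree <- snap_ultrametric(tree)
  ne <- nrow(tree$edge)
  if (length(cu_per_my) == 1L) cu_per_my <- rep(cu_per_my, ne)
  if (length(cu_per_my) != ne) stop("cu_per_my must be length 1 or Nedge")
  if (any(cu_per_my <= 0)) stop("cu_per_my must be positive")
  cu <- tree$edge.length * cu_per_my
  if (is.null(root_cu_per_my)) root_cu_per_my <- mean(cu_per_my)
  structure(list(tree = tree, ages = node_ages(tree), cu = cu,
                 root_cu_per_my = root_cu_per_my),
            class = "species_tree_truth")
}

#' @export
print.species_tree_truth <- function(x, ...) {
  cat("species_tree_truth:", ape::Ntip(x$tree), "tips, root age",
      format(max(x$ages), digits = 5), "Mya, CU range",
      format(min(x$cu), digits = 3), "-", format(max(x$cu), digits = 3), "\n")
  invisible(x)
}

#' Simulate an ultrametric species tree with an outgroup clade
#'
#' The ingroup (and, when `n_outgroup > 1`, the outgroup) topology is drawn
#' from a pure-birth process conditioned on the tip count; the ingroup crown
#' is placed at 3/4 of the root age and the outgroup crown at 1/2, so the
#' outgroup is always sister to the ingroup clade.
#'
#' @param n_ingroup Number of ingroup tips (>= 2).
#' @param n_outgroup Number of outgroup tips (>= 1).
#' @param root_age Root age in Mya.
#' @param seed Integer seed; the run is bit-reproducible.
#' @param cu_per_my Coalescent units per My (see [species_tree_truth()]).
#' @return A `species_tree_truth`.
#' @export
simulate_species_tree <- function(n_ingroup, n_outgroup = 1L, root_age = 100,
                                  seed = 1L, cu_per_my = 0.1) {
  check_scalar(n_ingroup, "n_ingroup", lo = 2)
  check_scalar(n_outgroup, "n_outgroup", lo = 1)
  check_scalar(root_age, "root_age", lo = 1e-12)
  set.seed(seed)
  scale_to <- function(tr, depth) {
    tr <- snap_ultrametric(tr)
    tr$edge.length <- tr$edge.length * depth / max(node_ages(tr))
    tr
  }
  subtree_newick <- function(n, prefix, crown, stem) {
    if (n == 1L) return(paste0(prefix, "1:", stem + crown))
    tr <- scale_to(ape::rphylo(n, birth = 1, death = 0), crown)
    tr$tip.label <- paste0(prefix, seq_len(n))
    paste0(sub(";$", "", ape::write.tree(tr)), ":", stem)
  }
  ing <- subtree_newick(n_ingroup, "IG", 0.75 * root_age, 0.25 * root_age)
  out <- subtree_newick(n_outgroup, "OG",
                        if (n_outgroup > 1L) 0.5 * root_age else 0,
                        if (n_outgroup > 1L) 0.5 * root_age else root_age)
  tree <- ape::read.tree(text = paste0("(", ing, ",", out, ");"))
  species_tree_truth(tree, cu_per_my = cu_per_my)
}

#' Describe a post-hybridization introgression event
#'
#' With probability `gamma` a gene lineage sampled in the recipient clade
#' follows the donor-side history: the recipient clade is regrafted onto the
#' donor lineage at `time` Mya for that gene.
#'
#' @param donor Character vector of tip labels spanning the donor clade.
#' @param recipient Character vector of tip labels spanning the recipient
#'   clade (moved as a unit).
#' @param gamma Probability in \[0, 1\] that a nuclear gene follows the donor
#'   history.
#' @param time Event age in Mya; must be older than both clades' crowns and
#'   younger than the donor/recipient MRCA.
#' @param affects Which genomic compartment the event can act on:
#'   `"plastid"` (chloroplast capture, the default), `"nuclear"`, or
#'   `"both"`.
#' @return An object of class `introgression_event`.
#' @export
introgression_event <- function(donor, recipient, gamma, time,
                                affects = c("plastid", "nuclear", "both")) {
  check_scalar(gamma, "gamma", 0, 1)
  check_scalar(time, "time", lo = 0)
  structure(list(donor = donor, recipient = recipient, gamma = gamma,
                 time = time, affects = match.arg(affects)),
            class = "introgression_event")
}

# Regraft the recipient clade onto the donor lineage at the event time,
# returning a new species_tree_truth with the same CU-per-My conversion.
regraft_truth <- function(truth, event) {
  tree <- truth$tree
  labs <- tree$tip.label
  if (!all(event$donor %in% labs) || !all(event$recipient %in% labs)) {
    stop("introgression event clades not present in the species tree")
  }
  ages <- truth$ages
  mrca_of <- function(tr, tips) {
    if (length(tips) == 1L) match(tips, tr$tip.label)
    else ape::getMRCA(tr, tips)
  }
  joint <- ape::getMRCA(tree, c(event$donor, event$recipient))
  rec_node <- mrca_of(tree, event$recipient)
  if (event$time >= ages[joint]) {
    stop("event time must be younger than the donor/recipient MRCA")
  }
  if (event$time <= ages[rec_node]) {
    stop("event time must be older than the recipient crown")
  }
  if (length(event$recipient) > 1L) {
    rec_sub <- ape::extract.clade(tree, rec_node)
    rec_sub$root.edge <- event$time - ages[rec_node]
  }
  backbone <- ape::drop.tip(tree, event$recipient)
  backbone <- snap_ultrametric(backbone)
  bb_ages <- node_ages(backbone)
  d <- mrca_of(backbone, event$donor)
  root <- ape::Ntip(backbone) + 1L
  repeat {
    if (d == root) stop("event time is above the root of the backbone")
    p <- backbone$edge[backbone$edge[, 2L] == d, 1L]
    if (bb_ages[p] > event$time) break
    d <- p
  }
  pos <- event$time - bb_ages[d]
  if (length(event$recipient) > 1L) {
    new <- ape::bind.tree(backbone, rec_sub, where = d, position = pos)
  } else {
    new <- phytools::bind.tip(backbone, event$recipient,
                              edge.length = event$time,
                              where = d, position = pos)
  }
  new <- snap_ultrametric(new)
  cu_per_my <- truth$cu[1L] / truth$tree$edge.length[1L]
  species_tree_truth(new, cu_per_my = cu_per_my,
                     root_cu_per_my = truth$root_cu_per_my)
}

# One MSC gene tree inside a species_tree_truth; returns a newick string with
# branch lengths in Mya. Coalescence proceeds bottom-up branch by branch: in
# a branch of c CU, j lineages coalesce pairwise at rate choose(j,2) per CU.
msc_one_tree <- function(truth) {
  tree <- truth$tree
  ntip <- ape::Ntip(tree)
  nnode <- tree$Nnode
  ages <- truth$ages
  edge <- tree$edge
  children <- split(edge[, 2L], edge[, 1L])
  edge_index <- integer(ntip + nnode)
  edge_index[edge[, 2L]] <- seq_len(nrow(edge))

  # lineage bookkeeping: newick fragment + age at fragment head
  coalesce_in <- function(lin, t_start, t_end, cu_len) {
    # lin: list of list(nwk=, age=); CU clock runs from 0 to cu_len (Inf above root)
    my_per_cu <- if (is.finite(cu_len)) (t_end - t_start) / cu_len
                 else 1 / truth$root_cu_per_my
    cur <- 0
    while (length(lin) > 1L) {
      n <- length(lin)
      cur <- cur + stats::rexp(1L, n * (n - 1) / 2)
      if (cur > cu_len) break
      h <- t_start + cur * my_per_cu
      ij <- sample.int(n, 2L)
      a <- lin[[ij[1L]]]; b <- lin[[ij[2L]]]
      merged <- list(
        nwk = paste0("(", a$nwk, ":", format(h - a$age, digits = 12),
                     ",", b$nwk, ":", format(h - b$age, digits = 12), ")"),
        age = h)
      lin <- c(lin[-ij], list(merged))
    }
    lin
  }

  pending <- vector("list", ntip + nnode)
  # process nodes in increasing age: tips first, then internal nodes
  ord <- order(ages[(ntip + 1L):(ntip + nnode)])
  for (v in seq_len(ntip)) {
    pending[[v]] <- list(list(nwk = tree$tip.label[v], age = 0))
  }
  for (v in seq_len(ntip)) {
    e <- edge_index[v]
    p <- edge[e, 1L]
    got <- coalesce_in(pending[[v]], ages[v], ages[p], truth$cu[e])
    pending[[p]] <- c(pending[[p]], got)
    pending[v] <- list(NULL)
  }
  for (v in ntip + ord) {
    if (v == ntip + 1L) next  # root handled last
    e <- edge_index[v]
    p <- edge[e, 1L]
    got <- coalesce_in(pending[[v]], ages[v], ages[p], truth$cu[e])
    pending[[p]] <- c(pending[[p]], got)
    pending[v] <- list(NULL)
  }
  root <- ntip + 1L
  fin <- coalesce_in(pending[[root]], ages[root], Inf, Inf)
  paste0(fin[[1L]]$nwk, ";")
}

#' Simulate gene trees under the multispecies coalescent
#'
#' Each gene tree is drawn by coalescent simulation within the species tree;
#' branch lengths are in Mya. Each gene carries a substitution rate
#' (attribute `"rates"` on the returned `multiPhylo`, substitutions/site/My)
#' drawn from a log-normal with median `rate_mean`. If an introgression
#' `event` with nuclear effect is supplied, each gene independently follows
#' the regrafted (donor-side) species history with probability `gamma`;
#' attribute `"followed"` records which genes did.
#'
#' @param truth A `species_tree_truth`.
#' @param n_genes Number of gene trees (>= 1).
#' @param event Optional `introgression_event`.
#' @param seed Integer seed.
#' @param rate_mean Median substitution rate (substitutions/site/My).
#' @param rate_sdlog Log-scale SD of the per-gene rate (default 0.3).
#' @return A `multiPhylo` with attributes `rates` and `followed`.
#' @export
simulate_gene_trees <- function(truth, n_genes, event = NULL, seed = 1L,
                                rate_mean = 1e-3, rate_sdlog = 0.3) {
  stopifnot(inherits(truth, "species_tree_truth"))
  check_scalar(n_genes, "n_genes", lo = 1)
  set.seed(seed)
  nuclear_event <- !is.null(event) && event$affects %in% c("nuclear", "both")
  alt <- if (nuclear_event) regraft_truth(truth, event) else NULL
  # the event-assignment draws happen unconditionally so that gamma = 0 is
  # byte-identical to running with no event at all
  u <- stats::runif(n_genes)
  followed <- if (nuclear_event) u < event$gamma else rep(FALSE, n_genes)
  rates <- stats::rlnorm(n_genes, meanlog = log(rate_mean), sdlog = rate_sdlog)
  trees <- vector("list", n_genes)
  for (g in seq_len(n_genes)) {
    src <- if (followed[g]) alt else truth
    trees[[g]] <- ape::read.tree(text = msc_one_tree(src))
  }
  names(trees) <- sprintf("gene%04d", seq_len(n_genes))
  class(trees) <- "multiPhylo"
  attr(trees, "rates") <- rates
  attr(trees, "followed") <- followed
  trees
}

#' Simulate the plastid c-gene tree
#'
#' The plastome is treated as a single non-recombining coalescent gene with
#' effectively zero within-branch coalescent variance: its tree is the
#' species time tree itself, regrafted when the introgression event captured
#' the plastid. Because the c-gene is a single binary realization, the
#' default `follow = "expected"` takes the maximum-probability outcome
#' (follow iff gamma >= 0.5), keeping scenario runs well defined;
#' `follow = "sample"` draws Bernoulli(gamma) instead.
#'
#' @param truth A `species_tree_truth`.
#' @param event Optional `introgression_event` (must affect the plastid).
#' @param follow `"expected"`, `"sample"`, or `"never"`.
#' @param seed Integer seed (used by `follow = "sample"`).
#' @return A rooted ultrametric `phylo` (Mya) with attribute `followed`.
#' @export
simulate_plastid_tree <- function(truth, event = NULL,
                                  follow = c("expected", "sample", "never"),
                                  seed = 1L) {
  stopifnot(inherits(truth, "species_tree_truth"))
  follow <- match.arg(follow)
  set.seed(seed)
  does <- FALSE
  if (!is.null(event) && event$affects %in% c("plastid", "both")) {
    does <- switch(follow,
                   expected = event$gamma >= 0.5,
                   sample = stats::runif(1L) < event$gamma,
                   never = FALSE)
  }
  tr <- if (does) regraft_truth(truth, event)$tree else truth$tree
  attr(tr, "followed") <- does
  tr
}

jc_pmat <- function(t) {
  e <- exp(-4 * t / 3)
  p <- matrix((1 - e) / 4, 4L, 4L)
  diag(p) <- (1 + 3 * e) / 4
  p
}

hky_pmat_factory <- function(kappa, bf) {
  q <- matrix(0, 4L, 4L)  # order A C G T; transitions A<->G, C<->T
  for (i in 1:4) for (j in 1:4) {
    if (i == j) next
    ti <- (i + j) %in% c(4L, 6L) && abs(i - j) == 2L  # A-G (1,3), C-T (2,4)
    q[i, j] <- bf[j] * if (ti) kappa else 1
  }
  diag(q) <- -rowSums(q)
  q <- q / sum(-diag(q) * bf)  # scale to 1 expected substitution per unit
  eg <- eigen(q)
  vinv <- solve(eg$vectors)
  function(t) {
    p <- eg$vectors %*% diag(exp(eg$values * t)) %*% vinv
    p[p < 0] <- 0
    Re(p)
  }
}

#' Simulate aligned, gap-free sequences along gene trees
#'
#' Sites evolve independently under JC69 (default) or HKY. Branch lengths in
#' substitutions/site are `branch length (My) x per-gene rate`, the rates
#' taken from the `rates` attribute of `genes` (or 1 if absent, i.e. branch
#' lengths already in substitutions/site).
#'
#' @param genes `multiPhylo` (or single `phylo`) of gene trees.
#' @param site_counts Alignment length per gene (recycled).
#' @param model List: `list(name = "JC69")` or
#'   `list(name = "HKY", kappa = 2, bf = c(A, C, G, T))`.
#' @param seed Integer seed.
#' @return Named list of character matrices (taxa x sites), with per-gene
#'   attributes `tree` and `rate`.
#' @export
simulate_alignments <- function(genes, site_counts, model = list(name = "JC69"),
                                seed = 1L) {
  if (inherits(genes, "phylo")) {
    genes <- structure(list(genes), class = "multiPhylo")
  }
  if (any(site_counts <= 0)) stop("site_counts must be positive")
  if (!model$name %in% c("JC69", "HKY")) stop("unknown model: ", model$name)
  set.seed(seed)
  n_genes <- length(genes)
  site_counts <- rep_len(site_counts, n_genes)
  rates <- attr(genes, "rates")
  if (is.null(rates)) rates <- rep(1, n_genes)
  bf <- if (model$name == "HKY") model$bf else rep(0.25, 4L)
  pmat <- if (model$name == "HKY") {
    hky_pmat_factory(model$kappa, bf)
  } else {
    jc_pmat
  }
  nuc <- c("A", "C", "G", "T")
  out <- vector("list", n_genes)
  for (g in seq_len(n_genes)) {
    tr <- ape::reorder.phylo(genes[[g]], "cladewise")
    ntip <- ape::Ntip(tr)
    L <- site_counts[g]
    states <- matrix(0L, ntip + tr$Nnode, L)
    root <- ntip + 1L
    states[root, ] <- sample.int(4L, L, replace = TRUE, prob = bf)
    for (e in seq_len(nrow(tr$edge))) {
      p <- tr$edge[e, 1L]; v <- tr$edge[e, 2L]
      P <- pmat(tr$edge.length[e] * rates[g])
      for (s in 1:4) {
        idx <- which(states[p, ] == s)
        if (length(idx)) {
          states[v, idx] <- sample.int(4L, length(idx), replace = TRUE,
                                       prob = P[s, ])
        }
      }
    }
    m <- matrix(nuc[states[seq_len(ntip), , drop = FALSE]], ntip, L)
    rownames(m) <- tr$tip.label
    attr(m, "tree") <- genes[[g]]
    attr(m, "rate") <- rates[g]
    out[[g]] <- m
  }
  names(out) <- names(genes)
  if (is.null(names(out))) names(out) <- sprintf("gene%04d", seq_len(n_genes))
  out
}

#' Construct a recovery matrix
#'
#' @param recovered_length Gene x accession integer matrix (0 = absent).
#' @param target_length Positive integer per gene.
#' @param copy_count Gene x accession integer matrix; must be >= 1 exactly
#'   where a sequence was recovered and 0 elsewhere.
#' @return Object of class `recovery_matrix`.
#' @export
recovery_matrix <- function(recovered_length, target_length, copy_count = NULL) {
  recovered_length <- as.matrix(recovered_length)
  if (is.null(copy_count)) copy_count <- (recovered_length > 0) * 1L
  copy_count <- as.matrix(copy_count)
  if (any(target_length <= 0)) stop("target_length must be positive")
  if (length(target_length) != nrow(recovered_length)) {
    stop("one target_length per gene required")
  }
  if (any((copy_count == 0) != (recovered_length == 0))) {
    stop("copy_count must be 0 exactly where recovered_length is 0")
  }
  structure(list(genes = rownames(recovered_length),
                 accessions = colnames(recovered_length),
                 recovered_length = recovered_length,
                 target_length = target_length,
                 copy_count = copy_count),
            class = "recovery_matrix")
}

#' Degrade simulated alignments into a patchy recovery matrix
#'
#' Emulates target-capture patchiness: per (gene, accession) the sequence is
#' dropped with probability `missing_rate`, otherwise truncated to a fraction
#' of its length drawn from `truncation`; with probability `paralog_rate`
#' extra divergent copies are recorded. Defaults emulate recovering most
#' genes at around half their target length.
#'
#' @param seqs Named list of character matrices from [simulate_alignments()].
#' @param missing_rate Probability a sequence is absent.
#' @param truncation Distribution of the retained length fraction:
#'   `list(kind = "fixed", value = )`, `list(kind = "uniform", min = , max = )`
#'   or `list(kind = "beta", shape1 = , shape2 = )`.
#' @param paralog_rate Probability a recovered cell carries extra copies.
#' @param seed Integer seed.
#' @return List with `matrix` (a `recovery_matrix`) and `seqs` (the degraded
#'   alignments; missing/truncated positions gapped).
#' @export
degrade_recovery <- function(seqs, missing_rate = 0.15,
                             truncation = list(kind = "beta",
                                               shape1 = 2, shape2 = 2),
                             paralog_rate = 0.02, seed = 1L) {
  check_scalar(missing_rate, "missing_rate", 0, 1)
  check_scalar(paralog_rate, "paralog_rate", 0, 1)
  set.seed(seed)
  genes <- names(seqs)
  accs <- sort(unique(unlist(lapply(seqs, rownames))))
  G <- length(genes); A <- length(accs)
  draw_frac <- function(n) {
    switch(truncation$kind,
           fixed = rep(truncation$value, n),
           uniform = stats::runif(n, truncation$min, truncation$max),
           beta = stats::rbeta(n, truncation$shape1, truncation$shape2),
           stop("unknown truncation kind: ", truncation$kind))
  }
  rec <- matrix(0L, G, A, dimnames = list(genes, accs))
  cc <- matrix(0L, G, A, dimnames = list(genes, accs))
  tl <- vapply(seqs, ncol, integer(1))
  out_seqs <- seqs
  for (g in seq_len(G)) {
    m <- seqs[[g]]
    L <- ncol(m)
    for (a in rownames(m)) {
      if (stats::runif(1L) < missing_rate) {
        m[a, ] <- "-"
        next
      }
      keep <- max(1L, round(draw_frac(1L) * L))
      if (keep < L) m[a, (keep + 1L):L] <- "-"
      rec[g, a] <- keep
      cc[g, a] <- 1L
      if (stats::runif(1L) < paralog_rate) {
        cc[g, a] <- cc[g, a] + 1L + stats::rpois(1L, 0.5)
      }
    }
    out_seqs[[g]] <- m
  }
  list(matrix = recovery_matrix(rec, tl, cc), seqs = out_seqs)
}

#' Evolve a discrete character under the equal-rates Mk model
#'
#' States evolve root-to-tip with rate `rate` to each alternative state
#' (P_stay(t) = 1/k + (1 - 1/k) exp(-k rate t)); the root state is uniform.
#'
#' @param truth A `species_tree_truth`.
#' @param rate Transition rate to each alternative state, per My.
#' @param states Ordered state names (default the three floral-symmetry
#'   states).
#' @param seed Integer seed.
#' @return List with `states` (named character vector per tip), `ancestral`
#'   (per internal ape node id), `rate`, `seed`.
#' @export
simulate_character <- function(truth, rate,
                               states = c("actinomorphic", "disymmetric",
                                          "zygomorphic"),
                               seed = 1L) {
  stopifnot(inherits(truth, "species_tree_truth"))
  check_scalar(rate, "rate", lo = 0)
  k <- length(states)
  if (k < 2L) stop("need at least two states")
  set.seed(seed)
  tr <- ape::reorder.phylo(truth$tree, "cladewise")
  ntip <- ape::Ntip(tr)
  st <- integer(ntip + tr$Nnode)
  st[ntip + 1L] <- sample.int(k, 1L)
  for (e in seq_len(nrow(tr$edge))) {
    p <- tr$edge[e, 1L]; v <- tr$edge[e, 2L]
    t <- tr$edge.length[e]
    stay <- 1 / k + (1 - 1 / k) * exp(-k * rate * t)
    probs <- rep((1 - stay) / (k - 1), k)
    probs[st[p]] <- stay
    st[v] <- sample.int(k, 1L, prob = probs)
  }
  # map back to the original node numbering (reorder preserves ids)
  tips <- stats::setNames(states[st[seq_len(ntip)]], tr$tip.label)
  anc <- stats::setNames(states[st[(ntip + 1L):(ntip + tr$Nnode)]],
                         (ntip + 1L):(ntip + tr$Nnode))
  list(states = tips[truth$tree$tip.label], ancestral = anc,
       rate = rate, seed = seed)
}
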