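# Gene- and concatenated-tree inference. The likelihood engine (JC69 pruning
# likelihood, NNI search, edge-length optimization) is phangorn's; this file
# owns the bootstrap-resampling schemes, support mapping and bipartition
# collapsing that the pipeline needs.

#' Jukes-Cantor distance from a mismatch proportion
#'
#' d = -(3/4) ln(1 - 4p/3).
#'
#' @param p Observed proportion of differing sites, in \[0, 0.75).
#' @return Distance in substitutions/site.
#' @export
jc_distance <- function(p) {
  if (any(p < 0) || any(p >= 0.75)) {
    stop("saturation: mismatch proportion must be in [0, 0.75)")
  }
  -0.75 * log(1 - 4 * p / 3)
}

# p-distance matrix over shared non-gap positions
p_distance <- function(msa) {
  gap <- matrix(msa %in% AMBIG, nrow(msa), ncol(msa))
  n <- nrow(msa)
  D <- matrix(0, n, n, dimnames = list(rownames(msa), rownames(msa)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ok <- !gap[i, ] & !gap[j, ]
    p <- if (any(ok)) mean(msa[i, ok] != msa[j, ok]) else 0
    D[i, j] <- D[j, i] <- min(p, 0.74)  # cap below JC saturation
  }
  D
}

# bipartition bootstrap percentages as internal node labels (root label "")
map_bootstrap <- function(tree, bs_trees) {
  cnt <- ape::prop.clades(tree, bs_trees, rooted = FALSE)
  pct <- round(100 * cnt / length(bs_trees))
  pct[is.na(pct)] <- 0L
  lab <- as.character(pct)
  lab[1L] <- ""  # root of the unrooted representation: trivial
  tree$node.label <- lab
  tree
}

# NJ starting tree on JC distances, then JC69 ML with NNI rearrangements.
ml_fit <- function(msa, optNni = TRUE, start = NULL) {
  dat <- as_phydat(msa)
  tree <- if (is.null(start)) {
    ape::nj(stats::as.dist(jc_distance(p_distance(msa))))
  } else {
    start
  }
  tree <- ape::unroot(tree)
  tree$edge.length[tree$edge.length < 1e-8] <- 1e-8
  fit <- phangorn::pml(tree, dat)
  phangorn::optim.pml(fit, model = "JC", optNni = optNni, optEdge = TRUE,
                      control = phangorn::pml.control(trace = 0, epsilon = 1e-8))
}

#' Maximum-likelihood gene tree with nonparametric bootstrap
#'
#' Topology from neighbor joining on JC distances followed by NNI
#' rearrangements under the JC69 likelihood; supports are classical
#' site-resampled bootstrap percentages mapped onto internal nodes.
#'
#' @param msa Character matrix (>= 4 taxa).
#' @param n_bootstrap Bootstrap replicates (0 skips supports).
#' @param seed Integer seed.
#' @return Unrooted `phylo` with `node.label` bootstrap percentages and
#'   attribute `logLik`; attribute `degenerate` is TRUE when the alignment
#'   has no variable site.
#' @export
ml_gene_tree <- function(msa, n_bootstrap = 100L, seed = 1L) {
  if (nrow(msa) < 4L) stop("need at least 4 sequences for an unrooted tree")
  set.seed(seed)
  fit <- ml_fit(msa)
  tree <- fit$tree
  degenerate <- all(apply(msa, 2L, function(x) {
    length(unique(x[!x %in% AMBIG])) <= 1L
  }))
  if (n_bootstrap > 0L) {
    bs <- phangorn::bootstrap.pml(fit, bs = n_bootstrap, optNni = TRUE,
                                  control = phangorn::pml.control(trace = 0))
    tree <- map_bootstrap(tree, bs)
  }
  attr(tree, "logLik") <- fit$logLik
  attr(tree, "degenerate") <- degenerate
  tree
}

#' Collapse weakly supported bipartitions into polytomies
#'
#' Contracts every internal edge whose bootstrap support is strictly below
#' `threshold` (the study collapsed at BS < 11). Pendant edges and edges
#' without a numeric support are never contracted.
#'
#' @param tree `phylo` with `node.label` supports on internal nodes.
#' @param threshold Bootstrap percentage in \[0, 100\].
#' @return `phylo`, possibly with polytomies.
#' @export
collapse_low_support <- function(tree, threshold) {
  check_scalar(threshold, "threshold", 0, 100)
  if (is.null(tree$node.label)) stop("tree has no support labels")
  ntip <- ape::Ntip(tree)
  sup <- suppressWarnings(as.numeric(tree$node.label))
  edge <- tree$edge
  internal_child <- edge[, 2L] > ntip
  root <- ntip + 1L
  child_sup <- rep(NA_real_, nrow(edge))
  child_sup[internal_child] <- sup[edge[internal_child, 2L] - ntip]
  kill <- internal_child & !is.na(child_sup) & child_sup < threshold
  if (!any(kill)) return(tree)
  # union-find: contracted child nodes map onto their parents
  map <- seq_len(ntip + tree$Nnode)
  find <- function(v) {
    while (map[v] != v) v <- map[v]
    v
  }
  for (e in which(kill)) map[edge[e, 2L]] <- edge[e, 1L]
  keep <- !kill
  new_edge <- cbind(vapply(edge[keep, 1L], find, integer(1)), edge[keep, 2L])
  new_len <- tree$edge.length[keep]
  # renumber: tips keep ids, surviving internals get consecutive ids
  surv_int <- sort(unique(c(root, new_edge[new_edge[, 1L] > ntip, 1L],
                            new_edge[new_edge[, 2L] > ntip, 2L])))
  renum <- integer(ntip + tree$Nnode)
  renum[seq_len(ntip)] <- seq_len(ntip)
  renum[surv_int] <- ntip + seq_along(surv_int)
  out <- list(edge = cbind(renum[new_edge[, 1L]], renum[new_edge[, 2L]]),
              edge.length = new_len,
              tip.label = tree$tip.label,
              Nnode = length(surv_int),
              node.label = tree$node.label[surv_int - ntip])
  class(out) <- "phylo"
  out <- ape::reorder.phylo(out, "cladewise")
  out
}

#' Build a partitioned supermatrix from per-gene alignments
#'
#' Missing taxa are filled with gaps; spans are 0-based half-open internally.
#'
#' @param alignments Named list of character matrices sharing a taxon pool.
#' @return Object of class `partitioned_matrix`: list with `matrix`, `spans`
#'   (data frame gene/start/end, 0-based half-open).
#' @export
concat_alignments <- function(alignments) {
  if (!length(alignments)) stop("no alignments")
  taxa <- sort(unique(unlist(lapply(alignments, rownames))))
  mats <- lapply(alignments, function(m) {
    full <- matrix("-", length(taxa), ncol(m), dimnames = list(taxa, NULL))
    full[rownames(m), ] <- m
    full
  })
  lens <- vapply(mats, ncol, integer(1))
  ends <- cumsum(lens)
  spans <- data.frame(gene = names(alignments),
                      start = c(0L, ends[-length(ends)]), end = ends,
                      stringsAsFactors = FALSE)
  structure(list(matrix = do.call(cbind, mats), spans = spans),
            class = "partitioned_matrix")
}

#' Read/write RAxML-style partition files
#'
#' Interchange format is 1-based inclusive ("DNA, gene1 = 1-500"); internal
#' spans are 0-based half-open.
#' @param path File path.
#' @return Data frame with `gene`, `start`, `end` (0-based half-open).
#' @export
read_partitions <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  m <- regmatches(lines,
                  regexec("^\\s*\\S+,\\s*(\\S+)\\s*=\\s*(\\d+)\\s*-\\s*(\\d+)", lines))
  bad <- vapply(m, length, integer(1)) != 4L
  if (any(bad)) stop("malformed partition line: ", lines[bad][1L])
  data.frame(gene = vapply(m, `[`, character(1), 2L),
             start = as.integer(vapply(m, `[`, character(1), 3L)) - 1L,
             end = as.integer(vapply(m, `[`, character(1), 4L)),
             stringsAsFactors = FALSE)
}

#' @rdname read_partitions
#' @param spans Data frame with `gene`, `start`, `end` (0-based half-open).
#' @export
write_partitions <- function(spans, path) {
  writeLines(sprintf("DNA, %s = %d-%d", spans$gene, spans$start + 1L,
                     spans$end), path)
  invisible(path)
}

# gene-and-site bootstrap replicate: resample partitions with replacement,
# then sites within each drawn partition
genesite_replicate <- function(parts) {
  spans <- parts$spans
  drawn <- sample.int(nrow(spans), nrow(spans), replace = TRUE)
  cols <- unlist(lapply(drawn, function(i) {
    cand <- (spans$start[i] + 1L):spans$end[i]
    sample(cand, length(cand), replace = TRUE)
  }))
  parts$matrix[, cols, drop = FALSE]
}

#' Concatenated partitioned maximum-likelihood tree
#'
#' ML tree on the concatenation under JC69 with NNI search; bootstrap
#' replicates first resample partitions with replacement, then sites within
#' each drawn partition ("gene-and-site" resampling), so every replicate has
#' the original total column count.
#'
#' @param parts A `partitioned_matrix` from [concat_alignments()].
#' @param n_bootstrap Bootstrap replicates (0 skips supports).
#' @param resample `"genesite"` (default) or `"site"`.
#' @param seed Integer seed.
#' @return Unrooted `phylo` with bootstrap `node.label`s.
#' @export
concat_ml <- function(parts, n_bootstrap = 100L,
                      resample = c("genesite", "site"), seed = 1L) {
  stopifnot(inherits(parts, "partitioned_matrix"))
  resample <- match.arg(resample)
  if (any(parts$spans$end - parts$spans$start <= 0L)) stop("empty partition")
  set.seed(seed)
  fit <- ml_fit(parts$matrix)
  tree <- fit$tree
  if (n_bootstrap > 0L) {
    reps <- vector("list", n_bootstrap)
    for (b in seq_len(n_bootstrap)) {
      rep_mat <- if (resample == "genesite" && nrow(parts$spans) > 1L) {
        genesite_replicate(parts)
      } else {
        parts$matrix[, sample.int(ncol(parts$matrix), ncol(parts$matrix),
                                  replace = TRUE), drop = FALSE]
      }
      reps[[b]] <- ml_fit(rep_mat, optNni = TRUE, start = tree)$tree
    }
    class(reps) <- "multiPhylo"
    tree <- map_bootstrap(tree, reps)
  }
  attr(tree, "logLik") <- fit$logLik
  tree
}

#' Re-estimate branch lengths on a fixed topology
#'
#' Maximizes the JC69 likelihood over branch lengths only; the topology is
#' left untouched (the concatenated-matrix `--evaluate` step).
#'
#' @param topology `phylo` whose tips are all present in `msa`.
#' @param msa Character matrix.
#' @return `phylo` with optimized branch lengths (substitutions/site) and
#'   attribute `logLik`.
#' @export
fixed_topology_brlens <- function(topology, msa) {
  if (!all(topology$tip.label %in% rownames(msa))) {
    stop("topology tips missing from the alignment")
  }
  msa <- msa[topology$tip.label, , drop = FALSE]
  dat <- as_phydat(msa)
  tr <- ape::unroot(topology)
  if (is.null(tr$edge.length)) tr$edge.length <- rep(0.05, nrow(tr$edge))
  tr$edge.length[tr$edge.length < 1e-8] <- 1e-8
  fit <- phangorn::pml(tr, dat)
  fit <- phangorn::optim.pml(fit, model = "JC", optNni = FALSE, optEdge = TRUE,
                             control = phangorn::pml.control(trace = 0,
                                                             epsilon = 1e-8))
  out <- fit$tree
  attr(out, "logLik") <- fit$logLik
  out
}
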