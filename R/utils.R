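# Shared tree helpers. Trees are ape 'phylo' objects throughout; time is in
# Mya, molecular branch lengths in substitutions/site, coalescent lengths in
# coalescent units (CU).

#' Node ages of a rooted ultrametric-or-not tree
#'
#' Ages are measured backwards from the most distant tip (age 0 at that tip).
#'
#' @param tree Rooted `phylo` with branch lengths.
#' @return Numeric vector of length `Ntip + Nnode`, indexed by ape node id.
#' @export
node_ages <- function(tree) {
  depth <- ape::node.depth.edgelength(tree)
  max(depth) - depth
}

is_ultrametric_strict <- function(tree, tol = 1e-8) {
  a <- node_ages(tree)[seq_len(ape::Ntip(tree))]
  diff(range(a)) <= tol * max(1, max(node_ages(tree)))
}

#' Force exact ultrametricity by snapping tip ages to zero
#' @noRd
snap_ultrametric <- function(tree, tol = 1e-6) {
  ages <- node_ages(tree)
  tips <- seq_len(ape::Ntip(tree))
  if (max(abs(ages[tips])) > tol * max(ages)) {
    stop("tree is not ultrametric within tolerance")
  }
  parent <- tree$edge[, 1L]
  child <- tree$edge[, 2L]
  ages[tips] <- 0
  tree$edge.length <- ages[parent] - ages[child]
  tree
}

# Non-trivial bipartitions of an (un)rooted tree, canonically encoded as the
# sorted label set on the side NOT containing the reference tip, one string
# per internal edge.
bipartitions <- function(tree, ref = NULL) {
  tree <- ape::unroot(tree)
  labs <- tree$tip.label
  if (is.null(ref)) ref <- sort(labs)[1L]
  n <- ape::Ntip(tree)
  out <- character(0)
  pp <- ape::prop.part(tree)
  for (i in seq_along(pp)) {
    side <- labs[pp[[i]]]
    if (length(side) <= 1L || length(side) >= n - 1L) next
    if (ref %in% side) side <- setdiff(labs, side)
    out <- c(out, paste(sort(side), collapse = "|"))
  }
  unique(out)
}

# Pairwise tip-to-tip path lengths with every edge counted as 1 (topological
# distances; used for quartet resolution via the four-point condition).
topo_dist <- function(tree) {
  t2 <- tree
  t2$edge.length <- rep(1, nrow(t2$edge))
  ape::cophenetic.phylo(t2)
}

# Resolution of the quartet {a,b,c,d} (indices into the rows of a topological
# distance matrix, assumed sorted) induced by a tree:
#   1 = ab|cd, 2 = ac|bd, 3 = ad|bc, 0 = unresolved (tie).
quartet_resolution <- function(D, a, b, c, d) {
  s <- c(D[a, b] + D[c, d], D[a, c] + D[b, d], D[a, d] + D[b, c])
  m <- min(s)
  w <- which(s <= m + 1e-9)
  if (length(w) == 1L) w else 0L
}

# Alignment character matrix -> phangorn phyDat
as_phydat <- function(msa) {
  phangorn::phyDat(msa, type = "DNA")
}

check_scalar <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi) {
    stop("invalid argument: ", name, " must be a number in [", lo, ", ", hi, "]")
  }
  invisible(x)
}
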