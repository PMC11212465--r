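# Nuclear-plastid discordance: Robinson-Foulds distance, shared and unique
# clades, tanglegram entanglement with one-sided untangling, and the
# LPP/BS support categories.

# prune both trees to the shared tip set; error below 4 shared tips
shared_pair <- function(t1, t2, min_tips = 4L) {
  shared <- intersect(t1$tip.label, t2$tip.label)
  if (length(shared) < min_tips) stop("fewer than ", min_tips, " shared tips")
  list(t1 = ape::keep.tip(t1, shared), t2 = ape::keep.tip(t2, shared),
       dropped_1 = setdiff(t1$tip.label, shared),
       dropped_2 = setdiff(t2$tip.label, shared))
}

#' Robinson-Foulds distance on the shared tip set
#'
#' Symmetric difference of non-trivial bipartitions, with taxa present in
#' only one tree pruned first; normalized by 2(n-3), the maximum for binary
#' trees on n shared tips.
#'
#' @param t1,t2 `phylo` objects.
#' @return List with `rf` and `rf_normalized`.
#' @export
rf_distance <- function(t1, t2) {
  pr <- shared_pair(t1, t2)
  b1 <- bipartitions(pr$t1)
  b2 <- bipartitions(pr$t2)
  rf <- length(setdiff(b1, b2)) + length(setdiff(b2, b1))
  n <- ape::Ntip(pr$t1)
  list(rf = rf, rf_normalized = rf / (2 * (n - 3)))
}

#' Shared and unique clades of two trees
#'
#' @param t1,t2 `phylo` objects (>= 4 shared tips).
#' @return Object of class `discordance_report`: list with `rf`,
#'   `rf_normalized`, `shared_clades`, `unique_to_a`, `unique_to_b`
#'   (bipartitions as sorted `|`-joined label strings on the side away from
#'   the alphabetically first shared tip), and `pruned` (tips dropped from
#'   either tree).
#' @export
clade_diff <- function(t1, t2) {
  pr <- shared_pair(t1, t2)
  b1 <- bipartitions(pr$t1)
  b2 <- bipartitions(pr$t2)
  ua <- setdiff(b1, b2)
  ub <- setdiff(b2, b1)
  structure(list(rf = length(ua) + length(ub),
                 rf_normalized = (length(ua) + length(ub)) /
                   (2 * (ape::Ntip(pr$t1) - 3)),
                 shared_clades = intersect(b1, b2),
                 unique_to_a = ua, unique_to_b = ub,
                 pruned = c(pr$dropped_1, pr$dropped_2)),
            class = "discordance_report")
}

#' @export
print.discordance_report <- function(x, ...) {
  cat("discordance_report: RF =", x$rf,
      sprintf("(normalized %.3f);", x$rf_normalized),
      length(x$shared_clades), "shared clades,",
      length(x$unique_to_a), "unique to A,",
      length(x$unique_to_b), "unique to B\n")
  invisible(x)
}

# drawn leaf order of a phylo (cladewise plotting order)
leaf_order <- function(tree) {
  tree <- ape::reorder.phylo(tree, "cladewise")
  e <- tree$edge[, 2L]
  tree$tip.label[e[e <= ape::Ntip(tree)]]
}

entanglement_value <- function(ord1, ord2, exponent) {
  n <- length(ord1)
  pos2 <- match(ord1, ord2)
  num <- sum(abs(seq_len(n) - pos2)^exponent)
  den <- sum(abs(seq_len(n) - rev(seq_len(n)))^exponent)
  if (den == 0) 0 else num / den
}

# flip the order of the two (or more) child clades of one internal node
rotate_node <- function(tree, node) {
  ape::rotate(tree, node)
}

#' Tanglegram entanglement with optional one-sided untangling
#'
#' With the leaf order of `t1` fixed, entanglement is the exponent-weighted
#' sum of rank displacements of the shared leaves in `t2`, normalized by the
#' value of the fully reversed ordering (0 = perfectly aligned, 1 =
#' reversed). `untangle = "step1side"` greedily rotates internal nodes of
#' `t2` only, accepting rotations that lower the value, until convergence.
#'
#' @param t1,t2 `phylo` objects on the same tip set.
#' @param exponent Displacement exponent L (default 1.5, the visualization
#'   default).
#' @param untangle `"none"` or `"step1side"`.
#' @return List with `entanglement` and `t2` (possibly rotated).
#' @export
entanglement <- function(t1, t2, exponent = 1.5,
                         untangle = c("none", "step1side")) {
  untangle <- match.arg(untangle)
  if (!setequal(t1$tip.label, t2$tip.label)) {
    pr <- shared_pair(t1, t2)
    t1 <- pr$t1; t2 <- pr$t2
  }
  ord1 <- leaf_order(t1)
  cur <- entanglement_value(ord1, leaf_order(t2), exponent)
  if (untangle == "step1side") {
    repeat {
      improved <- FALSE
      for (node in ape::Ntip(t2) + seq_len(t2$Nnode)) {
        cand <- tryCatch(rotate_node(t2, node), error = function(e) NULL)
        if (is.null(cand)) next
        val <- entanglement_value(ord1, leaf_order(cand), exponent)
        if (val < cur - 1e-12) {
          t2 <- cand
          cur <- val
          improved <- TRUE
        }
      }
      if (!improved) break
    }
  }
  list(entanglement = cur, t2 = t2)
}

#' Support category of an LPP or bootstrap value
#'
#' Mirrors the study's rules: maximal iff LPP = 1.0 / BS = 100; high iff
#' LPP >= 0.9 / BS >= 95; moderate iff LPP >= 0.7 / BS >= 75; weak below.
#'
#' @param metric `"LPP"` (range \[0, 1\]) or `"BS"` (range \[0, 100\]).
#' @param value Support value(s).
#' @return Character vector in `maximal|high|moderate|weak`.
#' @export
classify_support <- function(metric = c("LPP", "BS"), value) {
  metric <- match.arg(metric)
  hi <- if (metric == "LPP") 1 else 100
  if (any(value < 0 | value > hi)) {
    stop("support value out of range for ", metric)
  }
  cuts <- if (metric == "LPP") c(1, 0.9, 0.7) else c(100, 95, 75)
  ifelse(value >= cuts[1L], "maximal",
         ifelse(value >= cuts[2L], "high",
                ifelse(value >= cuts[3L], "moderate", "weak")))
}
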