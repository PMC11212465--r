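# Equal-rates Mk ancestral state reconstruction of floral symmetry:
# Felsenstein pruning likelihood, bounded 1-D rate fit, marginal
# probabilities by the standard down/up (re-rooting) recursion.

SYMMETRY_STATES <- c("actinomorphic", "disymmetric", "zygomorphic")

#' Prune tips from a tree
#'
#' Removes the listed tips, suppresses resulting degree-2 nodes and sums the
#' merged branch lengths (e.g. dropping the Sabiaceae outgroup before
#' ancestral reconstruction).
#'
#' @param tree `phylo`.
#' @param labels Tip labels to remove (may be empty).
#' @return `phylo` with at least 3 tips.
#' @export
prune_tips <- function(tree, labels) {
  labels <- intersect(labels, tree$tip.label)
  if (!length(labels)) return(tree)
  if (ape::Ntip(tree) - length(labels) < 3L) {
    stop("pruning would leave fewer than 3 tips")
  }
  ape::drop.tip(tree, labels)
}

#' Code floral symmetry states for a taxon list
#'
#' Every taxon defaults to actinomorphic; `overrides` reassigns states. The
#' packaged default override table encodes the study's coding rules:
#' Delphinium is zygomorphic, Euptelea missing, Hypecoum disymmetric,
#' Capnoides zygomorphic, and the Papaveraceae genera carry their pictured
#' states. Override keys match taxa by prefix (genus-level rules apply to
#' every accession of the genus).
#'
#' @param taxa Character vector of taxon labels.
#' @param overrides Named character vector `c(taxon_or_prefix = state)`, or
#'   NULL for the packaged defaults.
#' @return Named character vector of states (a character matrix in the
#'   field's sense), values in `actinomorphic|disymmetric|zygomorphic|missing`.
#' @export
code_symmetry <- function(taxa, overrides = NULL) {
  if (is.null(overrides)) overrides <- default_symmetry_overrides()
  ok <- c(SYMMETRY_STATES, "missing")
  if (!all(overrides %in% ok)) {
    stop("unknown state word: ", setdiff(overrides, ok)[1L])
  }
  states <- stats::setNames(rep("actinomorphic", length(taxa)), taxa)
  for (key in names(overrides)) {
    hit <- startsWith(taxa, key)
    states[hit] <- overrides[[key]]
  }
  states
}

default_symmetry_overrides <- function() {
  c(Delphinium = "zygomorphic",
    Euptelea = "missing",
    Hypecoum = "disymmetric",
    Capnoides = "zygomorphic",
    Corydalis = "zygomorphic",
    Fumaria = "zygomorphic",
    Rupicapnos = "zygomorphic",
    Platycapnos = "zygomorphic",
    Ceratocapnos = "zygomorphic",
    Sarcocapnos = "zygomorphic",
    Dactylicapnos = "disymmetric",
    Dicentra = "disymmetric",
    Lamprocapnos = "disymmetric",
    Adlumia = "disymmetric",
    Ichtyoselmis = "disymmetric",
    Ehrendorferia = "disymmetric")
}

# ER transition probability matrix: off-diagonal rate q each, k states.
er_pmat <- function(q, t, k) {
  e <- exp(-k * q * t)
  p <- matrix((1 - e) / k, k, k)
  diag(p) <- 1 / k + (1 - 1 / k) * e
  p
}

# tip conditional vectors: 1-hot, or all ones for "missing"
tip_conditionals <- function(chars, tips, states) {
  k <- length(states)
  L <- matrix(1, length(tips), k)
  for (i in seq_along(tips)) {
    s <- chars[[tips[i]]]
    if (is.null(s) || is.na(s) || s == "missing") next
    j <- match(s, states)
    if (is.na(j)) stop("unknown state word: ", s)
    L[i, ] <- 0
    L[i, j] <- 1
  }
  L
}

# pruning pass: per-node conditional likelihoods with per-node log scalers
mk_down_pass <- function(tree, chars, q, states) {
  k <- length(states)
  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  L <- matrix(1, nn, k)
  logscale <- numeric(nn)
  L[seq_len(ntip), ] <- tip_conditionals(chars, tree$tip.label, states)
  edge <- ape::reorder.phylo(tree, "postorder")$edge
  elen <- ape::reorder.phylo(tree, "postorder")$edge.length
  for (e in seq_len(nrow(edge))) {
    p <- edge[e, 1L]; v <- edge[e, 2L]
    P <- er_pmat(q, elen[e], k)
    contrib <- as.vector(P %*% L[v, ])
    L[p, ] <- L[p, ] * contrib
    logscale[p] <- logscale[p] + logscale[v]
    m <- max(L[p, ])
    if (m > 0 && m < 1e-10) {
      L[p, ] <- L[p, ] / m
      logscale[p] <- logscale[p] + log(m)
    }
  }
  list(L = L, logscale = logscale, edge = edge, elen = elen)
}

mk_loglik <- function(tree, chars, q, states = SYMMETRY_STATES) {
  k <- length(states)
  d <- mk_down_pass(tree, chars, q, states)
  root <- ape::Ntip(tree) + 1L
  log(sum(d$L[root, ] / k)) + d$logscale[root]
}

#' Fit the equal-rates Mk model on a chronogram
#'
#' All transitions share one rate q; the likelihood uses Felsenstein pruning
#' with uniform root frequencies; `missing` tips contribute an all-ones
#' conditional. q is fit by bounded 1-D maximization.
#'
#' @param chronogram Rooted tree with branch lengths in My (a `chronogram`
#'   or plain `phylo`).
#' @param chars Named character vector of tip states (see [code_symmetry()]).
#' @param states State space (default the three floral-symmetry states).
#' @param q_max Upper bound of the rate search (default 100 expected
#'   transitions over the tree depth).
#' @return List with `rate`, `logLik`, `states`, `tree`.
#' @export
fit_mk <- function(chronogram, chars, states = SYMMETRY_STATES, q_max = NULL) {
  tree <- if (inherits(chronogram, "chronogram")) chronogram$tree else chronogram
  chars <- chars[tree$tip.label]
  observed <- chars[!is.na(chars) & chars != "missing"]
  if (!length(observed)) stop("all tips missing")
  depth <- max(node_ages(tree))
  if (is.null(q_max)) q_max <- 100 / max(depth, 1e-9)
  # the profile can plateau at high rates; bracket the optimum on a log grid
  # before refining, so golden-section is not trapped on the plateau
  grid <- exp(seq(log(1e-6 / depth), log(q_max), length.out = 40L))
  ll <- vapply(grid, function(q) mk_loglik(tree, chars, q, states), numeric(1))
  i <- which.max(ll)
  lo <- grid[max(i - 1L, 1L)]
  hi <- grid[min(i + 1L, length(grid))]
  opt <- stats::optimize(function(q) mk_loglik(tree, chars, q, states),
                         interval = c(lo, hi), maximum = TRUE, tol = 1e-10)
  if (ll[i] > opt$objective) opt <- list(maximum = grid[i], objective = ll[i])
  list(rate = opt$maximum, logLik = opt$objective, states = states,
       tree = tree)
}

#' Marginal ancestral state probabilities under the ER Mk model
#'
#' Standard down/up algorithm: the marginal at a node is the normalized
#' product of its downward conditional likelihoods and the upward partial
#' likelihood of the rest of the tree (the re-rooting formulation), with
#' uniform root frequencies.
#'
#' @param chronogram Rooted tree (branch lengths in My) or `chronogram`.
#' @param chars Named tip-state vector.
#' @param rate Transition rate q (e.g. from [fit_mk()]).
#' @param states State space.
#' @return Object of class `asr_result`: list with `prob` (internal-node
#'   matrix of state probabilities, rows named by ape node id), `rate`,
#'   `logLik`.
#' @export
marginal_asr <- function(chronogram, chars, rate, states = SYMMETRY_STATES) {
  tree <- if (inherits(chronogram, "chronogram")) chronogram$tree else chronogram
  check_scalar(rate, "rate", lo = 0)
  chars <- chars[tree$tip.label]
  k <- length(states)
  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  d <- mk_down_pass(tree, chars, rate, states)
  root <- ntip + 1L
  # upward pass in preorder: U[v] = P^T (U[parent] * prod_siblings P L)
  U <- matrix(0, nn, k)
  U[root, ] <- 1 / k
  pre <- nrow(d$edge):1
  kids <- split(seq_len(nrow(d$edge)), d$edge[, 1L])
  contrib <- matrix(0, nrow(d$edge), k)  # P_e %*% L[child_e]
  for (e in seq_len(nrow(d$edge))) {
    contrib[e, ] <- as.vector(er_pmat(rate, d$elen[e], k) %*% L_row(d, e))
  }
  for (e in pre) {
    p <- d$edge[e, 1L]; v <- d$edge[e, 2L]
    sibs <- setdiff(kids[[as.character(p)]], e)
    above <- U[p, ]
    for (s in sibs) above <- above * contrib[s, ]
    U[v, ] <- as.vector(t(er_pmat(rate, d$elen[e], k)) %*% above)
    m <- max(U[v, ])
    if (m > 0) U[v, ] <- U[v, ] / m  # scale; normalization happens below
  }
  prob <- matrix(NA_real_, tree$Nnode, k,
                 dimnames = list((ntip + 1L):nn, states))
  for (v in (ntip + 1L):nn) {
    w <- d$L[v, ] * U[v, ]
    prob[v - ntip, ] <- w / sum(w)
  }
  structure(list(prob = prob, rate = rate,
                 logLik = mk_loglik(tree, chars, rate, states),
                 states = states, tree = tree),
            class = "asr_result")
}

L_row <- function(d, e) d$L[d$edge[e, 2L], ]

#' @export
print.asr_result <- function(x, ...) {
  cat("asr_result:", nrow(x$prob), "internal nodes, rate",
      format(x$rate, digits = 4), "logLik", format(x$logLik, digits = 6), "\n")
  invisible(x)
}
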