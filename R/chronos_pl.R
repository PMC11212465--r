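# Penalized-likelihood divergence dating: Poisson branch likelihood minus a
# roughness penalty on rate changes, under min/max node-age constraints,
# with multi-start ("priming") optimization and leave-one-out
# cross-validation of the smoothing parameter.

#' Dating configuration
#'
#' @param smoothing Smoothing parameter lambda >= 0. Presets matching the
#'   study: 0.01 for the nuclear track, 1e-6 for the plastid track.
#' @param cv_grid Candidate lambdas for [cross_validate()].
#' @param priming_iterations Multi-start restarts for [date_tree()]
#'   (default 5).
#' @param cv_iterations Restarts used inside cross-validation (default 5).
#' @param site_count Alignment columns behind the branch lengths; scales
#'   substitutions/site into expected substitution counts.
#' @return List of class `dating_config`.
#' @export
dating_config <- function(smoothing = 0.01,
                          cv_grid = 10^seq(-6, 3, by = 1),
                          priming_iterations = 5L, cv_iterations = 5L,
                          site_count = 10000L) {
  check_scalar(smoothing, "smoothing", lo = 0)
  check_scalar(site_count, "site_count", lo = 1)
  structure(list(smoothing = smoothing, cv_grid = cv_grid,
                 priming_iterations = priming_iterations,
                 cv_iterations = cv_iterations, site_count = site_count),
            class = "dating_config")
}

#' Penalized log-likelihood of a rate/age assignment
#'
#' sum over branches of \[x ln(r t) - r t\] minus lambda times the roughness
#' penalty: squared rate differences between each branch and its parent
#' branch, plus the variance of the rates on the root's child branches.
#' x is branch length (substitutions/site) times `site_count`; terminal
#' branches with zero length get a floor of 0.5 substitutions so the log
#' term stays finite.
#'
#' @param tree Rooted `phylo`, branch lengths in substitutions/site.
#' @param ages Node ages (Mya) indexed by ape node id.
#' @param rates Per-edge rates on the expected-substitution-count scale
#'   (so r t is compared against x = branch length x `site_count`; a
#'   [date_tree()] chronogram reports rates/`site_count`, i.e.
#'   substitutions/site/My), in `tree$edge` order.
#' @param lambda Smoothing parameter.
#' @param site_count Alignment columns.
#' @return The penalized log-likelihood (a scalar).
#' @export
pl_objective <- function(tree, ages, rates, lambda, site_count) {
  parent <- tree$edge[, 1L]; child <- tree$edge[, 2L]
  t_b <- ages[parent] - ages[child]
  if (any(t_b <= 0)) stop("invalid ages: every parent must be older than its child")
  x <- tree$edge.length * site_count
  terminal <- child <= ape::Ntip(tree)
  x[terminal & x <= 0] <- 0.5
  rt <- rates * t_b
  ll <- sum(ifelse(x > 0, x * log(rt), 0) - rt)
  ll - lambda * rate_penalty(tree, rates)
}

rate_penalty <- function(tree, rates) {
  parent <- tree$edge[, 1L]; child <- tree$edge[, 2L]
  root <- ape::Ntip(tree) + 1L
  parent_edge <- match(parent, child)  # NA for root children
  inner <- !is.na(parent_edge)
  pen <- sum((rates[inner] - rates[parent_edge[inner]])^2)
  root_rates <- rates[parent == root]
  if (length(root_rates) > 1L) pen <- pen + stats::var(root_rates)
  pen
}

#' Resolve a calibration table against a tree
#'
#' @param tree Rooted `phylo`.
#' @param calibrations Data frame with columns `label`, `tip_a`, `tip_b`,
#'   `min_age`, `max_age`; `tip_a = "root"` selects the root. Rows whose
#'   tips are absent error unless `partial = TRUE` (then they are dropped).
#' @param partial Drop unresolvable rows instead of erroring.
#' @return Data frame with `node`, `min_age`, `max_age`, `label`.
#' @export
resolve_calibrations <- function(tree, calibrations, partial = FALSE) {
  root <- ape::Ntip(tree) + 1L
  rows <- list()
  for (i in seq_len(nrow(calibrations))) {
    r <- calibrations[i, ]
    if (identical(r$tip_a, "root")) {
      node <- root
    } else {
      present <- c(r$tip_a, r$tip_b) %in% tree$tip.label
      if (!all(present)) {
        if (partial) next
        stop("calibration row ", i, " (", r$label,
             "): tip not in tree: ", c(r$tip_a, r$tip_b)[!present][1L])
      }
      node <- ape::getMRCA(tree, c(r$tip_a, r$tip_b))
    }
    mn <- if (is.na(r$min_age)) 0 else r$min_age
    mx <- if (is.na(r$max_age)) Inf else r$max_age
    if (mn > mx) stop("calibration row ", i, ": min_age > max_age")
    rows[[length(rows) + 1L]] <- data.frame(node = node, min_age = mn,
                                            max_age = mx, label = r$label,
                                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(node = integer(0), min_age = numeric(0),
                                      max_age = numeric(0),
                                      label = character(0))
  out
}

#' Load a calibration table from TSV
#'
#' Columns: `label`, `tip_a`, `tip_b`, `min_age`, `max_age` (empty = no
#' bound); `tip_a = "root"` is reserved for the root. The packaged default
#' (`system.file("extdata", "ranunculales_calibrations.tsv", package =
#' "symcord")`) encodes the Ranunculales fossil ledger: root and
#' Ranunculales crown at 125-201.5 Mya, Sabiaceae crown min 83.4,
#' Lardizabalaceae stem/crown min 110/41.2, Menispermaceae stem/crown min
#' 91/64.67, Coptidoideae+Ranunculoideae crown min 56, and 1 Mya caps on
#' the three within-species tip pairs.
#'
#' @param path TSV path (defaults to the packaged ledger).
#' @return Data frame usable by [resolve_calibrations()].
#' @export
load_calibrations <- function(path = system.file("extdata",
                                                 "ranunculales_calibrations.tsv",
                                                 package = "symcord")) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("label", "tip_a", "tip_b", "min_age", "max_age")
  if (!all(need %in% names(df))) stop("calibration file must have columns: ",
                                      paste(need, collapse = ", "))
  df$min_age <- suppressWarnings(as.numeric(df$min_age))
  df$max_age <- suppressWarnings(as.numeric(df$max_age))
  df
}

# Effective per-node bounds: lo from descendant minima (bottom-up), hi from
# ancestor maxima (top-down). Tips sit at age 0.
effective_bounds <- function(tree, resolved) {
  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  lo <- rep(0, nn); hi <- rep(Inf, nn)
  for (i in seq_len(nrow(resolved))) {
    v <- resolved$node[i]
    lo[v] <- max(lo[v], resolved$min_age[i])
    hi[v] <- min(hi[v], resolved$max_age[i])
  }
  edge <- ape::reorder.phylo(tree, "postorder")$edge
  for (e in seq_len(nrow(edge))) {  # postorder: children before parents
    lo[edge[e, 1L]] <- max(lo[edge[e, 1L]], lo[edge[e, 2L]])
  }
  pre <- nrow(edge):1
  for (e in pre) {
    hi[edge[e, 2L]] <- min(hi[edge[e, 2L]], hi[edge[e, 1L]])
  }
  bad <- which(lo > hi + 1e-12)
  if (length(bad)) {
    stop("infeasible calibrations around node ", bad[1L],
         ": effective minimum ", lo[bad[1L]], " exceeds maximum ", hi[bad[1L]])
  }
  list(lo = lo, hi = hi)
}

# ages from the proportional-depth parameter vector (preorder fill)
ages_from_par <- function(p, tree, lo, hi, internal_order, parent_of) {
  ntip <- ape::Ntip(tree)
  root <- ntip + 1L
  ages <- numeric(ntip + tree$Nnode)
  ages[root] <- lo[root] + stats::plogis(p[1L]) * (hi[root] - lo[root])
  k <- 1L
  for (v in internal_order) {  # preorder, root excluded
    k <- k + 1L
    up <- min(hi[v], ages[parent_of[v]])
    width <- max(up - lo[v], 0)
    ages[v] <- lo[v] + stats::plogis(p[k]) * width
  }
  ages
}

#' Date a tree by penalized likelihood under fossil constraints
#'
#' Ages are parameterized as proportional depths between each node's
#' effective bounds (so parent > child and every min/max holds by
#' construction); rates are log-parameterized per branch. The objective is
#' maximized with `priming_iterations` multi-start L-BFGS runs from a
#' clock-like initialization plus jittered restarts.
#'
#' @param tree Rooted `phylo`, branch lengths in substitutions/site; the
#'   root must carry a finite maximum (or fixed) age, otherwise the time
#'   scale is unidentifiable.
#' @param calibrations Calibration data frame (see [load_calibrations()]).
#' @param cfg A [dating_config()].
#' @param seed Integer seed.
#' @return Object of class `chronogram`: list with `tree` (ultrametric,
#'   branch lengths in My), `ages`, `rates` (per edge), `objective`,
#'   `calibration_report` (achieved age per constraint), `lambda`.
#' @export
date_tree <- function(tree, calibrations, cfg = dating_config(), seed = 1L) {
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  if (!ape::is.binary(tree)) tree <- ape::multi2di(tree)
  set.seed(seed)
  ntip <- ape::Ntip(tree)
  root <- ntip + 1L
  resolved <- resolve_calibrations(tree, calibrations)
  b <- effective_bounds(tree, resolved)
  lo <- b$lo; hi <- b$hi
  if (!is.finite(hi[root])) {
    stop("the root needs a maximum (or fixed) age; the time scale is ",
         "otherwise unidentifiable")
  }
  if (hi[root] <= lo[root]) hi[root] <- lo[root] + 1e-6  # fixed root age
  pre_edge <- ape::reorder.phylo(tree, "cladewise")$edge
  parent_of <- integer(ntip + tree$Nnode)
  parent_of[pre_edge[, 2L]] <- pre_edge[, 1L]
  internal_order <- pre_edge[pre_edge[, 2L] > ntip, 2L]  # preorder internals
  n_age <- 1L + length(internal_order)
  n_edge <- nrow(tree$edge)
  lambda <- cfg$smoothing
  sites <- cfg$site_count

  neg_obj <- function(par) {
    ages <- ages_from_par(par[seq_len(n_age)], tree, lo, hi,
                          internal_order, parent_of)
    rates <- exp(par[n_age + seq_len(n_edge)])
    t_b <- ages[tree$edge[, 1L]] - ages[tree$edge[, 2L]]
    t_b <- pmax(t_b, 1e-9 * max(ages))
    x <- tree$edge.length * sites
    x[tree$edge[, 2L] <= ntip & x <= 0] <- 0.5
    rt <- rates * t_b
    ll <- sum(ifelse(x > 0, x * log(rt), 0) - rt)
    -(ll - lambda * rate_penalty(tree, rates))
  }

  # clock-like init: node depths proportional to substitution path lengths
  depth <- ape::node.depth.edgelength(tree)
  rel <- 1 - depth / max(depth[seq_len(ntip)])
  root0 <- lo[root] + 0.5 * (hi[root] - lo[root])
  init_par <- function(jitter = 0) {
    ages0 <- rel * root0
    p <- numeric(n_age)
    p[1L] <- 0
    ages <- numeric(length(ages0))
    ages[root] <- lo[root] + stats::plogis(p[1L]) * (hi[root] - lo[root])
    k <- 1L
    for (v in internal_order) {
      k <- k + 1L
      up <- min(hi[v], ages[parent_of[v]])
      width <- max(up - lo[v], 1e-9)
      frac <- (ages0[v] - lo[v]) / width
      p[k] <- stats::qlogis(min(max(frac, 0.02), 0.98))
      ages[v] <- lo[v] + stats::plogis(p[k]) * width
    }
    r0 <- sum(tree$edge.length) / max(sum(ages[tree$edge[, 1L]] -
                                            ages[tree$edge[, 2L]]), 1e-9)
    par <- c(p, rep(log(max(r0, 1e-12)), n_edge))
    par + stats::rnorm(length(par), 0, jitter)
  }

  best <- NULL
  for (i in seq_len(max(1L, cfg$priming_iterations))) {
    par0 <- init_par(jitter = if (i == 1L) 0 else 0.5)
    fit <- tryCatch(
      stats::optim(par0, neg_obj, method = "L-BFGS-B",
                   control = list(maxit = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("optimization failed from every start")
  ages <- ages_from_par(best$par[seq_len(n_age)], tree, lo, hi,
                        internal_order, parent_of)
  # the objective works on count-scale rates (r t against x = length x sites);
  # the chronogram reports substitutions/site/My
  rates <- exp(best$par[n_age + seq_len(n_edge)]) / sites
  out_tree <- tree
  out_tree$edge.length <- ages[tree$edge[, 1L]] - ages[tree$edge[, 2L]]
  out_tree$node.label <- NULL
  report <- resolved
  report$achieved <- ages[resolved$node]
  report$ok <- report$achieved >= report$min_age - 1e-6 &
    report$achieved <= report$max_age + 1e-6
  if (!all(report$ok)) {
    stop("constraint violated after optimization: ",
         report$label[!report$ok][1L])
  }
  structure(list(tree = out_tree, ages = ages, rates = rates,
                 objective = -best$value, calibration_report = report,
                 lambda = lambda),
            class = "chronogram")
}

#' @export
print.chronogram <- function(x, ...) {
  cat("chronogram:", ape::Ntip(x$tree), "tips, root age",
      format(max(x$ages), digits = 6), "Mya, lambda =", x$lambda, "\n")
  cat("  calibrations satisfied:", sum(x$calibration_report$ok), "/",
      nrow(x$calibration_report), "\n")
  invisible(x)
}

#' Choose the smoothing parameter by leave-one-tip-out cross-validation
#'
#' For each tip, the tree is dated without it and the pendant substitution
#' count is predicted from the adjacent branch's rate and the (interpolated)
#' attachment age; the chi-square-style error (x - x_hat)^2 / max(x, 1) is
#' summed over tips. The grid value with the smallest score wins, ties going
#' to the smaller lambda.
#'
#' @param tree Rooted `phylo`, substitutions/site branch lengths.
#' @param calibrations Calibration data frame.
#' @param cfg A [dating_config()] whose `cv_grid` is the lambda grid.
#' @param seed Integer seed.
#' @return List with `lambda` (chosen), `table` (per-lambda scores).
#' @export
cross_validate <- function(tree, calibrations, cfg = dating_config(),
                           seed = 1L) {
  if (!length(cfg$cv_grid)) stop("cv_grid is empty")
  if (ape::Ntip(tree) < 3L) stop("need at least 3 tips")
  ntip <- ape::Ntip(tree)
  sites <- cfg$site_count
  scores <- numeric(length(cfg$cv_grid))
  for (li in seq_along(cfg$cv_grid)) {
    lam <- cfg$cv_grid[li]
    cfg_i <- cfg
    cfg_i$smoothing <- lam
    cfg_i$priming_iterations <- cfg$cv_iterations
    err <- 0
    for (tip in seq_len(ntip)) {
      lab <- tree$tip.label[tip]
      pruned <- ape::drop.tip(tree, lab)
      calib_ok <- calibrations[
        calibrations$tip_a == "root" |
          (calibrations$tip_a != lab & calibrations$tip_b != lab), ,
        drop = FALSE]
      chrono <- date_tree(pruned, calib_ok, cfg_i, seed = seed + li)
      # merged edge in the pruned tree: the edge above the tip's ex-sibling
      p_node <- tree$edge[tree$edge[, 2L] == tip, 1L]
      sib <- setdiff(tree$edge[tree$edge[, 1L] == p_node, 2L], tip)
      sib_tips <- if (sib <= ntip) tree$tip.label[sib]
                  else ape::extract.clade(tree, sib)$tip.label
      m_node <- if (length(sib_tips) == 1L) match(sib_tips, pruned$tip.label)
                else ape::getMRCA(pruned, sib_tips)
      m_edge <- which(pruned$edge[, 2L] == m_node)
      if (!length(m_edge)) next  # sibling became the root
      r_hat <- chrono$rates[m_edge]
      top <- pruned$edge[m_edge, 1L]
      a_top <- chrono$ages[top]
      # interpolate the attachment age along the merged branch
      gp_edge <- which(tree$edge[, 2L] == p_node)
      x_above <- if (length(gp_edge)) tree$edge.length[gp_edge] * sites else 0
      t_attach <- max(a_top - x_above / max(r_hat * sites, 1e-12),
                      1e-6 * a_top)
      x_i <- tree$edge.length[tree$edge[, 2L] == tip] * sites
      x_hat <- r_hat * t_attach * sites
      err <- err + (x_i - x_hat)^2 / max(x_i, 1)
    }
    scores[li] <- err
  }
  best <- which(scores <= min(scores) + 1e-12)[1L]
  list(lambda = cfg$cv_grid[best],
       table = data.frame(lambda = cfg$cv_grid, score = scores))
}

#' Root a tree on its outgroup
#'
#' @param tree Unrooted (or rooted) `phylo`.
#' @param outgroup Tip labels of the outgroup.
#' @return Rooted `phylo`.
#' @export
root_at_outgroup <- function(tree, outgroup) {
  outgroup <- intersect(outgroup, tree$tip.label)
  if (!length(outgroup)) stop("no outgroup tips present")
  ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
}

#' Synthetic Ranunculales exemplar chronogram
#'
#' A small synthetic ultrametric tree whose tip labels and clade structure
#' let every row of the packaged fossil-calibration ledger resolve: Sabiaceae
#' outgroup (four tips), Euptelea, Papaveraceae (the Hypecoum and Capnoides
#' within-species pairs), Lardizabalaceae + Circaeaster, Menispermaceae and
#' Ranunculaceae. Node ages are invented but feasible under every ledger
#' constraint (root 190 Mya, Ranunculales crown 187 Mya); this is a stand-in
#' scaffold for exercising the dating machinery, not an estimate.
#'
#' @return A rooted ultrametric `phylo` with 17 tips, branch lengths in Mya.
#' @export
ranunculales_exemplar_tree <- function() {
  txt <- paste0(
    "(((Sabia_japonica:40,Sabia_yunnanensis:40):60,",
    "(Meliosma_alba:40,Meliosma_cuneifolia:40):60):90,",
    "((Euptelea_pleiosperma_A:0.5,Euptelea_pleiosperma_B:0.5):186.5,",
    "(((Hypecoum_procumbens_A:0.5,Hypecoum_procumbens_B:0.5):139.5,",
    "(Capnoides_sempervirens_A:0.5,Capnoides_sempervirens_B:0.5):139.5):40,",
    "(((Lardizabala_biternata:60,Sargentodoxa_cuneata:60):100,",
    "Circaeaster_agrestis:160):18,",
    "((Tinospora_cordifolia:70,Menispermum_canadense:70):80,",
    "(Coptis_chinensis:109,Ranunculus_bulbosus:109):41):28):2):7):3);")
  ape::read.tree(text = txt)
}
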