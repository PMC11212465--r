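# Alignment QC: summary statistics, the 1/3-median length/P_PIC filter,
# column trimming with a conservation floor, per-species outlier flagging.

AMBIG <- c("-", "?", "N", "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")

#' Alignment summary statistics
#'
#' A column is parsimony-informative iff at least two distinct unambiguous
#' states each occur in at least two sequences. Gaps and IUPAC ambiguity
#' codes count as missing.
#'
#' @param msa Character matrix (taxa x sites).
#' @return List with `n_taxa`, `length`, `missing_fraction`, `p_pic`.
#' @export
msa_stats <- function(msa) {
  if (!is.matrix(msa)) stop("msa must be a character matrix")
  if (ncol(msa) < 1L) stop("empty alignment")
  miss <- matrix(msa %in% AMBIG, nrow(msa), ncol(msa))
  informative <- vapply(seq_len(ncol(msa)), function(j) {
    tab <- table(msa[!miss[, j], j])
    sum(tab >= 2L) >= 2L
  }, logical(1))
  list(n_taxa = nrow(msa), length = ncol(msa),
       missing_fraction = mean(miss),
       p_pic = mean(informative))
}

#' Filter genes whose alignment length or P_PIC falls below 1/3 of the median
#'
#' @param stats Named list of [msa_stats()] results (one per gene), or a data
#'   frame with columns `gene`, `length`, `p_pic`.
#' @param frac Fraction of the median (default 1/3); removal uses strict `<`.
#' @return List with `retained` gene names and `log` data frame.
#' @export
filter_alignments <- function(stats, frac = 1 / 3) {
  if (is.data.frame(stats)) {
    df <- stats
  } else {
    df <- data.frame(gene = names(stats),
                     length = vapply(stats, `[[`, numeric(1), "length"),
                     p_pic = vapply(stats, `[[`, numeric(1), "p_pic"),
                     stringsAsFactors = FALSE)
  }
  if (!nrow(df)) stop("no genes")
  thr_len <- frac * stats::median(df$length)
  thr_pic <- frac * stats::median(df$p_pic)
  bad_len <- df$length < thr_len
  bad_pic <- df$p_pic < thr_pic
  drop <- bad_len | bad_pic
  log <- data.frame(gene = df$gene[drop],
                    rule = ifelse(bad_len[drop], "length", "p_pic"),
                    stringsAsFactors = FALSE)
  list(retained = df$gene[!drop], log = log)
}

#' Trim alignment columns with a gap threshold and a conservation floor
#'
#' Columns whose non-gap fraction is at least `gap_keep` are kept; if fewer
#' than `cons_floor` percent of columns would survive, the `cons_floor`
#' percent of columns with the highest non-gap fraction are kept instead
#' (ties broken by left position). Column order is preserved. Mirrors lax
#' trimming with `-gt 0.1 -cons 35`.
#'
#' @param msa Character matrix (taxa x sites).
#' @param gap_keep Minimum non-gap fraction to keep a column (default 0.1).
#' @param cons_floor Minimum percentage of columns retained (default 35).
#' @return Trimmed character matrix with attribute `kept` (column indices).
#' @export
trim_alignment <- function(msa, gap_keep = 0.1, cons_floor = 35) {
  if (!is.matrix(msa) || ncol(msa) == 0L) stop("empty alignment")
  check_scalar(gap_keep, "gap_keep", 0, 1)
  check_scalar(cons_floor, "cons_floor", 0, 100)
  nongap <- colMeans(!matrix(msa %in% AMBIG, nrow(msa), ncol(msa)))
  pass <- which(nongap >= gap_keep)
  floor_n <- ceiling(cons_floor / 100 * ncol(msa))
  keep <- if (length(pass) >= floor_n) {
    pass
  } else {
    ord <- order(-nongap, seq_along(nongap))  # best first, ties by position
    sort(ord[seq_len(floor_n)])
  }
  out <- msa[, keep, drop = FALSE]
  attr(out, "kept") <- keep
  out
}

#' Flag per-species outlier sequences across gene trees
#'
#' For each gene tree and species present, the signature is the relative drop
#' in tree diameter when that species is pruned. Per species, occurrences are
#' flagged when the signature exceeds both the empirical (1 - alpha) quantile
#' of that species' signatures across genes and a global minimum effect.
#' This is a simplified per-species diameter-signature detector in the spirit
#' of TreeShrink's per-species mode, not a reimplementation of it.
#'
#' @param gene_trees `multiPhylo` of gene trees with branch lengths.
#' @param alpha False-positive tolerance in (0, 1\] (default 0.5, the
#'   filtering the study retained; 0.05 also ran there).
#' @param min_effect Minimum relative diameter drop to flag (default 0.2).
#' @param min_genes Species present in fewer genes are never flagged.
#' @return Data frame with columns `species`, `gene`, `signature`; attribute
#'   `skipped` lists species with too few genes.
#' @export
flag_outliers <- function(gene_trees, alpha = 0.5, min_effect = 0.2,
                          min_genes = 5L) {
  if (!(alpha > 0 && alpha <= 1)) stop("alpha must be in (0, 1]")
  sig <- list()
  for (g in seq_along(gene_trees)) {
    tr <- gene_trees[[g]]
    if (ape::Ntip(tr) < 4L) next
    D <- ape::cophenetic.phylo(tr)
    diam <- max(D)
    if (diam <= 0) next
    for (sp in tr$tip.label) {
      others <- setdiff(rownames(D), sp)
      s <- (diam - max(D[others, others])) / diam
      sig[[length(sig) + 1L]] <- data.frame(
        species = sp, gene = g, signature = s, stringsAsFactors = FALSE)
    }
  }
  sig <- do.call(rbind, sig)
  flagged <- sig[0, ]
  skipped <- character(0)
  for (sp in unique(sig$species)) {
    rows <- sig[sig$species == sp, ]
    if (nrow(rows) < min_genes) {
      skipped <- c(skipped, sp)
      next
    }
    # inverse-ECDF quantile: as alpha -> 0 the threshold reaches the maximum
    # and (strict >) nothing can be flagged
    q <- stats::quantile(rows$signature, 1 - alpha, names = FALSE, type = 1)
    hit <- rows$signature > q & rows$signature > min_effect
    flagged <- rbind(flagged, rows[hit, ])
  }
  rownames(flagged) <- NULL
  attr(flagged, "skipped") <- skipped
  flagged
}
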