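# Target-capture recovery QC: coverage score (representedness, completeness,
# evenness), paralog and median-score gene filters, k-medoids target picking.

#' Per-gene and per-cell recovery statistics (coverage score)
#'
#' For each gene g over accessions a:
#' representedness_g = share of accessions with a sequence;
#' completeness_ga = min(recovered/target, 1);
#' evenness_g = Pielou-style exp(H)/m over the normalized length shares of
#' the m recovering accessions (1 when m <= 1);
#' sequence_score_ga = completeness_ga * representedness_g * evenness_g;
#' gene_score_g = median sequence score over recovering accessions.
#'
#' @param matrix A [recovery_matrix()].
#' @return Object of class `qc_stats`: list with `representedness`,
#'   `evenness`, `gene_score` (per gene), `completeness` and
#'   `sequence_score` (gene x accession matrices, NA where absent).
#' @export
recovery_stats <- function(matrix) {
  stopifnot(inherits(matrix, "recovery_matrix"))
  rl <- matrix$recovered_length
  if (ncol(rl) == 0L) stop("recovery matrix has zero accessions")
  A <- ncol(rl)
  present <- rl > 0
  repr <- rowSums(present) / A
  compl <- pmin(sweep(rl, 1L, matrix$target_length, "/"), 1)
  compl[!present] <- NA_real_
  even <- apply(rl, 1L, function(x) {
    x <- x[x > 0]
    if (length(x) <= 1L) return(1)
    p <- x / sum(x)
    exp(-sum(p * log(p))) / length(p)
  })
  seq_score <- compl * repr * even
  gene_score <- apply(seq_score, 1L, function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) 0 else stats::median(x)
  })
  structure(list(representedness = repr, completeness = compl,
                 evenness = even, sequence_score = seq_score,
                 gene_score = gene_score, genes = matrix$genes),
            class = "qc_stats")
}

#' Apply the paralog and 2/3-median coverage-score gene filters
#'
#' Step 1 removes genes with multiple assembled copies in at least
#' `paralog_min` accessions ("three or more paralogs"). Step 2 takes the
#' median gene score over the survivors and removes genes scoring below
#' `score_frac` of it (strict inequality).
#'
#' @param stats A `qc_stats` from [recovery_stats()].
#' @param matrix The matching `recovery_matrix`.
#' @param paralog_min Accessions with >= 2 copies needed to drop a gene.
#' @param score_frac Fraction of the median gene score below which genes are
#'   dropped (default 2/3).
#' @return List with `retained` (gene names) and `log` (data frame of
#'   removals with the rule that fired).
#' @export
filter_genes <- function(stats, matrix, paralog_min = 3L, score_frac = 2 / 3) {
  stopifnot(inherits(stats, "qc_stats"), inherits(matrix, "recovery_matrix"))
  genes <- matrix$genes
  if (!identical(stats$genes, genes)) stop("stats and matrix gene sets differ")
  multi <- rowSums(matrix$copy_count >= 2L)
  drop1 <- multi >= paralog_min
  log <- data.frame(gene = genes[drop1],
                    rule = rep("paralog", sum(drop1)),
                    detail = sprintf("%d accessions with >=2 copies",
                                     multi[drop1]),
                    stringsAsFactors = FALSE)
  surv <- genes[!drop1]
  if (length(surv)) {
    med <- stats::median(stats$gene_score[!drop1])
    thr <- score_frac * med
    low <- stats$gene_score[!drop1] < thr
    log <- rbind(log, data.frame(
      gene = surv[low], rule = rep("score", sum(low)),
      detail = sprintf("gene_score %.4f < %.4f", stats$gene_score[!drop1][low],
                       thr),
      stringsAsFactors = FALSE))
    retained <- surv[!low]
  } else {
    retained <- character(0)
  }
  if (!length(retained)) warning("all genes removed by the filters")
  list(retained = retained, log = log)
}

# Pairwise distance 1 - (proportion of identical aligned positions), over
# columns where both sequences are non-gap.
pairwise_identity_dist <- function(msa) {
  n <- nrow(msa)
  D <- matrix(0, n, n, dimnames = list(rownames(msa), rownames(msa)))
  gap <- msa == "-" | msa == "N"
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- !gap[i, ] & !gap[j, ]
      p <- if (any(ok)) mean(msa[i, ok] == msa[j, ok]) else 0
      D[i, j] <- D[j, i] <- 1 - p
    }
  }
  D
}

#' Select representative target sequences per gene by k-medoids
#'
#' Finds the smallest k <= `max_k` such that PAM k-medoids clustering covers
#' every sequence within `radius` (1 - proportion identical positions) of its
#' medoid; mirrors picking up to six references within 15% similarity of all
#' sequences.
#'
#' @param seqs Character matrix of aligned sequences for one gene, or a named
#'   list of such matrices (one per gene).
#' @param max_k Maximum number of medoids (default 6).
#' @param radius Coverage radius on the identity distance (default 0.15).
#' @param seed Integer seed (kept for interface stability; PAM is
#'   deterministic).
#' @return For one gene: list with `medoids` (sequence ids), `k`, `covered`
#'   (logical per sequence), `uncovered` (ids beyond `radius` at `max_k`).
#'   For a list input: a named list of such results (empty genes skipped,
#'   with a message).
#' @export
select_targets_kmedoids <- function(seqs, max_k = 6L, radius = 0.15,
                                    seed = 1L) {
  if (is.list(seqs)) {
    out <- list()
    for (g in names(seqs)) {
      if (is.null(seqs[[g]]) || nrow(seqs[[g]]) == 0L) {
        message("gene ", g, " has no sequences; skipped")
        next
      }
      out[[g]] <- select_targets_kmedoids(seqs[[g]], max_k, radius, seed)
    }
    return(out)
  }
  ids <- rownames(seqs)
  n <- length(ids)
  if (n == 0L) stop("no sequences")
  if (n == 1L) {
    return(list(medoids = ids, k = 1L, covered = stats::setNames(TRUE, ids),
                uncovered = character(0)))
  }
  D <- pairwise_identity_dist(seqs)
  for (k in seq_len(min(max_k, n))) {
    med_idx <- if (k == 1L) {
      which.min(colSums(D))
    } else if (k >= n) {
      seq_len(n)
    } else {
      fit <- cluster::pam(stats::as.dist(D), k = k, diss = TRUE)
      match(fit$medoids, ids)
    }
    med_idx <- sort(med_idx)  # ties broken toward lowest sequence id
    d_near <- apply(D[, med_idx, drop = FALSE], 1L, min)
    if (all(d_near <= radius) || k == min(max_k, n)) {
      covered <- stats::setNames(d_near <= radius, ids)
      return(list(medoids = ids[med_idx], k = k, covered = covered,
                  uncovered = ids[!covered]))
    }
  }
}
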