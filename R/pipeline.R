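# End-to-end orchestration of the two-track workflow on synthetic data:
# simulate -> recovery QC -> alignment QC -> gene trees + collapse ->
# quartet species tree (nuclear track) and concatenated ML (plastid track)
# -> penalized-likelihood dating -> Mk ancestral reconstruction -> discord.

#' Pipeline configuration
#'
#' Bundles the scenario (species tree, genes, degradation, optional
#' introgression) with every filtering and inference threshold. Defaults
#' follow the study's settings: paralog filter at 3, 2/3-median coverage
#' score, 1/3-median alignment filter, trimming at gt 0.1 / cons 35,
#' outlier tolerance 0.5, collapse at BS < 11, smoothing 0.01 (nuclear) and
#' 1e-6 (plastid).
#'
#' @param truth A `species_tree_truth` (e.g. from [simulate_species_tree()]
#'   or a [scenario_preset()]).
#' @param n_genes Nuclear loci to simulate.
#' @param sites Sites per nuclear locus.
#' @param rate_mean Median substitution rate (substitutions/site/My).
#' @param event Optional [introgression_event()].
#' @param plastid_follow Passed to [simulate_plastid_tree()].
#' @param n_plastid_partitions Plastid loci (partitions of the c-gene).
#' @param plastid_sites Sites per plastid partition.
#' @param missing_rate,truncation,paralog_rate Passed to
#'   [degrade_recovery()].
#' @param n_bootstrap Bootstrap replicates for gene and concatenated trees.
#' @param collapse_bs Collapse gene-tree bipartitions with BS strictly below
#'   this (default 11).
#' @param char_rate Mk transition rate for the floral-symmetry character.
#' @param prune_outgroup Prune outgroup tips before ancestral
#'   reconstruction.
#' @param smooth_nuc,smooth_pl Smoothing presets for the two dating tracks.
#' @param paralog_min,score_frac,msa_frac,gap_keep,cons_floor,alpha QC
#'   thresholds (see the respective functions).
#' @param seed Master seed; every stage derives its own stream from it.
#' @param out_dir Output directory (created).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(truth,
                            n_genes = 32L, sites = 350L, rate_mean = 2e-3,
                            event = NULL,
                            plastid_follow = "expected",
                            n_plastid_partitions = 6L, plastid_sites = 400L,
                            missing_rate = 0.1,
                            truncation = list(kind = "uniform",
                                              min = 0.5, max = 1),
                            paralog_rate = 0.02,
                            n_bootstrap = 30L, collapse_bs = 11,
                            char_rate = 0.005, prune_outgroup = TRUE,
                            smooth_nuc = 0.01, smooth_pl = 1e-6,
                            paralog_min = 3L, score_frac = 2 / 3,
                            msa_frac = 1 / 3, gap_keep = 0.1,
                            cons_floor = 35, alpha = 0.5,
                            seed = 1L, out_dir = tempfile("symcord_run_")) {
  stopifnot(inherits(truth, "species_tree_truth"))
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

#' Scenario presets
#'
#' `"baseline"`: the fixed 10-tip two-track scenario with no introgression;
#' nuclear and plastid histories agree, so the tracks should be congruent.
#' `"chloroplast_capture"`: the same species tree with a plastid-captured
#' introgression event (gamma = 0.9) moving the recipient clade (R1, R2)
#' next to the donor clade (C1, C2); only the plastid track follows it, so
#' the two tracks disagree by exactly that reattachment.
#'
#' The fixed topology is (((A)(R((C)(D))))(O)) with 2-tip clades and long
#' internal branches (2-10 coalescent units), i.e. mild ILS.
#'
#' @param name Preset name.
#' @param seed Master seed.
#' @param ... Overrides forwarded to [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
scenario_preset <- function(name = c("baseline", "chloroplast_capture"),
                            seed = 1L, ...) {
  name <- match.arg(name)
  txt <- paste0(
    "(((A1:10,A2:10):50,((R1:10,R2:10):40,((C1:10,C2:10):25,",
    "(D1:10,D2:10):25):15):10):20,(O1:30,O2:30):50);")
  truth <- species_tree_truth(ape::read.tree(text = txt), cu_per_my = 0.2)
  event <- if (name == "chloroplast_capture") {
    introgression_event(donor = c("C1", "C2"), recipient = c("R1", "R2"),
                        gamma = 0.9, time = 20, affects = "plastid")
  } else {
    NULL
  }
  pipeline_config(truth, event = event, seed = seed, ...)
}

derive_seed <- function(seed, offset) (seed * 97L + offset) %% 2147483647L

drop_gapped_rows <- function(m) {
  keep <- rowSums(m != "-") > 0L
  m[keep, , drop = FALSE]
}

#' Run the full two-track pipeline on a scenario
#'
#' Executes simulation, recovery QC, alignment QC, gene-tree inference with
#' bootstrap and collapsing, quartet species-tree estimation (nuclear
#' track), concatenated partitioned ML (plastid track),
#' penalized-likelihood dating of both, Mk ancestral reconstruction on both
#' chronograms, and discordance quantification; writes all artifacts plus a
#' JSON manifest into `cfg$out_dir`.
#'
#' @param cfg A [pipeline_config()].
#' @return List of class `pipeline_result` with components `truth`,
#'   `gene_trees`, `nuclear` (species-tree estimate, rooted tree,
#'   chronogram, asr), `plastid` (likewise), `discord`, `manifest`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  truth <- cfg$truth
  taxa <- truth$tree$tip.label
  outgroup <- grep("^O", taxa, value = TRUE)
  manifest <- list(seed = cfg$seed,
                   scenario = list(n_taxa = length(taxa),
                                   n_genes = cfg$n_genes,
                                   sites = cfg$sites,
                                   introgression = !is.null(cfg$event)))

  # --- simulate --------------------------------------------------------
  gt <- simulate_gene_trees(truth, cfg$n_genes, event = cfg$event,
                            seed = derive_seed(cfg$seed, 1L),
                            rate_mean = cfg$rate_mean)
  aln <- simulate_alignments(gt, cfg$sites, seed = derive_seed(cfg$seed, 2L))
  deg <- degrade_recovery(aln, missing_rate = cfg$missing_rate,
                          truncation = cfg$truncation,
                          paralog_rate = cfg$paralog_rate,
                          seed = derive_seed(cfg$seed, 3L))
  chars <- simulate_character(truth, cfg$char_rate,
                              seed = derive_seed(cfg$seed, 4L))
  ptree <- simulate_plastid_tree(truth, cfg$event,
                                 follow = cfg$plastid_follow,
                                 seed = derive_seed(cfg$seed, 5L))
  manifest$plastid_followed_introgression <- attr(ptree, "followed")

  # --- recovery QC -----------------------------------------------------
  qstats <- recovery_stats(deg$matrix)
  filt <- filter_genes(qstats, deg$matrix, paralog_min = cfg$paralog_min,
                       score_frac = cfg$score_frac)
  manifest$recovery <- list(genes_in = cfg$n_genes,
                            genes_retained = length(filt$retained),
                            removed = filt$log$gene)

  # --- alignment QC ----------------------------------------------------
  kept_seqs <- lapply(deg$seqs[filt$retained], drop_gapped_rows)
  kept_seqs <- kept_seqs[vapply(kept_seqs, nrow, integer(1)) >= 4L]
  astats <- lapply(kept_seqs, msa_stats)
  afilt <- filter_alignments(astats, frac = cfg$msa_frac)
  trimmed <- lapply(kept_seqs[afilt$retained], trim_alignment,
                    gap_keep = cfg$gap_keep, cons_floor = cfg$cons_floor)
  manifest$alignment <- list(genes_in = length(kept_seqs),
                             genes_retained = length(trimmed))
  if (length(trimmed) < 2L) stop("pipeline stage alignment_qc: fewer than 2 ",
                                 "genes survived filtering")

  # --- nuclear track ---------------------------------------------------
  gene_ml <- vector("list", length(trimmed))
  for (i in seq_along(trimmed)) {
    gene_ml[[i]] <- ml_gene_tree(trimmed[[i]], n_bootstrap = cfg$n_bootstrap,
                                 seed = derive_seed(cfg$seed, 100L + i))
  }
  names(gene_ml) <- names(trimmed)
  collapsed <- lapply(gene_ml, collapse_low_support,
                      threshold = cfg$collapse_bs)
  class(collapsed) <- "multiPhylo"
  est <- infer_species_tree(collapsed, mode = "auto",
                            seed = derive_seed(cfg$seed, 6L))
  nuc_concat <- concat_alignments(trimmed)
  nuc_brlen <- fixed_topology_brlens(est$tree, nuc_concat$matrix)
  nuc_rooted <- root_at_outgroup(nuc_brlen, outgroup)
  nuc_calib <- data.frame(label = "root", tip_a = "root", tip_b = NA,
                          min_age = max(truth$ages), max_age = max(truth$ages),
                          stringsAsFactors = FALSE)
  nuc_chrono <- date_tree(nuc_rooted, nuc_calib,
                          dating_config(smoothing = cfg$smooth_nuc,
                                        site_count = ncol(nuc_concat$matrix)),
                          seed = derive_seed(cfg$seed, 7L))
  nuc_asr_tree <- if (cfg$prune_outgroup) {
    prune_tips(nuc_chrono$tree, outgroup)
  } else {
    nuc_chrono$tree
  }
  nuc_fit <- fit_mk(nuc_asr_tree, chars$states)
  nuc_asr <- marginal_asr(nuc_asr_tree, chars$states, nuc_fit$rate)

  # --- plastid track ---------------------------------------------------
  set.seed(derive_seed(cfg$seed, 8L))
  p_trees <- rep(list(ptree), cfg$n_plastid_partitions)
  class(p_trees) <- "multiPhylo"
  names(p_trees) <- sprintf("ptd%02d", seq_len(cfg$n_plastid_partitions))
  attr(p_trees, "rates") <- stats::rlnorm(cfg$n_plastid_partitions,
                                          log(cfg$rate_mean), 0.3)
  p_aln <- simulate_alignments(p_trees, cfg$plastid_sites,
                               seed = derive_seed(cfg$seed, 9L))
  p_parts <- concat_alignments(p_aln)
  p_ml <- concat_ml(p_parts, n_bootstrap = cfg$n_bootstrap,
                    seed = derive_seed(cfg$seed, 10L))
  p_rooted <- root_at_outgroup(p_ml, outgroup)
  p_chrono <- date_tree(p_rooted, nuc_calib,
                        dating_config(smoothing = cfg$smooth_pl,
                                      site_count = ncol(p_parts$matrix)),
                        seed = derive_seed(cfg$seed, 11L))
  p_asr_tree <- if (cfg$prune_outgroup) prune_tips(p_chrono$tree, outgroup)
                else p_chrono$tree
  p_fit <- fit_mk(p_asr_tree, chars$states)
  p_asr <- marginal_asr(p_asr_tree, chars$states, p_fit$rate)

  # --- discordance -----------------------------------------------------
  dis <- clade_diff(nuc_rooted, p_rooted)
  ent <- entanglement(nuc_chrono$tree, p_chrono$tree, untangle = "step1side")
  manifest$discord <- list(rf = dis$rf, rf_normalized = dis$rf_normalized,
                           unique_to_nuclear = dis$unique_to_a,
                           unique_to_plastid = dis$unique_to_b,
                           entanglement = ent$entanglement)

  # --- artifacts -------------------------------------------------------
  write_newick(truth$tree, file.path(cfg$out_dir, "species_tree_true.nwk"))
  write_newick(gt, file.path(cfg$out_dir, "gene_trees_true.nwk"))
  write_newick(ptree, file.path(cfg$out_dir, "plastid_tree_true.nwk"))
  write_species_tree(est, file.path(cfg$out_dir, "nuclear_species_tree.nwk"))
  write_newick(nuc_chrono$tree, file.path(cfg$out_dir,
                                          "nuclear_chronogram.nwk"))
  write_newick(p_chrono$tree, file.path(cfg$out_dir, "plastid_chronogram.nwk"))
  utils::write.table(
    data.frame(taxon = names(chars$states), state = chars$states),
    file.path(cfg$out_dir, "character_states.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  manifest$config <- cfg_summary(cfg)
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  structure(list(truth = truth, gene_trees = gt, character = chars,
                 recovery = list(stats = qstats, filter = filt),
                 nuclear = list(estimate = est, rooted = nuc_rooted,
                                chronogram = nuc_chrono, asr = nuc_asr),
                 plastid = list(tree_true = ptree, ml = p_ml,
                                rooted = p_rooted, chronogram = p_chrono,
                                asr = p_asr),
                 discord = list(report = dis,
                                entanglement = ent$entanglement),
                 manifest = manifest, out_dir = cfg$out_dir),
            class = "pipeline_result")
}

cfg_summary <- function(cfg) {
  keep <- setdiff(names(cfg), c("truth", "event", "out_dir", "truncation"))
  out <- cfg[keep]
  out$truncation <- paste(unlist(cfg$truncation), collapse = ",")
  out$introgression <- if (is.null(cfg$event)) "none" else {
    paste0("donor=", paste(cfg$event$donor, collapse = "+"),
           ";recipient=", paste(cfg$event$recipient, collapse = "+"),
           ";gamma=", cfg$event$gamma, ";time=", cfg$event$time,
           ";affects=", cfg$event$affects)
  }
  out
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result:", ape::Ntip(x$truth$tree), "taxa;",
      length(x$gene_trees), "gene trees; discord RF =",
      x$discord$report$rf, "\n")
  cat("  artifacts in", x$out_dir, "\n")
  invisible(x)
}

#' Read a scenario configuration from YAML
#'
#' Lightweight front end for scripted runs: the YAML holds scalar overrides
#' for [scenario_preset()] / [pipeline_config()] (e.g. `preset`, `seed`,
#' `n_genes`, `sites`, `n_bootstrap`).
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_scenario <- function(path) {
  y <- yaml::read_yaml(path)
  preset <- y$preset %||% "baseline"
  y$preset <- NULL
  do.call(scenario_preset, c(list(name = preset), y))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
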