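#' Pipeline configuration
#'
#' Collects every tunable constant of the analysis in one list so a run's
#' provenance is a single serialisable object.
#'
#' @param window_up,window_down promoter window around the TSS in bp
#'   (defaults 450 upstream, 50 downstream).
#' @param n_up,n_down genes kept per direction when trimming ranked lists
#'   (defaults 75 and 75).
#' @param fdr_threshold FDR level for the enriched call (0.05).
#' @param avoided_threshold p-score above which a motif counts as avoided
#'   (0.25).
#' @param var_threshold signature variance filter on p-scores (0.08).
#' @param fold_threshold switching fold cutoff (15).
#' @param k_groups number of phenotype groups for k-means (3).
#' @param pca_load_threshold absolute PCA load cutoff (0.05).
#' @param ppi_min_score minimum interactome combined confidence (500).
#' @param both_strands scan both promoter strands (TRUE).
#' @param kmeans_seed,sam_seed seeds for the stochastic stages (1234).
#' @param n_permutations SAM permutations (1000).
#' @return a named list of class `pipeline_config`.
#' @export
pipeline_config <- function(window_up = 450L, window_down = 50L,
                            n_up = 75L, n_down = 75L,
                            fdr_threshold = 0.05, avoided_threshold = 0.25,
                            var_threshold = 0.08, fold_threshold = 15,
                            k_groups = 3L, pca_load_threshold = 0.05,
                            ppi_min_score = 500L, both_strands = TRUE,
                            kmeans_seed = 1234L, sam_seed = 1234L,
                            n_permutations = 1000L) {
  cfg <- list(window_up = window_up, window_down = window_down,
              n_up = n_up, n_down = n_down,
              fdr_threshold = fdr_threshold,
              avoided_threshold = avoided_threshold,
              var_threshold = var_threshold, fold_threshold = fold_threshold,
              k_groups = k_groups, pca_load_threshold = pca_load_threshold,
              ppi_min_score = ppi_min_score, both_strands = both_strands,
              kmeans_seed = kmeans_seed, sam_seed = sam_seed,
              n_permutations = n_permutations)
  if (any(vapply(cfg[1:12], function(v) is.numeric(v) && v < 0, logical(1))))
    stop("all thresholds must be non-negative")
  structure(cfg, class = c("pipeline_config", "list"))
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  for (n in names(x)) cat(sprintf("  %-20s %s\n", n, format(x[[n]])))
  invisible(x)
}

#' Enrichment profiles for a simulated panel
#'
#' Convenience driver used throughout testing: converts a
#' [simulate_panel()] result into per-sample enrichment profiles.  The
#' shared background universe is scanned once; each sample's target-set
#' promoters are scanned and appended, so background moments are computed
#' over universe plus set (as for a genome that contains the regulated
#' genes).
#'
#' @param panel a [simulate_panel()] result.
#' @param config a [pipeline_config()].
#' @param pseudocount,background forwarded to [to_scoring_matrix()].
#' @return named list of [profile_sample()] results.
#' @export
profile_panel <- function(panel, config = pipeline_config(),
                          pseudocount = 1, background = rep(0.25, 4)) {
  catalog <- lapply(panel$catalog, to_scoring_matrix,
                    background = background, pseudocount = pseudocount)
  bg_table <- scan_catalog(panel$background, catalog,
                           both_strands = config$both_strands)
  profiles <- lapply(panel$samples, function(s) {
    set_table <- scan_catalog(s$promoters, catalog,
                              both_strands = config$both_strands)
    st <- rbind(bg_table, set_table)
    class(st) <- class(bg_table)
    profile_sample(s$genes, st,
                   fdr_threshold = config$fdr_threshold,
                   avoided_threshold = config$avoided_threshold)
  })
  names(profiles) <- names(panel$samples)
  profiles
}

#' Run the full signature pipeline on a set of enrichment profiles
#'
#' Orchestrates signature assembly, filtering, ranking, clustering, PCA,
#' the SAM screen and (optionally) switching detection between two named
#' samples and the seeded network stage.
#'
#' @param profiles named list of [profile_sample()] results.
#' @param config a [pipeline_config()].
#' @param switch_pair optional character vector of two sample ids to compare
#'   for switching motifs.
#' @param interactome optional [load_interactome()] result; used with
#'   `sensors` when `switch_pair` is given, seeding the network with the
#'   switching motif names per direction.
#' @param sensors optional character vector of sensor proteins.
#' @return list with elements `signature`, `distance`, `dendrogram`,
#'   `groups`, `pca`, `sam`, and when requested `switching`, `network`,
#'   `sensor_report`; plus `config`.
#' @export
run_pipeline <- function(profiles, config = pipeline_config(),
                         switch_pair = NULL, interactome = NULL,
                         sensors = NULL) {
  sig <- assemble_signature(profiles)
  sig <- filter_motifs(sig, var_threshold = config$var_threshold)
  sig <- rank_transform(sig)
  D <- spearman_distance(sig)
  hc <- hcluster_signature(D)
  grp <- kmeans_classify(sig, k = config$k_groups, seed = config$kmeans_seed)
  pca <- signature_pca(sig)
  sam <- sam_multiclass(sig, grp, n_permutations = config$n_permutations,
                        seed = config$sam_seed)
  out <- list(signature = sig, distance = D, dendrogram = hc, groups = grp,
              pca = pca, sam = sam, config = config)
  if (!is.null(switch_pair)) {
    stopifnot(length(switch_pair) == 2L, all(switch_pair %in% sig$samples))
    mk <- function(sid) data.frame(motif_id = sig$motifs,
                                   p = sig$p[sid, ],
                                   rank = sig$ranks[sid, ],
                                   stringsAsFactors = FALSE)
    sw <- detect_switching(mk(switch_pair[1]), mk(switch_pair[2]),
                           fold_threshold = config$fold_threshold,
                           enrich_threshold = config$fdr_threshold,
                           avoided_threshold = config$avoided_threshold,
                           labels = switch_pair)
    sw <- annotate_switches(sw, sam = sam,
                            pca_high = high_load_motifs(
                              pca, config$pca_load_threshold))
    out$switching <- sw
    if (!is.null(interactome)) {
      seeds_a <- sw$motif_id[sw$direction == "enriched_in_A"]
      seeds_b <- sw$motif_id[sw$direction == "enriched_in_B"]
      net <- build_min_network(interactome, seeds_a, seeds_b,
                               sensors = sensors %||% character())
      out$network <- net
      out$sensor_report <- probe_sensors(net)
    }
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
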