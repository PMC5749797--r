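#' Reference phenotype switching score table
#'
#' Published enrichment p-scores and within-sample ranks for the 14
#' transcription factor motifs reported to switch between two fibroblast
#' aging phenotypes: energy restriction in quiescence (ERiQ, condition A)
#' and replicative senescence versus quiescence (condition B).  Each row
#' carries the leading motif identifier, the factor name, any variant motifs
#' reported alongside, the score and rank in each condition, the published
#' fold ratio, and the published SAM / PCA evidence flags.
#'
#' These values serve as a fixed desk-checkable input for
#' [detect_switching()]: running the detector on the score pairs with the
#' default thresholds (fold 15, enriched 0.05, avoided 0.25) must return all
#' 14 motifs, 8 enriched in ERiQ and 6 in senescence.  Note that the
#' published fold ratios were computed from unrounded scores, so for rows
#' with very small denominators they differ from ratios of the printed
#' (4-decimal) scores.
#'
#' @return list with `a` and `b` (data.frames `motif_id`, `name`, `p`,
#'   `rank` for ERiQ and senescence respectively), `labels`, and `table`
#'   (the full reference data.frame including `fold_published`,
#'   `flag_sam`, `flag_pca`, `variants`).
#' @export
reference_switch_scores <- function() {
  path <- system.file("extdata", "phenotype_switch_scores.tsv",
                      package = "tfsig", mustWork = TRUE)
  tab <- read.delim(path, stringsAsFactors = FALSE)
  list(a = data.frame(motif_id = tab$motif_id, name = tab$name,
                      p = tab$p_eriq, rank = tab$rank_eriq,
                      stringsAsFactors = FALSE),
       b = data.frame(motif_id = tab$motif_id, name = tab$name,
                      p = tab$p_senescence, rank = tab$rank_senescence,
                      stringsAsFactors = FALSE),
       labels = c("ERiQ", "senescence"),
       table = tab)
}
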