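#' Fold ratio between two enrichment p-scores
#'
#' The sign-less ratio `max(p_a, p_b) / min(p_a, p_b)` quantifying how
#' strongly a motif's enrichment score differs between two conditions.
#'
#' @param p_a,p_b strictly positive p-scores (scores are floored at machine
#'   precision upstream, so a zero is an input error).
#' @return numeric fold ratio (vectorised).
#' @export
fold_ratio <- function(p_a, p_b) {
  if (any(p_a <= 0) || any(p_b <= 0))
    stop("p-scores must be strictly positive")
  pmax(p_a, p_b) / pmin(p_a, p_b)
}

#' Detect motifs switching between enrichment and avoidance
#'
#' Compares the enrichment profiles of two conditions and returns the motifs
#' that are enriched in one (p-score below `enrich_threshold`) while avoided
#' in the other (p-score above `avoided_threshold`), with an opposing fold
#' change in scores greater than `fold_threshold` and a change in
#' within-sample rank.  Motifs enriched in both conditions are removed
#' first.  Results are sorted by descending fold.
#'
#' @param profile_a,profile_b data.frames with columns `motif_id`, `p`,
#'   `rank` (and optionally `name`); an [profile_sample()] result works once
#'   a `rank` column is attached (e.g. from the ranked signature).  The two
#'   profiles must cover the same motif universe.
#' @param fold_threshold minimum opposing fold change, strict, on the
#'   unrounded ratio (default 15).
#' @param enrich_threshold enrichment p-score cutoff (default 0.05).
#' @param avoided_threshold avoidance p-score cutoff (default 0.25).
#' @param labels length-2 character vector naming conditions A and B (used
#'   in the `direction` column).
#' @return data.frame of class `switch_table`, one row per switching motif:
#'   `motif_id`, `name`, `p_a`, `p_b`, `rank_a`, `rank_b`, `fold`,
#'   `direction` (`"enriched_in_A"` / `"enriched_in_B"`), `flagged_sam`,
#'   `flagged_pca` (both `NA` until [annotate_switches()]).
#' @export
detect_switching <- function(profile_a, profile_b, fold_threshold = 15,
                             enrich_threshold = 0.05, avoided_threshold = 0.25,
                             labels = c("A", "B")) {
  a <- .as_switch_profile(profile_a)
  b <- .as_switch_profile(profile_b)
  extra_a <- setdiff(a$motif_id, b$motif_id)
  extra_b <- setdiff(b$motif_id, a$motif_id)
  if (length(extra_a) || length(extra_b))
    stop("profiles cover different motif universes; only in A: [",
         paste(extra_a, collapse = ", "), "], only in B: [",
         paste(extra_b, collapse = ", "), "]")
  b <- b[match(a$motif_id, b$motif_id), ]

  both_enriched <- a$p < enrich_threshold & b$p < enrich_threshold
  fold <- fold_ratio(a$p, b$p)
  keep <- !both_enriched &
    pmin(a$p, b$p) < enrich_threshold &
    pmax(a$p, b$p) > avoided_threshold &
    fold > fold_threshold &
    a$rank != b$rank
  out <- data.frame(
    motif_id = a$motif_id[keep],
    name = a$name[keep],
    p_a = a$p[keep], p_b = b$p[keep],
    rank_a = a$rank[keep], rank_b = b$rank[keep],
    fold = fold[keep],
    direction = ifelse(a$p[keep] < b$p[keep], "enriched_in_A", "enriched_in_B"),
    flagged_sam = NA, flagged_pca = NA,
    stringsAsFactors = FALSE)
  out <- out[order(-out$fold), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "labels") <- labels
  attr(out, "thresholds") <- c(fold = fold_threshold, enrich = enrich_threshold,
                               avoided = avoided_threshold)
  class(out) <- c("switch_table", class(out))
  out
}

.as_switch_profile <- function(pr) {
  pr <- as.data.frame(pr)
  need <- c("motif_id", "p", "rank")
  if (!all(need %in% names(pr)))
    stop("switching profile needs columns: ", paste(need, collapse = ", "))
  if (!"name" %in% names(pr)) pr$name <- ""
  pr[, c("motif_id", "name", "p", "rank")]
}

#' Annotate switching motifs with SAM and PCA-load evidence
#'
#' @param records a [detect_switching()] result.
#' @param sam a [sam_multiclass()] result (or `NULL`).
#' @param pca_high character vector from [high_load_motifs()] (or `NULL`).
#' @return `records` with `flagged_sam` / `flagged_pca` filled in.
#' @export
annotate_switches <- function(records, sam = NULL, pca_high = NULL) {
  if (!is.null(sam)) {
    sig <- sam$motif_id[sam$significant]
    records$flagged_sam <- records$motif_id %in% sig
  }
  if (!is.null(pca_high)) records$flagged_pca <- records$motif_id %in% pca_high
  records
}

#' @export
print.switch_table <- function(x, ...) {
  lab <- attr(x, "labels")
  thr <- attr(x, "thresholds")
  cat(sprintf("<switch_table> %d switching motifs (A = %s, B = %s; fold > %g, enriched < %g, avoided > %g)\n",
              nrow(x), lab[1], lab[2], thr["fold"], thr["enrich"], thr["avoided"]))
  df <- as.data.frame(x)
  df$fold <- signif(df$fold, 3)
  print.data.frame(df, digits = 4)
  invisible(x)
}

#' Write a switching-motif table as TSV
#'
#' Columns mirror the reporting convention: id, score (rank) in each
#' condition, fold, evidence flags.
#' @param x a `switch_table`.
#' @param path output path.
#' @export
write_switch_table <- function(x, path) {
  write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
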