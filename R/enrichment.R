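#' Trim a ranked differential-expression list to a sign-less gene set
#'
#' Reduces any upstream differential-expression ranking to its most extreme
#' genes: the `n_up` largest positive statistics (up-regulated) and the
#' `n_down` most negative (down-regulated), pooled into one sign-less target
#' set.  Ties on the statistic are broken lexicographically by gene id, so
#' the trim is deterministic.
#'
#' @param ranked data.frame with columns `gene_id` and `stat` (a signed
#'   ranking statistic: fold change, regression coefficient, ...).
#' @param n_up,n_down number of up- / down-regulated genes to keep
#'   (defaults 75 and 75, i.e. a 150-gene set).
#' @return object of class `gene_set`: list with `sample_id`, `up`, `down`.
#' @param sample_id label carried through to the enrichment profile.
#' @export
trim_ranked_list <- function(ranked, n_up = 75L, n_down = 75L,
                             sample_id = "sample") {
  stopifnot(all(c("gene_id", "stat") %in% names(ranked)))
  if (anyDuplicated(ranked$gene_id)) stop("duplicate gene ids in ranked list")
  if (n_up + n_down == 0L) stop("empty set requested (n_up = n_down = 0)")
  pos <- ranked[ranked$stat > 0, , drop = FALSE]
  neg <- ranked[ranked$stat < 0, , drop = FALSE]
  if (nrow(pos) < n_up || nrow(neg) < n_down)
    stop("insufficient genes: ", nrow(pos), " up-regulated (need ", n_up,
         "), ", nrow(neg), " down-regulated (need ", n_down, ")")
  pos <- pos[order(-pos$stat, pos$gene_id), , drop = FALSE]
  neg <- neg[order(neg$stat, neg$gene_id), , drop = FALSE]
  gene_set(sample_id,
           up = pos$gene_id[seq_len(n_up)],
           down = neg$gene_id[seq_len(n_down)])
}

#' @rdname trim_ranked_list
#' @param up,down character vectors of gene ids.
#' @export
gene_set <- function(sample_id, up, down) {
  genes <- c(up, down)
  if (anyDuplicated(genes))
    stop("gene set '", sample_id, "': duplicated gene ids across up/down")
  structure(list(sample_id = sample_id, up = up, down = down),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("<gene_set> %s: %d up + %d down = %d genes\n",
              x$sample_id, length(x$up), length(x$down),
              length(x$up) + length(x$down)))
  invisible(x)
}

#' z-test for motif over-/under-representation
#'
#' Compares the mean best-hit score of a gene set against the moments of the
#' genomic background score distribution:
#' \deqn{z = \frac{\bar x - \mu_{bg}}{\sigma_{bg}/\sqrt n}, \qquad
#'       p = P(Z > z)}
#' One-sided upper-tail, so over-represented (enriched) motifs get small p
#' and under-represented (avoided) motifs get p near 1.
#'
#' @param set_scores numeric vector of best-hit scores for the gene set
#'   (length at least 2).
#' @param bg_mean,bg_sd background mean and standard deviation (`bg_sd > 0`).
#' @return list with elements `z` and `p`.
#' @export
ztest_enrichment <- function(set_scores, bg_mean, bg_sd) {
  set_scores <- set_scores[!is.na(set_scores)]
  n <- length(set_scores)
  if (n < 2L) stop("need at least 2 set scores")
  if (!is.finite(bg_sd) || bg_sd <= 0) stop("degenerate background (bg_sd <= 0)")
  z <- (mean(set_scores) - bg_mean) / (bg_sd / sqrt(n))
  # floor at the smallest normal double so downstream fold ratios stay finite
  list(z = z, p = max(pnorm(z, lower.tail = FALSE), .Machine$double.xmin))
}

#' Per-sample motif enrichment profile
#'
#' For every motif column of the score table, computes the background mean
#' and (population) standard deviation over the whole gene universe, the gene
#' set mean, the z statistic and one-sided p-score from [ztest_enrichment()],
#' Benjamini-Hochberg q-values across the motifs of this sample, and the
#' enriched (`fdr_q < fdr_threshold`) / avoided (`p > avoided_threshold`)
#' flags.
#'
#' @param gs a [gene_set()] or a character vector of gene ids.
#' @param st a `score_table` over the gene universe (must contain the set
#'   genes; missing genes are dropped with a warning).
#' @param fdr_threshold FDR level for the enriched call (default 0.05).
#' @param avoided_threshold p-score above which a motif is flagged avoided
#'   (default 0.25).
#' @param sample_id label; defaults to the gene set's.
#' @return data.frame of class `enrichment_profile` with one row per motif:
#'   `motif_id`, `set_mean`, `bg_mean`, `bg_sd`, `n_set`, `z`, `p`, `fdr_q`,
#'   `enriched`, `avoided`.
#' @export
profile_sample <- function(gs, st, fdr_threshold = 0.05,
                           avoided_threshold = 0.25, sample_id = NULL) {
  if (inherits(gs, "gene_set")) {
    if (is.null(sample_id)) sample_id <- gs$sample_id
    genes <- c(gs$up, gs$down)
  } else {
    genes <- gs
    if (is.null(sample_id)) sample_id <- "sample"
  }
  missing <- setdiff(genes, rownames(st))
  if (length(missing)) {
    warning("dropping ", length(missing),
            " set gene(s) absent from the score table")
    genes <- setdiff(genes, missing)
  }
  if (length(genes) < 2L) stop("fewer than 2 set genes present in score table")
  if (nrow(st) < 10L * length(genes))
    warning("gene universe (", nrow(st), ") is less than 10x the set size (",
            length(genes), "); background moments may be unstable")
  sub <- st[genes, , drop = FALSE]
  res <- lapply(colnames(st), function(m) {
    bg <- st[, m]
    bg <- bg[!is.na(bg)]
    set <- sub[, m]
    set <- set[!is.na(set)]
    zt <- ztest_enrichment(set, mean(bg), .pop_sd(bg))
    data.frame(motif_id = m, set_mean = mean(set), bg_mean = mean(bg),
               bg_sd = .pop_sd(bg), n_set = length(set),
               z = zt$z, p = zt$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$fdr_q <- p.adjust(out$p, method = "BH")
  out$enriched <- out$fdr_q < fdr_threshold
  out$avoided <- out$p > avoided_threshold
  attr(out, "sample_id") <- sample_id
  attr(out, "fdr_threshold") <- fdr_threshold
  attr(out, "avoided_threshold") <- avoided_threshold
  class(out) <- c("enrichment_profile", class(out))
  out
}

#' @export
print.enrichment_profile <- function(x, ...) {
  cat(sprintf("<enrichment_profile> sample '%s': %d motifs, %d enriched (FDR < %g), %d avoided (p > %g)\n",
              attr(x, "sample_id"), nrow(x), sum(x$enriched), attr(x, "fdr_threshold"),
              sum(x$avoided), attr(x, "avoided_threshold")))
  print.data.frame(head(as.data.frame(x)[order(x$p), ], 10L), digits = 3)
  invisible(x)
}
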