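#' Assemble a samples-by-motifs signature matrix
#'
#' Stacks per-sample enrichment profiles into a matrix of p-scores on the
#' intersection of their motif sets.  Motifs absent from any profile are
#' dropped with a warning.
#'
#' @param profiles list of [profile_sample()] results (at least 2).
#' @return object of class `signature_matrix`: list with `p` (S x M p-score
#'   matrix), `enriched` (S x M logical), `ranks` (`NULL` until
#'   [rank_transform()]), `samples`, `motifs` and a `provenance` list.
#' @export
assemble_signature <- function(profiles) {
  if (length(profiles) < 2L) stop("need at least 2 enrichment profiles")
  ids <- vapply(profiles, function(p) attr(p, "sample_id"), "")
  if (anyDuplicated(ids)) stop("duplicate sample ids: ",
                               paste(ids[duplicated(ids)], collapse = ", "))
  motif_sets <- lapply(profiles, `[[`, "motif_id")
  common <- Reduce(intersect, motif_sets)
  if (length(common) == 0L) stop("profiles share no motifs")
  dropped <- setdiff(unique(unlist(motif_sets)), common)
  if (length(dropped))
    warning("dropping ", length(dropped),
            " motif(s) missing from at least one profile")
  p <- t(vapply(profiles, function(pr) {
    pr$p[match(common, pr$motif_id)]
  }, numeric(length(common))))
  enr <- t(vapply(profiles, function(pr) {
    pr$enriched[match(common, pr$motif_id)]
  }, logical(length(common))))
  dimnames(p) <- dimnames(enr) <- list(ids, common)
  structure(list(p = p, enriched = enr, ranks = NULL,
                 samples = ids, motifs = common,
                 provenance = list(n_motifs_input = length(common),
                                   dropped_not_shared = dropped)),
            class = "signature_matrix")
}

#' Filter signature motifs by significance and variance
#'
#' Retains a motif only if (i) it is enriched (sample-level FDR call) in at
#' least one sample and (ii) the population variance of its p-scores across
#' samples exceeds `var_threshold`.  Motifs that never reach significance
#' anywhere carry no phenotype information; near-constant motifs do not
#' discriminate samples.  The removed fractions are recorded in the
#' provenance.
#'
#' @param sm a [assemble_signature()] result.
#' @param var_threshold variance cutoff on p-scores (default 0.08; p-scores
#'   live in `[0, 1]` so the maximum attainable variance is 0.25).
#' @return filtered `signature_matrix` (motif order preserved).
#' @export
filter_motifs <- function(sm, var_threshold = 0.08) {
  stopifnot(inherits(sm, "signature_matrix"))
  sig <- apply(sm$enriched, 2, any)
  if (!any(sig))
    stop("no motif is significant in any sample; ",
         "lower the FDR threshold upstream or check the inputs")
  v <- apply(sm$p, 2, .pop_var)
  keep <- sig & v > var_threshold
  if (!any(keep))
    stop("all motifs filtered out; consider lowering var_threshold (",
         var_threshold, ")")
  out <- sm
  out$p <- sm$p[, keep, drop = FALSE]
  out$enriched <- sm$enriched[, keep, drop = FALSE]
  out$motifs <- sm$motifs[keep]
  out$ranks <- NULL
  out$provenance$var_threshold <- var_threshold
  out$provenance$removed_not_significant <- sum(!sig)
  out$provenance$frac_removed_not_significant <- mean(!sig)
  out$provenance$removed_low_variance <- sum(sig & v <= var_threshold)
  out
}

#' Rank-transform a signature matrix within samples
#'
#' Replaces each sample's p-scores by their within-sample ranks (rank 1 = the
#' most enriched motif; ties get midranks).  Ranks are invariant under any
#' strictly increasing transform of the scores, which is what makes
#' signatures comparable across platforms and study designs.
#'
#' @param sm a `signature_matrix`.
#' @return the matrix with `ranks` populated.
#' @export
rank_transform <- function(sm) {
  stopifnot(inherits(sm, "signature_matrix"))
  r <- t(apply(sm$p, 1, rank, ties.method = "average"))
  dimnames(r) <- dimnames(sm$p)
  sm$ranks <- r
  sm
}

#' @export
print.signature_matrix <- function(x, ...) {
  cat(sprintf("<signature_matrix> %d samples x %d motifs%s\n",
              length(x$samples), length(x$motifs),
              if (is.null(x$ranks)) " (p-scores only)" else " (ranked)"))
  if (!is.null(x$provenance$frac_removed_not_significant))
    cat(sprintf("  filtered: %d never-significant (%.0f%%), %d low-variance (Var <= %g)\n",
                x$provenance$removed_not_significant,
                100 * x$provenance$frac_removed_not_significant,
                x$provenance$removed_low_variance,
                x$provenance$var_threshold))
  invisible(x)
}

#' @method summary signature_matrix
#' @export
summary.signature_matrix <- function(object, ...) {
  cat(sprintf("signature matrix: %d samples, %d motifs\n",
              length(object$samples), length(object$motifs)))
  cat("p-score range: [", format(min(object$p), digits = 3), ", ",
      format(max(object$p), digits = 3), "]\n", sep = "")
  cat("enriched calls per sample:\n")
  print(rowSums(object$enriched))
  invisible(object)
}

#' Persist a signature matrix
#'
#' Writes `p_scores.tsv`, `ranks.tsv` (if ranked) and a `provenance.json`
#' sidecar of filter settings into `dir`.
#'
#' @param sm a `signature_matrix`.
#' @param dir output directory (created if needed).
#' @export
write_signature <- function(sm, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(m, f) {
    df <- data.frame(sample_id = rownames(m), as.data.frame(m),
                     check.names = FALSE)
    write.table(df, file.path(dir, f), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  wr(sm$p, "p_scores.tsv")
  if (!is.null(sm$ranks)) wr(sm$ranks, "ranks.tsv")
  jsonlite::write_json(sm$provenance, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
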