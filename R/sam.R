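#' Multiclass SAM screen of signature motifs
#'
#' A significance-analysis-of-microarrays style screen for motifs whose rank
#' differs between phenotype groups.  Per motif the statistic is
#' \deqn{d_j = \frac{\sqrt{\sum_k n_k (\bar x_{kj} - \bar x_j)^2}}{s_j + s_0}}
#' i.e. the square root of the between-group sum of squares over a
#' regularised pooled standard error
#' \eqn{s_j = \sqrt{\hat\sigma^2_j \sum_k 1/n_k}} with
#' \eqn{\hat\sigma^2_j} the pooled within-group variance, and the fudge
#' factor \eqn{s_0} set to the median of the per-motif standard errors.
#' False discovery rates come from permuting group labels: the q-value of a
#' motif is the median number of permuted statistics exceeding its observed
#' statistic divided by the observed count at that level, made monotone and
#' capped at 1.
#'
#' @param sm rank-transformed [signature_matrix()] (or numeric samples x
#'   motifs matrix).
#' @param groups a [kmeans_classify()] result or a (named) vector of group
#'   labels; every group needs at least 2 samples.
#' @param n_permutations number of label permutations (default 1000).
#' @param seed RNG seed for the permutations (default 1234).
#' @param q_threshold significance level on the q-value (default 0.05).
#' @return data.frame of class `sam_result` with columns `motif_id`, `d`,
#'   `q`, `significant`.
#' @export
sam_multiclass <- function(sm, groups, n_permutations = 1000L, seed = 1234L,
                           q_threshold = 0.05) {
  x <- .signature_ranks(sm)
  if (inherits(groups, "phenotype_grouping")) groups <- groups$assignments
  if (!is.null(names(groups))) groups <- groups[rownames(x)]
  groups <- as.integer(factor(groups))
  if (anyNA(groups)) stop("group labels do not cover all samples")
  sizes <- tabulate(groups)
  if (length(sizes) < 2L) stop("need at least 2 groups")
  if (any(sizes < 2L)) stop("every group needs at least 2 samples")

  d_obs <- .sam_stat(x, groups)
  set.seed(seed)
  d_perm <- vapply(seq_len(n_permutations),
                   function(b) .sam_stat(x, sample(groups)),
                   numeric(ncol(x)))

  # SAM-style FDR: for each observed d, median over permutations of the
  # count of permuted statistics >= d, over the observed count >= d.
  q <- vapply(seq_along(d_obs), function(j) {
    thr <- d_obs[j]
    n_obs <- sum(d_obs >= thr)
    exceed <- colSums(d_perm >= thr)
    min(stats::median(exceed) / n_obs, 1)
  }, 0)
  # enforce monotonicity: a larger d never gets a larger q
  ord <- order(d_obs, decreasing = TRUE)
  q[ord] <- cummax(q[ord])

  out <- data.frame(motif_id = colnames(x), d = d_obs, q = q,
                    significant = q < q_threshold,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("sam_result", class(out))
  attr(out, "n_permutations") <- n_permutations
  out
}

.sam_stat <- function(x, groups) {
  n <- nrow(x)
  K <- max(groups)
  sizes <- tabulate(groups, K)
  grand <- colMeans(x)
  bss <- numeric(ncol(x))
  wss <- numeric(ncol(x))
  for (k in seq_len(K)) {
    xk <- x[groups == k, , drop = FALSE]
    mk <- colMeans(xk)
    bss <- bss + sizes[k] * (mk - grand)^2
    wss <- wss + colSums(sweep(xk, 2, mk)^2)
  }
  s2 <- wss / (n - K)                       # pooled within-group variance
  se <- sqrt(s2 * sum(1 / sizes))           # pooled standard error
  s0 <- stats::median(se)
  sqrt(bss) / (se + s0)
}

#' @export
print.sam_result <- function(x, ...) {
  cat(sprintf("<sam_result> %d motifs, %d significant (q < 0.05), %d permutations\n",
              nrow(x), sum(x$significant), attr(x, "n_permutations")))
  print.data.frame(head(as.data.frame(x)[order(-x$d), ], 10L), digits = 3)
  invisible(x)
}
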