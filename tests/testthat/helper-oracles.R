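# Independent oracles used across tests. These deliberately avoid the
# package's scanning/scoring code paths: log-odds are recomputed from first
# principles and windows are enumerated with explicit loops.

oracle_best_score <- function(seq, m, background = rep(0.25, 4),
                              pseudocount = 1, both_strands = TRUE) {
  bases <- c("A", "C", "G", "T")
  bg <- background / sum(background)
  counts <- m$counts
  L <- nrow(counts)
  lo <- matrix(0, L, 4)
  for (i in seq_len(L)) for (b in 1:4) {
    lo[i, b] <- log(((counts[i, b] + pseudocount * bg[b]) /
                       (sum(counts[i, ]) + pseudocount)) / bg[b])
  }
  score_strand <- function(s) {
    ch <- strsplit(toupper(s), "")[[1]]
    best <- -Inf
    for (w in seq_len(length(ch) - L + 1)) {
      tot <- 0
      for (i in seq_len(L)) {
        b <- match(ch[w + i - 1], bases)
        tot <- tot + if (is.na(b)) sum(bg * lo[i, ]) else lo[i, b]
      }
      if (tot > best) best <- tot
    }
    best
  }
  rc <- function(s) {
    ch <- strsplit(toupper(s), "")[[1]]
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    out <- rev(ifelse(ch %in% bases, comp[ch], "N"))
    paste(out, collapse = "")
  }
  raw <- score_strand(seq)
  if (both_strands) raw <- max(raw, score_strand(rc(seq)))
  smin <- sum(apply(lo, 1, min))
  smax <- sum(apply(lo, 1, max))
  (raw - smin) / (smax - smin)
}

# Hubert & Arabie adjusted Rand index, from the contingency table.
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

random_dna_seq <- function(length, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), length, replace = TRUE, prob = p),
        collapse = "")
}

# Minimal hand-built enrichment profile for signature-level tests.
fake_profile <- function(sample_id, motif_ids, p, enriched = p < 0.05) {
  out <- data.frame(motif_id = motif_ids, p = p, enriched = enriched,
                    stringsAsFactors = FALSE)
  attr(out, "sample_id") <- sample_id
  attr(out, "fdr_threshold") <- 0.05
  attr(out, "avoided_threshold") <- 0.25
  class(out) <- c("enrichment_profile", class(out))
  out
}
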