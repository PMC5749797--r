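#' Construct a promoter set
#'
#' Gene-keyed promoter sequences on a fixed window relative to the
#' transcription start site, already oriented in the direction of
#' transcription.
#'
#' @param sequences named character vector (names are unique gene ids) of
#'   sequences over A,C,G,T,N (IUPAC ambiguity codes tolerated).
#' @param window_up bp upstream of the TSS included in each window.
#' @param window_down bp downstream of the TSS included.
#' @return object of class `promoter_set`.
#' @export
promoter_set <- function(sequences, window_up = 450L, window_down = 50L) {
  if (is.null(names(sequences)) || anyDuplicated(names(sequences)))
    stop("promoter sequences must carry unique gene ids as names")
  len <- window_up + window_down
  bad <- nchar(sequences) != len
  if (any(bad))
    stop(sum(bad), " promoter(s) do not have length window_up + window_down = ", len)
  structure(list(sequences = sequences,
                 window_up = as.integer(window_up),
                 window_down = as.integer(window_down)),
            class = "promoter_set")
}

#' @export
print.promoter_set <- function(x, ...) {
  cat(sprintf("<promoter_set> %d genes, window -%d..+%d bp around TSS\n",
              length(x$sequences), x$window_up, x$window_down))
  invisible(x)
}

#' @export
length.promoter_set <- function(x) length(x$sequences)

#' Extract strand-aware promoter windows from a genome
#'
#' For a plus-strand gene the window is `[tss - window_up, tss + window_down)`
#' (0-based, half-open); for a minus-strand gene the reverse complement of
#' `[tss - window_down, tss + window_up)`, so every returned sequence reads in
#' the direction of transcription.  TSS tables are commonly 1-based; set
#' `one_based = FALSE` if positions are already 0-based.
#'
#' @param genome a named character vector of chromosome sequences, a
#'   `Biostrings::DNAStringSet`, or a path to a FASTA file.
#' @param tss data.frame with columns `gene_id`, `chrom`, `tss`, `strand`
#'   (`"+"`/`"-"`), or a path to such a TSV.
#' @param window_up,window_down window extent in bp (defaults 450 and 50).
#' @param one_based logical; are `tss` positions 1-based? Default `TRUE`.
#' @return a [promoter_set()]. Genes whose window runs off the contig are
#'   skipped with a warning; an unknown chromosome is an error.
#' @export
extract_promoters <- function(genome, tss, window_up = 450L, window_down = 50L,
                              one_based = TRUE) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome))
    genome <- Biostrings::readDNAStringSet(genome)
  if (inherits(genome, "DNAStringSet")) {
    nm <- sub("\\s.*$", "", names(genome))
    genome <- setNames(as.character(genome), nm)
  }
  if (is.character(tss) && length(tss) == 1L)
    tss <- read.delim(tss, stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "tss", "strand")
  if (!all(need %in% names(tss)))
    stop("TSS table must have columns: ", paste(need, collapse = ", "))
  unknown <- setdiff(unique(tss$chrom), names(genome))
  if (length(unknown))
    stop("chromosome(s) not in genome: ", paste(unknown, collapse = ", "))

  out <- character(0)
  skipped <- character(0)
  for (i in seq_len(nrow(tss))) {
    chrom <- genome[[tss$chrom[i]]]
    pos0 <- tss$tss[i] - if (one_based) 1L else 0L
    if (tss$strand[i] == "+") {
      start0 <- pos0 - window_up; end0 <- pos0 + window_down
    } else if (tss$strand[i] == "-") {
      start0 <- pos0 - window_down; end0 <- pos0 + window_up
    } else stop("strand must be '+' or '-' (gene ", tss$gene_id[i], ")")
    if (start0 < 0L || end0 > nchar(chrom)) {
      skipped <- c(skipped, tss$gene_id[i]); next
    }
    s <- substr(chrom, start0 + 1L, end0)  # 0-based half-open -> R substr
    if (tss$strand[i] == "-") s <- .revcomp(s)
    out[tss$gene_id[i]] <- s
  }
  if (length(skipped))
    warning("skipped ", length(skipped),
            " gene(s) whose window extends past a contig boundary: ",
            paste(head(skipped, 5L), collapse = ", "),
            if (length(skipped) > 5L) ", ...")
  promoter_set(out, window_up, window_down)
}

# raw best window score of an encoded sequence against one scoring matrix
.best_raw_codes <- function(codes, sm, both_strands = TRUE) {
  L <- nrow(sm$logodds)
  lo5 <- cbind(sm$logodds, sm$ambig)  # column 5 scores ambiguity codes
  score_strand <- function(cv) {
    W <- length(cv) - L + 1L
    tot <- numeric(W)
    for (i in seq_len(L)) tot <- tot + lo5[i, cv[i:(i + W - 1L)]]
    max(tot)
  }
  best <- score_strand(codes)
  if (both_strands) best <- max(best, score_strand(.revcomp_codes(codes)))
  best
}

#' Best normalized motif match score of a sequence
#'
#' The PSCAN-style per-gene statistic: the maximum summed log-odds over all
#' windows of the sequence (and of its reverse complement when
#' `both_strands`), min-max normalized by the matrix's attainable score range
#' so that 1 means a perfect consensus site and 0 the worst possible window.
#'
#' @param seq character sequence (length must be at least the motif length).
#' @param sm a [to_scoring_matrix()] result.
#' @param both_strands scan the reverse complement too? Default `TRUE`.
#' @return numeric scalar in `[0, 1]`.
#' @export
best_site_score <- function(seq, sm, both_strands = TRUE) {
  stopifnot(inherits(sm, "scoring_matrix"))
  if (sm$degenerate)
    stop("motif '", sm$motif_id,
         "' is degenerate (score_max == score_min); cannot normalize")
  L <- nrow(sm$logodds)
  if (nchar(seq) < L)
    stop("sequence (", nchar(seq), " bp) shorter than motif '",
         sm$motif_id, "' (", L, " bp)")
  raw <- .best_raw_codes(.encode_seq(seq), sm, both_strands)
  min(max((raw - sm$score_min) / (sm$score_max - sm$score_min), 0), 1)
}

#' Scan a promoter set against a motif catalog
#'
#' Computes the [best_site_score()] of every promoter against every
#' non-degenerate scoring matrix.  Degenerate matrices are dropped with a
#' warning.  Promoters with more than `max_n_frac` ambiguous bases get `NA`
#' for all motifs (and are dropped from gene sets downstream); a promoter
#' shorter than a motif gets `NA` for that motif.
#'
#' @param p a [promoter_set()] (or named character vector of sequences).
#' @param catalog list of `scoring_matrix` objects (a single one is accepted).
#' @param both_strands scan both strands? Default `TRUE`.
#' @param max_n_frac maximum tolerated fraction of ambiguous bases per
#'   promoter (default 0.1).
#' @return a genes x motifs numeric matrix of class `score_table`.
#' @export
scan_catalog <- function(p, catalog, both_strands = TRUE, max_n_frac = 0.1) {
  if (inherits(p, "promoter_set")) p <- p$sequences
  if (length(p) == 0L) stop("empty promoter set")
  if (inherits(catalog, "scoring_matrix")) catalog <- list(catalog)
  if (length(catalog) == 0L) stop("empty motif catalog")
  degen <- vapply(catalog, function(s) s$degenerate, logical(1))
  if (any(degen)) {
    warning("dropping ", sum(degen), " degenerate motif(s): ",
            paste(vapply(catalog[degen], `[[`, "", "motif_id"), collapse = ", "))
    catalog <- catalog[!degen]
  }
  if (length(catalog) == 0L) stop("all motifs in the catalog are degenerate")
  codes <- lapply(p, .encode_seq)
  n_frac <- vapply(codes, function(cv) mean(cv == 5L), 0)
  masked <- n_frac > max_n_frac
  if (any(masked))
    warning(sum(masked), " promoter(s) exceed ", max_n_frac * 100,
            "% ambiguous bases and are recorded as missing")
  st <- matrix(NA_real_, nrow = length(p), ncol = length(catalog),
               dimnames = list(names(p),
                               vapply(catalog, `[[`, "", "motif_id")))
  for (j in seq_along(catalog)) {
    sm <- catalog[[j]]
    rng <- sm$score_max - sm$score_min
    L <- nrow(sm$logodds)
    for (g in seq_along(codes)) {
      if (masked[g] || length(codes[[g]]) < L) next
      raw <- .best_raw_codes(codes[[g]], sm, both_strands)
      st[g, j] <- min(max((raw - sm$score_min) / rng, 0), 1)
    }
  }
  class(st) <- c("score_table", class(st))
  st
}

#' Write / read a score table as TSV
#'
#' Gene rows, motif columns, `gene_id` as the first column.
#' @param st a `score_table` matrix.
#' @param path file path.
#' @export
write_score_table <- function(st, path) {
  df <- data.frame(gene_id = rownames(st), as.data.frame(unclass(st)),
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_score_table
#' @export
read_score_table <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  st <- as.matrix(df[, -1, drop = FALSE])
  rownames(st) <- df[[1]]
  class(st) <- c("score_table", class(st))
  st
}
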