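#' Construct a motif count matrix
#'
#' A `motif_matrix` holds one transcription factor binding specificity as an
#' L-by-4 position frequency matrix (PFM) over the fixed alphabet A, C, G, T.
#'
#' @param motif_id identifier, e.g. `"MA0474.1"` or `"M00005"`.
#' @param name factor name, e.g. `"Erg"`; may be `""`.
#' @param counts numeric matrix with 4 columns (A, C, G, T order) and one row
#'   per motif position; all cells non-negative, every row must contain at
#'   least one positive cell.
#' @param source one of `"jaspar"`, `"transfac"`, `"synthetic"`.
#' @return an object of class `motif_matrix`.
#' @export
motif_matrix <- function(motif_id, name = "", counts, source = "synthetic") {
  counts <- as.matrix(counts)
  if (ncol(counts) != 4L)
    stop("motif '", motif_id, "': counts must have 4 columns (A,C,G,T)")
  if (any(counts < 0) || any(!is.finite(counts)))
    stop("motif '", motif_id, "': counts must be finite and non-negative")
  if (any(rowSums(counts) == 0))
    stop("motif '", motif_id, "': every position needs at least one nonzero cell")
  colnames(counts) <- DNA_BASES
  rownames(counts) <- NULL
  structure(
    list(motif_id = motif_id, name = name, counts = counts, source = source),
    class = "motif_matrix")
}

#' @export
print.motif_matrix <- function(x, ...) {
  cat(sprintf("<motif_matrix> %s (%s), %d positions, source: %s\n",
              x$motif_id, x$name, nrow(x$counts), x$source))
  cat("consensus:", consensus(x), "\n")
  invisible(x)
}

#' @export
length.motif_matrix <- function(x) nrow(x$counts)

#' Consensus sequence of a motif (argmax base per position)
#'
#' Ties broken toward the earlier base in A,C,G,T order.
#' @param m a `motif_matrix`
#' @return character string of length `nrow(m$counts)`
#' @export
consensus <- function(m) {
  paste(DNA_BASES[apply(m$counts, 1, which.max)], collapse = "")
}

.open_text <- function(x) {
  if (length(x) == 1L && !grepl("\n", x, fixed = TRUE) && file.exists(x))
    return(readLines(x))  # path, possibly gzipped (readLines handles .gz)
  strsplit(paste(x, collapse = "\n"), "\n", fixed = TRUE)[[1]]
}

#' Read motifs in JASPAR PFM format
#'
#' Parses the 2016-style JASPAR text format: a `>ID name` header followed by
#' four rows, one per base, either bracketed (`A [ 4 19 0 ]`) or bare counts.
#' Rows may appear in any base order; they are remapped to A, C, G, T.
#'
#' @param x a file path (plain or gzip) or a character vector of lines.
#' @return list of [motif_matrix()] objects.
#' @export
read_jaspar <- function(x) {
  lines <- .open_text(x)
  lines <- lines[!grepl("^\\s*$", lines)]
  hdr <- grep("^>", lines)
  if (length(hdr) == 0L) {
    if (length(lines) == 0L) return(list())
    stop("JASPAR parse error: no '>' header found")
  }
  bounds <- c(hdr, length(lines) + 1L)
  motifs <- vector("list", length(hdr))
  for (k in seq_along(hdr)) {
    block <- lines[hdr[k]:(bounds[k + 1L] - 1L)]
    header <- sub("^>\\s*", "", block[1L])
    parts <- strsplit(trimws(header), "\\s+")[[1]]
    if (length(parts) == 0L || parts[1L] == "")
      stop("JASPAR parse error: malformed header at line ", hdr[k])
    motif_id <- parts[1L]
    name <- if (length(parts) > 1L) paste(parts[-1L], collapse = " ") else ""
    body <- block[-1L]
    if (length(body) != 4L)
      stop("JASPAR parse error: record '", motif_id, "' has ",
           length(body), " matrix rows, expected 4")
    rows <- list()
    for (ln in body) {
      base <- toupper(substr(trimws(ln), 1L, 1L))
      if (!base %in% DNA_BASES)
        stop("JASPAR parse error: record '", motif_id,
             "': cannot identify base of row '", ln, "'")
      nums <- regmatches(ln, gregexpr("-?[0-9]*\\.?[0-9]+([eE][+-]?[0-9]+)?", ln))[[1]]
      rows[[base]] <- as.numeric(nums)
    }
    if (length(rows) != 4L)
      stop("JASPAR parse error: record '", motif_id, "' is missing a base row")
    lens <- lengths(rows)
    if (length(unique(lens)) != 1L)
      stop("JASPAR parse error: record '", motif_id,
           "' has rows of unequal length (", paste(lens, collapse = ","), ")")
    counts <- cbind(A = rows$A, C = rows$C, G = rows$G, T = rows$T)
    motifs[[k]] <- motif_matrix(motif_id, name, counts, source = "jaspar")
  }
  motifs
}

#' Write motifs in JASPAR PFM format
#'
#' @param motifs list of `motif_matrix` objects.
#' @param path output file path, or `NULL` to return the lines invisibly.
#' @return (invisibly) the character vector written.
#' @export
write_jaspar <- function(motifs, path = NULL) {
  fmt_row <- function(base, v)
    sprintf("%s [ %s ]", base, paste(format(v, trim = TRUE), collapse = " "))
  lines <- unlist(lapply(motifs, function(m) {
    c(sprintf(">%s %s", m$motif_id, m$name),
      vapply(DNA_BASES, function(b) fmt_row(b, m$counts[, b]), ""))
  }))
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

#' Read motifs in TRANSFAC flat-file matrix format
#'
#' Parses records of the form `AC` / `ID` / `P0 A C G T` (also accepts the
#' `PO` spelling) followed by numbered position rows, terminated by `//`.
#' The accession (`AC`) is stored as the motif id.
#'
#' @inheritParams read_jaspar
#' @return list of [motif_matrix()] objects.
#' @export
read_transfac <- function(x) {
  lines <- .open_text(x)
  lines <- lines[!grepl("^\\s*$", lines)]
  if (length(lines) == 0L) return(list())
  motifs <- list()
  cur <- NULL
  in_record <- FALSE
  for (i in seq_along(lines)) {
    ln <- lines[i]
    tag <- substr(ln, 1L, 2L)
    if (tag == "AC") {
      cur <- list(ac = trimws(sub("^AC\\s*", "", ln)), id = "",
                  order = NULL, rows = list())
      in_record <- TRUE
    } else if (!in_record) {
      next  # preamble (VV, XX, ...) before the first record
    } else if (tag == "ID") {
      cur$id <- trimws(sub("^ID\\s*", "", ln))
    } else if (tag %in% c("P0", "PO")) {
      ord <- toupper(strsplit(trimws(sub("^P[0O]\\s*", "", ln)), "\\s+")[[1]])
      if (!setequal(ord[1:4], DNA_BASES))
        stop("TRANSFAC parse error: record '", cur$ac,
             "': matrix header must list A,C,G,T (line ", i, ")")
      cur$order <- ord[1:4]
    } else if (tag == "//") {
      if (length(cur$rows) == 0L)
        stop("TRANSFAC parse error: record '", cur$ac, "' has no matrix rows")
      counts <- do.call(rbind, cur$rows)
      colnames(counts) <- cur$order
      counts <- counts[, DNA_BASES, drop = FALSE]
      motifs[[length(motifs) + 1L]] <-
        motif_matrix(cur$ac, cur$id, counts, source = "transfac")
      cur <- NULL
      in_record <- FALSE
    } else if (grepl("^[0-9]+\\s", ln)) {
      if (is.null(cur$order))
        stop("TRANSFAC parse error: record '", cur$ac,
             "': position row before P0/PO header (line ", i, ")")
      cells <- strsplit(trimws(ln), "\\s+")[[1]][-1L]
      vals <- suppressWarnings(as.numeric(cells[1:4]))
      if (length(cells) < 4L || any(is.na(vals)))
        stop("TRANSFAC parse error: record '", cur$ac,
             "': non-numeric matrix cell (line ", i, ")")
      cur$rows[[length(cur$rows) + 1L]] <- vals
    }
    # other tags (NA, DE, BF, XX, CC ...) are metadata and skipped
  }
  if (in_record)
    stop("TRANSFAC parse error: record '", cur$ac, "' is missing its '//' terminator")
  motifs
}

#' Convert a count matrix into a log-odds scoring matrix
#'
#' Builds the standard pseudocount-regularised log-odds PWM used for
#' promoter scanning.  Cell \eqn{(i,b)} becomes
#' \deqn{\log\frac{(c_{ib} + s\,q_b)/(\sum_b c_{ib} + s)}{q_b}}
#' where \eqn{q} is the background distribution and \eqn{s} the total
#' pseudocount (distributed proportionally to the background).  The minimum
#' and maximum attainable window scores (sums of per-position row minima and
#' maxima) are precomputed for min-max normalisation, and the per-position
#' background expectation is stored for scoring ambiguity codes.
#'
#' @param m a [motif_matrix()].
#' @param background base frequencies (A,C,G,T), strictly positive, summing
#'   to 1. Default uniform.
#' @param pseudocount total pseudocount mass added per position (> 0 unless
#'   all counts are positive). Default 1.
#' @return object of class `scoring_matrix` with elements `motif_id`, `name`,
#'   `logodds` (L x 4), `ambig` (length-L background expectations),
#'   `score_min`, `score_max`, `background`, `degenerate`.
#' @export
to_scoring_matrix <- function(m, background = rep(0.25, 4), pseudocount = 1) {
  stopifnot(inherits(m, "motif_matrix"))
  if (length(background) != 4L || any(background <= 0))
    stop("background must be 4 strictly positive frequencies")
  background <- background / sum(background)
  if (pseudocount < 0) stop("pseudocount must be >= 0")
  if (pseudocount == 0 && any(m$counts == 0))
    stop("motif '", m$motif_id,
         "': zero counts require a positive pseudocount (log-odds would be -Inf)")
  rs <- rowSums(m$counts)
  prob <- (m$counts + pseudocount * rep(background, each = nrow(m$counts))) /
    (rs + pseudocount)
  lo <- log(sweep(prob, 2, background, "/"))
  score_min <- sum(apply(lo, 1, min))
  score_max <- sum(apply(lo, 1, max))
  structure(
    list(motif_id = m$motif_id, name = m$name,
         logodds = lo,
         ambig = as.numeric(lo %*% background),
         score_min = score_min, score_max = score_max,
         background = background,
         degenerate = (score_max - score_min) < 1e-9),
    class = "scoring_matrix")
}

#' @export
print.scoring_matrix <- function(x, ...) {
  cat(sprintf("<scoring_matrix> %s, %d positions, score range [%.3f, %.3f]%s\n",
              x$motif_id, nrow(x$logodds), x$score_min, x$score_max,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' @export
length.scoring_matrix <- function(x) nrow(x$logodds)
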