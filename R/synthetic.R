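#' Simulate a motif count matrix
#'
#' Draws per-position base probabilities from a symmetric Dirichlet and
#' converts them to multinomial counts.  Low `concentration` gives sharp,
#' near-one-hot columns (high information content); high concentration gives
#' near-uniform columns that will be flagged degenerate downstream.
#'
#' @param length motif length in bp (at least 4).
#' @param concentration Dirichlet concentration parameter (default 0.2).
#' @param depth multinomial depth per position (default 100 observations).
#' @param motif_id identifier for the simulated motif.
#' @return a [motif_matrix()] with `source = "synthetic"`.
#' @export
simulate_motif <- function(length, concentration = 0.2, depth = 100L,
                           motif_id = "SYN001") {
  if (length < 4L) stop("motif length must be at least 4")
  counts <- t(vapply(seq_len(length), function(i) {
    g <- rgamma(4, shape = concentration)
    if (all(g == 0)) g <- rep(1, 4)  # guard against underflow at tiny shapes
    drop(rmultinom(1, size = depth, prob = g / sum(g)))
  }, numeric(4)))
  # multinomial draws can zero out a position; keep the invariant
  zero <- rowSums(counts) == 0
  counts[zero, ] <- 1
  motif_matrix(motif_id, name = motif_id, counts, source = "synthetic")
}

.random_dna <- function(n, length, gc_content = 0.5) {
  p <- c((1 - gc_content) / 2, gc_content / 2, gc_content / 2,
         (1 - gc_content) / 2)
  vapply(seq_len(n), function(i) {
    paste(sample(DNA_BASES, length, replace = TRUE, prob = p), collapse = "")
  }, "")
}

# Insert `site` into `seq` at a position not overlapping `occupied`
# (list of c(start, end) 1-based inclusive). Returns list(seq, pos, strand)
# or NULL if no free slot is found.
.insert_site <- function(seq, site, occupied, max_tries = 50L) {
  L <- nchar(site)
  P <- nchar(seq)
  if (L > P) stop("motif instance longer than the promoter")
  for (t in seq_len(max_tries)) {
    pos <- sample.int(P - L + 1L, 1L)
    strand <- sample(c("+", "-"), 1L)
    clash <- any(vapply(occupied, function(iv)
      pos <= iv[2] && (pos + L - 1L) >= iv[1], logical(1)))
    if (clash) next
    ins <- if (strand == "+") site else .revcomp(site)
    substr(seq, pos, pos + L - 1L) <- ins
    return(list(seq = seq, pos = pos, strand = strand))
  }
  NULL
}

#' Simulate promoters with planted motif instances
#'
#' Generates i.i.d. background promoters at a given GC content and plants
#' motif instances (consensus sites by default) into designated genes at a
#' controlled per-gene rate, at uniform random positions and strands.
#' Planted instances may overwrite background sequence but never each other
#' (rejection sampling on positions).  Every insertion is recorded in a
#' ledger, so ground truth is fully known.
#'
#' @param n_genes number of promoters.
#' @param promoter_length bp per promoter (default 500).
#' @param gc_content background GC fraction (default 0.5).
#' @param plantings list of planting instructions, each a list with elements
#'   `motif` (a [motif_matrix()]), `rate` (fraction of the target genes that
#'   receive one instance), and optionally `genes` (gene ids to plant into;
#'   default all).  `round(rate * n_target)` genes are drawn without
#'   replacement, so the realised planting rate is exact.
#' @param gene_ids gene identifiers (default `G00001...`).
#' @param mode `"consensus"` (plant the argmax site) or `"sample"` (draw a
#'   site from the PFM probabilities).
#' @return list with `promoters` (a [promoter_set()]; the window split is
#'   cosmetic: 90% up / 10% down of `promoter_length`) and `ledger`
#'   (data.frame `gene_id`, `motif_id`, `pos`, `strand`, `site`).
#' @export
simulate_promoters <- function(n_genes, promoter_length = 500L,
                               gc_content = 0.5, plantings = list(),
                               gene_ids = NULL, mode = c("consensus", "sample")) {
  mode <- match.arg(mode)
  if (is.null(gene_ids)) gene_ids <- sprintf("G%05d", seq_len(n_genes))
  stopifnot(length(gene_ids) == n_genes)
  seqs <- setNames(.random_dna(n_genes, promoter_length, gc_content), gene_ids)
  occupied <- setNames(vector("list", n_genes), gene_ids)
  ledger <- list()
  for (pl in plantings) {
    m <- pl$motif
    if (nrow(m$counts) > promoter_length)
      stop("motif '", m$motif_id, "' is longer than the promoter")
    target <- if (is.null(pl$genes)) gene_ids else pl$genes
    n_plant <- round(pl$rate * length(target))
    if (n_plant == 0L) next
    chosen <- sample(target, n_plant)
    for (g in chosen) {
      site <- if (mode == "consensus") consensus(m) else .sample_site(m)
      res <- .insert_site(seqs[[g]], site, occupied[[g]])
      if (is.null(res)) next  # promoter saturated; skip silently
      seqs[[g]] <- res$seq
      occupied[[g]] <- c(occupied[[g]],
                         list(c(res$pos, res$pos + nchar(site) - 1L)))
      ledger[[length(ledger) + 1L]] <-
        data.frame(gene_id = g, motif_id = m$motif_id, pos = res$pos,
                   strand = res$strand, site = site, stringsAsFactors = FALSE)
    }
  }
  ledger <- if (length(ledger)) do.call(rbind, ledger) else
    data.frame(gene_id = character(), motif_id = character(),
               pos = integer(), strand = character(), site = character())
  up <- as.integer(round(promoter_length * 0.9))
  list(promoters = promoter_set(seqs, window_up = up,
                                window_down = promoter_length - up),
       ledger = ledger)
}

.sample_site <- function(m) {
  prob <- m$counts / rowSums(m$counts)
  paste(vapply(seq_len(nrow(prob)), function(i)
    sample(DNA_BASES, 1L, prob = prob[i, ]), ""), collapse = "")
}

#' Simulate a multi-sample panel with planted phenotype groups
#'
#' Emulates a meta-analysis panel: `n_groups` phenotype groups of
#' `samples_per_group` samples each, with disjoint sets of
#' `motifs_per_group` sharp synthetic motifs per group.  Every motif is
#' planted in the shared background universe at `bg_rate` (its genomic
#' baseline) and, for samples of its own group, in the sample's target gene
#' set at the much higher `set_rate` — so a motif is strongly enriched in
#' its own group's samples and avoided (present below baseline, i.e. absent)
#' in the others.  Per-sample jitter comes from independent sequence and
#' planting draws.
#'
#' @param n_groups,samples_per_group panel layout (defaults 3 and 5).
#' @param motifs_per_group planted motifs per group (default 4).
#' @param motif_length motif length in bp (default 8).
#' @param n_bg_genes size of the shared background gene universe
#'   (default 1500, ten times the default set size).
#' @param set_size genes per sample target set (default 150).
#' @param promoter_length bp (default 500).
#' @param gc_content background GC fraction.
#' @param set_rate planting rate inside a sample's own-group target set
#'   (default 0.8); each motif additionally carries a fixed strength factor
#'   drawn once from `[0.6, 1]`, so enrichment magnitudes differ between a
#'   group's motifs as they would between real factors.
#' @param bg_rate genomic baseline planting rate (default 0.25).
#' @param concentration Dirichlet concentration for the motifs (sharp by
#'   default, 0.1).
#' @param seed RNG seed (mandatory; the whole panel is deterministic).
#' @return list with `catalog` (motif list), `background` ([promoter_set()]
#'   of the shared universe), `samples` (list of per-sample lists:
#'   `sample_id`, `group`, `genes` (a [gene_set()]), `promoters`),
#'   `truth` (named integer group labels) and `motif_groups` (named integer:
#'   owning group per motif).
#' @export
simulate_panel <- function(n_groups = 3L, samples_per_group = 5L,
                           motifs_per_group = 4L, motif_length = 8L,
                           n_bg_genes = 1500L, set_size = 150L,
                           promoter_length = 500L, gc_content = 0.5,
                           set_rate = 0.8, bg_rate = 0.25,
                           concentration = 0.1, seed) {
  if (missing(seed)) stop("a seed is mandatory for panel simulation")
  if (samples_per_group < 2L) stop("each group needs at least 2 samples")
  set.seed(seed)
  n_motifs <- n_groups * motifs_per_group
  catalog <- lapply(seq_len(n_motifs), function(i)
    simulate_motif(motif_length, concentration,
                   motif_id = sprintf("SYN%03d", i)))
  motif_groups <- setNames(rep(seq_len(n_groups), each = motifs_per_group),
                           vapply(catalog, `[[`, "", "motif_id"))
  # fixed per-motif strength: motifs differ in enrichment magnitude, so the
  # within-sample ordering of a group's motifs is consistent across samples
  strengths <- setNames(runif(n_motifs, 0.6, 1), names(motif_groups))
  bg_plant <- lapply(catalog, function(m) list(motif = m, rate = bg_rate))
  background <- simulate_promoters(n_bg_genes, promoter_length, gc_content,
                                   plantings = bg_plant,
                                   gene_ids = sprintf("BG%05d", seq_len(n_bg_genes)))
  samples <- list()
  truth <- integer(0)
  for (g in seq_len(n_groups)) {
    own <- catalog[motif_groups == g]
    for (r in seq_len(samples_per_group)) {
      sid <- sprintf("grp%d_s%d", g, r)
      ids <- sprintf("%s_T%04d", sid, seq_len(set_size))
      pl <- lapply(own, function(m)
        list(motif = m, rate = set_rate * strengths[[m$motif_id]]))
      pr <- simulate_promoters(set_size, promoter_length, gc_content,
                               plantings = pl, gene_ids = ids)
      half <- floor(set_size / 2)
      gs <- gene_set(sid, up = ids[seq_len(half)], down = ids[(half + 1):set_size])
      samples[[sid]] <- list(sample_id = sid, group = g, genes = gs,
                             promoters = pr$promoters)
      truth[sid] <- g
    }
  }
  list(catalog = catalog, background = background$promoters,
       samples = samples, truth = truth, motif_groups = motif_groups)
}

#' Simulate a confidence-scored interactome with planted modules
#'
#' Builds a STRING-style edge list containing two densely connected seed
#' modules (A and B), per-module intermediate proteins, stress sensors wired
#' exclusively to their designated module, and background proteins with
#' random low-relevance edges.  Module and sensor edges always pass the
#' default confidence filter (combined score at least 700, positive
#' experimental channel); background noise edges draw scores across the full
#' range and lack experimental evidence half the time, so filtering is
#' exercised.  The two modules are never directly connected.
#'
#' @param module_a,module_b seed protein names for the two phenotypes.
#' @param sensors_a,sensors_b sensors wired to module A / module B.
#' @param n_intermediates intermediate proteins attached per module
#'   (default 2, each with 2 module edges so they survive degree-1 pruning).
#' @param n_background unrelated background proteins (default 20).
#' @param within_prob edge probability inside a module (default 0.6; a
#'   spanning chain guarantees each module is connected).
#' @param background_edge_prob edge probability among background proteins.
#' @param sensor_edges module edges per sensor (default 3).
#' @param seed RNG seed (mandatory).
#' @return list with `edges` (data.frame `protein_a`, `protein_b`,
#'   `experimental`, `combined_score`) and `truth` (module / sensor sets).
#' @export
simulate_interactome <- function(module_a = sprintf("TFA%d", 1:8),
                                 module_b = sprintf("TFB%d", 1:6),
                                 sensors_a = c("SENSA1", "SENSA2"),
                                 sensors_b = c("SENSB1", "SENSB2"),
                                 n_intermediates = 2L, n_background = 20L,
                                 within_prob = 0.6,
                                 background_edge_prob = 0.05,
                                 sensor_edges = 3L, seed) {
  if (missing(seed)) stop("a seed is mandatory for interactome simulation")
  set.seed(seed)
  edges <- list()
  add <- function(a, b, strong = TRUE) {
    score <- if (strong) round(runif(1, 700, 1000)) else round(runif(1, 100, 1000))
    exper <- if (strong) round(runif(1, 100, 900)) else
      if (runif(1) < 0.5) 0 else round(runif(1, 1, 900))
    edges[[length(edges) + 1L]] <<-
      data.frame(protein_a = a, protein_b = b, experimental = exper,
                 combined_score = score, stringsAsFactors = FALSE)
  }
  module_edges <- function(mod) {
    for (i in seq_len(length(mod) - 1L)) add(mod[i], mod[i + 1L])  # spanning chain
    pairs <- utils::combn(mod, 2L)
    for (j in seq_len(ncol(pairs)))
      if (runif(1) < within_prob) add(pairs[1, j], pairs[2, j])
    for (k in seq_len(n_intermediates)) {
      im <- sprintf("INT_%s_%d", mod[1L], k)
      for (tgt in sample(mod, 2L)) add(im, tgt)
    }
  }
  module_edges(module_a)
  module_edges(module_b)
  for (s in sensors_a) for (tgt in sample(module_a, sensor_edges)) add(s, tgt)
  for (s in sensors_b) for (tgt in sample(module_b, sensor_edges)) add(s, tgt)
  if (n_background > 1L && background_edge_prob > 0) {
    bg <- sprintf("BGP%02d", seq_len(n_background))
    pairs <- utils::combn(bg, 2L)
    for (j in seq_len(ncol(pairs)))
      if (runif(1) < background_edge_prob) add(pairs[1, j], pairs[2, j],
                                               strong = FALSE)
  }
  list(edges = do.call(rbind, edges),
       truth = list(module_a = module_a, module_b = module_b,
                    sensors_a = sensors_a, sensors_b = sensors_b))
}

#' Simulate a switching-motif condition pair at the profile level
#'
#' Draws per-motif enrichment p-scores for two conditions with planted
#' switching motifs: a planted switcher is strongly enriched in one
#' condition (p below 0.01) and clearly avoided in the other (p above 0.5);
#' non-switchers are either mid-range in both, enriched in both (and so
#' excluded by the both-enriched rule), or enriched in one but not avoided
#' in the other.  Ranks are the within-condition ranks of the p-scores.
#'
#' @param n_motifs total motifs (default 30).
#' @param n_switch_a,n_switch_b planted switchers enriched in condition A /
#'   condition B (defaults 8 and 6, the reference phenotype layout).
#' @param seed RNG seed (mandatory).
#' @return list with `a`, `b` (data.frames `motif_id`, `p`, `rank`) and
#'   `truth` (list of the planted switcher ids per direction).
#' @export
simulate_switch_profiles <- function(n_motifs = 30L, n_switch_a = 8L,
                                     n_switch_b = 6L, seed) {
  if (missing(seed)) stop("a seed is mandatory")
  if (n_switch_a + n_switch_b > n_motifs)
    stop("more switchers than motifs")
  set.seed(seed)
  ids <- sprintf("MOT%03d", seq_len(n_motifs))
  sw_a <- ids[seq_len(n_switch_a)]
  sw_b <- ids[n_switch_a + seq_len(n_switch_b)]
  rest <- setdiff(ids, c(sw_a, sw_b))
  p_a <- p_b <- setNames(numeric(n_motifs), ids)
  p_a[sw_a] <- runif(n_switch_a, 1e-4, 0.01)
  p_b[sw_a] <- runif(n_switch_a, 0.5, 0.99)
  p_a[sw_b] <- runif(n_switch_b, 0.5, 0.99)
  p_b[sw_b] <- runif(n_switch_b, 1e-4, 0.01)
  for (m in rest) {
    kind <- sample(c("mid", "both_enriched", "one_not_avoided"), 1L)
    if (kind == "mid") {
      p_a[m] <- runif(1, 0.06, 0.24); p_b[m] <- runif(1, 0.06, 0.24)
    } else if (kind == "both_enriched") {
      p_a[m] <- runif(1, 1e-3, 0.04); p_b[m] <- runif(1, 1e-3, 0.04)
    } else {
      p_a[m] <- runif(1, 1e-3, 0.04); p_b[m] <- runif(1, 0.06, 0.24)
      if (runif(1) < 0.5) { tmp <- p_a[m]; p_a[m] <- p_b[m]; p_b[m] <- tmp }
    }
  }
  mk <- function(p) data.frame(motif_id = ids, p = unname(p),
                               rank = rank(p, ties.method = "average"),
                               stringsAsFactors = FALSE)
  list(a = mk(p_a), b = mk(p_b),
       truth = list(enriched_in_a = sw_a, enriched_in_b = sw_b))
}
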