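#' Load a confidence-scored protein interaction edge list
#'
#' Reads a STRING-export-style TSV and keeps only edges with combined
#' confidence at least `min_score` (STRING scale 0-1000) and, optionally,
#' nonzero experimental-channel evidence.  Self loops are removed and
#' duplicate / reciprocal pairs collapsed keeping the maximum score.
#'
#' @param x path to a TSV or a data.frame.  Columns: the two proteins
#'   (`protein_a`/`protein_b`, STRING's `protein1`/`protein2` or
#'   `node1`/`node2` accepted), `combined_score`, and an experimental channel
#'   (`experimental`, configurable).
#' @param min_score minimum combined confidence (default 500).
#' @param require_experimental drop edges whose experimental channel is 0 or
#'   missing? Default `TRUE`.
#' @param experimental_col name of the experimental-evidence column.
#' @return data.frame of class `interactome` with columns `protein_a`,
#'   `protein_b`, `combined_score`, `experimental`.
#' @export
load_interactome <- function(x, min_score = 500L, require_experimental = TRUE,
                             experimental_col = "experimental") {
  df <- if (is.character(x)) read.delim(x, stringsAsFactors = FALSE) else
    as.data.frame(x, stringsAsFactors = FALSE)
  pick <- function(cands) {
    hit <- intersect(cands, names(df))
    if (!length(hit)) stop("interactome table is missing a column; tried: ",
                           paste(cands, collapse = ", "))
    df[[hit[1]]]
  }
  pa <- as.character(pick(c("protein_a", "protein1", "node1")))
  pb <- as.character(pick(c("protein_b", "protein2", "node2")))
  score <- suppressWarnings(as.numeric(pick("combined_score")))
  if (anyNA(score) || anyNA(pa) || anyNA(pb) || any(pa == "") || any(pb == ""))
    stop("malformed interactome row(s): ",
         paste(which(is.na(score) | pa == "" | pb == ""), collapse = ", "))
  if (any(score < 0 | score > 1000))
    stop("combined_score out of the 0-1000 range at row(s): ",
         paste(which(score < 0 | score > 1000), collapse = ", "))
  exper <- if (experimental_col %in% names(df))
    suppressWarnings(as.numeric(df[[experimental_col]])) else
      rep(NA_real_, nrow(df))
  keep <- score >= min_score & pa != pb
  if (require_experimental) keep <- keep & !is.na(exper) & exper > 0
  df <- data.frame(protein_a = pmin(pa, pb), protein_b = pmax(pa, pb),
                   combined_score = score, experimental = exper,
                   stringsAsFactors = FALSE)[keep, , drop = FALSE]
  # collapse duplicates keeping the maximum combined score
  df <- df[order(df$protein_a, df$protein_b, -df$combined_score), , drop = FALSE]
  df <- df[!duplicated(df[, c("protein_a", "protein_b")]), , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "min_score") <- min_score
  class(df) <- c("interactome", class(df))
  df
}

#' @export
print.interactome <- function(x, ...) {
  cat(sprintf("<interactome> %d edges over %d proteins (combined score >= %s)\n",
              nrow(x), length(unique(c(x$protein_a, x$protein_b))),
              attr(x, "min_score")))
  invisible(x)
}

#' Build a seeded minimum protein-interaction network
#'
#' First-order expansion of the seed and sensor proteins (seeds, sensors and
#' all their interactome neighbours), followed by iterative pruning of
#' peripheral non-seed, non-sensor nodes of degree at most 1, the
#' NetworkAnalyst-style "minimum network" heuristic.  Surviving non-seed,
#' non-sensor nodes are labelled `intermediate`.  Subnetwork group labels
#' (`"A"` / `"B"`) are assigned per connected component of the network with
#' sensors removed, by majority of the seed roles it contains.
#'
#' @param inter a [load_interactome()] result.
#' @param seeds_a,seeds_b character vectors of seed proteins for the two
#'   phenotypes. Seeds absent from the interactome are kept as isolated
#'   nodes and reported with a warning.
#' @param sensors character vector of stress-sensor proteins to probe.
#' @return object of class `seeded_network`: list with `graph` (igraph),
#'   `roles` (named character: `seed_A`, `seed_B`, `sensor`,
#'   `intermediate`), `groups` (named character `"A"`/`"B"`/`NA`).
#' @export
build_min_network <- function(inter, seeds_a, seeds_b, sensors = character()) {
  stopifnot(inherits(inter, "interactome"))
  if (nrow(inter) == 0L) stop("empty interactome")
  g <- igraph::graph_from_data_frame(
    inter[, c("protein_a", "protein_b", "combined_score")], directed = FALSE)
  anchors <- unique(c(seeds_a, seeds_b, sensors))
  absent <- setdiff(anchors, igraph::V(g)$name)
  if (length(absent)) {
    warning("seed/sensor protein(s) absent from the interactome kept as isolated nodes: ",
            paste(absent, collapse = ", "))
    g <- igraph::add_vertices(g, length(absent), name = absent)
  }
  present <- intersect(anchors, igraph::V(g)$name)
  nbrs <- unique(unlist(lapply(igraph::adjacent_vertices(g, present), names)))
  keep <- union(anchors, nbrs)
  sub <- igraph::induced_subgraph(g, keep)
  # iterative degree<=1 pruning of non-anchor nodes
  repeat {
    deg <- igraph::degree(sub)
    drop <- names(deg)[deg <= 1L & !(names(deg) %in% anchors)]
    if (!length(drop)) break
    sub <- igraph::delete_vertices(sub, drop)
  }
  nodes <- igraph::V(sub)$name
  roles <- setNames(rep("intermediate", length(nodes)), nodes)
  roles[nodes %in% seeds_a] <- "seed_A"
  roles[nodes %in% seeds_b] <- "seed_B"
  roles[nodes %in% sensors] <- "sensor"

  # group labelling on the sensor-free graph so sensors cannot merge modules
  core <- igraph::delete_vertices(sub, intersect(nodes, sensors))
  comp <- igraph::components(core)
  groups <- setNames(rep(NA_character_, length(nodes)), nodes)
  for (ci in seq_len(comp$no)) {
    members <- names(comp$membership)[comp$membership == ci]
    na <- sum(roles[members] == "seed_A")
    nb <- sum(roles[members] == "seed_B")
    if (na + nb == 0L) next
    groups[members] <- if (na > nb) "A" else if (nb > na) "B" else "mixed"
  }
  structure(list(graph = sub, roles = roles, groups = groups),
            class = "seeded_network")
}

#' @export
print.seeded_network <- function(x, ...) {
  tab <- table(x$roles)
  cat(sprintf("<seeded_network> %d nodes, %d edges (%s)\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph),
              paste(names(tab), tab, sep = ": ", collapse = ", ")))
  invisible(x)
}

#' Probe stress-sensor connectivity to the switching subnetworks
#'
#' For each sensor, counts its retained network edges terminating in nodes
#' of the seed-A-derived vs seed-B-derived subnetwork and flags which
#' subnetworks it connects to.
#'
#' @param net a [build_min_network()] result.
#' @param sensors sensors to report; defaults to all nodes with role
#'   `sensor`.
#' @return data.frame of class `sensor_report`: `sensor`, `edges_to_A`,
#'   `edges_to_B`, `connected_A`, `connected_B`.
#' @export
probe_sensors <- function(net, sensors = NULL) {
  stopifnot(inherits(net, "seeded_network"))
  if (is.null(sensors)) sensors <- names(net$roles)[net$roles == "sensor"]
  rows <- lapply(sensors, function(s) {
    if (!s %in% igraph::V(net$graph)$name) {
      warning("sensor '", s, "' absent from the network; reported unconnected")
      return(data.frame(sensor = s, edges_to_A = 0L, edges_to_B = 0L,
                        connected_A = FALSE, connected_B = FALSE))
    }
    nb <- names(igraph::neighbors(net$graph, s))
    grp <- net$groups[nb]
    data.frame(sensor = s,
               edges_to_A = sum(grp == "A", na.rm = TRUE),
               edges_to_B = sum(grp == "B", na.rm = TRUE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$connected_A <- out$edges_to_A > 0L
  out$connected_B <- out$edges_to_B > 0L
  rownames(out) <- NULL
  class(out) <- c("sensor_report", class(out))
  out
}

#' Export a seeded network
#'
#' Writes GraphML plus node/edge TSVs (with role and group columns) to
#' `dir`.
#'
#' @param net a `seeded_network`.
#' @param dir output directory.
#' @export
write_network <- function(net, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  g <- net$graph
  igraph::V(g)$role <- unname(net$roles[igraph::V(g)$name])
  igraph::V(g)$group <- unname(net$groups[igraph::V(g)$name])
  igraph::write_graph(g, file.path(dir, "network.graphml"), format = "graphml")
  nodes <- data.frame(node = igraph::V(g)$name,
                      role = igraph::V(g)$role,
                      group = igraph::V(g)$group)
  edges <- igraph::as_data_frame(g, what = "edges")
  write.table(nodes, file.path(dir, "nodes.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(edges, file.path(dir, "edges.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(dir)
}
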