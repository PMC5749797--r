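test_that("interactome loading filters on confidence and experimental evidence", {
  edges <- data.frame(
    protein_a = c("P1", "P2", "P3", "P4", "P5", "P5"),
    protein_b = c("P2", "P3", "P4", "P1", "P5", "P6"),
    experimental = c(100, 0, 250, 90, 50, 40),
    combined_score = c(700, 800, 499, 901, 600, 650))
  inter <- load_interactome(edges)
  # P2-P3 lacks experimental evidence, P3-P4 is below 500, P5-P5 is a self loop
  expect_equal(nrow(inter), 3L)
  expect_false(any(inter$protein_a == inter$protein_b))
  expect_true(all(inter$combined_score >= 500))
  expect_true(all(inter$experimental > 0))

  without <- load_interactome(edges, require_experimental = FALSE)
  expect_equal(nrow(without), 4L)
})

test_that("reciprocal duplicates collapse to one undirected edge keeping max score", {
  edges <- data.frame(protein_a = c("A", "B"), protein_b = c("B", "A"),
                      experimental = c(10, 20), combined_score = c(700, 900))
  inter <- load_interactome(edges)
  expect_equal(nrow(inter), 1L)
  expect_equal(inter$combined_score, 900)
})

test_that("STRING-style column names are accepted and malformed rows rejected", {
  edges <- data.frame(protein1 = "A", protein2 = "B",
                      experimental = 10, combined_score = 800)
  expect_equal(nrow(load_interactome(edges)), 1L)
  bad <- data.frame(protein_a = "A", protein_b = "B",
                    experimental = 10, combined_score = "high")
  expect_error(load_interactome(bad), "malformed")
  expect_error(load_interactome(data.frame(protein_a = "A")), "missing")
})

test_that("raising min_score never adds edges (monotonicity)", {
  set.seed(71)
  it <- simulate_interactome(seed = 71)
  low <- load_interactome(it$edges, min_score = 400)
  high <- load_interactome(it$edges, min_score = 700)
  expect_lte(nrow(high), nrow(low))
  key <- function(d) paste(d$protein_a, d$protein_b)
  expect_true(all(key(high) %in% key(low)))
})

test_that("synthetic edge counting matches an independent filter", {
  set.seed(72)
  it <- simulate_interactome(seed = 72)
  inter <- load_interactome(it$edges, min_score = 500)
  e <- it$edges
  a <- pmin(e$protein_a, e$protein_b); b <- pmax(e$protein_a, e$protein_b)
  pass <- e$combined_score >= 500 & e$experimental > 0 & a != b
  expect_equal(nrow(inter),
               length(unique(paste(a, b)[pass])))
})

test_that("minimum network: isolated seeds, chain intermediates, pruning fixpoint", {
  # seeds with no edges at all stay as isolated nodes
  inter0 <- load_interactome(data.frame(protein_a = "X", protein_b = "Y",
                                        experimental = 5, combined_score = 900))
  expect_warning(net0 <- build_min_network(inter0, "S1", "S2"), "absent")
  expect_setequal(names(net0$roles)[net0$roles != "intermediate"], c("S1", "S2"))

  # chain seedA - x - seedB: x has degree 2 and survives as intermediate
  chain <- load_interactome(data.frame(
    protein_a = c("SA", "X", "X"), protein_b = c("X", "SB", "LEAF"),
    experimental = c(5, 5, 5), combined_score = c(900, 900, 900)))
  net <- build_min_network(chain, "SA", "SB")
  expect_equal(unname(net$roles["X"]), "intermediate")
  # LEAF had degree 1 and is pruned
  expect_false("LEAF" %in% names(net$roles))
  # fixpoint: no prunable node remains
  deg <- igraph::degree(net$graph)
  anchors <- names(net$roles)[net$roles != "intermediate"]
  expect_true(all(deg[setdiff(names(deg), anchors)] >= 2))
})

test_that("planted modules are recovered with correct role and group labels", {
  it <- simulate_interactome(seed = 73)
  inter <- load_interactome(it$edges)
  net <- build_min_network(inter, it$truth$module_a, it$truth$module_b,
                           sensors = c(it$truth$sensors_a, it$truth$sensors_b))
  expect_true(all(net$roles[it$truth$module_a] == "seed_A"))
  expect_true(all(net$roles[it$truth$module_b] == "seed_B"))
  expect_true(all(net$groups[it$truth$module_a] == "A"))
  expect_true(all(net$groups[it$truth$module_b] == "B"))
  # intermediates wired into module A inherit group A
  ints <- grep("^INT_TFA", names(net$roles), value = TRUE)
  expect_true(length(ints) > 0 && all(net$groups[ints] == "A"))
})

test_that("sensor probing reports the planted asymmetry exactly", {
  it <- simulate_interactome(seed = 74)
  inter <- load_interactome(it$edges)
  net <- build_min_network(inter, it$truth$module_a, it$truth$module_b,
                           sensors = c(it$truth$sensors_a, it$truth$sensors_b))
  rep <- probe_sensors(net)
  rep_a <- rep[rep$sensor %in% it$truth$sensors_a, ]
  rep_b <- rep[rep$sensor %in% it$truth$sensors_b, ]
  expect_true(all(rep_a$connected_A) && !any(rep_a$connected_B))
  expect_true(all(rep_b$connected_B) && !any(rep_b$connected_A))
  expect_true(all(rep_a$edges_to_A > 0) && all(rep_a$edges_to_B == 0))
})

test_that("an isolated sensor is reported unconnected", {
  inter <- load_interactome(data.frame(
    protein_a = c("SA", "SA2"), protein_b = c("SA2", "SA"),
    experimental = 5, combined_score = 900))
  expect_warning(net <- build_min_network(inter, c("SA", "SA2"), character(),
                                          sensors = "GHOST"), "absent")
  rep <- probe_sensors(net)
  expect_false(rep$connected_A | rep$connected_B)
})

test_that("network export writes GraphML and role/group TSVs", {
  it <- simulate_interactome(seed = 75)
  inter <- load_interactome(it$edges)
  net <- build_min_network(inter, it$truth$module_a, it$truth$module_b,
                           sensors = it$truth$sensors_a)
  dir <- withr::local_tempdir()
  write_network(net, dir)
  expect_true(file.exists(file.path(dir, "network.graphml")))
  nodes <- utils::read.delim(file.path(dir, "nodes.tsv"))
  expect_setequal(nodes$node, names(net$roles))
  expect_true("role" %in% names(nodes) && "group" %in% names(nodes))
})
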