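# Exhaustive oracle: check every (birth defect, gene, drug) triple against
# the raw edge records, ignoring storage direction.
brute_force_cliques <- function(nodes, edges) {
  has_edge <- function(x, y) {
    any((edges$source == x & edges$target == y) |
        (edges$source == y & edges$target == x))
  }
  bds <- nodes$id[nodes$type == "BirthDefect"]
  genes <- nodes$id[nodes$type == "Gene"]
  drugs <- nodes$id[nodes$type == "Drug"]
  out <- list()
  for (bd in bds) for (g in genes) for (d in drugs) {
    if (has_edge(bd, g) && has_edge(bd, d) && has_edge(d, g)) {
      out[[length(out) + 1]] <- c(bd, g, d)
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(birth_defect = character(), gene = character(),
                          drug = character()))
  }
  m <- do.call(rbind, out)
  dplyr::arrange(tibble::tibble(birth_defect = m[, 1], gene = m[, 2], drug = m[, 3]),
                 birth_defect, gene, drug)
}

test_that("build_kg validates nodes, relations and endpoints", {
  recs <- tiny_kg_records()
  kg <- quiet_kg(recs$nodes, recs$edges)
  expect_s3_class(kg, "repro_kg")
  expect_equal(nrow(kg$edges), 3)
  # empty edge list: isolated nodes
  kg0 <- quiet_kg(recs$nodes, recs$edges[0, ])
  expect_equal(nrow(kg0$edges), 0)
  # dangling endpoint: error in strict mode naming the id, dropped otherwise
  bad <- recs$edges
  bad$target[1] <- "G99"
  expect_error(quiet_kg(recs$nodes, bad), "G99")
  expect_message(kg_lenient <- build_kg(recs$nodes, bad, strict = FALSE),
                 "dropping 1")
  expect_equal(nrow(kg_lenient$edges), 2)
  # unknown relation / type mismatch / duplicates / self-loops
  bad2 <- recs$edges
  bad2$relation[1] <- "causes"
  expect_error(quiet_kg(recs$nodes, bad2), "unknown relation")
  expect_error(quiet_kg(recs$nodes, recs$edges[c(1, 1), ]), "duplicate")
  # an HPO edge whose endpoints are two drugs fails type checking
  bad3 <- tibble::tibble(source = "D1", target = "D2", relation = "HPO")
  expect_error(quiet_kg(recs$nodes, bad3), "missing")
  # unknown property key rejected in strict mode only
  nodes2 <- recs$nodes
  nodes2$properties[[3]] <- list(banana = 1)
  expect_error(quiet_kg(nodes2, recs$edges), "banana")
  expect_s3_class(quiet_kg(nodes2, recs$edges, strict = FALSE), "repro_kg")
})

test_that("find_cliques matches exhaustive enumeration on random fixtures", {
  for (seed in 1:12) {
    recs <- random_kg_records(n_bd = 5, n_gene = 8, n_drug = 8,
                              density = 0.2, seed = seed)
    kg <- quiet_kg(recs$nodes, recs$edges)
    found <- find_cliques(kg)
    oracle <- brute_force_cliques(recs$nodes, recs$edges)
    expect_equal(found[, c("birth_defect", "gene", "drug")], oracle)
  }
})

test_that("find_cliques handles planted and degenerate graphs", {
  recs <- tiny_kg_records()
  kg <- quiet_kg(recs$nodes, recs$edges)
  cl <- find_cliques(kg)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$birth_defect, "HP:0000001")
  expect_equal(cl$gene, "G1")
  expect_equal(cl$drug, "D1")
  expect_equal(cl$drug_gene_relation, "upregulates")
  # drop the drug-gene edge: no cliques
  kg2 <- quiet_kg(recs$nodes, recs$edges[1:2, ])
  expect_equal(nrow(find_cliques(kg2)), 0)
})

test_that("filter_cliques applies the strict rank cutoff and exclusions", {
  cl <- tibble::tibble(
    birth_defect = c("HP:1", "HP:2", "HP:3"),
    gene = c("G1", "G2", "G3"),
    drug = c("D1", "D2", "D3"),
    bd_gene_resource = "r", bd_drug_resource = "r",
    drug_gene_relation = "upregulates"
  )
  ranks <- tibble::tibble(id = c("D1", "D2", "D3"),
                          rank = c(2999L, 3000L, 5L))
  out <- filter_cliques(cl, ranks, max_rank = 3000)
  expect_setequal(out$drug, c("D1", "D3"))      # 2999 kept, 3000 dropped
  out2 <- filter_cliques(cl, ranks, max_rank = 3000, exclude_known = "D3")
  expect_equal(out2$drug, "D1")                 # known drug dropped despite rank 5
  expect_error(filter_cliques(cl, ranks[1:2, ]), "D3")
})

test_that("gene_gene_edges matches brute force on small matrices", {
  brute <- function(corr, k) {
    genes <- rownames(corr)
    sel <- list()
    for (i in seq_along(genes)) {
      r <- corr[i, -i]
      partners <- rownames(corr)[-i]
      top <- partners[order(-r, partners)][seq_len(k)]
      bottom <- partners[order(r, partners)][seq_len(k)]
      for (p in union(top, bottom)) {
        key <- paste(min(genes[i], p), max(genes[i], p))
        sel[[key]] <- corr[genes[i], p]
      }
    }
    tibble::tibble(key = names(sel), weight = unname(unlist(sel))) |>
      dplyr::arrange(key)
  }
  for (seed in 1:8) {
    set.seed(seed)
    n <- sample(5:10, 1)
    k <- sample(1:3, 1)
    X <- matrix(rnorm(20 * n), ncol = n)
    corr <- cor(X)
    dimnames(corr) <- list(sprintf("g%02d", 1:n), sprintf("g%02d", 1:n))
    edges <- gene_gene_edges(corr, k = k)
    expect_equal(paste(edges$source, edges$target), brute(corr, k)$key)
    expect_equal(edges$weight, brute(corr, k)$weight)
    # transpose gives the same undirected edge set
    edges_t <- gene_gene_edges(t(corr), k = k)
    expect_equal(edges, edges_t)
  }
})

test_that("gene_gene_edges worked 3-gene example and relation labels", {
  corr <- matrix(c(1, 0.9, -0.8,
                   0.9, 1, 0.1,
                   -0.8, 0.1, 1), 3, byrow = TRUE,
                 dimnames = list(c("g1", "g2", "g3"), c("g1", "g2", "g3")))
  edges <- gene_gene_edges(corr, k = 1)
  expect_equal(nrow(edges), 3)
  key <- paste(edges$source, edges$target)
  expect_equal(edges$weight[key == "g1 g2"], 0.9)
  expect_equal(edges$relation[key == "g1 g2"], "pos_correlated")
  expect_equal(edges$weight[key == "g1 g3"], -0.8)
  expect_equal(edges$relation[key == "g1 g3"], "neg_correlated")
  # the mixed selection (g2's most-negative, g3's most-positive) appears once
  expect_equal(edges$weight[key == "g2 g3"], 0.1)
  expect_equal(edges$relation[key == "g2 g3"], "pos_correlated")
  expect_error(gene_gene_edges(corr, k = 3), "smaller")
  # all-equal correlations: ties by id, bounded edge count
  eq <- matrix(0.5, 4, 4, dimnames = list(paste0("g", 1:4), paste0("g", 1:4)))
  diag(eq) <- 1
  edges_eq <- gene_gene_edges(eq, k = 1)
  expect_lte(nrow(edges_eq), 4)
  expect_equal(anyDuplicated(paste(edges_eq$source, edges_eq$target)), 0L)
})

test_that("llr_overrepresentation follows the one-sided G-statistic", {
  expect_equal(llr_overrepresentation(30, 10, 10, 50), 35.55, tolerance = 0.01 / 35.55)
  # exact independence: G = 0
  expect_equal(llr_overrepresentation(20, 20, 20, 20), 0)
  expect_equal(llr_overrepresentation(10, 20, 20, 40), 0)
  # under-representation of the drug-and-term cell: clamped to 0
  expect_equal(llr_overrepresentation(5, 35, 35, 25), 0)
  # zero cells contribute nothing but zero margins are errors
  expect_gt(llr_overrepresentation(10, 0, 0, 10), 0)
  expect_error(llr_overrepresentation(0, 0, 5, 5), "margin")
  # monotone in the over-represented cell under compensating margins
  g <- sapply(0:5, function(delta) {
    llr_overrepresentation(30 + delta, 10 - delta, 10 - delta, 50 + delta)
  })
  expect_true(all(diff(g) > 0))
})

test_that("JSON export/import round-trips the graph exactly", {
  recs <- tiny_kg_records()
  kg <- quiet_kg(recs$nodes, recs$edges)
  dir <- withr::local_tempdir()
  path <- export_graph(kg, dir, "json")
  back <- read_kg_json(path)
  kg2 <- quiet_kg(back$nodes, back$edges)
  expect_equal(kg2$nodes$id, kg$nodes$id)
  expect_equal(kg2$nodes$type, kg$nodes$type)
  expect_equal(kg2$nodes$properties, kg$nodes$properties)
  expect_equal(kg2$edges, kg$edges)
  # NDJSON ingestion
  nd <- withr::local_tempfile(fileext = ".ndjson")
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  writeLines(vapply(c(doc$nodes, doc$edges),
                    jsonlite::toJSON, character(1),
                    auto_unbox = TRUE, digits = NA), nd)
  back_nd <- read_kg_json(nd)
  expect_equal(back_nd$nodes$id, kg$nodes$id)
  expect_equal(nrow(back_nd$edges), nrow(kg$edges))
})

test_that("csv bulk-load export writes one file per type and relation", {
  recs <- tiny_kg_records()
  kg <- quiet_kg(recs$nodes, recs$edges)
  dir <- withr::local_tempdir()
  files <- export_graph(kg, dir, "csv_bulkload")
  expect_length(files[grepl("nodes_", files)], 3)   # one per node type
  expect_length(files[grepl("edges_", files)], 3)   # one per relation
  nd <- readr::read_csv(file.path(dir, "nodes_Gene.csv"), show_col_types = FALSE)
  expect_true(all(c("id:ID", ":LABEL") %in% names(nd)))
  ed <- readr::read_csv(file.path(dir, "edges_HPO.csv"), show_col_types = FALSE)
  expect_equal(ed$`:START_ID`, "HP:0000001")
  # cypher export emits one MERGE per node and edge
  cy <- export_graph(kg, dir, "cypher_text")
  lines <- readLines(cy)
  expect_length(lines, nrow(kg$nodes) + nrow(kg$edges))
  expect_true(all(grepl("MERGE", lines)))
  # empty graph still exports valid (empty) files
  kg0 <- quiet_kg(recs$nodes[0, ], recs$edges[0, ])
  expect_no_error(export_graph(kg0, withr::local_tempdir(), "json"))
})
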