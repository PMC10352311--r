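# Shared fixtures built in code. Oracles live in the test files that use them.

# 3x3 worked similarity matrix used throughout the SSL tests
worked_sim <- function() {
  S <- matrix(c(1, .8, .2,
                .8, 1, .4,
                .2, .4, 1), nrow = 3, byrow = TRUE,
              dimnames = list(c("d1", "d2", "d3"), c("d1", "d2", "d3")))
  S
}

# a random symmetric similarity matrix with unit diagonal
random_sim <- function(n, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * 10), nrow = n)
  S <- tcrossprod(X / sqrt(rowSums(X^2)))
  ids <- sprintf("d%03d", seq_len(n))
  dimnames(S) <- list(ids, ids)
  S
}

# tiny KG fixture: explicit nodes/edges, one guaranteed triangle
tiny_kg_records <- function() {
  nodes <- tibble::tibble(
    id = c("HP:0000001", "HP:0000002", "G1", "G2", "D1", "D2"),
    type = c("BirthDefect", "BirthDefect", "Gene", "Gene", "Drug", "Drug"),
    properties = list(list(), list(meddra_code = "123"), list(pLI = 0.9),
                      list(), list(smiles = "CCO"), list())
  )
  edges <- tibble::tibble(
    source = c("HP:0000001", "HP:0000001", "D1"),
    target = c("G1", "D1", "G1"),
    relation = c("HPO", "Drugshot", "upregulates"),
    weight = NA_real_,
    resource = c("hpo", "lit", "expr")
  )
  list(nodes = nodes, edges = edges)
}

# random typed KG records for property-style tests
random_kg_records <- function(n_bd, n_gene, n_drug, density, seed) {
  set.seed(seed)
  bds <- sprintf("HP:%07d", seq_len(n_bd))
  genes <- sprintf("G%02d", seq_len(n_gene))
  drugs <- sprintf("D%02d", seq_len(n_drug))
  nodes <- tibble::tibble(
    id = c(bds, genes, drugs),
    type = rep(c("BirthDefect", "Gene", "Drug"), c(n_bd, n_gene, n_drug))
  )
  pick <- function(src, tgt, relation) {
    grid <- expand.grid(source = src, target = tgt, stringsAsFactors = FALSE)
    keep <- runif(nrow(grid)) < density
    tibble::tibble(source = grid$source[keep], target = grid$target[keep],
                   relation = relation)
  }
  edges <- dplyr::bind_rows(
    pick(bds, genes, "HPO"),
    pick(bds, drugs, "Drugshot"),
    pick(drugs, genes, "upregulates")
  )
  list(nodes = nodes, edges = edges)
}

# suppress the build_kg edge-count message in tests
quiet_kg <- function(nodes, edges, strict = TRUE) {
  suppressMessages(build_kg(nodes, edges, strict = strict))
}
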