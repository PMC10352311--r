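#' Parameters of the synthetic study conditions
#'
#' One object describing every planted-structure generator: the signature
#' matrix with a positive-drug cluster, the fingerprint matrix with a shared
#' scaffold among positives, the MOA pre-task, and the knowledge graph with
#' planted three-node cliques. Defaults are the package's reference study
#' conditions used throughout the tests.
#'
#' @param n_drugs number of drugs (default 200).
#' @param n_genes number of genes (default 500).
#' @param n_bits fingerprint length (default 2048).
#' @param n_positives size of the positive label set (default 20).
#' @param effect shift of the positive cluster along a random unit direction
#'   in signature space, in noise-SD units (default 3).
#' @param scaffold_bits number of fingerprint bits shared by all positives
#'   (default 30).
#' @param bit_flip_prob per-bit probability that a positive's scaffold bit is
#'   flipped off (default 0.1).
#' @param bit_density background Bernoulli density of fingerprint bits
#'   (default 0.05, mimicking sparse hashed fingerprints).
#' @param n_moa_classes number of MOA classes in the pre-task (default 6).
#' @param drugs_per_moa drugs per MOA class (default 15).
#' @param kg_sizes named vector of node counts
#'   (default c(BirthDefect = 10, Gene = 25, Drug = 25)).
#' @param kg_density background probability of each admissible edge
#'   (default 0.05).
#' @param n_planted_cliques guaranteed birth-defect/gene/drug triangles
#'   (default 5).
#' @param seed integer seed (default 1).
#' @return list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_drugs = 200, n_genes = 500, n_bits = 2048,
                           n_positives = 20, effect = 3, scaffold_bits = 30,
                           bit_flip_prob = 0.1, bit_density = 0.05,
                           n_moa_classes = 6, drugs_per_moa = 15,
                           kg_sizes = c(BirthDefect = 10, Gene = 25, Drug = 25),
                           kg_density = 0.05, n_planted_cliques = 5,
                           seed = 1L) {
  stopifnot(n_positives < n_drugs, scaffold_bits < n_bits,
            bit_flip_prob >= 0, bit_flip_prob <= 1,
            bit_density >= 0, bit_density <= 1, effect >= 0,
            all(kg_sizes > 0))
  structure(as.list(environment()), class = "synthetic_spec")
}

synth_ids <- function(prefix, n) sprintf("%s%03d", prefix, seq_len(n))

#' Generate a signature matrix with a planted positive cluster
#'
#' Background drugs draw iid standard-normal coefficients per gene; the
#' `n_positives` positive drugs share a random unit-direction centroid
#' scaled by `effect`, plus the same standard-normal noise, so with
#' `effect = 0` positives are exchangeable with the background.
#'
#' @param spec `synthetic_spec`.
#' @return list with `signatures` (validated signature matrix) and `labels`
#'   (`label_set` named "planted_positives").
#' @export
gen_signatures <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  drugs <- synth_ids("d", spec$n_drugs)
  genes <- synth_ids("g", spec$n_genes)
  mat <- matrix(stats::rnorm(spec$n_drugs * spec$n_genes),
                nrow = spec$n_drugs, dimnames = list(drugs, genes))
  centroid <- stats::rnorm(spec$n_genes)
  centroid <- centroid / sqrt(sum(centroid^2))
  pos <- drugs[seq_len(spec$n_positives)]
  mat[pos, ] <- mat[pos, ] +
    matrix(spec$effect * centroid, nrow = spec$n_positives,
           ncol = spec$n_genes, byrow = TRUE)
  validate_signature_matrix(mat)
  list(signatures = mat, labels = label_set("planted_positives", pos, drugs))
}

#' Generate a fingerprint matrix with a shared scaffold among positives
#'
#' All drugs draw iid Bernoulli(`bit_density`) background bits; positives
#' additionally set the same `scaffold_bits` randomly chosen bits, each then
#' flipped off independently with probability `bit_flip_prob`.
#'
#' @param spec `synthetic_spec`.
#' @return list with `fingerprints` (binary matrix, drugs x bits) and
#'   `labels` (`label_set`).
#' @export
gen_fingerprints <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed + 1L)
  drugs <- synth_ids("d", spec$n_drugs)
  bits <- matrix(
    stats::rbinom(spec$n_drugs * spec$n_bits, 1, spec$bit_density),
    nrow = spec$n_drugs,
    dimnames = list(drugs, NULL)
  )
  pos <- drugs[seq_len(spec$n_positives)]
  if (spec$scaffold_bits > 0) {
    scaffold <- sample.int(spec$n_bits, spec$scaffold_bits)
    for (d in pos) {
      keep <- stats::rbinom(spec$scaffold_bits, 1, 1 - spec$bit_flip_prob) == 1
      bits[d, scaffold[keep]] <- 1L
    }
  }
  storage.mode(bits) <- "integer"
  list(fingerprints = structure(bits, radius = 2L, n_bits = spec$n_bits),
       labels = label_set("planted_positives", pos, drugs))
}

#' Generate the MOA pre-task feature table
#'
#' Emulates the one-vs-rest mechanism-of-action classification pre-task:
#' for every (MOA task, drug) pair, modality scores are drawn so that class
#' members score higher on informative modalities (`N(separation, 1)` in
#' class vs `N(0, 1)` out of class) while noise modalities are `N(0, 1)`
#' everywhere.
#'
#' @param spec `synthetic_spec`.
#' @param informative logical vector over modalities (default: expression
#'   informative, structure noise).
#' @param separation class-mean shift of informative modalities (default 2).
#' @return list with `features` (tibble: `moa`, `drug_id`, `label`, one
#'   column per modality) and `moa_table` (tibble: `drug_id`, `moa`).
#' @export
gen_moa_dataset <- function(spec, informative = c(expression = TRUE, structure = FALSE),
                            separation = 2) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (spec$n_moa_classes < 2) stop("need at least 2 MOA classes")
  set.seed(spec$seed + 2L)
  n_drugs <- spec$n_moa_classes * spec$drugs_per_moa
  drugs <- synth_ids("m", n_drugs)
  moas <- sprintf("moa%02d", seq_len(spec$n_moa_classes))
  moa_table <- tibble::tibble(drug_id = drugs,
                              moa = rep(moas, each = spec$drugs_per_moa))
  features <- purrr::map_dfr(moas, function(m) {
    label <- as.integer(moa_table$moa == m)
    out <- tibble::tibble(moa = m, drug_id = drugs, label = label)
    for (mod in names(informative)) {
      mu <- if (informative[[mod]]) separation * label else 0
      out[[mod]] <- stats::rnorm(n_drugs, mean = mu)
    }
    out
  })
  list(features = features, moa_table = moa_table)
}

#' Generate knowledge-graph records with planted cliques
#'
#' Draws typed nodes with properties sampled in valid ranges (gene pLI/pHI/
#' pTS in [0, 1], drug ranks as integers), background edges of every
#' admissible relation at `kg_density`, and `n_planted_cliques` guaranteed
#' birth-defect/gene/drug triangles. Returns the planted triples as ground
#' truth for clique-recovery tests.
#'
#' @param spec `synthetic_spec`.
#' @return list with `nodes`, `edges` (record tibbles for [build_kg()]) and
#'   `planted` (tibble `birth_defect`, `gene`, `drug`).
#' @export
gen_kg <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed + 3L)
  sizes <- spec$kg_sizes
  bds <- sprintf("HP:%07d", seq_len(sizes[["BirthDefect"]]))
  genes <- synth_ids("GENE", sizes[["Gene"]])
  drugs <- synth_ids("CID", sizes[["Drug"]])
  nodes <- dplyr::bind_rows(
    tibble::tibble(id = bds, type = "BirthDefect",
                   properties = purrr::map(seq_along(bds), ~ list(
                     meddra_code = sprintf("%08d", sample.int(1e7, 1))))),
    tibble::tibble(id = genes, type = "Gene",
                   properties = purrr::map(seq_along(genes), ~ list(
                     pLI = stats::runif(1), pHI = stats::runif(1),
                     pTS = stats::runif(1), RVIS = stats::rnorm(1),
                     RVIS_percentile = stats::runif(1, 0, 100)))),
    tibble::tibble(id = drugs, type = "Drug",
                   properties = purrr::map(seq_along(drugs), ~ list(
                     placenta_crossing_score = stats::runif(1),
                     placenta_crossing_rank = sample.int(30000, 1))))
  )
  rand_edges <- function(src, tgt, relation, resource) {
    grid <- expand.grid(source = src, target = tgt, stringsAsFactors = FALSE)
    grid <- grid[grid$source != grid$target, ]
    keep <- stats::runif(nrow(grid)) < spec$kg_density
    tibble::tibble(source = grid$source[keep], target = grid$target[keep],
                   relation = relation, weight = NA_real_, resource = resource)
  }
  edges <- dplyr::bind_rows(
    rand_edges(bds, genes, "HPO", "hpo"),
    rand_edges(bds, drugs, "Drugshot", "literature"),
    rand_edges(drugs, genes, "upregulates", "expression")
  )
  planted <- tibble::tibble(
    birth_defect = sample(bds, spec$n_planted_cliques, replace = TRUE),
    gene = sample(genes, spec$n_planted_cliques, replace = TRUE),
    drug = sample(drugs, spec$n_planted_cliques, replace = TRUE)
  )
  planted <- dplyr::distinct(planted)
  edges <- dplyr::bind_rows(
    edges,
    tibble::tibble(source = planted$birth_defect, target = planted$gene,
                   relation = "HPO", weight = NA_real_, resource = "planted"),
    tibble::tibble(source = planted$birth_defect, target = planted$drug,
                   relation = "Drugshot", weight = NA_real_, resource = "planted"),
    tibble::tibble(source = planted$drug, target = planted$gene,
                   relation = "downregulates", weight = NA_real_, resource = "planted")
  )
  edges <- dplyr::distinct(edges, .data$source, .data$target, .data$relation,
                           .keep_all = TRUE)
  list(nodes = nodes, edges = edges,
       planted = dplyr::arrange(planted, .data$birth_defect, .data$gene, .data$drug))
}

#' Generate a gene-gene correlation matrix
#'
#' Correlations of iid Gaussian expression profiles across `n_samples`
#' pseudo-samples — a light null model whose off-diagonal structure is
#' random but symmetric and positive-semidefinite-consistent.
#'
#' @param spec `synthetic_spec` (uses `n_genes` capped at `max_genes`).
#' @param n_samples pseudo-samples used to form the correlations (default 50).
#' @param max_genes cap on matrix size (default 100).
#' @return `sim_matrix` with `kind = "correlation"`.
#' @export
gen_correlation_matrix <- function(spec, n_samples = 50, max_genes = 100) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed + 4L)
  g <- min(spec$n_genes, max_genes)
  expr <- matrix(stats::rnorm(n_samples * g), nrow = n_samples)
  corr <- stats::cor(expr)
  dimnames(corr) <- list(synth_ids("g", g), synth_ids("g", g))
  new_sim_matrix(corr, kind = "correlation")
}
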