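# Typed schema of the birth-defect/gene/drug knowledge graph.
# Relations are directional in storage (source type -> target type) but
# clique queries treat edges as undirected within a type pair.
kg_relations <- function() {
  tibble::tribble(
    ~relation,           ~source_type,  ~target_type,
    "HPO",               "BirthDefect", "Gene",
    "Geneshot",          "BirthDefect", "Gene",
    "FAERS",             "BirthDefect", "Drug",
    "Drugshot",          "BirthDefect", "Drug",
    "drug_target",       "Drug",        "Gene",
    "upregulates",       "Drug",        "Gene",
    "downregulates",     "Drug",        "Gene",
    "expression_cosine", "Drug",        "Drug",
    "pos_correlated",    "Gene",        "Gene",
    "neg_correlated",    "Gene",        "Gene"
  )
}

kg_node_types <- c("BirthDefect", "Gene", "Drug")

# property keys admitted per node type in strict mode
kg_property_keys <- list(
  BirthDefect = c("meddra_code"),
  Gene = c("pLI", "pHI", "pTS", "RVIS", "RVIS_percentile"),
  Drug = c("smiles", "placenta_crossing_score", "placenta_crossing_rank")
)

#' Assemble and validate the knowledge graph
#'
#' Takes typed node and edge records and returns a validated in-memory
#' graph. Node ids must be unique within their type; edge endpoints must
#' exist and match the relation's declared endpoint types; self-loops and
#' duplicate (source, target, relation) triples are rejected. In strict mode
#' unknown node property keys or dangling endpoints are errors; in lenient
#' mode dangling edges are dropped with a message.
#'
#' @param nodes tibble (or list of records) with columns `id`, `type`, and
#'   optionally `properties` (a list-column of named lists).
#' @param edges tibble with columns `source`, `target`, `relation`, and
#'   optionally `weight`, `resource`.
#' @param strict validation mode (default TRUE).
#' @return object of class `repro_kg`: list of tibbles `nodes`, `edges`.
#' @export
build_kg <- function(nodes, edges, strict = TRUE) {
  nodes <- tibble::as_tibble(nodes)
  edges <- tibble::as_tibble(edges)
  stopifnot(all(c("id", "type") %in% names(nodes)))
  if (!"properties" %in% names(nodes)) {
    nodes$properties <- purrr::map(seq_len(nrow(nodes)), ~ list())
  }
  if (nrow(edges) > 0) {
    stopifnot(all(c("source", "target", "relation") %in% names(edges)))
  } else {
    edges <- tibble::tibble(source = character(), target = character(),
                            relation = character(), weight = numeric(),
                            resource = character())
  }
  if (!"weight" %in% names(edges)) edges$weight <- NA_real_
  if (!"resource" %in% names(edges)) edges$resource <- NA_character_

  bad_type <- setdiff(unique(nodes$type), kg_node_types)
  if (length(bad_type) > 0) stop("unknown node type(s): ", paste(bad_type, collapse = ", "))
  dup <- nodes[duplicated(nodes[, c("id", "type")]), ]
  if (nrow(dup) > 0) stop("duplicate node id(s): ", paste(dup$id, collapse = ", "))

  if (strict) {
    purrr::pwalk(nodes[, c("id", "type", "properties")], function(id, type, properties) {
      unknown <- setdiff(names(properties), kg_property_keys[[type]])
      if (length(unknown) > 0) {
        stop("node ", id, ": unknown property key(s): ", paste(unknown, collapse = ", "))
      }
    })
  }

  rel <- kg_relations()
  bad_rel <- setdiff(unique(edges$relation), rel$relation)
  if (length(bad_rel) > 0) stop("unknown relation(s): ", paste(bad_rel, collapse = ", "))

  if (nrow(edges) > 0) {
    edges <- dplyr::left_join(edges, rel, by = "relation")
    node_key <- paste(nodes$type, nodes$id)
    dangling <- !(paste(edges$source_type, edges$source) %in% node_key) |
                !(paste(edges$target_type, edges$target) %in% node_key)
    if (any(dangling)) {
      who <- unique(c(edges$source[dangling], edges$target[dangling]))
      if (strict) stop("edge endpoint(s) missing from nodes: ", paste(who, collapse = ", "))
      message("build_kg: dropping ", sum(dangling), " dangling edge(s)")
      edges <- edges[!dangling, ]
    }
    if (any(edges$source == edges$target)) stop("self-loop edge(s) not allowed")
    key <- paste(edges$source, edges$target, edges$relation)
    if (anyDuplicated(key)) {
      stop("duplicate (source, target, relation) edge(s): ",
           paste(unique(key[duplicated(key)]), collapse = "; "))
    }
    edges <- edges[, c("source", "target", "relation", "weight", "resource")]
  }

  kg <- structure(list(nodes = nodes, edges = edges), class = "repro_kg")
  counts <- dplyr::count(edges, .data$relation)
  message("build_kg: ", nrow(nodes), " nodes, ", nrow(edges), " edges (",
          paste(sprintf("%s=%d", counts$relation, counts$n), collapse = ", "), ")")
  kg
}

#' @export
print.repro_kg <- function(x, ...) {
  tc <- table(x$nodes$type)
  cat(sprintf("<repro_kg: %d nodes (%s), %d edges>\n", nrow(x$nodes),
              paste(sprintf("%s=%d", names(tc), tc), collapse = ", "),
              nrow(x$edges)))
  invisible(x)
}

#' Gene-gene co-expression edges from a correlation matrix
#'
#' For each gene, selects its `k` most positively and `k` most negatively
#' correlated partner genes as a pure order statistic on the correlation
#' coefficients (the "most negative" partners are the k smallest r values,
#' whatever their sign); the diagonal is ignored and ties break by ascending
#' partner id. Selections from both endpoints of a pair are deduplicated to
#' a single undirected edge. Each edge is weighted by r; the relation label
#' records the sign of r (`pos_correlated` for r >= 0, `neg_correlated`
#' otherwise) so consumers can filter on true anticorrelation.
#'
#' @param corr square symmetric correlation matrix with gene ids as dimnames.
#' @param k partners per direction per gene (default 5); must be < number of
#'   genes.
#' @return edge tibble (`source`, `target`, `relation`, `weight`,
#'   `resource`) with `source < target` and deterministic row order.
#' @export
gene_gene_edges <- function(corr, k = 5) {
  genes <- rownames(corr)
  n <- length(genes)
  if (k >= n) stop("k must be smaller than the number of genes")
  picks <- purrr::map_dfr(seq_len(n), function(i) {
    r <- corr[i, -i]
    partners <- genes[-i]
    top <- order(-r, partners)[seq_len(k)]
    bottom <- order(r, partners)[seq_len(k)]
    sel <- unique(c(top, bottom))
    tibble::tibble(a = genes[i], b = partners[sel], weight = as.numeric(r[sel]))
  })
  und <- dplyr::mutate(picks,
    source = pmin(.data$a, .data$b),
    target = pmax(.data$a, .data$b)
  )
  und <- dplyr::distinct(und, .data$source, .data$target, .data$weight)
  dplyr::arrange(
    dplyr::transmute(und,
      source = .data$source, target = .data$target,
      relation = ifelse(.data$weight >= 0, "pos_correlated", "neg_correlated"),
      weight = .data$weight, resource = "coexpression"
    ),
    .data$source, .data$target
  )
}

#' Log-likelihood-ratio over-representation statistic (one-sided G-test)
#'
#' For a 2x2 contingency table of report counts
#' (`a` = term & drug, `b` = term & no drug, `c` = drug & no term,
#' `d` = neither), computes the G statistic `2 * sum(O * ln(O / E))` with
#' independence expectations E. Cells with O = 0 contribute 0. The statistic
#' is one-sided for over-representation: when the term-and-drug cell falls
#' below its expectation the function returns 0.
#'
#' @param a,b,c,d non-negative integer counts; all row/column margins must
#'   be positive.
#' @return the G statistic (0 under exact independence or
#'   under-representation).
#' @examples
#' llr_overrepresentation(30, 10, 10, 50)  # 35.55
#' @export
llr_overrepresentation <- function(a, b, c, d) {
  O <- c(a, b, c, d)
  stopifnot(all(O >= 0), all(O == round(O)))
  n <- sum(O)
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  if (any(c(r1, r2, c1, c2) == 0)) stop("zero margin in 2x2 table")
  E <- c(r1 * c1, r1 * c2, r2 * c1, r2 * c2) / n
  if (a < E[1]) return(0)
  terms <- ifelse(O == 0, 0, O * log(O / E))
  2 * sum(terms)
}

#' Extract all birth-defect/gene/drug three-node cliques
#'
#' Finds every triple (birth defect, gene, drug) such that the graph holds a
#' birth-defect--gene edge, a birth-defect--drug edge, and a drug--gene edge
#' (any relation of the matching type pair, either storage direction). Each
#' clique is reported once, with the resources/relations of its three
#' supporting edges, sorted by (birth_defect, gene, drug) id.
#'
#' @param kg `repro_kg`.
#' @return tibble with columns `birth_defect`, `gene`, `drug`,
#'   `bd_gene_resource`, `bd_drug_resource`, `drug_gene_relation`.
#' @export
find_cliques <- function(kg) {
  e <- dplyr::left_join(kg$edges, kg_relations(), by = "relation")
  empty <- tibble::tibble(birth_defect = character(), gene = character(),
                          drug = character(), bd_gene_resource = character(),
                          bd_drug_resource = character(),
                          drug_gene_relation = character())
  if (nrow(e) == 0) return(empty)
  bd_gene <- dplyr::transmute(
    dplyr::filter(e, .data$source_type == "BirthDefect" & .data$target_type == "Gene"),
    birth_defect = .data$source, gene = .data$target,
    bd_gene_resource = .data$resource)
  bd_drug <- dplyr::transmute(
    dplyr::filter(e, .data$source_type == "BirthDefect" & .data$target_type == "Drug"),
    birth_defect = .data$source, drug = .data$target,
    bd_drug_resource = .data$resource)
  dg <- dplyr::filter(e, (.data$source_type == "Drug" & .data$target_type == "Gene"))
  drug_gene <- dplyr::transmute(dg, drug = .data$source, gene = .data$target,
                                drug_gene_relation = .data$relation)
  if (nrow(bd_gene) == 0 || nrow(bd_drug) == 0 || nrow(drug_gene) == 0) return(empty)
  # one row per unordered pair even if multiple relations support it
  bd_gene <- dplyr::slice_head(dplyr::group_by(bd_gene, .data$birth_defect, .data$gene), n = 1)
  bd_drug <- dplyr::slice_head(dplyr::group_by(bd_drug, .data$birth_defect, .data$drug), n = 1)
  drug_gene <- dplyr::slice_head(dplyr::group_by(drug_gene, .data$drug, .data$gene), n = 1)
  out <- dplyr::inner_join(dplyr::ungroup(bd_gene), dplyr::ungroup(bd_drug),
                           by = "birth_defect", relationship = "many-to-many")
  out <- dplyr::inner_join(out, dplyr::ungroup(drug_gene), by = c("drug", "gene"))
  dplyr::arrange(
    out[, c("birth_defect", "gene", "drug", "bd_gene_resource",
            "bd_drug_resource", "drug_gene_relation")],
    .data$birth_defect, .data$gene, .data$drug
  )
}

#' Filter cliques by predicted drug rank and known-positive exclusion
#'
#' Keeps cliques whose drug has a predicted rank strictly below `max_rank`
#' (default 3000) and is not in the known-positive exclusion set — the
#' "novel, highly-ranked" filter.
#'
#' @param cliques tibble from [find_cliques()].
#' @param ranks ranked tibble (columns `id`, `rank`) covering every clique
#'   drug.
#' @param max_rank strict upper bound on the drug rank (default 3000).
#' @param exclude_known character vector of drug ids to drop (e.g. drugs
#'   already known to cross the placenta).
#' @return filtered clique tibble with a `drug_rank` column added.
#' @export
filter_cliques <- function(cliques, ranks, max_rank = 3000,
                           exclude_known = character()) {
  missing <- setdiff(unique(cliques$drug), ranks$id)
  if (length(missing) > 0) {
    stop("no rank for drug(s): ", paste(missing, collapse = ", "))
  }
  out <- dplyr::mutate(cliques, drug_rank = ranks$rank[match(.data$drug, ranks$id)])
  dplyr::filter(out, .data$drug_rank < max_rank, !.data$drug %in% exclude_known)
}

# ---- serialization --------------------------------------------------------

#' Export the knowledge graph
#'
#' * `json`: a single file with `nodes` and `edges` arrays in the ingestion
#'   schema (`{"id", "type", "properties"}` / `{"source", "target",
#'   "relation", "weight", "resource"}`); round-trips losslessly through
#'   [read_kg_json()] + [build_kg()].
#' * `csv_bulkload`: one node CSV per node type (`nodes_<type>.csv`) and one
#'   edge CSV per relation (`edges_<relation>.csv`) with bulk-import style
#'   headers (`id:ID`, `:START_ID`, `:END_ID`, `:TYPE`).
#' * `cypher_text`: a text file of MERGE statements.
#'
#' @param kg `repro_kg`.
#' @param dir output directory (created if needed).
#' @param format one of `"json"`, `"csv_bulkload"`, `"cypher_text"`.
#' @return character vector of the files written.
#' @export
export_graph <- function(kg, dir, format = c("json", "csv_bulkload", "cypher_text")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  switch(format,
    json = {
      path <- file.path(dir, "kg.json")
      recs <- list(
        nodes = purrr::pmap(kg$nodes, function(id, type, properties) {
          list(id = id, type = type, properties = properties)
        }),
        edges = purrr::pmap(kg$edges, function(source, target, relation, weight, resource) {
          rec <- list(source = source, target = target, relation = relation)
          if (!is.na(weight)) rec$weight <- weight
          if (!is.na(resource)) rec$resource <- resource
          rec
        })
      )
      jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA, null = "null")
      path
    },
    csv_bulkload = {
      files <- character()
      for (ty in unique(kg$nodes$type)) {
        sub <- kg$nodes[kg$nodes$type == ty, ]
        keys <- sort(unique(unlist(purrr::map(sub$properties, names))))
        df <- tibble::tibble(`id:ID` = sub$id, `:LABEL` = ty)
        for (k in keys) {
          df[[k]] <- purrr::map_chr(sub$properties,
                                    ~ if (is.null(.x[[k]])) NA_character_ else as.character(.x[[k]]))
        }
        f <- file.path(dir, paste0("nodes_", ty, ".csv"))
        readr::write_csv(df, f, progress = FALSE)
        files <- c(files, f)
      }
      for (rl in unique(kg$edges$relation)) {
        sub <- kg$edges[kg$edges$relation == rl, ]
        df <- tibble::tibble(`:START_ID` = sub$source, `:END_ID` = sub$target,
                             `:TYPE` = rl, weight = sub$weight,
                             resource = sub$resource)
        f <- file.path(dir, paste0("edges_", rl, ".csv"))
        readr::write_csv(df, f, progress = FALSE)
        files <- c(files, f)
      }
      files
    },
    cypher_text = {
      path <- file.path(dir, "kg.cypher")
      q <- function(x) gsub("'", "\\\\'", x)
      node_lines <- purrr::pmap_chr(kg$nodes, function(id, type, properties) {
        props <- c(sprintf("id: '%s'", q(id)),
                   purrr::imap_chr(properties, function(v, k) {
                     if (is.numeric(v)) sprintf("%s: %s", k, format(v, digits = 15))
                     else sprintf("%s: '%s'", k, q(as.character(v)))
                   }))
        sprintf("MERGE (:%s {%s});", type, paste(props, collapse = ", "))
      })
      edge_lines <- purrr::pmap_chr(kg$edges, function(source, target, relation, weight, resource) {
        rel <- dplyr::filter(kg_relations(), .data$relation == !!relation)
        props <- character()
        if (!is.na(weight)) props <- c(props, sprintf("weight: %s", format(weight, digits = 15)))
        if (!is.na(resource)) props <- c(props, sprintf("resource: '%s'", q(resource)))
        pstr <- if (length(props)) sprintf(" {%s}", paste(props, collapse = ", ")) else ""
        sprintf("MATCH (a:%s {id: '%s'}), (b:%s {id: '%s'}) MERGE (a)-[:%s%s]->(b);",
                rel$source_type, q(source), rel$target_type, q(target),
                relation, pstr)
      })
      writeLines(c(node_lines, edge_lines), path)
      path
    }
  )
}

#' Read knowledge-graph records from JSON
#'
#' Accepts the single-document schema written by [export_graph()] as well as
#' newline-delimited JSON (one node or edge record per line, distinguished
#' by the presence of a `source` key).
#'
#' @param path JSON or NDJSON file.
#' @return list with `nodes` and `edges` tibbles, ready for [build_kg()].
#' @export
read_kg_json <- function(path) {
  first <- trimws(readLines(path, n = 1))
  if (startsWith(first, "{") && !grepl("\"nodes\"", first)) {
    recs <- purrr::map(readLines(path), jsonlite::fromJSON, simplifyVector = FALSE)
    is_edge <- purrr::map_lgl(recs, ~ "source" %in% names(.x))
    doc <- list(nodes = recs[!is_edge], edges = recs[is_edge])
  } else {
    doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  }
  nodes <- tibble::tibble(
    id = purrr::map_chr(doc$nodes, "id"),
    type = purrr::map_chr(doc$nodes, "type"),
    properties = purrr::map(doc$nodes, ~ .x$properties %||% list())
  )
  edges <- tibble::tibble(
    source = purrr::map_chr(doc$edges, "source"),
    target = purrr::map_chr(doc$edges, "target"),
    relation = purrr::map_chr(doc$edges, "relation"),
    weight = purrr::map_dbl(doc$edges, ~ .x$weight %||% NA_real_),
    resource = purrr::map_chr(doc$edges, ~ .x$resource %||% NA_character_)
  )
  list(nodes = nodes, edges = edges)
}

#' Write cliques as TSV
#'
#' @param cliques tibble from [filter_cliques()] (or [find_cliques()]; a
#'   missing `drug_rank` column is written as NA).
#' @param path output file.
#' @export
write_cliques_tsv <- function(cliques, path) {
  if (!"drug_rank" %in% names(cliques)) cliques$drug_rank <- NA_integer_
  readr::write_tsv(
    cliques[, c("birth_defect", "gene", "drug", "bd_gene_resource",
                "bd_drug_resource", "drug_gene_relation", "drug_rank")],
    path, progress = FALSE)
  invisible(path)
}
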