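#' Validate a drug-by-gene signature matrix
#'
#' A signature matrix holds one differential-expression coefficient vector
#' (e.g. a characteristic-direction vector) per drug: rows are drugs, columns
#' are genes. Row and column names carry the identifiers and must be unique;
#' all values must be finite.
#'
#' @param mat numeric matrix with unique rownames (drug ids) and colnames
#'   (gene ids).
#' @return the matrix, invisibly, after validation.
#' @export
validate_signature_matrix <- function(mat) {
  stopifnot(is.matrix(mat), is.numeric(mat))
  if (is.null(rownames(mat)) || is.null(colnames(mat))) {
    stop("signature matrix needs drug ids as rownames and gene ids as colnames")
  }
  if (anyDuplicated(rownames(mat))) stop("duplicate drug ids")
  if (anyDuplicated(colnames(mat))) stop("duplicate gene ids")
  if (!all(is.finite(mat))) stop("signature matrix contains non-finite values")
  invisible(mat)
}

#' Consensus signature of a drug across replicate conditions
#'
#' Collapses the per-condition signatures of one drug (cell lines, time
#' points, doses) into a single consensus vector by the unweighted
#' element-wise arithmetic mean.
#'
#' @param reps list of numeric vectors over a shared gene axis, or a numeric
#'   matrix with one replicate per row.
#' @return numeric vector of the same length as each replicate. Names are
#'   taken from the first replicate when present.
#' @examples
#' consensus_signature(list(c(1, 3), c(3, 5)))  # (2, 4)
#' @export
consensus_signature <- function(reps) {
  if (is.matrix(reps)) reps <- asplit(reps, 1)
  if (length(reps) == 0) stop("no replicates")
  lens <- lengths(reps)
  if (length(unique(lens)) != 1) {
    stop("replicate vectors have mismatched lengths: ", paste(unique(lens), collapse = ", "))
  }
  reps <- lapply(reps, as.numeric)
  if (!all(vapply(reps, function(v) all(is.finite(v)), logical(1)))) {
    stop("replicate vectors contain non-finite values")
  }
  out <- Reduce(`+`, reps) / length(reps)
  out
}

#' Build consensus signatures for many drugs
#'
#' @param replicate_mat numeric matrix of replicate-level signatures
#'   (replicates x genes) with gene ids as colnames.
#' @param drug_ids character vector assigning each row to a drug.
#' @return a validated signature matrix with one consensus row per drug, in
#'   first-appearance order of `drug_ids`.
#' @export
consensus_matrix <- function(replicate_mat, drug_ids) {
  stopifnot(is.matrix(replicate_mat), length(drug_ids) == nrow(replicate_mat))
  drugs <- unique(drug_ids)
  out <- t(vapply(
    drugs,
    function(d) consensus_signature(replicate_mat[drug_ids == d, , drop = FALSE]),
    numeric(ncol(replicate_mat))
  ))
  rownames(out) <- drugs
  colnames(out) <- colnames(replicate_mat)
  validate_signature_matrix(out)
  out
}

#' Top up- and down-regulated genes of a signature
#'
#' Pure order statistic on the coefficient vector: `up` holds the gene ids of
#' the `k` largest values, `down` the `k` smallest. Ties are broken by
#' ascending gene id over a single full ordering (value descending, id
#' ascending), with `down` read from the bottom of that ordering, so the two
#' sets can never overlap. Zeros are eligible like any other value.
#'
#' If `2 * k` exceeds the number of genes a warning is raised and the genes
#' are split without overlap by rank position: the top half (rounded up) go
#' to `up`, the rest to `down`.
#'
#' @param signature named numeric vector (names are gene ids).
#' @param k number of genes per direction (default 25).
#' @return list with character vectors `up` and `down` (most extreme first)
#'   and the effective `k`.
#' @export
top_k_genes <- function(signature, k = 25) {
  stopifnot(k >= 1, !is.null(names(signature)))
  n <- length(signature)
  ord <- names(signature)[order(-signature, names(signature))]
  if (2 * k > n) {
    warning("k = ", k, " exceeds half the gene axis (", n, " genes); ",
            "splitting all genes by rank position")
    n_up <- ceiling(n / 2)
    return(list(up = ord[seq_len(n_up)], down = rev(ord)[seq_len(n - n_up)], k = k))
  }
  list(up = ord[seq_len(k)], down = rev(ord)[seq_len(k)], k = k)
}

#' Per-drug up/down gene sets for a whole signature matrix
#'
#' @param mat signature matrix (drugs x genes).
#' @inheritParams top_k_genes
#' @return tibble with columns `drug_id`, `direction` ("up"/"down") and a
#'   `genes` list-column, two rows per drug.
#' @export
gene_set_pairs <- function(mat, k = 25) {
  validate_signature_matrix(mat)
  rows <- purrr::map(rownames(mat), function(d) {
    sets <- top_k_genes(mat[d, ], k = k)
    tibble::tibble(
      drug_id = d,
      direction = c("up", "down"),
      genes = list(sets$up, sets$down)
    )
  })
  dplyr::bind_rows(rows)
}

#' Expression-based drug-drug cosine similarity
#'
#' S[i, j] is the cosine of the angle between the consensus signatures of
#' drugs i and j. Drugs whose signature is identically zero have no
#' direction: their row, column and diagonal entry are set to 0 and their ids
#' are attached as attribute `zero_rows` (with a warning), so downstream
#' scoring can drop them.
#'
#' @param mat signature matrix (drugs x genes), at least 2 drugs.
#' @return square symmetric similarity matrix with class `sim_matrix` and
#'   attribute `kind = "expression_cosine"`.
#' @export
cosine_similarity_matrix <- function(mat) {
  validate_signature_matrix(mat)
  if (nrow(mat) < 2) stop("need at least 2 drugs")
  norms <- sqrt(rowSums(mat^2))
  zero <- norms == 0
  safe <- ifelse(zero, 1, norms)
  S <- tcrossprod(mat / safe)
  # clamp numerical overshoot, then zero out degenerate drugs
  S[S > 1] <- 1
  S[S < -1] <- -1
  if (any(zero)) {
    warning("all-zero signature row(s): ", paste(rownames(mat)[zero], collapse = ", "))
    S[zero, ] <- 0
    S[, zero] <- 0
  }
  diag(S) <- ifelse(zero, 0, 1)
  new_sim_matrix(S, kind = "expression_cosine", zero_rows = rownames(mat)[zero])
}

new_sim_matrix <- function(S, kind, zero_rows = character()) {
  stopifnot(nrow(S) == ncol(S))
  structure(S, kind = kind, zero_rows = zero_rows,
            class = c("sim_matrix", class(S)))
}

#' @export
print.sim_matrix <- function(x, ...) {
  cat(sprintf("<sim_matrix kind=%s, %d ids>\n", attr(x, "kind"), nrow(x)))
  print(unclass(x)[seq_len(min(6, nrow(x))), seq_len(min(6, ncol(x))), drop = FALSE])
  invisible(x)
}

#' Align two matrices on a shared gene axis
#'
#' Intersects the column (gene) axes of two signature matrices and returns
#' both restricted to the common genes, in the first matrix's order. Dropped
#' genes are reported via `message()`.
#'
#' @param a,b signature matrices.
#' @return list with elements `a` and `b`.
#' @export
align_gene_axes <- function(a, b) {
  common <- intersect(colnames(a), colnames(b))
  if (length(common) == 0) stop("no shared genes")
  dropped <- length(union(colnames(a), colnames(b))) - length(common)
  if (dropped > 0) message("align_gene_axes: dropping ", dropped, " unshared gene(s)")
  list(a = a[, common, drop = FALSE], b = b[, common, drop = FALSE])
}

# ---- I/O ------------------------------------------------------------------

#' Read / write a signature matrix as TSV
#'
#' Layout: header row of gene ids, first column `drug_id`, one row per drug.
#'
#' @param path file path.
#' @return `read_signature_tsv`: validated signature matrix.
#' @export
read_signature_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df[[1]]
  storage.mode(mat) <- "double"
  validate_signature_matrix(mat)
  mat
}

#' @param mat signature matrix.
#' @rdname read_signature_tsv
#' @export
write_signature_tsv <- function(mat, path) {
  validate_signature_matrix(mat)
  df <- tibble::as_tibble(mat, rownames = "drug_id")
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Read / write a signature matrix as HDF5
#'
#' Datasets: `ids` (drugs), `gene_ids`, and `matrix` (drugs x genes).
#'
#' @param path file path; overwritten if it exists (write).
#' @return `read_signature_h5`: validated signature matrix.
#' @export
read_signature_h5 <- function(path) {
  ids <- as.character(rhdf5::h5read(path, "ids"))
  gene_ids <- as.character(rhdf5::h5read(path, "gene_ids"))
  mat <- rhdf5::h5read(path, "matrix")
  dimnames(mat) <- list(ids, gene_ids)
  validate_signature_matrix(mat)
  mat
}

#' @param mat signature matrix.
#' @rdname read_signature_h5
#' @export
write_signature_h5 <- function(mat, path) {
  validate_signature_matrix(mat)
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5write(rownames(mat), path, "ids")
  rhdf5::h5write(colnames(mat), path, "gene_ids")
  rhdf5::h5write(unname(mat), path, "matrix")
  rhdf5::h5closeAll()
  invisible(path)
}

#' Export per-drug gene sets in GMT format
#'
#' Two lines per drug, set names `<drug_id>_up` / `<drug_id>_down`, empty
#' description field.
#'
#' @param pairs tibble from [gene_set_pairs()].
#' @param path output file.
#' @export
write_gmt <- function(pairs, path) {
  lines <- purrr::pmap_chr(pairs, function(drug_id, direction, genes) {
    paste(c(paste0(drug_id, "_", direction), "", genes), collapse = "\t")
  })
  writeLines(lines, path)
  invisible(path)
}
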