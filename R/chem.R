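#' Read a SMILES file
#'
#' One record per line, `SMILES<TAB>drug_id`; lines starting with `#` and
#' blank lines are ignored.
#'
#' @param path file path.
#' @return tibble with columns `drug_id`, `smiles`.
#' @export
read_smiles <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 2
  if (any(bad)) stop("malformed SMILES line(s): ", paste(which(bad), collapse = ", "))
  tibble::tibble(
    drug_id = vapply(parts, `[[`, character(1), 2),
    smiles = vapply(parts, `[[`, character(1), 1)
  )
}

#' Circular fingerprints for a batch of SMILES
#'
#' Hashes each molecule into a fixed-length binary substructure fingerprint
#' of the extended-connectivity (Morgan) family, via OpenBabel's ECFP
#' implementation (`ECFP<2*radius>`), folded down to `n_bits`. The same
#' SMILES always yields the same bit vector. Unparseable SMILES are dropped
#' with a warning naming the record; the batch continues.
#'
#' @param smiles character vector of SMILES strings.
#' @param drug_ids unique identifiers, one per SMILES.
#' @param radius neighborhood radius of the circular fingerprint (default 2,
#'   the ECFP4-equivalent community standard).
#' @param n_bits fingerprint length after folding (default 2048). Must be a
#'   power-of-two divisor of 4096.
#' @return binary matrix (drugs x bits) with `drug_ids` as rownames and
#'   attributes `radius` and `n_bits`; dropped records are absent from the
#'   rows and listed in attribute `dropped`.
#' @export
fingerprint_matrix <- function(smiles, drug_ids, radius = 2, n_bits = 2048) {
  stopifnot(length(smiles) == length(drug_ids), !anyDuplicated(drug_ids),
            radius >= 1, n_bits >= 1)
  if (4096 %% n_bits != 0 || bitwAnd(n_bits, n_bits - 1L) != 0) {
    stop("n_bits must be a power-of-two divisor of 4096")
  }
  names(smiles) <- drug_ids
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(smiles))
  kept <- ChemmineR::cid(sdf)
  dropped <- setdiff(drug_ids, kept)
  if (length(dropped) > 0) {
    warning("unparseable SMILES dropped: ", paste(dropped, collapse = ", "))
  }
  if (length(kept) == 0) stop("no parseable SMILES")
  fp <- ChemmineR::fingerprintOB(sdf, paste0("ECFP", 2 * radius))
  while (ChemmineR::numBits(fp) > n_bits) fp <- ChemmineR::fold(fp)
  bits <- ChemmineR::as.matrix(fp)
  storage.mode(bits) <- "integer"
  rownames(bits) <- kept
  structure(bits[match(intersect(drug_ids, kept), kept), , drop = FALSE],
            radius = radius, n_bits = n_bits, dropped = dropped)
}

#' Inverse-document-frequency bit weights
#'
#' Each fingerprint bit is weighted by how rare it is across the compound
#' collection: `idf[j] = ln(N / df[j])` where `df[j]` counts the compounds
#' with bit j set. Bits set in every compound (df == N) or in none (df == 0)
#' get weight 0, so ubiquitous substructures carry no information. The
#' smoothed variant uses `ln(N / (1 + df))`, floored at 0.
#'
#' @param fps binary fingerprint matrix (drugs x bits).
#' @param variant `"plain"` (default) or `"smoothed"`.
#' @return list with numeric `idf` and integer `document_frequency`, one
#'   entry per bit.
#' @export
idf_weights <- function(fps, variant = c("plain", "smoothed")) {
  variant <- match.arg(variant)
  n <- nrow(fps)
  df <- colSums(fps > 0)
  idf <- switch(variant,
    plain = ifelse(df == 0, 0, log(n / df)),
    smoothed = pmax(0, ifelse(df == 0, 0, log(n / (1 + df))))
  )
  list(idf = as.numeric(idf), document_frequency = as.integer(df))
}

#' Structure-based drug-drug similarity with IDF bit weighting
#'
#' Similarity between two compounds is the cosine between their IDF-weighted
#' fingerprint vectors, so rare substructure bits dominate and ubiquitous
#' bits are ignored entirely. Compounds whose weighted vector is all zero
#' (only ubiquitous or no bits) get similarity 0 to everything, diagonal
#' included, and are flagged in attribute `zero_rows`.
#'
#' @param fps binary fingerprint matrix (drugs x bits), >= 2 drugs.
#' @inheritParams idf_weights
#' @return `sim_matrix` with `kind = "structure_idf"`.
#' @export
idf_similarity_matrix <- function(fps, variant = c("plain", "smoothed")) {
  if (is.null(dim(fps)) || nrow(fps) == 0 || ncol(fps) == 0) stop("empty fingerprint matrix")
  if (nrow(fps) < 2) stop("need at least 2 drugs")
  w <- idf_weights(fps, variant)
  weighted <- sweep(fps, 2, w$idf, `*`)
  norms <- sqrt(rowSums(weighted^2))
  zero <- norms == 0
  safe <- ifelse(zero, 1, norms)
  S <- tcrossprod(weighted / safe)
  S[S > 1] <- 1
  if (any(zero)) {
    S[zero, ] <- 0
    S[, zero] <- 0
  }
  diag(S) <- ifelse(zero, 0, 1)
  dimnames(S) <- list(rownames(fps), rownames(fps))
  new_sim_matrix(S, kind = "structure_idf", zero_rows = rownames(fps)[zero])
}

#' Tanimoto (Jaccard) drug-drug similarity
#'
#' Baseline structural similarity: shared bits over union of bits. Compounds
#' with empty fingerprints get similarity 0 everywhere (diagonal 0).
#'
#' @param fps binary fingerprint matrix (drugs x bits).
#' @return `sim_matrix` with `kind = "structure_tanimoto"`.
#' @export
tanimoto_matrix <- function(fps) {
  if (is.null(dim(fps)) || nrow(fps) == 0) stop("empty fingerprint matrix")
  A <- matrix(as.numeric(fps > 0), nrow = nrow(fps))
  inter <- tcrossprod(A)
  sizes <- rowSums(A)
  un <- outer(sizes, sizes, `+`) - inter
  S <- ifelse(un == 0, 0, inter / un)
  empty <- sizes == 0
  diag(S) <- ifelse(empty, 0, 1)
  dimnames(S) <- list(rownames(fps), rownames(fps))
  new_sim_matrix(S, kind = "structure_tanimoto", zero_rows = rownames(fps)[empty])
}

#' Fingerprint cache in HDF5
#'
#' Datasets `ids` and `bits` plus scalar datasets `radius` and `n_bits`.
#'
#' @param fps fingerprint matrix from [fingerprint_matrix()].
#' @param path file path.
#' @export
write_fingerprints_h5 <- function(fps, path) {
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5write(rownames(fps), path, "ids")
  rhdf5::h5write(unname(fps), path, "bits")
  rhdf5::h5write(as.integer(attr(fps, "radius") %||% 2L), path, "radius")
  rhdf5::h5write(as.integer(attr(fps, "n_bits") %||% ncol(fps)), path, "n_bits")
  rhdf5::h5closeAll()
  invisible(path)
}

#' @rdname write_fingerprints_h5
#' @export
read_fingerprints_h5 <- function(path) {
  ids <- as.character(rhdf5::h5read(path, "ids"))
  bits <- rhdf5::h5read(path, "bits")
  storage.mode(bits) <- "integer"
  rownames(bits) <- ids
  structure(bits,
            radius = as.integer(rhdf5::h5read(path, "radius")),
            n_bits = as.integer(rhdf5::h5read(path, "n_bits")))
}
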