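#' Labeled positive set within a drug universe
#'
#' @param name label name, e.g. `"placenta_crossing"`, `"category_D"`,
#'   `"category_X"`.
#' @param positives character vector of positive drug ids (deduplicated).
#' @param universe ordered character vector of all drug ids.
#' @return object of class `label_set`.
#' @export
label_set <- function(name, positives, universe) {
  positives <- unique(as.character(positives))
  universe <- as.character(universe)
  if (anyDuplicated(universe)) stop("duplicate ids in universe")
  if (length(positives) < 1) stop("need at least one positive")
  missing <- setdiff(positives, universe)
  if (length(missing) > 0) {
    stop("positives not in universe: ", paste(missing, collapse = ", "))
  }
  structure(list(name = name, positives = positives, universe = universe),
            class = "label_set")
}

#' @export
print.label_set <- function(x, ...) {
  cat(sprintf("<label_set '%s': %d positives / %d drugs>\n",
              x$name, length(x$positives), length(x$universe)))
  invisible(x)
}

#' Read a label set from a plain-text id list
#'
#' @param path file with one drug id per line ('#' comments ignored).
#' @param universe drug universe.
#' @param name label name (default: file base name).
#' @return `label_set`.
#' @export
read_label_set <- function(path, universe, name = NULL) {
  ids <- trimws(readLines(path))
  ids <- ids[nzchar(ids) & !startsWith(ids, "#")]
  label_set(name %||% tools::file_path_sans_ext(basename(path)), ids, universe)
}

#' Semi-supervised similarity scoring against a positive label set
#'
#' Each drug is scored by its mean similarity to the labeled positives,
#' excluding itself: `score_i = mean( S[i, p] : p in positives, p != i )`.
#' Removing the diagonal prevents a positive drug from contributing its own
#' (perfect) self-similarity. If the label set contains a single positive,
#' that drug has no peers to compare against and its score is `NA`
#' (undefined); [rank_scores()] places such drugs last.
#'
#' @param S `sim_matrix` (or plain square matrix with matching dimnames).
#' @param labels `label_set`; its universe must be a subset of the matrix ids.
#' @param source tag recorded on the output (default from the matrix `kind`).
#' @return tibble with columns `id`, `score`, `source` — one row per drug in
#'   `labels$universe`, in universe order.
#' @examples
#' S <- matrix(c(1, .8, .2, .8, 1, .4, .2, .4, 1), 3,
#'             dimnames = list(c("d1", "d2", "d3"), c("d1", "d2", "d3")))
#' ssl_score(S, label_set("x", "d1", c("d1", "d2", "d3")))
#' @export
ssl_score <- function(S, labels, source = NULL) {
  stopifnot(inherits(labels, "label_set"))
  ids <- rownames(S)
  missing <- setdiff(labels$universe, ids)
  if (length(missing) > 0) {
    stop("universe ids missing from similarity matrix: ",
         paste(missing, collapse = ", "))
  }
  pos <- labels$positives
  sub <- S[labels$universe, pos, drop = FALSE]
  sums <- rowSums(sub)
  n_pos <- rep(length(pos), length(labels$universe))
  is_pos <- labels$universe %in% pos
  # a positive's own column contributes S[i,i]; strip it
  sums[is_pos] <- sums[is_pos] - S[cbind(labels$universe[is_pos], labels$universe[is_pos])]
  n_pos[is_pos] <- n_pos[is_pos] - 1L
  scores <- ifelse(n_pos == 0, NA_real_, sums / n_pos)
  tibble::tibble(
    id = labels$universe,
    score = as.numeric(scores),
    source = source %||% attr(S, "kind") %||% "similarity"
  )
}

#' Rank a score vector
#'
#' Deterministic ranking: rank 1 is the most likely positive. With
#' `direction = "desc"` (the default, for similarity scores) larger scores
#' rank first; with `"asc"` (for aggregated best-rank scores) smaller values
#' rank first. Ties are broken by ascending drug id; `NA` (undefined) scores
#' rank after all defined scores, ties again by id.
#'
#' @param sv tibble with columns `id`, `score` (and optionally `source`).
#' @param direction `"desc"` or `"asc"`.
#' @return the input tibble with an integer `rank` column added, original
#'   row order preserved.
#' @export
rank_scores <- function(sv, direction = c("desc", "asc")) {
  direction <- match.arg(direction)
  key <- if (direction == "desc") -sv$score else sv$score
  ord <- order(is.na(sv$score), key, sv$id)
  rank <- integer(length(ord))
  rank[ord] <- seq_along(ord)
  dplyr::mutate(sv, rank = rank)
}

#' Top Rank aggregation of several ranked predictions
#'
#' For each drug, takes its best (smallest) rank across the input rankings.
#' The result is a score where smaller is better; re-rank it with
#' `rank_scores(..., direction = "asc")`.
#'
#' @param rvs list of ranked tibbles (from [rank_scores()]) over identical
#'   id universes.
#' @return tibble with columns `id`, `score` (the best rank), `source =
#'   "aggregated"`, and a fresh `rank` column.
#' @export
top_rank_aggregate <- function(rvs) {
  stopifnot(length(rvs) >= 1)
  ids <- sort(rvs[[1]]$id)
  for (rv in rvs) {
    if (!identical(sort(rv$id), ids)) stop("rank vectors have mismatched id universes")
  }
  best <- purrr::reduce(
    purrr::map(rvs, ~ .x$rank[match(ids, .x$id)]),
    pmin
  )
  sv <- tibble::tibble(id = ids, score = as.numeric(best), source = "aggregated")
  rank_scores(sv, direction = "asc")
}

# ---- learned modality weighting -------------------------------------------

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Build the MOA pre-task feature table from similarity matrices
#'
#' For every mechanism-of-action (MOA) class with at least `min_drugs`
#' members, runs [ssl_score()] once per modality with that class's drugs as
#' positives, yielding a per-(task, drug) score pair and a 0/1 membership
#' label. This is the training table for [train_modality_weights()].
#'
#' @param sims named list of similarity matrices (one per modality, e.g.
#'   `list(expression = ..., structure = ...)`).
#' @param moa_table tibble with columns `drug_id`, `moa`.
#' @param min_drugs minimum class size (default 10); smaller MOAs are
#'   excluded from the pre-task.
#' @return tibble with columns `moa`, `drug_id`, `label` and one score
#'   column per modality.
#' @export
moa_feature_table <- function(sims, moa_table, min_drugs = 10) {
  stopifnot(is.list(sims), length(sims) >= 1, !is.null(names(sims)))
  universe <- rownames(sims[[1]])
  counts <- dplyr::count(dplyr::filter(moa_table, .data$drug_id %in% universe), .data$moa)
  keep <- counts$moa[counts$n >= min_drugs]
  if (length(keep) == 0) stop("no MOA class with at least ", min_drugs, " drugs")
  purrr::map_dfr(keep, function(m) {
    pos <- moa_table$drug_id[moa_table$moa == m]
    pos <- intersect(pos, universe)
    ls <- label_set(m, pos, universe)
    scores <- purrr::map(sims, ~ ssl_score(.x, ls)$score)
    out <- tibble::tibble(moa = m, drug_id = universe,
                          label = as.integer(universe %in% pos))
    dplyr::bind_cols(out, tibble::as_tibble(scores))
  })
}

#' Learn global modality weights on the MOA pre-task
#'
#' Fits a single logistic combiner shared across all one-vs-rest MOA tasks:
#' `p = sigmoid(w . x + b)` on per-modality z-scored features, minimizing
#' binary cross-entropy with inverse-class-frequency weighting so the rare
#' positive class is not drowned out. Optimized with Adam (adaptive-moment
#' gradient descent) for `epochs` full-batch steps; the whole fit is
#' repeated `repeats` times with reshuffled row order and re-initialized
#' parameters, and the final weights are the mean over repeats.
#'
#' @param features tibble from [moa_feature_table()] (columns `moa`,
#'   `drug_id`, `label`, one column per modality), or any table with those
#'   columns. Rows with `NA` scores are dropped.
#' @param modalities character vector naming the feature columns; default:
#'   every column other than `moa`, `drug_id`, `label`.
#' @param min_drugs classes smaller than this are excluded (default 10).
#' @param repeats number of reshuffled training repeats (default 10).
#' @param lr,epochs Adam learning rate and full-batch step count.
#' @param seed integer seed for initialization and shuffling.
#' @return object of class `modality_weights`: list with `w` (named), `bias`,
#'   and `training_log` (tibble of per-repeat final loss).
#' @export
train_modality_weights <- function(features, modalities = NULL, min_drugs = 10,
                                   repeats = 10, lr = 0.01, epochs = 500,
                                   seed = 1L) {
  modalities <- modalities %||%
    setdiff(names(features), c("moa", "drug_id", "label"))
  stopifnot(length(modalities) >= 1, "label" %in% names(features))
  keep <- dplyr::count(features, .data$moa, wt = .data$label, name = "npos")
  keep <- keep$moa[keep$npos >= min_drugs]
  if (length(keep) < 2) stop("need >= 2 MOA classes with at least ", min_drugs, " drugs")
  features <- dplyr::filter(features, .data$moa %in% keep)
  X <- as.matrix(features[, modalities, drop = FALSE])
  ok <- stats::complete.cases(X)
  X <- apply(X[ok, , drop = FALSE], 2, zscore)
  y <- features$label[ok]
  n <- length(y)
  # inverse-class-frequency row weights, normalized to mean 1
  cw <- ifelse(y == 1, n / (2 * sum(y == 1)), n / (2 * sum(y == 0)))

  set.seed(seed)
  fits <- purrr::map(seq_len(repeats), function(r) {
    idx <- sample.int(n)
    Xi <- X[idx, , drop = FALSE]; yi <- y[idx]; cwi <- cw[idx]
    theta <- stats::rnorm(ncol(X) + 1, sd = 0.1)
    m <- v <- numeric(length(theta))
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
    loss <- NA_real_
    for (t in seq_len(epochs)) {
      z <- drop(Xi %*% theta[-length(theta)]) + theta[length(theta)]
      p <- sigmoid(z)
      # weighted BCE gradient: mean of cw * (p - y) * x
      g <- (p - yi) * cwi
      grad <- c(drop(crossprod(Xi, g)) / n, mean(g))
      m <- b1 * m + (1 - b1) * grad
      v <- b2 * v + (1 - b2) * grad^2
      mhat <- m / (1 - b1^t); vhat <- v / (1 - b2^t)
      theta <- theta - lr * mhat / (sqrt(vhat) + eps)
    }
    p <- pmin(pmax(sigmoid(drop(Xi %*% theta[-length(theta)]) + theta[length(theta)]),
                   1e-12), 1 - 1e-12)
    loss <- -mean(cwi * (yi * log(p) + (1 - yi) * log(1 - p)))
    list(theta = theta, loss = loss)
  })
  thetas <- do.call(rbind, purrr::map(fits, "theta"))
  theta_bar <- colMeans(thetas)
  structure(list(
    w = stats::setNames(theta_bar[-length(theta_bar)], modalities),
    bias = unname(theta_bar[length(theta_bar)]),
    training_log = tibble::tibble(
      repeat_id = seq_len(repeats),
      final_loss = purrr::map_dbl(fits, "loss")
    )
  ), class = "modality_weights")
}

#' @export
print.modality_weights <- function(x, ...) {
  cat("<modality_weights>\n  w:",
      paste(sprintf("%s=%.4f", names(x$w), x$w), collapse = ", "),
      sprintf("\n  bias: %.4f\n", x$bias))
  invisible(x)
}

#' @export
tidy.modality_weights <- function(x, ...) {
  tibble::tibble(term = c(names(x$w), "(bias)"),
                 estimate = c(unname(x$w), x$bias))
}

#' @export
glance.modality_weights <- function(x, ...) {
  tibble::tibble(repeats = nrow(x$training_log),
                 mean_final_loss = mean(x$training_log$final_loss),
                 sd_final_loss = stats::sd(x$training_log$final_loss))
}

#' Combine modality score vectors with learned weights
#'
#' Z-scores each modality's scores across the drug universe, then maps each
#' drug through `sigmoid(w . z + bias)`. Higher output = more likely
#' positive. Drugs with an undefined score in any modality get `NA`.
#'
#' @param svs named list of score tibbles (columns `id`, `score`) over
#'   aligned universes; names must match `names(w$w)` in order.
#' @param w `modality_weights`.
#' @return tibble with columns `id`, `score`, `source = "aggregated"`.
#' @export
weighted_aggregate <- function(svs, w) {
  stopifnot(inherits(w, "modality_weights"))
  if (length(svs) != length(w$w)) stop("modality count mismatch")
  if (!is.null(names(svs)) && !identical(names(svs), names(w$w))) {
    stop("modality order mismatch: ", paste(names(svs), collapse = ","),
         " vs ", paste(names(w$w), collapse = ","))
  }
  ids <- svs[[1]]$id
  for (sv in svs) {
    if (!identical(sort(sv$id), sort(ids))) stop("score vectors have mismatched universes")
  }
  Z <- vapply(svs, function(sv) {
    s <- sv$score[match(ids, sv$id)]
    zscore(s)
  }, numeric(length(ids)))
  combined <- sigmoid(drop(Z %*% unname(w$w)) + w$bias)
  tibble::tibble(id = ids, score = as.numeric(combined), source = "aggregated")
}
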