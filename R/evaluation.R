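#' Split a label set into seed and evaluation positives
#'
#' Uniformly random disjoint split of the positives: a `fraction` share
#' (rounded to the nearest integer) becomes the seed set used for scoring,
#' the remainder is held out for evaluation.
#'
#' @param labels `label_set` with at least 2 positives.
#' @param fraction share of positives kept as seed labels, in (0, 1).
#'   Default 0.5.
#' @param seed integer seed; same seed, same split.
#' @return list of class `holdout_split` with `seed_positives`,
#'   `eval_positives`, `fraction`, `seed`.
#' @export
split_labels <- function(labels, fraction = 0.5, seed = 1L) {
  stopifnot(inherits(labels, "label_set"))
  if (!(fraction > 0 && fraction < 1)) stop("fraction must be in (0, 1)")
  pos <- labels$positives
  if (length(pos) < 2) stop("need at least 2 positives to split")
  n_seed <- max(1L, min(length(pos) - 1L, round(fraction * length(pos))))
  set.seed(seed)
  seed_pos <- sort(sample(pos, n_seed))
  structure(list(
    seed_positives = seed_pos,
    eval_positives = sort(setdiff(pos, seed_pos)),
    fraction = fraction,
    seed = seed
  ), class = "holdout_split")
}

#' Bridge-plot (KS-like) enrichment score of a ranking
#'
#' Walks the ranked list from top to bottom, stepping up by `1/|P|` at each
#' positive and down by `1/(N-|P|)` otherwise; the running sum starts and
#' ends at 0. The enrichment score (ES) is the maximum prefix value of the
#' walk, the empty prefix (0) included, so ES is in [0, 1]: 1 when every
#' positive leads the list, 0 when the walk never rises above its start.
#'
#' @param ranked_ids character vector, best-ranked first.
#' @param positives character vector of positive ids, a strict non-empty
#'   subset of `ranked_ids`.
#' @param variant `"max_prefix"` (default; one-sided, rewards positives at
#'   the leading edge) or `"max_abs"` (largest absolute excursion of the
#'   walk, sign preserved).
#' @return list with `running_sum` (length N) and `es`.
#' @export
enrichment_score <- function(ranked_ids, positives,
                             variant = c("max_prefix", "max_abs")) {
  variant <- match.arg(variant)
  n <- length(ranked_ids)
  hits <- ranked_ids %in% positives
  p <- sum(hits)
  if (p == 0) stop("no positives in the ranked list")
  if (p == n) stop("positives equal the full list; walk is degenerate")
  if (length(setdiff(positives, ranked_ids)) > 0) {
    stop("positives missing from ranked list: ",
         paste(setdiff(positives, ranked_ids), collapse = ", "))
  }
  steps <- ifelse(hits, 1 / p, -1 / (n - p))
  running <- cumsum(steps)
  es <- switch(variant,
    max_prefix = max(0, max(running)),
    max_abs = running[which.max(abs(running))]
  )
  list(running_sum = running, es = es)
}

# ES without materializing the walk: the maximum of the running sum is
# attained immediately after a positive step (or at the empty prefix), so
# with sorted positive positions q_1 < ... < q_P the prefix value after the
# j-th positive is j/P - (q_j - j)/(N-P).
es_from_positions <- function(pos_positions, n) {
  p <- length(pos_positions)
  q <- sort.int(pos_positions, method = "quick")
  j <- seq_len(p)
  max(0, max(j / p - (q - j) / (n - p)))
}

#' Permutation-normalized enrichment score
#'
#' Computes the observed ES of the ranking, then its null distribution by
#' drawing `n_perm` label permutations: each permutation places `|P|`
#' pseudo-positives uniformly at random (without replacement) among the N
#' positions and recomputes ES. The normalized enrichment score is
#' `NES = ES / mean(permuted ES)`.
#'
#' @inheritParams enrichment_score
#' @param n_perm number of label permutations (default 10000).
#' @param seed integer seed for the permutation draws.
#' @return object of class `bridge_result`: list with `running_sum`, `es`,
#'   `perm_es`, `nes`, `n_perm`, `n`, `n_pos`, `seed`.
#' @export
normalized_enrichment <- function(ranked_ids, positives, n_perm = 10000,
                                  seed = 1L) {
  if (n_perm < 100) warning("n_perm < 100: the NES normalization is unstable")
  obs <- enrichment_score(ranked_ids, positives)
  n <- length(ranked_ids)
  p <- sum(ranked_ids %in% positives)
  set.seed(seed)
  perm_es <- vapply(seq_len(n_perm),
                    function(b) es_from_positions(sample.int(n, p), n),
                    numeric(1))
  structure(list(
    running_sum = obs$running_sum,
    es = obs$es,
    perm_es = perm_es,
    nes = if (obs$es == 0) 0 else obs$es / mean(perm_es),
    n_perm = as.integer(n_perm),
    n = n,
    n_pos = p,
    seed = as.integer(seed)
  ), class = "bridge_result")
}

#' @export
print.bridge_result <- function(x, ...) {
  cat(sprintf("<bridge_result: N=%d, |P|=%d, ES=%.4f, NES=%.3f (%d perms)>\n",
              x$n, x$n_pos, x$es, x$nes, x$n_perm))
  invisible(x)
}

#' @export
tidy.bridge_result <- function(x, ...) {
  tibble::tibble(position = seq_len(x$n), running_sum = x$running_sum)
}

#' @export
glance.bridge_result <- function(x, ...) {
  tibble::tibble(es = x$es, nes = x$nes, n = x$n, n_pos = x$n_pos,
                 n_perm = x$n_perm, mean_perm_es = mean(x$perm_es),
                 seed = x$seed)
}

#' Bridge plot of an enrichment result
#'
#' Rank position against the running sum, with the ES level marked.
#'
#' @param object `bridge_result`.
#' @param ... ignored.
#' @return a ggplot.
#' @export
autoplot.bridge_result <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$running_sum)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::geom_hline(yintercept = object$es, colour = "red",
                        linetype = "dashed") +
    ggplot2::labs(
      x = "rank position",
      y = "running sum",
      title = sprintf("ES = %.3f, NES = %.2f (%d permutations)",
                      object$es, object$nes, object$n_perm)
    ) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.bridge_result
#' @param result `bridge_result`.
#' @export
plot_bridge <- function(result, ...) autoplot.bridge_result(result, ...)

#' Export a bridge result
#'
#' Writes the scalar summary as JSON and (optionally) the running sum as TSV.
#'
#' @param result `bridge_result`.
#' @param json_path output JSON path.
#' @param tsv_path optional running-sum TSV path.
#' @export
write_bridge_result <- function(result, json_path, tsv_path = NULL) {
  jsonlite::write_json(
    list(es = result$es, nes = result$nes, n_perm = result$n_perm,
         n = result$n, n_pos = result$n_pos, seed = result$seed),
    json_path, auto_unbox = TRUE, digits = NA
  )
  if (!is.null(tsv_path)) {
    readr::write_tsv(tidy(result), tsv_path, progress = FALSE)
  }
  invisible(json_path)
}

#' Hold-out benchmark of a scoring pipeline
#'
#' Splits the positives into seed and evaluation halves, scores every drug
#' against the seed positives only, ranks, removes the seed positives from
#' the ranked list (so known labels cannot inflate the leading edge), and
#' measures how far up the held-out positives concentrate via the
#' permutation-normalized enrichment score.
#'
#' @param sources a single similarity matrix, or a named list of them (one
#'   per modality) when `method` is `"top_rank"` or `"weighted"`.
#' @param labels `label_set` over the drug universe.
#' @param method `"single"` (default; requires one matrix), `"top_rank"`, or
#'   `"weighted"` (requires `weights`).
#' @param weights `modality_weights`, required for `method = "weighted"`.
#' @param fraction seed share of the positives (default 0.5).
#' @param n_perm label permutations for the NES (default 10000).
#' @param seed integer seed controlling both the split and the permutations.
#' @return `bridge_result` (with the split attached as attribute `split`).
#' @export
holdout_benchmark <- function(sources, labels,
                              method = c("single", "top_rank", "weighted"),
                              weights = NULL, fraction = 0.5,
                              n_perm = 10000, seed = 1L) {
  method <- match.arg(method)
  if (inherits(sources, "sim_matrix") || (is.matrix(sources) && !is.list(sources))) {
    sources <- list(sources)
  }
  split <- split_labels(labels, fraction = fraction, seed = seed)
  seed_labels <- label_set(labels$name, split$seed_positives, labels$universe)
  svs <- purrr::map(sources, ssl_score, labels = seed_labels)
  ranked <- switch(method,
    single = {
      if (length(svs) != 1) stop("method 'single' needs exactly one similarity matrix")
      rank_scores(svs[[1]])
    },
    top_rank = top_rank_aggregate(purrr::map(svs, rank_scores)),
    weighted = {
      if (is.null(weights)) stop("method 'weighted' needs modality weights")
      rank_scores(weighted_aggregate(svs, weights))
    }
  )
  ranked <- dplyr::arrange(ranked, .data$rank)
  eval_list <- ranked$id[!ranked$id %in% split$seed_positives]
  res <- normalized_enrichment(eval_list, split$eval_positives,
                               n_perm = n_perm, seed = seed)
  attr(res, "split") <- split
  res
}
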