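test_that("ssl_score reproduces the worked 3x3 examples", {
  S <- worked_sim()
  uni <- c("d1", "d2", "d3")
  one <- ssl_score(S, label_set("x", "d1", uni))
  expect_equal(one$score[one$id == "d2"], 0.8)
  expect_equal(one$score[one$id == "d3"], 0.2)
  expect_true(is.na(one$score[one$id == "d1"]))  # sole positive: undefined
  two <- ssl_score(S, label_set("x", c("d1", "d2"), uni))
  expect_equal(two$score[two$id == "d3"], 0.3)
  expect_equal(two$score[two$id == "d1"], 0.8)
  expect_equal(two$score[two$id == "d2"], 0.8)
})

test_that("ssl_score edge contracts: constant matrix, errors, order invariance", {
  S <- matrix(0.4, 4, 4, dimnames = list(paste0("d", 1:4), paste0("d", 1:4)))
  diag(S) <- 1
  uni <- paste0("d", 1:4)
  sv <- ssl_score(S, label_set("x", c("d1", "d2"), uni))
  expect_true(all(abs(sv$score[sv$id %in% c("d3", "d4")] - 0.4) < 1e-12))
  expect_error(label_set("x", character(), uni), "at least one")
  expect_error(ssl_score(S, label_set("x", "d1", c(uni, "d9"))), "d9")
  # permuting the positives leaves scores unchanged
  a <- ssl_score(S, label_set("x", c("d1", "d2"), uni))
  b <- ssl_score(S, label_set("x", c("d2", "d1"), uni))
  expect_equal(a$score, b$score)
})

test_that("rank_scores ranks descending with id tie-break, NA last", {
  sv <- tibble::tibble(id = c("a", "b", "c"), score = c(0.9, 0.1, 0.5))
  expect_equal(rank_scores(sv)$rank, c(1L, 3L, 2L))
  ties <- tibble::tibble(id = c("b", "a", "c"), score = c(1, 1, 1))
  r <- rank_scores(ties)
  expect_equal(r$rank[match(c("a", "b", "c"), r$id)], c(1L, 2L, 3L))
  nas <- tibble::tibble(id = c("a", "b", "c"), score = c(0.2, NA, 0.7))
  r <- rank_scores(nas)
  expect_equal(r$rank[r$id == "b"], 3L)
  asc <- rank_scores(sv, direction = "asc")
  expect_equal(asc$rank, c(3L, 1L, 2L))
})

test_that("top_rank_aggregate takes the best rank per drug", {
  r1 <- tibble::tibble(id = c("a", "b"), score = c(2, 1), rank = c(3L, 5L))
  r2 <- tibble::tibble(id = c("a", "b"), score = c(1, 2), rank = c(4L, 2L))
  agg <- top_rank_aggregate(list(r1, r2))
  expect_equal(agg$score[agg$id == "a"], 3)
  expect_equal(agg$score[agg$id == "b"], 2)
  # single input is the identity on scores; idempotent on duplicates
  single <- top_rank_aggregate(list(r1))
  expect_equal(single$score, as.numeric(r1$rank[match(single$id, r1$id)]))
  dup <- top_rank_aggregate(list(r2, r2))
  expect_equal(dup$score, single_scores <- as.numeric(r2$rank[match(dup$id, r2$id)]))
  # aggregated rank never exceeds any input rank
  set.seed(11)
  ids <- sprintf("d%02d", 1:30)
  rvs <- lapply(1:3, function(i) {
    rank_scores(tibble::tibble(id = ids, score = rnorm(30)))
  })
  agg <- top_rank_aggregate(rvs)
  for (rv in rvs) {
    expect_true(all(agg$score[match(ids, agg$id)] <= rv$rank[match(ids, rv$id)]))
  }
  expect_error(top_rank_aggregate(list(r1, dplyr::mutate(r2, id = c("a", "z")))),
               "universe")
})

test_that("weighted_aggregate applies sigmoid(w.z + b) on z-scored inputs", {
  # population z-scores of (1, -1) are (1, -1): sigmoid(2) vs sigmoid(-2)
  w <- structure(list(w = c(m1 = 1, m2 = 1), bias = 0,
                      training_log = tibble::tibble()),
                 class = "modality_weights")
  svs <- list(m1 = tibble::tibble(id = c("a", "b"), score = c(1, -1)),
              m2 = tibble::tibble(id = c("a", "b"), score = c(1, -1)))
  out <- weighted_aggregate(svs, w)
  expect_equal(out$score[out$id == "a"], 1 / (1 + exp(-2)), tolerance = 1e-6)
  expect_equal(out$score[out$id == "b"], 1 / (1 + exp(2)), tolerance = 1e-6)
  expect_equal(round(out$score, 4), c(0.8808, 0.1192))
  # degenerate weight (1, 0): ranking equals modality 1 ranking
  set.seed(2)
  ids <- sprintf("d%02d", 1:25)
  svs <- list(m1 = tibble::tibble(id = ids, score = rnorm(25)),
              m2 = tibble::tibble(id = ids, score = rnorm(25)))
  w10 <- structure(list(w = c(m1 = 1, m2 = 0), bias = 0,
                        training_log = tibble::tibble()),
                   class = "modality_weights")
  out <- rank_scores(weighted_aggregate(svs, w10))
  expect_equal(out$rank, rank_scores(svs$m1)$rank)
  expect_error(weighted_aggregate(svs[1], w10), "modality count")
})

test_that("training recovers the informative modality on a planted task", {
  spec <- synthetic_spec(seed = 101)
  moa <- gen_moa_dataset(spec)
  w <- train_modality_weights(moa$features, seed = 101, repeats = 3, epochs = 300)
  expect_gt(w$w[["expression"]], w$w[["structure"]])
  expect_equal(nrow(w$training_log), 3)
  expect_true(all(is.finite(w$training_log$final_loss)))
  # duplicated modality: near-symmetric weights after repeat-averaging
  feats <- moa$features
  feats$structure <- feats$expression
  w2 <- train_modality_weights(feats, seed = 101, repeats = 10, epochs = 300)
  expect_lt(abs(w2$w[["expression"]] - w2$w[["structure"]]), 0.1)
})

test_that("MOA classes below min_drugs are excluded from the pre-task", {
  spec <- synthetic_spec(seed = 5, n_moa_classes = 3, drugs_per_moa = 12)
  moa <- gen_moa_dataset(spec)
  # shrink one class to 9 drugs
  small <- moa$features$drug_id %in% moa$moa_table$drug_id[moa$moa_table$moa == "moa03"][1:3]
  feats <- moa$features[!small, ]
  w <- train_modality_weights(feats, min_drugs = 10, seed = 5, repeats = 2,
                              epochs = 50)
  expect_s3_class(w, "modality_weights")
  # with only one surviving class, training refuses
  tiny <- dplyr::filter(moa$features, moa == "moa01")
  expect_error(train_modality_weights(tiny, min_drugs = 10, seed = 1), "2 MOA")
})

test_that("moa_feature_table builds per-task ssl features over each modality", {
  S <- random_sim(30, seed = 8)
  moa_table <- tibble::tibble(drug_id = rownames(S),
                              moa = rep(c("a", "b", "c"), each = 10))
  ft <- moa_feature_table(list(expr = S), moa_table, min_drugs = 10)
  expect_setequal(unique(ft$moa), c("a", "b", "c"))
  expect_equal(nrow(ft), 3 * 30)
  expect_equal(sum(ft$label), 30)
  # spot-check one feature value against a direct ssl_score call
  ls_a <- label_set("a", moa_table$drug_id[moa_table$moa == "a"], rownames(S))
  direct <- ssl_score(S, ls_a)
  expect_equal(ft$expr[ft$moa == "a"], direct$score)
  expect_error(moa_feature_table(list(expr = S), moa_table, min_drugs = 11),
               "no MOA")
})

test_that("raising similarity to a positive never worsens a drug's rank", {
  set.seed(13)
  S <- random_sim(15, seed = 13)
  uni <- rownames(S)
  labels <- label_set("x", uni[1:3], uni)
  base_rank <- rank_scores(ssl_score(S, labels))
  S2 <- S
  S2["d010", "d001"] <- S2["d001", "d010"] <- min(1, S["d010", "d001"] + 0.3)
  new_rank <- rank_scores(ssl_score(S2, labels))
  expect_lte(new_rank$rank[new_rank$id == "d010"],
             base_rank$rank[base_rank$id == "d010"])
})

test_that("label sets read from plain-text id lists", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# positives", "d1", "d3"), path)
  ls <- read_label_set(path, c("d1", "d2", "d3"), name = "pc")
  expect_equal(ls$positives, c("d1", "d3"))
  expect_equal(ls$name, "pc")
  expect_error(read_label_set(path, c("d1", "d2")), "d3")
})
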