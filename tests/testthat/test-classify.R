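test_that("cosine similarity: anchors and error cases", {
  set.seed(40)
  p <- rnorm(10)
  expect_equal(cosine_similarity(p, p), 1, tolerance = 1e-12)
  expect_equal(cosine_similarity(p, -p), -1, tolerance = 1e-12)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0)
  expect_error(cosine_similarity(c(1, 2), c(1, 2, 3)), "dimension")
  expect_error(cosine_similarity(c(0, 0), c(1, 2)), "zero-norm")
})

test_that("intimate sorting: argmax behaviour and invariances", {
  set.seed(41)
  Z <- matrix(rnorm(30 * 6), 30, 6)
  labs <- sample(letters[1:4], 30, replace = TRUE)
  ts <- training_set(Z, labs)

  # single-candidate training set
  one <- training_set(Z[5, , drop = FALSE], "only")
  expect_equal(predict_class(rnorm(6), one, 1)$label, "only")

  # a query equal to a training vector scores 1 and takes its label
  pr <- predict_class(Z[9, ], ts, 1)
  expect_equal(pr$label, labs[9])
  expect_equal(pr$best_score, 1, tolerance = 1e-12)

  # brute-force 1-NN equivalence over explicit similarity scores
  for (r in 1:20) {
    q <- rnorm(6)
    sims <- apply(Z, 1, cosine_similarity, q = q)
    expect_equal(predict_class(q, ts, 1)$label, labs[which.max(sims)])
  }

  # scale invariance in the query
  q <- rnorm(6)
  expect_equal(predict_class(q, ts, 3)$label,
               predict_class(137.5 * q, ts, 3)$label)

  expect_error(predict_class(rnorm(5), ts, 1), "dimension")
  expect_error(predict_class(rep(0, 6), ts, 1), "zero-norm")
  expect_error(training_set(rbind(rep(0, 3)), "z"), "zero-norm")
})

test_that("tie-breaking is seeded, reproducible and ~uniform", {
  # three colinear training vectors, distinct labels: an exact 3-way tie
  Z <- rbind(c(1, 1), c(2, 2), c(3, 3))
  ts <- training_set(Z, c("a", "b", "c"))
  q <- c(4, 4)
  first <- predict_class(q, ts, 99)$label
  for (r in 1:5) expect_identical(predict_class(q, ts, 99)$label, first)

  picks <- vapply(1:3000, function(s) predict_class(q, ts, s)$label,
                  character(1))
  freq <- table(picks) / 3000
  expect_setequal(names(freq), c("a", "b", "c"))
  # binomial 3.5-sigma band around 1/3
  expect_true(all(abs(freq - 1 / 3) < 3.5 * sqrt((1 / 3) * (2 / 3) / 3000)))
})

test_that("tie-breaking does not disturb the caller's RNG stream", {
  Z <- rbind(c(1, 1), c(2, 2))
  ts <- training_set(Z, c("a", "b"))
  set.seed(77)
  before <- rnorm(3)
  set.seed(77)
  invisible(predict_class(c(1, 1), ts, 5))
  expect_identical(rnorm(3), before)
})

test_that("hierarchical cascade recovers planted paths and stops correctly", {
  fx <- generate_fixtures(fixture_spec(n_classes = c(2, 2, 2),
                                       sequences_per_class = 8,
                                       length_range = c(60, 120), seed = 42))
  X <- suppressWarnings(extract_features_matrix(fx$sequences))
  model <- suppressWarnings(train_hierarchy(X, fx$labels, m = 8))

  # a sequence planted 3 levels deep recovers its full label path
  deep_id <- fx$labels$id[nzchar(fx$labels$level3)][1]
  s <- fx$sequences[[which(vapply(fx$sequences, `[[`, character(1), "id") == deep_id)]]
  path <- predict_hierarchy(s, model, rng_seed = 17)
  truth <- unlist(fx$labels[fx$labels$id == deep_id, c("level1", "level2", "level3")])
  expect_equal(nrow(path), 3L)
  expect_equal(path$label, unname(truth))

  # the non-target first-level class stops after one entry
  shallow_id <- fx$labels$id[fx$labels$level1 == "C2"][1]
  s2 <- fx$sequences[[which(vapply(fx$sequences, `[[`, character(1), "id") == shallow_id)]]
  path2 <- predict_hierarchy(s2, model, rng_seed = 17)
  expect_equal(nrow(path2), 1L)
  expect_equal(path2$label, "C2")

  # a ragged branch (level-2 class without children) terminates without error
  mid_ids <- fx$labels$id[nzchar(fx$labels$level2) & !nzchar(fx$labels$level3)]
  s3 <- fx$sequences[[which(vapply(fx$sequences, `[[`, character(1), "id") == mid_ids[1])]]
  path3 <- predict_hierarchy(s3, model, rng_seed = 17)
  expect_lte(nrow(path3), 2L)

  expect_error(predict_hierarchy(rnorm(10), model, 1), "dimension")
})
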