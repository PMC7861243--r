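make_lvs <- function(mat) {
  structure(list(mat = mat,
                 coverage = stats::setNames(as.numeric(
                   stats::complete.cases(mat)), rownames(mat))),
            class = "label_vector_set")
}

test_that("cosine and euclidean similarities follow their formulas", {
  expect_equal(cosine_sim(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(cosine_sim(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine_sim(c(1, 0), c(1, 1)), 1 / sqrt(2))
  expect_equal(cosine_sim(c(1, 2), c(2, 1)), 0.8)
  expect_error(cosine_sim(c(0, 0), c(1, 1)),
               class = "ontopop_error_zero_vector")
  expect_error(cosine_sim(c(1, 0), c(1, 0, 0)),
               class = "ontopop_error_bad_vectors")
  expect_equal(euclidean_sim(c(0, 0), c(3, 4)), -5)
})

test_that("sibling and parent scores match the centroid definition", {
  cfg <- mapper_config()
  expect_equal(score_siblings(c(1, 1), rbind(c(1, 1))), 1)
  expect_equal(score_siblings(c(1, 1), rbind(c(2, 0), c(0, 2))), 1)
  expect_equal(score_siblings(c(1, 0), rbind(c(1, 0), c(0, 1))), 1 / sqrt(2))
  expect_error(score_siblings(c(1, 0), matrix(numeric(), 0, 2)),
               class = "ontopop_error_empty_seeds")
  expect_equal(score_parent(c(1, 2), c(2, 1)), 0.8)
  lv <- structure(list(source_id = "x", vector = NULL, coverage = 0),
                  class = "label_vector")
  expect_error(score_parent(lv, c(1, 0)),
               class = "ontopop_error_undefined_vector")
})

test_that("jaccard and hamming similarities handle edge cases", {
  expect_equal(jaccard_sim(c("cow", "milk"), c("cow", "milk")), 1)
  expect_equal(jaccard_sim("a", "b"), 0)
  expect_equal(jaccard_sim(c("cow", "milk"), c("cow", "cheese")), 1 / 3)
  expect_equal(jaccard_sim(character(), character()), 0)
  expect_equal(jaccard_sim(c("a", "a", "b"), c("a", "b")), 1) # sets

  expect_equal(hamming_sim("cat", "cat"), 1)
  expect_equal(hamming_sim("cat", "car"), 2 / 3)
  expect_equal(hamming_sim("ab", "abcd"), 0.5)
  expect_equal(hamming_sim("", ""), 1)
  expect_equal(hamming_sim("", "ab"), 0)
})

test_that("map_instance picks the argmax class with deterministic ties", {
  ont <- star_ontology(c(2L, 2L))
  sk <- make_skeleton(ont, n_seed = 1L, rng_seed = 1)
  ids <- c("root", "c001", "c002", ont$instances$id)
  mat <- rbind(
    root = c(1, 1), c001 = c(4, 0), c002 = c(0, 4),
    i0001 = c(2, 0), i0002 = c(2, 0), # class c001 cluster
    i0003 = c(0, 2), i0004 = c(0, 2)  # class c002 cluster
  )
  lvs <- make_lvs(mat[ids, ])
  cand <- sort(sk$candidates)[1L]
  res <- map_instance(cand, sk, vectors = lvs)
  truth <- ont$instance_parents[[cand]]
  expect_equal(res$predicted_class_id, truth)
  expect_equal(res$score, 1)
  expect_equal(res$score, 0.8 * res$score_siblings + 0.2 * res$score_parent)
  expect_false(res$fallback)
  expect_error(map_instance("i9999", sk, vectors = lvs),
               class = "ontopop_error_unknown_id")

  # exact tie between identical classes: lexicographically smallest id wins
  mat_tie <- mat
  mat_tie["c002", ] <- mat_tie["c001", ]
  mat_tie["i0003", ] <- mat_tie["i0001", ]
  mat_tie["i0004", ] <- mat_tie["i0002", ]
  sk1 <- make_skeleton(ont, n_seed = 1L, rng_seed = 2)
  res_tie <- map_all(sk1, vectors = make_lvs(mat_tie[ids, ]))
  expect_true(all(res_tie$predicted_class_id == "c001"))
})

test_that("alpha limits reduce to nearest-centroid and nearest-class-label", {
  for (seed in 1:6) {
    b <- random_benchmark(seed)
    sk <- make_skeleton(b$ontology, 2L, rng_seed = seed + 100)
    r1 <- map_all(sk, vectors = b$vectors,
                  config = mapper_config(alpha = 1))
    expect_identical(stats::setNames(r1$predicted_class_id, r1$instance_id),
                     oracle_nearest_centroid(sk, b$vectors))
    r0 <- map_all(sk, vectors = b$vectors,
                  config = mapper_config(alpha = 0))
    expect_identical(stats::setNames(r0$predicted_class_id, r0$instance_id),
                     oracle_nearest_label(sk, b$vectors))
  }
})

test_that("map_all agrees with the brute-force double-loop oracle", {
  for (seed in 1:10) {
    b <- random_benchmark(seed, n_classes = sample(3:12, 1L))
    sk <- make_skeleton(b$ontology, 2L, rng_seed = seed)
    res <- map_all(sk, vectors = b$vectors,
                   config = mapper_config(alpha = 0.8))
    oracle <- oracle_map_embedding(sk, b$vectors, alpha = 0.8)
    expect_identical(res$predicted_class_id,
                     unname(oracle$predicted[res$instance_id]))
    expect_equal(res$score, unname(oracle$score[res$instance_id]),
                 tolerance = 1e-12)
    # convex combination invariant and cosine range
    ok <- !res$fallback
    expect_equal(res$score[ok], 0.8 * res$score_siblings[ok] +
                   0.2 * res$score_parent[ok])
    expect_true(all(abs(res$score[ok]) <= 1 + 1e-12))
  }
})

test_that("every method assigns each candidate exactly one target class", {
  b <- random_benchmark(21)
  sk <- make_skeleton(b$ontology, 2L, rng_seed = 3)
  for (m in c("embedding", "jaccard", "hamming", "random")) {
    res <- map_all(sk, vectors = b$vectors,
                   config = mapper_config(method = m, rng_seed = 9),
                   tokenized_labels = b$tokenized)
    expect_setequal(res$instance_id, sk$candidates)
    expect_true(all(res$predicted_class_id %in% sk$target_class_ids))
  }
  # the random method is reproducible under a fixed seed
  ra <- map_all(sk, config = mapper_config(method = "random", rng_seed = 7))
  rb <- map_all(sk, config = mapper_config(method = "random", rng_seed = 7))
  rc <- map_all(sk, config = mapper_config(method = "random", rng_seed = 8))
  expect_identical(ra, rb)
  expect_false(identical(ra, rc))
  # empty candidate set maps to an empty result
  lone <- star_ontology(1L)
  sk0 <- make_skeleton(lone, n_seed = 1L)
  expect_equal(nrow(map_all(sk0, config = mapper_config(method = "random"))),
               0L)
})

test_that("fully-OOV candidates fall back to a random target class", {
  ont <- star_ontology(c(2L, 2L))
  sk <- make_skeleton(ont, n_seed = 1L, rng_seed = 1)
  ids <- c("root", "c001", "c002", ont$instances$id)
  mat <- rbind(root = c(1, 1), c001 = c(4, 0), c002 = c(0, 4),
               i0001 = c(2, 0), i0002 = c(2, 0), i0003 = c(0, 2),
               i0004 = c(0, 2))
  lvs <- make_lvs(mat[ids, ])
  oov <- sort(sk$candidates)[1L]
  lvs$mat[oov, ] <- NA_real_
  lvs$coverage[oov] <- 0
  res <- map_all(sk, vectors = lvs)
  row <- res[res$instance_id == oov, ]
  expect_true(row$fallback)
  expect_true(is.na(row$score))
  expect_true(row$predicted_class_id %in% sk$target_class_ids)
  expect_false(any(res$fallback[res$instance_id != oov]))
})

test_that("euclidean similarity ranks by negative distance", {
  b <- random_benchmark(31)
  sk <- make_skeleton(b$ontology, 2L, rng_seed = 4)
  res <- map_all(sk, vectors = b$vectors,
                 config = mapper_config(similarity = "euclidean"))
  oracle <- oracle_map_embedding(sk, b$vectors, alpha = 0.8,
                                 similarity = "euclidean")
  expect_identical(res$predicted_class_id,
                   unname(oracle$predicted[res$instance_id]))
})

test_that("mapping TSV round trips", {
  b <- random_benchmark(8)
  sk <- make_skeleton(b$ontology, 2L, rng_seed = 2)
  res <- map_all(sk, vectors = b$vectors)
  p <- file.path(withr::local_tempdir(), "map.tsv")
  write_mapping(res, p)
  back <- read_mapping(p)
  expect_equal(back$predicted_class_id, res$predicted_class_id)
  expect_equal(back$score, res$score, tolerance = 1e-9)
})
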