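mapping_frame <- function(instance_id, predicted) {
  structure(data.frame(instance_id = instance_id,
                       predicted_class_id = predicted, score = NA_real_,
                       score_siblings = NA_real_, score_parent = NA_real_,
                       fallback = FALSE, stringsAsFactors = FALSE),
            class = c("mapping_result", "data.frame"))
}

test_that("precision counts TP by ground-truth set membership", {
  star <- star_ontology(c(2L, 1L))
  res <- mapping_frame(c("i0001", "i0002", "i0003"),
                       c("c001", "c001", "c001")) # i0003 truly under c002
  ev <- evaluate_mapping(res, star)
  expect_equal(ev$tp, 2L)
  expect_equal(ev$fp, 1L)
  expect_equal(ev$precision, 2 / 3)
  expect_equal(ev$tp + ev$fp, ev$n_candidates)

  all_right <- mapping_frame(c("i0001", "i0002"), c("c001", "c001"))
  expect_equal(evaluate_mapping(all_right, star)$precision, 1)

  multi <- ontology(
    class_labels = c(A = "a", B = "b", C = "c"),
    class_parents = list(A = character(), B = "A", C = "A"),
    instance_labels = c(i1 = "one"),
    instance_parents = list(i1 = c("B", "C"))
  )
  evm <- evaluate_mapping(mapping_frame("i1", "B"), multi)
  expect_equal(evm$precision, 1) # membership rule
  # strict single-parent switch scores against the primary parent only
  evs <- evaluate_mapping(mapping_frame("i1", "C"), multi,
                          strict_single = TRUE)
  expect_equal(evs$precision, 0)
  expect_error(evaluate_mapping(mapping_frame("ghost", "B"), multi),
               class = "ontopop_error_unknown_id")
})

test_that("path_distance is the undirected hop count, minimized over truth", {
  ont <- diamond_ontology()
  expect_equal(path_distance(ont, "D", "D"), 0L)
  expect_equal(path_distance(ont, "B", "C"), 2L) # siblings via A
  expect_equal(path_distance(ont, "B", c("C", "B")), 0L)
  expect_equal(path_distance(ont, "A", "D"), 2L)
  expect_error(path_distance(ont, "nope", "A"),
               class = "ontopop_error_unknown_id")
})

test_that("distance histogram mass at 0 equals the TP count", {
  for (seed in c(2, 9)) {
    b <- random_benchmark(seed, noise_sigma = 0.8)
    sk <- make_skeleton(b$ontology, 2L, rng_seed = seed)
    for (m in c("embedding", "random")) {
      res <- map_all(sk, vectors = b$vectors,
                     config = mapper_config(method = m, rng_seed = seed))
      ev <- evaluate_mapping(res, b$ontology)
      zero <- if ("0" %in% names(ev$distance_histogram)) {
        ev$distance_histogram[["0"]]
      } else 0L
      expect_identical(zero, ev$tp)
      expect_identical(sum(ev$distances == 0L), ev$tp)
      expect_equal(sum(ev$distance_histogram), ev$n_candidates)
    }
  }
})

test_that("mean distance respects the tree sanity bound", {
  # on a star tree every miss is exactly 2 hops, so
  # mean_distance = 2 * (1 - precision)
  star <- star_ontology(c(3L, 3L, 3L))
  sk <- make_skeleton(star, 1L, rng_seed = 5)
  res <- map_all(sk, config = mapper_config(method = "random", rng_seed = 5))
  ev <- evaluate_mapping(res, star)
  expect_gte(ev$mean_distance, 2 * (1 - ev$precision) - 1e-12)
  expect_equal(ev$mean_distance, 2 * (1 - ev$precision))
})

test_that("granularity is instances over classes within the subtree", {
  leaf3 <- star_ontology(c(3L, 0L))
  expect_equal(granularity(leaf3, "c001"), 3)
  expect_equal(granularity(leaf3, "c002"), 0)
  # diamond-shaped subtree: 4 classes under (and incl.) A, 8 distinct
  # instances spread over them -> 8 / 4 = 2
  ont <- ontology(
    class_labels = c(A = "a", B = "b", C = "c", D = "d"),
    class_parents = list(A = character(), B = "A", C = "A", D = c("B", "C")),
    instance_labels = stats::setNames(paste("x", 1:8), paste0("i", 1:8)),
    instance_parents = c(
      stats::setNames(as.list(rep(c("B", "C", "D"), c(3L, 2L, 2L))),
                      paste0("i", 1:7)),
      list(i8 = c("B", "C")) # multi-parent instance counted once
    )
  )
  expect_equal(granularity(ont, "A"), 2)
  expect_equal(granularity(ont, "B"), (3 + 2 + 1) / 2) # B, D subtree
  expect_error(granularity(ont, "zz"), class = "ontopop_error_unknown_id")
})

test_that("cohesiveness is the fraction of subclasses judged correct", {
  ann <- cohesiveness_annotation(
    "cheese_by_organism",
    c(cow_cheese = TRUE, goat_cheese = TRUE, sheep_cheese = TRUE,
      buffalo_milk_cheese = TRUE, blue_cheese = FALSE))
  expect_equal(cohesiveness(ann), 0.8)
  expect_equal(cohesiveness(cohesiveness_annotation("x", c(a = TRUE))), 1)
  expect_equal(cohesiveness(cohesiveness_annotation("x", c(a = FALSE,
                                                           b = FALSE))), 0)
  # ontology-aware validation: judged ids must be direct subclasses
  ont <- diamond_ontology()
  expect_error(
    cohesiveness_annotation("A", c(D = TRUE), ontology = ont),
    class = "ontopop_error_bad_input")
  ok <- cohesiveness_annotation("A", c(B = TRUE, C = FALSE), ontology = ont)
  expect_equal(cohesiveness(ok), 0.5)
})

test_that("cohesiveness annotations round trip through TSV", {
  anns <- list(
    cohesiveness_annotation("s1", c(a = TRUE, b = FALSE)),
    cohesiveness_annotation("s2", c(c = TRUE))
  )
  p <- file.path(withr::local_tempdir(), "coh.tsv")
  write_cohesiveness(anns, p)
  back <- read_cohesiveness(p)
  expect_equal(cohesiveness(back$s1), 0.5)
  expect_equal(cohesiveness(back$s2), 1)
})

test_that("run_experiment aggregates repeats deterministically", {
  b <- random_benchmark(13)
  cfg <- mapper_config()
  one <- run_experiment(b$ontology, vectors = b$vectors, config = cfg,
                        n_seed = 2L, n_repeats = 1L, base_seed = 50)
  sk <- make_skeleton(b$ontology, 2L, rng_seed = 51)
  res <- map_all(sk, vectors = b$vectors, config = cfg)
  ev <- evaluate_mapping(res, b$ontology)
  expect_equal(one$mean_precision, ev$precision)
  expect_equal(one$mean_distance, ev$mean_distance)

  twice <- run_experiment(b$ontology, vectors = b$vectors, config = cfg,
                          n_seed = 2L, n_repeats = 3L, base_seed = 50)
  again <- run_experiment(b$ontology, vectors = b$vectors, config = cfg,
                          n_seed = 2L, n_repeats = 3L, base_seed = 50)
  expect_identical(twice$per_repeat_precision, again$per_repeat_precision)
  expect_identical(twice$per_repeat_mean_distance,
                   again$per_repeat_mean_distance)
  expect_equal(twice$mean_precision, mean(twice$per_repeat_precision))
})

test_that("random mapping on a single-parent ontology hits 1/|C| precision", {
  star <- star_ontology(rep(6L, 20L)) # 20 target classes
  out <- run_experiment(star, config = mapper_config(method = "random"),
                        n_seed = 1L, n_repeats = 5L, base_seed = 77)
  n_cand <- (6L - 1L) * 20L * 5L
  p <- 1 / 20
  se <- sqrt(p * (1 - p) / n_cand)
  expect_lt(abs(out$pooled_precision - p), 3 * se)
})

test_that("correlate_structure computes Pearson r with a p-value", {
  prec <- c(a = 0.1, b = 0.4, c = 0.5, d = 0.9)
  expect_equal(correlate_structure(prec, prec)$r, 1)
  expect_equal(correlate_structure(prec, -prec)$r, -1)
  # direct formula oracle on 5 hand-listed pairs
  x <- c(s1 = 0.2, s2 = 0.5, s3 = 0.3, s4 = 0.9, s5 = 0.6)
  y <- c(s1 = 1.0, s2 = 2.5, s3 = 1.1, s4 = 4.0, s5 = 2.0)
  r_direct <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  got <- correlate_structure(x, y)
  expect_equal(got$r, r_direct)
  expect_true(got$p_value >= 0 && got$p_value <= 1)
  expect_equal(got$n, 5L)
  expect_error(correlate_structure(x[1:2], y[1:2]),
               class = "ontopop_error_bad_input")
  expect_error(correlate_structure(x, c(s1 = 1, s2 = 1, s3 = 1, s4 = 1,
                                        s5 = 1)),
               class = "ontopop_error_zero_variance")
})

test_that("per-superclass precision feeds the structure correlation", {
  b <- random_benchmark(17, n_classes = 12L, instances_mean = 5)
  sk <- make_skeleton(b$ontology, 2L, rng_seed = 17)
  res <- map_all(sk, vectors = b$vectors)
  supers <- setdiff(b$ontology$classes$id, b$ontology$root_id)
  psp <- per_superclass_precision(res, b$ontology, supers)
  expect_true(all(psp >= 0 & psp <= 1))
  gran <- vapply(names(psp), function(s) granularity(b$ontology, s),
                 numeric(1))
  if (length(psp) >= 3 && stats::sd(psp) > 0 && stats::sd(gran) > 0) {
    out <- correlate_structure(psp, gran)
    expect_true(abs(out$r) <= 1)
  }
})

test_that("compare_methods produces the comparison table", {
  b <- random_benchmark(19)
  cmp <- compare_methods(b$ontology, vectors = b$vectors,
                         tokenized_labels = b$tokenized,
                         methods = c("embedding", "random"),
                         n_repeats = 3L, base_seed = 5)
  expect_equal(cmp$table$method, c("embedding", "random"))
  expect_true(all(cmp$table$avg_precision >= 0 &
                    cmp$table$avg_precision <= 1))
  expect_true(all(cmp$table$avg_distance >= 0))
  expect_match(cmp$significance_test, "Wilcoxon")
})

test_that("relative_reduction computes the headline percentage arithmetic", {
  expect_equal(relative_reduction(4, 3), 0.25)
  expect_equal(relative_reduction(10, 10), 0)
  expect_error(relative_reduction(0, 1), class = "ontopop_error_bad_input")
})
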