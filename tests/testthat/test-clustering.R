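test_that("the lower median is used for the threshold", {
  expect_equal(delclust:::median_low(c(3, 1, 2)), 2)
  expect_equal(delclust:::median_low(c(4, 1, 3, 2)), 2)  # lower central value
  expect_equal(delclust:::median_low(5), 5)
})

test_that("threshold examples: two overlapping mappings, and a triple", {
  models <- test_models()
  # two overlapping mappings scoring s > 0: s_min is that score
  m2 <- tibble::tibble(id = c("a", "b"), sample_id = "s", chrom = "chr1",
                       left_inner = c(100, 150), right_inner = c(900, 850),
                       span_d = c(700, 720))
  cl <- singleton_clusters(m2, models)
  s <- cluster_similarity(cl[1, ], cl[2, ])
  est <- estimate_s_min(m2, models)
  expect_equal(est$s_min, s)
  expect_equal(est$contributing, 2L)

  # three mappings with pairwise scores {a < b < c}: per-mapping minima are
  # {a, a, b}, whose lower median is a
  m3 <- tibble::tibble(id = c("x", "y", "z"), sample_id = "s", chrom = "chr1",
                       left_inner = c(100, 120, 140),
                       right_inner = c(900, 880, 860),
                       span_d = c(700, 760, 830))
  cl3 <- singleton_clusters(m3, models)
  pair_scores <- c(cluster_similarity(cl3[1, ], cl3[2, ]),
                   cluster_similarity(cl3[1, ], cl3[3, ]),
                   cluster_similarity(cl3[2, ], cl3[3, ]))
  mins <- c(min(pair_scores[1:2]), min(pair_scores[c(1, 3)]),
            min(pair_scores[2:3]))
  expect_equal(estimate_s_min(m3, models)$s_min, sort(mins)[2])
  expect_equal(estimate_s_min(m3, models)$s_min, min(pair_scores))
})

test_that("no positive pair falls back to the default with a warning", {
  m <- tibble::tibble(id = c("a", "b"), sample_id = "s", chrom = "chr1",
                      left_inner = c(100, 5000), right_inner = c(600, 5500),
                      span_d = c(600, 600))
  expect_warning(est <- estimate_s_min(m, test_models(), fallback = 0.5),
                 "fallback")
  expect_equal(est$s_min, 0.5)
  expect_equal(est$contributing, 0L)
})

test_that("threshold estimation equals the brute-force median of minima", {
  withr::with_seed(71, {
    for (rep in 1:10) {
      m <- random_region_mappings(sample(6:25, 1))
      models <- test_models()
      got <- estimate_s_min(m, models)$s_min
      want <- naive_s_min(m, models)
      expect_equal(got, want, tolerance = 1e-12)
    }
  })
})

test_that("a lone mapping stays a singleton with an empty merge log", {
  m <- tibble::tibble(id = "only", sample_id = "s", chrom = "chr1",
                      left_inner = 100, right_inner = 700, span_d = 710)
  res <- agglomerate_region(m, test_models(), s_min = 0.01)
  expect_equal(nrow(res$clusters), 1)
  expect_equal(res$clusters$n, 1L)
  expect_equal(nrow(res$merge_log), 0)
})

test_that("two identical mappings merge at score one", {
  m <- tibble::tibble(id = c("a", "b"), sample_id = "s", chrom = "chr1",
                      left_inner = 100, right_inner = 700, span_d = 710)
  res <- agglomerate_region(m, test_models(), s_min = 0.5)
  expect_equal(nrow(res$clusters), 1)
  expect_equal(res$clusters$n, 2L)
  expect_equal(res$merge_log$score, 1)
})

test_that("a deviant noise mapping is left out as a singleton", {
  # several clean deletion loci drive the global threshold; one locus also
  # carries a mapping whose implied size is off by far more than 6 sigma
  mk_locus <- function(prefix, start, size, k, spread = 35) {
    tibble::tibble(
      id = paste0(prefix, seq_len(k)), sample_id = "s", chrom = "chr1",
      left_inner = start - sample(20:70, k, replace = TRUE),
      right_inner = start + size + sample(20:70, k, replace = TRUE),
      span_d = size + pmax(round(rnorm(k, 300, spread)), 210)
    )
  }
  withr::with_seed(81, {
    clean <- dplyr::bind_rows(mk_locus("a", 10000, 350, 8),
                              mk_locus("b", 30000, 500, 8),
                              mk_locus("c", 50000, 250, 8))
    # a tightly agreeing set of mappings from one deletion of size ~400
    good <- mk_locus("g", 70000, 400, 6, spread = 4)
    noise <- tibble::tibble(id = "noise", sample_id = "s", chrom = "chr1",
                            left_inner = 69980, right_inner = 71120,
                            span_d = 1100 + 300)
  })
  m <- dplyr::bind_rows(clean, good, noise)
  models <- test_models()
  s_min <- estimate_s_min(m, models)$s_min
  noisy_region <- dplyr::bind_rows(good, noise)
  # the noise mapping's best pair score sits below the global threshold
  cl <- singleton_clusters(noisy_region, models)
  noise_scores <- vapply(1:6, function(i) {
    cluster_similarity(cl[i, ], cl[7, ])
  }, numeric(1))
  expect_true(all(noise_scores < s_min))
  res <- agglomerate_region(noisy_region, models, s_min)
  expect_equal(nrow(res$clusters), 2)
  big <- res$clusters[which.max(res$clusters$n), ]
  expect_equal(big$n, 6L)
  expect_setequal(big$members[[1]], good$id)
  # and the naive rescan-everything oracle finds the same partition
  expect_equal(partition_of(res$clusters),
               naive_agglomerate(noisy_region, models, s_min))
})

test_that("two overlapping deletions of distinct sizes give two clusters", {
  withr::with_seed(91, {
    mk <- function(prefix, start, size, k) {
      tibble::tibble(
        id = paste0(prefix, seq_len(k)), sample_id = "s", chrom = "chr1",
        left_inner = start - sample(20:90, k, replace = TRUE),
        right_inner = start + size + sample(20:90, k, replace = TRUE),
        span_d = size + pmax(round(rnorm(k, 300, 35)), 210)
      )
    }
    # two deletions sharing breakpoint territory, sizes 300 vs 800 (>> 6
    # sigma apart), clustered at a threshold on the scale seen in data
    m <- dplyr::bind_rows(mk("a", 5000, 300, 7), mk("b", 5100, 800, 7))
  })
  models <- test_models()
  s_min <- 0.05
  res <- agglomerate_region(m, models, s_min)
  multi <- res$clusters[res$clusters$n >= 2, ]
  expect_equal(nrow(multi), 2)
  split_by_origin <- function(ids) substr(ids, 1, 1)
  expect_equal(length(unique(split_by_origin(multi$members[[1]]))), 1)
  expect_equal(length(unique(split_by_origin(multi$members[[2]]))), 1)
  expect_equal(partition_of(res$clusters), naive_agglomerate(m, models, s_min))
})

test_that("the engine reproduces the naive rescan oracle on random regions", {
  withr::with_seed(101, {
    seeds_ok <- 0
    for (rep in 1:20) {
      m <- random_region_mappings(sample(4:18, 1))
      models <- test_models()
      s_min <- estimate_s_min(m, models)$s_min
      res <- agglomerate_region(m, models, s_min)
      expect_equal(partition_of(res$clusters),
                   naive_agglomerate(m, models, s_min))
      # member conservation
      expect_setequal(unlist(res$clusters$members), m$id)
      # every merge exceeded the threshold
      if (nrow(res$merge_log) > 0) {
        expect_true(all(res$merge_log$score > s_min))
      }
      seeds_ok <- seeds_ok + 1
    }
    expect_equal(seeds_ok, 20)
  })
})

test_that("score computations grow subquadratically in the log factor", {
  withr::with_seed(111, {
    sizes <- c(10, 20, 40)
    ops <- vapply(sizes, function(n) {
      m <- random_region_mappings(n, n_signals = 2)
      delclust:::reset_op_counters()
      agglomerate_region(m, test_models(), s_min = 0)
      delclust:::op_counters()$similarity
    }, numeric(1))
  })
  # O(N^2 log N): quadrupling is allowed (plus log slack) on doubling
  expect_lt(ops[2] / ops[1], 4 * log2(20) / log2(10) * 1.5)
  expect_lt(ops[3] / ops[2], 4 * log2(40) / log2(20) * 1.5)
})

test_that("the pipeline fit is a partition of its input with flagged calls", {
  withr::with_seed(121, {
    m <- dplyr::bind_rows(
      random_region_mappings(12, n_signals = 2, chrom = "chr1"),
      random_region_mappings(8, n_signals = 1, chrom = "chr2")
    )
    m$id <- paste0("m", seq_len(nrow(m)))
  })
  models <- test_models()
  fit <- cluster_deletions(m, models, min_support = 2)
  expect_s3_class(fit, "delclust_fit")
  expect_setequal(unlist(fit$clusters$members), m$id)
  td <- tidy(fit)
  expect_equal(sum(td$n), nrow(m))
  expect_equal(td$below_min_support, td$n < 2)
  expect_equal(td$start, fit$clusters$l + 1)  # 1-based reporting
  expect_equal(td$end, fit$clusters$r)
  g <- glance(fit)
  expect_equal(g$n_mappings, nrow(m))
  expect_equal(g$n_clusters, nrow(fit$clusters))
  # per-sample counts sum to n
  expect_equal(td$n_s, td$n)
})
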