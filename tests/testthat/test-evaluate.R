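mk_truth <- function(start, end, locus, id = NULL, hap = "0,1") {
  tibble::tibble(
    deletion_id = id %||% paste0("d", seq_along(start)), chrom = "chr1",
    start = start, end = end, size = end - start, haplotypes = hap,
    partner_id = NA_character_, locus_id = locus
  )
}

mk_clusters <- function(l, r, mu, sigma = 35, n = 5, id = NULL,
                        chrom = "chr1") {
  tibble::tibble(chrom = chrom, cluster_id = id %||% paste0("c", seq_along(l)),
                 l = l, r = r, mu = mu, sigma = sigma, n = n)
}

test_that("locus classification follows the trapezoid-containment rule", {
  truth <- mk_truth(c(1000, 5000, 5200), c(1400, 5400, 5800),
                    c("L1", "L2", "L2"))
  # one matching cluster for the single, two for the pair
  cl <- mk_clusters(l = c(950, 4950, 5150), r = c(1450, 5450, 5850),
                    mu = c(410, 395, 590))
  loci <- classify_loci(cl, truth)
  expect_equal(loci$predicted_kind[loci$locus_id == "L1"], "single")
  expect_equal(loci$truth_kind[loci$locus_id == "L2"], "pair")
  expect_equal(loci$predicted_kind[loci$locus_id == "L2"], "pair")

  # a single vague cluster spanning both partners: a false single
  cl2 <- mk_clusters(l = 5150, r = 5850, mu = 500, sigma = 120)
  loci2 <- classify_loci(cl2, truth)
  expect_equal(loci2$predicted_kind[loci2$locus_id == "L2"], "single")
  expect_equal(loci2$predicted_kind[loci2$locus_id == "L1"], "none")

  # a supported cluster away from any truth creates a no-truth locus
  cl3 <- mk_clusters(l = 90000, r = 90600, mu = 400)
  loci3 <- classify_loci(cl3, truth)
  none <- loci3[loci3$truth_kind == "none", ]
  expect_equal(nrow(none), 1)
  expect_equal(none$predicted_kind, "single")
})

test_that("clusters below min-support never count as predictions", {
  truth <- mk_truth(1000, 1400, "L1")
  cl <- mk_clusters(l = 950, r = 1450, mu = 410, n = 1)
  loci <- classify_loci(cl, truth, min_support = 2)
  expect_equal(loci$predicted_kind, "none")
})

test_that("size must match within three sigmas for a cluster to match", {
  truth <- mk_truth(1000, 1400, "L1")  # size 400
  hit <- mk_clusters(l = 950, r = 1450, mu = 400 + 3 * 35)
  miss <- mk_clusters(l = 950, r = 1450, mu = 400 + 3 * 35 + 1)
  expect_equal(classify_loci(hit, truth)$predicted_kind[1], "single")
  loci_miss <- classify_loci(miss, truth)
  # the off-size cluster overlaps the locus but does not match a deletion
  expect_true(is.na(attr(loci_miss, "assignments")$matched_del[1]))
})

test_that("rates follow the printed definitions", {
  # all correct, no noise
  truth <- mk_truth(c(1000, 5000, 5200), c(1400, 5400, 5800),
                    c("L1", "L2", "L2"))
  cl <- mk_clusters(l = c(950, 4950, 5150), r = c(1450, 5450, 5850),
                    mu = c(410, 395, 590))
  r <- compute_rates(classify_loci(cl, truth))
  expect_equal(r$tpr1, 1)
  expect_equal(r$tpr2, 1)
  expect_equal(r$fpr1, 0)
  expect_equal(r$fpr2, 0)

  # 10 truth pairs, 4 predicted as single, rest as pairs, no no-truth
  # predictions: FPR1 = 4 / 10
  starts <- seq(0, by = 10000, length.out = 10)
  truth10 <- dplyr::bind_rows(lapply(seq_along(starts), function(i) {
    mk_truth(c(starts[i], starts[i] + 150), c(starts[i] + 400, starts[i] + 700),
             paste0("P", i), id = paste0("d", i, c("a", "b")))
  }))
  cl10 <- dplyr::bind_rows(lapply(seq_along(starts), function(i) {
    if (i <= 4) {
      mk_clusters(l = starts[i] - 50, r = starts[i] + 750, mu = 480,
                  sigma = 100, id = paste0("c", i))
    } else {
      mk_clusters(l = starts[i] - 50 + c(0, 180), r = starts[i] + c(420, 750),
                  mu = c(400, 550), id = paste0("c", i, c("a", "b")))
    }
  }))
  r10 <- compute_rates(classify_loci(cl10, truth10))
  expect_equal(r10$fpr1, 4 / 10)
  expect_equal(r10$tpr2, 6 / 10)
  expect_true(is.na(r10$tpr1))  # no simulated singles: undefined, not 0

  # rates are invariant under permuting loci and cluster ids
  perm <- sample(nrow(cl10))
  r_perm <- compute_rates(classify_loci(cl10[perm, ], truth10))
  expect_equal(r_perm[c("tpr1", "fpr1", "tpr2", "fpr2")],
               r10[c("tpr1", "fpr1", "tpr2", "fpr2")])
})

test_that("oracle clusters built from truth score perfectly", {
  withr::with_seed(131, {
    sp <- scenario_spec(n_single = 10, n_pairs = 5, zygosity_mode = "B",
                        chrom_length = 1e6, size_max = 2000,
                        min_pair_size_diff = 150)
    tr <- simulate_truth(sp, seed = 31)
    oracle <- mk_clusters(l = tr$start - 50, r = tr$end + 50, mu = tr$size,
                          id = tr$deletion_id, chrom = tr$chrom)
    r <- compute_rates(classify_loci(oracle, tr))
    expect_equal(r$tpr1, 1)
    expect_equal(r$tpr2, 1)
    expect_equal(r$fpr1, 0)
    expect_equal(r$fpr2, 0)
  })
})

test_that("mis-assigned mappings are counted over correctly called pairs", {
  sp <- scenario_spec(n_single = 0, n_pairs = 4, zygosity_mode = "B",
                      chrom_length = 1e6, size_min = 300, size_max = 3000,
                      min_pair_size_diff = 300, coverage = 30)
  tr <- simulate_truth(sp, seed = 41)
  m <- simulate_mappings(tr, sp, seed = 42)
  models <- fragment_model("sim", 300, 35)
  f <- filter_stretched(m, models)
  fit <- cluster_deletions(f, models)
  loci <- classify_loci(fit, tr)
  r <- compute_rates(loci, fit, m)
  expect_false(is.na(r$misassignment_rate))
  expect_gte(r$misassignment_rate, 0)
  expect_lte(r$misassignment_rate, 1)
  # manual recount for one correctly identified pair
  asg <- attr(loci, "assignments")
  pair_loci <- loci[loci$truth_kind == "pair" & loci$predicted_kind == "pair", ]
  expect_gt(nrow(pair_loci), 0)
  cids <- pair_loci$cluster_ids[[1]]
  truth_of <- setNames(m$truth_del, m$id)
  mismatch <- 0; total <- 0
  for (cid in cids) {
    mem <- fit$clusters$members[[match(cid, fit$clusters$cluster_id)]]
    td <- truth_of[mem]
    td <- td[!is.na(td)]
    own <- asg$matched_del[match(cid, asg$cluster_id)]
    mismatch <- mismatch + sum(td != own)
    total <- total + length(td)
  }
  expect_equal(r$pair_members >= total, TRUE)
})

test_that("evaluation outputs are written as tab-separated files", {
  truth <- mk_truth(1000, 1400, "L1")
  cl <- mk_clusters(l = 950, r = 1450, mu = 410)
  loci <- classify_loci(cl, truth)
  rates <- compute_rates(loci)
  p1 <- withr::local_tempfile(fileext = ".tsv")
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_rates(rates, p1)
  write_classifications(loci, p2)
  expect_equal(readr::read_tsv(p1, show_col_types = FALSE)$tpr1, 1)
  back <- readr::read_tsv(p2, show_col_types = FALSE)
  expect_equal(back$locus_id, "L1")
})
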