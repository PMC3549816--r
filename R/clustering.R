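# lower median: for an even count, the lower of the two central values, so
# the threshold is always a score actually observed between two mappings
median_low <- function(x) {
  n <- length(x)
  if (n == 0) return(NA_real_)
  sort(x)[ceiling(n / 2)]
}

#' Estimate the clustering stop threshold from the data
#'
#' Because the normal density is never exactly zero, any two clusters with
#' overlapping triangles have a positive similarity, however weak. Clustering
#' therefore stops once the maximum similarity falls to a threshold `s_min`,
#' estimated from the data in a preprocessing step rather than fixed by the
#' user: for each mapping, the smallest strictly positive similarity score
#' between its singleton cluster and any other mapping's singleton in the
#' same region is recorded, and `s_min` is the median of these minima
#' (lower median for an even count). Mappings with no positive score
#' contribute nothing; the estimate is computed once, dataset-wide.
#'
#' @param mappings a mapping tibble; partitioned into regions on the fly if
#'   no `region_id` column is present.
#' @param models per-sample fragment models.
#' @param fallback threshold returned (with a warning) when no mapping has a
#'   positive score to any other; no merges are possible in that case, so
#'   the value is inconsequential. Default 0.5.
#' @return A one-row tibble with `s_min` and `contributing`, the number of
#'   mappings that had at least one positive score.
#' @export
estimate_s_min <- function(mappings, models, fallback = 0.5) {
  mappings <- check_mappings(mappings)
  check_models(models)
  if (!"region_id" %in% names(mappings)) {
    mappings <- partition_regions(mappings)
  }
  minima <- numeric(0)
  for (rid in unique(mappings$region_id)) {
    reg <- mappings[mappings$region_id == rid, ]
    if (nrow(reg) < 2) next
    cl <- singleton_clusters(region_order(reg), models)
    k <- nrow(cl)
    mins <- rep(Inf, k)
    for (i in seq_len(k - 1)) {
      for (j in seq((i + 1), k)) {
        if (max(cl$l[i], cl$l[j]) >= min(cl$r[i], cl$r[j])) next
        s <- sim_raw(cl$l[i], cl$r[i], cl$mu[i], cl$sigma[i], cl$volume[i],
                     cl$l[j], cl$r[j], cl$mu[j], cl$sigma[j], cl$volume[j])
        if (s > 0) {
          mins[i] <- min(mins[i], s)
          mins[j] <- min(mins[j], s)
        }
      }
    }
    minima <- c(minima, mins[is.finite(mins)])
  }
  if (length(minima) == 0) {
    warn("no pair of mappings has a positive similarity; using the fallback threshold.")
    return(tibble(s_min = fallback, contributing = 0L))
  }
  tibble(s_min = median_low(minima), contributing = length(minima))
}

# deterministic within-region processing order, independent of input order
region_order <- function(reg) {
  reg |> arrange(.data$left_inner, .data$right_inner, .data$span_d,
                 .data$sample_id, .data$id)
}

#' Agglomeratively cluster the mappings of one region
#'
#' Starts from one singleton cluster per mapping and repeatedly merges the
#' pair of clusters with the highest similarity, as long as that similarity
#' exceeds `s_min` (strictly) and more than one cluster remains. After each
#' merge, scores between the new cluster and all surviving clusters whose
#' triangles overlap it are computed (scores to non-overlapping clusters are
#' provably zero). Candidate pair scores are kept in a pool with lazy
#' invalidation: entries referring to merged-away clusters are simply
#' skipped. Equal scores are broken deterministically in favour of the
#' lexicographically smaller (older) cluster-id pair.
#'
#' @param region_mappings the mapping tibble of a single region.
#' @param models per-sample fragment models.
#' @param s_min stop threshold in \[0, 1\], usually from [estimate_s_min()].
#' @return A list of class `delclust_region` with elements `clusters` (the
#'   final cluster tibble with integer region-local ids, `sample_counts`
#'   list-column and `members`) and `merge_log` (tibble of `id1`, `id2`,
#'   `score`, `new_id` in merge order).
#' @export
agglomerate_region <- function(region_mappings, models, s_min) {
  region_mappings <- check_mappings(region_mappings)
  check_models(models)
  if (nrow(region_mappings) == 0) abort("region contains no mappings.")
  if (!is.finite(s_min) || s_min < 0 || s_min > 1) {
    abort("`s_min` must be in [0, 1].")
  }
  reg <- region_order(region_mappings)
  cl <- singleton_clusters(reg, models)
  k <- nrow(cl)
  # cluster state as flat vectors; merged clusters get ids k+1, k+2, ...
  cap <- 2L * k
  L <- c(cl$l, numeric(k)); R <- c(cl$r, numeric(k))
  MU <- c(cl$mu, numeric(k)); SG <- c(cl$sigma, numeric(k))
  N <- c(rep(1L, k), integer(k)); V <- c(cl$volume, numeric(k))
  MEM <- c(as.list(reg$id), vector("list", k))
  alive <- c(rep(TRUE, k), rep(FALSE, k))
  # candidate pair pool (a < b always); lazily invalidated
  pa <- integer(0); pb <- integer(0); ps <- numeric(0)
  add_pairs <- function(new, others) {
    for (o in others) {
      if (max(L[new], L[o]) >= min(R[new], R[o])) next
      s <- sim_raw(L[new], R[new], MU[new], SG[new], V[new],
                   L[o], R[o], MU[o], SG[o], V[o])
      if (s > 0) {
        pa[length(pa) + 1L] <<- min(new, o)
        pb[length(pb) + 1L] <<- max(new, o)
        ps[length(ps) + 1L] <<- s
      }
    }
  }
  for (i in seq_len(max(k - 1, 0))) add_pairs(i, seq(i + 1, k))
  log_id1 <- integer(0); log_id2 <- integer(0)
  log_score <- numeric(0); log_new <- integer(0)
  next_id <- k
  repeat {
    ok <- alive[pa] & alive[pb] & ps > s_min
    if (!any(ok)) break
    idx <- which(ok)
    best <- max(ps[idx])
    cand <- idx[ps[idx] == best]
    if (length(cand) > 1) cand <- cand[order(pa[cand], pb[cand])]
    pick <- cand[1]
    a <- pa[pick]; b <- pb[pick]
    next_id <- next_id + 1L
    nn <- N[a] + N[b]
    L[next_id] <- max(L[a], L[b]); R[next_id] <- min(R[a], R[b])
    MU[next_id] <- (N[a] * MU[a] + N[b] * MU[b]) / nn
    SG[next_id] <- sqrt((N[a] * SG[a]^2 + N[b] * SG[b]^2) / nn +
                          N[a] * N[b] * (MU[a] - MU[b])^2 / nn^2)
    N[next_id] <- nn
    V[next_id] <- tri_vol(L[next_id], R[next_id], MU[next_id], SG[next_id])
    MEM[[next_id]] <- c(MEM[[a]], MEM[[b]])
    alive[a] <- FALSE; alive[b] <- FALSE; alive[next_id] <- TRUE
    log_id1 <- c(log_id1, a); log_id2 <- c(log_id2, b)
    log_score <- c(log_score, best); log_new <- c(log_new, next_id)
    keep <- alive[pa] & alive[pb]
    pa <- pa[keep]; pb <- pb[keep]; ps <- ps[keep]
    add_pairs(next_id, which(alive)[which(alive) != next_id])
  }
  ids <- which(alive)
  sample_of <- setNames(reg$sample_id, reg$id)
  clusters <- tibble(
    cluster_id = ids, n = N[ids], l = L[ids], r = R[ids],
    mu = MU[ids], sigma = SG[ids], volume = V[ids],
    members = MEM[ids],
    sample_counts = purrr::map(MEM[ids], function(mm) {
      tab <- table(factor(sample_of[mm], levels = sort(unique(models$sample_id))))
      setNames(as.integer(tab), names(tab))
    })
  ) |> arrange(.data$l, .data$r, .data$cluster_id)
  structure(
    list(clusters = clusters,
         merge_log = tibble(id1 = log_id1, id2 = log_id2, score = log_score,
                            new_id = log_new),
         n_mappings = k),
    class = "delclust_region"
  )
}

#' Call deletion clusters from stretched mappings
#'
#' Runs the full clustering pipeline: derives footprints, partitions the
#' mappings into independent regions, estimates the stop threshold `s_min`
#' from the data (unless overridden), and agglomeratively clusters each
#' region. Clusters with at least `min_support` member mappings are the
#' deletion calls; smaller clusters (typically singletons from erroneous
#' mappings) are retained but flagged.
#'
#' @param mappings a mapping tibble, e.g. from [read_mapping_table()],
#'   [read_bam_mappings()] or [simulate_mappings()]. Apply
#'   [filter_stretched()] first for table input.
#' @param models per-sample fragment models ([fragment_model()]).
#' @param s_min optional threshold override in \[0, 1\]; by default
#'   estimated with [estimate_s_min()].
#' @param min_support minimum cluster cardinality for a cluster to be
#'   reported as a deletion call (default 2).
#' @return An object of class `delclust_fit` with components `clusters`
#'   (all clusters across regions, with `chrom`, `region_id`, global
#'   `cluster_id`, parameters, `members` and `sample_counts`), `merge_log`,
#'   `mappings` (with `region_id`), `threshold`, `s_min`, `min_support`
#'   and `models`. Use [tidy()] for the per-cluster report table and
#'   [glance()] for a one-row summary.
#' @examples
#' ms <- tibble::tibble(
#'   id = paste0("m", 1:4), sample_id = "s", chrom = "chr1",
#'   left_inner = c(1000, 1010, 980, 5000),
#'   right_inner = c(1500, 1490, 1520, 5480),
#'   span_d = c(700, 690, 705, 650)
#' )
#' fit <- cluster_deletions(ms, fragment_model("s", 300, 35))
#' tidy(fit)
#' @export
cluster_deletions <- function(mappings, models, s_min = NULL, min_support = 2) {
  mappings <- check_mappings(mappings)
  check_models(models)
  if (nrow(mappings) == 0) abort("no mappings to cluster.")
  mappings <- partition_regions(mappings)
  threshold <- NULL
  if (is.null(s_min)) {
    threshold <- estimate_s_min(mappings, models)
    s_min <- threshold$s_min
  } else {
    threshold <- tibble(s_min = s_min, contributing = NA_integer_)
  }
  region_ids <- unique(mappings$region_id)
  chrom_of <- mappings |> distinct(.data$region_id, .data$chrom)
  results <- purrr::map(region_ids, function(rid) {
    agglomerate_region(mappings[mappings$region_id == rid, ], models, s_min)
  })
  clusters <- purrr::map2_dfr(results, region_ids, function(res, rid) {
    res$clusters |> mutate(region_id = rid, .before = 1)
  }) |>
    left_join(chrom_of, by = "region_id") |>
    mutate(cluster_id = paste0("r", .data$region_id, "_c", .data$cluster_id)) |>
    relocate("chrom", "region_id", "cluster_id") |>
    arrange(.data$chrom, .data$region_id, .data$l)
  merge_log <- purrr::map2_dfr(results, region_ids, function(res, rid) {
    res$merge_log |> mutate(region_id = rid, .before = 1)
  })
  structure(
    list(clusters = clusters, merge_log = merge_log, mappings = mappings,
         threshold = threshold, s_min = s_min, min_support = min_support,
         models = models),
    class = "delclust_fit"
  )
}

#' @export
print.delclust_fit <- function(x, ...) {
  g <- glance(x)
  cat("Deletion clustering of", g$n_mappings, "stretched mappings\n")
  cat("  regions:            ", g$n_regions, "\n")
  cat("  clusters:           ", g$n_clusters, "\n")
  cat(sprintf("  calls (n >= %d):     %d\n", x$min_support, g$n_calls))
  cat("  stop threshold:     ", signif(g$s_min, 4), "\n")
  invisible(x)
}

#' Tidy the clusters of a deletion-clustering fit
#'
#' @param x a `delclust_fit` from [cluster_deletions()].
#' @param ... unused.
#' @return One row per cluster with `chrom`, `region_id`, `cluster_id`,
#'   1-based inclusive breakpoint boundaries `start`/`end` (the deletion may
#'   start no earlier than `start` and end no later than `end`), `mu`,
#'   `sigma`, `n`, one `n_<sample>` count column per sample, a
#'   `below_min_support` flag and the `members` list-column.
#' @export
tidy.delclust_fit <- function(x, ...) {
  cl <- x$clusters
  samples <- sort(unique(x$models$sample_id))
  if (nrow(cl) == 0) {
    out <- tibble(chrom = character(0), region_id = integer(0),
                  cluster_id = character(0), start = numeric(0),
                  end = numeric(0), mu = numeric(0), sigma = numeric(0),
                  n = integer(0))
    for (s in samples) out[[paste0("n_", s)]] <- integer(0)
    out$below_min_support <- logical(0)
    out$members <- list()
    return(out)
  }
  counts <- purrr::map_dfr(cl$sample_counts, function(sc) {
    as_tibble(as.list(setNames(as.integer(sc[samples]), paste0("n_", samples))))
  })
  cl |>
    transmute(.data$chrom, .data$region_id, .data$cluster_id,
              start = .data$l + 1, end = .data$r,
              mu = .data$mu, sigma = .data$sigma, n = .data$n) |>
    bind_cols(counts) |>
    mutate(below_min_support = .data$n < x$min_support,
           members = cl$members)
}

#' Summarize a deletion-clustering fit in one row
#'
#' @param x a `delclust_fit`.
#' @param ... unused.
#' @return A one-row tibble: `n_mappings`, `n_regions`, `n_clusters`,
#'   `n_calls` (clusters meeting `min_support`), `n_singletons`, `s_min`,
#'   and `contributing` (mappings that informed the threshold estimate).
#' @export
glance.delclust_fit <- function(x, ...) {
  tibble(
    n_mappings = nrow(x$mappings),
    n_regions = length(unique(x$mappings$region_id)),
    n_clusters = nrow(x$clusters),
    n_calls = sum(x$clusters$n >= x$min_support),
    n_singletons = sum(x$clusters$n == 1),
    s_min = x$s_min,
    contributing = x$threshold$contributing
  )
}
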