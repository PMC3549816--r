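# truth loci = connected components of reference overlap among truth
# deletions (computed with a per-chromosome sweep when not annotated)
assign_truth_loci <- function(truth) {
  if ("locus_id" %in% names(truth) && !anyNA(truth$locus_id)) return(truth)
  t2 <- truth |> arrange(.data$chrom, .data$start, .data$end)
  lid <- integer(nrow(t2))
  cur <- 0L
  cur_chrom <- NA_character_
  cur_end <- -Inf
  for (i in seq_len(nrow(t2))) {
    if (!identical(t2$chrom[i], cur_chrom) || t2$start[i] >= cur_end) {
      cur <- cur + 1L
      cur_chrom <- t2$chrom[i]
      cur_end <- t2$end[i]
    } else {
      cur_end <- max(cur_end, t2$end[i])
    }
    lid[i] <- cur
  }
  t2 |> mutate(locus_id = paste0("L", lid))
}

#' Classify truth loci against predicted clusters
#'
#' A truth locus is a maximal set of truth deletions connected by reference
#' overlap (a single deletion, or a pair of overlapping partners). A cluster
#' with at least `min_support` members matches a truth deletion when its
#' breakpoint boundaries contain the deletion (`l <= start` and
#' `end <= r`) and the deletion size lies within three standard deviations
#' of the cluster's size estimate (`|size - mu| <= 3 sigma`) -- exactly the
#' trapezoid the cluster reports. Each supported cluster is assigned to at
#' most one locus: the locus of its matched deletions, or, if it matches
#' nothing, the locus whose reference span its breakpoint region overlaps;
#' supported clusters away from any truth form their own no-truth loci. The
#' predicted kind of a locus is the number of distinct supported clusters
#' assigned to it: none, single, pair, or multi (3 or more).
#'
#' @param fit a `delclust_fit`, or a cluster table (from [tidy()] or
#'   [read_cluster_table()], with 1-based `start`/`end` columns).
#' @param truth a truth tibble ([simulate_truth()] / [read_truth_bed()]).
#' @param min_support minimum cluster cardinality (default 2).
#' @return A tibble with one row per locus: `locus_id`, `chrom`,
#'   `truth_kind` (`none`/`single`/`pair`/`multi`), `predicted_kind`,
#'   `n_truth`, `n_clusters`, and list-columns `cluster_ids` and
#'   `matched_dels` (best-matched deletion per assigned cluster, `NA` where
#'   the cluster matched none). The full cluster-to-locus assignment is
#'   attached as attribute `"assignments"`.
#' @export
classify_loci <- function(fit, truth, min_support = 2) {
  cl <- if (inherits(fit, "delclust_fit")) {
    fit$clusters |> select("chrom", "cluster_id", "l", "r", "mu", "sigma", "n")
  } else if (all(c("start", "end") %in% names(fit))) {
    fit |> transmute(.data$chrom, .data$cluster_id, l = .data$start - 1,
                     r = .data$end, .data$mu, .data$sigma, .data$n)
  } else {
    fit |> select("chrom", "cluster_id", "l", "r", "mu", "sigma", "n")
  }
  truth <- assign_truth_loci(truth)
  if (!"size" %in% names(truth)) {
    truth <- truth |> mutate(size = .data$end - .data$start)
  }
  sup <- cl |> filter(.data$n >= min_support)
  locus_span <- truth |>
    group_by(.data$locus_id) |>
    summarize(chrom = first(.data$chrom), span_start = min(.data$start),
              span_end = max(.data$end), n_truth = n(), .groups = "drop")
  # per-cluster matched deletions and locus assignment
  assignments <- purrr::pmap_dfr(
    list(sup$chrom, sup$cluster_id, sup$l, sup$r, sup$mu, sup$sigma, sup$n),
    function(chrom, cid, l, r, mu, sigma, n) {
      cand <- truth[truth$chrom == chrom & l <= truth$start &
                      truth$end <= r & abs(truth$size - mu) <= 3 * sigma, ]
      if (nrow(cand) > 0) {
        by_locus <- cand |> count(.data$locus_id, sort = TRUE)
        locus <- by_locus$locus_id[1]
        in_locus <- cand[cand$locus_id == locus, ]
        best <- in_locus$deletion_id[which.min(abs(in_locus$size - mu))]
        return(tibble(cluster_id = cid, locus_id = locus, matched_del = best,
                      matched_dels = list(in_locus$deletion_id), n = n))
      }
      ls <- locus_span[locus_span$chrom == chrom &
                         locus_span$span_start < r &
                         l < locus_span$span_end, ]
      if (nrow(ls) > 0) {
        ov <- pmin(ls$span_end, r) - pmax(ls$span_start, l)
        locus <- ls$locus_id[which.max(ov)]
        return(tibble(cluster_id = cid, locus_id = locus,
                      matched_del = NA_character_,
                      matched_dels = list(character(0)), n = n))
      }
      tibble(cluster_id = cid, locus_id = paste0("none_", cid),
             matched_del = NA_character_, matched_dels = list(character(0)),
             n = n)
    })
  if (nrow(assignments) == 0) {
    assignments <- tibble(cluster_id = character(0), locus_id = character(0),
                          matched_del = character(0), matched_dels = list(),
                          n = integer(0))
  }
  kind_of <- function(k) {
    dplyr::case_when(k == 0 ~ "none", k == 1 ~ "single", k == 2 ~ "pair",
                     TRUE ~ "multi")
  }
  pred <- assignments |>
    group_by(.data$locus_id) |>
    summarize(n_clusters = n(), cluster_ids = list(.data$cluster_id),
              matched_dels_per_cluster = list(.data$matched_del),
              .groups = "drop")
  loci <- locus_span |>
    full_join(pred, by = "locus_id") |>
    mutate(
      n_truth = tidyr::replace_na(.data$n_truth, 0L),
      n_clusters = tidyr::replace_na(.data$n_clusters, 0L),
      truth_kind = kind_of(.data$n_truth),
      predicted_kind = kind_of(.data$n_clusters),
      cluster_ids = purrr::map(.data$cluster_ids, function(x) x %||% character(0)),
      matched_dels = purrr::map(.data$matched_dels_per_cluster,
                                function(x) x %||% character(0))
    ) |>
    select("locus_id", "chrom", "truth_kind", "predicted_kind", "n_truth",
           "n_clusters", "cluster_ids", "matched_dels")
  # fill chrom for no-truth loci from their cluster
  none_idx <- which(is.na(loci$chrom))
  if (length(none_idx) > 0) {
    chrom_by_cluster <- setNames(sup$chrom, sup$cluster_id)
    loci$chrom[none_idx] <- purrr::map_chr(
      loci$cluster_ids[none_idx], function(x) unname(chrom_by_cluster[x[1]]))
  }
  attr(loci, "assignments") <- assignments
  loci
}

# can the clusters of a predicted pair be matched one-to-one to the two
# partner deletions? returns the named assignment or NULL
pair_assignment <- function(cluster_ids, assignments, locus_dels) {
  sub <- assignments[match(cluster_ids, assignments$cluster_id), ]
  sets <- purrr::map(sub$matched_dels, intersect, locus_dels)
  if (length(cluster_ids) != 2 || length(locus_dels) != 2) return(NULL)
  for (d1 in sets[[1]]) {
    for (d2 in sets[[2]]) {
      if (d1 != d2) return(setNames(c(d1, d2), cluster_ids))
    }
  }
  NULL
}

#' Detection and mis-assignment rates against a simulated truth
#'
#' Computes the single- and pair-detection accuracy from a locus
#' classification:
#' \deqn{TPR_1 = \frac{\#\text{correctly predicted single deletions}}
#'   {\#\text{simulated single deletions}}, \quad
#'   FPR_1 = \frac{\#\text{falsely predicted single deletions}}
#'   {\#\text{simulated pairs} + \#\text{no deletion detected as deletion}}}
#' and analogously `TPR2`/`FPR2` for pairs of overlapping deletions. When
#' the fitted clusters and truth-annotated mappings are supplied, the
#' mapping mis-assignment rate is also computed over correctly identified
#' pairs: the fraction of member mappings placed in the cluster that does
#' not correspond to their haplotype-of-origin deletion (mappings without a
#' truth annotation, i.e. noise, are excluded).
#'
#' @param loci a classification from [classify_loci()].
#' @param fit optionally, the `delclust_fit` (for cluster membership).
#' @param mappings optionally, the truth-annotated mapping tibble
#'   ([simulate_mappings()]).
#' @return A one-row tibble: `tpr1`, `fpr1`, `tpr2`, `fpr2`,
#'   `misassignment_rate` (`NA` when not computable), and the underlying
#'   counts. Rates with zero denominators are `NA`.
#' @export
compute_rates <- function(loci, fit = NULL, mappings = NULL) {
  p1 <- sum(loci$truth_kind == "single")
  p2 <- sum(loci$truth_kind == "pair")
  none_pred <- sum(loci$truth_kind == "none" & loci$n_clusters > 0)
  tp1 <- sum(loci$truth_kind == "single" & loci$predicted_kind == "single")
  tp2 <- sum(loci$truth_kind == "pair" & loci$predicted_kind == "pair")
  fp1 <- sum(loci$truth_kind != "single" & loci$predicted_kind == "single")
  fp2 <- sum(loci$truth_kind != "pair" & loci$predicted_kind == "pair")
  rate <- function(num, den) if (den > 0) num / den else NA_real_
  mis_rate <- NA_real_
  mis_n <- NA_integer_
  mis_total <- NA_integer_
  if (!is.null(fit) && !is.null(mappings) && "truth_del" %in% names(mappings)) {
    assignments <- attr(loci, "assignments")
    members_of <- setNames(fit$clusters$members, fit$clusters$cluster_id)
    truth_of <- setNames(
      purrr::map_chr(strsplit(mappings$truth_del, ","),
                     function(x) x[1] %||% NA_character_),
      mappings$id)
    mis <- 0L; tot <- 0L
    pair_loci <- loci[loci$truth_kind == "pair" & loci$predicted_kind == "pair", ]
    for (i in seq_len(nrow(pair_loci))) {
      cids <- pair_loci$cluster_ids[[i]]
      dels <- assignments$matched_dels[match(cids, assignments$cluster_id)]
      locus_dels <- unique(unlist(dels))
      asg <- pair_assignment(cids, assignments, locus_dels)
      if (is.null(asg)) next
      for (cid in cids) {
        tm <- truth_of[members_of[[cid]]]
        tm <- tm[!is.na(tm)]
        mis <- mis + sum(tm != asg[[cid]])
        tot <- tot + length(tm)
      }
    }
    mis_rate <- rate(mis, tot)
    mis_n <- mis
    mis_total <- tot
  }
  tibble(
    tpr1 = rate(tp1, p1),
    fpr1 = rate(fp1, p2 + none_pred),
    tpr2 = rate(tp2, p2),
    fpr2 = rate(fp2, p1 + none_pred),
    misassignment_rate = mis_rate,
    n_single_truth = p1, n_pair_truth = p2, n_none_pred = none_pred,
    tp1 = tp1, fp1 = fp1, tp2 = tp2, fp2 = fp2,
    misassigned = mis_n, pair_members = mis_total
  )
}

#' Write evaluation outputs
#'
#' Writes the rate summary (and optionally the per-locus classification)
#' as tab-separated files.
#'
#' @param rates a one-row tibble from [compute_rates()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_rates <- function(rates, path) {
  readr::write_tsv(rates, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_rates
#' @param loci a classification from [classify_loci()].
#' @export
write_classifications <- function(loci, path) {
  loci |>
    mutate(cluster_ids = purrr::map_chr(.data$cluster_ids, paste, collapse = ","),
           matched_dels = purrr::map_chr(.data$matched_dels, function(x) {
             paste(tidyr::replace_na(x, "."), collapse = ",")
           })) |>
    readr::write_tsv(path, progress = FALSE)
  invisible(path)
}
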