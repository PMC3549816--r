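#' Fragment-length models
#'
#' A fragment-length model holds the mean and standard deviation of the
#' sequenced fragment length for one sample. A stretched mapping with outer
#' distance `span_d` then implies a deletion whose size is distributed
#' `Normal(span_d - mean, sd)`.
#'
#' @param sample_id sample identifier (matched against the `sample_id`
#'   column of mapping tables).
#' @param mean mean fragment length in base pairs; must be positive.
#' @param sd standard deviation of the fragment length in base pairs; must be
#'   positive.
#'
#' @return A tibble with columns `sample_id`, `mean`, `sd`; one row per
#'   sample. Several models can be bound together with [dplyr::bind_rows()].
#' @examples
#' fragment_model("tumor", mean = 300, sd = 35)
#' @export
fragment_model <- function(sample_id, mean, sd) {
  if (any(!is.finite(mean)) || any(mean <= 0)) {
    abort("`mean` must be a positive, finite fragment length.")
  }
  if (any(!is.finite(sd)) || any(sd <= 0)) {
    abort("`sd` must be a positive, finite standard deviation.")
  }
  tibble(sample_id = as.character(sample_id), mean = as.numeric(mean),
         sd = as.numeric(sd))
}

check_models <- function(models) {
  req <- c("sample_id", "mean", "sd")
  if (!is.data.frame(models) || !all(req %in% names(models))) {
    abort("`models` must be a data frame with columns sample_id, mean, sd.")
  }
  if (anyDuplicated(models$sample_id)) {
    abort("`models` has duplicated sample_id entries.")
  }
  if (any(models$mean <= 0) || any(models$sd <= 0)) {
    abort("fragment-length models require mean > 0 and sd > 0.")
  }
  invisible(models)
}

check_mappings <- function(mappings, require_id = TRUE) {
  req <- c("sample_id", "chrom", "left_inner", "right_inner", "span_d")
  missing_cols <- setdiff(req, names(mappings))
  if (!is.data.frame(mappings) || length(missing_cols) > 0) {
    abort(paste0("`mappings` must contain columns: ",
                 paste(req, collapse = ", "), "."))
  }
  if (require_id && !"id" %in% names(mappings)) {
    mappings <- mappings |> mutate(id = paste0("m", row_number()), .before = 1)
  }
  mappings
}

# one-row cluster tibble; volume is cached at construction so it is computed
# exactly once per cluster lifetime
new_cluster_row <- function(cluster_id, n, l, r, mu, sigma,
                            members = list(character(0))) {
  tibble(
    cluster_id = cluster_id,
    n = as.integer(n),
    l = as.numeric(l),
    r = as.numeric(r),
    mu = as.numeric(mu),
    sigma = as.numeric(sigma),
    volume = tri_vol(as.numeric(l), as.numeric(r), as.numeric(mu),
                     as.numeric(sigma)),
    members = members
  )
}

#' Build singleton deletion clusters from stretched mappings
#'
#' Every mapping starts out as its own cluster. For a mapping with inner
#' boundaries `left_inner`/`right_inner` and outer distance `span_d`, under
#' the fragment model `(mean, sd)` of its sample, the singleton cluster is
#' `n = 1`, `l = left_inner`, `r = right_inner`, `mu = span_d - mean`,
#' `sigma = sd`. Coordinates are 0-based half-open: `l` is the first position
#' at which the deletion may start and `r` the first position that may not be
#' deleted.
#'
#' @param mappings a mapping tibble with columns `id`, `sample_id`, `chrom`,
#'   `left_inner`, `right_inner`, `span_d` (see [read_mapping_table()]).
#' @param models per-sample fragment-length models, see [fragment_model()].
#'
#' @return A tibble with one cluster row per mapping: `cluster_id`, `n`, `l`,
#'   `r`, `mu`, `sigma`, `volume` (cached triangle volume) and a `members`
#'   list-column of mapping ids.
#' @examples
#' m <- tibble::tibble(id = "m1", sample_id = "s", chrom = "chr1",
#'                     left_inner = 1000, right_inner = 1500, span_d = 700)
#' singleton_clusters(m, fragment_model("s", 300, 35))
#' @export
singleton_clusters <- function(mappings, models) {
  mappings <- check_mappings(mappings)
  check_models(models)
  bad <- mappings$left_inner >= mappings$right_inner
  if (any(bad)) {
    abort(paste0("degenerate mapping(s) with left_inner >= right_inner: ",
                 paste(head(mappings$id[bad], 5), collapse = ", "),
                 if (sum(bad) > 5) ", ..." else ""))
  }
  unknown <- setdiff(unique(mappings$sample_id), models$sample_id)
  if (length(unknown) > 0) {
    abort(paste0("no fragment model for sample(s): ",
                 paste(unknown, collapse = ", ")))
  }
  m <- mappings |> left_join(models, by = "sample_id")
  purrr::pmap_dfr(
    list(m$id, m$left_inner, m$right_inner, m$span_d, m$mean, m$sd),
    function(id, l, r, d, mean, sd) {
      new_cluster_row(id, 1L, l, r, d - mean, sd, members = list(id))
    }
  )
}

#' Merge two deletion clusters
#'
#' Combines the parameters of two clusters whose triangles overlap into the
#' parameters of their union, following an average-link strategy: the new
#' base is the intersection of the two bases, the new size mean is the
#' membership-weighted mean, and the new variance aggregates the two
#' sub-populations,
#' \deqn{\sigma^2 = \frac{n_1\sigma_1^2 + n_2\sigma_2^2}{n} +
#'   \frac{n_1 n_2 (\mu_1-\mu_2)^2}{n^2}, \quad n = n_1 + n_2.}
#' The variance is deliberately independent of cluster cardinality (it does
#' not shrink as 1/n), so that merge order is driven by similarity rather
#' than cluster size; it broadens as the two clusters disagree about the
#' deletion size.
#'
#' @param c1,c2 one-row cluster tibbles as produced by [singleton_clusters()]
#'   or previous merges. The order of arguments does not matter.
#' @param cluster_id id for the merged cluster; defaults to pasting the two
#'   input ids.
#'
#' @return A one-row cluster tibble with `n = n1 + n2`, `l = max(l1, l2)`,
#'   `r = min(r1, r2)`, the weighted `mu`, the aggregated `sigma`, a freshly
#'   cached `volume`, and the union of `members`.
#' @examples
#' ms <- tibble::tibble(id = c("a", "b"), sample_id = "s", chrom = "chr1",
#'                      left_inner = c(100, 150), right_inner = c(900, 800),
#'                      span_d = c(700, 710))
#' cl <- singleton_clusters(ms, fragment_model("s", 300, 35))
#' merge_clusters(cl[1, ], cl[2, ])
#' @export
merge_clusters <- function(c1, c2, cluster_id = NULL) {
  stopifnot(is.data.frame(c1), nrow(c1) == 1, is.data.frame(c2), nrow(c2) == 1)
  l <- max(c1$l, c2$l)
  r <- min(c1$r, c2$r)
  if (l >= r) {
    abort("cannot merge clusters with non-overlapping triangles (max(l) >= min(r)).")
  }
  n1 <- c1$n; n2 <- c2$n; n <- n1 + n2
  mu <- (n1 * c1$mu + n2 * c2$mu) / n
  var <- (n1 * c1$sigma^2 + n2 * c2$sigma^2) / n +
    n1 * n2 * (c1$mu - c2$mu)^2 / n^2
  id <- cluster_id %||% paste(c1$cluster_id, c2$cluster_id, sep = "+")
  mem <- list(c(c1$members[[1]], c2$members[[1]]))
  new_cluster_row(id, n, l, r, mu, sqrt(var), members = mem)
}
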