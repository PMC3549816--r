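# Independent oracles and random-instance generators used across tests.

# fine-grid numerical integration of the ridge volume: the height is
# constant along anti-diagonals, so the 2-D integral over the triangle
# reduces exactly to a 1-D integral of line length times density
oracle_volume <- function(l, r, mu, sigma, h = 0.01) {
  w <- r - l
  if (w <= 0) return(0)
  s <- seq(h / 2, w - h / 2, by = h)
  sum((w - s) * dnorm(s, mu, sigma)) * h
}

oracle_inter_volume <- function(l1, r1, mu1, s1, l2, r2, mu2, s2, h = 0.01) {
  li <- max(l1, l2); ri <- min(r1, r2)
  w <- ri - li
  if (w <= 0) return(0)
  s <- seq(h / 2, w - h / 2, by = h)
  sum((w - s) * pmin(dnorm(s, mu1, s1), dnorm(s, mu2, s2))) * h
}

oracle_similarity <- function(c1, c2, h = 0.01) {
  v1 <- oracle_volume(c1$l, c1$r, c1$mu, c1$sigma, h)
  v2 <- oracle_volume(c2$l, c2$r, c2$mu, c2$sigma, h)
  oracle_inter_volume(c1$l, c1$r, c1$mu, c1$sigma,
                      c2$l, c2$r, c2$mu, c2$sigma, h) / max(v1, v2)
}

# well-formed random clusters: stretched-mapping filtering guarantees
# mu >= 3 sigma for singletons and merging keeps mu a convex combination,
# so realistic clusters carry their ridge with margin inside the triangle
random_cluster <- function() {
  sigma <- runif(1, 5, 50)
  w <- round(runif(1, 6 * sigma, 20 * sigma))
  l <- round(runif(1, 0, 1e6))
  mu <- runif(1, 3 * sigma, w - 3 * sigma)
  tibble::tibble(cluster_id = "x", n = 1L, l = l, r = l + w, mu = mu,
                 sigma = sigma,
                 volume = delclust::triangle_volume(
                   tibble::tibble(l = l, r = l + w, mu = mu, sigma = sigma)),
                 members = list("x"))
}

# brute-force connected components of the footprint-overlap graph
naive_partition <- function(mappings) {
  m <- delclust:::derive_footprints(mappings)
  n <- nrow(m)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      adj[i, j] <- i != j && m$chrom[i] == m$chrom[j] &&
        m$fp_start[i] < m$fp_end[j] && m$fp_start[j] < m$fp_end[i]
    }
  }
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    cid <- cid + 1L
    queue <- i
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cid
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  split(m$id, comp)
}

# brute-force stop-threshold estimate: per-mapping smallest positive
# singleton-to-singleton score within its component, lower median overall
naive_s_min <- function(mappings, models, fallback = 0.5) {
  comps <- naive_partition(mappings)
  minima <- c()
  for (ids in comps) {
    reg <- mappings[match(ids, mappings$id), ]
    cl <- delclust::singleton_clusters(reg, models)
    k <- nrow(cl)
    if (k < 2) next
    for (i in seq_len(k)) {
      pos <- c()
      for (j in seq_len(k)) {
        if (i == j) next
        if (max(cl$l[i], cl$l[j]) >= min(cl$r[i], cl$r[j])) next
        s <- delclust::cluster_similarity(cl[i, ], cl[j, ])
        if (s > 0) pos <- c(pos, s)
      }
      if (length(pos) > 0) minima <- c(minima, min(pos))
    }
  }
  if (length(minima) == 0) return(fallback)
  sort(minima)[ceiling(length(minima) / 2)]
}

# greedy agglomerative clustering that rescans all pairs at every
# iteration; same tie-breaking (first maximum in ascending id-pair order)
naive_agglomerate <- function(region_mappings, models, s_min) {
  reg <- dplyr::arrange(region_mappings, left_inner, right_inner, span_d,
                        sample_id, id)
  cl <- delclust::singleton_clusters(reg, models)
  active <- lapply(seq_len(nrow(cl)), function(i) {
    row <- cl[i, ]
    row$int_id <- i
    row
  })
  next_id <- nrow(cl)
  repeat {
    best <- NULL
    kk <- length(active)
    if (kk <= 1) break
    ord <- order(vapply(active, function(x) x$int_id, numeric(1)))
    for (ii in seq_len(kk - 1)) {
      for (jj in seq(ii + 1, kk)) {
        a <- active[[ord[ii]]]; b <- active[[ord[jj]]]
        if (max(a$l, b$l) >= min(a$r, b$r)) next
        s <- delclust::cluster_similarity(a, b)
        if (s > s_min && (is.null(best) || s > best$s)) {
          best <- list(i = ord[ii], j = ord[jj], s = s)
        }
      }
    }
    if (is.null(best)) break
    merged <- delclust::merge_clusters(active[[best$i]], active[[best$j]])
    next_id <- next_id + 1
    merged$int_id <- next_id
    active <- c(active[-c(best$i, best$j)], list(merged))
  }
  parts <- lapply(active, function(x) sort(x$members[[1]]))
  parts[order(vapply(parts, function(x) x[1], character(1)))]
}

partition_of <- function(result_clusters) {
  parts <- lapply(result_clusters$members, sort)
  parts[order(vapply(parts, function(x) x[1], character(1)))]
}

# random region of mappings whose implied deletions sit inside the triangle
random_region_mappings <- function(n, n_signals = max(1, n %/% 6),
                                   chrom = "chr1") {
  sig_pos <- sort(round(runif(n_signals, 0, 4000)))
  sig_size <- round(runif(n_signals, 105, 900))
  rows <- lapply(seq_len(n), function(i) {
    k <- sample.int(n_signals, 1)
    size <- sig_size[k]
    start <- sig_pos[k]
    frag <- max(200, round(rnorm(1, 300, 35)))
    slack_l <- sample.int(90, 1)
    slack_r <- (frag - 200) - slack_l + sample.int(20, 1)
    li <- start - slack_l
    ri <- start + size + max(slack_r, 1)
    tibble::tibble(id = sprintf("m%03d", i), sample_id = "s", chrom = chrom,
                   left_inner = li, right_inner = ri,
                   span_d = 300 + (ri - li) - 100 + sample(-50:50, 1))
  })
  m <- dplyr::bind_rows(rows)
  m[m$left_inner < m$right_inner, ]
}

test_models <- function() delclust::fragment_model("s", 300, 35)

`%||%` <- function(a, b) if (is.null(a)) b else a
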