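# log-uniform deletion sizes, a stand-in for an empirical size list; any
# vector of candidate sizes can be supplied instead via `size_pool`
rlunif_sizes <- function(n, min, max) {
  pmin(pmax(round(exp(runif(n, log(min), log(max)))), min), max)
}

#' Define a simulation scenario
#'
#' Describes a donor with `n_haplotypes` chromosome copies (4 = two diploid
#' genomes, e.g. a tumor/normal mixture) carrying non-overlapping single
#' deletions and pairs of overlapping deletions, from which stretched
#' paired-end mappings are generated at the mapping level (no read sequences
#' or alignment). Defaults follow the reference experimental design:
#' fragment length Normal(300, 35), read length 100, minimum deletion size
#' 105, 500 single + 500 paired loci, 20x coverage per haplotype.
#'
#' Zygosity modes for a pair of overlapping deletions: `"A"` puts both
#' partners homozygously in one diploid copy each (haplotypes \{0,1\} and
#' \{2,3\}); `"B"` makes the second partner heterozygous (haplotypes
#' \{0,1\} and \{2\}). Single deletions are homozygous in the first copy
#' (\{0,1\}).
#'
#' @param n_single number of non-overlapping single-deletion loci.
#' @param n_pairs number of loci carrying two overlapping deletions.
#' @param zygosity_mode `"A"` or `"B"`, see Details.
#' @param n_haplotypes number of donor chromosome copies (default 4).
#' @param chrom chromosome name used in the output.
#' @param chrom_length reference chromosome length in bp.
#' @param size_min,size_max deletion-size range; sizes are drawn
#'   log-uniformly (or from `size_pool` when given).
#' @param size_pool optional vector of candidate deletion sizes (e.g. an
#'   empirical list) sampled uniformly instead of the log-uniform draw.
#' @param min_pair_size_diff minimum absolute size difference between the
#'   two partners of a pair (default 0).
#' @param overlap_min,overlap_max bounds of the uniformly drawn overlap
#'   fraction between partners (fraction of the smaller partner's size).
#' @param frag_mean,frag_sd fragment-length distribution in bp.
#' @param read_length read length in bp.
#' @param coverage sequence coverage per haplotype.
#' @param noise_rate expected number of spurious stretched mappings per
#'   simulated deletion (default 0).
#' @param locus_gap minimum reference gap between loci in bp, so loci fall
#'   into separate regions (default 1000).
#' @return A list of class `scenario_spec`.
#' @export
scenario_spec <- function(n_single = 500, n_pairs = 500,
                          zygosity_mode = c("A", "B"), n_haplotypes = 4,
                          chrom = "sim1", chrom_length = 2e7,
                          size_min = 105, size_max = 10000, size_pool = NULL,
                          min_pair_size_diff = 0,
                          overlap_min = 0.2, overlap_max = 0.8,
                          frag_mean = 300, frag_sd = 35, read_length = 100,
                          coverage = 20, noise_rate = 0, locus_gap = 1000) {
  zygosity_mode <- match.arg(zygosity_mode)
  stopifnot(n_single >= 0, n_pairs >= 0, n_haplotypes >= 1,
            chrom_length > 0, size_min >= 1, size_max >= size_min,
            overlap_min > 0, overlap_max <= 1, overlap_min <= overlap_max,
            frag_mean > 0, frag_sd > 0, read_length > 0, coverage > 0,
            noise_rate >= 0, locus_gap >= 0)
  if (zygosity_mode == "A" && n_pairs > 0 && n_haplotypes < 4) {
    abort("zygosity mode A needs at least 4 haplotypes.")
  }
  if (zygosity_mode == "B" && n_pairs > 0 && n_haplotypes < 3) {
    abort("zygosity mode B needs at least 3 haplotypes.")
  }
  structure(
    list(n_single = n_single, n_pairs = n_pairs,
         zygosity_mode = zygosity_mode, n_haplotypes = n_haplotypes,
         chrom = chrom, chrom_length = chrom_length,
         size_min = size_min, size_max = size_max, size_pool = size_pool,
         min_pair_size_diff = min_pair_size_diff,
         overlap_min = overlap_min, overlap_max = overlap_max,
         frag_mean = frag_mean, frag_sd = frag_sd, read_length = read_length,
         coverage = coverage, noise_rate = noise_rate, locus_gap = locus_gap),
    class = "scenario_spec"
  )
}

draw_size <- function(n, spec) {
  if (!is.null(spec$size_pool)) {
    pool <- spec$size_pool[spec$size_pool >= spec$size_min]
    if (length(pool) == 0) abort("size_pool has no sizes above size_min.")
    sample(pool, n, replace = TRUE)
  } else {
    rlunif_sizes(n, spec$size_min, spec$size_max)
  }
}

#' Simulate a ground-truth deletion set
#'
#' Places `n_single` single loci and `n_pairs` paired loci uniformly along
#' the chromosome so that distinct loci are separated by at least
#' `locus_gap`. Within a paired locus, the partner's size is drawn
#' independently (respecting `min_pair_size_diff`) and its interval overlaps
#' the first deletion by a uniformly drawn fraction of the smaller size, on
#' a random side. Partners reside on disjoint haplotype sets, so no two
#' deletions on the same haplotype ever overlap.
#'
#' @param spec a [scenario_spec()].
#' @param seed integer seed; the simulation is deterministic given the seed.
#' @return A tibble with one row per deletion: `deletion_id`, `chrom`,
#'   `start`, `end` (0-based half-open), `size`, `haplotypes`
#'   (comma-separated haplotype indices), `partner_id` (`NA` for singles)
#'   and `locus_id`.
#' @export
simulate_truth <- function(spec, seed) {
  stopifnot(inherits(spec, "scenario_spec"))
  withr::with_seed(seed, simulate_truth_impl(spec))
}

simulate_truth_impl <- function(spec) {
  n_loci <- spec$n_single + spec$n_pairs
  if (n_loci == 0) {
    return(tibble(deletion_id = character(0), chrom = character(0),
                  start = numeric(0), end = numeric(0), size = numeric(0),
                  haplotypes = character(0), partner_id = character(0),
                  locus_id = character(0)))
  }
  is_pair <- c(rep(FALSE, spec$n_single), rep(TRUE, spec$n_pairs))
  # build locus-local geometry first (offsets relative to the locus anchor)
  loci <- purrr::map(seq_len(n_loci), function(i) {
    s1 <- draw_size(1, spec)
    if (!is_pair[i]) {
      return(list(extent = s1, d = tibble(off = 0, size = s1, which = 1L)))
    }
    s2 <- draw_size(1, spec)
    tries <- 0
    while (abs(s2 - s1) < spec$min_pair_size_diff) {
      s2 <- draw_size(1, spec)
      tries <- tries + 1
      if (tries > 1000) abort("cannot satisfy min_pair_size_diff; widen the size range.")
    }
    ov <- max(1, round(runif(1, spec$overlap_min, spec$overlap_max) * min(s1, s2)))
    right_side <- runif(1) < 0.5
    off2 <- if (right_side) s1 - ov else -(s2 - ov)
    d <- tibble(off = c(0, off2), size = c(s1, s2), which = c(1L, 2L))
    shift <- min(d$off)
    d$off <- d$off - shift
    list(extent = max(d$off + d$size), d = d)
  })
  extents <- purrr::map_dbl(loci, "extent")
  if (sum(extents + spec$locus_gap) > 0.8 * spec$chrom_length) {
    abort("chrom_length too small for the requested number of loci.")
  }
  # uniform anchor placement with rejection against accepted loci
  anchors <- numeric(n_loci)
  acc_start <- numeric(0); acc_end <- numeric(0)
  for (i in seq_len(n_loci)) {
    placed <- FALSE
    for (try in seq_len(500)) {
      a <- floor(runif(1, spec$locus_gap, spec$chrom_length - extents[i] - spec$locus_gap))
      if (!any(a - spec$locus_gap < acc_end & a + extents[i] + spec$locus_gap > acc_start)) {
        placed <- TRUE
        break
      }
    }
    if (!placed) abort("locus placement failed; chrom_length too small.")
    anchors[i] <- a
    acc_start <- c(acc_start, a)
    acc_end <- c(acc_end, a + extents[i])
  }
  hap_sets <- switch(spec$zygosity_mode,
                     A = list("0,1", "2,3"),
                     B = list("0,1", "2"))
  del_counter <- 0
  purrr::map_dfr(seq_len(n_loci), function(i) {
    d <- loci[[i]]$d
    n_d <- nrow(d)
    ids <- paste0("del", del_counter + seq_len(n_d))
    del_counter <<- del_counter + n_d
    tibble(
      deletion_id = ids,
      chrom = spec$chrom,
      start = anchors[i] + d$off,
      end = anchors[i] + d$off + d$size,
      size = d$size,
      haplotypes = if (n_d == 1) "0,1" else unlist(hap_sets)[d$which],
      partner_id = if (n_d == 1) NA_character_ else rev(ids),
      locus_id = paste0("L", i)
    )
  }) |> arrange(.data$start)
}

#' Simulate stretched mappings from a truth set
#'
#' Generates paired-end fragments along each donor haplotype at a rate
#' matching the per-haplotype coverage, with lengths drawn from
#' `Normal(frag_mean, frag_sd)` truncated below at twice the read length. A
#' fragment whose two reads flank a deletion breakpoint on its haplotype
#' yields a stretched mapping: `span_d` is the fragment length plus all
#' deleted bases it spans, and the inner boundaries are the donor-to-
#' reference projections of the left read's end and the right read's start.
#' Fragments with a breakpoint inside a read would not align and are
#' dropped; fragments spanning no breakpoint are concordant and only
#' emitted on request. Spurious mappings with uniformly mis-stated implied
#' deletion sizes are added at `noise_rate` per true deletion.
#'
#' A paired-end experiment also yields pairs that span no deletion but whose
#' fragment happens to fall in the upper tail of the length distribution;
#' with a length of at least `frag_mean + 3 frag_sd` such a pair is
#' indistinguishable from a weak deletion signal and passes the stretched
#' filter. Pairs spanning no breakpoint are not emitted by default; set
#' `emit_tails = TRUE` to include the stretched upper-tail pairs (flagged
#' `kind = "tail"`) -- part of what the data-driven stop threshold sees on
#' genome-scale data -- or `emit_concordant = TRUE` for all of them.
#'
#' @param truth a truth tibble from [simulate_truth()].
#' @param spec the [scenario_spec()] used to generate it.
#' @param seed integer seed.
#' @param sample_id sample id attached to the mappings (one pooled sample).
#' @param emit_tails emit non-spanning pairs from the stretched upper tail
#'   of the fragment-length distribution (default `FALSE`).
#' @param emit_concordant also emit all remaining concordant pairs
#'   (default `FALSE`).
#' @return A mapping tibble with truth annotations: `truth_del`
#'   (comma-separated ids of the spanned deletions, `NA` otherwise),
#'   `truth_hap` (haplotype of origin, `NA` for injected noise), `kind`
#'   (`"signal"`, `"tail"`, `"concordant"` or `"noise"`) and the
#'   convenience flag `noise` (`kind == "noise"`).
#' @export
simulate_mappings <- function(truth, spec, seed, sample_id = "sim",
                              emit_tails = FALSE, emit_concordant = FALSE) {
  stopifnot(inherits(spec, "scenario_spec"))
  withr::with_seed(seed,
                   simulate_mappings_impl(truth, spec, sample_id,
                                          emit_tails, emit_concordant))
}

simulate_mappings_impl <- function(truth, spec, sample_id, emit_tails,
                                   emit_concordant) {
  rl <- spec$read_length
  out <- vector("list", spec$n_haplotypes + 1)
  for (h in seq_len(spec$n_haplotypes) - 1L) {
    hdel <- truth[purrr::map_lgl(strsplit(truth$haplotypes, ","),
                                 function(x) as.character(h) %in% x), ]
    hdel <- hdel |> arrange(.data$start)
    if (nrow(hdel) > 1 && any(hdel$start[-1] < hdel$end[-nrow(hdel)])) {
      abort("truth set places overlapping deletions on one haplotype.")
    }
    sizes <- hdel$size
    cumsz <- c(0, cumsum(sizes))
    bks <- if (nrow(hdel)) hdel$start - cumsz[-length(cumsz)] else numeric(0)
    donor_len <- spec$chrom_length - sum(sizes)
    n_frag <- rpois(1, spec$coverage * donor_len / (2 * rl))
    len <- pmax(2 * rl, round(rnorm(n_frag, spec$frag_mean, spec$frag_sd)))
    f <- floor(runif(n_frag, 0, pmax(donor_len - len, 1)))
    # breakpoints strictly inside the fragment window (f, f + len)
    n_in <- findInterval(f + len - 0.5, bks) - findInterval(f + 0.5, bks)
    hit <- which(n_in > 0)
    rows <- purrr::map_dfr(hit, function(i) {
      lo <- findInterval(f[i] + 0.5, bks)
      hi <- findInterval(f[i] + len[i] - 0.5, bks)
      bw <- bks[seq(lo + 1, hi)]
      if (any(bw < f[i] + rl | bw > f[i] + len[i] - rl)) return(NULL)
      deleted <- cumsz[hi + 1] - cumsz[lo + 1]
      d0 <- cumsz[lo + 1]
      tibble(
        left_inner = f[i] + rl + d0,
        right_inner = f[i] + len[i] - rl + d0 + deleted,
        span_d = len[i] + deleted,
        fp_start = f[i] + d0,
        truth_del = paste(hdel$deletion_id[seq(lo + 1, hi)], collapse = ","),
        truth_hap = h, kind = "signal"
      )
    })
    non_span <- which(n_in == 0)
    cutoff <- spec$frag_mean + 3 * spec$frag_sd
    keep_ns <- if (emit_concordant) {
      non_span
    } else if (emit_tails) {
      non_span[len[non_span] >= cutoff]
    } else {
      integer(0)
    }
    if (length(keep_ns) > 0) {
      d0c <- cumsz[findInterval(f[keep_ns] + 0.5, bks) + 1]
      rows <- bind_rows(rows, tibble(
        left_inner = f[keep_ns] + rl + d0c,
        right_inner = f[keep_ns] + len[keep_ns] - rl + d0c,
        span_d = len[keep_ns],
        fp_start = f[keep_ns] + d0c,
        truth_del = NA_character_, truth_hap = h,
        kind = ifelse(len[keep_ns] >= cutoff, "tail", "concordant")
      ))
    }
    out[[h + 1]] <- rows
  }
  # spurious stretched mappings with uniformly mis-stated implied sizes
  n_noise <- if (spec$noise_rate > 0 && nrow(truth) > 0) {
    rpois(1, spec$noise_rate * nrow(truth))
  } else 0
  if (n_noise > 0) {
    fake_size <- rlunif_sizes(n_noise, spec$size_min, spec$size_max)
    flen <- pmax(2 * rl, round(rnorm(n_noise, spec$frag_mean, spec$frag_sd)))
    pos <- floor(runif(n_noise, 0, pmax(spec$chrom_length - fake_size - flen, 1)))
    out[[spec$n_haplotypes + 1]] <- tibble(
      left_inner = pos + rl,
      right_inner = pos + flen - rl + fake_size,
      span_d = flen + fake_size,
      fp_start = pos,
      truth_del = NA_character_, truth_hap = NA_integer_, kind = "noise"
    )
  }
  m <- bind_rows(out)
  if (nrow(m) == 0) {
    return(tibble(id = character(0), sample_id = character(0),
                  chrom = character(0), left_inner = numeric(0),
                  right_inner = numeric(0), span_d = numeric(0),
                  fp_start = numeric(0), fp_end = numeric(0),
                  truth_del = character(0), truth_hap = integer(0),
                  kind = character(0), noise = logical(0)))
  }
  m |>
    mutate(sample_id = sample_id, chrom = spec$chrom,
           fp_end = .data$fp_start + .data$span_d,
           noise = .data$kind == "noise") |>
    arrange(.data$fp_start, .data$left_inner, .data$span_d) |>
    mutate(id = paste0("m", row_number())) |>
    select("id", "sample_id", "chrom", "left_inner", "right_inner", "span_d",
           "fp_start", "fp_end", "truth_del", "truth_hap", "kind", "noise")
}

#' Write and read a truth deletion set as a BED-like table
#'
#' Tab-separated with header: `chrom`, `start`, `end`, `deletion_id`,
#' `haplotypes`, `partner_id`, `locus_id`; coordinates 0-based half-open.
#'
#' @param truth a truth tibble ([simulate_truth()]).
#' @param path file path.
#' @return `write_truth_bed()` returns `path` invisibly; `read_truth_bed()`
#'   returns the truth tibble (with `size` recomputed).
#' @export
write_truth_bed <- function(truth, path) {
  truth |>
    select("chrom", "start", "end", "deletion_id", "haplotypes",
           "partner_id", "locus_id") |>
    readr::write_tsv(path, progress = FALSE)
  invisible(path)
}

#' @rdname write_truth_bed
#' @export
read_truth_bed <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                  progress = FALSE) |>
    mutate(size = .data$end - .data$start)
}
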