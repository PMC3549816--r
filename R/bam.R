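#' Read stretched read-pair mappings from a BAM file
#'
#' Extracts paired-end mappings from a coordinate-sorted BAM file and applies
#' the standard filters: both mates mapped to the same chromosome in
#' forward--reverse orientation (left mate on the forward strand); mapping
#' quality at least `min_mapq` on both mates; gap-free, unclipped alignments
#' (the CIGAR must be a single match run); uniquely placed pairs (mapping
#' quality above zero and, where the aligner reports alternative-hit tags,
#' a unique best hit); outer distance at least `mean + stretch_sds * sd`
#' under the sample's fragment model; and non-degenerate inner boundaries.
#' Pairs failing a filter are counted, not errors.
#'
#' Uniqueness encoding is aligner-specific. By default a pair is rejected
#' when an `XA` tag (alternative hits) is present, when `X0` (number of best
#' hits) exceeds 1, or when `NH` (number of reported alignments) exceeds 1;
#' the tag set can be changed via `unique_tags`.
#'
#' @param path path to a BAM file.
#' @param sample_id sample identifier attached to the emitted mappings.
#' @param model a one-row fragment model for this sample
#'   ([fragment_model()]).
#' @param min_mapq minimum mapping quality on both mates (default 20).
#' @param stretch_sds stretched-length cutoff in standard deviations above
#'   the mean fragment length (default 3).
#' @param unique_tags optional-tag names consulted for uniqueness; any subset
#'   of `c("X0", "XA", "NH")`.
#' @param dedup collapse pairs with identical coordinates (default `FALSE`).
#' @return A mapping tibble (columns `id`, `sample_id`, `chrom`,
#'   `left_inner`, `right_inner`, `span_d`, `fp_start`, `fp_end`) with a
#'   `filter_counts` attribute.
#' @export
read_bam_mappings <- function(path, sample_id, model, min_mapq = 20,
                              stretch_sds = 3,
                              unique_tags = c("X0", "XA", "NH"),
                              dedup = FALSE) {
  if (!requireNamespace("Rsamtools", quietly = TRUE)) {
    abort("reading BAM files requires the Rsamtools package.")
  }
  if (!file.exists(path)) abort(paste0("BAM file not found: ", path))
  check_models(model)
  if (nrow(model) != 1) abort("`model` must be a one-row fragment model.")
  tags <- intersect(unique_tags, c("X0", "XA", "NH"))
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "strand", "pos", "mapq", "cigar"),
    tag = tags,
    flag = Rsamtools::scanBamFlag(isPaired = TRUE, isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE)
  )
  res <- tryCatch(Rsamtools::scanBam(path, param = param)[[1]],
                  error = function(e) {
                    abort(paste0("failed to read BAM '", path, "': ",
                                 conditionMessage(e)))
                  })
  rec <- tibble(
    qname = res$qname, flag = res$flag, chrom = as.character(res$rname),
    strand = as.character(res$strand), pos = res$pos, mapq = res$mapq,
    cigar = res$cigar
  )
  for (tg in tags) {
    vals <- res$tag[[tg]]
    rec[[tg]] <- if (is.null(vals)) rep(NA, nrow(rec)) else vals
  }
  counts <- c(pairs_total = 0, unpaired_or_unmapped = 0, different_chrom = 0,
              orientation = 0, low_mapq = 0, gapped_or_clipped = 0,
              not_unique = 0, degenerate = 0, not_stretched = 0,
              duplicate = 0, emitted = 0)

  n_per <- table(rec$qname)
  counts["pairs_total"] <- length(n_per)
  good_q <- names(n_per)[n_per == 2]
  counts["unpaired_or_unmapped"] <- length(n_per) - length(good_q)
  rec <- rec[rec$qname %in% good_q, ]
  if (nrow(rec) == 0) {
    return(empty_bam_result(sample_id, counts))
  }
  rec <- rec[order(rec$qname, rec$pos), ]
  i1 <- seq(1, nrow(rec), by = 2)
  i2 <- i1 + 1
  ref_w <- function(cig) {
    # only gap-free, unclipped alignments are accepted, so the reference
    # width is just the match-run length; anything else is marked invalid
    w <- suppressWarnings(as.numeric(sub("^([0-9]+)M$", "\\1", cig)))
    w[!grepl("^[0-9]+M$", cig)] <- NA
    w
  }
  p <- tibble(
    qname = rec$qname[i1],
    chrom1 = rec$chrom[i1], chrom2 = rec$chrom[i2],
    strand1 = rec$strand[i1], strand2 = rec$strand[i2],
    pos1 = rec$pos[i1], pos2 = rec$pos[i2],
    mapq1 = rec$mapq[i1], mapq2 = rec$mapq[i2],
    w1 = ref_w(rec$cigar[i1]), w2 = ref_w(rec$cigar[i2])
  )
  uniq_ok <- rep(TRUE, nrow(p))
  if ("X0" %in% tags) {
    x0 <- pmax(rec$X0[i1], rec$X0[i2], na.rm = TRUE)
    uniq_ok <- uniq_ok & (is.na(x0) | x0 <= 1)
  }
  if ("XA" %in% tags) {
    xa <- !is.na(rec$XA[i1]) | !is.na(rec$XA[i2])
    uniq_ok <- uniq_ok & !xa
  }
  if ("NH" %in% tags) {
    nh <- pmax(rec$NH[i1], rec$NH[i2], na.rm = TRUE)
    uniq_ok <- uniq_ok & (is.na(nh) | nh <= 1)
  }
  stage <- function(ok, name) {
    counts[name] <<- counts[name] + sum(alive & !ok)
    alive <<- alive & ok
  }
  alive <- rep(TRUE, nrow(p))
  stage(p$chrom1 == p$chrom2, "different_chrom")
  stage(p$strand1 == "+" & p$strand2 == "-", "orientation")
  stage(p$mapq1 >= min_mapq & p$mapq2 >= min_mapq & p$mapq1 > 0 & p$mapq2 > 0,
        "low_mapq")
  stage(!is.na(p$w1) & !is.na(p$w2), "gapped_or_clipped")
  stage(uniq_ok, "not_unique")
  p <- p[alive, ]
  # BAM pos is 1-based; convert to 0-based half-open
  m <- tibble(
    id = p$qname, sample_id = sample_id, chrom = p$chrom1,
    left_inner = (p$pos1 - 1) + p$w1,
    right_inner = p$pos2 - 1,
    span_d = (p$pos2 - 1 + p$w2) - (p$pos1 - 1),
    fp_start = p$pos1 - 1
  ) |> mutate(fp_end = .data$fp_start + .data$span_d)
  degen <- m$left_inner >= m$right_inner
  counts["degenerate"] <- sum(degen)
  m <- m[!degen, ]
  short <- m$span_d < model$mean + stretch_sds * model$sd
  counts["not_stretched"] <- sum(short)
  m <- m[!short, ]
  if (dedup) {
    before <- nrow(m)
    m <- m |> distinct(.data$chrom, .data$left_inner, .data$right_inner,
                       .data$span_d, .keep_all = TRUE)
    counts["duplicate"] <- before - nrow(m)
  }
  m <- m |> arrange(.data$chrom, .data$fp_start, .data$id)
  counts["emitted"] <- nrow(m)
  attr(m, "filter_counts") <- counts
  m
}

empty_bam_result <- function(sample_id, counts) {
  m <- tibble(id = character(0), sample_id = character(0), chrom = character(0),
              left_inner = numeric(0), right_inner = numeric(0),
              span_d = numeric(0), fp_start = numeric(0), fp_end = numeric(0))
  attr(m, "filter_counts") <- counts
  m
}
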