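default_palette <- c("red", "blue", "green3", "orange", "purple", "brown",
                     "deeppink", "turquoise3", "gold3", "gray40")

#' Read a sample configuration table
#'
#' The sample configuration is a tab-separated file with one row per input
#' file and columns `path`, `mean`, `sd` and optionally `color` (no header;
#' lines starting with `#` are ignored). `mean` and `sd` describe the
#' fragment-length distribution of the sample; `color` is used in region
#' plots. Sample ids are derived from the file name (basename without
#' extension) and must be unique. Missing colors are assigned from a fixed
#' palette in row order.
#'
#' @param path path to the configuration file.
#' @return A tibble with columns `sample_id`, `path`, `mean`, `sd`, `color`.
#' @export
read_sample_config <- function(path) {
  if (!file.exists(path)) abort(paste0("sample config not found: ", path))
  lines <- readr::read_lines(path)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  if (length(keep) == 0) abort("sample config contains no data rows.")
  rows <- purrr::map2_dfr(lines[keep], keep, function(line, rowno) {
    f <- strsplit(trimws(line), "\t|\\s+")[[1]]
    if (length(f) < 3 || length(f) > 4) {
      abort(paste0("sample config row ", rowno,
                   ": expected 3-4 fields (path, mean, sd, [color]), got ",
                   length(f), "."))
    }
    mean <- suppressWarnings(as.numeric(f[2]))
    sd <- suppressWarnings(as.numeric(f[3]))
    if (!is.finite(mean) || mean <= 0) {
      abort(paste0("sample config row ", rowno, ": invalid mean '", f[2], "'."))
    }
    if (!is.finite(sd) || sd <= 0) {
      abort(paste0("sample config row ", rowno, ": sd must be positive, got '",
                   f[3], "'."))
    }
    tibble(sample_id = sub("\\.[^.]*$", "", basename(f[1])), path = f[1],
           mean = mean, sd = sd,
           color = if (length(f) == 4) f[4] else NA_character_)
  })
  # ids must be unique even when paths repeat (e.g. re-used files with a
  # different fragment model): disambiguate colliding basenames in row order
  if (anyDuplicated(rows$sample_id)) {
    rows$sample_id <- make.unique(rows$sample_id, sep = "_")
  }
  fill <- is.na(rows$color)
  rows$color[fill] <- default_palette[((which(fill) - 1) %% length(default_palette)) + 1]
  rows
}

#' Read and write plain mapping tables
#'
#' The mapping table is a tab-separated, alignment-free representation of
#' stretched paired-end mappings, with a header line and columns
#' `sample_id`, `chrom`, `left_inner`, `right_inner`, `span_d`, and
#' optionally `truth_hap` and `truth_del` (simulator annotations).
#' Coordinates are 0-based half-open: `left_inner` is the position
#' immediately after the last base of the left read, `right_inner` the start
#' of the right read, and `span_d` the outer mapped distance of the pair.
#' Lines starting with `#` are ignored.
#'
#' @param path file path.
#' @param mappings a mapping tibble (for writing).
#' @return `read_mapping_table()` returns a mapping tibble with an `id`
#'   column added when absent; `write_mapping_table()` returns `path`
#'   invisibly.
#' @export
read_mapping_table <- function(path) {
  m <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                       progress = FALSE)
  m <- check_mappings(m)
  m |> mutate(across(c("left_inner", "right_inner", "span_d"), as.numeric))
}

#' @rdname read_mapping_table
#' @export
write_mapping_table <- function(mappings, path) {
  mappings <- check_mappings(mappings)
  out <- mappings |> select(-any_of(c("fp_start", "fp_end", "region_id")))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

# Genomic footprint of a pair: [leftmost mapped base, leftmost + span_d),
# half-open. BAM input records the true outer start; for table input the
# outer start is reconstructed assuming the two reads have equal length,
# outer_left = left_inner - (span_d - inner gap) / 2 (floored). The footprint
# is only used to partition mappings into independent regions; a footprint
# wider than the truth is harmless (it can only join regions).
derive_footprints <- function(mappings) {
  if (all(c("fp_start", "fp_end") %in% names(mappings))) return(mappings)
  gap <- mappings$right_inner - mappings$left_inner
  read_span <- pmax(mappings$span_d - gap, 0)
  fp_start <- floor(mappings$left_inner - read_span / 2)
  mappings |> mutate(fp_start = fp_start, fp_end = fp_start + .data$span_d)
}

#' Keep only stretched, usable mappings
#'
#' Applies the length filter to a mapping table: a pair is kept when its
#' outer distance `span_d` is at least `mean + stretch_sds * sd` under its
#' sample's fragment model (default three standard deviations above the
#' mean), and when its inner boundaries are non-degenerate
#' (`left_inner < right_inner`; degenerate rows are dropped with a warning).
#' Optionally collapses exact duplicate pairs.
#'
#' @param mappings a mapping tibble.
#' @param models per-sample fragment models ([fragment_model()]).
#' @param stretch_sds number of standard deviations above the mean fragment
#'   length required for a pair to count as stretched (default 3).
#' @param dedup collapse rows identical in (sample_id, chrom, left_inner,
#'   right_inner, span_d)? Default `FALSE`; duplicate removal is normally an
#'   upstream concern.
#' @return The filtered mapping tibble, with a `filter_counts` attribute
#'   giving the number of rows removed by each rule.
#' @export
filter_stretched <- function(mappings, models, stretch_sds = 3, dedup = FALSE) {
  mappings <- check_mappings(mappings)
  check_models(models)
  n0 <- nrow(mappings)
  m <- mappings |> left_join(models, by = "sample_id")
  if (any(is.na(m$mean))) {
    abort("some mappings reference samples without a fragment model.")
  }
  degenerate <- m$left_inner >= m$right_inner
  if (any(degenerate)) {
    warn(paste0("dropping ", sum(degenerate),
                " degenerate mapping(s) with left_inner >= right_inner."))
  }
  short <- !degenerate & m$span_d < m$mean + stretch_sds * m$sd
  keep <- m[!degenerate & !short, ] |> select(-"mean", -"sd")
  n_dup <- 0L
  if (dedup) {
    before <- nrow(keep)
    keep <- keep |>
      distinct(.data$sample_id, .data$chrom, .data$left_inner,
               .data$right_inner, .data$span_d, .keep_all = TRUE)
    n_dup <- before - nrow(keep)
  }
  attr(keep, "filter_counts") <- c(input = n0, degenerate = sum(degenerate),
                                   not_stretched = sum(short),
                                   duplicate = n_dup, emitted = nrow(keep))
  keep
}

#' Partition mappings into independent regions
#'
#' Regions are the connected components of the graph whose vertices are
#' mappings and whose edges join pairs with intersecting genomic footprints
#' on the same chromosome (footprint = outer span of the pair, half-open; two
#' footprints touching at a single point do not intersect). Mappings in
#' different regions cannot support a common deletion, so regions are
#' clustered independently.
#'
#' @param mappings a mapping tibble; footprints are derived with the
#'   equal-read-length convention if `fp_start`/`fp_end` are absent.
#' @return The mapping tibble sorted by (chrom, footprint start) with an
#'   integer `region_id` column; region ids are assigned in that order.
#' @export
partition_regions <- function(mappings) {
  mappings <- check_mappings(mappings)
  m <- derive_footprints(mappings) |>
    arrange(.data$chrom, .data$fp_start, .data$fp_end, .data$id)
  if (nrow(m) == 0) return(m |> mutate(region_id = integer(0)))
  # single left-to-right sweep per chromosome: a new region starts whenever
  # the next footprint begins at or after the running maximum end
  region <- integer(nrow(m))
  rid <- 0L
  cur_chrom <- NA_character_
  cur_end <- -Inf
  for (i in seq_len(nrow(m))) {
    if (!identical(m$chrom[i], cur_chrom) || m$fp_start[i] >= cur_end) {
      rid <- rid + 1L
      cur_chrom <- m$chrom[i]
      cur_end <- m$fp_end[i]
    } else {
      cur_end <- max(cur_end, m$fp_end[i])
    }
    region[i] <- rid
  }
  m |> mutate(region_id = region)
}
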