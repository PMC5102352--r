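#' Simulation-based null quantiles of the delta SNP index
#'
#' Simulates the null (no linked locus) distribution of the per-site delta
#' SNP index for a given cross design, bulk size and read depth, and returns
#' its two-sided quantiles at each depth of a grid. Each replicate draws the
#' two bulks' true allele frequencies by sampling `bulk_size` genotypes under
#' the null backcross segregation (heterozygote with probability `het_prob`,
#' recurrent homozygote otherwise), then draws `depth` reads binomially per
#' pool; the two-stage sampling keeps the bulk-size variance component that a
#' plain binomial on the expected frequency would lose.
#'
#' At low depth the delta is supported on multiples of `1/depth`, so the band
#' endpoints fall on attainable values; a window is flagged significant only
#' strictly outside the band (see [flag_windows()]), making the band
#' conservative (attained coverage at or above the nominal level).
#'
#' @param design a [cross_design()] (supplies `bulk_size`) or `NULL` if
#'   `bulk_size` is given directly.
#' @param depth_grid integer depths at which to tabulate quantiles.
#' @param n_replicates null replicates per depth.
#' @param confidence band level (0.95 default).
#' @param seed integer seed; deterministic given seed.
#' @param bulk_size plants per bulk (overrides `design`).
#' @param het_prob null heterozygote probability per plant (1/2 for a
#'   backcross segregating 1:1).
#' @return A `threshold_curve`: data.frame `depth, lower, upper` with
#'   attributes `confidence`, `n_replicates`, `bulk_size`, `het_prob`, `seed`.
#' @export
null_delta_quantiles <- function(design = NULL, depth_grid = 1:100,
                                 n_replicates = 10000, confidence = 0.95,
                                 seed = 1L,
                                 bulk_size = if (!is.null(design)) design$bulk_size else 20L,
                                 het_prob = 0.5) {
  stopifnot(bulk_size >= 1, n_replicates >= 2, confidence > 0, confidence < 1)
  depth_grid <- sort(unique(as.integer(depth_grid)))
  if (any(depth_grid <= 0)) stop("depths in the grid must be positive")
  set.seed(seed)
  alpha <- (1 - confidence) / 2
  qs <- vapply(depth_grid, function(d) {
    f1 <- stats::rbinom(n_replicates, bulk_size, het_prob) / (2 * bulk_size)
    f2 <- stats::rbinom(n_replicates, bulk_size, het_prob) / (2 * bulk_size)
    delta <- stats::rbinom(n_replicates, d, f1) / d -
             stats::rbinom(n_replicates, d, f2) / d
    stats::quantile(delta, c(alpha, 1 - alpha), names = FALSE)
  }, numeric(2))
  structure(data.frame(depth = depth_grid, lower = qs[1, ], upper = qs[2, ]),
            confidence = confidence, n_replicates = n_replicates,
            bulk_size = bulk_size, het_prob = het_prob, seed = seed,
            class = c("threshold_curve", "data.frame"))
}

#' Band at a depth (nearest grid point)
#' @param curve a `threshold_curve`.
#' @param depth numeric vector of (possibly non-integer) depths.
#' @return data.frame `lower, upper` aligned with `depth`.
#' @export
threshold_at_depth <- function(curve, depth) {
  if (nrow(curve) == 0L) stop("empty threshold curve")
  g <- curve$depth
  # nearest-neighbour lookup over the sorted grid
  i <- findInterval(depth, g + c(diff(g) / 2, Inf)) + 1L
  i[is.na(depth)] <- NA_integer_
  data.frame(lower = curve$lower[i], upper = curve$upper[i])
}

#' Flag significant windows against the null band
#'
#' A window is significant when its delta SNP index lies strictly outside the
#' `(lower, upper)` band at the grid depth nearest its mean per-pool depth.
#' Ineligible windows (too few SNPs) are never significant.
#'
#' @param profile window profile from [sliding_window_profile()].
#' @param curve a `threshold_curve`.
#' @return the profile with columns `threshold_lower`, `threshold_upper`,
#'   `significant` appended.
#' @export
flag_windows <- function(profile, curve) {
  band <- threshold_at_depth(curve, profile$mean_depth)
  profile$threshold_lower <- band$lower
  profile$threshold_upper <- band$upper
  profile$significant <- profile$eligible & !is.na(profile$delta) &
    (profile$delta < band$lower | profile$delta > band$upper)
  profile$significant[is.na(profile$significant)] <- FALSE
  profile
}

#' Candidate intervals from flagged windows
#'
#' Maximal runs of significant windows per chromosome; runs whose spans are
#' separated by at most `merge_gap_bp` are merged. An interval's span is the
#' union of its member windows.
#'
#' @param flagged profile from [flag_windows()].
#' @param merge_gap_bp merge runs separated by at most this many bp
#'   (default 0: only overlapping/abutting windows coalesce).
#' @return data.frame `chrom, start, end, peak_delta, n_windows`, sorted by
#'   chromosome and position; zero rows when nothing is significant.
#' @export
extract_candidate_intervals <- function(flagged, merge_gap_bp = 0) {
  sig <- flagged[flagged$significant, , drop = FALSE]
  if (nrow(sig) == 0L)
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      peak_delta = numeric(), n_windows = integer(),
                      stringsAsFactors = FALSE))
  out <- lapply(unique(sig$chrom), function(nm) {
    d <- sig[sig$chrom == nm, , drop = FALSE]
    d <- d[order(d$start), , drop = FALSE]
    run_end <- cummax(d$end)
    new_run <- c(TRUE, d$start[-1] > run_end[-nrow(d)] + 1 + merge_gap_bp)
    run <- cumsum(new_run)
    do.call(rbind, lapply(split(d, run), function(r)
      data.frame(chrom = nm, start = min(r$start), end = max(r$end),
                 peak_delta = r$delta[which.max(abs(r$delta))],
                 n_windows = nrow(r), stringsAsFactors = FALSE)))
  })
  out <- do.call(rbind, out)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write / read a threshold curve as TSV
#' @param curve a `threshold_curve`.
#' @param path file path.
#' @return `path` invisibly (writer); a `threshold_curve` (reader, with the
#'   provenance attributes carried in `#`-prefixed header lines).
#' @export
write_threshold_curve <- function(curve, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (a in c("confidence", "n_replicates", "bulk_size", "het_prob", "seed"))
    writeLines(sprintf("#%s\t%s", a, format(attr(curve, a))), con)
  utils::write.table(as.data.frame(curve), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_threshold_curve
#' @export
read_threshold_curve <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(grep("^#", lines, value = TRUE), "\t")
  tbl <- utils::read.delim(text = lines[!startsWith(lines, "#")])
  out <- structure(tbl, class = c("threshold_curve", "data.frame"))
  for (h in hdr) attr(out, sub("^#", "", h[1])) <- as.numeric(h[2])
  out
}

#' Write candidate intervals as BED
#'
#' Internal intervals are 1-based inclusive; BED is 0-based half-open, so
#' `start - 1` is written and the end is unchanged.
#'
#' @param intervals data.frame `chrom, start, end` (+ optional `peak_delta`).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_intervals_bed <- function(intervals, path) {
  if (nrow(intervals) == 0L) { writeLines(character(), path); return(invisible(path)) }
  name <- if ("peak_delta" %in% names(intervals))
    sprintf("delta=%.4f", intervals$peak_delta) else "."
  bed <- data.frame(intervals$chrom,
                    format(intervals$start - 1, scientific = FALSE, trim = TRUE),
                    format(intervals$end, scientific = FALSE, trim = TRUE), name)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED file of intervals into 1-based inclusive coordinates
#' @param path BED file.
#' @return data.frame `chrom, start, end` (1-based inclusive) plus `name`
#'   when present.
#' @export
read_intervals_bed <- function(path) {
  gr <- rtracklayer::import.bed(path)
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
             name = if (!is.null(gr$name)) gr$name else NA_character_,
             stringsAsFactors = FALSE)
}
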