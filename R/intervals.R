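#' Genomic interval (1-based inclusive)
#'
#' @param chrom chromosome name.
#' @param start,end bp coordinates, `start <= end`.
#' @param label optional label.
#' @return data.frame of class `genomic_interval` with one row (or zero rows
#'   for the empty interval).
#' @export
genomic_interval <- function(chrom, start, end, label = NA_character_) {
  if (any(start > end)) stop("interval start must not exceed end")
  structure(data.frame(chrom = chrom, start = as.numeric(start),
                       end = as.numeric(end), label = label,
                       stringsAsFactors = FALSE),
            class = c("genomic_interval", "data.frame"))
}

.empty_interval <- function() {
  structure(data.frame(chrom = character(), start = numeric(), end = numeric(),
                       label = character(), stringsAsFactors = FALSE),
            class = c("genomic_interval", "data.frame"))
}

#' Intersect two genomic intervals
#'
#' `[max(starts), min(ends)]`, or the empty interval when they do not
#' overlap. Intervals on different chromosomes never overlap (a warning is
#' issued, as this usually signals mismatched inputs).
#'
#' @param a,b one-row [genomic_interval()]s (or data.frames with `chrom`,
#'   `start`, `end`).
#' @param label label for the result.
#' @return a [genomic_interval()]; zero rows when empty.
#' @export
interval_intersect <- function(a, b, label = NA_character_) {
  stopifnot(nrow(a) == 1L, nrow(b) == 1L)
  if (a$chrom != b$chrom) {
    warning("intervals on different chromosomes (", a$chrom, " vs ", b$chrom,
            "): empty intersection")
    return(.empty_interval())
  }
  s <- max(a$start, b$start)
  e <- min(a$end, b$end)
  if (s > e) return(.empty_interval())
  genomic_interval(a$chrom, s, e, label)
}

#' Interval length in kb
#'
#' Reported as `end - start` (not `+ 1`), in kb rounded to the nearest
#' integer — the convention under which the printed bounds of the study-style
#' final region give exactly its printed size. This differs from the
#' inclusive base count by one base; it is the span between the bound
#' coordinates.
#'
#' @param interval a one-row interval.
#' @return integer kb.
#' @export
length_kb <- function(interval) {
  stopifnot(nrow(interval) == 1L)
  round((interval$end - interval$start) / 1000)
}

#' Total span of a set of intervals, in Mb
#'
#' Overlapping intervals are merged first, so any base is counted once; each
#' merged piece contributes `end - start`. Rounded to one decimal.
#'
#' @param intervals data.frame with `chrom`, `start`, `end` (any number of
#'   rows).
#' @return numeric Mb, one decimal.
#' @export
total_span_mb <- function(intervals) {
  if (nrow(intervals) == 0L) return(0.0)
  u <- merge_intervals(intervals)
  round(sum(u$end - u$start) / 1e6, 1)
}

#' Merge overlapping or abutting intervals into their union
#' @param intervals data.frame with `chrom`, `start`, `end`.
#' @return data.frame of disjoint intervals sorted by position.
#' @export
merge_intervals <- function(intervals) {
  out <- lapply(split(intervals, intervals$chrom), function(d) {
    d <- d[order(d$start), , drop = FALSE]
    run_end <- cummax(d$end)
    new_run <- c(TRUE, d$start[-1] > run_end[-nrow(d)])
    run <- cumsum(new_run)
    data.frame(chrom = d$chrom[1],
               start = tapply(d$start, run, min),
               end = tapply(d$end, run, max), row.names = NULL)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' Count genes overlapping an interval
#'
#' A gene counts when its span overlaps the interval by at least one base
#' (inclusive coordinates on both sides: a gene abutting the interval end is
#' counted).
#'
#' @param interval a one-row interval.
#' @param gene_models data.frame with `gene_id`, `chrom`, `start`, `end`
#'   (see [read_gene_models()]).
#' @return integer count.
#' @export
count_genes <- function(interval, gene_models) {
  stopifnot(nrow(interval) == 1L)
  sum(gene_models$chrom == interval$chrom &
        gene_models$start <= interval$end &
        gene_models$end >= interval$start)
}

#' Read gene models from GFF3 or BED
#'
#' GFF3 `gene` features (or all features, if none is typed `gene`) and BED
#' records are imported with \pkg{rtracklayer} and returned in 1-based
#' inclusive coordinates.
#'
#' @param path annotation file.
#' @param format `"gff3"` or `"bed"` (guessed from the extension by default).
#' @return data.frame `gene_id, chrom, start, end`.
#' @export
read_gene_models <- function(path, format = c("auto", "gff3", "bed")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "gff3"
  gr <- if (format == "bed") rtracklayer::import.bed(path)
        else rtracklayer::import.gff3(path)
  if (format == "gff3" && "type" %in% names(S4Vectors::mcols(gr)) &&
      any(gr$type == "gene"))
    gr <- gr[gr$type == "gene"]
  id <- if (!is.null(gr$ID)) gr$ID else if (!is.null(gr$name)) gr$name
        else sprintf("gene_%05d", seq_along(gr))
  data.frame(gene_id = as.character(id),
             chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}
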