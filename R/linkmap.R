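#' Recombinants between a marker and the phenotyped locus
#'
#' With the donor allele dominant (carriers show the donor phenotype, brown),
#' a plant is recombinant when its marker genotype disagrees with the
#' genotype its phenotype implies at the locus: heterozygous (`"H"`) yet
#' yellow, or recurrent homozygote (`"A"`) yet brown. Plants with a missing
#' genotype call are excluded from `n`.
#'
#' @param screen a `marker_screen`.
#' @param marker_id marker column to count.
#' @param donor_dominant set `FALSE` for a recessive donor allele (the
#'   phenotype-to-genotype coding flips).
#' @return list `k` (recombinants) and `n` (informative plants).
#' @export
count_recombinants <- function(screen, marker_id, donor_dominant = TRUE) {
  stopifnot(inherits(screen, "marker_screen"))
  if (!marker_id %in% names(screen$calls)) stop("unknown marker: ", marker_id)
  g <- screen$calls[[marker_id]]
  ph <- screen$calls$phenotype
  ok <- !is.na(g) & g != ""
  g <- g[ok]; ph <- ph[ok]
  carrier_pheno <- if (donor_dominant) "brown" else "yellow"
  k <- sum((g == "H" & ph != carrier_pheno) | (g == "A" & ph == carrier_pheno))
  list(k = k, n = length(g))
}

#' Kosambi map distance
#'
#' `d = 25 * ln((1 + 2r) / (1 - 2r))` centimorgans; approaches `100 r` cM for
#' small `r` and diverges as `r` approaches 0.5 (unlinked).
#'
#' @param r recombination fraction(s), in `[0, 0.5)`.
#' @return distance(s) in cM.
#' @examples
#' kosambi_distance(10 / 1739)  # 0.575 cM
#' @export
kosambi_distance <- function(r) {
  if (any(r < 0)) stop("recombination fraction must be non-negative")
  if (any(r >= 0.5)) stop("recombination fraction must be below 0.5 (linked)")
  25 * log((1 + 2 * r) / (1 - 2 * r))
}

#' Inverse Kosambi function
#'
#' @param d map distance(s) in cM, `>= 0`.
#' @return recombination fraction(s) `r = tanh(d / 50) / 2`.
#' @export
kosambi_inverse <- function(d) {
  if (any(d < 0)) stop("map distance must be non-negative")
  tanh(d / 50) / 2
}

#' Chi-square test of 1:1 segregation
#'
#' One-degree-of-freedom goodness-of-fit test of equal class counts,
#' `X^2 = (a - b)^2 / (a + b)` (no continuity correction).
#'
#' @param n_yellow,n_brown observed class counts (both totals > 0 together).
#' @return list `statistic`, `p_value`, `n_yellow`, `n_brown`, `ratio`.
#' @export
segregation_test <- function(n_yellow, n_brown) {
  if (n_yellow + n_brown <= 0) stop("no plants to test")
  ct <- stats::chisq.test(c(n_yellow, n_brown), p = c(0.5, 0.5), correct = FALSE)
  list(statistic = unname(ct$statistic), p_value = unname(ct$p.value),
       n_yellow = n_yellow, n_brown = n_brown, ratio = n_yellow / n_brown)
}

#' Genetic map from a marker screen
#'
#' Counts recombinants per marker, converts `r = k/n` to Kosambi cM, and
#' orders markers by physical position (cosegregating markers are ordered
#' physically since their genetic distances tie at 0).
#'
#' @param screen a `marker_screen`.
#' @param donor_dominant see [count_recombinants()].
#' @return data.frame `marker, chrom, start, end, k, n, r, cM,
#'   cosegregating`, class `linkage_result`.
#' @export
linkage_map <- function(screen, donor_dominant = TRUE) {
  stopifnot(inherits(screen, "marker_screen"))
  m <- screen$markers
  res <- lapply(m$marker, function(id) count_recombinants(screen, id, donor_dominant))
  k <- vapply(res, `[[`, numeric(1), "k")
  n <- vapply(res, `[[`, numeric(1), "n")
  r <- ifelse(n > 0, k / n, NA_real_)
  out <- data.frame(marker = m$marker, chrom = m$chrom,
                    start = pmin(m$start, m$end), end = pmax(m$start, m$end),
                    k = k, n = n, r = r, cM = kosambi_distance(r),
                    cosegregating = k == 0, stringsAsFactors = FALSE)
  out <- out[order(out$chrom, (out$start + out$end) / 2), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("linkage_result", "data.frame")
  out
}

#' Physical interval between the flanking markers
#'
#' Finds the block of cosegregating markers (zero recombinants) and the
#' nearest marker with a nonzero distance on each side, and returns the
#' physical interval they delimit. With `boundary = "outer"` (default) the
#' interval runs from the left flanking marker's lowest span coordinate to
#' the right flanking marker's highest — the convention that reproduces the
#' study-style bound where the flanking marker spans are included.
#' `"inner"` instead uses each flanking span's edge nearest the cosegregating
#' block. A side with no flanking marker is left open (`NA`) and flagged.
#'
#' @param results a `linkage_result` (markers physically ordered).
#' @param boundary `"outer"` or `"inner"`.
#' @return a [genomic_interval()] with attributes `open_left`, `open_right`,
#'   `left_marker`, `right_marker`.
#' @export
flanking_interval <- function(results, boundary = c("outer", "inner")) {
  boundary <- match.arg(boundary)
  stopifnot(inherits(results, "linkage_result"))
  co <- which(results$cosegregating)
  if (length(co) == 0L) stop("no cosegregating marker: locus position undefined")
  if (length(unique(results$chrom)) > 1L)
    stop("markers span more than one chromosome")
  left <- co[1] - 1L
  right <- co[length(co)] + 1L
  open_left <- left < 1L
  open_right <- right > nrow(results)
  lo <- if (open_left) NA_real_ else
    if (boundary == "outer") results$start[left] else results$end[left]
  hi <- if (open_right) NA_real_ else
    if (boundary == "outer") results$end[right] else results$start[right]
  if (open_left || open_right)
    warning("no flanking marker on the ", if (open_left) "left" else "right",
            " side: interval is open-ended")
  iv <- genomic_interval(results$chrom[1],
                         if (is.na(lo)) results$start[co[1]] else lo,
                         if (is.na(hi)) results$end[co[length(co)]] else hi,
                         label = "fine_mapping")
  attr(iv, "open_left") <- open_left
  attr(iv, "open_right") <- open_right
  attr(iv, "left_marker") <- if (open_left) NA_character_ else results$marker[left]
  attr(iv, "right_marker") <- if (open_right) NA_character_ else results$marker[right]
  iv
}

#' Write a genetic map as TSV (cM to three decimals, as customarily reported)
#' @param results a `linkage_result`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_linkage_map <- function(results, path) {
  out <- as.data.frame(results)
  out$cM <- sprintf("%.3f", out$cM)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
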