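#' Per-site SNP index
#'
#' The SNP index of a pool at a polarized site is the fraction of its reads
#' carrying the measured (non-reference-parent) allele. With no reads the
#' index is missing (`NA`).
#'
#' @param measured_allele_count reads supporting the measured allele.
#' @param total_depth total reads at the site.
#' @return numeric in `[0, 1]`, `NA` where `total_depth` is 0. Vectorized.
#' @examples
#' compute_snp_index(5, 20)   # 0.25
#' compute_snp_index(0, 0)    # NA
#' @export
compute_snp_index <- function(measured_allele_count, total_depth) {
  if (any(measured_allele_count < 0) || any(total_depth < 0))
    stop("counts must be non-negative")
  if (any(measured_allele_count > total_depth))
    stop("measured allele count exceeds total depth")
  ifelse(total_depth == 0, NA_real_, measured_allele_count / total_depth)
}

#' SNP-index table for two pools
#'
#' @param polarized polarized site table from [select_parent_homozygous()].
#' @param pools character(2): the two pool sample names, in the order
#'   (high-phenotype pool, reference-phenotype pool); the downstream delta is
#'   `pool1 - pool2`.
#' @return data.frame `chrom, pos, depth1, index1, depth2, index2` with
#'   attribute `pools`.
#' @export
snp_index_table <- function(polarized, pools = attr(polarized, "pools")) {
  stopifnot(length(pools) == 2L)
  for (p in pools)
    if (!paste0(p, ".depth") %in% names(polarized)) stop("pool not in table: ", p)
  out <- data.frame(chrom = polarized$chrom, pos = polarized$pos, stringsAsFactors = FALSE)
  for (i in 1:2) {
    d <- polarized[[paste0(pools[i], ".depth")]]
    m <- polarized[[paste0(pools[i], ".measured")]]
    out[[paste0("depth", i)]] <- d
    out[[paste0("index", i)]] <- compute_snp_index(m, d)
  }
  attr(out, "pools") <- pools
  out
}

#' Low-confidence site filters
#'
#' Removes a site when
#' (a) in *both* pools its index is below `low_index_threshold` *and* its
#' depth is below `low_depth_threshold` (a pattern expected from scattered
#' mis-mapped reads rather than a real segregating site), or
#' (b) its index is missing (zero depth) in *either* pool.
#'
#' @param idx SNP-index table from [snp_index_table()].
#' @param low_index_threshold default 0.3.
#' @param low_depth_threshold default 7 reads.
#' @return the retained rows, with attribute `removal_tally` — a named list
#'   counting removals per rule (`missing_either`,
#'   `low_index_low_depth_both`) which sums to rows removed.
#' @export
apply_filters <- function(idx, low_index_threshold = 0.3, low_depth_threshold = 7) {
  rule_missing <- is.na(idx$index1) | is.na(idx$index2)
  rule_low <- !rule_missing &
    (idx$index1 < low_index_threshold & idx$depth1 < low_depth_threshold) &
    (idx$index2 < low_index_threshold & idx$depth2 < low_depth_threshold)
  keep <- !(rule_missing | rule_low)
  out <- idx[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "pools") <- attr(idx, "pools")
  attr(out, "removal_tally") <- list(missing_either = sum(rule_missing),
                                     low_index_low_depth_both = sum(rule_low))
  out
}

# window means by cumulative sums: O(n + windows) per column
.window_means <- function(pos, val, starts, ends) {
  cs <- c(0, cumsum(val))
  lo <- findInterval(starts - 1, pos)
  hi <- findInterval(ends, pos)
  n <- hi - lo
  list(n = n, mean = ifelse(n > 0, (cs[hi + 1] - cs[lo + 1]) / n, NA_real_),
       sum = cs[hi + 1] - cs[lo + 1])
}

#' Sliding-window SNP-index profile
#'
#' Windows are anchored at position 1 and advanced by `step`; spans are
#' 1-based inclusive, and trailing windows truncated at the chromosome end
#' are emitted flagged `partial`. Each window reports the mean per-pool index
#' over its SNPs (unweighted by default; depth-weighted behind `weighted`),
#' the delta SNP index (pool1 minus pool2), the mean per-pool depth of its
#' SNPs, and whether it is `eligible` (at least `min_snps_per_window` SNPs)
#' for interval calling.
#'
#' @param idx filtered SNP-index table (position-sorted).
#' @param window window width in bp (study scale: 1 Mb).
#' @param step step in bp (study scale: 1 kb).
#' @param min_snps_per_window windows with fewer SNPs are flagged ineligible.
#' @param chrom_lengths optional named vector of chromosome lengths; defaults
#'   to the last SNP position per chromosome.
#' @param weighted if `TRUE`, window means weight each SNP by its depth.
#' @return data.frame `chrom, start, end, n_snps, mean_depth, index_pool1,
#'   index_pool2, delta, partial, eligible` with attribute `pools`.
#' @export
sliding_window_profile <- function(idx, window = 1e6, step = 1e3,
                                   min_snps_per_window = 10,
                                   chrom_lengths = NULL, weighted = FALSE) {
  if (window <= 0 || step <= 0 || window < step)
    stop("window must be positive and at least as large as step")
  out <- lapply(unique(idx$chrom), function(nm) {
    d <- idx[idx$chrom == nm, , drop = FALSE]
    if (is.unsorted(d$pos)) stop("SNP-index table must be position-sorted")
    L <- if (!is.null(chrom_lengths)) chrom_lengths[[nm]] else max(d$pos)
    starts <- seq(1, L, by = step)
    ends <- pmin(starts + window - 1, L)
    dep <- (d$depth1 + d$depth2) / 2
    if (weighted) {
      s1 <- .window_means(d$pos, d$index1 * d$depth1, starts, ends)
      w1 <- .window_means(d$pos, d$depth1, starts, ends)
      s2 <- .window_means(d$pos, d$index2 * d$depth2, starts, ends)
      w2 <- .window_means(d$pos, d$depth2, starts, ends)
      m1 <- ifelse(w1$sum > 0, s1$sum / w1$sum, NA_real_)
      m2 <- ifelse(w2$sum > 0, s2$sum / w2$sum, NA_real_)
      n <- s1$n
    } else {
      r1 <- .window_means(d$pos, d$index1, starts, ends)
      r2 <- .window_means(d$pos, d$index2, starts, ends)
      m1 <- r1$mean; m2 <- r2$mean; n <- r1$n
    }
    md <- .window_means(d$pos, dep, starts, ends)$mean
    data.frame(chrom = nm, start = starts, end = ends, n_snps = n,
               mean_depth = md, index_pool1 = m1, index_pool2 = m2,
               delta = m1 - m2,
               partial = ends - starts + 1 < window,
               eligible = n >= min_snps_per_window,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  attr(out, "pools") <- attr(idx, "pools")
  out
}

#' Write a window profile as TSV
#' @param profile window profile from [sliding_window_profile()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_window_profile <- function(profile, path) {
  utils::write.table(profile, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Manhattan-style profile plot
#'
#' Three panels per chromosome: each pool's windowed SNP index and the delta
#' SNP index, with the confidence band overlaid on the delta panel when a
#' threshold curve is supplied.
#'
#' @param profile window profile.
#' @param curve optional [null_delta_quantiles()] threshold curve.
#' @return a ggplot object.
#' @export
plot_bsa_profile <- function(profile, curve = NULL) {
  p <- profile[profile$eligible, , drop = FALSE]
  mid <- (p$start + p$end) / 2
  long <- rbind(
    data.frame(chrom = p$chrom, pos = mid, value = p$index_pool1, panel = "pool 1 SNP index"),
    data.frame(chrom = p$chrom, pos = mid, value = p$index_pool2, panel = "pool 2 SNP index"),
    data.frame(chrom = p$chrom, pos = mid, value = p$delta, panel = "delta SNP index"))
  long$panel <- factor(long$panel, levels = unique(long$panel))
  g <- ggplot2::ggplot(long, ggplot2::aes(x = .data$pos / 1e6, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_grid(panel ~ chrom, scales = "free") +
    ggplot2::labs(x = "position (Mb)", y = NULL) +
    ggplot2::theme_bw()
  if (!is.null(curve)) {
    band <- threshold_at_depth(curve, p$mean_depth)
    bd <- data.frame(chrom = p$chrom, pos = mid,
                     lower = band$lower, upper = band$upper,
                     panel = factor("delta SNP index", levels = levels(long$panel)))
    g <- g +
      ggplot2::geom_line(data = bd, ggplot2::aes(y = .data$lower),
                         colour = "blue", linewidth = 0.3) +
      ggplot2::geom_line(data = bd, ggplot2::aes(y = .data$upper),
                         colour = "blue", linewidth = 0.3)
  }
  g
}
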