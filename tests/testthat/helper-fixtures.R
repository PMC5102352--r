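# Shared fixtures, all built in code.

# Small two-chromosome genome with SNPs at fixed positions.
toy_genome <- function(n_snps = 200, lengths = c(A09 = 1e6, A02 = 8e5),
                       morgans = c(A09 = 0.5, A02 = 0.4), seed = 42) {
  simulate_genome(names(lengths), unname(lengths), n_snps, unname(morgans), seed)
}

# Genome with SNPs at exactly the positions asked for.
genome_at <- function(positions, length = 1e6, morgans = 0.5, name = "A09") {
  genome_spec(data.frame(name = name, length = length),
              stats::setNames(list(sort(positions)), name),
              stats::setNames(morgans, name))
}

# Allele-depth table from a compact spec: one row per site,
# counts = list of c(ref, alt) per sample.
toy_ad <- function(pos, counts, samples, chrom = "A09") {
  out <- data.frame(chrom = chrom, pos = pos, ref = "A", alt = "G",
                    stringsAsFactors = FALSE)
  for (i in seq_along(samples)) {
    m <- do.call(rbind, lapply(counts, `[[`, i))
    out[[paste0(samples[i], ".ref")]] <- m[, 1]
    out[[paste0(samples[i], ".alt")]] <- m[, 2]
  }
  attr(out, "samples") <- samples
  out
}

# SNP-index table built directly (for filter / window tests).
toy_idx <- function(pos, index1, index2, depth1 = 20, depth2 = 20, chrom = "A09") {
  out <- data.frame(chrom = chrom, pos = pos,
                    depth1 = rep_len(depth1, length(pos)),
                    index1 = index1,
                    depth2 = rep_len(depth2, length(pos)),
                    index2 = index2, stringsAsFactors = FALSE)
  attr(out, "pools") <- c("pool1", "pool2")
  out
}

# Marker screen shaped like the published SSR panel: 8 markers on A09 at the
# printed physical spans, 1,739 plants, 10 recombinants at the left flank
# (BrA10), 2 at the right flank (BrID10685), full cosegregation between.
published_marker_panel <- function() {
  data.frame(
    marker = c("BrA10", "BrA11", "BrA12", "BrA13", "BrA14", "BrA15", "BrID10685"),
    chrom = "A09",
    start = c(18255838, 18407330, 18570940, 18792152, 18962948, 19115029, 19342739),
    end   = c(18255987, 18407563, 18571067, 18792444, 18963069, 19115151, 19342792),
    k     = c(10, 0, 0, 0, 0, 0, 2),
    stringsAsFactors = FALSE)
}

published_screen <- function(n = 1739) {
  panel <- published_marker_panel()
  n_brown <- n %/% 2          # 869 brown, 870 yellow
  phenotype <- rep(c("yellow", "brown"), c(n - n_brown, n_brown))
  calls <- data.frame(plant_id = sprintf("plant_%04d", seq_len(n)),
                      phenotype = phenotype, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(panel))) {
    g <- ifelse(phenotype == "brown", "H", "A")      # cosegregation baseline
    if (panel$k[i] > 0) g[seq_len(panel$k[i])] <- "H"  # yellow plants -> recombinant
    calls[[panel$marker[i]]] <- g
  }
  structure(list(calls = calls, markers = panel[c("marker", "chrom", "start", "end")]),
            class = "marker_screen")
}

# Naive O(n * windows) window-mean oracle.
naive_window_means <- function(idx, window, step, L = max(idx$pos)) {
  starts <- seq(1, L, by = step)
  do.call(rbind, lapply(starts, function(s) {
    e <- min(s + window - 1, L)
    hit <- idx$pos >= s & idx$pos <= e
    data.frame(start = s, end = e, n_snps = sum(hit),
               m1 = if (any(hit)) mean(idx$index1[hit]) else NA_real_,
               m2 = if (any(hit)) mean(idx$index2[hit]) else NA_real_)
  }))
}
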