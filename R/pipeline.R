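#' Run configuration
#'
#' Assembles and validates every knob of the two pipelines. One master `seed`
#' derives per-stage seeds by fixed offsets (cross +1, bulks +2, pool
#' sequencing +3..+6, null thresholds +7), so any stage can be re-run in
#' isolation reproducibly.
#'
#' @param seed master integer seed.
#' @param genome a [genome_spec()], or `NULL` to build one from
#'   `genome_params` (arguments to [simulate_genome()]).
#' @param design a [cross_design()].
#' @param depth_model a [pool_depth_model()].
#' @param allele_depths optional path to an existing allele-depth table
#'   (skips simulation); `ad_format` its format.
#' @param parents character(2) parent sample names in `allele_depths`;
#'   `reference_parent` one of them.
#' @param pools character(2) pool sample names in `allele_depths`, ordered
#'   (high-phenotype pool, reference-phenotype pool) so that
#'   `delta = pool1 - pool2`; by default the non-parent samples in file order.
#' @param min_parent_depth parent homozygosity depth floor.
#' @param low_index_threshold,low_depth_threshold site filters
#'   (see [apply_filters()]).
#' @param window,step,min_snps_per_window scan geometry
#'   (see [sliding_window_profile()]).
#' @param confidence,n_replicates,depth_grid null-band settings
#'   (see [null_delta_quantiles()]).
#' @param merge_gap_bp interval merging (see [extract_candidate_intervals()]).
#' @param genome_params named list passed to [simulate_genome()] when
#'   `genome` is `NULL`.
#' @return validated config list of class `run_config`.
#' @export
run_config <- function(seed = 1L, genome = NULL, design = cross_design(),
                       depth_model = pool_depth_model(),
                       allele_depths = NULL, ad_format = "tsv",
                       parents = c("recurrent_yellow", "donor_brown"),
                       reference_parent = "donor_brown",
                       pools = NULL,
                       min_parent_depth = 4,
                       low_index_threshold = 0.3, low_depth_threshold = 7,
                       window = 1e6, step = 1e3, min_snps_per_window = 10,
                       confidence = 0.95, n_replicates = 10000,
                       depth_grid = 1:100, merge_gap_bp = 0,
                       genome_params = list()) {
  if (window <= 0 || step <= 0 || window < step)
    stop("invalid scan geometry: window must be positive and >= step")
  if (confidence <= 0 || confidence >= 1) stop("confidence must be in (0, 1)")
  if (!is.null(allele_depths) && !file.exists(allele_depths))
    stop("allele-depth file not found: ", allele_depths)
  if (is.null(genome) && is.null(allele_depths))
    genome <- do.call(simulate_genome, c(genome_params, list(seed = seed)))
  structure(list(seed = as.integer(seed), genome = genome, design = design,
                 depth_model = depth_model, allele_depths = allele_depths,
                 ad_format = ad_format, parents = parents,
                 reference_parent = reference_parent, pools = pools,
                 min_parent_depth = min_parent_depth,
                 low_index_threshold = low_index_threshold,
                 low_depth_threshold = low_depth_threshold,
                 window = window, step = step,
                 min_snps_per_window = min_snps_per_window,
                 confidence = confidence, n_replicates = n_replicates,
                 depth_grid = depth_grid, merge_gap_bp = merge_gap_bp),
            class = "run_config")
}

.config_as_list <- function(config) {
  list(seed = config$seed,
       design = unclass(config$design), depth_model = unclass(config$depth_model),
       filters = list(low_index_threshold = config$low_index_threshold,
                      low_depth_threshold = config$low_depth_threshold,
                      min_parent_depth = config$min_parent_depth),
       scan = list(window = config$window, step = config$step,
                   min_snps_per_window = config$min_snps_per_window),
       band = list(confidence = config$confidence,
                   n_replicates = config$n_replicates,
                   depth_grid = range(config$depth_grid)),
       merge_gap_bp = config$merge_gap_bp)
}

#' Bulked-segregant scan, end to end
#'
#' simulate (or read) pooled allele depths -> select parent-homozygous sites
#' and polarize -> per-pool SNP indices -> site filters -> sliding-window
#' delta profile -> simulation-based null band -> candidate intervals.
#' Pool 1 is the brown (donor-phenotype) bulk, pool 2 the yellow bulk, so
#' `delta = index(brown) - index(yellow)`.
#'
#' All artifacts are written under `outdir` when given: `windows.tsv`,
#' `thresholds.tsv`, `candidates.bed`, `summary.json`, `config.yaml` — the
#' summary is deterministic given (config, seed).
#'
#' @param config a [run_config()].
#' @param outdir optional output directory (created if missing).
#' @return list with `polarized`, `snp_index`, `profile` (flagged),
#'   `curve`, `candidates`, `tally`, `summary`, and (when simulated)
#'   `population`, `bulks`.
#' @export
run_bsa <- function(config, outdir = NULL) {
  stopifnot(inherits(config, "run_config"))
  seed <- config$seed
  population <- bulks <- NULL

  if (is.null(config$allele_depths)) {
    population <- simulate_cross(config$genome, config$design, seed = seed + 1L)
    bulks <- make_bulks(population, seed = seed + 2L)
    ad <- merge_allele_depths(list(
      simulate_pool_depths(lapply(config$genome$snp_positions, function(p) 0),
                           config$genome, config$depth_model, seed + 3L,
                           config$design$recurrent_parent),
      simulate_pool_depths(lapply(config$genome$snp_positions, function(p) 1),
                           config$genome, config$depth_model, seed + 4L,
                           config$design$donor_parent),
      simulate_pool_depths(bulks$yellow, config$genome, config$depth_model,
                           seed + 5L, "yellow_bulk"),
      simulate_pool_depths(bulks$brown, config$genome, config$depth_model,
                           seed + 6L, "brown_bulk")))
    parents <- c(config$design$recurrent_parent, config$design$donor_parent)
    reference_parent <- config$design$donor_parent
    pools <- c("brown_bulk", "yellow_bulk")
  } else {
    ad <- read_allele_depths(config$allele_depths, config$ad_format)
    parents <- config$parents
    reference_parent <- config$reference_parent
    pools <- if (!is.null(config$pools)) config$pools
             else setdiff(attr(ad, "samples"), parents)
    if (length(pools) != 2L)
      stop("expected exactly two offspring pools, found: ",
           paste(pools, collapse = ", "))
  }

  polarized <- select_parent_homozygous(ad, parents[1], parents[2],
                                        reference_parent,
                                        config$min_parent_depth)
  idx <- snp_index_table(polarized, pools)
  filtered <- apply_filters(idx, config$low_index_threshold,
                            config$low_depth_threshold)
  tally <- attr(filtered, "removal_tally")
  chrom_lengths <- if (!is.null(config$genome))
    stats::setNames(config$genome$chromosomes$length,
                    config$genome$chromosomes$name) else NULL
  profile <- sliding_window_profile(filtered, config$window, config$step,
                                    config$min_snps_per_window, chrom_lengths)
  curve <- null_delta_quantiles(config$design, config$depth_grid,
                                config$n_replicates, config$confidence,
                                seed = seed + 7L)
  profile <- flag_windows(profile, curve)
  candidates <- extract_candidate_intervals(profile, config$merge_gap_bp)

  summary <- list(
    seed = seed,
    n_sites_input = nrow(ad),
    n_sites_parent_homozygous = nrow(polarized),
    n_sites_filtered_out = tally,
    n_sites_retained = nrow(filtered),
    n_windows = nrow(profile),
    n_windows_eligible = sum(profile$eligible),
    n_windows_significant = sum(profile$significant),
    confidence = config$confidence,
    candidate_intervals = candidates)

  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_window_profile(profile, file.path(outdir, "windows.tsv"))
    write_threshold_curve(curve, file.path(outdir, "thresholds.tsv"))
    write_intervals_bed(candidates, file.path(outdir, "candidates.bed"))
    jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    yaml::write_yaml(.config_as_list(config), file.path(outdir, "config.yaml"))
  }

  list(population = population, bulks = bulks, allele_depths = ad,
       polarized = polarized, snp_index = filtered, profile = profile,
       curve = curve, candidates = candidates, tally = tally,
       summary = summary)
}

#' Fine mapping from a marker screen
#'
#' Builds the genetic map (recombinant counts, Kosambi cM), tests 1:1
#' segregation, derives the flanking-marker physical interval, and — when
#' candidate intervals from [run_bsa()] are supplied — intersects it with
#' each to give the final region(s), counting genes when an annotation is
#' given.
#'
#' @param screen a `marker_screen` or path to a TSV written by
#'   [write_marker_screen()].
#' @param candidates optional candidate intervals (data.frame `chrom, start,
#'   end`, e.g. `run_bsa(...)$candidates`, or a BED path).
#' @param gene_models optional gene models (data.frame from
#'   [read_gene_models()] or a GFF3/BED path).
#' @param boundary flanking-interval convention, see [flanking_interval()].
#' @param donor_dominant see [count_recombinants()].
#' @param outdir optional output directory (`genetic_map.tsv`,
#'   `summary.json`).
#' @return list with `map`, `segregation`, `interval`, and (when candidates
#'   were given) `final_regions` (each intersection, its `length_kb`, and
#'   `n_genes` when annotation was supplied).
#' @export
run_finemap <- function(screen, candidates = NULL, gene_models = NULL,
                        boundary = "outer", donor_dominant = TRUE,
                        outdir = NULL) {
  if (is.character(screen)) screen <- read_marker_screen(screen)
  if (is.character(candidates)) candidates <- read_intervals_bed(candidates)
  if (is.character(gene_models)) gene_models <- read_gene_models(gene_models)

  map <- linkage_map(screen, donor_dominant)
  ph <- table(factor(screen$calls$phenotype, levels = c("yellow", "brown")))
  seg <- segregation_test(ph[["yellow"]], ph[["brown"]])
  interval <- flanking_interval(map, boundary)

  final_regions <- NULL
  if (!is.null(candidates) && nrow(candidates) > 0L) {
    pieces <- lapply(seq_len(nrow(candidates)), function(i) {
      x <- interval_intersect(interval, candidates[i, , drop = FALSE],
                              label = "final_region")
      if (nrow(x) == 0L) return(NULL)
      x$length_kb <- length_kb(x)
      if (!is.null(gene_models)) x$n_genes <- count_genes(x, gene_models)
      x
    })
    pieces <- pieces[!vapply(pieces, is.null, logical(1))]
    final_regions <- if (length(pieces)) do.call(rbind, pieces) else .empty_interval()
  }

  summary <- list(
    n_plants = nrow(screen$calls),
    segregation = seg,
    genetic_map = as.data.frame(map),
    fine_mapping_interval = as.data.frame(interval),
    open_left = attr(interval, "open_left"),
    open_right = attr(interval, "open_right"),
    final_regions = if (!is.null(final_regions)) as.data.frame(final_regions))

  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_linkage_map(map, file.path(outdir, "genetic_map.tsv"))
    jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  list(map = map, segregation = seg, interval = interval,
       final_regions = final_regions, summary = summary)
}
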