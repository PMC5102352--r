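#' Genome specification for the simulator
#'
#' Describes the chromosomes the simulator works on: physical lengths, the
#' biallelic SNP positions that differ between the two inbred parents, and a
#' genetic length per chromosome. A uniform cM/bp rate is assumed within each
#' chromosome, so a SNP's map position is `pos / length * genetic_length`.
#'
#' @param chromosomes data.frame with columns `name` and `length` (bp).
#' @param snp_positions named list (one element per chromosome) of strictly
#'   increasing integer positions in `[1, length]`.
#' @param genetic_length named numeric vector of map lengths in Morgans
#'   (one per chromosome, all > 0).
#' @return An object of class `genome_spec`.
#' @examples
#' genome_spec(
#'   chromosomes   = data.frame(name = "A09", length = 1e6),
#'   snp_positions = list(A09 = c(1e5, 5e5, 9e5)),
#'   genetic_length = c(A09 = 0.05)
#' )
#' @export
genome_spec <- function(chromosomes, snp_positions, genetic_length) {
  stopifnot(is.data.frame(chromosomes), all(c("name", "length") %in% names(chromosomes)))
  if (nrow(chromosomes) == 0L) stop("genome must contain at least one chromosome")
  chromosomes$name <- as.character(chromosomes$name)
  if (anyDuplicated(chromosomes$name)) stop("duplicated chromosome names")
  if (any(chromosomes$length < 1)) stop("chromosome lengths must be positive")
  for (nm in chromosomes$name) {
    p <- snp_positions[[nm]]
    if (is.null(p) || length(p) == 0L) stop("no SNP positions for chromosome ", nm)
    if (is.unsorted(p, strictly = TRUE)) stop("SNP positions on ", nm, " must be strictly increasing")
    L <- chromosomes$length[chromosomes$name == nm]
    if (p[1] < 1 || p[length(p)] > L) stop("SNP positions on ", nm, " outside [1, length]")
    g <- genetic_length[[nm]]
    if (is.null(g) || is.na(g) || g < 0) stop("genetic_length for ", nm, " must be >= 0 Morgans")
  }
  structure(list(chromosomes = chromosomes,
                 snp_positions = lapply(snp_positions[chromosomes$name], as.numeric),
                 genetic_length = genetic_length[chromosomes$name]),
            class = "genome_spec")
}

#' Random genome with uniformly placed SNPs
#'
#' Convenience constructor: one or more chromosomes with SNP positions drawn
#' uniformly (then sorted and deduplicated). Defaults emulate *B. rapa*
#' chromosome A09: 37 Mb and 1.2 Morgans (about 3.2 cM/Mb).
#'
#' @param chrom_names,chrom_lengths chromosome names and bp lengths.
#' @param n_snps SNPs per chromosome (recycled).
#' @param morgans genetic length in Morgans per chromosome (recycled).
#' @param seed integer seed.
#' @return A `genome_spec`.
#' @export
simulate_genome <- function(chrom_names = "A09", chrom_lengths = 37e6,
                            n_snps = 2000, morgans = 1.2, seed = 1L) {
  set.seed(seed)
  n_snps <- rep_len(n_snps, length(chrom_names))
  morgans <- rep_len(morgans, length(chrom_names))
  chrom_lengths <- rep_len(chrom_lengths, length(chrom_names))
  pos <- lapply(seq_along(chrom_names), function(i) {
    sort(unique(ceiling(stats::runif(n_snps[i]) * chrom_lengths[i])))
  })
  names(pos) <- chrom_names
  genome_spec(data.frame(name = chrom_names, length = chrom_lengths),
              pos, stats::setNames(morgans, chrom_names))
}

#' Backcross design
#'
#' The breeding scheme: a donor-parent allele at one locus is carried
#' heterozygous through `n_backcrosses` generations of backcrossing to the
#' recurrent parent ("selective backcrosses"); the final generation is left
#' unselected, phenotyped, and bulked. The donor allele is dominant, so
#' carriers show the donor phenotype (brown seed) and the population
#' segregates 1:1.
#'
#' @param n_backcrosses number of backcross generations (>= 1); 4 gives a BC4.
#' @param selection_chrom,selection_pos chromosome and bp of the selected locus
#'   (must be one of the genome's SNP positions).
#' @param bulk_size plants per phenotype bulk.
#' @param population_size plants in the final, unselected generation.
#' @param recurrent_parent,donor_parent labels only.
#' @return An object of class `cross_design`.
#' @export
cross_design <- function(n_backcrosses = 4L, selection_chrom = "A09",
                         selection_pos = 18500000, bulk_size = 20L,
                         population_size = 1739L,
                         recurrent_parent = "recurrent_yellow",
                         donor_parent = "donor_brown") {
  stopifnot(n_backcrosses >= 1, bulk_size >= 1, population_size >= 1)
  if (bulk_size > population_size) stop("bulk_size must not exceed population_size")
  structure(list(n_backcrosses = as.integer(n_backcrosses),
                 selection_chrom = selection_chrom,
                 selection_pos = as.numeric(selection_pos),
                 bulk_size = as.integer(bulk_size),
                 population_size = as.integer(population_size),
                 recurrent_parent = recurrent_parent,
                 donor_parent = donor_parent),
            class = "cross_design")
}

#' Pooled-sequencing depth model
#'
#' Per-site read depth is Poisson with the given mean; each read reports the
#' donor allele with probability `f(1-e) + (1-f)e`, where `f` is the bulk's
#' true donor-allele frequency and `e` a symmetric per-read miscall rate.
#'
#' @param mean_depth expected reads per site per pool.
#' @param error_rate per-read allele miscall probability, in `[0, 0.5)`.
#' @return An object of class `pool_depth_model`.
#' @export
pool_depth_model <- function(mean_depth = 15, error_rate = 0.001) {
  stopifnot(mean_depth > 0, error_rate >= 0, error_rate < 0.5)
  structure(list(mean_depth = mean_depth, error_rate = error_rate),
            class = "pool_depth_model")
}

# one gamete from a parent whose donor-carrying homolog has donor alleles at
# `donor` (logical over SNPs); crossover count ~ Poisson(L Morgans), positions
# uniform, no interference. Returns logical: SNPs at which the gamete carries
# the donor allele.
.sim_gamete <- function(donor, snp_morgan, L) {
  k <- stats::rpois(1L, L)
  phase <- stats::rbinom(1L, 1L, 0.5)            # homolog at the chromosome start
  if (k == 0L) {
    if (phase == 1L) donor else rep(FALSE, length(donor))
  } else {
    breaks <- sort(stats::runif(k, 0, L))
    on_mosaic <- (findInterval(snp_morgan, breaks) + phase) %% 2L == 1L
    donor & on_mosaic
  }
}

#' Simulate a selective backcross population
#'
#' Starting from the F1 (heterozygous at every parent-differential SNP), each
#' backcross generation draws gametes from the current carrier plant; in all
#' but the final generation one progeny heterozygous at the selection locus is
#' retained as the next carrier (selection acts on the locus only). The final
#' generation is unselected: `population_size` plants, each scored brown if it
#' carries the (dominant) donor allele at the locus, yellow otherwise.
#'
#' @param genome a [genome_spec()].
#' @param design a [cross_design()].
#' @param seed integer seed; output is reproducible bit-for-bit given
#'   (seed, parameters).
#' @return An object of class `bc_population`: list with `donor` (per
#'   chromosome, a `population_size x n_snps` logical matrix, `TRUE` where the
#'   plant is heterozygous, i.e. carries the donor allele), `phenotype`
#'   (`"yellow"`/`"brown"`), plus the genome and design.
#' @export
simulate_cross <- function(genome, design, seed = 1L) {
  stopifnot(inherits(genome, "genome_spec"), inherits(design, "cross_design"))
  chroms <- genome$chromosomes$name
  if (!design$selection_chrom %in% chroms)
    stop("selection locus chromosome ", design$selection_chrom, " not in genome")
  locus_idx <- match(design$selection_pos, genome$snp_positions[[design$selection_chrom]])
  if (is.na(locus_idx))
    stop("selection locus position ", design$selection_pos,
         " is not a SNP position on ", design$selection_chrom)
  set.seed(seed)

  snp_morgan <- lapply(chroms, function(nm) {
    genome$snp_positions[[nm]] / genome$chromosomes$length[chroms == nm] *
      genome$genetic_length[[nm]]
  })
  names(snp_morgan) <- chroms
  Ls <- genome$genetic_length

  # carrier parent: donor-allele content of its non-recurrent homolog
  parent <- lapply(chroms, function(nm) rep(TRUE, length(genome$snp_positions[[nm]])))
  names(parent) <- chroms

  draw_plant <- function() {
    lapply(chroms, function(nm) .sim_gamete(parent[[nm]], snp_morgan[[nm]], Ls[[nm]]))
  }

  if (design$n_backcrosses > 1L) {
    for (g in seq_len(design$n_backcrosses - 1L)) {
      found <- FALSE
      for (try in 1:1000) {
        cand <- draw_plant()
        names(cand) <- chroms
        if (cand[[design$selection_chrom]][locus_idx]) { parent <- cand; found <- TRUE; break }
      }
      if (!found) stop("failed to recover a locus carrier in backcross generation ", g)
    }
  }

  n <- design$population_size
  donor <- lapply(chroms, function(nm)
    matrix(FALSE, nrow = n, ncol = length(genome$snp_positions[[nm]])))
  names(donor) <- chroms
  for (i in seq_len(n)) {
    pl <- draw_plant()
    for (j in seq_along(chroms)) donor[[chroms[j]]][i, ] <- pl[[j]]
  }
  phenotype <- ifelse(donor[[design$selection_chrom]][, locus_idx], "brown", "yellow")
  structure(list(donor = donor, phenotype = phenotype,
                 genome = genome, design = design, locus_idx = locus_idx),
            class = "bc_population")
}

#' @export
print.bc_population <- function(x, ...) {
  cat("Backcross population:", length(x$phenotype), "plants (",
      sum(x$phenotype == "yellow"), "yellow /", sum(x$phenotype == "brown"), "brown )\n")
  invisible(x)
}

.subset_population <- function(pop, idx) {
  structure(list(donor = lapply(pop$donor, function(m) m[idx, , drop = FALSE]),
                 phenotype = pop$phenotype[idx],
                 genome = pop$genome, design = pop$design, locus_idx = pop$locus_idx),
            class = "bc_population")
}

#' Draw the two phenotype bulks
#'
#' Samples `bulk_size` plants of each phenotype uniformly without replacement.
#'
#' @param population a `bc_population`.
#' @param design a [cross_design()]; defaults to the population's own.
#' @param seed integer seed.
#' @return list with elements `yellow` and `brown`, each a `bc_population`
#'   restricted to the sampled plants.
#' @export
make_bulks <- function(population, design = population$design, seed = 1L) {
  stopifnot(inherits(population, "bc_population"))
  set.seed(seed)
  out <- lapply(c(yellow = "yellow", brown = "brown"), function(ph) {
    idx <- which(population$phenotype == ph)
    if (length(idx) < design$bulk_size)
      stop("only ", length(idx), " ", ph, "-seeded plants available for a bulk of ",
           design$bulk_size)
    .subset_population(population, sort(sample(idx, design$bulk_size)))
  })
  out
}

#' True donor-allele frequencies of a bulk
#'
#' Each heterozygous plant contributes one donor allele of two, so the bulk
#' frequency at a site is (number of heterozygotes) / (2 * bulk size).
#'
#' @param bulk a `bc_population` (typically one element of [make_bulks()]).
#' @return named list per chromosome of numeric frequencies per SNP.
#' @export
allele_frequencies <- function(bulk) {
  stopifnot(inherits(bulk, "bc_population"))
  lapply(bulk$donor, function(m) colMeans(m) / 2)
}

#' Simulate pooled sequencing allele depths
#'
#' Per site, total depth is Poisson(`mean_depth`); donor-allele read count is
#' binomial with success probability `f(1-e) + (1-f)e`. Sites whose drawn
#' depth is 0 are still emitted (depth 0; downstream treats them as missing).
#'
#' @param bulk a `bc_population`, or a named list (per chromosome) of true
#'   donor-allele frequencies (e.g. all 0 for the recurrent parent, all 1 for
#'   the donor parent).
#' @param genome a [genome_spec()].
#' @param model a [pool_depth_model()].
#' @param seed integer seed.
#' @param sample_name column label for this pool in the returned table.
#' @return An allele-depth table (see [read_allele_depths()] for the layout):
#'   one row per SNP with columns `chrom, pos, ref, alt,
#'   <sample>.ref, <sample>.alt`. `ref` is the recurrent-parent allele, `alt`
#'   the donor allele.
#' @export
simulate_pool_depths <- function(bulk, genome, model = pool_depth_model(),
                                 seed = 1L, sample_name = "pool") {
  stopifnot(inherits(genome, "genome_spec"), inherits(model, "pool_depth_model"))
  freqs <- if (inherits(bulk, "bc_population")) allele_frequencies(bulk) else bulk
  if (inherits(bulk, "bc_population") && length(bulk$phenotype) == 0L)
    stop("bulk is empty")
  set.seed(seed)
  e <- model$error_rate
  tabs <- lapply(genome$chromosomes$name, function(nm) {
    pos <- genome$snp_positions[[nm]]
    f <- rep_len(freqs[[nm]], length(pos))
    depth <- stats::rpois(length(pos), model$mean_depth)
    p_donor <- f * (1 - e) + (1 - f) * e
    alt <- stats::rbinom(length(pos), depth, p_donor)
    data.frame(chrom = nm, pos = pos, ref = "A", alt = "G",
               x1 = depth - alt, x2 = alt, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, tabs)
  names(out)[5:6] <- paste0(sample_name, c(".ref", ".alt"))
  rownames(out) <- NULL
  attr(out, "samples") <- sample_name
  out
}

#' Combine single-pool allele-depth tables into one multi-sample table
#'
#' Tables must describe the same sites in the same order (as produced by
#' repeated [simulate_pool_depths()] calls on one genome).
#'
#' @param tables list of allele-depth tables.
#' @return one allele-depth table with every sample's count columns.
#' @export
merge_allele_depths <- function(tables) {
  stopifnot(length(tables) >= 1L)
  base <- tables[[1]][c("chrom", "pos", "ref", "alt")]
  for (t in tables[-1]) {
    if (!identical(t$chrom, base$chrom) || !identical(t$pos, base$pos))
      stop("allele-depth tables describe different sites")
  }
  counts <- do.call(cbind, lapply(tables, function(t) t[-(1:4)]))
  out <- cbind(base, counts)
  attr(out, "samples") <- unlist(lapply(tables, attr, "samples"), use.names = FALSE)
  out
}

#' Genotype a marker panel across the population
#'
#' Error-free genotype calls (`"A"` = recurrent homozygote, `"H"` =
#' heterozygote) at markers on the selected chromosome, paired with each
#' plant's phenotype. Marker positions must be SNP positions of the genome.
#'
#' @param population a `bc_population`.
#' @param markers data.frame with columns `marker`, `chrom`, `start`, `end`
#'   (physical span; genotyping uses the span midpoint's nearest listed SNP
#'   when `pos` is absent) or an additional `pos` column naming the SNP
#'   position directly.
#' @param design a [cross_design()]; defaults to the population's own.
#' @return A `marker_screen`: list with `calls` (data.frame `plant_id`,
#'   `phenotype`, one column per marker) and `markers`.
#' @export
simulate_marker_screen <- function(population, markers, design = population$design) {
  stopifnot(inherits(population, "bc_population"), is.data.frame(markers))
  need <- c("marker", "chrom", "start", "end")
  stopifnot(all(need %in% names(markers)))
  if (!all(markers$chrom == design$selection_chrom))
    stop("marker(s) off the selected chromosome: ",
         paste(markers$marker[markers$chrom != design$selection_chrom], collapse = ", "))
  snp_pos <- population$genome$snp_positions[[design$selection_chrom]]
  pos <- if ("pos" %in% names(markers)) markers$pos else (markers$start + markers$end) / 2
  idx <- vapply(pos, function(p) {
    j <- match(p, snp_pos)
    if (is.na(j)) j <- which.min(abs(snp_pos - p))
    j
  }, integer(1))
  geno <- population$donor[[design$selection_chrom]][, idx, drop = FALSE]
  calls <- data.frame(plant_id = sprintf("plant_%04d", seq_along(population$phenotype)),
                      phenotype = population$phenotype, stringsAsFactors = FALSE)
  for (j in seq_along(idx)) calls[[markers$marker[j]]] <- ifelse(geno[, j], "H", "A")
  structure(list(calls = calls, markers = markers), class = "marker_screen")
}

#' Write / read a marker screen as TSV
#'
#' The TSV carries `plant_id`, `phenotype`, then one genotype column per
#' marker; marker physical spans go in a companion header block prefixed `#`.
#'
#' @param screen a `marker_screen`.
#' @param path output file.
#' @return `path`, invisibly (writer); a `marker_screen` (reader).
#' @export
write_marker_screen <- function(screen, path) {
  stopifnot(inherits(screen, "marker_screen"))
  con <- file(path, "w")
  on.exit(close(con))
  m <- screen$markers
  for (i in seq_len(nrow(m)))
    writeLines(sprintf("#marker\t%s\t%s\t%d\t%d", m$marker[i], m$chrom[i],
                       as.integer(m$start[i]), as.integer(m$end[i])), con)
  utils::write.table(screen$calls, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_marker_screen
#' @export
read_marker_screen <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#marker\t", lines, value = TRUE)
  markers <- do.call(rbind, lapply(strsplit(hdr, "\t"), function(x)
    data.frame(marker = x[2], chrom = x[3], start = as.numeric(x[4]),
               end = as.numeric(x[5]), stringsAsFactors = FALSE)))
  calls <- utils::read.delim(text = lines[!startsWith(lines, "#")],
                             stringsAsFactors = FALSE)
  structure(list(calls = calls, markers = markers), class = "marker_screen")
}
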