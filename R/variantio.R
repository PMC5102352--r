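#' Read per-sample allele depths
#'
#' Reads a table of biallelic sites with, for every sample, read counts
#' supporting each of the two alleles. Two encodings are supported:
#'
#' * `tsv`: columns `chrom, pos, ref, alt`, then `<sample>.ref` and
#'   `<sample>.alt` count pairs;
#' * `vcf`: a VCF with a per-sample `AD` FORMAT field (parsed with
#'   \pkg{vcfR}). `REF` maps to `ref`, `ALT` to `alt`.
#'
#' Sites with more than two alleles are skipped; the number skipped is
#' reported as a message and stored in the `n_skipped` attribute. Positions
#' are 1-based, VCF convention; input must be position-sorted within each
#' chromosome.
#'
#' @param path file to read.
#' @param format `"tsv"` or `"vcf"`.
#' @return data.frame `chrom, pos, ref, alt, <sample>.ref, <sample>.alt, ...`
#'   with attributes `samples` and `n_skipped`.
#' @export
read_allele_depths <- function(path, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  out <- if (format == "tsv") .read_ad_tsv(path) else .read_ad_vcf(path)
  .check_sorted(out)
  out
}

.check_sorted <- function(tbl) {
  ok <- tapply(tbl$pos, tbl$chrom, function(p) !is.unsorted(p))
  if (!all(ok)) stop("input sites are not position-sorted on chromosome ",
                     names(ok)[!ok][1])
  invisible(tbl)
}

.read_ad_tsv <- function(path) {
  tbl <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "ref", "alt")
  if (!all(need %in% names(tbl))) stop("TSV must carry columns chrom, pos, ref, alt")
  cnt <- setdiff(names(tbl), need)
  samples <- unique(sub("\\.(ref|alt)$", "", cnt))
  miss <- c(setdiff(paste0(samples, ".ref"), cnt), setdiff(paste0(samples, ".alt"), cnt))
  if (length(miss)) stop("missing count column(s): ", paste(miss, collapse = ", "))
  tbl <- tbl[c(need, paste0(rep(samples, each = 2), c(".ref", ".alt")))]
  attr(tbl, "samples") <- samples
  attr(tbl, "n_skipped") <- 0L
  tbl
}

.read_ad_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT)
  if (any(multi)) {
    message(sum(multi), " site(s) with more than two alleles skipped")
    v <- v[!multi, ]
    fix <- fix[!multi, , drop = FALSE]
  }
  ad <- vcfR::extract.gt(v, element = "AD")
  if (is.null(ad) || any(is.na(ad)))
    stop("missing AD field at site ",
         fix$CHROM[which(apply(is.na(ad), 1, any))[1]], ":",
         fix$POS[which(apply(is.na(ad), 1, any))[1]])
  samples <- colnames(ad)
  out <- data.frame(chrom = fix$CHROM, pos = as.numeric(fix$POS),
                    ref = fix$REF, alt = fix$ALT, stringsAsFactors = FALSE)
  for (s in samples) {
    parts <- strsplit(ad[, s], ",", fixed = TRUE)
    if (any(lengths(parts) != 2L))
      stop("malformed AD for sample ", s, " at site ",
           out$chrom[which(lengths(parts) != 2L)[1]], ":",
           out$pos[which(lengths(parts) != 2L)[1]])
    m <- matrix(as.integer(unlist(parts)), ncol = 2, byrow = TRUE)
    out[[paste0(s, ".ref")]] <- m[, 1]
    out[[paste0(s, ".alt")]] <- m[, 2]
  }
  rownames(out) <- NULL
  attr(out, "samples") <- samples
  attr(out, "n_skipped") <- sum(multi)
  out
}

#' Write an allele-depth table
#'
#' `tsv` mirrors the reader's layout. `vcf` emits a minimal VCF 4.2 with one
#' `AD`-style FORMAT field per sample (reading always goes through
#' \pkg{vcfR}; this writer only serialises the fixed layout used here).
#'
#' @param tbl allele-depth table (as from [read_allele_depths()] or
#'   [simulate_pool_depths()]).
#' @param path output file.
#' @param format `"tsv"` or `"vcf"`.
#' @return `path`, invisibly.
#' @export
write_allele_depths <- function(tbl, path, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  samples <- attr(tbl, "samples")
  if (is.null(samples))
    samples <- unique(sub("\\.(ref|alt)$", "", setdiff(names(tbl), c("chrom", "pos", "ref", "alt"))))
  if (format == "tsv") {
    utils::write.table(tbl, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("##fileformat=VCFv4.2",
                 "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
                 "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">",
                 paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                         "INFO", "FORMAT", samples), collapse = "\t")), con)
    gt <- vapply(samples, function(s)
      paste0("./.:", tbl[[paste0(s, ".ref")]], ",", tbl[[paste0(s, ".alt")]]),
      character(nrow(tbl)))
    if (nrow(tbl) == 1L) gt <- matrix(gt, nrow = 1)
    body <- cbind(tbl$chrom, format(tbl$pos, scientific = FALSE, trim = TRUE),
                  ".", tbl$ref, tbl$alt, ".", "PASS", ".", "GT:AD", gt)
    writeLines(apply(body, 1, paste, collapse = "\t"), con)
  }
  invisible(path)
}

#' Select parent-homozygous SNPs and polarize against the reference parent
#'
#' Keeps sites at which both parents are homozygous for different alleles
#' (all of a parent's reads support one allele, with depth at least
#' `min_parent_depth`) and annotates each with the *measured* allele — the
#' allele of the non-reference parent. Downstream SNP indices are the
#' fraction of a pool's reads carrying the measured allele, so swapping the
#' reference parent maps every index `i` to `1 - i`.
#'
#' @param records allele-depth table including both parent samples.
#' @param parent1,parent2 parent sample names.
#' @param reference_parent which of the two is the reference (the study
#'   used the brown, donor parent).
#' @param min_parent_depth minimum reads per parent to call homozygosity.
#' @return Polarized site table: `chrom, pos, allele_ref_parent,
#'   allele_measured`, plus `<pool>.measured` and `<pool>.depth` for every
#'   non-parent sample; attribute `pools` lists them.
#' @export
select_parent_homozygous <- function(records, parent1, parent2,
                                     reference_parent = parent2,
                                     min_parent_depth = 4) {
  samples <- attr(records, "samples")
  if (is.null(samples))
    samples <- unique(sub("\\.(ref|alt)$", "", setdiff(names(records), c("chrom", "pos", "ref", "alt"))))
  for (p in c(parent1, parent2)) if (!p %in% samples) stop("unknown parent sample: ", p)
  if (!reference_parent %in% c(parent1, parent2))
    stop("reference_parent must be one of the two parents")
  other_parent <- setdiff(c(parent1, parent2), reference_parent)

  hom <- function(p) {
    r <- records[[paste0(p, ".ref")]]; a <- records[[paste0(p, ".alt")]]
    d <- r + a
    # "ref" / "alt" / NA call
    ifelse(d >= min_parent_depth & a == 0, "ref",
           ifelse(d >= min_parent_depth & r == 0, "alt", NA))
  }
  c1 <- hom(parent1); c2 <- hom(parent2)
  keep <- !is.na(c1) & !is.na(c2) & c1 != c2
  rec <- records[keep, , drop = FALSE]
  call_ref <- (if (reference_parent == parent1) c1 else c2)[keep]
  # measured allele = the non-reference parent's allele, opposite of call_ref
  measured_is_alt <- call_ref == "ref"
  pools <- setdiff(samples, c(parent1, parent2))
  out <- data.frame(chrom = rec$chrom, pos = rec$pos,
                    allele_ref_parent = ifelse(measured_is_alt, rec$ref, rec$alt),
                    allele_measured = ifelse(measured_is_alt, rec$alt, rec$ref),
                    stringsAsFactors = FALSE)
  for (s in pools) {
    r <- rec[[paste0(s, ".ref")]]; a <- rec[[paste0(s, ".alt")]]
    out[[paste0(s, ".measured")]] <- ifelse(measured_is_alt, a, r)
    out[[paste0(s, ".depth")]] <- r + a
  }
  rownames(out) <- NULL
  attr(out, "pools") <- pools
  attr(out, "reference_parent") <- reference_parent
  attr(out, "measured_parent") <- other_parent
  out
}

#' Write a polarized site table as TSV
#' @param tbl polarized table from [select_parent_homozygous()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_polarized_sites <- function(tbl, path) {
  utils::write.table(tbl, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
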