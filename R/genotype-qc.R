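# Genotype containers and the post-variant-calling filter chain:
# biallelic-only -> heterozygosity (homeolog screen) -> missingness -> MAF,
# plus one-SNP-per-fragment thinning and per-population allele frequencies.

#' Construct a genotype matrix object
#'
#' @param geno integer matrix, individuals x SNPs, entries in {0, 1, 2, NA}
#'   counting copies of the alternate allele.
#' @param snps tibble of per-SNP metadata: `snp_id`, `fragment`, `pos`
#'   (1-based), and optionally `ref`, `alt`, `n_alleles`.
#' @param samples tibble of per-individual metadata: `sample_id`,
#'   `population`.
#' @return object of class `genotype_matrix`.
#' @export
new_genotype_matrix <- function(geno, snps, samples) {
  stopifnot(nrow(geno) == nrow(samples), ncol(geno) == nrow(snps))
  if (anyDuplicated(samples$sample_id)) abort("duplicate sample ids")
  if (any(is.na(samples$population))) abort("every individual needs a population")
  if (!"n_alleles" %in% names(snps)) snps$n_alleles <- 2L
  if (any(snps$pos < 0)) abort("positions must be non-negative")
  structure(list(geno = geno, snps = as_tibble(snps),
                 samples = as_tibble(samples)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d individuals x %d SNPs, %d populations, %d fragments\n",
              nrow(x$geno), ncol(x$geno), dplyr::n_distinct(x$samples$population),
              dplyr::n_distinct(x$snps$fragment)))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$geno)

subset_snps <- function(g, keep) {
  new_genotype_matrix(g$geno[, keep, drop = FALSE], g$snps[keep, , drop = FALSE],
                      g$samples)
}

#' Read genotypes from a VCF and a popmap
#'
#' Parses GT fields of a diploid VCF. Sites containing half-calls (e.g.
#' `./1`) or non-diploid genotypes are rejected (dropped with a warning).
#' Multi-allelic sites are retained but flagged (`n_alleles > 2`) so the
#' biallelic filter can remove them; genotypes carrying allele indices > 1
#' are recorded as missing.
#'
#' @param vcf path to a VCF 4.x file.
#' @param popmap path to a tab-separated table with columns `sample_id` and
#'   `population`. Every VCF sample must appear; an unknown sample is a hard
#'   error naming it.
#' @return a [genotype_matrix][new_genotype_matrix].
#' @export
read_genotypes <- function(vcf, popmap) {
  if (!file.exists(vcf)) abort(sprintf("VCF not found: %s", vcf))
  if (!file.exists(popmap)) abort(sprintf("popmap not found: %s", popmap))
  v <- vcfR::read.vcfR(vcf, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  pm <- utils::read.table(popmap, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  names(pm)[1:2] <- c("sample_id", "population")
  samples <- colnames(gt)
  unknown <- setdiff(samples, pm$sample_id)
  if (length(unknown)) {
    abort(sprintf("VCF sample(s) absent from popmap: %s",
                  paste(unknown, collapse = ", ")))
  }

  gt[is.na(gt)] <- "./."
  alleles <- sub("^([^/|]*)[/|]([^/|]*)$", "\\1,\\2", gt)
  bad_site <- apply(gt, 1, function(row) {
    any(!grepl("^(\\.|[0-9]+)[/|](\\.|[0-9]+)$", row)) ||
      any(xor(grepl("^\\.[/|]", row), grepl("[/|]\\.$", row)))
  })
  if (any(bad_site)) {
    warn(sprintf("rejected %d site(s) with half-calls or non-diploid genotypes",
                 sum(bad_site)))
    gt <- gt[!bad_site, , drop = FALSE]
    fix <- fix[!bad_site, , drop = FALSE]
  }
  if (nrow(gt) == 0) abort("no usable sites in VCF")

  a1 <- suppressWarnings(as.integer(sub("[/|].*$", "", gt)))
  a2 <- suppressWarnings(as.integer(sub("^.*[/|]", "", gt)))
  code <- a1 + a2
  code[which(pmax(a1, a2) > 1L)] <- NA_integer_  # alleles beyond ALT1: flagged missing
  geno <- t(matrix(code, nrow = nrow(gt), ncol = ncol(gt)))

  alt <- fix$ALT
  n_alleles <- ifelse(is.na(alt) | alt == ".", 1L,
                      1L + lengths(strsplit(alt, ",", fixed = TRUE)))
  snp_id <- fix$ID
  if (any(is.na(snp_id) | snp_id == ".")) {
    snp_id <- ifelse(is.na(snp_id) | snp_id == ".",
                     paste0(fix$CHROM, "_", fix$POS), snp_id)
  }
  snps <- tibble(
    snp_id = snp_id, fragment = fix$CHROM, pos = as.integer(fix$POS),
    ref = fix$REF, alt = alt, n_alleles = as.integer(n_alleles)
  )
  dimnames(geno) <- list(samples, snps$snp_id)
  samp <- tibble(sample_id = samples,
                 population = pm$population[match(samples, pm$sample_id)])
  new_genotype_matrix(geno, snps, samp)
}

#' Filter variants with the standard post-calling rules
#'
#' Rules are applied in the fixed order biallelic -> heterozygosity ->
#' missingness -> MAF so that the per-rule removal accounting in the report
#' is reproducible. A SNP survives if it has exactly two alleles, its
#' heterozygote fraction among non-missing genotypes is <= `het_max`
#' (homeolog screen), its missing fraction is <= `miss_max`, and its pooled
#' minor allele frequency is >= `maf_min`.
#'
#' @param g a [genotype_matrix][new_genotype_matrix].
#' @param het_max,miss_max,maf_min filter thresholds in `[0, 1]`.
#' @param biallelic_only drop sites with a number of alleles other than 2?
#' @return list with elements `genotypes` (filtered [genotype_matrix][new_genotype_matrix]) and
#'   `report` (tibble of class `filter_report`: `rule`, `n_before`,
#'   `n_removed`, `n_after`, `removed` list-column of SNP ids).
#' @export
filter_variants <- function(g, het_max = 0.70, miss_max = 0.50,
                            maf_min = 0.05, biallelic_only = TRUE) {
  stopifnot(inherits(g, "genotype_matrix"))
  for (nm in c("het_max", "miss_max", "maf_min")) {
    stop_if_not_scalar_prob(get(nm), nm)
  }
  rules <- list(
    biallelic = function(gg) {
      if (!biallelic_only) rep(TRUE, ncol(gg$geno)) else gg$snps$n_alleles == 2L
    },
    heterozygosity = function(gg) {
      het <- colMeans(gg$geno == 1L, na.rm = TRUE)
      is.nan(het) | het <= het_max
    },
    missingness = function(gg) colMeans(is.na(gg$geno)) <= miss_max,
    maf = function(gg) {
      p <- colMeans(gg$geno, na.rm = TRUE) / 2
      maf <- pmin(p, 1 - p)
      !is.nan(maf) & maf >= maf_min
    }
  )
  report <- tibble(rule = character(), n_before = integer(),
                   n_removed = integer(), n_after = integer(),
                   removed = list())
  for (rule in names(rules)) {
    keep <- rules[[rule]](g)
    report <- dplyr::bind_rows(report, tibble(
      rule = rule, n_before = ncol(g$geno),
      n_removed = sum(!keep), n_after = sum(keep),
      removed = list(g$snps$snp_id[!keep])
    ))
    g <- subset_snps(g, keep)
  }
  if (ncol(g$geno) == 0) warn("no SNPs survive the filter chain")
  class(report) <- c("filter_report", class(report))
  list(genotypes = g, report = report)
}

#' Keep one SNP per fragment
#'
#' Retains, within each fragment, the SNP with the lowest position; ties are
#' broken by lexicographic SNP id, so the thinning is deterministic.
#'
#' @param g a [genotype_matrix][new_genotype_matrix] with fragment ids.
#' @return thinned [genotype_matrix][new_genotype_matrix].
#' @export
thin_one_per_fragment <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  ord <- order(g$snps$fragment, g$snps$pos, g$snps$snp_id)
  keep_ids <- g$snps$snp_id[ord][!duplicated(g$snps$fragment[ord])]
  subset_snps(g, g$snps$snp_id %in% keep_ids)
}

#' Construct an allele-frequency matrix object
#'
#' @param freq populations x SNPs matrix of alternate-allele frequencies in
#'   `[0, 1]` (`NA` where no alleles were genotyped).
#' @param counts matching matrix of non-missing allele counts
#'   (2 x genotyped individuals); `NA` marks true (parametric) frequencies.
#' @param snps per-SNP metadata tibble.
#' @param populations character vector of population ids (row order).
#' @return object of class `allele_freq`.
#' @export
new_allele_freq <- function(freq, counts, snps, populations) {
  stopifnot(nrow(freq) == length(populations), ncol(freq) == nrow(snps))
  if (any(freq < -1e-12 | freq > 1 + 1e-12, na.rm = TRUE)) {
    abort("frequencies outside [0, 1]")
  }
  structure(list(freq = freq, counts = counts, snps = as_tibble(snps),
                 populations = populations),
            class = "allele_freq")
}

#' @export
print.allele_freq <- function(x, ...) {
  cat(sprintf("<allele_freq> %d populations x %d SNPs\n",
              nrow(x$freq), ncol(x$freq)))
  invisible(x)
}

#' Per-population alternate-allele frequencies
#'
#' Frequency = alternate-allele count / non-missing allele count per
#' population; cells with zero genotyped alleles are `NA`. When
#' `min_poly_pops > 0`, SNPs polymorphic (0 < p < 1) in fewer than that many
#' populations are dropped.
#'
#' @param g a [genotype_matrix][new_genotype_matrix].
#' @param min_poly_pops minimum number of populations in which a SNP must be
#'   polymorphic (0 disables the rule).
#' @return an [allele_freq][new_allele_freq] object.
#' @export
population_frequencies <- function(g, min_poly_pops = 0) {
  stopifnot(inherits(g, "genotype_matrix"))
  pops <- sort(unique(g$samples$population))
  freq <- matrix(NA_real_, length(pops), ncol(g$geno),
                 dimnames = list(pops, g$snps$snp_id))
  counts <- matrix(0, length(pops), ncol(g$geno), dimnames = dimnames(freq))
  for (i in seq_along(pops)) {
    rows <- g$samples$population == pops[i]
    sub <- g$geno[rows, , drop = FALSE]
    n_called <- colSums(!is.na(sub))
    counts[i, ] <- 2 * n_called
    alt <- colSums(sub, na.rm = TRUE)
    freq[i, ] <- ifelse(n_called > 0, alt / (2 * n_called), NA_real_)
  }
  if (min_poly_pops > 0) {
    poly <- colSums(freq > 0 & freq < 1, na.rm = TRUE)
    keep <- poly >= min_poly_pops
    freq <- freq[, keep, drop = FALSE]
    counts <- counts[, keep, drop = FALSE]
    g <- subset_snps(g, keep)
  }
  new_allele_freq(freq, counts, g$snps, pops)
}
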