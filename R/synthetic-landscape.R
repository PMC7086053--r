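# Synthetic landscapes: gridded climates, population placements, allele
# frequency surfaces with isolation by distance and by environment, and
# diploid genotypes written as VCF + popmap. All randomness flows from the
# single `seed` carried by the config; independent streams are derived with
# derive_seed() so adding draws to one stage never perturbs another.

#' Default synthetic environmental variables
#'
#' A small set of climate-like surfaces emulating the kinds of predictors used
#' in conifer landscape genomics (reference evaporation, winter degree-days,
#' seasonal precipitation, climatic moisture deficit). Kinds:
#' `"gradient_lon"` / `"gradient_lat"` are linear gradients, `"sinusoid"` is a
#' longitudinal sine wave, `"noise"` is a Gaussian random field with
#' exponential covariance and autocorrelation length `length` (in degrees).
#'
#' @param n_noise number of additional independent noise variables to append
#'   (named `noise1`, `noise2`, ...), each with unit amplitude and zero
#'   autocorrelation length (white noise across cells).
#' @return tibble with columns `name`, `kind`, `baseline`, `amplitude`,
#'   `length`.
#' @export
default_variables <- function(n_noise = 0) {
  base <- tibble::tribble(
    ~name,       ~kind,          ~baseline, ~amplitude, ~length,
    "eref",      "gradient_lon", 600,       400,        NA,
    "dd_0_djf",  "gradient_lat", 100,       300,        NA,
    "ppt_djf",   "sinusoid",     50,        30,         8,
    "cmd",       "noise",        300,       80,         4
  )
  if (n_noise > 0) {
    base <- dplyr::bind_rows(base, tibble(
      name = paste0("noise", seq_len(n_noise)),
      kind = "noise", baseline = 0, amplitude = 1, length = 0
    ))
  }
  base
}

#' Configure a synthetic landscape
#'
#' @param n_lon,n_lat grid dimensions (cells along longitude / latitude);
#'   both must be >= 2.
#' @param lon_range,lat_range coordinate extents in decimal degrees.
#' @param variables tibble describing environmental surfaces
#'   (see [default_variables()]).
#' @param n_pops number of populations to place on the grid.
#' @param pop_cells optional integer vector of distinct cell ids for the
#'   populations; sampled uniformly without replacement if `NULL`.
#' @param n_per_pop diploid individuals sampled per population (scalar or
#'   length `n_pops`).
#' @param seed master integer seed fixing every downstream draw.
#' @return object of class `landscape_config`.
#' @export
landscape_config <- function(n_lon = 12, n_lat = 10,
                             lon_range = c(104, 120), lat_range = c(26, 42),
                             variables = default_variables(),
                             n_pops = 17, pop_cells = NULL, n_per_pop = 12,
                             seed = 1) {
  if (n_lon < 2 || n_lat < 2) abort("grid dimensions must be at least 2 x 2")
  if (n_pops < 1) abort("`n_pops` must be >= 1")
  if (n_pops > n_lon * n_lat) abort("more populations than grid cells")
  if (!is.null(pop_cells)) {
    if (anyDuplicated(pop_cells)) abort("population cells must be distinct")
    if (length(pop_cells) != n_pops) abort("`pop_cells` must have length `n_pops`")
    if (any(pop_cells < 1 | pop_cells > n_lon * n_lat)) abort("cell id out of range")
  }
  n_per_pop <- rep_len(as.integer(n_per_pop), n_pops)
  if (any(n_per_pop < 1)) abort("sample sizes must be >= 1")
  structure(list(
    n_lon = as.integer(n_lon), n_lat = as.integer(n_lat),
    lon_range = lon_range, lat_range = lat_range,
    variables = variables, n_pops = as.integer(n_pops),
    pop_cells = pop_cells, n_per_pop = n_per_pop, seed = as.integer(seed)
  ), class = "landscape_config")
}

# Gaussian random field with exponential covariance on point coordinates.
# length <= 0 degenerates to iid N(0, sd^2); amplitude 0 gives a flat field.
gaussian_field <- function(coords, sd, range) {
  n <- nrow(coords)
  if (sd == 0) return(rep(0, n))
  if (is.na(range) || range <= 0) return(rnorm(n, 0, sd))
  d <- as.matrix(dist(coords))
  sigma <- sd^2 * exp(-d / range)
  ch <- chol(sigma + diag(1e-10 * sd^2, n))
  drop(crossprod(ch, rnorm(n)))
}

make_variable <- function(v, grid, lon_range, lat_range) {
  lon01 <- (grid$lon - lon_range[1]) / diff(lon_range)
  lat01 <- (grid$lat - lat_range[1]) / diff(lat_range)
  val <- switch(v$kind,
    gradient_lon = v$amplitude * lon01,
    gradient_lat = v$amplitude * lat01,
    sinusoid = v$amplitude * sin(2 * pi * (grid$lon - lon_range[1]) /
                                   max(v$length, 1e-9)),
    noise = gaussian_field(cbind(grid$lon, grid$lat), v$amplitude, v$length),
    abort(sprintf("unknown variable kind '%s'", v$kind))
  )
  v$baseline + val
}

#' Generate a synthetic landscape
#'
#' Builds the climate grid, places populations on distinct cells, and reads
#' their site-level environments off the grid. Deterministic under the
#' config's seed.
#'
#' @param config a [landscape_config()].
#' @return object of class `landscape`: a list with elements `grid`
#'   (tibble: `cell_id`, `lon`, `lat`, one column per variable), `coords`
#'   (tibble: `population`, `cell_id`, `lon`, `lat`), `env` (tibble:
#'   `population` plus variable columns) and `config`.
#' @export
generate_landscape <- function(config) {
  stopifnot(inherits(config, "landscape_config"))
  set.seed(derive_seed(config$seed, 1L))
  lon <- seq(config$lon_range[1], config$lon_range[2], length.out = config$n_lon)
  lat <- seq(config$lat_range[1], config$lat_range[2], length.out = config$n_lat)
  grid <- tidyr::expand_grid(lat = lat, lon = lon)
  grid <- tibble(cell_id = seq_len(nrow(grid)), lon = grid$lon, lat = grid$lat)
  for (i in seq_len(nrow(config$variables))) {
    v <- as.list(config$variables[i, ])
    grid[[v$name]] <- make_variable(v, grid, config$lon_range, config$lat_range)
  }
  set.seed(derive_seed(config$seed, 2L))
  cells <- config$pop_cells %||% sample(nrow(grid), config$n_pops)
  pops <- sprintf("pop%02d", seq_len(config$n_pops))
  coords <- tibble(population = pops, cell_id = cells,
                   lon = grid$lon[cells], lat = grid$lat[cells])
  env <- dplyr::bind_cols(tibble(population = pops),
                          grid[cells, config$variables$name, drop = FALSE])
  structure(list(grid = grid, coords = coords, env = env, config = config),
            class = "landscape")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Describe a future-climate scenario as a shift of the current grid
#'
#' @param add named numeric vector of additive shifts (units of each
#'   variable).
#' @param mult named numeric vector of multiplicative scalings.
#' @param label scenario label, e.g. `"2055-RCP4.5"`.
#' @return object of class `scenario_shift`.
#' @export
scenario_shift <- function(add = numeric(), mult = numeric(), label = "future") {
  if (length(add) && is.null(names(add))) abort("`add` must be named")
  if (length(mult) && is.null(names(mult))) abort("`mult` must be named")
  structure(list(add = add, mult = mult, label = label), class = "scenario_shift")
}

#' Apply a scenario shift to a climate grid
#'
#' A zero shift returns the grid unchanged.
#'
#' @param grid climate grid tibble (`cell_id`, `lon`, `lat`, variables).
#' @param shift a [scenario_shift()].
#' @return shifted grid tibble with attribute `"scenario"`.
#' @export
apply_scenario <- function(grid, shift) {
  stopifnot(inherits(shift, "scenario_shift"))
  out <- grid
  for (v in names(shift$mult)) {
    if (!v %in% names(out)) abort(sprintf("variable '%s' not in grid", v))
    out[[v]] <- out[[v]] * shift$mult[[v]]
  }
  for (v in names(shift$add)) {
    if (!v %in% names(out)) abort(sprintf("variable '%s' not in grid", v))
    out[[v]] <- out[[v]] + shift$add[[v]]
  }
  attr(out, "scenario") <- shift$label
  out
}

#' Configure the genetic architecture of the simulated SNP panel
#'
#' Adaptive loci have allele frequencies that are logistic functions of one
#' standardized environmental driver (`logit p = a + beta * z`); neutral loci
#' are logistic transforms of spatially autocorrelated Gaussian fields over
#' the population coordinates, giving tunable isolation by distance.
#'
#' @param n_neutral,n_adaptive locus counts.
#' @param beta adaptive effect size on the logit scale (scalar or length
#'   `n_adaptive`).
#' @param driver environmental variable name driving each adaptive locus
#'   (scalar or length `n_adaptive`).
#' @param neutral_sd standard deviation of the neutral logit field.
#' @param neutral_range autocorrelation length (degrees) of the neutral
#'   field; 0 gives independent population deviates (no spatial structure).
#' @param base_freq_range range of baseline allele frequencies, drawn
#'   uniformly per locus.
#' @param mean_snps_per_fragment average number of SNPs per GBS-like
#'   fragment (fragment sizes drawn uniformly on 1..(2*mean-1); >= 1).
#' @param missing_rate probability that any genotype call is missing (MCAR).
#' @return object of class `genetic_architecture`.
#' @export
genetic_architecture <- function(n_neutral = 450, n_adaptive = 50,
                                 beta = 2, driver = "eref",
                                 neutral_sd = 0.6, neutral_range = 3,
                                 base_freq_range = c(0.1, 0.9),
                                 mean_snps_per_fragment = 3,
                                 missing_rate = 0.05) {
  stop_if_not_scalar_prob(missing_rate, "missing_rate")
  if (any(!is.finite(beta))) abort("`beta` must be finite")
  if (mean_snps_per_fragment < 1) abort("`mean_snps_per_fragment` must be >= 1")
  structure(list(
    n_neutral = as.integer(n_neutral), n_adaptive = as.integer(n_adaptive),
    beta = rep_len(beta, max(n_adaptive, 1L)),
    driver = rep_len(driver, max(n_adaptive, 1L)),
    neutral_sd = neutral_sd, neutral_range = neutral_range,
    base_freq_range = base_freq_range,
    mean_snps_per_fragment = mean_snps_per_fragment,
    missing_rate = missing_rate
  ), class = "genetic_architecture")
}

#' Simulate true population allele frequencies
#'
#' @param arch a [genetic_architecture()].
#' @param env site environment table (`population` plus variable columns).
#' @param coords population coordinates (`population`, `lon`, `lat`);
#'   required when `arch$n_neutral > 0`.
#' @param seed integer seed.
#' @return an [allele_freq][new_allele_freq] object holding the true frequencies, with SNP
#'   metadata columns `snp_id`, `fragment`, `pos`, `type` ("neutral" or
#'   "adaptive") and `driver`.
#' @export
simulate_allele_frequencies <- function(arch, env, coords = NULL, seed = 1) {
  stopifnot(inherits(arch, "genetic_architecture"))
  n_pop <- nrow(env)
  n_snp <- arch$n_neutral + arch$n_adaptive
  if (n_snp < 1) abort("architecture has no loci")
  if (arch$n_adaptive > 0) {
    missing_drv <- setdiff(unique(arch$driver), names(env))
    if (length(missing_drv)) {
      abort(sprintf("driver variable(s) not in env table: %s",
                    paste(missing_drv, collapse = ", ")))
    }
  }

  set.seed(derive_seed(seed, 11L))
  type <- sample(c(rep("neutral", arch$n_neutral), rep("adaptive", arch$n_adaptive)))
  a <- stats::qlogis(runif(n_snp, arch$base_freq_range[1], arch$base_freq_range[2]))

  # every locus drifts on the same spatially autocorrelated field family;
  # adaptive loci add the environmental effect beta * z on the logit scale,
  # so beta = 0 makes the two classes exchangeable by construction
  if (arch$neutral_sd > 0 && is.null(coords)) {
    abort("`coords` required to simulate drift fields")
  }
  xy <- if (!is.null(coords)) cbind(coords$lon, coords$lat)
  p <- matrix(NA_real_, n_pop, n_snp)
  drv_of <- rep(NA_character_, n_snp)
  adaptive_seen <- 0L
  set.seed(derive_seed(seed, 12L))
  for (l in seq_len(n_snp)) {
    f <- if (arch$neutral_sd > 0) {
      gaussian_field(xy, arch$neutral_sd, arch$neutral_range)
    } else 0
    eta <- a[l] + f
    if (type[l] == "adaptive") {
      adaptive_seen <- adaptive_seen + 1L
      z <- as.numeric(scale(env[[arch$driver[adaptive_seen]]]))
      eta <- eta + arch$beta[adaptive_seen] * z
      drv_of[l] <- arch$driver[adaptive_seen]
    }
    p[, l] <- stats::plogis(eta)
  }

  set.seed(derive_seed(seed, 14L))
  sizes <- integer(0)
  while (sum(sizes) < n_snp) {
    sizes <- c(sizes, sample.int(max(2L * arch$mean_snps_per_fragment - 1L, 1L), 1L))
  }
  frag <- rep(seq_along(sizes), sizes)[seq_len(n_snp)]
  fragment <- sprintf("frag%05d", frag)
  pos <- unlist(lapply(split(seq_len(n_snp), frag), function(ix) {
    sort(sample.int(99L, length(ix)))
  }), use.names = FALSE)
  snps <- tibble(
    snp_id = sprintf("%s_%02d", fragment, pos),
    fragment = fragment, pos = as.integer(pos),
    type = type, driver = drv_of
  )
  dimnames(p) <- list(env$population, snps$snp_id)
  counts <- matrix(NA_real_, n_pop, n_snp, dimnames = dimnames(p))
  new_allele_freq(p, counts, snps, env$population)
}

#' Sample diploid genotypes from true allele frequencies
#'
#' Each individual's genotype is a binomial draw of two allele copies at its
#' population's true frequency; missing calls are inserted completely at
#' random at the architecture's `missing_rate`. Optionally writes a VCF
#' (GT-only), popmap TSV, coordinates CSV, environment CSV and grid CSVs.
#'
#' @param freqs true [allele_freq][new_allele_freq] object from
#'   [simulate_allele_frequencies()].
#' @param config a [landscape_config()] (supplies per-population sizes).
#' @param arch a [genetic_architecture()] (supplies the missing rate).
#' @param seed integer seed.
#' @param out_dir if non-`NULL`, directory in which `genotypes.vcf` and
#'   `popmap.tsv` are written.
#' @return a [genotype_matrix][new_genotype_matrix] object (invisibly also written to disk when
#'   `out_dir` is given; file paths are attached as attribute `"files"`).
#' @export
sample_genotypes <- function(freqs, config, arch, seed = 1, out_dir = NULL) {
  stopifnot(inherits(freqs, "allele_freq"))
  p <- freqs$freq
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("frequencies must lie in [0, 1]")
  n_per_pop <- rep_len(config$n_per_pop, nrow(p))
  pops <- rep(rownames(p), n_per_pop)
  sample_id <- sprintf("%s_i%02d", pops,
                       unlist(lapply(n_per_pop, seq_len), use.names = FALSE))
  n_ind <- length(sample_id)
  n_snp <- ncol(p)

  set.seed(derive_seed(seed, 21L))
  pop_index <- rep(seq_len(nrow(p)), n_per_pop)
  geno <- matrix(rbinom(n_ind * n_snp, 2L, p[pop_index, , drop = FALSE]),
                 n_ind, n_snp)
  if (arch$missing_rate > 0) {
    miss <- runif(n_ind * n_snp) < arch$missing_rate
    geno[miss] <- NA_integer_
  }
  set.seed(derive_seed(seed, 22L))
  nts <- c("A", "C", "G", "T")
  ref <- sample(nts, n_snp, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(nts, r), 1L), character(1))
  snps <- freqs$snps
  snps$ref <- ref
  snps$alt <- alt
  snps$n_alleles <- 2L
  dimnames(geno) <- list(sample_id, snps$snp_id)
  g <- new_genotype_matrix(geno, snps,
                           tibble(sample_id = sample_id, population = pops))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    vcf <- file.path(out_dir, "genotypes.vcf")
    popmap <- file.path(out_dir, "popmap.tsv")
    write_genotype_vcf(g, vcf)
    utils::write.table(g$samples, popmap, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    attr(g, "files") <- c(vcf = vcf, popmap = popmap)
  }
  g
}

#' Write a genotype matrix as a minimal GT-only VCF 4.2 file
#'
#' Fragment ids are written as the CHROM field (and echoed as `FRAG=` in
#' INFO) so that fragment-based thinning round-trips through the reader.
#'
#' @param g a [genotype_matrix][new_genotype_matrix].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_genotype_vcf <- function(g, path) {
  stopifnot(inherits(g, "genotype_matrix"))
  gt_code <- c("0/0", "0/1", "1/1")
  gt <- matrix("./.", nrow(g$geno), ncol(g$geno))
  ok <- !is.na(g$geno)
  gt[ok] <- gt_code[g$geno[ok] + 1L]
  body <- vapply(seq_len(ncol(g$geno)), function(j) {
    paste(c(g$snps$fragment[j], g$snps$pos[j], g$snps$snp_id[j],
            g$snps$ref[j], g$snps$alt[j], ".", "PASS",
            paste0("FRAG=", g$snps$fragment[j]), "GT", gt[, j]),
          collapse = "\t")
  }, character(1))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=landgf-synthetic-landscape",
    "##INFO=<ID=FRAG,Number=1,Type=String,Description=\"Fragment id\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", g$samples$sample_id), collapse = "\t")
  )
  writeLines(c(header, body), path)
  invisible(path)
}
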