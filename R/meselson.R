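#' Mutation-accumulation (Meselson effect) parameters
#'
#' Parameters for the back-of-envelope arithmetic asking how long an
#' asexual lineage needs to accumulate its observed heterozygosity by
#' mutation alone, starting from a fully homozygous genome: a per-site
#' per-generation mutation rate `mu`, a haploid genome size, a target
#' heterozygous SNP count, and two generations-per-year scenarios bounding
#' the calendar time (a maximal rate for a 2-day nematode lifecycle, and a
#' conservative low rate).
#'
#' @param mu Mutation rate per site per generation (default 3.4e-9, a
#'   nematode germline estimate).
#' @param genome_bp Haploid genome size in bp (default 61,400,000).
#' @param n_snps Target heterozygous SNP count (default 620,000).
#' @param gens_per_year_hi Fast scenario, generations per year
#'   (default 182.5 = 365/2, one generation per 2 days).
#' @param gens_per_year_lo Slow scenario (default 10).
#' @param rate_basis `"HAPLOID"` (default) or `"DIPLOID"`. The haploid
#'   basis reproduces the headline rate `mu * genome_bp`; the diploid
#'   option doubles it, since a heterozygous site can arise by mutation on
#'   either haplotype.
#' @return List of class `"meselson_params"`.
#' @export
meselson_params <- function(mu = 3.4e-9, genome_bp = 61400000,
                            n_snps = 620000, gens_per_year_hi = 182.5,
                            gens_per_year_lo = 10,
                            rate_basis = c("HAPLOID", "DIPLOID")) {
  rate_basis <- match.arg(rate_basis)
  stopifnot(mu > 0, genome_bp > 0, n_snps >= 0,
            gens_per_year_hi > 0, gens_per_year_lo > 0)
  structure(list(mu = mu, genome_bp = genome_bp, n_snps = n_snps,
                 gens_per_year_hi = gens_per_year_hi,
                 gens_per_year_lo = gens_per_year_lo,
                 rate_basis = rate_basis),
            class = "meselson_params")
}

#' Per-genome per-generation mutation rate
#'
#' `mu * genome_bp` (doubled on the diploid basis). Returned with a
#' 1-decimal headline figure alongside the exact value, since the headline
#' arithmetic traditionally chains the rounded rate.
#'
#' @param params A [meselson_params()].
#' @return List with `rate` (exact) and `rate_rounded` (1 decimal).
#' @examples
#' per_genome_rate(meselson_params())$rate_rounded  # 0.2
#' @export
per_genome_rate <- function(params = meselson_params()) {
  stopifnot(inherits(params, "meselson_params"))
  r <- params$mu * params$genome_bp
  if (params$rate_basis == "DIPLOID") r <- 2 * r
  list(rate = r, rate_rounded = round(r, 1))
}

#' Generations needed to accumulate a SNP count
#'
#' @param n_snps Heterozygous SNP count to reach.
#' @param rate Per-genome per-generation mutation rate.
#' @return `n_snps / rate`.
#' @examples
#' generations_to_snps(620000, 0.2)  # 3.1e6
#' @export
generations_to_snps <- function(n_snps, rate) {
  stopifnot(rate > 0, n_snps >= 0)
  n_snps / rate
}

#' Calendar years for a generation count
#'
#' @param generations Number of generations.
#' @param gens_per_year Generations per year.
#' @return List with `years` (exact) and `years_rounded` (2 significant
#'   figures, the headline form).
#' @examples
#' years_required(3.1e6, 182.5)$years_rounded  # 17000
#' years_required(3.1e6, 10)$years_rounded     # 310000
#' @export
years_required <- function(generations, gens_per_year) {
  stopifnot(gens_per_year > 0, generations >= 0)
  y <- generations / gens_per_year
  list(years = y, years_rounded = signif(y, 2))
}

#' Heterozygous SNP density as percent of the genome
#'
#' @param n_snps Heterozygous SNP count.
#' @param genome_bp Haploid genome size in bp.
#' @return List with `percent` (exact) and `percent_rounded`
#'   (two decimals).
#' @examples
#' snp_density(707190, 61400000)$percent_rounded  # 1.15
#' @export
snp_density <- function(n_snps, genome_bp) {
  stopifnot(genome_bp > 0, n_snps >= 0)
  p <- 100 * n_snps / genome_bp
  list(percent = p, percent_rounded = round(p, 2))
}

#' Generations elapsed during a culture period
#'
#' Converts culture days to generation counts given a lifecycle length,
#' e.g. 11 days at a 3-day lifecycle is 3.7 generations; 7 days at a 48-h
#' lifecycle is 3.5.
#'
#' @param days Culture duration in days.
#' @param lifecycle_days Lifecycle length in days.
#' @return `days / lifecycle_days`, rounded to one decimal.
#' @examples
#' generations_elapsed(11, 3)  # 3.7
#' generations_elapsed(15, 3)  # 5
#' @export
generations_elapsed <- function(days, lifecycle_days) {
  stopifnot(lifecycle_days > 0, days >= 0)
  round(days / lifecycle_days, 1)
}

#' Stochastic mutation-accumulation trajectory
#'
#' Simulates the cumulative heterozygous SNP count of an asexual lineage
#' under an infinite-sites model: each generation adds
#' Poisson(per-genome rate) new mutations; there is no back-mutation,
#' selection, or drift loss, matching the deterministic arithmetic this
#' trajectory fluctuates around.
#'
#' @param params A [meselson_params()] (supplies the rate via
#'   [per_genome_rate()]).
#' @param generations Number of generations to simulate (>= 0).
#' @param seed Optional integer seed for reproducibility.
#' @return Numeric vector of length `generations` with the cumulative SNP
#'   count after each generation (length 0 for `generations = 0`).
#' @export
simulate_accumulation <- function(params = meselson_params(), generations,
                                  seed = NULL) {
  stopifnot(generations >= 0)
  if (!is.null(seed)) set.seed(seed)
  if (generations == 0) return(numeric(0))
  rate <- per_genome_rate(params)$rate
  cumsum(stats::rpois(generations, rate))
}

#' Full Meselson-effect accumulation report
#'
#' Chains the arithmetic end to end: per-genome rate, generations to reach
#' the SNP target, and calendar years under the fast and slow
#' generations-per-year scenarios. The headline chain uses the 1-decimal
#' rate and 2-significant-figure years; the unrounded chain is reported
#' alongside.
#'
#' @param params A [meselson_params()].
#' @return List of class `"meselson_report"` with components `rate`,
#'   `rate_rounded`, `generations` / `generations_unrounded`,
#'   `years_hi` / `years_lo` (headline, from the rounded rate),
#'   `years_hi_unrounded` / `years_lo_unrounded`, and `snp_density_pct`.
#' @examples
#' meselson_report()
#' @export
meselson_report <- function(params = meselson_params()) {
  pg <- per_genome_rate(params)
  gen_head <- generations_to_snps(params$n_snps, pg$rate_rounded)
  gen_exact <- generations_to_snps(params$n_snps, pg$rate)
  structure(list(
    rate = pg$rate,
    rate_rounded = pg$rate_rounded,
    generations = gen_head,
    generations_unrounded = gen_exact,
    years_hi = years_required(gen_head, params$gens_per_year_hi)$years_rounded,
    years_lo = years_required(gen_head, params$gens_per_year_lo)$years_rounded,
    years_hi_unrounded = years_required(gen_exact,
                                        params$gens_per_year_hi)$years,
    years_lo_unrounded = years_required(gen_exact,
                                        params$gens_per_year_lo)$years,
    snp_density_pct = snp_density(params$n_snps, params$genome_bp)$percent_rounded,
    params = params
  ), class = "meselson_report")
}

#' @exportS3Method base::print
print.meselson_report <- function(x, ...) {
  p <- x$params
  cat("Mutation-accumulation scenario (infinite-sites)\n")
  cat(sprintf("  mu = %.3g /site/gen over %.3g bp (%s basis)\n",
              p$mu, p$genome_bp, p$rate_basis))
  cat(sprintf("  per-genome rate: %.1f (exact %.5f)\n",
              x$rate_rounded, x$rate))
  cat(sprintf("  generations to %s SNPs: %.3g (exact %.0f)\n",
              format(p$n_snps, big.mark = ","), x$generations,
              x$generations_unrounded))
  cat(sprintf("  years: %s (at %.1f gen/yr) to %s (at %.1f gen/yr)\n",
              format(x$years_hi, big.mark = ","), p$gens_per_year_hi,
              format(x$years_lo, big.mark = ","), p$gens_per_year_lo))
  cat(sprintf("  SNP density: %.2f%% of the genome\n", x$snp_density_pct))
  invisible(x)
}
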