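test_that("marker counts follow the Bernoulli density and are reproducible", {
  cfg <- sim_config(contigs = data.frame(name = "c1", length = 1e6),
                    het_density = 0.01, seed = 13)
  g <- make_genome(cfg)
  n <- nrow(g$markers)
  sigma <- sqrt(1e6 * 0.01 * 0.99)
  expect_lt(abs(n - 10000), 5 * sigma)
  expect_true(all(diff(g$markers$pos) > 0))
  expect_true(all(g$markers$ref != g$markers$alt))
  expect_identical(make_genome(cfg)$markers, g$markers)
})

test_that("planted tracts shape the founder genotype", {
  planted <- data.frame(contig = "c1", start = c(300000, 600000),
                        end = c(500000, 700000),
                        state = c("HOM_REF", "HOM_ALT"))
  cfg <- sim_config(contigs = data.frame(name = "c1", length = 1e6),
                    het_density = 0.01, planted_tracts = planted, seed = 14)
  g <- make_genome(cfg)
  p0 <- g$markers$pos - 1
  expect_equal(sum(p0 >= 300000 & p0 < 500000), 0L)
  in_alt <- p0 >= 600000 & p0 < 700000
  expect_true(all(g$markers$founder_state[in_alt] == "HOM_ALT"))
  expect_true(all(g$markers$founder_state[!in_alt] == "HET"))

  bad <- rbind(planted,
               data.frame(contig = "c1", start = 450000, end = 650000,
                          state = "HOM_REF"))
  expect_error(sim_config(contigs = cfg$contigs, planted_tracts = bad),
               "overlap")
})

test_that("meiosis produces the modeled number of haplotype switches", {
  cfg <- sim_config(contigs = data.frame(name = "c1", length = 1e6),
                    het_density = 0.005, seed = 15)
  f1 <- founder_phase(make_genome(cfg))
  # obligate single crossover on a fully heterozygous contig: the gamete
  # is reference-strain on one side of one switch point, alternative on
  # the other (hap1 carries ref = 0, hap2 carries alt = 1)
  for (s in 1:20) {
    gam <- meiosis(f1, cfg, seed = 100 + s)
    expect_equal(sum(diff(gam) != 0), 1L)
    expect_length(attr(gam, "breakpoints")$c1, 1L)
  }
  # lambda = 0 Poisson model: a whole parental haplotype, unswitched
  cfg0 <- sim_config(contigs = cfg$contigs, crossover_model = "POISSON",
                     lambda = 0)
  gam0 <- meiosis(f1, cfg0, seed = 3)
  expect_true(all(gam0 == gam0[1]))

  # no segregating variation, no visible recombination
  hom <- f1
  hom$hap1 <- hom$hap2 <- rep(c(0L, 1L), length.out = nrow(hom))
  expect_equal(as.integer(meiosis(hom, cfg, seed = 4)), hom$hap1)
})

test_that("F2 genotypes are Mendelian and block boundaries come from gametes", {
  cfg <- sim_config(contigs = data.frame(name = "c1", length = 2e5),
                    het_density = 0.002, seed = 16)
  f1 <- founder_phase(make_genome(cfg))
  probe <- c(1L, nrow(f1) %/% 2L, nrow(f1))
  counts <- matrix(0L, 3, 3, dimnames = list(NULL, c("0", "1", "2")))
  set.seed(17)
  for (r in 1:500) {
    f2 <- make_f2(f1, cfg)
    dose <- f2$hap1 + f2$hap2
    for (k in 1:3) {
      counts[k, dose[probe[k]] + 1L] <- counts[k, dose[probe[k]] + 1L] + 1L
    }
    if (r <= 20) {
      # genotype changes only at gamete breakpoints
      chg <- which(diff(dose) != 0)
      bp <- attr(f2, "breakpoints")$c1
      for (i in chg) {
        expect_true(any(bp > f2$pos[i] - 1 & bp < f2$pos[i + 1]))
      }
    }
  }
  # 1/4 : 1/2 : 1/4 at each probed marker, within 5 sigma of binomial
  for (k in 1:3) {
    expect_lt(abs(counts[k, "0"] - 125), 5 * sqrt(500 * 0.25 * 0.75))
    expect_lt(abs(counts[k, "1"] - 250), 5 * sqrt(500 * 0.5 * 0.5))
    expect_lt(abs(counts[k, "2"] - 125), 5 * sqrt(500 * 0.25 * 0.75))
  }
})

test_that("clonal propagation preserves founder frequencies exactly", {
  planted <- data.frame(contig = "c1", start = 0, end = 50000,
                        state = "HOM_ALT")
  cfg <- sim_config(contigs = data.frame(name = "c1", length = 2e5),
                    het_density = 0.005, planted_tracts = planted,
                    propagation = "CLONAL", seed = 18)
  g <- make_genome(cfg)
  pop <- propagate(founder_phase(g), cfg)
  het <- g$markers$founder_state == "HET"
  expect_true(all(pop$markers$freq[het] == 0.5))
  expect_true(all(pop$markers$freq[!het] == 1))
})

test_that("selfing halves heterozygosity per round, conserving frequency", {
  cfg <- sim_config(contigs = data.frame(name = "c1", length = 2e5),
                    het_density = 0.005, propagation = "SELFING",
                    n_generations = 3.7, n_individuals = 200, seed = 19)
  f1 <- founder_phase(make_genome(cfg))
  n_mark <- nrow(f1)
  pop <- propagate(f1, cfg, seed = 20)
  expect_equal(pop$rounds, 3L)  # 3.7 generations = 3 full selfing rounds
  # per-individual het fraction: (1/2)^3, within 5 sigma over all
  # marker x individual Bernoulli draws
  p <- 0.125
  expect_lt(abs(pop$het_fraction - p),
            5 * sqrt(p * (1 - p) / (n_mark * 200)))
  # allele frequency conserved at 0.5 in expectation
  expect_lt(abs(mean(pop$markers$freq) - 0.5), 5 * 0.47 / sqrt(n_mark * 200))
  # a homozygous founder marker never segregates
  g2 <- make_genome(sim_config(contigs = cfg$contigs, het_density = 0.005,
                               planted_tracts = data.frame(
                                 contig = "c1", start = 0, end = 2e5,
                                 state = "HOM_ALT"), seed = 21))
  pop2 <- propagate(founder_phase(g2), cfg)
  expect_true(all(pop2$markers$freq == 1))
})

test_that("VCF emission follows the caller-silence convention", {
  cfg <- sim_config(contigs = data.frame(name = "c1", length = 5e4),
                    het_density = 0.01, error_rate = 0, seed = 22)
  g <- make_genome(cfg)
  pop <- propagate(founder_phase(g), cfg)

  # f = 0 with no sequencing error: never emitted
  pop0 <- pop
  pop0$markers$freq <- 0
  expect_equal(nrow(emit_vcf(pop0, g, cfg, seed = 1)$sites), 0L)

  # f = 1 with no error: emitted at AAF exactly 1 wherever depth >= 1
  pop1 <- pop
  pop1$markers$freq <- 1
  em1 <- emit_vcf(pop1, g, cfg, seed = 2)
  expect_true(all(em1$sites$aaf == 1))
  expect_equal(nrow(em1$sites), sum(em1$truth$depth >= 1))

  # het markers drop out only when no alternative read was sampled
  cfg2 <- sim_config(contigs = cfg$contigs, het_density = 0.01,
                     error_rate = 0.01, mean_depth = 25, seed = 23)
  em <- emit_vcf(pop, g, cfg2, seed = 3)
  expect_equal(nrow(em$sites),
               sum(em$truth$depth >= 1 & em$truth$alt_reads >= 1))
  expect_gt(nrow(em$sites) / nrow(g$markers), 0.99)

  # determinism under a fixed seed
  expect_identical(emit_vcf(pop, g, cfg2, seed = 3)$sites, em$sites)
})

test_that("depth emission doubles collapsed tracts and matches Poisson moments", {
  cfg <- sim_config(contigs = data.frame(name = "c1", length = 2e5),
                    mean_depth = 20, seed = 24)
  g <- make_genome(cfg)
  d <- emit_depth(g, cfg, seed = 25)
  expect_equal(nrow(d), 2e5)
  expect_lt(abs(mean(d$depth) - 20), 5 * sqrt(20 / 2e5))
  expect_identical(emit_depth(g, cfg, seed = 25), d)

  planted <- data.frame(contig = "c1", start = 50000, end = 100000,
                        state = "HOM_REF", collapsed = TRUE)
  cfgc <- sim_config(contigs = cfg$contigs, planted_tracts = planted,
                     mean_depth = 20, seed = 26)
  gc <- make_genome(cfgc)
  dc <- emit_depth(gc, cfgc, seed = 27)
  inside <- dc$pos > 50000 & dc$pos <= 100000
  expect_lt(abs(mean(dc$depth[inside]) / mean(dc$depth[!inside]) - 2), 0.1)
})
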