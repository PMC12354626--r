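ct <- function(name = "c1", length = 500000) {
  data.frame(name = name, length = length)
}

test_that("SNP deserts are called between, before, and after calls", {
  # dense heterozygosity: max gap 1 kb, nothing to call
  dense <- make_sites(seq(1000, 200000, by = 1000))
  expect_equal(nrow(detect_hom_ref_tracts(dense, ct(length = 200000))), 0L)

  # one central desert: SNPs only at <=150,000 and >=400,001
  sites <- make_sites(c(seq(500, 150000, by = 500),
                        seq(400001, 499501, by = 500)))
  tr <- detect_hom_ref_tracts(sites, ct())
  expect_equal(tr$start, 150000)
  expect_equal(tr$end, 400000)
  expect_equal(tr$state, "HOM_REF")
  expect_equal(tr$n_sites, 0L)
  # agrees with the per-base brute-force oracle
  bf <- brute_force_deserts(sites$pos, 500000, 100000)
  expect_equal(tr[, c("start", "end")], bf)

  # empty contig at least as long as the threshold: whole-contig tract
  none <- make_sites(integer(0))
  tr2 <- detect_hom_ref_tracts(none, ct(length = 150000))
  expect_equal(cbind(tr2$start, tr2$end), cbind(0L, 150000L))
  # shorter than the threshold: nothing can qualify
  expect_equal(nrow(detect_hom_ref_tracts(none, ct(length = 90000))), 0L)
})

test_that("desert detection validates its input", {
  s <- make_sites(c(200, 100))
  expect_error(detect_hom_ref_tracts(s, ct()), "sorted")
  s2 <- make_sites(100, contig = "other")
  expect_error(detect_hom_ref_tracts(s2, ct()), "off-contig")
})

test_that("fixed-allele runs become HOM_ALT tracts; het sites break runs", {
  run <- make_sites(seq(1000, by = 600, length.out = 200), aaf = 1)
  tr <- detect_hom_alt_tracts(run, ct())
  expect_equal(nrow(tr), 1L)
  expect_equal(tr$n_sites, 200L)
  expect_equal(tr$start, 999)
  expect_equal(tr$end, 1000 + 199 * 600)
  expect_gte(tr$mean_aaf, 0.9)

  # a single heterozygous site at the midpoint splits the run; each half
  # spans ~60 kb, below the 100 kb minimum
  broken <- run
  broken$aaf[100] <- 0.5
  expect_equal(nrow(detect_hom_alt_tracts(broken, ct())), 0L)

  # an ambiguous site (a stray reference read at a fixed position) does
  # not break the run and does not count toward it
  smudged <- run
  smudged$aaf[100] <- 0.85
  tr3 <- detect_hom_alt_tracts(smudged, ct())
  expect_equal(tr3$n_sites, 199L)
  expect_equal(nrow(tr3), 1L)

  # too few supporting sites never qualifies, whatever the span
  sparse <- make_sites(seq(1, 490000, length.out = 9), aaf = 1)
  expect_equal(nrow(detect_hom_alt_tracts(sparse, ct())), 0L)
})

test_that("tract summaries report totals and genome fractions", {
  tr <- data.frame(contig = "c1", start = c(0, 300000),
                   end = c(150000, 550000),
                   state = c("HOM_REF", "HOM_ALT"),
                   n_sites = c(0L, 100L), mean_aaf = c(NA, 0.99))
  s <- summarize_tracts(tr, 1e6)
  expect_equal(s$total_bp, 400000)
  expect_equal(s$fraction, 0.4)
  expect_equal(sort(s$by_state$total_bp), c(150000, 250000))
  expect_equal(summarize_tracts(tr[0, ], 1e6)$fraction, 0)
  expect_error(summarize_tracts(tr, 0), "positive")
})

test_that("state_track tiles the contig exactly and rejects overlaps", {
  tr <- data.frame(contig = "c1", start = 150000, end = 400000,
                   state = "HOM_REF", n_sites = 0L, mean_aaf = NA)
  seg <- state_track(tr, ct())
  expect_equal(seg$state, c("HET", "HOM_REF", "HET"))
  expect_equal(seg$start, c(0L, 150000L, 400000L))
  expect_equal(sum(seg$end - seg$start), 500000)
  expect_equal(seg$start[-1], seg$end[-3])

  expect_equal(state_track(tr[0, ], ct())$state, "HET")

  bad <- rbind(tr, within(tr, {start <- 300000; end <- 450000}))
  expect_error(state_track(bad, ct()), "overlap")
})

test_that("state_track recovers planted tracts of both classes", {
  planted <- data.frame(contig = "c1",
                        start = c(100000, 400000, 700000),
                        end = c(250000, 520000, 950000),
                        state = c("HOM_REF", "HOM_ALT", "HOM_REF"),
                        stringsAsFactors = FALSE)
  cfg <- sim_config(contigs = data.frame(name = "c1", length = 1e6),
                    het_density = 0.01, planted_tracts = planted,
                    seed = 99)
  genome <- make_genome(cfg)
  pop <- propagate(founder_phase(genome), cfg)
  sites <- emit_vcf(pop, genome, cfg)$sites
  contig <- ct(length = 1e6)
  tracts <- rbind(detect_hom_ref_tracts(sites, contig),
                  detect_hom_alt_tracts(sites, contig))
  seg <- state_track(tracts, contig)
  expect_equal(sum(seg$end - seg$start), 1e6)
  expect_equal(nrow(seg), 7L)  # HET / plant / HET / plant / HET / plant / HET
  got <- seg[seg$state != "HET", ]
  expect_equal(got$state, planted$state)
  # boundaries within one local inter-marker spacing of the plant
  expect_lt(max(abs(got$start - planted$start),
                abs(got$end - planted$end)), 2500)
})

test_that("desert detector matches the brute-force scan on random contigs", {
  set.seed(11)
  for (i in 1:10) {
    L <- 1000000L
    pos <- sort(sample.int(L, rpois(1, 1200)))
    # carve two random gaps so some instances contain real deserts
    for (g in 1:2) {
      a <- sample.int(L - 200000L, 1)
      pos <- pos[pos <= a | pos > a + sample(c(50000, 150000, 250000), 1)]
    }
    got <- detect_hom_ref_tracts(make_sites(pos, contig = "cX"),
                                 ct("cX", L))
    bf <- brute_force_deserts(pos, L, 100000)
    expect_equal(got[, c("start", "end")],
                 bf, ignore_attr = TRUE)
  }
})

test_that("no spurious tracts arise from sampling noise at realistic density", {
  # SNP-free 100 kb gaps are essentially impossible at 1 SNP / 500 bp;
  # across 100 seeded replicates no tract of either class may appear
  contig <- ct(length = 1e6)
  for (s in 1:100) {
    set.seed(s)
    pos <- sort(sample.int(1e6, 2000))
    aaf <- rbinom(length(pos), 25, 0.5) / 25
    sites <- make_sites(pos, aaf = aaf)
    expect_equal(nrow(detect_hom_ref_tracts(sites, contig)), 0L)
    expect_equal(nrow(detect_hom_alt_tracts(sites, contig)), 0L)
  }
})

test_that("tracts are exported as 0-based half-open BED", {
  tr <- data.frame(contig = "c1", start = 0, end = 150000,
                   state = "HOM_REF", n_sites = 0L, mean_aaf = NA)
  p <- tempfile(fileext = ".bed")
  tracts_to_bed(tr, p)
  expect_equal(readLines(p), "c1\t0\t150000\tHOM_REF\t0")
})
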