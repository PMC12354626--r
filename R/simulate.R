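#' Simulation configuration
#'
#' Parameters for generating synthetic diploid genomes, cross designs,
#' population propagation, and pooled-sequencing noise. Defaults emulate a
#' parthenogenetic nematode population: ~1.15% heterozygous SNP density,
#' 25x mean coverage with Poisson depth and binomial allele sampling, a 1%
#' per-read miscall rate, and populations grown from a single founder for
#' 3--5 generations before harvest.
#'
#' @param contigs data.frame with columns `name`, `length` (bp).
#' @param het_density Heterozygous sites per bp (default 0.0115).
#' @param planted_tracts Optional data.frame of ground-truth homozygous
#'   tracts to embed: columns `contig`, `start`, `end` (0-based half-open),
#'   `state` (`"HOM_REF"` or `"HOM_ALT"`), `collapsed` (logical; doubled
#'   read depth, emulating two haplotypes assembled as one contig).
#'   HOM_REF tracts contain no markers; markers inside HOM_ALT tracts are
#'   homozygous-alternative in the founder.
#' @param mean_depth Mean sequencing depth in reads (default 25).
#' @param error_rate Per-read miscall probability (default 0.01);
#'   symmetric, substitutions only.
#' @param propagation `"CLONAL"` (parthenogenetic: every descendant equals
#'   the founder) or `"SELFING"` (self-fertilization with Mendelian
#'   segregation each round).
#' @param n_generations Generations of growth from the founder
#'   (default 3.5). Selfing performs `floor(n_generations)` full rounds;
#'   the fraction describes culture time, not a partial meiosis.
#' @param n_individuals Population size pooled for sequencing
#'   (default 200).
#' @param crossover_model `"OBLIGATE_ONE"` (exactly one crossover per
#'   contig per meiosis, the typical nematode pattern) or `"POISSON"`
#'   (Poisson(`lambda`) crossovers, no interference).
#' @param lambda Mean crossovers per contig for the Poisson model
#'   (default 1).
#' @param qual_model `"constant"` (every record gets `qual_value`) or
#'   `"binomial"` (caller-like, depth-scaled: the Phred-scaled binomial
#'   tail probability of seeing that many alternative reads from
#'   sequencing error alone, so error-only records score low and true
#'   variants score high -- use this to exercise the quality filter).
#' @param qual_value QUAL for the constant model (default 200).
#' @param emit_zero_aaf Also emit records with zero alternative reads
#'   (default `FALSE`: a caller is silent at homozygous-reference sites,
#'   which is what makes reference-LOH appear as SNP deserts).
#' @param seed Optional integer seed stored with the config.
#' @return List of class `"sim_config"`.
#' @export
sim_config <- function(contigs = data.frame(name = c("c1", "c2"),
                                            length = c(2e6, 2e6)),
                       het_density = 0.0115, planted_tracts = NULL,
                       mean_depth = 25, error_rate = 0.01,
                       propagation = c("CLONAL", "SELFING"),
                       n_generations = 3.5, n_individuals = 200,
                       crossover_model = c("OBLIGATE_ONE", "POISSON"),
                       lambda = 1,
                       qual_model = c("constant", "binomial"),
                       qual_value = 200, emit_zero_aaf = FALSE,
                       seed = NULL) {
  propagation <- match.arg(propagation)
  crossover_model <- match.arg(crossover_model)
  qual_model <- match.arg(qual_model)
  stopifnot(all(c("name", "length") %in% names(contigs)),
            all(contigs$length > 0), !anyDuplicated(contigs$name),
            het_density > 0, het_density < 1,
            mean_depth > 0, error_rate >= 0, error_rate < 0.5,
            n_generations >= 0, n_individuals >= 1, lambda >= 0)
  if (!is.null(planted_tracts)) {
    stopifnot(all(c("contig", "start", "end", "state") %in%
                    names(planted_tracts)),
              all(planted_tracts$end > planted_tracts$start),
              all(planted_tracts$state %in% c("HOM_REF", "HOM_ALT")))
    if (is.null(planted_tracts$collapsed)) planted_tracts$collapsed <- FALSE
    by_ct <- split(planted_tracts, planted_tracts$contig)
    for (tr in by_ct) {
      tr <- tr[order(tr$start), , drop = FALSE]
      if (nrow(tr) > 1L && any(tr$start[-1L] < tr$end[-nrow(tr)])) {
        stop("overlapping planted tracts on ", tr$contig[1L])
      }
    }
  }
  structure(list(contigs = contigs, het_density = het_density,
                 planted_tracts = planted_tracts, mean_depth = mean_depth,
                 error_rate = error_rate, propagation = propagation,
                 n_generations = n_generations,
                 n_individuals = n_individuals,
                 crossover_model = crossover_model, lambda = lambda,
                 qual_model = qual_model, qual_value = qual_value,
                 emit_zero_aaf = emit_zero_aaf, seed = seed),
            class = "sim_config")
}

.in_intervals <- function(contig, pos0, intervals) {
  hit <- rep(FALSE, length(pos0))
  for (i in seq_len(nrow(intervals))) {
    hit <- hit | (contig == intervals$contig[i] &
                    pos0 >= intervals$start[i] & pos0 < intervals$end[i])
  }
  hit
}

#' Generate a synthetic diploid genome
#'
#' Draws heterozygous marker positions per contig as a Bernoulli
#' (`het_density`) process, assigns each marker a random pair of distinct
#' alleles, and enforces any planted tracts: HOM_REF tracts are scrubbed of
#' markers (there is nothing to call there), markers inside HOM_ALT tracts
#' are homozygous-alternative in the founder, all other markers are
#' heterozygous.
#'
#' @param cfg A [sim_config()].
#' @param seed Optional seed (defaults to `cfg$seed`).
#' @return List of class `"sim_genome"`: `contigs`, `markers` (data.frame
#'   `contig`, `pos` (1-based), `ref`, `alt`, `founder_state`),
#'   `planted_tracts`, `cfg`, `seed`.
#' @export
make_genome <- function(cfg = sim_config(), seed = cfg$seed) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  bases <- c("A", "C", "G", "T")
  per_ct <- lapply(seq_len(nrow(cfg$contigs)), function(i) {
    nm <- cfg$contigs$name[i]
    L <- as.integer(cfg$contigs$length[i])
    n <- stats::rbinom(1L, L, cfg$het_density)
    pos <- sort(sample.int(L, n))
    data.frame(contig = nm, pos = pos, stringsAsFactors = FALSE)
  })
  mk <- do.call(rbind, per_ct)
  mk$ref <- sample(bases, nrow(mk), replace = TRUE)
  mk$alt <- bases[(match(mk$ref, bases) - 1L +
                     sample(3L, nrow(mk), replace = TRUE)) %% 4L + 1L]
  mk$founder_state <- "HET"
  pt <- cfg$planted_tracts
  if (!is.null(pt) && nrow(pt)) {
    hr <- pt[pt$state == "HOM_REF", , drop = FALSE]
    if (nrow(hr)) mk <- mk[!.in_intervals(mk$contig, mk$pos - 1L, hr), ,
                           drop = FALSE]
    ha <- pt[pt$state == "HOM_ALT", , drop = FALSE]
    if (nrow(ha)) mk$founder_state[.in_intervals(mk$contig, mk$pos - 1L,
                                                 ha)] <- "HOM_ALT"
  }
  rownames(mk) <- NULL
  structure(list(contigs = cfg$contigs, markers = mk,
                 planted_tracts = pt, cfg = cfg, seed = seed),
            class = "sim_genome")
}

#' Founder phased genotype
#'
#' Expands the founder marker states into a phased diploid genotype:
#' heterozygous markers carry the reference allele on haplotype 1 and the
#' alternative on haplotype 2; homozygous markers carry the same allele on
#' both.
#'
#' @param genome A [make_genome()] result.
#' @return data.frame of class `"sim_phase"`: marker columns plus `hap1`,
#'   `hap2` (0 = reference allele, 1 = alternative allele).
#' @export
founder_phase <- function(genome) {
  mk <- genome$markers
  mk$hap1 <- ifelse(mk$founder_state == "HOM_ALT", 1L, 0L)
  mk$hap2 <- ifelse(mk$founder_state == "HOM_REF", 0L, 1L)
  class(mk) <- c("sim_phase", class(mk))
  attr(mk, "contigs") <- genome$contigs
  mk
}

#' Simulate one meiosis (gamete formation)
#'
#' Each contig is one linkage unit. A crossover count is drawn from the
#' model (`OBLIGATE_ONE`: exactly one; `POISSON`: Poisson(`lambda`), no
#' interference), breakpoint positions are uniform along the contig, the
#' starting haplotype is a fair coin, and the gamete alternates between the
#' two parental haplotypes at each breakpoint.
#'
#' @param phase A phased genotype from [founder_phase()] or [make_f2()].
#' @param cfg A [sim_config()] (crossover model and lambda).
#' @param seed Optional seed.
#' @return Integer vector of gamete alleles (0/1) aligned with the rows of
#'   `phase`, with attribute `breakpoints`: a named list of numeric
#'   breakpoint positions (0-based) per contig.
#' @export
meiosis <- function(phase, cfg = sim_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  contigs <- attr(phase, "contigs")
  allele <- integer(nrow(phase))
  bps <- list()
  for (i in seq_len(nrow(contigs))) {
    nm <- contigs$name[i]
    L <- contigs$length[i]
    idx <- which(phase$contig == nm)
    k <- switch(cfg$crossover_model,
                OBLIGATE_ONE = 1L,
                POISSON = stats::rpois(1L, cfg$lambda))
    bp <- sort(stats::runif(k, 0, L))
    start_hap <- sample(2L, 1L)
    if (length(idx)) {
      n_cross <- findInterval(phase$pos[idx] - 0.5, bp)
      hap <- (start_hap - 1L + n_cross) %% 2L + 1L
      allele[idx] <- ifelse(hap == 1L, phase$hap1[idx], phase$hap2[idx])
    }
    bps[[nm]] <- bp
  }
  structure(allele, breakpoints = bps)
}

#' Generate an F2 genotype by selfing a heterozygous F1
#'
#' Fuses two independent gametes of `f1` into one F2 individual. On a fully
#' heterozygous F1, the result is a mosaic of contiguous
#' homozygous-reference, heterozygous, and homozygous-alternative blocks
#' whose boundaries are the union of the two gametes' crossover points.
#'
#' @param f1 Phased F1 genotype ([founder_phase()] of a fully heterozygous
#'   genome).
#' @param cfg A [sim_config()].
#' @param seed Optional seed.
#' @return A `"sim_phase"` data.frame with new `hap1`/`hap2`, plus
#'   attributes `breakpoints` (union per contig) and `true_blocks`
#'   (data.frame `contig`, `start`, `end` (0-based half-open), `state` --
#'   the ground-truth genotype blocks; only meaningful when `f1` is fully
#'   heterozygous).
#' @export
make_f2 <- function(f1, cfg = sim_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  g1 <- meiosis(f1, cfg)
  g2 <- meiosis(f1, cfg)
  f2 <- f1
  f2$hap1 <- as.integer(g1)
  f2$hap2 <- as.integer(g2)
  f2$founder_state <- NULL
  contigs <- attr(f1, "contigs")
  bp1 <- attr(g1, "breakpoints"); bp2 <- attr(g2, "breakpoints")
  blocks <- list()
  for (i in seq_len(nrow(contigs))) {
    nm <- contigs$name[i]
    L <- contigs$length[i]
    cuts <- sort(unique(c(0, bp1[[nm]], bp2[[nm]], L)))
    blocks[[nm]] <- data.frame(contig = nm,
                               start = utils::head(cuts, -1L),
                               end = utils::tail(cuts, -1L),
                               stringsAsFactors = FALSE)
  }
  blocks <- do.call(rbind, blocks)
  # state per block from the nearest marker inside it (fully-het F1 =>
  # dosage constant per block); blocks without markers get NA state
  dosage <- f2$hap1 + f2$hap2
  st <- rep(NA_character_, nrow(blocks))
  for (j in seq_len(nrow(blocks))) {
    in_b <- f2$contig == blocks$contig[j] &
      f2$pos - 1L >= blocks$start[j] & f2$pos - 1L < blocks$end[j]
    if (any(in_b)) {
      st[j] <- c("HOM_REF", "HET", "HOM_ALT")[dosage[in_b][1L] + 1L]
    }
  }
  blocks$state <- st
  attr(f2, "breakpoints") <- Map(function(a, b) sort(c(a, b)), bp1, bp2)
  attr(f2, "true_blocks") <- blocks
  rownames(blocks) <- NULL
  f2
}

#' Force a loss-of-heterozygosity event into a phased genotype
#'
#' Sets every marker in the interval homozygous for the reference
#' (`to = "REF"`) or alternative (`to = "ALT"`) allele, emulating a gene
#' conversion or segregation-error LOH event in a descendant.
#'
#' @param phase A `"sim_phase"` data.frame.
#' @param contig Contig name.
#' @param start,end 0-based half-open interval (bp).
#' @param to `"REF"` or `"ALT"`.
#' @return The modified phase.
#' @export
apply_loh_event <- function(phase, contig, start, end,
                            to = c("REF", "ALT")) {
  to <- match.arg(to)
  a <- if (to == "ALT") 1L else 0L
  hit <- phase$contig == contig & phase$pos - 1L >= start &
    phase$pos - 1L < end
  phase$hap1[hit] <- a
  phase$hap2[hit] <- a
  phase
}

#' Propagate a founder into a sequenced population
#'
#' Turns a single founder genotype into the per-marker alternative allele
#' frequency of the pooled population that grew from it.
#' \describe{
#'   \item{CLONAL}{parthenogenesis: every individual equals the founder,
#'     so the allele frequency is exactly founder dosage / 2 -- a
#'     heterozygous founder yields AAF 0.5 at every heterozygous marker no
#'     matter how long the population grows.}
#'   \item{SELFING}{individual-based simulation: `n_individuals` copies of
#'     the founder undergo `floor(n_generations)` rounds of
#'     self-fertilization with independent Mendelian segregation per marker
#'     (sufficient for frequency behaviour; linkage is simulated by
#'     [meiosis()] where block structure matters). Expected allele
#'     frequency stays at the founder value while per-individual
#'     heterozygosity halves each round.}
#' }
#'
#' @param phase Founder phased genotype (`"sim_phase"`).
#' @param cfg A [sim_config()] (propagation mode, generations, population
#'   size).
#' @param seed Optional seed.
#' @return List of class `"sim_population"`: `markers` (marker columns plus
#'   `freq`, the population alternative-allele frequency), `mode`,
#'   `rounds` (full selfing rounds performed), `n_generations` (as
#'   requested, possibly fractional), `het_fraction` (mean per-individual
#'   heterozygous fraction in the final population).
#' @export
propagate <- function(phase, cfg = sim_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  dosage <- phase$hap1 + phase$hap2
  markers <- phase[, c("contig", "pos", "ref", "alt")]
  if (cfg$propagation == "CLONAL") {
    out <- list(markers = cbind(markers, freq = dosage / 2),
                mode = "CLONAL", rounds = 0L,
                n_generations = cfg$n_generations,
                het_fraction = mean(dosage == 1L))
    class(out) <- "sim_population"
    return(out)
  }
  g <- floor(cfg$n_generations)
  M <- matrix(rep(as.integer(dosage), cfg$n_individuals),
              nrow = length(dosage))
  for (r in seq_len(g)) {
    het <- which(M == 1L)
    if (length(het)) {
      M[het] <- stats::rbinom(length(het), 1L, 0.5) +
        stats::rbinom(length(het), 1L, 0.5)
    }
  }
  out <- list(markers = cbind(markers, freq = rowMeans(M) / 2),
              mode = "SELFING", rounds = g,
              n_generations = cfg$n_generations,
              het_fraction = mean(colMeans(M == 1L)))
  class(out) <- "sim_population"
  out
}

#' Emit a population as a VCF with sequencing noise
#'
#' Simulates pooled sequencing of a population and writes bcftools-style
#' VCF records. Per marker: total depth ~ Poisson(`mean_depth`);
#' alternative reads ~ Binomial(depth, `f(1-e) + (1-f)e`) where `f` is the
#' population allele frequency and `e` the per-read miscall rate. A record
#' is written only when at least one alternative read was seen at nonzero
#' depth -- the caller's silence at homozygous-reference sites is exactly
#' what turns reference-LOH into SNP deserts. The per-sample `AD` field
#' carries (ref, alt) read counts; QUAL follows `cfg$qual_model`.
#'
#' Setting `hap = 2` emulates mapping the same reads onto the alternative
#' ("Haplotype 2") assembly: allele roles swap, so the emitted frequency is
#' `1 - f` with REF and ALT exchanged, and sites fixed for haplotype 1 --
#' silent on haplotype 1 -- surface at AAF 1.0.
#'
#' @param pop A [propagate()] result.
#' @param genome The [make_genome()] the population derives from (contig
#'   headers).
#' @param cfg A [sim_config()] (depth, error, QUAL model).
#' @param path Optional output path; when given, the VCF is written there
#'   and the ground truth to `paste0(path, ".truth.tsv")`.
#' @param hap Reference haplotype to emit against (1 or 2).
#' @param seed Optional seed.
#' @return Invisibly, a list: `sites` (emitted records in [read_vcf()]
#'   layout), `truth` (every marker with its frequency, simulated reads,
#'   and `emitted` flag), `path`.
#' @export
emit_vcf <- function(pop, genome, cfg = genome$cfg, path = NULL, hap = 1,
                     seed = NULL) {
  stopifnot(inherits(pop, "sim_population"), hap %in% c(1, 2))
  if (!is.null(seed)) set.seed(seed)
  mk <- pop$markers
  f <- mk$freq
  ref <- mk$ref; alt <- mk$alt
  if (hap == 2) {
    f <- 1 - f
    tmp <- ref; ref <- mk$alt; alt <- tmp
  }
  n <- nrow(mk)
  depth <- stats::rpois(n, cfg$mean_depth)
  p <- f * (1 - cfg$error_rate) + (1 - f) * cfg$error_rate
  alt_reads <- stats::rbinom(n, depth, p)
  ref_reads <- depth - alt_reads
  qual <- switch(cfg$qual_model,
                 constant = rep(cfg$qual_value, n),
                 binomial = .binom_qual(alt_reads, depth, cfg$error_rate))
  emitted <- depth >= 1L & (alt_reads >= 1L | cfg$emit_zero_aaf)

  truth <- data.frame(contig = mk$contig, pos = mk$pos, ref = ref,
                      alt = alt, freq = f, depth = depth,
                      alt_reads = alt_reads, qual = round(qual, 2),
                      emitted = emitted, stringsAsFactors = FALSE)
  e <- which(emitted)
  sites <- data.frame(contig = mk$contig[e], pos = mk$pos[e],
                      ref = ref[e], alt = alt[e],
                      qual = round(qual[e], 2), depth = depth[e],
                      alt_depth = alt_reads[e],
                      aaf = alt_reads[e] / depth[e],
                      stringsAsFactors = FALSE)
  rownames(sites) <- NULL
  if (!is.null(path)) {
    hdr <- c("##fileformat=VCFv4.2",
             "##source=lohscape-simulator",
             sprintf("##contig=<ID=%s,length=%d>", genome$contigs$name,
                     as.integer(genome$contigs$length)),
             "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total read depth\">",
             "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
             "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
             "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tPOOL")
    rec <- sprintf("%s\t%d\t.\t%s\t%s\t%s\t.\tDP=%d\tAD:DP\t%d,%d:%d",
                   sites$contig, sites$pos, sites$ref, sites$alt,
                   format(sites$qual, trim = TRUE, scientific = FALSE),
                   sites$depth, sites$depth - sites$alt_depth,
                   sites$alt_depth, sites$depth)
    writeLines(c(hdr, rec), path)
    data.table::fwrite(truth, paste0(path, ".truth.tsv"), sep = "\t")
  }
  invisible(list(sites = sites, truth = truth, path = path))
}

# Phred-scaled upper-tail probability of >= k alternative reads arising
# from sequencing error alone; capped so e = 0 stays finite.
.binom_qual <- function(k, depth, error_rate, cap = 10000) {
  logp <- stats::pbinom(k - 1L, depth, error_rate, lower.tail = FALSE,
                        log.p = TRUE)
  q <- -10 * logp / log(10)
  pmin(ifelse(is.finite(q), q, cap), cap)
}

#' Emit a per-base depth table
#'
#' Simulates per-base read depth over the whole genome: Poisson
#' (`mean_depth`) everywhere, with the mean doubled inside planted tracts
#' flagged `collapsed` (two haplotypes' reads piling on one contig).
#'
#' @param genome A [make_genome()] result.
#' @param cfg A [sim_config()].
#' @param path Optional output TSV path (samtools-depth layout: contig,
#'   1-based position, depth; no header).
#' @param seed Optional seed.
#' @return Invisibly, a data.table (`contig`, `pos`, `depth`) sorted by
#'   contig then position.
#' @export
emit_depth <- function(genome, cfg = genome$cfg, path = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pt <- genome$planted_tracts
  per_ct <- lapply(seq_len(nrow(genome$contigs)), function(i) {
    nm <- genome$contigs$name[i]
    L <- as.integer(genome$contigs$length[i])
    mu <- rep(cfg$mean_depth, L)
    if (!is.null(pt)) {
      coll <- pt[pt$collapsed & pt$contig == nm, , drop = FALSE]
      for (j in seq_len(nrow(coll))) {
        mu[(coll$start[j] + 1L):coll$end[j]] <- 2 * cfg$mean_depth
      }
    }
    data.table::data.table(contig = nm, pos = seq_len(L),
                           depth = stats::rpois(L, mu))
  })
  dt <- data.table::rbindlist(per_ct)
  if (!is.null(path)) {
    data.table::fwrite(dt, path, sep = "\t", col.names = FALSE)
  }
  invisible(dt)
}

#' Simulate a complete study scenario
#'
#' High-level presets reproducing the package's three reference designs
#' end to end, with ground truth retained:
#' \describe{
#'   \item{`"f1"`}{two-strain cross F1: a fully heterozygous founder
#'     selfing for 5 generations (200 individuals), 2 contigs x 2 Mb at
#'     1% marker density, 25x depth. Expected readout: AAF centered at 0.5
#'     genome-wide, no homozygous tracts.}
#'   \item{`"f2"`}{one F2 individual from that F1 (one obligate crossover
#'     per gamete per contig) selfing for 3.7 generations; 50x depth, as
#'     for populations sequenced in the 21--54x range. Expected readout:
#'     contiguous homozygous-alternative tracts and SNP deserts over the
#'     F2's fixed blocks.}
#'   \item{`"clonal"`}{parthenogenetic parent and progeny populations from
#'     one founder, 2 contigs x 1 Mb at 1.15% density, 25x depth, with two
#'     planted collapsed homozygous-reference tracts. Expected readout: no
#'     new LOH between parent and progeny; planted tracts recovered as SNP
#'     deserts with doubled coverage.}
#' }
#' All scenarios use the depth-scaled (`"binomial"`) QUAL model so the
#' quality >= 70 filter behaves as it does on real caller output,
#' suppressing records supported only by sequencing-error reads.
#'
#' @param scenario `"f1"`, `"f2"`, or `"clonal"`.
#' @param seed Integer seed; the whole scenario is reproducible from it.
#' @param out_dir Optional directory; when given, VCFs (plus truth tables),
#'   the depth TSV (clonal), and the true-tract BED are written there.
#' @return List with `scenario`, `cfg`, `genome`, and per scenario:
#'   `pop` (f1); `f2_phase`, `pop`, `parent_pop`, `true_blocks` (f2);
#'   `parent_pop`, `child_pop`, `depth` (clonal). Populations carry their
#'   emitted `sites`/`truth` under `$emission` when `out_dir` is used or
#'   `emit = TRUE`.
#' @param emit Emit VCF/depth realizations in memory even without
#'   `out_dir` (default `TRUE`).
#' @export
simulate_scenario <- function(scenario = c("f1", "f2", "clonal"), seed = 1,
                              out_dir = NULL, emit = TRUE) {
  scenario <- match.arg(scenario)
  set.seed(seed)
  pth <- function(f) if (is.null(out_dir)) NULL else file.path(out_dir, f)
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE,
                                    showWarnings = FALSE)
  if (scenario == "f1") {
    cfg <- sim_config(contigs = data.frame(name = c("chrI", "chrII"),
                                           length = c(2e6, 2e6)),
                      het_density = 0.01, mean_depth = 25,
                      propagation = "SELFING", n_generations = 5,
                      qual_model = "binomial")
    genome <- make_genome(cfg, seed = NULL)
    pop <- propagate(founder_phase(genome), cfg)
    em <- if (emit || !is.null(out_dir)) {
      emit_vcf(pop, genome, cfg, path = pth("f1_population.vcf"))
    }
    return(list(scenario = scenario, cfg = cfg, genome = genome,
                pop = pop, emission = em))
  }
  if (scenario == "f2") {
    cfg <- sim_config(contigs = data.frame(name = c("chrI", "chrII"),
                                           length = c(2e6, 2e6)),
                      het_density = 0.01, mean_depth = 50,
                      propagation = "SELFING", n_generations = 3.7,
                      crossover_model = "OBLIGATE_ONE",
                      qual_model = "binomial")
    genome <- make_genome(cfg, seed = NULL)
    f1 <- founder_phase(genome)
    parent_cfg <- cfg; parent_cfg$n_generations <- 5
    parent_pop <- propagate(f1, parent_cfg)
    f2_phase <- make_f2(f1, cfg)
    pop <- propagate(f2_phase, cfg)
    em_parent <- if (emit || !is.null(out_dir)) {
      emit_vcf(parent_pop, genome, cfg, path = pth("f1_population.vcf"))
    }
    em <- if (emit || !is.null(out_dir)) {
      emit_vcf(pop, genome, cfg, path = pth("f2_population.vcf"))
    }
    blocks <- attr(f2_phase, "true_blocks")
    if (!is.null(out_dir)) {
      data.table::fwrite(blocks, file.path(out_dir, "f2_true_blocks.bed"),
                         sep = "\t", col.names = FALSE)
    }
    return(list(scenario = scenario, cfg = cfg, genome = genome,
                f2_phase = f2_phase, pop = pop, parent_pop = parent_pop,
                true_blocks = blocks, emission = em,
                parent_emission = em_parent))
  }
  # clonal: parthenogenetic parent + progeny with planted collapsed tracts
  planted <- data.frame(contig = c("ctg1", "ctg2"),
                        start = c(200000, 550000),
                        end = c(450000, 850000),
                        state = "HOM_REF", collapsed = TRUE,
                        stringsAsFactors = FALSE)
  cfg <- sim_config(contigs = data.frame(name = c("ctg1", "ctg2"),
                                         length = c(1e6, 1e6)),
                    het_density = 0.0115, planted_tracts = planted,
                    mean_depth = 25, propagation = "CLONAL",
                    n_generations = 3.5, qual_model = "binomial")
  genome <- make_genome(cfg, seed = NULL)
  founder <- founder_phase(genome)
  parent_pop <- propagate(founder, cfg)
  child_pop <- propagate(founder, cfg)
  em_parent <- em_child <- depth <- NULL
  if (emit || !is.null(out_dir)) {
    em_parent <- emit_vcf(parent_pop, genome, cfg,
                          path = pth("parent_population.vcf"))
    em_child <- emit_vcf(child_pop, genome, cfg,
                         path = pth("child_population.vcf"))
    depth <- emit_depth(genome, cfg, path = pth("combined_depth.tsv"))
  }
  if (!is.null(out_dir)) {
    data.table::fwrite(planted, file.path(out_dir, "planted_tracts.bed"),
                       sep = "\t", col.names = FALSE)
  }
  list(scenario = scenario, cfg = cfg, genome = genome,
       parent_pop = parent_pop, child_pop = child_pop,
       parent_emission = em_parent, child_emission = em_child,
       depth = depth, planted_tracts = planted)
}
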