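#' Tract detection parameters
#'
#' Settings for calling homozygous tracts (runs of homozygosity) from a
#' filtered site table. Two tract classes exist:
#' \describe{
#'   \item{HOM_REF}{a block of at least `min_tract_bp` containing no SNP
#'     calls at all -- homozygous-reference sequence is silent in a VCF, so
#'     its signature is a SNP desert;}
#'   \item{HOM_ALT}{a run of consecutive SNP calls all with
#'     AAF >= `hom_alt_aaf`, spanning at least `min_tract_bp` and containing
#'     at least `min_hom_alt_sites` sites -- sequence fixed for the
#'     alternative allele.}
#' }
#'
#' `hom_alt_aaf` defaults to 0.9 rather than exactly 1.0: at 21--25x pooled
#' coverage a truly fixed site can show a stray reference read, so an exact
#' 1.0 rule is idealized. `min_hom_alt_sites` guards against isolated
#' mis-calls spanning large gaps. The `het_band` is the AAF interval treated
#' as heterozygous by the parent/progeny comparison; it is wider than
#' \{0.5\} to accommodate binomial read-sampling spread at 21--54x depth.
#'
#' @param min_tract_bp Minimum tract span in bp (default 100,000).
#' @param hom_alt_aaf Per-site AAF threshold for homozygous-alternative
#'   (default 0.9).
#' @param het_band Numeric length-2 AAF interval treated as heterozygous
#'   (default `c(0.3, 0.7)`).
#' @param min_hom_alt_sites Minimum supporting sites for a HOM_ALT tract
#'   (default 10).
#' @return A list of class `"tract_params"`.
#' @export
tract_params <- function(min_tract_bp = 100000, hom_alt_aaf = 0.9,
                         het_band = c(0.3, 0.7), min_hom_alt_sites = 10) {
  stopifnot(min_tract_bp > 0,
            hom_alt_aaf > 0.5, hom_alt_aaf <= 1,
            length(het_band) == 2L, het_band[1] < het_band[2],
            het_band[1] > 0, het_band[2] < 1,
            het_band[1] <= 0.5, het_band[2] >= 0.5,
            min_hom_alt_sites >= 1)
  structure(list(min_tract_bp = min_tract_bp, hom_alt_aaf = hom_alt_aaf,
                 het_band = het_band, min_hom_alt_sites = min_hom_alt_sites),
            class = "tract_params")
}

.empty_tracts <- function() {
  data.frame(contig = character(), start = integer(), end = integer(),
             state = character(), n_sites = integer(), mean_aaf = numeric(),
             stringsAsFactors = FALSE)
}

.check_contig_sites <- function(sites, contig) {
  stopifnot(is.character(contig$name) || is.factor(contig$name),
            is.numeric(contig$length), contig$length > 0)
  if (nrow(sites) == 0L) return(invisible(NULL))
  if (!all(sites$contig == contig$name)) {
    stop("sites off-contig: expected all sites on ", contig$name)
  }
  if (is.unsorted(sites$pos, strictly = FALSE)) {
    stop("sites must be sorted by position on ", contig$name)
  }
  if (any(sites$pos < 1L | sites$pos > contig$length)) {
    stop("site positions outside [1, contig length] on ", contig$name)
  }
  invisible(NULL)
}

#' Detect homozygous-reference tracts (SNP deserts) on one contig
#'
#' Returns every maximal SNP-free interval on the contig whose span is at
#' least `min_tract_bp`. Because a variant caller emits no record at
#' homozygous-reference positions, such deserts are the only VCF signature
#' of reference-homozygous sequence. Intervals run from the contig start to
#' the first SNP, between consecutive SNPs (excluding the bounding SNP
#' positions themselves, which are evidence of heterozygosity), and from the
#' last SNP to the contig end. A contig with no sites at all yields a single
#' whole-contig tract when the contig itself reaches the span threshold.
#'
#' @param sites Filtered site data.frame, all on `contig`, sorted by `pos`.
#' @param contig One-row data.frame (or list) with `name` and `length`.
#' @param params A [tract_params()].
#' @return data.frame of tracts: `contig`, `start`, `end` (0-based
#'   half-open), `state` (`"HOM_REF"`), `n_sites` (0), `mean_aaf` (NA).
#' @export
detect_hom_ref_tracts <- function(sites, contig, params = tract_params()) {
  stopifnot(inherits(params, "tract_params"))
  .check_contig_sites(sites, contig)
  L <- as.integer(contig$length)
  pos <- sites$pos
  # gap bounds in 0-based half-open coordinates, excluding SNP bases:
  # a SNP at 1-based p occupies [p-1, p)
  starts <- c(0L, pos)
  ends <- c(pos - 1L, L)
  len <- ends - starts
  keep <- len >= params$min_tract_bp
  if (!any(keep)) return(.empty_tracts())
  data.frame(contig = contig$name, start = starts[keep], end = ends[keep],
             state = "HOM_REF", n_sites = 0L, mean_aaf = NA_real_,
             stringsAsFactors = FALSE)
}

#' Detect homozygous-alternative tracts on one contig
#'
#' Finds maximal runs of SNP calls supporting fixation of the alternative
#' allele: sites with AAF >= `hom_alt_aaf` support a run, any
#' heterozygous-looking site (AAF <= the upper edge of `het_band`) breaks
#' it, and sites in between -- too low to support fixation but far too
#' high to be heterozygous, the signature of a couple of stray
#' reference-miscalled reads at a truly fixed site -- are treated as
#' non-informative: they neither break the run nor count toward it.
#' A run is reported as a tract when it spans at least `min_tract_bp` and
#' contains at least `min_hom_alt_sites` supporting sites; the tract
#' interval spans the first through the last supporting site.
#'
#' @inheritParams detect_hom_ref_tracts
#' @return data.frame of tracts with `state = "HOM_ALT"`, `n_sites`
#'   (supporting sites), and `mean_aaf` over them (always
#'   >= `hom_alt_aaf`).
#' @export
detect_hom_alt_tracts <- function(sites, contig, params = tract_params()) {
  stopifnot(inherits(params, "tract_params"))
  .check_contig_sites(sites, contig)
  if (nrow(sites) == 0L) return(.empty_tracts())
  informative <- sites$aaf >= params$hom_alt_aaf |
    sites$aaf <= params$het_band[2]
  s <- sites[informative, , drop = FALSE]
  if (nrow(s) == 0L) return(.empty_tracts())
  hi <- s$aaf >= params$hom_alt_aaf
  r <- rle(hi)
  ends_idx <- cumsum(r$lengths)
  starts_idx <- ends_idx - r$lengths + 1L
  run <- which(r$values)
  if (!length(run)) return(.empty_tracts())
  out <- lapply(run, function(k) {
    i <- starts_idx[k]; j <- ends_idx[k]
    span_start <- s$pos[i] - 1L          # 0-based
    span_end <- s$pos[j]                 # half-open
    n <- j - i + 1L
    if (span_end - span_start < params$min_tract_bp ||
        n < params$min_hom_alt_sites) return(NULL)
    data.frame(contig = contig$name, start = span_start, end = span_end,
               state = "HOM_ALT", n_sites = n,
               mean_aaf = mean(s$aaf[i:j]), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) .empty_tracts() else out
}

#' Detect both tract classes across a whole genome
#'
#' Convenience wrapper running [detect_hom_ref_tracts()] and
#' [detect_hom_alt_tracts()] per contig over a multi-contig site table.
#'
#' @param sites Filtered site data.frame (any number of contigs; sorted by
#'   position within each contig).
#' @param contigs data.frame with columns `name`, `length`.
#' @param params A [tract_params()].
#' @return Combined tract data.frame sorted by (contig, start).
#' @export
detect_tracts <- function(sites, contigs, params = tract_params()) {
  res <- lapply(seq_len(nrow(contigs)), function(i) {
    ct <- contigs[i, , drop = FALSE]
    s <- sites[sites$contig == ct$name, , drop = FALSE]
    rbind(detect_hom_ref_tracts(s, ct, params),
          detect_hom_alt_tracts(s, ct, params))
  })
  out <- do.call(rbind, res)
  out <- out[order(out$contig, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summarize total homozygous extent
#'
#' Sums tract lengths and expresses them as a fraction of the haploid
#' genome, overall and per tract state.
#'
#' @param tracts Tract data.frame (disjoint per contig).
#' @param genome_bp Haploid genome size in bp (> 0).
#' @return List with `total_bp`, `genome_bp`, `fraction`, and `by_state`
#'   (data.frame with per-state `total_bp` and `fraction`).
#' @examples
#' t <- data.frame(contig = "c1", start = c(0, 3e5), end = c(15e4, 55e4),
#'                 state = c("HOM_REF", "HOM_ALT"), n_sites = c(0L, 500L),
#'                 mean_aaf = c(NA, 0.99))
#' summarize_tracts(t, 1e6)$fraction  # 0.4
#' @export
summarize_tracts <- function(tracts, genome_bp) {
  if (!is.numeric(genome_bp) || length(genome_bp) != 1L || genome_bp <= 0) {
    stop("genome_bp must be a single positive number")
  }
  len <- if (nrow(tracts)) tracts$end - tracts$start else numeric(0)
  total <- sum(len)
  by_state <- if (nrow(tracts)) {
    agg <- stats::aggregate(len, by = list(state = tracts$state), FUN = sum)
    data.frame(state = agg$state, total_bp = agg$x,
               fraction = agg$x / genome_bp, stringsAsFactors = FALSE)
  } else {
    data.frame(state = character(), total_bp = numeric(),
               fraction = numeric(), stringsAsFactors = FALSE)
  }
  list(total_bp = total, genome_bp = genome_bp,
       fraction = total / genome_bp, by_state = by_state)
}

#' Partition a contig into HET / HOM_REF / HOM_ALT segments
#'
#' Combines the detected tracts of one contig into a label track tiling the
#' contig exactly: tract intervals keep their state, everything else is
#' labeled HET. This is the data behind a chromosome heterozygosity plot
#' (AAF points above a colored state ideogram).
#'
#' @param tracts Tract data.frame for this contig (both states; disjoint).
#' @param contig One-row data.frame (or list) with `name` and `length`.
#' @return data.frame of segments: `contig`, `start`, `end` (0-based
#'   half-open), `state`; segments are contiguous and sum to the contig
#'   length.
#' @export
state_track <- function(tracts, contig) {
  L <- as.integer(contig$length)
  tr <- tracts[tracts$contig == contig$name, , drop = FALSE]
  tr <- tr[order(tr$start), , drop = FALSE]
  if (nrow(tr) > 1L && any(tr$start[-1L] < tr$end[-nrow(tr)])) {
    stop("overlapping tracts on ", contig$name)
  }
  segs <- list()
  cur <- 0L
  for (i in seq_len(nrow(tr))) {
    if (tr$start[i] > cur) {
      segs[[length(segs) + 1L]] <- c(cur, tr$start[i], NA)
    }
    segs[[length(segs) + 1L]] <- c(tr$start[i], tr$end[i], i)
    cur <- tr$end[i]
  }
  if (cur < L) segs[[length(segs) + 1L]] <- c(cur, L, NA)
  m <- do.call(rbind, segs)
  data.frame(contig = contig$name, start = as.integer(m[, 1L]),
             end = as.integer(m[, 2L]),
             state = ifelse(is.na(m[, 3L]), "HET", tr$state[m[, 3L]]),
             stringsAsFactors = FALSE)
}

#' Write tracts as a BED file
#'
#' Standard 5-column BED (0-based half-open) with the tract state in the
#' name field and the supporting-site count as the score.
#'
#' @param tracts Tract data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
tracts_to_bed <- function(tracts, path) {
  bed <- data.frame(chrom = tracts$contig, start = tracts$start,
                    end = tracts$end, name = tracts$state,
                    score = tracts$n_sites)
  data.table::fwrite(bed, path, sep = "\t", col.names = FALSE)
  invisible(path)
}
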