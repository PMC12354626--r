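#' Match SNPs between two population site tables
#'
#' Pairs every site shared between a parent-derived (A) and progeny-derived
#' (B) population on the key (contig, pos, ref, alt). Sites present in only
#' one table, or present at the same position with conflicting alleles
#' (a signature of a mis-call), are excluded and counted, never
#' force-paired. Both inputs should have been filtered with the same
#' [filter_config()].
#'
#' @param a,b Filtered site data.frames (see [read_vcf()]).
#' @return data.frame of pairs sorted by (contig, pos): `contig`, `pos`,
#'   `ref`, `alt`, `aaf_a`, `aaf_b`; with attributes `n_only_a`,
#'   `n_only_b` (sites unique to one input) and `n_conflict` (positions
#'   shared with disagreeing alleles).
#' @examples
#' a <- data.frame(contig = "c1", pos = c(10L, 20L, 30L), ref = "A",
#'                 alt = "T", qual = 200, depth = 24L, alt_depth = 12L,
#'                 aaf = 0.5)
#' b <- a[c(2, 3), ]; b$aaf <- 1
#' nrow(match_sites(a, b))  # 2
#' @export
match_sites <- function(a, b) {
  for (nm in c("a", "b")) {
    s <- get(nm)
    key <- paste(s$contig, s$pos)
    if (anyDuplicated(key)) {
      stop("duplicate (contig, pos) in input ", nm,
           " (malformed upstream VCF): ", key[duplicated(key)][1L])
    }
  }
  ka_pos <- paste(a$contig, a$pos)
  kb_pos <- paste(b$contig, b$pos)
  ka <- paste(ka_pos, a$ref, a$alt)
  kb <- paste(kb_pos, b$ref, b$alt)
  shared <- intersect(ka, kb)
  conflict <- length(intersect(ka_pos, kb_pos)) - length(shared)
  ia <- match(shared, ka)
  ib <- match(shared, kb)
  pairs <- data.frame(contig = a$contig[ia], pos = a$pos[ia],
                      ref = a$ref[ia], alt = a$alt[ia],
                      aaf_a = a$aaf[ia], aaf_b = b$aaf[ib],
                      stringsAsFactors = FALSE)
  pairs <- pairs[order(pairs$contig, pairs$pos), , drop = FALSE]
  rownames(pairs) <- NULL
  attr(pairs, "n_only_a") <- nrow(a) - length(shared) - conflict
  attr(pairs, "n_only_b") <- nrow(b) - length(shared) - conflict
  attr(pairs, "n_conflict") <- conflict
  pairs
}

#' Classify matched site pairs into LOH event classes
#'
#' Each matched pair is classified from its two AAFs:
#' \describe{
#'   \item{LOH_TO_ALT}{heterozygous in A (`aaf_a` inside `het_band`) and
#'     fixed alternative in B (`aaf_b >= hom_alt_aaf`) -- a new loss of
#'     heterozygosity toward the alternative allele, e.g. AAF 0.5 in a
#'     parent and 1.0 in a recombinant descendant;}
#'   \item{RETAINED_HET}{heterozygous in both;}
#'   \item{SHARED_HOM_ALT}{fixed alternative in both (pre-existing
#'     homozygosity, not a new event);}
#'   \item{OTHER}{anything else.}
#' }
#' The report also carries the joint AAF density grid underlying a
#' scatter-density comparison plot.
#'
#' @param pairs Matched pairs from [match_sites()].
#' @param params A [tract_params()] supplying `het_band` and `hom_alt_aaf`.
#' @param grid_bins Number of histogram bins per axis over \[0,1\]
#'   (default 100).
#' @return List of class `"comparison_report"`: `pairs` (with an added
#'   `event` column), `n_shared`, `counts` (named integer vector over the
#'   four classes), `grid` (`grid_bins` x `grid_bins` count matrix, A on
#'   rows), and `breaks` (shared bin edges).
#' @export
classify_pairs <- function(pairs, params = tract_params(), grid_bins = 100) {
  stopifnot(inherits(params, "tract_params"), grid_bins >= 1)
  lo <- params$het_band[1]; hi <- params$het_band[2]
  het_a <- pairs$aaf_a >= lo & pairs$aaf_a <= hi
  het_b <- pairs$aaf_b >= lo & pairs$aaf_b <= hi
  hom_a <- pairs$aaf_a >= params$hom_alt_aaf
  hom_b <- pairs$aaf_b >= params$hom_alt_aaf
  event <- rep("OTHER", nrow(pairs))
  event[het_a & het_b] <- "RETAINED_HET"
  event[hom_a & hom_b] <- "SHARED_HOM_ALT"
  event[het_a & hom_b] <- "LOH_TO_ALT"
  pairs$event <- event
  classes <- c("RETAINED_HET", "LOH_TO_ALT", "SHARED_HOM_ALT", "OTHER")
  counts <- vapply(classes, function(cl) sum(event == cl), 0L)
  breaks <- seq(0, 1, length.out = grid_bins + 1L)
  bin <- function(x) pmin(pmax(findInterval(x, breaks, rightmost.closed = TRUE,
                                            all.inside = TRUE), 1L), grid_bins)
  grid <- matrix(0L, grid_bins, grid_bins)
  if (nrow(pairs)) {
    tab <- table(factor(bin(pairs$aaf_a), levels = seq_len(grid_bins)),
                 factor(bin(pairs$aaf_b), levels = seq_len(grid_bins)))
    grid <- matrix(as.integer(tab), grid_bins, grid_bins)
  }
  structure(list(pairs = pairs, n_shared = nrow(pairs), counts = counts,
                 grid = grid, breaks = breaks),
            class = "comparison_report")
}

#' @exportS3Method base::print
print.comparison_report <- function(x, ...) {
  cat("Parent/progeny AAF comparison:", x$n_shared, "shared SNPs\n")
  for (nm in names(x$counts)) cat(sprintf("  %-15s %d\n", nm, x$counts[[nm]]))
  invisible(x)
}

#' Reconcile LOH calls from the two haplotype references
#'
#' A progeny region that becomes homozygous for the reference haplotype
#' simply vanishes from its VCF -- the caller emits no record -- so
#' comparison against one reference is blind to that event polarity.
#' Mapping the same reads to the alternative haplotype ("Haplotype 2")
#' reverses the polarity: loss toward Haplotype 1 appears there as AAF 1.0.
#' This function combines the two comparisons and reports LOH events seen
#' on either reference, and in particular events detectable only on
#' Haplotype 2.
#'
#' @param pairs_h1,pairs_h2 Matched pairs ([match_sites()]) from the
#'   comparisons on Haplotype 1 and Haplotype 2.
#' @param site_map data.frame giving the site-level correspondence between
#'   references, columns `contig_h1`, `pos_h1`, `contig_h2`, `pos_h2`.
#'   Required; for synthetic data where both emissions share marker
#'   coordinates, an identity map (`contig_h1 == contig_h2`,
#'   `pos_h1 == pos_h2`) is appropriate.
#' @param params A [tract_params()].
#' @param fp_tol False-positive tolerance: the number of apparent
#'   LOH_TO_ALT sites per comparison attributable to read-sampling noise.
#'   Default `1e-3 * n_shared` (0.1% of shared SNPs). Under Poisson depth
#'   the probability that a truly heterozygous site shows AAF >= 0.9 is
#'   about 2.7e-4 at 21x and 7e-5 at 25x, so the default sits an order of
#'   magnitude above expected noise while staying far below the ~1e3
#'   sites of the smallest tract-scale LOH event.
#' @return List of class `"haplotype_reconciliation"` with `verdict`
#'   (`"no data"`, `"no ongoing LOH"`, or `"LOH detected"`), per-haplotype
#'   LOH_TO_ALT counts `n_loh_h1` / `n_loh_h2`, `h2_only` (data.frame of
#'   Haplotype-2 LOH sites with no corresponding Haplotype-1 LOH call),
#'   and the two classified reports.
#' @export
dual_haplotype_reconcile <- function(pairs_h1, pairs_h2, site_map,
                                     params = tract_params(),
                                     fp_tol = NULL) {
  if (missing(site_map) || is.null(site_map)) {
    stop("site_map is required to reconcile the two haplotype references")
  }
  stopifnot(all(c("contig_h1", "pos_h1", "contig_h2", "pos_h2") %in%
                  names(site_map)))
  rep1 <- classify_pairs(pairs_h1, params)
  rep2 <- classify_pairs(pairs_h2, params)
  if (rep1$n_shared == 0L && rep2$n_shared == 0L) {
    return(structure(list(verdict = "no data", n_loh_h1 = 0L, n_loh_h2 = 0L,
                          h2_only = rep2$pairs[0, , drop = FALSE],
                          report_h1 = rep1, report_h2 = rep2),
                     class = "haplotype_reconciliation"))
  }
  n1 <- sum(rep1$pairs$event == "LOH_TO_ALT")
  n2 <- sum(rep2$pairs$event == "LOH_TO_ALT")
  # haplotype-2 LOH sites whose mapped haplotype-1 position is not an LOH call
  loh2 <- rep2$pairs[rep2$pairs$event == "LOH_TO_ALT", , drop = FALSE]
  key2 <- paste(loh2$contig, loh2$pos)
  map_key2 <- paste(site_map$contig_h2, site_map$pos_h2)
  idx <- match(key2, map_key2)
  mapped_h1 <- ifelse(is.na(idx), NA_character_,
                      paste(site_map$contig_h1[idx], site_map$pos_h1[idx]))
  loh1_key <- with(rep1$pairs[rep1$pairs$event == "LOH_TO_ALT", , drop = FALSE],
                   paste(contig, pos))
  h2_only <- loh2[is.na(mapped_h1) | !(mapped_h1 %in% loh1_key), ,
                  drop = FALSE]
  if (is.null(fp_tol)) {
    fp_tol <- 1e-3 * max(rep1$n_shared, rep2$n_shared)
  }
  verdict <- if (n1 <= fp_tol && n2 <= fp_tol) "no ongoing LOH" else
    "LOH detected"
  structure(list(verdict = verdict, n_loh_h1 = n1, n_loh_h2 = n2,
                 fp_tol = fp_tol, h2_only = h2_only,
                 report_h1 = rep1, report_h2 = rep2),
            class = "haplotype_reconciliation")
}

#' @exportS3Method base::print
print.haplotype_reconciliation <- function(x, ...) {
  cat("Dual-haplotype LOH reconciliation\n")
  cat("  LOH_TO_ALT on haplotype 1:", x$n_loh_h1, "\n")
  cat("  LOH_TO_ALT on haplotype 2:", x$n_loh_h2, "\n")
  cat("  haplotype-2-only events:  ", nrow(x$h2_only), "\n")
  cat("  verdict:", x$verdict, "\n")
  invisible(x)
}
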