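#' Run the full LOH analysis pipeline
#'
#' Orchestrates the stages over a parent and a progeny VCF: AAF extraction
#' and filtering, homozygous-tract detection, parent/progeny comparison,
#' optional coverage-doubling verification, and an optional dual-haplotype
#' reconciliation. All tabular results are written to `out_dir`
#' (TSV/BED/JSON only, so re-running with identical inputs and settings
#' yields byte-identical outputs); the assembled results are also returned.
#'
#' Per-species presets for the coverage cutoff are available through
#' `preset`: `"h_mephisto"` keeps the default 50x maximum depth (samples
#' sequenced at 21--25x), `"c_elegans"` raises it to 100x (21--54x).
#'
#' @param vcf_parent,vcf_child Paths to the two population VCFs.
#' @param depth_tsv Optional per-base depth table (samtools-depth layout)
#'   from diploid-assembly mapping, enabling the coverage-doubling test.
#' @param out_dir Output directory (created if needed).
#' @param filter_cfg A [filter_config()]; overridden by `preset` when that
#'   is given.
#' @param params A [tract_params()].
#' @param preset Optional species preset, `"h_mephisto"` or `"c_elegans"`.
#' @param contigs Optional contig data.frame (`name`, `length`); defaults
#'   to the parent VCF header.
#' @param window_bp Coverage window size (default 10,000).
#' @param ratio_window Coverage-doubling acceptance interval
#'   (default `c(1.6, 2.4)`).
#' @param hap2_parent,hap2_child Optional paths to the same populations'
#'   VCFs mapped against the alternative haplotype assembly.
#' @param site_map Optional site correspondence for the dual-haplotype
#'   reconciliation (see [dual_haplotype_reconcile()]).
#' @return Invisibly, a list with `sites_parent`, `sites_child`, `tracts`,
#'   `tract_summary`, `report` (classified comparison), `verdicts`
#'   (coverage doubling, when depth given), `reconciliation` (when
#'   haplotype-2 inputs given), and `out_dir`.
#' @export
run_loh_pipeline <- function(vcf_parent, vcf_child, depth_tsv = NULL,
                             out_dir, filter_cfg = filter_config(),
                             params = tract_params(), preset = NULL,
                             contigs = NULL, window_bp = 10000,
                             ratio_window = c(1.6, 2.4),
                             hap2_parent = NULL, hap2_child = NULL,
                             site_map = NULL) {
  for (f in c(vcf_parent, vcf_child, depth_tsv, hap2_parent, hap2_child)) {
    if (!is.null(f) && !file.exists(f)) stop("input file not found: ", f)
  }
  if (!is.null(preset)) {
    filter_cfg <- switch(match.arg(preset, c("h_mephisto", "c_elegans")),
                         h_mephisto = filter_config(max_depth = 50),
                         c_elegans = filter_config(max_depth = 100))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  vp <- stage("aaf(parent)", read_vcf(vcf_parent))
  vc <- stage("aaf(child)", read_vcf(vcf_child))
  if (is.null(contigs)) contigs <- vp$contigs
  sp <- filter_sites(vp$sites, filter_cfg)
  sc <- filter_sites(vc$sites, filter_cfg)
  write_aaf_tsv(sp, file.path(out_dir, "parent_aaf.tsv"))
  write_aaf_tsv(sc, file.path(out_dir, "child_aaf.tsv"))

  tracts <- stage("tracts", detect_tracts(sc, contigs, params))
  tracts_to_bed(tracts, file.path(out_dir, "child_tracts.bed"))
  tsum <- summarize_tracts(tracts, sum(contigs$length))
  data.table::fwrite(
    data.frame(scope = c("ALL", tsum$by_state$state),
               total_bp = c(tsum$total_bp, tsum$by_state$total_bp),
               fraction = c(tsum$fraction, tsum$by_state$fraction)),
    file.path(out_dir, "tract_summary.tsv"), sep = "\t")

  pairs <- stage("compare", match_sites(sp, sc))
  report <- classify_pairs(pairs, params)
  write_aaf_tsv(report$pairs, file.path(out_dir, "site_pairs.tsv"))

  verdicts <- NULL
  if (!is.null(depth_tsv)) {
    depths <- stage("coverage", read_depth_table(depth_tsv))
    wins <- window_coverage(depths, contigs, window_bp)
    data.table::fwrite(wins, file.path(out_dir, "coverage_windows.tsv"),
                       sep = "\t")
    if (nrow(tracts)) {
      verdicts <- doubling_test(wins, tracts, ratio_window)
      data.table::fwrite(verdicts, file.path(out_dir,
                                             "doubling_verdicts.tsv"),
                         sep = "\t")
    }
  }

  recon <- NULL
  if (!is.null(hap2_parent) && !is.null(hap2_child)) {
    p2 <- filter_sites(stage("aaf(hap2 parent)",
                             read_vcf(hap2_parent))$sites, filter_cfg)
    c2 <- filter_sites(stage("aaf(hap2 child)",
                             read_vcf(hap2_child))$sites, filter_cfg)
    pairs2 <- stage("compare(hap2)", match_sites(p2, c2))
    recon <- dual_haplotype_reconcile(pairs, pairs2, site_map, params)
  }

  json <- list(
    n_sites_parent = nrow(sp), n_sites_child = nrow(sc),
    n_shared = report$n_shared, counts = as.list(report$counts),
    n_tracts = nrow(tracts), tract_bp = tsum$total_bp,
    tract_fraction = tsum$fraction,
    n_collapsed = if (!is.null(verdicts))
      sum(verdicts$is_collapsed, na.rm = TRUE) else NULL,
    reconciliation_verdict = if (!is.null(recon)) recon$verdict else NULL,
    filter = unclass(filter_cfg), tract_params = unclass(params))
  jsonlite::write_json(json, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")

  invisible(list(sites_parent = sp, sites_child = sc, tracts = tracts,
                 tract_summary = tsum, report = report,
                 verdicts = verdicts, reconciliation = recon,
                 out_dir = out_dir))
}

#' Plot AAF along a contig above its homozygosity state track
#'
#' Draws the per-site alternative allele frequency along one contig with a
#' colored state ideogram underneath: gold for homozygous-reference
#' tracts, blue for homozygous-alternative, grey for heterozygous
#' background.
#'
#' @param sites Filtered site data.frame for one contig.
#' @param segments Segment data.frame from [state_track()].
#' @param contig Contig name (used for the title).
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `NULL`.
#' @export
plot_aaf_track <- function(sites, segments, contig = segments$contig[1],
                           ...) {
  cols <- c(HET = "grey85", HOM_REF = "gold", HOM_ALT = "royalblue")
  L <- max(segments$end)
  graphics::plot(NA, xlim = c(0, L), ylim = c(-0.18, 1), xlab = "position (bp)",
                 ylab = "alternative allele frequency", main = contig, ...)
  graphics::rect(segments$start, -0.18, segments$end, -0.06,
                 col = cols[segments$state], border = NA)
  s <- sites[sites$contig == contig, , drop = FALSE]
  graphics::points(s$pos, s$aaf, pch = 16, cex = 0.3,
                   col = grDevices::adjustcolor("black", 0.4))
  invisible(NULL)
}
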