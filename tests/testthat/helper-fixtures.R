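# In-code fixtures: small VCFs written by hand, quick site tables, and the
# independent brute-force oracle for SNP-desert detection.

# Write a VCF from a record table (chrom, pos, ref, alt, qual, ad_ref,
# ad_alt). ad = NA drops the AD field for that record; dp4 = TRUE moves
# allele depths into INFO/DP4 and drops the sample column entirely.
write_test_vcf <- function(records,
                           contigs = data.frame(name = "c1",
                                                length = 500000L),
                           path = tempfile(fileext = ".vcf"),
                           dp4 = FALSE, contig_lengths = TRUE) {
  ct <- if (contig_lengths) {
    sprintf("##contig=<ID=%s,length=%d>", contigs$name,
            as.integer(contigs$length))
  } else {
    sprintf("##contig=<ID=%s>", contigs$name)
  }
  hdr <- c("##fileformat=VCFv4.2", ct,
           "##INFO=<ID=DP4,Number=4,Type=Integer,Description=\"ref-fwd,ref-rev,alt-fwd,alt-rev\">",
           "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">")
  if (dp4) {
    hdr <- c(hdr, "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
    rec <- sprintf("%s\t%d\t.\t%s\t%s\t%s\t.\tDP4=%d,%d,%d,%d",
                   records$chrom, records$pos, records$ref, records$alt,
                   records$qual, records$ad_ref %/% 2,
                   records$ad_ref - records$ad_ref %/% 2,
                   records$ad_alt %/% 2,
                   records$ad_alt - records$ad_alt %/% 2)
  } else {
    hdr <- c(hdr, "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1")
    ad <- ifelse(is.na(records$ad_ref), ".",
                 paste0(records$ad_ref, ",", records$ad_alt))
    rec <- sprintf("%s\t%d\t.\t%s\t%s\t%s\t.\t.\tAD\t%s",
                   records$chrom, records$pos, records$ref, records$alt,
                   records$qual, ad)
  }
  writeLines(c(hdr, rec), path)
  path
}

# Minimal well-formed site table for filter/tract/compare tests.
make_sites <- function(pos, aaf = 0.5, contig = "c1", qual = 200,
                       depth = 24L, ref = "A", alt = "T") {
  n <- length(pos)
  aaf <- rep_len(aaf, n)
  depth <- rep_len(as.integer(depth), n)
  data.frame(contig = rep_len(contig, n), pos = as.integer(pos),
             ref = rep_len(ref, n), alt = rep_len(alt, n),
             qual = rep_len(qual, n), depth = depth,
             alt_depth = as.integer(round(aaf * depth)), aaf = aaf,
             stringsAsFactors = FALSE)
}

# Independent oracle for SNP-desert (HOM_REF tract) detection: mark every
# base, take maximal runs of non-SNP bases via rle, keep runs >= min_bp.
# Deliberately a different algorithm from the package's gap arithmetic.
brute_force_deserts <- function(pos, L, min_bp) {
  is_snp <- rep(FALSE, L)
  is_snp[pos] <- TRUE
  r <- rle(!is_snp)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_bp
  data.frame(start = starts[keep] - 1L, end = ends[keep])  # 0-based half-open
}
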