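#' Site filter settings
#'
#' Bundle the per-site filters applied before any downstream LOH analysis:
#' a minimum variant quality, a maximum total read depth (repeat avoidance),
#' and flags restricting the table to biallelic single-nucleotide variants.
#'
#' Defaults follow the pooled-sequencing workflow this package implements:
#' QUAL >= 70 (stringent but not excessive) and depth <= 50 reads, the cutoff
#' suited to samples sequenced at 21--25x; populations sequenced deeper
#' (e.g. 21--54x) should raise `max_depth` to 100. Both thresholds are
#' inclusive.
#'
#' @param min_qual Minimum variant quality (Phred-like); sites with
#'   `qual >= min_qual` are kept. Default 70.
#' @param max_depth Maximum total read depth; sites with `depth <= max_depth`
#'   are kept. Default 50.
#' @param snps_only Keep only sites whose REF and ALT alleles are single
#'   bases. Default `TRUE`.
#' @param biallelic_only Keep only sites with exactly one alternative
#'   allele. Default `TRUE`.
#' @return A list of class `"filter_config"`.
#' @examples
#' filter_config()                 # pooled 21-25x settings
#' filter_config(max_depth = 100)  # deeper-coverage populations
#' @export
filter_config <- function(min_qual = 70, max_depth = 50,
                          snps_only = TRUE, biallelic_only = TRUE) {
  stopifnot(is.numeric(min_qual), length(min_qual) == 1L, min_qual >= 0,
            is.numeric(max_depth), length(max_depth) == 1L, max_depth > 0,
            is.logical(snps_only), is.logical(biallelic_only))
  structure(list(min_qual = min_qual, max_depth = max_depth,
                 snps_only = snps_only, biallelic_only = biallelic_only),
            class = "filter_config")
}

#' Read a VCF into a site table with alternative allele frequencies
#'
#' Parses a VCF 4.x file (plain or bgzipped) and returns one row per record
#' carrying a defined alternative allele, with the alternative allele
#' frequency (AAF) computed from allele depths. The AAF of a pooled
#' population sample estimates heterozygosity at that site: ~0.5 at sites
#' heterozygous in every individual, 1.0 at sites fixed for the alternative
#' allele.
#'
#' Allele depths are taken from the per-sample `AD` FORMAT field when
#' present (summed across samples); otherwise from the `INFO/DP4` field
#' (ref forward+reverse vs alt forward+reverse) as emitted by bcftools-style
#' callers. A record with neither annotation is an error. Records with zero
#' usable depth are dropped with a warning rather than given an undefined
#' AAF.
#'
#' @param path Path to a VCF file.
#' @return A list with components:
#'   \describe{
#'     \item{sites}{data.frame with columns `contig`, `pos` (1-based),
#'       `ref`, `alt`, `qual`, `depth`, `alt_depth`, `aaf`, in file order.}
#'     \item{contigs}{data.frame with columns `name`, `length` (NA when the
#'       header lacks lengths, with a warning).}
#'   }
#' @seealso [filter_sites()] to apply quality/depth/SNP filters.
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  contigs <- .parse_contig_meta(v@meta)

  n <- nrow(fix)
  if (n == 0L) {
    return(list(sites = data.frame(contig = character(), pos = integer(),
                                   ref = character(), alt = character(),
                                   qual = numeric(), depth = integer(),
                                   alt_depth = integer(), aaf = numeric()),
                contigs = contigs))
  }
  alt <- fix$ALT
  keep <- !is.na(alt) & alt != "." & alt != ""
  fix <- fix[keep, , drop = FALSE]
  if (nrow(fix) == 0L) stop("no records with a defined alternative allele in ", path)

  # allele depths: per-sample AD preferred, INFO/DP4 fallback
  ad <- NULL
  if (ncol(v@gt) >= 2L) {
    fmt <- v@gt[keep, 1L]
    if (any(grepl("(^|:)AD(:|$)", fmt))) {
      ad_chr <- vcfR::extract.gt(v, element = "AD")[keep, , drop = FALSE]
      ad <- .sum_ad(ad_chr, fix)
    }
  }
  if (is.null(ad)) {
    dp4 <- .info_field(fix$INFO, "DP4")
    if (all(is.na(dp4))) {
      stop("no AD FORMAT field and no INFO/DP4 in ", path,
           "; first record without allele depths: ",
           fix$CHROM[1L], ":", fix$POS[1L])
    }
    bad <- which(is.na(dp4))
    if (length(bad)) {
      stop("record without allele-depth annotation: ",
           fix$CHROM[bad[1L]], ":", fix$POS[bad[1L]])
    }
    parts <- matrix(as.numeric(unlist(strsplit(dp4, ",", fixed = TRUE))),
                    ncol = 4L, byrow = TRUE)
    ad <- cbind(parts[, 1L] + parts[, 2L], parts[, 3L] + parts[, 4L])
  }

  depth <- ad[, 1L] + ad[, 2L]
  pos <- suppressWarnings(as.integer(fix$POS))
  if (anyNA(pos)) stop("malformed POS field near record ",
                       which(is.na(pos))[1L], " of ", path)
  qual <- suppressWarnings(as.numeric(fix$QUAL))

  sites <- data.frame(contig = fix$CHROM, pos = pos,
                      ref = fix$REF, alt = fix$ALT, qual = qual,
                      depth = as.integer(depth),
                      alt_depth = as.integer(ad[, 2L]),
                      stringsAsFactors = FALSE)
  zero <- sites$depth == 0L
  if (any(zero)) {
    warning(sum(zero), " record(s) with zero allele depth dropped from ", path)
    sites <- sites[!zero, , drop = FALSE]
  }
  sites$aaf <- sites$alt_depth / sites$depth
  rownames(sites) <- NULL
  list(sites = sites, contigs = contigs)
}

# Sum AD across samples; first value is REF depth, remaining are ALT depths
# (summed together for multi-allelic records).
.sum_ad <- function(ad_chr, fix) {
  ref_d <- numeric(nrow(ad_chr))
  alt_d <- numeric(nrow(ad_chr))
  for (j in seq_len(ncol(ad_chr))) {
    col <- ad_chr[, j]
    miss <- is.na(col) | col == "." | col == ""
    if (any(miss & ncol(ad_chr) == 1L)) {
      i <- which(miss)[1L]
      stop("record without allele-depth annotation: ",
           fix$CHROM[i], ":", fix$POS[i])
    }
    vals <- strsplit(ifelse(miss, "0,0", col), ",", fixed = TRUE)
    ref_d <- ref_d + vapply(vals, function(x) as.numeric(x[1L]), 0)
    alt_d <- alt_d + vapply(vals, function(x) sum(as.numeric(x[-1L])), 0)
  }
  cbind(ref_d, alt_d)
}

.info_field <- function(info, key) {
  m <- regmatches(info, regexpr(paste0("(^|;)", key, "=[^;]+"), info))
  out <- rep(NA_character_, length(info))
  hit <- grepl(paste0("(^|;)", key, "="), info)
  out[hit] <- sub(paste0("^;?", key, "="), "", m)
  out
}

.parse_contig_meta <- function(meta) {
  lines <- grep("^##contig=", meta, value = TRUE)
  if (!length(lines)) {
    warning("no ##contig header lines; contig lengths unknown")
    return(data.frame(name = character(), length = integer(),
                      stringsAsFactors = FALSE))
  }
  name <- sub(".*[<,]ID=([^,>]+).*", "\\1", lines)
  len <- rep(NA_integer_, length(lines))
  has_len <- grepl("length=", lines)
  len[has_len] <- as.integer(sub(".*length=([0-9]+).*", "\\1",
                                 lines[has_len]))
  if (anyNA(len)) warning("##contig lines without length=; marked unknown")
  data.frame(name = name, length = len, stringsAsFactors = FALSE)
}

#' Filter variant sites by quality, depth, and allele class
#'
#' Applies the shared site filters to a table produced by [read_vcf()] (or
#' the synthetic emitter). A site is retained iff `qual >= min_qual` and
#' `depth <= max_depth` (both inclusive) and, under the default flags, both
#' alleles are single bases and there is exactly one alternative allele.
#' Order is preserved and the output is always a subset of the input, so
#' tightening either threshold can only remove sites.
#'
#' @param sites data.frame of sites as from [read_vcf()]`$sites`.
#' @param cfg A [filter_config()].
#' @return The retained subset of `sites`, same columns, original order.
#' @examples
#' s <- data.frame(contig = "c1", pos = 1:3, ref = "A",
#'                 alt = c("T", "T", "ATT"), qual = c(60, 80, 90),
#'                 depth = c(30L, 30L, 30L), alt_depth = 15L, aaf = 0.5)
#' filter_sites(s, filter_config())  # keeps only the qual-80 SNP
#' @export
filter_sites <- function(sites, cfg = filter_config()) {
  stopifnot(inherits(cfg, "filter_config"))
  if (nrow(sites) == 0L) return(sites)
  keep <- sites$qual >= cfg$min_qual & sites$depth <= cfg$max_depth
  if (cfg$biallelic_only) keep <- keep & !grepl(",", sites$alt, fixed = TRUE)
  if (cfg$snps_only) {
    keep <- keep & nchar(sites$ref) == 1L & nchar(sites$alt) == 1L
  }
  out <- sites[keep & !is.na(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write / read a site table as TSV
#'
#' The tab-separated site table (contig, pos, ref, alt, qual, depth,
#' alt_depth, aaf) is the pipeline's interchange format between the AAF
#' extraction stage and the tract/comparison stages.
#'
#' @param sites Site data.frame.
#' @param path Output path.
#' @return `write_aaf_tsv` returns `path` invisibly; `read_aaf_tsv` returns
#'   the site data.frame.
#' @export
write_aaf_tsv <- function(sites, path) {
  data.table::fwrite(sites, path, sep = "\t")
  invisible(path)
}

#' @rdname write_aaf_tsv
#' @export
read_aaf_tsv <- function(path) {
  as.data.frame(data.table::fread(path, sep = "\t"))
}
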