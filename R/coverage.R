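#' Read a per-base depth table
#'
#' Reads the standard 3-column per-base depth TSV (contig, 1-based
#' position, depth) as produced by `samtools depth`. Positions absent from
#' the table are treated as depth 0 when windows are built downstream.
#'
#' @param path Path to the TSV (no header).
#' @return data.table with columns `contig`, `pos`, `depth`, sorted by
#'   (contig, pos).
#' @export
read_depth_table <- function(path) {
  if (!file.exists(path)) stop("depth table not found: ", path)
  dt <- data.table::fread(path, sep = "\t", header = FALSE,
                          col.names = c("contig", "pos", "depth"),
                          colClasses = list(character = 1))
  if (!is.numeric(dt$pos) || !is.numeric(dt$depth)) {
    bad <- which(is.na(suppressWarnings(as.numeric(dt$depth))))[1L]
    stop("non-numeric depth value at line ", bad, " of ", path)
  }
  if (anyNA(dt$depth) || anyNA(dt$pos)) {
    stop("non-numeric position or depth value in ", path, " at line ",
         which(is.na(dt$depth) | is.na(dt$pos))[1L])
  }
  dt[]
}

#' Mean read depth in tiling windows
#'
#' Tiles each contig with non-overlapping windows of `window_bp` and
#' computes the mean depth over every base in the window, counting bases
#' absent from the depth table as 0. The final window of a contig may be
#' shorter and keeps its true span. The default 10 kb window puts at least
#' ten windows inside a minimum-length (100 kb) tract.
#'
#' @param depths data.table/data.frame from [read_depth_table()] (or the
#'   synthetic emitter).
#' @param contigs data.frame with columns `name`, `length`.
#' @param window_bp Window size in bp (default 10,000).
#' @return data.frame of windows: `contig`, `start`, `end` (0-based
#'   half-open), `mean_depth`.
#' @export
window_coverage <- function(depths, contigs, window_bp = 10000) {
  stopifnot(window_bp > 0)
  dt <- data.table::as.data.table(depths)
  out <- lapply(seq_len(nrow(contigs)), function(i) {
    nm <- contigs$name[i]
    L <- as.integer(contigs$length[i])
    n_win <- ceiling(L / window_bp)
    starts <- (seq_len(n_win) - 1L) * window_bp
    ends <- pmin(starts + window_bp, L)
    d <- dt[dt$contig == nm & dt$pos >= 1L & dt$pos <= L, ]
    sums <- rep(0, n_win)
    if (nrow(d)) {
      win <- (d$pos - 1L) %/% window_bp + 1L
      agg <- tapply(d$depth, win, sum)
      sums[as.integer(names(agg))] <- agg
    }
    data.frame(contig = nm, start = as.integer(starts),
               end = as.integer(ends),
               mean_depth = sums / (ends - starts),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Test candidate LOH tracts for coverage doubling
#'
#' In a diploid assembly, a region whose two homozygous haplotypes have
#' collapsed into a single contig receives the reads of both alleles and
#' shows roughly twice the per-allele baseline coverage. This test computes,
#' for each candidate tract, the ratio of its mean window depth to a
#' genome-wide baseline, and flags the tract as collapsed when the ratio
#' falls inside `ratio_window`.
#'
#' The baseline is the median of window means over windows that do not
#' overlap any tract (robust to residual repeats); it can be overridden.
#' The default acceptance interval \[1.6, 2.4\] tolerates Poisson depth
#' noise and mapping edge effects at ~20--75x combined depth. The whole
#' test is scale-invariant: multiplying all depths by a constant changes
#' no ratio.
#'
#' @param windows Window data.frame from [window_coverage()].
#' @param tracts Tract data.frame (see [detect_tracts()]).
#' @param ratio_window Length-2 numeric interval for calling a tract
#'   collapsed (default `c(1.6, 2.4)`).
#' @param baseline Optional baseline depth; computed from out-of-tract
#'   windows when `NULL`.
#' @return data.frame, one row per tract: tract columns plus `n_windows`
#'   (windows fully inside the tract), `tract_mean_depth`,
#'   `tract_mean_ratio`, `is_collapsed`, and `baseline`. Tracts containing
#'   no complete window get `NA` ratio and `is_collapsed = NA` (flagged,
#'   not guessed).
#' @export
doubling_test <- function(windows, tracts, ratio_window = c(1.6, 2.4),
                          baseline = NULL) {
  stopifnot(length(ratio_window) == 2L, ratio_window[1] < ratio_window[2])
  in_tract <- rep(FALSE, nrow(windows))
  for (i in seq_len(nrow(tracts))) {
    in_tract <- in_tract | (windows$contig == tracts$contig[i] &
                              windows$end > tracts$start[i] &
                              windows$start < tracts$end[i])
  }
  if (is.null(baseline)) {
    baseline <- stats::median(windows$mean_depth[!in_tract])
  }
  if (!is.finite(baseline) || baseline <= 0) {
    stop("coverage baseline must be positive (no out-of-tract windows?)")
  }
  res <- lapply(seq_len(nrow(tracts)), function(i) {
    w <- windows[windows$contig == tracts$contig[i] &
                   windows$start >= tracts$start[i] &
                   windows$end <= tracts$end[i], , drop = FALSE]
    if (nrow(w) == 0L) {
      data.frame(n_windows = 0L, tract_mean_depth = NA_real_,
                 tract_mean_ratio = NA_real_, is_collapsed = NA)
    } else {
      m <- mean(w$mean_depth)
      r <- m / baseline
      data.frame(n_windows = nrow(w), tract_mean_depth = m,
                 tract_mean_ratio = r,
                 is_collapsed = r >= ratio_window[1] & r <= ratio_window[2])
    }
  })
  out <- cbind(tracts, do.call(rbind, res))
  out$baseline <- baseline
  rownames(out) <- NULL
  out
}
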