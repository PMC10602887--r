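#' Stitch peaks into candidate super-enhancer regions
#'
#' Rank-ordering super-enhancer analysis first merges peaks whose gaps are
#' at most `stitch_bp` (transitively) into stitched regions spanning the
#' minimum start to the maximum end of their constituents. The defaults
#' (12,500 bp stitch distance, optional exclusion of peaks fully inside
#' TSS +/- 2,500 bp) follow the published rank-ordering conventions.
#'
#' @param peaks `interval_set` of enhancer peaks (typically H3K4me1 or
#'   H3K27Ac).
#' @param stitch_bp maximum gap merged (positive integer; default 12500).
#' @param tss_exclusion optional `gene_records`; when given, peaks fully
#'   inside `tss +/- tss_window_bp` are dropped before stitching.
#' @param tss_window_bp half-width of the exclusion zone (default 2500).
#' @return A `stitched_regions` data.frame: `region_id`, `chrom`, `start`,
#'   `end`, `n_constituents`, `constituent_ids` (comma-separated), and
#'   placeholder `signal`, `rank`, `is_super` columns filled by
#'   [score_regions()] and [rank_and_cut()].
#' @export
stitch_peaks <- function(peaks, stitch_bp = 12500L, tss_exclusion = NULL,
                         tss_window_bp = 2500L) {
  stitch_bp <- as.integer(stitch_bp)
  if (is.na(stitch_bp) || stitch_bp <= 0L) stop("stitch_bp must be positive")
  ids <- peaks$name
  if (is.null(ids) || all(is.na(ids)))
    ids <- paste0("peak_", seq_len(nrow(peaks)))
  if (!is.null(tss_exclusion) && nrow(peaks) > 0L) {
    w <- as.integer(tss_window_bp)
    zones <- interval_set(tss_exclusion$chrom,
                          pmax(tss_exclusion$tss - w, 0L),
                          tss_exclusion$tss + w + 1L)
    gp <- as_granges(peaks)
    gz <- as_granges(zones)
    within <- GenomicRanges::countOverlaps(gp, gz, type = "within",
                                           ignore.strand = TRUE) > 0L
    peaks <- peaks[!within, , drop = FALSE]
    ids <- ids[!within]
  }
  if (nrow(peaks) == 0L) {
    empty <- data.frame(region_id = character(0), chrom = character(0),
                        start = integer(0), end = integer(0),
                        n_constituents = integer(0),
                        constituent_ids = character(0), signal = numeric(0),
                        rank = integer(0), is_super = logical(0),
                        stringsAsFactors = FALSE)
    class(empty) <- c("stitched_regions", "data.frame")
    return(empty)
  }
  gp <- as_granges(peaks)
  # gap <= stitch_bp merges; reduce() merges gaps < min.gapwidth
  merged <- GenomicRanges::reduce(gp, min.gapwidth = stitch_bp + 1L,
                                  ignore.strand = TRUE)
  # every peak lies within exactly one merged region
  memb <- GenomicRanges::findOverlaps(gp, merged, type = "within",
                                      ignore.strand = TRUE)
  by_region <- split(ids[S4Vectors::queryHits(memb)],
                     S4Vectors::subjectHits(memb))
  n <- length(merged)
  constituents <- character(n)
  counts <- integer(n)
  for (r in names(by_region)) {
    i <- as.integer(r)
    constituents[i] <- paste(by_region[[r]], collapse = ",")
    counts[i] <- length(by_region[[r]])
  }
  out <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(merged)),
    start = GenomicRanges::start(merged) - 1L,  # back to 0-based half-open
    end = GenomicRanges::end(merged),
    n_constituents = counts,
    constituent_ids = constituents,
    signal = NA_real_,
    rank = NA_integer_,
    is_super = NA,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out <- cbind(region_id = sprintf("region_%04d", seq_len(n)), out,
               stringsAsFactors = FALSE)
  class(out) <- c("stitched_regions", "data.frame")
  out
}

#' Score stitched regions by total normalized coverage
#'
#' Signal is the total normalized coverage over the region; when a control
#' track is given its total is subtracted and the result floored at zero.
#'
#' @param regions a `stitched_regions` data.frame.
#' @param track a depth-normalized `coverage_track`.
#' @param control optional control `coverage_track` (also normalized).
#' @return `regions` with the `signal` column filled.
#' @export
score_regions <- function(regions, track, control = NULL) {
  if (!track$normalized)
    stop("ranking signal requires a depth-normalized track")
  sig <- region_totals(track, regions)
  if (!is.null(control)) {
    if (!control$normalized) stop("control track must be normalized")
    sig <- pmax(sig - region_totals(control, regions), 0)
  }
  regions$signal <- sig
  regions
}

#' Rank regions and call super-enhancers by the tangent cutoff
#'
#' Regions are sorted by ascending signal; rank and signal are each
#' rescaled to `[0, 1]` and the cutoff is the signal at the point where the
#' rescaled curve has slope one, found by minimizing
#' `rescaled_signal - rescaled_rank` along the curve (latest rank on ties).
#' Regions with signal strictly above the cutoff are super-enhancers; ties
#' at the cutoff are not.
#'
#' @param regions scored `stitched_regions` (at least 3 regions with a
#'   non-zero signal range; degenerate inputs yield zero calls with a
#'   warning).
#' @return `regions` with `rank` (1 = lowest signal) and `is_super` filled,
#'   plus a `cutoff` attribute: list with `cutoff_signal`,
#'   `cutoff_rescaled`, `n_super`, `n_total`.
#' @export
rank_and_cut <- function(regions) {
  n <- nrow(regions)
  if (n == 0L) stop("no regions to rank")
  if (any(is.na(regions$signal)))
    stop("regions are unscored; run score_regions() first")
  o <- order(regions$signal, regions$chrom, regions$start)
  regions$rank[o] <- seq_len(n)
  s <- regions$signal[o]
  if (n < 3L || max(s) - min(s) <= 0) {
    warning("degenerate rank curve (n < 3 or flat signal); no SE called")
    regions$is_super <- FALSE
    attr(regions, "cutoff") <- list(cutoff_signal = NA_real_,
                                    cutoff_rescaled = NA_real_,
                                    n_super = 0L, n_total = n)
    return(regions)
  }
  x <- (seq_len(n) - 1) / (n - 1)
  y <- (s - min(s)) / (max(s) - min(s))
  gap <- y - x
  i_star <- max(which(gap == min(gap)))  # latest rank achieving the minimum
  cutoff_signal <- s[i_star]
  regions$is_super <- regions$signal > cutoff_signal
  attr(regions, "cutoff") <- list(
    cutoff_signal = cutoff_signal,
    cutoff_rescaled = y[i_star],
    n_super = sum(regions$is_super),
    n_total = n
  )
  regions
}

#' Write super-enhancer calls as BED6+ plus a cutoff JSON
#'
#' Columns: chrom, start, end, region_id, signal, ".", rank, is_super.
#'
#' @param regions ranked `stitched_regions` (after [rank_and_cut()]).
#' @param bed_path,json_path output paths (either may be `NULL`).
#' @return Written paths, invisibly.
#' @export
write_se_calls <- function(regions, bed_path = NULL, json_path = NULL) {
  if (!is.null(bed_path)) {
    lines <- sprintf("%s\t%d\t%d\t%s\t%.17g\t.\t%d\t%d",
                     regions$chrom, regions$start, regions$end,
                     regions$region_id, regions$signal, regions$rank,
                     as.integer(regions$is_super))
    writeLines(lines, bed_path)
  }
  if (!is.null(json_path))
    jsonlite::write_json(attr(regions, "cutoff"), json_path,
                         auto_unbox = TRUE, digits = NA)
  invisible(c(bed_path, json_path))
}
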