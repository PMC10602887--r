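#' Call enhancers and classify them AR-positive
#'
#' Enhancers are defined operationally as H3K4me1 peaks; an enhancer is
#' AR-positive when it overlaps at least one AR ChIP-seq peak (in the study
#' design, AR peaks at 4 h of androgen induction in parental cells).
#'
#' @param h3k4me1_peaks `interval_set` of H3K4me1 peaks.
#' @param ar_peaks `interval_set` of AR peaks.
#' @param min_overlap_bp minimum shared bases for a positive call.
#' @return An `enhancer_calls` data.frame: `enhancer_id`, `chrom`, `start`,
#'   `end`, `ar_positive`, `ar_peak_ids` (comma-separated, empty when
#'   negative).
#' @export
call_enhancers <- function(h3k4me1_peaks, ar_peaks, min_overlap_bp = 1L) {
  if (nrow(h3k4me1_peaks) == 0L) {
    warning("empty H3K4me1 peak set; no enhancers called")
    out <- data.frame(enhancer_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      ar_positive = logical(0), ar_peak_ids = character(0),
                      stringsAsFactors = FALSE)
    class(out) <- c("enhancer_calls", "data.frame")
    return(out)
  }
  ids <- h3k4me1_peaks$name
  if (is.null(ids) || all(is.na(ids)))
    ids <- paste0("enh_", seq_len(nrow(h3k4me1_peaks)))
  ar_ids <- ar_peaks$name
  if (is.null(ar_ids) || all(is.na(ar_ids)))
    ar_ids <- paste0("ar_", seq_len(nrow(ar_peaks)))
  hit_ids <- character(nrow(h3k4me1_peaks))
  if (nrow(ar_peaks) > 0L) {
    hits <- GenomicRanges::findOverlaps(
      as_granges(h3k4me1_peaks), as_granges(ar_peaks),
      minoverlap = as.integer(min_overlap_bp), ignore.strand = TRUE
    )
    by_enh <- split(ar_ids[S4Vectors::subjectHits(hits)],
                    S4Vectors::queryHits(hits))
    for (q in names(by_enh))
      hit_ids[as.integer(q)] <- paste(by_enh[[q]], collapse = ",")
  }
  out <- data.frame(
    enhancer_id = ids,
    chrom = h3k4me1_peaks$chrom,
    start = h3k4me1_peaks$start,
    end = h3k4me1_peaks$end,
    ar_positive = nzchar(hit_ids),
    ar_peak_ids = hit_ids,
    stringsAsFactors = FALSE
  )
  class(out) <- c("enhancer_calls", "data.frame")
  out
}

#' Link each gene to its nearest (AR-positive) enhancer
#'
#' The gene anchor is its TSS; the distance to an enhancer is 0 when the TSS
#' lies inside it and otherwise the distance to the nearest covered base
#' (see [point_interval_distance()]). Ties are broken by smaller enhancer
#' start, then smaller enhancer id. Genes with no eligible enhancer on their
#' chromosome yield no link and are counted in the `n_unlinked` attribute.
#'
#' @param genes a `gene_records` data.frame.
#' @param enhancers an `enhancer_calls` data.frame.
#' @param require_ar_positive restrict to AR-positive enhancers (default).
#' @param same_chromosome_only restrict links to the gene's chromosome
#'   (default); the alternative is not implemented as cross-chromosome
#'   distances are undefined here.
#' @return An `enhancer_links` data.frame: `gene_id`, `enhancer_id`,
#'   `enhancer_chrom`, `enhancer_start`, `enhancer_end`, `distance_bp`,
#'   `direction` (`upstream`/`downstream`/`overlapping` relative to gene
#'   strand).
#' @export
link_nearest <- function(genes, enhancers, require_ar_positive = TRUE,
                         same_chromosome_only = TRUE) {
  if (!same_chromosome_only)
    stop("cross-chromosome linking is not supported")
  elig <- enhancers
  if (require_ar_positive)
    elig <- elig[elig$ar_positive, , drop = FALSE]
  rows <- vector("list", nrow(genes))
  n_unlinked <- 0L
  for (i in seq_len(nrow(genes))) {
    e <- elig[elig$chrom == genes$chrom[i], , drop = FALSE]
    if (nrow(e) == 0L) { n_unlinked <- n_unlinked + 1L; next }
    p <- genes$tss[i]
    d <- point_interval_distance(p, e$start, e$end)
    best <- order(d, e$start, e$enhancer_id)[1L]
    dir <- if (d[best] == 0L) {
      "overlapping"
    } else {
      genomically_left <- e$end[best] - 1L < p
      if (genes$strand[i] == "+") {
        if (genomically_left) "upstream" else "downstream"
      } else {
        if (genomically_left) "downstream" else "upstream"
      }
    }
    rows[[i]] <- data.frame(
      gene_id = genes$gene_id[i],
      enhancer_id = e$enhancer_id[best],
      enhancer_chrom = e$chrom[best],
      enhancer_start = e$start[best],
      enhancer_end = e$end[best],
      distance_bp = d[best],
      direction = dir,
      stringsAsFactors = FALSE
    )
  }
  rows <- rows[!vapply(rows, is.null, TRUE)]
  out <- if (length(rows)) do.call(rbind, rows) else data.frame(
    gene_id = character(0), enhancer_id = character(0),
    enhancer_chrom = character(0), enhancer_start = integer(0),
    enhancer_end = integer(0), distance_bp = integer(0),
    direction = character(0), stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  if (n_unlinked > 0L)
    message(n_unlinked, " gene(s) had no eligible enhancer on their ",
            "chromosome and were not linked")
  attr(out, "n_unlinked") <- n_unlinked
  class(out) <- c("enhancer_links", "data.frame")
  out
}

#' Summarize enhancer-gene link distances
#'
#' The headline quantity is the median TSS-to-enhancer distance of a
#' regulated gene set; the median uses linear interpolation for even n.
#'
#' @param links an `enhancer_links` data.frame with at least one link.
#' @return A list with `n`, `median_distance_bp`, `mean_distance_bp`,
#'   `fraction_overlapping`.
#' @export
link_summary <- function(links) {
  if (nrow(links) == 0L) stop("no links to summarize")
  list(
    n = nrow(links),
    median_distance_bp = stats::median(links$distance_bp),
    mean_distance_bp = mean(links$distance_bp),
    fraction_overlapping = mean(links$direction == "overlapping")
  )
}

#' Write enhancer links as TSV plus a JSON summary
#'
#' @param links an `enhancer_links` data.frame.
#' @param tsv_path,json_path output paths (either may be `NULL` to skip).
#' @return Written paths, invisibly.
#' @export
write_links <- function(links, tsv_path = NULL, json_path = NULL) {
  if (!is.null(tsv_path))
    utils::write.table(links, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(link_summary(links), json_path,
                         auto_unbox = TRUE, digits = NA)
  invisible(c(tsv_path, json_path))
}
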