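#' Geometric-mean aggregate profile
#'
#' Aggregates the rows of a profile matrix into one per-bin geometric mean,
#' the robust summary used for all metaplots: a handful of extreme regions
#' moves the geometric mean far less than the arithmetic mean. Coverage
#' contains exact zeros, so a symmetric pseudocount is applied: per bin j,
#' `GM_j = exp(mean(log(x_ij + pseudocount))) - pseudocount` over unmasked
#' rows. Subtracting the pseudocount restores the zero fixed point (all-zero
#' bins aggregate to 0).
#'
#' @param matrix a `profile_matrix` with at least one row.
#' @param pseudocount strictly positive value in signal units (default 1).
#' @return An `aggregate_profile`: data.frame with columns `bin`,
#'   `bin_offset` (bp from anchor, or body fraction label for metagene
#'   matrices), `gm` and `n` (unmasked rows per bin; bins with `n = 0` are
#'   masked as `NA`). Pseudocount and provenance stored as attributes.
#' @export
geometric_profile <- function(matrix, pseudocount = 1.0) {
  m <- matrix$values
  if (is.null(m) || nrow(m) == 0L) stop("empty profile matrix")
  if (!is.numeric(pseudocount) || pseudocount <= 0)
    stop("pseudocount must be strictly positive")
  n <- colSums(!is.na(m))
  gm <- exp(colMeans(log(m + pseudocount), na.rm = TRUE)) - pseudocount
  gm[n == 0L] <- NA_real_
  out <- data.frame(
    bin = seq_len(ncol(m)),
    bin_offset = matrix$bin_offsets,
    gm = gm,
    n = n
  )
  attr(out, "pseudocount") <- pseudocount
  attr(out, "anchor_mode") <- matrix$anchor_mode
  attr(out, "label") <- matrix$label
  class(out) <- c("aggregate_profile", "data.frame")
  out
}

#' Metagene profile matrix with scaled gene bodies
#'
#' Each gene contributes one row: a fixed upstream flank binned at native
#' resolution, a body rescaled to `body_bins` bins, and a fixed downstream
#' flank. Body bins use fractional apportionment: each base contributes to a
#' body bin proportionally to its overlap with the bin's span of
#' `length / body_bins` bp, so genes shorter than `body_bins` bases remain
#' well-defined (a warning is logged). Minus-strand rows are reversed so
#' column order is always 5' (upstream) to 3' (downstream). Flank bins
#' extending past a chromosome end are masked.
#'
#' @param track a `coverage_track`.
#' @param genes a `gene_records` data.frame (stranded).
#' @param body_bins number of scaled body bins (default 100).
#' @param flank_bp fixed flank in bp added on both sides (default 1000).
#' @param flank_bin_width bin width for the flanks (divides `flank_bp`).
#' @return A `profile_matrix` with `anchor_mode = "metagene"`; `bin_offsets`
#'   are bp offsets (negative upstream) for flank bins and body-fraction
#'   midpoints scaled onto `[0, flank-equivalent]` for body bins (see
#'   `segment` attribute for the flank/body/flank split).
#' @export
metagene_matrix <- function(track, genes, body_bins = 100L,
                            flank_bp = 1000L, flank_bin_width = 10L) {
  body_bins <- as.integer(body_bins)
  flank_bp <- as.integer(flank_bp)
  flank_bin_width <- as.integer(flank_bin_width)
  if (body_bins <= 0L || flank_bp <= 0L || flank_bin_width <= 0L)
    stop("body_bins, flank_bp and flank_bin_width must be positive")
  if (flank_bp %% flank_bin_width != 0L)
    stop("flank_bp must be divisible by flank_bin_width")
  if (any(!genes$strand %in% c("+", "-")))
    stop("metagene requires stranded genes")
  short <- genes$end - genes$start < body_bins
  if (any(short))
    warning(sum(short), " gene(s) shorter than body_bins bases; ",
            "fractional apportionment still applies")
  fb <- flank_bp %/% flank_bin_width
  n_cols <- 2L * fb + body_bins
  m <- matrix(NA_real_, nrow = nrow(genes), ncol = n_cols)
  cum <- lapply(track$values, function(v) c(0, cumsum(v)))
  for (i in seq_len(nrow(genes))) {
    v <- track$values[[genes$chrom[i]]]
    if (is.null(v)) stop("unknown chromosome: ", genes$chrom[i])
    C <- cum[[genes$chrom[i]]]
    L <- length(v)
    gs <- genes$start[i]; ge <- genes$end[i]
    if (gs < 0L || ge > L) stop("gene ", genes$gene_id[i],
                                " outside chromosome bounds")
    left <- seg_means(C, v, L,
                      gs - flank_bp + flank_bin_width * (seq_len(fb) - 1L),
                      gs - flank_bp + flank_bin_width * seq_len(fb))
    bodyb <- gs + (ge - gs) * (0:body_bins) / body_bins
    body <- seg_means(C, v, L, bodyb[-(body_bins + 1L)], bodyb[-1L])
    right <- seg_means(C, v, L,
                       ge + flank_bin_width * (seq_len(fb) - 1L),
                       ge + flank_bin_width * seq_len(fb))
    row <- c(left, body, right)
    if (genes$strand[i] == "-") row <- rev(row)
    m[i, ] <- row
  }
  offsets <- c(
    seq(-flank_bp, -flank_bin_width, by = flank_bin_width),
    (seq_len(body_bins) - 0.5) / body_bins,            # body fraction midpoint
    seq(1, flank_bp - flank_bin_width + 1, by = flank_bin_width)
  )
  structure(
    list(values = m,
         bin_offsets = offsets,
         bin_width = flank_bin_width,
         anchor_mode = "metagene",
         segment = rep(c("upstream", "body", "downstream"),
                       c(fb, body_bins, fb)),
         region_ids = genes$gene_id,
         label = track$label),
    class = "profile_matrix"
  )
}

# Mean of the per-base step function over real segments [a_k, b_k) on one
# chromosome. I(t) integrates coverage from 0 to t; segments touching the
# outside of [0, L] are masked.
seg_means <- function(C, v, L, a, b) {
  integ <- function(t) {
    f <- floor(t)
    base <- C[pmin(pmax(f, 0), L) + 1L]
    frac <- t - f
    extra <- ifelse(frac > 0 & f >= 0 & f < L, frac * v[f + 1L], 0)
    base + extra
  }
  out <- (integ(b) - integ(a)) / (b - a)
  out[a < 0 | b > L] <- NA_real_
  out
}

#' Background-relative enrichment of an aggregate profile
#'
#' Summarizes a point-centered profile as fold enrichment over local
#' background: `(center - background) / background`, where the center is
#' the bin nearest `center_offset` and the background is the median of the
#' outermost `background_fraction` of bins on each side. Fold enrichment is
#' invariant under depth rescaling, so it is comparable across tracks with
#' different library sizes — the right unit for amplitude ratios between
#' genotypes.
#'
#' @param profile an `aggregate_profile` from a point-centered matrix.
#' @param center_offset bp offset of the bin treated as the peak center.
#' @param background_fraction fraction of bins at each edge used as
#'   background (default 0.2).
#' @return A list with `center`, `background`, `enrichment`.
#' @export
profile_enrichment <- function(profile, center_offset = 0,
                               background_fraction = 0.2) {
  ok <- !is.na(profile$gm)
  if (!any(ok)) stop("profile is fully masked")
  nb <- max(1L, floor(background_fraction * nrow(profile)))
  edge <- c(utils::head(which(ok), nb), utils::tail(which(ok), nb))
  bg <- stats::median(profile$gm[edge])
  center_bin <- which.min(abs(profile$bin_offset - center_offset))
  center <- profile$gm[center_bin]
  if (is.na(center)) stop("center bin is masked")
  if (bg <= 0) stop("non-positive background; enrichment undefined")
  list(center = center, background = bg,
       enrichment = (center - bg) / bg)
}

#' Five-number boxplot summary of region totals
#'
#' Quartiles use linear interpolation between order statistics
#' (`quantile(type = 7)`); whiskers extend to the most extreme data points
#' within 1.5 IQR of the quartiles, and values beyond them are listed as
#' outliers.
#'
#' @param totals numeric vector of per-region totals for one condition.
#' @return A list with `n`, `median`, `q1`, `q3`, `whisker_low`,
#'   `whisker_high`, `outliers`.
#' @export
boxplot_summary <- function(totals) {
  if (length(totals) == 0L) stop("empty input")
  q <- unname(stats::quantile(totals, c(0.25, 0.5, 0.75), type = 7))
  iqr <- q[3] - q[1]
  lo_fence <- q[1] - 1.5 * iqr
  hi_fence <- q[3] + 1.5 * iqr
  inside <- totals[totals >= lo_fence & totals <= hi_fence]
  list(
    n = length(totals),
    median = q[2], q1 = q[1], q3 = q[3],
    whisker_low = min(inside), whisker_high = max(inside),
    outliers = sort(totals[totals < lo_fence | totals > hi_fence])
  )
}

#' Superimpose aggregate profiles in long format
#'
#' Combines profiles sharing the same bin geometry (same offsets) into one
#' long table for overlay charts; no numeric transformation is applied.
#'
#' @param profiles named list of `aggregate_profile` objects; names become
#'   condition labels.
#' @param path optional TSV output path (columns `condition`, `bin`,
#'   `bin_offset`, `gm`, `n`; masked bins written as `NA`).
#' @return The long data.frame, invisibly when `path` is given.
#' @export
overlay_profiles <- function(profiles, path = NULL) {
  if (length(profiles) == 0L) stop("no profiles to overlay")
  if (is.null(names(profiles)) || any(!nzchar(names(profiles))))
    stop("profiles must be a named list (condition labels)")
  ref <- profiles[[1L]]$bin_offset
  for (p in profiles) {
    if (length(p$bin_offset) != length(ref) ||
        any(abs(p$bin_offset - ref) > 1e-9))
      stop("profiles have mismatched bin geometry")
  }
  long <- do.call(rbind, lapply(names(profiles), function(cond) {
    p <- profiles[[cond]]
    data.frame(condition = cond, bin = p$bin, bin_offset = p$bin_offset,
               gm = p$gm, n = p$n, stringsAsFactors = FALSE)
  }))
  rownames(long) <- NULL
  if (!is.null(path)) {
    utils::write.table(format_profile_table(long), path, sep = "\t",
                       quote = FALSE, row.names = FALSE, na = "NA")
    return(invisible(long))
  }
  long
}

format_profile_table <- function(long) {
  long$gm <- ifelse(is.na(long$gm), NA, sprintf("%.17g", long$gm))
  long$bin_offset <- sprintf("%.17g", long$bin_offset)
  long
}

#' Read a profile overlay TSV back into a long data.frame
#'
#' @param path TSV written by [overlay_profiles()].
#' @return Long data.frame with `condition`, `bin`, `bin_offset`, `gm`, `n`.
#' @export
read_profile_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(condition = "character"))
}

#' Plot superimposed profiles
#'
#' Thin optional layer over [overlay_profiles()] output; requires ggplot2.
#'
#' @param long long-format profile table.
#' @return A ggplot object.
#' @export
plot_profiles <- function(long) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$bin_offset, y = .data$gm,
                                     colour = .data$condition)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "offset from anchor (bp)",
                  y = "geometric mean coverage") +
    ggplot2::theme_minimal()
}
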