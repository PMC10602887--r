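#' Paired-sample t-test on aligned region totals
#'
#' The accessibility comparison between two conditions over one region set:
#' totals are aligned by region identity, differences `d = x - y` are
#' tested with a two-sided paired Student t-test
#' (`t = mean(d) / (sd(d) / sqrt(n))`, df `= n - 1`). Zero-variance inputs
#' are handled explicitly: all-zero differences give `t = 0, p = 1`;
#' constant non-zero differences are degenerate and raise an error rather
#' than reporting `p = 0`, to surface pathological inputs.
#'
#' @param x,y numeric vectors of per-region totals (same length, aligned by
#'   region; `n >= 2`).
#' @param comparison free-form label (region set, timepoint, genotype pair).
#' @param p_threshold optional per-test significance threshold (e.g. from
#'   [bonferroni_threshold()]); fills the `significant` field.
#' @return A `paired_test_result` list: `comparison`, `n`, `mean_difference`,
#'   `t`, `df`, `p`, `threshold`, `significant`.
#' @export
paired_t_test <- function(x, y, comparison = "", p_threshold = NULL) {
  if (length(x) != length(y))
    stop("x and y must be aligned vectors of equal length")
  if (length(x) < 2L) stop("paired t-test needs n >= 2 pairs")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("non-finite totals in input")
  d <- x - y
  if (stats::sd(d) == 0) {
    if (mean(d) == 0) {
      t_stat <- 0; p <- 1
    } else {
      stop("degenerate input: constant non-zero paired differences")
    }
  } else {
    tt <- stats::t.test(x, y, paired = TRUE, alternative = "two.sided")
    t_stat <- unname(tt$statistic)
    p <- tt$p.value
  }
  structure(
    list(comparison = comparison,
         n = length(x),
         mean_difference = mean(d),
         t = t_stat,
         df = length(x) - 1L,
         p = p,
         threshold = if (is.null(p_threshold)) NA_real_ else p_threshold,
         significant = if (is.null(p_threshold)) NA else p < p_threshold),
    class = "paired_test_result"
  )
}

#' @export
print.paired_test_result <- function(x, ...) {
  cat("paired t-test", if (nzchar(x$comparison)) paste0("[", x$comparison, "]"),
      "\n  n =", x$n, "| mean diff =", signif(x$mean_difference, 4),
      "| t =", signif(x$t, 5), "| df =", x$df,
      "| p =", signif(x$p, 4), "\n")
  if (!is.na(x$threshold))
    cat("  threshold =", x$threshold, "| significant:", x$significant, "\n")
  invisible(x)
}

#' Bonferroni per-test threshold
#'
#' Family-wise error control over `m` tests at level `alpha`: each test is
#' judged at `alpha / m`.
#'
#' @param alpha family-wise significance level in (0, 1).
#' @param m number of tests (positive integer).
#' @return The per-test threshold `alpha / m`.
#' @export
bonferroni_threshold <- function(alpha, m) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must be in (0, 1)")
  if (!is.numeric(m) || m < 1 || m != round(m))
    stop("m must be a positive integer")
  alpha / m
}

#' Run a paired test from two aligned region-total tables
#'
#' File-level surface: each table has columns `region_id` and `total`; rows
#' are aligned by `region_id` (an error if the id sets differ).
#'
#' @param path_x,path_y TSV paths.
#' @param comparison label for the comparison.
#' @param p_threshold optional per-test threshold.
#' @param json_path optional output path for the JSON result.
#' @return A `paired_test_result`.
#' @export
paired_t_test_files <- function(path_x, path_y, comparison = "",
                                p_threshold = NULL, json_path = NULL) {
  read_totals <- function(p) {
    df <- utils::read.delim(p, stringsAsFactors = FALSE)
    if (!all(c("region_id", "total") %in% names(df)))
      stop("totals table ", p, " needs columns region_id, total")
    df
  }
  a <- read_totals(path_x)
  b <- read_totals(path_y)
  if (!setequal(a$region_id, b$region_id))
    stop("region id sets differ between the two tables")
  b <- b[match(a$region_id, b$region_id), , drop = FALSE]
  res <- paired_t_test(a$total, b$total, comparison = comparison,
                       p_threshold = p_threshold)
  if (!is.null(json_path))
    jsonlite::write_json(unclass(res), json_path, auto_unbox = TRUE,
                         digits = NA)
  res
}
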