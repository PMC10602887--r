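#' Read a differential-expression result table
#'
#' Consumes DESeq2-style result tables (TSV or CSV). Column matching is
#' case-insensitive: the gene identifier is taken from a `gene_id`-like
#' column (or the first column), the effect from `log2FoldChange` and the
#' adjusted p-value from `padj`.
#'
#' @param path input file; `.csv` is comma-separated, anything else
#'   tab-separated.
#' @param id_aliases,lfc_aliases,padj_aliases acceptable column names
#'   (case-insensitive).
#' @return A data.frame with columns `gene_id`, `log2_fold_change`, `padj`.
#' @export
read_de_table <- function(path,
                          id_aliases = c("gene_id", "gene", "id"),
                          lfc_aliases = c("log2foldchange", "log2fc", "lfc"),
                          padj_aliases = c("padj", "p_adjusted", "fdr")) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  low <- tolower(names(df))
  pick <- function(aliases, default = NA_integer_) {
    hit <- which(low %in% aliases)
    if (length(hit)) hit[1L] else default
  }
  id_col <- pick(id_aliases, 1L)
  lfc_col <- pick(lfc_aliases)
  padj_col <- pick(padj_aliases)
  if (is.na(lfc_col)) stop("no log2 fold change column found in ", path)
  if (is.na(padj_col)) stop("no adjusted p-value column found in ", path)
  data.frame(
    gene_id = as.character(df[[id_col]]),
    log2_fold_change = as.numeric(df[[lfc_col]]),
    padj = as.numeric(df[[padj_col]]),
    stringsAsFactors = FALSE
  )
}

#' Filter a DE table into up- and down-regulated gene sets
#'
#' Selection follows the at-least-k-fold rule with strict adjusted-p cutoff:
#' up-regulated genes have `log2_fold_change >= log2(fold_threshold)` and
#' `padj < alpha`; down-regulated genes are symmetric. Records with missing
#' adjusted p-values (independent-filtering artifacts of upstream tools) are
#' excluded and counted.
#'
#' @param table data.frame with `gene_id`, `log2_fold_change`, `padj`
#'   (see [read_de_table()]); one record per gene.
#' @param fold_threshold linear fold change, `>= 1` (default 2).
#' @param alpha adjusted-p cutoff in (0, 1), strict (default 0.05).
#' @param contrast label for the contrast (timepoint/genotype).
#' @return A `regulated_sets` list: `up` and `down` character vectors of
#'   gene ids (disjoint by construction), `contrast`, `thresholds`,
#'   `n_missing_padj`.
#' @export
filter_de <- function(table, fold_threshold = 2.0, alpha = 0.05,
                      contrast = "") {
  if (nrow(table) == 0L) stop("empty DE table")
  if (is.null(table$log2_fold_change)) {  # accept DESeq2-style column names
    hit <- which(tolower(names(table)) %in% c("log2foldchange", "log2fc"))
    if (length(hit) == 0L) stop("no log2 fold change column in DE table")
    table$log2_fold_change <- table[[hit[1L]]]
  }
  if (is.null(table$padj)) stop("no padj column in DE table")
  if (!is.numeric(fold_threshold) || fold_threshold < 1)
    stop("fold_threshold must be >= 1")
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must be in (0, 1)")
  dup <- duplicated(table$gene_id)
  if (any(dup))
    stop("duplicate gene_id in DE table: ", table$gene_id[which(dup)[1L]])
  missing_p <- is.na(table$padj)
  if (any(missing_p))
    message(sum(missing_p), " record(s) with missing padj excluded")
  t2 <- table[!missing_p, , drop = FALSE]
  lfc_cut <- log2(fold_threshold)
  sig <- t2$padj < alpha
  structure(
    list(
      up = t2$gene_id[sig & t2$log2_fold_change >= lfc_cut],
      down = t2$gene_id[sig & t2$log2_fold_change <= -lfc_cut],
      contrast = contrast,
      thresholds = list(fold = fold_threshold, alpha = alpha),
      n_missing_padj = sum(missing_p)
    ),
    class = "regulated_sets"
  )
}

#' @export
print.regulated_sets <- function(x, ...) {
  cat("regulated_sets", if (nzchar(x$contrast)) paste0("[", x$contrast, "]"),
      "\n  up:", length(x$up), "| down:", length(x$down),
      "| thresholds: fold >=", x$thresholds$fold,
      ", padj <", x$thresholds$alpha, "\n")
  invisible(x)
}

#' Disjoint intersection cells of several regulated-gene sets
#'
#' For k sets, enumerates all `2^k - 1` membership combinations (the cells
#' of a Venn diagram) with exact gene memberships; cell counts sum to the
#' size of the union.
#'
#' @param sets named list of two or more `regulated_sets`.
#' @param direction `"up"` or `"down"`: which gene set of each contrast to
#'   compare.
#' @return A data.frame with one row per cell: logical membership columns
#'   (one per input set), `n`, and a `genes` list-column.
#' @export
set_overlap <- function(sets, direction = c("up", "down")) {
  direction <- match.arg(direction)
  if (length(sets) < 2L) stop("set_overlap needs at least 2 sets")
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("sets must be named")
  members <- lapply(sets, function(s) unique(s[[direction]]))
  universe <- unique(unlist(members))
  k <- length(sets)
  inset <- vapply(members, function(m) universe %in% m,
                  logical(length(universe)))
  if (length(universe) == 1L) inset <- matrix(inset, nrow = 1L)
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), k))[-1L, , drop = FALSE]
  names(combos) <- names(sets)
  rownames(combos) <- NULL
  genes <- lapply(seq_len(nrow(combos)), function(i) {
    want <- as.logical(combos[i, ])
    if (length(universe) == 0L) return(character(0))
    hit <- apply(inset, 1L, function(row) all(row == want))
    sort(universe[hit])
  })
  combos$n <- lengths(genes)
  combos$genes <- genes
  combos
}

#' Write gene lists and a JSON summary for a regulated set
#'
#' @param sets a `regulated_sets` object.
#' @param dir output directory (created if needed).
#' @param prefix file name prefix.
#' @return Paths of the written files, invisibly.
#' @export
write_regulated_sets <- function(sets, dir, prefix = sets$contrast) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!nzchar(prefix)) prefix <- "contrast"
  up_path <- file.path(dir, paste0(prefix, "_up.txt"))
  down_path <- file.path(dir, paste0(prefix, "_down.txt"))
  json_path <- file.path(dir, paste0(prefix, "_summary.json"))
  writeLines(sets$up, up_path)
  writeLines(sets$down, down_path)
  jsonlite::write_json(
    list(contrast = sets$contrast, n_up = length(sets$up),
         n_down = length(sets$down), thresholds = sets$thresholds,
         n_missing_padj = sets$n_missing_padj),
    json_path, auto_unbox = TRUE, digits = NA
  )
  invisible(c(up_path, down_path, json_path))
}
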