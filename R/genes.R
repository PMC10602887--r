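#' Read gene models from a TSV or GTF file
#'
#' Returns one record per gene with strand-aware TSS and TES anchors: for a
#' `+` strand gene over `[start, end)` the TSS is `start` and the TES is
#' `end - 1`; for a `-` strand gene the roles swap. Metagene and TSS-anchored
#' profiles require orientation, so unstranded genes are rejected.
#'
#' @param path path to the gene model file.
#' @param format `"tsv"` (header `gene_id, chrom, start, end, strand`,
#'   0-based half-open) or `"gtf"` (1-based inclusive; only `gene`-typed
#'   records are used, converted to half-open on read).
#' @return A `data.frame` with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`, `tss`, `tes`, class `gene_records`.
#' @export
read_gene_models <- function(path, format = c("tsv", "gtf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("gene model file not found: ", path)
  if (format == "tsv") {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("gene_id", "chrom", "start", "end", "strand")
    miss <- setdiff(need, names(df))
    if (length(miss))
      stop("gene TSV is missing column(s): ", paste(miss, collapse = ", "))
    df <- df[, need]
  } else {
    gr <- rtracklayer::import(path, format = "gtf")
    gr <- gr[S4Vectors::mcols(gr)$type == "gene"]
    df <- data.frame(
      gene_id = as.character(S4Vectors::mcols(gr)$gene_id),
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1L,  # to 0-based half-open
      end = GenomicRanges::end(gr),
      strand = as.character(GenomicRanges::strand(gr)),
      stringsAsFactors = FALSE
    )
  }
  gene_records(df$gene_id, df$chrom, df$start, df$end, df$strand)
}

#' Construct gene records with TSS/TES anchors
#'
#' @param gene_id unique gene identifiers.
#' @param chrom chromosome names.
#' @param start,end 0-based half-open gene body coordinates.
#' @param strand `"+"` or `"-"` (unstranded genes are rejected).
#' @return A `gene_records` data.frame; see [read_gene_models()].
#' @export
gene_records <- function(gene_id, chrom, start, end, strand) {
  df <- data.frame(
    gene_id = as.character(gene_id),
    chrom = as.character(chrom),
    start = as.integer(start),
    end = as.integer(end),
    strand = as.character(strand),
    stringsAsFactors = FALSE
  )
  if (any(!df$strand %in% c("+", "-")))
    stop("unstranded gene(s): ",
         paste(utils::head(df$gene_id[!df$strand %in% c("+", "-")], 3),
               collapse = ", "),
         " (metagene anchoring requires orientation)")
  dup <- duplicated(df$gene_id)
  if (any(dup))
    stop("duplicate gene_id: ", df$gene_id[which(dup)[1L]])
  if (any(!(df$start >= 0L & df$start < df$end)))
    stop("invalid gene coordinates (need 0 <= start < end)")
  df$tss <- ifelse(df$strand == "+", df$start, df$end - 1L)
  df$tes <- ifelse(df$strand == "+", df$end - 1L, df$start)
  class(df) <- c("gene_records", "data.frame")
  df
}

#' Write gene records as the package's gene TSV format
#'
#' @param genes a `gene_records` data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(genes, path) {
  utils::write.table(
    genes[, c("gene_id", "chrom", "start", "end", "strand")],
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' TSS anchors of genes as width-1 intervals
#'
#' Convenience for TSS-centered profile extraction: each gene contributes a
#' one-base interval at its TSS carrying the gene's strand, so minus-strand
#' rows are mirrored into 5'-to-3' orientation by [extract_matrix()].
#'
#' @param genes a `gene_records` data.frame.
#' @return An `interval_set` of width-1 TSS intervals.
#' @export
tss_anchors <- function(genes) {
  interval_set(genes$chrom, genes$tss, genes$tss + 1L,
               name = genes$gene_id, strand = genes$strand,
               provenance = "tss")
}
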