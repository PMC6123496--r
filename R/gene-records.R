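#' Build a gene record table with genomic order
#'
#' Assigns each gene its rank in the chromosome-then-position sort
#' (`order_index`). Only this ordering, never base-pair distance, is used
#' by the sliding-window copy-number inference. Coordinates are treated as
#' 1-based inclusive.
#'
#' @param gene_id,chromosome,start equal-length vectors.
#' @return data.frame with columns `gene_id`, `chromosome`, `start`,
#'   `order_index`, sorted by `order_index`.
#' @export
gene_records <- function(gene_id, chromosome, start) {
  gene_id <- as.character(gene_id)
  if (anyDuplicated(gene_id))
    stop("duplicate gene id: ", gene_id[duplicated(gene_id)][1])
  df <- data.frame(gene_id = gene_id, chromosome = as.character(chromosome),
                   start = as.numeric(start), stringsAsFactors = FALSE)
  ord <- order(chromosome_rank(df$chromosome), df$start, df$gene_id)
  df <- df[ord, , drop = FALSE]
  df$order_index <- seq_len(nrow(df))
  rownames(df) <- NULL
  df
}

#' Read a BED-like gene position table
#'
#' Tab-separated with columns `gene_id`, `chromosome`, `start` (header
#' optional, detected by a non-numeric third field on line one).
#'
#' @param path file path.
#' @return see [gene_records()].
#' @export
read_gene_positions <- function(path) {
  if (!file.exists(path)) stop("gene position file not found: ", path)
  first <- strsplit(readLines(path, n = 1), "\t")[[1]]
  has_header <- is.na(suppressWarnings(as.numeric(first[3])))
  df <- utils::read.delim(path, header = has_header, stringsAsFactors = FALSE)
  gene_records(df[[1]], df[[2]], df[[3]])
}

#' Read a WES copy-number segment table
#'
#' BED-like TSV with columns `chromosome`, `start`, `end`, `call`
#' (gain/loss/neutral), `mean_copy`. Segments are consumed, never computed,
#' by this package.
#'
#' @param path file path.
#' @return data.frame of segments.
#' @export
read_segments <- function(path) {
  if (!file.exists(path)) stop("segment file not found: ", path)
  first <- strsplit(readLines(path, n = 1), "\t")[[1]]
  has_header <- is.na(suppressWarnings(as.numeric(first[2])))
  df <- utils::read.delim(path, header = has_header, stringsAsFactors = FALSE)
  colnames(df)[1:5] <- c("chromosome", "start", "end", "call", "mean_copy")
  segment_table(df$chromosome, df$start, df$end, df$call, df$mean_copy)
}

#' Construct a validated segment table
#'
#' @param chromosome,start,end,call,mean_copy equal-length vectors; `call`
#'   in gain/loss/neutral; `start < end`; segments on one chromosome must
#'   not overlap.
#' @return data.frame of segments.
#' @export
segment_table <- function(chromosome, start, end, call,
                          mean_copy = rep(NA_real_, length(start))) {
  call <- as.character(call)
  bad <- setdiff(unique(call), c("gain", "loss", "neutral"))
  if (length(bad) > 0) stop("unknown segment call: ", bad[1])
  df <- data.frame(chromosome = as.character(chromosome),
                   start = as.numeric(start), end = as.numeric(end),
                   call = call, mean_copy = as.numeric(mean_copy),
                   stringsAsFactors = FALSE)
  if (any(df$start >= df$end)) stop("segment with start >= end")
  for (chr in unique(df$chromosome)) {
    seg <- df[df$chromosome == chr, , drop = FALSE]
    seg <- seg[order(seg$start), , drop = FALSE]
    if (nrow(seg) > 1 && any(seg$start[-1] < seg$end[-nrow(seg)]))
      stop("overlapping segments on chromosome ", chr)
  }
  df
}

#' Genes falling inside called segments
#'
#' Maps WES segments to the gene universe: a gene is selected when its
#' start position lies within (inclusive) any segment carrying the
#' requested call. Segments on chromosomes absent from the gene table are
#' skipped with a message.
#'
#' @param segments a segment table (see [segment_table()]).
#' @param genes a gene record table (see [gene_records()]).
#' @param call segment call to select, default `"gain"`.
#' @return character vector of gene ids.
#' @export
genes_in_segments <- function(segments, genes, call = "gain") {
  seg <- segments[segments$call == call, , drop = FALSE]
  unknown <- setdiff(unique(seg$chromosome), unique(genes$chromosome))
  if (length(unknown) > 0)
    message("genes_in_segments: skipping segments on unknown chromosomes: ",
            paste(unknown, collapse = ", "))
  hits <- character(0)
  for (i in seq_len(nrow(seg))) {
    inside <- genes$chromosome == seg$chromosome[i] &
      genes$start >= seg$start[i] & genes$start <= seg$end[i]
    hits <- c(hits, genes$gene_id[inside])
  }
  unique(hits)
}
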