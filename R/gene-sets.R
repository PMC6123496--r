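#' Gene signature
#'
#' A named gene set. Directional signatures carry paired up/down lists and
#' are scored as mean(up) - mean(down); undirected signatures have an empty
#' down list and are scored as mean(up).
#'
#' @param name signature name.
#' @param up_genes non-empty character vector.
#' @param down_genes character vector, possibly empty.
#' @param directional logical; defaults to `length(down_genes) > 0`.
#' @return an object of class `GeneSignature`.
#' @export
gene_signature <- function(name, up_genes, down_genes = character(0),
                           directional = length(down_genes) > 0) {
  up_genes <- unique(as.character(up_genes))
  down_genes <- unique(as.character(down_genes))
  if (length(up_genes) == 0) stop("signature '", name, "' has no up genes")
  if (length(intersect(up_genes, down_genes)) > 0)
    stop("signature '", name, "' has genes in both up and down lists")
  structure(list(name = as.character(name), up_genes = up_genes,
                 down_genes = down_genes, directional = isTRUE(directional)),
            class = "GeneSignature")
}

#' @export
print.GeneSignature <- function(x, ...) {
  cat("GeneSignature '", x$name, "': ", length(x$up_genes), " up",
      if (x$directional) paste0(", ", length(x$down_genes), " down") else "",
      "\n", sep = "")
  invisible(x)
}

#' Read gene signatures from a GMT file
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then gene ids. Entries named `X_UP` and `X_DN` are paired into a single
#' directional signature `X`; all other entries become undirected
#' signatures. An `X_DN` entry without its `X_UP` partner is an error.
#'
#' @param path GMT file path.
#' @return named list of [gene_signature()] objects.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  entries <- lapply(lines, function(ln) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stop("GMT entry '", f[1], "' has an empty gene list")
    genes <- unique(f[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (length(genes) == 0) stop("GMT entry '", f[1], "' has an empty gene list")
    list(name = f[1], genes = genes)
  })
  names(entries) <- vapply(entries, `[[`, character(1), "name")
  if (anyDuplicated(names(entries)))
    stop("duplicate GMT entry name: ", names(entries)[duplicated(names(entries))][1])
  is_up <- grepl("_UP$", names(entries))
  is_dn <- grepl("_DN$", names(entries))
  base_up <- sub("_UP$", "", names(entries)[is_up])
  base_dn <- sub("_DN$", "", names(entries)[is_dn])
  orphan_dn <- setdiff(base_dn, base_up)
  if (length(orphan_dn) > 0)
    stop("GMT entry '", orphan_dn[1], "_DN' has no matching '", orphan_dn[1], "_UP'")
  sigs <- list()
  for (b in base_up) {
    dn <- if (b %in% base_dn) entries[[paste0(b, "_DN")]]$genes else character(0)
    sigs[[b]] <- gene_signature(b, entries[[paste0(b, "_UP")]]$genes, dn,
                                directional = TRUE)
  }
  plain <- names(entries)[!is_up & !is_dn]
  for (nm in plain) sigs[[nm]] <- gene_signature(nm, entries[[nm]]$genes)
  sigs
}

#' Write gene signatures to a GMT file
#'
#' Directional signatures are emitted as paired `_UP`/`_DN` lines so that
#' [read_gmt()] round-trips them.
#'
#' @param signatures list of `GeneSignature` objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(signatures, path) {
  lines <- character(0)
  for (s in signatures) {
    if (s$directional && length(s$down_genes) > 0) {
      lines <- c(lines,
                 paste(c(paste0(s$name, "_UP"), "na", s$up_genes), collapse = "\t"),
                 paste(c(paste0(s$name, "_DN"), "na", s$down_genes), collapse = "\t"))
    } else {
      lines <- c(lines, paste(c(s$name, "na", s$up_genes), collapse = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}
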