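## Plain-text I/O: TSV matrices and tables, GMT gene sets, minimal GFF3
## chromosome extraction. Tab delimiter, no quoting, '.' decimal; floats
## serialized with 10 significant digits so checksums are stable.

fmt_num <- function(x) {
  if (is.double(x)) formatC(x, digits = 10, format = "g") else as.character(x)
}

#' Write a numeric matrix as TSV (genes x samples)
#'
#' First column holds row ids under the header \code{gene_id}; remaining
#' columns are samples.
#'
#' @param m matrix with dimnames.
#' @param path output file.
#' @export
write_matrix_tsv <- function(m, path) {
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' Read a TSV matrix written by [write_matrix_tsv()]
#' @param path input file.
#' @return numeric matrix with gene ids as rownames.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("matrix TSV needs an id column plus >= 1 sample: ", path)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  if (anyDuplicated(rownames(m))) stop("duplicate gene ids in ", path)
  if (anyDuplicated(colnames(m))) stop("duplicate sample ids in ", path)
  m
}

#' Write a data.frame as TSV (no quoting, no row names)
#' @param df data.frame.
#' @param path output file.
#' @export
write_tsv <- function(df, path) {
  df2 <- df
  for (j in seq_along(df2)) if (is.double(df2[[j]])) df2[[j]] <- fmt_num(df2[[j]])
  utils::write.table(df2, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "NA")
  invisible(path)
}

#' Read a sample-design table
#'
#' Expects columns \code{sample_id}, \code{lineage}, \code{state}.
#' @param path TSV file.
#' @return data.frame.
#' @export
read_design <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "lineage", "state")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("design file missing column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(d$sample_id)) stop("duplicate sample_id in design")
  d
}

#' Read a gene annotation table (gene_id, chromosome)
#' @param path TSV file, or a GFF3 file (see \code{format}).
#' @param format \code{"tsv"} (default) or \code{"gff3"}: for GFF3, gene
#'   features' \code{ID}/\code{gene_id} attribute is mapped to column 1
#'   (seqid).
#' @return data.frame with \code{gene_id}, \code{chromosome}.
#' @export
read_annotation <- function(path, format = c("tsv", "gff3")) {
  format <- match.arg(format)
  if (format == "tsv") {
    a <- utils::read.delim(path, stringsAsFactors = FALSE)
    if (!all(c("gene_id", "chromosome") %in% names(a)))
      stop("annotation TSV must have columns gene_id, chromosome")
    return(a[, c("gene_id", "chromosome")])
  }
  ln <- readLines(path)
  ln <- ln[!startsWith(ln, "#") & nzchar(ln)]
  fields <- strsplit(ln, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 9L)
  if (length(bad)) stop("malformed GFF3 line ", bad[1L], " in ", path)
  keep <- vapply(fields, function(f) f[3L] == "gene", logical(1))
  fields <- fields[keep]
  gid <- vapply(fields, function(f) {
    attrs <- strsplit(f[9L], ";", fixed = TRUE)[[1L]]
    kv <- strsplit(attrs, "=", fixed = TRUE)
    for (p in kv) if (p[1L] %in% c("ID", "gene_id")) return(p[2L])
    NA_character_
  }, character(1))
  chr <- vapply(fields, `[`, character(1), 1L)
  ok <- !is.na(gid)
  unique(data.frame(gene_id = sub("^gene:", "", gid[ok]),
                    chromosome = chr[ok], stringsAsFactors = FALSE))
}

#' Read gene sets in GMT format
#'
#' One set per line: name, description, then tab-separated gene ids.
#' Membership is deduplicated.
#'
#' @param path GMT file.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  ln <- readLines(path)
  ln <- ln[nzchar(ln)]
  out <- list()
  for (i in seq_along(ln)) {
    f <- strsplit(ln[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop("malformed GMT line ", i, ": need name, description, >= 1 gene")
    out[[f[1L]]] <- unique(f[-(1:2)])
  }
  out
}

#' Write gene sets in GMT format
#' @param sets named list of character vectors.
#' @param path output file.
#' @param descriptions optional per-set description strings.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], unique(sets[[i]])),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
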