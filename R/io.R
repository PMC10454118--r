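# File-format boundaries: FASTA / BED6 / GFF3 / TSV writers and readers, and
# lightweight format validation with line-level diagnostics.

#' Write a genome (or any sequence set) as wrapped FASTA
#'
#' @param x DNAStringSet, toy_genome, or named character vector.
#' @param path output path.
#' @param width line wrap (default 60 columns).
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(x, path, width = 60) {
  Biostrings::writeXStringSet(as_genome_seqs(x), path, width = width)
  invisible(path)
}

#' Write features as BED6
#'
#' The feature kind and id are encoded in the BED name field as `kind|id`;
#' coordinates are converted to the BED 0-based half-open convention.
#'
#' @param features GRanges with `kind` and `id` metadata columns.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_features_bed <- function(features, path) {
  gr <- features
  S4Vectors::mcols(gr) <- NULL
  names(gr) <- paste(S4Vectors::mcols(features)$kind,
                     S4Vectors::mcols(features)$id, sep = "|")
  S4Vectors::mcols(gr)$score <- 0L
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read a BED6 feature file written by [write_features_bed()]
#'
#' @param path BED file path.
#' @return GRanges with `kind` and `id` metadata columns.
#' @export
read_features_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  nm <- S4Vectors::mcols(gr)$name
  parts <- strsplit(nm, "|", fixed = TRUE)
  S4Vectors::mcols(gr) <- NULL
  S4Vectors::mcols(gr)$kind <- vapply(parts, `[`, "", 1)
  S4Vectors::mcols(gr)$id <- vapply(parts, `[`, "", 2)
  gr
}

#' Write features as GFF3
#'
#' The internal feature set is converted on write: the kind becomes the GFF3
#' type (repeat classes become `repeat_region` with the class in an
#' attribute) and the id becomes `ID`.
#'
#' @param features GRanges with `kind` and `id` metadata columns.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_features_gff3 <- function(features, path) {
  gr <- features
  kind <- S4Vectors::mcols(gr)$kind
  id <- S4Vectors::mcols(gr)$id
  S4Vectors::mcols(gr) <- NULL
  S4Vectors::mcols(gr)$source <- "eccpipe"
  S4Vectors::mcols(gr)$type <- ifelse(startsWith(kind, "repeat:"),
                                      "repeat_region", kind)
  S4Vectors::mcols(gr)$ID <- id
  cls <- sub("^repeat:", "", kind)
  S4Vectors::mcols(gr)$repeat_class <- ifelse(startsWith(kind, "repeat:"),
                                              cls, NA_character_)
  rtracklayer::export(gr, path, format = "GFF3")
  invisible(path)
}

#' Write a TMM expression matrix as TSV
#'
#' @param tmm gene x condition matrix with dimnames.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(tmm, path) {
  df <- data.frame(gene_id = rownames(tmm), tmm, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv_file(df, path)
  invisible(path)
}

#' Read a TMM expression TSV
#'
#' @param path TSV with a `gene_id` column and one column per condition.
#' @return gene x condition numeric matrix.
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, setdiff(names(df), "gene_id"), drop = FALSE])
  rownames(m) <- df$gene_id
  m
}

#' Validate an input file against a format
#'
#' Lightweight conformance checks with first-offending-line diagnostics.
#' BED is checked as 0-based half-open 6-column; FASTA for structure and
#' duplicate ids; GFF3 for the 9-column layout and 1-based closed
#' coordinates; TSV for a rectangular layout with a header.
#'
#' @param path file path (must exist).
#' @param format one of `"FASTA"`, `"BED6"`, `"GFF3"`, `"TSV"`.
#' @return list with `ok` (logical) and, on failure, `line` and `message`.
#' @export
validate_io <- function(path, format = c("FASTA", "BED6", "GFF3", "TSV")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  fail <- function(i, msg) list(ok = FALSE, line = i, message = msg)

  if (format == "FASTA") {
    ids <- character(0)
    seen_seq <- TRUE
    for (i in seq_along(lines)) {
      ln <- lines[i]
      if (startsWith(ln, ">")) {
        if (!seen_seq) return(fail(i, "header with no preceding sequence"))
        id <- sub("^>(\\S+).*", "\\1", ln)
        if (id %in% ids) return(fail(i, paste0("duplicate id: ", id)))
        ids <- c(ids, id)
        seen_seq <- FALSE
      } else {
        if (!length(ids)) return(fail(i, "sequence before first header"))
        if (!nzchar(ln)) return(fail(i, "empty sequence line"))
        if (grepl("[^A-Za-z*-]", ln)) return(fail(i, "invalid sequence characters"))
        seen_seq <- TRUE
      }
    }
    if (!length(ids)) return(fail(0L, "no records"))
    if (!seen_seq) return(fail(length(lines), "trailing header with no sequence"))
  } else if (format %in% c("BED6", "GFF3")) {
    body <- which(!startsWith(lines, "#") & nzchar(lines))
    need <- if (format == "BED6") 6L else 9L
    for (i in body) {
      f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
      if (length(f) < need)
        return(fail(i, sprintf("expected %d tab-separated fields, got %d",
                               need, length(f))))
      st <- suppressWarnings(as.numeric(f[if (format == "BED6") 2 else 4]))
      en <- suppressWarnings(as.numeric(f[if (format == "BED6") 3 else 5]))
      if (is.na(st) || is.na(en))
        return(fail(i, "non-numeric coordinates"))
      if (format == "BED6" && (st < 0 || st >= en))
        return(fail(i, "BED requires 0 <= start < end (0-based half-open)"))
      if (format == "GFF3" && (st < 1 || st > en))
        return(fail(i, "GFF3 requires 1 <= start <= end (1-based closed)"))
      strand_field <- f[if (format == "BED6") 6 else 7]
      if (!strand_field %in% c("+", "-", ".", "?"))
        return(fail(i, paste0("invalid strand: ", strand_field)))
    }
  } else { # TSV
    if (!length(lines)) return(fail(0L, "empty file"))
    ncol0 <- length(strsplit(lines[1], "\t", fixed = TRUE)[[1]])
    if (ncol0 < 1 || !nzchar(lines[1])) return(fail(1L, "missing header"))
    for (i in seq_along(lines)[-1]) {
      if (!nzchar(lines[i])) next
      nc <- length(strsplit(lines[i], "\t", fixed = TRUE)[[1]])
      if (nc != ncol0)
        return(fail(i, sprintf("expected %d fields, got %d", ncol0, nc)))
    }
  }
  list(ok = TRUE)
}
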