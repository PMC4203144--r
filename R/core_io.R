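#' @useDynLib mirheat, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

RNA_BASES <- c("A", "C", "G", "U")

#' Normalize a nucleotide string to the RNA alphabet
#'
#' Uppercases and converts T to U. All internal sequence handling in this
#' package is on the RNA alphabet \{A, C, G, U\}; DNA reads (cDNAs, ESTs)
#' are converted at the boundary. N is tolerated (ambiguity) but any
#' scanning/folding window containing N is excluded downstream.
#'
#' @param x character vector of nucleotide strings.
#' @return character vector over \{A,C,G,U,N\}.
#' @export
normalize_rna <- function(x) {
  out <- chartr("acgutT", "ACGUUU", x)
  bad <- grepl("[^ACGUN]", out)
  if (any(bad)) {
    stop("non-ACGUN symbol in sequence(s): ",
         paste(which(bad), collapse = ", "))
  }
  out
}

#' Read a FASTA file into sequence records
#'
#' Parses FASTA via Biostrings and returns one record per entry, in file
#' order, with residues normalized to the RNA alphabet. A record whose raw
#' residues contained T is flagged `moltype = "DNA-as-read"`, otherwise
#' `"RNA"`.
#'
#' @param path path to a FASTA file.
#' @return data.frame with columns `id`, `description`, `residues`,
#'   `moltype`, `has_n`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("malformed FASTA in ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(set) == 0L) {
    return(data.frame(id = character(), description = character(),
                      residues = character(), moltype = character(),
                      has_n = logical(), stringsAsFactors = FALSE))
  }
  raw <- as.character(set)
  headers <- names(set)
  id <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (any(nchar(raw) == 0L)) {
    stop("empty sequence for record(s): ",
         paste(id[nchar(raw) == 0L], collapse = ", "))
  }
  if (anyDuplicated(id)) {
    stop("duplicate FASTA id(s): ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  moltype <- ifelse(grepl("[Tt]", raw), "DNA-as-read", "RNA")
  residues <- normalize_rna(raw)
  data.frame(id = id, description = desc, residues = residues,
             moltype = moltype, has_n = grepl("N", residues),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write sequence records to FASTA
#'
#' @param records data.frame with at least `id` and `residues` columns
#'   (as returned by [read_fasta()]), or a named character vector.
#' @param path output path.
#' @param width line-wrap width (residues per line), default 70.
#' @export
write_fasta <- function(records, path, width = 70L) {
  if (is.character(records)) {
    records <- data.frame(id = names(records), description = "",
                          residues = unname(records),
                          stringsAsFactors = FALSE)
  }
  stopifnot(width >= 1L)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    hdr <- records$id[i]
    d <- if (!is.null(records$description)) records$description[i] else ""
    if (nzchar(d)) hdr <- paste(hdr, d)
    writeLines(paste0(">", hdr), con)
    s <- records$residues[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Reverse complement of an RNA string
#'
#' A-U, G-C complementarity on the RNA alphabet; N maps to N.
#'
#' @param residues character vector of ACGUN strings.
#' @return reverse complement(s), same lengths.
#' @export
reverse_complement <- function(residues) {
  if (any(grepl("[^ACGUN]", residues))) {
    stop("reverse_complement: non-ACGUN symbol")
  }
  vapply(residues, function(s) {
    paste(rev(strsplit(chartr("ACGUN", "UGCAN", s), "", fixed = TRUE)[[1]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Complement (no reversal) of an RNA string
#' @param residues ACGUN strings.
#' @return complement strings.
#' @export
complement_rna <- function(residues) {
  if (any(grepl("[^ACGUN]", residues))) stop("complement_rna: non-ACGUN symbol")
  chartr("ACGUN", "UGCAN", residues)
}

#' Read a TSV with a required column contract
#' @param path file path.
#' @param required character vector of column names that must be present.
#' @return data.frame.
#' @export
read_tsv_checked <- function(path, required = character()) {
  if (!file.exists(path)) stop("TSV file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          comment.char = "#", check.names = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    stop("TSV ", path, " missing column(s): ", paste(miss, collapse = ", "))
  }
  df
}

#' Write a data.frame as TSV
#' @param df data.frame. @param path output path.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
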