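# Core sequence / alignment types and FASTA I/O.
#
# A `seq_set` is a named character vector of ungapped, uppercase protein
# sequences; an `msa` wraps a character matrix (rows = sequences, one symbol
# per cell, gap = "-").  File parsing goes through Biostrings.

# 20 canonical residues + ambiguity codes; B, Z, X score as the wildcard.
AA_CANONICAL <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
AA_AMBIGUOUS <- c("B", "Z", "X")
AA_ALPHA <- c(AA_CANONICAL, AA_AMBIGUOUS)
GAP <- "-"

#' Construct a validated sequence set
#'
#' @param x Named character vector of protein sequences (ids as names), or a
#'   list coercible to one.
#' @return A `seq_set`: named character vector of uppercase, ungapped
#'   sequences.
#' @examples
#' seq_set(c(a = "PEPTIDE", b = "PEPTIDE"))
#' @export
seq_set <- function(x) {
  ids <- names(x)
  x <- vapply(x, as.character, character(1), USE.NAMES = FALSE)
  names(x) <- ids
  if (is.null(ids) || any(!nzchar(ids))) {
    stop("every sequence needs a non-empty id", call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    stop("duplicate sequence id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  x <- toupper(x)
  x <- gsub("\\*$", "", x)  # trailing stop symbols are cosmetic
  for (k in seq_along(x)) {
    sym <- strsplit(x[[k]], "")[[1]]
    if (length(sym) < 1) stop("sequence '", ids[k], "' is empty", call. = FALSE)
    bad <- which(!(sym %in% AA_ALPHA))
    if (length(bad)) {
      stop("sequence '", ids[k], "': symbol '", sym[bad[1]],
           "' at position ", bad[1], " outside the amino-acid alphabet",
           call. = FALSE)
    }
  }
  structure(x, class = "seq_set")
}

#' @export
print.seq_set <- function(x, ...) {
  cat("seq_set of", length(x), "sequences; lengths",
      paste(range(nchar(x)), collapse = "-"), "\n")
  invisible(x)
}

#' @export
`[.seq_set` <- function(x, i) {
  structure(unclass(x)[i], class = "seq_set")
}

#' Construct a validated multiple alignment
#'
#' @param rows Named character vector of equal-length gapped rows, or a
#'   character matrix with one symbol per cell (rownames = ids).
#' @return An `msa` object: a character matrix with class attribute, gap
#'   symbol `"-"`, no all-gap columns.
#' @examples
#' msa(c(a = "AC-D", b = "ACCD"))
#' @export
msa <- function(rows) {
  if (is.matrix(rows)) {
    mat <- rows
  } else {
    rows <- vapply(rows, as.character, character(1))
    if (length(unique(nchar(rows))) != 1) {
      stop("alignment rows have unequal lengths", call. = FALSE)
    }
    mat <- do.call(rbind, strsplit(toupper(rows), ""))
    rownames(mat) <- names(rows)
  }
  mat[mat == "."] <- GAP
  ids <- rownames(mat)
  if (is.null(ids) || anyDuplicated(ids)) {
    stop("alignment rows need unique ids", call. = FALSE)
  }
  if (ncol(mat) < 1) stop("alignment has no columns", call. = FALSE)
  res <- mat != GAP
  if (any(colSums(res) == 0)) {
    stop("alignment contains an all-gap column", call. = FALSE)
  }
  bad <- which(!(mat %in% c(AA_ALPHA, GAP)))
  if (length(bad)) {
    stop("alignment symbol '", mat[bad[1]], "' outside the alphabet",
         call. = FALSE)
  }
  structure(mat, class = c("msa", "matrix"))
}

#' @export
print.msa <- function(x, ...) {
  cat("msa:", nrow(x), "sequences x", ncol(x), "columns\n")
  rows <- msa_strings(x)
  show <- utils::head(rows, 8)
  wide <- nchar(show[1]) > 60
  for (id in names(show)) {
    cat(sprintf("%-12s %s%s\n", id, substr(show[[id]], 1, 60),
                if (wide) "..." else ""))
  }
  if (length(rows) > 8) cat("...\n")
  invisible(x)
}

#' Alignment rows as gapped strings
#' @param aln An `msa`.
#' @return Named character vector of gapped rows.
#' @export
msa_strings <- function(aln) {
  setNames(apply(unclass(aln), 1, paste, collapse = ""), rownames(aln))
}

#' Remove gaps from alignment rows
#' @param aln An `msa` (or named character vector of gapped strings).
#' @return The underlying `seq_set`.
#' @export
degap <- function(aln) {
  rows <- if (is.matrix(aln)) msa_strings(aln) else aln
  seq_set(gsub("[-.]", "", rows))
}

#' Drop columns made entirely of gaps
#' @param mat Character matrix of alignment symbols.
#' @return The matrix without all-gap columns (at least one column kept by
#'   construction of valid inputs).
#' @keywords internal
drop_allgap_cols <- function(mat) {
  keep <- colSums(mat != GAP) > 0
  mat[, keep, drop = FALSE]
}

#' Read sequences or an alignment from FASTA
#'
#' @param path Path to a FASTA file (or connection readable by Biostrings).
#' @param aligned If `FALSE` (default) gap characters are an error and a
#'   [seq_set()] is returned; if `TRUE` rows are returned as an [msa()]
#'   (`.` normalized to `-`).
#' @return A `seq_set` or an `msa`.
#' @export
read_fasta <- function(path, aligned = FALSE) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) stop("empty FASTA file: ", path, call. = FALSE)
  txt <- as.character(set)
  # headers: keep the first whitespace-delimited token, like most tools
  names(txt) <- sub("\\s.*$", "", names(txt))
  if (anyDuplicated(names(txt))) {
    stop("duplicate sequence id(s) in ", path, ": ",
         paste(unique(names(txt)[duplicated(names(txt))]), collapse = ", "),
         call. = FALSE)
  }
  if (aligned) {
    return(msa(txt))
  }
  gappy <- grepl("[-.]", txt)
  if (any(gappy)) {
    bad <- which(gappy)[1]
    stop("record '", names(txt)[bad], "' contains gap symbols; ",
         "use aligned = TRUE to read an alignment", call. = FALSE)
  }
  seq_set(txt)
}

#' Write an alignment as aligned FASTA
#'
#' Rows are written in order, wrapped at 60 columns; a round-trip through
#' [read_fasta()] with `aligned = TRUE` reproduces the alignment exactly.
#'
#' @param aln An `msa`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_alignment <- function(aln, path) {
  aln <- msa(unclass(aln))  # revalidate (ragged/all-gap inputs error here)
  rows <- msa_strings(aln)
  set <- Biostrings::BStringSet(rows)
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Write an unaligned sequence set as FASTA
#' @param seqs A `seq_set`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(seqs, path) {
  set <- Biostrings::BStringSet(unclass(seqs))
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

# residue coding for the DP kernels: canonical residues 1..20, wildcard 21
encode_residues <- function(s) {
  sym <- strsplit(s, "")[[1]]
  idx <- match(sym, AA_CANONICAL)
  idx[is.na(idx)] <- 21L
  as.integer(idx)
}
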