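#' @keywords internal
"_PACKAGE"

IUPAC_NT <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
              "B", "D", "H", "V", "N", "-")
AA_CHARS <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X", "*", "-")

#' Create a sequence record
#'
#' A minimal sequence container: an identifier, a residue string and an
#' alphabet tag.  Residues are upper-cased; for nucleotide sequences `U`
#' is mapped to `T`.
#'
#' @param id Non-empty identifier.
#' @param residues Character string of residues.
#' @param alphabet `"nucleotide"` or `"amino-acid"`.
#' @return An object of class `cea_seq`.
#' @export
cea_seq <- function(id, residues, alphabet = c("nucleotide", "amino-acid")) {
  alphabet <- match.arg(alphabet)
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    stop("sequence identifier must be a non-empty string", call. = FALSE)
  residues <- toupper(residues)
  if (alphabet == "nucleotide")
    residues <- gsub("U", "T", residues, fixed = TRUE)
  ok <- if (alphabet == "nucleotide") IUPAC_NT else AA_CHARS
  bad <- setdiff(unique(strsplit(residues, "")[[1]]), ok)
  if (length(bad))
    stop(sprintf("sequence '%s' contains illegal %s character(s): %s",
                 id, alphabet, paste(bad, collapse = ", ")), call. = FALSE)
  structure(list(id = id, residues = residues, alphabet = alphabet),
            class = "cea_seq")
}

#' @export
print.cea_seq <- function(x, ...) {
  cat(sprintf("<cea_seq %s [%s], %d residues>\n", x$id, x$alphabet,
              nchar(x$residues)))
  invisible(x)
}

#' Read a FASTA file
#'
#' Records are returned in file order, residues upper-cased (and `U`
#' mapped to `T` for nucleotide data).  Malformed input raises an error
#' naming the offending line; duplicated identifiers raise an identity
#' error.
#'
#' @param path Path to a FASTA file.
#' @param alphabet `"nucleotide"` or `"amino-acid"`.
#' @return List of [cea_seq] records (empty list for an empty file).
#' @export
read_fasta <- function(path, alphabet = c("nucleotide", "amino-acid")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (!length(nonblank)) return(list())
  if (!startsWith(trimws(lines[nonblank[1]]), ">"))
    stop(sprintf("FASTA format error at line %d: expected '>' header",
                 nonblank[1]), call. = FALSE)
  ok <- if (alphabet == "nucleotide") c(IUPAC_NT, "U") else AA_CHARS
  for (i in nonblank) {
    ln <- trimws(lines[i])
    if (startsWith(ln, ">")) {
      if (!nzchar(sub("^>\\s*", "", ln)))
        stop(sprintf("FASTA format error at line %d: empty header", i),
             call. = FALSE)
    } else {
      bad <- setdiff(unique(strsplit(toupper(ln), "")[[1]]), ok)
      if (length(bad))
        stop(sprintf("FASTA format error at line %d: illegal character(s) %s",
                     i, paste(bad, collapse = ", ")), call. = FALSE)
    }
  }
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids))
    stop("duplicate sequence identifier(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  lapply(seq_along(set), function(k)
    cea_seq(ids[k], as.character(set[[k]]), alphabet))
}

#' Write sequences to a FASTA file
#'
#' Standard FASTA with 60-column line wrapping.
#'
#' @param seqs List of [cea_seq] records.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(seqs, path) {
  ids <- vapply(seqs, function(s) s$id, character(1))
  if (any(!nzchar(ids))) stop("empty sequence identifier", call. = FALSE)
  set <- Biostrings::BStringSet(vapply(seqs, function(s) s$residues,
                                       character(1)))
  names(set) <- ids
  Biostrings::writeXStringSet(set, filepath = path, width = 60L)
  invisible(path)
}

#' Translate a nucleotide sequence
#'
#' Standard genetic code; stop codons are rendered `*`, codons containing
#' an ambiguity code or gap are rendered `X`, and an incomplete trailing
#' codon is dropped.
#'
#' @param nt Nucleotide string.
#' @param frame Reading-frame offset, 0, 1 or 2.
#' @return Amino-acid string (empty when fewer than 3 nt remain).
#' @export
translate_nt <- function(nt, frame = 0L) {
  stopifnot(frame %in% 0:2)
  nt <- gsub("U", "T", toupper(nt), fixed = TRUE)
  nt <- substring(nt, frame + 1L)
  n_codon <- nchar(nt) %/% 3L
  if (n_codon == 0L) return("")
  starts <- seq(1L, by = 3L, length.out = n_codon)
  codons <- substring(nt, starts, starts + 2L)
  code <- Biostrings::GENETIC_CODE
  aa <- unname(code[codons])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' Build a codon alignment
#'
#' Rows must have equal length; a length not divisible by 3 is truncated
#' to full codons with a warning.  A codon column is masked (excluded
#' from all downstream computation) if any row carries a gap or ambiguity
#' character in it — the deterministic analogue of manual gap editing of
#' a coding alignment.
#'
#' @param rows List of nucleotide [cea_seq] records of equal length.
#' @return Object of class `codon_alignment` with elements `ids`, `mat`
#'   (character matrix, rows = sequences), `n_codon` and `mask` (logical,
#'   `TRUE` = codon column usable).
#' @export
build_codon_alignment <- function(rows) {
  if (!length(rows)) stop("empty alignment", call. = FALSE)
  lens <- vapply(rows, function(s) nchar(s$residues), integer(1))
  if (length(unique(lens)) != 1L)
    stop("alignment error: rows have unequal lengths", call. = FALSE)
  len <- lens[1]
  if (len %% 3L != 0L) {
    warning(sprintf("alignment length %d not divisible by 3; dropping %d trailing column(s)",
                    len, len %% 3L))
    len <- len - len %% 3L
  }
  ids <- vapply(rows, function(s) s$id, character(1))
  if (anyDuplicated(ids))
    stop("duplicate row identifiers", call. = FALSE)
  mat <- t(vapply(rows, function(s)
    strsplit(substr(s$residues, 1L, len), "")[[1]], character(len)))
  rownames(mat) <- ids
  n_codon <- len %/% 3L
  usable <- matrix(mat %in% c("A", "C", "G", "T"), nrow = nrow(mat))
  col_ok <- apply(usable, 2, all)
  mask <- vapply(seq_len(n_codon), function(k)
    all(col_ok[(3L * k - 2L):(3L * k)]), logical(1))
  if (!any(mask))
    warning("no usable codon columns in alignment")
  structure(list(ids = ids, mat = mat, n_codon = n_codon, mask = mask),
            class = "codon_alignment")
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat(sprintf("<codon_alignment: %d sequences x %d codons (%d masked)>\n",
              length(x$ids), x$n_codon, sum(!x$mask)))
  invisible(x)
}

# codon strings of row i over unmasked columns (internal)
aln_codons <- function(aln, i) {
  s <- paste(aln$mat[i, ], collapse = "")
  starts <- seq(1L, by = 3L, length.out = aln$n_codon)
  substring(s, starts, starts + 2L)
}
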