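#' @keywords internal
"_PACKAGE"

AA_STANDARD <- c("A","R","N","D","C","Q","E","G","H","I",
                 "L","K","M","F","P","S","T","W","Y","V")
AA_ALLOWED <- c(AA_STANDARD, "X", "-")

#' Create a sequence record
#'
#' A sequence record holds a taxon/protein label and an upper-case residue
#' string: either amino acids (the 20 standard letters plus `X` and, inside
#' alignments, the gap character `-`) or in-frame nucleotides for codon
#' sequences (length divisible by 3).
#'
#' @param id taxon/protein label.
#' @param residues residue string.
#' @param description free-text description.
#' @param codon logical; if `TRUE` the record is validated as an in-frame
#'   nucleotide sequence.
#' @param gapped logical; allow gap characters (alignment rows only).
#' @return an object of class `seq_record` with fields `id`, `residues`,
#'   `description`.
#' @export
seq_record <- function(id, residues, description = "", codon = FALSE,
                       gapped = FALSE) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  residues <- toupper(as.character(residues))
  if (!nzchar(residues)) stop("sequence '", id, "': residues must be non-empty")
  chars <- strsplit(residues, "", fixed = TRUE)[[1]]
  if (codon) {
    ok <- c("A","C","G","T","U","N", if (gapped) "-")
    bad <- which(!chars %in% ok)
    if (length(bad))
      stop("sequence '", id, "': illegal nucleotide '", chars[bad[1]],
           "' at position ", bad[1])
    if (nchar(gsub("-", "", residues, fixed = TRUE)) %% 3L != 0L)
      stop("sequence '", id, "': codon sequence length ",
           nchar(gsub("-", "", residues, fixed = TRUE)),
           " not divisible by 3")
  } else {
    ok <- if (gapped) AA_ALLOWED else setdiff(AA_ALLOWED, "-")
    bad <- which(!chars %in% ok)
    if (length(bad))
      stop("sequence '", id, "': illegal residue '", chars[bad[1]],
           "' at position ", bad[1])
  }
  structure(list(id = id, residues = residues, description = description),
            class = "seq_record")
}

#' @export
print.seq_record <- function(x, ...) {
  cat(sprintf("<seq_record> %s (%d residues)%s\n", x$id, nchar(x$residues),
              if (nzchar(x$description)) paste0(" - ", x$description) else ""))
  invisible(x)
}

#' Read sequences from a FASTA file
#'
#' Parsing is delegated to [Biostrings::readBStringSet()]; this wrapper adds
#' structural validation (empty records reported with their header line
#' number) and alphabet validation (illegal characters reported with record
#' id and position).
#'
#' @param path FASTA file.
#' @param codon_mode logical; validate records as in-frame codon sequences
#'   (length divisible by 3).
#' @param gapped logical; allow gap characters (use for alignment files).
#' @return list of [seq_record()] objects, file order preserved.
#' @export
read_fasta <- function(path, codon_mode = FALSE, gapped = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^>", lines)
  if (!length(hdr)) stop("FASTA parse error at line 1: no header lines found")
  if (hdr[1] != which(nzchar(trimws(lines)))[1])
    stop("FASTA parse error at line 1: content before first header")
  ends <- c(hdr[-1] - 1L, length(lines))
  for (k in seq_along(hdr)) {
    body <- lines[seq(hdr[k] + 1L, length.out = max(0L, ends[k] - hdr[k]))]
    if (!any(nzchar(trimws(body))))
      stop("FASTA parse error at line ", hdr[k], ": empty record '",
           sub("^>", "", lines[hdr[k]]), "'")
  }
  set <- Biostrings::readBStringSet(path)
  out <- vector("list", length(set))
  for (k in seq_along(set)) {
    nm <- names(set)[k]
    id <- strsplit(nm, "[ \t]+")[[1]][1]
    desc <- sub("^\\S+[ \t]*", "", nm)
    out[[k]] <- seq_record(id, as.character(set[[k]]), desc,
                           codon = codon_mode, gapped = gapped)
  }
  out
}

#' Write sequences to a FASTA file
#'
#' @param seqs list of [seq_record()].
#' @param path output file.
#' @export
write_fasta <- function(seqs, path) {
  seqs <- as_seq_list(seqs)
  set <- Biostrings::BStringSet(vapply(seqs, `[[`, "", "residues"))
  names(set) <- vapply(seqs, function(s)
    trimws(paste(s$id, s$description)), "")
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

as_seq_list <- function(x) {
  if (inherits(x, "seq_record")) return(list(x))
  if (is.character(x)) {
    ids <- names(x)
    if (is.null(ids)) ids <- paste0("seq", seq_along(x))
    return(mapply(seq_record, ids, x, SIMPLIFY = FALSE, USE.NAMES = FALSE))
  }
  stopifnot(is.list(x), all(vapply(x, inherits, TRUE, "seq_record")))
  x
}

#' Create a multiple sequence alignment
#'
#' @param seqs list of [seq_record()] (gapped rows) or a named character
#'   vector of equal-length gapped strings.
#' @param codon logical; rows are codon sequences.
#' @return object of class `msa`: list with `sequences` (list of
#'   `seq_record`), `L` (number of columns) and `codon` flag. Columns are
#'   1-based in all user-facing reports.
#' @export
msa <- function(seqs, codon = FALSE) {
  seqs <- if (is.character(seqs)) {
    ids <- names(seqs)
    if (is.null(ids)) ids <- paste0("seq", seq_along(seqs))
    mapply(function(i, r) seq_record(i, r, codon = codon, gapped = TRUE),
           ids, seqs, SIMPLIFY = FALSE, USE.NAMES = FALSE)
  } else as_seq_list(seqs)
  if (length(seqs) < 2L) stop("an alignment needs at least 2 rows")
  lens <- vapply(seqs, function(s) nchar(s$residues), 0L)
  if (length(unique(lens)) != 1L)
    stop("alignment rows differ in length: ",
         paste(unique(lens), collapse = ", "))
  structure(list(sequences = seqs, L = lens[1], codon = codon),
            class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("<msa> %d sequences x %d columns%s\n", length(x$sequences),
              x$L, if (x$codon) " (codon)" else ""))
  invisible(x)
}

msa_taxa <- function(aln) vapply(aln$sequences, `[[`, "", "id")

#' Alignment as a character matrix (rows = taxa, columns = sites)
#' @param aln an `msa` object.
#' @return character matrix with taxon rownames.
#' @export
msa_matrix <- function(aln) {
  m <- do.call(rbind, lapply(aln$sequences, function(s)
    strsplit(s$residues, "", fixed = TRUE)[[1]]))
  rownames(m) <- msa_taxa(aln)
  m
}

#' Read an alignment from FASTA
#' @param path FASTA file of equal-length gapped sequences.
#' @param codon_mode logical; validate as codon alignment.
#' @return an `msa` object.
#' @export
read_msa <- function(path, codon_mode = FALSE) {
  msa(read_fasta(path, codon_mode = codon_mode, gapped = TRUE),
      codon = codon_mode)
}
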