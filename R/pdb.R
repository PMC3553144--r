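#' Create a C-alpha structure
#'
#' Holds per-residue C-alpha coordinates for one model of one entry, plus
#' optional experimental B-factors (Angstrom^2) and a one-letter sequence.
#'
#' @param id PDB-style identifier (model number appended for multi-model
#'   files).
#' @param coords N x 3 numeric matrix of C-alpha coordinates in Angstrom.
#' @param sequence one-letter amino-acid string of length N (optional;
#'   defaults to poly-alanine).
#' @param bfactors optional numeric vector of N experimental B-factors.
#' @param chain chain identifier(s), recycled to N.
#' @param resno residue numbers, default `1:N`.
#' @return object of class `ca_structure`.
#' @export
ca_structure <- function(id, coords, sequence = NULL, bfactors = NULL,
                         chain = "A", resno = NULL) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (ncol(coords) != 3L) stop("coords must be N x 3")
  n <- nrow(coords)
  if (!all(is.finite(coords))) stop("coordinates must be finite")
  if (is.null(resno)) resno <- seq_len(n)
  chain <- rep_len(chain, n)
  if (is.null(sequence)) sequence <- paste(rep("A", n), collapse = "")
  if (nchar(sequence) != n)
    stop("sequence length ", nchar(sequence), " != number of residues ", n)
  if (!is.null(bfactors)) {
    bfactors <- as.numeric(bfactors)
    if (length(bfactors) != n)
      stop("bfactors length ", length(bfactors), " != ", n, " residues")
  }
  structure(list(id = id, coords = coords, sequence = sequence,
                 bfactors = bfactors,
                 residue_ids = data.frame(chain = chain, resno = resno,
                                          stringsAsFactors = FALSE)),
            class = "ca_structure")
}

#' @export
print.ca_structure <- function(x, ...) {
  cat(sprintf("<ca_structure> %s: %d residues%s\n", x$id, nrow(x$coords),
              if (!is.null(x$bfactors)) " (+B-factors)" else ""))
  invisible(x)
}

#' Read C-alpha traces from a PDB file
#'
#' Parsing is delegated to [bio3d::read.pdb()]. One `ca_structure` is
#' returned per MODEL (a single implicit model if the file has none). Only
#' `ATOM` records with atom name `CA` are used; alternate locations other
#' than blank or `A` are dropped. The B-factor column is carried into
#' `bfactors`. All chains are concatenated in file order unless `chain`
#' names a subset. Residues lacking a CA atom are skipped silently but
#' counted in the parse report attached as attribute `"parse_report"`.
#'
#' @param path PDB coordinate file.
#' @param chain optional character vector of chain identifiers to keep.
#' @return list of [ca_structure()] objects, one per model.
#' @export
read_pdb_calpha <- function(path, chain = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE,
                                          verbose = FALSE))
  at <- pdb$atom
  is_atom <- at$type == "ATOM"
  if (!is.null(chain)) is_atom <- is_atom & at$chain %in% chain
  res_key <- paste(at$chain, at$resno, at$insert)
  all_res <- unique(res_key[is_atom])
  keep <- is_atom & at$elety == "CA" &
    (is.na(at$alt) | at$alt %in% c("", "A"))
  idx <- which(keep)
  if (!length(idx)) stop("no CA atoms found in ", path)
  kk <- res_key[idx]
  if (anyDuplicated(kk))
    stop("duplicate CA after altloc filtering at residue(s): ",
         paste(unique(kk[duplicated(kk)]), collapse = ", "))
  n_missing <- length(all_res) - length(idx)
  seq1 <- paste(vapply(at$resid[idx], function(r) {
    a <- suppressWarnings(bio3d::aa321(r))
    if (is.na(a) || !a %in% AA_STANDARD) "X" else a
  }, ""), collapse = "")
  n_models <- nrow(pdb$xyz)
  base_id <- sub("\\.(pdb|ent)$", "", basename(path), ignore.case = TRUE)
  out <- vector("list", n_models)
  xyz_idx <- bio3d::atom2xyz(idx)
  for (m in seq_len(n_models)) {
    coords <- matrix(pdb$xyz[m, xyz_idx], ncol = 3, byrow = TRUE)
    if (!all(is.finite(coords))) stop("non-finite coordinates in model ", m)
    out[[m]] <- ca_structure(
      id = if (n_models > 1) paste0(base_id, "_model", m) else base_id,
      coords = coords, sequence = seq1, bfactors = at$b[idx],
      chain = at$chain[idx], resno = at$resno[idx])
  }
  attr(out, "parse_report") <- list(n_models = n_models,
                                    n_ca = length(idx),
                                    n_residues_without_ca = n_missing)
  out
}

#' Write C-alpha structures to a PDB file
#'
#' Writes one MODEL block per structure (a plain single-model file when one
#' structure is given), using [bio3d::write.pdb()] for the fixed-width ATOM
#' records.
#'
#' @param structures a `ca_structure` or list of them (same residue count).
#' @param path output file.
#' @export
write_pdb_calpha <- function(structures, path) {
  if (inherits(structures, "ca_structure")) structures <- list(structures)
  one <- function(s) {
    tmp <- tempfile(fileext = ".pdb")
    on.exit(unlink(tmp))
    b <- if (is.null(s$bfactors)) rep(0, nrow(s$coords)) else s$bfactors
    res3 <- vapply(strsplit(s$sequence, "")[[1]], function(a) {
      r <- suppressWarnings(bio3d::aa123(a))
      if (is.na(r)) "UNK" else r
    }, "")
    bio3d::write.pdb(file = tmp, xyz = as.numeric(t(s$coords)),
                     resno = s$residue_ids$resno, resid = res3,
                     chain = s$residue_ids$chain,
                     elety = rep("CA", nrow(s$coords)), b = b)
    grep("^ATOM", readLines(tmp, warn = FALSE), value = TRUE)
  }
  if (length(structures) == 1L) {
    writeLines(c(one(structures[[1]]), "END"), path)
  } else {
    lines <- character(0)
    for (m in seq_along(structures))
      lines <- c(lines, sprintf("MODEL     %4d", m), one(structures[[m]]),
                 "ENDMDL")
    writeLines(c(lines, "END"), path)
  }
  invisible(path)
}
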