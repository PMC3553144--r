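.ankevol_cache <- new.env(parent = emptyenv())

#' Substitution matrix for protein global alignment
#'
#' Loads one of the matrices shipped with Biostrings (default BLOSUM62) and,
#' following the package convention, zeroes every score involving the
#' ambiguity residue `X` so that `X` neither rewards nor penalises a match.
#'
#' @param name matrix name (e.g. "BLOSUM62", "BLOSUM50") or path to a file
#'   in NCBI matrix format.
#' @return numeric substitution matrix.
#' @export
substitution_matrix <- function(name = "BLOSUM62") {
  key <- paste0("submat_", name)
  if (!is.null(.ankevol_cache[[key]])) return(.ankevol_cache[[key]])
  if (file.exists(name)) {
    m <- as.matrix(read.table(name, header = TRUE, check.names = FALSE))
    rownames(m) <- colnames(m)
  } else {
    e <- new.env()
    data(list = name, package = "Biostrings", envir = e)
    m <- e[[name]]
  }
  if ("X" %in% rownames(m)) {
    m["X", ] <- 0
    m[, "X"] <- 0
  }
  .ankevol_cache[[key]] <- m
  m
}

#' Global pairwise alignment (Needleman-Wunsch, affine gaps)
#'
#' Optimal global alignment via [Biostrings::pairwiseAlignment()]. Identity
#' and similarity percentages use the full alignment length (gap columns
#' included) as denominator, the convention of the EMBOSS `needle` report.
#' A column is *identical* when both residues are equal standard amino
#' acids (`X` never counts as identical); *similar* columns are identical
#' columns plus substitutions with a positive matrix score.
#'
#' @param a,b [seq_record()] objects or plain residue strings (ungapped).
#' @param matrix substitution matrix name or matrix (default BLOSUM62 with
#'   `X` scored 0 against everything).
#' @param gap_open,gap_extend affine gap penalties (defaults 10 and 0.5; a
#'   gap of length k costs `gap_open + k * gap_extend`).
#' @return object of class `aln_result`: list with `score`, `identity_pct`,
#'   `similarity_pct`, `aligned_a`, `aligned_b`, `length`.
#' @export
global_align <- function(a, b, matrix = "BLOSUM62", gap_open = 10,
                         gap_extend = 0.5) {
  a <- as_seq_list(a)[[1]]; b <- as_seq_list(b)[[1]]
  if (!nzchar(a$residues) || !nzchar(b$residues))
    stop("cannot align empty sequences")
  if (grepl("-", a$residues, fixed = TRUE) ||
      grepl("-", b$residues, fixed = TRUE))
    stop("global_align expects ungapped sequences")
  m <- if (is.matrix(matrix)) matrix else substitution_matrix(matrix)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a$residues), Biostrings::AAString(b$residues),
    substitutionMatrix = m, gapOpening = gap_open,
    gapExtension = gap_extend, type = "global")
  ga <- as.character(Biostrings::alignedPattern(pa))
  gb <- as.character(Biostrings::alignedSubject(pa))
  ca <- strsplit(ga, "")[[1]]; cb <- strsplit(gb, "")[[1]]
  len <- length(ca)
  both <- ca != "-" & cb != "-"
  ident <- both & ca == cb & ca != "X"
  pos <- rep(FALSE, len)
  if (any(both)) {
    sc <- m[cbind(ca[both], cb[both])]
    pos[both] <- sc > 0
  }
  similar <- ident | pos
  structure(list(score = as.numeric(Biostrings::score(pa)),
                 identity_pct = 100 * sum(ident) / len,
                 similarity_pct = 100 * sum(similar) / len,
                 aligned_a = ga, aligned_b = gb, length = len,
                 id_a = a$id, id_b = b$id),
            class = "aln_result")
}

#' @export
print.aln_result <- function(x, ...) {
  cat(sprintf("<aln_result> %s vs %s: score %.1f, identity %.1f%%, similarity %.1f%%\n",
              x$id_a, x$id_b, x$score, x$identity_pct, x$similarity_pct))
  invisible(x)
}

#' Inter/intra-group similarity (or identity) range matrix
#'
#' All-against-all global alignments across groups of sequences, reduced to
#' the minimum and maximum of the chosen metric for every group pair.
#' Diagonal entries are intra-group ranges over distinct unordered pairs;
#' singleton groups get `NA` there.
#'
#' @param groups named list; each element a list of [seq_record()].
#' @param metric `"similarity"` or `"identity"`.
#' @param ... passed to [global_align()].
#' @return object of class `group_range`: list with `groups`, `n` (group
#'   sizes), `min_pct` and `max_pct` matrices.
#' @export
group_range_matrix <- function(groups, metric = c("similarity", "identity"),
                               ...) {
  metric <- match.arg(metric)
  stopifnot(is.list(groups), !is.null(names(groups)),
            all(lengths(groups) >= 1L))
  gl <- names(groups)
  seqs <- unlist(groups, recursive = FALSE)
  gidx <- rep(seq_along(groups), lengths(groups))
  ns <- length(seqs)
  val <- matrix(NA_real_, ns, ns)
  for (i in seq_len(ns - 1L)) for (j in seq((i + 1L), ns)) {
    r <- global_align(seqs[[i]], seqs[[j]], ...)
    val[i, j] <- val[j, i] <-
      if (metric == "similarity") r$similarity_pct else r$identity_pct
  }
  k <- length(groups)
  mn <- mx <- matrix(NA_real_, k, k, dimnames = list(gl, gl))
  for (gi in seq_len(k)) for (gj in gi:k) {
    ii <- which(gidx == gi); jj <- which(gidx == gj)
    v <- if (gi == gj) {
      if (length(ii) < 2L) NA_real_ else val[ii, ii][upper.tri(diag(length(ii)))]
    } else as.vector(val[ii, jj])
    if (all(is.na(v))) next
    mn[gi, gj] <- mn[gj, gi] <- min(v)
    mx[gi, gj] <- mx[gj, gi] <- max(v)
  }
  structure(list(groups = gl, n = lengths(groups), metric = metric,
                 min_pct = mn, max_pct = mx),
            class = "group_range")
}

#' @export
print.group_range <- function(x, digits = 1, ...) {
  cat(sprintf("<group_range> %s ranges, %d groups\n", x$metric,
              length(x$groups)))
  print(format_group_range(x, digits))
  invisible(x)
}

#' Format a group range matrix as "min-max" strings
#' @param x a `group_range` object.
#' @param digits decimal places.
#' @return character matrix.
#' @export
format_group_range <- function(x, digits = 1) {
  f <- function(a, b) ifelse(is.na(a), "NA",
                             paste0(round(a, digits), "-", round(b, digits)))
  m <- matrix(f(x$min_pct, x$max_pct), length(x$groups),
              dimnames = dimnames(x$min_pct))
  rownames(m) <- sprintf("%s (%d)", x$groups, x$n)
  m
}

#' Filter homolog hits by length window and identity to a query
#'
#' Keeps hits whose ungapped length lies strictly inside `length_window`
#' (exclusive bounds, `>min` and `<max`) and whose global identity to the
#' query is strictly greater than `identity_min` percent. The rejection log
#' records which rule fired first (length before identity).
#'
#' @param hits list of [seq_record()].
#' @param query a [seq_record()].
#' @param identity_min minimum identity (percent, strict).
#' @param length_window numeric `c(min, max)`, exclusive bounds.
#' @param ... passed to [global_align()].
#' @return list with `kept` (list of records) and `log` (data.frame with
#'   columns id, length, identity_pct, kept, reason).
#' @export
filter_homologs <- function(hits, query, identity_min = 35,
                            length_window, ...) {
  stopifnot(length(length_window) == 2L, all(length_window > 0),
            length_window[1] < length_window[2])
  hits <- as_seq_list(hits); query <- as_seq_list(query)[[1]]
  log <- data.frame(id = vapply(hits, `[[`, "", "id"),
                    length = vapply(hits, function(s) nchar(s$residues), 0L),
                    identity_pct = NA_real_, kept = FALSE,
                    reason = "", stringsAsFactors = FALSE)
  kept <- list()
  for (k in seq_along(hits)) {
    len <- log$length[k]
    if (len <= length_window[1] || len >= length_window[2]) {
      log$reason[k] <- sprintf("length %d outside (%g,%g)", len,
                               length_window[1], length_window[2])
      next
    }
    idp <- global_align(hits[[k]], query, ...)$identity_pct
    log$identity_pct[k] <- idp
    if (idp <= identity_min) {
      log$reason[k] <- sprintf("identity %.1f%% <= %g%%", idp, identity_min)
      next
    }
    log$kept[k] <- TRUE
    kept <- c(kept, hits[k])
  }
  list(kept = kept, log = log)
}
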