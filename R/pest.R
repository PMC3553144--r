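# Average residue masses (Da, residue = amino acid minus water).
AA_MASS <- c(A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886,
             C = 103.1388, E = 129.1155, Q = 128.1307, G = 57.0519,
             H = 137.1411, I = 113.1594, L = 113.1594, K = 128.1741,
             M = 131.1926, F = 147.1766, P = 97.1167, S = 87.0782,
             T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326,
             X = 110.0)

# Kyte-Doolittle hydropathy.
KD_HYDROPATHY <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, E = -3.5,
                   Q = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
                   M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
                   Y = -1.3, V = 4.2, X = 0)

#' Find PEST motifs in a protein sequence
#'
#' PEST motifs are proline/glutamate/serine/threonine-rich stretches flanked
#' by positively charged residues (K, R, H) or the sequence termini; they
#' are associated with rapid protein turnover. Candidate spans are the
#' maximal stretches between positive residues of length at least
#' `min_length` that contain at least one D or E, at least one P and at
#' least one S or T (the classical composition rule). Each candidate is
#' scored as
#'
#' `score = 0.55 * pest_mass_pct - 0.5 * hydrophobicity_index`
#'
#' where `pest_mass_pct` is the mass percent of D/E/P/S/T within the span
#' corrected by one equivalent of each of (D or E), P and (S or T) - when
#' both members of a category are present the lighter one is subtracted, so
#' the correction is the least punitive - and `hydrophobicity_index` is the
#' mean Kyte-Doolittle hydropathy rescaled to `10 * KD + 45` (range 0-90).
#' A span is `valid` when its score reaches `threshold`.
#'
#' @param seq a [seq_record()] or residue string (ungapped).
#' @param threshold validity threshold on the score (default +5).
#' @param min_length minimum span length (default 12 residues).
#' @return data.frame with columns `start`, `end` (1-based inclusive, the
#'   span between the flanking positive residues), `length`, `score`,
#'   `valid`. Zero rows when no candidate passes the composition rule.
#' @export
find_pest <- function(seq, threshold = 5, min_length = 12) {
  s <- as_seq_list(seq)[[1]]
  if (grepl("-", s$residues, fixed = TRUE))
    stop("find_pest expects an ungapped sequence")
  chars <- strsplit(s$residues, "")[[1]]
  n <- length(chars)
  flank <- c(0L, which(chars %in% c("K", "R", "H")), n + 1L)
  out <- data.frame(start = integer(0), end = integer(0),
                    length = integer(0), score = numeric(0),
                    valid = logical(0))
  for (k in seq_len(length(flank) - 1L)) {
    a <- flank[k] + 1L; b <- flank[k + 1L] - 1L
    if (b - a + 1L < min_length) next
    span <- chars[a:b]
    if (!any(span %in% c("D", "E")) || !any(span == "P") ||
        !any(span %in% c("S", "T"))) next
    out <- rbind(out, data.frame(start = a, end = b, length = b - a + 1L,
                                 score = pest_score(span), valid = FALSE))
  }
  if (nrow(out)) out$valid <- out$score >= threshold
  rownames(out) <- NULL
  out
}

pest_score <- function(span) {
  mass <- AA_MASS[span]
  total <- sum(mass)
  pest_mass <- sum(mass[span %in% c("D", "E", "P", "S", "T")])
  # one-equivalent correction: subtract the lightest present member of each
  # category so the correction costs the least score
  eq <- 0
  de <- intersect(c("D", "E"), span)
  if (length(de)) eq <- eq + min(AA_MASS[de])
  eq <- eq + AA_MASS[["P"]]
  st <- intersect(c("S", "T"), span)
  if (length(st)) eq <- eq + min(AA_MASS[st])
  pest_mass_pct <- 100 * max(0, pest_mass - eq) / total
  hyd <- mean(10 * KD_HYDROPATHY[span] + 45)
  unname(0.55 * pest_mass_pct - 0.5 * hyd)
}
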