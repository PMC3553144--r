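codon_universe <- function() {
  gc <- Biostrings::GENETIC_CODE
  list(code = gc, codons = names(gc), stops = names(gc)[gc == "*"])
}

# fractional synonymous/nonsynonymous site counts of one codon (NG86).
# Changes to stop codons are excluded from the denominator.
ng86_sites_one <- function(codon, cu) {
  aa <- cu$code[[codon]]
  chars <- strsplit(codon, "")[[1]]
  s <- 0; tot <- 0
  for (pos in 1:3) for (nt in setdiff(c("A", "C", "G", "T"), chars[pos])) {
    alt <- chars; alt[pos] <- nt
    alt <- paste(alt, collapse = "")
    if (alt %in% cu$stops) next
    tot <- tot + 1
    if (cu$code[[alt]] == aa) s <- s + 1
  }
  if (tot == 0) return(c(s = 0, n = 0))
  c(s = 3 * s / tot, n = 3 - 3 * s / tot)
}

# pathway-averaged synonymous/nonsynonymous differences between two codons.
# All orderings of the differing positions are enumerated; pathways passing
# through a stop codon are excluded from the average (all pathways kept if
# every one is blocked).
ng86_diffs_one <- function(c1, c2, cu) {
  if (c1 == c2) return(c(sd = 0, nd = 0))
  p1 <- strsplit(c1, "")[[1]]; p2 <- strsplit(c2, "")[[1]]
  dpos <- which(p1 != p2)
  perms <- if (length(dpos) == 1L) list(dpos) else {
    if (length(dpos) == 2L) list(dpos, rev(dpos)) else {
      out <- list()
      for (a in 1:3) for (b in setdiff(1:3, a))
        out[[length(out) + 1L]] <- dpos[c(a, b, setdiff(1:3, c(a, b)))]
      out
    }
  }
  paths <- lapply(perms, function(ord) {
    cur <- p1; sd <- 0; nd <- 0; blocked <- FALSE
    for (pos in ord) {
      nxt <- cur; nxt[pos] <- p2[pos]
      from <- paste(cur, collapse = ""); to <- paste(nxt, collapse = "")
      if (to %in% cu$stops) blocked <- TRUE
      if (cu$code[[from]] == cu$code[[to]]) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    c(sd = sd, nd = nd, blocked = as.numeric(blocked))
  })
  pm <- do.call(rbind, paths)
  keep <- pm[, "blocked"] == 0
  if (!any(keep)) keep <- rep(TRUE, nrow(pm))
  c(sd = mean(pm[keep, "sd"]), nd = mean(pm[keep, "nd"]))
}

# cached 64-codon site table and 64x64 difference tables
ng86_tables <- function() {
  if (!is.null(.ankevol_cache$ng86)) return(.ankevol_cache$ng86)
  cu <- codon_universe()
  sites <- t(vapply(cu$codons, ng86_sites_one, c(s = 0, n = 0), cu = cu))
  nc <- length(cu$codons)
  sd <- nd <- matrix(0, nc, nc, dimnames = list(cu$codons, cu$codons))
  for (i in seq_len(nc)) for (j in seq_len(nc)) {
    if (i == j) next
    v <- ng86_diffs_one(cu$codons[i], cu$codons[j], cu)
    sd[i, j] <- v["sd"]; nd[i, j] <- v["nd"]
  }
  .ankevol_cache$ng86 <- list(cu = cu, sites = sites, sd = sd, nd = nd)
  .ankevol_cache$ng86
}

split_codons <- function(x) {
  if (nchar(x) %% 3L != 0L) stop("sequence length not divisible by 3")
  substring(x, seq(1, nchar(x), 3), seq(3, nchar(x), 3))
}

jc_nucleotide <- function(p) {
  if (is.na(p)) return(NA_real_)
  if (p >= 3 / 4) return(NA_real_)
  -(3 / 4) * log(1 - (4 / 3) * p)
}

#' Pairwise Ka/Ks by Nei-Gojobori (1986) counting
#'
#' Synonymous and nonsynonymous sites are counted by codon degeneracy
#' fractions; differences are averaged over all minimal mutational pathways
#' (pathways through stop codons excluded); both proportions are corrected
#' with the nucleotide Jukes-Cantor formula
#' `d = -(3/4) * ln(1 - (4/3) * p)`.
#'
#' @param a,b in-frame codon sequences ([seq_record()] or strings) of equal
#'   length without internal stop codons. Codon pairs containing gaps or
#'   ambiguity codes are skipped.
#' @return object of class `kaks_result`: list with `ka`, `ks`, `omega`
#'   (`NA` when `ks` is 0 or saturated), raw counts `S`, `N`, `Sd`, `Nd`,
#'   and `codons_used`.
#' @export
ng86_pairwise <- function(a, b) {
  sa <- if (inherits(a, "seq_record")) a$residues else toupper(a)
  sb <- if (inherits(b, "seq_record")) b$residues else toupper(b)
  sa <- gsub("U", "T", sa, fixed = TRUE); sb <- gsub("U", "T", sb, fixed = TRUE)
  if (nchar(sa) != nchar(sb)) stop("codon sequences differ in length")
  ca <- split_codons(sa); cb <- split_codons(sb)
  tb <- ng86_tables()
  plain <- function(x) x %in% rownames(tb$sites)
  usable <- plain(ca) & plain(cb)
  ncod <- length(ca)
  stop_a <- which(ca %in% tb$cu$stops); stop_b <- which(cb %in% tb$cu$stops)
  if (any(stop_a < ncod) || any(stop_b < ncod))
    stop("internal stop codon at codon ",
         min(c(stop_a[stop_a < ncod], stop_b[stop_b < ncod])))
  usable <- usable & !(seq_len(ncod) %in% c(stop_a, stop_b))
  if (!any(usable)) stop("no comparable codons")
  ca <- ca[usable]; cb <- cb[usable]
  S <- (sum(tb$sites[ca, "s"]) + sum(tb$sites[cb, "s"])) / 2
  N <- (sum(tb$sites[ca, "n"]) + sum(tb$sites[cb, "n"])) / 2
  Sd <- sum(tb$sd[cbind(ca, cb)])
  Nd <- sum(tb$nd[cbind(ca, cb)])
  ps <- if (S > 0) Sd / S else NA_real_
  pn <- if (N > 0) Nd / N else NA_real_
  ks <- jc_nucleotide(ps); ka <- jc_nucleotide(pn)
  omega <- if (is.na(ka) || is.na(ks) || ks == 0) NA_real_ else ka / ks
  structure(list(ka = ka, ks = ks, omega = omega, S = S, N = N,
                 Sd = Sd, Nd = Nd, codons_used = sum(usable)),
            class = "kaks_result")
}

#' @export
print.kaks_result <- function(x, ...) {
  cat(sprintf("<kaks_result> Ka = %s, Ks = %s, omega = %s (%d codons)\n",
              format(x$ka, digits = 4), format(x$ks, digits = 4),
              format(x$omega, digits = 4), x$codons_used))
  invisible(x)
}

#' Site-wise Ka/Ks along a query sequence
#'
#' For every codon column, pathway-averaged synonymous/nonsynonymous
#' differences and degeneracy sites are pooled between the query row and
#' every other row, then Jukes-Cantor corrected. Sites are classified as
#' `purifying` (omega < 0.9), `neutral` (within 0.1 of 1), `positive`
#' (omega > 1.1) or `NA` (no substitutions observed or undefined rates).
#'
#' @param aln codon [msa()] alignment.
#' @param query label of the query row.
#' @param neutral_band half-width of the neutral omega band (default 0.1).
#' @return list with `per_codon` data.frame (`site`, `ka`, `ks`, `omega`,
#'   `class`) and `overall` [ng86_pairwise()]-style totals.
#' @export
sitewise_kaks <- function(aln, query, neutral_band = 0.1) {
  stopifnot(inherits(aln, "msa"))
  taxa <- msa_taxa(aln)
  if (!query %in% taxa) stop("query row '", query, "' not in alignment")
  rows <- lapply(aln$sequences, function(s)
    split_codons(gsub("U", "T", s$residues, fixed = TRUE)))
  names(rows) <- taxa
  tb <- ng86_tables()
  plain <- rownames(tb$sites)
  nsite <- length(rows[[query]])
  others <- setdiff(taxa, query)
  Ssite <- Nsite <- Sdsite <- Ndsite <- numeric(nsite)
  npairs <- integer(nsite)
  qs <- rows[[query]]
  for (r in others) {
    os <- rows[[r]]
    ok <- qs %in% plain & os %in% plain &
      !(qs %in% tb$cu$stops) & !(os %in% tb$cu$stops)
    i <- which(ok)
    if (!length(i)) next
    Ssite[i] <- Ssite[i] + (tb$sites[qs[i], "s"] + tb$sites[os[i], "s"]) / 2
    Nsite[i] <- Nsite[i] + (tb$sites[qs[i], "n"] + tb$sites[os[i], "n"]) / 2
    Sdsite[i] <- Sdsite[i] + tb$sd[cbind(qs[i], os[i])]
    Ndsite[i] <- Ndsite[i] + tb$nd[cbind(qs[i], os[i])]
    npairs[i] <- npairs[i] + 1L
  }
  ka <- ks <- omega <- rep(NA_real_, nsite)
  class <- rep(NA_character_, nsite)
  for (i in seq_len(nsite)) {
    if (npairs[i] == 0L) next
    if (Sdsite[i] + Ndsite[i] == 0) next  # no substitutions: NA
    ks[i] <- jc_nucleotide(if (Ssite[i] > 0) Sdsite[i] / Ssite[i] else NA)
    ka[i] <- jc_nucleotide(if (Nsite[i] > 0) Ndsite[i] / Nsite[i] else NA)
    if (!is.na(ka[i]) && !is.na(ks[i]) && ks[i] > 0) {
      omega[i] <- ka[i] / ks[i]
      class[i] <- if (abs(omega[i] - 1) <= neutral_band) "neutral"
      else if (omega[i] > 1) "positive" else "purifying"
    }
  }
  Ssum <- sum(Ssite); Nsum <- sum(Nsite)
  ks_all <- jc_nucleotide(if (Ssum > 0) sum(Sdsite) / Ssum else NA)
  ka_all <- jc_nucleotide(if (Nsum > 0) sum(Ndsite) / Nsum else NA)
  overall <- list(ka = ka_all, ks = ks_all,
                  omega = if (is.na(ka_all) || is.na(ks_all) || ks_all == 0)
                    NA_real_ else ka_all / ks_all,
                  S = Ssum, N = Nsum, Sd = sum(Sdsite), Nd = sum(Ndsite))
  list(per_codon = data.frame(site = seq_len(nsite), ka = ka, ks = ks,
                              omega = omega, class = class,
                              stringsAsFactors = FALSE),
       overall = overall)
}
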