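# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: plain enumeration and closed forms only.

# exhaustive global-alignment optimum under affine gaps
# (gap of length k costs open + k * ext, matching the aligner convention)
oracle_global_score <- function(a, b, mat, open = 10, ext = 0.5) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  n <- length(ca); m <- length(cb)
  best <- -Inf
  score_path <- function(moves) {
    i <- 0; j <- 0; s <- 0
    run <- ""  # current gap run type
    for (mv in moves) {
      if (mv == "M") {
        i <- i + 1; j <- j + 1
        s <- s + mat[ca[i], cb[j]]
        run <- ""
      } else if (mv == "U") {      # consume a, gap in b
        i <- i + 1
        s <- s - ext - if (run == "U") 0 else open
        run <- "U"
      } else {                     # consume b, gap in a
        j <- j + 1
        s <- s - ext - if (run == "L") 0 else open
        run <- "L"
      }
    }
    s
  }
  rec <- function(i, j, moves) {
    if (i == n && j == m) {
      s <- score_path(moves)
      if (s > best) best <<- s
      return(invisible())
    }
    if (i < n && j < m) rec(i + 1, j + 1, c(moves, "M"))
    if (i < n) rec(i + 1, j, c(moves, "U"))
    if (j < m) rec(i, j + 1, c(moves, "L"))
  }
  rec(0, 0, character(0))
  best
}

# brute-force Fitch parsimony: minimise changes over all assignments of
# observed states to internal nodes
oracle_fitch <- function(tree, tip_states) {
  tree <- ape::multi2di(tree)
  nt <- ape::Ntip(tree)
  obs <- unique(tip_states[!is.na(tip_states)])
  if (length(obs) <= 1L) return(0L)
  n_int <- tree$Nnode
  grid <- as.matrix(expand.grid(rep(list(obs), n_int),
                                stringsAsFactors = FALSE))
  states <- tip_states[tree$tip.label]
  best <- Inf
  for (g in seq_len(nrow(grid))) {
    assign <- c(states, grid[g, ])
    cost <- 0
    for (e in seq_len(nrow(tree$edge))) {
      p <- assign[tree$edge[e, 1]]; ch <- assign[tree$edge[e, 2]]
      if (is.na(ch)) next  # missing tip contributes nothing
      if (p != ch) cost <- cost + 1
    }
    if (cost < best) best <- cost
  }
  best
}

# pathway-enumeration Nei-Gojobori differences, written from the genetic
# code directly
oracle_ng86_diffs <- function(c1, c2) {
  gc <- Biostrings::GENETIC_CODE
  stops <- names(gc)[gc == "*"]
  p1 <- strsplit(c1, "")[[1]]; p2 <- strsplit(c2, "")[[1]]
  dpos <- which(p1 != p2)
  if (!length(dpos)) return(c(sd = 0, nd = 0))
  perms <- if (length(dpos) == 1) matrix(dpos, 1) else
    do.call(rbind, lapply(combinat_perms(length(dpos)), function(o) dpos[o]))
  res <- apply(perms, 1, function(ord) {
    cur <- p1; sd <- 0; nd <- 0; blocked <- FALSE
    for (pos in ord) {
      nxt <- cur; nxt[pos] <- p2[pos]
      if (paste(nxt, collapse = "") %in% stops) blocked <- TRUE
      if (gc[[paste(cur, collapse = "")]] == gc[[paste(nxt, collapse = "")]])
        sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    c(sd, nd, blocked)
  })
  keep <- res[3, ] == 0
  if (!any(keep)) keep <- rep(TRUE, ncol(res))
  c(sd = mean(res[1, keep]), nd = mean(res[2, keep]))
}

combinat_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (k in seq_len(n)) {
    for (p in combinat_perms(n - 1L)) {
      rest <- setdiff(seq_len(n), k)
      out[[length(out) + 1L]] <- c(k, rest[p])
    }
  }
  out
}

random_aa_string <- function(n) {
  paste(sample(c("A","R","N","D","C","Q","E","G","H","I","L","K","M",
                 "F","P","S","T","W","Y","V"), n, replace = TRUE),
        collapse = "")
}

random_codon_string <- function(n_codons) {
  gc <- Biostrings::GENETIC_CODE
  sense <- names(gc)[gc != "*"]
  paste(sample(sense, n_codons, replace = TRUE), collapse = "")
}

# fixed-width PDB ATOM record (name cols 13-16, altLoc col 17)
pdb_atom_line <- function(serial, alt, resname, chain, resno, x, y, z,
                          occ = 1, b = 0, name = " CA ") {
  sprintf("ATOM  %5d %-4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
          serial, name, alt, resname, chain, resno, x, y, z, occ, b)
}

# named character vector -> list of seq_record
sl <- function(x) {
  out <- lapply(names(x), function(n) seq_record(n, x[[n]]))
  setNames(out, names(x))
}
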