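# biochemical property classes used for radical-change calls
AA_PROPERTY <- c(K = "+", R = "+", H = "+",
                 D = "-", E = "-",
                 A = "Hydrophobic", V = "Hydrophobic", L = "Hydrophobic",
                 I = "Hydrophobic", M = "Hydrophobic", F = "Hydrophobic",
                 W = "Hydrophobic",
                 S = "Hydrophilic", T = "Hydrophilic", N = "Hydrophilic",
                 Q = "Hydrophilic", C = "Hydrophilic", G = "Hydrophilic",
                 P = "Hydrophilic", Y = "Hydrophilic")

#' Biochemical property class of an amino acid
#'
#' Classes: `"+"` (K, R, H), `"-"` (D, E), `"Hydrophobic"`
#' (A, V, L, I, M, F, W) and `"Hydrophilic"` (S, T, N, Q, C, G, P, Y).
#'
#' @param aa character vector of one-letter amino acids.
#' @return character vector of class labels (`NA` for unknown letters).
#' @export
aa_property_class <- function(aa) {
  unname(AA_PROPERTY[toupper(aa)])
}

#' Property-change label for a fixed difference between two clusters
#'
#' @param a,b consensus residues of cluster A and cluster B.
#' @return string `"classA/classB"`, e.g. `"Hydrophilic/+"` for Q vs K.
#' @export
property_change_label <- function(a, b) {
  paste(aa_property_class(a), aa_property_class(b), sep = "/")
}

cluster_consensus <- function(m, taxa) {
  sub <- m[taxa, , drop = FALSE]
  apply(sub, 2, function(col) {
    col <- col[!(col %in% c("-", "X", "?"))]
    if (!length(col)) return(NA_character_)
    t <- sort(table(col), decreasing = TRUE)
    if (length(t) > 1L && t[1] == t[2]) return(NA_character_)  # tie
    if (t[1] * 2L <= length(col)) return(NA_character_)        # no strict majority
    names(t)[1]
  })
}

# probability that two lineages separated by t expected substitutions/site
# end in different residues (20-state uniform model)
p_diff_uniform <- function(t) (19 / 20) * (1 - exp(-(20 / 19) * t))

# background log-likelihood per column: rate lambda ~ Gamma(a0, mean 1)
# shared by the whole tree; counts Poisson(lambda * T), consensus difference
# Bernoulli(p_diff_uniform(lambda * T_AB)); marginalised by quadrature on
# the gamma quantile scale
log_background_type2 <- function(xa, xb, diff, a0, TA, TB, T_AB, K = 96) {
  u <- (seq_len(K) - 0.5) / K
  lam <- qgamma(u, shape = a0, rate = a0)
  pd <- pmin(pmax(p_diff_uniform(lam * T_AB), 1e-12), 1 - 1e-12)
  out <- numeric(length(xa))
  key <- paste(xa, xb, diff)
  for (k in unique(key)) {
    i <- which(key == k)
    f <- dpois(xa[i[1]], lam * TA) * dpois(xb[i[1]], lam * TB) *
      (if (diff[i[1]]) pd else 1 - pd)
    out[i] <- log(mean(f))
  }
  out
}

#' Estimate type II functional divergence between two clusters
#'
#' Type II divergence describes sites that are conserved within each
#' cluster but fixed for different residues between clusters - a radical
#' shift acquired early after duplication. Columns are scored under a
#' two-class mixture. In the background class a single gamma rate per site
#' drives both the within-cluster Poisson counts and the chance that the
#' cluster ancestors differ (20-state uniform model over the tree path
#' between cluster roots), marginalised numerically - so a site frozen in
#' both clusters is also expected to be identical between them, which is
#' exactly why a frozen fixed difference is surprising. The divergent class
#' expects near-frozen counts (Poisson with rate `delta` times the cluster
#' scale) and different consensus residues. `theta2` is the fitted mixture
#' weight; each column's `site_score` is the posterior ratio
#' divergent/background, reported on the same scale as the conventional
#' `> 17` cutoff. Radical sites additionally require a property-class
#' change between the cluster consensuses.
#'
#' @param pair a [cluster_pair()].
#' @param counts optional `site_counts` from [fitch_counts()] (computed if
#'   missing).
#' @param cutoff site-score cutoff for radical sites (strict `>`,
#'   default 17).
#' @param delta conserved-class rate factor (default 0.05).
#' @return object of class `type2_result`: list with `theta2`,
#'   `site_score` (length L, `NA` at columns without both consensuses),
#'   `radical_sites` (1-based columns), `property_change` (data.frame) and
#'   `excluded` (columns without a consensus).
#' @export
estimate_type2 <- function(pair, counts = NULL, cutoff = 17, delta = 0.05) {
  stopifnot(inherits(pair, "cluster_pair"))
  if (is.null(counts)) counts <- fitch_counts(pair)
  m <- msa_matrix(pair$msa)
  L <- ncol(m)
  consA <- cluster_consensus(m, pair$clusterA)
  consB <- cluster_consensus(m, pair$clusterB)
  defined <- !is.na(consA) & !is.na(consB)
  diff <- defined & consA != consB
  T_AB <- cluster_gap_length(pair)
  TA <- max(mean(counts$X_A[defined]), 1e-3)
  TB <- max(mean(counts$X_B[defined]), 1e-3)
  xa <- counts$X_A; xb <- counts$X_B
  v <- var(c(xa[defined], xb[defined])); Tm <- (TA + TB) / 2
  a0 <- if (is.finite(v) && v > Tm) min(max(Tm^2 / (v - Tm), 0.05), 50) else 5
  # background: one rate lambda per site shared by the whole tree, so the
  # chance of an ancestral difference is rate-coupled - a site frozen in
  # both clusters implies a low rate, hence a low probability of differing
  # between clusters. Marginalise numerically over the gamma rate.
  lN <- log_background_type2(xa, xb, diff, a0, TA, TB, T_AB)
  # divergent class: near-frozen within clusters, fixed different between
  lD <- dpois(xa, delta * TA, log = TRUE) + dpois(xb, delta * TB, log = TRUE) +
    ifelse(diff, 0, -Inf)
  use <- which(defined)
  nll <- function(th) {
    mx <- pmax(lN[use], ifelse(is.finite(lD[use]), lD[use], lN[use]))
    -sum(mx + log((1 - th) * exp(lN[use] - mx) +
                    th * exp(lD[use] - mx)))
  }
  theta2 <- if (any(diff)) optimize(nll, c(0, 1 - 1e-6))$minimum else 0
  score <- rep(NA_real_, L)
  score[defined] <- ifelse(is.finite(lD[defined]),
                           theta2 * exp(lD[defined] - lN[defined]) /
                             max(1 - theta2, 1e-12), 0)
  radical <- which(!is.na(score) & score > cutoff &
                     aa_property_class(consA) != aa_property_class(consB))
  reported <- which(!is.na(score) & score > cutoff)
  property_change <- data.frame(
    column = reported,
    consensusA = consA[reported], consensusB = consB[reported],
    classA = aa_property_class(consA[reported]),
    classB = aa_property_class(consB[reported]),
    label = property_change_label(consA[reported], consB[reported]),
    site_score = score[reported],
    radical = reported %in% radical,
    stringsAsFactors = FALSE)
  structure(list(theta2 = theta2, site_score = score,
                 radical_sites = radical, property_change = property_change,
                 excluded = which(!defined), T_AB = T_AB),
            class = "type2_result")
}

#' @export
print.type2_result <- function(x, ...) {
  cat(sprintf("<type2_result> theta2 = %.3f, %d scored columns, %d radical sites\n",
              x$theta2, sum(!is.na(x$site_score)), length(x$radical_sites)))
  invisible(x)
}

# tree path length between the root nodes of the two clusters
cluster_gap_length <- function(pair) {
  tr <- pair$tree
  if (!ape::is.rooted(tr)) {
    anchor <- setdiff(tr$tip.label, c(pair$clusterA, pair$clusterB))
    tr <- if (length(anchor)) ape::root(tr, outgroup = anchor[1],
                                        resolve.root = TRUE)
    else ape::root(tr, outgroup = pair$clusterA[1], resolve.root = TRUE)
  }
  mA <- ape::getMRCA(tr, pair$clusterA)
  mB <- ape::getMRCA(tr, pair$clusterB)
  dn <- ape::dist.nodes(tr)
  dn[mA, mB]
}

#' Build the pairwise cluster-comparison roster from taxonomic groups
#'
#' Groups taxa by a class label and emits every unordered pair of groups as
#' a [cluster_pair()] (10 groups give 45 comparisons). Groups with fewer
#' than 4 taxa are dropped with a warning.
#'
#' @param aln an [msa()] alignment.
#' @param labels named character vector mapping taxon -> group label.
#' @param tree [ape::phylo] tree used by downstream stages.
#' @param validate check monophyly of each group now (default FALSE; checked
#'   anyway by [fitch_counts()]).
#' @return list of `cluster_pair` objects; names are `"groupA|groupB"`.
#' @export
taxonomic_grouping <- function(aln, labels, tree, validate = FALSE) {
  taxa <- msa_taxa(aln)
  labels <- labels[names(labels) %in% taxa]
  groups <- split(names(labels), unname(labels))
  small <- names(groups)[lengths(groups) < 4L]
  if (length(small)) {
    warning("dropping groups with fewer than 4 taxa: ",
            paste(small, collapse = ", "))
    groups <- groups[lengths(groups) >= 4L]
  }
  gl <- names(groups)
  if (length(gl) < 2L) stop("need at least 2 groups of >= 4 taxa")
  out <- list()
  for (i in seq_len(length(gl) - 1L)) for (j in (i + 1L):length(gl)) {
    out[[paste(gl[i], gl[j], sep = "|")]] <-
      cluster_pair(aln, tree, groups[[gl[i]]], groups[[gl[j]]],
                   validate = validate)
  }
  out
}
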