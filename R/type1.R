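#' Sample per-site substitution counts under the type I divergence model
#'
#' Generative model used by [estimate_type1()]: each site carries a rate
#' drawn from a mean-1 gamma distribution. With probability `1 - theta` the
#' two clusters share one rate; with probability `theta` (the type I
#' coefficient) the rates are drawn independently. Counts are Poisson with
#' mean rate x cluster branch scale.
#'
#' @param L number of sites.
#' @param theta type I coefficient in \code{[0, 1]}.
#' @param alpha gamma shape (both clusters).
#' @param T_A,T_B cluster branch scales (expected substitutions at rate 1).
#' @param seed integer seed.
#' @return `site_counts` object with attribute `"truth"`.
#' @export
sample_type1_counts <- function(L, theta, alpha, T_A = 1.3, T_B = 1.3,
                                seed = 1) {
  stopifnot(theta >= 0, theta <= 1, alpha > 0, L >= 1)
  local_seed(seed, {
    shifted <- runif(L) < theta
    lamA <- rgamma(L, shape = alpha, rate = alpha)
    lamB <- ifelse(shifted, rgamma(L, shape = alpha, rate = alpha), lamA)
    xa <- rpois(L, lamA * T_A)
    xb <- rpois(L, lamB * T_B)
    structure(list(X_A = xa, X_B = xb,
                   mask_A = rep(FALSE, L), mask_B = rep(FALSE, L), L = L),
              class = "site_counts",
              truth = list(theta = theta, alpha = alpha, T_A = T_A,
                           T_B = T_B, shifted_sites = which(shifted),
                           seed = seed))
  })
}

# log joint density of (xa, xb) under a shared mean-1 gamma(alpha0) rate
# marginalised analytically (bivariate negative binomial form)
log_f12 <- function(xa, xb, alpha0, TA, TB) {
  lgamma(alpha0 + xa + xb) - lgamma(alpha0) - lgamma(xa + 1) -
    lgamma(xb + 1) + xa * log(TA) + xb * log(TB) +
    alpha0 * log(alpha0) - (alpha0 + xa + xb) * log(TA + TB + alpha0)
}

# negative log-likelihood over tabulated (xa, xb) pairs
# par = (theta, alpha_A, alpha_B, T_A, T_B) on natural scale
type1_nll <- function(par, tab) {
  theta <- par[1]; aA <- par[2]; aB <- par[3]; TA <- par[4]; TB <- par[5]
  if (theta < 0 || theta > 1 || aA <= 0 || aB <= 0 || TA <= 0 || TB <= 0)
    return(1e12)
  a0 <- (aA + aB) / 2
  lsh <- log_f12(tab$xa, tab$xb, a0, TA, TB)
  lin <- dnbinom(tab$xa, size = aA, mu = TA, log = TRUE) +
    dnbinom(tab$xb, size = aB, mu = TB, log = TRUE)
  m <- pmax(lsh, lin)
  ll <- m + log((1 - theta) * exp(lsh - m) + theta * exp(lin - m))
  v <- -sum(tab$w * ll)
  if (!is.finite(v)) 1e12 else v
}

type1_nll_null <- function(par, tab) {
  a0 <- par[1]; TA <- par[2]; TB <- par[3]
  if (a0 <= 0 || TA <= 0 || TB <= 0) return(1e12)
  v <- -sum(tab$w * log_f12(tab$xa, tab$xb, a0, TA, TB))
  if (!is.finite(v)) 1e12 else v
}

tab_counts <- function(xa, xb) {
  key <- paste(xa, xb)
  t <- table(key)
  parts <- do.call(rbind, strsplit(names(t), " ", fixed = TRUE))
  list(xa = as.integer(parts[, 1]), xb = as.integer(parts[, 2]),
       w = as.numeric(t))
}

moment_start <- function(xa, xb) {
  TA <- max(mean(xa), 1e-3); TB <- max(mean(xb), 1e-3)
  a_of <- function(x, T) {
    v <- var(x)
    if (!is.finite(v) || v <= T) return(5)
    min(max(T^2 / (v - T), 0.05), 50)
  }
  c(a_of(xa, TA), a_of(xb, TB), TA, TB)
}

#' Estimate the type I functional-divergence coefficient
#'
#' Fits by maximum likelihood the two-state mixture of Gu's type I model:
#' with probability `1 - theta` a site's evolutionary rate is shared between
#' the two clusters, with probability `theta` the rates are decoupled
#' (drawn independently). Rates are mean-1 gamma distributed (shape
#' `alpha_A`, `alpha_B` in the decoupled component; their mean in the shared
#' component) and per-site substitution counts are Poisson given the rate,
#' marginalised analytically to negative-binomial forms. The likelihood
#' ratio statistic contrasts the fit against `theta = 0`; its reference
#' distribution is the boundary 50:50 mixture of a point mass at zero and
#' chi-squared(1). The standard error of `theta` comes from the observed
#' information; per-site posterior probabilities of rate decoupling come
#' from Bayes' rule.
#'
#' @param counts a `site_counts` object ([fitch_counts()] or
#'   [sample_type1_counts()]). Columns masked in either cluster are
#'   excluded from the likelihood.
#' @param pair optional [cluster_pair()] (used only for context in
#'   warnings).
#' @param restarts number of jittered optimizer restarts (default 3).
#' @param seed seed for the restart jitter.
#' @return object of class `type1_result`: list with `theta`, `se`, `lrt`,
#'   `p_value`, `alpha_A`, `alpha_B`, `T_A`, `T_B`, `logLik`, `posterior`
#'   (length L, `NA` at masked columns).
#' @export
estimate_type1 <- function(counts, pair = NULL, restarts = 3, seed = 1) {
  stopifnot(inherits(counts, "site_counts"))
  use <- !(counts$mask_A | counts$mask_B)
  xa <- counts$X_A[use]; xb <- counts$X_B[use]
  L <- length(xa)
  if (L < 50)
    warning("only ", L, " usable sites; theta estimates below L = 50 are unstable")
  tab <- tab_counts(xa, xb)
  ms <- moment_start(xa, xb)

  fit_null <- best_optim(function(p) type1_nll_null(p, tab),
                         starts = list(c(mean(ms[1:2]), ms[3], ms[4])),
                         lower = c(0.05, 1e-4, 1e-4),
                         upper = c(50, 1e3, 1e3))
  starts <- list(c(0.2, ms), c(0.6, ms),
                 c(1e-4, mean(ms[1:2]), mean(ms[1:2]),
                   fit_null$par[2], fit_null$par[3]))
  local_seed(seed, {
    for (r in seq_len(max(0, restarts - 1))) {
      starts[[length(starts) + 1L]] <-
        c(runif(1, 0.05, 0.95), ms * exp(rnorm(4, 0, 0.3)))
    }
  })
  fit <- best_optim(function(p) type1_nll(p, tab), starts = starts,
                    lower = c(0, 0.05, 0.05, 1e-4, 1e-4),
                    upper = c(1 - 1e-6, 50, 50, 1e3, 1e3))
  ll1 <- -fit$value
  ll0 <- -fit_null$value
  lrt <- max(0, 2 * (ll1 - ll0))
  p_value <- if (lrt <= 0) 1 else 0.5 * pchisq(lrt, df = 1, lower.tail = FALSE)
  theta <- fit$par[1]
  se <- theta_se(fit$par, tab)
  post_use <- type1_posterior(fit$par, xa, xb)
  posterior <- rep(NA_real_, counts$L)
  posterior[use] <- post_use
  structure(list(theta = theta, se = se, lrt = lrt, p_value = p_value,
                 alpha_A = fit$par[2], alpha_B = fit$par[3],
                 T_A = fit$par[4], T_B = fit$par[5],
                 logLik = ll1, logLik_null = ll0, n_sites = L,
                 posterior = posterior),
            class = "type1_result")
}

#' @export
print.type1_result <- function(x, ...) {
  cat(sprintf("<type1_result> theta = %.3f +/- %s, LRT = %.2f (p = %.3g), alpha = (%.2f, %.2f)\n",
              x$theta, ifelse(is.na(x$se), "NA", sprintf("%.3f", x$se)),
              x$lrt, x$p_value, x$alpha_A, x$alpha_B))
  invisible(x)
}

best_optim <- function(fn, starts, lower, upper) {
  best <- NULL
  for (s in starts) {
    s <- pmin(pmax(s, lower + 1e-8), upper - 1e-8)
    f <- tryCatch(
      optim(s, fn, method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(maxit = 500)),
      error = function(e) NULL)
    if (is.null(f)) next
    if (is.null(best) || f$value < best$value) best <- f
  }
  if (is.null(best))
    stop("optimizer failed to converge from every start")
  best
}

type1_posterior <- function(par, xa, xb) {
  theta <- par[1]
  a0 <- (par[2] + par[3]) / 2
  lsh <- log_f12(xa, xb, a0, par[4], par[5])
  lin <- dnbinom(xa, size = par[2], mu = par[4], log = TRUE) +
    dnbinom(xb, size = par[3], mu = par[5], log = TRUE)
  m <- pmax(lsh, lin)
  num <- theta * exp(lin - m)
  den <- (1 - theta) * exp(lsh - m) + num
  num / den
}

theta_se <- function(par, tab) {
  if (par[1] < 1e-3 || par[1] > 1 - 1e-3) return(NA_real_)
  H <- tryCatch(pracma::hessian(function(p) type1_nll(p, tab), par),
                error = function(e) NULL)
  if (is.null(H)) return(NA_real_)
  v <- tryCatch(solve(H)[1, 1], error = function(e) NA_real_)
  if (is.na(v) || v <= 0) NA_real_ else sqrt(v)
}

#' Candidate type I sites above a posterior cutoff
#'
#' @param result a `type1_result`.
#' @param cutoff posterior cutoff (strict `>`, default 0.85).
#' @param aln optional [msa()] used to map alignment columns to the residue
#'   numbering of a reference row.
#' @param reference name of the reference row in `aln`.
#' @return data.frame with `column` (1-based alignment column), `posterior`
#'   and, when a reference is given, `ref_pos` (`NA` where the reference row
#'   has a gap).
#' @export
candidate_sites_type1 <- function(result, cutoff = 0.85, aln = NULL,
                                  reference = NULL) {
  stopifnot(inherits(result, "type1_result"))
  idx <- which(!is.na(result$posterior) & result$posterior > cutoff)
  out <- data.frame(column = idx, posterior = result$posterior[idx])
  if (!is.null(aln) && !is.null(reference)) {
    taxa <- msa_taxa(aln)
    if (!reference %in% taxa) stop("reference row '", reference, "' not in alignment")
    row <- msa_matrix(aln)[reference, ]
    refmap <- ifelse(row == "-", NA_integer_, cumsum(row != "-"))
    out$ref_pos <- refmap[idx]
  }
  out
}
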