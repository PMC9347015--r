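#' Log-likelihood of the admixture (STRUCTURE/ADMIXTURE) model
#'
#' Under K ancestral populations with allele frequencies `F` (K x sites)
#' and individual ancestry fractions `Q` (samples x K), each of the two
#' alleles of sample `i` at site `j` is alternate with probability
#' `p_ij = sum_k q_ik f_kj`, so a called genotype `g` contributes
#' `g log p + (2 - g) log(1 - p)`. Missing genotypes are skipped.
#'
#' @param gm a [genotype_matrix()].
#' @param Q samples x K matrix, rows summing to 1.
#' @param F K x sites matrix of ancestral alternate-allele frequencies.
#' @return log-likelihood (scalar).
#' @export
admixture_loglik <- function(gm, Q, F) {
  g <- gm$geno
  if (nrow(Q) != nrow(g) || ncol(F) != ncol(g) || ncol(Q) != nrow(F))
    stop("inconsistent shapes for genotypes, Q and F")
  if (any(abs(rowSums(Q) - 1) > 1e-6)) stop("Q rows must sum to 1")
  p <- Q %*% F
  if (any(p <= 0 | p >= 1))
    stop("mixture probabilities outside (0, 1); clamp F away from 0/1")
  ok <- !is.na(g)
  sum(g[ok] * log(p[ok]) + (2 - g[ok]) * log(1 - p[ok]))
}

# one EM sweep; returns list(Q, F, loglik of the INPUT parameters)
em_step <- function(g, called, m_i, Q, F, f_eps, q_floor) {
  P <- Q %*% F                       # n x m mixture probabilities
  K <- ncol(Q)
  n <- nrow(g); m <- ncol(g)
  g0 <- ifelse(called, g, 0)         # alt-allele counts, 0 where missing
  h0 <- ifelse(called, 2 - g, 0)     # ref-allele counts
  A <- g0 / P                        # shared factors of the E-step
  B <- h0 / (1 - P)
  Qn <- matrix(0, n, K)
  Fn <- matrix(0, K, m)
  for (k in seq_len(K)) {
    ak <- (A * F[rep(k, n), , drop = FALSE]) * Q[, k]   # E[alt alleles from k]
    bk <- (B * (1 - F)[rep(k, n), , drop = FALSE]) * Q[, k]
    Qn[, k] <- rowSums(ak + bk)
    Fn[k, ] <- colSums(ak) / pmax(colSums(ak) + colSums(bk), 1e-300)
  }
  Qn <- Qn / (2 * m_i)
  Qn <- pmax(Qn, q_floor)
  Qn <- Qn / rowSums(Qn)
  Fn <- pmin(pmax(Fn, f_eps), 1 - f_eps)
  ok <- called
  ll <- sum(g0[ok] * log(P[ok]) + h0[ok] * log(1 - P[ok]))
  list(Q = Qn, F = Fn, loglik = ll)
}

#' Estimate ancestry coefficients by EM
#'
#' Unsupervised maximum-likelihood estimation of `Q` and `F` for a given
#' K via the standard EM updates on allele-origin posteriors (simpler
#' and monotone, unlike ADMIXTURE's block-relaxation; adequate at this
#' scale). Multi-start; the best start by log-likelihood is returned.
#' The log-likelihood is checked to be non-decreasing at every
#' iteration. Deterministic given `seed`.
#'
#' @param gm a [genotype_matrix()].
#' @param K number of ancestral populations (>= 1).
#' @param n_starts random restarts.
#' @param max_iters EM iteration cap per start.
#' @param tol stop when the log-likelihood gain drops below `tol`.
#' @param seed integer seed.
#' @return a list of class `ancestry_result`: `K`, `Q`, `F`, `loglik`,
#'   `n_iters`, `loglik_trace`, `seed`.
#' @export
fit_admixture <- function(gm, K, n_starts = 8, max_iters = 2000, tol = 1e-6,
                          seed = 1) {
  if (K < 1) stop("K must be >= 1")
  if (n_samples(gm) < K) stop("need at least K samples")
  g <- gm$geno
  called <- !is.na(g)
  all_missing <- rowSums(called) == 0
  if (any(all_missing))
    stop("sample(s) with no called genotype: ",
         paste(gm$sample_ids[all_missing], collapse = ", "))
  f_eps <- 1e-6; q_floor <- 1e-9
  m_i <- rowSums(called)
  freq <- colSums(ifelse(called, g, 0)) / (2 * colSums(called))
  freq <- pmin(pmax(freq, f_eps), 1 - f_eps)
  if (K == 1) { # closed form: Q all ones, F the observed frequencies
    Q <- matrix(1, n_samples(gm), 1)
    F <- matrix(freq, 1)
    ll <- admixture_loglik(gm, Q, F)
    return(structure(list(K = 1L, Q = Q, F = F, loglik = ll, n_iters = 0L,
                          loglik_trace = ll, seed = seed),
                     class = "ancestry_result"))
  }
  set.seed(seed)
  best <- NULL
  for (st in seq_len(n_starts)) {
    # random perturbation of the pooled frequencies, Dirichlet-ish Q
    F <- matrix(rep(freq, each = K), K)
    F <- pmin(pmax(F + matrix(stats::runif(K * length(freq), -0.1, 0.1), K),
                   f_eps), 1 - f_eps)
    Q <- matrix(stats::rexp(n_samples(gm) * K), ncol = K)
    Q <- Q / rowSums(Q)
    trace <- numeric(0)
    ll_prev <- -Inf
    iter <- 0
    repeat {
      iter <- iter + 1
      stp <- em_step(g, called, m_i, Q, F, f_eps, q_floor)
      if (stp$loglik < ll_prev - 1e-6 * abs(ll_prev))
        stop("EM log-likelihood decreased; this should not happen")
      trace <- c(trace, stp$loglik)
      gain <- stp$loglik - ll_prev
      Q <- stp$Q; F <- stp$F
      ll_prev <- stp$loglik
      if (iter >= max_iters || (iter > 1 && gain < tol)) break
    }
    ll_final <- admixture_loglik(gm, Q, F)
    if (is.null(best) || ll_final > best$loglik)
      best <- list(Q = Q, F = F, loglik = ll_final, n_iters = iter,
                   trace = c(trace, ll_final))
  }
  rownames(best$Q) <- gm$sample_ids
  structure(list(K = as.integer(K), Q = best$Q, F = best$F,
                 loglik = best$loglik, n_iters = best$n_iters,
                 loglik_trace = best$trace, seed = seed),
            class = "ancestry_result")
}

#' @export
print.ancestry_result <- function(x, ...) {
  cat(sprintf("ancestry_result: K=%d, %d samples, loglik %.2f (%d iterations)\n",
              x$K, nrow(x$Q), x$loglik, x$n_iters))
  invisible(x)
}

#' Cross-validation error for choosing K
#'
#' Masks a random fold of the called genotypes, fits the admixture model
#' on the rest, and scores the masked cells by their mean predictive
#' binomial deviance `-2 [g log p + (2 - g) log(1 - p)] / 2`; averaged
#' over folds. A fold that would leave a sample or site with no data is
#' re-drawn (at most 10 attempts). Deterministic given `seed`.
#'
#' @param gm a [genotype_matrix()].
#' @param K number of ancestral populations.
#' @param folds number of folds (>= 2).
#' @param seed integer seed.
#' @param ... passed to [fit_admixture()].
#' @return a list of class `cv_result`: `mean_deviance`, `per_fold`,
#'   `n_masked`.
#' @export
cv_error <- function(gm, K, folds = 5, seed = 1, ...) {
  if (folds < 2) stop("folds must be >= 2")
  set.seed(seed)
  called_idx <- which(!is.na(gm$geno))
  assign_folds <- NULL
  for (attempt in 1:10) {
    cand <- sample(rep_len(seq_len(folds), length(called_idx)))
    ok <- TRUE
    for (f in seq_len(folds)) {
      g <- gm$geno
      g[called_idx[cand == f]] <- NA_integer_
      if (any(rowSums(!is.na(g)) == 0) || any(colSums(!is.na(g)) == 0)) {
        ok <- FALSE; break
      }
    }
    if (ok) { assign_folds <- cand; break }
  }
  if (is.null(assign_folds))
    stop("could not draw folds leaving every sample and site with data")
  dev <- numeric(folds)
  nm <- integer(folds)
  for (f in seq_len(folds)) {
    mask <- called_idx[assign_folds == f]
    g_train <- gm$geno
    g_train[mask] <- NA_integer_
    gm_train <- gm
    gm_train$geno <- g_train
    fit <- fit_admixture(gm_train, K, seed = seed + f, ...)
    p <- fit$Q %*% fit$F
    g_true <- gm$geno[mask]
    dev[f] <- mean(-2 * (g_true * log(p[mask]) +
                           (2 - g_true) * log(1 - p[mask])) / 2)
    nm[f] <- length(mask)
  }
  structure(list(mean_deviance = mean(dev), per_fold = dev, n_masked = nm,
                 K = K, folds = folds, seed = seed),
            class = "cv_result")
}

#' Write Q and F matrices in ADMIXTURE file conventions
#'
#' `Q` as a whitespace-delimited matrix (`.Q`), `F` transposed to sites x
#' K (`.P`).
#'
#' @param res an `ancestry_result`.
#' @param prefix output path prefix; writes `<prefix>.<K>.Q` and
#'   `<prefix>.<K>.P`.
#' @return the two paths, invisibly.
#' @export
write_ancestry <- function(res, prefix) {
  qp <- sprintf("%s.%d.Q", prefix, res$K)
  pp <- sprintf("%s.%d.P", prefix, res$K)
  utils::write.table(format(res$Q, digits = 6), qp, quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(format(t(res$F), digits = 6), pp, quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(c(qp, pp))
}
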