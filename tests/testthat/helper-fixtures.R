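## Shared fixtures and independent oracles used across the test files.

## small named expression matrix
toy_matrix <- function(n = 20, p = 3, seed = 1, prefix = "P") {
  set.seed(seed)
  m <- matrix(rnorm(n * p), n, p,
              dimnames = list(sprintf("s%02d", seq_len(n)),
                              sprintf("%s%d", prefix, seq_len(p))))
  m
}

## regression problem on a fixed design, bypassing the builder, so the
## marginal-likelihood tests control Z exactly
manual_problem <- function(y, Z, g = length(y)) {
  y <- y - mean(y)
  structure(list(target = "tgt", y = y, Z = Z,
                 meta = data.frame(name = colnames(Z),
                                   kind = "protein-regulator",
                                   prior_w = 0.5, stringsAsFactors = FALSE),
                 g = g, n = length(y)),
            class = "pronet_problem")
}

## Independent numerical-integration oracle for the (beta, sigma) marginal
## under the g-prior and p(sigma) ~ 1/sigma: tensor Gauss-Legendre over
## beta nested in adaptive quadrature over log sigma. Supports k <= 3.
oracle_log_marginal <- function(y, Z, model, g = length(y), nodes = 60) {
  y <- y - mean(y)
  n <- length(y)
  k <- length(model)
  if (k == 0) {
    f <- Vectorize(function(ls) {
      s <- exp(ls)
      (2 * pi * s^2)^(-n / 2) * exp(-sum(y^2) / (2 * s^2))
    })
    shat <- sqrt(sum(y^2) / n)
    return(log(stats::integrate(f, log(shat) - 6, log(shat) + 6,
                                rel.tol = 1e-11)$value))
  }
  Zm <- Z[, model, drop = FALSE]
  XtX <- crossprod(Zm)
  XtXinv <- solve(XtX)
  bhat <- as.vector(XtXinv %*% crossprod(Zm, y))
  beta_integral <- function(sigma) {
    m <- g / (1 + g) * bhat
    sdp <- sigma * sqrt(diag(XtXinv) * g / (1 + g))
    qs <- lapply(seq_len(k), function(j)
      pracma::gaussLegendre(nodes, m[j] - 10 * sdp[j], m[j] + 10 * sdp[j]))
    gr <- as.matrix(expand.grid(lapply(qs, `[[`, "x")))
    wg <- Reduce(function(a, b) as.vector(outer(a, b)),
                 lapply(qs, `[[`, "w"))
    resid2 <- colSums((matrix(y, n, nrow(gr)) - Zm %*% t(gr))^2)
    pb2 <- rowSums((gr %*% XtX) * gr) / g
    lik <- (2 * pi * sigma^2)^(-n / 2) * exp(-resid2 / (2 * sigma^2))
    pr <- (2 * pi * sigma^2)^(-k / 2) * sqrt(det(XtX / g)) *
      exp(-pb2 / (2 * sigma^2))
    sum(wg * lik * pr)
  }
  shat <- sqrt(sum(stats::lm.fit(Zm, y)$residuals^2) / n) + 1e-8
  log(stats::integrate(Vectorize(function(ls) beta_integral(exp(ls))),
                       log(shat) - 6, log(shat) + 6, rel.tol = 1e-10)$value)
}

## rank-based (Wilcoxon) AUROC, independent of any package code
auroc <- function(score, truth) {
  r <- rank(score)
  n1 <- sum(truth); n0 <- sum(!truth)
  (sum(r[truth]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

## moral-graph adjacency of a truth DAG (skeleton + married parents)
moral_adjacency <- function(dag, ids) {
  m <- matrix(FALSE, length(ids), length(ids), dimnames = list(ids, ids))
  for (r in seq_len(nrow(dag))) {
    m[dag$src[r], dag$dst[r]] <- m[dag$dst[r], dag$src[r]] <- TRUE
  }
  for (v in ids) {
    pa <- dag$src[dag$dst == v]
    if (length(pa) > 1) {
      for (i in seq_along(pa)) for (j in seq_along(pa)) {
        if (i < j) m[pa[i], pa[j]] <- m[pa[j], pa[i]] <- TRUE
      }
    }
  }
  m
}

## pooled PIP scores and moral-graph labels for protein-pair recovery
pip_recovery <- function(fits, moral) {
  ids <- names(fits)
  score <- numeric(); lab <- logical()
  for (j in ids) {
    pp <- fits[[j]]$pips
    prot <- intersect(names(pp), ids)
    score <- c(score, pp[prot])
    lab <- c(lab, moral[prot, j])
  }
  list(score = score, label = lab)
}

## exact P(theta1 > theta2) for independent Betas, by quadrature
beta_compare_exact <- function(a1, b1, a2, b2) {
  stats::integrate(function(t) stats::dbeta(t, a1, b1) *
                     stats::pbeta(t, a2, b2),
                   0, 1, rel.tol = 1e-10)$value
}
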