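#' Upstream covariates for one gene
#'
#' Builds the upstream covariate block used in a protein's regression: the
#' gene's mRNA is regressed on its methylation probe(s) by least squares,
#' the fitted values forming the methylation-modulated component and the
#' residuals the methylation-independent component; the expression vectors
#' of the miRNAs mapped to the gene are appended. With one or more
#' methylation probes and `m` mapped miRNAs the block has `2 + m` columns.
#'
#' @param mrna,methyl,mirna `pronet_em` objects (or matrices) with matched
#'   samples. `methyl` columns are matched to `gene` by name.
#' @param gene Gene id.
#' @param mirna_map Named list mapping genes to miRNA feature ids.
#' @return A numeric matrix (samples x K) with a `kinds` attribute tagging
#'   each column as `mrna-modulated`, `mrna-independent` or `mirna`;
#'   `NULL` if the gene is absent from every platform.
#' @export
construct_upstream_covariates <- function(mrna, methyl, mirna, gene,
                                          mirna_map = NULL) {
  r_mat <- if (!is.null(mrna)) em_values(mrna) else NULL
  m_mat <- if (!is.null(methyl)) em_values(methyl) else NULL
  q_mat <- if (!is.null(mirna)) em_values(mirna) else NULL
  cols <- list(); kinds <- character()

  has_mrna <- !is.null(r_mat) && gene %in% colnames(r_mat)
  if (has_mrna) {
    r <- r_mat[, gene]
    probes <- if (!is.null(m_mat)) which(colnames(m_mat) == gene) else integer()
    if (length(probes)) {
      fit <- stats::lm.fit(cbind(1, m_mat[, probes, drop = FALSE]), r)
      cols[[sprintf("%s.mrna_mod", gene)]] <- fit$fitted.values
      cols[[sprintf("%s.mrna_ind", gene)]] <- fit$residuals
    } else {
      ## no methylation probe: whole mRNA is methylation-independent
      cols[[sprintf("%s.mrna_mod", gene)]] <- rep(0, length(r))
      cols[[sprintf("%s.mrna_ind", gene)]] <- r
    }
    kinds <- c(kinds, "mrna-modulated", "mrna-independent")
  } else if (!is.null(r_mat)) {
    warning("gene ", gene, " absent from mRNA matrix; using miRNAs only")
  }
  mirs <- intersect(if (is.null(mirna_map)) character() else mirna_map[[gene]],
                    colnames(q_mat))
  for (mid in mirs) {
    cols[[mid]] <- q_mat[, mid]
    kinds <- c(kinds, "mirna")
  }
  if (!length(cols)) return(NULL)
  Z <- do.call(cbind, cols)
  colnames(Z) <- names(cols)
  attr(Z, "kinds") <- kinds
  Z
}

#' Assemble a node-wise regression problem
#'
#' Centers the target protein's expression and builds the standardized
#' design of candidate covariates: the candidate protein regulators (those
#' with positive prior inclusion probability for this target) and the
#' upstream covariate block. All design columns are centered and scaled to
#' unit standard deviation so the unit-information prior `g = n` has a
#' uniform meaning; coefficients are therefore on the standardized scale.
#'
#' @param target Protein id.
#' @param protein A `pronet_em` or matrix of protein expression.
#' @param prior A `pronet_prior` matrix (rows regulator, cols target), or
#'   `NULL` for no protein regulators.
#' @param upstream Optional matrix from [construct_upstream_covariates()].
#' @param config A [pronet_config()].
#' @return An object of class `pronet_problem`: `target`, centered `y`,
#'   design `Z`, candidate metadata (`name`, `kind`, `prior_w`), `g`, `n`.
#' @export
regression_problem <- function(target, protein, prior = NULL,
                               upstream = NULL, config = pronet_config()) {
  P <- em_values(protein)
  stopifnot(target %in% colnames(P))
  y <- P[, target]
  y <- y - mean(y)
  n <- length(y)
  meta <- data.frame(name = character(), kind = character(),
                     prior_w = numeric(), stringsAsFactors = FALSE)
  blocks <- list()
  if (!is.null(prior) && target %in% colnames(prior)) {
    w <- prior[, target]
    upa <- setdiff(names(w)[w > 0], target)
    upa <- intersect(upa, colnames(P))
    if (length(upa)) {
      blocks$prot <- P[, upa, drop = FALSE]
      meta <- rbind(meta, data.frame(name = upa, kind = "protein-regulator",
                                     prior_w = w[upa],
                                     stringsAsFactors = FALSE))
    }
  }
  if (!is.null(upstream) && ncol(upstream)) {
    blocks$up <- upstream
    meta <- rbind(meta, data.frame(name = colnames(upstream),
                                   kind = attr(upstream, "kinds"),
                                   prior_w = config$default_upstream_prior,
                                   stringsAsFactors = FALSE))
  }
  Z <- if (length(blocks)) do.call(cbind, blocks) else
    matrix(0, n, 0)
  colnames(Z) <- meta$name
  if (ncol(Z)) {
    sds <- apply(Z, 2, stats::sd)
    keep <- sds > 0
    if (!all(keep)) {
      warning("dropping constant candidate(s): ",
              paste(meta$name[!keep], collapse = ", "))
      Z <- Z[, keep, drop = FALSE]; meta <- meta[keep, , drop = FALSE]
      sds <- sds[keep]
    }
    Z <- scale(Z, center = TRUE, scale = sds)
    attr(Z, "scaled:center") <- NULL; attr(Z, "scaled:scale") <- NULL
  }
  rownames(meta) <- NULL
  g <- if (is.null(config$g)) n else config$g
  structure(list(target = target, y = y, Z = Z, meta = meta, g = g, n = n),
            class = "pronet_problem")
}

#' Closed-form log marginal likelihood under the Zellner g-prior
#'
#' For a centered response `y` with model design `Z_M` (k columns), the
#' coefficient prior `beta | sigma ~ N(0, sigma^2 g (Z'Z)^-1)` and the
#' scale prior `p(sigma) ~ 1/sigma`, the marginal likelihood is available
#' in closed form through the model's R-squared:
#' `log m(M) = c(y) - (k/2) log(1+g) + (n/2) log(1+g)
#'            - (n/2) log(1 + g (1 - R2_M))`
#' with `c(y)` shared across models. The value returned includes all
#' constants, so it is directly comparable with numerical integration of
#' the (beta, sigma) integral.
#'
#' Rank-deficient model designs fall back to a pseudo-inverse R-squared
#' with a warning (exact duplicates can occur in simulated data).
#'
#' @param problem A `pronet_problem`.
#' @param model Integer or logical index of the candidate columns in the
#'   model (possibly empty).
#' @return The log marginal likelihood (a scalar).
#' @export
log_marginal_likelihood <- function(problem, model = integer()) {
  y <- problem$y; n <- problem$n; g <- problem$g
  if (is.logical(model)) model <- which(model)
  k <- length(model)
  if (k >= n - 1) stop("model size must be below n - 1")
  yty <- sum(y^2)
  R2 <- if (k == 0) 0 else model_r2(problem$Z[, model, drop = FALSE], y)
  Q <- yty * (1 + g * (1 - R2)) / (1 + g)
  -(n / 2) * log(2 * pi) - (k / 2) * log1p(g) - log(2) + lgamma(n / 2) +
    (n / 2) * log(2) - (n / 2) * log(Q)
}

model_r2 <- function(Zm, y) {
  qrz <- qr(Zm)
  if (qrz$rank < ncol(Zm)) {
    warning("rank-deficient model design; using pseudo-inverse fit")
  }
  fit <- qr.fitted(qrz, y)
  min(max(sum(fit * y) / sum(y^2), 0), 1)
}

#' Posterior over models for one protein regression
#'
#' Independent Bernoulli model prior with each candidate's prior inclusion
#' probability: `P(M) = prod_c w_c^{g_c} (1-w_c)^{1-g_c}`. If the number of
#' candidates is at most `config$enumeration_limit`, all `2^k` models are
#' enumerated exactly; otherwise an MC3 add/delete/swap Metropolis sampler
#' is run for `config$mcmc_iters` iterations. Posterior inclusion
#' probabilities (PIPs) are exact model-probability sums under enumeration
#' and post-burn-in visit frequencies under MC3. The median probability
#' model (MPM) keeps candidates with PIP strictly greater than 0.5.
#'
#' @param problem A `pronet_problem`.
#' @param config A [pronet_config()].
#' @param method `"auto"` (regime switch on candidate count),
#'   `"enumeration"`, or `"mc3"`.
#' @return An object of class `pronet_nodefit`: `pips` (named), `mpm`
#'   (candidate names), `coef` (posterior mean/sd of standardized
#'   coefficients under the MPM), `sigma2` (posterior mean of the residual
#'   variance under the MPM), `log_evidence`, `method`, plus the problem
#'   dimensions needed downstream.
#' @export
model_posterior <- function(problem, config = pronet_config(),
                            method = c("auto", "enumeration", "mc3")) {
  method <- match.arg(method)
  k <- ncol(problem$Z)
  if (method == "auto") {
    method <- if (k <= config$enumeration_limit) "enumeration" else "mc3"
  }
  if (k == 0) {
    return(new_nodefit(problem, pips = stats::setNames(numeric(), character()),
                       method = "enumeration", log_evidence = NULL))
  }
  w <- problem$meta$prior_w
  if (method == "enumeration") {
    res <- enumerate_models(problem, w)
  } else {
    res <- mc3_sample(problem, w, config)
  }
  new_nodefit(problem, pips = stats::setNames(res$pips, problem$meta$name),
              method = method, log_evidence = res$log_evidence)
}

## Exact enumeration of all 2^k models using precomputed cross-products.
enumerate_models <- function(problem, w) {
  Z <- problem$Z; y <- problem$y
  k <- ncol(Z); n <- problem$n; g <- problem$g
  XtX <- crossprod(Z); Xty <- crossprod(Z, y)[, 1]; yty <- sum(y^2)
  lw1 <- log(w); lw0 <- log1p(-w)
  lw0[w == 1] <- -Inf
  n_models <- 2^k
  const <- -(n / 2) * log(2 * pi) - log(2) + lgamma(n / 2) + (n / 2) * log(2)
  logpost <- numeric(n_models)
  masks <- matrix(FALSE, n_models, k)
  for (m in seq_len(n_models)) {
    bits <- as.logical(bitwAnd(m - 1L, bitwShiftL(1L, 0:(k - 1L))))
    masks[m, ] <- bits
    km <- sum(bits)
    lprior <- sum(lw1[bits]) + sum(lw0[!bits])
    if (!is.finite(lprior)) { logpost[m] <- -Inf; next }
    R2 <- if (km == 0) 0 else subset_r2(XtX, Xty, yty, which(bits))
    Q <- yty * (1 + g * (1 - R2)) / (1 + g)
    lm_m <- const - (km / 2) * log1p(g) - (n / 2) * log(Q)
    logpost[m] <- lm_m + lprior
  }
  mx <- max(logpost)
  post <- exp(logpost - mx)
  post <- post / sum(post)
  pips <- as.vector(post %*% masks)
  list(pips = pips,
       log_evidence = list(log_posterior = logpost, post = post,
                           masks = masks))
}

subset_r2 <- function(XtX, Xty, yty, idx) {
  A <- XtX[idx, idx, drop = FALSE]
  b <- Xty[idx]
  coef <- tryCatch(solve(A, b), error = function(e) {
    warning("rank-deficient model design; using pseudo-inverse fit")
    MASS_ginv(A) %*% b
  })
  min(max(sum(coef * b) / yty, 0), 1)
}

## MC3: Metropolis over model space with toggle and swap moves.
mc3_sample <- function(problem, w, config) {
  Z <- problem$Z; y <- problem$y
  k <- ncol(Z); n <- problem$n; g <- problem$g
  XtX <- crossprod(Z); Xty <- crossprod(Z, y)[, 1]; yty <- sum(y^2)
  lw1 <- log(w); lw0 <- log1p(-w); lw0[w == 1] <- -Inf
  score <- function(bits) {
    lprior <- sum(lw1[bits]) + sum(lw0[!bits])
    if (!is.finite(lprior)) return(-Inf)
    km <- sum(bits)
    if (km >= n - 1) return(-Inf)
    R2 <- if (km == 0) 0 else subset_r2(XtX, Xty, yty, which(bits))
    Q <- yty * (1 + g * (1 - R2)) / (1 + g)
    -(km / 2) * log1p(g) - (n / 2) * log(Q) + lprior
  }
  rs <- local_rng(substream_seed(config$seed, paste0("mc3", problem$target)))
  on.exit(rs$restore(), add = TRUE)
  bits <- w >= 1            # forced candidates start included
  s_cur <- score(bits)
  iters <- config$mcmc_iters
  burn <- floor(iters / 10)
  incl <- numeric(k)
  visits <- new.env(parent = emptyenv())
  for (it in seq_len(iters)) {
    prop <- bits
    if (stats::runif(1) < 0.5 || all(bits) || !any(bits)) {
      j <- sample.int(k, 1)
      prop[j] <- !prop[j]
    } else {
      i_in <- which(bits); i_out <- which(!bits)
      prop[i_in[sample.int(length(i_in), 1)]] <- FALSE
      prop[i_out[sample.int(length(i_out), 1)]] <- TRUE
    }
    s_prop <- score(prop)
    if (is.finite(s_prop) &&
        log(stats::runif(1)) < s_prop - s_cur) {
      bits <- prop; s_cur <- s_prop
    }
    if (it > burn) {
      incl <- incl + bits
      key <- paste(which(bits), collapse = ",")
      visits[[key]] <- (if (is.null(visits[[key]])) 0 else visits[[key]]) + 1L
    }
  }
  list(pips = incl / (iters - burn),
       log_evidence = list(visit_counts = as.list(visits)))
}

new_nodefit <- function(problem, pips, method, log_evidence) {
  mpm <- names(pips)[pips > 0.5]
  fit <- mpm_summary(problem, mpm)
  structure(list(target = problem$target,
                 pips = pips,
                 mpm = mpm,
                 meta = problem$meta,
                 coef = fit$coef,
                 sigma2 = fit$sigma2,
                 Q = fit$Q,
                 method = method,
                 log_evidence = log_evidence,
                 n = problem$n, g = problem$g),
            class = "pronet_nodefit")
}

## Posterior summaries of the coefficients and residual scale under the MPM
mpm_summary <- function(problem, mpm) {
  y <- problem$y; n <- problem$n; g <- problem$g
  yty <- sum(y^2)
  if (!length(mpm)) {
    return(list(coef = data.frame(name = character(), mean = numeric(),
                                  sd = numeric(), stringsAsFactors = FALSE),
                sigma2 = yty / (n - 2), Q = yty))
  }
  Zm <- problem$Z[, mpm, drop = FALSE]
  qrz <- qr(Zm)
  bhat <- qr.coef(qrz, y)
  bhat[is.na(bhat)] <- 0
  R2 <- min(max(sum(qr.fitted(qrz, y) * y) / yty, 0), 1)
  Q <- yty * (1 + g * (1 - R2)) / (1 + g)
  shrink <- g / (1 + g)
  XtX <- crossprod(Zm)
  XtXinv <- tryCatch(solve(XtX), error = function(e) MASS_ginv(XtX))
  ## beta | y is multivariate-t: scale matrix shrink * (Z'Z)^-1 * Q/n, df n
  v <- diag(XtXinv) * shrink * Q / n * n / (n - 2)
  list(coef = data.frame(name = mpm, mean = shrink * bhat,
                         sd = sqrt(pmax(v, 0)), stringsAsFactors = FALSE),
       sigma2 = Q / (n - 2), Q = Q)
}

#' @export
print.pronet_nodefit <- function(x, ...) {
  cat(sprintf("<node fit %s: %d candidates, MPM size %d (%s)>\n",
              x$target, length(x$pips), length(x$mpm), x$method))
  invisible(x)
}

#' Integrated cancer-specific network from node fits
#'
#' Applies the median-probability-model edge typing: if protein i is in the
#' MPM of protein j but not vice versa, a directed regulatory edge i -> j;
#' if each is in the other's MPM, a single correlative edge. Selected
#' upstream covariates become upstream edges. The out-degree `C_i` counts
#' protein-protein edges only (regulatory out-edges plus correlative
#' incidences); upstream edges are reported but never enter the topology
#' weights.
#'
#' @param fits Named list of `pronet_nodefit`, one per pathway protein.
#' @param cancer_type,pathway Metadata strings.
#' @return A `pronet_network`.
#' @export
build_integrated_network <- function(fits, cancer_type = "NA",
                                     pathway = "NA") {
  proteins <- names(fits)
  stopifnot(!is.null(proteins))
  pip_of <- function(i, j) {           # pip of i as regulator of j
    v <- fits[[j]]$pips
    if (i %in% names(v)) unname(v[i]) else 0
  }
  in_mpm <- function(i, j) i %in% fits[[j]]$mpm
  pe <- NULL
  for (i in proteins) for (j in proteins) {
    if (i == j) next
    if (in_mpm(i, j)) {
      if (in_mpm(j, i)) {
        if (i < j) {                   # emit the correlative pair once
          pf <- pip_of(i, j); pr <- pip_of(j, i)
          pe <- rbind(pe, data.frame(src = i, dst = j, kind = "correlative",
                                     pip = max(pf, pr), pip_fwd = pf,
                                     pip_rev = pr, stringsAsFactors = FALSE))
        }
      } else {
        pe <- rbind(pe, data.frame(src = i, dst = j, kind = "regulatory",
                                   pip = pip_of(i, j), pip_fwd = pip_of(i, j),
                                   pip_rev = NA_real_,
                                   stringsAsFactors = FALSE))
      }
    }
  }
  if (is.null(pe)) {
    pe <- data.frame(src = character(), dst = character(), kind = character(),
                     pip = numeric(), pip_fwd = numeric(), pip_rev = numeric(),
                     stringsAsFactors = FALSE)
  }
  ue <- NULL
  for (j in proteins) {
    sel <- setdiff(fits[[j]]$mpm, proteins)
    for (cv in sel) {
      ue <- rbind(ue, data.frame(covariate = cv, target = j,
                                 pip = unname(fits[[j]]$pips[cv]),
                                 stringsAsFactors = FALSE))
    }
  }
  if (is.null(ue)) {
    ue <- data.frame(covariate = character(), target = character(),
                     pip = numeric(), stringsAsFactors = FALSE)
  }
  C <- stats::setNames(numeric(length(proteins)), proteins)
  if (nrow(pe)) {
    reg <- pe[pe$kind == "regulatory", , drop = FALSE]
    cor_e <- pe[pe$kind == "correlative", , drop = FALSE]
    for (i in proteins) {
      C[i] <- sum(reg$src == i) + sum(cor_e$src == i | cor_e$dst == i)
    }
  }
  new_network(cancer_type, pathway, proteins, pe, ue, C)
}

new_network <- function(cancer_type, pathway, proteins, protein_edges,
                        upstream_edges, C) {
  structure(list(cancer_type = cancer_type, pathway = pathway,
                 proteins = proteins, protein_edges = protein_edges,
                 upstream_edges = upstream_edges, C = C),
            class = "pronet_network")
}

#' @export
print.pronet_network <- function(x, ...) {
  cat(sprintf("<network %s/%s: %d proteins, %d regulatory + %d correlative edges, %d upstream>\n",
              x$cancer_type, x$pathway, length(x$proteins),
              sum(x$protein_edges$kind == "regulatory"),
              sum(x$protein_edges$kind == "correlative"),
              nrow(x$upstream_edges)))
  invisible(x)
}
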