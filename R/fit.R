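## Fit all node-wise regressions for one pathway and build the network.
## `upstream` is a named list (per protein) of covariate blocks, or NULL.
fit_pathway_network <- function(protein, prior, config, upstream = NULL,
                                cancer_type = "NA", pathway_name = "NA",
                                method = "auto") {
  P <- em_values(protein)
  proteins <- colnames(P)
  fits <- list(); problems <- list()
  for (pr in proteins) {
    prob <- regression_problem(pr, P, prior = prior,
                               upstream = upstream[[pr]], config = config)
    fits[[pr]] <- model_posterior(prob, config, method = method)
    problems[[pr]] <- prob
  }
  network <- build_integrated_network(fits, cancer_type = cancer_type,
                                      pathway = pathway_name)
  list(fits = fits, problems = problems, network = network)
}

#' Fit cancer-specific protein signaling networks
#'
#' The main fitting function. For each pathway it (1) calibrates prior
#' inclusion probabilities for protein regulators from PC-algorithm causal
#' structure learning under subsampling stability, averaged edge-wise with
#' PPI confidence scores (skipped if a `prior` matrix is supplied, and
#' replaced by a flat 0.5 prior when `use_causal_prior = FALSE` and no PPI
#' is given); (2) builds each member protein's upstream covariates from the
#' gene's mRNA (split into methylation-modulated and methylation-
#' independent components) and mapped miRNAs; (3) runs the node-wise
#' Bayesian variable selection with the Zellner g-prior (`g = n` unless
#' configured) and types the median-probability-model selections into
#' regulatory and correlative edges.
#'
#' @param protein A `pronet_em` (samples x proteins) of protein expression.
#' @param pathways Named list of pathway definitions (see
#'   [read_pathways()]); `NULL` treats all proteins as one pathway.
#' @param mrna,mirna,methylation Optional upstream `pronet_em`s sharing the
#'   protein samples.
#' @param ppi Optional `pronet_ppi`.
#' @param mirna_map Optional named list gene -> miRNA ids.
#' @param prior Optional precomputed `pronet_prior` over all proteins;
#'   skips causal-prior calibration.
#' @param use_causal_prior Run the PC-stability calibration (default TRUE
#'   when no `prior` is given).
#' @param config A [pronet_config()].
#' @param method Model-search regime passed to [model_posterior()].
#' @return An object of class `pronet`: per-pathway fits, problems and
#'   networks, plus the configuration and data references. Use
#'   [predict.pronet()] for patient-level activation probabilities and
#'   pathway scores.
#' @seealso [pathway_scores()], [cluster_patients()],
#'   [connectivity_score()]
#' @export
pronet <- function(protein, pathways = NULL, mrna = NULL, mirna = NULL,
                   methylation = NULL, ppi = NULL, mirna_map = NULL,
                   prior = NULL, use_causal_prior = is.null(prior),
                   config = pronet_config(), method = "auto") {
  P <- em_values(protein)
  cancer_type <- if (inherits(protein, "pronet_em")) protein$cancer_type else "NA"
  if (is.null(pathways)) {
    pathways <- list(all = list(
      name = "all",
      members = data.frame(protein = colnames(P), gene = gene_of(colnames(P)),
                           sign = 1, stringsAsFactors = FALSE),
      p = ncol(P)))
  }
  out <- list(pathway_fits = list(), config = config,
              cancer_type = cancer_type, call = match.call())
  for (pw in pathways) {
    members <- intersect(pw$members$protein, colnames(P))
    if (length(members) < 1) {
      warning("pathway ", pw$name, " has no proteins in the data; skipped")
      next
    }
    Ppw <- P[, members, drop = FALSE]
    pw_prior <- if (!is.null(prior)) {
      prior[members, members, drop = FALSE]
    } else if (use_causal_prior && length(members) >= 2) {
      causal <- stability_weights(Ppw, config)
      combine_prior(causal, ppi)
    } else if (!is.null(ppi)) {
      combine_prior(matrix(0, length(members), length(members),
                           dimnames = list(members, members)), ppi)
    } else {
      flat_prior(members)
    }
    upstream <- NULL
    if (!is.null(mrna) || !is.null(mirna)) {
      upstream <- lapply(stats::setNames(members, members), function(pr) {
        gid <- pw$members$gene[match(pr, pw$members$protein)]
        suppressWarnings(
          construct_upstream_covariates(mrna, methylation, mirna, gid,
                                        mirna_map))
      })
    }
    fit <- fit_pathway_network(Ppw, pw_prior, config, upstream,
                               cancer_type = cancer_type,
                               pathway_name = pw$name, method = method)
    fit$prior <- pw_prior
    fit$pathway <- pw
    out$pathway_fits[[pw$name]] <- fit
  }
  if (!length(out$pathway_fits)) stop("no pathway could be fitted")
  class(out) <- "pronet"
  out
}

#' @export
print.pronet <- function(x, ...) {
  cat(sprintf("Cancer-specific protein network fit (%s)\n", x$cancer_type))
  for (nm in names(x$pathway_fits)) {
    net <- x$pathway_fits[[nm]]$network
    cs <- if (length(net$proteins) >= 2) connectivity_score(net)$cs else NA
    cat(sprintf("  %s: %d proteins, %d regulatory, %d correlative, %d upstream edges (CS %.2f)\n",
                nm, length(net$proteins),
                sum(net$protein_edges$kind == "regulatory"),
                sum(net$protein_edges$kind == "correlative"),
                nrow(net$upstream_edges), cs))
  }
  invisible(x)
}

#' @export
summary.pronet <- function(object, ...) {
  rows <- lapply(names(object$pathway_fits), function(nm) {
    net <- object$pathway_fits[[nm]]$network
    cs <- if (length(net$proteins) >= 2) connectivity_score(net) else
      list(cs = NA, n_edges = NA, n_possible = NA)
    data.frame(pathway = nm, proteins = length(net$proteins),
               regulatory = sum(net$protein_edges$kind == "regulatory"),
               correlative = sum(net$protein_edges$kind == "correlative"),
               upstream = nrow(net$upstream_edges),
               cs = cs$cs, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("summary.pronet", class(out))
  out
}

#' @export
coef.pronet <- function(object, ...) {
  rows <- lapply(names(object$pathway_fits), function(nm) {
    pf <- object$pathway_fits[[nm]]
    do.call(rbind, lapply(pf$fits, function(f) {
      if (!nrow(f$coef)) return(NULL)
      data.frame(pathway = nm, target = f$target, covariate = f$coef$name,
                 estimate = f$coef$mean, sd = f$coef$sd,
                 pip = unname(f$pips[f$coef$name]),
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(pathway = character(),
                                      target = character(),
                                      covariate = character(),
                                      estimate = numeric(), sd = numeric(),
                                      pip = numeric())
  rownames(out) <- NULL
  out
}

#' Patient-level predictions from a fitted network model
#'
#' Computes the posterior-predictive activation tensor (suppressed /
#' neutral / activated probabilities per patient and protein) and, for
#' `type = "scores"`, the out-degree-weighted pathway activity scores.
#'
#' @param object A fitted `pronet`.
#' @param type `"probabilities"` (per-pathway tensors) or `"scores"`
#'   (per-pathway score tables).
#' @param delta Activation half-width (default `config$delta`).
#' @param loo Leave-one-out predictive (default in-sample).
#' @param ... Unused.
#' @return A named list per pathway: `pronet_tensor`s, or score
#'   data.frames (see [pathway_scores()]).
#' @export
predict.pronet <- function(object, type = c("probabilities", "scores"),
                           delta = object$config$delta, loo = FALSE, ...) {
  type <- match.arg(type)
  out <- lapply(object$pathway_fits, function(pf) {
    tensor <- activation_tensor(pf$fits, pf$problems, delta = delta,
                                loo = loo)
    if (type == "probabilities") tensor
    else pathway_scores(tensor, pf$network, pf$pathway)
  })
  out
}

#' @export
fitted.pronet <- function(object, ...) {
  lapply(object$pathway_fits, function(pf) {
    out <- vapply(names(pf$fits), function(pr) {
      f <- pf$fits[[pr]]; prob <- pf$problems[[pr]]
      if (!length(f$mpm)) return(rep(0, prob$n))
      bhat <- stats::setNames(f$coef$mean, f$coef$name)
      as.vector(prob$Z[, f$mpm, drop = FALSE] %*% bhat[f$mpm])
    }, numeric(pf$problems[[1]]$n))
    rownames(out) <- rownames(pf$problems[[1]]$Z)
    out
  })
}

#' @export
residuals.pronet <- function(object, ...) {
  f <- fitted(object)
  lapply(names(object$pathway_fits), function(nm) {
    pf <- object$pathway_fits[[nm]]
    y <- vapply(pf$problems, `[[`, numeric(pf$problems[[1]]$n), "y")
    y - f[[nm]]
  }) -> out
  names(out) <- names(object$pathway_fits)
  out
}

#' Posterior-predictive replicates of the protein data
#'
#' Draws node-wise posterior-predictive replicates of each protein at the
#' observed covariate rows (Student-t predictive under each node's median
#' probability model). Useful for posterior-predictive checking; the draws
#' are node-wise conditionals, not joint draws from a single structural
#' model.
#'
#' @param object A fitted `pronet`.
#' @param nsim Number of replicate datasets.
#' @param seed Integer seed.
#' @param ... Unused.
#' @return List of `nsim` named lists of samples x proteins matrices.
#' @export
simulate.pronet <- function(object, nsim = 1, seed = 1L, ...) {
  rs <- local_rng(substream_seed(seed, "simfit"))
  on.exit(rs$restore(), add = TRUE)
  lapply(seq_len(nsim), function(s) {
    lapply(object$pathway_fits, function(pf) {
      sapply(names(pf$fits), function(pr) {
        probs <- predictive_probabilities(pf$fits[[pr]], pf$problems[[pr]],
                                          delta = object$config$delta)
        loc <- attr(probs, "location"); sc <- attr(probs, "scale")
        loc + sc * stats::rt(length(loc), df = pf$problems[[pr]]$n)
      })
    })
  })
}

#' Plot a fitted pathway network
#'
#' Circular layout; regulatory edges drawn as arrows, correlative edges as
#' plain segments, upstream covariates omitted.
#'
#' @param x A fitted `pronet`.
#' @param pathway Pathway name (default: first).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.pronet <- function(x, pathway = names(x$pathway_fits)[1], ...) {
  net <- x$pathway_fits[[pathway]]$network
  p <- length(net$proteins)
  theta <- 2 * pi * (seq_len(p) - 1) / p
  xs <- cos(theta); ys <- sin(theta)
  names(xs) <- names(ys) <- net$proteins
  graphics::plot(xs, ys, xlim = c(-1.3, 1.3), ylim = c(-1.3, 1.3),
                 pch = 21, bg = "grey85", cex = 2.2, axes = FALSE,
                 xlab = "", ylab = "",
                 main = sprintf("%s (%s)", pathway, net$cancer_type), ...)
  e <- net$protein_edges
  for (r in seq_len(nrow(e))) {
    a <- e$src[r]; b <- e$dst[r]
    shrinkage <- 0.12
    dx <- xs[b] - xs[a]; dy <- ys[b] - ys[a]
    len <- sqrt(dx^2 + dy^2)
    x0 <- xs[a] + shrinkage * dx / len; y0 <- ys[a] + shrinkage * dy / len
    x1 <- xs[b] - shrinkage * dx / len; y1 <- ys[b] - shrinkage * dy / len
    if (e$kind[r] == "regulatory") {
      graphics::arrows(x0, y0, x1, y1, length = 0.08, col = "steelblue")
    } else {
      graphics::segments(x0, y0, x1, y1, col = "tomato", lwd = 1.5)
    }
  }
  graphics::text(1.15 * xs, 1.15 * ys, net$proteins, cex = 0.7)
  invisible(x)
}
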