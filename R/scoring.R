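#' Posterior-predictive activation probabilities for one protein
#'
#' Under the median probability model with the Zellner g-prior and
#' `p(sigma) ~ 1/sigma`, the posterior predictive of a protein at a
#' patient's own covariate row `z*` is Student-t with `n` degrees of
#' freedom, location `(g/(1+g)) z*' b_ols` and scale
#' `sqrt(Q/n (1 + g/(1+g) z*' (Z'Z)^-1 z*))`, where `Q` is the posterior
#' sum of squares of the model. The suppressed / neutral / activated
#' probabilities are the predictive masses below `-delta`, within
#' `[-delta, delta]`, and above `delta`. An empty MPM yields the
#' null-model predictive: centered at 0 with the marginal scale of `y`.
#'
#' By default the predictive conditions on the full cohort (in-sample
#' deconvolution); `loo = TRUE` re-estimates the posterior without the
#' patient's own row (same MPM).
#'
#' @param fit A `pronet_nodefit`.
#' @param problem The `pronet_problem` the fit came from.
#' @param patients Row indices (default all samples).
#' @param delta Activation half-width (default 0.5).
#' @param loo Leave the scored patient out of the posterior.
#' @return A matrix (patients x 3) with columns `p_minus`, `p_zero`,
#'   `p_plus`; rows sum to 1. Attribute `location`/`scale` carry the
#'   predictive parameters.
#' @export
predictive_probabilities <- function(fit, problem, patients = NULL,
                                     delta = 0.5, loo = FALSE) {
  n <- problem$n
  if (is.null(patients)) patients <- seq_len(n)
  mpm <- fit$mpm
  if (!length(mpm)) {
    scale <- sqrt(sum(problem$y^2) / n)
    loc <- rep(0, length(patients))
    sc <- rep(scale, length(patients))
    df <- rep(n, length(patients))
  } else if (!loo) {
    Zm <- problem$Z[, mpm, drop = FALSE]
    bhat <- stats::setNames(fit$coef$mean, fit$coef$name)[mpm]
    XtX <- crossprod(Zm)
    XtXinv <- tryCatch(solve(XtX), error = function(e) MASS_ginv(XtX))
    h <- rowSums((Zm %*% XtXinv) * Zm)
    shrink <- problem$g / (1 + problem$g)
    loc <- as.vector(Zm %*% bhat)[patients]     # bhat already shrunk
    sc <- sqrt(fit$Q / n * (1 + shrink * h))[patients]
    df <- rep(n, length(patients))
  } else {
    Zm <- problem$Z[, mpm, drop = FALSE]
    g <- problem$g; shrink <- g / (1 + g)
    loc <- sc <- df <- numeric(length(patients))
    for (ii in seq_along(patients)) {
      pt <- patients[ii]
      Zt <- Zm[-pt, , drop = FALSE]; yt <- problem$y[-pt]
      yt <- yt - mean(yt)
      qrz <- qr(Zt)
      bh <- qr.coef(qrz, yt); bh[is.na(bh)] <- 0
      yty <- sum(yt^2)
      R2 <- min(max(sum(qr.fitted(qrz, yt) * yt) / yty, 0), 1)
      Q <- yty * (1 + g * (1 - R2)) / (1 + g)
      XtX <- crossprod(Zt)
      XtXinv <- tryCatch(solve(XtX), error = function(e) MASS_ginv(XtX))
      z <- Zm[pt, ]
      m <- nrow(Zt)
      loc[ii] <- shrink * sum(z * bh)
      sc[ii] <- sqrt(Q / m * (1 + shrink * sum(z * (XtXinv %*% z))))
      df[ii] <- m
    }
  }
  p_plus <- stats::pt((delta - loc) / sc, df, lower.tail = FALSE)
  p_minus <- stats::pt((-delta - loc) / sc, df)
  p_zero <- 1 - p_plus - p_minus
  out <- cbind(p_minus = p_minus, p_zero = pmax(p_zero, 0), p_plus = p_plus)
  out <- out / rowSums(out)
  rownames(out) <- rownames(problem$Z)[patients]
  attr(out, "location") <- loc
  attr(out, "scale") <- sc
  out
}

## argmax with exact ties resolving to neutral (conservative default)
status_from_probs <- function(p_minus, p_zero, p_plus) {
  m <- pmax(p_minus, p_zero, p_plus)
  out <- rep("neutral", length(m))
  out[p_plus == m & p_minus < m & p_zero < m] <- "activated"
  out[p_minus == m & p_plus < m & p_zero < m] <- "suppressed"
  out
}

#' Patient-by-protein probability tensor
#'
#' Collects the per-protein posterior-predictive activation probabilities
#' into samples x proteins matrices plus the per-cell status call (argmax
#' of the triple; exact ties resolve to neutral).
#'
#' @param fits Named list of `pronet_nodefit`.
#' @param problems Named list of matching `pronet_problem`s.
#' @param delta Activation half-width.
#' @param loo Passed to [predictive_probabilities()].
#' @return An object of class `pronet_tensor`: matrices `p_minus`,
#'   `p_zero`, `p_plus`, `status` (samples x proteins) and `delta`.
#' @export
activation_tensor <- function(fits, problems, delta = 0.5, loo = FALSE) {
  proteins <- names(fits)
  stopifnot(identical(proteins, names(problems)))
  n <- problems[[1]]$n
  samples <- rownames(problems[[1]]$Z)
  if (is.null(samples)) samples <- sprintf("S%03d", seq_len(n))
  mk <- function() matrix(NA_real_, n, length(proteins),
                          dimnames = list(samples, proteins))
  pm <- mk(); pz <- mk(); pp <- mk()
  for (pr in proteins) {
    probs <- predictive_probabilities(fits[[pr]], problems[[pr]],
                                      delta = delta, loo = loo)
    pm[, pr] <- probs[, "p_minus"]
    pz[, pr] <- probs[, "p_zero"]
    pp[, pr] <- probs[, "p_plus"]
  }
  status <- matrix(status_from_probs(pm, pz, pp), n,
                   dimnames = list(samples, proteins))
  structure(list(p_minus = pm, p_zero = pz, p_plus = pp, status = status,
                 delta = delta),
            class = "pronet_tensor")
}

#' @export
print.pronet_tensor <- function(x, ...) {
  cat(sprintf("<activation tensor: %d samples x %d proteins, delta = %g>\n",
              nrow(x$p_plus), ncol(x$p_plus), x$delta))
  invisible(x)
}

#' Patient-specific network
#'
#' Every patient shares the cancer-specific topology; only the node labels
#' (activation statuses) differ.
#'
#' @param network A `pronet_network`.
#' @param tensor A `pronet_tensor` covering all network proteins.
#' @param patient Sample id or row index.
#' @return The network with a `labels` element (named status vector).
#' @export
patient_network <- function(network, tensor, patient) {
  missing <- setdiff(network$proteins, colnames(tensor$status))
  if (length(missing)) {
    stop("tensor missing protein(s): ", paste(missing, collapse = ", "))
  }
  out <- network
  out$patient <- patient
  out$labels <- tensor$status[patient, network$proteins]
  out
}

#' Out-degree-weighted pathway activity scores
#'
#' For a pathway with `p` member proteins, the activated score of patient
#' `j` is `kappa+_j = (1/p) sum_i p+_ij (C_i + 1)`, with the suppressed and
#' neutral scores defined analogously; `C_i` is the protein's out-degree in
#' the cancer-specific network (regulatory out-edges plus correlative
#' incidences), so hub proteins carry more weight. The combined score is
#' `kappa+ + kappa-`; the pathway status is the argmax of the three kappas
#' (ties resolve to neutral).
#'
#' @param tensor A `pronet_tensor`.
#' @param network A `pronet_network` providing `C`.
#' @param pathway A pathway definition (list with `members`), or `NULL` to
#'   use all network proteins.
#' @return A data.frame with one row per patient: `sample`, `pathway`,
#'   `kappa_plus`, `kappa_minus`, `kappa_zero`, `combined`, `status`.
#' @export
pathway_scores <- function(tensor, network, pathway = NULL) {
  members <- if (is.null(pathway)) network$proteins else pathway$members$protein
  present <- intersect(members, colnames(tensor$p_plus))
  dropped <- setdiff(members, present)
  if (length(dropped)) {
    warning("dropping pathway member(s) absent from tensor: ",
            paste(dropped, collapse = ", "))
  }
  p <- length(present)
  if (p == 0) stop("no pathway members with activation probabilities")
  Cw <- stats::setNames(rep(0, p), present)
  avail <- intersect(present, names(network$C))
  Cw[avail] <- network$C[avail]
  wt <- Cw + 1
  kp <- as.vector(tensor$p_plus[, present, drop = FALSE] %*% wt) / p
  km <- as.vector(tensor$p_minus[, present, drop = FALSE] %*% wt) / p
  kz <- as.vector(tensor$p_zero[, present, drop = FALSE] %*% wt) / p
  status <- rep("neutral", length(kp))
  mx <- pmax(kp, km, kz)
  status[kp == mx & km < mx & kz < mx] <- "activated"
  status[km == mx & kp < mx & kz < mx] <- "suppressed"
  data.frame(sample = rownames(tensor$p_plus),
             pathway = if (is.null(pathway)) network$pathway else pathway$name,
             kappa_plus = kp, kappa_minus = km, kappa_zero = kz,
             combined = kp + km, status = status,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Naive pathway score
#'
#' Cumulative sum of the member proteins' expression per patient; every
#' protein gets equal weight and network information is ignored.
#'
#' @param protein_data A `pronet_em` or matrix.
#' @param pathway Pathway definition (list with `members`).
#' @return Named numeric vector, one value per patient.
#' @export
naive_score <- function(protein_data, pathway) {
  P <- em_values(protein_data)
  members <- pathway$members$protein
  present <- intersect(members, colnames(P))
  if (!length(present)) stop("no pathway members present in protein data")
  dropped <- setdiff(members, present)
  if (length(dropped)) {
    warning("dropping pathway member(s) absent from data: ",
            paste(dropped, collapse = ", "))
  }
  rowSums(P[, present, drop = FALSE])
}

#' Native pathway score
#'
#' Signed sum of member proteins: positive regulatory components minus
#' negative regulatory components, using the pathway's sign annotation.
#'
#' @inheritParams naive_score
#' @return Named numeric vector, one value per patient.
#' @export
native_score <- function(protein_data, pathway) {
  P <- em_values(protein_data)
  mem <- pathway$members
  present <- mem$protein %in% colnames(P)
  if (!any(present)) stop("no pathway members present in protein data")
  if (!all(present)) {
    warning("dropping pathway member(s) absent from data: ",
            paste(mem$protein[!present], collapse = ", "))
    mem <- mem[present, , drop = FALSE]
  }
  as.vector(P[, mem$protein, drop = FALSE] %*% mem$sign)
}
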