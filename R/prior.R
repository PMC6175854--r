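#' Stability weights from subsampled PC runs
#'
#' Calibrates a directed edge-weight matrix from causal structure learning
#' under subsampling stability. The candidate edge set E-hat comes from a
#' single PC fit at `alpha_init` on the full data. Then, for each of
#' `n_subsamples` random half-samples of size `floor(n/2)` drawn without
#' replacement, the PC algorithm is rerun at every significance level in
#' `alpha_grid`. For each alpha the selection probability of a directed
#' edge is the fraction of subsamples whose CPDAG contains it (a directed
#' edge credits its direction fully; an undirected or bi-directed edge
#' credits each direction at half weight). The final weight of each
#' direction is the maximum selection probability over the alpha grid;
#' pairs outside E-hat are fixed at zero.
#'
#' @param data A `pronet_em` or numeric matrix (samples x proteins).
#' @param config A [pronet_config()].
#' @return An object of class `pronet_causal`: list with `weights` (p x p
#'   matrix, entry (i,j) = stability weight for direction i -> j),
#'   `skeleton` (data.frame of the E-hat pairs) and `alpha_freq` (p x p x
#'   n-alpha selection-probability array).
#' @export
stability_weights <- function(data, config = pronet_config()) {
  X <- em_values(data)
  n <- nrow(X); p <- ncol(X)
  labels <- colnames(X)
  if (floor(n / 2) < 10) stop("subsample size floor(n/2) below 10")
  full <- pc_skeleton(X, config$alpha_init)
  in_ehat <- full$adj
  dimnames(in_ehat) <- list(labels, labels)

  n_alpha <- length(config$alpha_grid)
  counts <- array(0, dim = c(p, p, n_alpha),
                  dimnames = list(labels, labels, NULL))
  rs <- local_rng(substream_seed(config$seed, "stability"))
  on.exit(rs$restore(), add = TRUE)
  m <- floor(n / 2)
  for (b in seq_len(config$n_subsamples)) {
    idx <- sample(n, m)
    Xs <- X[idx, , drop = FALSE]
    sds <- apply(Xs, 2, stats::sd)
    if (any(sds == 0)) next  # degenerate subsample: contributes no edges
    C <- stats::cor(Xs)
    cache <- new.env(parent = emptyenv())
    for (a in seq_len(n_alpha)) {
      cp <- pc_from_cor(C, m, config$alpha_grid[a], labels = labels,
                        cache = cache)
      counts[, , a] <- counts[, , a] + cpdag_credit(cp, labels)
    }
  }
  freq <- counts / config$n_subsamples
  weights <- apply(freq, c(1, 2), max)
  weights[!in_ehat] <- 0
  weights <- pmin(weights, 1)
  diag(weights) <- 0
  sk <- full$edges
  structure(list(weights = weights,
                 skeleton = sk[, c("a", "b", "type"), drop = FALSE],
                 alpha_freq = freq),
            class = "pronet_causal")
}

#' @export
print.pronet_causal <- function(x, ...) {
  cat(sprintf("<causal stability weights: %d proteins, %d skeleton edges>\n",
              ncol(x$weights), nrow(x$skeleton)))
  invisible(x)
}

#' Prior inclusion probabilities from causal weights and PPI scores
#'
#' Edge-wise averaging of the data-driven causal stability weight and the
#' PPI confidence score: `w[i,j] = (causal[i,j] + ppi(i,j)) / 2` wherever
#' either source is positive, and exactly 0 where both are 0, so those
#' pairs are excluded from the candidate regulator sets. The undirected
#' PPI score contributes identically to both directions; the averaging
#' denominator is always 2, with a missing source contributing 0.
#'
#' @param causal A `pronet_causal` (or a p x p weight matrix with
#'   dimnames).
#' @param ppi A `pronet_ppi` or `NULL`.
#' @return A p x p matrix of prior inclusion probabilities (rows =
#'   regulator, columns = target), class `pronet_prior`.
#' @export
combine_prior <- function(causal, ppi = NULL) {
  cw <- if (inherits(causal, "pronet_causal")) causal$weights else as.matrix(causal)
  labels <- rownames(cw)
  stopifnot(!is.null(labels), identical(labels, colnames(cw)))
  p <- length(labels)
  pm <- matrix(0, p, p, dimnames = list(labels, labels))
  if (!is.null(ppi)) {
    pairs <- expand.grid(i = seq_len(p), j = seq_len(p))
    pm[] <- ppi_score(ppi, labels[pairs$i], labels[pairs$j])
  }
  w <- (cw + pm) / 2
  w[cw == 0 & pm == 0] <- 0
  diag(w) <- 0
  class(w) <- c("pronet_prior", class(w))
  w
}

#' Flat prior inclusion matrix
#'
#' All off-diagonal entries equal to `w`; used when no PPI or causal
#' information is supplied (the "diluted" analysis mode) and in
#' simulation-based checks.
#'
#' @param proteins Character vector of protein ids.
#' @param w Common prior inclusion probability (default 0.5).
#' @return A `pronet_prior` matrix.
#' @export
flat_prior <- function(proteins, w = 0.5) {
  p <- length(proteins)
  m <- matrix(w, p, p, dimnames = list(proteins, proteins))
  diag(m) <- 0
  class(m) <- c("pronet_prior", class(m))
  m
}

#' Write / read a prior inclusion matrix as TSV
#'
#' Rows are regulators, columns targets; first column `regulator`.
#' @param prior A `pronet_prior` matrix.
#' @param path File path.
#' @export
write_prior <- function(prior, path) {
  df <- data.frame(regulator = rownames(prior), unclass(prior),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_prior
#' @export
read_prior <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  stopifnot(identical(rownames(m), colnames(m)),
            all(m >= 0), all(m <= 1))
  class(m) <- c("pronet_prior", class(m))
  m
}
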