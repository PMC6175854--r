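#' Patients-by-pathways combined score matrix
#'
#' Assembles the clustering input: one row per patient, one column per
#' pathway, entries the combined (activated + suppressed) pathway activity
#' score. Patients missing any pathway score are dropped with a warning
#' (inner join on samples).
#'
#' @param score_tables Named list of per-pathway score data.frames as
#'   returned by [pathway_scores()] (columns `sample`, `combined`), or a
#'   single data.frame with a `pathway` column covering all pathways.
#' @return Numeric matrix with sample row names and pathway column names.
#' @export
build_score_matrix <- function(score_tables) {
  if (is.data.frame(score_tables)) {
    score_tables <- split(score_tables, score_tables$pathway)
  }
  stopifnot(length(score_tables) >= 1)
  samples <- Reduce(intersect, lapply(score_tables, function(d) d$sample))
  if (!length(samples)) stop("no samples scored on every pathway")
  all_samples <- unique(unlist(lapply(score_tables, function(d) d$sample)))
  dropped <- setdiff(all_samples, samples)
  if (length(dropped)) {
    warning(sprintf("dropping %d patient(s) missing at least one pathway score",
                    length(dropped)))
  }
  m <- vapply(score_tables, function(d) {
    d$combined[match(samples, d$sample)]
  }, numeric(length(samples)))
  m <- matrix(m, nrow = length(samples),
              dimnames = list(samples, names(score_tables)))
  m
}

#' Hierarchical clustering with gap-statistic model selection
#'
#' Ward-linkage hierarchical clustering on Euclidean distances of the score
#' matrix. The number of clusters is chosen by the gap statistic with `B`
#' uniform reference datasets drawn over each feature's observed range,
#' `Gap(k) = E*[log W_k] - log W_k` with `W_k` the total within-cluster sum
#' of squares of the partition cut from the dendrogram at `k`; the selected
#' `k` is the smallest with `Gap(k) >= Gap(k+1) - s_{k+1}`.
#'
#' @param m Numeric matrix (patients x pathways).
#' @param k_max Largest cluster count considered.
#' @param config A [pronet_config()] (supplies `gap_B` and `seed`).
#' @return An object of class `pronet_clust`: `labels` (named cluster ids in
#'   `1..k_selected`), `k_selected`, `gap_curve` (data.frame `k`, `gap`,
#'   `se`), and `linkage` (the `hclust` merge history).
#' @export
cluster_patients <- function(m, k_max = 10, config = pronet_config()) {
  m <- as.matrix(m)
  n <- nrow(m)
  stopifnot(n >= 2)
  hc <- stats::hclust(stats::dist(m), method = "ward.D2")
  if (all(apply(m, 2, stats::sd) == 0)) {
    warning("constant score matrix; returning a single cluster")
    return(structure(list(labels = stats::setNames(rep(1L, n), rownames(m)),
                          k_selected = 1L,
                          gap_curve = data.frame(k = integer(), gap = numeric(),
                                                 se = numeric()),
                          linkage = hc),
                     class = "pronet_clust"))
  }
  k_max <- min(k_max, n - 1)
  stopifnot(k_max >= 2)
  rs <- local_rng(substream_seed(config$seed, "gap"))
  on.exit(rs$restore(), add = TRUE)
  fun <- function(x, k) list(cluster = stats::cutree(
    stats::hclust(stats::dist(x), method = "ward.D2"), k = k))
  gap <- cluster::clusGap(m, FUNcluster = fun, K.max = k_max,
                          B = config$gap_B, d.power = 2,
                          spaceH0 = "original", verbose = FALSE)
  tab <- gap$Tab
  k_sel <- cluster::maxSE(tab[, "gap"], tab[, "SE.sim"],
                          method = "Tibs2001SEmax")
  labels <- stats::cutree(hc, k = k_sel)
  structure(list(labels = labels, k_selected = as.integer(k_sel),
                 gap_curve = data.frame(k = seq_len(nrow(tab)),
                                        gap = tab[, "gap"],
                                        se = tab[, "SE.sim"]),
                 linkage = hc),
            class = "pronet_clust")
}

#' @export
print.pronet_clust <- function(x, ...) {
  cat(sprintf("<clustering: %d patients, k = %d selected by gap statistic>\n",
              length(x$labels), x$k_selected))
  invisible(x)
}

#' Enrichment probability of a category in a cluster
#'
#' Posterior probability that the category's proportion inside the group of
#' interest exceeds the proportion outside it, under independent
#' Beta(1, 1) priors: `theta_in ~ Beta(1 + x_in, 1 + n_cat - x_in)`,
#' `theta_out ~ Beta(1 + x_out, 1 + n_other - x_out)`, and
#' `EP = P(theta_in > theta_out)` estimated by seeded Monte Carlo.
#'
#' @param x_in,n_cat Successes and size of the group of interest.
#' @param x_out,n_other Successes and size of the complement group.
#' @param draws Monte Carlo sample size (default 20000).
#' @param seed Integer seed.
#' @return Scalar EP in [0, 1].
#' @export
enrichment_probability <- function(x_in, n_cat, x_out, n_other,
                                   draws = 20000, seed = 1L) {
  stopifnot(n_cat >= 1, n_other >= 1,
            x_in >= 0, x_in <= n_cat, x_out >= 0, x_out <= n_other,
            draws >= 1)
  rs <- local_rng(substream_seed(seed, "ep"))
  on.exit(rs$restore(), add = TRUE)
  t_in <- stats::rbeta(draws, 1 + x_in, 1 + n_cat - x_in)
  t_out <- stats::rbeta(draws, 1 + x_out, 1 + n_other - x_out)
  mean(t_in > t_out)
}

#' Normalized mutual information of two partitions
#'
#' `NMI = I(A;B) / sqrt(H(A) H(B))` by default; if either partition has
#' zero entropy (a single cluster) the value is defined as 0. Alternative
#' normalisations (arithmetic mean, min, max of the entropies) are
#' available since the normalisation convention varies across the
#' literature.
#'
#' @param labels_a,labels_b Cluster label vectors over the same samples.
#' @param normalization One of `"sqrt"`, `"mean"`, `"min"`, `"max"`.
#' @return Scalar in [0, 1].
#' @export
normalized_mutual_information <- function(labels_a, labels_b,
                                          normalization = c("sqrt", "mean",
                                                            "min", "max")) {
  normalization <- match.arg(normalization)
  if (length(labels_a) != length(labels_b)) {
    stop("partitions must cover the same sample set")
  }
  n <- length(labels_a)
  tab <- table(labels_a, labels_b)
  pj <- rowSums(tab) / n
  pk <- colSums(tab) / n
  pjk <- tab / n
  nz <- pjk > 0
  mi <- sum(pjk[nz] * log(pjk[nz] / outer(pj, pk)[nz]))
  ent <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  ha <- ent(pj); hb <- ent(pk)
  denom <- switch(normalization,
                  sqrt = sqrt(ha * hb),
                  mean = (ha + hb) / 2,
                  min = min(ha, hb),
                  max = max(ha, hb))
  if (denom == 0) return(0)
  max(min(mi / denom, 1), 0)
}
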