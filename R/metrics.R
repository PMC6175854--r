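#' Connectivity score of a pathway network
#'
#' Ratio of the observed number of protein-pair edges to the number of
#' possible pairs `p(p-1)/2`. Pairs are unordered and counted once
#' regardless of edge kind or direction, so the score lies in [0, 1] for
#' networks mixing regulatory and correlative edges.
#'
#' @param network A `pronet_network`.
#' @return List with `cs`, `n_edges`, `n_possible`.
#' @export
connectivity_score <- function(network) {
  p <- length(network$proteins)
  if (p < 2) stop("connectivity score needs at least 2 proteins")
  e <- network$protein_edges
  pairs <- unique(ifelse(e$src < e$dst, paste(e$src, e$dst),
                         paste(e$dst, e$src)))
  n_possible <- p * (p - 1) / 2
  list(cs = length(pairs) / n_possible, n_edges = length(pairs),
       n_possible = n_possible)
}

#' Permutation p-value of the connectivity score
#'
#' Null networks are built by independently permuting each protein
#' column's sample order (destroying inter-protein dependence while
#' preserving marginals), refitting the node-wise regressions with the
#' same prior inclusion matrix and upstream covariates, and recomputing
#' the connectivity score. The p-value uses add-one smoothing:
#' `p = (1 + #{null CS >= observed CS}) / (reps + 1)`, so it always lies
#' in (0, 1].
#'
#' @param protein A `pronet_em` or matrix restricted to the pathway.
#' @param prior A `pronet_prior` matrix over the pathway proteins.
#' @param config A [pronet_config()].
#' @param upstream Optional named list of upstream covariate blocks per
#'   protein (see [construct_upstream_covariates()]).
#' @param reps Number of permutation refits (default
#'   `config$permutation_reps`; must be at least 20).
#' @return List with `p_cs`, `cs_observed`, `cs_null` (vector).
#' @export
connectivity_pvalue <- function(protein, prior, config = pronet_config(),
                                upstream = NULL,
                                reps = config$permutation_reps) {
  if (reps < 20) stop("need at least 20 permutation reps")
  P <- em_values(protein)
  obs <- fit_pathway_network(P, prior, config, upstream)$network
  cs_obs <- connectivity_score(obs)$cs
  rs <- local_rng(substream_seed(config$seed, "permcs"))
  on.exit(rs$restore(), add = TRUE)
  n <- nrow(P)
  cs_null <- numeric(reps)
  for (r in seq_len(reps)) {
    Pp <- apply(P, 2, function(col) col[sample(n)])
    dimnames(Pp) <- dimnames(P)
    net <- fit_pathway_network(Pp, prior, config, upstream)$network
    cs_null[r] <- connectivity_score(net)$cs
  }
  list(p_cs = (1 + sum(cs_null >= cs_obs)) / (reps + 1),
       cs_observed = cs_obs, cs_null = cs_null)
}

#' Diversity score of a pathway across lineages
#'
#' Sample standard deviation of the pathway's connectivity scores across
#' lineages; high values flag pathways whose cross-signaling differs
#' strongly between tumor types.
#'
#' @param cs_values Numeric vector of per-lineage connectivity scores.
#' @return Scalar standard deviation.
#' @export
diversity_score <- function(cs_values) {
  if (length(cs_values) < 2) stop("diversity needs at least 2 lineages")
  stats::sd(cs_values)
}

#' Edge consistency across lineages
#'
#' For every unordered protein pair, counts the number of lineages whose
#' network holds any edge on the pair (regulatory in either direction or
#' correlative); pairs absent everywhere are omitted. The per-direction
#' regulatory counts are reported separately to surface conserved
#' directions, and each pair is flagged as known when its PPI confidence
#' score exceeds 0.5.
#'
#' @param networks List of `pronet_network`, one per lineage.
#' @param ppi Optional `pronet_ppi` for the known/new flag.
#' @return data.frame with `protein_a`, `protein_b`, `ec`,
#'   `n_dir_fwd` (regulatory a->b count), `n_dir_rev`, `ppi_score`,
#'   `known`.
#' @export
edge_consistency <- function(networks, ppi = NULL) {
  rows <- list()
  for (net in networks) {
    e <- net$protein_edges
    if (!nrow(e)) next
    a <- ifelse(e$src < e$dst, e$src, e$dst)
    b <- ifelse(e$src < e$dst, e$dst, e$src)
    fwd <- e$kind == "regulatory" & e$src == a
    rev <- e$kind == "regulatory" & e$src == b
    ## one occurrence per pair per lineage
    df <- data.frame(a = a, b = b, fwd = fwd, rev = rev,
                     stringsAsFactors = FALSE)
    df <- df[!duplicated(paste(df$a, df$b)), , drop = FALSE]
    rows[[length(rows) + 1L]] <- df
  }
  if (!length(rows)) {
    return(data.frame(protein_a = character(), protein_b = character(),
                      ec = integer(), n_dir_fwd = integer(),
                      n_dir_rev = integer(), ppi_score = numeric(),
                      known = logical(), stringsAsFactors = FALSE))
  }
  all <- do.call(rbind, rows)
  key <- paste(all$a, all$b)
  ec <- tapply(rep(1L, nrow(all)), key, sum)
  fwd <- tapply(all$fwd, key, sum)
  rev <- tapply(all$rev, key, sum)
  parts <- strsplit(names(ec), " ", fixed = TRUE)
  out <- data.frame(protein_a = vapply(parts, `[[`, "", 1L),
                    protein_b = vapply(parts, `[[`, "", 2L),
                    ec = as.integer(ec),
                    n_dir_fwd = as.integer(fwd),
                    n_dir_rev = as.integer(rev),
                    stringsAsFactors = FALSE)
  out$ppi_score <- ppi_score(ppi, out$protein_a, out$protein_b)
  out$known <- out$ppi_score > 0.5
  rownames(out) <- NULL
  out[order(-out$ec, out$protein_a, out$protein_b), , drop = FALSE]
}

#' Concordance between predicted and observed protein statuses
#'
#' Categorises each observed (centered) protein value by the same
#' delta-interval rule used for prediction, and reports the posterior-
#' predictive probability assigned to the observed category. Values lie in
#' [0, 1]; high values mean the patient-level predictions agree with the
#' measured protein.
#'
#' @param tensor A `pronet_tensor`.
#' @param observed A `pronet_em` or matrix of observed protein expression
#'   covering the tensor's samples and proteins. Columns are centered
#'   before categorisation, matching the model scale.
#' @param delta Activation half-width (default: the tensor's).
#' @return List with `concordance` (samples x proteins matrix),
#'   `per_sample` (named mean per sample) and `mean` (scalar).
#' @export
concordance_score <- function(tensor, observed, delta = tensor$delta) {
  Y <- em_values(observed)
  samples <- rownames(tensor$p_plus); proteins <- colnames(tensor$p_plus)
  if (!all(samples %in% rownames(Y)) || !all(proteins %in% colnames(Y))) {
    stop("observed matrix does not cover the tensor's samples/proteins")
  }
  Y <- Y[samples, proteins, drop = FALSE]
  Y <- sweep(Y, 2, colMeans(Y))
  conc <- tensor$p_zero
  conc[Y > delta] <- tensor$p_plus[Y > delta]
  conc[Y < -delta] <- tensor$p_minus[Y < -delta]
  list(concordance = conc,
       per_sample = rowMeans(conc),
       mean = mean(conc))
}
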