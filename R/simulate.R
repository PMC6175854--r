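#' Simulation specification for multi-platform cohorts
#'
#' Defines the ground-truth generative model used to test every pipeline
#' stage: sparse linear-Gaussian protein DAGs per pathway, mRNA split into a
#' methylation-modulated and a methylation-independent component, gene-
#' annotated miRNAs, multiple lineages with rewired networks, and patient
#' subgroups with shifted pathway activity.
#'
#' Proteins follow structural equations over the pathway DAG: each protein
#' loads on its parent proteins (coefficients with magnitude in
#' `coefficient_range` and random sign), on its own gene's mRNA
#' (`mrna_loading`), on its mapped miRNAs (`mirna_loading`), plus Gaussian
#' noise with sd `noise_sd`. mRNA is `methylation_effect` times a standard-
#' normal methylation value plus an independent Gaussian component scaled so
#' mRNA has unit variance. Subgroup shifts act transcriptionally: the shift
#' is added to the methylation-independent mRNA component of every gene in
#' the designated pathway for subgroup members, so the activation is
#' visible both in the proteins and in their upstream covariates.
#'
#' @param n_samples Samples per lineage.
#' @param pathway_sizes Integer vector; proteins per pathway.
#' @param edge_density Probability of each forward edge in the pathway DAG.
#' @param coefficient_range Magnitude range for DAG coefficients; the
#'   default `[0.5, 1]` keeps edges strong enough that structure recovery is
#'   feasible at moderate sample sizes.
#' @param noise_sd Protein-level residual noise sd (default 0.5).
#' @param n_lineages Number of lineages (cancer types); lineages beyond the
#'   first carry rewired copies of the truth DAGs.
#' @param rewire_fraction Fraction of DAG edges removed and replaced at
#'   random (preserving acyclicity) in each additional lineage.
#' @param n_mirna_per_gene Number of miRNAs annotated to each gene.
#' @param methylation_effect Loading of methylation on mRNA (default 0.6).
#' @param subgroup_shifts List of `list(pathway =, shift =)` entries; each
#'   defines one shifted patient subgroup.
#' @param subgroup_fraction Fraction of the cohort assigned to each shifted
#'   subgroup (default 0.3; the remainder is the control subgroup).
#' @param mrna_loading Protein loading on its own gene's mRNA (default 1).
#' @param mirna_loading Protein loading on each mapped miRNA (default 0.2).
#' @param seed Integer seed; identical spec + seed gives bit-identical
#'   cohorts.
#' @return An object of class `pronet_simspec`.
#' @export
sim_spec <- function(n_samples = 300,
                     pathway_sizes = c(8, 6),
                     edge_density = 0.2,
                     coefficient_range = c(0.5, 1),
                     noise_sd = 0.5,
                     n_lineages = 1,
                     rewire_fraction = 0,
                     n_mirna_per_gene = 1,
                     methylation_effect = 0.6,
                     subgroup_shifts = NULL,
                     subgroup_fraction = 0.3,
                     mrna_loading = 1,
                     mirna_loading = 0.2,
                     seed = 1L) {
  spec <- list(n_samples = as.integer(n_samples),
               pathway_sizes = as.integer(pathway_sizes),
               edge_density = edge_density,
               coefficient_range = coefficient_range,
               noise_sd = noise_sd,
               n_lineages = as.integer(n_lineages),
               rewire_fraction = rewire_fraction,
               n_mirna_per_gene = as.integer(n_mirna_per_gene),
               methylation_effect = methylation_effect,
               subgroup_shifts = subgroup_shifts,
               subgroup_fraction = subgroup_fraction,
               mrna_loading = mrna_loading,
               mirna_loading = mirna_loading,
               seed = as.integer(seed))
  stopifnot(spec$n_samples >= 1, all(spec$pathway_sizes >= 1),
            spec$edge_density >= 0, spec$edge_density <= 1,
            length(spec$coefficient_range) == 2,
            spec$coefficient_range[1] > 0,
            diff(spec$coefficient_range) >= 0,
            spec$noise_sd > 0, spec$n_lineages >= 1,
            spec$rewire_fraction >= 0, spec$rewire_fraction <= 1,
            spec$n_mirna_per_gene >= 0,
            spec$subgroup_fraction > 0, spec$subgroup_fraction < 1)
  if (!is.null(subgroup_shifts)) {
    for (s in subgroup_shifts) {
      stopifnot(s$pathway >= 1, s$pathway <= length(spec$pathway_sizes))
    }
    stopifnot(length(subgroup_shifts) * spec$subgroup_fraction < 1)
  }
  class(spec) <- "pronet_simspec"
  spec
}

protein_ids <- function(pathway, p) sprintf("P%d_%d", pathway, seq_len(p))
gene_of <- function(protein) sub("^P", "G", protein)

#' Simulate a ground-truth pathway network
#'
#' Draws an Erdos-Renyi-style DAG over the pathway's proteins under a fixed
#' topological order (edges only from lower to higher index), with edge
#' probability `edge_density` and coefficients drawn uniformly from
#' `coefficient_range` in magnitude with random sign.
#'
#' @param spec A `pronet_simspec`.
#' @param pathway Pathway index.
#' @param lineage Lineage index; lineages beyond the first rewire
#'   `rewire_fraction` of the lineage-1 edges.
#' @return A data.frame with columns `src`, `dst`, `coef`; acyclic by
#'   construction. Attribute `proteins` lists all node ids.
#' @export
simulate_truth_network <- function(spec, pathway, lineage = 1L) {
  p <- spec$pathway_sizes[pathway]
  ids <- protein_ids(pathway, p)
  rs <- local_rng(substream_seed(spec$seed, paste0("dag", pathway)))
  on.exit(rs$restore(), add = TRUE)
  pairs <- which(upper.tri(matrix(0, p, p)), arr.ind = TRUE) # src < dst
  if (nrow(pairs)) pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  keep <- stats::runif(nrow(pairs)) < spec$edge_density
  if (spec$edge_density > 0 && nrow(pairs) &&
      nrow(pairs) * spec$edge_density < 1) {
    warning("expected edge count below 1 at this density")
  }
  dag <- data.frame(src = ids[pairs[keep, 1]], dst = ids[pairs[keep, 2]],
                    coef = draw_coefs(sum(keep), spec),
                    stringsAsFactors = FALSE)
  if (lineage > 1L) {
    rs2 <- local_rng(substream_seed(spec$seed,
                                    paste0("rewire", pathway, "_", lineage)))
    on.exit(rs2$restore(), add = TRUE)
    dag <- rewire_dag(dag, ids, spec)
  }
  attr(dag, "proteins") <- ids
  dag
}

draw_coefs <- function(k, spec) {
  mag <- stats::runif(k, spec$coefficient_range[1], spec$coefficient_range[2])
  mag * sample(c(-1, 1), k, replace = TRUE)
}

## Remove rewire_fraction of edges at random and add the same number of
## currently-absent forward edges, preserving acyclicity via the fixed
## topological order of the node ids.
rewire_dag <- function(dag, ids, spec) {
  n_rw <- round(nrow(dag) * spec$rewire_fraction)
  if (n_rw == 0L) return(dag)
  drop_idx <- sample(nrow(dag), n_rw)
  p <- length(ids)
  all_pairs <- which(upper.tri(matrix(0, p, p)), arr.ind = TRUE)
  key <- function(s, d) paste(s, d)
  present <- key(dag$src, dag$dst)
  kept <- dag[-drop_idx, , drop = FALSE]
  cand <- all_pairs[!(key(ids[all_pairs[, 1]], ids[all_pairs[, 2]]) %in% present), ,
                    drop = FALSE]
  n_add <- min(n_rw, nrow(cand))
  if (n_add > 0L) {
    add <- cand[sample(nrow(cand), n_add), , drop = FALSE]
    kept <- rbind(kept, data.frame(src = ids[add[, 1]], dst = ids[add[, 2]],
                                   coef = draw_coefs(n_add, spec),
                                   stringsAsFactors = FALSE))
  }
  rownames(kept) <- NULL
  kept
}

## Save/restore the RNG state so simulator calls are deterministic without
## disturbing the caller's random stream.
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  list(restore = function() {
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
}

#' Simulate a multi-platform cohort with known ground truth
#'
#' Generates protein, mRNA, miRNA and methylation matrices for each lineage
#' from the structural equation model described in [sim_spec()], together
#' with the truth DAGs, per-sample subgroup labels, and per-sample/protein
#' truth activation statuses obtained by thresholding the systematic
#' (subgroup-mean, cohort-centered) noise-free protein signal at
#' `+/- delta`.
#'
#' @param spec A `pronet_simspec`.
#' @param delta Activation half-width used for truth statuses; kept equal to
#'   the analysis delta so simulator and scorer are commensurable.
#' @return A list of class `pronet_cohort` with elements `lineages` (one
#'   entry per lineage: `matrices` (named list of `pronet_em`), `truth_dag`
#'   (per pathway), `truth_status` (samples x proteins character matrix),
#'   `labels` (data.frame sample/subgroup/lineage)), plus `mirna_map`,
#'   `pathways` and, for convenience, the first lineage's components at the
#'   top level.
#' @export
simulate_cohort <- function(spec, delta = 0.5) {
  stopifnot(inherits(spec, "pronet_simspec"))
  n_path <- length(spec$pathway_sizes)
  all_prot <- unlist(lapply(seq_len(n_path),
                            function(k) protein_ids(k, spec$pathway_sizes[k])))
  genes <- gene_of(all_prot)
  mirna_map <- stats::setNames(lapply(genes, function(g) {
    if (spec$n_mirna_per_gene == 0) character() else
      sprintf("mir_%s_%d", g, seq_len(spec$n_mirna_per_gene))
  }), genes)

  lineages <- lapply(seq_len(spec$n_lineages), function(l) {
    simulate_lineage(spec, l, all_prot, genes, mirna_map, delta)
  })
  names(lineages) <- sprintf("LIN%d", seq_len(spec$n_lineages))
  pathways <- lapply(seq_len(n_path), function(k) {
    ids <- protein_ids(k, spec$pathway_sizes[k])
    list(name = sprintf("pathway_%d", k),
         members = data.frame(protein = ids, gene = gene_of(ids), sign = 1,
                              stringsAsFactors = FALSE),
         p = length(ids))
  })
  names(pathways) <- vapply(pathways, `[[`, "", "name")
  out <- list(lineages = lineages, mirna_map = mirna_map,
              pathways = pathways, spec = spec, delta = delta)
  out$matrices <- lineages[[1]]$matrices
  out$truth_dag <- lineages[[1]]$truth_dag
  out$truth_status <- lineages[[1]]$truth_status
  out$labels <- lineages[[1]]$labels
  class(out) <- "pronet_cohort"
  out
}

simulate_lineage <- function(spec, l, all_prot, genes, mirna_map, delta) {
  n <- spec$n_samples
  rs <- local_rng(substream_seed(spec$seed, paste0("lineage", l)))
  on.exit(rs$restore(), add = TRUE)
  samples <- sprintf("LIN%d_S%03d", l, seq_len(n))

  ## subgroups: each shift entry claims subgroup_fraction of the cohort
  shifts <- spec$subgroup_shifts
  n_shift_groups <- length(shifts)
  subgroup <- rep("control", n)
  if (n_shift_groups) {
    sz <- round(spec$subgroup_fraction * n)
    idx <- sample(n)
    for (s in seq_len(n_shift_groups)) {
      take <- idx[seq_len(sz) + (s - 1L) * sz]
      subgroup[take] <- sprintf("shift%d", s)
    }
  }

  ## per-gene mRNA shift (transcriptional subgroup effect)
  gshift <- matrix(0, n, length(genes), dimnames = list(samples, genes))
  if (n_shift_groups) {
    for (s in seq_len(n_shift_groups)) {
      pw <- shifts[[s]]$pathway
      g_in <- gene_of(protein_ids(pw, spec$pathway_sizes[pw]))
      gshift[subgroup == sprintf("shift%d", s), g_in] <- shifts[[s]]$shift
    }
  }

  me <- spec$methylation_effect
  resid_sd <- sqrt(max(1 - me^2, 0.05))
  meth <- matrix(stats::rnorm(n * length(genes)), n,
                 dimnames = list(samples, genes))
  mrna <- me * meth +
    matrix(stats::rnorm(n * length(genes), sd = resid_sd), n) + gshift
  dimnames(mrna) <- list(samples, genes)
  all_mirna <- unlist(mirna_map, use.names = FALSE)
  mirna <- matrix(stats::rnorm(n * length(all_mirna)), n,
                  dimnames = list(samples, all_mirna))

  n_path <- length(spec$pathway_sizes)
  dags <- lapply(seq_len(n_path), simulate_truth_network, spec = spec,
                 lineage = l)
  names(dags) <- sprintf("pathway_%d", seq_len(n_path))

  prot <- matrix(0, n, length(all_prot), dimnames = list(samples, all_prot))
  mu <- matrix(0, n, length(all_prot), dimnames = list(samples, all_prot))
  for (k in seq_len(n_path)) {
    ids <- attr(dags[[k]], "proteins")
    dag <- dags[[k]]
    for (i in seq_along(ids)) {      # ids are in topological order
      pid <- ids[i]
      gid <- gene_of(pid)
      base <- spec$mrna_loading * mrna[, gid]
      mu_base <- spec$mrna_loading * gshift[, gid]
      if (length(mirna_map[[gid]])) {
        base <- base + spec$mirna_loading *
          rowSums(mirna[, mirna_map[[gid]], drop = FALSE])
      }
      par_rows <- dag[dag$dst == pid, , drop = FALSE]
      if (nrow(par_rows)) {
        base <- base + as.vector(prot[, par_rows$src, drop = FALSE] %*%
                                   par_rows$coef)
        mu_base <- mu_base + as.vector(mu[, par_rows$src, drop = FALSE] %*%
                                         par_rows$coef)
      }
      prot[, pid] <- base + stats::rnorm(n, sd = spec$noise_sd)
      mu[, pid] <- mu_base
    }
  }

  ## truth status: systematic signal, centered across the cohort
  mu_c <- sweep(mu, 2, colMeans(mu))
  status <- matrix("neutral", n, length(all_prot),
                   dimnames = list(samples, all_prot))
  status[mu_c > delta] <- "activated"
  status[mu_c < -delta] <- "suppressed"

  ct <- sprintf("LIN%d", l)
  list(
    matrices = list(
      protein = expression_matrix(prot, "protein", ct),
      mrna = expression_matrix(mrna, "mrna", ct),
      mirna = expression_matrix(mirna, "mirna", ct),
      methylation = expression_matrix(meth, "methylation", ct)
    ),
    truth_dag = dags,
    truth_status = status,
    labels = data.frame(sample = samples, subgroup = subgroup, lineage = ct,
                        stringsAsFactors = FALSE)
  )
}

#' Write a simulated cohort to disk
#'
#' One TSV per platform and lineage, plus a truth JSON
#' (`{dag, status, labels}`) consumed only by tests and downstream tools.
#'
#' @param cohort A `pronet_cohort`.
#' @param dir Output directory (created if needed).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (ln in names(cohort$lineages)) {
    lin <- cohort$lineages[[ln]]
    for (pf in names(lin$matrices)) {
      write_expression_matrix(lin$matrices[[pf]],
                              file.path(dir, sprintf("%s_%s.tsv", ln, pf)))
    }
    truth <- list(
      dag = lapply(lin$truth_dag, function(d) d[, c("src", "dst", "coef")]),
      status = as.data.frame(lin$truth_status),
      labels = lin$labels
    )
    jsonlite::write_json(truth, file.path(dir, sprintf("%s_truth.json", ln)),
                         auto_unbox = TRUE, digits = NA)
  }
  gmt <- vapply(cohort$pathways, function(pw) {
    paste(c(pw$name, "simulated", pw$members$protein), collapse = "\t")
  }, "")
  writeLines(gmt, file.path(dir, "pathways.gmt"))
  sidecar <- do.call(rbind, lapply(cohort$pathways, function(pw) pw$members))
  utils::write.table(
    data.frame(protein = sidecar$protein, gene = sidecar$gene,
               sign = sidecar$sign),
    file.path(dir, "pathway_signs.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
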