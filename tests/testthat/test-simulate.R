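test_that("truth networks respect density boundaries and determinism", {
  spec0 <- sim_spec(pathway_sizes = 5, edge_density = 0, seed = 3)
  dag0 <- simulate_truth_network(spec0, 1)
  expect_equal(nrow(dag0), 0)
  ## density so low that the expected edge count is below one still works
  spec_lo <- sim_spec(pathway_sizes = 4, edge_density = 0.05, seed = 3)
  expect_warning(dag_lo <- simulate_truth_network(spec_lo, 1), "below 1")
  expect_true(nrow(dag_lo) >= 0)

  spec1 <- sim_spec(pathway_sizes = 4, edge_density = 1, seed = 3)
  dag1 <- simulate_truth_network(spec1, 1)
  expect_equal(nrow(dag1), 4 * 3 / 2)   # complete DAG
  ## acyclic under the fixed topological order: src index < dst index
  idx <- function(x) as.integer(sub("^P1_", "", x))
  expect_true(all(idx(dag1$src) < idx(dag1$dst)))

  spec <- sim_spec(pathway_sizes = 8, edge_density = 0.3, seed = 11)
  expect_identical(simulate_truth_network(spec, 1),
                   simulate_truth_network(spec, 1))
  ## coefficient magnitudes bounded away from zero
  expect_true(all(abs(dag1$coef) >= spec1$coefficient_range[1]))
})

test_that("cohorts are deterministic and lineages share samples", {
  spec <- sim_spec(n_samples = 40, pathway_sizes = c(4, 3), seed = 9,
                   n_lineages = 2, rewire_fraction = 0)
  c1 <- suppressWarnings(simulate_cohort(spec))
  c2 <- suppressWarnings(simulate_cohort(spec))
  expect_identical(c1$matrices$protein$values, c2$matrices$protein$values)
  expect_identical(c1$lineages[[2]]$matrices$mrna$values,
                   c2$lineages[[2]]$matrices$mrna$values)
  ## zero rewiring: identical truth DAGs across lineages
  expect_identical(c1$lineages[[1]]$truth_dag[[1]][c("src", "dst")],
                   c1$lineages[[2]]$truth_dag[[1]][c("src", "dst")])
  for (lin in c1$lineages) {
    ids <- lapply(lin$matrices, function(m) rownames(m$values))
    expect_true(all(vapply(ids, identical, TRUE, ids[[1]])))
  }
})

test_that("rewiring preserves acyclicity and edge count", {
  spec <- sim_spec(pathway_sizes = 10, edge_density = 0.4,
                   n_lineages = 3, rewire_fraction = 0.5, seed = 21)
  d1 <- simulate_truth_network(spec, 1, lineage = 1)
  d2 <- simulate_truth_network(spec, 1, lineage = 2)
  expect_equal(nrow(d1), nrow(d2))
  idx <- function(x) as.integer(sub("^P1_", "", x))
  expect_true(all(idx(d2$src) < idx(d2$dst)))
  expect_false(identical(sort(paste(d1$src, d1$dst)),
                         sort(paste(d2$src, d2$dst))))
})

test_that("child-parent correlation matches the closed-form SEM value", {
  ## single edge P1 -> P2, coefficient beta, loadings L (mRNA) and q
  ## (miRNA): the implied correlation is computable in closed form from
  ## the structural equations, independently of the simulator internals.
  spec <- sim_spec(n_samples = 2000, pathway_sizes = 2, edge_density = 1,
                   coefficient_range = c(0.9, 0.9), noise_sd = 0.2,
                   seed = 33)
  dag <- simulate_truth_network(spec, 1)
  expect_equal(nrow(dag), 1)
  beta <- dag$coef[1]
  coh <- simulate_cohort(spec)
  P <- coh$matrices$protein$values
  r_emp <- cor(P[, dag$src], P[, dag$dst])
  ## node variance: var(y) = L^2 * 1 + q^2 * m + noise^2 (+ beta^2 var(parent))
  own <- spec$mrna_loading^2 + spec$mirna_loading^2 * spec$n_mirna_per_gene +
    spec$noise_sd^2
  v_par <- own
  v_child <- beta^2 * v_par + own
  r_theory <- beta * v_par / sqrt(v_par * v_child)
  expect_lt(abs(r_emp - r_theory), 0.03)
})

test_that("SEM-implied protein covariance matches empirical covariance", {
  spec <- sim_spec(n_samples = 4000, pathway_sizes = 6, edge_density = 0.3,
                   seed = 44)
  coh <- simulate_cohort(spec)
  dag <- coh$truth_dag[[1]]
  ids <- colnames(coh$matrices$protein$values)
  p <- length(ids)
  B <- matrix(0, p, p, dimnames = list(ids, ids))
  for (r in seq_len(nrow(dag))) B[dag$src[r], dag$dst[r]] <- dag$coef[r]
  own_var <- spec$mrna_loading^2 + spec$mirna_loading^2 * spec$n_mirna_per_gene +
    spec$noise_sd^2
  A <- solve(diag(p) - t(B))             # y = (I - B')^{-1} u
  Sigma <- A %*% (diag(p) * own_var) %*% t(A)
  emp <- cov(coh$matrices$protein$values)
  expect_lt(max(abs(emp - Sigma)), 0.35)  # Monte-Carlo error at n=4000
})

test_that("strong shifts with vanishing noise force activated truth status", {
  spec <- sim_spec(n_samples = 200, pathway_sizes = c(3, 3),
                   noise_sd = 1e-4, edge_density = 0,
                   subgroup_shifts = list(list(pathway = 1, shift = 2)),
                   seed = 55)
  coh <- suppressWarnings(simulate_cohort(spec, delta = 0.5))
  shifted <- coh$labels$sample[coh$labels$subgroup == "shift1"]
  pw1 <- sprintf("P1_%d", 1:3)
  expect_true(all(coh$truth_status[shifted, pw1] == "activated"))
  ## unshifted pathway stays neutral for everyone
  pw2 <- sprintf("P2_%d", 1:3)
  expect_true(all(coh$truth_status[, pw2] == "neutral"))
})

test_that("cohorts write out and read back through the standard formats", {
  spec <- sim_spec(n_samples = 25, pathway_sizes = 3, seed = 66)
  coh <- suppressWarnings(simulate_cohort(spec))
  d <- tempfile()
  write_cohort(coh, d)
  em <- read_expression_matrix(file.path(d, "LIN1_protein.tsv"), "protein")
  expect_equal(em$values, coh$matrices$protein$values, tolerance = 1e-12)
  pws <- read_pathways(file.path(d, "pathways.gmt"),
                       file.path(d, "pathway_signs.tsv"))
  expect_identical(pws$pathway_1$members$protein, sprintf("P1_%d", 1:3))
  truth <- jsonlite::read_json(file.path(d, "LIN1_truth.json"),
                               simplifyVector = TRUE)
  expect_identical(nrow(truth$labels), 25L)
})
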