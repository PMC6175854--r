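test_that("upstream covariates split mRNA by methylation projection", {
  n <- 40
  set.seed(301)
  ## orthogonal methylation: modulated component is the constant fit only
  meth <- matrix(rnorm(n), n, 1, dimnames = list(sprintf("s%d", 1:n), "G1"))
  r <- rnorm(n)
  r <- r - mean(r)
  mc <- meth[, 1] - mean(meth[, 1])
  r <- r - mc * sum(r * mc) / sum(mc^2)   # orthogonal to {1, methylation}
  mrna <- matrix(r, n, 1, dimnames = list(rownames(meth), "G1"))
  up <- construct_upstream_covariates(mrna, meth, NULL, "G1")
  expect_lt(sd(up[, "G1.mrna_mod"]), 1e-10)     # constant after projection
  expect_equal(up[, "G1.mrna_ind"], r, tolerance = 1e-10,
               ignore_attr = TRUE)

  ## proportional mRNA: independent component identically zero
  mrna2 <- matrix(2.5 * meth[, 1], n, 1, dimnames = dimnames(meth))
  up2 <- construct_upstream_covariates(mrna2, meth, NULL, "G1")
  expect_lt(max(abs(up2[, "G1.mrna_ind"])), 1e-10)

  ## two mapped miRNAs: K = 4
  mir <- matrix(rnorm(n * 2), n, 2,
                dimnames = list(rownames(meth), c("mir1", "mir2")))
  up3 <- construct_upstream_covariates(mrna, meth, mir, "G1",
                                       list(G1 = c("mir1", "mir2")))
  expect_equal(ncol(up3), 4)
  expect_identical(attr(up3, "kinds"),
                   c("mrna-modulated", "mrna-independent", "mirna", "mirna"))

  expect_warning(up4 <- construct_upstream_covariates(mrna, meth, mir, "G9",
                                                      list(G9 = "mir1")),
                 "absent")
  expect_equal(colnames(up4), "mir1")
  expect_null(construct_upstream_covariates(NULL, NULL, NULL, "G9"))
})

test_that("closed-form log marginal matches the numerical oracle", {
  set.seed(302)
  n <- 20
  Z <- scale(matrix(rnorm(n * 3), n,
                    dimnames = list(sprintf("s%d", 1:n), c("a", "b", "c"))))
  attr(Z, "scaled:center") <- attr(Z, "scaled:scale") <- NULL
  y <- 0.8 * Z[, 1] - 0.5 * Z[, 2] + rnorm(n, sd = 0.7)
  prob <- manual_problem(y, Z, g = n)
  for (model in list(integer(), 1L, c(1L, 2L), 1:3)) {
    closed <- log_marginal_likelihood(prob, model)
    numeric_val <- oracle_log_marginal(y, Z, model, g = n)
    expect_lt(abs((closed - numeric_val) / numeric_val), 1e-3)
  }
})

test_that("Bayes factors are invariant to rescaling the response", {
  set.seed(303)
  n <- 30
  Z <- scale(matrix(rnorm(n * 2), n, dimnames = list(NULL, c("a", "b"))))
  y <- 0.6 * Z[, 1] + rnorm(n)
  p1 <- manual_problem(y, Z)
  p2 <- manual_problem(3.7 * y, Z)
  bf1 <- log_marginal_likelihood(p1, 1L) - log_marginal_likelihood(p1, integer())
  bf2 <- log_marginal_likelihood(p2, 1L) - log_marginal_likelihood(p2, integer())
  expect_equal(bf1, bf2, tolerance = 1e-10)
  expect_error(log_marginal_likelihood(p1, seq_len(n)), "below n - 1")
})

test_that("enumeration posterior normalizes and responds to the prior", {
  set.seed(304)
  n <- 60
  X <- cbind(tgt = rnorm(n), a = rnorm(n), b = rnorm(n), c = rnorm(n))
  X[, "tgt"] <- 0.8 * X[, "a"] + rnorm(n, sd = 0.5)
  rownames(X) <- sprintf("s%d", 1:n)
  cfg <- pronet_config(seed = 5)
  prob <- regression_problem("tgt", X, flat_prior(colnames(X)), config = cfg)
  fit <- model_posterior(prob, cfg)
  expect_equal(sum(fit$log_evidence$post), 1, tolerance = 1e-10)
  expect_true(all(fit$pips >= 0 & fit$pips <= 1))
  expect_true("a" %in% fit$mpm)

  ## candidate with prior weight 1 is forced into every model
  prior1 <- flat_prior(colnames(X))
  prior1["c", "tgt"] <- 1
  prob1 <- regression_problem("tgt", X, prior1, config = cfg)
  fit1 <- model_posterior(prob1, cfg)
  expect_equal(unname(fit1$pips["c"]), 1)

  ## zero candidates: empty fit, no error
  lone <- matrix(rnorm(n), n, 1, dimnames = list(rownames(X), "solo"))
  prob0 <- regression_problem("solo", lone, NULL, config = cfg)
  fit0 <- model_posterior(prob0, cfg)
  expect_length(fit0$mpm, 0)
})

test_that("the median probability model uses a strict 0.5 cutoff", {
  pips <- c(a = 0.5, b = 0.500000001, c = 0.9)
  prob <- manual_problem(rnorm(30), scale(matrix(rnorm(90), 30,
                                                 dimnames = list(NULL, c("a", "b", "c")))))
  fit <- pronet:::new_nodefit(prob, pips, "enumeration", NULL)
  expect_identical(fit$mpm, c("b", "c"))   # exactly 0.5 excluded
})

test_that("flat-prior pips are invariant to candidate ordering", {
  set.seed(305)
  n <- 80
  X <- cbind(tgt = rnorm(n), a = rnorm(n), b = rnorm(n), c = rnorm(n))
  X[, "tgt"] <- 0.5 * X[, "b"] + rnorm(n, sd = 0.8)
  rownames(X) <- sprintf("s%d", 1:n)
  cfg <- pronet_config(seed = 5)
  f1 <- model_posterior(regression_problem("tgt", X, flat_prior(colnames(X)),
                                           config = cfg), cfg)
  X2 <- X[, c("tgt", "c", "b", "a")]
  f2 <- model_posterior(regression_problem("tgt", X2, flat_prior(colnames(X2)),
                                           config = cfg), cfg)
  expect_equal(f1$pips[c("a", "b", "c")], f2$pips[c("a", "b", "c")],
               tolerance = 1e-12)
})

test_that("raising a true regulator's prior weight never lowers its pip", {
  set.seed(306)
  n <- 100
  X <- cbind(tgt = rnorm(n), a = rnorm(n), b = rnorm(n))
  X[, "tgt"] <- 0.6 * X[, "a"] + rnorm(n, sd = 0.7)
  rownames(X) <- sprintf("s%d", 1:n)
  cfg <- pronet_config(seed = 5)
  last <- 0
  for (w in c(0.2, 0.4, 0.6, 0.8, 0.95)) {
    pri <- flat_prior(colnames(X))
    pri["a", "tgt"] <- w
    fit <- model_posterior(regression_problem("tgt", X, pri, config = cfg), cfg)
    expect_gte(fit$pips[["a"]], last)
    last <- fit$pips[["a"]]
  }
})

test_that("MC3 agrees with enumeration on a moderate problem", {
  set.seed(307)
  n <- 150; k <- 10
  Z <- matrix(rnorm(n * k), n,
              dimnames = list(sprintf("s%d", 1:n), paste0("c", 1:k)))
  y <- 0.7 * Z[, 1] - 0.5 * Z[, 4] + 0.3 * Z[, 7] + rnorm(n, sd = 0.8)
  X <- cbind(tgt = y, Z)
  cfg <- pronet_config(seed = 9, mcmc_iters = 50000)
  prob <- regression_problem("tgt", X, flat_prior(colnames(X)), config = cfg)
  fe <- model_posterior(prob, cfg, method = "enumeration")
  fm <- model_posterior(prob, cfg, method = "mc3")
  expect_lt(max(abs(fe$pips - fm$pips)), 0.02)
})

test_that("network edge typing follows mutual-selection rules", {
  mk_fit <- function(target, pips) {
    prob <- manual_problem(rnorm(30),
                           scale(matrix(rnorm(30 * length(pips)), 30,
                                        dimnames = list(NULL, names(pips)))))
    prob$target <- target
    pronet:::new_nodefit(prob, pips, "enumeration", NULL)
  }
  ## mutual selection of (A,B): one correlative edge; A -> C regulatory
  fits <- list(
    A = mk_fit("A", c(B = 0.8, C = 0.2)),
    B = mk_fit("B", c(A = 0.7, C = 0.1)),
    C = mk_fit("C", c(A = 0.9, B = 0.3))
  )
  net <- build_integrated_network(fits, "BRCA", "pw")
  e <- net$protein_edges
  expect_equal(sum(e$kind == "correlative"), 1)
  expect_equal(sum(e$kind == "regulatory"), 1)
  cor_e <- e[e$kind == "correlative", ]
  expect_setequal(c(cor_e$src, cor_e$dst), c("A", "B"))
  expect_equal(cor_e$pip, 0.8)   # max of the two direction pips
  reg <- e[e$kind == "regulatory", ]
  expect_identical(c(reg$src, reg$dst), c("A", "C"))
  ## out-degree: A has correlative + regulatory out; B correlative only
  expect_equal(unname(net$C[c("A", "B", "C")]), c(2, 1, 0))

  ## empty mpms everywhere: empty network
  fits0 <- list(A = mk_fit("A", c(B = 0.1)), B = mk_fit("B", c(A = 0.2)))
  net0 <- build_integrated_network(fits0)
  expect_equal(nrow(net0$protein_edges), 0)
  expect_true(all(net0$C == 0))
})
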