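test_that("predictive probabilities are symmetric, limit correctly and sum to 1", {
  set.seed(401)
  n <- 60
  X <- cbind(tgt = rnorm(n), a = rnorm(n))
  X[, "tgt"] <- 0.7 * X[, "a"] + rnorm(n, sd = 0.6)
  rownames(X) <- sprintf("s%d", 1:n)
  cfg <- pronet_config(seed = 3)
  prob <- regression_problem("tgt", X, flat_prior(colnames(X)), config = cfg)
  fit <- model_posterior(prob, cfg)
  pr <- predictive_probabilities(fit, prob, delta = 0.5)
  expect_lt(max(abs(rowSums(pr) - 1)), 1e-12)

  ## delta -> large: everything neutral
  pr_big <- predictive_probabilities(fit, prob, delta = 50)
  expect_true(all(pr_big[, "p_zero"] > 0.999999))

  ## empty MPM: symmetric null predictive centered at zero
  lone <- matrix(rnorm(n), n, 1, dimnames = list(rownames(X), "solo"))
  prob0 <- regression_problem("solo", lone, NULL, config = cfg)
  fit0 <- model_posterior(prob0, cfg)
  pr0 <- predictive_probabilities(fit0, prob0, delta = 0.5)
  expect_equal(pr0[, "p_plus"], pr0[, "p_minus"], tolerance = 1e-12)
  expect_equal(unname(attr(pr0, "scale")[1]),
               sqrt(sum(prob0$y^2) / n), tolerance = 1e-12)
})

test_that("delta-interval probabilities match the t-distribution oracle", {
  ## location 1.0, scale 0.5, 10 df, delta 0.5:
  ## p_plus = P(T > (0.5-1)/0.5) = F_t10(1), checked against numerical
  ## integration of the t density
  f_t10_1 <- integrate(function(x) dt(x, 10), -Inf, 1, rel.tol = 1e-10)$value
  p_plus <- pt((0.5 - 1.0) / 0.5, df = 10, lower.tail = FALSE)
  expect_equal(p_plus, f_t10_1, tolerance = 1e-8)
  p_minus <- pt((-0.5 - 1.0) / 0.5, df = 10)
  p_minus_num <- integrate(function(x) dt(x, 10), -Inf, -3, rel.tol = 1e-10)$value
  expect_equal(p_minus, p_minus_num, tolerance = 1e-8)
})

test_that("patient networks share topology and validate coverage", {
  spec <- sim_spec(n_samples = 60, pathway_sizes = 4, seed = 402)
  coh <- simulate_cohort(spec)
  cfg <- pronet_config(seed = 403)
  X <- coh$matrices$protein$values
  fit <- pronet:::fit_pathway_network(X, flat_prior(colnames(X)), cfg)
  tensor <- activation_tensor(fit$fits, fit$problems)
  pn1 <- patient_network(fit$network, tensor, 1)
  pn2 <- patient_network(fit$network, tensor, 2)
  expect_identical(pn1$protein_edges, pn2$protein_edges)
  expect_length(pn1$labels, 4)

  tensor_cut <- tensor
  tensor_cut$status <- tensor_cut$status[, -2, drop = FALSE]
  expect_error(patient_network(fit$network, tensor_cut, 1), "P1_2")

  ## all-neutral tensor labels every node neutral
  tensor_n <- tensor
  tensor_n$p_zero[] <- 1; tensor_n$p_plus[] <- 0; tensor_n$p_minus[] <- 0
  tensor_n$status[] <- pronet:::status_from_probs(tensor_n$p_minus,
                                                  tensor_n$p_zero,
                                                  tensor_n$p_plus)
  expect_true(all(patient_network(fit$network, tensor_n, 3)$labels == "neutral"))
})

test_that("pathway scores follow the out-degree-weighted formula", {
  ## p = 2, edge 1 -> 2 (C_1 = 1, C_2 = 0), p_plus = 1 for both:
  ## kappa+ = (1/2)(1*2 + 1*1) = 1.5
  samples <- c("s1", "s2")
  mk <- function(v) matrix(v, 2, 2, dimnames = list(samples, c("A", "B")))
  tensor <- structure(list(p_minus = mk(0), p_zero = mk(0), p_plus = mk(1),
                           status = mk("activated"), delta = 0.5),
                      class = "pronet_tensor")
  net <- pronet:::new_network("NA", "pw", c("A", "B"),
                              data.frame(src = "A", dst = "B",
                                         kind = "regulatory", pip = 0.9,
                                         pip_fwd = 0.9, pip_rev = NA,
                                         stringsAsFactors = FALSE),
                              data.frame(covariate = character(),
                                         target = character(),
                                         pip = numeric()),
                              c(A = 1, B = 0))
  sc <- pathway_scores(tensor, net)
  expect_equal(sc$kappa_plus, c(1.5, 1.5))
  expect_equal(sc$kappa_minus, c(0, 0))
  expect_equal(sc$kappa_zero, c(0, 0))
  expect_identical(sc$status, c("activated", "activated"))

  ## uniform triples: all three kappas equal, status neutral by tie rule
  tensor_u <- structure(list(p_minus = mk(1 / 3), p_zero = mk(1 / 3),
                             p_plus = mk(1 / 3), status = mk("neutral"),
                             delta = 0.5),
                        class = "pronet_tensor")
  sc_u <- pathway_scores(tensor_u, net)
  expect_equal(sc_u$kappa_plus, sc_u$kappa_minus)
  expect_equal(sc_u$kappa_plus, sc_u$kappa_zero)
  expect_identical(sc_u$status, c("neutral", "neutral"))
})

test_that("kappa sums equal the independently-computed degree constant", {
  set.seed(404)
  for (rep in 1:20) {
    p <- 6; n <- 8
    ids <- sprintf("P%d", 1:p)
    samples <- sprintf("s%d", 1:n)
    raw <- array(rexp(n * p * 3), c(n, p, 3))
    tot <- raw[, , 1] + raw[, , 2] + raw[, , 3]
    mk <- function(sl) {
      m <- raw[, , sl] / tot
      dimnames(m) <- list(samples, ids); m
    }
    tensor <- structure(list(p_minus = mk(1), p_zero = mk(2), p_plus = mk(3),
                             status = NULL, delta = 0.5),
                        class = "pronet_tensor")
    edges <- which(upper.tri(matrix(0, p, p)) &
                     matrix(runif(p * p) < 0.4, p, p), arr.ind = TRUE)
    pe <- data.frame(src = ids[edges[, 1]], dst = ids[edges[, 2]],
                     kind = sample(c("regulatory", "correlative"),
                                   nrow(edges), replace = TRUE),
                     pip = rep(1, nrow(edges)),
                     pip_fwd = rep(1, nrow(edges)),
                     pip_rev = rep(1, nrow(edges)),
                     stringsAsFactors = FALSE)
    C <- sapply(ids, function(i) {
      sum(pe$src == i & pe$kind == "regulatory") +
        sum((pe$src == i | pe$dst == i) & pe$kind == "correlative")
    })
    net <- pronet:::new_network("NA", "pw", ids, pe,
                                data.frame(covariate = character(),
                                           target = character(),
                                           pip = numeric()), C)
    sc <- pathway_scores(tensor, net)
    ## independent explicit-loop oracle for the degree constant
    const <- 0
    for (i in ids) const <- const + (C[[i]] + 1)
    const <- const / p
    expect_lt(max(abs(sc$kappa_plus + sc$kappa_minus + sc$kappa_zero - const)),
              1e-10)
  }
})

test_that("naive and native scores reduce to signed sums", {
  P <- matrix(c(2, 3, -1, 1, 0, 4), 2, 3, byrow = TRUE,
              dimnames = list(c("s1", "s2"), c("A", "B", "C")))
  pw <- list(name = "pw",
             members = data.frame(protein = c("A", "B", "C"),
                                  gene = c("A", "B", "C"),
                                  sign = c(1, 1, -1), stringsAsFactors = FALSE))
  expect_equal(unname(naive_score(P, pw)), c(4, 5))
  expect_equal(native_score(P, pw), c(2 + 3 + 1, 1 + 0 - 4))

  pw_pos <- pw; pw_pos$members$sign <- 1
  expect_equal(native_score(P, pw_pos), unname(naive_score(P, pw_pos)))
  pw_neg <- pw; pw_neg$members$sign <- -pw$members$sign
  expect_equal(native_score(P, pw_neg), -native_score(P, pw))

  pw_one <- list(name = "pw1",
                 members = data.frame(protein = "B", gene = "B", sign = 1))
  expect_equal(unname(naive_score(P, pw_one)), P[, "B"], ignore_attr = TRUE)
  pw_miss <- list(name = "pwm",
                  members = data.frame(protein = c("A", "ZZ"),
                                       gene = c("A", "ZZ"), sign = c(1, 1)))
  expect_warning(s <- naive_score(P, pw_miss), "ZZ")
  expect_equal(unname(s), P[, "A"], ignore_attr = TRUE)
  pw_none <- list(name = "pw0",
                  members = data.frame(protein = "QQ", gene = "QQ", sign = 1))
  expect_error(naive_score(P, pw_none), "no pathway members")
})
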