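#' PC-algorithm causal structure estimation
#'
#' Estimates the causal structure of a set of continuous variables with the
#' PC algorithm: skeleton search by Gaussian conditional-independence tests
#' (partial correlation, Fisher z-transform), v-structure orientation, and
#' Meek's propagation rules. The order-independent ("PC-stable") skeleton
#' variant is used so results do not depend on column order. Output is a
#' CPDAG-style graph with directed, undirected and bi-directed edges; a
#' bi-directed edge records conflicting v-structure orientations and, like
#' an undirected edge, means the direction is not identifiable from the
#' data.
#'
#' @param data A `pronet_em` or numeric matrix (samples x variables),
#'   typically a protein matrix restricted to one pathway.
#' @param alpha Significance level of the conditional-independence tests.
#' @return An object of class `pronet_cpdag`: list with `edges` (data.frame
#'   `a`, `b`, `type` in directed/undirected/bidirected, where `directed`
#'   means `a -> b`), `amat` (arrowhead matrix), and the inputs' `labels`.
#' @export
pc_skeleton <- function(data, alpha) {
  X <- em_values(data)
  n <- nrow(X); p <- ncol(X)
  if (p < 2) stop("need at least 2 variables")
  if (n < 10) stop("need at least 10 samples for CI testing")
  stopifnot(alpha > 0, alpha < 1)
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant column(s): ", paste(colnames(X)[sds == 0], collapse = ", "))
  }
  pc_from_cor(stats::cor(X), n, alpha, labels = colnames(X))
}

## Core engine working from a correlation matrix; `cache` optionally memoises
## CI-test p-values across calls sharing the same data (used by the
## stability subsampling, where 100 alpha values share each subsample).
pc_from_cor <- function(C, n, alpha, labels = NULL, cache = NULL) {
  p <- ncol(C)
  if (is.null(labels)) labels <- paste0("V", seq_len(p))
  sk <- pc_skeleton_search(C, n, alpha, cache)
  orient_cpdag(sk$adj, sk$sepset, labels)
}

## p-value of the Fisher-z partial correlation test of i _||_ j | S
ci_test_p <- function(C, n, i, j, S) {
  if (length(S) == 0L) {
    r <- C[i, j]
  } else {
    sub <- C[c(i, j, S), c(i, j, S), drop = FALSE]
    prec <- tryCatch(solve(sub), error = function(e) MASS_ginv(sub))
    r <- -prec[1, 2] / sqrt(prec[1, 1] * prec[2, 2])
  }
  r <- max(min(r, 1 - 1e-12), -1 + 1e-12)
  df <- n - length(S) - 3
  if (df <= 0) return(1)
  stat <- sqrt(df) * abs(atanh(r))
  2 * stats::pnorm(-stat)
}

## minimal Moore-Penrose inverse via SVD (degenerate correlation submatrices)
MASS_ginv <- function(m, tol = 1e-10) {
  s <- svd(m)
  pos <- s$d > tol * s$d[1]
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

pc_skeleton_search <- function(C, n, alpha, cache = NULL) {
  p <- ncol(C)
  adj <- matrix(TRUE, p, p); diag(adj) <- FALSE
  sepset <- vector("list", p * p)
  dim(sepset) <- c(p, p)
  get_p <- function(i, j, S) {
    if (is.null(cache)) return(ci_test_p(C, n, i, j, S))
    key <- paste(min(i, j), max(i, j), paste(sort(S), collapse = ","), sep = "|")
    v <- cache[[key]]
    if (is.null(v)) {
      v <- ci_test_p(C, n, i, j, S)
      cache[[key]] <- v
    }
    v
  }
  l <- 0L
  repeat {
    any_big <- FALSE
    adj_fixed <- adj  # PC-stable: neighbourhoods frozen within each level
    for (i in seq_len(p)) {
      for (j in seq_len(p)) {
        if (i >= j || !adj[i, j]) next
        nbrs <- setdiff(which(adj_fixed[i, ] | adj_fixed[j, ]), c(i, j))
        nbrs_i <- setdiff(which(adj_fixed[i, ]), j)
        nbrs_j <- setdiff(which(adj_fixed[j, ]), i)
        if (length(nbrs_i) >= l || length(nbrs_j) >= l) any_big <- TRUE
        removed <- FALSE
        for (side in list(nbrs_i, nbrs_j)) {
          if (removed || length(side) < l) next
          subsets <- if (l == 0L) list(integer()) else
            utils::combn(side, l, simplify = FALSE)
          for (S in subsets) {
            if (get_p(i, j, S) > alpha) {
              adj[i, j] <- adj[j, i] <- FALSE
              sepset[[i, j]] <- sepset[[j, i]] <- S
              removed <- TRUE
              break
            }
          }
        }
      }
    }
    l <- l + 1L
    if (!any_big || l > p - 2L) break
  }
  list(adj = adj, sepset = sepset)
}

orient_cpdag <- function(adj, sepset, labels) {
  p <- ncol(adj)
  ## arrowhead[i,j] = TRUE means an arrowhead at j on edge i-j (i -> j)
  arrow <- matrix(FALSE, p, p)
  ## v-structures: i - k - j, i,j non-adjacent, k not in sepset(i,j)
  for (k in seq_len(p)) {
    nb <- which(adj[k, ])
    if (length(nb) < 2) next
    for (ii in seq_along(nb)) {
      for (jj in seq_along(nb)) {
        if (ii >= jj) next
        i <- nb[ii]; j <- nb[jj]
        if (adj[i, j]) next
        if (!(k %in% sepset[[i, j]])) {
          arrow[i, k] <- TRUE
          arrow[j, k] <- TRUE
        }
      }
    }
  }
  ## edge typing after v-structures; conflicts (arrowheads both ends) stay
  ## bi-directed and are excluded from Meek propagation
  directed <- function() arrow & t(!arrow) & adj  # i->j, no head at i
  undirected <- function() adj & !arrow & t(!arrow)
  ## Meek rules on undirected edges
  repeat {
    changed <- FALSE
    dmat <- directed(); umat <- undirected()
    for (a in seq_len(p)) for (b in seq_len(p)) {
      if (!umat[a, b]) next
      ## R1: c -> a, a - b, c,b non-adjacent  =>  a -> b
      r1 <- any(dmat[, a] & !adj[, b] & seq_len(p) != b)
      ## R2: a -> c -> b and a - b  =>  a -> b
      r2 <- any(dmat[a, ] & dmat[, b])
      ## R3: a - c -> b, a - d -> b, c,d non-adjacent, a - b => a -> b
      r3 <- FALSE
      cand <- which(umat[a, ] & dmat[, b])
      if (length(cand) >= 2) {
        for (c1 in cand) for (d1 in cand) {
          if (c1 < d1 && !adj[c1, d1]) { r3 <- TRUE; break }
        }
      }
      if (r1 || r2 || r3) {
        arrow[a, b] <- TRUE
        changed <- TRUE
        dmat <- directed(); umat <- undirected()
      }
    }
    if (!changed) break
  }
  edges <- NULL
  for (i in seq_len(p)) for (j in seq_len(p)) {
    if (i >= j || !adj[i, j]) next
    type <- if (arrow[i, j] && arrow[j, i]) "bidirected"
      else if (arrow[i, j]) "directed"        # i -> j
      else if (arrow[j, i]) NA                # j -> i; emit as (j, i)
      else "undirected"
    if (is.na(type)) {
      edges <- rbind(edges, data.frame(a = labels[j], b = labels[i],
                                       type = "directed",
                                       stringsAsFactors = FALSE))
    } else {
      edges <- rbind(edges, data.frame(a = labels[i], b = labels[j],
                                       type = type, stringsAsFactors = FALSE))
    }
  }
  if (is.null(edges)) {
    edges <- data.frame(a = character(), b = character(), type = character(),
                        stringsAsFactors = FALSE)
  }
  amat <- arrow & adj
  dimnames(amat) <- list(labels, labels)
  structure(list(edges = edges, amat = amat, adj = adj, labels = labels),
            class = "pronet_cpdag")
}

#' @export
print.pronet_cpdag <- function(x, ...) {
  cat(sprintf("<CPDAG: %d nodes, %d edges (%d directed, %d undirected, %d bidirected)>\n",
              length(x$labels), nrow(x$edges),
              sum(x$edges$type == "directed"),
              sum(x$edges$type == "undirected"),
              sum(x$edges$type == "bidirected")))
  invisible(x)
}

## Directed credit matrix for stability counting: a directed edge credits
## its direction fully; an undirected or bi-directed edge credits each
## direction at half weight, since the direction is not identifiable.
cpdag_credit <- function(cpdag, labels) {
  p <- length(labels)
  cr <- matrix(0, p, p, dimnames = list(labels, labels))
  e <- cpdag$edges
  for (r in seq_len(nrow(e))) {
    a <- e$a[r]; b <- e$b[r]
    if (!(a %in% labels) || !(b %in% labels)) next
    if (e$type[r] == "directed") {
      cr[a, b] <- cr[a, b] + 1
    } else {
      cr[a, b] <- cr[a, b] + 0.5
      cr[b, a] <- cr[b, a] + 0.5
    }
  }
  cr
}
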