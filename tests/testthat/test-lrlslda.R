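random_spd <- function(n, ids = paste0("e", seq_len(n))) {
  M <- matrix(rnorm(n * n), n, n)
  K <- crossprod(M) / n + diag(0.5, n)
  dimnames(K) <- list(ids, ids)
  K
}

random_sim <- function(n, ids = paste0("e", seq_len(n))) {
  m <- matrix(runif(n * n), n, n)
  m <- (m + t(m)) / 2
  diag(m) <- 1
  dimnames(m) <- list(ids, ids)
  m
}

test_that("normalized Laplacian matches direct arithmetic and spectral bounds", {
  expect_equal(unname(normalized_laplacian(diag(2))), matrix(0, 2, 2))
  expect_equal(unname(normalized_laplacian(matrix(1, 2, 2))),
               matrix(c(0.5, -0.5, -0.5, 0.5), 2))
  set.seed(3)
  for (rep in 1:8) {
    L <- normalized_laplacian(random_sim(sample(3:10, 1L)))
    ev <- eigen(L, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-8)
    expect_lte(max(ev), 2 + 1e-8)
  }
  # zero-sum row becomes an identity row
  s <- matrix(0, 2, 2); s[1, 1] <- 1
  L <- normalized_laplacian(s)
  expect_equal(L[2, ], c(0, 1))
  expect_error(normalized_laplacian(matrix(c(1, -0.1, -0.1, 1), 2)), "negative")
})

test_that("lrls_solve has the right closed-form limits", {
  set.seed(8)
  K <- random_spd(6)
  L <- normalized_laplacian(random_sim(6))
  Y <- matrix(rnorm(12), 6, 2)
  # regularizer off: exact interpolation
  expect_equal(lrls_solve(K, L, Y, eta = 0, jitter = 0), Y)
  # identity kernel and Laplacian: uniform shrinkage
  I6 <- diag(6)
  expect_equal(lrls_solve(I6, I6, Y, eta = 3, jitter = 0), Y / 4)
})

test_that("lrls_solve matches a generic numerical minimizer of the objective", {
  set.seed(21)
  for (rep in 1:3) {
    n <- 15L
    K <- random_spd(n)
    L <- normalized_laplacian(random_sim(n))
    Y <- matrix(rnorm(n * 2), n, 2)
    eta <- runif(1, 0.3, 2)
    Fhat <- lrls_solve(K, L, Y, eta = eta, jitter = 0)
    obj <- function(f) {
      Fm <- matrix(f, n)
      sum((Y - Fm)^2) + eta * sum(diag(t(Fm) %*% L %*% Fm))
    }
    grad <- function(f) {
      Fm <- matrix(f, n)
      as.vector(2 * (Fm - Y) + 2 * eta * (L %*% Fm))
    }
    opt <- optim(rep(0, n * 2), obj, grad, method = "BFGS",
                 control = list(maxit = 5000, reltol = 1e-15))
    expect_lt(max(abs(Fhat - matrix(opt$par, n))), 1e-6)
    # minimizer sanity: objective at F below objective at Y and at 0
    expect_lte(obj(as.vector(Fhat)), obj(as.vector(Y)) + 1e-10)
    expect_lte(obj(as.vector(Fhat)), obj(rep(0, n * 2)) + 1e-10)
  }
})

test_that("lrls_solve is invariant under simultaneous entity permutation", {
  set.seed(13)
  n <- 8L
  K <- random_spd(n); S <- random_sim(n); L <- normalized_laplacian(S)
  Y <- matrix(rnorm(n * 3), n, 3)
  Fhat <- lrls_solve(K, L, Y, eta = 0.7)
  p <- sample(n)
  Fp <- lrls_solve(K[p, p], L[p, p], Y[p, , drop = FALSE], eta = 0.7)
  expect_equal(unname(Fp), unname(Fhat[p, , drop = FALSE]), tolerance = 1e-8)
})

test_that("predict combines the two spaces linearly and monotonically in w", {
  set.seed(30)
  A <- matrix(rbinom(20, 1, 0.3), 5, 4,
              dimnames = list(paste0("L", 1:5), paste0("D", 1:4)))
  assoc <- association_table(A)
  sl <- random_sim(5, rownames(A)); sd <- random_sim(4, colnames(A))
  s1 <- lrls_predict(assoc, sl, sd, lrls_params(w = 1))
  s0 <- lrls_predict(assoc, sl, sd, lrls_params(w = 0))
  shalf <- lrls_predict(assoc, sl, sd, lrls_params(w = 0.5))
  expect_equal(shalf, (s1 + s0) / 2)
  for (w in c(0.2, 0.8)) {
    sw <- lrls_predict(assoc, sl, sd, lrls_params(w = w))
    expect_true(all(sw >= pmin(s0, s1) - 1e-12 & sw <= pmax(s0, s1) + 1e-12))
  }
})

test_that("held-out within-cluster pairs outscore cross-cluster pairs on block data", {
  # two clean 5x5 blocks; withhold one within-cluster association
  A <- matrix(0, 10, 10,
              dimnames = list(paste0("L", 1:10), paste0("D", 1:10)))
  A[1:5, 1:5] <- 1
  A[6:10, 6:10] <- 1
  A["L1", "D1"] <- 0                      # held out
  assoc <- association_table(A)
  kl <- gaussian_kernel(assoc, "lncrna")
  kd <- gaussian_kernel(assoc, "disease")
  scores <- lrls_predict(assoc, kl, kd)
  cross <- c(scores[1:5, 6:10], scores[6:10, 1:5])
  expect_gt(scores["L1", "D1"], max(cross))
})

test_that("candidate ranking orders unknown pairs with stable ties", {
  scores <- matrix(c(0.9, 0.1, 0.5, 0.7, 0.3, 0.2), 2, 3,
                   dimnames = list(c("L1", "L2"), c("D1", "D2", "D3")))
  known <- association_table(matrix(c(1, 0, 0, 0, 0, 0), 2, 3,
                                    dimnames = dimnames(scores)))
  g <- rank_candidates(scores, known, scope = "global")
  expect_equal(g$rank, seq_len(5))
  expect_equal(g$score, sort(scores[known$matrix == 0], decreasing = TRUE))
  pd <- rank_candidates(scores, known, scope = "per-disease")
  expect_equal(pd$rank[pd$disease == "D2"], 1:2)
  expect_equal(pd$lncrna[pd$disease == "D2"][1], "L2")  # 0.7 > 0.5

  # full ties fall back to identifier order
  tied <- matrix(1, 2, 3, dimnames = dimnames(scores))
  gt <- rank_candidates(tied, known, scope = "global")
  expect_equal(gt$lncrna, c("L1", "L1", "L2", "L2", "L2"))

  # single unknown pair ranks first
  known1 <- association_table(matrix(c(1, 1, 1, 1, 1, 0), 2, 3,
                                     dimnames = dimnames(scores)))
  expect_equal(nrow(rank_candidates(scores, known1, "global")), 1L)
  expect_equal(rank_candidates(scores, known1, "global")$rank, 1L)
})
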