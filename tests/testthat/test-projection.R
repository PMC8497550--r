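sim_mat <- function(v, names) {
  similarity_matrix(named(v, names, names), kind = "integrated")
}

test_that("projections match hand-evaluated cases and identity limits", {
  psi <- score_matrix(named(diag(2), c("L1", "L2"), c("D1", "D2")),
                      stage = "reconstructed")
  ident_l <- sim_mat(diag(2), c("L1", "L2"))
  ident_d <- sim_mat(diag(2), c("D1", "D2"))
  expect_equal(lncrna_projection(ident_l, psi)$values, psi$values)
  expect_equal(disease_projection(ident_d, psi)$values, psi$values)

  ones_l <- sim_mat(matrix(1, 2, 2), c("L1", "L2"))
  ones_d <- sim_mat(matrix(1, 2, 2), c("D1", "D2"))
  expect_equal(unname(lncrna_projection(ones_l, psi)$values),
               matrix(1 / sqrt(2), 2, 2))
  expect_equal(unname(disease_projection(ones_d, psi)$values),
               matrix(1 / sqrt(2), 2, 2))

  # an isolated entity (all-zero similarity row) projects to zero
  iso <- sim_mat(rbind(c(1, 0), c(0, 0)), c("L1", "L2"))
  expect_equal(unname(lncrna_projection(iso, psi)$values[2, ]), c(0, 0))

  bad <- sim_mat(diag(2), c("X1", "X2"))
  expect_error(lncrna_projection(bad, psi), "do not match")
})

test_that("disease projection is the transpose of the lncRNA projection", {
  set.seed(41)
  for (rep in 1:5) {
    n <- sample(2:5, 1)
    s <- crossprod(random_binary_matrix(n + 1, n)) / (n + 1)
    diag(s) <- 1
    nm <- sprintf("E%d", seq_len(n))
    psi_v <- named(matrix(rnorm(n * n), n, n), nm, nm)
    dp <- disease_projection(sim_mat(s, nm),
                             score_matrix(psi_v, stage = "reconstructed"))
    lp_t <- lncrna_projection(sim_mat(s, nm),
                              score_matrix(t(psi_v), stage = "reconstructed"))
    expect_equal(dp$values, t(lp_t$values))
  }
})

test_that("fusion obeys the identity limit, endpoints and input checks", {
  nm_l <- c("L1", "L2", "L3"); nm_d <- c("D1", "D2")
  psi <- score_matrix(named(matrix(c(3, 1, 4, 1, 5, 9), 3, 2), nm_l, nm_d),
                      stage = "reconstructed")
  ident_l <- sim_mat(diag(3), nm_l)
  ident_d <- sim_mat(diag(2), nm_d)
  lp <- lncrna_projection(ident_l, psi)
  dp <- disease_projection(ident_d, psi)
  # with identity similarities the fusion is psi / 2 at every omega
  for (w in c(0, 0.3, 1)) {
    expect_equal(fuse_projections(lp, dp, ident_l, ident_d, omega = w)$values,
                 psi$values / 2)
  }
  expect_error(fuse_projections(lp, dp, ident_l, ident_d, omega = 1.2), "omega")
  expect_error(fuse_projections(lp, dp, ident_l, ident_d, omega = -0.1), "omega")
})

test_that("omega endpoints isolate one projection over the shared denominator", {
  set.seed(53)
  a_lm <- random_binary_matrix(5, 4, rn = sprintf("L%d", 1:5), cn = sprintf("M%d", 1:4))
  a_md <- random_binary_matrix(4, 3, rn = sprintf("M%d", 1:4), cn = sprintf("D%d", 1:3))
  tri <- make_triple(a_lm, a_md)
  ils <- integrated_similarity(tri$a_lm$adjacency)
  ids <- integrated_similarity(t(tri$a_md$adjacency))
  psi <- score_matrix(named(matrix(runif(15), 5, 3), rownames(a_lm),
                            colnames(a_md)), stage = "reconstructed")
  lp <- lncrna_projection(ils, psi)
  dp <- disease_projection(ids, psi)
  denom <- outer(sqrt(rowSums(ils$values^2)), sqrt(colSums(ids$values^2)), "+")
  expect_equal(fuse_projections(lp, dp, ils, ids, omega = 1)$values,
               lp$values / denom, ignore_attr = TRUE)
  expect_equal(fuse_projections(lp, dp, ils, ids, omega = 0)$values,
               dp$values / denom, ignore_attr = TRUE)
})

test_that("vectorized projections match the naive triple-loop oracle", {
  set.seed(59)
  for (rep in 1:20) {
    m <- sample(2:6, 1); n <- sample(2:6, 1); e <- sample(2:6, 1)
    a_lm <- random_binary_matrix(m, n, rn = sprintf("L%d", 1:m), cn = sprintf("M%d", 1:n))
    a_md <- random_binary_matrix(n, e, rn = sprintf("M%d", 1:n), cn = sprintf("D%d", 1:e))
    ils <- integrated_similarity(a_lm)
    ids <- integrated_similarity(t(a_md))
    psi_v <- named(matrix(runif(m * e, 0, 3), m, e), rownames(a_lm), colnames(a_md))
    psi <- score_matrix(psi_v, stage = "reconstructed")
    lp <- lncrna_projection(ils, psi)
    dp <- disease_projection(ids, psi)
    expect_equal(unname(lp$values), naive_lp(ils$values, psi_v), tolerance = 1e-12)
    expect_equal(unname(dp$values), naive_dp(ids$values, psi_v), tolerance = 1e-12)
    w <- runif(1)
    fused <- fuse_projections(lp, dp, ils, ids, omega = w)
    expect_equal(unname(fused$values),
                 naive_fuse(lp$values, dp$values, ils$values, ids$values, w),
                 tolerance = 1e-12)
    # single-normalization variant: raw projections through the same fusion
    ncp <- fuse_projections(lp, dp, ils, ids, omega = w, projection_style = "ncp")
    raw_lp <- ils$values %*% psi_v
    raw_dp <- psi_v %*% ids$values
    expect_equal(unname(ncp$values),
                 naive_fuse(raw_lp, raw_dp, ils$values, ids$values, w),
                 tolerance = 1e-12)
  }
})

test_that("fusion is homogeneous in the projections and entrywise bracketed", {
  set.seed(61)
  nm_l <- sprintf("L%d", 1:4); nm_d <- sprintf("D%d", 1:3)
  ils <- sim_mat({s <- crossprod(matrix(runif(16), 4)); s / max(s)}, nm_l)
  ids <- sim_mat({s <- crossprod(matrix(runif(9), 3)); s / max(s)}, nm_d)
  lp <- score_matrix(named(matrix(runif(12), 4, 3), nm_l, nm_d),
                     stage = "lncrna_projection")
  dp <- score_matrix(named(matrix(runif(12), 4, 3), nm_l, nm_d),
                     stage = "disease_projection")
  f1 <- fuse_projections(lp, dp, ils, ids, omega = 0.4)$values
  lp3 <- score_matrix(lp$values * 3, stage = "lncrna_projection")
  dp3 <- score_matrix(dp$values * 3, stage = "disease_projection")
  expect_equal(fuse_projections(lp3, dp3, ils, ids, omega = 0.4)$values, 3 * f1)

  denom <- outer(sqrt(rowSums(ils$values^2)), sqrt(colSums(ids$values^2)), "+")
  lo <- pmin(lp$values, dp$values) / denom
  hi <- pmax(lp$values, dp$values) / denom
  for (w in seq(0, 1, 0.25)) {
    fw <- fuse_projections(lp, dp, ils, ids, omega = w)$values
    expect_true(all(fw >= lo - 1e-12 & fw <= hi + 1e-12))
  }
})

test_that("ranked_pairs sorts descending with name-order tie-breaks", {
  sm <- score_matrix(named(rbind(c(0.5, 0.9), c(0.5, 0.1)),
                           c("La", "Lb"), c("D1", "D2")), stage = "final")
  rp <- ranked_pairs(sm)
  expect_equal(rp$score, c(0.9, 0.5, 0.5, 0.1))
  expect_equal(rp$lncrna[2:3], c("La", "Lb"))
})
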