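# Preliminary score matrix A_LD = A_LM %*% A_MD and its densification by a
# K-dimensional latent factor model fitted with regularized full-batch
# gradient descent.

#' Preliminary lncRNA-disease scores
#'
#' `A_LD = A_LM %*% A_MD`: entry (i, j) counts the miRNAs associated with
#' both lncRNA i and disease j (length-2 paths through the shared axis).
#'
#' @param triple an `aligned_triple` from [align_on_mirna()] (or any list
#'   with `a_lm` and `a_md` bipartite networks sharing the miRNA axis).
#' @return A [score_matrix] at stage `"preliminary"`.
#' @export
preliminary_scores <- function(triple) {
  a_lm <- triple$a_lm$adjacency
  a_md <- triple$a_md$adjacency
  check_same_names(colnames(a_lm), rownames(a_md), "miRNA axis")
  score_matrix(a_lm %*% a_md, stage = "preliminary")
}

lfm_loss <- function(target, X, Y, lambda) {
  resid <- target - X %*% Y
  sum(resid^2) + lambda * (sum(X^2) + sum(Y^2))
}

#' Fit the latent factor model
#'
#' Approximates the preliminary score matrix `A` (m x e) by `psi = X %*% Y`
#' with `X` (m x K) and `Y` (K x e), minimizing the squared reconstruction
#' error over ALL m x e entries plus L2 penalties on both factors:
#' `L = sum_ij (A_ij - X_i' Y_j)^2 + lambda (||X||_F^2 + ||Y||_F^2)`.
#' Both factors are updated simultaneously each iteration by full-batch
#' gradient descent, `X <- X - alpha * (2 (XY - A) Y' + 2 lambda X)` and
#' symmetrically for `Y`.
#'
#' Factors are initialized uniformly on `[0, 1/sqrt(K))` from the seeded
#' generator, a non-negative start whose initial reconstruction entries are
#' O(1) for a non-negative count target.  Training stops at `max_iters` or
#' when the relative loss change drops below `tol`.
#'
#' @param target a [score_matrix] (stage `"preliminary"`) or plain named
#'   matrix to factorize.
#' @param k_dim latent dimension K (default 50).
#' @param alpha learning rate (default 2e-4).
#' @param lambda L2 regularization weight (default 4e-3).
#' @param max_iters iteration cap (default 5000).
#' @param tol relative loss-change stopping tolerance (default 1e-6).
#' @param seed integer seed for the factor initialization.
#' @return An object of class `latent_factor_model`: factors `X`, `Y`, the
#'   hyperparameters, the per-iteration `loss_trace` (element 1 is the loss
#'   at initialization), `iterations` actually run and a `converged` flag.
#' @export
lfm_fit <- function(target, k_dim = 50, alpha = 2e-4, lambda = 4e-3,
                    max_iters = 5000, tol = 1e-6, seed = 1L) {
  A <- if (inherits(target, "score_matrix")) target$values else as.matrix(target)
  if (is.null(rownames(A))) rownames(A) <- paste0("L", seq_len(nrow(A)))
  if (is.null(colnames(A))) colnames(A) <- paste0("D", seq_len(ncol(A)))
  m <- nrow(A)
  e <- ncol(A)
  stopifnot(k_dim >= 1, alpha > 0, lambda >= 0, max_iters >= 1)
  if (k_dim >= min(m, e)) {
    warning(sprintf("k_dim = %d is not below min(m, e) = %d; the factorization is not low-rank",
                    k_dim, min(m, e)))
  }
  init <- with_rng(seed, {
    list(X = matrix(stats::runif(m * k_dim, 0, 1 / sqrt(k_dim)), m, k_dim),
         Y = matrix(stats::runif(k_dim * e, 0, 1 / sqrt(k_dim)), k_dim, e))
  })
  X <- init$X
  Y <- init$Y
  loss <- numeric(max_iters + 1)
  loss[1] <- lfm_loss(A, X, Y, lambda)
  eps <- .Machine$double.eps
  iters <- 0L
  converged <- FALSE
  for (t in seq_len(max_iters)) {
    resid <- X %*% Y - A
    grad_x <- 2 * (resid %*% t(Y)) + 2 * lambda * X
    grad_y <- 2 * (t(X) %*% resid) + 2 * lambda * Y
    X <- X - alpha * grad_x
    Y <- Y - alpha * grad_y
    l <- lfm_loss(A, X, Y, lambda)
    if (!is.finite(l)) {
      stop(sprintf("loss diverged at iteration %d; decrease alpha (current %g)", t, alpha))
    }
    loss[t + 1] <- l
    iters <- t
    if (abs(l - loss[t]) / max(loss[t], eps) < tol) {
      converged <- TRUE
      break
    }
  }
  dimnames(X) <- NULL  # names travel on the model, not the factors
  dimnames(Y) <- NULL
  structure(list(X = X, Y = Y, k_dim = k_dim, alpha = alpha, lambda = lambda,
                 max_iters = max_iters, tol = tol, seed = seed,
                 loss_trace = loss[seq_len(iters + 1)], iterations = iters,
                 converged = converged,
                 lncrna_names = rownames(A), disease_names = colnames(A)),
            class = "latent_factor_model")
}

#' @export
print.latent_factor_model <- function(x, ...) {
  cat(sprintf("latent_factor_model: %d x %d, K = %d, %d iterations (%s), final loss %.6g\n",
              nrow(x$X), ncol(x$Y), x$k_dim, x$iterations,
              if (x$converged) "converged" else "iteration cap",
              x$loss_trace[length(x$loss_trace)]))
  invisible(x)
}

#' Reconstruct the densified score matrix
#'
#' `psi = X %*% Y`; larger entries mean stronger predicted association, so
#' scores are always interpreted descending.
#'
#' @param model a fitted `latent_factor_model`.
#' @return A [score_matrix] at stage `"reconstructed"`.
#' @export
lfm_reconstruct <- function(model) {
  stopifnot(inherits(model, "latent_factor_model"))
  psi <- model$X %*% model$Y
  dimnames(psi) <- list(model$lncrna_names, model$disease_names)
  score_matrix(psi, stage = "reconstructed")
}

#' Serialize a fitted model to a JSON bundle
#'
#' @param model `latent_factor_model`.
#' @param path output path.
#' @export
lfm_save <- function(model, path) {
  stopifnot(inherits(model, "latent_factor_model"))
  jsonlite::write_json(
    list(X = model$X, Y = model$Y, k_dim = model$k_dim, alpha = model$alpha,
         lambda = model$lambda, max_iters = model$max_iters, tol = model$tol,
         seed = model$seed, loss_trace = model$loss_trace,
         iterations = model$iterations, converged = model$converged,
         lncrna_names = model$lncrna_names, disease_names = model$disease_names),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Restore a model saved by [lfm_save()]
#'
#' @param path path to the JSON bundle.
#' @return `latent_factor_model`.
#' @export
lfm_load <- function(path) {
  b <- jsonlite::read_json(path, simplifyVector = TRUE)
  b$X <- as.matrix(b$X)
  b$Y <- as.matrix(b$Y)
  structure(b, class = "latent_factor_model")
}
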