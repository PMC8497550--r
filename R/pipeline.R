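# End-to-end orchestration: edge lists -> aligned networks -> similarities
# -> latent factor densification -> projection fusion -> ranked predictions,
# with a reproducibility manifest and an omega sweep.

#' Pipeline configuration
#'
#' Collects every tunable of the pipeline with the published defaults:
#' learning rate `alpha = 2e-4`, regularization `lambda = 4e-3` and fusion
#' weight `omega = 0.3`.
#'
#' @param lncrna_mirna,mirna_disease paths to the two input edge lists.
#' @param labels optional path to a lncRNA-disease edge list used ONLY as
#'   evaluation labels, never as model input.
#' @param k_dim,alpha,lambda,max_iters,tol,seed latent factor model
#'   hyperparameters, see [lfm_fit()].
#' @param omega fusion weight, see [fuse_projections()].
#' @param projection_style `"paper"` or `"ncp"`, see [fuse_projections()].
#' @param evaluation `"loocv"` or `"kfold"`.
#' @param folds fold count when `evaluation = "kfold"`.
#' @param normalize normalize identifiers while parsing, see
#'   [read_edge_list()].
#' @param align miRNA axis reconciliation mode, see [align_on_mirna()].
#' @param out_dir optional output directory for matrices, rankings and the
#'   run manifest.
#' @return A list of class `lfmp_config`.
#' @export
lfmp_config <- function(lncrna_mirna = NULL, mirna_disease = NULL,
                        labels = NULL, k_dim = 50, alpha = 2e-4,
                        lambda = 4e-3, max_iters = 5000, tol = 1e-6,
                        seed = 1L, omega = 0.3,
                        projection_style = c("paper", "ncp"),
                        evaluation = c("loocv", "kfold"), folds = 5,
                        normalize = FALSE,
                        align = c("intersection", "union"), out_dir = NULL) {
  cfg <- list(lncrna_mirna = lncrna_mirna, mirna_disease = mirna_disease,
              labels = labels, k_dim = k_dim, alpha = alpha, lambda = lambda,
              max_iters = max_iters, tol = tol, seed = as.integer(seed),
              omega = omega, projection_style = match.arg(projection_style),
              evaluation = match.arg(evaluation), folds = folds,
              normalize = normalize, align = match.arg(align),
              out_dir = out_dir)
  if (cfg$omega < 0 || cfg$omega > 1) stop("omega must lie in [0, 1]")
  structure(cfg, class = "lfmp_config")
}

#' Run the prediction pipeline on an aligned triple
#'
#' The in-memory core of [lfmp_predict()]: integrated similarities from the
#' two layers, preliminary scores `A_LD`, latent factor densification,
#' similarity-space projections and omega fusion.
#'
#' @param triple an `aligned_triple` ([align_on_mirna()] or
#'   [generate_network()]`$triple`).
#' @param cfg an [lfmp_config()] (paths ignored).
#' @return A list with the fitted `model` and score matrices `a_ld`, `psi`,
#'   `lp`, `dp`, `scores` (final), plus `ils`, `ids`.
#' @export
lfmp_run <- function(triple, cfg = lfmp_config()) {
  ils <- integrated_similarity(triple$a_lm$adjacency)
  ids <- integrated_similarity(t(triple$a_md$adjacency))
  a_ld <- preliminary_scores(triple)
  model <- lfm_fit(a_ld, k_dim = cfg$k_dim, alpha = cfg$alpha,
                   lambda = cfg$lambda, max_iters = cfg$max_iters,
                   tol = cfg$tol, seed = cfg$seed)
  psi <- lfm_reconstruct(model)
  lp <- lncrna_projection(ils, psi)
  dp <- disease_projection(ids, psi)
  scores <- fuse_projections(lp, dp, ils, ids, omega = cfg$omega,
                             projection_style = cfg$projection_style)
  list(model = model, a_ld = a_ld, psi = psi, lp = lp, dp = dp,
       scores = scores, ils = ils, ids = ids)
}

#' Predict lncRNA-disease associations from edge-list files
#'
#' Runs parsing, alignment, similarity, latent factor fitting, projection
#' and fusion; optionally writes the psi/LP/DP/final matrices, the ranked
#' pair list and a run manifest (all parameters, seed, input checksums) to
#' `cfg$out_dir`.  On error, partial outputs are removed.
#'
#' @param cfg an [lfmp_config()] with input paths set.
#' @return The [lfmp_run()] result list, plus `triple`, `ranked` and
#'   `manifest`.
#' @export
lfmp_predict <- function(cfg) {
  stopifnot(inherits(cfg, "lfmp_config"))
  if (is.null(cfg$lncrna_mirna) || is.null(cfg$mirna_disease)) {
    stop("lncrna_mirna and mirna_disease input paths are required")
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE)
    })
  }
  lm_net <- stage("data_io", build_network(
    read_edge_list(cfg$lncrna_mirna, normalize = cfg$normalize,
                   row_case = "upper", col_case = "upper")))
  md_net <- stage("data_io", build_network(
    read_edge_list(cfg$mirna_disease, normalize = cfg$normalize,
                   row_case = "upper", col_case = "lower")))
  triple <- stage("data_io", align_on_mirna(lm_net, md_net, mode = cfg$align))
  res <- stage("pipeline", lfmp_run(triple, cfg))
  res$triple <- triple
  res$ranked <- ranked_pairs(res$scores)
  res$manifest <- list(
    package_version = as.character(utils::packageVersion("lfmp")),
    parameters = cfg[c("k_dim", "alpha", "lambda", "max_iters", "tol",
                       "seed", "omega", "projection_style", "normalize",
                       "align")],
    inputs = list(
      lncrna_mirna = list(path = cfg$lncrna_mirna,
                          md5 = unname(tools::md5sum(cfg$lncrna_mirna))),
      mirna_disease = list(path = cfg$mirna_disease,
                           md5 = unname(tools::md5sum(cfg$mirna_disease)))),
    dimensions = list(lncrnas = nrow(triple$a_lm$adjacency),
                      mirnas = length(triple$mirnas),
                      diseases = ncol(triple$a_md$adjacency)))
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    written <- character(0)
    tryCatch({
      out <- function(f) file.path(cfg$out_dir, f)
      for (nm in c("psi", "lp", "dp")) {
        written <- c(written, out(paste0(nm, ".tsv")))
        write_matrix(res[[nm]], out(paste0(nm, ".tsv")))
      }
      written <- c(written, out("lfmp_scores.tsv"))
      write_matrix(res$scores, out("lfmp_scores.tsv"))
      written <- c(written, out("ranked_pairs.tsv"))
      utils::write.table(res$ranked, out("ranked_pairs.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      written <- c(written, out("manifest.json"))
      jsonlite::write_json(res$manifest, out("manifest.json"),
                           auto_unbox = TRUE, digits = NA)
    }, error = function(e) {
      unlink(written)
      stop(sprintf("[output] %s", conditionMessage(e)), call. = FALSE)
    })
  }
  res
}

#' Evaluate pipeline scores against labels
#'
#' @param scores final [score_matrix] (or an [lfmp_predict()] result list).
#' @param labels [bipartite_network] of known lncRNA-disease associations,
#'   or a path to their edge list.
#' @param cfg an [lfmp_config()] supplying the evaluation mode, folds and
#'   seed.
#' @return An `evaluation_result`.
#' @export
lfmp_evaluate <- function(scores, labels, cfg = lfmp_config()) {
  if (is.list(scores) && !inherits(scores, "score_matrix")) scores <- scores$scores
  if (is.character(labels)) {
    labels <- build_network(read_edge_list(labels, normalize = cfg$normalize,
                                           row_case = "upper",
                                           col_case = "lower"))
  }
  if (cfg$evaluation == "loocv") {
    loocv_auc(scores, labels)
  } else {
    kfold_auc(scores, labels, k = cfg$folds, seed = cfg$seed)
  }
}

#' Sweep the fusion weight omega
#'
#' Computes psi, LP and DP once and re-fuses per grid point, reporting the
#' LOOCV AUC at each omega.  The default grid is 0.0 to 1.0 in steps of 0.1.
#'
#' @param run an [lfmp_run()] / [lfmp_predict()] result list.
#' @param labels [bipartite_network] of evaluation labels.
#' @param grid numeric vector of omega values in [0, 1].
#' @param projection_style passed to [fuse_projections()].
#' @return `data.frame` with columns `omega` and `auc`.
#' @export
lfmp_sweep_omega <- function(run, labels, grid = seq(0, 1, by = 0.1),
                             projection_style = "paper") {
  if (length(grid) == 0) stop("empty omega grid")
  auc <- vapply(grid, function(w) {
    sc <- fuse_projections(run$lp, run$dp, run$ils, run$ids, omega = w,
                           projection_style = projection_style)
    loocv_auc(sc, labels)$auc
  }, numeric(1))
  data.frame(omega = grid, auc = auc)
}
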