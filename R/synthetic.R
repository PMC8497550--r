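# Planted partition tripartite network generator: module-structured
# lncRNA-miRNA and miRNA-disease layers whose implied lncRNA-disease truth
# (same-module pairs) is exactly the shared-miRNA-neighbourhood signal the
# predictor exploits.

#' Configuration for the tripartite network simulator
#'
#' @param m,n,e numbers of lncRNAs, miRNAs and diseases.
#' @param g number of planted modules; every entity is assigned one module
#'   uniformly at random.
#' @param p_in,p_out within- and between-module edge probabilities for both
#'   bipartite layers; `p_out < p_in` is required so signal exists (equality
#'   is allowed only to simulate the null model explicitly).
#' @param q probability that a same-module lncRNA-disease pair is a planted
#'   positive.
#' @param seed integer seed; a fixed seed makes [generate_network()]
#'   bit-reproducible.
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(m = 60, n = 30, e = 40, g = 3,
                             p_in = 0.6, p_out = 0.05, q = 0.5, seed = 1L) {
  probs <- c(p_in = p_in, p_out = p_out, q = q)
  if (any(probs < 0) || any(probs > 1)) stop("probabilities must lie in [0, 1]")
  if (p_out > p_in) stop("p_out must not exceed p_in")
  if (g < 1) stop("g must be >= 1")
  if (min(m, n, e) < g) stop("entity counts must be >= g")
  structure(list(m = m, n = n, e = e, g = g, p_in = p_in, p_out = p_out,
                 q = q, seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Generate a module-structured tripartite network with planted truth
#'
#' Each lncRNA, miRNA and disease is assigned a module uniformly at random;
#' lncRNA-miRNA and miRNA-disease edges are drawn independently with
#' probability `p_in` for same-module pairs and `p_out` otherwise; planted
#' lncRNA-disease positives are drawn among same-module pairs with
#' probability `q`.  The truth network is returned on the full lncRNA and
#' disease axes (absent pairs are unlabeled) and is for evaluation only —
#' the predictor never sees it.
#'
#' @param cfg a [synthetic_config].
#' @return A list with fields `triple` (an `aligned_triple` of the two
#'   layers on a shared miRNA axis), `truth` (a [bipartite_network] of
#'   planted positives), `modules` (the module assignment of each entity)
#'   and `config`.
#' @export
generate_network <- function(cfg = synthetic_config()) {
  stopifnot(inherits(cfg, "synthetic_config"))
  with_rng(cfg$seed, {
    lnc <- sprintf("LNC%03d", seq_len(cfg$m))
    mir <- sprintf("MIR%03d", seq_len(cfg$n))
    dis <- sprintf("DIS%03d", seq_len(cfg$e))
    mod_l <- sample.int(cfg$g, cfg$m, replace = TRUE)
    mod_m <- sample.int(cfg$g, cfg$n, replace = TRUE)
    mod_d <- sample.int(cfg$g, cfg$e, replace = TRUE)
    draw_layer <- function(mod_row, mod_col, rn, cn) {
      same <- outer(mod_row, mod_col, "==")
      p <- ifelse(same, cfg$p_in, cfg$p_out)
      adj <- matrix(as.numeric(stats::runif(length(p)) < p), nrow(p),
                    dimnames = list(rn, cn))
      adj
    }
    a_lm <- draw_layer(mod_l, mod_m, lnc, mir)
    a_md <- draw_layer(mod_m, mod_d, mir, dis)
    same_ld <- outer(mod_l, mod_d, "==")
    truth <- matrix(0, cfg$m, cfg$e, dimnames = list(lnc, dis))
    truth[same_ld] <- as.numeric(stats::runif(sum(same_ld)) < cfg$q)
    triple <- structure(list(a_lm = bipartite_network(a_lm),
                             a_md = bipartite_network(a_md),
                             mirnas = mir),
                        class = "aligned_triple")
    list(triple = triple, truth = bipartite_network(truth),
         modules = list(lncrna = stats::setNames(mod_l, lnc),
                        mirna = stats::setNames(mod_m, mir),
                        disease = stats::setNames(mod_d, dis)),
         config = cfg)
  })
}

#' Write a simulated network to edge-list files
#'
#' Emits the same file format [read_edge_list()] consumes: three edge lists
#' (lncRNA-miRNA, miRNA-disease, planted truth) plus the configuration as
#' JSON, into `dir`.
#'
#' @param sim output of [generate_network()].
#' @param dir output directory (created if needed).
#' @return Named character vector of the four file paths, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(lncrna_mirna = file.path(dir, "lncrna_mirna.tsv"),
             mirna_disease = file.path(dir, "mirna_disease.tsv"),
             truth = file.path(dir, "lncrna_disease_truth.tsv"),
             config = file.path(dir, "config.json"))
  write_edge_list(sim$triple$a_lm, paths[["lncrna_mirna"]])
  write_edge_list(sim$triple$a_md, paths[["mirna_disease"]])
  write_edge_list(sim$truth, paths[["truth"]])
  jsonlite::write_json(unclass(sim$config), paths[["config"]],
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
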