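# Network consistency projection of the densified score matrix through the
# integrated lncRNA and disease similarity spaces, and the omega-weighted
# fusion of the two projections.

row_norms <- function(x) sqrt(rowSums(x^2))

#' Project scores through the lncRNA similarity space
#'
#' Row i of the projection is the similarity-weighted sum of all score rows
#' (the self term j = i included) divided by the Euclidean norm of
#' similarity row i: `LP(i, ) = sum_j ILS(i, j) * psi(j, ) / ||ILS(i, )||`.
#' Entities with an all-zero similarity row get an all-zero projection row.
#'
#' @param ils integrated lncRNA [similarity_matrix].
#' @param psi [score_matrix] with the same lncRNA axis on its rows.
#' @return A [score_matrix] at stage `"lncrna_projection"`.
#' @export
lncrna_projection <- function(ils, psi) {
  stopifnot(inherits(ils, "similarity_matrix"), inherits(psi, "score_matrix"))
  check_same_names(rownames(ils$values), rownames(psi$values), "lncRNA")
  s <- ils$values
  nrm <- row_norms(s)
  lp <- s %*% psi$values
  scale <- ifelse(nrm > 0, 1 / nrm, 0)
  score_matrix(lp * scale, stage = "lncrna_projection")
}

#' Project scores through the disease similarity space
#'
#' Column j of the projection is the similarity-weighted sum of all score
#' columns divided by the Euclidean norm of similarity column j:
#' `DP(, j) = sum_i IDS(i, j) * psi(, i) / ||IDS(, j)||`.  All-zero
#' similarity columns give all-zero projection columns.  Structurally,
#' `disease_projection(S, psi)` equals `t(lncrna_projection(S, t(psi)))`.
#'
#' @param ids integrated disease [similarity_matrix].
#' @param psi [score_matrix] with the same disease axis on its columns.
#' @return A [score_matrix] at stage `"disease_projection"`.
#' @export
disease_projection <- function(ids, psi) {
  stopifnot(inherits(ids, "similarity_matrix"), inherits(psi, "score_matrix"))
  check_same_names(rownames(ids$values), colnames(psi$values), "disease")
  s <- ids$values
  nrm <- sqrt(colSums(s^2))
  dp <- psi$values %*% s
  scale <- ifelse(nrm > 0, 1 / nrm, 0)
  score_matrix(sweep(dp, 2, scale, "*"), stage = "disease_projection")
}

#' Fuse the two projections into final association scores
#'
#' With the default `projection_style = "paper"` the printed formula is
#' applied literally: the already norm-divided projections are combined as
#' `(omega * LP + (1 - omega) * DP) / (||ILS(i, )|| + ||IDS(, j)||)` — a
#' double normalization.  `projection_style = "ncp"` gives the classical
#' network-consistency-projection variant that normalizes once: the raw
#' (un-divided) projections enter the same formula.  Entries whose two
#' similarity norms are both zero are set to 0.
#'
#' @param lp,dp [score_matrix] projections from [lncrna_projection()] and
#'   [disease_projection()].
#' @param ils,ids the integrated similarity matrices used to build them.
#' @param omega fusion weight in [0, 1] for the lncRNA projection share
#'   (default 0.3, the sweep optimum).
#' @param projection_style `"paper"` (default) or `"ncp"`.
#' @return A [score_matrix] at stage `"final"`.
#' @export
fuse_projections <- function(lp, dp, ils, ids, omega = 0.3,
                             projection_style = c("paper", "ncp")) {
  projection_style <- match.arg(projection_style)
  stopifnot(inherits(lp, "score_matrix"), inherits(dp, "score_matrix"))
  if (!is.numeric(omega) || length(omega) != 1 || omega < 0 || omega > 1) {
    stop("omega must be a single value in [0, 1]")
  }
  check_same_names(rownames(lp$values), rownames(dp$values), "lncRNA")
  check_same_names(colnames(lp$values), colnames(dp$values), "disease")
  check_same_names(rownames(ils$values), rownames(lp$values), "lncRNA")
  check_same_names(rownames(ids$values), colnames(lp$values), "disease")
  l_norm <- row_norms(ils$values)
  d_norm <- sqrt(colSums(ids$values^2))
  lpv <- lp$values
  dpv <- dp$values
  if (projection_style == "ncp") {
    # undo the per-projection normalization so the norm sum divides raw sums
    lpv <- lpv * l_norm
    dpv <- sweep(dpv, 2, d_norm, "*")
  }
  denom <- outer(l_norm, d_norm, "+")
  num <- omega * lpv + (1 - omega) * dpv
  score_matrix(ifelse(denom > 0, num / denom, 0), stage = "final")
}

#' Ranked association list
#'
#' Flattens a score matrix into a three-column table (lncRNA, disease,
#' score), descending by score with deterministic name-order tie-breaks.
#'
#' @param scores [score_matrix].
#' @return `data.frame` with columns `lncrna`, `disease`, `score`.
#' @export
ranked_pairs <- function(scores) {
  stopifnot(inherits(scores, "score_matrix"))
  v <- scores$values
  df <- data.frame(lncrna = rep(rownames(v), times = ncol(v)),
                   disease = rep(colnames(v), each = nrow(v)),
                   score = as.vector(v), stringsAsFactors = FALSE)
  df[order(-df$score, df$lncrna, df$disease), , drop = FALSE]
}
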