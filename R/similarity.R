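# Cosine and Jaccard similarity over binary association profiles, and their
# integration: the average where cosine is non-zero, Jaccard otherwise.
#
# Profiles come in as the rows of a matrix (one row per entity).  For
# lncRNAs that is A_LM itself; for diseases it is t(A_MD) (one row per
# disease, its miRNA association profile).

check_profiles <- function(profiles) {
  profiles <- as.matrix(profiles)
  if (ncol(profiles) < 1) stop("profiles must have length >= 1")
  if (is.null(rownames(profiles))) {
    rownames(profiles) <- paste0("e", seq_len(nrow(profiles)))
  }
  profiles
}

#' Cosine similarity between binary entity profiles
#'
#' `values[i, j] = <p_i, p_j> / (||p_i|| ||p_j||)`; if either profile has
#' zero norm the similarity is 0, including on the diagonal, so isolated
#' entities contribute nothing downstream.
#'
#' @param profiles numeric matrix, one row per entity (binary association
#'   profile), with row names.
#' @return A [similarity_matrix] of kind `"cosine"`.
#' @export
cosine_similarity <- function(profiles) {
  p <- check_profiles(profiles)
  dots <- tcrossprod(p)
  norms <- sqrt(diag(dots))
  denom <- outer(norms, norms)
  vals <- ifelse(denom > 0, dots / denom, 0)
  # guard against fp drift outside [0,1] for identical rows
  vals[vals > 1] <- 1
  dimnames(vals) <- list(rownames(p), rownames(p))
  similarity_matrix(vals, kind = "cosine")
}

#' Jaccard similarity between binary entity profiles
#'
#' `values[i, j] = |support_i & support_j| / |support_i | support_j|`, with
#' the 0/0 case (two empty profiles) defined as 0.
#'
#' @inheritParams cosine_similarity
#' @return A [similarity_matrix] of kind `"jaccard"`.
#' @export
jaccard_similarity <- function(profiles) {
  p <- check_profiles(profiles)
  if (!all(p %in% c(0, 1))) stop("Jaccard similarity requires binary profiles")
  inter <- tcrossprod(p)
  sizes <- diag(inter)
  un <- outer(sizes, sizes, "+") - inter
  vals <- ifelse(un > 0, inter / un, 0)
  dimnames(vals) <- list(rownames(p), rownames(p))
  similarity_matrix(vals, kind = "jaccard")
}

#' Integrate cosine and Jaccard similarity
#'
#' Entrywise: `(cos + jac) / 2` where the cosine entry is non-zero, else the
#' Jaccard entry.  On binary profiles the two kernels vanish together
#' (disjoint supports), so the fallback branch only ever returns 0; it is
#' implemented literally anyway so non-binary profiles behave as documented.
#'
#' @param cos,jac [similarity_matrix] objects over the same entity list,
#'   computed from the same profiles.
#' @return A [similarity_matrix] of kind `"integrated"`.
#' @export
integrate_similarity <- function(cos, jac) {
  stopifnot(inherits(cos, "similarity_matrix"), inherits(jac, "similarity_matrix"))
  check_same_names(rownames(cos$values), rownames(jac$values), "entity")
  vals <- ifelse(cos$values != 0, (cos$values + jac$values) / 2, jac$values)
  similarity_matrix(vals, kind = "integrated")
}

#' Integrated similarity in one call
#'
#' Convenience wrapper: cosine + Jaccard + integration over one profile
#' matrix.
#'
#' @inheritParams cosine_similarity
#' @return A [similarity_matrix] of kind `"integrated"`.
#' @export
integrated_similarity <- function(profiles) {
  integrate_similarity(cosine_similarity(profiles), jaccard_similarity(profiles))
}
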