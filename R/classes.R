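# Evaluate `expr` under a fixed seed without disturbing the caller's RNG stream.
with_rng <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  expr
}

#' Bipartite association network
#'
#' A binary adjacency matrix over two ordered, named entity axes.  This is the
#' universal carrier for lncRNA-miRNA networks, miRNA-disease networks and
#' lncRNA-disease evaluation labels.
#'
#' @param adjacency numeric matrix with entries in \{0, 1\}.
#' @param row_names,col_names character vectors of unique entity identifiers;
#'   taken from `dimnames(adjacency)` when omitted.
#' @return An object of class `bipartite_network` with fields `adjacency`
#'   (a named binary matrix), and accessors via `dimnames`.
#' @export
bipartite_network <- function(adjacency, row_names = NULL, col_names = NULL) {
  adjacency <- as.matrix(adjacency)
  if (!is.null(row_names)) rownames(adjacency) <- row_names
  if (!is.null(col_names)) colnames(adjacency) <- col_names
  if (is.null(rownames(adjacency)) || is.null(colnames(adjacency))) {
    stop("bipartite_network requires row and column names")
  }
  if (anyDuplicated(rownames(adjacency)) || anyDuplicated(colnames(adjacency))) {
    stop("entity names must be unique on each axis")
  }
  if (!all(adjacency %in% c(0, 1))) {
    stop("adjacency entries must be binary (0/1)")
  }
  storage.mode(adjacency) <- "double"
  structure(list(adjacency = adjacency), class = "bipartite_network")
}

#' @export
print.bipartite_network <- function(x, ...) {
  a <- x$adjacency
  cat(sprintf("bipartite_network: %d x %d, %d associations\n",
              nrow(a), ncol(a), sum(a)))
  invisible(x)
}

#' @export
summary.bipartite_network <- function(object, ...) {
  a <- object$adjacency
  out <- list(n_row = nrow(a), n_col = ncol(a), n_edges = as.integer(sum(a)),
              density = mean(a))
  class(out) <- "summary.bipartite_network"
  out
}

#' @export
print.summary.bipartite_network <- function(x, ...) {
  cat(sprintf("rows: %d  cols: %d  edges: %d  density: %.4f\n",
              x$n_row, x$n_col, x$n_edges, x$density))
  invisible(x)
}

#' Square similarity matrix over one entity axis
#'
#' @param values square numeric matrix with entries in [0, 1], symmetric.
#' @param names entity identifiers; taken from dimnames when omitted.
#' @param kind one of `"cosine"`, `"jaccard"`, `"integrated"`.
#' @return An object of class `similarity_matrix`.
#' @export
similarity_matrix <- function(values, names = NULL,
                              kind = c("cosine", "jaccard", "integrated")) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  if (!is.null(names)) dimnames(values) <- list(names, names)
  if (nrow(values) != ncol(values)) stop("similarity matrix must be square")
  if (is.null(rownames(values))) stop("similarity matrix requires entity names")
  if (max(abs(values - t(values))) > 1e-10) stop("similarity matrix must be symmetric")
  if (min(values) < -1e-12 || max(values) > 1 + 1e-12) {
    stop("similarity values must lie in [0, 1]")
  }
  structure(list(values = values, kind = kind), class = "similarity_matrix")
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf("similarity_matrix (%s): %d entities\n", x$kind, nrow(x$values)))
  invisible(x)
}

#' lncRNA x disease score matrix
#'
#' Carries every real-valued lncRNA-by-disease matrix in the pipeline: the
#' preliminary common-neighbour counts A_LD, the latent-factor reconstruction
#' psi, the two similarity-space projections, and the final fused scores.
#'
#' @param values numeric matrix (lncRNA rows, disease columns) with dimnames.
#' @param stage one of `"preliminary"`, `"reconstructed"`, `"lncrna_projection"`,
#'   `"disease_projection"`, `"final"`.
#' @return An object of class `score_matrix`.
#' @export
score_matrix <- function(values,
                         stage = c("preliminary", "reconstructed",
                                   "lncrna_projection", "disease_projection",
                                   "final")) {
  stage <- match.arg(stage)
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("score_matrix requires lncRNA and disease names as dimnames")
  }
  if (stage == "preliminary" &&
      (any(values < 0) || max(abs(values - round(values))) > 1e-9)) {
    stop("preliminary scores must be non-negative integer counts")
  }
  structure(list(values = values, stage = stage), class = "score_matrix")
}

#' @export
print.score_matrix <- function(x, ...) {
  cat(sprintf("score_matrix (%s): %d lncRNAs x %d diseases\n",
              x$stage, nrow(x$values), ncol(x$values)))
  invisible(x)
}

# Shared axis check used across modules.
check_same_names <- function(a, b, what) {
  if (length(a) != length(b) || !all(a == b)) {
    stop(sprintf("%s name lists do not match", what))
  }
  invisible(TRUE)
}
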