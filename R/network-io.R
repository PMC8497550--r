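# Edge-list parsing, adjacency construction and miRNA-axis alignment.

detect_delimiter <- function(lines) {
  cand <- c("\t", ",", ";")
  counts <- vapply(cand, function(d) {
    sum(lengths(strsplit(lines, d, fixed = TRUE)) >= 2)
  }, numeric(1))
  if (max(counts) == 0) stop("could not detect a delimiter (tab/comma/semicolon)")
  cand[which.max(counts)]
}

normalize_id <- function(x, case = c("none", "upper", "lower")) {
  case <- match.arg(case)
  x <- gsub("\\s+", " ", trimws(x))
  switch(case, none = x, upper = toupper(x), lower = tolower(x))
}

#' Read a two-column association edge list
#'
#' Parses a delimited text file of entity pairs (e.g. lncRNA-miRNA or
#' miRNA-disease associations), optionally normalizing identifiers, and
#' returns deduplicated pairs in order of first appearance.
#'
#' A header line is auto-detected: if neither field of line 1 reappears as an
#' identifier in the body, line 1 is treated as a header and dropped.  The
#' delimiter is auto-detected among tab, comma and semicolon unless given.
#'
#' @param path path to the edge-list file.
#' @param delimiter field separator; `NULL` (default) auto-detects.
#' @param normalize if `TRUE`, identifiers are trimmed, internal whitespace
#'   runs collapsed, and case-folded (`row_case` applied to column 1,
#'   `col_case` to column 2) before deduplication.  RNA symbols are
#'   conventionally upper-cased and disease terms lower-cased.
#' @param row_case,col_case case folding per column when `normalize = TRUE`:
#'   `"upper"`, `"lower"` or `"none"`.
#' @param header `TRUE`, `FALSE`, or `NA` (default) to auto-detect.
#' @return A two-column character `data.frame` with columns `from` and `to`,
#'   one row per distinct pair.
#' @export
read_edge_list <- function(path, delimiter = NULL, normalize = FALSE,
                           row_case = "upper", col_case = "lower",
                           header = NA) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop(sprintf("empty edge list: %s", path))
  if (is.null(delimiter)) delimiter <- detect_delimiter(lines)
  fields <- strsplit(lines, delimiter, fixed = TRUE)
  bad <- which(lengths(fields) < 2)
  if (length(bad) > 0) {
    stop(sprintf("malformed line %d in %s: fewer than 2 fields", bad[1], path))
  }
  from <- vapply(fields, function(f) trimws(f[1]), character(1))
  to <- vapply(fields, function(f) trimws(f[2]), character(1))
  if (is.na(header)) {
    # header iff line 1's fields never recur as identifiers in the body
    header <- length(from) > 1 &&
      !(from[1] %in% from[-1]) && !(to[1] %in% to[-1])
  }
  if (isTRUE(header)) {
    from <- from[-1]
    to <- to[-1]
    if (length(from) == 0) stop(sprintf("empty edge list (header only): %s", path))
  }
  if (normalize) {
    from <- normalize_id(from, row_case)
    to <- normalize_id(to, col_case)
  }
  keep <- !duplicated(paste(from, to, sep = "\r"))
  data.frame(from = from[keep], to = to[keep], stringsAsFactors = FALSE)
}

#' Build a bipartite network from entity pairs
#'
#' Row and column name order is the order of first appearance in `pairs`;
#' `adjacency[i, j] = 1` iff the pair occurs.
#'
#' @param pairs two-column `data.frame` (or matrix) of (row entity, column
#'   entity) pairs, as returned by [read_edge_list()].
#' @return A [bipartite_network].
#' @export
build_network <- function(pairs) {
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  if (nrow(pairs) == 0) stop("empty pair list")
  from <- as.character(pairs[[1]])
  to <- as.character(pairs[[2]])
  rn <- unique(from)
  cn <- unique(to)
  adj <- matrix(0, length(rn), length(cn), dimnames = list(rn, cn))
  adj[cbind(match(from, rn), match(to, cn))] <- 1
  bipartite_network(adj)
}

#' Align two networks on a shared miRNA axis
#'
#' The lncRNA-miRNA network has miRNAs on its columns; the miRNA-disease
#' network has them on its rows.  In `"intersection"` mode, miRNAs absent
#' from either network are dropped from both (an error if none are shared);
#' lncRNAs or diseases left with all-zero association profiles are retained.
#' In `"union"` mode, missing miRNA columns/rows are zero-padded.  Either
#' way both outputs share one ordered miRNA list (order of the lncRNA-miRNA
#' axis first, then any union-only additions).
#'
#' @param lm [bipartite_network], lncRNA x miRNA.
#' @param md [bipartite_network], miRNA x disease.
#' @param mode `"intersection"` (default) or `"union"`.
#' @return A list of class `aligned_triple` with fields `a_lm`, `a_md` and
#'   `mirnas` (the shared ordered miRNA axis).
#' @export
align_on_mirna <- function(lm, md, mode = c("intersection", "union")) {
  mode <- match.arg(mode)
  stopifnot(inherits(lm, "bipartite_network"), inherits(md, "bipartite_network"))
  lm_mir <- colnames(lm$adjacency)
  md_mir <- rownames(md$adjacency)
  if (mode == "intersection") {
    shared <- lm_mir[lm_mir %in% md_mir]
    if (length(shared) == 0) stop("no shared miRNAs between the two networks")
  } else {
    shared <- c(lm_mir, setdiff(md_mir, lm_mir))
  }
  a_lm <- matrix(0, nrow(lm$adjacency), length(shared),
                 dimnames = list(rownames(lm$adjacency), shared))
  keep_lm <- intersect(shared, lm_mir)
  a_lm[, keep_lm] <- lm$adjacency[, keep_lm, drop = FALSE]
  a_md <- matrix(0, length(shared), ncol(md$adjacency),
                 dimnames = list(shared, colnames(md$adjacency)))
  keep_md <- intersect(shared, md_mir)
  a_md[keep_md, ] <- md$adjacency[keep_md, , drop = FALSE]
  structure(list(a_lm = bipartite_network(a_lm),
                 a_md = bipartite_network(a_md),
                 mirnas = shared),
            class = "aligned_triple")
}

#' @export
print.aligned_triple <- function(x, ...) {
  cat(sprintf("aligned_triple: %d lncRNAs, %d miRNAs, %d diseases\n",
              nrow(x$a_lm$adjacency), length(x$mirnas), ncol(x$a_md$adjacency)))
  invisible(x)
}

#' Write a bipartite network back out as an edge list
#'
#' One line per association, two delimited columns, no header; row order is
#' row-major over the adjacency matrix so [read_edge_list()] +
#' [build_network()] round-trips the object exactly.
#'
#' @param net [bipartite_network].
#' @param path output file path.
#' @param delimiter field separator (default tab).
#' @export
write_edge_list <- function(net, path, delimiter = "\t") {
  stopifnot(inherits(net, "bipartite_network"))
  a <- net$adjacency
  idx <- which(t(a) == 1)  # transpose for row-major order
  j <- (idx - 1) %% ncol(a) + 1
  i <- (idx - 1) %/% ncol(a) + 1
  writeLines(paste(rownames(a)[i], colnames(a)[j], sep = delimiter), path)
  invisible(path)
}

#' Write a labeled numeric matrix as delimited text
#'
#' @param x matrix (or `score_matrix` / `similarity_matrix`, whose `values`
#'   field is used).
#' @param path output path.
#' @export
write_matrix <- function(x, path) {
  if (inherits(x, c("score_matrix", "similarity_matrix"))) x <- x$values
  if (inherits(x, "bipartite_network")) x <- x$adjacency
  utils::write.table(x, path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}

#' Read a labeled numeric matrix written by [write_matrix()]
#'
#' @param path input path.
#' @return numeric matrix with dimnames.
#' @export
read_matrix <- function(path) {
  as.matrix(utils::read.table(path, sep = "\t", header = TRUE, row.names = 1,
                              check.names = FALSE))
}
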