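#' Geometric center of a nucleotide's backbone atoms
#'
#' The arithmetic mean of whichever of the six backbone atoms
#' (C3', C4', C5', O3', O5', P) carry coordinates.
#'
#' @param nt a [nucleotide()].
#' @return numeric 3-vector (Angstrom).
#' @export
nucleotide_center <- function(nt) {
  if (is.null(nt$coords) || nrow(nt$coords) == 0L)
    stop("nucleotide ", nt$residue_number, " has no backbone atoms")
  colMeans(nt$coords)
}

#' RMSD after optimal rigid superposition (Kabsch algorithm)
#'
#' Superposes `Q` onto `P` by the SVD-based optimal rotation and translation
#' (proper rotation only, no reflection) and returns the residual RMSD.
#'
#' @param P,Q numeric k x 3 coordinate matrices, corresponded by row index.
#' @return RMSD in the units of the input (Angstrom).
#' @export
kabsch_rmsd <- function(P, Q) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  if (!all(dim(P) == dim(Q)) || ncol(P) != 3L)
    stop("P and Q must be k x 3 matrices with equal k")
  k <- nrow(P)
  Pc <- sweep(P, 2, colMeans(P)); Qc <- sweep(Q, 2, colMeans(Q))
  H <- crossprod(Pc, Qc)              # covariance
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)           # rotates Pc onto Qc
  diff <- Qc - Pc %*% t(R)
  sqrt(sum(diff^2) / k)
}

#' Pairwise inter-nucleotide distance matrix for a loop
#'
#' Two distance definitions are provided. `center_euclidean` (default) is the
#' Euclidean distance between the backbone-atom geometric centers of the two
#' nucleotides. `kabsch_backbone` is the Kabsch-superposition RMSD over the
#' backbone atoms the two nucleotides have in common.
#'
#' @param loop an `rna_loop` with coordinates attached.
#' @param mode `"center_euclidean"` or `"kabsch_backbone"`.
#' @return symmetric N x N numeric matrix with zero diagonal (Angstrom).
#' @export
pairwise_distances <- function(loop, mode = c("center_euclidean", "kabsch_backbone")) {
  mode <- match.arg(mode)
  n <- length(loop$nucleotides)
  if (mode == "center_euclidean") {
    centers <- t(vapply(loop$nucleotides, nucleotide_center, numeric(3)))
    return(as.matrix(stats::dist(centers)))
  }
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ci <- loop$nucleotides[[i]]$coords
    cj <- loop$nucleotides[[j]]$coords
    if (is.null(ci) || is.null(cj))
      stop("nucleotide without coordinates at index ", if (is.null(ci)) i else j)
    common <- intersect(rownames(ci), rownames(cj))
    if (length(common) == 0L)
      stop("no common backbone atoms between nucleotides ", i, " and ", j)
    D[i, j] <- D[j, i] <- kabsch_rmsd(ci[common, , drop = FALSE],
                                      cj[common, , drop = FALSE])
  }
  dimnames(D) <- NULL
  D
}

#' Encode a loop as a strongly connected directed attributed graph
#'
#' Every ordered pair of nucleotides gets one directed edge, so an N-nucleotide
#' loop yields N(N-1) edges. Node features are the 4-element one-hot of the
#' base (A, C, G, U; non-standard bases get an all-zero row). Each edge carries
#' a 23-element feature vector: element 1 is the inter-nucleotide distance,
#' elements 2-19 the one-hot over the 18 LW base-pair classes (in
#' [LW_CLASSES] order), elements 20-23 the one-hot over the 4 stacking
#' directions. A base-pair annotation (i, j, class) sets the class bit on the
#' edge i->j and the direction-reversed class ([lw_transpose()]) on j->i;
#' stacking reversal follows [stack_transpose()].
#'
#' @param loop an `rna_loop` with coordinates attached.
#' @param distance_mode passed to [pairwise_distances()].
#' @return an object of class `loop_graph`: list with `node_features`
#'   (N x 4), `edges` (M x 2 integer matrix of ordered pairs, M = N(N-1)),
#'   `edge_features` (M x 23), `adjacency` (N x N distances), `label`
#'   (family or NA) and `loop_id`.
#' @export
encode_loop <- function(loop, distance_mode = c("center_euclidean", "kabsch_backbone")) {
  distance_mode <- match.arg(distance_mode)
  n <- length(loop$nucleotides)
  bases <- vapply(loop$nucleotides, `[[`, character(1), "base")
  node_features <- matrix(0, n, 4, dimnames = list(NULL, STANDARD_BASES))
  for (b in STANDARD_BASES) node_features[bases == b, b] <- 1
  D <- pairwise_distances(loop, distance_mode)

  edges <- cbind(from = rep(seq_len(n), each = n), to = rep(seq_len(n), n))
  edges <- edges[edges[, 1] != edges[, 2], , drop = FALSE]
  m <- nrow(edges)
  ef <- matrix(0, m, 23)
  colnames(ef) <- c("dist", LW_CLASSES, STACK_CLASSES)
  ef[, 1] <- D[edges]
  eidx <- function(i, j) match(TRUE, edges[, 1] == i & edges[, 2] == j)

  bp <- unique(loop$base_pairs)
  for (r in seq_len(nrow(bp))) {
    i <- bp$i[r]; j <- bp$j[r]; cls <- bp$lw[r]
    if (i > n || j > n) stop("base-pair annotation index out of range")
    row_f <- eidx(i, j); row_b <- eidx(j, i)
    ef[row_f, 1L + match(cls, LW_CLASSES)] <- 1
    ef[row_b, 1L + match(lw_transpose(cls), LW_CLASSES)] <- 1
  }
  stk <- unique(loop$stackings)
  for (r in seq_len(nrow(stk))) {
    i <- stk$i[r]; j <- stk$j[r]; dir <- stk$direction[r]
    if (i > n || j > n) stop("stacking annotation index out of range")
    ef[eidx(i, j), 19L + match(dir, STACK_CLASSES)] <- 1
    ef[eidx(j, i), 19L + match(stack_transpose(dir), STACK_CLASSES)] <- 1
  }
  structure(list(node_features = node_features, edges = edges,
                 edge_features = ef, adjacency = D,
                 label = if (is.null(loop$family)) NA_character_ else loop$family,
                 loop_id = loop_id(loop)),
            class = "loop_graph")
}

#' @export
print.loop_graph <- function(x, ...) {
  cat("<loop_graph> ", x$loop_id, "  nodes=", nrow(x$node_features),
      "  edges=", nrow(x$edges),
      if (!is.na(x$label)) paste0("  label=", x$label) else "", "\n", sep = "")
  invisible(x)
}

#' Write / read loop graphs as JSON lines
#'
#' One graph per line: `loop_id`, `label`, `nodes` (one-hot rows), `edges`
#' (0-based from/to), `edge_features`. Any graph-neural-network backend can
#' consume this dialect.
#'
#' @param graphs list of `loop_graph` objects.
#' @param path file path.
#' @export
write_graphs_jsonl <- function(graphs, path) {
  con <- file(path, "w"); on.exit(close(con))
  for (g in graphs) {
    rec <- list(loop_id = g$loop_id, label = g$label,
                nodes = unname(g$node_features),
                edges = unname(g$edges - 1L),
                edge_features = unname(g$edge_features))
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA,
                                na = "null"), con)
  }
  invisible(path)
}

#' @rdname write_graphs_jsonl
#' @return `read_graphs_jsonl`: list of `loop_graph` objects. The adjacency
#'   matrix is rebuilt from the distance channel of the edge features.
#' @export
read_graphs_jsonl <- function(path) {
  lines <- readLines(path)
  lapply(lines, function(l) {
    rec <- jsonlite::fromJSON(l, simplifyMatrix = TRUE)
    nodes <- matrix(as.numeric(rec$nodes), nrow = nrow(rec$nodes),
                    dimnames = list(NULL, STANDARD_BASES))
    edges <- matrix(as.integer(rec$edges), ncol = 2) + 1L
    colnames(edges) <- c("from", "to")
    ef <- matrix(as.numeric(rec$edge_features), nrow = nrow(rec$edge_features))
    colnames(ef) <- c("dist", LW_CLASSES, STACK_CLASSES)
    n <- nrow(nodes)
    D <- matrix(0, n, n)
    D[edges] <- ef[, 1]
    structure(list(node_features = nodes, edges = edges, edge_features = ef,
                   adjacency = D,
                   label = if (is.null(rec$label)) NA_character_ else rec$label,
                   loop_id = rec$loop_id),
              class = "loop_graph")
  })
}
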