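#' Pairwise loop similarity under a pluggable backend
#'
#' Three backends are available.
#'
#' * `interaction_internal`: a base-interaction alignment score. Base-pair
#'   annotations of the two loops are greedily matched (a match is two
#'   annotations with the same LW class, each annotation used at most once);
#'   stacking annotations are matched the same way by direction.
#'   `score = 2 * matched_pairs + 0.5 * matched_stackings`,
#'   `alignment_length = matched_pairs`, and `rmsd` is the Kabsch RMSD over
#'   the backbone centers of the nucleotides of the matched pairs.
#' * `structure_internal`: a backbone-shape score. Nucleotide centers are
#'   aligned in sequence order (truncated to the shorter loop), superposed
#'   by the Kabsch algorithm; `rmsd` is the residual RMSD,
#'   `score = mean(1 / (1 + (d_k / d0)^2))` over aligned center distances
#'   after superposition with d0 = 4 Angstrom, `alignment_length` the
#'   aligned count.
#' * `external_table`: values looked up from a user-supplied per-pair table
#'   (e.g. produced by dedicated interaction- or structure-alignment tools),
#'   TSV `loop_a loop_b backend score rmsd aln_len`.
#'
#' The internal backends are simplified, fully documented scores — not
#' reimplementations of any external alignment tool; the external table
#' reproduces a tool-based workflow exactly when its outputs are supplied.
#'
#' @param loop_a,loop_b `rna_loop` objects with coordinates attached.
#' @param backend one of `"interaction_internal"`, `"structure_internal"`,
#'   `"external_table"`.
#' @param table per-pair data frame (required for `external_table`).
#' @param d0 softness scale of the structural score (Angstrom).
#' @return list with `score`, `rmsd`, `alignment_length`.
#' @export
pair_similarity <- function(loop_a, loop_b,
                            backend = c("interaction_internal",
                                        "structure_internal",
                                        "external_table"),
                            table = NULL, d0 = 4) {
  backend <- match.arg(backend)
  if (backend == "external_table") {
    if (is.null(table)) stop("external_table backend needs a pair table")
    ida <- loop_id(loop_a); idb <- loop_id(loop_b)
    hit <- (table$loop_a == ida & table$loop_b == idb) |
      (table$loop_a == idb & table$loop_b == ida)
    if (!any(hit))
      stop("pair (", ida, ", ", idb, ") absent from the external table")
    r <- table[which(hit)[1], ]
    return(list(score = r$score, rmsd = r$rmsd, alignment_length = r$aln_len))
  }
  if (backend == "interaction_internal") {
    greedy_match <- function(xa, xb) {
      # multiset intersection, pairing first-come within each class
      matched <- list()
      used_b <- rep(FALSE, length(xb$cls))
      for (ia in seq_along(xa$cls)) {
        hit <- which(!used_b & xb$cls == xa$cls[ia])
        if (length(hit)) {
          used_b[hit[1]] <- TRUE
          matched[[length(matched) + 1L]] <- c(ia, hit[1])
        }
      }
      matched
    }
    bpa <- list(cls = loop_a$base_pairs$lw, i = loop_a$base_pairs$i,
                j = loop_a$base_pairs$j)
    bpb <- list(cls = loop_b$base_pairs$lw, i = loop_b$base_pairs$i,
                j = loop_b$base_pairs$j)
    mp <- greedy_match(bpa, bpb)
    ms <- greedy_match(list(cls = loop_a$stackings$direction),
                       list(cls = loop_b$stackings$direction))
    score <- 2 * length(mp) + 0.5 * length(ms)
    rmsd <- 0
    if (length(mp)) {
      Pa <- do.call(rbind, lapply(mp, function(m) rbind(
        nucleotide_center(loop_a$nucleotides[[bpa$i[m[1]]]]),
        nucleotide_center(loop_a$nucleotides[[bpa$j[m[1]]]]))))
      Pb <- do.call(rbind, lapply(mp, function(m) rbind(
        nucleotide_center(loop_b$nucleotides[[bpb$i[m[2]]]]),
        nucleotide_center(loop_b$nucleotides[[bpb$j[m[2]]]]))))
      rmsd <- kabsch_rmsd(Pa, Pb)
    }
    return(list(score = score, rmsd = rmsd, alignment_length = length(mp)))
  }
  # structure_internal
  ca <- t(vapply(loop_a$nucleotides, nucleotide_center, numeric(3)))
  cb <- t(vapply(loop_b$nucleotides, nucleotide_center, numeric(3)))
  k <- min(nrow(ca), nrow(cb))
  P <- ca[seq_len(k), , drop = FALSE]; Q <- cb[seq_len(k), , drop = FALSE]
  rmsd <- kabsch_rmsd(P, Q)
  # per-point distances after the optimal superposition
  Pc <- sweep(P, 2, colMeans(P)); Qc <- sweep(Q, 2, colMeans(Q))
  s <- svd(crossprod(Pc, Qc))
  R <- s$v %*% diag(c(1, 1, sign(det(s$v %*% t(s$u))))) %*% t(s$u)
  dk <- sqrt(rowSums((Qc - Pc %*% t(R))^2))
  list(score = mean(1 / (1 + (dk / d0)^2)), rmsd = rmsd, alignment_length = k)
}

#' Average pairwise similarity statistics for one subcluster
#'
#' Means over all unordered member pairs of the interaction-backend and
#' structure-backend score, RMSD and alignment length. Singletons cannot
#' form pairs: their statistics are zeroed and flagged.
#'
#' @param members list of `rna_loop` objects in the subcluster.
#' @param subcluster_id identifier carried through to the report.
#' @param interaction_backend,structure_backend backend names (or
#'   `"external_table"`).
#' @param table external pair table, if either backend needs it.
#' @return one-row data frame with `subcluster_id, M` (member count),
#'   `SXsc, SXd, SXal` (interaction score / RMSD / length),
#'   `TMsc, TMd, TMal` (structure score / RMSD / length), `flagged`.
#' @export
subcluster_stats <- function(members, subcluster_id = NA,
                             interaction_backend = "interaction_internal",
                             structure_backend = "structure_internal",
                             table = NULL) {
  M <- length(members)
  # a table with a `backend` column carries both kinds of rows; split it
  tab_for <- function(kind) {
    if (is.null(table) || is.null(table$backend)) return(table)
    table[table$backend == kind, , drop = FALSE]
  }
  tab_sx <- tab_for("interaction"); tab_tm <- tab_for("structure")
  if (M < 2L)
    return(data.frame(subcluster_id = subcluster_id, M = M,
                      SXsc = 0, SXd = 0, SXal = 0,
                      TMsc = 0, TMd = 0, TMal = 0, flagged = TRUE))
  acc <- matrix(0, 0, 6)
  for (a in seq_len(M - 1L)) for (b in (a + 1L):M) {
    sx <- pair_similarity(members[[a]], members[[b]], interaction_backend,
                          table = tab_sx)
    tm <- pair_similarity(members[[a]], members[[b]], structure_backend,
                          table = tab_tm)
    acc <- rbind(acc, c(sx$score, sx$rmsd, sx$alignment_length,
                        tm$score, tm$rmsd, tm$alignment_length))
  }
  m <- colMeans(acc)
  data.frame(subcluster_id = subcluster_id, M = M,
             SXsc = m[1], SXd = m[2], SXal = m[3],
             TMsc = m[4], TMd = m[5], TMal = m[6], flagged = FALSE)
}

#' Q-scores for a set of subclusters
#'
#' For subcluster i with interaction statistics (SXsc_i, SXd_i, SXal_i),
#' structural statistics (TMsc_i, TMd_i, TMal_i) and member count M_i, with
#' maxima taken over all subclusters in the run:
#'
#' SXQ_i = SXsc_i/SXsc_max + SXal_i/SXal_max + M_i/M_max - SXd_i/SXd_max
#'
#' TMQ_i = TMsc_i/TMsc_max + TMal_i/TMal_max + M_i/M_max - TMd_i/TMd_max
#'
#' Q_i = (SXQ_i + TMQ_i) / 2
#'
#' A ratio with a zero maximum is defined as 0.
#'
#' @param stats data frame of rows from [subcluster_stats()].
#' @return the input with columns `SXQ`, `TMQ`, `Q` appended, plus the
#'   corpus maxima as attributes, sorted by decreasing `Q`.
#' @export
q_scores <- function(stats) {
  if (nrow(stats) == 0L) stop("empty subcluster statistics")
  rat <- function(x, mx) if (mx == 0) rep(0, length(x)) else x / mx
  mx <- list(SXsc = max(stats$SXsc), SXd = max(stats$SXd),
             SXal = max(stats$SXal), TMsc = max(stats$TMsc),
             TMd = max(stats$TMd), TMal = max(stats$TMal), M = max(stats$M))
  stats$SXQ <- rat(stats$SXsc, mx$SXsc) + rat(stats$SXal, mx$SXal) +
    rat(stats$M, mx$M) - rat(stats$SXd, mx$SXd)
  stats$TMQ <- rat(stats$TMsc, mx$TMsc) + rat(stats$TMal, mx$TMal) +
    rat(stats$M, mx$M) - rat(stats$TMd, mx$TMd)
  stats$Q <- (stats$SXQ + stats$TMQ) / 2
  out <- stats[order(-stats$Q), ]
  rownames(out) <- NULL
  attr(out, "maxima") <- mx
  out
}

#' Read an external per-pair similarity table
#'
#' TSV `loop_a loop_b backend score rmsd aln_len`.
#'
#' @param path TSV path.
#' @return data frame.
#' @export
read_pair_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  stopifnot(all(c("loop_a", "loop_b", "score", "rmsd", "aln_len") %in% names(df)))
  df
}
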