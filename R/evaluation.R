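#' Map subclusters to motif family labels
#'
#' In `majority` mode (default) each subcluster is assigned to the family
#' holding the largest fraction of its labelled members, but only when that
#' fraction strictly exceeds `threshold` (default 0.60 — the ">60% of loop
#' members belong to a single family" rule); otherwise the subcluster stays
#' `"unassigned"`. Fractions are computed over labelled members only, after
#' removing any caller-supplied exclusions (outliers, loops with missing or
#' conflicting annotations). `hungarian` mode instead computes the
#' one-to-one subcluster-to-family assignment maximising the total number of
#' matched members.
#'
#' @param assignment data frame `loop_id, cluster, subcluster` (from
#'   [subcluster()]), or a named vector of subcluster ids.
#' @param true_labels named character vector loop_id -> family; loops absent
#'   from it count as unlabelled.
#' @param mode `"majority"` or `"hungarian"`.
#' @param threshold strict majority bound for `majority` mode.
#' @param exclude character vector of loop_ids to drop before mapping.
#' @return an object of class `family_assignment`: data frame `mapping`
#'   (`subcluster`, `family`, `majority_fraction`, `n_labelled`),
#'   `threshold`, `mode`.
#' @export
map_clusters_to_labels <- function(assignment, true_labels,
                                   mode = c("majority", "hungarian"),
                                   threshold = 0.60, exclude = character(0)) {
  mode <- match.arg(mode)
  if (is.data.frame(assignment)) {
    sc <- stats::setNames(assignment$subcluster, assignment$loop_id)
  } else {
    sc <- assignment
  }
  sc <- sc[!names(sc) %in% exclude]
  labelled <- names(sc)[names(sc) %in% names(true_labels)]
  if (length(labelled) == 0L) stop("no labelled items to map")
  subs <- sort(unique(sc))
  fams <- sort(unique(true_labels[labelled]))
  counts <- table(factor(sc[labelled], levels = subs),
                  factor(true_labels[labelled], levels = fams))
  n_lab <- rowSums(counts)
  if (mode == "majority") {
    frac <- ifelse(n_lab > 0, apply(counts, 1, max) / n_lab, 0)
    top <- fams[apply(counts, 1, which.max)]
    family <- ifelse(n_lab > 0 & frac > threshold, top, "unassigned")
  } else {
    amat <- matrix(as.numeric(counts), nrow(counts), ncol(counts))
    sol <- hungarian_max(amat)
    family <- rep("unassigned", length(subs))
    for (r in seq_along(sol)) {
      if (!is.na(sol[r]) && amat[r, sol[r]] > 0) family[r] <- fams[sol[r]]
    }
    frac <- ifelse(n_lab > 0, apply(counts, 1, max) / n_lab, 0)
  }
  structure(list(mapping = data.frame(subcluster = subs, family = family,
                                      majority_fraction = as.numeric(frac),
                                      n_labelled = as.integer(n_lab),
                                      stringsAsFactors = FALSE),
                 threshold = threshold, mode = mode),
            class = "family_assignment")
}

#' @export
print.family_assignment <- function(x, ...) {
  cat("<family_assignment> mode=", x$mode, ", threshold=", x$threshold, "\n",
      sep = "")
  print(x$mapping, row.names = FALSE)
  invisible(x)
}

# maximum-weight one-to-one assignment of rows to columns.
# Potential-based Hungarian algorithm, O(n^3); rows beyond the column count
# (or assigned to padding) come back NA.
hungarian_max <- function(weights) {
  w <- as.matrix(weights)
  n0 <- nrow(w); m0 <- ncol(w)
  n <- max(n0, m0)
  cost <- matrix(0, n, n)
  cost[seq_len(n0), seq_len(m0)] <- -w   # minimise negated weight
  INF <- sum(abs(cost)) + 1
  u <- rep(0, n + 1); v <- rep(0, n + 1); p <- rep(0, n + 1); way <- rep(0, n + 1)
  for (i in seq_len(n)) {
    p[1] <- i; j0 <- 0
    minv <- rep(INF, n + 1); used <- rep(FALSE, n + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]; delta <- INF; j1 <- 0
      for (j in seq_len(n)) {
        if (!used[j + 1]) {
          cur <- cost[i0, j] - u[i0 + 1] - v[j + 1]
          if (cur < minv[j + 1]) { minv[j + 1] <- cur; way[j + 1] <- j0 }
          if (minv[j + 1] < delta) { delta <- minv[j + 1]; j1 <- j }
        }
      }
      for (j in 0:n) {
        if (used[j + 1]) { u[p[j + 1] + 1] <- u[p[j + 1] + 1] + delta
                           v[j + 1] <- v[j + 1] - delta }
        else minv[j + 1] <- minv[j + 1] - delta
      }
      j0 <- j1
      if (p[j0 + 1] == 0) break
    }
    repeat {
      j1 <- way[j0 + 1]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
      if (j0 == 0) break
    }
  }
  assign <- rep(NA_integer_, n0)
  for (j in seq_len(n)) {
    i <- p[j + 1]
    if (i >= 1 && i <= n0 && j <= m0) assign[i] <- j
  }
  assign
}

#' Classification report for a cluster-to-family mapping
#'
#' Converts each item's subcluster to its mapped family label and compares
#' with the truth: per-family precision, recall, F1 and support, weighted
#' averages, overall accuracy, and the confusion matrix. Items in
#' unassigned subclusters count as wrong for their true class. Families with
#' zero support or zero predictions get zeroed metrics and are flagged.
#'
#' @param assignment as in [map_clusters_to_labels()].
#' @param true_labels named vector loop_id -> family.
#' @param family_assignment a `family_assignment`; computed with defaults if
#'   missing.
#' @return list with `per_family` data frame, `weighted` (precision, recall,
#'   f1), `accuracy`, `confusion` (true x predicted matrix).
#' @export
classification_report <- function(assignment, true_labels,
                                  family_assignment = NULL) {
  if (is.null(family_assignment))
    family_assignment <- map_clusters_to_labels(assignment, true_labels)
  if (is.data.frame(assignment)) {
    sc <- stats::setNames(assignment$subcluster, assignment$loop_id)
  } else sc <- assignment
  items <- names(sc)[names(sc) %in% names(true_labels)]
  map <- stats::setNames(family_assignment$mapping$family,
                         family_assignment$mapping$subcluster)
  pred <- unname(map[as.character(sc[items])])
  pred[is.na(pred)] <- "unassigned"
  truth <- unname(true_labels[items])
  fams <- sort(unique(truth))
  lev <- union(fams, unique(pred))
  conf <- table(factor(truth, levels = lev), factor(pred, levels = lev))
  per <- lapply(fams, function(f) {
    tp <- sum(pred == f & truth == f)
    fp <- sum(pred == f & truth != f)
    fn <- sum(pred != f & truth == f)
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    data.frame(family = f, precision = prec, recall = rec, f1 = f1,
               support = sum(truth == f),
               flagged = (tp + fp == 0) || (tp + fn == 0))
  })
  per <- do.call(rbind, per)
  wts <- per$support / sum(per$support)
  list(per_family = per,
       weighted = c(precision = sum(per$precision * wts),
                    recall = sum(per$recall * wts),
                    f1 = sum(per$f1 * wts)),
       accuracy = mean(pred == truth),
       confusion = conf[fams, , drop = FALSE])
}

#' Motif clustering accuracy (MCA) for one family
#'
#' The number of known motifs of the family that land in subclusters
#' assigned to that family, divided by the total number of known motifs of
#' the family.
#'
#' @param family family label.
#' @param family_assignment a `family_assignment`.
#' @param assignment as in [map_clusters_to_labels()].
#' @param true_labels named vector loop_id -> family (the known motifs).
#' @return ratio in \[0, 1\].
#' @export
mca <- function(family, family_assignment, assignment, true_labels) {
  known <- names(true_labels)[true_labels == family]
  if (length(known) == 0L) stop("no known motifs for family ", sQuote(family))
  if (is.data.frame(assignment)) {
    sc <- stats::setNames(assignment$subcluster, assignment$loop_id)
  } else sc <- assignment
  fam_subs <- family_assignment$mapping$subcluster[
    family_assignment$mapping$family == family]
  known_in <- known[known %in% names(sc)]
  sum(sc[known_in] %in% fam_subs) / length(known)
}

#' Two-standard-deviation upper bound of a similarity distribution
#'
#' `mean + 2 * sd` of the pairwise RMSD values observed within known motif
#' families; loop pairs below this bound are considered structurally
#' similar (about 95% of known-family pairs fall inside the band).
#'
#' @param values numeric vector of pairwise RMSDs.
#' @return upper bound (Angstrom).
#' @export
two_sd_upper <- function(values) {
  stopifnot(length(values) >= 1L)
  s <- if (length(values) > 1L) stats::sd(values) else 0
  mean(values) + 2 * s
}

#' RMSD purity of multi-member subclusters
#'
#' Fraction of subclusters with at least two members whose average pairwise
#' RMSD falls below the supplied bound (singletons have no pairs and are
#' excluded, mirroring the single-loop filtering step).
#'
#' @param members_by_subcluster named list: subcluster id -> list of
#'   `rna_loop` members.
#' @param threshold upper bound (e.g. from [two_sd_upper()] on known-family
#'   pairs).
#' @param backend similarity backend for the RMSD (see [pair_similarity()]).
#' @param table external pair table if needed.
#' @return list with `fraction`, and `per_subcluster` data frame
#'   (`subcluster`, `avg_rmsd`, `below`).
#' @export
purity_analysis <- function(members_by_subcluster, threshold,
                            backend = "structure_internal", table = NULL) {
  multi <- members_by_subcluster[vapply(members_by_subcluster, length,
                                        integer(1)) >= 2L]
  if (length(multi) == 0L) stop("no multi-member subclusters")
  rows <- lapply(names(multi), function(id) {
    mem <- multi[[id]]
    rmsds <- c()
    for (a in seq_len(length(mem) - 1L)) for (b in (a + 1L):length(mem))
      rmsds <- c(rmsds, pair_similarity(mem[[a]], mem[[b]], backend,
                                        table = table)$rmsd)
    data.frame(subcluster = id, avg_rmsd = mean(rmsds),
               below = mean(rmsds) < threshold)
  })
  per <- do.call(rbind, rows)
  list(fraction = mean(per$below), per_subcluster = per)
}
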