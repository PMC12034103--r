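#' Normalize raw annotation rows from an external annotation tool
#'
#' Two adapter dialects are supported, one for FR3D-style tables and one for
#' DSSR-style tables. Both are TSVs with columns
#' `structure_id chain_i res_i base_i chain_j res_j base_j kind class`.
#' Class spellings are canonicalized to the package vocabularies:
#'
#' * FR3D dialect: LW tokens as `cWW`/`tSH` (any case for the orientation
#'   letter); stacking tokens `s35`, `s53`, `s33`, `s55` mapped to
#'   upward, downward, inward, outward.
#' * DSSR dialect: hyphenated LW tokens (`cW-W`, `tS-H`); stacking tokens as
#'   the words `upward`/`downward`/`inward`/`outward`.
#'
#' @param raw_rows data frame in the adapter dialect.
#' @param source `"FR3D"` or `"DSSR"`.
#' @return a data frame of normalized annotation records with columns
#'   `structure_id, chain_i, res_i, base_i, chain_j, res_j, base_j, kind,
#'   class_token, source`.
#' @export
normalize_records <- function(raw_rows, source = c("FR3D", "DSSR")) {
  source <- match.arg(source)
  need <- c("structure_id", "chain_i", "res_i", "base_i",
            "chain_j", "res_j", "base_j", "kind", "class")
  if (!all(need %in% names(raw_rows)))
    stop("adapter rows must have columns: ", paste(need, collapse = ", "))
  if (nrow(raw_rows) == 0L)
    return(cbind(raw_rows[need[-9]],
                 data.frame(class_token = character(), source = character())))
  tok <- as.character(raw_rows$class)
  kind <- as.character(raw_rows$kind)
  if (!all(kind %in% c("pair", "stack")))
    stop("kind must be 'pair' or 'stack'")
  canon <- character(length(tok))
  for (r in seq_along(tok)) {
    t0 <- tok[r]
    if (kind[r] == "pair") {
      t1 <- gsub("-", "", t0, fixed = TRUE)
      t1 <- paste0(tolower(substr(t1, 1, 1)), toupper(substr(t1, 2, 3)))
      if (!t1 %in% LW_CLASSES)
        stop("unmappable base-pair token ", sQuote(t0), " (", source, " dialect)")
      canon[r] <- t1
    } else {
      if (source == "FR3D") {
        map <- c(s35 = "upward", s53 = "downward", s33 = "inward", s55 = "outward")
        if (!tolower(t0) %in% names(map))
          stop("unmappable stacking token ", sQuote(t0), " (FR3D dialect)")
        canon[r] <- unname(map[tolower(t0)])
      } else {
        if (!tolower(t0) %in% STACK_CLASSES)
          stop("unmappable stacking token ", sQuote(t0), " (DSSR dialect)")
        canon[r] <- tolower(t0)
      }
    }
  }
  out <- raw_rows[need[-9]]
  out$class_token <- canon
  out$source <- source
  out
}

#' Read a base-interaction pattern frequency table
#'
#' TSV `base_i base_j class count`: occurrence counts of each interaction
#' pattern over a reference corpus (the merge conflict rule prefers the
#' pattern that occurred most frequently corpus-wide).
#'
#' @param path TSV path.
#' @return a data frame with those four columns.
#' @export
read_frequency_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  stopifnot(all(c("base_i", "base_j", "class", "count") %in% names(df)))
  stopifnot(all(df$count >= 0))
  df
}

#' Build a pattern frequency table from annotated loops
#'
#' Counts every (base_i, base_j, class) base-pair pattern across a corpus of
#' loops; used as the reference corpus for conflict resolution in
#' [merge_annotations()].
#'
#' @param loops list of `rna_loop` objects.
#' @return frequency data frame `base_i base_j class count`.
#' @export
frequency_table_from_loops <- function(loops) {
  rows <- lapply(loops, function(loop) {
    bp <- loop$base_pairs
    if (nrow(bp) == 0L) return(NULL)
    data.frame(
      base_i = vapply(bp$i, function(k) loop$nucleotides[[k]]$base, character(1)),
      base_j = vapply(bp$j, function(k) loop$nucleotides[[k]]$base, character(1)),
      class = bp$lw)
  })
  all <- do.call(rbind, rows)
  if (is.null(all))
    return(data.frame(base_i = character(), base_j = character(),
                      class = character(), count = integer()))
  agg <- stats::aggregate(list(count = rep(1L, nrow(all))),
                          by = all[c("base_i", "base_j", "class")], FUN = sum)
  agg
}

# corpus frequency of one record's pattern; records without base letters
# fall back to the class-marginal count
.pattern_freq <- function(rec, freq) {
  if (nrow(freq) == 0L) return(0)
  bi <- rec$base_i; bj <- rec$base_j
  if (!is.null(bi) && !is.na(bi) && nzchar(bi)) {
    hit <- freq$base_i == bi & freq$base_j == bj & freq$class == rec$class_token
    if (any(hit)) return(sum(freq$count[hit]))
    # a pair and its direction-reversed spelling are the same pattern
    hit <- freq$base_i == bj & freq$base_j == bi &
      freq$class == lw_transpose(rec$class_token)
    if (any(hit)) return(sum(freq$count[hit]))
    return(0)
  }
  sum(freq$count[freq$class == rec$class_token])
}

#' Merge two annotation record sets with frequency-based conflict resolution
#'
#' Takes normalized record sets from two annotation sources for the same
#' structure and returns their union, resolving two kinds of base-pair
#' conflict: (a) the same unordered nucleotide pair annotated with different
#' LW classes, and (b) the same Leontis-Westhof edge (W, H or S side) of one
#' nucleotide claimed by pairs with two different partners. Each conflict is
#' decided in favour of the variant whose (base_i, base_j, class) pattern
#' occurs most frequently in the reference corpus; ties prefer the
#' FR3D-source record, then the lexicographically smaller class token.
#' Stacking records never conflict.
#'
#' @param a,b normalized record data frames (see [normalize_records()]).
#' @param freq frequency table (see [read_frequency_table()]); may be empty,
#'   in which case every conflict falls through to the tie rule.
#' @return a list with `records` (the merged, conflict-free set) and
#'   `conflicts` (a log data frame, one row per dropped record, with the
#'   kept and dropped record keys and the deciding frequencies).
#' @export
merge_annotations <- function(a, b, freq = NULL) {
  if (is.null(freq))
    freq <- data.frame(base_i = character(), base_j = character(),
                       class = character(), count = integer())
  recs <- rbind(a, b)
  if (nrow(recs) == 0L)
    return(list(records = recs,
                conflicts = data.frame(kept = character(), dropped = character(),
                                       kept_freq = numeric(), dropped_freq = numeric())))
  sid <- unique(recs$structure_id)
  if (length(sid) > 1L)
    stop("both inputs must refer to the same structure; got: ",
         paste(sid, collapse = ", "))
  # canonical identity of a record (unordered pair + directional class)
  key_of <- function(r) {
    fwd <- paste(r$chain_i, r$res_i, r$chain_j, r$res_j, r$kind, r$class_token)
    rev_cls <- if (r$kind == "pair") lw_transpose(r$class_token)
               else stack_transpose(r$class_token)
    rev <- paste(r$chain_j, r$res_j, r$chain_i, r$res_i, r$kind, rev_cls)
    min(fwd, rev)
  }
  recs$.key <- vapply(seq_len(nrow(recs)), function(r) key_of(recs[r, ]), character(1))
  # de-duplicate exact (direction-insensitive) repeats; keep first occurrence
  recs <- recs[!duplicated(recs$.key), , drop = FALSE]

  stacks <- recs[recs$kind == "stack", , drop = FALSE]
  pairs <- recs[recs$kind == "pair", , drop = FALSE]
  conflicts <- list()

  if (nrow(pairs) > 0L) {
    pairs$.freq <- vapply(seq_len(nrow(pairs)),
                          function(r) .pattern_freq(pairs[r, ], freq), numeric(1))
    # deterministic precedence: frequency desc, FR3D first, class token asc
    ord <- order(-pairs$.freq, pairs$source != "FR3D", pairs$class_token,
                 pairs$chain_i, pairs$res_i, pairs$chain_j, pairs$res_j)
    pairs <- pairs[ord, , drop = FALSE]
    edge_slot <- function(r) {
      ed <- lw_edges(r$class_token)
      ends <- sort(c(paste(r$chain_i, r$res_i), paste(r$chain_j, r$res_j)))
      c(paste(r$chain_i, r$res_i, ed[1, "i_edge"]),
        paste(r$chain_j, r$res_j, ed[1, "j_edge"]),
        # one pair record at most per unordered nucleotide pair
        paste("pair", ends[1], ends[2]))
    }
    taken <- character(0)
    keep <- logical(nrow(pairs))
    kept_by_slot <- list()
    for (r in seq_len(nrow(pairs))) {
      slots <- edge_slot(pairs[r, ])
      if (any(slots %in% taken)) {
        winner_key <- kept_by_slot[[slots[slots %in% taken][1]]]
        conflicts[[length(conflicts) + 1L]] <- data.frame(
          kept = winner_key, dropped = pairs$.key[r],
          kept_freq = pairs$.freq[match(winner_key, pairs$.key)],
          dropped_freq = pairs$.freq[r])
      } else {
        keep[r] <- TRUE
        taken <- c(taken, slots)
        for (s in slots) kept_by_slot[[s]] <- pairs$.key[r]
      }
    }
    pairs <- pairs[keep, , drop = FALSE]
    pairs$.freq <- NULL
  }
  merged <- rbind(pairs, stacks)
  merged <- merged[order(merged$.key), , drop = FALSE]
  merged$.key <- NULL
  rownames(merged) <- NULL
  conflicts <- if (length(conflicts)) do.call(rbind, conflicts) else
    data.frame(kept = character(), dropped = character(),
               kept_freq = numeric(), dropped_freq = numeric())
  list(records = merged, conflicts = conflicts)
}
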