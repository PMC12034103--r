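#' Parse a loop-location string
#'
#' Loop locations identify a motif candidate by structure, chain and one or
#' more inclusive author-numbered residue ranges, e.g.
#' `"1U9S_A:136-139_161-162"` (an internal loop: two strands) or
#' `"XXXX_A:10-15"` (a hairpin: one strand). One segment is a hairpin loop,
#' two an internal loop, three or more a multiloop. Residue tokens may carry
#' an insertion code appended after a caret (`"102^A"`); insertion codes are
#' carried opaquely and never used for arithmetic.
#'
#' @param text a single location string `PDBID_CHAIN:a-b(_c-d)*`.
#' @return an object of class `loop_location` with fields `pdb_id`, `chain`
#'   and `segments` (data frame with integer `start`, `end` and character
#'   `start_ins`, `end_ins`).
#' @export
#' @examples
#' loc <- parse_loop_location("1U9S_A:136-139_161-162")
#' loc$segments
parse_loop_location <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  m <- regmatches(text, regexec("^([A-Za-z0-9]{4})_([A-Za-z0-9]+):(.+)$", text))[[1]]
  if (length(m) == 0L)
    stop("malformed loop location: ", sQuote(text))
  seg_tokens <- strsplit(m[4], "_", fixed = TRUE)[[1]]
  res_rx <- "^([0-9]+)(\\^[A-Za-z0-9])?$"
  parse_res <- function(tok) {
    mm <- regmatches(tok, regexec(res_rx, tok))[[1]]
    if (length(mm) == 0L)
      stop("malformed residue token ", sQuote(tok), " in ", sQuote(text))
    list(num = as.integer(mm[2]),
         ins = if (nzchar(mm[3])) substr(mm[3], 2, 2) else "")
  }
  segs <- lapply(seg_tokens, function(tok) {
    parts <- strsplit(tok, "-", fixed = TRUE)[[1]]
    if (length(parts) != 2L)
      stop("malformed segment token ", sQuote(tok), " in ", sQuote(text))
    a <- parse_res(parts[1]); b <- parse_res(parts[2])
    if (a$num > b$num)
      stop("segment start > end in token ", sQuote(tok), " of ", sQuote(text))
    data.frame(start = a$num, end = b$num,
               start_ins = a$ins, end_ins = b$ins,
               stringsAsFactors = FALSE)
  })
  structure(list(pdb_id = m[2], chain = m[3],
                 segments = do.call(rbind, segs)),
            class = "loop_location")
}

#' Format a loop location back to its string form
#'
#' Inverse of [parse_loop_location()]: `format_loop_location(parse_loop_location(x))`
#' is `x` for any well-formed location string.
#'
#' @param loc a `loop_location`.
#' @return a single string.
#' @export
format_loop_location <- function(loc) {
  stopifnot(inherits(loc, "loop_location"))
  seg <- loc$segments
  tok <- function(num, ins) paste0(num, ifelse(nzchar(ins), paste0("^", ins), ""))
  segs <- paste0(tok(seg$start, seg$start_ins), "-", tok(seg$end, seg$end_ins))
  paste0(loc$pdb_id, "_", loc$chain, ":", paste(segs, collapse = "_"))
}

#' @export
print.loop_location <- function(x, ...) {
  kind <- c("hairpin loop", "internal loop")[min(nrow(x$segments), 2)]
  if (nrow(x$segments) >= 3) kind <- "multiloop"
  cat("<loop_location> ", format_loop_location(x), "  (", kind, ")\n", sep = "")
  invisible(x)
}

#' Number of residues covered by a loop location
#' @param loc a `loop_location`.
#' @return integer residue count (inclusive ranges).
#' @export
loop_location_length <- function(loc) {
  sum(loc$segments$end - loc$segments$start + 1L)
}

#' Construct a nucleotide record
#'
#' @param residue_number author residue number (integer).
#' @param base one of A, C, G, U; anything else is mapped to `"other"`
#'   (modified or unknown bases get an all-zero one-hot downstream).
#' @param coords optional numeric matrix of backbone-atom coordinates in
#'   Angstrom, with row names among [BACKBONE_ATOMS].
#' @param ins_code optional insertion code, carried opaquely.
#' @return a list of class `nucleotide`.
#' @export
nucleotide <- function(residue_number, base, coords = NULL, ins_code = "") {
  base <- toupper(as.character(base))
  if (identical(base, "T")) base <- "U"
  if (!base %in% STANDARD_BASES) base <- "other"
  if (!is.null(coords)) {
    coords <- as.matrix(coords)
    stopifnot(ncol(coords) == 3L, !is.null(rownames(coords)))
    bad <- setdiff(rownames(coords), BACKBONE_ATOMS)
    if (length(bad)) stop("unknown backbone atom(s): ", paste(bad, collapse = ", "))
    if (!all(is.finite(coords))) stop("non-finite coordinates for residue ", residue_number)
  }
  structure(list(residue_number = as.integer(residue_number),
                 base = base, coords = coords, ins_code = ins_code),
            class = "nucleotide")
}

#' Construct an RNA loop (motif candidate)
#'
#' A loop is an ordered list of nucleotides (strand 1 in 5'->3' order, then
#' strand 2, ...), base-pair annotations over the 18 directional
#' Leontis-Westhof classes, base-stacking annotations over the 4 stacking
#' directions, and an optional motif family label. Annotation indices are
#' 1-based positions in the nucleotide list.
#'
#' @param location a `loop_location` (or a location string).
#' @param nucleotides list of [nucleotide()] records, one per residue covered
#'   by the location.
#' @param base_pairs data frame with columns `i`, `j`, `lw` (directional:
#'   the class reads from `i` to `j`).
#' @param stackings data frame with columns `i`, `j`, `direction`.
#' @param family optional family label (e.g. SR, KT, TS, HT, EL, CL, TL, GL).
#' @return an object of class `rna_loop`.
#' @export
rna_loop <- function(location, nucleotides, base_pairs = NULL, stackings = NULL,
                     family = NULL) {
  if (is.character(location)) location <- parse_loop_location(location)
  stopifnot(inherits(location, "loop_location"))
  n <- length(nucleotides)
  if (n != loop_location_length(location))
    stop("loop ", format_loop_location(location), ": ", n,
         " nucleotides but location covers ", loop_location_length(location))
  if (is.null(base_pairs))
    base_pairs <- data.frame(i = integer(), j = integer(), lw = character())
  if (is.null(stackings))
    stackings <- data.frame(i = integer(), j = integer(), direction = character())
  check_ann <- function(df, classes, what, col) {
    if (nrow(df) == 0L) return(invisible())
    stopifnot(all(df$i >= 1L), all(df$j >= 1L))
    if (any(df$i > n | df$j > n))
      stop(what, " annotation index out of range (loop has ", n, " nucleotides)")
    if (any(df$i == df$j)) stop(what, " annotation with i == j")
    bad <- setdiff(df[[col]], classes)
    if (length(bad)) stop("unknown ", what, " class: ", paste(bad, collapse = ", "))
  }
  check_ann(base_pairs, LW_CLASSES, "base-pair", "lw")
  check_ann(stackings, STACK_CLASSES, "stacking", "direction")
  structure(list(location = location, nucleotides = nucleotides,
                 base_pairs = base_pairs, stackings = stackings,
                 family = family),
            class = "rna_loop")
}

#' @export
print.rna_loop <- function(x, ...) {
  cat("<rna_loop> ", format_loop_location(x$location),
      "  n=", length(x$nucleotides),
      "  bp=", nrow(x$base_pairs), "  stk=", nrow(x$stackings),
      if (!is.null(x$family)) paste0("  family=", x$family) else "", "\n", sep = "")
  invisible(x)
}

#' @export
length.rna_loop <- function(x) length(x$nucleotides)

#' Sequence of a loop, one string per strand
#' @param loop an `rna_loop`.
#' @return character vector of strand sequences ("N" for non-standard bases).
#' @export
loop_sequences <- function(loop) {
  bases <- vapply(loop$nucleotides, function(nt)
    if (nt$base %in% STANDARD_BASES) nt$base else "N", character(1))
  seg <- loop$location$segments
  lens <- seg$end - seg$start + 1L
  ends <- cumsum(lens); starts <- ends - lens + 1L
  vapply(seq_len(nrow(seg)), function(k)
    paste(bases[starts[k]:ends[k]], collapse = ""), character(1))
}

#' Identifier string of a loop (its formatted location)
#' @param loop an `rna_loop`.
#' @return a string.
#' @export
loop_id <- function(loop) format_loop_location(loop$location)
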