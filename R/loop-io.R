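#' Read and write loop files
#'
#' The loop file is a plain-text TSV dialect, one block per loop:
#' a header line `>LOCATION<TAB>FAMILY` (family optional), one `SEQ` line per
#' strand (5'->3'), then zero or more annotation lines
#' `BP<TAB>i<TAB>j<TAB>CLASS` and `STK<TAB>i<TAB>j<TAB>DIRECTION` with
#' 0-based loop-internal indices. Residue numbers of the nucleotides follow
#' from the location ranges.
#'
#' @param path file path.
#' @return `read_loop_file`: a list of [rna_loop()] objects.
#' @export
read_loop_file <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(list())
  starts <- grep("^>", lines)
  if (length(starts) == 0L || starts[1] != 1L)
    stop("loop file must start with a '>' header line: ", path)
  ends <- c(starts[-1] - 1L, length(lines))
  loops <- vector("list", length(starts))
  lineno <- function(local) local  # indices into the filtered lines; report raw text instead
  for (b in seq_along(starts)) {
    block <- lines[starts[b]:ends[b]]
    head_parts <- strsplit(sub("^>", "", block[1]), "\t", fixed = TRUE)[[1]]
    loc <- parse_loop_location(head_parts[1])
    family <- if (length(head_parts) >= 2L && nzchar(head_parts[2])) head_parts[2] else NULL
    body <- block[-1]
    tag <- sub("\t.*$", "", body)
    seqs <- sub("^SEQ\t", "", body[tag == "SEQ"])
    seg <- loc$segments
    if (length(seqs) != nrow(seg))
      stop("loop ", head_parts[1], ": ", length(seqs), " SEQ lines for ",
           nrow(seg), " segments")
    nts <- list()
    for (k in seq_len(nrow(seg))) {
      resnums <- seq.int(seg$start[k], seg$end[k])
      bases <- strsplit(seqs[k], "")[[1]]
      if (length(bases) != length(resnums))
        stop("loop ", head_parts[1], ": segment ", k, " sequence length ",
             length(bases), " != range length ", length(resnums))
      nts <- c(nts, lapply(seq_along(resnums), function(t)
        nucleotide(resnums[t], bases[t])))
    }
    parse_ann <- function(kind, classes) {
      rows <- body[tag == kind]
      if (length(rows) == 0L)
        return(data.frame(i = integer(), j = integer(), cls = character()))
      parts <- strsplit(rows, "\t", fixed = TRUE)
      out <- lapply(seq_along(parts), function(r) {
        p <- parts[[r]]
        if (length(p) != 4L)
          stop("malformed ", kind, " line in block ", head_parts[1], ": ", rows[r])
        if (!p[4] %in% classes)
          stop("unknown ", kind, " class ", sQuote(p[4]), " in line: ", rows[r])
        data.frame(i = as.integer(p[2]) + 1L, j = as.integer(p[3]) + 1L, cls = p[4])
      })
      do.call(rbind, out)
    }
    bp <- parse_ann("BP", LW_CLASSES); names(bp) <- c("i", "j", "lw")
    stk <- parse_ann("STK", STACK_CLASSES); names(stk) <- c("i", "j", "direction")
    unknown <- setdiff(unique(tag), c("SEQ", "BP", "STK"))
    if (length(unknown))
      stop("unknown line tag(s) ", paste(unknown, collapse = ", "),
           " in block ", head_parts[1])
    loops[[b]] <- rna_loop(loc, nts, bp, stk, family)
  }
  loops
}

#' @param loops list of `rna_loop` objects.
#' @rdname read_loop_file
#' @return `write_loop_file`: the path, invisibly. `write(read(x))` is the
#'   identity on every field.
#' @export
write_loop_file <- function(loops, path) {
  con <- file(path, "w"); on.exit(close(con))
  for (loop in loops) {
    header <- paste0(">", loop_id(loop),
                     if (!is.null(loop$family)) paste0("\t", loop$family) else "")
    writeLines(header, con)
    for (s in loop_sequences(loop)) writeLines(paste0("SEQ\t", s), con)
    bp <- loop$base_pairs
    for (r in seq_len(nrow(bp)))
      writeLines(sprintf("BP\t%d\t%d\t%s", bp$i[r] - 1L, bp$j[r] - 1L, bp$lw[r]), con)
    stk <- loop$stackings
    for (r in seq_len(nrow(stk)))
      writeLines(sprintf("STK\t%d\t%d\t%s", stk$i[r] - 1L, stk$j[r] - 1L,
                         stk$direction[r]), con)
  }
  invisible(path)
}

#' Read / write a flat coordinate file
#'
#' TSV with columns `loop_id  nt_index  atom_name  x  y  z` (Angstrom),
#' `nt_index` 0-based within the loop's nucleotide list.
#'
#' @param path file path.
#' @return a data frame with those six columns.
#' @export
read_coordinate_file <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "")
  need <- c("loop_id", "nt_index", "atom_name", "x", "y", "z")
  if (!all(need %in% names(df)))
    stop("coordinate file must have columns: ", paste(need, collapse = ", "))
  df[need]
}

#' @param coords data frame as returned by [read_coordinate_file()].
#' @rdname read_coordinate_file
#' @export
write_coordinate_file <- function(coords, path) {
  utils::write.table(coords, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Extract a coordinate table from a set of loops
#'
#' Inverse companion of [attach_coordinates()]: flattens the backbone-atom
#' coordinates of each loop into the flat coordinate-file layout.
#'
#' @param loops list of `rna_loop` objects with coordinates attached.
#' @return a coordinate data frame.
#' @export
loops_to_coordinates <- function(loops) {
  rows <- list()
  for (loop in loops) {
    id <- loop_id(loop)
    for (t in seq_along(loop$nucleotides)) {
      xyz <- loop$nucleotides[[t]]$coords
      if (is.null(xyz)) next
      rows[[length(rows) + 1L]] <- data.frame(
        loop_id = id, nt_index = t - 1L, atom_name = rownames(xyz),
        x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], row.names = NULL)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(loop_id = character(), nt_index = integer(),
                      atom_name = character(), x = numeric(), y = numeric(),
                      z = numeric()))
  do.call(rbind, rows)
}

#' Attach backbone-atom coordinates to loops
#'
#' Fills the `coords` slot of every nucleotide from either a flat coordinate
#' table (see [read_coordinate_file()]) or a parsed structure (a `bio3d`
#' `pdb` object, or a path to a `.pdb`/`.cif` file). Nucleotides with no
#' matching atom record are flagged in the returned `missing` attribute
#' (they are not fatal; the graph encoder rejects them later). A chain
#' absent from a structure source is an error.
#'
#' @param loops list of `rna_loop` objects.
#' @param source a coordinate data frame, a path to a coordinate TSV, a
#'   `bio3d` pdb object, or a path to a PDB/mmCIF file.
#' @return the loops, with coordinates filled; attribute `missing` is a
#'   data frame listing (loop_id, nt_index) of nucleotides left without
#'   coordinates.
#' @export
attach_coordinates <- function(loops, source) {
  if (is.character(source) && length(source) == 1L) {
    if (grepl("\\.(pdb|ent|cif)$", source, ignore.case = TRUE)) {
      if (!requireNamespace("bio3d", quietly = TRUE))
        stop("reading PDB/mmCIF files requires the 'bio3d' package")
      source <- if (grepl("\\.cif$", source, ignore.case = TRUE))
        bio3d::read.cif(source) else bio3d::read.pdb(source)
    } else {
      source <- read_coordinate_file(source)
    }
  }
  if (inherits(source, "pdb")) {
    atoms <- source$atom
    tab <- data.frame(chain = atoms$chain, resno = atoms$resno,
                      atom_name = atoms$elety,
                      x = atoms$x, y = atoms$y, z = atoms$z,
                      stringsAsFactors = FALSE)
    lookup <- function(loop, t) {
      nt <- loop$nucleotides[[t]]
      ch <- loop$location$chain
      if (!ch %in% tab$chain)
        stop("chain ", sQuote(ch), " not found in structure for loop ",
             loop_id(loop))
      sel <- tab$chain == ch & tab$resno == nt$residue_number &
        tab$atom_name %in% BACKBONE_ATOMS
      tab[sel, c("atom_name", "x", "y", "z")]
    }
  } else {
    stopifnot(is.data.frame(source))
    lookup <- function(loop, t) {
      sel <- source$loop_id == loop_id(loop) & source$nt_index == t - 1L &
        source$atom_name %in% BACKBONE_ATOMS
      source[sel, c("atom_name", "x", "y", "z")]
    }
  }
  missing <- list()
  for (li in seq_along(loops)) {
    loop <- loops[[li]]
    for (t in seq_along(loop$nucleotides)) {
      rec <- lookup(loop, t)
      if (nrow(rec) == 0L) {
        missing[[length(missing) + 1L]] <-
          data.frame(loop_id = loop_id(loop), nt_index = t - 1L)
        next
      }
      xyz <- as.matrix(rec[, c("x", "y", "z")])
      rownames(xyz) <- rec$atom_name
      loop$nucleotides[[t]]$coords <- xyz
    }
    loops[[li]] <- loop
  }
  attr(loops, "missing") <- if (length(missing)) do.call(rbind, missing) else
    data.frame(loop_id = character(), nt_index = integer())
  loops
}
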