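#' Vocabularies for base-pair and base-stacking annotations
#'
#' The 18 directional Leontis-Westhof base-pair classes, in the fixed order
#' used throughout the edge-feature encoding, the 4 base-stacking directions,
#' and the 6 nucleotide backbone atom names.
#'
#' @name vocabularies
NULL

#' @rdname vocabularies
#' @export
LW_CLASSES <- c("cWW", "cWH", "cHW", "cWS", "cSW", "cHH", "cHS", "cSH", "cSS",
                "tWW", "tWH", "tHW", "tWS", "tSW", "tHH", "tHS", "tSH", "tSS")

#' @rdname vocabularies
#' @export
STACK_CLASSES <- c("upward", "downward", "inward", "outward")

#' @rdname vocabularies
#' @export
BACKBONE_ATOMS <- c("C3'", "C4'", "C5'", "O3'", "O5'", "P")

#' @rdname vocabularies
#' @export
STANDARD_BASES <- c("A", "C", "G", "U")

#' Reverse the direction of a Leontis-Westhof class token
#'
#' A pair annotated `i -> j` with class `xYZ` (orientation x, edge Y of i,
#' edge Z of j) is seen from `j -> i` as `xZY`: the interacting edges swap,
#' the glycosidic orientation does not.
#'
#' @param lw character vector of LW class tokens.
#' @return character vector of reversed tokens.
#' @export
#' @examples
#' lw_transpose("tHS")  # "tSH"
lw_transpose <- function(lw) {
  stopifnot(all(lw %in% LW_CLASSES))
  paste0(substr(lw, 1, 1), substr(lw, 3, 3), substr(lw, 2, 2))
}

#' Reverse the direction of a stacking annotation
#'
#' Seen from the opposite direction, an upward stack is downward and vice
#' versa; inward and outward are self-symmetric.
#'
#' @param direction character vector of stacking directions.
#' @return character vector of reversed directions.
#' @export
stack_transpose <- function(direction) {
  stopifnot(all(direction %in% STACK_CLASSES))
  map <- c(upward = "downward", downward = "upward",
           inward = "inward", outward = "outward")
  unname(map[direction])
}

# edge occupied on each partner by a pair record: class xYZ uses edge Y of i
# and edge Z of j
lw_edges <- function(lw) {
  stopifnot(all(lw %in% LW_CLASSES))
  cbind(i_edge = substr(lw, 2, 2), j_edge = substr(lw, 3, 3))
}
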