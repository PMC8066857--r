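# Linear-rule encoding over the radius-1 Moore neighborhood.
#
# Bit b (b = 0..8) of the 9-bit rule integer selects the offset with index
# b + 1 in the fixed row-major enumeration below. The assignment of powers
# of two to neighbors is a declared convention: any bijection yields the
# same detector family up to a relabeling of the rule integer.

#' Moore neighborhood offsets
#'
#' The nine (row, col) offsets of the radius-1 Moore neighborhood in
#' row-major order: (-1,-1), (-1,0), (-1,1), (0,-1), (0,0), (0,1),
#' (1,-1), (1,0), (1,1). Bit \code{b} (0-based) of a linear rule selects
#' offset \code{b + 1} of this enumeration.
#'
#' @format An integer matrix with 9 rows and columns \code{dr}, \code{dc}.
#' @export
moore_offsets <- local({
  m <- cbind(dr = rep(-1:1, each = 3L), dc = rep(-1:1, times = 3L))
  storage.mode(m) <- "integer"
  m
})

rule_to_bits <- function(rule) {
  if (length(rule) != 1L || is.na(rule) || rule != as.integer(rule) ||
      rule < 0 || rule > 511) {
    stop("'rule' must be a single integer in 0..511", call. = FALSE)
  }
  as.logical(bitwAnd(as.integer(rule), bitwShiftL(1L, 0:8)))
}

#' Decode a linear rule into a neighbor mask
#'
#' Expands the 9-bit rule integer into the set of Moore-neighborhood
#' offsets that participate in the local difference sum.
#'
#' @param rule Integer in 0..511.
#' @return An integer matrix with columns \code{dr}, \code{dc}; one row per
#'   selected offset (zero rows for rule 0).
#' @examples
#' decode_rule(1)    # just the (-1,-1) corner
#' decode_rule(511)  # the full neighborhood
#' @export
decode_rule <- function(rule) {
  moore_offsets[rule_to_bits(rule), , drop = FALSE]
}

#' Encode a neighbor mask as a linear rule
#'
#' Inverse of [decode_rule()]: maps a set of Moore-neighborhood offsets to
#' the 9-bit rule integer.
#'
#' @param mask Two-column matrix (or data frame) of (row, col) offsets,
#'   each in \{-1, 0, 1\}; duplicate rows are not allowed.
#' @return Integer in 0..511.
#' @export
encode_rule <- function(mask) {
  mask <- as.matrix(mask)
  if (nrow(mask) == 0L) return(0L)
  if (ncol(mask) != 2L || !all(mask %in% c(-1L, 0L, 1L))) {
    stop("mask offsets must be pairs drawn from {-1, 0, 1}^2", call. = FALSE)
  }
  idx <- match(paste(mask[, 1L], mask[, 2L]),
               paste(moore_offsets[, 1L], moore_offsets[, 2L]))
  if (anyNA(idx) || anyDuplicated(idx)) {
    stop("mask contains invalid or duplicated offsets", call. = FALSE)
  }
  sum(bitwShiftL(1L, idx - 1L))
}
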