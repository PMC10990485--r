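# Category templates, rotations and quadruplet realisation.
#
# A template is a 3x2 integer matrix of transition vectors (columns di, dj),
# one row per step. Compass convention: N = (0,+1), E = (+1,0); diagonals
# combine them. Rotations are counterclockwise multiples of 90 degrees.

.compass <- list(
  N = c(0L, 1L), S = c(0L, -1L), E = c(1L, 0L), W = c(-1L, 0L),
  NE = c(1L, 1L), NW = c(-1L, 1L), SE = c(1L, -1L), SW = c(-1L, -1L)
)

step_matrix <- function(...) {
  m <- do.call(rbind, lapply(list(...), function(d) .compass[[d]]))
  dimnames(m) <- list(NULL, c("di", "dj"))
  m
}

#' Canonical category templates
#'
#' The three categories of the quadruplet task, each an ordered triple of
#' compass transition vectors: category 0 is \{E, N, W\}, category 1 is
#' \{NE, W, SE\}, category 2 is \{N, SE, N\}. Walking a template from a
#' suitable start cell visits the four cells of one unit square.
#'
#' @return a list of three 3x2 integer matrices (columns \code{di},
#'   \code{dj}), named \code{"0"}, \code{"1"}, \code{"2"}.
#' @export
#' @examples
#' canonical_templates()[["1"]] # NE, W, SE
canonical_templates <- function() {
  list(
    "0" = step_matrix("E", "N", "W"),
    "1" = step_matrix("NE", "W", "SE"),
    "2" = step_matrix("N", "SE", "N")
  )
}

#' Rotate a template counterclockwise
#'
#' Rotates every transition vector of a template by a multiple of 90 degrees
#' counterclockwise, e.g. \{NE, W, SE\} becomes \{NW, S, NE\} after 90.
#'
#' @param template a 3x2 integer matrix of transition vectors.
#' @param rotation one of 0, 90, 180, 270.
#' @return the rotated template.
#' @export
rotate_template <- function(template, rotation) {
  if (!rotation %in% c(0, 90, 180, 270)) {
    stop("rotation must be a multiple of 90 in {0, 90, 180, 270}")
  }
  out <- template
  for (q in seq_len((rotation %/% 90) %% 4)) {
    out <- cbind(di = -out[, "dj"], dj = out[, "di"])
  }
  out
}

# Position offsets (relative to the anchor, the lower-left corner of the
# occupied unit square) of the four stimuli for one category x rotation.
# Each rotated template admits exactly one start corner keeping the walk
# inside the unit square; cached after first use.
.offset_cache <- new.env(parent = emptyenv())

quad_offsets <- function(category, rotation) {
  key <- paste(category, rotation, sep = ":")
  if (!is.null(.offset_cache[[key]])) return(.offset_cache[[key]])
  tmpl <- rotate_template(canonical_templates()[[as.character(category)]], rotation)
  square <- rbind(c(0L, 0L), c(1L, 0L), c(0L, 1L), c(1L, 1L))
  found <- NULL
  for (s in seq_len(4)) {
    pos <- matrix(0L, 4, 2)
    pos[1, ] <- square[s, ]
    for (t in 1:3) pos[t + 1, ] <- pos[t, ] + tmpl[t, ]
    inside <- all(pos >= 0L & pos <= 1L)
    if (inside && nrow(unique(pos)) == 4L) {
      if (!is.null(found)) stop("template walk start is not unique")
      found <- pos
    }
  }
  if (is.null(found)) stop("no in-square walk exists for this template")
  colnames(found) <- c("i", "j")
  .offset_cache[[key]] <- found
  found
}

#' Realise a quadruplet trial
#'
#' Places a category's (rotated) transition-vector walk at a given anchor,
#' the lower-left corner of the occupied unit square. Anchors range over the
#' nine positions \code{[0,2] x [0,2]} so that every walk stays on the 4x4
#' grid; the start stimulus within the square is the unique cell from which
#' the rotated walk stays in-square.
#'
#' @param category integer in 0:2.
#' @param rotation one of 0, 90, 180, 270.
#' @param anchor length-2 integer vector in \code{[0,2]^2}.
#' @param far_transfer logical; whether the trial lives on the far-transfer
#'   grid (metadata: coordinates are unchanged).
#' @return a list with elements \code{category}, \code{rotation},
#'   \code{far_transfer}, \code{anchor} and \code{positions} (a 4x2 matrix).
#' @export
#' @examples
#' realise_quadruplet(0, 0, c(0, 0))$positions
realise_quadruplet <- function(category, rotation, anchor, far_transfer = FALSE) {
  stopifnot(category %in% 0:2, length(anchor) == 2)
  if (any(anchor < 0) || any(anchor > 2)) {
    stop("invalid anchor: must lie in [0,2] x [0,2]")
  }
  pos <- quad_offsets(category, rotation)
  pos[, 1] <- pos[, 1] + as.integer(anchor[1])
  pos[, 2] <- pos[, 2] + as.integer(anchor[2])
  list(
    category = as.integer(category), rotation = as.integer(rotation),
    far_transfer = isTRUE(far_transfer),
    anchor = as.integer(anchor), positions = pos
  )
}

#' Enumerate all quadruplets for a set of rotations
#'
#' Deterministic enumeration of every category x rotation x anchor trial,
#' used for ideal-observer derivations and exact accuracy benchmarks.
#'
#' @param rotations non-empty subset of \code{c(0, 90, 180, 270)}.
#' @param far_transfer logical flag recorded on every trial.
#' @return a trial data.frame (one row per quadruplet) with the position
#'   columns \code{pos1_i .. pos4_j}.
#' @export
enumerate_quadruplets <- function(rotations, far_transfer = FALSE) {
  if (length(rotations) == 0) stop("rotations must be non-empty")
  stopifnot(all(rotations %in% c(0, 90, 180, 270)))
  grid <- expand.grid(
    anchor_j = 0:2, anchor_i = 0:2,
    rotation_deg = sort(unique(as.integer(rotations))), category = 0:2
  )[, 4:1]
  n <- nrow(grid)
  pos <- matrix(NA_integer_, n, 8)
  colnames(pos) <- as.vector(t(outer(paste0("pos", 1:4), c("_i", "_j"), paste0)))
  for (r in seq_len(n)) {
    p <- quad_offsets(grid$category[r], grid$rotation_deg[r])
    pos[r, ] <- as.vector(t(cbind(p[, 1] + grid$anchor_i[r], p[, 2] + grid$anchor_j[r])))
  }
  out <- cbind(grid, as.data.frame(pos))
  out$far_transfer <- isTRUE(far_transfer)
  rownames(out) <- NULL
  out
}

#' Level pattern of a quadruplet along one dimension
#'
#' Reduces the four stimuli to a four-letter token over \code{A}/\code{B} on
#' the chosen dimension, where \code{A} is the lower of the two feature
#' levels occupied. Unsigned patterns identify a token with its A/B swap
#' (e.g. \code{"BABA"} and \code{"ABAB"} share a representative); the
#' canonical representative is the lexicographically smaller of the pair.
#'
#' @param positions 4x2 matrix of grid positions (or a trial list from
#'   \code{\link{realise_quadruplet}}).
#' @param dimension \code{"i"} or \code{"j"}.
#' @param signed logical; if \code{FALSE} the unsigned representative is
#'   returned.
#' @return a single pattern token such as \code{"ABAB"}.
#' @export
pattern_of <- function(positions, dimension = c("i", "j"), signed = TRUE) {
  dimension <- match.arg(dimension)
  if (is.list(positions) && !is.null(positions$positions)) {
    positions <- positions$positions
  }
  v <- positions[, if (dimension == "i") 1L else 2L]
  lev <- sort(unique(v))
  if (length(lev) != 2L) stop("quadruplet must occupy exactly two levels per dimension")
  tok <- paste(c("A", "B")[match(v, lev)], collapse = "")
  if (signed) tok else unsigned_pattern(tok)
}

#' @rdname pattern_of
#' @param token a signed pattern token.
#' @export
unsigned_pattern <- function(token) {
  swapped <- chartr("AB", "BA", token)
  ifelse(token <= swapped, token, swapped)
}

# Vectorised signed patterns for a trial table (used by model predictions).
patterns_from_trials <- function(trials, dimension) {
  cols <- paste0("pos", 1:4, if (dimension == "i") "_i" else "_j")
  m <- as.matrix(trials[, cols])
  lo <- pmin(m[, 1], m[, 2], m[, 3], m[, 4])
  letters_m <- matrix("A", nrow(m), 4)
  letters_m[m > lo] <- "B"
  paste0(letters_m[, 1], letters_m[, 2], letters_m[, 3], letters_m[, 4])
}
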