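# Ideal-observer strategy models.
#
# Eleven static models assign a probability distribution over the three
# categories to every quadruplet:
#   R      responds uniformly at random (k = 0 free parameters);
#   Rp     ("R-prime") responds with the true category on training trials and
#          uniformly on transfer trials (the non-generalising model);
#   1Di_u, 1Dj_u, 1Di_s, 1Dj_s track the level pattern along one dimension,
#          unsigned (_u: a token and its A/B swap are identified) or signed;
#   2D     matches the full transition-vector sequence against the rotated
#          templates and is therefore rotation- and translation-invariant;
#   1Dij_u, 1Dji_u, 1Dij_s, 1Dji_s (far-transfer roster only) track one
#          dimension during training but read the *other* far-transfer
#          dimension as its continuation (first letter: trained dimension,
#          second: the far dimension treated as it).
# All models except R carry one free softmax temperature when fitted.

#' Model rosters
#'
#' The seven models fitted to training + near-transfer choices, or the
#' eleven fitted to training + far-transfer choices (adding the four
#' cross-mapped one-dimensional variants).
#'
#' @param transfer_kind \code{"near"} or \code{"far"}.
#' @return a named list of model specs (lists with \code{name},
#'   \code{family}, \code{dim}, \code{signed}, \code{far_dim},
#'   \code{n_params}).
#' @export
#' @examples
#' names(model_roster("near"))
model_roster <- function(transfer_kind = c("near", "far")) {
  transfer_kind <- match.arg(transfer_kind)
  spec <- function(name, family, dim = NA, signed = NA, far_dim = dim) {
    list(name = name, family = family, dim = dim, signed = signed,
         far_dim = far_dim, n_params = if (name == "R") 0L else 1L)
  }
  ms <- list(
    spec("R", "random"),
    spec("Rp", "random"),
    spec("1Di_u", "oneD", "i", FALSE),
    spec("1Dj_u", "oneD", "j", FALSE),
    spec("1Di_s", "oneD", "i", TRUE),
    spec("1Dj_s", "oneD", "j", TRUE),
    spec("2D", "twoD")
  )
  if (transfer_kind == "far") {
    ms <- c(ms, list(
      spec("1Dij_u", "oneD", "i", FALSE, far_dim = "j"),
      spec("1Dji_u", "oneD", "j", FALSE, far_dim = "i"),
      spec("1Dij_s", "oneD", "i", TRUE, far_dim = "j"),
      spec("1Dji_s", "oneD", "j", TRUE, far_dim = "i")
    ))
  }
  setNames(ms, vapply(ms, `[[`, character(1), "name"))
}

#' Prediction context
#'
#' The training distribution a model is idealised on: which rotations were
#' shown with feedback (0 only in experiment 1; 0 and 90 in experiments
#' 2 to 4).
#'
#' @param trained_rotations non-empty subset of \code{c(0, 90, 180, 270)}.
#' @return a list with element \code{trained_rotations}.
#' @export
prediction_context <- function(trained_rotations = 0) {
  stopifnot(length(trained_rotations) >= 1,
            all(trained_rotations %in% c(0, 90, 180, 270)))
  list(trained_rotations = sort(unique(as.integer(trained_rotations))))
}

#' Ideal pattern-to-category mapping of a one-dimensional model
#'
#' Enumerates the training distribution (all categories x trained rotations
#' x nine anchors, weighted equally) and returns, for each realisable
#' pattern token on the tracked dimension, the probability vector uniform
#' over the categories that produce it. Patterns never seen in training map
#' to the uniform distribution.
#'
#' @param model a one-dimensional model spec from \code{\link{model_roster}}.
#' @param context a \code{\link{prediction_context}}.
#' @return a named list of length-3 probability vectors, keyed by token.
#' @export
derive_ideal_mapping <- function(model, context) {
  if (!identical(model$family, "oneD")) {
    stop("ideal mappings are defined for one-dimensional models only")
  }
  trials <- enumerate_quadruplets(context$trained_rotations)
  tok <- patterns_from_trials(trials, model$dim)
  if (!model$signed) tok <- unsigned_pattern(tok)
  counts <- table(tok, factor(trials$category, levels = 0:2))
  mapping <- lapply(rownames(counts), function(tt) {
    as.numeric(counts[tt, ] / sum(counts[tt, ]))
  })
  setNames(mapping, rownames(counts))
}

.mapping_cache <- new.env(parent = emptyenv())

cached_mapping <- function(model, context) {
  key <- paste(model$dim, model$signed, paste(context$trained_rotations, collapse = ","))
  if (is.null(.mapping_cache[[key]])) {
    .mapping_cache[[key]] <- derive_ideal_mapping(model, context)
  }
  .mapping_cache[[key]]
}

# Lookup from the 12 rotated vector sequences to their category; the
# sequences are pairwise distinct so matching is unambiguous.
template_keys <- function() {
  if (is.null(.mapping_cache[["..template_keys"]])) {
    keys <- character(0)
    cats <- integer(0)
    for (cc in 0:2) for (rr in c(0, 90, 180, 270)) {
      tmpl <- rotate_template(canonical_templates()[[as.character(cc)]], rr)
      keys <- c(keys, paste(t(tmpl), collapse = ","))
      cats <- c(cats, cc)
    }
    stopifnot(!anyDuplicated(keys))
    .mapping_cache[["..template_keys"]] <- setNames(cats, keys)
  }
  .mapping_cache[["..template_keys"]]
}

vector_sequence_keys <- function(trials) {
  pi_ <- as.matrix(trials[, paste0("pos", 1:4, "_i")])
  pj_ <- as.matrix(trials[, paste0("pos", 1:4, "_j")])
  di <- pi_[, 2:4, drop = FALSE] - pi_[, 1:3, drop = FALSE]
  dj <- pj_[, 2:4, drop = FALSE] - pj_[, 1:3, drop = FALSE]
  paste(di[, 1], dj[, 1], di[, 2], dj[, 2], di[, 3], dj[, 3], sep = ",")
}

#' Model predictions for a table of quadruplet trials
#'
#' Returns the category probabilities each model assigns to each trial.
#' One-dimensional models look the trial's pattern up in their ideal
#' mapping; on far-transfer trials the cross-mapped variants read their
#' \code{far_dim} instead of the trained dimension (plain one-dimensional
#' models treat the far dimensions as direct continuations). The 2D model
#' template-matches the full vector sequence under all four rotations; Rp
#' responds with the true category on feedback-bearing training trials and
#' uniformly otherwise.
#'
#' @param model a model spec.
#' @param context a \code{\link{prediction_context}}.
#' @param trials a trial data.frame (only \code{task == "quadruplet"} rows
#'   are meaningful).
#' @return an \code{nrow(trials) x 3} matrix of probabilities, rows summing
#'   to one.
#' @export
predict_categories <- function(model, context, trials) {
  n <- nrow(trials)
  P <- matrix(1 / 3, n, 3)
  if (model$name == "R") return(P)
  if (model$name == "Rp") {
    is_train <- if ("phase" %in% names(trials)) trials$phase == "training" else
      trials$rotation_deg %in% context$trained_rotations & !trials$far_transfer
    idx <- which(is_train)
    P[idx, ] <- 0
    P[cbind(idx, trials$category[idx] + 1L)] <- 1
    return(P)
  }
  if (model$family == "twoD") {
    keys <- vector_sequence_keys(trials)
    cat_hat <- template_keys()[keys]
    if (anyNA(cat_hat)) stop("corrupt quadruplet: no template matches its vector sequence")
    P[] <- 0
    P[cbind(seq_len(n), cat_hat + 1L)] <- 1
    return(P)
  }
  # one-dimensional trackers
  mapping <- cached_mapping(model, context)
  use_dim <- ifelse(trials$far_transfer, model$far_dim, model$dim)
  tok <- character(n)
  for (d in c("i", "j")) {
    sel <- use_dim == d
    if (any(sel)) tok[sel] <- patterns_from_trials(trials[sel, , drop = FALSE], d)
  }
  if (!model$signed) tok <- unsigned_pattern(tok)
  hit <- match(tok, names(mapping))
  known <- !is.na(hit)
  if (any(known)) {
    P[known, ] <- do.call(rbind, mapping[hit[known]])
  }
  P
}

#' Expected training accuracy of a model
#'
#' Exact expected proportion correct over the uniform training distribution
#' (all categories x trained rotations x nine anchors), responding with the
#' argmax category and breaking ties uniformly.
#'
#' @param model a model spec.
#' @param context a \code{\link{prediction_context}}.
#' @return a proportion in \code{[0, 1]}.
#' @export
#' @examples
#' training_accuracy(model_roster("near")[["2D"]], prediction_context(c(0, 90)))
training_accuracy <- function(model, context) {
  trials <- enumerate_quadruplets(context$trained_rotations)
  trials$phase <- "training" # Rp sees these as feedback trials
  P <- predict_categories(model, context, trials)
  rowmax <- P == matrixStats_rowMaxs(P)
  mean(rowmax[cbind(seq_len(nrow(P)), trials$category + 1L)] / rowSums(rowmax))
}

# max per row without extra dependencies
matrixStats_rowMaxs <- function(P) {
  apply(P, 1, max)
}

#' Dump model predictions for audit
#'
#' Enumerates all category x rotation x anchor trials (optionally on the
#' far-transfer grid) and tabulates each roster model's category
#' probabilities, one row per model x trial.
#'
#' @param context a \code{\link{prediction_context}}.
#' @param rotations rotations to enumerate.
#' @param far_transfer logical.
#' @param transfer_kind roster to use.
#' @return a data.frame with columns model, category, rotation_deg,
#'   far_transfer, anchor_i, anchor_j, p0, p1, p2.
#' @export
prediction_table <- function(context, rotations = c(0, 90, 180, 270),
                             far_transfer = FALSE,
                             transfer_kind = if (far_transfer) "far" else "near") {
  trials <- enumerate_quadruplets(rotations, far_transfer = far_transfer)
  trials$phase <- ifelse(trials$rotation_deg %in% context$trained_rotations &
                           !trials$far_transfer, "training",
                         ifelse(trials$far_transfer, "far_transfer", "near_transfer"))
  out <- lapply(model_roster(transfer_kind), function(m) {
    P <- predict_categories(m, context, trials)
    data.frame(model = m$name,
               trials[, c("category", "rotation_deg", "far_transfer",
                          "anchor_i", "anchor_j")],
               p0 = P[, 1], p1 = P[, 2], p2 = P[, 3])
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
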