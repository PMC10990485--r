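# Softmax choice likelihood, temperature-grid fitting and BIC selection.
#
# Choice probabilities are the softmax of the model's category probabilities
# at temperature beta (division convention: exp(p/beta), so larger beta
# means noisier choices and beta = 0.5 is a high-noise regime). Likelihoods
# are maximised over 200 linearly spaced temperatures in [0.01, 0.5].

#' Temperature grid used for maximum-likelihood fitting
#' @return 200 linearly spaced values between 0.01 and 0.5, inclusive.
#' @export
beta_grid <- function() seq(0.01, 0.5, length.out = 200)

#' Softmax choice probability
#'
#' Probability of choosing a category given a model's prediction vector and
#' a softmax temperature: \code{exp(p[chosen]/beta) / sum(exp(p/beta))},
#' computed with max-subtraction for numerical stability.
#'
#' @param p_vec length-3 prediction vector.
#' @param beta positive temperature.
#' @param chosen category in 0:2.
#' @return a probability.
#' @export
#' @examples
#' response_probability(c(1, 0, 0), 0.5, 0) # exp(2) / (exp(2) + 2)
response_probability <- function(p_vec, beta, chosen) {
  if (beta <= 0) stop("beta must be positive")
  z <- p_vec / beta
  z <- z - max(z)
  exp(z[chosen + 1]) / sum(exp(z))
}

# Log-likelihood curve over a beta grid: P is the T x 3 prediction matrix,
# chosen the T-vector of choices (0-based). Models emit few distinct
# prediction vectors, so identical (prediction, choice) pairs are counted
# once and weighted.
loglik_curve <- function(P, chosen, betas) {
  key <- paste(P[, 1], P[, 2], P[, 3], chosen)
  first <- !duplicated(key)
  cnt <- tabulate(match(key, key[first]), nbins = sum(first))
  Pu <- P[first, , drop = FALSE]
  chu <- chosen[first] + 1L
  idx <- cbind(seq_len(nrow(Pu)), chu)
  vapply(betas, function(b) {
    Z <- Pu / b
    m <- apply(Z, 1, max)
    sum(cnt * (Z[idx] - m - log(rowSums(exp(Z - m)))))
  }, numeric(1))
}

#' Log-likelihood of a model for one participant
#'
#' Sum over trials of the log softmax choice probability.
#'
#' @param model a model spec from \code{\link{model_roster}}.
#' @param data a choice table: trial columns plus \code{chosen_category}.
#' @param beta softmax temperature.
#' @param context a \code{\link{prediction_context}}; defaults to the
#'   rotations present on the data's training trials.
#' @return a scalar log-likelihood.
#' @export
log_likelihood <- function(model, data, beta, context = data_context(data)) {
  if (nrow(data) == 0) stop("empty dataset")
  P <- predict_categories(model, context, data)
  loglik_curve(P, data$chosen_category, beta)
}

#' Infer the prediction context from a choice table
#'
#' The trained rotations are those occurring on \code{phase == "training"}
#' rows.
#'
#' @param data a choice or trial table with \code{phase} and
#'   \code{rotation_deg} columns.
#' @return a \code{\link{prediction_context}}.
#' @export
data_context <- function(data) {
  rots <- unique(data$rotation_deg[data$phase == "training"])
  if (length(rots) == 0) rots <- 0
  prediction_context(rots)
}

#' Fit one model to one participant by temperature-grid maximum likelihood
#'
#' For parametric models the temperature is the argmax of the likelihood
#' over \code{\link{beta_grid}} (ties resolved to the smallest value); the
#' parameter-free random model skips the grid. BIC is
#' \code{k * log(T) - 2 * logLik}.
#'
#' @inheritParams log_likelihood
#' @return a one-row data.frame: model, k, beta_hat, logLik, bic, n_trials.
#' @export
fit_model <- function(model, data, context = data_context(data)) {
  if (nrow(data) == 0) stop("empty dataset")
  T_ <- nrow(data)
  if (model$n_params == 0L) {
    ll <- T_ * log(1 / 3)
    beta_hat <- NA_real_
  } else {
    curve <- log_likelihood(model, data, beta_grid(), context)
    best <- which.max(curve) # which.max takes the first (smallest beta) tie
    beta_hat <- beta_grid()[best]
    ll <- curve[best]
  }
  data.frame(model = model$name, k = model$n_params, beta_hat = beta_hat,
             logLik = ll, bic = model$n_params * log(T_) - 2 * ll,
             n_trials = T_)
}

#' Fit the roster and select the best model for one participant
#'
#' Restricts the choice table to training plus the requested transfer
#' trials, fits every roster model, and selects the one with the lowest
#' BIC (ties resolved in roster order).
#'
#' @param data a choice table covering training and transfer phases.
#' @param transfer_kind \code{"near"} or \code{"far"}.
#' @return an object of class \code{rotgen_fit}: a list with \code{fits}
#'   (a data.frame, one row per model), \code{best_model},
#'   \code{transfer_kind} and \code{context}.
#' @export
select_best <- function(data, transfer_kind = c("near", "far")) {
  transfer_kind <- match.arg(transfer_kind)
  phases <- c("training", paste0(transfer_kind, "_transfer"))
  sub <- data[data$task == "quadruplet" & data$phase %in% phases, , drop = FALSE]
  if (!all(phases %in% sub$phase)) {
    stop("dataset is missing a required phase: ", paste(phases, collapse = ", "))
  }
  context <- data_context(sub)
  fits <- do.call(rbind, lapply(model_roster(transfer_kind), fit_model,
                                data = sub, context = context))
  rownames(fits) <- NULL
  best <- fits$model[which.min(fits$bic)]
  structure(list(fits = fits, best_model = best,
                 transfer_kind = transfer_kind, context = context,
                 participant_id = if ("participant_id" %in% names(data))
                   data$participant_id[1] else NA_character_),
            class = "rotgen_fit")
}

#' @export
print.rotgen_fit <- function(x, ...) {
  cat("Strategy-model fit (", x$transfer_kind, " transfer), best model: ",
      x$best_model, "\n", sep = "")
  print(x$fits, digits = 4)
  invisible(x)
}

#' Split a choice table by trial parity
#'
#' Even/odd split by 0-based position within the given subset: trials at
#' positions 0, 2, 4, ... form the even half (used for fitting), the rest
#' the odd half (held out for response matrices).
#'
#' @param data a choice table.
#' @return a list with elements \code{even} and \code{odd}.
#' @export
crossval_split <- function(data) {
  if (nrow(data) < 2) stop("need at least two trials to split")
  pos0 <- seq_len(nrow(data)) - 1L
  list(even = data[pos0 %% 2L == 0L, , drop = FALSE],
       odd = data[pos0 %% 2L == 1L, , drop = FALSE])
}

#' Response matrix for one transformation
#'
#' Row-normalised confusion matrix of true category against chosen
#' category, restricted to trials of one transformation (rotation and
#' far-transfer flag).
#'
#' @param data a choice table.
#' @param rotation rotation in degrees.
#' @param far_transfer logical.
#' @return a 3x3 matrix; rows with no trials are NA.
#' @export
response_matrix <- function(data, rotation, far_transfer = FALSE) {
  sub <- data[data$task == "quadruplet" & data$rotation_deg == rotation &
                data$far_transfer == far_transfer, , drop = FALSE]
  tab <- table(factor(sub$category, levels = 0:2),
               factor(sub$chosen_category, levels = 0:2))
  out <- unclass(tab / rowSums(tab))
  dimnames(out) <- list(true = 0:2, chosen = 0:2)
  out
}
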