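# Random-effects Bayesian group model selection.
#
# Each participant's strategy is treated as drawn from unknown population
# model frequencies r with a Dirichlet prior Dir(alpha0). Per-participant
# marginal likelihoods are approximated from BIC as exp(-BIC/2). Posteriors
# are computed with the standard variational scheme: iterate participant
# responsibilities proportional to evidence times exp(digamma terms), then
# update the Dirichlet concentrations, until the free energy converges. The
# free energy approximates the log group evidence and drives the
# between-group Bayes factor (pooled H0 vs split H1).

#' Log model evidence from BIC
#'
#' The BIC approximation to the log marginal likelihood,
#' \code{log p(C|M) = -BIC/2}.
#'
#' @param bic BIC value(s).
#' @return log-evidence value(s).
#' @export
evidence_from_bic <- function(bic) -bic / 2

#' Assemble a participants x models log-evidence matrix
#'
#' @param fits a list of \code{rotgen_fit} objects sharing one roster.
#' @return a numeric matrix, one row per participant, columns named by
#'   model.
#' @export
evidence_matrix <- function(fits) {
  models <- fits[[1]]$fits$model
  rows <- lapply(fits, function(f) {
    stopifnot(identical(f$fits$model, models))
    evidence_from_bic(f$fits$bic)
  })
  out <- do.call(rbind, rows)
  colnames(out) <- models
  rownames(out) <- vapply(fits, function(f) as.character(f$participant_id),
                          character(1))
  out
}

#' Collapse model evidences into families
#'
#' Family evidence per participant is the mean of the member evidences
#' (a uniform within-family prior). Computed in the log domain.
#'
#' @param log_evidence participants x models matrix of log evidences.
#' @param partition named list of character vectors of model names;
#'   families must be disjoint.
#' @return a participants x families log-evidence matrix.
#' @export
#' @examples
#' m <- matrix(c(-10, -12, -11), 1, dimnames = list(NULL, c("a", "b", "c")))
#' family_collapse(m, list(ab = c("a", "b"), c = "c"))
family_collapse <- function(log_evidence, partition) {
  members <- unlist(partition, use.names = FALSE)
  if (anyDuplicated(members)) stop("families must be disjoint")
  if (!all(members %in% colnames(log_evidence))) {
    stop("partition names models absent from the evidence matrix")
  }
  out <- vapply(partition, function(fam) {
    sub <- log_evidence[, fam, drop = FALSE]
    apply(sub, 1, logsumexp) - log(length(fam))
  }, numeric(nrow(log_evidence)))
  out <- matrix(out, nrow = nrow(log_evidence),
                dimnames = list(rownames(log_evidence), names(partition)))
  out
}

#' Random-effects Bayesian model selection
#'
#' Variational Dirichlet posterior over population model frequencies given
#' per-participant log evidences.
#'
#' @param log_evidence participants x models matrix of log evidences (rows
#'   may be shifted by any per-participant constant).
#' @param alpha0 prior Dirichlet concentration (scalar or per-model vector).
#' @param tol convergence threshold on the relative free-energy change.
#' @param max_iter iteration cap.
#' @return an object of class \code{rotgen_bms}: list with \code{alpha}
#'   (posterior concentrations), \code{freq} (expected model frequencies),
#'   \code{resp} (participant responsibilities), \code{free_energy} (the
#'   approximate log group evidence), and \code{free_energy_trace}.
#' @export
rfx_bms <- function(log_evidence, alpha0 = 1, tol = 1e-8, max_iter = 10000) {
  log_evidence <- as.matrix(log_evidence)
  K <- ncol(log_evidence)
  N <- nrow(log_evidence)
  alpha0 <- rep_len(alpha0, K)
  if (N == 0) {
    return(structure(list(alpha = alpha0, freq = alpha0 / sum(alpha0),
                          resp = matrix(numeric(0), 0, K),
                          free_energy = 0, free_energy_trace = numeric(0)),
                     class = "rotgen_bms"))
  }
  alpha <- alpha0
  trace <- numeric(0)
  free_energy <- function(alpha, z) {
    w <- digamma(alpha) - digamma(sum(alpha))
    acc <- sum(z * (log_evidence + rep(w, each = N) - log(pmax(z, 1e-300))))
    acc + lgamma(sum(alpha0)) - sum(lgamma(alpha0)) -
      lgamma(sum(alpha)) + sum(lgamma(alpha)) +
      sum((alpha0 - alpha) * w)
  }
  for (it in seq_len(max_iter)) {
    w <- digamma(alpha) - digamma(sum(alpha))
    lu <- log_evidence + rep(w, each = N)
    z <- exp(lu - apply(lu, 1, logsumexp))
    alpha <- alpha0 + colSums(z)
    trace <- c(trace, free_energy(alpha, z))
    if (it > 1 && abs(trace[it] - trace[it - 1]) <=
        tol * max(1, abs(trace[it]))) break
  }
  if (it == max_iter) stop("rfx_bms failed to converge within max_iter iterations")
  structure(list(alpha = setNames(alpha, colnames(log_evidence)),
                 freq = setNames(alpha / sum(alpha), colnames(log_evidence)),
                 resp = z, free_energy = trace[length(trace)],
                 free_energy_trace = trace),
            class = "rotgen_bms")
}

#' @export
print.rotgen_bms <- function(x, ...) {
  cat("Random-effects BMS:", length(x$freq), "models,",
      nrow(x$resp), "participants\n")
  print(round(x$freq, 4))
  cat("log group evidence:", format(x$free_energy, digits = 6), "\n")
  invisible(x)
}

#' Exceedance probabilities
#'
#' Posterior probability that each model is the most frequent in the
#' population, by Monte-Carlo sampling of the Dirichlet posterior.
#' Offered as a diagnostic; the between-group Bayes factor does not use it.
#'
#' @param bms a \code{rotgen_bms} object.
#' @param n_draws number of Dirichlet draws.
#' @param seed integer seed.
#' @return a named probability vector.
#' @export
exceedance_prob <- function(bms, n_draws = 1e5, seed = 1) {
  with_seed(seed, {
    K <- length(bms$alpha)
    g <- matrix(stats::rgamma(n_draws * K, shape = rep(bms$alpha, each = n_draws)),
                n_draws, K)
    win <- max.col(g, ties.method = "random")
    setNames(tabulate(win, K) / n_draws, names(bms$alpha))
  })
}

#' Between-group Bayes factor on model frequencies
#'
#' Compares H0, both groups share one population frequency profile, against
#' H1, each group has its own. The H0 evidence is the free energy of the
#' pooled cohort; the H1 evidence is the sum of the two groups' separate
#' free energies. Under a uniform prior over hypotheses,
#' \code{BF = (1 - p(H0|C)) / p(H0|C)}; BF > 1 favours a difference in
#' model frequencies.
#'
#' @param log_evidence_a,log_evidence_b participants x models log-evidence
#'   matrices over the same model roster.
#' @param alpha0 prior Dirichlet concentration.
#' @return an object of class \code{rotgen_bf}: list with \code{bf},
#'   \code{log_bf}, \code{p_h0}, \code{label}, and the three BMS fits.
#' @export
between_group_bf <- function(log_evidence_a, log_evidence_b, alpha0 = 1) {
  if (!identical(colnames(log_evidence_a), colnames(log_evidence_b))) {
    stop("the two groups must share one model roster")
  }
  fit_a <- rfx_bms(log_evidence_a, alpha0)
  fit_b <- rfx_bms(log_evidence_b, alpha0)
  fit_pooled <- rfx_bms(rbind(log_evidence_a, log_evidence_b), alpha0)
  log_bf <- (fit_a$free_energy + fit_b$free_energy) - fit_pooled$free_energy
  p_h0 <- 1 / (1 + exp(log_bf))
  structure(list(bf = exp(log_bf), log_bf = log_bf, p_h0 = p_h0,
                 label = interpret_bf(exp(log_bf)),
                 group_a = fit_a, group_b = fit_b, pooled = fit_pooled),
            class = "rotgen_bf")
}

#' @export
print.rotgen_bf <- function(x, ...) {
  cat("Between-group BF =", format(x$bf, digits = 4),
      paste0("(", x$label, ")"), "; p(H0|C) =",
      format(x$p_h0, digits = 4), "\n")
  invisible(x)
}

#' Interpret a Bayes factor on the customary evidence scale
#'
#' BF > 3, > 10 and > 100 count as substantial, strong and decisive
#' evidence for a difference in model frequencies; BF < 0.3, < 0.1 and
#' < 0.01 as substantial, strong and decisive evidence for no difference;
#' anything between 0.3 and 3 is weak.
#'
#' @param bf a positive Bayes factor.
#' @return a label string.
#' @export
#' @examples
#' interpret_bf(34) # "strong-difference"
interpret_bf <- function(bf) {
  if (!is.numeric(bf) || any(bf <= 0)) stop("bf must be positive")
  vapply(bf, function(b) {
    if (b > 100) "decisive-difference"
    else if (b > 10) "strong-difference"
    else if (b > 3) "substantial-difference"
    else if (b >= 0.3) "weak"
    else if (b >= 0.1) "substantial-null"
    else if (b >= 0.01) "strong-null"
    else "decisive-null"
  }, character(1))
}

#' Monte-Carlo estimate of the log group evidence
#'
#' Brute-force check of the variational free energy: draws population
#' frequency vectors from the Dirichlet prior and averages the exact
#' conditional likelihood of all participants. Practical only for small
#' rosters and cohorts; used as an independent oracle for
#' \code{\link{rfx_bms}}.
#'
#' @param log_evidence participants x models log-evidence matrix.
#' @param alpha0 prior Dirichlet concentration.
#' @param n_draws number of Monte-Carlo draws.
#' @param seed integer seed.
#' @return the estimated log evidence.
#' @export
group_evidence_mc <- function(log_evidence, alpha0 = 1, n_draws = 1e6, seed = 1) {
  log_evidence <- as.matrix(log_evidence)
  K <- ncol(log_evidence)
  N <- nrow(log_evidence)
  alpha0 <- rep_len(alpha0, K)
  shift <- apply(log_evidence, 1, max)
  E <- exp(log_evidence - shift) # N x K, entries in (0, 1]
  with_seed(seed, {
    g <- matrix(stats::rgamma(n_draws * K, shape = rep(alpha0, each = n_draws)),
                n_draws, K)
    r <- g / rowSums(g)
    # log prod_n sum_k r_k E_nk for each draw
    lp <- rowSums(log(tcrossprod(r, E)))
    sum(shift) + logsumexp(lp) - log(n_draws)
  })
}
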