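# Synthetic participants: softmax-noisy strategy agents on full schedules,
# mapping-task agents, and the model/parameter recovery experiments.

#' Simulate one participant
#'
#' A static strategy agent walks the categorisation trials of a schedule
#' and samples each choice from the softmax (at temperature \code{beta}) of
#' its generating model's category probabilities. Agents do not learn:
#' feedback affects nothing.
#'
#' @param model_name name of the generating model (see
#'   \code{\link{model_roster}}).
#' @param beta positive softmax temperature.
#' @param schedule a \code{\link{build_schedule}} trial table.
#' @param seed integer seed for the agent's private stream.
#' @param participant_id identifier stored on the rows.
#' @return the schedule with \code{participant_id} and
#'   \code{chosen_category} columns added (non-categorisation rows get NA
#'   choices).
#' @export
simulate_participant <- function(model_name, beta, schedule, seed = 1,
                                 participant_id = paste0(model_name, "_", seed)) {
  stopifnot(beta > 0)
  roster <- model_roster("far")
  if (!model_name %in% names(roster)) stop("unknown model: ", model_name)
  model <- roster[[model_name]]
  data <- as.data.frame(schedule)
  data$participant_id <- participant_id
  data$chosen_category <- NA_integer_
  qi <- which(data$task == "quadruplet")
  context <- data_context(data[qi, , drop = FALSE])
  P <- predict_categories(model, context, data[qi, , drop = FALSE])
  Z <- P / beta
  Z <- Z - apply(Z, 1, max)
  W <- exp(Z) / rowSums(exp(Z))
  data$chosen_category[qi] <- with_seed(seed, {
    vapply(seq_len(nrow(W)), function(r) {
      sample(0:2, 1, prob = W[r, ])
    }, integer(1))
  })
  attr(data, "generating_model") <- model_name
  attr(data, "beta") <- beta
  data
}

#' Simulate a cohort of agents
#'
#' Independent agents with deterministically derived sub-seeds; ground
#' truth is recorded on each dataset's attributes.
#'
#' @param model_names character vector of generating models, recycled
#'   against \code{n_per_model}.
#' @param beta softmax temperature (scalar or per-agent).
#' @param n_per_model agents per listed model.
#' @param schedule a trial schedule.
#' @param seed master seed.
#' @return a list of choice tables.
#' @export
simulate_cohort <- function(model_names, beta, n_per_model, schedule, seed = 1) {
  stopifnot(n_per_model >= 1)
  agents <- expand.grid(rep_ = seq_len(n_per_model), model = model_names,
                        stringsAsFactors = FALSE)
  beta <- rep_len(beta, nrow(agents))
  lapply(seq_len(nrow(agents)), function(a) {
    simulate_participant(
      agents$model[a], beta[a], schedule,
      seed = derive_seed(seed, a),
      participant_id = sprintf("%s_b%g_%02d", agents$model[a], beta[a],
                               agents$rep_[a])
    )
  })
}

#' Model-recovery experiment
#'
#' Simulates agents from every roster model at each temperature, fits the
#' full roster to each synthetic dataset with \code{\link{select_best}},
#' and tabulates the confusion between generating and selected models.
#'
#' @param schedule trial schedule to simulate on.
#' @param temperatures vector of softmax temperatures.
#' @param n_per_model agents per model per temperature.
#' @param seed master seed.
#' @param transfer_kind roster / fitting side (\code{"near"} or
#'   \code{"far"}).
#' @return an object of class \code{rotgen_recovery}: list with
#'   \code{confusion} (a named list, one generating x selected count matrix
#'   per temperature) and \code{details} (one row per simulated agent).
#' @export
run_model_recovery <- function(schedule, temperatures = c(0.05, 0.2, 0.35, 0.5),
                               n_per_model = 100, seed = 1,
                               transfer_kind = "near") {
  stopifnot(all(temperatures > 0))
  models <- names(model_roster(transfer_kind))
  details <- list()
  confusion <- list()
  stream <- 0L
  for (tt in temperatures) {
    tab <- matrix(0L, length(models), length(models),
                  dimnames = list(generating = models, selected = models))
    for (m in models) {
      for (a in seq_len(n_per_model)) {
        stream <- stream + 1L
        dat <- simulate_participant(m, tt, schedule,
                                    seed = derive_seed(seed, stream))
        sel <- select_best(dat, transfer_kind)
        tab[m, sel$best_model] <- tab[m, sel$best_model] + 1L
        details[[length(details) + 1L]] <-
          data.frame(temperature = tt, generating = m,
                     selected = sel$best_model,
                     beta_hat = sel$fits$beta_hat[sel$fits$model == sel$best_model])
      }
    }
    confusion[[as.character(tt)]] <- tab
  }
  structure(list(confusion = confusion,
                 details = do.call(rbind, details),
                 n_per_model = n_per_model,
                 transfer_kind = transfer_kind),
            class = "rotgen_recovery")
}

#' @export
print.rotgen_recovery <- function(x, ...) {
  for (tt in names(x$confusion)) {
    cat("temperature", tt, "- recovery confusion (rows: generating):\n")
    print(x$confusion[[tt]])
  }
  invisible(x)
}

#' Recovery rate per generating model
#'
#' @param recovery a \code{rotgen_recovery} object.
#' @return a temperatures x models matrix of diagonal recovery proportions.
#' @export
recovery_rates <- function(recovery) {
  t(vapply(recovery$confusion, function(tab) diag(tab) / rowSums(tab),
           numeric(nrow(recovery$confusion[[1]]))))
}

#' Mapping-task agents
#'
#' Idealised responders for the 16-cell cross-modal mapping task: the
#' random agent clicks uniformly over the 16 cells (expected accuracy
#' 1/16), the one-dimension agent knows the target's level on a single
#' attended dimension, chosen once per agent, and clicks uniformly among
#' the 4 cells sharing it (expected accuracy 1/4), and the perfect agent
#' always clicks the target.
#'
#' @param kind \code{"random"}, \code{"one_dimension"} or \code{"perfect"}.
#' @param trials a mapping trial table (targets in
#'   \code{anchor_i}/\code{anchor_j}).
#' @param seed integer seed.
#' @return a list with \code{accuracy} (proportion correct) and
#'   \code{choices} (two-column matrix of clicked cells).
#' @export
simulate_mapping_agent <- function(kind = c("random", "one_dimension", "perfect"),
                                   trials, seed = 1) {
  kind <- match.arg(kind)
  trials <- trials[trials$task == "mapping", , drop = FALSE]
  if (nrow(trials) == 0) stop("no mapping trials supplied")
  n <- nrow(trials)
  with_seed(seed, {
    choice <- switch(kind,
      random = cbind(sample(0:3, n, TRUE), sample(0:3, n, TRUE)),
      perfect = cbind(trials$anchor_i, trials$anchor_j),
      one_dimension = {
        attended <- sample(c("i", "j"), 1)
        if (attended == "i") {
          cbind(trials$anchor_i, sample(0:3, n, TRUE))
        } else {
          cbind(sample(0:3, n, TRUE), trials$anchor_j)
        }
      })
    correct <- choice[, 1] == trials$anchor_i & choice[, 2] == trials$anchor_j
    list(kind = kind, accuracy = mean(correct), choices = choice)
  })
}

#' Expected mapping-task accuracy
#'
#' Closed-form expected proportion correct of each mapping agent.
#'
#' @param kind agent kind.
#' @return a probability.
#' @export
#' @examples
#' mapping_agent_expected_accuracy("random") # 1/16
mapping_agent_expected_accuracy <- function(kind = c("random", "one_dimension",
                                                     "perfect")) {
  switch(match.arg(kind), random = 1 / 16, one_dimension = 1 / 4, perfect = 1)
}
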