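# Derived indices (2Dness, normalised likelihoods), correlation analyses,
# and the end-to-end cohort pipeline.

#' Rotational generalisation index (2Dness)
#'
#' The difference in maximised log-likelihood between the 2D model and the
#' best one-dimensional model on the near-transfer fit. Positive values
#' indicate rotation-invariant (2D) behaviour, negative values a
#' single-dimension strategy.
#'
#' @param selection a \code{rotgen_fit} from \code{\link{select_best}}.
#' @return a scalar in log-likelihood units.
#' @export
two_d_ness <- function(selection) {
  fits <- selection$fits
  oned <- fits$model %in% names(Filter(function(m) m$family == "oneD",
                                       model_roster(selection$transfer_kind)))
  if (!"2D" %in% fits$model || !any(oned)) {
    stop("2Dness needs fits for the 2D model and at least one 1D model")
  }
  fits$logLik[fits$model == "2D"] - max(fits$logLik[oned])
}

#' Log-likelihood normalised by the random model
#'
#' \code{logLik(model) - logLik(R)}; the R-relative scale used for the
#' individual-participant likelihood scatter.
#'
#' @param selection a \code{rotgen_fit}.
#' @param model_name a fitted model name.
#' @return a scalar.
#' @export
normalised_log_likelihood <- function(selection, model_name) {
  fits <- selection$fits
  if (!model_name %in% fits$model) stop("model was not fitted: ", model_name)
  fits$logLik[fits$model == model_name] - fits$logLik[fits$model == "R"]
}

#' Pearson and partial correlations
#'
#' Standard Pearson correlation with a two-sided t-test, and partial
#' correlation by residualising both variables on the control variables
#' (degrees of freedom adjusted for the number of controls).
#'
#' @param x,y numeric vectors of equal length (n >= 3).
#' @param controls optional numeric vector, matrix or data.frame of control
#'   variables for the partial correlation.
#' @param label optional pair label carried into the report.
#' @return a one-row data.frame: label, r, n, df, statistic, p_value,
#'   n_controls.
#' @export
pearson_cor <- function(x, y, controls = NULL, label = NULL) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (var(x) == 0 || var(y) == 0) stop("zero-variance input")
  g <- 0L
  if (!is.null(controls)) {
    cm <- as.matrix(controls)
    stopifnot(nrow(cm) == length(x))
    if (any(apply(cm, 2, var) == 0)) stop("zero-variance control")
    x <- resid(lm(x ~ cm))
    y <- resid(lm(y ~ cm))
    if (var(x) < .Machine$double.eps || var(y) < .Machine$double.eps) {
      stop("a variable is fully explained by the controls")
    }
    g <- ncol(cm)
  }
  r <- cor(x, y)
  df <- length(x) - 2L - g
  stat <- r * sqrt(df / (1 - r^2))
  data.frame(label = if (is.null(label)) NA_character_ else label,
             r = r, n = length(x), df = df, statistic = stat,
             p_value = 2 * pt(-abs(stat), df), n_controls = g)
}

#' @rdname pearson_cor
#' @export
partial_cor <- function(x, y, controls, label = NULL) {
  pearson_cor(x, y, controls = controls, label = label)
}

#' Per-participant analysis record
#'
#' Accuracy summaries and the 2Dness index for one simulated or observed
#' participant.
#'
#' @param data a choice table for one participant.
#' @param selection optional precomputed near-transfer \code{rotgen_fit}.
#' @return a one-row data.frame.
#' @export
participant_record <- function(data, selection = select_best(data, "near")) {
  acc <- function(phase) {
    sub <- data[data$task == "quadruplet" & data$phase == phase, , drop = FALSE]
    if (nrow(sub) == 0) return(NA_real_)
    mean(sub$chosen_category == sub$category)
  }
  data.frame(
    participant_id = data$participant_id[1],
    best_model = selection$best_model,
    two_d_ness = two_d_ness(selection),
    training_accuracy = acc("training"),
    pretraining_accuracy = acc("pretraining")
  )
}

#' Run the full cohort analysis pipeline
#'
#' Simulates (or loads) every cohort, fits the strategy-model roster to
#' each participant, computes per-participant records and 2Dness, runs
#' random-effects group BMS per cohort, and computes the between-group
#' Bayes factor with its evidence label for every requested cohort pair.
#' The pipeline is a pure function of (config, seed): rerunning with the
#' same configuration gives identical outputs.
#'
#' @param config a list with elements:
#'   \describe{
#'     \item{cohorts}{named list; each cohort is either
#'       \code{list(experiment, model, beta, n)} (simulated) or
#'       \code{list(file = "choices.csv")} (a choice table of one or more
#'       participants).}
#'     \item{transfer_kind}{\code{"near"} (default) or \code{"far"}.}
#'     \item{family_partition}{optional named list of model-name vectors for
#'       family-level inference, e.g. the 1D-vs-2D partition.}
#'     \item{pairs}{optional list of length-2 character vectors of cohort
#'       names to compare; defaults to all pairs.}
#'     \item{seed}{integer master seed.}
#'   }
#' @param out_dir optional directory; when given, writes \code{fits.csv},
#'   \code{records.csv}, \code{bms.json} and \code{run.log} there.
#' @return an object of class \code{rotgen_pipeline}: list with
#'   \code{records}, \code{fits}, \code{bms} (per cohort), \code{bf}
#'   (per pair), and \code{config}.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(is.list(config), !is.null(config$cohorts))
  transfer_kind <- if (is.null(config$transfer_kind)) "near" else config$transfer_kind
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  log_lines <- character(0)
  say <- function(...) {
    log_lines <<- c(log_lines, paste0(...))
  }
  say("rotgen pipeline; transfer_kind=", transfer_kind, "; seed=", seed)

  cohort_fits <- list()
  records <- list()
  fit_rows <- list()
  for (ci in seq_along(config$cohorts)) {
    cname <- names(config$cohorts)[ci]
    spec <- config$cohorts[[ci]]
    if (!is.null(spec$file)) {
      tab <- read_trials(spec$file)
      datasets <- split(tab, tab$participant_id)
      check_choice_table(tab)
    } else {
      sched <- build_schedule(spec$experiment, seed = derive_seed(seed, ci))
      datasets <- simulate_cohort(spec$model, spec$beta, spec$n, sched,
                                  seed = derive_seed(seed, 1000 + ci))
    }
    say("cohort ", cname, ": ", length(datasets), " participants")
    fits <- lapply(datasets, select_best, transfer_kind = transfer_kind)
    cohort_fits[[cname]] <- fits
    for (f in fits) {
      fr <- f$fits
      fr$participant_id <- f$participant_id
      fr$cohort <- cname
      fr$best <- fr$model == f$best_model
      fit_rows[[length(fit_rows) + 1L]] <- fr
    }
    recs <- do.call(rbind, Map(function(d, f) participant_record(d, f),
                               datasets, fits))
    recs$cohort <- cname
    records[[cname]] <- recs
  }
  records <- do.call(rbind, records)
  rownames(records) <- NULL
  fits_table <- do.call(rbind, fit_rows)
  rownames(fits_table) <- NULL

  bms <- lapply(cohort_fits, function(fits) rfx_bms(evidence_matrix(fits)))
  pairs <- config$pairs
  if (is.null(pairs) && length(cohort_fits) >= 2) {
    nm <- names(cohort_fits)
    pairs <- list()
    for (a in seq_along(nm)) for (b in seq_along(nm)) {
      if (a < b) pairs[[length(pairs) + 1L]] <- c(nm[a], nm[b])
    }
  }
  bf <- list()
  for (pr in pairs) {
    ev_a <- evidence_matrix(cohort_fits[[pr[1]]])
    ev_b <- evidence_matrix(cohort_fits[[pr[2]]])
    if (!is.null(config$family_partition)) {
      ev_a <- family_collapse(ev_a, config$family_partition)
      ev_b <- family_collapse(ev_b, config$family_partition)
    }
    res <- between_group_bf(ev_a, ev_b)
    key <- paste(pr, collapse = "_vs_")
    bf[[key]] <- res
    say(key, ": BF=", format(res$bf, digits = 4), " (", res$label, ")")
  }

  out <- structure(list(records = records, fits = fits_table, bms = bms,
                        bf = bf, config = config, log = log_lines),
                   class = "rotgen_pipeline")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(fits_table, file.path(out_dir, "fits.csv"), row.names = FALSE)
    write.csv(records, file.path(out_dir, "records.csv"), row.names = FALSE)
    jsonlite::write_json(pipeline_summary(out),
                         file.path(out_dir, "bms.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeLines(log_lines, file.path(out_dir, "run.log"))
  }
  out
}

#' Summarise a pipeline run as plain lists (JSON-ready)
#'
#' @param pipeline a \code{rotgen_pipeline} object.
#' @return a nested list with per-cohort model frequencies and per-pair
#'   Bayes factors.
#' @export
pipeline_summary <- function(pipeline) {
  list(
    transfer_kind = if (is.null(pipeline$config$transfer_kind)) "near"
                    else pipeline$config$transfer_kind,
    seed = if (is.null(pipeline$config$seed)) 1L else pipeline$config$seed,
    cohorts = lapply(pipeline$bms, function(b) list(
      model_frequencies = as.list(b$freq),
      log_group_evidence = b$free_energy
    )),
    comparisons = lapply(pipeline$bf, function(b) list(
      bf = b$bf, p_h0 = b$p_h0, label = b$label
    ))
  )
}

#' @export
print.rotgen_pipeline <- function(x, ...) {
  cat("rotgen pipeline:", length(x$bms), "cohorts,",
      nrow(x$records), "participants\n")
  tab <- table(x$records$cohort, x$records$best_model)
  print(tab)
  for (nm in names(x$bf)) {
    cat(nm, ": BF=", format(x$bf[[nm]]$bf, digits = 4),
        " (", x$bf[[nm]]$label, ")\n", sep = "")
  }
  invisible(x)
}

# Schema check for externally supplied choice tables; reports offending
# rows by number.
check_choice_table <- function(tab) {
  needed <- c("participant_id", "phase", "task", "category", "rotation_deg",
              "far_transfer", "chosen_category",
              as.vector(t(outer(paste0("pos", 1:4), c("_i", "_j"), paste0))))
  missing <- setdiff(needed, names(tab))
  if (length(missing)) {
    stop("choice table is missing columns: ", paste(missing, collapse = ", "))
  }
  quad <- tab$task == "quadruplet"
  bad <- which(quad & (!tab$chosen_category %in% 0:2 | !tab$category %in% 0:2))
  if (length(bad)) {
    stop("invalid category/choice on rows: ",
         paste(head(bad, 10), collapse = ", "))
  }
  invisible(TRUE)
}
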