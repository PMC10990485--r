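# Trial-schedule generation for the four experiments.
#
# A schedule is a data.frame with one row per trial and a task column in
# {quadruplet, mapping, filler}. Quadruplet rows carry category, rotation,
# far-transfer flag, anchor and the four stimulus positions; mapping rows
# carry the target cell in (anchor_i, anchor_j) and the varying-dimension
# restriction; filler rows carry the colour-count category and the star
# location in (anchor_i, anchor_j).

transform_code <- function(rotation, far) paste0(ifelse(far, "f", ""), rotation)

parse_transform <- function(code) {
  far <- startsWith(code, "f")
  rot <- as.integer(sub("^f", "", code))
  list(rotation = rot, far = far)
}

# Near-transfer rotations are the untrained ones on the original grid; far
# transfer shows all four rotations on the second grid.
.phase_tables <- local({
  exp1 <- list(
    list(day = 1, task = "quadruplet", kind = "train", n = 120, trans = "0",
         feedback = TRUE, phase = "training"),
    list(day = 1, task = "quadruplet", kind = "mixed", n_train = 105, n_transfer = 105,
         train_trans = "0",
         transfer_trans = c("90", "180", "270", "f0", "f90", "f180", "f270"),
         phase = "training")
  )
  mapping_day1 <- function(day) list(
    list(day = day, task = "mapping", restriction = "i", n = 48),
    list(day = day, task = "mapping", restriction = "j", n = 48),
    list(day = day, task = "mapping", restriction = "both", n = 48),
    list(day = day, task = "mapping", restriction = "i", n = 48),
    list(day = day, task = "mapping", restriction = "j", n = 48),
    list(day = day, task = "mapping", restriction = "both", n = 96)
  )
  mapping_block <- function(day, restriction, n = 48) {
    list(list(day = day, task = "mapping", restriction = restriction, n = n))
  }
  # Exp 2/3 share a skeleton; they differ in the pre-training rotations and
  # in the rotations of the first mixed-modality training block on day 2.
  exp23 <- function(pre_trans, mixed30_trans) c(
    list(list(day = 1, task = "quadruplet", kind = "train", n = 60, trans = pre_trans,
              feedback = TRUE, phase = "pretraining")),
    mapping_day1(1),
    list(list(day = 2, task = "quadruplet", kind = "train", n = 60, trans = pre_trans,
              feedback = TRUE, phase = "pretraining")),
    mapping_block(2, "i"), mapping_block(2, "j"), mapping_block(2, "both"),
    list(list(day = 2, task = "quadruplet", kind = "train", n = 30, trans = mixed30_trans,
              feedback = TRUE, phase = "training"),
         list(day = 2, task = "quadruplet", kind = "train", n = 30, trans = c("0", "90"),
              feedback = TRUE, phase = "training")),
    mapping_block(2, "both"),
    list(list(day = 2, task = "quadruplet", kind = "train", n = 60, trans = c("0", "90"),
              feedback = TRUE, phase = "training")),
    mapping_block(2, "both"),
    list(list(day = 2, task = "quadruplet", kind = "mixed", n_train = 90, n_transfer = 90,
              train_trans = c("0", "90"),
              transfer_trans = c("180", "270", "f0", "f90", "f180", "f270"),
              phase = "training"))
  )
  exp4 <- c(
    list(list(day = 1, task = "filler", n = 60, phase = "pretraining")),
    mapping_day1(1),
    list(list(day = 2, task = "filler", n = 60, phase = "pretraining")),
    mapping_block(2, "i"), mapping_block(2, "j"), mapping_block(2, "both"),
    list(list(day = 2, task = "quadruplet", kind = "train", n = 60, trans = c("0", "90"),
              feedback = TRUE, phase = "training")),
    mapping_block(2, "both"),
    list(list(day = 2, task = "quadruplet", kind = "train", n = 60, trans = c("0", "90"),
              feedback = TRUE, phase = "training")),
    mapping_block(2, "both"),
    list(list(day = 2, task = "quadruplet", kind = "mixed", n_train = 90, n_transfer = 90,
              train_trans = c("0", "90"),
              transfer_trans = c("180", "270", "f0", "f90", "f180", "f270"),
              phase = "training"))
  )
  out <- list()
  for (id in c("1a", "1b", "1c")) out[[id]] <- exp1
  for (id in c("2a", "2b", "2c")) out[[id]] <- exp23(c("0", "90"), c("0", "90"))
  for (id in c("3a", "3b", "3c")) out[[id]] <- exp23("0", "0")
  for (id in c("4a", "4b")) out[[id]] <- exp4
  out
})

#' Experiment identifiers
#' @return character vector of the eleven experiment ids.
#' @export
experiment_ids <- function() names(.phase_tables)

empty_trial_row <- function(n) {
  data.frame(
    day = integer(n), phase_index = integer(n), phase = character(n),
    task = character(n), trial_index = integer(n), block_index = integer(n),
    category = NA_integer_, rotation_deg = NA_integer_, far_transfer = NA,
    anchor_i = NA_integer_, anchor_j = NA_integer_,
    pos1_i = NA_integer_, pos1_j = NA_integer_, pos2_i = NA_integer_,
    pos2_j = NA_integer_, pos3_i = NA_integer_, pos3_j = NA_integer_,
    pos4_i = NA_integer_, pos4_j = NA_integer_,
    feedback = NA, restriction = NA_character_
  )
}

quad_rows <- function(category, code, phase, feedback) {
  n <- length(category)
  tr <- lapply(code, parse_transform)
  rot <- vapply(tr, `[[`, integer(1), "rotation")
  far <- vapply(tr, `[[`, logical(1), "far")
  anchor_i <- sample(0:2, n, replace = TRUE)
  anchor_j <- sample(0:2, n, replace = TRUE)
  out <- empty_trial_row(n)
  out$task <- "quadruplet"
  out$phase <- phase
  out$category <- as.integer(category)
  out$rotation_deg <- rot
  out$far_transfer <- far
  out$anchor_i <- anchor_i
  out$anchor_j <- anchor_j
  for (r in seq_len(n)) {
    p <- quad_offsets(category[r], rot[r])
    out[r, paste0("pos", 1:4, "_i")] <- p[, 1] + anchor_i[r]
    out[r, paste0("pos", 1:4, "_j")] <- p[, 2] + anchor_j[r]
  }
  out$feedback <- feedback
  out
}

# Balanced deal: shuffle x and split into n_blocks equal hands.
deal <- function(x, n_blocks) {
  x <- sample(x)
  split(x, rep(seq_len(n_blocks), each = length(x) / n_blocks))
}

# A pure training phase: blocks of 30 with 10 trials per category; with two
# trained rotations each category contributes 5 trials per rotation per block.
build_training_phase <- function(n, trans, phase, feedback) {
  stopifnot(n %% 30 == 0)
  n_blocks <- n %/% 30
  per_cat <- 10L
  rows <- vector("list", n_blocks)
  for (b in seq_len(n_blocks)) {
    cats <- rep(0:2, each = per_cat)
    codes <- unlist(lapply(0:2, function(cc) {
      sample(rep(trans, length.out = per_cat)) # 10/1 or 5/5 per category
    }))
    ord <- sample(per_cat * 3L)
    blk <- quad_rows(cats[ord], codes[ord], phase, feedback)
    blk$block_index <- b - 1L
    rows[[b]] <- blk
  }
  do.call(rbind, rows)
}

# A mixed train/transfer phase: blocks of 30 holding, per category, 5
# feedback training trials and 5 no-feedback transfer trials; transfer
# transformations are balanced within category at phase level (n_transfer /
# 3 categories / n transformations exemplars each), training rotations
# likewise, then trials are randomly interleaved within each block.
build_mixed_phase <- function(n_train, n_transfer, train_trans, transfer_trans, phase) {
  stopifnot(n_train == n_transfer, (n_train + n_transfer) %% 30 == 0)
  n_blocks <- (n_train + n_transfer) %/% 30L
  per_cat_train <- n_train / 3L
  per_cat_transfer <- n_transfer / 3L
  stopifnot(per_cat_transfer %% length(transfer_trans) == 0)
  train_codes <- lapply(0:2, function(cc) {
    deal(rep(train_trans, length.out = per_cat_train), n_blocks)
  })
  transfer_codes <- lapply(0:2, function(cc) {
    deal(rep(transfer_trans, each = per_cat_transfer / length(transfer_trans)), n_blocks)
  })
  rows <- vector("list", n_blocks)
  for (b in seq_len(n_blocks)) {
    cats <- codes <- fb <- NULL
    for (cc in 0:2) {
      tc <- train_codes[[cc + 1]][[b]]
      xc <- transfer_codes[[cc + 1]][[b]]
      cats <- c(cats, rep(cc, length(tc) + length(xc)))
      codes <- c(codes, tc, xc)
      fb <- c(fb, rep(TRUE, length(tc)), rep(FALSE, length(xc)))
    }
    ord <- sample(length(cats))
    blk <- quad_rows(cats[ord], codes[ord], phase, fb[ord])
    blk$block_index <- b - 1L
    # transfer trials are phased by what they show, not by block membership
    blk$phase[!blk$feedback] <- ifelse(blk$far_transfer[!blk$feedback],
                                       "far_transfer", "near_transfer")
    rows[[b]] <- blk
  }
  do.call(rbind, rows)
}

#' Build one 48-trial mapping block
#'
#' Every one of the 16 grid cells appears exactly three times per block. In
#' restricted blocks only the requested dimension varies within a run: the
#' block is four 12-trial runs, each holding the other dimension fixed at one
#' of its four levels (run order and within-run order randomised), so the
#' 3-per-cell count is preserved.
#'
#' @param restriction \code{"i"}, \code{"j"} or \code{"both"}.
#' @param seed optional integer seed (omit to use the current RNG stream).
#' @return a 48-row trial data.frame with targets in
#'   \code{anchor_i}/\code{anchor_j}.
#' @export
build_mapping_block <- function(restriction = c("both", "i", "j"), seed = NULL) {
  restriction <- match.arg(restriction)
  if (!is.null(seed)) return(with_seed(seed, build_mapping_block(restriction)))
  if (restriction == "both") {
    cells <- expand.grid(i = 0:3, j = 0:3)
    idx <- sample(rep(seq_len(16), 3))
    ti <- cells$i[idx]
    tj <- cells$j[idx]
  } else {
    fixed_levels <- sample(0:3) # one 12-trial run per level of the fixed dim
    ti <- tj <- integer(0)
    for (lev in fixed_levels) {
      vary <- sample(rep(0:3, 3))
      if (restriction == "i") {
        ti <- c(ti, vary); tj <- c(tj, rep(lev, 12))
      } else {
        ti <- c(ti, rep(lev, 12)); tj <- c(tj, vary)
      }
    }
  }
  out <- empty_trial_row(48)
  out$task <- "mapping"
  out$phase <- "mapping"
  out$anchor_i <- as.integer(ti)
  out$anchor_j <- as.integer(tj)
  out$feedback <- TRUE
  out$restriction <- restriction
  out
}

build_filler_phase <- function(n, phase = "pretraining") {
  stopifnot(n %% 30 == 0)
  n_blocks <- n %/% 30
  rows <- vector("list", n_blocks)
  for (b in seq_len(n_blocks)) {
    cats <- sample(rep(0:2, each = 10))
    out <- empty_trial_row(30)
    out$task <- "filler"
    out$phase <- phase
    out$category <- cats
    out$anchor_i <- sample(0:3, 30, replace = TRUE)
    out$anchor_j <- sample(0:3, 30, replace = TRUE)
    out$feedback <- TRUE
    out$block_index <- b - 1L
    rows[[b]] <- out
  }
  do.call(rbind, rows)
}

#' Build the full trial schedule of one experiment
#'
#' Generates every phase of the requested experiment (quadruplet
#' categorisation, cross-modal mapping, and for experiment 4 the filler
#' task), with the pseudo-randomisation constraints of the design: each
#' 30-trial categorisation block shows each category 10 times; mixed
#' train/transfer phases interleave 15 feedback and 15 no-feedback trials
#' per block with transformation mixes balanced within category; anchors
#' are drawn uniformly from the nine unit-square positions.
#'
#' @param experiment_id one of \code{experiment_ids()}.
#' @param seed integer seed controlling all randomisation.
#' @return a trial data.frame of class \code{rotgen_schedule} with
#'   attributes \code{experiment_id} and \code{seed}.
#' @export
#' @examples
#' sched <- build_schedule("1a", seed = 1)
#' nrow(sched) # 330 categorisation trials
build_schedule <- function(experiment_id, seed = 1L) {
  if (!experiment_id %in% names(.phase_tables)) {
    stop("unknown experiment id: ", experiment_id)
  }
  phases <- .phase_tables[[experiment_id]]
  rows <- with_seed(seed, {
    lapply(seq_along(phases), function(pi) {
      ph <- phases[[pi]]
      df <- switch(ph$task,
        quadruplet = if (identical(ph$kind, "mixed")) {
          build_mixed_phase(ph$n_train, ph$n_transfer, ph$train_trans,
                            ph$transfer_trans, ph$phase)
        } else {
          build_training_phase(ph$n, ph$trans, ph$phase, ph$feedback)
        },
        mapping = build_mapping_block(ph$restriction, seed = NULL) |>
          (\(x) if (ph$n == 96) rbind(x, local({
            y <- build_mapping_block(ph$restriction, seed = NULL)
            y$block_index <- 1L
            y
          })) else x)(),
        filler = build_filler_phase(ph$n)
      )
      df$day <- ph$day
      df$phase_index <- pi - 1L
      df
    })
  })
  out <- do.call(rbind, rows)
  out$trial_index <- seq_len(nrow(out)) - 1L
  out <- cbind(experiment_id = experiment_id, out)
  rownames(out) <- NULL
  attr(out, "experiment_id") <- experiment_id
  attr(out, "seed") <- as.integer(seed)
  class(out) <- c("rotgen_schedule", "data.frame")
  out
}

#' Write or read a schedule / choice table as CSV
#'
#' One row per trial, UTF-8, comma-separated, with a header row. Choice
#' tables add \code{participant_id} and \code{chosen_category} columns.
#'
#' @param x a trial data.frame.
#' @param path file path.
#' @export
write_trials <- function(x, path) {
  write.csv(as.data.frame(x), path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  df <- read.csv(path, fileEncoding = "UTF-8")
  df$far_transfer <- as.logical(df$far_transfer)
  df$feedback <- as.logical(df$feedback)
  df
}
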