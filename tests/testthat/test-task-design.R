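test_that("canonical templates match the three category definitions", {
  tmpl <- canonical_templates()
  expect_length(tmpl, 3)
  # category 1 is {NE, W, SE}; category 2 is {N, SE, N}
  expect_equal(unname(tmpl[["1"]]),
               rbind(c(1, 1), c(-1, 0), c(1, -1)), ignore_attr = TRUE)
  expect_equal(unname(tmpl[["2"]]),
               rbind(c(0, 1), c(1, -1), c(0, 1)), ignore_attr = TRUE)
  # each template visits 4 distinct cells of a unit square when walked
  for (cc in names(tmpl)) {
    pos <- walk_template_oracle(as.integer(cc), 0, c(0L, 0L))
    expect_equal(nrow(unique(pos)), 4)
    expect_equal(sort(unique(pos[, 1])), c(0L, 1L))
    expect_equal(sort(unique(pos[, 2])), c(0L, 1L))
  }
})

test_that("rotation is counterclockwise in 90-degree steps", {
  cat1 <- canonical_templates()[["1"]]
  expect_equal(unname(rotate_template(cat1, 90)),
               rbind(c(-1, 1), c(0, -1), c(1, 1)), ignore_attr = TRUE) # NW,S,NE
  expect_identical(rotate_template(cat1, 0), cat1)
  cat0 <- canonical_templates()[["0"]]
  expect_equal(unname(rotate_template(cat0, 180)),
               rbind(c(-1, 0), c(0, -1), c(1, 0)), ignore_attr = TRUE) # W,S,E
  expect_error(rotate_template(cat1, 45), "multiple of 90")
})

test_that("the 12 rotated vector sequences are pairwise distinct", {
  keys <- c()
  for (cc in 0:2) for (rr in c(0, 90, 180, 270)) {
    keys <- c(keys, paste(t(rotate_template(canonical_templates()[[as.character(cc)]], rr)),
                          collapse = ","))
  }
  expect_equal(anyDuplicated(keys), 0L)
})

test_that("realised quadruplets occupy the anchor's unit square", {
  expect_equal(realise_quadruplet(0, 0, c(0, 0))$positions,
               rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)), ignore_attr = TRUE)
  expect_equal(realise_quadruplet(0, 90, c(0, 0))$positions,
               rbind(c(1, 0), c(1, 1), c(0, 1), c(0, 0)), ignore_attr = TRUE)
  expect_error(realise_quadruplet(1, 0, c(3, 3)), "invalid anchor")
  # exhaustive: every category x rotation x anchor matches the walk oracle
  # and covers exactly {anchor, anchor+(1,0), anchor+(0,1), anchor+(1,1)}
  for (cc in 0:2) for (rr in c(0, 90, 180, 270)) for (ai in 0:2) for (aj in 0:2) {
    q <- realise_quadruplet(cc, rr, c(ai, aj))
    expect_equal(q$positions, walk_template_oracle(cc, rr, c(ai, aj)),
                 ignore_attr = TRUE)
    sq <- rbind(c(ai, aj), c(ai + 1, aj), c(ai, aj + 1), c(ai + 1, aj + 1))
    expect_setequal(apply(q$positions, 1, paste, collapse = ","),
                    apply(sq, 1, paste, collapse = ","))
  }
})

test_that("enumeration covers categories x rotations x nine anchors", {
  expect_equal(nrow(enumerate_quadruplets(0)), 27)
  expect_equal(nrow(enumerate_quadruplets(c(0, 90))), 54)
  expect_error(enumerate_quadruplets(integer(0)), "non-empty")
})

test_that("patterns reduce to six signed (three unsigned) tokens per dimension", {
  expect_equal(pattern_of(realise_quadruplet(1, 0, c(1, 1)), "i"), "ABAB")
  expect_equal(pattern_of(realise_quadruplet(0, 0, c(2, 0)), "j"), "AABB")
  expect_equal(unsigned_pattern("BABA"), unsigned_pattern("ABAB"))
  all_trials <- enumerate_quadruplets(c(0, 90, 180, 270))
  for (d in c("i", "j")) {
    signed <- unique(rotgen:::patterns_from_trials(all_trials, d))
    expect_length(signed, 6)
    expect_length(unique(unsigned_pattern(signed)), 3)
  }
})

test_that("schedules reproduce the per-phase trial counts of every experiment", {
  # per-experiment totals: categorisation trials, day totals, phase totals
  expected <- list(
    `1` = list(total = 330, train = 225, near = 45, far = 60, pre = 0, map = 0),
    `2` = list(d1 = 396, d2 = 600, train = 210, near = 30, far = 60, pre = 120,
               map = 576),
    `3` = list(d1 = 396, d2 = 600, train = 210, near = 30, far = 60, pre = 120,
               map = 576),
    `4` = list(d1 = 396, d2 = 600, train = 210, near = 30, far = 60, pre = 120,
               map = 576)
  )
  for (id in experiment_ids()) {
    s <- build_schedule(id, seed = 11)
    exp_row <- expected[[substr(id, 1, 1)]]
    if (substr(id, 1, 1) == "1") {
      expect_equal(nrow(s), exp_row$total)
    } else {
      expect_equal(sum(s$day == 1), exp_row$d1)
      expect_equal(sum(s$day == 2), exp_row$d2)
    }
    expect_equal(sum(s$phase == "training"), exp_row$train)
    expect_equal(sum(s$phase == "near_transfer"), exp_row$near)
    expect_equal(sum(s$phase == "far_transfer"), exp_row$far)
    expect_equal(sum(s$phase == "pretraining"), exp_row$pre)
    expect_equal(sum(s$task == "mapping"), exp_row$map)
    expect_equal(sum(is.na(s$trial_index)), 0)
    expect_equal(s$trial_index, seq_len(nrow(s)) - 1L)
  }
  # experiment 4 replaces pre-training with the filler task
  s4 <- build_schedule("4a", seed = 11)
  expect_equal(sum(s4$task == "filler"), 120)
  expect_error(build_schedule("9z"), "unknown experiment")
})

test_that("every 30-trial categorisation block balances categories 10/10/10", {
  for (seed in c(1, 23)) {
    for (id in c("1a", "2a", "4b")) {
      s <- build_schedule(id, seed = seed)
      q <- s[s$task %in% c("quadruplet", "filler"), ]
      for (pi in unique(q$phase_index)) {
        ph <- q[q$phase_index == pi, ]
        counts <- table(ph$block_index, ph$category)
        expect_true(all(counts == 10),
                    label = sprintf("%s phase %d balanced", id, pi))
      }
    }
  }
})

test_that("mixed phases interleave 15 training / 15 transfer per block with balanced transformations", {
  s <- build_schedule("1a", seed = 3)
  mixed <- s[s$phase_index == 1, ]
  expect_equal(nrow(mixed), 210)
  fb <- table(mixed$block_index, mixed$feedback)
  expect_true(all(fb == 15))
  transfer <- mixed[!mixed$feedback, ]
  combo <- table(paste(transfer$rotation_deg, transfer$far_transfer))
  expect_length(combo, 7) # 90/180/270 near + 4 far rotations
  expect_true(all(combo == 15))
  expect_true(all(table(transfer$category, paste(transfer$rotation_deg,
                                                 transfer$far_transfer)) == 5))
  # experiments 2-4: training rotations balanced within category per phase
  s2 <- build_schedule("2a", seed = 3)
  tr <- s2[s2$phase == "training", ]
  rot_by_cat <- table(tr$category, tr$rotation_deg)
  expect_true(all(rot_by_cat[, "0"] == rot_by_cat[, "90"]))
})

test_that("anchors stay in range and positions match the category walk", {
  s <- build_schedule("2b", seed = 9)
  q <- s[s$task == "quadruplet", ]
  expect_true(all(q$anchor_i %in% 0:2 & q$anchor_j %in% 0:2))
  pos_cols <- as.vector(t(outer(paste0("pos", 1:4), c("_i", "_j"), paste0)))
  expect_true(all(q[, pos_cols] >= 0 & q[, pos_cols] <= 3))
  idx <- sample(nrow(q), 25)
  for (r in idx) {
    expect_equal(matrix(as.numeric(q[r, pos_cols]), 4, 2, byrow = TRUE),
                 walk_template_oracle(q$category[r], q$rotation_deg[r],
                                      c(q$anchor_i[r], q$anchor_j[r])),
                 ignore_attr = TRUE)
  }
})

test_that("mapping blocks show each of the 16 cells exactly three times", {
  for (restr in c("both", "i", "j")) {
    blk <- build_mapping_block(restr, seed = 5)
    expect_equal(nrow(blk), 48)
    expect_true(all(table(blk$anchor_i, blk$anchor_j) == 3))
  }
  # restricted blocks vary only the requested dimension within a run
  blk_i <- build_mapping_block("i", seed = 5)
  runs <- split(seq_len(48), rep(1:4, each = 12))
  for (rr in runs) {
    expect_length(unique(blk_i$anchor_j[rr]), 1)
    expect_length(unique(blk_i$anchor_i[rr]), 4)
  }
  # different seeds permute but preserve the target multiset
  b1 <- build_mapping_block("both", seed = 1)
  b2 <- build_mapping_block("both", seed = 2)
  expect_false(identical(b1$anchor_i, b2$anchor_i))
  expect_setequal(paste(b1$anchor_i, b1$anchor_j), paste(b2$anchor_i, b2$anchor_j))
})

test_that("schedule generation is deterministic in the seed and round-trips CSV", {
  a <- build_schedule("3c", seed = 77)
  b <- build_schedule("3c", seed = 77)
  expect_identical(as.data.frame(a), as.data.frame(b))
  f <- withr::local_tempfile(fileext = ".csv")
  write_trials(a, f)
  back <- read_trials(f)
  expect_equal(back$category, a$category)
  expect_equal(back$far_transfer, a$far_transfer)
  expect_equal(back$pos4_j, a$pos4_j)
})
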