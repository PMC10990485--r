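ctx0 <- prediction_context(0)
ctx09 <- prediction_context(c(0, 90))

test_that("model rosters hold 7 near / 11 far models with the right parameter counts", {
  near <- model_roster("near")
  far <- model_roster("far")
  expect_setequal(names(near), c("R", "Rp", "1Di_u", "1Dj_u", "1Di_s", "1Dj_s", "2D"))
  expect_length(far, 11)
  expect_true(all(c("1Dij_u", "1Dji_u", "1Dij_s", "1Dji_s") %in% names(far)))
  expect_equal(near[["R"]]$n_params, 0L)
  expect_true(all(vapply(far[names(far) != "R"], `[[`, integer(1), "n_params") == 1L))
})

test_that("ideal mappings follow the training distribution", {
  m_iu <- model_roster("near")[["1Di_u"]]
  map0 <- derive_ideal_mapping(m_iu, ctx0)
  expect_equal(map0[["ABBA"]], c(1, 0, 0))
  expect_equal(map0[["ABAB"]], c(0, 1, 0))
  expect_equal(map0[["AABB"]], c(0, 0, 1))
  map09 <- derive_ideal_mapping(m_iu, ctx09)
  expect_equal(map09[["ABBA"]], c(0.5, 0.5, 0)) # cat0 at 0 and cat1 at 90
  # signed i patterns are unique under {0, 90}: six tokens, one category each
  m_is <- model_roster("near")[["1Di_s"]]
  sm <- derive_ideal_mapping(m_is, ctx09)
  expect_length(sm, 6)
  expect_true(all(vapply(sm, max, numeric(1)) == 1))
  expect_error(derive_ideal_mapping(model_roster("near")[["2D"]], ctx0),
               "one-dimensional")
})

test_that("predictions are proper distributions and match the strategy logic", {
  trials <- enumerate_quadruplets(c(0, 90, 180, 270))
  trials$phase <- ifelse(trials$rotation_deg == 0, "training", "near_transfer")
  for (m in model_roster("near")) {
    P <- predict_categories(m, ctx0, trials)
    expect_equal(rowSums(P), rep(1, nrow(P)), tolerance = 1e-12)
    expect_true(all(P >= 0))
  }
  # R is uniform everywhere
  expect_equal(predict_categories(model_roster("near")[["R"]], ctx0, trials[1, ]),
               matrix(1 / 3, 1, 3))
  # 2D recovers the true category for any rotation (e.g. category 1 at 180)
  t180 <- trials[trials$category == 1 & trials$rotation_deg == 180, ][1, ]
  expect_equal(predict_categories(model_roster("near")[["2D"]], ctx0, t180),
               matrix(c(0, 1, 0), 1, 3))
  # 1Di_u on a canonical category-2 trial: AABB is unique to category 2
  t2 <- trials[trials$category == 2 & trials$rotation_deg == 0, ][1, ]
  expect_equal(predict_categories(model_roster("near")[["1Di_u"]], ctx0, t2),
               matrix(c(0, 0, 1), 1, 3))
  # Rp: true category on training trials, uniform on transfer
  Prp <- predict_categories(model_roster("near")[["Rp"]], ctx0, trials)
  is_train <- trials$phase == "training"
  expect_true(all(Prp[cbind(which(is_train), trials$category[is_train] + 1)] == 1))
  expect_true(all(Prp[!is_train, ] == 1 / 3))
})

test_that("2D predictions are invariant to rotation and translation", {
  m2d <- model_roster("near")[["2D"]]
  trials <- enumerate_quadruplets(c(0, 90, 180, 270))
  P <- predict_categories(m2d, ctx0, trials)
  # prediction depends only on the category, whatever rotation and anchor
  for (cc in 0:2) {
    rows <- P[trials$category == cc, , drop = FALSE]
    expect_true(all(rows[, cc + 1] == 1))
  }
})

test_that("far-transfer cross-mapped models relabel dimensions", {
  far <- model_roster("far")
  trials <- enumerate_quadruplets(c(0, 90, 180, 270), far_transfer = TRUE)
  trials$phase <- "far_transfer"
  # 1Dij_u reads the far j dimension exactly as 1Dj_u does, through the
  # i-trained mapping; with symmetric training ({0,90}) on unsigned patterns
  # the two mappings coincide pattern-for-pattern after relabelling
  P_cross <- predict_categories(far[["1Dij_u"]], ctx09, trials)
  tok_j <- unsigned_pattern(rotgen:::patterns_from_trials(trials, "j"))
  map_i <- derive_ideal_mapping(far[["1Di_u"]], ctx09)
  expected <- do.call(rbind, map_i[tok_j])
  expect_equal(P_cross, expected, ignore_attr = TRUE)
  # identity-mapped near models read far dimensions as direct continuations
  P_near <- predict_categories(far[["1Dj_u"]], ctx09, trials)
  map_j <- derive_ideal_mapping(far[["1Dj_u"]], ctx09)
  expect_equal(P_near, do.call(rbind, map_j[tok_j]), ignore_attr = TRUE)
})

test_that("expected training accuracies reproduce the ideal-observer table", {
  near <- model_roster("near")
  acc0 <- vapply(near, training_accuracy, numeric(1), context = ctx0)
  expect_equal(unname(acc0["R"]), 1 / 3)
  expect_equal(unname(acc0[c("1Di_u", "1Dj_u", "1Di_s", "1Dj_s", "2D")]),
               rep(1, 5))
  acc09 <- vapply(near, training_accuracy, numeric(1), context = ctx09)
  expect_equal(unname(acc09["R"]), 1 / 3)
  expect_equal(unname(acc09[c("1Di_u", "1Dj_u", "1Dj_s")]), rep(0.5, 3))
  expect_equal(unname(acc09[c("1Di_s", "2D")]), c(1, 1))
})

test_that("one-dimensional models diverge from the true category on rotated trials", {
  # under canonical-only training, a 90-degree trial's i pattern belongs to a
  # different category's canonical pattern: enumerate and check the modal
  # category is never the true one for trials where the mapping is decisive
  m_iu <- model_roster("near")[["1Di_u"]]
  trials <- enumerate_quadruplets(90)
  P <- predict_categories(m_iu, ctx0, trials)
  decisive <- apply(P, 1, max) == 1
  modal <- max.col(P)
  expect_true(all(modal[decisive] != trials$category[decisive] + 1))
})

test_that("prediction table dumps one row per model and trial", {
  tab <- prediction_table(ctx0, rotations = 0)
  expect_equal(nrow(tab), 27 * 7)
  expect_true(all(abs(rowSums(tab[, c("p0", "p1", "p2")]) - 1) < 1e-12))
})
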