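# a fake ranked library of n songs with ranks already decided
fake_ranking <- function(n) {
  structure(list(entries = data.frame(rank = seq_len(n),
                                      song_id = sprintf("song_%05d", seq_len(n)),
                                      pred_z = 0, sim_z = 0,
                                      score = seq(n, 1)),
                 library_size = n),
            class = "ranked_library")
}

test_that("selection windows reproduce the printed positions at 7225", {
  cfg <- run_config()
  expect_equal(selection_window("AugEEG", 3, 7225, cfg), c(1L, 72L))
  expect_equal(selection_window("AugNoEEG", 2, 7225, cfg), c(1L, 432L))
  expect_equal(selection_window("DimEEG", 5, 7225, cfg), c(7154L, 7225L))
  # bottom-432 window = library_size - 432 + 1 ... library_size
  expect_equal(selection_window("DimNoEEG", 2, 7225, cfg), c(6794L, 7225L))
  for (cond in c("AugEEG", "AugNoEEG", "DimEEG", "DimNoEEG")) {
    expect_equal(selection_window(cond, 1, 7225, cfg), c(3577L, 3649L))
  }
  # window widths 72 / 432 / 73
  expect_equal(diff(selection_window("AugEEG", 2, 7225, cfg)) + 1L, 72L)
  expect_equal(diff(selection_window("DimNoEEG", 3, 7225, cfg)) + 1L, 432L)
  expect_equal(diff(selection_window("AugEEG", 1, 7225, cfg)) + 1L, 73L)
  expect_error(selection_window("AugEEG", 8, 7225, cfg), "slot")
})

test_that("windows scale by the same fractions for other library sizes", {
  cfg <- run_config()
  n <- 1445L   # 7225 / 5
  expect_equal(selection_window("AugEEG", 2, n, cfg),
               c(1L, floor(72 * n / 7225)))
  expect_equal(selection_window("DimNoEEG", 2, n, cfg),
               c(n - floor(432 * n / 7225) + 1L, n))
  bw <- selection_window("AugEEG", 1, n, cfg)
  expect_equal(diff(bw) + 1L, floor(73 * n / 7225))
  expect_gt(bw[1], n / 2 - 40); expect_lt(bw[2], n / 2 + 40)
})

test_that("song selection draws uniformly, without replacement, seeded", {
  rk <- fake_ranking(100)
  expect_equal(select_song(rk, c(7, 7)), "song_00007")
  expect_identical(select_song(rk, c(1, 72), seed = 5),
                   select_song(rk, c(1, 72), seed = 5))
  played <- sprintf("song_%05d", 1:71)
  expect_equal(select_song(rk, c(1, 72), played, seed = 1), "song_00072")
  expect_error(select_song(rk, c(1, 72), sprintf("song_%05d", 1:72)),
               "exhausted")
})

test_that("composite ranking matches a hand-computed 5-song toy", {
  # 5 candidates x 3 features; model and self songs built by hand
  feats <- rbind(c(1, 0, 0),
                 c(0, 1, 0),
                 c(1, 1, 0),
                 c(-1, 0, 1),
                 c(0.5, 0.5, 0.2))
  rownames(feats) <- paste0("c", 1:5)
  self <- rbind(c(1, 0.1, -0.1), c(0.9, 0, 0), c(1.1, 0.2, 0))
  model <- structure(list(beta0 = 0, beta = c(1, 0.5, -0.5), fitted = TRUE),
                     class = "pleasure_regressor")
  rk <- rank_candidates(model, feats, self)
  # independent computation
  pred <- as.numeric(feats %*% c(1, 0.5, -0.5))
  sims <- apply(feats, 1, function(v) mean(apply(self, 1, cor, y = v)))
  score <- z_pop(pred) + z_pop(sims)
  ord <- order(-score, rownames(feats))
  expect_equal(rk$entries$song_id, rownames(feats)[ord])
  expect_equal(rk$entries$score, unname(score[ord]), tolerance = 1e-12)
})

test_that("degenerate models rank purely by similarity", {
  w <- shared_world()
  m0 <- w$cal$model1
  m0$beta[] <- 0
  rk <- rank_candidates(m0, w$cal$lib_features, w$cal$self_features)
  sims <- apply(w$cal$lib_features, 1, function(v)
    mean(as.numeric(cor(v, t(w$cal$self_features)))))
  expect_equal(rk$entries$song_id,
               rownames(w$cal$lib_features)[order(-z_pop(sims),
                                                  rownames(w$cal$lib_features))])
})

test_that("a candidate duplicating a self-selected song ranks first", {
  # dominance: the duplicate has similarity exactly 1 to every self song and
  # the maximal model prediction, so it must take rank 1
  set.seed(31)
  v <- rnorm(12)
  feats <- rbind(matrix(rnorm(9 * 12, sd = 0.8), 9, 12), v)
  rownames(feats) <- c(sprintf("cand_%02d", 1:9), "planted_dup")
  self <- rbind(v, v, v)
  model <- structure(list(beta0 = 0, beta = v, fitted = TRUE),
                     class = "pleasure_regressor")
  rk <- rank_candidates(model, feats, self)
  expect_equal(rk$entries$song_id[1], "planted_dup")
})

test_that("playlist plans follow the per-condition contracts", {
  rk <- fake_ranking(7225)
  cfg <- run_config()
  plan_aug <- build_playlist_plan("AugNoEEG", rk, seed = 3, cfg = cfg)
  expect_false(any(is.na(plan_aug$slots)))
  ranks <- match(plan_aug$slots, rk$entries$song_id)
  expect_true(all(ranks[2:7] >= 1 & ranks[2:7] <= 432))
  expect_true(ranks[1] >= 3577 && ranks[1] <= 3649)
  expect_equal(anyDuplicated(plan_aug$slots), 0)

  plan_eeg <- build_playlist_plan("AugEEG", rk, seed = 3, cfg = cfg)
  expect_false(is.na(plan_eeg$slots[1]))
  expect_true(all(is.na(plan_eeg$slots[2:7])))
  expect_true(plan_eeg$deferred)

  plan_dim <- build_playlist_plan("DimNoEEG", rk, seed = 4, cfg = cfg)
  ranks_d <- match(plan_dim$slots[2:7], rk$entries$song_id)
  expect_true(all(ranks_d >= 6794))
})

test_that("planted preferences enrich the top window", {
  w <- shared_world()
  rk <- w$cal$ranking
  own <- w$library$true_pleasure[, 1]
  names(own) <- w$library$song_ids
  top <- selection_window("AugEEG", 2, rk$library_size, w$cfg)
  bot <- selection_window("DimEEG", 2, rk$library_size, w$cfg)
  top_mean <- mean(own[rk$entries$song_id[top[1]:top[2]]])
  bot_mean <- mean(own[rk$entries$song_id[bot[1]:bot[2]]])
  expect_gt(top_mean, mean(own))
  expect_gt(mean(own), bot_mean)
})
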