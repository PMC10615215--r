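rand_windows <- function(n, width = 40L, seed = 1L) {
  set.seed(seed)
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), width, replace = TRUE),
          collapse = "")
  }, character(1L))
}

test_that("window construction balances flanks to a fixed 40 nt", {
  f5 <- strrep("A", 12); f3 <- strrep("T", 12)
  w20 <- build_window(strrep("G", 20), f5, f3)
  expect_equal(nchar(w20), 40L)
  expect_equal(w20, paste0(strrep("A", 10), strrep("G", 20), strrep("T", 10)))
  w23 <- build_window(strrep("G", 23), f5, f3)
  expect_equal(c(regexpr("G", w23), nchar(w23) - regexpr("T", w23) + 1L),
               c(10L, 8L))  # flanks (9, 8)
  w18 <- build_window(strrep("G", 18), f5, f3)
  expect_equal(regexpr("G", w18)[1], 12L)  # flanks (11, 11)
  expect_error(build_window(strrep("G", 20), "ACGT", f3), "insufficient")
  # position labels: -1 adjacent to the PAM, +1.. on the PAM side
  pos <- window_positions(20L)
  expect_equal(sum(pos < 0), 30L)
  expect_equal(pos[30], -1L)
  expect_equal(pos[31], 1L)
})

test_that("one-hot encoding is 160-long, one-hot per position, and invertible", {
  w <- rand_windows(1, seed = 31L)
  v <- onehot_encode(w)
  expect_length(v, 160L)
  expect_equal(sum(v), 40L)
  expect_true(all(colSums(matrix(v, nrow = 4L)) == 1L))
  expect_equal(onehot_decode(v), w)
  # encoding convention: A -> (1,0,0,0) at the first position group
  va <- onehot_encode(paste0("A", substr(w, 2, 40)))
  expect_equal(unname(va[1:4]), c(1L, 0L, 0L, 0L))
  expect_error(onehot_encode(paste0("N", substr(w, 2, 40))), "non-ACGT")
  # invertibility over many random windows
  ws <- rand_windows(25, seed = 32L)
  expect_equal(vapply(ws, function(x) onehot_decode(onehot_encode(x)),
                      character(1L), USE.NAMES = FALSE), ws)
})

test_that("efficacy labels bin at 0.5 with the boundary mapping to high", {
  expect_equal(as.character(label_efficacy(c(0.49, 0.5, 1, 0))),
               c("low", "high", "high", "low"))
  expect_error(label_efficacy(1.2), "\\[0, 1\\]")
})

test_that("the modeling set keeps guides of targets with |F_wmean| >= 1 somewhere", {
  sg <- data.frame(sgrna_id = rep(sprintf("s%d", 1:6), 2L),
                   target_id = rep(c("g1", "g1", "g2", "g2", "g3", "g3"), 2L),
                   condition_id = rep(c("c1", "c2"), each = 6L),
                   F = 0, E = 0, R_scaled = 1, w = 0)
  tg <- data.frame(target_id = rep(c("g1", "g2", "g3"), 2L),
                   condition_id = rep(c("c1", "c2"), each = 3L),
                   F_wmean = c(-0.5, 0.3, -2, 0.2, -0.9, 0.1),
                   p = 0.5, p_adj = 0.5, S = 0)
  ft <- fitness_table(sg, tg)
  ids <- select_modeling_set(ft)
  # g3 reaches -2 in c1; g1 and g2 never reach |F| = 1
  expect_setequal(ids, c("s5", "s6"))
  # brute-force agreement on a random table
  set.seed(33)
  tg2 <- tg; tg2$F_wmean <- rnorm(6, sd = 1.2)
  ft2 <- fitness_table(sg, tg2)
  brute <- unique(sg$sgrna_id[sg$target_id %in%
    unique(tg2$target_id[abs(tg2$F_wmean) >= 1])])
  expect_setequal(select_modeling_set(ft2), brute)
})

test_that("train/validation split has published sizes and is seed-deterministic", {
  sp <- split_train_validation(6306, seed = 5L)
  expect_length(sp$train, 4730L)
  expect_length(sp$validation, 1576L)
  expect_length(intersect(sp$train, sp$validation), 0L)
  expect_setequal(c(sp$train, sp$validation), 1:6306)
  sp4 <- split_train_validation(4, seed = 5L)
  expect_length(sp4$train, 3L)
  expect_identical(split_train_validation(1000, seed = 9L),
                   split_train_validation(1000, seed = 9L))
})

test_that("classifiers learn a separable positional rule and union recall behaves", {
  width <- 40L
  ws <- rand_windows(600, width, seed = 41L)
  pos <- window_positions(20L, width)
  # label = high iff G at PAM-relative position -5
  slot <- which(pos == -5L)
  lab <- factor(ifelse(substr(ws, slot, slot) == "G", "high", "low"),
                levels = c("low", "high"))
  x <- encode_windows(ws, pos)
  sp <- split_train_validation(length(ws), seed = 42L)
  res <- train_and_evaluate(x[sp$train, ], lab[sp$train],
                            x[sp$validation, ], lab[sp$validation],
                            models = c("random_forest", "gradient_boosting",
                                       "svm", "mlp"),
                            seed = 43L)
  rec <- res$metrics[res$metrics$class == "high", ]
  expect_true(all(rec$recall >= 0.95),
              info = paste(rec$model, round(rec$recall, 3), collapse = "; "))
  expect_gte(res$union_high, max(rec$recall) * res$n_high_val)

  # randomized labels: union recall of a single weak model stays near
  # prevalence; with memorization (train = validation) trees reach 1
  lab_r <- sample(lab)
  res_mem <- train_and_evaluate(x[1:100, ], lab_r[1:100],
                                x[1:100, ], lab_r[1:100],
                                models = "random_forest", seed = 44L)
  expect_equal(res_mem$metrics$recall[res_mem$metrics$class == "high"], 1)
  expect_error(train_and_evaluate(x[1:10, ], factor(rep("low", 10),
                                                    levels = c("low", "high")),
                                  x[1:10, ], lab[1:10]),
               "single-class")
})

test_that("importance and logo analysis localize a planted motif to (-5, G)", {
  width <- 40L
  ws <- rand_windows(900, width, seed = 51L)
  pos <- window_positions(20L, width)
  slot <- which(pos == -5L)
  lab <- factor(ifelse(substr(ws, slot, slot) == "G", "high", "low"),
                levels = c("low", "high"))
  x <- encode_windows(ws, pos)
  res <- train_and_evaluate(x, lab, x, lab, models = "random_forest",
                            seed = 52L)
  imp <- position_importance(res$fits$random_forest, colnames(x))
  expect_equal(sum(imp$sequence$importance), 1, tolerance = 1e-9)
  top <- imp$sequence[which.max(imp$sequence$importance), ]
  expect_equal(top$position, -5L)
  expect_equal(top$base, "G")

  lw <- logo_weights(ws[lab == "high"], ws, positions = pos)
  top_lw <- lw[which.max(lw$weight), ]
  expect_equal(top_lw$position, -5L)
  expect_equal(top_lw$base, "G")
  # G fixed against uniform background gives ~2 bits with small pseudocount
  fixed <- ws
  substr(fixed, slot, slot) <- "G"
  lw2 <- logo_weights(fixed, ws, positions = pos, pseudocount = 0.001)
  wG <- lw2$weight[lw2$position == -5L & lw2$base == "G"]
  fbg <- mean(substr(ws, slot, slot) == "G")
  expect_equal(wG, log2(((1 + 0.001) / (1 + 0.004)) /
                          ((fbg + 0.001) / (1 + 0.004))), tolerance = 1e-9)
  # class identical to background -> all zero
  lw3 <- logo_weights(ws, ws, positions = pos)
  expect_true(all(lw3$weight == 0))
  expect_error(logo_weights(ws[0], ws), "at least 2")
  expect_error(position_importance(structure(list(), class = "svm_fake"),
                                   colnames(x)),
               "logo_weights")
})

test_that("whole-guide extras follow the Wallace rule and impute crisproff", {
  lib <- data.frame(sgrna_id = c("a", "b"),
                    spacer = c("ACGTACGTACGTACGTACGT", strrep("GC", 10)),
                    distance_to_start = c(0L, 100L),
                    crisproff = c(NA, -20))
  ex <- guide_extras(lib)
  expect_equal(unname(ex[, "gc"]), c(0.5, 1))
  # Wallace: 2(A+T) + 4(G+C)
  expect_equal(unname(ex[, "tm"]), c(2 * 10 + 4 * 10, 4 * 20))
  expect_equal(unname(ex[, "crisproff"]), c(-20, -20))
})
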