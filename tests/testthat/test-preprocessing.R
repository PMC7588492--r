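test_that("resampling carries the last observation onto the 15-min grid", {
  w <- tibble::tibble(start_h = 10, end_h = 11)
  ev <- tibble::tibble(channel = "hr",
                       time_h = c(10.12, 10.60, 10.70),
                       value = c(95, 88, 84))
  g <- resample_to_grid(ev, w, "hr")
  expect_equal(g$values$time_h, c(10, 10.25, 10.5, 10.75, 11))
  # observation at 10:07-ish appears from the next grid point onward
  expect_true(is.na(g$values$hr[1]))
  expect_equal(g$values$hr[2], 95)
  # two observations inside one interval: the later one wins
  expect_equal(g$values$hr[4], 84)
  expect_equal(g$values$hr[5], 84)
  expect_equal(g$mask$hr, c(NA, "observed", "locf", "observed", "locf"))
  # unobserved channel: all slots missing
  g2 <- resample_to_grid(ev, w, c("hr", "map"))
  expect_true(all(is.na(g2$values$map)))
})

test_that("imputation forward-fills, then falls back to clinical defaults", {
  w <- tibble::tibble(start_h = 0, end_h = 0.75)
  g <- resample_to_grid(tibble::tibble(channel = "x", time_h = 0.2,
                                       value = 5), w, c("x", "y"))
  defaults <- tibble::tibble(channel = c("x", "y"), default = c(9, 1))
  gi <- impute_grid(g, defaults)
  expect_equal(gi$values$x, c(9, 5, 5, 5))
  expect_equal(gi$mask$x, c("default", "observed", "locf", "locf"))
  # all-missing channel takes the default everywhere
  expect_equal(gi$values$y, rep(1, 4))
  expect_equal(unique(gi$mask$y), "default")
  # fully observed channel is untouched
  full <- resample_to_grid(tibble::tibble(channel = "x", time_h = -1,
                                          value = 2), w, "x")
  expect_equal(impute_grid(full, defaults)$values$x, rep(2, 4))
  # missing default with a leading gap errors
  expect_error(impute_grid(g, defaults[1, ]), "no default")
})

test_that("robust scaler uses pooled median/IQR and centres constants", {
  mk <- function(v) structure(list(
    values = tibble::tibble(time_h = seq_along(v), x = v,
                            const = rep(7, length(v))),
    mask = NULL, window = NULL, scaled = FALSE), class = "aki_grid")
  grids <- list(mk(c(1, 2, 3)), mk(c(4, 5)))
  sc <- fit_scaler(grids, ids = c("a", "b"))
  expect_equal(sc$center[sc$channel == "x"], 3)
  expect_equal(sc$iqr[sc$channel == "x"], 2)
  expect_true(sc$constant[sc$channel == "const"])
  # permutation invariance over admissions
  sc2 <- fit_scaler(rev(grids), ids = c("b", "a"))
  expect_equal(sc$center, sc2$center)
  expect_equal(sc$iqr, sc2$iqr)
  # application: (5 - 3) / 2 = 1; centre-only for constants
  out <- apply_scaler(mk(c(5, 3)), sc)
  expect_equal(out$values$x, c(1, 0))
  expect_equal(out$values$const, c(0, 0))
  expect_true(out$scaled)
  # unknown features are refused
  bad <- mk(c(1, 2)); names(bad$values)[2] <- "zz"
  expect_error(apply_scaler(bad, sc), "unknown")
  # invertibility to 1e-9 for IQR > 0 features
  back <- akirisk:::invert_scaler(out, sc)
  expect_equal(back$values$x, c(5, 3), tolerance = 1e-9)
})

test_that("drug doses mark the single slice immediately after the event", {
  w <- tibble::tibble(start_h = 10, end_h = 10.5)
  g <- resample_to_grid(tibble::tibble(channel = "x", time_h = 10,
                                       value = 0), w, "x")
  drugs <- tibble::tibble(time_h = c(10.12), agent = "nsaid")
  ge <- encode_drug_events(drugs, g, agents = c("nsaid", "ppi"))
  expect_equal(ge$values$drug_nsaid, c(0, 1, 0))
  expect_equal(ge$values$drug_ppi, c(0, 0, 0))
  # two doses in one interval still give a binary 1
  two <- tibble::tibble(time_h = c(10.05, 10.12), agent = "nsaid")
  expect_equal(encode_drug_events(two, g, "nsaid")$values$drug_nsaid,
               c(0, 1, 0))
  # a dose exactly on a grid point fires the NEXT slice (strictly after)
  on_grid <- tibble::tibble(time_h = 10.25, agent = "nsaid")
  expect_equal(encode_drug_events(on_grid, g, "nsaid")$values$drug_nsaid,
               c(0, 0, 1))
  # doses after the window end are ignored
  late <- tibble::tibble(time_h = 99, agent = "nsaid")
  expect_equal(sum(encode_drug_events(late, g, "nsaid")$values$drug_nsaid), 0)
})

test_that("text models recover surgery categories well above chance", {
  set.seed(19)
  cats <- sample(names(akirisk:::surgery_vocab()), 1000, replace = TRUE)
  texts <- vapply(cats, function(cc) generate_surgery_text(cc),
                  character(1))
  tr <- 1:700; te <- 701:1000
  m <- fit_surgery_text_model(texts[tr], cats[tr])
  pr <- predict_surgery_type(m, texts[te])
  # 17-way argmax accuracy far above the 1/17 chance level
  pick <- m$types[max.col(as.matrix(pr))]
  expect_gt(mean(pick == cats[te]), 3 / 17)
  # per-type ranking beats chance
  aucs <- vapply(m$types, function(ty) {
    akirisk:::auc_rank(pr[[paste0("surgtype_", ty)]],
                       as.integer(cats[te] == ty))
  }, numeric(1))
  expect_true(all(aucs > 0.5))
  # the guaranteed template token separates its type on held-out texts
  has_token <- grepl("cabg", texts[te], fixed = TRUE)
  expect_gt(min(pr$surgtype_cabg[has_token]), 0.9)
  # out-of-vocabulary words are ignored
  p1 <- predict_surgery_type(m, "cabg lima")
  p2 <- predict_surgery_type(m, "cabg lima zzz_neverseen qqq")
  expect_equal(p1, p2)
  expect_error(fit_surgery_text_model(c("a", "b"), c("x", "y")),
               "at least 2")
})

test_that("assembled grids have the documented shape and causal truncation", {
  co <- demo_cohort(); lab <- demo_labels(); win <- demo_windows()
  gb <- demo_grids()
  # a 24-h window yields floor(24 * 4) + 1 = 97 steps
  id24 <- win$admission_id[which.min(abs(win$length_h - 24))]
  w24 <- win[win$admission_id == id24, ]
  g24 <- assemble_features(co, id24, w24, 0, demo_text_model())
  expect_equal(nrow(g24$values), floor(w24$length_h * 4) + 1)
  # AKI windows are truncated at onset
  aki_ids <- lab$admission_id[lab$label == 1 & !lab$excluded]
  id_aki <- aki_ids[1]
  g_aki <- gb$grids[[id_aki]]
  expect_lte(max(g_aki$values$time_h),
             lab$onset_h[lab$admission_id == id_aki])
  # complete: no missing values; drug channels binary
  expect_false(anyNA(g_aki$values))
  drug_cols <- grep("^drug_", names(g_aki$values), value = TRUE)
  expect_true(all(unlist(g_aki$values[drug_cols]) %in% c(0, 1)))
  # surgery-type probabilities are genuine probabilities, not normalised
  st_cols <- grep("^surgtype_", names(g_aki$values), value = TRUE)
  expect_length(st_cols, 17)
  expect_true(all(unlist(g_aki$values[st_cols]) > 0 &
                    unlist(g_aki$values[st_cols]) < 1))
  # round trip through the grid exchange format
  stem <- file.path(withr::local_tempdir(), "grid")
  write_feature_grid(g_aki, stem)
  back <- read_feature_grid(stem)
  expect_equal(back$values, g_aki$values)
  expect_equal(back$label, g_aki$label)
})

test_that("the pipeline refuses components not fitted on the training split", {
  gb <- demo_grids()
  ids <- names(gb$grids)
  sc <- fit_scaler(gb$grids[1:5], ids = ids[1:5])
  expect_silent(assert_fit_provenance(sc, ids[1:5]))
  expect_error(assert_fit_provenance(sc, ids[6:10]), "provenance")
  tm <- demo_text_model()
  expect_error(assert_fit_provenance(tm, c("not", "these", "texts")),
               "provenance")
})
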