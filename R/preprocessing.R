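#' Resample one admission's channels onto the 15-min grid
#'
#' Grid timestamps run from the window start in fixed `step_h` steps
#' (start-anchored, the start point included). The value of a channel at
#' grid time `t_j` is the last raw observation with timestamp `<= t_j`
#' anywhere in the admission -- the carry-forward convention under which a
#' value "holds" until superseded. Slots with no prior observation are
#' left missing for [impute_grid()]. Values at `t_j` therefore depend only
#' on raw events up to `t_j` (causality), and nothing after the window end
#' is ever read.
#'
#' @param events long data frame (`channel`, `time_h`, `value`) of one
#'   admission.
#' @param window one-row window (`start_h`, `end_h`).
#' @param channels channel roster to materialise (missing channels give
#'   all-missing columns).
#' @param step_h grid spacing, hours (default 0.25).
#' @return object of class `aki_grid`: list with `values` (tibble,
#'   `time_h` + one column per channel), parallel `mask` tibble
#'   (`"observed"`, `"locf"`, `"default"`, `NA` while missing), `window`,
#'   `scaled = FALSE`.
#' @export
resample_to_grid <- function(events, window, channels, step_h = 0.25) {
  start <- window$start_h[1]; end <- window$end_h[1]
  stopifnot(end >= start)
  tg <- start + step_h * seq(0, floor((end - start) / step_h + 1e-9))
  vals <- tibble::tibble(time_h = tg)
  mask <- tibble::tibble(time_h = tg)
  for (ch in channels) {
    obs <- events[events$channel == ch, , drop = FALSE]
    obs <- obs[order(obs$time_h), ]
    idx <- findInterval(tg, obs$time_h)
    v <- ifelse(idx > 0, obs$value[pmax(idx, 1)], NA_real_)
    m <- rep(NA_character_, length(tg))
    has <- idx > 0
    m[has] <- ifelse(obs$time_h[pmax(idx[has], 1)] > tg[has] - step_h,
                     "observed", "locf")
    vals[[ch]] <- as.numeric(v)
    mask[[ch]] <- m
  }
  structure(list(values = vals, mask = mask, window = window,
                 scaled = FALSE), class = "aki_grid")
}

#' Fill the remaining gaps of a feature grid
#'
#' Forward-fills each channel within the grid, then replaces any leading
#' gap (no observation yet) with the channel's static clinical default --
#' one value per feature, identical for every patient. Binary drug
#' channels are exempt (they are never missing). The provenance mask
#' records which slots were observed, carried forward, or defaulted.
#'
#' @param grid an `aki_grid`.
#' @param defaults data frame `channel`, `default` covering every
#'   continuous channel of the grid.
#' @return the completed `aki_grid` (no missing values).
#' @export
impute_grid <- function(grid, defaults) {
  vals <- grid$values; mask <- grid$mask
  for (ch in setdiff(names(vals), "time_h")) {
    v <- vals[[ch]]; m <- mask[[ch]]
    if (anyNA(v)) {
      # forward fill
      idx <- cumsum(!is.na(v))
      filled <- ifelse(idx > 0, v[!is.na(v)][pmax(idx, 1)], NA_real_)
      m[is.na(v) & idx > 0] <- "locf"
      v <- filled
      if (anyNA(v)) {
        d <- defaults$default[match(ch, defaults$channel)]
        if (is.na(d)) {
          abort(sprintf("channel '%s' has a leading gap and no default", ch))
        }
        m[is.na(v)] <- "default"
        v[is.na(v)] <- d
      }
    }
    vals[[ch]] <- v; mask[[ch]] <- m
  }
  grid$values <- vals; grid$mask <- mask
  grid
}

#' Fit the robust feature scaler on training grids
#'
#' Pools every time step of every training admission per feature and
#' records the median and interquartile range: scaled values are
#' `(X - median) / IQR` (linear-interpolation quantiles). Features listed
#' in `unscaled` -- operation-type probabilities, binary drug indicators
#' and other already-bounded channels -- pass through untouched. Features
#' with IQR = 0 are flagged constant and are centred only. The fit records
#' a hash of the training admission ids so downstream code can audit that
#' no test data leaked into it.
#'
#' @param grids list of completed `aki_grid`s (training admissions only).
#' @param unscaled character vector of feature names to pass through.
#' @param ids optional admission ids the grids came from (for the audit
#'   hash; defaults to grid attributes if present).
#' @return object of class `aki_scaler`: tibble `channel`, `center`,
#'   `iqr`, `constant`, `scaled`; `fitted_on` hash attribute.
#' @export
fit_scaler <- function(grids, unscaled = character(), ids = NULL) {
  stopifnot(length(grids) > 0)
  chans <- setdiff(names(grids[[1]]$values), "time_h")
  pooled <- purrr::map(chans, function(ch) {
    unlist(purrr::map(grids, function(g) g$values[[ch]]), use.names = FALSE)
  })
  stats_tbl <- purrr::map2_dfr(chans, pooled, function(ch, x) {
    do_scale <- !(ch %in% unscaled)
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), na.rm = TRUE, names = FALSE)
    tibble::tibble(channel = ch,
                   center = if (do_scale) q[2] else 0,
                   iqr = if (do_scale) q[3] - q[1] else 1,
                   constant = do_scale && (q[3] - q[1]) == 0,
                   scaled = do_scale)
  })
  ids <- ids %||% purrr::map_chr(grids, function(g)
    g$admission_id %||% NA_character_)
  attr(stats_tbl, "fitted_on") <- rlang::hash(sort(ids))
  class(stats_tbl) <- c("aki_scaler", class(stats_tbl))
  stats_tbl
}

#' Apply (or invert) the fitted scaler
#'
#' `(X - center) / IQR` elementwise for scaled features; constant features
#' (IQR = 0) are centred only; unscaled features pass through. Errors on a
#' grid feature the scaler has never seen.
#'
#' @param grid a completed `aki_grid`.
#' @param scaler an `aki_scaler`.
#' @return the scaled `aki_grid` (`scaled = TRUE`).
#' @export
apply_scaler <- function(grid, scaler) {
  vals <- grid$values
  chans <- setdiff(names(vals), "time_h")
  unknown <- setdiff(chans, scaler$channel)
  if (length(unknown) > 0) {
    abort(paste("features unknown to the scaler:",
                paste(unknown, collapse = ", ")))
  }
  for (ch in chans) {
    s <- scaler[scaler$channel == ch, ]
    if (!s$scaled) next
    denom <- if (s$constant) 1 else s$iqr
    vals[[ch]] <- (vals[[ch]] - s$center) / denom
  }
  grid$values <- vals
  grid$scaled <- TRUE
  grid
}

# Inverse transform, used by the invertibility audit.
invert_scaler <- function(grid, scaler) {
  vals <- grid$values
  for (ch in setdiff(names(vals), "time_h")) {
    s <- scaler[scaler$channel == ch, ]
    if (nrow(s) == 0 || !s$scaled) next
    denom <- if (s$constant) 1 else s$iqr
    vals[[ch]] <- vals[[ch]] * denom + s$center
  }
  grid$values <- vals
  grid$scaled <- FALSE
  grid
}

#' Encode drug administrations as single-slice binary channels
#'
#' Drug effect durations are unknowable from the chart, so each
#' administration is treated as an event: per agent class the channel is 1
#' at the single grid step immediately following (strictly after) the
#' administration time and 0 elsewhere. Multiple administrations set
#' multiple slices; administrations after the window end are ignored (the
#' count is recorded in the `dropped_doses` attribute).
#'
#' @param drugs data frame (`time_h`, `agent`) of one admission.
#' @param grid an `aki_grid`.
#' @param agents agent-class roster (one binary channel each).
#' @return the grid with `drug_<agent>` columns appended (mask
#'   `"observed"`).
#' @export
encode_drug_events <- function(drugs, grid, agents) {
  tg <- grid$values$time_h
  dropped <- 0L
  for (ag in agents) {
    col <- rep(0, length(tg))
    t_adm <- drugs$time_h[drugs$agent == ag]
    for (t in t_adm) {
      j <- which(tg > t)
      if (length(j) == 0) {
        if (t <= max(tg)) dropped <- dropped + 1L
        next
      }
      col[j[1]] <- 1
    }
    dropped <- dropped + sum(t_adm > max(tg))
    grid$values[[paste0("drug_", ag)]] <- col
    grid$mask[[paste0("drug_", ag)]] <- "observed"
  }
  attr(grid, "dropped_doses") <- dropped
  grid
}

tokenize_text <- function(x) {
  strsplit(gsub("[^a-z0-9_]+", " ", tolower(x)), "\\s+") |>
    purrr::map(function(w) w[nzchar(w)])
}

text_count_matrix <- function(tokens, vocab) {
  i <- unlist(purrr::map2(unname(tokens), seq_along(tokens),
                          function(w, d) rep(d, sum(w %in% vocab))))
  j <- unlist(purrr::map(tokens, function(w) match(w[w %in% vocab], vocab)))
  Matrix::sparseMatrix(i = if (length(i)) i else integer(0),
                       j = if (length(j)) j else integer(0),
                       x = 1, dims = c(length(tokens), length(vocab)),
                       dimnames = list(NULL, vocab))
}

#' Fit the bag-of-words surgery-type text models
#'
#' One independent L2-regularised binary logistic regression per surgery
#' type: `P(Y_i = 1) = plogis(b0 + b1 x1 + ...)`, where `x_j` counts how
#' often word/abbreviation `j` occurs in the operative-note text. The
#' vocabulary is every distinct token of the training texts. Ridge
#' regularisation keeps perfectly separating vocabularies (common with
#' template-like notes) from diverging.
#'
#' @param texts character vector of operative notes.
#' @param categories surgery type per text.
#' @param lambda ridge penalty (default 3e-5: weak, enough to keep
#'   perfectly separating template vocabularies finite while letting a
#'   separating token drive its type probability close to 1).
#' @param on_rare what to do with types having fewer than 2 training
#'   texts: `"error"` (default) or `"drop"` (fit the remaining types only,
#'   with a warning) -- small cohorts rarely cover all 17 types twice.
#' @return object of class `aki_text_model` with per-type `glmnet` fits;
#'   `fitted_on` hash attribute.
#' @export
fit_surgery_text_model <- function(texts, categories, lambda = 3e-5,
                                   on_rare = c("error", "drop")) {
  on_rare <- match.arg(on_rare)
  tab <- table(categories)
  if (any(tab < 2)) {
    if (on_rare == "error") {
      abort("need at least 2 training texts per surgery type")
    }
    rare <- names(tab)[tab < 2]
    warn(paste("dropping surgery types with fewer than 2 texts:",
               paste(rare, collapse = ", ")))
    tab <- tab[tab >= 2]
    if (length(tab) == 0) abort("no surgery type has 2 training texts")
  }
  tokens <- tokenize_text(texts)
  vocab <- sort(unique(unlist(tokens)))
  if (length(vocab) == 0) abort("empty vocabulary")
  X <- text_count_matrix(tokens, vocab)
  # fit along a short decreasing path ending at the target penalty:
  # glmnet converges far more reliably warm-started than cold at one lambda
  lambda_path <- exp(seq(log(max(1, lambda * 100)), log(lambda),
                         length.out = 8))
  fits <- purrr::map(names(tab), function(ty) {
    y <- as.integer(categories == ty)
    # rare-class warnings are expected at desk scale (17 types)
    suppressWarnings(
      glmnet::glmnet(X, y, family = "binomial", alpha = 0,
                     lambda = lambda_path, standardize = FALSE))
  })
  names(fits) <- names(tab)
  structure(list(vocab = vocab, fits = fits, types = names(tab),
                 lambda = lambda,
                 fitted_on = rlang::hash(sort(texts))),
            class = "aki_text_model")
}

#' Predict surgery-type probabilities from operative-note text
#'
#' Applies every per-type model; tokens outside the training vocabulary
#' are ignored (count 0). The probabilities are NOT normalised across
#' types -- the models are independent binary classifiers, as in the
#' feature set they feed.
#'
#' @param model an `aki_text_model`.
#' @param texts character vector.
#' @return tibble, one row per text, one `surgtype_<type>` column per type.
#' @export
predict_surgery_type <- function(model, texts) {
  X <- text_count_matrix(tokenize_text(texts), model$vocab)
  out <- purrr::map(model$fits, function(f) {
    as.numeric(stats::predict(f, newx = X, type = "response",
                              s = model$lambda))
  })
  names(out) <- paste0("surgtype_", model$types)
  tibble::as_tibble(out)
}

#' Assemble the complete feature grid of one admission
#'
#' End-to-end per-admission preprocessing: dynamic channels resampled to
#' the 15-min grid and imputed (forward fill, then clinical defaults);
#' nephrotoxic drug administrations encoded as single-slice binaries;
#' static features (age, sex, weight, height, surgery duration) and the
#' surgery-type probabilities broadcast to every step; optionally scaled
#' with a training-fitted scaler. The per-step supervised target is the
#' admission's global AKI label, constant over the sequence, stored in the
#' `label` field.
#'
#' @param cohort an `aki_cohort`.
#' @param id admission id.
#' @param window one-row observation window for this admission.
#' @param label 0/1 global label (or NA when assembling unlabeled data).
#' @param text_model fitted [fit_surgery_text_model()] model.
#' @param defaults channel defaults table.
#' @param scaler optional fitted [fit_scaler()]; `NULL` leaves the grid
#'   unscaled (used while the scaler itself is being fit).
#' @param agents drug agent-class roster.
#' @param step_h grid spacing.
#' @return an `aki_grid` with `admission_id` and `label` fields.
#' @export
assemble_features <- function(cohort, id, window, label, text_model,
                              defaults = cohort$channel_defaults,
                              scaler = NULL,
                              agents = c("nsaid", "vancomycin",
                                         "aminoglycoside", "ppi",
                                         "diuretic_adj"),
                              step_h = 0.25) {
  ev <- cohort$events[cohort$events$admission_id == id, ]
  st <- cohort$static[cohort$static$admission_id == id, ]
  dr <- cohort$drugs[cohort$drugs$admission_id == id, ]
  tx <- cohort$surgery_text[cohort$surgery_text$admission_id == id, ]
  if (nrow(st) != 1) abort(sprintf("unknown admission '%s'", id))

  grid <- resample_to_grid(ev, window, defaults$channel, step_h = step_h)
  grid <- impute_grid(grid, defaults)
  grid <- encode_drug_events(dr, grid, agents)

  n <- nrow(grid$values)
  statics <- tibble::tibble(
    age = rep(st$age, n),
    sex = rep(as.numeric(st$sex == "m"), n),
    weight_kg = rep(st$weight_kg, n),
    height_cm = rep(st$height_cm, n),
    surgery_duration_h = rep(st$surgery_end_h - st$surgery_start_h, n)
  )
  probs <- predict_surgery_type(text_model, tx$text)
  probs <- probs[rep(1, n), ]
  grid$values <- dplyr::bind_cols(grid$values, statics, probs)
  for (nm in c(names(statics), names(probs))) grid$mask[[nm]] <- "observed"
  grid$admission_id <- id
  grid$label <- label
  if (!is.null(scaler)) grid <- apply_scaler(grid, scaler)
  grid
}

# Channels of a grid that pass through the scaler untouched.
unscaled_channels <- function(grid) {
  chans <- setdiff(names(grid$values), "time_h")
  chans[startsWith(chans, "drug_") | startsWith(chans, "surgtype_") |
          chans == "sex"]
}

#' Build feature grids for a set of admissions
#'
#' Maps [assemble_features()] over admissions and, when no scaler is
#' supplied, fits one on exactly these grids (training use) before
#' applying it. Pass the training-fitted scaler when preprocessing test
#' admissions so no test statistics leak into the transform.
#'
#' @param cohort an `aki_cohort`.
#' @param windows window tibble ([build_observation_windows()]).
#' @param labels label tibble ([label_cohort()]).
#' @param text_model fitted text model.
#' @param scaler `NULL` (fit here, on these admissions) or a fitted
#'   `aki_scaler`.
#' @param ids admissions to process (default: all rows of `windows`).
#' @inheritParams assemble_features
#' @return list with `grids` (named list of scaled `aki_grid`s) and
#'   `scaler`.
#' @export
build_feature_grids <- function(cohort, windows, labels, text_model,
                                scaler = NULL, ids = windows$admission_id,
                                step_h = 0.25) {
  raw <- purrr::map(ids, function(id) {
    w <- windows[windows$admission_id == id, ]
    l <- labels$label[labels$admission_id == id]
    assemble_features(cohort, id, w, l, text_model, step_h = step_h)
  })
  names(raw) <- ids
  if (is.null(scaler)) {
    scaler <- fit_scaler(raw, unscaled = unscaled_channels(raw[[1]]),
                         ids = ids)
  }
  list(grids = purrr::map(raw, apply_scaler, scaler = scaler),
       scaler = scaler)
}
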