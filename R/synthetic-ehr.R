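#' Configuration for the synthetic EHR cohort generator
#'
#' Defines the statistical structure of a simulated postoperative cohort:
#' how many admissions, what fraction develop severe AKI within the 7-day
#' study period, by which criterion (creatinine doubling, sustained
#' oliguria, or both), how long the creatinine criterion lags the urine
#' criterion when both fire, and how much learnable signal the dynamic
#' channels carry. The defaults emulate the published criterion statistics
#' of a cardiothoracic cohort: ~30% of cases involve the urine criterion,
#' ~12% are diagnosable by urine only, and the median creatinine lag among
#' dual-criterion cases is 14 h (lognormal, sdlog 1.05, matching an IQR of
#' roughly 6-27 h).
#'
#' @param n_admissions number of admissions.
#' @param aki_fraction fraction of admissions with planted AKI (0.5 for
#'   the balanced design, 0.1 for the imbalanced variant).
#' @param criterion_mix named proportions `creatinine_only`, `urine_only`,
#'   `both`; must sum to 1.
#' @param creatinine_lag_median_h median creatinine-after-urine lag (h)
#'   among dual-criterion cases.
#' @param creatinine_lag_sdlog lognormal sdlog of that lag.
#' @param oliguria_rate_band ml/kg/h interval (below 0.5) from which
#'   oliguric-episode rates are drawn.
#' @param peak_creatinine_multiplier list `meanlog`, `sdlog`, `min`
#'   (support >= 2) for the peak creatinine / baseline ratio of cases.
#' @param onset_meanlog,onset_sdlog lognormal parameters of AKI onset time
#'   (hours after surgery end); controls draw their discharge offsets from
#'   the same distribution so matching on observation length is feasible.
#' @param n_informative_channels extra channels whose mean shifts by
#'   `effect_size` (in SD units) in AKI cases from surgery end onwards.
#' @param n_noise_channels extra pure-noise channels.
#' @param effect_size mean shift (SD units) of informative channels and
#'   scaling of the physiological AKI shifts (MAP down, lactate up).
#' @param drug_event_rate nephrotoxic drug administrations per day.
#' @param observation_cap_h study-period cap, hours (<= 168).
#' @param seed integer; fully determines the cohort.
#' @return object of class `aki_cohort_config` (a named list).
#' @export
cohort_config <- function(n_admissions = 300,
                          aki_fraction = 0.5,
                          criterion_mix = c(creatinine_only = 0.70,
                                            urine_only = 0.12,
                                            both = 0.18),
                          creatinine_lag_median_h = 14,
                          creatinine_lag_sdlog = 1.05,
                          oliguria_rate_band = c(0.15, 0.45),
                          peak_creatinine_multiplier = list(
                            meanlog = log(2.8), sdlog = 0.25, min = 2.15),
                          onset_meanlog = log(30),
                          onset_sdlog = 0.7,
                          n_informative_channels = 2,
                          n_noise_channels = 3,
                          effect_size = 1.0,
                          drug_event_rate = 1.5,
                          observation_cap_h = 168,
                          seed = 1) {
  cfg <- list(
    n_admissions = as.integer(n_admissions), aki_fraction = aki_fraction,
    criterion_mix = criterion_mix,
    creatinine_lag_median_h = creatinine_lag_median_h,
    creatinine_lag_sdlog = creatinine_lag_sdlog,
    oliguria_rate_band = oliguria_rate_band,
    peak_creatinine_multiplier = peak_creatinine_multiplier,
    onset_meanlog = onset_meanlog, onset_sdlog = onset_sdlog,
    n_informative_channels = as.integer(n_informative_channels),
    n_noise_channels = as.integer(n_noise_channels),
    effect_size = effect_size, drug_event_rate = drug_event_rate,
    observation_cap_h = observation_cap_h, seed = as.integer(seed)
  )
  validate_cohort_config(cfg)
  structure(cfg, class = "aki_cohort_config")
}

validate_cohort_config <- function(cfg) {
  if (cfg$aki_fraction < 0 || cfg$aki_fraction > 1) {
    abort("`aki_fraction` must lie in [0, 1]")
  }
  mix <- cfg$criterion_mix
  if (!all(c("creatinine_only", "urine_only", "both") %in% names(mix))) {
    abort("`criterion_mix` needs creatinine_only, urine_only, both")
  }
  if (any(mix < 0) || any(mix > 1) || abs(sum(mix) - 1) > 1e-9) {
    abort("`criterion_mix` proportions must lie in [0, 1] and sum to 1")
  }
  b <- cfg$oliguria_rate_band
  if (length(b) != 2 || b[1] >= b[2] || b[2] >= 0.5 || b[1] <= 0) {
    abort("`oliguria_rate_band` must be an interval inside (0, 0.5)")
  }
  if (cfg$observation_cap_h > 168 || cfg$observation_cap_h <= 0) {
    abort("`observation_cap_h` must lie in (0, 168]")
  }
  if (cfg$peak_creatinine_multiplier$min < 2) {
    abort("peak creatinine multiplier support must be >= 2")
  }
  invisible(cfg)
}

# The 17 surgery categories and their discriminative template tokens.
surgery_vocab <- function() {
  list(
    cabg = c("cabg", "lima", "saphenous"),
    avr = c("avr", "aortic_prosthesis", "leaflet_calcification"),
    mvr = c("mvr", "mitral_annuloplasty", "p2_prolapse"),
    tvr = c("tricuspid_ring", "tvr", "annular_dilatation"),
    tavi = c("tavi", "transfemoral", "valve_in_valve"),
    aortic_dissection = c("dissection", "stanford_a", "frozen_elephant"),
    aneurysm_repair = c("aneurysm", "dacron_graft", "bentall"),
    heart_transplant = c("htx", "donor_heart", "bicaval"),
    lung_transplant = c("ltx", "bronchial_anastomosis", "donor_lung"),
    lvad = c("lvad", "assist_device", "driveline"),
    ecmo = c("ecmo", "cannulation", "va_support"),
    asd_closure = c("asd", "septal_patch", "secundum"),
    vsd_closure = c("vsd", "ventricular_septum", "residual_shunt"),
    pericardiectomy = c("pericardiectomy", "constrictive", "decortication"),
    myxoma_resection = c("myxoma", "left_atrial_mass", "tumor_excision"),
    maze = c("maze", "ablation_lines", "atrial_fibrillation"),
    lobectomy = c("lobectomy", "pulmonary_resection", "hilar")
  )
}

surgery_filler <- c(
  "sternotomy", "cardiopulmonary", "bypass", "weaning", "hemostasis",
  "closure", "drains", "uneventful", "anesthesia", "heparin", "protamine",
  "perfusion", "cross_clamp", "reperfusion", "transfer", "icu", "stable",
  "pericardium", "wires", "layers"
)

#' Generate free-text surgery descriptions
#'
#' Draws template-based operative-note text for one of the 17 configured
#' surgery categories: a guaranteed category token plus further
#' category-specific tokens mixed into shared filler vocabulary, so the
#' category is recoverable from the text by a linear bag-of-words
#' classifier well above chance, as in real operative notes.
#'
#' @param category one of `names(surgery_vocab())`.
#' @param n number of texts.
#' @return character vector of length `n`. Deterministic given the RNG
#'   state (seed before calling for reproducibility).
#' @export
generate_surgery_text <- function(category, n = 1) {
  vocab <- surgery_vocab()
  if (!category %in% names(vocab)) {
    abort(sprintf("unknown surgery category '%s'", category))
  }
  disc <- vocab[[category]]
  vapply(seq_len(n), function(i) {
    words <- c(disc[1],
               sample(disc, sample(1:2, 1)),
               sample(surgery_filler, sample(6:10, 1), replace = TRUE))
    paste(sample(words), collapse = " ")
  }, character(1))
}

# Draw the planted scenario table for a cohort: outcome, criterion, onset
# offsets (hours after surgery end), lags, hard-negative types.
draw_scenarios <- function(cfg) {
  n <- cfg$n_admissions
  n_aki <- round(n * cfg$aki_fraction)
  outcome <- c(rep("aki", n_aki), rep("non_aki", n - n_aki))
  crit <- rep(NA_character_, n)
  if (n_aki > 0) {
    crit[seq_len(n_aki)] <- sample(
      c("creatinine", "urine", "both"), n_aki, replace = TRUE,
      prob = cfg$criterion_mix[c("creatinine_only", "urine_only", "both")])
  }
  r_onset <- function(k, lo, hi) {
    x <- stats::rlnorm(k, cfg$onset_meanlog, cfg$onset_sdlog)
    while (any(bad <- x < lo | x > hi)) {
      x[bad] <- stats::rlnorm(sum(bad), cfg$onset_meanlog, cfg$onset_sdlog)
    }
    x
  }
  cap <- cfg$observation_cap_h
  onset <- rep(NA_real_, n)
  lag <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (outcome[i] == "aki") {
      if (crit[i] == "creatinine") {
        onset[i] <- r_onset(1, 6, cap - 2)
      } else {
        onset[i] <- r_onset(1, 14, min(150, cap - 2))  # urine onset
        if (crit[i] == "both") {
          l <- stats::rlnorm(1, log(cfg$creatinine_lag_median_h),
                             cfg$creatinine_lag_sdlog)
          while (l < 1 || onset[i] + l > cap - 1) {
            l <- stats::rlnorm(1, log(cfg$creatinine_lag_median_h),
                               cfg$creatinine_lag_sdlog)
          }
          lag[i] <- l
        }
      }
    }
  }
  hard_neg <- rep("none", n)
  ctrl <- which(outcome == "non_aki")
  if (length(ctrl) > 0) {
    u <- stats::runif(length(ctrl))
    hard_neg[ctrl[u < 0.25]] <- "short_dip"
    hard_neg[ctrl[u >= 0.25 & u < 0.40]] <- "ward_oliguria"
    hard_neg[ctrl[u >= 0.40 & u < 0.50]] <- "creatinine_rise"
  }
  disch_offset <- rep(NA_real_, n)
  disch_offset[ctrl] <- r_onset(length(ctrl), 14, min(160, cap))
  tibble::tibble(
    admission_id = sprintf("adm%04d", seq_len(n)),
    outcome = outcome, criterion = crit, onset_offset_h = onset,
    lag_h = lag, hard_negative = hard_neg, disch_offset_h = disch_offset
  )
}

#' Simulate one admission from a planted scenario
#'
#' Produces the full multichannel record of a single hospital stay --
#' statics, care-location segments, irregular channel streams, drug
#' events, operative-note text -- whose trajectories are engineered to
#' satisfy (for planted AKI) or provably violate (for planted controls,
#' including hard negatives) the severe-AKI criteria. Creatinine cases
#' ramp below 1.85x baseline before the planted onset and cross 2x exactly
#' at it; urine cases embed an oliguric episode whose trailing 12-h
#' time-weighted mean first drops below 0.5 ml/kg/h at the planted onset;
#' hard negatives include sub-12-h oliguric dips shallow enough that no
#' 12-h window mean reaches 0.5, ward-only oliguria (masked by the
#' reliable-location rule), and sub-doubling creatinine rises.
#'
#' @param scenario one-row scenario (as produced inside
#'   [generate_cohort()]); a list/row with `admission_id`, `outcome`,
#'   `criterion`, `onset_offset_h`, `lag_h`, `hard_negative`,
#'   `disch_offset_h`.
#' @param config an [cohort_config()] object.
#' @return list of tibbles: `static`, `locations`, `events`, `drugs`,
#'   `surgery_text`, `truth`. Uses the current RNG state.
#' @export
simulate_admission <- function(scenario, config) {
  cfg <- config
  sc <- as.list(scenario)
  if (!is.na(sc$onset_offset_h) && sc$onset_offset_h > cfg$observation_cap_h) {
    abort("planted onset lies beyond the observation cap")
  }
  id <- sc$admission_id
  s_start <- stats::runif(1, 12, 24)
  s_end <- s_start + stats::runif(1, 2.5, 5.5)
  weight <- clamp(stats::rnorm(1, 80, 15), 45, 140)
  baseline <- stats::rlnorm(1, log(1.0), 0.25)
  while (baseline >= 3.5) baseline <- stats::rlnorm(1, log(1.0), 0.25)

  is_aki <- sc$outcome == "aki"
  crit <- sc$criterion
  urine_onset <- if (is_aki && crit %in% c("urine", "both")) {
    s_end + sc$onset_offset_h
  } else NA_real_
  creat_onset <- if (is_aki) {
    if (crit == "creatinine") s_end + sc$onset_offset_h
    else if (crit == "both") urine_onset + sc$lag_h
    else NA_real_
  } else NA_real_
  onset_abs <- suppressWarnings(min(c(urine_onset, creat_onset), na.rm = TRUE))
  if (!is.finite(onset_abs)) onset_abs <- NA_real_

  discharge <- if (is_aki) {
    onset_end <- max(c(urine_onset, creat_onset), na.rm = TRUE)
    onset_end + stats::runif(1, 24, 72)
  } else {
    s_end + sc$disch_offset_h
  }

  # care locations: ward -> theatre -> recovery -> icu (-> ward)
  icu_start <- s_end + 2
  icu_end <- if (sc$hard_negative == "ward_oliguria") {
    s_end + stats::runif(1, 18, 30)
  } else if (is_aki) {
    max(onset_abs, creat_onset, urine_onset, na.rm = TRUE) + 4
  } else if (stats::runif(1) < 0.2 && discharge - icu_start > 30) {
    icu_start + 0.7 * (discharge - icu_start)
  } else {
    discharge
  }
  icu_end <- min(icu_end, discharge)
  loc <- tibble::tibble(
    admission_id = id,
    start_h = c(0, s_start, s_end, icu_start,
                if (icu_end < discharge) icu_end),
    end_h = c(s_start, s_end, icu_start, icu_end,
              if (icu_end < discharge) discharge),
    location = c("ward", "theatre", "recovery", "icu",
                 if (icu_end < discharge) "ward")
  )

  ev <- list()
  noise_mult <- function(k, sd = 0.02) clamp(exp(stats::rnorm(k, 0, sd)),
                                             0.97, 1.03)

  ## --- creatinine -----------------------------------------------------
  has_preop <- stats::runif(1) > 0.12
  pre_t <- if (has_preop) sort(stats::runif(sample(1:2, 1),
                                            max(0, s_start - 96),
                                            s_start - 2)) else numeric(0)
  post_t <- s_end + stats::runif(1, 2, 6)
  while (utils::tail(post_t, 1) < min(discharge, s_end + 170) - 12) {
    post_t <- c(post_t, utils::tail(post_t, 1) + stats::runif(1, 6, 12))
  }
  post_t <- post_t[post_t <= min(discharge, s_end + 170)]
  if (!is.na(creat_onset)) {
    post_t <- sort(unique(c(post_t[abs(post_t - creat_onset) > 0.5],
                            creat_onset)))
  }
  # without a pre-operative value the labeler falls back to the first
  # post-operative measurement; chart one at baseline right after surgery
  # so that fallback reproduces the true reference value.
  if (!has_preop) post_t <- sort(unique(c(s_end + 1, post_t)))
  mult <- rep(1, length(post_t))
  if (!is.na(creat_onset)) {
    peak <- stats::rlnorm(1, cfg$peak_creatinine_multiplier$meanlog,
                          cfg$peak_creatinine_multiplier$sdlog)
    peak <- max(peak, cfg$peak_creatinine_multiplier$min)
    before <- post_t < creat_onset
    frac <- pmax(0, (post_t[before] - s_end) / (creat_onset - s_end))
    mult[before] <- pmin(1 + 0.85 * frac^2, 1.85)
    at_on <- abs(post_t - creat_onset) < 1e-9
    mult[at_on] <- 2.15
    after <- post_t > creat_onset
    mult[after] <- pmin(2.15 + (peak - 2.15) *
                          pmin(1, (post_t[after] - creat_onset) / 24), peak)
  } else if (sc$hard_negative == "creatinine_rise") {
    top <- stats::runif(1, 1.45, 1.6)
    frac <- pmin(1, (post_t - s_end) / 48)
    mult <- 1 + (top - 1) * frac
  } else {
    mult <- 1 + 0.1 * pmin(1, (post_t - s_end) / 72) *
      stats::runif(length(post_t), -1, 1)
  }
  val_pre <- baseline * noise_mult(length(pre_t))
  val_post <- baseline * mult * noise_mult(length(post_t))
  if (!is.na(creat_onset)) {
    bef <- post_t < creat_onset
    val_post[bef] <- pmin(val_post[bef], 1.88 * baseline)
    val_post[!bef] <- pmax(val_post[!bef], 2.12 * baseline)
  } else {
    val_post <- pmin(val_post, 1.85 * baseline)
  }
  if (!has_preop) val_post[abs(post_t - (s_end + 1)) < 1e-9] <- baseline
  ev$creatinine <- tibble::tibble(time_h = c(pre_t, post_t),
                                  value = c(val_pre, val_post),
                                  channel = "creatinine")

  ## --- urine flow (ml/h as charted; rates are ml/kg/h) ----------------
  f0 <- stats::runif(1, 0.9, 1.5)
  u_t <- seq(s_start, min(discharge, s_end + 172), by = 1)
  rate <- pmax(0.7, f0 * exp(stats::rnorm(length(u_t), 0, 0.1)))
  quiet <- function(lo, hi, level) {
    z <- u_t >= lo & u_t <= hi
    rate[z] <<- level
  }
  if (!is.na(urine_onset)) {
    r_ep <- stats::runif(1, cfg$oliguria_rate_band[1],
                         cfg$oliguria_rate_band[2])
    # sustained sub-threshold episode: the rate sits at r_ep (< 0.5) for
    # exactly 12 h before the planted onset (and a little beyond), so the
    # earliest fully-low 12-h window ends at the onset; the record just
    # before the episode holds a normal rate, which keeps earlier windows
    # from qualifying. Start the episode 0.05 h early so the 15-min
    # labeler grid lands within one step after the planted onset.
    ep_start <- urine_onset - 12 - 0.05
    u_t <- sort(unique(c(u_t, ep_start, urine_onset + 2)))
    rate <- pmax(0.7, f0 * exp(stats::rnorm(length(u_t), 0, 0.1)))
    rate[u_t >= ep_start & u_t <= urine_onset + 2] <- r_ep
  } else if (sc$hard_negative == "short_dip") {
    # a genuine oliguric dip, but shorter than 12 h: never a criterion hit
    dur <- stats::runif(1, 6, 11)
    r_dip <- stats::runif(1, cfg$oliguria_rate_band[1],
                          cfg$oliguria_rate_band[2])
    latest <- min(icu_end, discharge, s_end + 168) - dur - 2
    if (latest > icu_start + 2) {
      dip_start <- stats::runif(1, icu_start + 1, latest)
      quiet(dip_start, dip_start + dur, r_dip)
    }
  } else if (sc$hard_negative == "ward_oliguria") {
    r_dip <- stats::runif(1, 0.2, 0.4)
    dip_start <- icu_end + 1
    dip_end <- min(dip_start + stats::runif(1, 14, 20), discharge - 1)
    if (dip_end > dip_start) quiet(dip_start, dip_end, r_dip)
  }
  ev$urine_flow <- tibble::tibble(time_h = u_t, value = rate * weight,
                                  channel = "urine_flow")

  ## --- other dynamic channels -----------------------------------------
  shift <- if (is_aki) cfg$effect_size else 0
  t_end_dyn <- min(discharge, s_end + 172)
  vital <- function(name, times, base, sd, aki_delta) {
    k <- length(times)
    on_post <- as.numeric(times >= s_end + 4)
    tibble::tibble(time_h = times,
                   value = stats::rnorm(k, base + aki_delta * on_post, sd),
                   channel = name)
  }
  hourly <- seq(s_start, t_end_dyn, by = 1)
  ev$map <- vital("map", hourly, stats::rnorm(1, 75, 5), 6, -5 * shift)
  ev$heart_rate <- vital("heart_rate", hourly, stats::rnorm(1, 80, 6), 7,
                         6 * shift)
  ev$lactate <- vital("lactate", seq(s_end, t_end_dyn, by = 4),
                      stats::rnorm(1, 1.3, 0.2), 0.25, 0.5 * shift)
  ev$hemoglobin <- vital("hemoglobin", seq(s_end, t_end_dyn, by = 8),
                         stats::rnorm(1, 11, 1), 0.5, 0)
  urea_t <- seq(s_end + 4, t_end_dyn, by = 10)
  urea_mult <- stats::approx(c(0, ev$creatinine$time_h, 1e6),
                             c(1, ev$creatinine$value / baseline, 1),
                             xout = urea_t, rule = 2, ties = "ordered")$y
  ev$urea <- tibble::tibble(time_h = urea_t,
                            value = 35 * urea_mult *
                              exp(stats::rnorm(length(urea_t), 0, 0.1)),
                            channel = "urea")
  every2 <- seq(s_end, t_end_dyn, by = 2)
  for (j in seq_len(cfg$n_informative_channels)) {
    ev[[paste0("marker_", j)]] <- tibble::tibble(
      time_h = every2,
      value = stats::rnorm(length(every2), shift, 1),
      channel = paste0("marker_", j))
  }
  for (j in seq_len(cfg$n_noise_channels)) {
    ev[[paste0("noise_", j)]] <- tibble::tibble(
      time_h = every2,
      value = stats::rnorm(length(every2), 0, 1),
      channel = paste0("noise_", j))
  }

  events <- dplyr::bind_rows(ev)
  events$admission_id <- id
  events <- events[events$time_h >= 0 & events$time_h <= discharge, ]
  events <- dplyr::arrange(events, .data$channel, .data$time_h)
  events$location <- loc$location[
    findInterval(events$time_h, loc$start_h, rightmost.closed = TRUE)]
  events <- dplyr::select(events, "admission_id", "time_h", "channel",
                          "value", "location")

  ## --- drugs and text ---------------------------------------------------
  agents <- c("nsaid", "vancomycin", "aminoglycoside", "ppi", "diuretic_adj")
  n_drug <- stats::rpois(1, cfg$drug_event_rate * discharge / 24)
  drugs <- tibble::tibble(
    admission_id = id,
    time_h = sort(stats::runif(n_drug, 0, discharge)),
    agent = sample(agents, n_drug, replace = TRUE)
  )
  category <- sample(names(surgery_vocab()), 1)
  text <- generate_surgery_text(category)

  list(
    static = tibble::tibble(
      admission_id = id, age = round(stats::runif(1, 35, 85)),
      sex = sample(c("f", "m"), 1), weight_kg = weight,
      height_cm = round(clamp(stats::rnorm(1, 172, 10), 150, 200)),
      surgery_start_h = s_start, surgery_end_h = s_end,
      surgery_category = category, discharge_h = discharge,
      dialysis_before_surgery_end = FALSE, baseline_creatinine_true = baseline
    ),
    locations = loc,
    events = events,
    drugs = drugs,
    surgery_text = tibble::tibble(admission_id = id, category = category,
                                  text = text),
    truth = tibble::tibble(
      admission_id = id, aki = as.integer(is_aki),
      criterion = ifelse(is_aki, crit, "none"),
      onset_h = onset_abs, urine_onset_h = urine_onset,
      creatinine_onset_h = creat_onset,
      lag_h = sc$lag_h %||% NA_real_, hard_negative = sc$hard_negative
    )
  )
}

#' Generate a synthetic postoperative EHR cohort
#'
#' Draws planted scenarios (outcome, criterion, onset, hard-negative type)
#' according to the configuration and simulates every admission. The
#' planted AKI fraction is exact up to rounding (`round(n *
#' aki_fraction)` cases); the criterion mix matches the configured
#' proportions up to multinomial sampling error; the entire cohort is a
#' pure function of the configuration including its seed. The ground truth
#' is returned as a separate table so the pipeline can be run blinded.
#'
#' @param config an [cohort_config()] object.
#' @return object of class `aki_cohort`: list of tibbles `static`,
#'   `events`, `locations`, `drugs`, `surgery_text`, `truth`,
#'   `channel_defaults`, plus the `config`.
#' @export
generate_cohort <- function(config) {
  validate_cohort_config(config)
  with_seed(config$seed, {
    scen <- draw_scenarios(config)
    sims <- purrr::map(seq_len(nrow(scen)),
                       function(i) simulate_admission(scen[i, ], config))
  })
  pick <- function(what) dplyr::bind_rows(purrr::map(sims, what))
  out <- list(
    config = config,
    static = pick("static"),
    events = pick("events"),
    locations = pick("locations"),
    drugs = pick("drugs"),
    surgery_text = pick("surgery_text"),
    truth = pick("truth"),
    channel_defaults = channel_defaults(config)
  )
  structure(out, class = "aki_cohort")
}

#' Default clinical values for every channel of a cohort
#'
#' One static default per feature, imputed when a channel has no
#' observation yet at the start of a window. The physiological channels'
#' defaults ship as an editable CSV (`inst/extdata/clinical_defaults.csv`);
#' configurable synthetic channels default to their generative mean.
#'
#' @param config an [cohort_config()] object.
#' @return tibble `channel`, `default`, `unit`.
#' @export
channel_defaults <- function(config) {
  base <- utils::read.csv(
    system.file("extdata", "clinical_defaults.csv", package = "akirisk"),
    stringsAsFactors = FALSE)
  extra <- tibble::tibble(
    channel = c(paste0("marker_", seq_len(config$n_informative_channels)),
                paste0("noise_", seq_len(config$n_noise_channels))),
    default = 0, unit = "sd"
  )
  dplyr::bind_rows(tibble::as_tibble(base), extra)
}

#' @export
print.aki_cohort <- function(x, ...) {
  cat(sprintf(
    "<aki_cohort> %d admissions (%d planted AKI), %d events, seed %d\n",
    nrow(x$static), sum(x$truth$aki), nrow(x$events), x$config$seed))
  invisible(x)
}
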