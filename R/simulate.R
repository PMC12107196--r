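#' Simulation configuration for the synthetic ED registry
#'
#' Bundles every tunable of the synthetic-registry generator. The defaults
#' emulate the case mix of a large tertiary-hospital ED cohort of ambulatory
#' (triage priority 3/4) presentations: ~510 distinct primary ICD-10 codes
#' with Zipf-like frequencies, four latent admission-risk tiers with rates of
#' roughly 5%, 20%, 48% and 78%, presentation-mass shares of
#' 61% / 20.6% / 12.9% / 5.5% across the tiers (giving an overall admission
#' rate near 17.3%), and covariate effects on the admission odds of the
#' magnitudes reported for comorbidity burden, vital-sign derangement and
#' recent utilisation in such cohorts.
#'
#' @param n_presentations number of ED presentations to simulate.
#' @param n_codes number of distinct ICD-10 codes in the universe.
#' @param n_tiers number of latent risk tiers.
#' @param tier_risk_centers strictly increasing admission probabilities, one
#'   per tier; the Beta distribution of each tier's per-code risks is centred
#'   here.
#' @param tier_risk_spread Beta concentration parameter (shape1 + shape2);
#'   larger is tighter around the centre. `Inf` collapses every code's risk
#'   onto its tier centre exactly.
#' @param tier_proportions share of *codes* per tier (normalised internally).
#' @param zipf_exponent positive exponent `s` of the rank-frequency law
#'   `weight(rank) = rank^-s`.
#' @param frequency_allocation how Zipf ranks are assigned to codes:
#'   `"tier_mass"` (default) steers each tier's total presentation mass
#'   towards `tier_mass_targets` by a greedy largest-deficit fill;
#'   `"random"` permutes ranks uniformly over codes.
#' @param tier_mass_targets target share of presentations per tier, used only
#'   under `frequency_allocation = "tier_mass"`.
#' @param covariate_effects named numeric vector of log-odds effects added to
#'   the admission logit on top of the code's base risk. Supported names:
#'   `age`, `sex_male`, `ethnicity_indian`, `ethnicity_malay`,
#'   `ethnicity_others`, `hypotension`, `hypertension`, `bradycardia`,
#'   `tachycardia`, `hypothermia`, `hyperthermia`, `cci_mild`,
#'   `cci_moderate`, `cci_severe`, `prior_ed`, `prior_inpt`, `prior_surg`,
#'   `prior_icu`, `prior_hd`, `prior_ica`, `prior_infect`. Effects are applied
#'   to covariates centred at their sample means, so a code's configured risk
#'   remains (up to Jensen error) its marginal admission probability.
#' @param covariate_params list of distribution parameters for the simulated
#'   covariates; see the defaults in the function signature.
#' @param seed integer seed; the code universe is drawn with `seed` and the
#'   presentations with `seed + 1`.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_presentations = 215477L,
                       n_codes = 510L,
                       n_tiers = 4L,
                       tier_risk_centers = c(0.047, 0.195, 0.478, 0.78),
                       tier_risk_spread = 500,
                       tier_proportions = c(262, 104, 66, 78) / 510,
                       zipf_exponent = 1,
                       frequency_allocation = c("tier_mass", "random"),
                       tier_mass_targets = c(0.61, 0.206, 0.129, 0.055),
                       covariate_effects = default_covariate_effects(),
                       covariate_params = default_covariate_params(),
                       seed = 1L) {
  frequency_allocation <- match.arg(frequency_allocation)
  if (n_tiers != length(tier_risk_centers)) {
    abort("n_tiers must equal length(tier_risk_centers)", "edrisk_config_error")
  }
  if (any(diff(tier_risk_centers) <= 0) ||
      any(tier_risk_centers <= 0) || any(tier_risk_centers >= 1)) {
    abort("tier_risk_centers must be strictly increasing and inside (0, 1)",
          "edrisk_config_error")
  }
  if (zipf_exponent <= 0) {
    abort("zipf_exponent must be positive", "edrisk_config_error")
  }
  if (length(tier_proportions) != n_tiers || any(tier_proportions <= 0)) {
    abort("tier_proportions must be positive, one per tier", "edrisk_config_error")
  }
  if (frequency_allocation == "tier_mass" &&
      (length(tier_mass_targets) != n_tiers || any(tier_mass_targets <= 0))) {
    abort("tier_mass_targets must be positive, one per tier", "edrisk_config_error")
  }
  structure(list(
    n_presentations = as.integer(n_presentations),
    n_codes = as.integer(n_codes),
    n_tiers = as.integer(n_tiers),
    tier_risk_centers = tier_risk_centers,
    tier_risk_spread = tier_risk_spread,
    tier_proportions = tier_proportions / sum(tier_proportions),
    zipf_exponent = zipf_exponent,
    frequency_allocation = frequency_allocation,
    tier_mass_targets = tier_mass_targets / sum(tier_mass_targets),
    covariate_effects = covariate_effects,
    covariate_params = covariate_params,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Default covariate effects on the admission logit
#'
#' Log odds ratios calibrated to the magnitudes reported for ambulatory ED
#' cohorts: comorbidity burden is the strongest driver, followed by
#' hyperthermia and tachycardia; recent surgery and inpatient admission raise
#' the odds modestly, while recent ED/ICU/high-dependency contact lowers them
#' slightly.
#'
#' @return named numeric vector of log odds ratios.
#' @export
default_covariate_effects <- function() {
  log(c(
    tachycardia   = 1.46,
    hyperthermia  = 2.32,
    cci_mild      = 2.55,
    cci_moderate  = 3.50,
    cci_severe    = 5.28,
    prior_surg    = 1.31,
    prior_inpt    = 1.16,
    prior_ed      = 0.86,
    prior_icu     = 0.85,
    prior_hd      = 0.85
  ))
}

#' Default covariate distribution parameters
#'
#' Marginal distributions chosen so that the simulated cohort reproduces the
#' descriptive profile of an ambulatory ED population: mean age 46.2 (SD 19.4)
#' years, 53.4% male, ethnic mix 58.4/15.5/12.2/13.9% Chinese/Indian/Malay/
#' Others, ~0.1% hypotensive and ~41% hypertensive, ~3.6% bradycardic and
#' ~27% tachycardic, ~2% hypothermic and ~8% hyperthermic, CCI none/mild/
#' moderate/severe of roughly 82/11/3.8/3.4%, and sparse overdispersed prior
#' six-month utilisation counts.
#'
#' @return named list of distribution parameters.
#' @export
default_covariate_params <- function() {
  list(
    age_mean = 46.2, age_sd = 19.4, age_range = c(0, 110),
    male_prev = 0.534,
    ethnicity_levels = c("Chinese", "Indian", "Malay", "Others"),
    ethnicity_probs = c(0.584, 0.155, 0.122, 0.139),
    sbp_mean = 127, sbp_sd = 12, sbp_range = c(50, 250),
    pulse_mean = 82, pulse_sd = 12, pulse_range = c(30, 220),
    temp_mean = 36.65, temp_sd = 0.6, temp_range = c(33, 42),
    cci_probs = c(`0` = 0.819, `1` = 0.070, `2` = 0.040, `3` = 0.025,
                  `4` = 0.013, `5` = 0.015, `6` = 0.010, `7` = 0.005,
                  `8` = 0.003),
    prior_nb = list( # negative-binomial mu / size per prior-count column
      prior_ed     = c(mu = 0.60, size = 0.12),
      prior_inpt   = c(mu = 0.20, size = 0.20),
      prior_surg   = c(mu = 0.04, size = 0.10),
      prior_icu    = c(mu = 0.01, size = 0.10),
      prior_hd     = c(mu = 0.02, size = 0.10),
      prior_ica    = c(mu = 0.01, size = 0.10),
      prior_infect = c(mu = 0.08, size = 0.10)
    )
  )
}

#' Construct a code universe by hand
#'
#' Low-level constructor used by [generate_code_universe()] and convenient in
#' tests for degenerate universes (e.g. a single code of known risk).
#'
#' @param code character vector of unique ICD-10 codes.
#' @param true_risk per-code admission probability in `[0, 1]`.
#' @param tier integer tier index per code.
#' @param frequency_weight positive sampling weight per code (normalised).
#' @return data frame of class `code_universe`.
#' @export
code_universe <- function(code, true_risk, tier = rep(1L, length(code)),
                          frequency_weight = rep(1, length(code))) {
  code <- as.character(code)
  if (anyDuplicated(code)) abort("code strings must be unique", "edrisk_config_error")
  if (any(true_risk < 0 | true_risk > 1)) {
    abort("true_risk must lie in [0, 1]", "edrisk_config_error")
  }
  if (any(frequency_weight <= 0)) {
    abort("frequency weights must be positive", "edrisk_config_error")
  }
  structure(
    data.frame(code = code, tier = as.integer(tier), true_risk = true_risk,
               frequency_weight = frequency_weight / sum(frequency_weight),
               stringsAsFactors = FALSE),
    class = c("code_universe", "data.frame")
  )
}

# All 3-character prefixes covered by a block table (used to draw realistic,
# mappable code strings).
block_prefixes <- function(blocks) {
  letters26 <- LETTERS
  expand_one <- function(start, end) {
    l1 <- substr(start, 1, 1); l2 <- substr(end, 1, 1)
    n1 <- as.integer(substr(start, 2, 3)); n2 <- as.integer(substr(end, 2, 3))
    if (l1 == l2) {
      sprintf("%s%02d", l1, n1:n2)
    } else {
      ls <- letters26[match(l1, letters26):match(l2, letters26)]
      unlist(lapply(seq_along(ls), function(i) {
        lo <- if (i == 1) n1 else 0L
        hi <- if (i == length(ls)) n2 else 99L
        sprintf("%s%02d", ls[i], lo:hi)
      }))
    }
  }
  unique(unlist(Map(expand_one,
                    sub("-.*", "", blocks$block_id),
                    sub(".*-", "", blocks$block_id))))
}

#' Generate the ICD-10 code universe
#'
#' Draws `n_codes` distinct ICD-10 codes (3-character prefixes sampled from
#' the ranges of the packaged WHO block table, a random ~30% of them extended
#' with a fourth digit), partitions them into latent risk tiers, draws each
#' code's true admission risk from a Beta distribution centred at its tier's
#' centre, and attaches Zipf rank-frequency sampling weights.
#'
#' Under the default `frequency_allocation = "tier_mass"`, Zipf ranks are
#' dealt to tiers by a greedy largest-deficit fill so that each tier's total
#' presentation mass tracks `tier_mass_targets`; this is what lets the
#' simulated overall admission rate land near the frequency-weighted mean of
#' the tier centres. With `"random"`, ranks are permuted uniformly over codes.
#'
#' @param config a [sim_config()].
#' @param blocks block table used to draw mappable prefixes; defaults to the
#'   packaged WHO table.
#' @return a `code_universe` data frame with `n_codes` rows.
#' @export
generate_code_universe <- function(config, blocks = icd10_blocks()) {
  stopifnot(inherits(config, "sim_config"))
  with_rng(config$seed, {
    n <- config$n_codes
    prefixes <- block_prefixes(blocks)
    if (n > length(prefixes)) {
      abort("n_codes exceeds the number of available ICD-10 prefixes",
            "edrisk_config_error")
    }
    codes <- sample(prefixes, n)
    ext <- sample(c(TRUE, FALSE), n, replace = TRUE, prob = c(0.3, 0.7))
    codes[ext] <- paste0(codes[ext], sample(0:9, sum(ext), replace = TRUE))

    # tier sizes by largest remainder, then tiers dealt in a fixed order
    raw <- config$tier_proportions * n
    sizes <- floor(raw)
    rem <- n - sum(sizes)
    if (rem > 0) {
      top_up <- order(raw - sizes, decreasing = TRUE)[seq_len(rem)]
      sizes[top_up] <- sizes[top_up] + 1L
    }
    tier <- rep(seq_len(config$n_tiers), sizes)

    centers <- config$tier_risk_centers[tier]
    s <- config$tier_risk_spread
    true_risk <- if (is.infinite(s)) centers else {
      stats::rbeta(n, shape1 = centers * s, shape2 = (1 - centers) * s)
    }

    w <- seq_len(n)^(-config$zipf_exponent)
    w <- w / sum(w)
    if (config$frequency_allocation == "random") {
      weight <- numeric(n)
      weight[sample.int(n)] <- w
    } else {
      # greedy largest-deficit fill: rank r goes to the tier whose assigned
      # presentation mass is furthest below its target (among tiers with
      # unranked codes left), then to a random unranked code of that tier
      queues <- lapply(split(seq_len(n), tier), sample)
      remaining <- vapply(queues, length, integer(1))
      assigned <- numeric(config$n_tiers)
      weight <- numeric(n)
      for (r in seq_len(n)) {
        deficit <- config$tier_mass_targets - assigned
        deficit[remaining == 0] <- -Inf
        t <- which.max(deficit)
        idx <- queues[[t]][remaining[t]]
        remaining[t] <- remaining[t] - 1L
        assigned[t] <- assigned[t] + w[r]
        weight[idx] <- w[r]
      }
    }
    code_universe(codes, true_risk, tier, weight)
  })
}

# covariate columns supported in covariate_effects, computed from records
admission_covariates <- function(rec) {
  cbind(
    age = rec$age,
    sex_male = as.numeric(rec$sex == "male"),
    ethnicity_indian = as.numeric(rec$ethnicity == "Indian"),
    ethnicity_malay = as.numeric(rec$ethnicity == "Malay"),
    ethnicity_others = as.numeric(rec$ethnicity == "Others"),
    hypotension = as.numeric(rec$sbp < 90),
    hypertension = as.numeric(rec$sbp > 130),
    bradycardia = as.numeric(rec$pulse < 60),
    tachycardia = as.numeric(rec$pulse > 90),
    hypothermia = as.numeric(rec$temp < 35.5),
    hyperthermia = as.numeric(rec$temp > 37.5),
    cci_mild = as.numeric(rec$cci >= 1 & rec$cci <= 2),
    cci_moderate = as.numeric(rec$cci >= 3 & rec$cci <= 4),
    cci_severe = as.numeric(rec$cci >= 5),
    prior_ed = rec$prior_ed, prior_inpt = rec$prior_inpt,
    prior_surg = rec$prior_surg, prior_icu = rec$prior_icu,
    prior_hd = rec$prior_hd, prior_ica = rec$prior_ica,
    prior_infect = rec$prior_infect
  )
}

registry_columns <- c("id", "icd10", "admitted", "age", "sex", "ethnicity",
                      "sbp", "pulse", "temp", "cci", "prior_ed", "prior_inpt",
                      "prior_surg", "prior_icu", "prior_hd", "prior_ica",
                      "prior_infect")

empty_registry <- function() {
  data.frame(id = character(), icd10 = character(), admitted = integer(),
             age = integer(), sex = character(), ethnicity = character(),
             sbp = integer(), pulse = integer(), temp = numeric(),
             cci = integer(), prior_ed = integer(), prior_inpt = integer(),
             prior_surg = integer(), prior_icu = integer(), prior_hd = integer(),
             prior_ica = integer(), prior_infect = integer(),
             stringsAsFactors = FALSE)
}

# truncated-normal sampler via inverse-CDF on the truncated range
rtnorm <- function(n, mean, sd, range) {
  lo <- stats::pnorm(range[1], mean, sd)
  hi <- stats::pnorm(range[2], mean, sd)
  stats::qnorm(stats::runif(n, lo, hi), mean, sd)
}

#' Simulate presentation-level ED records
#'
#' Each presentation draws a primary diagnosis code from the universe by its
#' frequency weight, covariates from the configured marginal distributions,
#' and an admission outcome from a Bernoulli whose logit is the code's base
#' risk logit plus the configured covariate effects. Effects are applied to
#' covariates centred at their sample means, so the configured per-code risks
#' keep their meaning as (approximate) marginal admission probabilities.
#'
#' @param universe a `code_universe`.
#' @param config a [sim_config()]; presentations are drawn with seed
#'   `config$seed + 1`.
#' @return data frame with one row per presentation (the registry layout:
#'   `id, icd10, admitted, age, sex, ethnicity, sbp, pulse, temp, cci,
#'   prior_*`).
#' @export
generate_presentations <- function(universe, config) {
  stopifnot(inherits(config, "sim_config"))
  if (nrow(universe) == 0) abort("code universe is empty", "edrisk_config_error")
  n <- config$n_presentations
  if (n == 0) return(empty_registry())
  p <- config$covariate_params
  with_rng(config$seed + 1L, {
    idx <- sample.int(nrow(universe), n, replace = TRUE,
                      prob = universe$frequency_weight)
    rec <- data.frame(
      id = sprintf("P%07d", seq_len(n)),
      icd10 = universe$code[idx],
      admitted = NA_integer_,
      age = as.integer(round(rtnorm(n, p$age_mean, p$age_sd, p$age_range))),
      sex = ifelse(stats::runif(n) < p$male_prev, "male", "female"),
      ethnicity = sample(p$ethnicity_levels, n, replace = TRUE,
                         prob = p$ethnicity_probs),
      sbp = as.integer(round(rtnorm(n, p$sbp_mean, p$sbp_sd, p$sbp_range))),
      pulse = as.integer(round(rtnorm(n, p$pulse_mean, p$pulse_sd, p$pulse_range))),
      temp = round(rtnorm(n, p$temp_mean, p$temp_sd, p$temp_range), 1),
      cci = as.integer(sample(as.integer(names(p$cci_probs)), n, replace = TRUE,
                              prob = p$cci_probs)),
      stringsAsFactors = FALSE
    )
    for (col in names(p$prior_nb)) {
      par <- p$prior_nb[[col]]
      rec[[col]] <- stats::rnbinom(n, mu = par[["mu"]], size = par[["size"]])
    }
    eta <- stats::qlogis(universe$true_risk[idx])
    eff <- config$covariate_effects
    if (length(eff)) {
      X <- admission_covariates(rec)
      unknown <- setdiff(names(eff), colnames(X))
      if (length(unknown)) {
        abort(paste0("unknown covariate effect(s): ",
                     paste(unknown, collapse = ", ")), "edrisk_config_error")
      }
      Xc <- scale(X[, names(eff), drop = FALSE], center = TRUE, scale = FALSE)
      eta <- eta + as.vector(Xc %*% eff)
    }
    rec$admitted <- stats::rbinom(n, 1L, stats::plogis(eta))
    rec
  })
}

#' Write / read a registry file
#'
#' The registry is a plain comma-delimited file with a header row and the
#' fixed column set `id, icd10, admitted, age, sex, ethnicity, sbp, pulse,
#' temp, cci, prior_ed, prior_inpt, prior_surg, prior_icu, prior_hd,
#' prior_ica, prior_infect`. Empty fields are missing values. Reading
#' validates each field and fails with the offending row and column named.
#'
#' @param records registry data frame.
#' @param path file path.
#' @return `write_registry()` returns `path` invisibly; `read_registry()`
#'   returns the registry data frame.
#' @export
write_registry <- function(records, path) {
  stopifnot(all(registry_columns %in% names(records)))
  utils::write.csv(records[registry_columns], path, row.names = FALSE,
                   quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_registry
#' @export
read_registry <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character", na.strings = "",
                         stringsAsFactors = FALSE)
  missing_cols <- setdiff(registry_columns, names(raw))
  if (length(missing_cols)) {
    abort(paste0("registry is missing column(s): ",
                 paste(missing_cols, collapse = ", ")), "edrisk_parse_error")
  }
  raw <- raw[registry_columns]
  if (nrow(raw) == 0) return(empty_registry())

  fail_cell <- function(col, rows) {
    abort(sprintf("malformed value in column '%s' at row %d", col, rows[1]),
          "edrisk_parse_error")
  }
  bad <- which(!is.na(raw$icd10) &
                 !grepl("^[A-Z][0-9]{2}[A-Za-z0-9]?$", raw$icd10))
  if (length(bad)) fail_cell("icd10", bad)
  bad <- which(!is.na(raw$admitted) & !raw$admitted %in% c("0", "1"))
  if (length(bad)) fail_cell("admitted", bad)
  for (col in c("sex", "ethnicity")) {
    ok <- c(female = "sex", male = "sex", Chinese = "ethnicity",
            Indian = "ethnicity", Malay = "ethnicity", Others = "ethnicity")
    bad <- which(!is.na(raw[[col]]) & !raw[[col]] %in% names(ok)[ok == col])
    if (length(bad)) fail_cell(col, bad)
  }
  num_cols <- setdiff(registry_columns, c("id", "icd10", "admitted", "sex",
                                          "ethnicity"))
  out <- raw
  out$admitted <- as.integer(raw$admitted)
  for (col in num_cols) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & !is.na(raw[[col]]))
    if (length(bad)) fail_cell(col, bad)
    if (any(v < 0, na.rm = TRUE) && col != "temp") fail_cell(col, which(v < 0))
    out[[col]] <- if (col == "temp") v else as.integer(v)
  }
  out
}
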