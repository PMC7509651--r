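# Synthetic cohort generator. No subject-level data are distributed with the
# study this package operationalises, so every downstream stage is exercised
# on simulated cohorts that reproduce the features the method depends on:
# right-skewed positively correlated nuclear markers, a cancer shift up on
# nuclear markers and down on MNR, per-marker AUC separations matching the
# published estimates, an age bias (healthy younger, cancer older), and
# missing values on tree variables.

#' Generator configuration for synthetic cohorts
#'
#' Markers are drawn from a multivariate log-normal: group-specific location
#' on the log10 scale with a covariance shared across groups (location-shift
#' model). MNR and DII are derived from the sampled markers, never sampled,
#' so the defining ratios hold exactly. Ages are integers drawn from
#' piecewise-constant distributions over bands.
#'
#' @param n_cancer,n_healthy Group sizes (>= 0).
#' @param log_mean_cancer,log_mean_healthy Named numeric vectors of log10
#'   locations for `ref_a67`, `ref_a145`, `ref_a320`, `ref_m67`.
#' @param log_cov 4x4 symmetric positive-definite covariance on the log10
#'   scale, shared across groups, with marker names as dimnames.
#' @param age_bands_cancer,age_bands_healthy Data frames with columns
#'   `lower`, `upper`, `weight`: integer ages are drawn uniformly within a
#'   band chosen with probability proportional to `weight`.
#' @param sex_female_prob_cancer,sex_female_prob_healthy Probability of
#'   female sex per group; ignored when `female_only = TRUE`.
#' @param female_only All subjects female (breast-cancer cohorts).
#' @param stage_probs Named probabilities over cancer stage labels, or NULL
#'   for no stage assignment.
#' @param stage_shift_frac Optional named vector mapping stage labels to the
#'   fraction of the full cancer log-mean shift that subjects of that stage
#'   receive (e.g. early stages < 1); NULL applies the full shift to all.
#' @param missing_rate Named per-marker probabilities of missingness.
#' @param age_marker_slope Optional named per-marker linear trend of the
#'   log10 marker on centred age (units: log10 copies/mL per year), applied
#'   to both groups; 0 (off) by default because its magnitude is not
#'   established.
#' @param cancer_label Group label for cancer subjects (e.g. `"crc"`).
#' @param seed Default RNG seed used by [generate_cohort()].
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_cancer, n_healthy,
                             log_mean_cancer, log_mean_healthy, log_cov,
                             age_bands_cancer, age_bands_healthy,
                             sex_female_prob_cancer = 0.45,
                             sex_female_prob_healthy = 0.40,
                             female_only = FALSE,
                             stage_probs = NULL,
                             stage_shift_frac = NULL,
                             missing_rate = c(ref_a67 = 0, ref_a145 = 0,
                                              ref_a320 = 0, ref_m67 = 0),
                             age_marker_slope = NULL,
                             cancer_label = "cancer",
                             seed = NULL) {
  mk <- measured_markers()
  stopifnot(n_cancer >= 0, n_healthy >= 0)
  log_mean_cancer <- log_mean_cancer[mk]
  log_mean_healthy <- log_mean_healthy[mk]
  if (anyNA(log_mean_cancer) || anyNA(log_mean_healthy)) {
    stop_invalid("log means must be named for all four measured markers")
  }
  log_cov <- as.matrix(log_cov)
  if (!isTRUE(all.equal(log_cov, t(log_cov)))) {
    stop_invalid("log_cov must be symmetric")
  }
  ev <- eigen(log_cov, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop_invalid("log_cov must be positive-definite")
  mr <- missing_rate[mk]
  mr[is.na(mr)] <- 0
  names(mr) <- mk
  if (any(mr < 0 | mr > 1)) stop_invalid("missing_rate must be in [0, 1]")
  for (b in list(age_bands_cancer, age_bands_healthy)) {
    stopifnot(all(c("lower", "upper", "weight") %in% names(b)),
              all(b$upper >= b$lower), all(b$weight >= 0), sum(b$weight) > 0)
  }
  structure(
    list(n_cancer = as.integer(n_cancer), n_healthy = as.integer(n_healthy),
         log_mean_cancer = log_mean_cancer, log_mean_healthy = log_mean_healthy,
         log_cov = log_cov,
         age_bands_cancer = age_bands_cancer,
         age_bands_healthy = age_bands_healthy,
         sex_female_prob_cancer = sex_female_prob_cancer,
         sex_female_prob_healthy = sex_female_prob_healthy,
         female_only = isTRUE(female_only),
         stage_probs = stage_probs, stage_shift_frac = stage_shift_frac,
         missing_rate = mr, age_marker_slope = age_marker_slope,
         cancer_label = cancer_label, seed = seed),
    class = "generator_config"
  )
}

# Shared covariance used by both shipped defaults: log10-scale SDs chosen to
# span the order-of-magnitude spread seen in plasma cfDNA, a tightly nested
# nuclear block (the 145 and 320 bp amplicons measure sub-fractions of the
# 67 bp total) and a mitochondrial marker independent of the nuclear block.
default_log_cov <- function() {
  mk <- measured_markers()
  sds <- c(0.50, 0.55, 0.60, 0.60)
  corr <- diag(4)
  corr[1, 2] <- corr[2, 1] <- 0.90
  corr[1, 3] <- corr[3, 1] <- 0.70
  corr[2, 3] <- corr[3, 2] <- 0.75
  cov <- corr * (sds %o% sds)
  dimnames(cov) <- list(mk, mk)
  cov
}

#' Default colorectal-cancer cohort configuration
#'
#' Healthy log10 locations place the marker medians at realistic plasma
#' levels (Ref A 67 about 2000 copies/mL, Ref M 67 about 5e7 copies/mL).
#' Cancer shifts are solved analytically from the published per-marker AUC
#' estimates for CRC versus healthy (0.83, 0.83, 0.76 for the nuclear
#' markers, 0.59 for Ref M 67, implying 0.78 for the derived MNR) via
#' AUC = pnorm(shift / (sd * sqrt(2))) under the shared-covariance
#' log-normal model. Ages carry the cohort's bias: healthy subjects peak in
#' their 40s, cancer subjects in their 60s, over the 30-70 window.
#'
#' @param n_cancer,n_healthy Group sizes; defaults match the retrospective
#'   CRC cohort (791 cancer, 289 healthy).
#' @param seed Default seed recorded in the config.
#' @return A `generator_config`.
#' @export
default_crc_config <- function(n_cancer = 791, n_healthy = 289, seed = NULL) {
  mk <- measured_markers()
  healthy <- c(ref_a67 = 3.30, ref_a145 = 3.00, ref_a320 = 2.40,
               ref_m67 = 7.70)
  shift <- c(ref_a67 = 0.675, ref_a145 = 0.742, ref_a320 = 0.599,
             ref_m67 = -0.193)
  bands <- function(w) data.frame(
    lower = seq(30, 65, by = 5), upper = c(seq(34, 64, by = 5), 70),
    weight = w
  )
  generator_config(
    n_cancer = n_cancer, n_healthy = n_healthy,
    log_mean_cancer = healthy + shift, log_mean_healthy = healthy,
    log_cov = default_log_cov(),
    age_bands_cancer = bands(c(0.02, 0.03, 0.05, 0.08, 0.12, 0.18, 0.24, 0.28)),
    age_bands_healthy = bands(c(0.10, 0.15, 0.20, 0.20, 0.15, 0.10, 0.06, 0.04)),
    sex_female_prob_cancer = 0.42, sex_female_prob_healthy = 0.38,
    stage_probs = c("0" = 0.05, "I" = 0.22, "II" = 0.27,
                    "III" = 0.23, "IV" = 0.23),
    missing_rate = c(ref_a67 = 0, ref_a145 = 0.04, ref_a320 = 0.04,
                     ref_m67 = 0.04),
    cancer_label = "crc", seed = seed
  )
}

#' Default breast-cancer cohort configuration
#'
#' All subjects female, ages restricted to the 25-65 window with healthy
#' subjects over-represented at young ages. Cancer shifts are solved from
#' the published breast-versus-healthy AUC estimates (Ref A 67 0.77,
#' Ref A 145 0.69, Ref A 320 0.60, Ref M 67 0.72, implying 0.82 for MNR).
#'
#' @param n_cancer,n_healthy Group sizes; defaults match the breast cohort
#'   (169 cancer, 289 healthy).
#' @param seed Default seed recorded in the config.
#' @return A `generator_config`.
#' @export
default_breast_config <- function(n_cancer = 169, n_healthy = 289,
                                  seed = NULL) {
  healthy <- c(ref_a67 = 3.30, ref_a145 = 3.00, ref_a320 = 2.40,
               ref_m67 = 7.70)
  shift <- c(ref_a67 = 0.522, ref_a145 = 0.386, ref_a320 = 0.215,
             ref_m67 = -0.495)
  bands <- function(w) data.frame(
    lower = seq(25, 60, by = 5), upper = c(seq(29, 59, by = 5), 65),
    weight = w
  )
  generator_config(
    n_cancer = n_cancer, n_healthy = n_healthy,
    log_mean_cancer = healthy + shift, log_mean_healthy = healthy,
    log_cov = default_log_cov(),
    age_bands_cancer = bands(c(0.04, 0.08, 0.12, 0.18, 0.22, 0.16, 0.12, 0.08)),
    age_bands_healthy = bands(c(0.18, 0.18, 0.16, 0.14, 0.12, 0.10, 0.07, 0.05)),
    female_only = TRUE,
    stage_probs = c("II" = 0.6, "III" = 0.4),
    missing_rate = c(ref_a67 = 0, ref_a145 = 0.01, ref_a320 = 0.01,
                     ref_m67 = 0.01),
    cancer_label = "breast", seed = seed
  )
}

draw_ages <- function(n, bands) {
  if (n == 0) return(integer(0))
  band <- sample.int(nrow(bands), n, replace = TRUE,
                     prob = bands$weight / sum(bands$weight))
  lo <- bands$lower[band]
  hi <- bands$upper[band]
  as.integer(lo + floor(stats::runif(n) * (hi - lo + 1)))
}

#' Generate a synthetic cohort
#'
#' Draws `n_cancer + n_healthy` subjects under a `generator_config`:
#' markers from the group-specific multivariate log-normal (shared
#' covariance), integer ages from the per-group band distributions, sex and
#' stage labels, derived `mnr` and `dii`, then per-marker missingness.
#' Deterministic given the seed.
#'
#' @param config A [generator_config()].
#' @param seed RNG seed; defaults to `config$seed`.
#' @return Cohort data frame (cancer rows first) with a `provenance`
#'   attribute recording the source and seed.
#' @export
generate_cohort <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "generator_config"))
  mk <- measured_markers()
  n_c <- config$n_cancer
  n_h <- config$n_healthy
  n <- n_c + n_h
  with_seed(seed, {
    group <- c(rep(config$cancer_label, n_c), rep("healthy", n_h))
    stage <- rep(NA_character_, n)
    if (n_c > 0 && !is.null(config$stage_probs)) {
      stage[seq_len(n_c)] <- sample(names(config$stage_probs), n_c,
                                    replace = TRUE,
                                    prob = config$stage_probs)
    }
    age <- c(draw_ages(n_c, config$age_bands_cancer),
             draw_ages(n_h, config$age_bands_healthy))
    sex <- if (config$female_only) {
      rep("F", n)
    } else {
      p <- c(rep(config$sex_female_prob_cancer, n_c),
             rep(config$sex_female_prob_healthy, n_h))
      ifelse(stats::runif(n) < p, "F", "M")
    }
    # centred multivariate normal noise, then group/stage-specific location
    z <- if (n > 0) {
      MASS::mvrnorm(n, mu = rep(0, 4), Sigma = config$log_cov)
    } else {
      matrix(numeric(0), 0, 4)
    }
    if (n == 1) z <- matrix(z, 1, 4)
    colnames(z) <- mk
    full_shift <- config$log_mean_cancer - config$log_mean_healthy
    mu <- matrix(rep(config$log_mean_healthy, each = n), n, 4,
                 dimnames = list(NULL, mk))
    if (n_c > 0) {
      frac <- rep(1, n_c)
      if (!is.null(config$stage_shift_frac)) {
        frac <- unname(config$stage_shift_frac[stage[seq_len(n_c)]])
        frac[is.na(frac)] <- 1
      }
      mu[seq_len(n_c), ] <- mu[seq_len(n_c), , drop = FALSE] +
        frac %o% full_shift
    }
    logv <- mu + z
    if (!is.null(config$age_marker_slope)) {
      slope <- config$age_marker_slope[mk]
      slope[is.na(slope)] <- 0
      logv <- logv + (age - mean(age)) %o% unname(slope)
    }
    cohort <- data.frame(
      subject_id = sprintf("S%05d", seq_len(n)),
      group = group, stage = stage, age = age, sex = sex,
      stringsAsFactors = FALSE
    )
    for (j in seq_along(mk)) cohort[[mk[j]]] <- 10^logv[, j]
    cohort <- add_derived_markers(cohort)
    cohort <- inject_missing(cohort, config$missing_rate,
                             seed = derive_seed(seed, "missing"))
    attr(cohort, "provenance") <- list(source = "synthetic", seed = seed,
                                       cancer_label = config$cancer_label)
    cohort
  })
}

#' Mark marker values missing at random
#'
#' Sets each marker value missing independently with the given per-marker
#' rate; never removes subjects. Derived ratios (`mnr`, `dii`) are
#' recomputed so missingness propagates to them.
#'
#' @param cohort Cohort data frame.
#' @param rates Named per-marker missingness probabilities in `[0, 1]`.
#' @param seed RNG seed.
#' @return The cohort with missing values injected.
#' @export
inject_missing <- function(cohort, rates, seed = NULL) {
  rates <- rates[!is.na(rates) & rates > 0]
  if (length(rates) == 0 || nrow(cohort) == 0) return(cohort)
  if (any(rates < 0 | rates > 1)) stop_invalid("rates must be in [0, 1]")
  unknown <- setdiff(names(rates), measured_markers())
  if (length(unknown)) {
    stop_invalid("unknown marker in rates: ", paste(unknown, collapse = ", "))
  }
  with_seed(seed, {
    for (m in names(rates)) {
      hit <- stats::runif(nrow(cohort)) < rates[[m]]
      cohort[[m]][hit] <- NA_real_
    }
    add_derived_markers(cohort)
  })
}
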