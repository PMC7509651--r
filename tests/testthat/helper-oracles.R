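# Independent oracles and fixture builders used across the suite. The
# oracles deliberately use brute-force formulations (pair counting,
# exhaustive scans, permutation enumeration) so they share no code with the
# implementations they check.

# AUC by exhaustive pair counting: P(cancer > healthy) + 0.5 P(tie).
auc_pairwise <- function(values, cancer) {
  vc <- values[cancer]
  vh <- values[!cancer]
  cmp <- outer(vc, vh, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Closest-corner threshold by naive scan over all candidate thresholds
# (midpoints between consecutive distinct pooled values plus sentinels),
# counting Se/Sp directly; ties toward the smaller threshold.
brute_optimal_threshold <- function(values, cancer,
                                    orientation = "higher") {
  w <- if (orientation == "lower") -values else values
  sv <- sort(unique(w))
  cand <- c(-Inf, if (length(sv) > 1) (sv[-1] + sv[-length(sv)]) / 2, Inf)
  best_d <- Inf
  best_t <- NA_real_
  for (tw in cand) {
    se <- mean(w[cancer] > tw)
    sp <- mean(w[!cancer] <= tw)
    d <- sqrt((1 - se)^2 + (1 - sp)^2)
    t_orig <- if (orientation == "lower") -tw else tw
    if (d < best_d || (d == best_d && t_orig < best_t)) {
      best_d <- d
      best_t <- t_orig
    }
  }
  best_t
}

# Exact one-sided Mann-Whitney p-value by permutation enumeration (tiny n).
exact_mw_p <- function(x, y, alternative = "greater") {
  n1 <- length(x)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(length(pooled), n1)
  us <- apply(combos, 2, function(i) sum(r[i]) - n1 * (n1 + 1) / 2)
  if (alternative == "greater") mean(us >= u_obs) else mean(us <= u_obs)
}

# Exhaustive best-split oracle: scan every variable and every midpoint,
# recomputing child impurities from scratch; same admissibility and
# tie-break rules as the engine contract (lower variable index, then lower
# threshold).
brute_best_split <- function(x, y, minsplit, min_leaf, cp_abs) {
  n <- length(y)
  if (n < minsplit) return(NULL)
  ss <- function(v) if (length(v) == 0) 0 else sum((v - mean(v))^2)
  parent <- ss(y)
  if (parent <= 0) return(NULL)
  best <- NULL
  for (j in seq_len(ncol(x))) {
    sv <- sort(unique(x[, j]))
    if (length(sv) < 2) next
    for (t in (sv[-1] + sv[-length(sv)]) / 2) {
      l <- x[, j] <= t
      if (sum(l) < min_leaf || sum(!l) < min_leaf) next
      gain <- parent - ss(y[l]) - ss(y[!l])
      if (gain < cp_abs) next
      if (is.null(best) || gain > best$gain) {
        best <- list(variable = colnames(x)[j], threshold = t, gain = gain)
      }
    }
  }
  best
}

# The five-subject QC fixture: ref_a67 {400,450,500,600,700} with
# dii {0.1,0.1,0.41,0.4,0.2} realised through ref_a320.
toy_qc_cohort <- function() {
  ref_a67 <- c(400, 450, 500, 600, 700)
  dii <- c(0.1, 0.1, 0.41, 0.4, 0.2)
  data.frame(
    subject_id = paste0("T", 1:5),
    group = c("crc", "healthy", "crc", "healthy", "crc"),
    stage = NA_character_, age = c(50L, 55L, 60L, 45L, 65L), sex = "M",
    ref_a67 = ref_a67, ref_a145 = ref_a67 / 2, ref_a320 = dii * ref_a67,
    ref_m67 = ref_a67 * 10, stringsAsFactors = FALSE
  )
}

# Small labelled cohort straight from marker vectors (ages optional).
toy_cohort <- function(values, cancer, marker = "x", age = NULL) {
  n <- length(values)
  df <- data.frame(
    subject_id = sprintf("A%03d", seq_len(n)),
    group = ifelse(cancer, "crc", "healthy"),
    stage = NA_character_,
    age = if (is.null(age)) rep(50L, n) else age,
    sex = "M", stringsAsFactors = FALSE
  )
  df[[marker]] <- values
  df
}

zero_shift <- c(ref_a67 = 0, ref_a145 = 0, ref_a320 = 0, ref_m67 = 0)

# Generator config with custom per-marker shifts on the default healthy
# locations/covariance; balanced flat ages unless age bias is requested.
shifted_config <- function(n_cancer, n_healthy, shift = zero_shift,
                           age_bias = FALSE, seed = NULL, ...) {
  healthy <- c(ref_a67 = 3.30, ref_a145 = 3.00, ref_a320 = 2.40,
               ref_m67 = 7.70)
  flat <- data.frame(lower = seq(30, 65, by = 5),
                     upper = c(seq(34, 64, by = 5), 70),
                     weight = rep(1, 8))
  cbands <- if (age_bias) {
    transform(flat, weight = c(0.02, 0.03, 0.05, 0.08, 0.12, 0.18, 0.24,
                               0.28))
  } else {
    flat
  }
  hbands <- if (age_bias) {
    transform(flat, weight = c(0.10, 0.15, 0.20, 0.20, 0.15, 0.10, 0.06,
                               0.04))
  } else {
    flat
  }
  generator_config(
    n_cancer = n_cancer, n_healthy = n_healthy,
    log_mean_cancer = healthy + shift[names(healthy)],
    log_mean_healthy = healthy,
    log_cov = cfscreen:::default_log_cov(),
    age_bands_cancer = cbands, age_bands_healthy = hbands,
    cancer_label = "crc", seed = seed, ...
  )
}

tree_depth_of <- function(tree) cfscreen:::tree_depth(tree)

# Fast split-control for small fixtures.
loose_control <- function(...) {
  split_control(minsplit = 2, min_leaf_fraction = 0, cp = 0, ...)
}
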