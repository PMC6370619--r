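# Fixture builders shared across test files. Everything is generated in code;
# seeds are fixed so the suite is reproducible.

series_df <- function(times, values) {
  data.frame(time_months = times, value = values)
}

# deterministic cohort: no patient-level dispersion, no noise, no missingness
noise_free_config <- function(n_air = 14, n_pir = 19) {
  cohort_config(
    n_air = n_air, n_pir = n_pir,
    cd4 = list(AIR = group_kinetics(130.1, 499.0, 17.6),
               PIR = group_kinetics(130.1, 284.5, 31.9)),
    ratio = list(AIR = group_kinetics(0.163, 0.644, 27.620, floor = 0.001),
                 PIR = group_kinetics(0.163, 0.475, 27.620, floor = 0.001)),
    covariates = covariate_model(missing_prob = 0))
}

# well-separated construction: printed kinetics, minimal dispersion
small_noise_config <- function(sigma_A = 5, sigma_B = 10, sigma_eps = 2) {
  cohort_config(
    cd4 = list(AIR = group_kinetics(130.1, 499.0, 17.6, sigma_A, sigma_B,
                                    sigma_eps),
               PIR = group_kinetics(130.1, 284.5, 31.9, sigma_A, sigma_B,
                                    sigma_eps)),
    covariates = covariate_model(missing_prob = 0))
}

true_labels <- function(cohort) {
  data.frame(patient_id = cohort$covariates$patient_id,
             label = cohort$covariates$true_group,
             stringsAsFactors = FALSE)
}

# brute-force two-sided Mann-Whitney p by enumeration of all group
# assignments of the pooled sample (oracle; independent of the package and of
# the closed-form null distribution)
mw_enum_p <- function(a, b) {
  pooled <- c(a, b)
  n_a <- length(a)
  u_of <- function(idx) {
    x <- pooled[idx]; y <- pooled[-idx]
    sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  }
  obs <- u_of(seq_len(n_a))
  us <- apply(utils::combn(length(pooled), n_a), 2, u_of)
  mu <- n_a * length(b) / 2
  if (obs >= mu) {
    p <- mean(us >= obs) + mean(us <= mu - (obs - mu))
  } else {
    p <- mean(us <= obs) + mean(us >= mu + (mu - obs))
  }
  min(p, 1)
}

# brute-force two-sided Fisher p: enumerate all tables with the observed
# margins using pure choose() arithmetic
fisher_enum_p <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  n <- r1 + r2
  support <- max(0, c1 - r2):min(c1, r1)
  pr <- vapply(support, function(a) {
    exp(lchoose(r1, a) + lchoose(r2, c1 - a) - lchoose(n, c1))
  }, numeric(1))
  obs <- pr[match(tab[1, 1], support)]
  sum(pr[pr <= obs * (1 + 1e-7)])
}
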