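# Independent oracles and fixture builders used across the suite.

# Brute-force maximization of the written-out Bernoulli log-likelihood,
# independent of the IRLS path used by the package.
bf_logistic <- function(y, F) {
  negll <- function(b) {
    eta <- b[1] + b[2] * F
    -sum(y * eta - log1p(exp(eta)))
  }
  fit <- optim(c(0, 0), negll, method = "Nelder-Mead",
               control = list(reltol = 1e-14, maxit = 5000))
  fit <- optim(fit$par, negll, method = "Nelder-Mead",
               control = list(reltol = 1e-14, maxit = 5000))
  fit$par
}

# Newton iteration for the founder-normalizing growth rate, using the
# analytic derivative of mean w(r); independent of the bracketed
# root-finder in the package.
newton_solve_r <- function(founders, tol = 1e-12) {
  x_mid <- (founders$start_h + founders$end_h) / 2
  m <- founders$adult_progeny
  ids <- founders$female_id
  n_f <- length(unique(ids))
  mean_w <- function(r) sum(m * exp(-r * x_mid)) / n_f
  dmean_w <- function(r) -sum(x_mid * m * exp(-r * x_mid)) / n_f
  r <- 0
  for (i in 1:200) {
    step <- (mean_w(r) - 1) / dmean_w(r)
    r <- r - step
    if (abs(step) < tol) break
  }
  r
}

# Cross records with independently drawn conditional stage outcomes at the
# F levels of a 20-generation sib-mating experiment.
make_stage_records <- function(n, stage_betas, seed) {
  set.seed(seed)
  sched <- sib_mating_F(18)
  F <- parental_F(sample(1:20, n, replace = TRUE), sched)
  p_of <- function(b) plogis(b[1] + b[2] * F)
  cop <- runif(n) < p_of(stage_betas$copulation)
  fert <- runif(n) < p_of(stage_betas$fertility)
  dev <- runif(n) < p_of(stage_betas$development)
  succ <- cop & fert & dev
  fert_obs <- fert; fert_obs[!cop] <- NA
  dev_obs <- dev; dev_obs[!(cop & fert)] <- NA
  data.frame(line_id = sprintf("L%05d", seq_len(n)), generation = 1L,
             F_parents = F, copulated = cop, fertile = fert_obs,
             developed = dev_obs, success = succ,
             stringsAsFactors = FALSE)
}

# One female's schedule as a data frame, from interval midpoount spec.
one_female_schedule <- function(id, counts, strain = "S", role = "inbred",
                                delay_h = 0) {
  nI <- length(counts)
  start_h <- c(0, 6 + 8 * (seq_len(nI - 1L) - 1L)) + delay_h
  end_h <- c(6, 6 + 8 * seq_len(nI - 1L)) + delay_h
  data.frame(female_id = id, strain_id = strain, role = role,
             start_h = start_h, end_h = end_h,
             adult_progeny = as.integer(counts), censored = FALSE,
             stringsAsFactors = FALSE)
}

# The published coefficient table for the 11 strains, with the printed
# load values frozen as expected outputs of the conversion.
printed_loads <- function() {
  data.frame(
    strain = c("fog-2", "EM464", "PB219", "QG548", "QG549", "QG122",
               "QG123", "QG702", "QG703", "QG704", "QG711"),
    A_R = c(0.198, 0.035, 0.063, 0.019, 0.017, 0.026, 0.043, 0.012,
            0.012, 0.029, 0.025),
    B_R = c(0.043, 0.164, 0.322, 0.132, 0.046, 0.160, 0.220, 0.171,
            0.153, 0.041, 0.041),
    stringsAsFactors = FALSE
  )
}
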