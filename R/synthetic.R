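#' @title Synthetic line-extinction experiments and reproductive schedules
#' @description
#' Generators with the exact statistical structure the analysis assumes:
#' per-generation Bernoulli cross success with probability
#' logistic(beta0 + beta1 * F_parents(g)), optionally factorized into three
#' sequential conditional stages (copulation, fertility, development), an
#' optional per-line maternal-effect lethal event that kills whole broods,
#' and negative-binomial per-interval progeny counts for the reproductive
#' schedule assay. Closed-form survival probabilities are provided as the
#' analytic oracle the simulator is checked against.
#' @name synthetic_data
NULL

# Deterministic per-unit seed stream: mixing keeps every derived seed in
# [0, 2^31) and means adding lines never perturbs existing lines' draws.
unit_seed <- function(seed, i) {
  as.integer((seed * 48271 + i * 1103515245) %% 2147483647L)
}

#' Configuration for the synthetic-data generators
#'
#' Defaults mirror the design of a serial sib-mating line-extinction
#' experiment: 108 independent lines followed for up to 20 generations,
#' and a reproductive-schedule assay with 6 females per strain laying in
#' a 0-6 h interval then successive 8-h plates.
#'
#' @param n_lines number of independent inbreeding lines.
#' @param max_generations last experiment generation simulated.
#' @param betas overall \code{c(beta0, beta1)} for single-stage cross
#'   success. Ignored when \code{stage_betas} is given.
#' @param stage_betas optional named list with elements
#'   \code{copulation}, \code{fertility}, \code{development}, each a
#'   \code{c(beta0, beta1)} pair for that conditional stage.
#' @param maternal_lethal_rate per-line, per-generation probability of a
#'   maternal-effect lethal event that forces the development stage to
#'   fail (the whole brood dies, with no segregation within it).
#' @param seed integer master seed; identical configurations produce
#'   byte-identical output tables.
#' @param schedule list of reproductive-schedule parameters:
#'   \code{founder_strain} (label), \code{n_females} (per strain, default
#'   6), \code{interval_means} (founder mean adult progeny per interval; a
#'   hump-shaped default), \code{dispersion} (negative-binomial size;
#'   \code{Inf} gives Poisson), and \code{lines}, a named list per inbred
#'   line with \code{multiplier} (fitness effect on all interval means),
#'   \code{delay_h} (laying delay in hours) and \code{maternal_lethal}
#'   (all counts zero).
#' @return An object of class \code{"sim_config"}.
#' @export
sim_config <- function(n_lines = 108, max_generations = 20,
                       betas = c(3.5, -1.0), stage_betas = NULL,
                       maternal_lethal_rate = 0, seed = 1,
                       schedule = list()) {
  if (n_lines < 1 || n_lines != floor(n_lines)) {
    stop("`n_lines` must be a positive integer", call. = FALSE)
  }
  if (max_generations < 1 || max_generations != floor(max_generations)) {
    stop("`max_generations` must be a positive integer", call. = FALSE)
  }
  if (!is.null(stage_betas)) {
    need <- c("copulation", "fertility", "development")
    if (!is.list(stage_betas) || !setequal(names(stage_betas), need) ||
        !all(vapply(stage_betas, function(b)
          is.numeric(b) && length(b) == 2 && all(is.finite(b)), TRUE))) {
      stop("`stage_betas` must be a named list of three (beta0, beta1) ",
           "pairs: copulation, fertility, development", call. = FALSE)
    }
    stage_betas <- stage_betas[need]
  } else {
    if (!is.numeric(betas) || length(betas) != 2 || !all(is.finite(betas))) {
      stop("`betas` must be a finite (beta0, beta1) pair", call. = FALSE)
    }
  }
  if (!is.finite(maternal_lethal_rate) || maternal_lethal_rate < 0 ||
      maternal_lethal_rate > 1) {
    stop("`maternal_lethal_rate` must be a probability", call. = FALSE)
  }
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    stop("`seed` must be an integer", call. = FALSE)
  }
  sched <- utils::modifyList(list(
    founder_strain = "founder",
    n_females = 6L,
    interval_means = c(45, 110, 95, 60, 30, 12, 5, 2),
    dispersion = 8,
    lines = list()
  ), schedule)
  if (!is.infinite(sched$dispersion) &&
      (!is.finite(sched$dispersion) || sched$dispersion <= 0)) {
    stop("schedule `dispersion` must be positive (Inf for Poisson)",
         call. = FALSE)
  }
  if (any(sched$interval_means < 0)) {
    stop("schedule `interval_means` must be non-negative", call. = FALSE)
  }
  sched$lines <- lapply(sched$lines, function(ln) {
    ln <- utils::modifyList(list(multiplier = 1, delay_h = 0,
                                 maternal_lethal = FALSE,
                                 n_females = sched$n_females), ln)
    if (ln$multiplier < 0) stop("line multiplier must be >= 0", call. = FALSE)
    ln
  })
  structure(
    list(n_lines = as.integer(n_lines),
         max_generations = as.integer(max_generations),
         betas = if (is.null(stage_betas)) betas else NULL,
         stage_betas = stage_betas,
         maternal_lethal_rate = maternal_lethal_rate,
         seed = as.integer(seed),
         schedule = sched),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic experiment configuration\n")
  cat("  lines:", x$n_lines, " max generations:", x$max_generations, "\n")
  if (is.null(x$stage_betas)) {
    cat(sprintf("  overall betas: (%.3f, %.3f)\n", x$betas[1], x$betas[2]))
  } else {
    for (s in names(x$stage_betas)) {
      cat(sprintf("  %-11s betas: (%.3f, %.3f)\n", s,
                  x$stage_betas[[s]][1], x$stage_betas[[s]][2]))
    }
  }
  cat("  maternal-lethal rate:", x$maternal_lethal_rate,
      " seed:", x$seed, "\n")
  invisible(x)
}

#' Simulate a serial sib-mating line-extinction experiment
#'
#' Each line is followed from generation 1 until its first failed cross
#' (or \code{max_generations}). At generation g the cross succeeds with
#' probability logistic(beta0 + beta1 * F_parents(g)); with stage-level
#' betas, the three conditional stage Bernoullis are drawn sequentially
#' and success requires all three. A maternal-lethal event (drawn per line
#' per generation) forces the development stage to fail regardless of its
#' own draw. Random streams are split per line, so enlarging
#' \code{n_lines} never changes existing lines' trajectories.
#'
#' @param config a \code{"sim_config"}.
#' @return Cross-record data frame with columns \code{line_id},
#'   \code{generation}, \code{F_parents}, \code{copulated},
#'   \code{fertile}, \code{developed}, \code{success}. Stage columns are
#'   \code{NA} in overall (single-stage) mode, and follow the conditional
#'   observability rules otherwise (fertility unobserved without
#'   copulation, development unobserved without fertility).
#' @export
simulate_line_extinction <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  G <- config$max_generations
  N <- config$n_lines
  Fpar <- parental_F_curve(G)
  mlr <- config$maternal_lethal_rate
  staged <- !is.null(config$stage_betas)
  if (staged) {
    P <- vapply(config$stage_betas,
                function(b) stats::plogis(b[1] + b[2] * Fpar),
                numeric(G))          # G x 3
  } else {
    p_all <- stats::plogis(config$betas[1] + config$betas[2] * Fpar)
  }

  total <- N * G
  line_i <- integer(total); gen <- integer(total); Fv <- numeric(total)
  copv <- logical(total); fertv <- logical(total); devv <- logical(total)
  succv <- logical(total)
  copv[] <- NA; fertv[] <- NA; devv[] <- NA
  pos <- 0L

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  for (i in seq_len(N)) {
    set.seed(unit_seed(config$seed, i))
    if (staged) {
      u <- matrix(stats::runif(3L * G), G, 3L)
      ml <- if (mlr > 0) stats::runif(G) < mlr else FALSE
      cop <- u[, 1L] < P[, 1L]
      fert <- u[, 2L] < P[, 2L]
      dev <- u[, 3L] < P[, 3L] & !ml
      succ <- cop & fert & dev
      k <- match(FALSE, succ)
      if (is.na(k)) k <- G
      idx <- seq_len(k)
      rows <- pos + idx
      f_obs <- fert[idx]; f_obs[!cop[idx]] <- NA
      d_obs <- dev[idx]; d_obs[!(cop[idx] & fert[idx])] <- NA
      copv[rows] <- cop[idx]
      fertv[rows] <- f_obs
      devv[rows] <- d_obs
      succv[rows] <- succ[idx]
    } else {
      u <- stats::runif(G)
      ml <- if (mlr > 0) stats::runif(G) < mlr else FALSE
      succ <- u < p_all & !ml
      k <- match(FALSE, succ)
      if (is.na(k)) k <- G
      idx <- seq_len(k)
      rows <- pos + idx
      succv[rows] <- succ[idx]
    }
    line_i[rows] <- i
    gen[rows] <- idx
    Fv[rows] <- Fpar[idx]
    pos <- pos + length(rows)
  }
  keep <- seq_len(pos)
  data.frame(
    line_id = sprintf("L%04d", line_i[keep]),
    generation = gen[keep],
    F_parents = Fv[keep],
    copulated = copv[keep],
    fertile = fertv[keep],
    developed = devv[keep],
    success = succv[keep],
    stringsAsFactors = FALSE
  )
}

#' Closed-form line-survival probability
#'
#' Analytic oracle for [simulate_line_extinction()]: the probability a
#' line survives its first \code{generation} crosses,
#' \deqn{\prod_{t=1}^{g} (1 - \mu) \prod_s
#'   \mathrm{logistic}(\beta_{0s} + \beta_{1s} F_{\mathrm{par}}(t)),}
#' with \eqn{\mu} the maternal-lethal rate. The Monte-Carlo survival
#' fraction converges to this value.
#'
#' @param config a \code{"sim_config"}.
#' @param generation non-negative generation count (0 returns 1).
#' @return Survival probability in \[0, 1\].
#' @export
analytic_survival <- function(config, generation) {
  stopifnot(inherits(config, "sim_config"))
  if (generation < 0 || generation != floor(generation)) {
    stop("`generation` must be a non-negative integer", call. = FALSE)
  }
  if (generation == 0) return(1)
  Fpar <- parental_F_curve(generation)
  per_gen <- if (!is.null(config$stage_betas)) {
    Reduce(`*`, lapply(config$stage_betas, function(b)
      stats::plogis(b[1] + b[2] * Fpar)))
  } else {
    stats::plogis(config$betas[1] + config$betas[2] * Fpar)
  }
  prod((1 - config$maternal_lethal_rate) * per_gen)
}

#' Simulate reproductive schedules
#'
#' Founder females draw per-interval adult-progeny counts from a negative
#' binomial around the hump-shaped mean schedule in
#' \code{config$schedule$interval_means}; inbred-line females apply their
#' line's multiplicative fitness effect to the means, an optional laying
#' delay shifting all intervals, and maternal-lethal lines produce
#' all-zero counts. The first interval spans 0-6 h from pairing and
#' subsequent plates are 8 h wide.
#'
#' @param config a \code{"sim_config"}; lines come from
#'   \code{config$schedule$lines}.
#' @return Schedule data frame with columns \code{female_id},
#'   \code{strain_id}, \code{role}, \code{start_h}, \code{end_h},
#'   \code{adult_progeny}, \code{censored} (all \code{FALSE}).
#' @export
simulate_repro_schedules <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  sp <- config$schedule
  nI <- length(sp$interval_means)
  start_h <- c(0, 6 + 8 * (seq_len(nI - 1L) - 1L))
  end_h <- c(6, 6 + 8 * seq_len(nI - 1L))
  draw <- function(mu) {
    if (is.infinite(sp$dispersion)) stats::rpois(length(mu), mu)
    else stats::rnbinom(length(mu), mu = mu, size = sp$dispersion)
  }
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  out <- list()
  strains <- c(list(founder = list(multiplier = 1, delay_h = 0,
                                   maternal_lethal = FALSE,
                                   n_females = sp$n_females)),
               sp$lines)
  names(strains)[1] <- sp$founder_strain
  for (si in seq_along(strains)) {
    ln <- strains[[si]]
    sname <- names(strains)[si]
    role <- if (si == 1L) "founder" else "inbred"
    mu <- sp$interval_means * ln$multiplier
    for (j in seq_len(ln$n_females)) {
      set.seed(unit_seed(config$seed, 7919L * si + j))
      counts <- if (ln$maternal_lethal) integer(nI) else draw(mu)
      out[[length(out) + 1L]] <- data.frame(
        female_id = sprintf("%s_f%02d", sname, j),
        strain_id = sname,
        role = role,
        start_h = start_h + ln$delay_h,
        end_h = end_h + ln$delay_h,
        adult_progeny = as.integer(counts),
        censored = FALSE,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
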