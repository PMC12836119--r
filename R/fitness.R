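#' @title Relative fitness from age-structured reproductive schedules
#' @description
#' Each assayed female yields a reproductive schedule: counts of progeny
#' that reached adulthood, per laying interval (0-6 h from pairing, then
#' successive 8-h plates). Fitness is scored through the Lotka-Euler
#' identity for age-structured populations: at growth rate r, a female's
#' contribution is
#' \deqn{w(r) = \sum_j m_j e^{-r x_j},}
#' where \eqn{m_j} is the adult-progeny count of interval j and \eqn{x_j}
#' its midpoint age in hours from pairing. The rate r is solved so the mean
#' w of the outbred founder females equals 1; every female's w at that r is
#' then her fitness relative to the founder population.
#' @name fitness
NULL

check_schedule_df <- function(x, what = "schedule") {
  need <- c("female_id", "start_h", "end_h", "adult_progeny")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    stop(what, " table missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (any(x$end_h <= x$start_h)) {
    stop(what, ": intervals must satisfy end_h > start_h", call. = FALSE)
  }
  if (any(x$adult_progeny < 0) ||
      any(x$adult_progeny != floor(x$adult_progeny))) {
    stop(what, ": adult_progeny must be non-negative integers", call. = FALSE)
  }
  bad <- unlist(lapply(split(x, x$female_id), function(d) {
    d <- d[order(d$start_h), ]
    any(d$start_h[-1] < d$end_h[-nrow(d)])
  }))
  if (any(bad)) {
    stop(what, ": overlapping intervals for female(s) ",
         paste(names(bad)[bad], collapse = ", "), call. = FALSE)
  }
  invisible(x)
}

drop_censored <- function(x) {
  if ("censored" %in% names(x)) x[!as_logical01(x$censored), , drop = FALSE]
  else x
}

#' Lotka-Euler fitness contribution of one female
#'
#' Evaluates \eqn{w(r) = \sum_j m_j e^{-r x_j}} over a female's laying
#' intervals, with \eqn{x_j} the interval midpoint in hours from pairing.
#' Strictly decreasing in r whenever total progeny > 0.
#'
#' @param schedule data frame of one female's intervals with columns
#'   \code{start_h}, \code{end_h}, \code{adult_progeny} (and optionally
#'   \code{censored}).
#' @param r population growth rate, per hour.
#' @param maturation_offset fixed number of hours added to every interval
#'   midpoint, for sensitivity analyses that account for the unmeasured
#'   development time to reproductive maturity. Default 0.
#' @return Non-negative scalar w; 0 iff total progeny is 0.
#' @export
euler_lotka_w <- function(schedule, r, maturation_offset = 0) {
  check_schedule_df(schedule)
  if ("censored" %in% names(schedule) &&
      any(as_logical01(schedule$censored))) {
    stop("schedule is censored; censored females are excluded from estimation",
         call. = FALSE)
  }
  if (length(unique(schedule$female_id)) > 1L) {
    stop("`schedule` must describe a single female; see relative_fitness()",
         call. = FALSE)
  }
  x_mid <- (schedule$start_h + schedule$end_h) / 2 + maturation_offset
  sum(schedule$adult_progeny * exp(-r * x_mid))
}

# w for every female in a (multi-female) schedule table at a fixed r.
w_by_female <- function(tab, r, maturation_offset = 0) {
  x_mid <- (tab$start_h + tab$end_h) / 2 + maturation_offset
  contrib <- tab$adult_progeny * exp(-r * x_mid)
  out <- tapply(contrib, tab$female_id, sum)
  out[unique(as.character(tab$female_id))]
}

#' Solve the founder-normalizing growth rate
#'
#' Finds the r at which the mean Lotka-Euler w of the (non-censored)
#' founder females equals 1. Mean w is continuous and strictly decreasing
#' in r, so when mean total progeny exceeds 1 there is a unique positive
#' root, located by bracketed root-finding to |mean w - 1| < 1e-8.
#'
#' @param founders schedule table for the founder females (may contain
#'   several females; censored ones are dropped).
#' @param maturation_offset passed to the w evaluation.
#' @param allow_nonpositive if \code{TRUE}, also search r <= 0 when mean
#'   total progeny is at or below 1 (a declining population); otherwise
#'   that situation is an error.
#' @return The solved growth rate r, per hour.
#' @export
solve_r <- function(founders, maturation_offset = 0,
                    allow_nonpositive = FALSE) {
  founders <- drop_censored(founders)
  check_schedule_df(founders, "founders")
  if (nrow(founders) == 0L) {
    stop("no non-censored founder schedules", call. = FALSE)
  }
  mean_w <- function(r) mean(w_by_female(founders, r, maturation_offset))
  total <- mean_w(0)   # mean total progeny
  if (total <= 1 && !allow_nonpositive) {
    stop("mean founder total progeny is ", signif(total, 4),
         " (<= 1): no positive growth rate exists; ",
         "set allow_nonpositive = TRUE to solve r <= 0", call. = FALSE)
  }
  if (total == 1) return(0)
  f <- function(r) mean_w(r) - 1
  if (total > 1) {
    lo <- 0; hi <- 1e-3
    while (f(hi) > 0) hi <- hi * 2
  } else {
    hi <- 0; lo <- -1e-3
    while (f(lo) < 0) lo <- lo * 2
  }
  stats::uniroot(f, c(lo, hi), tol = .Machine$double.eps^0.75)$root
}

#' Relative fitness of inbred lines against their outbred founder
#'
#' Solves r on the founder females ([solve_r()]), then evaluates every
#' female's Lotka-Euler w at that r. By construction the founder mean is 1;
#' inbred females' w values are their fitness relative to the ancestral
#' outbred population. Comparisons are within one founder: all founder
#' schedules must share a single strain.
#'
#' @param inbred schedule table for the inbred-line females, with a
#'   \code{strain_id} column identifying the derived line.
#' @param founders schedule table for the founder females (one strain).
#' @param maturation_offset hours added to interval midpoints (see
#'   [euler_lotka_w()]).
#' @return An object of class \code{"fitness_estimate"} with the solved
#'   \code{r}, a per-female table (\code{females}), per-strain mean
#'   relative fitness (\code{strain_means}) and the founder strain label.
#' @examples
#' cfg <- sim_config(seed = 3, schedule = list(
#'   lines = list(L1 = list(multiplier = 0.4), L2 = list(multiplier = 1))))
#' sch <- simulate_repro_schedules(cfg)
#' est <- relative_fitness(sch[sch$role == "inbred", ],
#'                         sch[sch$role == "founder", ])
#' est
#' @export
relative_fitness <- function(inbred, founders, maturation_offset = 0) {
  founders <- drop_censored(founders)
  inbred <- drop_censored(inbred)
  check_schedule_df(founders, "founders")
  check_schedule_df(inbred, "inbred")
  if (!"strain_id" %in% names(founders) || !"strain_id" %in% names(inbred)) {
    stop("schedule tables need a strain_id column", call. = FALSE)
  }
  fstrain <- unique(as.character(founders$strain_id))
  if (length(fstrain) != 1L) {
    stop("founders must all come from one founder strain; got: ",
         paste(fstrain, collapse = ", "), call. = FALSE)
  }
  r <- solve_r(founders, maturation_offset)
  all_tab <- rbind(
    founders[c("female_id", "strain_id", "start_h", "end_h", "adult_progeny")],
    inbred[c("female_id", "strain_id", "start_h", "end_h", "adult_progeny")]
  )
  role <- c(rep("founder", nrow(founders)), rep("inbred", nrow(inbred)))
  w <- w_by_female(all_tab, r, maturation_offset)
  meta <- unique(data.frame(
    female_id = as.character(all_tab$female_id),
    strain_id = as.character(all_tab$strain_id),
    role = role, stringsAsFactors = FALSE))
  meta <- meta[match(names(w), meta$female_id), ]
  tot <- tapply(all_tab$adult_progeny, all_tab$female_id, sum)[names(w)]
  females <- data.frame(
    female_id = meta$female_id, strain_id = meta$strain_id, role = meta$role,
    total_progeny = as.numeric(tot), w = as.numeric(w),
    row.names = NULL, stringsAsFactors = FALSE)
  inb <- females[females$role == "inbred", ]
  strain_means <- tapply(inb$w, inb$strain_id, mean)
  structure(
    list(r = r, founder_strain = fstrain, females = females,
         w_by_female = stats::setNames(females$w, females$female_id),
         strain_means = strain_means,
         maturation_offset = maturation_offset),
    class = "fitness_estimate"
  )
}

#' @export
print.fitness_estimate <- function(x, digits = 3, ...) {
  cat("Lotka-Euler relative-fitness estimate\n")
  cat("  founder strain:", x$founder_strain,
      sprintf(" (mean fitness normalized to 1; r = %.6g /h)\n", x$r))
  cat("  females:", nrow(x$females),
      sprintf("(%d founder, %d inbred)\n",
              sum(x$females$role == "founder"),
              sum(x$females$role == "inbred")))
  cat("  inbred strain mean relative fitness:\n")
  print(round(x$strain_means, digits))
  invisible(x)
}

#' @export
summary.fitness_estimate <- function(object, ...) {
  inb <- object$females[object$females$role == "inbred", ]
  tab <- do.call(rbind, lapply(split(inb, inb$strain_id), function(d) {
    data.frame(strain_id = d$strain_id[1], n_females = nrow(d),
               mean_w = mean(d$w), min_w = min(d$w), max_w = max(d$w),
               severely_damaged = mean(d$w) < 0.5)
  }))
  rownames(tab) <- NULL
  tab
}

#' Kruskal-Wallis test of fitness heterogeneity among inbred strains
#'
#' Rank-based test that the inbred lines derived from one founder differ
#' in relative fitness, as in the standard heterogeneity screen for inbred
#' line panels.
#'
#' @param estimates a \code{"fitness_estimate"} from [relative_fitness()].
#' @return The \code{htest} from [stats::kruskal.test()] (chi-square
#'   approximation, tie-corrected).
#' @export
strain_heterogeneity_test <- function(estimates) {
  stopifnot(inherits(estimates, "fitness_estimate"))
  inb <- estimates$females[estimates$females$role == "inbred", ]
  grp <- factor(inb$strain_id)
  if (nlevels(grp) < 2L) {
    stop_design("heterogeneity test needs >= 2 inbred strains")
  }
  if (any(table(grp) < 2L)) {
    stop_design("each inbred strain needs >= 2 females")
  }
  if (length(unique(inb$w)) == 1L) {
    # all observations tied: the tie-corrected H statistic is 0/0 in the
    # textbook formula; by continuity there is no rank signal, so H = 0.
    return(structure(list(
      statistic = c(`Kruskal-Wallis chi-squared` = 0),
      parameter = c(df = nlevels(grp) - 1L),
      p.value = 1,
      method = "Kruskal-Wallis rank sum test",
      data.name = "relative fitness by strain"), class = "htest"))
  }
  stats::kruskal.test(inb$w, grp)
}
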