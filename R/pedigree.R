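#' Inbreeding coefficients under serial full-sib mating
#'
#' Computes the sequence of inbreeding coefficients F produced by repeated
#' brother-sister mating, using the classical recursion
#' \deqn{F_t = 0.25 (1 + 2 F_{t-1} + F_{t-2})}
#' with boundary conditions \eqn{F_0 = F_{-1} = 0} (unrelated, non-inbred
#' founders). The first sib mating therefore yields offspring with
#' \eqn{F_1 = 0.25}, and F increases monotonically toward 1; the
#' per-generation ratio \eqn{(1-F_t)/(1-F_{t-1})} converges to
#' \eqn{(1+\sqrt{5})/4 \approx 0.809}.
#'
#' @param n_generations non-negative integer; number of consecutive sib
#'   matings.
#' @return An object of class \code{"inbreeding_schedule"}: a list with
#'   \code{n_sib_generations} and \code{F_values}, where
#'   \code{F_values[k + 1]} is the inbreeding coefficient of offspring after
#'   \code{k} consecutive sib matings (so \code{F_values[1] == 0}).
#' @examples
#' sched <- sib_mating_F(20)
#' sched$F_values[c(2, 5)]  # F_1 = 0.25, F_4 = 0.59375
#' @seealso [parental_F()] for mapping experiment generations to the F of
#'   the crossed parents.
#' @export
sib_mating_F <- function(n_generations) {
  if (length(n_generations) != 1L || !is.numeric(n_generations) ||
      is.na(n_generations) || n_generations < 0 ||
      n_generations != floor(n_generations)) {
    stop("`n_generations` must be a single non-negative integer", call. = FALSE)
  }
  n <- as.integer(n_generations)
  F_values <- numeric(n + 1L)
  if (n >= 1L) {
    for (t in seq_len(n)) {
      F_tm1 <- F_values[t]                     # F_{t-1}
      F_tm2 <- if (t >= 2L) F_values[t - 1L] else 0
      F_values[t + 1L] <- 0.25 * (1 + 2 * F_tm1 + F_tm2)
    }
  }
  structure(
    list(n_sib_generations = n, F_values = F_values),
    class = "inbreeding_schedule"
  )
}

#' Parental inbreeding coefficient for an experiment generation
#'
#' In a serial sib-mating line experiment, generation-1 crosses pair outbred
#' (F = 0) individuals and so do generation-2 crosses (the offspring of
#' unrelated parents are themselves non-inbred). From generation 3 onward
#' the paired siblings carry the inbreeding accumulated by g - 2 rounds of
#' sib mating, i.e. \code{F_values[g - 2]} on the schedule's 0-based count.
#'
#' @param generation positive integer experiment generation (1-based; the
#'   first cross of each line is generation 1).
#' @param schedule an \code{"inbreeding_schedule"} from [sib_mating_F()],
#'   long enough to cover \code{generation - 2} sib matings.
#' @return The inbreeding coefficient of the two crossed individuals.
#' @examples
#' sched <- sib_mating_F(20)
#' parental_F(1, sched)  # 0
#' parental_F(3, sched)  # 0.25
#' @export
parental_F <- function(generation, schedule) {
  if (!inherits(schedule, "inbreeding_schedule")) {
    stop("`schedule` must be an inbreeding_schedule", call. = FALSE)
  }
  if (any(is.na(generation)) || any(generation < 1) ||
      any(generation != floor(generation))) {
    stop("`generation` must contain positive integers", call. = FALSE)
  }
  k <- pmax(generation - 2L, 0L)   # sib matings behind the crossed parents
  if (max(k) > schedule$n_sib_generations) {
    stop("schedule too short: needs ", max(k), " sib generations but has ",
         schedule$n_sib_generations, call. = FALSE)
  }
  schedule$F_values[k + 1L]
}

#' @export
print.inbreeding_schedule <- function(x, ...) {
  cat("Serial full-sib mating inbreeding schedule\n")
  cat("  sib generations:", x$n_sib_generations, "\n")
  n_show <- min(length(x$F_values), 8L)
  cat("  F_values: ", paste(signif(x$F_values[seq_len(n_show)], 4),
                            collapse = ", "),
      if (length(x$F_values) > n_show) ", ...", "\n", sep = "")
  if (x$n_sib_generations >= 1L) {
    cat("  final F:", signif(x$F_values[length(x$F_values)], 6), "\n")
  }
  invisible(x)
}

# Parental F for experiment generations 1..n as a plain vector.
parental_F_curve <- function(n_generations, schedule = NULL) {
  if (is.null(schedule)) {
    schedule <- sib_mating_F(max(n_generations - 2L, 0L))
  }
  parental_F(seq_len(n_generations), schedule)
}
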