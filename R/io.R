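#' @title Tabular input/output for cross records and schedules
#' @description
#' TSV is the primary dialect (CSV accepted, detected from the header
#' line); booleans are written as 0/1 with missing values as empty fields,
#' UTF-8 throughout.
#' @name cross_io
NULL

as_logical01 <- function(x) {
  if (is.logical(x)) return(x)
  if (is.numeric(x)) {
    out <- rep(NA, length(x))
    out[x == 1] <- TRUE
    out[x == 0] <- FALSE
    return(out)
  }
  x <- trimws(as.character(x))
  out <- rep(NA, length(x))
  out[x %in% c("1", "TRUE", "true")] <- TRUE
  out[x %in% c("0", "FALSE", "false")] <- FALSE
  out
}

sniff_sep <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first)) "\t" else ","
}

#' Read a cross-record table
#'
#' Expects a header with \code{line_id}, \code{generation},
#' \code{copulated}, \code{fertile}, \code{developed}, \code{success}
#' (booleans as 0/1, missing as empty fields) and optionally
#' \code{F_parents}. When the F column is absent it is attached from the
#' generation via the sib-mating recursion ([parental_F()]). The staged
#' observability invariants are enforced: a successful cross must not
#' carry a failed stage flag, fertility must be unobserved without
#' copulation, and development unobserved without fertility.
#'
#' @param path TSV or CSV file.
#' @return Validated cross-record data frame with an \code{F_parents}
#'   column.
#' @export
read_cross_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- sniff_sep(path)
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, na.strings = "", quote = "",
                           colClasses = NA, encoding = "UTF-8")
  need <- c("line_id", "generation", "success")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop("cross table missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  for (col in c("copulated", "fertile", "developed", "success")) {
    if (col %in% names(tab)) tab[[col]] <- as_logical01(tab[[col]])
    else tab[[col]] <- NA
  }
  if (any(is.na(tab$success))) {
    stop("parse error: missing success value on row(s) ",
         paste(utils::head(which(is.na(tab$success)), 5), collapse = ", "),
         call. = FALSE)
  }
  if (any(is.na(tab$generation)) || any(tab$generation < 1)) {
    stop("parse error: generation must be a positive integer on every row",
         call. = FALSE)
  }

  staged <- !all(is.na(tab$copulated))
  if (staged) {
    bad_succ <- which(tab$success &
                        ((!is.na(tab$copulated) & !tab$copulated) |
                         (!is.na(tab$fertile) & !tab$fertile) |
                         (!is.na(tab$developed) & !tab$developed)))
    bad_fert <- which(!is.na(tab$copulated) & !tab$copulated &
                        !is.na(tab$fertile))
    bad_dev <- which(!(!is.na(tab$fertile) & tab$fertile) &
                       !is.na(tab$developed))
    bad <- sort(unique(c(bad_succ, bad_fert, bad_dev)))
    if (length(bad)) {
      stop("stage-consistency validation failed on row(s): ",
           paste(utils::head(bad, 10), collapse = ", "),
           if (length(bad) > 10) " ...", call. = FALSE)
    }
  }

  if (!"F_parents" %in% names(tab)) {
    sched <- sib_mating_F(max(tab$generation) - 2L)
    tab$F_parents <- parental_F(tab$generation, sched)
  }
  if (any(tab$F_parents < 0 | tab$F_parents >= 1)) {
    stop("F_parents must lie in [0, 1)", call. = FALSE)
  }
  tab
}

fmt01 <- function(x) ifelse(is.na(x), "", as.character(as.integer(x)))

#' Write a cross-record table
#'
#' @param records cross-record data frame.
#' @param path output file; tab-separated, booleans as 0/1, missing as
#'   empty fields.
#' @export
write_cross_table <- function(records, path) {
  out <- data.frame(
    line_id = records$line_id,
    generation = records$generation,
    F_parents = records$F_parents,
    copulated = fmt01(records$copulated),
    fertile = fmt01(records$fertile),
    developed = fmt01(records$developed),
    success = fmt01(records$success),
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a reproductive-schedule table
#'
#' Expects columns \code{female_id}, \code{strain_id}, \code{role},
#' \code{start_h}, \code{end_h}, \code{adult_progeny}, \code{censored}.
#'
#' @param path TSV or CSV file.
#' @return Validated schedule data frame.
#' @export
read_schedule_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- sniff_sep(path)
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, na.strings = "", quote = "",
                           encoding = "UTF-8")
  if ("censored" %in% names(tab)) {
    tab$censored <- as_logical01(tab$censored)
    tab$censored[is.na(tab$censored)] <- FALSE
  } else {
    tab$censored <- FALSE
  }
  check_schedule_df(tab)
  tab
}

#' Write a reproductive-schedule table
#'
#' @param schedules schedule data frame.
#' @param path output file (tab-separated).
#' @export
write_schedule_table <- function(schedules, path) {
  out <- schedules
  out$censored <- fmt01(as_logical01(out$censored))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Assemble a strain-level load report
#'
#' One row per strain (and per stage, if stage-wise fits are supplied)
#' with the logistic coefficients, their standard errors, the derived
#' loads and the Wald p-value — the conventional layout for reporting
#' expressed and concealed load estimates.
#'
#' @param fits named list: one \code{"load_fit"} per strain, or a named
#'   list of stage-wise fit lists from [stagewise_fits()]. Degenerate
#'   stages (condition objects) are skipped.
#' @param locality optional named character vector of strain localities.
#' @return Data frame with columns \code{strain}, \code{stage},
#'   \code{locality}, \code{beta0}, \code{se_beta0}, \code{beta1},
#'   \code{se_beta1}, \code{A_R}, \code{B_R}, \code{p_beta1},
#'   \code{n_crosses}.
#' @export
load_report <- function(fits, locality = NULL) {
  row1 <- function(strain, fit) {
    data.frame(
      strain = strain, stage = fit$stage,
      locality = if (!is.null(locality) && strain %in% names(locality))
        locality[[strain]] else NA_character_,
      beta0 = fit$coefficients[[1]], se_beta0 = fit$se[[1]],
      beta1 = fit$coefficients[[2]], se_beta1 = fit$se[[2]],
      A_R = fit$A_R, B_R = fit$B_R, p_beta1 = fit$p_beta1,
      n_crosses = fit$n_crosses, stringsAsFactors = FALSE
    )
  }
  rows <- list()
  for (strain in names(fits)) {
    f <- fits[[strain]]
    if (inherits(f, "load_fit")) {
      rows[[length(rows) + 1L]] <- row1(strain, f)
    } else if (is.list(f)) {
      for (s in names(f)) {
        if (inherits(f[[s]], "load_fit")) {
          rows[[length(rows) + 1L]] <- row1(strain, f[[s]])
        }
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(strain = character(), stage = character(),
                      locality = character(), beta0 = numeric(),
                      se_beta0 = numeric(), beta1 = numeric(),
                      se_beta1 = numeric(), A_R = numeric(),
                      B_R = numeric(), p_beta1 = numeric(),
                      n_crosses = integer(), stringsAsFactors = FALSE))
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Write a strain-level load report
#'
#' Tab-separated, with coefficients and loads at 3 decimals and the
#' p-value in scientific notation — the precision conventional for load
#' tables.
#'
#' @param report data frame from [load_report()] (an empty one yields a
#'   header-only file).
#' @param path output file.
#' @export
write_report <- function(report, path) {
  out <- report
  for (col in c("beta0", "se_beta0", "beta1", "se_beta1", "A_R", "B_R")) {
    if (col %in% names(out)) out[[col]] <- sprintf("%.3f", out[[col]])
  }
  if ("p_beta1" %in% names(out)) {
    out$p_beta1 <- ifelse(report$p_beta1 < 1e-3,
                          sprintf("%.2e", report$p_beta1),
                          sprintf("%.3f", report$p_beta1))
  }
  if (nrow(report) == 0L) out <- report
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Reference load-regression coefficients for 11 Caenorhabditis strains
#'
#' Returns the published logistic-regression coefficient table for the
#' eleven strains of the load-estimation experiment shipped with the
#' package (species, strain, locality, beta0, SE, beta1, SE, p), read
#' from \code{inst/extdata/strain_load_coefficients.tsv}. Useful as a
#' worked example for [beta_to_load()] and [write_report()].
#'
#' @return Data frame, one row per strain.
#' @export
strain_coefficients <- function() {
  path <- system.file("extdata", "strain_load_coefficients.tsv",
                      package = "nemaload")
  utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                    stringsAsFactors = FALSE, encoding = "UTF-8")
}
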