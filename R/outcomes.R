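# Mapping of the two raw survey questions to the analysis outcomes.
#
# Q1 ("did you fail to receive needed medical treatment or examination in the
# past 12 months?"): 1 = experienced unmet need at least once, 2 = did not
# experience it (needs were met), 3 = no care of any kind was needed.
# Q2 (main reason, asked only when Q1 = 1): 1 = financial reasons, 7 = no time
# to visit a health facility, the remaining listed reasons (2-6, 8-10) are
# grouped as lack of caring and support.

q2_financial <- 1L
q2_time <- 7L
q2_other <- c(2L, 3L, 4L, 5L, 6L, 8L, 9L, 10L)

#' Derive the needs and barrier outcomes from raw survey answers
#'
#' Builds the dichotomous needs indicator \code{y1} (1 = experienced
#' healthcare needs, i.e. Q1 in \{1, 2\}; 0 = no care needed, Q1 = 3) and,
#' within the needs group, the quadchotomous outcome \code{y2}
#' (1 = met needs, 2 = financial difficulty, 3 = time constraint,
#' 4 = lack of caring and support).  \code{y2} is \code{NA} whenever
#' \code{y1 = 0}.  Records with missing Q1, or Q1 = 1 with missing Q2, are
#' removed (listwise deletion) and tallied in the exclusion log.
#'
#' @param data data frame with columns \code{q1} and \code{q2} (raw answer
#'   codes; \code{NA} for missing).
#' @return list with \code{data} (input rows retained, \code{y1}/\code{y2}
#'   columns appended) and \code{exclusions} (per-reason counts).
#' @export
derive_outcomes <- function(data) {
  stopifnot(is.data.frame(data), all(c("q1", "q2") %in% names(data)))
  q1 <- data$q1
  q2 <- data$q2
  bad_q1 <- !is.na(q1) & !(q1 %in% 1:3)
  if (any(bad_q1))
    stop("unknown q1 code(s) ", paste(unique(q1[bad_q1]), collapse = ", "),
         " in record(s) ", paste(utils::head(which(bad_q1), 5L), collapse = ", "),
         call. = FALSE)
  bad_q2 <- !is.na(q1) & q1 == 1L & !is.na(q2) & !(q2 %in% 1:10)
  if (any(bad_q2))
    stop("unknown q2 code(s) ", paste(unique(q2[bad_q2]), collapse = ", "),
         " in record(s) ", paste(utils::head(which(bad_q2), 5L), collapse = ", "),
         call. = FALSE)

  drop_q1 <- is.na(q1)
  drop_q2 <- !is.na(q1) & q1 == 1L & is.na(q2)
  keep <- !(drop_q1 | drop_q2)

  out <- data[keep, , drop = FALSE]
  q1 <- q1[keep]; q2 <- q2[keep]
  y1 <- ifelse(q1 %in% c(1L, 2L), 1L, 0L)
  y2 <- rep(NA_integer_, length(q1))
  y2[q1 == 2L] <- 1L
  y2[q1 == 1L & q2 == q2_financial] <- 2L
  y2[q1 == 1L & q2 == q2_time] <- 3L
  y2[q1 == 1L & q2 %in% q2_other] <- 4L
  out$y1 <- y1
  out$y2 <- y2

  exclusions <- data.frame(
    reason = c("missing needs answer (q1)",
               "unmet needs without reason (q1 = 1, q2 missing)"),
    n = c(sum(drop_q1), sum(drop_q2)))
  list(data = out, exclusions = exclusions)
}

#' Invert coded outcomes back to raw answer codes
#'
#' Inverse of [derive_outcomes()]: used by the synthetic generator so the
#' simulated panel carries raw survey codes.  For the lack-of-caring group the
#' reason code is drawn uniformly from the non-financial, non-time reasons.
#'
#' @param y1,y2 coded outcomes.
#' @return data frame with columns \code{q1}, \code{q2}.
#' @keywords internal
outcomes_to_codes <- function(y1, y2) {
  n <- length(y1)
  q1 <- integer(n); q2 <- rep(NA_integer_, n)
  q1[y1 == 0L] <- 3L
  q1[y1 == 1L & y2 == 1L] <- 2L
  unmet <- y1 == 1L & y2 %in% 2:4
  q1[unmet] <- 1L
  q2[y1 == 1L & y2 == 2L] <- q2_financial
  q2[y1 == 1L & y2 == 3L] <- q2_time
  lack <- which(y1 == 1L & y2 == 4L)
  if (length(lack))
    q2[lack] <- sample(q2_other, length(lack), replace = TRUE)
  data.frame(q1 = q1, q2 = q2)
}

#' Write an exclusion log as plain text
#'
#' @param exclusions data frame from [derive_outcomes()].
#' @param path file path.
#' @export
write_exclusion_log <- function(exclusions, path) {
  lines <- c("Excluded records (listwise deletion)",
             sprintf("  %-50s %d", exclusions$reason, exclusions$n),
             sprintf("  %-50s %d", "total", sum(exclusions$n)))
  writeLines(lines, path)
  invisible(path)
}
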