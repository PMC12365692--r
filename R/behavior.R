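DROWSINESS_CODES <- c(none = 0L, tired = 1L, sleepy = 2L,
                      difficulty_staying_awake = 3L)

#' Attention score: percent of recall questions answered correctly
#'
#' Pools the two runs of one viewing condition within a session:
#' `100 * total correct / total asked`.
#'
#' @param correct Integer vector of correct responses per run.
#' @param asked Integer vector of questions asked per run.
#' @return Percentage in `[0, 100]`, or `NA` when nothing was asked.
#' @export
attention_score <- function(correct, asked) {
  stopifnot(length(correct) == length(asked))
  if (any(correct > asked)) stop_invalid("`correct` cannot exceed `asked`")
  if (sum(asked) == 0) return(NA_real_)
  100 * sum(correct) / sum(asked)
}

#' Drowsiness score: coded endorsements summed over the two runs
#'
#' Coding: none/no response = 0, felt tired = 1, sleepy = 2, difficulty
#' staying awake = 3; the two runs' codes are summed, giving 0-6. If a
#' run endorses several levels the maximum is taken.
#'
#' @param run1,run2 Endorsement(s) for each run: names from
#'   `c("none", "tired", "sleepy", "difficulty_staying_awake")`.
#' @return Integer in 0..6.
#' @export
drowsiness_score <- function(run1, run2) {
  code <- function(x, which) {
    if (length(x) == 0 || any(is.na(x)))
      stop_invalid("missing drowsiness response for %s", which)
    bad <- setdiff(x, names(DROWSINESS_CODES))
    if (length(bad))
      stop_invalid("unknown drowsiness level(s): %s",
                   paste(bad, collapse = ", "))
    max(DROWSINESS_CODES[x])
  }
  as.integer(code(run1, "run 1") + code(run2, "run 2"))
}

#' Score a survey table
#'
#' Takes one row per subject x session x condition x run (columns
#' `subject_id`, `session`, `condition`, `run`, `correct`, `asked`,
#' `drowsiness`) and returns per subject x session x condition attention
#' and drowsiness scores.
#'
#' @param surveys Survey data frame (two runs per condition per session).
#' @return Data frame (subject_id, session, condition, attention,
#'   drowsiness).
#' @export
score_surveys <- function(surveys) {
  need <- c("subject_id", "session", "condition", "run", "correct",
            "asked", "drowsiness")
  missing_cols <- setdiff(need, names(surveys))
  if (length(missing_cols))
    stop_invalid("survey table lacks column(s): %s",
                 paste(missing_cols, collapse = ", "))
  key <- interaction(surveys$subject_id, surveys$session,
                     surveys$condition, drop = TRUE)
  rows <- lapply(split(surveys, key), function(d) {
    if (nrow(d) != 2L)
      stop_invalid("expected exactly 2 runs for %s ses %s cond %s",
                   d$subject_id[1L], d$session[1L], d$condition[1L])
    d <- d[order(d$run), ]
    data.frame(subject_id = d$subject_id[1L], session = d$session[1L],
               condition = d$condition[1L],
               attention = attention_score(d$correct, d$asked),
               drowsiness = drowsiness_score(d$drowsiness[1L],
                                             d$drowsiness[2L]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$subject_id, out$session, out$condition), ]
}
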