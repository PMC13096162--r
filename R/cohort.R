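#' Truncated-normal draws by inverse-CDF
#'
#' @param n number of draws.
#' @param mean,sd location and scale of the untruncated normal.
#' @param lower,upper truncation bounds.
#' @return numeric vector of length `n`; with `sd = 0` every draw equals
#'   `mean` (degenerate case).
#' @keywords internal
rtruncnorm <- function(n, mean, sd, lower, upper) {
  if (lower > upper) stop("invalid bounds: lower > upper")
  if (sd < 0) stop("sd must be non-negative")
  if (sd == 0) {
    if (mean < lower || mean > upper)
      stop("degenerate mean outside truncation bounds")
    return(rep(mean, n))
  }
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

#' Default cohort configuration
#'
#' Marginal distributions emulating the demographics of a bilingual adult
#' sample: a continuous bilingualism composite (LSBQ) score from a
#' truncated normal with mean 9.01, SD 2.69 on \[5.05, 14.05\]; age
#' truncated normal (33.11, 9.57) on \[18, 57\]; second-language age of
#' acquisition truncated normal (6.25, 4.63) on \[0, 20\]; education as an
#' ordinal 1-4 (GCSE, A-level, degree, postgraduate) with probabilities
#' 1/28, 4/28, 10/28, 13/28; gender female/male with probabilities 21/28,
#' 7/28; handedness right/left 26/28, 2/28; and a task-order label drawn
#' uniformly from the six permutations of three tasks.
#'
#' @return a list of distribution parameters consumed by [sample_cohort()].
#' @export
cohort_config <- function() {
  list(
    lsbq = list(mean = 9.01, sd = 2.69, lower = 5.05, upper = 14.05),
    age = list(mean = 33.11, sd = 9.57, lower = 18, upper = 57),
    l2_aoa = list(mean = 6.25, sd = 4.63, lower = 0, upper = 20),
    education = list(levels = c("GCSE", "A-level", "Degree", "Postgraduate"),
                     prob = c(1, 4, 10, 13) / 28),
    gender = list(levels = c("F", "M"), prob = c(21, 7) / 28),
    handedness = list(levels = c("R", "L"), prob = c(26, 2) / 28),
    task_order = list(levels = c("ABC", "ACB", "BAC", "BCA", "CAB", "CBA"),
                      prob = rep(1 / 6, 6))
  )
}

#' Sample a participant cohort
#'
#' Draws `n` participant profiles from the configured marginals; identical
#' `(config, seed)` pairs always give identical cohorts.
#'
#' @param n cohort size.
#' @param seed RNG seed.
#' @param config a [cohort_config()] list.
#' @return data frame with one row per participant: `id`, `lsbq`, `age`,
#'   `l2_aoa`, `education` (ordinal integer 1-4 with level labels kept in
#'   `education_label`), `gender`, `handedness`, `task_order`.
#' @examples
#' cohort <- sample_cohort(28, seed = 1)
#' range(cohort$lsbq)
#' @export
sample_cohort <- function(n, seed = 1L, config = cohort_config()) {
  if (n < 1) stop("n must be >= 1")
  for (v in c("lsbq", "age", "l2_aoa")) {
    cc <- config[[v]]
    if (cc$lower > cc$upper) stop("invalid bounds for ", v)
  }
  set.seed(seed)
  draw_num <- function(cc) rtruncnorm(n, cc$mean, cc$sd, cc$lower, cc$upper)
  draw_cat <- function(cc) {
    if (length(cc$levels) == 1L || any(cc$prob == 1))
      return(rep(cc$levels[which.max(cc$prob)], n))
    sample(cc$levels, n, replace = TRUE, prob = cc$prob)
  }
  edu <- draw_cat(config$education)
  data.frame(
    id = seq_len(n),
    lsbq = draw_num(config$lsbq),
    age = draw_num(config$age),
    l2_aoa = draw_num(config$l2_aoa),
    education = match(edu, config$education$levels),
    education_label = edu,
    gender = draw_cat(config$gender),
    handedness = draw_cat(config$handedness),
    task_order = draw_cat(config$task_order),
    stringsAsFactors = FALSE
  )
}
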