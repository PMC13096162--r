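#' Behavioral generator parameters
#'
#' Defaults emulate the qualitative learning pattern of the serial
#' reaction-time task: reaction times fall across blocks (the default
#' per-block slope of -12 ms gives a -84 ms change from the first to the
#' eighth block for an average participant), participants with more
#' bilingual experience respond faster overall (negative per-unit LSBQ
#' offset), and their learning slopes on hierarchically ambiguous material
#' are flatter (positive block-by-LSBQ interaction on trials with ambiguity
#' level >= 1, consistent with lower starting reaction times leaving less
#' room to improve).  Magnitudes are generator configuration, not empirical
#' claims.
#'
#' @param baseline_rt_ms intercept reaction time at the first block for an
#'   average participant.
#' @param block_slope_ms per-block change in expected reaction time.
#' @param lsbq_rt_offset ms change per LSBQ unit (centered at
#'   `lsbq_center`).
#' @param lsbq_slope_flattening ms/block/LSBQ-unit added to the block slope
#'   on trials with ambiguity level >= 1 (positive = flatter learning for
#'   higher scores).
#' @param class_effect_ambiguous,class_effect_disambiguated additive ms
#'   penalties for surface-ambiguous points that are never resolved at the
#'   annotation depth vs. resolved at some level >= 1.
#' @param lsbq_center centering constant for the score.
#' @param noise_sigma log-normal noise scale (SD of log reaction time);
#'   noise is mean-one multiplicative, so expected reaction times equal the
#'   structural mean.
#' @param accuracy_rate per-trial probability of a correct response.
#' @return list of class `behavior_params`.
#' @export
behavior_params <- function(baseline_rt_ms = 450,
                            block_slope_ms = -12,
                            lsbq_rt_offset = -12,
                            lsbq_slope_flattening = 2,
                            class_effect_ambiguous = 12,
                            class_effect_disambiguated = 4,
                            lsbq_center = 9.01,
                            noise_sigma = 0.12,
                            accuracy_rate = 0.97) {
  if (accuracy_rate <= 0 || accuracy_rate > 1)
    stop("accuracy_rate must be in (0, 1]")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  structure(as.list(environment()), class = "behavior_params")
}

#' Simulate trial-level responses for a cohort
#'
#' For every participant and session trial the expected reaction time is
#'
#' `baseline + slope(trial) * block + lsbq_rt_offset * lsbq_c + class effect`
#'
#' where `lsbq_c` is the centered bilingualism score and `slope(trial)`
#' equals `block_slope_ms` plus, on trials whose ambiguity level is >= 1,
#' `lsbq_slope_flattening * lsbq_c`.  Observed reaction times multiply the
#' mean by mean-one log-normal noise; correctness is Bernoulli with the
#' configured accuracy.  Training-block trials (no annotations) receive
#' only baseline, block, and offset terms.
#'
#' @param profiles cohort data frame from [sample_cohort()].
#' @param session a [build_session()] result (must carry annotations).
#' @param params a [behavior_params()] list.
#' @param seed RNG seed.
#' @return data frame: cohort covariates joined to trial rows with
#'   simulated `rt_ms` and `correct`.
#' @export
simulate_behavior <- function(profiles, session, params = behavior_params(),
                              seed = 1L) {
  tr <- session$trials
  if (!"ambiguity_level" %in% names(tr))
    stop("session has no annotations; build it with build_session()")
  set.seed(seed)
  out <- vector("list", nrow(profiles))
  for (r in seq_len(nrow(profiles))) {
    p <- profiles[r, ]
    lsbq_c <- p$lsbq - params$lsbq_center
    lev <- tr$ambiguity_level
    hier <- !is.na(tr$block) & tr$block > 0 &
      (is.na(lev) & tr$status == "unresolved" | !is.na(lev) & lev >= 1)
    hier[is.na(hier)] <- FALSE
    slope <- params$block_slope_ms + ifelse(hier,
                                            params$lsbq_slope_flattening *
                                              lsbq_c, 0)
    class_eff <- rep(0, nrow(tr))
    class_eff[which(tr$block > 0 & tr$status == "unresolved")] <-
      params$class_effect_ambiguous
    class_eff[which(tr$block > 0 & !is.na(lev) & lev >= 1)] <-
      params$class_effect_disambiguated
    mu <- params$baseline_rt_ms + slope * tr$block +
      params$lsbq_rt_offset * lsbq_c + class_eff
    noise <- if (params$noise_sigma == 0) 1 else
      exp(stats::rnorm(nrow(tr), 0, params$noise_sigma) -
            params$noise_sigma^2 / 2)
    d <- tr
    d$participant_id <- p$id
    d$lsbq <- p$lsbq
    d$rt_ms <- mu * noise
    d$correct <- stats::rbinom(nrow(tr), 1, params$accuracy_rate)
    out[[r]] <- d
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Mean reaction-time change from the first to the last block
#'
#' @param responses output of [simulate_behavior()].
#' @return mean reaction time in the final block minus the first block, ms.
#' @export
rt_block_change <- function(responses) {
  bl <- range(responses$block)
  mean(responses$rt_ms[responses$block == bl[2]]) -
    mean(responses$rt_ms[responses$block == bl[1]])
}
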