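# Shared fixture builders (all generated in code; nothing on disk).

fib_chr <- function(n) paste(fib_generate(n)$symbols, collapse = "")

# Balanced long-form edge table for a given cohort with configurable
# per-connection mean structure.  `effect` is a function(connection, lsbq)
# returning the mean GC value.
make_edge_table <- function(cohort, effect = function(cn, l) 0,
                            noise_sd = 0.02, seed = 1) {
  labs <- roi_labels()
  conns <- as.vector(outer(labs, labs, function(a, b) paste0(a, "->", b)))
  conns <- conns[rep(labs, times = 8) != rep(labs, each = 8)]
  et <- expand.grid(participant_id = cohort$id, connection = conns,
                    stringsAsFactors = FALSE)
  et <- merge(et, cohort[, c("id", "lsbq", "age", "l2_aoa", "education",
                             "gender", "task_order")],
              by.x = "participant_id", by.y = "id")
  set.seed(seed)
  mu <- mapply(effect, et$connection, et$lsbq)
  et$gc <- mu + rnorm(nrow(et), 0, noise_sd)
  et
}

# Closed-form GC oracle for a bivariate VAR with true innovation variance
# sigma2_full for the target: restricted AR(p) residual variance from the
# stationary autocovariances (Yule-Walker), independent of the estimator.
gc_oracle_var <- function(coef, sigma, target, p_restricted = 1L) {
  G <- var_stationary_autocov(coef, sigma, lags = p_restricted)
  g <- vapply(G, function(m) m[target, target], 0)   # lags 0..p
  Gam <- outer(seq_len(p_restricted), seq_len(p_restricted),
               function(i, j) g[abs(i - j) + 1L])
  rhs <- g[2:(p_restricted + 1L)]
  phi <- solve(Gam, rhs)
  s2r <- g[1] - sum(phi * rhs)
  log(s2r / sigma[target, target])
}

# Independent white-noise recording at a given amplitude (uV).
white_recording <- function(n_s = 60, fs = 128, k = 8, sd_uv = 5,
                            seed = 1) {
  set.seed(seed)
  eeg_recording(matrix(rnorm(n_s * fs * k, 0, sd_uv), ncol = k), fs = fs,
                channels = roi_labels()[seq_len(k)], participant_id = 1,
                condition = "pre")
}

identity_montage <- function(channels = roi_labels())
  as.list(stats::setNames(as.list(channels), channels))
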