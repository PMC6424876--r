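# Shared fixtures, all built in code at test time.

# Small labelled synthetic cohort on an inhomogeneous (S2G) radiobiology.
tiny_s2g_cohort <- function(n = 40, shape = c(8, 8), seed = 11,
                            event_rate = 0.4, n_exp = 0.3, ...) {
  g <- grid_spec(shape)
  rs <- make_rs_map(g, "s2g")
  simulate_cohort(n, g, rs = rs, n_exp = n_exp, event_rate = event_rate,
                  seed = seed, ...)
}

# Cohort with a hand-planted informative voxel: outcome driven by the dose
# at one voxel only, all other voxels pure noise.
planted_cohort <- function(n = 60, shape = c(4, 4), signal_voxel = 6,
                           beta = c(-1, 3), seed = 1) {
  set.seed(seed)
  g <- grid_spec(shape)
  repeat {
    maps <- replicate(n, matrix(runif(prod(shape)), shape[1], shape[2]),
                      simplify = FALSE)
    dsig <- vapply(maps, function(m) m[signal_voxel], numeric(1))
    y <- rbinom(n, 1, plogis(beta[1] + beta[2] * dsig))
    if (length(unique(y)) == 2) break
  }
  out <- tibble::tibble(id = sprintf("P%03d", seq_len(n)), dose = maps,
                        outcome = y)
  attr(out, "grid") <- g
  out
}

# Exhaustive pair-counting AUC oracle (independent of roc_auc's rank form)
auc_pairs <- function(probs, outcomes) {
  cases <- probs[outcomes == 1]
  ctrls <- probs[outcomes == 0]
  s <- 0
  for (a in cases) for (b in ctrls) {
    s <- s + (a > b) + 0.5 * (a == b)
  }
  s / (length(cases) * length(ctrls))
}
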