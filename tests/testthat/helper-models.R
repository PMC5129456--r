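# shared fixtures: the published best-fit models used across tests

scabra_bsfs_model <- function() {
  demographic_model("IM2", theta = 0.00129, T = 12.0, M = 0.032,
                    direction = "B->A", size_factor = 2.07,
                    factor_target = "B")
}

bombina_bsfs_model <- function() {
  demographic_model("IM2", theta = 0.00154, T = 19.8, M = 0.015,
                    direction = "B->A", size_factor = 1.36,
                    factor_target = "A")
}

orientalis_bsfs_model <- function() {
  demographic_model("Div2", theta = 0.00752, T = 3.75, size_factor = 0.2,
                    factor_target = "A")
}

# a small deterministic block table
toy_blocks <- function() {
  data.frame(orthogroup = sprintf("og%02d", 1:6), n_sites = 150,
             kA = c(3, 0, 1, 0, 2, 0), kB = c(0, 3, 1, 0, 0, 1),
             kAB = c(0, 0, 0, 0, 1, 0), kAABB = c(2, 4, 0, 0, 3, 5),
             four_gamete_pass = c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE))
}

# independent two-lineage oracle: expected pairwise coalescence time for
# a single pair sampled in one population, integrating the two-population
# phase by explicit Euler steps.  Deliberately naive so it shares nothing
# with the package's matrix-exponential machinery.
pair_expected_time <- function(Tsplit, coal_rate, mig_rate, dt = 1e-4) {
  # states: both in the sampled population, one migrated, both migrated
  # (the non-sampled population is assumed at the ancestral size),
  # coalesced
  p <- c(two_here = 1, split = 0, two_there = 0, done = 0)
  et <- 0
  t <- 0
  while (t < Tsplit) {
    et <- et + (1 - p[["done"]]) * dt
    dp1 <- -(coal_rate + 2 * mig_rate) * p[["two_here"]]
    dp2 <- 2 * mig_rate * p[["two_here"]] - mig_rate * p[["split"]]
    dp3 <- mig_rate * p[["split"]] - 1 * p[["two_there"]]
    dpd <- coal_rate * p[["two_here"]] + 1 * p[["two_there"]]
    p <- p + c(dp1, dp2, dp3, dpd) * dt
    t <- t + dt
  }
  # ancestral phase: a surviving pair coalesces at rate 1, so it adds an
  # expected time of 1
  et + (1 - p[["done"]]) * 1
}

# closed-form probability of an invariant panmictic block (4 lineages,
# per-branch mutation rate lam): stage-wise competition between
# coalescence and mutation
panmictic_invariant_prob <- function(lam) {
  (6 / (6 + 4 * lam)) * (3 / (3 + 3 * lam)) * (1 / (1 + 2 * lam))
}
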