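#' Convert scaled estimates to absolute demographic quantities
#'
#' Converts coalescent-scaled parameter estimates into absolute
#' quantities, given a per-generation mutation rate \eqn{\mu} at the
#' analysed sites and a generation time \eqn{g} in years:
#' \itemize{
#'   \item ancestral effective size \eqn{N_{anc} = \theta / (4\mu)}
#'     (diploid individuals),
#'   \item divergence time \eqn{t = T \times 2 N_{anc} \times g} years,
#'   \item mean waiting time between effective immigrants \eqn{g / M}
#'     years (\code{Inf} when \eqn{M = 0}),
#'   \item expected fraction of the recipient genome affected by
#'     post-divergence introgression, \eqn{1 - e^{-M T}}.
#' }
#'
#' @param fit A \code{"divmig_fit"} object, a named parameter vector
#'   containing \code{theta} and \code{T} (optionally \code{M}), or a
#'   \code{\link{demographic_model}}.
#' @param mu Mutation rate per site per generation (default
#'   \code{9.15e-9}, a fourfold-degenerate-site rate for archaeobatrachian
#'   frogs with a three-year generation time).
#' @param g Generation time in years (default 3).
#' @return An object of class \code{"absolute_estimates"}.
#' @examples
#' to_absolute(c(theta = 0.00129, T = 12, M = 0.032))
#' @export
to_absolute <- function(fit, mu = 9.15e-9, g = 3) {
  stopifnot(mu > 0, g > 0)
  if (inherits(fit, "divmig_fit")) par <- coef(fit)
  else if (inherits(fit, "demographic_model"))
    par <- c(theta = fit$theta, T = fit$T, M = fit$M)
  else par <- fit
  if (!all(c("theta", "T") %in% names(par)))
    stop("need at least theta and T")
  theta <- par[["theta"]]
  Tsplit <- par[["T"]]
  M <- if ("M" %in% names(par)) par[["M"]] else 0
  N_anc <- theta / (4 * mu)
  structure(list(
    N_anc = N_anc,
    t_years = Tsplit * 2 * N_anc * g,
    immigrant_waiting_years = if (M > 0) g / M else Inf,
    introgressed_fraction = 1 - exp(-M * Tsplit),
    theta = theta, T = Tsplit, M = M, mu = mu, g = g),
    class = "absolute_estimates")
}

#' @export
print.absolute_estimates <- function(x, ...) {
  cat(sprintf("Absolute estimates (mu = %.3g /site/generation, g = %g years):\n",
              x$mu, x$g))
  cat(sprintf("  ancestral Ne:          %.3g diploid individuals\n", x$N_anc))
  cat(sprintf("  divergence time:       %.3g years (%.2g My)\n",
              x$t_years, x$t_years / 1e6))
  cat(sprintf("  immigrant waiting:     %s\n",
              if (is.finite(x$immigrant_waiting_years))
                sprintf("%.3g years", x$immigrant_waiting_years) else "Inf (M = 0)"))
  cat(sprintf("  introgressed fraction: %.3g\n", x$introgressed_fraction))
  invisible(x)
}

#' Binomial test for an excess of blocks lacking particular site classes
#'
#' Under a fitted model, the probability that a block carries no mutations
#' of the pinned classes is computed exactly
#' (\code{\link{pattern_probability_marginal}}); the observed number of
#' such blocks is then compared to binomial sampling among the retained
#' blocks with a one-sided upper-tail test.  Pinning \code{"kAABB"} asks
#' whether blocks without fixed differences are over-represented (a
#' signature of introgression under a strict-divergence model); pinning
#' all four classes tests for an excess of completely invariant blocks.
#'
#' @param blocks Block table.
#' @param model A \code{\link{demographic_model}} (typically a fitted one).
#' @param pinned Character vector of classes required to be absent.
#' @param n_sites Sites per block; taken from the table if present.
#' @return List with \code{observed}, \code{n}, \code{p_model} and the
#'   upper-tail binomial probability \code{P}.
#' @export
excess_block_test <- function(blocks, model, pinned = "kAABB",
                              n_sites = NULL) {
  blocks <- .check_blocks(blocks)
  blocks <- blocks[blocks$four_gamete_pass, , drop = FALSE]
  n <- nrow(blocks)
  if (n == 0L) stop("no blocks to test")
  if (is.null(n_sites))
    n_sites <- if ("n_sites" %in% names(blocks)) blocks$n_sites[1] else 150
  kmat <- as.matrix(blocks[, c("kA", "kB", "kAB", "kAABB")])
  idx <- match(pinned, c("kA", "kB", "kAB", "kAABB"))
  if (anyNA(idx)) stop("unknown class in pinned")
  observed <- sum(rowSums(kmat[, idx, drop = FALSE]) == 0)
  p_model <- pattern_probability_marginal(model, pinned, n_sites = n_sites)
  P <- stats::pbinom(observed - 1, n, p_model, lower.tail = FALSE)
  list(observed = observed, n = n, p_model = p_model, P = P,
       pinned = pinned)
}
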