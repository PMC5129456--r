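#' Multinomial log-likelihood of site-frequency counts
#'
#' Log-likelihood of the folded joint SFS for one unphased diploid genome
#' per population: category counts of the four variable site classes plus
#' the invariant complement, with per-site probabilities
#' \eqn{(\theta/2) E[t_c]} under the model.
#'
#' @param model A \code{\link{demographic_model}}.
#' @param counts Named or positional numeric vector of length 5:
#'   \code{kA, kB, kAB, kAABB, invariant}.
#' @return The log-likelihood; \code{-Inf} if any category probability is
#'   non-positive under the model.
#' @export
sfs_loglik <- function(model, counts) {
  stopifnot(length(counts) == 5L, all(counts >= 0))
  if (!is.null(names(counts)))
    counts <- counts[c("kA", "kB", "kAB", "kAABB", "invariant")]
  p <- tryCatch(expected_site_frequencies(model), error = function(e) NULL)
  if (is.null(p) || any(p[counts > 0] <= 0)) return(-Inf)
  sum(counts[counts > 0] * log(p[counts > 0]))
}

#' Blockwise SFS log-likelihood
#'
#' Sum of log pattern probabilities \eqn{\sum \ln p(k)} over blocks,
#' treating blocks as independent replicates of the coalescent.  Blocks
#' that fail the four-gamete test are excluded (with a message), because
#' they are incompatible with the single-genealogy assumption of the
#' blockwise likelihood.  Probabilities are cached over distinct \code{k}
#' vectors, so the cost scales with the number of distinct configurations.
#'
#' @param model A \code{\link{demographic_model}}.
#' @param blocks Data frame with columns \code{kA}, \code{kB}, \code{kAB},
#'   \code{kAABB} and optionally \code{n_sites} and
#'   \code{four_gamete_pass}.
#' @param n_sites Sites per block; taken from the table if present.
#' @param quiet Suppress the exclusion message.
#' @return The log-likelihood.
#' @export
bsfs_loglik <- function(model, blocks, n_sites = NULL, quiet = FALSE) {
  blocks <- .check_blocks(blocks)
  if (is.null(n_sites))
    n_sites <- if ("n_sites" %in% names(blocks)) blocks$n_sites[1] else 150
  fail <- !blocks$four_gamete_pass
  if (any(fail)) {
    if (!quiet)
      message(sum(fail), " block(s) violating the four-gamete test excluded")
    blocks <- blocks[!fail, , drop = FALSE]
  }
  if (nrow(blocks) == 0L) stop("no blocks left after four-gamete filtering")
  key <- paste(blocks$kA, blocks$kB, blocks$kAB, blocks$kAABB)
  tab <- table(key)
  uk <- .as_k_matrix(blocks[match(names(tab), key), c("kA", "kB", "kAB", "kAABB")])
  p <- pattern_probability(model, uk, n_sites = n_sites)
  if (any(p <= 0)) return(-Inf)
  sum(as.numeric(tab) * log(p))
}

# validate and normalise a block table
.check_blocks <- function(blocks) {
  if (is.matrix(blocks)) blocks <- as.data.frame(blocks)
  need <- c("kA", "kB", "kAB", "kAABB")
  if (!all(need %in% names(blocks)))
    stop("block table must have columns ", paste(need, collapse = ", "))
  if (!"four_gamete_pass" %in% names(blocks))
    blocks$four_gamete_pass <- !(blocks$kAB > 0 & blocks$kAABB > 0)
  blocks
}

# 5-category counts (all-sites SFS) from a block table
.sfs_counts <- function(blocks, n_sites = NULL) {
  blocks <- .check_blocks(blocks)
  if (is.null(n_sites))
    n_sites <- if ("n_sites" %in% names(blocks)) blocks$n_sites[1] else 150
  tot <- nrow(blocks) * n_sites
  v <- c(kA = sum(blocks$kA), kB = sum(blocks$kB), kAB = sum(blocks$kAB),
         kAABB = sum(blocks$kAABB))
  c(v, invariant = tot - sum(v))
}
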