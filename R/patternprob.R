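# shared plumbing: assemble the C++ arguments for a model
.coalcore_args <- function(model) {
  ss <- .statespace_for(model)
  list(ss = ss,
       t1_from = as.integer(ss$trans1[, 1L] - 1L),
       t1_to = as.integer(ss$trans1[, 2L] - 1L),
       t1_rate = .trans1_rates(ss, model),
       t2_from = as.integer(ss$trans2[, 1L] - 1L),
       t2_to = as.integer(ss$trans2[, 2L] - 1L),
       t2_rate = as.numeric(ss$trans2[, 3L]),
       map12 = as.integer(ss$map12 - 1L),
       abs2 = as.integer(ss$abs2 - 1L),
       init1 = as.integer(ss$init1 - 1L))
}

# active down-closed cell set for a set of query count vectors
.active_cells <- function(k) {
  kmax <- apply(k, 2L, max)
  dims <- kmax + 1L
  nfull <- prod(dims)
  if (nfull > 5e5)
    stop("mutation-count box too large (", nfull, " cells); ",
         "check the block counts")
  grid <- as.matrix(expand.grid(0:kmax[1], 0:kmax[2], 0:kmax[3], 0:kmax[4],
                                KEEP.OUT.ATTRS = FALSE))
  active <- rep(FALSE, nfull)
  for (r in seq_len(nrow(k)))
    active <- active | (grid[, 1L] <= k[r, 1L] & grid[, 2L] <= k[r, 2L] &
                        grid[, 3L] <= k[r, 3L] & grid[, 4L] <= k[r, 4L])
  cells <- grid[active, , drop = FALSE]
  ord <- order(rowSums(cells))
  cells <- cells[ord, , drop = FALSE]
  strides <- c(1L, cumprod(dims)[1:3])
  full_idx <- as.integer(cells %*% strides)
  lookup <- rep(-1L, nfull)
  lookup[full_idx + 1L] <- seq_len(nrow(cells)) - 1L
  qidx <- lookup[as.integer(k %*% strides) + 1L]
  list(dims = as.integer(dims), cells = cells, lookup = lookup, query = qidx)
}

.patternprob_call <- function(model, k, lambda, tol = 1e-12) {
  a <- .coalcore_args(model)
  cs <- .active_cells(k)
  patternprob_cpp(model$T, lambda,
                  a$ss$n1, a$init1, a$t1_from, a$t1_to, a$t1_rate, a$ss$nclass1,
                  a$ss$n2, a$abs2, a$t2_from, a$t2_to, a$t2_rate, a$ss$nclass2,
                  a$map12, cs$dims, cs$lookup,
                  matrix(as.integer(cs$cells), ncol = 4L), cs$query, tol)
}

.as_k_matrix <- function(k) {
  if (is.data.frame(k)) k <- as.matrix(k[, c("kA", "kB", "kAB", "kAABB")])
  if (is.null(dim(k))) k <- matrix(k, nrow = 1L)
  if (ncol(k) != 4L) stop("k must have four columns (kA, kB, kAB, kAABB)")
  storage.mode(k) <- "integer"
  if (any(k < 0)) stop("mutation counts must be non-negative")
  k
}

#' Exact probability of a blockwise mutation configuration
#'
#' Computes \eqn{p(k)}, the probability that a non-recombining block of
#' \code{n_sites} sites carries exactly \code{k = (kA, kB, kAB, kAABB)}
#' mutations of the four folded site classes, under a
#' \code{\link{demographic_model}}.  Mutations fall on the genealogy as a
#' Poisson process with intensity \eqn{\lambda = n_{sites} \theta / 2} per
#' branch per unit of \eqn{2 N_{anc}} generations; the probability is exact
#' up to the numerical tolerance of the uniformised transient solution.
#'
#' @param model A \code{\link{demographic_model}}.
#' @param k Integer vector of length 4, a 4-column matrix, or a data frame
#'   with columns \code{kA}, \code{kB}, \code{kAB}, \code{kAABB}.
#' @param n_sites Number of sites per block (default 150).
#' @param tol Truncation tolerance of the uniformised series.
#' @return Numeric vector of probabilities, one per row of \code{k}.
#' @examples
#' m <- demographic_model("Div", theta = 0.001, T = 0)
#' # panmictic invariant block: (6/(6+4L))(3/(3+3L))(1/(1+2L)), L = 0.075
#' pattern_probability(m, c(0, 0, 0, 0), n_sites = 150)
#' @export
pattern_probability <- function(model, k, n_sites = 150, tol = 1e-12) {
  stopifnot(inherits(model, "demographic_model"), n_sites > 0)
  k <- .as_k_matrix(k)
  lambda <- rep(n_sites * model$theta / 2, 4L)
  p <- .patternprob_call(model, k, lambda, tol)
  if (any(p > 1 + 1e-8)) stop("pattern probability exceeds 1; numerical failure")
  p
}

#' Probability that selected site classes are absent from a block
#'
#' Computes \eqn{P(k_c = 0)} jointly for a set of pinned classes, i.e. the
#' Laplace transform \eqn{E[\exp(-\sum_c \lambda t_c)]} of the pinned
#' branch lengths.  Classes that are not pinned are unconstrained
#' (marginalised over), which corresponds to switching their mutation
#' intensity off.
#'
#' @inheritParams pattern_probability
#' @param pinned Character vector naming the classes constrained to zero,
#'   a subset of \code{c("kA", "kB", "kAB", "kAABB")}.
#' @return A single probability.
#' @examples
#' m <- demographic_model("IM2", theta = 0.00154, T = 19.8, M = 0.015,
#'                        direction = "B->A", size_factor = 1.36,
#'                        factor_target = "A")
#' # probability of a block with no fixed differences
#' pattern_probability_marginal(m, "kAABB")
#' @export
pattern_probability_marginal <- function(model, pinned, n_sites = 150,
                                         tol = 1e-12) {
  classes <- c("kA", "kB", "kAB", "kAABB")
  if (length(pinned) == 0L) return(1)
  if (!all(pinned %in% classes)) stop("pinned must be a subset of ",
                                      paste(classes, collapse = ", "))
  lambda <- ifelse(classes %in% pinned, n_sites * model$theta / 2, 0)
  .patternprob_call(model, matrix(0L, 1L, 4L), lambda, tol)
}

#' Simulate blockwise mutation configurations
#'
#' Draws independent structured-coalescent genealogies for one unphased
#' diploid genome per population (Gillespie simulation of the lineage
#' process, exact in distribution) and overlays Poisson mutation counts
#' per folded site class.  This simulator is the Monte-Carlo oracle for
#' \code{\link{pattern_probability}} and the engine behind the synthetic
#' data generator.
#'
#' @inheritParams pattern_probability
#' @param n_blocks Number of independent blocks to draw.
#' @return Integer matrix with \code{n_blocks} rows and columns
#'   \code{kA}, \code{kB}, \code{kAB}, \code{kAABB}.  Uses the R random
#'   number generator; seed with \code{set.seed} for reproducibility.
#' @examples
#' set.seed(1)
#' m <- demographic_model("Div", theta = 0.005, T = 8)
#' colMeans(simulate_blocks(m, 1000)) / 150  # close to expected_site_frequencies
#' @export
simulate_blocks <- function(model, n_blocks, n_sites = 150) {
  stopifnot(inherits(model, "demographic_model"), n_blocks >= 1)
  a <- .coalcore_args(model)
  lambda <- rep(n_sites * model$theta / 2, 4L)
  k <- simulate_blocks_cpp(as.integer(n_blocks), model$T, lambda,
                           a$ss$n1, a$init1, a$t1_from, a$t1_to, a$t1_rate,
                           a$ss$nclass1, a$ss$n2, a$abs2, a$t2_from, a$t2_to,
                           a$t2_rate, a$ss$nclass2, a$map12)
  colnames(k) <- c("kA", "kB", "kAB", "kAABB")
  k
}
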