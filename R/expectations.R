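#' Expected branch lengths per folded mutation class
#'
#' Computes the expected total branch length subtending each of the four
#' folded site classes (heterozygous only in A, only in B, in both, and
#' alternate homozygotes) for a sample of one unphased diploid genome per
#' population, under a two-population divergence model.  Lengths are in
#' units of \eqn{2 N_{anc}} generations, so the expected per-site frequency
#' of class \eqn{c} is \eqn{(\theta/2) E[t_c]}.
#'
#' The calculation is exact: the structured coalescent over the interval
#' \eqn{[0, T)} is a finite-state Markov chain whose accumulated rewards
#' (number of branches of each class) are obtained from a single matrix
#' exponential of an augmented generator; the panmictic phase after
#' \eqn{T} contributes its expected rewards through a linear solve.
#'
#' @param model A \code{\link{demographic_model}}.
#' @return Named numeric vector \code{c(tA, tB, tAB, tAABB)}.
#' @examples
#' # panmictic limit: (4/3, 4/3, 2/3, 1/3)
#' expected_branch_lengths(demographic_model("Div", theta = 0.001, T = 0))
#' @export
expected_branch_lengths <- function(model) {
  stopifnot(inherits(model, "demographic_model"))
  ss <- .statespace_for(model)
  n1 <- ss$n1

  # panmictic phase: expected remaining rewards until full coalescence
  live <- setdiff(seq_len(ss$n2), ss$abs2)
  Q2 <- matrix(0, ss$n2, ss$n2)
  Q2[ss$trans2[, 1:2, drop = FALSE]] <- ss$trans2[, 3L]
  diag(Q2) <- diag(Q2) - rowSums(Q2)
  h <- matrix(0, ss$n2, 4L)
  h[live, ] <- solve(-Q2[live, live, drop = FALSE], ss$nclass2[live, , drop = FALSE])

  if (model$T <= 0) {
    et <- h[ss$map12[ss$init1], ]
  } else {
    rates <- .trans1_rates(ss, model)
    Q <- matrix(0, n1, n1)
    idx <- ss$trans1[, 1:2, drop = FALSE]
    for (r in seq_len(nrow(idx))) Q[idx[r, 1L], idx[r, 2L]] <- Q[idx[r, 1L], idx[r, 2L]] + rates[r]
    diag(Q) <- diag(Q) - rowSums(Q)
    A <- rbind(cbind(Q, ss$nclass1), matrix(0, 4L, n1 + 4L))
    E <- as.matrix(Matrix::expm(Matrix::Matrix(A * model$T)))
    p_T <- E[ss$init1, seq_len(n1)]
    acc <- E[ss$init1, n1 + 1:4]
    et <- acc + as.numeric(p_T %*% h[ss$map12, , drop = FALSE])
  }
  stats::setNames(et, c("tA", "tB", "tAB", "tAABB"))
}

#' Expected per-site frequencies of the four site classes
#'
#' Converts expected branch lengths into expected per-site frequencies
#' \eqn{E[k_c] = (\theta/2) E[t_c]} and the complementary probability that
#' a site is invariant (small-\eqn{\theta} linearisation).
#'
#' @inheritParams expected_branch_lengths
#' @return Named numeric vector \code{c(kA, kB, kAB, kAABB, invariant)}.
#' @examples
#' m <- demographic_model("Div2", theta = 0.00752, T = 3.75,
#'                        size_factor = 0.2, factor_target = "A")
#' round(expected_site_frequencies(m), 5)
#' @export
expected_site_frequencies <- function(model) {
  et <- expected_branch_lengths(model)
  ek <- model$theta / 2 * et
  if (sum(ek) >= 1)
    stop("theta too large for per-site linearization")
  stats::setNames(c(ek, 1 - sum(ek)), c("kA", "kB", "kAB", "kAABB", "invariant"))
}

#' Folded class of a branch from the lineages it subtends
#'
#' Maps a subset of the sample \{a1, a2, b1, b2\} (one unphased diploid per
#' population) to the folded mutation class a mutation on that branch
#' produces.  Complementary subsets map to the same class because genotypes
#' are unpolarised.
#'
#' @param labels Character vector, a proper non-empty subset of
#'   \code{c("a1", "a2", "b1", "b2")}.
#' @return One of \code{"kA"}, \code{"kB"}, \code{"kAB"}, \code{"kAABB"}.
#' @examples
#' branch_class_of(c("a1"))             # "kA"
#' branch_class_of(c("a1", "b1", "b2")) # "kA" (fold of {a2})
#' @export
branch_class_of <- function(labels) {
  all_labels <- c("a1", "a2", "b1", "b2")
  if (!all(labels %in% all_labels) || anyDuplicated(labels))
    stop("labels must be a subset of {a1, a2, b1, b2} without duplicates")
  n <- length(labels)
  if (n == 0L || n == 4L)
    stop("no mutation is observable on a branch subtending ",
         if (n == 0L) "no lineages" else "the full sample")
  cl <- .lineage_class(sum(labels %in% c("a1", "a2")),
                       sum(labels %in% c("b1", "b2")))
  c("kA", "kB", "kAB", "kAABB")[cl]
}
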