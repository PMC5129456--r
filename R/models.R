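#' Specify a two-population demographic model
#'
#' Constructs a demographic model for a pair of populations A and B that
#' descend from a common ancestral population of effective size
#' \eqn{N_{anc}}.  The ancestral population splits at time \code{T}
#' (measured in units of \eqn{2 N_{anc}} generations, looking back from the
#' present).  After the split, migration may occur in one direction at a
#' constant scaled rate \code{M}, and one descendant population may take an
#' effective size that differs from \eqn{N_{anc}} by a constant factor.
#'
#' The four model classes are
#' \describe{
#'   \item{\code{Div}}{strict divergence: no migration, both descendants
#'     keep size \eqn{N_{anc}}.}
#'   \item{\code{IM}}{isolation with migration: unidirectional gene flow at
#'     rate \code{M}, equal sizes.}
#'   \item{\code{Div2}}{strict divergence, but one descendant has size
#'     \code{size_factor} \eqn{\times N_{anc}}.}
#'   \item{\code{IM2}}{both migration and a one-sided size change.}
#' }
#'
#' @param model_class One of \code{"Div"}, \code{"IM"}, \code{"Div2"},
#'   \code{"IM2"}.
#' @param theta Ancestral scaled mutation rate \eqn{\theta = 4 N_{anc} \mu}
#'   per site.  Must be positive.
#' @param T Split time in units of \eqn{2 N_{anc}} generations
#'   (\code{T >= 0}).
#' @param M Scaled migration rate \eqn{M = 4 N_{anc} m}, the effective
#'   number of migrants per generation.  Must be 0 for \code{Div} and
#'   \code{Div2}.
#' @param direction Direction of migration in forward time,
#'   \code{"B->A"} (donor B, recipient A) or \code{"A->B"}.  Ignored when
#'   \code{M = 0}.
#' @param size_factor Ratio of the affected descendant's effective size to
#'   \eqn{N_{anc}}.  Must be 1 for \code{Div} and \code{IM}.
#' @param factor_target Which descendant population ("A" or "B") carries
#'   \code{size_factor}.
#'
#' @return An object of class \code{"demographic_model"}.
#'
#' @examples
#' # the best-supported model for a pair of hybridizing taxa:
#' m <- demographic_model("IM2", theta = 0.00154, T = 19.8, M = 0.015,
#'                        direction = "B->A", size_factor = 1.36,
#'                        factor_target = "A")
#' expected_site_frequencies(m)
#' @export
demographic_model <- function(model_class = c("Div", "IM", "Div2", "IM2"),
                              theta, T, M = 0,
                              direction = c("B->A", "A->B"),
                              size_factor = 1,
                              factor_target = c("A", "B")) {
  model_class <- match.arg(model_class)
  direction <- match.arg(direction)
  factor_target <- match.arg(factor_target)
  if (!is.finite(theta) || theta <= 0) stop("theta must be positive and finite")
  if (!is.finite(T) || T < 0) stop("T must be non-negative and finite")
  if (!is.finite(M) || M < 0) stop("M must be non-negative and finite")
  if (!is.finite(size_factor) || size_factor <= 0)
    stop("size_factor must be positive and finite")
  if (model_class %in% c("Div", "Div2") && M != 0)
    stop("M must be 0 under ", model_class)
  if (model_class %in% c("Div", "IM") && size_factor != 1)
    stop("size_factor must be 1 under ", model_class)
  structure(
    list(model_class = model_class, theta = theta, T = T, M = M,
         direction = direction, size_factor = size_factor,
         factor_target = factor_target),
    class = "demographic_model")
}

#' @export
print.demographic_model <- function(x, ...) {
  cat(sprintf("Demographic model %s: theta = %g, T = %g", x$model_class,
              x$theta, x$T))
  if (x$M > 0) cat(sprintf(", M = %g (%s)", x$M, x$direction))
  if (x$size_factor != 1)
    cat(sprintf(", size factor %g on %s", x$size_factor, x$factor_target))
  cat("\n")
  invisible(x)
}

# effective sizes of the two descendant populations, in units of N_anc
.pop_sizes <- function(model) {
  sizes <- c(A = 1, B = 1)
  sizes[model$factor_target] <- model$size_factor
  sizes
}

# which migration "kind" is active backward in time: lineages sampled in
# the forward-time *recipient* population may trace their ancestry to the
# donor, i.e. jump recipient -> donor when looking back.
.mig_kind <- function(model) {
  if (model$M == 0) return("none")
  if (model$direction == "B->A") "AtoB" else "BtoA"
}
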