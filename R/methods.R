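#' @export
print.divmig_fit <- function(x, ...) {
  cat(sprintf("Divergence-model fit (%s) on %d blocks of %d sites", x$mode,
              x$n_blocks, x$n_sites))
  if (x$n_excluded > 0)
    cat(sprintf(" (%d four-gamete violations excluded)", x$n_excluded))
  cat("\n\nModel support (dlnL relative to best):\n")
  cmp <- x$comparison
  cmp$theta <- signif(cmp$theta, 3)
  cmp$T <- signif(cmp$T, 3)
  cmp$M <- signif(cmp$M, 3)
  cmp$factor <- signif(cmp$factor, 3)
  cmp$lnL <- round(cmp$lnL, 2)
  cmp$dlnL <- round(cmp$dlnL, 2)
  print(cmp[, c("variant", "theta", "T", "M", "factor", "lnL", "dlnL",
                "collapsed")], row.names = FALSE)
  cat("\nBest-supported model:", x$best, "\n")
  invisible(x)
}

#' @export
summary.divmig_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.divmig_fit")
}

#' @export
print.summary.divmig_fit <- function(x, ...) {
  print(x$fit)
  best <- x$fit$fits[[x$fit$best]]
  cat("\nBest-fit parameters:\n")
  print(signif(best$par, 4))
  cat("\nObserved per-site class frequencies vs best-model expectation:\n")
  obs <- x$fit$counts / sum(x$fit$counts)
  exp_ <- expected_site_frequencies(best$model)
  print(rbind(observed = signif(obs, 3), expected = signif(exp_, 3)))
  invisible(x)
}

#' Extract the best-fit parameter estimates
#'
#' @param object A \code{"divmig_fit"}.
#' @param ... Unused.
#' @return Named vector \code{c(theta, T, M, factor)} of the
#'   best-supported variant.
#' @export
coef.divmig_fit <- function(object, ...) object$fits[[object$best]]$par

#' @export
logLik.divmig_fit <- function(object, ...) {
  best <- object$fits[[object$best]]
  structure(best$lnL, df = length(.variant_parnames(best$model_class)),
            nobs = object$n_blocks, class = "logLik")
}

#' Expected site-class frequencies under the best-supported model
#'
#' @param object A \code{"divmig_fit"}.
#' @param ... Unused.
#' @return Named vector of per-site frequencies (including the invariant
#'   complement) under the best-fit model.
#' @export
predict.divmig_fit <- function(object, ...) {
  expected_site_frequencies(object$fits[[object$best]]$model)
}

#' Simulate block tables from a fitted model
#'
#' Draws new block tables under the best-supported fitted model, matching
#' the size of the fitted dataset by default.
#'
#' @param object A \code{"divmig_fit"}.
#' @param nsim Number of simulated tables.
#' @param seed Optional seed.
#' @param n_blocks Blocks per table (default: as fitted).
#' @param ... Unused.
#' @return A block table (data frame), or a list of them if
#'   \code{nsim > 1}.
#' @export
simulate.divmig_fit <- function(object, nsim = 1, seed = NULL,
                                n_blocks = object$n_blocks, ...) {
  if (!is.null(seed)) set.seed(seed)
  model <- object$fits[[object$best]]$model
  one <- function(i) {
    k <- simulate_blocks(model, n_blocks, object$n_sites)
    data.frame(orthogroup = sprintf("sim%04d", seq_len(n_blocks)),
               n_sites = object$n_sites, k,
               four_gamete_pass = !(k[, "kAB"] > 0 & k[, "kAABB"] > 0))
  }
  if (nsim == 1) one(1) else lapply(seq_len(nsim), one)
}
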