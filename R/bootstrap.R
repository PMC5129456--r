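#' Bootstrap confidence intervals for SFS parameter estimates
#'
#' Generates bootstrap replicates of the folded SFS by drawing one
#' randomly chosen variable site per block (blocks without variable sites
#' contribute only invariant sites), refits the model to each replicate,
#' and summarises the spread of the estimates.  Confidence intervals are
#' reported as the point estimate plus or minus 1.96 bootstrap standard
#' deviations.
#'
#' @param blocks Block table (see \code{\link{fit_divergence}}).
#' @param fit A \code{"divmig_fit"} in SFS mode whose best variant is
#'   refitted to each replicate; if missing, a Div model is fitted first.
#' @param B Number of bootstrap replicates (at least 2).
#' @param seed Optional integer seed.
#' @param n_starts Optimisation starts per replicate (each replicate also
#'   starts from the point estimate).
#' @param maxit Optimiser iteration cap per replicate.
#' @return An object of class \code{"divmig_boot"}: matrix of replicate
#'   estimates, per-parameter SD and CI.
#' @export
bootstrap_sfs <- function(blocks, fit = NULL, B = 1000, seed = NULL,
                          n_starts = 1, maxit = 100) {
  if (B < 2) stop("B must be at least 2")
  blocks <- .check_blocks(blocks)
  if (!is.null(seed)) set.seed(seed)
  n_sites <- if ("n_sites" %in% names(blocks)) blocks$n_sites[1] else 150
  if (is.null(fit))
    fit <- fit_divergence(blocks, mode = "SFS", models = "Div",
                          n_starts = 3, n_sites = n_sites)
  if (fit$mode != "SFS") stop("bootstrap_sfs requires an SFS-mode fit")
  best <- fit$fits[[fit$best]]
  variant <- list(class = best$model_class, direction = best$direction,
                  target = best$target)
  parnames <- .variant_parnames(variant$class)
  point_full <- c(ltheta = log(best$par[["theta"]]), lT = log(best$par[["T"]]),
                  M = best$par[["M"]], lfactor = log(best$par[["factor"]]))
  bounds <- .default_bounds
  bb <- .par_bounds(parnames, bounds)

  kmat <- as.matrix(blocks[, c("kA", "kB", "kAB", "kAABB")])
  n_var <- rowSums(kmat)
  n_blocks <- nrow(kmat)

  est <- matrix(NA_real_, B, 4,
                dimnames = list(NULL, c("theta", "T", "M", "factor")))
  for (b in seq_len(B)) {
    # one variable site per block, drawn with probability proportional to
    # the class counts of that block; the rest of the block is invariant
    drawn <- integer(4)
    has <- which(n_var > 0)
    if (length(has)) {
      cls <- vapply(has, function(i)
        sample.int(4L, 1L, prob = kmat[i, ]), 0L)
      drawn <- tabulate(cls, nbins = 4L)
    }
    counts <- c(drawn, n_blocks * n_sites - sum(drawn))
    names(counts) <- c("kA", "kB", "kAB", "kAABB", "invariant")
    objective <- function(p) {
      ll <- sfs_loglik(.variant_model(variant, stats::setNames(p, parnames)),
                       counts)
      if (!is.finite(ll)) 1e10 else -ll
    }
    starts <- list(point_full)
    while (length(starts) < n_starts + 1L)
      starts <- c(starts, list(.random_start(c("ltheta", "lT", "M", "lfactor"),
                                             bounds)))
    bestv <- NULL
    for (st in starts) {
      res <- .safe_optim(st[parnames], objective, bb$lower, bb$upper, maxit)
      if (is.null(bestv) || res$value < bestv$value) bestv <- res
    }
    m <- .variant_model(variant, stats::setNames(bestv$par, parnames))
    est[b, ] <- c(m$theta, m$T, m$M, m$size_factor)
  }
  sds <- apply(est, 2, stats::sd)
  point <- best$par[c("theta", "T", "M", "factor")]
  ci <- rbind(lower = point - 1.96 * sds, upper = point + 1.96 * sds)
  structure(list(estimates = est, point = point, sd = sds, ci = ci, B = B,
                 variant = .variant_label(variant), seed = seed),
            class = "divmig_boot")
}

#' @export
print.divmig_boot <- function(x, ...) {
  cat(sprintf("SFS bootstrap (%d replicates of one variable site per block), variant %s\n",
              x$B, x$variant))
  out <- rbind(estimate = x$point, sd = x$sd, x$ci)
  print(signif(out, 4))
  invisible(x)
}
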