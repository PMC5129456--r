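# optimisation bounds in natural units (bracket published estimates by >10x)
.default_bounds <- list(theta = c(1e-5, 0.05), T = c(0.01, 100),
                        M = c(0, 2), factor = c(0.05, 20))

# variant = (model_class, direction, factor_target); parameters are
# optimised as (log theta, log T [, M] [, log factor])
.variant_parnames <- function(class) {
  switch(class,
         Div = c("ltheta", "lT"),
         IM = c("ltheta", "lT", "M"),
         Div2 = c("ltheta", "lT", "lfactor"),
         IM2 = c("ltheta", "lT", "M", "lfactor"))
}

.variant_model <- function(variant, par) {
  theta <- exp(par[["ltheta"]])
  Tsplit <- exp(par[["lT"]])
  M <- if ("M" %in% names(par)) par[["M"]] else 0
  f <- if ("lfactor" %in% names(par)) exp(par[["lfactor"]]) else 1
  demographic_model(variant$class, theta = theta, T = Tsplit, M = M,
                    direction = variant$direction, size_factor = f,
                    factor_target = variant$target)
}

.variant_label <- function(variant) {
  lbl <- variant$class
  if (variant$class %in% c("IM", "IM2")) lbl <- paste0(lbl, "[", variant$direction, "]")
  if (variant$class %in% c("Div2", "IM2")) lbl <- paste0(lbl, "[N", variant$target, "]")
  lbl
}

.par_bounds <- function(parnames, bounds) {
  lo <- c(ltheta = log(bounds$theta[1]), lT = log(bounds$T[1]),
          M = bounds$M[1], lfactor = log(bounds$factor[1]))
  hi <- c(ltheta = log(bounds$theta[2]), lT = log(bounds$T[2]),
          M = bounds$M[2], lfactor = log(bounds$factor[2]))
  list(lower = lo[parnames], upper = hi[parnames])
}

.clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# moment-based starting point from category frequencies
.mom_start <- function(counts, parnames, bounds) {
  f <- counts / sum(counts)
  theta0 <- .clip(max(f[["kA"]], 1e-5), bounds$theta[1] * 1.01, bounds$theta[2] * 0.99)
  T0 <- .clip(f[["kAABB"]] / theta0 - 1, bounds$T[1] * 1.05, bounds$T[2] * 0.95)
  f0 <- .clip(max(f[["kB"]], 1e-6) / theta0, bounds$factor[1] * 1.05,
              bounds$factor[2] * 0.95)
  full <- c(ltheta = log(theta0), lT = log(T0), M = 0.01, lfactor = log(f0))
  full[parnames]
}

.random_start <- function(parnames, bounds) {
  full <- c(
    ltheta = stats::runif(1, log(bounds$theta[1]), log(bounds$theta[2])),
    lT = stats::runif(1, log(bounds$T[1]), log(bounds$T[2])),
    M = 10^stats::runif(1, -3, log10(max(bounds$M[2], 1e-3))),
    lfactor = stats::runif(1, log(bounds$factor[1]), log(bounds$factor[2])))
  full[parnames]
}

.safe_optim <- function(start, objective, lower, upper, maxit) {
  start <- .clip(start, lower, upper)
  res <- tryCatch(
    stats::optim(start, objective, method = "L-BFGS-B", lower = lower,
                 upper = upper, control = list(maxit = maxit)),
    error = function(e) NULL)
  if (is.null(res)) {
    pen <- function(p) {
      if (any(p < lower) || any(p > upper)) return(1e10)
      objective(p)
    }
    res <- stats::optim(start, pen, method = "Nelder-Mead",
                        control = list(maxit = 4 * maxit))
  }
  res
}

.fit_variant <- function(variant, objective, starts, bounds, maxit) {
  parnames <- .variant_parnames(variant$class)
  bb <- .par_bounds(parnames, bounds)
  best <- NULL
  conv <- integer(0)
  for (st in starts) {
    res <- .safe_optim(st[parnames], objective, bb$lower, bb$upper, maxit)
    conv <- c(conv, res$convergence)
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best) || !is.finite(best$value))
    stop("no convergent optimisation start for variant ",
         .variant_label(variant),
         " (convergence codes: ", paste(conv, collapse = ","), ")")
  par <- stats::setNames(best$par, parnames)
  model <- .variant_model(variant, par)
  est <- c(theta = model$theta, T = model$T, M = model$M,
           factor = model$size_factor)
  collapsed <- variant$class %in% c("IM", "IM2") && model$M < 1e-4
  list(label = .variant_label(variant), model_class = variant$class,
       direction = variant$direction, target = variant$target,
       par = est, model = model, lnL = -best$value,
       convergence = best$convergence, n_starts = length(starts),
       collapsed = collapsed)
}

#' Fit divergence models to blockwise site-class data
#'
#' Fits the four two-population model classes (\code{Div}, \code{IM},
#' \code{Div2}, \code{IM2}) by maximum likelihood, either on the folded
#' joint SFS (5-category multinomial over all sites) or on the blockwise
#' SFS (product of exact block pattern probabilities).  For models with
#' migration both directions are fitted; for models with a one-sided size
#' change both target populations are fitted.  \code{IM2} is only
#' identifiable in bSFS mode and is rejected for SFS fits.
#'
#' Fitting proceeds from the simplest model outward, and every richer
#' model receives the optimum of its nested submodel as one of its
#' starting points, so that the likelihood ordering of nested models is
#' respected up to optimiser tolerance.
#'
#' @param blocks Block table: data frame with columns \code{kA},
#'   \code{kB}, \code{kAB}, \code{kAABB}, optionally \code{n_sites} and
#'   \code{four_gamete_pass} (see \code{\link{make_blocks}} or
#'   \code{\link{simulate_block_table}}).
#' @param mode \code{"bSFS"} (default) or \code{"SFS"}.
#' @param models Character vector of model classes to fit.
#' @param n_sites Sites per block; taken from the table if present.
#' @param directions Migration directions to evaluate for IM/IM2
#'   (default: both).
#' @param targets Size-change target populations to evaluate for
#'   Div2/IM2 (default: both).
#' @param n_starts Number of optimisation starts per variant (a
#'   moment-based start and the nested-model optima are always included).
#' @param seed Optional integer seed for the random starts.
#' @param bounds Optional list overriding the default parameter bounds
#'   (\code{theta}, \code{T}, \code{M}, \code{factor}, each \code{c(lo, hi)}).
#' @param maxit Maximum optimiser iterations per start.
#' @return An object of class \code{"divmig_fit"}; see
#'   \code{\link{compare_models}}, \code{\link{coef.divmig_fit}},
#'   \code{\link{to_absolute}}.
#' @examples
#' set.seed(7)
#' truth <- demographic_model("Div", theta = 0.002, T = 10)
#' tab <- simulate_block_table(synthetic_scenario(model = truth,
#'                                                n_blocks = 300, seed = 7))
#' fit <- fit_divergence(tab, mode = "SFS", models = c("Div", "IM"),
#'                       n_starts = 3, seed = 1)
#' fit
#' @export
fit_divergence <- function(blocks, mode = c("bSFS", "SFS"), models = NULL,
                           n_sites = NULL, directions = c("A->B", "B->A"),
                           targets = c("A", "B"), n_starts = 10, seed = NULL,
                           bounds = NULL, maxit = 200) {
  mode <- match.arg(mode)
  blocks <- .check_blocks(blocks)
  if (is.null(models))
    models <- if (mode == "bSFS") c("Div", "IM", "Div2", "IM2")
              else c("Div", "IM", "Div2")
  if (mode == "SFS" && "IM2" %in% models)
    stop("IM2 is not identifiable from the SFS; use bSFS mode")
  if (!all(models %in% c("Div", "IM", "Div2", "IM2")))
    stop("unknown model class")
  if (!is.null(seed)) set.seed(seed)
  bounds <- utils::modifyList(.default_bounds, if (is.null(bounds)) list() else bounds)
  if (is.null(n_sites))
    n_sites <- if ("n_sites" %in% names(blocks)) blocks$n_sites[1] else 150

  counts <- .sfs_counts(blocks, n_sites)
  n_excluded <- sum(!blocks$four_gamete_pass)

  if (mode == "SFS") {
    objective_for <- function(variant) {
      function(p) {
        ll <- sfs_loglik(.variant_model(variant, stats::setNames(p, .variant_parnames(variant$class))), counts)
        if (!is.finite(ll)) 1e10 else -ll
      }
    }
    n_used <- nrow(blocks)
  } else {
    used <- blocks[blocks$four_gamete_pass, , drop = FALSE]
    if (nrow(used) == 0L) stop("no blocks pass the four-gamete test")
    key <- paste(used$kA, used$kB, used$kAB, used$kAABB)
    tab <- table(key)
    uk <- .as_k_matrix(used[match(names(tab), key), c("kA", "kB", "kAB", "kAABB")])
    wt <- as.numeric(tab)
    cs <- .active_cells(uk) # cell geometry is shared by all evaluations
    cells_int <- matrix(as.integer(cs$cells), ncol = 4L)
    objective_for <- function(variant) {
      function(p) {
        m <- tryCatch(.variant_model(variant, stats::setNames(p, .variant_parnames(variant$class))),
                      error = function(e) NULL)
        if (is.null(m)) return(1e10)
        a <- .coalcore_args(m)
        lambda <- rep(n_sites * m$theta / 2, 4L)
        pr <- tryCatch(
          patternprob_cpp(m$T, lambda, a$ss$n1, a$init1, a$t1_from, a$t1_to,
                          a$t1_rate, a$ss$nclass1, a$ss$n2, a$abs2, a$t2_from,
                          a$t2_to, a$t2_rate, a$ss$nclass2, a$map12, cs$dims,
                          cs$lookup, cells_int, cs$query, 1e-10),
          error = function(e) NULL)
        if (is.null(pr) || any(pr <= 0) || any(!is.finite(pr))) return(1e10)
        -sum(wt * log(pr))
      }
    }
    n_used <- nrow(used)
  }

  variants <- list()
  for (cls in intersect(c("Div", "IM", "Div2", "IM2"), models)) {
    dirs <- if (cls %in% c("IM", "IM2")) directions else "B->A"
    tgts <- if (cls %in% c("Div2", "IM2")) targets else "A"
    for (d in dirs) for (tg in tgts)
      variants[[length(variants) + 1L]] <- list(class = cls, direction = d, target = tg)
  }

  mom <- .mom_start(counts, c("ltheta", "lT", "M", "lfactor"), bounds)
  fits <- list()
  opt_par <- list() # nested-model optima keyed by label, as full vectors
  for (variant in variants) {
    starts <- list(mom)
    # nested-model optima as additional starts
    seed_labels <- switch(variant$class,
      Div = character(0),
      IM = "Div",
      Div2 = "Div",
      IM2 = c(paste0("IM[", variant$direction, "]"),
              paste0("Div2[N", variant$target, "]"), "Div"))
    for (sl in seed_labels)
      if (!is.null(opt_par[[sl]])) starts <- c(starts, list(opt_par[[sl]]))
    while (length(starts) < n_starts)
      starts <- c(starts, list(.random_start(c("ltheta", "lT", "M", "lfactor"), bounds)))
    ft <- .fit_variant(variant, objective_for(variant), starts, bounds, maxit)
    fits[[ft$label]] <- ft
    full <- c(ltheta = log(ft$par[["theta"]]), lT = log(ft$par[["T"]]),
              M = ft$par[["M"]], lfactor = log(ft$par[["factor"]]))
    opt_par[[ft$label]] <- full
  }

  lnL <- vapply(fits, `[[`, 0, "lnL")
  out <- structure(
    list(call = match.call(), mode = mode, n_sites = n_sites,
         n_blocks = n_used, n_excluded = if (mode == "bSFS") n_excluded else 0L,
         counts = counts, fits = fits,
         best = names(fits)[which.max(lnL)]),
    class = "divmig_fit")
  out$comparison <- compare_models(out)
  out
}

#' Compare fitted model variants by log-likelihood difference
#'
#' Tabulates \eqn{\Delta \ln L} for each fitted variant relative to the
#' best-supported one (which is assigned 0), flagging boundary collapses
#' of migration models onto their strict-divergence counterparts.
#'
#' @param fits A \code{"divmig_fit"} object, or a list of fit entries from
#'   several such objects fitted to the same data in the same mode.
#' @return Data frame with one row per variant: label, model class,
#'   direction, size-change target, estimates, \code{lnL}, \code{dlnL},
#'   and a \code{collapsed} flag.
#' @export
compare_models <- function(fits) {
  if (inherits(fits, "divmig_fit")) {
    entries <- fits$fits
  } else if (is.list(fits) && all(vapply(fits, inherits, TRUE, "divmig_fit"))) {
    modes <- unique(vapply(fits, `[[`, "", "mode"))
    if (length(modes) > 1L) stop("cannot compare fits from different modes")
    entries <- do.call(c, lapply(fits, `[[`, "fits"))
  } else stop("fits must be a divmig_fit or a list of divmig_fit objects")
  if (length(entries) < 1L) stop("nothing to compare")
  lnL <- vapply(entries, `[[`, 0, "lnL")
  df <- data.frame(
    variant = vapply(entries, `[[`, "", "label"),
    model_class = vapply(entries, `[[`, "", "model_class"),
    direction = vapply(entries, function(f)
      if (f$model_class %in% c("IM", "IM2")) f$direction else NA_character_, ""),
    target = vapply(entries, function(f)
      if (f$model_class %in% c("Div2", "IM2")) f$target else NA_character_, ""),
    theta = vapply(entries, function(f) f$par[["theta"]], 0),
    T = vapply(entries, function(f) f$par[["T"]], 0),
    M = vapply(entries, function(f) f$par[["M"]], 0),
    factor = vapply(entries, function(f) f$par[["factor"]], 0),
    lnL = lnL,
    dlnL = lnL - max(lnL),
    collapsed = vapply(entries, `[[`, TRUE, "collapsed"),
    row.names = NULL)
  df[order(-df$lnL), ]
}
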