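# State space of the structured coalescent for one unphased diploid
# genome per population: the sample is {a1, a2} from A and {b1, b2} from B.
# A lineage is summarised by the number of a- and b-labels it is ancestral
# to plus its current population; genotypes are unphased, so states are
# lumped over the exchangeable relabelings a1<->a2 and b1<->b2.
#
# Mutation classes (folded; indices used throughout the package):
#   1 = kA    heterozygous only in A   (subtends one a, or one a + both b)
#   2 = kB    heterozygous only in B
#   3 = kAB   heterozygous in both     (subtends one a + one b)
#   4 = kAABB alternate homozygotes    (subtends both a or both b)
# A branch ancestral to the full sample carries no observable mutations.

.divmig_env <- new.env(parent = emptyenv())

.lineage_class <- function(na, nb) {
  if (na + nb == 4L) return(0L)
  if (na == 1L && nb %in% c(0L, 2L)) return(1L)
  if (nb == 1L && na %in% c(0L, 2L)) return(2L)
  if (na == 1L && nb == 1L) return(3L)
  4L # (2,0) or (0,2)
}

.canon_config <- function(m) {
  o <- do.call(order, lapply(seq_len(ncol(m)), function(j) m[, j]))
  m[o, , drop = FALSE]
}

.config_key <- function(m) paste(t(m), collapse = ",")

# enumerate reachable configurations by breadth-first search
#
# migration: which backward-time lineage movement is possible
#   "none", "AtoB" (lineages in A jump to B), "BtoA"
# Returns the two-population (pre-split) space, the panmictic (ancestral)
# space, transition templates and branch-class counts.
.build_statespace <- function(migration) {
  # ---- phase 1: two populations, pops coded 1 = A, 2 = B -------------
  init <- .canon_config(cbind(na = c(1L, 1L, 0L, 0L),
                              nb = c(0L, 0L, 1L, 1L),
                              pop = c(1L, 1L, 2L, 2L)))
  states <- list(init)
  keys <- new.env(parent = emptyenv())
  assign(.config_key(init), 1L, envir = keys)
  trans <- list() # (from, to, kind, mult)
  add_trans <- function(from, cfg, kind, mult) {
    key <- .config_key(cfg)
    idx <- keys[[key]]
    if (is.null(idx)) {
      states[[length(states) + 1L]] <<- cfg
      idx <- length(states)
      assign(key, idx, envir = keys)
    }
    trans[[length(trans) + 1L]] <<- c(from, idx, kind, mult)
    idx
  }
  i <- 1L
  while (i <= length(states)) {
    cfg <- states[[i]]
    n <- nrow(cfg)
    # coalescence within each population
    if (n >= 2L) {
      moves <- list()
      for (p in seq_len(n - 1L)) for (q in seq(p + 1L, n)) {
        if (cfg[p, 3L] != cfg[q, 3L]) next
        merged <- c(cfg[p, 1L] + cfg[q, 1L], cfg[p, 2L] + cfg[q, 2L], cfg[p, 3L])
        nxt <- .canon_config(rbind(cfg[-c(p, q), , drop = FALSE], merged))
        kind <- if (cfg[p, 3L] == 1L) 1L else 2L # coalA / coalB
        moves[[length(moves) + 1L]] <- list(nxt, kind)
      }
      if (length(moves)) {
        sig <- vapply(moves, function(mv) paste(.config_key(mv[[1]]), mv[[2]]), "")
        for (s in unique(sig)) {
          mv <- moves[[match(s, sig)]]
          add_trans(i, mv[[1]], mv[[2]], sum(sig == s))
        }
      }
    }
    # backward migration
    if (migration != "none") {
      from_pop <- if (migration == "AtoB") 1L else 2L
      to_pop <- if (migration == "AtoB") 2L else 1L
      idxs <- which(cfg[, 3L] == from_pop)
      if (length(idxs)) {
        moves <- lapply(idxs, function(p) {
          nxt <- cfg
          nxt[p, 3L] <- to_pop
          .canon_config(nxt)
        })
        sig <- vapply(moves, .config_key, "")
        for (s in unique(sig))
          add_trans(i, moves[[match(s, sig)]], 3L, sum(sig == s)) # kind 3 = mig
      }
    }
    i <- i + 1L
  }
  n1 <- length(states)
  t1 <- do.call(rbind, trans)
  nclass1 <- t(vapply(states, function(cfg) {
    cl <- vapply(seq_len(nrow(cfg)),
                 function(r) .lineage_class(cfg[r, 1L], cfg[r, 2L]), 0L)
    tabulate(cl[cl > 0L], nbins = 4L)
  }, integer(4)))

  # ---- phase 2: single ancestral population --------------------------
  pinit <- .canon_config(cbind(na = c(1L, 1L, 0L, 0L), nb = c(0L, 0L, 1L, 1L)))
  pstates <- list(pinit)
  pkeys <- new.env(parent = emptyenv())
  assign(.config_key(pinit), 1L, envir = pkeys)
  ptrans <- list()
  j <- 1L
  while (j <= length(pstates)) {
    cfg <- pstates[[j]]
    n <- nrow(cfg)
    if (n >= 2L) {
      moves <- list()
      for (p in seq_len(n - 1L)) for (q in seq(p + 1L, n)) {
        merged <- c(cfg[p, 1L] + cfg[q, 1L], cfg[p, 2L] + cfg[q, 2L])
        moves[[length(moves) + 1L]] <-
          .canon_config(rbind(cfg[-c(p, q), , drop = FALSE], merged))
      }
      sig <- vapply(moves, .config_key, "")
      for (s in unique(sig)) {
        cfg2 <- moves[[match(s, sig)]]
        idx <- pkeys[[s]]
        if (is.null(idx)) {
          pstates[[length(pstates) + 1L]] <- cfg2
          idx <- length(pstates)
          assign(s, idx, envir = pkeys)
        }
        ptrans[[length(ptrans) + 1L]] <- c(j, idx, sum(sig == s))
      }
    }
    j <- j + 1L
  }
  n2 <- length(pstates)
  t2 <- do.call(rbind, ptrans)
  abs2 <- which(vapply(pstates, nrow, 0L) == 1L)
  nclass2 <- t(vapply(pstates, function(cfg) {
    cl <- vapply(seq_len(nrow(cfg)),
                 function(r) .lineage_class(cfg[r, 1L], cfg[r, 2L]), 0L)
    tabulate(cl[cl > 0L], nbins = 4L)
  }, integer(4)))

  map12 <- vapply(states, function(cfg) {
    pkeys[[.config_key(.canon_config(cfg[, 1:2, drop = FALSE]))]]
  }, 0L)

  list(n1 = n1, states1 = states, init1 = 1L, trans1 = t1, nclass1 = nclass1,
       n2 = n2, states2 = pstates, trans2 = t2, abs2 = abs2,
       nclass2 = nclass2, map12 = map12, migration = migration)
}

.statespace <- function(migration = c("none", "AtoB", "BtoA")) {
  migration <- match.arg(migration)
  key <- paste0("ss_", migration)
  ss <- .divmig_env[[key]]
  if (is.null(ss)) {
    ss <- .build_statespace(migration)
    .divmig_env[[key]] <- ss
  }
  ss
}

.statespace_for <- function(model) .statespace(.mig_kind(model))

# numeric per-transition rates for the phase-1 templates
# kinds: 1 coalescence in A, 2 coalescence in B, 3 backward migration
.trans1_rates <- function(ss, model) {
  sizes <- .pop_sizes(model)
  kind_rate <- c(1 / sizes[["A"]], 1 / sizes[["B"]], model$M / 2)
  ss$trans1[, 4L] * kind_rate[ss$trans1[, 3L]]
}
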