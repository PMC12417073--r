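# Independent test oracles. These never call the package's LP or overlap
# code paths: the flux polytope is enumerated vertex by vertex, and the
# overlap integral is done by brute-force trapezoid quadrature on a fine
# grid.

# All basic feasible solutions (vertices) of {v : S v = 0, lb <= v <= ub}.
# Enumerates every basis of size rank(S) with all nonbasic variables pinned
# at a bound; only valid for small models with finite bounds.
enumerate_vertices <- function(S, lb, ub, tol = 1e-7) {
  n <- ncol(S)
  r <- qr(S)$rank
  verts <- list()
  bases <- if (r == 0L) list(integer()) else utils::combn(n, r, simplify = FALSE)
  for (B in bases) {
    SB <- S[, B, drop = FALSE]
    if (length(B) && qr(SB)$rank < length(B)) next
    N <- setdiff(seq_len(n), B)
    picks <- expand.grid(rep(list(c(FALSE, TRUE)), length(N)))
    if (nrow(picks) == 0L) picks <- data.frame(row.names = 1)
    for (g in seq_len(nrow(picks))) {
      vN <- ifelse(unlist(picks[g, ]), ub[N], lb[N])
      v <- numeric(n)
      v[N] <- vN
      if (length(B)) {
        rhs <- if (length(N)) -S[, N, drop = FALSE] %*% vN else matrix(0, nrow(S), 1)
        vB <- qr.coef(qr(SB), rhs)
        if (anyNA(vB)) next
        v[B] <- vB
      }
      if (max(abs(S %*% v)) > 1e-6) next
      if (any(v < lb - tol) || any(v > ub + tol)) next
      verts[[length(verts) + 1L]] <- v
    }
  }
  if (!length(verts)) return(NULL)
  unique(do.call(rbind, verts))
}

# LP optimum of c'v over the flux polytope by vertex enumeration
oracle_lp_opt <- function(S, lb, ub, obj, maximize = TRUE) {
  V <- enumerate_vertices(S, lb, ub)
  if (is.null(V)) return(NA_real_)
  vals <- as.numeric(V %*% obj)
  if (maximize) max(vals) else min(vals)
}

# FVA bounds of one reaction by vertex enumeration
oracle_fva <- function(S, lb, ub, j) {
  V <- enumerate_vertices(S, lb, ub)
  if (is.null(V)) return(c(NA_real_, NA_real_))
  c(min(V[, j]), max(V[, j]))
}

# model -> (S, lb, ub) triple, with optional bound tightening
model_polytope <- function(model, extra = NULL) {
  S <- matrix(0, nrow(model$metabolites), nrow(model$reactions),
              dimnames = list(model$metabolites$id, model$reactions$id))
  for (j in seq_len(nrow(model$reactions))) {
    st <- model$reactions$metabolites[[j]]
    S[names(st), j] <- st
  }
  lb <- model$reactions$lower_bound
  ub <- model$reactions$upper_bound
  if (!is.null(extra)) {
    for (k in seq_len(nrow(extra))) {
      i <- match(extra$id[k], model$reactions$id)
      lb[i] <- max(lb[i], extra$lb[k])
      ub[i] <- min(ub[i], extra$ub[k])
    }
  }
  list(S = S, lb = lb, ub = ub)
}

# overlap of two normal densities by trapezoid quadrature on a fine grid.
# The minimum density is bounded by both densities, so it is negligible
# outside the intersection of the two 9-sigma windows; gridding only that
# window keeps the step size far below the smaller sigma.
oracle_overlap <- function(m1, s1, m2, s2, n_grid = 200001L) {
  lo <- max(m1 - 9 * s1, m2 - 9 * s2)
  hi <- min(m1 + 9 * s1, m2 + 9 * s2)
  if (hi <= lo) return(0)
  x <- seq(lo, hi, length.out = n_grid)
  y <- pmin(stats::dnorm(x, m1, s1), stats::dnorm(x, m2, s2))
  sum((y[-1] + y[-n_grid]) / 2) * (x[2] - x[1])
}

# small chain model EX_A -> R1 -> EX_P used by LP unit tests
chain_model <- function(uptake = 10) {
  rxns <- data.frame(
    id = c("EX_A", "R1", "EX_P"),
    name = c("", "", ""),
    lower_bound = c(-uptake, 0, 0),
    upper_bound = c(1000, 1000, 1000),
    gpr = c("", "g1", ""),
    stringsAsFactors = FALSE
  )
  rxns$metabolites <- list(c(A = -1), c(A = -1, P = 1), c(P = -1))
  metabolic_model(
    "chain",
    metabolites = data.frame(id = c("A", "P"), compartment = "c",
                             stringsAsFactors = FALSE),
    reactions = rxns, genes = "g1", objective_reaction = "EX_P"
  )
}
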