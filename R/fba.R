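#' Knock out reactions in a model
#'
#' Returns a copy of the model in which each listed reaction has both flux
#' bounds forced to zero, simulating an enzyme/gene deletion. The input model
#' is not modified.
#'
#' @param gem a [GEM-class].
#' @param ids character vector of reaction ids (may be empty).
#' @return the modified `GEM`.
#' @examples
#' gem <- makeToyGEM("TOY6")
#' reactions(knockout(gem, "R3"))[4, c("lowerBound", "upperBound")]
#' @export
knockout <- function(gem, ids) {
  ids <- as.character(ids)
  unknown <- setdiff(ids, gem@reactions$id)
  if (length(unknown))
    stopf("unknown reaction id(s): %s", paste(unknown, collapse = ", "))
  hit <- gem@reactions$id %in% ids
  gem@reactions$lowerBound[hit] <- 0
  gem@reactions$upperBound[hit] <- 0
  gem
}

#' Flux balance analysis
#'
#' Solves the linear program
#' \deqn{\max\ c^T v \quad \mathrm{s.t.}\quad S v = 0,\ lb \le v \le ub}
#' where S is the stoichiometric matrix over non-boundary metabolites, c the
#' objective coefficients and the bounds those of the model, with knocked-out
#' reactions fixed to zero flux. The optimal objective value of the LP is
#' unique even where the flux vector is not; the solver configuration is
#' deterministic, so repeated solves of the same model return the same vertex.
#'
#' @param gem a [GEM-class].
#' @param knockouts reaction ids whose bounds are forced to `[0, 0]` for this
#'   solve (the model itself is untouched).
#' @param objective optional reaction id to maximize, overriding (or supplying,
#'   when the model declares none) the model objective with coefficient 1.
#' @param zeroTolerance fluxes with absolute value at or below this are
#'   treated as zero by downstream filters (default `1e-9`, the solver noise
#'   floor).
#' @return a [FluxState-class]. `status` is `"optimal"` with fluxes for every
#'   reaction, or `"infeasible"` / `"unbounded"` with no fluxes.
#' @examples
#' fs <- optimizeFlux(makeToyGEM("TOY6"))
#' objectiveValue(fs)        # 5
#' fluxes(fs)[["UPT"]]       # 10
#' @export
optimizeFlux <- function(gem, knockouts = character(), objective = NULL,
                         zeroTolerance = 1e-9) {
  r <- gem@reactions
  knockouts <- as.character(knockouts)
  unknown <- setdiff(knockouts, r$id)
  if (length(unknown))
    stopf("unknown knockout reaction id(s): %s", paste(unknown, collapse = ", "))

  cc <- r$objectiveCoefficient
  if (!is.null(objective)) {
    if (!objective %in% r$id) stopf("unknown objective reaction id: %s", objective)
    cc <- ifelse(r$id == objective, 1, 0)
  }
  if (all(cc == 0))
    stopf("model has no objective reaction; supply one via 'objective'")

  lb <- r$lowerBound; ub <- r$upperBound
  # the LP is solved over a box; unbounded declarations are clamped
  lb <- pmax(lb, -1e6); ub <- pmin(ub, 1e6)
  ko <- r$id %in% knockouts
  lb[ko] <- 0; ub[ko] <- 0

  S <- stoichiometricMatrix(gem)
  n <- nrow(r)
  newState <- function(status, v = numeric(), obj = NA_real_)
    new("FluxState", fluxes = v, objectiveValue = obj, status = status,
        knockedOut = knockouts, zeroTolerance = zeroTolerance)

  if (any(ub < lb)) return(newState("infeasible"))

  # shift to x = v - lb >= 0:  max c'x  s.t.  S x = -S lb,  0 <= x <= ub - lb
  beq <- if (nrow(S)) as.numeric(-S %*% lb) else numeric()
  # the big-M penalty must dominate the largest bound range for phase-I; the
  # solver breaks pivot ties through the RNG, so the stream is pinned to make
  # repeated solves return the identical optimal vertex
  sol <- withSeed(20260101L, tryCatch(
    pracma::linprog(cc, A = diag(n), b = ub - lb,
                    Aeq = if (nrow(S)) S else NULL,
                    beq = if (nrow(S)) beq else NULL,
                    maximize = TRUE, maxiter = max(10000L, 100L * n),
                    bigM = max(1e6, 1e4 * max(abs(ub - lb), abs(cc)))),
    error = function(e) list(errno = -99, message = conditionMessage(e))))
  if (sol$errno != 1) {
    # big-M simplex can stall on degenerate bases; fall back to the
    # anti-cycling (Bland-rule) two-phase solver for a definitive status
    sol <- .blandLP(cc, S, beq, ub - lb)
    if (sol$status != "optimal") return(newState(sol$status))
  }

  v <- sol$x[seq_len(n)] + lb
  v[ko] <- 0
  v[abs(v) < .Machine$double.eps * 100] <- 0
  names(v) <- r$id
  newState("optimal", v = v, obj = sum(cc * v))
}

# Two-phase dense simplex with Bland's anti-cycling rule for the box-bounded
# problem  max c'x  s.t.  S x = beq,  0 <= x <= u.  Upper bounds become
# explicit slack rows, so the standard form is
#   [S 0; I I] [x; s] = [beq; u],  x, s >= 0.
# Bland's rule (smallest-index entering, smallest-basis-index leaving)
# guarantees termination; the box makes the LP never unbounded.
.blandLP <- function(cc, S, beq, u) {
  n <- length(cc)
  m1 <- if (is.null(dim(S))) 0L else nrow(S)
  A <- rbind(
    if (m1) cbind(S, matrix(0, m1, n)) else NULL,
    cbind(diag(n), diag(n)))
  b <- c(beq, u)
  obj <- c(cc, rep(0, n))
  neg <- b < 0
  A[neg, ] <- -A[neg, , drop = FALSE]
  b[neg] <- -b[neg]
  m <- nrow(A)

  # phase 1: minimize artificial infeasibility
  Ae <- cbind(A, diag(m))
  ce <- c(rep(0, 2 * n), rep(-1, m))
  basis <- 2L * n + seq_len(m)
  p1 <- .simplexBland(ce, Ae, b, basis)
  if (p1$status != "optimal" || p1$val < -1e-7)
    return(list(status = "infeasible"))
  Ae <- p1$A; b <- p1$b; basis <- p1$basis

  # drive any zero-level artificial out of the basis, dropping redundant rows
  keep <- rep(TRUE, m)
  for (i in seq_len(m)) {
    if (basis[i] <= 2 * n) next
    j <- which(abs(Ae[i, seq_len(2 * n)]) > 1e-9)[1]
    if (is.na(j)) { keep[i] <- FALSE; next }
    piv <- Ae[i, j]
    Ae[i, ] <- Ae[i, ] / piv; b[i] <- b[i] / piv
    for (k in seq_len(m)) if (k != i && Ae[k, j] != 0) {
      b[k] <- b[k] - Ae[k, j] * b[i]
      Ae[k, ] <- Ae[k, ] - Ae[k, j] * Ae[i, ]
    }
    basis[i] <- j
  }
  Ae <- Ae[keep, seq_len(2 * n), drop = FALSE]
  b <- b[keep]; basis <- basis[keep]

  p2 <- .simplexBland(obj, Ae, b, basis)
  if (p2$status != "optimal") return(list(status = p2$status))
  x <- numeric(2 * n)
  x[p2$basis] <- p2$b
  list(status = "optimal", x = x[seq_len(n)], val = p2$val)
}

# one simplex phase on a tableau already canonical w.r.t. `basis`
.simplexBland <- function(cc, A, b, basis, maxit = 200000L) {
  m <- nrow(A)
  for (it in seq_len(maxit)) {
    r <- cc - as.numeric(crossprod(cc[basis], A))
    r[basis] <- 0
    ent <- which(r > 1e-9)
    if (!length(ent))
      return(list(status = "optimal", A = A, b = b, basis = basis,
                  val = sum(cc[basis] * b)))
    j <- ent[1]                       # Bland: smallest entering index
    col <- A[, j]
    pos <- which(col > 1e-9)
    if (!length(pos)) return(list(status = "unbounded"))
    ratio <- b[pos] / col[pos]
    cand <- pos[ratio <= min(ratio) + 1e-12]
    i <- cand[which.min(basis[cand])] # Bland: smallest leaving basis index
    piv <- A[i, j]
    A[i, ] <- A[i, ] / piv; b[i] <- b[i] / piv
    hit <- which(A[, j] != 0)
    for (k in setdiff(hit, i)) {
      b[k] <- b[k] - A[k, j] * b[i]
      A[k, ] <- A[k, ] - A[k, j] * A[i, ]
    }
    b[abs(b) < 1e-12] <- 0
    basis[i] <- j
  }
  list(status = "infeasible")         # should be unreachable with Bland's rule
}
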