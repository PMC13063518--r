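#' Box-constrained strictly convex quadratic program
#'
#' Minimizes `0.5 x' Q x - q' x` subject to `lb <= x <= ub` by an exact
#' active-set method: variables pinned at a bound are fixed, the free block
#' is solved by dense linear algebra, violating free variables are clamped,
#' and pinned variables whose KKT multiplier has the wrong sign are
#' released. For a strictly convex Q with a handful of variables (the
#' activation-tracking problem is diagonal-plus-rank-one) this terminates
#' in a few iterations regardless of conditioning.
#'
#' @param Q Symmetric positive-definite matrix.
#' @param q Linear term vector.
#' @param lb,ub Bound vectors.
#' @param tol Infinity norm of the projected gradient at convergence.
#' @param max_iter Iteration cap; exceeding it is an error (diagnostics in
#'   the message).
#' @return List with `x`, `kkt` (final projected-gradient norm), `iters`.
#' @export
solve_box_qp <- function(Q, q, lb, ub, tol = 1e-10, max_iter = 500) {
  n <- length(q)
  Q <- as.matrix(Q)
  if (!all(dim(Q) == n)) stop("Q and q are inconsistent")
  if (length(lb) != n || length(ub) != n || any(ub < lb))
    stop("invalid bounds")
  if (any(diag(Q) <= 0)) stop("Q must have positive diagonal (strict convexity)")
  kkt_res <- function(x) {
    g <- drop(Q %*% x) - q
    max(abs(x - pmin(pmax(x - g, lb), ub)))
  }
  # active-set state: -1 pinned at lb, +1 pinned at ub, 0 free
  state <- integer(n)
  x <- pmin(pmax(q / diag(Q), lb), ub)
  state[x <= lb] <- -1L
  state[x >= ub] <- 1L
  for (it in seq_len(max_iter)) {
    x <- ifelse(state == -1L, lb, ifelse(state == 1L, ub, 0))
    free <- which(state == 0L)
    if (length(free) > 0) {
      rhs <- q[free] - if (length(free) < n)
        drop(Q[free, -free, drop = FALSE] %*% x[-free]) else 0
      x[free] <- solve(Q[free, free, drop = FALSE], rhs)
    }
    viol_lo <- free[x[free] < lb[free] - 1e-14]
    viol_hi <- free[x[free] > ub[free] + 1e-14]
    if (length(viol_lo) + length(viol_hi) > 0) {
      state[viol_lo] <- -1L
      state[viol_hi] <- 1L
      next
    }
    g <- drop(Q %*% x) - q
    bad_lo <- which(state == -1L & g < -tol / 2)
    bad_hi <- which(state == 1L & g > tol / 2)
    if (length(bad_lo) + length(bad_hi) > 0) {
      # release the single worst offender (anti-cycling)
      cand <- c(bad_lo, bad_hi)
      worst <- cand[which.max(abs(g[cand]))]
      state[worst] <- 0L
      next
    }
    return(list(x = x, kkt = kkt_res(x), iters = it))
  }
  stop(sprintf("box-QP did not converge: kkt %.3e after %d iterations",
               kkt_res(x), max_iter))
}

#' Tracking weights of the activation objective
#'
#' Defaults are the study values `w_c = 1` (force tracking), `w_a = 0.0025`
#' (l2 regularization of activations), `w_d = 0.00001` (damping toward the
#' previous step's activations).
#'
#' @param w_c,w_a,w_d Nonnegative weights.
#' @return A list of class `tracking_weights`.
#' @export
tracking_weights <- function(w_c = 1, w_a = 0.0025, w_d = 0.00001) {
  if (any(c(w_c, w_a, w_d) < 0)) stop("weights must be nonnegative")
  structure(list(w_c = w_c, w_a = w_a, w_d = w_d),
            class = "tracking_weights")
}

#' Solve one force-tracking step
#'
#' Minimizes the per-step activation objective
#' `0.5 w_c ||cbar - H a||^2 + 0.5 w_a a'a + 0.5 w_d ||a_prev - a||^2`
#' subject to box bounds (the squared tracking norm makes the problem the
#' standard strictly convex tracking QP). The solution is unique for
#' `w_a + w_d > 0` and is reported with its KKT residual.
#'
#' @param H Excitation-response matrix, `n_targets x n_vars` (a vector is a
#'   single row).
#' @param cbar Target vector (N).
#' @param a_prev Previous activations (warm-start/damping reference).
#' @param weights A [tracking_weights()] object.
#' @param lower,upper Bounds (default 0 and 1).
#' @return List with `a` (solution), `kkt`, `objective`.
#' @export
solve_tracking_step <- function(H, cbar, a_prev = NULL,
                                weights = tracking_weights(),
                                lower = NULL, upper = NULL) {
  if (is.null(dim(H))) H <- matrix(H, nrow = 1)
  n <- ncol(H)
  if (is.null(a_prev)) a_prev <- numeric(n)
  if (is.null(lower)) lower <- rep(0, n)
  if (is.null(upper)) upper <- rep(1, n)
  if (length(a_prev) != n) stop("a_prev has wrong length")
  w <- weights
  Q <- w$w_c * crossprod(H) + diag(w$w_a + w$w_d, n)
  q <- w$w_c * drop(crossprod(H, cbar)) + w$w_d * a_prev
  sol <- solve_box_qp(Q, q, lower, upper)
  a <- sol$x
  obj <- 0.5 * w$w_c * sum((cbar - drop(H %*% a))^2) +
    0.5 * w$w_a * sum(a^2) + 0.5 * w$w_d * sum((a_prev - a)^2)
  list(a = a, kkt = sol$kkt, objective = obj)
}

#' Impose IC ratios by combining paired muscle columns
#'
#' Reduces each left/right muscle pair to a single free activation variable
#' `u` with `a_ipsi = r u` and `a_contra = u` (the ipsilateral side defined
#' by the task side), replacing the pair's two columns of the excitation
#' response matrix by `r * col_ipsi + col_contra`. The free variable's upper
#' bound is tightened to `min(1, 1/r)` so both expanded activations stay in
#' `[0, 1]`.
#'
#' @param H Excitation-response matrix (row vector or matrix), one column
#'   per physical muscle.
#' @param pairs A list of pairs; each element is
#'   `list(ipsi = col_index, contra = col_index, ratio = r)`.
#' @return A list with `H` (reduced matrix), `upper` (bounds of the reduced
#'   variables), and `expand(u)` mapping reduced activations back to
#'   physical ones.
#' @export
impose_ic_ratios <- function(H, pairs) {
  if (is.null(dim(H))) H <- matrix(H, nrow = 1)
  n <- ncol(H)
  used <- integer(0)
  for (p in pairs) {
    if (!is.finite(p$ratio) || p$ratio <= 0)
      stop("IC ratios must be positive")
    if (any(c(p$ipsi, p$contra) %in% used) || p$ipsi == p$contra)
      stop("muscle columns may appear in one pair only")
    used <- c(used, p$ipsi, p$contra)
  }
  free <- setdiff(seq_len(n), used)
  ncol_red <- length(pairs) + length(free)
  Hr <- matrix(0, nrow(H), ncol_red)
  upper <- numeric(ncol_red)
  map <- vector("list", ncol_red)
  for (k in seq_along(pairs)) {
    p <- pairs[[k]]
    Hr[, k] <- p$ratio * H[, p$ipsi] + H[, p$contra]
    upper[k] <- min(1, 1 / p$ratio)
    map[[k]] <- list(idx = c(p$ipsi, p$contra), coef = c(p$ratio, 1))
  }
  for (k in seq_along(free)) {
    j <- length(pairs) + k
    Hr[, j] <- H[, free[k]]
    upper[j] <- 1
    map[[j]] <- list(idx = free[k], coef = 1)
  }
  expand <- function(u) {
    a <- numeric(n)
    for (j in seq_along(map))
      a[map[[j]]$idx] <- map[[j]]$coef * u[j]
    a
  }
  list(H = Hr, upper = upper, expand = expand, map = map)
}
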