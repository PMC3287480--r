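# Dense linear programming for the small reconciliation and growth LPs.
#
# The solver is a textbook two-phase primal simplex on the standard form
# min c'x, A x = b, x >= 0 with Bland's anti-cycling pivot rule, which is
# immune to the degenerate cycling these highly degenerate flux LPs provoke.
# General box bounds (negative, infinite) are handled by shifting variables
# with a finite lower bound, splitting free variables, eliminating fixed
# variables, and turning finite upper bounds into slack rows. All problems
# in this package have tens of variables, where the dense tableau is exact
# and fast.

# Two-phase tableau simplex, Bland's rule. min c'x s.t. A x = b, x >= 0.
simplex_bland <- function(cvec, A, b, tol = 1e-9) {
  m <- nrow(A); n <- ncol(A)
  flip <- b < 0
  A[flip, ] <- -A[flip, , drop = FALSE]; b[flip] <- -b[flip]

  tab <- cbind(A, diag(m), b)
  basis <- n + seq_len(m)
  ncols <- n + m

  pivot <- function(pr, pc) {
    tab[pr, ] <<- tab[pr, ] / tab[pr, pc]
    for (i in seq_len(m)) if (i != pr && abs(tab[i, pc]) > 0) {
      tab[i, ] <<- tab[i, ] - tab[i, pc] * tab[pr, ]
    }
    cost <<- cost - cost[pc] * tab[pr, ]
    basis[pr] <<- pc
  }

  run_phase <- function(active_cols) {
    repeat {
      enter <- 0L
      for (j in active_cols) {         # Bland: first improving column
        if (!(j %in% basis) && cost[j] < -tol) { enter <- j; break }
      }
      if (enter == 0L) return("optimal")
      rows <- which(tab[, enter] > tol)
      if (!length(rows)) return("unbounded")
      ratios <- tab[rows, ncols + 1] / tab[rows, enter]
      cand <- rows[ratios <= min(ratios) + tol]
      leave <- cand[which.min(basis[cand])]   # Bland: smallest basis index
      pivot(leave, enter)
    }
  }

  # phase 1: minimize sum of artificials
  c1 <- c(rep(0, n), rep(1, m))
  cost <- c(c1, 0) - colSums(tab[basis - n, , drop = FALSE])
  st <- run_phase(seq_len(n))
  z1 <- -cost[ncols + 1]
  if (z1 > 1e-7) return(list(x = NULL, value = NA_real_, status = "infeasible"))
  # pivot lingering zero-level artificials out where possible
  for (i in seq_len(m)) {
    if (basis[i] > n) {
      pc <- which(abs(tab[i, seq_len(n)]) > tol)[1]
      if (!is.na(pc)) pivot(i, pc)
    }
  }
  keep_rows <- basis <= n
  if (!all(keep_rows)) {               # redundant constraints: drop rows
    tab <- tab[keep_rows, , drop = FALSE]
    basis <- basis[keep_rows]
    m <- nrow(tab)
  }

  # phase 2
  cb <- cvec[basis]
  cost <- c(cvec, rep(0, ncols - n), 0) -
    as.vector(cb %*% tab)
  st <- run_phase(seq_len(n))
  if (st == "unbounded") return(list(x = NULL, value = NA_real_, status = "unbounded"))
  x <- numeric(n)
  inb <- basis <= n
  x[basis[inb]] <- tab[inb, ncols + 1]
  list(x = x, value = sum(cvec * x), status = "optimal")
}

# min (or max) obj'x  s.t.  A_eq x = b_eq, lower <= x <= upper.
# Returns list(x, value, status); status "optimal", "infeasible" or "unbounded".
solve_lp <- function(obj, A_eq, b_eq, lower, upper, maximize = FALSE) {
  n <- length(obj)
  stopifnot(ncol(A_eq) == n, length(lower) == n, length(upper) == n)
  if (any(lower > upper)) return(list(x = NULL, value = NA_real_, status = "infeasible"))

  # eliminate fixed variables (lower == upper): they are constants
  fixed <- lower == upper
  if (any(fixed)) {
    b_red <- as.vector(b_eq - A_eq[, fixed, drop = FALSE] %*% lower[fixed])
    if (all(fixed)) {
      feas <- all(abs(b_red) <= 1e-9)
      return(if (feas) list(x = lower, value = sum(obj * lower), status = "optimal")
             else list(x = NULL, value = NA_real_, status = "infeasible"))
    }
    sub <- solve_lp(obj[!fixed], A_eq[, !fixed, drop = FALSE], b_red,
                    lower[!fixed], upper[!fixed], maximize)
    if (sub$status != "optimal") return(sub)
    x <- numeric(n); x[fixed] <- lower[fixed]; x[!fixed] <- sub$x
    return(list(x = x, value = sum(obj * x), status = "optimal"))
  }

  split <- !is.finite(lower)              # free below -> x = xp - xn
  shift <- ifelse(split, 0, lower)
  var_of <- c(seq_len(n), which(split))
  sign_of <- c(rep(1, n), rep(-1, sum(split)))
  n_cols <- length(var_of)

  cc <- obj[var_of] * sign_of
  if (maximize) cc <- -cc
  A <- A_eq[, var_of, drop = FALSE] * rep(sign_of, each = nrow(A_eq))
  b <- as.vector(b_eq - A_eq %*% shift)

  # finite upper bounds -> slack rows  y_j (+ parts) + s = ub - shift
  ub_rows <- which(is.finite(upper))
  if (length(ub_rows)) {
    n_slack <- length(ub_rows)
    Aub <- matrix(0, n_slack, n_cols)
    for (i in seq_along(ub_rows)) {
      j <- ub_rows[i]
      Aub[i, var_of == j] <- sign_of[var_of == j]
    }
    A <- rbind(cbind(A, matrix(0, nrow(A), n_slack)),
               cbind(Aub, diag(n_slack)))
    b <- c(b, upper[ub_rows] - shift[ub_rows])
    cc <- c(cc, rep(0, n_slack))
  }

  res <- simplex_bland(cc, A, b)
  if (res$status != "optimal") return(res)
  x <- shift
  for (k in seq_len(n_cols)) x[var_of[k]] <- x[var_of[k]] + sign_of[k] * res$x[k]
  list(x = x, value = sum(obj * x), status = "optimal")
}
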