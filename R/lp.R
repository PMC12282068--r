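## Linear-programming layer.
##
## All optimization in this package reduces to LPs of the form
##     min  c'x   s.t.  A x = b,  lb <= x <= ub,
## with a few dozen variables. The solver is a dense bounded-variable
## two-phase primal simplex: nonbasic variables sit at a finite bound,
## phase I drives artificial variables to zero, phase II optimizes c.
## Degeneracy is handled by switching to Bland's rule after a run of
## degenerate pivots. Correctness is checked in the test suite via
## optimality certificates (reduced-cost signs + complementary
## slackness) and brute-force vertex enumeration on small models.

# Bound used to stand in for an infinite bound during pivoting; genuine
# unboundedness is detected by re-solving with the clamp relaxed.
.lp_big <- 1e7

#' Solve a bounded linear program
#'
#' Minimizes (or maximizes) `obj` subject to `A %*% x == rhs` and
#' `lb <= x <= ub`. This is the solver behind [fba()], [morp()],
#' [min_total_proteome()] and [fva()]; it is exported so that bound
#' or constraint experiments can be scripted directly.
#'
#' @param obj Numeric objective coefficient vector (length n).
#' @param A Dense constraint matrix (m x n).
#' @param rhs Right-hand side vector (length m).
#' @param lb,ub Variable bounds; `-Inf`/`Inf` allowed.
#' @param maximize Maximize instead of minimize.
#' @param tol Pivoting/feasibility tolerance.
#'
#' @return A list with `status` (`"optimal"`, `"infeasible"`,
#'   `"unbounded"`), `x` (primal solution, length n) and `objval`.
#' @examples
#' # max x2 subject to x1 - x2 = 0, 0 <= x1 <= 3
#' lp_solve(c(0, 1), matrix(c(1, -1), 1), 0,
#'          lb = c(0, 0), ub = c(3, Inf), maximize = TRUE)
#' @export
lp_solve <- function(obj, A, rhs, lb, ub, maximize = FALSE, tol = 1e-9) {
  stopifnot(is.matrix(A), length(obj) == ncol(A), length(rhs) == nrow(A),
            length(lb) == ncol(A), length(ub) == ncol(A))
  if (any(lb > ub + tol)) {
    return(list(status = "infeasible", x = rep(NA_real_, ncol(A)),
                objval = NA_real_))
  }
  sense <- if (maximize) -1 else 1
  res <- .simplex_bounded(sense * obj, A, rhs, lb, ub, big = .lp_big, tol = tol)
  if (res$status == "optimal" && length(res$clamped_active) > 0) {
    # solution rests on a clamp that replaced an infinite bound: relax the
    # clamp and re-solve to distinguish a finite optimum from unboundedness
    res2 <- .simplex_bounded(sense * obj, A, rhs, lb, ub,
                             big = .lp_big * 100, tol = tol)
    if (res2$status == "optimal" &&
        res2$objval < res$objval - max(1, abs(res$objval)) * 1e-6) {
      return(list(status = "unbounded", x = res2$x, objval = sense * -Inf))
    }
    res <- res2
  }
  list(status = res$status, x = res$x,
       objval = if (res$status == "optimal") sense * res$objval else NA_real_)
}

# Core routine: min c'x, A x = b, bounds clamped at +-big.
# Returns status, x, objval, and which originally-infinite bounds are active.
.simplex_bounded <- function(cc, A, b, lb, ub, big, tol) {
  m <- nrow(A); n <- ncol(A)
  inf_lb <- !is.finite(lb); inf_ub <- !is.finite(ub)
  l <- ifelse(inf_lb, -big, lb)
  u <- ifelse(inf_ub, big, ub)

  # artificial variables close the phase-I residual
  x <- ifelse(abs(l) <= abs(u), l, u)              # start at smaller-|.| bound
  r0 <- b - as.vector(A %*% x)
  sgn <- ifelse(r0 >= 0, 1, -1)
  Afull <- cbind(A, diag(sgn, m))
  l_full <- c(l, rep(0, m))
  u_full <- c(u, rep(big * 10, m))
  ntot <- n + m

  basis <- (n + 1L):ntot
  stat <- c(ifelse(abs(l) <= abs(u), 1L, 2L), rep(0L, m))  # 1 at lb, 2 at ub
  xval <- c(x, abs(r0))

  run_phase <- function(cvec, basis, stat, xval, lo, hi) {
    degen <- 0L
    for (it in seq_len(20000L)) {
      B <- Afull[, basis, drop = FALSE]
      Binv_ok <- TRUE
      xB <- tryCatch({
        nb <- setdiff(seq_len(ntot), basis)
        rhs_eff <- b - as.vector(Afull[, nb, drop = FALSE] %*% xval[nb])
        solve(B, rhs_eff)
      }, error = function(e) { Binv_ok <<- FALSE; NULL })
      if (!Binv_ok) return(list(status = "singular"))
      xval[basis] <- xB
      y <- tryCatch(solve(t(B), cvec[basis]), error = function(e) NULL)
      if (is.null(y)) return(list(status = "singular"))
      d <- cvec - as.vector(crossprod(Afull, y))   # reduced costs
      cand_lo <- which(stat == 1L & d < -tol)
      cand_hi <- which(stat == 2L & d > tol)
      cand <- c(cand_lo, cand_hi)
      if (length(cand) == 0) {
        return(list(status = "optimal", basis = basis, stat = stat,
                    xval = xval))
      }
      if (degen > 40L) {
        j <- min(cand)                              # Bland's rule
      } else {
        viol <- abs(d[cand]); j <- cand[which.max(viol)]
      }
      s <- if (stat[j] == 1L) 1 else -1             # direction of change
      w <- solve(B, Afull[, j])
      # ratio test: entering var moves by t >= 0, basics move by -s*t*w
      t_own <- hi[j] - lo[j]
      t_best <- t_own; leave <- 0L; leave_to <- 0L
      sw <- s * w
      for (k in seq_len(m)) {
        if (sw[k] > tol) {
          tk <- (xval[basis[k]] - lo[basis[k]]) / sw[k]
          if (tk < t_best - 1e-12 ||
              (tk < t_best + 1e-12 && leave > 0L && basis[k] < basis[leave])) {
            t_best <- tk; leave <- k; leave_to <- 1L
          }
        } else if (sw[k] < -tol) {
          tk <- (hi[basis[k]] - xval[basis[k]]) / (-sw[k])
          if (tk < t_best - 1e-12 ||
              (tk < t_best + 1e-12 && leave > 0L && basis[k] < basis[leave])) {
            t_best <- tk; leave <- k; leave_to <- 2L
          }
        }
      }
      if (!is.finite(t_best)) return(list(status = "unbounded"))
      t_best <- max(t_best, 0)
      degen <- if (t_best < 1e-11) degen + 1L else 0L
      xval[j] <- xval[j] + s * t_best
      xval[basis] <- xval[basis] - sw * t_best
      if (leave == 0L) {
        stat[j] <- if (stat[j] == 1L) 2L else 1L    # bound flip
      } else {
        out <- basis[leave]
        stat[out] <- leave_to
        xval[out] <- if (leave_to == 1L) lo[out] else hi[out]
        basis[leave] <- j
        stat[j] <- 0L
      }
    }
    list(status = "maxit")
  }

  # phase I: minimize sum of artificials
  c1 <- c(rep(0, n), rep(1, m))
  p1 <- run_phase(c1, basis, stat, xval, l_full, u_full)
  if (p1$status != "optimal") {
    return(list(status = if (p1$status == "unbounded") "infeasible"
                         else p1$status,
                x = rep(NA_real_, n), objval = NA_real_,
                clamped_active = integer(0)))
  }
  art_sum <- sum(p1$xval[(n + 1L):ntot])
  if (art_sum > 1e-7) {
    return(list(status = "infeasible", x = rep(NA_real_, n),
                objval = NA_real_, clamped_active = integer(0)))
  }
  # lock artificials at zero for phase II
  u_full[(n + 1L):ntot] <- 0
  p1$xval[(n + 1L):ntot] <- 0
  c2 <- c(cc, rep(0, m))
  p2 <- run_phase(c2, p1$basis, p1$stat, p1$xval, l_full, u_full)
  if (p2$status != "optimal") {
    return(list(status = p2$status, x = rep(NA_real_, n), objval = NA_real_,
                clamped_active = integer(0)))
  }
  xs <- p2$xval[seq_len(n)]
  clamped <- which((inf_lb & xs < -big * 0.99) | (inf_ub & xs > big * 0.99))
  list(status = "optimal", x = xs, objval = sum(cc * xs),
       clamped_active = clamped)
}
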