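## Flux-space sampling: hit-and-run on the polytope {v : S v = 0,
## lb <= v <= ub}. Directions are drawn isotropically inside the null
## space of S so every proposal stays on the stoichiometric subspace;
## coordinates whose FVA width is (numerically) zero are frozen, which
## doubles as the fallback for degenerate, zero-volume polytopes.

# FVA ranges plus the optimizer vertices (feasible points for warm-up)
.fva_points <- function(parts) {
  n <- length(parts$ids)
  pts <- list(); lo <- hi <- rep(NA_real_, n)
  for (j in seq_len(n)) {
    cc <- numeric(n); cc[j] <- 1
    rmin <- lp_solve(cc, parts$S, rep(0, nrow(parts$S)), parts$lb, parts$ub)
    if (rmin$status != "optimal") return(NULL)
    rmax <- lp_solve(cc, parts$S, rep(0, nrow(parts$S)), parts$lb,
                     parts$ub, maximize = TRUE)
    if (rmax$status != "optimal") return(NULL)
    lo[j] <- rmin$objval; hi[j] <- rmax$objval
    pts[[length(pts) + 1L]] <- rmin$x
    pts[[length(pts) + 1L]] <- rmax$x
  }
  list(lo = lo, hi = hi, points = do.call(rbind, pts))
}

#' Sample the feasible flux space
#'
#' Draws `n` (approximately uniform) samples from the flux polytope by a
#' hit-and-run random walk started at the mean of the flux-variability
#' vertices. Reactions with zero flux variability are held fixed. The
#' walk is deterministic for a fixed seed.
#'
#' @param model A `stoich_model` or `ec_model` (current bounds apply).
#' @param n Number of samples, > 0.
#' @param seed Integer seed; the global RNG state is restored on exit.
#' @param thinning Steps between recorded samples (default 100).
#' @param burn_in Warm-up steps; default `100 * dim` where `dim` is the
#'   dimension of the bounded null space.
#' @return A `flux_sample`: `matrix` (n x reactions, with column
#'   names), `reaction_ids`, `seed`, `n`, `thinning`.
#' @export
sample_flux_space <- function(model, n, seed = 1L, thinning = 100L,
                              burn_in = NULL) {
  if (n <= 0) abort_validation("n must be > 0")
  if (thinning < 1) abort_validation("thinning must be >= 1")
  parts <- .lp_parts(model)
  fv <- .fva_points(parts)
  if (is.null(fv)) {
    abort_infeasible("model is infeasible; nothing to sample")
  }
  nr <- length(parts$ids)
  width <- fv$hi - fv$lo
  fixed <- width < 1e-9
  x <- colMeans(fv$points)
  # effective box: FVA ranges are tighter than raw bounds and free of
  # infinities
  lb <- fv$lo; ub <- fv$hi
  if (all(fixed)) {
    warning("flux polytope has zero volume; returning the unique point")
    mat <- matrix(rep(x, n), nrow = n, byrow = TRUE,
                  dimnames = list(NULL, parts$ids))
    return(structure(list(matrix = mat, reaction_ids = parts$ids,
                          seed = as.integer(seed), n = as.integer(n),
                          thinning = as.integer(thinning)),
                     class = "flux_sample"))
  }
  Sfree <- parts$S[, !fixed, drop = FALSE]
  sv <- svd(Sfree, nu = 0, nv = ncol(Sfree))   # full V: null space included
  rank <- sum(sv$d > max(dim(Sfree)) * max(sv$d, 0) * 1e-12)
  dim_ns <- ncol(Sfree) - rank
  if (dim_ns == 0) {
    warning("flux polytope has zero volume; returning the unique point")
    mat <- matrix(rep(x, n), nrow = n, byrow = TRUE,
                  dimnames = list(NULL, parts$ids))
    return(structure(list(matrix = mat, reaction_ids = parts$ids,
                          seed = as.integer(seed), n = as.integer(n),
                          thinning = as.integer(thinning)),
                     class = "flux_sample"))
  }
  Z <- sv$v[, (rank + 1):ncol(sv$v), drop = FALSE]   # null basis
  if (is.null(burn_in)) burn_in <- 100L * dim_ns
  old <- if (exists(".Random.seed", .GlobalEnv)) {
    get(".Random.seed", .GlobalEnv)
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  xf <- x[!fixed]
  lbf <- lb[!fixed]; ubf <- ub[!fixed]
  out <- matrix(NA_real_, n, nr, dimnames = list(NULL, parts$ids))
  total <- burn_in + n * thinning
  got <- 0L
  for (step in seq_len(total)) {
    g <- stats::rnorm(dim_ns)
    d <- as.vector(Z %*% g)
    nz <- abs(d) > 1e-12
    if (any(nz)) {
      a1 <- (lbf[nz] - xf[nz]) / d[nz]
      a2 <- (ubf[nz] - xf[nz]) / d[nz]
      amin <- max(pmin(a1, a2)); amax <- min(pmax(a1, a2))
      amin <- min(amin, 0); amax <- max(amax, 0)  # x is feasible
      if (amax - amin > 1e-12) {
        xf <- xf + stats::runif(1, amin, amax) * d
        xf <- pmin(pmax(xf, lbf), ubf)
      }
    }
    if (step > burn_in && (step - burn_in) %% thinning == 0L) {
      got <- got + 1L
      xx <- x; xx[!fixed] <- xf
      out[got, ] <- xx
    }
  }
  structure(list(matrix = out, reaction_ids = parts$ids,
                 seed = as.integer(seed), n = as.integer(n),
                 thinning = as.integer(thinning)),
            class = "flux_sample")
}

#' Is a predicted flux within the sampled range?
#'
#' Flags, per reaction, whether the solution's flux lies inside the
#' [min, max] envelope of the sample.
#'
#' @param sample A `flux_sample`.
#' @param solution A `flux_solution`.
#' @param reaction_ids Reactions to test (must be present in both).
#' @param tol Envelope tolerance.
#' @return Tibble `reaction_id`, `flux`, `sample_min`, `sample_max`,
#'   `within`.
#' @export
flux_within_sampled_range <- function(sample, solution, reaction_ids,
                                      tol = 1e-9) {
  stopifnot(inherits(sample, "flux_sample"),
            inherits(solution, "flux_solution"))
  if (nrow(sample$matrix) == 0) abort_validation("sample is empty")
  miss <- setdiff(reaction_ids,
                  intersect(sample$reaction_ids, names(solution$fluxes)))
  if (length(miss)) {
    abort_validation(paste0("reaction absent from sample or solution: ",
                            miss[1]))
  }
  lo <- apply(sample$matrix[, reaction_ids, drop = FALSE], 2, min)
  hi <- apply(sample$matrix[, reaction_ids, drop = FALSE], 2, max)
  fl <- solution$fluxes[reaction_ids]
  tibble::tibble(reaction_id = reaction_ids, flux = unname(fl),
                 sample_min = unname(lo), sample_max = unname(hi),
                 within = unname(fl >= lo - tol & fl <= hi + tol))
}

#' @export
print.flux_sample <- function(x, ...) {
  cat("<flux_sample> ", x$n, " samples x ", length(x$reaction_ids),
      " reactions (seed ", x$seed, ", thinning ", x$thinning, ")\n",
      sep = "")
  invisible(x)
}
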