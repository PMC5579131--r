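#' Propagate an ensemble under linear kinetics by the matrix exponential
#'
#' Applies `expm(M * dt)` to every cell's abundance vector: the exact
#' solution of the linear first-order mass-action ODE system.
#'
#' @param x0 N x n matrix of abundances.
#' @param M a `linear_rate_matrix` or a plain n x n rate matrix.
#' @param dt non-negative time increment.
#' @return N x n matrix of propagated abundances.
#' @export
propagate_linear <- function(x0, M, dt) {
  if (inherits(M, "linear_rate_matrix")) M <- M$M
  if (dt < 0) stop("'dt' must be non-negative")
  x0 <- as.matrix(x0)
  if (ncol(x0) != nrow(M)) stop("ncol(x0) must match dim(M)")
  if (dt == 0) return(x0)
  E <- as.matrix(Matrix::expm(M * dt))
  x0 %*% t(E)
}

# mass-action propensities a(x) for a state matrix X (cells x species),
# returning cells x reactions
mass_action_rates <- function(net, X, pairs) {
  r <- length(net$rates)
  A <- matrix(rep(net$rates, each = nrow(X)), nrow(X), r)
  for (j in seq_len(r)) {
    if (pairs$i1[j] > 0L) A[, j] <- A[, j] * X[, pairs$i1[j]]
    if (pairs$i2[j] > 0L) A[, j] <- A[, j] * X[, pairs$i2[j]]
  }
  A
}

#' Deterministic mass-action trajectories
#'
#' Integrates the mass-action ODE system for every cell of an ensemble with
#' a stiff-capable solver (`deSolve::lsoda`), recording the state at the
#' requested times. Tiny negative excursions from the integrator are clipped
#' at zero and counted.
#'
#' @param net a [reaction_network()].
#' @param x0 N x n matrix of non-negative initial abundances.
#' @param times increasing recording times (the first is the initial time).
#' @param rtol,atol integration tolerances.
#' @return N x n x T array (dimnames carry species and times); attribute
#'   `clipped` counts negative values clipped to zero.
#' @export
ode_trajectories <- function(net, x0, times, rtol = 1e-8, atol = 1e-8) {
  stopifnot(inherits(net, "reaction_network"))
  x0 <- as.matrix(x0)
  n <- length(net$species)
  if (ncol(x0) != n) stop("ncol(x0) must match the species count")
  if (any(x0 < 0)) stop("initial abundances must be non-negative")
  if (any(diff(times) <= 0)) stop("'times' must be strictly increasing")
  pairs <- reactant_pairs(net)
  Sn <- t(net$net_change)            # n x r
  i1 <- pairs$i1; i2 <- pairs$i2
  has1 <- i1 > 0L; has2 <- i2 > 0L
  rates <- net$rates
  rhs <- function(t, y, parms) {
    a <- rates
    a[has1] <- a[has1] * y[i1[has1]]
    a[has2] <- a[has2] * y[i2[has2]]
    list(as.vector(Sn %*% a))
  }
  N <- nrow(x0)
  # cells are independent: integrating them separately keeps the solver's
  # numerical Jacobian at n x n instead of coupling the whole ensemble
  out <- array(NA_real_, c(N, n, length(times)),
               dimnames = list(NULL, net$species, signif(times, 8)))
  clipped <- 0L
  for (cell in seq_len(N)) {
    sol <- deSolve::lsoda(y = x0[cell, ], times = times, func = rhs,
                          parms = NULL, rtol = rtol, atol = atol)
    if (nrow(sol) < length(times))
      stop("ODE integration failed for cell ", cell)
    vals <- sol[, -1, drop = FALSE]
    neg <- vals < 0
    clipped <- clipped + sum(neg)
    vals[neg] <- 0
    out[cell, , ] <- t(vals)
  }
  if (clipped > 0)
    warning(sprintf("clipped %d negative values to zero", clipped))
  attr(out, "clipped") <- clipped
  out
}

#' Exact stochastic trajectories (Gillespie direct method)
#'
#' Simulates every cell of an ensemble with the direct stochastic simulation
#' algorithm, recording the state at the requested times (last-event hold).
#' Reproducibility is governed by `seed` (the sampler consumes R's RNG
#' stream).
#'
#' @param net a [reaction_network()].
#' @param x0 N x n matrix of non-negative integer copy numbers.
#' @param times increasing recording times (the first is the initial time).
#' @param seed integer seed.
#' @return N x n x T array.
#' @export
ssa_trajectories <- function(net, x0, times, seed = 1L) {
  stopifnot(inherits(net, "reaction_network"))
  x0 <- as.matrix(x0)
  n <- length(net$species)
  if (ncol(x0) != n) stop("ncol(x0) must match the species count")
  if (any(x0 < 0)) stop("copy numbers must be non-negative")
  if (any(x0 != round(x0))) stop("SSA requires integer copy numbers")
  if (any(diff(times) <= 0)) stop("'times' must be strictly increasing")
  pairs <- reactant_pairs(net)
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  out <- ssa_ensemble_cpp(x0, pairs$i1, pairs$i2, net$rates,
                          net$net_change, as.numeric(times))
  dimnames(out) <- list(NULL, net$species, signif(times, 8))
  out
}

#' Draw a multivariate-normal initial ensemble
#'
#' Samples N cells from a multivariate normal with the given mean abundances
#' and covariance — the standard model of extrinsic cell-to-cell variability
#' in total protein content and basal signalling — clipping negatives at
#' zero (the clip fraction is reported, with a warning above 20%) and
#' rounding to integers when the draw feeds the stochastic simulator.
#'
#' @param mean mean abundance vector.
#' @param cov covariance matrix (symmetric PSD).
#' @param n_cells number of cells.
#' @param seed integer seed.
#' @param integer round to integer copy numbers.
#' @param lognormal draw from a lognormal with matching mean and covariance
#'   of the log-scale fit instead (moment-matched per species, independent
#'   copula as in the normal case only when `cov` is diagonal).
#' @return N x n matrix; attribute `clip_fraction` reports the fraction of
#'   entries clipped at zero.
#' @export
sample_initial_conditions <- function(mean, cov, n_cells, seed = 1L,
                                      integer = FALSE, lognormal = FALSE) {
  n <- length(mean)
  cov <- as.matrix(cov)
  if (!identical(dim(cov), c(n, n))) stop("'cov' must be n x n")
  if (max(abs(cov - t(cov))) > 1e-8 * max(abs(cov), 1))
    stop("'cov' must be symmetric")
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  if (lognormal) {
    X <- sapply(seq_len(n), function(i) {
      m <- mean[i]; v <- cov[i, i]
      if (m <= 0) return(rep(0, n_cells))
      s2 <- log(1 + v / m^2)
      stats::rlnorm(n_cells, log(m) - s2 / 2, sqrt(s2))
    })
  } else {
    X <- MASS::mvrnorm(n_cells, mu = mean, Sigma = cov)
  }
  X <- matrix(X, n_cells, n)
  neg <- X < 0
  X[neg] <- 0
  if (integer) X <- round(X)
  cf <- mean(neg)
  if (cf > 0.2)
    warning(sprintf("%.1f%% of sampled abundances clipped at zero; revise the ensemble parameters",
                    100 * cf))
  colnames(X) <- names(mean)
  attr(X, "clip_fraction") <- cf
  X
}

#' Simulate trajectories from a reaction network
#'
#' `simulate()` method dispatching to [ode_trajectories()] or
#' [ssa_trajectories()]. When `x0` is missing, `nsim` cells are drawn from
#' the network's default initial ensemble.
#'
#' @param object a [reaction_network()].
#' @param nsim number of cells when `x0` is not given.
#' @param seed integer seed.
#' @param x0 optional N x n matrix of initial abundances.
#' @param times recording times.
#' @param method `"ode"` or `"ssa"`.
#' @param ... passed to the trajectory engine.
#' @return N x n x T array.
#' @export
simulate.reaction_network <- function(object, nsim = 1, seed = 1L, x0 = NULL,
                                      times = c(0, 1),
                                      method = c("ode", "ssa"), ...) {
  method <- match.arg(method)
  if (is.null(x0)) {
    if (is.null(object$init_mean))
      stop("network carries no default initial ensemble; supply 'x0'")
    x0 <- sample_initial_conditions(object$init_mean, object$init_cov, nsim,
                                    seed = seed, integer = method == "ssa")
  }
  if (method == "ode") ode_trajectories(object, x0, times, ...)
  else ssa_trajectories(object, x0, times, seed = seed + 1L, ...)
}

#' Generate a snapshot series with ground truth
#'
#' The synthetic-data front end. In `"tracked"` mode one cohort of cells is
#' propagated and recorded at every time (ground truth is the identity
#' pairing). In `"batch"` mode an independent cohort is drawn for each time
#' point — as in cytometry, where no cell is measured twice — and the ground
#' truth for each interval is obtained by forward-simulating the earlier
#' batch to the later time (for stochastic kinetics this is the same
#' realisation continued, the cell's own later state). An optional
#' measured-species projection restricts the recorded snapshots while the
#' ground truth keeps all species.
#'
#' @param network a [reaction_network()] or `linear_rate_matrix`.
#' @param n_cells cells per time point.
#' @param times increasing measurement times.
#' @param mode `"tracked"` or `"batch"`.
#' @param method `"ode"`, `"ssa"`, or `"expm"` (linear matrices only;
#'   defaults to `"expm"` for a linear matrix, `"ode"` otherwise).
#' @param record species names/indices to record in the snapshots (default
#'   all).
#' @param init optional list with `mean` and `cov` overriding the network's
#'   default initial ensemble.
#' @param seed integer seed; batch mode derives disjoint per-batch seeds.
#' @return A list with `series` (a [snapshot_series] of the recorded
#'   species), `ground_truth` (per interval: `partner_abundances`, an
#'   N x n matrix of every t1 cell's correct-partner state at t2 over all
#'   species, plus `partner_index` in tracked mode), and `x_full` (list of
#'   full-species abundance matrices per time).
#' @export
generate_snapshot_series <- function(network, n_cells, times,
                                     mode = c("tracked", "batch"),
                                     method = NULL, record = NULL,
                                     init = NULL, seed = 1L) {
  mode <- match.arg(mode)
  if (any(diff(times) <= 0)) stop("'times' must be strictly increasing")
  is_linear <- inherits(network, "linear_rate_matrix")
  if (is.null(method)) method <- if (is_linear) "expm" else "ode"
  method <- match.arg(method, c("expm", "ode", "ssa"))
  if (method == "expm" && !is_linear)
    stop("method 'expm' needs a linear_rate_matrix")
  net <- if (is_linear && method == "ssa") as_reaction_network(network)
         else network
  n <- if (is_linear) nrow(network$M) else length(network$species)
  species <- if (is_linear) paste0("x", seq_len(n)) else network$species
  if (is.null(init)) {
    if (!is_linear && !is.null(network$init_mean)) {
      init <- list(mean = network$init_mean, cov = network$init_cov)
    } else {
      # default ensemble: seeded means with 25% coefficient of variation
      old <- get_rng_state()
      set.seed(as.integer(seed) + 7L)
      mu <- stats::runif(n, 100, 1000)
      restore_rng_state(old)
      init <- list(mean = mu, cov = diag((0.25 * mu)^2, n))
    }
  }
  rec_idx <- if (is.null(record)) seq_len(n)
             else subset_indices(species, record)

  propagate <- function(x0, tt, sub_seed) {
    if (method == "expm") {
      arr <- array(NA_real_, c(nrow(x0), n, length(tt)))
      for (i in seq_along(tt))
        arr[, , i] <- propagate_linear(x0, network, tt[i] - tt[1])
      arr
    } else if (method == "ode") {
      if (length(tt) == 1L) {
        arr <- array(x0, c(nrow(x0), n, 1L))
      } else {
        ode_trajectories(net, x0, tt)
      }
    } else {
      tt2 <- if (length(tt) == 1L) c(tt, tt + 1e-9) else tt
      arr <- ssa_trajectories(net, x0, tt2, seed = sub_seed)
      arr[, , seq_along(tt), drop = FALSE]
    }
  }

  nt <- length(times)
  snap_list <- vector("list", nt)
  gt <- vector("list", max(nt - 1L, 0L))
  x_full <- vector("list", nt)

  if (mode == "tracked") {
    x0 <- sample_initial_conditions(init$mean, init$cov, n_cells,
                                    seed = seed, integer = method == "ssa")
    tt <- unique(c(times[1], times))
    arr <- propagate(x0, tt, sub_seed = seed + 100L)
    keep <- match(times, tt)
    for (i in seq_len(nt)) {
      x_full[[i]] <- arr[, , keep[i], drop = TRUE]
      if (is.null(dim(x_full[[i]])))
        x_full[[i]] <- matrix(x_full[[i]], n_cells, n)
      snap_list[[i]] <- snapshot(x_full[[i]][, rec_idx, drop = FALSE],
                                 times[i], species[rec_idx],
                                 cell_ids = as.character(seq_len(n_cells)))
    }
    for (i in seq_len(nt - 1L))
      gt[[i]] <- list(t1 = times[i], t2 = times[i + 1L],
                      partner_abundances = x_full[[i + 1L]],
                      partner_index = seq_len(n_cells))
  } else {
    for (i in seq_len(nt)) {
      bseed <- as.integer(seed) + 1000L * i
      x0 <- sample_initial_conditions(init$mean, init$cov, n_cells,
                                      seed = bseed,
                                      integer = method == "ssa")
      tt <- if (i < nt) c(times[1], times[i], times[i + 1L])
            else c(times[1], times[i])
      tt <- unique(tt)
      arr <- propagate(x0, tt, sub_seed = bseed + 1L)
      at_ti <- arr[, , match(times[i], tt), drop = TRUE]
      if (is.null(dim(at_ti))) at_ti <- matrix(at_ti, n_cells, n)
      x_full[[i]] <- at_ti
      snap_list[[i]] <- snapshot(at_ti[, rec_idx, drop = FALSE], times[i],
                                 species[rec_idx],
                                 cell_ids = as.character(seq_len(n_cells)))
      if (i < nt) {
        at_next <- arr[, , match(times[i + 1L], tt), drop = TRUE]
        if (is.null(dim(at_next))) at_next <- matrix(at_next, n_cells, n)
        gt[[i]] <- list(t1 = times[i], t2 = times[i + 1L],
                        partner_abundances = at_next, partner_index = NULL)
      }
    }
  }
  series <- snapshot_series(snap_list,
                            metadata = list(generator = list(
                              network = if (is_linear) "linear" else net$name,
                              mode = mode, method = method,
                              seed = as.integer(seed), n_cells = n_cells,
                              recorded = species[rec_idx])))
  list(series = series, ground_truth = gt, x_full = x_full,
       species = species, recorded = rec_idx)
}
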