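#' Construct a mass-action reaction network
#'
#' A network is a species list plus elementary reactions of mass-action order
#' at most 2, each given by reactant and product stoichiometries and a
#' non-negative rate constant. Conservation subsets — groups of species whose
#' plain abundance total is left unchanged by every reaction — may be
#' declared and are verified stoichiometrically at construction.
#'
#' @param species character vector of unique species names.
#' @param reactants,products r x n non-negative integer matrices of
#'   stoichiometric coefficients (rows = reactions).
#' @param rates non-negative rate constants, length r.
#' @param conservations named list of character vectors (species groups); each
#'   group must have zero net stoichiometry in every reaction.
#' @param init_mean,init_cov optional default initial-condition ensemble
#'   (mean vector and covariance matrix in copy numbers) carried with the
#'   network.
#' @param name optional network label.
#' @return An object of class `reaction_network`.
#' @export
reaction_network <- function(species, reactants, products, rates,
                             conservations = list(), init_mean = NULL,
                             init_cov = NULL, name = "network") {
  species <- as.character(species)
  n <- length(species)
  if (anyDuplicated(species)) stop("species names must be unique")
  reactants <- as.matrix(reactants); products <- as.matrix(products)
  r <- nrow(reactants)
  if (!identical(dim(reactants), dim(products)) || ncol(reactants) != n)
    stop("'reactants' and 'products' must be r x n matrices")
  if (length(rates) != r) stop("'rates' must have one entry per reaction")
  if (any(rates < 0)) stop("rate constants must be non-negative")
  if (any(reactants < 0) || any(products < 0))
    stop("stoichiometries must be non-negative")
  if (any(rowSums(reactants) > 2))
    stop("mass-action order is capped at 2 (at most two reactant molecules)")
  net_change <- products - reactants
  for (nm in names(conservations)) {
    grp <- conservations[[nm]]
    idx <- match(grp, species)
    if (anyNA(idx)) stop("conservation group '", nm, "' names unknown species")
    tot <- rowSums(net_change[, idx, drop = FALSE])
    if (any(tot != 0))
      stop("conservation group '", nm, "' is violated by reaction(s) ",
           paste(which(tot != 0), collapse = ", "))
  }
  colnames(reactants) <- colnames(products) <- species
  structure(list(species = species, reactants = reactants,
                 products = products, rates = as.numeric(rates),
                 net_change = net_change, conservations = conservations,
                 init_mean = init_mean, init_cov = init_cov, name = name),
            class = "reaction_network")
}

#' @export
print.reaction_network <- function(x, ...) {
  cat(sprintf("<reaction_network> '%s': %d species, %d reactions, %d declared conservation group(s)\n",
              x$name, length(x$species), nrow(x$reactants),
              length(x$conservations)))
  invisible(x)
}

# reactant index pairs for fast mass-action propensities: i1/i2 are species
# indices (0 = absent); a reaction with reactants {A} has i1=A, i2=0.
reactant_pairs <- function(net) {
  r <- nrow(net$reactants)
  i1 <- integer(r); i2 <- integer(r)
  for (j in seq_len(r)) {
    sp <- rep(seq_along(net$species), net$reactants[j, ])
    i1[j] <- if (length(sp) >= 1L) sp[1L] else 0L
    i2[j] <- if (length(sp) >= 2L) sp[2L] else 0L
  }
  list(i1 = i1, i2 = i2)
}

#' Generate a random linear first-order rate matrix
#'
#' Builds the rate matrix M of a linear first-order reaction system: the
#' off-diagonal entry `M[i, j] >= 0` is the rate of the conversion j -> i.
#' Off-diagonal rates are drawn uniformly on a seeded random sparsity
#' pattern. With `conservative = TRUE` each diagonal entry is set to minus
#' its column's off-diagonal sum, so every column sums to zero and the total
#' abundance of all species is conserved in every cell; otherwise a random
#' first-order degradation is added on the diagonal.
#'
#' @param n number of species (>= 2).
#' @param density fraction of ordered species pairs connected by a reaction
#'   (0 < density <= 1).
#' @param conservative whether columns must sum to zero.
#' @param seed integer seed.
#' @param rate_range range from which off-diagonal rates are drawn
#'   (units: reciprocal model time).
#' @return An object of class `linear_rate_matrix` with fields `M`,
#'   `conservative`, `seed`.
#' @export
make_linear_network <- function(n, density = 0.3, conservative = TRUE,
                                seed = 1L, rate_range = c(0.02, 0.2)) {
  n <- as.integer(n)
  if (is.na(n) || n < 2L) stop("'n' must be an integer >= 2")
  if (!(density > 0 && density <= 1)) stop("'density' must be in (0, 1]")
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  M <- matrix(0, n, n)
  off <- which(row(M) != col(M))
  # guarantee a connected conversion cycle so no species is isolated
  cyc <- cbind(c(2:n, 1L), 1:n)
  pick <- off[stats::runif(length(off)) < density]
  sel <- union(pick, (cyc[, 2] - 1L) * n + cyc[, 1])
  M[sel] <- stats::runif(length(sel), rate_range[1], rate_range[2])
  diag(M) <- 0
  if (conservative) {
    diag(M) <- -colSums(M)
  } else {
    diag(M) <- -colSums(M) - stats::runif(n, rate_range[1], rate_range[2])
  }
  structure(list(M = M, conservative = conservative, seed = as.integer(seed)),
            class = "linear_rate_matrix")
}

#' @export
print.linear_rate_matrix <- function(x, ...) {
  cat(sprintf("<linear_rate_matrix> %d species, %s, %d reactions\n",
              nrow(x$M), if (x$conservative) "conservative (zero column sums)"
              else "with degradation",
              sum(x$M > 0)))
  invisible(x)
}

#' Convert a linear rate matrix to an elementary reaction network
#'
#' Each positive off-diagonal `M[i, j]` becomes the first-order conversion
#' j -> i; any residual diagonal loss beyond the conversions becomes a
#' degradation reaction. For a conservative matrix the all-species group is
#' declared conserved.
#'
#' @param x a `linear_rate_matrix`.
#' @param species optional species names.
#' @return A [reaction_network()].
#' @export
as_reaction_network <- function(x, species = NULL) {
  stopifnot(inherits(x, "linear_rate_matrix"))
  M <- x$M
  n <- nrow(M)
  if (is.null(species)) species <- paste0("x", seq_len(n))
  rx <- list(); k <- 0L
  add <- function(re, pr, rate) {
    k <<- k + 1L
    rx[[k]] <<- list(re = re, pr = pr, rate = rate)
  }
  for (j in seq_len(n)) for (i in seq_len(n)) {
    if (i != j && M[i, j] > 0) add(j, i, M[i, j])
  }
  loss <- -diag(M) - colSums(M * (row(M) != col(M)))
  for (j in seq_len(n)) if (loss[j] > 1e-12) add(j, 0L, loss[j])
  r <- length(rx)
  Re <- matrix(0L, r, n); Pr <- matrix(0L, r, n)
  rates <- numeric(r)
  for (q in seq_len(r)) {
    Re[q, rx[[q]]$re] <- 1L
    if (rx[[q]]$pr > 0L) Pr[q, rx[[q]]$pr] <- 1L
    rates[q] <- rx[[q]]$rate
  }
  cons <- if (x$conservative) list(total = species) else list()
  reaction_network(species, Re, Pr, rates, conservations = cons,
                   name = "linear")
}

# Ras-activation model species and reactions. Free parameters live in one
# list so presets differ only in rates/initial abundances.
ras_species <- c("RasGDP", "RasGTP", "SOS", "SOS-RasGDP", "SOS-RasGTP",
                 "SOScat-RasGDP", "RasGRP1", "DAG", "RasGRP1-DAG",
                 "RasGRP1-DAG-RasGDP", "RasGAP", "RasGAP-RasGTP",
                 "DGK", "DGK-DAG")

ras_reactions <- function(p) {
  # each row: reactants, products (by species name), rate
  list(
    list(c("SOS", "RasGDP"),          "SOS-RasGDP",                 p$a1f),
    list("SOS-RasGDP",                c("SOS", "RasGDP"),           p$a1r),
    list(c("SOS", "RasGTP"),          "SOS-RasGTP",                 p$a2f),
    list("SOS-RasGTP",                c("SOS", "RasGTP"),           p$a2r),
    list(c("SOS", "RasGDP"),          "SOScat-RasGDP",              p$c1f),
    list("SOScat-RasGDP",             c("SOS", "RasGDP"),           p$c1r),
    list("SOScat-RasGDP",             c("SOS", "RasGTP"),           p$kcat0),
    list(c("SOS-RasGDP", "RasGDP"),   c("SOS-RasGDP", "RasGTP"),    p$kcatD),
    list(c("SOS-RasGTP", "RasGDP"),   c("SOS-RasGTP", "RasGTP"),    p$kcatT),
    list(c("RasGRP1", "DAG"),         "RasGRP1-DAG",                p$g1f),
    list("RasGRP1-DAG",               c("RasGRP1", "DAG"),          p$g1r),
    list(c("RasGRP1-DAG", "RasGDP"),  "RasGRP1-DAG-RasGDP",         p$g2f),
    list("RasGRP1-DAG-RasGDP",        c("RasGRP1-DAG", "RasGDP"),   p$g2r),
    list("RasGRP1-DAG-RasGDP",        c("RasGRP1-DAG", "RasGTP"),   p$gcat),
    list(c("RasGAP", "RasGTP"),       "RasGAP-RasGTP",              p$p1f),
    list("RasGAP-RasGTP",             c("RasGAP", "RasGTP"),        p$p1r),
    list("RasGAP-RasGTP",             c("RasGAP", "RasGDP"),        p$pcat),
    list(c("DGK", "DAG"),             "DGK-DAG",                    p$d1f),
    list("DGK-DAG",                   c("DGK", "DAG"),              p$d1r))
}

# Binding/unbinding arms are an order of magnitude slower than catalysis, so
# enzyme loading after stimulus onset unfolds over ~100 s and the bistable
# commitment (driven by the accumulating RasGTP-loaded SOS) over hundreds of
# seconds; RasGAP turnover is strongly saturating (Km ~ 11 copies), the
# zero-order ultrasensitivity that carries the bistability.
ras_params <- function(preset) {
  base <- list(
    a1f = 2e-5, a1r = 0.02,     # SOS allosteric site, RasGDP
    a2f = 6e-5, a2r = 6e-3,     # SOS allosteric site, RasGTP (tighter)
    c1f = 1e-5, c1r = 0.1,      # free-SOS catalytic site
    kcat0 = 0.01,               # basal SOS catalysis
    kcatD = 5e-4,               # allosteric-RasGDP SOS catalysis (per RasGDP)
    kcatT = 5e-3,               # allosteric-RasGTP SOS catalysis: feedback
    g1f = 1e-5, g1r = 0.01,     # RasGRP1 + DAG
    g2f = 2e-5, g2r = 0.05, gcat = 0.1,
    p1f = 0.05, p1r = 0.05, pcat = 0.5,  # RasGAP: strongly saturating (Km ~ 11)
    d1f = 2e-5, d1r = 5e-3)
  if (preset == "monostable") {
    base$kcatT <- 1.5e-3         # weak feedback: single steady state
  }
  base
}

ras_init <- function(preset) {
  mean <- c(RasGDP = 580, RasGTP = 10, SOS = 100, `SOS-RasGDP` = 0,
            `SOS-RasGTP` = 0, `SOScat-RasGDP` = 0, RasGRP1 = 120, DAG = 250,
            `RasGRP1-DAG` = 0, `RasGRP1-DAG-RasGDP` = 0, RasGAP = 120,
            `RasGAP-RasGTP` = 0, DGK = 60, `DGK-DAG` = 0)
  cv <- 0.22
  sd <- cv * mean
  list(mean = mean, cov = diag(sd^2, length(mean)))
}

#' Build the Ras-activation signalling network
#'
#' A 14-species mass-action model of Ras activation in T cells: Ras cycles
#' between RasGDP and RasGTP under two activating enzymes, SOS and RasGRP1
#' (the latter recruited by DAG), and the deactivating enzyme RasGAP. SOS
#' carries an allosteric Ras-binding site; RasGTP bound there confers a much
#' higher catalytic rate than RasGDP, a positive feedback that makes the
#' deterministic kinetics bistable in RasGTP for the `"bistable"` preset
#' (verified at build time by relaxing the mean-cell ODE from low- and
#' high-RasGTP initialisations). A DAG kinase arm sequesters DAG. The total
#' Ras content and the RasGRP1 group {RasGRP1, RasGRP1-DAG,
#' RasGRP1-DAG-RasGDP} are exactly conserved, among other groups, and are
#' declared on the network.
#'
#' @param preset `"bistable"` (default) or `"monostable"`.
#' @param check run the stability self-check (ODE relaxation from two
#'   initialisations) at build time.
#' @return A [reaction_network()] carrying a default multivariate-normal
#'   initial ensemble (`init_mean`, `init_cov`).
#' @export
build_ras_network <- function(preset = c("bistable", "monostable"),
                              check = TRUE) {
  preset <- match.arg(preset)
  p <- ras_params(preset)
  rx <- ras_reactions(p)
  n <- length(ras_species); r <- length(rx)
  Re <- matrix(0L, r, n, dimnames = list(NULL, ras_species))
  Pr <- matrix(0L, r, n, dimnames = list(NULL, ras_species))
  rates <- numeric(r)
  for (j in seq_len(r)) {
    for (s in rx[[j]][[1]]) Re[j, s] <- Re[j, s] + 1L
    for (s in rx[[j]][[2]]) Pr[j, s] <- Pr[j, s] + 1L
    rates[j] <- rx[[j]][[3]]
  }
  cons <- list(
    ras_total = c("RasGDP", "RasGTP", "SOS-RasGDP", "SOS-RasGTP",
                  "SOScat-RasGDP", "RasGRP1-DAG-RasGDP", "RasGAP-RasGTP"),
    rasgrp1 = c("RasGRP1", "RasGRP1-DAG", "RasGRP1-DAG-RasGDP"),
    sos_total = c("SOS", "SOS-RasGDP", "SOS-RasGTP", "SOScat-RasGDP"),
    rasgap = c("RasGAP", "RasGAP-RasGTP"),
    dgk = c("DGK", "DGK-DAG"),
    dag_total = c("DAG", "RasGRP1-DAG", "RasGRP1-DAG-RasGDP", "DGK-DAG"))
  init <- ras_init(preset)
  net <- reaction_network(ras_species, Re, Pr, rates, conservations = cons,
                          init_mean = init$mean, init_cov = init$cov,
                          name = paste0("ras_", preset))
  if (check) {
    fp <- ras_fixed_points(net)
    if (preset == "bistable" && !fp$bistable)
      stop("bistable preset failed its stability self-check: ",
           sprintf("RasGTP fixed points %.1f / %.1f", fp$low, fp$high))
    if (preset == "monostable" && fp$bistable)
      stop("monostable preset failed its stability self-check")
    attr(net, "fixed_points") <- fp
  }
  net
}

# Relax the mean-cell deterministic kinetics from a low-RasGTP and a
# high-RasGTP initialisation; distinct stable RasGTP levels => bistable.
# The high-branch start preloads the SOS allosteric site with RasGTP: the
# high state lives on the loaded-enzyme manifold and is not reachable from
# an all-free state before the GAP arm removes the excess RasGTP.
ras_fixed_points <- function(net, t_end = 20000, tol = 0.05) {
  x_low <- net$init_mean
  x_high <- net$init_mean
  iT <- match("RasGTP", net$species); iD <- match("RasGDP", net$species)
  iS <- match("SOS", net$species); iSaT <- match("SOS-RasGTP", net$species)
  x_high[iT] <- x_low[iT] + 0.6 * x_low[iD]
  x_high[iD] <- 0.4 * x_low[iD]
  x_high[iSaT] <- 0.7 * x_low[iS]
  x_high[iS] <- 0.3 * x_low[iS]
  run <- function(x0) {
    tr <- ode_trajectories(net, matrix(x0, 1), times = c(0, t_end, 2 * t_end))
    c(mid = tr[1, iT, 2], end = tr[1, iT, 3])
  }
  lo <- run(x_low); hi <- run(x_high)
  settled <- abs(lo["end"] - lo["mid"]) < tol * max(lo["end"], 1) &&
    abs(hi["end"] - hi["mid"]) < tol * max(hi["end"], 1)
  list(low = unname(lo["end"]), high = unname(hi["end"]),
       settled = settled,
       bistable = settled &&
         abs(hi["end"] - lo["end"]) > 0.25 * max(hi["end"], lo["end"]))
}

#' Read a reaction network from a YAML description
#'
#' The file lists `species` (names) and `reactions`, each reaction a mapping
#' with `reactants` and `products` (species-name lists, repeats for
#' stoichiometry 2) and `rate`. Optional `conservations` (named groups) are
#' verified at construction; optional `init_mean`/`init_sd` define the
#' default initial ensemble.
#'
#' @param path YAML file path.
#' @return A [reaction_network()].
#' @export
read_network_yaml <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  y <- yaml::read_yaml(path)
  species <- as.character(y$species)
  n <- length(species)
  r <- length(y$reactions)
  Re <- matrix(0L, r, n); Pr <- matrix(0L, r, n)
  rates <- numeric(r)
  fill <- function(M, j, names) {
    for (s in names) {
      i <- match(s, species)
      if (is.na(i)) stop("reaction ", j, " names unknown species '", s, "'")
      M[j, i] <- M[j, i] + 1L
    }
    M
  }
  for (j in seq_len(r)) {
    rx <- y$reactions[[j]]
    Re <- fill(Re, j, as.character(rx$reactants))
    Pr <- fill(Pr, j, as.character(rx$products))
    rates[j] <- as.numeric(rx$rate)
  }
  cons <- lapply(y$conservations, as.character)
  im <- if (!is.null(y$init_mean)) stats::setNames(as.numeric(y$init_mean),
                                                   species) else NULL
  ic <- if (!is.null(y$init_sd)) diag(as.numeric(y$init_sd)^2, n) else NULL
  reaction_network(species, Re, Pr, rates, conservations = cons %||% list(),
                   init_mean = im, init_cov = ic,
                   name = y$name %||% basename(path))
}
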