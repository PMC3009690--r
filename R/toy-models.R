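# ODE network models for benchmark time courses and the synthetic-mixture
# generator used to test the factorization against known ground truth.

#' Sigmoidal Hill interaction
#'
#' Production rate contributed by a regulator at concentration `x`:
#' activation `beta * x^h / (K^h + x^h)`, inhibition
#' `beta * K^h / (K^h + x^h)`.
#'
#' @param x regulator level, nonnegative.
#' @param sign `"+"` (activation) or `"-"` (inhibition).
#' @param beta maximal rate (gain), `beta >= 0`.
#' @param K half-saturation threshold, `K > 0`.
#' @param h Hill coefficient, `h >= 1`.
#' @return nonnegative production rate.
#' @export
hill_interaction <- function(x, sign = c("+", "-"), beta = 1, K = 1, h = 2) {
  sign <- match.arg(sign)
  if (any(x < 0)) stop("regulator level must be nonnegative")
  stopifnot(K > 0, h >= 1, beta >= 0)
  xh <- x^h
  if (sign == "+") beta * xh / (K^h + xh) else beta * K^h / (K^h + xh)
}

#' Construct an ODE network model
#'
#' Each node obeys `dx_i/dt = -gamma_i * x_i + sum_j f_ji(x_j) + u_i(t)`,
#' where the sum runs over regulators j of i, f_ji is a sigmoidal Hill
#' term ([hill_interaction()]) and u_i is an optional exogenous input.
#'
#' @param nodes character vector of node names.
#' @param edges data.frame with columns `from`, `to`, `sign` ("+"/"-") and
#'   optionally `beta`, `K`, `h` (defaults 1, 1, 2).
#' @param gamma per-node degradation rates (recycled), all > 0.
#' @param inputs named list of functions of time giving exogenous
#'   production per node; missing nodes get zero input.
#' @return object of class `ode_network_model`.
#' @export
ode_network_model <- function(nodes, edges, gamma = 1, inputs = list()) {
  nodes <- as.character(nodes)
  stopifnot(all(c("from", "to", "sign") %in% names(edges)))
  if (!all(edges$from %in% nodes) || !all(edges$to %in% nodes)) {
    stop("edge endpoints must be model nodes")
  }
  if (!all(edges$sign %in% c("+", "-"))) stop("edge sign must be '+' or '-'")
  if (is.null(edges$beta)) edges$beta <- rep(1, nrow(edges))
  if (is.null(edges$K)) edges$K <- rep(1, nrow(edges))
  if (is.null(edges$h)) edges$h <- rep(2, nrow(edges))
  gamma <- rep_len(gamma, length(nodes))
  if (any(gamma <= 0)) stop("degradation rates must be positive")
  if (any(edges$K <= 0) || any(edges$h < 1)) {
    stop("Hill parameters must satisfy K > 0, h >= 1")
  }
  extra <- setdiff(names(inputs), nodes)
  if (length(extra) > 0L) stop("inputs for unknown nodes: ",
                               paste(extra, collapse = ", "))
  structure(list(nodes = nodes, edges = edges,
                 gamma = stats::setNames(gamma, nodes), inputs = inputs),
            class = "ode_network_model")
}

#' Simulate an ODE network model
#'
#' Integrates the model with a stiff-safe solver; the maximum step size is
#' bounded so that discontinuous (step) inputs are not skipped.
#'
#' @param model an `ode_network_model`.
#' @param times strictly increasing time grid.
#' @param x0 nonnegative initial state (recycled over nodes).
#' @param rtol,atol solver tolerances.
#' @param hmax maximum internal step; default half the smallest grid
#'   spacing.
#' @return object of class `trajectory`: list with `time` and `state`
#'   (length(times) x nodes matrix).
#' @export
simulate_ode <- function(model, times, x0 = 0, rtol = 1e-8, atol = 1e-10,
                         hmax = NULL) {
  stopifnot(inherits(model, "ode_network_model"))
  if (any(diff(times) <= 0)) stop("time grid must be strictly increasing")
  x0 <- rep_len(x0, length(model$nodes))
  if (any(x0 < 0)) stop("initial state must be nonnegative")
  names(x0) <- model$nodes
  if (is.null(hmax)) hmax <- min(diff(times)) / 2
  e <- model$edges
  from_i <- match(e$from, model$nodes)
  to_i <- match(e$to, model$nodes)
  deriv <- function(t, x, parms) {
    x <- pmax(x, 0)
    dx <- -model$gamma * x
    if (nrow(e) > 0L) {
      xf <- x[from_i]
      f <- ifelse(e$sign == "+",
                  e$beta * xf^e$h / (e$K^e$h + xf^e$h),
                  e$beta * e$K^e$h / (e$K^e$h + xf^e$h))
      acc <- numeric(length(x))
      for (k in seq_along(f)) acc[to_i[k]] <- acc[to_i[k]] + f[k]
      dx <- dx + acc
    }
    for (nm in names(model$inputs)) {
      dx[[nm]] <- dx[[nm]] + model$inputs[[nm]](t)
    }
    list(dx)
  }
  sol <- deSolve::ode(y = x0, times = times, func = deriv, parms = NULL,
                      method = "lsoda", rtol = rtol, atol = atol, hmax = hmax)
  if (!all(is.finite(sol))) stop("ODE integration failed: non-finite states")
  state <- unname(as.matrix(sol[, -1L, drop = FALSE]))
  colnames(state) <- model$nodes
  structure(list(time = times, state = pmax(state, 0)), class = "trajectory")
}

#' Bifan benchmark model
#'
#' A four-node bifan motif driven by two switched inputs, plus an
#' incoherent feed-forward readout (six observed genes in total). Input
#' gene g1 is produced until the switch time (default 10), when production
#' moves to g2. Target g3 is activated by g1, so it peaks at the switch;
#' target g4 carries the crossed inhibitions from both inputs and is
#' active early because its inhibitor g2 is still off. The readout genes
#' form an incoherent feed-forward loop from g3 (g3 activates g5, g5
#' activates g6, g3 inhibits g6), the most common readout motif in real
#' regulatory networks; its odd cycle keeps the undirected skeleton
#' non-bipartite, so the delayed-correlation spectrum is not forced into
#' symmetric +/- eigenvalue pairs and a small number of sources dominates,
#' as in the published illustration of this system.
#'
#' @param t_switch time at which production switches from g1 to g2.
#' @param t_end end of the sampling window.
#' @param n_points number of evenly spaced sample times (default 11).
#' @return list with `model` (an `ode_network_model`), `times` (sampling
#'   grid), and `graph` (the signed topology as a [regulatory_graph()],
#'   the prior handed to the factorization).
#' @export
bifan_fixture <- function(t_switch = 10, t_end = 20, n_points = 11L) {
  nodes <- paste0("g", 1:6)
  edges <- data.frame(
    from = c("g1", "g2", "g2", "g1", "g3", "g5", "g3"),
    to   = c("g3", "g3", "g4", "g4", "g5", "g6", "g6"),
    sign = c("+",  "-",  "-",  "-",  "+",  "+",  "-"),
    stringsAsFactors = FALSE)
  inputs <- list(
    g1 = function(t) if (t <= t_switch) 1 else 0,
    g2 = function(t) if (t <= t_switch) 0 else 1)
  model <- ode_network_model(nodes, edges, gamma = 1, inputs = inputs)
  graph <- regulatory_graph(data.frame(
    source = edges$from, target = edges$to,
    weight = ifelse(edges$sign == "+", 1, -1), stringsAsFactors = FALSE))
  list(model = model, times = seq(0, t_end, length.out = n_points),
       graph = graph)
}

#' Funnel benchmark model
#'
#' Three input genes converge on a single hub that feeds a two-step
#' cascade (six genes). Expression is evaluated under three input
#' conditions, one input active per condition, giving three condition
#' vectors.
#'
#' @param t_end simulation horizon per condition (quasi-steady state).
#' @return list with `model`, `graph`, `conditions` (3 x 6 matrix of
#'   end-point expression, rows = conditions), and `times` (the grid used).
#' @export
funnel_fixture <- function(t_end = 30) {
  nodes <- paste0("g", 1:6)
  edges <- data.frame(
    from = c("g1", "g2", "g3", "g4", "g5"),
    to   = c("g4", "g4", "g4", "g5", "g6"),
    sign = "+", stringsAsFactors = FALSE)
  graph <- regulatory_graph(data.frame(
    source = edges$from, target = edges$to, weight = 1,
    stringsAsFactors = FALSE))
  times <- seq(0, t_end, by = 1)
  conditions <- matrix(0, 3L, length(nodes),
                       dimnames = list(paste0("cond", 1:3), nodes))
  models <- vector("list", 3L)
  for (k in 1:3) {
    inputs <- stats::setNames(list(function(t) 1), nodes[k])
    model <- ode_network_model(nodes, edges, gamma = 1, inputs = inputs)
    traj <- simulate_ode(model, times)
    conditions[k, ] <- traj$state[nrow(traj$state), ]
    models[[k]] <- model
  }
  list(model = models[[1L]], models = models, graph = graph,
       conditions = conditions, times = times)
}

#' Generate a synthetic mixture with known factorization
#'
#' Realizes the model `X = A %*% S + noise` under the separation condition:
#' the rows of S are unit-variance, zero-mean patterns whose symmetrized
#' graph-delayed cross-correlations (for the given W and tau) vanish
#' off-diagonal. S is built by whitening random data and rotating it into
#' the eigenbasis of its realized delayed correlation; A has orthonormal
#' columns.
#'
#' @param m observations, `m >= n`.
#' @param n sources.
#' @param l genes.
#' @param W weight matrix (l x l), must be nonzero.
#' @param noise_sd standard deviation of i.i.d. Gaussian noise added to X.
#' @param tau shift under which sources decorrelate.
#' @param seed integer seed fixing all randomness.
#' @param min_gap minimal relative eigenvalue gap required for an
#'   identifiable ground truth; the generator redraws a few times and then
#'   errors.
#' @return list with `X` (m x l), `A` (m x n), `S` (n x l), `eigenvalues`
#'   (delayed-correlation eigenvalues of S).
#' @export
synthetic_mixture <- function(m, n, l, W, noise_sd = 0, tau = 1L,
                              seed = 1L, min_gap = 1e-4) {
  stopifnot(n <= m, l > n)
  if (max(abs(W)) == 0) {
    stop("degenerate (all-zero) W cannot induce distinct delayed eigenvalues")
  }
  withr::local_seed(as.integer(seed))
  for (attempt in 1:25) {
    R0 <- matrix(stats::rnorm(n * l), n, l)
    R0 <- center_rows(R0)$x
    wh <- whiten(R0)
    if (length(wh$retained) < n) next
    Z0 <- wh$z
    Ct <- symmetrize(graph_delayed_correlation(Z0, W, tau))
    eg <- eigen(unclass(Ct), symmetric = TRUE)
    lam <- eg$values
    gap <- if (n > 1L) min(abs(diff(lam))) / max(abs(lam)) else 1
    if (gap < min_gap) next
    S <- t(eg$vectors) %*% Z0
    A <- qr.Q(qr(matrix(stats::rnorm(m * n), m, n)))
    X <- A %*% S
    if (noise_sd > 0) X <- X + matrix(stats::rnorm(m * l, sd = noise_sd), m, l)
    colnames(X) <- colnames(S) <- paste0("g", seq_len(l))
    return(list(X = X, A = A, S = S, eigenvalues = lam))
  }
  stop("could not realize a ground truth with distinct delayed eigenvalues; ",
       "W may carry too little information")
}

#' Random sparse weight matrix for simulations
#'
#' Draws a directed graph over `l` genes with the given edge density and
#' i.i.d. signed weights; used to exercise the factorization and the
#' robustness protocol on data of known structure.
#'
#' @param l number of genes.
#' @param density expected fraction of the l^2 possible edges.
#' @param seed integer seed.
#' @return list with `graph` (a `regulatory_graph`) and `W` (sparse l x l).
#' @export
random_network <- function(l, density = 0.05, seed = 1L) {
  withr::local_seed(as.integer(seed))
  n_e <- max(2L, round(density * l * l))
  cells <- sample.int(l * l, n_e)
  i <- ((cells - 1L) %% l) + 1L
  j <- ((cells - 1L) %/% l) + 1L
  w <- sample(c(-1, 1), n_e, replace = TRUE) * stats::runif(n_e, 0.5, 1.5)
  genes <- paste0("g", seq_len(l))
  graph <- regulatory_graph(data.frame(source = genes[i], target = genes[j],
                                       weight = w, stringsAsFactors = FALSE))
  list(graph = graph, W = to_weight_matrix(graph, genes))
}
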