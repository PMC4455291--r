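#' Adaptive glomerular network
#'
#' The pre-processor is a network of L glomerular units, each comprising one
#' mitral cell (MC) and one periglomerular (PG) cell, driven by N sensor
#' channels. Sensor j excites branch j of MC i through weight `c[i, j]`
#' (nonzero only if sensor j belongs to class i — the convergence rule of
#' olfactory receptor neurons onto "their" glomerulus), and sensor k excites
#' subcompartment k of PG cell i through weight `d[i, k]` (PG cells receive
#' input from all sensors). Each PG subcompartment potential can inhibit each
#' MC branch multiplicatively through fixed coefficients `f[i, j, k]`.
#'
#' Forward pass for an input vector r (normalised responses in `[0, 1]`):
#' \deqn{p_{ik} = d_{ik} r_k}
#' \deqn{m_{ij} = c_{ij} r_j \prod_k (1 - f_{ijk} p_{ik})}
#' \deqn{m_i = \sum_j m_{ij}}
#'
#' The synaptic weights adapt on-line by a local, nonlinear Hebbian rule driven
#' by the branch potentials (not the cell outputs): a saturating growth term
#' plus a quadratic decay,
#' \deqn{\Delta c_{ij} = \gamma_a m_{ij} (1 - c_{ij}) - \gamma_b c_{ij}^2}
#' \deqn{\Delta d_{ik} = \delta_b p_{ik} (1 - d_{ik}) - \delta_a d_{ik}^2}
#' with rate constants \eqn{\gamma_a = 5 \cdot 10^{-0.7}} (MC growth),
#' \eqn{\gamma_b = 10^{-0.7}} (MC decay), \eqn{\delta_a = 10^{-0.6}} (PG
#' decay), \eqn{\delta_b = 5 \cdot 10^{-0.6}} (PG growth): for both weight
#' families the growth rate is five times the decay rate, so that under
#' sustained drive both kinds of weights settle near the same equilibrium law
#' \eqn{w^* = 5x/(1+5x)} (x the local drive) while the PG weights adapt about
#' twice as fast. Keeping the PG equilibria of the same order as the MC
#' equilibria is what keeps the feed-forward inhibition effective — with the
#' growth/decay roles reversed the PG weights would collapse to about 0.1 and
#' the inhibitory pathway would be inert. The quadratic decay makes a deprived
#' weight fall first rapidly, then ever more slowly, and lets small weights
#' persist far longer than a linear decay would — which is what allows rapid
#' recovery after a transient sensor fault. Weights are clipped to `[0, 1]`
#' after each update; `f` does not adapt.
#'
#' @name glomerular-network
NULL

#' Default learning rates
#' @return named numeric vector (gamma_a, gamma_b, delta_a, delta_b)
#' @export
default_learning_rates <- function() {
  c(gamma_a = 5 * 10^-0.7, gamma_b = 10^-0.7,
    delta_a = 10^-0.6, delta_b = 5 * 10^-0.6)
}

#' Class mask with consecutive blocks
#'
#' @param L number of glomerular units / sensor classes
#' @param N number of sensor channels; must be a multiple of L
#' @return L x N binary matrix, 1 iff the channel belongs to the class
#' @export
block_class_mask <- function(L = 4L, N = 16L) {
  if (N %% L != 0) stop("'N' must be a multiple of 'L' for a block mask")
  cls <- rep(seq_len(L), each = N %/% L)
  outer(seq_len(L), cls, `==`) * 1
}

#' Initialise a glomerular network
#'
#' Excitatory weights `c` are Uniform(0,1) on within-class entries and exactly
#' 0 elsewhere; PG weights `d` are Uniform(0,1) everywhere; inhibitory
#' coefficients `f` are Uniform(0, 0.1) times an independent Bernoulli
#' existence mask with density `f_density`, and are forced to 0 wherever the
#' target MC branch does not exist (masked-out `(i, j)`).
#'
#' @param L number of glomerular units
#' @param N number of sensor channels
#' @param class_mask L x N binary matrix; each channel in exactly one class.
#'   Default: consecutive blocks of N/L channels.
#' @param f_density probability that a given PG->MC inhibitory synapse exists
#' @param learning_rates named vector as [default_learning_rates()]
#' @param seed integer seed; identical seeds give identical networks
#' @return an object of class `glom_network` with elements `L`, `N`,
#'   `class_mask`, `c`, `d`, `f` (L x N x N array, `f[i, j, k]` = strength with
#'   which PG subcompartment k of glomerulus i inhibits MC branch j) and
#'   `rates`
#' @export
init_network <- function(L = 4L, N = 16L, class_mask = NULL,
                         f_density = 0.5,
                         learning_rates = default_learning_rates(),
                         seed = 1L) {
  L <- as.integer(L); N <- as.integer(N)
  if (is.null(class_mask)) class_mask <- block_class_mask(L, N)
  class_mask <- as.matrix(class_mask)
  if (nrow(class_mask) != L || ncol(class_mask) != N ||
      !all(class_mask %in% c(0, 1)))
    stop("'class_mask' must be a binary L x N matrix")
  if (any(colSums(class_mask) != 1))
    stop("each sensor must belong to exactly one class")
  if (any(rowSums(class_mask) == 0)) stop("'class_mask' rows must be non-empty")
  if (f_density < 0 || f_density > 1) stop("'f_density' must be in [0, 1]")
  rt <- learning_rates
  if (!all(c("gamma_a", "gamma_b", "delta_a", "delta_b") %in% names(rt)) ||
      any(rt[c("gamma_a", "gamma_b", "delta_a", "delta_b")] <= 0))
    stop("'learning_rates' must name positive gamma_a, gamma_b, delta_a, delta_b")
  set.seed(as.integer(seed))
  cmat <- matrix(stats::runif(L * N), L, N) * class_mask
  dmat <- matrix(stats::runif(L * N), L, N)
  f <- array(stats::runif(L * N * N, 0, 0.1) *
               (stats::runif(L * N * N) < f_density), dim = c(L, N, N))
  f <- f * as.vector(class_mask)   # f[i, j, ] = 0 where branch (i, j) absent
  structure(list(L = L, N = N, class_mask = class_mask,
                 c = cmat, d = dmat, f = f,
                 rates = rt[c("gamma_a", "gamma_b", "delta_a", "delta_b")]),
            class = "glom_network")
}

#' @export
print.glom_network <- function(x, ...) {
  cat(sprintf("glom_network: %d glomerular units, %d sensor channels\n", x$L, x$N))
  cat(sprintf("nonzero c: %d / %d, nonzero f: %d / %d\n",
              sum(x$c > 0), sum(x$class_mask), sum(x$f > 0), length(x$f)))
  invisible(x)
}

check_input <- function(net, r) {
  if (length(r) != net$N) stop("input length must equal net$N")
  if (any(!is.finite(r)) || any(r < 0) || any(r > 1))
    stop("inputs must be normalised to [0, 1]; see normalize_fit()")
  as.numeric(r)
}

#' Periglomerular subcompartment potentials
#'
#' @param net a `glom_network`
#' @param r length-N input vector in `[0, 1]`
#' @return L x N matrix `p` with `p[i, k] = d[i, k] * r[k]`
#' @export
pg_potentials <- function(net, r) {
  r <- check_input(net, r)
  net$d * rep(r, each = net$L)
}

#' Mitral-cell branch potentials under multiplicative inhibition
#'
#' `m[i, j] = c[i, j] * r[j] * prod_k (1 - f[i, j, k] * p[i, k])`. Branches of
#' masked-out channels are exactly 0. Since `f <= 0.1` and `p <= 1`, every
#' inhibition factor lies in `[0.9, 1]` and the product is positive: moderate
#' coefficients accumulate into strong total inhibition.
#'
#' @param net a `glom_network`
#' @param r length-N input vector
#' @param p L x N PG potentials, as returned by [pg_potentials()]
#' @return L x N branch-potential matrix
#' @export
mc_branch_potentials <- function(net, r, p) {
  r <- check_input(net, r)
  L <- net$L; N <- net$N
  # inhib[i, j] = prod_k (1 - f[i, j, k] * p[i, k]); build A[i, j, k] = p[i, k]
  # by recycling p along the third dim, then swapping j and k
  A <- aperm(array(p, dim = c(L, N, N)), c(1, 3, 2))
  fac <- 1 - net$f * A
  if (any(fac < 0)) stop("inhibition factor < 0: network invariants violated")
  dim(fac) <- c(L * N, N)
  inhib <- fac[, 1]
  for (k in seq_len(N)[-1]) inhib <- inhib * fac[, k]
  m <- net$c * rep(r, each = L) * matrix(inhib, L, N)
  m * net$class_mask
}

#' Mitral-cell outputs
#'
#' @param m_branch L x N branch potentials
#' @return length-L vector of MC outputs, `m[i] = sum_j m_branch[i, j]`
#' @export
mc_outputs <- function(m_branch) {
  if (any(!is.finite(m_branch)) || any(m_branch < 0))
    stop("'m_branch' must be finite and non-negative")
  rowSums(m_branch)
}

#' One step of the nonlinear local Hebbian weight update
#'
#' @param net a `glom_network`
#' @param r length-N input vector
#' @param m_branch,p branch potentials computed from `net` and `r`
#' @return the updated `glom_network` (`f` unchanged)
#' @export
update_weights <- function(net, r, m_branch, p) {
  rt <- net$rates
  dc <- rt[["gamma_a"]] * m_branch * (1 - net$c) - rt[["gamma_b"]] * net$c^2
  dd <- rt[["delta_b"]] * p * (1 - net$d) - rt[["delta_a"]] * net$d^2
  if (any(!is.finite(dc)) || any(!is.finite(dd)))
    stop("non-finite weight update")
  net$c <- pmin(pmax(net$c + dc, 0), 1) * net$class_mask
  net$d <- pmin(pmax(net$d + dd, 0), 1)
  net
}

#' Run the network over a response table
#'
#' Processes samples in order. For each sample: any active fault is applied to
#' the input vector, the forward pass is computed with the current weights, the
#' MC outputs are recorded, and only then (if `adapt`) the weights are updated
#' — so a downstream classifier always sees pre-update responses.
#'
#' @param net a `glom_network`
#' @param data a `response_matrix` with `net$N` channels, values in `[0, 1]`
#' @param adapt logical: apply the Hebbian update after each sample
#' @param faults optional list of `fault_spec`s applied to the stream
#' @param fault_seed seed for random-mode fault draws
#' @param record_branches logical: also record branch potentials (samples x L x N)
#' @param record_weights logical: also record `c` and `d` trajectories
#'   (samples x L x N; the weights *used* for each sample, i.e. pre-update)
#' @return list of class `glom_trace` with elements `net` (final network),
#'   `mc_outputs` (samples x L), `sample_index`, `stimulus`, and optionally
#'   `branches`, `c_traj`, `d_traj`
#' @export
process_sequence <- function(net, data, adapt = TRUE, faults = NULL,
                             fault_seed = 1L, record_branches = FALSE,
                             record_weights = FALSE) {
  stopifnot(inherits(net, "glom_network"), inherits(data, "response_matrix"))
  if (ncol(data$values) != net$N)
    stop("data channel count must equal net$N")
  if (!is.null(faults)) {
    if (inherits(faults, "fault_spec")) faults <- list(faults)
    for (i in seq_along(faults))
      data <- apply_fault(data, faults[[i]], seed = as.integer(fault_seed) + i - 1L)
  }
  n <- nrow(data$values); L <- net$L; N <- net$N
  mc <- matrix(NA_real_, n, L)
  branches <- if (record_branches) array(NA_real_, c(n, L, N)) else NULL
  c_traj <- if (record_weights) array(NA_real_, c(n, L, N)) else NULL
  d_traj <- if (record_weights) array(NA_real_, c(n, L, N)) else NULL
  for (t in seq_len(n)) {
    r <- data$values[t, ]
    p <- pg_potentials(net, r)
    mb <- mc_branch_potentials(net, r, p)
    mc[t, ] <- rowSums(mb)
    if (record_branches) branches[t, , ] <- mb
    if (record_weights) { c_traj[t, , ] <- net$c; d_traj[t, , ] <- net$d }
    if (adapt) net <- update_weights(net, r, mb, p)
  }
  colnames(mc) <- sprintf("m%d", seq_len(L))
  structure(list(net = net, mc_outputs = mc,
                 sample_index = data$sample_index, stimulus = data$stimulus,
                 branches = branches, c_traj = c_traj, d_traj = d_traj),
            class = "glom_trace")
}

#' Disinhibition induced by silencing one input
#'
#' Computes, at fixed weights, the change of every MC branch potential when a
#' single input channel is set to zero: `m_branch(r with r[k] = 0) -
#' m_branch(r)` for all branches other than k itself. Removing an input removes
#' inhibition factors `< 1` from the products, so no surviving branch can
#' decrease — the disinhibition that lets the remaining inputs of an affected
#' glomerulus strengthen during a sensor fault.
#'
#' @param net a `glom_network`
#' @param r length-N input vector
#' @param k channel to silence
#' @return L x N matrix of deltas; column `k` is `NA` (the silenced branch)
#' @export
disinhibition_check <- function(net, r, k) {
  r <- check_input(net, r)
  m0 <- mc_branch_potentials(net, r, pg_potentials(net, r))
  r1 <- r; r1[k] <- 0
  m1 <- mc_branch_potentials(net, r1, pg_potentials(net, r1))
  delta <- m1 - m0
  delta[, k] <- NA_real_
  delta
}
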