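# shared builders for small deterministic test objects

tiny_response <- function(values, stimulus = NULL, episode = NULL,
                          channel_class = NULL) {
  values <- as.matrix(values)
  n <- nrow(values)
  if (is.null(stimulus)) stimulus <- rep(1L, n)
  if (is.null(episode)) episode <- rep(0L, n)
  if (is.null(channel_class)) channel_class <- rep(1L, ncol(values))
  response_matrix(values, stimulus, episode, channel_class)
}

random_network <- function(seed, L = 4L, N = 16L, f_density = 0.5) {
  init_network(L = L, N = N, f_density = f_density, seed = seed)
}

# scalar triple-loop evaluation of the MC output, independent of the
# vectorised implementation
mc_outputs_bruteforce <- function(net, r) {
  m <- numeric(net$L)
  for (i in seq_len(net$L)) {
    acc <- 0
    for (j in seq_len(net$N)) {
      prod_inh <- 1
      for (k in seq_len(net$N)) {
        prod_inh <- prod_inh * (1 - net$f[i, j, k] * net$d[i, k] * r[k])
      }
      acc <- acc + net$c[i, j] * r[j] * prod_inh
    }
    m[i] <- acc
  }
  m
}

mc_branches_bruteforce <- function(net, r) {
  m <- matrix(0, net$L, net$N)
  for (i in seq_len(net$L)) for (j in seq_len(net$N)) {
    prod_inh <- 1
    for (k in seq_len(net$N))
      prod_inh <- prod_inh * (1 - net$f[i, j, k] * net$d[i, k] * r[k])
    m[i, j] <- net$c[i, j] * r[j] * prod_inh
  }
  m
}

# two-pass textbook Pearson correlation, independent of stats::cor
pearson_bruteforce <- function(x) {
  n <- nrow(x); p <- ncol(x)
  mu <- colMeans(x)
  out <- matrix(NA_real_, p, p)
  for (a in seq_len(p)) for (b in seq_len(p)) {
    xa <- x[, a] - mu[a]; xb <- x[, b] - mu[b]
    out[a, b] <- sum(xa * xb) / sqrt(sum(xa^2) * sum(xb^2))
  }
  out
}

small_benchmark <- function(seed = 1L) {
  make_fixture(seed = seed)
}
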