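# Independent brute-force oracles and small fixture builders. These share no
# code with the package internals beyond the public data layout.

# a simple chain a -> b -> c ... (first element is the headwater)
chain_network <- function(areas) {
  n <- length(areas)
  watershed_network(data.frame(
    shed_id = seq_len(n), area_acres = areas,
    downstream_id = c(seq_len(n)[-1], NA)))
}

# random forest over n sheds: each shed drains into a random earlier one
random_tree <- function(n, seed, root_prob = 0.1) {
  set.seed(seed)
  down <- rep(NA_integer_, n)
  if (n > 1)
    for (i in 2:n)
      if (runif(1) > root_prob) down[i] <- sample.int(i - 1L, 1L)
  watershed_network(data.frame(
    shed_id = seq_len(n),
    area_acres = runif(n, 50, 5000),
    downstream_id = down))
}

# downstream path of shed i as a sequence of row indices, by naive following
oracle_down_path <- function(net, i) {
  pos <- match(net$downstream_id, net$shed_id)
  path <- i
  while (!is.na(pos[path[length(path)]]))
    path <- c(path, pos[path[length(path)]])
  path
}

# pi_s for every shed by independent double loop over (w, s) pairs
oracle_accumulate <- function(net, rho) {
  n <- nrow(net)
  pi_s <- numeric(n)
  for (w in seq_len(n)) {
    path <- oracle_down_path(net, w)
    for (j in seq_along(path)) {
      s <- path[j]
      area <- sum(net$area_acres[path[seq_len(j)]])
      pi_s[s] <- pi_s[s] + rho[w] / area
    }
  }
  pi_s
}

# upstream set of s by exhaustive path enumeration from every shed
oracle_upstream <- function(net, s) {
  si <- match(s, net$shed_id)
  hits <- vapply(seq_len(nrow(net)), function(w)
    si %in% oracle_down_path(net, w), logical(1))
  net$shed_id[hits]
}

# compact end-to-end study configuration for fixture-level tests: large
# enough that every stratum supports the full 14-term model, small enough
# to keep the suite fast
small_config <- function(seed = 1, ...) {
  simulation_config(n_watersheds = 25, n_counties = 100, n_facilities = 250,
                    extent = c(0, 80, 0, 80), seed = seed, ...)
}
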