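# Independent oracles and small fixture builders, kept deliberately naive.

# Brute-force SAB enumerator: literal sliding 3-window count.
brute_force_sab <- function(arms) {
  n <- length(arms)
  if (n < 3) return(NA_real_)
  alt <- 0L
  for (k in 1:(n - 2)) {
    w <- arms[k:(k + 2)]
    if (length(unique(w)) == 3L) alt <- alt + 1L
  }
  100 * alt / (n - 2)
}

# Random valid arm sequence (no consecutive duplicates).
random_arm_sequence <- function(len, labels = c("A", "B", "C")) {
  out <- character(len)
  out[1] <- sample(labels, 1)
  for (k in seq_len(len)[-1]) out[k] <- sample(setdiff(labels, out[k - 1]), 1)
  out
}

# All set partitions of n elements (restricted growth strings).
all_partitions <- function(n) {
  out <- list()
  rec <- function(prefix, maxid) {
    k <- length(prefix)
    if (k == n) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible())
    }
    for (id in seq_len(maxid + 1L)) rec(c(prefix, id), max(maxid, id))
  }
  rec(integer(0), 0L)
  out
}

# Brute-force maximum modularity over every partition of the graph's nodes.
brute_force_best_modularity <- function(graph) {
  n <- length(graph$nodes)
  best <- -Inf
  for (p in all_partitions(n)) {
    memb <- stats::setNames(p, graph$nodes)
    q <- modularity(graph, memb)
    if (q > best) best <- q
  }
  best
}

# Two cliques of sizes na, nb with unit intra-clique weights and an
# optional bridge weight between node 1 of each clique.
two_clique_graph <- function(na, nb, bridge = 0) {
  n <- na + nb
  w <- matrix(0, n, n)
  w[seq_len(na), seq_len(na)] <- 1
  w[na + seq_len(nb), na + seq_len(nb)] <- 1
  diag(w) <- 0
  if (bridge > 0) {
    w[1, na + 1] <- bridge
    w[na + 1, 1] <- bridge
  }
  rownames(w) <- colnames(w) <- paste0("n", seq_len(n))
  similarity_graph(w)
}

# Two disjoint unit-weight triangles on nodes a..f.
two_triangle_graph <- function() two_clique_graph(3, 3)

# Small planted-effect two-group cohort; "slow" shares nothing with "fast".
planted_cohort <- function(n_fish = 8, duration = 300, rate = 5, seed = 7,
                           doses = c("control", "200ug"), days = "Day1") {
  design <- study_design(doses = doses, days = days,
                         n_fish_per_group = n_fish,
                         trial_duration = duration, sample_rate = rate,
                         seed = seed)
  params <- list(
    behavior_params(doses[1], mean_speed = 6, speed_sd = 2,
                    freeze_rate = 0.5, freeze_duration = 3,
                    p_alternate = 0.7),
    behavior_params(doses[2], mean_speed = 2.5, speed_sd = 1.2,
                    freeze_rate = 4, freeze_duration = 5,
                    p_alternate = 0.5))
  names(params) <- doses
  simulate_cohort(design, params)
}

# Null cohort: every group shares identical behavioural parameters.
null_cohort <- function(n_fish = 6, duration = 600, rate = 5, seed = 1,
                        doses = c("control", "200ug"), days = "Day1") {
  design <- study_design(doses = doses, days = days,
                         n_fish_per_group = n_fish,
                         trial_duration = duration, sample_rate = rate,
                         seed = seed)
  params <- lapply(doses, function(d) behavior_params(d, p_alternate = 0.7))
  names(params) <- doses
  simulate_cohort(design, params)
}
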