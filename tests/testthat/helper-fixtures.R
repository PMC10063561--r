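# shared fixtures: small synthetic records built in code

baseline_protocol <- function(duration = 50, sbp = 120, dbp = 80,
                              jitter = 0.02, bp_noise = 0, hr = 60) {
  bp_protocol(segments = data.frame(kind = "baseline", duration = duration,
                                    sbp = sbp, dbp = dbp),
              hr_base = hr, ibi_jitter_sd = jitter, bp_noise_sd = bp_noise)
}

# a conditioned clean trial (carrier path) plus its ground truth
clean_trial <- function(seed = 1, duration = 50, jitter = 0.03,
                        noise_sd = 0, beat_offset = 2L) {
  beats <- generate_bp_trajectory(baseline_protocol(duration, jitter = jitter),
                                  seed)
  trial <- modulate(beats, sensor_model(noise_sd = noise_sd), seed = seed,
                    beat_offset = beat_offset)
  wave <- condition_record(trial$record)
  list(wave = wave, truth = trial$truth, reference = trial$reference)
}

# brute-force DTW oracles, independent of the package implementation.
# dijkstra over the alignment lattice minimises over exactly the set of
# monotone warping paths with steps {(1,0),(0,1),(1,1)}
dtw_oracle_dijkstra <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  n <- length(a); m <- length(b)
  # degenerate lattice: only one monotone path exists
  if (n == 1L || m == 1L) return(sum(abs(a - b)))
  id <- function(i, j) (j - 1L) * n + i
  from <- integer(0); to <- integer(0)
  for (j in seq_len(m)) for (i in seq_len(n)) {
    if (i < n) { from <- c(from, id(i, j)); to <- c(to, id(i + 1L, j)) }
    if (j < m) { from <- c(from, id(i, j)); to <- c(to, id(i, j + 1L)) }
    if (i < n && j < m) { from <- c(from, id(i, j)); to <- c(to, id(i + 1L, j + 1L)) }
  }
  g <- igraph::graph_from_edgelist(cbind(from, to), directed = TRUE)
  # entering node (i,j) costs |a_i - b_j|; edge weight = cost of head node
  cost <- outer(a, b, function(x, y) abs(x - y))
  w <- cost[cbind((to - 1L) %% n + 1L, (to - 1L) %/% n + 1L)]
  d <- igraph::distances(g, v = id(1L, 1L), to = id(n, m), weights = w,
                         mode = "out")
  as.numeric(d) + cost[1L, 1L]
}

# exhaustive path enumeration for tiny series (depth-first recursion)
dtw_oracle_enumerate <- function(a, b) {
  rec <- function(i, j) {
    c0 <- abs(a[i] - b[j])
    if (i == 1L && j == 1L) return(c0)
    best <- Inf
    if (i > 1L) best <- min(best, rec(i - 1L, j))
    if (j > 1L) best <- min(best, rec(i, j - 1L))
    if (i > 1L && j > 1L) best <- min(best, rec(i - 1L, j - 1L))
    c0 + best
  }
  rec(length(a), length(b))
}
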