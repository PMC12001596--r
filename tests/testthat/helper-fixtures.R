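# Shared in-code fixtures: a small longitudinal design and quantification
# table, built deterministically.

toy_design <- function(n_ind = 6L, times = c("t1", "t2", "t3"),
                       conditions = c("ctl", "trt")) {
  ind <- sprintf("i%02d", seq_len(n_ind))
  data.frame(
    sample_id = paste0(rep(ind, length(times)), "_",
                       rep(times, each = n_ind)),
    individual = rep(ind, length(times)),
    time = rep(times, each = n_ind),
    condition = rep(rep(conditions, length.out = n_ind), length(times)),
    stringsAsFactors = FALSE)
}

toy_qt <- function(seed = 1L, n_ind = 6L, m = 10L,
                   times = c("t1", "t2", "t3")) {
  set.seed(seed)
  d <- toy_design(n_ind, times)
  v <- matrix(exp(rnorm(nrow(d) * m, mean = 1, sd = 0.5)), nrow(d), m,
              dimnames = list(d$sample_id, sprintf("met_%02d", seq_len(m))))
  quant_table(v, d)
}

toy_pathways <- function(m = 10L) {
  ids <- sprintf("met_%02d", seq_len(m))
  pathway_set(list(pw_a = ids[1:3], pw_b = ids[3:6], pw_c = ids[7:8]))
}

# independent step-up BH oracle (recursion by hand)
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  prev <- 1
  for (i in seq(n, 1L)) {
    prev <- min(prev, n * p[o[i]] / i)
    adj[o[i]] <- prev
  }
  pmin(adj, 1)
}

# independent Simes oracle (direct formula on sorted values)
simes_oracle <- function(p) {
  p <- sort(p)
  min(1, min(length(p) * p / seq_along(p)))
}

# brute-force hypergeometric upper tail via binomial coefficients
hyper_tail_oracle <- function(x, N, K, n) {
  xs <- x:min(K, n)
  sum(choose(K, xs) * choose(N - K, n - xs)) / choose(N, n)
}
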