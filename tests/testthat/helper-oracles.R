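# independent brute-force oracles for the exact rank tests (shared by the
# analysis and acceptance tests)
brute_rank_sum_p <- function(a, b, alternative = "two.sided") {
  n <- length(a) + length(b)
  r <- rank(c(a, b))
  w_obs <- sum(r[seq_along(a)])
  e_w <- length(a) * (n + 1) / 2
  ws <- apply(utils::combn(n, length(a)), 2, function(idx) sum(r[idx]))
  switch(alternative,
         two.sided = mean(abs(ws - e_w) >= abs(w_obs - e_w) - 1e-9),
         greater = mean(ws >= w_obs - 1e-9),
         less = mean(ws <= w_obs + 1e-9))
}
brute_signed_rank_p <- function(d, alternative = "two.sided") {
  d <- d[d != 0]
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  e_v <- length(d) * (length(d) + 1) / 4
  vs <- vapply(0:(2^length(d) - 1), function(mask) {
    sum(r[bitwAnd(bitwShiftR(mask, seq_along(d) - 1L), 1L) == 1L])
  }, numeric(1))
  switch(alternative,
         two.sided = mean(abs(vs - e_v) >= abs(v_obs - e_v) - 1e-9),
         greater = mean(vs >= v_obs - 1e-9),
         less = mean(vs <= v_obs + 1e-9))
}

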