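# Independent oracles, deliberately kept apart from the implementation paths
# they check.

# Exact two-sided signed-rank p by brute-force enumeration of all 2^n sign
# assignments: P(|W - mu| >= |W_obs - mu|) under the null.
wilcoxon_enum_oracle <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(1)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  ws <- as.vector(signs %*% r)
  mu <- n * (n + 1) / 4
  mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-9)
}

# Step-up BH written directly from the definition q_(i) = min_{j>=i} p_(j) m/j.
bh_stepup_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# tiny fixture writers -------------------------------------------------------

write_bed_fixture <- function(lines, path = tempfile(fileext = ".bed")) {
  writeLines(lines, path)
  path
}

sample_sheet_fixture <- function() {
  tibble::tibble(
    sample_id = c("T1", "N1", "T2", "N2", "T3", "N3"),
    patient_id = rep(c("P1", "P2", "P3"), each = 2),
    tissue = rep(c("tumor", "normal"), 3),
    cohort = "COH"
  )
}
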