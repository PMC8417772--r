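# brute-force Benjamini-Hochberg step-up oracle
bh_oracle <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- which(ps <= q * seq_len(m) / m)
  rej <- logical(m)
  if (length(k)) rej[o[seq_len(max(k))]] <- TRUE
  rej
}
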