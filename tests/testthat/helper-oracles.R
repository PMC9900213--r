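# Brute-force metric oracles, deliberately naive and independent of the
# implementations they check.

roc_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

pr_oracle <- function(scores, labels) {
  n1 <- sum(labels == 1)
  th <- sort(unique(scores), decreasing = TRUE)
  prec <- rec <- numeric(length(th))
  for (i in seq_along(th)) {
    call <- scores >= th[i]
    prec[i] <- sum(labels[call]) / sum(call)
    rec[i] <- sum(labels[call]) / n1
  }
  sum(diff(c(0, rec)) * prec)
}
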