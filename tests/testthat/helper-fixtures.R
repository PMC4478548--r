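# Shared fixture builders; everything is generated in code.

`%||%` <- function(a, b) if (is.null(a)) b else a

small_intensity <- function() {
  x <- matrix(c(1, 0, 0.5, 0.2, 1.2, 0.4), 2, 3,
              dimnames = list(c("m1", "m2"), c("s1", "s2", "s3")))
  y <- matrix(c(0, 1, 0.5, 1.1, 0.1, 0.6), 2, 3,
              dimnames = dimnames(x))
  intensity_table(rownames(x), colnames(x), x = x, y = y)
}

abh_fixture <- function(rows) {
  m <- do.call(rbind, lapply(rows, function(r) strsplit(r, "")[[1]]))
  rownames(m) <- sprintf("m%d", seq_along(rows))
  colnames(m) <- sprintf("i%d", seq_len(ncol(m)))
  m
}

# independent brute-force SARF optimum over all permutations
brute_force_sarf <- function(d) {
  n <- nrow(d)
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  best <- Inf
  for (p in perms(seq_len(n))) {
    cost <- sum(d[cbind(p[-n], p[-1])])
    if (cost < best) best <- cost
  }
  best
}

# independent two-locus F2 likelihood by gamete enumeration
f2_loglik_enum <- function(counts, r) {
  gam <- expand.grid(a1 = 0:1, a2 = 0:1)
  pg <- function(g) ifelse(g$a1 == g$a2, (1 - r) / 2, r / 2)
  p <- matrix(0, 3, 3)
  for (i in seq_len(4)) for (j in seq_len(4)) {
    g1 <- gam[i, ]; g2 <- gam[j, ]
    d1 <- g1$a1 + g2$a1
    d2 <- g1$a2 + g2$a2
    p[d1 + 1, d2 + 1] <- p[d1 + 1, d2 + 1] + pg(g1) * pg(g2)
  }
  sum(counts * log(p))
}

kendall_up_to_reversal <- function(found, truth) {
  x <- match(found, truth)
  tau <- stats::cor(seq_along(x), x, method = "kendall")
  abs(tau)
}
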