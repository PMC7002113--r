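# Independent brute-force oracles used to pin expected values. These stay
# deliberately naive (explicit loops, no shared code with the package).

oracle_revcomp <- function(s) {
  chartr("ACGTN", "TGCAN",
         paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
}

# Longest stop-free stretch (nt) over all six frames, by explicit
# codon-by-codon enumeration.
oracle_orf_fraction <- function(seq) {
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n < 3) return(0)
  stops <- c("TAA", "TAG", "TGA")
  best <- 0
  for (s in c(seq, oracle_revcomp(seq))) {
    for (f in 0:2) {
      run <- 0
      i <- 1 + f
      while (i + 2 <= n) {
        codon <- substr(s, i, i + 2)
        if (codon %in% stops) {
          run <- 0
        } else {
          run <- run + 1
          if (run * 3 > best) best <- run * 3
        }
        i <- i + 3
      }
    }
  }
  best / n
}

# Upper binomial tail P(K >= k | n, p) by direct summation.
oracle_binom_tail <- function(k, n, p) {
  if (k <= 0) return(1)
  total <- 0
  for (j in k:n) total <- total + choose(n, j) * p^j * (1 - p)^(n - j)
  min(1, total)
}

# Benjamini-Hochberg step-up by hand: sort, p * n / rank, cumulative min
# from the largest rank down, restore order.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  running <- 1
  for (r in n:1) {
    running <- min(running, p[o[r]] * n / r)
    adj[o[r]] <- running
  }
  adj
}

random_seq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}
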