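# Shared fixtures and independent oracles. Everything is generated in code
# under fixed seeds; no data files.

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
  collapse = "")

# codons free of stops, for in-frame constructions
rand_cds_codons <- function(n_codons) {
  pool <- setdiff(names(vntrfam:::CODON_TABLE), c("TAA", "TAG", "TGA"))
  paste(sample(pool, n_codons, replace = TRUE), collapse = "")
}

# brute-force autocorrelation oracle: best 2p-window match fraction
oracle_period_score <- function(seq, p) {
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  m <- ch[1:(n - p)] == ch[(p + 1):n]
  w <- min(2 * p, length(m))
  best <- -Inf
  for (s in 1:(length(m) - w + 1)) best <- max(best, mean(m[s:(s + w - 1)]))
  best
}

# independent identity: compare with every codon-aligned single-codon
# deletion, via plain substring surgery
oracle_identity <- function(unit, cons) {
  lu <- nchar(unit); lc <- nchar(cons)
  cnt <- function(a, b) {
    x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
    sum(x == y)
  }
  if (lu == lc) return(cnt(unit, cons) / lc)
  if (abs(lu - lc) != 3) return(0)
  long <- if (lu > lc) unit else cons
  short <- if (lu > lc) cons else unit
  best <- 0
  for (d in seq(1, nchar(long) - 2, by = 3)) {
    trimmed <- paste0(substr(long, 1, d - 1), substr(long, d + 3, nchar(long)))
    best <- max(best, cnt(trimmed, short))
  }
  best / max(lu, lc)
}

# exhaustive tiling search replicating the segmentation objective
# (matched bases, identity sum, unit count, 5'-most), written as plain
# recursion over all codon-granular tilings
oracle_tiling <- function(cds, cons, min_identity = 0.8,
                          lens = c(30L, 33L), indel_penalty = 2) {
  n <- nchar(cds)
  lc <- nchar(cons)
  lens <- sort(intersect(lens, lc + c(-3L, 0L, 3L)))
  best <- list(score = 0, start = n, lens = integer(0))
  chains <- function(i, acc_score, acc_lens, start) {
    # record the completed tiling
    if (length(acc_lens) > 0 &&
        (acc_score > best$score + 1e-6 ||
         (abs(acc_score - best$score) <= 1e-6 && start < best$start))) {
      best <<- list(score = acc_score, start = start, lens = acc_lens)
    }
    for (l in lens) {
      if (i + l - 1L > n) next
      u <- substr(cds, i, i + l - 1L)
      ident <- oracle_identity(u, cons)
      if (ident < min_identity) next
      pen <- if (l != lc) indel_penalty else 0
      s <- (ident * max(l, lc) - pen) * 1000 + ident * 10 - 0.01
      chains(i + l, acc_score + s, c(acc_lens, l), start)
    }
  }
  for (i in 1:n) chains(i, 0, integer(0), i - 1L)
  best
}

# tiny engineered family configs reused across tests
small_family_config <- function(seed = 7, ...) {
  family_config(n_members = 6, motifs = c("YRSKDD", "CNDSGD", "YHYQEH"),
    seed = seed, ...)
}
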