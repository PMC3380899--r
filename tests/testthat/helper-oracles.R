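# Independent oracles used across the suite; deliberately naive and separate
# from the package's own algorithms.

# Brute-force digestion: enumerate every substring and check the rules.
brute_digest <- function(protein, max_missed = 2L, trypticity = "full",
                         min_length = 1L, blocked = integer(0)) {
  chars <- strsplit(protein, "")[[1L]]
  n <- length(chars)
  cleav <- which(chars %in% c("K", "R") & c(chars[-1L], "") != "P")
  cleav <- setdiff(cleav, c(blocked, n))
  keys <- character(0)
  for (from in seq_len(n)) for (to in from:n) {
    if (to - from + 1L < min_length) next
    start_ok <- (from - 1L) %in% c(0L, cleav)
    end_ok <- to %in% c(cleav, n)
    ok <- if (trypticity == "full") start_ok && end_ok else start_ok || end_ok
    if (!ok) next
    internal <- sum(cleav >= from & cleav <= to - 1L)
    if (internal > max_missed) next
    keys <- c(keys, paste(from, to))
  }
  sort(keys)
}

# Plain union-find over protein ids connected through shared peptides.
uf_families <- function(peptides, protein_lists) {
  prots <- unique(unlist(protein_lists))
  parent <- stats::setNames(prots, prots)
  find <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
  peps <- unique(peptides)
  for (p in peps) {
    members <- unique(unlist(protein_lists[peptides == p]))
    r <- find(members[1L])
    for (m in members[-1L]) parent[[find(m)]] <- r
  }
  roots <- vapply(prots, find, "")
  unname(lapply(split(prots, roots), function(g) sort(unname(g))))
}

random_peptide <- function(len) {
  paste(sample(names(aggregome::AA_MONO), len, replace = TRUE), collapse = "")
}

# tolerance of one unit in the last digit of a value printed to 3 sig figs
ulp3 <- function(x) 10^(ceiling(log10(abs(x))) - 3L)
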