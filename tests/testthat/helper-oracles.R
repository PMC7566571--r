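# Independent oracles and small fixture builders shared across tests.
# Oracles use direct enumeration / closed forms, never the package's own
# code path for the quantity they check.

# Signed -log10 hypergeometric landscape value by explicit summation of
# the probability mass function.
oracle_landscape_value <- function(N, K, t, x) {
  pmf <- function(k) choose(K, k) * choose(N - K, t - k) / choose(N, t)
  kmax <- min(K, t)
  p_ge <- sum(vapply(x:kmax, pmf, numeric(1)))
  p_le <- sum(vapply(0:x, pmf, numeric(1)))
  if (x / t >= K / N) -log10(p_ge) else log10(p_le)
}

# Brute-force read placement: enumerate every (tail length, start)
# split of the read over the context, keep exact substring matches
# anchored within max_shift of the mature 5' end, and pick the longest
# templated core, then the smallest |5' offset|, then the more negative
# offset.
oracle_align <- function(read, ctx, context_offset, m_start, m_len,
                         min_core = 16L, max_shift = 5L) {
  n <- nchar(read)
  cands <- list()
  for (k in 0:(n - min_core)) {
    core <- substr(read, 1, n - k)
    for (s in 0:(nchar(ctx) - nchar(core))) {
      if (substr(ctx, s + 1, s + nchar(core)) != core) next
      off5 <- m_start - (s - context_offset)
      if (abs(off5) > max_shift) next
      cands[[length(cands) + 1]] <- list(
        k = k, five = off5,
        three = (s - context_offset + nchar(core)) - (m_start + m_len),
        tail = if (k > 0) substr(read, n - k + 1, n) else "")
    }
  }
  if (length(cands) == 0) return(NULL)
  ks <- vapply(cands, `[[`, numeric(1), "k")
  cands <- cands[ks == min(ks)]
  fv <- vapply(cands, `[[`, numeric(1), "five")
  pick <- order(abs(fv), fv)[1]
  c <- cands[[pick]]
  list(five_prime_offset = c$five, three_prime_offset = c$three,
       nontemplated_tail = c$tail)
}

# Published mature sequences of the two miR-140-3p isomiR species
# (DNA as printed; package functions normalize to RNA).
MIR140_3P_1 <- "ACCACAGGGUAGAACCACGGAC"
MIR140_3P_2 <- "UACCACAGGGUAGAACCACGGA"

# A minimal catalog data.frame for seed-group / threshold tests.
toy_records <- function(sequence, count, ref = "miR-x",
                        five_prime_offset = 0L, three_prime_offset = 0L,
                        nontemplated_tail = "") {
  five_mod <- five_prime_offset != 0
  three_mod <- three_prime_offset != 0 | nchar(nontemplated_tail) > 0
  category <- ifelse(!five_mod & !three_mod, "canonical",
              ifelse(five_mod & !three_mod, "5prime_only",
              ifelse(three_mod & !five_mod, "3prime_only", "mixed")))
  data.frame(sequence = sequence, count = count, ref = ref,
             five_prime_offset = five_prime_offset,
             three_prime_offset = three_prime_offset,
             nontemplated_tail = nontemplated_tail,
             templated = nchar(nontemplated_tail) == 0,
             seed = extract_seed(sequence),
             category = category, ambiguous = FALSE,
             stringsAsFactors = FALSE)
}

# DE table built directly (not via the generator) for enrichment tests.
toy_de <- function(genes, log2fc, adj_p = rep(1, length(genes))) {
  data.frame(gene = genes, log2fc = log2fc, adj_p = adj_p,
             stringsAsFactors = FALSE)
}

# Wrap DE tables into StudyComparison records without the generator.
toy_study <- function(id, de, host) {
  study_comparisons(stats::setNames(list(de), id), host)[[1]]
}
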