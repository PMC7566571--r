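test_that("extract_seed returns positions 2-8 after RNA normalization", {
  expect_identical(extract_seed("ACCACAGGGUAGAACCACGGAC"), "CCACAGG")
  expect_identical(extract_seed("TACCACAGGGTAGAACCACGGA"), "ACCACAG")
  expect_identical(extract_seed("AUGCAUGC"), "UGCAUGC")
  expect_error(extract_seed("AUGCAUG"), "shorter")
})

test_that("the two published miR-140-3p species have distinct seeds that
           map onto each other under the -1 shift", {
  s1 <- extract_seed(MIR140_3P_1)
  s2 <- extract_seed(MIR140_3P_2)
  expect_false(s1 == s2)
  # .1 is .2 shifted by -1 nt: .1's seed window is .2's positions 3-9
  expect_identical(s1, substr(normalize_rna(MIR140_3P_2), 3, 9))
})

test_that("align_read computes offsets and minimal nontemplated tail", {
  locus <- gen_locus(1)
  refs <- mature_refs(locus)
  ref <- refs[refs$arm == "3p", ]
  ctx <- locus_context(locus)
  off <- nchar(locus$flank5)

  # identity
  al <- align_read(ref$sequence, ref, ctx, context_offset = off)
  expect_equal(al[c("five_prime_offset", "three_prime_offset")],
               list(five_prime_offset = 0, three_prime_offset = 0))
  expect_identical(al$nontemplated_tail, "")

  # drop first base, add next templated base: (-1, +1, "")
  nxt <- substr(ctx, off + ref$start + 23, off + ref$start + 23)
  shifted <- paste0(substr(ref$sequence, 2, 22), nxt)
  al2 <- align_read(shifted, ref, ctx, context_offset = off)
  expect_equal(al2$five_prime_offset, -1)
  expect_equal(al2$three_prime_offset, 1)
  expect_identical(al2$nontemplated_tail, "")

  # nontemplated A where the next templated base differs
  expect_false(nxt == "A")  # guaranteed by locus construction
  al3 <- align_read(paste0(ref$sequence, "A"), ref, ctx, context_offset = off)
  expect_equal(al3$five_prime_offset, 0)
  expect_equal(al3$three_prime_offset, 0)
  expect_identical(al3$nontemplated_tail, "A")

  # unplaceable read is NULL, not an error
  expect_null(align_read(strrep("ACGU", 5), ref, ctx, context_offset = off))
})

test_that("align_read agrees with the brute-force placement oracle", {
  locus <- gen_locus(42)
  refs <- mature_refs(locus)
  ref <- refs[refs$arm == "3p", ]
  ctx <- locus_context(locus)
  off <- nchar(locus$flank5)
  set.seed(99)
  # enumerate systematic variants plus random tails
  for (d5 in -2:2) {
    for (d3 in -2:2) {
      for (tail in c("", "A", "AA", "C")) {
        start <- ref$start - d5
        end <- ref$start + 22 + d3
        core <- substr(ctx, off + start + 1, off + end)
        read <- paste0(core, tail)
        if (nchar(read) < 16 || nchar(read) > 30) next
        got <- align_read(read, ref, ctx, context_offset = off)
        want <- oracle_align(read, ctx, off, ref$start, 22)
        expect_equal(got, want, label = paste("read", read))
      }
    }
  }
})

test_that("classify_isomir follows the category definitions", {
  mk <- function(f, t, tail) list(five_prime_offset = f,
                                  three_prime_offset = t,
                                  nontemplated_tail = tail)
  expect_equal(classify_isomir(mk(0, 0, "")),
               list(category = "canonical", templated = TRUE))
  expect_equal(classify_isomir(mk(0, 2, "")),
               list(category = "3prime_only", templated = TRUE))
  expect_equal(classify_isomir(mk(-1, 1, "A")),
               list(category = "mixed", templated = FALSE))
  expect_equal(classify_isomir(mk(2, 0, ""))$category, "5prime_only")
  expect_equal(classify_isomir(mk(0, 0, "A"))$category, "3prime_only")
})

test_that("5' isomiR calling is strict at both thresholds", {
  # one miRNA: canonical bulk + boundary candidates
  recs <- rbind(
    toy_records("UAUAUAGCUGAAUCAUUUAAAG", 556),
    toy_records("AUAUAGCUGAAUCAUUUAAAGC", 99, five_prime_offset = -4L),
    toy_records("GUAUAUAGCUGAAUCAUUUAAA", 150, five_prime_offset = 1L),
    toy_records("AAUAUAGCUGAAUCAUUUAAAG", 195, five_prime_offset = -1L)
  )
  # fractions: 99/1000, 150/1000, 195/1000
  recs$count <- c(556, 99, 150, 195)
  calls <- call_5p_isomirs(recs)
  by_seq <- calls[match(recs$sequence, calls$sequence), ]
  expect_false(by_seq$passes[1])  # canonical, offset 0
  expect_false(by_seq$passes[2])  # count 99 <= 100, like the near-miss case
  expect_true(by_seq$passes[3])   # 150 reads, 15%
  expect_true(by_seq$passes[4])

  # exact boundaries never pass: count == 100, fraction == 0.05
  b <- rbind(toy_records("UAUAUAGCUGAAUCAUUUAAAG", 1900),
             toy_records("AUAUAGCUGAAUCAUUUAAAGC", 100,
                         five_prime_offset = -1L))
  expect_false(any(call_5p_isomirs(b)$passes))
  b2 <- rbind(toy_records("UAUAUAGCUGAAUCAUUUAAAG", 3800),
              toy_records("AUAUAGCUGAAUCAUUUAAAGC", 200,
                          five_prime_offset = -1L))
  # fraction = 200/4000 = 0.05 exactly; count passes but fraction does not
  expect_false(any(call_5p_isomirs(b2)$passes))
  # nudge above both thresholds
  b3 <- rbind(toy_records("UAUAUAGCUGAAUCAUUUAAAG", 3800),
              toy_records("AUAUAGCUGAAUCAUUUAAAGC", 201,
                          five_prime_offset = -1L))
  expect_true(call_5p_isomirs(b3)$passes[
    call_5p_isomirs(b3)$offset == -1])

  expect_equal(nrow(call_5p_isomirs(recs[0, ])), 0)
})

test_that("canonical_only denominator changes the fraction base", {
  recs <- rbind(
    toy_records("UAUAUAGCUGAAUCAUUUAAAG", 1000),
    toy_records("AUAUAGCUGAAUCAUUUAAAGC", 110, five_prime_offset = -1L)
  )
  arm <- call_5p_isomirs(recs, fraction_denominator = "arm_total")
  can <- call_5p_isomirs(recs, fraction_denominator = "canonical_only")
  i <- which(arm$offset == -1)
  expect_equal(arm$fraction[i], 110 / 1110)
  expect_equal(can$fraction[i], 110 / 1000)
})

test_that("group_by_seed groups the published sequences correctly", {
  recs <- rbind(
    toy_records(MIR140_3P_1, 600, ref = "miR-140-3p",
                five_prime_offset = -1L),
    toy_records(MIR140_3P_2, 400, ref = "miR-140-3p")
  )
  g <- group_by_seed(recs)
  expect_setequal(g$seed, c("CCACAGG", "ACCACAG"))
  expect_identical(g$seed[1], "CCACAGG")        # most abundant first
  expect_identical(g$suffix_name, c(".1", ".2"))
  expect_equal(g$fraction_of_mirna, c(0.6, 0.4))
  expect_equal(sum(g$total_count), sum(recs$count))

  # identical seeds collapse into one group
  two <- rbind(toy_records("UAUAUAGCUGAAUCAUUUAAAG", 10),
               toy_records("UAUAUAGCUGAAUCAUUUAAAGC", 5,
                           three_prime_offset = 1L))
  g2 <- group_by_seed(two)
  expect_equal(nrow(g2), 1)
  expect_equal(g2$total_count, 15)
  expect_identical(g2$representative, "UAUAUAGCUGAAUCAUUUAAAG")

  expect_equal(nrow(group_by_seed(two[0, ])), 0)

  # override map reproduces externally fixed naming
  g3 <- group_by_seed(recs, name_override = c(CCACAGG = ".1", ACCACAG = ".2"))
  expect_identical(g3$suffix_name, c(".1", ".2"))
})

test_that("tail_composition counts nucleotides weighted by reads", {
  recs <- rbind(
    toy_records("UAUAUAGCUGAAUCAUUUAAAGA", 2, nontemplated_tail = "A"),
    toy_records("UAUAUAGCUGAAUCAUUUAAAGU", 1, nontemplated_tail = "U")
  )
  expect_equal(tail_composition(recs), c(A = 2, C = 0, G = 0, U = 1))
  empty <- toy_records("UAUAUAGCUGAAUCAUUUAAAG", 5)
  expect_equal(tail_composition(empty), c(A = 0, C = 0, G = 0, U = 0))
  expect_equal(tail_composition(empty[0, ]), c(A = 0, C = 0, G = 0, U = 0))
})

test_that("extra-adenylation rate is recovered from generated pools", {
  locus <- gen_locus(1)
  spec <- read_composition_spec(
    data.frame(five_prime_offset = c(0L, -1L),
               three_prime_templated = c(0L, 0L),
               nontemplated_tail = c("", ""), weight = c(0.5, 0.5)),
    total_depth = 1e5, tail_A_rate = 0.3)
  pool <- gen_read_pool(locus, spec, rng_seed = 13)
  res <- build_catalog(pool$reads, mature_refs(locus), locus_context(locus),
                       context_offset = nchar(locus$flank5))
  tc <- tail_composition(res$catalog)
  frac_a <- tc["A"] / sum(pool$reads$count)
  expect_lt(abs(frac_a - 0.3), 3 * sqrt(0.3 * 0.7 / 1e5))
})

test_that("catalog conserves counts and reproduces generator truth", {
  locus <- gen_locus(3)
  pool <- gen_read_pool(locus, default_composition(5e4, 0.3), rng_seed = 4)
  res <- build_catalog(pool$reads, mature_refs(locus), locus_context(locus),
                       context_offset = nchar(locus$flank5))
  expect_equal(nrow(res$rejects), 0)
  expect_equal(sum(res$catalog$count), sum(pool$reads$count))
  m <- merge(res$catalog, pool$truth, by = "sequence",
             suffixes = c(".obs", ".true"))
  expect_equal(nrow(m), nrow(pool$truth))
  expect_equal(m$five_prime_offset.obs, m$five_prime_offset.true)
  expect_equal(m$three_prime_offset.obs, m$three_prime_offset.true)
  expect_identical(m$nontemplated_tail.obs, m$nontemplated_tail.true)
  expect_identical(m$category.obs, m$category.true)
  expect_equal(m$templated.obs, m$templated.true)
  # category fractions over the catalog sum to 1
  expect_equal(sum(tapply(res$catalog$count, res$catalog$category, sum)) /
                 sum(res$catalog$count), 1)
})
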