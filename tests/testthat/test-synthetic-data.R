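test_that("gen_locus builds a valid two-arm locus, deterministically", {
  locus <- gen_locus(1, hairpin_length = 110, mature_length = 22)
  ann <- locus$mature_annotations
  expect_equal(nrow(ann), 2)
  expect_setequal(ann$arm, c("5p", "3p"))
  expect_equal(nchar(locus$hairpin_seq), 110)
  expect_true(all(ann$start >= 0 & ann$start + ann$length <= 110))
  # arms disjoint
  o <- order(ann$start)
  expect_true(ann$start[o][2] >= ann$start[o][1] + ann$length[o][1])
  # mature sequences are hairpin substrings at their coordinates
  refs <- mature_refs(locus)
  for (i in seq_len(nrow(refs))) {
    expect_identical(refs$sequence[i],
                     substr(locus$hairpin_seq, refs$start[i] + 1,
                            refs$start[i] + nchar(refs$sequence[i])))
  }
  expect_identical(gen_locus(1), gen_locus(1))
  expect_false(identical(gen_locus(1)$hairpin_seq, gen_locus(2)$hairpin_seq))
  expect_error(gen_locus(2, hairpin_length = 40, mature_length = 22),
               "hairpin_length")
})

test_that("gen_read_pool handles degenerate and tail-free mixtures", {
  locus <- gen_locus(1)
  one <- read_composition_spec(
    data.frame(five_prime_offset = 0L, three_prime_templated = 0L,
               nontemplated_tail = "", weight = 1),
    total_depth = 1000)
  pool <- gen_read_pool(locus, one, rng_seed = 5)
  ref3 <- mature_refs(locus)
  ref3 <- ref3[ref3$arm == "3p", ]
  expect_equal(nrow(pool$reads), 1)
  expect_identical(pool$reads$sequence, ref3$sequence)
  expect_equal(pool$reads$count, 1000)
  expect_true(all(pool$truth$templated))
  expect_true(all(pool$truth$category == "canonical"))

  templated_only <- read_composition_spec(
    data.frame(five_prime_offset = c(0L, -1L),
               three_prime_templated = c(0L, 1L),
               nontemplated_tail = c("", ""), weight = c(0.5, 0.5)),
    total_depth = 5000, tail_A_rate = 0)
  pool2 <- gen_read_pool(locus, templated_only, rng_seed = 6)
  expect_true(all(pool2$truth$templated))
  expect_equal(sum(pool2$truth$count), 5000)
})

test_that("gen_read_pool recovers mixture weights within binomial error", {
  locus <- gen_locus(1)
  spec <- read_composition_spec(
    data.frame(five_prime_offset = c(0L, -1L),
               three_prime_templated = c(0L, 0L),
               nontemplated_tail = c("", ""), weight = c(0.7, 0.3)),
    total_depth = 1e5)
  se <- sqrt(0.7 * 0.3 / 1e5)
  for (seed in 1:20) {
    pool <- gen_read_pool(locus, spec, rng_seed = seed)
    p_hat <- with(pool$truth, sum(count[five_prime_offset == 0]) / sum(count))
    expect_lt(abs(p_hat - 0.7), 3 * se)
  }
})

test_that("gen_read_pool rejects escapes and ambiguous tails", {
  locus <- gen_locus(1)
  escape <- read_composition_spec(
    data.frame(five_prime_offset = 0L, three_prime_templated = 50L,
               nontemplated_tail = "", weight = 1),
    total_depth = 10)
  expect_error(gen_read_pool(locus, escape, 1), "escapes")
  # next templated base downstream of the mature; a tail starting with it
  # is indistinguishable from templated extension
  refs <- mature_refs(locus)
  ref3 <- refs[refs$arm == "3p", ]
  ctx <- locus_context(locus)
  nb <- substr(ctx, nchar(locus$flank5) + ref3$start + 23,
               nchar(locus$flank5) + ref3$start + 23)
  amb <- read_composition_spec(
    data.frame(five_prime_offset = 0L, three_prime_templated = 0L,
               nontemplated_tail = nb, weight = 1),
    total_depth = 10)
  expect_error(gen_read_pool(locus, amb, 1), "indistinguishable")
})

test_that("gen_utrome plants exactly the requested sites", {
  m2 <- site_motifs(MIR140_3P_2, isomir = "iso2")
  plant <- data.frame(gene = "g1", isomir = "iso2", site_type = "8mer",
                      utr_position = 20L, stringsAsFactors = FALSE)
  u <- gen_utrome(5, plant, list(iso2 = m2), rng_seed = 3, utr_length = 120)
  hits <- site_table(u$utrs, m2)
  expect_equal(nrow(hits), 1)
  expect_identical(hits$gene, "g1")
  expect_identical(hits$site_type, "8mer")
  expect_equal(hits$position, 20L)

  expect_equal(length(gen_utrome(0, rng_seed = 1)$utrs), 0)

  # 6mer and 8mer planted in one gene: strongest site reports 8mer
  plant2 <- data.frame(gene = c("g1", "g1"), isomir = "iso2",
                       site_type = c("6mer", "8mer"),
                       utr_position = c(10L, 60L), stringsAsFactors = FALSE)
  u2 <- gen_utrome(3, plant2, list(iso2 = m2), rng_seed = 4, utr_length = 120)
  ss <- strongest_site(site_table(u2$utrs, m2))
  expect_identical(ss$strongest_site[ss$gene == "g1"], "8mer")

  expect_error(gen_utrome(2, data.frame(gene = "g1", isomir = "iso2",
                                        site_type = "8mer",
                                        utr_position = 115L),
                          list(iso2 = m2), 1, utr_length = 120),
               "does not fit")
})

test_that("gen_utrome background is seed-free away from planted sites", {
  m1 <- site_motifs(MIR140_3P_1, isomir = "iso1")
  m2 <- site_motifs(MIR140_3P_2, isomir = "iso2")
  plant <- data.frame(gene = paste0("g", 1:10), isomir = "iso1",
                      site_type = "7mer-m8", utr_position = 30L,
                      stringsAsFactors = FALSE)
  u <- gen_utrome(40, plant, list(iso1 = m1, iso2 = m2), rng_seed = 7,
                  utr_length = 150)
  # no occurrence of either 6mer core outside planted site spans; the
  # planted isomiR's core sits exactly at its anchor
  for (g in names(u$utrs)) {
    planted <- u$truth$utr_position[u$truth$gene == g]
    # 7mer-m8 span is [anchor-1, anchor+6)
    spans <- cbind(planted - 1, planted + 6)
    for (core in c(m1$six_mer, m2$six_mer)) {
      pos <- gregexpr(core, u$utrs[[g]], fixed = TRUE)[[1]]
      pos <- pos[pos > 0] - 1
      ok <- vapply(pos, function(p) {
        nrow(spans) > 0 && any(p < spans[, 2] & p + 6 > spans[, 1])
      }, logical(1))
      expect_true(all(ok))
    }
    m1_pos <- gregexpr(m1$six_mer, u$utrs[[g]], fixed = TRUE)[[1]]
    m1_pos <- m1_pos[m1_pos > 0] - 1
    expect_true(all(planted %in% m1_pos))
  }
})

test_that("gen_de_table plants effects with BH-adjusted z-test P", {
  exact <- gen_de_table(c("g1", "g2"), effect_delta = 1, noise_sd = 0,
                        n_genes = 10, rng_seed = 1)
  expect_equal(exact$log2fc[exact$gene %in% c("g1", "g2")], c(-1, -1))
  expect_equal(exact$log2fc[!exact$gene %in% c("g1", "g2")], rep(0, 8))
  expect_true(all(exact$adj_p[exact$gene %in% c("g1", "g2")] == 0))

  # null effect: mean target log2FC near 0 across replicate seeds
  means <- vapply(1:10, function(s) {
    de <- gen_de_table(paste0("g", 1:50), 0, 0.5, 500, s)
    mean(de$log2fc[de$gene %in% paste0("g", 1:50)])
  }, numeric(1))
  expect_lt(abs(mean(means)), 3 * 0.5 / sqrt(50 * 10))

  # CLT recovery at the planted effect
  tg <- paste0("g", 1:200)
  de <- gen_de_table(tg, 1, 0.5, 2000, rng_seed = 11)
  expect_lt(abs(mean(de$log2fc[de$gene %in% tg]) - (-1)), 3 * 0.5 / sqrt(200))

  expect_error(gen_de_table("not_a_gene", 1, 0.1, 10, 1), "universe")
})

test_that("gen_compendium couples mean target shift to host fold change", {
  noiseless <- gen_compendium(compendium_spec(
    n_studies = 30, host_gene = "HOST", coupling_beta = -0.4, noise_sd = 0,
    n_genes = 300, target_fraction = 0.1, rng_seed = 2))
  mt <- vapply(noiseless$studies, function(d) {
    mean(d$log2fc[d$gene %in% noiseless$targets])
  }, numeric(1))
  fit <- lm(mt ~ noiseless$manifest$host_log2fc)
  expect_equal(unname(coef(fit)[2]), -0.4, tolerance = 1e-12)
  expect_equal(suppressWarnings(summary(fit)$r.squared), 1, tolerance = 1e-12)

  # zero coupling, zero noise: exactly flat
  flat <- gen_compendium(compendium_spec(30, "HOST", 0, 0, 300, 0.1, 3))
  mtf <- vapply(flat$studies, function(d) {
    mean(d$log2fc[d$gene %in% flat$targets])
  }, numeric(1))
  expect_equal(unname(mtf), rep(0, 30), tolerance = 1e-12)

  # with study noise the OLS slope lands within 3 SE of the truth
  noisy <- gen_compendium(compendium_spec(124, "HOST", -0.4, 0.1, 500,
                                          0.1, 4))
  mtn <- vapply(noisy$studies, function(d) {
    mean(d$log2fc[d$gene %in% noisy$targets])
  }, numeric(1))
  sm <- summary(lm(mtn ~ noisy$manifest$host_log2fc))
  expect_lt(abs(sm$coefficients[2, 1] - (-0.4)), 3 * sm$coefficients[2, 2])

  expect_error(compendium_spec(1, "H", -0.4, 0.1, 100, 0.1, 1), "n_studies")
  expect_error(compendium_spec(5, "H", -0.4, 0.1, 100, 1.2, 1),
               "target_fraction")
})

test_that("generators are bit-reproducible for a fixed seed", {
  expect_identical(gen_locus(9), gen_locus(9))
  locus <- gen_locus(9)
  spec <- default_composition(5000, 0.3)
  expect_identical(gen_read_pool(locus, spec, 3), gen_read_pool(locus, spec, 3))
  m2 <- site_motifs(MIR140_3P_2, "iso2")
  plant <- data.frame(gene = "g1", isomir = "iso2", site_type = "7mer-A1",
                      utr_position = 10L)
  expect_identical(gen_utrome(10, plant, list(iso2 = m2), 5, 100),
                   gen_utrome(10, plant, list(iso2 = m2), 5, 100))
  expect_identical(gen_de_table("g1", 1, 0.3, 50, 7),
                   gen_de_table("g1", 1, 0.3, 50, 7))
  cs <- compendium_spec(5, "H", -0.2, 0.1, 100, 0.1, 8)
  expect_identical(gen_compendium(cs), gen_compendium(cs))
})
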