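test_that("name generators are reproducible and grammatical", {
  set.seed(101)
  a <- generate_chemical_name(5)
  set.seed(101)
  b <- generate_chemical_name(5)
  expect_identical(a, b)
  set.seed(102)
  names <- generate_chemical_name(1000)
  expect_true(all(matches_chemical_grammar(names)))
  n_tok <- lengths(strsplit(names, " "))
  expect_true(all(n_tok >= 2 & n_tok <= 5))
  set.seed(103)
  words <- generate_nonchemical_name(1000)
  toks <- unlist(strsplit(words, " "))
  expect_true(all(toks %in% abbrsim:::.biomed_words))
  expect_true(all(lengths(strsplit(words, " ")) >= 2))
  mean_len <- mean(nchar(words))
  expect_gt(mean_len, 2 * 4)    # >= 2 tokens of >= 4 letters plus separator
  expect_lt(mean_len, 5 * 11)   # <= 5 tokens of the longest word
})

test_that("chemical and non-chemical letter distributions differ", {
  set.seed(104)
  chem <- generate_chemical_name(800)
  other <- generate_nonchemical_name(800)
  tab <- rbind(letter_frequencies(chem), letter_frequencies(other))
  tab <- tab[, colSums(tab) > 0]
  test <- suppressWarnings(chisq.test(tab))
  expect_lt(test$p.value, 1e-3)
})

test_that("letter-frequency balancing pulls the aggregate profiles closer", {
  chisq_stat <- function(x) {
    tab <- rbind(x$a, x$b)
    tab <- tab[, colSums(tab) > 0]
    suppressWarnings(chisq.test(tab))$statistic
  }
  set.seed(105)
  chem <- generate_chemical_name(800)
  plain <- generate_nonchemical_name(800)
  balanced <- generate_nonchemical_name(800, match_letter_frequencies = TRUE)
  s_plain <- chisq_stat(list(a = letter_frequencies(chem),
                             b = letter_frequencies(plain)))
  s_bal <- chisq_stat(list(a = letter_frequencies(chem),
                           b = letter_frequencies(balanced)))
  expect_lt(s_bal, s_plain)
})

test_that("variants stay within the benign-edit envelope", {
  expect_identical(make_variants("diethyl ether", TRUE, 1), "diethyl ether")
  # rate 0: only hyphen/space swaps and plural inflection remain
  set.seed(106)
  for (i in 1:50) {
    v <- make_variants("diethyl ether", TRUE, 4, noise_rate = 0)
    expect_identical(sub("s$", "", gsub("[ -]", "", v)),
                     rep(gsub(" ", "", "diethyl ether"), 4))
  }
  # default rates: every variant within normalized edit distance 0.3
  set.seed(107)
  for (i in 1:50) {
    nm <- generate_chemical_name(1)
    v <- make_variants(nm, TRUE, 4)
    expect_true(all(normalized_edit_distance(v, nm) <= 0.3))
    nm2 <- generate_nonchemical_name(1)
    v2 <- make_variants(nm2, FALSE, 4)
    expect_true(all(normalized_edit_distance(v2, nm2) <= 0.3))
  }
  # chemical compound tokens are never corrupted by noise
  set.seed(108)
  for (i in 1:50) {
    v <- make_variants("monomethyl glycol", TRUE, 5, noise_rate = 1,
                       noise_chars = "q")
    expect_true(all(grepl("^monomethyl[ -]", v)))
  }
})

test_that("near misses are distinct grammatical names within edit distance 2", {
  set.seed(109)
  for (i in 1:200) {
    nm <- generate_chemical_name(1)
    miss <- make_near_miss(nm)
    expect_false(identical(miss, nm))
    expect_lte(edit_distance(nm, miss), 2L)
    expect_true(matches_chemical_grammar(miss))
  }
  expect_error(make_near_miss("glycol ether"), "compound token")
})

test_that("dataset generation is deterministic and respects the config", {
  cfg <- generator_config(n_concepts_chemical = 0, n_concepts_other = 5,
                          variants_per_concept = 1, collision_group_size = 1,
                          seed = 42)
  d <- generate_dataset(cfg)
  expect_identical(nrow(d), 5L)
  expect_true(all(!d$is_chemical))
  expect_identical(nrow(generate_candidates(d)), 0L)
  cfg2 <- generator_config(n_concepts_chemical = 40, n_concepts_other = 40,
                           seed = 7)
  d1 <- generate_dataset(cfg2)
  d2 <- generate_dataset(cfg2)
  expect_identical(d1, d2)
  expect_setequal(unique(d1$is_chemical), c(TRUE, FALSE))
  # within a concept all variant pairs are gold-true; near misses sit close
  cand <- generate_candidates(d1[d1$is_chemical, ])
  expect_true(all(cand$gold[cand$concept_id_1 == cand$concept_id_2]))
  expect_false(any(cand$gold[cand$concept_id_1 != cand$concept_id_2]))
})

test_that("near-miss neighbors create hard negatives in the chemical subset", {
  cfg <- generator_config(n_concepts_chemical = 60, n_concepts_other = 0,
                          near_miss_rate = 1, variant_noise_rate = 0,
                          variants_per_concept = 1, seed = 13)
  d <- generate_dataset(cfg)
  cand <- score_pairs(generate_candidates(d), "edit")
  neg <- cand[!cand$gold, ]
  expect_gt(nrow(neg), 0)
  # with one variant per concept and no noise, every base near-miss pair is
  # at raw edit distance <= 2
  raw <- edit_distance(neg$full_form_1, neg$full_form_2)
  expect_true(any(raw <= 2))
})

test_that("gold-true pair fraction matches the count-level expectation", {
  cfg <- generator_config(seed = 17)
  d <- generate_dataset(cfg)
  # independent count-level simulation of the configured group structure
  sim_fraction <- function(chemical, n_groups = 20000) {
    set.seed(999)
    gold <- 0; total <- 0
    for (g in seq_len(n_groups)) {
      m <- 1 + rpois(1, cfg$collision_group_size - 1)
      if (chemical) m <- m + rbinom(1, m, cfg$near_miss_rate)
      v <- 1 + rpois(m, cfg$variants_per_concept - 1)
      gold <- gold + sum(choose(v, 2))
      total <- total + choose(sum(v), 2)
    }
    gold / total
  }
  for (chem in c(TRUE, FALSE)) {
    cand <- generate_candidates(d[d$is_chemical == chem, ])
    measured <- mean(cand$gold)
    expected <- sim_fraction(chem)
    expect_gt(measured, expected * 0.8)
    expect_lt(measured, expected * 1.2)
  }
})
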