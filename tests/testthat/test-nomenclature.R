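test_that("vocabulary construction, ids and specials behave", {
  v <- term_vocabulary(c("benz", "ene", "ol"))
  expect_equal(v$n_base, 3L)
  expect_equal(vocab_size(v), 5L)
  expect_equal(term_ids(v, c("benz", "ol")), c(1L, 3L))
  expect_equal(startseq_id(v), 4L)
  expect_equal(endseq_id(v), 5L)
  expect_error(term_vocabulary(c("ene", "ene")), "duplicate")
  expect_error(term_vocabulary(character()), "at least one")
  expect_error(term_vocabulary(c("a", "startseq")), "reserved")
})

test_that("vocabulary files round-trip and the loader rejects bad input", {
  v <- toy_vocab()
  f <- withr::local_tempfile(fileext = ".tsv")
  write_term_vocabulary(v, f)
  v2 <- load_term_vocabulary(f)
  expect_identical(v2$terms, v$terms)
  expect_identical(v2$is_attribute, v$is_attribute)

  writeLines(c("ene\t0", "ene\t1"), f)
  expect_error(load_term_vocabulary(f), "duplicate term.*ene")
  writeLines(character(), f)
  expect_error(load_term_vocabulary(f), "empty")
  expect_error(load_term_vocabulary(file.path(tempdir(), "nope.tsv")),
               "not found")
})

test_that("packaged vocabularies satisfy their schema", {
  red <- default_vocabulary()
  expect_gt(sum(red$is_attribute), 0L)
  full <- full_schema_vocabulary()
  expect_equal(full$n_base, 199L)
  expect_equal(sum(full$is_attribute), 100L)
})

test_that("tokenization reproduces names and reports uncovered positions", {
  v <- default_vocabulary()
  s <- tokenize_name("perylene-1,12-diol", v)
  expect_identical(s$terms[1:6], c("per", "yl", "ene", "-", "1", ","))
  expect_identical(detokenize(s), "perylene-1,12-diol")
  expect_identical(tokenize_name("dibenzothiophene", v)$terms,
                   c("di", "benzo", "thi", "oph", "ene"))
  expect_error(tokenize_name("", v), "non-empty")
  expect_error(tokenize_name("benzeneX", v), "position 8")
})

test_that("greedy tokenizer with backtracking matches the exhaustive oracle", {
  # backtracking case from a deliberately ambiguous toy vocabulary
  v1 <- term_vocabulary(c("benz", "ene", "benzen"))
  expect_identical(tokenize_name("benzene", v1)$terms, c("benz", "ene"))
  v2 <- term_vocabulary(c("benz", "ene", "benzen", "e"))
  expect_identical(tokenize_name("benzene", v2)$terms, c("benzen", "e"))

  set.seed(42)
  alphabet <- c("a", "b", "c")
  for (rep in 1:40) {
    terms <- unique(replicate(sample(3:8, 1), paste(
      sample(alphabet, sample(1:3, 1), replace = TRUE), collapse = "")))
    vv <- term_vocabulary(terms)
    name <- paste(sample(terms, sample(2:6, 1), replace = TRUE),
                  collapse = "")
    want <- oracle_greedy_segmentation(name, terms)
    got <- tokenize_name(name, vv)
    expect_identical(got$terms, want)
    expect_identical(detokenize(got), name)
  }
})

test_that("detokenize is plain concatenation", {
  v <- default_vocabulary()
  expect_identical(detokenize(term_sequence(character(), v)), "")
  expect_identical(detokenize(term_sequence(c("benz", "ene"), v)), "benzene")
  expect_identical(
    detokenize(term_sequence(
      c("per", "yl", "ene", "-", "1", ",", "12", "-", "di", "ol"), v)),
    "perylene-1,12-diol")
})

test_that("attribute extraction dedupes, sorts and ignores non-attributes", {
  v <- term_vocabulary(c("chlor", "o", "brom", "phen", "ol", "-"),
                       attributes = c("chlor", "brom", "phen", "ol"))
  s <- term_sequence(c("chlor", "o", "chlor", "o", "phen", "ol"), v)
  a <- extract_attributes(s, v)
  expect_identical(a$attributes, c("ol", "phen", "chlor"))

  s2 <- term_sequence(c("brom", "o", "phen", "ol"), v)
  expect_identical(extract_attributes(s2, v)$attributes,
                   oracle_attribute_sort(c("brom", "phen", "ol")))
  expect_identical(extract_attributes(s2, v)$attributes,
                   c("ol", "brom", "phen"))
  # descending length, alphabetical order within equal lengths unchanged
  expect_identical(extract_attributes(s2, v, "desc")$attributes,
                   c("brom", "phen", "ol"))

  expect_length(extract_attributes(term_sequence(character(), v), v), 0L)

  # idempotent and order-independent
  set.seed(7)
  for (i in 1:10) {
    terms <- sample(c("chlor", "o", "brom", "phen", "ol", "-"), 8,
                    replace = TRUE)
    a1 <- extract_attributes(term_sequence(terms, v), v)
    a2 <- extract_attributes(term_sequence(sample(terms), v), v)
    expect_identical(a1$attributes, a2$attributes)
  }
})

test_that("admission filters enforce length, attribute count and vocabulary", {
  v <- default_vocabulary()
  # boundary: 57 terms, few attributes -> admitted
  s57 <- term_sequence(rep(c("benz", "ene", "-"), length.out = 57), v)
  expect_true(passes_filters(s57, v)$pass)
  s58 <- term_sequence(rep(c("benz", "ene", "-"), length.out = 58), v)
  flt <- passes_filters(s58, v)
  expect_false(flt$pass)
  expect_identical(flt$reason, "length")

  # attribute-count boundary on a synthetic wide vocabulary
  wide <- term_vocabulary(sprintf("q%02d", 1:20),
                          attributes = sprintf("q%02d", 1:20))
  s17 <- term_sequence(sprintf("q%02d", 1:17), wide)
  expect_true(passes_filters(s17, wide)$pass)
  s18 <- term_sequence(sprintf("q%02d", 1:18), wide)
  expect_identical(passes_filters(s18, wide)$reason, "attributes")

  # out-of-vocabulary
  s_oov <- structure(list(terms = c("benz", "xx"), ids = c(1L, NA_integer_)),
                     class = "term_sequence")
  expect_identical(passes_filters(s_oov, v)$reason, "vocabulary")

  # monotonicity: removing terms never causes a length/attribute rejection
  set.seed(3)
  for (i in 1:10) {
    terms <- sample(v$terms[seq_len(v$n_base)], 30, replace = TRUE)
    s_full <- term_sequence(terms, v)
    if (!passes_filters(s_full, v)$pass) next
    keep <- sort(sample(30, 15))
    expect_true(passes_filters(term_sequence(terms[keep], v), v)$pass)
  }
})
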