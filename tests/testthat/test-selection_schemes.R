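test_that("orders are reproducible bijections; lex order is the identity", {
  o1 <- random_order(4, 3, 99)
  o2 <- random_order(4, 3, 99)
  expect_identical(o1$key, o2$key)
  expect_setequal_num(o1$key, 0:63)
  expect_false(identical(o1$key, random_order(4, 3, 100)$key))
  expect_equal(lex_order(2, 4)$key, 0:15)
  expect_equal(o1$seed, 99L)
})

test_that("syncmer selection follows the left-most minimal s-mer rule", {
  ## tie between equal minimal 5-mers at offsets 0 and 2 -> not selected at t=2
  phi <- syncmer_set(9, 4, 5, 2)
  expect_false(ks_contains(phi, encode_kmers("ACACACACA", 4)))
  ## ...but the k-mer with its unique minimal 5-mer at offset 2 is selected
  expect_true(ks_contains(phi, encode_kmers("TTAAAAATT", 4)))
  ## minimal 2-mer "AA" left-most at 0
  phi2 <- syncmer_set(3, 4, 2, 0)
  expect_true(ks_contains(phi2, encode_kmers("AAC", 4)))
  expect_false(ks_contains(phi2, encode_kmers("CAA", 4)))
  expect_error(syncmer_set(6, 2, 3, 5), "t <= k - s")
})

test_that("t = 0 syncmers are decycling for any seeded order", {
  for (seed in c(1, 7, 1234)) {
    phi <- syncmer_set(6, 2, 3, 0, order = random_order(2, 3, seed))
    expect_true(is_decycling(phi))
  }
})

test_that("syncmer sets over t partition the k-mer space", {
  ord <- random_order(2, 3, 5)
  sets <- lapply(0:3, function(t) syncmer_set(6, 2, 3, t, order = ord))
  allm <- sort(unlist(lapply(sets, ks_members)))
  expect_equal(allm, 0:63)                                # disjoint cover
})

test_that("parameterized syncmers generalize syncmers", {
  ## full mask selects everything
  full <- parameterized_syncmer_set(6, 2, 3, 0:3)
  expect_equal(length(full), 64)
  ## singleton masks equal plain syncmers across random specs
  set.seed(2)
  for (i in 1:50) {
    sigma <- sample(c(2, 4), 1)
    k <- sample(4:7, 1)
    s <- sample(2:(k - 1), 1)
    t <- sample(0:(k - s), 1)
    ord <- random_order(sigma, s, i)
    expect_equal(ks_members(parameterized_syncmer_set(k, sigma, s, t, ord)),
                 ks_members(syncmer_set(k, sigma, s, t, ord)))
  }
  ## masks containing 0 are decycling
  for (seed in c(3, 8)) {
    phi <- parameterized_syncmer_set(6, 2, 3, c(0, 2),
                                     order = random_order(2, 3, seed))
    expect_true(is_decycling(phi))
  }
  expect_error(parameterized_syncmer_set(6, 2, 3, integer(0)), "non-empty")
})

test_that("fractional sets have exact cardinality round(f * sigma^k)", {
  expect_equal(length(fractional_set(4, 2, 1)), 16)
  ## the f = 1/(k-s+1) configuration at reduced scale: 10% of 2^10
  phi <- fractional_set(10, 2, 0.1, seed = 4)
  expect_equal(length(phi), round(0.1 * 2^10))
  expect_equal(relative_size(phi), round(0.1 * 1024) / 1024)
  set.seed(9)
  for (i in 1:20) {
    f <- runif(1, 0.05, 1)
    phi <- fractional_set(6, 2, f, seed = i)
    expect_equal(length(phi), round(f * 64))
  }
  ## same seed reproduces, different seed differs
  expect_equal(ks_members(fractional_set(8, 2, .3, 7)),
               ks_members(fractional_set(8, 2, .3, 7)))
})

test_that("mykkeltveit_set: one per PCR, decycling, published cardinalities", {
  expect_equal(length(mykkeltveit_set(5, 2)), 8)
  expect_equal(length(mykkeltveit_set(7, 4)), 2344)
  for (k in 3:8) {
    phi <- mykkeltveit_set(k, 2)
    expect_equal(length(phi), necklace_count(2, k))
    expect_true(is_decycling(phi))
    ## exactly one member per PCR
    cls <- pcr_classes(k, 2)
    hits <- vapply(cls, function(cy) sum(ks_contains(phi, cy)), numeric(1))
    expect_true(all(hits == 1))
  }
  for (k in 3:6) {
    phi <- mykkeltveit_set(k, 4)
    expect_equal(length(phi), necklace_count(4, k))
    expect_true(is_decycling(phi))
  }
})

test_that("mykkeltveit longest paths match the published per-k statistics", {
  ## printed values 11 and 21 count the k-mers on the path (= edges + 1)
  expect_equal(longest_path(mykkeltveit_set(5, 2)), 10)
  expect_equal(longest_path(mykkeltveit_set(6, 2)), 20)
  expect_equal(longest_path(mykkeltveit_set(7, 2)), 26)
})

test_that("champarnaud_set: one per PCR, decycling, distinct from mykkeltveit", {
  expect_equal(length(champarnaud_set(7, 2)), 20)
  for (k in 3:8) {
    phi <- champarnaud_set(k, 2)
    expect_equal(length(phi), necklace_count(2, k))
    expect_true(is_decycling(phi))
    cls <- pcr_classes(k, 2)
    hits <- vapply(cls, function(cy) sum(ks_contains(phi, cy)), numeric(1))
    expect_true(all(hits == 1))
  }
  for (k in 4:6) {
    phi <- champarnaud_set(k, 4)
    expect_equal(length(phi), necklace_count(4, k))
    expect_true(is_decycling(phi))
  }
  for (k in 5:8)
    expect_false(identical(ks_members(champarnaud_set(k, 2)),
                           ks_members(mykkeltveit_set(k, 2))))
})

test_that("expected density equals relative set size on uniform sequences", {
  S <- random_sequence(1e5, 2, seed = 31)
  for (phi in list(fractional_set(10, 2, 0.1, 2),
                   syncmer_set(8, 2, 4, 0, order = random_order(2, 4, 3)))) {
    p <- relative_size(phi)
    n <- nchar(S) - phi$k + 1
    se <- sqrt(p * (1 - p) / n)
    expect_lt(abs(sketch_density(S, phi) - p), 3 * se)
  }
})
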