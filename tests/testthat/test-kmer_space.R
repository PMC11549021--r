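test_that("alphabet validates sigma and builds an involutive complement", {
  ab <- alphabet(4)
  expect_equal(ab$glyphs, c("A", "C", "G", "T"))
  expect_equal(ab$complement, c(3L, 2L, 1L, 0L))
  expect_true(all(ab$complement[ab$complement + 1] == 0:3))
  expect_false(any(ab$complement == 0:3))       # no fixed point
  expect_error(alphabet(3), "even")
  expect_error(alphabet(1), ">= 2")
})

test_that("encode/decode round-trips and rank order is lexicographic", {
  for (sigma in c(2, 4)) {
    k <- 5
    all <- 0:(sigma^k - 1)
    strs <- decode_kmers(all, k, sigma)
    expect_equal(encode_kmers(strs, sigma), all)
    expect_identical(order(strs), order(all))    # lex order == rank order
  }
  expect_equal(decode_kmers(encode_kmers("acgt", 4), 4, 4), "ACGT")
  expect_error(encode_kmers("ABC", 4), "outside the alphabet")
})

test_that("reverse complement matches examples and is an involution", {
  ## the classic self-reverse-complement binary example
  r <- encode_kmers("0011", 2)
  expect_equal(rc_kmers(r, 4, 2), r)
  expect_equal(decode_kmers(rc_kmers(encode_kmers("TTT", 4), 3, 4), 3, 4), "AAA")
  set.seed(7)
  for (sigma in c(2, 4)) {
    k <- 7
    m <- sample(0:(sigma^k - 1), 1000, replace = TRUE)
    expect_equal(rc_kmers(rc_kmers(m, k, sigma), k, sigma), m)
    ## string-level oracle
    sub <- m[1:25]
    expect_equal(decode_kmers(rc_kmers(sub, k, sigma), k, sigma),
                 vapply(decode_kmers(sub, k, sigma), oracle_rc,
                        character(1), sigma = sigma, USE.NAMES = FALSE))
  }
})

test_that("canonical is idempotent and no odd-k binary k-mer is self-rc", {
  for (k in 2:6) {
    all <- 0:(2^k - 1)
    can <- canonical_kmers(all, k, 2)
    expect_equal(canonical_kmers(can, k, 2), can)        # idempotent
    expect_true(all(can <= all))
  }
  ## odd k: middle symbol would need to equal its own complement
  all5 <- 0:(2^5 - 1)
  expect_true(all(rc_kmers(all5, 5, 2) != all5))
  expect_equal(decode_kmers(canonical_kmers(encode_kmers("TTT", 4), 3, 4), 3, 4),
               "AAA")
})

test_that("canonical partition covers the space; overlap is the self-rc set", {
  cp <- canonical_partition(4, 2)
  inter <- ks_intersect(cp$C, cp$Crc)
  expect_equal(length(inter), 4)                         # sigma^(k/2)
  expect_equal(length(ks_union(cp$C, cp$Crc)), 16)
  cp5 <- canonical_partition(5, 2)
  expect_equal(length(ks_intersect(cp5$C, cp5$Crc)), 0)
  cp43 <- canonical_partition(3, 4)
  expect_equal(length(ks_union(cp43$C, cp43$Crc)), 64)
})

test_that("rotate is a left rotation with period k and a de Bruijn edge", {
  expect_equal(decode_kmers(rotate_kmers(encode_kmers("000010", 2), 6, 2), 6, 2),
               "000100")
  set.seed(1)
  m <- sample(0:(4^6 - 1), 50)
  r <- m
  for (i in 1:6) r <- rotate_kmers(r, 6, 4)
  expect_equal(r, m)
  succ <- successor_kmers(m, 6, 4)
  expect_true(all(rotate_kmers(m, 6, 4) == succ[cbind(seq_along(m),
               (m %/% 4^5) + 1)]))
})

test_that("PCRs partition the space with sizes dividing k", {
  for (spec in list(c(2, 5, 8), c(2, 6, 14), c(4, 7, 2344))) {
    sigma <- spec[1]; k <- spec[2]
    cls <- pcr_classes(k, sigma)
    expect_equal(length(cls), spec[3])
    expect_equal(sort(unlist(cls)), 0:(sigma^k - 1))     # partition
    expect_true(all(k %% lengths(cls) == 0))             # sizes divide k
    expect_true(all(vapply(cls, function(cy)
      all(rotate_kmers(cy, k, sigma) %in% cy), logical(1))))
  }
})

test_that("rc maps PCRs onto PCRs (same size, reversed order)", {
  k <- 6; sigma <- 2
  cls <- pcr_classes(k, sigma)
  necks <- vapply(cls, min, numeric(1))
  for (cyc in cls) {
    img <- rc_of_pcr(cyc, k, sigma)
    expect_equal(length(img), length(cyc))
    expect_true(min(img) %in% necks)                 # image is a real PCR
    expect_setequal_num(img, rc_kmers(cyc, k, sigma))
  }
  ## homopolymer PCR maps to the complementary homopolymer
  expect_equal(rc_of_pcr(0, k, sigma), sigma^k - 1)
  ## a PCR containing a self-rc k-mer maps to itself (k=4 exhaustive)
  cls4 <- pcr_classes(4, 2)
  for (cyc in cls4) {
    if (any(rc_kmers(cyc, 4, 2) == cyc))
      expect_setequal_num(rc_of_pcr(cyc, 4, 2), cyc)
  }
})

test_that("necklace_count matches enumeration and the published values", {
  for (sigma in c(2, 4)) for (k in 1:8) {
    if (sigma^k > 2^17) next
    expect_equal(necklace_count(sigma, k), length(pcr_classes(k, sigma)),
                 info = paste(sigma, k))
  }
  expect_equal(necklace_count(2, 5), 8)
  expect_equal(necklace_count(4, 7), 2344)
  ## analytic relative size at full scale, no enumeration
  expect_equal(round(100 * necklace_count(4, 15) / 4^15, 2), 6.67)
  ## string-rotation oracle at small size
  expect_equal(necklace_count(2, 6), oracle_pcr_count(6, 2))
  expect_equal(necklace_count(4, 3), oracle_pcr_count(3, 4))
})

test_that("kmer_set algebra, membership and io round-trip", {
  phi <- kmer_set(c(5, 1, 5, 9), 3, 4)
  expect_equal(ks_members(phi), c(1, 5, 9))              # sorted unique
  expect_equal(length(phi), 3)
  expect_equal(relative_size(phi), 3 / 64)
  expect_true(all(ks_contains(phi, c(1, 9))))
  psi <- kmer_set(c(9, 11), 3, 4)
  expect_equal(ks_members(ks_union(phi, psi)), c(1, 5, 9, 11))
  expect_equal(ks_members(ks_intersect(phi, psi)), 9)
  expect_equal(ks_members(ks_setdiff(phi, psi)), c(1, 5))
  expect_equal(length(ks_complement(phi)), 61)
  f <- tempfile(fileext = ".txt")
  write_kmer_set(phi, f)
  expect_identical(readLines(f)[1], "#sigma=4 k=3")
  back <- read_kmer_set(f)
  expect_equal(ks_members(back), ks_members(phi))
  writeLines(c("#sigma=4 k=3", "ACGT"), f)
  expect_error(read_kmer_set(f), "length")
  expect_error(kmer_set(1, 3, 4) |> ks_union(kmer_set(1, 4, 4)),
               "different")
})
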