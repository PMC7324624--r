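test_that("fragment extraction pads termini and preserves window length", {
  expect_identical(extract_fragment("MKSTE", 2, 2), "XMKST")
  expect_identical(extract_fragment("AAAKAAA", 4, 3), "AAAKAAA")
  # length 2n+1 for every half-width, center always K
  seq <- paste(c(rep("A", 40), "K", rep("C", 40)), collapse = "")
  for (n in 5:19) {
    fr <- extract_fragment(seq, 41, n)
    expect_identical(nchar(fr), 2L * n + 1L)
    expect_identical(substr(fr, n + 1, n + 1), "K")
  }
  # interior sites equal the raw slice (round trip, no padding)
  expect_identical(extract_fragment(seq, 41, 15), substr(seq, 26, 56))
  # padding appears only at termini, and only as much as is missing
  expect_identical(extract_fragment("KAAAA", 1, 3), "XXXKAAA")
  expect_identical(extract_fragment("AAAAK", 5, 3), "AAAKXXX")
})

test_that("fragment extraction rejects bad centers and positions", {
  expect_error(extract_fragment("MKSTE", 3, 2), "not 'K'")
  expect_warning(fr <- extract_fragment("MKSTE", 3, 2, strict = FALSE),
                 "non-K center")
  expect_identical(fr, NA_character_)
  expect_error(extract_fragment("MKSTE", 9, 2), "out of range")
})

test_that("lysine enumeration finds all and only K positions", {
  expect_identical(enumerate_lysines("KAKA"), c(1L, 3L))
  expect_identical(enumerate_lysines("AAAA"), integer(0))
  expect_identical(enumerate_lysines("K"), 1L)
})

test_that("greedy redundancy reduction matches the all-pairs identity oracle", {
  expect_identical(reduce_redundancy(c("AAAA", "AAAA", "CCCC"), 0.40),
                   c(1L, 3L))
  # distinct inputs at threshold 1.0 are all retained
  expect_identical(reduce_redundancy(c("AAAA", "AAAC", "CCCC"), 1.0), 1:3)
  # random fragments with low mutual identity: oracle confirms all retained
  set.seed(42)
  frs <- replicate(10, random_fragment(31))
  ids <- outer(frs, frs, Vectorize(brute_identity))
  diag(ids) <- 0
  expect_true(max(ids) < 0.40)  # construction check via the oracle
  expect_identical(reduce_redundancy(frs, 0.40), 1:10)
  # idempotence
  set.seed(7)
  mix <- c(frs, frs[1:3], replicate(5, random_fragment(31)))
  k1 <- reduce_redundancy(mix, 0.40)
  expect_identical(reduce_redundancy(mix[k1], 0.40), seq_along(k1))
  # X padding never counts as a match
  expect_identical(seq_identity("XXAK", "XXCK"), 0.25)
})

test_that("cross-class filtering agrees with the brute-force all-pairs filter", {
  pos <- c("AAKAA", "CCKCC")
  expect_identical(cross_class_filter(pos, c("AAKAA", "GGKGG"), 0.40), 2L)
  # disjoint alphabets leave negatives untouched
  expect_identical(cross_class_filter("AAKAA", c("CCKCC", "GGKGG"), 0.40), 1:2)
  set.seed(13)
  p <- replicate(8, random_fragment(15))
  ng <- c(replicate(8, random_fragment(15)), p[1:2])
  oracle <- which(vapply(ng, function(x)
    all(vapply(p, function(y) brute_identity(x, y) < 0.40, logical(1))),
    logical(1), USE.NAMES = FALSE))
  expect_identical(cross_class_filter(p, ng, 0.40), oracle)
})

test_that("stratified splits are reproducible and preserve class balance", {
  labels <- rep(c(1L, 0L), c(20L, 80L))
  s1 <- split_dataset(labels, 0.8, seed = 5)
  s2 <- split_dataset(labels, 0.8, seed = 5)
  expect_identical(s1$train, s2$train)
  expect_length(s1$train, 80L)
  expect_length(intersect(s1$train, s1$test), 0L)
  # per-class proportions preserved within one item
  expect_equal(sum(labels[s1$train]), 16L)
  s3 <- split_dataset(labels, 0.8, seed = 6)
  expect_false(identical(s1$train, s3$train))
  # 7:3 on 10 records
  s <- split_dataset(rep(c(1L, 0L), c(4L, 6L)), 0.7, seed = 1)
  expect_length(s$train, 7L)
  expect_error(split_dataset(c(1L, rep(0L, 9L)), 0.8, 1), "at least 2")
})

test_that("FASTA and site-table round trips reproduce generator fragments", {
  pr <- generate_annotated_proteome(4, c(80, 120), site_rate = 0.5,
                                    window = 15L, seed = 21)
  fa <- tempfile(fileext = ".fasta"); cs <- tempfile(fileext = ".csv")
  write_proteome(pr, fa, cs)
  seqs <- read_fasta(fa)
  sites <- read_site_table(cs)
  expect_identical(sort(names(seqs)), sort(names(pr$sequences)))
  fr <- build_fragments(seqs, sites, 7L)
  expect_identical(fr$fragment, pr$fragments)
  expect_true(all(mapply(function(id, p) substr(seqs[[id]], p, p) == "K",
                         sites$protein_id, sites$position)))
  # TSV variant of the site table parses identically
  ts <- tempfile(fileext = ".tsv")
  utils::write.table(sites, ts, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_identical(read_site_table(ts), sites)
})
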