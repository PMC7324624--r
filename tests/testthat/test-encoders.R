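test_that("AAC excludes the center, sums to 1 and has 21 dimensions", {
  v <- encode_aac(paste(rep("K", 15), collapse = ""))
  expect_length(v, 21L)
  expect_equal(unname(v["K"]), 1)
  v2 <- encode_aac("AAAAAAAKCCCCCCC")
  expect_equal(unname(v2[c("A", "C")]), c(0.5, 0.5))
  expect_equal(unname(v2["K"]), 0)  # the site itself is not counted
  set.seed(3)
  sums <- vapply(seq_len(1000), function(i) {
    sum(encode_aac(random_fragment(sample(c(11L, 21L, 31L, 35L), 1))))
  }, numeric(1))
  expect_equal(sums, rep(1, 1000))
})

test_that("one-hot drops the center row and is consistent with AAC", {
  m <- encode_onehot(paste(c(rep("A", 15), "K", rep("C", 15)), collapse = ""))
  expect_identical(dim(m), c(30L, 21L))
  expect_true(all(rowSums(m) == 1))
  m3 <- encode_onehot("AKC")
  expect_equal(unname(which(m3[1, ] == 1)), which(aa_alphabet() == "A"))
  expect_equal(unname(which(m3[2, ] == 1)), which(aa_alphabet() == "C"))
  # column sums equal 2n * AAC over the same flanks
  set.seed(8)
  f <- random_fragment(25)
  expect_equal(unname(colSums(encode_onehot(f))), unname(24 * encode_aac(f)))
})

test_that("PAAC matches the printed dimension and a brute-force theta oracle", {
  f <- paste(c(rep("A", 8), "K", rep("C", 8)), collapse = "")
  v <- encode_paac(f, lambda = 13L)
  expect_length(v, 34L)  # 21 composition + 13 correlation tiers
  expect_equal(sum(v), 1)
  # homopolymer flanks and center give a single non-center property profile
  allk <- paste(rep("K", 29), collapse = "")
  vk <- encode_paac(allk)
  expect_equal(unname(vk[22:34]), rep(0, 13))  # zero property differences
  expect_equal(unname(vk["K"]), 1)
  # theta oracle on a heterogeneous fragment
  set.seed(5)
  f2 <- random_fragment(31)
  v2 <- encode_paac(f2, lambda = 13L, w = 0.05)
  th <- brute_theta(strsplit(f2, "")[[1]], 13L)
  den <- 1 + 0.05 * sum(th)
  expect_equal(unname(v2[22:34]), 0.05 * th / den, tolerance = 1e-12)
  # w = 0 reduces to the plain 21-letter composition
  v0 <- encode_paac(f2, w = 0)
  expect_equal(sum(v0[22:34]), 0)
  comp <- table(factor(strsplit(f2, "")[[1]], levels = aa_alphabet())) / 31
  expect_equal(unname(v0[1:21]), as.numeric(comp))
  # short windows fail loudly with the minimum stated
  expect_error(encode_paac("AAAAAKAAAAA"), "minimum window")
})

test_that("padded fragments keep PAAC usable-residue accounting", {
  # window 29 with 1 X pad: 28 usable residues >= lambda + 1
  f <- paste(c("X", rep("A", 13), "K", rep("C", 14)), collapse = "")
  expect_equal(sum(encode_paac(f)), 1)
  # X mass shows up in the composition block
  expect_gt(encode_paac(f)[["X"]], 0)
})

test_that("information-gain selection finds separating properties", {
  # two-class set: positives all-E flanks, negatives all-G flanks
  pos <- rep(paste(c(rep("E", 7), "K", rep("E", 7)), collapse = ""), 12)
  neg <- rep(paste(c(rep("G", 7), "K", rep("G", 7)), collapse = ""), 12)
  y <- rep(c(1L, 0L), each = 12L)
  tab <- synthetic_aaindex(10L)
  # a property constant across residues contributes zero gain
  tab <- rbind(tab, CONST00001 = rep(1, 20))
  sel <- select_properties_by_ig(c(pos, neg), y, k = 11L, table = tab)
  expect_s3_class(sel, "property_selection")
  expect_equal(sel$gains[sel$ids == "CONST00001"], 0)
  # any property separating E from G reaches positional IG = H(label), so the
  # summed gain over the 14 flank positions is 14 * H(label)
  expect_equal(max(sel$gains), 14 * brute_entropy(y))
  expect_true(all(diff(sel$gains) <= 1e-12))
  expect_error(select_properties_by_ig(c(pos, neg), y, k = 600L), "exceeds")
  # permutation invariance to sample order
  set.seed(2)
  p <- sample(length(y))
  sel2 <- select_properties_by_ig(c(pos, neg)[p], y[p], k = 11L, table = tab)
  expect_identical(sel$ids, sel2$ids)
})

test_that("AAindex encoding matches printed shapes and zeroes padding", {
  sel46 <- structure(list(ids = rownames(synthetic_aaindex(46L)),
                          gains = rep(1, 46), k = 46L,
                          values = synthetic_aaindex(46L)),
                     class = "property_selection")
  f33 <- paste(c(rep("A", 16), "K", rep("C", 16)), collapse = "")
  m <- encode_aaindex(f33, sel46)
  expect_identical(dim(m), c(32L, 46L))
  # single known property/residue entry equals the table value
  expect_equal(unname(m[1, "KYTJ820101"]),
               synthetic_aaindex(1)["KYTJ820101", "A"])
  fpad <- paste(c("X", "X", rep("A", 14), "K", rep("C", 16)), collapse = "")
  mp <- encode_aaindex(fpad, sel46)
  expect_true(all(mp[1:2, ] == 0))
  sel30 <- structure(list(ids = rownames(synthetic_aaindex(30L)),
                          gains = rep(1, 30), k = 30L,
                          values = synthetic_aaindex(30L)),
                     class = "property_selection")
  f27 <- paste(c(rep("A", 13), "K", rep("C", 13)), collapse = "")
  expect_identical(dim(encode_aaindex(f27, sel30)), c(26L, 30L))
})

test_that("the synthetic property table is stable and anchored", {
  tab <- synthetic_aaindex()
  expect_identical(dim(tab), c(531L, 20L))
  expect_false(anyNA(tab))
  expect_equal(tab["KYTJ820101", "I"], 4.5)   # Kyte-Doolittle isoleucine
  expect_equal(tab["HOPT810101", "K"], 3.0)   # Hopp-Woods lysine
  expect_identical(tab, synthetic_aaindex())  # deterministic
})

test_that("the AAindex1 flat-file parser reads H/I blocks and drops NA scales", {
  path <- system.file("extdata", "aaindex1_sample.txt", package = "malopred")
  tab <- parse_aaindex1(path)
  expect_identical(rownames(tab), c("KYTJ820101", "HOPT810101"))
  expect_equal(tab["KYTJ820101", c("A", "V", "R")], c(A = 1.8, V = 4.2, R = -4.5))
  expect_equal(tab["HOPT810101", "W"], -3.4)
})

test_that("PSSM parsing round-trips written profiles and slices windows", {
  set.seed(10)
  prof <- matrix(sample(-5:8, 100 * 20, replace = TRUE), 100, 20,
                 dimnames = list(NULL, aa_standard()))
  res <- sample(aa_standard(), 100, replace = TRUE)
  path <- tempfile(fileext = ".pssm")
  write_pssm_ascii(prof, res, path)
  parsed <- parse_pssm_profile(path)
  expect_equal(parsed, prof, ignore_attr = TRUE)
  sl <- parse_pssm_profile(path, window_slice = 5:35)
  expect_identical(dim(sl), c(31L, 20L))
  expect_equal(sl, prof[5:35, ], ignore_attr = TRUE)
  expect_identical(attr(sl, "residues"), res[5:35])
  expect_error(parse_pssm_profile(path, window_slice = 90:110), "out of range")
  expect_error(parse_pssm_profile(c("no header", "here")), "header")
})

test_that("surrogate profiles use substitution rows and zero padding", {
  f <- paste(c("X", rep("A", 14), "K", rep("C", 15)), collapse = "")
  m <- pseudo_pssm(f)
  expect_identical(dim(m), c(31L, 20L))
  expect_true(all(m[1, ] == 0))                    # padding row
  expect_equal(unname(m[16, "K"]), 5)              # BLOSUM62 K->K
  expect_true(isTRUE(attr(m, "surrogate")))
  f33 <- paste(c(rep("A", 16), "K", rep("C", 16)), collapse = "")
  expect_identical(dim(pseudo_pssm(f33)), c(33L, 20L))
})

test_that("feature export writes readable text", {
  f <- random_fragment(15)
  pv <- tempfile(fileext = ".csv"); pm <- tempfile(fileext = ".txt")
  export_feature(encode_aac(f), pv)
  expect_equal(as.numeric(utils::read.csv(pv)), unname(encode_aac(f)))
  export_feature(encode_onehot(f), pm)
  m <- as.matrix(utils::read.table(pm, skip = 1))
  expect_equal(unname(m), unname(encode_onehot(f)))
})
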