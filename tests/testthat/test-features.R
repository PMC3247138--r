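k <- load_constants()

test_that("sequence validation: sanitization, case, minimum length", {
  s <- protein_sequence("x", paste(rep("acdefghiklmnpqrstvwy", 2), collapse = ""))
  expect_equal(s$length, 40L)
  expect_error(protein_sequence("x", strrep("AXB", 20)), "nonstandard")
  dropped <- protein_sequence("x", paste0(strrep("A", 35), "XXB"),
                              sanitize = "drop")
  expect_equal(dropped$residues, strrep("A", 35))
  expect_error(protein_sequence("x", strrep("A", 30)), "too short")
  expect_error(protein_sequence("x", paste0(strrep("A", 30), "XX"),
                                sanitize = "drop"), "too short")
})

test_that("amino acid composition: exact counts and oracle equality", {
  homo <- protein_sequence("h", strrep("A", 40))
  f <- compute_aac(homo)
  expect_equal(unname(f["A"]), 1)
  expect_equal(sum(f), 1)

  s31 <- protein_sequence("s31", paste0(paste(AMINO_ACIDS, collapse = ""),
                                        strrep("A", 11)))
  f31 <- compute_aac(s31)
  expect_equal(unname(f31["A"]), 12 / 31)
  expect_true(all(abs(f31[setdiff(AMINO_ACIDS, "A")] - 1 / 31) < 1e-15))

  s <- random_seq(500, seed = 11)
  expect_equal(compute_aac(s), naive_aac(s), tolerance = 1e-12)
})

test_that("dipeptide composition: patterns and oracle equality", {
  homo <- protein_sequence("h", strrep("A", 40))
  d <- compute_dc(homo)
  expect_equal(unname(d["AA"]), 1)
  expect_equal(sum(d), 1)

  alt <- protein_sequence("ac", strrep("AC", 20))  # L = 40
  d2 <- compute_dc(alt)
  expect_equal(unname(d2["AC"]), 20 / 39)
  expect_equal(unname(d2["CA"]), 19 / 39)

  s <- random_seq(500, seed = 12)
  expect_equal(compute_dc(s), naive_dc(s), tolerance = 1e-12)
})

test_that("autocorrelation descriptors match the naive-loop oracle", {
  s <- random_seq(200, seed = 13)
  for (pid in 1:8) {
    P <- k$properties[[pid]]$standardized_values
    for (kind in c("NMB", "Moran", "Geary")) {
      expect_close(compute_autocorrelation(s, k$properties[[pid]], kind),
                   naive_autocorr(s, P, kind), rel_tol = 1e-12)
    }
  }
})

test_that("autocorrelation degenerate cases", {
  homo <- protein_sequence("h", strrep("A", 40))
  p1 <- k$properties[[1]]
  pa <- unname(p1$standardized_values["A"])
  expect_equal(compute_autocorrelation(homo, p1, "NMB"), rep(pa^2, 30))
  expect_equal(compute_autocorrelation(homo, p1, "Moran"), rep(0, 30))
  expect_equal(compute_autocorrelation(homo, p1, "Geary"), rep(0, 30))
  expect_error(compute_autocorrelation(
    structure(list(id = "t", residues = strrep("A", 30), length = 30L),
              class = "protein_sequence"), p1, "NMB"), "too short")
})

test_that("mean Moran lag-1 autocorrelation of i.i.d. sequences is ~0", {
  vals <- vapply(1:200, function(r) {
    s <- random_seq(1000, seed = 5000 + r)
    compute_autocorrelation(s, k$properties[[1]], "Moran")[1]
  }, numeric(1))
  se <- sd(vals) / sqrt(length(vals))
  expect_lt(abs(mean(vals)), 3 * se + 1e-12)
})

test_that("Moran and Geary are invariant to affine rescaling of the raw scale", {
  s <- random_seq(150, seed = 14)
  p <- k$properties[[3]]
  shifted <- p
  shifted$raw_values <- 7 * p$raw_values + 3
  shifted$standardized_values <- standardize_property(shifted$raw_values)
  for (kind in c("Moran", "Geary")) {
    expect_equal(compute_autocorrelation(s, shifted, kind),
                 compute_autocorrelation(s, p, kind), tolerance = 1e-12)
  }
})

test_that("global descriptors reproduce the printed two-symbol worked example", {
  seqstr <- "BABBABABBABBAABABABBAAABBABABA"
  g <- ifelse(strsplit(seqstr, "")[[1]] == "A", 1L, 2L)
  v <- round(featkit:::ctd_descriptors(g, 3L), 2)
  expect_equal(v[1:3], c(46.67, 53.33, 0))                    # Comp
  # the worked example computes Tran as (21/29)*100; its printed rendering
  # transposes the decimals (72.14), the formula value is 72.41
  expect_equal(v[4:6], c(72.41, 0, 0))                        # Tran
  expect_equal(v[7:11], c(6.67, 23.33, 53.33, 73.33, 100.00)) # Dist(A)
  expect_equal(v[12:16], c(3.33, 20.00, 40.00, 66.67, 96.67)) # Dist(B)
  expect_equal(v[17:21], rep(0, 5))                           # absent symbol
})

test_that("global descriptors: single-group sequence and absent groups", {
  # alanine maps to group 2 of the relative-hydrophobicity scheme; build the
  # expectation pattern generically from the scheme
  sch <- k$groupings[[7]]
  homo <- protein_sequence("h", strrep("A", 40))
  gi <- which(vapply(sch$groups, function(g) "A" %in% g, logical(1)))
  v <- compute_global_descriptors(homo, sch)
  comp_exp <- rep(0, 3); comp_exp[gi] <- 100
  expect_equal(v[1:3], comp_exp)
  expect_equal(v[4:6], rep(0, 3))
  dist_exp <- rep(0, 15)
  dist_exp[(gi - 1) * 5 + 1:5] <- c(2.5, 25, 50, 75, 100)
  expect_equal(v[7:21], dist_exp)
})

test_that("global descriptors match the naive prose implementation", {
  s <- random_seq(300, seed = 15)
  for (sch in k$groupings) {
    expect_equal(compute_global_descriptors(s, sch),
                 naive_ctd(recode3(s, sch)), tolerance = 1e-12)
  }
})

test_that("sequence-order-coupling numbers: closed forms and oracle", {
  homo <- protein_sequence("h", strrep("A", 40))
  G <- k$distances$grantham
  expect_equal(compute_socn(homo, G), rep(0, 30))

  alt <- protein_sequence("ac", strrep("AC", 20))  # alternating, L = 40
  tau <- compute_socn(alt, G)
  dac <- G$values["A", "C"]
  expected <- vapply(1:30, function(j)
    if (j %% 2 == 1) (40 - j) * dac^2 else 0, numeric(1))
  expect_equal(tau, expected)

  s <- random_seq(100, seed = 16)
  for (dm in k$distances) {
    expect_close(compute_socn(s, dm), naive_socn(s, dm$values), rel_tol = 1e-12)
  }
})

test_that("quasi-sequence-order descriptors: normalization and oracle", {
  homo <- protein_sequence("h", strrep("A", 40))
  q <- compute_qso(homo, k$distances$grantham)
  expect_equal(q[match("A", AMINO_ACIDS)], 1)
  expect_equal(sum(abs(q[-match("A", AMINO_ACIDS)])), 0)

  s <- random_seq(120, seed = 17)
  for (dm in k$distances) {
    q <- compute_qso(s, dm)
    expect_equal(sum(q), 1, tolerance = 1e-12)
    expect_close(q, naive_qso(s, dm$values), rel_tol = 1e-12)
  }
})

test_that("pseudo amino acid composition: normalization and oracle", {
  homo <- protein_sequence("h", strrep("A", 40))
  v <- compute_pseaac(homo)
  expect_equal(v[match("A", AMINO_ACIDS)], 1)
  expect_equal(v[21:50], rep(0, 30))

  s <- random_seq(150, seed = 18)
  v <- compute_pseaac(s)
  expect_equal(sum(v), 1, tolerance = 1e-12)
  expect_close(v, naive_pseaac(s, pseaac_H()), rel_tol = 1e-12)
})

test_that("full feature vector: block structure, determinism, order sensitivity", {
  s <- random_seq(90, seed = 19)
  v <- extract_features(s)
  expect_length(v, 1497L)
  fb <- feature_blocks()
  expect_equal(fb$length, c(20L, 400L, 720L, 147L, 160L, 50L))
  expect_equal(fb$end[6], 1497L)

  # determinism: bitwise identical on repeated calls
  expect_identical(v, extract_features(s))

  # a shuffled copy keeps the composition block, changes order-aware blocks
  set.seed(20)
  perm <- protein_sequence("perm", paste(sample(seq_chars(s)), collapse = ""))
  vp <- extract_features(perm)
  expect_equal(unname(vp[1:20]), unname(v[1:20]), tolerance = 1e-12)
  ad <- (fb$start[3]):(fb$end[3])
  expect_gt(max(abs(vp[ad] - v[ad])), 1e-6)
})
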