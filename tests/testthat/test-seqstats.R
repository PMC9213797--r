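test_that("charge statistics match the reference values for the EK family", {
  for (pat in c("alternating", "diblock", "block_length_5")) {
    s <- ek_variant(pat)
    expect_equal(unname(net_charge_per_residue(s)), 0)
    expect_equal(unname(fraction_charged(s)), 1)
    expect_equal(unname(mean_hydropathy(s)), 0.8)
    expect_equal(unname(disorder_fraction(s)), 1)
    expect_equal(unname(classify_phase(s)), "Strong polyampholytes")
  }
  expect_equal(unname(charge_kappa(ek_variant("diblock"))), 1)
})

test_that("charge statistics match the reference values for amyloid beta", {
  ab <- abeta40()
  expect_equal(unname(net_charge_per_residue(ab)), -0.075)
  expect_equal(unname(fraction_charged(ab)), 0.225)
  expect_equal(round(unname(mean_hydropathy(ab)), 3), 4.558)
  expect_equal(unname(disorder_fraction(ab)), 0.6)
  expect_equal(unname(classify_phase(ab)), "Weak polyampholytes")
})

test_that("simple closed-form cases evaluate exactly", {
  expect_equal(unname(net_charge_per_residue("EE")), -1)
  expect_equal(unname(fraction_charged("GGGG")), 0)
  expect_equal(unname(mean_hydropathy("IIII")), 9)
  expect_equal(unname(disorder_fraction("IIII")), 0)
})

test_that("invalid sequences raise structured errors", {
  expect_error(net_charge_per_residue(""), "non-empty")
  expect_error(mean_hydropathy("EKX"), "non-standard")
  expect_error(charge_kappa("EK"), "blob size")
})

test_that("kappa is undefined without charges and bounded otherwise", {
  expect_true(is.na(charge_kappa("GGGGGG")))
  expect_lt(unname(charge_kappa(ek_variant("alternating"))), 1)
  set.seed(42)
  for (i in 1:20) {
    k <- charge_kappa(random_seq(30, min_charged = 2))
    if (!is.na(k)) expect_true(k >= 0 && k <= 1)
  }
})

test_that("segregated diblock arrangements score kappa of exactly 1", {
  # any composition with both signs, arranged negatives/neutrals/positives
  set.seed(7)
  for (i in 1:10) {
    nneg <- sample(3:10, 1)
    npos <- sample(3:10, 1)
    nneu <- sample(0:10, 1)
    s <- paste(c(rep("E", nneg), rep("G", nneu), rep("K", npos)),
               collapse = "")
    expect_equal(unname(charge_kappa(s)), 1)
  }
})

test_that("kappa is reversal-invariant; composition stats are permutation-invariant", {
  set.seed(11)
  for (i in 1:10) {
    s <- random_seq(40, min_charged = 4)
    res <- strsplit(s, "")[[1]]
    rev_s <- paste(rev(res), collapse = "")
    perm <- paste(sample(res), collapse = "")
    expect_equal(charge_kappa(s), charge_kappa(rev_s))
    expect_equal(net_charge_per_residue(s), net_charge_per_residue(perm))
    expect_equal(fraction_charged(s), fraction_charged(perm))
    expect_equal(mean_hydropathy(s), mean_hydropathy(perm))
  }
})

test_that("|NCPR| <= FCR and hydropathy stays in [0, 9] on random sequences", {
  set.seed(3)
  for (i in 1:30) {
    s <- random_seq(sample(10:80, 1))
    expect_lte(abs(net_charge_per_residue(s)), fraction_charged(s))
    h <- mean_hydropathy(s)
    expect_true(h >= 0 && h <= 9)
    expect_true(disorder_fraction(s) >= 0 && disorder_fraction(s) <= 1)
  }
})

test_that("Das-Pappu regions follow the (f+, f-) boundaries", {
  expect_equal(classify_phase(fplus = 0.1, fminus = 0.1),
               "Weak polyampholytes")
  expect_equal(classify_phase(fplus = 0.15, fminus = 0.15),
               "Janus sequences")
  expect_equal(classify_phase(fplus = 0.3, fminus = 0.3),
               "Strong polyampholytes")
  expect_equal(classify_phase(fplus = 0.05, fminus = 0.5),
               "Strong polyelectrolytes")
  # a strong polyelectrolyte by sequence: mostly glutamate
  expect_equal(unname(classify_phase(paste(c(rep("E", 40), rep("G", 30),
                                             rep("K", 5)),
                                           collapse = ""))),
               "Strong polyelectrolytes")
})

test_that("seq_profile assembles the per-sequence table", {
  prof <- seq_profile(c(sv30 = unname(ek_variant("diblock")), abeta40()))
  expect_s3_class(prof, "tbl_df")
  expect_equal(names(prof), c("name", "length", "ncpr", "fcr", "kappa",
                              "hydropathy", "disorder", "category"))
  expect_equal(prof$name[1], "sv30")
  expect_equal(prof$length, c(50L, 40L))
  expect_equal(prof$kappa[1], 1)
})

test_that("FASTA round trip preserves sequences", {
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">sv30", ek_variant("diblock"), ">ab", abeta40()), path)
  seqs <- read_sequences(path)
  expect_equal(unname(seqs),
               unname(c(ek_variant("diblock"), abeta40())))
  expect_equal(names(seqs), c("sv30", "ab"))
})
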