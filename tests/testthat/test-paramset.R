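doc <- builtin_parameter_set()

test_that("shipped parameter set has the full published section counts", {
  expect_equal(nrow(doc$bonds), 22L)
  expect_equal(nrow(doc$angles), 56L)
  expect_equal(nrow(doc$torsions), 40L)
  expect_equal(length(unique(doc$torsions$group)), 25L)
  expect_equal(nrow(doc$impropers), 13L)
  expect_equal(nrow(doc$nonbonded), 10L)
  expect_equal(nrow(doc$mass), 10L)
})

test_that("spot values match the printed tables exactly", {
  b <- frcmod_lookup(doc, "bond", c("cc", "cd"))
  expect_identical(b$k_r, 500.9)
  expect_identical(b$r_eq, 1.3729)
  expect_identical(frcmod_lookup(doc, "bond", c("c", "o"))$k_r, 637.7)
  expect_identical(frcmod_lookup(doc, "bond", c("nf", "CX"))$r_eq, 1.4560)

  a <- frcmod_lookup(doc, "angle", c("cc", "nc", "cd"))
  expect_identical(a$k_theta, 71.8)
  expect_identical(a$theta_eq, 105.49)
  expect_identical(frcmod_lookup(doc, "angle", c("C", "ne", "cf"))$theta_eq,
                   118.53)
  expect_identical(frcmod_lookup(doc, "angle", c("cd", "C*", "CB"))$theta_eq,
                   128.6)

  t1 <- frcmod_lookup(doc, "torsion", c("ha", "cc", "cd", "N"))
  expect_equal(nrow(t1), 1L)
  expect_identical(t1$paths_divisor, 4L)
  expect_identical(t1$half_barrier, 16.0)
  expect_identical(t1$phase, 180)
  expect_identical(t1$periodicity, 2L)

  im <- frcmod_lookup(doc, "improper", c("X", "X", "c", "o"))
  expect_identical(im$half_barrier, 10.5)
  expect_identical(im$phase, 180)
  expect_identical(im$periodicity, 2L)
  expect_true(all(doc$impropers$phase == 180))
  expect_true(all(doc$impropers$periodicity == 2L))
  expect_true(all(doc$impropers$half_barrier %in% c(10.5, 1.1)))

  nb <- frcmod_lookup(doc, "nonbonded", "ha")
  expect_identical(nb$r_star, 1.459)
  expect_identical(nb$epsilon, 0.015)
  expect_identical(frcmod_lookup(doc, "nonbonded", "o")$r_star, 1.6612)
  expect_identical(frcmod_lookup(doc, "mass", "c")$polarizability, 0.616)
})

test_that("multi-term sidechain torsions are stored as linked continuations", {
  tt <- frcmod_lookup(doc, "torsion", c("cd", "CX", "3C", "CT"))
  expect_equal(nrow(tt), 4L)
  expect_equal(tt$half_barrier, c(0.112, 0.148, 0.289, 0.406))
  expect_equal(tt$periodicity, c(4L, 3L, 2L, 1L))
  expect_equal(tt$phase, c(0, 0, 180, 180))
  expect_true(all(tt$paths_divisor == 1L))
  # written with the AMBER continuation convention
  txt <- write_frcmod(doc)
  cx3c <- grep("^cd-CX-3C-CT", txt, value = TRUE)
  expect_equal(length(cx3c), 4L)
  pers <- as.integer(sub(".*?(-?\\d+)\\s+#.*", "\\1", cx3c))
  expect_equal(pers, c(-4L, -3L, -2L, 1L))
})

test_that("lookup is symmetric for bonds and angles and honours wildcards", {
  for (i in seq_len(nrow(doc$bonds))) {
    fwd <- frcmod_lookup(doc, "bond", c(doc$bonds$a1[i], doc$bonds$a2[i]))
    rev <- frcmod_lookup(doc, "bond", c(doc$bonds$a2[i], doc$bonds$a1[i]))
    expect_identical(fwd, rev)
  }
  for (i in seq_len(nrow(doc$angles))) {
    tup <- c(doc$angles$a1[i], doc$angles$a2[i], doc$angles$a3[i])
    expect_identical(frcmod_lookup(doc, "angle", tup),
                     frcmod_lookup(doc, "angle", rev(tup)))
  }
  # explicit quadruples beat wildcard entries wherever both match
  d <- doc$torsions
  explicit <- d[d$a1 != "X" & !duplicated(d$group), , drop = FALSE]
  for (i in seq_len(nrow(explicit))) {
    q <- c(explicit$a1[i], explicit$a2[i], explicit$a3[i], explicit$a4[i])
    hit <- frcmod_lookup(doc, "torsion", q)
    expect_false(any(hit$a1 == "X"))
    expect_equal(hit$group[1L], explicit$group[i])
  }
  # improper: central atom fixed, outer atoms unordered, X matches anything
  im1 <- frcmod_lookup(doc, "improper", c("ha", "nd", "cc", "cd"))
  expect_identical(im1$a3, "cc")
  expect_identical(im1$half_barrier, 1.1)
  expect_identical(frcmod_lookup(doc, "improper", c("CX", "c", "nd", "cd")),
                   frcmod_lookup(doc, "improper", c("c", "CX", "nd", "cd")))
  expect_error(frcmod_lookup(doc, "improper", c("cc", "cc", "zz", "cc")),
               "no improper")
  expect_error(frcmod_lookup(doc, "bond", c("zz", "qq")), "no bond")
})

test_that("serialization round trips field-for-field and byte-identically", {
  txt <- write_frcmod(doc)
  back <- parse_frcmod(txt)
  expect_equal(back, doc)
  expect_identical(write_frcmod(back), txt)
  # empty document: header plus empty sections
  empty <- frcmod_document(title = "empty")
  etxt <- write_frcmod(empty)
  expect_true(all(c("MASS", "BOND", "ANGLE", "DIHE", "IMPROPER", "NONBON")
                  %in% etxt))
  eback <- parse_frcmod(etxt)
  expect_equal(nrow(eback$bonds), 0L)
  expect_identical(write_frcmod(eback), etxt)
})

test_that("malformed documents and files are rejected with named offenders", {
  dup <- doc
  dup$bonds <- rbind(dup$bonds, dup$bonds[1, ])
  expect_error(write_frcmod(dup), "cc-cd")
  rev_dup <- doc
  row <- rev_dup$bonds[1, ]
  row[, c("a1", "a2")] <- row[, c("a2", "a1")]
  rev_dup$bonds <- rbind(rev_dup$bonds, row)
  expect_error(write_frcmod(rev_dup), "duplicate bond")

  txt <- write_frcmod(doc)
  bad <- c(txt[1], "FOO", txt[-1])
  expect_error(parse_frcmod(bad), "unknown section|unexpected content")
  bad2 <- sub("500.9", "fivehundred", txt, fixed = TRUE)
  expect_error(parse_frcmod(bad2), "line")

  # new bonded types must appear in MASS and NONBON
  orphan <- doc
  orphan$bonds$a1[1] <- "zz"
  expect_error(write_frcmod(orphan), "zz")
})

test_that("random documents survive write-parse-write byte-identically", {
  for (seed in 1:10) {
    rd <- random_frcmod(seed)
    txt <- write_frcmod(rd)
    back <- parse_frcmod(txt)
    expect_equal(back, rd)
    expect_identical(write_frcmod(back), txt)
  }
})
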