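test_that("site strings derive from the seed span by reverse complement", {
  m <- omy_mir122()
  expect_equal(site_sequence(m, "6mer")$residues, "CACTCC")
  expect_equal(site_sequence(m, "7mer-m8")$residues, "ACACTCC")
  expect_equal(site_sequence(m, "7mer-A1")$residues, "CACTCCA")
  expect_equal(site_sequence(m, "8mer")$residues, "ACACTCCA")
  polyA <- mature_mirna("pa", strrep("A", 10), seed_span = c(1, 6))
  expect_equal(site_sequence(polyA, "6mer")$residues, "TTTTTT")
  short <- mature_mirna("s", "AUGCUGA", seed_span = c(2, 7))
  expect_error(site_sequence(short, "7mer-m8"), "outside")
  expect_error(mature_mirna("s", "AUGC", seed_span = c(2, 7)), "within")
})

test_that("scanning reports every occurrence, including overlaps", {
  m <- omy_mir122()
  ts <- scan_utrs(c(u1 = "AAACACTCCAAA"), m)
  expect_equal(ts$sites$start, 4L)
  expect_equal(ts$target_ids, "u1")
  ts <- scan_utrs(c(u1 = "CACTCCACTCC"), m)
  expect_equal(ts$sites$start, c(1L, 6L))
  # N never matches
  ts <- scan_utrs(c(u1 = "AAACANTCCAAA", u2 = "CACTCN"), m)
  expect_equal(nrow(ts$sites), 0L)
  expect_equal(length(ts$target_ids), 0L)
  expect_error(scan_utrs(list(), m), "empty UTR set")
  expect_error(scan_utrs(c(u1 = "ACGT"), m, site_types = character(0)),
               "at least one site type")
  # RNA UTRs are coerced before matching
  ts <- scan_utrs(list(nuc_sequence("r1", "AAACACUCCAAA", "RNA")), m)
  expect_equal(ts$sites$start, 4L)
})

test_that("scanning equals the brute-force window oracle on random UTRs", {
  m <- omy_mir122()
  set.seed(303)
  utrs <- stats::setNames(
    vapply(1:60, function(i) rand_dna(sample(6:200, 1)), ""),
    sprintf("u%03d", 1:60))
  for (st in c("6mer", "7mer-A1", "7mer-m8", "8mer")) {
    ts <- scan_utrs(utrs, m, st)
    pat <- site_sequence(m, st)$residues
    for (id in names(utrs)) {
      expect_identical(ts$sites$start[ts$sites$utr_id == id],
                       oracle_scan_starts(utrs[[id]], pat))
    }
  }
})

test_that("adding site types never removes targets", {
  m <- omy_mir122()
  set.seed(99)
  utrs <- stats::setNames(vapply(1:80, function(i) rand_dna(300), ""),
                          sprintf("u%02d", 1:80))
  t6 <- scan_utrs(utrs, m, "6mer")
  tall <- scan_utrs(utrs, m, c("6mer", "7mer-A1", "7mer-m8", "8mer"))
  expect_true(all(t6$target_ids %in% tall$target_ids))
})

test_that("planted sites are recovered exactly and clean pools stay clean", {
  pool <- simulate_utrs(n_utrs = 120, planted_target_fraction = 0.25,
                        sites_per_target = 2, length_range = c(80, 300),
                        seed = 21)
  ts <- scan_utrs(pool$utrs, omy_mir122())
  expect_identical(ts$target_ids, pool$truth$target_ids)
  # every recorded planted position is reported
  key <- paste(ts$sites$utr_id, ts$sites$start)
  expect_true(all(paste(pool$truth$sites$utr_id, pool$truth$sites$start) %in% key))
  none <- simulate_utrs(n_utrs = 50, planted_target_fraction = 0,
                        length_range = c(50, 150), seed = 22)
  expect_equal(length(scan_utrs(none$utrs, omy_mir122())$target_ids), 0L)
})

test_that("ortholog mapping keeps order and reports unmapped ids", {
  mp <- ortholog_map(c("t1", "t2"), c("H1", "H2"))
  res <- map_orthologs(c("t1", "t2", "t3"), mp)
  expect_equal(res$n_mapped, 2L)
  expect_equal(res$mapped$ortholog_id, c("H1", "H2"))
  expect_equal(res$unmapped, "t3")
  empty <- ortholog_map(character(0), character(0))
  res <- map_orthologs(c("a", "b"), empty)
  expect_equal(res$n_mapped, 0L)
  expect_equal(res$unmapped, c("a", "b"))
  expect_message(ortholog_map(c("a", "a"), c("X", "Y")), "duplicate")
  # an 83-target set with a 76-entry map: 76 mapped, 7 unmapped
  targets <- sprintf("trout%03d", 1:83)
  mp83 <- ortholog_map(targets[1:76], sprintf("HUM%03d", 1:76))
  res <- map_orthologs(targets, mp83)
  expect_equal(res$n_mapped, 76L)
  expect_equal(length(res$unmapped), 7L)
})

test_that("conserved-target percentage uses half-up whole-percent rounding", {
  nine <- c("dditl4", "igf2", "parp3", "rtn3", "serpinh1", "socs6", "ucp2a",
            "slc2a1", "adam10")
  cf <- conserved_fraction(83, nine)
  expect_equal(cf$overlap, 9L)
  expect_equal(cf$percent, 100 * 9 / 83)
  expect_equal(cf$percent_rounded, 11)
  expect_equal(conserved_fraction(10, "x")$percent_rounded, 10)
  expect_equal(conserved_fraction(c("a", "b"), c("x", "y"))$overlap, 0L)
  expect_equal(conserved_fraction(c("a", "b"), c("x", "y"))$percent, 0)
  expect_error(conserved_fraction(character(0), "x"), "empty")
  # id-based overlap is case-insensitive, and 0.5 rounds up
  cf <- conserved_fraction(c("A", "b", "c", "d"), c("a", "B"))
  expect_equal(cf$overlap, 2L)
  expect_equal(cf$percent_rounded, 50)
  expect_equal(conserved_fraction(8, c("x", "y", "z", "w"))$percent_rounded, 50)
})

test_that("background 6mer density on random UTRs matches the analytic rate", {
  # (L - 5)/4^6 expected sites per uniform UTR of length L
  pool <- simulate_utrs(n_utrs = 2000, planted_target_fraction = 0,
                        background = "natural", length_range = c(500, 500),
                        seed = 77)
  ts <- scan_utrs(pool$utrs, omy_mir122())
  counts <- table(factor(ts$sites$utr_id, levels = names(pool$utrs)))
  expected <- (500 - 5) / 4^6
  se <- stats::sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - expected), 3 * se)
})
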