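test_that("global alignment handles trivial and degenerate inputs", {
  aln <- pairwise_align("ACGT", "ACGT")
  expect_equal(aln$score, 4)
  expect_equal(aln$a_aln, "ACGT")
  expect_equal(aln$b_aln, "ACGT")
  expect_error(pairwise_align("ACGT", ""), "nonempty")
})

test_that("alignment scores are optimal against an independent aligner", {
  skip_if_not_installed("Biostrings")
  bs_score <- function(a, b, match, mismatch, gap) {
    m <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch,
                                                  baseOnly = TRUE)
    Biostrings::score(Biostrings::pairwiseAlignment(
      a, b, substitutionMatrix = m, gapOpening = 0, gapExtension = -gap,
      type = "global"))
  }
  expect_equal(pairwise_align("GATTACA", "GCATGCT", gap = -1)$score,
               bs_score("GATTACA", "GCATGCT", 1, -1, -1))
  set.seed(11)
  for (i in 1:20) {
    a <- rand_dna(sample(4:12, 1)); b <- rand_dna(sample(4:12, 1))
    prm <- list(match = sample(1:3, 1), mismatch = -sample(1:3, 1),
                gap = -sample(1:3, 1))
    mine <- pairwise_align(a, b, prm$match, prm$mismatch, prm$gap)
    expect_equal(mine$score, bs_score(a, b, prm$match, prm$mismatch, prm$gap))
    # the returned alignment realizes the returned score
    ac <- strsplit(mine$a_aln, "")[[1]]; bc <- strsplit(mine$b_aln, "")[[1]]
    realized <- sum(ifelse(ac == "-" | bc == "-", prm$gap,
                           ifelse(ac == bc, prm$match, prm$mismatch)))
    expect_equal(realized, mine$score)
    expect_equal(gsub("-", "", mine$a_aln), a)
    expect_equal(gsub("-", "", mine$b_aln), b)
  }
})

test_that("progressive msa degaps to its inputs and aligns easy families", {
  s <- rand_dna(70)
  two <- as_family(c(a = s, b = s))
  aln <- progressive_msa(two)
  expect_equal(aln$ncol, 70)
  expect_false(any(grepl("-", aln$rows, fixed = TRUE)))
  # substitution-only family: hand alignment is the sequences themselves
  base <- "ACGTACGTACGTACGTACGT"
  v1 <- base; substr(v1, 5, 5) <- "T"
  v2 <- base; substr(v2, 12, 12) <- "A"
  aln3 <- progressive_msa(as_family(c(r = base, s1 = v1, s2 = v2)))
  expect_identical(aln3$rows, c(base, v1, v2))
  expect_error(progressive_msa(as_family(c(a = base))), "at least 2")
  # indel-bearing simulated families still degap to their inputs
  for (seed in 1:5) {
    fam <- simulate_family(n_species = 8, seed = seed,
                           rates = c(mature = 0, star = 0.1, loop = 0.35))$family
    aln <- progressive_msa(as_family(fam))
    expect_identical(unname(degap(aln)), unname(fam))
    expect_identical(names(degap(aln)), names(fam))
  }
})

test_that("conservation profile is the modal non-gap residue fraction", {
  aln <- msa(c("a", "b"), c("ACGT", "ACGT"))
  expect_equal(conservation_profile(aln)$score, rep(1, 4))
  aln <- msa(letters[1:4], c("A", "A", "C", "G"))
  expect_equal(conservation_profile(aln)$score, 0.5)
  aln <- msa(letters[1:3], c("A", "-", "A"))
  p <- conservation_profile(aln)
  expect_equal(p$score, 1)
  expect_equal(p$gap_fraction, 1 / 3)
  expect_false(p$flagged)
  # gap-majority flagged; all-gap undefined; a half-gapped column is not flagged
  aln <- msa(letters[1:4], c("AA-", "-A-", "-A-", "-A-"))
  p <- conservation_profile(aln)
  expect_equal(p$flagged, c(TRUE, FALSE, TRUE))
  expect_true(is.na(p$score[3]))
  expect_equal(p$score[1:2], c(1, 1))
})

test_that("region conservation projects reference coordinates and ranks regions", {
  fam <- simulate_family(n_species = 10, seed = 5,
                         rates = c(mature = 0, star = 0.05, loop = 0.3))
  aln <- progressive_msa(as_family(fam$family))
  rc <- region_conservation(aln, annot = fam$annotation)
  expect_equal(rc$mean_score[rc$region == "mature"], 1.0)
  # identical family: every region fully conserved
  same <- stats::setNames(rep(rand_dna(72), 3), c("sp01", "sp02", "sp03"))
  rc2 <- region_conservation(progressive_msa(as_family(same)),
                             annot = default_hairpin_annotation("sp01"))
  expect_equal(rc2$mean_score, rep(1, 3))
  bad <- region_annotation("sp01", mature = c(40, 70), star = c(1, 20),
                           loop = c(25, 35))
  expect_error(region_conservation(aln, annot = region_annotation(
    "sp01", mature = c(60, 80), star = c(1, 20), loop = c(25, 35))),
    "outside reference")
  expect_error(region_conservation(aln, annot = region_annotation(
    "zz", mature = c(5, 26), star = c(42, 63), loop = c(27, 41))),
    "not in msa")
})

test_that("region annotation invariants are enforced", {
  expect_error(region_annotation("r", mature = c(5, 15), star = c(42, 63),
                                 loop = c(27, 41)), ">= 18")
  expect_error(region_annotation("r", mature = c(5, 26), star = c(20, 45),
                                 loop = c(27, 41)), "non-overlapping")
  expect_error(region_annotation("r", mature = c(26, 5), star = c(42, 63),
                                 loop = c(27, 41)), "start <= end")
})

test_that("region conservation ordering follows planted substitution rates", {
  ok <- 0L
  for (seed in 1:20) {
    fam <- simulate_family(n_species = 12, seed = seed,
                           rates = c(mature = 0, star = 0.05, loop = 0.3))
    aln <- progressive_msa(as_family(fam$family))
    rc <- region_conservation(aln, annot = fam$annotation)
    sc <- stats::setNames(rc$mean_score, rc$region)
    if (sc["mature"] == 1 && sc["mature"] > sc["star"] && sc["star"] > sc["loop"]) {
      ok <- ok + 1L
    }
  }
  expect_gte(ok, 19L)
})
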