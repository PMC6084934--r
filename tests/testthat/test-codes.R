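test_that("the standard code has the canonical structure", {
  sgc <- standardCode()
  expect_length(sgc@assignment, 61L)
  expect_setequal(unique(sgc@assignment), aminoAcids())
  expect_identical(stopCodons(), c("TAA", "TAG", "TGA"))
  # six-fold Leu/Ser/Arg, single-codon Met/Trp
  for (aa in c("L", "S", "R")) expect_length(codonsOf(sgc, aa), 6L)
  expect_identical(codonsOf(sgc, "M"), "ATG")
  expect_identical(codonsOf(sgc, "W"), "TGG")
  expect_identical(degeneracyProfile(sgc),
                   c(`1` = 2L, `2` = 9L, `3` = 1L, `4` = 5L, `6` = 3L))
})

test_that("degeneracy profile sums to 61 and survives whole-set swaps", {
  sgc <- standardCode()
  prof <- degeneracyProfile(sgc)
  expect_equal(sum(as.integer(names(prof)) * prof), 61L)
  swapped <- swapAminoAcids(sgc, "L", "F")  # 6-codon vs 2-codon swap
  expect_identical(degeneracyProfile(swapped), prof)
  set.seed(42)
  g <- randomCode("GEN")
  expect_identical(degeneracyProfile(swapAminoAcids(g, "A", "Y")),
                   degeneracyProfile(g))
})

test_that("assignment vectors have 61 ones and the documented Hamming law", {
  sgc <- standardCode()
  v <- assignmentVector(sgc)
  expect_length(v, 1220L)
  expect_equal(sum(v), 61L)
  expect_true(all(colSums(matrix(v, nrow = 20L)) == 1L))
  # one reassigned codon flips exactly two bits
  one <- sgc@assignment
  one["TTT"] <- "L"
  v2 <- assignmentVector(new("GeneticCode", assignment = one))
  expect_equal(sum(v != v2), 2L)
  # Met<->Trp swap: two single-codon amino acids, four changed indicators
  vswap <- assignmentVector(swapAminoAcids(sgc, "M", "W"))
  expect_equal(sum(v != vswap), 4L)
  # Hamming distance is twice the number of differing codons, any models
  set.seed(7)
  for (model in c("DEG", "BLO", "NUM", "GEN")) {
    a <- randomCodeOf(model); b <- randomCodeOf(model)
    expect_equal(sum(assignmentVector(a) != assignmentVector(b)),
                 2L * sum(a@assignment != b@assignment))
  }
})

test_that("codes round-trip through the assignment vector", {
  set.seed(11)
  for (model in c("DEG", "BLO", "NUM", "GEN")) {
    code <- randomCodeOf(model)
    back <- codeFromAssignmentVector(assignmentVector(code))
    expect_identical(back@assignment, code@assignment)
  }
  expect_error(codeFromAssignmentVector(rep(0L, 1220L)), "exactly one")
  expect_error(codeFromAssignmentVector(rep(1L, 10L)), "length 1220")
})

test_that("swapAminoAcids matches the Met/Trp example and is an involution", {
  sgc <- standardCode()
  sw <- swapAminoAcids(sgc, "M", "W")
  expect_identical(unname(sw@assignment["TGG"]), "M")
  expect_identical(unname(sw@assignment["ATG"]), "W")
  same <- sw@assignment == sgc@assignment
  expect_equal(sum(!same), 2L)
  expect_identical(swapAminoAcids(sw, "M", "W")@assignment, sgc@assignment)
  expect_error(swapAminoAcids(sgc, "M", "M"), "itself")
})

test_that("validateCode applies the model constraint hierarchy", {
  sgc <- standardCode()
  for (m in c("DEG", "BLO", "NUM", "GEN"))
    expect_true(validateCode(sgc, m)$valid)
  # whole-set swap of unequal-degeneracy amino acids: BLO yes, NUM/DEG no
  sw <- swapAminoAcids(sgc, "L", "F")
  expect_true(validateCode(sw, "BLO")$valid)
  rep <- validateCode(sw, "NUM")
  expect_false(rep$valid)
  expect_match(rep$violations, "codon count", all = FALSE)
  expect_false(validateCode(sw, "DEG")$valid)
  # breaking a block: invalid under BLO, fine under GEN
  a <- sgc@assignment
  a["TTT"] <- "L"
  broken <- new("GeneticCode", assignment = a)
  expect_false(validateCode(broken, "BLO")$valid)
  expect_true(validateCode(broken, "GEN")$valid)
})

test_that("constructors reject malformed tables with specific errors", {
  tab <- codonTable(standardCode())
  expect_identical(geneticCode(tab)@assignment, standardCode()@assignment)
  expect_error(geneticCode(tab[-1]), "missing codon")
  bad <- tab; names(bad)[1] <- names(bad)[2]
  expect_error(geneticCode(bad), "duplicate codon")
  bad <- tab; bad["TGG"] <- "*"
  expect_error(geneticCode(bad), "stop set mismatch")
  bad <- tab; bad["TTT"] <- "B"
  expect_error(geneticCode(bad), "unknown amino-acid")
  bad <- tab[tab != "*"]; bad[] <- "A"   # not surjective
  expect_error(geneticCode(bad), "missing amino acid")
})
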