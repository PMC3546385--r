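test_that("kinship recursion reproduces textbook relationships", {
  ped <- pedigree(tibble::tibble(
    id = c("P", "Q", "O", "S", "H1", "H2"),
    sex = c("F", "M", "F", "M", "F", "M"),
    birth_year = c(1, 1, 2, 1, 2, 2),
    mother_id = c(NA, NA, "P", NA, "P", "P"),
    father_id = c(NA, NA, "Q", NA, "Q", "S")
  ))
  K <- kinship_matrix(ped)
  expect_identical(K["P", "Q"], 0)           # founders unrelated
  expect_identical(K["P", "O"], 0.25)        # parent-offspring kinship
  expect_identical(relatedness(K, "H1", "H2"), 0.25)  # maternal half sibs
  expect_identical(relatedness(K, "H1", "O"), 0.5)    # full sibs
  expect_error(relatedness(K, "P", "P"), "distinct")
  expect_error(relatedness(K, "P", "nope"), "not present")
})

test_that("worked aunt-half-niece example gives 0.125 and 0.375", {
  K <- kinship_matrix(aunt_halfniece_pedigree())
  expect_identical(relatedness(K, "AUNT2", "NIECE"), 0.125)
  expect_identical(relatedness(K, "AUNT", "NIECE"), 0.375)
})

test_that("three-loop inbred offspring has f = 0.080078125 exactly", {
  f <- inbreeding(three_loop_pedigree())
  expect_identical(f$f[f$id == "X"], 41 / 512)
  expect_identical(round(f$f[f$id == "X"], 5), 0.08008)
  # the three loops, via the oracle on the parents
  kin <- oracle_maker(three_loop_pedigree())
  expect_identical(kin("PM", "QF"), 1 / 16 + 1 / 64 + 1 / 512)
})

test_that("inbreeding follows parental kinship", {
  ped <- pedigree(tibble::tibble(
    id = c("A", "B", "S1", "S2", "C"),
    sex = c("F", "M", "F", "M", "F"),
    birth_year = c(1, 1, 2, 2, 3),
    mother_id = c(NA, NA, "A", "A", "S1"),
    father_id = c(NA, NA, "B", "B", "S2")
  ))
  f <- inbreeding(ped)
  expect_identical(f$f[f$id == "C"], 0.25)  # full-sib mating
  expect_identical(f$f[f$id == "S1"], 0)    # offspring of founders
})

test_that("recursive kinship agrees with the path-counting oracle", {
  for (s in 1:25) {
    ped <- random_pedigree(n = sample(10:30, 1), n_founders = sample(4:8, 1),
                           seed = s)
    K <- kinship_matrix(ped)
    Ko <- oracle_kinship_matrix(ped)
    expect_lt(max(abs(K - Ko[rownames(K), colnames(K)])), 1e-12)
  }
})

test_that("kinship matrix identities hold on random pedigrees", {
  for (s in 101:110) {
    ped <- random_pedigree(n = 25, seed = s)
    K <- kinship_matrix(ped)
    f <- inbreeding(ped)
    expect_identical(K, t(K))
    expect_equal(diag(K) - 0.5, 0.5 * f$f, ignore_attr = TRUE)
    expect_true(all(K >= 0 & K <= 1))
  }
})

test_that("adding a shared-father link never decreases relatedness", {
  base <- tibble::tibble(
    id = c("G", "S2", "D", "S1", "A", "M", "B"),
    sex = c("F", "M", "M", "M", "F", "F", "F"),
    birth_year = c(1, 1, 1, 1, 2, 2, 3),
    mother_id = c(NA, NA, NA, NA, "G", "G", "M"),
    father_id = c(NA, NA, NA, NA, "S1", "S2", "D")
  )
  without <- kinship_matrix(pedigree(base))
  with_link <- base
  with_link$father_id[with_link$id == "A"] <- "D"
  with <- kinship_matrix(pedigree(with_link))
  expect_gt(relatedness(with, "A", "B"), relatedness(without, "A", "B"))
})

test_that("pedigree validation rejects malformed input", {
  expect_error(pedigree(tibble::tibble(
    id = c("A", "B"), sex = c("F", "M"),
    mother_id = c(NA, "C"), father_id = c(NA, NA)
  )), "not in the pedigree")
  expect_error(pedigree(tibble::tibble(
    id = c("A", "B"), sex = c("M", "F"),
    mother_id = c(NA, "A"), father_id = c(NA, NA)
  )), "male")
  expect_error(pedigree(tibble::tibble(
    id = c("A", "B"), sex = c("F", "M"), birth_year = c(5, 5),
    mother_id = c(NA, "A"), father_id = c(NA, NA)
  )), "older")
  # parent-link cycle (no birth years so only the graph can catch it)
  expect_error(pedigree(tibble::tibble(
    id = c("A", "B"), sex = c("F", "M"),
    mother_id = c("B", NA), father_id = c(NA, "A")
  )), "male|cycle")
  expect_error(pedigree(tibble::tibble(
    id = c("A", "B", "C"), sex = c("F", "F", "F"),
    mother_id = c("B", "C", "A"), father_id = c(NA, NA, NA)
  )), "cycle")
})

test_that("full-sibship sizes partition by parent pair", {
  st <- micro_study()
  sib <- sibship_sizes(st$ped)
  expect_setequal(sib$size, c(2L, 1L))
  expect_identical(attr(sib, "mean_size"), 1.5)
  # all-distinct pairs
  ped2 <- random_pedigree(n = 12, seed = 3)
  kids <- ped2[!is.na(ped2$mother_id) & !is.na(ped2$father_id), ]
  sib2 <- sibship_sizes(ped2)
  expect_identical(sum(sib2$size), nrow(kids))
  empty <- sibship_sizes(pedigree(tibble::tibble(
    id = "A", sex = "F", mother_id = NA, father_id = NA
  )))
  expect_identical(nrow(empty), 0L)
  expect_true(is.na(attr(empty, "mean_size")))
})

test_that("matrilines trace the maternal line to a founder female", {
  ped <- pedigree(tibble::tibble(
    id = c("F0", "S", "D1", "D2", "SON", "ORPH"),
    sex = c("F", "M", "F", "F", "M", "F"),
    birth_year = c(1, 1, 2, 3, 3, 2),
    mother_id = c(NA, NA, "F0", "D1", "D1", NA),
    father_id = c(NA, NA, "S", "S", "S", "S")
  ))
  ml <- matrilines(ped)
  expect_identical(matriline_of(ped, "F0"), "F0")
  expect_identical(matriline_of(ped, "D2"), "F0")
  expect_identical(matriline_of(ped, "SON"), "F0")  # through the mother
  # ORPH's maternal chain ends at a non-founder (father known)
  expect_true(is.na(ml$matriline[ml$id == "ORPH"]))
  expect_true(is.na(matriline_of(ped, "S")))        # male founder
})
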